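#' Configuration for an end-to-end synthetic run
#'
#' @param out_dir run directory (created)
#' @param n_samples bulk cohort size
#' @param modes reference modes to run (subset of TIIC+PBMC / TIIC / PBMC)
#' @param model_kind classifier for the combination search
#' @param subset_sizes combination sizes searched (default 1:3; `NULL`
#'   searches all 2^k - 1 subsets)
#' @param n_repeats Monte Carlo splits (default 100)
#' @param n_trees ensemble size per fit
#' @param fdr_threshold,min_delta_beta,max_per_class signature selection
#' @param p_threshold DMC cutoff
#' @param window_bp RE proximity window
#' @param sim a [sim_config()] object (the benchmark conditions)
#' @param seed master seed for splits/models (generator seeds live in `sim`)
#' @return validated list of class `run_config`
#' @export
run_config <- function(out_dir, n_samples = 100,
                       modes = c("TIIC+PBMC", "TIIC", "PBMC"),
                       model_kind = "extra_trees", subset_sizes = 1:3,
                       n_repeats = 100, n_trees = 50,
                       fdr_threshold = 0.05, min_delta_beta = 0.2,
                       max_per_class = 200, p_threshold = 0.001,
                       window_bp = 1250, sim = sim_config(), seed = 1L) {
  stopifnot(all(modes %in% c("TIIC+PBMC", "TIIC", "PBMC")), n_samples >= 2)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic pipeline: simulate, signature, deconvolve,
#' predict, interpret
#'
#' Stages execute in order, every intermediate artifact is written under
#' `out_dir`, and a JSON manifest records seeds, counts and wall-clock per
#' stage. The same configuration reproduces every output.
#'
#' @param config a [run_config()] object
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seeds = list(sim = config$sim$seed, run = config$seed),
                   stages = list())
  tic <- function() proc.time()[["elapsed"]]
  stage_t0 <- tic()
  note <- function(name, info) {
    manifest$stages[[name]] <<- c(list(seconds = round(tic() - stage_t0, 2)),
                                  info)
    stage_t0 <<- tic()
  }

  # simulate
  genome <- generate_toy_genome(config$sim)
  refs <- generate_reference_profiles(genome, config$sim)
  cohort <- generate_bulk_cohort(refs$atlas, genome, config$sim,
                                 config$n_samples)
  sim_dir <- file.path(config$out_dir, "sim")
  write_methylome(refs$atlas, sim_dir, "atlas")
  write_methylome(cohort$bulk, sim_dir, "bulk")
  write_bed6(genome$re_intervals, file.path(sim_dir, "res.bed"))
  write_re_targets(genome$re_targets, file.path(sim_dir, "re_targets.tsv"))
  write_gmt(genome$gene_sets, file.path(sim_dir, "gene_sets.gmt"))
  write.table(cohort$clinical, file.path(sim_dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(true_proportions = as.data.frame(cohort$truth$true_proportions),
         label_model = cohort$truth$label_model,
         planted_state_dmcs = refs$truth$planted_state_dmcs,
         planted_class_markers = refs$truth$planted_class_markers),
    file.path(sim_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  note("simulate", list(n_cpgs = config$sim$n_cpgs,
                        n_samples = config$n_samples))

  # signature + deconvolution per mode
  uni <- intersect_universe(refs$atlas, cohort$bulk)
  signatures <- props <- list()
  for (mode in config$modes) {
    sig <- select_signature_cpgs(uni$atlas, mode,
                                 fdr_threshold = config$fdr_threshold,
                                 min_delta_beta = config$min_delta_beta,
                                 max_per_class = config$max_per_class)
    tag <- gsub("[+]", "_", mode)
    write_signature(sig, file.path(config$out_dir,
                                   paste0("signature_", tag, ".tsv")),
                    file.path(config$out_dir,
                              paste0("signature_", tag, ".json")))
    pr <- deconvolve_cohort(uni$bulk, sig)
    write.table(as.data.frame(pr),
                file.path(config$out_dir, paste0("proportions_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    signatures[[mode]] <- sig
    props[[mode]] <- pr
  }
  note("signature_deconvolution",
       list(signature_sizes = lapply(signatures, function(s)
         length(s$cpg_ids))))

  # recurrence prediction: shared splits across modes
  splits <- monte_carlo_splits(config$n_samples, cohort$clinical$recurrence,
                               n_repeats = config$n_repeats,
                               seed = config$seed)
  reports <- list()
  for (mode in config$modes) {
    labs <- props[[mode]]$class_labels
    combos <- enumerate_combinations(labs)
    if (!is.null(config$subset_sizes)) {
      combos <- combos[lengths(combos) %in% config$subset_sizes]
    }
    rep_ <- search_combinations(props[[mode]], cohort$clinical, combos,
                                splits = splits,
                                model_kind = config$model_kind,
                                n_trees = config$n_trees,
                                seed = config$seed)
    tag <- gsub("[+]", "_", mode)
    write.table(rep_$ranking,
                file.path(config$out_dir, paste0("ranking_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    reports[[mode]] <- rep_
  }
  note("recurrence", list(n_repeats = config$n_repeats,
                          n_combinations = lapply(reports, function(r)
                            nrow(r$ranking))))

  # interpretation: DMC categories, enrichment, DC-marker hypomethylation
  interp <- NULL
  if ("TIIC+PBMC" %in% names(signatures)) {
    sig <- signatures[["TIIC+PBMC"]]
    cats <- categorize_signature_dmcs(sig, uni$atlas,
                                      p_threshold = config$p_threshold)
    mapping <- map_cpgs_to_res(cats$members[["TIIC-PBMC"]], genome,
                               window_bp = config$window_bp)
    bg_map <- map_cpgs_to_res(uni$atlas$cpg_ids, genome,
                              window_bp = config$window_bp)
    enr <- if (nrow(mapping)) {
      enrich_go(unique(mapping$gene), unique(bg_map$gene), genome$gene_sets)
    }
    dc_dmcs <- call_dmcs(uni$atlas, "TIIC-DC", "PBMC-DC",
                         p_threshold = config$p_threshold)
    markers <- marker_hypomethylation_test(
      dc_dmcs, c("HLA-DRA", "CCR7", "CD40", "CCL22", "IFNG", "IL12", "CD86"),
      genome, window_bp = config$window_bp)
    if (!is.null(enr)) {
      write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(markers, file.path(config$out_dir, "dc_markers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    interp <- list(categories = cats$counts, enrichment = enr,
                   markers = markers)
    note("interpretation", list(dmc_categories = as.list(cats$counts)))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genome = genome, atlas = refs$atlas, truth = refs$truth,
                 cohort = cohort, signatures = signatures,
                 proportions = props, reports = reports,
                 interpretation = interp, manifest = manifest))
}
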