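test_that("CpG-to-RE mapping uses an inclusive base-distance window", {
  re_map <- list(intervals = data.frame(chrom = "chr1", start = 2000L,
                                        end = 2100L, re_id = "RE1"),
                 re_targets = c(RE1 = "GENE1"))
  hit <- function(pos) nrow(map_cpgs_to_res(paste0("chr1:", pos), re_map))
  expect_equal(hit(1000), 1)   # gap 1000 <= 1250
  expect_equal(hit(100), 0)    # gap 1900 > 1250
  expect_equal(hit(750), 1)    # gap exactly 1250: inclusive boundary
  expect_equal(hit(749), 0)    # gap 1251 just outside
  expect_equal(hit(2050), 1)   # inside the interval, distance 0
  expect_equal(hit(3349), 1)   # right side: 3349 - 2099 = 1250
  expect_equal(hit(3350), 0)   # 1251 > 1250
  m <- map_cpgs_to_res("chr1:1000", re_map)
  expect_equal(m$gene, "GENE1")
  expect_equal(m$distance, 1000)
  expect_error(map_cpgs_to_res("chrX:1000", re_map), "chrX")
})

test_that("mapping agrees with a brute-force all-pairs scan", {
  set.seed(17)
  n_cpg <- 200; n_re <- 60
  pos_df <- data.frame(chrom = sample(c("chr1", "chr2"), n_cpg, TRUE),
                       pos = sample.int(50000, n_cpg))
  pos_df <- pos_df[order(pos_df$chrom, pos_df$pos), ]
  pos_df <- pos_df[!duplicated(pos_df), ]
  starts <- sample.int(50000, n_re)
  intervals <- data.frame(chrom = sample(c("chr1", "chr2"), n_re, TRUE),
                          start = starts,
                          end = starts + sample(50:500, n_re, TRUE),
                          re_id = paste0("RE", seq_len(n_re)))
  re_map <- list(intervals = intervals,
                 re_targets = setNames(paste0("G", seq_len(n_re)),
                                       intervals$re_id))
  ids <- paste0(pos_df$chrom, ":", pos_df$pos)
  got <- map_cpgs_to_res(ids, re_map, window_bp = 1250)
  want <- map_brute(pos_df, intervals, 1250)
  got_keys <- sort(paste(got$cpg_id, got$re_id))
  want_keys <- sort(paste(ids[want[, 1]], intervals$re_id[want[, 2]]))
  expect_identical(got_keys, want_keys)
  # distances agree too
  want_d <- setNames(want[, 3], paste(ids[want[, 1]], intervals$re_id[want[, 2]]))
  expect_equal(unname(want_d[paste(got$cpg_id, got$re_id)]), got$distance)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  background <- paste0("g", 1:20)
  sets <- list(term5 = paste0("g", 1:5), all = background)
  enr <- enrich_go(paste0("g", 1:5), background, sets)
  expect_equal(enr$p[enr$term == "term5"], 1 / choose(20, 5), tolerance = 1e-12)
  # a term containing every background gene always overlaps fully
  expect_equal(enr$p[enr$term == "all"], 1)

  # single tested term: BH-adjusted equals raw
  e1 <- enrich_go(paste0("g", 1:5), background, sets["term5"])
  expect_equal(e1$adj_p, e1$p)

  # exhaustive enumeration on a 12-gene universe
  bg <- paste0("x", 1:12)
  term <- paste0("x", 1:5)
  target_size <- 4
  all_targets <- combn(12, target_size)
  for (obs_overlap in 0:3) {
    target <- c(term[seq_len(obs_overlap)],
                setdiff(bg, term)[seq_len(target_size - obs_overlap)])
    p_fn <- enrich_go(target, bg, list(t = term))$p
    overlaps <- apply(all_targets, 2, function(ix) sum(bg[ix] %in% term))
    expect_equal(p_fn, mean(overlaps >= obs_overlap), tolerance = 1e-12)
  }

  expect_error(enrich_go(c("g1", "zz"), background, sets), "zz")
  expect_error(enrich_go("g1", background, list()), "empty")

  # restriction to a configured term list drops other terms
  e2 <- enrich_go(paste0("g", 1:5), background, sets, restrict_to = "term5")
  expect_equal(e2$term, "term5")
})

test_that("DC-marker regions show the planted TIIC hypomethylation", {
  w <- small_world()
  d <- call_dmcs(w$atlas, "TIIC-DC", "PBMC-DC", return_all = TRUE)
  dmcs <- d[d$dmc, ]
  markers <- c("HLA-DRA", "CCR7", "CD40", "CCL22", "IFNG", "IL12", "CD86")
  mt <- marker_hypomethylation_test(dmcs, markers, w$genome)
  expect_setequal(mt$marker, markers)
  testable <- mt[mt$testable, ]
  expect_gt(nrow(testable), 0)
  expect_true(all(testable$mean_diff < 0))          # hypo in TIIC-DC
  expect_true(all(testable$direction == "hypo-in-a"))
  expect_lt(min(testable$p_value), 0.01)

  # identical profiles near a marker: no significant shift
  null_dmcs <- d[d$p > 0.5, ][1:20, ]
  null_dmcs$mean_b <- null_dmcs$mean_a            # force exact equality
  # give them fake proximity by testing against an RE map targeting CD40
  fake_map <- list(intervals = data.frame(
    chrom = methylstate:::split_cpg_id(null_dmcs$cpg_id)$chrom,
    start = methylstate:::split_cpg_id(null_dmcs$cpg_id)$pos + 10L,
    end = methylstate:::split_cpg_id(null_dmcs$cpg_id)$pos + 60L,
    re_id = paste0("F", 1:20)),
    re_targets = setNames(rep("CD40", 20), paste0("F", 1:20)))
  # jitter one value to avoid a zero-variance paired test
  null_dmcs$mean_a[1] <- null_dmcs$mean_a[1] + 1e-6
  mt0 <- marker_hypomethylation_test(null_dmcs, "CD40", fake_map)
  expect_gt(mt0$p_value[1], 0.3)

  # marker absent from the RE map is reported untestable
  mt_abs <- marker_hypomethylation_test(dmcs, "NOPE", w$genome)
  expect_false(mt_abs$testable)
  expect_match(mt_abs$reason, "absent")
})
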