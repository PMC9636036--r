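# plain-text readers/writers: TSV matrices keyed by "chrom:pos", BED6 REs,
# 2-column RE->gene TSV, GMT gene sets, clinical TSV, ground-truth JSON

#' Write a CpG x sample matrix as TSV
#'
#' @param mat matrix with CpG-id rownames
#' @param path output file
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(cpg_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a CpG x sample matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file with a `cpg_id` column
#' @return numeric matrix with CpG-id rownames
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$cpg_id
  m
}

#' Write regulatory elements as BED6
#'
#' 0-based half-open intervals; the name field carries the RE id.
#'
#' @param intervals data.frame chrom/start/end/re_id
#' @param path output file
#' @export
write_bed6 <- function(intervals, path) {
  bed <- data.frame(intervals$chrom, intervals$start, intervals$end,
                    intervals$re_id, 0L, ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read a BED6 file of regulatory elements
#'
#' @param path BED file
#' @return data.frame chrom/start/end/re_id
#' @export
read_bed6 <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
             re_id = bed[[4]], stringsAsFactors = FALSE)
}

#' Write/read the RE -> target-gene map as 2-column TSV
#'
#' @param re_targets named character vector (re_id -> gene)
#' @param path file path
#' @export
write_re_targets <- function(re_targets, path) {
  write.table(data.frame(re_id = names(re_targets), gene = unname(re_targets)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_re_targets
#' @export
read_re_targets <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(df$gene, df$re_id)
}

#' Write/read gene sets in GMT format
#'
#' @param gene_sets named list of gene vectors
#' @param path file path
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[`, "", 1L))
}

#' Write a reference atlas or bulk methylome to a directory
#'
#' Separate TSVs for betas, methylated and total counts, a BED3+name CpG
#' coordinate sidecar, and (for an atlas) a sample-annotation TSV.
#'
#' @param x `ReferenceAtlas` or `BulkMethylome`
#' @param dir output directory (created if needed)
#' @param prefix file-name prefix
#' @export
write_methylome <- function(x, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("betas", "meth", "total")) {
    if (!is.null(x[[f]])) {
      write_matrix_tsv(x[[f]], file.path(dir, paste0(prefix, "_", f, ".tsv")))
    }
  }
  cpg_bed <- data.frame(x$positions$chrom, x$positions$pos,
                        x$positions$pos + 1L, x$cpg_ids)
  write.table(cpg_bed, file.path(dir, paste0(prefix, "_cpgs.bed")),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(x$class_labels) && length(x$class_labels) == length(x$sample_ids)) {
    write.table(data.frame(sample_id = x$sample_ids, class = x$class_labels,
                           state = x$state),
                file.path(dir, paste0(prefix, "_samples.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

#' Write the signature matrix as TSV plus JSON metadata
#'
#' @param signature a `SignatureMatrix`
#' @param path_tsv,path_json output files
#' @export
write_signature <- function(signature, path_tsv, path_json) {
  df <- data.frame(cpg_id = signature$cpg_ids,
                   attributed_class = unname(signature$attribution),
                   signature$values, check.names = FALSE)
  write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(mode = signature$mode,
               n_cpgs = length(signature$cpg_ids),
               per_class = as.list(table(signature$attribution)))
  jsonlite::write_json(meta, path_json, auto_unbox = TRUE, pretty = TRUE)
}
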