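# small shared helpers

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Draw one or more Dirichlet vectors
#'
#' @param n number of draws
#' @param alpha concentration vector (all entries > 0)
#' @return an `n x length(alpha)` matrix whose rows sum to 1
#' @keywords internal
rdirichlet <- function(n, alpha) {
  if (any(alpha <= 0)) stop("dirichlet_alpha must be strictly positive")
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# "chrom:pos" CpG identifiers (0-based positions, BED convention)
cpg_id <- function(chrom, pos) paste0(chrom, ":", pos)

split_cpg_id <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
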