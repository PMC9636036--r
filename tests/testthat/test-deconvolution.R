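# a small synthetic signature with clean class-specific blocks
toy_signature <- function(K = 10, markers = 20, seed = 7) {
  set.seed(seed)
  n <- K * markers
  bg <- ifelse(rbinom(n, 1, 0.5) == 1, rbeta(n, 8, 0.5), rbeta(n, 0.5, 8))
  S <- matrix(rep(bg, K), n, K)
  for (k in seq_len(K)) {
    idx <- ((k - 1) * markers + 1):(k * markers)
    S[idx, k] <- bg[idx] + ifelse(bg[idx] < 0.5, 0.4, -0.4)
  }
  dimnames(S) <- list(paste0("chr1:", seq_len(n) * 100),
                      paste0("class", seq_len(K)))
  structure(list(cpg_ids = rownames(S), class_labels = colnames(S),
                 values = S, attribution = setNames(rep(colnames(S),
                                                        each = markers),
                                                    rownames(S)),
                 mode = "TIIC+PBMC"), class = "SignatureMatrix")
}

rdir <- function(n, K) {
  g <- matrix(rgamma(n * K, 1), n, K)
  g / rowSums(g)
}

test_that("nu-SVR recovers pure and mixed samples", {
  sig <- toy_signature()
  S <- sig$values
  r <- deconvolve_sample(S[, 3], sig)
  expect_equal(unname(r$proportions[3]), 1, tolerance = 1e-3)
  expect_lt(max(r$proportions[-3]), 1e-3)
  expect_false(r$degenerate)

  r2 <- deconvolve_sample(0.5 * S[, 1] + 0.5 * S[, 2], sig)
  expect_equal(unname(r2$proportions[1:2]), c(0.5, 0.5), tolerance = 0.01)

  # zero-variance column is rejected by name
  sig_bad <- sig; sig_bad$values[, 4] <- 0.5
  expect_error(deconvolve_sample(S[, 1], sig_bad), "class4")
  expect_error(deconvolve_sample(c(NA, S[-1, 1]), sig), "missing")
})

test_that("SVR agrees with the NNLS oracle on noiseless mixtures", {
  sig <- toy_signature()
  set.seed(11)
  W <- rdir(20, 10)
  for (i in seq_len(nrow(W))) {
    m <- drop(sig$values %*% W[i, ])
    svr <- deconvolve_sample(m, sig)$proportions
    nnls <- nnls_oracle(m, sig)$proportions
    expect_lt(max(abs(svr - nnls)), 0.02)
    expect_lt(max(abs(svr - W[i, ])), 0.02)
    expect_lt(max(abs(nnls - W[i, ])), 1e-6)   # oracle recovers exactly
  }
})

test_that("the NNLS oracle flags rank deficiency and handles pure columns", {
  sig <- toy_signature()
  r <- nnls_oracle(sig$values[, 5], sig)
  expect_equal(unname(r$proportions[5]), 1, tolerance = 1e-9)
  expect_true(r$unique)

  sig_flat <- sig
  sig_flat$values <- matrix(rep(sig$values[, 1], 3), ncol = 3,
                            dimnames = list(sig$cpg_ids, paste0("c", 1:3)))
  r2 <- nnls_oracle(sig$values[, 1], sig_flat)
  expect_false(r2$unique)
  expect_equal(sum(r2$proportions), 1)
})

test_that("proportions are simplex points, scale-invariant, noise-monotone", {
  sig <- toy_signature()
  set.seed(13)
  W <- rdir(10, 10)
  M <- sig$values %*% t(W)
  for (i in 1:10) {
    p <- deconvolve_sample(M[, i], sig)$proportions
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    # positive rescaling of the raw mixture leaves proportions unchanged
    # (standardization absorbs the scale entirely)
    p2 <- deconvolve_sample(5 * M[, i], sig)$proportions
    expect_equal(p, p2, tolerance = 1e-6)
  }

  # average recovery error is non-decreasing in the noise level
  err_at <- function(noise_sd) {
    errs <- numeric(0)
    for (seed in 1:2) {
      set.seed(100 + seed)
      Wn <- rdir(10, 10)
      Mn <- sig$values %*% t(Wn) +
        matrix(rnorm(nrow(sig$values) * 10, 0, noise_sd), ncol = 10)
      for (i in 1:10) {
        p <- deconvolve_sample(pmin(pmax(Mn[, i], 0), 1), sig)$proportions
        errs <- c(errs, mean(abs(p - Wn[i, ])))
      }
    }
    mean(errs)
  }
  errs <- vapply(c(0, 0.05, 0.15), err_at, 0)
  expect_true(all(diff(errs) >= -1e-4))
})

test_that("cohort deconvolution recovers known proportions from noisy data", {
  w <- small_world()
  uni <- intersect_universe(w$atlas, w$bulk)
  sig <- select_signature_cpgs(uni$atlas, "TIIC+PBMC")
  pr <- deconvolve_cohort(uni$bulk, sig)
  expect_s3_class(pr, "CellProportionTable")
  expect_true(all(abs(rowSums(pr$proportions) - 1) < 1e-9))
  W <- w$bulk_truth$true_proportions[, colnames(pr$proportions)]
  r_by_class <- vapply(colnames(W), function(k)
    cor(pr$proportions[, k], W[, k]), 0)
  expect_true(all(r_by_class >= 0.9))
  expect_true(all(is.finite(pr$diagnostics$rmse)))

  # empty cohort passes through without error
  empty <- methylstate:::subset_methylome(w$bulk, seq_along(w$bulk$cpg_ids))
  empty$betas <- empty$betas[, 0, drop = FALSE]
  empty$sample_ids <- character(0)
  pr0 <- deconvolve_cohort(empty, sig)
  expect_equal(nrow(pr0$proportions), 0)
})
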