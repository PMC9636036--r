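#' Deconvolve one bulk sample by linear-kernel nu-SVR
#'
#' CIBERSORT-style estimation: the signature matrix is standardized by its
#' global mean and standard deviation, the mixture by its own mean/sd (the
#' regression intercept absorbs the shift, so a convex mixing m = S w is
#' preserved). For each nu on the grid a linear-kernel nu-SVR of the
#' mixture on the signature columns is fitted; negative coefficients are
#' zeroed and the solution with the lowest RMSE of the unnormalized
#' reconstruction S w against the mixture is kept, then renormalized to
#' the simplex. An all-nonpositive solution returns the uniform vector
#' flagged degenerate.
#'
#' @param mixture_column numeric beta vector over the signature CpGs
#' @param signature a `SignatureMatrix`
#' @param nu_grid nu values to try (default 0.25, 0.5, 0.75)
#' @param cost SVR regularization constant (default 1)
#' @param standardize standardize signature/mixture (default TRUE; raw
#'   betas when FALSE)
#' @return list: `proportions` (named, sums to 1), `rmse`, `pearson_r`,
#'   `nu`, `degenerate`
#' @export
deconvolve_sample <- function(mixture_column, signature,
                              nu_grid = c(0.25, 0.5, 0.75), cost = 1,
                              standardize = TRUE) {
  S <- signature$values
  stopifnot(length(mixture_column) == nrow(S))
  csd <- apply(S, 2, sd)
  if (any(csd == 0)) {
    stop("zero-variance signature column: ",
         paste(colnames(S)[csd == 0], collapse = ", "))
  }
  if (any(is.na(mixture_column))) stop("mixture contains missing values; impute upstream")
  if (standardize) {
    Sz <- (S - mean(S)) / sd(as.vector(S))
    msd <- sd(mixture_column)
    mz <- if (msd > 0) (mixture_column - mean(mixture_column)) / msd
          else mixture_column - mean(mixture_column)
  } else {
    Sz <- S; mz <- mixture_column
  }
  best <- NULL
  for (nu in nu_grid) {
    fit <- e1071::svm(x = Sz, y = mz, type = "nu-regression",
                      kernel = "linear", nu = nu, cost = cost, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    w[w < 0] <- 0
    if (sum(w) == 0) {
      cand <- list(w = rep(1 / ncol(S), ncol(S)), rmse = Inf, nu = nu,
                   degenerate = TRUE)
    } else {
      recon <- drop(Sz %*% w)
      cand <- list(w = w, rmse = sqrt(mean((recon - mz)^2)), nu = nu,
                   degenerate = FALSE)
    }
    if (is.null(best) || cand$rmse < best$rmse) best <- cand
  }
  if (is.infinite(best$rmse)) {       # all grid points degenerate
    p <- setNames(rep(1 / ncol(S), ncol(S)), colnames(S))
    return(list(proportions = p, rmse = NA_real_, pearson_r = NA_real_,
                nu = best$nu, degenerate = TRUE))
  }
  p <- setNames(best$w / sum(best$w), colnames(S))
  recon <- drop(Sz %*% best$w)
  list(proportions = p, rmse = best$rmse,
       pearson_r = suppressWarnings(cor(recon, mz)),
       nu = best$nu, degenerate = FALSE)
}

#' Nonnegative-least-squares oracle for deconvolution
#'
#' Solves min ||S w - m||^2 subject to w >= 0 and renormalizes to the
#' simplex. Used as an independent check on the SVR solver. A rank-deficient
#' signature is flagged non-unique.
#'
#' @inheritParams deconvolve_sample
#' @return list: `proportions` (named, sums to 1), `unique` (FALSE when the
#'   signature is column-rank-deficient)
#' @export
nnls_oracle <- function(mixture_column, signature) {
  S <- signature$values
  stopifnot(length(mixture_column) == nrow(S))
  fit <- pracma::lsqnonneg(S, as.numeric(mixture_column))
  w <- fit$x
  if (sum(w) == 0) w <- rep(1 / ncol(S), ncol(S))
  list(proportions = setNames(w / sum(w), colnames(S)),
       unique = qr(S)$rank == ncol(S))
}

#' Deconvolve a whole cohort
#'
#' Applies [deconvolve_sample()] to every column of the mixture matrix
#' built by [build_mixture_matrix()]. Deterministic given its inputs.
#'
#' @param bulk a `BulkMethylome`
#' @param signature a `SignatureMatrix`
#' @param ... passed to [deconvolve_sample()]
#' @return object of class `CellProportionTable`: `proportions` (sample x
#'   class matrix), `diagnostics` (data.frame with rmse, pearson_r, nu,
#'   degenerate), `class_labels`, `sample_ids`
#' @export
deconvolve_cohort <- function(bulk, signature, ...) {
  bm <- build_mixture_matrix(bulk, signature)
  mixture <- bm$mixture; signature <- bm$signature
  n <- ncol(mixture)
  K <- ncol(signature$values)
  P <- matrix(0, n, K, dimnames = list(colnames(mixture),
                                       colnames(signature$values)))
  diag_df <- data.frame(sample_id = colnames(mixture) %||% seq_len(n),
                        rmse = numeric(n), pearson_r = numeric(n),
                        nu = numeric(n), degenerate = logical(n),
                        stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    r <- tryCatch(deconvolve_sample(mixture[, j], signature, ...),
                  error = function(e) stop("sample ", colnames(mixture)[j],
                                           ": ", conditionMessage(e)))
    P[j, ] <- r$proportions
    diag_df$rmse[j] <- r$rmse; diag_df$pearson_r[j] <- r$pearson_r
    diag_df$nu[j] <- r$nu; diag_df$degenerate[j] <- r$degenerate
  }
  structure(list(proportions = P, diagnostics = diag_df,
                 class_labels = colnames(P), sample_ids = rownames(P),
                 mode = signature$mode),
            class = "CellProportionTable")
}

#' @export
as.data.frame.CellProportionTable <- function(x, ...) {
  cbind(data.frame(sample_id = x$sample_ids, stringsAsFactors = FALSE),
        as.data.frame(x$proportions),
        x$diagnostics[, c("rmse", "pearson_r", "nu")])
}
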