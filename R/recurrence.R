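#' Enumerate all nonempty cell-state combinations
#'
#' Deterministic order: by subset size, then lexicographically within size.
#'
#' @param class_labels character vector (at most 16 labels)
#' @return list of character vectors (length `2^k - 1`)
#' @export
enumerate_combinations <- function(class_labels) {
  k <- length(class_labels)
  if (k < 1 || k > 16) {
    stop("combination search supports 1..16 labels; restrict the label list")
  }
  sorted <- sort(class_labels)
  out <- list()
  for (size in seq_len(k)) {
    subsets <- combn(sorted, size, simplify = FALSE)
    ord <- order(vapply(subsets, paste, "", collapse = "\r"))
    out <- c(out, subsets[ord])
  }
  out
}

#' Stratified Monte Carlo train/test splits
#'
#' Repeated random 70/30 splitting (by default), stratified by the binary
#' label so both classes appear in every train and test set. Reproducible
#' from `seed`.
#'
#' @param n_samples cohort size
#' @param labels binary 0/1 vector of length `n_samples`
#' @param train_fraction fraction of samples used for training (default 0.7)
#' @param n_repeats number of random splits (default 100)
#' @param seed integer seed
#' @param stratified stratify by label (default TRUE)
#' @param max_retries resample attempts when a split lacks a class
#' @return list of `n_repeats` lists with integer `train` and `test` indices
#' @export
monte_carlo_splits <- function(n_samples, labels, train_fraction = 0.7,
                               n_repeats = 100, seed = 1L,
                               stratified = TRUE, max_retries = 100) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == n_samples)
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2) {
    stop("both classes need >= 2 members for splitting")
  }
  set.seed(seed)
  n_train <- round(train_fraction * n_samples)
  make_split <- function() {
    if (stratified) {
      train <- integer(0)
      cls_idx <- split(seq_len(n_samples), labels)
      sizes <- vapply(cls_idx, length, 1L)
      raw <- train_fraction * sizes
      base <- floor(raw)
      rem <- n_train - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      } else if (rem < 0) {
        cut <- order(raw - base)[seq_len(-rem)]
        base[cut] <- base[cut] - 1L
      }
      base <- pmin(pmax(base, 1L), sizes - 1L)
      for (g in seq_along(cls_idx)) {
        train <- c(train, sample(cls_idx[[g]], base[g]))
      }
    } else {
      train <- sample.int(n_samples, n_train)
    }
    list(train = sort(train), test = sort(setdiff(seq_len(n_samples), train)))
  }
  out <- vector("list", n_repeats)
  for (i in seq_len(n_repeats)) {
    for (try in seq_len(max_retries)) {
      s <- make_split()
      if (length(unique(labels[s$train])) == 2) break
      if (try == max_retries) stop("could not form a split containing both classes")
    }
    out[[i]] <- s
  }
  out
}

#' Encode model features from proportions and clinical covariates
#'
#' Selected cell-state proportion columns plus encoded clinical fields:
#' TNM stage ordinal 1-4, binaries as 0/1, tumor location side/organ as
#' 0/1 indicators (right, rectum).
#'
#' @param proportions a `CellProportionTable` or a sample x class matrix
#' @param clinical data.frame as produced by [generate_bulk_cohort()]
#'   (or `NULL` when `clinical_fields` is empty)
#' @param combination character vector of cell-state classes to include
#' @param clinical_fields subset of `c("tnm", "metastasis", "msi", "side",
#'   "organ", "adjuvant")`
#' @return numeric feature matrix, one row per sample
#' @export
encode_features <- function(proportions, clinical = NULL,
                            combination = NULL,
                            clinical_fields = character(0)) {
  P <- if (inherits(proportions, "CellProportionTable")) proportions$proportions
       else as.matrix(proportions)
  combination <- combination %||% colnames(P)
  missing_cols <- setdiff(combination, colnames(P))
  if (length(missing_cols)) {
    stop("proportion columns missing: ", paste(missing_cols, collapse = ", "))
  }
  X <- P[, combination, drop = FALSE]
  enc <- list(
    tnm = function(cl) as.numeric(cl$tnm_stage),
    metastasis = function(cl) as.numeric(cl$metastasis),
    msi = function(cl) as.numeric(cl$msi),
    side = function(cl) as.numeric(cl$tumor_location_side == "right"),
    organ = function(cl) as.numeric(cl$tumor_location_organ == "rectum"),
    adjuvant = function(cl) as.numeric(cl$adjuvant_therapy)
  )
  for (f in clinical_fields) {
    if (!f %in% names(enc)) stop("unknown clinical field: ", f)
    X <- cbind(X, setNames(data.frame(enc[[f]](clinical)), f))
  }
  X <- as.matrix(X)
  if (anyNA(X)) stop("features contain missing values")
  X
}

# one fit + class-1 probability on the test rows
fit_predict_model <- function(Xtr, ytr, Xte, model_kind = "extra_trees",
                              n_trees = 50, seed = 1L, mtry = NULL,
                              min_split = 2L) {
  p <- ncol(Xtr)
  mtry <- mtry %||% max(1L, floor(sqrt(p)))
  if (model_kind == "extra_trees") {
    .et_fit_predict(Xtr, as.integer(ytr), Xte, as.integer(n_trees),
                    as.integer(mtry), as.integer(min_split),
                    as.integer(seed))$prob
  } else if (model_kind == "random_forest") {
    set.seed(seed)
    m <- ranger::ranger(x = Xtr, y = factor(ytr, levels = c(0, 1)),
                        num.trees = n_trees, mtry = min(mtry, p),
                        probability = TRUE, num.threads = 1, verbose = FALSE,
                        seed = seed)
    predict(m, Xte, num.threads = 1, verbose = FALSE)$predictions[, "1"]
  } else if (model_kind == "gradient_boosting") {
    dtr <- xgboost::xgb.DMatrix(Xtr, label = as.numeric(ytr), nthread = 1)
    m <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                    nthread = 1, seed = seed),
      data = dtr, nrounds = n_trees, verbose = 0)
    predict(m, xgboost::xgb.DMatrix(Xte, nthread = 1))
  } else {
    stop("unknown model_kind: ", model_kind)
  }
}

#' Evaluate one cell-state combination over Monte Carlo splits
#'
#' Per split: fit the chosen tree ensemble on the training rows, score
#' class-1 probabilities on the test rows; AUC via the rank formulation,
#' Cohen's kappa at probability threshold `kappa_threshold`. A test split
#' with one class yields `NA` for that split (excluded from means).
#'
#' @param proportions a `CellProportionTable` or sample x class matrix
#' @param clinical clinical data.frame (may be `NULL`)
#' @param combination character vector of cell-state classes
#' @param clinical_fields clinical fields to append (see [encode_features()])
#' @param splits list from [monte_carlo_splits()]
#' @param labels binary outcome vector (defaults to `clinical$recurrence`)
#' @param model_kind `"extra_trees"` (built-in), `"random_forest"` (ranger)
#'   or `"gradient_boosting"` (xgboost)
#' @param n_trees ensemble size per fit (default 50)
#' @param seed base seed; the per-split model seed is `seed + split index`
#' @param kappa_threshold probability cutoff for kappa (default 0.5)
#' @return list with per-split `auc` and `kappa` vectors
#' @export
train_eval_combination <- function(proportions, clinical, combination,
                                   clinical_fields = character(0), splits,
                                   labels = clinical$recurrence,
                                   model_kind = "extra_trees", n_trees = 50,
                                   seed = 1L, kappa_threshold = 0.5) {
  X <- encode_features(proportions, clinical, combination, clinical_fields)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(X))
  n_rep <- length(splits)
  auc <- kappa <- rep(NA_real_, n_rep)
  for (i in seq_len(n_rep)) {
    s <- splits[[i]]
    yte <- y[s$test]
    prob <- fit_predict_model(X[s$train, , drop = FALSE], y[s$train],
                              X[s$test, , drop = FALSE],
                              model_kind = model_kind, n_trees = n_trees,
                              seed = seed + i)
    auc[i] <- auc_rank(prob, yte)
    if (length(unique(yte)) == 2) {
      kappa[i] <- cohen_kappa(as.integer(prob >= kappa_threshold), yte)
    }
  }
  list(auc = auc, kappa = kappa, combination = combination,
       clinical_fields = clinical_fields)
}

#' Evaluate and rank many combinations on shared splits
#'
#' All combinations are scored on the same split list so that per-split
#' comparisons between combinations (and between reference modes) are
#' paired.
#'
#' @inheritParams train_eval_combination
#' @param combinations list of character vectors (e.g. from
#'   [enumerate_combinations()])
#' @param top_k rows to keep in the `top` table (default 10)
#' @return object of class `RecurrenceModelReport`: `ranking` data.frame,
#'   `auc` and `kappa` matrices (combination x split), `combinations`,
#'   `top`, `seed`
#' @export
search_combinations <- function(proportions, clinical, combinations,
                                clinical_fields = character(0), splits,
                                labels = clinical$recurrence,
                                model_kind = "extra_trees", n_trees = 50,
                                seed = 1L, top_k = 10) {
  n_comb <- length(combinations)
  n_rep <- length(splits)
  auc_mat <- matrix(NA_real_, n_comb, n_rep)
  kap_mat <- matrix(NA_real_, n_comb, n_rep)
  for (ci in seq_len(n_comb)) {
    r <- train_eval_combination(proportions, clinical, combinations[[ci]],
                                clinical_fields, splits, labels = labels,
                                model_kind = model_kind, n_trees = n_trees,
                                seed = seed)
    auc_mat[ci, ] <- r$auc
    kap_mat[ci, ] <- r$kappa
  }
  rank_combinations(combinations, auc_mat, kap_mat, top_k = top_k, seed = seed)
}

#' Rank evaluated combinations by mean AUC
#'
#' Descending mean AUC; ties broken by fewer features, then
#' lexicographically.
#'
#' @param combinations list of character vectors
#' @param auc_mat,kappa_mat combination x split matrices of per-split metrics
#' @param top_k rows in the `top` table
#' @param seed seed recorded in the report
#' @return `RecurrenceModelReport` (see [search_combinations()])
#' @export
rank_combinations <- function(combinations, auc_mat, kappa_mat = NULL,
                              top_k = 10, seed = NA_integer_) {
  key <- vapply(combinations, function(x) paste(sort(x), collapse = "+"), "")
  sizes <- lengths(combinations)
  mean_auc <- rowMeans(auc_mat, na.rm = TRUE)
  sd_auc <- apply(auc_mat, 1, sd, na.rm = TRUE)
  mean_kap <- if (is.null(kappa_mat)) NA_real_
              else rowMeans(kappa_mat, na.rm = TRUE)
  ord <- order(-mean_auc, sizes, key)
  ranking <- data.frame(
    combination = key[ord], n_classes = sizes[ord],
    mean_auc = mean_auc[ord], sd_auc = sd_auc[ord],
    mean_kappa = if (is.null(kappa_mat)) NA_real_ else mean_kap[ord],
    rank = seq_along(ord), stringsAsFactors = FALSE
  )
  structure(list(
    ranking = ranking,
    top = head(ranking, top_k),
    combinations = combinations[ord],
    auc = auc_mat[ord, , drop = FALSE],
    kappa = if (is.null(kappa_mat)) NULL else kappa_mat[ord, , drop = FALSE],
    seed = seed
  ), class = "RecurrenceModelReport")
}

#' Permutation-based feature importance with significance
#'
#' Fits the ensemble on the true labels to obtain observed (Gini)
#' importances, then `n_perms` times on label permutations; the per-feature
#' p-value is `(1 + #{null >= observed}) / (1 + n_perms)`, so a feature
#' dominating every null draw has p = 1/(n_perms + 1).
#'
#' @param features numeric feature matrix (>= 2 columns)
#' @param labels binary 0/1 outcome
#' @param n_perms number of response permutations (default 100)
#' @param mtry features tried per split (default 10, capped at `ncol`)
#' @param n_trees ensemble size (default 100)
#' @param seed integer seed
#' @param model_kind `"extra_trees"` (built-in) or `"random_forest"` (ranger)
#' @return data.frame with feature, observed importance and p-value
#' @export
permutation_feature_importance <- function(features, labels, n_perms = 100,
                                           mtry = 10, n_trees = 100,
                                           seed = 1L,
                                           model_kind = "extra_trees") {
  if (n_perms < 1) stop("n_perms must be >= 1")
  X <- as.matrix(features)
  if (ncol(X) < 2) stop("need >= 2 features")
  y <- as.integer(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  mtry <- min(mtry, ncol(X))
  imp_of <- function(yy, s) {
    if (model_kind == "extra_trees") {
      .et_fit_predict(X, yy, X[1, , drop = FALSE], as.integer(n_trees),
                      as.integer(mtry), 2L, as.integer(s))$importance
    } else {
      m <- ranger::ranger(x = X, y = factor(yy, levels = c(0, 1)),
                          num.trees = n_trees, mtry = mtry,
                          importance = "impurity", num.threads = 1,
                          verbose = FALSE, seed = s)
      unname(m$variable.importance)
    }
  }
  observed <- imp_of(y, seed)
  set.seed(seed)
  exceed <- numeric(ncol(X))
  for (b in seq_len(n_perms)) {
    null_imp <- imp_of(sample(y), seed + b)
    exceed <- exceed + (null_imp >= observed)
  }
  data.frame(
    feature = colnames(X) %||% paste0("f", seq_len(ncol(X))),
    importance = observed,
    p_value = (1 + exceed) / (1 + n_perms),
    stringsAsFactors = FALSE
  )
}

#' Train on one cohort, predict recurrence in another
#'
#' Fits `n_repeats` models (differing only in seed) on the full training
#' cohort and scores each on the full test cohort, mirroring cross-cohort
#' transfer of a fixed signature.
#'
#' @param train_proportions,test_proportions `CellProportionTable`s (same
#'   signature) or matrices with identical class columns
#' @param train_clinical,test_clinical clinical data.frames
#' @param combination cell-state classes used as features
#' @param clinical_fields clinical fields appended (must exist in both)
#' @param n_repeats model fits (default 100)
#' @param model_kind,n_trees,seed as in [train_eval_combination()]
#' @param kappa_threshold probability cutoff for kappa
#' @return list with per-repeat `auc` and `kappa` vectors
#' @export
cross_cohort_predict <- function(train_proportions, train_clinical,
                                 test_proportions, test_clinical,
                                 combination, clinical_fields = character(0),
                                 n_repeats = 100, model_kind = "extra_trees",
                                 n_trees = 100, seed = 1L,
                                 kappa_threshold = 0.5) {
  Xtr <- encode_features(train_proportions, train_clinical, combination,
                         clinical_fields)
  Xte <- encode_features(test_proportions, test_clinical, combination,
                         clinical_fields)
  if (!identical(colnames(Xtr), colnames(Xte))) {
    stop("feature mismatch between cohorts: ",
         paste(setdiff(colnames(Xtr), colnames(Xte)), collapse = ", "))
  }
  ytr <- as.integer(train_clinical$recurrence)
  yte <- as.integer(test_clinical$recurrence)
  auc <- kappa <- rep(NA_real_, n_repeats)
  for (i in seq_len(n_repeats)) {
    prob <- fit_predict_model(Xtr, ytr, Xte, model_kind = model_kind,
                              n_trees = n_trees, seed = seed + i)
    auc[i] <- auc_rank(prob, yte)
    kappa[i] <- cohen_kappa(as.integer(prob >= kappa_threshold), yte)
  }
  list(auc = auc, kappa = kappa)
}
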