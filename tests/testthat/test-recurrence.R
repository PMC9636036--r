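test_that("combination enumeration is complete and deterministically ordered", {
  expect_length(enumerate_combinations(letters[1:10]), 1023)
  cc <- enumerate_combinations(c("b", "a"))
  expect_equal(cc, list("a", "b", c("a", "b")))
  expect_equal(enumerate_combinations("x"), list("x"))
  expect_error(enumerate_combinations(letters[1:17]), "16")
})

test_that("Monte Carlo splits are stratified, sized and reproducible", {
  labels <- rep(c(0, 1), each = 5)
  sp <- monte_carlo_splits(10, labels, n_repeats = 20, seed = 9)
  expect_length(sp, 20)
  for (s in sp) {
    expect_length(s$train, 7)
    expect_length(s$test, 3)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), 1:10)
    expect_equal(length(unique(labels[s$train])), 2)
    expect_equal(length(unique(labels[s$test])), 2)
  }
  sp2 <- monte_carlo_splits(10, labels, n_repeats = 20, seed = 9)
  expect_identical(sp, sp2)
  expect_false(identical(sp, monte_carlo_splits(10, labels, n_repeats = 20,
                                                seed = 10)))
  expect_gt(length(unique(vapply(sp, function(s)
    paste(s$train, collapse = ","), ""))), 10)
  expect_error(monte_carlo_splits(6, rep(1, 6)), "both classes")
})

test_that("AUC and kappa match brute-force values on toy cases", {
  expect_equal(auc_rank(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  s <- c(0.1, 0.8, 0.2, 0.9); l <- c(0, 0, 1, 1)
  expect_equal(auc_rank(s, l), 0.75)
  expect_equal(auc_rank(s, l), auc_brute(s, l))
  # ties get half credit, matching the brute-force pair count
  st <- c(0.5, 0.5, 0.5, 0.9); lt <- c(0, 1, 0, 1)
  expect_equal(auc_rank(st, lt), auc_brute(st, lt))
  expect_true(is.na(auc_rank(1:3, c(1, 1, 1))))

  # confusion [[20,5],[10,15]]: po = 0.7, pe = 0.5 -> kappa 0.4
  truth <- rep(c(1, 1, 0, 0), c(20, 5, 10, 15))
  pred <- rep(c(1, 0, 1, 0), c(20, 5, 10, 15))
  expect_equal(cohen_kappa(pred, truth), 0.4)
  expect_equal(cohen_kappa(c(1, 0), c(1, 0)), 1)
})

test_that("rank-sum comparison matches enumeration and guards length", {
  a <- rep(0.9, 50); b <- rep(0.5, 50)
  expect_lt(compare_approaches(a, b), 1e-10)
  expect_gte(compare_approaches(a, a), 0.99)
  expect_error(compare_approaches(1:3, 4:6), ">= 10")

  # exact two-sided p for distinct values matches exhaustive enumeration
  set.seed(2)
  x <- round(runif(10), 3); y <- round(runif(10) + 0.3, 3)
  p_fn <- compare_approaches(x, y)
  pooled <- c(x, y)
  r_obs <- sum(rank(pooled)[1:10])
  combos <- combn(20, 10)
  null_sums <- colSums(matrix(rank(pooled)[combos], nrow = 10))
  mu <- 10 * 21 / 2
  p_exact <- mean(abs(null_sums - mu) >= abs(r_obs - mu) - 1e-9)
  expect_equal(p_fn, p_exact, tolerance = 1e-9)
})

test_that("per-split evaluation handles models, degenerate tests, rankings", {
  w <- small_world()
  P <- w$bulk_truth$true_proportions
  cl <- w$clinical
  splits <- monte_carlo_splits(nrow(P), cl$recurrence, n_repeats = 10, seed = 4)
  for (mk in c("extra_trees", "random_forest", "gradient_boosting")) {
    r <- train_eval_combination(P, cl, c("TIIC-CD8T", "TIIC-DC", "PBMC-DC"),
                                splits = splits, model_kind = mk,
                                n_trees = 30, seed = 6)
    expect_length(r$auc, 10)
    expect_true(all(r$auc >= 0 & r$auc <= 1, na.rm = TRUE))
    expect_true(all(r$kappa >= -1 & r$kappa <= 1, na.rm = TRUE))
  }
  # clinical covariates append as encoded columns
  X <- encode_features(P, cl, c("TIIC-DC"),
                       c("tnm", "metastasis", "msi", "side", "organ"))
  expect_equal(colnames(X)[-1], c("tnm", "metastasis", "msi", "side", "organ"))
  expect_true(all(X[, "tnm"] %in% 1:4))
  expect_error(encode_features(P, cl, "no-such-class"), "missing")

  # one-class test split yields NA AUC, excluded from the mean
  sp1 <- list(list(train = which(cl$recurrence %in% c(0, 1))[1:30],
                   test = which(cl$recurrence == 0)[1:5]))
  r1 <- train_eval_combination(P, cl, "TIIC-DC", splits = sp1, seed = 1)
  expect_true(is.na(r1$auc[1]))

  # ranking: higher mean first; ties broken by fewer features
  rep_ <- rank_combinations(list("a", c("a", "b"), "c"),
                            matrix(c(0.6, 0.6, 0.5), 3, 2,
                                   byrow = FALSE))
  expect_equal(rep_$ranking$combination, c("a", "a+b", "c"))
})

test_that("built-in extra-trees agrees with ranger's extratrees splitrule", {
  w <- small_world()
  P <- w$bulk_truth$true_proportions
  cl <- w$clinical
  splits <- monte_carlo_splits(nrow(P), cl$recurrence, n_repeats = 20, seed = 8)
  combo <- c("TIIC-CD8T", "TIIC-DC", "PBMC-DC")
  a <- train_eval_combination(P, cl, combo, splits = splits,
                              model_kind = "extra_trees", n_trees = 100,
                              seed = 2)
  X <- encode_features(P, NULL, combo)
  y <- factor(cl$recurrence, levels = c(0, 1))
  b_auc <- vapply(seq_along(splits), function(i) {
    s <- splits[[i]]
    m <- ranger::ranger(x = X[s$train, ], y = y[s$train], num.trees = 100,
                        splitrule = "extratrees", num.random.splits = 1,
                        probability = TRUE, num.threads = 1, verbose = FALSE,
                        seed = i)
    pr <- predict(m, X[s$test, ], num.threads = 1,
                  verbose = FALSE)$predictions[, "1"]
    auc_rank(pr, as.integer(as.character(y[s$test])))
  }, 0)
  expect_lt(abs(mean(a$auc, na.rm = TRUE) - mean(b_auc)), 0.05)
})

test_that("permutation importance flags real features and errors on misuse", {
  set.seed(3)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  X <- cbind(signal = y + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("noise", 1:4))))
  imp <- permutation_feature_importance(X, y, n_perms = 50, seed = 5)
  expect_equal(imp$p_value[1], 1 / 51)
  expect_gt(min(imp$p_value[-1]), 0.05)
  expect_error(permutation_feature_importance(X, y, n_perms = 0), "n_perms")
  expect_error(permutation_feature_importance(X[, 1, drop = FALSE], y), "features")
})

test_that("cross-cohort transfer retains performance and checks features", {
  cfg <- small_cfg(seed = 61L)
  g <- generate_toy_genome(cfg)
  refs <- generate_reference_profiles(g, cfg)
  c1 <- generate_bulk_cohort(refs$atlas, g, cfg, 80, seed = 100)
  c2 <- generate_bulk_cohort(refs$atlas, g, cfg, 80, seed = 200)
  combo <- c("TIIC-CD8T", "TIIC-DC", "PBMC-DC")
  tr <- cross_cohort_predict(c1$truth$true_proportions, c1$clinical,
                             c2$truth$true_proportions, c2$clinical,
                             combo, n_repeats = 20, seed = 3)
  expect_length(tr$auc, 20)
  expect_gt(mean(tr$auc), 0.6)   # signal transfers between cohorts

  # permuted test labels give chance-level transfer
  c2p <- c1$clinical; set.seed(7); c2p$recurrence <- sample(c2p$recurrence)
  tr0 <- cross_cohort_predict(c1$truth$true_proportions, c1$clinical,
                              c1$truth$true_proportions, c2p,
                              combo, n_repeats = 20, seed = 3)
  expect_lt(abs(mean(tr0$auc) - 0.5), 0.1)

  P2 <- c2$truth$true_proportions[, 1:5]
  expect_error(cross_cohort_predict(c1$truth$true_proportions, c1$clinical,
                                    P2, c2$clinical, combo),
               "missing")
})

test_that("informative clinical covariates do not hurt the best model", {
  cfg <- small_cfg(seed = 91L)
  g <- generate_toy_genome(cfg)
  refs <- generate_reference_profiles(g, cfg)
  co <- generate_bulk_cohort(refs$atlas, g, cfg, 150)
  splits <- monte_carlo_splits(150, co$clinical$recurrence,
                               n_repeats = 40, seed = 2)
  combo <- c("TIIC-CD8T", "TIIC-DC", "PBMC-DC")
  base <- train_eval_combination(co$truth$true_proportions, co$clinical,
                                 combo, splits = splits, n_trees = 50,
                                 seed = 3)
  with_cl <- train_eval_combination(co$truth$true_proportions, co$clinical,
                                    combo, c("tnm", "metastasis", "msi"),
                                    splits = splits, n_trees = 50, seed = 3)
  expect_gte(mean(with_cl$auc, na.rm = TRUE),
             mean(base$auc, na.rm = TRUE) - 0.02)
})
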