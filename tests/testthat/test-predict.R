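test_that("train/test split is a reproducible 1:1 partition", {
  ids <- sprintf("s%03d", 1:154)
  sp <- split_train_test(ids, seed = 3)
  expect_equal(sort(table(sp$set)), sort(c(train = 77L, test = 77L)),
               ignore_attr = TRUE)
  expect_setequal(sp$sample_id, ids)
  expect_equal(split_train_test(ids, seed = 3), sp)
  expect_false(identical(split_train_test(ids, seed = 4), sp))

  sp5 <- split_train_test(sprintf("x%d", 1:5), seed = 1)
  expect_equal(abs(diff(table(sp5$set))) <= 1, TRUE, ignore_attr = TRUE)
  expect_error(split_train_test(c("a", "b", "c"), seed = 1), "at least 4")

  strat <- rep(c(0, 1), c(100, 54))
  sps <- split_train_test(ids, seed = 5, stratify = strat)
  tab <- table(sps$set, strat[match(sps$sample_id, ids)])
  expect_true(all(abs(tab["train", ] - tab["test", ]) <= 1))
})

test_that("ridge IRLS reproduces the ML fit and survives separation", {
  set.seed(121)
  n <- 20
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 * X[, "a"] - 0.8 * X[, "b"]))
  fit <- fit_logistic_ridge(X, y, lambda = 0)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(predict(fit, X)),
               unname(fitted(ref)), tolerance = 1e-6)
  # perfectly separated feature: ridge keeps coefficients finite
  Xs <- cbind(s = ifelse(y == 1, 1, -1))
  fs <- fit_logistic_ridge(Xs, y)
  expect_true(all(is.finite(fs$coef)))
  expect_equal(roc_auc(predict(fs, Xs), y)$auc, 1.0)
})

test_that("heterozygote averaging at prediction time", {
  fit <- structure(list(coef = c("(Intercept)" = 0, f = 1),
                        converged = TRUE, lambda = 0),
                   class = "ridge_logit")
  rows <- tibble::tibble(sample_id = c("hom", "het", "het"),
                         f = qlogis(c(0.7, 0.2, 0.4)))
  pr <- predict_target(fit, rows)
  expect_equal(pr$prediction[pr$sample_id == "hom"], 0.7)
  expect_equal(pr$prediction[pr$sample_id == "het"], 0.3)
  rows_swapped <- rows[c(1, 3, 2), ]
  expect_equal(dplyr::arrange(predict_target(fit, rows_swapped), sample_id),
               dplyr::arrange(pr, sample_id))
})

test_that("ROC/AUC equals the exhaustive pairwise concordance oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0))$auc, 0.0)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(122)
  for (i in 1:12) {
    n <- sample(10:50, 1)
    scores <- round(rnorm(n), 1) # ties on purpose
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    ra <- roc_auc(scores, labels)
    expect_equal(ra$auc, auc_oracle(scores, labels))
    expect_equal(ra$roc$fpr[1], 0)
    expect_equal(ra$roc$tpr[1], 0)
    expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
    expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
    expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
  }
})

test_that("stacking degenerates sensibly", {
  set.seed(123)
  n <- 60
  y <- rep(0:1, each = n / 2)
  # one target whose predictions equal the labels: perfect stacked AUC
  pw <- tibble::tibble(sample_id = sprintf("s%d", 1:n), smoking = y,
                       t1 = ifelse(y == 1, 0.9, 0.1))
  fit <- fit_stacked_model(pw, "t1")
  expect_equal(roc_auc(predict(fit, pw["t1"]), y)$auc, 1.0)
  # five identical columns add no information
  p <- plogis(rnorm(n) + y)
  pw5 <- tibble::tibble(sample_id = pw$sample_id, smoking = y,
                        a = p, b = p, c = p, d = p, e = p)
  f5 <- fit_stacked_model(pw5, c("a", "b", "c", "d", "e"))
  f1 <- fit_stacked_model(pw5, "a")
  expect_equal(roc_auc(predict(f5, pw5[c("a", "b", "c", "d", "e")]), y)$auc,
               roc_auc(predict(f1, pw5["a"]), y)$auc)
})

simulate_eval_setup <- function(cfg, targets, mat_seed = 1, depth = 30) {
  coh <- simulate_cohort(targets, cfg)
  mat <- simulate_meth_matrix(coh, mean_depth = depth, seed = mat_seed)
  mat <- logit_matrix(impute_missing(mask_cpg_snps(
    apply_depth_filter(mat), targets)))
  list(mat = mat,
       covs = dplyr::rename(coh$subjects, sample_id = "subject_id"),
       idx = setNames(targets$index_cpg, targets$gene_label))
}

test_that("model evaluation is deterministic and leak-free", {
  tg <- simulate_targets(n_targets = 3, lengths = 500L, n_cpgs = 15L,
                         n_cpg_snps = 0L, seed = 124)
  s <- simulate_eval_setup(cohort_config(n_subjects = 60, seed = 125), tg,
                           mat_seed = 126)
  r1 <- evaluate_three_models(s$mat, s$covs, s$idx, seed = 7)
  r2 <- evaluate_three_models(s$mat, s$covs, s$idx, seed = 7)
  expect_equal(glance(r1), glance(r2))
  expect_equal(r1$boruta$selected, r2$boruta$selected)

  # permuting test labels must change no fitted coefficient
  test_ids <- r1$index$split$sample_id[r1$index$split$set == "test"]
  covs_perm <- s$covs
  flip <- covs_perm$sample_id %in% test_ids
  set.seed(1)
  covs_perm$smoking[flip] <- sample(covs_perm$smoking[flip])
  r3 <- evaluate_three_models(s$mat, covs_perm, s$idx, seed = 7)
  expect_equal(lapply(r3$boruta$target_fits, `[[`, "coef"),
               lapply(r1$boruta$target_fits, `[[`, "coef"))
  expect_equal(r3$boruta.adjusted$stacked_fit$coef,
               r1$boruta.adjusted$stacked_fit$coef)
  expect_equal(r3$index$selected, r1$index$selected)
})

test_that("a no-signal cohort yields chance-level AUCs", {
  tg <- simulate_targets(n_targets = 3, lengths = 500L, n_cpgs = 15L,
                         n_cpg_snps = 0L, seed = 127)
  cfg <- cohort_config(n_subjects = 154, smoking_effect = 0, asm_effect = 0,
                       seed = 128)
  s <- simulate_eval_setup(cfg, tg, mat_seed = 129)
  reps <- evaluate_three_models(s$mat, s$covs, s$idx, seed = 8)
  for (r in reps) {
    expect_gt(r$auc, 0.35)
    expect_lt(r$auc, 0.65)
  }
})
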