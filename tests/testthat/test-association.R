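make_M_matrix <- function(values, n_samples) {
  # values: sample x cpg matrix; single target, one hom row per sample
  df <- tidyr::expand_grid(sample_id = rownames(values),
                           cpg_pos = as.integer(colnames(values))) |>
    dplyr::mutate(target = "t", allele = "ref", hom = TRUE, depth = 10L,
                  m = 0.5, M = as.vector(t(values)))
  haplometh:::new_haplo_meth(df, n_samples = n_samples)
}

test_that("residualisation matches the normal-equations oracle", {
  set.seed(91)
  n <- 10
  covs <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                         age = rnorm(n, 30, 6),
                         gender = rep(0:1, 5),
                         diagnosis = rep(c(0, 0, 1, 1, 1), 2),
                         smoking = rep(0:1, each = 5))
  vals <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(covs$sample_id, c(101, 102, 103)))
  mat <- make_M_matrix(vals, n)
  res <- residualize(mat, covs)
  X <- cbind(1, covs$age, covs$gender, covs$diagnosis)
  R_oracle <- vals - X %*% solve(t(X) %*% X, t(X) %*% vals)
  got <- tidyr::pivot_wider(res[, c("sample_id", "cpg_pos", "resid")],
                            names_from = "cpg_pos", values_from = "resid")
  expect_equal(as.matrix(got[match(covs$sample_id, got$sample_id), -1]),
               R_oracle, ignore_attr = TRUE, tolerance = 1e-10)
  # residuals orthogonal to every design column
  expect_lt(max(abs(t(X) %*% R_oracle)), 1e-8)
  expect_lt(max(abs(t(X) %*% as.matrix(got[match(covs$sample_id,
                                                 got$sample_id), -1]))), 1e-8)
})

test_that("an exact linear function of age residualises to zero", {
  set.seed(92)
  n <- 12
  covs <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                         age = rnorm(n, 30, 6), gender = rep(0:1, 6),
                         diagnosis = rep(0:1, each = 6),
                         smoking = rbinom(n, 1, 0.4))
  vals <- matrix(2 * covs$age + 1, n, 2,
                 dimnames = list(covs$sample_id, c(11, 12)))
  res <- residualize(make_M_matrix(vals, n), covs)
  expect_lt(max(abs(res$resid)), 1e-10)
  # constant covariates are dropped rather than fatal
  covs2 <- dplyr::mutate(covs, gender = 1)
  expect_silent(residualize(make_M_matrix(vals, n), covs2))
  # duplicated covariate column is rank-deficient
  covs3 <- dplyr::mutate(covs, gender = age)
  expect_error(residualize(make_M_matrix(vals, n), covs3,
                           adjust_for = c("age", "gender")),
               "rank-deficient")
})

test_that("BH adjustment equals the hand step-up formula", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(93)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))^2
    expect_equal(bh_adjust(p), bh_oracle(p))
    # order-preserving w.r.t. input ranks and never below the raw p
    expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(-0.1), "\\[0, 1\\]")
})

test_that("covariate tests behave on degenerate and strong-signal cases", {
  # identical groups: p = 1
  y <- c(1, 2, 3, 4, 1, 2, 3, 4)
  x <- rep(c(0, 1), each = 4)
  r <- haplometh:::test_one(y, x)
  expect_gte(r$p_value, 0.999)
  # strongly separated groups: tiny p
  set.seed(94)
  y2 <- c(rnorm(50), rnorm(50, 3))
  x2 <- rep(0:1, each = 50)
  r2 <- haplometh:::test_one(y2, x2)
  expect_lt(r2$p_value, 1e-6)
  expect_gt(r2$estimate, 0)
  # against R's own Welch test on a rough case
  set.seed(95)
  ya <- rnorm(13)
  yb <- rnorm(9, 0.4, 2)
  ours <- haplometh:::test_one(c(ya, yb), rep(c(0, 1), c(13, 9)))
  ref <- t.test(yb, ya)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  # group of one: untestable
  r3 <- haplometh:::test_one(c(1, 2, 3), c(0, 0, 1))
  expect_true(r3$untestable)
  # slope test agrees with lm
  set.seed(96)
  xx <- rnorm(20)
  yy <- 0.3 * xx + rnorm(20)
  rs <- haplometh:::test_one(yy, xx, continuous = TRUE)
  lm_p <- summary(lm(yy ~ xx))$coefficients[2, 4]
  expect_equal(rs$p_value, lm_p, tolerance = 1e-12)
})

test_that("an injected ASM effect is the top-ranked CpG of its target", {
  tg <- simulate_targets(n_targets = 2, lengths = 600L, n_cpgs = 20L,
                         n_cpg_snps = 0L, seed = 97)
  cfg <- cohort_config(n_subjects = 100, smoking_effect = 0, asm_effect = 1.0,
                       asm_targets = 1L, allele_freq = 0.5, seed = 98)
  coh <- simulate_cohort(tg, cfg)
  mat <- simulate_meth_matrix(coh, mean_depth = 25, seed = 99)
  mat <- logit_matrix(impute_missing(apply_depth_filter(mat)))
  covs <- dplyr::rename(coh$subjects, sample_id = "subject_id")
  tests <- covariate_tests(mat, covs, "haplotype")
  asm_pos <- coh$effect_map$cpg_pos[coh$effect_map$asm_cpg]
  t1 <- dplyr::filter(tests, target == "synt01")
  expect_equal(t1$cpg_pos[which.min(t1$p_adjusted)], asm_pos)
  expect_lt(min(t1$p_adjusted), 0.05)
  # the untouched target shows nothing at the same gate
  t2 <- dplyr::filter(tests, target == "synt02")
  expect_gt(min(t2$p_adjusted), 0.05)
})

test_that("testing a residualised-out covariate yields null-like p-values", {
  set.seed(100)
  ps <- c()
  for (i in 1:20) {
    n <- 60
    covs <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                           age = rnorm(n, 30, 6),
                           gender = rbinom(n, 1, 0.5),
                           diagnosis = rbinom(n, 1, 0.5),
                           smoking = rbinom(n, 1, 0.3))
    vals <- matrix(rnorm(n * 5), n, 5,
                   dimnames = list(covs$sample_id, 1:5))
    mat <- make_M_matrix(vals, n)
    tests <- covariate_tests(mat, covs, "gender",
                             adjust_for = c("age", "diagnosis"))
    ps <- c(ps, tests$p_value)
  }
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
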