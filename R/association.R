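#' Regress covariates out of the methylation matrix
#'
#' Per CpG, ordinary least squares of the (logit) methylation values on an
#' intercept plus the requested covariates — by default age, gender and
#' diagnosis, plus the haplotype allele (alt = 1) when
#' `include_haplotype = TRUE`, as the allele-adjusted model uses. Residuals
#' replace the values; they are orthogonal to every design column.
#'
#' @param mat A `haplo_meth` tibble with an `M` column (see [logit_matrix()]).
#' @param covariates Tibble with `sample_id` and the covariate columns.
#' @param adjust_for Covariate column names to regress out.
#' @param include_haplotype Also regress out the haplotype allele indicator.
#' @param value_col Column to residualise (default `"M"`).
#' @return The matrix with a `resid` column.
#' @export
residualize <- function(mat, covariates,
                        adjust_for = c("age", "gender", "diagnosis"),
                        include_haplotype = FALSE, value_col = "M") {
  df <- left_join(mat, covariates, by = "sample_id")
  if (anyNA(df[adjust_for])) abort("missing covariate values")
  df$.hap <- as.integer(df$allele == "alt")
  cols <- c(adjust_for, if (include_haplotype) ".hap")
  out <- df |>
    group_by(.data$target) |>
    group_modify(function(g, key) {
      wide <- tidyr::pivot_wider(
        g[, c("sample_id", "allele", "cpg_pos", value_col, cols)],
        names_from = "cpg_pos", values_from = all_of(value_col))
      X <- cbind(`(Intercept)` = 1, as.matrix(wide[cols]))
      keep <- apply(X[, -1, drop = FALSE], 2, function(v) var(v) > 0)
      X <- X[, c(TRUE, keep), drop = FALSE]
      if (qr(X)$rank < ncol(X)) {
        abort(paste0("rank-deficient covariate design in target ",
                     key$target, " (columns: ",
                     paste(colnames(X), collapse = ", "), ")"))
      }
      Y <- as.matrix(wide[setdiff(names(wide),
                                  c("sample_id", "allele", cols))])
      R <- stats::lm.fit(X, Y)$residuals
      res <- wide[c("sample_id", "allele")]
      res <- bind_cols(res, as_tibble(R))
      tidyr::pivot_longer(res, cols = -c("sample_id", "allele"),
                          names_to = "cpg_pos", values_to = "resid") |>
        mutate(cpg_pos = as.integer(.data$cpg_pos))
    }) |>
    ungroup()
  out <- left_join(mat, out, by = c("target", "sample_id", "allele", "cpg_pos"))
  new_haplo_meth(out, n_samples = attr(mat, "n_samples"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1 (wraps the standard implementation after validating inputs).
#'
#' @param pvals Numeric p-values in `[0, 1]` (`NA` allowed, passed through).
#' @return Adjusted p-values, order-preserving with respect to input ranks.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) abort("p-values must be in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Per-CpG covariate tests
#'
#' For each CpG of each target, tests the association between the
#' residualised methylation values and one covariate: binary covariates
#' (smoking, gender, diagnosis, or the haplotype allele) by a two-tailed
#' Welch two-sample t test, the continuous age covariate by the t statistic
#' of its OLS slope. The remaining covariates are regressed out first.
#' Testing `"haplotype"` is the allele-specific methylation contrast and is
#' restricted to heterozygous (haplotype-resolved) rows. p-values are
#' Benjamini-Hochberg adjusted within each target by default
#' (`bh_by = "pooled"` adjusts across all targets jointly).
#'
#' @param mat A `haplo_meth` tibble with `M` (see [logit_matrix()]).
#' @param covariates Covariate tibble (`sample_id`, `age`, `gender`,
#'   `diagnosis`, `smoking`).
#' @param covariate One of `"smoking"`, `"age"`, `"gender"`, `"diagnosis"`,
#'   `"haplotype"`.
#' @param adjust_for Covariates regressed out before testing; default all of
#'   age/gender/diagnosis except the tested one.
#' @param bh_by Family for the BH adjustment.
#' @return A tibble of class `asm_tests`: `target`, `cpg_pos`, `covariate`,
#'   `estimate` (group mean difference or slope; its sign is the effect
#'   direction), `statistic`, `df`, `p_value`, `p_adjusted`, `untestable`.
#' @export
covariate_tests <- function(mat, covariates,
                            covariate = c("smoking", "haplotype", "age",
                                          "gender", "diagnosis"),
                            adjust_for = NULL,
                            bh_by = c("target", "pooled")) {
  covariate <- match.arg(covariate)
  bh_by <- match.arg(bh_by)
  if (is.null(adjust_for)) {
    adjust_for <- setdiff(c("age", "gender", "diagnosis"), covariate)
  }
  res <- residualize(mat, covariates, adjust_for = adjust_for)
  df <- left_join(res, covariates, by = "sample_id")
  if (covariate == "haplotype") {
    df <- filter(df, !.data$hom)
    df$.x <- as.integer(df$allele == "alt")
  } else {
    df$.x <- df[[covariate]]
  }
  tests <- df |>
    summarise(test_one(.data$resid, .data$.x,
                       continuous = covariate == "age"),
              .by = c("target", "cpg_pos")) |>
    mutate(covariate = covariate, .after = "cpg_pos")
  tests <- tests |>
    mutate(p_adjusted = bh_adjust(.data$p_value),
           .by = if (bh_by == "target") "target" else NULL)
  class(tests) <- c("asm_tests", class(tests))
  tests
}

# Welch two-sample t (binary x) or OLS slope t (continuous x)
test_one <- function(y, x, continuous = FALSE) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]
  x <- x[ok]
  if (continuous) {
    n <- length(y)
    if (n < 3 || var(x) == 0) {
      return(tibble(estimate = NA_real_, statistic = NA_real_, df = NA_real_,
                    p_value = NA_real_, untestable = TRUE))
    }
    b <- stats::cov(x, y) / var(x)
    a <- mean(y) - b * mean(x)
    se <- sqrt(sum((y - a - b * x)^2) / (n - 2) / sum((x - mean(x))^2))
    tt <- b / se
    return(tibble(estimate = b, statistic = tt, df = n - 2,
                  p_value = 2 * pt(-abs(tt), n - 2), untestable = FALSE))
  }
  y1 <- y[x == 1]
  y0 <- y[x == 0]
  if (length(y1) < 2 || length(y0) < 2) {
    return(tibble(estimate = NA_real_, statistic = NA_real_, df = NA_real_,
                  p_value = NA_real_, untestable = TRUE))
  }
  d <- mean(y1) - mean(y0)
  v1 <- var(y1) / length(y1)
  v0 <- var(y0) / length(y0)
  se <- sqrt(v1 + v0)
  if (se == 0) {
    return(tibble(estimate = d, statistic = ifelse(d == 0, 0, Inf),
                  df = NA_real_, p_value = as.numeric(d == 0),
                  untestable = FALSE))
  }
  tt <- d / se
  dfree <- (v1 + v0)^2 /
    (v1^2 / (length(y1) - 1) + v0^2 / (length(y0) - 1))
  tibble(estimate = d, statistic = tt, df = dfree,
         p_value = 2 * pt(-abs(tt), dfree), untestable = FALSE)
}
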