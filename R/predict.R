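#' Random 1:1 train/test split of samples
#'
#' Unstratified uniform split by default (an optional stratification vector
#' keeps class balance for small cohorts); reproducible under `seed`.
#'
#' @param sample_ids Character vector of sample identifiers (>= 4).
#' @param seed RNG seed.
#' @param stratify Optional vector aligned with `sample_ids`; the split is
#'   performed within each stratum.
#' @return Tibble `sample_id`, `set` (`"train"` / `"test"`); set sizes
#'   differ by at most one.
#' @export
split_train_test <- function(sample_ids, seed = 1L, stratify = NULL) {
  n <- length(sample_ids)
  if (n < 4) abort("need at least 4 samples to split")
  withr_seed(child_seed(seed, 101L))
  assign_half <- function(ids) {
    k <- length(ids)
    shuffled <- sample(ids)
    tibble(sample_id = shuffled,
           set = rep(c("train", "test"), c(floor(k / 2), ceiling(k / 2))))
  }
  if (is.null(stratify)) {
    out <- assign_half(sample_ids)
  } else {
    out <- tibble(sample_id = sample_ids, stratum = stratify) |>
      group_by(.data$stratum) |>
      group_modify(~ assign_half(.x$sample_id)) |>
      ungroup() |>
      select(-"stratum")
  }
  arrange(out, match(.data$sample_id, sample_ids))
}

#' Ridge-stabilised logistic regression (IRLS)
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' with a mild L2 penalty on the standardised slopes (never the intercept).
#' The default `lambda = 1e-4` is a numerical guard against perfect
#' separation in small training sets, not a model change; `lambda = 0`
#' recovers the ordinary ML fit.
#'
#' @param X Numeric feature matrix (no intercept column).
#' @param y Binary outcome (0/1).
#' @param lambda L2 penalty on standardised slopes.
#' @param maxit,tol IRLS iteration controls.
#' @return List of class `ridge_logit`: `coef` (intercept + per-feature
#'   coefficients on the original scale), `converged`, `lambda`.
#' @export
fit_logistic_ridge <- function(X, y, lambda = 1e-4, maxit = 100L,
                               tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  D <- cbind(1, Xs)
  P <- diag(c(0, rep(lambda, p)), p + 1)
  beta <- rep(0, p + 1)
  converged <- FALSE
  for (i in seq_len(maxit)) {
    eta <- drop(D %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    DW <- D * w
    beta_new <- solve(crossprod(D, DW) + P, crossprod(DW, z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      converged <- TRUE
      break
    }
    beta <- drop(beta_new)
  }
  slopes <- beta[-1] / scl
  intercept <- beta[1] - sum(beta[-1] * ctr / scl)
  structure(list(coef = setNames(c(intercept, slopes),
                                 c("(Intercept)", colnames(X))),
                 converged = converged, lambda = lambda),
            class = "ridge_logit")
}

#' @rdname fit_logistic_ridge
#' @param object A `ridge_logit` fit.
#' @param newdata Feature matrix with the fit's columns.
#' @param ... Unused.
#' @return `predict()`: vector of probabilities.
#' @export
predict.ridge_logit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, names(object$coef)[-1], drop = FALSE]
  plogis(drop(cbind(1, X) %*% object$coef))
}

#' Per-target logistic smoking model
#'
#' Fits the ridge-stabilised logistic model of smoking status on the
#' (residualised logit) methylation values at the selected CpGs. Training
#' rows are haplotype rows — each contributes once; the heterozygote
#' averaging of the published procedure applies at prediction time
#' ([predict_target()]).
#'
#' @param train Wide tibble of training haplotype rows: `sample_id`,
#'   `smoking`, and one column per CpG.
#' @param cpgs Character vector of selected CpG column names (non-empty).
#' @param lambda Ridge stabiliser (see [fit_logistic_ridge()]).
#' @return A `ridge_logit` fit.
#' @export
fit_target_model <- function(train, cpgs, lambda = 1e-4) {
  if (length(cpgs) == 0) abort("no CpGs selected for target model")
  fit_logistic_ridge(as.matrix(train[cpgs]), train$smoking, lambda = lambda)
}

#' Per-subject target predictions with heterozygote averaging
#'
#' Scores every haplotype row with the target model, then returns one value
#' per subject: the probability of its single row for homozygotes, the
#' arithmetic mean of the two haplotype rows' probabilities for
#' heterozygotes.
#'
#' @param fit A `ridge_logit` from [fit_target_model()].
#' @param rows Wide tibble of haplotype rows (`sample_id` + CpG columns).
#' @return Tibble `sample_id`, `prediction`.
#' @export
predict_target <- function(fit, rows) {
  rows$`.p` <- predict(fit, rows[names(fit$coef)[-1]])
  summarise(rows, prediction = mean(.data$.p), .by = "sample_id")
}

#' Stacked combiner over per-target predictions
#'
#' Logistic fit of smoking status on the per-target prediction columns,
#' with the same ridge stabilisation as the target models.
#'
#' @param pred_wide Tibble: `sample_id`, `smoking`, one column per target.
#' @param targets_used Names of the per-target prediction columns.
#' @param lambda Ridge stabiliser.
#' @return A `ridge_logit` fit.
#' @export
fit_stacked_model <- function(pred_wide, targets_used, lambda = 1e-4) {
  fit_logistic_ridge(as.matrix(pred_wide[targets_used]), pred_wide$smoking,
                     lambda = lambda)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation with ties counted one half;
#' ROC points from descending-score thresholds, a step curve from (0, 0)
#' to (1, 1).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1); both classes must be present.
#' @return List: `roc` (tibble `fpr`, `tpr`, `threshold`), `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- rowsum(l, grp)
  fp <- rowsum(1 - l, grp)
  roc <- tibble(threshold = c(Inf, unique(s)),
                tpr = c(0, cumsum(tp) / n1),
                fpr = c(0, cumsum(fp) / n0))
  list(roc = roc, auc = auc)
}

# wide per-target haplotype-row tables from a residualised matrix
target_wide <- function(mat, value_col = "resid") {
  mat |>
    mutate(cpg = paste0("cpg_", .data$cpg_pos)) |>
    select("sample_id", "allele", "hom", "target", "cpg", all_of(value_col)) |>
    split(f = ~ target) |>
    lapply(function(df) {
      tidyr::pivot_wider(select(df, -"target"), names_from = "cpg",
                         values_from = all_of(value_col))
    })
}

#' Evaluate the three smoking-prediction models
#'
#' Runs the `index`, `boruta` and `boruta.adjusted` models end to end on an
#' identical 1:1 subject split: per-target CpG selection (the designated
#' index CpG; Boruta-confirmed CpGs on covariate residuals; or
#' Boruta-confirmed CpGs on covariate-plus-haplotype residuals), per-target
#' ridge-stabilised logistic fits on training haplotype rows, heterozygote
#' prediction averaging, a stacked logistic combiner over per-target
#' predictions, and test-set ROC/AUC. Feature selection and all fits see
#' training subjects only. A target whose Boruta run confirms nothing falls
#' back to its index CpG; a subject missing a target's prediction receives
#' the training-set mean at stacking.
#'
#' @param mat A `haplo_meth` tibble with `M` (imputed, masked,
#'   depth-filtered, coverage-pruned).
#' @param covariates Tibble `sample_id`, `smoking`, `age`, `gender`,
#'   `diagnosis`.
#' @param index_cpgs Named integer vector: genomic position of the index
#'   CpG per target (names = target labels). Positions absent from the
#'   matrix fall back to the nearest retained CpG.
#' @param seed Seed controlling the split and the Boruta runs.
#' @param models Which of the three models to run.
#' @param boruta_args List of extra arguments for [boruta_select()].
#' @param lambda Ridge stabiliser for all logistic fits.
#' @param stratify_split Stratify the 1:1 split by smoking status.
#' @return A named list of `smoking_model_report` objects (class
#'   `smoking_model_set`), each with `$model`, `$auc`, `$roc`,
#'   `$selected` (per-target CpGs), `$target_fits`, `$stacked_fit`,
#'   `$predictions` (per subject: set, score, smoking), `$split`.
#' @export
evaluate_three_models <- function(mat, covariates, index_cpgs, seed = 1L,
                                  models = c("index", "boruta",
                                             "boruta.adjusted"),
                                  boruta_args = list(), lambda = 1e-4,
                                  stratify_split = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  res_base <- residualize(mat, covariates)
  res_adj <- residualize(mat, covariates, include_haplotype = TRUE)
  ids <- sort(intersect(unique(mat$sample_id), covariates$sample_id))
  strat <- if (stratify_split) {
    covariates$smoking[match(ids, covariates$sample_id)]
  }
  split <- split_train_test(ids, seed = seed, stratify = strat)
  train_ids <- split$sample_id[split$set == "train"]

  smoking <- setNames(covariates$smoking, covariates$sample_id)
  wide_base <- target_wide(res_base)
  wide_adj <- target_wide(res_adj)
  tlabels <- names(wide_base)

  select_for <- function(wide, model_seed) {
    sel <- vector("list", length(tlabels))
    names(sel) <- tlabels
    for (i in seq_along(tlabels)) {
      w <- wide[[tlabels[i]]]
      tr <- filter(w, .data$sample_id %in% train_ids)
      cpg_cols <- grep("^cpg_", names(tr), value = TRUE)
      br <- do.call(boruta_select, c(
        list(X = as.matrix(tr[cpg_cols]), y = smoking[tr$sample_id],
             seed = child_seed(model_seed, i)),
        boruta_args))
      picked <- selected_features(br)
      if (length(picked) == 0) picked <- index_col(tlabels[i], cpg_cols,
                                                   index_cpgs)
      sel[[i]] <- list(cpgs = picked, boruta = br)
    }
    sel
  }
  index_col <- function(tl, cpg_cols, index_cpgs) {
    pos <- as.integer(sub("^cpg_", "", cpg_cols))
    cpg_cols[which.min(abs(pos - index_cpgs[[tl]]))]
  }

  run_model <- function(name) {
    wide <- if (name == "boruta.adjusted") wide_adj else wide_base
    if (name == "index") {
      sel <- lapply(tlabels, function(tl) {
        cpg_cols <- grep("^cpg_", names(wide[[tl]]), value = TRUE)
        list(cpgs = index_col(tl, cpg_cols, index_cpgs), boruta = NULL)
      })
      names(sel) <- tlabels
    } else {
      sel <- select_for(wide, child_seed(seed, match(name, c(
        "index", "boruta", "boruta.adjusted")) * 1000L))
    }
    fits <- list()
    preds <- list()
    for (tl in tlabels) {
      w <- wide[[tl]]
      w$smoking <- smoking[w$sample_id]
      tr <- filter(w, .data$sample_id %in% train_ids)
      fit <- fit_target_model(tr, sel[[tl]]$cpgs, lambda = lambda)
      fits[[tl]] <- fit
      preds[[tl]] <- predict_target(fit, w) |>
        mutate(target = tl)
    }
    pred_wide <- bind_rows(preds) |>
      tidyr::pivot_wider(names_from = "target", values_from = "prediction")
    # train-set mean imputation for subjects missing a target
    pred_wide <- left_join(tibble(sample_id = ids), pred_wide,
                           by = "sample_id")
    for (tl in tlabels) {
      tr_mean <- mean(pred_wide[[tl]][pred_wide$sample_id %in% train_ids],
                      na.rm = TRUE)
      pred_wide[[tl]][is.na(pred_wide[[tl]])] <- tr_mean
    }
    pred_wide$smoking <- smoking[pred_wide$sample_id]
    tr_wide <- filter(pred_wide, .data$sample_id %in% train_ids)
    stacked <- fit_stacked_model(tr_wide, tlabels, lambda = lambda)
    pred_wide$score <- predict(stacked, pred_wide[tlabels])
    pred_wide <- left_join(pred_wide, split, by = "sample_id")
    test <- filter(pred_wide, .data$set == "test")
    ra <- roc_auc(test$score, test$smoking)
    structure(list(model = name, auc = ra$auc, roc = ra$roc,
                   selected = lapply(sel, `[[`, "cpgs"),
                   boruta = lapply(sel, `[[`, "boruta"),
                   target_fits = fits, stacked_fit = stacked,
                   predictions = select(pred_wide, "sample_id", "set",
                                        "score", "smoking"),
                   split = split, seed = seed),
              class = "smoking_model_report")
  }
  out <- lapply(models, run_model)
  names(out) <- models
  class(out) <- "smoking_model_set"
  out
}

#' @export
print.smoking_model_report <- function(x, ...) {
  cat(sprintf("<smoking_model_report> model = %s, test AUC = %.3f\n",
              x$model, x$auc))
  cat(sprintf("  targets: %s\n", paste(names(x$selected), collapse = ", ")))
  invisible(x)
}

#' @export
print.smoking_model_set <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}
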