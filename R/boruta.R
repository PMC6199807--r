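#' Random-forest feature importance
#'
#' Default importance backend for [boruta_select()]: a compact random
#' forest (bootstrap resampling, `mtry` feature subsampling, depth-limited
#' CART trees with Gini splits). The default measure is the Z-score of
#' out-of-bag permutation importance (mean accuracy drop over trees divided
#' by its standard error) — the conventional input to the Boruta gate; the
#' raw mean decrease in Gini impurity is available as `type = "gini"`.
#' Deterministic for a fixed seed, independent of R's RNG state.
#'
#' @param X Numeric feature matrix (rows = observations).
#' @param y Binary outcome vector (0/1), length `nrow(X)`.
#' @param ntree Number of trees.
#' @param mtry Features tried per split; default `floor(sqrt(ncol(X)))`.
#' @param max_depth Maximum tree depth.
#' @param min_node Minimum observations per child node.
#' @param seed RNG seed.
#' @param type `"permutation"` (Z-score, default) or `"gini"`.
#' @return Numeric importance vector, one value per column of `X`.
#' @export
rf_importance <- function(X, y, ntree = 100L, mtry = NULL, max_depth = 6L,
                          min_node = 5L, seed = 1L,
                          type = c("permutation", "gini")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) abort("y must be binary 0/1")
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X)")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  rf_importance_cpp(X, y, as.integer(ntree), as.integer(mtry),
                    as.integer(max_depth), as.integer(min_node),
                    as.integer(seed), type == "permutation")
}

#' Boruta all-relevant feature selection
#'
#' Each iteration appends one shadow copy of every real feature (its values
#' permuted), obtains importances for the extended matrix, and scores a
#' "hit" for each real feature whose importance exceeds the maximum shadow
#' importance. Hits are compared to Binomial(iterations, 1/2) by two-sided
#' binomial tests with Bonferroni correction over the features still in
#' play: significantly more hits than chance confirms a feature,
#' significantly fewer rejects it (rejected features leave the matrix).
#' Features undecided at `max_iter` stay tentative.
#'
#' @param X Numeric feature matrix with named columns (rows = observations).
#' @param y Binary outcome (0/1).
#' @param importance Importance oracle, a function `(X, y, seed)` returning
#'   one score per column; any permutation-invariant ensemble importance
#'   satisfies the contract. Default [rf_importance()].
#' @param max_iter Maximum iterations.
#' @param alpha Significance level of the binomial gate.
#' @param seed RNG seed (drives both permutations and the default oracle).
#' @param early_stop Stop once no feature is tentative.
#' @param ... Passed on to the importance oracle.
#' @return A `boruta_result`: tibble with `feature`, `status`
#'   (`confirmed` / `tentative` / `rejected`), `hits`, `iterations`,
#'   `mean_importance`; attributes record `alpha` and the importance
#'   history matrix.
#' @export
boruta_select <- function(X, y, importance = rf_importance, max_iter = 100L,
                          alpha = 0.05, seed = 1L, early_stop = TRUE, ...) {
  X <- as.matrix(X)
  y_int <- as.integer(y)
  if (!all(y_int %in% c(0L, 1L))) abort("y must be binary 0/1")
  p <- ncol(X)
  if (p == 0) {
    return(new_boruta_result(
      tibble(feature = character(0), status = character(0),
             hits = integer(0), iterations = integer(0),
             mean_importance = numeric(0)),
      alpha = alpha, history = matrix(numeric(0), 0, 0)))
  }
  feats <- colnames(X) %||% paste0("V", seq_len(p))
  colnames(X) <- feats
  if (nrow(X) < 10) abort("need at least 10 rows for selection")

  status <- setNames(rep("tentative", p), feats)
  hits <- setNames(rep(0L, p), feats)
  iters <- setNames(rep(0L, p), feats)
  history <- matrix(NA_real_, nrow = max_iter, ncol = p,
                    dimnames = list(NULL, feats))
  withr_seed(seed)
  for (it in seq_len(max_iter)) {
    active <- names(status)[status != "rejected"]
    if (length(active) == 0) break
    Xa <- X[, active, drop = FALSE]
    # one shadow per active feature, padded to a minimum of five so the
    # max-shadow bar stays stable when few features remain in play
    shadow_src <- active
    while (length(shadow_src) < 5 && length(shadow_src) > 0) {
      shadow_src <- c(shadow_src,
                      active[seq_len(min(length(active),
                                         5 - length(shadow_src)))])
    }
    shadows <- apply(X[, shadow_src, drop = FALSE], 2, sample)
    colnames(shadows) <- paste0(".shadow_", seq_along(shadow_src))
    imp <- importance(cbind(Xa, shadows), y_int,
                      seed = child_seed(seed, it), ...)
    real_imp <- imp[seq_along(active)]
    shadow_max <- max(imp[-seq_along(active)])
    history[it, active] <- real_imp
    hit <- real_imp > shadow_max
    hits[active] <- hits[active] + hit
    iters[active] <- it

    open <- names(status)[status == "tentative"]
    n_open <- length(open)
    p_greater <- pbinom(hits[open] - 1L, it, 0.5, lower.tail = FALSE)
    p_less <- pbinom(hits[open], it, 0.5)
    confirm <- pmin(1, p_greater * n_open * 2) < alpha
    reject <- pmin(1, p_less * n_open * 2) < alpha
    status[open][confirm] <- "confirmed"
    status[open][reject & !confirm] <- "rejected"
    if (early_stop && !any(status == "tentative")) break
  }
  res <- tibble(feature = feats,
                status = unname(status[feats]),
                hits = unname(hits[feats]),
                iterations = unname(iters[feats]),
                mean_importance = colMeans(history[, feats, drop = FALSE],
                                           na.rm = TRUE))
  new_boruta_result(res, alpha = alpha,
                    history = history[seq_len(max(iters, 1L)), , drop = FALSE])
}

new_boruta_result <- function(df, alpha, history) {
  structure(df, alpha = alpha, history = history,
            class = c("boruta_result", class(df)))
}

#' Features selected by a Boruta run
#'
#' @param result A `boruta_result`.
#' @param policy `"confirmed"` (default) or `"confirmed+tentative"`.
#' @return Character vector of selected feature names (never shadows).
#' @export
selected_features <- function(result,
                              policy = c("confirmed", "confirmed+tentative")) {
  policy <- match.arg(policy)
  keep <- if (policy == "confirmed") "confirmed" else c("confirmed", "tentative")
  result$feature[result$status %in% keep]
}
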