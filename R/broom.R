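#' Tidiers for fitted objects
#'
#' `tidy()` returns per-term (or per-feature) tables; `glance()` one-row
#' model summaries.
#'
#' @param x A fitted object (`ridge_logit`, `boruta_result`,
#'   `smoking_model_report`, or `smoking_model_set`).
#' @param ... Unused.
#' @return A tibble.
#' @name haplometh-tidiers
NULL

#' @rdname haplometh-tidiers
#' @method tidy ridge_logit
#' @export
tidy.ridge_logit <- function(x, ...) {
  tibble(term = names(x$coef), estimate = unname(x$coef))
}

#' @rdname haplometh-tidiers
#' @method glance ridge_logit
#' @export
glance.ridge_logit <- function(x, ...) {
  tibble(lambda = x$lambda, converged = x$converged,
         n_terms = length(x$coef))
}

#' @rdname haplometh-tidiers
#' @method tidy boruta_result
#' @export
tidy.boruta_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname haplometh-tidiers
#' @method glance boruta_result
#' @export
glance.boruta_result <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_confirmed = sum(x$status == "confirmed"),
         n_tentative = sum(x$status == "tentative"),
         n_rejected = sum(x$status == "rejected"),
         iterations = if (nrow(x)) max(x$iterations) else 0L,
         alpha = attr(x, "alpha"))
}

#' @rdname haplometh-tidiers
#' @method tidy smoking_model_report
#' @export
tidy.smoking_model_report <- function(x, ...) {
  per_target <- purrr::imap_dfr(x$target_fits, function(fit, tl) {
    mutate(tidy(fit), target = tl, .before = 1)
  })
  stacked <- mutate(tidy(x$stacked_fit), target = "(stacked)", .before = 1)
  mutate(bind_rows(per_target, stacked), model = x$model, .before = 1)
}

#' @rdname haplometh-tidiers
#' @method glance smoking_model_report
#' @export
glance.smoking_model_report <- function(x, ...) {
  tibble(model = x$model, auc = x$auc,
         n_train = sum(x$split$set == "train"),
         n_test = sum(x$split$set == "test"),
         n_targets = length(x$selected),
         n_cpgs = length(unlist(x$selected)))
}

#' @rdname haplometh-tidiers
#' @method glance smoking_model_set
#' @export
glance.smoking_model_set <- function(x, ...) {
  purrr::map_dfr(x, glance)
}
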