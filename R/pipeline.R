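#' Pipeline configuration
#'
#' Bundles every threshold of the analysis under its documented default:
#' mean read quality >= 30, unconverted CpH fraction < 0.05 (strict),
#' per-haplotype depth >= 5, per-target covered-sample fraction >= 0.8,
#' selection/test alpha 0.05, and the three seeds (simulation, split,
#' selection). The demonstration cohort/read sizes are scaled down from the
#' full stated world so an end-to-end read-level run stays interactive; the
#' generator defaults themselves ([cohort_config()], [read_sim_config()])
#' are the full-size world.
#'
#' @param targets Target registry with reference sequences (default: a
#'   scaled synthetic panel).
#' @param cohort A [cohort_config()].
#' @param reads A [read_sim_config()].
#' @param min_q,conv_threshold,min_depth,min_sample_fraction,alpha
#'   The documented thresholds.
#' @param seed Master seed; simulation, split, and selection seeds derive
#'   from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(targets = simulate_targets(
                              n_targets = 3, lengths = 420L, n_cpgs = 12L,
                              n_cpg_snps = c(1L, 0L, 0L), seed = 7L),
                            cohort = cohort_config(n_subjects = 16L,
                                                   dispersion = 30),
                            reads = read_sim_config(mean_depth = 12),
                            min_q = 30, conv_threshold = 0.05,
                            min_depth = 5L, min_sample_fraction = 0.8,
                            alpha = 0.05, seed = 1L) {
  stopifnot(conv_threshold > 0, conv_threshold <= 1,
            min_depth >= 0, min_sample_fraction >= 0,
            min_sample_fraction <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the pipeline end to end
#'
#' Executes simulate -> demultiplex -> trim -> quality filter -> align ->
#' conversion filter -> deduplicate -> haplotype sorting -> matrix assembly
#' (depth filter, coverage pruning, CpG-SNP masking, imputation, logit) ->
#' covariate/ASM tests -> three-model evaluation, recording per-stage read
#' and row counts in a manifest. With `min_depth` set prohibitively high
#' all targets drop and the run completes with status `"no-model"`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_run`: `manifest` (stage counts),
#'   `status` (`"ok"` or `"no-model"`), `conversion` (per-target QC),
#'   `coverage`, `genotypes`, `matrix`, `tests` (smoking + ASM),
#'   `models` (a `smoking_model_set`, or `NULL`), `cohort`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  note <- function(stage, n, detail = "") {
    stages[[length(stages) + 1L]] <<- tibble(stage = stage, n = n,
                                             detail = detail)
  }

  cohort <- simulate_cohort(config$targets, config$cohort)
  sim <- simulate_reads(cohort, config$reads, seed = child_seed(config$seed, 11L))
  note("simulate", nrow(sim$reads), sprintf("%d molecules", sim$molecule_count))

  dm <- demultiplex(sim$reads, sim$barcodes)
  note("demultiplex", nrow(dm$assigned), sprintf("%d discarded", dm$n_discarded))

  tr <- trim_flanks(dm$assigned)
  tr <- filter(tr, !.data$unassignable)
  note("trim", nrow(tr))

  qf <- quality_filter(tr, min_mean_q = config$min_q)
  note("quality_filter", nrow(qf))

  al <- align_reads(qf, config$targets)
  al <- filter(al, .data$mapped)
  note("align", nrow(al))

  al <- filter_conversion(al, threshold = config$conv_threshold)
  al <- filter(al, .data$conv_pass)
  note("conversion_filter", nrow(al))
  conv <- conversion_rate(al)

  dd <- deduplicate(al)
  note("deduplicate", nrow(dd))

  sp <- split_by_allele(dd, config$targets)
  note("haplotype_sort", nrow(sp$reads),
       sprintf("%d conflict, %d uninformative", sp$n_conflict,
               sp$n_uninformative))

  n_samples <- nrow(cohort$subjects)
  mat <- methylation_rates(sp, config$targets, n_samples = n_samples)
  mat <- apply_depth_filter(mat, min_depth = config$min_depth)
  cov_tbl <- check_target_coverage(mat, config$min_sample_fraction)
  kept <- cov_tbl$target[cov_tbl$retained]
  mat <- new_haplo_meth(filter(mat, .data$target %in% kept),
                        n_samples = n_samples)
  mat <- mask_cpg_snps(mat, config$targets)
  note("matrix", nrow(mat), sprintf("%d targets retained", length(kept)))

  covariates <- rename(cohort$subjects, sample_id = "subject_id")
  if (nrow(mat) == 0 || length(kept) == 0) {
    return(structure(list(manifest = bind_rows(stages), status = "no-model",
                          conversion = conv, coverage = cov_tbl,
                          genotypes = sp$genotypes, matrix = mat,
                          tests = NULL, models = NULL, cohort = cohort,
                          config = config),
                     class = "pipeline_run"))
  }
  mat <- impute_missing(mat)
  mat <- logit_matrix(mat)

  tests <- list(
    smoking = covariate_tests(mat, covariates, "smoking"),
    asm = covariate_tests(mat, covariates, "haplotype"))
  note("tests", nrow(tests$smoking))

  index_cpgs <- setNames(config$targets$index_cpg, config$targets$gene_label)
  models <- tryCatch(
    evaluate_three_models(mat, covariates, index_cpgs,
                          seed = child_seed(config$seed, 31L)),
    error = function(e) NULL)
  note("models", length(models %||% list()),
       if (is.null(models)) "skipped" else
         paste(sprintf("%s=%.3f", names(models),
                       vapply(models, `[[`, numeric(1), "auc")),
               collapse = " "))

  structure(list(manifest = bind_rows(stages),
                 status = if (is.null(models)) "no-model" else "ok",
                 conversion = conv, coverage = cov_tbl,
                 genotypes = sp$genotypes, matrix = mat, tests = tests,
                 models = models, cohort = cohort, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> status:", x$status, "\n")
  print(as.data.frame(x$manifest), row.names = FALSE)
  invisible(x)
}
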