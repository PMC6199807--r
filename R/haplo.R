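#' Sort reads into haplotypes by SNP allele
#'
#' Reads of each (sample, target) are sorted by their allele calls at the
#' target's usable (non-CpG, bisulfite-distinguishable) SNPs. A read whose
#' usable-SNP calls conflict (both ref and alt seen) is excluded and
#' counted. A sample is called heterozygous when both alleles are supported
#' by at least `min_het_reads` reads and `min_het_frac` of its informative
#' reads; heterozygotes yield two haplotype rows (allele-informative reads
#' only), homozygotes a single row over all their passing reads.
#'
#' @param aligned Mapped, conversion-filtered, deduplicated reads
#'   (see [align_reads()]).
#' @param targets Target registry.
#' @param min_het_reads,min_het_frac Heterozygote evidence thresholds.
#' @return A list: `reads` (input rows kept, with `row_allele` and `hom`),
#'   `genotypes` (per sample x target: `n_ref`, `n_alt`, `het`, `genotype`),
#'   `n_conflict` (reads excluded for internal phase conflict),
#'   `n_uninformative` (heterozygote reads without an allele call).
#' @export
split_by_allele <- function(aligned, targets, min_het_reads = 2L,
                            min_het_frac = 0.1) {
  ctx <- target_context(targets)
  usable <- lapply(ctx, function(tc) {
    s <- tc$snps
    if (nrow(s) == 0) return(integer(0))
    coll <- function(b) ifelse(b == "C", "T", b)
    which(!s$is_cpg_snp & coll(s$ref_allele) != coll(s$alt_allele))
  })
  names(usable) <- vapply(ctx, `[[`, character(1), "gene_label")

  # per-read consolidated allele over the usable SNPs
  read_call <- function(alleles, target) {
    idx <- usable[[target]]
    if (length(idx) == 0) return("U")
    calls <- substring(alleles, idx, idx)
    has_r <- any(calls == "R")
    has_a <- any(calls == "A")
    if (has_r && has_a) "conflict" else if (has_r) "R" else if (has_a) "A" else "U"
  }
  aligned <- filter(aligned, .data$mapped)
  aligned$call <- vapply(seq_len(nrow(aligned)), function(i) {
    read_call(aligned$alleles[i], aligned$target[i])
  }, character(1))
  n_conflict <- sum(aligned$call == "conflict")
  aligned <- filter(aligned, .data$call != "conflict")

  genotypes <- aligned |>
    summarise(n_ref = sum(.data$call == "R"),
              n_alt = sum(.data$call == "A"),
              .by = c("sample_id", "target")) |>
    mutate(
      n_inf = .data$n_ref + .data$n_alt,
      het = .data$n_ref >= min_het_reads & .data$n_alt >= min_het_reads &
        .data$n_inf > 0 &
        pmin(.data$n_ref, .data$n_alt) / pmax(.data$n_inf, 1L) >= min_het_frac,
      genotype = ifelse(.data$het, "het",
                        ifelse(.data$n_alt > .data$n_ref, "alt", "ref")))

  aligned <- left_join(aligned, select(genotypes, "sample_id", "target",
                                       "het", "genotype"),
                       by = c("sample_id", "target"))
  het_rows <- filter(aligned, .data$het, .data$call %in% c("R", "A")) |>
    mutate(row_allele = as.character(ifelse(.data$call == "R", "ref", "alt")),
           hom = FALSE)
  n_uninformative <- sum(aligned$het & aligned$call == "U")
  hom_rows <- filter(aligned, !.data$het) |>
    mutate(row_allele = .data$genotype, hom = TRUE)
  reads <- bind_rows(het_rows, hom_rows) |>
    select(-"call", -"het", -"genotype") |>
    arrange(.data$sample_id, .data$target, .data$row_allele, .data$read_id)
  list(reads = reads, genotypes = genotypes,
       n_conflict = n_conflict, n_uninformative = n_uninformative)
}

#' Per-haplotype methylation rates
#'
#' Aggregates sorted reads into the long per-haplotype matrix: for every
#' (sample, target, haplotype row) and CpG, `m` = methylated calls /
#' (methylated + unmethylated calls), with missing calls excluded from both
#' sides, and `depth` = the row's read count.
#'
#' @param split Output of [split_by_allele()] (or a reads tibble carrying
#'   `row_allele` and `hom`).
#' @param targets Target registry.
#' @param n_samples Number of subjects in the analysis set (stored on the
#'   result; it is the `n` of [logit_transform()]).
#' @return A `haplo_meth` tibble: `sample_id`, `target`, `allele`, `hom`,
#'   `depth`, `cpg_pos` (genomic), `m` (`NA` when no calls).
#' @export
methylation_rates <- function(split, targets,
                              n_samples = NULL) {
  reads <- if (is.data.frame(split)) split else split$reads
  if (is.null(n_samples)) n_samples <- n_distinct(reads$sample_id)
  out <- list()
  for (i in seq_len(nrow(targets))) {
    tgt <- targets[i, ]
    sub <- filter(reads, .data$target == tgt$gene_label)
    if (nrow(sub) == 0) next
    cpg_genomic <- cpg_positions(tgt$reference_seq) + tgt$start - 1L
    chars <- matrix(unlist(strsplit(sub$meth, "", fixed = TRUE)),
                    nrow = nrow(sub), byrow = TRUE)
    grp <- paste(sub$sample_id, sub$row_allele, sep = "\r")
    n1 <- rowsum((chars == "1") + 0, grp)
    n0 <- rowsum((chars == "0") + 0, grp)
    keys <- do.call(rbind, strsplit(rownames(n1), "\r", fixed = TRUE))
    depth <- as.integer(table(grp)[rownames(n1)])
    hom <- sub$hom[match(paste(keys[, 1], keys[, 2], sep = "\r"), grp)]
    df <- tibble(sample_id = rep(keys[, 1], each = ncol(n1)),
                 target = tgt$gene_label,
                 allele = rep(keys[, 2], each = ncol(n1)),
                 hom = rep(hom, each = ncol(n1)),
                 depth = rep(depth, each = ncol(n1)),
                 cpg_pos = rep(cpg_genomic, times = nrow(n1)),
                 m = {
                   tot <- as.vector(t(n1 + n0))
                   ifelse(tot > 0, as.vector(t(n1)) / tot, NA_real_)
                 })
    out[[length(out) + 1L]] <- df
  }
  mat <- bind_rows(out) |>
    arrange(.data$sample_id, .data$target, .data$allele, .data$cpg_pos)
  new_haplo_meth(mat, n_samples = n_samples)
}

#' Minimum per-haplotype read depth filter
#'
#' Removes haplotype rows below the depth threshold; the default keeps rows
#' with depth of at least 5 (a row at exactly 5x passes).
#'
#' @param mat A `haplo_meth` tibble.
#' @param min_depth Minimum read depth per haplotype row (inclusive).
#' @return The filtered matrix; the number of removed rows is recorded in
#'   attribute `n_rows_removed`.
#' @export
apply_depth_filter <- function(mat, min_depth = 5L) {
  keep <- mat$depth >= min_depth
  n_removed <- length(unique(paste(mat$sample_id, mat$target,
                                   mat$allele)[!keep]))
  out <- new_haplo_meth(mat[keep, , drop = FALSE],
                        n_samples = attr(mat, "n_samples"))
  attr(out, "n_rows_removed") <- n_removed
  out
}

#' Per-target sample coverage after depth filtering
#'
#' A target is retained when at least `min_sample_fraction` of the analysis
#' samples keep one or more haplotype rows; starved targets (the real-world
#' analogue dropped an entire amplicon for insufficient data) are flagged
#' for removal.
#'
#' @param mat A depth-filtered `haplo_meth` tibble.
#' @param min_sample_fraction Minimum covered-sample fraction (default 0.8).
#' @param n_samples Analysis sample count; defaults to the matrix attribute.
#' @return Tibble: `target`, `n_covered`, `fraction`, `retained`.
#' @export
check_target_coverage <- function(mat, min_sample_fraction = 0.8,
                                  n_samples = attr(mat, "n_samples")) {
  mat |>
    summarise(n_covered = n_distinct(.data$sample_id), .by = "target") |>
    mutate(fraction = .data$n_covered / n_samples,
           retained = .data$fraction >= min_sample_fraction)
}

#' Mask CpG-SNP columns
#'
#' Removes the methylation columns of CpGs overlapped by a known CpG-SNP
#' (the SNP at either the C or the G of the dinucleotide): their signal is
#' confounded by genotype. Idempotent.
#'
#' @param mat A `haplo_meth` tibble.
#' @param targets Target registry with `snps` flagged `is_cpg_snp`.
#' @return The matrix without masked columns.
#' @export
mask_cpg_snps <- function(mat, targets) {
  masked <- purrr::map2_dfr(targets$gene_label, targets$snps, function(lab, s) {
    s <- filter(s, .data$is_cpg_snp)
    if (nrow(s) == 0) return(tibble(target = character(0), cpg_pos = integer(0)))
    tibble(target = lab, cpg_pos = c(s$position, s$position - 1L))
  })
  out <- anti_join(mat, masked, by = c("target", "cpg_pos"))
  new_haplo_meth(out, n_samples = attr(mat, "n_samples"))
}

#' Mean-impute missing methylation rates
#'
#' Each missing cell is replaced by its column (target x CpG) mean over
#' observed rows; observed cells are never altered. A column with no
#' observed value is an error naming the CpG.
#'
#' @param mat A `haplo_meth` tibble.
#' @return The imputed matrix.
#' @export
impute_missing <- function(mat) {
  out <- mat |>
    mutate(.col_mean = mean(.data$m, na.rm = TRUE),
           .by = c("target", "cpg_pos"))
  bad <- is.nan(out$.col_mean)
  if (any(bad)) {
    b <- distinct(out[bad, c("target", "cpg_pos")])
    abort(paste0("no observed values to impute from at: ",
                 paste(b$target, b$cpg_pos, sep = ":", collapse = ", ")))
  }
  out$m <- ifelse(is.na(out$m), out$.col_mean, out$m)
  out$.col_mean <- NULL
  new_haplo_meth(out, n_samples = attr(mat, "n_samples"))
}

#' Smoothed logit transform of methylation rates
#'
#' `M = log(m' / (1 - m'))` with `m' = (m (n - 1) + 0.5) / n`, where `m` is
#' the raw methylation rate and `n` the sample size of the analysis set.
#' The smoothing keeps `m'` inside (0, 1) so `M` is always finite; natural
#' logarithm (downstream t tests and logistic fits are invariant to the
#' base). `M(0.5, n) = 0` for every `n` and `M(m, n) = -M(1 - m, n)`.
#'
#' @param m Methylation rate(s) in `[0, 1]`.
#' @param n Sample size (>= 1).
#' @return The transformed value(s).
#' @export
logit_transform <- function(m, n) {
  if (any(n < 1)) abort("n must be >= 1")
  assert_prob(m[!is.na(m)], "m")
  mp <- (m * (n - 1) + 0.5) / n
  log(mp / (1 - mp))
}

#' Apply the logit transform to a methylation matrix
#'
#' @param mat A `haplo_meth` tibble (imputed).
#' @param n Smoothing sample size; defaults to the number of analysis
#'   samples recorded on the matrix.
#' @return The matrix with an `M` column.
#' @export
logit_matrix <- function(mat, n = attr(mat, "n_samples")) {
  out <- mutate(mat, M = logit_transform(.data$m, n))
  new_haplo_meth(out, n_samples = attr(mat, "n_samples"))
}
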