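#' Simulate synthetic amplicon targets
#'
#' Builds a registry of synthetic amplicons with planted CpGs, one usable
#' (A/G) allele-sorting SNP per target, and optionally CpG-SNPs. Default
#' geometry mirrors the six-amplicon panel the package documents: amplicon
#' lengths (1342, 1301, 1319, 1304, 1358, 1300) bp and CpG counts
#' (44, 114, 19, 85, 73, 17). Sequences are the amplified strand; synthetic
#' targets are generated as plus-strand amplicons.
#'
#' @param n_targets Number of targets.
#' @param lengths Integer vector of amplicon lengths (bp), recycled.
#' @param n_cpgs Integer vector of CpG counts per target, recycled.
#' @param n_cpg_snps Number of CpG-SNPs to plant per target (recycled).
#'   Default plants one in the first target only.
#' @param margin CpG/SNP-free bp at each amplicon end (primer footprint).
#' @param seed RNG seed; fixed seed gives an identical registry.
#' @return A target registry tibble (see [load_targets()]) with
#'   `reference_seq`, populated `snps`, and extra columns `index_cpg`
#'   (genomic position of the designated reference CpG) and `cpg_pos`
#'   (list-column of all CpG positions).
#' @export
simulate_targets <- function(n_targets = 6,
                             lengths = c(1342L, 1301L, 1319L, 1304L, 1358L, 1300L),
                             n_cpgs = c(44L, 114L, 19L, 85L, 73L, 17L),
                             n_cpg_snps = c(1L, rep(0L, n_targets - 1L)),
                             margin = 40L,
                             seed = 1L) {
  lengths <- rep_len(as.integer(lengths), n_targets)
  n_cpgs <- rep_len(as.integer(n_cpgs), n_targets)
  n_cpg_snps <- rep_len(as.integer(n_cpg_snps), n_targets)
  withr_seed(seed)
  rows <- purrr::map(seq_len(n_targets), function(i) {
    len <- lengths[i]
    k <- n_cpgs[i]
    base <- sample(DNA_BASES, len, replace = TRUE)
    # break accidental CpGs so planted positions are the only ones
    repeat {
      cg <- which(base[-len] == "C" & base[-1] == "G")
      if (length(cg) == 0) break
      base[cg + 1L] <- "A"
    }
    usable <- seq.int(margin + 1L, len - margin - 1L)
    cpg_at <- as.integer(round(seq(min(usable), max(usable), length.out = k)))
    base[cpg_at] <- "C"
    base[cpg_at + 1L] <- "G"
    # planting must not create flanking CpGs
    base[setdiff(cpg_at - 1L, c(cpg_at, cpg_at + 1L))] <- "T"
    base[setdiff(cpg_at + 2L, c(cpg_at, cpg_at + 1L))] <- "A"

    # allele-sorting SNP: A/G, distinguishable after bisulfite C/T collapse
    gaps <- setdiff(usable, c(cpg_at, cpg_at + 1L, cpg_at - 1L, cpg_at + 2L))
    snp_at <- gaps[which.min(abs(gaps - stats::median(cpg_at)))]
    base[snp_at] <- "A"
    snps <- tibble(snp_id = sprintf("ss%d_1", i), position = snp_at,
                   ref_allele = "A", alt_allele = "G", is_cpg_snp = FALSE)
    if (n_cpg_snps[i] > 0) {
      # CpG-SNP: C>T at the C of a CpG (away from the index CpG)
      pick <- cpg_at[seq_len(n_cpg_snps[i])]
      snps <- bind_rows(snps, tibble(
        snp_id = sprintf("ss%d_cpg%d", i, seq_along(pick)),
        position = pick, ref_allele = "C", alt_allele = "T",
        is_cpg_snp = TRUE))
    }
    idx <- cpg_at[ceiling(k / 2)]
    tibble(gene_label = sprintf("synt%02d", i),
           reference_cpg = sprintf("cg_synt%02d", i),
           chrom = sprintf("chrS%02d", i),
           start = 1L, end = len, strand = "+",
           expected_cpg_count = k,
           snps = list(snps),
           reference_seq = paste(base, collapse = ""),
           index_cpg = idx,
           cpg_pos = list(cpg_at))
  })
  validate_targets(bind_rows(rows))
}

withr_seed <- function(seed) {
  set.seed(as.integer(seed) %% 2147483563L)
}

#' Cohort simulation parameters
#'
#' Defaults state the cohort the analysis assumes: 154 subjects with 50/154
#' smoking prevalence, ages around 26-28 years, roughly half women, 54%
#' patients; per-target sorting-SNP allele frequency 0.3; baseline CpG
#' methylation 0.75; a -1.5 logit smoking effect at 3 CpGs centred on each
#' target's index CpG (smoking hypomethylates these loci); a +1.0 logit
#' allele-specific effect on the alt-carrying haplotype at one CpG in two
#' targets; Beta biological dispersion with concentration 30.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param smoking_prevalence Fraction of smokers; the simulated count is
#'   `round(n_subjects * smoking_prevalence)` exactly.
#' @param age_mean,age_sd Age distribution (years).
#' @param p_female,p_patient Bernoulli probabilities for gender (1 = female)
#'   and diagnosis (1 = patient).
#' @param age_confound Extra mean years added to smokers (0 = smoking
#'   independent of age; stress-test knob).
#' @param allele_freq Alt-allele frequency of each target's sorting SNP
#'   (scalar or per-target vector), Hardy-Weinberg diplotypes.
#' @param baseline_meth Baseline per-CpG methylation fraction.
#' @param smoking_effect Logit-scale shift applied to smokers at smoking CpGs.
#' @param n_smoking_cpgs Number of smoking-affected CpGs per target, centred
#'   on the index CpG.
#' @param asm_effect Logit-scale shift applied to the alt haplotype at the
#'   ASM CpG of affected targets.
#' @param asm_targets Indices of targets carrying an ASM effect.
#' @param subject_effect_sd SD (logit scale) of each smoker's personal
#'   smoking-effect size, shared across all smoking CpGs — exposure-dose
#'   heterogeneity; without it prediction is unrealistically easy.
#' @param subject_baseline_sd SD (logit scale) of a per-subject global
#'   methylation shift shared across all CpGs (cell-composition-like).
#' @param dispersion Beta concentration for per-haplotype biological jitter;
#'   `Inf` disables jitter.
#' @param seed RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 154L,
                          smoking_prevalence = 50 / 154,
                          age_mean = 26.6, age_sd = 6.4,
                          p_female = 0.5, p_patient = 0.54,
                          age_confound = 0,
                          allele_freq = 0.3,
                          baseline_meth = 0.75,
                          smoking_effect = -1.5,
                          n_smoking_cpgs = 3L,
                          asm_effect = 1.0,
                          asm_targets = c(1L, 3L),
                          subject_effect_sd = 0.75,
                          subject_baseline_sd = 0.5,
                          dispersion = 30,
                          seed = 1L) {
  assert_prob(smoking_prevalence, "smoking_prevalence")
  assert_prob(allele_freq, "allele_freq")
  assert_prob(baseline_meth, "baseline_meth")
  if (!all(is.finite(c(smoking_effect, asm_effect)))) {
    abort("effects must be finite")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a cohort with allele-specific and smoking methylation effects
#'
#' Draws subjects (smoking, age, gender, diagnosis), Hardy-Weinberg
#' diplotypes at each target's sorting SNP, and per-haplotype per-CpG
#' methylation probabilities
#' `plogis(qlogis(baseline) + smoking_effect * smoker + asm_effect * alt_hap)`
#' jittered by a Beta distribution with the configured concentration.
#'
#' @param targets A synthetic target registry from [simulate_targets()].
#' @param config A [cohort_config()].
#' @return A list of class `asm_cohort` with tidy tables:
#'   `subjects` (one row per subject), `haplotypes` (subject x target x
#'   haplotype alleles), `meth_probs` (long truth table of per-haplotype
#'   methylation probabilities), `effect_map` (which CpGs carry which
#'   effects), plus `targets` and `config`.
#' @export
simulate_cohort <- function(targets, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_subjects < 2) abort("n_subjects must be >= 2")
  nt <- nrow(targets)
  af <- rep_len(config$allele_freq, nt)
  withr_seed(config$seed)

  n <- as.integer(config$n_subjects)
  n_smk <- as.integer(round(n * config$smoking_prevalence))
  smoking <- integer(n)
  smoking[sample.int(n, n_smk)] <- 1L
  subjects <- tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    smoking = smoking,
    age = round(rnorm(n, config$age_mean + config$age_confound * smoking,
                      config$age_sd), 1),
    gender = rbinom(n, 1, config$p_female),
    diagnosis = rbinom(n, 1, config$p_patient)
  )

  if (is.null(targets$cpg_pos)) {
    targets$cpg_pos <- purrr::map2(targets$reference_seq, targets$start,
                                   ~ cpg_positions(.x, start = .y))
  }
  if (is.null(targets$index_cpg)) {
    targets$index_cpg <- purrr::map_int(targets$cpg_pos,
                                        ~ .x[ceiling(length(.x) / 2)])
  }

  effect_map <- purrr::map2_dfr(seq_len(nt), targets$gene_label, function(i, lab) {
    cpg <- targets$cpg_pos[[i]]
    idx_at <- which(cpg == targets$index_cpg[i])
    half <- (config$n_smoking_cpgs - 1L) %/% 2L
    smoking_idx <- idx_at + seq(-half, half + (config$n_smoking_cpgs - 1L) %% 2L)
    smoking_idx <- smoking_idx[smoking_idx >= 1 & smoking_idx <= length(cpg)]
    smoking_idx <- head(smoking_idx, config$n_smoking_cpgs)
    asm_idx <- integer(0)
    if (i %in% config$asm_targets) {
      # one ASM CpG adjacent to the index CpG, i.e. on a smoking-informative
      # CpG: allele-specific variance masking a predictive site is the
      # scenario allele adjustment is meant to recover
      asm_idx <- max(1L, idx_at - 1L)
    }
    tibble(target = lab, cpg_pos = cpg,
           is_index = cpg == targets$index_cpg[i],
           smoking_cpg = seq_along(cpg) %in% smoking_idx,
           asm_cpg = seq_along(cpg) %in% asm_idx)
  })

  # subject-level random effects: a global baseline shift shared by all
  # CpGs, and each smoker's personal smoking-effect size (dose heterogeneity)
  subjects$b_base <- rnorm(n, 0, config$subject_baseline_sd %||% 0)
  subjects$e_smk <- rnorm(n, 0, config$subject_effect_sd %||% 0) * smoking

  haplotypes <- tidyr::expand_grid(
    subject_id = subjects$subject_id,
    target = targets$gene_label,
    hap = c(1L, 2L)
  ) |>
    mutate(allele = ifelse(
      runif(n()) < af[match(.data$target, targets$gene_label)], "alt", "ref"))

  meth_probs <- haplotypes |>
    left_join(select(subjects, "subject_id", "smoking", "b_base", "e_smk"),
              by = "subject_id") |>
    left_join(effect_map, by = "target", relationship = "many-to-many") |>
    mutate(
      mu = qlogis(config$baseline_meth) + .data$b_base +
        (config$smoking_effect + .data$e_smk) * .data$smoking *
          .data$smoking_cpg +
        config$asm_effect * (.data$allele == "alt") * .data$asm_cpg,
      prob = plogis(.data$mu)
    )
  if (is.finite(config$dispersion)) {
    k <- config$dispersion
    meth_probs$prob <- rbeta(nrow(meth_probs),
                             meth_probs$prob * k, (1 - meth_probs$prob) * k)
  }
  meth_probs <- select(meth_probs, "subject_id", "target", "hap", "allele",
                       "cpg_pos", "prob")

  structure(list(subjects = subjects, haplotypes = haplotypes,
                 meth_probs = meth_probs, effect_map = effect_map,
                 targets = targets, config = config),
            class = "asm_cohort")
}

#' Simulate a per-haplotype methylation matrix directly from cohort truth
#'
#' Bypasses read simulation: draws a negative-binomial read depth per
#' (subject, target, haplotype) and binomial methylated-read counts per CpG,
#' yielding the same long per-haplotype matrix the read pipeline produces
#' ([methylation_rates()]). Heterozygotes at the sorting SNP give two rows
#' (ref and alt); homozygotes one pooled row. Used for statistical and
#' model-level studies where read-level fidelity is not the question.
#'
#' @param cohort An `asm_cohort`.
#' @param mean_depth Negative-binomial mean read depth per haplotype.
#' @param depth_size Negative-binomial size (dispersion) parameter.
#' @param depth_scale Optional named vector of per-target multipliers on
#'   `mean_depth` (e.g. to starve one target).
#' @param seed RNG seed.
#' @return A `haplo_meth` long tibble: `sample_id`, `target`, `allele`,
#'   `hom`, `depth`, `cpg_pos`, `m`.
#' @export
simulate_meth_matrix <- function(cohort, mean_depth = 30, depth_size = 8,
                                 depth_scale = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "asm_cohort"))
  withr_seed(seed)
  hap <- cohort$haplotypes
  mu <- rep(mean_depth, nrow(hap))
  if (!is.null(depth_scale)) {
    sc <- depth_scale[hap$target]
    mu <- mu * ifelse(is.na(sc), 1, sc)
  }
  hap$depth <- rnbinom(nrow(hap), mu = mu, size = depth_size)

  mp <- cohort$meth_probs
  hap_key <- paste(hap$subject_id, hap$target, hap$hap, sep = "\r")
  mp_hap <- match(paste(mp$subject_id, mp$target, mp$hap, sep = "\r"),
                  hap_key)
  depth_h <- hap$depth[mp_hap]
  n_meth <- rbinom(nrow(mp), depth_h, mp$prob)

  # pool the two haplotypes of homozygotes; heterozygotes keep separate
  # rows (rowsum over the row key keeps this fast at cohort scale)
  row_key <- paste(mp$subject_id, mp$target, mp$allele, mp$cpg_pos,
                   sep = "\r")
  first <- !duplicated(row_key)
  agg_meth <- rowsum(n_meth, row_key, reorder = FALSE)
  agg_depth <- rowsum(depth_h, row_key, reorder = FALSE)
  geno_key <- paste(hap$subject_id, hap$target, sep = "\r")
  n_alleles <- vapply(split(hap$allele, geno_key), function(a)
    length(unique(a)), integer(1))
  hom <- n_alleles[paste(mp$subject_id, mp$target, sep = "\r")[first]] == 1L
  depth <- as.integer(agg_depth[, 1])
  mat <- tibble(sample_id = mp$subject_id[first],
                target = mp$target[first],
                allele = mp$allele[first],
                hom = unname(hom),
                depth = depth,
                cpg_pos = mp$cpg_pos[first],
                m = ifelse(depth > 0, agg_meth[, 1] / depth, NA_real_)) |>
    arrange(.data$sample_id, .data$target, .data$allele, .data$cpg_pos)
  new_haplo_meth(mat, n_samples = nrow(cohort$subjects))
}

new_haplo_meth <- function(df, n_samples) {
  structure(as_tibble(df), n_samples = n_samples,
            class = c("haplo_meth", class(as_tibble(df))))
}
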