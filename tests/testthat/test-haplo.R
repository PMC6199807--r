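test_that("allele sorting splits heterozygotes and pools homozygotes", {
  tg <- tiny_targets()
  lab <- tg$gene_label[1]
  # heterozygote: 6 ref reads, 7 alt reads, 1 uninformative
  het <- make_aligned(rep("h1", 14), lab,
                      rep(strrep("1", 10), 14),
                      c(rep("R", 6), rep("A", 7), "U"), n_cpg = 10)
  # homozygote ref: all reads one row, uninformative included
  hom <- make_aligned(rep("h2", 5), lab,
                      rep(strrep("0", 10), 5),
                      c(rep("R", 4), "U"), n_cpg = 10)
  hom$read_id <- sprintf("h%03d", 1:5)
  sp <- split_by_allele(dplyr::bind_rows(het, hom), tg)
  mat <- methylation_rates(sp, tg, n_samples = 2)
  rows <- dplyr::distinct(mat, sample_id, allele, hom, depth)
  expect_equal(nrow(rows), 3)
  expect_setequal(rows$depth[rows$sample_id == "h1"], c(6L, 7L))
  expect_equal(rows$depth[rows$sample_id == "h2"], 5L)
  expect_true(all(rows$hom[rows$sample_id == "h2"]))
  expect_equal(sp$n_uninformative, 1L)
  g <- sp$genotypes
  expect_equal(g$genotype[g$sample_id == "h1"], "het")
  expect_equal(g$genotype[g$sample_id == "h2"], "ref")
})

test_that("per-read haplotype assignment matches simulator truth", {
  tg <- tiny_targets()
  coh <- simulate_cohort(tg, cohort_config(n_subjects = 6, allele_freq = 0.5,
                                           seed = 61))
  sim <- simulate_reads(coh, read_sim_config(
    mean_depth = 10, error_rate = 0, duplicate_rate = 0), seed = 62)
  al <- align_reads(
    trim_flanks(demultiplex(sim$reads, sim$barcodes)$assigned), tg)
  sp <- split_by_allele(al, tg)
  tru <- sim$truth[match(sp$reads$read_id, sim$truth$read_id), ]
  het <- !sp$reads$hom
  expect_gt(sum(het), 0)
  expect_equal(sp$reads$row_allele[het], tru$allele[het])
  expect_equal(sp$n_conflict, 0L)
})

test_that("methylation rates average calls with missing excluded", {
  tg <- tiny_targets()
  lab <- tg$gene_label[1]
  a <- make_aligned(rep("s", 8), lab,
                    c(rep("1110000000", 2), rep("0110000000", 6)),
                    rep("R", 8), n_cpg = 10)
  a$meth[1] <- paste0(".", substr(a$meth[1], 2, 10)) # one missing call
  sp <- split_by_allele(a, tg)
  mat <- methylation_rates(sp, tg, n_samples = 1)
  cpg1 <- dplyr::filter(mat, cpg_pos == tg$cpg_pos[[1]][1])
  expect_equal(cpg1$m, 1 / 7)   # 1 methylated of 7 informative calls
  expect_equal(cpg1$depth, 8L)  # depth is the row read count
  cpg2 <- dplyr::filter(mat, cpg_pos == tg$cpg_pos[[1]][2])
  expect_equal(cpg2$m, 1.0)
})

test_that("depth filter keeps exactly-5x rows and coverage prunes targets", {
  mk <- function(sample, target, depth) {
    tibble::tibble(sample_id = sample, target = target, allele = "ref",
                   hom = TRUE, depth = depth, cpg_pos = 1:2,
                   m = 0.5)
  }
  mat <- haplometh:::new_haplo_meth(
    dplyr::bind_rows(mk("a", "t1", 5L), mk("b", "t1", 4L),
                     mk("a", "t2", 2L), mk("b", "t2", 3L)),
    n_samples = 2)
  f <- apply_depth_filter(mat, min_depth = 5)
  expect_setequal(unique(f$target), "t1")
  expect_equal(unique(f$depth), 5L)
  cov_tbl <- check_target_coverage(f, min_sample_fraction = 0.8)
  expect_false(any(cov_tbl$target == "t2"))
  expect_equal(cov_tbl$retained, 1 / 2 >= 0.8) # t1 covered by 1 of 2 samples
  expect_true(all(check_target_coverage(f, min_sample_fraction = 0)$retained))
})

test_that("a starved target is the one dropped", {
  tg <- tiny_targets()
  coh <- simulate_cohort(tg, cohort_config(n_subjects = 20, seed = 71))
  mat <- simulate_meth_matrix(coh, mean_depth = 30,
                              depth_scale = c(synt02 = 2 / 30), seed = 72)
  f <- apply_depth_filter(mat)
  cov_tbl <- check_target_coverage(f)
  expect_true(cov_tbl$retained[cov_tbl$target == "synt01"])
  expect_false(isTRUE(cov_tbl$retained[cov_tbl$target == "synt02"]) &&
                 cov_tbl$n_covered[cov_tbl$target == "synt02"] > 16)
})

test_that("CpG-SNP masking removes confounded columns idempotently", {
  tg <- tiny_targets(n_cpg_snps = c(1L, 0L))
  coh <- simulate_cohort(tg, cohort_config(n_subjects = 6, seed = 81))
  mat <- simulate_meth_matrix(coh, mean_depth = 20, seed = 82)
  n_cpg_before <- dplyr::n_distinct(mat$cpg_pos[mat$target == "synt01"])
  m1 <- mask_cpg_snps(mat, tg)
  n_cpg_after <- dplyr::n_distinct(m1$cpg_pos[m1$target == "synt01"])
  expect_equal(n_cpg_after, n_cpg_before - 1L)
  expect_equal(mask_cpg_snps(m1, tg), m1) # idempotent
  # untouched target unchanged
  expect_equal(dplyr::filter(m1, target == "synt02"),
               dplyr::filter(mat, target == "synt02"), ignore_attr = TRUE)
})

test_that("mean imputation fills only missing cells with column means", {
  mat <- haplometh:::new_haplo_meth(
    tibble::tibble(sample_id = c("a", "b", "c"), target = "t",
                   allele = "ref", hom = TRUE, depth = 10L,
                   cpg_pos = 100L, m = c(0.2, NA, 0.4)),
    n_samples = 3)
  imp <- impute_missing(mat)
  expect_equal(imp$m, c(0.2, 0.3, 0.4))
  expect_identical(imp$m[c(1, 3)], mat$m[c(1, 3)]) # observed cells bitwise
  expect_equal(mean(imp$m), mean(mat$m, na.rm = TRUE))
  expect_equal(impute_missing(imp), imp) # no missing -> identity
  allna <- dplyr::mutate(mat, m = NA_real_)
  expect_error(impute_missing(haplometh:::new_haplo_meth(allna, 3)),
               "t:100")
})

test_that("logit transform matches its closed form and properties", {
  expect_equal(logit_transform(0.5, 7), 0)
  expect_equal(logit_transform(0.5, 154), 0)
  expect_equal(logit_transform(1, 154), log(307), tolerance = 1e-12)
  for (m in c(0, 0.1, 0.3, 0.77, 1)) {
    expect_equal(logit_transform(m, 154), -logit_transform(1 - m, 154))
  }
  # strictly increasing in m; bounded by the 0/1 extremes
  ms <- seq(0, 1, by = 0.05)
  M <- logit_transform(ms, 40)
  expect_true(all(diff(M) > 0))
  expect_true(all(abs(M) <= log((40 - 0.5) / 0.5) + 1e-12))
  expect_error(logit_transform(0.5, 0), "n must be")
})
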