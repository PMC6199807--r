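test_that("reference conversion is a validated C->T map", {
  expect_equal(convert_reference("ACGC"), "ATGT")
  expect_equal(convert_reference("TTTT"), "TTTT")
  s <- "ACGTNCCG"
  expect_equal(convert_reference(convert_reference(s)), convert_reference(s))
  expect_error(convert_reference("ACGX"), "non-ACGTN")
})

test_that("allele calls respect bisulfite equivalence classes", {
  expect_equal(call_allele("G", "A", "G"), "alt")
  expect_equal(call_allele("A", "A", "G"), "ref")
  # C>T on the plus strand is never distinguishable
  expect_equal(call_allele("C", "C", "T"), "unknown")
  expect_equal(call_allele("T", "C", "T"), "unknown")
  # G>A on the minus strand likewise
  expect_equal(call_allele("G", "G", "A", strand = "-"), "unknown")
  # but G>A on the plus strand is fine
  expect_equal(call_allele("G", "G", "A", strand = "+"), "ref")
  # gap and off-class bases
  expect_equal(call_allele(NA, "A", "G"), "unknown")
  expect_equal(call_allele("T", "A", "G"), "unknown")
})

test_that("error-free methylated reads align perfectly with correct calls", {
  tg <- tiny_targets()
  coh <- simulate_cohort(tg, cohort_config(
    n_subjects = 4, baseline_meth = 1, smoking_effect = 0, asm_effect = 0,
    subject_effect_sd = 0, subject_baseline_sd = 0, dispersion = Inf,
    seed = 41))
  sim <- simulate_reads(coh, read_sim_config(
    mean_depth = 5, error_rate = 0, conversion_failure_rate = 0,
    duplicate_rate = 0), seed = 42)
  tr <- trim_flanks(demultiplex(sim$reads, sim$barcodes)$assigned)
  al <- align_reads(tr, tg)
  expect_true(all(al$mapped))
  expect_true(all(grepl("^[0-9]+M$", al$cigar)))
  # alt-haplotype reads mismatch the reference only at the sorting SNP
  tru0 <- sim$truth[match(al$read_id, sim$truth$read_id), ]
  expect_equal(al$n_mismatch, as.integer(tru0$allele == "alt"))
  expect_true(all(al$cph_unconverted == 0))
  expect_true(all(grepl("^1+$", al$meth)))
  # target assignment matches the simulated origin for every read
  tru <- sim$truth[match(al$read_id, sim$truth$read_id), ]
  expect_equal(al$target, tru$target)
  # allele call matches the simulated haplotype
  expect_equal(substr(al$alleles, 1, 1),
               c(ref = "R", alt = "A")[tru$allele], ignore_attr = TRUE)
})

test_that("gapped reads produce correct CIGARs and DP matches the oracle", {
  tg <- tiny_targets()
  ref <- tg$reference_seq[1]
  # plant a 2 bp deletion mid-read in a fully converted read
  read <- convert_reference(ref)
  del_at <- 201
  read_del <- paste0(substr(read, 1, del_at - 1), substr(read, del_at + 2,
                                                         nchar(read)))
  al <- align_reads(tibble::tibble(read_id = "d", sample_id = "s",
                                   insert = read_del), tg)
  expect_equal(al$target, tg$gene_label[1])
  expect_match(al$cigar, "2D")

  # implementation DP score equals the full DP oracle on short sequences
  set.seed(7)
  for (i in 1:15) {
    a <- paste(sample(c("A", "G", "T"), sample(8:14, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "G", "T"), sample(8:14, 1), replace = TRUE),
               collapse = "")
    got <- haplometh:::dp_align(a, b)$score
    expect_equal(got, dp_oracle_score(a, b), info = paste(a, b))
  }
})

test_that("reads with garbage sequence are reported unmapped", {
  tg <- tiny_targets()
  junk <- paste(rep("A", 400), collapse = "")
  al <- align_reads(tibble::tibble(read_id = "j", sample_id = "s",
                                   insert = junk), tg, min_identity = 0.8)
  expect_false(al$mapped)
})

test_that("conversion filter is strict and vacuously passes zero-CpH reads", {
  base <- make_aligned("s1", "t", "11", "R")
  aligned <- dplyr::bind_rows(
    dplyr::mutate(base, cph_total = 100L, cph_unconverted = 4L),
    dplyr::mutate(base, cph_total = 100L, cph_unconverted = 5L),
    dplyr::mutate(base, cph_total = 0L, cph_unconverted = 0L))
  out <- filter_conversion(aligned, threshold = 0.05)
  expect_equal(out$conv_pass, c(TRUE, FALSE, TRUE))
  expect_equal(out$cph_vacuous, c(FALSE, FALSE, TRUE))
})

test_that("deduplication collapses identical reads and is idempotent", {
  a <- make_aligned(rep("s1", 3), "t", c("101", "101", "100"),
                    c("R", "R", "R"), n_cpg = 3)
  d1 <- deduplicate(a)
  expect_equal(nrow(d1), 2)
  expect_equal(d1$read_id[1], "r001") # deterministic representative
  expect_equal(deduplicate(d1), d1)

  # simulator round trip: survivors track the unique molecule count
  tg <- tiny_targets()
  coh <- simulate_cohort(tg, cohort_config(n_subjects = 5, seed = 51))
  sim <- simulate_reads(coh, read_sim_config(
    mean_depth = 6, error_rate = 0, duplicate_rate = 0.3), seed = 52)
  al <- align_reads(
    trim_flanks(demultiplex(sim$reads, sim$barcodes)$assigned), tg)
  dd <- deduplicate(al)
  # the conservative key can also merge distinct molecules with identical
  # methylation vectors, so survivors <= molecules; duplicates always go
  expect_lte(nrow(dd), sim$molecule_count)
  expect_gte(nrow(dd), sim$molecule_count * 0.6)
  expect_lt(nrow(dd), nrow(al))
})

test_that("conversion rate summarises unconverted CpH per target", {
  base <- make_aligned(c("s1", "s1"), "t", c("11", "11"), c("R", "R"))
  a <- dplyr::mutate(base, cph_total = c(50L, 50L),
                     cph_unconverted = c(0L, 0L))
  expect_equal(conversion_rate(a)$conversion_rate, 1.0)
  b <- dplyr::mutate(base, cph_total = c(50L, 50L),
                     cph_unconverted = c(50L, 50L))
  expect_equal(conversion_rate(b, passing_only = FALSE)$conversion_rate, 0.0)
})
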