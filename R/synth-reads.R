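#' The shared "panhandle" primer sequence
#'
#' Both target-specific primers carry this common 5' tail, so every amplicon
#' is flanked by the primer on the left and its reverse complement on the
#' right; the simulator reproduces that layout and [trim_flanks()] removes it.
#'
#' @return A 30-nt DNA string.
#' @export
u1_primer <- function() "GCAGTCGAACATGTAGCTGACTCAGGTCAC"

#' Read simulation parameters
#'
#' Defaults state the sequencing world the analysis assumes: negative-binomial
#' read depth with mean 17 per (sample, target, haplotype) — about 200 reads
#' per barcode over a six-target panel, matching the reported median of 202 —
#' constant Q40 base qualities, a small substitution error rate, 0.99
#' bisulfite conversion efficiency for unmethylated CpG cytosines, a 0.01 CpH
#' conversion-failure rate, and 5% exact PCR duplicates.
#'
#' @param mean_depth Negative-binomial mean reads per haplotype per target.
#' @param depth_size Negative-binomial size parameter.
#' @param error_rate Per-base substitution sequencing error probability.
#' @param conversion_efficiency Probability an unmethylated CpG cytosine
#'   reads as T.
#' @param conversion_failure_rate Probability a CpH cytosine remains C.
#' @param duplicate_rate Probability a molecule emits one exact duplicate read.
#' @param quality Constant Phred base quality of simulated reads.
#' @param p_revcomp Probability a read is emitted reverse-complemented.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(mean_depth = 17, depth_size = 6,
                            error_rate = 0.001,
                            conversion_efficiency = 0.99,
                            conversion_failure_rate = 0.01,
                            duplicate_rate = 0.05,
                            quality = 40L,
                            p_revcomp = 0.5) {
  for (nm in c("error_rate", "conversion_efficiency",
               "conversion_failure_rate", "duplicate_rate", "p_revcomp")) {
    assert_prob(get(nm), nm)
  }
  structure(as.list(environment()), class = "read_sim_config")
}

#' Default dual 5-nt barcode table
#'
#' Two fixed oligo sets (8 and 12 five-letter codes) giving 96 unique
#' combinations; combinations are mapped to samples in row-major order.
#'
#' @param sample_ids Sample identifiers to map (at most 96).
#' @return A `barcode_table` list with `first_set`, `second_set`, and a
#'   `sample_map` tibble (`code1`, `code2`, `sample_id`).
#' @export
default_barcode_table <- function(sample_ids = character(0)) {
  first_set <- c("ACTGA", "CGATC", "GTCAG", "TAGCT",
                 "AAGGC", "CCTTA", "GGAAT", "TTCCG")
  second_set <- c("ACACG", "CACAT", "GAGAC", "TGTGA",
                  "AGAGT", "CTCTG", "GCGCA", "TCTCC",
                  "ATTGG", "CGGAA", "GATTC", "TCAAG")
  barcode_table(first_set, second_set, sample_ids)
}

#' Construct and validate a barcode table
#'
#' @param first_set,second_set Character vectors of unique 5-letter codes.
#' @param sample_ids Sample identifiers mapped to combinations in row-major
#'   order (first set varying slowest); at most
#'   `length(first_set) * length(second_set)`.
#' @return A `barcode_table` list.
#' @export
barcode_table <- function(first_set, second_set, sample_ids = character(0)) {
  if (anyDuplicated(first_set) || anyDuplicated(second_set)) {
    abort("barcode codes must be unique within each set")
  }
  combos <- tidyr::expand_grid(code1 = first_set, code2 = second_set)
  if (length(sample_ids) > nrow(combos)) {
    abort(sprintf("cannot map %d samples onto %d barcode combinations",
                  length(sample_ids), nrow(combos)))
  }
  sample_map <- combos[seq_along(sample_ids), , drop = FALSE]
  sample_map$sample_id <- as.character(sample_ids)
  structure(list(first_set = first_set, second_set = second_set,
                 sample_map = sample_map),
            class = "barcode_table")
}

#' Number of distinct barcode combinations
#'
#' @param table A [barcode_table()].
#' @return Integer: `|first_set| * |second_set|`.
#' @export
count_barcode_combinations <- function(table) {
  if (anyDuplicated(table$first_set) || anyDuplicated(table$second_set)) {
    abort("barcode codes must be unique within each set")
  }
  length(table$first_set) * length(table$second_set)
}

#' Simulate barcoded bisulfite amplicon reads
#'
#' For each (subject, target, haplotype) a negative-binomial number of
#' molecules is drawn. Each molecule takes the haplotype's allele at every
#' target SNP, methylates each CpG by its truth probability, undergoes
#' bisulfite conversion (unmethylated CpG cytosines read T with
#' `conversion_efficiency`; CpH cytosines read T except with
#' `conversion_failure_rate`), acquires substitution sequencing errors, and
#' is wrapped as `bc1 + U1 + insert + revcomp(U1) + revcomp(bc2)`, possibly
#' reverse-complemented. Exact duplicate reads are emitted at
#' `duplicate_rate`. A per-read truth table is returned alongside.
#'
#' @param cohort An `asm_cohort` from [simulate_cohort()].
#' @param config A [read_sim_config()].
#' @param barcodes A [barcode_table()]; defaults to
#'   [default_barcode_table()] over the cohort's subjects (at most 96).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return A list with `reads` (tibble: `read_id`, `sequence`, `quality`),
#'   `truth` (tibble: `read_id`, `sample_id`, `target`, `hap`, `allele`,
#'   `is_duplicate`, `meth` — the molecule's methylation vector as a string
#'   of 1/0/`.` over the target's CpGs), `barcodes`, and `molecule_count`.
#' @export
simulate_reads <- function(cohort, config = read_sim_config(),
                           barcodes = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "asm_cohort"),
            inherits(config, "read_sim_config"))
  targets <- cohort$targets
  if (any(is.na(targets$reference_seq))) {
    abort("all targets need a reference_seq to simulate reads")
  }
  subjects <- cohort$subjects$subject_id
  if (is.null(barcodes)) barcodes <- default_barcode_table(subjects)
  if (!all(subjects %in% barcodes$sample_map$sample_id)) {
    abort("barcode table does not map every subject (max 96 per library)")
  }
  withr_seed(seed)

  u1 <- u1_primer()
  u1rc <- revcomp(u1)
  bc <- barcodes$sample_map
  q_char <- rawToChar(as.raw(33L + config$quality))

  hap_tbl <- cohort$haplotypes
  hap_tbl$n_mol <- rnbinom(nrow(hap_tbl), mu = config$mean_depth,
                           size = config$depth_size)
  probs <- cohort$meth_probs

  out_reads <- list()
  out_truth <- list()
  mol_id <- 0L
  for (ti in seq_len(nrow(targets))) {
    tgt <- targets[ti, ]
    ref <- seq_chars(tgt$reference_seq)
    cpg_local <- cpg_positions(tgt$reference_seq) # 1-based in amplicon
    cpg_genomic <- cpg_local + tgt$start - 1L
    snps <- tgt$snps[[1]]
    snp_local <- snps$position - tgt$start + 1L
    hsub <- filter(hap_tbl, .data$target == tgt$gene_label, .data$n_mol > 0)
    psub <- filter(probs, .data$target == tgt$gene_label)
    for (hi in seq_len(nrow(hsub))) {
      h <- hsub[hi, ]
      hap_seq <- ref
      if (h$allele == "alt" && nrow(snps) > 0) {
        hap_seq[snp_local] <- snps$alt_allele
      }
      is_c <- hap_seq == "C"
      cpg_c <- intersect(which(is_c), cpg_local)
      cph_c <- setdiff(which(is_c), cpg_local)
      pvec <- psub$prob[psub$subject_id == h$subject_id & psub$hap == h$hap]
      names(pvec) <- psub$cpg_pos[psub$subject_id == h$subject_id &
                                    psub$hap == h$hap]
      p_at <- pvec[as.character(cpg_c + tgt$start - 1L)]
      bc_row <- bc[bc$sample_id == h$subject_id, ]
      for (m in seq_len(h$n_mol)) {
        mol_id <- mol_id + 1L
        mol <- hap_seq
        meth_state <- runif(length(cpg_c)) < p_at
        conv_fail <- runif(length(cpg_c)) >= config$conversion_efficiency
        mol[cpg_c] <- ifelse(meth_state | conv_fail, "C", "T")
        cph_keep <- runif(length(cph_c)) < config$conversion_failure_rate
        mol[cph_c] <- ifelse(cph_keep, "C", "T")
        err <- which(runif(length(mol)) < config$error_rate)
        if (length(err) > 0) {
          mol[err] <- vapply(mol[err], function(b) {
            sample(setdiff(DNA_BASES, b), 1)
          }, character(1))
        }
        insert <- paste(mol, collapse = "")
        read_seq <- paste0(bc_row$code1, u1, insert, u1rc,
                           revcomp(bc_row$code2))
        if (runif(1) < config$p_revcomp) read_seq <- revcomp(read_seq)
        meth_str <- paste(ifelse(cpg_genomic %in% (cpg_c + tgt$start - 1L),
                                 as.integer(meth_state)[match(
                                   cpg_genomic, cpg_c + tgt$start - 1L)],
                                 "."), collapse = "")
        rid <- sprintf("mol%07d", mol_id)
        n_copies <- 1L + (runif(1) < config$duplicate_rate)
        for (cp in seq_len(n_copies)) {
          this_id <- if (cp == 1L) rid else paste0(rid, "_dup", cp - 1L)
          out_reads[[length(out_reads) + 1L]] <- list(
            read_id = this_id, sequence = read_seq,
            quality = strrep(q_char, nchar(read_seq)))
          out_truth[[length(out_truth) + 1L]] <- list(
            read_id = this_id, sample_id = h$subject_id,
            target = tgt$gene_label, hap = h$hap, allele = h$allele,
            is_duplicate = cp > 1L, molecule_id = rid, meth = meth_str)
        }
      }
    }
  }
  list(reads = bind_rows(out_reads), truth = bind_rows(out_truth),
       barcodes = barcodes, molecule_count = mol_id)
}

#' Write / read FASTQ
#'
#' @param reads A tibble with `read_id`, `sequence`, `quality`.
#' @param path FASTQ file path (uncompressed).
#' @return `write_fastq()` the path, invisibly; `read_fastq()` a reads tibble.
#' @export
write_fastq <- function(reads, path) {
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(reads$quality))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # benign container detail: qualities live in metadata columns on read
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(read_id = names(qs),
         sequence = unname(as.character(qs)),
         quality = unname(as.character(Biostrings::quality(qs))))
}
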