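#' Amplicon target registry
#'
#' A target is one bisulfite PCR amplicon: a genomic interval (hg19, 1-based
#' inclusive), the strand the primers amplify, the EWAS reference ("index")
#' CpG probe it was designed around, and optionally the amplified-strand
#' reference sequence and a set of amplicon-internal SNPs used for allele
#' sorting. The packaged default registry holds the six smoking-associated
#' amplicons used throughout the package documentation.
#'
#' @param path Path to a TSV (columns `gene_label`, `reference_cpg`, `chrom`,
#'   `start`, `end`, `strand`, `expected_cpg_count`) or JSON registry file.
#' @return A tibble with one row per target and an empty `snps` list-column.
#'   Attach SNPs with [add_snps()] and sequences with [add_reference_seq()].
#' @export
#' @examples
#' targets <- target_registry()
#' amplicon_length(targets)
load_targets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as_tibble(jsonlite::fromJSON(path))
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(df) == 0) {
    return(empty_targets())
  }
  needed <- c("gene_label", "reference_cpg", "chrom", "start", "end",
              "strand", "expected_cpg_count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste("target registry is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  df <- df |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end),
           expected_cpg_count = as.integer(.data$expected_cpg_count)) |>
    as_tibble()
  bad <- which(is.na(df$start) | is.na(df$end) | df$start > df$end)
  if (length(bad) > 0) {
    abort(paste0("malformed coordinates for target(s): ",
                 paste(df$gene_label[bad], collapse = ", ")))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  df$snps <- rep(list(empty_snps()), nrow(df))
  if (!"reference_seq" %in% names(df)) df$reference_seq <- NA_character_
  validate_targets(df)
}

empty_targets <- function() {
  tibble(gene_label = character(), reference_cpg = character(),
         chrom = character(), start = integer(), end = integer(),
         strand = character(), expected_cpg_count = integer(),
         snps = list(), reference_seq = character())
}

empty_snps <- function() {
  tibble(snp_id = character(), position = integer(),
         ref_allele = character(), alt_allele = character(),
         is_cpg_snp = logical())
}

validate_targets <- function(targets) {
  if (any(targets$start > targets$end)) abort("invalid interval: start > end")
  has_seq <- !is.na(targets$reference_seq)
  if (any(has_seq)) {
    len <- nchar(targets$reference_seq[has_seq])
    exp_len <- targets$end[has_seq] - targets$start[has_seq] + 1L
    if (any(len != exp_len)) {
      abort(paste("reference_seq length does not match amplicon length for:",
                  paste(targets$gene_label[has_seq][len != exp_len],
                        collapse = ", ")))
    }
  }
  for (i in seq_len(nrow(targets))) {
    s <- targets$snps[[i]]
    if (nrow(s) == 0) next
    if (any(s$position < targets$start[i] | s$position > targets$end[i])) {
      abort(paste0("SNP outside target interval in ", targets$gene_label[i]))
    }
    if (any(s$ref_allele == s$alt_allele)) {
      abort(paste0("SNP with identical alleles in ", targets$gene_label[i]))
    }
  }
  targets
}

#' @rdname load_targets
#' @export
target_registry <- function() {
  load_targets(system.file("extdata", "targets.tsv", package = "haplometh"))
}

#' Amplicon lengths
#'
#' Appends `amplicon_length = end - start + 1` (bp, 1-based inclusive
#' coordinates) to a target registry.
#'
#' @param targets A target registry tibble (see [load_targets()]).
#' @return The input tibble with an `amplicon_length` integer column.
#' @export
amplicon_length <- function(targets) {
  if (any(targets$start > targets$end)) abort("invalid interval: start > end")
  mutate(targets, amplicon_length = .data$end - .data$start + 1L)
}

#' CpG positions in an amplicon sequence
#'
#' Scans the plus-strand (amplified-strand) sequence for CpG dinucleotides and
#' reports the genomic position of each C. CpG is its own reverse complement
#' as a dinucleotide class, so the count is strand-symmetric.
#'
#' @param seq Uppercase DNA string whose length equals the amplicon length.
#' @param start Genomic position of the first base (default 1).
#' @param target Optionally, a one-row target registry to take `start` from
#'   and to validate the sequence length against.
#' @return Integer vector of 1-based genomic positions, strictly increasing.
#' @export
cpg_positions <- function(seq, start = 1L, target = NULL) {
  if (!is.null(target)) {
    stopifnot(nrow(target) == 1)
    if (nchar(seq) != target$end - target$start + 1L) {
      abort("sequence length does not match amplicon length")
    }
    start <- target$start
  }
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  as.integer(hits) + as.integer(start) - 1L
}

#' Attach SNP definitions to a target registry
#'
#' @param targets A target registry tibble.
#' @param snps A tibble with columns `gene_label`, `snp_id`, `position`
#'   (1-based genomic), `ref_allele`, `alt_allele`, and optionally
#'   `is_cpg_snp`. If `is_cpg_snp` is absent and reference sequences are
#'   available it is derived (a SNP overlapping either base of a CpG).
#' @return The registry with its `snps` list-column populated.
#' @export
add_snps <- function(targets, snps) {
  snps <- as_tibble(snps)
  if (!"is_cpg_snp" %in% names(snps)) snps$is_cpg_snp <- NA
  targets$snps <- lapply(seq_len(nrow(targets)), function(i) {
    s <- filter(snps, .data$gene_label == targets$gene_label[i]) |>
      select(-"gene_label") |>
      mutate(position = as.integer(.data$position))
    if (nrow(s) > 0 && any(is.na(s$is_cpg_snp)) &&
        !is.na(targets$reference_seq[i])) {
      cpg <- cpg_positions(targets$reference_seq[i], start = targets$start[i])
      overlaps <- s$position %in% c(cpg, cpg + 1L)
      s$is_cpg_snp <- ifelse(is.na(s$is_cpg_snp), overlaps, s$is_cpg_snp)
    }
    s$is_cpg_snp[is.na(s$is_cpg_snp)] <- FALSE
    s
  })
  validate_targets(targets)
}

#' Attach amplified-strand reference sequences
#'
#' @param targets A target registry tibble.
#' @param seqs Named character vector or a named list of DNA strings,
#'   names matching `gene_label`; or a FASTA path.
#' @return The registry with `reference_seq` filled in.
#' @export
add_reference_seq <- function(targets, seqs) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs)) {
    ss <- Biostrings::readDNAStringSet(seqs)
    seqs <- setNames(as.character(ss), names(ss))
  }
  seqs <- unlist(seqs)
  idx <- match(targets$gene_label, names(seqs))
  targets$reference_seq <- ifelse(is.na(idx), targets$reference_seq,
                                  toupper(seqs[idx]))
  validate_targets(targets)
}
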