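#' Bisulfite conversion of a reference sequence
#'
#' Fully converts a sequence into bisulfite ("three-letter") space by
#' replacing every C with T. Alignment happens between a converted read and
#' a converted reference so that methylation state does not penalise the
#' alignment; methylation is then called from the original read base over
#' each reference CpG.
#'
#' @param seq Uppercase DNA string (A/C/G/T/N).
#' @return The converted string, same length.
#' @export
convert_reference <- function(seq) {
  if (grepl("[^ACGTN]", seq)) abort("sequence contains non-ACGTN characters")
  chartr("C", "T", seq)
}

#' Bisulfite allele call at a SNP
#'
#' Compares a read base against the two alleles after bisulfite
#' equivalence-classing: on a plus-strand amplicon C and T are
#' indistinguishable (unmethylated C reads as T), on a minus-strand amplicon
#' G and A are (in plus-strand coordinates). SNPs whose alleles collapse to
#' the same class — C>T on the plus strand, G>A on the minus strand — are
#' unusable and always return `"unknown"`, as are gapped or off-class bases.
#'
#' @param read_base Single original read base (plus-strand coordinates), or
#'   `NA` for a gapped position.
#' @param ref_allele,alt_allele SNP alleles (plus-strand).
#' @param strand Amplified strand, `"+"` or `"-"`.
#' @return `"ref"`, `"alt"`, or `"unknown"`.
#' @export
call_allele <- function(read_base, ref_allele, alt_allele, strand = "+") {
  collapse <- function(b) {
    if (strand == "+") ifelse(b == "C", "T", b) else ifelse(b == "G", "A", b)
  }
  r <- collapse(ref_allele)
  a <- collapse(alt_allele)
  if (r == a) return("unknown")
  if (is.na(read_base)) return("unknown")
  b <- collapse(read_base)
  if (b == r) "ref" else if (b == a) "alt" else "unknown"
}

# per-target alignment context, precomputed once
target_context <- function(targets) {
  lapply(seq_len(nrow(targets)), function(i) {
    tgt <- targets[i, ]
    ref_chars <- seq_chars(tgt$reference_seq)
    conv_chars <- ifelse(ref_chars == "C", "T", ref_chars)
    cpg_local <- cpg_positions(tgt$reference_seq)
    cph_local <- setdiff(which(ref_chars == "C"), cpg_local)
    snps <- tgt$snps[[1]]
    # alleles restated on the amplified strand, where conversion is C->T
    if (nrow(snps) > 0 && tgt$strand == "-") {
      comp <- function(b) chartr("ACGT", "TGCA", b)
      snps$ref_allele <- comp(snps$ref_allele)
      snps$alt_allele <- comp(snps$alt_allele)
    }
    list(gene_label = tgt$gene_label, start = tgt$start,
         strand = tgt$strand, len = length(ref_chars),
         ref_chars = ref_chars, conv_chars = conv_chars,
         conv_str = paste(conv_chars, collapse = ""),
         cpg_local = cpg_local, cph_local = cph_local,
         snps = snps, snp_local = snps$position - tgt$start + 1L)
  })
}

#' Align insert reads to amplicon references and call methylation/alleles
#'
#' Each read (and its reverse complement) is converted to bisulfite space
#' and compared against every target's converted reference. Reads matching
#' a reference's length take an exact ungapped comparison; length mismatches
#' fall back to global affine-gap dynamic programming
#' (`Biostrings::pairwiseAlignment`). The best-scoring target/orientation
#' wins; reads below the identity floor are reported unmapped. Per read the
#' following are derived from ORIGINAL bases over the alignment: methylation
#' call at each reference CpG (C = methylated, T = unmethylated, other/gap =
#' missing), CpH conversion tallies, and an allele call at each target SNP.
#'
#' @param reads Tibble with `read_id`, `sample_id`, and `insert` (from
#'   [trim_flanks()]); rows with `NA` insert are dropped.
#' @param targets Target registry with `reference_seq` and `snps`.
#' @param min_identity Minimum fraction of matching converted-space bases.
#' @return A tibble, one row per input read: `read_id`, `sample_id`,
#'   `target`, `mapped`, `cigar`, `aligned_start`, `n_mismatch`, `identity`,
#'   `meth` (string over the target's CpGs: `1` methylated, `0`
#'   unmethylated, `.` missing), `alleles` (string over the target's SNPs:
#'   `R`/`A`/`U`), `cph_total`, `cph_unconverted`.
#' @export
align_reads <- function(reads, targets, min_identity = 0.8) {
  stopifnot(all(c("read_id", "insert") %in% names(reads)))
  if (!"sample_id" %in% names(reads)) reads$sample_id <- NA_character_
  reads <- reads[!is.na(reads$insert), , drop = FALSE]
  ctx <- target_context(targets)
  rows <- vector("list", nrow(reads))
  for (k in seq_len(nrow(reads))) {
    rows[[k]] <- align_one(reads$insert[k], ctx, min_identity,
                           reads$read_id[k], reads$sample_id[k])
  }
  bind_rows(rows)
}

align_one <- function(insert, ctx, min_identity, read_id, sample_id) {
  orients <- list(fwd = insert, rev = revcomp(insert))
  best <- NULL
  for (ori in names(orients)) {
    ins <- orients[[ori]]
    ch <- seq_chars(ins)
    conv <- ifelse(ch == "C", "T", ch)
    for (tc in ctx) {
      if (length(conv) == tc$len) {
        mm <- sum(conv != tc$conv_chars)
        ident <- 1 - mm / tc$len
        if (is.null(best) || ident > best$identity) {
          best <- list(tc = tc, chars = ch, identity = ident, n_mismatch = mm,
                       cigar = paste0(tc$len, "M"),
                       map = seq_len(tc$len), lead_del = 0L)
        }
      }
    }
  }
  if (is.null(best)) {
    # gapped path: global DP against each target, both orientations
    for (ori in names(orients)) {
      ins <- orients[[ori]]
      conv_str <- chartr("C", "T", ins)
      for (tc in ctx) {
        al <- dp_align(conv_str, tc$conv_str)
        ident <- al$n_match / tc$len
        if (is.null(best) || ident > best$identity) {
          best <- list(tc = tc, chars = seq_chars(ins), identity = ident,
                       n_mismatch = al$n_mismatch, cigar = al$cigar,
                       map = al$map, lead_del = al$lead_del)
        }
      }
    }
  }
  tc <- best$tc
  if (best$identity < min_identity) {
    return(tibble(read_id = read_id, sample_id = sample_id,
                  target = NA_character_, mapped = FALSE,
                  cigar = NA_character_, aligned_start = NA_integer_,
                  n_mismatch = best$n_mismatch, identity = best$identity,
                  meth = NA_character_, alleles = NA_character_,
                  cph_total = 0L, cph_unconverted = 0L))
  }
  base_at <- function(local_pos) {
    rp <- best$map[local_pos]
    ifelse(is.na(rp), NA_character_, best$chars[rp])
  }
  cpg_base <- base_at(tc$cpg_local)
  meth <- ifelse(is.na(cpg_base), ".",
                 ifelse(cpg_base == "C", "1",
                        ifelse(cpg_base == "T", "0", ".")))
  cph_base <- base_at(tc$cph_local)
  cph_total <- sum(cph_base %in% c("C", "T"))
  cph_unconv <- sum(cph_base %in% "C")
  alleles <- ""
  if (nrow(tc$snps) > 0) {
    ab <- vapply(seq_along(tc$snp_local), function(j) {
      call_allele(base_at(tc$snp_local[j]),
                  tc$snps$ref_allele[j], tc$snps$alt_allele[j], strand = "+")
    }, character(1))
    alleles <- paste(c(ref = "R", alt = "A", unknown = "U")[ab],
                     collapse = "")
  }
  tibble(read_id = read_id, sample_id = sample_id,
         target = tc$gene_label, mapped = TRUE,
         cigar = best$cigar,
         aligned_start = tc$start + best$lead_del,
         n_mismatch = best$n_mismatch, identity = best$identity,
         meth = paste(meth, collapse = ""), alleles = alleles,
         cph_total = as.integer(cph_total),
         cph_unconverted = as.integer(cph_unconv))
}

# global affine-gap DP via Biostrings; returns CIGAR, ref->read map, counts
dp_align <- function(read_conv, ref_conv) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(read_conv, ref_conv, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 4, gapExtension = 1)
  p <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  op <- ifelse(p == "-", "D", ifelse(s == "-", "I", "M"))
  r <- rle(op)
  cigar <- paste0(r$lengths, r$values, collapse = "")
  ref_len <- sum(s != "-")
  map <- rep(NA_integer_, ref_len)
  rp <- 0L
  sp <- 0L
  for (i in seq_along(op)) {
    if (op[i] == "M") {
      rp <- rp + 1L; sp <- sp + 1L; map[sp] <- rp
    } else if (op[i] == "I") {
      rp <- rp + 1L
    } else {
      sp <- sp + 1L
    }
  }
  lead_del <- if (r$values[1] == "D") r$lengths[1] else 0L
  n_match <- sum(op == "M" & p == s)
  list(cigar = cigar, map = map, lead_del = lead_del,
       n_match = n_match, n_mismatch = sum(op == "M" & p != s),
       score = Biostrings::score(pa))
}

#' Bisulfite conversion filter
#'
#' Flags reads by the strict unconverted-CpH gate: a read passes iff its
#' unconverted CpH fraction is strictly below the threshold (a read at
#' exactly 5% fails the default gate). Reads with no observable CpH sites
#' pass vacuously — failed conversion is unobservable without CpH — and are
#' separately flagged.
#'
#' @param aligned Output of [align_reads()].
#' @param threshold Maximum unconverted CpH fraction (exclusive).
#' @return `aligned` with logical `conv_pass` and `cph_vacuous` columns.
#' @export
filter_conversion <- function(aligned, threshold = 0.05) {
  aligned$cph_vacuous <- aligned$cph_total == 0L
  aligned$conv_pass <- aligned$cph_vacuous |
    (aligned$cph_unconverted / pmax(aligned$cph_total, 1L)) < threshold
  aligned
}

#' Remove PCR duplicates
#'
#' Within each (sample, target) group, reads sharing the duplicate key —
#' aligned start, CIGAR, full methylation-call vector, and full allele-call
#' vector — are collapsed to one representative (first by read id). The
#' default key is deliberately conservative; `key = "position"` keeps only
#' start/CIGAR.
#'
#' @param aligned Output of [align_reads()] (mapped reads).
#' @param key `"full"` (default) or `"position"`.
#' @return The deduplicated tibble.
#' @export
deduplicate <- function(aligned, key = c("full", "position")) {
  key <- match.arg(key)
  aligned <- arrange(aligned, .data$read_id)
  kv <- if (key == "full") {
    paste(aligned$sample_id, aligned$target, aligned$aligned_start,
          aligned$cigar, aligned$meth, aligned$alleles)
  } else {
    paste(aligned$sample_id, aligned$target, aligned$aligned_start,
          aligned$cigar)
  }
  aligned[!duplicated(kv), , drop = FALSE]
}

#' Per-target bisulfite conversion rate
#'
#' `1 - sum(unconverted CpH) / sum(CpH)` over passing reads; the QC gate the
#' pipeline audits is a rate of at least 0.98 per target.
#'
#' @param aligned Aligned (typically conversion-filtered) reads.
#' @param passing_only Use only reads with `conv_pass`, when present.
#' @return Tibble: `target`, `cph_total`, `cph_unconverted`,
#'   `conversion_rate` (`NA` when no CpH observed).
#' @export
conversion_rate <- function(aligned, passing_only = TRUE) {
  if (passing_only && "conv_pass" %in% names(aligned)) {
    aligned <- filter(aligned, .data$conv_pass)
  }
  aligned |>
    filter(.data$mapped) |>
    summarise(cph_total = sum(.data$cph_total),
              cph_unconverted = sum(.data$cph_unconverted),
              .by = "target") |>
    mutate(conversion_rate = ifelse(
      .data$cph_total > 0,
      1 - .data$cph_unconverted / .data$cph_total, NA_real_))
}
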