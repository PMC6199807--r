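#' Mean-quality read filter
#'
#' Keeps reads whose quality is no less than `min_mean_q` (inclusive:
#' a read with mean quality exactly 30 passes the default gate). By default
#' the mean Phred score over the read is used, mirroring the aggregate
#' accuracy of circular-consensus reads; `per_base = TRUE` instead requires
#' every base to reach the threshold.
#'
#' @param reads Tibble with `sequence` and `quality` (Phred+33 string).
#' @param min_mean_q Quality threshold (default 30).
#' @param per_base Require all bases, not the mean, to pass.
#' @return The passing subset of `reads`, with a `mean_quality` column.
#' @export
quality_filter <- function(reads, min_mean_q = 30, per_base = FALSE) {
  if (nrow(reads) == 0) return(mutate(reads, mean_quality = numeric(0)))
  qs <- lapply(reads$quality, function(q) utf8ToInt(q) - 33L)
  reads$mean_quality <- vapply(qs, mean, numeric(1))
  keep <- if (per_base) {
    vapply(qs, function(x) all(x >= min_mean_q), logical(1))
  } else {
    reads$mean_quality >= min_mean_q
  }
  reads[keep, , drop = FALSE]
}

#' Exact-match dual-barcode demultiplexing
#'
#' The first five bases carry the first barcode and the last five the
#' reverse complement of the second. Both codes must match a mapped
#' combination exactly — no errors in the barcode sequences are allowed —
#' otherwise the read is discarded. Reads are tried in both orientations;
#' when the reverse complement matches, the read is orientation-normalised
#' so downstream flanks sit at fixed offsets.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param table A [barcode_table()].
#' @return A list: `assigned` (reads tibble with `sample_id`, normalised
#'   orientation), `n_discarded`, and `report` (per-sample read counts).
#' @export
demultiplex <- function(reads, table) {
  map <- table$sample_map
  key <- paste(map$code1, map$code2)
  lookup <- setNames(map$sample_id, key)
  n <- nrow(reads)
  if (n == 0) {
    return(list(assigned = mutate(reads, sample_id = character(0)),
                n_discarded = 0L,
                report = tibble(sample_id = character(0), n_reads = integer(0))))
  }
  fwd1 <- substr(reads$sequence, 1L, 5L)
  len <- nchar(reads$sequence)
  fwd2 <- revcomp(substr(reads$sequence, len - 4L, len))
  hit_f <- unname(lookup[paste(fwd1, fwd2)])

  rc <- revcomp(reads$sequence)
  rc1 <- substr(rc, 1L, 5L)
  rc2 <- revcomp(substr(rc, len - 4L, len))
  hit_r <- unname(lookup[paste(rc1, rc2)])

  sample_id <- ifelse(!is.na(hit_f), hit_f, hit_r)
  use_rc <- is.na(hit_f) & !is.na(hit_r)
  out <- reads
  out$sequence[use_rc] <- rc[use_rc]
  out$quality[use_rc] <- vapply(strsplit(reads$quality[use_rc], ""),
                                function(x) paste(rev(x), collapse = ""),
                                character(1))
  out$sample_id <- sample_id
  assigned <- out[!is.na(sample_id), , drop = FALSE]
  list(assigned = assigned,
       n_discarded = sum(is.na(sample_id)),
       report = count(assigned, .data$sample_id, name = "n_reads"))
}

#' Trim barcodes and shared-primer flanks from demultiplexed reads
#'
#' Expects orientation-normalised reads laid out as
#' `bc1(5) + U1 + insert + revcomp(U1) + revcomp(bc2)(5)`. The shared
#' "panhandle" primer is verified at both fixed offsets within a Hamming
#' mismatch budget; reads where it is not found are flagged unassignable
#' rather than trimmed.
#'
#' @param reads Demultiplexed reads tibble.
#' @param u1 The shared primer sequence.
#' @param barcode_len Barcode length at each end.
#' @param max_mismatch Mismatch budget per primer copy.
#' @return The reads tibble with `insert` (the amplified-strand amplicon
#'   body, `NA` when unassignable) and `unassignable` columns.
#' @export
trim_flanks <- function(reads, u1 = u1_primer(), barcode_len = 5L,
                        max_mismatch = 3L) {
  nu <- nchar(u1)
  len <- nchar(reads$sequence)
  flank <- barcode_len + nu
  too_short <- len <= 2L * flank
  left <- substr(reads$sequence, barcode_len + 1L, flank)
  right <- substr(reads$sequence, len - flank + 1L, len - barcode_len)
  mm_left <- hamming(left, u1)
  mm_right <- hamming(right, revcomp(u1))
  ok <- !too_short & mm_left <= max_mismatch & mm_right <= max_mismatch
  reads$insert <- ifelse(ok, substr(reads$sequence, flank + 1L, len - flank),
                         NA_character_)
  reads$unassignable <- !ok
  reads
}

# vectorised Hamming distance of equal-length strings vs one pattern
hamming <- function(x, pattern) {
  pat <- seq_chars(pattern)
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    if (length(ch) != length(pat)) return(length(pat))
    sum(ch != pat)
  }, integer(1))
}
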