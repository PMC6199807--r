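# Internal sequence helpers. All coordinates in this package are 1-based
# inclusive; amplicon sequences are stored as the amplified strand.

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence string into a character vector of bases
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

logit <- function(p) qlogis(p)
inv_logit <- function(x) plogis(x)

# derive a reproducible child seed (kept below 2^31) from a base seed
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 7919) %% 2147483563) + 1L
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", name, "` must be in [0, 1]"))
  }
  invisible(x)
}
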