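# Independent oracles and small fixture builders shared across tests.

# Full (unbanded) global affine-gap dynamic programme, written independently
# of the package's alignment path. Gap of length L costs open + L * ext,
# matching the pairwise-alignment convention used by the implementation.
dp_oracle_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 4, gap_ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1) # gap in b (consume a)
  Iy <- matrix(NEG, n + 1, m + 1) # gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(gap_open + j * gap_ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# exhaustive pairwise-concordance AUC oracle
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + (p > q) + 0.5 * (p == q)
  }
  conc / (length(pos) * length(neg))
}

# hand step-up BH oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# small two-target synthetic panel shared by read-level tests
tiny_targets <- function(seed = 11, n_cpg_snps = c(0L, 0L)) {
  simulate_targets(n_targets = 2, lengths = 400L, n_cpgs = 10L,
                   n_cpg_snps = n_cpg_snps, seed = seed)
}

# a minimal hand-built aligned-read tibble for haplotype-sorting tests
make_aligned <- function(sample_id, target, meth, alleles,
                         n_cpg = nchar(meth[1])) {
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(sample_id)),
    sample_id = sample_id, target = target, mapped = TRUE,
    cigar = paste0(n_cpg, "M"), aligned_start = 1L,
    n_mismatch = 0L, identity = 1, meth = meth, alleles = alleles,
    cph_total = 10L, cph_unconverted = 0L)
}

# deterministic toy importance oracle: absolute mean group difference
tstat_importance <- function(X, y, seed = 1L, ...) {
  abs(colMeans(X[y == 1, , drop = FALSE]) -
        colMeans(X[y == 0, , drop = FALSE]))
}
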