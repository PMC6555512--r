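# Shared fixtures, generated in code (no stored data files).

STANDARD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) {
  paste(sample(STANDARD_AA, len, replace = TRUE), collapse = "")
}

random_gseq <- function(len, n_groups = 7L) {
  sample.int(n_groups, len, replace = TRUE)
}

# Write a small FASTA file; `wrap` controls line wrapping of sequences.
write_toy_fasta <- function(records, path = tempfile(fileext = ".fasta"),
                            wrap = 10L) {
  lines <- unlist(lapply(names(records), function(id) {
    s <- records[[id]]
    chunks <- substring(s, seq(1L, nchar(s), wrap),
                        pmin(seq(1L, nchar(s), wrap) + wrap - 1L, nchar(s)))
    c(paste0(">", id), chunks)
  }))
  writeLines(lines, path)
  path
}

# Two well-separated Gaussian blobs in `dim` dimensions as a
# pair_feature_table stand-in for a linearly separable problem.
separable_table <- function(n_per_class = 120L, dim = 58L, seed = 1L,
                            gap = 3) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * dim, -gap / 2, 1),
                    n_per_class),
             matrix(stats::rnorm(n_per_class * dim, gap / 2, 1),
                    n_per_class))
  colnames(x) <- paste0("f", seq_len(dim))
  rownames(x) <- paste0("p", seq_len(2L * n_per_class))
  labels <- rep(c(0L, 1L), each = n_per_class)
  structure(list(x = x, labels = labels,
                 pairs = data.frame(id_a = rownames(x), id_b = rownames(x),
                                    label = labels),
                 encoder = mosppi::encoder_spec("MOS"),
                 n_pos = n_per_class, n_neg = n_per_class, n_skipped = 0L),
            class = "pair_feature_table")
}

# Exhaustive pairwise-rank AUC: fraction of (positive, negative) pairs
# ranked correctly, ties counted one half.
auc_rank_oracle <- function(labels, probs) {
  pos <- probs[labels == 1L]
  neg <- probs[labels == 0L]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Conservation identities every sequence matrix must satisfy.
expect_mos_invariants <- function(mos, gseq) {
  L <- length(gseq)
  counts <- tabulate(gseq, nbins = nrow(mos$m))
  expect_true(all(mos$m >= 0))
  expect_equal(sum(mos$m), L * (L + 1) / 2)
  expect_equal(diag(mos$m), counts * (counts + 1) / 2)
  off <- outer(counts, counts)
  sym <- mos$m + t(mos$m)
  diag(sym) <- diag(off) # only off-diagonal identity is asserted
  expect_equal(sym, off)
}
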