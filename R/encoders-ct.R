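#' Conjoint-triad (CT) sequence encoder
#'
#' Counts every consecutive residue triad after reduction to the seven-group
#' alphabet: a sequence of length L yields L-2 sliding windows, each binned
#' into one of 7^3 = 343 triad classes. Raw counts `f` are rescaled per
#' protein as `d = (f - min f) / max f`, the conventional conjoint-triad
#' normalization, giving a 343-dimensional vector per protein (686 per pair).
#'
#' @inheritParams map_to_groups
#' @return named numeric vector of length 343 (`ct_<i>_<j>_<k>` for the
#'   group triad i-j-k).
#' @export
ct_features <- function(seq, alphabet = build_group_alphabet()) {
  gseq <- map_to_groups(seq, alphabet)
  L <- length(gseq)
  abort_if(L < 3L, "sequence length %d is too short for triads (need >= 3)", L)
  n <- alphabet$n_groups
  tri <- (gseq[seq_len(L - 2L)] - 1L) * n * n +
    (gseq[seq_len(L - 2L) + 1L] - 1L) * n +
    gseq[seq_len(L - 2L) + 2L]
  f <- tabulate(tri, nbins = n^3)
  d <- (f - min(f)) / max(f)
  grid <- expand.grid(k = seq_len(n), j = seq_len(n), i = seq_len(n))
  names(d) <- sprintf("ct_%d_%d_%d", grid$i, grid$j, grid$k)
  d
}

# Raw triad counts (un-normalized); used by tests and diagnostics.
ct_counts <- function(seq, alphabet = build_group_alphabet()) {
  gseq <- map_to_groups(seq, alphabet)
  abort_if(length(gseq) < 3L, "need >= 3 residues")
  n <- alphabet$n_groups
  L <- length(gseq)
  tri <- (gseq[seq_len(L - 2L)] - 1L) * n * n +
    (gseq[seq_len(L - 2L) + 1L] - 1L) * n + gseq[seq_len(L - 2L) + 2L]
  tabulate(tri, nbins = n^3)
}
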