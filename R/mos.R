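#' Per-group residue counts (vector of sequence)
#'
#' Tallies how many positions of a group-index sequence fall in each group.
#' This is the VOS of the streaming matrix algorithm: scanned from the end of
#' the sequence, it holds the running suffix counts.
#'
#' @param gseq integer vector of group indices in `1..n_groups`.
#' @param n_groups number of groups (default 7).
#' @return integer vector of length `n_groups`; entries sum to `length(gseq)`.
#' @export
compute_vos <- function(gseq, n_groups = 7L) {
  check_gseq(gseq, n_groups)
  tabulate(gseq, nbins = n_groups)
}

check_gseq <- function(gseq, n_groups) {
  abort_if(length(gseq) == 0L, "group sequence must be non-empty")
  abort_if(anyNA(gseq) || !is.numeric(gseq),
           "group sequence must be numeric without NA")
  abort_if(any(gseq < 1L | gseq > n_groups | gseq != as.integer(gseq)),
           "group indices must be integers in 1..%d", n_groups)
  invisible(TRUE)
}

new_sequence_matrix <- function(m, L) {
  dimnames(m) <- NULL
  structure(list(m = m, L = as.integer(L)), class = "sequence_matrix")
}

#' Sequence matrix by the linear streaming scan
#'
#' Accumulates the matrix of sequence (MOS): entry `m[i, j]` counts ordered
#' position pairs `p <= q` whose p-th residue lies in group `i` and q-th in
#' group `j`. The scan runs from the last position to the first; at each
#' position the suffix count vector (VOS) is updated and added to the row of
#' the current position's group, giving O(L * n_groups) time. The result
#' satisfies the conservation identities: all entries sum to `L(L+1)/2`,
#' `m[i, i] = C_i (C_i + 1) / 2`, and `m[i, j] + m[j, i] = C_i C_j` for
#' `i != j`, where `C_i` is the group-i residue count.
#'
#' @inheritParams compute_vos
#' @return an object of class `sequence_matrix`: list with the `n_groups` x
#'   `n_groups` count matrix `m` (stored as doubles, exact for L below ~9e7)
#'   and the source length `L`.
#' @seealso [compute_mos_bruteforce()] for the quadratic pair-enumeration
#'   reference, [normalize_matrix()] for the probability-scaled matrix.
#' @export
compute_mos_streaming <- function(gseq, n_groups = 7L) {
  check_gseq(gseq, n_groups)
  L <- length(gseq)
  vos <- numeric(n_groups)
  m <- matrix(0, n_groups, n_groups)
  for (i in seq(L, 1L)) {
    s <- gseq[i]
    vos[s] <- vos[s] + 1
    m[s, ] <- m[s, ] + vos
  }
  new_sequence_matrix(m, L)
}

#' Sequence matrix by explicit pair enumeration
#'
#' Reference implementation of the matrix of sequence: enumerates every
#' ordered position pair `p <= q` and tallies the group pair
#' `(group(p), group(q))`. Quadratic in sequence length; intended as an
#' independent cross-check of [compute_mos_streaming()] on sequences up to a
#' few thousand residues.
#'
#' @inheritParams compute_vos
#' @return a `sequence_matrix`, elementwise equal to the streaming result.
#' @export
compute_mos_bruteforce <- function(gseq, n_groups = 7L) {
  check_gseq(gseq, n_groups)
  L <- length(gseq)
  pairs <- which(upper.tri(matrix(TRUE, L, L), diag = TRUE), arr.ind = TRUE)
  cell <- (gseq[pairs[, 1L]] - 1L) * n_groups + gseq[pairs[, 2L]]
  m <- matrix(as.numeric(tabulate(cell, nbins = n_groups^2)),
              n_groups, n_groups, byrow = TRUE)
  new_sequence_matrix(m, L)
}

#' Normalize a sequence matrix to a probability matrix
#'
#' Divides each entry by the total mass `L(L+1)/2`, so entries lie in
#' `[0, 1]` and sum to 1.
#'
#' @param mos a `sequence_matrix`.
#' @return an object of class `normalized_matrix`: list with the real matrix
#'   `p` and the source length `L`.
#' @export
normalize_matrix <- function(mos) {
  abort_if(!inherits(mos, "sequence_matrix"), "`mos` must be a sequence_matrix")
  L <- mos$L
  p <- mos$m * (2 / (L * (L + 1)))
  structure(list(p = p, L = L), class = "normalized_matrix")
}

# Row-major upper-triangle (diagonal included) index pairs for an n x n
# matrix: (1,1),(1,2),...,(1,n),(2,2),...,(n,n). Frozen flattening order.
upper_tri_order <- function(n) {
  idx <- do.call(rbind, lapply(seq_len(n), function(i) cbind(i, i:n)))
  colnames(idx) <- NULL
  idx
}

#' Assemble the 29-dimensional MOS feature vector
#'
#' Flattens the diagonal and above-diagonal entries of the normalized
#' sequence matrix in row-major order — (1,1), (1,2), ..., (1,7), (2,2), ...,
#' (7,7), 28 values for 7 groups — and appends the reciprocal sequence length
#' `1/L` as a length tag, separating equal-composition proteins of different
#' lengths.
#'
#' @param p a `normalized_matrix`.
#' @param L source sequence length; defaults to the length recorded in `p`.
#' @return a named numeric vector of length 29 (`m11`, `m12`, ..., `m77`,
#'   `invlen`).
#' @export
mos_features <- function(p, L = p$L) {
  abort_if(!inherits(p, "normalized_matrix"),
           "`p` must be a normalized_matrix")
  abort_if(length(L) != 1L || L < 1, "`L` must be a positive integer")
  n <- nrow(p$p)
  idx <- upper_tri_order(n)
  vals <- c(p$p[idx], 1 / L)
  names(vals) <- c(sprintf("m%d%d", idx[, 1L], idx[, 2L]), "invlen")
  vals
}

#' MOS-encode a protein sequence
#'
#' Convenience wrapper: reduces the sequence to the seven-group alphabet,
#' accumulates the sequence matrix with the streaming scan, normalizes, and
#' flattens to the 29-dimensional feature vector.
#'
#' @inheritParams map_to_groups
#' @return named numeric vector of length 29.
#' @examples
#' v <- encode_mos(strrep("AGCRQTSPLGVKSE", 4))
#' length(v) # 29
#' @export
encode_mos <- function(seq, alphabet = build_group_alphabet()) {
  gseq <- map_to_groups(seq, alphabet)
  mos_features(normalize_matrix(compute_mos_streaming(gseq,
                                                      alphabet$n_groups)))
}
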