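# Fractional [start, end) boundaries of the ten local-descriptor regions:
# four quarters, the two halves, the central 50%, the first and last 75%,
# and the central 75%.
ld_region_fractions <- function() {
  list(
    q1 = c(0, 0.25), q2 = c(0.25, 0.5), q3 = c(0.5, 0.75), q4 = c(0.75, 1),
    h1 = c(0, 0.5), h2 = c(0.5, 1),
    mid50 = c(0.25, 0.75),
    first75 = c(0, 0.75), last75 = c(0.25, 1),
    mid75 = c(0.125, 0.875)
  )
}

# 1-based inclusive index range for a fractional region of a length-L
# sequence. Boundaries use floor on 0-based half-open slices:
# positions floor(a*L)+1 .. floor(b*L). Frozen tie-break.
ld_region_indices <- function(L, frac) {
  start <- floor(frac[1L] * L) + 1L
  end <- floor(frac[2L] * L)
  seq.int(start, end)
}

# 63 features of one region: 7 composition + 21 transition + 35 distribution.
ld_region_features <- function(gr, n_groups = 7L) {
  n <- length(gr)
  comp <- tabulate(gr, nbins = n_groups) / n

  trans <- numeric(n_groups * (n_groups - 1L) / 2L)
  if (n >= 2L) {
    a <- gr[-n]
    b <- gr[-1L]
    keep <- a != b
    if (any(keep)) {
      lo <- pmin(a[keep], b[keep])
      hi <- pmax(a[keep], b[keep])
      # index of unordered pair (lo, hi), lo < hi, in row-major order
      k <- (lo - 1L) * n_groups - lo * (lo - 1L) / 2L + (hi - lo)
      tab <- tabulate(k, nbins = length(trans))
      trans <- tab / (n - 1L)
    }
  }

  distr <- numeric(n_groups * 5L)
  for (g in seq_len(n_groups)) {
    pos <- which(gr == g)
    if (length(pos) > 0L) {
      np <- length(pos)
      picks <- pos[c(1L, ceiling(np * c(0.25, 0.5, 0.75)), np)]
      distr[(g - 1L) * 5L + 1:5] <- picks / n
    }
  }
  c(comp, trans, distr)
}

#' Local-descriptor (LD) sequence encoder
#'
#' Computes composition/transition/distribution features of the seven-group
#' reduced sequence over ten overlapping regions: the four quarters, the two
#' halves, the central 50%, the first 75%, the last 75% and the central 75%.
#' Each region contributes 7 composition fractions, 21 unordered-group-pair
#' transition frequencies (adjacent positions changing group, normalized by
#' region length minus one) and 35 distribution values (relative positions
#' of the first, 25th-, 50th-, 75th-percentile and last occurrence of each
#' group; zero when the group is absent), for 63 features per region and
#' 630 per protein (1260 per pair).
#'
#' @inheritParams map_to_groups
#' @return named numeric vector of length 630, region-major
#'   (`ld_<region>_<feature>`).
#' @export
ld_features <- function(seq, alphabet = build_group_alphabet()) {
  gseq <- map_to_groups(seq, alphabet)
  L <- length(gseq)
  abort_if(L < 10L,
           "sequence length %d is too short for local descriptors (need >= 10)",
           L)
  n <- alphabet$n_groups
  fracs <- ld_region_fractions()
  pair_names <- {
    idx <- upper_tri_order(n)
    idx <- idx[idx[, 1L] != idx[, 2L], , drop = FALSE]
    sprintf("t%d%d", idx[, 1L], idx[, 2L])
  }
  feat_names <- c(sprintf("c%d", seq_len(n)), pair_names,
                  as.vector(t(outer(seq_len(n), c("first", "q25", "q50",
                                                  "q75", "last"),
                                    function(g, w) sprintf("d%d_%s", g, w)))))
  out <- lapply(names(fracs), function(rn) {
    v <- ld_region_features(gseq[ld_region_indices(L, fracs[[rn]])], n)
    names(v) <- sprintf("ld_%s_%s", rn, feat_names)
    v
  })
  unlist(out)
}
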