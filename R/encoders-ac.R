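# Physicochemical property scales used by the auto-covariance encoder.
# Seven classical per-residue scales: hydrophobicity (Eisenberg consensus),
# hydrophilicity (Hopp-Woods), side-chain volume (A^3), polarity (Grantham),
# polarizability, solvent-accessible surface area and net charge index of
# side chains — the standard seven-scale set of the sequence auto-covariance
# literature. Rows: the 20 standard residues; columns: scales. Each scale is
# z-standardized across the 20 residues before use.
ac_property_scales <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- cbind(
    hydrophobicity = c(0.62, -2.53, -0.78, -0.90, 0.29, -0.85, -0.74, 0.48,
                       -0.40, 1.38, 1.06, -1.50, 0.64, 1.19, 0.12, -0.18,
                       -0.05, 0.81, 0.26, 1.08),
    hydrophilicity = c(-0.5, 3.0, 0.2, 3.0, -1.0, 0.2, 3.0, 0.0, -0.5, -1.8,
                       -1.8, 3.0, -1.3, -2.5, 0.0, 0.3, -0.4, -3.4, -2.3,
                       -1.5),
    volume = c(27.5, 105.0, 58.7, 40.0, 44.6, 80.7, 62.0, 0.0, 79.0, 93.5,
               93.5, 100.0, 94.1, 115.5, 41.9, 29.3, 51.3, 145.5, 117.3,
               71.5),
    polarity = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
                 4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    polarizability = c(0.046, 0.291, 0.134, 0.105, 0.128, 0.180, 0.151,
                       0.000, 0.230, 0.186, 0.186, 0.219, 0.221, 0.290,
                       0.131, 0.062, 0.108, 0.409, 0.298, 0.140),
    sasa = c(1.181, 2.560, 1.655, 1.587, 1.461, 1.932, 1.862, 0.881, 2.025,
             1.810, 1.931, 2.258, 2.034, 2.228, 1.468, 1.298, 1.525, 2.663,
             2.368, 1.645),
    net_charge_index = c(0.007187, 0.043587, 0.005392, -0.023820, -0.036610,
                         0.049211, 0.006802, 0.179052, -0.010690, 0.021631,
                         0.051672, 0.017708, 0.002683, 0.037552, 0.239531,
                         0.004627, 0.003352, 0.037977, 0.023599, 0.057004)
  )
  rownames(m) <- aa
  m
}

# z-standardized scales (mean 0, unit sample sd across the 20 residues)
ac_scales_standardized <- function() {
  scale(ac_property_scales())[, , drop = FALSE]
}

#' Auto-covariance (AC) sequence encoder
#'
#' Encodes a protein as lagged auto-covariances of seven physicochemical
#' property series. Each property scale is z-standardized across the 20
#' residues, mapped along the sequence, centered at the protein's own mean,
#' and for each lag `d` in `1..max_lag` the covariance
#' `AC(d, j) = (1/(L-d)) * sum_i (x[i,j] - xbar_j)(x[i+d,j] - xbar_j)`
#' is computed. With the default `max_lag = 30` this yields a
#' 7 x 30 = 210-dimensional vector per protein (420 per pair).
#'
#' @inheritParams map_to_groups
#' @param max_lag largest sequence-separation lag (default 30); the sequence
#'   must be strictly longer than `max_lag`.
#' @return named numeric vector of length `7 * max_lag`, ordered lag-within-
#'   property (`ac_<property>_lag<d>`).
#' @export
ac_features <- function(seq, max_lag = 30L) {
  gseq <- map_to_groups(seq) # validates residues; indices unused
  L <- length(gseq)
  abort_if(L <= max_lag,
           "sequence length %d is too short for max_lag %d", L, max_lag)
  scales <- ac_scales_standardized()
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  x <- scales[chars, , drop = FALSE]
  xc <- sweep(x, 2L, colMeans(x))
  out <- matrix(0, nrow = max_lag, ncol = ncol(scales))
  for (d in seq_len(max_lag)) {
    out[d, ] <- colSums(xc[seq_len(L - d), , drop = FALSE] *
                          xc[seq_len(L - d) + d, , drop = FALSE]) / (L - d)
  }
  vals <- as.numeric(out) # lag fastest within each property column
  names(vals) <- as.vector(outer(seq_len(max_lag), colnames(scales),
                                 function(d, p) sprintf("ac_%s_lag%d", p, d)))
  vals
}
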