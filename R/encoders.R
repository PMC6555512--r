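#' Encoder specification
#'
#' Describes one of the four per-protein sequence encoders and its fixed
#' dimensionalities. Per-pair vectors are concatenations of the two
#' per-protein vectors, so the per-pair dimension is always twice the
#' per-protein dimension: MOS 29/58, CT 343/686, AC 210/420, LD 630/1260.
#'
#' @param name one of `"MOS"`, `"CT"`, `"AC"`, `"LD"` (case-insensitive).
#' @return an object of class `encoder_spec`: list with `name`,
#'   `per_protein_dim` and `per_pair_dim`.
#' @export
encoder_spec <- function(name = c("MOS", "CT", "AC", "LD")) {
  name <- toupper(name)
  name <- match.arg(name)
  per_protein <- c(MOS = 29L, CT = 343L, AC = 210L, LD = 630L)[[name]]
  structure(list(name = name, per_protein_dim = per_protein,
                 per_pair_dim = 2L * per_protein),
            class = "encoder_spec")
}

#' Encode a single protein with a named encoder
#'
#' Dispatches to [encode_mos()], [ct_features()], [ac_features()] or
#' [ld_features()].
#'
#' @param seq protein sequence string.
#' @param encoder encoder name or an `encoder_spec`.
#' @return numeric feature vector of the encoder's per-protein dimension.
#' @export
encode_protein <- function(seq, encoder = "MOS") {
  spec <- as_encoder_spec(encoder)
  v <- switch(spec$name,
              MOS = encode_mos(seq),
              CT = ct_features(seq),
              AC = ac_features(seq),
              LD = ld_features(seq))
  stopifnot(length(v) == spec$per_protein_dim)
  v
}

as_encoder_spec <- function(encoder) {
  if (inherits(encoder, "encoder_spec")) encoder else encoder_spec(encoder)
}
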