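#' Seven-group reduced amino-acid alphabet
#'
#' Builds the fixed classification of the 20 standard amino acids into seven
#' groups by dipole moment and side-chain volume:
#' \{A,G,V\}=1, \{I,L,F,P\}=2, \{Y,M,T,S\}=3, \{H,N,Q,W\}=4, \{R,K\}=5,
#' \{D,E\}=6, \{C\}=7. All encoders in this package operate on sequences
#' reduced through this alphabet.
#'
#' @return an object of class `group_alphabet`: a list with
#'   `residue_to_group`, a named integer vector mapping each one-letter
#'   residue code to its group index, and `n_groups` (7).
#' @examples
#' ab <- build_group_alphabet()
#' ab$residue_to_group[c("A", "R", "C")] # 1 5 7
#' @export
build_group_alphabet <- function() {
  residue_to_group <- c(
    A = 1L, G = 1L, V = 1L,
    I = 2L, L = 2L, F = 2L, P = 2L,
    Y = 3L, M = 3L, T = 3L, S = 3L,
    H = 4L, N = 4L, Q = 4L, W = 4L,
    R = 5L, K = 5L,
    D = 6L, E = 6L,
    C = 7L
  )
  structure(list(residue_to_group = residue_to_group, n_groups = 7L),
            class = "group_alphabet")
}

#' Map a protein sequence to group indices
#'
#' Translates each residue of a protein sequence into its group index under
#' the seven-group alphabet. Input is upper-cased before lookup. Any character
#' outside the 20 standard residues (including the ambiguity/unusual codes
#' B, J, O, U, X, Z and the stop/gap symbols `*`, `-`) is an error that names
#' the character and its 1-based position.
#'
#' @param seq a single protein sequence string.
#' @param alphabet a `group_alphabet`; defaults to [build_group_alphabet()].
#' @return an integer vector of group indices in `1..7`, one per residue.
#' @examples
#' paste(map_to_groups("AGCRQTSPLGVKSE"), collapse = "") # "11754332211536"
#' @export
map_to_groups <- function(seq, alphabet = build_group_alphabet()) {
  abort_if(!is.character(seq) || length(seq) != 1L || is.na(seq),
           "`seq` must be a single character string")
  abort_if(nchar(seq) == 0L, "`seq` must be non-empty")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  g <- unname(alphabet$residue_to_group[chars])
  if (anyNA(g)) {
    bad <- which(is.na(g))[1L]
    stop(sprintf("invalid residue '%s' at position %d", chars[bad], bad),
         call. = FALSE)
  }
  g
}

#' Validate a protein sequence against dataset-inclusion rules
#'
#' A sequence is rejected if it contains any character outside the 20
#' standard residues (the unusual codes B, J, O, U, X and Z in particular) or
#' if it is shorter than `min_length` residues. Rejection is a verdict, not
#' an error; the verdict carries the first failing rule, with the residue
#' check applied before the length check.
#'
#' @param seq a single protein sequence string.
#' @param min_length minimum accepted length (default 50 residues).
#' @return a list with `accept` (logical) and `reason` (`NA` when accepted,
#'   otherwise `"unusual_residue"` or `"too_short"`).
#' @examples
#' validate_protein(strrep("A", 60))$accept       # TRUE
#' validate_protein(strrep("A", 49))$reason       # "too_short"
#' @export
validate_protein <- function(seq, min_length = 50L) {
  abort_if(!is.character(seq) || length(seq) != 1L || is.na(seq),
           "`seq` must be a single character string")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  standard <- names(build_group_alphabet()$residue_to_group)
  if (length(chars) == 0L || !all(chars %in% standard)) {
    return(list(accept = FALSE, reason = "unusual_residue"))
  }
  if (length(chars) < min_length) {
    return(list(accept = FALSE, reason = "too_short"))
  }
  list(accept = TRUE, reason = NA_character_)
}
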