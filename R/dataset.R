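#' Read a FASTA proteome
#'
#' Reads amino-acid sequences from a FASTA file. Record ids are the header
#' token up to the first whitespace; wrapped sequence lines are concatenated
#' and upper-cased. When an id occurs more than once the last record wins and
#' a warning is emitted. Sequence text appearing before any header is a parse
#' error reporting the line number.
#'
#' @param path path to a FASTA file.
#' @return named character vector, id -> sequence (empty for an empty file).
#' @export
read_fasta <- function(path) {
  abort_if(!file.exists(path), "FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) return(setNames(character(0), character(0)))
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop(sprintf("malformed FASTA %s: sequence before header at line %d",
                 path, nonblank[1L]), call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning(sprintf("duplicate FASTA id(s) %s: keeping the last occurrence",
                    paste(dup, collapse = ", ")), call. = FALSE)
    keep <- !duplicated(ids, fromLast = TRUE)
    seqs <- seqs[keep]
    ids <- ids[keep]
  }
  setNames(unname(seqs), ids)
}

#' Read a two-column interaction pair list
#'
#' Parses a whitespace- or tab-delimited file with one protein pair per line
#' (the shape of published supplementary interaction lists: first column one
#' protein id, second column the other). A first line whose two tokens are
#' both non-numeric and look like column labels (matching
#' `^(protein|id|name)` case-insensitively) is skipped as a header, with a
#' message. Lines with a token count other than two are parse errors naming
#' the line.
#'
#' @param path path to the pair list.
#' @param label class label to attach to every pair: 1 interacting,
#'   0 non-interacting.
#' @return data.frame with columns `id_a`, `id_b` (character) and `label`
#'   (integer).
#' @export
read_pairs <- function(path, label) {
  abort_if(!file.exists(path), "pair file not found: %s", path)
  abort_if(!label %in% c(0L, 1L), "`label` must be 0 or 1")
  lines <- readLines(path, warn = FALSE)
  keep <- which(trimws(lines) != "")
  tokens <- strsplit(trimws(lines[keep]), "[ \t]+")
  bad <- which(lengths(tokens) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("parse error in %s at line %d: expected 2 fields, found %d",
                 path, keep[bad[1L]], lengths(tokens)[bad[1L]]),
         call. = FALSE)
  }
  if (length(tokens) > 0L) {
    first <- tokens[[1L]]
    looks_header <- all(is.na(suppressWarnings(as.numeric(first)))) &&
      any(grepl("^(protein|id|name)", tolower(first)))
    if (looks_header) {
      message(sprintf("skipping header line in %s: '%s'", path,
                      paste(first, collapse = " ")))
      tokens <- tokens[-1L]
    }
  }
  data.frame(
    id_a = vapply(tokens, `[[`, character(1), 1L),
    id_b = vapply(tokens, `[[`, character(1), 2L),
    label = rep(as.integer(label), length(tokens)),
    stringsAsFactors = FALSE
  )
}

#' Filter interaction records by the dataset-inclusion rules
#'
#' Applies, in order, each removal counted in the exclusion report:
#' records whose ids have no sequence; self-interactions (`id_a == id_b`);
#' duplicate pairs, treating (a, b) and (b, a) as the same unordered pair
#' (first occurrence kept); pairs in which either protein contains an
#' unusual residue (B, J, O, U, X, Z or any non-standard character); pairs
#' in which either protein is shorter than `min_length`; and optionally
#' pairs whose two proteins have equal length and equal per-group residue
#' counts (such proteins share one sequence matrix, so the pair's two
#' feature blocks are identical).
#'
#' @param records data.frame of `id_a`, `id_b`, `label` rows, as returned by
#'   [read_pairs()].
#' @param sequences named character vector, id -> sequence.
#' @param min_length minimum protein length (default 50).
#' @param drop_self drop self-interactions (default TRUE).
#' @param drop_duplicates drop unordered duplicate pairs (default TRUE).
#' @param collision_filter drop equal-length, equal-composition pairs
#'   (default FALSE).
#' @return list with `records` (the retained rows) and `report`, a named
#'   integer vector of counts: `input`, `missing_sequence`,
#'   `self_interaction`, `duplicate`, `unusual_residue`, `too_short`,
#'   `composition_collision`, `output`; exclusions sum to input - output.
#' @export
filter_records <- function(records, sequences, min_length = 50L,
                           drop_self = TRUE, drop_duplicates = TRUE,
                           collision_filter = FALSE) {
  abort_if(!all(c("id_a", "id_b", "label") %in% names(records)),
           "`records` must have columns id_a, id_b, label")
  report <- c(input = nrow(records), missing_sequence = 0L,
              self_interaction = 0L, duplicate = 0L, unusual_residue = 0L,
              too_short = 0L, composition_collision = 0L, output = 0L)

  miss <- !(records$id_a %in% names(sequences)) |
    !(records$id_b %in% names(sequences))
  report["missing_sequence"] <- sum(miss)
  records <- records[!miss, , drop = FALSE]

  if (drop_self) {
    self <- records$id_a == records$id_b
    report["self_interaction"] <- sum(self)
    records <- records[!self, , drop = FALSE]
  }

  if (drop_duplicates) {
    key <- paste(pmin(records$id_a, records$id_b),
                 pmax(records$id_a, records$id_b))
    dup <- duplicated(key)
    report["duplicate"] <- sum(dup)
    records <- records[!dup, , drop = FALSE]
  }

  ids <- unique(c(records$id_a, records$id_b))
  verdicts <- lapply(sequences[ids], validate_protein, min_length = min_length)
  reason <- vapply(verdicts, `[[`, character(1), "reason")
  names(reason) <- ids
  # a pair is attributed to the first failing protein (a before b)
  pair_reason <- ifelse(!is.na(reason[records$id_a]), reason[records$id_a],
                        reason[records$id_b])
  report["unusual_residue"] <- sum(pair_reason == "unusual_residue",
                                   na.rm = TRUE)
  report["too_short"] <- sum(pair_reason == "too_short", na.rm = TRUE)
  records <- records[is.na(pair_reason), , drop = FALSE]

  if (collision_filter && nrow(records) > 0L) {
    sig <- vapply(sequences[unique(c(records$id_a, records$id_b))],
                  function(s) paste(c(nchar(s), compute_vos(map_to_groups(s))),
                                    collapse = ","),
                  character(1))
    coll <- sig[records$id_a] == sig[records$id_b]
    report["composition_collision"] <- sum(coll)
    records <- records[!coll, , drop = FALSE]
  }

  report["output"] <- nrow(records)
  rownames(records) <- NULL
  list(records = records, report = report)
}

#' Build a labeled pair-feature table
#'
#' Encodes every distinct protein once with the chosen encoder and assembles
#' one row per interaction record: the concatenation of the two per-protein
#' vectors in the record's (a, b) order, of length `per_pair_dim`. Proteins
#' that the encoder cannot handle (e.g. too short for AC's maximum lag) cause
#' their pairs to be skipped, counted in `n_skipped` with a warning.
#'
#' @inheritParams filter_records
#' @param encoder encoder name or [encoder_spec()].
#' @return an object of class `pair_feature_table`: list with the numeric
#'   feature matrix `x` (rows named "id_a:id_b"), integer `labels`,
#'   data.frame `pairs`, the `encoder` spec, and counts `n_pos`, `n_neg`,
#'   `n_skipped`.
#' @export
build_pair_table <- function(records, sequences, encoder = "MOS") {
  spec <- as_encoder_spec(encoder)
  ids <- unique(c(records$id_a, records$id_b))
  feats <- vector("list", length(ids))
  names(feats) <- ids
  ok <- logical(length(ids))
  for (i in seq_along(ids)) {
    f <- tryCatch(encode_protein(sequences[[ids[i]]], spec),
                  error = function(e) NULL)
    if (!is.null(f)) {
      feats[[i]] <- f
      ok[i] <- TRUE
    }
  }
  names(ok) <- ids
  usable <- ok[records$id_a] & ok[records$id_b]
  if (any(!usable)) {
    warning(sprintf("%d pair(s) skipped: protein(s) not encodable with %s",
                    sum(!usable), spec$name), call. = FALSE)
  }
  kept <- records[usable, , drop = FALSE]
  x <- matrix(0, nrow(kept), spec$per_pair_dim)
  if (nrow(kept) > 0L) {
    xa <- do.call(rbind, feats[kept$id_a])
    xb <- do.call(rbind, feats[kept$id_b])
    x <- cbind(xa, xb)
    colnames(x) <- c(paste0("a_", colnames(xa)), paste0("b_", colnames(xb)))
  }
  rownames(x) <- paste(kept$id_a, kept$id_b, sep = ":")
  structure(list(x = x, labels = as.integer(kept$label), pairs = kept,
                 encoder = spec,
                 n_pos = sum(kept$label == 1L), n_neg = sum(kept$label == 0L),
                 n_skipped = sum(!usable)),
            class = "pair_feature_table")
}

#' @export
print.pair_feature_table <- function(x, ...) {
  cat(sprintf("pair_feature_table: %d pairs (%d pos, %d neg), encoder %s, dim %d\n",
              nrow(x$x), x$n_pos, x$n_neg, x$encoder$name,
              x$encoder$per_pair_dim))
  invisible(x)
}

# Row subset of a pair_feature_table.
subset_pair_table <- function(table, idx) {
  structure(list(x = table$x[idx, , drop = FALSE],
                 labels = table$labels[idx],
                 pairs = table$pairs[idx, , drop = FALSE],
                 encoder = table$encoder,
                 n_pos = sum(table$labels[idx] == 1L),
                 n_neg = sum(table$labels[idx] == 0L),
                 n_skipped = 0L),
            class = "pair_feature_table")
}

#' Stratified train / hold-out split
#'
#' Randomly draws exactly `n_train_pos` positive and `n_train_neg` negative
#' rows into a training table; all remaining rows form the hold-out table.
#' The split is deterministic given `seed` and leaves the two tables
#' disjoint and jointly exhaustive.
#'
#' @param table a `pair_feature_table`.
#' @param n_train_pos,n_train_neg class counts for the training table.
#' @param seed integer seed for the draw.
#' @return list with `train` and `holdout` pair_feature_tables.
#' @export
split_train_holdout <- function(table, n_train_pos, n_train_neg, seed) {
  abort_if(table$n_pos < n_train_pos,
           "requested %d positive training pairs but only %d available",
           n_train_pos, table$n_pos)
  abort_if(table$n_neg < n_train_neg,
           "requested %d negative training pairs but only %d available",
           n_train_neg, table$n_neg)
  idx <- with_local_seed(seed, {
    pos <- sample(which(table$labels == 1L), n_train_pos)
    neg <- sample(which(table$labels == 0L), n_train_neg)
    sort(c(pos, neg))
  })
  list(train = subset_pair_table(table, idx),
       holdout = subset_pair_table(table, setdiff(seq_along(table$labels),
                                                  idx)))
}

#' Write a pair-feature table as delimited text
#'
#' @param table a `pair_feature_table`.
#' @param path output path; tab-separated with a header row (pair, label,
#'   then one column per feature).
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(pair = rownames(table$x), label = table$labels,
                   table$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
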