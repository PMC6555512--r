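#' Configuration for the synthetic PPI benchmark generator
#'
#' The generator emulates the shape of a curated PPI benchmark: a proteome
#' of random amino-acid sequences (length at least 50, the 20-letter
#' alphabet, so every protein passes the dataset-inclusion filters) and
#' labeled interacting / non-interacting pairs carrying a planted signal at
#' the level of the seven-group residue composition. Proteins belong to
#' latent composition archetypes; `effect` in \code{[0, 1]} sets how far the
#' archetype composition centers are pulled apart from the shared baseline.
#' Interacting pairs join proteins of the same archetype, non-interacting
#' pairs proteins of different archetypes, so at `effect = 0` the archetype
#' centers coincide and the labels carry no recoverable signal.
#'
#' @param n_proteins number of proteins in the proteome.
#' @param length_range integer (min, max) sequence length; min must be >= 50.
#' @param n_pos,n_neg number of interacting / non-interacting pairs.
#' @param effect class-separation strength in \code{[0, 1]}.
#' @param n_archetypes number of latent composition archetypes (default 4).
#' @param concentration Dirichlet concentration of per-protein residue
#'   frequencies around their mixture target (default 100; larger = tighter).
#' @param seed master integer seed; every random stream derives from it.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 600L, length_range = c(50L, 200L),
                             n_pos = 1000L, n_neg = 1000L, effect = 0.8,
                             n_archetypes = 4L, concentration = 100,
                             seed = 1L) {
  abort_if(length_range[1L] < 50L, "minimum length must be >= 50")
  abort_if(effect < 0 || effect > 1, "`effect` must be in [0, 1]")
  abort_if(n_proteins < 2L * n_archetypes,
           "need at least two proteins per archetype")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 effect = effect, n_archetypes = as.integer(n_archetypes),
                 concentration = concentration, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Dirichlet draws via gamma normalization.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` sequences over the 20 standard residues. A baseline
#' residue frequency vector is drawn once; each archetype's residue target
#' shifts the baseline toward a distinct random seven-group composition
#' center, with `effect` interpolating between baseline (0) and the full
#' archetype center (1). Each protein samples its own residue frequencies
#' from a Dirichlet centered on its archetype target
#' (`concentration` controls tightness), then draws i.i.d. residues.
#' Reproducible: the same config yields byte-identical output.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_proteome`: list with `sequences`
#'   (named character vector), `archetype` (named integer vector) and the
#'   `config`.
#' @export
generate_proteome <- function(config) {
  abort_if(!inherits(config, "synthetic_config"),
           "`config` must be a synthetic_config")
  alphabet <- build_group_alphabet()
  residues <- names(alphabet$residue_to_group)
  groups <- unname(alphabet$residue_to_group)
  with_local_seed(sub_seed(config$seed, 1L), {
    baseline <- rdirichlet1(rep(10, 20))
    # archetype centers: distinct compositions over the 7 groups, spread
    # uniformly over that group's residues
    centers <- t(vapply(seq_len(config$n_archetypes), function(k) {
      gfreq <- rdirichlet1(rep(1.0, alphabet$n_groups))
      target <- gfreq[groups] / tabulate(groups, alphabet$n_groups)[groups]
      (1 - config$effect) * baseline + config$effect * target
    }, numeric(20)))
    archetype <- sample(rep_len(seq_len(config$n_archetypes),
                                config$n_proteins))
    lens <- sample(seq(config$length_range[1L], config$length_range[2L]),
                   config$n_proteins, replace = TRUE)
    seqs <- vapply(seq_len(config$n_proteins), function(i) {
      p <- rdirichlet1(centers[archetype[i], ] * config$concentration)
      paste(sample(residues, lens[i], replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
    ids <- sprintf("SYN%05d", seq_len(config$n_proteins))
    structure(list(sequences = setNames(seqs, ids),
                   archetype = setNames(archetype, ids),
                   config = config),
              class = "synthetic_proteome")
  })
}

#' Generate labeled interaction pairs from a synthetic proteome
#'
#' Samples exactly `n_pos` interacting pairs (both proteins from the same
#' archetype) and `n_neg` non-interacting pairs (different archetypes),
#' with no self-pairs and no duplicates (unordered). Deterministic given the
#' config's seed.
#'
#' @param proteome a `synthetic_proteome`.
#' @param config a [synthetic_config()]; defaults to the proteome's own.
#' @return data.frame with columns `id_a`, `id_b`, `label`.
#' @export
generate_interactions <- function(proteome, config = proteome$config) {
  abort_if(!inherits(proteome, "synthetic_proteome"),
           "`proteome` must come from generate_proteome()")
  ids <- names(proteome$sequences)
  arch <- proteome$archetype
  per_arch <- split(ids, arch)
  abort_if(any(lengths(per_arch) < 2L) && config$n_pos > 0L,
           "an archetype has fewer than 2 proteins; cannot form positives")
  with_local_seed(sub_seed(config$seed, 2L), {
    draw_pairs <- function(n, same) {
      seen <- character(0)
      out_a <- character(n)
      out_b <- character(n)
      got <- 0L
      attempts <- 0L
      max_attempts <- 200L * n + 1000L
      while (got < n) {
        attempts <- attempts + 1L
        abort_if(attempts > max_attempts,
                 "proteome too small for %d requested %s pairs", n,
                 if (same) "positive" else "negative")
        if (same) {
          k <- sample.int(length(per_arch), 1L)
          if (length(per_arch[[k]]) < 2L) next
          ab <- sample(per_arch[[k]], 2L)
        } else {
          ab <- sample(ids, 2L)
          if (arch[ab[1L]] == arch[ab[2L]]) next
        }
        key <- paste(min(ab), max(ab))
        if (key %in% seen) next
        seen <- c(seen, key)
        got <- got + 1L
        out_a[got] <- ab[1L]
        out_b[got] <- ab[2L]
      }
      data.frame(id_a = out_a, id_b = out_b, stringsAsFactors = FALSE)
    }
    pos <- draw_pairs(config$n_pos, same = TRUE)
    neg <- draw_pairs(config$n_neg, same = FALSE)
    pos$label <- 1L
    neg$label <- 0L
    rbind(pos, neg)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: proteome plus labeled pairs, optionally written to
#' disk as a FASTA file, two pair-list files (positive / negative) and a
#' JSON manifest recording the configuration.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional directory; when given, writes
#'   `proteome.fasta`, `positive_pairs.txt`, `negative_pairs.txt` and
#'   `manifest.json` there.
#' @return list with `sequences`, `records` (data.frame) and `proteome`.
#' @export
generate_ppi_dataset <- function(config, out_dir = NULL) {
  proteome <- generate_proteome(config)
  records <- generate_interactions(proteome, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(out_dir, "proteome.fasta")
    writeLines(paste0(">", names(proteome$sequences), "\n",
                      proteome$sequences), fa)
    utils::write.table(records[records$label == 1L, c("id_a", "id_b")],
                       file.path(out_dir, "positive_pairs.txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(records[records$label == 0L, c("id_a", "id_b")],
                       file.path(out_dir, "negative_pairs.txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(sequences = proteome$sequences, records = records,
       proteome = proteome)
}
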