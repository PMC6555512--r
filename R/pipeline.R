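#' Run the full prediction pipeline from a config file
#'
#' Executes simulate (or load) -> encode -> filter -> split -> train ->
#' evaluate from a single YAML configuration and writes a manifest. The
#' config has either a `synthetic:` block (fields of [synthetic_config()])
#' or a `data:` block with `fasta`, `positive_pairs`, `negative_pairs`
#' paths; plus optional `encoder` (default MOS), `model:` overrides for
#' [model_config()], `classifier` (default "mlp"), `split:` with
#' `n_train_pos` / `n_train_neg` (default 75% of each class) and `seed`.
#'
#' Every stage failure is reported with the stage name. The manifest records
#' the config, seeds, input digests, per-stage row counts, the exclusion
#' report and output paths; feature tables are byte-deterministic given the
#' config and seed.
#'
#' @param config path to a YAML file or an equivalent named list.
#' @param out_dir output directory (created); manifest, feature table and
#'   metrics are written there.
#' @param quiet suppress per-stage messages.
#' @return (invisibly) list with `manifest`, `metrics` (an `eval_metrics`),
#'   `model`, and the train/holdout tables.
#' @export
run_pipeline <- function(config, out_dir = tempfile("mosppi_run_"),
                         quiet = FALSE) {
  cfg <- if (is.character(config)) {
    abort_if(!file.exists(config), "[config] file not found: %s", config)
    yaml::read_yaml(config)
  } else {
    config
  }
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  encoder <- if (is.null(cfg$encoder)) "MOS" else cfg$encoder
  manifest <- list(seed = seed, encoder = toupper(encoder),
                   out_dir = out_dir)

  if (!is.null(cfg$synthetic)) {
    ds <- stage("simulate", {
      sc <- do.call(synthetic_config,
                    utils::modifyList(cfg$synthetic, list(seed = seed)))
      generate_ppi_dataset(sc, out_dir = file.path(out_dir, "data"))
    })
    sequences <- ds$sequences
    records <- ds$records
    manifest$synthetic <- cfg$synthetic
    say("simulate: %d proteins, %d pairs", length(sequences), nrow(records))
  } else {
    abort_if(is.null(cfg$data), "[config] needs a `synthetic` or `data` block")
    sequences <- stage("read_fasta", read_fasta(cfg$data$fasta))
    records <- stage("read_pairs", rbind(
      read_pairs(cfg$data$positive_pairs, 1L),
      read_pairs(cfg$data$negative_pairs, 0L)))
    manifest$inputs <- lapply(
      cfg$data[c("fasta", "positive_pairs", "negative_pairs")],
      function(p) list(path = p, md5 = unname(tools::md5sum(p))))
    say("load: %d proteins, %d pairs", length(sequences), nrow(records))
  }

  filt <- stage("filter", {
    args <- c(list(records = records, sequences = sequences),
              cfg$filter %||% list())
    do.call(filter_records, args)
  })
  manifest$exclusion_report <- as.list(filt$report)
  say("filter: %d -> %d pairs", filt$report[["input"]],
      filt$report[["output"]])

  table <- stage("encode", build_pair_table(filt$records, sequences, encoder))
  feature_path <- file.path(out_dir, "features.tsv")
  write_feature_table(table, feature_path)
  manifest$features <- list(path = feature_path,
                            md5 = unname(tools::md5sum(feature_path)),
                            n_rows = nrow(table$x),
                            dim = table$encoder$per_pair_dim)
  say("encode: %d rows x %d features (%s)", nrow(table$x),
      table$encoder$per_pair_dim, table$encoder$name)

  sp <- stage("split", {
    ntp <- cfg$split$n_train_pos %||% floor(0.75 * table$n_pos)
    ntn <- cfg$split$n_train_neg %||% floor(0.75 * table$n_neg)
    split_train_holdout(table, ntp, ntn, seed = sub_seed(seed, 3L))
  })
  manifest$split <- list(train = nrow(sp$train$x),
                         holdout = nrow(sp$holdout$x))

  classifier <- cfg$classifier %||% "mlp"
  model <- stage("train", {
    if (identical(classifier, "mlp")) {
      mc <- do.call(model_config,
                    utils::modifyList(cfg$model %||% list(),
                                      list(seed = sub_seed(seed, 4L))))
      train_mlp(sp$train, mc)
    } else {
      classic_classifier(sp$train, algorithm = classifier,
                         seed = sub_seed(seed, 4L))
    }
  })
  metrics <- stage("evaluate",
                   evaluate(sp$holdout$labels, predict(model, sp$holdout)))
  manifest$metrics <- metrics[c("accuracy", "recall", "auc", "loss")]
  say("evaluate: accuracy %.4f recall %.4f auc %.4f loss %.4f",
      metrics$accuracy, metrics$recall, metrics$auc, metrics$loss)

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(manifest$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, metrics = metrics, model = model,
                 train = sp$train, holdout = sp$holdout))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
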