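#' @title End-to-end pipeline
#' @name pipeline
#' @description One reproducible run from a single configuration:
#'   corpus (loaded or synthesized) -> 1/N database subset -> train/val/
#'   test split -> shuffle-augmented encoding -> CNN training ->
#'   evaluation, with manifests, images, a metrics report and structured
#'   logging in a deterministic directory layout.
NULL

#' Pipeline run configuration
#'
#' @param corpus either a directory of xyz files (with `labels.csv`) or a
#'   [synthesis_config()] to generate one.
#' @param out_dir output directory for the run.
#' @param denominator N of the 1/N database subset (1 = whole corpus).
#' @param split train/val/test fractions summing to 1.
#' @param encoding an [encoding_config()].
#' @param shuffle a [shuffle_spec()].
#' @param k images per training molecule.
#' @param train a [train_config()].
#' @param model_architecture `"s2cnn"` or `"s1cnn"`.
#' @param seed master seed; every stage's randomness derives from it.
#' @param test_shuffle how held-out molecules are encoded: the default
#'   `"none"` gives one deterministic image per molecule (k = 1).
#' @return list of class `run_config`.
#' @export
run_config <- function(corpus = synthesis_config(), out_dir = tempfile("rgbchem_run_"),
                       denominator = 1L, split = c(0.8, 0.1, 0.1),
                       encoding = encoding_config(), shuffle = shuffle_spec("groups"),
                       k = 1L, train = train_config(),
                       model_architecture = "s2cnn", seed = 1L,
                       test_shuffle = "none") {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (length(split) != 3L) stop("split must give train/val/test fractions")
  structure(list(corpus = corpus, out_dir = out_dir,
                 denominator = as.integer(denominator), split = split,
                 encoding = encoding, shuffle = shuffle, k = as.integer(k),
                 train = train, model_architecture = model_architecture,
                 seed = as.integer(seed), test_shuffle = test_shuffle),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror [run_config()] arguments; nested sections `encoding`,
#' `shuffle`, `train` and `corpus` (a synthesis spec) mirror the
#' respective constructors.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("out_dir", "denominator", "k", "seed", "model_architecture",
               "test_shuffle", "split")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$split)) args$split <- as.numeric(y$split)
  if (!is.null(y$encoding)) args$encoding <- do.call(encoding_config, y$encoding)
  if (!is.null(y$shuffle)) args$shuffle <- do.call(shuffle_spec, y$shuffle)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$corpus)) {
    args$corpus <- if (is.character(y$corpus)) y$corpus else do.call(synthesis_config, y$corpus)
  }
  do.call(run_config, args)
}

load_corpus_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.xyz$", full.names = TRUE))
  if (length(files) == 0L) stop("no .xyz files in corpus directory: ", dir)
  mols <- lapply(files, read_xyz)
  label_path <- file.path(dir, "labels.csv")
  if (file.exists(label_path)) {
    labels <- read_labels_csv(label_path)
    mols <- lapply(mols, function(m) {
      if (!is.null(labels[m$id]) && !is.na(labels[m$id])) m$label <- unname(labels[m$id])
      m
    })
  }
  mols
}

stage_log <- function(log_path, stage, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(sprintf(...), collapse = " "))
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Execute one pipeline run
#'
#' Stages, each seeded from the master seed: synthesize/load corpus;
#' draw the 1/N subset; split molecules into train/val/test; encode with
#' shuffle augmentation (k images per training molecule; held-out
#' molecules get one deterministic image each by default); train the
#' requested SnCNN; evaluate. Writes `manifest_{train,val,test}.csv`,
#' `images/`, `report.json` and `run.log` under the output directory.
#'
#' @param cfg a [run_config()].
#' @param verbose print training progress.
#' @return the run report (invisibly also written as JSON): counts,
#'   epochs, train/val/test MAE in eV, config fingerprint.
#' @export
rgbchem_run <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  cat("", file = log_path)
  fp <- config_fingerprint(cfg)

  set.seed(cfg$seed)
  mols <- if (is.character(cfg$corpus)) load_corpus_dir(cfg$corpus)
          else generate_corpus(cfg$corpus)
  stage_log(log_path, "corpus", "n=%d seed=%d", length(mols), cfg$seed)

  set.seed(cfg$seed + 1L)
  pool <- subset_database(mols, cfg$denominator)
  stage_log(log_path, "subset", "denominator=%d n=%d", cfg$denominator, length(pool))

  set.seed(cfg$seed + 2L)
  n <- length(pool)
  idx <- sample.int(n)
  n_train <- floor(cfg$split[1] * n)
  n_val <- floor(cfg$split[2] * n)
  if (n_train < 1L || n_val < 1L || n_train + n_val >= n) {
    stop("split leaves an empty partition; enlarge the corpus")
  }
  parts <- list(train = pool[idx[seq_len(n_train)]],
                val = pool[idx[n_train + seq_len(n_val)]],
                test = pool[idx[(n_train + n_val + 1L):n]])
  stage_log(log_path, "split", "train=%d val=%d test=%d",
            n_train, n_val, n - n_train - n_val)

  img_dir <- file.path(cfg$out_dir, "images")
  set.seed(cfg$seed + 3L)
  train_set <- generate_dataset(parts$train, file.path(img_dir, "train"),
                                cfg$encoding, cfg$shuffle, cfg$k)
  eval_spec <- shuffle_spec(cfg$test_shuffle)
  set.seed(cfg$seed + 4L)
  val_set <- generate_dataset(parts$val, file.path(img_dir, "val"),
                              cfg$encoding, eval_spec, 1L)
  set.seed(cfg$seed + 5L)
  test_set <- generate_dataset(parts$test, file.path(img_dir, "test"),
                               cfg$encoding, eval_spec, 1L)
  for (nm in c("train", "val", "test")) {
    write_manifest(get(paste0(nm, "_set"))$manifest,
                   file.path(cfg$out_dir, sprintf("manifest_%s.csv", nm)))
  }
  stage_log(log_path, "encode", "k=%d train_images=%d fingerprint=%s",
            cfg$k, nrow(train_set$manifest), fp)
  stopifnot(nrow(train_set$manifest) == length(parts$train) * cfg$k)

  set.seed(cfg$seed + 6L)
  model <- sncnn(cfg$model_architecture, input_size = cfg$encoding$canvas_size)
  fit <- train_from_manifest(model, train_set$manifest, val_set$manifest,
                             cfg$train, verbose = verbose)
  stage_log(log_path, "train", "epochs=%d best=%d", fit$stopped_epoch, fit$best_epoch)

  report <- list(
    fingerprint = fp,
    seed = cfg$seed,
    n_molecules = length(mols),
    n_pool = length(pool),
    n_train_molecules = length(parts$train),
    images_per_molecule = cfg$k,
    n_train_images = nrow(train_set$manifest),
    epochs_run = fit$stopped_epoch,
    best_epoch = fit$best_epoch,
    train_mae = evaluate_mae(fit, train_set$manifest),
    val_mae = evaluate_mae(fit, val_set$manifest),
    test_mae = evaluate_mae(fit, test_set$manifest))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  stage_log(log_path, "report", "val_mae=%.4f test_mae=%.4f",
            report$val_mae, report$test_mae)
  invisible(report)
}

#' Summarize completed runs into a comparison table
#'
#' @param run_dirs character vector of run output directories.
#' @return data.frame, one row per run with a readable report, sorted by
#'   validation MAE; malformed directories are skipped with a warning.
#' @export
summarize_runs <- function(run_dirs) {
  rows <- list()
  for (d in run_dirs) {
    path <- file.path(d, "report.json")
    if (!file.exists(path)) {
      warning("no report.json in ", d, "; skipped")
      next
    }
    rep <- jsonlite::read_json(path, simplifyVector = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(run_dir = d, as.data.frame(rep))
  }
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  out[order(out$val_mae), , drop = FALSE]
}
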