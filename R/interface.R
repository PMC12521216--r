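#' Experiment configuration
#'
#' One experiment = one config = one output directory. The configuration
#' nests the simulation settings, the paradigm thresholds and the
#' classifier choice, and serialises to YAML; every random stream in a run
#' is derived from the single root `seed`.
#'
#' @param data_source `"simulated"` or a directory of `.mat` session files.
#' @param simulation a [simulation_config()].
#' @param selection a [selection_config()].
#' @param classifier_kind `"batch_discriminant"` or `"incremental_convnet"`.
#' @param paradigm `"NONE"`, `"QA"`, `"ENN"` or `"CR"`.
#' @param mode `"none"`, `"retrain"`, `"reject"` or `"both"`.
#' @param seed root seed.
#' @param output_dir output directory.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(data_source = "simulated",
                              simulation = simulation_config(),
                              selection = selection_config(),
                              classifier_kind = "batch_discriminant",
                              paradigm = "NONE", mode = "none",
                              seed = 0L, output_dir = "results") {
  structure(list(
    data_source = data_source, simulation = simulation,
    selection = selection, classifier_kind = classifier_kind,
    paradigm = paradigm, mode = mode, seed = as.integer(seed),
    output_dir = output_dir
  ), class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' Round-trip stable: `read_experiment_config(write_experiment_config(cfg))`
#' reproduces `cfg`.
#'
#' @param cfg an [experiment_config()].
#' @param path YAML file path.
#' @export
write_experiment_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  lst <- unclass(cfg)
  lst$simulation <- unclass(lst$simulation)
  lst$simulation$class_pattern_gain <-
    as.list(as.data.frame(t(lst$simulation$class_pattern_gain)))
  names(lst$simulation$class_pattern_gain) <- paste0("class", 1:7)
  lst$selection <- unclass(lst$selection)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  lst <- yaml::read_yaml(path)
  pat <- do.call(rbind, lapply(lst$simulation$class_pattern_gain, as.numeric))
  dimnames(pat) <- NULL
  sim <- lst$simulation
  sim$class_pattern_gain <- pat
  sim <- do.call(simulation_config, sim)
  sel <- do.call(selection_config, lst$selection)
  experiment_config(
    data_source = lst$data_source, simulation = sim, selection = sel,
    classifier_kind = lst$classifier_kind, paradigm = lst$paradigm,
    mode = lst$mode, seed = lst$seed, output_dir = lst$output_dir)
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over the package functions, used by the
#' `inst/exec/semgretrain` script. Subcommands:
#'
#' * `simulate --out DIR [--sessions N] [--seed S] ...` — generate a
#'   synthetic multi-session dataset and write portable containers.
#' * `preprocess --in DIR --out DIR [--seed S]` — window, label, split and
#'   balance every session container found in `--in`.
#' * `augment --in DIR --out DIR [--seed S]` — pink-noise-degrade every
#'   session container.
#' * `run --out DIR [--paradigm P] [--classifier K] [--mode M] [--seed S]
#'   ...` — simulate (or load) sessions and run the full protocol, writing
#'   a results table, the resolved config and a progress log.
#' * `report --in DIR` — summarise a results directory.
#'
#' @param argv character vector of arguments (as from
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code (0 on success), invisibly.
#' @export
cli_run <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) == 0L) { cat(cli_usage()); return(invisible(2L)) }
    cmd <- argv[1L]
    opts <- parse_cli_opts(argv[-1L])
    switch(cmd,
      simulate = cli_simulate(opts),
      preprocess = cli_preprocess(opts),
      augment = cli_augment(opts),
      run = cli_run_protocol(opts),
      report = cli_report(opts),
      { cat(cli_usage()); stopf("unknown subcommand '%s'", cmd) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

cli_usage <- function() {
  paste0(
    "usage: semgretrain <simulate|preprocess|augment|run|report> [options]\n",
    "  common options: --seed S --out DIR --in DIR\n",
    "  simulate: --sessions N --reps N --fs HZ --channels N --drift X\n",
    "  run: --paradigm NONE|QA|ENN|CR --classifier batch|convnet\n",
    "       --mode none|retrain|reject|both --sessions N --majority-vote\n")
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE   # bare flag
      i <- i + 1L
    }
  }
  opts
}

opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}
opt_chr <- function(opts, key, default = NULL) {
  v <- opts[[key]]
  if (is.null(v)) default else as.character(v)
}
need_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

cli_sim_config <- function(opts) {
  simulation_config(
    n_sessions = opt_num(opts, "sessions", 10L),
    n_reps = opt_num(opts, "reps", 12L),
    fs = opt_num(opts, "fs", 2000),
    n_channels = opt_num(opts, "channels", 14L),
    activation_s = opt_num(opts, "activation", 4),
    rest_s = opt_num(opts, "rest", 4),
    drift_scale = opt_num(opts, "drift", 0.4),
    seed = opt_num(opts, "seed", 0L))
}

cli_simulate <- function(opts) {
  out <- need_dir(opt_chr(opts, "out") %||% stopf("simulate needs --out DIR"))
  cfg <- cli_sim_config(opts)
  sessions <- simulate_multisession(cfg)
  for (s in seq_along(sessions))
    write_session(sessions[[s]], file.path(out, sprintf("session%02d", s)))
  message(sprintf("wrote %d session container(s) to %s", length(sessions), out))
}

cli_load_sessions <- function(dir) {
  if (!dir.exists(dir)) stopf("input directory not found: %s", dir)
  prefixes <- sort(sub("\\.yaml$", "",
                       list.files(dir, pattern = "^session[0-9]+\\.yaml$",
                                  full.names = TRUE)))
  if (length(prefixes) == 0L) stopf("no session containers found in %s", dir)
  lapply(prefixes, read_session)
}

cli_preprocess <- function(opts) {
  ind <- opt_chr(opts, "in") %||% stopf("preprocess needs --in DIR")
  out <- need_dir(opt_chr(opts, "out") %||% stopf("preprocess needs --out DIR"))
  seed <- opt_num(opts, "seed", 0L)
  sessions <- cli_load_sessions(ind)
  for (s in seq_along(sessions)) {
    prep <- prepare_session(sessions[[s]], seed = fan_seed(seed, 10L + s))
    write_features(prep$train, file.path(out, sprintf("session%02d_train.tsv", s)))
    write_features(prep$test, file.path(out, sprintf("session%02d_test.tsv", s)))
    message(sprintf("session %d: %d train / %d test windows", s,
                    prep$train$n_windows, prep$test$n_windows))
  }
}

cli_augment <- function(opts) {
  ind <- opt_chr(opts, "in") %||% stopf("augment needs --in DIR")
  out <- need_dir(opt_chr(opts, "out") %||% stopf("augment needs --out DIR"))
  seed <- opt_num(opts, "seed", 0L)
  sessions <- cli_load_sessions(ind)
  for (s in seq_along(sessions)) {
    aug <- augment_session(sessions[[s]], seed = fan_seed(seed, s))
    write_session(aug, file.path(out, sprintf("session%02d", s)))
    message(sprintf("session %d: noise scale k = %d, average SNR %.2f dB",
                    s, attr(aug, "noise_scale"), attr(aug, "average_snr_db")))
  }
}

cli_run_protocol <- function(opts) {
  out <- need_dir(opt_chr(opts, "out") %||% stopf("run needs --out DIR"))
  seed <- opt_num(opts, "seed", 0L)
  paradigm <- toupper(opt_chr(opts, "paradigm", "NONE"))
  kind <- switch(opt_chr(opts, "classifier", "batch"),
                 batch = "batch_discriminant", convnet = "incremental_convnet",
                 stopf("--classifier must be 'batch' or 'convnet'"))
  mode <- opt_chr(opts, "mode", "none")
  sessions <- if (!is.null(opts[["in"]])) cli_load_sessions(opts[["in"]])
              else simulate_multisession(cli_sim_config(opts))
  ec <- experiment_config(
    data_source = opt_chr(opts, "in", "simulated"),
    simulation = cli_sim_config(opts), classifier_kind = kind,
    paradigm = paradigm, mode = mode, seed = seed, output_dir = out)
  write_experiment_config(ec, file.path(out, "config.yaml"))
  logf <- file.path(out, "run.log")
  res <- run_protocol(sessions, paradigm = paradigm, classifier_kind = kind,
                      mode = mode, seed = seed,
                      apply_majority_vote = isTRUE(opts[["majority-vote"]]))
  lines <- character(0)
  for (r in res) {
    ln <- sprintf(
      "session %d: accuracy %.2f%%, macro F1 %.3f, rejection %s%%, retention [%s]",
      r$session_id, r$accuracy_pct, r$macro_f1,
      ifelse(is.na(r$rejection_pct), "-", sprintf("%.1f", r$rejection_pct)),
      paste(ifelse(is.na(r$retention_pct), "-",
                   sprintf("%.0f", r$retention_pct)), collapse = " "))
    message(ln)
    lines <- c(lines, ln)
  }
  writeLines(lines, logf)
  write_results(res, file.path(out, "results.tsv"),
                meta = list(paradigm = paradigm, classifier = kind, mode = mode,
                            seed = seed))
  message(sprintf("results written to %s", file.path(out, "results.tsv")))
}

cli_report <- function(opts) {
  ind <- opt_chr(opts, "in") %||% stopf("report needs --in DIR")
  files <- list.files(ind, pattern = "^results.*\\.tsv$", full.names = TRUE,
                      recursive = TRUE)
  if (length(files) == 0L)
    stopf("no results tables (results*.tsv) found under %s", ind)
  tab <- data.table::rbindlist(lapply(files, data.table::fread), fill = TRUE)
  agg <- tab[, list(mean_accuracy_pct = mean(accuracy_pct, na.rm = TRUE)),
             by = c(intersect(c("paradigm", "classifier", "mode", "session"),
                              names(tab)))]
  print(as.data.frame(agg))
}
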