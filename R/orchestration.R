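#' Run configuration for the full optimization loop
#'
#' Defaults mirror the reference study conditions: population 10,
#' 10 iterations, 5 training epochs per fitness evaluation, 85/15
#' train/test split, SNR cleaning threshold 1.15, 128 x 128 x 3 input.
#'
#' @param dataset_dir Class-per-folder PNG tree to load, or `NULL` to
#'   generate data from `synthetic`.
#' @param synthetic A [synthetic_spec()] used when `dataset_dir` is `NULL`.
#' @param backbone Backbone name (see [backbone_spec()]); default
#'   `"toy_cnn"`.
#' @param population Population size; default 10.
#' @param iterations GTO iterations; default 10.
#' @param epochs Training epochs per fitness evaluation; default 5.
#' @param test_fraction Held-out test share; default 0.15.
#' @param validation_fraction Validation share of the training part;
#'   default 0.10.
#' @param snr_threshold SNR cleaning threshold; default 1.15. Set to
#'   `NULL`/`NA` to skip cleaning.
#' @param eval_on `"all"` or `"test"`, passed to [train_config()].
#' @param seed Master seed for the run.
#' @param out_dir Output directory for reports, history, checkpoint and
#'   log; `NULL` disables file output.
#' @param resume Resume from `out_dir/checkpoint.json` if present.
#' @return A `run_config` list.
#' @export
run_config <- function(dataset_dir = NULL, synthetic = synthetic_spec(),
                       backbone = "toy_cnn", population = 10L,
                       iterations = 10L, epochs = 5L, test_fraction = 0.15,
                       validation_fraction = 0.10, snr_threshold = 1.15,
                       eval_on = c("all", "test"), seed = 1L,
                       out_dir = NULL, resume = FALSE) {
  structure(list(dataset_dir = dataset_dir, synthetic = synthetic,
                 backbone = backbone, population = as.integer(population),
                 iterations = as.integer(iterations),
                 epochs = as.integer(epochs),
                 test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 snr_threshold = snr_threshold,
                 eval_on = match.arg(eval_on), seed = as.integer(seed),
                 out_dir = out_dir, resume = isTRUE(resume)),
            class = "run_config")
}

run_log <- function(path, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                 sprintf(fmt, ...))
  message(msg)
  if (!is.null(path)) cat(msg, "\n", file = path, append = TRUE, sep = "")
}

checkpoint_write <- function(path, t, pop, best_per_iter) {
  st <- gto_capture_state(t, pop, best_per_iter)
  obj <- list(t = st$t,
              X = st$pop$X, GX = st$pop$GX, fitness = st$pop$fitness,
              silverback = st$pop$silverback, history = st$pop$history,
              n_skipped = st$pop$n_skipped,
              best_per_iter = st$best_per_iter,
              random_seed = st$random_seed)
  # 17 significant digits round-trip IEEE doubles exactly, so a resumed
  # run continues bit-identically
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
}

checkpoint_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pop <- structure(list(X = as.matrix(obj$X), GX = as.matrix(obj$GX),
                        fitness = as.numeric(obj$fitness),
                        silverback = as.integer(obj$silverback),
                        history = as.numeric(obj$history),
                        n_skipped = as.integer(obj$n_skipped)),
                   class = "gto_population")
  list(t = as.integer(obj$t), pop = pop,
       best_per_iter = as.numeric(obj$best_per_iter),
       random_seed = as.integer(obj$random_seed))
}

#' Run the full hyperparameter-optimization pipeline
#'
#' Executes acquisition (load a PNG tree or generate synthetic data),
#' preprocessing (optional SNR cleaning, stratified splitting), then the
#' GTO loop over the 16-dimensional unit hypercube with the training-based
#' fitness, and finally decodes and reports the best configuration.
#'
#' When `out_dir` is set, the run writes `best_config.json` (decoded best
#' configuration plus raw solution), `metrics.json`/`metrics.csv` (full
#' metric report of the best solution), `history.csv` (per-iteration best
#' fitness), `cleaning_manifest.csv` (when cleaning ran), `run.log`, a
#' JSON-lines `evaluations.jsonl` ledger, and after each completed
#' iteration a `checkpoint.json` from which an interrupted run resumes
#' (`resume = TRUE`).
#'
#' @param config A [run_config()].
#' @return List with `best` (the best `fitness_result`), `best_solution`,
#'   `history` (data frame, `iterations` rows, non-increasing best
#'   fitness), `removed` (cleaning count) and `bundle` (the preprocessed
#'   data).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_path <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(config$out_dir, "run.log")
  }

  # --- acquisition ---------------------------------------------------
  if (!is.null(config$dataset_dir)) {
    if (!dir.exists(config$dataset_dir))
      stop(sprintf("dataset directory not found: %s", config$dataset_dir),
           call. = FALSE)
    run_log(log_path, "loading image tree from %s", config$dataset_dir)
    bundle <- read_image_tree(config$dataset_dir)
  } else {
    run_log(log_path, "generating synthetic dataset (K=%d, n=%d/class)",
            config$synthetic$K, config$synthetic$n_per_class)
    bundle <- generate_brain_dataset(config$synthetic)$bundle
  }

  # --- preprocessing -------------------------------------------------
  removed <- 0L
  thr <- config$snr_threshold
  if (!is.null(thr) && !is.na(thr)) {
    cl <- clean_dataset(bundle, threshold = thr)
    removed <- cl$removed
    if (!is.null(config$out_dir))
      write_cleaning_manifest(bundle, cl$snr, thr,
                              file.path(config$out_dir,
                                        "cleaning_manifest.csv"))
    bundle <- cl$bundle
    run_log(log_path, "SNR cleaning at %.2f removed %d images", thr,
            removed)
  }
  bundle <- split_dataset(bundle, test_fraction = config$test_fraction,
                          validation_fraction = config$validation_fraction,
                          seed = config$seed)

  # --- optimization --------------------------------------------------
  space <- build_default_space()
  train_cfg <- train_config(epochs = config$epochs,
                            eval_on = config$eval_on,
                            seed = config$seed)
  backbone <- backbone_spec(config$backbone)
  ledger_path <- if (is.null(config$out_dir)) NULL
                 else file.path(config$out_dir, "evaluations.jsonl")
  fitness_fn <- function(x) {
    res <- evaluate_fitness(x, bundle, space, backbone, train_cfg)
    if (!is.null(ledger_path)) append_run_ledger(res, x, ledger_path)
    res$fitness
  }
  params <- gto_params(N = config$population, Tmax = config$iterations,
                       D = space$D, lower = 0, upper = 1,
                       seed = config$seed)
  ckpt_path <- if (is.null(config$out_dir)) NULL
               else file.path(config$out_dir, "checkpoint.json")
  state <- NULL
  if (config$resume && !is.null(ckpt_path) && file.exists(ckpt_path)) {
    state <- checkpoint_read(ckpt_path)
    run_log(log_path, "resuming from checkpoint after iteration %d",
            state$t)
  }
  best_per_iter_env <- new.env()
  callback <- NULL
  if (!is.null(ckpt_path)) {
    callback <- function(t, pop) {
      hist <- pop$history
      bpi <- get0("bpi", envir = best_per_iter_env, ifnotfound = numeric(0))
      bpi <- c(bpi, pop$fitness[pop$silverback])
      assign("bpi", bpi, envir = best_per_iter_env)
      checkpoint_write(ckpt_path, t, pop, bpi)
    }
    if (!is.null(state))
      assign("bpi", state$best_per_iter, envir = best_per_iter_env)
  }
  run_log(log_path, "starting GTO: N=%d, Tmax=%d, D=%d",
          params$N, params$Tmax, params$D)
  result <- gto_optimize(fitness_fn, params, callback = callback,
                         state = state)
  run_log(log_path, "finished: best fitness %.4f", result$best_fitness)

  # --- reporting -----------------------------------------------------
  best <- evaluate_fitness(result$best_solution, bundle, space, backbone,
                           train_cfg)
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(
      list(solution = as.numeric(result$best_solution),
           fitness = result$best_fitness,
           config = unclass(best$config)),
      file.path(config$out_dir, "best_config.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(best$report))
      write_metric_report(best$report,
                          json_path = file.path(config$out_dir,
                                                "metrics.json"),
                          csv_path = file.path(config$out_dir,
                                               "metrics.csv"))
    write_gto_history(result, file.path(config$out_dir, "history.csv"))
  }
  list(best = best, best_solution = result$best_solution,
       history = result$history, removed = removed, bundle = bundle)
}

#' Decode a best-configuration JSON written by [run_pipeline()]
#'
#' @param path Path to `best_config.json`.
#' @return List with `solution`, `fitness` and the decoded `config`
#'   (an `hp_config`).
#' @export
read_best_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  cfg$brightness_range <- as.numeric(cfg$brightness_range)
  class(cfg) <- "hp_config"
  list(solution = as.numeric(obj$solution), fitness = obj$fitness,
       config = cfg)
}
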