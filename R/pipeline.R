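#' Experiment pipeline configuration
#'
#' Bundles every choice of the end-to-end protocol: data source,
#' preprocessing treatment, 3:1 stratified split, ELM size, optimiser and
#' which partition the optimiser's fitness is scored on.
#'
#' @param data a [labeled_spectra()], a spectra CSV path, or `NULL` to
#'   generate synthetic spectra from `synth`.
#' @param synth a [spectra_config()] used when `data` is `NULL` (default:
#'   `spectra_config(seed = seed)`).
#' @param preprocessing one of `"nm"` (default), `"none"`, `"msc"`, `"snv"`.
#' @param train_fraction training fraction of the stratified split
#'   (default 0.75, the 3:1 protocol).
#' @param n_hidden ELM hidden-layer size `L`; conventionally 135 for the
#'   plain ELM and 120 for optimiser-tuned runs.
#' @param optimizer `"none"` (plain ELM), `"ga"`, `"hba"` or `"thba"`.
#' @param optimizer_config matching config object ([ga_config()],
#'   [hba_config()] or [thba_config()]); defaults to that constructor's
#'   defaults (N = 50, tmax = 300, P = 0.8).
#' @param fitness_eval_set `"validation"` (default) scores the optimiser's
#'   fitness on an inner held-out slice of the training partition;
#'   `"test_paper_mode"` scores it on the test partition itself, reproducing
#'   the protocol in which the test-set error rate is the fitness (at the
#'   cost of leaking test labels into model selection).
#' @param validation_fraction inner validation fraction of the training
#'   partition in `"validation"` mode (default 0.2).
#' @param seed master integer seed; propagated to generation, splitting, ELM
#'   initialisation and the optimiser.
#' @param output_dir optional directory for run artifacts (metrics CSV,
#'   confusion CSV, trace CSV, manifest JSON).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(data = NULL, synth = NULL,
                            preprocessing = c("nm", "none", "msc", "snv"),
                            train_fraction = 0.75,
                            n_hidden = 120,
                            optimizer = c("none", "ga", "hba", "thba"),
                            optimizer_config = NULL,
                            fitness_eval_set = c("validation", "test_paper_mode"),
                            validation_fraction = 0.2,
                            seed = 1L,
                            output_dir = NULL) {
  preprocessing <- match.arg(preprocessing)
  optimizer <- match.arg(optimizer)
  fitness_eval_set <- match.arg(fitness_eval_set)
  seed <- as.integer(seed)
  if (is.null(data) && is.null(synth)) synth <- spectra_config(seed = seed)
  if (optimizer != "none" && is.null(optimizer_config)) {
    optimizer_config <- switch(optimizer,
      ga = ga_config(seed = seed),
      hba = hba_config(seed = seed),
      thba = thba_config(seed = seed))
  }
  if (!is.null(optimizer_config)) {
    expected <- switch(optimizer, ga = "ga_config", hba = "hba_config",
                       thba = "thba_config", "none" = NULL)
    if (!is.null(expected) && !inherits(optimizer_config, expected))
      stop(sprintf("optimizer '%s' requires a %s()", optimizer, expected))
  }
  structure(list(data = data, synth = synth, preprocessing = preprocessing,
                 train_fraction = train_fraction, n_hidden = as.integer(n_hidden),
                 optimizer = optimizer, optimizer_config = optimizer_config,
                 fitness_eval_set = fitness_eval_set,
                 validation_fraction = validation_fraction,
                 seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

#' Build the optimiser fitness adapter
#'
#' Returns the objective the metaheuristics minimise: a deterministic
#' function of a packed position vector (`omega` column-major, then `bias`)
#' that trains an ELM with those fixed hidden parameters on `train` and
#' returns the misclassification rate on `eval`. The matching `[-1, 1]`
#' search box is attached as attribute `"space"`.
#'
#' @param train,eval preprocessed [labeled_spectra()] partitions.
#' @param n_hidden hidden-layer size `L`.
#' @param weight_low,weight_high bounds of the weight box (defaults -1, 1).
#' @param classes ordered class labels (default 0:4).
#' @return Fitness `function(position) -> error rate in [0, 1]`.
#' @export
make_fitness <- function(train, eval, n_hidden,
                         weight_low = -1, weight_high = 1,
                         classes = 0:4) {
  stopifnot(inherits(train, "labeled_spectra"),
            inherits(eval, "labeled_spectra"))
  d <- ncol(train$reflectance)
  l <- as.integer(n_hidden)
  cfg <- elm_config(l, weight_low = weight_low, weight_high = weight_high)
  x_tr <- train$reflectance; y_tr <- train$labels
  x_ev <- eval$reflectance; y_ev <- eval$labels
  fn <- function(position) {
    par <- unpack_position(position, d, l)
    model <- elm_train(x_tr, y_tr, cfg, omega = par$omega, bias = par$bias,
                       classes = classes)
    mean(elm_predict(model, x_ev) != y_ev)
  }
  attr(fn, "space") <- search_space(weight_low, weight_high, dim = d * l + l)
  attr(fn, "d") <- d
  attr(fn, "n_hidden") <- l
  fn
}

load_spectra <- function(config) {
  if (inherits(config$data, "labeled_spectra")) return(config$data)
  if (is.character(config$data)) return(read_spectra(config$data))
  generate_spectra(config$synth)
}

#' Run one end-to-end classification experiment
#'
#' Stage chain: load or generate spectra, 3:1 stratified split, preprocessing
#' fitted on the training partition, then either a plain random-weight ELM or
#' an optimiser (GA / HBA / tHBA) searching the packed `(omega, b)` space.
#' The final model is trained on the full training partition with the best
#' hidden parameters and scored on the test partition. Everything is
#' reproducible from `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return List with `model`, `metrics` (a `metrics_report`), `confusion`,
#'   `run` (the `optimizer_run`, or `NULL` for plain ELM), `split_idx`
#'   (train/test row indices), `config`, and `predictions`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spectra <- load_spectra(config)
  split <- stratified_split(spectra, config$train_fraction, seed = config$seed)
  prep <- preprocess_spectra(split$train, split$test, config$preprocessing)
  train <- prep$train; test <- prep$test
  classes <- sort(unique(spectra$labels))
  run <- NULL
  if (config$optimizer == "none") {
    cfg <- elm_config(config$n_hidden, seed = config$seed)
    model <- elm_train(train$reflectance, train$labels, cfg, classes = classes)
  } else {
    if (config$fitness_eval_set == "validation") {
      inner <- stratified_split(train, 1 - config$validation_fraction,
                                seed = config$seed + 1L)
      fitness <- make_fitness(inner$train, inner$test, config$n_hidden,
                              classes = classes)
    } else {
      fitness <- make_fitness(train, test, config$n_hidden, classes = classes)
    }
    space <- attr(fitness, "space")
    ocfg <- config$optimizer_config
    if (is.null(ocfg$seed)) ocfg$seed <- config$seed
    run <- switch(config$optimizer,
      ga = ga_optimize(fitness, space, ocfg),
      hba = hba_optimize(fitness, space, ocfg),
      thba = thba_optimize(fitness, space, ocfg))
    par <- unpack_position(run$best_position, attr(fitness, "d"),
                           attr(fitness, "n_hidden"))
    cfg <- elm_config(config$n_hidden)
    model <- elm_train(train$reflectance, train$labels, cfg,
                       omega = par$omega, bias = par$bias, classes = classes)
  }
  pred <- elm_predict(model, test$reflectance)
  cm <- confusion(test$labels, pred, k = length(classes),
                  class_names = spectra$class_names[classes + 1L])
  metrics <- per_class_metrics(cm)
  result <- list(model = model, metrics = metrics, confusion = cm, run = run,
                 split_idx = list(train = attr(split, "train_idx"),
                                  test = attr(split, "test_idx")),
                 predictions = pred, config = config)
  if (!is.null(config$output_dir)) write_run_artifacts(result, config)
  result
}

write_run_artifacts <- function(result, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  label <- if (config$optimizer == "none") "elm" else
    paste0(config$optimizer, "-elm")
  reports <- stats::setNames(list(result$metrics), label)
  write_metrics_csv(reports, file.path(config$output_dir, "metrics.csv"))
  write_confusion_csv(result$confusion,
                      file.path(config$output_dir, "confusion.csv"))
  if (!is.null(result$run))
    write_trace(result$run, file.path(config$output_dir, "trace.csv"))
  manifest <- list(
    seed = config$seed, preprocessing = config$preprocessing,
    optimizer = config$optimizer, n_hidden = config$n_hidden,
    train_fraction = config$train_fraction,
    fitness_eval_set = config$fitness_eval_set,
    package_version = as.character(utils::packageVersion("badgerlm")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Compare classifier variants across paired seeds
#'
#' Runs each requested model on identical data and identical stratified
#' splits for every seed (splits depend only on the seed, never on the
#' model), then summarises the overall test metrics per model.
#'
#' @param config a [pipeline_config()] providing the shared data source,
#'   preprocessing and budgets; its `optimizer` field is overridden per
#'   model.
#' @param models character vector drawn from `"none"`, `"ga"`, `"hba"`,
#'   `"thba"` (output preserves this order).
#' @param seeds integer vector of seeds.
#' @return List with `summary` (per-model mean/sd of accuracy, precision,
#'   sensitivity, F1 across seeds) and `runs` (nested list,
#'   `runs[[model]][[seed index]]`).
#' @export
compare_models <- function(config, models = c("none", "ga", "hba", "thba"),
                           seeds = 1L) {
  stopifnot(inherits(config, "pipeline_config"), length(models) >= 1,
            length(seeds) >= 1)
  models <- match.arg(models, c("none", "ga", "hba", "thba"),
                      several.ok = TRUE)
  runs <- lapply(models, function(m) {
    lapply(seeds, function(s) {
      cfg <- config
      cfg$seed <- as.integer(s)
      cfg$optimizer <- m
      cfg$output_dir <- NULL
      cfg$optimizer_config <- if (m == "none") NULL else {
        oc <- config$optimizer_config
        if (!is.null(oc)) {
          ok <- switch(m, ga = "ga_config", hba = "hba_config",
                       thba = "thba_config")
          if (!inherits(oc, ok)) oc <- NULL
        }
        if (is.null(oc)) oc <- switch(m, ga = ga_config(),
                                      hba = hba_config(), thba = thba_config())
        oc$seed <- as.integer(s)
        oc
      }
      run_experiment(cfg)
    })
  })
  names(runs) <- models
  summary <- do.call(rbind, lapply(models, function(m) {
    ov <- do.call(rbind, lapply(runs[[m]], function(r) r$metrics$overall))
    data.frame(model = m,
               accuracy_mean = mean(ov$accuracy), accuracy_sd = stats::sd(ov$accuracy),
               precision_mean = mean(ov$precision),
               sensitivity_mean = mean(ov$sensitivity),
               f1_mean = mean(ov$f1),
               n_seeds = length(seeds))
  }))
  list(summary = summary, runs = runs)
}
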