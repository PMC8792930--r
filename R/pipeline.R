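# Experiment runner and end-to-end pipeline: repeated seeded train/test
# splits of the count-to-yield models, and the full simulate -> evaluate ->
# fit -> accumulate chain with a JSON report.

#' Run a seeded train/test yield-model experiment
#'
#' One run draws a random pot-level 80/20 (or `train_frac`) split, fits the
#' requested model on the training pots' observed per-pot count totals
#' against their true seed numbers, and scores ACC on the held-out pots.
#' Several runs differ only in their derived seeds; their mean is the summary
#' usually reported.
#'
#' @param dataset A `pot_dataset` from [generate_pot_dataset()], or a data
#'   frame with columns `n_leaf`, `n_pod1` .. `n_pod5` and `true_seeds`.
#' @param model `"grnn"`, `"plsr"` or `"bpnn"`.
#' @param n_runs Number of repeated splits.
#' @param train_frac Training fraction of pots.
#' @param seed Base seed; run r uses `seed + r - 1`.
#' @param sigma GRNN bandwidth policy (`"auto"` or a number); ignored by the
#'   baselines.
#' @return List with `per_run` (data frame: run, seed, ACC, n_test),
#'   `mean_acc`, and `last_fit` (the fitted model of the final run).
#' @export
run_yield_experiment <- function(dataset, model = c("grnn", "plsr", "bpnn"),
                                 n_runs = 3L, train_frac = 0.8, seed = 1L,
                                 sigma = "auto") {
  model <- match.arg(model)
  pots <- if (inherits(dataset, "pot_dataset")) dataset$pots else dataset
  need <- c(count_cols(), "true_seeds")
  if (!all(need %in% names(pots)))
    stop("dataset must carry observed count columns and true_seeds")
  if (any(pots$true_seeds <= 0))
    pots <- pots[pots$true_seeds > 0, , drop = FALSE]  # ACC needs y > 0
  n <- nrow(pots)
  if (n < 5L) stop("too few pots with positive seed counts")
  X <- as_count_matrix(pots[, count_cols()])
  y <- pots$true_seeds
  per_run <- vector("list", n_runs)
  fit <- NULL
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r - 1L
    idx_train <- withr::with_seed(run_seed,
                                  sample.int(n, round(n * train_frac)))
    idx_test <- setdiff(seq_len(n), idx_train)
    fit <- switch(model,
      grnn = grnn_fit(X[idx_train, , drop = FALSE], y[idx_train], sigma = sigma),
      plsr = plsr_fit(X[idx_train, , drop = FALSE], y[idx_train]),
      bpnn = bpnn_fit(X[idx_train, , drop = FALSE], y[idx_train],
                      seed = run_seed))
    pred <- switch(model,
      grnn = grnn_predict(fit, X[idx_test, , drop = FALSE]),
      plsr = plsr_predict(fit, X[idx_test, , drop = FALSE]),
      bpnn = bpnn_predict(fit, X[idx_test, , drop = FALSE]))
    per_run[[r]] <- data.frame(run = r, seed = run_seed,
                               acc = acc(y[idx_test], pred),
                               n_test = length(idx_test))
  }
  per_run <- do.call(rbind, per_run)
  list(per_run = per_run, mean_acc = mean_run_accuracy(per_run$acc),
       model = model, last_fit = fit)
}

#' Score predicted yield mass against the true mass
#'
#' Converts model-predicted seed numbers to grams and scores them with the
#' same relative-deviation ACC used for seed numbers. Under `"uniform"`
#' every predicted seed weighs the all-types average `w_a`. Under
#' `"per_type"` the observed pod-type mix of each pot distributes the
#' predicted seed number over types before weighing, so type-specific grain
#' weights can be applied even though the model predicts only a total.
#'
#' @param pots Per-pot data frame with observed counts, `true_seeds` and
#'   `true_grams`.
#' @param predicted_seeds Model predictions aligned with `pots` rows.
#' @param weights A [seed_weights()].
#' @param mode `"per_type"` or `"uniform"`.
#' @return List with `acc`, `predicted_grams`, `total_predicted`,
#'   `total_true`.
#' @export
score_yield_mass <- function(pots, predicted_seeds, weights = seed_weights(),
                             mode = c("per_type", "uniform")) {
  mode <- match.arg(mode)
  obs <- as_count_matrix(pots[, count_cols()])
  obs_seeds <- seed_number(obs)
  grams <- if (mode == "uniform") {
    predicted_seeds * weights$w_a
  } else {
    # per-type grams of the observed mix, rescaled to the predicted total
    mix_grams <- yield_grams(obs, weights, mode = "per_type")
    scale <- ifelse(obs_seeds > 0, predicted_seeds / obs_seeds, 0)
    mix_grams * scale
  }
  list(acc = acc(pots$true_grams, grams), predicted_grams = grams,
       total_predicted = sum(grams), total_true = sum(pots$true_grams))
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. All seeds are recorded in the
#' report so any output can be regenerated from its provenance block.
#'
#' @param n_pots Pots to simulate.
#' @param pot A [pot_spec()].
#' @param noise Detector counting noise, `list(precision =, recall =)` or
#'   `NULL`.
#' @param weights A [seed_weights()].
#' @param n_runs Train/test repeats per model.
#' @param train_frac Training fraction.
#' @param sigma GRNN bandwidth policy.
#' @param models Models to fit.
#' @param eval_scenes Rendered scenes to generate for detection evaluation
#'   (0 skips rendering).
#' @param scene A [scene_spec()] template for those scenes.
#' @param iou_thresh Matching threshold for detection evaluation.
#' @param seed Global seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_pots = 90L, pot = pot_spec(),
                            noise = list(precision = 0.903, recall = 0.876),
                            weights = seed_weights(), n_runs = 3L,
                            train_frac = 0.8, sigma = "auto",
                            models = c("grnn", "plsr", "bpnn"),
                            eval_scenes = 8L, scene = scene_spec(),
                            iou_thresh = 0.5, seed = 1L) {
  structure(list(n_pots = as.integer(n_pots), pot = pot, noise = noise,
                 weights = weights, n_runs = as.integer(n_runs),
                 train_frac = train_frac, sigma = sigma, models = models,
                 eval_scenes = as.integer(eval_scenes), scene = scene,
                 iou_thresh = iou_thresh, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a flat key-value YAML file whose keys mirror the arguments of
#' [pipeline_config()] (nested `pot:`, `scene:` and `noise:` blocks map to
#' [pot_spec()], [scene_spec()] and the noise list). Keys not present keep
#' their defaults.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file (flags beat file values).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_pots", "n_runs", "train_frac", "sigma", "models",
              "eval_scenes", "iou_thresh", "seed"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$pot)) args$pot <- do.call(pot_spec, raw$pot)
  if (!is.null(raw$scene)) args$scene <- do.call(scene_spec, raw$scene)
  if (!is.null(raw$weights)) args$weights <- do.call(seed_weights, raw$weights)
  if ("noise" %in% names(raw)) args$noise <- raw$noise
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

log_stage <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " [podyield] ", ...)
}

#' Run the full yield-prediction pipeline
#'
#' Simulates (or loads) the pot count dataset, optionally renders scenes and
#' scores a simulated detector against their ground truth, runs the seeded
#' train/test experiments for every requested model, converts the best
#' model's predictions to grain mass under both weighting modes, and returns
#' (optionally writes) a JSON-ready report with full provenance.
#'
#' @param config A [pipeline_config()].
#' @param counts Optional pre-existing per-pot data frame (observed counts +
#'   `true_seeds` + `true_grams`); when supplied, simulation is skipped.
#' @param report_path Optional path for the JSON report.
#' @param verbose Log stage progress to stderr.
#' @return The report, an S3 list of class `"pipeline_report"`.
#' @export
run_pipeline <- function(config = pipeline_config(), counts = NULL,
                         report_path = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (is.null(counts)) {
    log_stage(verbose, "simulating ", config$n_pots, " pots (seed ",
              config$seed, ")")
    ds <- generate_pot_dataset(config$n_pots, config$pot, seed = config$seed,
                               noise = config$noise, weights = config$weights)
    pots <- ds$pots
  } else {
    log_stage(verbose, "using supplied counts (", nrow(counts), " pots)")
    pots <- counts
  }

  detection <- NULL
  if (config$eval_scenes > 0L) {
    log_stage(verbose, "rendering ", config$eval_scenes,
              " scenes and scoring simulated detections")
    gt <- preds <- vector("list", config$eval_scenes)
    for (i in seq_len(config$eval_scenes)) {
      sc_spec <- config$scene
      sc_spec$seed <- config$seed + 1000L + i
      sc <- generate_scene(sc_spec)
      gt[[i]] <- sc$boxes
      preds[[i]] <- simulate_detections(
        sc$boxes, sc_spec$width, sc_spec$height,
        precision = if (is.null(config$noise)) 1 else config$noise$precision,
        recall = if (is.null(config$noise)) 1 else config$noise$recall,
        seed = config$seed + 2000L + i)
    }
    ev <- evaluate_detections(preds, gt, iou_thresh = config$iou_thresh)
    overall <- ev$per_class[ev$per_class$class == "overall", ]
    detection <- list(precision = overall$precision, recall = overall$recall,
                      f1 = overall$f1, map = ev$map,
                      n_scenes = config$eval_scenes)
  }

  experiments <- list()
  for (m in config$models) {
    log_stage(verbose, "fitting ", m, " (", config$n_runs, " runs)")
    experiments[[m]] <- run_yield_experiment(
      pots, model = m, n_runs = config$n_runs,
      train_frac = config$train_frac, seed = config$seed, sigma = config$sigma)
  }

  log_stage(verbose, "accumulating yield mass")
  best <- names(experiments)[which.max(vapply(experiments, `[[`, numeric(1),
                                              "mean_acc"))]
  # in-sample predictions over all pots with the last fitted best model
  fit <- experiments[[best]]$last_fit
  X <- as_count_matrix(pots[, count_cols()])
  pred_seeds <- switch(best,
    grnn = grnn_predict(fit, X),
    plsr = plsr_predict(fit, X),
    bpnn = bpnn_predict(fit, X))
  mass_per_type <- score_yield_mass(pots, pred_seeds, config$weights,
                                    "per_type")
  mass_uniform <- score_yield_mass(pots, pred_seeds, config$weights,
                                   "uniform")
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report <- structure(list(
    detection = detection,
    models = lapply(experiments, function(e)
      list(per_run_acc = e$per_run$acc, mean_acc = e$mean_acc)),
    best_model = best,
    yield = list(
      per_type = list(acc = mass_per_type$acc,
                      total_grams = mass_per_type$total_predicted),
      uniform = list(acc = mass_uniform$acc,
                     total_grams = mass_uniform$total_predicted),
      total_true_grams = mass_per_type$total_true),
    grams_per_pot = mass_per_type$predicted_grams,
    provenance = list(seed = config$seed, n_pots = nrow(pots),
                      n_runs = config$n_runs, sigma_policy = config$sigma,
                      noise = config$noise, elapsed_s = elapsed)),
    class = "pipeline_report")
  if (!is.null(report_path)) {
    jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    log_stage(verbose, "report written to ", report_path)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("podyield pipeline report (seed", x$provenance$seed, ")\n")
  if (!is.null(x$detection))
    cat(sprintf("  detection: P=%.3f R=%.3f F1=%.3f mAP=%.3f\n",
                x$detection$precision, x$detection$recall, x$detection$f1,
                x$detection$map))
  for (m in names(x$models))
    cat(sprintf("  %s: mean ACC=%.4f (runs: %s)\n", m, x$models[[m]]$mean_acc,
                paste(sprintf("%.4f", x$models[[m]]$per_run_acc),
                      collapse = ", ")))
  cat(sprintf("  yield mass ACC: per-type %.4f, uniform %.4f\n",
              x$yield$per_type$acc, x$yield$uniform$acc))
  cat(sprintf("  total predicted mass: %.1f g (true %.1f g)\n",
              x$yield$per_type$total_grams, x$yield$total_true_grams))
  invisible(x)
}
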