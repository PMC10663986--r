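# Repeated patient-disjoint cross-validation harness and the mask ablation
# suite. At iteration i of each repeat, fold i is the test set, fold
# (i + 1) mod k the validation set (early stopping), and the remaining
# folds the training set. Deep models are not re-trained on train +
# validation after early stopping; the classical linear Cox baseline is
# re-fit on train + validation.

evaluate_survival_model <- function(model, test, metric) {
  if (metric == "harrell") {
    risks <- switch(model$config$loss,
      cox = forward_risk(model, test$features),
      # for non-Cox heads rank by expected cumulative hazard at the horizon
      deephit = rowSums(sweep(forward_risk(model, test$features), 2L,
                              seq_len(model$config$n_intervals), "*")) * -1,
      pc_hazard = rowSums(sweep(forward_risk(model, test$features), 2L,
                                model$grid$widths, "*")))
    harrell_cindex(risks, test$events, test$durations)
  } else {
    times <- sort(unique(test$durations[test$events == 1]))
    curves <- survival_curves(model, test$features, times = times)
    antolini_cindex(curves, test$events, test$durations)
  }
}

#' Repeated cross-validated evaluation of one model configuration
#'
#' Runs `repeats` x `k` iterations of patient-disjoint cross-validation
#' ([make_folds()]); in each iteration the model is trained on the training
#' folds with early stopping on the validation fold and evaluated on the
#' test fold. Survival models are scored by the time-dependent (Antolini)
#' concordance by default (each family's own survival curves; Cox-loss
#' models compose their risk with the training-fold Breslow baseline) or by
#' the Harrell index on risk scores; classification models are scored by
#' AUROC. Iterations whose test fold has no event (or one class) are
#' excluded with a warning.
#'
#' @param ds a [survival_dataset()].
#' @param cfg a [risk_model_config()]; each iteration initializes with
#'   `cfg$seed + iteration` so repeat runs are deterministic.
#' @param pm a [pathway_matrix()] when `cfg$pathway_informed`.
#' @param k,repeats,seed cross-validation shape and fold seed.
#' @param metric "antolini", "harrell" (survival) or "auroc"
#'   (classification; chosen automatically for classification heads).
#' @param model_label label recorded in the results table.
#' @param folds optional precomputed [make_folds()] list (to share folds
#'   across paired model comparisons).
#' @return object of class `experiment_result`: `results` (one row per
#'   iteration: model, repeat, fold, iteration, seed, n_train, epochs,
#'   metric, value) and `summary` (median, IQR over iterations).
#' @export
run_cv <- function(ds, cfg, pm = NULL, k = 5L, repeats = 3L, seed = 1L,
                   metric = c("antolini", "harrell"),
                   model_label = NULL, folds = NULL) {
  stopifnot(inherits(ds, "survival_dataset"),
            inherits(cfg, "risk_model_config"))
  metric <- match.arg(metric)
  classification <- cfg$head == "classification"
  if (classification) metric <- "auroc"
  folds <- folds %||% make_folds(ds, k, repeats, seed)
  label <- model_label %||% paste0(
    if (cfg$pathway_informed) "pathway_informed" else "dense",
    "_depth", cfg$depth, "_", cfg$loss)
  rows <- list()
  for (fa in folds) {
    train <- subset_dataset(ds, fa$role == "train")
    val <- subset_dataset(ds, fa$role == "validation")
    test <- subset_dataset(ds, fa$role == "test")
    if (!classification && sum(test$events) == 0) {
      warning("iteration ", fa$iteration,
              " excluded: no events in its test fold")
      next
    }
    if (classification &&
        (is.null(test$malignancy) || length(unique(test$malignancy)) < 2L)) {
      warning("iteration ", fa$iteration,
              " excluded: single-class test fold")
      next
    }
    it_cfg <- cfg
    it_cfg$seed <- cfg$seed + fa$iteration
    model <- build_risk_model(it_cfg, pm)
    model <- fit_risk_model(model, train, val)
    value <- if (classification) {
      classification_metrics(forward_risk(model, test$features),
                             test$malignancy)$auroc
    } else {
      evaluate_survival_model(model, test, metric)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      model = label, repeat_index = fa$repeat_index, fold = fa$test_fold,
      iteration = fa$iteration, seed = fa$seed,
      n_train = n_samples(train), epochs = model$epochs_trained,
      metric = metric, value = value)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 summary = list(median = stats::median(results$value),
                                iqr = stats::IQR(results$value)),
                 config = cfg, metric = metric, model_label = label),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s | %d iterations | median %s %.4f (IQR %.4f)\n",
              x$model_label, nrow(x$results), x$metric,
              x$summary$median, x$summary$iqr))
  invisible(x)
}

#' Ablation suite for the pathway mask
#'
#' Runs the identical CV protocol under one of five perturbations:
#' \describe{
#'   \item{dense138}{fully connected first layer width-matched to the
#'     number of pathways (the mask's size without its biology).}
#'   \item{random_matrix}{edge-count-matched random mask, resampled per
#'     repeat seed.}
#'   \item{shuffled_matrix}{row-shuffled mask (pathway in-degrees
#'     preserved), resampled per repeat seed.}
#'   \item{dropout_sweep}{dense baseline with dropout rates
#'     `params$rates` (default 0.5-0.9) after the first hidden layer.}
#'   \item{sample_size_sweep}{the given configuration on patient
#'     subsamples of sizes `params$sizes` (default 50, 100, 200), drawn
#'     without replacement before folding.}
#' }
#'
#' @param ds a [survival_dataset()].
#' @param base_cfg a [risk_model_config()] (pathway-informed for the matrix
#'   ablations).
#' @param pm the reference [pathway_matrix()].
#' @param which ablation to run.
#' @param params ablation-specific parameters (see Description).
#' @param k,repeats,seed,metric as in [run_cv()].
#' @return named list of `experiment_result` objects (one per swept value,
#'   or length one).
#' @export
run_ablation <- function(ds, base_cfg, pm,
                         which = c("dense138", "random_matrix",
                                   "shuffled_matrix", "dropout_sweep",
                                   "sample_size_sweep"),
                         params = list(), k = 5L, repeats = 3L, seed = 1L,
                         metric = "antolini") {
  which <- match.arg(which)
  q <- length(pm$pathway_names)
  if (which == "dense138") {
    cfg <- base_cfg
    cfg$pathway_informed <- FALSE
    cfg$first_width <- q
    res <- run_cv(ds, cfg, NULL, k, repeats, seed, metric,
                  model_label = paste0("dense_width", q))
    return(stats::setNames(list(res), paste0("dense_width", q)))
  }
  if (which %in% c("random_matrix", "shuffled_matrix")) {
    perturb <- if (which == "random_matrix") {
      randomize_pathway_matrix
    } else {
      shuffle_pathway_rows
    }
    # resample the perturbed mask per repeat seed, same CV protocol
    parts <- lapply(seq_len(repeats), function(r) {
      rep_seed <- seed + r - 1L
      pm_r <- perturb(pm, rep_seed)
      res <- run_cv(ds, base_cfg, pm_r, k, repeats = 1L, seed = rep_seed,
                    metric = metric, model_label = which)
      res$results$repeat_index <- r
      res$results$iteration <- (r - 1L) * k + res$results$fold
      res
    })
    results <- do.call(rbind, lapply(parts, function(p) p$results))
    res <- structure(list(results = results,
                          summary = list(median = stats::median(results$value),
                                         iqr = stats::IQR(results$value)),
                          config = base_cfg, metric = parts[[1L]]$metric,
                          model_label = which),
                     class = "experiment_result")
    return(stats::setNames(list(res), which))
  }
  if (which == "dropout_sweep") {
    rates <- params$rates %||% c(0.5, 0.6, 0.7, 0.8, 0.9)
    out <- lapply(rates, function(rate) {
      cfg <- base_cfg
      cfg$pathway_informed <- FALSE
      cfg$dropout_rate <- rate
      run_cv(ds, cfg, NULL, k, repeats, seed, metric,
             model_label = sprintf("dense_dropout%.1f", rate))
    })
    return(stats::setNames(out, sprintf("dropout_%.1f", rates)))
  }
  # sample_size_sweep
  sizes <- params$sizes %||% c(50L, 100L, 200L)
  patients <- unique(ds$patient_ids)
  out <- lapply(sizes, function(sz) {
    if (sz > length(patients)) {
      stop("requested subsample of ", sz, " patients exceeds the ",
           length(patients), " available")
    }
    keep <- with_seed(seed + sz, sample(patients, sz))
    sub <- subset_dataset(ds, ds$patient_ids %in% keep)
    run_cv(sub, base_cfg, if (base_cfg$pathway_informed) pm, k, repeats,
           seed, metric,
           model_label = sprintf("%s_n%d", if (base_cfg$pathway_informed) {
             "pathway_informed"
           } else "dense", sz))
  })
  stats::setNames(out, paste0("n_", sizes))
}
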