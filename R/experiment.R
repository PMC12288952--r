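#' Train and evaluate a model family over a split plan
#'
#' The workhorse behind [run_experiment()], usable on its own: for an RS
#' plan it optionally trains one model per cross-validation fold (evaluated
#' on that fold's validation set) and always trains a final model on the
#' full training pool, evaluated on the independent test set and on the
#' pool itself; for a LOCO plan it trains one model per fold and evaluates
#' each on its held-out chromosome. Per-fold training seeds are derived
#' deterministically from `config$seed`, so a plan + spec + config triple
#' fully reproduces every number.
#'
#' @param features An [encode_dataset()] bundle covering every id in the
#'   plan.
#' @param plan An `m6a_split_plan` ([random_split()] or [loco_split()]).
#' @param spec An [model_spec()].
#' @param config An [train_config()].
#' @param with_cv For RS plans, also train/evaluate the per-fold
#'   cross-validation models (default `TRUE`).
#' @param threshold Decision threshold for the threshold metrics.
#' @param keep_predictions Attach the per-record predictions as the
#'   `"predictions"` attribute of the result.
#' @return Tibble of [evaluate_predictions()] rows, one per evaluated
#'   (fold, scope) pair, with columns `fold` and `scope` identifying what
#'   was evaluated (`scope` is `"validation"`, `"test"`, or `"train"`).
#' @export
evaluate_split_plan <- function(features, plan, spec, config = train_config(),
                                with_cv = TRUE, threshold = 0.5,
                                keep_predictions = FALSE) {
  stopifnot(inherits(plan, "m6a_split_plan"))
  rows <- list()
  preds <- list()
  fit_and_eval <- function(train_ids, eval_sets, fold_label, fold_index) {
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, "train", fold_index)
    fit <- train_model(build_model(spec), subset_features(features, train_ids),
                       fold_cfg)
    for (scope in names(eval_sets)) {
      ids <- eval_sets[[scope]]
      fs <- subset_features(features, ids)
      p <- predict(fit, fs)
      rows[[length(rows) + 1]] <<- dplyr::bind_cols(
        tibble::tibble(fold = fold_label),
        evaluate_predictions(fs$label, p, threshold = threshold, scope = scope))
      if (keep_predictions) {
        preds[[length(preds) + 1]] <<- tibble::tibble(
          fold = fold_label, scope = scope, id = ids, truth = fs$label,
          prob = unname(p))
      }
    }
    invisible(fit)
  }

  if (plan$mode == "RS") {
    if (with_cv) {
      for (i in seq_len(nrow(plan$folds))) {
        fit_and_eval(plan$folds$train[[i]],
                     list(validation = plan$folds$validation[[i]]),
                     plan$folds$fold[i], i)
      }
    }
    pool <- c(plan$folds$train[[1]], plan$folds$validation[[1]])
    fit_and_eval(pool,
                 list(train = pool, test = plan$folds$test[[1]]),
                 "final", 0L)
  } else {
    for (i in seq_len(nrow(plan$folds))) {
      fit_and_eval(plan$folds$train[[i]],
                   list(test = plan$folds$test[[i]]),
                   plan$folds$fold[i], i)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (keep_predictions) attr(out, "predictions") <- dplyr::bind_rows(preds)
  out
}

#' Run an end-to-end experiment
#'
#' Orchestrates the full workflow: obtain a dataset (given directly or
#' generated from a synthetic config), balance negatives into disjoint 1:1
#' replicates, build RS and/or LOCO split plans (audited for leakage),
#' encode, train every requested model variant, and write all artifacts
#' under `out_dir`: per-fold metric reports, aggregates with confidence
#' intervals, split-plan JSONs, per-record test predictions, and a run
#' manifest recording config, seeds, package and R versions, and wall
#' times. Every number in the aggregate tables is traceable to a stored
#' per-fold report.
#'
#' @param data An [as_m6a_dataset()] tibble, or `NULL` to generate from
#'   `synth`.
#' @param synth An [synth_config()] used when `data` is `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param modes Validation protocols to run: `"RS"`, `"LOCO"`, or both.
#' @param variants Model variants to train (`"SM"`, `"HM"`, `"DHM"`).
#' @param n_subsets Number of balanced negative replicates.
#' @param test_fraction,cv_folds RS plan parameters.
#' @param with_cv Train the per-fold RS cross-validation models.
#' @param spec_fn Function `(variant, L, k)` returning an [model_spec()];
#'   the default uses the faithful full-scale spec for `L >= 1001` and the
#'   desk-scale profile otherwise.
#' @param config An [train_config()].
#' @param k k-mer length for encoding; default 5 at full scale
#'   (`L >= 1001`), 3 at desk scale, matching the default `spec_fn`.
#' @param seed Global seed; all stage seeds derive from it.
#' @param threshold Decision threshold.
#' @return Invisibly, a tibble of all per-fold reports with `replicate`,
#'   `mode`, `variant` metadata columns (also written to
#'   `<out_dir>/reports.csv`, with aggregates in
#'   `<out_dir>/aggregates.csv`).
#' @export
run_experiment <- function(data = NULL, synth = NULL, out_dir,
                           modes = c("RS", "LOCO"), variants = "SM",
                           n_subsets = 1, test_fraction = 0.2, cv_folds = 5,
                           with_cv = TRUE, spec_fn = NULL,
                           config = train_config_fast(),
                           k = NULL, seed = 1, threshold = 0.5) {
  modes <- match.arg(modes, several.ok = TRUE)
  variants <- match.arg(variants, c("SM", "HM", "DHM"), several.ok = TRUE)
  t0 <- Sys.time()
  if (is.null(data)) {
    if (is.null(synth)) stop("provide either data or a synth config", call. = FALSE)
    data <- generate_dataset(synth)
  }
  if (!inherits(data, "m6a_dataset")) data <- as_m6a_dataset(data)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  k <- k %||% if (attr(data, "L") >= 1001) 5L else 3L
  spec_fn <- spec_fn %||% function(variant, L, k) {
    if (L >= 1001) model_spec(variant, L = L, kmer_k = k)
    else model_spec_fast(variant, L = L, kmer_k = k)
  }
  scheme <- if (any(variants %in% c("HM", "DHM"))) "both" else "onehot"
  L <- attr(data, "L")

  replicates <- balance_negatives(data, n_subsets,
                                  seed = derive_seed(seed, "balance"))
  all_reports <- list()
  all_aggregates <- list()
  for (r in seq_along(replicates)) {
    rep_ds <- replicates[[r]]
    features <- encode_dataset(rep_ds, scheme = scheme, k = k)
    for (mode in modes) {
      plan <- if (mode == "RS") {
        random_split(rep_ds, test_fraction = test_fraction,
                     cv_folds = cv_folds, seed = derive_seed(seed, "split", r))
      } else {
        loco_split(rep_ds, seed = derive_seed(seed, "split", r))
      }
      audit_split(plan, rep_ds)
      mode_dir <- file.path(out_dir, sprintf("replicate%d", r), mode)
      dir.create(mode_dir, recursive = TRUE, showWarnings = FALSE)
      split_to_json(plan, file.path(mode_dir, "split_plan.json"))
      for (variant in variants) {
        spec <- spec_fn(variant, L, k)
        cfg <- config
        cfg$seed <- derive_seed(seed, paste0("fit_", variant), r)
        reports <- evaluate_split_plan(features, plan, spec, cfg,
                                       with_cv = with_cv, threshold = threshold,
                                       keep_predictions = TRUE)
        vdir <- file.path(mode_dir, variant)
        dir.create(vdir, showWarnings = FALSE)
        readr::write_csv(reports, file.path(vdir, "fold_reports.csv"),
                         progress = FALSE)
        readr::write_csv(attr(reports, "predictions"),
                         file.path(vdir, "predictions.csv"), progress = FALSE)
        test_rows <- reports[reports$scope == "test", , drop = FALSE]
        agg_scope <- if (mode == "LOCO") test_rows else
          reports[reports$scope == "validation", , drop = FALSE]
        agg <- if (nrow(agg_scope) >= 2) aggregate_metrics(agg_scope) else
          aggregate_metrics(test_rows)
        agg <- dplyr::bind_cols(
          tibble::tibble(replicate = r, mode = mode, variant = variant,
                         aggregated_over = if (mode == "LOCO") "chromosome"
                                           else "cv_fold")[rep(1, nrow(agg)), ],
          agg)
        readr::write_csv(agg, file.path(vdir, "aggregate.csv"), progress = FALSE)
        all_aggregates[[length(all_aggregates) + 1]] <- agg
        all_reports[[length(all_reports) + 1]] <- dplyr::bind_cols(
          tibble::tibble(replicate = r, mode = mode,
                         variant = variant)[rep(1, nrow(reports)), ],
          reports)
      }
    }
  }
  reports <- dplyr::bind_rows(all_reports)
  aggregates <- dplyr::bind_rows(all_aggregates)
  readr::write_csv(reports, file.path(out_dir, "reports.csv"), progress = FALSE)
  readr::write_csv(aggregates, file.path(out_dir, "aggregates.csv"),
                   progress = FALSE)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = seed, modes = modes, variants = variants,
    n_subsets = n_subsets, test_fraction = test_fraction,
    cv_folds = cv_folds, with_cv = with_cv, k = k, threshold = threshold,
    L = L, n_records = nrow(data),
    train_config = unclass(config),
    package_version = as.character(utils::packageVersion("m6aloco")),
    r_version = R.version.string,
    wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(reports)
}

#' Compare completed experiment runs
#'
#' Reads the aggregate tables of two or more [run_experiment()] output
#' directories and binds them into one long comparison table
#' (run x mode x variant x metric with point estimate and confidence
#' interval), the shape used to contrast RS against LOCO performance per
#' variant.
#'
#' @param run_dirs Character vector of at least two run directories.
#' @return Tibble: `run`, `replicate`, `mode`, `variant`, `metric`,
#'   `mean`, `lower`, `upper`, `n_used`, `n_undefined`.
#' @export
compare_runs <- function(run_dirs) {
  if (length(run_dirs) < 2) {
    stop("need at least two runs to compare", call. = FALSE)
  }
  tabs <- lapply(run_dirs, function(d) {
    f <- file.path(d, "aggregates.csv")
    if (!file.exists(f)) {
      stop("run ", d, " has no aggregate table (", f, " missing)", call. = FALSE)
    }
    agg <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    dplyr::bind_cols(tibble::tibble(run = basename(d))[rep(1, nrow(agg)), ], agg)
  })
  metric_sets <- lapply(tabs, function(t) sort(unique(t$metric)))
  if (length(unique(vapply(metric_sets, paste, character(1), collapse = ","))) > 1) {
    stop("runs report incompatible metric sets: ",
         paste(vapply(metric_sets, paste, character(1), collapse = "/"),
               collapse = " vs "), call. = FALSE)
  }
  dplyr::bind_rows(tabs)
}
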