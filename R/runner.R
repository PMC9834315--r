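#' Assemble a full pipeline configuration
#'
#' One master seed fans out into named sub-streams (synthesis, folds,
#' shuffles, permutations), so any stage can be re-run in isolation and a
#' whole run reproduces bit-for-bit from its config.
#'
#' @param n_sf,n_ori,image_side Feature-grid parameters.
#' @param n_per_class Synthetic images per class.
#' @param trials_per_condition Trials per condition (48 gives the full
#'   6 x 48 = 288-trial design).
#' @param delta_magnitude Per-wedge expression-signature offset.
#' @param identity_sd Between-image lognormal jitter sigma.
#' @param target_michelson Michelson contrast of synthesized stimuli.
#' @param driver_sf_bands SF bands of the response model's driver wedges
#'   (placed on the horizontal Fourier axis); `NULL` uses the middle
#'   third.
#' @param beta,lapse Response-model inverse temperature and lapse rate.
#' @param ensemble An [ensemble_config()].
#' @param behavior_k_folds,n_permutations Bias-prediction parameters.
#' @param seed Master seed.
#' @return A `run_config` list (round-trips through YAML via
#'   [write_run_config()] / [read_run_config()]).
#' @export
run_config <- function(n_sf = 24, n_ori = 16, image_side = 128,
                       n_per_class = 39, trials_per_condition = 48,
                       delta_magnitude = 0.35, identity_sd = 0.15,
                       target_michelson = 0.176,
                       driver_sf_bands = NULL, beta = 4, lapse = 0.02,
                       ensemble = ensemble_config(),
                       behavior_k_folds = 10, n_permutations = 10000,
                       seed = 1) {
  structure(list(
    n_sf = n_sf, n_ori = n_ori, image_side = image_side,
    n_per_class = n_per_class, trials_per_condition = trials_per_condition,
    delta_magnitude = delta_magnitude, identity_sd = identity_sd,
    target_michelson = target_michelson,
    driver_sf_bands = driver_sf_bands, beta = beta, lapse = lapse,
    ensemble = ensemble,
    behavior_k_folds = behavior_k_folds, n_permutations = n_permutations,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path for the YAML representation.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$ensemble <- unclass(lst$ensemble)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ens <- do.call(ensemble_config, lst$ensemble[!vapply(lst$ensemble, is.null, logical(1))])
  lst$ensemble <- NULL
  cfg <- do.call(run_config, lst[!vapply(lst, is.null, logical(1))])
  cfg$ensemble <- ens
  cfg
}

#' Filter a trial table by condition type
#'
#' @param trials Trial tibble.
#' @param mode One of `"different_expression"`, `"same_expression"`,
#'   `"pair:happy-angry"` (either class order), or `"contains:happy"`
#'   (different-class trials containing the class).
#' @return The filtered trials, order preserved. An empty result carries
#'   attribute `empty_subset = TRUE` and a warning.
#' @export
subset_trials <- function(trials, mode) {
  if (nrow(trials) == 0) abort("empty trial table", class = "firstsight_data_error")
  out <- if (mode == "different_expression") {
    different_class_trials(trials)
  } else if (mode == "same_expression") {
    trials[trials$left_class == trials$right_class, , drop = FALSE]
  } else if (grepl("^pair:", mode)) {
    cls <- strsplit(sub("^pair:", "", mode), "-")[[1]]
    if (length(cls) != 2 || !all(cls %in% CLASS_LABELS)) {
      abort("pair: mode needs two class labels, e.g. pair:happy-angry",
            class = "firstsight_config_error")
    }
    conds <- c(condition_name(cls[1], cls[2]), condition_name(cls[2], cls[1]))
    trials[trials$condition %in% conds, , drop = FALSE]
  } else if (grepl("^contains:", mode)) {
    cl <- sub("^contains:", "", mode)
    if (!cl %in% CLASS_LABELS) {
      abort("contains: mode needs a class label", class = "firstsight_config_error")
    }
    d <- different_class_trials(trials)
    d[d$left_class == cl | d$right_class == cl, , drop = FALSE]
  } else {
    abort(sprintf("unknown subset mode '%s'", mode), class = "firstsight_config_error")
  }
  if (nrow(out) == 0) {
    warn(sprintf("subset '%s' selected no trials", mode))
    attr(out, "empty_subset") <- TRUE
  }
  out
}

result_manifest <- c(
  "trials.csv", "features.csv",
  "relevance_awareness.csv", "relevance_expression.csv",
  "relevance_same_expression.csv",
  "weight_correlations.json", "behavior.json"
)

#' Run the full synthetic-data analysis pipeline
#'
#' Executes synthesis, feature extraction, the three decoding analyses
#' (which image is seen first on different-expression trials; which
#' expression an image carries; which image is seen first on
#' same-expression trials), the feature-weight correlations, the
#' behavioral statistics, and the bias-based prediction, writing every
#' result to `out_dir` (seven result files plus a run log).
#'
#' @param config A [run_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, a list with every intermediate object.
#' @export
run_all <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- c(sprintf("firstsight run | seed %d | started %s",
                         config$seed, format(t0)))
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  grid <- build_grid(config$n_sf, config$n_ori, config$image_side)
  say("stage grid: %d wedges (%d SF x %d ori), side %d px",
      grid$n_wedges, grid$n_sf, grid$n_ori, grid$image_side)

  deltas <- expression_delta_spec(grid, config$delta_magnitude)
  spec <- wedge_energy_spec(grid, class_deltas = deltas,
                            identity_sd = config$identity_sd,
                            target_michelson = config$target_michelson)
  images <- make_stimulus_set(spec, grid, config$n_per_class,
                              seed = derive_seed(config$seed, "synthesis"))
  features <- extract_feature_table(images, grid)
  say("stage synth: %d images (%d per class), %d features each",
      nrow(images), config$n_per_class, grid$n_wedges)

  sf_bands <- config$driver_sf_bands %||%
    seq(max(1, floor(grid$n_sf / 3)), min(grid$n_sf, ceiling(2 * grid$n_sf / 3)))
  model <- response_model(horizontal_axis_wedges(grid, sf_bands),
                          beta = config$beta, lapse = config$lapse)
  trials <- make_trial_table(images, config$trials_per_condition,
                             seed = derive_seed(config$seed, "design"))
  trials <- simulate_responses(trials, features, model,
                               seed = derive_seed(config$seed, "behavior"))
  say("stage trials: %d trials processed (%d conditions x %d)",
      nrow(trials), length(unique(trials$condition)), config$trials_per_condition)

  decode_subset <- function(trial_subset, stream) {
    rows <- make_trial_rows(trial_subset, features, "response_side")
    decode_features(rows, config$ensemble, seed = derive_seed(config$seed, stream))
  }
  aware <- decode_subset(subset_trials(trials, "different_expression"), "decode_awareness")
  say("stage decode-awareness: %d runs, %d controls, %d/%d features significant",
      nrow(aware$runs), nrow(aware$controls),
      sum(aware$relevance$significant), nrow(aware$relevance))

  expr_rows <- make_trial_rows(NULL, features, "expression")
  expr <- decode_features(expr_rows, config$ensemble,
                          seed = derive_seed(config$seed, "decode_expression"))
  say("stage decode-expression: %d runs, %d controls, %d/%d features significant",
      nrow(expr$runs), nrow(expr$controls),
      sum(expr$relevance$significant), nrow(expr$relevance))

  same <- decode_subset(subset_trials(trials, "same_expression"), "decode_same_expression")
  say("stage decode-same-expression: %d/%d features significant",
      sum(same$relevance$significant), nrow(same$relevance))

  sides <- split_sides(aware$relevance)
  corr_lr <- correlate_weights(stats::setNames(sides$left, sides$wedge_id),
                               stats::setNames(sides$right, sides$wedge_id))
  avg <- average_sides(sides)
  expr_w <- stats::setNames(expr$relevance$weight, expr$relevance$feature_id)
  corr_ae <- correlate_weights(avg, expr_w)
  sig_expr <- expr$relevance$feature_id[expr$relevance$significant]
  corr_sig <- if (length(sig_expr) >= 3) {
    correlate_weights(avg, expr_w, exclusion = "subset", subset = sig_expr)
  } else NULL
  say("stage correlate-weights: left-right r = %.3f (n = %d)", corr_lr$r, corr_lr$n)

  behav <- behavior_summary(trials)
  bias <- bias_cv_predict(trials, config$behavior_k_folds, config$n_permutations,
                          seed = derive_seed(config$seed, "bias_prediction"))
  fixed_ha <- fixed_class_predict(trials, "happy", c("happy", "angry"),
                                  config$n_permutations,
                                  seed = derive_seed(config$seed, "fixed_ha"))
  fixed_h <- fixed_class_predict(trials, "happy", NULL, config$n_permutations,
                                 seed = derive_seed(config$seed, "fixed_h"))
  say("stage behavior: bias prediction %.2f%% (perm p = %.4f)",
      100 * bias$overall_accuracy, bias$perm_p)

  readr::write_csv(trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(features, file.path(out_dir, "features.csv"))
  readr::write_csv(aware$relevance, file.path(out_dir, "relevance_awareness.csv"))
  readr::write_csv(expr$relevance, file.path(out_dir, "relevance_expression.csv"))
  readr::write_csv(same$relevance, file.path(out_dir, "relevance_same_expression.csv"))
  corr_out <- list(
    left_right = as.list(corr_lr),
    awareness_vs_expression = as.list(corr_ae),
    awareness_vs_expression_significant_subset = if (!is.null(corr_sig)) as.list(corr_sig)
  )
  jsonlite::write_json(corr_out, file.path(out_dir, "weight_correlations.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  behav_out <- list(
    fractions = behav$fractions,
    friedman = if (!is.null(behav$friedman)) as.list(behav$friedman),
    pairwise = behav$pairwise,
    bias_prediction = list(overall_accuracy = bias$overall_accuracy,
                           perm_p = bias$perm_p,
                           fold_accuracies = bias$fold_accuracies,
                           n_permutations = bias$n_permutations),
    fixed_happy_vs_angry = as.list(fixed_ha),
    fixed_happy_all = as.list(fixed_h),
    seed = config$seed
  )
  jsonlite::write_json(behav_out, file.path(out_dir, "behavior.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("finished in %.1f s; wrote %d result files + run_log.txt",
      as.numeric(difftime(Sys.time(), t0, units = "secs")),
      length(result_manifest))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(grid = grid, spec = spec, images = images, features = features,
                 trials = trials, awareness = aware, expression = expr,
                 same_expression = same,
                 correlations = list(left_right = corr_lr,
                                     awareness_vs_expression = corr_ae,
                                     significant_subset = corr_sig),
                 behavior = behav, bias = bias,
                 fixed = list(happy_vs_angry = fixed_ha, happy_all = fixed_h),
                 manifest = result_manifest, log = log_lines))
}
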