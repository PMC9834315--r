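# Shared small fixtures, built in code. Sizes are kept small so the whole
# suite runs comfortably on one CPU; the vignette states the scales used.

small_grid <- function() build_grid(8, 4, 64)

tiny_ensemble_config <- function(...) {
  ensemble_config(k_folds = 3, models_per_method = 3, control_reps = 4,
                  filter_sizes = c(2, 3, 4), wrapper_cap = 3, wrapper_pool = 6,
                  inner_folds = 2, ...)
}

# stimulus set + features on the small grid, with class signatures
small_study <- function(n_per_class = 12, magnitude = 0.35, seed = 42) {
  g <- small_grid()
  deltas <- expression_delta_spec(g, magnitude)
  spec <- wedge_energy_spec(g, class_deltas = deltas)
  imgs <- make_stimulus_set(spec, g, n_per_class = n_per_class, seed = seed)
  feats <- extract_feature_table(imgs, g)
  list(grid = g, spec = spec, deltas = deltas, images = imgs, features = feats,
       signal_wedges = attr(deltas, "signal_wedges"))
}

# labeled feature rows with a clean linearly separable 2-class signal in
# the first `n_signal` columns, the rest N(0,1) noise
separable_rows <- function(n_per_class = 20, n_features = 10, n_signal = 1,
                           gap = 4, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    X <- matrix(rnorm(n * n_features), n, n_features)
    y <- rep(c("a", "b"), each = n_per_class)
    X[y == "b", seq_len(n_signal)] <- X[y == "b", seq_len(n_signal)] + gap
    colnames(X) <- sprintf("v%02d", seq_len(n_features))
    dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(label = factor(y)))
  })
}

# trial table + responses driven by given wedges at a given beta
driven_trials <- function(study, beta, trials_per_condition = 8,
                          driver = NULL, lapse = 0, seed = 7) {
  driver <- driver %||% horizontal_axis_wedges(study$grid, sf_bands = 4:6)
  model <- response_model(driver, beta = beta, lapse = lapse)
  trials <- make_trial_table(study$images, trials_per_condition, seed = seed)
  simulate_responses(trials, study$features, model, seed = seed + 1)
}

`%||%` <- rlang::`%||%`

perms3 <- function() {
  list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
}
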