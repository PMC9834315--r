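#' Configure the ensemble feature-selection decoder
#'
#' Defaults reproduce the reference design: 10 stratified folds, four
#' selection methods (filter, wrapper, random, pseudo-random) with 10
#' models each per fold (400 model runs), and 25 shuffled-label control
#' models per fold x method (1000 chance performances).
#'
#' @param k_folds Outer stratified folds (default 10).
#' @param models_per_method Models per selection method per fold (default 10).
#' @param control_reps Shuffled-label control models per fold x method
#'   (default 25).
#' @param filter_sizes Sizes of the nested top-k filter models; `NULL`
#'   (default) uses 3, 6, ..., 30 capped at the number of features.
#' @param wrapper_cap Maximum features a wrapper model may include.
#' @param wrapper_pool Stepwise candidates: the wrapper searches the top
#'   `wrapper_pool` chi-square-ranked features of its (resampled) training
#'   data.
#' @param inner_folds Inner CV folds used by the wrapper (default 3).
#' @param chi_bins Quantile bins for the chi-square filter score.
#' @param null_resamples Resampled null means per tested-count when scoring
#'   relevance (default 1000, i.e. significance at p < 0.001).
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(k_folds = 10, models_per_method = 10, control_reps = 25,
                            filter_sizes = NULL, wrapper_cap = 10, wrapper_pool = 24,
                            inner_folds = 3, chi_bins = 10, null_resamples = 1000) {
  stopifnot(k_folds >= 2, models_per_method >= 1, control_reps >= 1,
            wrapper_cap >= 1, inner_folds >= 2, chi_bins >= 2, null_resamples >= 1)
  structure(list(k_folds = k_folds, models_per_method = models_per_method,
                 control_reps = control_reps, filter_sizes = filter_sizes,
                 wrapper_cap = wrapper_cap, wrapper_pool = wrapper_pool,
                 inner_folds = inner_folds, chi_bins = chi_bins,
                 null_resamples = null_resamples),
            class = "ensemble_config")
}

#' Rank features by chi-square association with the class labels
#'
#' Each feature is discretized into quantile bins on the supplied data and
#' scored by the chi-square statistic of the bin x class contingency table
#' (expected counts from the margins). Constant features score 0. Ties are
#' broken by feature order, so the ranking is deterministic.
#'
#' @param X Numeric matrix (rows = observations, columns = features) or a
#'   data frame of numeric columns.
#' @param y Class labels (>= 2 classes present).
#' @param n_bins Number of quantile bins (default 10).
#' @return A tibble `feature`, `score`, sorted by descending score.
#' @export
chi_square_rank <- function(X, y, n_bins = 10) {
  X <- as.matrix(X)
  y <- factor(y)
  if (any(table(y) == 0) || nlevels(y) < 2) {
    abort("need >= 2 classes with at least one row each",
          class = "firstsight_data_error")
  }
  B <- quantile_bins(X, n_bins)
  scores <- chi_scores_from_bins(B, y)
  ord <- order(-scores, seq_along(scores))
  tibble::tibble(feature = colnames(X)[ord] %||% as.character(ord),
                 index = ord, score = scores[ord])
}

# Integer quantile-bin codes per feature (0 = constant feature). The bins
# depend on X only, so they can be computed once and reused across many
# label vectors (in particular the shuffled-label controls).
quantile_bins <- function(X, n_bins) {
  X <- as.matrix(X)
  apply(X, 2, function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) return(rep(0L, length(x)))
    as.integer(cut(x, breaks = br, include.lowest = TRUE))
  })
}

chi_scores_from_bins <- function(B, y) {
  y <- factor(y)
  yi <- as.integer(y)
  nc <- nlevels(y)
  n <- length(yi)
  vapply(seq_len(ncol(B)), function(j) {
    b <- B[, j]
    if (b[1] == 0L && all(b == 0L)) return(0)
    nb <- max(b)
    O <- matrix(tabulate(b + nb * (yi - 1L), nbins = nb * nc), nrow = nb)
    O <- O[rowSums(O) > 0, , drop = FALSE]
    if (nrow(O) < 2) return(0)
    E <- outer(rowSums(O), colSums(O)) / n
    sum((O - E)^2 / E)
  }, numeric(1))
}

chi_square_score <- function(x, y, n_bins) {
  chi_scores_from_bins(quantile_bins(matrix(x, ncol = 1), n_bins), y)[1]
}

#' Fit a linear SVM on selected features and score it on held-out data
#'
#' Features are standardized by the training-split mean and SD; selected
#' features with zero training variance are dropped (an error is raised if
#' none survive). The classifier is a linear-kernel SVM with cost 1
#' (one-vs-one for three classes). Returns the fraction of correct test
#' predictions.
#'
#' @param X_train,X_test Numeric feature matrices.
#' @param y_train,y_test Class labels.
#' @param selected Integer or character indices of the features to use.
#' @return Fraction correct in `[0, 1]`.
#' @export
fit_eval <- function(X_train, y_train, X_test, y_test, selected) {
  if (length(selected) == 0) {
    abort("selected feature set is empty", class = "firstsight_degenerate_model")
  }
  if (nrow(X_train) == 0) {
    abort("empty training split", class = "firstsight_data_error")
  }
  Xtr <- as.matrix(X_train)[, selected, drop = FALSE]
  Xte <- as.matrix(X_test)[, selected, drop = FALSE]
  mu <- colMeans(Xtr)
  sig <- apply(Xtr, 2, sd)
  keep <- sig > 0
  if (!any(keep)) {
    abort("all selected features have zero training variance",
          class = "firstsight_degenerate_model")
  }
  Xtr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, mu[keep]), 2, sig[keep], "/")
  Xte <- sweep(sweep(Xte[, keep, drop = FALSE], 2, mu[keep]), 2, sig[keep], "/")
  y_train <- factor(y_train)
  if (nlevels(droplevels(y_train)) < 2) {
    only <- as.character(droplevels(y_train)[1])
    return(mean(as.character(y_test) == only))
  }
  fit <- e1071::svm(Xtr, droplevels(y_train), kernel = "linear", cost = 1,
                    scale = FALSE)
  pred <- predict(fit, Xte)
  mean(as.character(pred) == as.character(y_test))
}

# Pooled inner-CV accuracy of an SVM on the given feature subset.
inner_cv_accuracy <- function(X, y, fold, selected) {
  correct <- 0
  total <- 0
  for (f in sort(unique(fold))) {
    te <- fold == f
    acc <- fit_eval(X[!te, , drop = FALSE], y[!te],
                    X[te, , drop = FALSE], y[te], selected)
    correct <- correct + acc * sum(te)
    total <- total + sum(te)
  }
  correct / total
}

#' Forward stepwise (wrapper) feature selection
#'
#' Starting from the empty set, repeatedly adds the candidate feature that
#' maximizes inner cross-validated SVM accuracy on the training split;
#' stops when no candidate improves the accuracy or when `cap` features
#' have been included. Candidates are the top `pool` chi-square-ranked
#' features of the training data, which keeps the stepwise search
#' tractable without changing its performance-driven semantics. The
#' recorded accuracy path is non-decreasing by construction.
#'
#' @param X_train,y_train Training split.
#' @param cap Maximum number of features to include.
#' @param inner_folds Inner stratified CV folds.
#' @param pool Number of chi-square-ranked candidates searched.
#' @param seed Integer seed (inner fold assignment).
#' @param n_bins Quantile bins for the candidate ranking.
#' @return List with `selected` (integer indices, in inclusion order) and
#'   `path_accuracy` (inner-CV accuracy after each inclusion).
#' @export
wrapper_select <- function(X_train, y_train, cap = 10, inner_folds = 3,
                           pool = 24, seed = 1, n_bins = 10) {
  stopifnot(cap >= 1)
  X_train <- as.matrix(X_train)
  if (nrow(X_train) == 0) {
    abort("empty training split", class = "firstsight_data_error")
  }
  candidates <- chi_square_rank(X_train, y_train, n_bins)$index
  candidates <- candidates[seq_len(min(pool, length(candidates)))]
  # drop constant candidates up front
  candidates <- candidates[apply(X_train[, candidates, drop = FALSE], 2, sd) > 0]
  if (length(candidates) == 0) {
    abort("no non-constant candidate features", class = "firstsight_degenerate_model")
  }
  fold <- with_stream(seed, "wrapper_inner", stratified_folds(y_train, inner_folds))
  selected <- integer(0)
  path <- numeric(0)
  best <- -Inf
  while (length(selected) < cap) {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    accs <- vapply(remaining, function(j) {
      inner_cv_accuracy(X_train, y_train, fold, c(selected, j))
    }, numeric(1))
    top <- remaining[which.max(accs)] # which.max: first max, id order tiebreak
    if (max(accs) > best || length(selected) == 0) {
      best <- max(accs)
      selected <- c(selected, top)
      path <- c(path, best)
    } else {
      break
    }
  }
  list(selected = selected, path_accuracy = path)
}

# Stratified subsample (without replacement) used to diversify the
# wrapper's stepwise path across models. Sampling with replacement would
# put duplicate rows on both sides of the wrapper's inner CV splits,
# inflating the apparent value of noise features.
wrapper_resample <- function(y, frac = 0.7) {
  idx <- unlist(lapply(split(seq_along(y), y), function(i) {
    sample(i, max(2, round(frac * length(i))))
  }), use.names = FALSE)
  sort(idx)
}

#' Run the ensemble of selection models with its shuffled-label controls
#'
#' Over `k_folds` stratified folds, four families of linear-SVM models are
#' trained per fold: `models_per_method` filter models (nested top-k sets
#' from the chi-square ranking of the training split), wrapper models
#' (stepwise selection on seeded stratified subsamples of the training
#' split), random models (feature sets drawn uniformly, sizes
#' matched to the filter models), and pseudo-random models (sizes matched,
#' drawn from the features unused by the fold's filter and wrapper
#' selections). For every fold x method, `control_reps` control models
#' re-run that method's selection on label-shuffled training data, train
#' on the shuffled labels and are scored against the true test labels,
#' yielding the pool of chance performances (1000 at the defaults).
#'
#' @param rows Labeled feature tibble from [make_trial_rows()] (feature
#'   columns plus a `label` column).
#' @param config An [ensemble_config()].
#' @param seed Integer master seed; everything downstream is derived from
#'   it, so identical input + seed reproduce the result exactly.
#' @return An `ensemble_result`: tibbles `runs` (400 rows at defaults) and
#'   `controls` (1000 rows), plus the config, seed and feature ids.
#'   Feed it to [score_relevance()] for per-feature weights/significance.
#' @export
run_ensemble <- function(rows, config = ensemble_config(), seed = 1) {
  stopifnot(inherits(config, "ensemble_config"))
  feat_cols <- feature_columns(rows)
  X <- as.matrix(rows[, feat_cols])
  y <- factor(as.character(rows$label))
  if (any(table(y) < 2)) {
    abort("need >= 2 rows per class", class = "firstsight_data_error")
  }
  if (any(table(y) < config$k_folds)) {
    abort("every class needs at least k_folds rows", class = "firstsight_config_error")
  }
  p <- ncol(X)
  sizes <- config$filter_sizes
  if (is.null(sizes)) {
    sizes <- unique(pmin(seq(3, 30, by = 3), p))
    sizes <- rep_len(sizes, config$models_per_method)
  }
  sizes <- rep_len(pmin(sizes, p), config$models_per_method)

  fold <- with_stream(seed, "outer_folds", stratified_folds(y, config$k_folds))
  methods <- c("filter", "wrapper", "random", "pseudo_random")
  runs <- list()
  controls <- list()

  for (f in seq_len(config$k_folds)) {
    te <- fold == f
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y[!te]
    Xte <- X[te, , drop = FALSE]
    yte <- y[te]
    fold_seed <- derive_seed(seed, paste0("fold_", f))

    bins_tr <- quantile_bins(Xtr, config$chi_bins)
    sc <- chi_scores_from_bins(bins_tr, ytr)
    rank_tr <- order(-sc, seq_along(sc))
    filter_sel <- lapply(sizes, function(k) rank_tr[seq_len(k)])

    wrapper_sel <- lapply(seq_len(config$models_per_method), function(j) {
      with_stream(fold_seed, paste0("wrapper_boot_", j), {
        bi <- wrapper_resample(ytr)
        wrapper_select(Xtr[bi, , drop = FALSE], ytr[bi],
                       cap = config$wrapper_cap, inner_folds = config$inner_folds,
                       pool = config$wrapper_pool,
                       seed = derive_seed(fold_seed, paste0("wrapper_inner_", j)),
                       n_bins = config$chi_bins)$selected
      })
    })

    used <- unique(c(unlist(filter_sel), unlist(wrapper_sel)))
    # random/pseudo draws are restricted to features that vary in the
    # training split (empty wedges are constant zero and untrainable)
    varying <- which(apply(Xtr, 2, sd) > 0)
    random_sel <- with_stream(fold_seed, "random_models", {
      lapply(pmin(sizes, length(varying)), function(k) sample(varying, k))
    })
    pseudo_sel <- with_stream(fold_seed, "pseudo_models", {
      lapply(pmin(sizes, length(varying)), function(k) {
        draw_pseudo_random(varying, k, used, unlist(wrapper_sel))
      })
    })

    sel_by_method <- list(filter = filter_sel, wrapper = wrapper_sel,
                          random = random_sel, pseudo_random = pseudo_sel)
    for (m in methods) {
      sels <- sel_by_method[[m]]
      perfs <- vapply(sels, function(s) fit_eval(Xtr, ytr, Xte, yte, s), numeric(1))
      runs[[paste(f, m)]] <- tibble::tibble(
        fold = f, method = m, replicate = seq_along(sels), is_control = FALSE,
        performance = perfs, selected = lapply(sels, as.integer))
      ctrl <- control_models(Xtr, ytr, Xte, yte, m, sizes, used,
                             unlist(wrapper_sel), varying, bins_tr, config, fold_seed)
      controls[[paste(f, m)]] <- tibble::tibble(
        fold = f, method = m, replicate = seq_len(config$control_reps),
        is_control = TRUE, performance = ctrl$performance, selected = ctrl$selected)
    }
  }

  structure(list(
    runs = dplyr::bind_rows(runs),
    controls = dplyr::bind_rows(controls),
    feature_ids = feat_cols,
    n_classes = nlevels(y),
    config = config,
    seed = seed
  ), class = "ensemble_result")
}

draw_pseudo_random <- function(pool_features, k, used, wrapper_used) {
  unused <- setdiff(pool_features, used)
  if (length(unused) >= k) return(sample(unused, k))
  # fallback: fill the remainder from features unused by the wrapper only
  fallback <- setdiff(setdiff(pool_features, wrapper_used), unused)
  if (length(unused) + length(fallback) >= k) {
    return(c(unused, sample(fallback, k - length(unused))))
  }
  sample(pool_features, min(k, length(pool_features))) # degenerate tiny-feature case
}

# Shuffled-label control models for one fold x method: selection is re-run
# on the shuffled labels, the SVM is trained on them, and evaluated against
# the true test labels, so the pool estimates chance decoding with the
# method's selection optimism preserved.
control_models <- function(Xtr, ytr, Xte, yte, method, sizes, used,
                           wrapper_used, varying, bins_tr, config, fold_seed) {
  perfs <- numeric(config$control_reps)
  sels <- vector("list", config$control_reps)
  for (r in seq_len(config$control_reps)) {
    res <- with_stream(fold_seed, paste0("control_", method, "_", r), {
      ys <- sample(ytr)
      k <- min(sizes[(r - 1) %% length(sizes) + 1], length(varying))
      sel <- switch(method,
        filter = {
          scs <- chi_scores_from_bins(bins_tr, ys)
          order(-scs, seq_along(scs))[seq_len(k)]
        },
        wrapper = {
          bi <- wrapper_resample(ys)
          wrapper_select(Xtr[bi, , drop = FALSE], ys[bi],
                         cap = config$wrapper_cap, inner_folds = config$inner_folds,
                         pool = config$wrapper_pool,
                         seed = derive_seed(fold_seed, paste0("ctrl_wrap_", r)),
                         n_bins = config$chi_bins)$selected
        },
        random = sample(varying, k),
        pseudo_random = draw_pseudo_random(varying, k, used, wrapper_used))
      list(sel = as.integer(sel), perf = fit_eval(Xtr, ys, Xte, yte, sel))
    })
    perfs[r] <- res$perf
    sels[[r]] <- res$sel
  }
  list(performance = perfs, selected = sels)
}

#' Score per-feature relevance against a tested-count-matched null
#'
#' A feature's weight is the mean test performance of every (real) model
#' that included it; a feature never tested gets weight 0. Because
#' features tested few times have noisier means (regression to the mean),
#' the significance threshold is matched to the tested count: for each
#' observed count m, `null_resamples` means of m performances drawn with
#' replacement from the control pool are computed, and the feature is
#' significant only if its weight exceeds the maximum of that matched null
#' (empirical p below 1 / `null_resamples`; p < 0.001 at the default).
#'
#' @param result An [run_ensemble()] result with non-empty controls.
#' @param null_resamples Resampled null means per tested count; defaults
#'   to the config value (1000).
#' @param seed Seed for the null resampling; defaults to the ensemble seed.
#' @return The `ensemble_result` with a `relevance` tibble added:
#'   `feature_id`, `times_tested`, `weight`, `null_max`, `significant`.
#' @export
score_relevance <- function(result, null_resamples = NULL, seed = NULL) {
  stopifnot(inherits(result, "ensemble_result"))
  if (nrow(result$controls) == 0 || nrow(result$runs) == 0) {
    abort("ensemble result has empty runs or controls", class = "firstsight_state_error")
  }
  null_resamples <- null_resamples %||% result$config$null_resamples
  seed <- seed %||% result$seed
  p <- length(result$feature_ids)
  idx <- unlist(result$runs$selected)
  perf_rep <- rep(result$runs$performance, lengths(result$runs$selected))
  times_tested <- tabulate(idx, nbins = p)
  weight_sum <- numeric(p)
  acc <- rowsum(perf_rep, idx)
  weight_sum[as.integer(rownames(acc))] <- acc[, 1]
  weight <- ifelse(times_tested > 0, weight_sum / pmax(times_tested, 1), 0)

  ctrl <- result$controls$performance
  null_max <- rep(NA_real_, p)
  with_stream(seed, "relevance_null", {
    for (m in sort(unique(times_tested[times_tested > 0]))) {
      draws <- matrix(sample(ctrl, null_resamples * m, replace = TRUE),
                      nrow = null_resamples)
      null_max[times_tested == m] <- max(rowMeans(draws))
    }
  })
  result$relevance <- tibble::tibble(
    feature_id = result$feature_ids,
    times_tested = as.integer(times_tested),
    weight = weight,
    null_max = null_max,
    significant = times_tested > 0 & !is.na(null_max) & weight > null_max
  )
  result
}

#' Run the full decoder: ensemble plus relevance scoring
#'
#' @inheritParams run_ensemble
#' @param null_resamples Passed to [score_relevance()].
#' @return A scored `ensemble_result` (with `relevance`).
#' @export
decode_features <- function(rows, config = ensemble_config(), seed = 1,
                            null_resamples = NULL) {
  score_relevance(run_ensemble(rows, config, seed), null_resamples, seed)
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d model runs, %d controls, %d features, %d classes\n",
              nrow(x$runs), nrow(x$controls), length(x$feature_ids), x$n_classes))
  if (!is.null(x$relevance)) {
    cat(sprintf("  significant features: %d of %d\n",
                sum(x$relevance$significant), nrow(x$relevance)))
  }
  invisible(x)
}
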