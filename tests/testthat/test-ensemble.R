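test_that("chi-square scores equal the explicit contingency computation", {
  # 12-row two-class example with a two-valued feature, worked by hand:
  # bins {1}, {2}; happy: 4 ones, 2 twos; angry: 2 ones, 4 twos.
  x <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 1, 1)
  y <- rep(c("happy", "angry"), each = 6)
  O <- table(cut(x, breaks = c(1, 1.5, 2), include.lowest = TRUE), y)
  E <- outer(rowSums(O), colSums(O)) / 12
  expected <- sum((O - E)^2 / E) # = 4/3
  expect_equal(expected, 4 / 3)
  rk <- chi_square_rank(cbind(f = x), y)
  expect_equal(rk$score[1], expected)
})

test_that("chi-square ranking places associated features above permuted ones", {
  withr::with_seed(5, {
    y <- rep(c("a", "b"), each = 30)
    perfect <- as.numeric(y == "a") # two distinct values, perfect association
    noise <- sample(perfect) # same values, independence by permutation
    X <- cbind(n1 = rnorm(60), perfect = perfect, shuffled = noise)
    rk <- chi_square_rank(X, y)
    expect_equal(rk$feature[1], "perfect")
    expect_gt(rk$score[rk$feature == "perfect"], rk$score[rk$feature == "shuffled"])
  })
  expect_error(chi_square_rank(cbind(1:4), rep("a", 4)),
               class = "firstsight_data_error")
})

test_that("SVM evaluation is exact on separable data and at chance on shuffled labels", {
  rows <- separable_rows(n_per_class = 15, n_features = 6, gap = 6)
  X <- as.matrix(rows[, 1:6])
  y <- rows$label
  expect_equal(fit_eval(X, y, X, y, 1:6), 1.0)

  accs <- vapply(1:60, function(i) {
    withr::with_seed(i, {
      ys <- sample(y)
      fit_eval(X[1:20, ], ys[1:20], X[21:30, ], ys[21:30], 1:6)
    })
  }, numeric(1))
  se <- 0.5 / sqrt(60 * 10)
  expect_lt(abs(mean(accs) - 0.5), 4 * se)

  Xc <- X
  Xc[, 2] <- 5 # constant features are dropped, others keep working
  expect_equal(fit_eval(Xc, y, Xc, y, 1:6), 1.0)
  expect_error(fit_eval(Xc[, 2, drop = FALSE], y, Xc[, 2, drop = FALSE], y, 1),
               class = "firstsight_degenerate_model")
  expect_error(fit_eval(X, y, X, y, integer(0)),
               class = "firstsight_degenerate_model")
})

test_that("wrapper selects a perfect feature first and stops; cap binds on noise", {
  rows <- separable_rows(n_per_class = 12, n_features = 8, n_signal = 1, gap = 8)
  X <- as.matrix(rows[, 1:8])
  sel <- wrapper_select(X, rows$label, cap = 5, inner_folds = 2, pool = 8, seed = 3)
  expect_equal(sel$selected[1], 1L)
  expect_equal(sel$path_accuracy[1], 1.0)
  expect_length(sel$selected, 1) # nothing can improve on 1.0

  withr::with_seed(9, {
    Xn <- matrix(rnorm(40 * 10), 40, 10)
    yn <- rep(c("a", "b"), each = 20)
  })
  seln <- wrapper_select(Xn, yn, cap = 3, inner_folds = 2, pool = 10, seed = 4)
  expect_lte(length(seln$selected), 3)
})

test_that("wrapper accuracy path is non-decreasing across random problems", {
  for (s in 1:8) {
    withr::with_seed(s, {
      X <- matrix(rnorm(36 * 8), 36, 8)
      X[1:18, 1] <- X[1:18, 1] + 1.2
      y <- rep(c("a", "b"), each = 18)
    })
    path <- wrapper_select(X, y, cap = 4, inner_folds = 2, pool = 8,
                           seed = s)$path_accuracy
    expect_true(all(diff(path) >= 0))
  }
})

test_that("ensemble produces the configured run and control structure, reproducibly", {
  study <- small_study(n_per_class = 8)
  rows <- make_trial_rows(NULL, study$features, "expression")
  cfg <- tiny_ensemble_config()
  res <- run_ensemble(rows, cfg, seed = 21)
  expect_equal(nrow(res$runs), 3 * 4 * 3)
  expect_equal(nrow(res$controls), 3 * 4 * 4)
  expect_setequal(unique(res$runs$method),
                  c("filter", "wrapper", "random", "pseudo_random"))
  all_sel <- unlist(c(res$runs$selected, res$controls$selected))
  expect_true(all(all_sel >= 1 & all_sel <= study$grid$n_wedges))
  expect_true(all(res$runs$performance >= 0 & res$runs$performance <= 1))
  expect_true(all(lengths(res$runs$selected) > 0))

  res2 <- run_ensemble(rows, cfg, seed = 21)
  expect_equal(res, res2)
  res3 <- run_ensemble(rows, cfg, seed = 22)
  expect_false(identical(res$runs$performance, res3$runs$performance))

  expect_error(run_ensemble(rows, ensemble_config(k_folds = 10), seed = 1),
               class = "firstsight_config_error") # classes smaller than k
})

test_that("pseudo-random models avoid the fold's filter and wrapper selections", {
  study <- small_study(n_per_class = 10)
  rows <- make_trial_rows(NULL, study$features, "expression")
  res <- run_ensemble(rows, tiny_ensemble_config(), seed = 31)
  for (f in unique(res$runs$fold)) {
    fold_runs <- res$runs[res$runs$fold == f & !res$runs$is_control, ]
    used <- unique(unlist(fold_runs$selected[fold_runs$method %in% c("filter", "wrapper")]))
    pseudo <- unlist(fold_runs$selected[fold_runs$method == "pseudo_random"])
    expect_lt(mean(pseudo %in% used), 0.5) # overwhelmingly drawn from unused space
  }
})

test_that("relevance weights average performance and respect the matched null", {
  # hand-built ensemble result: controls all at 0.5, two features with known
  # appearance patterns
  res <- structure(list(
    runs = tibble::tibble(
      fold = c(1, 1, 2), method = "random", replicate = 1:3, is_control = FALSE,
      performance = c(0.9, 0.7, 0.2),
      selected = list(c(1L, 2L), 1L, 2L)),
    controls = tibble::tibble(
      fold = 1, method = "random", replicate = 1:50, is_control = TRUE,
      performance = rep(0.5, 50), selected = replicate(50, 1L, simplify = FALSE)),
    feature_ids = c("a", "b", "c"), n_classes = 2,
    config = ensemble_config(null_resamples = 200), seed = 1
  ), class = "ensemble_result")
  rel <- score_relevance(res)$relevance
  expect_equal(rel$weight, c((0.9 + 0.7) / 2, (0.9 + 0.2) / 2, 0))
  expect_equal(rel$times_tested, c(2L, 2L, 0L))
  # degenerate constant control pool: every resampled mean is 0.5
  expect_equal(rel$null_max[1:2], c(0.5, 0.5))
  expect_equal(rel$significant, c(TRUE, TRUE, FALSE))
  expect_false(rel$significant[3]) # untested => never significant

  empty <- res
  empty$controls <- empty$controls[0, ]
  expect_error(score_relevance(empty), class = "firstsight_state_error")
})

test_that("matched null thresholds shrink toward the pool mean as testing deepens", {
  # means of more control draws concentrate, so null_max(m) decreases in m
  res <- structure(list(
    runs = tibble::tibble(
      fold = 1, method = "random", replicate = 1:4, is_control = FALSE,
      performance = rep(0.5, 4),
      selected = list(1L, rep(2L, 1), 3L, 4L)),
    controls = tibble::tibble(
      fold = 1, method = "random", replicate = 1:200, is_control = TRUE,
      performance = withr::with_seed(8, runif(200, 0.2, 0.8)),
      selected = replicate(200, 1L, simplify = FALSE)),
    feature_ids = letters[1:4], n_classes = 2,
    config = ensemble_config(null_resamples = 1000), seed = 2
  ), class = "ensemble_result")
  # force distinct times_tested: 1, 2, 4, 8
  res$runs <- tibble::tibble(
    fold = 1, method = "random", replicate = 1:15, is_control = FALSE,
    performance = rep(0.5, 15),
    selected = c(list(1L), rep(list(2L), 2), rep(list(3L), 4), rep(list(4L), 8)))
  rel <- score_relevance(res)$relevance
  expect_true(all(diff(rel$null_max) < 0))
})

test_that("shuffled-label inputs leave model and control pools indistinguishable", {
  study <- small_study(n_per_class = 10)
  rows <- make_trial_rows(NULL, study$features, "expression")
  real <- c()
  ctrl <- c()
  for (s in 1:3) {
    shuffled <- rows
    shuffled$label <- withr::with_seed(40 + s, sample(shuffled$label))
    res <- run_ensemble(shuffled, tiny_ensemble_config(), seed = 50 + s)
    real <- c(real, res$runs$performance)
    ctrl <- c(ctrl, res$controls$performance)
  }
  p <- stats::wilcox.test(real, ctrl, exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("tidy and glance summarize a scored ensemble", {
  study <- small_study(n_per_class = 8)
  rows <- make_trial_rows(NULL, study$features, "expression")
  res <- decode_features(rows, tiny_ensemble_config(null_resamples = 100), seed = 61)
  rel <- tidy(res)
  expect_named(rel, c("feature_id", "times_tested", "weight", "null_max", "significant"))
  expect_equal(nrow(rel), study$grid$n_wedges)
  g <- glance(res)
  expect_equal(g$n_runs, nrow(res$runs))
  expect_equal(g$chance, 1 / 3)
  expect_equal(g$n_significant, sum(rel$significant))
})
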