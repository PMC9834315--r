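make_trials_manual <- function(left_class, right_class, response_side,
                               subject = "s01") {
  tibble::tibble(
    trial_id = seq_along(left_class), subject = subject,
    condition = mapply(function(a, b) {
      codes <- c(happy = "HA", angry = "AN", neutral = "NE")
      paste(codes[a], codes[b], sep = "-")
    }, left_class, right_class),
    left_image_id = paste0("L", seq_along(left_class)),
    right_image_id = paste0("R", seq_along(left_class)),
    left_class = left_class, right_class = right_class,
    response_side = response_side, rt_seconds = 3
  )
}

test_that("first-percept fractions count class wins over eligible trials", {
  tr <- make_trials_manual(
    left_class  = c("happy", "happy", "angry", "happy", "happy", "neutral"),
    right_class = c("angry", "neutral", "neutral", "angry", "happy", "neutral"),
    response_side = c("left", "left", "right", "left", "left", "right")
  )
  fr <- first_percept_fractions(tr)
  expect_equal(fr$fraction[fr$class == "happy"], 1) # 3/3 eligible wins
  expect_equal(fr$n_eligible[fr$class == "happy"], 3) # same-class rows excluded
  expect_equal(fr$fraction[fr$class == "angry"], 0)

  # swapping sides and responses together leaves fractions unchanged
  sw <- tr
  sw[, c("left_class", "right_class")] <- tr[, c("right_class", "left_class")]
  sw$response_side <- ifelse(tr$response_side == "left", "right", "left")
  expect_equal(first_percept_fractions(sw)$fraction, fr$fraction)
})

test_that("for one subject with a balanced design the class fractions average 0.5", {
  study <- small_study(n_per_class = 6)
  for (seed in 1:5) {
    tr <- driven_trials(study, beta = 2, trials_per_condition = 8, seed = seed)
    fr <- first_percept_fractions(tr)
    expect_equal(mean(fr$fraction), 0.5, tolerance = 1e-12)
  }
})

test_that("friedman statistic matches closed forms and stats::friedman.test", {
  same <- matrix(rep(c(0.4, 0.4, 0.4), 6), ncol = 3, byrow = TRUE)
  res <- friedman_rank_test(same)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  # perfect concordance over n = 10 subjects, k = 3: chi2 = n (k - 1) = 20
  conc <- matrix(rep(c(0.2, 0.5, 0.8), 10), ncol = 3, byrow = TRUE)
  expect_equal(friedman_rank_test(conc)$chi2, 20)

  withr::with_seed(31, {
    m <- matrix(runif(21), ncol = 3)
  })
  ours <- friedman_rank_test(m)
  ref <- stats::friedman.test(m)
  expect_equal(ours$chi2, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_error(friedman_rank_test(matrix(c(1, NA, 2, 3, 4, 5), 2)),
               class = "firstsight_data_error")
})

test_that("friedman p approximates the exhaustive within-row permutation null", {
  m <- matrix(c(0.30, 0.55, 0.60,
                0.25, 0.50, 0.45,
                0.40, 0.60, 0.70,
                0.35, 0.30, 0.65), ncol = 3, byrow = TRUE)
  obs <- friedman_rank_test(m)
  perms <- perms3()
  grid_idx <- expand.grid(1:6, 1:6, 1:6, 1:6)
  stats_all <- apply(grid_idx, 1, function(ix) {
    mp <- m
    for (i in 1:4) mp[i, ] <- m[i, perms[[ix[i]]]]
    friedman_rank_test(mp)$chi2
  })
  p_exact <- mean(stats_all >= obs$chi2 - 1e-12)
  expect_lt(abs(obs$p - p_exact), 0.02)
})

test_that("wilcoxon signed-rank matches sign-flip enumeration and wilcox.test", {
  x <- c(0.62, 0.55, 0.70, 0.48, 0.66, 0.58, 0.75, 0.51)
  y <- c(0.50, 0.52, 0.58, 0.55, 0.52, 0.49, 0.60, 0.47)
  res <- wilcoxon_signed_rank(x, y)
  d <- x - y
  r <- rank(abs(d))
  expect_equal(res$W, sum(r[d > 0]))

  # exact two-sided p from all 2^8 sign assignments
  n <- length(d)
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% r
  p_exact <- mean(abs(W_all - mu) >= abs(res$W - mu) - 1e-12)
  expect_lt(abs(res$p - p_exact), 0.01)

  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)

  # maximal one-sided case and the degenerate contract
  res2 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(res2$W, 15)
  expect_gt(res2$z, 0)
  expect_error(wilcoxon_signed_rank(x, x), class = "firstsight_degenerate_test")
})

test_that("behavior summary assembles fractions and group tests", {
  study <- small_study(n_per_class = 6)
  trs <- dplyr::bind_rows(lapply(1:6, function(s) {
    tr <- driven_trials(study, beta = 1, trials_per_condition = 4, seed = 100 + s)
    tr$subject <- sprintf("s%02d", s)
    tr
  }))
  bs <- behavior_summary(trs)
  expect_equal(nrow(bs$fractions), 18)
  expect_s3_class(bs$friedman, "tbl_df")
  expect_equal(nrow(bs$pairwise), 3)
  expect_true(all(bs$pairwise$p <= 1, na.rm = TRUE))
})

test_that("bias prediction is perfect for a fully biased subject", {
  study <- small_study(n_per_class = 6)
  trials <- make_trial_table(study$images, 10, seed = 3)
  # always report the happy side when present, else the angry side
  has_happy_left <- trials$left_class == "happy"
  has_happy_right <- trials$right_class == "happy"
  trials$response_side <- ifelse(has_happy_left, "left",
                          ifelse(has_happy_right, "right",
                          ifelse(trials$left_class == "angry", "left", "right")))
  trials$rt_seconds <- 3
  res <- bias_cv_predict(trials, k_folds = 5, n_permutations = 400, seed = 2)
  expect_equal(res$overall_accuracy, 1)
  expect_lte(res$perm_p, 0.01)
  fx <- fixed_class_predict(trials, "happy", c("happy", "angry"),
                            n_permutations = 400, seed = 2)
  expect_equal(fx$accuracy, 1)
})

test_that("bias prediction folds cover the different-class trials evenly", {
  study <- small_study(n_per_class = 6)
  tr <- driven_trials(study, beta = 1, trials_per_condition = 48, seed = 5)
  res <- bias_cv_predict(tr, k_folds = 10, n_permutations = 50, seed = 1)
  expect_equal(res$n_trials, 144)
  expect_length(res$fold_accuracies, 10)
  expect_equal(glance(res)$overall_accuracy, res$overall_accuracy)
})

test_that("cross-validated bias accuracy approaches the pair-bias optimum", {
  # condition-stationary responses: reference class first w.p. 0.8 in every
  # pair; expected asymptotic accuracy = 0.8
  withr::with_seed(77, {
    accs <- replicate(6, {
      lc <- rep(c("happy", "happy", "angry"), each = 60)
      rc <- rep(c("angry", "neutral", "neutral"), each = 60)
      ref_left <- runif(180) < 0.5
      l <- ifelse(ref_left, pmin(lc, rc), pmax(lc, rc))
      r <- ifelse(ref_left, pmax(lc, rc), pmin(lc, rc))
      ref_first <- runif(180) < 0.8
      resp <- ifelse(ref_first == ref_left, "left", "right")
      tr <- make_trials_manual(l, r, resp)
      bias_cv_predict(tr, k_folds = 10, n_permutations = 10, seed = 1)$overall_accuracy
    })
    expect_lt(abs(mean(accs) - 0.8), 0.05)
  })
})

test_that("fixed-class accuracy sits at chance for unbiased responses", {
  study <- small_study(n_per_class = 6)
  accs <- vapply(1:20, function(s) {
    tr <- driven_trials(study, beta = 0, trials_per_condition = 8, seed = 200 + s)
    fixed_class_predict(tr, "happy", n_permutations = 10, seed = s)$accuracy
  }, numeric(1))
  se <- 0.5 / sqrt(20 * 32)
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
  tr <- driven_trials(study, beta = 0, trials_per_condition = 2, seed = 1)
  expect_error(fixed_class_predict(tr, "happy", c("angry", "neutral")),
               class = "firstsight_data_error")
})
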