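trial_first_class <- function(trials) {
  ifelse(trials$response_side == "left", trials$left_class, trials$right_class)
}

different_class_trials <- function(trials) {
  trials[trials$left_class != trials$right_class, , drop = FALSE]
}

#' Per-subject first-percept fractions by image class
#'
#' For every class, the fraction of different-class trials containing it
#' in which it was reported first. Same-class conditions are excluded
#' (neither side "wins" a class comparison there). With equal trial counts
#' per condition the three fractions of one subject average to 0.5: every
#' eligible trial has exactly one winning class.
#'
#' @param trials Trial tibble with responses set; a `subject` column is
#'   added (single synthetic subject) if absent.
#' @return Tibble `subject`, `class`, `n_eligible`, `fraction`. Classes
#'   with no eligible trials get `fraction = NA` and a warning.
#' @export
first_percept_fractions <- function(trials) {
  if (anyNA(trials$response_side)) {
    abort("responses are unset", class = "firstsight_data_error")
  }
  if (is.null(trials$subject)) trials$subject <- "s01"
  diff <- different_class_trials(trials)
  diff$first_class <- trial_first_class(diff)
  out <- tidyr::expand_grid(subject = unique(trials$subject), class = CLASS_LABELS)
  stats_tbl <- dplyr::bind_rows(lapply(seq_len(nrow(out)), function(i) {
    sub <- out$subject[i]
    cl <- out$class[i]
    elig <- diff[diff$subject == sub &
                   (diff$left_class == cl | diff$right_class == cl), , drop = FALSE]
    tibble::tibble(subject = sub, class = cl, n_eligible = nrow(elig),
                   fraction = if (nrow(elig) > 0) mean(elig$first_class == cl) else NA_real_)
  }))
  if (anyNA(stats_tbl$fraction)) {
    warn("some subject x class cells have no eligible trials (fraction = NA)")
  }
  stats_tbl
}

#' Friedman rank test for within-subject class differences
#'
#' Nonparametric one-way repeated-measures ANOVA on ranks: each subject's
#' k condition values are ranked (midranks for ties), and the chi-square
#' statistic with k - 1 degrees of freedom is computed with the standard
#' tie correction. Identical values across conditions for every subject
#' give chi-square 0 and p = 1.
#'
#' @param mat Numeric matrix or data frame, subjects in rows, conditions
#'   (e.g. the 3 class fractions) in columns; no missing cells.
#' @return A one-row tibble: `chi2`, `df`, `p`, `n`.
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) abort("missing cells", class = "firstsight_data_error")
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) {
    abort("need >= 2 subjects and >= 2 conditions", class = "firstsight_data_error")
  }
  R <- t(apply(mat, 1, rank))
  Rj <- colSums(R)
  chi2 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(mat, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  C <- 1 - ties / (n * k * (k^2 - 1))
  chi2 <- if (C > 0) chi2 / C else 0
  df <- k - 1
  tibble::tibble(chi2 = chi2, df = df,
                 p = pchisq(chi2, df, lower.tail = FALSE), n = n)
}

#' Wilcoxon signed-rank test (normal approximation, tie-corrected)
#'
#' Zero differences are discarded (Wilcoxon's original convention), tied
#' absolute differences get midranks, W is the sum of ranks of positive
#' differences, and the signed normal deviate z uses the tie-corrected
#' variance without continuity correction. Two-tailed p.
#'
#' @param x,y Equal-length paired observations (e.g. per-subject
#'   first-percept fractions for two classes).
#' @return A one-row tibble: `z`, `W`, `p`, `n` (pairs after zero
#'   removal).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "firstsight_data_error")
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    abort("all differences are zero; test degenerate",
          class = "firstsight_degenerate_test")
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu) / sqrt(sigma2)
  tibble::tibble(z = z, W = W, p = min(1, 2 * pnorm(-abs(z))), n = n)
}

#' Behavioral summary: fractions, Friedman ANOVA, pairwise Wilcoxon
#'
#' @param trials Multi-subject trial tibble with responses set.
#' @return A `behavior_summary`: `fractions` tibble, `friedman` row, and
#'   `pairwise` tibble (one Wilcoxon row per class pair). Friedman and
#'   pairwise tests require >= 2 subjects and are `NULL` otherwise.
#' @export
behavior_summary <- function(trials) {
  fr <- first_percept_fractions(trials)
  wide <- tidyr::pivot_wider(fr[, c("subject", "class", "fraction")],
                             names_from = "class", values_from = "fraction")
  mat <- as.matrix(wide[, CLASS_LABELS])
  friedman <- NULL
  pairwise <- NULL
  if (nrow(mat) >= 2 && !anyNA(mat)) {
    friedman <- friedman_rank_test(mat)
    pairs <- utils::combn(CLASS_LABELS, 2, simplify = FALSE)
    pairwise <- dplyr::bind_rows(lapply(pairs, function(pr) {
      res <- tryCatch(wilcoxon_signed_rank(mat[, pr[1]], mat[, pr[2]]),
                      firstsight_degenerate_test = function(e) {
                        tibble::tibble(z = NA_real_, W = NA_real_, p = NA_real_, n = 0L)
                      })
      dplyr::bind_cols(tibble::tibble(class_a = pr[1], class_b = pr[2]), res)
    }))
  }
  structure(list(fractions = fr, friedman = friedman, pairwise = pairwise),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary>\n")
  agg <- dplyr::summarise(dplyr::group_by(x$fractions, .data$class),
                          fraction = mean(.data$fraction, na.rm = TRUE))
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-8s first-percept fraction %.3f\n", agg$class[i], agg$fraction[i]))
  }
  if (!is.null(x$friedman)) {
    cat(sprintf("  Friedman chi2(%d) = %.2f, p = %.4f (n = %d subjects)\n",
                x$friedman$df, x$friedman$chi2, x$friedman$p, x$friedman$n))
  }
  invisible(x)
}

# Permute response sides within condition: returns n x P matrix of
# "responded left" indicators under the within-condition exchange null.
permute_response_left <- function(resp_left, condition, n_perm) {
  blocks <- split(seq_along(resp_left), condition)
  out <- matrix(0L, length(resp_left), n_perm)
  for (p in seq_len(n_perm)) {
    col <- integer(length(resp_left))
    for (b in blocks) col[b] <- resp_left[sample(b)]
    out[, p] <- col
  }
  out
}

#' Cross-validated prediction of the first percept from expression biases
#'
#' Uses only the class pair shown on each different-class trial: in each
#' of `k_folds` stratified folds, the class most often perceived first for
#' a pair in the training split is predicted for every test trial of that
#' pair (an exactly 50/50 training bias falls back to a seeded coin flip).
#' Significance comes from a permutation test in which response sides are
#' re-shuffled across trials within each condition and the whole
#' cross-validated accuracy is recomputed.
#'
#' @param trials Trial tibble with responses set; same-class trials are
#'   dropped internally.
#' @param k_folds Number of folds (default 10).
#' @param n_permutations Permutations for the null (default 10000).
#' @param seed Integer seed (fold assignment, tie coin flips,
#'   permutations).
#' @return A `bias_prediction`: `fold_accuracies`, `overall_accuracy`,
#'   `perm_p`, `n_permutations`, `n_trials`, `by_pair` bias tibble.
#' @export
bias_cv_predict <- function(trials, k_folds = 10, n_permutations = 10000, seed = 1) {
  stopifnot(k_folds >= 2)
  tr <- different_class_trials(trials)
  if (anyNA(tr$response_side)) {
    abort("responses are unset", class = "firstsight_data_error")
  }
  n <- nrow(tr)
  resp_left <- as.integer(tr$response_side == "left")
  # reference class of each pair: alphabetically first of the two labels
  ref_class <- pmin(tr$left_class, tr$right_class)
  ref_on_left <- as.integer(tr$left_class == ref_class)
  o_obs <- as.integer(resp_left == ref_on_left) # reference class seen first

  fold <- with_stream(seed, "bias_folds", stratified_folds(tr$condition, k_folds))
  pairs <- sort(unique(tr$condition))

  cv_accuracy <- function(O, tie_value = NULL, tie_seed = NULL) {
    # O: n x P matrix (P >= 1) of reference-first indicators
    P <- ncol(O)
    correct <- matrix(0, k_folds, P)
    count <- matrix(0, k_folds, P)
    for (f in seq_len(k_folds)) {
      for (pr in pairs) {
        te <- fold == f & tr$condition == pr
        trn <- fold != f & tr$condition == pr
        nte <- sum(te)
        if (nte == 0) next
        if (sum(trn) == 0) {
          warn(sprintf("pair %s absent from training split of fold %d; using global bias", pr, f))
          trn <- fold != f
        }
        s <- colSums(O[trn, , drop = FALSE])
        ntr <- sum(trn)
        t1 <- colSums(O[te, , drop = FALSE])
        hit <- ifelse(s > ntr / 2, t1,
               ifelse(s < ntr / 2, nte - t1, NA_real_))
        if (anyNA(hit)) {
          if (!is.null(tie_seed)) {
            flips <- with_stream(tie_seed, paste0("tie_", f, "_", pr),
                                 as.integer(runif(nte) < 0.5))
            tie_hit <- sum(flips * O[te, 1] + (1 - flips) * (1 - O[te, 1]))
          } else {
            tie_hit <- tie_value * nte
          }
          hit[is.na(hit)] <- tie_hit
        }
        correct[f, ] <- correct[f, ] + hit
        count[f, ] <- count[f, ] + nte
      }
    }
    list(fold_acc = correct / pmax(count, 1), overall = colSums(correct) / colSums(count))
  }

  obs <- cv_accuracy(matrix(o_obs, ncol = 1), tie_seed = derive_seed(seed, "ties"))
  perm_overall <- with_stream(seed, "bias_permutations", {
    RL <- permute_response_left(resp_left, tr$condition, n_permutations)
    O <- (RL == ref_on_left) * 1L
    cv_accuracy(O, tie_value = 0.5)$overall
  })
  perm_p <- (1 + sum(perm_overall >= obs$overall[1])) / (n_permutations + 1)

  by_pair <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(pair = tr$condition, ref_first = o_obs), .data$pair),
    n = dplyr::n(), ref_first_fraction = mean(.data$ref_first))

  structure(list(fold_accuracies = as.numeric(obs$fold_acc),
                 overall_accuracy = obs$overall[1],
                 perm_p = perm_p, n_permutations = n_permutations,
                 n_trials = n, by_pair = by_pair, seed = seed),
            class = "bias_prediction")
}

#' @export
print.bias_prediction <- function(x, ...) {
  cat(sprintf("<bias_prediction> accuracy %.2f%% over %d trials, permutation p = %.4f\n",
              100 * x$overall_accuracy, x$n_trials, x$perm_p))
  invisible(x)
}

#' Accuracy of always predicting one class to be perceived first
#'
#' @param trials Trial tibble with responses set.
#' @param predicted_class The class always predicted first.
#' @param pair_filter Optional length-2 character vector restricting the
#'   analysis to one class pair (e.g. `c("happy", "angry")`).
#' @param n_permutations Permutations (response sides shuffled within
#'   condition) for the p-value.
#' @param seed Integer seed.
#' @return A one-row tibble: `accuracy`, `perm_p`, `n`.
#' @export
fixed_class_predict <- function(trials, predicted_class, pair_filter = NULL,
                                n_permutations = 10000, seed = 1) {
  tr <- different_class_trials(trials)
  if (!is.null(pair_filter)) {
    cond <- condition_name(pair_filter[1], pair_filter[2])
    alt <- condition_name(pair_filter[2], pair_filter[1])
    tr <- tr[tr$condition %in% c(cond, alt), , drop = FALSE]
  }
  tr <- tr[tr$left_class == predicted_class | tr$right_class == predicted_class, ,
           drop = FALSE]
  if (nrow(tr) == 0) {
    abort("no eligible trials", class = "firstsight_data_error")
  }
  resp_left <- as.integer(tr$response_side == "left")
  pred_on_left <- as.integer(tr$left_class == predicted_class)
  o <- as.integer(resp_left == pred_on_left)
  accuracy <- mean(o)
  perm_acc <- with_stream(seed, "fixed_permutations", {
    RL <- permute_response_left(resp_left, tr$condition, n_permutations)
    colMeans((RL == pred_on_left) * 1L)
  })
  perm_p <- (1 + sum(perm_acc >= accuracy)) / (n_permutations + 1)
  tibble::tibble(accuracy = accuracy, perm_p = perm_p, n = nrow(tr))
}
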