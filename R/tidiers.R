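#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ensemble result into its per-feature relevance table
#'
#' @param x A scored `ensemble_result` (see [score_relevance()]).
#' @param ... Unused.
#' @return Tibble `feature_id`, `times_tested`, `weight`, `null_max`,
#'   `significant`.
#' @method tidy ensemble_result
#' @export
tidy.ensemble_result <- function(x, ...) {
  if (is.null(x$relevance)) x <- score_relevance(x)
  x$relevance
}

#' One-row summary of an ensemble result
#'
#' @inheritParams tidy.ensemble_result
#' @return Tibble: run/control counts, mean performances, chance level,
#'   and the significant-feature count.
#' @method glance ensemble_result
#' @export
glance.ensemble_result <- function(x, ...) {
  tibble::tibble(
    n_runs = nrow(x$runs),
    n_controls = nrow(x$controls),
    n_features = length(x$feature_ids),
    n_classes = x$n_classes,
    mean_performance = mean(x$runs$performance),
    mean_control = mean(x$controls$performance),
    chance = 1 / x$n_classes,
    n_significant = if (!is.null(x$relevance)) sum(x$relevance$significant) else NA_integer_
  )
}

#' Tidy a bias-prediction result into per-fold accuracies
#'
#' @param x A `bias_prediction` from [bias_cv_predict()].
#' @param ... Unused.
#' @method tidy bias_prediction
#' @export
tidy.bias_prediction <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_accuracies),
                 accuracy = x$fold_accuracies)
}

#' One-row summary of a bias-prediction result
#'
#' @inheritParams tidy.bias_prediction
#' @method glance bias_prediction
#' @export
glance.bias_prediction <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 perm_p = x$perm_p,
                 n_permutations = x$n_permutations,
                 n_trials = x$n_trials)
}
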