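#' Split a 2-image feature-weight vector into its left and right halves
#'
#' Trial-row features concatenate the left image's wedges (positions
#' 1..384 at defaults, columns suffixed `_L`) and then the right image's
#' (`_R`). This splits a relevance table (or plain weight vector) over the
#' concatenated layout into side-wise per-wedge weights.
#'
#' @param relevance A relevance tibble from [score_relevance()] (columns
#'   `feature_id`, `weight`) or a numeric weight vector of even length.
#' @return A tibble `wedge_id`, `left`, `right` (384 rows at defaults).
#' @export
split_sides <- function(relevance) {
  if (is.data.frame(relevance)) {
    w <- relevance$weight
    ids <- relevance$feature_id
  } else {
    w <- as.numeric(relevance)
    ids <- names(relevance)
  }
  n <- length(w)
  if (n < 2 || n %% 2 != 0) {
    abort("weight vector must have even length (left block then right block)",
          class = "firstsight_data_error")
  }
  half <- n / 2
  if (!is.null(ids)) {
    l_ok <- grepl("_L$", ids[seq_len(half)])
    r_ok <- grepl("_R$", ids[half + seq_len(half)])
    if (all(c(l_ok, r_ok))) {
      if (!identical(sub("_L$", "", ids[seq_len(half)]),
                     sub("_R$", "", ids[half + seq_len(half)]))) {
        abort("left/right feature ids are not in matching wedge order",
              class = "firstsight_data_error")
      }
    }
  }
  wedge_id <- if (!is.null(ids)) sub("_L$", "", ids[seq_len(half)]) else
    sprintf("w%04d", seq_len(half))
  tibble::tibble(wedge_id = wedge_id, left = w[seq_len(half)],
                 right = w[half + seq_len(half)])
}

#' Average left-eye and right-eye feature weights element-wise
#'
#' @param left,right Equal-length numeric vectors, or a single tibble from
#'   [split_sides()] passed as `left`.
#' @return Numeric vector of element-wise means (named by wedge id when
#'   available).
#' @export
average_sides <- function(left, right = NULL) {
  if (is.data.frame(left) && is.null(right)) {
    out <- (left$left + left$right) / 2
    names(out) <- left$wedge_id
    return(out)
  }
  if (length(left) != length(right)) {
    abort("left and right must have equal length", class = "firstsight_data_error")
  }
  (as.numeric(left) + as.numeric(right)) / 2
}

#' Correlate two feature-weight vectors
#'
#' Pearson correlation with a two-tailed p-value from the exact t
#' transform on n - 2 degrees of freedom. Weight-zero features were never
#' tested by any model, so the default exclusion drops pairs in which
#' either weight is exactly zero; `subset` restricts the correlation to a
#' supplied feature set (e.g. the features significant in another
#' analysis).
#'
#' @param a,b Equal-length numeric weight vectors (or tibbles with
#'   `weight`).
#' @param exclusion `"untested_either"` (default), `"none"`, or
#'   `"subset"`.
#' @param subset Feature names (matched against `names(a)`) or integer
#'   positions retained when `exclusion = "subset"`.
#' @return A one-row tibble: `r`, `p`, `n`, `exclusion`.
#' @export
correlate_weights <- function(a, b, exclusion = c("untested_either", "none", "subset"),
                              subset = NULL) {
  exclusion <- match.arg(exclusion)
  if (is.data.frame(a)) a <- stats::setNames(a$weight, a$feature_id)
  if (is.data.frame(b)) b <- stats::setNames(b$weight, b$feature_id)
  if (length(a) != length(b)) {
    abort("weight vectors must have equal length", class = "firstsight_data_error")
  }
  keep <- switch(exclusion,
    untested_either = a != 0 & b != 0,
    none = rep(TRUE, length(a)),
    subset = {
      if (is.null(subset)) {
        abort("exclusion = 'subset' needs a subset", class = "firstsight_data_error")
      }
      if (is.character(subset)) {
        if (is.null(names(a))) {
          abort("named subset requires named weight vectors",
                class = "firstsight_data_error")
        }
        names(a) %in% subset
      } else {
        seq_along(a) %in% subset
      }
    })
  x <- as.numeric(a[keep])
  y <- as.numeric(b[keep])
  if (length(x) < 3) {
    abort("fewer than 3 pairs retained; correlation undefined",
          class = "firstsight_data_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in a retained weight vector; correlation undefined",
          class = "firstsight_undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x),
                 exclusion = exclusion)
}
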