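#' @importFrom rlang abort warn %||%
#' @importFrom stats fft quantile sd pchisq pnorm pt rnorm runif rlnorm
NULL

CLASS_LABELS <- c("happy", "angry", "neutral")
CLASS_CODES <- c(happy = "HA", angry = "AN", neutral = "NE")

#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package flows through named RNG streams derived
#' deterministically from one master seed, so any stage can be re-run in
#' isolation and full runs are bit-reproducible.
#'
#' @param seed Integer master seed.
#' @param stream Character name of the sub-stream (e.g. "synthesis").
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes) * 131) %% 104729
  as.integer((abs(as.numeric(seed)) * 7919 + h * 613 + 17) %% 2147483629)
}

# Run code under a seeded RNG without disturbing the caller's RNG state.
with_stream <- function(seed, stream, code) {
  withr::with_seed(derive_seed(seed, stream), code)
}

# Stratified k-fold assignment: returns integer fold id per row, each
# class spread as evenly as possible across folds.
stratified_folds <- function(y, k) {
  y <- as.character(y)
  n <- length(y)
  if (any(table(y) < k)) {
    abort(sprintf("every class needs at least k = %d rows for stratified folds", k),
          class = "firstsight_config_error")
  }
  fold <- integer(n)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

class_code <- function(label) unname(CLASS_CODES[match(label, names(CLASS_CODES))])

condition_name <- function(class_a, class_b) {
  paste(class_code(class_a), class_code(class_b), sep = "-")
}
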