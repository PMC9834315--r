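#' Centered-mean Fourier magnitude spectrum of a grayscale image
#'
#' Subtracts the image mean (removing the DC component) and returns the
#' absolute value of the 2-D discrete Fourier transform in unshifted (fft
#' index) order, matching the layout of a [build_grid()] assignment matrix.
#'
#' @param image A numeric square matrix of luminances, or a `gray_image`.
#' @return A non-negative matrix of Fourier magnitudes.
#' @export
magnitude_spectrum <- function(image) {
  px <- image_pixels(image)
  if (nrow(px) != ncol(px)) {
    abort("image must be square", class = "firstsight_data_error")
  }
  Mod(stats::fft(px - mean(px)))
}

image_pixels <- function(image) {
  if (inherits(image, "gray_image")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  abort("expected a gray_image or a numeric matrix", class = "firstsight_data_error")
}

#' Extract wedge contrast-energy features from one image
#'
#' Sums the magnitude spectrum over each spatial-frequency x orientation
#' wedge of `grid`. The total over all wedges equals the summed magnitude
#' of every included Fourier coefficient (the binning is a partition).
#'
#' @param image A `gray_image` or numeric square matrix.
#' @param grid A [build_grid()] feature grid whose `image_side` matches.
#' @return Named numeric vector of length `grid$n_wedges` (384 at defaults),
#'   names are wedge ids `f{sf}_{ori}`.
#' @export
extract_features <- function(image, grid) {
  px <- image_pixels(image)
  if (nrow(px) != grid$image_side || ncol(px) != grid$image_side) {
    abort(sprintf("image side %d does not match grid side %d",
                  nrow(px), grid$image_side),
          class = "firstsight_config_error")
  }
  M <- magnitude_spectrum(px)
  keep <- !is.na(grid$assignment)
  sums <- rowsum(M[keep], grid$assignment[keep])
  out <- numeric(grid$n_wedges)
  out[as.integer(rownames(sums))] <- sums[, 1]
  names(out) <- grid$wedge_ids
  out
}

#' Extract features for a whole stimulus set
#'
#' @param images A stimulus tibble from [make_stimulus_set()] (columns
#'   `image_id`, `class`, `pixels`), or a named list of `gray_image`s.
#' @param grid A [build_grid()] feature grid.
#' @return A tibble with one row per image: `image_id`, `class`, then one
#'   numeric column per wedge id.
#' @export
extract_feature_table <- function(images, grid) {
  if (!tibble::is_tibble(images)) {
    images <- tibble::tibble(
      image_id = vapply(images, function(g) g$image_id, character(1)),
      class = vapply(images, function(g) g$class_label %||% NA_character_, character(1)),
      pixels = lapply(images, function(g) g$pixels)
    )
  }
  feats <- lapply(images$pixels, extract_features, grid = grid)
  mat <- do.call(rbind, feats)
  dplyr::bind_cols(
    tibble::tibble(image_id = images$image_id, class = images$class),
    tibble::as_tibble(mat)
  )
}

#' Assemble labeled feature rows for decoding
#'
#' In `response_side` mode each trial becomes one row: the left image's
#' wedge features (suffix `_L`), then the right image's (suffix `_R`), 768
#' columns at the default grid, labeled by which side was perceived first.
#' In `expression` mode each *image* becomes one 384-feature row labeled by
#' its expression class, independent of behavior.
#'
#' @param trials A trial tibble (see [make_trial_table()]); required in
#'   `response_side` mode.
#' @param features A feature tibble from [extract_feature_table()].
#' @param label_mode `"response_side"` or `"expression"`.
#' @return A tibble: `trial_id` (or `image_id`), feature columns, `label`.
#' @export
make_trial_rows <- function(trials, features, label_mode = c("response_side", "expression")) {
  label_mode <- match.arg(label_mode)
  wedge_cols <- setdiff(names(features), c("image_id", "class"))
  if (label_mode == "expression") {
    out <- features
    out$label <- factor(out$class)
    return(dplyr::select(out, "image_id", dplyr::all_of(wedge_cols), "label"))
  }
  missing <- setdiff(unique(c(trials$left_image_id, trials$right_image_id)),
                     features$image_id)
  if (length(missing) > 0) {
    abort(paste0("missing feature vectors for image(s): ",
                 paste(utils::head(missing, 5), collapse = ", ")),
          class = "firstsight_data_error")
  }
  if (anyNA(trials$response_side)) {
    abort("trials have unset responses; run simulate_responses() first",
          class = "firstsight_data_error")
  }
  fmat <- as.matrix(features[, wedge_cols])
  rownames(fmat) <- features$image_id
  left <- fmat[trials$left_image_id, , drop = FALSE]
  right <- fmat[trials$right_image_id, , drop = FALSE]
  colnames(left) <- paste0(wedge_cols, "_L")
  colnames(right) <- paste0(wedge_cols, "_R")
  dplyr::bind_cols(
    tibble::tibble(trial_id = trials$trial_id),
    tibble::as_tibble(left), tibble::as_tibble(right),
    tibble::tibble(label = factor(trials$response_side))
  )
}

feature_columns <- function(rows) {
  setdiff(names(rows), c("trial_id", "image_id", "class", "label", "subject"))
}
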