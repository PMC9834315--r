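#' Write a stimulus set as 8-bit grayscale PNGs
#'
#' @param images Stimulus tibble from [make_stimulus_set()].
#' @param dir Output directory (created if needed); the filename stem is
#'   the `image_id`.
#' @return Invisibly, the written paths.
#' @export
write_stimulus_pngs <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(images$image_id, ".png"))
  for (i in seq_len(nrow(images))) {
    px <- pmin(pmax(images$pixels[[i]], 0), 1)
    png::writePNG(px, paths[i])
  }
  invisible(paths)
}

#' Read grayscale PNG stimuli from a directory
#'
#' The filename stem becomes the `image_id`; a leading `HA_`/`AN_`/`NE_`
#' prefix, if present, is decoded into the class label.
#'
#' @param dir Directory of `.png` files.
#' @return A stimulus tibble (`image_id`, `class`, `pixels`).
#' @export
read_stimulus_pngs <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(paths) == 0) abort("no PNG files found", class = "firstsight_data_error")
  ids <- sub("\\.png$", "", basename(paths))
  code2class <- stats::setNames(names(CLASS_CODES), CLASS_CODES)
  cls <- unname(code2class[sub("_.*$", "", ids)])
  px <- lapply(paths, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  tibble::tibble(image_id = ids, class = cls, pixels = px)
}

trial_csv_cols <- c("trial_id", "condition", "left_image_id", "right_image_id",
                    "left_class", "right_class", "response_side", "rt_seconds")

#' Read / write trial tables as CSV
#'
#' @param trials Trial tibble.
#' @param path CSV path.
#' @return `read_trial_table()` returns the trial tibble.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(setdiff(trial_csv_cols, c("response_side", "rt_seconds")),
                     names(tr))
  if (length(missing) > 0) {
    abort(paste0("trial CSV lacks column(s): ", paste(missing, collapse = ", ")),
          class = "firstsight_data_error")
  }
  if (is.null(tr$subject)) tr$subject <- "s01"
  if (is.null(tr$response_side)) tr$response_side <- NA_character_
  if (is.null(tr$rt_seconds)) tr$rt_seconds <- NA_real_
  tr
}
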