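#' Specify target wedge energies for synthetic stimuli
#'
#' A `wedge_energy_spec` describes a family of synthetic stimuli in the
#' feature space itself: a base contrast energy per wedge, optional
#' additive per-class offsets (an "expression signature"), a multiplicative
#' lognormal identity jitter applied per wedge per image, and the Michelson
#' contrast the final pixels are rescaled to. The default contrast, 0.176,
#' matches the mean maximum Michelson contrast of the face photographs the
#' design emulates (stimuli ramped up to 20% of maximum contrast, giving
#' per-class means of about 17.5-17.6%).
#'
#' @param grid A [build_grid()] feature grid.
#' @param base_energy Scalar or per-wedge vector of non-negative base
#'   energies (arbitrary units). Default 1 in every populated wedge.
#' @param class_deltas Named list (`happy`, `angry`, `neutral`) of additive
#'   per-wedge offsets, or `NULL` for no class signal.
#' @param identity_sd Lognormal sigma of the per-wedge multiplicative
#'   jitter between images (default 0.15).
#' @param target_michelson Michelson contrast of the synthesized pixels,
#'   in (0, 1] (default 0.176).
#' @return A `wedge_energy_spec` object.
#' @export
wedge_energy_spec <- function(grid, base_energy = 1, class_deltas = NULL,
                              identity_sd = 0.15, target_michelson = 0.176) {
  stopifnot(inherits(grid, "feature_grid"))
  if (length(base_energy) == 1) {
    base_energy <- ifelse(grid$wedge_counts > 0, base_energy, 0)
  }
  if (length(base_energy) != grid$n_wedges) {
    abort("base_energy must be scalar or one value per wedge",
          class = "firstsight_config_error")
  }
  if (any(base_energy < 0)) {
    abort("base_energy must be non-negative", class = "firstsight_domain_error")
  }
  if (!is.null(class_deltas)) {
    for (cl in names(class_deltas)) {
      d <- class_deltas[[cl]]
      if (length(d) != grid$n_wedges) {
        abort("each class delta must have one value per wedge",
              class = "firstsight_config_error")
      }
      if (any(base_energy + d < 0)) {
        abort(sprintf("base_energy + class delta for '%s' is negative in some wedge", cl),
              class = "firstsight_domain_error")
      }
    }
  }
  if (!(target_michelson > 0 && target_michelson <= 1)) {
    abort("target_michelson must be in (0, 1]", class = "firstsight_domain_error")
  }
  structure(
    list(base_energy = as.numeric(base_energy), class_deltas = class_deltas,
         identity_sd = identity_sd, target_michelson = target_michelson,
         grid_id = grid$grid_id, n_wedges = grid$n_wedges),
    class = "wedge_energy_spec"
  )
}

#' Default disjoint expression signatures
#'
#' Places each class's energy offset in its own orientation band over two
#' mid-range spatial-frequency bands: happy on the vertical Fourier axis
#' (horizontal image contours, where a smile lives), angry and neutral on
#' the two diagonals. Signatures are energy-neutral: the energy added in
#' the signature wedges is removed uniformly from the remaining populated
#' wedges, so every class has the same expected total contrast energy
#' (mirroring stimuli presented at equal Michelson contrast; without this
#' the global contrast rescale would make every wedge class-informative).
#' The three signature wedge sets are disjoint and are
#' deliberately sparse - a few wedges out of hundreds, like the localized
#' expression information in real face spectra - so planted-signal
#' recovery can be scored against a known wedge set. (The per-feature
#' relevance criterion presumes the informative set is small relative to
#' the feature space; signatures occupying a large share of the wedges
#' make every co-selected feature genuinely informative by association.)
#'
#' @param grid A [build_grid()] feature grid.
#' @param magnitude Offset added in each signature wedge (default 0.35,
#'   i.e. roughly twice the default identity jitter: the signature is
#'   reliably decodable from the wedge set as a whole while no single
#'   wedge separates the classes on its own, as with real expression
#'   information spread over several frequency bands).
#' @param sf_bands SF bands carrying the signatures; default the two bands
#'   just above the middle of the range.
#' @return Named list of per-wedge delta vectors with attribute
#'   `signal_wedges` (named list of wedge ids per class).
#' @export
expression_delta_spec <- function(grid, magnitude = 0.35,
                                  sf_bands = floor(grid$n_sf / 2) + c(1, 2)) {
  sf_bands <- sf_bands[sf_bands >= 1 & sf_bands <= grid$n_sf]
  ori_for <- c(happy = grid$n_ori / 2 + 1, # 90 deg: vertical Fourier axis
               angry = grid$n_ori / 4 + 1, # 45 deg
               neutral = 3 * grid$n_ori / 4 + 1) # 135 deg
  deltas <- list()
  wedges <- list()
  pop <- which(grid$wedge_counts > 0)
  for (cl in names(ori_for)) {
    idx <- (sf_bands - 1L) * grid$n_ori + as.integer(round(ori_for[[cl]]))
    idx <- idx[grid$wedge_counts[idx] > 0]
    d <- numeric(grid$n_wedges)
    d[idx] <- magnitude
    # energy-neutral: spread a compensating decrement over the remaining
    # populated wedges so total contrast energy is class-independent, as
    # in the real stimuli (equal maximum Michelson contrast per class).
    # Otherwise the final contrast rescale would leak class information
    # into every wedge via the image's total energy.
    rest <- setdiff(pop, idx)
    d[rest] <- -magnitude * length(idx) / length(rest)
    deltas[[cl]] <- d
    wedges[[cl]] <- grid$wedge_ids[idx]
  }
  attr(deltas, "signal_wedges") <- wedges
  deltas
}

#' Synthesize a noise image with controlled wedge energies
#'
#' Builds a Hermitian-symmetric Fourier spectrum whose magnitude is
#' constant within each wedge and sums to the spec's per-wedge target
#' (after the class offset and identity jitter), with uniform-random
#' phases, then inverse-transforms and rescales the pixels around mean
#' luminance 0.5 with one deterministic contrast factor derived from the
#' spec's analytic pixel SD, so the realized Michelson contrast varies
#' slightly around `target_michelson` from image to image. Because the
#' image is constructed directly in the Fourier domain, re-extracting its
#' wedge features returns the jittered targets exactly, up to that single
#' set-wide scale factor.
#'
#' @param spec A [wedge_energy_spec()].
#' @param grid The matching [build_grid()] feature grid.
#' @param side Image side in pixels; must equal `grid$image_side`.
#' @param class_label Optional class whose delta is applied.
#' @param seed Integer seed; identical inputs + seed give bit-identical
#'   images.
#' @param image_id Identifier stored on the image.
#' @return A `gray_image`: list of `pixels` (side x side matrix in
#'   `[0, 1]`), `image_id`, `class_label`.
#' @export
make_wedge_noise_image <- function(spec, grid, side = grid$image_side,
                                   class_label = NULL, seed = 1,
                                   image_id = "img") {
  stopifnot(inherits(spec, "wedge_energy_spec"), inherits(grid, "feature_grid"))
  if (side != grid$image_side || spec$grid_id != grid$grid_id) {
    abort("spec/grid/side mismatch", class = "firstsight_config_error")
  }
  target <- spec$base_energy
  if (!is.null(class_label)) {
    if (!class_label %in% CLASS_LABELS) {
      abort("unknown class label", class = "firstsight_domain_error")
    }
    d <- spec$class_deltas[[class_label]]
    if (!is.null(d)) target <- target + d
  }
  if (any(target < 0)) {
    abort("negative wedge energy target", class = "firstsight_domain_error")
  }
  px <- with_stream(seed, paste0("image_", image_id), {
    if (spec$identity_sd > 0) {
      jit <- rlnorm(grid$n_wedges, meanlog = -spec$identity_sd^2 / 2,
                    sdlog = spec$identity_sd)
      target <- target * jit
    }
    per_coef <- ifelse(grid$wedge_counts > 0, target / pmax(grid$wedge_counts, 1), 0)
    mag <- matrix(0, side, side)
    keep <- !is.na(grid$assignment)
    mag[keep] <- per_coef[grid$assignment[keep]]
    # Hermitian phases from the FFT of white noise
    z <- stats::fft(matrix(rnorm(side * side), side, side))
    u <- ifelse(Mod(z) > 0, z / Mod(z), 1)
    Re(stats::fft(mag * u, inverse = TRUE)) / (side * side)
  })
  # Deterministic contrast scale from the spec's analytic pixel SD
  # (Parseval), shared by the whole stimulus set. Rescaling each image by
  # its own realized range would inject a per-image global factor into
  # every wedge - a shared component that spuriously couples all features
  # to anything driven by any wedge. With a common scale the per-image
  # Michelson contrast varies slightly around the target instead, as the
  # unmanipulated photographs in the emulated design did (SD ~ 0.3%).
  sd_ref <- sqrt(sum(spec$base_energy^2 / pmax(grid$wedge_counts, 1))) / side^2
  if (sd_ref > 0) {
    px <- 0.5 + px * (spec$target_michelson / (2 * 3.29 * sd_ref))
    px <- pmin(pmax(px, 0), 1)
  } else {
    px <- matrix(0.5, side, side)
  }
  structure(list(pixels = px, image_id = image_id, class_label = class_label),
            class = "gray_image")
}

#' Generate a labeled synthetic stimulus set
#'
#' @param spec A [wedge_energy_spec()].
#' @param grid The matching feature grid.
#' @param n_per_class Images per class (default 39, i.e. 117 in total,
#'   the size of the face set the design emulates).
#' @param seed Integer seed.
#' @return A tibble: `image_id`, `class`, `pixels` (list column).
#' @export
make_stimulus_set <- function(spec, grid, n_per_class = 39, seed = 1) {
  if (n_per_class < 1) {
    abort("n_per_class must be >= 1", class = "firstsight_domain_error")
  }
  rows <- list()
  for (cl in CLASS_LABELS) {
    for (i in seq_len(n_per_class)) {
      id <- sprintf("%s_%03d", class_code(cl), i)
      img <- make_wedge_noise_image(spec, grid, class_label = cl,
                                    seed = derive_seed(seed, id), image_id = id)
      rows[[id]] <- tibble::tibble(image_id = id, class = cl,
                                   pixels = list(img$pixels))
    }
  }
  dplyr::bind_rows(rows)
}

#' Build the six-condition trial design
#'
#' Six conditions - HA-HA, HA-NE, HA-AN, AN-NE, AN-AN, NE-NE - with
#' `trials_per_condition` trials each (48 by default, 288 trials in
#' total). Within each different-class condition the left/right placement
#' of the two classes is counterbalanced exactly (+/-1 for odd counts);
#' image identities are sampled per trial with the two sides always
#' showing different images.
#'
#' @param images Stimulus tibble from [make_stimulus_set()].
#' @param trials_per_condition Trials per condition (default 48).
#' @param seed Integer seed.
#' @param subject Subject id attached to every trial.
#' @return A trial tibble with unset `response_side` / `rt_seconds`.
#' @export
make_trial_table <- function(images, trials_per_condition = 48, seed = 1,
                             subject = "s01") {
  stopifnot(trials_per_condition >= 1)
  conditions <- list(c("happy", "happy"), c("happy", "neutral"), c("happy", "angry"),
                     c("angry", "neutral"), c("angry", "angry"), c("neutral", "neutral"))
  by_class <- split(images$image_id, images$class)
  for (cond in conditions) {
    if (cond[1] == cond[2] && length(by_class[[cond[1]]]) < 2) {
      abort(sprintf("same-class condition %s needs >= 2 images of class %s",
                    condition_name(cond[1], cond[2]), cond[1]),
            class = "firstsight_config_error")
    }
    if (any(lengths(by_class[cond]) < 1)) {
      abort("missing images for a condition class", class = "firstsight_config_error")
    }
  }
  tab <- with_stream(seed, "trial_design", {
    rows <- lapply(conditions, function(cond) {
      n <- trials_per_condition
      n_first_left <- ceiling(n / 2)
      left_cls <- c(rep(cond[1], n_first_left), rep(cond[2], n - n_first_left))
      right_cls <- c(rep(cond[2], n_first_left), rep(cond[1], n - n_first_left))
      left_id <- character(n)
      right_id <- character(n)
      for (t in seq_len(n)) {
        li <- sample(by_class[[left_cls[t]]], 1)
        ri <- sample(setdiff(by_class[[right_cls[t]]], li), 1)
        left_id[t] <- li
        right_id[t] <- ri
      }
      tibble::tibble(condition = condition_name(cond[1], cond[2]),
                     left_image_id = left_id, right_image_id = right_id,
                     left_class = left_cls, right_class = right_cls)
    })
    tab <- dplyr::bind_rows(rows)
    tab[sample(nrow(tab)), ]
  })
  dplyr::bind_cols(
    tibble::tibble(trial_id = seq_len(nrow(tab)), subject = subject),
    tab,
    tibble::tibble(response_side = NA_character_, rt_seconds = NA_real_)
  )
}

#' Define the generative first-percept response model
#'
#' The probability of reporting the left image first is
#' `(1 - lapse) * plogis(beta * d) + lapse / 2`, where `d` is the
#' difference in summed contrast energy over the driver wedges between the
#' left and the right image (divided by its SD over the trial set when
#' `normalize = TRUE`, which makes `beta` unit-free). This is a deliberate
#' generative stand-in: it encodes "contrast energy in specific wedges
#' drives which image is seen first" as a samplable rule.
#'
#' @param driver_wedges Character vector of wedge ids whose energy drives
#'   the response.
#' @param beta Inverse temperature (>= 0). 0 gives unbiased coin flips;
#'   large values make the higher-energy side win deterministically.
#' @param lapse Lapse rate in `[0, 1]`: fraction of trials answered at
#'   random regardless of the stimuli.
#' @param normalize Divide the energy difference by its SD across trials.
#' @param rt_meanlog,rt_sdlog Lognormal parameters of the stored (never
#'   analyzed) reaction times; defaults give a median near 3 s.
#' @return A `response_model` object.
#' @export
response_model <- function(driver_wedges, beta = 4, lapse = 0.02,
                           normalize = TRUE, rt_meanlog = log(3), rt_sdlog = 0.35) {
  stopifnot(beta >= 0, lapse >= 0, lapse <= 1, length(driver_wedges) >= 1)
  structure(list(driver_wedges = driver_wedges, beta = beta, lapse = lapse,
                 normalize = normalize, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog),
            class = "response_model")
}

#' Simulate first-percept responses for a trial table
#'
#' @param trials Trial tibble from [make_trial_table()].
#' @param features Feature tibble from [extract_feature_table()] covering
#'   every image referenced by `trials`.
#' @param model A [response_model()].
#' @param seed Integer seed.
#' @return The trial tibble with `response_side` and `rt_seconds` filled.
#' @export
simulate_responses <- function(trials, features, model, seed = 1) {
  stopifnot(inherits(model, "response_model"))
  missing <- setdiff(unique(c(trials$left_image_id, trials$right_image_id)),
                     features$image_id)
  if (length(missing) > 0) {
    abort(paste0("no features for image(s): ", paste(utils::head(missing, 5), collapse = ", ")),
          class = "firstsight_data_error")
  }
  bad <- setdiff(model$driver_wedges, names(features))
  if (length(bad) > 0) {
    abort(paste0("unknown driver wedge(s): ", paste(bad, collapse = ", ")),
          class = "firstsight_data_error")
  }
  e <- rowSums(as.matrix(features[, model$driver_wedges, drop = FALSE]))
  names(e) <- features$image_id
  d <- unname(e[trials$left_image_id] - e[trials$right_image_id])
  if (model$normalize && sd(d) > 0) d <- d / sd(d)
  p_left <- (1 - model$lapse) * stats::plogis(model$beta * d) + model$lapse / 2
  with_stream(seed, "responses", {
    trials$response_side <- ifelse(runif(nrow(trials)) < p_left, "left", "right")
    trials$rt_seconds <- rlnorm(nrow(trials), model$rt_meanlog, model$rt_sdlog)
  })
  trials
}
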