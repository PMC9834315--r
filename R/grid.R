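#' Build a spatial-frequency x orientation feature grid
#'
#' Partitions the (unshifted) 2-D discrete Fourier plane of a square image
#' into `n_sf` spatial-frequency bands times `n_ori` orientation wedges.
#' Each non-DC Fourier coefficient whose radius lies between 1 cycle/image
#' and the Nyquist frequency (`image_side / 2` cycles/image) is assigned to
#' exactly one wedge; conjugate-symmetric coefficient pairs land in the same
#' wedge because orientation is taken modulo 180 degrees. Summing the
#' magnitude spectrum within each wedge yields the per-image contrast-energy
#' features (384 of them at the 24 x 16 default).
#'
#' Spatial-frequency band edges follow a log spacing from 1 to Nyquist,
#' snapped to geometric midpoints between consecutive radii that actually
#' occur on the integer frequency lattice. The snapping guarantees that
#' every band contains at least one Fourier coefficient (a pure log spacing
#' leaves low-frequency bands empty, because lattice radii below ~3
#' cycles/image are sparse: 1, sqrt 2, 2, sqrt 5, ...). Orientation bins
#' have uniform width `180 / n_ori` degrees with the first bin centered on
#' 0 degrees, i.e. on the horizontal Fourier axis; energy there reflects
#' left-right luminance change and hence vertical contours in the image.
#'
#' @param n_sf Number of spatial-frequency bands (default 24).
#' @param n_ori Number of orientation bins (default 16).
#' @param image_side Side length in pixels of the (square, even-sided)
#'   images the grid will be applied to (default 128).
#' @return A `feature_grid` object: edges, the per-coefficient assignment
#'   matrix (NA = excluded), wedge ids `f{sf}_{ori}`, and per-wedge
#'   coefficient counts.
#' @examples
#' g <- build_grid(24, 16, 128)
#' g$n_wedges # 384
#' @export
build_grid <- function(n_sf = 24, n_ori = 16, image_side = 128) {
  stopifnot(n_sf >= 1, n_ori >= 1, image_side >= 2)
  if (image_side %% 2 != 0) {
    abort("image_side must be even", class = "firstsight_config_error")
  }
  nyq <- image_side / 2

  freqs <- c(0:nyq, -(nyq - 1):-1) # fft index order
  fx <- matrix(freqs, image_side, image_side, byrow = TRUE) # columns: x (left-right)
  fy <- matrix(freqs, image_side, image_side, byrow = FALSE)
  r <- sqrt(fx^2 + fy^2)
  included <- r >= 1 & r <= nyq

  sf_edges <- sf_band_edges(n_sf, image_side, r[included])

  theta <- (atan2(fy, fx) * 180 / pi) %% 180
  ori_width <- 180 / n_ori
  ori_bin <- floor(((theta + ori_width / 2) %% 180) / ori_width) + 1L

  sf_bin <- matrix(NA_integer_, image_side, image_side)
  sf_bin[included] <- findInterval(r[included], sf_edges, rightmost.closed = TRUE)

  assignment <- matrix(NA_integer_, image_side, image_side)
  assignment[included] <- (sf_bin[included] - 1L) * n_ori + ori_bin[included]

  counts <- tabulate(assignment[included], nbins = n_sf * n_ori)
  wedge_ids <- as.vector(t(outer(seq_len(n_sf), seq_len(n_ori),
                                 function(s, o) sprintf("f%02d_%02d", s, o))))

  structure(
    list(
      n_sf = as.integer(n_sf), n_ori = as.integer(n_ori),
      image_side = as.integer(image_side),
      sf_edges = sf_edges,
      ori_edges = seq(-ori_width / 2, 180 - ori_width / 2, by = ori_width),
      assignment = assignment,
      wedge_ids = wedge_ids,
      wedge_counts = counts,
      n_wedges = as.integer(n_sf * n_ori),
      grid_id = sprintf("grid_%dx%d_%dpx", n_sf, n_ori, image_side)
    ),
    class = "feature_grid"
  )
}

# Log-spaced SF edges from 1 to Nyquist, snapped to geometric midpoints
# between consecutive achievable lattice radii so no band is empty.
sf_band_edges <- function(n_sf, image_side, radii) {
  nyq <- image_side / 2
  u <- sort(unique(round(radii, 9)))
  if (length(u) < n_sf) {
    abort(sprintf(
      "image_side %d yields only %d distinct lattice radii; cannot populate %d SF bands",
      image_side, length(u), n_sf), class = "firstsight_config_error")
  }
  if (n_sf == 1) return(c(1, nyq))
  mids <- sqrt(u[-length(u)] * u[-1]) # geometric midpoints
  ideal <- exp(seq(log(1), log(nyq), length.out = n_sf + 1))[2:n_sf]
  cuts <- numeric(n_sf - 1)
  last <- 0L
  for (i in seq_along(ideal)) {
    j <- which.min(abs(log(mids) - log(ideal[i])))
    j <- max(j, last + 1L)
    remaining <- (n_sf - 1) - i
    if (j > length(mids) - remaining) j <- length(mids) - remaining
    cuts[i] <- mids[j]
    last <- j
  }
  c(1, cuts, nyq)
}

#' @export
print.feature_grid <- function(x, ...) {
  cat(sprintf(
    "<feature_grid> %d SF bands x %d orientation bins = %d wedges (%d px images)\n",
    x$n_sf, x$n_ori, x$n_wedges, x$image_side))
  cat(sprintf("  SF range: %.2f-%.2f cycles/image; %d of %d wedges populated\n",
              x$sf_edges[1], x$sf_edges[length(x$sf_edges)],
              sum(x$wedge_counts > 0), x$n_wedges))
  invisible(x)
}

# sf band and orientation bin of each wedge index
wedge_sf <- function(grid, wedge) (wedge - 1L) %/% grid$n_ori + 1L
wedge_ori <- function(grid, wedge) (wedge - 1L) %% grid$n_ori + 1L

#' Wedge ids lying on (or near) the horizontal Fourier axis
#'
#' Convenience selector for the orientation bins whose centers are nearest
#' 0 degrees (left-right luminance change, i.e. vertical image contours).
#'
#' @param grid A `feature_grid`.
#' @param sf_bands Integer vector of SF bands to include (default all).
#' @param ori_bins Orientation bins to select (default bin 1, centered 0).
#' @return Character vector of wedge ids.
#' @export
horizontal_axis_wedges <- function(grid, sf_bands = seq_len(grid$n_sf), ori_bins = 1L) {
  idx <- as.vector(outer(ori_bins, (sf_bands - 1L) * grid$n_ori, `+`))
  grid$wedge_ids[sort(idx)]
}
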