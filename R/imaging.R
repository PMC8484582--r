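#' Synthetic imaging configuration
#'
#' Parameters for rendering fluorescence time-lapse frames of an anchored
#' filament and for the downstream measurement chain. Intensities are in
#' arbitrary camera counts. The default blur radius of 1.00 px matches the
#' Gaussian blur applied to each cropped frame before maximum projection in
#' the reference measurement workflow.
#'
#' @param pixel_um Pixel size, um/px.
#' @param size_px Image side length, px (square frames).
#' @param psf_sigma_px Gaussian PSF sigma, px.
#' @param blur_radius_px Post-acquisition Gaussian blur sigma, px.
#' @param background Constant background level, counts.
#' @param amplitude Peak filament signal above background, counts.
#' @param noise_sd Gaussian read-noise standard deviation, counts.
#' @param shot_noise Add Poisson shot noise on signal + background?
#' @param anchor_px Anchor position `c(x, y)` in px; default frame centre.
#' @return Object of class `imaging_config`.
#' @export
imaging_config <- function(pixel_um = 0.1, size_px = 161, psf_sigma_px = 1.5,
                           blur_radius_px = 1.0, background = 100,
                           amplitude = 500, noise_sd = 20, shot_noise = TRUE,
                           anchor_px = NULL) {
  vals <- c(pixel_um, size_px, psf_sigma_px, blur_radius_px, amplitude)
  if (any(vals <= 0) || background < 0 || noise_sd < 0)
    abort("Imaging parameters must be positive (background/noise non-negative).",
          class = "windsock_domain_error")
  structure(list(pixel_um = pixel_um, size_px = as.integer(size_px),
                 psf_sigma_px = psf_sigma_px, blur_radius_px = blur_radius_px,
                 background = background, amplitude = amplitude,
                 noise_sd = noise_sd, shot_noise = shot_noise,
                 anchor_px = anchor_px %||% rep((size_px + 1) / 2, 2)),
            class = "imaging_config")
}

#' Render one fluorescence frame of an anchored filament
#'
#' Draws a line segment of length `length_um` from the anchor at azimuth
#' `phi_rad`, convolved analytically with the Gaussian PSF (the exact line
#' integral of an isotropic Gaussian: a transverse Gaussian profile times
#' longitudinal error-function end caps), then adds background and, when
#' `noise = TRUE`, Poisson--Gaussian noise.
#'
#' @param phi_rad Filament azimuth, radians (0 along +x).
#' @param length_um Filament length, um.
#' @param config An [imaging_config()].
#' @param seed Optional RNG seed for the noise.
#' @param noise Add noise? `FALSE` returns the clean signal + background.
#' @return `size_px` x `size_px` intensity matrix (x indexes rows).
#' @export
render_frame <- function(phi_rad, length_um, config = imaging_config(),
                         seed = NULL, noise = TRUE) {
  stopifnot(inherits(config, "imaging_config"))
  L <- length_um / config$pixel_um
  ax <- config$anchor_px[1]; ay <- config$anchor_px[2]
  ex <- ax + L * cos(phi_rad); ey <- ay + L * sin(phi_rad)
  pad <- 4 * config$psf_sigma_px
  if (min(ex, ey) < 1 - pad / 2 || max(ex, ey) > config$size_px + pad / 2 ||
      min(ax, ay) < 1 || max(ax, ay) > config$size_px)
    abort("Filament does not fit inside the frame.",
          class = "windsock_geometry_error")
  img <- matrix(0, config$size_px, config$size_px)
  # bounding window of the segment, +/- 4 sigma
  x0 <- max(1L, floor(min(ax, ex) - pad)); x1 <- min(config$size_px, ceiling(max(ax, ex) + pad))
  y0 <- max(1L, floor(min(ay, ey) - pad)); y1 <- min(config$size_px, ceiling(max(ay, ey) + pad))
  gx <- x0:x1; gy <- y0:y1
  ux <- cos(phi_rad); uy <- sin(phi_rad)
  X <- matrix(gx, length(gx), length(gy))
  Y <- matrix(gy, length(gx), length(gy), byrow = TRUE)
  tpar <- (X - ax) * ux + (Y - ay) * uy            # along-segment coordinate
  dper <- -(X - ax) * uy + (Y - ay) * ux           # transverse coordinate
  s <- config$psf_sigma_px
  prof <- exp(-dper^2 / (2 * s^2)) *
    (stats::pnorm((L - tpar) / s) - stats::pnorm(-tpar / s))
  img[gx, gy] <- config$amplitude * prof
  out <- img + config$background
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    if (config$shot_noise)
      out <- matrix(rpois(length(out), pmax(out, 0)), nrow(out), ncol(out))
    out <- out + rnorm(length(out), 0, config$noise_sd)
  }
  out
}

#' Render a time-lapse stack from a trajectory
#'
#' Samples the trajectory at the protocol's frame times and renders one
#' frame per time point.
#'
#' @param traj Trajectory tibble (`time_s`, `phi_rad`), e.g. from
#'   [simulate_trajectory()].
#' @param length_um Filament length, um.
#' @param config An [imaging_config()].
#' @param protocol A [sampling_protocol()].
#' @param seed RNG seed for the noise (one substream per frame).
#' @param noise Add noise?
#' @return 3-D array `[x, y, frame]`.
#' @export
render_stack <- function(traj, length_um, config = imaging_config(),
                         protocol = sampling_protocol(), seed = 1,
                         noise = TRUE) {
  frame_t <- (seq_len(protocol$n_frames) - 1) * protocol$interval_s
  if (max(traj$time_s) < frame_t[length(frame_t)] - 1e-9)
    abort("Trajectory shorter than the imaging protocol.",
          class = "windsock_coverage_error")
  ph <- approx(traj$time_s, traj$phi_rad, xout = frame_t, ties = "ordered")$y
  set.seed(seed)
  frame_seeds <- sample.int(.Machine$integer.max - 1L, length(ph))
  arr <- array(0, c(config$size_px, config$size_px, length(ph)))
  for (i in seq_along(ph))
    arr[, , i] <- render_frame(ph[i], length_um, config,
                               seed = frame_seeds[i], noise = noise)
  arr
}

#' Gaussian-blur the frames of a stack
#'
#' @param frames 3-D array `[x, y, frame]` or a single matrix.
#' @param radius_px Gaussian sigma in px.
#' @return Blurred array/matrix of the same shape.
#' @export
blur_frames <- function(frames, radius_px = 1.0) {
  if (is.matrix(frames)) return(EBImage::gblur(frames, sigma = radius_px))
  for (i in seq_len(dim(frames)[3]))
    frames[, , i] <- EBImage::gblur(frames[, , i], sigma = radius_px)
  frames
}

#' Maximum time projection
#'
#' Pixelwise maximum over the frames of a time-lapse stack: the envelope of
#' the moving filament's positions.
#'
#' @param frames 3-D array `[x, y, frame]`, or a list of equal-shape
#'   matrices.
#' @return Projection matrix.
#' @export
max_time_projection <- function(frames) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(frames) == 0)
      abort("Need at least one frame.", class = "windsock_domain_error")
    if (length(dims) != 1)
      abort("All frames must have the same shape.",
            class = "windsock_domain_error")
    return(Reduce(pmax, frames))
  }
  if (is.matrix(frames)) return(frames)
  if (length(dim(frames)) != 3)
    abort("`frames` must be a matrix, list of matrices, or 3-D array.",
          class = "windsock_domain_error")
  out <- frames[, , 1]
  for (i in seq_len(dim(frames)[3])[-1]) out <- pmax(out, frames[, , i])
  out
}

#' Angular extent of a filament's excursions from a projection image
#'
#' Automates reading the total rotation angle off a maximum time projection:
#' threshold the projection (Otsu by default), keep foreground pixels in an
#' annulus about the anchor (excluding the near-anchor region where polar
#' angles are ill-defined and the far field beyond the filament), build an
#' intensity-weighted polar-angle histogram, and return the circular range of
#' the occupied bins. Invariant under global intensity scaling.
#'
#' @param projection Projection matrix (x indexes rows).
#' @param config The [imaging_config()] used to render (provides anchor and
#'   pixel size).
#' @param length_um Estimate of the filament length, um (sets the annulus).
#' @param bin_deg Angular bin width, degrees.
#' @param threshold `"otsu"` or `"quantile"` (low-SNR fallback).
#' @param quantile Quantile used when `threshold = "quantile"`.
#' @param r_inner,r_outer Annulus radii as fractions of the filament length.
#' @param occupancy Fraction of the maximum bin weight a bin must carry to
#'   count as visited (an FWHM-style criterion that rejects the Gaussian
#'   tails bleeding into neighbouring bins).
#' @return Angular extent Phi in degrees, in \[0, 360\].
#' @export
measure_angle_extent <- function(projection, config, length_um,
                                 bin_deg = 5, threshold = c("otsu", "quantile"),
                                 quantile = 0.995, r_inner = 0.3,
                                 r_outer = 1.15, occupancy = 0.5) {
  stopifnot(inherits(config, "imaging_config"))
  threshold <- match.arg(threshold)
  rng <- range(projection)
  if (rng[1] == rng[2])
    abort("Projection is constant: no foreground detected.",
          class = "windsock_empty_detection")
  scaled <- (projection - rng[1]) / (rng[2] - rng[1])
  thr <- if (threshold == "otsu") EBImage::otsu(scaled, range = c(0, 1))
         else stats::quantile(scaled, quantile, names = FALSE)
  L <- length_um / config$pixel_um
  ax <- config$anchor_px[1]; ay <- config$anchor_px[2]
  X <- matrix(seq_len(nrow(projection)), nrow(projection), ncol(projection))
  Y <- matrix(seq_len(ncol(projection)), nrow(projection), ncol(projection),
              byrow = TRUE)
  r <- sqrt((X - ax)^2 + (Y - ay)^2)
  keep <- scaled > thr & r >= r_inner * L & r <= r_outer * L
  if (!any(keep))
    abort("No foreground above threshold inside the measurement annulus.",
          class = "windsock_empty_detection")
  ang <- atan2(Y[keep] - ay, X[keep] - ax) * 180 / pi        # (-180, 180]
  wts <- scaled[keep] - thr
  edges <- seq(-180, 180, by = bin_deg)
  bin <- cut(ang, edges, include.lowest = TRUE, labels = FALSE)
  w <- vapply(split(wts, factor(bin, levels = seq_len(length(edges) - 1))),
              sum, numeric(1))
  occupied <- which(w >= occupancy * max(w))
  if (length(occupied) == length(w)) return(360)
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  occ <- sort(centers[occupied])
  gaps <- if (length(occ) == 1) 360 else
    c(diff(occ), 360 - (occ[length(occ)] - occ[1]))
  # largest empty arc, net of the bins' own width
  min(360, 360 - (max(gaps) - bin_deg))
}

#' Measure Phi through the full image pipeline
#'
#' Convenience chain render -> per-frame Gaussian blur -> maximum time
#' projection -> [measure_angle_extent()], for validating the image-based
#' measurement against the trajectory-based [total_angle()].
#'
#' @inheritParams render_stack
#' @param ... Passed to [measure_angle_extent()].
#' @return Phi in degrees.
#' @export
pipeline_phi <- function(traj, length_um, config = imaging_config(),
                         protocol = sampling_protocol(), seed = 1,
                         noise = TRUE, ...) {
  stack <- render_stack(traj, length_um, config, protocol, seed, noise)
  stack <- blur_frames(stack, config$blur_radius_px)
  proj <- max_time_projection(stack)
  measure_angle_extent(proj, config, length_um, ...)
}

#' Write / read a 16-bit grayscale TIFF stack
#'
#' Frames are stored as TIFF pages. Intensities are scaled by `max_count`
#' into the unit range the TIFF writer expects; reading reverses the scale.
#'
#' @param frames 3-D array `[x, y, frame]`.
#' @param path Output file.
#' @param max_count Full-scale intensity mapped to 65535.
#' @return `write_stack_tiff()` returns `path` invisibly;
#'   `read_stack_tiff()` returns the 3-D array.
#' @export
write_stack_tiff <- function(frames, path, max_count = 4096) {
  pages <- lapply(seq_len(dim(frames)[3]), function(i)
    pmin(pmax(t(frames[, , i]) / max_count, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, max_count = 4096) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- t(pages[[i]]) * max_count
  arr
}
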