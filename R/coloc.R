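#' Binary region masks for point patterns
#'
#' A mask is a logical raster plus a pixel size; points live in micrometre
#' coordinates with the raster's lower-left corner at the origin.
#' `ellipse_mask()` rasterises an axis-aligned ellipse (the default 30 x 20
#' um footprint approximates an adherent HeLa cell); `rect_mask()` covers the
#' full rectangle.
#'
#' @param width_um,height_um Bounding-box dimensions, um.
#' @param pixel_um Pixel size, um.
#' @return An object of class `windsock_mask`.
#' @export
ellipse_mask <- function(width_um = 30, height_um = 20, pixel_um = 0.1) {
  nx <- ceiling(width_um / pixel_um)
  ny <- ceiling(height_um / pixel_um)
  cx <- width_um / 2; cy <- height_um / 2
  x <- (seq_len(nx) - 0.5) * pixel_um
  y <- (seq_len(ny) - 0.5) * pixel_um
  r <- outer(((x - cx) / (width_um / 2))^2, ((y - cy) / (height_um / 2))^2, `+`)
  structure(list(raster = r <= 1, pixel_um = pixel_um),
            class = "windsock_mask")
}

#' @rdname ellipse_mask
#' @export
rect_mask <- function(width_um = 30, height_um = 20, pixel_um = 0.1) {
  nx <- ceiling(width_um / pixel_um)
  ny <- ceiling(height_um / pixel_um)
  structure(list(raster = matrix(TRUE, nx, ny), pixel_um = pixel_um),
            class = "windsock_mask")
}

#' @export
print.windsock_mask <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<windsock_mask> %g x %g um at %g um/px (%.0f%% inside)\n",
              d[1] * x$pixel_um, d[2] * x$pixel_um, x$pixel_um,
              100 * mean(x$raster)))
  invisible(x)
}

#' Area of a mask
#' @param mask A `windsock_mask`.
#' @return Area of the TRUE region, um^2.
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "windsock_mask"))
  sum(mask$raster) * mask$pixel_um^2
}

#' Are points inside a mask?
#' @param points Data frame with `x_um`, `y_um`.
#' @param mask A `windsock_mask`.
#' @return Logical vector.
#' @export
in_mask <- function(points, mask) {
  stopifnot(inherits(mask, "windsock_mask"))
  d <- dim(mask$raster)
  ix <- ceiling(points$x_um / mask$pixel_um)
  iy <- ceiling(points$y_um / mask$pixel_um)
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2]
  ok[ok] <- mask$raster[cbind(ix[ok], iy[ok])]
  ok
}

#' Uniform random points inside a mask
#'
#' Rejection sampling from the bounding box.
#'
#' @param n Number of points.
#' @param mask A `windsock_mask`.
#' @param seed Optional RNG seed.
#' @return Tibble with `x_um`, `y_um`.
#' @export
sample_in_mask <- function(n, mask, seed = NULL) {
  stopifnot(inherits(mask, "windsock_mask"))
  if (!is.null(seed)) set.seed(seed)
  frac <- mean(mask$raster)
  if (frac == 0)
    abort("Mask has no interior pixels.", class = "windsock_placement_error")
  d <- dim(mask$raster)
  wx <- d[1] * mask$pixel_um; wy <- d[2] * mask$pixel_um
  xs <- numeric(0); ys <- numeric(0)
  guard <- 0L
  while (length(xs) < n) {
    m <- ceiling((n - length(xs)) / frac * 1.2) + 16L
    px <- runif(m, 0, wx); py <- runif(m, 0, wy)
    keep <- in_mask(tibble(x_um = px, y_um = py), mask)
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
    guard <- guard + 1L
    if (guard > 1000L)
      abort("Mask too small for the requested point count.",
            class = "windsock_placement_error")
  }
  tibble(x_um = xs[seq_len(n)], y_um = ys[seq_len(n)])
}

#' Fraction of seed points colocalized with antibody points
#'
#' A seed counts as colocalized when at least one antibody localisation lies
#' within `radius_um` (Euclidean). Monotone non-decreasing in the radius.
#'
#' @param seeds,antibodies Data frames with columns `x_um`, `y_um`.
#' @param radius_um Colocalization radius, um. The criterion radius is an
#'   analysis parameter and is recorded in results; default 0.5 um (about
#'   two confocal pixels at 60x).
#' @return Colocalized fraction in \[0, 1\].
#' @export
coloc_fraction <- function(seeds, antibodies, radius_um = 0.5) {
  if (!is.data.frame(seeds) || nrow(seeds) == 0)
    abort("`seeds` must contain at least one point.",
          class = "windsock_undefined_error")
  if (radius_um <= 0)
    abort("`radius_um` must be positive.", class = "windsock_domain_error")
  if (!is.data.frame(antibodies) || nrow(antibodies) == 0) return(0)
  mean(has_neighbor_within(seeds$x_um, seeds$y_um,
                           antibodies$x_um, antibodies$y_um, radius_um))
}

#' Randomized-placement null for colocalization
#'
#' Keeps the antibody pattern fixed and repeatedly redraws the same number of
#' seed positions uniformly inside the cell mask (the "stochastic
#' attachment" null), recomputing the colocalized fraction each time. The
#' permutation p-value uses the add-one rule
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}.
#'
#' @inheritParams coloc_fraction
#' @param mask `windsock_mask` for the cell region.
#' @param n_perm Number of randomisations (>= 100).
#' @param seed RNG seed.
#' @return Object of class `windsock_coloc`: list with `observed`,
#'   `null_fractions`, `null_mean`, `null_sd`, `p_value`, `n_perm`,
#'   `radius_um`.
#' @export
randomized_null <- function(seeds, antibodies, mask, radius_um = 0.5,
                            n_perm = 199, seed = 1) {
  if (n_perm < 100)
    abort("`n_perm` must be >= 100.", class = "windsock_domain_error")
  observed <- coloc_fraction(seeds, antibodies, radius_um)
  set.seed(seed)
  nulls <- vapply(seq_len(n_perm), function(i) {
    rnd <- sample_in_mask(nrow(seeds), mask)
    coloc_fraction(rnd, antibodies, radius_um)
  }, numeric(1))
  structure(list(observed = observed, null_fractions = nulls,
                 null_mean = mean(nulls), null_sd = sd(nulls),
                 p_value = (1 + sum(nulls >= observed)) / (1 + n_perm),
                 n_perm = n_perm, radius_um = radius_um),
            class = "windsock_coloc")
}

#' @export
print.windsock_coloc <- function(x, ...) {
  cat(sprintf(paste0("<windsock_coloc> observed %.3f vs null %.3f +/- %.3f ",
                     "(p = %.4g, %d randomisations, r = %g um)\n"),
              x$observed, x$null_mean, x$null_sd, x$p_value, x$n_perm,
              x$radius_um))
  invisible(x)
}

#' Cohort summary of per-cell colocalized fractions
#'
#' Mean over cells with a t-based confidence interval, matching how per-cell
#' fractions are reported for an imaged cohort.
#'
#' @param fractions Numeric vector of per-cell fractions, or a data frame
#'   with a `fraction` column.
#' @param conf_level Confidence level.
#' @return Tibble with `mean`, `ci_lower`, `ci_upper`, `ci_half`, `n_cells`.
#' @export
per_cell_summary <- function(fractions, conf_level = 0.95) {
  f <- if (is.data.frame(fractions)) fractions$fraction else fractions
  if (length(f) < 2)
    abort("Need at least 2 cells.", class = "windsock_domain_error")
  half <- qt(1 - (1 - conf_level) / 2, df = length(f) - 1) *
    sd(f) / sqrt(length(f))
  tibble(mean = mean(f), ci_lower = mean(f) - half,
         ci_upper = mean(f) + half, ci_half = half, n_cells = length(f))
}
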