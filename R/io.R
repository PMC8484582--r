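#' Write a trajectory to CSV with a JSON parameter sidecar
#'
#' The CSV holds `time_s, phi_rad`; every simulation parameter, the seed and
#' the package version go to `<path>.json` so a run can be reproduced
#' exactly.
#'
#' @param traj A trajectory tibble from [simulate_trajectory()].
#' @param path Output CSV path.
#' @param overwrite Overwrite existing files?
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, overwrite = FALSE) {
  sidecar <- paste0(path, ".json")
  if (!overwrite && (file.exists(path) || file.exists(sidecar)))
    abort(sprintf("'%s' exists; pass overwrite = TRUE.", path),
          class = "windsock_io_error")
  readr::write_csv(as_tibble(traj)[c("time_s", "phi_rad")], path)
  meta <- attr(traj, "params") %||% list()
  meta$package_version <- as.character(utils::packageVersion("windsock"))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    attr(out, "params") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  class(out) <- c("windsock_trajectory", class(out))
  out
}

#' Write / read a calibration curve CSV
#'
#' Columns `shear_dyn_cm2, phi_mean_deg, phi_sd_deg, n_rods` (the per-rod
#' pool is not serialised; re-run [build_calibration()] with the recorded
#' seed to reproduce it).
#'
#' @param cal A [build_calibration()] result.
#' @param path CSV path.
#' @param overwrite Overwrite an existing file?
#' @return `path` / a tibble.
#' @export
write_calibration <- function(cal, path, overwrite = FALSE) {
  stopifnot(inherits(cal, "windsock_calibration"))
  if (!overwrite && file.exists(path))
    abort(sprintf("'%s' exists; pass overwrite = TRUE.", path),
          class = "windsock_io_error")
  readr::write_csv(cal$curve[c("shear_dyn_cm2", "phi_mean_deg", "phi_sd_deg",
                               "n_rods")], path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read / write decay series and point-pattern CSVs
#'
#' Decay series use columns `time_h, fraction` (optional `cell`); point
#' patterns use `x_um, y_um, channel` (optional `cell`).
#'
#' @param x Tibble to write.
#' @param path CSV path.
#' @param overwrite Overwrite an existing file?
#' @return `path` / a tibble.
#' @export
write_decay_series <- function(x, path, overwrite = FALSE) {
  if (!overwrite && file.exists(path))
    abort(sprintf("'%s' exists; pass overwrite = TRUE.", path),
          class = "windsock_io_error")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_decay_series
#' @export
read_decay_series <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname write_decay_series
#' @export
write_points <- function(x, path, overwrite = FALSE) {
  if (!overwrite && file.exists(path))
    abort(sprintf("'%s' exists; pass overwrite = TRUE.", path),
          class = "windsock_io_error")
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_decay_series
#' @export
read_points <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
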