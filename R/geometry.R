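#' Spatial calibration of a serial-section image stack
#'
#' Converts pixel and section coordinates to micrometres: `pixel_size_um`
#' scales x/y, `section_thickness_um` is the nominal optical-section
#' spacing (0.5 um for the imaging protocol this tool targets). The axial
#' step uses the nominal thickness only; no refractive-index correction
#' is applied.
#'
#' @param pixel_size_um Micrometres per pixel, strictly positive.
#' @param section_thickness_um Micrometres per optical section, strictly
#'   positive; default 0.5.
#' @return An object of class `calibration`.
#' @export
calibration <- function(pixel_size_um, section_thickness_um = 0.5) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    rlang::abort("pixel_size_um must be a single positive number",
                 class = "spinemorph_domain_error")
  }
  if (!is.numeric(section_thickness_um) ||
      length(section_thickness_um) != 1L ||
      !is.finite(section_thickness_um) || section_thickness_um <= 0) {
    rlang::abort("section_thickness_um must be a single positive number",
                 class = "spinemorph_domain_error")
  }
  structure(list(pixel_size_um = pixel_size_um,
                 section_thickness_um = section_thickness_um),
            class = "calibration")
}

#' Derive the pixel size from a known-length calibration line
#'
#' Given a line of known physical length drawn on the image and its
#' measured length in pixels, returns micrometres per pixel.
#'
#' @param known_length_um Physical length of the calibration line (um).
#' @param measured_length_px Its measured length in pixels.
#' @return Pixel size in um/px.
#' @examples
#' calibrate_pixel_size(10, 100) # 0.1 um/px
#' @export
calibrate_pixel_size <- function(known_length_um, measured_length_px) {
  if (!is.numeric(known_length_um) || !is.numeric(measured_length_px) ||
      any(!is.finite(known_length_um)) || any(!is.finite(measured_length_px)) ||
      any(known_length_um <= 0) || any(measured_length_px <= 0)) {
    rlang::abort("calibration lengths must be positive",
                 class = "spinemorph_domain_error")
  }
  known_length_um / measured_length_px
}

#' Calibrated 2D line length
#'
#' Euclidean distance between two pixel-coordinate points, scaled to
#' micrometres. This is the measurement behind a spine head width: a
#' straight line drawn across the head, perpendicular to the spine axis.
#'
#' @param p1,p2 Numeric `(x, y)` pairs in pixels.
#' @param cal A [calibration()].
#' @return Length in micrometres.
#' @export
line_length_2d <- function(p1, p2, cal) {
  stopifnot(inherits(cal, "calibration"),
            length(p1) == 2L, length(p2) == 2L)
  sqrt(sum((as.numeric(p2) - as.numeric(p1))^2)) * cal$pixel_size_um
}

#' Construct a Z-polyline
#'
#' A Z-polyline is a 3D path clicked through successive optical sections:
#' each vertex has pixel coordinates `x`, `y` and a 0-based integer
#' `section`. Consecutive vertices may change any coordinate. At least
#' two vertices are required.
#'
#' @param x,y Numeric vertex coordinates in pixels.
#' @param section Integer optical-section indices (0-based, >= 0).
#' @return A tibble of class `z_polyline` with columns `x`, `y`,
#'   `section`.
#' @export
z_polyline <- function(x, y, section) {
  n <- length(x)
  if (n < 2L || length(y) != n || length(section) != n) {
    rlang::abort("a Z-polyline needs >= 2 vertices with equal-length x, y, section",
                 class = "spinemorph_domain_error")
  }
  if (any(section < 0) || any(section != round(section))) {
    rlang::abort("section indices must be non-negative integers",
                 class = "spinemorph_domain_error")
  }
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        section = as.integer(round(section)))
  class(out) <- c("z_polyline", class(out))
  out
}

#' Calibrated 3D length of a Z-polyline
#'
#' Sums, over consecutive vertex pairs, the 3D segment length
#' `sqrt((dx * pixel)^2 + (dy * pixel)^2 + (dsection * thickness)^2)`.
#' This is the raw polyline length with no smoothing or resampling,
#' matching how serial-section tracing tools report Z-trace lengths.
#'
#' @param poly A [z_polyline()] (or any data frame with `x`, `y`,
#'   `section` columns).
#' @param cal A [calibration()].
#' @return Length in micrometres.
#' @examples
#' cal <- calibration(1, 0.5)
#' ztrace_length(z_polyline(c(0, 3), c(0, 4), c(0, 0)), cal) # 5
#' ztrace_length(z_polyline(c(0, 0), c(0, 0), c(0, 4)), cal) # 2
#' @export
ztrace_length <- function(poly, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (!all(c("x", "y", "section") %in% names(poly))) {
    rlang::abort("polyline needs x, y, section columns",
                 class = "spinemorph_domain_error")
  }
  n <- nrow(poly)
  if (n < 2L) {
    rlang::abort("a Z-polyline needs at least 2 vertices",
                 class = "spinemorph_domain_error")
  }
  dx <- diff(poly$x) * cal$pixel_size_um
  dy <- diff(poly$y) * cal$pixel_size_um
  dz <- diff(as.numeric(poly$section)) * cal$section_thickness_um
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

#' Read ground-truth polylines
#'
#' Reads a polyline CSV (columns `x`, `y`, `section`, `name`) as emitted
#' by the synthetic generator and returns one [z_polyline()] per trace
#' name, preserving vertex order.
#'
#' @param path Path to the CSV file.
#' @return A named list of `z_polyline` objects.
#' @export
read_polylines <- function(path) {
  raw <- readr::read_csv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE,
                         col_types = readr::cols(
                           x = "d", y = "d", section = "i",
                           .default = "c"))
  if (!all(c("x", "y", "section", "name") %in% names(raw))) {
    rlang::abort(sprintf("%s: expected columns x, y, section, name", path),
                 class = "spinemorph_schema_error")
  }
  split(raw, factor(raw$name, levels = unique(raw$name))) |>
    lapply(function(d) z_polyline(d$x, d$y, d$section))
}

#' @rdname read_polylines
#' @param polylines Named list of `z_polyline` objects.
#' @return `write_polylines()`: `path`, invisibly.
#' @export
write_polylines <- function(polylines, path) {
  stopifnot(rlang::is_named(polylines))
  rows <- purrr::imap(polylines, function(p, nm) {
    tibble::tibble(x = p$x, y = p$y, section = p$section, name = nm)
  })
  readr::write_csv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}
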