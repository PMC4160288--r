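#' Default per-type sampling regions
#'
#' Width/length sampling boxes for each spine type, kept a configurable
#' margin away from every classification threshold so that noise-free
#' samples are always classified back to the type they were drawn from.
#' Widths and lengths are uniform within a region; for `thin` and `stub`
#' the width bound depends on the drawn length through the LWR
#' constraint. These are deliberately simple study-condition regions, not
#' an empirical model of real within-type morphology.
#'
#' @param margin_um Distance kept from the length/width thresholds (um).
#' @param margin_lwr Relative margin kept from the LWR threshold.
#' @param thresholds A [spine_thresholds()].
#' @return Named list of regions, one per [spine_types()] entry. Each has
#'   `length_range`, and either `width_range` or `width_of_length` (a
#'   function of the drawn length returning the admissible width range).
#' @export
spine_regions <- function(margin_um = 0.05, margin_lwr = 0.05,
                          thresholds = spine_thresholds()) {
  th <- thresholds
  wmax <- th$mush_min_width_um - margin_um         # stay out of mushroom
  lmax_sub_filo <- th$filo_min_length_um - margin_um
  regions <- list(
    # branched spines are flagged by name, not geometry; give them a
    # plausible wide-headed shape
    branch = list(length_range = c(1.0, lmax_sub_filo),
                  width_range = c(th$mush_min_width_um + margin_um, 1.0)),
    filo = list(length_range = c(th$filo_min_length_um + margin_um, 4.0),
                width_range = c(0.1, wmax)),
    mush = list(length_range = c(0.4, lmax_sub_filo),
                width_range = c(th$mush_min_width_um + margin_um, 1.2)),
    long_thin = list(
      length_range = c(th$long_thin_min_length_um + margin_um,
                       lmax_sub_filo),
      width_range = c(0.1, wmax)),
    thin = list(
      length_range = c(0.4, th$long_thin_min_length_um - margin_um),
      # LWR = length / width > thin_min_lwr * (1 + margin), and the
      # width must also stay below the mushroom cutoff
      width_of_length = function(len) {
        c(0.1, min(wmax, len / (th$thin_min_lwr * (1 + margin_lwr))))
      }),
    stub = list(
      length_range = c(0.2, 0.5),
      # LWR = length / width <= thin_min_lwr * (1 - margin)
      width_of_length = function(len) {
        c(len / (th$thin_min_lwr * (1 - margin_lwr)), wmax)
      })
  )
  validate_regions(regions, thresholds)
  regions
}

validate_regions <- function(regions, thresholds) {
  missing_types <- setdiff(setdiff(spine_types(), "branch"), names(regions))
  if (length(missing_types) > 0L) {
    rlang::abort(sprintf("no sampling region for type(s): %s",
                         paste(missing_types, collapse = ", ")),
                 class = "spinemorph_config_error")
  }
  u <- seq(0, 1, length.out = 11)
  for (ty in setdiff(names(regions), "branch")) {
    r <- regions[[ty]]
    grid <- expand.grid(ul = u, uw = u)
    len <- r$length_range[1] + grid$ul * diff(r$length_range)
    wr <- if (!is.null(r$width_range)) {
      matrix(rep(r$width_range, each = length(len)), ncol = 2)
    } else {
      t(vapply(len, r$width_of_length, numeric(2)))
    }
    if (any(wr[, 2] <= wr[, 1]) || any(wr[, 1] <= 0)) {
      rlang::abort(sprintf(
        "sampling region for \"%s\" is empty or non-positive", ty),
        class = "spinemorph_config_error")
    }
    wid <- wr[, 1] + grid$uw * (wr[, 2] - wr[, 1])
    got <- classify_spine(wid, len, branch = FALSE, thresholds)
    if (!all(got == ty)) {
      rlang::abort(sprintf(
        "sampling region for \"%s\" is inconsistent with the thresholds (grid point classified as \"%s\")",
        ty, as.character(got[got != ty][1])),
        class = "spinemorph_config_error")
    }
  }
  invisible(regions)
}

#' Synthetic-data generator configuration
#'
#' Describes a simulated tracing session: number of dendritic segments,
#' their length, the protrusion density, the spine-type mixture, and the
#' per-type width/length sampling regions. Defaults emulate a healthy
#' ~10 um segment of cortical dendrite at around one protrusion per
#' micrometre with a mixed, mature-leaning type composition.
#'
#' @param seed Integer seed; all randomness in [generate_dataset()] flows
#'   from it.
#' @param n_dendrites Number of dendritic segments.
#' @param segment_length_um Straight (reference-line) segment length, um.
#' @param density_per_um Protrusions per um of dendrite contour length.
#' @param type_probabilities Named probabilities over [spine_types()];
#'   must sum to 1.
#' @param regions Per-type sampling regions, see [spine_regions()].
#' @param noise_sd_um Gaussian measurement noise added to widths and
#'   lengths (um); 0 gives exactly recoverable labels.
#' @param tortuosity_range Multiplier range mapping straight length to
#'   Z-trace contour length (contours are never shorter than chords).
#' @param calibration A [calibration()] used for ground-truth polylines.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_dendrites = 10L,
                             segment_length_um = 10,
                             density_per_um = 1.0,
                             type_probabilities = c(
                               branch = 0.02, filo = 0.10, mush = 0.25,
                               long_thin = 0.13, thin = 0.30, stub = 0.20),
                             regions = spine_regions(),
                             noise_sd_um = 0,
                             tortuosity_range = c(1.02, 1.12),
                             calibration = spinemorph::calibration(0.1, 0.5)) {
  p <- type_probabilities[spine_types()]
  if (anyNA(p) || abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
    rlang::abort(
      "type_probabilities must be named over all spine types, be non-negative and sum to 1",
      class = "spinemorph_config_error")
  }
  stopifnot(n_dendrites >= 1L, segment_length_um > 0, density_per_um >= 0,
            noise_sd_um >= 0, length(tortuosity_range) == 2L,
            tortuosity_range[1] >= 1, diff(tortuosity_range) >= 0)
  validate_regions(regions, spine_thresholds())
  structure(list(
    seed = as.integer(seed), n_dendrites = as.integer(n_dendrites),
    segment_length_um = segment_length_um, density_per_um = density_per_um,
    type_probabilities = p, regions = regions, noise_sd_um = noise_sd_um,
    tortuosity_range = tortuosity_range, calibration = calibration
  ), class = "generator_config")
}

#' Two-group developmental ("maturation") scenario
#'
#' A preset pair of generator configurations contrasting an immature-like
#' group (sparser protrusions, many long filopodia, few mushrooms) with a
#' mature-like group (denser protrusions, many mushrooms, few
#' filopodia), the direction of change expected across early postnatal
#' cortical development.
#'
#' @param seed Integer; the two groups get distinct sub-seeds derived
#'   from it.
#' @param n_dendrites Dendrites per group.
#' @return Named list with `generator_config` elements `immature` and
#'   `mature`.
#' @export
maturation_scenario <- function(seed = 1L, n_dendrites = 15L) {
  list(
    immature = generator_config(
      seed = derive_seed(seed, 1L), n_dendrites = n_dendrites,
      density_per_um = 0.6,
      type_probabilities = c(branch = 0.02, filo = 0.25, mush = 0.08,
                             long_thin = 0.20, thin = 0.30, stub = 0.15)),
    mature = generator_config(
      seed = derive_seed(seed, 2L), n_dendrites = n_dendrites,
      density_per_um = 1.0,
      type_probabilities = c(branch = 0.02, filo = 0.04, mush = 0.35,
                             long_thin = 0.09, thin = 0.25, stub = 0.25))
  )
}

# deterministic sub-stream seeds, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919) %%
               2147483647)
}

#' Draw one spine's width and length for a given type
#'
#' Samples uniformly within the type's region; with `noise_sd_um = 0`
#' the classifier always recovers the requested type (regions keep a
#' margin from every threshold).
#'
#' @param type One of [spine_types()].
#' @param config A [generator_config()].
#' @param n Number of spines to draw.
#' @return Tibble with columns `width_um`, `length_um`.
#' @export
sample_spine <- function(type, config, n = 1L) {
  r <- config$regions[[type]]
  if (is.null(r)) {
    rlang::abort(sprintf("no sampling region configured for \"%s\"", type),
                 class = "spinemorph_config_error")
  }
  len <- stats::runif(n, r$length_range[1], r$length_range[2])
  wid <- if (!is.null(r$width_range)) {
    stats::runif(n, r$width_range[1], r$width_range[2])
  } else {
    b <- t(vapply(len, r$width_of_length, numeric(2)))
    stats::runif(n, b[, 1], b[, 2])
  }
  tibble::tibble(width_um = wid, length_um = len)
}

#' Realize a 3D polyline of prescribed length
#'
#' Constructs a Z-polyline whose calibrated [ztrace_length()] equals
#' `length_um` (to floating-point accuracy), emulating a hand-clicked
#' Z-trace through the optical sections. Styles: `"mixed"` wanders in x,
#' y and section; `"planar"` stays on one section; `"axial"` moves only
#' through sections (requires `length_um` to be a whole number of
#' section hops).
#'
#' @param length_um Target 3D length, > 0.
#' @param cal A [calibration()].
#' @param n_segments Number of polyline segments (`mixed`/`planar`).
#' @param style One of `"mixed"`, `"planar"`, `"axial"`.
#' @param start_section First section index.
#' @return A [z_polyline()].
#' @export
realize_polyline <- function(length_um, cal, n_segments = 6L,
                             style = c("mixed", "planar", "axial"),
                             start_section = 0L) {
  style <- match.arg(style)
  if (!is.numeric(length_um) || length_um <= 0) {
    rlang::abort("length_um must be positive",
                 class = "spinemorph_domain_error")
  }
  th <- cal$section_thickness_um
  if (style == "axial") {
    hops <- length_um / th
    if (abs(hops - round(hops)) > 1e-9 || round(hops) < 1) {
      rlang::abort(
        "axial-only polyline needs a length that is a positive whole number of section hops",
        class = "spinemorph_generation_error")
    }
    hops <- as.integer(round(hops))
    return(z_polyline(rep(0, hops + 1L), rep(0, hops + 1L),
                      start_section + 0:hops))
  }
  k <- max(2L, as.integer(n_segments))
  # random positive partition of the total length over k segments
  w <- stats::runif(k, 0.5, 1.5)
  s <- length_um * w / sum(w)
  if (style == "planar") {
    dz_sections <- rep(0L, k)
  } else {
    # climb a section when the segment is long enough to afford the hop
    dz_sections <- ifelse(s > th * 1.05,
                          sample(c(-1L, 0L, 1L), k, replace = TRUE),
                          0L)
  }
  axial <- abs(dz_sections) * th
  planar <- sqrt(pmax(s^2 - axial^2, 0))
  theta <- stats::runif(k, 0, 2 * pi)
  dx_px <- planar * cos(theta) / cal$pixel_size_um
  dy_px <- planar * sin(theta) / cal$pixel_size_um
  sections <- start_section + cumsum(c(0L, dz_sections))
  if (min(sections) < 0L) sections <- sections - min(sections)
  z_polyline(cumsum(c(0, dx_px)), cumsum(c(0, dy_px)), sections)
}

#' Generate a synthetic tracing session on disk
#'
#' Emits the file structure a real session produces: one Trace List CSV
#' per dendrite (Export List A: straight reference line plus spine head
#' widths, with the manual `branch` suffix on branched spines) and one
#' Z-Trace List CSV for the whole series (Export List B: dendrite
#' contour lengths plus spine lengths). Ground truth (true type, true
#' width/length, per-dendrite density) and, optionally, the 3D polylines
#' whose lengths are the reported Z-lengths, are written alongside.
#'
#' Deterministic given `config$seed`; each dendrite draws from its own
#' deterministically derived sub-stream, so increasing `n_dendrites`
#' never reshuffles earlier dendrites.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @param write_polylines If `TRUE`, also emit `polylines.csv` with a
#'   ground-truth Z-polyline per spine length and dendrite contour.
#' @return Invisibly, a list with `trace_files` (per-dendrite Export
#'   List A paths), `ztrace_file`, `ground_truth_file`, `polyline_file`
#'   (or `NULL`), plus the `ground_truth` and `dendrite_truth` tibbles.
#' @export
generate_dataset <- function(config, dir, write_polylines = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  cal <- config$calibration
  trace_files <- character(config$n_dendrites)
  z_rows <- list()
  truth <- list()
  den_truth <- list()
  polys <- list()

  for (d in seq_len(config$n_dendrites)) {
    set.seed(derive_seed(config$seed, d))
    straight <- config$segment_length_um
    z_len <- straight * stats::runif(1, config$tortuosity_range[1],
                                     config$tortuosity_range[2])
    n_sp <- max(0L, as.integer(round(config$density_per_um * z_len)))
    types <- if (n_sp > 0L) {
      sample(spine_types(), n_sp, replace = TRUE,
             prob = config$type_probabilities)
    } else {
      character()
    }
    geom <- purrr::map(types, ~ sample_spine(.x, config, 1L)) |>
      dplyr::bind_rows()
    width_obs <- geom$width_um
    length_obs <- geom$length_um
    if (config$noise_sd_um > 0 && n_sp > 0L) {
      width_obs <- pmax(0.01, width_obs +
                          stats::rnorm(n_sp, 0, config$noise_sd_um))
      length_obs <- pmax(0, length_obs +
                           stats::rnorm(n_sp, 0, config$noise_sd_um))
    }
    is_branch <- types == "branch"
    width_names <- character(0)
    zlen_names <- character(0)
    if (n_sp > 0L) {
      width_names <- render_trace_name(d, "spine_width",
                                       spine_index = seq_len(n_sp),
                                       branch = is_branch)
      zlen_names <- render_trace_name(d, "spine_zlen",
                                      spine_index = seq_len(n_sp))
    }

    a_rows <- tibble::tibble(
      section = rep(10L, n_sp + 1L),
      name = c(render_trace_name(d, "straight_ref"), width_names),
      length_um = c(straight, width_obs)
    )
    trace_files[d] <- file.path(dir, sprintf("d%d_traces.csv", d))
    write_trace_list(a_rows, trace_files[d])

    z_rows[[d]] <- tibble::tibble(
      name = c(render_trace_name(d, "dendrite_zlen"), zlen_names),
      length_um = c(z_len, length_obs)
    )

    if (n_sp > 0L) {
      truth[[d]] <- tibble::tibble(
        den_id = as.character(d), spine_index = seq_len(n_sp),
        true_type = types, width_um = geom$width_um,
        length_um = geom$length_um
      )
    }
    den_truth[[d]] <- tibble::tibble(
      den_id = as.character(d), straight_length_um = straight,
      z_length_um = z_len, n_spines = n_sp,
      true_density_per_um = n_sp / z_len
    )
    if (write_polylines) {
      pl <- c(
        stats::setNames(list(realize_polyline(z_len, cal)),
                        render_trace_name(d, "dendrite_zlen")),
        stats::setNames(
          purrr::map(length_obs, ~ realize_polyline(.x, cal,
                                                    n_segments = 3L)),
          zlen_names)
      )
      polys <- c(polys, pl)
    }
  }

  ztrace_file <- file.path(dir, "ztraces.csv")
  write_ztrace_list(dplyr::bind_rows(z_rows), ztrace_file)

  ground_truth <- dplyr::bind_rows(truth)
  dendrite_truth <- dplyr::bind_rows(den_truth)
  ground_truth_file <- file.path(dir, "ground_truth.csv")
  readr::write_csv(ground_truth, ground_truth_file, progress = FALSE)
  readr::write_csv(dendrite_truth, file.path(dir, "dendrite_truth.csv"),
                   progress = FALSE)

  polyline_file <- NULL
  if (write_polylines) {
    polyline_file <- file.path(dir, "polylines.csv")
    write_polylines(polys, polyline_file)
  }

  invisible(list(
    trace_files = trace_files, ztrace_file = ztrace_file,
    ground_truth_file = ground_truth_file, polyline_file = polyline_file,
    ground_truth = ground_truth, dendrite_truth = dendrite_truth
  ))
}
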