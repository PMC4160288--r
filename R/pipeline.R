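#' Pipeline run configuration
#'
#' Bundles every tunable of an analysis run: classification thresholds,
#' spatial calibration, the density denominator, whether branched spines
#' enter the per-dendrite means, and the CSV column mapping. Defaults are
#' the method's published operating point: thresholds 2.0 / 0.6 / 1.0 /
#' 1.0 and 0.5 um optical sections.
#'
#' @param thresholds A [spine_thresholds()].
#' @param calibration A [calibration()].
#' @param density_denominator `"ztrace"` or `"straight"`.
#' @param include_branch_in_means Logical.
#' @param columns A [trace_columns()] mapping for input files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(thresholds = spine_thresholds(),
                       calibration = spinemorph::calibration(0.1, 0.5),
                       density_denominator = c("ztrace", "straight"),
                       include_branch_in_means = TRUE,
                       columns = trace_columns()) {
  stopifnot(inherits(thresholds, "spine_thresholds"),
            inherits(calibration, "calibration"))
  structure(list(
    thresholds = thresholds,
    calibration = calibration,
    density_denominator = match.arg(density_denominator),
    include_branch_in_means = isTRUE(include_branch_in_means),
    columns = columns
  ), class = "run_config")
}

#' Load a run configuration from a flat key-value file
#'
#' Reads a plain `key = value` (or `key: value`) text file overriding the
#' defaults of [run_config()]. Recognised keys: `filo_min_length_um`,
#' `mush_min_width_um`, `long_thin_min_length_um`, `thin_min_lwr`,
#' `pixel_size_um`, `section_thickness_um`, `density_denominator`,
#' `include_branch_in_means`, `col_name`, `col_length`, `col_section`.
#' Unknown keys are an error (they are usually typos).
#'
#' @param path Path to the config file; `NULL` gives pure defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- stringr::str_match(lines, "^([A-Za-z_0-9]+)\\s*[:=]\\s*(.+)$")
  if (anyNA(kv[, 1])) {
    rlang::abort(sprintf("%s: cannot parse line: %s", path,
                         lines[is.na(kv[, 1])][1]),
                 class = "spinemorph_config_error")
  }
  vals <- stats::setNames(trimws(kv[, 3]), kv[, 2])
  known <- c("filo_min_length_um", "mush_min_width_um",
             "long_thin_min_length_um", "thin_min_lwr", "pixel_size_um",
             "section_thickness_um", "density_denominator",
             "include_branch_in_means", "col_name", "col_length",
             "col_section")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    rlang::abort(sprintf("%s: unknown config key(s): %s", path,
                         paste(unknown, collapse = ", ")),
                 class = "spinemorph_config_error")
  }
  num <- function(key, default) {
    if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  }
  chr <- function(key, default) {
    if (key %in% names(vals)) vals[[key]] else default
  }
  run_config(
    thresholds = spine_thresholds(
      filo_min_length_um = num("filo_min_length_um", 2.0),
      mush_min_width_um = num("mush_min_width_um", 0.6),
      long_thin_min_length_um = num("long_thin_min_length_um", 1.0),
      thin_min_lwr = num("thin_min_lwr", 1.0)),
    calibration = calibration(
      pixel_size_um = num("pixel_size_um", 0.1),
      section_thickness_um = num("section_thickness_um", 0.5)),
    density_denominator = chr("density_denominator", "ztrace"),
    include_branch_in_means =
      tolower(chr("include_branch_in_means", "true")) %in%
        c("true", "yes", "1"),
    columns = trace_columns(name = chr("col_name", "Name"),
                            length = chr("col_length", "Length"),
                            section = chr("col_section", "Section"))
  )
}

config_metadata <- function(config) {
  th <- config$thresholds
  sprintf(
    paste0("# spinemorph %s | thresholds: filo_len>%g mush_width>%g ",
           "long_thin_len>%g thin_lwr>%g%s | denominator: %s | ",
           "branch_in_means: %s"),
    as.character(utils::packageVersion("spinemorph")),
    th$filo_min_length_um, th$mush_min_width_um,
    th$long_thin_min_length_um, th$thin_min_lwr,
    if (is_default_thresholds(th)) "" else " (non-default)",
    config$density_denominator,
    tolower(config$include_branch_in_means)
  )
}

write_audited_csv <- function(df, path, config) {
  readr::write_lines(config_metadata(config), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Classify a tracing session from its exports
#'
#' End-to-end per-spine analysis: read the Trace List files (Export
#' List A, typically one per dendrite) and the Z-Trace List (Export
#' List B), pair widths with lengths, compute LWRs and assign types.
#'
#' @param trace_files Character vector of Export List A paths.
#' @param ztrace_file Export List B path.
#' @param config A [run_config()].
#' @param output Optional CSV path; when given, the per-spine table is
#'   written with a metadata comment line recording the thresholds and
#'   denominator in force.
#' @param strict Passed to [assemble_dendrites()].
#' @return A classified `dendrite_set`.
#' @export
run_classify <- function(trace_files, ztrace_file, config = run_config(),
                         output = NULL, strict = TRUE) {
  width_rows <- dplyr::bind_rows(
    purrr::map(trace_files, read_trace_list, columns = config$columns))
  zlen_rows <- read_ztrace_list(ztrace_file, columns = config$columns)
  ds <- assemble_dendrites(width_rows, zlen_rows, strict = strict)
  ds <- classify_table(ds, config$thresholds)
  if (!is.null(output)) {
    write_audited_csv(ds$spines, output, config)
  }
  ds
}

#' Summarize a tracing session per dendrite
#'
#' Runs [run_classify()] then [summarize_dendrites()] under one
#' configuration.
#'
#' @inheritParams run_classify
#' @return The per-dendrite summary tibble.
#' @export
run_summarize <- function(trace_files, ztrace_file,
                          config = run_config(), output = NULL,
                          strict = TRUE) {
  ds <- run_classify(trace_files, ztrace_file, config, strict = strict)
  s <- summarize_dendrites(
    ds, denominator = config$density_denominator,
    include_branch_in_means = config$include_branch_in_means)
  if (!is.null(output)) {
    write_audited_csv(s, output, config)
  }
  s
}

#' Compare two groups of tracing sessions
#'
#' Each group directory must contain `d<k>_traces.csv` files and a
#' `ztraces.csv` (the layout [generate_dataset()] emits and a tracing
#' session produces). Per-dendrite summaries are computed per group and
#' the chosen metric is compared with a pooled-variance Student's t-test.
#'
#' @param dir_a,dir_b Group directories.
#' @param metric Summary column to compare.
#' @param config A [run_config()].
#' @param labels Group display names.
#' @param output Optional path for a CSV report.
#' @return A `group_comparison`.
#' @export
run_compare <- function(dir_a, dir_b,
                        metric = "protrusion_density_per_um",
                        config = run_config(),
                        labels = c(basename(dir_a), basename(dir_b)),
                        output = NULL) {
  summarize_dir <- function(dir) {
    files <- sort(list.files(dir, pattern = "^d[0-9]+_traces\\.csv$",
                             full.names = TRUE))
    zfile <- file.path(dir, "ztraces.csv")
    if (length(files) == 0L || !file.exists(zfile)) {
      rlang::abort(
        sprintf("%s: expected d<k>_traces.csv files and ztraces.csv", dir),
        class = "spinemorph_io_error")
    }
    run_summarize(files, zfile, config)
  }
  cmp <- compare_groups(summarize_dir(dir_a), summarize_dir(dir_b),
                        metric = metric, labels = labels)
  if (!is.null(output)) {
    write_audited_csv(as.data.frame(cmp), output, config)
  }
  cmp
}

#' Simulate a tracing session to disk
#'
#' Thin wrapper over [generate_dataset()] for the command-line surface.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param config A [generator_config()]; its seed is replaced by `seed`
#'   when one is given.
#' @param write_polylines Also write ground-truth 3D polylines.
#' @return See [generate_dataset()].
#' @export
run_simulate <- function(dir, seed = NULL, config = generator_config(),
                         write_polylines = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  generate_dataset(config, dir, write_polylines = write_polylines)
}
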