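#' Spine type levels
#'
#' The six morphological classes, in classification (precedence) order:
#' branched spine, filopodium, mushroom, long thin, thin, stubby.
#'
#' @return Character vector of type names.
#' @export
spine_types <- function() {
  c("branch", "filo", "mush", "long_thin", "thin", "stub")
}

#' Classification thresholds
#'
#' The cutoffs of the hierarchical spine-type rule, all in micrometres
#' except the dimensionless length-to-width ratio (LWR):
#'
#' * `filo_min_length_um` (2.0): length **>** this is a filopodium;
#' * `mush_min_width_um` (0.6): head width **>** this is a mushroom;
#' * `long_thin_min_length_um` (1.0): length **>** this is long thin;
#' * `thin_min_lwr` (1.0): LWR **>** this is thin, **<=** is stubby.
#'
#' All comparisons are strict (`>`) except the final stubby rule (`<=`),
#' exactly as the source spreadsheet formula evaluates them. Defaults may
#' be overridden, but downstream output records non-default thresholds in
#' its metadata so analyses stay comparable between users.
#'
#' @param filo_min_length_um,mush_min_width_um,long_thin_min_length_um,thin_min_lwr
#'   Positive reals; `long_thin_min_length_um` must be below
#'   `filo_min_length_um` or the long-thin rule could never fire.
#' @return An object of class `spine_thresholds`.
#' @export
spine_thresholds <- function(filo_min_length_um = 2.0,
                             mush_min_width_um = 0.6,
                             long_thin_min_length_um = 1.0,
                             thin_min_lwr = 1.0) {
  vals <- c(filo_min_length_um, mush_min_width_um,
            long_thin_min_length_um, thin_min_lwr)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    rlang::abort("all thresholds must be strictly positive",
                 class = "spinemorph_domain_error")
  }
  if (long_thin_min_length_um >= filo_min_length_um) {
    rlang::abort(
      "long_thin_min_length_um must be less than filo_min_length_um",
      class = "spinemorph_domain_error")
  }
  structure(list(filo_min_length_um = filo_min_length_um,
                 mush_min_width_um = mush_min_width_um,
                 long_thin_min_length_um = long_thin_min_length_um,
                 thin_min_lwr = thin_min_lwr),
            class = "spine_thresholds")
}

is_default_thresholds <- function(th) {
  identical(unclass(th), unclass(spine_thresholds()))
}

#' Length-to-width ratio
#'
#' The spine length divided by the spine head width. The width must be
#' strictly positive; a zero width is a measurement error, not an
#' infinite ratio.
#'
#' @param width_um Head width(s), um, > 0.
#' @param length_um Spine length(s), um, >= 0.
#' @return Numeric vector of ratios.
#' @export
lwr <- function(width_um, length_um) {
  if (!is.numeric(width_um) || !is.numeric(length_um) ||
      any(!is.finite(width_um)) || any(width_um <= 0)) {
    rlang::abort("width_um must be strictly positive and finite",
                 class = "spinemorph_domain_error")
  }
  if (any(!is.finite(length_um)) || any(length_um < 0)) {
    rlang::abort("length_um must be non-negative and finite",
                 class = "spinemorph_domain_error")
  }
  length_um / width_um
}

#' Classify spines by the hierarchical geometric rule
#'
#' Assigns each spine exactly one of six types by testing the rules in
#' precedence order; the first rule that fires wins:
#'
#' 1. `branch` -- the trace name was flagged as a branched spine;
#' 2. `filo`   -- length > 2 um (filopodium);
#' 3. `mush`   -- head width > 0.6 um (mushroom);
#' 4. `long_thin` -- length > 1 um;
#' 5. `thin`   -- LWR > 1;
#' 6. `stub`   -- LWR <= 1 (stubby).
#'
#' The rule set is exhaustive: rules 5 and 6 partition whatever remains,
#' so every spine with a positive width receives exactly one type.
#' Branch status comes from the manual flag in the trace name, never from
#' geometry.
#'
#' @param width_um,length_um Numeric vectors, um. Width must be > 0 even
#'   for types whose rule ignores it, because the LWR is computed for
#'   every spine.
#' @param branch Logical vector (recycled), the manual branched-spine
#'   flag.
#' @param thresholds A [spine_thresholds()].
#' @return Factor with levels [spine_types()].
#' @examples
#' classify_spine(c(0.3, 0.7, 0.4, 0.4, 0.5), c(2.5, 1.5, 1.2, 0.8, 0.4))
#' @export
classify_spine <- function(width_um, length_um, branch = FALSE,
                           thresholds = spine_thresholds()) {
  stopifnot(inherits(thresholds, "spine_thresholds"))
  ratio <- lwr(width_um, length_um)
  n <- length(ratio)
  branch <- rep_len(as.logical(branch), n)
  if (anyNA(branch)) {
    rlang::abort("branch must be TRUE or FALSE",
                 class = "spinemorph_domain_error")
  }
  type <- dplyr::case_when(
    branch ~ "branch",
    length_um > thresholds$filo_min_length_um ~ "filo",
    width_um > thresholds$mush_min_width_um ~ "mush",
    length_um > thresholds$long_thin_min_length_um ~ "long_thin",
    ratio > thresholds$thin_min_lwr ~ "thin",
    .default = "stub"
  )
  factor(type, levels = spine_types())
}

#' Add LWR and spine type to a spine table
#'
#' The per-spine ("by spine") computation: appends `lwr` and
#' `spine_type` columns to a spine table, leaving row order untouched.
#' Re-running on already-classified output reproduces it (idempotent).
#'
#' @param spines A tibble with columns `width_um`, `length_um` and
#'   optionally `branch` (assumed `FALSE` when absent), or a
#'   `dendrite_set` from [assemble_dendrites()] whose `spines` table is
#'   classified in place.
#' @param thresholds A [spine_thresholds()].
#' @return The input with `lwr` and `spine_type` columns filled in.
#' @export
classify_table <- function(spines, thresholds = spine_thresholds()) {
  if (inherits(spines, "dendrite_set")) {
    spines$spines <- classify_table(spines$spines, thresholds)
    attr(spines, "thresholds") <- thresholds
    return(spines)
  }
  stopifnot(is.data.frame(spines))
  if (nrow(spines) == 0L) {
    spines$lwr <- double()
    spines$spine_type <- factor(character(), levels = spine_types())
    return(spines)
  }
  required <- c("width_um", "length_um")
  missing_cols <- setdiff(required, names(spines))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf("spine table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 class = "spinemorph_schema_error")
  }
  bad <- which(!is.finite(spines$width_um) | spines$width_um <= 0 |
                 !is.finite(spines$length_um) | spines$length_um < 0)
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("invalid width/length at row(s) %s",
              paste(utils::head(bad, 10L), collapse = ", ")),
      class = "spinemorph_value_error"
    )
  }
  branch <- if ("branch" %in% names(spines)) spines$branch else FALSE
  spines$lwr <- lwr(spines$width_um, spines$length_um)
  spines$spine_type <- classify_spine(spines$width_um, spines$length_um,
                                      branch, thresholds)
  spines
}
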