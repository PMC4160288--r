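#' Column mapping for trace-list exports
#'
#' RECONSTRUCT's CSV export headers vary between versions and locales, so
#' the reader takes an explicit name-to-role mapping. The defaults match
#' the headers the synthetic generator writes.
#'
#' @param name Header of the column holding trace names.
#' @param length Header of the column holding lengths (micrometres).
#' @param section Header of the column holding the optical-section index
#'   (Trace List only; Z-traces span sections and carry no section).
#' @return A named list of class `trace_columns`.
#' @export
trace_columns <- function(name = "Name", length = "Length",
                          section = "Section") {
  stopifnot(is.character(name), is.character(length))
  structure(list(name = name, length = length, section = section),
            class = "trace_columns")
}

read_export <- function(path, columns, with_section) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path),
                 class = "spinemorph_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  need <- c(columns$name, columns$length)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      sprintf("%s: missing required column(s): %s (found: %s)",
              path, paste(missing_cols, collapse = ", "),
              paste(names(raw), collapse = ", ")),
      class = "spinemorph_schema_error"
    )
  }
  len <- suppressWarnings(as.numeric(raw[[columns$length]]))
  bad <- which(is.na(len) & !is.na(raw[[columns$length]]))
  if (length(bad) > 0L) {
    rlang::abort(
      sprintf("%s: non-numeric length %s at data row %s",
              path, sprintf("\"%s\"", raw[[columns$length]][bad[1]]),
              bad[1]),
      class = "spinemorph_value_error"
    )
  }
  if (any(len < 0, na.rm = TRUE)) {
    rlang::abort(sprintf("%s: negative length", path),
                 class = "spinemorph_value_error")
  }
  out <- tibble::tibble(name = raw[[columns$name]], length_um = len)
  if (with_section) {
    sec <- if (columns$section %in% names(raw)) {
      as.integer(raw[[columns$section]])
    } else {
      rep(NA_integer_, nrow(raw))
    }
    out <- tibble::add_column(out, section = sec, .before = 1L)
  }
  # validate names eagerly so malformed rows fail at the file boundary
  parse_trace_name(out$name)
  out
}

#' Read a Trace List export (Export List A)
#'
#' Reads the 2D trace list saved from a tracing session: the straight
#' reference line for a dendritic segment plus one head-width line per
#' spine. Row order is preserved because width/length pairing relies on
#' the order of analysis.
#'
#' @param path Path to the CSV file.
#' @param columns A [trace_columns()] mapping.
#' @return A tibble with columns `section` (integer, may be `NA`), `name`
#'   and `length_um`, in file order.
#' @seealso [read_ztrace_list()], [assemble_dendrites()]
#' @export
read_trace_list <- function(path, columns = trace_columns()) {
  read_export(path, columns, with_section = TRUE)
}

#' Read a Z-Trace List export (Export List B)
#'
#' Reads the 3D Z-trace list for a whole series: one dendrite contour
#' length per segment plus one spine-length Z-trace per spine. A Z-trace
#' spans optical sections, so there is no section column.
#'
#' @inheritParams read_trace_list
#' @return A tibble with columns `name` and `length_um`, in file order.
#' @export
read_ztrace_list <- function(path, columns = trace_columns()) {
  rows <- read_export(path, columns, with_section = FALSE)
  parsed <- parse_trace_name(rows$name)
  dup <- duplicated(parsed[c("dendrite_id", "kind", "spine_index")])
  if (any(dup)) {
    rlang::abort(
      sprintf("%s: duplicated z-trace name(s): %s", path,
              paste(unique(rows$name[dup]), collapse = ", ")),
      class = "spinemorph_value_error"
    )
  }
  rows
}

#' Write trace-list exports
#'
#' Writes rows in the same CSV dialect the readers accept, names verbatim
#' and lengths at full double precision, so that write-then-read is the
#' identity. Used mainly by the synthetic generator.
#'
#' @param rows A tibble as returned by [read_trace_list()] /
#'   [read_ztrace_list()].
#' @param path Output path.
#' @param columns A [trace_columns()] mapping supplying the headers.
#' @return `path`, invisibly.
#' @export
write_trace_list <- function(rows, path, columns = trace_columns()) {
  stopifnot(all(c("name", "length_um") %in% names(rows)))
  out <- tibble::tibble(
    section = if ("section" %in% names(rows)) rows$section else NA_integer_,
    name = rows$name,
    length = rows$length_um
  )
  names(out) <- c(columns$section, columns$name, columns$length)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trace_list
#' @export
write_ztrace_list <- function(rows, path, columns = trace_columns()) {
  stopifnot(all(c("name", "length_um") %in% names(rows)))
  out <- tibble::tibble(name = rows$name, length = rows$length_um)
  names(out) <- c(columns$name, columns$length)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Assemble dendritic segments from trace exports
#'
#' Joins the 2D Trace List rows (Export List A: straight reference line
#' and spine head widths) with the Z-Trace List rows (Export List B:
#' dendrite contour lengths and spine lengths) into per-dendrite records
#' with one width/length pair per spine.
#'
#' Pairing prefers the explicit numeric spine indices carried by the
#' names; when the index sets on the two sides of a dendrite differ but
#' the counts agree, spines are paired by rank order (the order of
#' analysis, which the tracing protocol keeps identical for widths and
#' lengths). A count mismatch is an error, never a silent drop. The
#' branch flag is taken from either side's name.
#'
#' A contour is never shorter than its chord, so `z_length_um <
#' straight_length_um` indicates a tracing problem; it is an error when
#' `strict = TRUE` (the default for synthetic data) and a warning
#' otherwise (hand traces are noisy).
#'
#' @param width_rows Tibble from [read_trace_list()]; several files may
#'   be row-bound first (one Export List A per dendrite is typical).
#' @param zlen_rows Tibble from [read_ztrace_list()].
#' @param den_id_prefix Prefix prepended to the dendrite number to form
#'   the DEN ID, which must be unique per dendrite in a data set.
#' @param strict If `TRUE`, a Z-length shorter than the straight length
#'   is an error; if `FALSE`, a warning.
#' @return An object of class `dendrite_set`: a list with tibbles
#'   `dendrites` (`den_id`, `dendrite_id`, `straight_length_um`,
#'   `z_length_um`, `n_spines`) and `spines` (`den_id`, `spine_index`,
#'   `trace_name`, `width_um`, `length_um`, `branch`).
#' @export
assemble_dendrites <- function(width_rows, zlen_rows,
                               den_id_prefix = "", strict = TRUE) {
  wp <- dplyr::bind_cols(width_rows["length_um"],
                         parse_trace_name(width_rows$name))
  zp <- dplyr::bind_cols(zlen_rows["length_um"],
                         parse_trace_name(zlen_rows$name))
  wp$rank <- stats::ave(seq_len(nrow(wp)), wp$dendrite_id, wp$kind,
                        FUN = seq_along)
  zp$rank <- stats::ave(seq_len(nrow(zp)), zp$dendrite_id, zp$kind,
                        FUN = seq_along)

  ids <- sort(union(wp$dendrite_id, zp$dendrite_id))
  dendrites <- vector("list", length(ids))
  spines <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- ids[i]
    slen <- wp[wp$dendrite_id == d & wp$kind == "straight_ref", ]
    zlen <- zp[zp$dendrite_id == d & zp$kind == "dendrite_zlen", ]
    if (nrow(slen) != 1L || nrow(zlen) != 1L) {
      rlang::abort(
        sprintf(paste0("dendrite %d: expected exactly one straight ",
                       "reference and one dendrite Z-trace, found %d and %d"),
                d, nrow(slen), nrow(zlen)),
        class = "spinemorph_structure_error"
      )
    }
    w <- wp[wp$dendrite_id == d & wp$kind == "spine_width", ]
    z <- zp[zp$dendrite_id == d & zp$kind == "spine_zlen", ]
    if (nrow(w) != nrow(z)) {
      rlang::abort(
        sprintf("dendrite %d: %d width trace(s) but %d spine Z-trace(s)",
                d, nrow(w), nrow(z)),
        class = "spinemorph_pairing_error"
      )
    }
    if (anyDuplicated(w$spine_index) || anyDuplicated(z$spine_index)) {
      rlang::abort(
        sprintf("dendrite %d: duplicated spine index", d),
        class = "spinemorph_pairing_error"
      )
    }
    den_id <- paste0(den_id_prefix, d)
    if (nrow(w) > 0L) {
      by_index <- setequal(w$spine_index, z$spine_index)
      key <- if (by_index) "spine_index" else "rank"
      z_ord <- z[match(w[[key]], z[[key]]), ]
      spines[[i]] <- tibble::tibble(
        den_id = den_id,
        spine_index = w$spine_index,
        trace_name = w$raw,
        width_um = w$length_um,
        length_um = z_ord$length_um,
        branch = w$branch | z_ord$branch
      )
    }
    if (strict && zlen$length_um < slen$length_um) {
      rlang::abort(
        sprintf(paste0("dendrite %d: Z-trace length (%.4g) shorter than ",
                       "straight reference (%.4g); a contour cannot be ",
                       "shorter than its chord"),
                d, zlen$length_um, slen$length_um),
        class = "spinemorph_structure_error"
      )
    } else if (!strict && zlen$length_um < slen$length_um) {
      warning(sprintf(
        "dendrite %d: Z-trace length (%.4g) shorter than straight reference (%.4g)",
        d, zlen$length_um, slen$length_um), call. = FALSE)
    }
    dendrites[[i]] <- tibble::tibble(
      den_id = den_id,
      dendrite_id = d,
      straight_length_um = slen$length_um,
      z_length_um = zlen$length_um,
      n_spines = nrow(w)
    )
  }
  new_dendrite_set(dplyr::bind_rows(dendrites), dplyr::bind_rows(spines))
}

new_dendrite_set <- function(dendrites, spines) {
  if (nrow(spines) == 0L) {
    spines <- tibble::tibble(
      den_id = character(), spine_index = integer(),
      trace_name = character(), width_um = double(),
      length_um = double(), branch = logical()
    )
  }
  if (anyDuplicated(dendrites$den_id)) {
    rlang::abort("DEN ID must be unique to each dendrite",
                 class = "spinemorph_structure_error")
  }
  structure(list(dendrites = dendrites, spines = spines),
            class = "dendrite_set")
}

#' @export
print.dendrite_set <- function(x, ...) {
  cat(sprintf("<dendrite_set> %d dendrite(s), %d spine(s)\n",
              nrow(x$dendrites), nrow(x$spines)))
  cat(sprintf("  total Z-length %.2f um, overall density %.3f /um\n",
              sum(x$dendrites$z_length_um),
              nrow(x$spines) / sum(x$dendrites$z_length_um)))
  if ("spine_type" %in% names(x$spines)) {
    tab <- table(x$spines$spine_type)
    cat("  types:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = " "), "\n")
  }
  invisible(x)
}
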