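#' Parse RECONSTRUCT trace names
#'
#' Decodes the naming conventions used to label traces during a spine
#' analysis session. Four kinds of trace are recognised for dendrite
#' number `<d>` and spine number `<s>`:
#'
#' * `d<d>_slen` -- the straight reference line along a dendritic segment
#'   (`straight_ref`);
#' * `d<d>_zlen` -- the 3D Z-trace along the same segment
#'   (`dendrite_zlen`);
#' * `d<d>_spine<s>` -- a straight line across a spine head, i.e. the head
#'   width (`spine_width`);
#' * `d<d>spineZlen<s>` -- the 3D Z-trace down a spine, i.e. the spine
#'   length (`spine_zlen`).
#'
#' Branched spines (several heads on one neck) are flagged manually by the
#' tracer appending `branch` to the name, e.g. `d1_spine1branch`. The
#' suffix is matched case-insensitively, after the spine index digits, on
#' spine traces only. The underscore before `spine`/`spineZlen` is
#' optional in either direction: `d1spineZlen1` and `d1_spineZlen1` both
#' parse (tracing sessions are inconsistent about it).
#'
#' @param raw Character vector of trace names.
#' @return A tibble with one row per input name and columns `raw`,
#'   `dendrite_id` (integer), `kind` (one of `"straight_ref"`,
#'   `"dendrite_zlen"`, `"spine_width"`, `"spine_zlen"`), `spine_index`
#'   (integer, `NA` for dendrite-level traces) and `branch` (logical).
#' @examples
#' parse_trace_name(c("d1_slen", "d2_zlen", "d1_spine3", "d1spineZlen3",
#'                    "d1_spine1branch"))
#' @export
parse_trace_name <- function(raw) {
  if (length(raw) == 0L) {
    return(tibble::tibble(
      raw = character(), dendrite_id = integer(), kind = character(),
      spine_index = integer(), branch = logical()
    ))
  }
  stopifnot(is.character(raw))
  if (anyNA(raw) || any(!nzchar(raw))) {
    stop_parse_error(raw[is.na(raw) | !nzchar(raw)],
                     "empty or missing trace name")
  }
  m <- stringr::str_match(
    raw,
    stringr::regex(
      "^d([0-9]+)(?:(_slen)|(_zlen)|_?spine([0-9]+)(branch)?|_?spinezlen([0-9]+)(branch)?)$",
      ignore_case = TRUE
    )
  )
  bad <- is.na(m[, 1])
  if (any(bad)) {
    stop_parse_error(raw[bad], "not a recognised trace name")
  }
  # distinguish spine_width from spine_zlen: the zlen alternative fills
  # capture group 6, the width alternative group 4
  kind <- dplyr::case_when(
    !is.na(m[, 3]) ~ "straight_ref",
    !is.na(m[, 4]) ~ "dendrite_zlen",
    !is.na(m[, 7]) ~ "spine_zlen",
    !is.na(m[, 5]) ~ "spine_width"
  )
  # "d1_spine2" also matches the width branch when lowercased; the regex
  # alternatives are ordered so spineZlen is only reachable via group 6/7,
  # but case-insensitivity makes "spinezlen" match the width branch first
  # ("zlen3" would not be digits). That cannot happen: "spinezlen3" fails
  # _?spine([0-9]+) because "zlen3" is not numeric. Safe.
  spine_index <- ifelse(kind == "spine_width", m[, 5],
                 ifelse(kind == "spine_zlen", m[, 7], NA))
  branch <- !is.na(m[, 6]) | !is.na(m[, 8])
  tibble::tibble(
    raw = raw,
    dendrite_id = as.integer(m[, 2]),
    kind = kind,
    spine_index = as.integer(spine_index),
    branch = branch
  )
}

#' Render a canonical trace name
#'
#' Inverse of [parse_trace_name()] on canonical names: `d1_slen`,
#' `d1_zlen`, `d1_spine2` (plus `branch`), `d1spineZlen2`.
#'
#' @param dendrite_id Integer vector of dendrite numbers.
#' @param kind Character vector of trace kinds (see [parse_trace_name()]).
#' @param spine_index Integer vector; required for spine kinds.
#' @param branch Logical vector; may be `TRUE` only for spine kinds.
#' @return Character vector of trace names.
#' @export
render_trace_name <- function(dendrite_id, kind,
                              spine_index = NA_integer_, branch = FALSE) {
  n <- max(length(dendrite_id), length(kind), length(spine_index),
           length(branch))
  dendrite_id <- rep_len(as.integer(dendrite_id), n)
  kind <- rep_len(kind, n)
  spine_index <- rep_len(as.integer(spine_index), n)
  branch <- rep_len(branch, n)
  is_spine <- kind %in% c("spine_width", "spine_zlen")
  if (any(is_spine & is.na(spine_index))) {
    stop("spine traces require a spine_index", call. = FALSE)
  }
  if (any(!is_spine & branch)) {
    stop("the branch flag applies to spine traces only", call. = FALSE)
  }
  suffix <- ifelse(branch, "branch", "")
  out <- character(n)
  out[kind == "straight_ref"] <-
    sprintf("d%d_slen", dendrite_id[kind == "straight_ref"])
  out[kind == "dendrite_zlen"] <-
    sprintf("d%d_zlen", dendrite_id[kind == "dendrite_zlen"])
  w <- kind == "spine_width"
  out[w] <- sprintf("d%d_spine%d%s", dendrite_id[w], spine_index[w],
                    suffix[w])
  z <- kind == "spine_zlen"
  out[z] <- sprintf("d%dspineZlen%d%s", dendrite_id[z], spine_index[z],
                    suffix[z])
  if (any(out == "")) stop("unknown trace kind", call. = FALSE)
  out
}

stop_parse_error <- function(offending, reason, context = NULL) {
  msg <- sprintf(
    "cannot parse trace name%s: %s (%s)",
    if (length(offending) > 1L) "s" else "",
    paste(sprintf("\"%s\"", utils::head(offending, 5L)), collapse = ", "),
    reason
  )
  if (!is.null(context)) msg <- paste0(msg, " [", context, "]")
  rlang::abort(msg, class = "spinemorph_parse_error",
               offending = offending)
}
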