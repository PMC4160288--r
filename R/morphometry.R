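#' Per-dendrite morphometric summaries
#'
#' Computes the "by dendrite" block for each dendritic segment: spine
#' count, protrusion density (spines per micrometre of dendrite length),
#' mean head width, mean length, mean length-to-width ratio, and per-type
#' counts, fractions and densities.
#'
#' The density denominator defaults to the Z-trace length: the Z-trace
#' follows the dendrite's 3D contour and is the accurate length, while
#' the straight reference line only marks the start and stop positions.
#' Dividing by the straight length is available for comparison with
#' 2D-only workflows.
#'
#' Branched spines are protrusions like any other and are included in
#' counts, means and fractions by default; set
#' `include_branch_in_means = FALSE` to drop them from the width, length
#' and LWR means only (they always count toward density).
#'
#' Dendrites with no spines get density 0 and missing (`NA`) means;
#' missing never silently becomes zero.
#'
#' @param x A classified `dendrite_set` (see [classify_table()]).
#' @param denominator `"ztrace"` (default) or `"straight"`.
#' @param include_branch_in_means Logical, see above.
#' @return A tibble with one row per DEN ID: `den_id`, `n_spines`,
#'   `denominator_um`, `protrusion_density_per_um`, `mean_width_um`,
#'   `mean_length_um`, `mean_lwr`, then `n_<type>`, `frac_<type>` and
#'   `density_<type>` for each of [spine_types()].
#' @export
summarize_dendrites <- function(x, denominator = c("ztrace", "straight"),
                                include_branch_in_means = TRUE) {
  stopifnot(inherits(x, "dendrite_set"))
  denominator <- match.arg(denominator)
  if (!"spine_type" %in% names(x$spines)) {
    rlang::abort("spines are not classified; run classify_table() first",
                 class = "spinemorph_state_error")
  }
  den_len <- if (denominator == "ztrace") {
    x$dendrites$z_length_um
  } else {
    x$dendrites$straight_length_um
  }
  if (any(den_len <= 0)) {
    rlang::abort("dendrite length must be positive to compute densities",
                 class = "spinemorph_domain_error")
  }

  base <- tibble::tibble(den_id = x$dendrites$den_id,
                         denominator_um = den_len)
  sp <- x$spines
  per_den <- sp |>
    dplyr::group_by(.data$den_id) |>
    dplyr::summarise(
      n_spines = dplyr::n(),
      mean_width_um = mean(.data$width_um[include_branch_in_means |
                                            !.data$branch]),
      mean_length_um = mean(.data$length_um[include_branch_in_means |
                                              !.data$branch]),
      mean_lwr = mean(.data$lwr[include_branch_in_means | !.data$branch]),
      .groups = "drop"
    )
  counts <- sp |>
    dplyr::count(.data$den_id, .data$spine_type, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "spine_type", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)

  out <- base |>
    dplyr::left_join(per_den, by = "den_id") |>
    dplyr::left_join(counts, by = "den_id") |>
    dplyr::mutate(
      n_spines = dplyr::coalesce(.data$n_spines, 0L),
      dplyr::across(dplyr::starts_with("n_") & !dplyr::any_of("n_spines"),
                    ~ dplyr::coalesce(.x, 0L)),
      protrusion_density_per_um = .data$n_spines / .data$denominator_um
    )
  for (ty in spine_types()) {
    col <- paste0("n_", ty)
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]] <- dplyr::coalesce(out[[col]], 0L)
  }
  for (ty in spine_types()) {
    out[[paste0("frac_", ty)]] <-
      ifelse(out$n_spines > 0, out[[paste0("n_", ty)]] / out$n_spines, NA_real_)
    out[[paste0("density_", ty)]] <- out[[paste0("n_", ty)]] / out$denominator_um
  }
  dplyr::relocate(out, "den_id", "n_spines", "denominator_um",
                  "protrusion_density_per_um", "mean_width_um",
                  "mean_length_um", "mean_lwr")
}

#' Per-type protrusion density of one segment
#'
#' Count of spines of one type divided by the dendrite length (same
#' denominator choice as [summarize_dendrites()]). Summing over all types
#' recovers the total protrusion density exactly.
#'
#' @param x A classified `dendrite_set`.
#' @param type One of [spine_types()].
#' @inheritParams summarize_dendrites
#' @return A tibble `den_id`, `density_per_um`.
#' @export
type_density <- function(x, type, denominator = c("ztrace", "straight")) {
  stopifnot(inherits(x, "dendrite_set"))
  if (!type %in% spine_types()) {
    rlang::abort(sprintf("unknown spine type \"%s\" (expected one of %s)",
                         type, paste(spine_types(), collapse = ", ")),
                 class = "spinemorph_domain_error")
  }
  s <- summarize_dendrites(x, denominator = denominator)
  tibble::tibble(den_id = s$den_id,
                 density_per_um = s[[paste0("density_", type)]])
}

#' Two-group comparison of a per-dendrite metric
#'
#' Classical two-sample Student's t-test (pooled variance, two-tailed)
#' on a per-dendrite summary metric, the dendrite being the statistical
#' unit. Returns group means, standard errors of the mean, the t
#' statistic, degrees of freedom and the p-value.
#'
#' @param a,b Tibbles from [summarize_dendrites()] (one per group), or
#'   bare numeric vectors of per-dendrite values.
#' @param metric Name of the summary column to compare (ignored for
#'   numeric input).
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `group_comparison` (a list with fields
#'   `metric`, `labels`, `n`, `means`, `sems`, `t_statistic`, `df`,
#'   `p_value`).
#' @export
compare_groups <- function(a, b, metric = "protrusion_density_per_um",
                           labels = c("A", "B")) {
  va <- if (is.numeric(a)) a else pull_metric(a, metric)
  vb <- if (is.numeric(b)) b else pull_metric(b, metric)
  for (v in list(va, vb)) {
    if (anyNA(v)) {
      rlang::abort(
        sprintf("metric \"%s\" is undefined (NA) for %d dendrite(s)",
                metric, sum(is.na(v))),
        class = "spinemorph_domain_error")
    }
  }
  if (length(va) < 2L || length(vb) < 2L) {
    rlang::abort("each group needs at least 2 dendrites",
                 class = "spinemorph_domain_error")
  }
  ht <- stats::t.test(va, vb, var.equal = TRUE)
  structure(list(
    metric = metric,
    labels = labels,
    n = c(length(va), length(vb)),
    means = c(mean(va), mean(vb)),
    sems = c(stats::sd(va) / sqrt(length(va)),
             stats::sd(vb) / sqrt(length(vb))),
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value)
  ), class = "group_comparison")
}

pull_metric <- function(x, metric) {
  if (!is.data.frame(x) || !metric %in% names(x)) {
    rlang::abort(sprintf("metric \"%s\" not found in summary table", metric),
                 class = "spinemorph_domain_error")
  }
  x[[metric]]
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Two-sample Student's t-test (pooled variance) on %s\n",
              x$metric))
  for (i in 1:2) {
    cat(sprintf("  %s: mean %.4g +/- %.3g SEM (n = %d dendrites)\n",
                x$labels[i], x$means[i], x$sems[i], x$n[i]))
  }
  cat(sprintf("  t = %.4g, df = %.0f, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
format.group_comparison <- function(x, ...) {
  utils::capture.output(print(x))
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return `as.data.frame()`: a one-row data frame.
#' @export
as.data.frame.group_comparison <- function(x, ...) {
  data.frame(metric = x$metric,
             group_a = x$labels[1], group_b = x$labels[2],
             n_a = x$n[1], n_b = x$n[2],
             mean_a = x$means[1], mean_b = x$means[2],
             sem_a = x$sems[1], sem_b = x$sems[2],
             t_statistic = x$t_statistic, df = x$df,
             p_value = x$p_value)
}
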