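# Independent oracles used across the suite. Each deliberately mirrors a
# definition, not the package's implementation path.

# Literal transcription of the spreadsheet's nested conditional, evaluated
# strictly left to right on one row, exactly as a spreadsheet cell would:
# IF(branch in name, "branch", IF(G>2, "filo", IF(F>0.6, "mush",
#   IF(G>1, "long_thin", IF(H>1, "thin", "stub")))))
spreadsheet_type <- function(trace_name, width, length) {
  ratio <- length / width
  if (grepl("branch", trace_name, ignore.case = TRUE)) {
    "branch"
  } else if (length > 2) {
    "filo"
  } else if (width > 0.6) {
    "mush"
  } else if (length > 1) {
    "long_thin"
  } else if (ratio > 1) {
    "thin"
  } else {
    "stub"
  }
}

# Segment-wise 3D norm summation with an explicit loop.
polyline_length_oracle <- function(x, y, section, pixel, thickness) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    dx <- (x[i + 1] - x[i]) * pixel
    dy <- (y[i + 1] - y[i]) * pixel
    dz <- (section[i + 1] - section[i]) * thickness
    total <- total + sqrt(dx^2 + dy^2 + dz^2)
  }
  total
}

# Closed-form pooled-variance two-sample t and its two-tailed p via the
# incomplete beta function (no call to pt or t.test).
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- pbeta(df / (df + t^2), df / 2, 0.5)
  list(t = t, df = df, p = p)
}

# Small valid session built in code: two dendrites, explicit indices.
make_session_rows <- function() {
  widths <- tibble::tibble(
    section = rep(10L, 8),
    name = c("d1_slen", "d1_spine1", "d1_spine2branch", "d1_spine3",
             "d2_slen", "d2_spine1", "d2_spine2", "d2_spine3"),
    length_um = c(10.0, 0.3, 0.7, 0.4, 9.5, 0.5, 0.65, 0.4)
  )
  zlens <- tibble::tibble(
    name = c("d1_zlen", "d1spineZlen1", "d1spineZlen2", "d1spineZlen3",
             "d2_zlen", "d2spineZlen1", "d2spineZlen2", "d2spineZlen3"),
    length_um = c(10.4, 2.5, 1.5, 1.2, 10.1, 0.4, 0.8, 0.9)
  )
  list(widths = widths, zlens = zlens)
}
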