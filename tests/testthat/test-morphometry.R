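make_segment <- function(widths, lengths, branch = FALSE, z_len = 10,
                         straight = min(z_len, 10), den = "1") {
  n <- length(widths)
  spines <- tibble::tibble(
    den_id = rep(den, n), spine_index = seq_len(n),
    trace_name = sprintf("d%s_spine%d", den, seq_len(n)),
    width_um = widths, length_um = lengths,
    branch = rep_len(branch, n)
  )
  ds <- structure(list(
    dendrites = tibble::tibble(den_id = den, dendrite_id = as.integer(den),
                               straight_length_um = straight,
                               z_length_um = z_len, n_spines = n),
    spines = spines
  ), class = "dendrite_set")
  classify_table(ds)
}

test_that("protrusion density is spine count over dendrite length", {
  set.seed(41)
  ds <- make_segment(runif(17, 0.2, 0.55), runif(17, 0.3, 0.9),
                     z_len = 10.0)
  s <- summarize_dendrites(ds)
  expect_identical(s$n_spines, 17L)
  expect_equal(s$protrusion_density_per_um, 1.7)
  # the density identity: density x denominator = count
  expect_equal(s$protrusion_density_per_um * s$denominator_um,
               as.numeric(s$n_spines), tolerance = 1e-12)
})

test_that("means are plain arithmetic means over the segment's spines", {
  ds <- make_segment(c(0.3, 0.6, 0.9), c(0.3, 0.6, 0.9) * 2, z_len = 12)
  s <- summarize_dendrites(ds)
  expect_equal(s$mean_width_um, 0.6)
  expect_equal(s$mean_length_um, 1.2)
  expect_equal(s$mean_lwr, 2.0)
})

test_that("empty dendrites give zero density and missing means", {
  ds <- structure(list(
    dendrites = tibble::tibble(den_id = "1", dendrite_id = 1L,
                               straight_length_um = 10, z_length_um = 10.4,
                               n_spines = 0L),
    spines = tibble::tibble(den_id = character(), spine_index = integer(),
                            trace_name = character(), width_um = double(),
                            length_um = double(), branch = logical())
  ), class = "dendrite_set")
  s <- summarize_dendrites(classify_table(ds))
  expect_identical(s$n_spines, 0L)
  expect_equal(s$protrusion_density_per_um, 0)
  expect_true(is.na(s$mean_width_um))
  expect_true(is.na(s$frac_mush))
  expect_equal(s$density_mush, 0)
})

test_that("the straight-length denominator is available as a switch", {
  ds <- make_segment(rep(0.3, 5), rep(0.5, 5), z_len = 12.5, straight = 10)
  expect_equal(summarize_dendrites(ds)$protrusion_density_per_um, 0.4)
  expect_equal(summarize_dendrites(ds, denominator = "straight")
               $protrusion_density_per_um, 0.5)
})

test_that("type densities partition the total density exactly", {
  set.seed(42)
  ds <- make_segment(runif(30, 0.1, 1.2), runif(30, 0, 3),
                     branch = runif(30) < 0.1, z_len = 11.7)
  s <- summarize_dendrites(ds)
  dens <- vapply(spine_types(),
                 function(ty) type_density(ds, ty)$density_per_um,
                 numeric(1))
  expect_equal(sum(dens), s$protrusion_density_per_um, tolerance = 1e-12)
  expect_equal(sum(vapply(spine_types(),
                          function(ty) s[[paste0("frac_", ty)]],
                          numeric(1))), 1)
  expect_identical(sum(vapply(spine_types(),
                              function(ty) s[[paste0("n_", ty)]],
                              integer(1))), s$n_spines)
  expect_error(type_density(ds, "spiny"), class = "spinemorph_domain_error")
})

test_that("branch spines can be excluded from the means but not the counts", {
  ds <- make_segment(c(0.3, 0.9), c(0.5, 1.5), branch = c(FALSE, TRUE),
                     z_len = 10)
  s_in <- summarize_dendrites(ds)
  s_out <- summarize_dendrites(ds, include_branch_in_means = FALSE)
  expect_equal(s_in$mean_width_um, 0.6)
  expect_equal(s_out$mean_width_um, 0.3)
  expect_identical(s_in$n_spines, s_out$n_spines)
  expect_identical(s_in$protrusion_density_per_um,
                   s_out$protrusion_density_per_um)
})

test_that("pooled t and two-tailed p match the closed-form oracle", {
  a <- c(1.2, 1.5, 1.1, 1.9, 1.4)
  b <- c(1.0, 0.8, 1.3, 0.9)
  cmp <- compare_groups(a, b)
  want <- pooled_t_oracle(a, b)
  expect_equal(cmp$t_statistic, want$t, tolerance = 1e-9)
  expect_equal(cmp$p_value, want$p, tolerance = 1e-9)
  expect_identical(cmp$df, as.numeric(want$df))
  expect_equal(cmp$sems, c(sd(a) / sqrt(5), sd(b) / sqrt(4)))
})

test_that("group comparison is symmetric and detects separation", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  fwd <- compare_groups(a, b)
  rev <- compare_groups(b, a)
  expect_equal(fwd$p_value, rev$p_value)
  expect_equal(fwd$t_statistic, -rev$t_statistic)
  expect_lt(fwd$p_value, 0.001)
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(1, c(1, 2)), class = "spinemorph_domain_error")
})

test_that("comparisons work on summary tables and flag missing metrics", {
  set.seed(43)
  mk <- function(seed, shift) {
    set.seed(seed)
    dplyr::bind_rows(lapply(1:4, function(i) {
      ds <- make_segment(runif(8, 0.2, 0.55), runif(8, 0.3, 0.9) + shift,
                         z_len = 10, den = as.character(i))
      summarize_dendrites(ds)
    }))
  }
  sa <- mk(1, 0); sb <- mk(2, 0.15)
  cmp <- compare_groups(sa, sb, metric = "mean_length_um",
                        labels = c("ctl", "trt"))
  expect_s3_class(cmp, "group_comparison")
  expect_identical(cmp$n, c(4L, 4L))
  expect_error(compare_groups(sa, sb, metric = "nope"),
               class = "spinemorph_domain_error")
  sa$mean_lwr[2] <- NA
  expect_error(compare_groups(sa, sb, metric = "mean_lwr"),
               class = "spinemorph_domain_error")
})

test_that("observed type fractions converge to generation probabilities", {
  set.seed(44)
  n <- 1e4
  probs <- c(branch = 0.02, filo = 0.10, mush = 0.25, long_thin = 0.13,
             thin = 0.30, stub = 0.20)
  cfg <- generator_config(seed = 44)
  types <- sample(names(probs), n, replace = TRUE, prob = probs)
  geom <- dplyr::bind_rows(lapply(types, sample_spine, config = cfg))
  got <- classify_spine(geom$width_um, geom$length_um, types == "branch")
  frac <- as.numeric(table(got)[names(probs)]) / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(frac - probs) <= 3 * se + 1e-12))
})
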