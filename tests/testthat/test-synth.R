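test_that("sampling regions always produce their intended type", {
  cfg <- generator_config(seed = 51)
  set.seed(51)
  for (ty in spine_types()) {
    g <- sample_spine(ty, cfg, n = 2000L)
    got <- classify_spine(g$width_um, g$length_um, branch = ty == "branch")
    expect_true(all(got == ty), label = sprintf("recovery for %s", ty))
    if (ty == "filo") expect_true(all(g$length_um > 2))
    if (ty == "stub") expect_true(all(g$length_um / g$width_um <= 1))
  }
})

test_that("inconsistent regions are rejected when the config is built", {
  bad <- spine_regions()
  bad$filo$length_range <- c(1.5, 4.0)   # reaches under the filo cutoff
  expect_error(generator_config(regions = bad),
               class = "spinemorph_config_error")
  expect_error(
    generator_config(type_probabilities = c(branch = 0.5, filo = 0.5)),
    class = "spinemorph_config_error")
})

test_that("realized polylines carry exactly the requested 3D length", {
  cal <- calibration(0.1, 0.5)
  # axial-only construction: 2.0 um at 0.5 um sections = 5 vertices
  p <- realize_polyline(2.0, cal, style = "axial")
  expect_identical(nrow(p), 5L)
  expect_identical(p$section, 0:4)
  expect_equal(ztrace_length(p, cal), 2.0, tolerance = 1e-9)
  # planar construction stays on one section
  set.seed(52)
  p <- realize_polyline(5.0, cal, style = "planar")
  expect_identical(length(unique(p$section)), 1L)
  expect_equal(ztrace_length(p, cal), 5.0, tolerance = 1e-6)
  # random lengths, mixed style
  set.seed(53)
  for (L in runif(100, 0.3, 12)) {
    expect_equal(ztrace_length(realize_polyline(L, cal), cal), L,
                 tolerance = 1e-6)
  }
  expect_error(realize_polyline(0.3, cal, style = "axial"),
               class = "spinemorph_generation_error")
  expect_error(realize_polyline(-1, cal), class = "spinemorph_domain_error")
})

test_that("generation is deterministic in the seed and prefix-stable", {
  cfg <- generator_config(seed = 54, n_dendrites = 4L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1)
  generate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = sprintf("file %s identical across runs", f))
  }
  # a different seed gives different data
  d3 <- withr::local_tempdir()
  generate_dataset(generator_config(seed = 99, n_dendrites = 4L), d3)
  expect_false(identical(readLines(file.path(d1, "d1_traces.csv")),
                         readLines(file.path(d3, "d1_traces.csv"))))
  # adding dendrites never reshuffles earlier ones
  d4 <- withr::local_tempdir()
  generate_dataset(generator_config(seed = 54, n_dendrites = 6L), d4)
  expect_identical(readLines(file.path(d1, "d3_traces.csv")),
                   readLines(file.path(d4, "d3_traces.csv")))
})

test_that("generated files follow the naming conventions with branch flags", {
  cfg <- generator_config(seed = 55, n_dendrites = 3L)
  dir <- withr::local_tempdir()
  res <- generate_dataset(cfg, dir)
  a <- read_trace_list(res$trace_files[1])
  p <- parse_trace_name(a$name)
  expect_identical(p$kind[1], "straight_ref")
  expect_true(all(p$kind[-1] == "spine_width"))
  b <- read_ztrace_list(res$ztrace_file)
  pb <- parse_trace_name(b$name)
  expect_setequal(unique(pb$dendrite_id), 1:3)
  # branch flags in the files match the ground truth
  gt <- res$ground_truth
  wide <- parse_trace_name(dplyr::bind_rows(
    lapply(res$trace_files, read_trace_list))$name)
  n_branch_names <- sum(wide$branch, na.rm = TRUE)
  expect_identical(n_branch_names, sum(gt$true_type == "branch"))
})

test_that("the full pipeline recovers ground truth exactly at zero noise", {
  cfg <- generator_config(seed = 56, n_dendrites = 25L)
  dir <- withr::local_tempdir()
  res <- generate_dataset(cfg, dir, write_polylines = TRUE)
  ds <- run_classify(res$trace_files, res$ztrace_file)
  merged <- dplyr::inner_join(ds$spines, res$ground_truth,
                              by = c("den_id", "spine_index"))
  expect_identical(nrow(merged), nrow(res$ground_truth))
  expect_identical(nrow(ds$spines), nrow(res$ground_truth))
  expect_identical(as.character(merged$spine_type), merged$true_type)
  expect_equal(merged$width_um.x, merged$width_um.y, tolerance = 1e-12)
  # densities equal count over z-length
  s <- summarize_dendrites(ds)
  dt <- res$dendrite_truth[match(s$den_id, res$dendrite_truth$den_id), ]
  expect_equal(s$protrusion_density_per_um, dt$true_density_per_um,
               tolerance = 1e-12)
  # emitted polylines reproduce the exported z-lengths
  cal <- cfg$calibration
  polys <- read_polylines(res$polyline_file)
  b <- read_ztrace_list(res$ztrace_file)
  lens <- vapply(polys, ztrace_length, numeric(1), cal = cal)
  expect_equal(unname(lens[b$name]), b$length_um, tolerance = 1e-6)
})

test_that("measurement noise only confuses spines near a threshold", {
  cfg <- generator_config(seed = 57, n_dendrites = 20L,
                          noise_sd_um = 0.02)
  dir <- withr::local_tempdir()
  res <- generate_dataset(cfg, dir)
  ds <- run_classify(res$trace_files, res$ztrace_file)
  merged <- dplyr::inner_join(ds$spines, res$ground_truth,
                              by = c("den_id", "spine_index"),
                              suffix = c("_obs", "_true"))
  wrong <- merged[as.character(merged$spine_type) != merged$true_type, ]
  if (nrow(wrong) > 0) {
    # every misclassified spine has a true measurement within noise reach
    # (5 sd) of some threshold in the quantity that decides its rule
    margin <- 5 * cfg$noise_sd_um
    near <- abs(wrong$length_um_true - 2) < margin |
      abs(wrong$width_um_true - 0.6) < margin |
      abs(wrong$length_um_true - 1) < margin |
      abs(wrong$length_um_true / wrong$width_um_true - 1) < 0.5
    expect_true(all(near))
  }
  expect_gt(mean(as.character(merged$spine_type) == merged$true_type), 0.9)
})

test_that("the maturation preset shifts composition in opposite directions", {
  sc <- maturation_scenario(seed = 58, n_dendrites = 15L)
  expect_gt(sc$mature$type_probabilities[["mush"]],
            sc$immature$type_probabilities[["mush"]])
  expect_lt(sc$mature$type_probabilities[["filo"]],
            sc$immature$type_probabilities[["filo"]])
  expect_false(identical(sc$mature$seed, sc$immature$seed))
})
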