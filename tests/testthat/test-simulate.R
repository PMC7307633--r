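test_that("morphology generation is a pure function of (spec, seed)", {
  spec <- morph_cohort_spec()
  a <- gen_morphology_cohort(spec, 3, seed = 21)
  b <- gen_morphology_cohort(spec, 3, seed = 21)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cells[[2]]$nodes, b$cells[[2]]$nodes)
  c2 <- gen_morphology_cohort(spec, 3, seed = 22)
  expect_false(identical(a$truth$apical_tdbl, c2$truth$apical_tdbl))

  # identical seeds give byte-identical SWC files
  f1 <- withr::local_tempfile(fileext = ".swc")
  f2 <- withr::local_tempfile(fileext = ".swc")
  write_swc(a$cells[[1]], f1)
  write_swc(b$cells[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("generated cells match their own ground truth after analysis", {
  coh <- gen_morphology_cohort(morph_cohort_spec(), 6, seed = 14)
  for (i in seq_along(coh$cells)) {
    bt <- decompose_branches(coh$cells[[i]])
    expect_equal(sum(bt$compartment == "apical"), coh$truth$apical_nb[i])
    expect_equal(sum(bt$compartment == "basal"), coh$truth$basal_nb[i])
    expect_equal(sum(bt$length[bt$compartment == "apical"]),
                 coh$truth$apical_tdbl[i], tolerance = 1e-9)
    expect_equal(sum(bt$length[bt$compartment == "basal"]),
                 coh$truth$basal_tdbl[i], tolerance = 1e-9)
    expect_equal(sum(bt$kind == "stem" & bt$compartment == "apical"),
                 coh$truth$apical_stems[i])
  }
})

test_that("cohorts survive the disk round trip", {
  coh <- gen_morphology_cohort(morph_cohort_spec(), 3, seed = 8)
  dir <- withr::local_tempdir()
  write_morph_cohort(coh, dir)
  m <- read_swc(file.path(dir, "cell_002.swc"))
  bt <- decompose_branches(m)
  expect_equal(sum(bt$compartment == "apical"), coh$truth$apical_nb[2])
  expect_equal(sum(bt$length), coh$truth$apical_tdbl[2] +
                 coh$truth$basal_tdbl[2], tolerance = 1e-4)
  g <- read_layer_geometry(file.path(dir, "layer_geometry.csv"))
  nd <- normalized_depth(m$soma_centroid[1:2], g)
  expect_equal(nd$depth_norm, coh$truth$depth_norm[2], tolerance = 1e-5)
})

test_that("infeasible morphology targets are rejected", {
  expect_error(morph_cohort_spec(apical_tdbl = 10, apical_nb = 25),
               "infeasible")
  expect_error(morph_cohort_spec(depth_range = c(0.9, 0.1)), "depth_range")
})

test_that("calcium FOV generation is seeded and self-consistent", {
  spec <- ca_fov_spec(n_cells = 8, frames = 900)
  a <- gen_ca_fov(spec, seed = 4)
  b <- gen_ca_fov(spec, seed = 4)
  expect_identical(a$rois$traces, b$rois$traces)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$rois$traces, gen_ca_fov(spec, seed = 5)$rois$traces))
  # truth events live inside the recording and amplitudes respect the floor
  expect_true(all(a$truth$onset >= 1 & a$truth$offset_ext <= spec$frames))
  expect_true(all(a$truth$amp_sd >= spec$amp_min))
})

test_that("detection recovers generated events with high recall", {
  fov <- gen_ca_fov(ca_fov_spec(n_cells = 20), seed = 6)
  sc <- score_events(detect_fov_events(fov$rois), fov$truth)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.9)
})

test_that("a zero-rate FOV produces an empty truth table", {
  fov <- gen_ca_fov(ca_fov_spec(n_cells = 5, frames = 600,
                                event_rate_per_min = 0,
                                global_rate_per_min = 0), seed = 9)
  expect_equal(nrow(fov$truth), 0L)
  sc <- score_events(detect_fov_events(fov$rois), fov$truth)
  expect_true(is.na(sc$recall))
})

test_that("overlapping transients are merged in the truth table", {
  tr <- data.frame(roi_id = c(1L, 1L, 1L, 2L),
                   onset = c(10L, 14L, 50L, 12L),
                   offset = c(13L, 17L, 53L, 15L),
                   offset_ext = c(20L, 24L, 60L, 22L),
                   amp_sd = c(4, 6, 5, 3), width = 4L,
                   global_id = c(NA, 1L, NA, 1L))
  merged <- apcdend:::.merge_truth_events(tr)
  expect_equal(nrow(merged), 3L)
  one <- merged[merged$roi_id == 1L & merged$onset == 10L, ]
  expect_equal(one$offset_ext, 24L)
  expect_equal(one$amp_sd, 6)
  expect_equal(one$global_id, 1L)
})

test_that("calcium spec validation catches bad recruitment settings", {
  expect_error(ca_fov_spec(recruit_range = c(0.8, 0.4)), "non-decreasing")
  expect_error(ca_fov_spec(recruit_range = c(0.5, 1.4)), "\\[0, 1\\]")
  expect_error(gen_ca_fov(ca_fov_spec(frames = 60, decay_tau_s = 5)),
               "too short")
})

test_that("ephys generation is seeded and truth-complete", {
  spec <- ephys_spec(noise_sd_mv = 0.1)
  a <- gen_ephys_sweeps(spec, seed = 2)
  b <- gen_ephys_sweeps(spec, seed = 2)
  expect_identical(a$passive$sweeps[[1]]$voltage,
                   b$passive$sweeps[[1]]$voltage)
  expect_false(identical(a$passive$sweeps[[1]]$voltage,
                         gen_ephys_sweeps(spec, seed = 3)$passive$sweeps[[1]]$voltage))
  expect_named(a$truth, c("Vm", "Rin", "tau", "Cm", "ap_threshold",
                          "ap_threshold_index", "fAHP", "instant_freq",
                          "chosen_step", "epsp_amplitude", "epsp_auc"))
  expect_error(ephys_spec(sampling_rate = 5000), ">= 10 kHz")
})
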