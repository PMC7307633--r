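test_that("noise-free RC sweeps recover Vm, Rin, tau and Cm exactly", {
  sim <- gen_ephys_sweeps(ephys_spec(), seed = 1)
  pp <- passive_properties(sim$passive)
  expect_equal(pp$Vm, -70)
  expect_equal(pp$Rin, 200, tolerance = 1e-6)
  expect_equal(pp$tau, 20, tolerance = 1e-4)
  expect_equal(pp$Cm, 100, tolerance = 1e-4)
  expect_equal(pp$tau_status, "ok")
})

test_that("RC units scale as Rin = 1000 dV/I and Cm = 1000 tau/Rin", {
  sim <- gen_ephys_sweeps(ephys_spec(r_mohm = 150, tau_ms = 30,
                                     step_pa = -50), seed = 1)
  pp <- passive_properties(sim$passive)
  expect_equal(pp$Rin, 150, tolerance = 1e-6)
  expect_equal(pp$Cm, 1000 * 30 / 150, tolerance = 1e-4)
})

test_that("noisy RC sweeps recover Rin within 1% across seeds", {
  err <- vapply(1:20, function(s) {
    sim <- gen_ephys_sweeps(ephys_spec(noise_sd_mv = 0.2), seed = s)
    abs(passive_properties(sim$passive)$Rin - 200) / 200
  }, 0)
  expect_true(all(err < 0.01))
})

test_that("step metadata can be inferred from a command-current series", {
  rate <- 20000
  n <- rate %/% 2
  current <- numeric(n)
  on <- round(0.15 * rate) + 1L
  current[on:(on + round(0.2 * rate) - 1L)] <- -80
  v <- rep(-70, n)
  idx <- on:(on + round(0.2 * rate) - 1L)
  v[idx] <- -70 - 16 * (1 - exp(-(seq_along(idx) - 1) / rate * 1000 / 20))
  v[(max(idx) + 1L):n] <- -70 - 16 * exp(-(seq_len(n - max(idx)) - 1) /
                                           rate * 1000 / 20)
  pp <- passive_properties(sweep_set(list(list(voltage = v,
                                               current = current)), rate))
  # the 200-ms step leaves ~2e-4 of the deflection uncharged
  expect_equal(pp$Rin, 200, tolerance = 1e-3)
  expect_error(passive_properties(sweep_set(list(list(
    voltage = v, current = numeric(n))), rate)),
    "no sweep with a nonzero current step")
})

test_that("AP detection merges peaks within the refractory window", {
  rate <- 20000
  v <- rep(-70, 1000)
  v[100] <- 20; v[105] <- 30          # 0.25 ms apart: merged, larger wins
  v[400] <- 25                        # separate AP
  peaks <- detect_aps(v, rate)
  expect_equal(peaks, c(105L, 400L))
  expect_equal(detect_aps(rep(-70, 100), rate), integer(0))
})

test_that("spike features match the constructed ground truth to the sample", {
  sim <- gen_ephys_sweeps(ephys_spec(), seed = 1)
  sf <- spike_features(sim$spiking)
  expect_equal(sf$status, "ok")
  expect_equal(sf$chosen_step, sim$truth$chosen_step)   # first step with >= 9 APs
  expect_equal(sf$threshold_index, sim$truth$ap_threshold_index)
  expect_equal(sf$ap_threshold, sim$truth$ap_threshold, tolerance = 1e-9)
  expect_equal(sf$fAHP, 8, tolerance = 1e-9)
  expect_equal(sf$instant_freq, 40, tolerance = 1e-9)   # 25-ms first ISI
})

test_that("steps of the wrong duration or too few APs are skipped", {
  sim <- gen_ephys_sweeps(ephys_spec(spike_counts = c(2, 3, 4)), seed = 1)
  sf <- spike_features(sim$spiking)
  expect_match(sf$status, "no 600-ms step")
  expect_true(is.na(sf$ap_threshold))
})

test_that("square EPSP fixtures give exact amplitude and AUC", {
  sim <- gen_ephys_sweeps(ephys_spec(epsp_shape = "square"), seed = 1)
  em <- epsp_metrics(sim$epsp$sweeps[[1]], sim$epsp$sampling_rate)
  expect_equal(em$amplitude, 2, tolerance = 1e-9)
  expect_equal(em$auc, 120, tolerance = 1e-6)
  expect_equal(em$baseline, -70, tolerance = 1e-9)
  expect_false(em$has_ap)
})

test_that("EPSP metrics are invariant to a DC offset and scale with amplitude", {
  sim <- gen_ephys_sweeps(ephys_spec(epsp_shape = "square"), seed = 1)
  sw <- sim$epsp$sweeps[[1]]
  rate <- sim$epsp$sampling_rate
  base <- epsp_metrics(sw, rate)
  shifted <- sw; shifted$voltage <- sw$voltage + 12
  em <- epsp_metrics(shifted, rate)
  expect_equal(em$amplitude, base$amplitude, tolerance = 1e-9)
  expect_equal(em$auc, base$auc, tolerance = 1e-9)

  sim2 <- gen_ephys_sweeps(ephys_spec(epsp_shape = "square",
                                      epsp_amplitudes_mv = c(1, 1.5, 4)),
                           seed = 1)
  em2 <- epsp_metrics(sim2$epsp$sweeps[[1]], rate)
  expect_equal(em2$amplitude, 4, tolerance = 1e-9)
  expect_equal(em2$auc, 240, tolerance = 1e-6)
})

test_that("EPSP sweeps missing stimuli or baseline room are rejected", {
  expect_error(epsp_metrics(list(voltage = rep(-70, 100),
                                 stim_times = c(0.001)), 20000),
               "three `stim_times`")
  expect_error(epsp_metrics(list(voltage = rep(-70, 2000),
                                 stim_times = c(0.001, 0.021, 0.041)), 20000),
               "too short for the pre-stimulus baseline")
})

test_that("the APV comparison picks the largest AP-free intensity", {
  sim <- gen_ephys_sweeps(ephys_spec(epsp_shape = "square"), seed = 1)
  rate <- sim$epsp$sampling_rate
  good <- sim$epsp$sweeps[[1]]
  good$stim_intensity <- 1
  bigger <- good; bigger$stim_intensity <- 2
  spiking <- good; spiking$stim_intensity <- 3
  i3 <- round(spiking$stim_times[3] * rate) + 1L
  spiking$voltage[i3 + 10L] <- 20       # AP inside the analysis window
  pre <- sweep_set(list(good, spiking, bigger), rate)
  post <- sweep_set(list(good), rate)
  cmp <- apv_comparison(pre, post)
  expect_equal(cmp$sweep_index[cmp$condition == "pre"], 3L)
  expect_equal(cmp$stim_intensity, c(2, 1))
  all_spiking <- sweep_set(list(spiking), rate)
  expect_error(apv_comparison(all_spiking, post), "evoke an AP")
})

test_that("sweep sets round-trip through CSV + sidecar", {
  sim <- gen_ephys_sweeps(ephys_spec(), seed = 5)
  dir <- withr::local_tempdir()
  write_ephys_sweeps(sim, dir)
  meta <- yaml::read_yaml(file.path(dir, "sweeps.yaml"))
  files <- vapply(meta$sweeps, `[[`, "", "file")
  ss <- read_sweeps(file.path(dir, files), file.path(dir, "sweeps.yaml"))
  expect_equal(length(ss$sweeps), 5L)   # 1 passive + 3 spiking + 1 EPSP
  pp <- passive_properties(ss)
  expect_equal(pp$Rin, 200, tolerance = 1e-6)
  sf <- spike_features(ss)
  expect_equal(sf$ap_threshold, sim$truth$ap_threshold, tolerance = 1e-6)
})
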