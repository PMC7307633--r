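# Seeded synthetic-data generators. Each generator is a pure function of
# (spec, seed): identical inputs give identical outputs, and every output
# comes with a ground-truth table sufficient to score the downstream
# analysis without re-deriving truth.

# ---------------------------------------------------------------- morphology

#' Specification of a synthetic morphology cohort
#'
#' Targets describe one developmental group. Defaults emulate critical-
#' period (p12-p14) layer 2 neurons: apical TDBL 1800 um over 25 branches
#' (mean BL 72 um), a smaller basal tree whose size grows with soma depth
#' in layer 2 (the superficial-to-deep gradient separating layer 2a from
#' layer 2b), log-normal branch lengths and a flat soma-depth
#' distribution across layer 2.
#'
#' @param age_group label stored in cell metadata.
#' @param apical_nb,apical_tdbl apical branch-count and TDBL (um) targets.
#' @param basal_nb,basal_tdbl basal targets; `basal_tdbl` is the cohort
#'   mean, modulated per cell by the depth gradient.
#' @param basal_depth_gradient relative basal-TDBL slope over depth: the
#'   per-cell target is `basal_tdbl * (1 + g * (depth - mean(depth)))`.
#' @param bl_cv coefficient of variation of log-normal branch lengths.
#' @param nb_sd_frac SD of per-cell branch counts as a fraction of the
#'   target.
#' @param apical_stems,basal_stems stem counts (basal: inclusive range).
#' @param depth_range soma depth_norm range within layer 2.
#' @param layer2_width,l1b_width laminar widths, um.
#' @param min_branch_len feasibility floor for branch lengths, um.
#' @return Object of class `morph_cohort_spec`.
#' @export
morph_cohort_spec <- function(age_group = "p12-p14",
                              apical_nb = 25, apical_tdbl = 1800,
                              basal_nb = 15, basal_tdbl = 900,
                              basal_depth_gradient = 0.8,
                              bl_cv = 0.35, nb_sd_frac = 0.15,
                              apical_stems = 1, basal_stems = c(2, 4),
                              depth_range = c(0.02, 0.98),
                              layer2_width = 120, l1b_width = 60,
                              min_branch_len = 2) {
  spec <- list(age_group = age_group, apical_nb = apical_nb,
               apical_tdbl = apical_tdbl, basal_nb = basal_nb,
               basal_tdbl = basal_tdbl,
               basal_depth_gradient = basal_depth_gradient,
               bl_cv = bl_cv, nb_sd_frac = nb_sd_frac,
               apical_stems = apical_stems,
               basal_stems = sort(basal_stems)[c(1, length(basal_stems))],
               depth_range = depth_range, layer2_width = layer2_width,
               l1b_width = l1b_width, min_branch_len = min_branch_len)
  for (nm in c("apical_nb", "apical_tdbl", "basal_nb", "basal_tdbl",
               "layer2_width", "l1b_width"))
    .assert_scalar_num(spec[[nm]], nm, 0, strict = TRUE)
  if (any(depth_range < 0) || any(depth_range > 1 + 1e-9) ||
      depth_range[1] >= depth_range[2])
    stop("`depth_range` must be an increasing range inside [0, 1]",
         call. = FALSE)
  # infeasible targets: mean branch length below the floor
  if (apical_tdbl / apical_nb < min_branch_len ||
      basal_tdbl / basal_nb < min_branch_len)
    stop("infeasible targets: TDBL < NB * minimum branch length",
         call. = FALSE)
  structure(spec, class = "morph_cohort_spec")
}

# branch topology for one compartment: exact branch count `nb` with
# `stems` stems; bifurcations added at random tips (one trifurcation
# absorbs an odd remainder)
.gen_tree_topology <- function(nb, stems) {
  stems <- max(1L, min(stems, nb))
  if ((nb - stems) == 1L) nb <- nb + 1L  # a single extra branch is not a tree
  parent <- rep(0L, stems)               # 0 = soma
  remaining <- nb - stems
  adds <- rep(2L, remaining %/% 2L)
  if (remaining %% 2L == 1L) adds[1L] <- 3L
  for (k in adds) {
    is_tip <- !(seq_along(parent) %in% parent)
    tip <- if (sum(is_tip) == 1L) which(is_tip) else
      sample(which(is_tip), 1L)
    parent <- c(parent, rep(tip, k))
  }
  parent
}

# log-normal lengths with given mean and CV
.rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# planar/axial split of branch length: planar^2 + z^2 = 1 keeps the
# realised 3-D arc length equal to the designed branch length
.z_frac <- 0.1
.planar_frac <- sqrt(1 - .z_frac^2)

# grow one compartment's node table from a branch topology; each branch is
# a straight 2-segment chain (the midpoint node exercises degree-2 merging)
.grow_compartment <- function(soma_xy, parent_branch, lengths, base_angle,
                              spread, type_code, next_id) {
  nb <- length(parent_branch)
  nodes <- vector("list", nb)
  endpos <- matrix(NA_real_, nb, 3)   # distal node position per branch
  endang <- numeric(nb)               # planar heading per branch
  end_id <- integer(nb)
  for (b in seq_len(nb)) {
    p <- parent_branch[b]
    if (p == 0L) {
      anchor <- c(soma_xy, 0)
      ang <- base_angle + stats::runif(1, -spread, spread)
      par_id <- 1L
    } else {
      anchor <- endpos[p, ]
      ang <- endang[p] + stats::runif(1, -spread, spread)
      par_id <- end_id[p]
    }
    dz <- lengths[b] * .z_frac * sign(stats::runif(1) - 0.5)
    step <- c(cos(ang), sin(ang)) * lengths[b] * .planar_frac
    mid <- anchor + c(step, dz) / 2
    fin <- anchor + c(step, dz)
    id_mid <- next_id; id_end <- next_id + 1L
    next_id <- next_id + 2L
    nodes[[b]] <- data.frame(
      id = c(id_mid, id_end), type = type_code,
      x = c(mid[1], fin[1]), y = c(mid[2], fin[2]), z = c(mid[3], fin[3]),
      radius = 0.5, parent = c(par_id, id_mid))
    endpos[b, ] <- fin
    endang[b] <- ang
    end_id[b] <- id_end
  }
  list(nodes = do.call(rbind, nodes), next_id = next_id)
}

#' Generate a ground-truthed cohort of SWC morphologies
#'
#' Builds `n_cells` stochastic recursive trees matching a
#' [morph_cohort_spec()], in slice coordinates compatible with the
#' generated [layer_geometry()] (depth axis +y; apical trees grow
#' superficially, basal trees grow deep). Per-cell realised branch
#' counts, TDBL and branch lengths are recorded as ground truth, and the
#' SWC node tables round-trip through [read_swc()]/[write_swc()].
#'
#' @param spec a `morph_cohort_spec`.
#' @param n_cells number of cells.
#' @param seed RNG seed.
#' @return list of class `morph_cohort`: `cells` (list of
#'   [neuron_morphology()]), `truth` (one row per cell: realised and
#'   target morphometrics), `geometry` (a `layer_geometry`), `spec`,
#'   `seed`.
#' @export
gen_morphology_cohort <- function(spec, n_cells, seed = 1) {
  stopifnot(inherits(spec, "morph_cohort_spec"))
  .assert_scalar_num(n_cells, "n_cells", 1)
  geometry <- layer_geometry(
    l1a_l1b = cbind(c(-400, 0, 400), -spec$l1b_width),
    l1b_l2a = cbind(c(-400, 0, 400), 0),
    l2_l3 = cbind(c(-400, 0, 400), spec$layer2_width),
    depth_axis = "+y")
  .with_seed(seed, {
    cells <- vector("list", n_cells)
    rows <- vector("list", n_cells)
    mid_depth <- mean(spec$depth_range)
    for (i in seq_len(n_cells)) {
      d <- stats::runif(1, spec$depth_range[1], spec$depth_range[2])
      cls <- if (d < 1 / 3) "L2A" else "L2B"
      soma <- c(stats::runif(1, -50, 50), d * spec$layer2_width)
      basal_tdbl_i <- spec$basal_tdbl *
        (1 + spec$basal_depth_gradient * (d - mid_depth))

      draw_nb <- function(target) max(1L, as.integer(round(
        stats::rnorm(1, target, spec$nb_sd_frac * target))))
      nb_a <- draw_nb(spec$apical_nb)
      nb_b <- draw_nb(spec$basal_nb)
      stems_b <- sample(seq(spec$basal_stems[1], spec$basal_stems[2]), 1L)

      topo_a <- .gen_tree_topology(nb_a, spec$apical_stems)
      topo_b <- .gen_tree_topology(nb_b, stems_b)
      len_a <- pmax(spec$min_branch_len, .rlnorm_mean_cv(
        length(topo_a), spec$apical_tdbl / length(topo_a), spec$bl_cv))
      len_b <- pmax(spec$min_branch_len, .rlnorm_mean_cv(
        length(topo_b), basal_tdbl_i / length(topo_b), spec$bl_cv))

      soma_node <- data.frame(id = 1L, type = SWC_SOMA, x = soma[1],
                              y = soma[2], z = 0, radius = 5, parent = -1L)
      ap <- .grow_compartment(soma, topo_a, len_a, base_angle = -pi / 2,
                              spread = 0.7, type_code = SWC_APICAL,
                              next_id = 2L)
      ba <- .grow_compartment(soma, topo_b, len_b, base_angle = pi / 2,
                              spread = 1.0, type_code = SWC_BASAL,
                              next_id = ap$next_id)
      md <- list(age_group = spec$age_group, depth_norm = d,
                 cell_class = cls)
      cells[[i]] <- neuron_morphology(rbind(soma_node, ap$nodes, ba$nodes),
                                      metadata = md)
      rows[[i]] <- data.frame(
        cell_id = i, age_group = spec$age_group, cell_class = cls,
        depth_norm = d,
        apical_nb = length(topo_a), apical_tdbl = sum(len_a),
        apical_stems = min(spec$apical_stems, length(topo_a)),
        basal_nb = length(topo_b), basal_tdbl = sum(len_b),
        basal_stems = min(stems_b, length(topo_b)),
        target_apical_nb = spec$apical_nb,
        target_apical_tdbl = spec$apical_tdbl,
        target_basal_nb = spec$basal_nb,
        target_basal_tdbl = basal_tdbl_i)
    }
    structure(list(cells = cells, truth = do.call(rbind, rows),
                   geometry = geometry, spec = spec, seed = seed),
              class = "morph_cohort")
  })
}

#' Write a generated cohort to disk (SWC + CSV)
#'
#' @param cohort a `morph_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; writes `cell_###.swc`, `layer_geometry.csv`
#'   and `ground_truth.csv`.
#' @export
write_morph_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "morph_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$cells))
    write_swc(cohort$cells[[i]],
              file.path(dir, sprintf("cell_%03d.swc", i)))
  write_layer_geometry(cohort$geometry, file.path(dir, "layer_geometry.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# ------------------------------------------------------------------- calcium

#' Specification of a synthetic calcium-imaging field of view
#'
#' Defaults emulate a neonatal aPCx population recording: 50 layer-2
#' cells, 5 min at 10 Hz, additive Gaussian noise, sparse per-cell
#' transients (instant rise to a plateau of the stated width, then
#' exponential decay, GCaMP6f-like tau = 0.5 s), plus network-wide global
#' events that recruit cells with a probability increasing linearly with
#' depth in layer 2 — the depth-graded synchrony the coactivity analysis
#' is designed to detect.
#'
#' @param n_cells number of ROIs.
#' @param frames recording length in frames.
#' @param sampling_rate Hz.
#' @param noise_sd baseline noise SD in dF/F units.
#' @param event_rate_per_min per-cell rate of individual transients.
#' @param global_rate_per_min rate of network-wide events.
#' @param recruit_range global-event recruitment probability at depth 0
#'   and depth 1 (must be non-decreasing).
#' @param amp_meanlog,amp_sdlog log-normal amplitude distribution in
#'   units of the noise SD.
#' @param amp_min amplitude floor (noise-SD units).
#' @param width_range plateau width range, frames (inclusive).
#' @param decay_tau_s transient decay time constant, s.
#' @param baseline_range raw-fluorescence baseline range (a.u.).
#' @return Object of class `ca_fov_spec`.
#' @export
ca_fov_spec <- function(n_cells = 50, frames = 3000, sampling_rate = 10,
                        noise_sd = 0.02, event_rate_per_min = 1,
                        global_rate_per_min = 1,
                        recruit_range = c(0.4, 0.8),
                        amp_meanlog = log(5), amp_sdlog = 0.25,
                        amp_min = 3, width_range = c(3, 6),
                        decay_tau_s = 0.5, baseline_range = c(80, 120)) {
  .assert_scalar_num(n_cells, "n_cells", 1)
  .assert_scalar_num(frames, "frames", 60)
  .assert_scalar_num(sampling_rate, "sampling_rate", 0, strict = TRUE)
  .assert_scalar_num(noise_sd, "noise_sd", 0)
  .assert_scalar_num(event_rate_per_min, "event_rate_per_min", 0)
  .assert_scalar_num(global_rate_per_min, "global_rate_per_min", 0)
  if (recruit_range[2] < recruit_range[1])
    stop("recruitment probability must be non-decreasing with depth",
         call. = FALSE)
  if (any(recruit_range < 0) || any(recruit_range > 1))
    stop("`recruit_range` must lie in [0, 1]", call. = FALSE)
  structure(list(n_cells = n_cells, frames = frames,
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 event_rate_per_min = event_rate_per_min,
                 global_rate_per_min = global_rate_per_min,
                 recruit_range = recruit_range, amp_meanlog = amp_meanlog,
                 amp_sdlog = amp_sdlog, amp_min = amp_min,
                 width_range = width_range, decay_tau_s = decay_tau_s,
                 baseline_range = baseline_range),
            class = "ca_fov_spec")
}

#' Generate a ground-truthed calcium-imaging field of view
#'
#' Traces are `F0 * (1 + signal) + F0 * noise_sd * N(0, 1)` with signal
#' transients as described in [ca_fov_spec()]. Global events recruit
#' cells by depth-dependent Bernoulli draws; all recruited cells share the
#' event onset. The truth table records every injected transient (merged
#' when overlapping within a cell) with its plateau span, an extended
#' offset including decay frames expected above a 2.5-SD threshold, the
#' amplitude and the global-event id (`NA` for individual transients).
#'
#' @param spec a `ca_fov_spec`.
#' @param seed RNG seed.
#' @return list of class `ca_fov`: `rois` (a [roi_trace_set()]), `truth`,
#'   `spec`, `seed`.
#' @export
gen_ca_fov <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "ca_fov_spec"))
  .with_seed(seed, {
    nt <- spec$frames; nc <- spec$n_cells
    dur_min <- nt / spec$sampling_rate / 60
    depth <- stats::runif(nc)
    f0 <- stats::runif(nc, spec$baseline_range[1], spec$baseline_range[2])
    tau_frames <- spec$decay_tau_s * spec$sampling_rate
    decay_len <- max(1L, ceiling(6 * tau_frames))
    margin <- 5L
    max_onset <- nt - max(spec$width_range) - decay_len - margin
    if (max_onset <= margin)
      stop("recording too short for the transient kernel", call. = FALSE)

    draw_amp <- function(n) pmax(spec$amp_min,
                                 stats::rlnorm(n, spec$amp_meanlog,
                                               spec$amp_sdlog))
    draw_width <- function(n)
      sample(seq(spec$width_range[1], spec$width_range[2]), n, replace = TRUE)

    # global events: shared onsets, depth-dependent recruitment
    n_glob <- stats::rpois(1, spec$global_rate_per_min * dur_min)
    glob_onset <- if (n_glob) sort(sample(seq(margin + 1L, max_onset),
                                          n_glob)) else integer(0)
    p_recruit <- spec$recruit_range[1] +
      (spec$recruit_range[2] - spec$recruit_range[1]) * depth

    signal <- matrix(0, nt, nc)
    ev <- list()
    add_event <- function(cell, onset, amp, width, gid) {
      idx_plateau <- onset:(onset + width - 1L)
      k <- seq_len(decay_len)
      idx_decay <- onset + width - 1L + k
      sig <- numeric(nt)
      sig[idx_plateau] <- amp
      sig[idx_decay] <- amp * exp(-k / tau_frames)
      # decay frames until the transient falls back to the 1-SD noise
      # floor; detections starting in this span are signal-driven
      extra <- if (amp > 1) floor(tau_frames * log(amp)) else 0L
      list(sig = sig,
           row = data.frame(roi_id = cell, onset = onset,
                            offset = onset + width - 1L,
                            offset_ext = min(nt, onset + width - 1L + extra),
                            amp_sd = amp, width = width, global_id = gid))
    }
    for (cell in seq_len(nc)) {
      n_ind <- stats::rpois(1, spec$event_rate_per_min * dur_min)
      onsets <- if (n_ind) sample(seq(margin + 1L, max_onset), n_ind)
        else integer(0)
      gids <- rep(NA_integer_, n_ind)
      if (n_glob) {
        hit <- stats::runif(n_glob) < p_recruit[cell]
        onsets <- c(onsets, glob_onset[hit])
        gids <- c(gids, which(hit))
      }
      if (length(onsets)) {
        amps <- draw_amp(length(onsets))
        widths <- draw_width(length(onsets))
        for (j in seq_along(onsets)) {
          e <- add_event(cell, onsets[j], amps[j], widths[j], gids[j])
          signal[, cell] <- signal[, cell] + e$sig
          ev[[length(ev) + 1L]] <- e$row
        }
      }
    }
    truth <- if (length(ev)) do.call(rbind, ev) else
      data.frame(roi_id = integer(0), onset = integer(0),
                 offset = integer(0), offset_ext = integer(0),
                 amp_sd = numeric(0), width = integer(0),
                 global_id = integer(0))
    truth <- .merge_truth_events(truth)

    noise <- matrix(stats::rnorm(nt * nc), nt, nc)
    traces <- sweep(1 + signal * spec$noise_sd, 2L, f0, `*`) +
      sweep(noise * spec$noise_sd, 2L, f0, `*`)
    rois <- roi_trace_set(traces, spec$sampling_rate,
                          depth_norm = depth,
                          pixel_count = rep(100L, nc))
    structure(list(rois = rois, truth = truth, global_onsets = glob_onset,
                   spec = spec, seed = seed), class = "ca_fov")
  })
}

# merge overlapping injected transients within a cell into one truth event
.merge_truth_events <- function(truth) {
  if (nrow(truth) < 2L) return(truth)
  out <- list()
  for (cell in unique(truth$roi_id)) {
    sub <- truth[truth$roi_id == cell, , drop = FALSE]
    sub <- sub[order(sub$onset), , drop = FALSE]
    cur <- sub[1L, ]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$onset[i] <= cur$offset_ext) {
        cur$offset <- max(cur$offset, sub$offset[i])
        cur$offset_ext <- max(cur$offset_ext, sub$offset_ext[i])
        cur$amp_sd <- max(cur$amp_sd, sub$amp_sd[i])
        if (is.na(cur$global_id)) cur$global_id <- sub$global_id[i]
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- sub[i, ]
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$roi_id, res$onset), ]
  rownames(res) <- NULL
  res
}

#' Score detected events against generator ground truth
#'
#' A detected event is a true positive if its span overlaps a truth
#' event's span (plateau plus the decay frames still above the noise
#' floor) in the same ROI; a truth event is recalled if at least one
#' detection overlaps it.
#'
#' @param detected data.frame from [detect_fov_events()] (`roi_id`,
#'   `onset`, `offset`).
#' @param truth truth table from [gen_ca_fov()].
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`,
#'   `true_positives`.
#' @export
score_events <- function(detected, truth) {
  if (nrow(truth) == 0L)
    return(list(recall = NA_real_, precision = if (nrow(detected)) 0 else
      NA_real_, n_truth = 0L, n_detected = nrow(detected),
      true_positives = 0L))
  match_det <- logical(nrow(detected))
  match_truth <- logical(nrow(truth))
  for (i in seq_len(nrow(detected))) {
    hit <- truth$roi_id == detected$roi_id[i] &
      truth$onset <= detected$offset[i] &
      truth$offset_ext >= detected$onset[i]
    if (any(hit)) {
      match_det[i] <- TRUE
      match_truth[hit] <- TRUE
    }
  }
  list(recall = mean(match_truth),
       precision = if (nrow(detected)) mean(match_det) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(detected),
       true_positives = sum(match_det))
}

#' Write a generated FOV to disk (long CSV + truth CSV)
#' @param fov a `ca_fov`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ca_fov <- function(fov, dir) {
  stopifnot(inherits(fov, "ca_fov"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- fov$rois$traces
  long <- data.frame(
    frame = rep(seq_len(nrow(tr)), times = ncol(tr)),
    roi_id = rep(fov$rois$roi_id, each = nrow(tr)),
    F = as.vector(tr),
    depth_norm = rep(fov$rois$depth_norm, each = nrow(tr)),
    pixel_count = rep(fov$rois$pixel_count, each = nrow(tr)))
  utils::write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(fov$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# --------------------------------------------------------------------- ephys

#' Specification of synthetic current-clamp sweeps
#'
#' Ground-truthed fixtures for the feature extractors: an RC response to a
#' hyperpolarizing step, a family of depolarizing 600-ms steps carrying
#' stylised action potentials whose 1%-of-max-slope threshold, fAHP and
#' first ISI are known by construction, and 3 x 50 Hz EPSP sweeps.
#'
#' @param vm resting potential, mV.
#' @param r_mohm input resistance, MOhm.
#' @param tau_ms membrane time constant, ms.
#' @param step_pa hyperpolarizing step amplitude, pA.
#' @param baseline_ms,step_ms pre-step baseline and step duration, ms.
#' @param sampling_rate Hz (>= 10 kHz).
#' @param noise_sd_mv additive Gaussian voltage noise, mV.
#' @param spike_step_pa depolarizing step amplitudes, pA.
#' @param spike_counts AP count per depolarizing step.
#' @param first_isi_ms ISI between APs 1 and 2, ms.
#' @param ap_threshold_mv,ap_peak_mv,fahp_mv AP waveform parameters; the
#'   fAHP trough sits 3 ms after the peak.
#' @param epsp_amplitudes_mv per-pulse EPSP amplitudes (3 pulses, 50 Hz).
#' @param epsp_shape `"alpha"` (5-ms alpha kernels) or `"square"`
#'   (rectangular 60-ms third response, analytically exact metrics).
#' @return Object of class `ephys_spec`.
#' @export
ephys_spec <- function(vm = -70, r_mohm = 200, tau_ms = 20, step_pa = -80,
                       baseline_ms = 200, step_ms = 600,
                       sampling_rate = 20000, noise_sd_mv = 0,
                       spike_step_pa = c(100, 180, 260),
                       spike_counts = c(4, 10, 13),
                       first_isi_ms = 25,
                       ap_threshold_mv = -45, ap_peak_mv = 30,
                       fahp_mv = 8,
                       epsp_amplitudes_mv = c(1, 1.5, 2),
                       epsp_shape = c("alpha", "square")) {
  .assert_scalar_num(r_mohm, "r_mohm", 0, strict = TRUE)
  .assert_scalar_num(tau_ms, "tau_ms", 0, strict = TRUE)
  if (sampling_rate < 10000)
    stop("`sampling_rate` must be >= 10 kHz", call. = FALSE)
  structure(list(vm = vm, r_mohm = r_mohm, tau_ms = tau_ms,
                 step_pa = step_pa, baseline_ms = baseline_ms,
                 step_ms = step_ms, sampling_rate = sampling_rate,
                 noise_sd_mv = noise_sd_mv, spike_step_pa = spike_step_pa,
                 spike_counts = spike_counts, first_isi_ms = first_isi_ms,
                 ap_threshold_mv = ap_threshold_mv,
                 ap_peak_mv = ap_peak_mv, fahp_mv = fahp_mv,
                 epsp_amplitudes_mv = epsp_amplitudes_mv,
                 epsp_shape = match.arg(epsp_shape)),
            class = "ephys_spec")
}

# Stylised AP upstroke as per-sample slope increments (mV/ms). The
# central-difference slope at sample j of the upstroke is
# (s[j] + s[j+1]) / 2, so the 1%-of-max-slope threshold sample is known
# analytically from the template.
.ap_slope_template <- function(total_rise_mv, dt_ms) {
  shape <- c(1, 1, 4, 40, 120, 240, 400, 400, 240, 54)
  shape * total_rise_mv / (sum(shape) * dt_ms)
}

# analytic threshold offset (samples from upstroke start) and rise to it
.ap_template_threshold <- function(s, ramp_slope) {
  cen <- (c(ramp_slope, s[-length(s)]) + s) / 2   # central slope at sample j-1
  crit <- 0.01 * max(cen)
  j <- which(cen >= crit)[1L]                     # first crossing
  list(offset = j - 1L, rise = sum(s[seq_len(j - 1L)]))
}

#' Generate ground-truthed current-clamp sweeps
#'
#' @param spec an [ephys_spec()].
#' @param seed RNG seed (only used when `noise_sd_mv > 0`).
#' @return list of class `ephys_sweeps`: `passive`, `spiking`, `epsp`
#'   ([sweep_set()]s) and `truth` (designed Vm/Rin/tau/Cm, AP threshold
#'   voltage and sample, fAHP, instant frequency, chosen step, EPSP
#'   amplitude/AUC for the square shape).
#' @export
gen_ephys_sweeps <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "ephys_spec"))
  .with_seed(seed, {
    rate <- spec$sampling_rate
    dt_ms <- 1000 / rate
    noise <- function(n) if (spec$noise_sd_mv > 0)
      stats::rnorm(n, 0, spec$noise_sd_mv) else numeric(n)

    # ---- passive RC sweep
    nb <- round(spec$baseline_ms / dt_ms)
    ns <- round(spec$step_ms / dt_ms)
    npost <- round(200 / dt_ms)
    dv <- spec$r_mohm * spec$step_pa / 1000          # mV
    t_step <- (seq_len(ns) - 1L) * dt_ms
    v_pass <- c(rep(spec$vm, nb),
                spec$vm + dv * (1 - exp(-t_step / spec$tau_ms)),
                spec$vm + dv * exp(-(seq_len(npost) - 1L) * dt_ms /
                                     spec$tau_ms))
    passive <- sweep_set(list(list(
      voltage = v_pass + noise(length(v_pass)),
      step = list(amplitude = spec$step_pa, onset = spec$baseline_ms / 1000,
                  duration = spec$step_ms / 1000))), rate)

    # ---- spiking sweeps
    ramp_slope <- 0.5                                # mV/ms pre-AP ramp
    inter_level <- spec$ap_threshold_mv - 1.3        # flat inter-AP level
    s_up <- .ap_slope_template(spec$ap_peak_mv - inter_level -
                                 ramp_slope * 1.4, dt_ms)
    # waveform pieces (sample counts)
    n_ramp <- round(1.4 / dt_ms)
    thr <- .ap_template_threshold(s_up, ramp_slope)
    gt_thr_v <- inter_level + ramp_slope * 1.4 + thr$rise * dt_ms
    n_down <- round(3 / dt_ms)                       # peak -> trough, 3 ms
    trough_v <- gt_thr_v - spec$fahp_mv
    n_rec <- round(2 / dt_ms)                        # trough -> inter level

    ap_wave <- function() {
      up <- cumsum(s_up) * dt_ms
      c(inter_level + ramp_slope * dt_ms * seq_len(n_ramp),
        inter_level + ramp_slope * 1.4 + up,
        spec$ap_peak_mv + (trough_v - spec$ap_peak_mv) *
          seq_len(n_down) / n_down,
        trough_v + (inter_level - trough_v) * seq_len(n_rec) / n_rec)
    }
    wave <- ap_wave()
    ap_len <- length(wave)
    peak_offset <- n_ramp + length(s_up)             # sample of the peak
    sweeps <- list()
    for (k in seq_along(spec$spike_step_pa)) {
      n_ap <- spec$spike_counts[k]
      on_idx <- nb + 1L
      # subthreshold charging toward the inter-AP level
      v <- c(rep(spec$vm, nb),
             inter_level + (spec$vm - inter_level) *
               exp(-(seq_len(ns) - 1L) * dt_ms / spec$tau_ms),
             rep(spec$vm, npost))
      first_ap <- on_idx + round(60 / dt_ms)         # 60 ms after onset
      isi <- round(spec$first_isi_ms / dt_ms)
      starts <- first_ap + (seq_len(n_ap) - 1L) * isi
      for (st in starts) v[st:(st + ap_len - 1L)] <- wave
      sweeps[[k]] <- list(
        voltage = v + noise(length(v)),
        step = list(amplitude = spec$spike_step_pa[k],
                    onset = spec$baseline_ms / 1000,
                    duration = spec$step_ms / 1000))
    }
    spiking <- sweep_set(sweeps, rate)
    chosen <- which(spec$spike_counts >= 9)[1L]
    gt_thr_idx <- as.integer(nb + round(60 / dt_ms) + n_ramp + thr$offset)

    # ---- EPSP sweeps (3 pulses at 50 Hz)
    stim1 <- 0.3
    stims <- stim1 + c(0, 0.02, 0.04)
    n_epsp <- round(0.5 * rate)
    t_s <- (seq_len(n_epsp) - 1L) / rate
    kernel <- function(t0, amp, dur) {
      # sample-index bounds avoid floating-point misses at the window edges
      i0 <- round(t0 * rate) + 1L
      i1 <- round((t0 + dur) * rate) + 1L
      idx <- seq_len(n_epsp)
      if (spec$epsp_shape == "alpha") {
        tt <- pmax(t_s - t_s[i0], 0)
        taua <- 0.005
        amp * (tt / taua) * exp(1 - tt / taua) * (idx >= i0)
      } else {
        amp * (idx >= i0 & idx <= i1)
      }
    }
    # square responses to pulses 1-2 are kept short so the third-pulse
    # analysis window carries the third response alone
    v_epsp <- spec$vm + kernel(stims[1], spec$epsp_amplitudes_mv[1], 0.01) +
      kernel(stims[2], spec$epsp_amplitudes_mv[2], 0.01) +
      kernel(stims[3], spec$epsp_amplitudes_mv[3], 0.06)
    epsp <- sweep_set(list(list(voltage = v_epsp + noise(n_epsp),
                                stim_times = stims, stim_intensity = 1)),
                      rate)

    truth <- list(
      Vm = spec$vm, Rin = spec$r_mohm, tau = spec$tau_ms,
      Cm = 1000 * spec$tau_ms / spec$r_mohm,
      ap_threshold = gt_thr_v, ap_threshold_index = gt_thr_idx,
      fAHP = spec$fahp_mv,
      instant_freq = 1000 / spec$first_isi_ms,
      chosen_step = chosen,
      epsp_amplitude = if (spec$epsp_shape == "square")
        spec$epsp_amplitudes_mv[3] else NA_real_,
      epsp_auc = if (spec$epsp_shape == "square")
        spec$epsp_amplitudes_mv[3] * 60 else NA_real_)
    structure(list(passive = passive, spiking = spiking, epsp = epsp,
                   truth = truth, spec = spec, seed = seed),
              class = "ephys_sweeps")
  })
}

#' Write generated sweeps to disk (CSV per sweep + YAML sidecar)
#' @param sim an `ephys_sweeps` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ephys_sweeps <- function(sim, dir) {
  stopifnot(inherits(sim, "ephys_sweeps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_sweeps <- list()
  paths <- character(0)
  for (grp in c("passive", "spiking", "epsp")) {
    ss <- sim[[grp]]
    for (i in seq_along(ss$sweeps)) {
      sw <- ss$sweeps[[i]]
      f <- sprintf("%s_%02d.csv", grp, i)
      utils::write.csv(data.frame(voltage = sw$voltage),
                       file.path(dir, f), row.names = FALSE)
      paths <- c(paths, f)
      all_sweeps[[length(all_sweeps) + 1L]] <-
        list(file = f, step = sw$step,
             stim_times = as.list(sw$stim_times),
             stim_intensity = sw$stim_intensity)
    }
  }
  yaml::write_yaml(list(sampling_rate = sim$passive$sampling_rate,
                        sweeps = all_sweeps),
                   file.path(dir, "sweeps.yaml"))
  invisible(dir)
}
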