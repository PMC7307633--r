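# Current-clamp feature extraction: passive membrane properties from a
# hyperpolarizing step, action-potential features from depolarizing step
# families, and EPSP metrics from 3 x 50 Hz afferent stimulation sweeps.
#
# Units: voltage mV, current pA, time s (sampling_rate Hz), Rin MOhm,
# tau ms, Cm pF. With these units Rin = 1000 * dV/I and Cm = 1000 * tau/Rin.

#' A set of current-clamp sweeps
#'
#' @param sweeps list of sweeps; each sweep is a list with `voltage` (mV
#'   per sample) and either `current` (pA per sample) or `step` metadata
#'   (`amplitude` pA, `onset` s, `duration` s), plus optional `stim_times`
#'   (s, for EPSP sweeps) and `stim_intensity` (arbitrary units, for
#'   pharmacology comparisons).
#' @param sampling_rate Hz.
#' @return Object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, sampling_rate) {
  .assert_scalar_num(sampling_rate, "sampling_rate", 0, strict = TRUE)
  stopifnot(is.list(sweeps), length(sweeps) >= 1L)
  for (s in sweeps) {
    if (is.null(s$voltage)) stop("every sweep needs a `voltage` vector",
                                 call. = FALSE)
    if (!is.null(s$current) && length(s$current) != length(s$voltage))
      stop("sweep `current` and `voltage` lengths differ", call. = FALSE)
  }
  structure(list(sweeps = sweeps, sampling_rate = sampling_rate),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps @ %g kHz\n", length(x$sweeps),
              x$sampling_rate / 1000))
  invisible(x)
}

# step metadata for a sweep: from explicit metadata, or inferred from the
# command-current series (largest contiguous nonzero block)
.sweep_step <- function(s, rate) {
  if (!is.null(s$step)) return(s$step)
  if (is.null(s$current)) return(NULL)
  nz <- s$current != 0
  if (!any(nz)) return(list(amplitude = 0, onset = 0, duration = 0))
  r <- rle(nz)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  blocks <- which(r$values)
  k <- blocks[which.max(r$lengths[blocks])]
  list(amplitude = s$current[starts[k]], onset = (starts[k] - 1L) / rate,
       duration = r$lengths[k] / rate)
}

#' Passive membrane properties from a hyperpolarizing current step
#'
#' `Vm` is the mean of the pre-step baseline (which must span at least
#' 100 ms); the steady-state response is the mean over the last 20% of the
#' step; `Rin = dV_steady / I`; `tau` comes from a single-exponential fit
#' of the onset transient; `Cm = tau / Rin`.
#'
#' @param s a [sweep_set()]; the first sweep with a negative step
#'   amplitude is analysed.
#' @param fit_window fraction of the step duration used for the
#'   exponential fit (default 1, i.e. the whole step).
#' @return list of class `intrinsic_properties`: `Vm` (mV), `Rin` (MOhm),
#'   `tau` (ms), `Cm` (pF), plus `dV_steady`, `step` and `fit`
#'   (`NULL` with a `tau_status` diagnostic if the fit failed).
#' @export
passive_properties <- function(s, fit_window = 1) {
  stopifnot(inherits(s, "sweep_set"))
  rate <- s$sampling_rate
  sw <- NULL; step <- NULL
  for (cand in s$sweeps) {
    st <- .sweep_step(cand, rate)
    if (!is.null(st) && st$amplitude < 0) { sw <- cand; step <- st; break }
  }
  if (is.null(sw)) {
    # fall back to the first sweep and validate its amplitude
    sw <- s$sweeps[[1L]]
    step <- .sweep_step(sw, rate)
    if (is.null(step) || step$amplitude == 0)
      stop("no sweep with a nonzero current step", call. = FALSE)
  }
  v <- sw$voltage
  on_idx <- round(step$onset * rate) + 1L
  off_idx <- on_idx + round(step$duration * rate) - 1L
  if (step$onset < 0.1)
    stop("pre-step baseline must be at least 100 ms", call. = FALSE)
  vm <- mean(v[1:(on_idx - 1L)])
  ss_idx <- seq(off_idx - floor(0.2 * (off_idx - on_idx + 1L)) + 1L, off_idx)
  v_steady <- mean(v[ss_idx])
  dv <- v_steady - vm
  rin <- 1000 * dv / step$amplitude            # MOhm

  # exponential fit of the onset transient
  fit_len <- max(10L, round(fit_window * (off_idx - on_idx + 1L)))
  idx <- seq(on_idx, min(on_idx + fit_len - 1L, off_idx))
  tt <- (idx - on_idx) / rate * 1000           # ms from step onset
  vv <- v[idx]
  # crude tau start: time to reach 63.2% of the total deflection
  frac <- (vv - vm) / dv
  t63 <- tt[which(frac >= 0.632)[1L]]
  if (is.na(t63) || t63 <= 0) t63 <- max(tt) / 5
  fit <- tryCatch(
    stats::nls(vv ~ vs + (v0 - vs) * exp(-tt / tau),
               start = list(vs = v_steady, v0 = vm, tau = t63),
               # scaleOffset keeps the fit well-posed on (near-)noise-free
               # traces, where the relative-offset criterion degenerates
               control = stats::nls.control(maxiter = 200,
                                            scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tau <- NA_real_; cm <- NA_real_
    status <- "tau fit did not converge"
  } else {
    tau <- unname(stats::coef(fit)[["tau"]])
    cm <- 1000 * tau / rin                     # pF
    status <- "ok"
  }
  structure(list(Vm = vm, Rin = rin, tau = tau, Cm = cm,
                 dV_steady = dv, step = step, fit = fit,
                 tau_status = status),
            class = "intrinsic_properties")
}

#' @export
print.intrinsic_properties <- function(x, ...) {
  cat(sprintf("<intrinsic_properties> Vm %.1f mV | Rin %.1f MOhm | tau %s ms | Cm %s pF\n",
              x$Vm, x$Rin,
              if (is.na(x$tau)) "-" else sprintf("%.1f", x$tau),
              if (is.na(x$Cm)) "-" else sprintf("%.1f", x$Cm)))
  invisible(x)
}

#' Detect action potentials in a voltage trace
#'
#' APs are suprathreshold excursions whose peak exceeds `peak_threshold`
#' (default 0 mV); peaks closer than `refractory_ms` are merged (the
#' larger wins).
#'
#' @param v voltage trace (mV).
#' @param sampling_rate Hz.
#' @param peak_threshold mV.
#' @param refractory_ms merge window in ms.
#' @return integer vector of AP peak sample indices.
#' @export
detect_aps <- function(v, sampling_rate, peak_threshold = 0,
                       refractory_ms = 1) {
  above <- v > peak_threshold
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peaks <- vapply(runs, function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(v[seg])]
  }, 0L)
  # refractory merging
  if (length(peaks) > 1L) {
    min_gap <- refractory_ms / 1000 * sampling_rate
    keep <- peaks[1L]
    for (p in peaks[-1L]) {
      if (p - keep[length(keep)] < min_gap) {
        if (v[p] > v[keep[length(keep)]]) keep[length(keep)] <- p
      } else keep <- c(keep, p)
    }
    peaks <- keep
  }
  peaks
}

#' Action-potential features from depolarizing step sweeps
#'
#' Features are read from the first 600-ms current step that elicits at
#' least `min_aps` APs (default 9), on that step's first AP:
#' * **threshold** — membrane potential at the point where dV/dt (central
#'   differences) first reaches 1% of that AP's maximum rising slope,
#'   found by searching backward from the peak within the rising phase
#'   (bounded by the preceding ISI midpoint, or the step onset for the
#'   first AP);
#' * **fAHP** — threshold minus the voltage minimum within 5 ms after the
#'   peak;
#' * **instant_freq** — 1 / ISI between the first and second AP.
#'
#' @param s a [sweep_set()] of depolarizing steps.
#' @param min_aps minimum AP count for step selection.
#' @param step_duration_s required step duration (default 0.6 s;
#'   tolerance 10%).
#' @param peak_threshold,refractory_ms AP detection, see [detect_aps()].
#' @return list of class `spike_features`: `ap_threshold` (mV), `fAHP`
#'   (mV), `instant_freq` (Hz), `chosen_step` (index into the sweep set),
#'   `n_aps` and `status` ("ok" or a reason when no step qualifies).
#' @export
spike_features <- function(s, min_aps = 9, step_duration_s = 0.6,
                           peak_threshold = 0, refractory_ms = 1) {
  stopifnot(inherits(s, "sweep_set"))
  rate <- s$sampling_rate
  missing <- list(ap_threshold = NA_real_, fAHP = NA_real_,
                  instant_freq = NA_real_, chosen_step = NA_integer_,
                  n_aps = NA_integer_)
  for (i in seq_along(s$sweeps)) {
    sw <- s$sweeps[[i]]
    st <- .sweep_step(sw, rate)
    if (is.null(st) || st$amplitude <= 0) next
    if (abs(st$duration - step_duration_s) > 0.1 * step_duration_s) next
    peaks <- detect_aps(sw$voltage, rate, peak_threshold, refractory_ms)
    if (length(peaks) < min_aps) next

    v <- sw$voltage
    on_idx <- round(st$onset * rate) + 1L
    p1 <- peaks[1L]
    # rising-phase bound: preceding ISI midpoint, or step onset for AP #1
    thr <- .ap_threshold(v, rate, p1, lower = on_idx)
    post <- seq(p1 + 1L, min(p1 + round(0.005 * rate), length(v)))
    fahp <- thr$voltage - min(v[post])
    ifreq <- if (length(peaks) >= 2L) rate / (peaks[2L] - peaks[1L])
      else NA_real_
    return(structure(list(ap_threshold = thr$voltage, fAHP = fahp,
                          instant_freq = ifreq, chosen_step = i,
                          n_aps = length(peaks),
                          threshold_index = thr$index, status = "ok"),
                     class = "spike_features"))
  }
  structure(c(missing, list(status = sprintf(
    "no %g-ms step with >= %d APs", step_duration_s * 1000, min_aps))),
    class = "spike_features")
}

# 1%-of-max-slope AP threshold: central-difference dV/dt, max taken over
# the rising phase (lower..peak); searching backward from the peak, the
# threshold sample is the one after the last sample whose slope falls
# below 1% of the maximum.
.ap_threshold <- function(v, rate, peak, lower) {
  lower <- max(lower, 2L)
  hi <- min(peak, length(v) - 1L)
  idx <- lower:hi
  dvdt <- (v[idx + 1L] - v[idx - 1L]) / 2 * rate / 1000   # mV/ms
  mx <- max(dvdt)
  crit <- 0.01 * mx
  below <- which(dvdt < crit)
  k <- if (length(below)) max(below) + 1L else 1L
  if (k > length(idx)) k <- length(idx)
  list(voltage = v[idx[k]], index = idx[k])
}

#' @export
print.spike_features <- function(x, ...) {
  if (x$status != "ok") {
    cat("<spike_features>", x$status, "\n")
  } else {
    cat(sprintf(
      "<spike_features> threshold %.2f mV | fAHP %.2f mV | instant freq %s Hz (step %d, %d APs)\n",
      x$ap_threshold, x$fAHP,
      if (is.na(x$instant_freq)) "-" else sprintf("%.1f", x$instant_freq),
      x$chosen_step, x$n_aps))
  }
  invisible(x)
}

#' EPSP metrics from a 3 x 50 Hz stimulation sweep
#'
#' Baseline is the mean over the 50 ms preceding the first stimulus. The
#' analysis window is the 60 ms following the third pulse; `amplitude` is
#' the peak of the baseline-subtracted voltage in the window (the window
#' mean is reported alongside) and `auc` its trapezoidal integral in
#' mV*ms. A sweep with an AP inside the window is flagged.
#'
#' @param sweep one sweep (list with `voltage`, `stim_times`).
#' @param sampling_rate Hz.
#' @param window_ms analysis window after the third pulse (default 60).
#' @param baseline_ms pre-stimulus baseline length (default 50).
#' @param peak_threshold AP flag threshold (mV).
#' @return list of class `epsp_metrics`: `amplitude`, `amplitude_mean`
#'   (mV), `auc` (mV*ms), `baseline` (mV), `has_ap`.
#' @export
epsp_metrics <- function(sweep, sampling_rate, window_ms = 60,
                         baseline_ms = 50, peak_threshold = 0) {
  v <- sweep$voltage
  stim <- sweep$stim_times
  if (is.null(stim) || length(stim) < 3L)
    stop("sweep needs three `stim_times`", call. = FALSE)
  rate <- sampling_rate
  i1 <- round(stim[1L] * rate) + 1L
  i3 <- round(stim[3L] * rate) + 1L
  b0 <- i1 - round(baseline_ms / 1000 * rate)
  if (b0 < 1L) stop("trace too short for the pre-stimulus baseline",
                    call. = FALSE)
  w_end <- i3 + round(window_ms / 1000 * rate)
  if (w_end > length(v))
    stop("60-ms analysis window extends beyond the trace", call. = FALSE)
  baseline <- mean(v[b0:(i1 - 1L)])
  win <- i3:w_end
  dv <- v[win] - baseline
  t_ms <- (win - win[1L]) / rate * 1000
  structure(list(amplitude = max(dv), amplitude_mean = mean(dv),
                 auc = .trapz(t_ms, dv), baseline = baseline,
                 has_ap = any(v[win] > peak_threshold),
                 window = c(i3, w_end)),
            class = "epsp_metrics")
}

#' @export
print.epsp_metrics <- function(x, ...) {
  cat(sprintf("<epsp_metrics> amplitude %.2f mV | AUC %.1f mV*ms%s\n",
              x$amplitude, x$auc, if (x$has_ap) " [AP in window]" else ""))
  invisible(x)
}

#' Paired EPSP comparison across a pharmacological condition
#'
#' For each condition, selects the largest-intensity sweep that does not
#' evoke an AP within the analysis window and returns its EPSP metrics,
#' e.g. to quantify NMDA-receptor blockade (APV) effects on apical
#' dendritic integration.
#'
#' @param pre,post [sweep_set()]s for the two conditions; sweeps carry
#'   `stim_intensity` and `stim_times`.
#' @param ... passed to [epsp_metrics()].
#' @return data.frame with one row per condition: `condition`,
#'   `sweep_index`, `stim_intensity`, `amplitude`, `auc`.
#' @export
apv_comparison <- function(pre, post, ...) {
  pick <- function(ss, label) {
    stopifnot(inherits(ss, "sweep_set"))
    intens <- vapply(ss$sweeps, function(s) s$stim_intensity %||% NA_real_, 0)
    ord <- order(intens, decreasing = TRUE)
    for (i in ord) {
      m <- epsp_metrics(ss$sweeps[[i]], ss$sampling_rate, ...)
      if (!m$has_ap)
        return(data.frame(condition = label, sweep_index = i,
                          stim_intensity = intens[i],
                          amplitude = m$amplitude, auc = m$auc))
    }
    stop("all ", label, " sweeps evoke an AP in the analysis window",
         call. = FALSE)
  }
  rbind(pick(pre, "pre"), pick(post, "post"))
}

#' Read a sweep set from CSV files plus a metadata sidecar
#'
#' Each sweep lives in a one-column (or `voltage` column) CSV; the sidecar
#' (YAML or JSON) provides `sampling_rate` and per-sweep `step`,
#' `stim_times` and `stim_intensity` entries under `sweeps`.
#'
#' @param paths character vector of sweep CSV paths (order = sidecar
#'   order).
#' @param sidecar path to the YAML/JSON metadata file.
#' @return A [sweep_set()].
#' @export
read_sweeps <- function(paths, sidecar) {
  meta <- if (grepl("\\.json$", sidecar, ignore.case = TRUE))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else
    yaml::read_yaml(sidecar)
  sweeps <- lapply(seq_along(paths), function(i) {
    df <- utils::read.csv(paths[i])
    v <- if ("voltage" %in% names(df)) df$voltage else df[[1L]]
    sm <- if (!is.null(meta$sweeps) && length(meta$sweeps) >= i)
      meta$sweeps[[i]] else list()
    list(voltage = as.numeric(v), step = sm$step,
         stim_times = unlist(sm$stim_times),
         stim_intensity = sm$stim_intensity)
  })
  sweep_set(sweeps, meta$sampling_rate)
}
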