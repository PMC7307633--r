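# Two-layer dendritic integration model.
#
# A layer 2 neuron fires to a stimulus if the distributed input over the
# whole tree reaches ndist active synapses (linear somatic integration),
# or if any single branch collects nclus active synapses and triggers a
# dendritic NMDA-spike (nonlinear branch gate). With synapse placement
# uniform per unit dendritic length, the per-branch active-synapse count
# is Poisson with mean S * BL / TDBL, and the clustered response
# probability is one minus the probability that no branch crosses nclus.

#' Circuit census and threshold parameters for the integration model
#'
#' Defaults follow the quantitative description of mouse piriform cortex
#' used throughout: 3700 olfactory-bulb glomeruli, 9.7e7 glomerular
#' synapses onto 41,000 layer 2 neurons, at most 70 coincidently active
#' synapses per neuron, somatic threshold `ndist = 40`, dendritic-spike
#' threshold `nclus = 10`, mean total dendritic branch length 1800 um and
#' mean branch lengths between 40 and 110 um (mean 72).
#'
#' @param n_glomeruli,total_synapses,n_neurons circuit census counts.
#' @param s_max maximum number of active synapses per neuron.
#' @param ndist distributed (somatic) threshold, active synapses.
#' @param nclus clustered (single-branch, NMDA-spike) threshold.
#' @param tdbl total dendritic branch length, um.
#' @param bl_range,bl_mean observed mean-branch-length range and mean, um.
#' @return Object of class `integration_params`.
#' @export
integration_params <- function(n_glomeruli = 3700, total_synapses = 9.7e7,
                               n_neurons = 41000, s_max = 70, ndist = 40,
                               nclus = 10, tdbl = 1800,
                               bl_range = c(40, 110), bl_mean = 72) {
  for (nm in c("n_glomeruli", "total_synapses", "n_neurons", "s_max",
               "ndist", "nclus", "tdbl", "bl_mean"))
    .assert_scalar_num(get(nm), nm, 0, strict = TRUE)
  if (nclus > ndist) stop("`nclus` must be <= `ndist`", call. = FALSE)
  if (any(bl_range <= 0) || bl_range[1] > bl_range[2] || bl_range[2] > tdbl)
    stop("`bl_range` must be positive, ordered and <= `tdbl`", call. = FALSE)
  structure(list(n_glomeruli = n_glomeruli, total_synapses = total_synapses,
                 n_neurons = n_neurons, s_max = s_max, ndist = ndist,
                 nclus = nclus, tdbl = tdbl, bl_range = bl_range,
                 bl_mean = bl_mean),
            class = "integration_params")
}

#' @export
print.integration_params <- function(x, ...) {
  cat(sprintf(
    "<integration_params> %g glomeruli | %.3g synapses | %g neurons | S_max %g\n",
    x$n_glomeruli, x$total_synapses, x$n_neurons, x$s_max))
  cat(sprintf("  ndist %g, nclus %g | TDBL %g um, BL %g-%g um (mean %g)\n",
              x$ndist, x$nclus, x$tdbl, x$bl_range[1], x$bl_range[2],
              x$bl_mean))
  invisible(x)
}

#' Poisson exceedance probability
#'
#' Probability that a Poisson(`lambda`) count reaches `n` or more. The
#' `"standard_tail"` variant is the complement of the Poisson CDF,
#' `P(X >= n) = 1 - sum_{k=0}^{n-1} lambda^k e^-lambda / k!`. The
#' `"printed_eq"` variant starts the sum at k = 1 (omitting the k = 0
#' mass), exactly as some texts print it; it therefore upper-bounds the
#' standard tail by `e^-lambda` and equals 1 for n = 1 regardless of
#' `lambda`.
#'
#' @param lambda mean count(s), >= 0 (vectorised).
#' @param n threshold count, integer >= 1.
#' @param variant `"standard_tail"` (default) or `"printed_eq"`.
#' @return probability (same length as `lambda`).
#' @examples
#' poisson_exceedance(log(2), 1)  # 0.5
#' @export
poisson_exceedance <- function(lambda, n,
                               variant = c("standard_tail", "printed_eq")) {
  variant <- match.arg(variant)
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("`lambda` must be finite and >= 0", call. = FALSE)
  .assert_scalar_num(n, "n", 1)
  if (n != round(n)) stop("`n` must be an integer", call. = FALSE)
  tail <- stats::ppois(n - 1, lambda, lower.tail = FALSE)
  switch(variant,
         standard_tail = tail,
         printed_eq = pmin(tail + exp(-lambda), 1))
}

#' Response probability of the two-layer integration model
#'
#' * `"distributed"` — probability that the total active-synapse count
#'   reaches `ndist`: `poisson_exceedance(S, ndist)`.
#' * `"clustered"` — probability that at least one branch collects
#'   `nclus` active synapses. Branches carry independent Poisson counts
#'   with per-branch mean `lambda_b = S * BL / TDBL`, giving
#'   `P = 1 - (1 - poisson_exceedance(lambda_b, nclus))^(TDBL/BL)`.
#'   The exponent is the real-valued branch count TDBL/BL by default;
#'   `branch_count` substitutes an integer branch count (then
#'   `lambda_b = S / branch_count`), matching the Monte-Carlo oracle's
#'   discretisation exactly.
#' * `"combined"` — probability of the distributed OR the clustered route
#'   firing; no closed form is claimed, the estimate comes from
#'   [monte_carlo_response()].
#'
#' @param params [integration_params()].
#' @param S number of active input synapses (>= 0).
#' @param BL mean branch length, um, in (0, TDBL].
#' @param mode `"clustered"`, `"distributed"` or `"combined"`.
#' @param variant passed to [poisson_exceedance()].
#' @param branch_count optional integer branch count overriding TDBL/BL.
#' @param n_trials,seed Monte-Carlo settings for `mode = "combined"`.
#' @return a probability.
#' @export
response_probability <- function(params, S, BL,
                                 mode = c("clustered", "distributed",
                                          "combined"),
                                 variant = "standard_tail",
                                 branch_count = NULL,
                                 n_trials = 1e5, seed = NULL) {
  stopifnot(inherits(params, "integration_params"))
  mode <- match.arg(mode)
  .assert_scalar_num(S, "S", 0)
  .assert_scalar_num(BL, "BL", 0, strict = TRUE)
  if (BL > params$tdbl) stop("`BL` must be <= TDBL", call. = FALSE)
  if (mode == "distributed")
    return(poisson_exceedance(S, params$ndist, variant))
  if (mode == "combined")
    return(monte_carlo_response(params, S, BL, mode = "combined",
                                n_trials = n_trials, seed = seed)$estimate)
  nb <- branch_count %||% (params$tdbl / BL)
  lambda_b <- S / nb
  p_b <- poisson_exceedance(lambda_b, params$nclus, variant)
  # log1p form keeps tiny p_b accurate at large exponents
  -expm1(nb * log1p(-p_b))
}

#' Monte-Carlo oracle for the integration model
#'
#' Per trial, draws the total active-synapse count N ~ Poisson(S), places
#' each synapse uniformly on one of `floor(TDBL/BL)` branches
#' (multinomial placement — no independence assumption), and fires
#' according to the mode thresholds: any branch count >= nclus
#' (clustered), N >= ndist (distributed), or either (combined).
#'
#' @param params [integration_params()].
#' @param S,BL as in [response_probability()].
#' @param mode `"clustered"`, `"distributed"` or `"combined"`.
#' @param n_trials number of trials (>= 1000).
#' @param seed RNG seed; identical seeds give identical estimates.
#' @return list with `estimate`, `se` (binomial), `n_trials`,
#'   `branch_count`.
#' @export
monte_carlo_response <- function(params, S, BL,
                                 mode = c("clustered", "distributed",
                                          "combined"),
                                 n_trials = 1e5, seed = NULL) {
  stopifnot(inherits(params, "integration_params"))
  mode <- match.arg(mode)
  .assert_scalar_num(S, "S", 0)
  .assert_scalar_num(BL, "BL", 0, strict = TRUE)
  if (BL > params$tdbl) stop("`BL` must be <= TDBL", call. = FALSE)
  if (n_trials < 1e3) stop("`n_trials` must be >= 1000", call. = FALSE)
  nb <- max(1L, floor(params$tdbl / BL))
  if (S == 0)
    return(list(estimate = 0, se = 0, n_trials = n_trials,
                branch_count = nb))
  fired <- .with_seed(seed, {
    N <- stats::rpois(n_trials, S)
    clus <- logical(n_trials)
    if (mode != "distributed") {
      total <- sum(N)
      trial <- rep.int(seq_len(n_trials), N)
      branch <- sample.int(nb, total, replace = TRUE)
      # per-(trial, branch) counts; max count per trial against nclus
      counts <- tabulate((trial - 1L) * nb + branch, nbins = n_trials * nb)
      maxcnt <- Reduce(pmax, asplit(matrix(counts, nrow = nb), 1L))
      clus <- maxcnt >= params$nclus
    }
    switch(mode,
           clustered = clus,
           distributed = N >= params$ndist,
           combined = clus | (N >= params$ndist))
  })
  p <- mean(fired)
  list(estimate = p, se = sqrt(p * (1 - p) / n_trials),
       n_trials = n_trials, branch_count = nb)
}

#' Circuit-census derivations
#'
#' Reproduces the printed parameter arithmetic: synapses per neuron
#' (rounded), activated glomeruli per odor (floored), and the maximum and
#' minimum branch counts implied by the branch-length range (floored).
#' Under the default census these are 2366, 109, 45 and 16.
#'
#' @param params [integration_params()].
#' @return list with `synapses_per_neuron`, `glomeruli_per_odor`,
#'   `max_branches`, `min_branches`.
#' @export
derive_census <- function(params = integration_params()) {
  stopifnot(inherits(params, "integration_params"))
  if (params$n_neurons == 0 || params$bl_range[1] == 0)
    stop("zero denominator in census derivation", call. = FALSE)
  spn <- round(params$total_synapses / params$n_neurons)
  list(synapses_per_neuron = spn,
       glomeruli_per_odor = floor(params$n_glomeruli * params$s_max / spn),
       max_branches = floor(params$tdbl / params$bl_range[1]),
       min_branches = floor(params$tdbl / params$bl_range[2]))
}

#' Response-probability curves over a branch-length grid
#'
#' Evaluates [response_probability()] on a BL grid for several values of
#' the active-synapse count S. Clustered curves are checked to be
#' non-decreasing along BL and S.
#'
#' @param params [integration_params()].
#' @param bl_grid branch-length grid, um, within [1, TDBL].
#' @param s_values active-synapse counts.
#' @param mode,variant see [response_probability()].
#' @return Object of class `response_curve`: `bl_grid`, `s_values`,
#'   `prob` (matrix, rows = BL, cols = S), `mode`, `variant`.
#' @export
response_curve <- function(params, bl_grid, s_values, mode = "clustered",
                           variant = "standard_tail") {
  stopifnot(inherits(params, "integration_params"))
  if (length(bl_grid) == 0L) stop("`bl_grid` is empty", call. = FALSE)
  if (any(bl_grid < 1) || any(bl_grid > params$tdbl))
    stop("`bl_grid` must lie within [1, TDBL]", call. = FALSE)
  prob <- vapply(s_values, function(S)
    vapply(bl_grid, function(bl)
      response_probability(params, S, bl, mode = mode, variant = variant),
      0), numeric(length(bl_grid)))
  prob <- matrix(prob, nrow = length(bl_grid),
                 dimnames = list(BL = bl_grid, S = s_values))
  if (mode == "clustered") {
    stopifnot(all(apply(prob, 2L, function(p) all(diff(p) >= -1e-12))),
              all(apply(prob, 1L, function(p) all(diff(p) >= -1e-12))))
  }
  structure(list(bl_grid = bl_grid, s_values = s_values, prob = prob,
                 mode = mode, variant = variant, params = params),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> mode %s, variant %s; BL %g-%g um x S {%s}\n",
              x$mode, x$variant, min(x$bl_grid), max(x$bl_grid),
              paste(x$s_values, collapse = ", ")))
  print(round(x$prob[unique(round(seq(1, length(x$bl_grid),
                                      length.out = min(6, length(x$bl_grid))))), ,
                     drop = FALSE], 5))
  invisible(x)
}

#' @export
plot.response_curve <- function(x, ylab = "response probability",
                                xlab = "mean branch length (um)", ...) {
  graphics::matplot(x$bl_grid, x$prob, type = "l", lty = 1,
                    xlab = xlab, ylab = ylab, ...)
  graphics::legend("topleft", legend = paste("S =", x$s_values),
                   col = seq_along(x$s_values), lty = 1, bty = "n")
  invisible(x)
}

#' Export a response curve as a tidy data.frame
#' @param x a `response_curve`.
#' @param ... unused.
#' @return data.frame with `S`, `BL`, `probability`, `mode`, `variant`.
#' @export
as.data.frame.response_curve <- function(x, ...) {
  data.frame(S = rep(x$s_values, each = length(x$bl_grid)),
             BL = rep(x$bl_grid, times = length(x$s_values)),
             probability = as.vector(x$prob),
             mode = x$mode, variant = x$variant)
}
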