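#' Default fibril-formation rate constants for synthetic data
#'
#' Rate constants reproducing the study conditions used throughout the
#' package's validation: at 100 uM monomer the effective proliferation
#' rate is `kappa = 0.4` per hour with the primary pathway three orders of
#' magnitude slower (`lambda/kappa = 0.01`), giving unseeded half-times
#' near 24 h. The `"secondary"` mechanism realizes proliferation through
#' saturated (order-0) surface-catalysed nucleation; `"fragmentation"`
#' realizes the same proliferation rate through fibril breakage instead.
#'
#' @param mechanism `"secondary"` or `"fragmentation"`.
#' @param kappa Proliferation rate at `m_ref` (h^-1, default 0.4).
#' @param lambda Primary pathway rate at `m_ref` (h^-1, default 0.004).
#' @param m_ref Reference monomer concentration (uM, default 100).
#' @param kplus Elongation rate constant (uM^-1 h^-1, default 10).
#' @param nc Primary nucleation reaction order (default 1, an effective
#'   order consistent with heterogeneous primary nucleation).
#' @return A [rate_constants()] object.
#' @export
default_rates <- function(mechanism = c("secondary", "fragmentation"),
                          kappa = 0.4, lambda = 0.004, m_ref = 100,
                          kplus = 10, nc = 1) {
  mechanism <- match.arg(mechanism)
  kn <- lambda^2 / (2 * kplus * m_ref^nc)
  second <- kappa^2 / (2 * kplus * m_ref)
  if (mechanism == "secondary") {
    rate_constants(kn = kn, nc = nc, kplus = kplus, k2 = second, n2 = 0)
  } else {
    rate_constants(kn = kn, nc = nc, kplus = kplus, kminus = second)
  }
}

#' Generate synthetic plate-reader aggregation traces
#'
#' Simulates sigmoidal aggregation curves over a grid of monomer and seed
#' concentrations with the moment ODE model, maps them to raw fluorescence
#' (direction-aware affine map) and adds Gaussian noise scaled to the
#' dynamic range. Ground-truth parameters are attached to each trace and
#' to the returned list as the `"ground_truth"` attribute.
#'
#' @param rates [rate_constants()] shared by all conditions.
#' @param m_total Vector of total monomer concentrations (uM).
#' @param seed_pct Vector of seed masses as percent of total monomer.
#' @param times Acquisition time grid (h).
#' @param noise Additive Gaussian noise SD as a fraction of the dynamic
#'   range (default 0.01).
#' @param amplitude Signal dynamic range (a.u., default 150).
#' @param baseline Baseline signal (a.u., default 100).
#' @param direction `"increasing"` (ThT-like) or `"decreasing"`
#'   (quench-like).
#' @param seed_mean_length Mean seed length in monomer units used to set
#'   the seed number concentration (default 2000).
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return List of [kinetic_trace()] objects (one per condition in the
#'   `m_total` x `seed_pct` grid) with a `"ground_truth"` attribute.
#' @export
gen_kinetic_traces <- function(rates = default_rates(),
                               m_total = 100, seed_pct = c(0, 0.25, 1),
                               times = seq(0, 40, by = 1 / 6),
                               noise = 0.01, amplitude = 150,
                               baseline = 100,
                               direction = c("increasing", "decreasing"),
                               seed_mean_length = 2000, seed = 1) {
  direction <- match.arg(direction)
  if (noise < 0) stop("noise must be >= 0")
  grid <- expand.grid(m_total = m_total, seed_pct = seed_pct)
  sgn <- if (direction == "increasing") 1 else -1
  traces <- with_seed(seed, {
    lapply(seq_len(nrow(grid)), function(i) {
      mt <- grid$m_total[i]
      M0 <- grid$seed_pct[i] / 100 * mt
      P0 <- M0 / seed_mean_length
      traj <- simulate_fibril_mass(rates, mt, M0, P0, times)
      signal <- baseline + sgn * amplitude * traj$M / mt +
        stats::rnorm(length(times), sd = noise * amplitude)
      tr <- kinetic_trace(times, signal, m_total = mt, seed_mass = M0,
                          direction = direction)
      attr(tr, "ground_truth") <- list(
        rates = rates, M0 = M0, P0 = P0,
        kappa = kappa_rate(rates, mt - M0),
        lambda = lambda_rate(rates, mt - M0))
      tr
    })
  })
  attr(traces, "ground_truth") <- list(
    rates = rates, grid = grid, noise = noise,
    seed_mean_length = seed_mean_length, seed = seed)
  traces
}

#' Generate synthetic plateau-phase fibril length samples
#'
#' Draws individual fibril lengths at several plateau timepoints from an
#' exponential distribution whose mean follows the plateau fragmentation
#' law [mean_length_model()]. The per-timepoint fibril counts honour the
#' study's minimum of 650 measured fibrils by default.
#'
#' @param kminus Fragmentation rate constant (h^-1, default 1e-5).
#' @param L_plateau Mean length at plateau onset in monomer units
#'   (default 1000; the defaults' product is `kappa_frag = 0.01` h^-1).
#' @param timepoints Plateau times (h), >= 3.
#' @param n_per Fibrils measured per timepoint (>= 100, default 700).
#' @param seed RNG seed.
#' @return List of [length_sample()] objects with a `"ground_truth"`
#'   attribute containing the generating parameters.
#' @export
gen_length_samples <- function(kminus = 1e-5, L_plateau = 1000,
                               timepoints = seq(0, 100, by = 25),
                               n_per = 700, seed = 1) {
  if (length(timepoints) < 3) stop("need >= 3 plateau timepoints")
  if (n_per < 100) stop("need >= 100 fibrils per timepoint")
  samples <- with_seed(seed, {
    lapply(timepoints, function(t) {
      mu <- mean_length_model(t, kminus, L_plateau)
      length_sample(t, lengths = stats::rexp(n_per, rate = 1 / mu))
    })
  })
  attr(samples, "ground_truth") <- list(
    kminus = kminus, L_plateau = L_plateau,
    kappa_frag = kminus * L_plateau, seed = seed)
  samples
}

#' Generate a synthetic oligomer time series along a bulk trajectory
#'
#' Integrates the oligomer rate equation along a fibril-formation
#' trajectory, then emulates single-molecule counting measurements:
#' per-timepoint replicates with multiplicative log-normal noise, averaged
#' into a series with SEMs (the final timepoint is measured once and
#' carries no SEM, as single-sample points do).
#'
#' @param params [oligomer_params()]; the defaults of
#'   [default_oligomer_params()] are used when `NULL`.
#' @param bulk A `fibril_trajectory` for the matching condition.
#' @param times Measurement times; default: 12 points spanning the
#'   reaction up to shortly after completion.
#' @param n_replicates Replicates per timepoint (default 8).
#' @param noise Multiplicative log-normal noise (fractional SD,
#'   default 0.1).
#' @param seed RNG seed.
#' @return An [oligomer_series()] with a `"ground_truth"` attribute.
#' @export
gen_oligomer_series <- function(params = NULL, bulk, times = NULL,
                                n_replicates = 8, noise = 0.1, seed = 1) {
  if (is.null(params)) params <- default_oligomer_params()
  if (noise < 0) stop("noise must be >= 0")
  if (is.null(times)) {
    frac <- bulk$M / attr(bulk, "m_total")
    t_end <- if (max(frac) >= 0.98) {
      bulk$times[which(frac >= 0.98)[1]]
    } else {
      max(bulk$times)
    }
    times <- seq(0, min(1.3 * t_end, max(bulk$times)), length.out = 13)[-1]
  }
  truth <- integrate_oligomers(params, bulk, S0 = 0, times = times)$S
  n_rep <- rep(n_replicates, length(times))
  n_rep[length(n_rep)] <- 1L
  sdlog <- sqrt(log(1 + noise^2))
  obs <- with_seed(seed, {
    lapply(seq_along(times), function(i) {
      truth[i] * stats::rlnorm(n_rep[i], meanlog = -sdlog^2 / 2,
                               sdlog = sdlog)
    })
  })
  S <- vapply(obs, mean, 0)
  sem <- vapply(obs, function(x) {
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  }, 0)
  out <- oligomer_series(times, S, sem = sem, n_rep = n_rep)
  attr(out, "ground_truth") <- list(params = params, noise = noise,
                                    S_true = truth, seed = seed)
  out
}

#' Default oligomer model parameters for synthetic data
#'
#' Fibril-catalysed oligomer kinetics at the study's reported formation
#' rate: `k_form * m = 4e-5` per second per uM fibril mass at 100 uM
#' monomer, with dissociation fast on the reaction timescale so the
#' oligomer population tracks monomer consumption.
#'
#' @param formation_rate_s Formation rate at `m_ref` (s^-1 per uM fibril
#'   mass, default 4e-5).
#' @param k_diss Dissociation rate constant (uM^-1 h^-1 per fibril mass,
#'   default 0.2).
#' @param n_o Reaction order in monomer (default 1).
#' @param m_ref Reference monomer concentration (uM, default 100).
#' @return An [oligomer_params()] object in secondary mode.
#' @export
default_oligomer_params <- function(formation_rate_s = 4e-5, k_diss = 0.2,
                                    n_o = 1, m_ref = 100) {
  oligomer_params("secondary",
                  k_form = formation_rate_s * 3600 / m_ref^n_o,
                  k_diss = k_diss, n_o = n_o)
}

#' Generate synthetic confocal photon-count timetraces
#'
#' Poisson background with rare bright bursts: burst arrivals are Poisson
#' in time at a rate proportional to the oligomer concentration, and burst
#' brightness is log-normal (heavy-tailed, emulating heterogeneous
#' oligomer sizes). Optionally a per-burst uniform detection-efficiency
#' multiplier emulates the non-uniform confocal intensity profile.
#'
#' @param n_traces Number of traces/positions (default 5).
#' @param duration_s Trace duration in seconds (default 60).
#' @param bin_width_ms Bin width (default 1 ms).
#' @param bg_rate Mean background photons per bin (default 5).
#' @param burst_rate_hz Mean burst arrival rate (default 2 per second).
#' @param brightness_meanlog,brightness_sdlog Log-normal brightness
#'   parameters (photons per burst above background).
#' @param uniform_efficiency If `TRUE`, multiply each burst by a uniform
#'   detection efficiency in `[0, 1]` (default `FALSE`).
#' @param seed RNG seed.
#' @return List of [photon_trace()] objects with a `"ground_truth"`
#'   attribute.
#' @export
gen_photon_traces <- function(n_traces = 5, duration_s = 60,
                              bin_width_ms = 1, bg_rate = 5,
                              burst_rate_hz = 2,
                              brightness_meanlog = log(50),
                              brightness_sdlog = 0.8,
                              uniform_efficiency = FALSE, seed = 1) {
  n_bins <- round(duration_s * 1000 / bin_width_ms)
  traces <- with_seed(seed, {
    lapply(seq_len(n_traces), function(j) {
      counts <- stats::rpois(n_bins, bg_rate)
      nb <- stats::rpois(1, burst_rate_hz * duration_s)
      if (nb > 0) {
        at <- sample.int(n_bins, nb, replace = TRUE)
        bright <- stats::rlnorm(nb, brightness_meanlog, brightness_sdlog)
        if (uniform_efficiency) bright <- bright * stats::runif(nb)
        for (k in seq_len(nb)) {
          counts[at[k]] <- counts[at[k]] + round(bright[k])
        }
      }
      photon_trace(counts, bin_width_ms = bin_width_ms, position = j)
    })
  })
  attr(traces, "ground_truth") <- list(
    bg_rate = bg_rate, burst_rate_hz = burst_rate_hz,
    brightness_meanlog = brightness_meanlog,
    brightness_sdlog = brightness_sdlog, seed = seed)
  traces
}
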