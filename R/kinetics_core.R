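#' Simulate fibril mass and number kinetics (moment ODEs)
#'
#' Integrates the coarse-grained moment equations of fibril formation:
#' \deqn{dP/dt = kn m^{nc} + k2 m^{n2} M + kminus M}
#' \deqn{dM/dt = 2 kplus m P, \quad m = m_{total} - M}
#' where `M` is the fibril mass concentration, `P` the fibril number
#' concentration (both in monomer-equivalent uM) and `m` the free monomer.
#' The factor 2 reflects growth at both fibril ends; monomer consumption by
#' nucleation itself is neglected (nuclei are mass-negligible).
#'
#' @param rates A [rate_constants()] object.
#' @param m_total Total monomer concentration (uM), > 0.
#' @param M0 Initial seed mass concentration (uM), in `[0, m_total)`.
#' @param P0 Initial seed number concentration (uM).
#' @param times Strictly increasing time grid starting at 0 (h).
#' @return A `fibril_trajectory`: data frame with columns `times`, `m`,
#'   `M`, `P` plus attributes `m_total`, `M0`, `P0` and `rates`.
#' @examples
#' rc <- rate_constants(kn = 8e-9, nc = 1, kplus = 10, k2 = 8e-5)
#' tr <- simulate_fibril_mass(rc, m_total = 100, times = seq(0, 40, 0.2))
#' half_time(as_normalized_trace(tr))
#' @export
simulate_fibril_mass <- function(rates, m_total, M0 = 0, P0 = 0, times) {
  stopifnot(inherits(rates, "rate_constants"))
  if (!is.numeric(m_total) || length(m_total) != 1 || m_total <= 0) {
    stop("m_total must be a single positive concentration")
  }
  if (M0 < 0 || M0 >= m_total) stop("M0 must lie in [0, m_total)")
  if (P0 < 0) stop("P0 must be non-negative")
  check_time_grid(times)

  deriv <- function(t, y, p) {
    m <- max(m_total - y[[1L]], 0)
    dM <- 2 * rates$kplus * m * y[[2L]]
    dP <- rates$kn * m^rates$nc +
      (rates$k2 * m^rates$n2 + rates$kminus) * y[[1L]]
    list(c(dM, dP))
  }
  out <- tryCatch(
    deSolve::ode(y = c(M = M0, P = P0), times = times, func = deriv,
                 parms = NULL, method = "lsoda",
                 atol = 1e-9 * m_total, rtol = 1e-8),
    error = function(e) {
      stop(sprintf(
        "stiff integration failed (kn=%g, kplus=%g, k2=%g, kminus=%g, m_total=%g): %s",
        rates$kn, rates$kplus, rates$k2, rates$kminus, m_total,
        conditionMessage(e)))
    }
  )
  if (nrow(out) < length(times)) {
    stop(sprintf(
      "integration stopped early at t=%g (kplus=%g, k2=%g, m_total=%g)",
      max(out[, 1]), rates$kplus, rates$k2, m_total))
  }
  M <- pmin(pmax(out[, "M"], 0), m_total)
  traj <- data.frame(times = times, m = m_total - M, M = M,
                     P = pmax(out[, "P"], 0))
  structure(traj, m_total = m_total, M0 = M0, P0 = P0, rates = rates,
            class = c("fibril_trajectory", "data.frame"))
}

#' Analytical fixed-point approximation of the fibril mass curve
#'
#' Fast approximation to [simulate_fibril_mass()] built on the
#' self-consistent (fixed-point) solution of the moment equations. The
#' monomer depletion is first neglected to obtain the linearized solution
#' \deqn{M_{lin}(t)/m_0 = \frac{2 k_+ P_0}{\kappa}\sinh(\kappa t)
#'   + (\lambda^2/\kappa^2 + M_0/m_0)\cosh(\kappa t)
#'   - \lambda^2/\kappa^2}
#' with effective rates `kappa` ([kappa_rate()]) and `lambda`
#' ([lambda_rate()]); substituting it back into the monomer balance gives
#' `m(t) = m0 exp(-(M_lin - M0)/m0)`, and one further refinement step
#' (re-integrating the nucleation fluxes along that estimate on a dense
#' internal grid) corrects the mid-transition overshoot. Fragmentation is
#' covered by the same expression because `kminus` enters `kappa` exactly
#' as order-0 secondary nucleation does.
#'
#' Valid when fibril mass saturates by monomer depletion; both effective
#' rates zero with no seeds is flagged as outside the approximation.
#'
#' @inheritParams simulate_fibril_mass
#' @param refine Internal grid refinement factor for the quadrature step.
#' @return A `normalized_trace` (fraction aggregated `M(t)/m_total`).
#' @export
closed_form_fibril_mass <- function(rates, m_total, M0 = 0, P0 = 0, times,
                                    refine = 10) {
  stopifnot(inherits(rates, "rate_constants"))
  if (m_total <= 0) stop("m_total must be positive")
  if (M0 < 0 || M0 >= m_total) stop("M0 must lie in [0, m_total)")
  check_time_grid(times)

  m0 <- m_total - M0
  lam <- lambda_rate(rates, m0)
  kap <- kappa_rate(rates, m0)
  if (lam == 0 && kap == 0 && P0 == 0) {
    stop("no dynamics: lambda and kappa are both zero and no seeds present")
  }

  tt <- seq(min(times), max(times),
            length.out = max(length(times) * refine, 200L))
  u <- linearized_growth(tt, lam, kap, rates$kplus, P0, M0, m0)
  m1 <- m0 * exp(-u)
  M1 <- m_total - m1
  # Picard refinement: nucleation fluxes re-evaluated along the first
  # iterate, then the monomer balance is re-integrated.
  flux <- rates$kn * m1^rates$nc +
    (rates$k2 * m1^rates$n2 + rates$kminus) * M1
  P2 <- P0 + cumtrapz(tt, flux)
  w <- 2 * rates$kplus * cumtrapz(tt, P2)
  frac <- 1 - (m0 / m_total) * exp(-w)
  normalized_trace(times,
                   stats::approx(tt, frac, xout = times, ties = "ordered")$y,
                   m_total = m_total,
                   seed_fraction = 100 * M0 / m_total)
}

# linearized (constant-monomer) fibril mass growth, numerically stable in
# the kappa -> 0 limit
linearized_growth <- function(tt, lam, kap, kplus, P0, M0, m0) {
  if (kap > 0) {
    x <- kap * tt
    sinhc <- ifelse(x < 1e-6, 1 + x^2 / 6, sinh(x) / ifelse(x == 0, 1, x))
    2 * kplus * P0 * tt * sinhc +
      (lam^2 / kap^2 + M0 / m0) * 2 * sinh(x / 2)^2
  } else {
    2 * kplus * P0 * tt + lam^2 * tt^2 / 2
  }
}

#' Construct a normalized aggregation trace
#'
#' A time series of the fraction of monomer converted to fibril mass,
#' `M(t)/m_total` in `[0, 1]` up to noise.
#'
#' @param times Time grid (h).
#' @param fraction_aggregated Fraction aggregated at each time.
#' @param m_total Total monomer concentration (uM), optional.
#' @param seed_fraction Seed mass as percent of total monomer.
#' @return An object of class `normalized_trace`.
#' @export
normalized_trace <- function(times, fraction_aggregated, m_total = NA_real_,
                             seed_fraction = 0) {
  check_time_grid(times, require_zero = FALSE)
  if (length(fraction_aggregated) != length(times)) {
    stop("times and fraction_aggregated must have equal length")
  }
  if (any(!is.finite(fraction_aggregated))) {
    stop("fraction_aggregated must be finite")
  }
  structure(
    list(times = times, fraction_aggregated = fraction_aggregated,
         m_total = m_total, seed_fraction = seed_fraction),
    class = "normalized_trace"
  )
}

#' Convert a fibril trajectory to a normalized trace
#'
#' @param traj A `fibril_trajectory` from [simulate_fibril_mass()].
#' @return A `normalized_trace` with `fraction_aggregated = M/m_total`.
#' @export
as_normalized_trace <- function(traj) {
  stopifnot(inherits(traj, "fibril_trajectory"))
  m_total <- attr(traj, "m_total")
  normalized_trace(traj$times, traj$M / m_total, m_total = m_total,
                   seed_fraction = 100 * attr(traj, "M0") / m_total)
}

#' Aggregation half-time
#'
#' First time at which the fraction aggregated crosses 0.5, linearly
#' interpolated between the bracketing samples (ties broken by the first
#' crossing).
#'
#' @param trace A `normalized_trace`.
#' @return Half-time in h.
#' @export
half_time <- function(trace) {
  crossing_time(trace, 0.5)
}

#' Aggregation lag time
#'
#' Time taken to reach a threshold fraction aggregated (default 25%).
#' A trace that starts at or above the threshold has lag time 0.
#'
#' @param trace A `normalized_trace`.
#' @param threshold Fraction defining the end of the lag phase.
#' @return Lag time in h.
#' @export
lag_time <- function(trace, threshold = 0.25) {
  crossing_time(trace, threshold)
}

crossing_time <- function(trace, level) {
  stopifnot(inherits(trace, "normalized_trace"))
  f <- trace$fraction_aggregated
  t <- trace$times
  if (f[1] >= level) return(0)
  above <- which(f >= level)
  if (length(above) == 0) {
    stop(sprintf("trace never reaches fraction %.3g (max %.3g)",
                 level, max(f)))
  }
  i <- above[1]
  t[i - 1] + (level - f[i - 1]) / (f[i] - f[i - 1]) * (t[i] - t[i - 1])
}

#' Half-time scaling exponent
#'
#' Least-squares slope of `log10(t_half)` against `log10(m_total)`. Under
#' fibril proliferation dominated by either saturated (order-0) secondary
#' nucleation or fragmentation the predicted exponent is -1/2; under
#' primary nucleation alone it approaches `-nc/2`.
#'
#' @param half_times Positive aggregation half-times (h).
#' @param m_totals Matching total monomer concentrations (uM), at least 3
#'   distinct values.
#' @return The scaling exponent (dimensionless slope).
#' @export
scaling_exponent <- function(half_times, m_totals) {
  if (length(half_times) != length(m_totals)) {
    stop("half_times and m_totals must have equal length")
  }
  if (length(unique(m_totals)) < 3) {
    stop("need at least 3 distinct monomer concentrations")
  }
  if (any(half_times <= 0) || any(m_totals <= 0)) {
    stop("half-times and concentrations must be positive")
  }
  unname(stats::coef(stats::lm(log10(half_times) ~ log10(m_totals)))[2])
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf(
    "Normalized aggregation trace: %d points, t = [%g, %g] h\n",
    length(x$times), min(x$times), max(x$times)))
  if (is.finite(x$m_total)) {
    cat(sprintf("  m_total = %g uM, seeds = %g%% mass\n",
                x$m_total, x$seed_fraction))
  }
  invisible(x)
}

#' @export
print.fibril_trajectory <- function(x, ...) {
  cat(sprintf(
    "Fibril trajectory: %d points, m_total = %g uM, M0 = %g uM\n",
    nrow(x), attr(x, "m_total"), attr(x, "M0")))
  print.data.frame(utils::head(x, 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

# ---- shared small utilities ----

check_time_grid <- function(times, require_zero = TRUE) {
  if (length(times) < 2 || any(!is.finite(times))) {
    stop("times must be a finite grid with >= 2 points")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (require_zero && abs(times[1]) > .Machine$double.eps * 100) {
    stop("time grid must start at 0")
  }
  invisible(times)
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-length(y)] + y[-1]) / 2))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
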