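#' Construct a raw plate-reader kinetic trace
#'
#' One well's aggregation time course: signal in arbitrary fluorescence
#' units, assumed proportional to fibril mass. Amyloid-binding dyes (ThT)
#' give increasing signal; aggregation-induced quenching of a covalent
#' label (e.g. AlexaFluor-488) gives decreasing signal.
#'
#' @param times Strictly increasing times (h), at least 20 samples.
#' @param signal Fluorescence signal (a.u.), finite.
#' @param m_total Total monomer concentration in the well (uM).
#' @param seed_mass Preformed seed mass (uM monomer equivalents).
#' @param direction `"increasing"` (dye binding) or `"decreasing"` (quench).
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, signal, m_total, seed_mass = 0,
                          direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (length(times) < 20) stop("kinetic traces need at least 20 samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(signal) != length(times) || any(!is.finite(signal))) {
    stop("signal must be finite and match times in length")
  }
  if (m_total <= 0) stop("m_total must be positive")
  if (seed_mass < 0 || seed_mass >= m_total) {
    stop("seed_mass must lie in [0, m_total)")
  }
  structure(
    list(times = times, signal = signal, m_total = m_total,
         seed_mass = seed_mass, direction = direction),
    class = "kinetic_trace"
  )
}

#' Normalize a raw kinetic trace to fraction aggregated
#'
#' Maps the raw signal affinely to `[0, 1]` using the mean of the first 5%
#' of points as baseline and the mean of the last 5% as plateau. The same
#' affine map orients decreasing (quench) traces correctly, so aggregation
#' always increases. The map is exactly idempotent: normalizing an already
#' normalized trace returns it unchanged.
#'
#' @param trace A [kinetic_trace()] or an already-normalized
#'   `normalized_trace`.
#' @param edge_fraction Fraction of points used for the baseline and
#'   plateau estimates (default 0.05).
#' @param min_snr Minimum ratio of signal range to estimated noise SD;
#'   below it the trace is rejected as having no transition.
#' @return A `normalized_trace`.
#' @export
normalize_trace <- function(trace, edge_fraction = 0.05, min_snr = 5) {
  if (inherits(trace, "normalized_trace")) {
    times <- trace$times
    signal <- trace$fraction_aggregated
    m_total <- trace$m_total
    seed_fraction <- trace$seed_fraction
  } else if (inherits(trace, "kinetic_trace")) {
    times <- trace$times
    signal <- trace$signal
    m_total <- trace$m_total
    seed_fraction <- 100 * trace$seed_mass / trace$m_total
  } else {
    stop("trace must be a kinetic_trace or normalized_trace")
  }
  n <- length(signal)
  k <- max(2L, ceiling(edge_fraction * n))
  baseline <- mean(signal[seq_len(k)])
  plateau <- mean(signal[seq.int(n - k + 1L, n)])
  noise_sd <- stats::sd(diff(signal)) / sqrt(2)
  if (!is.finite(noise_sd) || noise_sd == 0) {
    noise_sd <- .Machine$double.eps
  }
  if (abs(plateau - baseline) <= min_snr * noise_sd) {
    stop("no transition: signal range is not distinguishable from noise")
  }
  normalized_trace(times, (signal - baseline) / (plateau - baseline),
                   m_total = m_total, seed_fraction = seed_fraction)
}

#' Global multi-curve fit of aggregation kinetics
#'
#' Fits a shared set of rate parameters to several normalized aggregation
#' curves measured at different monomer and/or seed concentrations, by
#' minimizing the summed squared residuals against the analytical
#' fibril-mass solution ([closed_form_fibril_mass()]) or the full ODE
#' model. Only composite parameters are identifiable from bulk data, so
#' the fit works in log10 space on `kplus*kn` together with `kplus*k2`
#' (secondary model) or `kplus*kminus` (fragmentation model); when seeded
#' traces are present `kplus` itself is additionally constrained through
#' the seed number concentration `P0 = seed_mass / seed_mean_length` and is
#' fitted (or may be fixed).
#'
#' @param traces List of `normalized_trace` objects with known `m_total`
#'   (and `seed_fraction`), at least 2 traces spanning at least 2 distinct
#'   conditions.
#' @param model `"primary_plus_secondary"`, `"primary_only"` or
#'   `"primary_plus_fragmentation"`.
#' @param fixed Named list of parameters to hold fixed, on natural scale:
#'   any of `kplus_kn`, `kplus_k2`, `kplus_kminus`, `kplus`.
#' @param nc Primary nucleation reaction order (fixed, default 1).
#' @param n2 Secondary nucleation reaction order (fixed, default 0,
#'   i.e. saturated).
#' @param seed_mean_length Mean seed fibril length in monomer units used to
#'   convert seed mass to seed number (default 2000, of the order of an
#'   unsonicated micron-long alpha-synuclein fibril).
#' @param forward Forward model: `"closed_form"` (default, fast) or
#'   `"ode"`.
#' @param n_starts Number of multi-start optimizations (default 5).
#' @param seed RNG seed for the multi-start perturbations.
#' @param m_ref Reference monomer concentration (uM) at which the derived
#'   proliferation rate `kappa` is reported (default 100).
#' @return A `bulk_fit` object: fitted composites, derived `kappa` and
#'   `lambda` at `m_ref`, per-trace residual sums of squares, total
#'   objective, convergence flag and the RNG seed used.
#' @export
global_fit <- function(traces,
                       model = c("primary_plus_secondary", "primary_only",
                                 "primary_plus_fragmentation"),
                       fixed = list(), nc = 1, n2 = 0,
                       seed_mean_length = 2000,
                       forward = c("closed_form", "ode"),
                       n_starts = 5, seed = 1, m_ref = 100) {
  model <- match.arg(model)
  forward <- match.arg(forward)
  meta <- check_fit_traces(traces)

  second_name <- switch(model,
                        primary_plus_secondary = "kplus_k2",
                        primary_plus_fragmentation = "kplus_kminus",
                        primary_only = NULL)
  any_seeded <- any(meta$M0 > 0)
  par_names <- c("kplus_kn", second_name,
                 if (any_seeded) "kplus")
  free <- setdiff(par_names, names(fixed))
  if (model == "primary_only" && !any_seeded &&
      length(meta$m_total) < 2 && length(free) > 0) {
    stop("non-identifiable configuration: single unseeded curve")
  }

  make_resid <- residual_builder(meta, model, fixed, nc, n2,
                                 seed_mean_length, forward)

  if (length(free) == 0) {
    res <- make_resid(numeric(0), character(0))
    par_full <- resolve_pars(numeric(0), character(0), fixed, model)
    return(build_bulk_fit(model, par_full, res, meta, nc, n2, m_ref,
                          converged = TRUE, n_starts = 0, seed = seed,
                          seed_mean_length = seed_mean_length))
  }

  bases <- lapply(fit_start_heuristic(meta, nc, n2), `[`, free)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(j) {
      b <- bases[[(j - 1) %% 2 + 1]]
      if (j <= 2) b else b + stats::runif(length(free), -1, 1)
    })
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        fn = function(p) make_resid(p, free),
        lower = rep(-30, length(free)), upper = rep(10, length(free)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$obj ||
        (abs(obj - best$obj) < 1e-12 * (1 + best$obj) &&
         sum(fit$par^2) < sum(best$fit$par^2))) {
      best <- list(fit = fit, obj = obj)
    }
  }
  if (is.null(best)) {
    stop("global fit failed to converge from any start; check the traces")
  }
  conv <- best$fit$info %in% 1:4
  if (!conv) {
    warning(sprintf("optimizer reported non-convergence (info = %d)",
                    best$fit$info))
  }
  p <- stats::setNames(best$fit$par, free)
  res <- make_resid(best$fit$par, free)
  par_full <- resolve_pars(p, free, fixed, model)
  build_bulk_fit(model, par_full, res, meta, nc, n2, m_ref,
                 converged = conv, n_starts = n_starts, seed = seed,
                 seed_mean_length = seed_mean_length)
}

#' Compare models with and without secondary processes
#'
#' Fits the same traces with the primary-nucleation-only model and with
#' the model including secondary nucleation, and reports the ratio of the
#' two objectives. Seeded aggregation that accelerates with seed
#' concentration, or sigmoidal unseeded curves that the primary-only model
#' cannot reproduce, drive the ratio up.
#'
#' @inheritParams global_fit
#' @param factor Objective ratio above which secondary processes are
#'   declared required (default 5).
#' @param ... Passed on to [global_fit()].
#' @return A `model_comparison`: both fits, their objectives, the ratio,
#'   per-trace misfit, and a verdict of `"secondary required"`,
#'   `"indeterminate"` or `"primary sufficient"`.
#' @export
compare_primary_vs_secondary <- function(traces, factor = 5, ...) {
  fit_sec <- global_fit(traces, model = "primary_plus_secondary", ...)
  fit_pri <- global_fit(traces, model = "primary_only", ...)
  ratio <- fit_pri$objective / fit_sec$objective
  verdict <- if (ratio >= factor) {
    "secondary required"
  } else if (ratio > 1) {
    "indeterminate"
  } else {
    "primary sufficient"
  }
  structure(
    list(fit_secondary = fit_sec, fit_primary = fit_pri,
         objective_ratio = ratio, factor = factor, verdict = verdict,
         per_trace_rss = rbind(primary = fit_pri$per_trace_rss,
                               secondary = fit_sec$per_trace_rss)),
    class = "model_comparison"
  )
}

#' Fit with the fragmentation proliferation rate fixed
#'
#' Fits the primary + elongation + fragmentation model with the
#' fragmentation-driven proliferation rate pinned to an independently
#' measured value (e.g. the plateau fibril-length bound from
#' [fit_length_series()]), leaving only the primary pathway free. Comparing
#' the resulting objective with an unconstrained fit shows whether
#' fragmentation alone can account for the kinetics.
#'
#' @inheritParams global_fit
#' @param kappa_frag Fragmentation-only proliferation rate (h^-1) at the
#'   measurement concentration `m_ref`.
#' @param ... Passed on to [global_fit()].
#' @return A `bulk_fit`.
#' @export
fit_with_fragmentation_fixed <- function(traces, kappa_frag, m_ref = 100,
                                         ...) {
  if (kappa_frag <= 0) stop("kappa_frag must be positive")
  # kappa^2 = 2 (kplus kminus) m, so the fixed composite follows directly
  global_fit(traces, model = "primary_plus_fragmentation",
             fixed = list(kplus_kminus = kappa_frag^2 / (2 * m_ref)),
             m_ref = m_ref, ...)
}

# ---- internal fitting machinery ----

check_fit_traces <- function(traces) {
  if (!is.list(traces) || length(traces) < 2 ||
      !all(vapply(traces, inherits, TRUE, "normalized_trace"))) {
    stop("traces must be a list of >= 2 normalized_trace objects")
  }
  m_total <- vapply(traces, function(x) x$m_total, 0)
  seed_fraction <- vapply(traces, function(x) x$seed_fraction, 0)
  if (any(!is.finite(m_total))) {
    stop("every trace needs a known m_total for global fitting")
  }
  cond <- paste(signif(m_total, 8), signif(seed_fraction, 8))
  if (length(unique(cond)) < 2) {
    stop("traces must span at least 2 distinct m_total or seed conditions")
  }
  list(traces = traces, m_total = m_total,
       M0 = seed_fraction / 100 * m_total)
}

resolve_pars <- function(p_log10, free, fixed, model) {
  second_name <- if (model == "primary_plus_fragmentation") {
    "kplus_kminus"
  } else {
    "kplus_k2"
  }
  get1 <- function(nm, default = 0) {
    if (nm %in% free) 10^p_log10[[nm]]
    else if (nm %in% names(fixed)) fixed[[nm]]
    else default
  }
  list(kplus_kn = get1("kplus_kn"),
       second = if (model == "primary_only") 0 else get1(second_name),
       second_name = second_name,
       kplus = get1("kplus", default = 1))
}

residual_builder <- function(meta, model, fixed, nc, n2, seed_mean_length,
                             forward) {
  function(p, free) {
    par <- resolve_pars(stats::setNames(p, free), free, fixed, model)
    kplus <- max(par$kplus, 1e-30)
    rates <- rate_constants(
      kn = par$kplus_kn / kplus, nc = nc, kplus = kplus,
      k2 = if (par$second_name == "kplus_k2") par$second / kplus else 0,
      n2 = n2,
      kminus = if (par$second_name == "kplus_kminus") {
        par$second / kplus
      } else {
        0
      })
    unlist(lapply(seq_along(meta$traces), function(i) {
      tr <- meta$traces[[i]]
      m_tot <- meta$m_total[i]
      M0 <- meta$M0[i]
      P0 <- M0 / seed_mean_length
      f <- tryCatch({
        if (forward == "closed_form") {
          closed_form_fibril_mass(rates, m_tot, M0, P0,
                                  tr$times)$fraction_aggregated
        } else {
          traj <- simulate_fibril_mass(rates, m_tot, M0, P0, tr$times)
          traj$M / m_tot
        }
      }, error = function(e) rep(NA_real_, length(tr$times)))
      if (any(!is.finite(f))) return(rep(1e3, length(tr$times)))
      # data are normalized to the observed transition, which excludes the
      # pre-existing seed mass: map model fraction onto the same scale
      f0 <- M0 / m_tot
      tr$fraction_aggregated - (f - f0) / (1 - f0)
    }))
  }
}

fit_start_heuristic <- function(meta, nc, n2) {
  # two start bases: a secondary-dominated guess (steepest growth rate of
  # an order-0 secondary sigmoid is ~ kappa/3, with lambda far below) and
  # a primary-dominated guess (lambda set by the observed half-time)
  slopes <- vapply(meta$traces, function(tr) {
    max(diff(tr$fraction_aggregated) / diff(tr$times))
  }, 0)
  t_half <- vapply(meta$traces, function(tr) {
    i <- which(tr$fraction_aggregated >= 0.5)
    if (length(i) == 0) max(tr$times) else tr$times[i[1]]
  }, 0)
  m_max <- max(meta$m_total)
  kappa0 <- max(3 * stats::median(slopes), 1e-6)
  lambda_pri <- sqrt(2 * log(2)) / max(stats::median(t_half), 1e-6)
  mk <- function(lambda0) {
    c(kplus_kn = log10(lambda0^2 / (2 * m_max^nc)),
      kplus_k2 = log10(kappa0^2 / (2 * m_max^(n2 + 1))),
      kplus_kminus = log10(kappa0^2 / (2 * m_max)),
      kplus = 1)
  }
  list(mk(kappa0 / 100), mk(lambda_pri))
}

build_bulk_fit <- function(model, par_full, res, meta, nc, n2, m_ref,
                           converged, n_starts, seed, seed_mean_length) {
  lens <- vapply(meta$traces, function(x) length(x$times), 0L)
  idx <- rep(seq_along(lens), lens)
  per_trace <- as.numeric(tapply(res^2, idx, sum))
  exp_second <- if (model == "primary_plus_fragmentation") 1 else n2 + 1
  structure(
    list(model = model,
         kplus_kn = par_full$kplus_kn,
         kplus_k2 = if (par_full$second_name == "kplus_k2") {
           par_full$second
         } else {
           0
         },
         kplus_kminus = if (par_full$second_name == "kplus_kminus") {
           par_full$second
         } else {
           0
         },
         kplus = par_full$kplus,
         nc = nc, n2 = n2, m_ref = m_ref,
         seed_mean_length = seed_mean_length,
         kappa = sqrt(2 * par_full$second * m_ref^exp_second),
         lambda = sqrt(2 * par_full$kplus_kn * m_ref^nc),
         per_trace_rss = per_trace,
         objective = sum(res^2),
         converged = converged,
         n_starts = n_starts,
         seed = seed),
    class = "bulk_fit"
  )
}

#' @export
print.bulk_fit <- function(x, ...) {
  cat(sprintf("Global kinetic fit: %s model\n", x$model))
  cat(sprintf("  kappa  = %.4g h^-1 at %g uM\n", x$kappa, x$m_ref))
  cat(sprintf("  lambda = %.4g h^-1 at %g uM\n", x$lambda, x$m_ref))
  cat(sprintf("  objective = %.4g over %d traces (converged: %s)\n",
              x$objective, length(x$per_trace_rss), x$converged))
  invisible(x)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison: primary-only vs primary + secondary\n")
  cat(sprintf("  objective ratio = %.3g (threshold %.3g)\n",
              x$objective_ratio, x$factor))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}
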