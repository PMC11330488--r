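#' Microscopic rate constants of the fibril-formation network
#'
#' Bundles the rate constants and reaction orders of the coarse-grained
#' moment model of amyloid fibril formation: primary nucleation
#' (`kn`, order `nc`), elongation (`kplus`), surface-catalysed secondary
#' nucleation (`k2`, order `n2`) and fragmentation (`kminus`).
#' Concentrations are in uM and times in hours throughout; conversions to
#' per-second rates happen only at reporting boundaries.
#'
#' Saturated secondary nucleation, where monomer attachment to the fibril
#' surface is fast and nucleus conversion/release is rate limiting, is
#' encoded as reaction order `n2 = 0`, so the secondary term is independent
#' of the free monomer concentration.
#'
#' @param kn Primary nucleation rate constant (uM^(1-nc) h^-1). Default 0.
#' @param nc Primary nucleation reaction order (>= 1). Default 1.
#' @param kplus Elongation rate constant (uM^-1 h^-1). Default 0.
#' @param k2 Secondary nucleation rate constant (uM^-n2 h^-1 per
#'   monomer-equivalent fibril mass). Default 0.
#' @param n2 Secondary nucleation reaction order (>= 0). Default 0
#'   (saturated secondary nucleation).
#' @param kminus Fragmentation rate constant (h^-1 per monomer-equivalent
#'   of fibril). Default 0.
#' @return An object of class `rate_constants`.
#' @seealso [kappa_rate()], [lambda_rate()], [simulate_fibril_mass()]
#' @examples
#' rc <- rate_constants(kn = 8e-9, nc = 1, kplus = 10, k2 = 8e-5)
#' kappa_rate(rc, m_total = 100)   # effective proliferation rate, h^-1
#' @export
rate_constants <- function(kn = 0, nc = 1, kplus = 0, k2 = 0, n2 = 0,
                           kminus = 0) {
  vals <- c(kn = kn, nc = nc, kplus = kplus, k2 = k2, n2 = n2,
            kminus = kminus)
  if (any(!is.finite(vals))) {
    stop("all rate constants and reaction orders must be finite")
  }
  if (any(c(kn, kplus, k2, kminus, n2) < 0)) {
    stop("rate constants and n2 must be non-negative")
  }
  if (nc < 1) stop("primary nucleation reaction order nc must be >= 1")
  structure(
    list(kn = kn, nc = nc, kplus = kplus, k2 = k2, n2 = n2,
         kminus = kminus),
    class = "rate_constants"
  )
}

#' Effective proliferation rate kappa
#'
#' `kappa = sqrt(2 * kplus * (k2 * m0^n2 + kminus) * m0)` is the effective
#' rate at which fibril mass multiplies through secondary processes
#' (surface-catalysed nucleation and/or fragmentation) at initial free
#' monomer concentration `m0`. Fragmentation enters on the same footing as
#' saturated (order-0) secondary nucleation because both produce new fibril
#' ends at a rate proportional to fibril mass.
#'
#' @param rates A [rate_constants()] object.
#' @param m_total Initial free monomer concentration (uM).
#' @return Proliferation rate in h^-1 (zero iff the secondary-process
#'   constants are zero).
#' @export
kappa_rate <- function(rates, m_total) {
  stopifnot(inherits(rates, "rate_constants"), m_total >= 0)
  sqrt(2 * rates$kplus * (rates$k2 * m_total^rates$n2 + rates$kminus) *
         m_total)
}

#' Effective primary pathway rate lambda
#'
#' `lambda = sqrt(2 * kplus * kn * m0^nc)` combines primary nucleation and
#' elongation into the effective rate at which fibril mass is first
#' generated from monomer alone.
#'
#' @inheritParams kappa_rate
#' @return Rate in h^-1.
#' @export
lambda_rate <- function(rates, m_total) {
  stopifnot(inherits(rates, "rate_constants"), m_total >= 0)
  sqrt(2 * rates$kplus * rates$kn * m_total^rates$nc)
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Fibril-formation rate constants (uM, h units)\n")
  cat(sprintf("  primary:       kn = %.4g, nc = %g\n", x$kn, x$nc))
  cat(sprintf("  elongation:    kplus = %.4g\n", x$kplus))
  cat(sprintf("  secondary:     k2 = %.4g, n2 = %g\n", x$k2, x$n2))
  cat(sprintf("  fragmentation: kminus = %.4g\n", x$kminus))
  invisible(x)
}
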