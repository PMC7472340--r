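#' Mono-exponential luminescent emission process
#'
#' One first-order (mono-exponential) luminescent process of a possibly
#' multiexponential sensing phase. The process is characterised by its
#' low-frequency modulation-factor at null quencher concentration (`M0`),
#' its unquenched lifetime (`tau0`, microseconds) and its Stern-Volmer
#' quenching constant (`k`, kPa^-1). The quenched lifetime follows
#' \eqn{\tau_q(C) = \tau_0 / (1 + k C)}.
#'
#' @param M0 dimensionless modulation-factor at null concentration and low
#'   frequency; must be > 0.
#' @param tau0 unquenched lifetime in microseconds; must be > 0.
#' @param k Stern-Volmer constant in kPa^-1; must be >= 0.
#' @return An object of class `emission_process`.
#' @examples
#' p <- emission_process(M0 = 0.8, tau0 = 65, k = 0.11)
#' tau_quenched(p, C = 10)
#' @export
emission_process <- function(M0, tau0, k) {
  stopifnot(is.numeric(M0), length(M0) == 1L, is.finite(M0),
            is.numeric(tau0), length(tau0) == 1L, is.finite(tau0),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (M0 <= 0) stop("M0 must be > 0")
  if (tau0 <= 0) stop("tau0 must be > 0 (microseconds)")
  if (k < 0) stop("k must be >= 0 (kPa^-1)")
  structure(list(M0 = M0, tau0 = tau0, k = k), class = "emission_process")
}

#' @export
print.emission_process <- function(x, ...) {
  cat(sprintf("<emission process>  M0 = %.4g, tau0 = %.4g us, k = %.4g kPa^-1\n",
              x$M0, x$tau0, x$k))
  invisible(x)
}

as_process_list <- function(procs) {
  if (inherits(procs, "emission_process")) procs <- list(procs)
  if (!is.list(procs) || length(procs) == 0L)
    stop("'procs' must be one emission_process or a non-empty list of them")
  if (!all(vapply(procs, inherits, logical(1), "emission_process")))
    stop("all elements of 'procs' must be emission_process objects")
  procs
}

check_conc <- function(C) {
  if (!is.numeric(C) || any(!is.finite(C)) || any(C < 0))
    stop("concentration C must be finite and >= 0 kPa")
  C
}

# angular frequency (rad/s) times a lifetime in microseconds, dimensionless
omega_tau <- function(freq_hz, tau_us) 2 * pi * freq_hz * tau_us * 1e-6

#' Quenched lifetime of a mono-exponential process
#'
#' Stern-Volmer quenching of a single process: \eqn{\tau_q = \tau_0/(1+kC)}.
#'
#' @param proc an [emission_process()].
#' @param C quencher concentration(s), kPa; must be >= 0.
#' @return Lifetime(s) in microseconds.
#' @export
tau_quenched <- function(proc, C) {
  stopifnot(inherits(proc, "emission_process"))
  check_conc(C)
  proc$tau0 / (1 + proc$k * C)
}

#' Frequency-domain transfer function of a multiexponential sensor
#'
#' Complex frequency response at modulation frequency `freq_hz` and
#' concentration `C` of a sum of first-order luminescent processes:
#' \deqn{H(C, j\omega) = \sum_n M_{0,n} \frac{\tau_{q,n}}{\tau_{0,n}}
#'   \frac{1}{1 + j\omega\tau_{q,n}}, \qquad
#'   \tau_{q,n} = \frac{\tau_{0,n}}{1 + k_n C}.}
#' At \eqn{\omega = 0} this reduces to the real multi-site quenching value
#' \eqn{\sum_n M_{0,n}/(1+k_n C)}.
#'
#' @param procs an [emission_process()] or a list of them.
#' @param C concentration(s), kPa.
#' @param freq_hz modulation frequency in Hz; must be >= 0.
#' @return Complex response, vectorised over `C`.
#' @export
transfer_function <- function(procs, C, freq_hz) {
  procs <- as_process_list(procs)
  check_conc(C)
  stopifnot(is.numeric(freq_hz), length(freq_hz) == 1L, freq_hz >= 0)
  out <- complex(real = numeric(length(C)), imaginary = numeric(length(C)))
  for (p in procs) {
    tq <- p$tau0 / (1 + p$k * C)
    out <- out + p$M0 * (tq / p$tau0) / (1 + 1i * omega_tau(freq_hz, tq))
  }
  out
}

#' Modulation-factor of a multiexponential sensor
#'
#' Modulus of [transfer_function()]. For a single process this equals
#' \eqn{M_0 (\tau_q/\tau_0) / \sqrt{1+(\omega\tau_q)^2}}.
#'
#' @inheritParams transfer_function
#' @return Dimensionless modulation-factor(s).
#' @export
modulation_factor <- function(procs, C, freq_hz) {
  Mod(transfer_function(procs, C, freq_hz))
}

#' Phase-shift of a multiexponential sensor
#'
#' Magnitude of the argument of [transfer_function()], in degrees.
#' The physical phase lag is negative; by convention the magnitude is
#' stored and reported, so a single process gives
#' \eqn{\arctan(\omega\tau_q)} in degrees.
#'
#' @inheritParams transfer_function
#' @return Phase-shift magnitude(s), degrees in `[0, 90)`.
#' @export
phase_shift <- function(procs, C, freq_hz) {
  abs(Arg(transfer_function(procs, C, freq_hz))) * 180 / pi
}

#' Modulation-factor at null concentration and a given frequency
#'
#' The low-frequency null-concentration modulation-factor `M0` rolls off
#' with frequency for a first-order process:
#' \eqn{m_0(\omega) = M_0/\sqrt{1+(\omega\tau_0)^2}}.
#'
#' @param M0 low-frequency null-concentration modulation-factor (> 0).
#' @param tau0 unquenched lifetime, microseconds (> 0).
#' @param freq_hz modulation frequency, Hz (>= 0).
#' @return Dimensionless modulation-factor.
#' @export
m0_at_frequency <- function(M0, tau0, freq_hz) {
  stopifnot(M0 > 0, tau0 > 0, freq_hz >= 0)
  M0 / sqrt(1 + omega_tau(freq_hz, tau0)^2)
}

#' Apparent lifetime from the phase-shift
#'
#' First-order estimator \eqn{\tau_\phi = \tan(\phi)/\omega}. Under the
#' positive-magnitude phase convention used throughout this package the
#' minus sign of the raw (negative) phase lag cancels.
#'
#' @param phase_deg phase-shift magnitude(s) in degrees, in `[0, 90)`.
#' @param freq_hz modulation frequency, Hz (> 0).
#' @return Apparent lifetime(s), microseconds.
#' @export
tau_from_phase <- function(phase_deg, freq_hz) {
  stopifnot(is.numeric(phase_deg), freq_hz > 0)
  if (any(!is.finite(phase_deg)) || any(phase_deg < 0) || any(phase_deg >= 90))
    stop("phase_deg must lie in [0, 90) degrees (tangent singularity at 90)")
  tan(phase_deg * pi / 180) / (2 * pi * freq_hz) * 1e6
}

#' Apparent lifetime from the modulation-factor
#'
#' First-order estimator using the modulation-factor referenced to its
#' null-concentration value at the same frequency. With \eqn{s = m/m_0}:
#' \deqn{\tau_m = \frac{\tau_0\, s}{\sqrt{1 + (\omega\tau_0)^2 (1 - s^2)}}}
#' which is the algebraic inverse of the first-order modulation-factor
#' response, so that on mono-exponential data \eqn{\tau_m} recovers the
#' quenched lifetime exactly. Requires the unquenched lifetime `tau0`,
#' in practice estimated as \eqn{\tau_\phi} at null concentration.
#'
#' @param m measured modulation-factor(s) (> 0).
#' @param m0 modulation-factor at null concentration and the same
#'   frequency (> 0), see [m0_at_frequency()].
#' @param tau0 unquenched lifetime, microseconds (> 0).
#' @param freq_hz modulation frequency, Hz (> 0).
#' @return Apparent lifetime(s), microseconds.
#' @export
tau_from_modulation <- function(m, m0, tau0, freq_hz) {
  stopifnot(is.numeric(m), m0 > 0, tau0 > 0, freq_hz > 0)
  if (any(!is.finite(m)) || any(m <= 0)) stop("m must be finite and > 0")
  s <- m / m0
  wt0 <- omega_tau(freq_hz, tau0)
  rad <- 1 + wt0^2 * (1 - s^2)
  if (any(rad <= 0))
    stop("modulation-factor inconsistent with a first-order response at ",
         "this frequency (radicand <= 0); m/m0 too large")
  tau0 * s / sqrt(rad)
}
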