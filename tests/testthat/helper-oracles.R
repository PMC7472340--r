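# Shared oracles and fixture builders. Oracles are deliberately independent
# of the implementation paths they check (bisection instead of the quadratic
# formula, dense grids instead of golden-section, direct nonlinear
# minimisation instead of the profiled searches).

# brute-force inverse of any calibration model by bisection on the forward
# direction; assumes a strictly decreasing response
bisect_inverse <- function(model, phi, C_hi = 1e4, tol = 1e-12) {
  vapply(phi, function(ph) {
    lo <- 0; hi <- C_hi
    f <- function(C) model_signal(model, C) - ph
    if (f(lo) < 0) return(0)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < tol * (1 + hi)) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

# noiseless averaged calibration data generated from a forward model
exact_dataset <- function(model, C, signal_type = "phase_deg") {
  calibration_dataset(C, model_signal(model, C), signal_type = signal_type)
}

# noiseless two-process fixture used where multiexponential behaviour matters
two_proc_fixture <- function() {
  list(emission_process(0.5, 10, 0.1), emission_process(0.3, 50, 0.5))
}

# direct nonlinear minimisation of the concentration-domain RMS relative
# error, multi-start Nelder-Mead; the independent check on the profiled
# Lehrer/Demas schemes
oracle_lehrer <- function(ds) {
  p <- ds$points[ds$points$concentration > 0, ]
  C <- p$concentration; phi <- p$signal_mean
  obj <- function(th) {
    phi0 <- th[1]; k <- exp(th[2]); x <- stats::plogis(th[3])
    r <- phi / phi0
    if (phi0 <= 0 || any(r <= 1 - x) || any(r >= 1)) return(1e6)
    Cp <- (x / (r - (1 - x)) - 1) / k
    100 * sqrt(mean(((Cp - C) / C)^2))
  }
  best <- Inf
  for (k0 in c(-3, -1.5, 0, 1.5)) for (l0 in c(0, 2, 6)) {
    o <- stats::optim(c(max(phi) * 1.05, k0, l0), obj,
                      control = list(maxit = 4000, reltol = 1e-12))
    if (o$value < best) best <- o$value
  }
  best
}

oracle_demas <- function(ds) {
  p <- ds$points[ds$points$concentration > 0, ]
  C <- p$concentration; phi <- p$signal_mean
  obj <- function(th) {
    m <- tryCatch(demas_model(th[1], stats::plogis(th[2]), exp(th[3]), exp(th[4])),
                  error = function(e) NULL)
    if (is.null(m) || any(phi >= m$phi0)) return(1e6)
    Cp <- tryCatch(model_concentration(m, phi), error = function(e) NULL)
    if (is.null(Cp)) return(1e6)
    100 * sqrt(mean(((Cp - C) / C)^2))
  }
  best <- Inf
  starts <- list(c(max(phi) * 1.05, 0, log(0.3), log(0.03)),
                 c(max(phi) * 1.05, 1, log(0.8), log(0.1)),
                 c(max(phi) * 1.1, -1, log(0.15), log(0.01)),
                 c(max(phi) * 1.02, 0.5, log(2), log(0.3)))
  for (s in starts) {
    o <- stats::optim(s, obj, control = list(maxit = 8000, reltol = 1e-12))
    if (o$value < best) best <- o$value
  }
  best
}
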