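#' Calibration model constructors
#'
#' Constructors for the four calibration model families mapping an
#' analytical signal (phase-shift, modulation-factor, or an apparent
#' lifetime) to analyte concentration in quenching-based luminescence
#' sensors:
#'
#' * `sv_model(phi0, k)` — Stern-Volmer: \eqn{\phi(C) = \phi_0/(1+kC)}.
#' * `lehrer_model(phi0, k, x)` — Lehrer: only a fraction `x` of the
#'   luminophore population is quenchable,
#'   \eqn{\phi(C) = \phi_0 (x/(1+kC) + 1-x)}.
#' * `demas_model(phi0, x, k1, k2)` — two-site Demas: two independent
#'   quenching sites, \eqn{\phi(C) = \phi_0 (x/(1+k_1 C) + (1-x)/(1+k_2 C))}.
#'   Parameters are canonicalised to `k1 >= k2` (swapping `x` for `1-x`
#'   when needed) to remove the label ambiguity.
#' * `pe_model(coeffs, alpha, ...)` — polynomial-exponent:
#'   \eqn{C(\phi) = \sum_{n=0}^p a_n \phi^{n\alpha}}; the concentration is
#'   a degree-`p` polynomial in the exponent-corrected signal
#'   \eqn{\phi^\alpha}. With `p = 1`, `alpha = -1` this is exactly the
#'   Stern-Volmer model (see [sv_to_pe()]).
#'
#' All models share the generics [model_concentration()], [model_signal()],
#' [null_response()], [sensitivity()] and can be serialised with
#' [write_cal_model()].
#'
#' @param phi0 response at null concentration, signal units (> 0).
#' @param k,k1,k2 Stern-Volmer quenching constants, kPa^-1.
#' @param x quenchable fraction in `[0, 1]`.
#' @param coeffs numeric vector `c(a0, ..., ap)` of polynomial
#'   coefficients (units kPa); degree `p = length(coeffs) - 1 >= 1`.
#' @param alpha signal exponent, dimensionless, non-zero (fits exclude a
#'   dead zone `|alpha| < 0.01` where the transform degenerates).
#' @param signal_range length-2 numeric, the declared signal interval on
#'   which the PE model is used (and over which monotonicity of
#'   \eqn{C(\phi)} is verified numerically at construction). Defaults to
#'   `c(1e-6, 1) * null_response` of the model.
#' @param alpha_free logical; whether `alpha` counts as a fitted parameter
#'   (`FALSE` for the constrained P2 model).
#' @return An object of class `c("<variant>_model", "cal_model")`.
#' @name cal_models
NULL

new_cal_model <- function(x, subclass) {
  structure(x, class = c(subclass, "cal_model"))
}

#' @rdname cal_models
#' @export
sv_model <- function(phi0, k) {
  stopifnot(is.numeric(phi0), length(phi0) == 1L, is.numeric(k), length(k) == 1L)
  if (!is.finite(phi0) || phi0 <= 0) stop("phi0 must be > 0")
  if (!is.finite(k) || k <= 0) stop("k must be > 0 (kPa^-1)")
  new_cal_model(list(phi0 = phi0, k = k), "sv_model")
}

#' @rdname cal_models
#' @export
lehrer_model <- function(phi0, k, x) {
  stopifnot(length(phi0) == 1L, length(k) == 1L, length(x) == 1L)
  if (!is.finite(phi0) || phi0 <= 0) stop("phi0 must be > 0")
  if (!is.finite(k) || k <= 0) stop("k must be > 0 (kPa^-1)")
  if (!is.finite(x) || x < 0 || x > 1) stop("x must lie in [0, 1]")
  new_cal_model(list(phi0 = phi0, k = k, x = x), "lehrer_model")
}

#' @rdname cal_models
#' @export
demas_model <- function(phi0, x, k1, k2) {
  stopifnot(length(phi0) == 1L, length(x) == 1L, length(k1) == 1L, length(k2) == 1L)
  if (!is.finite(phi0) || phi0 <= 0) stop("phi0 must be > 0")
  if (!is.finite(x) || x < 0 || x > 1) stop("x must lie in [0, 1]")
  if (!is.finite(k1) || k1 < 0 || !is.finite(k2) || k2 < 0)
    stop("k1 and k2 must be >= 0 (kPa^-1)")
  if (k1 < k2) { tmp <- k1; k1 <- k2; k2 <- tmp; x <- 1 - x }
  new_cal_model(list(phi0 = phi0, x = x, k1 = k1, k2 = k2), "demas_model")
}

#' @rdname cal_models
#' @export
pe_model <- function(coeffs, alpha, signal_range = NULL, alpha_free = TRUE) {
  stopifnot(is.numeric(coeffs), length(coeffs) >= 2L, all(is.finite(coeffs)),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha == 0) stop("alpha must be non-zero")
  m <- new_cal_model(list(coeffs = coeffs, alpha = alpha,
                          degree = length(coeffs) - 1L,
                          signal_range = NULL,
                          alpha_free = isTRUE(alpha_free)),
                     "pe_model")
  if (is.null(signal_range)) {
    phi0 <- tryCatch(pe_null_root(m, range_hint = NULL), error = function(e)
      stop("cannot derive a default signal range: ", conditionMessage(e)))
    signal_range <- c(1e-6 * phi0, phi0)
  }
  stopifnot(is.numeric(signal_range), length(signal_range) == 2L,
            all(is.finite(signal_range)), all(signal_range > 0),
            signal_range[1] < signal_range[2])
  m$signal_range <- as.numeric(signal_range)
  check_pe_monotone(m)
  m
}

# numeric strict-monotonicity check of C(phi) over the declared range
check_pe_monotone <- function(m, n = 201L) {
  phi <- exp(seq(log(m$signal_range[1]), log(m$signal_range[2]), length.out = n))
  C <- pe_eval(m, phi)
  d <- diff(C)
  if (!(all(d < 0) || all(d > 0)))
    stop("PE model is not strictly monotone over its declared signal range [",
         format(m$signal_range[1]), ", ", format(m$signal_range[2]), "]")
  invisible(m)
}

pe_eval <- function(m, phi) {
  y <- outer(phi, (0:m$degree) * m$alpha, `^`)
  drop(y %*% m$coeffs)
}

# real positive root(s) phi0 of C(phi) = 0 for a PE model
pe_null_root <- function(m, range_hint = m$signal_range) {
  p <- m$degree
  a <- m$coeffs
  if (p == 1L) {
    y <- -a[1] / a[2]
    if (!is.finite(y) || y <= 0) stop("no admissible null-response root")
    cand <- y^(1 / m$alpha)
  } else if (p == 2L) {
    disc <- a[2]^2 - 4 * a[1] * a[3]
    if (disc < 0) stop("no admissible null-response root (negative discriminant)")
    # numerically stable quadratic: a near-zero curvature coefficient must
    # degrade gracefully to the first-degree root
    q <- -(a[2] + sign(a[2] + (a[2] == 0)) * sqrt(disc)) / 2
    ys <- c(if (q != 0) a[1] / q, if (a[3] != 0) q / a[3])
    cand <- ys[is.finite(ys) & ys > 0]^(1 / m$alpha)
  } else {
    ys <- polyroot(a)
    ys <- Re(ys[abs(Im(ys)) < 1e-8 * (1 + abs(Re(ys)))])
    cand <- ys[ys > 0]^(1 / m$alpha)
  }
  cand <- cand[is.finite(cand) & cand > 0]
  if (length(cand) == 0L) stop("no admissible null-response root")
  if (length(cand) > 1L) {
    if (!is.null(range_hint)) {
      lo <- range_hint[1] / 1.5; hi <- range_hint[2] * 1.5
      inside <- cand[cand >= lo & cand <= hi]
      if (length(inside) == 1L) return(inside)
      if (length(inside) > 1L) stop("several admissible null-response roots: ",
                                    paste(signif(inside, 6), collapse = ", "))
      stop("no null-response root inside the declared signal range")
    }
    stop("several admissible null-response roots")
  }
  cand
}

#' Concentration predicted from an analytical signal
#'
#' Inverts (SV, Lehrer, Demas) or directly evaluates (PE) the calibration
#' model at signal value(s) `phi`. For the quenching-type models `phi`
#' must lie in `(0, phi0]`; the Lehrer model additionally requires
#' `phi/phi0 > 1 - x` (the unquenchable-fraction floor). The Demas
#' inverse solves the quadratic obtained by clearing denominators of the
#' two-site response, selecting the unique non-negative root (the other
#' root is non-positive whenever `phi <= phi0`).
#'
#' @param model a `cal_model`.
#' @param phi analytical signal value(s), model signal units.
#' @return Concentration(s), kPa.
#' @seealso [model_signal()] for the forward direction.
#' @export
model_concentration <- function(model, phi) UseMethod("model_concentration")

check_phi_range <- function(phi, lo, hi, what) {
  if (any(!is.finite(phi)) || any(phi <= lo) || any(phi > hi))
    stop(what, ": signal out of range; valid interval is (",
         format(lo), ", ", format(hi), "]")
}

#' @export
model_concentration.sv_model <- function(model, phi) {
  check_phi_range(phi, 0, model$phi0, "Stern-Volmer inverse")
  (model$phi0 / phi - 1) / model$k
}

#' @export
model_concentration.lehrer_model <- function(model, phi) {
  check_phi_range(phi, 0, model$phi0, "Lehrer inverse")
  r <- phi / model$phi0
  if (any(r <= 1 - model$x))
    stop("Lehrer inverse: signal at or below the unquenchable-fraction ",
         "floor phi0*(1-x) = ", format(model$phi0 * (1 - model$x)))
  (model$x / (r - (1 - model$x)) - 1) / model$k
}

# stable quadratic inversion of the two-site Demas response; r = phi/phi0
demas_root <- function(r, k1, k2, x) {
  a <- r * k1 * k2
  b <- r * (k1 + k2) - (x * k2 + (1 - x) * k1)
  cc <- r - 1
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    if (a[i] == 0) {                        # k1 or k2 zero: linear in C
      out[i] <- if (b[i] > 0) max(0, -cc[i] / b[i])
                else if (cc[i] == 0) 0 else NA_real_
    } else {
      disc <- b[i]^2 - 4 * a[i] * cc[i]
      if (disc < 0) { out[i] <- NA_real_; next }
      q <- -(b[i] + sign(b[i] + (b[i] == 0)) * sqrt(disc)) / 2
      roots <- c(q / a[i], if (q != 0) cc[i] / q else 0)
      pos <- roots[roots >= -1e-12]
      out[i] <- if (length(pos)) max(0, min(pos)) else NA_real_
    }
  }
  out
}

#' @export
model_concentration.demas_model <- function(model, phi) {
  check_phi_range(phi, 0, model$phi0, "Demas inverse")
  C <- demas_root(phi / model$phi0, model$k1, model$k2, model$x)
  if (any(is.na(C))) stop("Demas inverse: no admissible root for some signals")
  C
}

#' @export
model_concentration.pe_model <- function(model, phi) {
  sr <- model$signal_range
  if (any(!is.finite(phi)) || any(phi < sr[1] * (1 - 1e-9)) ||
      any(phi > sr[2] * (1 + 1e-9)))
    stop("PE model: signal outside the declared range [",
         format(sr[1]), ", ", format(sr[2]), "]")
  pe_eval(model, phi)
}

#' Analytical signal predicted at a concentration
#'
#' Forward direction of a calibration model. Closed-form for the
#' Stern-Volmer, Lehrer and Demas models; for the PE model (whose natural
#' direction is signal to concentration) the unique signal in the declared
#' monotone range is found by bracketed root search to a relative
#' tolerance of 1e-10.
#'
#' @param model a `cal_model`.
#' @param C concentration(s), kPa (>= 0).
#' @return Signal value(s), model signal units.
#' @export
model_signal <- function(model, C) UseMethod("model_signal")

#' @export
model_signal.sv_model <- function(model, C) {
  check_conc(C)
  model$phi0 / (1 + model$k * C)
}

#' @export
model_signal.lehrer_model <- function(model, C) {
  check_conc(C)
  model$phi0 * (model$x / (1 + model$k * C) + 1 - model$x)
}

#' @export
model_signal.demas_model <- function(model, C) {
  check_conc(C)
  model$phi0 * (model$x / (1 + model$k1 * C) + (1 - model$x) / (1 + model$k2 * C))
}

#' @export
model_signal.pe_model <- function(model, C) {
  check_conc(C)
  sr <- model$signal_range
  clo <- pe_eval(model, sr[1]); chi <- pe_eval(model, sr[2])
  vapply(C, function(Ci) {
    f <- function(phi) pe_eval(model, phi) - Ci
    if ((clo - Ci) * (chi - Ci) > 0) {
      # accept range endpoints whose residual is only rounding noise
      tol <- 1e-9 * (1 + abs(Ci) + abs(clo) + abs(chi))
      if (abs(chi - Ci) < tol) return(sr[2])
      if (abs(clo - Ci) < tol) return(sr[1])
      stop("PE forward: concentration ", format(Ci),
           " kPa not attainable within the declared signal range")
    }
    uniroot(f, interval = sr, tol = 1e-10 * sr[2])$root
  }, numeric(1))
}

#' Model response at null concentration
#'
#' The signal the model predicts at `C = 0`. For the classical models this
#' is the `phi0` parameter; for the PE model it is derived from the
#' positive real root of the polynomial in \eqn{y = \phi^\alpha} (closed
#' form for degrees 1 and 2) mapped back through the `1/alpha` power.
#'
#' @param model a `cal_model`.
#' @return Signal value at null concentration.
#' @export
null_response <- function(model) UseMethod("null_response")

#' @export
null_response.cal_model <- function(model) model$phi0

#' @export
null_response.pe_model <- function(model) pe_null_root(model)

#' Relative sensitivity of the calibration at a concentration
#'
#' The magnitude of the relative slope of the response,
#' \eqn{K_C = |(1/\phi)\, d\phi/dC|}, in kPa^-1. At `C = 0` this is the
#' (generalised) Stern-Volmer constant: `k` for SV, `x k` for Lehrer and
#' `x k1 + (1-x) k2` for Demas. For the PE model
#' \eqn{K_C = 1/|\sum_n n \alpha a_n \phi^{n\alpha}|} evaluated at
#' \eqn{\phi(C)}. The raw derivative is negative for quenched sensors;
#' magnitudes are reported.
#'
#' @param model a `cal_model`.
#' @param C concentration, kPa (scalar or vector, >= 0).
#' @return Sensitivity magnitude(s), kPa^-1.
#' @export
sensitivity <- function(model, C) UseMethod("sensitivity")

#' @export
sensitivity.sv_model <- function(model, C) {
  check_conc(C)
  model$k / (1 + model$k * C)
}

#' @export
sensitivity.lehrer_model <- function(model, C) {
  check_conc(C)
  phi <- model_signal(model, C)
  abs(model$phi0 * model$x * model$k / (1 + model$k * C)^2) / phi
}

#' @export
sensitivity.demas_model <- function(model, C) {
  check_conc(C)
  phi <- model_signal(model, C)
  dphi <- model$phi0 * (model$x * model$k1 / (1 + model$k1 * C)^2 +
                        (1 - model$x) * model$k2 / (1 + model$k2 * C)^2)
  dphi / phi
}

#' @export
sensitivity.pe_model <- function(model, C) {
  check_conc(C)
  phi <- vapply(C, function(Ci)
    if (Ci == 0) null_response(model) else model_signal(model, Ci), numeric(1))
  n <- 0:model$degree
  dsum <- vapply(phi, function(p) sum(n * model$alpha * model$coeffs * p^(n * model$alpha)),
                 numeric(1))
  if (any(dsum == 0)) stop("flat response: derivative of C(phi) vanishes")
  1 / abs(dsum)
}

#' Embed a Stern-Volmer model as a first-degree PE model
#'
#' The Stern-Volmer model is the special case of the degree-1 PE model
#' with `alpha = -1`, `a0 = -1/k`, `a1 = phi0/k`; equivalently
#' `phi0 = -a1/a0` and `k = -1/a0`. The two parameterisations agree
#' exactly as maps from signal to concentration.
#'
#' @param sv an [sv_model()].
#' @return A [pe_model()] of degree 1 with `alpha = -1`.
#' @export
sv_to_pe <- function(sv) {
  stopifnot(inherits(sv, "sv_model"))
  pe_model(c(-1 / sv$k, sv$phi0 / sv$k), alpha = -1,
           signal_range = c(1e-6 * sv$phi0, sv$phi0))
}

#' Number of free parameters of a calibration model
#' @param model a `cal_model`.
#' @return Integer parameter count (SV 2, Lehrer 3, P2 3, PE1 3, Demas 4,
#'   PE2 4, ...).
#' @export
n_params <- function(model) UseMethod("n_params")

#' @export
n_params.sv_model <- function(model) 2L
#' @export
n_params.lehrer_model <- function(model) 3L
#' @export
n_params.demas_model <- function(model) 4L
#' @export
n_params.pe_model <- function(model) model$degree + 1L + as.integer(model$alpha_free)

variant_label <- function(model) {
  if (inherits(model, "sv_model")) return("SV")
  if (inherits(model, "lehrer_model")) return("L")
  if (inherits(model, "demas_model")) return("D")
  if (model$degree == 2L && !model$alpha_free) return("P2")
  paste0("PE", model$degree)
}

#' @export
coef.cal_model <- function(object, ...) {
  unlist(object[setdiff(names(object), c("degree", "signal_range", "alpha_free"))])
}

#' @export
print.cal_model <- function(x, ...) {
  cat(sprintf("<%s calibration model>\n", variant_label(x)))
  cf <- coef(x)
  cat(paste0("  ", names(cf), " = ", signif(cf, 6), collapse = "\n"), "\n")
  if (inherits(x, "pe_model"))
    cat(sprintf("  signal range: [%.6g, %.6g]\n",
                x$signal_range[1], x$signal_range[2]))
  invisible(x)
}

# ---- lenient prediction used for scoring noisy data -------------------------
# Quenching-type inverses are clamped to [0, cap] kPa (signals beyond the
# null response predict 0; signals past the invertible floor predict cap).
# PE predictions are the raw polynomial values: the minimized objective is
# then exactly the weighted least-squares criterion.
score_conc <- function(model, phi, cap) {
  if (inherits(model, "pe_model")) return(pe_eval(model, phi))
  C <- if (inherits(model, "sv_model")) {
    ifelse(phi <= 0, cap, (model$phi0 / phi - 1) / model$k)
  } else if (inherits(model, "lehrer_model")) {
    r <- phi / model$phi0
    floorx <- 1 - model$x
    ifelse(r <= floorx, cap, (model$x / (r - floorx) - 1) / model$k)
  } else if (inherits(model, "demas_model")) {
    out <- demas_root(pmin(phi / model$phi0, 1), model$k1, model$k2, model$x)
    out[is.na(out)] <- cap
    out
  } else stop("unsupported model class")
  pmin(pmax(C, 0), cap)
}
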