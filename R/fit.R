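#' Calibration dataset
#'
#' Per-concentration averaged signals used to calibrate a model. Points at
#' `C = 0` are retained for inspection but excluded from fitting, because
#' the minimized criterion is the relative concentration error.
#'
#' @param concentration reference concentrations, kPa (>= 0).
#' @param signal_mean mean analytical signal at each concentration (> 0).
#' @param signal_sd optional per-concentration signal standard deviation.
#' @param n_reps optional replicate count behind each mean.
#' @param signal_type one of `"phase_deg"`, `"mod_factor"`, `"tau_phi_us"`,
#'   `"tau_m_us"`.
#' @return An object of class `calibration_dataset` (a data frame of
#'   points plus the signal type).
#' @export
calibration_dataset <- function(concentration, signal_mean, signal_sd = NULL,
                                n_reps = NULL,
                                signal_type = c("phase_deg", "mod_factor",
                                                "tau_phi_us", "tau_m_us")) {
  signal_type <- match.arg(signal_type)
  stopifnot(is.numeric(concentration), is.numeric(signal_mean),
            length(concentration) == length(signal_mean))
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentrations must be finite and >= 0 kPa")
  if (any(!is.finite(signal_mean)) || any(signal_mean <= 0))
    stop("signal means must be finite and > 0")
  if (anyDuplicated(concentration))
    stop("duplicate concentrations; average replicates first")
  o <- order(concentration)
  pts <- data.frame(concentration = concentration[o],
                    signal_mean = signal_mean[o])
  pts$signal_sd <- if (is.null(signal_sd)) NA_real_ else signal_sd[o]
  pts$n_reps <- if (is.null(n_reps)) NA_integer_ else as.integer(n_reps[o])
  structure(list(points = pts, signal_type = signal_type),
            class = "calibration_dataset")
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat(sprintf("<calibration dataset>  signal: %s, %d concentrations (%.3g-%.3g kPa)\n",
              x$signal_type, nrow(x$points),
              min(x$points$concentration), max(x$points$concentration)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

as_cal_dataset <- function(data, signal_type = "phase_deg") {
  if (inherits(data, "calibration_dataset")) return(data)
  if (is.data.frame(data)) {
    nm <- names(data)
    cc <- intersect(c("concentration", "concentration_kPa", "C"), nm)[1]
    sc <- intersect(c("signal", "signal_mean", "value"), nm)[1]
    if (is.na(cc) || is.na(sc))
      stop("data frame must have a concentration and a signal column")
    st <- if ("signal_type" %in% nm) as.character(data$signal_type[1]) else signal_type
    return(calibration_dataset(data[[cc]], data[[sc]], signal_type = st))
  }
  stop("'data' must be a calibration_dataset or a data frame")
}

# fitting points: strictly positive concentrations only
fit_points <- function(ds) {
  p <- ds$points[ds$points$concentration > 0, , drop = FALSE]
  if (nrow(p) < 3L) stop("need at least 3 points with C > 0 to calibrate")
  p
}

#' RMS relative concentration error, in percent
#'
#' \eqn{100 \sqrt{\mathrm{mean}\left(((C_{pred}-C_{ref})/C_{ref})^2\right)}}
#' — the optimization criterion minimized by every calibration engine in
#' this package, and the figure of merit reported for evaluation data.
#'
#' @param C_pred predicted concentrations, kPa.
#' @param C_ref reference concentrations, kPa (all > 0).
#' @return RMS relative error in percent.
#' @export
rms_relative_error <- function(C_pred, C_ref) {
  stopifnot(length(C_pred) == length(C_ref), length(C_ref) > 0)
  if (any(!is.finite(C_ref)) || any(C_ref <= 0))
    stop("all reference concentrations must be > 0 for a relative error")
  100 * sqrt(mean(((C_pred - C_ref) / C_ref)^2))
}

#' Polynomial coefficients of a PE model at a fixed exponent
#'
#' One-step weighted linear least squares for the PE coefficients at a
#' given exponent: minimises \eqn{\sum_i (1/C_i^2)(\sum_n a_n
#' \phi_i^{n\alpha} - C_i)^2}, i.e. exactly the squared relative
#' concentration error, on the design matrix \eqn{X_{i,n} =
#' \phi_i^{n\alpha}}. No search is involved; this is the inner step of the
#' profiled exponent optimisation.
#'
#' @param data a [calibration_dataset()] (or data frame, see
#'   [fit_calibration()]).
#' @param degree polynomial degree `p >= 1`.
#' @param alpha fixed exponent (non-zero).
#' @return Numeric vector `c(a0, ..., ap)`.
#' @export
fit_poly_alpha_fixed <- function(data, degree, alpha) {
  ds <- as_cal_dataset(data)
  stopifnot(degree >= 1L, alpha != 0)
  p <- fit_points(ds)
  if (length(unique(p$concentration)) < degree + 2L)
    stop("need at least degree + 2 distinct concentrations")
  X <- outer(p$signal_mean, (0:degree) * alpha, `^`)
  w <- 1 / p$concentration^2
  fit <- stats::lm.wfit(x = X, y = p$concentration, w = w)
  if (fit$rank < degree + 1L) {
    kap <- kappa(sqrt(w) * X)
    stop("rank-deficient PE design matrix (condition number ",
         format(kap, digits = 3), "); signals nearly collinear at alpha = ",
         format(alpha))
  }
  unname(fit$coefficients)
}

# profiled objective at fixed alpha: RMS relative error of the WLS solution
pe_profile_objective <- function(p, degree, alpha) {
  X <- outer(p$signal_mean, (0:degree) * alpha, `^`)
  w <- 1 / p$concentration^2
  fit <- tryCatch(stats::lm.wfit(x = X, y = p$concentration, w = w),
                  error = function(e) NULL)
  if (is.null(fit) || fit$rank < degree + 1L || any(!is.finite(fit$coefficients)))
    return(list(J = Inf, coeffs = NULL))
  Cp <- drop(X %*% fit$coefficients)
  list(J = 100 * sqrt(mean(((Cp - p$concentration) / p$concentration)^2)),
       coeffs = unname(fit$coefficients))
}

# deterministic golden-section minimisation of f over [a, b] with a fixed
# evaluation budget; returns the best evaluated point
golden_section <- function(f, a, b, budget) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2); used <- 2L
  best <- if (f1 <= f2) c(x1, f1) else c(x2, f2)
  while (used < budget) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
    used <- used + 1L
    cand <- if (f1 <= f2) c(x1, f1) else c(x2, f2)
    if (cand[2] < best[2]) best <- cand
  }
  list(x = best[1], fx = best[2], used = used)
}

# alpha grid over bounds minus the dead zone, always containing -1 if in range
alpha_grid <- function(bounds, dead_zone, n) {
  iv <- list()
  if (bounds[1] < -dead_zone) iv <- c(iv, list(c(bounds[1], min(-dead_zone, bounds[2]))))
  if (bounds[2] > dead_zone) iv <- c(iv, list(c(max(dead_zone, bounds[1]), bounds[2])))
  if (!length(iv)) stop("alpha bounds lie entirely inside the dead zone")
  len <- vapply(iv, diff, numeric(1))
  pts <- unlist(lapply(seq_along(iv), function(i) {
    ni <- max(4L, round(n * len[i] / sum(len)))
    seq(iv[[i]][1], iv[[i]][2], length.out = ni)
  }))
  if (bounds[1] <= -1 && -1 <= bounds[2]) pts <- c(pts, -1)
  sort(unique(pts))
}

#' Fit a PE calibration model by profiled exponent search
#'
#' Minimises the RMS relative concentration error over the exponent
#' `alpha` by profiling: for each candidate `alpha` the polynomial
#' coefficients are obtained in one weighted least-squares step
#' ([fit_poly_alpha_fixed()]), so the search is one-dimensional regardless
#' of the polynomial degree. A coarse grid over `alpha_bounds` (always
#' containing `alpha = -1`, the Stern-Volmer exponent) is refined by
#' golden-section search within the total evaluation budget `iterations`.
#' Ties within 1e-12 are broken toward `alpha = -1`.
#'
#' @inheritParams fit_poly_alpha_fixed
#' @param alpha_bounds length-2 numeric search interval for the exponent;
#'   a dead zone `|alpha| < 0.01` is always excluded.
#' @param iterations total number of objective evaluations (default 100).
#' @return A [cal_fit] object.
#' @export
fit_pe <- function(data, degree = 1L, alpha_bounds = c(-5, 5),
                   iterations = 100L) {
  ds <- as_cal_dataset(data)
  stopifnot(length(alpha_bounds) == 2L, alpha_bounds[1] < alpha_bounds[2],
            all(is.finite(alpha_bounds)), iterations >= 10L)
  p <- fit_points(ds)
  dead <- 0.01
  n_grid <- max(10L, as.integer(floor(iterations * 0.6)))
  grid <- alpha_grid(alpha_bounds, dead, n_grid)
  Js <- vapply(grid, function(a) pe_profile_objective(p, degree, a)$J, numeric(1))
  used <- length(grid)
  if (all(!is.finite(Js))) stop("PE fit infeasible at every grid exponent")
  jb <- best_alpha_index(grid, Js)
  lo <- grid[max(1L, jb - 1L)]; hi <- grid[min(length(grid), jb + 1L)]
  # keep the refinement bracket clear of the dead zone
  if (lo < -dead && hi > -dead) { if (grid[jb] <= -dead) hi <- -dead else lo <- dead }
  best_a <- grid[jb]; best_J <- Js[jb]
  rem <- iterations - used
  if (rem >= 4L && hi > lo) {
    gs <- golden_section(function(a) pe_profile_objective(p, degree, a)$J,
                         lo, hi, rem)
    used <- used + gs$used
    if (gs$fx < best_J - 1e-12 ||
        (abs(gs$fx - best_J) <= 1e-12 && abs(gs$x + 1) < abs(best_a + 1))) {
      best_a <- gs$x; best_J <- gs$fx
    }
  }
  prof <- pe_profile_objective(p, degree, best_a)
  model <- build_pe_model(prof$coeffs, best_a, p$signal_mean, alpha_free = TRUE)
  new_cal_fit(model, ds, objective_pct = prof$J, iterations_used = used)
}

best_alpha_index <- function(grid, Js) {
  jmin <- min(Js[is.finite(Js)])
  cand <- which(Js <= jmin + 1e-12)
  cand[which.min(abs(grid[cand] + 1))]     # tie-break toward alpha = -1
}

# declared signal range for a fitted PE model: wide enough to contain the
# null-response root when the fit is monotone there, else the data range
build_pe_model <- function(coeffs, alpha, signals, alpha_free) {
  lo <- min(signals); hi <- max(signals)
  for (rng in list(c(lo / 2, hi * 1.5), c(lo * 0.99, hi * 1.01))) {
    m <- tryCatch(pe_model(coeffs, alpha, signal_range = rng,
                           alpha_free = alpha_free),
                  error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
  stop("fitted PE polynomial is not monotone over the data signal range")
}

#' Direct (non-iterative) Stern-Volmer and P2 calibrations
#'
#' Both are single weighted least-squares solves at the fixed exponent
#' `alpha = -1`: the Stern-Volmer model is the degree-1 case (coefficients
#' mapped to `phi0 = -a1/a0`, `k = -1/a0`), and the P2 model is the
#' degree-2 case reported as a PE model with the exponent constrained.
#'
#' @inheritParams fit_poly_alpha_fixed
#' @param variant `"sv"` or `"p2"`.
#' @return A [cal_fit] object.
#' @export
fit_direct <- function(data, variant = c("sv", "p2")) {
  variant <- match.arg(variant)
  ds <- as_cal_dataset(data)
  p <- fit_points(ds)
  if (variant == "sv") {
    a <- fit_poly_alpha_fixed(ds, 1L, -1)
    if (a[1] >= 0 || a[2] <= 0)
      stop("non-physical Stern-Volmer fit (requires a0 < 0 and a1 > 0); ",
           "the data do not follow a quenching response")
    model <- sv_model(phi0 = -a[2] / a[1], k = -1 / a[1])
    J <- pe_profile_objective(p, 1L, -1)$J
    return(new_cal_fit(model, ds, objective_pct = J, iterations_used = 1L))
  }
  prof <- pe_profile_objective(p, 2L, -1)
  if (!is.finite(prof$J)) stop("P2 design matrix is rank deficient")
  model <- build_pe_model(prof$coeffs, -1, p$signal_mean, alpha_free = FALSE)
  new_cal_fit(model, ds, objective_pct = prof$J, iterations_used = 1L)
}

# ordinary LS of phi on columns of X with nonnegative coefficients,
# via unconstrained solve then the better feasible boundary (2 columns max)
nnls2 <- function(X, y) {
  cf <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, ncol(X)))
  if (all(is.finite(cf)) && all(cf >= 0)) return(cf)
  best <- NULL; bss <- Inf
  for (jdrop in seq_len(ncol(X))) {
    keep <- setdiff(seq_len(ncol(X)), jdrop)
    c1 <- sum(X[, keep] * y) / sum(X[, keep]^2)
    if (!is.finite(c1) || c1 < 0) c1 <- 0
    cf2 <- numeric(ncol(X)); cf2[keep] <- c1
    ss <- sum((y - X %*% cf2)^2)
    if (ss < bss) { bss <- ss; best <- cf2 }
  }
  best
}

score_fit <- function(model, p, cap) {
  Cp <- score_conc(model, p$signal_mean, cap)
  100 * sqrt(mean(((Cp - p$concentration) / p$concentration)^2))
}

#' Fit the Lehrer model
#'
#' Profiled one-dimensional search over the quenching constant `k`: for
#' each candidate `k` the amplitudes `A = phi0 x` and `B = phi0 (1-x)` are
#' obtained by a nonnegative linear least-squares solve in the signal
#' domain (`phi ~ A/(1+kC) + B`), and the candidate is scored by the RMS
#' relative concentration error through the analytic Lehrer inverse. A
#' log-spaced grid is refined by golden-section search within the
#' iteration budget. The direct Stern-Volmer fit is always scored as a
#' candidate, so the Lehrer objective can never exceed the Stern-Volmer
#' one; when it wins (or the fitted `x` reaches 1) the fit is flagged as
#' degenerate to SV.
#'
#' @inheritParams fit_pe
#' @param k_bounds search interval for `k`, kPa^-1.
#' @return A [cal_fit] object (field `degenerate` is `"sv"` when the
#'   unquenchable fraction vanishes).
#' @export
fit_lehrer <- function(data, iterations = 100L, k_bounds = c(1e-4, 1e3)) {
  ds <- as_cal_dataset(data)
  p <- fit_points(ds)
  cap <- 5 * max(p$concentration)
  make_cand <- function(k) {
    X <- cbind(1 / (1 + k * p$concentration), 1)
    cf <- nnls2(X, p$signal_mean)
    A <- cf[1]; B <- cf[2]
    if (!is.finite(A) || A + B <= 0 || A <= 0) return(NULL)
    x <- A / (A + B)
    tryCatch(lehrer_model(phi0 = A + B, k = k, x = min(x, 1)),
             error = function(e) NULL)
  }
  obj <- function(k) {
    m <- make_cand(k)
    if (is.null(m)) return(Inf)
    score_fit(m, p, cap)
  }
  n_grid <- max(10L, as.integer(floor(iterations * 0.5)))
  kg <- exp(seq(log(k_bounds[1]), log(k_bounds[2]), length.out = n_grid))
  Js <- vapply(kg, obj, numeric(1))
  used <- length(kg)
  if (all(!is.finite(Js))) stop("Lehrer fit infeasible at every grid k")
  jb <- which.min(Js)
  lo <- log(kg[max(1L, jb - 1L)]); hi <- log(kg[min(length(kg), jb + 1L)])
  best_k <- kg[jb]; best_J <- Js[jb]
  rem <- iterations - used
  if (rem >= 4L && hi > lo) {
    gs <- golden_section(function(lk) obj(exp(lk)), lo, hi, rem)
    used <- used + gs$used
    if (gs$fx < best_J) { best_k <- exp(gs$x); best_J <- gs$fx }
  }
  model <- make_cand(best_k)
  # concentration-domain polish: the signal-domain inner solve is linear but
  # not exactly optimal for the relative-concentration criterion; a short
  # deterministic Nelder-Mead from the profiled optimum closes the gap
  if (!is.null(model)) {
    th0 <- c(log(model$phi0), log(model$k),
             stats::qlogis(min(max(model$x, 1e-6), 1 - 1e-6)))
    pol <- stats::optim(th0, function(th) {
      k <- exp(th[2])
      if (k < k_bounds[1] || k > k_bounds[2]) return(Inf)
      m <- tryCatch(lehrer_model(exp(th[1]), k, stats::plogis(th[3])),
                    error = function(e) NULL)
      if (is.null(m)) return(Inf)
      score_fit(m, p, cap)
    }, method = "Nelder-Mead", control = list(maxit = 300, reltol = 1e-12))
    used <- used + pol$counts[[1]]
    if (is.finite(pol$value) && pol$value < best_J) {
      model <- lehrer_model(exp(pol$par[1]), exp(pol$par[2]),
                            stats::plogis(pol$par[3]))
      best_J <- pol$value
    }
  }
  degen <- NA_character_
  # the SV fit is a Lehrer model with x = 1: keep whichever scores better
  sv <- tryCatch(fit_direct(ds, "sv"), error = function(e) NULL)
  if (!is.null(sv)) {
    svJ <- score_fit(lehrer_model(sv$model$phi0, sv$model$k, 1), p, cap)
    if (is.null(model) || svJ <= best_J) {
      model <- lehrer_model(sv$model$phi0, sv$model$k, 1)
      best_J <- svJ
    }
  }
  if (is.null(model)) stop("Lehrer fit failed: no feasible candidate")
  if (model$x >= 1 - 1e-9) degen <- "sv"
  new_cal_fit(model, ds, objective_pct = best_J, iterations_used = used,
              degenerate = degen)
}

#' Fit the two-site Demas model
#'
#' Two-dimensional search over the quenching constants `(k1, k2)` with the
#' canonical ordering `k1 >= k2 >= 0`: a coarse logarithmic grid
#' (including the single-site boundary `k2 = 0`) followed by local grid
#' refinement within the iteration budget. For each `(k1, k2)` the site
#' amplitudes are a nonnegative linear least-squares solve in the signal
#' domain; candidates are scored by the RMS relative concentration error
#' through the quadratic Demas inverse. The fitted Lehrer (`k2 = 0`
#' embedding) and Stern-Volmer (`k1 = k2`) models are always scored as
#' candidates, so the Demas objective can never exceed theirs; boundary
#' wins are flagged as degenerations.
#'
#' @inheritParams fit_lehrer
#' @param iterations total objective-evaluation budget (default 500; the
#'   search is two-dimensional).
#' @return A [cal_fit] object (field `degenerate` in `"sv"`, `"lehrer"`
#'   or `NA`).
#' @export
fit_demas <- function(data, iterations = 500L, k_bounds = c(1e-4, 1e3)) {
  ds <- as_cal_dataset(data)
  p <- fit_points(ds)
  cap <- 5 * max(p$concentration)
  make_cand <- function(k1, k2) {
    X <- cbind(1 / (1 + k1 * p$concentration), 1 / (1 + k2 * p$concentration))
    cf <- nnls2(X, p$signal_mean)
    if (is.null(cf) || sum(cf) <= 0) return(NULL)
    tryCatch(demas_model(phi0 = sum(cf), x = cf[1] / sum(cf), k1 = k1, k2 = k2),
             error = function(e) NULL)
  }
  obj <- function(k1, k2) {
    m <- make_cand(k1, k2)
    if (is.null(m)) return(Inf)
    score_fit(m, p, cap)
  }
  used <- 0L
  kg <- exp(seq(log(k_bounds[1]), log(k_bounds[2]), length.out = 12L))
  pairs <- expand.grid(k1 = kg, k2 = c(0, kg))
  pairs <- pairs[pairs$k1 >= pairs$k2, ]
  Js <- mapply(obj, pairs$k1, pairs$k2)
  used <- used + nrow(pairs)
  if (all(!is.finite(Js))) stop("Demas fit infeasible at every grid point")
  jb <- which.min(Js)
  best <- c(pairs$k1[jb], pairs$k2[jb]); best_J <- Js[jb]
  # local refinement: Nelder-Mead in (log k1, log k2) from the best few grid
  # points (the scored surface has a narrow curved valley that axis-aligned
  # grids track poorly); deterministic, budget split across starts
  ord <- order(Js)
  starts <- unique(lapply(ord[seq_len(min(4L, sum(is.finite(Js))))], function(j)
    c(pmax(pairs$k1[j], k_bounds[1]), pmax(pairs$k2[j], k_bounds[1]))))
  budget_per <- max(50L, (iterations - used) %/% length(starts))
  lkb <- log(k_bounds)
  for (s in starts) {
    o <- stats::optim(log(s), function(th) {
      if (any(th < lkb[1]) || any(th > lkb[2])) return(Inf)
      obj(exp(th[1]), exp(th[2]))
    }, method = "Nelder-Mead",
       control = list(maxit = budget_per, reltol = 1e-12))
    used <- used + o$counts[[1]]
    if (is.finite(o$value) && o$value < best_J) {
      best <- sort(exp(o$par), decreasing = TRUE); best_J <- o$value
    }
  }
  model <- make_cand(best[1], best[2])
  # concentration-domain polish of all four parameters (see fit_lehrer)
  if (!is.null(model)) {
    th0 <- c(log(model$phi0), stats::qlogis(min(max(model$x, 1e-6), 1 - 1e-6)),
             log(max(model$k1, k_bounds[1])), log(max(model$k2, k_bounds[1])))
    pol <- stats::optim(th0, function(th) {
      ks <- exp(th[3:4])
      if (any(ks < k_bounds[1]) || any(ks > k_bounds[2])) return(Inf)
      m <- tryCatch(demas_model(exp(th[1]), stats::plogis(th[2]), ks[1], ks[2]),
                    error = function(e) NULL)
      if (is.null(m)) return(Inf)
      score_fit(m, p, cap)
    }, method = "Nelder-Mead", control = list(maxit = 400, reltol = 1e-12))
    used <- used + pol$counts[[1]]
    if (is.finite(pol$value) && pol$value < best_J) {
      model <- demas_model(exp(pol$par[1]), stats::plogis(pol$par[2]),
                           exp(pol$par[3]), exp(pol$par[4]))
      best_J <- pol$value
    }
  }
  # boundary embeddings: a Lehrer fit is Demas with k2 = 0, an SV fit has k1 = k2
  leh <- tryCatch(fit_lehrer(ds, iterations = 100L, k_bounds = k_bounds),
                  error = function(e) NULL)
  degen <- NA_character_
  if (!is.null(leh)) {
    lm2 <- demas_model(leh$model$phi0, leh$model$x, leh$model$k, 0)
    lJ <- score_fit(lm2, p, cap)
    if (is.null(model) || lJ <= best_J) {
      model <- lm2; best_J <- lJ
      degen <- if (!is.na(leh$degenerate)) "sv" else "lehrer"
    }
  }
  if (is.null(model)) stop("Demas fit failed: no feasible candidate")
  if (is.na(degen)) {
    if (model$x >= 1 - 1e-9 || model$k1 - model$k2 < 1e-9 * model$k1)
      degen <- "sv"
    else if (model$k2 <= 1e-12 && model$x < 1 - 1e-9) degen <- "lehrer"
  }
  new_cal_fit(model, ds, objective_pct = best_J, iterations_used = used,
              degenerate = degen)
}

# ---- the fitted-model container --------------------------------------------

new_cal_fit <- function(model, ds, objective_pct, iterations_used,
                        degenerate = NA_character_) {
  p <- fit_points(ds)
  cap <- 5 * max(p$concentration)
  Cp <- score_conc(model, p$signal_mean, cap)
  w <- 1 / p$concentration^2
  ssr <- sum(w * (Cp - p$concentration)^2)
  sst <- sum(w * (p$concentration - sum(w * p$concentration) / sum(w))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - ssr / sst)) else NA_real_
  derived <- tryCatch(derived_params(model), error = function(e) NULL)
  structure(list(model = model, variant = variant_label(model),
                 objective_pct = objective_pct, r_squared = r2,
                 iterations_used = iterations_used, derived = derived,
                 degenerate = degenerate, dataset = ds, conc_cap = cap),
            class = "cal_fit")
}

#' Derived physical parameters of a calibration model
#'
#' Null-concentration response and relative-sensitivity magnitudes at 0, 1
#' and 10 kPa — the physically interpretable summary shared by all model
#' families.
#'
#' @param model a `cal_model`.
#' @return Named list with `phi0`, `K0`, `K1`, `K10`.
#' @export
derived_params <- function(model) {
  list(phi0 = null_response(model),
       K0 = sensitivity(model, 0),
       K1 = sensitivity(model, 1),
       K10 = sensitivity(model, 10))
}

#' Fit a calibration model to a dataset
#'
#' Front end to all calibration engines. `data` is either a
#' [calibration_dataset()] or a data frame with a concentration column
#' (`concentration`, `concentration_kPa` or `C`, kPa) and a signal column
#' (`signal`, `signal_mean` or `value`). The optimization criterion is
#' always the RMS relative concentration error; see [fit_pe()],
#' [fit_direct()], [fit_lehrer()] and [fit_demas()] for the per-family
#' procedures and iteration budgets (100 for the one-dimensional Lehrer /
#' PE1 / PE2 searches, 500 for the two-dimensional Demas search, none for
#' SV and P2 which are single least-squares solves).
#'
#' @param data calibration data (see Details).
#' @param model one of `"sv"`, `"lehrer"`, `"demas"`, `"p2"`, `"pe1"`,
#'   `"pe2"`, or `"pe"` with an explicit `degree`.
#' @param degree polynomial degree for `model = "pe"`.
#' @param alpha_bounds exponent search interval for PE fits.
#' @param iterations objective-evaluation budget for the iterative fits;
#'   `NULL` uses the per-family default.
#' @param signal_type signal label used when `data` is a plain data frame
#'   without one.
#' @return An object of class `cal_fit`, with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot` methods.
#' @examples
#' sv <- sv_model(64.5, 0.109)
#' C <- c(0.5, 1, 2, 5, 10, 15, 20)
#' d <- data.frame(concentration = C, signal = model_signal(sv, C))
#' fit <- fit_calibration(d, "pe1")
#' coef(fit)             # alpha recovered at -1, the Stern-Volmer exponent
#' predict(fit, newdata = 32.25)
#' @export
fit_calibration <- function(data,
                            model = c("sv", "lehrer", "demas", "p2",
                                      "pe1", "pe2", "pe"),
                            degree = NULL, alpha_bounds = c(-5, 5),
                            iterations = NULL, signal_type = "phase_deg") {
  model <- match.arg(model)
  ds <- as_cal_dataset(data, signal_type)
  switch(model,
    sv = fit_direct(ds, "sv"),
    p2 = fit_direct(ds, "p2"),
    lehrer = fit_lehrer(ds, iterations = iterations %||% 100L),
    demas = fit_demas(ds, iterations = iterations %||% 500L),
    pe1 = fit_pe(ds, 1L, alpha_bounds, iterations %||% 100L),
    pe2 = fit_pe(ds, 2L, alpha_bounds, iterations %||% 100L),
    pe = {
      if (is.null(degree)) stop("model = \"pe\" requires 'degree'")
      fit_pe(ds, as.integer(degree), alpha_bounds, iterations %||% 100L)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cal_fit <- function(x, ...) {
  cat(sprintf("<%s calibration fit>  signal: %s\n", x$variant,
              x$dataset$signal_type))
  cat(sprintf("  RMS relative error: %.4g %%   R^2: %.5f   parameters: %d\n",
              x$objective_pct, x$r_squared, n_params(x$model)))
  if (!is.na(x$degenerate))
    cat(sprintf("  note: fit degenerated to the %s model\n",
                toupper(x$degenerate)))
  print(x$model)
  invisible(x)
}

#' @export
summary.cal_fit <- function(object, ...) {
  d <- object$derived
  structure(list(fit = object,
                 derived = data.frame(phi0 = d$phi0, K0 = d$K0,
                                      K1 = d$K1, K10 = d$K10)),
            class = "summary.cal_fit")
}

#' @export
print.summary.cal_fit <- function(x, ...) {
  print(x$fit)
  cat("  derived parameters (signal units / kPa^-1):\n")
  print(x$derived, row.names = FALSE)
  cat(sprintf("  objective evaluations used: %d\n", x$fit$iterations_used))
  invisible(x)
}

#' @export
coef.cal_fit <- function(object, ...) coef(object$model)

#' Predict concentrations (or signals) from a calibration fit
#'
#' @param object a `cal_fit`.
#' @param newdata signal values (numeric vector, or a data frame with a
#'   `signal`/`value` column) for `type = "concentration"`, or
#'   concentration values for `type = "signal"`. Defaults to the
#'   calibration signals.
#' @param type direction of the prediction.
#' @param lenient if `TRUE` (default) out-of-range signals are clamped to
#'   the model's invertible limits and predictions to `[0, conc_cap]`
#'   (suitable for noisy evaluation replicates); if `FALSE`, the strict
#'   [model_concentration()] contract is used and out-of-range signals
#'   are an error.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.cal_fit <- function(object, newdata = NULL,
                            type = c("concentration", "signal"),
                            lenient = TRUE, ...) {
  type <- match.arg(type)
  if (type == "signal") {
    C <- if (is.null(newdata)) fit_points(object$dataset)$concentration
         else as.numeric(newdata)
    return(model_signal(object$model, C))
  }
  phi <- if (is.null(newdata)) fit_points(object$dataset)$signal_mean
         else if (is.data.frame(newdata)) {
           sc <- intersect(c("signal", "signal_mean", "value"), names(newdata))[1]
           if (is.na(sc)) stop("newdata needs a signal column")
           newdata[[sc]]
         } else as.numeric(newdata)
  if (lenient) score_conc(object$model, phi, object$conc_cap)
  else model_concentration(object$model, phi)
}

#' @export
fitted.cal_fit <- function(object, ...) predict(object)

#' @export
residuals.cal_fit <- function(object, type = c("relative", "absolute"), ...) {
  type <- match.arg(type)
  p <- fit_points(object$dataset)
  Cp <- predict(object)
  if (type == "relative") (Cp - p$concentration) / p$concentration
  else Cp - p$concentration
}

#' @export
plot.cal_fit <- function(x, n_curve = 200, ...) {
  p <- fit_points(x$dataset)
  Cg <- seq(0, max(p$concentration) * 1.05, length.out = n_curve)
  phi_g <- tryCatch(model_signal(x$model, Cg), error = function(e) NULL)
  graphics::plot(p$concentration, p$signal_mean,
                 xlab = "concentration (kPa)",
                 ylab = x$dataset$signal_type,
                 main = sprintf("%s calibration (RMSE %.3g %%)",
                                x$variant, x$objective_pct), ...)
  if (!is.null(phi_g)) graphics::lines(Cg, phi_g, col = "steelblue")
  invisible(x)
}
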