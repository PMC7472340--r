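ALL_VARIANTS <- c("sv", "lehrer", "p2", "pe1", "demas", "pe2")

fit_variant_safe <- function(ds, variant) {
  tryCatch(fit_calibration(ds, variant), error = function(e) {
    warning(sprintf("%s fit failed: %s", variant, conditionMessage(e)),
            call. = FALSE)
    NULL
  })
}

#' Fit and evaluate a set of calibration model variants
#'
#' Fits each requested model variant on the averaged calibration data and
#' reports the RMS relative concentration error on (a) the averaged
#' calibration points (the minimized quantity) and (b) the pooled
#' individual evaluation replicates (the expected accuracy of an actual
#' analyte determination). Fit failures are recorded as `NA` rows rather
#' than raised.
#'
#' @param x a [simulate_experiment()] result, or a
#'   [calibration_dataset()] (then supply `eval_reps`).
#' @param signal_type which analytical signal to calibrate on (for a
#'   `sim_experiment`).
#' @param variants model variants to fit (default all six).
#' @param eval_reps replicate-level evaluation data: data frame with
#'   columns `concentration` and `value` (ignored for a
#'   `sim_experiment`).
#' @return Data frame with one row per variant: `variant`, `n_params`,
#'   `cal_rmse_pct`, `eval_rmse_pct`, `degenerate`; the fitted objects are
#'   attached as attribute `"fits"`.
#' @export
evaluate_suite <- function(x, signal_type = "phase_deg",
                           variants = ALL_VARIANTS, eval_reps = NULL) {
  if (inherits(x, "sim_experiment")) {
    ds <- x$cal[[signal_type]]
    eval_reps <- eval_replicates(x, signal_type)
  } else {
    ds <- as_cal_dataset(x, signal_type)
    signal_type <- ds$signal_type
  }
  if (!is.null(eval_reps) && !all(c("concentration", "value") %in% names(eval_reps)))
    stop("eval_reps needs columns 'concentration' and 'value'")
  fits <- lapply(variants, function(v) fit_variant_safe(ds, v))
  names(fits) <- variants
  rows <- lapply(variants, function(v) {
    f <- fits[[v]]
    if (is.null(f))
      return(data.frame(variant = v, n_params = NA_integer_,
                        cal_rmse_pct = NA_real_, eval_rmse_pct = NA_real_,
                        degenerate = NA_character_))
    ev <- NA_real_
    if (!is.null(eval_reps) && nrow(eval_reps) > 0) {
      keep <- eval_reps$concentration > 0
      Cp <- predict(f, newdata = eval_reps$value[keep])
      ev <- rms_relative_error(Cp, eval_reps$concentration[keep])
    }
    data.frame(variant = v, n_params = n_params(f$model),
               cal_rmse_pct = f$objective_pct, eval_rmse_pct = ev,
               degenerate = f$degenerate)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "signal_type") <- signal_type
  out
}

#' Accuracy comparison across several experiments
#'
#' Builds the model-by-experiment accuracy table: for each experiment the
#' per-variant RMS relative errors on averaged calibration data and on
#' individual evaluation replicates, plus an `average` column across
#' experiments.
#'
#' @param sims named list of `sim_experiment` objects.
#' @param signal_types character vector (recycled) choosing the
#'   analytical signal per experiment.
#' @param variants model variants to fit.
#' @return List with two data frames, `calibration` and `evaluation`
#'   (rows = variants, columns = experiments plus `average`), and
#'   `n_params`.
#' @export
comparison_report <- function(sims, signal_types = "phase_deg",
                              variants = ALL_VARIANTS) {
  stopifnot(is.list(sims), length(sims) >= 1L)
  if (is.null(names(sims))) names(sims) <- paste0("exp", seq_along(sims))
  signal_types <- rep_len(signal_types, length(sims))
  res <- Map(function(s, st) evaluate_suite(s, st, variants),
             sims, signal_types)
  cal <- sapply(res, function(r) r$cal_rmse_pct)
  ev <- sapply(res, function(r) r$eval_rmse_pct)
  to_df <- function(m) {
    m <- matrix(m, nrow = length(variants),
                dimnames = list(variants, names(sims)))
    df <- as.data.frame(m)
    df$average <- rowMeans(m, na.rm = TRUE)
    cbind(variant = variants, df, row.names = NULL)
  }
  list(calibration = to_df(cal), evaluation = to_df(ev),
       n_params = vapply(attr(res[[1]], "fits"), function(f)
         if (is.null(f)) NA_integer_ else n_params(f$model), integer(1)))
}

#' Derived-parameter table for a set of fits
#'
#' Null-concentration response and relative sensitivity magnitudes at 0,
#' 1 and 10 kPa for each fitted model — the physically comparable summary
#' across model families.
#'
#' @param fits a list of `cal_fit` objects (e.g. the `"fits"` attribute
#'   of [evaluate_suite()]).
#' @return Data frame with columns `variant`, `phi0`, `K0`, `K1`, `K10`.
#' @export
derived_report <- function(fits) {
  stopifnot(is.list(fits))
  rows <- lapply(fits, function(f) {
    if (is.null(f)) return(NULL)
    m <- if (inherits(f, "cal_fit")) f$model else f
    d <- derived_params(m)
    data.frame(variant = variant_label(m), phi0 = d$phi0, K0 = d$K0,
               K1 = d$K1, K10 = d$K10)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

primary_signal_for <- function(signal_type) {
  if (signal_type %in% c("phase_deg", "tau_phi_us")) "phase_deg" else "mod_factor"
}

#' Sensitivity of the calibration accuracy to an instrumental bias
#'
#' Sweeps an additive instrumental bias on the primary signal (phase-shift
#' for phase-based signals, modulation-factor for modulation-based ones)
#' across `bias_grid`. For each bias value the bias is applied identically
#' to the calibration and evaluation subsets ([apply_bias()]; apparent
#' lifetimes are re-derived when the analytical signal is a lifetime),
#' every model variant is refitted, and both error surfaces are recorded,
#' together with flags marking where the Lehrer / Demas fits degenerate to
#' the Stern-Volmer model (quenchable fraction `x` pinned at 1).
#'
#' Default grids: phase bias from -5 to +5 degrees in 0.25-degree steps;
#' modulation-factor bias from -10% to +10% of the null-concentration
#' modulation-factor in 0.5% steps.
#'
#' @param sim a [simulate_experiment()] result.
#' @param signal_type analytical signal used for calibration.
#' @param variants model variants to fit at each bias.
#' @param bias_grid numeric vector of additive biases in primary-signal
#'   units; `NULL` for the default grid.
#' @return Data frame (class `bias_sweep`) with columns `bias`,
#'   `variant`, `cal_rmse_pct`, `eval_rmse_pct`, `degenerate_sv`; bias
#'   values whose shifted signals leave the measurable range are skipped
#'   with a warning.
#' @export
bias_sweep <- function(sim, signal_type = "phase_deg",
                       variants = ALL_VARIANTS, bias_grid = NULL) {
  stopifnot(inherits(sim, "sim_experiment"))
  primary <- primary_signal_for(signal_type)
  if (is.null(bias_grid)) {
    bias_grid <- if (primary == "phase_deg") seq(-5, 5, by = 0.25)
                 else seq(-0.10, 0.10, by = 0.005) * sim$meta$m0_est
  }
  stopifnot(!is.unsorted(bias_grid, strictly = TRUE))
  rows <- list()
  for (b in bias_grid) {
    simb <- tryCatch(apply_bias(sim, b, primary), error = function(e) NULL)
    if (is.null(simb)) {
      warning("bias ", format(b), " drives signals out of range; skipped")
      next
    }
    r <- suppressWarnings(evaluate_suite(simb, signal_type, variants))
    r$bias <- b
    r$degenerate_sv <- !is.na(r$degenerate) & r$degenerate == "sv"
    rows[[length(rows) + 1L]] <- r[, c("bias", "variant", "n_params",
                                       "cal_rmse_pct", "eval_rmse_pct",
                                       "degenerate_sv")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bias_sweep", "data.frame")
  attr(out, "signal_type") <- signal_type
  attr(out, "primary") <- primary
  out
}

#' @export
plot.bias_sweep <- function(x, surface = c("eval", "cal"), ...) {
  surface <- match.arg(surface)
  col <- if (surface == "eval") "eval_rmse_pct" else "cal_rmse_pct"
  vs <- unique(x$variant)
  pal <- grDevices::hcl.colors(length(vs), "Dark 3")
  graphics::matplot(unique(x$bias),
                    sapply(vs, function(v) x[[col]][x$variant == v]),
                    type = "l", lty = 1, col = pal,
                    xlab = sprintf("bias on %s", attr(x, "primary")),
                    ylab = "RMS relative error (%)", ...)
  graphics::legend("top", legend = toupper(vs), col = pal, lty = 1,
                   bty = "n", horiz = TRUE, cex = 0.8)
  invisible(x)
}
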