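#' Instrument configuration for a synthetic phase-resolved experiment
#'
#' Describes the measuring chain of a phase-resolved luminescence
#' instrument: modulation frequency, Gaussian measurement noise on the
#' phase-shift (degrees) and on the modulation-factor (relative), and
#' additive instrumental biases on either primary signal.
#'
#' @param freq_hz sinusoidal modulation frequency, Hz (> 0).
#' @param noise_phase_deg standard deviation of the phase-shift
#'   measurement noise, degrees (>= 0).
#' @param noise_mod_rel relative standard deviation of the
#'   modulation-factor measurement noise (>= 0).
#' @param bias_phase_deg additive phase-shift bias, degrees.
#' @param bias_mod additive modulation-factor bias.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(freq_hz, noise_phase_deg = 0.2,
                              noise_mod_rel = 0.005,
                              bias_phase_deg = 0, bias_mod = 0) {
  stopifnot(freq_hz > 0, noise_phase_deg >= 0, noise_mod_rel >= 0,
            is.finite(bias_phase_deg), is.finite(bias_mod))
  structure(list(freq_hz = freq_hz, noise_phase_deg = noise_phase_deg,
                 noise_mod_rel = noise_mod_rel,
                 bias_phase_deg = bias_phase_deg, bias_mod = bias_mod),
            class = "instrument_config")
}

#' Design of a synthetic calibration experiment
#'
#' @param concentrations strictly increasing concentrations, kPa (> 0).
#' @param reps_per_conc replicate measurements per concentration (>= 2).
#' @param cal_fraction fraction of replicates randomly assigned to the
#'   calibration subset (the rest form the disjoint evaluation subset).
#' @param seed integer master seed; per-concentration substreams are
#'   derived from it deterministically.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(concentrations, reps_per_conc,
                              cal_fraction = 0.5, seed = 1L) {
  stopifnot(is.numeric(concentrations), length(concentrations) >= 3L,
            all(concentrations > 0), !is.unsorted(concentrations, strictly = TRUE),
            reps_per_conc >= 2L, cal_fraction > 0, cal_fraction < 1,
            is.finite(seed))
  structure(list(concentrations = as.numeric(concentrations),
                 reps_per_conc = as.integer(reps_per_conc),
                 cal_fraction = cal_fraction, seed = as.integer(seed)),
            class = "experiment_design")
}

SIGNAL_TYPES <- c("phase_deg", "mod_factor", "tau_phi_us", "tau_m_us")

#' Built-in synthetic sensor fixtures
#'
#' Two two-process multiexponential sensor fixtures emulating typical
#' oxygen-sensing films measured in the frequency domain:
#'
#' * `"A"` — a PtTFPP-in-polystyrene-like film at 5145 Hz, concentrations
#'   0.5-20 kPa, 250 replicates per concentration; phase span roughly
#'   25-62 degrees. Moderate departure from a mono-exponential response:
#'   the two-site Demas fit improves clearly on Stern-Volmer at zero
#'   instrumental bias, and collapses onto it under negative phase bias.
#' * `"B"` — an iridium-complex-like film on a nanostructured support at
#'   30,100 Hz, 0.25-10 kPa, 100 replicates; phase span roughly 27-53
#'   degrees, with widely separated quenching constants (strongly
#'   non-Stern-Volmer).
#'
#' @param which `"A"` or `"B"`.
#' @param seed master seed for the replicate noise and the
#'   calibration/evaluation split.
#' @return List with elements `procs`, `inst`, `design`, ready for
#'   [simulate_experiment()].
#' @export
sensor_fixture <- function(which = c("A", "B"), seed = 1L) {
  which <- match.arg(which)
  if (which == "A") {
    list(procs = list(emission_process(0.75, 92, 0.23),
                      emission_process(0.25, 44, 0.58)),
         inst = instrument_config(freq_hz = 5145),
         design = experiment_design(c(0.5, 1, 2, 5, 10, 15, 20),
                                    reps_per_conc = 250L, seed = seed))
  } else {
    list(procs = list(emission_process(0.55, 15, 2.2),
                      emission_process(0.45, 6.0, 0.10)),
         inst = instrument_config(freq_hz = 30100),
         design = experiment_design(c(0.25, 0.5, 1, 2, 5, 10),
                                    reps_per_conc = 100L, seed = seed))
  }
}

sub_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + 7919 * i) %% 2147483647)
}

with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Simulate a phase-resolved calibration experiment
#'
#' Generates replicate phase-shift and modulation-factor measurements of a
#' (possibly multiexponential) sensor at each design concentration: the
#' noiseless values come from the closed-form frequency response
#' ([phase_shift()], [modulation_factor()]), independent Gaussian noise
#' and the configured instrumental biases are added, apparent lifetimes
#' are derived per replicate ([tau_from_phase()], [tau_from_modulation()]
#' with the unquenched lifetime taken from the null-concentration phase,
#' bias included), and replicates are split randomly (seeded) into
#' disjoint calibration and evaluation subsets. Calibration replicates are
#' averaged per concentration into one [calibration_dataset()] per signal
#' type.
#'
#' @param procs an [emission_process()] or list of them.
#' @param inst an [instrument_config()].
#' @param design an [experiment_design()].
#' @param experiment_id label stored with the replicate table.
#' @return An object of class `sim_experiment`: list with `cal` (named
#'   list of calibration datasets per signal type), `replicates` (long
#'   data frame: `experiment_id, signal_type, concentration_kPa,
#'   replicate, value, subset`), and `meta`.
#' @export
simulate_experiment <- function(procs, inst, design, experiment_id = "sim") {
  procs <- as_process_list(procs)
  stopifnot(inherits(inst, "instrument_config"),
            inherits(design, "experiment_design"))
  f <- inst$freq_hz
  concs <- design$concentrations
  reps <- design$reps_per_conc
  raw <- with_preserved_rng({
    out <- vector("list", length(concs))
    for (i in seq_along(concs)) {
      set.seed(sub_seed(design$seed, i))
      ph0 <- phase_shift(procs, concs[i], f)
      md0 <- modulation_factor(procs, concs[i], f)
      ph <- ph0 + stats::rnorm(reps, sd = inst$noise_phase_deg)
      md <- md0 * (1 + stats::rnorm(reps, sd = inst$noise_mod_rel))
      n_cal <- round(reps * design$cal_fraction)
      subset <- rep("eval", reps)
      subset[sample.int(reps, n_cal)] <- "cal"
      out[[i]] <- data.frame(concentration_kPa = concs[i],
                             replicate = seq_len(reps),
                             subset = subset, phase_deg = ph, mod_factor = md)
    }
    do.call(rbind, out)
  })
  sim <- structure(list(raw = raw,
                        meta = list(procs = procs, inst = inst,
                                    design = design, freq_hz = f,
                                    experiment_id = experiment_id,
                                    phase0_true = phase_shift(procs, 0, f),
                                    m0_true = modulation_factor(procs, 0, f),
                                    extra_bias_phase = 0, extra_bias_mod = 0)),
                   class = "sim_experiment")
  assemble_sim(sim)
}

# apply biases, derive lifetimes, average the calibration subset
assemble_sim <- function(sim) {
  meta <- sim$meta
  inst <- meta$inst
  f <- meta$freq_hz
  bp <- inst$bias_phase_deg + meta$extra_bias_phase
  bm <- inst$bias_mod + meta$extra_bias_mod
  raw <- sim$raw
  ph <- raw$phase_deg + bp
  md <- raw$mod_factor + bm
  # clamp into physically measurable ranges; a noisy instrument would
  # saturate similarly, but pervasive clamping means the noise/bias setting
  # is unusable
  n_bad <- sum(ph < 0 | ph >= 90) + sum(md <= 0)
  if (n_bad > 0.01 * 2 * nrow(raw))
    stop("noise/bias drives ", n_bad, " draws outside the measurable range ",
         "(phase in [0,90) deg, positive modulation-factor); ",
         "reduce the noise or bias")
  ph <- pmin(pmax(ph, 0), 90 - 1e-9)
  md <- pmax(md, 1e-12)
  # unquenched-lifetime and null-modulation references as the instrument
  # would estimate them, i.e. from the (biased) null-concentration response
  phase0 <- min(max(meta$phase0_true + bp, 1e-9), 90 - 1e-9)
  tau0_est <- tau_from_phase(phase0, f)
  m0_est <- max(meta$m0_true + bm, 1e-12)
  wt0 <- 2 * pi * f * tau0_est * 1e-6
  s_max <- sqrt(1 + 1 / wt0^2) * (1 - 1e-12)
  s <- pmin(md / m0_est, s_max)
  tau_phi <- tau_from_phase(ph, f)
  tau_m <- tau0_est * s / sqrt(1 + wt0^2 * (1 - s^2))
  vals <- cbind(phase_deg = ph, mod_factor = md,
                tau_phi_us = tau_phi, tau_m_us = tau_m)
  reps_long <- do.call(rbind, lapply(SIGNAL_TYPES, function(st)
    data.frame(experiment_id = meta$experiment_id, signal_type = st,
               concentration_kPa = raw$concentration_kPa,
               replicate = raw$replicate, value = vals[, st],
               subset = raw$subset)))
  rownames(reps_long) <- NULL
  cal_idx <- raw$subset == "cal"
  cal <- lapply(SIGNAL_TYPES, function(st) {
    v <- vals[cal_idx, st]
    cc <- raw$concentration_kPa[cal_idx]
    mu <- tapply(v, cc, mean)
    sdv <- tapply(v, cc, stats::sd)
    nn <- tapply(v, cc, length)
    concs <- as.numeric(names(mu))
    o <- order(concs)
    calibration_dataset(concs[o], as.numeric(mu)[o], as.numeric(sdv)[o],
                        as.numeric(nn)[o], signal_type = st)
  })
  names(cal) <- SIGNAL_TYPES
  sim$cal <- cal
  sim$replicates <- reps_long
  sim$meta$tau0_est <- tau0_est
  sim$meta$m0_est <- m0_est
  sim
}

#' @export
print.sim_experiment <- function(x, ...) {
  d <- x$meta$design
  cat(sprintf("<simulated experiment '%s'>  %d processes, %g Hz\n",
              x$meta$experiment_id, length(x$meta$procs), x$meta$freq_hz))
  cat(sprintf("  %d concentrations (%g-%g kPa), %d replicates each, cal fraction %.2g\n",
              length(d$concentrations), min(d$concentrations),
              max(d$concentrations), d$reps_per_conc, d$cal_fraction))
  bias <- total_bias(x)
  if (any(bias != 0))
    cat(sprintf("  applied bias: phase %+g deg, modulation %+g\n",
                bias[1], bias[2]))
  invisible(x)
}

total_bias <- function(sim) {
  c(phase = sim$meta$inst$bias_phase_deg + sim$meta$extra_bias_phase,
    mod = sim$meta$inst$bias_mod + sim$meta$extra_bias_mod)
}

#' Add an instrumental bias to a simulated experiment
#'
#' Adds `delta` to every value of the chosen primary signal (phase-shift
#' or modulation-factor), in both the calibration and the evaluation
#' subsets, and re-derives both apparent lifetimes (the
#' null-concentration references used by the lifetime estimators are
#' shifted by the same bias, as they would be on a real instrument).
#' `apply_bias(sim, 0)` returns the experiment unchanged.
#'
#' @param sim a [simulate_experiment()] result.
#' @param delta additive bias, in the units of `signal`.
#' @param signal which primary signal the bias enters.
#' @return A new `sim_experiment` with the bias applied.
#' @export
apply_bias <- function(sim, delta, signal = c("phase_deg", "mod_factor")) {
  stopifnot(inherits(sim, "sim_experiment"), is.finite(delta))
  signal <- match.arg(signal)
  if (signal == "phase_deg") sim$meta$extra_bias_phase <-
      sim$meta$extra_bias_phase + delta
  else sim$meta$extra_bias_mod <- sim$meta$extra_bias_mod + delta
  assemble_sim(sim)
}

#' Evaluation-subset replicates for one signal type
#'
#' @param sim a `sim_experiment`.
#' @param signal_type one of the four signal types.
#' @return Data frame with columns `concentration` and `value`.
#' @export
eval_replicates <- function(sim, signal_type = SIGNAL_TYPES) {
  signal_type <- match.arg(signal_type)
  r <- sim$replicates
  sel <- r$signal_type == signal_type & r$subset == "eval"
  data.frame(concentration = r$concentration_kPa[sel], value = r$value[sel])
}
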