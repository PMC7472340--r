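noise_free <- function(freq) instrument_config(freq, noise_phase_deg = 0,
                                               noise_mod_rel = 0)

test_that("noise-free simulation reproduces the closed-form response exactly", {
  p <- emission_process(0.7, 50, 0.2)
  des <- experiment_design(c(0.5, 2, 10), reps_per_conc = 10L, seed = 1)
  sim <- simulate_experiment(p, noise_free(5145), des)
  expect_equal(sim$cal$phase_deg$points$signal_mean,
               phase_shift(p, des$concentrations, 5145), tolerance = 1e-14)
  expect_equal(sim$cal$mod_factor$points$signal_mean,
               modulation_factor(p, des$concentrations, 5145), tolerance = 1e-14)
  # both derived lifetimes equal the quenched lifetime for one process
  expect_equal(sim$cal$tau_phi_us$points$signal_mean,
               tau_quenched(p, des$concentrations), tolerance = 1e-10)
  expect_equal(sim$cal$tau_m_us$points$signal_mean,
               tau_quenched(p, des$concentrations), tolerance = 1e-10)
})

test_that("simulation is reproducible by seed and varies across seeds", {
  fx <- sensor_fixture("A", seed = 13)
  s1 <- simulate_experiment(fx$procs, fx$inst, fx$design)
  s2 <- simulate_experiment(fx$procs, fx$inst, fx$design)
  expect_identical(s1$replicates, s2$replicates)
  fx3 <- sensor_fixture("A", seed = 14)
  s3 <- simulate_experiment(fx3$procs, fx3$inst, fx3$design)
  expect_false(isTRUE(all.equal(s1$replicates$value, s3$replicates$value)))
  expect_identical(s1$replicates$concentration_kPa,
                   s3$replicates$concentration_kPa)
})

test_that("replicates split into disjoint, exhaustive halves", {
  fx <- sensor_fixture("A", seed = 2)
  sim <- simulate_experiment(fx$procs, fx$inst, fx$design)
  r <- sim$replicates[sim$replicates$signal_type == "phase_deg", ]
  for (cc in unique(r$concentration_kPa)) {
    rc <- r[r$concentration_kPa == cc, ]
    expect_identical(sum(rc$subset == "cal"), 125L)
    expect_identical(sum(rc$subset == "eval"), 125L)
    expect_identical(sort(rc$replicate), 1:250)
    expect_length(intersect(rc$replicate[rc$subset == "cal"],
                            rc$replicate[rc$subset == "eval"]), 0)
  }
  expect_identical(nrow(sim$cal$phase_deg$points), 7L)
  expect_true(all(sim$cal$phase_deg$points$n_reps == 125L))
})

test_that("calibration means converge to the closed form as replicates grow", {
  p <- emission_process(0.7, 50, 0.2)
  inst <- instrument_config(5145, noise_phase_deg = 0.5, noise_mod_rel = 0.01)
  truth <- phase_shift(p, c(1, 5, 15), 5145)
  err <- vapply(c(1e3, 1e5), function(n) {
    des <- experiment_design(c(1, 5, 15), reps_per_conc = as.integer(n),
                             cal_fraction = 0.5, seed = 77)
    sim <- simulate_experiment(p, inst, des)
    max(abs(sim$cal$phase_deg$points$signal_mean - truth))
  }, numeric(1))
  # ~1/sqrt(n): two decades in n should buy about one decade in error
  expect_lt(err[2], err[1] / 3)
})

test_that("single-process fits recover the generator as noise vanishes", {
  p <- emission_process(0.7, 50, 0.2)
  des <- experiment_design(c(0.5, 1, 2, 5, 10, 20), 50L, seed = 21)
  f <- 5145
  # the phase-based lifetime of a mono-exponential sensor follows the
  # Stern-Volmer law exactly, so the fit recovers (tau0, k)
  for (noise in c(0.2, 0)) {
    inst <- instrument_config(f, noise_phase_deg = noise, noise_mod_rel = 0)
    fit <- fit_direct(simulate_experiment(p, inst, des)$cal$tau_phi_us, "sv")
    tol <- if (noise == 0) 1e-6 else 0.05
    expect_lt(abs(fit$model$phi0 - 50) / 50, tol)
    expect_lt(abs(fit$model$k - 0.2) / 0.2, tol)
  }
})

test_that("excessive noise is rejected rather than silently clamped", {
  p <- emission_process(0.7, 15, 0.2)   # phase near 26 deg at 5145 Hz
  des <- experiment_design(c(0.5, 1, 2), 200L, seed = 4)
  inst <- instrument_config(5145, noise_phase_deg = 40)
  expect_error(simulate_experiment(p, inst, des), "measurable range")
})

test_that("bias application shifts the primary signal and re-derives lifetimes", {
  fx <- sensor_fixture("A", seed = 31)
  sim <- simulate_experiment(fx$procs, fx$inst, fx$design)
  sim0 <- apply_bias(sim, 0)
  expect_equal(sim0$replicates, sim$replicates, tolerance = 1e-15)
  simb <- apply_bias(sim, 1, "phase_deg")
  ph <- function(s) s$replicates$value[s$replicates$signal_type == "phase_deg"]
  expect_equal(ph(simb), ph(sim) + 1, tolerance = 1e-12)
  # lifetimes recomputed through the tangent, point by point
  tp <- simb$replicates$value[simb$replicates$signal_type == "tau_phi_us"]
  expect_equal(tp, tau_from_phase(ph(sim) + 1, fx$inst$freq_hz),
               tolerance = 1e-12)
  # modulation bias leaves the phase channel untouched
  simm <- apply_bias(sim, 0.01, "mod_factor")
  expect_equal(ph(simm), ph(sim), tolerance = 1e-15)
  md <- function(s) s$replicates$value[s$replicates$signal_type == "mod_factor"]
  expect_equal(md(simm), md(sim) + 0.01, tolerance = 1e-12)
})
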