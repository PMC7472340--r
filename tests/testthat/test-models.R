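test_that("Stern-Volmer inverse and forward are exact and consistent", {
  sv <- sv_model(64.5, 0.109)
  expect_equal(model_concentration(sv, 32.25), (64.5 / 32.25 - 1) / 0.109)
  expect_equal(model_concentration(sv, 32.25), 9.174, tolerance = 1e-3)
  expect_equal(model_signal(sv, 0), 64.5)
  expect_equal(null_response(sv), 64.5)
  C <- seq(0, 25, length.out = 50)
  expect_equal(model_concentration(sv, model_signal(sv, C)), C, tolerance = 1e-12)
  expect_error(model_concentration(sv, 70), "out of range")
  expect_error(model_concentration(sv, 0), "out of range")
})

test_that("the model family degenerates along the expected chain", {
  phi_grid <- function(phi0) seq(0.3 * phi0, phi0, length.out = 100)
  sv <- sv_model(60, 0.25)
  # Lehrer with full quenchable fraction is Stern-Volmer
  leh1 <- lehrer_model(60, 0.25, 1)
  expect_equal(model_concentration(leh1, phi_grid(60)),
               model_concentration(sv, phi_grid(60)), tolerance = 1e-10)
  # Demas with equal site constants is Stern-Volmer
  dem <- demas_model(60, 0.37, 0.25, 0.25)
  expect_equal(model_concentration(dem, phi_grid(60)),
               model_concentration(sv, phi_grid(60)), tolerance = 1e-10)
  # Demas with one unquenchable site is Lehrer
  leh <- lehrer_model(60, 0.4, 0.8)
  dem2 <- demas_model(60, 0.8, 0.4, 0)
  phis <- seq(60 * (1 - 0.8) * 1.05, 60, length.out = 100)
  expect_equal(model_concentration(dem2, phis),
               model_concentration(leh, phis), tolerance = 1e-10)
  # first-degree PE at alpha = -1 is Stern-Volmer under the coefficient map
  pe <- sv_to_pe(sv)
  expect_equal(model_concentration(pe, phi_grid(60)),
               model_concentration(sv, phi_grid(60)), tolerance = 1e-12)
  expect_equal(pe$coeffs, c(-1 / 0.25, 60 / 0.25))
  expect_equal(null_response(pe), 60, tolerance = 1e-12)
  expect_equal(sensitivity(pe, c(0, 1, 7)), sensitivity(sv, c(0, 1, 7)),
               tolerance = 1e-10)
})

test_that("Lehrer inverse respects the unquenchable-fraction floor", {
  leh <- lehrer_model(50, 0.3, 0.6)
  expect_equal(model_concentration(leh, 50), 0, tolerance = 1e-9)
  floor_phi <- 50 * (1 - 0.6)
  expect_error(model_concentration(leh, floor_phi), "floor")
  C <- seq(0, 25, length.out = 40)
  expect_equal(model_concentration(leh, model_signal(leh, C)), C,
               tolerance = 1e-10)
})

test_that("forward responses are strictly decreasing and inverses consistent", {
  set.seed(42)
  C <- seq(0, 25, length.out = 60)
  models <- list(sv_model(70, 0.4),
                 lehrer_model(55, 1.2, 0.75),
                 demas_model(65, 0.6, 0.9, 0.07),
                 pe_model(c(-2, 50, 3), -0.7),
                 sv_to_pe(sv_model(33, 0.08)))
  for (m in models) {
    phi <- model_signal(m, C)
    expect_true(all(diff(phi) < 0))
    expect_equal(model_concentration(m, pmin(phi, null_response(m))), C,
                 tolerance = 1e-8)
  }
})

test_that("Demas quadratic inversion agrees with bisection on random models", {
  set.seed(1234)
  n <- 1000
  for (i in seq_len(n)) {
    phi0 <- runif(1, 5, 100)
    x <- runif(1)
    k1 <- 10^runif(1, -2, 1)
    k2 <- k1 * runif(1)
    m <- demas_model(phi0, x, k1, k2)
    phi <- runif(1, model_signal(m, 40), phi0)
    C_quad <- model_concentration(m, phi)
    C_bis <- bisect_inverse(m, phi, C_hi = 50)
    expect_equal(C_quad, C_bis, tolerance = 1e-8)
  }
})

test_that("PE null response uses the admissible polynomial root", {
  # coefficient map of SV(64.5, 0.109): a0 = -1/k, a1 = phi0/k
  pe1 <- pe_model(c(-1 / 0.109, 64.5 / 0.109), alpha = -1)
  expect_equal(null_response(pe1), 64.5, tolerance = 1e-12)
  expect_equal(pe1$coeffs[1], -9.174, tolerance = 1e-4)
  expect_equal(pe1$coeffs[2], 591.74, tolerance = 1e-5)
  # degenerate second-degree model reduces to the first-degree root
  pe2 <- pe_model(c(-1 / 0.109, 64.5 / 0.109, 0), alpha = -1)
  expect_equal(null_response(pe2), null_response(pe1), tolerance = 1e-12)
  # a proper second-degree model: root checked against its own inverse
  m <- pe_model(c(-2, 50, 3), -0.7)
  phi0 <- null_response(m)
  expect_equal(model_concentration(m, phi0), 0, tolerance = 1e-9)
})

test_that("sensitivities reduce to the classical null-concentration constants", {
  expect_equal(sensitivity(sv_model(64.5, 0.109), 0), 0.109)
  expect_equal(sensitivity(lehrer_model(60, 0.3, 0.85), 0), 0.85 * 0.3)
  expect_equal(sensitivity(demas_model(60, 0.7, 0.5, 0.05), 0),
               0.7 * 0.5 + 0.3 * 0.05)
  expect_equal(sensitivity(demas_model(60, 1, 0.5, 0.05), 0), 0.5)
  expect_equal(sensitivity(sv_to_pe(sv_model(64.5, 0.109)), 0), 0.109,
               tolerance = 1e-12)
  # closed forms at 1 and 10 kPa for Stern-Volmer
  k <- 0.109
  expect_equal(sensitivity(sv_model(64.5, k), c(1, 10)),
               c(k / (1 + k), k / (1 + 10 * k)))
})

test_that("model constructors validate their invariants", {
  expect_error(sv_model(-1, 0.1), "phi0")
  expect_error(sv_model(10, 0), "k must be")
  expect_error(lehrer_model(10, 0.1, 1.2), "x must")
  expect_error(pe_model(c(-1, 10), alpha = 0), "alpha")
  # canonical ordering of Demas site constants
  d <- demas_model(60, 0.3, 0.05, 0.5)
  expect_true(d$k1 >= d$k2)
  expect_equal(d$x, 0.7)
  # non-monotone PE polynomial over its declared range is rejected
  expect_error(pe_model(c(0, -5, 1), alpha = 1, signal_range = c(0.1, 10)),
               "monotone")
})

test_that("models serialise to text and back losslessly", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  models <- list(sv_model(64.5, 0.109),
                 lehrer_model(55.3, 1.23456789012345, 0.75),
                 demas_model(65, 0.6, 0.9, 0.07),
                 pe_model(c(-2, 50, 3), -0.7, alpha_free = FALSE))
  for (m in models) {
    write_cal_model(m, tmp)
    m2 <- read_cal_model(tmp)
    expect_equal(class(m2), class(m))
    expect_equal(coef(m2), coef(m), tolerance = 1e-15)
  }
})
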