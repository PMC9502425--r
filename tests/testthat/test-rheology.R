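# Carreau-Arrhenius model: shift factor, viscosity, inversion, refitting.

test_that("shift factor is 1 at the reference temperature and follows the Arrhenius form", {
  p <- ref_mats$pvpva$rheology
  expect_identical(shift_factor(p, p$T_ref), 1)
  # independent hand computation of the exponent at 483 K
  expect_equal(shift_factor(p, 483),
               exp(198292 / 8.314 * (1 / 483 - 1 / 473)))
  expect_lt(shift_factor(p, 493), 1)       # above T_ref
  expect_gt(shift_factor(p, 453), 1)       # below T_ref
  expect_error(shift_factor(p, -10), "positive")
})

test_that("viscosity matches an independent scalar oracle over a parameter grid", {
  for (key in names(ref_mats)) {
    p <- ref_mats[[key]]$rheology
    for (gd in c(0, 1, 264, 2500)) {
      for (Tk in c(433, 473, 513)) {
        expect_equal(
          melt_viscosity(p, gd, Tk),
          oracle_viscosity(p$eta0, p$gammadot_c, p$c, p$Ea, p$T_ref, gd, Tk),
          tolerance = 1e-12, label = sprintf("%s gd=%g T=%g", key, gd, Tk))
      }
    }
  }
  expect_error(melt_viscosity(ref_mats$pvpva$rheology, -1, 473), "non-negative")
})

test_that("viscosity is strictly decreasing in shear rate and temperature", {
  set.seed(101)
  for (i in 1:25) {
    p <- carreau_arrhenius(eta0 = runif(1, 10, 500),
                           gammadot_c = runif(1, 50, 2000),
                           c = runif(1, 0.05, 0.9),
                           Ea = runif(1, 5e4, 2.5e5), T_ref = 473)
    gd <- sort(runif(5, 0, 3000))
    Tk <- sort(runif(5, 380, 560))
    expect_true(all(diff(melt_viscosity(p, gd, 460)) < 0))
    expect_true(all(diff(melt_viscosity(p, 100, Tk)) < 0))
  }
})

test_that("Ostwald index is the complement of the Carreau index", {
  expect_equal(ostwald_index(carreau_arrhenius(1, 1, 0, 1, 473)), 1)
  expect_equal(ostwald_index(ref_mats$pvpva$rheology), 1 - 0.387)
  expect_equal(ostwald_index(ref_mats$bbma$rheology), 1 - 0.561)
})

test_that("temperature inversion round-trips viscosity to within 0.01 K", {
  for (key in names(ref_mats)) {
    p <- ref_mats[[key]]$rheology
    for (Tk in c(430, 450, 473, 520)) {
      for (gd in c(0, 100, 1500)) {
        target <- melt_viscosity(p, gd, Tk)
        expect_equal(invert_temperature(p, gd, target), Tk,
                     tolerance = 0.01 / Tk,
                     label = sprintf("%s T=%g gd=%g", key, Tk, gd))
      }
    }
  }
  # zero-shear target equal to eta0 recovers the reference temperature
  expect_equal(invert_temperature(ref_mats$sol$rheology, 0, 147.3), 473,
               tolerance = 1e-5)
})

test_that("temperature inversion agrees with an exhaustive 0.01 K grid search", {
  set.seed(202)
  keys <- sample(names(ref_mats), 30, replace = TRUE)
  for (key in keys) {
    p <- ref_mats[[key]]$rheology
    gd <- runif(1, 0, 2000)
    Tk <- runif(1, 400, 560)
    target <- melt_viscosity(p, gd, Tk)
    expect_equal(invert_temperature(p, gd, target),
                 oracle_invert_T(p, gd, target, p$T_ref - 150, p$T_ref + 150),
                 tolerance = 0.011 / Tk)
  }
})

test_that("unreachable inversion targets raise a bracketing error naming the endpoint viscosities", {
  p <- ref_mats$pvpva$rheology
  expect_error(invert_temperature(p, 100, 1e9), "outside the bracket")
  expect_error(invert_temperature(p, 100, 1e-6), "outside the bracket")
  err <- tryCatch(invert_temperature(p, 100, 1e9), error = identity)
  expect_match(conditionMessage(err), "viscosity\\(.*K\\)")
})

test_that("refitting noiseless model data recovers the generating parameters", {
  tr <- ref_mats$pvpva$rheology
  set.seed(7)
  sr <- 10^runif(40, 0, 3.5)
  Tk <- sample(c(433, 453, 473, 493), 40, replace = TRUE)
  pts <- data.frame(shear_rate = sr, temperature = Tk,
                    viscosity = melt_viscosity(tr, sr, Tk))
  fit <- fit_carreau_arrhenius(pts, T_ref = 473)
  expect_equal(fit$eta0, tr$eta0, tolerance = 1e-6)
  expect_equal(fit$gammadot_c, tr$gammadot_c, tolerance = 1e-6)
  expect_equal(fit$c, tr$c, tolerance = 1e-6)
  expect_equal(fit$Ea, tr$Ea, tolerance = 1e-6)
})

test_that("refitting under multiplicative noise recovers eta0 within the calibrated band", {
  # 2% log-normal noise, 50 points: repeated-seed simulation gave an
  # empirical sd of ~0.84 Pa s for eta0; the band is ~4 sigma.
  tr <- ref_mats$pvpva$rheology
  set.seed(11)
  sr <- 10^runif(50, 0, 3.5)
  Tk <- sample(c(433, 453, 473, 493), 50, replace = TRUE)
  eta <- melt_viscosity(tr, sr, Tk) * exp(rnorm(50, 0, 0.02))
  fit <- fit_carreau_arrhenius(
    data.frame(shear_rate = sr, temperature = Tk, viscosity = eta), 473)
  expect_lt(abs(fit$eta0 - tr$eta0), 4)
})

test_that("degenerate refit designs are rejected", {
  tr <- ref_mats$pvpva$rheology
  sr <- c(1, 10, 100, 1000)
  one_T <- data.frame(shear_rate = sr, temperature = 473,
                      viscosity = melt_viscosity(tr, sr, 473))
  expect_error(fit_carreau_arrhenius(one_T, 473), "single temperature")
  expect_error(fit_carreau_arrhenius(one_T[1:3, ], 473), "at least 4")
})

test_that("parameter-set invariants are enforced at construction", {
  expect_error(carreau_arrhenius(-1, 100, 0.4, 1e5, 473), "eta0")
  expect_error(carreau_arrhenius(100, 100, 1.2, 1e5, 473), "c must")
  expect_error(carreau_arrhenius(100, 100, 0.4, -5, 473), "Ea")
})
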