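# Small, fast inverse-fitting checks; the full 20-start recovery protocols
# live in test-acceptance.R.

make_data_with_residuals <- function(params, stretches1, res1, stretches2,
                                     res2) {
  # data = model - residual, so that fit_residuals(params, data) = residual
  c1 <- stress_curve(params, stretches1, 1)
  c2 <- stress_curve(params, stretches2, 2)
  c1$stresses <- c1$stresses - res1
  c2$stresses <- c2$stresses - res2
  experiment_data(c1, c2)
}

test_that("objective is the plain sum of squared stress residuals", {
  p <- skin_preset("F")$params
  # hand-set residuals: 0.01 + 0.04 + 0.09 = 0.14 by construction
  dat <- make_data_with_residuals(p, c(1.1, 1.2, 1.3), c(0.1, -0.2, 0),
                                  c(1.1, 1.2, 1.3), c(0.3, 0, 0))
  expect_equal(fit_objective(p, dat), 0.14, tolerance = 1e-12)
  # perfect data: objective at floating round-off
  perfect <- simulate_experiment(p, noise = noise_spec("none"))
  expect_lt(fit_objective(p, perfect), 1e-18)
})

test_that("objective agrees with an independently coded double loop", {
  p <- skin_preset("F")$params
  dat <- simulate_experiment(skin_preset("G")$params,
                             noise = noise_spec(amplitude = 0.05, seed = 7))
  expect_equal(fit_objective(p, dat), objective_by_loops(p, dat),
               tolerance = 1e-12)
})

test_that("epsilon is the mean-stress-normalized rms residual in percent", {
  p <- skin_preset("F")$params
  perfect <- simulate_experiment(p, noise = noise_spec("none"))
  expect_equal(fit_epsilon(p, perfect), 0, tolerance = 1e-7)

  # uniform residuals of 0.1 MPa with the data rescaled so the grand mean
  # stress is exactly 1 MPa -> epsilon = 10 percent by arithmetic
  dat <- make_data_with_residuals(p, c(1.1, 1.2, 1.3), rep(0, 3),
                                  c(1.1, 1.2, 1.3), rep(0, 3))
  sig <- c(dat$curve1$stresses, dat$curve2$stresses)
  dat$curve1$stresses <- dat$curve1$stresses / mean(sig) - 0.1
  dat$curve2$stresses <- dat$curve2$stresses / mean(sig) - 0.1
  p_scaled <- skin_params(mu = p$mu / mean(sig), k1 = p$k1 / mean(sig),
                          k2 = p$k2, beta = p$beta, kappa = p$kappa,
                          m = p$m, zeta = p$zeta, n = p$n, xi = p$xi)
  sig2 <- c(dat$curve1$stresses, dat$curve2$stresses)
  expect_equal(fit_epsilon(p_scaled, dat),
               100 * sqrt(6 * 0.01 / 6) / mean(sig2), tolerance = 1e-10)
})

test_that("epsilon is invariant under a joint stress rescaling", {
  p <- skin_preset("G")$params
  dat <- simulate_experiment(p, noise = noise_spec(amplitude = 0.03,
                                                   seed = 5))
  c_ <- 7.3
  dat2 <- dat
  dat2$curve1$stresses <- dat$curve1$stresses * c_
  dat2$curve2$stresses <- dat$curve2$stresses * c_
  # stress is linear in mu and k1, so scaling both scales the model stress
  p2 <- skin_params(mu = p$mu * c_, k1 = p$k1 * c_, k2 = p$k2,
                    beta = p$beta, kappa = p$kappa, m = p$m, zeta = p$zeta,
                    n = p$n, xi = p$xi)
  expect_equal(fit_epsilon(p, dat), fit_epsilon(p2, dat2),
               tolerance = 1e-10)
})

test_that("epsilon decreases with the noise amplitude on matched seeds", {
  p <- skin_preset("G")$params
  eps <- vapply(c(0.05, 0.02, 0), function(a) {
    noise <- if (a > 0) noise_spec(amplitude = a, seed = 31)
             else noise_spec("none")
    fit_epsilon(p, simulate_experiment(p, noise = noise))
  }, numeric(1))
  expect_true(all(diff(eps) <= 1e-10))
})

test_that("normalization maps bounds to the unit box and round-trips", {
  b <- default_bounds()
  expect_equal(unname(normalize_params(b$lower, b)), rep(0, 9))
  expect_equal(unname(normalize_params(b$upper, b)), rep(1, 9))
  set.seed(17)
  for (rep in 1:20) {
    x <- runif(9)
    names(x) <- names(b$lower)
    v <- denormalize_params(x, b)
    expect_equal(normalize_params(v, b), x, tolerance = 1e-12)
  }
  bad <- b$upper * 1.5
  expect_error(normalize_params(bad, b), "outside bounds")
})

test_that("fit configuration validates pinned values and bounds", {
  expect_error(fit_config(fixed = list(zzz = 1)), "unknown fixed")
  expect_error(fit_config(fixed = list(kappa = 0.9)), "outside bounds")
  expect_error(fit_config(n_starts = 0), "n_starts")
  cfg <- fit_config(kappa_window = TRUE)
  expect_equal(unname(cfg$bounds$lower["kappa"]), 0.1009)
  expect_equal(unname(cfg$bounds$upper["kappa"]), 0.1675)
})

test_that("fits are deterministic given the seed and recover pinned-down truth", {
  truth <- skin_preset("D")$params
  dat <- simulate_experiment(truth, noise = noise_spec("none"))
  pins <- as.list(param_vector(truth)[c("mu", "k1", "beta", "kappa", "m",
                                        "zeta", "n")])
  cfg <- fit_config(fixed = pins, n_starts = 3, refine_hops = 3, seed = 11)
  f1 <- suppressWarnings(fit_uniaxial(dat, cfg))
  f2 <- suppressWarnings(fit_uniaxial(dat, cfg))
  expect_identical(f1$objective, f2$objective)
  expect_identical(param_vector(f1$params), param_vector(f2$params))
  # two free parameters, noiseless data: k2 and xi come back
  expect_equal(f1$params$k2, truth$k2, tolerance = 1e-4)
  expect_equal(f1$params$xi, truth$xi, tolerance = 1e-4)
  expect_lt(f1$objective, 1e-10)
})

test_that("an active bound triggers extension and the fit escapes the box", {
  truth <- skin_preset("D")$params   # k1 = 15.25 MPa
  dat <- simulate_experiment(truth, noise = noise_spec("none"))
  b <- default_bounds()
  b$upper["k1"] <- 10                # deliberately below the truth
  pins <- as.list(param_vector(truth)[c("mu", "k2", "beta", "kappa", "m",
                                        "zeta", "n", "xi")])
  cfg <- fit_config(bounds = b, fixed = pins, n_starts = 3,
                    refine_hops = 3, seed = 4)
  fit <- suppressWarnings(fit_uniaxial(dat, cfg))
  expect_gte(fit$extensions, 1)
  expect_equal(fit$params$k1, truth$k1, tolerance = 1e-3)
})
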