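test_that("presets match the checked-in published table digit for digit", {
  fx <- read.csv(system.file("extdata", "published_cases.csv",
                             package = "skindamage"),
                 stringsAsFactors = FALSE)
  expect_identical(fx$case, LETTERS[1:11])
  for (i in seq_len(nrow(fx))) {
    ps <- skin_preset(fx$case[i])
    v <- param_vector(ps$params)
    for (nm in c("mu", "k1", "k2", "beta", "kappa")) {
      expect_equal(unname(v[nm]), fx[[nm]][i], tolerance = 1e-12,
                   label = sprintf("case %s %s", fx$case[i], nm))
    }
    if (!ps$params$no_damage) {
      for (nm in c("m", "zeta", "n", "xi")) {
        expect_equal(unname(v[nm]), fx[[nm]][i], tolerance = 1e-12,
                     label = sprintf("case %s %s", fx$case[i], nm))
      }
    } else {
      expect_true(all(is.na(fx[c("m", "zeta", "n", "xi")][i, ])))
    }
    expect_equal(ps$fitted_epsilon, fx$epsilon_percent[i])
    expect_equal(ps$strain_rate, fx$strain_rate[i])
    expect_identical(ps$break_reported, fx$break_reported[i])
  }
})

test_that("preset lookup is case-insensitive and rejects unknown ids", {
  expect_equal(skin_preset("d")$params$beta, 41.00)
  expect_equal(skin_preset("D")$params$kappa, 0.1404)
  expect_equal(skin_preset("F")$params$xi, 1.06)
  expect_true(skin_preset("A")$params$no_damage)
  expect_error(skin_preset("Z"), "unknown preset")
  expect_equal(nrow(preset_table()), 11)
})

test_that("noiseless simulation reproduces the forward curves bit for bit", {
  p <- skin_preset("F")$params
  grid <- seq(1, 1.55, length.out = 40)
  dat <- simulate_experiment(p, grid, grid, noise_spec("none"))
  expect_identical(dat$curve1$stresses, stress_curve(p, grid, 1)$stresses)
  expect_identical(dat$curve2$stresses, stress_curve(p, grid, 2)$stresses)
})

test_that("simulation is deterministic given the seed", {
  p <- skin_preset("F")$params
  d1 <- simulate_experiment(p, noise = noise_spec(amplitude = 0.02,
                                                  seed = 42))
  d2 <- simulate_experiment(p, noise = noise_spec(amplitude = 0.02,
                                                  seed = 42))
  expect_identical(d1$curve1$stresses, d2$curve1$stresses)
  expect_identical(d1$curve2$stresses, d2$curve2$stresses)
  d3 <- simulate_experiment(p, noise = noise_spec(amplitude = 0.02,
                                                  seed = 43))
  expect_false(identical(d1$curve1$stresses, d3$curve1$stresses))
})

test_that("multiplicative noise has the configured relative spread", {
  p <- skin_preset("F")$params
  grid <- seq(1.2, 1.5, length.out = 5000)
  dat <- simulate_experiment(p, grid, grid,
                             noise_spec(amplitude = 0.02, seed = 8))
  clean <- stress_curve(p, grid, 1)$stresses
  relres <- dat$curve1$stresses / clean - 1
  expect_equal(sd(relres), 0.02, tolerance = 0.05)
})

test_that("experiment CSV round-trips and rejects malformed files", {
  p <- skin_preset("F")$params
  dat <- simulate_experiment(p, noise = noise_spec(amplitude = 0.02,
                                                   seed = 3))
  path <- tempfile(fileext = ".csv")
  write_experiment(dat, path)
  back <- read_experiment(path)
  expect_equal(back$curve1$stresses, dat$curve1$stresses,
               tolerance = 1e-11)
  expect_equal(back$curve2$stretches, dat$curve2$stretches,
               tolerance = 1e-11)

  # stretch below 1 is rejected with the offending row
  writeLines(c("specimen,stretch,stress_mpa",
               "1,0.9,0.1", "1,1.1,0.2", "1,1.2,0.3",
               "2,1.0,0.0", "2,1.1,0.1", "2,1.2,0.2"), path)
  expect_error(read_experiment(path), "stretch < 1 at data row 1")

  # a single specimen cannot feed the two-sum objective
  writeLines(c("specimen,stretch,stress_mpa",
               "1,1.0,0.0", "1,1.1,0.2", "1,1.2,0.3"), path)
  expect_error(read_experiment(path), "two specimens required")

  # duplicated (specimen, stretch) pair
  writeLines(c("specimen,stretch,stress_mpa",
               "1,1.0,0.0", "1,1.0,0.1", "1,1.2,0.3",
               "2,1.0,0.0", "2,1.1,0.1", "2,1.2,0.2"), path)
  expect_error(read_experiment(path), "duplicate")

  # missing column
  writeLines(c("specimen,stretch", "1,1.0"), path)
  expect_error(read_experiment(path), "must have columns")

  # non-numeric cell
  writeLines(c("specimen,stretch,stress_mpa",
               "1,1.0,abc", "1,1.1,0.2", "1,1.2,0.3",
               "2,1.0,0.0", "2,1.1,0.1", "2,1.2,0.2"), path)
  expect_error(read_experiment(path), "non-numeric")
})

test_that("parameter and fit-config JSON round-trip", {
  p <- skin_preset("G")$params
  path <- tempfile(fileext = ".json")
  write_params(p, path)
  back <- read_params(path)
  expect_equal(param_vector(back), param_vector(p), tolerance = 1e-12)

  goh <- skin_preset("A")$params
  write_params(goh, path)
  expect_true(read_params(path)$no_damage)

  jsonlite::write_json(list(fixed = list(kappa = 0.1404), n_starts = 7,
                            seed = 3, kappa_window = TRUE,
                            bounds = list(upper = list(k1 = 500))),
                       path, auto_unbox = TRUE)
  cfg <- read_fit_config(path)
  expect_equal(unname(cfg$fixed["kappa"]), 0.1404)
  expect_equal(cfg$n_starts, 7L)
  expect_true(cfg$kappa_window)
  expect_equal(unname(cfg$bounds$upper["k1"]), 500)
  expect_equal(unname(cfg$bounds$lower["kappa"]), 0.1009)
})

test_that("noise specification validates its inputs", {
  expect_error(noise_spec(amplitude = -0.1), ">= 0")
  expect_error(noise_spec("bogus"), "arg")
  expect_identical(noise_spec("none")$model, "none")
})
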