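# Shared test oracles, all independent of the package's analytic code
# paths: central finite differences of the energy for gradients and
# stresses, and a plainly-coded objective.

# Central finite difference (five-point stencil, fourth-order accurate)
# of strain_energy with respect to one parameter. beta is perturbed in
# radians to match the gradient's units. The high-order stencil keeps the
# truncation error of the steep exponential terms well below the 1e-5
# comparison tolerance.
fd_energy_gradient <- function(params, lambda1, specimen, h = 1e-4) {
  v <- param_vector(params)
  w_at <- function(vec) {
    p <- do.call(skin_params, as.list(vec))
    strain_energy(p, kinematics(lambda1, p$beta, specimen))
  }
  vapply(names(v), function(nm) {
    # beta: O(1) step in radians (its derivative is reported per radian);
    # other parameters: relative step
    hi <- if (nm == "beta") h else h * max(1, abs(v[nm]))
    step <- if (nm == "beta") hi * 180 / pi else hi
    shift <- function(k) { u <- v; u[nm] <- v[nm] + k * step; w_at(u) }
    (-shift(2) + 8 * shift(1) - 8 * shift(-1) + shift(-2)) / (12 * hi)
  }, numeric(1))
}

# Central finite difference of W(lambda1) after the uniaxial substitution;
# lambda1 * this is the Cauchy stress.
fd_stress <- function(params, lambda1, specimen, h = 1e-6) {
  wp <- strain_energy(params, kinematics(lambda1 + h, params$beta, specimen))
  wm <- strain_energy(params, kinematics(lambda1 - h, params$beta, specimen))
  lambda1 * (wp - wm) / (2 * h)
}

# Independently coded least-squares objective (plain loops).
objective_by_loops <- function(params, data) {
  tot <- 0
  for (i in seq_along(data$curve1$stretches)) {
    s <- cauchy_stress(params, data$curve1$stretches[i], 1)
    tot <- tot + (s - data$curve1$stresses[i])^2
  }
  for (i in seq_along(data$curve2$stretches)) {
    s <- cauchy_stress(params, data$curve2$stretches[i], 2)
    tot <- tot + (s - data$curve2$stresses[i])^2
  }
  tot
}

# Random admissible parameter set / stretch for property tests. States
# are redrawn until the fibre strain measure A is clearly positive: at
# the tension switch A = 0 the energy is only C1, so finite-difference
# stencils that straddle it do not measure the one-sided derivative the
# analytic gradient reports.
random_admissible <- function() {
  repeat {
    params <- skin_params(
      mu = runif(1, 0.01, 1), k1 = runif(1, 0.5, 50),
      k2 = runif(1, 0.1, 50), beta = runif(1, 5, 85),
      kappa = runif(1, 0.01, 0.33), m = runif(1, 0.8, 5),
      zeta = runif(1, 3.05, 4), n = runif(1, 1, 10),
      xi = runif(1, 1.03, 1.4))
    lambda1 <- runif(1, 1.02, 1.5)
    specimen <- sample(1:2, 1)
    st <- kinematics(lambda1, params$beta, specimen)
    A <- fibre_stretch(st$I1, st$I4, params$kappa)$A
    if (A > 0.05) {
      return(list(params = params, lambda1 = lambda1,
                  specimen = specimen))
    }
  }
}
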