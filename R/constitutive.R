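# Constitutive layer: kinematics of incompressible uniaxial extension,
# fibre-stretch measure, and the strain-energy functions (damage model and
# its GOH limit) at a single material point.

# Largest exponent passed to exp(); beyond this the energy is treated as
# numerically meaningless and an error is raised instead of returning Inf.
.EXP_CAP <- 700

.safe_exp <- function(x) {
  if (any(x > .EXP_CAP)) {
    stop("non-finite energy: exp argument ", format(max(x)),
         " exceeds overflow guard (", .EXP_CAP, ")", call. = FALSE)
  }
  exp(x)
}

# Guarded exponential for use inside the inverse fit only: monotone and
# finite everywhere, identical to exp() below the cap, linear growth of the
# log beyond it. Trial parameter sets deep in the overflow region then
# produce huge but finite residuals whose gradient still points back
# toward the feasible region.
.guarded_exp <- function(x, cap = 50) {
  exp(pmin(x, cap)) * (1 + pmax(x - cap, 0))
}

#' Uniaxial kinematics for a skin specimen
#'
#' Computes stretches and invariants for incompressible uniaxial extension
#' of one of the two orthogonal skin specimens. Specimen 1 is cut along the
#' reference direction (spine or Langer's lines), so the mean fibre angle
#' to the loading axis is \eqn{\beta}; specimen 2 is cut perpendicular to
#' it, so the fibre angle to its loading axis is \eqn{90^\circ - \beta}.
#' Incompressibility with equal lateral stretches gives
#' \eqn{\lambda_t = \lambda_h = \lambda_1^{-1/2}},
#' \eqn{I_1 = \lambda_1^2 + 2/\lambda_1}, and
#' \eqn{I_4 = \lambda_1^2\cos^2\beta + \lambda_t^2\sin^2\beta}
#' for specimen 1 (sine and cosine swapped for specimen 2).
#'
#' @param lambda1 Axial stretch (scalar, > 0).
#' @param beta_deg Mean fibre angle in degrees, in \[0, 90\].
#' @param specimen 1 (along the reference direction) or 2 (across it).
#' @return A list of class `kinematic_state` with elements `lambda1`,
#'   `lambda_t`, `lambda_h`, `I1`, `I4` and `specimen`.
#' @examples
#' kinematics(1.5, beta_deg = 0, specimen = 1)$I4   # 2.25
#' kinematics(1.5, beta_deg = 0, specimen = 2)$I4   # 1/1.5
#' @export
kinematics <- function(lambda1, beta_deg, specimen) {
  if (!is.numeric(lambda1) || any(lambda1 <= 0))
    stop("lambda1 must be positive", call. = FALSE)
  if (beta_deg < 0 || beta_deg > 90)
    stop("beta_deg must lie in [0, 90]", call. = FALSE)
  specimen <- .check_specimen(specimen)
  b <- beta_deg * pi / 180
  # fibre angle to the loading axis: beta for specimen 1, 90 - beta for 2
  ang <- if (specimen == 1L) b else pi / 2 - b
  lt <- lambda1^(-1 / 2)
  state <- list(lambda1 = lambda1, lambda_t = lt, lambda_h = lt,
                I1 = lambda1^2 + 2 / lambda1,
                I4 = lambda1^2 * cos(ang)^2 + lt^2 * sin(ang)^2,
                specimen = specimen)
  class(state) <- "kinematic_state"
  state
}

.check_specimen <- function(specimen) {
  if (!specimen %in% c(1, 2))
    stop("specimen must be 1 or 2", call. = FALSE)
  as.integer(specimen)
}

#' Dispersion-weighted fibre stretch
#'
#' \eqn{\lambda_f = \sqrt{\kappa I_1 + (1 - 3\kappa) I_4}} averages the
#' squared tissue stretch \eqn{I_1} and the squared stretch along the mean
#' fibre direction \eqn{I_4} according to the fibre orientation dispersion
#' \eqn{\kappa}. The fibre strain measure \eqn{A = \lambda_f^2 - 1} drives
#' both the fibre energy and the fibre damage limiter.
#'
#' @param I1 First invariant (vectorized).
#' @param I4 Squared stretch along the mean fibre direction (vectorized).
#' @param kappa Fibre dispersion in \[0, 1/3\].
#' @return A list with `lambda_f` and `A` (both vectors matching the input).
#' @examples
#' fibre_stretch(3.5833, 2.25, 0.1404)$lambda_f
#' fibre_stretch(3.6, 1.2, 0)$lambda_f^2      # == I4 when kappa = 0
#' @export
fibre_stretch <- function(I1, I4, kappa) {
  if (kappa < 0 || kappa > 1 / 3)
    stop("kappa must lie in [0, 1/3]", call. = FALSE)
  if (any(I4 <= 0)) stop("I4 must be positive", call. = FALSE)
  rad <- kappa * I1 + (1 - 3 * kappa) * I4
  if (any(rad < 0))
    stop("negative radicand in fibre stretch: inadmissible state",
         call. = FALSE)
  lf <- sqrt(rad)
  list(lambda_f = lf, A = lf^2 - 1)
}

# Internal vectorized energy kernel. Takes raw invariants; the fibre term is
# tension-only (zero for A <= 0) since A is raised to non-integer powers.
.energy <- function(p, I1, I4, goh = FALSE) {
  e1 <- I1 - 3
  if (any(e1 < -1e-9)) stop("I1 < 3: inadmissible state", call. = FALSE)
  e1 <- pmax(e1, 0)
  A <- fibre_stretch(I1, I4, p$kappa)$A
  tens <- A > 0
  Af <- ifelse(tens, A, 0)

  if (goh || p$no_damage) {
    Wm <- p$mu / 2 * e1
    Wf <- p$k1 / p$k2 * (.safe_exp(p$k2 * Af^2) - 1)
  } else {
    Wm <- p$mu / 2 * (e1 - e1^(p$m + 1) / ((p$m + 1) * (p$zeta - 3)^p$m))
    Wf <- p$k1 / p$k2 * (.safe_exp(p$k2 * Af^2) - 1 -
      2 * p$k2 * Af^(p$n + 2) / ((p$n + 2) * (p$xi^2 - 1)^p$n))
  }
  Wf[!tens] <- 0
  Wm + Wf
}

#' Strain-energy density of the damage model
#'
#' Evaluates the nine-parameter damage strain energy at a material point.
#' The matrix term is the neo-Hookean energy reduced by a power-law limiter
#' that caps it as \eqn{I_1} approaches the matrix damage onset \eqn{\zeta};
#' the fibre term is the GOH exponential reduced by the corresponding fibre
#' limiter as \eqn{\lambda_f} approaches \eqn{\xi}. Fibres carry energy in
#' tension only: the fibre term vanishes for \eqn{A \le 0}. With
#' `no_damage` parameters the result equals [strain_energy_goh()].
#'
#' @param params A [skin_params] object.
#' @param state A `kinematic_state` from [kinematics()].
#' @return Energy density in MPa.
#' @examples
#' p <- skin_preset("F")$params
#' strain_energy(p, kinematics(1.1, p$beta, 1))
#' @export
strain_energy <- function(params, state) {
  validate_skin_params(params)
  .energy(params, state$I1, state$I4)
}

#' Strain-energy density of the GOH limit
#'
#' The Gasser--Ogden--Holzapfel energy
#' \eqn{W = \frac{\mu}{2}(I_1-3) + \frac{k_1}{k_2}\{e^{k_2 A^2} - 1\}},
#' i.e. the damage model with both limiters removed. The damage parameters
#' in `params` are ignored.
#'
#' @inheritParams strain_energy
#' @return Energy density in MPa.
#' @export
strain_energy_goh <- function(params, state) {
  validate_skin_params(params)
  .energy(params, state$I1, state$I4, goh = TRUE)
}
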