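# Forward uniaxial mechanics: Cauchy stress, stress curves, stress-peak
# (fibre break limit) detection and brittle/ductile classification.

# dW/dA of the fibre term (tension-only); shared by stress and sensitivities.
# With guard = TRUE the exponential and the limiter power are evaluated
# through the capped exponential (powers in log space), so arbitrarily bad
# trial parameters still yield finite values with a usable gradient.
.dWf_dA <- function(p, A, goh = FALSE, guard = FALSE) {
  tens <- A > 0
  Af <- ifelse(tens, A, 0)
  out <- if (goh || p$no_damage) {
    2 * p$k1 * Af * (if (guard) .guarded_exp else .safe_exp)(p$k2 * Af^2)
  } else if (guard) {
    lim <- ifelse(tens,
                  .guarded_exp((p$n + 1) * log(pmax(Af, 1e-300)) -
                               p$n * log(p$xi^2 - 1)), 0)
    2 * p$k1 * Af * .guarded_exp(p$k2 * Af^2) - 2 * p$k1 * lim
  } else {
    2 * p$k1 * Af * .safe_exp(p$k2 * Af^2) -
      2 * p$k1 * Af^(p$n + 1) / (p$xi^2 - 1)^p$n
  }
  out[!tens] <- 0
  out
}

# dW/dI1 of the matrix term.
.dWm_dI1 <- function(p, I1, goh = FALSE, guard = FALSE) {
  if (goh || p$no_damage) return(rep(p$mu / 2, length(I1)))
  e1 <- pmax(I1 - 3, 0)
  if (guard) {
    pw <- .guarded_exp(p$m * (log(pmax(e1, 1e-300)) - log(p$zeta - 3)))
    pw[e1 == 0] <- 0
    return(p$mu / 2 * (1 - pw))
  }
  p$mu / 2 * (1 - (e1 / (p$zeta - 3))^p$m)
}

#' Uniaxial Cauchy stress
#'
#' Axial Cauchy stress \eqn{\sigma_1 = \lambda_1\, dW/d\lambda_1} of an
#' incompressible uniaxial extension, with the lateral stretches eliminated
#' through \eqn{\lambda_t = \lambda_h = \lambda_1^{-1/2}}. Expanding via the
#' invariants,
#' \eqn{\sigma_1 = \lambda_1(\partial W/\partial I_1\, dI_1/d\lambda_1 +
#' \partial W/\partial I_4\, dI_4/d\lambda_1)} with
#' \eqn{dI_1/d\lambda_1 = 2\lambda_1 - 2\lambda_1^{-2}} and, for specimen 1,
#' \eqn{dI_4/d\lambda_1 = 2\lambda_1\cos^2\beta - \lambda_1^{-2}\sin^2\beta}
#' (sine and cosine swapped for specimen 2).
#'
#' @param params A [skin_params] object.
#' @param lambda1 Axial stretch(es), each >= 1 (extension only).
#' @param specimen 1 or 2.
#' @param goh If `TRUE`, use the GOH energy regardless of the damage
#'   parameters.
#' @return Cauchy stress in MPa, one value per element of `lambda1`.
#' @examples
#' p <- skin_preset("G")$params
#' cauchy_stress(p, c(1, 1.1, 1.3), specimen = 1)
#' @export
cauchy_stress <- function(params, lambda1, specimen, goh = FALSE) {
  validate_skin_params(params)
  out <- .stress_impl(params, lambda1, specimen, goh = goh)
  if (any(!is.finite(out)))
    stop("non-finite stress at lambda1 = ",
         format(lambda1[which(!is.finite(out))[1L]]), call. = FALSE)
  out
}

# Stress kernel; guard = TRUE is used inside the inverse fit so that
# infeasible trial parameter sets yield finite, monotone residuals.
.stress_impl <- function(params, lambda1, specimen, goh = FALSE,
                         guard = FALSE) {
  specimen <- .check_specimen(specimen)
  if (any(lambda1 < 1))
    stop("lambda1 < 1: compression is outside the supported regime",
         call. = FALSE)
  b <- params$beta * pi / 180
  ang <- if (specimen == 1L) b else pi / 2 - b
  I1 <- lambda1^2 + 2 / lambda1
  I4 <- lambda1^2 * cos(ang)^2 + sin(ang)^2 / lambda1
  A <- fibre_stretch(I1, I4, params$kappa)$A

  dI1 <- 2 * lambda1 - 2 / lambda1^2
  dI4 <- 2 * lambda1 * cos(ang)^2 - sin(ang)^2 / lambda1^2
  dWdA <- .dWf_dA(params, A, goh = goh, guard = guard)
  dWdI1 <- .dWm_dI1(params, I1, goh = goh, guard = guard) +
    dWdA * params$kappa
  dWdI4 <- dWdA * (1 - 3 * params$kappa)
  lambda1 * (dWdI1 * dI1 + dWdI4 * dI4)
}

#' Stress curve on a stretch grid
#'
#' Vectorized forward prediction: Cauchy stress at every point of a strictly
#' increasing stretch grid, packaged as a `specimen_curve`.
#'
#' @inheritParams cauchy_stress
#' @param grid Strictly increasing stretches, minimum >= 1.
#' @return A `specimen_curve`: list with `specimen`, `stretches`, `stresses`.
#' @export
stress_curve <- function(params, grid, specimen) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  stresses <- cauchy_stress(params, grid, specimen)
  specimen_curve(specimen, grid, stresses)
}

#' Construct a specimen stress--stretch curve
#'
#' @param specimen 1 or 2.
#' @param stretches Strictly increasing stretches >= 1.
#' @param stresses Cauchy stresses in MPa, same length.
#' @return A `specimen_curve` object.
#' @export
specimen_curve <- function(specimen, stretches, stresses) {
  specimen <- .check_specimen(specimen)
  if (length(stretches) != length(stresses))
    stop("stretches and stresses must have equal length", call. = FALSE)
  if (any(stretches < 1))
    stop("stretches must be >= 1", call. = FALSE)
  if (is.unsorted(stretches, strictly = TRUE))
    stop("stretches must be strictly increasing", call. = FALSE)
  if (any(!is.finite(stresses)))
    stop("stresses must be finite", call. = FALSE)
  structure(list(specimen = specimen, stretches = stretches,
                 stresses = stresses),
            class = "specimen_curve")
}

#' @export
print.specimen_curve <- function(x, ...) {
  cat(sprintf("Specimen %d uniaxial curve: %d points, lambda1 in [%g, %g], peak stress %.4g MPa\n",
              x$specimen, length(x$stretches), min(x$stretches),
              max(x$stretches), max(x$stresses)))
  invisible(x)
}

#' Fibre break limit: stretch and fibre stretch at peak Cauchy stress
#'
#' Locates the first interior maximum of the Cauchy stress over
#' \eqn{\lambda_1 \in (1, \lambda_{max}]}. The fibre stretch
#' \eqn{\lambda_f^*} at that peak is the fibre break limit. The search uses
#' a dense bracketing grid followed by golden-section refinement; if the
#' stress is non-decreasing over the whole range (e.g. the GOH limit, whose
#' exponential stress grows without bound) the result is `NULL`.
#'
#' @inheritParams cauchy_stress
#' @param lambda_max Upper end of the search range (> 1); default 2.
#' @param n_grid Bracketing grid size; default 2000.
#' @return `NULL` if no interior peak exists, otherwise a list with
#'   `lambda1_star`, `lambda_f_star`, `sigma_star` (MPa), `sqrtI4_star`
#'   and `I1_star`.
#' @examples
#' break_limit(skin_preset("G")$params, specimen = 1)
#' break_limit(skin_preset("A")$params, specimen = 1)  # NULL: no damage
#' @export
break_limit <- function(params, specimen, lambda_max = 2, n_grid = 2000L) {
  validate_skin_params(params)
  specimen <- .check_specimen(specimen)
  if (lambda_max <= 1) stop("lambda_max must exceed 1", call. = FALSE)
  grid <- seq(1, lambda_max, length.out = n_grid + 1L)
  sig <- cauchy_stress(params, grid, specimen)
  # first interior local maximum strictly inside (1, lambda_max)
  i <- which(diff(sig) < 0)
  if (length(i) == 0L || i[1L] == 1L) return(NULL)
  k <- i[1L]   # sig[k] > sig[k + 1], sig rising up to k
  lo <- grid[k - 1L]; hi <- grid[k + 1L]
  opt <- stats::optimize(function(l) cauchy_stress(params, l, specimen),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  l1 <- opt$maximum
  st <- kinematics(l1, params$beta, specimen)
  fs <- fibre_stretch(st$I1, st$I4, params$kappa)
  list(lambda1_star = l1, lambda_f_star = fs$lambda_f,
       sigma_star = opt$objective, sqrtI4_star = sqrt(st$I4),
       I1_star = st$I1)
}

#' Brittle vs ductile damage classification
#'
#' Computes the fibre break limit for both specimens and compares them.
#' If both specimens show a stress peak at the same fibre stretch (within
#' `tolerance`, relative), the damage is fibre-dominated: a brittle break.
#' If both peak but at different fibre stretches, matrix damage also
#' contributes: a ductile break. If either specimen has no interior stress
#' peak on the searched range the verdict is `"none"`. The alternative
#' measures \eqn{\sqrt{I_4^*}} and \eqn{I_1^*} at the peaks are reported so
#' that their inequality across specimens can be checked: unlike
#' \eqn{\lambda_f^*}, they do not provide a specimen-independent breaking
#' criterion.
#'
#' @inheritParams break_limit
#' @param tolerance Relative tolerance on the equality of the two fibre
#'   break limits; default 0.01 (1 percent).
#' @return A `break_analysis` object: list with `specimen1`, `specimen2`
#'   (each as in [break_limit()], or `NULL`), `verdict`
#'   ("brittle", "ductile" or "none") and `tolerance_used`.
#' @examples
#' classify_damage(skin_preset("G")$params)$verdict   # "brittle"
#' classify_damage(skin_preset("H")$params)$verdict   # "ductile"
#' @export
classify_damage <- function(params, lambda_max = 2, tolerance = 0.01,
                            n_grid = 2000L) {
  b1 <- break_limit(params, 1, lambda_max, n_grid)
  b2 <- break_limit(params, 2, lambda_max, n_grid)
  verdict <- if (is.null(b1) || is.null(b2)) {
    "none"
  } else if (abs(b1$lambda_f_star - b2$lambda_f_star) / b1$lambda_f_star <=
             tolerance) {
    "brittle"
  } else {
    "ductile"
  }
  structure(list(specimen1 = b1, specimen2 = b2, verdict = verdict,
                 tolerance_used = tolerance, lambda_max = lambda_max),
            class = "break_analysis")
}

#' @export
print.break_analysis <- function(x, ...) {
  cat("Damage classification (lambda1 searched up to", x$lambda_max, ")\n")
  for (s in 1:2) {
    b <- x[[paste0("specimen", s)]]
    if (is.null(b)) {
      cat(sprintf("  specimen %d: no interior stress peak\n", s))
    } else {
      cat(sprintf(
        "  specimen %d: peak %.4g MPa at lambda1* = %.4f, lambda_f* = %.4f (sqrt(I4)* = %.4f, I1* = %.4f)\n",
        s, b$sigma_star, b$lambda1_star, b$lambda_f_star, b$sqrtI4_star,
        b$I1_star))
    }
  }
  cat(sprintf("  verdict: %s (tolerance %.2g relative on lambda_f*)\n",
              x$verdict, x$tolerance_used))
  invisible(x)
}
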