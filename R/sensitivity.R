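# Analytic parameter sensitivities of the strain energy, and the ranking /
# grouping of parameters by the magnitude of their partial derivatives.
#
# The derivatives below differentiate the implemented energy exactly and are
# validated against central finite differences in the test suite. Several
# published derivative expressions for this model family contain
# typographical slips (a sign on the k2 derivative, an off-by-one power of
# (xi^2 - 1) in the xi derivative, the exponents and log-term signs in the
# m and n derivatives, and a dI4/dbeta that omits the transverse-stretch
# contribution); see the package vignette for the full comparison. The
# finite-difference oracle, not any printed form, is the ground truth here.

# Vectorized gradient kernel: rows = stretches, columns = parameters in
# canonical order. beta derivative is per radian.
.gradient_matrix <- function(p, lambda1, specimen) {
  b <- p$beta * pi / 180
  ang <- if (specimen == 1L) b else pi / 2 - b
  I1 <- lambda1^2 + 2 / lambda1
  I4 <- lambda1^2 * cos(ang)^2 + sin(ang)^2 / lambda1
  e1 <- pmax(I1 - 3, 0)
  A <- fibre_stretch(I1, I4, p$kappa)$A
  tens <- A > 0
  Af <- ifelse(tens, A, 1)     # placeholder 1 avoids log(<=0); masked below
  Efib <- .safe_exp(p$k2 * ifelse(tens, A, 0)^2)

  g <- matrix(0, nrow = length(lambda1), ncol = 9,
              dimnames = list(NULL, PARAM_NAMES))

  if (p$no_damage) {
    g[, "mu"] <- e1 / 2
    g[tens, "k1"] <- (Efib[tens] - 1) / p$k2
    g[tens, "k2"] <- p$k1 / p$k2 *
      ((1 - Efib[tens]) / p$k2 + Af[tens]^2 * Efib[tens])
    dWdA <- .dWf_dA(p, A)
  } else {
    D <- p$zeta - 3
    X <- p$xi^2 - 1
    lim <- 2 * p$k2 * Af^(p$n + 2) / ((p$n + 2) * X^p$n)
    g[, "mu"] <- (e1 - e1^(p$m + 1) / ((p$m + 1) * D^p$m)) / 2
    g[tens, "k1"] <- (Efib[tens] - 1 - lim[tens]) / p$k2
    g[tens, "k2"] <- p$k1 / p$k2 *
      ((1 - Efib[tens]) / p$k2 + Af[tens]^2 * Efib[tens])
    g[tens, "xi"] <- 4 * p$k1 * p$n * Af[tens]^(p$n + 2) * p$xi /
      ((p$n + 2) * X^(p$n + 1))
    g[, "zeta"] <- p$mu * p$m / (2 * (p$m + 1)) * e1^(p$m + 1) / D^(p$m + 1)
    g[, "m"] <- -p$mu / 2 * e1^(p$m + 1) / ((p$m + 1) * D^p$m) *
      (log(pmax(e1, .Machine$double.xmin)) - log(D) - 1 / (p$m + 1))
    g[e1 == 0, "m"] <- 0     # e1^(m+1) * log(e1) -> 0 as e1 -> 0+
    g[tens, "n"] <- -2 * p$k1 * Af[tens]^(p$n + 2) / ((p$n + 2) * X^p$n) *
      (log(Af[tens]) - log(X) - 1 / (p$n + 2))
    dWdA <- .dWf_dA(p, A)
  }
  # kappa and beta act through A only: dW/dA * dA/d(.)
  g[, "kappa"] <- dWdA * (I1 - 3 * I4)
  dI4_db <- if (specimen == 1L) {
    (1 / lambda1 - lambda1^2) * sin(2 * b)
  } else {
    (lambda1^2 - 1 / lambda1) * sin(2 * b)
  }
  g[, "beta"] <- dWdA * (1 - 3 * p$kappa) * dI4_db
  g
}

#' Analytic gradient of the strain energy in the material parameters
#'
#' Partial derivatives of the damage strain energy with respect to each of
#' the nine parameters (mu, k1, k2, beta, kappa, m, zeta, n, xi), evaluated
#' at a uniaxial state. The parameters with the largest derivative
#' magnitudes are the ones the inverse fit can determine most reliably.
#' The beta derivative is reported per radian. The fibre-related components
#' are zero when the fibre strain measure A is non-positive; the m and n
#' derivatives contain logarithms of \eqn{I_1 - 3} and A, so the reference
#' state \eqn{\lambda_1 = 1} is a singular point and is rejected.
#'
#' @param params A [skin_params] object.
#' @param lambda1 Axial stretch, strictly > 1.
#' @param specimen 1 or 2.
#' @return Named numeric vector of the nine derivatives (energy units, MPa,
#'   per unit of each parameter).
#' @examples
#' p <- skin_preset("B")$params
#' energy_gradients(p, 1.3, specimen = 1)
#' @export
energy_gradients <- function(params, lambda1, specimen) {
  validate_skin_params(params)
  specimen <- .check_specimen(specimen)
  if (length(lambda1) != 1L || lambda1 <= 1)
    stop("lambda1 must be a single stretch strictly greater than 1 ",
         "(the m and n derivatives are singular at the reference state)",
         call. = FALSE)
  drop(.gradient_matrix(params, lambda1, specimen))
}

#' Sensitivity ranking and group partition of the parameters
#'
#' Evaluates all nine energy gradients over a stretch grid, summarises each
#' parameter by the maximum absolute derivative attained (the magnitudes
#' rise sharply near the damage turning point, so the maximum is the
#' discriminating statistic), ranks the parameters by decreasing summary,
#' and splits them into group I (most influential) and group II at the
#' largest gap in log10 magnitude. The partition is flagged valid only when
#' that gap is at least one decade.
#'
#' @param params A [skin_params] object.
#' @param grid Stretch grid, all values strictly > 1; default 200 points
#'   spanning (1, `lambda_max`].
#' @param specimen 1 or 2.
#' @param lambda_max Upper stretch used for the default grid; default 1.6,
#'   matching the default synthetic uniaxial protocol.
#' @return A `sensitivity_profile` object: list with `specimen`, `grid`,
#'   `magnitudes` (grid x 9 matrix of absolute derivatives), `summary`
#'   (named per-parameter maxima), `ranking` (parameter names, decreasing),
#'   `group1`, `group2`, `gap_decades` and `valid_partition`.
#' @examples
#' rank_parameters(skin_preset("B")$params, specimen = 1)$ranking[1:4]
#' @export
rank_parameters <- function(params, grid = NULL, specimen = 1,
                            lambda_max = 1.6) {
  validate_skin_params(params)
  specimen <- .check_specimen(specimen)
  if (is.null(grid)) {
    grid <- seq(1, lambda_max, length.out = 201L)[-1L]
  }
  if (any(grid <= 1))
    stop("grid must lie strictly above lambda1 = 1 (singular point)",
         call. = FALSE)
  mag <- abs(.gradient_matrix(params, grid, specimen))
  summ <- apply(mag, 2, max)
  ord <- order(summ, decreasing = TRUE)
  ranking <- PARAM_NAMES[ord]
  s <- summ[ord]
  # split at the largest log10 gap between consecutive ranked summaries
  logs <- log10(pmax(s, .Machine$double.xmin))
  gaps <- -diff(logs)
  split_at <- which.max(gaps)
  gap <- gaps[split_at]
  structure(list(specimen = specimen, grid = grid, magnitudes = mag,
                 summary = summ, ranking = ranking,
                 group1 = ranking[seq_len(split_at)],
                 group2 = ranking[-seq_len(split_at)],
                 gap_decades = gap, valid_partition = gap >= 1),
            class = "sensitivity_profile")
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  cat(sprintf("Sensitivity profile, specimen %d, lambda1 in (%g, %g], %d grid points\n",
              x$specimen, min(x$grid), max(x$grid), length(x$grid)))
  s <- x$summary[x$ranking]
  for (i in seq_along(s)) {
    grp <- if (x$ranking[i] %in% x$group1) "I " else "II"
    cat(sprintf("  %2d. %-5s group %s  max|dW/dp| = %.4g MPa\n",
                i, x$ranking[i], grp, s[i]))
  }
  cat(sprintf("  group gap: %.2f decades (%s partition)\n", x$gap_decades,
              if (x$valid_partition) "valid" else "weak"))
  invisible(x)
}
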