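#' Material parameters of the skin damage model
#'
#' Constructs and validates the nine constitutive constants of the
#' anisotropic damage model for skin. The strain energy is an extended
#' Gasser--Ogden--Holzapfel (GOH) function in which both the ground-substance
#' matrix term and the collagen-fibre term carry Volokh-type energy-limiter
#' corrections responsible for damage-induced softening:
#' \deqn{W = \frac{\mu}{2}\left[(I_1-3) -
#'       \frac{(I_1-3)^{m+1}}{(m+1)(\zeta-3)^m}\right] +
#'       \frac{k_1}{k_2}\left\{e^{k_2 A^2} - 1 -
#'       \frac{2 k_2 A^{n+2}}{(n+2)(\xi^2-1)^n}\right\}}
#' with \eqn{A = \lambda_f^2 - 1} and fibre stretch
#' \eqn{\lambda_f = \sqrt{\kappa I_1 + (1-3\kappa) I_4}}.
#'
#' @param mu Matrix (ground substance) stiffness, MPa. Must be positive.
#' @param k1 Fibre stiffness, MPa. Must be positive.
#' @param k2 Dimensionless fibre exponent. Must be positive.
#' @param beta Mean collagen fibre angle measured from the reference
#'   direction (spine or Langer's lines), in degrees, in \[0, 90\].
#' @param kappa Fibre orientation dispersion, in \[0, 1/3\]; 0 means
#'   perfectly aligned fibres, 1/3 an isotropic fibre distribution.
#' @param m Matrix-damage sharpness exponent (dimensionless, positive).
#' @param zeta Matrix-damage onset expressed as a value of the first
#'   invariant \eqn{I_1}; must exceed 3.
#' @param n Fibre-damage sharpness exponent (dimensionless, positive).
#' @param xi Fibre-damage onset expressed as a fibre stretch
#'   \eqn{\lambda_f}; must exceed 1.
#' @param no_damage Logical; if `TRUE` the limiter terms are dropped
#'   (conceptually \eqn{\xi = \zeta = \infty}, \eqn{m = n = 1}) and the
#'   model reduces exactly to the GOH law. `m`, `n`, `xi`, `zeta` may then
#'   be omitted.
#'
#' @return An object of class `skin_params`: a named list with the nine
#'   parameters and the `no_damage` flag.
#' @examples
#' p <- skin_params(mu = 0.147, k1 = 14.72, k2 = 22.91, beta = 41,
#'                  kappa = 0.1404, m = 3.30, zeta = 3.27,
#'                  n = 6.33, xi = 1.11)
#' p
#' goh <- skin_params(mu = 0.0015, k1 = 26.38, k2 = 3.58, beta = 41,
#'                    kappa = 0.1404, no_damage = TRUE)
#' @export
skin_params <- function(mu, k1, k2, beta, kappa,
                        m = NA_real_, zeta = NA_real_,
                        n = NA_real_, xi = NA_real_,
                        no_damage = FALSE) {
  if (isTRUE(no_damage)) {
    # GOH limit: limiter terms vanish; sharpness exponents are immaterial
    # but stored as 1 so derived quantities stay well defined.
    m <- 1; n <- 1; zeta <- Inf; xi <- Inf
  }
  p <- list(mu = as.numeric(mu), k1 = as.numeric(k1), k2 = as.numeric(k2),
            beta = as.numeric(beta), kappa = as.numeric(kappa),
            m = as.numeric(m), zeta = as.numeric(zeta),
            n = as.numeric(n), xi = as.numeric(xi),
            no_damage = isTRUE(no_damage))
  class(p) <- "skin_params"
  validate_skin_params(p)
  p
}

#' @rdname skin_params
#' @param x A `skin_params` object.
#' @export
validate_skin_params <- function(x) {
  stopifnot(inherits(x, "skin_params"))
  num <- unlist(x[c("mu", "k1", "k2", "beta", "kappa", "m", "zeta", "n", "xi")])
  if (anyNA(num)) {
    stop("skin_params: all nine parameters must be supplied and numeric ",
         "(missing: ", paste(names(num)[is.na(num)], collapse = ", "), ")",
         call. = FALSE)
  }
  with(x, {
    if (mu <= 0 || k1 <= 0 || k2 <= 0)
      stop("skin_params: mu, k1, k2 must be positive", call. = FALSE)
    if (kappa < 0 || kappa > 1 / 3)
      stop("skin_params: kappa must lie in [0, 1/3]", call. = FALSE)
    if (beta < 0 || beta > 90)
      stop("skin_params: beta must lie in [0, 90] degrees", call. = FALSE)
    if (!no_damage) {
      if (m <= 0 || n <= 0)
        stop("skin_params: m and n must be positive", call. = FALSE)
      if (!is.finite(zeta) || zeta <= 3)
        stop("skin_params: zeta must be finite and > 3", call. = FALSE)
      if (!is.finite(xi) || xi <= 1)
        stop("skin_params: xi must be finite and > 1", call. = FALSE)
    }
  })
  invisible(x)
}

#' @export
print.skin_params <- function(x, ...) {
  cat("Skin damage model parameters",
      if (x$no_damage) "(GOH limit, no damage)" else "", "\n")
  cat(sprintf("  mu    = %.6g MPa   (matrix stiffness)\n", x$mu))
  cat(sprintf("  k1    = %.6g MPa   (fibre stiffness)\n", x$k1))
  cat(sprintf("  k2    = %.6g       (fibre exponent)\n", x$k2))
  cat(sprintf("  beta  = %.6g deg   (mean fibre angle)\n", x$beta))
  cat(sprintf("  kappa = %.6g       (fibre dispersion)\n", x$kappa))
  if (!x$no_damage) {
    cat(sprintf("  m     = %.6g       (matrix damage sharpness)\n", x$m))
    cat(sprintf("  zeta  = %.6g       (matrix damage onset, I1)\n", x$zeta))
    cat(sprintf("  n     = %.6g       (fibre damage sharpness)\n", x$n))
    cat(sprintf("  xi    = %.6g       (fibre damage onset, lambda_f)\n", x$xi))
  }
  invisible(x)
}

# Canonical parameter order used throughout (fitting, sensitivities, I/O).
PARAM_NAMES <- c("mu", "k1", "k2", "beta", "kappa", "m", "zeta", "n", "xi")

#' Convert a skin_params object to a named numeric vector
#'
#' @param x A `skin_params` object.
#' @return Named numeric vector in the canonical order
#'   (mu, k1, k2, beta, kappa, m, zeta, n, xi).
#' @export
param_vector <- function(x) {
  stopifnot(inherits(x, "skin_params"))
  unlist(x[PARAM_NAMES])
}
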