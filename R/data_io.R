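# Synthetic experiment generation and file I/O (CSV curves, JSON
# parameters / fit configuration / fit results).

#' Noise specification for synthetic experiments
#'
#' @param model "multiplicative-gaussian" (stress scaled by `1 + a Z`,
#'   Z standard normal), "additive-gaussian" (`a` in MPa) or "none".
#' @param amplitude Noise amplitude `a` (relative for multiplicative,
#'   MPa for additive); >= 0. Default 0.02.
#' @param seed Integer seed used when the noise is drawn.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(model = c("multiplicative-gaussian",
                                 "additive-gaussian", "none"),
                       amplitude = 0.02, seed = 1L) {
  model <- match.arg(model)
  if (amplitude < 0) stop("noise amplitude must be >= 0", call. = FALSE)
  structure(list(model = model, amplitude = amplitude,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate a two-specimen uniaxial experiment
#'
#' Evaluates the forward model on the two stretch grids and optionally
#' perturbs the stresses. This emulates the standard skin protocol: one
#' strip cut along the spine (or Langer's lines) and one perpendicular to
#' it, both loaded in uniaxial tension. With `noise = noise_spec("none")`
#' the output equals the exact model curves; otherwise the perturbation is
#' drawn from the seeded RNG, so identical seeds give identical data sets.
#'
#' @param params A [skin_params] object (the generating "true" material).
#' @param grid1,grid2 Stretch grids for specimens 1 and 2; default 50
#'   points over \[1, 1.6\].
#' @param noise A [noise_spec]; default multiplicative Gaussian with
#'   relative amplitude 0.02.
#' @return An [experiment_data] object.
#' @examples
#' dat <- simulate_experiment(skin_preset("F")$params,
#'                            noise = noise_spec("none"))
#' @export
simulate_experiment <- function(params,
                                grid1 = seq(1, 1.6, length.out = 50),
                                grid2 = seq(1, 1.6, length.out = 50),
                                noise = noise_spec()) {
  stopifnot(inherits(noise, "noise_spec"))
  c1 <- stress_curve(params, grid1, 1)
  c2 <- stress_curve(params, grid2, 2)
  if (noise$model != "none" && noise$amplitude > 0) {
    set.seed(noise$seed)
    z1 <- stats::rnorm(length(grid1))
    z2 <- stats::rnorm(length(grid2))
    if (noise$model == "multiplicative-gaussian") {
      c1$stresses <- c1$stresses * (1 + noise$amplitude * z1)
      c2$stresses <- c2$stresses * (1 + noise$amplitude * z2)
    } else {
      c1$stresses <- c1$stresses + noise$amplitude * z1
      c2$stresses <- c2$stresses + noise$amplitude * z2
    }
  }
  experiment_data(c1, c2)
}

#' Read / write a two-specimen uniaxial data set as CSV
#'
#' The CSV dialect is comma-separated, dot decimal, UTF-8, with the
#' mandatory header `specimen,stretch,stress_mpa`. Rows are written sorted
#' by specimen then stretch, stresses with 12 significant digits, so a
#' write/read round trip preserves the data.
#'
#' @param path File path.
#' @return `read_experiment`: an [experiment_data] object.
#' @export
read_experiment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "stretch", "stress_mpa")
  if (!all(need %in% names(df)))
    stop("experiment CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ",
           bad[1L], call. = FALSE)
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!all(df$specimen %in% c(1, 2)))
    stop("specimen must be 1 or 2 (first offending data row ",
         which(!df$specimen %in% c(1, 2))[1L], ")", call. = FALSE)
  bad <- which(df$stretch < 1)
  if (length(bad))
    stop("stretch < 1 at data row ", bad[1L], call. = FALSE)
  dup <- duplicated(df[c("specimen", "stretch")])
  if (any(dup))
    stop("duplicate (specimen, stretch) pair at data row ",
         which(dup)[1L], call. = FALSE)
  if (!all(c(1, 2) %in% df$specimen))
    stop("two specimens required: the objective sums residuals over both",
         call. = FALSE)
  df <- df[order(df$specimen, df$stretch), ]
  mk <- function(s) {
    sub <- df[df$specimen == s, ]
    specimen_curve(s, sub$stretch, sub$stress_mpa)
  }
  experiment_data(mk(1), mk(2))
}

#' @rdname read_experiment
#' @param data An [experiment_data] object.
#' @export
write_experiment <- function(data, path) {
  stopifnot(inherits(data, "experiment_data"))
  df <- rbind(
    data.frame(specimen = 1L, stretch = data$curve1$stretches,
               stress_mpa = data$curve1$stresses),
    data.frame(specimen = 2L, stretch = data$curve2$stretches,
               stress_mpa = data$curve2$stresses))
  df$stretch <- signif(df$stretch, 12)
  df$stress_mpa <- signif(df$stress_mpa, 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write material parameters as JSON
#'
#' @param path File path.
#' @return `read_params`: a [skin_params] object.
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(skin_params, x[c(PARAM_NAMES[PARAM_NAMES %in% names(x)],
                           intersect("no_damage", names(x)))])
}

#' @rdname read_params
#' @param params A [skin_params] object.
#' @export
write_params <- function(params, path) {
  validate_skin_params(params)
  x <- params[c(PARAM_NAMES, "no_damage")]
  if (params$no_damage) x <- x[!vapply(x, function(v)
    is.numeric(v) && !is.finite(v), logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a fit result or break analysis to JSON
#'
#' @param x A `fit_result` or `break_analysis` object.
#' @param path File path.
#' @export
write_result_json <- function(x, path) {
  out <- if (inherits(x, "fit_result")) {
    list(params = as.list(unclass(x$params)[PARAM_NAMES]),
         objective_mpa2 = x$objective, epsilon_percent = x$epsilon,
         converged = x$converged, extensions = x$extensions,
         active_bounds = as.list(x$active_bounds),
         fixed = as.list(x$fixed), seed = x$seed,
         starts = x$starts)
  } else if (inherits(x, "break_analysis")) {
    list(verdict = x$verdict, tolerance_used = x$tolerance_used,
         lambda_max = x$lambda_max,
         specimen1 = x$specimen1, specimen2 = x$specimen2)
  } else {
    stop("unsupported object for JSON serialization", call. = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fit configuration from JSON
#'
#' Recognized fields: `bounds` (object with `lower`/`upper` named
#' objects), `fixed`, `n_starts`, `seed`, `kappa_window`, plus any other
#' [fit_config] argument.
#'
#' @param path File path.
#' @return A `fit_config` object.
#' @export
read_fit_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(x$bounds)) {
    b <- default_bounds()
    for (side in c("lower", "upper")) {
      v <- unlist(x$bounds[[side]])
      b[[side]][names(v)] <- v
    }
    args$bounds <- b
  }
  for (f in c("fixed", "n_starts", "seed", "objective_tol", "step_min",
              "step_max", "max_iter", "boundary_tol",
              "boundary_extension_factor", "max_extensions", "refine_hops",
              "kappa_window")) {
    if (!is.null(x[[f]])) args[[f]] <- x[[f]]
  }
  do.call(fit_config, args)
}
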