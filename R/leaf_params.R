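#' Leaf photosynthesis parameter set
#'
#' Builds the parameter set of the coupled FvCB / Ball-Berry leaf model.
#' Defaults are read from the package configuration file
#' (`system.file("extdata", "leaf_params.yaml", package = "soycansim")`),
#' which records every constant of the leaf model with its units: the
#' 25 degC photosynthetic capacities (`vcmax25`, `jmax25`, `rd25`,
#' `tpu25`), the light-response curvature `theta` and the absorptance
#' convention (`leaf_absorb`, `f_spectral`), the standard C3 Rubisco
#' kinetic constants (`kc25`, `ko25`, `gamma_star25`, `o2`), the
#' Ball-Berry coefficients, and the Arrhenius activation energies used
#' for temperature scaling.
#'
#' @param ... Named overrides of any constant in the configuration file,
#'   e.g. `leaf_params(vcmax25 = 120)`.
#' @param file Optional path to an alternative YAML configuration with
#'   the same keys.
#'
#' @return An object of class `leaf_params`: a named list of constants.
#' @examples
#' p <- leaf_params()
#' p$vcmax25
#' leaf_params(jmax25 = 234)$jmax25
#' @export
leaf_params <- function(..., file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "leaf_params.yaml", package = "soycansim")
  }
  p <- yaml::read_yaml(file)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown leaf parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  p <- lapply(p, as.numeric)
  validate_leaf_params(p)
  structure(p, class = "leaf_params")
}

validate_leaf_params <- function(p) {
  rates <- c("vcmax25", "jmax25", "rd25", "tpu25", "kc25", "ko25",
             "gamma_star25", "o2", "bb_intercept")
  for (nm in rates) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop("leaf parameter `", nm, "` must be a non-negative number",
           call. = FALSE)
    }
  }
  if (p$theta <= 0 || p$theta >= 1) {
    stop("`theta` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (p$leaf_absorb <= 0 || p$leaf_absorb > 1) {
    stop("`leaf_absorb` must lie in (0, 1]", call. = FALSE)
  }
  if (p$gamma_star25 >= p$kc25) {
    stop("`gamma_star25` must be smaller than `kc25`", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.leaf_params <- function(x, ...) {
  cat("<leaf_params>\n")
  cat(sprintf("  vcmax25 %.1f  jmax25 %.1f  rd25 %.3f  tpu25 %.1f (umol m-2 s-1)\n",
              x$vcmax25, x$jmax25, x$rd25, x$tpu25))
  cat(sprintf("  theta %.2f  PSII light fraction %.3f\n",
              x$theta, psii_alpha(x)))
  cat(sprintf("  kc25 %.1f  ko25 %.1f  gamma_star25 %.2f  o2 %.0f\n",
              x$kc25, x$ko25, x$gamma_star25, x$o2))
  cat(sprintf("  Ball-Berry: slope %.1f  intercept %.3f mol m-2 s-1\n",
              x$bb_slope, x$bb_intercept))
  invisible(x)
}

# Effective fraction of incident light delivered to PSII:
# absorptance * (1 - spectral correction) / 2 (two photosystems).
psii_alpha <- function(params) {
  params$leaf_absorb * (1 - params$f_spectral) / 2
}

#' Scale photosynthetic capacities
#'
#' Applies multiplicative scaling factors to `vcmax25` and `jmax25`.
#' Dark respiration `rd25` is co-scaled with the Vcmax factor, so a
#' scenario that raises carboxylation capacity also pays the associated
#' respiratory cost.
#'
#' @param params A [leaf_params()] object.
#' @param scale_v,scale_j Multiplicative factors (1 = unchanged).
#' @return A `leaf_params` object with scaled capacities.
#' @examples
#' scale_params(leaf_params(), 1.2, 1.2)$vcmax25
#' @export
scale_params <- function(params, scale_v = 1, scale_j = 1) {
  stopifnot(inherits(params, "leaf_params"), scale_v > 0, scale_j > 0)
  params$vcmax25 <- params$vcmax25 * scale_v
  params$jmax25 <- params$jmax25 * scale_j
  params$rd25 <- params$rd25 * scale_v
  params
}

arrhenius <- function(value25, ea, t_leaf) {
  tk <- t_leaf + 273.15
  value25 * exp(ea * (tk - 298.15) / (298.15 * 8.314 * tk))
}

#' Temperature adjustment of leaf parameters
#'
#' Scales the 25 degC capacities and kinetic constants to the leaf
#' temperature with Arrhenius response functions
#' `x(T) = x25 * exp(Ea * (T - 298.15) / (298.15 * R * T))` (T in K),
#' using the activation energies stored in the parameter set. At 25 degC
#' every value equals its reference value exactly.
#'
#' @param params A [leaf_params()] object.
#' @param t_leaf Leaf temperature, degC; must lie in \[-10, 50\].
#' @return A named list with elements `vcmax`, `jmax`, `rd`, `tpu`,
#'   `kc`, `ko`, `gamma_star` (units as at 25 degC) plus the
#'   temperature-independent `o2`, `theta`, `alpha` (PSII light
#'   fraction), `bb_slope`, `bb_intercept`.
#' @examples
#' temperature_adjust(leaf_params(), 25)$vcmax  # 110
#' temperature_adjust(leaf_params(), 35)$kc > leaf_params()$kc25
#' @export
temperature_adjust <- function(params, t_leaf) {
  stopifnot(inherits(params, "leaf_params"))
  if (any(!is.finite(t_leaf)) || any(t_leaf < -10) || any(t_leaf > 50)) {
    stop("`t_leaf` outside the supported range [-10, 50] degC", call. = FALSE)
  }
  list(
    vcmax = arrhenius(params$vcmax25, params$ea_vcmax, t_leaf),
    jmax = arrhenius(params$jmax25, params$ea_jmax, t_leaf),
    rd = arrhenius(params$rd25, params$ea_rd, t_leaf),
    tpu = arrhenius(params$tpu25, params$ea_tpu, t_leaf),
    kc = arrhenius(params$kc25, params$ea_kc, t_leaf),
    ko = arrhenius(params$ko25, params$ea_ko, t_leaf),
    gamma_star = arrhenius(params$gamma_star25, params$ea_gamma_star, t_leaf),
    o2 = params$o2,
    theta = params$theta,
    alpha = psii_alpha(params),
    bb_slope = params$bb_slope,
    bb_intercept = params$bb_intercept
  )
}
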