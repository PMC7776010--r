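#' Create a set of discrete relaxation-diffusion components
#'
#' A component is one discrete configuration of the 5D relaxation-diffusion
#' distribution: a transverse relaxation rate `r2` (s^-1), axial and radial
#' diffusivities `d_par`, `d_perp` (m^2 s^-1) of an axisymmetric diffusion
#' tensor, its orientation as polar/azimuth angles `theta`, `phi` (radians),
#' and a non-negative signal-fraction `weight` (the weights absorb the
#' unweighted signal amplitude S0, so they need not sum to one).
#'
#' @param r2 transverse relaxation rate, s^-1 (positive).
#' @param d_par axial diffusivity, m^2 s^-1 (non-negative).
#' @param d_perp radial diffusivity, m^2 s^-1 (non-negative).
#' @param theta polar angle from +z, radians in `[0, pi]`.
#' @param phi azimuth from +x, radians (wrapped to `[0, 2*pi)`).
#' @param weight non-negative signal fraction.
#' @return a `data.frame` of class `rd_components` with the six columns
#'   above, one row per component.
#' @examples
#' rd_components(r2 = 1 / 0.06, d_par = 2.1e-9, d_perp = 0.075e-9,
#'               theta = 0, phi = 0, weight = 1)
#' @export
rd_components <- function(r2 = numeric(), d_par = numeric(),
                          d_perp = numeric(), theta = numeric(),
                          phi = numeric(), weight = numeric()) {
  x <- data.frame(r2 = as.numeric(r2), d_par = as.numeric(d_par),
                  d_perp = as.numeric(d_perp), theta = as.numeric(theta),
                  phi = as.numeric(phi) %% (2 * pi),
                  weight = as.numeric(weight))
  if (nrow(x)) {
    if (any(!is.finite(as.matrix(x)))) stop("non-finite component fields")
    if (any(x$r2 <= 0)) stop("r2 must be positive")
    if (any(x$d_par < 0) || any(x$d_perp < 0))
      stop("diffusivities must be non-negative")
    if (any(x$theta < 0 | x$theta > pi)) stop("theta must lie in [0, pi]")
    if (any(x$weight < 0)) stop("weights must be non-negative")
  }
  class(x) <- c("rd_components", "data.frame")
  x
}

as_rd_components <- function(x) {
  rd_components(x$r2, x$d_par, x$d_perp, x$theta, x$phi, x$weight)
}

#' Isotropic diffusivity and normalised diffusion anisotropy
#'
#' Converts the eigenvalues of an axisymmetric diffusion tensor to its
#' isotropic diffusivity `D_iso = (d_par + 2 d_perp) / 3` and normalised
#' anisotropy `D_delta = (d_par - d_perp) / (3 D_iso)`, which lies in
#' `[-0.5, 1]` (-0.5 planar, 0 spherical, 1 stick).
#'
#' @param d_par axial diffusivity, m^2 s^-1.
#' @param d_perp radial diffusivity, m^2 s^-1.
#' @return list with numeric vectors `d_iso` and `d_delta`.
#' @examples
#' diso_ddelta(2.1e-9, 0.075e-9) # D_iso = 0.75e-9, D_delta = 0.9
#' @export
diso_ddelta <- function(d_par, d_perp) {
  if (any(d_par < 0) || any(d_perp < 0))
    stop("diffusivities must be non-negative")
  if (any(d_par == 0 & d_perp == 0))
    stop("d_par and d_perp cannot both be zero (anisotropy undefined)")
  d_iso <- (d_par + 2 * d_perp) / 3
  list(d_iso = d_iso, d_delta = (d_par - d_perp) / (3 * d_iso))
}

# internal, tolerant variant used in kernel evaluation (d_iso = 0 allowed)
.diso_ddelta <- function(d_par, d_perp) {
  d_iso <- (d_par + 2 * d_perp) / 3
  d_delta <- ifelse(d_iso > 0, (d_par - d_perp) / (3 * pmax(d_iso, 1e-300)), 0)
  list(d_iso = d_iso, d_delta = d_delta)
}

#' Inverse of [diso_ddelta()]
#'
#' @param d_iso isotropic diffusivity, m^2 s^-1.
#' @param d_delta normalised anisotropy in `[-0.5, 1]`.
#' @return list with `d_par = d_iso * (1 + 2 d_delta)` and
#'   `d_perp = d_iso * (1 - d_delta)`.
#' @export
dpar_dperp <- function(d_iso, d_delta) {
  if (any(d_delta < -0.5) || any(d_delta > 1))
    stop("d_delta must lie in [-0.5, 1]")
  list(d_par = d_iso * (1 + 2 * d_delta), d_perp = d_iso * (1 - d_delta))
}

# per-component metric values used throughout the orientation-resolved maps
component_metric <- function(comps, metric) {
  dd <- .diso_ddelta(comps$d_par, comps$d_perp)
  switch(metric,
         r2 = comps$r2,
         t2 = 1 / comps$r2,
         d_iso = dd$d_iso,
         d_delta2 = dd$d_delta^2,
         stop("unknown metric '", metric,
              "' (use one of r2, t2, d_iso, d_delta2)"))
}
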