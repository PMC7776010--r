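#' Second Legendre polynomial
#'
#' `P2(x) = (3 x^2 - 1) / 2`, the angular factor coupling the b-tensor
#' anisotropy to the diffusion-tensor anisotropy in the forward signal
#' model. Vanishes at the magic angle (54.7356 degrees).
#'
#' @param x numeric in `[-1, 1]` (a cosine).
#' @return `(3 x^2 - 1) / 2`.
#' @export
p2_legendre <- function(x) {
  if (any(abs(x) > 1 + 1e-12)) stop("p2_legendre: |x| must be <= 1")
  (3 * x^2 - 1) / 2
}

#' Smallest angle between two symmetry axes
#'
#' The angle between the symmetry axes of the diffusion tensor and the
#' b-tensor, taken as the smallest of the two supplementary angles
#' (axes are undirected), so the result lies in `[0, pi/2]`.
#'
#' @param u_b,u_d unit 3-vectors (or matrices of row vectors).
#' @return angle(s) in radians in `[0, pi/2]`.
#' @export
beta_angle <- function(u_b, u_d) {
  u_b <- rbind(u_b); u_d <- rbind(u_d)
  if (any(abs(sqrt(rowSums(u_b^2)) - 1) > 1e-6) ||
      any(abs(sqrt(rowSums(u_d^2)) - 1) > 1e-6))
    stop("beta_angle expects unit vectors (tolerance 1e-6)")
  axis_angle(u_b, u_d)
}

#' Forward signal kernel for one measurement and one component
#'
#' The mono-exponential relaxation-diffusion kernel
#' `exp(-tau_e R2) * exp(-b D_iso [1 + 2 b_delta D_delta P2(cos beta)])`
#' where `beta` is the smallest angle between the symmetry axes of the
#' component diffusion tensor and the b-tensor.
#'
#' @param m one-row [rd_scheme()] (a single measurement).
#' @param c one-row [rd_components()] (a single component; its weight is
#'   ignored here).
#' @return the dimensionless kernel value.
#' @export
kernel_value <- function(m, c) {
  K <- build_kernel_matrix(m, c)
  unname(K[1, 1])
}

#' Discretised inversion kernel matrix
#'
#' Builds the M x N matrix `K` of the discretised forward model
#' `s = K w`, with entry (i, n) the kernel value of measurement i and
#' candidate component n.
#'
#' @param scheme an [rd_scheme()] with M measurements.
#' @param comps an [rd_components()] table of N candidate components.
#' @return numeric M x N matrix.
#' @export
build_kernel_matrix <- function(scheme, comps) {
  if (nrow(scheme) < 1L || nrow(comps) < 1L)
    stop("scheme and components must be non-empty")
  G <- scheme_directions(scheme)                      # M x 3
  U <- sph_to_cart(comps$theta, comps$phi)            # N x 3
  cosb <- G %*% t(U)                                  # M x N
  cosb[cosb > 1] <- 1; cosb[cosb < -1] <- -1
  dd <- .diso_ddelta(comps$d_par, comps$d_perp)
  att <- outer(scheme$b, dd$d_iso) *
    (1 + 2 * outer(scheme$b_delta, dd$d_delta) * p2_legendre(cosb))
  exp(-outer(scheme$tau_e, comps$r2)) * exp(-att)
}

#' Forward signal of a weighted component set
#'
#' Evaluates `s = K w`: the noiseless multi-echo, multi-b-tensor signal of
#' a discrete relaxation-diffusion distribution. Linear in the weights; for
#' spherical encoding (`b_delta = 0`) it is independent of component
#' orientation.
#'
#' @param scheme an [rd_scheme()].
#' @param comps an [rd_components()] table (weights used).
#' @return numeric signal vector of length M (arbitrary units; the weights
#'   absorb S0).
#' @export
forward_signal <- function(scheme, comps) {
  if (nrow(comps) == 0L) return(rep(0, nrow(scheme)))
  as.vector(build_kernel_matrix(scheme, comps) %*% comps$weight)
}
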