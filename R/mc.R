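#' Sampling box of the Monte-Carlo candidate space
#'
#' Candidates are drawn uniformly in the transformed coordinates
#' `(log10 R2, log10 D_par, log10 D_perp, cos theta, phi)`. The defaults
#' span R2 from 1 to 31.6 s^-1 and diffusivities from 5e-12 to 5e-9
#' m^2 s^-1, with orientations uniform on the upper hemisphere (all
#' downstream orientation handling is antipodally symmetric).
#'
#' @param log10_r2 interval of log10(R2 / s^-1).
#' @param log10_d_par interval of log10(D_par / m^2 s^-1).
#' @param log10_d_perp interval of log10(D_perp / m^2 s^-1).
#' @param cos_theta interval of cos(theta).
#' @param phi interval of phi (radians).
#' @return list of class `rd_ranges`.
#' @export
sampling_ranges <- function(log10_r2 = c(0, 1.5),
                            log10_d_par = c(-11.3, -8.3),
                            log10_d_perp = c(-11.3, -8.3),
                            cos_theta = c(0, 1),
                            phi = c(0, 2 * pi)) {
  r <- list(log10_r2 = log10_r2, log10_d_par = log10_d_par,
            log10_d_perp = log10_d_perp, cos_theta = cos_theta, phi = phi)
  for (nm in names(r)) {
    iv <- r[[nm]]
    if (length(iv) != 2L || !all(is.finite(iv)) || iv[2] <= iv[1])
      stop("degenerate sampling interval for ", nm)
  }
  class(r) <- "rd_ranges"
  r
}

#' Monte-Carlo inversion configuration
#'
#' Defaults follow the reference analysis settings: 200 fresh random
#' candidates per proliferation round, 20 proliferation and 20 mutation
#' rounds, 20 retained components, 96 bootstrap solutions. The mutation
#' perturbation is additive Gaussian in the sampling coordinates with
#' standard deviation `mutation_scale` times each interval width, clipped
#' to the box.
#'
#' @param n_in fresh candidates per proliferation round.
#' @param n_p proliferation rounds.
#' @param n_m mutation rounds.
#' @param n_keep components retained in the final solution.
#' @param n_boot bootstrap solutions per voxel.
#' @param seed integer RNG seed (sub-seeds are derived per bootstrap).
#' @param mutation_scale per-coordinate perturbation width, as a fraction
#'   of each sampling-interval width.
#' @return list of class `rd_config`.
#' @export
mc_config <- function(n_in = 200L, n_p = 20L, n_m = 20L, n_keep = 20L,
                      n_boot = 96L, seed = 1L, mutation_scale = 0.05) {
  cfg <- list(n_in = as.integer(n_in), n_p = as.integer(n_p),
              n_m = as.integer(n_m), n_keep = as.integer(n_keep),
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              mutation_scale = mutation_scale)
  if (any(unlist(cfg[1:5]) < 1L)) stop("all counts must be >= 1")
  if (mutation_scale < 0) stop("mutation_scale must be >= 0")
  class(cfg) <- "rd_config"
  cfg
}

# relative weight below which NNLS output is treated as numerically zero
.w_floor <- 1e-12

#' Draw random candidate components
#'
#' Uniform draws in the `(log10 R2, log10 D_par, log10 D_perp, cos theta,
#' phi)` sampling box, converted back to component parameters.
#'
#' @param ranges a [sampling_ranges()].
#' @param n number of candidates.
#' @return an [rd_components()] table with zero weights.
#' @export
sample_candidates <- function(ranges, n) {
  if (n < 1) stop("n must be >= 1")
  ru <- function(iv) runif(n, iv[1], iv[2])
  rd_components(r2 = 10^ru(ranges$log10_r2),
                d_par = 10^ru(ranges$log10_d_par),
                d_perp = 10^ru(ranges$log10_d_perp),
                theta = acos(ru(ranges$cos_theta)),
                phi = ru(ranges$phi),
                weight = rep(0, n))
}

#' Non-negative least-squares fit
#'
#' Solves `argmin_{w >= 0} || s - K w ||^2` with a Lawson-Hanson
#' active-set solver (compiled). The solution support never exceeds the
#' number of measurements.
#'
#' @param kernel M x N kernel matrix.
#' @param s signal vector of length M.
#' @return list with `w` (non-negative weights) and `ssr` (sum of squared
#'   residuals).
#' @export
nnls_fit <- function(kernel, s) {
  kernel <- as.matrix(kernel)
  if (nrow(kernel) != length(s)) stop("dimension mismatch in nnls_fit")
  fit <- nnls_cpp(kernel, as.numeric(s))
  list(w = as.vector(fit$w), ssr = fit$ssr)
}

# components <-> sampling-coordinate matrix (columns: log10 r2, log10 dpar,
# log10 dperp, cos theta, phi)
comps_to_coords <- function(comps) {
  cbind(log10(comps$r2), log10(pmax(comps$d_par, 1e-300)),
        log10(pmax(comps$d_perp, 1e-300)), cos(comps$theta), comps$phi)
}

coords_to_comps <- function(xy, weight = 0) {
  rd_components(r2 = 10^xy[, 1], d_par = 10^xy[, 2], d_perp = 10^xy[, 3],
                theta = acos(pmin(1, pmax(-1, xy[, 4]))),
                phi = xy[, 5] %% (2 * pi),
                weight = rep_len(weight, nrow(xy)))
}

#' Proliferation cycle of the Monte-Carlo inversion
#'
#' Repeats `n_p` rounds of: draw `n_in` fresh random candidates, append
#' the current survivors, solve the NNLS problem, and keep the components
#' with non-zero weights. The sum of squared residuals is non-increasing
#' across rounds because each round's pool contains the previous
#' survivors.
#'
#' @param scheme an [rd_scheme()].
#' @param s signal vector (length `nrow(scheme)`).
#' @param ranges a [sampling_ranges()].
#' @param config an [mc_config()].
#' @return list of class `rd_solution`: `components` (weighted survivors)
#'   and `ssr`.
#' @export
proliferate <- function(scheme, s, ranges = sampling_ranges(),
                        config = mc_config()) {
  surv <- rd_components()
  ssr <- sum(s^2)
  trace <- numeric(config$n_p)
  for (r in seq_len(config$n_p)) {
    cand <- sample_candidates(ranges, config$n_in)
    pool <- if (nrow(surv)) rbind(surv, cand) else cand
    fit <- nnls_fit(build_kernel_matrix(scheme, pool), s)
    keep <- fit$w > .w_floor * max(fit$w, 0)
    surv <- pool[keep, , drop = FALSE]
    surv$weight <- fit$w[keep]
    rownames(surv) <- NULL
    ssr <- trace[r] <- fit$ssr
  }
  structure(list(components = surv, ssr = ssr, ssr_trace = trace),
            class = "rd_solution")
}

#' Mutation cycle of the Monte-Carlo inversion
#'
#' For `n_m` rounds the current configuration is duplicated and every
#' coordinate of the duplicate is perturbed (Gaussian in the sampling
#' coordinates, clipped to the box). Original and perturbed components
#' then compete through a joint NNLS fit on their union: the solver's
#' weights decide, per component, whether the original or its mutated
#' counterpart survives, and the sum of squared residuals is
#' non-increasing by construction (the union contains the current
#' support). With `mutation_scale = 0` the duplicate is identical and the
#' residual is unchanged.
#'
#' @param sol an `rd_solution` (from [proliferate()]).
#' @inheritParams proliferate
#' @return an `rd_solution`.
#' @export
mutate <- function(sol, scheme, s, ranges = sampling_ranges(),
                   config = mc_config()) {
  if (nrow(sol$components) == 0L) return(sol)
  lims <- rbind(ranges$log10_r2, ranges$log10_d_par, ranges$log10_d_perp,
                ranges$cos_theta, ranges$phi)
  widths <- lims[, 2] - lims[, 1]
  cur <- sol$components
  cur_ssr <- sol$ssr
  trace <- numeric(config$n_m)
  for (r in seq_len(config$n_m)) {
    xy <- comps_to_coords(cur)
    pert <- xy + matrix(rnorm(length(xy)), nrow(xy), 5) *
      rep(config$mutation_scale * widths, each = nrow(xy))
    pert <- pmin(pmax(pert, rep(lims[, 1], each = nrow(xy))),
                 rep(lims[, 2], each = nrow(xy)))
    pool <- rbind(cur, coords_to_comps(pert))
    fit <- nnls_fit(build_kernel_matrix(scheme, pool), s)
    if (fit$ssr <= cur_ssr) {
      keep <- fit$w > .w_floor * max(fit$w, 0)
      pool$weight <- fit$w
      cur <- pool[keep, , drop = FALSE]
      rownames(cur) <- NULL
      cur_ssr <- fit$ssr
    }
    trace[r] <- cur_ssr
  }
  structure(list(components = cur, ssr = cur_ssr, ssr_trace = trace),
            class = "rd_solution")
}

#' Solve one voxel: proliferation, mutation, truncation
#'
#' Runs the two Monte-Carlo cycles, keeps the `n_keep` highest-weight
#' components and refits their weights by NNLS on the truncated set. An
#' all-zero signal returns an empty (flagged) solution.
#'
#' @inheritParams proliferate
#' @return an `rd_solution` with at most `config$n_keep` components, all
#'   with strictly positive weights.
#' @export
solve_voxel <- function(scheme, s, ranges = sampling_ranges(),
                        config = mc_config()) {
  if (length(s) != nrow(scheme)) stop("signal/scheme length mismatch")
  if (all(s == 0))
    return(structure(list(components = rd_components(), ssr = 0,
                          empty = TRUE), class = "rd_solution"))
  sol <- proliferate(scheme, s, ranges, config)
  sol <- mutate(sol, scheme, s, ranges, config)
  comps <- sol$components
  if (nrow(comps) > config$n_keep) {
    comps <- comps[order(comps$weight, decreasing = TRUE), , drop = FALSE]
    comps <- comps[seq_len(config$n_keep), , drop = FALSE]
    fit <- nnls_fit(build_kernel_matrix(scheme, comps), s)
    keep <- fit$w > .w_floor * max(fit$w, 0)
    comps$weight <- fit$w
    comps <- comps[keep, , drop = FALSE]
    sol$ssr <- fit$ssr
  }
  rownames(comps) <- NULL
  structure(list(components = comps, ssr = sol$ssr), class = "rd_solution")
}

#' Bootstrap ensemble of per-voxel solutions
#'
#' Resamples the M measurements with replacement `n_boot` times and solves
#' each resample with [solve_voxel()]. Every bootstrap uses a sub-seed
#' derived from `config$seed` and the bootstrap index, so the ensemble is
#' reproducible and independent of evaluation order.
#'
#' @inheritParams proliferate
#' @param stratified logical; if `TRUE`, resampling is done with
#'   replacement within each (tau_e, b, b_delta) shell, preserving the
#'   shell structure of the protocol. Default is unrestricted resampling
#'   over all M measurements.
#' @return list of class `rd_ensemble`: `solutions` (list of
#'   `rd_solution`), `resample_indices` (n_boot x M integer matrix) and
#'   the `config` used.
#' @export
bootstrap_invert <- function(scheme, s, ranges = sampling_ranges(),
                             config = mc_config(), stratified = FALSE) {
  M <- nrow(scheme)
  shell <- if (stratified)
    interaction(scheme$tau_e, scheme$b, scheme$b_delta, drop = TRUE)
  sols <- vector("list", config$n_boot)
  idxm <- matrix(0L, config$n_boot, M)
  for (nb in seq_len(config$n_boot)) {
    set.seed(derive_seed(config$seed, nb))
    idx <- if (stratified) {
      unlist(lapply(split(seq_len(M), shell),
                    function(i) i[sample.int(length(i), length(i),
                                             replace = TRUE)]),
             use.names = FALSE)
    } else {
      sample.int(M, M, replace = TRUE)
    }
    idxm[nb, ] <- idx
    sols[[nb]] <- solve_voxel(scheme_subset(scheme, idx), s[idx],
                              ranges, config)
  }
  structure(list(solutions = sols, resample_indices = idxm,
                 config = config), class = "rd_ensemble")
}
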