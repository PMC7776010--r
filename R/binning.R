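#' Bin definitions in (log ratio, log D_iso, log R2) space
#'
#' The built-in bins partition the physically relevant corner of the
#' relaxation-diffusion space into three boxes named after the geometry of
#' the diffusion tensors they capture: 'thin' (elongated, white-matter
#' fibre like), 'thick' (low anisotropy, grey-matter like) and 'big'
#' (fast-diffusing, CSF like). Intervals are open: a component exactly on
#' a boundary belongs to no bin. All logs are base 10.
#'
#' @param name bin label.
#' @param log10_ratio open interval on log10(D_par / D_perp).
#' @param log10_diso open interval on log10(D_iso / m^2 s^-1).
#' @param log10_r2 open interval on log10(R2 / s^-1).
#' @return a `rd_bin` list.
#' @export
bin_definition <- function(name, log10_ratio, log10_diso,
                           log10_r2 = c(-0.5, 2)) {
  stopifnot(length(log10_ratio) == 2L, length(log10_diso) == 2L,
            length(log10_r2) == 2L)
  structure(list(name = name, log10_ratio = log10_ratio,
                 log10_diso = log10_diso, log10_r2 = log10_r2),
            class = "rd_bin")
}

#' @rdname bin_definition
#' @export
default_bins <- function() {
  list(thin = bin_definition("thin", c(0.6, 3.5), c(-10, -8.7)),
       thick = bin_definition("thick", c(-3.5, 0.6), c(-10, -8.7)),
       big = bin_definition("big", c(-3.5, 3.5), c(-8.7, -8)))
}

.bins_overlap <- function(a, b) {
  ov <- function(x, y) x[1] < y[2] && y[1] < x[2]
  ov(a$log10_ratio, b$log10_ratio) && ov(a$log10_diso, b$log10_diso) &&
    ov(a$log10_r2, b$log10_r2)
}

#' Classify components into bins
#'
#' Components are placed in (log10 D_par/D_perp, log10 D_iso, log10 R2)
#' space and assigned to the unique bin whose three open intervals contain
#' them, or to `"none"`. Classification ignores orientation. A zero
#' radial (or axial) diffusivity makes the ratio infinite; its log is then
#' clipped to +/-3, the edge of the Monte-Carlo sampling box, so that
#' simulator-style stick components still classify sensibly.
#'
#' @param comps an [rd_components()] table.
#' @param bins list of [bin_definition()]s (must be pairwise disjoint).
#' @return factor of bin names (levels: bin names plus `"none"`).
#' @export
classify_components <- function(comps, bins = default_bins()) {
  nb <- length(bins)
  if (nb > 1L) {
    for (i in seq_len(nb - 1L)) for (j in seq(i + 1L, nb)) {
      if (.bins_overlap(bins[[i]], bins[[j]]))
        stop("ambiguous binning: bins '", bins[[i]]$name, "' and '",
             bins[[j]]$name, "' overlap")
    }
  }
  lr <- log10(comps$d_par) - log10(comps$d_perp)
  lr[comps$d_perp == 0 & comps$d_par > 0] <- 3
  lr[comps$d_par == 0 & comps$d_perp > 0] <- -3
  ld <- log10(.diso_ddelta(comps$d_par, comps$d_perp)$d_iso)
  lz <- log10(comps$r2)
  lab <- rep("none", nrow(comps))
  for (b in bins) {
    inb <- lr > b$log10_ratio[1] & lr < b$log10_ratio[2] &
      ld > b$log10_diso[1] & ld < b$log10_diso[2] &
      lz > b$log10_r2[1] & lz < b$log10_r2[2]
    lab[inb] <- b$name
  }
  factor(lab, levels = c(vapply(bins, `[[`, "", "name"), "none"))
}

#' Thin-bin (fibre-like) subset of a solution
#'
#' @param sol an `rd_solution` (or an [rd_components()] table).
#' @param bins bin definitions; the `"thin"` bin is used.
#' @return the sub-table of components classified 'thin', weights
#'   untouched (possibly empty).
#' @export
thin_subset <- function(sol, bins = default_bins()) {
  comps <- if (inherits(sol, "rd_solution")) sol$components else sol
  if (nrow(comps) == 0L) return(comps)
  lab <- classify_components(comps, bins)
  out <- comps[lab == "thin", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-voxel bin signal fractions
#'
#' For each bootstrap solution the fraction of total weight in each bin
#' (plus `"none"`) is computed; the voxel value is the median over
#' bootstraps. `f_thin` is the thin-bin fraction; its complement
#' `1 - f_thin` is the fraction not entering ODF computation.
#'
#' @param ens an `rd_ensemble` (from [bootstrap_invert()]).
#' @param bins bin definitions.
#' @return list with `fractions` (named numeric, medians per bin,
#'   including `"none"`), `f_thin` and `f_not_thin`. All `NA` when every
#'   bootstrap has zero total weight (masked voxel).
#' @export
bin_fraction_maps <- function(ens, bins = default_bins()) {
  if (length(ens$solutions) == 0L) stop("empty ensemble")
  lev <- c(vapply(bins, `[[`, "", "name"), "none")
  fr <- vapply(ens$solutions, function(sol) {
    comps <- sol$components
    tot <- sum(comps$weight)
    if (nrow(comps) == 0L || tot <= 0) return(rep(NA_real_, length(lev)))
    lab <- classify_components(comps, bins)
    vapply(lev, function(l) sum(comps$weight[lab == l]) / tot, 0)
  }, numeric(length(lev)))
  if (all(is.na(fr))) {
    med <- setNames(rep(NA_real_, length(lev)), lev)
  } else {
    med <- apply(fr, 1, median, na.rm = TRUE)
  }
  list(fractions = med, f_thin = unname(med["thin"]),
       f_not_thin = 1 - unname(med["thin"]))
}

#' Per-voxel bin-resolved parameter means
#'
#' Within each bootstrap, the weight-weighted mean of a metric over the
#' components of one bin; the voxel value is the median over bootstraps.
#' Undefined (NA) when the bin is empty in more than half the bootstraps.
#'
#' @param ens an `rd_ensemble`.
#' @param bin bin name (e.g. `"thin"`).
#' @param metric one of `"r2"`, `"t2"`, `"d_iso"`, `"d_delta2"`.
#' @param bins bin definitions.
#' @return scalar (median over bootstraps of the in-bin weighted mean).
#' @export
bin_parameter_means <- function(ens, bin = "thin", metric = "t2",
                                bins = default_bins()) {
  if (!bin %in% vapply(bins, `[[`, "", "name"))
    stop("unknown bin '", bin, "'")
  vals <- vapply(ens$solutions, function(sol) {
    comps <- sol$components
    if (nrow(comps) == 0L) return(NA_real_)
    lab <- classify_components(comps, bins)
    inb <- lab == bin
    if (!any(inb) || sum(comps$weight[inb]) <= 0) return(NA_real_)
    x <- component_metric(comps[inb, , drop = FALSE], metric)
    sum(comps$weight[inb] * x) / sum(comps$weight[inb])
  }, 0)
  if (mean(is.na(vals)) > 0.5) return(NA_real_)
  median(vals, na.rm = TRUE)
}
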