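#' Extract ODF peaks
#'
#' A peak is a mesh vertex whose amplitude is strictly greater than all of
#' its 1-ring (triangle-edge) neighbours and at least 10% of the global
#' maximum. Because the Watson ODF is antipodally symmetric every lobe
#' appears twice on a full-sphere mesh; near-antipodal duplicates are
#' merged (the representative with positive z, ties positive x, and the
#' larger amplitude is kept). At most `max_peaks` peaks are returned,
#' sorted by amplitude.
#'
#' @param amplitude per-vertex ODF amplitudes (e.g. the median ODF), or an
#'   `rd_odf` object.
#' @param mesh an [make_mesh()] object (ignored when `amplitude` is an
#'   `rd_odf`).
#' @param threshold relative amplitude threshold (default 0.1).
#' @param max_peaks maximum number of peaks (default 4).
#' @param merge_angle peaks whose axes are closer than this angle
#'   (degrees) are considered duplicates of the same lobe; defaults to 2.5
#'   mesh edge lengths, which is well below any resolvable crossing.
#' @return a `data.frame` of class `rd_peaks` with columns `vertex`, `x`,
#'   `y`, `z`, `amplitude` (possibly zero rows).
#' @export
extract_peaks <- function(amplitude, mesh = NULL, threshold = 0.1,
                          max_peaks = 4L, merge_angle = NULL) {
  if (inherits(amplitude, "rd_odf")) {
    mesh <- amplitude$mesh
    amplitude <- amplitude$amplitude
  }
  if (is.null(mesh)) stop("a mesh is required")
  nv <- nrow(mesh$vertices)
  if (length(amplitude) != nv) stop("amplitude/mesh size mismatch")
  if (is.null(merge_angle)) merge_angle <- 2.5 * mesh$median_nn_angle
  empty <- data.frame(vertex = integer(), x = numeric(), y = numeric(),
                      z = numeric(), amplitude = numeric())
  class(empty) <- c("rd_peaks", "data.frame")
  amax <- max(amplitude)
  if (amax <= 0) return(empty)
  is_peak <- vapply(seq_len(nv), function(v) {
    nb <- mesh$neighbors[[v]]
    amplitude[v] >= threshold * amax && all(amplitude[v] > amplitude[nb])
  }, TRUE)
  cand <- which(is_peak)
  if (length(cand) == 0L) return(empty)
  cand <- cand[order(amplitude[cand], decreasing = TRUE)]
  kept <- integer()
  for (v in cand) {
    if (length(kept)) {
      ang <- rad2deg(axis_angle(
        mesh$vertices[rep(v, length(kept)), , drop = FALSE],
        mesh$vertices[kept, , drop = FALSE]))
      if (any(ang < merge_angle)) next  # duplicate / antipode of a lobe
    }
    kept <- c(kept, v)
    if (length(kept) >= max_peaks) break
  }
  U <- mesh$vertices[kept, , drop = FALSE]
  flip <- U[, 3] < 0 | (U[, 3] == 0 & U[, 1] < 0)
  U[flip, ] <- -U[flip, ]
  out <- data.frame(vertex = kept, x = U[, 1], y = U[, 2], z = U[, 3],
                    amplitude = amplitude[kept])
  rownames(out) <- NULL
  class(out) <- c("rd_peaks", "data.frame")
  out
}

#' Attach orientation-resolved metrics to peaks
#'
#' Evaluates the per-vertex metric means of an [odf_from_ensemble()]
#' result at the peak vertices.
#'
#' @param peaks an `rd_peaks` table.
#' @param odf an `rd_odf` object.
#' @return the peaks table with one extra column per metric.
#' @export
peak_metrics <- function(peaks, odf) {
  for (m in names(odf$means)) peaks[[m]] <- odf$means[[m]][peaks$vertex]
  peaks
}

#' Fibre-population statistics around the ODF peaks
#'
#' Divides orientation space into regions centred on the peak axes (and
#' their antipodes): every thin-bin component of every bootstrap is
#' assigned to the peak with the largest `|u . peak|` (ties to the lowest
#' peak index). Per peak and per bootstrap the weight-weighted means of
#' signal fraction, R2, D_iso, squared anisotropy and mean orientation are
#' computed; the ensemble statistics are the median and interquartile
#' range over bootstraps.
#'
#' @param ens an `rd_ensemble`.
#' @param peaks an `rd_peaks` table with at least one peak.
#' @param bins bin definitions for the thin subset.
#' @return a `data.frame` with one row per (peak, statistic) pair:
#'   columns `peak`, `stat` (`"median"` / `"iqr"`), `fraction`, `r2`,
#'   `d_iso`, `d_delta2`, `ux`, `uy`, `uz`.
#' @export
population_stats <- function(ens, peaks, bins = default_bins()) {
  if (nrow(peaks) == 0L) stop("need at least one peak")
  P <- as.matrix(peaks[, c("x", "y", "z")])
  nb_stats <- lapply(ens$solutions, function(sol) {
    thin <- thin_subset(sol, bins)
    if (nrow(thin) == 0L) return(NULL)
    U <- sph_to_cart(thin$theta, thin$phi)
    aff <- abs(U %*% t(P))                  # components x peaks
    assign <- apply(aff, 1, which.max)      # first max = lowest peak index
    tot <- sum(thin$weight)
    t(vapply(seq_len(nrow(P)), function(k) {
      sel <- assign == k
      if (!any(sel) || sum(thin$weight[sel]) <= 0)
        return(rep(NA_real_, 7))
      w <- thin$weight[sel]
      comps <- thin[sel, , drop = FALSE]
      # align orientations with the peak axis before averaging
      Us <- U[sel, , drop = FALSE]
      sgn <- sign(Us %*% P[k, ])
      sgn[sgn == 0] <- 1
      ubar <- colSums(w * Us * as.vector(sgn)) / sum(w)
      ubar <- ubar / max(sqrt(sum(ubar^2)), 1e-12)
      c(sum(w) / tot,
        sum(w * component_metric(comps, "r2")) / sum(w),
        sum(w * component_metric(comps, "d_iso")) / sum(w),
        sum(w * component_metric(comps, "d_delta2")) / sum(w),
        ubar)
    }, numeric(7)))
  })
  nb_stats <- nb_stats[!vapply(nb_stats, is.null, TRUE)]
  if (length(nb_stats) == 0L) stop("no thin components in any bootstrap")
  arr <- simplify2array(nb_stats)           # peaks x 7 x boots
  med <- apply(arr, c(1, 2), median, na.rm = TRUE)
  iqr <- apply(arr, c(1, 2), function(v)
    diff(quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE)))
  mk <- function(m, lab) data.frame(peak = seq_len(nrow(P)), stat = lab,
                                    fraction = m[, 1], r2 = m[, 2],
                                    d_iso = m[, 3], d_delta2 = m[, 4],
                                    ux = m[, 5], uy = m[, 6], uz = m[, 7])
  rbind(mk(rbind(med), "median"), mk(rbind(iqr), "iqr"))
}

#' Directional colour coding
#'
#' Standard directional colouring: for mesh vertices (or any unit axes)
#' the colour is the absolute value of the vector components,
#' `[R,G,B] = |[mu_x, mu_y, mu_z]|`. For components, the axis colour is
#' additionally scaled by the linearity factor
#' `|d_par - d_perp| / max(d_par, d_perp)`, so isotropic tensors map to
#' black.
#'
#' @param x an n x 3 matrix of unit vectors, or an [rd_components()]
#'   table.
#' @return n x 3 matrix of RGB values in `[0, 1]`.
#' @export
directional_colors <- function(x) {
  if (inherits(x, "rd_components") ||
      (is.data.frame(x) && all(c("theta", "phi") %in% names(x)))) {
    U <- sph_to_cart(x$theta, x$phi)
    lin <- abs(x$d_par - x$d_perp) / pmax(x$d_par, x$d_perp)
    lin[!is.finite(lin)] <- 0
    abs(U) * lin
  } else {
    unname(abs(rbind(x)))
  }
}
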