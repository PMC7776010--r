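#' Read a 4D signal volume aligned to a protocol
#'
#' @param path NIfTI file with the 4th dimension matching the protocol
#'   length.
#' @param scheme the [rd_scheme()] the volumes were acquired with.
#' @param mask optional NIfTI path or 3D array; voxels outside the mask
#'   are excluded.
#' @return list with `signal` (n_voxel x M matrix of in-mask voxels),
#'   `coords` (n_voxel x 3 voxel indices), `dim` (3D grid dimensions) and
#'   `image` (the `RNifti` image, for affine/metadata propagation).
#'   Voxels containing non-finite values are dropped with a warning.
#' @export
read_signal <- function(path, scheme, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D NIfTI volume, got ", length(d), " dimensions")
  if (d[4] != nrow(scheme))
    stop("signal has ", d[4], " volumes but the protocol lists ",
         nrow(scheme), " measurements")
  msk <- if (is.null(mask)) array(TRUE, d[1:3]) else {
    m <- if (is.character(mask)) RNifti::readNifti(mask) else mask
    if (!all(dim(m)[1:3] == d[1:3])) stop("mask/signal grid mismatch")
    array(m != 0, d[1:3])
  }
  coords <- which(msk, arr.ind = TRUE)
  sig <- t(apply(coords, 1, function(v) img[v[1], v[2], v[3], ]))
  ok <- apply(sig, 1, function(r) all(is.finite(r)))
  if (!all(ok)) {
    warning(sum(!ok), " voxel(s) with non-finite signal excluded")
    sig <- sig[ok, , drop = FALSE]
    coords <- coords[ok, , drop = FALSE]
  }
  list(signal = sig, coords = coords, dim = d[1:3], image = img)
}

#' Write a scalar (or multi-channel) map as NIfTI
#'
#' Masked / undefined voxels are written as NA.
#'
#' @param values n_voxel vector (or n_voxel x k matrix) of map values.
#' @param coords n_voxel x 3 voxel indices.
#' @param dim 3-vector grid dimensions.
#' @param path output path.
#' @param reference optional `RNifti` image whose header (affine, units)
#'   is propagated.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, coords, dim, path, reference = NULL) {
  values <- cbind(values)
  k <- ncol(values)
  arr <- array(NA_real_, if (k == 1L) dim else c(dim, k))
  for (j in seq_len(k)) {
    a <- array(NA_real_, dim)
    a[coords] <- values[, j]
    if (k == 1L) arr <- a else arr[, , , j] <- a
  }
  img <- if (is.null(reference)) RNifti::asNifti(arr) else
    RNifti::asNifti(arr, reference = reference)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write peaks in the stacked-vector NIfTI convention
#'
#' Each voxel stores up to 4 peak direction vectors scaled by their
#' amplitude, zero-padded, as 12 consecutive components: the layout
#' consumed by common tracking tools.
#'
#' @param peaks_list list of `rd_peaks` tables, one per voxel.
#' @param coords,dim,path,reference as in [write_map()].
#' @return `path`, invisibly.
#' @export
write_peaks_nifti <- function(peaks_list, coords, dim, path,
                              reference = NULL) {
  vals <- t(vapply(peaks_list, function(pk) {
    v <- numeric(12)
    if (!is.null(pk) && nrow(pk)) {
      n <- min(nrow(pk), 4L)
      for (i in seq_len(n))
        v[(3 * i - 2):(3 * i)] <-
          unlist(pk[i, c("x", "y", "z")]) * pk$amplitude[i]
    }
    v
  }, numeric(12)))
  write_map(vals, coords, dim, path, reference)
}

.ensemble_version <- "rdfibre-ensemble-1"

#' Write / read a bootstrap solution ensemble
#'
#' Flat tab-separated store: one row per (voxel, bootstrap, component)
#' with the six component fields, plus a JSON sidecar (`<path>.json`)
#' carrying a format version tag and the inversion configuration. Stored
#' values round-trip through 17 significant digits.
#'
#' @param ensembles list of `rd_ensemble` objects (one per voxel), or a
#'   single ensemble.
#' @param path output TSV path.
#' @return `read_ensembles` returns a list of `rd_ensemble`s;
#'   `write_ensembles` returns `path` invisibly.
#' @export
write_ensembles <- function(ensembles, path) {
  if (inherits(ensembles, "rd_ensemble")) ensembles <- list(ensembles)
  rows <- list()
  for (v in seq_along(ensembles)) {
    ens <- ensembles[[v]]
    for (nb in seq_along(ens$solutions)) {
      comps <- ens$solutions[[nb]]$components
      if (nrow(comps) == 0L) next
      rows[[length(rows) + 1L]] <-
        cbind(voxel = v, boot = nb, as.data.frame(comps),
              ssr = ens$solutions[[nb]]$ssr)
    }
  }
  out <- do.call(rbind, rows)
  for (j in c("r2", "d_par", "d_perp", "theta", "phi", "weight", "ssr"))
    out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- ensembles[[1]]$config
  jsonlite::write_json(
    list(version = .ensemble_version, n_voxel = length(ensembles),
         n_boot = cfg$n_boot,
         config = unclass(cfg)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensembles
#' @export
read_ensembles <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$version, .ensemble_version))
    stop("unsupported ensemble store version: ", meta$version)
  x <- read.delim(path, sep = "\t")
  lapply(seq_len(meta$n_voxel), function(v) {
    sols <- lapply(seq_len(meta$n_boot), function(nb) {
      d <- x[x$voxel == v & x$boot == nb, , drop = FALSE]
      structure(list(components = rd_components(d$r2, d$d_par, d$d_perp,
                                                d$theta, d$phi, d$weight),
                     ssr = if (nrow(d)) d$ssr[1] else NA_real_),
                class = "rd_solution")
    })
    structure(list(solutions = sols, resample_indices = NULL,
                   config = meta$config), class = "rd_ensemble")
  })
}

#' Invert every voxel of a masked signal volume
#'
#' Voxel loop over [bootstrap_invert()] with per-voxel derived sub-seeds,
#' so results do not depend on voxel order.
#'
#' @param signal n_voxel x M matrix (e.g. from [read_signal()]).
#' @param scheme an [rd_scheme()].
#' @param ranges a [sampling_ranges()].
#' @param config an [mc_config()].
#' @param stratified passed to [bootstrap_invert()].
#' @param verbose print progress.
#' @return list of `rd_ensemble`, one per voxel row.
#' @export
invert_volume <- function(signal, scheme, ranges = sampling_ranges(),
                          config = mc_config(), stratified = FALSE,
                          verbose = FALSE) {
  signal <- rbind(signal)
  lapply(seq_len(nrow(signal)), function(v) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 7919L, v)
    if (verbose) message("voxel ", v, "/", nrow(signal))
    bootstrap_invert(scheme, signal[v, ], ranges, cfg,
                     stratified = stratified)
  })
}
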