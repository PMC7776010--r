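#' Create an acquisition scheme
#'
#' An acquisition scheme is the ordered table of the M measurement points of
#' a relaxation-diffusion protocol. Each row holds the echo time `tau_e`
#' (seconds), the conventional b-value `b` (trace of the b-tensor,
#' s m^-2), the normalised b-tensor anisotropy `b_delta` (-0.5 planar,
#' 0 spherical, 0.5 prolate, 1 linear/Stejskal-Tanner) and the unit
#' symmetry axis (`gx`, `gy`, `gz`) of the axisymmetric b-tensor. Row order
#' is preserved: row i of any signal vector corresponds to measurement i.
#'
#' @param tau_e echo times, seconds (positive).
#' @param b b-values, s m^-2 (non-negative).
#' @param b_delta normalised b-tensor anisotropies in `[-0.5, 1]`.
#' @param direction M x 3 matrix of unit vectors (rows may be arbitrary
#'   unit vectors where `b = 0`).
#' @return a `data.frame` of class `rd_scheme` with columns
#'   `tau_e`, `b`, `b_delta`, `gx`, `gy`, `gz`.
#' @export
rd_scheme <- function(tau_e, b, b_delta, direction) {
  direction <- rbind(direction)
  n <- max(length(tau_e), length(b), length(b_delta), nrow(direction))
  tau_e <- rep_len(as.numeric(tau_e), n)
  b <- rep_len(as.numeric(b), n)
  b_delta <- rep_len(as.numeric(b_delta), n)
  if (nrow(direction) == 1L) direction <- direction[rep(1L, n), , drop = FALSE]
  if (nrow(direction) != n || ncol(direction) != 3L)
    stop("direction must be an M x 3 matrix")
  if (n < 1L) stop("a scheme needs at least one measurement")
  if (any(!is.finite(tau_e)) || any(tau_e <= 0))
    stop("tau_e must be positive and finite")
  if (any(b < 0)) stop("b must be non-negative")
  if (any(b_delta < -0.5 | b_delta > 1))
    stop("b_delta must lie in [-0.5, 1]")
  nrm <- sqrt(rowSums(direction^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("directions must be unit vectors (tolerance 1e-6)")
  direction <- direction / nrm
  x <- data.frame(tau_e = tau_e, b = b, b_delta = b_delta,
                  gx = direction[, 1], gy = direction[, 2],
                  gz = direction[, 3])
  class(x) <- c("rd_scheme", "data.frame")
  x
}

scheme_directions <- function(scheme) {
  as.matrix(scheme[, c("gx", "gy", "gz")])
}

#' Subset a scheme by measurement index (used by the bootstrap)
#'
#' @param scheme an [rd_scheme()].
#' @param idx integer indices into the measurement rows (repeats allowed).
#' @return the re-indexed `rd_scheme`.
#' @export
scheme_subset <- function(scheme, idx) {
  x <- as.data.frame(scheme)[idx, , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("rd_scheme", "data.frame")
  x
}

#' Write / read a protocol table
#'
#' Plain TSV with columns `tau_e_ms`, `b_si`, `b_delta`, `gx`, `gy`, `gz`
#' (echo time in milliseconds, b-value in SI s m^-2), one row per acquired
#' volume. The round trip is exact to the printed precision (17 significant
#' digits).
#'
#' @param scheme an [rd_scheme()].
#' @param path file path.
#' @return `read_protocol` returns an `rd_scheme`;
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(scheme, path) {
  out <- data.frame(tau_e_ms = scheme$tau_e * 1e3, b_si = scheme$b,
                    b_delta = scheme$b_delta, gx = scheme$gx,
                    gy = scheme$gy, gz = scheme$gz)
  for (j in seq_along(out)) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_protocol
#' @param b_unit unit of the b column in the file: `"si"` (s m^-2, default)
#'   or `"s_mm2"` (s mm^-2, multiplied by 1e6 on read).
#' @export
read_protocol <- function(path, b_unit = c("si", "s_mm2")) {
  b_unit <- match.arg(b_unit)
  x <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("tau_e_ms", "b_si", "b_delta", "gx", "gy", "gz")
  if (!all(need %in% names(x)))
    stop("protocol file must have columns ", paste(need, collapse = ", "))
  b <- x$b_si * if (b_unit == "s_mm2") 1e6 else 1
  rd_scheme(tau_e = x$tau_e_ms * 1e-3, b = b, b_delta = x$b_delta,
            direction = as.matrix(x[, c("gx", "gy", "gz")]))
}
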