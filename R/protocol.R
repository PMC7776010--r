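#' Built-in 5D relaxation-diffusion shell table
#'
#' The shell structure of the 666-point multi-echo b-tensor protocol used
#' throughout this package: Stejskal-Tanner (`b_delta = 1, ST`) shells at
#' short echo time and at high b, plus linear, prolate, spherical and
#' planar b-tensor shells repeated over echo times of 80/110/150 ms.
#' Spherical (`b_delta = 0`) shells at 80 ms are repeated for six gradient
#' axis permutations of the waveform. In addition to these 666 points the
#' in vivo protocol acquires a handful of reversed-blip b = 0 volumes for
#' distortion correction (quoted as a 686-point session); those correction
#' volumes carry no extra encoding information and are not part of the
#' table.
#'
#' @return a list of shell rows, each with elements `b_delta`, `label`,
#'   `tau_e_ms`, `b_1e9` (b-values in 1e9 s m^-2), `counts` (printed
#'   direction counts; one fewer than the b-values), `n_perm`, `total`.
#' @export
default_shells <- function() {
  list(
    list(b_delta = 1,    label = "ST", tau_e_ms = 60,
         b_1e9 = c(0, 0.1, 0.7, 1.4, 2.0), counts = c(6, 6, 12, 30),
         n_perm = 1, total = 54),
    list(b_delta = 1,    label = "ST", tau_e_ms = 80,
         b_1e9 = c(0, 0.1, 0.8, 2.0, 4.0), counts = c(6, 6, 16, 50),
         n_perm = 1, total = 78),
    list(b_delta = 1,    label = "",   tau_e_ms = c(80, 110, 150),
         b_1e9 = c(0, 0.1, 0.7, 1.4, 2.0), counts = c(6, 6, 12, 30),
         n_perm = 1, total = 162),
    list(b_delta = 0.5,  label = "",   tau_e_ms = c(80, 110, 150),
         b_1e9 = c(0, 0.1, 0.7, 1.4, 2.0), counts = c(6, 6, 10, 16),
         n_perm = 1, total = 114),
    list(b_delta = 0,    label = "",   tau_e_ms = 80,
         b_1e9 = c(0, 0.3, 1.0, 2.0), counts = c(6, 6, 6),
         n_perm = 6, total = 108),
    list(b_delta = 0,    label = "",   tau_e_ms = c(80, 110, 150),
         b_1e9 = c(0, 0.1, 0.7, 1.4), counts = c(4, 4, 4),
         n_perm = 1, total = 36),
    list(b_delta = -0.5, label = "",   tau_e_ms = c(80, 110, 150),
         b_1e9 = c(0, 0.1, 0.7, 1.4, 2.0), counts = c(6, 6, 10, 16),
         n_perm = 1, total = 114)
  )
}

#' Expand a shell table into a full acquisition scheme
#'
#' Each shell row lists one more b-value (leading `b = 0`) than direction
#' counts. The builder acquires `b = 0` once per repetition (echo time x
#' waveform permutation) and lets the first printed count cover the pair
#' `{b = 0, first non-zero b}`: counts `(c1, c2, ...)` over b-values
#' `(0, b1, b2, ...)` expand to `1, c1 - 1, c2, ...` measurements. This
#' mapping reproduces every printed per-row total exactly (the row totals,
#' not the per-b split, are the verifiable quantities). Directions are
#' generated per (row, b-value) by electrostatic repulsion on the
#' half-sphere and reused across echo times and permutations.
#'
#' @param shells a list of shell rows as returned by [default_shells()];
#'   the optional `total` element is checked against the expansion.
#' @param seed integer seed for the direction-set generation.
#' @return an [rd_scheme()] with one row per acquired volume.
#' @export
protocol_from_table <- function(shells, seed = 1L) {
  if (length(shells) == 0L) stop("empty shell table")
  rows <- list()
  for (r in seq_along(shells)) {
    sh <- shells[[r]]
    b <- sh$b_1e9 * 1e9
    counts <- sh$counts
    n_perm <- if (is.null(sh$n_perm)) 1L else sh$n_perm
    if (length(b) < 2L || b[1] != 0)
      stop("shell row ", r, ": b-values must start at b = 0")
    if (length(counts) != length(b) - 1L)
      stop("shell row ", r, ": need one direction count per non-zero ",
           "b-value (got ", length(counts), " counts for ",
           length(b) - 1L, " non-zero b-values)")
    if (counts[1] < 2L)
      stop("shell row ", r, ": first count must be >= 2 (it covers b = 0 ",
           "plus the first non-zero shell)")
    per_b <- c(1L, counts[1] - 1L, counts[-1])
    dirs <- vector("list", length(b))
    for (k in seq_along(b)) {
      nk <- per_b[k]
      dirs[[k]] <- if (nk == 1L) matrix(c(0, 0, 1), 1) else
        repulsion_directions(nk, hemisphere = TRUE,
                             seed = derive_seed(seed, r, k))
    }
    n_rep <- length(sh$tau_e_ms) * n_perm
    got <- sum(per_b) * n_rep
    if (!is.null(sh$total) && got != sh$total)
      stop("shell row ", r, ": expansion yields ", got,
           " measurements but the row total says ", sh$total)
    for (te in sh$tau_e_ms) for (p in seq_len(n_perm)) {
      for (k in seq_along(b)) {
        nk <- per_b[k]
        rows[[length(rows) + 1L]] <- data.frame(
          tau_e = rep(te * 1e-3, nk), b = rep(b[k], nk),
          b_delta = rep(sh$b_delta, nk),
          gx = dirs[[k]][, 1], gy = dirs[[k]][, 2], gz = dirs[[k]][, 3])
      }
    }
  }
  x <- do.call(rbind, rows)
  rd_scheme(x$tau_e, x$b, x$b_delta, as.matrix(x[, c("gx", "gy", "gz")]))
}

#' The default 666-point acquisition scheme
#'
#' @param seed integer seed for direction generation.
#' @return an [rd_scheme()] of 666 measurements expanding
#'   [default_shells()].
#' @export
default_protocol <- function(seed = 1L) {
  protocol_from_table(default_shells(), seed = seed)
}
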