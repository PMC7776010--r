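# Shared fixtures, built lazily and cached for the whole run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

scheme_666 <- function() fixture("scheme666", function() default_protocol(1L))

mesh_300 <- function() fixture("mesh300", function()
  make_mesh(300, seed = 2L, max_iter = 300L))

mesh_1000 <- function() fixture("mesh1000", function()
  make_mesh(1000, seed = 3L))

mesh_3994 <- function() fixture("mesh3994", function()
  make_mesh(3994, seed = 3L))

# Compact multi-echo b-tensor scheme: enough (tau_e, b, b_delta,
# orientation) variety to invert simple systems quickly in unit tests.
scheme_small <- function() fixture("scheme_small", function() {
  dirs6 <- repulsion_directions(6, hemisphere = TRUE, seed = 4L)
  dirs10 <- repulsion_directions(10, hemisphere = TRUE, seed = 5L)
  rows <- list()
  add <- function(te, b, bd, dirs) {
    n <- nrow(dirs)
    rows[[length(rows) + 1L]] <<- data.frame(
      tau_e = te, b = b, b_delta = bd,
      gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3])
  }
  z <- matrix(c(0, 0, 1), 1)
  for (te in c(0.063, 0.09, 0.13)) {
    add(te, 0, 1, z)
    add(te, 1e9, 1, dirs10)
    add(te, 2e9, 1, dirs10)
    add(te, 0.5e9, 0, z)
    add(te, 1.5e9, 0, z)
    add(te, 1e9, -0.5, dirs6)
  }
  x <- do.call(rbind, rows)
  rd_scheme(x$tau_e, x$b, x$b_delta, as.matrix(x[, c("gx", "gy", "gz")]))
})

# Exhaustive-support NNLS oracle: the global non-negative optimum equals
# the best feasible unconstrained fit over all column subsets.
nnls_enumerate <- function(K, s) {
  n <- ncol(K)
  best <- sum(s^2)
  for (code in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    cf <- tryCatch(qr.coef(qr(K[, sel, drop = FALSE]), s),
                   error = function(e) NULL)
    if (is.null(cf) || anyNA(cf) || any(cf < 0)) next
    r <- s - K[, sel, drop = FALSE] %*% cf
    best <- min(best, sum(r^2))
  }
  best
}

# Independent brute-force Watson sum (scalar double loop)
odf_loop_oracle <- function(thin, vertices, kappa) {
  out <- numeric(nrow(vertices))
  for (v in seq_len(nrow(vertices))) {
    acc <- 0
    for (i in seq_len(nrow(thin))) {
      u <- c(cos(thin$phi[i]) * sin(thin$theta[i]),
             sin(thin$phi[i]) * sin(thin$theta[i]),
             cos(thin$theta[i]))
      acc <- acc + thin$weight[i] * exp(kappa * sum(vertices[v, ] * u)^2)
    }
    out[v] <- acc
  }
  out
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# fake minimal mesh wrapper around chosen vertices (odf_single and
# orientation_means only use $vertices)
vertex_mesh <- function(V) list(vertices = rbind(V))
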