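test_that("candidate sampling respects the box, the scales and the seed", {
  rg <- sampling_ranges()
  set.seed(10)
  cs <- sample_candidates(rg, 200)
  expect_equal(nrow(cs), 200)
  expect_true(all(log10(cs$r2) > 0 & log10(cs$r2) < 1.5))
  expect_true(all(log10(cs$d_par) > -11.3 & log10(cs$d_par) < -8.3))
  expect_true(all(log10(cs$d_perp) > -11.3 & log10(cs$d_perp) < -8.3))
  expect_true(all(cos(cs$theta) > 0 & cos(cs$theta) < 1))
  expect_true(all(cs$weight == 0))
  set.seed(77); a <- sample_candidates(rg, 50)
  set.seed(77); b <- sample_candidates(rg, 50)
  expect_identical(a, b)
  # marginal of log10(R2) is uniform on (0, 1.5)
  set.seed(11)
  big <- sample_candidates(rg, 1e5)
  ks <- suppressWarnings(ks.test(log10(big$r2), "punif", 0, 1.5))
  expect_gt(ks$p.value, 0.01)
  expect_error(sampling_ranges(log10_r2 = c(1, 1)), "degenerate")
})

test_that("NNLS solves trivial systems and matches two independent oracles", {
  f <- nnls_fit(diag(2), c(1, 0))
  expect_equal(f$w, c(1, 0))
  expect_equal(f$ssr, 0)
  f0 <- nnls_fit(matrix(runif(12), 4), rep(0, 4))
  expect_equal(f0$w, rep(0, 3))
  expect_equal(f0$ssr, 0)
  expect_error(nnls_fit(matrix(c(1, NA, 0, 1), 2), c(1, 1)), "finite")
  set.seed(12)
  for (rep in 1:20) {
    K <- matrix(rnorm(50), 10, 5)
    s <- as.vector(K %*% pmax(rnorm(5), 0) + 0.3 * rnorm(10))
    f <- nnls_fit(K, s)
    expect_true(all(f$w >= 0))
    expect_lte(f$ssr, sum(s^2) + 1e-12)
    expect_equal(f$ssr, nnls_enumerate(K, s), tolerance = 1e-8)
    p <- pracma::lsqnonneg(K, s)
    expect_equal(f$ssr, p$resid.norm, tolerance = 1e-8)
  }
  # KKT: gradient non-positive on active set, ~zero on support
  K <- matrix(rnorm(200), 20, 10)
  s <- as.vector(K %*% pmax(rnorm(10), 0) + 0.1 * rnorm(20))
  f <- nnls_fit(K, s)
  g <- as.vector(t(K) %*% (s - K %*% f$w))
  expect_true(all(g[f$w == 0] < 1e-8))
  expect_true(all(abs(g[f$w > 0]) < 1e-8))
})

test_that("proliferation accumulates survivors with non-increasing residuals", {
  sch <- scheme_small()
  sys <- make_crossing_system(1, 0, 0.1, 1)
  s <- forward_signal(sch, sys$components)
  ratios <- sapply(c(13, 23, 33), function(seed) {
    set.seed(seed)
    sol <- proliferate(sch, s)
    expect_true(all(diff(sol$ssr_trace) <= 1e-12))
    expect_lte(nrow(sol$components), nrow(sch))  # NNLS support bound
    expect_true(all(sol$components$weight > 0))
    sol$ssr / sum(s^2)
  })
  expect_lt(median(ratios), 1e-3)  # typical 20-round relative residual
  # a single round is exactly one sample + NNLS pass
  cfg1 <- mc_config(n_p = 1)
  set.seed(14)
  sol1 <- proliferate(sch, s, config = cfg1)
  set.seed(14)
  cand <- sample_candidates(sampling_ranges(), cfg1$n_in)
  fit <- nnls_fit(build_kernel_matrix(sch, cand), s)
  expect_equal(sol1$ssr, fit$ssr, tolerance = 1e-12)
  expect_equal(sum(sol1$components$weight), sum(fit$w), tolerance = 1e-10)
})

test_that("mutation is monotone, no-ops at zero scale, and refines the fit", {
  sch <- scheme_small()
  sys <- make_crossing_system(2, 60, 0.1, 1)
  s <- forward_signal(sch, sys$components)
  set.seed(15)
  sol <- proliferate(sch, s)
  frozen <- mutate(sol, sch, s, config = mc_config(mutation_scale = 0))
  expect_equal(frozen$ssr, sol$ssr, tolerance = 1e-10)
  improved <- 0L
  for (k in 1:8) {
    set.seed(100 + k)
    p <- proliferate(sch, s, config = mc_config(n_p = 10))
    m <- mutate(p, sch, s, config = mc_config(n_m = 20))
    expect_true(all(diff(m$ssr_trace) <= 1e-12))
    expect_lte(m$ssr, p$ssr + 1e-15)
    if (m$ssr < p$ssr * 0.99) improved <- improved + 1L
  }
  expect_gte(improved, 7L)  # mutation nearly always refines markedly
})

test_that("per-voxel solve truncates, recovers a single component, flags zero signal", {
  sch <- scheme_small()
  sys <- make_crossing_system(1, 0, 0.1, 1)
  s <- forward_signal(sch, sys$components)
  set.seed(16)
  sol <- solve_voxel(sch, s)
  expect_lte(nrow(sol$components), 20)
  dd <- diso_ddelta(sol$components$d_par, sol$components$d_perp)
  mlog <- sum(sol$components$weight * log10(dd$d_iso)) /
    sum(sol$components$weight)
  expect_lt(abs(mlog - log10(0.75e-9)), 0.05)
  z <- solve_voxel(sch, rep(0, nrow(sch)))
  expect_equal(nrow(z$components), 0)
  expect_true(isTRUE(z$empty))
})

test_that("bootstrap ensembles are reproducible and structured", {
  sch <- scheme_small()
  sys <- make_crossing_system(1, 0, 0.1, 1)
  s <- forward_signal(sch, sys$components) +
    0.003 * rnorm(nrow(sch))
  cfg <- mc_config(n_p = 6, n_m = 6, n_boot = 3, seed = 21)
  e1 <- bootstrap_invert(sch, s, config = cfg)
  e2 <- bootstrap_invert(sch, s, config = cfg)
  expect_equal(length(e1$solutions), 3)
  expect_identical(e1$resample_indices, e2$resample_indices)
  expect_equal(e1$solutions[[2]]$components, e2$solutions[[2]]$components)
  expect_equal(dim(e1$resample_indices), c(3L, nrow(sch)))
  for (sol in e1$solutions) {
    expect_true(all(is.finite(sol$components$weight)))
    expect_true(all(sol$components$weight > 0))
    expect_gte(sol$ssr, 0)
  }
  # stratified mode preserves per-shell measurement counts
  es <- bootstrap_invert(sch, s, config = cfg, stratified = TRUE)
  shell <- paste(sch$tau_e, sch$b, sch$b_delta)
  for (nb in 1:3) {
    idx <- es$resample_indices[nb, ]
    expect_equal(table(shell[idx]), table(shell), ignore_attr = TRUE)
  }
})
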