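test_that("second Legendre polynomial has the right values and domain", {
  expect_equal(p2_legendre(1), 1)
  expect_equal(p2_legendre(-1), 1)
  expect_equal(p2_legendre(0), -0.5)
  expect_equal(p2_legendre(cos(54.7356 * pi / 180)), 0, tolerance = 1e-6)
  expect_error(p2_legendre(1.1), "<=")
})

test_that("isotropic diffusivity and anisotropy conversions invert", {
  expect_equal(diso_ddelta(1e-9, 1e-9), list(d_iso = 1e-9, d_delta = 0))
  expect_equal(diso_ddelta(3e-9, 0), list(d_iso = 1e-9, d_delta = 1))
  # D_iso = 0.75e-9 with D_delta = 0.9 corresponds to the fibre tensor
  dd <- diso_ddelta(2.1e-9, 0.075e-9)
  expect_equal(dd$d_iso, 0.75e-9)
  expect_equal(dd$d_delta, 0.9)
  back <- dpar_dperp(dd$d_iso, dd$d_delta)
  expect_equal(back$d_par, 2.1e-9)
  expect_equal(back$d_perp, 0.075e-9)
  expect_error(diso_ddelta(0, 0), "both")
  # range of d_delta over random nonnegative eigenvalue pairs
  set.seed(1)
  dp <- runif(200, 0, 3e-9); dq <- runif(200, 0, 3e-9)
  dd <- diso_ddelta(dp, dq)
  expect_true(all(dd$d_delta >= -0.5 - 1e-12 & dd$d_delta <= 1 + 1e-12))
})

test_that("beta_angle is the smallest (sign-invariant) axis angle", {
  z <- c(0, 0, 1); x <- c(1, 0, 0)
  expect_equal(beta_angle(z, z), 0)
  expect_equal(beta_angle(z, -z), 0)
  expect_equal(beta_angle(z, x), pi / 2)
  expect_error(beta_angle(z, c(1, 1, 1)), "unit")
  set.seed(2)
  u <- matrix(rnorm(30), 10); u <- u / sqrt(rowSums(u^2))
  v <- matrix(rnorm(30), 10); v <- v / sqrt(rowSums(v^2))
  b <- beta_angle(u, v)
  expect_true(all(b >= 0 & b <= pi / 2 + 1e-12))
})

test_that("kernel evaluates the relaxation-diffusion decay exactly", {
  c1 <- rd_components(r2 = 1 / 0.06, d_par = 2.1e-9, d_perp = 0.075e-9,
                      theta = 0, phi = 0, weight = 1)
  # vanishing weighting: kernel tends to 1
  m0 <- rd_scheme(tau_e = 1e-9, b = 0, b_delta = 1, direction = c(0, 0, 1))
  expect_equal(kernel_value(m0, c1), 1, tolerance = 1e-6)
  # magic-angle linear encoding removes the anisotropic term
  bm <- 54.7356 * pi / 180
  mm <- rd_scheme(tau_e = 0.08, b = 2e9, b_delta = 1,
                  direction = c(sin(bm), 0, cos(bm)))
  expect_equal(kernel_value(mm, c1),
               exp(-0.08 / 0.06) * exp(-2e9 * 0.75e-9), tolerance = 1e-6)
  # aligned linear encoding at b = 2e9: exp(-80/60) exp(-2 * 0.75 * 2.8)
  ma <- rd_scheme(tau_e = 0.08, b = 2e9, b_delta = 1, direction = c(0, 0, 1))
  expect_equal(kernel_value(ma, c1), 3.9528e-3, tolerance = 1e-4)
})

test_that("kernel matrix matches per-entry evaluation and decays monotonically", {
  set.seed(3)
  sch <- scheme_small()
  comps <- sample_candidates(sampling_ranges(), 7)
  K <- build_kernel_matrix(sch, comps)
  expect_equal(dim(K), c(nrow(sch), 7))
  for (i in sample(nrow(sch), 5)) for (n in seq_len(7)) {
    expect_equal(K[i, n], kernel_value(sch[i, ], comps[n, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_true(all(K > 0 & K <= 1))
  # monotone decay in b along an aligned stick, and in tau_e
  bgrid <- seq(0, 3e9, length.out = 12)
  mb <- rd_scheme(tau_e = 0.08, b = bgrid, b_delta = 1,
                  direction = matrix(c(0, 0, 1), 12, 3, byrow = TRUE))
  kb <- forward_signal(mb, rd_components(10, 2e-9, 0.1e-9, 0, 0, 1))
  expect_true(all(diff(kb) < 0))
  mt <- rd_scheme(tau_e = seq(0.05, 0.2, length.out = 10), b = 0,
                  b_delta = 0, direction = c(0, 0, 1))
  kt <- forward_signal(mt, rd_components(10, 2e-9, 0.1e-9, 0, 0, 1))
  expect_true(all(diff(kt) < 0))
})

test_that("forward signal is linear, mono-exponential at b = 0, and rotation invariant", {
  expect_equal(forward_signal(scheme_small(), rd_components()),
               rep(0, nrow(scheme_small())))
  # b = 0 shell: pure T2 decay with the stated echo-time ratios
  m <- rd_scheme(tau_e = c(0.08, 0.11, 0.15), b = 0, b_delta = 0,
                 direction = c(0, 0, 1))
  s <- forward_signal(m, rd_components(1 / 0.06, 1e-9, 1e-9, 0, 0, 1))
  expect_equal(s[2] / s[1], exp(-0.03 / 0.06), tolerance = 1e-12)
  expect_equal(s[3] / s[2], exp(-0.04 / 0.06), tolerance = 1e-12)
  # linearity in the weights
  set.seed(4)
  a <- sample_candidates(sampling_ranges(), 4); a$weight <- runif(4)
  b <- sample_candidates(sampling_ranges(), 4); b$weight <- runif(4)
  ab <- rbind(a, b)
  expect_equal(forward_signal(scheme_small(), ab),
               forward_signal(scheme_small(), a) +
                 forward_signal(scheme_small(), b), tolerance = 1e-12)
  # joint rotation of measurement axes and component axes changes nothing
  sch <- scheme_small()
  comps <- sample_candidates(sampling_ranges(), 5)
  comps$weight <- runif(5)
  R <- random_rotation()
  G2 <- scheme_directions(sch) %*% t(R)
  sch2 <- rd_scheme(sch$tau_e, sch$b, sch$b_delta, G2)
  U <- cbind(cos(comps$phi) * sin(comps$theta),
             sin(comps$phi) * sin(comps$theta), cos(comps$theta)) %*% t(R)
  th2 <- acos(pmin(1, pmax(-1, U[, 3])))
  ph2 <- atan2(U[, 2], U[, 1]) %% (2 * pi)
  comps2 <- rd_components(comps$r2, comps$d_par, comps$d_perp, th2, ph2,
                          comps$weight)
  expect_equal(forward_signal(sch2, comps2), forward_signal(sch, comps),
               tolerance = 1e-10)
  # spherical encoding is orientation independent
  iso <- sch[sch$b_delta == 0, ]
  class(iso) <- class(sch)
  expect_equal(forward_signal(iso, comps2[, ]),
               forward_signal(iso, rd_components(comps$r2, comps$d_par,
                                                 comps$d_perp,
                                                 runif(5, 0, pi),
                                                 runif(5, 0, 2 * pi),
                                                 comps$weight)),
               tolerance = 1e-12)
})

test_that("shell-table expansion reproduces the printed row totals", {
  shells <- default_shells()
  expect_equal(nrow(protocol_from_table(shells[1], seed = 1)), 54)
  expect_equal(nrow(protocol_from_table(shells[4], seed = 1)), 114)
  sch <- scheme_666()
  expect_equal(nrow(sch), 666)
  # shell composition by b-tensor shape
  expect_equal(sum(sch$b_delta == 1), 54 + 78 + 162)
  expect_equal(sum(sch$b_delta == 0.5), 114)
  expect_equal(sum(sch$b_delta == 0), 108 + 36)
  expect_equal(sum(sch$b_delta == -0.5), 114)
  expect_true(all(abs(rowSums(scheme_directions(sch)^2) - 1) < 1e-9))
  expect_error(protocol_from_table(list()), "empty")
  bad <- shells[[1]]; bad$counts <- c(6, 6)
  expect_error(protocol_from_table(list(bad)), "count")
  bad2 <- shells[[1]]; bad2$total <- 99
  expect_error(protocol_from_table(list(bad2)), "99")
})

test_that("protocol files round-trip", {
  sch <- scheme_small()
  f <- tempfile(fileext = ".tsv")
  write_protocol(sch, f)
  back <- read_protocol(f)
  expect_equal(as.data.frame(back), as.data.frame(sch), tolerance = 1e-15)
  # s/mm^2 unit flag scales b by 1e6
  x <- read.delim(f)
  x$b_si <- x$b_si / 1e6
  write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_protocol(f, b_unit = "s_mm2")
  expect_equal(back2$b, sch$b, tolerance = 1e-9)
})
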