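fib_pars <- dpar_dperp(0.75e-9, 0.9)

watson_odf_on <- function(mesh, theta, phi, weight = NULL, t2 = NULL) {
  n <- length(theta)
  if (is.null(weight)) weight <- rep(1 / n, n)
  if (is.null(t2)) t2 <- rep(0.08, n)
  comps <- rd_components(1 / t2, fib_pars$d_par, fib_pars$d_perp,
                         theta, phi, weight)
  odf_single(comps, mesh, 14.9)
}

test_that("peak extraction finds lobes, thresholds, deduplicates and caps", {
  m <- mesh_300()
  # single fibre along a random axis: one peak within one mesh edge
  set.seed(40)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  amp <- watson_odf_on(m, acos(u[3]), atan2(u[2], u[1]) %% (2 * pi))
  pk <- extract_peaks(amp, m)
  expect_equal(nrow(pk), 1)
  miss <- acos(min(1, abs(sum(unlist(pk[1, c("x", "y", "z")]) * u))))
  expect_lt(miss * 180 / pi, 1.5 * m$median_nn_angle)
  expect_true(pk$z[1] >= 0)
  # two orthogonal equal fibres: two peaks
  amp2 <- watson_odf_on(m, c(0, pi / 2), c(0, 0))
  pk2 <- extract_peaks(amp2, m)
  expect_equal(nrow(pk2), 2)
  # weak lobe below the 10% relative threshold disappears
  amp3 <- watson_odf_on(m, c(0, pi / 2), c(0, 0), weight = c(1, 0.01))
  expect_equal(nrow(extract_peaks(amp3, m)), 1)
  # many well-separated lobes: truncated to the 4 strongest
  th <- c(0, 90, 90, 50, 50, 130) * pi / 180
  ph <- c(0, 0, 90, 45, 225, 135) * pi / 180
  amp4 <- watson_odf_on(m, th, ph, weight = c(6:1) / 21)
  expect_lte(nrow(extract_peaks(amp4, m)), 4)
  # zero ODF: no peaks
  expect_equal(nrow(extract_peaks(rep(0, 300), m)), 0)
})

test_that("peak metrics read the orientation means at the peak vertices", {
  m <- mesh_300()
  comps <- rd_components(c(1 / 0.06, 1 / 0.1), fib_pars$d_par,
                         fib_pars$d_perp, c(0, pi / 2), c(0, 0),
                         c(0.5, 0.5))
  sols <- lapply(1:3, function(i)
    structure(list(components = comps, ssr = 0), class = "rd_solution"))
  ens <- structure(list(solutions = sols, config = mc_config(n_boot = 3)),
                   class = "rd_ensemble")
  odf <- odf_from_ensemble(ens, m)
  pk <- peak_metrics(extract_peaks(odf), odf)
  expect_equal(nrow(pk), 2)
  # the z-ish peak carries T2 = 60 ms, the x-ish peak 100 ms
  t2z <- pk$t2[which.max(abs(pk$z))]
  t2x <- pk$t2[which.max(abs(pk$x))]
  expect_equal(t2z, 0.06, tolerance = 0.03)
  expect_equal(t2x, 0.10, tolerance = 0.03)
})

test_that("population statistics split thin components by nearest peak axis", {
  peaks <- data.frame(vertex = c(1L, 2L), x = c(0, 1), y = c(0, 0),
                      z = c(1, 0), amplitude = c(1, 1))
  comps <- rd_components(c(1 / 0.06, 1 / 0.1), fib_pars$d_par,
                         fib_pars$d_perp, c(0.05, pi / 2), c(0, 0.05),
                         c(0.6, 0.4))
  sols <- lapply(1:4, function(i)
    structure(list(components = comps, ssr = 0), class = "rd_solution"))
  ens <- structure(list(solutions = sols, config = mc_config(n_boot = 4)),
                   class = "rd_ensemble")
  st <- population_stats(ens, peaks)
  med <- st[st$stat == "median", ]
  expect_equal(med$fraction, c(0.6, 0.4))
  expect_equal(med$r2, c(1 / 0.06, 1 / 0.1))
  expect_equal(med$d_iso, rep(0.75e-9, 2))
  expect_equal(med$d_delta2, rep(0.81, 2))
  iqr <- st[st$stat == "iqr", ]
  expect_equal(iqr$r2, c(0, 0))  # identical bootstraps: no dispersion
  # single population: statistics match the thin-bin means
  one <- population_stats(ens, peaks[1, , drop = FALSE])
  expect_equal(one$r2[one$stat == "median"],
               bin_parameter_means(ens, "thin", "r2"), tolerance = 1e-9)
  # exact 45-degree tie goes to the first (lowest-index) peak
  tie <- rd_components(10, fib_pars$d_par, fib_pars$d_perp, pi / 4, 0, 1)
  solt <- list(structure(list(components = tie, ssr = 0),
                         class = "rd_solution"))
  enst <- structure(list(solutions = solt, config = mc_config(n_boot = 1)),
                    class = "rd_ensemble")
  stt <- population_stats(enst, peaks)
  frac <- stt$fraction[stt$stat == "median"]
  expect_equal(frac[1], 1)
  expect_true(is.na(frac[2]))
})

test_that("directional colours follow the absolute-component convention", {
  expect_equal(directional_colors(c(0, 0, 1)), rbind(c(0, 0, 1)))
  expect_equal(directional_colors(c(-1, 0, 0)), rbind(c(1, 0, 0)))
  iso <- rd_components(10, 1e-9, 1e-9, 0.7, 0.3, 1)
  expect_equal(as.vector(directional_colors(iso)), c(0, 0, 0))
  stick <- rd_components(10, 2e-9, 0, pi / 2, 0, 1)  # along x
  expect_equal(as.vector(directional_colors(stick)), c(1, 0, 0),
               tolerance = 1e-12)
  set.seed(41)
  cs <- sample_candidates(sampling_ranges(), 20)
  cols <- directional_colors(cs)
  expect_true(all(cols >= 0 & cols <= 1))
})

test_that("peaks are matched to their antipodally nearest ground-truth fibre", {
  sys <- make_crossing_system(2, 90, 0.1, 1)
  exact <- data.frame(vertex = 1:2, x = c(0, 1), y = c(0, 0), z = c(1, 0),
                      amplitude = c(1, 1), t2 = c(0.06, 0.1),
                      d_iso = rep(0.75e-9, 2), d_delta2 = rep(0.81, 2))
  ev <- evaluate_peaks(exact, sys)
  expect_equal(ev$fibre, c(1, 2))  # one-to-one at 90 degrees
  expect_equal(ev$dbeta_deg, c(0, 0))
  expect_equal(ev$dt2, c(0, 0))
  expect_equal(ev$dd_iso, c(0, 0))
  expect_equal(ev$dd_delta2, c(0, 0))
  # a peak at the antipode of a fibre has zero angular bias
  anti <- data.frame(vertex = 1L, x = 0, y = 0, z = -1, amplitude = 1)
  expect_equal(evaluate_peaks(anti, sys)$dbeta_deg, 0)
  none <- exact[0, ]
  expect_equal(attr(evaluate_peaks(none, sys), "n_peaks"), 0)
})
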