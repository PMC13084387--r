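test_that("MRE conversion matches hand arithmetic and scaling laws", {
  expect_equal(mre_from_ellipticity(0, 0.1995, 0.1), 0)
  got <- mre_from_ellipticity(-36.56, 0.1995, 0.1, 110)
  expect_equal(got, -36.56 * 110 / (10 * 0.1995 * 0.1), tolerance = 1e-12)
  expect_equal(got, -20159, tolerance = 5 / 20159)
  expect_equal(mre_from_ellipticity(-36.56, 2 * 0.1995, 0.1), got / 2,
               tolerance = 1e-12)
  expect_error(mre_from_ellipticity(1, 0, 0.1), "conc")
})

test_that("mass and molar MRE forms agree for consistent parameters", {
  # 66.5 kDa protein, 604.5 residues of mean weight 110
  mass <- mre_from_ellipticity(-36.56, conc = 0.1995, path_length = 0.1,
                               mrw = 110)
  molar <- mre_from_ellipticity(-36.56, conc = 3e-6, path_length = 0.1,
                                n_residues = 66500 / 110, form = "molar")
  expect_equal(mass, molar, tolerance = 1e-9)
})

test_that("Bowman's equation hits its boundary and reported values", {
  expect_equal(as.numeric(helix_fraction(-33000)), 100)
  expect_equal(as.numeric(helix_fraction(-4000)), 0)
  expect_equal(as.numeric(helix_fraction(-22183)), 62.7, tolerance = 1e-3)
  expect_equal(as.numeric(helix_fraction(-7422)), 11.8, tolerance = 1e-3)
})

test_that("helix percent is clamped with the raw value kept", {
  over <- helix_fraction(-40000)
  expect_equal(as.numeric(over), 100)
  expect_gt(attr(over, "raw"), 100)
  under <- helix_fraction(-1000)
  expect_equal(as.numeric(under), 0)
  expect_lt(attr(under, "raw"), 0)
})

test_that("helix fraction decreases strictly in MRE on the open range", {
  mre <- seq(-33000, -4000, length.out = 50)
  raw <- attr(helix_fraction(mre), "raw")
  expect_true(all(diff(raw) < 0))
})

test_that("peak finding locates a Gaussian voltammetric peak", {
  v <- simulate_voltammogram(E_p = 0.95, I_p = 12, width = 0.05)
  p <- find_peak(v)
  expect_equal(p$position, 0.95, tolerance = 0.002 / 0.95)
  pr <- find_peak(v, refine = TRUE)
  expect_equal(pr$position, 0.95, tolerance = 1e-6)
  expect_equal(pr$method, "parabolic")
})

test_that("peak finding breaks ties to the smallest abscissa", {
  sp <- spectrum(1:10, rep(3, 10))
  expect_equal(find_peak(sp)$position, 1)
  expect_error(find_peak(sp, window = c(100, 200)), "range error")
})

test_that("parabolic refinement recovers an exact vertex", {
  sp <- spectrum(c(1, 2, 3), c(1, 4, 1))
  p <- find_peak(sp, refine = TRUE)
  expect_equal(p$position, 2.0, tolerance = 1e-12)
})

test_that("shift/quench table reports blue shifts and percent changes", {
  wl <- 250:400
  base <- 100 * exp(-(wl - 282)^2 / (2 * 15^2))
  final <- 12.75 * exp(-(wl - 278)^2 / (2 * 15^2))  # 4 nm blue, 87.25% down
  tab <- shift_and_quench_table(list(spectrum(wl, base, "0"),
                                     spectrum(wl, final, "80")))
  expect_equal(tab$shift[2], -4)
  expect_equal(tab$percent_change[2], -87.25, tolerance = 1e-9)

  same <- shift_and_quench_table(list(spectrum(wl, base), spectrum(wl, base)))
  expect_true(all(same$shift == 0) && all(same$percent_change == 0))

  doubled <- shift_and_quench_table(list(spectrum(wl, base),
                                         spectrum(wl, 2 * base)))
  expect_equal(doubled$percent_change[2], 100)
  expect_equal(doubled$shift[2], 0)

  expect_error(shift_and_quench_table(list(spectrum(wl, base))),
               "at least 2")
})

test_that("EEM peak table recovers fluorophore peaks under Rayleigh masking", {
  e <- simulate_eem(data.frame(ex = c(280, 230), em = c(350, 343),
                               height = c(248, 198)), rayleigh = TRUE)
  peaks <- eem_peak_table(e, rayleigh_halfwidth = 15)
  expect_gte(nrow(peaks), 2)
  expect_equal(peaks$excitation[1:2], c(280, 230))
  # within one grid step (5 nm ex, 1 nm em)
  expect_lte(abs(peaks$emission[1] - 350), 1)
  expect_lte(abs(peaks$emission[2] - 343), 1)
  expect_equal(peaks$intensity[1], 248, tolerance = 0.01)
  expect_equal(peaks$intensity[2], 198, tolerance = 0.01)
})

test_that("EEM peak table masks ridges and degenerate cases", {
  zero <- simulate_eem(data.frame(ex = numeric(), em = numeric(),
                                  height = numeric()), rayleigh = FALSE)
  expect_equal(nrow(eem_peak_table(zero)), 0)

  on_ridge <- simulate_eem(data.frame(ex = 300, em = 300, height = 50),
                           rayleigh = FALSE)
  expect_equal(nrow(eem_peak_table(on_ridge, rayleigh_halfwidth = 15)), 0)

  small <- eem(c(220, 225), c(220, 226), matrix(1, 2, 2))
  expect_error(eem_peak_table(small, rayleigh_halfwidth = 500),
               "mask covers")
})

test_that("DPV series metrics report potential shift and current trend", {
  series <- lapply(seq(12, 2, length.out = 6), function(ip) {
    ep <- 0.95 + 0.13 * (12 - ip) / 10
    simulate_voltammogram(E_p = ep, I_p = ip, width = 0.05)
  })
  m <- dpv_series_metrics(series)
  expect_equal(m$delta_E_p, 0.13, tolerance = 1e-3)
  expect_true(m$I_p_strictly_decreasing)
  expect_error(dpv_series_metrics(series[1]), "at least 2")
})
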