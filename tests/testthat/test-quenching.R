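test_that("Stern-Volmer fit recovers exact synthetic data", {
  Q <- seq(1e-5, 8e-5, 1e-5)
  y <- 1 + 1e4 * Q
  fit <- stern_volmer_fit(1, 1 / y, Q)
  expect_equal(fit$K_SV, 1e4, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$k_q, fit$K_SV / fit$tau0)

  flat <- stern_volmer_fit(100, rep(100, 8), Q)
  expect_equal(flat$K_SV, 0, tolerance = 1e-9)
})

test_that("k_q is K_SV over tau0 and scales inversely with tau0", {
  Q <- seq(1e-5, 8e-5, 1e-5)
  f <- 1000 / (1 + 3.62e4 * Q)
  fit <- stern_volmer_fit(1000, f, Q, tau0 = 1e-8)
  expect_equal(fit$k_q, 3.62e12, tolerance = 1e-9)
  half <- stern_volmer_fit(1000, f, Q, tau0 = 0.5e-8)
  expect_equal(half$k_q, 2 * fit$k_q, tolerance = 1e-12)
})

test_that("Stern-Volmer fit validates its inputs", {
  Q <- seq(1e-5, 8e-5, 1e-5)
  expect_error(stern_volmer_fit(1000, c(rep(10, 7), -1), Q), "positive")
  expect_error(stern_volmer_fit(1000, c(900, 800), c(1e-5, 2e-5)),
               "at least 3")
  expect_error(stern_volmer_fit(-1, rep(10, 8), Q), "F0")
})

test_that("OLS agrees with the closed-form two-point line to 1e-12", {
  cases <- list(c(1, 2, 3, 7), c(-2, 5, 4, -1), c(0.1, 0.2, 0.3, 0.25))
  for (cs in cases) {
    oracle <- two_point_line(cs[1], cs[2], cs[3], cs[4])
    got <- quenchlab:::ols_line(c(cs[1], cs[3]), c(cs[2], cs[4]))
    expect_equal(got$slope, oracle$slope, tolerance = 1e-12)
    expect_equal(got$intercept, oracle$intercept, tolerance = 1e-12)
  }
})

test_that("mechanism classification follows the K_SV temperature trend", {
  tab <- data.frame(temperature = c(287, 298, 307),
                    K_SV = c(1.25e4, 3.62e4, 7.73e4))
  expect_equal(classify_mechanism(tab)$verdict, "dynamic")
  tab$K_SV <- c(7e4, 5e4, 3e4)
  expect_equal(classify_mechanism(tab)$verdict, "static")
  tie <- data.frame(temperature = c(287, 298), K_SV = c(5e4, 5e4))
  expect_equal(classify_mechanism(tie)$verdict, "indeterminate")
  dup <- data.frame(temperature = c(298, 298), K_SV = c(1, 2))
  expect_error(classify_mechanism(dup), "duplicate")
})

test_that("mechanism call can annotate the diffusion limit on k_q", {
  Q <- seq(1e-5, 8e-5, 1e-5)
  fits <- lapply(c(287, 298), function(T) {
    k <- if (T == 287) 1.25e4 else 3.62e4
    stern_volmer_fit(1000, 1000 / (1 + k * Q), Q, temperature = T)
  })
  mc <- classify_mechanism(fits, annotate_diffusion_limit = TRUE)
  expect_true(all(mc$k_q_exceeds_diffusion_limit))
})

test_that("double-log fit recovers K_a and n without depletion", {
  L <- seq(1e-5, 8e-5, 1e-5)
  K_a <- 1e4
  f0 <- 1000
  f <- f0 / (1 + K_a * L)          # (F0-F)/F = K_a * L, n = 1
  fit <- double_log_fit(f0, f, L, P_T = 0)
  expect_equal(fit$K_a, 1e4, tolerance = 1e-6)
  expect_equal(fit$n, 1, tolerance = 1e-6)
  expect_false(fit$warning_flag)
})

test_that("double-log fit recovers K_a and n under ligand depletion", {
  L <- seq(1e-5, 8e-5, 1e-5)
  f0 <- 1000
  P <- 3e-6
  f <- vapply(L, static_F_oracle, numeric(1), F0 = f0, PT = P,
              Ka = 2.76e4, n = 1)
  fit <- double_log_fit(f0, f, L, P)
  expect_equal(fit$K_a, 2.76e4, tolerance = 1e-4)
  expect_equal(fit$n, 1, tolerance = 1e-4)
})

test_that("double-log fit is invariant to uniform intensity rescaling", {
  L <- seq(1e-5, 8e-5, 1e-5)
  f0 <- 1000
  f <- vapply(L, static_F_oracle, numeric(1), F0 = f0, PT = 3e-6,
              Ka = 2.76e4, n = 1)
  a <- double_log_fit(f0, f, L, 3e-6)
  b <- double_log_fit(f0 * 37.5, f * 37.5, L, 3e-6)
  expect_equal(a$K_a, b$K_a, tolerance = 1e-12)
  expect_equal(a$n, b$n, tolerance = 1e-12)
})

test_that("double-log fit drops bad points with a warning and can fail", {
  L <- seq(1e-5, 8e-5, 1e-5)
  f0 <- 1000
  f <- f0 / (1 + 1e4 * L)
  f[3] <- f0 * 1.01                 # apparent enhancement
  expect_warning(fit <- double_log_fit(f0, f, L, 0), "dropped 1 point")
  expect_equal(fit$dropped, 3L)
  expect_equal(fit$K_a, 1e4, tolerance = 1e-6)
  expect_error(double_log_fit(f0, f0 / (1 + 1e4 * 1e-5), 1e-5, 0),
               "fit error")
})

test_that("percent quench matches direct arithmetic", {
  expect_equal(percent_quench(100, 25), 75)
  expect_equal(percent_quench(100, 100), 0)
  expect_equal(percent_quench(100, 0), 100)
  expect_error(percent_quench(0, 10), "F0")
})

test_that("site-marker comparison assigns the more-perturbed marker's site", {
  ladder <- seq(0, 8e-5, 1e-5)
  plain <- make_dynamic_series(K_SV = 3.62e4, ladder = ladder)
  # premixing with marker A halves the apparent quench; B barely changes it
  markerA <- make_dynamic_series(K_SV = 3.62e4 / 2, ladder = ladder)
  markerB <- make_dynamic_series(K_SV = 3.62e4 * 0.98, ladder = ladder)
  rep1 <- site_marker_comparison(plain, markerA, markerB, wavelength = 347)
  expect_gt(rep1$divergence_A, rep1$divergence_B)
  expect_equal(rep1$assigned_site, "I")

  rep2 <- site_marker_comparison(plain, plain, plain)
  expect_equal(rep2$assigned_site, "indeterminate")

  short <- make_dynamic_series(ladder = seq(0, 7e-5, 1e-5))
  expect_error(site_marker_comparison(plain, markerA, short), "ladders")
})

test_that("K_SV recovery stays within 2% median error at 1% noise", {
  n_seeds <- 200
  errs <- vapply(seq_len(n_seeds), function(s) {
    sim <- simulate_titration(sim_config(seed = s, mechanism = "dynamic",
                                         true_K_SV = 3.62e4,
                                         noise_sigma_rel = 0.01))
    f <- titration_intensities(sim$series, wavelength = 347,
                               smooth_halfwidth = 5)
    fit <- stern_volmer_fit(f[1], f[-1], sim$series$ligand_concs[-1])
    abs(fit$K_SV - 3.62e4) / 3.62e4
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)
})
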