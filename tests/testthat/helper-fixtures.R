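# Closed-form two-point line: the independent oracle for OLS checks.
two_point_line <- function(x1, y1, x2, y2) {
  slope <- (y2 - y1) / (x2 - x1)
  list(slope = slope, intercept = y1 - slope * x1)
}

# Independent root-finding oracle for the static-binding isotherm:
# solves log10((F0-F)/F) = n log10(Ka) + n log10(LT - (F0-F) PT / F0)
# for F by bisection (uniroot), unrelated to the package's fixed-point
# generator.
static_F_oracle <- function(F0, LT, PT, Ka, n) {
  if (LT <= 0) return(F0)
  g <- function(f) {
    free <- LT - (F0 - f) * PT / F0
    if (free <= 0) return(Inf)
    log10((F0 - f) / f) - n * log10(Ka) - n * log10(free)
  }
  stats::uniroot(g, c(F0 * 1e-12, F0 * (1 - 1e-12)), tol = 1e-15)$root
}

# Gaussian-band titration built directly from the Stern-Volmer closed form
# (independent of simulate_titration).
make_dynamic_series <- function(K_SV = 3.62e4, F0 = 1000,
                                ladder = seq(0, 80e-6, 10e-6),
                                temperature = 298, protein_conc = 3e-6,
                                center = 347, sigma = 25) {
  wl <- 300:450
  band <- exp(-(wl - center)^2 / (2 * sigma^2))
  spectra <- lapply(ladder, function(q) {
    spectrum(wl, F0 / (1 + K_SV * q) * band, sprintf("%g", q * 1e6))
  })
  titration_series(temperature, protein_conc, ladder, spectra)
}

table1_Ka <- c(1.25e4, 2.76e4, 5.24e4)
table1_T <- c(287, 298, 307)
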