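test_that("spectrum constructor enforces its invariants", {
  sp <- spectrum(c(300, 301, 302), c(1, 2, 3), "a")
  expect_s3_class(sp, "spectrum")
  expect_error(spectrum(c(300, 301), c(1, 2)), "at least 3")
  expect_error(spectrum(c(300, 301, 302), c(1, 2)), "equal length")
  expect_error(spectrum(c(300, 350, 340), c(1, 2, 3)),
               "strictly increasing")
})

test_that("titration series validates its ladder and spectrum counts", {
  sp <- lapply(1:3, function(i) spectrum(300:310, rep(i, 11)))
  expect_error(titration_series(298, 3e-6, c(1e-5, 2e-5, 3e-5), sp),
               "start at 0")
  expect_error(titration_series(298, 3e-6, c(0, 2e-5), sp),
               "one emission spectrum per")
  expect_error(titration_series(0, 3e-6, c(0, 1e-5, 2e-5), sp),
               "temperature")
  s <- titration_series(298, 3e-6, c(0, 1e-5, 2e-5), sp)
  expect_equal(length(s$emission_spectra), 3)
})

test_that("wide spectral tables round-trip through CSV to 1e-12", {
  wl <- seq(300, 450, 0.5)
  spectra <- list(
    spectrum(wl, 1000 * exp(-(wl - 347)^2 / 1250) + pi * 1e-7, "0"),
    spectrum(wl, 700 * exp(-(wl - 345)^2 / 1250), "10"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_table(spectra, path, kind = "emission")
  back <- read_spectrum_table(path, kind = "emission")
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$abscissa, spectra[[i]]$abscissa,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$signal, spectra[[i]]$signal, tolerance = 1e-12)
    expect_identical(back[[i]]$label, spectra[[i]]$label)
  }
  expect_equal(attr(back, "concentrations_M"), c(0, 10e-6))
})

test_that("malformed spectral tables are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,0,10", "300,1,2", "350,3,4", "340,5,6"), path)
  expect_error(read_spectrum_table(path), "row 4")
  writeLines(c("wavelength_nm,0,0", "300,1,2", "301,3,4"), path)
  expect_error(read_spectrum_table(path), "duplicate")
  writeLines(c("intensity,0", "300,1", "301,2"), path)
  expect_error(read_spectrum_table(path), "wavelength_nm")
  writeLines(c("potential_V,0", "0.5,1", "0.6,2", "0.7,2"), path)
  expect_silent(read_spectrum_table(path, kind = "voltammogram"))
})

test_that("EEM reader accepts the study-shaped matrix and rejects bad files", {
  ex <- seq(220, 350, 5)
  em <- seq(220, 500, 1)
  e <- simulate_eem(data.frame(ex = 280, em = 350, height = 248),
                    ex_grid = ex, em_grid = em)
  path <- withr::local_tempfile(fileext = ".csv")
  write_eem(e, path)
  back <- read_eem(path)
  expect_equal(dim(back$intensity), c(27, 281))
  expect_equal(back$intensity, e$intensity, tolerance = 1e-12,
               ignore_attr = TRUE)

  writeLines(c("x,220,221", "230,1,2,3", "235,1,2"), path)
  expect_error(read_eem(path), "ragged")
  writeLines(c("x,220,221", "230,1,2"), path)
  expect_error(read_eem(path), "at least 2 excitation rows")
})

test_that("a constant EEM is readable and max-finding uses the first cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,220,221,222", "230,5,5,5", "235,5,5,5", "240,5,5,5"), path)
  e <- read_eem(path)
  expect_equal(dim(e$intensity), c(3, 3))
  idx <- which(e$intensity == max(e$intensity), arr.ind = TRUE)[1, ]
  expect_equal(unname(idx), c(1, 1))
})

test_that("result records serialize to JSON (and CSV for tables)", {
  fit <- stern_volmer_fit(1000, 1000 / (1 + 3.62e4 * seq(1e-5, 8e-5, 1e-5)),
                          seq(1e-5, 8e-5, 1e-5))
  path <- withr::local_tempfile(fileext = ".json")
  write_results(fit, path)
  js <- jsonlite::read_json(path)
  expect_true(all(c("K_SV", "k_q", "tau0", "r") %in% names(js)))
  expect_equal(js$K_SV, 3.62e4, tolerance = 1e-9)

  th <- vant_hoff_fit(table1_Ka, table1_T)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_results(th, path2)
  csv <- utils::read.csv(sub("\\.json$", ".csv", path2))
  expect_equal(nrow(csv), 3)
  expect_equal(as.numeric(csv$dG), th$dG_by_T$dG, tolerance = 1e-9)

  expect_error(write_results(list(), path), "empty")
})
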