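test_that("spectrum constructors enforce grid and finiteness invariants", {
  expect_s3_class(spectrum(1:3, c(0, 1, 2)), "anap_spectrum")
  expect_error(spectrum(c(1, 1, 2), 1:3), class = "anap_validation_error")
  expect_error(spectrum(1:3, c(1, NA, 2)), class = "anap_validation_error")
  expect_error(spectrum(1:3, c(1, -1, 2)), class = "anap_validation_error")
  expect_silent(spectrum(1:3, c(1, -1, 2), allow_negative = TRUE))
  expect_error(absorbance_spectrum(c(2, 1), c(0, 0)),
               class = "anap_validation_error")
})

test_that("blank subtraction is pointwise, keeps negatives, rejects grid mismatch", {
  s <- gauss_spectrum()
  zero <- spectrum(s$wavelength, rep(0, length(s$wavelength)))
  expect_equal(subtract_blank(s, zero)$intensity, s$intensity)
  expect_equal(subtract_blank(s, s)$intensity, rep(0, length(s$wavelength)))

  # a blank worth 15.2% of the total at 448 nm leaves 84.8% of the raw signal
  blank <- spectrum(s$wavelength, 0.152 * s$intensity)
  out <- subtract_blank(s, blank)
  at448 <- which(s$wavelength == 448)
  expect_equal(out$intensity[at448], 0.848 * s$intensity[at448])

  shifted <- spectrum(s$wavelength + 0.5, s$intensity)
  err <- tryCatch(subtract_blank(s, shifted), error = function(e) e)
  expect_s3_class(err, "anap_data_error")
  expect_match(conditionMessage(err), "380")

  # negatives retained and flagged
  big <- spectrum(s$wavelength, s$intensity + 1)
  out2 <- subtract_blank(s, big)
  expect_true(all(out2$intensity < 0))
  expect_true(out2$meta$has_negative)
})

test_that("absorbance smoothing preserves constants, interior ramps and the mean", {
  grid <- seq(380, 420, by = 0.5)
  const <- absorbance_spectrum(grid, rep(0.3, length(grid)))
  expect_equal(smooth_absorbance(const)$od, const$od)

  ramp <- absorbance_spectrum(grid, 0.01 * (grid - 380))
  sm <- smooth_absorbance(ramp, bandwidth = 0.25)
  interior <- grid >= 382 & grid <= 418
  expect_equal(sm$od[interior], ramp$od[interior], tolerance = 1e-12)
  expect_equal(mean(sm$od[interior]), mean(ramp$od[interior]),
               tolerance = 1e-3)
  expect_equal(sm$wavelength, ramp$wavelength)

  # bandwidth much smaller than the grid spacing degenerates to the identity
  tiny <- smooth_absorbance(ramp, bandwidth = 0.01)
  expect_equal(tiny$od, ramp$od)
  expect_error(smooth_absorbance(ramp, bandwidth = 0),
               class = "anap_validation_error")
})

test_that("inner-filter correction applies the printed factor and is monotone", {
  grid <- 400:500
  s <- flat_spectrum(1, grid)
  ab0 <- absorbance_spectrum(grid, rep(0, length(grid)))
  expect_equal(inner_filter_correct(s, 0, ab0)$intensity, s$intensity)

  ab05 <- absorbance_spectrum(grid, rep(0.5, length(grid)))
  out <- inner_filter_correct(s, 1.0, ab05)
  expect_equal(out$intensity, rep(10^0.35, length(grid)), tolerance = 1e-12)

  ab2 <- absorbance_spectrum(grid, rep(2.0, length(grid)))
  expect_equal(inner_filter_correct(s, 0, ab2)$intensity,
               rep(10, length(grid)), tolerance = 1e-12)

  # monotone nondecreasing in OD_ex and OD_em; factor >= 1 for ODs >= 0
  for (odex in c(0, 0.5, 1)) {
    prev <- NULL
    for (odem in c(0, 0.3, 0.9)) {
      ab <- absorbance_spectrum(grid, rep(odem, length(grid)))
      v <- inner_filter_correct(s, odex, ab)$intensity[1]
      expect_gte(v, 1)
      if (!is.null(prev)) expect_gte(v, prev)
      prev <- v
    }
  }

  narrow <- absorbance_spectrum(420:480, rep(0.1, 61))
  expect_error(inner_filter_correct(s, 0, narrow), class = "anap_data_error")
})

test_that("band mean averages inclusively on the measured grid", {
  expect_equal(band_mean(flat_spectrum(3)), 3)
  ramp <- spectrum(380:600, as.numeric(380:600))
  expect_equal(band_mean(ramp, 445, 455), 450)  # symmetric grid -> midpoint
  s <- gauss_spectrum()
  single <- band_mean(s, 447.5, 448.5)  # one grid point at 448
  expect_equal(single, s$intensity[s$wavelength == 448])
  expect_error(band_mean(s, 455, 445), class = "anap_validation_error")
  expect_error(band_mean(s, 600.5, 601.5), class = "anap_data_error")
})

test_that("band mean is linear under blank subtraction", {
  s <- gauss_spectrum(451)
  b <- gauss_spectrum(460, amplitude = 10)
  expect_equal(band_mean(subtract_blank(s, b)),
               band_mean(s) - band_mean(b), tolerance = 1e-12)
})

test_that("peak wavelength takes the argmax with short-wavelength tie-break", {
  expect_equal(peak_wavelength(gauss_spectrum(451)), 451)
  expect_equal(peak_wavelength(gauss_spectrum(447)), 447)  # -4 nm shift
  two <- spectrum(c(440, 450, 460), c(1, 0.5, 1))
  expect_equal(peak_wavelength(two), 440)
  expect_warning(pk <- peak_wavelength(flat_spectrum()), "flat")
  expect_equal(pk, 380)
})

test_that("spectrum CSV round trip reproduces values and text exactly", {
  s <- gauss_spectrum()
  s$meta$sample_id <- "demo"
  s$meta$excitation_nm <- 370
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, p1)
  r <- read_spectrum_csv(p1)
  expect_identical(r$wavelength, s$wavelength)
  expect_identical(r$intensity, s$intensity)
  expect_equal(r$meta$excitation_nm, 370)
  write_spectrum_csv(r, p2)
  expect_identical(readLines(p1), readLines(p2))

  ab <- absorbance_spectrum(380:420, seq(0.31, 0.71, by = 0.01))
  pa <- tempfile(fileext = ".csv")
  write_absorbance_csv(ab, pa)
  expect_identical(read_absorbance_csv(pa)$od, ab$od)
})
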