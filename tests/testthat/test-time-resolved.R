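test_that("decay trace and IRF constructors enforce their invariants", {
  g <- trace_grid(10)
  expect_error(decay_trace(c(0, 0.4, 0.9), c(1, 1, 1)),
               class = "anap_validation_error")  # non-uniform
  expect_error(irf(g, rep(-1, length(g))), class = "anap_validation_error")
  expect_message(ir <- irf(g, exp(-g)), "normalizing")
  expect_equal(sum(ir$response), 1, tolerance = 1e-12)
})

test_that("TAS construction matches the log-ratio law and masks nonpositive bins", {
  g <- trace_grid(10)
  n <- length(g)
  unp <- decay_trace(g, rep(100, n))
  fl <- decay_trace(g, rep(20, n))

  null_tr <- build_tas_trace(decay_trace(g, rep(120, n)), unp, fl)
  expect_equal(null_tr$signal, rep(0, n))

  p <- rep(120, n)
  p[5] <- 70   # numerator 50 = 0.5 x unpumped
  p[6] <- 220  # numerator 200 = 2 x unpumped
  p[7] <- 10   # numerator -10: masked
  tr <- build_tas_trace(decay_trace(g, p), unp, fl)
  expect_equal(tr$signal[5], 0.30103, tolerance = 1e-5)
  expect_equal(tr$signal[6], -0.30103, tolerance = 1e-5)
  expect_true(tr$mask[7])
  expect_equal(tr$meta$n_masked_nonpositive, 1)

  # inverse transform reproduces the intensity ratio on unmasked bins
  ratio <- 10^(-tr$signal)
  expect_equal(ratio[!tr$mask], ((p - 20) / 100)[!tr$mask], tolerance = 1e-12)

  bad <- decay_trace(g, rep(10, n))
  expect_error(build_tas_trace(bad, unp, fl), class = "anap_data_error")
  expect_error(build_tas_trace(decay_trace(g, c(rep(120, n))),
                               decay_trace(g, c(rep(0, n))), fl),
               class = "anap_data_error")
})

test_that("background subtraction isolates the fast component of a mixture", {
  g <- trace_grid(60)
  ir <- simulate_irf(8, g, 20)
  mixture <- decay_trace(g, convolve_with_irf(ir, "exp2",
    list(lifetimes = c(2.14, 6), amplitudes = c(300, 150)), g))
  slow <- decay_trace(g, convolve_with_irf(ir, "exp1",
    list(lifetimes = 6, amplitudes = 150), g))
  resid <- subtract_background_trace(mixture, slow)
  f <- fit_reconvolution(resid, ir, model = "exp1", weighting = "uniform")
  expect_equal(f$lifetimes, 2.14, tolerance = 1e-6)

  zero <- decay_trace(g, rep(0, length(g)))
  expect_equal(subtract_background_trace(mixture, zero)$signal, mixture$signal)
  expect_equal(subtract_background_trace(mixture, mixture)$signal,
               rep(0, length(g)))
  tas <- decay_trace(g, rep(1, length(g)), kind = "tas")
  expect_error(subtract_background_trace(mixture, tas),
               class = "anap_data_error")
})

test_that("convolution has a delta identity, is linear, and preserves area", {
  g <- trace_grid(80)
  d <- delta_irf(g)
  pars <- list(lifetimes = 2, amplitudes = 5)
  expect_equal(convolve_with_irf(d, "exp1", pars, g),
               5 * exp(-g / 2), tolerance = 1e-9)

  ir <- simulate_irf(8, g, 20)
  h1 <- convolve_with_irf(ir, "exp1", list(lifetimes = 2, amplitudes = 1), g)
  h2 <- convolve_with_irf(ir, "exp1", list(lifetimes = 7, amplitudes = 1), g)
  h12 <- convolve_with_irf(ir, "exp2",
                           list(lifetimes = c(2, 7), amplitudes = c(3, 4)), g)
  expect_equal(h12, 3 * h1 + 4 * h2, tolerance = 1e-10)

  # unit-area kernel: constant passes through on interior points
  so <- convolve_with_irf(ir, "second_order",
                          list(rate = 0, amplitudes = 2), g)
  interior <- g > 45
  expect_equal(so[interior], rep(2, sum(interior)), tolerance = 1e-3)

  # discrete integral preserved within 0.1 percent away from edges
  bare <- exp(-pmax(g - 0, 0) / 2.776)
  conv <- convolve_with_irf(ir, "exp1",
                            list(lifetimes = 2.776, amplitudes = 1), g)
  expect_equal(sum(conv), sum(bare), tolerance = 1e-3)

  expect_error(convolve_with_irf(ir, "exp1",
                                 list(lifetimes = -1, amplitudes = 1), g),
               class = "anap_validation_error")
})

test_that("reconvolution fitting recovers noiseless parameters in every model class", {
  g <- trace_grid(80)
  d <- delta_irf(g)
  tr <- decay_trace(g, 100 * exp(-g / 2))
  f <- fit_reconvolution(tr, d, model = "exp1", weighting = "uniform")
  expect_equal(f$lifetimes, 2, tolerance = 1e-6)

  ir <- simulate_irf(8, g, 20)
  tr1 <- decay_trace(g, convolve_with_irf(ir, "exp1",
    list(lifetimes = 2.776, amplitudes = 1000), g))
  f1 <- fit_reconvolution(tr1, ir, model = "exp1", weighting = "uniform")
  expect_equal(f1$lifetimes, 2.776, tolerance = 1e-3)
  expect_lt(abs(f1$t0), 1e-3)
  expect_lt(abs(f1$baseline) / 1000, 1e-6)

  tr2 <- decay_trace(g, convolve_with_irf(ir, "exp2",
    list(lifetimes = c(1.5, 7.5), amplitudes = c(800, 300)), g))
  f2 <- fit_reconvolution(tr2, ir, model = "exp2", weighting = "uniform")
  expect_equal(f2$lifetimes, c(1.5, 7.5), tolerance = 1e-3)
  expect_equal(f2$amplitudes, c(800, 300), tolerance = 1e-3)

  trs <- decay_trace(g, convolve_with_irf(ir, "second_order",
    list(rate = 0.4, amplitudes = 500), g))
  fs <- fit_reconvolution(trs, ir, model = "second_order",
                          weighting = "uniform")
  expect_equal(fs$rate, 0.4, tolerance = 1e-3)
})

test_that("model comparison prefers the generating model and parsimony on noise", {
  cfg <- sim_config(seed = 11)
  sim <- simulate_trpl(cfg, "anap", stream = "cmp")
  cmp1 <- compare_decay_models(sim$trace, sim$irf)
  expect_equal(cmp1$ranking$model[1], "exp1")

  g <- trace_grid(80)
  ir <- simulate_irf(8, g, 20)
  y2 <- convolve_with_irf(ir, "exp2",
                          list(lifetimes = c(1.2, 6), amplitudes = c(3000, 1500)), g)
  set.seed(5)
  tr2 <- decay_trace(g, y2 + rnorm(length(g), 0, 2))
  cmp2 <- compare_decay_models(tr2, ir, weighting = "uniform")
  expect_equal(cmp2$ranking$model[1], "exp2")

  set.seed(6)
  noise <- decay_trace(g, 100 + rnorm(length(g), 0, 1))
  cmp3 <- compare_decay_models(noise, ir, weighting = "uniform")
  expect_equal(cmp3$ranking$npar[1], min(cmp3$ranking$npar))
})

test_that("residual plateau distinguishes complete recovery from a step", {
  g <- trace_grid(80)
  ir <- simulate_irf(8, g, 20)
  dec <- convolve_with_irf(ir, "exp1", list(lifetimes = 3, amplitudes = 1), g)
  set.seed(7)
  tr <- decay_trace(g, dec + rnorm(length(g), 0, 1e-4))
  pl <- residual_plateau(tr, c(60, 80))
  expect_true(pl$recovered)

  tr_c <- decay_trace(g, dec + 0.05)
  pl_c <- residual_plateau(tr_c, c(60, 80))
  expect_equal(pl_c$mean, 0.05, tolerance = 1e-2)
  expect_false(pl_c$recovered)

  # (mixture + step) - mixture leaves exactly the step amplitude
  step <- 0.02 * cumsum(ir$response)
  summed <- decay_trace(g, dec + step)
  diff_tr <- subtract_background_trace(summed, tr_c)
  pl_s <- residual_plateau(diff_tr, c(60, 80))
  expect_equal(pl_s$mean, 0.02 - 0.05, tolerance = 1e-3)

  expect_error(residual_plateau(tr, c(79.9, 90)), class = "anap_data_error")
})

test_that("Savitzky-Golay smoothing is exact on polynomials and attenuates noise by the coefficient norm", {
  g <- trace_grid(80)
  quad <- decay_trace(g, 3 + 0.5 * g - 0.01 * g^2)
  expect_equal(savitzky_golay(quad)$signal, quad$signal, tolerance = 1e-9)
  const <- decay_trace(g, rep(4, length(g)))
  expect_equal(savitzky_golay(const)$signal, const$signal, tolerance = 1e-10)
  expect_error(savitzky_golay(quad, window = 20),
               class = "anap_validation_error")
  expect_error(savitzky_golay(quad, window = 5, order = 5),
               class = "anap_validation_error")

  # variance gain oracle: squared norm of the central SG coefficient row
  gain <- sum(signal::sgolay(p = 2, n = 21)[11, ]^2)
  set.seed(8)
  ratios <- replicate(200, {
    tr <- decay_trace(g, rnorm(length(g)))
    sm <- savitzky_golay(tr)$signal
    interior <- 11:(length(g) - 10)
    var(sm[interior]) / var(tr$signal[interior])
  })
  expect_equal(mean(ratios), gain, tolerance = 0.2)
})

test_that("trace CSV round trip preserves values and metadata", {
  g <- trace_grid(20)
  tr <- decay_trace(g, exp(-g / 3) * 1000, kind = "tas", averages = 500)
  p <- tempfile(fileext = ".csv")
  write_trace_csv(tr, p)
  r <- read_trace_csv(p)
  expect_identical(r$signal, tr$signal)
  expect_equal(r$kind, "tas")
  expect_equal(r$averages, 500)

  ir <- simulate_irf(8, g, 10)
  pi <- tempfile(fileext = ".csv")
  write_trace_csv(ir, pi)
  r2 <- read_trace_csv(pi)
  expect_s3_class(r2, "anap_irf")
  expect_equal(r2$response, ir$response, tolerance = 1e-12)
})
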