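# Seeded synthetic-data generators. Every generator derives an independent
# substream seed from the master seed and a stream name, records it in the
# output metadata, and restores the caller's RNG state, so one SimConfig
# reproduces the full dataset bit-identically.

derive_seed <- function(seed, key) {
  # avalanche-hash the (seed, stream name) pair: a linear map of the seed
  # leaves early Mersenne draws correlated across related substreams
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  x <- as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
  for (i in 1:3) {
    x <- bitwXor(x, bitwShiftR(x, 15))
    x <- as.integer((as.numeric(x) * 69069 + 12345) %% 2147483629)
  }
  x
}

with_stream <- function(seed, key, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, key))
  invisible(stats::runif(20))  # burn-in decorrelates first draws
  expr
}

#' Ground-truth configuration for the synthetic generators
#'
#' Collects every parameter of the synthetic experiment in one seeded
#' object; the generators consume it and the recovery tests treat its values
#' as the oracle. Defaults reproduce the study conditions: a 5-HT titration
#' with K_sv = 13.3 per M and intercept 0.98 measured in 445-455 nm band
#' units, TRPL/TAS on 0.4 ns bins under an 8 ns FWHM Gaussian IRF with
#' lifetimes 2.776 ns (ANAP), 2.231 ns (5-HT), 2.14 ns (quenched ANAP) and a
#' 3.18 ns transient product, 64 (TRPL) / 500 (TAS) shot averages, and
#' 6 cells with EC50 594 nM, slope -0.46, 66% mean maximal quench and
#' single-exponential photobleaching.
#'
#' @param seed master integer seed (mandatory; every output records it).
#' @param titration,trpl,tas,cells named lists overriding individual
#'   defaults (partial overrides are merged).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, titration = list(), trpl = list(),
                       tas = list(), cells = list()) {
  if (is.null(seed) || !is.finite(seed))
    stop_validation("a finite integer seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    titration = modifyList(list(
      ksv = 13.3,              # per M
      intercept = 0.98,
      peak_nm = 451, width_nm = 23, amplitude = 1000,
      baseline = 20,           # stray-light floor, shared by sample and blank
      peak_shift_per_M = 0,    # nm per M solvatochromic shift
      blank_fraction_ref = 0.152, ref_conc = 0.1,  # blank share at 448 nm
      blank_peak_nm = 448, blank_width_nm = 45,
      abs370_per_M = 2.0,      # OD per M at 370 nm, linear to 0 at 600 nm
      inner_filter = FALSE,
      concentrations = c(0, 0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1),
      noise_sigma = 0.005,     # additive, relative to amplitude
      replicates = 3,
      grid = seq(380, 600, by = 1), abs_grid = seq(360, 600, by = 1)
    ), titration),
    trpl = modifyList(list(
      tau_ns = c(anap = 2.776, serotonin = 2.231, quenched_anap = 2.14),
      peak_counts = c(anap = 5000, serotonin = 2000, quenched_anap = 3000),
      irf_fwhm = 8, irf_center = 20, bin_ns = 0.4, t_max = 80,
      averages = 64, noise = "poisson"
    ), trpl),
    tas = modifyList(list(
      product_tau = 3.18, product_dod = 0.05,
      i0 = 1000, fluor_scale = 0.3,
      artifact_window = c(16, 23), artifact_amp = 5,  # x i0, inside window
      emi = list(freq_ghz = 0.08, amplitude = 1, damping_ns = 20, phase = 0.7),
      step_dod = 0,            # permanent product offset (0 = full recovery)
      averages = 500, noise_sigma = 0.01, noise = "gaussian",
      irf_fwhm = 8, irf_center = 20, bin_ns = 0.4, t_max = 80
    ), tas),
    cells = modifyList(list(
      ec50 = 594e-9, slope = -0.46,
      max_quench = 0.66, max_quench_sd = 0.17, ec50_cv = 0.10,
      bleach = list(A = 0.3, tau_s = 60, C = 0.7),
      anap_peak = 495, anap_width = 30, anap_amp = 1000,
      morange_peak = 562, morange_width = 25, morange_amp = 600,
      n_cells = 6, noise_sigma = 0.03,
      concentrations = c(1e-8, 3e-8, 1e-7, 3e-7, 1e-6, 3e-6, 1e-5, 1e-4),
      n_pre = 5, exposure_s = 10, preparation = "cell",
      grid = seq(400, 650, by = 1)
    ), cells)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- character()
  tt <- cfg$titration
  if (!any(tt$concentrations == 0)) bad <- c(bad, "titration$concentrations must include 0")
  if (tt$ref_conc <= 0) bad <- c(bad, "titration$ref_conc must be > 0")
  if (tt$blank_fraction_ref < 0 || tt$blank_fraction_ref >= 1)
    bad <- c(bad, "titration$blank_fraction_ref must be in [0, 1)")
  if (any(cfg$trpl$tau_ns <= 0)) bad <- c(bad, "trpl$tau_ns must be > 0")
  if (cfg$tas$product_tau <= 0) bad <- c(bad, "tas$product_tau must be > 0")
  if (diff(cfg$tas$artifact_window) < 0) bad <- c(bad, "tas$artifact_window must be ordered")
  cc <- cfg$cells
  if (cc$ec50 <= 0) bad <- c(bad, "cells$ec50 must be > 0")
  if (cc$max_quench < 0 || cc$max_quench > 1)
    bad <- c(bad, "cells$max_quench must be in [0, 1]")
  if (cc$bleach$tau_s <= 0) bad <- c(bad, "cells$bleach$tau_s must be > 0")
  if (cc$bleach$A + cc$bleach$C <= 0) bad <- c(bad, "cells$bleach A + C must be > 0")
  if (cc$n_cells < 1) bad <- c(bad, "cells$n_cells must be >= 1")
  if (length(bad)) stop_validation(paste("invalid SimConfig:",
                                         paste(bad, collapse = "; ")))
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config seed=%d: titration ksv=%g, trpl taus=%s ns, tas tau=%g ns, cells ec50=%g M>\n",
              x$seed, x$titration$ksv,
              paste(x$trpl$tau_ns, collapse = "/"), x$tas$product_tau,
              x$cells$ec50))
  invisible(x)
}

#' Simulate a single emission band
#'
#' Asymmetric (log-normal in wavelength, red-tailed) emission band with its
#' maximum at `peak`, emulating the shape of ANAP / mOrange emission. The
#' band rises from zero at `peak - 3 * width`.
#'
#' @param peak peak wavelength, nm.
#' @param width width scale, nm, > 0.
#' @param amplitude peak intensity (a.u.).
#' @param grid wavelength grid, must cover `peak +/- 3 * width`.
#' @param meta metadata list for the resulting spectrum.
#' @return An `anap_spectrum` whose [peak_wavelength()] equals `peak` to
#'   grid resolution.
#' @export
sim_emission_spectrum <- function(peak, width, amplitude, grid,
                                  meta = list()) {
  if (width <= 0) stop_validation("width must be > 0")
  if (min(grid) > peak - 3 * width || max(grid) < peak + 3 * width)
    stop_data("grid does not cover peak +/- 3 width")
  spectrum(grid, lognormal_band(grid, peak, width) * amplitude, meta = meta)
}

lognormal_band <- function(grid, peak, width, shape = 0.25) {
  origin <- peak - 3 * width
  x <- grid - origin
  mu <- log(3 * width) + shape^2  # density mode at x = 3 * width
  y <- numeric(length(x))
  pos <- x > 0
  y[pos] <- exp(-(log(x[pos]) - mu)^2 / (2 * shape^2)) / x[pos]
  ymax <- exp(-(log(3 * width) - mu)^2 / (2 * shape^2)) / (3 * width)
  y / ymax
}

#' Simulate a quencher titration
#'
#' Generates one replicate of the solution-quenching experiment: a
#' blank-subtracted emission spectrum per concentration plus the raw
#' spectra, matched quencher-only blanks and per-solution absorbance
#' spectra. Relative to the zero-quencher spectrum, the fluorophore signal
#' at concentration c > 0 is scaled by `1 / (intercept + ksv * c)`, so the
#' measured band ratios F0/F reproduce the Stern-Volmer line exactly before
#' noise. Quencher autofluorescence is added in proportion to c, anchored so
#' that at `ref_conc` it accounts for `blank_fraction_ref` of the total
#' signal at the blank's peak wavelength. With `inner_filter = TRUE` both
#' signal and blank are attenuated per-wavelength by the Beer-Lambert
#' factor `10^-((0.2 OD_ex + OD_em) / 2)` implied by the emitted absorbance
#' spectra, which downstream [inner_filter_correct()] inverts.
#'
#' @param cfg a [sim_config()].
#' @param quencher `"5-HT"` or `"DA"` (label only; parameters come from
#'   `cfg$titration`).
#' @param replicate replicate index (selects an independent noise
#'   substream).
#' @return List with `series` (a [titration_series()] of blank-subtracted
#'   spectra with absorbances attached), `raw`, `blanks`, `absorbances`.
#' @export
simulate_titration <- function(cfg, quencher = "5-HT", replicate = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  tt <- cfg$titration
  conc <- tt$concentrations
  grid <- tt$grid
  with_stream(cfg$seed, paste0("titration/", quencher, "/", replicate), {
    sd_noise <- tt$noise_sigma * tt$amplitude
    # anchor blank amplitude: fraction of total at the blank peak, ref conc
    s_ref <- 1 / (tt$intercept + tt$ksv * tt$ref_conc)
    sig_ref <- tt$amplitude * s_ref *
      lognormal_band(tt$blank_peak_nm, tt$peak_nm + tt$peak_shift_per_M * tt$ref_conc,
                     tt$width_nm)
    beta <- if (tt$blank_fraction_ref > 0)
      tt$blank_fraction_ref / (1 - tt$blank_fraction_ref) * sig_ref / tt$ref_conc
    else 0

    raw <- list(); blanks <- list(); subtracted <- list(); absorb <- list()
    for (i in seq_along(conc)) {
      c_i <- conc[i]
      scale <- if (c_i == 0) 1 else 1 / (tt$intercept + tt$ksv * c_i)
      peak_i <- tt$peak_nm + tt$peak_shift_per_M * c_i
      signal <- tt$amplitude * scale * lognormal_band(grid, peak_i, tt$width_nm)
      blank_true <- beta * c_i *
        lognormal_band(grid, tt$blank_peak_nm, tt$blank_width_nm)
      att <- rep(1, length(grid))
      od <- absorbance_per_m(tt$abs_grid, tt$abs370_per_M) * c_i
      if (isTRUE(tt$inner_filter)) {
        od_em <- stats::approx(tt$abs_grid, od, xout = grid)$y
        od_ex <- stats::approx(tt$abs_grid, od, xout = 370)$y
        att <- 10^(-(0.2 * od_ex + od_em) / 2)
      }
      eps1 <- if (sd_noise > 0) stats::rnorm(length(grid), 0, sd_noise) else 0
      eps2 <- if (sd_noise > 0) stats::rnorm(length(grid), 0, sd_noise) else 0
      meta <- list(quencher = quencher, conc_M = c_i, seed = cfg$seed,
                   stream = paste0("titration/", quencher, "/", replicate))
      # the stray-light floor appears in both measurements and cancels on
      # blank subtraction; it keeps noisy raw intensities positive so no
      # clipping is needed (clipping near zero would bias the blank upward)
      floor_i <- max(tt$baseline, 10 * sd_noise)  # >= 10 sigma: raw stays positive
      raw_i <- spectrum(grid, (signal + blank_true) * att + floor_i + eps1,
                        meta = meta)
      blank_i <- spectrum(grid, blank_true * att + floor_i + eps2,
                          meta = c(meta, list(sample_id = sprintf("blank_%g", c_i))))
      raw[[i]] <- raw_i
      blanks[[i]] <- blank_i
      subtracted[[i]] <- subtract_blank(raw_i, blank_i)
      absorb[[i]] <- absorbance_spectrum(tt$abs_grid, od, meta = meta)
    }
    list(series = titration_series(conc, subtracted, absorbances = absorb,
                                   quencher = quencher),
         raw = raw, blanks = blanks, absorbances = absorb)
  })
}

absorbance_per_m <- function(grid, a370) {
  # linear OD ramp: a370 per M at 370 nm, falling to 0 at 600 nm
  pmax(a370 * (600 - grid) / (600 - 370), 0)
}

#' Simulate a Gaussian instrument response function
#'
#' @param fwhm full width at half maximum, ns (default 8 ns pulse).
#' @param grid uniform ns grid.
#' @param center peak position, ns.
#' @return An [irf()], normalized; its measured FWHM is within one bin of
#'   the request.
#' @export
simulate_irf <- function(fwhm = 8, grid, center = 20) {
  bin <- grid[2] - grid[1]
  if (fwhm < 2 * bin)
    stop_validation(sprintf("IRF FWHM %g ns under-resolved on %g ns bins", fwhm, bin))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- exp(-0.5 * ((grid - center) / sigma)^2)
  irf(grid, r / sum(r), meta = list(fwhm_ns = fwhm, center_ns = center))
}

#' Simulate a TRPL decay trace
#'
#' Single-species time-resolved photoluminescence: the configured lifetime's
#' exponential convolved with the Gaussian IRF, scaled to the configured
#' peak counts, with per-bin Poisson (or Gaussian) counting noise emulating
#' `averages` analog-averaged laser shots.
#'
#' @param cfg a [sim_config()].
#' @param species one of the names of `cfg$trpl$tau_ns` (`"anap"`,
#'   `"serotonin"`, `"quenched_anap"`).
#' @param noise override of `cfg$trpl$noise`: `"poisson"`, `"gaussian"` or
#'   `"none"`.
#' @param stream extra substream tag so repeated calls draw independent
#'   noise.
#' @return List with `trace` (a [decay_trace()]) and `irf`.
#' @export
simulate_trpl <- function(cfg, species = "anap", noise = NULL, stream = "") {
  stopifnot(inherits(cfg, "sim_config"))
  tp <- cfg$trpl
  if (!species %in% names(tp$tau_ns))
    stop_validation(sprintf("unknown species '%s' (configured: %s)", species,
                            paste(names(tp$tau_ns), collapse = ", ")))
  if (is.null(noise)) noise <- tp$noise
  grid <- seq(0, tp$t_max, by = tp$bin_ns)
  ir <- simulate_irf(tp$irf_fwhm, grid, tp$irf_center)
  shape <- convolve_with_irf(ir, "exp1",
                             list(lifetimes = tp$tau_ns[[species]], amplitudes = 1),
                             grid)
  lam <- shape / max(shape) * tp$peak_counts[[species]]
  with_stream(cfg$seed, paste0("trpl/", species, "/", stream), {
    y <- switch(noise,
      none = lam,
      poisson = stats::rpois(length(lam), tp$averages * lam) / tp$averages,
      gaussian = lam + stats::rnorm(length(lam), 0, sqrt(pmax(lam, 1e-12) / tp$averages)),
      stop_validation(sprintf("unknown noise mode '%s'", noise)))
    list(trace = decay_trace(grid, y, kind = "trpl", averages = tp$averages,
                             meta = list(species = species, tau_true = tp$tau_ns[[species]],
                                         seed = cfg$seed)),
         irf = ir)
  })
}

#' Simulate a quenched mixture TRPL experiment
#'
#' The mixture trace is the sum of a quencher-only component (serotonin
#' lifetime) and a quenched-fluorophore component (shortened ANAP lifetime);
#' the background trace is the quencher-only solution measured separately
#' (independent noise). Subtracting background from mixture isolates the
#' quenched-fluorophore decay.
#'
#' @param cfg a [sim_config()].
#' @param noise,stream as in [simulate_trpl()].
#' @return List with `mixture`, `background` (decay traces) and `irf`.
#' @export
simulate_trpl_mixture <- function(cfg, noise = NULL, stream = "") {
  stopifnot(inherits(cfg, "sim_config"))
  tp <- cfg$trpl
  if (is.null(noise)) noise <- tp$noise
  grid <- seq(0, tp$t_max, by = tp$bin_ns)
  ir <- simulate_irf(tp$irf_fwhm, grid, tp$irf_center)
  comp <- function(sp) {
    s <- convolve_with_irf(ir, "exp1",
                           list(lifetimes = tp$tau_ns[[sp]], amplitudes = 1), grid)
    s / max(s) * tp$peak_counts[[sp]]
  }
  lam_q <- comp("serotonin")
  lam_f <- comp("quenched_anap")
  draw <- function(lam, key) with_stream(cfg$seed, paste0("trpl_mix/", key, "/", stream),
    switch(noise,
      none = lam,
      poisson = stats::rpois(length(lam), tp$averages * lam) / tp$averages,
      gaussian = lam + stats::rnorm(length(lam), 0, sqrt(pmax(lam, 1e-12) / tp$averages))))
  mk <- function(y, id) decay_trace(grid, y, kind = "trpl", averages = tp$averages,
                                    meta = list(component = id, seed = cfg$seed))
  list(mixture = mk(draw(lam_q + lam_f, "mixture"), "mixture"),
       background = mk(draw(lam_q, "background"), "quencher_only"),
       irf = ir)
}

#' Simulate a transient-absorption experiment
#'
#' Produces the raw intensity triple consumed by [build_tas_trace()]: a
#' constant unpumped probe trace, a pump-induced fluorescence trace, and a
#' pumped trace constructed so the assembled delta-OD equals the
#' IRF-convolved exponential decay of the charge-transfer product (lifetime
#' `product_tau`), plus a saturating detector artifact inside the artifact
#' window, damped-sinusoid electromagnetic interference on the pumped
#' channel, and Gaussian shot noise scaled by `1/sqrt(averages)`. With
#' `step_dod = 0` the delta-OD recovers fully to zero (reversible product);
#' a positive step adds a permanent absorbance increase.
#'
#' @param cfg a [sim_config()].
#' @param noise `"gaussian"` or `"none"` (overrides config).
#' @param emi logical, include the EMI oscillation.
#' @param stream substream tag.
#' @return List with `pumped`, `unpumped`, `fluorescence` decay traces,
#'   `irf`, and `artifact_window`.
#' @export
simulate_tas <- function(cfg, noise = NULL, emi = TRUE, stream = "") {
  stopifnot(inherits(cfg, "sim_config"))
  ts <- cfg$tas
  if (is.null(noise)) noise <- ts$noise
  grid <- seq(0, ts$t_max, by = ts$bin_ns)
  ir <- simulate_irf(ts$irf_fwhm, grid, ts$irf_center)
  shape <- convolve_with_irf(ir, "exp1",
                             list(lifetimes = ts$product_tau, amplitudes = 1), grid)
  dod <- shape / max(shape) * ts$product_dod
  if (ts$step_dod > 0) dod <- dod + ts$step_dod * cumsum(ir$response)
  fl_shape <- convolve_with_irf(ir, "exp1",
                                list(lifetimes = cfg$trpl$tau_ns[["anap"]],
                                     amplitudes = 1), grid)
  fl <- fl_shape / max(fl_shape) * ts$fluor_scale * ts$i0
  pumped_clean <- ts$i0 * 10^(-dod) + fl
  if (emi && ts$emi$amplitude > 0) {
    pumped_clean <- pumped_clean + ts$emi$amplitude *
      exp(-grid / ts$emi$damping_ns) *
      sin(2 * pi * ts$emi$freq_ghz * grid + ts$emi$phase)
  }
  art <- grid >= ts$artifact_window[1] & grid <= ts$artifact_window[2]
  pumped_clean[art] <- pumped_clean[art] + ts$artifact_amp * ts$i0
  sd_tr <- if (noise == "none") 0 else ts$noise_sigma * ts$i0 / sqrt(ts$averages)
  with_stream(cfg$seed, paste0("tas/", stream), {
    eps <- function() if (sd_tr > 0) stats::rnorm(length(grid), 0, sd_tr) else 0
    mk <- function(y, id) decay_trace(grid, y, kind = "trpl", averages = ts$averages,
                                      meta = list(channel = id, seed = cfg$seed))
    list(pumped = mk(pumped_clean + eps(), "pumped"),
         unpumped = mk(rep(ts$i0, length(grid)) + eps(), "unpumped"),
         fluorescence = mk(fl + eps(), "fluorescence"),
         irf = ir, artifact_window = ts$artifact_window)
  })
}

#' Simulate concentration-stepped cell spectra
#'
#' Generates one [exposure_series()] per cell: `n_pre` agonist-free PRE
#' exposures followed by one exposure per concentration. Each spectrum is an
#' ANAP band (peak ~495 nm) plus an overlapping mOrange band (peak 562 nm),
#' scaled by single-exponential photobleaching in cumulative exposure time.
#' The ANAP band is additionally scaled by `1 - q_i * OccN(c)`, where
#' `OccN` is the modified-Hill occupancy at the cell's EC50 and slope,
#' range-normalized over the applied concentrations, and `q_i` is the
#' cell's maximal quench ceiling. Cell-to-cell variability (ceiling spread
#' `max_quench_sd`, EC50 log-scatter `ec50_cv`) and per-wavelength
#' multiplicative Gaussian noise emulate the reported spread; set them and
#' `noise_sigma` to 0 for noiseless recovery runs.
#'
#' @param cfg a [sim_config()].
#' @param stream substream tag for independent repeats.
#' @return List of [exposure_series()], length `cfg$cells$n_cells`.
#' @export
simulate_cell_series <- function(cfg, stream = "") {
  stopifnot(inherits(cfg, "sim_config"))
  cc <- cfg$cells
  grid <- cc$grid
  conc <- sort(cc$concentrations)
  bl <- cc$bleach
  lapply(seq_len(cc$n_cells), function(i) {
    with_stream(cfg$seed, paste0("cells/", stream, "/", i), {
      q_i <- if (cc$max_quench_sd > 0)
        min(max(stats::rnorm(1, cc$max_quench, cc$max_quench_sd), 0.05), 0.995)
      else cc$max_quench
      ec50_i <- if (cc$ec50_cv > 0) cc$ec50 * exp(stats::rnorm(1, 0, cc$ec50_cv))
                else cc$ec50
      occ <- 1 - hill_core(conc, ec50_i, cc$slope)
      occ_n <- (occ - occ[1]) / (occ[length(occ)] - occ[1])
      anap <- lognormal_band(grid, cc$anap_peak, cc$anap_width) * cc$anap_amp
      mor <- lognormal_band(grid, cc$morange_peak, cc$morange_width) * cc$morange_amp
      times <- (seq_len(cc$n_pre + length(conc)) - 1) * cc$exposure_s
      conc_col <- c(rep(NA_real_, cc$n_pre), conc)
      bfrac <- (bl$A * exp(-times / bl$tau_s) + bl$C) / (bl$A + bl$C)
      spectra <- lapply(seq_along(times), function(j) {
        scale_anap <- if (is.na(conc_col[j])) 1
                      else 1 - q_i * occ_n[match(conc_col[j], conc)]
        clean <- (anap * scale_anap + mor) * bfrac[j]
        y <- if (cc$noise_sigma > 0)
          clean * (1 + stats::rnorm(length(grid), 0, cc$noise_sigma))
        else clean
        spectrum(grid, pmax(y, 0),
                 meta = list(cell = i, conc_M = conc_col[j], seed = cfg$seed))
      })
      exposure_series(times, conc_col, spectra,
                      cell_id = sprintf("cell%02d", i),
                      preparation = cc$preparation, min_pre = cc$n_pre)
    })
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Materializes the full synthetic experiment as the CSV dialects the
#' analysis functions read, plus a `config.json` echo of the configuration
#' (seed included): per-replicate titration spectra with blanks, absorbances
#' and a manifest; TRPL traces and IRF; the TAS triple; and per-cell
#' exposure manifests and spectra.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param quenchers titration quenchers to emit.
#' @return `dir`, invisibly.
#' @export
simulate_dataset <- function(cfg, dir, quenchers = "5-HT") {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (q in quenchers) {
    qdir <- file.path(dir, paste0("titration_", gsub("[^A-Za-z0-9]", "", q)))
    dir.create(qdir, showWarnings = FALSE)
    for (r in seq_len(cfg$titration$replicates)) {
      sim <- simulate_titration(cfg, quencher = q, replicate = r)
      man <- data.frame(conc_M = sim$series$conc,
                        spectrum_path = sprintf("rep%d_raw_%02d.csv", r,
                                                seq_along(sim$series$conc)),
                        absorbance_path = sprintf("rep%d_abs_%02d.csv", r,
                                                  seq_along(sim$series$conc)),
                        blank_path = sprintf("rep%d_blank_%02d.csv", r,
                                             seq_along(sim$series$conc)))
      for (i in seq_along(sim$raw)) {
        write_spectrum_csv(sim$raw[[i]], file.path(qdir, man$spectrum_path[i]))
        write_spectrum_csv(sim$blanks[[i]], file.path(qdir, man$blank_path[i]))
        write_absorbance_csv(sim$absorbances[[i]], file.path(qdir, man$absorbance_path[i]))
      }
      write_table_csv(man, file.path(qdir, sprintf("manifest_rep%d.csv", r)))
    }
  }
  tdir <- file.path(dir, "trpl"); dir.create(tdir, showWarnings = FALSE)
  for (sp in names(cfg$trpl$tau_ns)) {
    sim <- simulate_trpl(cfg, species = sp)
    write_trace_csv(sim$trace, file.path(tdir, paste0(sp, ".csv")))
    write_trace_csv(sim$irf, file.path(tdir, "irf.csv"))
  }
  adir <- file.path(dir, "tas"); dir.create(adir, showWarnings = FALSE)
  sim <- simulate_tas(cfg)
  for (ch in c("pumped", "unpumped", "fluorescence"))
    write_trace_csv(sim[[ch]], file.path(adir, paste0(ch, ".csv")))
  write_trace_csv(sim$irf, file.path(adir, "irf.csv"))
  cdir <- file.path(dir, "cells"); dir.create(cdir, showWarnings = FALSE)
  cells <- simulate_cell_series(cfg)
  rows <- list()
  for (s in cells) {
    for (j in seq_along(s$time_s)) {
      p <- sprintf("%s_exp%02d.csv", s$cell_id, j)
      write_spectrum_csv(s$spectra[[j]], file.path(cdir, p))
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = s$cell_id, cum_exposure_s = s$time_s[j],
        conc_M_or_PRE = if (is.na(s$conc[j])) "PRE" else fmt_num(s$conc[j]),
        spectrum_path = p, preparation = s$preparation)
    }
  }
  write_table_csv(do.call(rbind, rows), file.path(cdir, "manifest.csv"))
  invisible(dir)
}
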