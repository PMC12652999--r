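#' Construct a cell exposure series
#'
#' Ordered spectra from a single cell (or unroofed membrane sheet) exposed
#' first to agonist-free bath solution (PRE exposures, used to fit
#' photobleaching) and then to increasing agonist concentrations.
#'
#' @param time_s cumulative exposure times in seconds, strictly increasing.
#' @param conc molar concentrations; `NA` tags a PRE (zero-agonist)
#'   exposure. PRE exposures must precede all concentration steps.
#' @param spectra list of [spectrum()] objects, one per exposure.
#' @param cell_id label.
#' @param preparation `"cell"` or `"unroofed"`.
#' @param min_pre minimum number of PRE exposures required (default 5, the
#'   standard acquisition; [fit_bleach()] itself accepts >= 3).
#' @return An object of class `exposure_series`.
#' @export
exposure_series <- function(time_s, conc, spectra, cell_id = "cell1",
                            preparation = c("cell", "unroofed"),
                            min_pre = 5) {
  preparation <- match.arg(preparation)
  time_s <- as.numeric(time_s)
  if (is.unsorted(time_s, strictly = TRUE))
    stop_validation("exposure times must be strictly increasing")
  if (length(conc) != length(time_s) || length(spectra) != length(time_s))
    stop_validation("time_s, conc and spectra must have equal length")
  pre <- is.na(conc)
  if (sum(pre) < min_pre)
    stop_validation(sprintf("need >= %d PRE exposures, got %d", min_pre, sum(pre)))
  if (any(which(pre) > min(which(!pre), Inf)))
    stop_validation("all PRE exposures must precede concentration steps")
  structure(list(time_s = time_s, conc = as.numeric(conc), spectra = spectra,
                 cell_id = cell_id, preparation = preparation),
            class = "exposure_series")
}

#' @export
print.exposure_series <- function(x, ...) {
  cat(sprintf("<exposure series %s (%s): %d PRE + %d concentration steps>\n",
              x$cell_id, x$preparation, sum(is.na(x$conc)), sum(!is.na(x$conc))))
  invisible(x)
}

#' Detect the ANAP reporting band of an exposure series
#'
#' Peak wavelength of the first PRE spectrum, searched inside
#' `search_window` (default 450-540 nm, below the mOrange band), widened to
#' a band of `width` nm. Using a fixed narrow band centred on the detected
#' ANAP peak limits contamination from the overlapping mOrange emission.
#'
#' @param series an [exposure_series()].
#' @param width band width in nm, default 10.
#' @param search_window `c(lo, hi)` nm peak search window.
#' @return `c(lo, hi)` band in nm.
#' @export
anap_band <- function(series, width = 10, search_window = c(450, 540)) {
  stopifnot(inherits(series, "exposure_series"))
  first_pre <- series$spectra[[which(is.na(series$conc))[1]]]
  pk <- peak_wavelength(first_pre, window = search_window)
  c(pk - width / 2, pk + width / 2)
}

#' Fit a photobleaching model to PRE exposures
#'
#' Least-squares fit of the band-averaged ANAP intensity of the agonist-free
#' PRE exposures against cumulative exposure time to
#' `A * exp(-t / tau_b) + C`. If intensity does not decrease across the PRE
#' exposures a no-bleach model (`A = 0`) is returned with a flag.
#'
#' @param series an [exposure_series()].
#' @param band `c(lo, hi)` nm reporting band; default [anap_band()] of the
#'   series.
#' @param offset include the plateau offset `C` (default TRUE); with
#'   `FALSE`, `C` is fixed at 0.
#' @return An object of class `bleach_fit` with `amplitude`, `time_constant`
#'   (s), `offset`, `r_squared`, `no_bleach` flag and the PRE data. Methods:
#'   `print`, `coef`, `predict`.
#' @export
fit_bleach <- function(series, band = NULL, offset = TRUE) {
  stopifnot(inherits(series, "exposure_series"))
  if (is.null(band)) band <- anap_band(series)
  pre <- which(is.na(series$conc))
  if (length(pre) < 3L) stop_validation("need >= 3 PRE exposures")
  t <- series$time_s[pre]
  f <- vapply(series$spectra[pre], band_mean, numeric(1), lo = band[1], hi = band[2])
  if (f[length(f)] >= f[1]) {
    return(structure(list(amplitude = 0, time_constant = Inf,
                          offset = mean(f), r_squared = NA_real_,
                          no_bleach = TRUE, time_s = t, intensity = f,
                          band = band),
                     class = "bleach_fit"))
  }
  span <- max(t) - min(t)
  # LM on (A, log tau, C) with multiple tau starts; the PRE window is short
  # so tau can be weakly identified under noise
  model_fn <- function(p) {
    m <- p["A"] * exp(-t / exp(p["ltau"])) + if (offset) p["C"] else 0
    f - m
  }
  best <- NULL
  for (tau0 in c(span / 2, span, 4 * span)) {
    st <- c(A = max(f[1] - f[length(f)], 1e-12 * f[1]), ltau = log(tau0))
    lo <- c(A = 0, ltau = log(span / 50))
    hi <- c(A = Inf, ltau = log(span * 1e3))
    if (offset) { st <- c(st, C = max(f[length(f)], 0))
                  # the plateau is a fluorescence level: nonnegative;
                  # unbounded C admits near-linear fits whose extrapolation
                  # wrecks the correction of later exposures
                  lo <- c(lo, C = 0); hi <- c(hi, C = Inf) }
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = model_fn, lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$deviance < best$deviance))
      best <- res
  }
  if (is.null(best)) stop_fit("bleach fit failed for all starts")
  cf <- best$par
  r2 <- 1 - best$deviance / sum((f - mean(f))^2)
  structure(list(amplitude = unname(cf["A"]),
                 time_constant = exp(unname(cf["ltau"])),
                 offset = if (offset) unname(cf["C"]) else 0,
                 r_squared = r2, no_bleach = FALSE, time_s = t, intensity = f,
                 band = band),
            class = "bleach_fit")
}

#' @export
print.bleach_fit <- function(x, ...) {
  if (x$no_bleach)
    cat(sprintf("Bleach fit: no bleach detected (constant %.4g)\n", x$offset))
  else
    cat(sprintf("Bleach fit: A = %.4g, tau_b = %.4g s, C = %.4g (R^2 = %.4g)\n",
                x$amplitude, x$time_constant, x$offset, x$r_squared))
  invisible(x)
}

#' @export
coef.bleach_fit <- function(object, ...) {
  c(amplitude = object$amplitude, time_constant = object$time_constant,
    offset = object$offset)
}

#' @export
predict.bleach_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time_s else newdata
  if (object$no_bleach) rep(object$offset, length(t))
  else object$amplitude * exp(-t / object$time_constant) + object$offset
}

#' Correct an exposure series for photobleaching
#'
#' Divides each exposure's spectrum by the bleach model's predicted
#' fractional intensity at that exposure's cumulative time, with the
#' prediction normalized to 1 at the first PRE exposure.
#'
#' @param series an [exposure_series()].
#' @param model a [fit_bleach()] result from the same cell's PRE exposures.
#' @return The corrected `exposure_series`.
#' @export
bleach_correct <- function(series, model) {
  stopifnot(inherits(series, "exposure_series"), inherits(model, "bleach_fit"))
  ref <- predict(model, newdata = series$time_s[1])
  frac <- predict(model, newdata = series$time_s) / ref
  if (any(frac <= 0)) stop_data("bleach model predicts nonpositive intensity")
  out <- series
  for (i in seq_along(out$spectra)) {
    sp <- out$spectra[[i]]
    sp$intensity <- sp$intensity / frac[i]
    sp$meta$bleach_fraction <- frac[i]
    out$spectra[[i]] <- sp
  }
  out
}

#' Bleach-corrected band intensities per concentration
#'
#' Convenience accessor: band-averaged ANAP intensity of each concentration
#' step of a (bleach-corrected) exposure series.
#'
#' @param series an [exposure_series()].
#' @param band `c(lo, hi)` nm; default [anap_band()].
#' @return `data.frame` with columns `conc` (M) and `intensity`.
#' @export
concentration_peaks <- function(series, band = NULL) {
  stopifnot(inherits(series, "exposure_series"))
  if (is.null(band)) band <- anap_band(series)
  steps <- which(!is.na(series$conc))
  data.frame(
    conc = series$conc[steps],
    intensity = vapply(series$spectra[steps], band_mean, numeric(1),
                       lo = band[1], hi = band[2]))
}

#' Normalize a concentration-response series
#'
#' Standardizes bleach-corrected band intensities for comparison across
#' cells: subtract the fluorescence at the saturating (highest)
#' concentration and divide by the span down from the lowest applied
#' concentration (where no appreciable quenching is expected):
#' `F_norm(c) = (F(c) - F_min) / (F_lowest - F_min)`. The output is
#' invariant to any affine transform of the input intensities.
#'
#' @param peaks `data.frame` with columns `conc` (M, > 0) and `intensity`.
#' @param fmin_top_mean use the mean of the top two concentrations as
#'   `F_min` instead of the single highest point.
#' @return `data.frame` with columns `conc` and `fnorm`.
#' @export
normalize_response <- function(peaks, fmin_top_mean = FALSE) {
  if (!all(c("conc", "intensity") %in% names(peaks)))
    stop_validation("peaks must have columns conc and intensity")
  if (any(peaks$conc <= 0)) stop_validation("concentrations must be > 0")
  peaks <- peaks[order(peaks$conc), , drop = FALSE]
  n <- nrow(peaks)
  if (n < 3L) warning("fewer than 3 concentrations")
  if (max(peaks$conc) / min(peaks$conc) < 100)
    warning("concentrations span less than 2 orders of magnitude")
  fmin <- if (fmin_top_mean && n >= 2) mean(peaks$intensity[(n - 1):n])
          else peaks$intensity[n]
  flow <- peaks$intensity[1]
  if (flow == fmin) stop_data("degenerate range: F(lowest) equals F(min)")
  data.frame(conc = peaks$conc, fnorm = (peaks$intensity - fmin) / (flow - fmin))
}

# Core logistic of the modified Hill law in log10 concentration. With
# negative h this decreases from 1 (c -> 0) to 0 (c -> Inf).
hill_core <- function(conc, ec50, h) {
  1 / (1 + 10^(h * (log10(ec50) - log10(conc))))
}

#' Fit the modified Hill concentration-response curve
#'
#' Least-squares fit of normalized fluorescence against concentration with
#' the modified Hill equation in log10 concentration,
#' \deqn{F_{norm}(c) = F_{min} + (F_{max} - F_{min}) \cdot
#'   \frac{1}{1 + 10^{h (\log_{10} EC_{50} - \log_{10} c)}}}
#' with the slope factor `h` free in sign (negative for quenching). By
#' default the asymptotes `fmax`/`fmin` are fitted alongside `EC50` and `h`:
#' because the slope factors here are shallow (|h| around 0.5), normalized
#' data from a finite concentration range are an affine transform of the
#' underlying logistic, and free asymptotes absorb that transform so the
#' midpoint and slope are recovered without range bias. Fixing
#' `fix_asymptotes = TRUE` instead fits the pure two-parameter logistic.
#'
#' The fit is performed in `log10(EC50)`, so it is invariant to
#' concentration-unit rescaling up to the corresponding EC50 rescale. A 95%
#' confidence interval is computed by seeded nonparametric bootstrap over
#' points, or over cells when a `cell` column is present and
#' `boot_over = "cells"`.
#'
#' @param points `data.frame` with columns `conc` (M, > 0) and `fnorm`, and
#'   optionally `cell` for pooled multi-cell fits.
#' @param fix_asymptotes fix `fmax = 1`, `fmin = 0`.
#' @param bootstrap number of bootstrap resamples for the 95% CI (0 to skip).
#' @param boot_over `"points"` or `"cells"`.
#' @param seed integer seed for the bootstrap.
#' @param preparation label carried into the result (`"cell"`/`"unroofed"`).
#' @return An object of class `hill_fit` with `ec50` (M), `slope`, `fmax`,
#'   `fmin`, `ci95` (named list of `c(lo, hi)`), `boundary` flag, `points`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#' @export
#' @examples
#' cc <- 10^seq(-8, -4, length.out = 9)
#' pts <- data.frame(conc = cc, fnorm = 1 / (1 + 10^(-0.46 * (log10(594e-9) - log10(cc)))))
#' fit_hill(pts, fix_asymptotes = TRUE, bootstrap = 0)
fit_hill <- function(points, fix_asymptotes = FALSE, bootstrap = 1000,
                     boot_over = c("points", "cells"), seed = 1,
                     preparation = "cell") {
  boot_over <- match.arg(boot_over)
  if (!all(c("conc", "fnorm") %in% names(points)))
    stop_validation("points must have columns conc and fnorm")
  if (any(points$conc <= 0)) stop_validation("concentrations must be > 0")
  if (nrow(points) < 4L) stop_validation("need >= 4 points")
  est <- hill_point_fit(points, fix_asymptotes)
  ci <- list()
  if (bootstrap > 0) {
    boots <- hill_bootstrap(points, fix_asymptotes, bootstrap, boot_over, seed)
    n_cells <- length(unique(points$cell))
    if (boot_over == "cells" && !is.null(points$cell) && n_cells > 1) {
      # few-cluster inference: bootstrap SE (log scale for EC50) inflated by
      # sqrt(n/(n-1)), t_{n-1} quantiles; the plain percentile interval
      # undercovers with a handful of cells
      tq <- stats::qt(0.975, n_cells - 1)
      infl <- sqrt(n_cells / (n_cells - 1))
      half <- function(v) tq * infl * stats::sd(v, na.rm = TRUE)
      ci <- list(
        ec50 = 10^(log10(est$ec50) + c(-1, 1) * half(log10(boots$ec50))),
        slope = est$slope + c(-1, 1) * half(boots$slope),
        fmax = est$fmax + c(-1, 1) * half(boots$fmax),
        fmin = est$fmin + c(-1, 1) * half(boots$fmin))
    } else {
      ci <- lapply(boots, function(v)
        unname(stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)))
    }
  }
  boundary <- est$ec50 <= min(points$conc) || est$ec50 >= max(points$conc)
  structure(c(est, list(ci95 = ci, boundary = boundary, points = points,
                        preparation = preparation, n_boot = bootstrap,
                        boot_over = boot_over)),
            class = "hill_fit")
}

hill_point_fit <- function(points, fix_asymptotes) {
  conc <- points$conc
  y <- points$fnorm
  lc <- log10(conc)
  st <- c(lec = stats::median(lc), h = -0.5)
  lo <- c(lec = min(lc) - 6, h = -20)
  hi <- c(lec = max(lc) + 6, h = 20)
  if (!fix_asymptotes) {
    st <- c(st, fmax = max(y), fmin = min(y))
    lo <- c(lo, fmax = -Inf, fmin = -Inf)
    hi <- c(hi, fmax = Inf, fmin = Inf)
  }
  fn <- function(p) {
    core <- 1 / (1 + 10^(p["h"] * (p["lec"] - lc)))
    m <- if (fix_asymptotes) core else p["fmin"] + (p["fmax"] - p["fmin"]) * core
    y - m
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = st, fn = fn, lower = lo, upper = hi,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) stop_fit(paste("Hill fit failed:", conditionMessage(e))))
  p <- res$par
  npar <- length(p)
  dof <- max(length(y) - npar, 1)
  se <- tryCatch({
    covm <- solve(res$hessian) * 2 * res$deviance / dof  # hessian ~ 2 J'J
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, npar))
  names(se) <- names(p)
  list(ec50 = unname(10^p["lec"]), slope = unname(p["h"]),
       fmax = if (fix_asymptotes) 1 else unname(p["fmax"]),
       fmin = if (fix_asymptotes) 0 else unname(p["fmin"]),
       se_log10_ec50 = unname(se["lec"]), se_slope = unname(se["h"]),
       rss = res$deviance)
}

hill_bootstrap <- function(points, fix_asymptotes, n_boot, boot_over, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  cells <- if (boot_over == "cells" && !is.null(points$cell))
    unique(points$cell) else NULL
  draws <- replicate(n_boot, {
    idx <- if (!is.null(cells)) {
      pick <- sample(cells, length(cells), replace = TRUE)
      unlist(lapply(pick, function(cl) which(points$cell == cl)))
    } else sample(nrow(points), replace = TRUE)
    est <- tryCatch(hill_point_fit(points[idx, , drop = FALSE], fix_asymptotes),
                    error = function(e) NULL)
    if (is.null(est)) c(NA_real_, NA_real_, NA_real_, NA_real_)
    else c(est$ec50, est$slope, est$fmax, est$fmin)
  })
  list(ec50 = draws[1, ], slope = draws[2, ], fmax = draws[3, ],
       fmin = draws[4, ])
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s): EC50 = %.4g M, slope = %.4g, fmax = %.4g, fmin = %.4g\n",
              x$preparation, x$ec50, x$slope, x$fmax, x$fmin))
  if (length(x$ci95))
    cat(sprintf("  95%% CI (bootstrap %d over %s): EC50 [%.4g, %.4g] M, slope [%.4g, %.4g]\n",
                x$n_boot, x$boot_over, x$ci95$ec50[1], x$ci95$ec50[2],
                x$ci95$slope[1], x$ci95$slope[2]))
  if (x$boundary) cat("  note: EC50 at concentration-range boundary\n")
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  n points = %d, RSS = %.4g\n", nrow(object$points), object$rss))
  invisible(object)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50 = object$ec50, slope = object$slope, fmax = object$fmax,
    fmin = object$fmin)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$points$conc else newdata$conc
  object$fmin + (object$fmax - object$fmin) * hill_core(conc, object$ec50, object$slope)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$points$fnorm - predict(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$points$conc, x$points$fnorm, log = "x",
                 xlab = "[5-HT] (M)", ylab = "normalized F", pch = 19, ...)
  cc <- 10^seq(log10(min(x$points$conc)), log10(max(x$points$conc)),
               length.out = 200)
  graphics::lines(cc, predict(x, newdata = data.frame(conc = cc)),
                  col = "firebrick")
  invisible(x)
}

#' Maximal quench fraction across cells
#'
#' Per cell: one minus the ratio of the bleach-corrected band intensity at
#' the saturating (highest) concentration to that at the lowest applied
#' concentration; then mean and SEM across cells. This is the statistic
#' behind the reported partial (rather than complete) quenching at
#' saturating agonist.
#'
#' @param peaks_per_cell list of `data.frame`s with columns `conc` and
#'   `intensity` (one per cell), as from [concentration_peaks()].
#' @return List with `per_cell`, `mean`, and `sem` (`NA` for a single cell).
#' @export
maximal_quench <- function(peaks_per_cell) {
  q <- vapply(peaks_per_cell, function(pk) {
    pk <- pk[order(pk$conc), , drop = FALSE]
    1 - pk$intensity[nrow(pk)] / pk$intensity[1]
  }, numeric(1))
  list(per_cell = q, mean = mean(q),
       sem = if (length(q) > 1) stats::sd(q) / sqrt(length(q)) else NA_real_)
}

#' Full binding pipeline over multiple cells
#'
#' Runs, for each cell: photobleach fit on the PRE exposures
#' ([fit_bleach()]), bleach correction ([bleach_correct()]), band-intensity
#' extraction ([concentration_peaks()]) and per-cell normalization
#' ([normalize_response()]); then pools the normalized points across cells
#' and fits a single modified Hill curve ([fit_hill()]) with bootstrap over
#' cells.
#'
#' @param series_list list of [exposure_series()].
#' @param band `c(lo, hi)` nm; default per-cell [anap_band()].
#' @param bootstrap,seed,fix_asymptotes passed to [fit_hill()].
#' @return List with `hill` (the pooled `hill_fit`), `bleach` (per-cell
#'   `bleach_fit`s), `peaks` (per-cell corrected peaks), `max_quench`.
#' @export
fit_binding <- function(series_list, band = NULL, bootstrap = 1000, seed = 1,
                        fix_asymptotes = FALSE) {
  stopifnot(length(series_list) >= 1)
  bleach <- list(); peaks <- list(); pooled <- list()
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    b <- if (is.null(band)) anap_band(s) else band
    bl <- fit_bleach(s, band = b)
    cs <- bleach_correct(s, bl)
    pk <- concentration_peaks(cs, band = b)
    nr <- normalize_response(pk)
    nr$cell <- s$cell_id
    bleach[[s$cell_id]] <- bl
    peaks[[s$cell_id]] <- pk
    pooled[[i]] <- nr
  }
  pooled <- do.call(rbind, pooled)
  hill <- fit_hill(pooled, fix_asymptotes = fix_asymptotes,
                   bootstrap = bootstrap,
                   boot_over = if (length(series_list) > 1) "cells" else "points",
                   seed = seed,
                   preparation = series_list[[1]]$preparation)
  list(hill = hill, bleach = bleach, peaks = peaks,
       max_quench = maximal_quench(peaks))
}
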