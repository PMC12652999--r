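#' Construct a quencher titration series
#'
#' Bundles blank-subtracted emission spectra measured at increasing quencher
#' concentrations, optionally with the per-solution absorbance spectra needed
#' for inner-filter correction. The zero-concentration entry defines F0.
#'
#' @param conc numeric molar concentrations, >= 0, strictly increasing,
#'   containing 0.
#' @param spectra list of [spectrum()] objects, one per concentration.
#' @param absorbances optional list of [absorbance_spectrum()] objects, one
#'   per concentration.
#' @param quencher label, e.g. `"5-HT"` or `"DA"`.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(conc, spectra, absorbances = NULL,
                             quencher = "5-HT") {
  conc <- as.numeric(conc)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop_validation("concentrations must be finite and >= 0")
  if (is.unsorted(conc, strictly = TRUE))
    stop_validation("concentrations must be strictly increasing")
  if (!any(conc == 0))
    stop_validation("the series must include concentration 0 (defines F0)")
  if (length(spectra) != length(conc))
    stop_validation("one spectrum per concentration required")
  if (!is.null(absorbances) && length(absorbances) != length(conc))
    stop_validation("one absorbance spectrum per concentration required")
  structure(list(conc = conc, spectra = spectra, absorbances = absorbances,
                 quencher = quencher),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration: %s, %d concentrations (%g-%g M)%s>\n", x$quencher,
              length(x$conc), min(x$conc), max(x$conc),
              if (is.null(x$absorbances)) "" else ", with absorbances"))
  invisible(x)
}

#' Stern-Volmer ratios from a titration
#'
#' Computes F0/F per concentration, where F is the band-averaged peak
#' fluorescence ([band_mean()], default 445-455 nm) of each blank-subtracted
#' spectrum, optionally after inner-filter correction, and F0 is the value at
#' zero quencher. The zero-concentration point is excluded from the output.
#'
#' @param series a [titration_series()].
#' @param band `c(lo, hi)` nm averaging band.
#' @param inner_filter logical; apply [inner_filter_correct()] using the
#'   series' absorbance spectra before taking band means.
#' @param excitation_nm excitation wavelength for reading OD_ex, default 370.
#' @param excitation_path_factor geometry factor passed to
#'   [inner_filter_correct()].
#' @return `data.frame` with columns `conc` (M) and `ratio` (F0/F).
#' @export
sv_ratios <- function(series, band = c(445, 455), inner_filter = FALSE,
                      excitation_nm = 370, excitation_path_factor = 0.2) {
  stopifnot(inherits(series, "titration_series"))
  if (inner_filter && is.null(series$absorbances))
    stop_validation("inner_filter = TRUE requires absorbance spectra for every concentration")
  f <- vapply(seq_along(series$conc), function(i) {
    sp <- series$spectra[[i]]
    if (inner_filter) {
      ab <- smooth_absorbance(series$absorbances[[i]])
      od_ex <- stats::approx(ab$wavelength, ab$od, xout = excitation_nm)$y
      if (is.na(od_ex))
        stop_data(sprintf("absorbance spectrum %d does not cover the excitation wavelength %g nm",
                          i, excitation_nm))
      sp <- inner_filter_correct(sp, od_ex, ab,
                                 excitation_path_factor = excitation_path_factor)
    }
    band_mean(sp, band[1], band[2])
  }, numeric(1))
  bad <- which(f <= 0)
  if (length(bad))
    stop_data(sprintf("nonpositive band fluorescence at concentration %g M",
                      series$conc[bad[1]]))
  f0 <- f[series$conc == 0][1]
  keep <- series$conc > 0
  data.frame(conc = series$conc[keep], ratio = f0 / f[keep])
}

#' Fit the Stern-Volmer relation
#'
#' Ordinary least squares of F0/F on quencher concentration:
#' \deqn{F_0/F = F_{intercept} + K_{sv} [Q]}
#' The slope K_sv (per molar) is proportional to quenching efficiency for
#' collisional quenching; the intercept is expected to be close to 1.
#'
#' @param points `data.frame` with columns `conc` (M) and `ratio` (F0/F), as
#'   produced by [sv_ratios()].
#' @param corrected logical flag recording whether the input was
#'   inner-filter corrected (carried into the fit object).
#' @param drop_enhancement drop points with ratio < 1 (solvatochromic
#'   enhancement) before fitting; default keeps all points.
#' @return An object of class `sv_fit` with components `ksv`, `intercept`,
#'   `r_squared`, `stderr` (named vector), `corrected`, `points` and the
#'   underlying `lm` fit. Methods: `print`, `summary`, `coef`, `predict`,
#'   `residuals`, `plot`.
#' @export
#' @examples
#' fit <- fit_stern_volmer(data.frame(conc = c(0, 0.1), ratio = c(1, 2.33)))
#' coef(fit)  # ksv = 13.3 per M
fit_stern_volmer <- function(points, corrected = FALSE,
                             drop_enhancement = FALSE) {
  if (!all(c("conc", "ratio") %in% names(points)))
    stop_validation("points must have columns conc and ratio")
  if (drop_enhancement) points <- points[points$ratio >= 1, , drop = FALSE]
  if (nrow(points) < 2L || length(unique(points$conc)) < 2L)
    stop_fit("Stern-Volmer fit needs >= 2 distinct concentrations")
  lmfit <- stats::lm(ratio ~ conc, data = points)
  cf <- stats::coef(lmfit)
  rss <- sum(stats::resid(lmfit)^2)
  df <- nrow(points) - 2L
  xtxinv <- chol2inv(qr.R(lmfit$qr))
  se <- if (df > 0) sqrt(diag(xtxinv) * rss / df) else rep(NA_real_, 2)
  names(se) <- names(cf)
  tss <- sum((points$ratio - mean(points$ratio))^2)
  r2 <- if (tss == 0) 1.0 else 1 - sum(stats::resid(lmfit)^2) / tss
  structure(list(ksv = unname(cf["conc"]), intercept = unname(cf["(Intercept)"]),
                 r_squared = r2,
                 stderr = c(intercept = unname(se["(Intercept)"]),
                            ksv = unname(se["conc"])),
                 corrected = corrected, points = points, lm = lmfit),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit%s: K_sv = %.4g per M, intercept = %.4g, R^2 = %.4g (n = %d)\n",
              if (x$corrected) " (inner-filter corrected)" else "",
              x$ksv, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
summary.sv_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  std. errors: intercept %.3g, K_sv %.3g\n",
              object$stderr["intercept"], object$stderr["ksv"]))
  invisible(object)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(intercept = object$intercept, ksv = object$ksv)
}

#' @export
predict.sv_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$points
  object$intercept + object$ksv * newdata$conc
}

#' @export
residuals.sv_fit <- function(object, ...) {
  object$points$ratio - predict(object)
}

#' @export
plot.sv_fit <- function(x, ...) {
  graphics::plot(x$points$conc, x$points$ratio, xlab = "[quencher] (M)",
                 ylab = expression(F[0] / F), pch = 19, ...)
  graphics::abline(a = x$intercept, b = x$ksv, col = "firebrick")
  invisible(x)
}

#' Fraction of fluorescence quenched
#'
#' Converts a Stern-Volmer ratio into the reporting convention "quenched by
#' X percent": `1 - 1/(F0/F)`. Ratios below 1 (fluorescence enhancement,
#' e.g. solvatochromic) yield negative fractions and a warning.
#'
#' @param f0_over_f positive ratio F0/F.
#' @return Quench fraction; negative values carry attribute
#'   `enhancement = TRUE`.
#' @export
quench_fraction <- function(f0_over_f) {
  if (any(!is.finite(f0_over_f)) || any(f0_over_f <= 0))
    stop_validation("F0/F must be positive and finite")
  out <- 1 - 1 / f0_over_f
  if (any(f0_over_f < 1)) {
    warning("F0/F < 1: fluorescence enhancement, quench fraction negative")
    attr(out, "enhancement") <- TRUE
  }
  out
}
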