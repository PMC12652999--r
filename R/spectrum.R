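#' Construct an emission spectrum
#'
#' A spectrum is a wavelength-indexed set of fluorescence intensities, the
#' unit of all steady-state analysis in this package. Wavelengths must be
#' strictly increasing and finite; raw intensities must be nonnegative
#' (negative values are only admitted after blank subtraction, see
#' [subtract_blank()]).
#'
#' @param wavelength numeric, wavelength grid in nm, strictly increasing.
#' @param intensity numeric, fluorescence in arbitrary units, same length.
#' @param meta named list of free-form labels (solvent, excitation wavelength
#'   in nm, sample id, ...).
#' @param allow_negative logical, permit negative intensities (used
#'   internally after blank subtraction).
#' @return An object of class `anap_spectrum` with elements `wavelength`,
#'   `intensity` and `meta`.
#' @export
#' @examples
#' s <- spectrum(400:500, dnorm(400:500, 451, 15))
#' peak_wavelength(s)
spectrum <- function(wavelength, intensity, meta = list(),
                     allow_negative = FALSE) {
  check_grid(wavelength)
  if (length(intensity) != length(wavelength))
    stop_validation("intensity and wavelength must have equal length")
  if (!all(is.finite(intensity)))
    stop_validation("intensity must be finite")
  if (!allow_negative && any(intensity < 0))
    stop_validation("raw spectra must be nonnegative; negatives are only permitted after blank subtraction")
  structure(list(wavelength = as.numeric(wavelength),
                 intensity = as.numeric(intensity),
                 meta = meta),
            class = "anap_spectrum")
}

#' Construct an absorbance spectrum
#'
#' Optical density (dimensionless) on a strictly increasing wavelength grid,
#' used for inner-filter correction.
#'
#' @param wavelength numeric nm grid, strictly increasing.
#' @param od numeric optical density, finite, same length.
#' @param meta named list of labels.
#' @return An object of class `anap_absorbance`.
#' @export
absorbance_spectrum <- function(wavelength, od, meta = list()) {
  check_grid(wavelength)
  if (length(od) != length(wavelength))
    stop_validation("od and wavelength must have equal length")
  if (!all(is.finite(od)))
    stop_validation("od must be finite")
  structure(list(wavelength = as.numeric(wavelength), od = as.numeric(od),
                 meta = meta),
            class = "anap_absorbance")
}

check_grid <- function(wavelength) {
  if (length(wavelength) < 1L || !all(is.finite(wavelength)))
    stop_validation("wavelength grid must be nonempty and finite")
  if (length(wavelength) > 1L && any(diff(wavelength) <= 0))
    stop_validation("wavelength grid must be strictly increasing")
  invisible(TRUE)
}

#' @export
print.anap_spectrum <- function(x, ...) {
  cat(sprintf("<emission spectrum: %d points, %.4g-%.4g nm>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta),
                         vapply(x$meta, function(v) paste(format(v), collapse = ","), ""),
                         sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
print.anap_absorbance <- function(x, ...) {
  cat(sprintf("<absorbance spectrum: %d points, %.4g-%.4g nm>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
as.data.frame.anap_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, intensity = x$intensity)
}

#' @export
as.data.frame.anap_absorbance <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, od = x$od)
}

#' Subtract a blank spectrum
#'
#' Removes quencher autofluorescence measured on a matched solution without
#' fluorophore. The grids must be identical; the result may carry negative
#' intensities, which are retained (not clipped) and flagged in the metadata,
#' because clipping would bias downstream band means.
#'
#' @param sample an [spectrum()] measured with fluorophore.
#' @param blank an [spectrum()] of the matched fluorophore-free solution.
#' @return The blank-subtracted `anap_spectrum`; `meta$blank_id` records the
#'   blank's sample id (if any) and `meta$has_negative` flags negative points.
#' @export
subtract_blank <- function(sample, blank) {
  stopifnot(inherits(sample, "anap_spectrum"), inherits(blank, "anap_spectrum"))
  mism <- which(sample$wavelength != blank$wavelength |
                  length(sample$wavelength) != length(blank$wavelength))
  if (length(sample$wavelength) != length(blank$wavelength))
    stop_data("wavelength grids differ in length")
  if (length(mism))
    stop_data(sprintf("wavelength grids differ, first at %.6g nm (blank %.6g nm)",
                      sample$wavelength[mism[1]], blank$wavelength[mism[1]]))
  out <- sample
  out$intensity <- sample$intensity - blank$intensity
  out$meta$blank_id <- if (!is.null(blank$meta$sample_id)) blank$meta$sample_id else "blank"
  out$meta$has_negative <- any(out$intensity < 0)
  class(out) <- "anap_spectrum"
  out
}

#' Kernel-smooth an absorbance spectrum
#'
#' Local Gaussian-kernel smoothing of the optical density, applied to
#' measured absorbance spectra before inner-filter correction. The kernel has
#' standard deviation `bandwidth` (nm), is truncated at +/- 4 sigma and
#' renormalized at the grid edges so boundary points do not droop. The grid
#' is unchanged; constants and (away from the edges) linear ramps pass
#' through unaltered.
#'
#' @param spec an [absorbance_spectrum()].
#' @param bandwidth kernel standard deviation in nm, > 0. Default 0.25 nm.
#' @return The smoothed `anap_absorbance` on the same grid.
#' @export
smooth_absorbance <- function(spec, bandwidth = 0.25) {
  stopifnot(inherits(spec, "anap_absorbance"))
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop_validation("bandwidth must be > 0")
  out <- spec
  out$od <- gaussian_kernel_smooth(spec$wavelength, spec$od, bandwidth)
  out$meta$smoothed_bandwidth_nm <- bandwidth
  out
}

gaussian_kernel_smooth <- function(x, y, bw) {
  n <- length(x)
  half <- 4 * bw
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- which(abs(x - x[i]) <= half)
    w <- exp(-0.5 * ((x[j] - x[i]) / bw)^2)
    out[i] <- sum(w * y[j]) / sum(w)
  }
  out
}

#' Inner-filter correction of an emission spectrum
#'
#' Corrects observed fluorescence for attenuation of the excitation beam and
#' re-absorption of emitted light by the sample itself:
#' \deqn{F(\lambda) = F_{obs}(\lambda) \times
#'   10^{(g \cdot OD_{ex} + OD_{em}(\lambda)) / 2}}
#' where `g` is the excitation path factor (default 0.2, for a low-volume
#' cuvette with a short 0.2 cm path toward the excitation light), `OD_ex` the
#' optical density at the excitation wavelength and `OD_em` the optical
#' density at each emission wavelength, interpolated from `abs`.
#'
#' @param spec blank-subtracted [spectrum()] to correct.
#' @param od_ex optical density at the excitation wavelength.
#' @param abs an [absorbance_spectrum()] covering the full emission range of
#'   `spec`; no extrapolation is performed.
#' @param excitation_path_factor dimensionless geometry factor, default 0.2.
#' @return Corrected `anap_spectrum`; the per-wavelength correction factors
#'   are recorded in `meta$inner_filter_factor`.
#' @export
inner_filter_correct <- function(spec, od_ex, abs,
                                 excitation_path_factor = 0.2) {
  stopifnot(inherits(spec, "anap_spectrum"), inherits(abs, "anap_absorbance"))
  if (!is.finite(od_ex)) stop_validation("od_ex must be finite")
  rng <- range(spec$wavelength)
  if (rng[1] < min(abs$wavelength) || rng[2] > max(abs$wavelength))
    stop_data(sprintf(
      "absorbance spectrum (%.4g-%.4g nm) does not cover emission range (%.4g-%.4g nm)",
      min(abs$wavelength), max(abs$wavelength), rng[1], rng[2]))
  od_em <- stats::approx(abs$wavelength, abs$od, xout = spec$wavelength)$y
  factor <- 10^((excitation_path_factor * od_ex + od_em) / 2)
  out <- spec
  out$intensity <- spec$intensity * factor
  out$meta$inner_filter_factor <- factor
  out$meta$inner_filter_od_ex <- od_ex
  out
}

#' Mean intensity over a wavelength band
#'
#' Averaged peak fluorescence over the grid points with
#' `lo <= lambda <= hi` (inclusive on both ends, no interpolation). The
#' default 445-455 nm band is the reporting band for ANAP emission in DMSO.
#'
#' @param spec an [spectrum()].
#' @param lo,hi band limits in nm, `lo < hi`.
#' @return Mean intensity (a.u.) over the band.
#' @export
band_mean <- function(spec, lo = 445, hi = 455) {
  stopifnot(inherits(spec, "anap_spectrum"))
  if (!(lo < hi)) stop_validation("band requires lo < hi")
  sel <- spec$wavelength >= lo & spec$wavelength <= hi
  if (!any(sel))
    stop_data(sprintf("band [%g, %g] nm contains no grid points", lo, hi))
  mean(spec$intensity[sel])
}

#' Wavelength of maximum intensity
#'
#' Ties are broken toward the shorter wavelength. An all-equal spectrum
#' returns its shortest wavelength with a warning.
#'
#' @param spec an [spectrum()].
#' @param window optional `c(lo, hi)` nm restricting the search (used to
#'   avoid a neighbouring band such as mOrange).
#' @return Peak wavelength in nm.
#' @export
peak_wavelength <- function(spec, window = NULL) {
  stopifnot(inherits(spec, "anap_spectrum"))
  wl <- spec$wavelength
  it <- spec$intensity
  if (!is.null(window)) {
    sel <- wl >= window[1] & wl <= window[2]
    if (!any(sel)) stop_data("peak search window contains no grid points")
    wl <- wl[sel]; it <- it[sel]
  }
  if (length(unique(it)) == 1L) {
    warning("flat spectrum: returning shortest wavelength")
    return(wl[1])
  }
  wl[which.max(it)]  # which.max takes the first (shortest-wavelength) maximum
}
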