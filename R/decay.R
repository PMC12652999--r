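#' Construct a time-resolved decay trace
#'
#' Uniform-time-grid signal from time-resolved photoluminescence (TRPL,
#' photon counts) or transient absorption (TAS, delta-OD). The default bin
#' width throughout the package is 0.4 ns, the detector's highest
#' time-resolution mode.
#'
#' @param time numeric ns grid, strictly increasing, uniform spacing (within
#'   1e-9 relative tolerance).
#' @param signal numeric, counts (TRPL) or delta-OD (TAS), same length.
#' @param kind `"trpl"` or `"tas"`.
#' @param averages number of laser shots averaged.
#' @param mask optional logical vector marking bins excluded from fits
#'   (e.g. the TAS saturation artifact); `TRUE` = masked.
#' @param meta named list of labels.
#' @return An object of class `decay_trace`.
#' @export
decay_trace <- function(time, signal, kind = c("trpl", "tas"), averages = 1,
                        mask = NULL, meta = list()) {
  kind <- match.arg(kind)
  time <- as.numeric(time)
  if (length(time) < 2L || !all(is.finite(time)))
    stop_validation("time grid must be finite with >= 2 points")
  dt <- diff(time)
  if (any(dt <= 0)) stop_validation("time grid must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop_validation("time grid must be uniform (1e-9 relative tolerance)")
  if (length(signal) != length(time))
    stop_validation("signal and time must have equal length")
  if (!all(is.finite(signal))) stop_validation("signal must be finite")
  if (is.null(mask)) mask <- rep(FALSE, length(time))
  structure(list(time = time, signal = as.numeric(signal), kind = kind,
                 averages = averages, mask = mask, meta = meta),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("<%s trace: %d bins x %.3g ns, %g averages%s>\n",
              toupper(x$kind), length(x$time), x$time[2] - x$time[1],
              x$averages,
              if (any(x$mask)) sprintf(", %d masked", sum(x$mask)) else ""))
  invisible(x)
}

#' @export
plot.decay_trace <- function(x, ...) {
  graphics::plot(x$time, x$signal, type = "l", xlab = "time (ns)",
                 ylab = if (x$kind == "tas") expression(Delta * OD) else "counts",
                 ...)
  invisible(x)
}

#' Construct an instrument response function
#'
#' The apparatus's temporal response to an instantaneous pulse, measured as
#' the elastically scattered laser pulse. The response is nonnegative and is
#' normalized to sum to 1 (a notice is emitted if normalization was needed).
#'
#' @param time ns grid matching the trace convention (uniform, increasing).
#' @param response nonnegative response values.
#' @param meta named list of labels.
#' @return An object of class `anap_irf`.
#' @export
irf <- function(time, response, meta = list()) {
  time <- as.numeric(time)
  response <- as.numeric(response)
  if (length(time) != length(response))
    stop_validation("response and time must have equal length")
  if (any(!is.finite(response)) || any(response < 0))
    stop_validation("IRF response must be finite and nonnegative")
  s <- sum(response)
  if (s <= 0) stop_validation("IRF response must have positive total")
  if (abs(s - 1) > 1e-12) {
    message(sprintf("normalizing IRF (sum was %.6g)", s))
    response <- response / s
  }
  structure(list(time = time, response = response, meta = meta),
            class = "anap_irf")
}

#' @export
print.anap_irf <- function(x, ...) {
  cat(sprintf("<IRF: %d bins, peak at %.3g ns, FWHM ~ %.3g ns>\n",
              length(x$time), irf_peak_time(x), irf_fwhm(x)))
  invisible(x)
}

irf_peak_time <- function(x) x$time[which.max(x$response)]

irf_fwhm <- function(x) {
  half <- max(x$response) / 2
  above <- which(x$response >= half)
  if (length(above) < 2) return(x$time[2] - x$time[1])
  x$time[max(above)] - x$time[min(above)]
}

#' Build a transient-absorption trace from raw intensity traces
#'
#' The pump-probe delta-OD signal is assembled from the probe intensity with
#' the pump on (`pumped`), with the pump off (`unpumped`), and the
#' pump-induced fluorescence background measured with the probe off
#' (`fluorescence`):
#' \deqn{\Delta OD(t) = -\log_{10}\frac{I_{pumped}(t) - I_{fluor}(t)}
#'   {I_{unpumped}(t)}}
#' Bins where the numerator is nonpositive are masked (not dropped) and
#' counted in `meta$n_masked_nonpositive`.
#'
#' @param pumped,unpumped,fluorescence `decay_trace` objects on identical
#'   grids; `unpumped` must be positive everywhere.
#' @return A `decay_trace` of kind `"tas"`.
#' @export
build_tas_trace <- function(pumped, unpumped, fluorescence) {
  check_same_grid(pumped, unpumped)
  check_same_grid(pumped, fluorescence)
  if (any(unpumped$signal <= 0))
    stop_data("unpumped intensity must be positive everywhere")
  num <- pumped$signal - fluorescence$signal
  bad <- num <= 0
  if (all(bad)) stop_data("all bins have nonpositive numerator")
  dod <- rep(0, length(num))
  dod[!bad] <- -log10(num[!bad] / unpumped$signal[!bad])
  decay_trace(pumped$time, dod, kind = "tas", averages = pumped$averages,
              mask = bad | pumped$mask,
              meta = c(pumped$meta, list(n_masked_nonpositive = sum(bad))))
}

check_same_grid <- function(a, b) {
  if (length(a$time) != length(b$time) ||
      max(abs(a$time - b$time)) > 1e-9 * max(abs(a$time), 1))
    stop_data("time grids differ between traces")
  invisible(TRUE)
}

#' Subtract a background decay trace
#'
#' Plain pointwise subtraction of a separately measured background trace
#' (e.g. the quencher-only fluorescence) from a mixture trace. No rescaling
#' is applied. Grids and kinds must match; averaging metadata is taken from
#' the mixture.
#'
#' @param mixture,background `decay_trace` objects on identical grids of the
#'   same kind.
#' @return The background-subtracted `decay_trace`.
#' @export
subtract_background_trace <- function(mixture, background) {
  stopifnot(inherits(mixture, "decay_trace"), inherits(background, "decay_trace"))
  if (mixture$kind != background$kind)
    stop_data(sprintf("trace kinds differ: %s vs %s", mixture$kind, background$kind))
  check_same_grid(mixture, background)
  out <- mixture
  out$signal <- mixture$signal - background$signal
  out$meta$background_subtracted <- TRUE
  out
}

# Bare (un-convolved) decay laws, evaluated at elapsed time t >= 0 and zero
# before t = 0. `model` is "exp1", "exp2" or "second_order".
decay_law <- function(t, model, pars) {
  h <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  h[pos] <- switch(model,
    exp1 = pars$amplitudes[1] * exp(-tp / pars$lifetimes[1]),
    exp2 = pars$amplitudes[1] * exp(-tp / pars$lifetimes[1]) +
           pars$amplitudes[2] * exp(-tp / pars$lifetimes[2]),
    second_order = pars$amplitudes[1] / (1 + pars$rate * tp),
    stop_validation(sprintf("unknown model '%s'", model)))
  h
}

#' Convolve a decay model with the IRF
#'
#' Causal discrete convolution of the (unit-sum) IRF with a model decay law
#' evaluated on the trace grid, shifted by `t0`. Supported laws:
#' single exponential (`"exp1"`), biexponential (`"exp2"`,
#' `h(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2)`) and second-order kinetics
#' (`"second_order"`, `h(t) = a / (1 + k t)`). Because the IRF sums to 1 the
#' convolution preserves the discrete integral of `h` away from the grid
#' edges.
#'
#' @param irf an [irf()] object on a grid with the same bin width.
#' @param model `"exp1"`, `"exp2"` or `"second_order"`.
#' @param pars list with `lifetimes` (ns) and `amplitudes` (and `rate`,
#'   per ns, for `"second_order"`).
#' @param time trace time grid (ns, uniform).
#' @param t0 shift of the decay origin in ns.
#' @return Numeric model trace on `time`.
#' @export
convolve_with_irf <- function(irf, model, pars, time, t0 = 0) {
  stopifnot(inherits(irf, "anap_irf"))
  if (model %in% c("exp1", "exp2") && any(pars$lifetimes <= 0))
    stop_validation("lifetimes must be positive")
  if (model == "second_order" && pars$rate < 0)
    stop_validation("second-order rate must be nonnegative")
  h <- decay_law(time - time[1] - t0, model, pars)
  r <- irf$response
  n <- length(h)
  # z[k] = sum_j r[j] h[k - j + 1] — causal convolution, first n points
  z <- stats::convolve(r, rev(h), type = "open")
  z[seq_len(n)]
}
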