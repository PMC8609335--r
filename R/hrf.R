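#' Canonical double-gamma HRF specification
#'
#' The canonical shape peaks near 5 s with a late undershoot
#' (gamma(6, 1) - gamma(16, 1)/6 in seconds); responses are modeled as this
#' kernel convolved with a boxcar of the stimulus duration.
#'
#' @param duration stimulus (boxcar) duration in seconds (default 1.6).
#' @param amplitude kernel scale factor (default 1).
#' @param peakShape,peakScale,undershootShape,undershootScale,undershootRatio
#'   double-gamma parameters.
#' @return an \linkS4class{HRFSpec}.
#' @export
hrfSpec <- function(duration = 1.6, amplitude = 1, peakShape = 6,
                    peakScale = 1, undershootShape = 16, undershootScale = 1,
                    undershootRatio = 1 / 6) {
  new("HRFSpec", peakShape = peakShape, peakScale = peakScale,
      undershootShape = undershootShape, undershootScale = undershootScale,
      undershootRatio = undershootRatio, duration = duration,
      amplitude = amplitude)
}

#' Sample the double-gamma impulse response
#'
#' @param hrf an \linkS4class{HRFSpec}.
#' @param dt sampling interval in seconds.
#' @param length_s kernel support in seconds (default 32).
#' @return numeric vector of kernel values at 0, dt, 2*dt, ...
#' @export
hrfKernel <- function(hrf, dt, length_s = 32) {
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = hrf@peakShape, scale = hrf@peakScale) -
    hrf@undershootRatio *
      stats::dgamma(t, shape = hrf@undershootShape, scale = hrf@undershootScale)
  hrf@amplitude * h
}

#' Build one HRF-convolved regressor on the TR grid
#'
#' Events are rendered as boxcars of their duration (scaled by their
#' amplitude) on an oversampled grid, convolved with the double-gamma kernel,
#' and sampled at TR resolution.  Events whose onsets coincide have their
#' amplitudes summed with a warning.
#'
#' @param onsets event onsets in seconds.
#' @param durations event durations in seconds.
#' @param amplitudes event amplitudes.
#' @param nTimes number of TRs in the output.
#' @param tr repetition time (s).
#' @param hrf an \linkS4class{HRFSpec}.
#' @param oversample oversampling factor of the internal grid (default 16).
#' @export
hrfRegressor <- function(onsets, durations, amplitudes, nTimes, tr, hrf,
                         oversample = 16) {
  if (any(duplicated(onsets[amplitudes != 0])))
    warning("identical onsets within one regressor; amplitudes summed")
  dt <- tr / oversample
  nGrid <- nTimes * oversample
  stim <- numeric(nGrid)
  for (i in seq_along(onsets)) {
    if (amplitudes[i] == 0) next
    a <- floor(onsets[i] / dt) + 1
    b <- min(nGrid, ceiling((onsets[i] + durations[i]) / dt))
    if (a > nGrid) next
    stim[a:b] <- stim[a:b] + amplitudes[i]
  }
  kern <- hrfKernel(hrf, dt)
  conv <- stats::convolve(stim, rev(kern), type = "open")[seq_len(nGrid)] * dt
  conv[seq(1, nGrid, by = oversample)]
}
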