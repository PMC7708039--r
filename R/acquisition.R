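#' TCSPC acquisition settings
#'
#' Bundles the instrument settings that define a time-correlated
#' single-photon counting (TCSPC) histogram: the time window, the number of
#' equal-width channels, the target expected count in the peak channel, an
#' optional Gaussian instrument response function (IRF), and a uniform
#' background rate. Defaults mirror a typical picosecond TCSPC acquisition
#' for lifetime-FRET work on labelled DNA: a 100 ns window resolved into
#' 4096 channels, collected to 10 000 counts in the peak channel.
#'
#' @param window Time span of the histogram in ns. Must be positive.
#' @param n_channels Number of equal-width channels (at least 2).
#' @param peak_counts Target expected counts in the maximum channel.
#' @param irf_fwhm Full width at half maximum of a Gaussian IRF in ns;
#'   `0` means an ideal delta-function response (no convolution).
#' @param background_rate Expected uniform background counts per channel.
#' @param seed Integer RNG seed used when Poisson noise is drawn.
#'
#' @return A list of class `"acquisition"` with the validated fields.
#' @examples
#' acq <- acquisition()
#' acq$window / acq$n_channels # channel width in ns
#' @export
acquisition <- function(window = 100, n_channels = 4096, peak_counts = 10000,
                        irf_fwhm = 0, background_rate = 0, seed = 1L) {
  stopifnot(
    "window must be > 0" = is.numeric(window) && length(window) == 1 && window > 0,
    "n_channels must be >= 2" = n_channels >= 2,
    "peak_counts must be > 0" = peak_counts > 0,
    "irf_fwhm must be >= 0" = irf_fwhm >= 0,
    "background_rate must be >= 0" = background_rate >= 0
  )
  structure(
    list(
      window = as.numeric(window),
      n_channels = as.integer(n_channels),
      peak_counts = as.numeric(peak_counts),
      irf_fwhm = as.numeric(irf_fwhm),
      background_rate = as.numeric(background_rate),
      seed = as.integer(seed)
    ),
    class = "acquisition"
  )
}

#' @export
print.acquisition <- function(x, ...) {
  cat(sprintf(
    "<acquisition> %g ns / %d channels, peak %g counts, IRF FWHM %g ns, bkg %g/channel, seed %d\n",
    x$window, x$n_channels, x$peak_counts, x$irf_fwhm, x$background_rate, x$seed
  ))
  invisible(x)
}

#' Lifetime component table
#'
#' A set of exponential decay components, each with a lifetime `tau` (ns)
#' and a fractional amplitude. Amplitudes are the relative weights of the
#' components at time zero and must sum to 1; each corresponds to the
#' fractional population of one conformational state in a lifetime-FRET
#' experiment.
#'
#' @param tau Numeric vector of lifetimes in ns, all positive.
#' @param amplitude Numeric vector of non-negative fractional amplitudes,
#'   same length as `tau`, summing to 1 within `1e-9`.
#'
#' @return A tibble with columns `tau` and `amplitude`.
#' @examples
#' lifetime_components(c(0.40, 1.7, 5.2), c(0.39, 0.33, 0.28))
#' @export
lifetime_components <- function(tau, amplitude) {
  stopifnot(
    "tau and amplitude must have equal length" = length(tau) == length(amplitude),
    "tau must be positive" = all(tau > 0),
    "amplitudes must be non-negative" = all(amplitude >= 0)
  )
  total <- sum(amplitude)
  if (abs(total - 1) > 1e-9) {
    stop(sprintf("component amplitudes must sum to 1 (got %.12g)", total), call. = FALSE)
  }
  tibble::tibble(tau = as.numeric(tau), amplitude = as.numeric(amplitude))
}
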