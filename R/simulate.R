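#' Channel-center time axis for an acquisition
#'
#' @param acq An [acquisition()] object.
#' @return Numeric vector of channel-center times in ns, channel 1 centred
#'   at half a channel width.
#' @keywords internal
#' @noRd
channel_times <- function(acq) {
  dt <- acq$window / acq$n_channels
  (seq_len(acq$n_channels) - 0.5) * dt
}

#' Multi-exponential decay basis on the acquisition time grid
#'
#' Returns one unit-peak column per lifetime: `exp(-(t_k - t_1)/tau)` for a
#' delta-function IRF, or the same ideal decay convolved with a Gaussian
#' instrument response when `irf_fwhm > 0`. In both cases channel 1 sits at
#' the IRF peak position, so the kernel is the forward model shared by the
#' simulator and the maximum-entropy inversion.
#'
#' @param acq An [acquisition()] object.
#' @param taus Vector of lifetimes in ns.
#' @return `n_channels x length(taus)` matrix.
#' @keywords internal
decay_kernel <- function(acq, taus) {
  stopifnot(all(taus > 0))
  n <- acq$n_channels
  dt <- acq$window / n
  t_rel <- (seq_len(n) - 1) * dt
  if (acq$irf_fwhm <= 0) {
    K <- exp(-outer(t_rel, taus, `/`))
    return(K)
  }
  # Gaussian IRF: convolve the ideal decay on an extended grid that covers
  # the pre-peak rise, then read off channels starting at the IRF peak (t=0).
  sigma <- acq$irf_fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma / dt))
  kern <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  kern <- kern / sum(kern)
  t_ext <- (seq(-half, n - 1 + half)) * dt
  K <- matrix(0, n, length(taus))
  for (i in seq_along(taus)) {
    ideal <- ifelse(t_ext >= 0, exp(-t_ext / taus[i]), 0)
    padded <- c(rep(0, half), ideal, rep(0, half))
    sm <- as.numeric(stats::filter(padded, kern, sides = 2))
    sm <- sm[(half + 1):(half + length(t_ext))]
    K[, i] <- sm[(half + 1):(half + n)]
  }
  K
}

#' Simulate a TCSPC fluorescence decay trace
#'
#' Forward-models a photon-count histogram from a set of exponential
#' lifetime components under given acquisition settings. The expected value
#' in channel k is
#' \deqn{\mu_k = b + S \sum_i a_i e^{-t_k/\tau_i}}
#' (convolved with a Gaussian IRF when `irf_fwhm > 0`), with the scale S
#' chosen so that the maximum expected channel equals `peak_counts`.
#' Recorded counts are independent Poisson draws of \eqn{\mu_k}, matching
#' the photon statistics of TCSPC; with `noiseless = TRUE` the expectation
#' itself is returned.
#'
#' @param components A data frame with columns `tau` (ns) and `amplitude`
#'   (fractional, summing to 1), e.g. from [lifetime_components()].
#' @param acq An [acquisition()] object; its `seed` drives the Poisson draw.
#' @param noiseless If `TRUE`, return expected counts instead of draws.
#'
#' @return A `decay_trace`: a tibble with columns `time_ns` and `counts`,
#'   carrying the acquisition settings and ground-truth components as
#'   attributes.
#' @examples
#' comps <- lifetime_components(4.9, 1)
#' tr <- simulate_decay(comps, acquisition(), noiseless = TRUE)
#' max(tr$counts) # 10000 in the peak channel
#' @export
simulate_decay <- function(components, acq = acquisition(), noiseless = FALSE) {
  stopifnot(is.data.frame(components), all(c("tau", "amplitude") %in% names(components)))
  total <- sum(components$amplitude)
  if (abs(total - 1) > 1e-9) {
    stop(sprintf("component amplitudes must sum to 1 (got %.12g)", total), call. = FALSE)
  }
  if (any(components$tau <= 0)) stop("lifetimes must be positive", call. = FALSE)
  if (any(components$tau >= 10 * acq$window)) {
    warning("a lifetime is >= 10x the acquisition window and cannot be resolved",
      call. = FALSE
    )
  }
  K <- decay_kernel(acq, components$tau)
  shape <- as.numeric(K %*% components$amplitude)
  b <- acq$background_rate
  if (acq$peak_counts <= b) {
    stop("peak_counts must exceed background_rate", call. = FALSE)
  }
  scale <- (acq$peak_counts - b) / max(shape)
  mu <- b + scale * shape
  counts <- if (noiseless) {
    mu
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(acq$seed)
    stats::rpois(length(mu), mu)
  }
  new_decay_trace(
    tibble::tibble(time_ns = channel_times(acq), counts = as.numeric(counts)),
    acq = acq, components = components, noiseless = noiseless
  )
}

new_decay_trace <- function(df, acq, components = NULL, noiseless = NA) {
  structure(df,
    class = c("decay_trace", class(tibble::tibble())),
    acq = acq, components = components, noiseless = noiseless
  )
}

#' @export
print.decay_trace <- function(x, ...) {
  acq <- attr(x, "acq")
  cat(sprintf(
    "<decay_trace> %d channels over %g ns, %s total counts\n",
    nrow(x), acq$window, format(sum(x$counts), big.mark = ",")
  ))
  NextMethod()
}

# Preserve the caller's RNG state around seeded draws so that simulation is
# reproducible without clobbering the session stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
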