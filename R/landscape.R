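#' FRET efficiency from donor lifetimes
#'
#' Computes \eqn{E = 1 - \tau_{DA}/\tau_D}, where \eqn{\tau_{DA}} and
#' \eqn{\tau_D} are the donor lifetimes in the presence and absence of the
#' acceptor. Peaks with \eqn{\tau_{DA}} slightly above \eqn{\tau_D}
#' (within measurement precision of zero transfer) give small negative raw
#' values; with `clamp = TRUE` these are reported as 0 while the raw value
#' is kept in the `"raw"` attribute.
#'
#' @param tau_DA Donor lifetime(s) with acceptor present, ns. Vectorized.
#' @param tau_D Donor-only reference lifetime, ns.
#' @param clamp If `TRUE`, negative efficiencies are floored at 0 (raw
#'   values retained in `attr(, "raw")`).
#' @return Numeric vector of efficiencies.
#' @examples
#' fret_efficiency(0.32, 4.9) # ~0.93
#' fret_efficiency(5.2, 4.9, clamp = TRUE) # 0, raw -0.061
#' @export
fret_efficiency <- function(tau_DA, tau_D, clamp = FALSE) {
  if (any(tau_DA <= 0) || any(tau_D <= 0)) {
    stop("lifetimes must be positive", call. = FALSE)
  }
  e <- 1 - tau_DA / tau_D
  if (clamp) {
    raw <- e
    e <- pmax(e, 0)
    attr(e, "raw") <- raw
  }
  e
}

#' Amplitude-weighted average FRET efficiency
#'
#' Computes \eqn{\langle E \rangle = 1 - (\sum_i A_i \tau_{DA,i})/\tau_D},
#' where \eqn{A_i = \alpha_i / \sum_i \alpha_i} are normalized amplitudes.
#' The weights may come from the raw grid amplitudes of a
#' [mem_fit()] distribution, from Gaussian peak areas, or be supplied
#' directly; the source used is recorded in the `"weights"` attribute.
#'
#' @param x A `lifetime_distribution`, a data frame of peaks (columns
#'   `center_ns` and `area`), or a numeric vector of lifetimes.
#' @param tau_D Donor-only reference lifetime in ns.
#' @param amplitudes For the numeric method: non-negative weights, one per
#'   lifetime.
#' @param ... Passed between methods.
#' @return Length-one numeric: the average FRET efficiency.
#' @examples
#' average_fret(c(0.40, 1.7, 5.2), 4.9, amplitudes = c(0.39, 0.33, 0.28))
#' @export
average_fret <- function(x, tau_D, ...) UseMethod("average_fret")

#' @rdname average_fret
#' @export
average_fret.default <- function(x, tau_D, amplitudes, ...) {
  if (length(x) == 0) stop("no lifetime components supplied", call. = FALSE)
  stopifnot(length(amplitudes) == length(x), tau_D > 0, all(x > 0), all(amplitudes >= 0))
  total <- sum(amplitudes)
  if (total <= 0) stop("amplitudes sum to zero", call. = FALSE)
  A <- amplitudes / total
  out <- 1 - sum(A * x) / tau_D
  attr(out, "weights") <- "supplied"
  out
}

#' @rdname average_fret
#' @export
average_fret.lifetime_distribution <- function(x, tau_D, ...) {
  keep <- x$amplitude > 0
  if (!any(keep)) stop("distribution has no amplitude", call. = FALSE)
  out <- average_fret.default(x$tau_ns[keep], tau_D, x$amplitude[keep])
  attr(out, "weights") <- "grid amplitudes"
  out
}

#' @rdname average_fret
#' @export
average_fret.data.frame <- function(x, tau_D, ...) {
  if (!all(c("center_ns", "area") %in% names(x))) {
    stop("peak table must have columns center_ns and area", call. = FALSE)
  }
  out <- average_fret.default(x$center_ns, tau_D, x$area)
  attr(out, "weights") <- "peak areas"
  out
}

# Gaussian-kernel smoothing over grid index, used for peak seeding/counting.
smooth_amplitude <- function(amplitude, sd_points = 2) {
  n <- length(amplitude)
  half <- max(1L, ceiling(3 * sd_points))
  kern <- stats::dnorm(seq(-half, half), sd = sd_points)
  kern <- kern / sum(kern)
  padded <- c(rep(0, half), amplitude, rep(0, half))
  sm <- as.numeric(stats::filter(padded, kern, sides = 2))
  sm[(half + 1):(half + n)]
}

# Indices of local maxima of the smoothed amplitude profile that exceed
# threshold_fraction of the total amplitude.
find_peaks <- function(amplitude, threshold_fraction = 0.02, sd_points = 2) {
  total <- sum(amplitude)
  if (total <= 0) {
    return(integer(0))
  }
  sm <- smooth_amplitude(amplitude, sd_points)
  n <- length(sm)
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) sm[i - 1] else -Inf
    right <- if (i < n) sm[i + 1] else -Inf
    sm[i] > left && sm[i] >= right
  }, logical(1))
  idx <- which(is_max & sm > threshold_fraction * sum(sm))
  idx[order(sm[idx], decreasing = TRUE)]
}

#' Count resolved peaks in a lifetime distribution
#'
#' Counts smoothed local maxima whose height exceeds a fraction of the
#' total amplitude. This operational peak count seeds [fit_gaussians()]
#' and is the statistic used to classify a distribution as, e.g.,
#' mono-modal (a donor-only sample) or tri-modal (a heterogeneous
#' donor-acceptor sample).
#'
#' @param dist A `lifetime_distribution`.
#' @param threshold_fraction Minimum smoothed peak height as a fraction of
#'   total amplitude (default 0.02).
#' @param sd_points Gaussian smoothing width in grid points.
#' @return Integer peak count (0 for an all-zero distribution).
#' @export
count_peaks <- function(dist, threshold_fraction = 0.02, sd_points = 2) {
  length(find_peaks(dist$amplitude, threshold_fraction, sd_points))
}

#' Decompose a lifetime distribution into Gaussian peaks
#'
#' Fits sums of 1..`max_components` Gaussians to the amplitude profile in
#' log10-lifetime, where log-spaced MEM distributions are natural, and
#' selects the component count by BIC. Initial centers are seeded at
#' smoothed local maxima exceeding `threshold_fraction` of total
#' amplitude. The area under each Gaussian, normalized over all peaks, is
#' the fractional population of the corresponding conformational state.
#'
#' @param dist A `lifetime_distribution` with non-zero total amplitude.
#' @param max_components Largest number of Gaussians tried (>= 1).
#' @param threshold_fraction Seeding threshold, as in [count_peaks()].
#' @return A tibble of peaks ordered by center: `center_ns`, `width_log10`,
#'   `height`, `area`, `fractional_population`, with the selected BIC table
#'   in `attr(, "model_selection")`.
#' @examples
#' \donttest{
#' tr <- simulate_decay(
#'   lifetime_components(c(0.40, 1.7, 5.2), c(0.39, 0.33, 0.28)),
#'   acquisition(seed = 2)
#' )
#' peaks <- fit_gaussians(mem_fit(tr))
#' peaks$fractional_population
#' }
#' @export
fit_gaussians <- function(dist, max_components = 4, threshold_fraction = 0.02) {
  if (max_components < 1) stop("max_components must be >= 1", call. = FALSE)
  y <- dist$amplitude
  if (sum(y) <= 0) stop("degenerate input: distribution has no amplitude", call. = FALSE)
  x <- log10(dist$tau_ns)
  yscale <- max(y)
  ys <- y / yscale
  n <- length(x)
  dx <- mean(diff(x))

  seeds <- find_peaks(y, threshold_fraction)
  if (length(seeds) == 0) seeds <- which.max(y)

  # Centers are confined to the grid range and widths to
  # [dx/2, full span] through logistic transforms, so the optimizer cannot
  # park a component outside the measured lifetime axis.
  x_lo <- min(x) - 2 * dx
  x_hi <- max(x) + 2 * dx
  w_lo <- dx / 2
  w_hi <- max(x) - min(x)
  to_box <- function(p, lo, hi) lo + (hi - lo) * stats::plogis(p)
  from_box <- function(v, lo, hi) {
    stats::qlogis(pmin(pmax((v - lo) / (hi - lo), 1e-6), 1 - 1e-6))
  }

  model_y <- function(par, g) {
    h <- exp(par[seq_len(g)])
    cc <- to_box(par[g + seq_len(g)], x_lo, x_hi)
    wd <- to_box(par[2 * g + seq_len(g)], w_lo, w_hi)
    rowSums(vapply(seq_len(g), function(j) {
      h[j] * exp(-(x - cc[j])^2 / (2 * wd[j]^2))
    }, numeric(n)))
  }

  fit_one <- function(g) {
    centers <- if (length(seeds) >= g) {
      sort(x[seeds[seq_len(g)]])
    } else {
      extra <- stats::quantile(x[y > threshold_fraction * sum(y) / n],
        probs = seq(0.15, 0.85, length.out = g - length(seeds))
      )
      sort(c(x[seeds], as.numeric(extra)))
    }
    h0 <- pmax(vapply(centers, function(cj) ys[which.min(abs(x - cj))], numeric(1)), 1e-3)
    par0 <- c(
      log(h0),
      from_box(centers, x_lo, x_hi),
      rep(from_box(4 * dx, w_lo, w_hi), g)
    )
    res <- try(
      minpack.lm::nls.lm(
        par = par0,
        fn = function(p) ys - model_y(p, g),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      silent = TRUE
    )
    if (inherits(res, "try-error")) {
      return(NULL)
    }
    rss <- sum(res$fvec^2)
    list(par = res$par, g = g, rss = rss, bic = n * log(rss / n) + 3 * g * log(n))
  }

  fits <- purrr::compact(purrr::map(seq_len(max_components), fit_one))
  if (length(fits) == 0) {
    stop("Gaussian decomposition failed for every component count", call. = FALSE)
  }
  # parsimony rule: the smallest component count whose BIC comes within 10
  # of the minimum (differences under ~10 are weak evidence for the larger
  # model)
  bics <- purrr::map_dbl(fits, "bic")
  best <- fits[[min(which(bics <= min(bics) + 10))]]
  g <- best$g
  h <- exp(best$par[seq_len(g)]) * yscale
  cc <- to_box(best$par[g + seq_len(g)], x_lo, x_hi)
  wd <- to_box(best$par[2 * g + seq_len(g)], w_lo, w_hi)
  # Gaussian area restricted to the measured lifetime axis, so a broad
  # component reaching past the grid cannot claim off-axis mass.
  area <- h * wd * sqrt(2 * pi) *
    (stats::pnorm((max(x) - cc) / wd) - stats::pnorm((min(x) - cc) / wd))
  # components below the peak threshold are fit artifacts, not states
  keep <- area >= threshold_fraction * sum(area)
  if (!any(keep)) keep <- area == max(area)
  cc <- cc[keep]
  wd <- wd[keep]
  h <- h[keep]
  area <- area[keep]
  ord <- order(cc)
  peaks <- tibble::tibble(
    center_ns = 10^cc[ord],
    width_log10 = wd[ord],
    height = h[ord],
    area = area[ord],
    fractional_population = area[ord] / sum(area)
  )
  attr(peaks, "model_selection") <- tibble::tibble(
    n_components = purrr::map_int(fits, ~ as.integer(.x$g)),
    rss = purrr::map_dbl(fits, "rss"),
    bic = purrr::map_dbl(fits, "bic")
  )
  peaks
}

#' Assemble a conformational landscape from Gaussian peaks
#'
#' Attaches per-peak FRET efficiencies and the amplitude-weighted average
#' efficiency to a Gaussian decomposition, given the donor-only reference
#' lifetime. Each peak represents one co-existing conformational state;
#' its area fraction is the state's fractional population and its center
#' lifetime maps to a FRET efficiency \eqn{E = 1 - \tau_{peak}/\tau_D}
#' (clamped at 0 for reporting, raw value kept in `E_raw`).
#'
#' @param peaks A peak table from [fit_gaussians()].
#' @param tau_D Donor-only reference lifetime in ns.
#' @return A `conformational_landscape`: the peak tibble with `E_peak` and
#'   `E_raw` columns, plus `tau_D` and `mean_E` attributes.
#' @examples
#' pk <- tibble::tibble(
#'   center_ns = c(0.40, 1.7, 5.2), width_log10 = 0.1,
#'   height = 1, area = c(0.39, 0.33, 0.28),
#'   fractional_population = c(0.39, 0.33, 0.28)
#' )
#' ls <- conformational_landscape(pk, tau_D = 4.9)
#' attr(ls, "mean_E")
#' @export
conformational_landscape <- function(peaks, tau_D) {
  stopifnot(tau_D > 0, nrow(peaks) >= 1)
  e_raw <- fret_efficiency(peaks$center_ns, tau_D)
  out <- dplyr::mutate(peaks, E_raw = e_raw, E_peak = pmax(e_raw, 0))
  mean_e <- average_fret.default(peaks$center_ns, tau_D, peaks$area)
  structure(out,
    class = c("conformational_landscape", class(tibble::tibble())),
    tau_D = tau_D, mean_E = as.numeric(mean_e)
  )
}

#' @export
print.conformational_landscape <- function(x, ...) {
  cat(sprintf(
    "<conformational_landscape> %d peak(s), tau_D = %g ns, <E> = %.3f\n",
    nrow(x), attr(x, "tau_D"), attr(x, "mean_E")
  ))
  NextMethod()
}
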