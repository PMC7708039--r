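#' Block-averaged mean and uncertainty of a correlated series
#'
#' Partitions a series into `n_blocks` contiguous equal blocks (discarding
#' and reporting any trailing remainder) and returns the overall mean and
#' the standard deviation of the block means. For correlated data - e.g.
#' per-frame geometry descriptors along a trajectory - the block-mean SD
#' is a less optimistic uncertainty than the naive standard error, and for
#' iid data with variance sigma^2 and block length L it approaches
#' sigma/sqrt(L).
#'
#' @param x Numeric series, length >= `n_blocks`.
#' @param n_blocks Number of blocks (>= 2).
#' @return A list: `mean`, `block_sd`, `block_means`, `block_length`,
#'   `n_blocks`, `n_discarded`.
#' @examples
#' block_average(rnorm(1000), n_blocks = 10)$block_sd
#' @export
block_average <- function(x, n_blocks) {
  stopifnot(n_blocks >= 2)
  n <- length(x)
  if (n < n_blocks) {
    stop("series shorter than the requested number of blocks", call. = FALSE)
  }
  L <- n %/% n_blocks
  used <- x[seq_len(L * n_blocks)]
  means <- colMeans(matrix(used, nrow = L))
  list(
    mean = mean(used),
    block_sd = stats::sd(means),
    block_means = means,
    block_length = L,
    n_blocks = as.integer(n_blocks),
    n_discarded = n - L * n_blocks
  )
}

#' Scan block counts for a plateau in the block-mean SD
#'
#' @param x Numeric series.
#' @param block_counts Block counts to evaluate.
#' @return Tibble with `n_blocks`, `block_length`, `block_sd`.
#' @export
block_average_scan <- function(x, block_counts = c(2, 4, 5, 8, 10, 20)) {
  block_counts <- block_counts[block_counts <= length(x)]
  purrr::map_dfr(block_counts, function(nb) {
    ba <- block_average(x, nb)
    tibble::tibble(
      n_blocks = ba$n_blocks,
      block_length = ba$block_length,
      block_sd = ba$block_sd
    )
  })
}

#' Per-model descriptor series with block-averaged uncertainty
#'
#' @param name Descriptor name (e.g. "untwist").
#' @param values Per-model values.
#' @param units Unit string, default degrees.
#' @param n_blocks Blocks for the uncertainty estimate; skipped (NA) when
#'   the series is shorter than the block count.
#' @param reference Optional reference value (e.g. the initial twist).
#' @return A `descriptor_series` tibble (columns `model`, `value`) with
#'   `name`, `units`, `block` and `reference` attributes.
#' @export
descriptor_series <- function(name, values, units = "degrees",
                              n_blocks = 5, reference = NULL) {
  blk <- if (length(values) >= n_blocks && n_blocks >= 2) {
    block_average(values, n_blocks)
  } else {
    list(mean = mean(values), block_sd = NA_real_, n_blocks = NA_integer_)
  }
  structure(
    tibble::tibble(model = seq_along(values), value = as.numeric(values)),
    class = c("descriptor_series", class(tibble::tibble())),
    name = name, units = units, block = blk, reference = reference
  )
}

#' @export
print.descriptor_series <- function(x, ...) {
  blk <- attr(x, "block")
  cat(sprintf(
    "<descriptor_series> %s: %d model(s), mean %.3f %s (block SD %.3f)\n",
    attr(x, "name"), nrow(x), blk$mean, attr(x, "units"), blk$block_sd
  ))
  NextMethod()
}
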