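# Shared fixtures: the two reference component sets used throughout the
# suite (a heterogeneous three-state donor-acceptor sample and a
# mono-exponential donor-only sample), plus small acquisition settings for
# fast unit tests.

ccc_components <- function() {
  lifetime_components(c(0.40, 1.7, 5.2), c(0.39, 0.33, 0.28))
}

donor_components <- function(tau_D = 4.9) {
  lifetime_components(tau_D, 1)
}

small_acq <- function(seed = 1L, ...) {
  acquisition(window = 50, n_channels = 512, peak_counts = 5000, seed = seed, ...)
}

straight_duplex <- function(n = 24, twist = 36, sequence = NULL) {
  sequence <- sequence %||% strrep("GC", ceiling(n / 2))
  build_duplex(duplex_spec(substr(sequence, 1, n), twist = twist))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_rotation <- function(seed) {
  set.seed(seed)
  qr_res <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
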