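# Independent oracles used across the suite.

# Brute-force debiased WPLI: double loop over all ordered observation pairs
# j != k of the imaginary cross-spectral terms.
oracle_dwpli <- function(x, y) {
  I <- Im(x * Conj(y))
  n <- length(I)
  num <- 0; den <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) if (a != b) {
    num <- num + I[a] * I[b]
    den <- den + abs(I[a] * I[b])
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Union-find connected components over an edge list; returns the edge count
# of the largest component.
oracle_max_component_edges <- function(ei, ej, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
  for (e in seq_along(ei)) {
    a <- find(ei[e]); b <- find(ej[e])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(ei, find, 0L)
  if (length(roots) == 0) return(0L)
  max(table(roots))
}

# Single-pass analog Butterworth magnitude response.
butter_mag <- function(f, fc, order, type = c("low", "high")) {
  type <- match.arg(type)
  r <- if (type == "low") f / fc else fc / f
  1 / sqrt(1 + r^(2 * order))
}

# Two narrow-band analytic signals sharing an oscillation at a constant lag,
# with independent additive in-band noise setting the coupling strength.
coupled_pair <- function(n, fs = 100, f = 5, lag = pi / 2, noise = 0.2) {
  tt <- seq_len(n) / fs
  drift <- cumsum(rnorm(n, 0, 0.02))
  base <- 2 * pi * f * tt + drift
  x <- exp(1i * base) + noise * scale_complex(rnorm(n), rnorm(n))
  y <- exp(1i * (base - lag)) + noise * scale_complex(rnorm(n), rnorm(n))
  list(x = x, y = y)
}

scale_complex <- function(re, im) complex(real = re, imaginary = im) / sqrt(2)

# Gaussian edge-level tensors (edges x subjects x bands) for statistics-only
# tests that do not need signal generation.
gaussian_tensor <- function(n_edges, n_subjects, n_bands, shift_rows = NULL,
                            shift_bands = NULL, shift = 0) {
  a <- array(rnorm(n_edges * n_subjects * n_bands),
             c(n_edges, n_subjects, n_bands))
  if (!is.null(shift_rows))
    a[shift_rows, , shift_bands] <- a[shift_rows, , shift_bands] + shift
  a
}
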