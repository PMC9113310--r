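#' Analytic signal of narrow-band parcel signals
#'
#' FFT-based Hilbert transform of each row: the result's real part equals the
#' input, its modulus is the instantaneous amplitude and its argument the
#' instantaneous phase.
#'
#' @param x parcels x samples real matrix (or a vector for one parcel).
#' @return complex matrix of the same shape, with attribute `degenerate`: a
#'   logical vector flagging zero-variance rows (their phase is meaningless
#'   and downstream edges become undefined).
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  X <- t(stats::mvfft(t(x)))
  Z <- t(stats::mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / n
  degenerate <- apply(x, 1, function(r) stats::var(r) == 0)
  attr(Z, "degenerate") <- degenerate
  if (vec) Z <- drop(Z)
  Z
}

#' Debiased weighted phase-lag index of two analytic signals
#'
#' The per-sample observations are the cross-spectral terms
#' `X_t = x_t * Conj(y_t)` with imaginary parts `I_t`. The debiased
#' (squared) WPLI estimator is
#' \deqn{((\sum I_t)^2 - \sum I_t^2) / ((\sum |I_t|)^2 - \sum I_t^2),}
#' the ratio of sums over all ordered sample pairs j != k of
#' `I_j I_k` and `|I_j I_k|`. It lies in \[-1, 1\], is insensitive to
#' zero-lag (volume-conducted) coupling, and removes the positive
#' sample-size bias of the squared WPLI, so independent signals average to
#' zero. Strictly zero-lag pairs have all `I_t = 0`; the estimator is then
#' undefined and `NA` is returned (the edge is recorded as invalid, never
#' infinite).
#'
#' @param x,y equal-length complex vectors (analytic signals).
#' @return scalar in \[-1, 1\], or `NA` when the denominator is degenerate.
#' @export
dwpli <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  I <- Im(x * Conj(y))
  s <- sum(I); s2 <- sum(I^2); sa <- sum(abs(I))
  scale <- sum(Mod(x) * Mod(y))
  denom <- sa^2 - s2
  if (scale == 0 || denom <= 1e-12 * scale^2) return(NA_real_)
  (s^2 - s2) / denom
}

#' Per-subject dwPLI adjacency matrices over a filter bank
#'
#' For each band: narrow-band filter the parcel signals, take the analytic
#' signal, discard a guard interval at each epoch end (default 2 cycles of
#' the band center frequency, absorbing filter and Hilbert edge effects),
#' and compute the dwPLI between every parcel pair.
#'
#' @param epoch a [subject_epoch()] (or any list with elements `parcels`,
#'   `fs`, `subject_id`, `state`).
#' @param bank a [build_filter_bank()] table (any subset of rows).
#' @param trim_cycles guard interval at each end, in cycles of the band
#'   center frequency.
#' @param band_order narrow-band filter order per stage.
#' @return an `adjacency_stack`: list with `values` (parcels x parcels x
#'   bands array, `NA` on the diagonal and on undefined edges), `bank`,
#'   `subject_id`, `state`, `n_edges_total`.
#' @export
subject_adjacency <- function(epoch, bank, trim_cycles = 2, band_order = 6L) {
  x <- epoch$parcels
  stopifnot(is.matrix(x), nrow(x) >= 2)
  P <- nrow(x)
  vals <- array(NA_real_, dim = c(P, P, nrow(bank)))
  for (b in seq_len(nrow(bank))) {
    band <- bank[b, ]
    y <- apply_band(x, band, fs = epoch$fs, order = band_order)
    Z <- analytic_signal(y)
    trim <- ceiling(trim_cycles * epoch$fs / band$fc)
    keep <- seq.int(trim + 1L, ncol(Z) - trim)
    if (length(keep) < 2)
      stop("epoch too short after edge trimming at band ", band$index)
    A <- dwpli_all_pairs(Z[, keep, drop = FALSE])
    A[attr(Z, "degenerate"), ] <- NA_real_
    A[, attr(Z, "degenerate")] <- NA_real_
    vals[, , b] <- A
  }
  structure(list(values = vals, bank = bank,
                 subject_id = epoch$subject_id, state = epoch$state,
                 n_edges_total = P * (P - 1) / 2),
            class = "adjacency_stack")
}

#' Binary fidelity mask over parcel pairs
#'
#' Marks which parcel pairs can be estimated reliably given the electrode
#' layout; unreliable edges are excluded from every downstream edge count.
#'
#' @param mask symmetric binary matrix with zero diagonal.
#' @return a `fidelity_mask` object with element `n_valid_edges` (count of
#'   upper-triangle ones).
#' @export
fidelity_mask <- function(mask) {
  stopifnot(is.matrix(mask), nrow(mask) == ncol(mask))
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (!isTRUE(all.equal(mask, t(mask)))) stop("mask must be symmetric")
  diag(mask) <- 0
  structure(list(mask = mask,
                 n_valid_edges = sum(mask[upper.tri(mask)])),
            class = "fidelity_mask")
}

#' Random fidelity mask with guaranteed edges
#'
#' Draws a binary mask by uniform sampling of `n_valid` upper-triangle edges
#' (default: the 1128/1653 density of the 58-parcel layout), always
#' including the edges in `include` — used by the synthetic cohort generator
#' so planted effects are never masked out.
#'
#' @param n_parcels number of parcels.
#' @param n_valid number of reliable edges.
#' @param include optional 2-column matrix of (i, j) edges forced into the
#'   mask.
#' @return a [fidelity_mask()].
#' @export
random_fidelity_mask <- function(n_parcels,
                                 n_valid = round(n_parcels * (n_parcels - 1) /
                                                   2 * 1128 / 1653),
                                 include = NULL) {
  ed <- edge_table(n_parcels)
  m <- nrow(ed)
  stopifnot(n_valid <= m)
  forced <- integer(0)
  if (!is.null(include)) {
    include <- cbind(pmin(include[, 1], include[, 2]),
                     pmax(include[, 1], include[, 2]))
    forced <- match(paste(include[, 1], include[, 2]),
                    paste(ed$i, ed$j))
    if (anyNA(forced)) stop("include contains invalid parcel pairs")
    if (length(forced) > n_valid)
      stop("more forced edges than n_valid")
  }
  free <- setdiff(seq_len(m), forced)
  pick <- c(forced, sample(free, n_valid - length(forced)))
  mk <- matrix(0, n_parcels, n_parcels)
  for (e in pick) mk[ed$i[e], ed$j[e]] <- mk[ed$j[e], ed$i[e]] <- 1
  fidelity_mask(mk)
}

#' Apply a fidelity mask to an adjacency stack
#'
#' Edges with mask zero are set to `NA` (invalid) in every band.
#'
#' @param adj an `adjacency_stack` from [subject_adjacency()].
#' @param mask a [fidelity_mask()].
#' @return the masked `adjacency_stack`.
#' @export
apply_fidelity_mask <- function(adj, mask) {
  stopifnot(inherits(adj, "adjacency_stack"), inherits(mask, "fidelity_mask"))
  P <- dim(adj$values)[1]
  if (nrow(mask$mask) != P) stop("mask and adjacency shapes disagree")
  drop_idx <- mask$mask == 0
  for (b in seq_len(dim(adj$values)[3])) {
    A <- adj$values[, , b]
    A[drop_idx] <- NA_real_
    adj$values[, , b] <- A
  }
  adj$mask <- mask
  adj
}

#' Upper-triangle edge table
#'
#' Canonical edge ordering used throughout the package: column-major over the
#' upper triangle (all pairs i < j ordered by j, then i).
#'
#' @param n_parcels number of parcels.
#' @return data frame with columns `i`, `j`.
#' @export
edge_table <- function(n_parcels) {
  ut <- upper.tri(matrix(0, n_parcels, n_parcels))
  idx <- which(ut, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2])
}

# Extract the upper-triangle edge vector of one band of an adjacency stack,
# restricted to mask-valid edges (others NA).
edge_vector <- function(A) {
  P <- nrow(A)
  ed <- edge_table(P)
  A[cbind(ed$i, ed$j)]
}
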