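#' One-tailed Wilcoxon rank-sum p-value
#'
#' Thin wrapper around [stats::wilcox.test()]: exact-distribution p-values
#' when both samples are small (min n at or below `exact_max_n`) and tie-free,
#' the normal approximation with mid-rank tie correction otherwise.
#' Completely degenerate input (every value identical across both samples)
#' carries no evidence for a shift and returns p = 1.
#'
#' @param a,b numeric samples.
#' @param direction `"greater"` tests a shifted above b, `"less"` the
#'   reverse.
#' @param exact_max_n largest min(n) for which the exact distribution is
#'   used.
#' @return p-value in (0, 1\].
#' @export
wilcoxon_one_tailed <- function(a, b, direction = c("greater", "less"),
                                exact_max_n = 25L) {
  direction <- match.arg(direction)
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1L) return(1)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && min(length(a), length(b)) <= exact_max_n
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = direction, exact = use_exact,
                       correct = TRUE)$p.value
  )
}

#' Rank-biserial correlation effect size
#'
#' `r = 2U/(n_a n_b) - 1`, where U counts pairs with the a-value above the
#' b-value (ties count one half). Positive values mean a tends to exceed b;
#' swapping the samples flips the sign.
#'
#' @param a,b numeric samples.
#' @return effect size in \[-1, 1\].
#' @export
rank_biserial <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1, nb >= 1)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  2 * U / (na * nb) - 1
}

#' Storey-Tibshirani adaptive FDR
#'
#' Estimates the proportion of true nulls pi0 with the smoother method
#' (lambda grid 0.05-0.95 in steps of 0.05, natural cubic smoothing spline
#' of pi0(lambda) with 3 df, evaluated at the largest lambda, clamped to
#' (0, 1\]) and converts p-values to monotone q-values. With fewer than 20
#' p-values the smoother is unsupported and the estimate conservatively
#' falls back to pi0 = 1.
#'
#' @param p p-values in \[0, 1\].
#' @param q FDR level for the significance mask.
#' @param lambda grid for the pi0 smoother.
#' @return list with `pi0`, `qvalues`, `significant` (logical,
#'   qvalue <= q), and `n_expected_false = floor(q * length(p))`.
#' @export
storey_fdr <- function(p, q = 0.05, lambda = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ok <- !is.na(p)
  m <- sum(ok)
  if (m == 0)
    return(list(pi0 = NA_real_, qvalues = p, significant = rep(FALSE, length(p)),
                n_expected_false = NA_integer_))
  pv <- p[ok]
  if (m < 20) {
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), 0)
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  o <- order(pv, decreasing = TRUE)
  qv <- numeric(m)
  qv[o] <- cummin(pi0 * m * pv[o] / rank(pv, ties.method = "max")[o])
  qv <- pmin(qv, 1)
  out_q <- rep(NA_real_, length(p))
  out_q[ok] <- qv
  list(pi0 = pi0, qvalues = out_q,
       significant = !is.na(out_q) & out_q <= q,
       n_expected_false = as.integer(floor(q * m)))
}

#' Edgewise two-group contrast with network-density summaries
#'
#' Runs the one-tailed Wilcoxon rank-sum test edge by edge, in both
#' directions, for every band of two connectivity tensors (valid edges x
#' subjects x bands, as built by [connect_cohort()]). Within each edge,
#' subjects with an undefined value are dropped; an edge tested with fewer
#' than 2 subjects per group is invalid. The density K is the fraction of
#' valid edges with p below `alpha` (raw thresholding); the
#' Storey-Tibshirani expected-false-discovery bound at level `q` and the
#' effect size (modulus of the mean rank-biserial correlation over
#' significant edges) are reported alongside.
#'
#' @param a,b edge x subject x band arrays for the two groups (group a is
#'   the first-named group of each direction, e.g. EP in "EP > HC").
#' @param alpha edgewise significance level.
#' @param q adaptive-FDR level for the expected-false bound.
#' @param exact_max_n passed to [wilcoxon_one_tailed()].
#' @return a `ppc_contrast` object: `summary` data frame (band, direction,
#'   n_valid, n_sig, K, n_expected_false, pi0, effect_size) plus matrices
#'   `p` and `sig` (edges x bands per direction) and `effect` (rank-biserial
#'   per edge x band).
#' @export
edgewise_contrast <- function(a, b, alpha = 0.01, q = 0.01,
                              exact_max_n = 25L) {
  stopifnot(length(dim(a)) == 3, length(dim(b)) == 3,
            dim(a)[1] == dim(b)[1], dim(a)[3] == dim(b)[3],
            alpha > 0, alpha < 1, q > 0, q < 1)
  nE <- dim(a)[1]; nB <- dim(a)[3]
  dirs <- c("greater", "less")
  p_arr <- array(NA_real_, c(nE, nB, 2), dimnames = list(NULL, NULL, dirs))
  eff <- matrix(NA_real_, nE, nB)
  for (bnd in seq_len(nB)) {
    for (e in seq_len(nE)) {
      xa <- a[e, , bnd]; xb <- b[e, , bnd]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (length(xa) < 2 || length(xb) < 2) next
      p_arr[e, bnd, 1] <- wilcoxon_one_tailed(xa, xb, "greater", exact_max_n)
      p_arr[e, bnd, 2] <- wilcoxon_one_tailed(xa, xb, "less", exact_max_n)
      eff[e, bnd] <- rank_biserial(xa, xb)
    }
  }
  rows <- list()
  sig <- array(FALSE, c(nE, nB, 2), dimnames = list(NULL, NULL, dirs))
  for (bnd in seq_len(nB)) for (d in 1:2) {
    pv <- p_arr[, bnd, d]
    n_valid <- sum(!is.na(pv))
    s <- !is.na(pv) & pv < alpha
    sig[, bnd, d] <- s
    fdr <- storey_fdr(pv, q = q)
    es <- if (any(s)) abs(mean(eff[s, bnd])) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      band = bnd, direction = dirs[d], n_valid = n_valid, n_sig = sum(s),
      K = if (n_valid > 0) sum(s) / n_valid else NA_real_,
      n_expected_false = fdr$n_expected_false, pi0 = fdr$pi0,
      effect_size = es)
  }
  structure(list(summary = do.call(rbind, rows), p = p_arr, sig = sig,
                 effect = eff, alpha = alpha, q = q),
            class = "ppc_contrast")
}

#' @export
print.ppc_contrast <- function(x, ...) {
  cat("Edgewise group contrast (one-tailed Wilcoxon, alpha =", x$alpha,
      ", Storey q =", x$q, ")\n")
  s <- x$summary
  top <- s[order(-s$K), ][seq_len(min(6, nrow(s))), ]
  cat("Top densities:\n")
  print(data.frame(band = top$band, direction = top$direction,
                   K = round(top$K, 4), n_sig = top$n_sig,
                   n_valid = top$n_valid,
                   effect = round(top$effect_size, 3)), row.names = FALSE)
  invisible(x)
}

#' Plot network density against frequency band
#'
#' Mirrors the frequency-wise K curves of the analysis: one line per
#' direction, with the adaptive-FDR expected-false bound as a shaded band.
#'
#' @param x a `ppc_contrast` object.
#' @param fc optional band center frequencies for the x axis.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ppc_contrast <- function(x, fc = NULL, ...) {
  s <- x$summary
  bands <- sort(unique(s$band))
  xs <- if (is.null(fc)) bands else fc
  kg <- s$K[s$direction == "greater"]
  kl <- s$K[s$direction == "less"]
  qb <- x$q
  plot(xs, kg, type = "n", ylim = c(0, max(kg, kl, qb, na.rm = TRUE) * 1.1),
       xlab = if (is.null(fc)) "band" else "Fc (Hz)", ylab = "K", log =
         if (is.null(fc)) "" else "x", ...)
  polygon(c(xs, rev(xs)), c(rep(0, length(xs)), rep(qb, length(xs))),
          col = "grey90", border = NA)
  lines(xs, kg, col = "red3", lwd = 2)
  lines(xs, kl, col = "blue3", lwd = 2)
  legend("topright", c("a > b", "a < b"), col = c("red3", "blue3"), lwd = 2,
         bty = "n")
  invisible(x)
}

#' Age-confound check on global mean connectivity strength
#'
#' Correlates each subject's global mean edge strength with conceptional age
#' (two-tailed Spearman) per group, sleep state and band, then pools the
#' p-values of both sleep states within each group and applies
#' Benjamini-Hochberg correction.
#'
#' @param strengths named list (by group) of named lists (by state) of
#'   subjects x bands matrices of global mean strength, e.g. from
#'   [global_mean_strength()].
#' @param ages list with the same group/state structure giving each
#'   subject's conceptional age in weeks.
#' @param alpha significance level applied to the adjusted p-values.
#' @return data frame (group, state, band, rho, p, p_adj, flagged).
#' @export
age_confound_check <- function(strengths, ages, alpha = 0.05) {
  rows <- list()
  for (g in names(strengths)) {
    for (st in names(strengths[[g]])) {
      M <- strengths[[g]][[st]]
      age <- ages[[g]][[st]]
      stopifnot(nrow(M) == length(age))
      for (bnd in seq_len(ncol(M))) {
        v <- M[, bnd]
        ok <- !is.na(v)
        if (sd(v[ok]) == 0 || length(unique(age[ok])) < 2) {
          rho <- NA_real_; pv <- NA_real_
        } else {
          ct <- suppressWarnings(
            stats::cor.test(v[ok], age[ok], method = "spearman"))
          rho <- unname(ct$estimate); pv <- ct$p.value
        }
        rows[[length(rows) + 1]] <- data.frame(group = g, state = st,
                                               band = bnd, rho = rho, p = pv)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (g in unique(out$group)) {          # pool states within group, then BH
    sel <- out$group == g
    out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$flagged <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}

#' Global mean connectivity strength per subject and band
#'
#' @param tensor valid-edge x subject x band array.
#' @return subjects x bands matrix of means over defined edges.
#' @export
global_mean_strength <- function(tensor) {
  apply(tensor, c(2, 3), mean, na.rm = TRUE)
}
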