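#' Partial Spearman correlation with one covariate
#'
#' Rank-transforms `x`, `y` and `z` and computes the correlation of `x` and
#' `y` with the linear effect of `z` removed on the ranks (equivalently the
#' first-order partial correlation of the rank variables). The two-tailed
#' p-value uses the t-approximation with n - 3 degrees of freedom (one
#' covariate). Incomplete triples are dropped listwise.
#'
#' @param x,y,z numeric vectors of equal length.
#' @param min_n minimum number of complete triples.
#' @return list with `rho`, `p`, `n` (`NA` values if undefined, e.g. a
#'   constant input after ranking).
#' @export
partial_spearman <- function(x, y, z, min_n = 5L) {
  ok <- stats::complete.cases(x, y, z)
  n <- sum(ok)
  if (n < min_n) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x[ok]); ry <- rank(y[ok]); rz <- rank(z[ok])
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  if (sd(rz) == 0) {                    # constant covariate: plain Spearman
    r <- cor(rx, ry)
  } else {
    rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
    den <- sqrt((1 - rxz^2) * (1 - ryz^2))
    if (den == 0) return(list(rho = NA_real_, p = NA_real_, n = n))
    r <- (rxy - rxz * ryz) / den
  }
  r <- max(-1, min(1, r))
  df <- n - 3
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  list(rho = r, p = p, n = n)
}

#' HNNE composite scores by principal component analysis
#'
#' First two principal-component scores of the standardized item matrix
#' (three neurological items in the reference analysis). Components are
#' sign-aligned so the loading on the first item is nonnegative. By the
#' post hoc assignment of the reference analysis, C1 tracks later motor and
#' C2 later cognitive performance; higher scores mean better performance.
#'
#' @param item_scores subjects x items numeric matrix (at least 3 subjects).
#' @return subjects x 2 matrix with columns `C1`, `C2` and attribute
#'   `var_explained` (proportion per component).
#' @export
composite_scores <- function(item_scores) {
  stopifnot(is.matrix(item_scores), nrow(item_scores) >= 3,
            ncol(item_scores) >= 2)
  if (any(apply(item_scores, 2, stats::sd) == 0))
    stop("constant item column: cannot standardize")
  pc <- stats::prcomp(item_scores, center = TRUE, scale. = TRUE)
  if (length(pc$sdev) < 2)
    stop("fewer than 2 principal components available")
  flip <- ifelse(pc$rotation[1, 1:2] < 0, -1, 1)
  scores <- sweep(pc$x[, 1:2, drop = FALSE], 2, flip, `*`)
  colnames(scores) <- c("C1", "C2")
  attr(scores, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  scores
}

#' Edgewise clinical correlation scan
#'
#' Correlates each valid edge's connectivity strength across subjects with a
#' clinical score, partialling out conceptional age (two-tailed partial
#' Spearman). Subjects with a missing score are dropped listwise. Edges
#' significant at `alpha` are split by correlation sign; the
#' Storey-Tibshirani adaptive FDR at level `q` is run separately within the
#' positive-rho and negative-rho test sets (each about half the network, so
#' each bounds about q/2 of the full network's edges as potential false
#' discoveries). K is the fraction of valid edges significant in either
#' direction; effect sizes are the mean rho over each signed significant
#' set.
#'
#' @param tensor valid-edge x subject x band array (one state).
#' @param scores per-subject clinical score (higher = better performance);
#'   `NA` allowed.
#' @param ca per-subject conceptional age in weeks (the covariate).
#' @param alpha two-tailed significance level.
#' @param q adaptive-FDR level per sign set.
#' @return a `ppc_corr` object: `summary` data frame (band, n_valid, n_pos,
#'   n_neg, K, effect_pos, effect_neg, n_expected_false_pos/neg), matrices
#'   `rho` and `p` (edges x bands), logical `sig_pos`/`sig_neg`.
#' @export
clinical_scan <- function(tensor, scores, ca, alpha = 0.05, q = 0.05) {
  stopifnot(length(dim(tensor)) == 3, dim(tensor)[2] == length(scores),
            length(scores) == length(ca))
  keep <- !is.na(scores)
  if (!any(keep)) stop("score missing for all subjects")
  tensor <- tensor[, keep, , drop = FALSE]
  scores <- scores[keep]; ca <- ca[keep]
  nE <- dim(tensor)[1]; nB <- dim(tensor)[3]
  rho <- p <- matrix(NA_real_, nE, nB)
  for (bnd in seq_len(nB)) {
    for (e in seq_len(nE)) {
      v <- tensor[e, , bnd]
      if (all(is.na(v))) next
      ps <- partial_spearman(v, scores, ca)
      rho[e, bnd] <- ps$rho; p[e, bnd] <- ps$p
    }
  }
  sig_pos <- !is.na(p) & p < alpha & rho > 0
  sig_neg <- !is.na(p) & p < alpha & rho < 0
  rows <- list()
  for (bnd in seq_len(nB)) {
    pos_set <- !is.na(rho[, bnd]) & rho[, bnd] > 0
    neg_set <- !is.na(rho[, bnd]) & rho[, bnd] < 0
    fdr_pos <- storey_fdr(p[pos_set, bnd], q = q)
    fdr_neg <- storey_fdr(p[neg_set, bnd], q = q)
    n_valid <- sum(!is.na(p[, bnd]))
    np <- sum(sig_pos[, bnd]); nn <- sum(sig_neg[, bnd])
    rows[[length(rows) + 1]] <- data.frame(
      band = bnd, n_valid = n_valid, n_pos = np, n_neg = nn,
      K = if (n_valid > 0) (np + nn) / n_valid else NA_real_,
      effect_pos = if (np > 0) mean(rho[sig_pos[, bnd], bnd]) else NA_real_,
      effect_neg = if (nn > 0) mean(rho[sig_neg[, bnd], bnd]) else NA_real_,
      n_expected_false_pos = fdr_pos$n_expected_false,
      n_expected_false_neg = fdr_neg$n_expected_false)
  }
  structure(list(summary = do.call(rbind, rows), rho = rho, p = p,
                 sig_pos = sig_pos, sig_neg = sig_neg,
                 alpha = alpha, q = q, n_subjects = length(scores)),
            class = "ppc_corr")
}

#' @export
print.ppc_corr <- function(x, ...) {
  cat("Edgewise clinical correlation (partial Spearman, alpha =", x$alpha,
      ", Storey q =", x$q, ",", x$n_subjects, "subjects)\n")
  s <- x$summary
  top <- s[order(-s$K), ][seq_len(min(6, nrow(s))), ]
  print(data.frame(band = top$band, K = round(top$K, 4), pos = top$n_pos,
                   neg = top$n_neg,
                   effect_pos = round(top$effect_pos, 3),
                   effect_neg = round(top$effect_neg, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.ppc_corr <- function(x, fc = NULL, ...) {
  s <- x$summary
  xs <- if (is.null(fc)) s$band else fc
  kp <- s$n_pos / s$n_valid; kn <- s$n_neg / s$n_valid
  plot(xs, kp, type = "n",
       ylim = c(0, max(kp, kn, x$q, na.rm = TRUE) * 1.1),
       xlab = if (is.null(fc)) "band" else "Fc (Hz)", ylab = "K",
       log = if (is.null(fc)) "" else "x", ...)
  polygon(c(xs, rev(xs)), c(rep(0, length(xs)), rep(x$q, length(xs))),
          col = "grey90", border = NA)
  lines(xs, kp, col = "red3", lwd = 2)
  lines(xs, kn, col = "blue3", lwd = 2)
  legend("topright", c("rho > 0", "rho < 0"), col = c("red3", "blue3"),
         lwd = 2, bty = "n")
  invisible(x)
}
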