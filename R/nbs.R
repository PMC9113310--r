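#' Network-based statistic permutation test
#'
#' Cross-check for the edgewise contrast: computes a pooled-variance
#' two-sample t-statistic per edge in the requested direction, keeps edges
#' with t above `t_threshold`, finds connected components of the resulting
#' graph in topological space, and compares each observed component's extent
#' (edge count) against the permutation distribution of the maximal
#' suprathreshold component under group-label shuffling. Family-wise error
#' corrected p-values use the +1 correction,
#' `p = (1 + #\{null max >= observed\}) / (1 + n_perm)`.
#'
#' When fewer distinct label assignments exist than requested permutations,
#' all assignments are enumerated instead (with a warning).
#'
#' @param a,b edge x subject matrices for the two groups (one band, one
#'   state); rows follow the [edge_table()] ordering described by `edges`.
#' @param edges data frame with parcel indices `i`, `j` for each row of
#'   `a`/`b`.
#' @param n_parcels number of parcels (graph nodes).
#' @param t_threshold initial t-statistic threshold.
#' @param n_perm number of label permutations.
#' @param alpha FWER level used for the `significant` flags.
#' @param direction `"greater"` tests a above b, `"less"` the reverse.
#' @param seed optional integer seed for the permutation stream.
#' @return an `nbs_result`: list of `components` (edge-index sets),
#'   `component_sizes` (edge counts), `fwer_p`, `significant`,
#'   `null_max_sizes`, `t` (per-edge statistics), `threshold`.
#' @export
nbs_test <- function(a, b, edges, n_parcels, t_threshold = 2.5,
                     n_perm = 5000L, alpha = 0.05,
                     direction = c("greater", "less"), seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(a), is.matrix(b), nrow(a) == nrow(b),
            nrow(a) == nrow(edges), t_threshold > 0, n_perm >= 1)
  if (ncol(a) < 2 || ncol(b) < 2) stop("need at least 2 subjects per group")
  if (!is.null(seed)) set.seed(seed)
  na <- ncol(a); nb <- ncol(b); n <- na + nb
  X <- cbind(a, b)
  sign_flip <- if (direction == "less") -1 else 1

  pooled_t <- function(G) {            # G: n x k indicator of group-a labels
    S1 <- X %*% G; Q1 <- X^2 %*% G
    Stot <- rowSums(X); Qtot <- rowSums(X^2)
    m1 <- S1 / na; m2 <- (Stot - S1) / nb
    ss1 <- Q1 - S1^2 / na
    ss2 <- (Qtot - Q1) - (Stot - S1)^2 / nb
    sp2 <- (ss1 + ss2) / (n - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / na + 1 / nb))
    tt[sp2 <= 0] <- NA_real_           # zero-variance edge: undefined
    sign_flip * tt
  }

  valid <- apply(X, 1, function(r) !anyNA(r))
  t_obs <- rep(NA_real_, nrow(X))
  Xfull <- X
  X <- X[valid, , drop = FALSE]
  G_obs <- matrix(0, n, 1); G_obs[seq_len(na), 1] <- 1
  t_obs[valid] <- pooled_t(G_obs)[, 1]

  supra <- which(!is.na(t_obs) & t_obs > t_threshold)
  g <- igraph::graph_from_edgelist(
    as.matrix(edges[supra, c("i", "j")]), directed = FALSE)
  if (length(supra) > 0 && igraph::vcount(g) < n_parcels)
    g <- igraph::add_vertices(g, n_parcels - igraph::vcount(g))
  comps <- if (length(supra) > 0) igraph::components(g) else NULL
  components <- list(); sizes <- integer(0)
  if (!is.null(comps)) {
    memb <- comps$membership
    comp_of_edge <- memb[edges$i[supra]]
    for (cid in unique(comp_of_edge)) {
      es <- supra[comp_of_edge == cid]
      if (length(es) >= 1) {
        components[[length(components) + 1]] <- es
        sizes <- c(sizes, length(es))
      }
    }
    o <- order(-sizes)
    components <- components[o]; sizes <- sizes[o]
  }

  n_distinct <- choose(n, na)
  enumerated <- FALSE
  if (n_distinct <= n_perm) {
    warning("fewer distinct permutations (", n_distinct,
            ") than requested; enumerating all")
    sel <- utils::combn(n, na)
    G <- matrix(0, n, ncol(sel))
    for (k in seq_len(ncol(sel))) G[sel[, k], k] <- 1
    enumerated <- TRUE
  } else {
    G <- matrix(0, n, n_perm)
    for (k in seq_len(n_perm)) G[sample.int(n, na), k] <- 1
  }
  Tp <- pooled_t(G)
  ei <- edges$i[valid]; ej <- edges$j[valid]
  null_max <- vapply(seq_len(ncol(G)), function(k) {
    sel <- which(!is.na(Tp[, k]) & Tp[, k] > t_threshold)
    if (length(sel) == 0) return(0L)
    max_component_edges(ei[sel], ej[sel], n_parcels)
  }, 0L)

  np <- length(null_max)
  fwer_p <- vapply(sizes, function(sz) (1 + sum(null_max >= sz)) / (1 + np), 0)
  structure(list(components = components, component_sizes = sizes,
                 fwer_p = fwer_p, significant = fwer_p <= alpha,
                 null_max_sizes = null_max, t = t_obs,
                 threshold = t_threshold, direction = direction,
                 n_perm = np, enumerated = enumerated),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("NBS (t >", x$threshold, ",", x$n_perm, "permutations, direction",
      x$direction, ")\n")
  if (length(x$component_sizes) == 0) {
    cat("no suprathreshold components\n")
  } else {
    print(data.frame(component = seq_along(x$component_sizes),
                     edges = x$component_sizes,
                     fwer_p = signif(x$fwer_p, 3),
                     significant = x$significant), row.names = FALSE)
  }
  invisible(x)
}
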