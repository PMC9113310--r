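#' Compute masked connectivity tensors for a cohort
#'
#' Runs [subject_adjacency()] for every subject and state, applies the
#' cohort's fidelity mask, and stacks the valid-edge vectors into one tensor
#' per state (valid edges x subjects x bands).
#'
#' @param cohort a `ppc_cohort` from [generate_cohort()], or any list with
#'   `epochs`, `subjects`, `mask` and a `spec` carrying `bank`.
#' @param bank filter bank; defaults to the cohort spec's bank.
#' @param trim_cycles,band_order passed to [subject_adjacency()].
#' @param verbose print per-subject progress.
#' @return a `ppc_connectivity`: list with `states` (named list of
#'   tensors), `meta` (subject table), `edges` (valid-edge parcel pairs),
#'   `mask`, `bank`, `n_parcels`.
#' @export
connect_cohort <- function(cohort, bank = cohort$spec$bank, trim_cycles = 2,
                           band_order = 6L, verbose = FALSE) {
  mask <- cohort$mask
  P <- nrow(mask$mask)
  ed <- edge_table(P)
  valid <- mask$mask[cbind(ed$i, ed$j)] == 1
  tensors <- list()
  for (st in names(cohort$epochs)) {
    eps <- cohort$epochs[[st]]
    tens <- array(NA_real_, c(sum(valid), length(eps), nrow(bank)))
    for (s in seq_along(eps)) {
      if (verbose) message("  connectivity: ", st, " subject ", s)
      adj <- subject_adjacency(eps[[s]], bank, trim_cycles = trim_cycles,
                               band_order = band_order)
      for (b in seq_len(nrow(bank)))
        tens[, s, b] <- edge_vector(adj$values[, , b])[valid]
    }
    tensors[[st]] <- tens
  }
  structure(list(states = tensors, meta = cohort$subjects,
                 edges = ed[valid, ], mask = mask, bank = bank,
                 n_parcels = P),
            class = "ppc_connectivity")
}

#' Edgewise group contrast for every sleep state
#'
#' @param conn a [connect_cohort()] result.
#' @param alpha,q,exact_max_n passed to [edgewise_contrast()].
#' @return named list of `ppc_contrast` objects, one per state, with an
#'   attached `K_table` attribute combining all states.
#' @export
contrast_scan <- function(conn, alpha = 0.01, q = 0.01, exact_max_n = 25L) {
  out <- list()
  for (st in names(conn$states)) {
    tens <- conn$states[[st]]
    a <- tens[, conn$meta$group == "EP", , drop = FALSE]
    b <- tens[, conn$meta$group == "HC", , drop = FALSE]
    out[[st]] <- edgewise_contrast(a, b, alpha = alpha, q = q,
                                   exact_max_n = exact_max_n)
  }
  kt <- do.call(rbind, lapply(names(out), function(st)
    cbind(state = st, out[[st]]$summary)))
  attr(out, "K_table") <- kt
  out
}

#' Run the full analysis pipeline on a synthetic specification
#'
#' Executes the stages in dependency order — simulate, connect, contrast,
#' optionally NBS, clinical correlation — and returns a manifest with the
#' per-band network-density tables (the machine-readable analog of the
#' frequency-wise K curves), all stage results, and the accounting a
#' reviewer needs (edge and subject counts, seeds). Deterministic: the same
#' spec yields identical results.
#'
#' @param spec a [cohort_spec()] (or an already generated `ppc_cohort`).
#' @param alpha,q edgewise significance and FDR levels for the group
#'   contrast.
#' @param clinical_alpha,clinical_q levels for the clinical scan.
#' @param run_nbs run the NBS cross-check (can dominate runtime).
#' @param nbs_t,nbs_perm NBS threshold and permutation count.
#' @param trim_cycles,band_order connectivity settings.
#' @param verbose print stage progress.
#' @return a `ppc_pipeline` manifest.
#' @export
run_pipeline <- function(spec, alpha = 0.01, q = 0.01,
                         clinical_alpha = 0.05, clinical_q = 0.05,
                         run_nbs = FALSE, nbs_t = 2.5, nbs_perm = 5000L,
                         trim_cycles = 2, band_order = 6L,
                         verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  cohort <- if (inherits(spec, "ppc_cohort")) spec else generate_cohort(spec)
  spec <- cohort$spec
  if (verbose) message("stage: connectivity")
  conn <- connect_cohort(cohort, trim_cycles = trim_cycles,
                         band_order = band_order, verbose = verbose)
  if (verbose) message("stage: group contrast")
  contrasts <- contrast_scan(conn, alpha = alpha, q = q)
  nbs <- NULL
  if (run_nbs) {
    if (verbose) message("stage: NBS")
    nbs <- list()
    for (st in names(conn$states)) {
      tens <- conn$states[[st]]
      a <- tens[, conn$meta$group == "EP", , drop = FALSE]
      b <- tens[, conn$meta$group == "HC", , drop = FALSE]
      for (bnd in seq_len(dim(tens)[3])) for (dr in c("greater", "less")) {
        key <- sprintf("%s_band%02d_%s", st, bnd, dr)
        nbs[[key]] <- nbs_test(a[, , bnd], b[, , bnd], conn$edges,
                               conn$n_parcels, t_threshold = nbs_t,
                               n_perm = nbs_perm, direction = dr,
                               seed = spec$seed + bnd)
      }
    }
  }
  if (verbose) message("stage: clinical correlation")
  clinical <- list()
  for (sm in spec$score_models) {
    sc <- cohort$clinical[cohort$clinical$score_name == sm$score, ]
    sc <- sc[match(cohort$subjects$subject_id, sc$subject_id), ]
    for (st in names(conn$states)) {
      key <- paste(sm$score, st, sep = "_")
      clinical[[key]] <- clinical_scan(conn$states[[st]], sc$score_value,
                                       cohort$subjects$ca_weeks,
                                       alpha = clinical_alpha,
                                       q = clinical_q)
    }
  }
  k_clinical <- if (length(clinical) > 0)
    do.call(rbind, lapply(names(clinical), function(k)
      cbind(scan = k, clinical[[k]]$summary))) else NULL
  structure(list(
    cohort = cohort, connectivity = conn, contrasts = contrasts,
    nbs = nbs, clinical = clinical,
    k_group = attr(contrasts, "K_table"), k_clinical = k_clinical,
    counts = list(n_ep = spec$n_ep, n_hc = spec$n_hc,
                  n_parcels = spec$n_parcels,
                  n_valid_edges = cohort$mask$n_valid_edges,
                  n_bands = nrow(spec$bank)),
    seed = spec$seed,
    elapsed_s = proc.time()[["elapsed"]] - t0),
    class = "ppc_pipeline")
}

#' @export
print.ppc_pipeline <- function(x, ...) {
  cat("PPC network pipeline:", x$counts$n_ep, "EP +", x$counts$n_hc, "HC,",
      x$counts$n_valid_edges, "valid edges,", x$counts$n_bands, "bands",
      sprintf("(%.1f s)\n", x$elapsed_s))
  kt <- x$k_group
  top <- kt[order(-kt$K), ][seq_len(min(4, nrow(kt))), ]
  cat("Largest group-contrast densities:\n")
  print(data.frame(state = top$state, band = top$band,
                   direction = top$direction, K = round(top$K, 4),
                   n_sig = top$n_sig), row.names = FALSE)
  if (!is.null(x$k_clinical)) {
    kc <- x$k_clinical
    topc <- kc[order(-kc$K), ][seq_len(min(4, nrow(kc))), ]
    cat("Largest clinical-correlation densities:\n")
    print(data.frame(scan = topc$scan, band = topc$band,
                     K = round(topc$K, 4)), row.names = FALSE)
  }
  invisible(x)
}

#' Write pipeline results as CSV files
#'
#' Emits the per-band density summaries and long-format edge-level tables
#' (band, state, direction, parcel pair, p, effect) with documented headers.
#'
#' @param x a `ppc_pipeline`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "ppc_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  pth <- file.path(dir, "k_group.csv")
  write.csv(x$k_group, pth, row.names = FALSE); paths <- c(paths, pth)
  if (!is.null(x$k_clinical)) {
    pth <- file.path(dir, "k_clinical.csv")
    write.csv(x$k_clinical, pth, row.names = FALSE); paths <- c(paths, pth)
  }
  ed <- x$connectivity$edges
  long <- list()
  for (st in names(x$contrasts)) {
    ct <- x$contrasts[[st]]
    for (bnd in seq_len(dim(ct$p)[2])) for (d in dimnames(ct$p)[[3]]) {
      long[[length(long) + 1]] <- data.frame(
        state = st, band = bnd, direction = d,
        edge_i = ed$i, edge_j = ed$j, p = ct$p[, bnd, d],
        effect = ct$effect[, bnd])
    }
  }
  pth <- file.path(dir, "contrast_edges.csv")
  write.csv(do.call(rbind, long), pth, row.names = FALSE)
  paths <- c(paths, pth)
  invisible(paths)
}
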