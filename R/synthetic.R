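# Synthetic cohorts: frequency-specific phase-coupled oscillator pairs
# planted in 1/f background noise, with known ground truth for every
# downstream stage (group contrasts, NBS, clinical correlation).

#' One subject-state epoch of parcel signals
#'
#' @param subject_id subject identifier.
#' @param group cohort label, `"EP"` (early preterm) or `"HC"` (healthy
#'   control).
#' @param state sleep state, `"AS"` (active) or `"QS"` (quiet).
#' @param ca_weeks conceptional age at recording in weeks.
#' @param fs sampling frequency in Hz.
#' @param parcels parcels x samples matrix.
#' @return a `subject_epoch` object.
#' @export
subject_epoch <- function(subject_id, group, state, ca_weeks, fs, parcels) {
  stopifnot(is.matrix(parcels), group %in% c("EP", "HC"),
            state %in% c("AS", "QS"))
  structure(list(subject_id = subject_id, group = group, state = state,
                 ca_weeks = ca_weeks, fs = fs, parcels = parcels),
            class = "subject_epoch")
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Gaussian 1/f noise
#'
#' White Gaussian noise spectrally shaped so power falls as `1/f^exponent`,
#' scaled to unit standard deviation.
#'
#' @param n number of samples.
#' @param exponent spectral slope of the power spectrum.
#' @return numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, exponent = 1) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))                  # avoid DC blow-up
  f <- pmin(f, n - f + 1)                    # two-sided frequency index
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# slowly varying phase jitter: white noise smoothed with a Gaussian kernel
# of standard deviation `w` samples (via FFT), rescaled to the target
# standard deviation. The Gaussian kernel's spectrum has Gaussian tails, so
# the jitter's phase-modulation sidebands stay spectrally confined and
# planted coupling does not bleed into distant filter-bank bands.
smooth_jitter <- function(n, w, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  f <- (seq_len(n) - 1) / n
  f <- pmin(f, 1 - f)                        # two-sided frequency, cycles/sample
  G <- exp(-2 * pi^2 * w^2 * f^2)
  m <- Re(stats::fft(stats::fft(stats::rnorm(n)) * G, inverse = TRUE)) / n
  s <- stats::sd(m)
  if (s == 0) return(numeric(n))
  m / s * sd_target
}

#' Sample edges for a planted effect
#'
#' Greedy random edge sampling with a parcel-degree cap, so that no parcel
#' hosts too many independent oscillators (which would dilute pairwise
#' coupling on every edge it participates in).
#'
#' @param n_parcels number of parcels.
#' @param n_edges number of edges to draw.
#' @param max_degree maximum edges per parcel (default scales with the
#'   average degree implied by `n_edges`).
#' @return 2-column matrix of parcel pairs (i < j).
#' @export
sample_planted_edges <- function(n_parcels, n_edges, max_degree = NULL) {
  ed <- edge_table(n_parcels)
  if (is.null(max_degree))
    max_degree <- max(2L, ceiling(2 * n_edges / n_parcels) + 1L)
  deg <- integer(n_parcels)
  pick <- integer(0)
  for (e in sample.int(nrow(ed))) {
    if (length(pick) >= n_edges) break
    i <- ed$i[e]; j <- ed$j[e]
    if (deg[i] < max_degree && deg[j] < max_degree) {
      pick <- c(pick, e)
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    }
  }
  if (length(pick) < n_edges)
    stop("cannot place ", n_edges, " edges under the degree cap")
  as.matrix(ed[sort(pick), ])
}

#' Planted group effect
#'
#' Describes one planted connectivity difference at `band` and `state`,
#' whose phase coupling is stronger by `coupling_delta` in the favored
#' group (`direction = "greater"` favors EP, `"less"` favors HC). Two
#' coupling mechanisms are available:
#'
#' * per-edge oscillators (`groups = NULL`): every row of `edges` gets its
#'   own shared band-limited oscillation between its two parcels. Suited to
#'   sparse edge sets; parcels participating in many edges mix several
#'   independent oscillators, which dilutes each pairwise coupling.
#' * a network oscillation (`groups` given): one oscillation is injected
#'   into all parcels of `groups$a` (at lag 0) and `groups$b` (at `lag`),
#'   each parcel with its own phase jitter. The planted edge set is every
#'   a-b pair; pairs within the same group are coupled at zero lag and are
#'   therefore invisible to dwPLI by construction. Each parcel hosts
#'   exactly one oscillator, so dense planted sets keep full coupling
#'   strength.
#'
#' @param band filter-bank band index.
#' @param state sleep state the effect applies to.
#' @param edges 2-column matrix of parcel pairs (per-edge mechanism).
#' @param coupling_delta additive increase of the coupling parameter in the
#'   favored group.
#' @param direction `"greater"` (EP > HC) or `"less"` (EP < HC).
#' @param lag planted phase lag in radians (quarter cycle by default, which
#'   maximizes the imaginary cross-spectrum; 0 makes the coupling invisible
#'   to dwPLI by construction).
#' @param groups optional list with integer vectors `a` and `b` (disjoint
#'   parcel sets) selecting the network-oscillation mechanism; `edges` is
#'   then derived as all a-b pairs and must not be supplied.
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(band, state, edges = NULL, coupling_delta = 0.35,
                           direction = c("greater", "less"), lag = pi / 2,
                           groups = NULL) {
  direction <- match.arg(direction)
  if (!is.null(groups)) {
    stopifnot(is.null(edges), length(intersect(groups$a, groups$b)) == 0,
              length(groups$a) >= 1, length(groups$b) >= 1)
    edges <- as.matrix(expand.grid(i = groups$a, j = groups$b))
  }
  stopifnot(!is.null(edges))
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  colnames(edges) <- c("i", "j")
  structure(list(band = band, state = state, edges = edges,
                 coupling_delta = coupling_delta, direction = direction,
                 lag = lag, groups = groups), class = "planted_effect")
}

#' Bipartite parcel groups covering a target edge count
#'
#' Chooses two disjoint parcel sets whose complete bipartite graph has as
#' close to `n_edges` edges as possible, for use with the
#' network-oscillation mechanism of [planted_effect()]. Parcels are drawn
#' at random from `1:n_parcels`.
#'
#' @param n_parcels number of parcels available.
#' @param n_edges target edge count.
#' @return list with integer vectors `a` and `b`.
#' @export
bipartite_groups <- function(n_parcels, n_edges) {
  best <- NULL; best_err <- Inf
  for (a in 2:(n_parcels - 2)) {
    b <- max(2, round(n_edges / a))
    if (a + b > n_parcels) next
    err <- abs(a * b - n_edges)
    if (err < best_err) { best <- c(a, b); best_err <- err }
  }
  if (is.null(best)) stop("cannot fit ", n_edges, " bipartite edges into ",
                          n_parcels, " parcels")
  sel <- sample.int(n_parcels, sum(best))
  list(a = sel[seq_len(best[1])], b = sel[best[1] + seq_len(best[2])])
}

#' Synthetic cohort specification
#'
#' Defines a two-group, two-state cohort of 5-minute 58-parcel epochs at
#' 100 Hz, mirroring the reference study's configuration: 46 early-preterm
#' and 67 control subjects, conceptional age 41.4 +/- 1.4 weeks, a fidelity
#' mask keeping 1128 of 1653 edges, and two planted group effects covering
#' about 10% of the valid edges each — one in the theta range during active
#' sleep where EP connectivity is stronger (band 14, Fc = 5.3 Hz) and one in
#' the delta range during quiet sleep (band 8, Fc = 1.8 Hz). Clinical
#' scores are noisy monotone functions of the subject's planted coupling
#' strength plus a conceptional-age term.
#'
#' @param n_ep,n_hc subjects per group.
#' @param n_parcels number of cortical parcels.
#' @param fs sampling frequency in Hz.
#' @param duration_s epoch length in seconds.
#' @param bank filter bank whose band indices the effects refer to.
#' @param states sleep states to generate.
#' @param effects list of [planted_effect()]s; `NULL` plants the two default
#'   effects above, a fraction `effect_frac` of the valid edges each.
#' @param effect_frac fraction of valid edges covered by each default
#'   effect.
#' @param base_coupling coupling parameter of planted edges in the
#'   unfavored group (phase-locking scale, 0 = none, 1 = rigid).
#' @param coupling_sd between-subject standard deviation of the coupling
#'   parameter.
#' @param osc_snr oscillator strength as an amplitude ratio to the 1/f
#'   background *within the effect band* (in-band power ratio is its
#'   square). Scaling relative to the local background keeps the planted
#'   oscillation physiologically proportioned at every frequency and below
#'   the analysis filters' stop-band skirts elsewhere.
#' @param noise_exponent spectral slope of the background power spectrum.
#' @param ca_mean,ca_sd conceptional age distribution in weeks.
#' @param score_models list of score definitions: each a list with `score`
#'   (name), `effect` (index into `effects`), `n_driver` (edges of the
#'   effect that drive the score), `beta` (slope on the coupling parameter),
#'   `covariate_weight` (slope on standardized CA), `noise_sd`; `NULL` gives
#'   a motor score driven by the theta/AS effect and a cognitive score
#'   driven by the delta/QS effect.
#' @param mask_density fraction of edges marked reliable.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_ep = 46L, n_hc = 67L, n_parcels = 58L, fs = 100,
                        duration_s = 300, bank = build_filter_bank(),
                        states = c("AS", "QS"), effects = NULL,
                        effect_frac = 0.10, base_coupling = 0.4,
                        coupling_sd = 0.06, osc_snr = 3,
                        noise_exponent = 1, ca_mean = 41.4, ca_sd = 1.4,
                        score_models = NULL, mask_density = 1128 / 1653,
                        seed = 1L) {
  stopifnot(n_ep >= 2, n_hc >= 2, n_parcels >= 4,
            mask_density >= 0, mask_density <= 1)
  n_total_edges <- n_parcels * (n_parcels - 1) / 2
  n_valid <- round(mask_density * n_total_edges)
  if (is.null(effects)) {
    n_eff_edges <- max(1L, round(effect_frac * n_valid))
    effects <- with_seed(seed + 101L, {
      th_band <- min(14L, nrow(bank))
      de_band <- min(8L, nrow(bank))
      list(
        planted_effect(th_band, "AS", direction = "greater",
                       groups = bipartite_groups(n_parcels, n_eff_edges)),
        planted_effect(de_band, "QS", direction = "greater",
                       groups = bipartite_groups(n_parcels, n_eff_edges)))
    })
    effects <- Filter(function(e) e$state %in% states, effects)
  }
  for (e in effects) {
    if (e$band > nrow(bank)) stop("effect band outside the filter bank")
    if (base_coupling + e$coupling_delta + 3 * coupling_sd >= 1)
      stop("coupling target too close to 1 for the jitter model; ",
           "attainable range is base + delta + 3 sd < 1")
    if (any(e$edges > n_parcels)) stop("effect edges outside parcel range")
  }
  if (is.null(score_models)) {
    score_models <- list()
    add <- function(nm, eff_idx) {
      if (eff_idx <= length(effects))
        score_models[[length(score_models) + 1]] <<- list(
          score = nm, effect = eff_idx,
          n_driver = min(60L, nrow(effects[[eff_idx]]$edges)),
          beta = 1, covariate_weight = 0.1, noise_sd = 0.3)
    }
    add("C1_motor", 1L)
    add("C2_cognitive", 2L)
  }
  structure(list(n_ep = as.integer(n_ep), n_hc = as.integer(n_hc),
                 n_parcels = as.integer(n_parcels), fs = fs,
                 duration_s = duration_s, bank = bank, states = states,
                 effects = effects, base_coupling = base_coupling,
                 coupling_sd = coupling_sd, osc_snr = osc_snr,
                 noise_exponent = noise_exponent, ca_mean = ca_mean,
                 ca_sd = ca_sd, score_models = score_models,
                 n_valid_edges = n_valid, mask_density = mask_density,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# standard deviation of the unit-variance 1/f background within one band
# (share of the discrete spectrum falling between f_lo and f_hi)
band_noise_sd <- function(n, fs, f_lo, f_hi, exponent) {
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  shape2 <- f^(-exponent)
  shape2[1] <- 0
  fr <- (seq_len(n) - 1) / n * fs
  fr <- pmin(fr, fs - fr)
  sqrt(sum(shape2[fr >= f_lo & fr <= f_hi]) / sum(shape2))
}

# band-limited analytic oscillator base: complex Gaussian noise confined to
# [f_lo, f_hi] by brick-wall spectral masking (one-sided, so the result is
# analytic), unit RMS in its real part. Confinement keeps planted coupling
# out of bands two or more steps away; overlap with directly adjacent bands
# is a property of the 50%-overlapping bank itself.
band_limited_oscillator <- function(n, f_lo, f_hi, fs) {
  f <- (seq_len(n) - 1) / n * fs
  keep <- f >= f_lo & f <= f_hi
  X <- stats::fft(stats::rnorm(n))
  X[!keep] <- 0
  z <- stats::fft(X, inverse = TRUE) / n
  z / stats::sd(Re(z))
}

#' Generate one synthetic subject-state epoch
#'
#' Each parcel signal is unit-variance 1/f noise; for every planted edge
#' whose effect matches `state`, the two parcels additionally receive a
#' shared band-limited oscillation (complex Gaussian noise spectrally
#' confined to the effect band), injected with a constant phase lag and
#' independent slowly varying Gaussian phase jitter on each parcel. The
#' jitter standard deviation is `sqrt(-log(c))` for coupling parameter `c`,
#' the closed-form mapping for which the pairwise phase-locking of two
#' jittered copies equals `c`; stronger coupling therefore means tighter
#' phase locking and a larger dwPLI at that band.
#'
#' @param spec a [cohort_spec()].
#' @param subject row of the cohort's subject table (list with `subject_id`,
#'   `group`, `ca_weeks`).
#' @param state sleep state to generate.
#' @param couplings numeric vector, one coupling parameter per effect in
#'   `spec$effects` (as drawn by [generate_cohort()]); defaults to the
#'   group-level values without subject noise.
#' @param seed optional seed for standalone use.
#' @return a [subject_epoch()].
#' @export
generate_epoch <- function(spec, subject, state, couplings = NULL,
                           seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, generate_epoch(
    spec, subject, state, couplings)))
  N <- round(spec$duration_s * spec$fs)
  P <- spec$n_parcels
  x <- matrix(0, P, N)
  for (p in seq_len(P)) x[p, ] <- one_over_f_noise(N, spec$noise_exponent)
  if (is.null(couplings))
    couplings <- vapply(spec$effects, function(e) {
      favored <- (e$direction == "greater") == (subject$group == "EP")
      spec$base_coupling + if (favored) e$coupling_delta else 0
    }, 0)
  for (k in seq_along(spec$effects)) {
    e <- spec$effects[[k]]
    if (e$state != state) next
    cp <- min(max(couplings[k], 0.02), 0.98)
    sigma <- sqrt(-log(cp))
    band <- spec$bank[e$band, ]
    w <- max(2L, round(8 * spec$fs / band$fc))   # jitter much slower than the band
    o_lo <- 0.92 * band$fc; o_hi <- 1.08 * band$fc   # core of the band
    amp <- spec$osc_snr *
      band_noise_sd(N, spec$fs, o_lo, o_hi, spec$noise_exponent)
    if (!is.null(e$groups)) {
      # one network oscillation; each parcel hosts it once with its own
      # jitter, group b at the planted lag
      z <- band_limited_oscillator(N, o_lo, o_hi, spec$fs)
      for (p in e$groups$a)
        x[p, ] <- x[p, ] + amp * Re(z * exp(1i * smooth_jitter(N, w, sigma)))
      for (p in e$groups$b)
        x[p, ] <- x[p, ] + amp *
          Re(z * exp(1i * (smooth_jitter(N, w, sigma) - e$lag)))
    } else {
      for (r in seq_len(nrow(e$edges))) {
        z <- band_limited_oscillator(N, o_lo, o_hi, spec$fs)
        i <- e$edges[r, 1]; j <- e$edges[r, 2]
        x[i, ] <- x[i, ] + amp * Re(z * exp(1i * smooth_jitter(N, w, sigma)))
        x[j, ] <- x[j, ] + amp *
          Re(z * exp(1i * (smooth_jitter(N, w, sigma) - e$lag)))
      }
    }
  }
  subject_epoch(subject$subject_id, subject$group, state,
                subject$ca_weeks, spec$fs, x)
}

#' Generate a full synthetic cohort with ground truth
#'
#' Draws subject metadata, per-subject coupling parameters, all
#' subject-state epochs, a fidelity mask (uniform random at the requested
#' density, planted edges always included) and clinical scores. Scores are
#' `beta * coupling + covariate_weight * standardized CA + noise`, i.e.
#' noisy increasing functions of the subject's planted network strength.
#' The returned ground-truth record is meant for tests and audit only.
#'
#' @param spec a [cohort_spec()].
#' @return a `ppc_cohort`: list with `spec`, `subjects` (data frame),
#'   `epochs` (per state, a list of [subject_epoch()]s), `mask`
#'   ([fidelity_mask()]), `clinical` (long data frame: subject_id,
#'   score_name, score_value, ca_weeks), and `truth` (effects with
#'   oscillator frequencies, per-subject couplings, score driver edges).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_ep + spec$n_hc
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = rep(c("EP", "HC"), c(spec$n_ep, spec$n_hc)),
      ca_weeks = stats::rnorm(n, spec$ca_mean, spec$ca_sd))
    couplings <- matrix(NA_real_, n, length(spec$effects))
    for (k in seq_along(spec$effects)) {
      e <- spec$effects[[k]]
      favored <- (e$direction == "greater") == (subjects$group == "EP")
      mu <- spec$base_coupling + ifelse(favored, e$coupling_delta, 0)
      couplings[, k] <- pmin(pmax(
        stats::rnorm(n, mu, spec$coupling_sd), 0.02), 0.98)
    }
    planted <- do.call(rbind, lapply(spec$effects, function(e) e$edges))
    mask <- random_fidelity_mask(spec$n_parcels, spec$n_valid_edges,
                                 include = planted)
    epochs <- list()
    for (st in spec$states) {
      epochs[[st]] <- lapply(seq_len(n), function(s)
        generate_epoch(spec, subjects[s, ], st,
                       couplings = couplings[s, ]))
    }
    ca_std <- as.numeric(scale(subjects$ca_weeks))
    clinical <- do.call(rbind, lapply(spec$score_models, function(sm) {
      drive <- couplings[, sm$effect]
      data.frame(subject_id = subjects$subject_id,
                 score_name = sm$score,
                 score_value = sm$beta * drive +
                   sm$covariate_weight * ca_std +
                   stats::rnorm(n, 0, sm$noise_sd),
                 ca_weeks = subjects$ca_weeks)
    }))
    truth <- list(effects = spec$effects,
                  couplings = couplings,
                  score_drivers = lapply(spec$score_models, function(sm)
                    spec$effects[[sm$effect]]$edges[
                      seq_len(sm$n_driver), , drop = FALSE]),
                  score_bands = vapply(spec$score_models, function(sm)
                    as.integer(spec$effects[[sm$effect]]$band), 0L),
                  score_states = vapply(spec$score_models, function(sm)
                    spec$effects[[sm$effect]]$state, ""))
    structure(list(spec = spec, subjects = subjects, epochs = epochs,
                   mask = mask, clinical = clinical, truth = truth),
              class = "ppc_cohort")
  })
}

#' @export
print.ppc_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$spec$n_ep, "EP +", x$spec$n_hc, "HC subjects,",
      x$spec$n_parcels, "parcels,", length(x$spec$states), "state(s),",
      x$spec$duration_s, "s at", x$spec$fs, "Hz\n")
  cat("Fidelity mask:", x$mask$n_valid_edges, "of",
      x$spec$n_parcels * (x$spec$n_parcels - 1) / 2, "edges\n")
  cat("Planted effects:\n")
  for (e in x$spec$effects)
    cat(sprintf("  band %d (%s, %s): %d edges, delta = %.2f\n", e$band,
                e$state, e$direction, nrow(e$edges), e$coupling_delta))
  invisible(x)
}
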