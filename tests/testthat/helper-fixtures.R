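# Shared fixtures and independent oracles used across the suite.

# Wrap a noiseless synthesized beat as an averaged_beat so the biomarker
# module can be exercised without the preprocessing chain.
beat_from_archetype <- function(archetype, fs = 1000) {
  b <- synthesize_beat(archetype, fs)
  structure(list(samples = b$samples, fs = b$fs, leads = b$leads,
                 r_index = b$fiducials$r_peak, fiducials = b$fiducials,
                 n_beats_used = 1L, alignment_shifts = 0L,
                 rr_ms = 60000 / archetype$heart_rate_bpm,
                 subject_id = "fixture"),
            class = "averaged_beat")
}

zero_noise <- function() {
  noise_model(baseline_wander_amp_uV = 0, mains_amp_uV = 0,
              broadband_sd_uV = 0)
}

# Two well-separated blobs in 2 informative dimensions plus pure-noise
# columns; informative features are f1, f2.
blob_matrix <- function(seed, n = 60, noise_cols = 20, sep = 10) {
  set.seed(seed)
  lab <- rep(1:2, each = n / 2)
  X <- cbind(matrix(stats::rnorm(n * 2), n) + sep * (lab == 2),
             matrix(stats::rnorm(n * noise_cols), n))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  list(X = X, labels = lab)
}

# Brute-force DBSCAN oracle: core points by neighbourhood count (self
# included), clusters as the transitive closure of core-core reachability
# computed by repeated boolean matrix products, borders assigned to the
# nearest core within eps (ties: lower index), renumbered by size.
dbscan_oracle <- function(coords, eps, min_pts) {
  D <- as.matrix(stats::dist(coords))
  n <- nrow(D)
  within <- D <= eps
  core <- rowSums(within) >= min_pts
  labels <- integer(n)
  if (any(core) && eps > 0) {
    R <- within & outer(core, core, "&")
    diag(R) <- core
    repeat {
      R2 <- (R %*% R) > 0
      R2 <- R2 | R
      if (identical(R2, R)) break
      R <- R2
    }
    lab <- integer(n)
    nxt <- 0L
    for (i in which(core)) {
      if (lab[i] == 0L) {
        nxt <- nxt + 1L
        lab[R[i, ] & core] <- nxt
      }
    }
    labels[core] <- lab[core]
    for (i in which(!core)) {
      cand <- which(core & within[i, ])
      if (length(cand)) {
        nearest <- cand[order(D[i, cand], cand)][1]
        labels[i] <- labels[nearest]
      }
    }
  }
  # renumber by descending size, ties by first occurrence
  ids <- setdiff(unique(labels), 0L)
  if (length(ids)) {
    sizes <- vapply(ids, function(k) sum(labels == k), integer(1))
    first <- vapply(ids, function(k) which(labels == k)[1], integer(1))
    ids <- ids[order(-sizes, first)]
    out <- labels
    for (j in seq_along(ids)) out[labels == ids[j]] <- j
    labels <- out
  }
  labels
}

# Exhaustive single-beat lag oracle for Woody alignment: the integer lag
# maximising the inner product with the reference, ties toward smaller |lag|.
lag_oracle <- function(ref, x, max_lag) {
  shift1 <- function(v, k) {
    n <- length(v)
    if (k == 0) v
    else if (k > 0) c(numeric(k), v[seq_len(n - k)])
    else c(v[(1 - k):n], numeric(-k))
  }
  best <- NULL; best_cc <- -Inf
  for (k in seq(-max_lag, max_lag)) {
    cc <- sum(ref * shift1(x, k))
    if (cc > best_cc + 1e-12 ||
        (abs(cc - best_cc) <= 1e-12 && abs(k) < abs(best))) {
      best <- k; best_cc <- cc
    }
  }
  best
}

# Two-sided Fisher p for a 2x2 table by exhaustive hypergeometric
# enumeration from first principles (binomial coefficients only).
fisher_oracle_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ntot <- r1 + r2
  p_a <- function(a) {
    b <- r1 - a; cc <- c1 - a; dd <- r2 - cc
    if (b < 0 || cc < 0 || dd < 0) return(0)
    exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(ntot, c1))
  }
  obs <- p_a(tab[1, 1])
  amax <- min(r1, c1)
  probs <- vapply(0:amax, p_a, numeric(1))
  sum(probs[probs <= obs * (1 + 1e-7)])
}
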