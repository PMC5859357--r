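# QRS and T-wave biomarker extraction from an averaged beat.
#
# Wave decomposition rule: within the QRS window, waves are successive signed
# lobes between baseline (zero) crossings; R is the largest positive lobe,
# Q the nearest negative lobe before R, S the nearest negative lobe after R.
# Durations use linearly interpolated zero crossings; amplitudes are lobe
# extrema. Axes are computed from net areas of lead I and derived
# aVF = II - I/2 via atan2 (positive axis pointing inferior).

# Trapezoidal area of a uniformly sampled segment, in value-units * ms.
trapz_ms <- function(x, fs) {
  n <- length(x)
  (sum(x) - (x[1] + x[n]) / 2) * 1000 / fs
}

# Decompose a window into signed lobes. Returns a data.frame with one row per
# lobe whose |extremum| exceeds `eps`: sign, peak index (absolute), amplitude,
# and interpolated left/right boundary (fractional sample indices).
find_lobes <- function(x, idx, eps = 20) {
  s <- sign(x) * (abs(x) > eps)
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (i in seq_along(runs$values)) {
    v <- runs$values[i]
    if (v == 0) next
    seg <- starts[i]:ends[i]
    pk <- seg[which.max(abs(x[seg]))]
    # walk outward to the true zero crossing (or window edge)
    l <- starts[i]
    while (l > 1 && sign(x[l - 1]) == v && abs(x[l - 1]) > 0) l <- l - 1L
    left <- if (l > 1) (l - 1) + (0 - x[l - 1]) / (x[l] - x[l - 1]) else l
    r <- ends[i]
    while (r < length(x) && sign(x[r + 1]) == v && abs(x[r + 1]) > 0) r <- r + 1L
    right <- if (r < length(x)) r + (0 - x[r]) / (x[r + 1] - x[r]) else r
    out[[length(out) + 1L]] <- data.frame(
      sign = v, peak = idx[pk], amplitude = x[pk],
      left = idx[1] - 1 + left, right = idx[1] - 1 + right)
  }
  if (!length(out))
    return(data.frame(sign = numeric(0), peak = numeric(0),
                      amplitude = numeric(0), left = numeric(0),
                      right = numeric(0)))
  do.call(rbind, out)
}

# Derived frontal-plane axis from per-lead areas (area_I, area_II in uV*ms).
axis_from_areas <- function(area_I, area_II) {
  area_aVF <- area_II - area_I / 2
  ax <- atan2(area_aVF, area_I) * 180 / pi
  if (ax <= -180) ax <- ax + 360
  ax
}

#' Measure QRS biomarkers on an averaged beat
#'
#' Per lead: Q/R/S durations (ms) and amplitudes (uV) by the signed-lobe
#' rule, ascending/descending slopes (uV/ms, max |derivative| on the R
#' upstroke/downstroke). Global: QRS axis (degrees, from net areas of I and
#' derived aVF), QRS duration (lead II onset to offset), maximum peak-to-peak
#' QRS amplitude across leads, and maximum R amplitude.
#'
#' @param beat an `averaged_beat`.
#' @param lobe_eps baseline threshold in uV for lobe detection (default 20).
#' @param search_pad_ms per-lead search padding beyond the lead II QRS bounds.
#' @return list of class `qrs_biomarkers`: `per_lead` data.frame and
#'   `global` list.
#' @export
measure_qrs <- function(beat, lobe_eps = 20, search_pad_ms = 40) {
  fs <- beat$fs
  fid <- beat$fiducials
  pad <- round(search_pad_ms * fs / 1000)
  lo <- max(1, fid$qrs_onset - pad)
  hi <- min(nrow(beat$samples), fid$qrs_offset + pad)
  idx <- lo:hi
  per <- lapply(seq_along(beat$leads), function(l) {
    x <- beat$samples[idx, l]
    lobes <- find_lobes(x, idx, eps = lobe_eps)
    row <- data.frame(lead = beat$leads[l],
                      q_duration_ms = 0, q_amplitude_uV = 0,
                      r_duration_ms = 0, r_amplitude_uV = 0,
                      s_duration_ms = 0, s_amplitude_uV = 0,
                      ascending_slope = NA_real_, descending_slope = NA_real_,
                      r_absent = TRUE, stringsAsFactors = FALSE)
    pos <- lobes[lobes$sign > 0, , drop = FALSE]
    if (nrow(pos)) {
      rl <- pos[which.max(pos$amplitude), ]
      row$r_duration_ms <- (rl$right - rl$left) * 1000 / fs
      row$r_amplitude_uV <- rl$amplitude
      row$r_absent <- FALSE
      neg <- lobes[lobes$sign < 0, , drop = FALSE]
      before <- neg[neg$peak < rl$left, , drop = FALSE]
      if (nrow(before)) {
        ql <- before[nrow(before), ]
        row$q_duration_ms <- (ql$right - ql$left) * 1000 / fs
        row$q_amplitude_uV <- ql$amplitude
      }
      after <- neg[neg$peak > rl$right, , drop = FALSE]
      if (nrow(after)) {
        sl <- after[1, ]
        row$s_duration_ms <- (sl$right - sl$left) * 1000 / fs
        row$s_amplitude_uV <- sl$amplitude
      }
      up <- max(1, floor(rl$left)):round(rl$peak - idx[1] + 1)
      dn <- round(rl$peak - idx[1] + 1):min(length(x), ceiling(rl$right))
      dx <- diff(x) * fs / 1000
      if (length(up) > 1) row$ascending_slope <- max(dx[up[-length(up)]])
      if (length(dn) > 1) row$descending_slope <- min(dx[dn[-length(dn)]])
    } else if (nrow(lobes)) {
      # QS complex: no positive lobe, report the dominant negative lobe as S
      sl <- lobes[which.max(abs(lobes$amplitude)), ]
      row$s_duration_ms <- (sl$right - sl$left) * 1000 / fs
      row$s_amplitude_uV <- sl$amplitude
    }
    row
  })
  per <- do.call(rbind, per)
  area_I <- trapz_ms(beat$samples[idx, "I"], fs)
  area_II <- trapz_ms(beat$samples[idx, "II"], fs)
  p2p <- apply(beat$samples[fid$qrs_onset:fid$qrs_offset, , drop = FALSE], 2,
               function(x) max(x) - min(x))
  structure(list(
    per_lead = per,
    global = list(
      qrs_axis_deg = axis_from_areas(area_I, area_II),
      qrs_duration_ms = (fid$qrs_offset - fid$qrs_onset) * 1000 / fs,
      qrs_amplitude_uV = max(p2p),
      r_amplitude_uV = max(per$r_amplitude_uV))
  ), class = "qrs_biomarkers")
}

#' Pathological Q wave detection
#'
#' Lead-level rule (configurable): a Q wave is pathological iff its duration
#' is >= `dur_ms` (default 40 ms) or its depth exceeds `frac` (default 0.25)
#' of the same lead's R amplitude. The global flag requires pathological Q in
#' at least two contiguous leads (lead order I, II, V1-V6; aVR/V1 excluded).
#'
#' @param qrs a `qrs_biomarkers` object.
#' @param dur_ms,frac rule parameters.
#' @return list with `per_lead` (named logical) and `global` (logical).
#' @export
detect_pathological_q <- function(qrs, dur_ms = 40, frac = 0.25) {
  per <- qrs$per_lead
  path <- (per$q_duration_ms >= dur_ms) |
    (abs(per$q_amplitude_uV) > frac * per$r_amplitude_uV &
       per$q_amplitude_uV < 0)
  names(path) <- per$lead
  elig <- setdiff(per$lead, "V1")
  v <- path[elig]
  global <- any(v[-length(v)] & v[-1])
  list(per_lead = path, global = isTRUE(global))
}

#' Measure T-wave biomarkers on an averaged beat
#'
#' Per lead: signed T amplitude (extremum in the T window relative to the
#' isoelectric baseline) and an inversion flag (amplitude <= `twi_uV`,
#' default -100 uV; |amplitude| < `flat_uV` = 25 uV sets a flat-T flag and no
#' polarity). Global: T axis from I/derived-aVF T areas, abnormal-T-axis flag
#' (outside -15 to 75 degrees), TWI (>= 2 contiguous inverted leads among
#' V3-V6), giant TWI (two contiguous V3-V6 leads <= -1000 uV), T-peak-to-
#' T-end, ST displacement at J+60 ms (max-|value| lead), and Bazett QTc/JTc.
#'
#' @param beat an `averaged_beat`.
#' @param twi_uV inversion threshold (default -100).
#' @param giant_uV giant-inversion threshold (default -1000).
#' @param flat_uV flat-T threshold (default 25).
#' @param axis_band normal T-axis band in degrees (default c(-15, 75)).
#' @param qtc_formula `"bazett"` (default) or `"fridericia"`.
#' @return list of class `twave_biomarkers` with `per_lead` data.frame and
#'   `global` list.
#' @export
measure_twave <- function(beat, twi_uV = -100, giant_uV = -1000, flat_uV = 25,
                          axis_band = c(-15, 75), qtc_formula = "bazett") {
  fs <- beat$fs
  fid <- beat$fiducials
  lo <- min(nrow(beat$samples), fid$qrs_offset + round(0.06 * fs))
  hi <- min(nrow(beat$samples), fid$t_end + round(0.04 * fs))
  idx <- lo:hi
  t_amp <- vapply(seq_along(beat$leads), function(l) {
    x <- beat$samples[idx, l]
    x[which.max(abs(x))]
  }, numeric(1))
  flat <- abs(t_amp) < flat_uV
  inverted <- !flat & t_amp <= twi_uV
  per <- data.frame(lead = beat$leads, t_amplitude_uV = t_amp,
                    inverted = inverted, flat = flat,
                    stringsAsFactors = FALSE)
  v36 <- per[match(c("V3", "V4", "V5", "V6"), per$lead), ]
  twi <- any(v36$inverted[-4] & v36$inverted[-1])
  deep <- !v36$flat & v36$t_amplitude_uV <= giant_uV
  giant <- any(deep[-4] & deep[-1])
  area_I <- trapz_ms(beat$samples[idx, "I"], fs)
  area_II <- trapz_ms(beat$samples[idx, "II"], fs)
  t_axis <- axis_from_areas(area_I, area_II)
  j60 <- min(nrow(beat$samples), fid$qrs_offset + round(0.06 * fs))
  st <- beat$samples[j60, ]
  st_disp <- st[which.max(abs(st))]
  qt_ms <- (fid$t_end - fid$qrs_onset) * 1000 / fs
  rr_s <- beat$rr_ms / 1000
  qtc <- switch(qtc_formula,
                bazett = qt_ms / sqrt(rr_s),
                fridericia = qt_ms / rr_s^(1 / 3),
                stop("unknown qtc_formula"))
  qrs_ms <- (fid$qrs_offset - fid$qrs_onset) * 1000 / fs
  structure(list(
    per_lead = per,
    global = list(
      t_axis_deg = t_axis,
      abnormal_t_axis = t_axis < axis_band[1] || t_axis > axis_band[2],
      twi = twi, giant_twi = giant,
      tpeak_tend_ms = (fid$t_end - fid$t_peak) * 1000 / fs,
      st_displacement_uV = unname(st_disp),
      qt_ms = qt_ms, qtc_ms = qtc, jtc_ms = qtc - qrs_ms)
  ), class = "twave_biomarkers")
}

#' Per-subject feature vector for clustering and group tables
#'
#' Combines the Hermite QRS morphology representation (per-lead coefficients)
#' with T-wave biomarkers and standard QRS biomarkers into a single named
#' numeric vector. Feature names carry a type tag retrievable with
#' [feature_types()]: Hermite coefficients are `qrs_morphology`, T-wave
#' derived features `t_wave`, remaining QRS measurements `qrs_other`.
#'
#' @param beat an `averaged_beat`.
#' @param hermite a `hermite_representation` from [fit_hermite_beat()].
#' @param normalize_energy scale each lead's coefficient vector by the QRS
#'   window energy (so coefficients describe unit-energy shape and are
#'   invariant to overall amplitude; default TRUE). The raw coefficients in
#'   uV*sqrt(ms) are used when FALSE.
#' @return named numeric vector.
#' @export
subject_features <- function(beat, hermite, normalize_energy = TRUE) {
  qrs <- measure_qrs(beat)
  tw <- measure_twave(beat)
  h <- unlist(lapply(names(hermite), function(l) {
    cc <- hermite[[l]]$coefficients
    if (normalize_energy)
      cc <- cc * sqrt(hermite[[l]]$energy_fraction / sum(cc^2))
    stats::setNames(cc, paste0("hermite_", l, "_c", seq_along(cc) - 1L))
  }))
  tv <- c(stats::setNames(tw$per_lead$t_amplitude_uV,
                          paste0("t_amp_", tw$per_lead$lead)),
          stats::setNames(as.numeric(tw$per_lead$inverted),
                          paste0("t_inv_", tw$per_lead$lead)),
          t_axis_deg = tw$global$t_axis_deg,
          abnormal_t_axis = as.numeric(tw$global$abnormal_t_axis),
          twi = as.numeric(tw$global$twi),
          giant_twi = as.numeric(tw$global$giant_twi),
          tpeak_tend_ms = tw$global$tpeak_tend_ms,
          st_displacement_uV = tw$global$st_displacement_uV,
          qtc_ms = tw$global$qtc_ms, jtc_ms = tw$global$jtc_ms)
  pq <- detect_pathological_q(qrs)
  qv <- c(qrs_axis_deg = qrs$global$qrs_axis_deg,
          qrs_duration_ms = qrs$global$qrs_duration_ms,
          qrs_amplitude_uV = qrs$global$qrs_amplitude_uV,
          r_amplitude_uV = qrs$global$r_amplitude_uV,
          pathological_q = as.numeric(pq$global),
          stats::setNames(qrs$per_lead$r_duration_ms,
                          paste0("r_dur_", qrs$per_lead$lead)),
          stats::setNames(qrs$per_lead$s_amplitude_uV,
                          paste0("s_amp_", qrs$per_lead$lead)))
  c(h, tv, qv)
}

#' Feature type tags for a feature vector
#'
#' @param feature_names character vector of feature names as produced by
#'   [subject_features()].
#' @return character vector of tags: `qrs_morphology` (Hermite coefficients),
#'   `t_wave` (the T biomarkers appended in `qrs_plus_t` clustering: per-lead
#'   T amplitudes, inversion flags, TWI/giant-TWI, T axis), `t_other`
#'   (interval/displacement T measurements used in group tables only), or
#'   `qrs_other` (standard QRS biomarkers used in group tables only).
#' @export
feature_types <- function(feature_names) {
  ifelse(grepl("^hermite_", feature_names), "qrs_morphology",
         ifelse(grepl("^(t_amp_|t_inv_|t_axis_deg$|twi|giant_twi)",
                      feature_names), "t_wave",
                ifelse(grepl("^(abnormal_t|tpeak|st_disp|qtc|jtc)",
                             feature_names), "t_other", "qrs_other")))
}

#' Cohort feature matrix from a synthetic cohort
#'
#' Runs the full per-subject pipeline (denoise, delineate, select, average,
#' Hermite fit, biomarkers) over every subject and assembles the cohort
#' feature table. Before the Hermite fit, the averaged beats are brought onto
#' a common QRS time anchor by a cohort-level Woody alignment of their
#' multi-lead RMS envelopes: the per-subject R-peak anchor is precise but can
#' land on different QRS peaks for deep-S/low-R morphologies, and the
#' envelope alignment removes such anchor inconsistencies so that Hermite
#' coefficients are comparable across subjects.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param N Hermite order (default 4).
#' @param sigma_grid_ms Hermite width search grid.
#' @param verbose print progress every 10 subjects.
#' @return data.frame with `subject_id` followed by feature columns;
#'   attribute `feature_types` tags each feature column.
#' @export
cohort_features <- function(cohort, N = 4, sigma_grid_ms = seq(5, 50, by = 0.5),
                            verbose = FALSE) {
  fs <- cohort$fs
  dt <- 1000 / fs
  bank <- hermite_basis_bank(N, sigma_grid_ms, seq(-400, 400, by = dt))
  beats <- lapply(seq_along(cohort$subjects), function(i) {
    beat <- preprocess_recording(cohort$subjects[[i]])
    if (verbose && i %% 10 == 0) message("preprocessed ", i, " subjects")
    beat
  })
  centers <- cohort_qrs_anchors(beats, fs)
  rows <- lapply(seq_along(beats), function(i) {
    hr <- fit_hermite_beat(beats[[i]], N = N, sigma_grid_ms = sigma_grid_ms,
                           bank = bank, center = centers[i])
    subject_features(beats[[i]], hr)
  })
  X <- do.call(rbind, rows)
  out <- data.frame(subject_id = cohort$labels$subject_id, X,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "feature_types") <- feature_types(colnames(X))
  out
}

# Common QRS anchor across subjects: Woody alignment of the averaged beats'
# multi-lead RMS envelopes (window +/-90 ms around each subject's R anchor),
# returning the per-subject window-centre index. With a single subject the
# R anchor is returned unchanged.
cohort_qrs_anchors <- function(beats, fs, half_ms = 90, max_lag_ms = 40) {
  r0 <- vapply(beats, function(b) as.integer(b$fiducials$r_peak), integer(1))
  if (length(beats) < 2) return(r0)
  half <- round(half_ms * fs / 1000)
  env <- vapply(seq_along(beats), function(i) {
    idx <- (r0[i] - half):(r0[i] + half)
    idx <- pmin(pmax(idx, 1), nrow(beats[[i]]$samples))
    sqrt(rowMeans(beats[[i]]$samples[idx, , drop = FALSE]^2))
  }, numeric(2 * half + 1))
  wa <- woody_align(env, max_lag = round(max_lag_ms * fs / 1000))
  r0 - wa$shifts
}
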