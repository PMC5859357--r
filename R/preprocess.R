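# Beat preprocessing: denoising, delineation, beat selection, Woody
# alignment and ensemble averaging. Everything in this file is deterministic
# given the input samples (no RNG). Amplitudes are microvolts throughout;
# windows are sample-index based (1-based, inclusive).

#' Construct an ECG recording object
#'
#' @param samples numeric matrix, time x lead, microvolts.
#' @param fs sampling frequency in Hz.
#' @param leads lead labels (default the 8 independent leads I, II, V1-V6).
#' @param subject_id subject label.
#' @return object of class `ecg_recording`.
#' @export
ecg_recording <- function(samples, fs, leads = colnames(samples),
                          subject_id = "S1") {
  samples <- as.matrix(samples)
  if (is.null(leads)) leads <- ECG_LEADS[seq_len(ncol(samples))]
  stopifnot(fs > 0, nrow(samples) >= 10 * fs)
  colnames(samples) <- leads
  structure(list(samples = samples, fs = fs, leads = leads,
                 subject_id = subject_id),
            class = "ecg_recording")
}

#' Denoise a multi-lead ECG recording
#'
#' Three stages, each applied zero-phase (forward-backward filtering):
#' a low-pass Butterworth filter (order `lp_order`, -3 dB per pass at
#' `lowpass_hz`), a band-stop notch around `notch_hz` with quality factor
#' `notch_q`, and cubic-spline baseline removal with knots at per-beat PR
#' midpoints (isoelectric segment before each QRS). If no beats can be
#' anchored (e.g. a flat or beat-free signal) the per-lead median is
#' subtracted instead.
#'
#' @param rec an `ecg_recording`.
#' @param lowpass_hz low-pass cutoff (default 45 Hz).
#' @param lp_order Butterworth order (default 4).
#' @param notch_hz mains frequency to reject (default 50 Hz).
#' @param notch_q notch quality factor, bandwidth = notch_hz / notch_q
#'   (default 30).
#' @param baseline logical; run the spline baseline stage (default TRUE).
#' @param lowpass,notch logicals to toggle the filter stages.
#' @return an `ecg_recording` of the same shape.
#' @export
ecg_denoise <- function(rec, lowpass_hz = 45, lp_order = 4, notch_hz = 50,
                        notch_q = 30, baseline = TRUE, lowpass = TRUE,
                        notch = TRUE) {
  fs <- rec$fs
  if (notch && fs <= 2 * notch_hz)
    stop("sampling rate too low to design the mains notch filter")
  M <- rec$samples
  if (lowpass) {
    bf <- signal::butter(lp_order, lowpass_hz / (fs / 2), type = "low")
    for (l in seq_len(ncol(M)))
      M[, l] <- signal::filtfilt(bf, M[, l])
  }
  if (notch) {
    bw <- notch_hz / notch_q
    nf <- signal::butter(2, c(notch_hz - bw / 2, notch_hz + bw / 2) / (fs / 2),
                         type = "stop")
    for (l in seq_len(ncol(M)))
      M[, l] <- signal::filtfilt(nf, M[, l])
  }
  if (baseline) {
    anchor <- detect_r_peaks(M[, "II"], fs)
    for (l in seq_len(ncol(M)))
      M[, l] <- M[, l] - spline_baseline(M[, l], anchor, fs)
  }
  out <- rec
  out$samples <- M
  out
}

# Cubic-spline baseline through PR-segment knots (window centred 120 ms
# before each detected R peak). Falls back to the median when fewer than
# 4 knots are available.
spline_baseline <- function(x, r_peaks, fs) {
  n <- length(x)
  knots <- r_peaks - round(0.12 * fs)
  knots <- knots[knots > round(0.01 * fs) & knots <= n]
  if (length(knots) < 4) return(rep(stats::median(x), n))
  w <- round(0.01 * fs)
  kv <- vapply(knots, function(k) {
    i <- max(1, k - w):min(n, k + w)
    stats::median(x[i])
  }, numeric(1))
  sf <- stats::splinefun(knots, kv, method = "natural")
  sf(seq_len(n))
}

# R-peak detection on a single lead: band-passed (10-30 Hz, above the T-wave
# band) derivative energy, 80 ms moving integration, adaptive threshold with
# a second pass that
# re-thresholds at half the upper-quartile detected peak energy (rejects
# T-wave detections, whose energy is well below the QRS level, without
# losing genuine beats), 300 ms refractory period, then refinement to the
# largest positive peak (fallback: largest |peak|) within +/-60 ms.
detect_r_peaks <- function(x, fs) {
  bp <- signal::butter(2, c(10, 30) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  d <- c(0, diff(xf))
  e <- stats::filter(d^2, rep(1 / round(0.08 * fs), round(0.08 * fs)),
                     sides = 2)
  e[is.na(e)] <- 0
  e <- as.numeric(e)
  refr <- round(0.3 * fs)
  find <- function(thr) {
    cand <- which(e > thr)
    peaks <- integer(0)
    while (length(cand)) {
      seg_end <- c(which(diff(cand) > refr %/% 2), length(cand))
      first_seg <- cand[seq_len(seg_end[1])]
      p <- first_seg[which.max(e[first_seg])]
      peaks <- c(peaks, p)
      cand <- cand[cand > p + refr]
    }
    peaks
  }
  thr <- 0.2 * stats::quantile(e, 0.98)
  if (thr <= 0) return(integer(0))
  peaks <- find(thr)
  if (length(peaks) >= 4) {
    thr2 <- 0.5 * stats::quantile(e[peaks], 0.75)
    if (thr2 > thr) peaks <- find(thr2)
  }
  w <- round(0.06 * fs)
  vapply(peaks, function(p) {
    i <- max(1, p - w):min(length(x), p + w)
    pos <- i[x[i] > 0]
    if (length(pos)) pos[which.max(x[pos])] else i[which.max(abs(x[i]))]
  }, integer(1))
}

# Onset/offset around an R peak by outward threshold crossing on the
# derivative (threshold = frac of the max |derivative| in the QRS region);
# a below-threshold run of `quiet_ms` marks the boundary.
qrs_bounds <- function(x, r, fs, frac = 0.05, search_ms = 180, quiet_ms = 10) {
  n <- length(x)
  s <- round(search_ms * fs / 1000)
  q <- round(quiet_ms * fs / 1000)
  lo <- max(2, r - s); hi <- min(n, r + s)
  d <- abs(c(0, diff(x)))
  thr <- frac * max(d[lo:hi])
  onset <- lo
  i <- r
  run <- 0L
  while (i > lo) {
    i <- i - 1L
    run <- if (d[i] < thr) run + 1L else 0L
    if (run >= q) { onset <- i + run - 1L; break }
  }
  offset <- hi
  i <- r
  run <- 0L
  while (i < hi) {
    i <- i + 1L
    run <- if (d[i] < thr) run + 1L else 0L
    if (run >= q) { offset <- i - run + 1L; break }
  }
  c(onset = onset, offset = offset)
}

# T-peak (extremum of |x| after the QRS) and T-end (tangent method on the
# descending limb: intersect the steepest post-peak tangent with baseline 0).
t_wave_bounds <- function(x, offset, fs, rr, baseline = 0) {
  n <- length(x)
  lo <- min(n, offset + round(0.06 * fs))
  hi <- min(n, offset + round(min(0.55 * rr, 0.45 * fs)))
  if (hi - lo < round(0.05 * fs)) return(c(t_peak = NA, t_end = NA))
  seg <- x[lo:hi]
  tp <- lo + which.max(abs(seg)) - 1L
  amp <- x[tp]
  after <- tp:hi
  if (length(after) < 5) return(c(t_peak = tp, t_end = hi))
  d <- c(diff(x[after]), 0)
  k <- if (amp >= baseline) which.min(d) else which.max(d)
  i0 <- after[k]
  slope <- d[k]
  if (abs(slope) < 1e-9) return(c(t_peak = tp, t_end = hi))
  te <- i0 + (baseline - x[i0]) / slope
  te <- min(max(round(te), tp + 1L), n)
  c(t_peak = tp, t_end = te)
}

#' Delineate a denoised ECG recording
#'
#' Beat detection and fiducial estimation are anchored on lead II: R peaks by
#' band-passed derivative energy with adaptive threshold and refractory
#' period, QRS onset/offset by outward derivative-threshold crossing, T peak
#' as the post-QRS extremum, T end by the tangent method on the descending
#' limb. Per-lead wave measurements later refine within these anchors.
#'
#' @param rec a denoised `ecg_recording`.
#' @param min_beats minimum number of delineated beats (default 25).
#' @return data.frame of class `fiducial_set`, one row per beat with columns
#'   qrs_onset, r_peak, qrs_offset, t_peak, t_end (1-based sample indices).
#' @export
ecg_delineate <- function(rec, min_beats = 25) {
  x <- rec$samples[, "II"]
  fs <- rec$fs
  r <- detect_r_peaks(x, fs)
  r <- r[r > round(0.25 * fs) & r < length(x) - round(0.6 * fs)]
  if (length(r) < min_beats)
    stop("insufficient data: fewer than ", min_beats, " beats detected")
  rr <- stats::median(diff(r))
  rows <- lapply(seq_along(r), function(i) {
    b <- qrs_bounds(x, r[i], fs)
    tw <- t_wave_bounds(x, b[["offset"]], fs, rr)
    data.frame(qrs_onset = b[["onset"]], r_peak = r[i],
               qrs_offset = b[["offset"]], t_peak = tw[["t_peak"]],
               t_end = tw[["t_end"]])
  })
  fid <- do.call(rbind, rows)
  fid <- fid[!is.na(fid$t_end), , drop = FALSE]
  ok <- with(fid, qrs_onset < r_peak & r_peak < qrs_offset &
               qrs_offset <= t_peak & t_peak < t_end)
  fid <- fid[ok, , drop = FALSE]
  if (nrow(fid) < min_beats)
    stop("insufficient data: fewer than ", min_beats, " beats delineated")
  rownames(fid) <- NULL
  class(fid) <- c("fiducial_set", "data.frame")
  fid
}

#' Select beats by ST-T signal-to-noise ratio
#'
#' SNR of a beat is the peak-to-peak amplitude of its ST-T segment (lead II,
#' 100-500 ms after the R peak) divided by the RMS of its residual against
#' the ensemble median ST-T. Returns the `n` highest-SNR beats; ties are
#' broken by earlier time.
#'
#' @param rec a denoised `ecg_recording`.
#' @param fids a `fiducial_set` from [ecg_delineate()].
#' @param n number of beats to select (default 20).
#' @return integer vector of beat row indices into `fids`, time-ordered.
#' @export
select_beats <- function(rec, fids, n = 20) {
  if (nrow(fids) < n)
    stop("insufficient data: fewer than ", n, " delineated beats")
  fs <- rec$fs
  x <- rec$samples[, "II"]
  a <- round(0.1 * fs); b <- round(0.5 * fs)
  seg <- t(vapply(fids$r_peak, function(r) x[(r + a):(r + b)],
                  numeric(b - a + 1L)))
  med <- apply(seg, 2, stats::median)
  snr <- vapply(seq_len(nrow(seg)), function(i) {
    res <- seg[i, ] - med
    rms <- sqrt(mean(res^2))
    (max(seg[i, ]) - min(seg[i, ])) / max(rms, 1e-9)
  }, numeric(1))
  ord <- order(-snr, seq_along(snr))
  sort(ord[seq_len(n)])
}

#' Woody iterative alignment of QRS-centred windows
#'
#' Aligns each beat to the running ensemble average by maximising the
#' cross-correlation over integer lags (|lag| <= `max_lag`), re-averages, and
#' repeats until the shift vector is unchanged or `max_iter` is reached. The
#' mean shift is forced to zero by convention.
#'
#' @param beats numeric matrix, window samples x beats (equal-length,
#'   QRS-centred windows).
#' @param max_lag maximum absolute lag in samples.
#' @param max_iter maximum number of iterations (default 10).
#' @return list with `shifts` (integer per beat), `average` (aligned ensemble
#'   average), `iterations`, and `converged`.
#' @export
woody_align <- function(beats, max_lag = 50, max_iter = 10) {
  beats <- as.matrix(beats)
  if (ncol(beats) < 2) stop("woody_align needs at least 2 beats")
  if (nrow(beats) < 2 * max_lag + 2)
    stop("window shorter than twice the maximum lag")
  nb <- ncol(beats)
  shifts <- integer(nb)
  avg <- rowMeans(beats)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    new <- vapply(seq_len(nb), function(j)
      best_lag(avg, beats[, j], max_lag), integer(1))
    new <- new - as.integer(round(mean(new)))
    aligned <- vapply(seq_len(nb), function(j)
      shift_window(beats[, j], new[j]), numeric(nrow(beats)))
    avg <- rowMeans(aligned)
    if (identical(new, shifts)) { shifts <- new; converged <- TRUE; break }
    shifts <- new
  }
  list(shifts = shifts, average = avg, iterations = it, converged = converged)
}

# Lag maximising sum(ref[t] * shift_window(x, lag)[t]); ties -> smallest |lag|,
# then negative first (deterministic).
best_lag <- function(ref, x, max_lag) {
  lags <- seq(-max_lag, max_lag)
  cc <- vapply(lags, function(k) sum(ref * shift_window(x, k)), numeric(1))
  ord <- order(-cc, abs(lags), lags)
  as.integer(lags[ord[1]])
}

# Shift right by k (k > 0 delays), zero padding at the edges.
shift_window <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (k > 0) c(numeric(k), x[seq_len(n - k)])
  else c(x[(1 - k):n], numeric(-k))
}

#' Ensemble-averaged beat from selected, aligned beats
#'
#' Extracts a window around each selected R peak (default 250 ms before to
#' 600 ms after), estimates Woody alignment shifts on the lead II QRS
#' sub-window, applies the same integer shift to every lead, averages, and
#' re-delineates the fiducials on the averaged lead II waveform.
#'
#' @param rec a denoised `ecg_recording`.
#' @param fids a `fiducial_set`.
#' @param selected beat row indices from [select_beats()].
#' @param pre_ms,post_ms window extent around the R peak in ms.
#' @param max_lag_ms Woody maximum lag (default 50 ms).
#' @return list of class `averaged_beat`: `samples` (window x lead matrix),
#'   `fs`, `leads`, `r_index` (R sample within the window), `fiducials`
#'   (window-relative qrs_onset, r_peak, qrs_offset, t_peak, t_end),
#'   `n_beats_used`, `alignment_shifts`, `rr_ms` (median RR of the source
#'   beats), `subject_id`.
#' @export
average_beat <- function(rec, fids, selected, pre_ms = 250, post_ms = 600,
                         max_lag_ms = 50) {
  fs <- rec$fs
  pre <- round(pre_ms * fs / 1000); post <- round(post_ms * fs / 1000)
  r <- fids$r_peak[selected]
  r <- r[r - pre >= 1 & r + post <= nrow(rec$samples)]
  if (length(r) < 2) stop("insufficient beats inside the record for averaging")
  qw <- round(0.09 * fs)                      # lead II QRS window for alignment
  qrs_windows <- vapply(r, function(p)
    rec$samples[(p - qw):(p + qw), "II"], numeric(2 * qw + 1L))
  wa <- woody_align(qrs_windows, max_lag = round(max_lag_ms * fs / 1000))
  r_adj <- r - wa$shifts
  keep <- r_adj - pre >= 1 & r_adj + post <= nrow(rec$samples)
  r_adj <- r_adj[keep]
  win <- array(0, c(pre + post + 1L, length(rec$leads), length(r_adj)))
  for (j in seq_along(r_adj))
    win[, , j] <- rec$samples[(r_adj[j] - pre):(r_adj[j] + post), ]
  avg <- apply(win, c(1, 2), mean)
  colnames(avg) <- rec$leads
  r_index <- pre + 1L
  x <- avg[, "II"]
  b <- qrs_bounds(x, r_index, fs)
  rr <- stats::median(diff(sort(fids$r_peak))) * 1000 / fs
  tw <- t_wave_bounds(x, b[["offset"]], fs, rr * fs / 1000)
  structure(list(samples = avg, fs = fs, leads = rec$leads,
                 r_index = r_index,
                 fiducials = list(qrs_onset = b[["onset"]], r_peak = r_index,
                                  qrs_offset = b[["offset"]],
                                  t_peak = tw[["t_peak"]],
                                  t_end = tw[["t_end"]]),
                 n_beats_used = length(r_adj),
                 alignment_shifts = wa$shifts[keep],
                 rr_ms = rr, subject_id = rec$subject_id),
            class = "averaged_beat")
}

#' Full preprocessing of one recording into an averaged beat
#'
#' Convenience wrapper: [ecg_denoise()] then [ecg_delineate()],
#' [select_beats()] and [average_beat()].
#'
#' @param rec an `ecg_recording`.
#' @param n_beats number of beats to average (default 20).
#' @param ... passed to [ecg_denoise()].
#' @return an `averaged_beat`.
#' @export
preprocess_recording <- function(rec, n_beats = 20, ...) {
  den <- ecg_denoise(rec, ...)
  fids <- ecg_delineate(den)
  sel <- select_beats(den, fids, n = n_beats)
  average_beat(den, fids, sel)
}
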