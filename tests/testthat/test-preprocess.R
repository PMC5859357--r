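make_rec <- function(x, fs = 1000) {
  ecg_recording(matrix(rep(x, 8), ncol = 8,
                       dimnames = list(NULL, c("I", "II", paste0("V", 1:6)))),
                fs = fs)
}

test_that("denoising removes offset, mains and spares the passband", {
  fs <- 1000
  tt <- seq_len(20 * fs) / fs
  # pure DC offset comes out flat
  dc <- make_rec(rep(250, length(tt)))
  out <- ecg_denoise(dc)
  mid <- seq(2 * fs, 18 * fs)
  expect_lt(max(abs(out$samples[mid, 1])), 1)
  # 50 Hz, 100 uV is crushed by the notch (>= 20x)
  mains <- make_rec(100 * sin(2 * pi * 50 * tt))
  outm <- ecg_denoise(mains, baseline = FALSE)
  rms <- sqrt(mean(outm$samples[mid, 1]^2))
  expect_lt(rms, 5)
  expect_lt(rms, (100 / sqrt(2)) / 20)
  # 45 Hz through the low-pass stage only: |H|^2 = 1/2 at the cutoff
  s45 <- make_rec(100 * sin(2 * pi * 45 * tt))
  out45 <- ecg_denoise(s45, notch = FALSE, baseline = FALSE)
  ratio <- max(abs(out45$samples[mid, 1])) / 100
  expect_equal(ratio, 0.5, tolerance = 0.02)
  # 10 Hz passband gain is unity within 1%
  s10 <- make_rec(100 * sin(2 * pi * 10 * tt))
  out10 <- ecg_denoise(s10, baseline = FALSE)
  expect_equal(max(abs(out10$samples[mid, 1])) / 100, 1, tolerance = 0.01)
  expect_error(ecg_denoise(make_rec(rep(0, 1000), fs = 90)), "notch")
})

test_that("delineation matches generator ground truth", {
  arcs <- make_default_archetypes()
  rec <- simulate_recording(arcs$normal_upright_T, zero_noise(),
                            duration_s = 60, seed = 3)
  den <- ecg_denoise(rec)
  fid <- ecg_delineate(den)
  expect_equal(nrow(fid), nrow(rec$true_fiducials) -
                 sum(rec$true_fiducials$r_peak >= nrow(rec$samples) - 600))
  err <- vapply(fid$r_peak, function(r)
    min(abs(rec$true_fiducials$r_peak - r)), numeric(1))
  expect_lte(max(err), 1)
  expect_true(all(fid$qrs_onset < fid$r_peak & fid$r_peak < fid$qrs_offset &
                    fid$qrs_offset <= fid$t_peak & fid$t_peak < fid$t_end))
  # flat signal: no beats
  flat <- make_rec(rep(0, 30000))
  expect_error(ecg_delineate(flat), "insufficient")
  # default noise: at least 95% of beats within 10 ms
  recn <- simulate_recording(arcs$normal_upright_T, noise_model(),
                             duration_s = 60, seed = 4)
  fidn <- ecg_delineate(ecg_denoise(recn))
  errn <- vapply(fidn$r_peak, function(r)
    min(abs(recn$true_fiducials$r_peak - r)), numeric(1))
  expect_gte(mean(errn <= 10), 0.95)
})

test_that("beat selection ranks by ST-T signal-to-noise", {
  arcs <- make_default_archetypes()
  rec <- simulate_recording(arcs$normal_upright_T, zero_noise(),
                            duration_s = 60, seed = 9)
  den <- ecg_denoise(rec)
  fid <- ecg_delineate(den)
  # inject heavy ST-T noise into 10 known beats
  noisy <- sort(sample(seq_len(nrow(fid)), 10))
  set.seed(1)
  for (i in noisy) {
    seg <- (fid$r_peak[i] + 100):(fid$r_peak[i] + 500)
    den$samples[seg, "II"] <- den$samples[seg, "II"] +
      stats::rnorm(length(seg), 0, 150)
  }
  sel <- select_beats(den, fid, n = 20)
  expect_length(sel, 20)
  expect_length(intersect(sel, noisy), 0)
  # all-identical beats (selection on the raw noiseless record, where beat
  # windows are exactly equal): ties broken by earlier time
  rec0 <- simulate_recording(arcs$normal_upright_T, zero_noise(),
                             duration_s = 60, seed = 9)
  fid0 <- ecg_delineate(ecg_denoise(rec0))
  sel0 <- select_beats(rec0, fid0, n = 20)
  expect_equal(sel0, seq_len(20))
  expect_equal(select_beats(rec0, fid0, n = nrow(fid0)), seq_len(nrow(fid0)))
  expect_error(select_beats(rec0, fid0, n = nrow(fid0) + 1), "insufficient")
})

test_that("Woody alignment recovers known shifts and converges", {
  t_ms <- seq(-150, 150)
  template <- 900 * exp(-t_ms^2 / 200) - 300 * exp(-(t_ms - 40)^2 / 150)
  shift1 <- function(v, k) {
    n <- length(v)
    if (k == 0) v else if (k > 0) c(numeric(k), v[seq_len(n - k)])
    else c(v[(1 - k):n], numeric(-k))
  }
  applied <- c(-5L, 0L, 7L)
  beats <- vapply(applied, function(k) shift1(template, k),
                  numeric(length(template)))
  wa <- woody_align(beats, max_lag = 20)
  expect_true(wa$converged)
  # recovered shifts undo the applied ones up to a common integer offset
  undone <- wa$shifts + applied
  expect_equal(length(unique(undone)), 1L)
  # identical beats: all shifts zero
  same <- vapply(1:5, function(i) template, numeric(length(template)))
  wa0 <- woody_align(same, max_lag = 20)
  expect_true(all(wa0$shifts == 0))
  expect_equal(wa0$average, template)
  # per-beat lags agree with the exhaustive-search oracle
  for (j in seq_along(applied)) {
    expect_equal(hcmecg:::best_lag(wa$average, beats[, j], 20),
                 lag_oracle(wa$average, beats[, j], 20))
  }
  expect_error(woody_align(beats[1:30, ], max_lag = 20), "maximum lag")
})

test_that("ensemble averaging reduces broadband noise like 1/sqrt(n)", {
  arcs <- make_default_archetypes()
  sigma <- 40
  rec <- simulate_recording(arcs$normal_upright_T,
                            noise_model(baseline_wander_amp_uV = 0,
                                        mains_amp_uV = 0,
                                        broadband_sd_uV = sigma),
                            duration_s = 60, seed = 12)
  den <- ecg_denoise(rec, lowpass = FALSE, notch = FALSE, baseline = FALSE)
  fid <- ecg_delineate(den)
  sel <- select_beats(den, fid, n = 20)
  beat <- average_beat(den, fid, sel)
  expect_equal(beat$n_beats_used, 20)
  # residual on the flat pre-QRS baseline (template is zero there, and beat
  # alignment jitter cannot contribute on a flat segment): averaging n beats
  # shrinks broadband noise by sqrt(n)
  tmpl <- synthesize_beat(arcs$normal_upright_T, 1000)
  r0 <- tmpl$fiducials$r_peak
  flat <- beat$samples[beat$r_index + (-220):(-120), "V6"]
  expect_equal(sqrt(mean(flat^2)), sigma / sqrt(20), tolerance = 0.3)
  idx <- -40:300
  # identical beats average to any single beat
  rec0 <- simulate_recording(arcs$normal_upright_T, zero_noise(),
                             duration_s = 60, seed = 12)
  den0 <- ecg_denoise(rec0, lowpass = FALSE, notch = FALSE, baseline = FALSE)
  fid0 <- ecg_delineate(den0)
  beat0 <- average_beat(den0, fid0, select_beats(den0, fid0))
  res0 <- beat0$samples[beat0$r_index + idx, "V4"] -
    tmpl$samples[r0 + idx, "V4"]
  expect_lt(max(abs(res0)), 1e-9)
})
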