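test_that("noiseless beats round-trip through the QRS biomarkers", {
  arcs <- make_default_archetypes()
  b2 <- beat_from_archetype(arcs$shortR_deepS_V4)
  q2 <- measure_qrs(b2)
  v4 <- q2$per_lead[q2$per_lead$lead == "V4", ]
  expect_equal(v4$r_duration_ms, 38, tolerance = 2)
  expect_equal(v4$s_amplitude_uV, -1170, tolerance = 10)
  expect_equal(q2$global$qrs_axis_deg, 29, tolerance = 3)
  b3 <- beat_from_archetype(arcs$LAD_shortR_longS_V4to6)
  q3 <- measure_qrs(b3)
  expect_equal(q3$global$qrs_axis_deg, -37, tolerance = 3)
  b1 <- beat_from_archetype(arcs$normal_upright_T)
  q1 <- measure_qrs(b1)
  v4n <- q1$per_lead[q1$per_lead$lead == "V4", ]
  expect_equal(v4n$r_duration_ms, 47, tolerance = 2)
  expect_equal(v4n$r_amplitude_uV, 1400, tolerance = 1)
  expect_equal(q1$global$qrs_axis_deg, 30, tolerance = 3)
})

test_that("wave decomposition handles single-lobe and QS morphologies", {
  fs <- 1000
  n <- 700
  M <- matrix(0, n, 8, dimnames = list(NULL, c("I", "II", paste0("V", 1:6))))
  tri <- c(seq(0, 600, length.out = 31), seq(580, 0, length.out = 30))
  M[185:245, ] <- tri
  beat <- structure(list(samples = M, fs = fs,
                         leads = colnames(M), r_index = 215,
                         fiducials = list(qrs_onset = 180, r_peak = 215,
                                          qrs_offset = 250, t_peak = 500,
                                          t_end = 560),
                         n_beats_used = 1, alignment_shifts = 0,
                         rr_ms = 1000, subject_id = "tri"),
                    class = "averaged_beat")
  q <- measure_qrs(beat)
  lead1 <- q$per_lead[1, ]
  expect_equal(lead1$r_amplitude_uV, 600, tolerance = 1)
  expect_equal(lead1$q_duration_ms, 0)
  expect_equal(lead1$s_duration_ms, 0)
  # QS complex: only a negative lobe
  M2 <- M; M2[] <- 0
  M2[185:245, ] <- -tri
  beat$samples <- M2
  q2 <- measure_qrs(beat)
  expect_true(q2$per_lead$r_absent[1])
  expect_equal(q2$per_lead$s_amplitude_uV[1], -600, tolerance = 1)
})

test_that("pathological Q rule follows duration and depth criteria", {
  per <- data.frame(lead = c("I", "II", paste0("V", 1:6)),
                    q_duration_ms = 0, q_amplitude_uV = 0,
                    r_duration_ms = 40, r_amplitude_uV = 1000,
                    s_duration_ms = 20, s_amplitude_uV = -100,
                    stringsAsFactors = FALSE)
  qb <- structure(list(per_lead = per, global = list()),
                  class = "qrs_biomarkers")
  expect_false(detect_pathological_q(qb)$global)
  # deep-but-brief Q below the depth criterion is not pathological
  per2 <- per
  per2$q_duration_ms[3] <- 20
  per2$q_amplitude_uV[3] <- -100
  qb$per_lead <- per2
  expect_false(any(detect_pathological_q(qb)$per_lead))
  # 45 ms Q of any depth is pathological; two contiguous leads set the flag
  per3 <- per
  per3$q_duration_ms[c(5, 6)] <- 45
  per3$q_amplitude_uV[c(5, 6)] <- -80
  qb$per_lead <- per3
  pq <- detect_pathological_q(qb)
  expect_true(all(pq$per_lead[c("V3", "V4")]))
  expect_true(pq$global)
  # depth > 25% of R
  per4 <- per
  per4$q_duration_ms[2] <- 20
  per4$q_amplitude_uV[2] <- -300
  qb$per_lead <- per4
  expect_true(detect_pathological_q(qb)$per_lead[["II"]])
})

test_that("T-wave inversion needs two contiguous lateral leads", {
  arcs <- make_default_archetypes()
  a <- arcs$normal_upright_T
  a$t_amplitude_uV[c("V3", "V4", "V5", "V6")] <- c(-150, -200, 50, 100)
  tw <- measure_twave(beat_from_archetype(a))
  expect_true(tw$global$twi)
  a$t_amplitude_uV[c("V3", "V4", "V5", "V6")] <- c(-150, 50, -200, 100)
  tw2 <- measure_twave(beat_from_archetype(a))
  expect_false(tw2$global$twi)
  expect_equal(tw2$per_lead$t_amplitude_uV[tw2$per_lead$lead == "V5"], -200,
               tolerance = 1)
  # giant inversion requires <= -1000 uV in two contiguous leads
  a$t_amplitude_uV[c("V3", "V4", "V5", "V6")] <- c(-1100, -1200, -300, 100)
  tw3 <- measure_twave(beat_from_archetype(a))
  expect_true(tw3$global$giant_twi)
  # near-flat T neither inverted nor counted
  a$t_amplitude_uV[c("V3", "V4", "V5", "V6")] <- c(-150, -200, 5, 5)
  tw4 <- measure_twave(beat_from_archetype(a))
  v5 <- tw4$per_lead[tw4$per_lead$lead == "V5", ]
  expect_true(v5$flat)
  expect_false(v5$inverted)
})

test_that("QTc follows Bazett on the measured intervals", {
  arcs <- make_default_archetypes()
  beat <- beat_from_archetype(arcs$normal_upright_T)
  tw <- measure_twave(beat)
  qt_ms <- (beat$fiducials$t_end - beat$fiducials$qrs_onset) * 1000 / beat$fs
  expect_equal(tw$global$qt_ms, qt_ms)
  expect_equal(tw$global$qtc_ms, qt_ms / sqrt(beat$rr_ms / 1000),
               tolerance = 1e-9)
  expect_gte(tw$global$jtc_ms, 0)
  frid <- measure_twave(beat, qtc_formula = "fridericia")
  expect_equal(frid$global$qtc_ms, qt_ms / (beat$rr_ms / 1000)^(1 / 3),
               tolerance = 1e-9)
  # spec of the arithmetic: QT 352 ms at RR 640 ms gives 440 ms
  expect_equal(352 / sqrt(0.640), 440, tolerance = 0.05)
})

test_that("amplitude scaling moves amplitudes only", {
  arcs <- make_default_archetypes()
  beat <- beat_from_archetype(arcs$shortR_deepS_V4)
  beat2 <- beat
  beat2$samples <- 2 * beat$samples
  q1 <- measure_qrs(beat); q2 <- measure_qrs(beat2)
  expect_equal(q2$per_lead$r_amplitude_uV, 2 * q1$per_lead$r_amplitude_uV,
               tolerance = 1e-6)
  expect_equal(q2$per_lead$r_duration_ms, q1$per_lead$r_duration_ms,
               tolerance = 0.5)
  expect_equal(q2$global$qrs_axis_deg, q1$global$qrs_axis_deg,
               tolerance = 1e-6)
  t1 <- measure_twave(beat); t2 <- measure_twave(beat2)
  expect_equal(t2$per_lead$t_amplitude_uV, 2 * t1$per_lead$t_amplitude_uV,
               tolerance = 1e-6)
  inv <- beat_from_archetype(arcs$normal_inverted_T)
  inv2 <- inv; inv2$samples <- 3 * inv$samples
  expect_true(measure_twave(inv)$global$twi)
  expect_true(measure_twave(inv2)$global$twi)
})

test_that("feature vectors are tagged by family", {
  arcs <- make_default_archetypes()
  beat <- beat_from_archetype(arcs$normal_upright_T)
  hr <- fit_hermite_beat(beat, N = 4)
  fv <- subject_features(beat, hr)
  ty <- feature_types(names(fv))
  expect_equal(sum(ty == "qrs_morphology"), 32)   # 8 leads x 4 coefficients
  expect_true(all(c("t_wave", "qrs_other", "t_other") %in% ty))
  expect_true(all(ty[grepl("^t_amp_", names(fv))] == "t_wave"))
  expect_true(ty[names(fv) == "qtc_ms"] == "t_other")
  # energy normalisation makes Hermite features amplitude-invariant
  beat2 <- beat; beat2$samples <- 2 * beat$samples
  hr2 <- fit_hermite_beat(beat2, N = 4)
  fv2 <- subject_features(beat2, hr2)
  h <- grepl("^hermite_", names(fv))
  expect_equal(unname(fv2[h]), unname(fv[h]), tolerance = 1e-9)
})
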