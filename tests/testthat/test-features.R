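# a syntactically valid fiducial set over an arbitrary signal
flat_beat <- function(fs = 500) {
  fiducial_beat(qrs_onset = 50, q_peak = 60, r_peak = 70, s_peak = 80,
                qrs_offset = 90, t_onset = 120, t_peak = 150,
                t_offset = 180, next_p_onset = 240, sampling_rate = fs)
}

test_that("a flat zero signal yields zero features and fiducial-difference durations", {
  fb <- flat_beat()
  v <- extract_lead_features(numeric(300), list(fb))
  expect_equal(unname(v["qrs_duration"]), 40 / 500)
  expect_equal(unname(v["qrs_nonterminal_duration"]), 20 / 500)
  expect_equal(unname(v["qrs_terminal_duration"]), 20 / 500)
  expect_equal(unname(v["st_duration"]), 30 / 500)
  expect_equal(unname(v["t_duration"]), 60 / 500)
  expect_equal(unname(v["tp_duration"]), 60 / 500)
  others <- setdiff(names(v), grep("duration", names(v), value = TRUE))
  expect_true(all(v[others] == 0))
})

test_that("features are averaged arithmetically across beats", {
  fs <- 500
  make_t <- function(amp) {
    s <- numeric(300)
    s[151] <- amp  # t_peak at index 150 (0-based)
    s
  }
  fb <- flat_beat()
  two_beats <- c(make_t(0.2), make_t(0.6))
  fb2 <- fb
  for (f in c("qrs_onset", "q_peak", "r_peak", "s_peak", "qrs_offset",
              "t_onset", "t_peak", "t_offset", "next_p_onset")) {
    fb2[[f]] <- fb2[[f]] + 300L
  }
  v <- extract_lead_features(two_beats, list(fb, fb2))
  expect_equal(unname(v["t_amplitude"]), 0.4)
  # permuting beat order leaves the mean unchanged
  v2 <- extract_lead_features(two_beats, list(fb2, fb))
  expect_equal(v, v2)
})

test_that("noise-free synthetic beats match the analytic oracle within 1e-3", {
  set.seed(7)
  worst <- 0
  for (i in 1:50) {
    b <- generate_beat(random_beat_params(), noise_sd = 0)
    ex <- extract_lead_features(b$samples, list(b$fiducials))
    worst <- max(worst, max(rel_err(ex, b$features, floor = 1e-3)))
  }
  expect_lt(worst, 1e-3)
})

test_that("fiducial violations and missing input are rejected informatively", {
  expect_error(extract_lead_features(numeric(300), list()), "no beats")
  bad <- flat_beat()
  bad$r_peak <- 95L  # after qrs_offset
  expect_error(extract_lead_features(numeric(300), list(flat_beat(), bad)),
               "beat 2")
  sig <- lapply(ecg_leads(), function(x) numeric(300))
  names(sig) <- ecg_leads()
  expect_error(extract_ecg_features(sig[-c(1, 4)], list()), "I, aVR")
})

test_that("the 12-lead vector is lead-major and symmetric for identical leads", {
  ecg <- simulate_ecg(n_beats = 2, noise_sd = 0, amplitude_jitter = 0,
                      seed = 3)
  v <- extract_ecg_features(ecg$signals, ecg$beats)
  expect_length(v, 276L)
  expect_equal(names(v), ecg_feature_names())
  # all leads fed the same signal -> identical 23-blocks
  sig1 <- ecg$signals[[1]]; beats1 <- ecg$beats[[1]]
  same <- stats::setNames(rep(list(sig1), 12), ecg_leads())
  same_beats <- stats::setNames(rep(list(beats1), 12), ecg_leads())
  v2 <- extract_ecg_features(same, same_beats)
  blocks <- matrix(v2, nrow = 23)
  expect_true(all(apply(blocks, 1, function(r) max(r) - min(r)) < 1e-12))
})

test_that("fragmentation counts extra extrema with threshold denoising", {
  fs <- 500
  tt <- 0:199
  # monophasic R: smooth single bump, no annotated Q/S
  fb_mono <- fiducial_beat(qrs_onset = 10, r_peak = 30, qrs_offset = 50,
                           t_onset = 60, t_peak = 80, t_offset = 100,
                           next_p_onset = 150, sampling_rate = fs)
  mono <- exp(-(tt - 30)^2 / 30)
  expect_equal(fragmentation_count(mono, fb_mono), 0L)
  # RSR' morphology: R (1 mV) and S notch (-0.3 mV) annotated, second R
  # deflection unannotated -> one extra extremum
  fb_rsr <- fiducial_beat(qrs_onset = 10, r_peak = 25, qrs_offset = 50,
                          t_onset = 60, t_peak = 80, t_offset = 100,
                          next_p_onset = 150, sampling_rate = fs,
                          s_peak = 33L)
  rsr <- exp(-(tt - 25)^2 / 8) - 0.3 * exp(-(tt - 33)^2 / 4) +
    exp(-(tt - 41)^2 / 8)
  expect_equal(fragmentation_count(rsr, fb_rsr), 1L)
  # sub-threshold ripple (1% of R) leaves the count unchanged
  ripple <- rsr + 0.01 * sin(tt * 2)
  expect_equal(fragmentation_count(ripple, fb_rsr), 1L)
})

test_that("feature scaling covariance holds under amplitude scaling", {
  b <- with_seed_test(11, generate_beat(random_beat_params()))
  v1 <- extract_lead_features(b$samples, list(b$fiducials))
  k <- 3.7
  v2 <- extract_lead_features(k * b$samples, list(b$fiducials))
  lin <- c("q_amplitude", "r_amplitude", "s_amplitude", "r_upslope",
           "r_downslope", "st_deviation", "st_slope", "t_amplitude",
           "t_upslope", "t_downslope", "tp_slope", "qrs_auc", "t_auc")
  expect_equal(v2[lin], k * v1[lin], tolerance = 1e-10)
  expect_equal(v2[c("qrs_energy", "t_energy")],
               k^2 * v1[c("qrs_energy", "t_energy")], tolerance = 1e-10)
  durs <- grep("duration", names(v1), value = TRUE)
  expect_equal(v2[durs], v1[durs])
  expect_equal(v2["qrs_fragmentation"], v1["qrs_fragmentation"])
})

test_that("doubling the sampling rate changes smooth-beat features by < 1%", {
  # wide, gentle waves and non-degenerate ST/TP structure so every feature
  # has a meaningful magnitude for a relative comparison
  mk <- function(fs) beat_shape_params(
    q = list(amplitude = -0.10, center = 0.200, width = 0.015),
    r = list(amplitude = 1.00, center = 0.250, width = 0.020),
    s = list(amplitude = -0.15, center = 0.300, width = 0.020),
    t = list(amplitude = 0.30, center = 0.520, width = 0.045),
    st_level = 0.10, tp_slope = 0.30, beat_duration = 0.9,
    sampling_rate = fs)
  b1 <- generate_beat(mk(1000))
  b2 <- generate_beat(mk(2000))
  v1 <- extract_lead_features(b1$samples, list(b1$fiducials))
  v2 <- extract_lead_features(b2$samples, list(b2$fiducials))
  nonzero <- abs(v1) > 1e-9
  expect_lt(max(rel_err(v2[nonzero], v1[nonzero])), 0.01)
})

test_that("non-terminal plus terminal QRS duration equals the total exactly", {
  set.seed(13)
  for (i in 1:20) {
    b <- generate_beat(random_beat_params())
    v <- extract_lead_features(b$samples, list(b$fiducials))
    expect_equal(unname(v["qrs_nonterminal_duration"] +
                           v["qrs_terminal_duration"]),
                 unname(v["qrs_duration"]), tolerance = 1e-12)
    # the underlying index identity is exact
    fb <- b$fiducials
    expect_identical((fb$r_peak - fb$qrs_onset) + (fb$qrs_offset - fb$r_peak),
                     fb$qrs_offset - fb$qrs_onset)
  }
})

test_that("waveform CSV and fiducial JSON round-trip through files", {
  ecg <- simulate_ecg(n_beats = 2, seed = 9)
  wf <- tempfile(fileext = ".csv")
  fj <- tempfile(fileext = ".json")
  write_waveform_csv(ecg$signals, wf)
  write_fiducial_json(ecg$beats, ecg$sampling_rate, fj)
  v_direct <- extract_ecg_features(ecg$signals, ecg$beats)
  v_files <- extract_from_files(wf, fj)
  expect_equal(v_files, v_direct, tolerance = 1e-10)
})
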