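test_that("feature registry and vector layout are fixed", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 23L)
  expect_equal(length(ecg_leads()), 12L)
  fn <- ecg_feature_names()
  expect_equal(length(fn), 276L)
  expect_false(anyDuplicated(fn) > 0)
  # name <-> index map is bijective
  idx <- feature_index(rep(ecg_leads(), each = 23), rep(reg$name, 12))
  expect_equal(sort(idx), 1:276)
  expect_equal(fn[feature_index("aVR", "q_amplitude")], "aVR_q_amplitude")
  # components partition the registry
  expect_setequal(unique(reg$component), c("Q", "QRS", "ST", "T", "TP"))
})

test_that("a silent beat yields all-zero amplitude, slope, energy and AUC features", {
  zero <- function(a) list(amplitude = 0, center = a[1], width = a[2])
  p <- beat_shape_params(q = zero(c(0.20, 0.012)), r = zero(c(0.24, 0.016)),
                         s = zero(c(0.285, 0.013)), t = zero(c(0.50, 0.040)))
  b <- generate_beat(p, noise_sd = 0)
  zero_feats <- setdiff(feature_registry()$name,
                        c("qrs_duration", "qrs_nonterminal_duration",
                          "qrs_terminal_duration", "st_duration",
                          "t_duration", "tp_duration"))
  expect_true(all(abs(b$features[zero_feats]) < 1e-12))
  ex <- extract_lead_features(b$samples, list(b$fiducials))
  expect_true(all(abs(ex[zero_feats]) < 1e-12))
})

test_that("a lone R wave gives unit R amplitude and no T inversion", {
  zero <- function(a) list(amplitude = 0, center = a[1], width = a[2])
  p <- beat_shape_params(q = zero(c(0.20, 0.012)),
                         r = list(amplitude = 1, center = 0.24, width = 0.016),
                         s = zero(c(0.285, 0.013)), t = zero(c(0.50, 0.040)))
  b <- generate_beat(p, noise_sd = 0)
  expect_equal(unname(b$features["r_amplitude"]), 1, tolerance = 1e-9)
  expect_equal(unname(b$features["t_inversion"]), 0)
})

test_that("QRS energy of a Gaussian R bump matches dense trapezoid quadrature", {
  zero <- function(a) list(amplitude = 0, center = a[1], width = a[2])
  a_r <- 1; sig <- 0.02
  p <- beat_shape_params(q = zero(c(0.18, 0.012)),
                         r = list(amplitude = a_r, center = 0.24, width = sig),
                         s = zero(c(0.31, 0.013)), t = zero(c(0.52, 0.040)))
  b <- generate_beat(p, noise_sd = 0)
  fb <- b$fiducials
  fs <- fb$sampling_rate
  # independent oracle: trapezoid quadrature of a^2 exp(-(t-c)^2/sigma^2)
  # at 10x the sampling rate over the QRS window
  tt <- seq(fb$qrs_onset / fs, (fb$qrs_offset - 1) / fs, by = 1 / (10 * fs))
  integrand <- a_r^2 * exp(-(tt - 0.24)^2 / sig^2)
  oracle <- sum((integrand[-1] + integrand[-length(integrand)]) / 2) *
    (1 / (10 * fs))
  expect_lt(rel_err(unname(b$features["qrs_energy"]), oracle), 1e-3)
  ex <- extract_lead_features(b$samples, list(fb))
  expect_lt(rel_err(unname(ex["qrs_energy"]), oracle), 1e-3)
})

test_that("overlapping wave supports are rejected", {
  expect_error(
    beat_shape_params(t = list(amplitude = 0.3, center = 0.33, width = 0.04)),
    "overlap"
  )
  expect_error(beat_shape_params(sampling_rate = 0), "sampling_rate")
  expect_error(
    beat_shape_params(r = list(amplitude = 1, center = 0.18, width = 0.016)),
    "ordered"
  )
})

test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- cohort_config(n_patients = 50, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- cohort_config(n_patients = 50, seed = 12)
  expect_false(identical(generate_cohort(cfg)$features,
                         generate_cohort(cfg2)$features))
})

test_that("confounder correlation targets are realized within tolerance", {
  co <- generate_cohort(cohort_config(n_patients = 1000, seed = 21))
  pm <- co$meta[!duplicated(co$meta$patient_id), ]
  pf <- patient_features(co)
  r_energy <- cor(pm$lvmi, pf$X[, feature_index("V4", "qrs_energy")])
  r_burden <- cor(pm$lvmi, pm$scar_burden)
  expect_lt(abs(r_energy - 0.6), 0.1)
  expect_lt(abs(r_burden - 0.4), 0.1)
})

test_that("infeasible correlation targets are rejected", {
  expect_error(cohort_config(r_lvmi_qrs_energy = 1), "correlation")
  expect_error(cohort_config(r_lvmi_burden = -1.2), "correlation")
  expect_error(cohort_config(scar_prevalence = cbind(c(0, 0.5, 0.5))),
               "prevalence")
})

test_that("a null cohort shows no scar/no-scar feature differences", {
  em <- default_scar_effects()
  em$effect <- 0
  co <- generate_cohort(cohort_config(n_patients = 150, n_clusters = 1,
                                      scar_effect_map = em, seed = 31))
  # patient-level rows: replicate ECGs share labels and would inflate the
  # nominal type-I rate of an independence-assuming t-test
  pf <- patient_features(co)
  wc <- welch_compare(pf$X, pf$meta$label_basal)
  frac_sig <- mean(wc$p_value < 0.05, na.rm = TRUE)
  # p-values roughly uniform: about 5% below 0.05 across 276 features
  expect_lt(frac_sig, 0.12)
})

test_that("planted clusters are recoverable by an independent clustering oracle", {
  em <- default_scar_effects()
  em$effect <- 0
  co <- generate_cohort(cohort_config(n_patients = 200, n_clusters = 2,
                                      cluster_separation = 6,
                                      scar_effect_map = em, seed = 41))
  pf <- patient_features(co)
  km <- with_seed_test(42, stats::kmeans(scale(pf$X), 2, nstart = 10))
  expect_gte(adjusted_rand(km$cluster, pf$meta$cluster), 0.95)
})

test_that("increasing a planted effect increases its Welch t statistic", {
  t_for_effect <- function(eff) {
    em <- default_scar_effects()
    em$effect[em$lead == "aVR" & em$feature == "q_amplitude"] <- eff
    co <- generate_cohort(cohort_config(n_patients = 400, n_clusters = 1,
                                        scar_effect_map = em, seed = 51))
    wc <- welch_compare(co$features, co$meta$label_basal)
    abs(wc$t[wc$feature == "aVR_q_amplitude"])
  }
  ts <- vapply(c(-0.5, -1.5, -3.0), t_for_effect, numeric(1))
  expect_true(all(diff(ts) > 0))
})
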