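#' Parametric single-beat shape
#'
#' Describes one heartbeat in one lead as a sum of Gaussian-shaped Q, R, S
#' and T deflections on a piecewise baseline (constant ST offset over the ST
#' segment, linear drift over the TP segment). The Gaussian form gives
#' closed-form amplitudes and quadrature-exact energies and areas, so beats
#' built this way carry analytically known feature values that are
#' independent of the feature extractor.
#'
#' Each of `q`, `r`, `s`, `t` is a list with `amplitude` (mV, signed),
#' `center` (s) and `width` (s, the Gaussian sigma). Wave supports are taken
#' as center +/- 3 widths; the QRS window runs from the start of the Q
#' support to the end of the S support, the T window is the T support, and
#' the TP segment runs from T offset to the end of the beat.
#'
#' @param q,r,s,t Per-wave shape lists (`amplitude`, `center`, `width`).
#' @param st_level Constant ST-segment offset from baseline, mV.
#' @param tp_slope Linear baseline drift over the TP segment, mV/s.
#' @param baseline Resting potential, mV.
#' @param sampling_rate Sampling rate, Hz.
#' @param beat_duration Beat length, s; the next P onset is placed at its end.
#' @param overlap_tol Tolerated overlap (s) between the S and T supports
#'   before the parameters are rejected as invalid.
#' @return An object of class `beat_shape_params`.
#' @export
beat_shape_params <- function(q = list(amplitude = -0.10, center = 0.200, width = 0.012),
                              r = list(amplitude = 1.00, center = 0.240, width = 0.016),
                              s = list(amplitude = -0.25, center = 0.285, width = 0.013),
                              t = list(amplitude = 0.30, center = 0.500, width = 0.040),
                              st_level = 0,
                              tp_slope = 0,
                              baseline = 0,
                              sampling_rate = 1000,
                              beat_duration = 0.85,
                              overlap_tol = 0.005) {
  p <- list(q = q, r = r, s = s, t = t, st_level = st_level,
            tp_slope = tp_slope, baseline = baseline,
            sampling_rate = sampling_rate, beat_duration = beat_duration,
            overlap_tol = overlap_tol)
  class(p) <- "beat_shape_params"
  validate_beat_params(p)
  p
}

validate_beat_params <- function(p) {
  for (w in c("q", "r", "s", "t")) {
    wave <- p[[w]]
    if (!all(c("amplitude", "center", "width") %in% names(wave))) {
      stopf("invalid parameters: wave '%s' must have amplitude, center, width", w)
    }
    if (!is_number(wave$width) || wave$width <= 0) {
      stopf("invalid parameters: wave '%s' width must be > 0", w)
    }
  }
  if (!is_number(p$sampling_rate) || p$sampling_rate <= 0) {
    stopf("invalid parameters: sampling_rate must be > 0")
  }
  cen <- vapply(p[c("q", "r", "s", "t")], `[[`, numeric(1), "center")
  if (any(diff(cen) <= 0)) {
    stopf("invalid parameters: wave centers must be strictly ordered Q < R < S < T")
  }
  sup <- beat_support(p)
  if (sup$qrs_on < 0 || sup$t_off >= p$beat_duration) {
    stopf("invalid parameters: wave supports must lie inside the beat duration")
  }
  t_on_raw <- p$t$center - 3 * p$t$width
  if (t_on_raw < sup$qrs_off - p$overlap_tol) {
    stopf("invalid parameters: S and T wave supports overlap beyond tolerance")
  }
  invisible(p)
}

# continuous-time wave supports (seconds)
beat_support <- function(p) {
  list(
    qrs_on = p$q$center - 3 * p$q$width,
    qrs_off = p$s$center + 3 * p$s$width,
    t_on = max(p$t$center - 3 * p$t$width, p$s$center + 3 * p$s$width),
    t_off = p$t$center + 3 * p$t$width
  )
}

# evaluate the continuous beat model at times tt (seconds); `bounds` places
# the piecewise-baseline breakpoints (defaults to the analytic supports, but
# the generator snaps them to the emitted fiducial times so that the
# discontinuities sit exactly on the native sampling grid)
beat_signal <- function(p, tt, bounds = NULL) {
  sup <- beat_support(p)
  b <- bounds %||% list(st_on = sup$qrs_off, st_off = sup$t_on, tp_on = sup$t_off)
  v <- rep(p$baseline, length(tt))
  for (w in c("q", "r", "s", "t")) {
    wave <- p[[w]]
    if (wave$amplitude != 0) {
      v <- v + wave$amplitude * exp(-(tt - wave$center)^2 / (2 * wave$width^2))
    }
  }
  v <- v + p$st_level * (tt >= b$st_on & tt < b$st_off)
  v <- v + p$tp_slope * pmax(tt - b$tp_on, 0)
  v
}

fiducial_bounds <- function(fb) {
  fs <- fb$sampling_rate
  list(st_on = fb$qrs_offset / fs, st_off = fb$t_onset / fs,
       tp_on = fb$t_offset / fs)
}

#' Generate one annotated synthetic beat
#'
#' Samples the parametric beat at its native sampling rate, derives exact
#' fiducial indices from the known wave supports, and computes the analytic
#' values of all 23 per-lead features. Amplitudes come from the continuous
#' model evaluated at the peaks; energies, areas and slopes from dense
#' quadrature/least squares at `oversample` times the native rate; durations
#' are exact functions of the emitted fiducial indices.
#'
#' @param params A `beat_shape_params` object.
#' @param noise_sd Additive white noise SD in mV (0 for a clean beat).
#' @param seed Optional integer seed for the noise.
#' @param oversample Densification factor for the analytic quadrature.
#' @return A list with `samples` (mV), `time` (s), `fiducials`
#'   (a `fiducial_beat`, 0-based indices), and `features` (named 23-vector
#'   of analytic values, valid for the noise-free beat).
#' @export
generate_beat <- function(params, noise_sd = 0, seed = NULL, oversample = 16L) {
  stopifnot(inherits(params, "beat_shape_params"))
  validate_beat_params(params)
  if (!is_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  fs <- params$sampling_rate
  n <- round(params$beat_duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  sup <- beat_support(params)
  idx <- function(x) as.integer(round(x * fs))
  fb <- fiducial_beat(
    qrs_onset = idx(sup$qrs_on),
    q_peak = if (params$q$amplitude != 0) idx(params$q$center) else NA_integer_,
    r_peak = idx(params$r$center),
    s_peak = if (params$s$amplitude != 0) idx(params$s$center) else NA_integer_,
    qrs_offset = idx(sup$qrs_off),
    t_onset = idx(sup$t_on),
    t_peak = idx(params$t$center),
    t_offset = idx(sup$t_off),
    next_p_onset = n,
    sampling_rate = fs
  )
  samples <- beat_signal(params, tt, bounds = fiducial_bounds(fb))
  if (noise_sd > 0) {
    samples <- samples + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  feats <- analytic_beat_features(params, fb, oversample = oversample)
  list(samples = samples, time = tt, fiducials = fb, features = feats)
}

# Analytic feature values for a noise-free parametric beat.
#
# Point-evaluated features (amplitudes, slopes, ST deviation, the baseline
# median) are closed-form: the feature definitions operate on the native
# sample times, where the continuous model is known exactly. Integral
# features (energy, signed AUC) are computed by dense trapezoid quadrature
# at `oversample` times the native rate over the same time span the
# discrete definition covers, so they are an independent check of the
# extractor's native-resolution quadrature.
analytic_beat_features <- function(params, fb, oversample = 16L) {
  fs <- params$sampling_rate
  dfs <- fs * oversample
  v_at <- function(tt) beat_signal(params, tt, bounds = fiducial_bounds(fb))
  # native sample times of the half-open window [i0, i1): i0 .. i1-1
  tn_ho <- function(i0, i1) if (i1 <= i0) numeric(0) else (i0:(i1 - 1L)) / fs
  tn_cl <- function(i0, i1) (i0:i1) / fs
  # dense grid spanning exactly the discrete half-open window [i0, i1-1]
  td_ho <- function(i0, i1) {
    if (i1 - i0 < 2L) return(numeric(0))
    seq(i0 * oversample, (i1 - 1L) * oversample) / dfs
  }

  baseline <- stats::median(v_at(tn_ho(fb$t_offset, fb$next_p_onset)))

  peak_amp <- function(i) if (is.na(i)) 0 else v_at(i / fs) - baseline
  seg_dur <- function(i0, i1) (i1 - i0) / fs
  seg_energy <- function(i0, i1) {
    trapz((v_at(td_ho(i0, i1)) - baseline)^2, 1 / dfs)
  }
  seg_auc <- function(i0, i1) {
    trapz(v_at(td_ho(i0, i1)) - baseline, 1 / dfs)
  }
  seg_slope <- function(tt) ls_slope(tt, v_at(tt))

  st_mid <- (fb$qrs_offset + fb$t_onset) %/% 2L
  qrs_dense <- v_at(seq((fb$qrs_onset + 1L) * oversample,
                        (fb$qrs_offset - 1L) * oversample) / dfs)
  canonical <- sum(!is.na(c(fb$q_peak, fb$r_peak, fb$s_peak)))
  frag <- frag_count_core(qrs_dense, abs(peak_amp(fb$r_peak)), canonical,
                          threshold = 0.05)

  feats <- c(
    q_amplitude = peak_amp(fb$q_peak),
    r_amplitude = peak_amp(fb$r_peak),
    s_amplitude = peak_amp(fb$s_peak),
    qrs_duration = seg_dur(fb$qrs_onset, fb$qrs_offset),
    qrs_nonterminal_duration = seg_dur(fb$qrs_onset, fb$r_peak),
    qrs_terminal_duration = seg_dur(fb$r_peak, fb$qrs_offset),
    r_upslope = seg_slope(tn_cl(fb$qrs_onset, fb$r_peak)),
    r_downslope = seg_slope(tn_ho(fb$r_peak, fb$qrs_offset)),
    qrs_fragmentation = frag,
    qrs_energy = seg_energy(fb$qrs_onset, fb$qrs_offset),
    qrs_auc = seg_auc(fb$qrs_onset, fb$qrs_offset),
    st_duration = seg_dur(fb$qrs_offset, fb$t_onset),
    st_deviation = v_at(st_mid / fs) - baseline,
    st_slope = seg_slope(tn_ho(fb$qrs_offset, fb$t_onset)),
    t_amplitude = v_at(fb$t_peak / fs) - baseline,
    t_duration = seg_dur(fb$t_onset, fb$t_offset),
    t_inversion = t_sign(v_at(fb$t_peak / fs) - baseline),
    t_upslope = seg_slope(tn_cl(fb$t_onset, fb$t_peak)),
    t_downslope = seg_slope(tn_ho(fb$t_peak, fb$t_offset)),
    t_energy = seg_energy(fb$t_onset, fb$t_offset),
    t_auc = seg_auc(fb$t_onset, fb$t_offset),
    tp_slope = seg_slope(tn_ho(fb$t_offset, fb$next_p_onset)),
    tp_duration = seg_dur(fb$t_offset, fb$next_p_onset)
  )
  feats[feature_registry()$name]
}

#' Default per-lead beat shapes for a synthetic 12-lead ECG
#'
#' Plausible resting-morphology parameters per lead (dominant R in lateral
#' leads, negative complexes in aVR, rS pattern in V1-V2). Each lead gets
#' its own independent shape; no dipole model is simulated because the
#' downstream pipeline consumes per-lead features only.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @return Named list of `beat_shape_params`, one per standard lead.
#' @export
default_lead_params <- function(sampling_rate = 1000) {
  amp <- list(
    I   = c(q = -0.06, r = 0.70, s = -0.15, t = 0.22),
    II  = c(q = -0.08, r = 1.00, s = -0.20, t = 0.30),
    III = c(q = -0.05, r = 0.45, s = -0.12, t = 0.12),
    aVR = c(q = -0.15, r = -0.60, s = -0.10, t = -0.22),
    aVL = c(q = -0.04, r = 0.35, s = -0.10, t = 0.10),
    aVF = c(q = -0.06, r = 0.70, s = -0.15, t = 0.20),
    V1  = c(q = -0.03, r = 0.25, s = -0.80, t = -0.10),
    V2  = c(q = -0.03, r = 0.45, s = -1.00, t = 0.35),
    V3  = c(q = -0.04, r = 0.70, s = -0.70, t = 0.40),
    V4  = c(q = -0.06, r = 1.20, s = -0.40, t = 0.38),
    V5  = c(q = -0.08, r = 1.10, s = -0.25, t = 0.32),
    V6  = c(q = -0.08, r = 0.90, s = -0.18, t = 0.26)
  )
  out <- lapply(amp, function(a) {
    beat_shape_params(
      q = list(amplitude = a[["q"]], center = 0.200, width = 0.012),
      r = list(amplitude = a[["r"]], center = 0.240, width = 0.016),
      s = list(amplitude = a[["s"]], center = 0.285, width = 0.013),
      t = list(amplitude = a[["t"]], center = 0.500, width = 0.040),
      sampling_rate = sampling_rate
    )
  })
  names(out) <- ecg_leads()
  out
}
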