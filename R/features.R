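#' Fiducial annotation of one beat in one lead
#'
#' Sample indices of the wave boundaries and peaks of a single heartbeat.
#' Indices are 0-based; segment boundaries delimit half-open windows
#' `[on, off)` and peaks are inclusive. `q_peak` and `s_peak` may be `NA`
#' when the wave is absent, in which case the corresponding amplitude is 0
#' and duration boundaries are unaffected.
#'
#' @param qrs_onset,q_peak,r_peak,s_peak,qrs_offset Depolarization indices.
#' @param t_onset,t_peak,t_offset Repolarization indices.
#' @param next_p_onset Index of the next P onset (end of the TP segment).
#' @param sampling_rate Sampling rate, Hz.
#' @return An object of class `fiducial_beat`.
#' @export
fiducial_beat <- function(qrs_onset, r_peak, qrs_offset,
                          t_onset, t_peak, t_offset, next_p_onset,
                          sampling_rate,
                          q_peak = NA_integer_, s_peak = NA_integer_) {
  fb <- list(
    qrs_onset = as.integer(qrs_onset), q_peak = as.integer(q_peak),
    r_peak = as.integer(r_peak), s_peak = as.integer(s_peak),
    qrs_offset = as.integer(qrs_offset), t_onset = as.integer(t_onset),
    t_peak = as.integer(t_peak), t_offset = as.integer(t_offset),
    next_p_onset = as.integer(next_p_onset),
    sampling_rate = as.numeric(sampling_rate)
  )
  class(fb) <- "fiducial_beat"
  fb
}

validate_fiducial_beat <- function(fb, n_samples = NULL, what = "beat") {
  need <- c("qrs_onset", "r_peak", "qrs_offset", "t_onset", "t_peak",
            "t_offset", "next_p_onset")
  vals <- unlist(fb[need], use.names = FALSE)
  if (anyNA(vals)) stopf("%s: required fiducials contain NA", what)
  ok <- fb$qrs_onset < fb$r_peak && fb$r_peak < fb$qrs_offset &&
    fb$qrs_offset <= fb$t_onset && fb$t_onset < fb$t_peak &&
    fb$t_peak < fb$t_offset && fb$t_offset < fb$next_p_onset
  if (!ok) {
    stopf("%s: fiducial ordering violated (need qrs_onset < r_peak < qrs_offset <= t_onset < t_peak < t_offset <= next_p_onset)",
          what)
  }
  if (!is.na(fb$q_peak) && !(fb$q_peak >= fb$qrs_onset && fb$q_peak < fb$r_peak)) {
    stopf("%s: q_peak outside [qrs_onset, r_peak)", what)
  }
  if (!is.na(fb$s_peak) && !(fb$s_peak > fb$r_peak && fb$s_peak <= fb$qrs_offset)) {
    stopf("%s: s_peak outside (r_peak, qrs_offset]", what)
  }
  if (!is.null(n_samples)) {
    if (fb$qrs_onset < 0 || fb$next_p_onset > n_samples) {
      stopf("%s: fiducial indices outside the signal (length %d)", what, n_samples)
    }
  }
  if (!is_number(fb$sampling_rate) || fb$sampling_rate <= 0) {
    stopf("%s: sampling_rate must be > 0", what)
  }
  invisible(fb)
}

# window helpers: fiducials are 0-based, R vectors 1-based
win_half_open <- function(samples, i0, i1) {
  if (i1 <= i0) return(numeric(0))
  samples[(i0 + 1L):i1]
}
win_times <- function(i0, i1, fs) {
  if (i1 <= i0) return(numeric(0))
  (i0:(i1 - 1L)) / fs
}

# features of a single beat; returns named 23-vector in registry order
beat_features <- function(samples, fb) {
  fs <- fb$sampling_rate
  baseline <- stats::median(win_half_open(samples, fb$t_offset, fb$next_p_onset))
  at <- function(i) samples[i + 1L]
  peak_amp <- function(i) if (is.na(i)) 0 else at(i) - baseline
  dur <- function(i0, i1) (i1 - i0) / fs
  slope_cl <- function(i0, i1) ls_slope((i0:i1) / fs, samples[(i0 + 1L):(i1 + 1L)])
  slope_ho <- function(i0, i1) ls_slope(win_times(i0, i1, fs), win_half_open(samples, i0, i1))
  energy <- function(i0, i1) trapz((win_half_open(samples, i0, i1) - baseline)^2, 1 / fs)
  auc <- function(i0, i1) trapz(win_half_open(samples, i0, i1) - baseline, 1 / fs)

  st_mid <- (fb$qrs_offset + fb$t_onset) %/% 2L
  t_amp <- at(fb$t_peak) - baseline

  c(
    q_amplitude = peak_amp(fb$q_peak),
    r_amplitude = peak_amp(fb$r_peak),
    s_amplitude = peak_amp(fb$s_peak),
    qrs_duration = dur(fb$qrs_onset, fb$qrs_offset),
    qrs_nonterminal_duration = dur(fb$qrs_onset, fb$r_peak),
    qrs_terminal_duration = dur(fb$r_peak, fb$qrs_offset),
    r_upslope = slope_cl(fb$qrs_onset, fb$r_peak),
    r_downslope = slope_ho(fb$r_peak, fb$qrs_offset),
    qrs_fragmentation = fragmentation_count(samples, fb),
    qrs_energy = energy(fb$qrs_onset, fb$qrs_offset),
    qrs_auc = auc(fb$qrs_onset, fb$qrs_offset),
    st_duration = dur(fb$qrs_offset, fb$t_onset),
    st_deviation = at(st_mid) - baseline,
    st_slope = slope_ho(fb$qrs_offset, fb$t_onset),
    t_amplitude = t_amp,
    t_duration = dur(fb$t_onset, fb$t_offset),
    t_inversion = t_sign(t_amp),
    t_upslope = slope_cl(fb$t_onset, fb$t_peak),
    t_downslope = slope_ho(fb$t_peak, fb$t_offset),
    t_energy = energy(fb$t_onset, fb$t_offset),
    t_auc = auc(fb$t_onset, fb$t_offset),
    tp_slope = slope_ho(fb$t_offset, fb$next_p_onset),
    tp_duration = dur(fb$t_offset, fb$next_p_onset)
  )
}

#' Count QRS fragmentation
#'
#' Number of local extrema strictly inside the QRS window beyond the
#' annotated Q/R/S deflections, after amplitude-threshold denoising: an
#' extremum only counts if it stands out from its neighbouring extrema by at
#' least `threshold` times the absolute R amplitude. Sub-threshold ripple is
#' cancelled pairwise, least-prominent pair first.
#'
#' @param samples Lead samples in mV.
#' @param fb A `fiducial_beat`.
#' @param threshold Prominence threshold as a fraction of |R amplitude|.
#' @return Integer count (0 for an unfragmented complex).
#' @export
fragmentation_count <- function(samples, fb, threshold = 0.05) {
  i0 <- fb$qrs_onset; i1 <- fb$qrs_offset
  if (i1 - i0 < 4L) return(0L)
  # strictly inside (qrs_onset, qrs_offset)
  y <- samples[(i0 + 2L):i1]
  baseline <- stats::median(win_half_open(samples, fb$t_offset, fb$next_p_onset))
  r_amp <- abs(samples[fb$r_peak + 1L] - baseline)
  canonical <- sum(!is.na(c(fb$q_peak, fb$r_peak, fb$s_peak)))
  frag_count_core(y, r_amp, canonical, threshold)
}

# extrema counting shared by the extractor (native samples) and the
# synthetic-beat oracle (dense grid): find interior turning points, cancel
# sub-threshold swings (threshold * |R amplitude|) pairwise, least-prominent
# first -- the window endpoints take part in the cancellation so stray
# unpaired ripple at the window edges is absorbed -- then count extrema in
# excess of the annotated Q/R/S deflections
frag_count_core <- function(y, r_amp, canonical, threshold) {
  d <- diff(y)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(0L)
  s <- sign(d[nz])
  ch <- which(diff(s) != 0)
  vals <- y[nz[ch] + 1L]
  tol <- threshold * r_amp
  seq_v <- c(y[1L], vals, y[length(y)])
  repeat {
    n <- length(seq_v)
    if (n < 3L) break
    sw <- abs(diff(seq_v))
    j <- which.min(sw)
    if (sw[j] >= tol) break
    if (j == 1L) {
      seq_v <- seq_v[-2L]
    } else if (j == n - 1L) {
      seq_v <- seq_v[-(n - 1L)]
    } else {
      seq_v <- seq_v[-c(j, j + 1L)]
    }
  }
  max(0L, length(seq_v) - 2L - canonical)
}

#' Extract the 23 per-lead features
#'
#' Computes the registry features for every annotated beat of one lead and
#' averages them arithmetically across beats. The per-beat baseline is the
#' median of the TP segment; amplitudes are the sample value at the peak
#' minus that baseline; energies and signed areas use the trapezoid rule at
#' native sampling; slopes are least-squares line fits over their
#' sub-window.
#'
#' @param samples Numeric vector of lead samples, mV.
#' @param beats List of `fiducial_beat` annotations (at least one).
#' @return Named numeric vector of length 23 in registry order.
#' @export
extract_lead_features <- function(samples, beats) {
  if (length(beats) == 0L) stopf("no beats supplied")
  if (inherits(beats, "fiducial_beat")) beats <- list(beats)
  per_beat <- vapply(seq_along(beats), function(i) {
    fb <- beats[[i]]
    validate_fiducial_beat(fb, n_samples = length(samples),
                           what = sprintf("beat %d", i))
    beat_features(samples, fb)
  }, numeric(nrow(feature_registry())))
  rowMeans(matrix(per_beat, nrow = nrow(feature_registry()),
                  dimnames = list(feature_registry()$name, NULL)))
}

#' Extract the 276-dimensional ECG feature vector
#'
#' Concatenates the 23 per-lead features of the 12 standard leads in
#' lead-major order (`ecg_feature_names()`).
#'
#' @param signals Named list of per-lead sample vectors; names must be
#'   exactly the 12 standard leads.
#' @param beats Named list (same leads) of lists of `fiducial_beat`.
#' @return Named numeric vector of length 276.
#' @export
extract_ecg_features <- function(signals, beats) {
  leads <- ecg_leads()
  missing <- setdiff(leads, names(signals))
  extra <- setdiff(names(signals), leads)
  if (length(missing) || length(extra)) {
    stopf("signals must contain exactly the 12 standard leads%s%s",
          if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
          if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")) else "")
  }
  if (anyDuplicated(names(signals))) {
    stopf("duplicate leads in signals: %s",
          paste(unique(names(signals)[duplicated(names(signals))]), collapse = ", "))
  }
  out <- unlist(lapply(leads, function(ld) {
    if (is.null(beats[[ld]])) stopf("no beat annotations for lead %s", ld)
    extract_lead_features(signals[[ld]], beats[[ld]])
  }), use.names = FALSE)
  names(out) <- ecg_feature_names()
  out
}
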