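#' Simulate a multi-beat annotated 12-lead ECG
#'
#' Concatenates `n_beats` parametric beats per lead (each lead with its own
#' shape, optionally jittered per beat) and returns the per-lead sample
#' vectors together with per-beat fiducial annotations, ready for
#' [extract_ecg_features()].
#'
#' @param lead_params Named list of `beat_shape_params`, one per standard
#'   lead (default [default_lead_params()]).
#' @param n_beats Number of beats per lead.
#' @param noise_sd Additive white noise SD in mV.
#' @param amplitude_jitter Relative SD of per-beat amplitude scaling.
#' @param seed Integer seed.
#' @return List with `signals` (named list of sample vectors), `beats`
#'   (named list of lists of `fiducial_beat`), `sampling_rate`.
#' @export
simulate_ecg <- function(lead_params = default_lead_params(), n_beats = 8L,
                         noise_sd = 0.01, amplitude_jitter = 0.05,
                         seed = 1L) {
  stopifnot(setequal(names(lead_params), ecg_leads()))
  with_seed(seed, {
    signals <- list()
    beats <- list()
    for (ld in ecg_leads()) {
      p <- lead_params[[ld]]
      n_per <- round(p$beat_duration * p$sampling_rate)
      sig <- numeric(0)
      fbs <- list()
      for (b in seq_len(n_beats)) {
        pb <- p
        if (amplitude_jitter > 0) {
          k <- 1 + stats::rnorm(1, sd = amplitude_jitter)
          for (w in c("q", "r", "s", "t")) pb[[w]]$amplitude <- p[[w]]$amplitude * k
        }
        g <- generate_beat(pb, noise_sd = noise_sd)
        off <- length(sig)
        fb <- g$fiducials
        for (f in c("qrs_onset", "q_peak", "r_peak", "s_peak", "qrs_offset",
                    "t_onset", "t_peak", "t_offset", "next_p_onset")) {
          if (!is.na(fb[[f]])) fb[[f]] <- fb[[f]] + off
        }
        sig <- c(sig, g$samples)
        fbs[[b]] <- fb
      }
      signals[[ld]] <- sig
      beats[[ld]] <- fbs
    }
    list(signals = signals, beats = beats,
         sampling_rate = lead_params[[1]]$sampling_rate)
  })
}

#' Write / read 12-lead waveforms as CSV
#'
#' One column per lead (mV), rows are samples at the shared sampling rate.
#'
#' @param signals Named list of equal-length sample vectors.
#' @param path CSV path.
#' @export
write_waveform_csv <- function(signals, path) {
  utils::write.csv(as.data.frame(signals, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.list(df)
}

#' Write / read fiducial annotations as JSON
#'
#' Schema: `{"sampling_rate_hz": <Hz>, "leads": {"<lead>": {"beats":
#' [{"qrs_onset": ..., "q_peak": ..., ...}]}}}` with 0-based sample
#' indices; absent Q/S peaks are `null`.
#'
#' @param beats Named list (per lead) of lists of `fiducial_beat`.
#' @param sampling_rate Sampling rate in Hz.
#' @param path JSON path.
#' @export
write_fiducial_json <- function(beats, sampling_rate, path) {
  fields <- c("qrs_onset", "q_peak", "r_peak", "s_peak", "qrs_offset",
              "t_onset", "t_peak", "t_offset", "next_p_onset")
  obj <- list(
    sampling_rate_hz = sampling_rate,
    leads = lapply(beats, function(lead_beats) {
      list(beats = lapply(lead_beats, function(fb) {
        vals <- lapply(fields, function(f) {
          v <- fb[[f]]
          if (is.null(v) || is.na(v)) NULL else as.integer(v)
        })
        names(vals) <- fields
        vals
      }))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_fiducial_json
#' @export
read_fiducial_json <- function(path) {
  obj <- jsonlite::read_json(path)
  fs <- obj$sampling_rate_hz
  if (is.null(fs)) stopf("fiducial JSON lacks sampling_rate_hz")
  beats <- lapply(obj$leads, function(lead) {
    lapply(lead$beats, function(b) {
      fiducial_beat(
        qrs_onset = b$qrs_onset, r_peak = b$r_peak,
        qrs_offset = b$qrs_offset, t_onset = b$t_onset,
        t_peak = b$t_peak, t_offset = b$t_offset,
        next_p_onset = b$next_p_onset, sampling_rate = fs,
        q_peak = b$q_peak %||% NA_integer_,
        s_peak = b$s_peak %||% NA_integer_
      )
    })
  })
  list(beats = beats, sampling_rate = fs)
}

#' Extract features from waveform CSV plus fiducial JSON
#'
#' @param waveform_csv Path to a per-lead waveform CSV.
#' @param fiducial_json Path to the matching fiducial annotation JSON.
#' @return Named length-276 feature vector.
#' @export
extract_from_files <- function(waveform_csv, fiducial_json) {
  signals <- read_waveform_csv(waveform_csv)
  ann <- read_fiducial_json(fiducial_json)
  extract_ecg_features(signals, ann$beats)
}
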