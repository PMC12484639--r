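#' Standard 12-lead names in canonical order
#'
#' Order is fixed (limb, augmented, precordial) and defines the lead-major
#' layout of the 276-dimensional ECG feature vector.
#'
#' @return Character vector of length 12.
#' @export
ecg_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' The 23-feature per-lead registry
#'
#' Each lead of a fiducial-annotated ECG is summarised by 23 features of
#' ventricular depolarization and repolarization: amplitudes, durations and
#' slopes of the QRS complex and T wave, energy and signed area under the
#' curve of both, ST-segment level and slope, TP-segment slope and duration,
#' a QRS fragmentation count, and a T-inversion sign indicator.
#'
#' The `component` column partitions features into the five ECG components
#' Q, QRS, ST, T, TP used when aggregating Shapley importances.
#'
#' @return A data.frame with columns `name`, `unit`, `component`.
#' @export
feature_registry <- function() {
  data.frame(
    name = c(
      "q_amplitude", "r_amplitude", "s_amplitude",
      "qrs_duration", "qrs_nonterminal_duration", "qrs_terminal_duration",
      "r_upslope", "r_downslope", "qrs_fragmentation",
      "qrs_energy", "qrs_auc",
      "st_duration", "st_deviation", "st_slope",
      "t_amplitude", "t_duration", "t_inversion",
      "t_upslope", "t_downslope", "t_energy", "t_auc",
      "tp_slope", "tp_duration"
    ),
    unit = c(
      "mV", "mV", "mV",
      "s", "s", "s",
      "mV/s", "mV/s", "count",
      "mV^2*s", "mV*s",
      "s", "mV", "mV/s",
      "mV", "s", "sign",
      "mV/s", "mV/s", "mV^2*s", "mV*s",
      "mV/s", "s"
    ),
    component = c(
      "Q", "QRS", "QRS",
      "QRS", "QRS", "QRS",
      "QRS", "QRS", "QRS",
      "QRS", "QRS",
      "ST", "ST", "ST",
      "T", "T", "T",
      "T", "T", "T", "T",
      "TP", "TP"
    ),
    stringsAsFactors = FALSE
  )
}

#' Names of the 276 lead-major ECG features
#'
#' Lead-major order: all 23 features of lead I, then lead II, and so on
#' through V6; within a lead, registry order. Names are `<lead>_<feature>`,
#' e.g. `aVR_q_amplitude`.
#'
#' @return Character vector of length 276.
#' @export
ecg_feature_names <- function() {
  reg <- feature_registry()$name
  as.vector(t(outer(ecg_leads(), reg, paste, sep = "_")))
}

#' Index of a (lead, feature) pair in the 276-vector
#'
#' @param lead Lead name, e.g. `"V4"`.
#' @param feature Registry feature name, e.g. `"qrs_energy"`.
#' @return Integer position in `ecg_feature_names()`.
#' @export
feature_index <- function(lead, feature) {
  leads <- ecg_leads()
  reg <- feature_registry()$name
  li <- match(lead, leads)
  fi <- match(feature, reg)
  if (any(is.na(li))) stop("unknown lead: ", paste(lead[is.na(li)], collapse = ", "))
  if (any(is.na(fi))) stop("unknown feature: ", paste(feature[is.na(fi)], collapse = ", "))
  (li - 1L) * nrow(feature_registry()) + fi
}

# stable fingerprint of the registry so persisted models can refuse
# feature tables produced under a different layout
registry_hash <- function() {
  reg <- feature_registry()
  txt <- paste(c(ecg_leads(), reg$name, reg$unit, reg$component), collapse = "|")
  # small polynomial rolling hash; no digest dependency
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
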