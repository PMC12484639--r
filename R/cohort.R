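#' Default regional scar signatures planted by the cohort generator
#'
#' Effect directions follow the reported regional ECG markers of LV scar in
#' hypertrophic cardiomyopathy: deeper Q waves (aVR, I, V1), prolonged
#' intrinsicoid deflection and less negative QRS area for basal scar;
#' lateral-precordial T-amplitude loss for mid scar; widespread precordial
#' T-wave inversion, positive QRS area and TP-slope change for apical scar.
#' Magnitudes are in units of the between-patient feature SD and are sized
#' so each region carries a strong but not trivially separable multivariate
#' signal; they are configuration, not assertions about clinical effect
#' sizes.
#'
#' @return data.frame with columns `region`, `lead`, `feature`, `effect`.
#' @export
default_scar_effects <- function() {
  eff <- rbind(
    c("basal", "aVR", "q_amplitude", -3.0),
    c("basal", "I", "q_amplitude", -2.2),
    c("basal", "V1", "q_amplitude", -2.2),
    c("basal", "aVR", "qrs_nonterminal_duration", 1.5),
    c("basal", "V1", "qrs_auc", 1.5),
    c("basal", "V2", "t_amplitude", -1.2),
    c("mid", "V4", "t_amplitude", -3.0),
    c("mid", "V5", "t_amplitude", -2.2),
    c("mid", "V6", "t_amplitude", -2.2),
    c("mid", "aVL", "t_amplitude", -1.2),
    c("mid", "V5", "t_energy", 1.5),
    c("apical", "V2", "t_amplitude", -2.2),
    c("apical", "V3", "t_amplitude", -2.2),
    c("apical", "V4", "t_amplitude", -3.0),
    c("apical", "V5", "t_amplitude", -2.2),
    c("apical", "V6", "t_amplitude", -1.5),
    c("apical", "V4", "qrs_auc", 1.5),
    c("apical", "V4", "tp_slope", 1.2)
  )
  data.frame(region = eff[, 1], lead = eff[, 2], feature = eff[, 3],
             effect = as.numeric(eff[, 4]), stringsAsFactors = FALSE)
}

# physical location/scale per registry feature (same for all leads), used to
# map standardized latent features onto interpretable ECG units
feature_scales <- function() {
  data.frame(
    name = feature_registry()$name,
    loc = c(-0.10, 1.00, -0.30, 0.090, 0.050, 0.040, 20, -22, 0.3,
            15.0, 1.5, 0.080, 0.03, 0.3, 0.25, 0.180, 0, 3.0, -3.2,
            8.0, 25.0, 0.1, 0.230),
    scale = c(0.15, 0.40, 0.20, 0.015, 0.012, 0.012, 8, 9, 0.6,
              8.0, 8.0, 0.020, 0.08, 0.8, 0.30, 0.040, 1, 1.2, 1.3,
              4.0, 12.0, 0.4, 0.040),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure of a generated cohort: latent patient
#' clusters, per-region scar prevalence (optionally per cluster), regional
#' scar signatures on specific (lead, feature) pairs, and confounder
#' couplings between LV mass index, QRS energy in V4, and scar burden.
#'
#' @param n_patients Number of patients.
#' @param n_clusters Number of latent patient clusters (>= 1).
#' @param cluster_separation Pairwise Euclidean distance between cluster
#'   means, in per-feature SD (z-score) units.
#' @param scar_prevalence Numeric matrix with rownames `basal`, `mid`,
#'   `apical` and one column per cluster (values in (0,1)); a vector or
#'   single column is recycled across clusters. The defaults give the two
#'   clusters distinct scar prevalences, emulating patient subgroups with
#'   different scar burden.
#' @param scar_effect_map data.frame like [default_scar_effects()].
#' @param cluster_effect_sign Per-cluster multiplier applied to planted
#'   effects (recycled). The default `c(1, 1)` expresses the same signature
#'   in every cluster; `c(1, -1)` makes the signature cluster-specific
#'   (subgroup-dependent ECG expression of scar), the heterogeneity regime
#'   probed by the ablation study.
#' @param cluster_noise_scale Per-cluster multiplier on the within-cluster
#'   feature SD (recycled across clusters). Values far from 1 emulate
#'   morphology subgroups with very different feature variability (e.g.
#'   low- versus high-voltage ECGs); planted effects scale with their
#'   cluster so the signature stays proportional to the subgroup's own
#'   variability.
#' @param effect_expression_prob Probability that a scar-positive patient
#'   expresses each individual signature component, independently per
#'   component. Expressed components carry magnitude
#'   `effect / effect_expression_prob`, so the population-mean shift equals
#'   the nominal effect while individual patients show patchy,
#'   patient-specific signatures (scar patients form a diffuse shell rather
#'   than a tight secondary cluster in feature space).
#' @param r_lvmi_qrs_energy Target Pearson correlation between LVMI and QRS
#'   energy in lead V4.
#' @param r_lvmi_burden Target Pearson correlation between LVMI and scar
#'   burden.
#' @param ecgs_per_patient `c(mean, sd)` of the per-patient ECG count,
#'   drawn from a clipped normal with minimum 1.
#' @param ecg_noise_sd Within-patient (between-ECG) feature noise, SD units.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 600,
                          n_clusters = 2,
                          cluster_separation = 6,
                          scar_prevalence = cbind(c(basal = 0.55, mid = 0.50, apical = 0.45),
                                                  c(basal = 0.20, mid = 0.18, apical = 0.15)),
                          scar_effect_map = default_scar_effects(),
                          cluster_effect_sign = c(1, 1),
                          cluster_noise_scale = 1,
                          effect_expression_prob = 0.6,
                          r_lvmi_qrs_energy = 0.6,
                          r_lvmi_burden = 0.4,
                          ecgs_per_patient = c(mean = 3, sd = 2),
                          ecg_noise_sd = 0.3,
                          seed = 1L) {
  if (!is_count(n_patients)) stopf("n_patients must be a positive integer")
  if (!is_count(n_clusters)) stopf("n_clusters must be >= 1")
  if (!is_number(cluster_separation) || cluster_separation < 0) {
    stopf("cluster_separation must be >= 0")
  }
  prev <- scar_prevalence
  if (is.null(dim(prev))) prev <- matrix(prev, nrow = 3, ncol = 1,
                                         dimnames = list(names(prev), NULL))
  if (is.null(rownames(prev)) || !setequal(rownames(prev), scar_regions())) {
    rownames(prev) <- scar_regions()
  }
  prev <- prev[scar_regions(), , drop = FALSE]
  prev <- prev[, rep_len(seq_len(ncol(prev)), n_clusters), drop = FALSE]
  if (any(prev <= 0 | prev >= 1)) stopf("scar prevalences must lie in (0, 1)")
  for (r in c(r_lvmi_qrs_energy, r_lvmi_burden)) {
    if (!is_number(r) || abs(r) >= 1) {
      stopf("infeasible correlation target: |r| must be < 1")
    }
  }
  if (!is_number(effect_expression_prob) || effect_expression_prob <= 0 ||
      effect_expression_prob > 1) {
    stopf("effect_expression_prob must lie in (0, 1]")
  }
  stopifnot(is.data.frame(scar_effect_map),
            all(c("region", "lead", "feature", "effect") %in% names(scar_effect_map)))
  # validates lead/feature names
  invisible(feature_index(scar_effect_map$lead, scar_effect_map$feature))
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_clusters = as.integer(n_clusters),
    cluster_separation = cluster_separation,
    scar_prevalence = prev,
    scar_effect_map = scar_effect_map,
    cluster_effect_sign = rep_len(cluster_effect_sign, n_clusters),
    cluster_noise_scale = rep_len(cluster_noise_scale, n_clusters),
    effect_expression_prob = effect_expression_prob,
    r_lvmi_qrs_energy = r_lvmi_qrs_energy,
    r_lvmi_burden = r_lvmi_burden,
    ecgs_per_patient = c(mean = unname(ecgs_per_patient[1]),
                         sd = unname(ecgs_per_patient[2])),
    ecg_noise_sd = ecg_noise_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' The three LV regions with scar labels
#' @return `c("basal", "mid", "apical")`
#' @export
scar_regions <- function() c("basal", "mid", "apical")

#' Generate a synthetic patient cohort in ECG feature space
#'
#' Draws a cohort with planted ground truth: latent patient clusters with a
#' guaranteed pairwise mean separation, per-region scar labels at the
#' configured (per-cluster) prevalence, regional scar effects added to the
#' configured (lead, feature) pairs of scar-positive patients, and a
#' Gaussian-copula coupling that realises the configured Pearson
#' correlations of LVMI with QRS energy in V4 and with scar burden. Each
#' patient contributes one or more ECG rows (patient value plus
#' within-patient noise); features are returned on physical ECG scales.
#'
#' The T-inversion indicator is derived as the sign of the same lead's
#' T amplitude after all effects are applied, so planted T-amplitude
#' effects flip it coherently.
#'
#' @param config A `cohort_config`.
#' @return A list of class `ecg_cohort`: `features` (ECG-by-276 matrix,
#'   physical units), `meta` (data.frame with `ecg_id`, `patient_id`,
#'   `cluster`, `lvmi`, `age`, `sex`, `scar_burden`, `label_basal`,
#'   `label_mid`, `label_apical`), and `truth` (cluster centers in z-space,
#'   per-patient cluster ids, applied effect list).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  d <- length(ecg_feature_names())
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    K <- cfg$n_clusters

    # cluster means: scaled orthonormal directions -> exact pairwise
    # separation cfg$cluster_separation in z units
    centers <- matrix(0, K, d)
    if (K > 1L) {
      A <- matrix(stats::rnorm(d * K), d, K)
      Q <- qr.Q(qr(A))
      centers <- t(Q) * (cfg$cluster_separation / sqrt(2))
    }
    cluster <- sample.int(K, n, replace = TRUE)

    # confounders via Gaussian copula
    g_lvmi <- stats::rnorm(n)
    lvmi <- exp(log(110) + 0.25 * g_lvmi)
    age <- round(stats::rnorm(n, 52, 12))
    sex <- stats::rbinom(n, 1, 0.5)
    rb <- cfg$r_lvmi_burden
    b_lat <- rb * g_lvmi + sqrt(1 - rb^2) * stats::rnorm(n)
    scar_burden <- round(0.4 * stats::pnorm(b_lat), 4)

    # regional labels thresholded from the burden latent at per-cluster
    # prevalence
    lambda <- 0.6
    labels <- sapply(scar_regions(), function(rg) {
      u <- lambda * b_lat + sqrt(1 - lambda^2) * stats::rnorm(n)
      thr <- stats::qnorm(1 - cfg$scar_prevalence[rg, cluster])
      as.integer(u > thr)
    })

    # patient-level standardized features; per-cluster noise scale
    nsc <- cfg$cluster_noise_scale[cluster]
    X <- centers[cluster, , drop = FALSE] +
      matrix(stats::rnorm(n * d), n, d) * nsc

    # LVMI <-> QRS energy (V4) coupling
    re <- cfg$r_lvmi_qrs_energy
    j_energy <- feature_index("V4", "qrs_energy")
    X[, j_energy] <- centers[cluster, j_energy] +
      re * g_lvmi + sqrt(1 - re^2) * stats::rnorm(n)

    # planted regional effects, modulated per cluster; each scar patient
    # expresses each signature component with probability p at magnitude
    # effect / p, keeping the population-mean shift at the nominal effect
    em <- cfg$scar_effect_map
    sgn <- cfg$cluster_effect_sign
    p_exp <- cfg$effect_expression_prob
    for (i in seq_len(nrow(em))) {
      j <- feature_index(em$lead[i], em$feature[i])
      on <- labels[, em$region[i]] == 1L
      expressed <- stats::rbinom(sum(on), 1, p_exp)
      X[on, j] <- X[on, j] +
        (em$effect[i] / p_exp) * expressed * sgn[cluster[on]] * nsc[on]
    }

    # expand to ECG rows
    m <- pmax(1L, as.integer(round(stats::rnorm(
      n, cfg$ecgs_per_patient["mean"], cfg$ecgs_per_patient["sd"]))))
    pid <- rep(seq_len(n), m)
    E <- X[pid, , drop = FALSE] +
      matrix(stats::rnorm(length(pid) * d, sd = cfg$ecg_noise_sd),
             length(pid), d) * nsc[pid]

    # map to physical scales
    sc <- feature_scales()
    # lead-major layout: within each lead block, registry order
    loc <- rep(sc$loc, 12)
    scl <- rep(sc$scale, 12)
    F <- sweep(sweep(E, 2, scl, `*`), 2, loc, `+`)
    colnames(F) <- ecg_feature_names()

    # derived sign indicator follows the realized T amplitude
    for (ld in ecg_leads()) {
      F[, feature_index(ld, "t_inversion")] <-
        sign(F[, feature_index(ld, "t_amplitude")])
    }
    # fragmentation is a count
    fidx <- feature_index(rep(ecg_leads(), each = 1), rep("qrs_fragmentation", 12))
    F[, fidx] <- pmax(0, round(F[, fidx]))

    meta <- data.frame(
      ecg_id = seq_along(pid),
      patient_id = pid,
      cluster = cluster[pid],
      lvmi = lvmi[pid],
      age = age[pid],
      sex = sex[pid],
      scar_burden = scar_burden[pid],
      label_basal = labels[pid, "basal"],
      label_mid = labels[pid, "mid"],
      label_apical = labels[pid, "apical"]
    )
    out <- list(
      features = F,
      meta = meta,
      truth = list(centers = centers, cluster = cluster,
                   effects = em, effect_sign = sgn,
                   patient_labels = labels)
    )
    class(out) <- "ecg_cohort"
    out
  })
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("ecg_cohort: %d ECGs from %d patients, %d features\n",
              nrow(x$features), length(unique(x$meta$patient_id)),
              ncol(x$features)))
  prev <- colMeans(x$meta[, paste0("label_", scar_regions())])
  cat(sprintf("  ECG-level scar prevalence: basal %.2f, mid %.2f, apical %.2f\n",
              prev[1], prev[2], prev[3]))
  invisible(x)
}

#' Patient-level feature matrix (mean over each patient's ECGs)
#'
#' @param cohort An `ecg_cohort`, or any (features, meta) pair.
#' @return List with `X` (patients x 276), `meta` (one row per patient).
#' @export
patient_features <- function(cohort) {
  aggregate_patients(cohort$features, cohort$meta)
}

aggregate_patients <- function(features, meta) {
  pid <- meta$patient_id
  ids <- sort(unique(pid))
  X <- rowsum(features, group = pid) / as.vector(table(pid)[as.character(ids)])
  first <- match(ids, pid)
  list(X = X[as.character(ids), , drop = FALSE], meta = meta[first, , drop = FALSE])
}

#' Write / read a cohort feature table as CSV
#'
#' One row per ECG: metadata columns followed by the 276 lead-major feature
#' columns named `<lead>_<feature>`.
#'
#' @param cohort An `ecg_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cbind(cohort$meta, as.data.frame(cohort$features, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param check_names If TRUE, require all 276 feature columns.
#' @export
read_cohort_csv <- function(path, check_names = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE)
  fn <- ecg_feature_names()
  if (check_names && !all(fn %in% names(df))) {
    stopf("feature table is missing columns: %s",
          paste(utils::head(setdiff(fn, names(df)), 5), collapse = ", "))
  }
  feats <- as.matrix(df[, fn, drop = FALSE])
  meta <- df[, setdiff(names(df), fn), drop = FALSE]
  out <- list(features = feats, meta = meta, truth = NULL)
  class(out) <- "ecg_cohort"
  out
}
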