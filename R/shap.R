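#' Kernel SHAP explanation of a scalar model
#'
#' Estimates per-feature Shapley values for one prediction by weighted
#' least squares over sampled feature coalitions (Shapley-kernel weights).
#' Masked-out features are imputed by averaging the model output over
#' background substitutions. Coalition sizes are enumerated completely from
#' the outside in while the budget allows (paired with their complements)
#' and sampled proportionally to the kernel weight beyond that. The
#' solution is constrained so the attributions plus the base value sum
#' exactly to the model output (local accuracy); with the full coalition
#' enumeration the estimate equals the exact Shapley value.
#'
#' @param model_fn Function mapping a feature matrix (rows = inputs) to a
#'   numeric vector of scalar outputs (e.g. scar probabilities).
#' @param background Background data matrix (rows used for imputation).
#' @param x The input vector to explain.
#' @param n_coalitions Number of distinct coalitions to evaluate (>= d+2
#'   where d = number of features).
#' @param seed Integer seed for coalition sampling.
#' @param chunk_rows Cap on rows per model_fn call.
#' @return Object of class `shap_explanation`: `phi` (named attributions),
#'   `base` (mean model output over the background), `fx` (model output at
#'   `x`).
#' @export
kernel_shap <- function(model_fn, background, x, n_coalitions = 1000L,
                        seed = 1L, chunk_rows = 20000L) {
  background <- as.matrix(background)
  if (nrow(background) < 1L) stopf("background must be nonempty")
  x <- as.numeric(x)
  d <- length(x)
  if (d != ncol(background)) stopf("x and background dimensions differ")
  if (n_coalitions < d + 2L) {
    stopf("n_coalitions (%d) must be at least d + 2 = %d", n_coalitions, d + 2L)
  }

  fx <- as.numeric(model_fn(matrix(x, nrow = 1)))[1]
  base <- mean(as.numeric(model_fn(background)))

  Zs <- with_seed(seed, sample_coalitions(d, n_coalitions))
  Z <- Zs$Z
  w <- Zs$w
  nz <- nrow(Z)

  # model value of each coalition: mean over background-imputed rows
  m <- nrow(background)
  y <- numeric(nz)
  per <- max(1L, floor(chunk_rows / m))
  for (start in seq(1L, nz, by = per)) {
    idx <- start:min(start + per - 1L, nz)
    big <- background[rep(seq_len(m), length(idx)), , drop = FALSE]
    zrep <- Z[rep(idx, each = m), , drop = FALSE]
    xa <- matrix(x, nrow(big), d, byrow = TRUE)
    big[zrep] <- xa[zrep]
    out <- as.numeric(model_fn(big))
    y[idx] <- colMeans(matrix(out, nrow = m))
  }

  # weighted least squares with the sum constraint eliminated through the
  # last feature: phi_d = (fx - base) - sum(phi_-d)
  t_vec <- y - base - Z[, d] * (fx - base)
  Z2 <- Z[, -d, drop = FALSE] - Z[, d]
  A <- crossprod(Z2 * w, Z2)
  b <- crossprod(Z2 * w, t_vec)
  phi_rest <- tryCatch(
    solve(A, b),
    error = function(e) solve(A + diag(1e-10, ncol(A)), b)
  )
  phi <- c(phi_rest, (fx - base) - sum(phi_rest))
  names(phi) <- colnames(background) %||% paste0("f", seq_len(d))

  out <- list(phi = phi, base = base, fx = fx,
              n_coalitions = nz)
  class(out) <- "shap_explanation"
  out
}

# sample coalition indicator matrix with Shapley kernel weights:
# weight(s) ~ (d - 1) / (choose(d, s) * s * (d - s)); complete size levels
# are enumerated from the outside in while the budget allows, then the
# remainder is sampled (paired with complements)
sample_coalitions <- function(d, budget) {
  sizes <- seq_len(d - 1L)
  size_w <- (d - 1) / (sizes * (d - sizes))
  size_w <- size_w / sum(size_w)
  Zl <- list(); wl <- list()
  remaining <- budget
  rem_sizes <- rep(TRUE, d - 1L)
  half <- seq_len(ceiling((d - 1L) / 2))
  for (s in half) {
    pair <- unique(c(s, d - s))
    count <- sum(choose(d, pair))
    if (count > remaining) break
    for (p in pair) {
      combs <- utils::combn(d, p)
      M <- matrix(FALSE, ncol(combs), d)
      M[cbind(rep(seq_len(ncol(combs)), each = p), as.vector(combs))] <- TRUE
      Zl[[length(Zl) + 1L]] <- M
      wl[[length(wl) + 1L]] <- rep(size_w[p] / choose(d, p), nrow(M))
      rem_sizes[p] <- FALSE
    }
    remaining <- remaining - count
  }
  if (any(rem_sizes) && remaining > 0L) {
    pr <- size_w * rem_sizes
    pr <- pr / sum(pr)
    n_pairs <- floor(remaining / 2)
    if (n_pairs > 0L) {
      ss <- sample(sizes, n_pairs, replace = TRUE, prob = pr)
      M <- matrix(FALSE, 2L * n_pairs, d)
      for (i in seq_len(n_pairs)) {
        on <- sample.int(d, ss[i])
        M[2L * i - 1L, on] <- TRUE
        M[2L * i, -on] <- TRUE       # antithetic complement
      }
      Zl[[length(Zl) + 1L]] <- M
      # sampled coalitions estimate the conditional mean within their size
      # stratum; weight = stratum weight / draws in stratum
      szs <- rowSums(M)
      tab <- table(szs)
      wl[[length(wl) + 1L]] <- size_w[szs] / as.numeric(tab[as.character(szs)])
    }
  }
  Z <- do.call(rbind, Zl)
  w <- unlist(wl)
  list(Z = Z, w = w)
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("shap_explanation: f(x) = %.4f, base = %.4f, %d features\n",
              x$fx, x$base, length(x$phi)))
  top <- utils::head(order(-abs(x$phi)), 5)
  for (i in top) cat(sprintf("  %-28s %+.4f\n", names(x$phi)[i], x$phi[i]))
  invisible(x)
}

#' Component-level Shapley importance summary
#'
#' Aggregates per-feature Shapley magnitudes over a set of explanations
#' into the five ECG components (Q, QRS, ST, T, TP) crossed with leads:
#' mean |phi| per (component, lead), ranked. Signed means are included for
#' direction reading.
#'
#' @param explanations List of `shap_explanation` objects over the 276
#'   ECG features.
#' @return data.frame with `component`, `lead`, `mean_abs_shap`,
#'   `mean_shap`, sorted by decreasing importance.
#' @export
summarize_components <- function(explanations) {
  if (length(explanations) == 0L) stopf("need at least one explanation")
  fn <- ecg_feature_names()
  for (e in explanations) {
    if (!identical(names(e$phi), fn)) {
      stopf("explanations use mixed feature registries")
    }
  }
  Phi <- do.call(rbind, lapply(explanations, `[[`, "phi"))
  reg <- feature_registry()
  lead <- rep(ecg_leads(), each = nrow(reg))
  comp <- rep(reg$component, times = 12)
  key <- paste(comp, lead, sep = ":")
  mean_abs <- tapply(colMeans(abs(Phi)), key, mean)
  mean_signed <- tapply(colMeans(Phi), key, mean)
  parts <- do.call(rbind, strsplit(names(mean_abs), ":", fixed = TRUE))
  out <- data.frame(component = parts[, 1], lead = parts[, 2],
                    mean_abs_shap = as.numeric(mean_abs),
                    mean_shap = as.numeric(mean_signed),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_abs_shap), ]
}

#' Top-quantile Shapley selection frequency
#'
#' For each prediction, ranks features by Shapley magnitude (ties broken by
#' registry index) and marks the top `ceiling(quantile * d)` features; the
#' frequency of a feature is the fraction of predictions in which it is
#' marked. With the default quantile 0.2 and d = 276, exactly 56 features
#' are marked per prediction.
#'
#' @param explanations List of `shap_explanation` objects.
#' @param quantile Fraction of features marked per prediction, in (0, 1).
#' @return Named numeric vector of per-feature frequencies in [0, 1],
#'   in registry order.
#' @export
top_feature_frequency <- function(explanations, quantile = 0.2) {
  if (length(explanations) == 0L) stopf("need at least one explanation")
  if (!is_number(quantile) || quantile <= 0 || quantile >= 1) {
    stopf("quantile must lie in (0, 1)")
  }
  d <- length(explanations[[1]]$phi)
  k <- ceiling(quantile * d)
  marks <- vapply(explanations, function(e) {
    top <- order(-abs(e$phi), seq_len(d))[seq_len(k)]
    v <- numeric(d)
    v[top] <- 1
    v
  }, numeric(d))
  freq <- rowMeans(marks)
  names(freq) <- names(explanations[[1]]$phi)
  freq
}

#' Welch's t-test feature comparison between scar and no-scar groups
#'
#' Per feature: group means and SDs plus the unequal-variance (Welch)
#' two-sided t-test. Features where either class has fewer than two
#' observations get NA statistics.
#'
#' @param features Numeric matrix (rows = ECGs).
#' @param labels Binary labels aligned with rows (1 = scar).
#' @return data.frame with `feature`, `mean_scar`, `sd_scar`,
#'   `mean_noscar`, `sd_noscar`, `t`, `p_value`.
#' @export
welch_compare <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  g1 <- features[labels == 1L, , drop = FALSE]
  g0 <- features[labels == 0L, , drop = FALSE]
  res <- lapply(seq_len(ncol(features)), function(j) {
    x1 <- g1[, j]; x0 <- g0[, j]
    if (length(x1) < 2L || length(x0) < 2L) {
      return(c(mean(x1), stats::sd(x1), mean(x0), stats::sd(x0), NA, NA))
    }
    tt <- tryCatch(stats::t.test(x1, x0), error = function(e) NULL)
    if (is.null(tt)) {
      # essentially constant data: identical means give t = 0, p = 1
      eq <- isTRUE(all.equal(mean(x1), mean(x0)))
      c(mean(x1), stats::sd(x1), mean(x0), stats::sd(x0),
        if (eq) 0 else Inf, if (eq) 1 else 0)
    } else {
      c(mean(x1), stats::sd(x1), mean(x0), stats::sd(x0),
        unname(tt$statistic), tt$p.value)
    }
  })
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("mean_scar", "sd_scar", "mean_noscar", "sd_noscar",
                  "t", "p_value")
  cbind(feature = colnames(features) %||%
          paste0("f", seq_len(ncol(features))), out)
}

#' Explain routed scar predictions with Kernel SHAP
#'
#' For each input ECG and region, routes the ECG to its merged group and
#' explains that group model's probability output against a background of
#' the group's training rows.
#'
#' @param models A `regional_scar_models`.
#' @param partitions Named list (region -> `partition_model`).
#' @param X Matrix of ECG feature rows to explain (raw features).
#' @param background Training feature matrix used as SHAP background.
#' @param regions Regions to explain (default all three).
#' @param n_coalitions,background_size,seed Kernel SHAP controls; the
#'   background is subsampled to at most `background_size` rows.
#' @return Nested list: per region, a list of `shap_explanation` (one per
#'   row of `X`).
#' @export
explain_scar <- function(models, partitions, X, background,
                         regions = scar_regions(),
                         n_coalitions = 600L, background_size = 50L,
                         seed = 1L) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  background <- as.matrix(background)
  bg <- if (nrow(background) > background_size) {
    background[with_seed(child_seed(seed, "bg"),
                         sample.int(nrow(background), background_size)), ,
               drop = FALSE]
  } else background
  out <- list()
  for (region in regions) {
    gid <- assign_group(partitions[[region]], X)
    exps <- vector("list", nrow(X))
    for (i in seq_len(nrow(X))) {
      model <- models$models[[region]][[gid[i]]]
      fn <- function(M) predict_group_prob(model, M)
      exps[[i]] <- kernel_shap(fn, bg, X[i, ], n_coalitions = n_coalitions,
                               seed = child_seed(seed, paste(region, i)))
      exps[[i]]$region <- region
      exps[[i]]$group <- gid[i]
    }
    out[[region]] <- exps
  }
  out
}
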