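# shared helpers: independent oracles and small fixtures

f1_score <- function(pred, truth) {
  tp <- sum(pred & truth)
  tp / (tp + 0.5 * (sum(pred & !truth) + sum(!pred & truth)))
}

rel_err <- function(got, want, floor = 1e-12) {
  abs(got - want) / pmax(abs(want), floor)
}

# exact Shapley values by subset enumeration (d <= ~10), with background
# imputation matching the Kernel SHAP value function
exact_shapley <- function(model_fn, bg, x) {
  d <- length(x); m <- nrow(bg)
  cache <- new.env()
  v <- function(S) {
    key <- paste0("s", paste(S, collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    M <- bg
    if (length(S)) M[, S] <- matrix(x[S], m, length(S), byrow = TRUE)
    r <- mean(model_fn(M))
    assign(key, r, envir = cache)
    r
  }
  phi <- numeric(d)
  for (j in seq_len(d)) {
    others <- setdiff(seq_len(d), j)
    for (k in 0:(d - 1)) {
      w <- factorial(k) * factorial(d - k - 1) / factorial(d)
      if (k == 0) {
        phi[j] <- phi[j] + w * (v(j) - v(integer(0)))
      } else {
        combs <- utils::combn(others, k)
        for (ci in seq_len(ncol(combs))) {
          S <- combs[, ci]
          phi[j] <- phi[j] + w * (v(sort(c(S, j))) - v(S))
        }
      }
    }
  }
  phi
}

# random physiologically plausible beat parameters for oracle tests; all
# feature magnitudes kept away from zero so relative tolerances are
# meaningful
random_beat_params <- function() {
  beat_shape_params(
    q = list(amplitude = runif(1, -0.3, -0.05), center = 0.20,
             width = runif(1, 0.010, 0.016)),
    r = list(amplitude = runif(1, 0.5, 1.8), center = runif(1, 0.235, 0.25),
             width = runif(1, 0.013, 0.020)),
    s = list(amplitude = runif(1, -0.9, -0.1), center = 0.285,
             width = runif(1, 0.010, 0.016)),
    t = list(amplitude = sample(c(-1, 1), 1) * runif(1, 0.15, 0.6),
             center = runif(1, 0.48, 0.52), width = runif(1, 0.03, 0.05)),
    st_level = sample(c(-1, 1), 1) * runif(1, 0.05, 0.2),
    tp_slope = sample(c(-1, 1), 1) * runif(1, 0.1, 0.4)
  )
}

# adjusted-rand index between two labelings (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small, fast pipeline config for structural tests
tiny_pipeline_config <- function(seed = 1L, n_patients = 60L) {
  pipeline_config(
    cohort = cohort_config(n_patients = n_patients,
                           seed = ecgscar:::child_seed(seed, "cohort")),
    scarf = scarf_config(pretrain_epochs = 3L, finetune_epochs = 6L,
                         n_ensemble = 1L, seed = seed),
    seed = seed
  )
}

with_seed_test <- function(seed, code) ecgscar:::with_seed(seed, code)
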