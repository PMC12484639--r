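test_that("corruption replaces the configured number of coordinates", {
  set.seed(1)
  train <- matrix(rnorm(50 * 276), 50, 276)
  x <- matrix(rnorm(276), 1)
  # spying on indices: a replacement drawn from a disjoint-valued training
  # matrix must differ from the original everywhere it was applied
  train_far <- train + 100
  xc <- corrupt(x, train_far, rate = 0.6)
  expect_equal(sum(xc != x), round(0.6 * 276))  # = 166
  expect_equal(round(0.6 * 276), 166L)
  # rate 0 is the identity
  expect_identical(corrupt(x, train, rate = 0), x)
  # a constant training column never changes the corresponding coordinate
  train_const <- train
  train_const[, 5] <- x[1, 5]
  set.seed(2)
  changed <- replicate(20, corrupt(x, train_const, rate = 1)[1, 5] != x[1, 5])
  expect_false(any(changed))
})

test_that("the InfoNCE loss equals log N when all similarities coincide", {
  N <- 16
  Z <- matrix(rep(1, N * 8), N, 8)  # identical embeddings
  nce <- ecgscar:::info_nce(Z, Z, tau = 1)
  expect_equal(nce$loss, log(N), tolerance = 1e-12)
})

test_that("pretraining reduces the contrastive loss and aligns own corruptions", {
  co <- generate_cohort(cohort_config(n_patients = 120, seed = 3))
  X <- scale(co$features[1:250, ])
  cfg <- scarf_config(pretrain_epochs = 8, batch_size = 64, seed = 5)
  pt <- pretrain_encoder(X[1:200, ], cfg)
  expect_lt(tail(pt$loss_history, 1), pt$loss_history[1])
  # held-out anchor/own-corruption cosine similarity beats cross-pairs
  ho <- X[201:250, ]
  hc <- with_seed_test(9, corrupt(ho, X[1:200, ], 0.6))
  U <- ecgscar:::l2_normalize(ecgscar:::mlp_forward(pt$encoder, ho)$out)$U
  V <- ecgscar:::l2_normalize(ecgscar:::mlp_forward(pt$encoder, hc)$out)$U
  S <- U %*% t(V)
  expect_gt(mean(diag(S)), mean(S[row(S) != col(S)]))
})

test_that("a strongly separable planted effect is learned to high F1", {
  # 4-SD shifts on 5 features, one cluster: near-noiseless decision problem
  em <- data.frame(region = "basal",
                   lead = c("aVR", "I", "V1", "V2", "V3"),
                   feature = "q_amplitude",
                   effect = -4)
  co <- generate_cohort(cohort_config(n_patients = 250, n_clusters = 1,
                                      scar_effect_map = em,
                                      effect_expression_prob = 1, seed = 7))
  n <- nrow(co$features)
  tr <- co$meta$patient_id <= 200
  m <- train_group_model(co$features[tr, ], co$meta$label_basal[tr],
                         scarf_config(seed = 5, pretrain_epochs = 10,
                                      finetune_epochs = 30, n_ensemble = 1))
  p <- ecgscar:::predict_group_prob(m, co$features[!tr, ])
  expect_gte(f1_score(p >= 0.5, co$meta$label_basal[!tr] == 1), 0.95)
})

test_that("shuffled labels collapse performance to the prevalence baseline", {
  co <- generate_cohort(cohort_config(n_patients = 250, n_clusters = 1,
                                      seed = 11))
  tr <- co$meta$patient_id <= 200
  y <- co$meta$label_basal
  y_shuf <- with_seed_test(13, sample(y[tr]))
  m <- train_group_model(co$features[tr, ], y_shuf,
                         scarf_config(seed = 5, pretrain_epochs = 5,
                                      finetune_epochs = 15, n_ensemble = 1))
  p <- ecgscar:::predict_group_prob(m, co$features[!tr, ])
  # baseline: always predict scar
  base <- f1_score(rep(TRUE, sum(!tr)), y[!tr] == 1)
  expect_lt(abs(f1_score(p >= 0.5, y[!tr] == 1) - base), 0.25)
})

test_that("a single-class group falls back to a constant model with a warning", {
  X <- matrix(rnorm(50 * 10), 50, 10)
  expect_warning(
    m <- train_group_model(X, rep(1L, 50), scarf_config(seed = 1)),
    "single class"
  )
  expect_equal(ecgscar:::predict_group_prob(m, X[1:3, ]), rep(1, 3))
})

test_that("regional predictions OR into the global call with threshold-positive boundary", {
  mk_const <- function(p) structure(list(type = "constant", prob = p,
                                         center = 0, scale = 1,
                                         threshold = 0.5),
                                    class = "scar_group_model")
  part <- structure(list(groups = list(list(centroid = 0)),
                         center = 0, scale = 1), class = "partition_model")
  parts <- list(basal = part, mid = part, apical = part)
  mods <- structure(list(models = list(basal = list(mk_const(0.9)),
                                       mid = list(mk_const(0.1)),
                                       apical = list(mk_const(0.5))),
                         config = scarf_config(seed = 1)),
                    class = "regional_scar_models")
  pr <- predict_scar(mods, parts, matrix(0, 2, 1))
  expect_equal(pr$pred_basal, c(1, 1))
  expect_equal(pr$pred_mid, c(0, 0))
  expect_equal(pr$pred_apical, c(1, 1))  # exactly at threshold -> positive
  expect_equal(pr$pred_global, c(1, 1))
  mods$models$basal[[1]] <- mk_const(0.2)
  mods$models$apical[[1]] <- mk_const(0.3)
  pr2 <- predict_scar(mods, parts, matrix(0, 1, 1))
  expect_equal(pr2$pred_global, 0)      # (0,0,0) -> global false
})

test_that("group training is deterministic under a fixed seed", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 17))
  cfg <- scarf_config(seed = 23, pretrain_epochs = 3, finetune_epochs = 5,
                      n_ensemble = 1)
  m1 <- train_group_model(co$features, co$meta$label_mid, cfg)
  m2 <- train_group_model(co$features, co$meta$label_mid, cfg)
  expect_identical(m1$nets, m2$nets)
})
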