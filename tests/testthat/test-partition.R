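test_that("the DP mixture separates two well-separated blobs", {
  set.seed(1)
  X <- rbind(matrix(rnorm(100 * 5), 100, 5),
             matrix(rnorm(100 * 5, mean = 6 / sqrt(5)), 100, 5))
  cl <- fit_dpgmm(scale(X), partition_config(seed = 3))
  expect_equal(cl$n_effective, 2L)
  expect_gte(adjusted_rand(cl$assignment, rep(1:2, each = 100)), 0.95)
})

test_that("the DP prior shrinks clusters on structureless data", {
  set.seed(2)
  X <- matrix(rnorm(50 * 5), 50, 5)
  cl <- fit_dpgmm(scale(X), partition_config(max_components = 10, seed = 5))
  expect_lte(cl$n_effective, 3L)
})

test_that("a degenerate point cloud collapses to one cluster", {
  X <- matrix(1, 60, 4) + matrix(rnorm(240, sd = 1e-6), 60, 4)
  cl <- fit_dpgmm(X, partition_config(seed = 2))
  expect_equal(cl$n_effective, 1L)
})

test_that("non-finite clustering input is rejected", {
  X <- matrix(rnorm(100), 20, 5)
  X[3, 2] <- NA
  expect_error(fit_dpgmm(X, partition_config()), "finite")
})

test_that("class dominance follows the multiplicative rule", {
  expect_true(is_dominated(10, 4, 2))    # 10 >= 2 * 4
  expect_false(is_dominated(5, 4, 2))
  expect_true(is_dominated(5, 4, 1))
  expect_true(is_dominated(4, 10, 2))    # symmetric
  expect_true(is_dominated(0, 0, 2))     # vacuous boundary convention
  expect_error(is_dominated(-1, 2, 2))
})

test_that("default ratios force at most two iterations and two merged groups", {
  set.seed(4)
  for (rep in 1:5) {
    n <- 120
    X <- matrix(rnorm(n * 8), n, 8)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pm <- recursive_partition(X, labels, partition_config(seed = rep))
    expect_lte(pm$n_iterations, 2L)
    expect_lte(length(pm$groups), 2L)
    # partition property: every patient in exactly one group
    members <- sort(unlist(lapply(pm$groups, `[[`, "members")))
    expect_identical(members, 1:n)
  }
})

test_that("two class-skewed blobs are pooled in the first iteration", {
  set.seed(6)
  X <- rbind(matrix(rnorm(80 * 6), 80, 6),
             matrix(rnorm(80 * 6, mean = 3), 80, 6))
  labels <- c(rbinom(80, 1, 0.9), rbinom(80, 1, 0.1))
  pm <- recursive_partition(X, labels, partition_config(seed = 7))
  expect_equal(length(pm$groups), 1L)
  expect_equal(pm$groups[[1]]$iteration, 0L)
})

test_that("single-class labels give one warned group; ablation mode gives one group", {
  X <- matrix(rnorm(40 * 5), 40, 5)
  expect_warning(pm <- recursive_partition(X, rep(0L, 40),
                                           partition_config(seed = 1)),
                 "single")
  expect_equal(length(pm$groups), 1L)
  pm2 <- recursive_partition(X, rbinom(40, 1, 0.5),
                             partition_config(seed = 1, no_partitioning = TRUE))
  expect_equal(length(pm2$groups), 1L)
  expect_length(pm2$groups[[1]]$members, 40L)
})

test_that("recursive partitioning is deterministic under a fixed seed", {
  co <- generate_cohort(cohort_config(n_patients = 80, seed = 13))
  pf <- patient_features(co)
  cfg <- partition_config(seed = 21)
  expect_identical(recursive_partition(pf$X, pf$meta$label_basal, cfg),
                   recursive_partition(pf$X, pf$meta$label_basal, cfg))
})

test_that("group routing hits the exact centroid and breaks ties low", {
  X <- matrix(rnorm(60 * 4), 60, 4)
  labels <- rbinom(60, 1, 0.5)
  pm <- recursive_partition(X, labels, partition_config(seed = 2))
  # a point exactly at a group centroid routes to that group
  for (g in seq_along(pm$groups)) {
    x <- pm$groups[[g]]$centroid * pm$scale + pm$center
    expect_equal(assign_group(pm, x), g)
  }
  # equidistant point routes to the lowest index
  if (length(pm$groups) == 2L) {
    mid <- (pm$groups[[1]]$centroid + pm$groups[[2]]$centroid) / 2
    expect_equal(assign_group(pm, mid * pm$scale + pm$center), 1L)
  }
  expect_error(assign_group(pm, rnorm(3)), "dimension")
})

test_that("held-out patients route to the group of their generative cluster", {
  em <- default_scar_effects()
  em$effect <- 0
  co <- generate_cohort(cohort_config(n_patients = 700, seed = 31,
                                      scar_effect_map = em))
  pf <- patient_features(co)
  tr <- 1:400; ho <- 401:700
  pm <- recursive_partition(pf$X[tr, ], pf$meta$label_basal[tr],
                            partition_config(seed = 17))
  gid_tr <- assign_group(pm, pf$X[tr, ])
  map <- apply(table(gid_tr, pf$meta$cluster[tr]), 2, which.max)
  gid_ho <- assign_group(pm, pf$X[ho, ])
  agreement <- mean(gid_ho == map[pf$meta$cluster[ho]])
  expect_gte(agreement, 0.9)
})
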