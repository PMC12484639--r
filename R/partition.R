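#' Configuration of recursive patient partitioning
#'
#' @param init_dominance_ratio Initial class-dominance ratio (>= 1). A
#'   cluster is dominated when one class's count is at least this multiple
#'   of the other's.
#' @param decay Multiplier applied to the ratio at each recursion (in
#'   (0, 1)); the default 0.5 halves it, so with the default initial ratio
#'   2 the recursion runs at most twice and yields at most two merged
#'   groups.
#' @param max_components Truncation level of the Dirichlet-process mixture.
#' @param covariance_type `"diagonal"` or `"full"` component covariances.
#' @param concentration Stick-breaking concentration prior; default
#'   `1 / max_components`.
#' @param min_cluster_size Clusters smaller than this are dissolved into
#'   the nearest surviving cluster.
#' @param merge_policy `"per_iteration"` pools all clusters dominated at
#'   the same recursion depth into one merged group (the default);
#'   `"by_class"` keeps scar-dominated and noscar-dominated pools separate.
#' @param no_partitioning Ablation switch: a single group containing every
#'   patient, skipping clustering entirely.
#' @param seed Integer seed for the mixture initialisation.
#' @return An object of class `partition_config`.
#' @export
partition_config <- function(init_dominance_ratio = 2.0,
                             decay = 0.5,
                             max_components = 20L,
                             covariance_type = c("diagonal", "full"),
                             concentration = NULL,
                             min_cluster_size = 5L,
                             merge_policy = c("per_iteration", "by_class"),
                             no_partitioning = FALSE,
                             seed = 1L) {
  if (!is_number(init_dominance_ratio) || init_dominance_ratio < 1) {
    stopf("init_dominance_ratio must be >= 1")
  }
  if (!is_number(decay) || decay <= 0 || decay >= 1) {
    stopf("decay must lie in (0, 1)")
  }
  cfg <- list(
    init_dominance_ratio = init_dominance_ratio,
    decay = decay,
    max_components = as.integer(max_components),
    covariance_type = match.arg(covariance_type),
    concentration = concentration %||% (1 / max_components),
    min_cluster_size = as.integer(min_cluster_size),
    merge_policy = match.arg(merge_policy),
    no_partitioning = isTRUE(no_partitioning),
    seed = as.integer(seed)
  )
  class(cfg) <- "partition_config"
  cfg
}

#' Dirichlet-process Gaussian mixture clustering
#'
#' Variational stick-breaking approximation of a DP Gaussian mixture,
#' truncated at `max_components`, with per-dimension Normal-Gamma priors
#' (diagonal covariance). The effective number of clusters is data-driven:
#' the small concentration prior shrinks away unneeded components, and
#' clusters below `min_cluster_size` are dissolved into the nearest
#' surviving cluster. Responsibilities are initialised from k-means on the
#' leading principal components.
#'
#' @param X Standardized numeric matrix (rows = patients).
#' @param config A `partition_config`.
#' @param max_iter,tol Variational iteration controls.
#' @return List with `assignment` (integer cluster per row, consecutive
#'   ids), `centers` (cluster x feature posterior means), `n_effective`.
#' @export
fit_dpgmm <- function(X, config = partition_config(), max_iter = 100L,
                      tol = 1e-5) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("non-finite values in clustering input")
  n <- nrow(X); d <- ncol(X)
  K <- min(config$max_components, n)
  if (n < max(10L, 2L)) stopf("need at least 10 rows to cluster")
  alpha <- config$concentration

  # priors (data assumed standardized)
  m0 <- colMeans(X)
  beta0 <- 1
  a0 <- 1
  b0 <- pmax(apply(X, 2, stats::var), 1e-6)

  with_seed(config$seed, {
    # soft responsibilities around k-means centers: the softening (length
    # scale ~ the expected within-cluster squared distance, d in z-space)
    # lets redundant components overlap and die under the stick prior
    # instead of freezing into hard sub-cluster splits
    km <- tryCatch(
      stats::kmeans(X, centers = K, nstart = 3, iter.max = 30),
      error = function(e) NULL
    )
    centers0 <- if (is.null(km)) {
      X[sample.int(n, K), , drop = FALSE]
    } else km$centers
    D2 <- vapply(seq_len(K), function(k) {
      rowSums(sweep(X, 2, centers0[k, ])^2)
    }, numeric(n))
    R <- exp(-(D2 - apply(D2, 1, min)) / (2 * d))
    R <- R / rowSums(R)

    Nk <- colSums(R)
    elbo_prev <- -Inf
    for (iter in seq_len(max_iter)) {
      # variational M-step
      Nk <- colSums(R) + 1e-10
      xbar <- t(R) %*% X / Nk
      Sk <- t(R) %*% (X^2) / Nk - xbar^2
      beta_k <- beta0 + Nk
      m_k <- (beta0 * m0[col(xbar)] + Nk * xbar) / beta_k
      a_k <- a0 + Nk / 2
      b_k <- b0[col(xbar)] + 0.5 * (Nk * Sk +
        (beta0 * Nk / beta_k) * sweep(xbar, 2, m0)^2)
      g1 <- 1 + Nk
      g2 <- alpha + rev(cumsum(rev(Nk)))[-1]
      g2 <- c(g2, alpha)  # align: g2[k] = alpha + sum_{j>k} Nj

      # E-step
      dg <- digamma(g1) - digamma(g1 + g2)
      dg2 <- digamma(g2) - digamma(g1 + g2)
      elogpi <- dg + c(0, cumsum(dg2)[-K])
      elog_lam <- digamma(a_k) - log(b_k)      # K x d
      e_lam <- a_k / b_k                        # K x d
      quad <- matrix(0, n, K)
      for (k in seq_len(K)) {
        xc2 <- sweep(X, 2, m_k[k, ])^2
        quad[, k] <- xc2 %*% e_lam[k, ] + d / beta_k[k]
      }
      logrho <- sweep(-0.5 * quad, 2, elogpi + 0.5 * rowSums(elog_lam), `+`)
      mx <- apply(logrho, 1, max)
      R <- exp(logrho - mx)
      R <- R / rowSums(R)
      elbo <- sum(mx + log(rowSums(exp(logrho - mx))))  # proxy
      if (is.finite(elbo) && abs(elbo - elbo_prev) < tol * abs(elbo_prev + 1)) break
      elbo_prev <- elbo
    }

    assign <- max.col(R, ties.method = "first")
    centers <- m_k
    # dissolve tiny clusters into the nearest surviving cluster
    repeat {
      tab <- tabulate(assign, K)
      small <- which(tab > 0 & tab < config$min_cluster_size)
      if (length(small) == 0L) break
      surv <- which(tab >= config$min_cluster_size)
      if (length(surv) == 0L) { assign[] <- which.max(tab); break }
      for (k in small) {
        rows <- which(assign == k)
        dists <- outer(rep(1, length(rows)), rep(0, length(surv)))
        for (si in seq_along(surv)) {
          dists[, si] <- rowSums(sweep(X[rows, , drop = FALSE], 2,
                                       centers[surv[si], ])^2)
        }
        assign[rows] <- surv[apply(dists, 1, which.min)]
      }
    }
    keep <- sort(unique(assign))
    relabel <- match(assign, keep)
    list(
      assignment = relabel,
      centers = centers[keep, , drop = FALSE],
      n_effective = length(keep)
    )
  })
}

#' Class-dominance test
#'
#' A cluster is dominated when one class's population is at least `ratio`
#' times the other's (multiplicative form, no division; an empty cluster is
#' vacuously dominated, though empty clusters are dissolved upstream).
#'
#' @param scar_count,noscar_count Non-negative class counts.
#' @param ratio Dominance ratio (>= 1 in normal use).
#' @return TRUE iff `scar >= ratio * noscar` or `noscar >= ratio * scar`.
#' @export
is_dominated <- function(scar_count, noscar_count, ratio) {
  stopifnot(scar_count >= 0, noscar_count >= 0)
  scar_count >= ratio * noscar_count || noscar_count >= ratio * scar_count
}

#' Recursive partitioning into class-dominated merged groups
#'
#' Iteration k (k = 0, 1, ...) uses the dominance ratio
#' `init_dominance_ratio * decay^k`: the still-unassigned patients are
#' clustered with the DP mixture, every cluster dominated at the current
#' ratio is pooled into merged group G_k, and the remaining patients carry
#' over to the next iteration. Once the ratio reaches 1 every cluster is
#' dominated, so termination is guaranteed; with the defaults (2.0, 0.5)
#' the recursion runs at most twice and yields at most two merged groups.
#'
#' Features are z-scored on the training patients before clustering; the
#' scaler is stored so held-out patients can be routed with
#' [assign_group()].
#'
#' @param X Numeric matrix, one row per patient (adjusted features).
#' @param labels Binary scar labels aligned with rows (1 = scar).
#' @param config A `partition_config`.
#' @return Object of class `partition_model`: per-group member indices,
#'   centroid (z-space), creation iteration, ratio used; plus the
#'   standardization parameters.
#' @export
recursive_partition <- function(X, labels, config = partition_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  labels <- as.integer(labels)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)

  groups <- list()
  if (config$no_partitioning || length(unique(labels)) == 1L) {
    if (length(unique(labels)) == 1L && !config$no_partitioning) {
      warnf("all patients share one class; returning a single merged group")
    }
    groups[[1]] <- list(members = seq_len(n),
                        centroid = colMeans(Z),
                        iteration = 0L, ratio = NA_real_,
                        label = "all")
  } else {
    remaining <- seq_len(n)
    k <- 0L
    max_iter <- 1L + ceiling(log(config$init_dominance_ratio) /
                               log(1 / config$decay))
    while (length(remaining) > 0L) {
      ratio_k <- config$init_dominance_ratio * config$decay^k
      if (length(remaining) < max(10L, config$min_cluster_size) ||
          ratio_k <= 1 || k >= max_iter) {
        # every cluster is dominated at ratio <= 1: pool the rest
        groups[[length(groups) + 1L]] <- list(
          members = remaining,
          centroid = colMeans(Z[remaining, , drop = FALSE]),
          iteration = k, ratio = ratio_k, label = "pooled")
        break
      }
      cl_cfg <- config
      cl_cfg$seed <- child_seed(config$seed, paste0("iter", k))
      cl <- fit_dpgmm(Z[remaining, , drop = FALSE], cl_cfg)
      dominated <- logical(length(remaining))
      dom_class <- character(cl$n_effective)
      for (c_id in seq_len(cl$n_effective)) {
        in_c <- cl$assignment == c_id
        sc <- sum(labels[remaining][in_c] == 1L)
        ns <- sum(labels[remaining][in_c] == 0L)
        if (is_dominated(sc, ns, ratio_k)) {
          dominated[in_c] <- TRUE
          dom_class[c_id] <- if (sc >= ns) "scar" else "noscar"
        }
      }
      if (any(dominated)) {
        if (config$merge_policy == "per_iteration") {
          mem <- remaining[dominated]
          groups[[length(groups) + 1L]] <- list(
            members = mem,
            centroid = colMeans(Z[mem, , drop = FALSE]),
            iteration = k, ratio = ratio_k, label = "dominated")
        } else {
          for (cls in c("scar", "noscar")) {
            sel <- dominated & dom_class[cl$assignment] == cls
            if (any(sel)) {
              mem <- remaining[sel]
              groups[[length(groups) + 1L]] <- list(
                members = mem,
                centroid = colMeans(Z[mem, , drop = FALSE]),
                iteration = k, ratio = ratio_k, label = cls)
            }
          }
        }
        remaining <- remaining[!dominated]
      }
      k <- k + 1L
    }
  }
  model <- list(groups = groups, center = mu, scale = sdv,
                n_iterations = max(vapply(groups, `[[`, integer(1),
                                          "iteration")) + 1L,
                config = config)
  class(model) <- "partition_model"
  model
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf("partition_model: %d merged group(s), %d iteration(s)\n",
              length(x$groups), x$n_iterations))
  for (i in seq_along(x$groups)) {
    g <- x$groups[[i]]
    cat(sprintf("  group %d: %d members (iteration %d, ratio %.2f)\n",
                i, length(g$members), g$iteration, g$ratio))
  }
  invisible(x)
}

#' Route a feature vector to its merged group
#'
#' Nearest merged-group centroid by Euclidean distance in the model's
#' z-scored feature space; ties break to the lowest group index.
#'
#' @param model A `partition_model`.
#' @param x A feature vector (length matching the training features) or a
#'   matrix of rows to route.
#' @return Integer group id(s).
#' @export
assign_group <- function(model, x) {
  stopifnot(inherits(model, "partition_model"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != length(model$center)) {
    stopf("dimension mismatch: expected %d features, got %d",
          length(model$center), ncol(X))
  }
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  cent <- do.call(rbind, lapply(model$groups, `[[`, "centroid"))
  D2 <- outer(rowSums(Z^2), rep(1, nrow(cent))) -
    2 * Z %*% t(cent) + outer(rep(1, nrow(Z)), rowSums(cent^2))
  ids <- apply(D2, 1, which.min)  # which.min takes the first (lowest) index
  as.integer(ids)
}
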