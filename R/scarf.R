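#' Configuration of the self-supervised scar classifier
#'
#' Settings for contrastive pretraining with random feature corruption and
#' the supervised fine-tuning stage. The corruption rate of 0.6 replaces
#' 60 percent of a vector's features with draws from the empirical training
#' distribution of the same feature; the contrastive loss is InfoNCE over
#' cosine similarities at temperature `temperature`.
#'
#' @param corruption_rate Fraction of features corrupted per view (0, 1].
#' @param temperature InfoNCE temperature (> 0).
#' @param embedding_dim Encoder output width.
#' @param encoder_hidden Hidden-layer widths of the encoder.
#' @param head_hidden Hidden-layer widths of the classification head.
#' @param batch_size Minibatch size.
#' @param pretrain_epochs,finetune_epochs Training lengths.
#' @param pretrain_lr,finetune_lr Adam learning rates.
#' @param weight_decay Decoupled (AdamW-style) L2 weight decay.
#' @param finetune_noise_sd SD (in standardized units) of Gaussian input
#'   jitter applied to fine-tuning minibatches. Replicate ECGs of one
#'   patient differ only by small within-patient noise, so an unregularized
#'   network can memorize patient fingerprints; the jitter breaks them.
#' @param labeled_fraction Fraction of training patients whose labels are
#'   used during fine-tuning (pretraining always uses all rows).
#' @param corrupt_dist `"empirical"` draws replacements uniformly from the
#'   observed training values of a feature; `"interval"` draws uniformly
#'   from its observed [min, max] range.
#' @param freeze_encoder If TRUE the encoder is frozen during fine-tuning;
#'   by default encoder and head are tuned jointly.
#' @param n_ensemble Number of independently initialised encoder+head
#'   replicates per group; predicted probabilities are averaged.
#' @param no_self_supervised Ablation switch: skip contrastive pretraining.
#' @param cv_grid Optional named list (`finetune_lr`, `embedding_dim`,
#'   `finetune_epochs`) of candidate values; when any component has more
#'   than one value, the combination is selected by 5-fold cross-validated
#'   F1 within each group.
#' @param threshold Decision threshold on the scar probability (a
#'   probability exactly at the threshold classifies positive).
#' @param seed Integer seed.
#' @return Object of class `scarf_config`.
#' @export
scarf_config <- function(corruption_rate = 0.6,
                         temperature = 1.0,
                         embedding_dim = 32L,
                         encoder_hidden = c(128L, 128L),
                         head_hidden = 32L,
                         batch_size = 128L,
                         pretrain_epochs = 30L,
                         finetune_epochs = 60L,
                         pretrain_lr = 1e-3,
                         finetune_lr = 1e-3,
                         weight_decay = 1e-2,
                         finetune_noise_sd = 0.6,
                         labeled_fraction = 1.0,
                         corrupt_dist = c("empirical", "interval"),
                         freeze_encoder = FALSE,
                         n_ensemble = 3L,
                         no_self_supervised = FALSE,
                         cv_grid = NULL,
                         threshold = 0.5,
                         seed = 1L) {
  if (!is_number(corruption_rate) || corruption_rate <= 0 || corruption_rate > 1) {
    stopf("corruption_rate must lie in (0, 1]")
  }
  if (!is_number(temperature) || temperature <= 0) {
    stopf("temperature must be > 0")
  }
  cfg <- list(
    corruption_rate = corruption_rate, temperature = temperature,
    embedding_dim = as.integer(embedding_dim),
    encoder_hidden = as.integer(encoder_hidden),
    head_hidden = as.integer(head_hidden),
    batch_size = as.integer(batch_size),
    pretrain_epochs = as.integer(pretrain_epochs),
    finetune_epochs = as.integer(finetune_epochs),
    pretrain_lr = pretrain_lr, finetune_lr = finetune_lr,
    weight_decay = weight_decay,
    finetune_noise_sd = finetune_noise_sd,
    labeled_fraction = labeled_fraction,
    corrupt_dist = match.arg(corrupt_dist),
    freeze_encoder = isTRUE(freeze_encoder),
    n_ensemble = as.integer(n_ensemble),
    no_self_supervised = isTRUE(no_self_supervised),
    cv_grid = cv_grid,
    threshold = threshold,
    seed = as.integer(seed)
  )
  class(cfg) <- "scarf_config"
  cfg
}

#' Random feature corruption
#'
#' Picks `round(rate * d)` distinct feature indices uniformly at random and
#' replaces each with a draw from that feature's empirical distribution
#' over the training matrix (or from its [min, max] interval when
#' `dist = "interval"`). Remaining features are unchanged. Vectorised over
#' the rows of `X`.
#'
#' @param X Matrix of rows to corrupt.
#' @param train Training matrix supplying the replacement distribution.
#' @param rate Corruption rate in (0, 1].
#' @param dist `"empirical"` or `"interval"`.
#' @return Matrix of the same shape as `X`.
#' @export
corrupt <- function(X, train, rate, dist = "empirical") {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (nrow(train) < 1L) stopf("empty training matrix")
  d <- ncol(X)
  k <- round(rate * d)
  if (k == 0L) return(X)
  n <- nrow(X)
  idx <- vapply(seq_len(n), function(i) sample.int(d, k), integer(k))
  rows <- cbind(rep(seq_len(n), each = k), as.vector(idx))
  if (dist == "empirical") {
    src <- sample.int(nrow(train), n * k, replace = TRUE)
    X[rows] <- train[cbind(src, as.vector(idx))]
  } else {
    lo <- apply(train, 2, min)[as.vector(idx)]
    hi <- apply(train, 2, max)[as.vector(idx)]
    X[rows] <- stats::runif(n * k, lo, hi)
  }
  X
}

# InfoNCE loss and gradients for a batch of anchor/corrupted embeddings.
# L = -mean_i log softmax_j( cos(z_i, z~_j) / tau )_{j=i}
info_nce <- function(Zu, Zv, tau) {
  nu <- l2_normalize(Zu); nv <- l2_normalize(Zv)
  N <- nrow(Zu)
  S <- (nu$U %*% t(nv$U)) / tau
  mx <- apply(S, 1, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  loss <- mean(lse - diag(S))
  P <- exp(S - lse)                       # softmax rows
  G <- (P - diag(N)) / (N * tau)
  Gu_unit <- G %*% nv$U
  Gv_unit <- t(G) %*% nu$U
  # back through row normalization: g_z = (g_u - u (u . g_u)) / ||z||
  Gu <- (Gu_unit - nu$U * rowSums(nu$U * Gu_unit)) / nu$nrm
  Gv <- (Gv_unit - nv$U * rowSums(nv$U * Gv_unit)) / nv$nrm
  list(loss = loss, Gu = Gu, Gv = Gv)
}

#' Contrastive pretraining of the encoder
#'
#' Trains the encoder with the InfoNCE objective: for each minibatch, every
#' row is paired with its own corrupted view as the positive and all other
#' corrupted views as negatives, pulling an ECG and its corruption together
#' in embedding space without using labels.
#'
#' @param X Numeric matrix of (standardized) training rows.
#' @param config A `scarf_config`.
#' @return List with `encoder` (an internal MLP) and `loss_history`
#'   (mean epoch loss).
#' @export
pretrain_encoder <- function(X, config = scarf_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L * min(config$batch_size, n)) {
    if (n < 4L) stopf("need at least 4 rows for contrastive pretraining")
  }
  sizes <- c(ncol(X), config$encoder_hidden, config$embedding_dim)
  with_seed(config$seed, {
    enc <- mlp_init(sizes)
    st <- adam_init(enc)
    t_step <- 0L
    B <- min(config$batch_size, n)
    history <- numeric(config$pretrain_epochs)
    for (ep in seq_len(config$pretrain_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = B)) {
        rows <- ord[start:min(start + B - 1L, n)]
        if (length(rows) < 2L) next
        Xa <- X[rows, , drop = FALSE]
        Xc <- corrupt(Xa, X, config$corruption_rate, config$corrupt_dist)
        fa <- mlp_forward(enc, Xa)
        fc <- mlp_forward(enc, Xc)
        nce <- info_nce(fa$out, fc$out, config$temperature)
        ga <- mlp_backward(enc, fa$acts, nce$Gu)
        gc <- mlp_backward(enc, fc$acts, nce$Gv)
        g <- lapply(seq_along(ga), function(i) list(
          W = ga[[i]]$W + gc[[i]]$W, b = ga[[i]]$b + gc[[i]]$b))
        if (!is.finite(nce$loss)) {
          stopf("non-finite contrastive loss at epoch %d", ep)
        }
        t_step <- t_step + 1L
        upd <- adam_step(enc, g, st, config$pretrain_lr, t_step,
                         weight_decay = config$weight_decay)
        enc <- upd$net; st <- upd$state
        losses <- c(losses, nce$loss)
      }
      history[ep] <- mean(losses)
    }
    list(encoder = enc, loss_history = history)
  })
}

# weighted binary cross-entropy fine-tuning of encoder (+) head
finetune_classifier <- function(net, X, y, config, freeze_layers = 0L) {
  n <- nrow(X)
  w_pos <- n / (2 * max(sum(y == 1), 1))
  w_neg <- n / (2 * max(sum(y == 0), 1))
  st <- adam_init(net)
  t_step <- 0L
  B <- min(config$batch_size, n)
  history <- numeric(config$finetune_epochs)
  for (ep in seq_len(config$finetune_epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = B)) {
      rows <- ord[start:min(start + B - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      if (config$finetune_noise_sd > 0) {
        Xb <- Xb + matrix(stats::rnorm(length(Xb),
                                       sd = config$finetune_noise_sd),
                          nrow(Xb))
      }
      yb <- y[rows]
      wb <- ifelse(yb == 1, w_pos, w_neg)
      fw <- mlp_forward(net, Xb)
      p <- 1 / (1 + exp(-fw$out[, 1L]))
      eps <- 1e-12
      loss <- -sum(wb * (yb * log(p + eps) + (1 - yb) * log(1 - p + eps))) / sum(wb)
      G <- matrix(wb * (p - yb) / sum(wb), ncol = 1L)
      g <- mlp_backward(net, fw$acts, G)
      if (freeze_layers > 0L) {
        for (i in seq_len(freeze_layers)) g[[i]] <- list(W = g[[i]]$W * 0,
                                                         b = g[[i]]$b * 0)
      }
      t_step <- t_step + 1L
      upd <- adam_step(net, g, st, config$finetune_lr, t_step,
                       weight_decay = config$weight_decay)
      net <- upd$net; st <- upd$state
      losses <- c(losses, loss)
    }
    history[ep] <- mean(losses)
  }
  list(net = net, loss_history = history)
}

# train one group-level scar classifier: standardize, then an ensemble of
# (pretrain -> finetune) replicates whose probabilities are averaged
train_group_model <- function(X, y, config, label_rows = NULL) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  if (length(unique(y[label_rows %||% seq_along(y)])) < 2L) {
    rate <- mean(y[label_rows %||% seq_along(y)])
    warnf("group has a single class; using a constant-probability model")
    m <- list(type = "constant", prob = rate, center = mu, scale = sdv,
              threshold = config$threshold)
    class(m) <- "scar_group_model"
    return(m)
  }
  rows <- label_rows %||% seq_along(y)
  nets <- vector("list", max(1L, config$n_ensemble))
  pre_hist <- NULL
  ft_hist <- NULL
  # pretraining is label-free representation learning and is shared across
  # the ensemble; members differ in head initialisation and fine-tuning
  # (the stage whose estimation variance the ensemble targets)
  if (config$no_self_supervised) {
    enc0 <- NULL
  } else {
    pt <- pretrain_encoder(Z, config)
    enc0 <- pt$encoder
    pre_hist <- pt$loss_history
  }
  for (k in seq_along(nets)) {
    cfg_k <- config
    cfg_k$seed <- child_seed(config$seed, paste0("member", k))
    enc <- enc0 %||% with_seed(cfg_k$seed,
                               mlp_init(c(ncol(X), config$encoder_hidden,
                                          config$embedding_dim)))
    head <- with_seed(child_seed(cfg_k$seed, "head"),
                      mlp_init(c(config$embedding_dim, config$head_hidden, 1L)))
    net <- mlp_stack(enc, head)
    ft <- with_seed(child_seed(cfg_k$seed, "finetune"), {
      finetune_classifier(net, Z[rows, , drop = FALSE], y[rows], cfg_k,
                          freeze_layers = if (config$freeze_encoder)
                            length(enc$layers) else 0L)
    })
    nets[[k]] <- ft$net
    if (k == 1L) ft_hist <- ft$loss_history
  }
  m <- list(type = "mlp", nets = nets, center = mu, scale = sdv,
            threshold = config$threshold,
            pretrain_loss = pre_hist, finetune_loss = ft_hist)
  class(m) <- "scar_group_model"
  m
}

# scar probability from a fitted group model (ensemble mean)
predict_group_prob <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (model$type == "constant") return(rep(model$prob, nrow(X)))
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  ps <- vapply(model$nets, function(net) {
    1 / (1 + exp(-mlp_forward(net, Z)$out[, 1L]))
  }, numeric(nrow(Z)))
  if (nrow(Z) == 1L) mean(ps) else rowMeans(matrix(ps, nrow(Z)))
}

#' Train the per-group, per-region scar models
#'
#' For each LV region and each merged patient group of that region's
#' partition: pretrain the encoder on all of the group's training rows
#' (label-free), attach the classification head, and fine-tune encoder and
#' head jointly on weighted cross-entropy. When `config$cv_grid` offers
#' more than one hyperparameter combination it is selected by 5-fold
#' cross-validation within the group. The `no_self_supervised` ablation
#' skips pretraining; the partition's `no_partitioning` ablation has every
#' patient in one group.
#'
#' @param partitions Named list (region -> `partition_model`) built on the
#'   training patients.
#' @param features Training feature matrix, one row per ECG (adjusted
#'   features during training).
#' @param meta data.frame aligned with `features`; needs `patient_id` and
#'   `label_<region>` columns.
#' @param config A `scarf_config`.
#' @return Object of class `regional_scar_models`.
#' @export
train_regional_models <- function(partitions, features, meta,
                                  config = scarf_config()) {
  stopifnot(all(scar_regions() %in% names(partitions)))
  features <- as.matrix(features)
  pid <- meta$patient_id
  ids <- sort(unique(pid))
  models <- list()
  for (region in scar_regions()) {
    part <- partitions[[region]]
    y_all <- meta[[paste0("label_", region)]]
    region_models <- list()
    for (g in seq_along(part$groups)) {
      member_ids <- ids[part$groups[[g]]$members]
      rows <- which(pid %in% member_ids)
      Xg <- features[rows, , drop = FALSE]
      yg <- y_all[rows]
      cfg_g <- select_group_config(Xg, yg, config,
                                   seed = child_seed(config$seed,
                                                     paste(region, g)))
      lab_rows <- labeled_rows(pid[rows], cfg_g$labeled_fraction,
                               child_seed(cfg_g$seed, "labels"))
      region_models[[g]] <- train_group_model(Xg, yg, cfg_g,
                                              label_rows = lab_rows)
    }
    models[[region]] <- region_models
  }
  out <- list(models = models, config = config,
              registry_hash = registry_hash())
  class(out) <- "regional_scar_models"
  out
}

# choose labeled rows by patient so replicate ECGs stay together
labeled_rows <- function(pid_rows, fraction, seed) {
  if (fraction >= 1) return(seq_along(pid_rows))
  ids <- unique(pid_rows)
  n_lab <- max(2L, round(fraction * length(ids)))
  keep <- with_seed(seed, sample(ids, min(n_lab, length(ids))))
  which(pid_rows %in% keep)
}

# 5-fold CV hyperparameter selection within a group (no-op for unit grids)
select_group_config <- function(X, y, config, seed) {
  cfg <- config
  cfg$seed <- seed
  grid <- expand.grid(
    finetune_lr = config$cv_grid$finetune_lr %||% config$finetune_lr,
    embedding_dim = config$cv_grid$embedding_dim %||% config$embedding_dim,
    finetune_epochs = config$cv_grid$finetune_epochs %||% config$finetune_epochs
  )
  if (nrow(grid) <= 1L) {
    cfg$finetune_lr <- grid$finetune_lr[1]
    cfg$embedding_dim <- as.integer(grid$embedding_dim[1])
    cfg$finetune_epochs <- as.integer(grid$finetune_epochs[1])
    return(cfg)
  }
  folds <- with_seed(child_seed(seed, "folds"),
                     sample(rep_len(1:5, nrow(X))))
  scores <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    cand <- cfg
    cand$finetune_lr <- grid$finetune_lr[gi]
    cand$embedding_dim <- as.integer(grid$embedding_dim[gi])
    cand$finetune_epochs <- as.integer(grid$finetune_epochs[gi])
    f1s <- c()
    for (f in 1:5) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) next
      m <- train_group_model(X[tr, , drop = FALSE], y[tr], cand)
      p <- predict_group_prob(m, X[!tr, , drop = FALSE])
      pred <- as.integer(p >= cand$threshold)
      tp <- sum(pred == 1 & y[!tr] == 1)
      f1 <- if (tp == 0) 0 else
        tp / (tp + 0.5 * (sum(pred == 1 & y[!tr] == 0) +
                            sum(pred == 0 & y[!tr] == 1)))
      f1s <- c(f1s, f1)
    }
    scores[gi] <- mean(f1s)
  }
  best <- which.max(scores)
  cfg$finetune_lr <- grid$finetune_lr[best]
  cfg$embedding_dim <- as.integer(grid$embedding_dim[best])
  cfg$finetune_epochs <- as.integer(grid$finetune_epochs[best])
  cfg
}

#' Predict regional and global LV scar
#'
#' Routes each ECG feature vector to its merged group per region, takes the
#' scar probability from that group's model, thresholds the regional
#' probabilities, and combines them with the inclusive OR rule for the
#' global call: a patient with scar predicted in at least one region is
#' globally scar-positive.
#'
#' @param models A `regional_scar_models`.
#' @param partitions Named list (region -> `partition_model`).
#' @param X Feature matrix (raw, unadjusted features), one row per ECG.
#' @return data.frame with per-region probabilities (`p_basal`, ...),
#'   regional booleans (`pred_basal`, ...), and `pred_global`.
#' @export
predict_scar <- function(models, partitions, X) {
  stopifnot(inherits(models, "regional_scar_models"))
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  out <- data.frame(row.names = seq_len(nrow(X)))
  for (region in scar_regions()) {
    if (is.null(models$models[[region]])) {
      stopf("no fitted models for region %s", region)
    }
    gid <- assign_group(partitions[[region]], X)
    p <- numeric(nrow(X))
    for (g in unique(gid)) {
      rows <- gid == g
      p[rows] <- predict_group_prob(models$models[[region]][[g]],
                                    X[rows, , drop = FALSE])
    }
    thr <- models$config$threshold
    out[[paste0("p_", region)]] <- p
    out[[paste0("pred_", region)]] <- as.integer(p >= thr)
    out[[paste0("group_", region)]] <- gid
  }
  out$pred_global <- as.integer(out$pred_basal | out$pred_mid | out$pred_apical)
  out
}
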