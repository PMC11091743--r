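#' Training configuration
#'
#' Defaults follow the published training recipe: AdaDelta (learning rate
#' 1.0, rho 0.9), batch size 256, 300 pretraining epochs on the ZINB loss,
#' joint training of the full objective
#' \code{L = L_ZINB + g1 L_DC + g2 L_Triplet + g3 L_Pairwise + g4 L_WCE}
#' until fewer than \code{stop_tol} of cells change hard label per epoch.
#'
#' @param gamma1,gamma2,gamma3,gamma4 nonnegative loss coefficients
#'   (deep clustering, triplet, pairwise, weighted cross-entropy).
#' @param pretrain_epochs epochs of ZINB-only denoising pretraining.
#' @param max_joint_epochs cap on joint-training epochs.
#' @param batch_size minibatch size.
#' @param lr,rho AdaDelta learning rate and decay.
#' @param stop_tol stop when the fraction of cells whose hard label changed
#'   since the previous epoch falls below this (in (0, 1]).
#' @param noise_sd sd of the additive Gaussian denoising corruption
#'   (pretraining only).
#' @param hidden,bottleneck encoder widths and latent dimension.
#' @param temperature,temp_decay,temp_floor Gaussian-kernel bandwidth of the
#'   soft K-means weights with geometric per-epoch annealing.
#' @param grad_clip cap on the global L2 norm of each update's gradient
#'   (guards the exponential decoder heads against optimizer overshoot);
#'   \code{Inf} disables.
#' @param seed master seed; every random draw in a run derives from it.
#' @return validated list of class \code{TrainConfig}.
#' @export
train_config <- function(gamma1 = 1, gamma2 = 1, gamma3 = 1, gamma4 = 1,
                         pretrain_epochs = 300, max_joint_epochs = 300,
                         batch_size = 256, lr = 1.0, rho = 0.9,
                         stop_tol = 0.001, noise_sd = 0.25,
                         hidden = c(256, 128), bottleneck = 32,
                         temperature = 1, temp_decay = 0.95,
                         temp_floor = 0.1, grad_clip = 5, seed = 0) {
  cfg <- list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
              gamma4 = gamma4, pretrain_epochs = as.integer(pretrain_epochs),
              max_joint_epochs = as.integer(max_joint_epochs),
              batch_size = as.integer(batch_size), lr = lr, rho = rho,
              stop_tol = stop_tol, noise_sd = noise_sd, hidden = hidden,
              bottleneck = bottleneck, temperature = temperature,
              temp_decay = temp_decay, temp_floor = temp_floor,
              grad_clip = grad_clip, seed = as.integer(seed))
  if (any(c(gamma1, gamma2, gamma3, gamma4) < 0)) stop("gammas must be >= 0")
  if (cfg$pretrain_epochs < 1 || cfg$max_joint_epochs < 1)
    stop("epoch counts must be >= 1")
  if (stop_tol <= 0 || stop_tol > 1) stop("stop_tol must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(cfg, class = "TrainConfig")
}

#' Read a TrainConfig from a YAML file
#'
#' @param path YAML file whose keys mirror \code{\link{train_config}}
#'   arguments.
#' @return a \code{TrainConfig}.
#' @export
train_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(train_config)))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(train_config, vals)
}

minibatches <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

# forward + full backward of the ZINB reconstruction loss on one batch
zinb_pass <- function(model, x_in, x_raw, sf, corrupt_sd = 0) {
  enc <- zae_encode(model, x_in, corrupt_sd)
  dec <- zae_decode(model, enc$z, sf)
  g <- zinb_fused(x_raw, dec$pi, dec$mu, dec$theta)
  db <- zae_decoder_grad(model, dec$cache, g$dpi, g$dmu, g$dtheta)
  list(loss = g$loss, dec_grads = db$grads, dz = db$dz, enc = enc)
}

#' Pretrain the ZINB denoising autoencoder
#'
#' Minimizes the ZINB negative log-likelihood alone, with additive Gaussian
#' corruption of the standardized input (the raw-count target is never
#' corrupted).
#'
#' @param data a \code{\link{preprocess}} result.
#' @param cfg a \code{\link{train_config}}.
#' @return list of class \code{zc_pretrain}: \code{model}, \code{opt}
#'   (AdaDelta state), \code{loss_history} (mean batch NLL per epoch),
#'   \code{cfg}.
#' @export
zc_pretrain <- function(data, cfg = train_config()) {
  stopifnot(inherits(data, "PreprocessedData"))
  model <- zae_new(ncol(data$x_input), cfg$hidden, cfg$bottleneck,
                   seed = cfg$seed)
  # GLM-style intercept: start the mean head at the per-gene log mean of the
  # size-factor-normalized counts so the decoder opens on the count scale
  gene_mean <- colMeans(data$x_raw / data$size_factors)
  model$params$head_b_mu <- log(pmax(gene_mean, 1e-8))
  opt <- adadelta_new(model$params, rho = cfg$rho)
  n <- nrow(data$x_input)
  set.seed(cfg$seed)
  # fixed clean-input evaluation subset: the logged curve is free of
  # corruption noise
  eval_idx <- seq_len(min(n, 200L))
  hist <- numeric(cfg$pretrain_epochs)
  for (ep in seq_len(cfg$pretrain_epochs)) {
    for (b in minibatches(n, cfg$batch_size)) {
      ps <- zinb_pass(model, data$x_input[b, , drop = FALSE],
                      data$x_raw[b, , drop = FALSE],
                      data$size_factors[b], cfg$noise_sd)
      if (!is.finite(ps$loss))
        stop("non-finite ZINB loss in pretraining epoch ", ep,
             " (batch of ", length(b), " cells)")
      ge <- zae_encoder_grad(model, ps$enc$cache, ps$dz)
      st <- adadelta_step(opt, model$params,
                          clip_grads(c(ps$dec_grads, ge), cfg$grad_clip),
                          cfg$lr)
      model$params <- st$params; opt <- st$opt
    }
    ez <- zae_encode(model, data$x_input[eval_idx, , drop = FALSE])
    ed <- zae_decode(model, ez$z, data$size_factors[eval_idx])
    hist[ep] <- zinb_nll(data$x_raw[eval_idx, , drop = FALSE],
                         ed$pi, ed$mu, ed$theta)
  }
  structure(list(model = model, opt = opt, loss_history = hist, cfg = cfg),
            class = "zc_pretrain")
}

# full-dataset loss components at the current state (clean encoding)
zc_eval_losses <- function(model, data, centers, temperature, P, constraints,
                           mapping, cfg) {
  z <- zae_encode(model, data$x_input)$z
  dec <- zae_decode(model, z, data$size_factors)
  zinb <- zinb_nll(data$x_raw, dec$pi, dec$mu, dec$theta)
  skm <- soft_kmeans_loss(z, centers, temperature)
  Q <- soft_assign(z, centers)
  kl <- kl_loss(P, Q)
  tri <- pwc <- wce <- 0
  cs <- constraints
  if (!is.null(cs) && length(cs$labeled_idx) > 0) {
    if (!is.null(cs$triplets))
      tri <- triplet_loss(Q, cs$triplets, cs$margin, cs$triplet_form)
    lidx <- cs$labeled_idx
    # cap the logged pairwise evaluation near 1e5 pairs
    if (length(lidx) > 316) {
      sub <- sort(sample(seq_along(lidx), 316))
    } else sub <- seq_along(lidx)
    pwc <- pairwise_loss(pairwise_similarity(Q[lidx[sub], , drop = FALSE]),
                         cs$Y[sub, sub, drop = FALSE])
    if (!is.null(mapping))
      wce <- weighted_ce_loss(Q[lidx, , drop = FALSE], cs$labels, mapping,
                              cs$class_weights)
  }
  total <- zinb + cfg$gamma1 * (skm$loss + kl) + cfg$gamma2 * tri +
    cfg$gamma3 * pwc + cfg$gamma4 * wce
  list(zinb = zinb, soft_k = skm$loss, kl = kl, triplet = tri,
       pairwise = pwc, wce = wce, total = total)
}

#' Fit the semisupervised deep clustering model
#'
#' Starting from a pretrained autoencoder, initializes K cluster centers in
#' the latent space (anchored to labeled-class centroids when labels are
#' available) and then jointly optimizes the encoder, decoder, and centers
#' under the full objective. Each epoch refreshes the target distribution P
#' and the cluster-to-class alignment; each minibatch contributes the ZINB
#' and deep-clustering terms on its cells plus the constraint terms on a
#' same-size random draw of triplets and labeled cells. Training stops when
#' the fraction of cells changing hard label drops below \code{stop_tol}.
#'
#' @param data a \code{\link{preprocess}} result.
#' @param K number of clusters (>= 2).
#' @param constraints a \code{\link{constraint_set}} or \code{NULL} for fully
#'   unsupervised fitting.
#' @param cfg a \code{\link{train_config}}.
#' @param pretrained optional \code{\link{zc_pretrain}} result to start from;
#'   computed here when missing.
#' @return list of class \code{zc_fit}: \code{hard_labels}, \code{Q},
#'   \code{z}, \code{centers}, \code{mapping}, \code{loss_history}
#'   (data.frame per epoch), \code{epochs_run}, \code{model},
#'   \code{pretrain_history}, \code{cfg}.
#' @export
zc_fit <- function(data, K, constraints = NULL, cfg = train_config(),
                   pretrained = NULL) {
  stopifnot(inherits(data, "PreprocessedData"))
  if (K < 2) stop("K must be >= 2")
  if (is.null(pretrained)) pretrained <- zc_pretrain(data, cfg)
  model <- pretrained$model
  n <- nrow(data$x_input)
  cs <- constraints
  has_labels <- !is.null(cs) && length(cs$labeled_idx) > 0

  z0 <- zae_encode(model, data$x_input)$z
  centers <- init_centers(z0, K, seed = cfg$seed + 1L,
                          labeled = if (has_labels)
                            list(idx = cs$labeled_idx, labels = cs$labels))
  params <- c(model$params, list(centers = centers))
  opt <- adadelta_new(params, rho = cfg$rho)
  temp <- cfg$temperature
  set.seed(cfg$seed + 2L)

  prev_hard <- NULL
  hist <- list()
  epochs_run <- 0L
  mapping <- NULL
  for (ep in seq_len(cfg$max_joint_epochs)) {
    model$params <- params[names(model$params)]
    centers <- params$centers
    z <- zae_encode(model, data$x_input)$z
    Q <- soft_assign(z, centers)
    hard <- max.col(Q)
    # reseed hard-empty clusters to the cell farthest from its nearest center
    empty <- setdiff(seq_len(K), unique(hard))
    if (length(empty) > 0) {
      d2 <- sqdist(z, centers)
      far <- order(apply(d2, 1, min), decreasing = TRUE)
      for (i in seq_along(empty)) {
        centers[empty[i], ] <- z[far[i], ]
        message("epoch ", ep, ": reseeded empty cluster ", empty[i])
      }
      params$centers <- centers
      Q <- soft_assign(z, centers)
      hard <- max.col(Q)
    }
    P <- target_distribution(Q)
    if (has_labels)
      mapping <- align_clusters(Q[cs$labeled_idx, , drop = FALSE], cs$labels)

    change <- if (is.null(prev_hard)) NA_real_ else mean(hard != prev_hard)
    ev <- zc_eval_losses(model, data, centers, temp, P, cs, mapping, cfg)
    hist[[ep]] <- c(epoch = ep, unlist(ev), label_change = change)
    if (!is.null(prev_hard) && change < cfg$stop_tol) {
      epochs_run <- ep
      break
    }
    prev_hard <- hard
    epochs_run <- ep

    for (b in minibatches(n, cfg$batch_size)) {
      grads <- NULL
      # --- pass 1: ZINB + deep clustering on the batch cells -------------
      ps <- zinb_pass(model, data$x_input[b, , drop = FALSE],
                      data$x_raw[b, , drop = FALSE], data$size_factors[b])
      if (!is.finite(ps$loss))
        stop("non-finite ZINB loss in joint epoch ", ep)
      dz <- ps$dz
      grads <- grad_add(grads, ps$dec_grads)
      if (cfg$gamma1 > 0) {
        zb <- ps$enc$z
        skm <- soft_kmeans_loss(zb, params$centers, temp)
        gs <- soft_kmeans_grad(zb, params$centers, skm$omega)
        Qb <- soft_assign(zb, params$centers)
        ga <- soft_assign_grad(zb, params$centers,
                               kl_loss_qgrad(P[b, , drop = FALSE], Qb))
        dz <- dz + cfg$gamma1 * (gs$dz + ga$dz)
        grads <- grad_add(grads, list(
          centers = cfg$gamma1 * (gs$dcenters + ga$dcenters)))
      }
      grads <- grad_add(grads, zae_encoder_grad(model, ps$enc$cache, dz))

      # --- pass 2: triplet term on a same-size draw of triplets ----------
      if (has_labels && cfg$gamma2 > 0 && !is.null(cs$triplets)) {
        take <- sample.int(nrow(cs$triplets),
                           min(cfg$batch_size, nrow(cs$triplets)))
        tri <- cs$triplets[take, , drop = FALSE]
        cells <- unique(as.vector(tri))
        local <- matrix(match(tri, cells), ncol = 3)
        enc_t <- zae_encode(model, data$x_input[cells, , drop = FALSE])
        Qt <- soft_assign(enc_t$z, params$centers)
        tg <- triplet_loss_grad(Qt, local, cs$margin, cs$triplet_form)
        if (any(tg$dQ != 0)) {
          gq <- soft_assign_grad(enc_t$z, params$centers,
                                 cfg$gamma2 * tg$dQ)
          grads <- grad_add(grads, zae_encoder_grad(model, enc_t$cache,
                                                    gq$dz))
          grads <- grad_add(grads, list(centers = gq$dcenters))
        }
      }

      # --- pass 3: pairwise + weighted CE on a labeled draw --------------
      if (has_labels && (cfg$gamma3 > 0 || cfg$gamma4 > 0)) {
        nl <- length(cs$labeled_idx)
        sub <- sort(sample.int(nl, min(cfg$batch_size, nl)))
        cells <- cs$labeled_idx[sub]
        enc_l <- zae_encode(model, data$x_input[cells, , drop = FALSE])
        Ql <- soft_assign(enc_l$z, params$centers)
        dQl <- Ql * 0
        if (cfg$gamma3 > 0 && length(sub) >= 2) {
          pg <- pairwise_loss_grad(Ql, cs$Y[sub, sub, drop = FALSE])
          dQl <- dQl + cfg$gamma3 * pg$dQ
        }
        if (cfg$gamma4 > 0 && !is.null(mapping)) {
          wg <- weighted_ce_grad(Ql, cs$labels[sub], mapping,
                                 cs$class_weights)
          dQl <- dQl + cfg$gamma4 * wg$dQ
        }
        if (any(dQl != 0)) {
          gq <- soft_assign_grad(enc_l$z, params$centers, dQl)
          grads <- grad_add(grads, zae_encoder_grad(model, enc_l$cache,
                                                    gq$dz))
          grads <- grad_add(grads, list(centers = gq$dcenters))
        }
      }

      st <- adadelta_step(opt, params, clip_grads(grads, cfg$grad_clip),
                          cfg$lr)
      params <- st$params; opt <- st$opt
      model$params <- params[names(model$params)]
    }
    temp <- max(cfg$temp_floor, temp * cfg$temp_decay)
  }

  model$params <- params[names(model$params)]
  centers <- params$centers
  z <- zae_encode(model, data$x_input)$z
  Q <- soft_assign(z, centers)
  hist_df <- as.data.frame(do.call(rbind, hist))
  structure(list(hard_labels = max.col(Q), Q = Q, z = z, centers = centers,
                 mapping = mapping, loss_history = hist_df,
                 epochs_run = epochs_run, model = model,
                 pretrain_history = pretrained$loss_history, cfg = cfg),
            class = "zc_fit")
}

#' @export
print.zc_fit <- function(x, ...) {
  cat("zc_fit: ", length(x$hard_labels), " cells, K = ", ncol(x$Q),
      ", ", x$epochs_run, " joint epochs\n", sep = "")
  cat("  cluster sizes:", paste(tabulate(x$hard_labels, ncol(x$Q)),
                                collapse = " "), "\n")
  invisible(x)
}

arm_settings <- function(arm, cfg) {
  switch(arm,
         complete    = list(cfg = cfg, use_constraints = TRUE),
         no_label    = {
           cfg$gamma2 <- cfg$gamma3 <- cfg$gamma4 <- 0
           list(cfg = cfg, use_constraints = FALSE)
         },
         no_triplet  = { cfg$gamma2 <- 0; list(cfg = cfg,
                                               use_constraints = TRUE) },
         no_pairwise = { cfg$gamma3 <- 0; list(cfg = cfg,
                                               use_constraints = TRUE) },
         no_ce       = { cfg$gamma4 <- 0; list(cfg = cfg,
                                               use_constraints = TRUE) },
         stop("unknown arm '", arm, "'"))
}

#' Run the loss-removal ablation and hyperparameter sweeps
#'
#' Arms: the complete model, removal of one constraint loss at a time
#' (\code{no_triplet}, \code{no_pairwise}, \code{no_ce}), and fully
#' unsupervised \code{no_label}. Optional sweeps over the labeled fraction
#' and the triplet count add one arm per value. Pretraining is shared across
#' arms within a seed (it does not depend on the constraints).
#'
#' @param data a \code{\link{preprocess}} result with \code{labels} present.
#' @param arms character vector of arm names.
#' @param seeds integer seeds; each seed is a full train run.
#' @param K number of clusters.
#' @param cfg base \code{\link{train_config}} (its \code{seed} is replaced
#'   per run).
#' @param labeled_fraction,n_triplets constraint-set parameters for the
#'   non-sweep arms.
#' @param labeled_fractions optional numeric vector: adds arms
#'   \code{"r=<f>"} with the complete model at each labeled fraction.
#' @param triplet_counts optional integer vector: adds arms
#'   \code{"triplets=<t>"}.
#' @return data.frame with columns arm, seed, nmi, ari, ami, acc,
#'   epochs_run.
#' @export
zc_ablation <- function(data, arms = c("complete", "no_label", "no_triplet",
                                       "no_pairwise", "no_ce"),
                        seeds = 0:4, K, cfg = train_config(),
                        labeled_fraction = 0.10, n_triplets = 10000,
                        labeled_fractions = NULL, triplet_counts = NULL) {
  stopifnot(inherits(data, "PreprocessedData"))
  if (is.null(data$labels)) stop("ablation requires true labels in data")
  truth <- data$labels
  runs <- data.frame(arm = character(0), r = numeric(0), nt = numeric(0))
  for (a in arms) runs <- rbind(runs, data.frame(arm = a,
                                                 r = labeled_fraction,
                                                 nt = n_triplets))
  for (f in labeled_fractions)
    runs <- rbind(runs, data.frame(arm = sprintf("r=%g", f), r = f,
                                   nt = n_triplets))
  for (t in triplet_counts)
    runs <- rbind(runs, data.frame(arm = sprintf("triplets=%d", t),
                                   r = labeled_fraction, nt = t))
  out <- list()
  for (seed in seeds) {
    cfg_s <- cfg; cfg_s$seed <- as.integer(seed)
    pre <- zc_pretrain(data, cfg_s)
    for (i in seq_len(nrow(runs))) {
      arm <- runs$arm[i]
      base_arm <- if (grepl("^r=", arm)) {
        if (runs$r[i] == 0) "no_label" else "complete"
      } else if (grepl("^triplets=", arm)) {
        if (runs$nt[i] == 0) "no_triplet" else "complete"
      } else arm
      as <- arm_settings(base_arm, cfg_s)
      cs <- if (as$use_constraints)
        constraint_set(truth, labeled_fraction = runs$r[i],
                       n_triplets = runs$nt[i], seed = as.integer(seed))
      fit <- zc_fit(data, K, constraints = cs, cfg = as$cfg,
                    pretrained = pre)
      m <- cluster_metrics(truth, fit$hard_labels)
      out[[length(out) + 1]] <- data.frame(arm = arm, seed = seed,
                                           nmi = m["nmi"], ari = m["ari"],
                                           ami = m["ami"], acc = m["acc"],
                                           epochs_run = fit$epochs_run,
                                           row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Coordinate grid search over the loss coefficients
#'
#' Varies one gamma at a time over \code{grid} with the others at their
#' \code{cfg} values, reporting clustering agreement against the true
#' labels.
#'
#' @param data a \code{\link{preprocess}} result with labels.
#' @param K number of clusters.
#' @param grid candidate values for each gamma (default 0.01, 0.1, 1).
#' @param cfg base \code{\link{train_config}}.
#' @param labeled_fraction,n_triplets constraint-set parameters.
#' @return data.frame with columns gamma, value, nmi, ari, ami, acc.
#' @export
zc_grid_search <- function(data, K, grid = c(0.01, 0.1, 1),
                           cfg = train_config(), labeled_fraction = 0.10,
                           n_triplets = 10000) {
  if (is.null(data$labels)) stop("grid search requires true labels in data")
  pre <- zc_pretrain(data, cfg)
  cs <- constraint_set(data$labels, labeled_fraction, n_triplets,
                       seed = cfg$seed)
  out <- list()
  for (g in c("gamma1", "gamma2", "gamma3", "gamma4")) {
    for (v in grid) {
      cfg_g <- cfg; cfg_g[[g]] <- v
      fit <- zc_fit(data, K, constraints = cs, cfg = cfg_g, pretrained = pre)
      m <- cluster_metrics(data$labels, fit$hard_labels)
      out[[length(out) + 1]] <- data.frame(gamma = g, value = v,
                                           nmi = m["nmi"], ari = m["ari"],
                                           ami = m["ami"], acc = m["acc"],
                                           row.names = NULL)
    }
  }
  do.call(rbind, out)
}
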