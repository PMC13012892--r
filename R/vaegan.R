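#' Graph VAE-GAN configuration
#'
#' Architecture and training regime of the weak-binder decoy generator: a
#' two-layer GCN encoder to a 16-dimensional Gaussian latent, per-size-
#' bucket decoders emitting adjacency, node-feature and edge-feature
#' blocks, and a Wasserstein critic on the flattened concatenation of those
#' blocks, trained with weight clipping (gradient penalty available via
#' `gp_weight`), noise injection on critic inputs and an optional
#' feature-matching term.
#'
#' @param latent_dim Latent dimensionality (16).
#' @param hidden_dim Hidden width (64); must exceed `latent_dim`.
#' @param lr_encdec Encoder-decoder learning rate (1e-3).
#' @param lr_disc Critic learning rate (1e-4); must be below `lr_encdec`.
#' @param clip_value Critic weight-clipping bound.
#' @param gp_weight Gradient-penalty coefficient (0 = clipping-only).
#' @param adversarial Enable the critic; with `FALSE` training reduces to a
#'   plain graph VAE (reconstruction + KL only).
#' @param feature_matching Add a critic-feature matching term to the
#'   generator loss.
#' @param n_critic Critic updates per generator update.
#' @param noise_sd Gaussian noise injected into critic inputs.
#' @param size_bucket_width Node-count width of each decoder bucket.
#' @param w_adj,w_node,w_edge,w_kl Reconstruction-loss weights (adjacency
#'   cross-entropy, node/edge squared error, KL).
#' @param max_epochs,early_stop_patience Training schedule; early stopping
#'   on convergence of the smoothed reconstruction loss.
#' @param batch_size Graphs per mini-batch.
#' @param seed RNG seed for all training randomness.
#' @return List of class `gan_config`.
#' @export
gan_config <- function(latent_dim = 16, hidden_dim = 64,
                       lr_encdec = 1e-3, lr_disc = 1e-4,
                       clip_value = 0.01, gp_weight = 0,
                       adversarial = TRUE,
                       feature_matching = FALSE, n_critic = 5,
                       noise_sd = 0.05, size_bucket_width = 10,
                       w_adj = 1, w_node = 1, w_edge = 1, w_kl = 0.1,
                       max_epochs = 60, early_stop_patience = 8,
                       batch_size = 8, seed = 1) {
  stopifnot(latent_dim < hidden_dim, lr_disc < lr_encdec, clip_value > 0,
            gp_weight >= 0)
  structure(as.list(environment()), class = "gan_config")
}

# upper-triangle pair index for padded size P
.pair_index <- function(P) {
  ut <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)
  ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
}

# pad one graph into bucket tensors: adjacency vector over the upper
# triangle, zero-padded node features, pair-indexed edge features, node mask
.pad_graph <- function(g, P, pairs) {
  n <- n_nodes(g)
  stopifnot(n <= P)
  Fn <- ncol(g$node_feats); Fe <- ncol(g$edge_feats)
  adj <- numeric(nrow(pairs))
  ef <- matrix(0, nrow(pairs), Fe)
  if (n_edges(g)) {
    eid <- match(paste(g$edge_index[1, ], g$edge_index[2, ]),
                 paste(pairs[, 1], pairs[, 2]))
    adj[eid] <- 1
    ef[eid, ] <- g$edge_feats
  }
  nf <- rbind(g$node_feats, matrix(0, P - n, Fn))
  mask <- c(rep(1, n), rep(0, P - n))
  pairmask <- mask[pairs[, 1]] * mask[pairs[, 2]]
  list(adj = adj, nf = nf, ef = ef, mask = mask, pairmask = pairmask, n = n)
}

.flatten_padded <- function(pg) {
  c(pg$adj, as.vector(pg$nf), as.vector(pg$ef), pg$mask)
}

# ---- encoder -------------------------------------------------------------

gcn_init <- function(n_feats, n_efeats, cfg) {
  h <- cfg$hidden_dim; z <- cfg$latent_dim
  P <- list()
  P <- nn_add_linear(P, "gcn1.self", n_feats, h)
  P <- nn_add_linear(P, "gcn1.nbr", n_feats, h, bias = FALSE)
  P <- nn_add_linear(P, "gcn1.edge", max(1, n_efeats), h, bias = FALSE)
  P <- nn_add_linear(P, "gcn2.self", h, h)
  P <- nn_add_linear(P, "gcn2.nbr", h, h, bias = FALSE)
  P <- nn_add_linear(P, "gcn2.edge", max(1, n_efeats), h, bias = FALSE)
  P <- nn_add_linear(P, "mu", h, z)
  P <- nn_add_linear(P, "logvar", h, z)
  P
}

# two GCN layers with edge attributes embedded and added to the neighbour
# messages, then global mean pooling to mu / logvar
gcn_encode <- function(Pn, g, cfg) {
  N <- n_nodes(g)
  x <- ag_const(g$node_feats)
  ne <- n_edges(g)
  if (ne > 0) {
    src <- c(g$edge_index[1, ], g$edge_index[2, ])
    dst <- c(g$edge_index[2, ], g$edge_index[1, ])
    ef <- ag_const(rbind(g$edge_feats, g$edge_feats))
  }
  layer <- function(hh, tag) {
    self <- nn_linear(Pn, paste0(tag, ".self"), hh)
    if (ne > 0) {
      msg <- ag_mm(ag_rows(hh, src), Pn[[paste0(tag, ".nbr.W")]])
      if (ncol(g$edge_feats) > 0) {
        msg <- ag_add(msg, ag_mm(ef, Pn[[paste0(tag, ".edge.W")]]))
      }
      agg <- ag_group_mean(msg, dst, N)
      self <- ag_add(self, agg)
    }
    ag_relu(self)
  }
  h1 <- layer(x, "gcn1")
  h2 <- layer(h1, "gcn2")
  pooled <- ag_group_mean(h2, rep(1L, N), 1L)
  list(mu = nn_linear(Pn, "mu", pooled),
       logvar = nn_linear(Pn, "logvar", pooled))
}

#' Encode an interface graph into the VAE latent space
#'
#' Two graph-convolution layers (edge attributes embedded and added to the
#' neighbour messages), global mean pooling, and linear heads for the mean
#' and log-variance of the latent Gaussian. In deterministic mode the
#' latent code equals the mean; otherwise `z = mu + exp(logvar/2) * eps`.
#'
#' @param g A non-empty, feature-normalised `interface_graph`.
#' @param model A trained `gan_model` (or a list with `enc_params`, `cfg`).
#' @param deterministic Use `z = mu` (default TRUE).
#' @return List with `mu`, `logvar`, `z` and the stored `eps`.
#' @export
gan_encode <- function(g, model, deterministic = TRUE) {
  if (n_nodes(g) == 0) stop("cannot encode an empty graph")
  Pn <- nn_wrap(model$enc_params)
  out <- gcn_encode(Pn, g, model$cfg)
  mu <- as.vector(ag_value(out$mu))
  logvar <- as.vector(ag_value(out$logvar))
  eps <- if (deterministic) rep(0, length(mu)) else stats::rnorm(length(mu))
  list(mu = mu, logvar = logvar, z = mu + exp(logvar / 2) * eps, eps = eps)
}

# ---- decoder -------------------------------------------------------------

dec_init <- function(P, Fn, Fe, cfg, params = list(), tag = "dec") {
  npair <- P * (P - 1) / 2
  h <- cfg$hidden_dim
  params <- nn_add_linear(params, paste0(tag, ".h1"), cfg$latent_dim, h)
  params <- nn_add_linear(params, paste0(tag, ".h2"), h, h)
  params <- nn_add_linear(params, paste0(tag, ".adj"), h, npair)
  params <- nn_add_linear(params, paste0(tag, ".node"), h, P * Fn)
  params <- nn_add_linear(params, paste0(tag, ".edge"), h, max(1, npair * Fe))
  params
}

# decode a batch of latent rows Z (B x latent) with one bucket's decoder;
# returns ag nodes of adjacency logits, node features, edge features
dec_forward <- function(Pn, Z, tag = "dec") {
  hid <- ag_relu(nn_linear(Pn, paste0(tag, ".h2"),
                           ag_relu(nn_linear(Pn, paste0(tag, ".h1"), Z))))
  list(adj_logits = nn_linear(Pn, paste0(tag, ".adj"), hid),
       node = nn_linear(Pn, paste0(tag, ".node"), hid),
       edge = nn_linear(Pn, paste0(tag, ".edge"), hid))
}

#' Decode a latent vector into a padded graph
#'
#' Deterministic mapping from a latent code to adjacency probabilities (a
#' symmetric matrix with zero diagonal, parameterised on the upper
#' triangle), a node-feature matrix and an edge-feature block for one size
#' bucket. Discretisation at 0.5 plus masking to a node count yields a
#' simple undirected graph.
#'
#' @param z Latent vector.
#' @param model A trained `gan_model`.
#' @param bucket Bucket id (see `model$buckets`).
#' @return List with `adj_prob` (P x P), `node_feats` (P x Fn),
#'   `edge_feats` (npair x Fe), `pairs` (upper-triangle index).
#' @export
gan_decode <- function(z, model, bucket) {
  bk <- model$buckets[[as.character(bucket)]]
  if (is.null(bk)) stop("unknown size bucket: ", bucket)
  Pn <- nn_wrap(model$dec_params[[as.character(bucket)]])
  Z <- matrix(z, nrow = 1)
  out <- dec_forward(Pn, ag_const(Z))
  P <- bk$padded_size
  pairs <- .pair_index(P)
  aprob <- 1 / (1 + exp(-as.vector(ag_value(out$adj_logits))))
  A <- matrix(0, P, P)
  A[pairs] <- aprob
  A <- A + t(A)
  nf <- matrix(ag_value(out$node), P, model$n_feats,
               dimnames = list(NULL, model$feat_names))
  ef <- matrix(ag_value(out$edge), nrow(pairs), model$n_efeats,
               dimnames = list(NULL, model$efeat_names))
  list(adj_prob = A, node_feats = nf, edge_feats = ef, pairs = pairs)
}

# ---- critic --------------------------------------------------------------

critic_init <- function(D, cfg, params = list(), tag = "crit") {
  h <- cfg$hidden_dim
  params <- nn_add_linear(params, paste0(tag, ".h1"), D, h)
  params <- nn_add_linear(params, paste0(tag, ".h2"), h, h)
  params <- nn_add_linear(params, paste0(tag, ".out"), h, 1)
  params
}

critic_forward <- function(Pn, X, tag = "crit") {
  h1 <- ag_relu(nn_linear(Pn, paste0(tag, ".h1"), X))
  h2 <- ag_relu(nn_linear(Pn, paste0(tag, ".h2"), h1))
  list(score = nn_linear(Pn, paste0(tag, ".out"), h2), features = h2)
}

# analytic input-gradient norm of the ReLU-MLP critic at given inputs,
# expressed through the weight parameters (activation masks held fixed) so
# the gradient penalty itself is differentiable w.r.t. the critic weights
critic_grad_norm <- function(Pn, Xhat, tag = "crit") {
  W1 <- Pn[[paste0(tag, ".h1.W")]]; b1 <- Pn[[paste0(tag, ".h1.b")]]
  W2 <- Pn[[paste0(tag, ".h2.W")]]; b2 <- Pn[[paste0(tag, ".h2.b")]]
  W3 <- Pn[[paste0(tag, ".out.W")]]
  a1 <- ag_value(ag_add(ag_mm(ag_const(Xhat), W1), b1))
  m1 <- (a1 > 0) * 1
  a2 <- pmax(a1, 0) %*% ag_value(W2) + matrix(ag_value(b2),
                                              nrow(Xhat), ncol(ag_value(W2)),
                                              byrow = TRUE)
  m2 <- (a2 > 0) * 1
  B <- nrow(Xhat)
  ones <- ag_const(matrix(1, B, 1))
  w3row <- ag_mm(ones, ag_t(W3))                       # B x h
  g2 <- ag_mul(w3row, ag_const(m2))
  g1 <- ag_mul(ag_mm(g2, ag_t(W2)), ag_const(m1))
  gx <- ag_mm(g1, ag_t(W1))                            # B x D
  ag_sqrt(ag_add(ag_rowsums(ag_mul(gx, gx)),
                 ag_const(matrix(1e-12, B, 1))))
}

#' @rdname ag_ops
#' @export
ag_t <- function(a) {
  a <- .ag_coerce(a)
  .ag_new(t(a$val), list(a), list(function(g) t(g)))
}

#' One Wasserstein-critic evaluation
#'
#' Computes the critic objective on matched real and generated flattened
#' batches: `mean score(fake) - mean score(real)` plus `gp_weight` times
#' the gradient penalty on interpolates. Used inside [train_gan()]; exposed
#' for inspection and testing.
#'
#' @param real_flat,fake_flat Matrices (batch x flattened dimension).
#' @param crit_params Critic parameter list.
#' @param cfg A [gan_config()].
#' @return List with `critic_loss`, `wasserstein` (fake minus real mean
#'   score) and `gp`.
#' @export
wgan_critic_objective <- function(real_flat, fake_flat, crit_params, cfg) {
  if (ncol(real_flat) != ncol(fake_flat)) {
    stop("mismatched flattened lengths: ", ncol(real_flat), " vs ",
         ncol(fake_flat))
  }
  Pn <- nn_wrap(crit_params)
  sr <- ag_mean(critic_forward(Pn, ag_const(real_flat))$score)
  sf <- ag_mean(critic_forward(Pn, ag_const(fake_flat))$score)
  wass <- ag_value(sf)[1] - ag_value(sr)[1]
  loss <- ag_sub(sf, sr)
  gp <- 0
  if (cfg$gp_weight > 0) {
    alpha <- stats::runif(nrow(real_flat))
    xhat <- real_flat * alpha + fake_flat * (1 - alpha)
    gn <- critic_grad_norm(Pn, xhat)
    gp_node <- ag_mse(gn, matrix(1, nrow(xhat), 1))
    gp <- ag_value(gp_node)[1]
    loss <- ag_add(loss, ag_scale(gp_node, cfg$gp_weight))
  }
  list(loss_node = loss, Pn = Pn, critic_loss = ag_value(loss)[1],
       wasserstein = wass, gp = gp)
}

# ---- training ------------------------------------------------------------

.bucket_of <- function(n, width) (n %/% width) * width

#' Train the graph VAE-GAN on weak-binding interface graphs
#'
#' The generator is trained exclusively on experimentally weak-binding
#' graphs (passing a strong-labelled graph is an error). Graphs are
#' partitioned into node-count buckets, each with its own decoder and
#' critic; the shared GCN encoder is trained across buckets. Each
#' mini-batch performs `n_critic` critic updates (weight clipping after
#' each, Gaussian noise injected into critic inputs) followed by one
#' encoder-decoder update minimising adjacency cross-entropy, node/edge
#' feature squared error, the KL term and the adversarial score (plus the
#' optional feature-matching term). Early stopping monitors the smoothed
#' reconstruction loss.
#'
#' @param weak_graphs List of feature-normalised `interface_graph`s all
#'   labelled `weak_exp`.
#' @param cfg A [gan_config()].
#' @param verbose Print per-epoch losses.
#' @return A `gan_model`: encoder/decoder/critic parameters, bucket
#'   registry (with node-count frequencies), config and loss history.
#' @export
train_gan <- function(weak_graphs, cfg = gan_config(), verbose = FALSE) {
  labs <- vapply(weak_graphs, function(g) g$label %||% NA_character_,
                 character(1))
  if (any(labs %in% c("strong"))) {
    stop("train_gan is restricted to weak-binding graphs; got a strong label")
  }
  if (any(!is.na(labs) & labs != "weak_exp")) {
    stop("train_gan expects graphs labelled weak_exp")
  }
  set.seed(cfg$seed)
  Fn <- ncol(weak_graphs[[1]]$node_feats)
  Fe <- ncol(weak_graphs[[1]]$edge_feats)
  sizes <- vapply(weak_graphs, n_nodes, integer(1))
  bks <- .bucket_of(sizes, cfg$size_bucket_width)
  buckets <- list()
  for (b in sort(unique(bks))) {
    buckets[[as.character(b)]] <- list(
      lo = b, hi = b + cfg$size_bucket_width,
      padded_size = b + cfg$size_bucket_width - 1,
      node_counts = sizes[bks == b],
      freq = sum(bks == b) / length(sizes)
    )
  }
  enc_params <- gcn_init(Fn, Fe, cfg)
  dec_params <- list(); crit_params <- list()
  for (bn in names(buckets)) {
    P <- buckets[[bn]]$padded_size
    npair <- P * (P - 1) / 2
    D <- npair + P * Fn + npair * Fe + P
    dec_params[[bn]] <- dec_init(P, Fn, Fe, cfg)
    crit_params[[bn]] <- critic_init(D, cfg)
    buckets[[bn]]$flat_dim <- D
  }
  enc_state <- rmsprop_init(enc_params)
  dec_state <- lapply(dec_params, rmsprop_init)
  crit_state <- lapply(crit_params, rmsprop_init)

  padded <- lapply(seq_along(weak_graphs), function(i) {
    bn <- as.character(bks[i])
    .pad_graph(weak_graphs[[i]], buckets[[bn]]$padded_size,
               .pair_index(buckets[[bn]]$padded_size))
  })
  history <- data.frame(epoch = integer(0), recon = numeric(0),
                        kl = numeric(0), critic = numeric(0),
                        gen_adv = numeric(0))
  best <- Inf; wait <- 0
  smooth <- numeric(0)

  for (epoch in seq_len(cfg$max_epochs)) {
    ep <- c(recon = 0, kl = 0, critic = 0, gen_adv = 0); nb <- 0
    for (bn in names(buckets)) {
      members <- which(as.character(bks) == bn)
      ord <- members[sample.int(length(members))]
      pairs <- .pair_index(buckets[[bn]]$padded_size)
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(length(ord), b0 + cfg$batch_size - 1)]
        B <- length(idx)
        # --- encode + decode (generator path) --------------------------
        gen_pass <- function(Pe, Pd, collect_fake_flat = FALSE) {
          mus <- vector("list", B); lvs <- vector("list", B)
          for (k in seq_len(B)) {
            enc <- gcn_encode(Pe, weak_graphs[[idx[k]]], cfg)
            mus[[k]] <- enc$mu; lvs[[k]] <- enc$logvar
          }
          mu <- do.call(ag_cbind, lapply(mus, ag_t))  # latent x B
          mu <- ag_t(mu)
          lv <- ag_t(do.call(ag_cbind, lapply(lvs, ag_t)))
          eps <- matrix(stats::rnorm(B * cfg$latent_dim), B)
          Z <- ag_add(mu, ag_mul(ag_exp(ag_scale(lv, 0.5)), ag_const(eps)))
          out <- dec_forward(Pd, Z)
          list(mu = mu, lv = lv, Z = Z, out = out)
        }
        recon_terms <- function(gp, out) {
          adj_t <- do.call(rbind, lapply(padded[idx], `[[`, "adj"))
          pm <- do.call(rbind, lapply(padded[idx], `[[`, "pairmask"))
          nf_t <- do.call(rbind, lapply(padded[idx],
                                        function(p) as.vector(p$nf)))
          nm <- do.call(rbind, lapply(padded[idx], function(p) {
            matrix(rep(p$mask, Fn), nrow = 1)
          }))
          ef_t <- do.call(rbind, lapply(padded[idx],
                                        function(p) as.vector(p$ef)))
          em <- do.call(rbind, lapply(padded[idx], function(p) {
            matrix(rep(p$adj, Fe), nrow = 1)  # feature loss on real edges
          }))
          l_adj <- ag_bce_logits(out$adj_logits, adj_t, pm)
          l_node <- ag_mse(out$node, nf_t, nm)
          l_edge <- ag_mse(out$edge, ef_t, em)
          list(adj = l_adj, node = l_node, edge = l_edge)
        }
        fake_flat_from <- function(out) {
          al <- ag_value(out$adj_logits)
          aprob <- 1 / (1 + exp(-al))
          nfv <- ag_value(out$node)
          efv <- ag_value(out$edge)
          masks <- do.call(rbind, lapply(padded[idx], `[[`, "mask"))
          cbind(aprob, nfv, efv, masks)
        }
        real_flat <- do.call(rbind, lapply(padded[idx], .flatten_padded))

        # --- critic updates --------------------------------------------
        for (ci in seq_len(if (cfg$adversarial) cfg$n_critic else 0)) {
          Pe <- nn_wrap(enc_params); Pd <- nn_wrap(dec_params[[bn]])
          gp <- gen_pass(Pe, Pd)
          fake_flat <- fake_flat_from(gp$out)
          noise <- function(m) m + matrix(stats::rnorm(length(m), 0,
                                                       cfg$noise_sd),
                                          nrow(m))
          obj <- wgan_critic_objective(noise(real_flat), noise(fake_flat),
                                       crit_params[[bn]], cfg)
          ag_backward(obj$loss_node)
          grads <- nn_grads(obj$Pn, crit_params[[bn]])
          st <- rmsprop_step(crit_params[[bn]], grads, crit_state[[bn]],
                             cfg$lr_disc)
          crit_params[[bn]] <- clip_params(st$params, cfg$clip_value)
          crit_state[[bn]] <- st$state
          ep["critic"] <- ep["critic"] + obj$critic_loss / cfg$n_critic
        }

        # --- generator / VAE update ------------------------------------
        Pe <- nn_wrap(enc_params); Pd <- nn_wrap(dec_params[[bn]])
        Pc <- nn_wrap(crit_params[[bn]])
        gp <- gen_pass(Pe, Pd)
        rt <- recon_terms(gp, gp$out)
        kl <- ag_scale(
          ag_sum(ag_sub(ag_scale(ag_add(ag_mul(gp$mu, gp$mu),
                                        ag_exp(gp$lv)), 0.5),
                        ag_scale(ag_add(gp$lv, ag_const(matrix(1, B, cfg$latent_dim))),
                                 0.5))),
          1 / B)
        loss <- ag_add(ag_add(ag_scale(rt$adj, cfg$w_adj),
                              ag_scale(rt$node, cfg$w_node)),
                       ag_add(ag_scale(rt$edge, cfg$w_edge),
                              ag_scale(kl, cfg$w_kl)))
        adv <- ag_const(matrix(0, 1, 1)); cf <- NULL
        if (cfg$adversarial) {
          # adversarial: critic score of the differentiable fake graphs
          aprob_node <- ag_sigmoid(gp$out$adj_logits)
          masks <- ag_const(do.call(rbind, lapply(padded[idx], `[[`, "mask")))
          fake_node <- ag_cbind(aprob_node, gp$out$node, gp$out$edge, masks)
          cf <- critic_forward(Pc, fake_node)
          adv <- ag_scale(ag_mean(cf$score), -1)
          loss <- ag_add(loss, adv)
        }
        if (cfg$adversarial && cfg$feature_matching) {
          cr <- critic_forward(Pc, ag_const(real_flat))
          fm <- ag_mse(ag_group_mean(cf$features, rep(1L, B), 1L),
                       ag_value(ag_group_mean(cr$features, rep(1L, B), 1L)))
          loss <- ag_add(loss, fm)
        }
        ag_backward(loss)
        ge <- nn_grads(Pe, enc_params)
        gd <- nn_grads(Pd, dec_params[[bn]])
        st <- rmsprop_step(enc_params, ge, enc_state, cfg$lr_encdec)
        enc_params <- st$params; enc_state <- st$state
        st <- rmsprop_step(dec_params[[bn]], gd, dec_state[[bn]],
                           cfg$lr_encdec)
        dec_params[[bn]] <- st$params; dec_state[[bn]] <- st$state
        recon_val <- ag_value(rt$adj)[1] * cfg$w_adj +
          ag_value(rt$node)[1] * cfg$w_node + ag_value(rt$edge)[1] * cfg$w_edge
        ep["recon"] <- ep["recon"] + recon_val
        ep["kl"] <- ep["kl"] + ag_value(kl)[1]
        ep["gen_adv"] <- ep["gen_adv"] + ag_value(adv)[1]
        nb <- nb + 1
      }
    }
    ep <- ep / max(nb, 1)
    history <- rbind(history, data.frame(epoch = epoch, recon = ep["recon"],
                                         kl = ep["kl"], critic = ep["critic"],
                                         gen_adv = ep["gen_adv"]))
    if (verbose) {
      message(sprintf("epoch %d: recon %.4f kl %.4f critic %.4f",
                      epoch, ep["recon"], ep["kl"], ep["critic"]))
    }
    smooth <- c(smooth, ep["recon"])
    win <- mean(utils::tail(smooth, 10))
    if (win < best - 1e-4) { best <- win; wait <- 0 } else {
      wait <- wait + 1
      if (wait >= cfg$early_stop_patience) break
    }
  }
  rownames(history) <- NULL
  # identity-conditioned node-attribute model: per-residue-type mean and sd
  # of every non-one-hot node feature over the training corpus, used to
  # enforce physicochemical consistency of generated nodes
  all_nf <- do.call(rbind, lapply(weak_graphs, `[[`, "node_feats"))
  aacols <- grep("^aa_", colnames(all_nf))
  other <- setdiff(seq_len(ncol(all_nf)), aacols)
  aa_of <- apply(all_nf[, aacols, drop = FALSE], 1, which.max)
  cond_mean <- matrix(rep(colMeans(all_nf[, other, drop = FALSE]),
                          each = 20), 20,
                      dimnames = list(aa_order(), colnames(all_nf)[other]))
  cond_sd <- matrix(rep(apply(all_nf[, other, drop = FALSE], 2, stats::sd),
                        each = 20), 20,
                    dimnames = dimnames(cond_mean))
  for (k in unique(aa_of)) {
    rows <- aa_of == k
    if (sum(rows) >= 3) {
      cond_mean[k, ] <- colMeans(all_nf[rows, other, drop = FALSE])
      cond_sd[k, ] <- apply(all_nf[rows, other, drop = FALSE], 2, stats::sd)
    }
  }
  cond_sd[is.na(cond_sd)] <- 0
  structure(list(enc_params = enc_params, dec_params = dec_params,
                 node_cond = list(mean = cond_mean, sd = cond_sd,
                                  aa_cols = aacols, other_cols = other),
                 crit_params = crit_params, buckets = buckets, cfg = cfg,
                 n_feats = Fn, n_efeats = Fe,
                 feat_names = colnames(weak_graphs[[1]]$node_feats),
                 efeat_names = colnames(weak_graphs[[1]]$edge_feats),
                 history = history),
            class = "gan_model")
}

#' Generate weak-binding decoy graphs
#'
#' Samples a size bucket per decoy in proportion to the training bucket
#' frequencies, a node count from the bucket's empirical counts and a
#' standard-normal latent vector, then decodes deterministically:
#' adjacency discretised at 0.5 and masked to the sampled node count.
#' Output graphs carry `label = "weak_aug"`, `provenance = "generated"`
#' and no coordinates. Fixed `(model, n, seed)` give identical output.
#'
#' Node attributes: the amino-acid block is snapped to the one-hot argmax
#' of the decoder output; with `feature_mode = "conditional"` (default)
#' the remaining node features are then drawn from the identity-
#' conditioned attribute model fitted on the training corpus, enforcing
#' physicochemical consistency between a generated residue's identity and
#' its descriptors; `"decoder"` keeps the raw decoder feature output.
#'
#' @param model A trained `gan_model`.
#' @param n Number of decoys (>= 1).
#' @param seed RNG seed.
#' @param feature_mode `"conditional"` or `"decoder"` (see above).
#' @return List of `interface_graph`s.
#' @export
generate_decoys <- function(model, n, seed = 1,
                            feature_mode = c("conditional", "decoder")) {
  feature_mode <- match.arg(feature_mode)
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  bnames <- names(model$buckets)
  freqs <- vapply(model$buckets, `[[`, numeric(1), "freq")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    bn <- if (length(bnames) == 1) bnames else
      sample(bnames, 1, prob = freqs)
    bk <- model$buckets[[bn]]
    nn <- if (length(bk$node_counts) == 1) bk$node_counts else
      sample(bk$node_counts, 1)
    z <- stats::rnorm(model$cfg$latent_dim)
    dec <- gan_decode(z, model, bn)
    keep_pair <- dec$pairs[, 1] <= nn & dec$pairs[, 2] <= nn
    on_edge <- dec$adj_prob[dec$pairs] >= 0.5 & keep_pair
    ei <- t(dec$pairs[on_edge, , drop = FALSE])
    ef <- dec$edge_feats[on_edge, , drop = FALSE]
    nf <- dec$node_feats[seq_len(nn), , drop = FALSE]
    # snap the amino-acid block to a valid one-hot
    aacols <- grep("^aa_", colnames(nf))
    if (length(aacols) == 20) {
      am <- apply(nf[, aacols, drop = FALSE], 1, which.max)
      nf[, aacols] <- 0
      nf[cbind(seq_len(nn), aacols[am])] <- 1
      res_names <- aa_order()[am]
      if (feature_mode == "conditional" && !is.null(model$node_cond)) {
        nc <- model$node_cond
        mu <- nc$mean[am, , drop = FALSE]
        sg <- nc$sd[am, , drop = FALSE]
        nf[, nc$other_cols] <- mu + sg *
          matrix(stats::rnorm(nn * length(nc$other_cols)), nn)
      }
    } else {
      res_names <- rep("ALA", nn)
    }
    nodes <- data.frame(chain_id = "G", res_seq = seq_len(nn), icode = "",
                        res_name = res_names,
                        role = rep(c("MHC", "PEPTIDE", "TCRA", "TCRB"),
                                   length.out = nn),
                        stringsAsFactors = FALSE)
    out[[i]] <- new_interface_graph(
      graph_id = sprintf("decoy_%04d", i), nodes = nodes, node_feats = nf,
      coords = NULL, edge_index = ei, edge_feats = ef,
      edge_zone = rep("GEN", ncol(ei)), zone = "UNIFIED",
      label = "weak_aug", provenance = "generated"
    )
  }
  out
}

#' Save / load a GAN checkpoint
#'
#' Text (JSON) checkpoint holding encoder, per-bucket decoder and critic
#' parameter blobs, the bucket registry, configuration and loss history.
#'
#' @param model A `gan_model`.
#' @param path Checkpoint file.
#' @return `path` invisibly (save); the restored `gan_model` (load).
#' @export
gan_save <- function(model, path) {
  pack <- function(pl) lapply(pl, function(m) list(d = dim(m),
                                                   v = as.vector(m)))
  ser <- list(
    enc_params = pack(model$enc_params),
    dec_params = lapply(model$dec_params, pack),
    crit_params = lapply(model$crit_params, pack),
    node_cond = list(mean = list(d = dim(model$node_cond$mean),
                                 v = as.vector(model$node_cond$mean)),
                     sd = list(d = dim(model$node_cond$sd),
                               v = as.vector(model$node_cond$sd)),
                     aa_cols = model$node_cond$aa_cols,
                     other_cols = model$node_cond$other_cols),
    buckets = model$buckets, cfg = unclass(model$cfg),
    n_feats = model$n_feats, n_efeats = model$n_efeats,
    feat_names = model$feat_names, efeat_names = model$efeat_names,
    history = model$history
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gan_save
#' @export
gan_load <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(pl) lapply(pl, function(m) matrix(m$v, m$d[1], m$d[2]))
  raw$enc_params <- unpack(raw$enc_params)
  raw$dec_params <- lapply(raw$dec_params, unpack)
  raw$crit_params <- lapply(raw$crit_params, unpack)
  raw$node_cond <- list(
    mean = matrix(raw$node_cond$mean$v, raw$node_cond$mean$d[1]),
    sd = matrix(raw$node_cond$sd$v, raw$node_cond$sd$d[1]),
    aa_cols = raw$node_cond$aa_cols,
    other_cols = raw$node_cond$other_cols)
  raw$buckets <- lapply(raw$buckets, as.list)
  raw$cfg <- structure(as.list(raw$cfg), class = "gan_config")
  raw$history <- as.data.frame(raw$history)
  structure(raw, class = "gan_model")
}
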