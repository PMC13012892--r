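# small weak-graph corpus and a briefly trained model shared across tests
.gan_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ds <- simulate_graph_dataset(synthetic_spec(n_strong = 5, n_weak = 40,
                                                seed = 21))
    norm <- normalize_features(ds$graphs)
    weak <- norm$train[ds$labels == "weak_exp"]
    model <- train_gan(weak, gan_config(max_epochs = 8, seed = 7))
    cache <<- list(weak = weak, model = model,
                   strong = norm$train[ds$labels == "strong"])
    cache
  }
})

test_that("deterministic encoding is reproducible and permutation-invariant", {
  fx <- .gan_fixture()
  g <- fx$weak[[1]]
  e1 <- gan_encode(g, fx$model)
  e2 <- gan_encode(g, fx$model)
  expect_identical(e1$z, e2$z)
  expect_identical(e1$z, e1$mu)           # eps = 0 in deterministic mode
  set.seed(5)
  perm <- sample(tcrgraphs:::n_nodes(g))
  inv <- order(perm)
  g2 <- g
  g2$nodes <- g$nodes[perm, ]; g2$node_feats <- g$node_feats[perm, ]
  g2$coords <- g$coords[perm, ]
  ei <- apply(g$edge_index, 2, function(e) sort(inv[e]))
  ord <- order(ei[1, ], ei[2, ])
  g2$edge_index <- ei[, ord]; g2$edge_feats <- g$edge_feats[ord, , drop = FALSE]
  e3 <- gan_encode(g2, fx$model)
  expect_lt(max(abs(e3$mu - e1$mu)), 1e-6)
  expect_lt(max(abs(e3$logvar - e1$logvar)), 1e-6)
  empty <- toy_graph(1, matrix(integer(0), 0, 2))
  empty$nodes <- empty$nodes[0, ]; empty$node_feats <- empty$node_feats[0, , drop = FALSE]
  expect_error(gan_encode(empty, fx$model), "empty")
})

test_that("decoding yields symmetric, self-loop-free, reproducible output", {
  fx <- .gan_fixture()
  bn <- names(fx$model$buckets)[1]
  z <- rnorm(fx$model$cfg$latent_dim)
  d1 <- gan_decode(z, fx$model, bn)
  expect_equal(d1$adj_prob, t(d1$adj_prob))
  expect_true(all(diag(d1$adj_prob) == 0))
  expect_true(all(d1$adj_prob >= 0 & d1$adj_prob <= 1))
  d2 <- gan_decode(z, fx$model, bn)
  expect_identical(d1, d2)
  expect_error(gan_decode(z, fx$model, "999"), "unknown")
})

test_that("the Wasserstein term vanishes for identical batches", {
  fx <- .gan_fixture()
  bn <- names(fx$model$buckets)[1]
  D <- fx$model$buckets[[bn]]$flat_dim
  set.seed(8)
  batch <- matrix(rnorm(3 * D, 0, 0.3), 3, D)
  obj <- wgan_critic_objective(batch, batch, fx$model$crit_params[[bn]],
                               fx$model$cfg)
  expect_equal(obj$wasserstein, 0, tolerance = 1e-12)
  expect_error(wgan_critic_objective(batch, batch[, -1],
                                     fx$model$crit_params[[bn]],
                                     fx$model$cfg), "mismatch")
})

test_that("the critic objective matches a hand-computed oracle (gp = 0)", {
  cfg <- gan_config(hidden_dim = 20, seed = 1)
  set.seed(9)
  D <- 15
  cp <- tcrgraphs:::critic_init(D, cfg)
  cp <- lapply(cp, function(p) p + matrix(rnorm(length(p), 0, 0.1), nrow(p)))
  real <- matrix(rnorm(2 * D), 2, D)
  fake <- matrix(rnorm(2 * D), 2, D)
  score <- function(X) {
    h1 <- pmax(X %*% cp$crit.h1.W + matrix(cp$crit.h1.b, 2, 20, byrow = TRUE), 0)
    h2 <- pmax(h1 %*% cp$crit.h2.W + matrix(cp$crit.h2.b, 2, 20, byrow = TRUE), 0)
    h2 %*% cp$crit.out.W + as.vector(cp$crit.out.b)
  }
  oracle <- mean(score(fake)) - mean(score(real))
  obj <- wgan_critic_objective(real, fake, cp, cfg)
  expect_equal(obj$critic_loss, oracle, tolerance = 1e-10)
  expect_equal(obj$gp, 0)
})

test_that("the analytic critic input-gradient matches finite differences", {
  cfg <- gan_config(latent_dim = 4, hidden_dim = 10, gp_weight = 1)
  set.seed(10)
  D <- 8
  cp <- tcrgraphs:::critic_init(D, cfg)
  cp <- lapply(cp, function(p) p + matrix(rnorm(length(p), 0, 0.2), nrow(p)))
  x <- matrix(rnorm(D), 1, D)
  Pn <- tcrgraphs:::nn_wrap(cp)
  gn <- ag_value(tcrgraphs:::critic_grad_norm(Pn, x))[1]
  sc <- function(x) {
    ag_value(tcrgraphs:::critic_forward(tcrgraphs:::nn_wrap(cp),
                                        ag_const(x))$score)[1]
  }
  num <- vapply(seq_len(D), function(i) {
    e <- 1e-6
    x1 <- x; x1[i] <- x1[i] + e
    x0 <- x; x0[i] <- x0[i] - e
    (sc(x1) - sc(x0)) / (2 * e)
  }, numeric(1))
  expect_equal(gn, sqrt(sum(num^2)), tolerance = 1e-5)
})

test_that("weight clipping bounds every critic parameter", {
  fx <- .gan_fixture()
  for (bn in names(fx$model$crit_params)) {
    mx <- max(vapply(fx$model$crit_params[[bn]], function(p) max(abs(p)),
                     numeric(1)))
    expect_lte(mx, fx$model$cfg$clip_value + 1e-12)
  }
})

test_that("training refuses strong-labelled graphs", {
  fx <- .gan_fixture()
  bad <- fx$weak
  bad[[1]]$label <- "strong"
  expect_error(train_gan(bad, gan_config(max_epochs = 1)), "strong")
})

test_that("reconstruction loss decreases over training (fixed seed)", {
  fx <- .gan_fixture()
  h <- fx$model$history
  sm <- function(v) mean(tail(v, 3))
  expect_lt(sm(h$recon), h$recon[1])
})

test_that("two runs with the same seed give identical loss histories", {
  fx <- .gan_fixture()
  m2 <- train_gan(fx$weak, gan_config(max_epochs = 3, seed = 7))
  m3 <- train_gan(fx$weak, gan_config(max_epochs = 3, seed = 7))
  expect_identical(m2$history, m3$history)
})

test_that("a pure VAE overfits a single repeated graph to high adjacency accuracy", {
  fx <- .gan_fixture()
  g <- fx$weak[[1]]
  cfg <- gan_config(adversarial = FALSE, feature_matching = FALSE,
                    max_epochs = 150, early_stop_patience = 150,
                    lr_encdec = 5e-3, seed = 3)
  m <- train_gan(rep(list(g), 8), cfg)
  enc <- gan_encode(g, m)
  bn <- names(m$buckets)[1]
  dec <- gan_decode(enc$z, m, bn)
  n <- tcrgraphs:::n_nodes(g)
  A_true <- matrix(0, n, n)
  A_true[t(g$edge_index)] <- 1
  A_true <- A_true + t(A_true)
  A_hat <- (dec$adj_prob[seq_len(n), seq_len(n)] >= 0.5) * 1
  acc <- mean(A_hat[upper.tri(A_hat)] == A_true[upper.tri(A_true)])
  expect_gt(acc, 0.95)
})

test_that("decoy generation is seeded, sized and structurally valid", {
  fx <- .gan_fixture()
  d1 <- generate_decoys(fx$model, 25, seed = 13)
  d2 <- generate_decoys(fx$model, 25, seed = 13)
  expect_length(d1, 25)
  expect_identical(lapply(d1, `[[`, "node_feats"),
                   lapply(d2, `[[`, "node_feats"))
  expect_identical(lapply(d1, `[[`, "edge_index"),
                   lapply(d2, `[[`, "edge_index"))
  for (g in d1[1:5]) {
    expect_s3_class(validate_interface_graph(g), "interface_graph")
    expect_equal(g$label, "weak_aug")
    expect_equal(g$provenance, "generated")
    expect_null(g$coords)
    aa <- g$node_feats[, grep("^aa_", colnames(g$node_feats)), drop = FALSE]
    expect_equal(unname(rowSums(aa)), rep(1, nrow(aa)))
  }
  expect_error(generate_decoys(fx$model, 0), ">= 1")
})

test_that("decoy node-feature marginals stay close to the training marginals", {
  ds <- simulate_graph_dataset(synthetic_spec(n_strong = 10, n_weak = 30,
                                              seed = 61))
  norm <- normalize_features(ds$graphs)
  weak <- norm$train[ds$labels == "weak_exp"]
  strong <- norm$train[ds$labels == "strong"]
  gm <- train_gan(weak, gan_config(max_epochs = 40, seed = 5))
  dec <- generate_decoys(gm, 40, seed = 3)
  fk <- feature_divergence_report(weak, dec)
  node_kl <- fk$kl_real_gen[fk$level == "node"]
  expect_true(all(node_kl < 0.5))
  # decoys sit in lower-density latent regions than the strong binders
  sz <- t(vapply(strong, function(g) gan_encode(g, gm)$mu,
                 numeric(gm$cfg$latent_dim)))
  dz <- t(vapply(dec, function(g) gan_encode(g, gm)$mu,
                 numeric(gm$cfg$latent_dim)))
  fit <- tcrgraphs:::.kde_fit(sz)
  expect_lt(mean(tcrgraphs:::.kde_density(fit, dz)),
            mean(tcrgraphs:::.kde_density(fit, sz)))
})

test_that("checkpoint save/load round-trips parameters and generation", {
  fx <- .gan_fixture()
  tf <- tempfile(fileext = ".json")
  gan_save(fx$model, tf)
  m2 <- gan_load(tf)
  expect_equal(m2$enc_params, fx$model$enc_params, tolerance = 1e-12,
               ignore_attr = TRUE)
  d1 <- generate_decoys(fx$model, 5, seed = 4)
  d2 <- generate_decoys(m2, 5, seed = 4)
  expect_equal(lapply(d1, `[[`, "edge_index"), lapply(d2, `[[`, "edge_index"))
  expect_equal(lapply(d1, `[[`, "node_feats"), lapply(d2, `[[`, "node_feats"),
               tolerance = 1e-9, ignore_attr = TRUE)
})
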