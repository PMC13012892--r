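test_that("feature KL matches the closed-form two-bin example", {
  # construct samples whose 2-bin histograms are P=(1/2,1/2), Q=(1/4,3/4)
  real <- c(rep(0.25, 2), rep(0.75, 2))
  gen <- c(rep(0.25, 1), rep(0.75, 3))
  kl <- feature_kl(real, gen, bins = 2, eps = 0)
  expect_equal(kl, 0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(kl, 0.1438, tolerance = 1e-3)
})

test_that("KL is zero on identical samples and non-negative in general", {
  set.seed(1)
  x <- rnorm(200)
  expect_lt(feature_kl(x, x), 1e-9)
  for (i in 1:200) {
    a <- rnorm(sample(10:80, 1), sample(-2:2, 1))
    b <- rnorm(sample(10:80, 1), sample(-2:2, 1))
    expect_gte(feature_kl(a, b), 0)
  }
  expect_error(feature_kl(numeric(0), x), "non-empty")
  expect_error(feature_kl(rep(1, 5), rep(1, 7)), "distinct")
})

test_that("WL kernel matches the hand example at h = 0", {
  g1 <- toy_graph(2, rbind(c(1, 2)), "a")
  g1$nodes$res_name <- c("ALA", "ARG")   # labels {A, B}
  g2 <- toy_graph(2, rbind(c(1, 2)), "b")
  g2$nodes$res_name <- c("ALA", "ALA")   # labels {A, A}
  # use residue identity directly (no one-hot block)
  g1$node_feats <- g1$node_feats[, 1:3]; g2$node_feats <- g2$node_feats[, 1:3]
  expect_equal(wl_kernel(g1, g2, h = 0), 2)
  expect_equal(wl_kernel(g2, g2, h = 0), 4)
})

test_that("WL kernel matches a naive reference implementation", {
  naive_wl <- function(g, h) {
    n <- tcrgraphs:::n_nodes(g)
    A <- matrix(FALSE, n, n)
    if (tcrgraphs:::n_edges(g)) {
      A[t(g$edge_index)] <- TRUE
      A <- A | t(A)
    }
    labs <- list(g$nodes$res_name)
    for (r in seq_len(h)) {
      prev <- labs[[r]]
      labs[[r + 1]] <- vapply(seq_len(n), function(i) {
        paste0(prev[i], "|", paste(sort(prev[A[i, ]]), collapse = ","))
      }, character(1))
    }
    labs
  }
  naive_dot <- function(l1, l2) {
    s <- 0
    for (r in seq_along(l1)) {
      for (lab in unique(l1[[r]])) {
        s <- s + sum(l1[[r]] == lab) * sum(l2[[r]] == lab)
      }
    }
    s
  }
  set.seed(3)
  for (i in 1:30) {
    mk <- function(seed) {
      n <- sample(4:10, 1)
      edges <- t(combn(n, 2))
      edges <- edges[runif(nrow(edges)) < 0.4, , drop = FALSE]
      g <- toy_graph(n, edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
                     seed = seed)
      g$node_feats <- g$node_feats[, 1:2, drop = FALSE]  # no one-hot block
      g
    }
    g1 <- mk(i); g2 <- mk(i + 100)
    h <- sample(0:3, 1)
    expect_equal(wl_kernel(g1, g2, h),
                 naive_dot(naive_wl(g1, h), naive_wl(g2, h)))
    kn <- wl_kernel(g1, g2, h, normalize = TRUE)
    expect_gte(kn, 0); expect_lte(kn, 1)
  }
})

test_that("MMD is zero on identical sets, symmetric, and shrinks on resamples", {
  set.seed(4)
  gs <- lapply(1:8, function(i) toy_graph(sample(5:9, 1),
                                          rbind(c(1, 2), c(2, 3), c(3, 4)),
                                          paste0("g", i), seed = i))
  expect_lt(abs(wl_mmd(gs, gs, h = 2)$mmd2), 1e-12)
  other <- lapply(1:8, function(i) {
    g <- toy_graph(sample(10:14, 1),
                   rbind(c(1, 2), c(1, 3), c(1, 4), c(5, 6)),
                   paste0("h", i), seed = 50 + i)
    g
  })
  m_ab <- wl_mmd(gs, other, h = 2)$mmd2
  m_ba <- wl_mmd(other, gs, h = 2)$mmd2
  expect_equal(m_ab, m_ba, tolerance = 1e-12)
  # bootstrap resample of the real set is closer than a different set
  boot <- gs[sample(8, 8, replace = TRUE)]
  expect_lt(wl_mmd(gs, boot, h = 2)$mmd2, m_ab)
})

test_that("topology metrics match closed forms and an igraph oracle", {
  tri <- toy_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)), "tri")
  tm <- topology_metrics(tri)
  expect_equal(tm$connectivity, 1)
  expect_equal(unname(tm$degrees), c(2, 2, 2))
  expect_equal(tm$mean_clustering, 1)
  path3 <- toy_graph(3, rbind(c(1, 2), c(2, 3)), "path")
  expect_equal(topology_metrics(path3)$mean_clustering, 0)
  skip_if_not_installed("igraph")
  set.seed(5)
  for (i in 1:50) {
    n <- sample(5:14, 1)
    edges <- t(combn(n, 2))
    edges <- edges[runif(nrow(edges)) < 0.3, , drop = FALSE]
    if (!nrow(edges)) next
    g <- toy_graph(n, edges[order(edges[, 1], edges[, 2]), , drop = FALSE],
                   seed = i)
    tm <- topology_metrics(g)
    ig <- igraph::graph_from_edgelist(t(g$edge_index), directed = FALSE)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    expect_equal(tm$connectivity,
                 max(igraph::components(ig)$csize) / n)
    expect_equal(unname(tm$degrees), as.numeric(igraph::degree(ig)))
    tr <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
    expect_equal(tm$mean_clustering, mean(tr), tolerance = 1e-12)
  }
})

test_that("latent filter drops high-density decoys and keeps outliers", {
  set.seed(6)
  strong <- matrix(rnorm(40 * 4), 40, 4)
  centroid <- matrix(colMeans(strong), 1)
  far <- matrix(10 * apply(strong, 2, sd) * 10, 1)
  dec <- rbind(centroid, far)
  res <- latent_filter(dec, strong, percentile = 5)
  expect_false(res$keep[1])
  expect_true(res$keep[2])
  expect_error(latent_filter(dec[, 1:3], strong), "mismatch")
  expect_error(latent_filter(dec, strong[1:3, ]), "at least 5")
})

test_that("latent filter decisions equal a direct KDE-sum oracle", {
  set.seed(7)
  strong <- matrix(rnorm(30 * 3), 30, 3)
  dec <- matrix(rnorm(100 * 3, 0, 2), 100, 3)
  res <- latent_filter(dec, strong, percentile = 10)
  n <- nrow(strong); d <- 3
  bw <- apply(strong, 2, sd) * n^(-1 / (d + 4))
  kde <- function(q) {
    s <- 0
    for (i in seq_len(n)) {
      z <- (q - strong[i, ]) / bw
      s <- s + exp(-0.5 * sum(z^2))
    }
    s / (n * prod(bw) * (2 * pi)^(d / 2))
  }
  self_d <- vapply(seq_len(n), function(i) kde(strong[i, ]), numeric(1))
  thr <- quantile(self_d, 0.10, names = FALSE)
  for (i in seq_len(nrow(dec))) {
    expect_equal(res$keep[i], kde(dec[i, ]) < thr)
  }
})
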