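#' Histogram KL divergence between real and generated feature samples
#'
#' Shared bin edges are taken over the pooled range; a smoothing mass of
#' `eps` is added to every bin before normalisation and
#' `KL(P_real || Q_gen)` is returned in nats. Both directions are reported
#' by [feature_divergence_report()].
#'
#' @param real_values,gen_values Non-empty numeric vectors.
#' @param bins Number of shared bins (default 20).
#' @param eps Smoothing mass per bin.
#' @return KL divergence in nats (non-negative).
#' @export
feature_kl <- function(real_values, gen_values, bins = 20, eps = 1e-8) {
  if (!length(real_values) || !length(gen_values)) {
    stop("both samples must be non-empty")
  }
  pooled <- c(real_values, gen_values)
  if (length(unique(pooled)) < 2) {
    stop("need at least 2 distinct pooled values to bin")
  }
  edges <- seq(min(pooled), max(pooled), length.out = bins + 1)
  edges[1] <- edges[1] - 1e-12
  cnt <- function(v) {
    h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE,
                               left.open = TRUE), nbins = bins)
    p <- h + eps
    p / sum(p)
  }
  p <- cnt(real_values); q <- cnt(gen_values)
  sum(p * log(p / q))
}

#' Per-feature divergence report between two graph sets
#'
#' Computes histogram KL divergences for every continuous node and edge
#' feature, in both directions (real||gen asserted downstream, gen||real
#' reported).
#'
#' @param real_graphs,gen_graphs Lists of `interface_graph`s.
#' @param bins,eps See [feature_kl()].
#' @return data.frame: feature, level (node/edge), kl_real_gen,
#'   kl_gen_real.
#' @export
feature_divergence_report <- function(real_graphs, gen_graphs, bins = 20,
                                      eps = 1e-8) {
  sch <- feature_schema()
  pool <- function(graphs, what, col) {
    unlist(lapply(graphs, function(g) {
      m <- g[[what]]
      if (col %in% colnames(m)) m[, col] else numeric(0)
    }))
  }
  rows <- list()
  for (col in sch$node_continuous) {
    rv <- pool(real_graphs, "node_feats", col)
    gv <- pool(gen_graphs, "node_feats", col)
    if (length(rv) && length(gv) && length(unique(c(rv, gv))) >= 2) {
      rows[[length(rows) + 1]] <- data.frame(
        feature = col, level = "node",
        kl_real_gen = feature_kl(rv, gv, bins, eps),
        kl_gen_real = feature_kl(gv, rv, bins, eps))
    }
  }
  for (col in sch$edge_continuous) {
    rv <- pool(real_graphs, "edge_feats", col)
    gv <- pool(gen_graphs, "edge_feats", col)
    if (length(rv) && length(gv) && length(unique(c(rv, gv))) >= 2) {
      rows[[length(rows) + 1]] <- data.frame(
        feature = col, level = "edge",
        kl_real_gen = feature_kl(rv, gv, bins, eps),
        kl_gen_real = feature_kl(gv, rv, bins, eps))
    }
  }
  do.call(rbind, rows)
}

# discrete initial labels for WL refinement: residue identity (argmax of
# the one-hot block for generated graphs)
wl_initial_labels <- function(g) {
  aacols <- grep("^aa_", colnames(g$node_feats))
  if (length(aacols) == 20) {
    aa_order()[apply(g$node_feats[, aacols, drop = FALSE], 1, which.max)]
  } else {
    g$nodes$res_name
  }
}

# adjacency list from canonical edge index
.adjlist <- function(g) {
  n <- n_nodes(g)
  adj <- vector("list", n)
  if (n_edges(g)) {
    for (e in seq_len(n_edges(g))) {
      i <- g$edge_index[1, e]; j <- g$edge_index[2, e]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# WL label refinement: list of label vectors for rounds 0..h
wl_refine <- function(g, h, labels = wl_initial_labels(g)) {
  adj <- .adjlist(g)
  out <- list(labels)
  cur <- labels
  for (r in seq_len(h)) {
    cur <- vapply(seq_along(adj), function(i) {
      nb <- sort(cur[adj[[i]]])
      paste0(cur[i], "|", paste(nb, collapse = ","))
    }, character(1))
    out[[r + 1]] <- cur
  }
  out
}

#' Weisfeiler-Lehman subtree kernel
#'
#' Iteratively refines discrete node labels by neighbourhood aggregation
#' for `h` rounds; the kernel is the dot product of label-count vectors
#' accumulated over rounds 0..h, optionally cosine-normalised (normalised
#' values lie in `[0, 1]`).
#'
#' @param g1,g2 `interface_graph`s with discrete initial labels (residue
#'   identity by default).
#' @param h Number of refinement rounds (>= 0).
#' @param normalize Cosine-normalise the kernel.
#' @return Kernel value.
#' @export
wl_kernel <- function(g1, g2, h = 3, normalize = FALSE) {
  if (h < 0) stop("h must be >= 0")
  l1 <- wl_refine(g1, h); l2 <- wl_refine(g2, h)
  dot <- function(a, b) {
    k <- 0
    for (r in seq_len(h + 1)) {
      t1 <- table(a[[r]]); t2 <- table(b[[r]])
      common <- intersect(names(t1), names(t2))
      k <- k + sum(as.numeric(t1[common]) * as.numeric(t2[common]))
    }
    k
  }
  k12 <- dot(l1, l2)
  if (!normalize) return(k12)
  k12 / sqrt(dot(l1, l1) * dot(l2, l2))
}

#' Maximum mean discrepancy between two graph sets (WL kernel)
#'
#' Biased V-statistic: `MMD^2 = mean k(real,real) + mean k(gen,gen) -
#' 2 mean k(real,gen)` with the (normalised by default) WL subtree kernel.
#'
#' @param set_real,set_gen Lists of `interface_graph`s.
#' @param h WL refinement rounds.
#' @param normalize Cosine-normalise the kernel (default TRUE).
#' @return List with `mmd2`, `h`, `normalized`.
#' @export
wl_mmd <- function(set_real, set_gen, h = 3, normalize = TRUE) {
  lab <- function(set) lapply(set, wl_refine, h = h)
  kmat <- function(la, lb) {
    outer(seq_along(la), seq_along(lb), Vectorize(function(i, j) {
      k <- 0
      for (r in seq_len(h + 1)) {
        t1 <- table(la[[i]][[r]]); t2 <- table(lb[[j]][[r]])
        common <- intersect(names(t1), names(t2))
        k <- k + sum(as.numeric(t1[common]) * as.numeric(t2[common]))
      }
      k
    }))
  }
  la <- lab(set_real); lb <- lab(set_gen)
  Kaa <- kmat(la, la); Kbb <- kmat(lb, lb); Kab <- kmat(la, lb)
  if (normalize) {
    da <- sqrt(diag(Kaa)); db <- sqrt(diag(Kbb))
    Kaa <- Kaa / outer(da, da); Kbb <- Kbb / outer(db, db)
    Kab <- Kab / outer(da, db)
  }
  mmd2 <- mean(Kaa) + mean(Kbb) - 2 * mean(Kab)
  list(mmd2 = max(mmd2, -1e-12), h = h, normalized = normalize)
}

#' Graph-level topology metrics
#'
#' Connectivity (fraction of nodes in the largest connected component),
#' the degree histogram and the mean local clustering coefficient (nodes
#' of degree below 2 contribute 0).
#'
#' @param g A non-empty `interface_graph`.
#' @return List with `connectivity`, `degrees`, `degree_hist`,
#'   `mean_clustering`.
#' @export
topology_metrics <- function(g) {
  n <- n_nodes(g)
  if (!n) stop("empty graph")
  adj <- .adjlist(g)
  deg <- lengths(adj)
  # largest component by BFS
  comp <- integer(n); cid <- 0
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (!comp[u]) { comp[u] <- cid; queue <- c(queue, u) }
    }
  }
  connectivity <- max(tabulate(comp)) / n
  clust <- vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (nb[b] %in% adj[[nb[a]]]) links <- links + 1
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
  list(connectivity = connectivity, degrees = deg,
       degree_hist = tabulate(deg + 1),  # bin 1 = degree 0
       mean_clustering = mean(clust))
}

# Gaussian KDE with Scott's-rule bandwidth per dimension
.kde_fit <- function(X) {
  n <- nrow(X); d <- ncol(X)
  bw <- apply(X, 2, stats::sd) * n^(-1 / (d + 4))
  bw[bw < 1e-8] <- 1e-8
  list(X = X, bw = bw)
}

.kde_density <- function(fit, q) {
  n <- nrow(fit$X); d <- ncol(fit$X)
  const <- 1 / (n * prod(fit$bw) * (2 * pi)^(d / 2))
  vapply(seq_len(nrow(q)), function(i) {
    z <- sweep(fit$X, 2, q[i, ]) / matrix(fit$bw, n, d, byrow = TRUE)
    const * sum(exp(-0.5 * rowSums(z^2)))
  }, numeric(1))
}

#' Latent-space filter for generated decoys
#'
#' Fits a Gaussian kernel density (Scott's-rule bandwidth) on the latent
#' embeddings of strong-binding complexes and drops any decoy whose
#' density under that model reaches the `percentile`-th percentile of the
#' strong binders' self-densities, i.e. decoys must lie outside the
#' high-density region of the strong-binder latent distribution.
#'
#' @param decoys_z Matrix of decoy latent vectors (rows).
#' @param strong_z Matrix of strong-binder latent vectors (>= 5 rows).
#' @param percentile Density percentile defining the high-density region.
#' @return data.frame: decoy (row index), density, threshold, keep.
#' @export
latent_filter <- function(decoys_z, strong_z, percentile = 5) {
  decoys_z <- as.matrix(decoys_z); strong_z <- as.matrix(strong_z)
  if (nrow(strong_z) < 5) stop("need at least 5 strong-binder embeddings")
  if (ncol(decoys_z) != ncol(strong_z)) {
    stop("latent dimensionality mismatch: ", ncol(decoys_z), " vs ",
         ncol(strong_z))
  }
  fit <- .kde_fit(strong_z)
  self_d <- .kde_density(fit, strong_z)
  thr <- stats::quantile(self_d, percentile / 100, names = FALSE)
  dens <- .kde_density(fit, decoys_z)
  data.frame(decoy = seq_len(nrow(decoys_z)), density = dens,
             threshold = thr, keep = dens < thr)
}

#' Full decoy quality-control report
#'
#' Runs the three-level validation of generated decoys against real weak
#' binders: per-feature KL divergences, topology metrics and WL-kernel
#' MMD, plus the latent filter against strong binders when a GAN model and
#' strong graphs are supplied.
#'
#' @param real_graphs Real (weak-binding) graphs.
#' @param gen_graphs Generated decoys.
#' @param strong_graphs Optional strong-binding graphs for the latent
#'   filter.
#' @param model Optional `gan_model` (required with `strong_graphs`).
#' @param h WL rounds.
#' @param percentile Latent filter percentile.
#' @return List with `feature_kl`, `mmd`, `topology` (per-set connectivity
#'   and clustering summaries) and optionally `latent` (filter decisions).
#' @export
decoy_qc_report <- function(real_graphs, gen_graphs, strong_graphs = NULL,
                            model = NULL, h = 3, percentile = 5) {
  topo_sum <- function(graphs) {
    ms <- lapply(graphs, topology_metrics)
    list(connectivity = mean(vapply(ms, `[[`, numeric(1), "connectivity")),
         mean_clustering = mean(vapply(ms, `[[`, numeric(1), "mean_clustering")),
         mean_degree = mean(unlist(lapply(ms, `[[`, "degrees"))))
  }
  out <- list(
    feature_kl = feature_divergence_report(real_graphs, gen_graphs),
    mmd = wl_mmd(real_graphs, gen_graphs, h = h),
    topology = list(real = topo_sum(real_graphs), generated = topo_sum(gen_graphs))
  )
  if (!is.null(strong_graphs) && !is.null(model)) {
    sz <- t(vapply(strong_graphs,
                   function(g) gan_encode(g, model)$mu,
                   numeric(model$cfg$latent_dim)))
    dz <- t(vapply(gen_graphs,
                   function(g) gan_encode(g, model)$mu,
                   numeric(model$cfg$latent_dim)))
    out$latent <- latent_filter(dz, sz, percentile)
  }
  out
}
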