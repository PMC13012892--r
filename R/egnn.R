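#' EGNN architecture configuration
#'
#' @param n_layers Number of stacked equivariant message-passing layers.
#' @param hidden_dim Node embedding width.
#' @param mlp_hidden Hidden width of the graph-level MLP head.
#' @param dropout Dropout rate on node embeddings during training.
#' @param decision_threshold Binding-score threshold for the binary call.
#' @return List of class `egnn_config`.
#' @export
egnn_config <- function(n_layers = 2, hidden_dim = 32, mlp_hidden = 32,
                        dropout = 0.1, decision_threshold = 0.5) {
  stopifnot(n_layers >= 1, decision_threshold > 0, decision_threshold < 1)
  structure(as.list(environment()), class = "egnn_config")
}

#' Classifier training configuration
#'
#' Stochastic gradient descent with decoupled weight decay; momentum is an
#' implementation default. Early stopping monitors validation loss.
#'
#' @param lr Learning rate.
#' @param weight_decay Weight decay.
#' @param momentum SGD momentum.
#' @param batch_size Graphs per mini-batch.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs).
#' @param min_delta Minimum validation-loss improvement.
#' @param max_restarts Extra training attempts from fresh initialisations
#'   when a run stalls in the warmup plateau (see `stall_threshold`).
#' @param stall_threshold A run counts as stalled when the dropout-free
#'   training loss of its returned parameters does not drop below
#'   `stall_threshold` times the training loss of the trivial train-prior
#'   predictor; stalled runs are retried up to `max_restarts` times and the
#'   attempt with the lowest monitored validation loss is kept.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, weight_decay = 1e-3, momentum = 0.9,
                         batch_size = 8, max_epochs = 100, patience = 10,
                         min_delta = 1e-4, max_restarts = 2,
                         stall_threshold = 0.99, seed = 1) {
  structure(as.list(environment()), class = "train_config")
}

.egnn_classes <- c("strong", "weak_exp", "weak_aug")

#' Inverse-frequency class weights with unit mean
#'
#' @param counts Vector of per-class sample counts (all at least 1).
#' @return Weights proportional to `1/counts`, rescaled so their mean is 1.
#' @export
class_weights <- function(counts) {
  if (any(counts < 1)) stop("all class counts must be >= 1")
  w <- 1 / counts
  w / mean(w)
}

# assemble a disjoint-union batch from a list of graphs
egnn_batch <- function(graphs, n_feats = NULL, n_efeats = NULL) {
  n <- vapply(graphs, n_nodes, integer(1))
  offs <- cumsum(c(0L, head(n, -1)))
  X <- do.call(rbind, lapply(graphs, `[[`, "node_feats"))
  N <- nrow(X)
  coords <- matrix(0, N, 3)
  hascrd <- logical(N)
  src <- integer(0); dst <- integer(0)
  ef_rows <- list()
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    rows <- offs[k] + seq_len(n[k])
    if (!is.null(g$coords)) {
      coords[rows, ] <- g$coords
      hascrd[rows] <- TRUE
    }
    if (n_edges(g)) {
      i <- g$edge_index[1, ] + offs[k]
      j <- g$edge_index[2, ] + offs[k]
      src <- c(src, i, j); dst <- c(dst, j, i)
      ef_rows[[length(ef_rows) + 1L]] <- rbind(g$edge_feats, g$edge_feats)
    }
  }
  ef <- if (length(ef_rows)) do.call(rbind, ef_rows) else
    matrix(0, 0, ncol(graphs[[1]]$edge_feats))
  membership <- rep(seq_along(graphs), n)
  list(X = X, coords = coords, hascrd = hascrd, src = src, dst = dst,
       ef = ef, membership = membership, n_graphs = length(graphs),
       edge_coord_mask = hascrd[src] & hascrd[dst])
}

# initialise EGNN parameters
egnn_init <- function(n_feats, n_efeats, cfg) {
  h <- cfg$hidden_dim
  P <- list()
  P <- nn_add_linear(P, "embed", n_feats, h)
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("l", l, ".")
    P <- nn_add_linear(P, paste0(pre, "edge1"), 2 * h + 1 + n_efeats, h)
    P <- nn_add_linear(P, paste0(pre, "edge2"), h, h)
    P <- nn_add_linear(P, paste0(pre, "coord"), h, 1, bias = FALSE)
    P <- nn_add_linear(P, paste0(pre, "node1"), 2 * h, h)
    P <- nn_add_linear(P, paste0(pre, "node2"), h, h)
  }
  P <- nn_add_linear(P, "head1", h, cfg$mlp_hidden)
  P <- nn_add_linear(P, "head2", cfg$mlp_hidden, 3)
  P
}

# forward pass; returns logits (ag), final coords (ag or matrix) and node
# embeddings. `Pn` is the list of wrapped ag_param nodes.
egnn_forward <- function(Pn, batch, cfg, training = FALSE, dropout = 0) {
  h <- ag_silu(nn_linear(Pn, "embed", ag_const(batch$X)))
  x <- ag_const(batch$coords)
  ne <- length(batch$src)
  N <- nrow(batch$X)
  emask <- matrix(as.numeric(batch$edge_coord_mask), ncol = 1)
  drop_h <- function(hh) {
    if (training && dropout > 0) {
      keep <- matrix(stats::rbinom(N * cfg$hidden_dim, 1, 1 - dropout) /
                       (1 - dropout), N, cfg$hidden_dim)
      ag_mul(hh, ag_const(keep))
    } else hh
  }
  h <- drop_h(h)
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("l", l, ".")
    if (ne > 0) {
      hi <- ag_rows(h, batch$dst)   # receiving node i
      hj <- ag_rows(h, batch$src)   # neighbour j
      xi <- ag_rows(x, batch$dst)
      xj <- ag_rows(x, batch$src)
      diff <- ag_sub(xi, xj)
      d2 <- ag_mul(ag_rowsums(ag_mul(diff, diff)), ag_const(emask))
      min_parts <- list(hi, hj, d2)
      if (ncol(batch$ef) > 0) min_parts <- c(min_parts, list(ag_const(batch$ef)))
      m_in <- do.call(ag_cbind, min_parts)
      m <- ag_silu(nn_linear(Pn, paste0(pre, "edge2"),
                             ag_silu(nn_linear(Pn, paste0(pre, "edge1"), m_in))))
      # equivariant coordinate update: x_i <- x_i + mean_j (x_i - x_j) phi_x(m)
      w <- ag_tanh(nn_linear(Pn, paste0(pre, "coord"), m))
      wmask <- ag_mul(w, ag_const(emask))
      xupd <- ag_group_mean(ag_mul(diff, wmask), batch$dst, N)
      x <- ag_add(x, xupd)
      magg <- ag_group_sum(m, batch$dst, N)
    } else {
      magg <- ag_const(matrix(0, N, cfg$hidden_dim))
    }
    h <- ag_silu(nn_linear(Pn, paste0(pre, "node2"),
                           ag_silu(nn_linear(Pn, paste0(pre, "node1"),
                                             ag_cbind(h, magg)))))
    h <- drop_h(h)
  }
  G <- ag_group_mean(h, batch$membership, batch$n_graphs)
  logits <- nn_linear(Pn, "head2",
                      ag_relu(nn_linear(Pn, "head1", G)))
  list(logits = logits, coords = x, node_emb = h, graph_emb = G)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the EGNN strong/weak classifier
#'
#' Three-class training (strong, experimentally weak, augmented weak) with
#' inverse-frequency class weights normalised to unit mean, mini-batches of
#' disjoint graph unions, SGD with weight decay and early stopping on
#' validation loss. Graphs without coordinates (generated decoys) skip the
#' coordinate pathway; their messages use node and edge features only.
#'
#' @param graphs List of feature-normalised `interface_graph`s.
#' @param labels Character labels in `c("strong","weak_exp","weak_aug")`.
#' @param val_graphs,val_labels Optional validation set; when absent a
#'   stratified 15% split is carved from the training data.
#' @param cfg An [egnn_config()].
#' @param tcfg A [train_config()].
#' @return An `egnn_model`: list with `params`, `cfg`, `classes`,
#'   `history` (per-epoch train/val losses) and feature dimensions.
#' @export
train_egnn <- function(graphs, labels, val_graphs = NULL, val_labels = NULL,
                       cfg = egnn_config(), tcfg = train_config()) {
  bad <- setdiff(unique(labels), .egnn_classes)
  if (length(bad)) stop("labels outside the 3-class set: ",
                        paste(bad, collapse = ", "))
  set.seed(tcfg$seed)
  y <- match(labels, .egnn_classes)
  if (is.null(val_graphs)) {
    vidx <- unlist(lapply(split(seq_along(y), y), function(ix) {
      if (length(ix) < 3) return(integer(0))
      sample(ix, max(1, round(0.15 * length(ix))))
    }))
    val_graphs <- graphs[vidx]; val_labels <- labels[vidx]
    graphs <- graphs[-vidx]; labels <- labels[-vidx]
    y <- y[-vidx]
  }
  yv <- match(val_labels, .egnn_classes)
  counts <- tabulate(y, 3)
  w <- numeric(3)
  present <- counts > 0
  w[present] <- class_weights(counts[present])
  n_feats <- ncol(graphs[[1]]$node_feats)
  n_efeats <- ncol(graphs[[1]]$edge_feats)
  vbatch <- if (length(val_graphs)) egnn_batch(val_graphs) else NULL
  # weighted CE of the trivial train-prior predictor on the training set:
  # runs whose dropout-free training loss (of the returned parameters)
  # never beats a fraction of this have stalled in the warmup plateau and
  # are retried from a fresh initialisation. The training loss is used
  # because small validation carves are too noisy a stall signal, and it
  # is recomputed without dropout because per-epoch losses are inflated
  # by dropout noise under strong class weighting.
  prior <- pmax(counts / sum(counts), 1e-12)
  loss0 <- mean(w[y] * -log(prior[y]))
  full_batch <- egnn_batch(graphs)
  nb <- length(graphs)
  max_restarts <- tcfg$max_restarts %||% 0
  stall_threshold <- tcfg$stall_threshold %||% 0.99
  clean_loss <- function(params) {
    fout <- egnn_forward(nn_wrap(params), full_batch, cfg)
    ag_value(ag_wce_softmax(fout$logits, y, w))[1]
  }
  run_attempt <- function() {
    params <- egnn_init(n_feats, n_efeats, cfg)
    vel <- lapply(params, function(p) p * 0)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    best <- Inf; best_params <- params; wait <- 0
    for (epoch in seq_len(tcfg$max_epochs)) {
      ord <- sample(nb)
      tl <- 0; nbatches <- 0
      for (b0 in seq(1, nb, by = tcfg$batch_size)) {
        idx <- ord[b0:min(nb, b0 + tcfg$batch_size - 1)]
        batch <- egnn_batch(graphs[idx])
        Pn <- nn_wrap(params)
        out <- egnn_forward(Pn, batch, cfg, training = TRUE,
                            dropout = cfg$dropout)
        loss <- ag_wce_softmax(out$logits, y[idx], w)
        ag_backward(loss)
        grads <- nn_grads(Pn, params)
        for (k in seq_along(params)) {
          vel[[k]] <- tcfg$momentum * vel[[k]] + grads[[k]] +
            tcfg$weight_decay * params[[k]]
          params[[k]] <- params[[k]] - tcfg$lr * vel[[k]]
        }
        tl <- tl + ag_value(loss)[1]; nbatches <- nbatches + 1
      }
      vl <- NA_real_
      if (!is.null(vbatch)) {
        Pn <- nn_wrap(params)
        vout <- egnn_forward(Pn, vbatch, cfg)
        vl <- ag_value(ag_wce_softmax(vout$logits, yv, w))[1]
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = tl / nbatches,
                                           val_loss = vl))
      monitor <- if (is.na(vl)) tl / nbatches else vl
      if (monitor < best - tcfg$min_delta) {
        best <- monitor; best_params <- params; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= tcfg$patience) break
      }
      # abandon attempts that have not left the warmup plateau by epoch 60
      # (noisy small-validation improvements can otherwise keep an
      # unlearnable run alive to max_epochs)
      if (epoch >= 60 && epoch %% 20 == 0 &&
          clean_loss(best_params) > stall_threshold * loss0) break
    }
    list(best = best, best_params = best_params, history = history,
         clean_train = clean_loss(best_params))
  }
  overall <- NULL
  for (attempt in 0:max_restarts) {
    if (attempt > 0) set.seed(tcfg$seed + 100000L * attempt)
    res <- run_attempt()
    res$attempt <- attempt + 1L
    if (is.null(overall) || res$best < overall$best) overall <- res
    if (res$clean_train <= stall_threshold * loss0) break
  }
  structure(list(params = overall$best_params, cfg = cfg,
                 classes = .egnn_classes,
                 class_weights = w, n_feats = n_feats, n_efeats = n_efeats,
                 history = overall$history, attempts = overall$attempt,
                 stall_loss = loss0),
            class = "egnn_model")
}

#' Predict binding for interface graphs
#'
#' Runs the trained EGNN and returns per-graph three-class probabilities,
#' the binding score (the probability of the strong class) and the binary
#' call at the decision threshold.
#'
#' @param model An `egnn_model`.
#' @param graphs List of feature-normalised `interface_graph`s.
#' @param threshold Decision threshold (default from the model config).
#' @return data.frame: graph_id, p_strong, p_weak_exp, p_weak_aug,
#'   binding_score, call.
#' @export
predict_egnn <- function(model, graphs, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$cfg$decision_threshold
  batch <- egnn_batch(graphs)
  Pn <- nn_wrap(model$params)
  out <- egnn_forward(Pn, batch, model$cfg)
  p <- softmax_rows(ag_value(out$logits))
  data.frame(
    graph_id = vapply(graphs, `[[`, character(1), "graph_id"),
    p_strong = p[, 1], p_weak_exp = p[, 2], p_weak_aug = p[, 3],
    binding_score = p[, 1],
    call = ifelse(p[, 1] > threshold, "strong", "weak"),
    stringsAsFactors = FALSE
  )
}
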