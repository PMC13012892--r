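# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every value is a node (environment) holding a matrix `val`, an
# accumulated gradient `grad`, its parent nodes and one backward closure
# per parent mapping the node's output gradient to a gradient contribution
# for that parent. `ag_backward()` traverses nodes in reverse creation
# order, which is a valid topological order. Gradients are only propagated
# into subgraphs that contain parameters (`requires = TRUE`), keeping
# constant-heavy graphs cheap. Correctness is pinned down by
# finite-difference tests.

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

.ag_new <- function(val, parents = list(), pbw = list()) {
  .ag_env$counter <- .ag_env$counter + 1L
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$pbw <- pbw
  e$id <- .ag_env$counter
  e$requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  class(e) <- "ag"
  e
}

#' Wrap a constant matrix for the autodiff graph
#' @param x Matrix or vector (vectors become 1-column matrices).
#' @return An `ag` node that receives no gradient.
#' @export
ag_const <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  .ag_new(x)
}

#' Wrap a parameter matrix for the autodiff graph
#' @param x Matrix or vector.
#' @return An `ag` node that accumulates a gradient during backward.
#' @export
ag_param <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  e <- .ag_new(x)
  e$requires <- TRUE
  e
}

.ag_coerce <- function(x) if (inherits(x, "ag")) x else ag_const(x)

#' Extract the value matrix of an autodiff node
#' @param x An `ag` node.
#' @return The matrix value.
#' @export
ag_value <- function(x) x$val

#' Run backward pass from a scalar loss node
#'
#' Accumulates gradients into every parameter node reachable from `loss`.
#' @param loss An `ag` node holding a 1x1 matrix.
#' @export
ag_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (p$requires) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  loss$grad <- matrix(1, 1, 1)
  for (nd in nodes[ord]) {
    if (is.null(nd$grad)) next
    g <- nd$grad
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$requires) next
      contrib <- nd$pbw[[k]](g)
      p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
    }
  }
  invisible(loss)
}

# ---- operators -----------------------------------------------------------

#' @rdname ag_ops
#' @name ag_ops
#' @title Autodiff matrix operations
#' @description Differentiable primitives: matrix product (`ag_mm`),
#'   addition with row-vector bias broadcast (`ag_add`), subtraction,
#'   elementwise product with column broadcast (`ag_mul`), scalar scaling,
#'   elementwise nonlinearities, reductions, row gather/scatter
#'   (`ag_rows`), grouped sum/mean aggregation, column concatenation and
#'   fused losses.
#' @param a,b,x `ag` nodes (plain matrices are treated as constants).
#' @param s Numeric scalar.
#' @return An `ag` node.
NULL

#' @rdname ag_ops
#' @export
ag_mm <- function(a, b) {
  a <- .ag_coerce(a); b <- .ag_coerce(b)
  .ag_new(a$val %*% b$val, list(a, b),
          list(function(g) g %*% t(b$val), function(g) t(a$val) %*% g))
}

#' @rdname ag_ops
#' @export
ag_add <- function(a, b) {
  a <- .ag_coerce(a); b <- .ag_coerce(b)
  if (nrow(b$val) == 1L && nrow(a$val) > 1L) {
    .ag_new(sweep(a$val, 2, b$val, "+"), list(a, b),
            list(function(g) g,
                 function(g) matrix(colSums(g), 1)))
  } else {
    stopifnot(all(dim(a$val) == dim(b$val)))
    .ag_new(a$val + b$val, list(a, b),
            list(function(g) g, function(g) g))
  }
}

#' @rdname ag_ops
#' @export
ag_sub <- function(a, b) {
  a <- .ag_coerce(a); b <- .ag_coerce(b)
  stopifnot(all(dim(a$val) == dim(b$val)))
  .ag_new(a$val - b$val, list(a, b), list(function(g) g, function(g) -g))
}

#' @rdname ag_ops
#' @export
ag_mul <- function(a, b) {
  a <- .ag_coerce(a); b <- .ag_coerce(b)
  if (ncol(b$val) == 1L && ncol(a$val) > 1L) {
    v <- as.vector(b$val)
    .ag_new(a$val * v, list(a, b),
            list(function(g) g * v,
                 function(g) matrix(rowSums(g * a$val), ncol = 1)))
  } else {
    stopifnot(all(dim(a$val) == dim(b$val)))
    .ag_new(a$val * b$val, list(a, b),
            list(function(g) g * b$val, function(g) g * a$val))
  }
}

#' @rdname ag_ops
#' @export
ag_scale <- function(a, s) {
  a <- .ag_coerce(a)
  .ag_new(a$val * s, list(a), list(function(g) g * s))
}

#' @rdname ag_ops
#' @export
ag_relu <- function(a) {
  a <- .ag_coerce(a)
  mask <- a$val > 0
  .ag_new(a$val * mask, list(a), list(function(g) g * mask))
}

#' @rdname ag_ops
#' @export
ag_silu <- function(a) {
  a <- .ag_coerce(a)
  s <- 1 / (1 + exp(-a$val))
  .ag_new(a$val * s, list(a), list(function(g) g * (s + a$val * s * (1 - s))))
}

#' @rdname ag_ops
#' @export
ag_sigmoid <- function(a) {
  a <- .ag_coerce(a)
  s <- 1 / (1 + exp(-a$val))
  .ag_new(s, list(a), list(function(g) g * s * (1 - s)))
}

#' @rdname ag_ops
#' @export
ag_tanh <- function(a) {
  a <- .ag_coerce(a)
  t <- tanh(a$val)
  .ag_new(t, list(a), list(function(g) g * (1 - t^2)))
}

#' @rdname ag_ops
#' @export
ag_exp <- function(a) {
  a <- .ag_coerce(a)
  v <- exp(a$val)
  .ag_new(v, list(a), list(function(g) g * v))
}

#' @rdname ag_ops
#' @export
ag_sqrt <- function(a) {
  a <- .ag_coerce(a)
  v <- sqrt(a$val)
  .ag_new(v, list(a), list(function(g) g * 0.5 / pmax(v, 1e-12)))
}

#' @rdname ag_ops
#' @export
ag_sum <- function(a) {
  a <- .ag_coerce(a)
  dims <- dim(a$val)
  .ag_new(matrix(sum(a$val), 1, 1), list(a),
          list(function(g) matrix(g[1], dims[1], dims[2])))
}

#' @rdname ag_ops
#' @export
ag_mean <- function(a) {
  a <- .ag_coerce(a)
  n <- length(a$val)
  dims <- dim(a$val)
  .ag_new(matrix(mean(a$val), 1, 1), list(a),
          list(function(g) matrix(g[1] / n, dims[1], dims[2])))
}

#' @rdname ag_ops
#' @export
ag_rowsums <- function(a) {
  a <- .ag_coerce(a)
  k <- ncol(a$val)
  .ag_new(matrix(rowSums(a$val), ncol = 1), list(a),
          list(function(g) matrix(g, nrow(g), k)))
}

#' @rdname ag_ops
#' @param idx Integer row indices for `ag_rows`.
#' @export
ag_rows <- function(a, idx) {
  a <- .ag_coerce(a)
  n <- nrow(a$val)
  .ag_new(a$val[idx, , drop = FALSE], list(a),
          list(function(g) {
            z <- matrix(0, n, ncol(g))
            rs <- rowsum(g, idx)
            z[as.integer(rownames(rs)), ] <- rs
            z
          }))
}

# grouped aggregation: rows of `a` summed (or averaged) by group, result
# has `ngroups` rows; groups without members yield zero rows
.ag_group <- function(a, grp, ngroups, mean) {
  a <- .ag_coerce(a)
  cnt <- tabulate(grp, nbins = ngroups)
  agg <- matrix(0, ngroups, ncol(a$val))
  rs <- rowsum(a$val, grp)
  agg[as.integer(rownames(rs)), ] <- rs
  w <- if (mean) 1 / pmax(cnt, 1) else rep(1, ngroups)
  .ag_new(agg * w, list(a),
          list(function(g) (g * w)[grp, , drop = FALSE]))
}

#' @rdname ag_ops
#' @param grp Integer group index per row; `ngroups` total groups.
#' @param ngroups Number of groups.
#' @export
ag_group_sum <- function(a, grp, ngroups) .ag_group(a, grp, ngroups, FALSE)

#' @rdname ag_ops
#' @export
ag_group_mean <- function(a, grp, ngroups) .ag_group(a, grp, ngroups, TRUE)

#' @rdname ag_ops
#' @param ... `ag` nodes with equal row counts for `ag_cbind`.
#' @export
ag_cbind <- function(...) {
  parts <- lapply(list(...), .ag_coerce)
  widths <- vapply(parts, function(p) ncol(p$val), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  pbw <- lapply(seq_along(parts), function(k) {
    force(k)
    function(g) g[, starts[k]:ends[k], drop = FALSE]
  })
  .ag_new(do.call(cbind, lapply(parts, ag_value)), parts, pbw)
}

#' @rdname ag_ops
#' @param labels Integer class labels (1-based) for the fused weighted
#'   softmax cross-entropy; `weights` one weight per class.
#' @param weights Per-class weights.
#' @export
ag_wce_softmax <- function(logits, labels, weights) {
  logits <- .ag_coerce(logits)
  z <- logits$val
  z <- z - apply(z, 1, max)
  p <- exp(z) / rowSums(exp(z))
  n <- nrow(z)
  w <- weights[labels]
  ll <- -log(pmax(p[cbind(seq_len(n), labels)], 1e-12))
  loss <- sum(w * ll) / n
  onehot <- matrix(0, n, ncol(z))
  onehot[cbind(seq_len(n), labels)] <- 1
  .ag_new(matrix(loss, 1, 1), list(logits),
          list(function(g) g[1] * (p - onehot) * w / n))
}

#' @rdname ag_ops
#' @param target Constant target matrix for the fused losses; `mask`
#'   optional 0/1 weight matrix (losses average over mask weight).
#' @param mask Optional mask.
#' @export
ag_bce_logits <- function(x, target, mask = NULL) {
  x <- .ag_coerce(x)
  v <- x$val
  if (is.null(mask)) mask <- matrix(1, nrow(v), ncol(v))
  tot <- max(sum(mask), 1)
  l <- pmax(v, 0) - v * target + log1p(exp(-abs(v)))
  s <- 1 / (1 + exp(-v))
  .ag_new(matrix(sum(l * mask) / tot, 1, 1), list(x),
          list(function(g) g[1] * (s - target) * mask / tot))
}

#' @rdname ag_ops
#' @export
ag_mse <- function(x, target, mask = NULL) {
  x <- .ag_coerce(x)
  v <- x$val
  if (is.null(mask)) mask <- matrix(1, nrow(v), ncol(v))
  tot <- max(sum(mask), 1)
  d <- v - target
  .ag_new(matrix(sum(d^2 * mask) / tot, 1, 1), list(x),
          list(function(g) g[1] * 2 * d * mask / tot))
}
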