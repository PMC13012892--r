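# Parameter containers, initialisation and optimisers for the neural
# components. Parameters live as plain matrices in a named list; every
# training step wraps them in fresh `ag_param` nodes, runs
# forward/backward, reads the gradients off the nodes and updates the raw
# matrices in place.

# Glorot-uniform weight matrix
nn_init_w <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -s, s), n_in, n_out)
}

nn_init_b <- function(n_out) matrix(0, 1, n_out)

# add a linear layer's parameters under names <prefix>.W / <prefix>.b
nn_add_linear <- function(params, prefix, n_in, n_out, bias = TRUE) {
  params[[paste0(prefix, ".W")]] <- nn_init_w(n_in, n_out)
  if (bias) params[[paste0(prefix, ".b")]] <- nn_init_b(n_out)
  params
}

# apply <prefix> linear layer given a list of ag nodes `P`
nn_linear <- function(P, prefix, x) {
  out <- ag_mm(x, P[[paste0(prefix, ".W")]])
  bn <- paste0(prefix, ".b")
  if (!is.null(P[[bn]])) out <- ag_add(out, P[[bn]])
  out
}

# two-layer MLP with ReLU hidden activation
nn_mlp2 <- function(P, prefix, x, out_act = c("identity", "relu")) {
  out_act <- match.arg(out_act)
  h <- ag_relu(nn_linear(P, paste0(prefix, "1"), x))
  o <- nn_linear(P, paste0(prefix, "2"), h)
  if (out_act == "relu") ag_relu(o) else o
}

# wrap raw parameter list as ag_param nodes
nn_wrap <- function(params) lapply(params, ag_param)

# read gradients after backward (zero for untouched params)
nn_grads <- function(Pnodes, params) {
  lapply(seq_along(params), function(k) {
    g <- Pnodes[[k]]$grad
    if (is.null(g)) params[[k]] * 0 else g
  })
}

# plain SGD with decoupled weight decay
sgd_step <- function(params, grads, lr, weight_decay = 0) {
  for (k in seq_along(params)) {
    params[[k]] <- params[[k]] - lr * (grads[[k]] + weight_decay * params[[k]])
  }
  params
}

# RMSprop (standard choice for Wasserstein-GAN critics)
rmsprop_init <- function(params) lapply(params, function(p) p * 0)

rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (k in seq_along(params)) {
    state[[k]] <- rho * state[[k]] + (1 - rho) * grads[[k]]^2
    params[[k]] <- params[[k]] - lr * grads[[k]] / (sqrt(state[[k]]) + eps)
  }
  list(params = params, state = state)
}

# clamp every parameter matrix to [-c, c] (WGAN weight clipping)
clip_params <- function(params, clip_value) {
  lapply(params, function(p) pmin(pmax(p, -clip_value), clip_value))
}
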