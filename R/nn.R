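# Minimal dense-layer toolkit with manual reverse-mode gradients.
# Parameters live in flat named lists of matrices/vectors; every forward
# helper returns what its backward twin needs.

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

lin_fwd <- function(x, W, b) sweep(x %*% W, 2, b, "+")

relu <- function(x) { x[x < 0] <- 0; x }

# grad wrt (x, W, b) of y = relu(xW + b), given dy and the activation a
lin_relu_bwd <- function(dy, a, x, W) {
  dz <- dy * (a > 0)
  list(dx = dz %*% t(W), dW = crossprod(x, dz), db = colSums(dz))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# weighted cross-entropy over rows; y is 1-based class index, w per-class
# weights. Returns loss (weighted mean, PyTorch convention) and dlogits.
ce_loss <- function(logits, y, w = rep(1, ncol(logits))) {
  n <- nrow(logits)
  if (n == 0L) return(list(loss = 0, dlogits = logits))
  p <- softmax_rows(logits)
  wy <- w[y]
  li <- -log(pmax(p[cbind(seq_len(n), y)], 1e-12))
  loss <- sum(wy * li) / sum(wy)
  dl <- p
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  dl <- dl * (wy / sum(wy))
  list(loss = loss, dlogits = dl)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

grad_zero <- function(params) lapply(params, function(p) p * 0)

grad_add <- function(g, nm, val) { g[[nm]] <- g[[nm]] + val; g }

# PointNet-style set encoder: shared 2-layer MLP + per-group max pool.
pointnet_fwd <- function(x, group, n_groups, W1, b1, W2, b2) {
  a1 <- relu(lin_fwd(x, W1, b1))
  a2 <- relu(lin_fwd(a1, W2, b2))
  mp <- group_max_pool(a2, as.integer(group), as.integer(n_groups))
  list(pooled = mp$max, cache = list(x = x, a1 = a1, a2 = a2,
                                     argmax = mp$argmax, n = nrow(x)))
}

pointnet_bwd <- function(dpooled, cache, W1, W2) {
  da2 <- group_max_pool_grad(dpooled, cache$argmax, cache$n)
  g2 <- lin_relu_bwd(da2, cache$a2, cache$a1, W2)
  g1 <- lin_relu_bwd(g2$dx, cache$a1, cache$x, W1)
  list(dW1 = g1$dW, db1 = g1$db, dW2 = g2$dW, db2 = g2$db)
}
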