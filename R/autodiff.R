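# Minimal reverse-mode automatic differentiation on matrices.
#
# A tape records nodes in creation order; each node holds its value, an
# accumulated gradient, and a backward closure that pushes gradient to its
# parents. Gradients are verified against central finite differences in the
# test suite. This is deliberately small: just the operations the gated
# attention, fusion and clinical towers need.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$params <- list()
  t
}

ad_node <- function(tape, value, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$backward <- backward
  tape$nodes[[length(tape$nodes) + 1L]] <- n
  n
}

ad_acc <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# parameter leaf; registered so the optimizer can collect gradients in order
ad_param <- function(tape, value, name = NULL) {
  n <- ad_node(tape, value)
  n$name <- name
  tape$params[[length(tape$params) + 1L]] <- n
  n
}

ad_const <- function(tape, value) ad_node(tape, value)

ad_matmul <- function(tape, x, w) {
  out <- ad_node(tape, x$value %*% w$value)
  out$backward <- function(g) {
    ad_acc(x, g %*% t(w$value))
    ad_acc(w, t(x$value) %*% g)
  }
  out
}

# adds a length-k bias vector to every row of an n x k matrix
ad_add_bias <- function(tape, x, b) {
  out <- ad_node(tape, sweep(x$value, 2L, as.vector(b$value), "+"))
  out$backward <- function(g) {
    ad_acc(x, g)
    ad_acc(b, colSums(g))
  }
  out
}

ad_linear <- function(tape, x, w, b) ad_add_bias(tape, ad_matmul(tape, x, w), b)

ad_add <- function(tape, x, y) {
  out <- ad_node(tape, x$value + y$value)
  out$backward <- function(g) { ad_acc(x, g); ad_acc(y, g) }
  out
}

ad_mul <- function(tape, x, y) {
  out <- ad_node(tape, x$value * y$value)
  out$backward <- function(g) {
    ad_acc(x, g * y$value)
    ad_acc(y, g * x$value)
  }
  out
}

ad_relu <- function(tape, x) {
  out <- ad_node(tape, pmax(x$value, 0))
  out$backward <- function(g) ad_acc(x, g * (x$value > 0))
  out
}

ad_tanh <- function(tape, x) {
  v <- tanh(x$value)
  out <- ad_node(tape, v)
  out$backward <- function(g) ad_acc(x, g * (1 - v^2))
  out
}

ad_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-x$value))
  out <- ad_node(tape, v)
  out$backward <- function(g) ad_acc(x, g * v * (1 - v))
  out
}

ad_cbind <- function(tape, x, y) {
  kx <- ncol(x$value)
  out <- ad_node(tape, cbind(x$value, y$value))
  out$backward <- function(g) {
    ad_acc(x, g[, seq_len(kx), drop = FALSE])
    ad_acc(y, g[, -seq_len(kx), drop = FALSE])
  }
  out
}

# softmax of a single-column score over instances, independently per group
# (group = case id for MIL bags); groups must be positive integers
ad_group_softmax <- function(tape, x, groups) {
  z <- as.vector(x$value)
  zmax <- ave(z, groups, FUN = max)
  e <- exp(z - zmax)
  s <- e / ave(e, groups, FUN = sum)
  out <- ad_node(tape, matrix(s, ncol = 1L))
  out$backward <- function(g) {
    gv <- as.vector(g)
    dot <- ave(gv * s, groups, FUN = sum)
    ad_acc(x, matrix(s * (gv - dot), ncol = 1L))
  }
  out
}

# attention pooling: pooled[group g, ] = sum_{i in g} w_i * f_i
# groups must be 1..G with every group nonempty
ad_group_pool <- function(tape, w, f, groups) {
  wv <- as.vector(w$value)
  pooled <- rowsum(f$value * wv, groups)
  out <- ad_node(tape, pooled)
  out$backward <- function(g) {
    gi <- g[groups, , drop = FALSE]
    ad_acc(w, matrix(rowSums(gi * f$value), ncol = 1L))
    ad_acc(f, gi * wv)
  }
  out
}

# BatchNorm1d over rows. state is a mutable environment with running_mean /
# running_var; training mode normalizes with batch statistics (biased
# variance) and updates the running estimates with momentum, evaluation mode
# uses the frozen running statistics.
ad_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  X <- x$value
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    var_b <- colMeans(sweep(X, 2L, mu)^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    var_u <- if (n > 1) var_b * n / (n - 1) else var_b
    state$running_var <- (1 - momentum) * state$running_var + momentum * var_u
  } else {
    mu <- state$running_mean
    var_b <- state$running_var
  }
  invstd <- 1 / sqrt(var_b + eps)
  xhat <- sweep(sweep(X, 2L, mu), 2L, invstd, "*")
  gvec <- as.vector(gamma$value); bvec <- as.vector(beta$value)
  out <- ad_node(tape, sweep(sweep(xhat, 2L, gvec, "*"), 2L, bvec, "+"))
  out$backward <- function(g) {
    ad_acc(beta, colSums(g))
    ad_acc(gamma, colSums(g * xhat))
    dxhat <- sweep(g, 2L, gvec, "*")
    if (training) {
      t1 <- sweep(dxhat, 2L, colMeans(dxhat))
      t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
      ad_acc(x, sweep(t1 - t2, 2L, invstd, "*"))
    } else {
      ad_acc(x, sweep(dxhat, 2L, invstd, "*"))
    }
  }
  out
}

# class-weighted cross-entropy over two-class logits (n x 2); y in {0,1};
# returns scalar loss node = mean_i w_{y_i} * (-log p_{i, y_i})
ad_wce_loss <- function(tape, logits, y, w0 = 0.5, w1 = 1.2) {
  Z <- logits$value
  zmax <- apply(Z, 1L, max)
  E <- exp(Z - zmax)
  P <- E / rowSums(E)
  n <- nrow(Z)
  wy <- ifelse(y == 1L, w1, w0)
  py <- P[cbind(seq_len(n), y + 1L)]
  py <- pmax(py, 1e-12)
  out <- ad_node(tape, sum(wy * (-log(py))) / n)
  out$backward <- function(g) {
    onehot <- matrix(0, n, 2L)
    onehot[cbind(seq_len(n), y + 1L)] <- 1
    ad_acc(logits, as.numeric(g) * (wy / n) * (P - onehot))
  }
  out
}

ad_softmax_rows <- function(Z) {
  E <- exp(Z - apply(Z, 1L, max))
  E / rowSums(E)
}

# reverse sweep; seeds the loss gradient with 1
ad_backward <- function(tape, loss) {
  loss$grad <- if (is.matrix(loss$value)) {
    matrix(1, nrow(loss$value), ncol(loss$value))
  } else 1
  for (i in rev(seq_along(tape$nodes))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$backward) && !is.null(n$grad)) n$backward(n$grad)
  }
  invisible(NULL)
}

ad_param_grads <- function(tape) {
  lapply(tape$params, function(n) {
    if (is.null(n$grad)) n$value * 0 else n$grad
  })
}

# ---- Adam optimizer over a flat named list of parameter matrices ----

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (weight_decay > 0) g <- g + weight_decay * params[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# learning-rate schedules used by the training protocol
lr_inverse_time <- function(lr0, decay_rate) {
  function(epoch) lr0 / (1 + decay_rate * (epoch - 1))
}

lr_warmup_cosine <- function(lr0, warmup = 10L, total = 500L) {
  function(epoch) {
    if (epoch <= warmup) return(lr0 * epoch / warmup)
    frac <- (epoch - warmup) / max(total - warmup, 1L)
    lr0 * 0.5 * (1 + cos(pi * min(frac, 1)))
  }
}
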