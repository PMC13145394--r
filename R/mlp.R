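# Matrix-based feedforward network with optional person-embedding input.
#
# Architecture: input = [features, embedding(id)] -> fully connected hidden
# layers with ReLU -> linear output node. Trained by backpropagation on the
# mean squared error with the Adam optimizer, full-batch (datasets here are
# a few thousand rows). All randomness flows through a single seed.

relu <- function(x) pmax(x, 0)

mlp_init <- function(n_in, hidden, n_ids = 0L, d = 0L, seed = 1L,
                     y_mean = 0) {
  set.seed(seed)
  sizes <- c(n_in + d, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    # He initialization for ReLU layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                           sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  b[[length(b)]] <- y_mean  # start the output at the label mean
  E <- if (d > 0) matrix(rnorm(n_ids * d, 0, 0.1), n_ids, d) else NULL
  list(W = W, b = b, E = E, hidden = hidden, d = d)
}

mlp_forward <- function(par, X, emb_idx = NULL) {
  A <- if (par$d > 0) {
    stopifnot(!is.null(emb_idx))
    cbind(X, par$E[emb_idx, , drop = FALSE])
  } else X
  acts <- list(A)
  L <- length(par$W)
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% par$W[[l]], 2, par$b[[l]], `+`)
    acts[[l + 1]] <- if (l < L) relu(Z) else Z
  }
  list(yhat = as.numeric(acts[[L + 1]]), acts = acts)
}

# One full-batch gradient of the MSE loss (plus L2 on layer weights).
mlp_gradient <- function(par, X, y, emb_idx, l2) {
  fw <- mlp_forward(par, X, emb_idx)
  n <- length(y)
  L <- length(par$W)
  delta <- matrix((fw$yhat - y) * (2 / n), ncol = 1)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$acts[[l]], delta) + 2 * l2 * par$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(par$W[[l]])) * (fw$acts[[l]] > 0)
    } else if (par$d > 0) {
      dIn <- delta %*% t(par$W[[1]])
      dEmb <- dIn[, ncol(X) + seq_len(par$d), drop = FALSE]
      gE <- rowsum(dEmb, group = emb_idx)
      gE_full <- matrix(0, nrow(par$E), par$d)
      gE_full[as.integer(rownames(gE)), ] <- gE
    }
  }
  list(W = gW, b = gb,
       E = if (par$d > 0) gE_full else NULL,
       loss = mean((fw$yhat - y)^2))
}

# Adam update for one flat list of parameter arrays.
adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in seq_along(theta)) {
    if (is.null(grad[[k]])) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grad[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grad[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    theta[[k]] <- theta[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(theta = theta, state = state)
}

flatten_params <- function(par) c(par$W, par$b, list(E = par$E))

unflatten_params <- function(par, flat) {
  L <- length(par$W)
  par$W <- flat[seq_len(L)]
  par$b <- flat[L + seq_len(L)]
  par$E <- flat[[2 * L + 1]]
  par
}

# Core trainer. `trainable`: "all", or "embedding" (optionally restricted to
# `trainable_rows` of the embedding table).
mlp_train <- function(par, X, y, emb_idx = NULL, epochs = 300, lr = 0.01,
                      l2 = 1e-4, trainable = "all", trainable_rows = NULL) {
  flat <- flatten_params(par)
  state <- list(t = 0,
                m = lapply(flat, function(p) if (is.null(p)) NULL else p * 0),
                v = lapply(flat, function(p) if (is.null(p)) NULL else p * 0))
  curve <- numeric(epochs)
  L <- length(par$W)
  for (ep in seq_len(epochs)) {
    g <- mlp_gradient(par, X, y, emb_idx, l2)
    gflat <- c(g$W, g$b, list(E = g$E))
    if (trainable == "embedding") {
      gflat[seq_len(2 * L)] <- list(NULL)
      if (!is.null(trainable_rows) && !is.null(gflat[[2 * L + 1]])) {
        gE <- gflat[[2 * L + 1]]
        frozen <- setdiff(seq_len(nrow(gE)), trainable_rows)
        gE[frozen, ] <- 0
        gflat[[2 * L + 1]] <- gE
      }
    }
    upd <- adam_step(flat, gflat, state, lr)
    flat <- upd$theta; state <- upd$state
    par <- unflatten_params(par, flat)
    curve[ep] <- g$loss
  }
  par$curve <- curve
  par
}
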