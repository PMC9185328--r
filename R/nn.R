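# Dense softmax network used as the CPU-trainable "toy" classifier of the
# fitness harness: small enough to train in seconds, yet exercising every
# searched hyperparameter (loss, optimizer, batch size, dropout, unfreezing
# ratio, augmentation) with real gradient descent.

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

relu <- function(x) pmax(x, 0)

# Gradient of each supported loss with respect to the predicted
# probabilities p (n x K), given one-hot y. Losses follow the usual
# conventions: crossentropy/KLD sum over classes; the hinge family acts on
# {-1, 1} targets and averages over classes; Poisson averages over classes.
loss_grad_probs <- function(loss, y, p, eps = 1e-7) {
  K <- ncol(p)
  pc <- pmax(p, eps)
  switch(loss,
    categorical_crossentropy = -y / pc,
    kld = -y / pc,
    poisson = (1 - y / pc) / K,
    hinge = {
      yhat <- 2 * y - 1
      ifelse(1 - yhat * p > 0, -yhat, 0) / K
    },
    squared_hinge = {
      yhat <- 2 * y - 1
      (-2 * yhat * pmax(0, 1 - yhat * p)) / K
    },
    categorical_hinge = {
      neg <- (1 - y) * p
      jmax <- max.col(neg, ties.method = "first")
      active <- 1 + neg[cbind(seq_len(nrow(p)), jmax)] - rowSums(y * p) > 0
      g <- -y
      g[cbind(seq_len(nrow(p)), jmax)] <-
        g[cbind(seq_len(nrow(p)), jmax)] + 1
      g * active
    },
    stop(sprintf("unknown loss '%s'", loss), call. = FALSE))
}

loss_value <- function(loss, y, p, eps = 1e-7) {
  pc <- pmax(p, eps)
  switch(loss,
    categorical_crossentropy = mean(-rowSums(y * log(pc))),
    kld = mean(rowSums(ifelse(y > 0, y * log(pmax(y, eps) / pc), 0))),
    poisson = mean(p - y * log(pc)),
    hinge = mean(pmax(0, 1 - (2 * y - 1) * p)),
    squared_hinge = mean(pmax(0, 1 - (2 * y - 1) * p)^2),
    categorical_hinge = mean(pmax(0, 1 + apply((1 - y) * p, 1, max) -
                                    rowSums(y * p))))
}

# One first-order update rule per optimizer name in the default search
# space. Each returns list(init = function(shape), step = function(param,
# grad, state, t)) with step returning list(param, state).
make_optimizer <- function(name, lr = 0.05) {
  eps <- 1e-7
  zero <- function(param) param * 0
  switch(name,
    sgd = list(
      init = function(p) list(),
      step = function(p, g, s, t) list(param = p - lr * g, state = s)),
    sgd_nesterov = list(
      init = function(p) list(v = zero(p)),
      step = function(p, g, s, t) {
        mu <- 0.9
        v <- mu * s$v - lr * g
        list(param = p + mu * v - lr * g, state = list(v = v))
      }),
    adagrad = list(
      init = function(p) list(a = zero(p)),
      step = function(p, g, s, t) {
        a <- s$a + g^2
        list(param = p - lr * g / (sqrt(a) + eps), state = list(a = a))
      }),
    adadelta = list(
      init = function(p) list(a = zero(p), d = zero(p)),
      step = function(p, g, s, t) {
        rho <- 0.95
        a <- rho * s$a + (1 - rho) * g^2
        upd <- -sqrt(s$d + eps) / sqrt(a + eps) * g
        d <- rho * s$d + (1 - rho) * upd^2
        list(param = p + upd, state = list(a = a, d = d))
      }),
    adamax = list(
      init = function(p) list(m = zero(p), u = zero(p)),
      step = function(p, g, s, t) {
        b1 <- 0.9; b2 <- 0.999
        m <- b1 * s$m + (1 - b1) * g
        u <- pmax(b2 * s$u, abs(g))
        list(param = p - (lr / (1 - b1^t)) * m / (u + eps),
             state = list(m = m, u = u))
      }),
    rmsprop = list(
      init = function(p) list(a = zero(p)),
      step = function(p, g, s, t) {
        rho <- 0.9
        a <- rho * s$a + (1 - rho) * g^2
        list(param = p - lr * g / (sqrt(a) + eps), state = list(a = a))
      }),
    rmsprop_centered = list(
      init = function(p) list(a = zero(p), mg = zero(p)),
      step = function(p, g, s, t) {
        rho <- 0.9
        a <- rho * s$a + (1 - rho) * g^2
        mg <- rho * s$mg + (1 - rho) * g
        list(param = p - lr * g / (sqrt(pmax(a - mg^2, 0)) + eps),
             state = list(a = a, mg = mg))
      }),
    adam = list(
      init = function(p) list(m = zero(p), v = zero(p)),
      step = function(p, g, s, t) {
        b1 <- 0.9; b2 <- 0.999
        m <- b1 * s$m + (1 - b1) * g
        v <- b2 * s$v + (1 - b2) * g^2
        mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
        list(param = p - lr * mh / (sqrt(vh) + eps),
             state = list(m = m, v = v))
      }),
    adam_amsgrad = list(
      init = function(p) list(m = zero(p), v = zero(p), vmax = zero(p)),
      step = function(p, g, s, t) {
        b1 <- 0.9; b2 <- 0.999
        m <- b1 * s$m + (1 - b1) * g
        v <- b2 * s$v + (1 - b2) * g^2
        vmax <- pmax(s$vmax, v)
        mh <- m / (1 - b1^t); vh <- vmax / (1 - b2^t)
        list(param = p - lr * mh / (sqrt(vh) + eps),
             state = list(m = m, v = v, vmax = vmax))
      }),
    nadam = list(
      init = function(p) list(m = zero(p), v = zero(p)),
      step = function(p, g, s, t) {
        b1 <- 0.9; b2 <- 0.999
        m <- b1 * s$m + (1 - b1) * g
        v <- b2 * s$v + (1 - b2) * g^2
        mh <- m / (1 - b1^(t + 1)); vh <- v / (1 - b2^t)
        list(param = p - lr * (b1 * mh + (1 - b1) * g / (1 - b1^t)) /
               (sqrt(vh) + eps),
             state = list(m = m, v = v))
      }),
    ftrl = list(
      init = function(p) list(z = zero(p), n = zero(p)),
      step = function(p, g, s, t) {
        n_new <- s$n + g^2
        sigma <- (sqrt(n_new) - sqrt(s$n)) / lr
        z <- s$z + g - sigma * p
        param <- -z * lr / (1 + sqrt(n_new))
        list(param = param, state = list(z = z, n = n_new))
      }),
    stop(sprintf("unknown optimizer '%s'", name), call. = FALSE))
}

# Glorot-uniform initialization, drawn from the caller's RNG stream.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

new_dense_net <- function(feature_dim, hidden, K) {
  dims <- c(feature_dim, hidden, K)
  layers <- lapply(seq_len(length(dims) - 1L), function(i)
    list(W = glorot(dims[i], dims[i + 1]), b = rep(0, dims[i + 1])))
  layers
}

# Forward pass; ReLU on all but the last (softmax) layer. Inverted dropout
# on the last hidden activation when `dropout_rate > 0` and training.
net_forward <- function(layers, X, dropout_rate = 0, training = FALSE) {
  acts <- list(X)
  nl <- length(layers)
  H <- X
  for (i in seq_len(nl)) {
    Z <- sweep(H %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    if (i < nl) {
      H <- relu(Z)
      if (training && dropout_rate > 0 && i == nl - 1L) {
        mask <- matrix(stats::runif(length(H)) >= dropout_rate,
                       nrow(H), ncol(H)) / (1 - dropout_rate)
        H <- H * mask
        acts$dropout_mask <- mask
      }
      acts[[i + 1L]] <- H
    } else {
      acts$logits <- Z
      acts$probs <- softmax_rows(Z)
    }
  }
  acts
}

# Backpropagation from dL/dprobs through the softmax and the dense stack.
# Returns per-layer gradients (same shapes as the parameters).
net_backward <- function(layers, acts, dL_dp) {
  p <- acts$probs
  # chain through the softmax Jacobian: dL/dz = p*(v - sum(p*v)) rowwise
  s <- rowSums(p * dL_dp)
  delta <- p * (dL_dp - s)
  nl <- length(layers)
  grads <- vector("list", nl)
  n <- nrow(p)
  for (i in rev(seq_len(nl))) {
    A <- acts[[i]]
    grads[[i]] <- list(W = crossprod(A, delta) / n,
                       b = colMeans(delta))
    if (i > 1L) {
      delta <- delta %*% t(layers[[i]]$W)
      if (i == nl && !is.null(acts$dropout_mask))
        delta <- delta * acts$dropout_mask
      delta <- delta * (acts[[i]] > 0)   # ReLU derivative
    }
  }
  grads
}
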