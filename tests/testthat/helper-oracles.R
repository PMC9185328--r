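# Independent brute-force oracles, written straight from the update
# equations as scalar-level loops. They consume the random stream in the
# same documented order as the package (row-major initialization; per
# iteration: coefficient draws r4 then l, then member-major branch draw
# followed by branch-specific draws) but share no code with it.

oracle_gto_run <- function(fitness_fn, N, D, Tmax, lb, ub, seed,
                           p = 0.03, beta = 3, w = 0.8) {
  set.seed(seed)
  LB <- rep_len(lb, D); UB <- rep_len(ub, D)
  X <- matrix(0, N, D)
  for (i in 1:N) for (j in 1:D)              # Eq 5, row-major
    X[i, j] <- runif(1) * (UB[j] - LB[j]) + LB[j]
  fit <- numeric(N)
  for (i in 1:N) fit[i] <- fitness_fn(X[i, ])
  history <- min(fit)
  clipv <- function(v) pmin(pmax(v, LB), UB)
  for (t in seq_len(Tmax)) {
    # ---- exploration (Eq 7) ----
    r4 <- runif(1); Fc <- cos(2 * r4) + 1; C <- Fc * (1 - t / Tmax)
    l <- runif(1, -1, 1); L <- C * l
    GX <- X
    for (i in 1:N) {
      branch <- runif(1)
      if (branch < p) {
        gx <- numeric(D)
        for (j in 1:D) gx[j] <- (UB[j] - LB[j]) * runif(1) + LB[j]
      } else if (branch >= 0.5) {
        r2 <- runif(1)
        Z <- numeric(D)
        for (j in 1:D) Z[j] <- runif(1, -C, C)
        H <- Z * X[i, ]
        xr <- X[sample.int(N, 1), ]
        gx <- (r2 - C) * xr + L * H
      } else {
        xr <- X[sample.int(N, 1), ]
        r3 <- runif(1)
        gx <- X[i, ] - L * (L * (X[i, ] - xr) + r3 * (X[i, ] - xr))
      }
      GX[i, ] <- clipv(gx)
    }
    for (i in 1:N) {
      f <- fitness_fn(GX[i, ])
      if (is.finite(f) && f < fit[i]) { X[i, ] <- GX[i, ]; fit[i] <- f }
    }
    history <- c(history, min(fit))
    # ---- exploitation (Eqs 8-9) ----
    r4 <- runif(1); Fc <- cos(2 * r4) + 1; C <- Fc * (1 - t / Tmax)
    l <- runif(1, -1, 1); L <- C * l
    sb <- X[which.min(fit), ]
    GX <- X
    if (C >= w) {
      g <- 2^L
      M <- numeric(D)
      for (j in 1:D) M[j] <- (abs(mean(X[, j]))^g)^(1 / g)
      for (i in 1:N) GX[i, ] <- clipv(L * M * (X[i, ] - sb) + X[i, ])
    } else {
      for (i in 1:N) {
        r5 <- runif(1); Q <- 2 * r5 - 1
        E <- if (runif(1) >= 0.5) rnorm(D) else rnorm(1)
        A <- beta * E
        GX[i, ] <- clipv(sb - (sb * Q - X[i, ] * Q) * A)
      }
    }
    for (i in 1:N) {
      f <- fitness_fn(GX[i, ])
      if (is.finite(f) && f < fit[i]) { X[i, ] <- GX[i, ]; fit[i] <- f }
    }
    history <- c(history, min(fit))
  }
  list(X = X, fitness = fit, history = history,
       best = X[which.min(fit), ], best_fitness = min(fit))
}

# Brute-force one-vs-rest confusion tables, summed over classes.
oracle_confusion <- function(truth, pred, K) {
  TP <- TN <- FP <- FN <- 0
  for (c in 0:(K - 1)) {
    for (i in seq_along(truth)) {
      t_is <- truth[i] == c; p_is <- pred[i] == c
      if (t_is && p_is) TP <- TP + 1
      else if (t_is && !p_is) FN <- FN + 1
      else if (!t_is && p_is) FP <- FP + 1
      else TN <- TN + 1
    }
  }
  list(TP = TP, TN = TN, FP = FP, FN = FN)
}

# Elementwise brute-force probability losses (per-sample loops).
oracle_losses <- function(y, p, eps = 1e-7) {
  n <- nrow(y); K <- ncol(y)
  cc <- kld <- ch <- hg <- sq <- po <- lc <- mae <- mse <- msle <- cs <- 0
  for (i in 1:n) {
    yy <- y[i, ]; pp <- p[i, ]; pcl <- pmin(pmax(pp, eps), 1)
    cc <- cc - sum(yy * log(pcl))
    kld <- kld + sum(ifelse(yy > 0, yy * log(pmax(yy, eps) / pcl), 0))
    ch <- ch + max(0, 1 + max((1 - yy) * pp) - sum(yy * pp))
    yh <- 2 * yy - 1
    hg <- hg + mean(pmax(0, 1 - yh * pp))
    sq <- sq + mean(pmax(0, 1 - yh * pp)^2)
    po <- po + mean(pp - yy * log(pcl))
    lc <- lc + mean(log(cosh(pp - yy)))
    mae <- mae + mean(abs(pp - yy))
    mse <- mse + mean((pp - yy)^2)
    msle <- msle + mean((log1p(pp) - log1p(yy))^2)
    cs <- cs + sum(yy * pp) / max(sqrt(sum(yy^2)) * sqrt(sum(pp^2)), eps)
  }
  list(categorical_crossentropy = cc / n, kld = kld / n,
       categorical_hinge = ch / n, hinge = hg / n, squared_hinge = sq / n,
       poisson = po / n, logcosh = lc / n, mae = mae / n, mse = mse / n,
       msle = msle / n, rmse = sqrt(mse / n), cosine_similarity = cs / n)
}

# Rank-based (Mann-Whitney) AUC for one binary column.
oracle_auc_binary <- function(resp, score) {
  pos <- score[resp == 1]; neg <- score[resp == 0]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Small 3-class bundle shared by harness/pipeline tests.
make_test_bundle <- function(K = 3, n_per_class = 20, seed = 42,
                             noisy_fraction = 0) {
  gen <- generate_brain_dataset(synthetic_spec(
    K = K, n_per_class = n_per_class, image_size = c(32, 32),
    noisy_fraction = noisy_fraction, seed = seed))
  split_dataset(gen$bundle, seed = seed)
}
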