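## Single-hidden-layer feed-forward network for binary classification.
##
## ReLU hidden activation, sigmoid output, binary cross-entropy loss,
## mini-batch Adam. Inputs are standardized internally (the one model
## family here that needs scaling). Deterministic given the seed.

mlp_fit <- function(x, y, hidden = 128L, epochs = 100L, batch_size = 64L,
                    learning_rate = 1e-4, seed = 1L) {
  stopifnot(nrow(x) == length(y))
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  n <- nrow(xs); p <- ncol(xs)
  withr::with_seed(seed, {
    W1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
    b1 <- rep(0, hidden)
    W2 <- matrix(stats::rnorm(hidden, 0, sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
    # Adam state
    adam <- lapply(list(W1, b1, W2, b2), function(z) list(m = z * 0, v = z * 0))
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1, n)]
        xb <- xs[ix, , drop = FALSE]; yb <- y[ix]; m <- length(ix)
        h_pre <- sweep(xb %*% W1, 2, b1, "+")
        h <- pmax(h_pre, 0)
        z <- drop(h %*% W2) + b2
        prob <- stats::plogis(z)
        dz <- (prob - yb) / m
        gW2 <- crossprod(h, dz); gb2 <- sum(dz)
        dh <- (dz %*% t(W2)) * (h_pre > 0)
        gW1 <- crossprod(xb, dh); gb1 <- colSums(dh)
        t <- t + 1
        upd <- function(par, g, st) {
          st$m <- beta1 * st$m + (1 - beta1) * g
          st$v <- beta2 * st$v + (1 - beta2) * g^2
          mh <- st$m / (1 - beta1^t); vh <- st$v / (1 - beta2^t)
          list(par = par - learning_rate * mh / (sqrt(vh) + eps), st = st)
        }
        u <- upd(W1, gW1, adam[[1]]); W1 <- u$par; adam[[1]] <- u$st
        u <- upd(b1, gb1, adam[[2]]); b1 <- u$par; adam[[2]] <- u$st
        u <- upd(W2, gW2, adam[[3]]); W2 <- u$par; adam[[3]] <- u$st
        u <- upd(b2, gb2, adam[[4]]); b2 <- u$par; adam[[4]] <- u$st
      }
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = center, scale = scale)
  })
}

mlp_predict <- function(fit, x) {
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  h <- pmax(sweep(xs %*% fit$W1, 2, fit$b1, "+"), 0)
  stats::plogis(drop(h %*% fit$W2) + fit$b2)
}
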