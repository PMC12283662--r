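# Single-hidden-layer feedforward network (tanh hidden units, linear
# output) with full-batch gradient-descent backpropagation on squared error.
# Written in-package because the PSO-coupled trainer optimizes the flattened
# weight vector directly and then fine-tunes from it by plain gradient
# descent, a contract general-purpose fitters do not expose.

mlp_dim <- function(d, h) d * h + h + h + 1L

mlp_unpack <- function(theta, d, h) {
  i <- 0L
  W1 <- matrix(theta[seq_len(d * h)], d, h); i <- d * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  w2 <- theta[i + seq_len(h)]; i <- i + h
  b2 <- theta[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_forward <- function(theta, X, h) {
  p <- mlp_unpack(theta, ncol(X), h)
  H <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  as.numeric(H %*% p$w2 + p$b2)
}

mlp_mse <- function(theta, X, y, h) mean((mlp_forward(theta, X, h) - y)^2)

mlp_grad <- function(theta, X, y, h) {
  n <- nrow(X); d <- ncol(X)
  p <- mlp_unpack(theta, d, h)
  H <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  r <- as.numeric(H %*% p$w2 + p$b2) - y
  g_out <- 2 * r / n
  gw2 <- as.numeric(crossprod(H, g_out))
  gb2 <- sum(g_out)
  dH <- (g_out %o% p$w2) * (1 - H^2)
  gW1 <- crossprod(X, dH)
  gb1 <- colSums(dH)
  c(as.numeric(gW1), gb1, gw2, gb2)
}

mlp_init <- function(d, h, seed) {
  with_seed(seed, c(stats::runif(d * h, -0.5, 0.5) / sqrt(d),
                    stats::runif(h, -0.5, 0.5),
                    stats::runif(h, -0.5, 0.5) / sqrt(h),
                    0))
}

# Per-layer box at the weight-initialization scale: input weights shrink
# with fan-in so hidden units start unsaturated. Used as the PSO search
# region over the flattened weight vector.
mlp_weight_box <- function(d, h, scale = 1) {
  half <- scale * c(rep(0.5 / sqrt(d), d * h), rep(0.5, h),
                    rep(0.5 / sqrt(h), h), 0.5)
  cbind(-half, half)
}

# Monitored full-batch gradient descent: a step that increases the loss is
# reverted and the learning rate halved, so the final loss never exceeds the
# starting loss.
mlp_descend <- function(theta, X, y, h, max_iter, learning_rate) {
  loss <- mlp_mse(theta, X, y, h)
  if (!is.finite(loss)) stopf("non-finite training loss")
  lr <- learning_rate
  for (it in seq_len(max_iter)) {
    g <- mlp_grad(theta, X, y, h)
    cand <- theta - lr * g
    cand_loss <- mlp_mse(cand, X, y, h)
    if (is.finite(cand_loss) && cand_loss <= loss) {
      theta <- cand; loss <- cand_loss
    } else {
      lr <- lr / 2
      if (lr < 1e-12) break
    }
  }
  list(theta = theta, loss = loss)
}
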