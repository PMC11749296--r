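# Feed-forward multi-step regressor: hidden layers 32 (ELU) and 16
# (linear), linear output, mean-squared-error loss, RMSprop updates,
# mini-batches of 32, early stopping on validation loss. Written directly
# in base matrix algebra so the family is fully deterministic under a seed
# and carries no external runtime.

elu <- function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1)
elu_grad <- function(z, a) ifelse(z > 0, 1, a + 1)

nn_init <- function(sizes, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(i) {
      fan_in <- sizes[i]
      list(
        W = matrix(stats::rnorm(fan_in * sizes[i + 1], sd = sqrt(2 / fan_in)),
                   fan_in, sizes[i + 1]),
        b = rep(0, sizes[i + 1])
      )
    })
  })
}

nn_forward <- function(layers, x) {
  z1 <- sweep(x %*% layers[[1]]$W, 2, layers[[1]]$b, "+")
  a1 <- elu(z1)
  z2 <- sweep(a1 %*% layers[[2]]$W, 2, layers[[2]]$b, "+")
  a2 <- z2                                  # linear second hidden layer
  out <- sweep(a2 %*% layers[[3]]$W, 2, layers[[3]]$b, "+")
  list(z1 = z1, a1 = a1, a2 = a2, out = out)
}

nn_predict <- function(fit, x) {
  nn_forward(fit$layers, x)$out
}

nn_loss <- function(layers, x, y) {
  mean((nn_forward(layers, x)$out - y)^2)
}

fit_nn <- function(spec, x, y, validation = NULL) {
  sizes <- c(ncol(x), spec$opts$hidden, ncol(y))
  stopifnot(length(sizes) == 4)             # two hidden layers
  layers <- nn_init(sizes, spec$seed)
  cache <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  n <- nrow(x)
  lr <- spec$learning_rate
  rho <- 0.9; eps <- 1e-8
  best <- list(layers = layers, loss = Inf, epoch = 0L)
  monitor <- if (!is.null(validation)) validation else list(x = x, y = y)
  history <- numeric(0)

  order_seed <- spec$seed + 7919L
  for (epoch in seq_len(spec$epochs)) {
    perm <- withr::with_seed(order_seed + epoch, sample.int(n))
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- perm[start:min(start + spec$batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx, , drop = FALSE]
      fw <- nn_forward(layers, xb)
      m <- nrow(xb)
      d_out <- 2 * (fw$out - yb) / (m * ncol(yb))
      g3W <- t(fw$a2) %*% d_out
      g3b <- colSums(d_out)
      d_a2 <- d_out %*% t(layers[[3]]$W)    # linear layer: gradient passes through
      g2W <- t(fw$a1) %*% d_a2
      g2b <- colSums(d_a2)
      d_a1 <- (d_a2 %*% t(layers[[2]]$W)) * elu_grad(fw$z1, fw$a1)
      g1W <- t(xb) %*% d_a1
      g1b <- colSums(d_a1)
      grads <- list(list(W = g1W, b = g1b), list(W = g2W, b = g2b), list(W = g3W, b = g3b))
      for (i in 1:3) {
        cache[[i]]$W <- rho * cache[[i]]$W + (1 - rho) * grads[[i]]$W^2
        cache[[i]]$b <- rho * cache[[i]]$b + (1 - rho) * grads[[i]]$b^2
        layers[[i]]$W <- layers[[i]]$W - lr * grads[[i]]$W / (sqrt(cache[[i]]$W) + eps)
        layers[[i]]$b <- layers[[i]]$b - lr * grads[[i]]$b / (sqrt(cache[[i]]$b) + eps)
      }
    }
    loss <- nn_loss(layers, monitor$x, monitor$y)
    history <- c(history, loss)
    if (loss < best$loss - 1e-12) {
      best <- list(layers = layers, loss = loss, epoch = epoch)
    } else if (epoch - best$epoch >= spec$patience) {
      break
    }
  }
  list(layers = best$layers, loss = best$loss, epochs_run = length(history), history = history)
}
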