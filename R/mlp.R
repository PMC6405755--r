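# Minimal feed-forward network used by the gap classifier: fully connected
# layers, rectified-linear hidden activations, softmax output, categorical
# cross-entropy loss, Adam updates on shuffled mini-batches. Written in
# plain matrix algebra -- the network is tiny (2 inputs, two hidden layers
# of 10 units, 4 classes) so no compiled backend is needed.

.mlp_init <- function(sizes) {
  # He-style initialisation, appropriate for ReLU hidden units.
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = rep(0, sizes[l + 1])
    )
  }
  layers
}

.mlp_forward <- function(layers, x) {
  n_layers <- length(layers)
  acts <- vector("list", n_layers + 1)
  acts[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, `+`)
    acts[[l + 1]] <- if (l < n_layers) pmax(z, 0) else z
  }
  logits <- acts[[n_layers + 1]]
  # numerically stable softmax
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  list(acts = acts, probs = probs)
}

# Gradients of mean cross-entropy w.r.t. every W and b.
.mlp_backward <- function(layers, acts, probs, y_onehot) {
  n_layers <- length(layers)
  n <- nrow(y_onehot)
  grads <- vector("list", n_layers)
  delta <- (probs - y_onehot) / n
  for (l in rev(seq_len(n_layers))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
    }
  }
  grads
}

.mlp_train <- function(x, y_idx, sizes, epochs = 100, learning_rate = 0.01,
                       batch_size = 32) {
  layers <- .mlp_init(sizes)
  n_class <- sizes[length(sizes)]
  n <- nrow(x)
  onehot <- matrix(0, n, n_class)
  onehot[cbind(seq_len(n), y_idx)] <- 1
  # Adam state
  mom <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  vel <- mom
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  step <- 0
  loss_trace <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1, n)]
      fw <- .mlp_forward(layers, x[idx, , drop = FALSE])
      grads <- .mlp_backward(layers, fw$acts, fw$probs,
                             onehot[idx, , drop = FALSE])
      step <- step + 1
      for (l in seq_along(layers)) {
        for (p in c("W", "b")) {
          g <- grads[[l]][[p]]
          mom[[l]][[p]] <- beta1 * mom[[l]][[p]] + (1 - beta1) * g
          vel[[l]][[p]] <- beta2 * vel[[l]][[p]] + (1 - beta2) * g^2
          m_hat <- mom[[l]][[p]] / (1 - beta1^step)
          v_hat <- vel[[l]][[p]] / (1 - beta2^step)
          layers[[l]][[p]] <- layers[[l]][[p]] -
            learning_rate * m_hat / (sqrt(v_hat) + eps)
        }
      }
    }
    fw <- .mlp_forward(layers, x)
    loss_trace[epoch] <-
      -mean(log(pmax(fw$probs[cbind(seq_len(n), y_idx)], 1e-12)))
  }
  list(layers = layers, loss_trace = loss_trace)
}
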