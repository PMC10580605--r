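# Feed-forward network with sigmoid hidden layers and a linear output,
# trained by per-pattern (online) backpropagation with momentum: the
# weight update is applied after every training example, in row order,
# for a fixed number of epochs. This is the classic trainer that the
# (learning rate, momentum, iteration-count, hidden-layer) parameter
# vocabulary belongs to. The inner loop lives in src/mlp.cpp; weight
# initialization is seeded here so fits are reproducible.

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(stats::runif(sizes[l] * sizes[l + 1L],
                                   -1, 1) / sqrt(fan_in),
                      sizes[l], sizes[l + 1L]),
           b = rep(0, sizes[l + 1L]))
    })
  })
}

mlp_train <- function(x, y, hidden = c(3, 9, 8), learning_rate = 0.2,
                      momentum = 0.1, iterations = 2000, seed = 1) {
  sizes <- c(ncol(x), hidden, 1L)
  init <- mlp_init(sizes, seed)
  fit <- mlp_train_cpp(x, as.numeric(y),
                       lapply(init, `[[`, "W"),
                       lapply(init, `[[`, "b"),
                       learning_rate, momentum, as.integer(iterations))
  if (fit$diverged_at > 0) {
    stop(sprintf("network training diverged at epoch %d", fit$diverged_at),
         call. = FALSE)
  }
  list(W = fit$W, B = fit$B)
}

mlp_predict <- function(net, x) {
  nl <- length(net$W)
  a <- x
  for (l in seq_len(nl)) {
    z <- a %*% net$W[[l]] +
      matrix(net$B[[l]], nrow(a), length(net$B[[l]]), byrow = TRUE)
    a <- if (l < nl) sigmoid(z) else z
  }
  as.vector(a)
}
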