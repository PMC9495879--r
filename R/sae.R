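# Sparse autoencoder: a single-hidden-layer autoencoder with sigmoid
# activations on both layers whose cost adds a KL-divergence penalty keeping
# the average hidden activation near a small target rho. Used to compress
# each node-class feature block to a common latent width.

#' Sparse autoencoder configuration
#'
#' @param hidden_dim latent width `d` (default 128).
#' @param rho sparsity target in (0, 1): desired average activation of each
#'   hidden unit (default 0.05).
#' @param delta weight of the KL sparsity penalty in the cost (default 1e-3).
#' @param lr learning rate of the full-batch gradient descent (default 0.01).
#' @param epochs number of descent steps (default 100).
#' @param seed seed for the weight initialization.
#' @return Object of class `sae_config`.
#' @export
sae_config <- function(hidden_dim = 128L, rho = 0.05, delta = 1e-3,
                       lr = 0.01, epochs = 100L, seed = 1L) {
  stopifnot(hidden_dim >= 1L, rho > 0, rho < 1, lr > 0, epochs >= 0L)
  structure(
    list(hidden_dim = as.integer(hidden_dim), rho = rho, delta = delta,
         lr = lr, epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "sae_config"
  )
}

# Seeded initialization: untied encoder/decoder weights, uniform in
# +/- 1/sqrt(fan_in).
sae_init <- function(input_dim, config) {
  d <- config$hidden_dim
  local_seed(config$seed, {
    r1 <- 1 / sqrt(input_dim)
    r2 <- 1 / sqrt(d)
    model <- list(
      W_enc = matrix(stats::runif(input_dim * d, -r1, r1), input_dim, d),
      b_enc = rep(0, d),
      W_dec = matrix(stats::runif(d * input_dim, -r2, r2), d, input_dim),
      b_dec = rep(0, input_dim),
      config = config
    )
    class(model) <- "sae_model"
    model
  })
}

#' Sparse autoencoder forward pass
#'
#' Computes `hidden = sigmoid(X W_enc + b_enc)` and
#' `reconstruction = sigmoid(hidden W_dec + b_dec)`.
#'
#' @param model an `sae_model` (see [sae_train()]).
#' @param X input matrix whose width matches the encoder.
#' @return List with matrices `hidden` (n x d) and `reconstruction`
#'   (n x input width); all activations lie in (0, 1).
#' @export
sae_forward <- function(model, X) {
  stopifnot(inherits(model, "sae_model"))
  if (ncol(X) != nrow(model$W_enc)) {
    stop(sprintf("input width %d does not match encoder width %d",
                 ncol(X), nrow(model$W_enc)), call. = FALSE)
  }
  hidden <- sigmoid(sweep(X %*% model$W_enc, 2, model$b_enc, `+`))
  recon <- sigmoid(sweep(hidden %*% model$W_dec, 2, model$b_dec, `+`))
  list(hidden = hidden, reconstruction = recon)
}

#' KL-divergence sparsity penalty
#'
#' The penalty summed over hidden units,
#' `P_s = sum_j [rho log(rho / rho_hat_j) + (1 - rho) log((1 - rho) / (1 - rho_hat_j))]`,
#' where `rho_hat_j` is the average activation of unit `j`. It is
#' non-negative, zero exactly when every `rho_hat_j` equals `rho`, and grows
#' monotonically as any `rho_hat_j` moves away from `rho` on either side.
#' Inputs are clamped to `[1e-8, 1 - 1e-8]` to keep the logs finite.
#'
#' @param rho sparsity target in (0, 1).
#' @param rho_hat numeric vector of per-unit average activations.
#' @return Scalar penalty value.
#' @export
kl_penalty <- function(rho, rho_hat) {
  eps <- 1e-8
  rho <- min(max(rho, eps), 1 - eps)
  rho_hat <- pmin(pmax(rho_hat, eps), 1 - eps)
  sum(rho * log(rho / rho_hat) + (1 - rho) * log((1 - rho) / (1 - rho_hat)))
}

#' Sparse autoencoder cost
#'
#' Total cost `mean((reconstruction - X)^2) + delta * P_s`, with the per-unit
#' average activations taken over the rows of the hidden layer.
#'
#' @param model an `sae_model`.
#' @param X input matrix.
#' @return List with `total`, `reconstruction` (MSE) and `penalty`
#'   (the unweighted KL term).
#' @export
sae_cost <- function(model, X) {
  fwd <- sae_forward(model, X)
  mse <- mean((fwd$reconstruction - X)^2)
  rho_hat <- colMeans(fwd$hidden)
  ps <- kl_penalty(model$config$rho, rho_hat)
  list(total = mse + model$config$delta * ps, reconstruction = mse,
       penalty = ps)
}

# Analytic gradient of the total cost with respect to all four parameter
# blocks. The derivative of the clamp on rho_hat is ignored (standard
# practice; the clamp is active only in pathological saturation).
sae_gradients <- function(model, X) {
  n <- nrow(X)
  p <- ncol(X)
  cfg <- model$config
  fwd <- sae_forward(model, X)
  H <- fwd$hidden
  R <- fwd$reconstruction
  dR <- 2 * (R - X) / (n * p)
  dZ2 <- dR * R * (1 - R)
  dW_dec <- crossprod(H, dZ2)
  db_dec <- colSums(dZ2)
  rho_hat <- pmin(pmax(colMeans(H), 1e-8), 1 - 1e-8)
  d_rho <- cfg$delta * (-cfg$rho / rho_hat + (1 - cfg$rho) / (1 - rho_hat))
  dH <- tcrossprod(dZ2, model$W_dec) +
    matrix(d_rho / n, n, ncol(H), byrow = TRUE)
  dZ1 <- dH * H * (1 - H)
  list(
    W_enc = crossprod(X, dZ1), b_enc = colSums(dZ1),
    W_dec = dW_dec, b_dec = db_dec
  )
}

#' Train a sparse autoencoder
#'
#' Full-batch gradient descent on the penalized reconstruction cost. The run
#' is deterministic given the seed in `config`; epoch 0 corresponds to the
#' initialized model.
#'
#' @param X input matrix (rows are nodes, columns features), finite.
#' @param config an [sae_config()].
#' @return List with `model` (class `sae_model`) and `trace`, a data frame
#'   with per-epoch `total`, `reconstruction` and `penalty`.
#' @export
sae_train <- function(X, config = sae_config()) {
  stopifnot(inherits(config, "sae_config"))
  X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L || !all(is.finite(X))) {
    stop("input matrix must be non-empty and finite", call. = FALSE)
  }
  model <- sae_init(ncol(X), config)
  trace <- data.frame(epoch = integer(0), total = numeric(0),
                      reconstruction = numeric(0), penalty = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    grads <- sae_gradients(model, X)
    model$W_enc <- model$W_enc - config$lr * grads$W_enc
    model$b_enc <- model$b_enc - config$lr * grads$b_enc
    model$W_dec <- model$W_dec - config$lr * grads$W_dec
    model$b_dec <- model$b_dec - config$lr * grads$b_dec
    cost <- sae_cost(model, X)
    if (!is.finite(cost$total)) {
      stop(sprintf("autoencoder cost became non-finite at epoch %d", epoch),
           call. = FALSE)
    }
    trace[epoch, ] <- list(epoch, cost$total, cost$reconstruction,
                           cost$penalty)
  }
  list(model = model, trace = trace)
}

#' Encode inputs to the latent representation
#'
#' @param model a trained `sae_model`.
#' @param X input matrix.
#' @return Latent matrix (rows x `hidden_dim`): the hidden activations.
#' @export
sae_encode <- function(model, X) {
  sae_forward(model, X)$hidden
}

#' Compress both node-class feature blocks to one latent table
#'
#' Trains one sparse autoencoder per node class (their raw feature widths
#' differ) with a shared latent width, then stacks the circRNA and miRNA
#' latent representations into the `(C + M) x d` node table used as the
#' input-layer features of the graph convolutional encoder.
#'
#' @param features a `node_features` object.
#' @param config an [sae_config()]; per-class seeds are derived from
#'   `config$seed`.
#' @return List with `H0` (the stacked latent table, rownames = node ids),
#'   `circ_model`, `mirna_model` and the per-class training traces.
#' @export
sae_compress <- function(features, config = sae_config()) {
  stopifnot(inherits(features, "node_features"))
  seeds <- derive_seeds(config$seed, 2L)
  cfg_c <- config
  cfg_c$seed <- seeds[1]
  cfg_m <- config
  cfg_m$seed <- seeds[2]
  fit_c <- sae_train(features$circ, cfg_c)
  fit_m <- sae_train(features$mirna, cfg_m)
  Hc <- sae_encode(fit_c$model, features$circ)
  Hm <- sae_encode(fit_m$model, features$mirna)
  H0 <- rbind(Hc, Hm)
  rownames(H0) <- c(rownames(features$circ), rownames(features$mirna))
  list(H0 = H0, circ_model = fit_c$model, mirna_model = fit_m$model,
       circ_trace = fit_c$trace, mirna_trace = fit_m$trace)
}
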