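# Graph convolutional encoder with layer attention, sigmoid inner-product
# decoder and weighted cross-entropy training. The two node classes are
# merged into one node set (circRNAs first, then miRNAs); the combined
# adjacency carries the bipartite incidence in its off-diagonal blocks.

#' GCN configuration
#'
#' @param n_layers number of graph convolution layers (default 3).
#' @param dim embedding width, shared by all layers so the layer-attention
#'   sum is well defined (default 64).
#' @param attention `"fixed"` (use `attention_weights` as given) or
#'   `"learnable"` (weights parameterized through a softmax so they stay
#'   non-negative and sum to 1, and are trained with the rest of the model).
#' @param attention_weights per-layer contribution weights; the default
#'   (0.7, 0.2, 0.1) front-loads the first convolution. Must have
#'   `n_layers` entries. The input features (layer 0) are excluded from the
#'   attention sum unless `include_input = TRUE`.
#' @param include_input include the layer-0 (input feature) table in the
#'   attention sum; requires `n_layers + 1` weights. Default `FALSE`.
#' @param lr Adam learning rate (default 0.01).
#' @param epochs full-batch training epochs (default 200).
#' @param omega weight on the positive-class term of the loss; `NULL`
#'   (default) uses the ratio of negative to positive training pairs, which
#'   is 1 under balanced negative sampling.
#' @param seed seed for weight initialization.
#' @return Object of class `gcn_config`.
#' @export
gcn_config <- function(n_layers = 3L, dim = 64L,
                       attention = c("fixed", "learnable"),
                       attention_weights = NULL, include_input = FALSE,
                       lr = 0.01, epochs = 200L, omega = NULL, seed = 1L) {
  attention <- match.arg(attention)
  stopifnot(n_layers >= 1L, dim >= 1L, lr > 0, epochs >= 0L)
  n_terms <- n_layers + as.integer(include_input)
  if (is.null(attention_weights)) {
    attention_weights <- if (n_terms == 3L) c(0.7, 0.2, 0.1) else
      rep(1 / n_terms, n_terms)
  }
  if (length(attention_weights) != n_terms) {
    stop(sprintf("need %d attention weights, got %d",
                 n_terms, length(attention_weights)), call. = FALSE)
  }
  if (any(attention_weights < 0)) {
    stop("attention weights must be non-negative", call. = FALSE)
  }
  structure(
    list(n_layers = as.integer(n_layers), dim = as.integer(dim),
         attention = attention,
         attention_weights = as.numeric(attention_weights),
         include_input = isTRUE(include_input),
         lr = lr, epochs = as.integer(epochs), omega = omega,
         seed = as.integer(seed)),
    class = "gcn_config"
  )
}

#' Combined graph adjacency from the bipartite incidence
#'
#' Builds the `(C + M) x (C + M)` symmetric adjacency
#' `A = rbind(cbind(0, B), cbind(t(B), 0))` over the merged node set.
#'
#' @param B bipartite C x M incidence matrix.
#' @return Square symmetric matrix; circRNA nodes first.
#' @export
combined_adjacency <- function(B) {
  C <- nrow(B)
  M <- ncol(B)
  A <- matrix(0, C + M, C + M)
  A[seq_len(C), C + seq_len(M)] <- B
  A[C + seq_len(M), seq_len(C)] <- t(B)
  nm <- c(rownames(B), colnames(B))
  if (!is.null(nm) && length(nm) == C + M) dimnames(A) <- list(nm, nm)
  A
}

#' Add self-loops
#'
#' `A_hat = A + I`: every node contributes its own features during
#' propagation. Applied literally, so an existing diagonal is incremented.
#'
#' @param A square matrix.
#' @return `A + I`.
#' @export
add_self_loops <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  A + diag(nrow(A))
}

#' Symmetric degree normalization
#'
#' Computes `A_tilde = D^-1/2 A_hat D^-1/2` with `D` the diagonal row-sum
#' (degree) matrix. After self-loops every degree is positive and the
#' spectral radius of the result is at most 1, which keeps deep propagation
#' numerically stable.
#'
#' @param A_hat square non-negative matrix with no zero rows.
#' @return Normalized adjacency of the same shape.
#' @export
normalize_adjacency <- function(A_hat) {
  if (!is.matrix(A_hat) || nrow(A_hat) != ncol(A_hat)) {
    stop("adjacency must be a square matrix", call. = FALSE)
  }
  deg <- rowSums(A_hat)
  if (any(deg <= 0)) {
    stop("zero row sum; add self-loops before normalizing", call. = FALSE)
  }
  inv_sqrt <- 1 / sqrt(deg)
  A_hat * tcrossprod(inv_sqrt)
}

# Seeded per-layer weight initialization, uniform +/- 1/sqrt(fan_in).
gcn_init <- function(input_dim, config) {
  local_seed(config$seed, {
    dims <- c(input_dim, rep(config$dim, config$n_layers))
    W <- vector("list", config$n_layers)
    for (l in seq_len(config$n_layers)) {
      r <- 1 / sqrt(dims[l])
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -r, r),
                       dims[l], dims[l + 1])
    }
    theta <- if (config$attention == "learnable") {
      log(pmax(config$attention_weights, 1e-6))
    } else {
      NULL
    }
    structure(list(W = W, theta = theta, config = config),
              class = "gcn_model")
  })
}

attention_vector <- function(model) {
  if (model$config$attention == "learnable") {
    e <- exp(model$theta - max(model$theta))
    e / sum(e)
  } else {
    model$config$attention_weights
  }
}

#' GCN forward pass
#'
#' Iterates `H^(l+1) = ReLU(A_tilde H^(l) W^(l))` from the input features.
#'
#' @param model a `gcn_model`.
#' @param A_norm normalized adjacency over the merged node set.
#' @param H0 input feature table, one row per node.
#' @return List of per-layer embeddings; element 1 is `H0` itself, elements
#'   `2..n_layers+1` the successive convolutions.
#' @export
gcn_forward <- function(model, A_norm, H0) {
  stopifnot(inherits(model, "gcn_model"))
  if (nrow(H0) != nrow(A_norm)) {
    stop("feature table rows must match the node count", call. = FALSE)
  }
  if (ncol(H0) != nrow(model$W[[1]])) {
    stop("feature width does not match the first layer weights", call. = FALSE)
  }
  H <- vector("list", model$config$n_layers + 1L)
  H[[1]] <- H0
  for (l in seq_len(model$config$n_layers)) {
    H[[l + 1]] <- relu(A_norm %*% H[[l]] %*% model$W[[l]])
  }
  H
}

#' Combine per-layer embeddings with attention weights
#'
#' `M = sum_l n_l H^(l)`, the weighted sum of equal-shaped layer embeddings.
#'
#' @param embeddings list of equal-shaped matrices.
#' @param weights numeric vector, one weight per embedding.
#' @return The combined embedding matrix.
#' @export
layer_attention_combine <- function(embeddings, weights) {
  if (length(embeddings) != length(weights)) {
    stop("one weight per layer embedding is required", call. = FALSE)
  }
  dims <- vapply(embeddings, dim, integer(2))
  if (any(dims != dims[, 1])) {
    stop("layer embeddings must share one shape", call. = FALSE)
  }
  out <- matrix(0, dims[1, 1], dims[2, 1], dimnames = dimnames(embeddings[[1]]))
  for (l in seq_along(embeddings)) {
    out <- out + weights[l] * embeddings[[l]]
  }
  out
}

# Embeddings entering the attention sum: layers 1..L, optionally prefixed by
# the layer-0 input features.
attended_layers <- function(model, H) {
  if (model$config$include_input) H else H[-1]
}

#' Final node embedding
#'
#' Runs the forward pass and combines the attended layers into the final
#' embedding table.
#'
#' @inheritParams gcn_forward
#' @return Node embedding matrix (nodes x dim).
#' @export
gcn_embed <- function(model, A_norm, H0) {
  H <- gcn_forward(model, A_norm, H0)
  layer_attention_combine(attended_layers(model, H), attention_vector(model))
}

#' Sigmoid inner-product decoder
#'
#' Scores every node pair as `S = sigmoid(M M^T)`, the matrix-factorization
#' style link score on the final embeddings.
#'
#' @param M node embedding matrix.
#' @return Symmetric score matrix with entries in (0, 1).
#' @export
inner_product_decode <- function(M) {
  if (!all(is.finite(M))) stop("embeddings must be finite", call. = FALSE)
  sigmoid(tcrossprod(M))
}

#' Weighted binary cross-entropy on logits
#'
#' Mean over training pairs of
#' `-(b * log(sigmoid(z)) * omega + (1 - b) * log(1 - sigmoid(z)))`, where
#' `omega` reweights the positive class by the negative:positive ratio of the
#' training set. Log arguments are clamped at 1e-12.
#'
#' @param labels 0/1 vector.
#' @param logits raw inner-product scores `z`, parallel to `labels`.
#' @param omega positive-class weight (default 1, the balanced case).
#' @return Scalar loss.
#' @export
weighted_bce_loss <- function(labels, logits, omega = 1) {
  stopifnot(length(labels) == length(logits), all(labels %in% c(0, 1)))
  p <- sigmoid(logits)
  mean(-(labels * clamped_log(p) * omega + (1 - labels) * clamped_log(1 - p)))
}

# Loss and analytic gradients for one parameter state. `pairs` is a 2-column
# matrix of global node indices. Backpropagates through the decoder, the
# attention sum and every convolution layer.
gcn_loss_grad <- function(model, A_norm, H0, pairs, labels, omega) {
  cfg <- model$config
  H <- gcn_forward(model, A_norm, H0)
  att <- attention_vector(model)
  layers <- attended_layers(model, H)
  M <- layer_attention_combine(layers, att)
  a <- pairs[, 1]
  b <- pairs[, 2]
  z <- rowSums(M[a, , drop = FALSE] * M[b, , drop = FALSE])
  p <- sigmoid(z)
  Tn <- length(z)
  loss <- mean(-(labels * clamped_log(p) * omega +
                   (1 - labels) * clamped_log(1 - p)))
  # d loss / d z for each pair
  dz <- (-labels * omega * (1 - p) + (1 - labels) * p) / Tn
  # accumulate into dM: pair (a, b) contributes dz * M[b, ] to row a and
  # dz * M[a, ] to row b
  N <- nrow(M)
  Ea <- Matrix::sparseMatrix(i = a, j = seq_len(Tn), x = 1, dims = c(N, Tn))
  Eb <- Matrix::sparseMatrix(i = b, j = seq_len(Tn), x = 1, dims = c(N, Tn))
  dM <- as.matrix(Ea %*% (dz * M[b, , drop = FALSE]) +
                    Eb %*% (dz * M[a, , drop = FALSE]))
  # attention gradients (learnable mode): through the softmax
  d_theta <- NULL
  if (cfg$attention == "learnable") {
    d_att <- vapply(layers, function(Hl) sum(dM * Hl), numeric(1))
    d_theta <- att * (d_att - sum(att * d_att))
  }
  # backprop through the convolution stack; layer l output is H[[l + 1]]
  offset <- as.integer(!cfg$include_input)  # attention index of H[[l + 1]]
  dH <- vector("list", cfg$n_layers + 1L)
  for (l in seq_len(cfg$n_layers + 1L)) dH[[l]] <- matrix(0, N, ncol(H[[l]]))
  for (l in seq_len(cfg$n_layers)) {
    wl <- att[l + 1L - offset]
    if (l + 1L - offset >= 1L) dH[[l + 1]] <- dH[[l + 1]] + wl * dM
  }
  if (cfg$include_input) dH[[1]] <- dH[[1]] + att[1] * dM
  dW <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    dZ <- dH[[l + 1]] * (H[[l + 1]] > 0)
    AH <- A_norm %*% H[[l]]
    dW[[l]] <- crossprod(AH, dZ)
    dH[[l]] <- dH[[l]] + crossprod(A_norm, dZ %*% t(model$W[[l]]))
  }
  list(loss = loss, dW = dW, d_theta = d_theta)
}

#' Train the GCN link predictor
#'
#' Full-batch Adam minimization of the weighted cross-entropy over the
#' training pairs (known positive edges plus sampled negatives). The
#' adjacency must be built from training positives only so held-out edges
#' are never visible to the encoder.
#'
#' @param H0 input feature table over the merged node set (circRNAs first).
#' @param A_norm normalized adjacency from training edges.
#' @param pairs 2-column integer matrix of global node index pairs
#'   (circRNA index, C + miRNA index).
#' @param labels 0/1 vector parallel to `pairs`.
#' @param config a [gcn_config()].
#' @return List with `model` (class `gcn_model`) and `trace`, the per-epoch
#'   loss values.
#' @export
gcn_train <- function(H0, A_norm, pairs, labels, config = gcn_config()) {
  stopifnot(inherits(config, "gcn_config"))
  pairs <- as.matrix(pairs)
  if (max(pairs) > nrow(H0) || min(pairs) < 1) {
    stop("training pairs index nodes outside the feature table", call. = FALSE)
  }
  omega <- config$omega
  if (is.null(omega)) {
    n_pos <- sum(labels == 1)
    omega <- if (n_pos > 0) sum(labels == 0) / n_pos else 1
  }
  model <- gcn_init(ncol(H0), config)
  # Adam state
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mW <- lapply(model$W, function(w) w * 0)
  vW <- mW
  mT <- vT <- if (!is.null(model$theta)) model$theta * 0 else NULL
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    g <- gcn_loss_grad(model, A_norm, H0, pairs, labels, omega)
    if (!is.finite(g$loss)) {
      stop(sprintf("training loss became non-finite at epoch %d", epoch),
           call. = FALSE)
    }
    trace[epoch] <- g$loss
    corr1 <- 1 - beta1^epoch
    corr2 <- 1 - beta2^epoch
    for (l in seq_along(model$W)) {
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * g$dW[[l]]
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * g$dW[[l]]^2
      model$W[[l]] <- model$W[[l]] -
        config$lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
    }
    if (!is.null(model$theta)) {
      mT <- beta1 * mT + (1 - beta1) * g$d_theta
      vT <- beta2 * vT + (1 - beta2) * g$d_theta^2
      model$theta <- model$theta -
        config$lr * (mT / corr1) / (sqrt(vT / corr2) + eps)
    }
  }
  model$omega <- omega
  list(model = model, trace = trace)
}

#' Score the circRNA x miRNA block
#'
#' Extracts the evaluation view of the full pairwise score matrix: rows are
#' circRNAs, columns miRNAs.
#'
#' @param S full `(C + M) x (C + M)` score matrix.
#' @param n_circ number of circRNA nodes (the leading block).
#' @return C x M score matrix.
#' @export
score_block <- function(S, n_circ) {
  S[seq_len(n_circ), (n_circ + 1):nrow(S), drop = FALSE]
}

#' Rank candidate pairs by predicted score
#'
#' Orders all circRNA x miRNA pairs not among the known positives by
#' descending score; ties are broken by ascending (circRNA index, miRNA
#' index) so the ranking is deterministic.
#'
#' @param S_cm C x M score matrix (see [score_block()]).
#' @param known_positives 2-column integer matrix of (circ, mirna) index
#'   pairs to exclude from the ranking.
#' @param top optional number of top rows to keep.
#' @return Data frame with columns `circ`, `mirna` (indices), `circ_id`,
#'   `mirna_id` (when `S_cm` carries dimnames), `score` and `rank`.
#' @export
rank_candidates <- function(S_cm, known_positives = NULL, top = NULL) {
  C <- nrow(S_cm)
  M <- ncol(S_cm)
  ci <- rep(seq_len(C), times = M)
  mi <- rep(seq_len(M), each = C)
  keep <- rep(TRUE, C * M)
  if (!is.null(known_positives) && nrow(known_positives) > 0L) {
    keep[(known_positives[, 2] - 1) * C + known_positives[, 1]] <- FALSE
  }
  out <- data.frame(circ = ci[keep], mirna = mi[keep],
                    score = as.vector(S_cm)[keep])
  ord <- order(-out$score, out$circ, out$mirna)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(rownames(S_cm))) out$circ_id <- rownames(S_cm)[out$circ]
  if (!is.null(colnames(S_cm))) out$mirna_id <- colnames(S_cm)[out$mirna]
  if (!is.null(top)) out <- utils::head(out, top)
  rownames(out) <- NULL
  out
}
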