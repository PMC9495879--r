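# Independent brute-force oracles: deliberately written as scalar loops with
# no shared code paths with the package internals, so agreement is evidence
# of correctness rather than repetition.

oracle_gip <- function(P, alpha_prime = 0.5) {
  n <- nrow(P)
  norms <- numeric(n)
  for (i in seq_len(n)) {
    for (q in seq_len(ncol(P))) norms[i] <- norms[i] + P[i, q]^2
  }
  alpha <- alpha_prime / (sum(norms) / n)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d2 <- 0
      for (q in seq_len(ncol(P))) d2 <- d2 + (P[i, q] - P[j, q])^2
      G[i, j] <- exp(-alpha * d2)
    }
  }
  G
}

oracle_sigmoid_kernel <- function(X) {
  n <- nrow(X)
  V <- ncol(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ip <- 0
      for (q in seq_len(V)) ip <- ip + X[i, q] * X[j, q]
      K[i, j] <- tanh(ip / V)
    }
  }
  K
}

oracle_normalize_adjacency <- function(A_hat) {
  n <- nrow(A_hat)
  deg <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) deg[i] <- deg[i] + A_hat[i, j]
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- A_hat[i, j] / (sqrt(deg[i]) * sqrt(deg[j]))
    }
  }
  out
}

oracle_matmul <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      s <- 0
      for (q in seq_len(ncol(A))) s <- s + A[i, q] * B[q, j]
      out[i, j] <- s
    }
  }
  out
}

oracle_gcn_forward <- function(A_norm, H0, W_list) {
  H <- H0
  out <- list(H0)
  for (W in W_list) {
    Z <- oracle_matmul(oracle_matmul(A_norm, H), W)
    H <- matrix(pmax(as.vector(Z), 0), nrow(Z), ncol(Z))
    out[[length(out) + 1]] <- H
  }
  out
}

oracle_decoder <- function(M) {
  n <- nrow(M)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      z <- 0
      for (q in seq_len(ncol(M))) z <- z + M[i, q] * M[j, q]
      S[i, j] <- 1 / (1 + exp(-z))
    }
  }
  S
}

oracle_bce <- function(labels, logits, omega) {
  total <- 0
  for (t in seq_along(labels)) {
    p <- 1 / (1 + exp(-logits[t]))
    total <- total - (labels[t] * log(p) * omega + (1 - labels[t]) * log(1 - p))
  }
  total / length(labels)
}

# AUC as the fraction of concordant (positive, negative) score pairs, ties
# counted half.
oracle_auc <- function(labels, scores) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  conc <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) conc <- conc + 1
      else if (scores[i] == scores[j]) conc <- conc + 0.5
    }
  }
  conc / (length(pos) * length(neg))
}

# AUPR by explicit threshold sweep over the distinct score values.
oracle_aupr <- function(labels, scores) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1)
  prev_rec <- 0
  area <- 0
  for (t in cuts) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / n1
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

oracle_sae_cost <- function(W_enc, b_enc, W_dec, b_dec, X, rho, delta) {
  n <- nrow(X)
  p <- ncol(X)
  d <- ncol(W_enc)
  sig <- function(x) 1 / (1 + exp(-x))
  H <- matrix(0, n, d)
  for (i in seq_len(n)) {
    for (j in seq_len(d)) {
      s <- b_enc[j]
      for (q in seq_len(p)) s <- s + X[i, q] * W_enc[q, j]
      H[i, j] <- sig(s)
    }
  }
  R <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      s <- b_dec[j]
      for (q in seq_len(d)) s <- s + H[i, q] * W_dec[q, j]
      R[i, j] <- sig(s)
    }
  }
  mse <- 0
  for (i in seq_len(n)) for (j in seq_len(p)) mse <- mse + (R[i, j] - X[i, j])^2
  mse <- mse / (n * p)
  ps <- 0
  for (j in seq_len(d)) {
    rh <- sum(H[, j]) / n
    ps <- ps + rho * log(rho / rh) + (1 - rho) * log((1 - rho) / (1 - rh))
  }
  mse + delta * ps
}
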