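test_that("self-loops and symmetric normalization follow their definitions", {
  expect_equal(add_self_loops(matrix(0, 3, 3)), diag(3))
  expect_equal(diag(add_self_loops(diag(3))), rep(2, 3))
  expect_error(add_self_loops(matrix(0, 2, 3)), "square")

  # two nodes, one edge, self-loops: D = diag(2, 2)
  A_hat <- add_self_loops(matrix(c(0, 1, 1, 0), 2))
  expect_equal(normalize_adjacency(A_hat), matrix(0.5, 2, 2))

  # isolated node keeps a unit diagonal entry
  A2 <- add_self_loops(matrix(0, 1, 1))
  expect_equal(normalize_adjacency(A2), matrix(1, 1, 1))

  expect_error(normalize_adjacency(matrix(0, 2, 2)), "zero row")

  set.seed(21)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    A <- matrix(rbinom(n * n, 1, 0.3), n, n)
    A <- 1 * ((A + t(A)) > 0)
    diag(A) <- 0
    A_norm <- normalize_adjacency(add_self_loops(A))
    expect_equal(A_norm, t(A_norm))
    expect_equal(unname(A_norm), oracle_normalize_adjacency(add_self_loops(A)),
                 tolerance = 1e-12)
    ev <- eigen(A_norm, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-10 & ev <= 1 + 1e-10))
  }
})

test_that("combined adjacency carries the bipartite incidence off-diagonal", {
  B <- matrix(c(1, 0, 1, 1), 2, 2)
  A <- combined_adjacency(B)
  expect_equal(dim(A), c(4L, 4L))
  expect_equal(A[1:2, 3:4], B)
  expect_equal(A[3:4, 1:2], t(B))
  expect_equal(A[1:2, 1:2], matrix(0, 2, 2))
  expect_equal(A, t(A))
})

test_that("the forward pass is the normalized propagation rule", {
  cfg <- gcn_config(n_layers = 1L, dim = 3L, attention_weights = 1, seed = 1)
  model <- circmir:::gcn_init(3L, cfg)
  model$W[[1]] <- diag(3)
  H0 <- matrix(runif(9), 3, 3)
  H <- gcn_forward(model, diag(3), H0)
  expect_equal(H[[2]], H0)

  set.seed(8)
  cfg2 <- gcn_config(n_layers = 2L, dim = 3L,
                     attention_weights = c(0.5, 0.5), seed = 8)
  model2 <- circmir:::gcn_init(4L, cfg2)
  A <- normalize_adjacency(add_self_loops(
    combined_adjacency(matrix(c(1, 0, 1, 1), 2, 2))))
  H0b <- matrix(rnorm(16), 4, 4)
  got <- gcn_forward(model2, A, H0b)
  want <- oracle_gcn_forward(A, H0b, model2$W)
  for (l in 1:3) expect_equal(unname(got[[l]]), unname(want[[l]]),
                              tolerance = 1e-10)
  expect_true(all(got[[2]] >= 0))
  expect_true(all(got[[3]] >= 0))
  expect_error(gcn_forward(model2, A, matrix(0, 3, 4)), "node count")
  expect_error(gcn_forward(model2, A, matrix(0, 4, 5)), "width")
})

test_that("layer attention combines embeddings as a weighted sum", {
  H1 <- matrix(1:6, 2, 3)
  expect_equal(layer_attention_combine(list(H1), 1), H1)
  expect_equal(layer_attention_combine(list(H1, H1, H1), c(0.7, 0.2, 0.1)),
               H1)
  H2 <- matrix(rnorm(6), 2, 3)
  expect_equal(layer_attention_combine(list(H1, H2), c(0.3, 0.7)),
               0.3 * H1 + 0.7 * H2)
  # a degenerate weight vector selects a single layer
  expect_equal(layer_attention_combine(list(H1, H2, H2), c(1, 0, 0)), H1)
  expect_error(layer_attention_combine(list(H1, H2), 1), "one weight per")
  expect_error(layer_attention_combine(list(H1, matrix(0, 3, 3)), c(1, 1)),
               "share one shape")
  expect_equal(gcn_config()$attention_weights, c(0.7, 0.2, 0.1))
})

test_that("the inner-product decoder produces symmetric probabilities", {
  expect_equal(inner_product_decode(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  M <- rbind(c(1, 0), c(0, 1))
  S <- inner_product_decode(M)
  expect_equal(S[1, 2], 0.5)
  expect_equal(S[1, 1], 1 / (1 + exp(-1)), tolerance = 1e-10)
  set.seed(2)
  M2 <- matrix(rnorm(12), 4, 3)
  S2 <- inner_product_decode(M2)
  expect_equal(S2, t(S2))
  expect_true(all(S2 > 0 & S2 < 1))
  expect_equal(unname(S2), oracle_decoder(M2), tolerance = 1e-10)
})

test_that("weighted cross-entropy matches direct substitution", {
  expect_equal(weighted_bce_loss(1, 0), log(2), tolerance = 1e-12)
  expect_equal(weighted_bce_loss(0, 0), log(2), tolerance = 1e-12)
  expect_lt(weighted_bce_loss(1, 40), 1e-10)
  set.seed(4)
  labels <- rbinom(20, 1, 0.5)
  logits <- rnorm(20)
  for (omega in c(0.5, 1, 2)) {
    expect_equal(weighted_bce_loss(labels, logits, omega),
                 oracle_bce(labels, logits, omega), tolerance = 1e-10)
  }
})

test_that("analytic gradients match finite differences on a small fixture", {
  set.seed(31)
  B <- matrix(c(1, 0, 1, 1, 0, 1), 3, 2)
  A <- normalize_adjacency(add_self_loops(combined_adjacency(B)))
  H0 <- matrix(rnorm(5 * 3), 5, 3)
  pairs <- cbind(c(1, 2, 3, 1), c(4, 5, 4, 5))
  labels <- c(1, 1, 0, 0)
  for (att in c("fixed", "learnable")) {
    cfg <- gcn_config(n_layers = 2L, dim = 3L, attention = att,
                      attention_weights = c(0.6, 0.4), seed = 31)
    model <- circmir:::gcn_init(3L, cfg)
    g <- circmir:::gcn_loss_grad(model, A, H0, pairs, labels, omega = 1.5)
    loss_at <- function(m) {
      circmir:::gcn_loss_grad(m, A, H0, pairs, labels, omega = 1.5)$loss
    }
    h <- 1e-5
    for (l in seq_along(model$W)) {
      for (idx in sample(length(model$W[[l]]), 4)) {
        up <- model; up$W[[l]][idx] <- up$W[[l]][idx] + h
        dn <- model; dn$W[[l]][idx] <- dn$W[[l]][idx] - h
        expect_equal(g$dW[[l]][idx], (loss_at(up) - loss_at(dn)) / (2 * h),
                     tolerance = 1e-5)
      }
    }
    if (att == "learnable") {
      for (idx in seq_along(model$theta)) {
        up <- model; up$theta[idx] <- up$theta[idx] + h
        dn <- model; dn$theta[idx] <- dn$theta[idx] - h
        expect_equal(g$d_theta[idx], (loss_at(up) - loss_at(dn)) / (2 * h),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("training reduces the loss on a planted graph and is reproducible", {
  spec <- synthetic_spec(n_circ = 20L, n_mirna = 20L, circ_len = c(50L, 80L),
                         n_blocks = 2L, p = 0.7, q = 0.05)
  ds <- generate_planted_bipartite(spec, 3)
  B <- build_bipartite_adjacency(ds)
  A <- normalize_adjacency(add_self_loops(combined_adjacency(B)))
  C <- length(ds$circ_ids)
  set.seed(77)
  H0 <- matrix(rnorm((C + length(ds$mirna_ids)) * 8), ncol = 8)
  neg <- sample_negative_pairs(ds, nrow(ds$pairs), seed = 5)
  pairs <- rbind(cbind(ds$pairs[, 1], C + ds$pairs[, 2]),
                 cbind(neg[, 1], C + neg[, 2]))
  labels <- rep(c(1, 0), c(nrow(ds$pairs), nrow(neg)))
  cfg <- gcn_config(dim = 8L, epochs = 60L, seed = 11)
  fit <- gcn_train(H0, A, pairs, labels, cfg)
  expect_lt(fit$trace[60], fit$trace[1])
  fit2 <- gcn_train(H0, A, pairs, labels, cfg)
  expect_identical(fit$trace, fit2$trace)

  cfg0 <- gcn_config(dim = 8L, epochs = 0L, seed = 11)
  fit0 <- gcn_train(H0, A, pairs, labels, cfg0)
  init <- circmir:::gcn_init(8L, cfg0)
  expect_identical(fit0$model$W, init$W)
})

test_that("candidate ranking excludes known pairs and breaks ties by index", {
  S <- matrix(0.1, 3, 4)
  ranked <- rank_candidates(S)
  expect_equal(ranked$circ, rep(1:3, each = 4))
  expect_equal(ranked$mirna, rep(1:4, times = 3))

  S2 <- matrix(0.1, 3, 4)
  S2[2, 3] <- 0.9
  expect_equal(rank_candidates(S2)[1, c("circ", "mirna")],
               data.frame(circ = 2L, mirna = 3L))

  known <- cbind(2L, 3L)
  ranked3 <- rank_candidates(S2, known)
  expect_equal(nrow(ranked3), 11L)
  expect_false(any(ranked3$circ == 2 & ranked3$mirna == 3))

  top <- rank_candidates(S2, top = 5)
  expect_equal(nrow(top), 5L)
  expect_equal(top$rank, 1:5)
})
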