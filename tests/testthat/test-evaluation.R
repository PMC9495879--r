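test_that("fold test sets partition the positives with fresh disjoint negatives", {
  bench <- small_benchmark(2)
  ds <- bench$dataset
  folds <- kfold_split(ds, k = 5, seed = 3)
  expect_length(folds, 5L)

  key <- function(m) paste(m[, 1], m[, 2])
  all_pos <- key(ds$pairs)
  test_keys <- lapply(folds, function(f) key(f$test_pos))
  # disjoint across folds, union = all positives
  expect_length(unlist(test_keys), length(all_pos))
  expect_setequal(unlist(test_keys), all_pos)
  sizes <- lengths(test_keys)
  expect_lte(max(sizes) - min(sizes), 1L)

  for (f in folds) {
    expect_setequal(c(key(f$train_pos), key(f$test_pos)), all_pos)
    negs <- c(key(f$train_neg), key(f$test_neg))
    expect_length(intersect(negs, all_pos), 0L)
    expect_false(any(duplicated(negs)))
    expect_equal(nrow(f$train_neg), nrow(f$train_pos))
    expect_equal(nrow(f$test_neg), nrow(f$test_pos))
  }

  expect_identical(kfold_split(ds, k = 5, seed = 3), folds)
  expect_error(kfold_split(ds, k = 1, seed = 1), "at least 2")
})

test_that("small and large fold-size arithmetic is balanced", {
  ds10 <- interaction_dataset(paste0("c", 1:10), rep(paste0("m", 1:5), 2))
  folds <- kfold_split(ds10, k = 5, seed = 1)
  expect_equal(vapply(folds, function(f) nrow(f$test_pos), integer(1)),
               rep(2L, 5))

  # a 9905-pair dataset splits into five folds of exactly 1981 test positives
  ci <- rep(seq_len(200), length.out = 9905)
  mi <- rep(seq_len(100), each = 100)[seq_len(9905)]
  big <- interaction_dataset(paste0("c", ci), paste0("m", mi))
  expect_equal(nrow(big$pairs), 9905L)
  folds_big <- kfold_split(big, k = 5, seed = 1)
  expect_equal(vapply(folds_big, function(f) nrow(f$test_pos), integer(1)),
               rep(1981L, 5))
})

test_that("confusion-matrix metrics match direct substitution", {
  m <- compute_metrics(c(1, 0), c(0.9, 0.1))
  expect_equal(m$acc, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  labels <- c(1, 1, 1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.9, 0.9, 0.1, 0.1, 0.9, 0.1, 0.1)
  m2 <- compute_metrics(labels, scores)
  expect_equal(list(m2$tp, m2$tn, m2$fp, m2$fn), list(3L, 2L, 1L, 2L))
  expect_equal(m2$acc, 0.625)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 0.6)

  expect_warning(m3 <- compute_metrics(labels, scores, threshold = 1.1),
                 "precision undefined")
  expect_equal(m3$tp + m3$fp, 0L)
  expect_true(is.nan(m3$precision))
})

test_that("AUC and AUPR agree with brute-force oracles", {
  expect_equal(auc_aupr(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(auc_aupr(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(auc_aupr(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(19)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)  # rounding forces ties
    got <- auc_aupr(labels, scores)
    expect_equal(got$auc, oracle_auc(labels, scores), tolerance = 1e-10)
    expect_equal(got$aupr, oracle_aupr(labels, scores), tolerance = 1e-10)
  }
})

test_that("rank-statistic AUC matches an established implementation", {
  set.seed(23)
  labels <- rbinom(60, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- runif(60)
  got <- auc_aupr(labels, scores)$auc
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("cross-validation reports five folds plus a mean row, deterministically", {
  bench <- small_benchmark(4)
  rep1 <- suppressWarnings(cross_validate(
    bench$dataset, mode = "sequence", circ_seqs = bench$sequences$circ,
    mirna_seqs = bench$sequences$mirna, seed = 2, sae = small_sae(),
    gcn = small_gcn()
  ))
  expect_s3_class(rep1, "metrics_report")
  expect_equal(rownames(rep1), c(paste0("fold", 1:5), "mean"))
  expect_equal(colnames(rep1),
               c("fold", "acc", "precision", "recall", "auc", "aupr"))
  expect_equal(rep1["mean", "auc"], mean(rep1$auc[1:5]))
  expect_true(all(rep1$auc >= 0 & rep1$auc <= 1))

  rep2 <- suppressWarnings(cross_validate(
    bench$dataset, mode = "sequence", circ_seqs = bench$sequences$circ,
    mirna_seqs = bench$sequences$mirna, seed = 2, sae = small_sae(),
    gcn = small_gcn()
  ))
  expect_identical(as.data.frame(rep1), as.data.frame(rep2))

  # profile-only mode runs from the interaction table alone
  rep3 <- suppressWarnings(cross_validate(
    bench$dataset, mode = "profile", seed = 2, sae = small_sae(),
    gcn = small_gcn()
  ))
  expect_equal(dim(rep3), dim(rep1))

  expect_error(cross_validate(bench$dataset, mode = "sequence", seed = 1),
               "sequence mode requires")
})

test_that("the no-GCN ablation shares the protocol and report shape", {
  bench <- small_benchmark(5)
  abl <- suppressWarnings(ablate_no_gcn(
    bench$dataset, mode = "profile", seed = 2, sae = small_sae(),
    gcn = small_gcn()
  ))
  expect_s3_class(abl, "metrics_report")
  expect_equal(rownames(abl), c(paste0("fold", 1:5), "mean"))
  abl2 <- suppressWarnings(ablate_no_gcn(
    bench$dataset, mode = "profile", seed = 2, sae = small_sae(),
    gcn = small_gcn()
  ))
  expect_identical(as.data.frame(abl), as.data.frame(abl2))
})

test_that("sweep drivers tabulate one row per configuration", {
  bench <- small_benchmark(6)
  sw <- suppressWarnings(sweep_layers(
    bench$dataset, layers = c(1, 2), mode = "profile", seed = 2,
    sae = small_sae(), gcn = small_gcn()
  ))
  expect_equal(sw$layers, c(1L, 2L))
  expect_equal(colnames(sw), c("layers", "auc", "aupr"))

  swa <- suppressWarnings(sweep_attention(
    bench$dataset, triples = list(c(0.7, 0.2, 0.1), c(1, 0, 0)),
    mode = "profile", seed = 2, sae = small_sae(), gcn = small_gcn()
  ))
  expect_equal(nrow(swa), 2L)
  expect_equal(colnames(swa),
               c("weights", paste0("fold", 1:5), "mean"))
  expect_equal(swa$mean[1], mean(unlist(swa[1, paste0("fold", 1:5)])))
})
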