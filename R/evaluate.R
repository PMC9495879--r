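# Cross-validation harness: fold construction, classification and ranking
# metrics, the full pipeline per fold, the no-GCN ablation, and the
# layer-count / attention-weight sweep drivers.

#' Split positives into cross-validation folds
#'
#' Randomly partitions the positive pairs into `k` near-equal test subsets
#' (disjoint, union = all positives). For each fold, fresh negative pairs are
#' sampled from the non-edges — as many training negatives as training
#' positives and as many test negatives as test positives — disjoint from
#' every positive and from each other within the fold.
#'
#' @param ds an [interaction_dataset].
#' @param k number of folds (>= 2).
#' @param seed master seed; fold-level seeds are derived from it.
#' @return List of `k` fold objects, each with `fold`, `train_pos`,
#'   `test_pos`, `train_neg`, `test_neg` (2-column index matrices) and
#'   `seed`.
#' @export
kfold_split <- function(ds, k = 5L, seed = 1L) {
  stopifnot(inherits(ds, "interaction_dataset"))
  k <- stop_if_not_scalar_count(k, "k")
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  n_pos <- nrow(ds$pairs)
  if (n_pos < k) stop("fewer positive pairs than folds", call. = FALSE)
  seeds <- derive_seeds(seed, k + 1L)
  perm <- local_seed(seeds[k + 1L], sample.int(n_pos))
  fold_id <- rep_len(seq_len(k), n_pos)[order(perm)]
  lapply(seq_len(k), function(f) {
    test_idx <- which(fold_id == f)
    train_pos <- ds$pairs[-test_idx, , drop = FALSE]
    test_pos <- ds$pairs[test_idx, , drop = FALSE]
    neg_seeds <- derive_seeds(seeds[f], 2L)
    train_neg <- sample_negative_pairs(ds, nrow(train_pos), neg_seeds[1])
    test_neg <- sample_negative_pairs(ds, nrow(test_pos), neg_seeds[2],
                                      exclude = train_neg)
    list(fold = f, train_pos = train_pos, test_pos = test_pos,
         train_neg = train_neg, test_neg = test_neg, seed = seeds[f])
  })
}

#' Classification metrics at a decision threshold
#'
#' Confusion counts at the cutoff and the derived accuracy
#' `(TN + TP) / (TN + TP + FN + FP)`, precision `TP / (TP + FP)` and recall
#' `TP / (TP + FN)`. Undefined ratios (empty denominator) are reported as
#' `NaN` with a warning.
#'
#' @param labels 0/1 vector of true labels.
#' @param scores predicted scores, parallel to `labels`.
#' @param threshold decision cutoff (default 0.5): predict 1 when
#'   `score > threshold`.
#' @return Named list with `tp`, `tn`, `fp`, `fn`, `acc`, `precision`,
#'   `recall`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (empty denominator); reporting NaN", what),
              call. = FALSE)
      return(NaN)
    }
    num / den
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       acc = (tn + tp) / length(labels),
       precision = ratio(tp, tp + fp, "precision"),
       recall = ratio(tp, tp + fn, "recall"))
}

#' Ranking metrics: AUC and AUPR
#'
#' AUC is computed from the rank statistic with tie-averaged ranks
#' (equivalent to the Mann-Whitney U normalization), AUPR by step
#' integration of the precision-recall curve over distinct score cutoffs.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores predicted scores, parallel to `labels`.
#' @return Named list with `auc` and `aupr`.
#' @export
auc_aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUC/AUPR", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(l)
  fp <- cumsum(1 - l)
  # evaluate only at the last index of each tied-score group
  keep <- c(s[-length(s)] != s[-1], TRUE)
  prec <- (tp / (tp + fp))[keep]
  rec <- (tp / n1)[keep]
  aupr <- sum(prec * diff(c(0, rec)))
  list(auc = auc, aupr = aupr)
}

# Global node indices of (circ, mirna) pairs in the merged node set.
global_pairs <- function(pairs, n_circ) {
  cbind(pairs[, 1], n_circ + pairs[, 2])
}

# Node feature construction for one training adjacency, shared by the full
# pipeline and the ablation. Kernels always come from the training-fold
# adjacency only, never from held-out edges.
fold_features <- function(B_train, mode, circ_seqs, mirna_seqs, k_circ,
                          k_mirna, alpha_prime, circular) {
  if (mode == "sequence") {
    sequence_features(B_train, circ_seqs, mirna_seqs, k_circ = k_circ,
                      k_mirna = k_mirna, alpha_prime = alpha_prime,
                      circular = circular)
  } else {
    profile_only_features(B_train, alpha_prime)
  }
}

# One cross-validation fold: refit featurization + SAE (+ GCN unless
# ablated) from training data, then score the held-out pairs.
run_fold <- function(ds, fold, mode, circ_seqs, mirna_seqs, sae, gcn,
                     k_circ, k_mirna, alpha_prime, circular, ablate) {
  C <- n_circ(ds)
  B_train <- matrix(0, C, n_mirna(ds),
                    dimnames = list(ds$circ_ids, ds$mirna_ids))
  B_train[fold$train_pos] <- 1
  feats <- fold_features(B_train, mode, circ_seqs, mirna_seqs, k_circ,
                         k_mirna, alpha_prime, circular)
  seeds <- derive_seeds(fold$seed, 2L)
  sae_cfg <- sae
  sae_cfg$seed <- seeds[1]
  comp <- sae_compress(feats, sae_cfg)
  H0 <- standardize_columns(comp$H0)
  test_pairs <- global_pairs(rbind(fold$test_pos, fold$test_neg), C)
  test_labels <- rep(c(1, 0), c(nrow(fold$test_pos), nrow(fold$test_neg)))
  if (ablate) {
    # no-GCN ablation: decode directly on the (standardized) latents
    scores <- sigmoid(rowSums(H0[test_pairs[, 1], , drop = FALSE] *
                                H0[test_pairs[, 2], , drop = FALSE]))
    model <- NULL
  } else {
    A_norm <- normalize_adjacency(add_self_loops(combined_adjacency(B_train)))
    train_pairs <- global_pairs(rbind(fold$train_pos, fold$train_neg), C)
    train_labels <- rep(c(1, 0),
                        c(nrow(fold$train_pos), nrow(fold$train_neg)))
    gcn_cfg <- gcn
    gcn_cfg$seed <- seeds[2]
    fit <- gcn_train(H0, A_norm, train_pairs, train_labels, gcn_cfg)
    M <- gcn_embed(fit$model, A_norm, H0)
    scores <- sigmoid(rowSums(M[test_pairs[, 1], , drop = FALSE] *
                                M[test_pairs[, 2], , drop = FALSE]))
    model <- fit$model
  }
  cls <- compute_metrics(test_labels, scores)
  rnk <- auc_aupr(test_labels, scores)
  list(metrics = data.frame(fold = fold$fold, acc = cls$acc,
                            precision = cls$precision, recall = cls$recall,
                            auc = rnk$auc, aupr = rnk$aupr),
       labels = test_labels, scores = scores, model = model)
}

metrics_report <- function(per_fold) {
  tab <- do.call(rbind, per_fold)
  mean_row <- tab[1, , drop = FALSE]
  mean_row$fold <- NA_integer_
  for (col in c("acc", "precision", "recall", "auc", "aupr")) {
    mean_row[[col]] <- mean(tab[[col]])
  }
  out <- rbind(tab, mean_row)
  rownames(out) <- c(paste0("fold", tab$fold), "mean")
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  print.data.frame(x, digits = digits, row.names = TRUE)
  invisible(x)
}

#' Cross-validate the full pipeline
#'
#' Runs `k`-fold cross-validation of the complete model. In every fold the
#' bipartite adjacency, the kernel similarities and the autoencoder latents
#' are rebuilt from the training positives only, the GCN is trained on the
#' fold's balanced training pairs, and the held-out positives plus fresh
#' negatives are scored. The whole run is a deterministic function of
#' `seed`.
#'
#' @param ds an [interaction_dataset].
#' @param mode `"sequence"` (k-mer + kernel features; requires both sequence
#'   catalogs) or `"profile"` (kernel features on interaction profiles only,
#'   the mode used for association tables without molecular sequences).
#' @param circ_seqs,mirna_seqs sequence catalogs (sequence mode only).
#' @param k number of folds (default 5).
#' @param seed master seed.
#' @param sae an [sae_config()].
#' @param gcn a [gcn_config()].
#' @param k_circ,k_mirna k-mer windows (defaults 5 and 2).
#' @param alpha_prime GIP bandwidth numerator (default 0.5).
#' @param circular circular k-mer scan for circRNAs (default `FALSE`).
#' @param ablate if `TRUE`, skip the GCN and decode directly on the
#'   autoencoder latents (see [ablate_no_gcn()]).
#' @param keep_scores keep per-fold labels and scores (for ROC/PR export).
#' @return A `metrics_report`: data frame of per-fold rows plus a `mean` row
#'   with columns `acc`, `precision`, `recall`, `auc`, `aupr`. With
#'   `keep_scores = TRUE` the per-fold scores are attached as attribute
#'   `"folds"`.
#' @export
cross_validate <- function(ds, mode = c("sequence", "profile"),
                           circ_seqs = NULL, mirna_seqs = NULL, k = 5L,
                           seed = 1L, sae = sae_config(),
                           gcn = gcn_config(), k_circ = 5L, k_mirna = 2L,
                           alpha_prime = 0.5, circular = FALSE,
                           ablate = FALSE, keep_scores = FALSE) {
  mode <- match.arg(mode)
  if (mode == "sequence" && (is.null(circ_seqs) || is.null(mirna_seqs))) {
    stop("sequence mode requires both sequence catalogs", call. = FALSE)
  }
  folds <- kfold_split(ds, k = k, seed = seed)
  runs <- lapply(folds, function(fold) {
    run_fold(ds, fold, mode, circ_seqs, mirna_seqs, sae, gcn, k_circ,
             k_mirna, alpha_prime, circular, ablate)
  })
  report <- metrics_report(lapply(runs, `[[`, "metrics"))
  if (keep_scores) {
    attr(report, "folds") <- lapply(runs, function(r) {
      list(labels = r$labels, scores = r$scores)
    })
  }
  report
}

#' No-GCN ablation
#'
#' Identical cross-validation protocol to [cross_validate()] except that the
#' graph convolution step is removed: after the autoencoder compresses the
#' node features, the sigmoid inner-product decoder is applied directly to
#' the latents. Comparing this report against the full model isolates the
#' contribution of graph propagation.
#'
#' @inheritParams cross_validate
#' @param ... further arguments passed to [cross_validate()].
#' @return A `metrics_report` with the same shape as [cross_validate()]'s.
#' @export
ablate_no_gcn <- function(ds, mode = c("sequence", "profile"), ...) {
  cross_validate(ds, mode = match.arg(mode), ..., ablate = TRUE)
}

#' Sweep the number of GCN layers
#'
#' Cross-validates a plain GCN of each depth: the final embedding is the
#' last layer's output (attention weight 1 on layer `L`), so each row
#' measures an `L`-layer graph convolutional encoder rather than a mixture
#' of depths, with everything else held fixed.
#'
#' @inheritParams cross_validate
#' @param layers integer vector of layer counts (default `1:5`).
#' @return Data frame with one row per depth: `layers`, mean `auc`, mean
#'   `aupr`.
#' @export
sweep_layers <- function(ds, layers = 1:5, mode = c("sequence", "profile"),
                         circ_seqs = NULL, mirna_seqs = NULL, k = 5L,
                         seed = 1L, sae = sae_config(), gcn = gcn_config(),
                         ...) {
  mode <- match.arg(mode)
  stopifnot(all(layers >= 1))
  rows <- lapply(layers, function(L) {
    w <- rep(0, L)
    w[L] <- 1
    cfg <- gcn_config(n_layers = L, dim = gcn$dim, attention = "fixed",
                      attention_weights = w, lr = gcn$lr,
                      epochs = gcn$epochs, omega = gcn$omega,
                      seed = gcn$seed)
    rep <- cross_validate(ds, mode = mode, circ_seqs = circ_seqs,
                          mirna_seqs = mirna_seqs, k = k, seed = seed,
                          sae = sae, gcn = cfg, ...)
    data.frame(layers = L, auc = rep["mean", "auc"],
               aupr = rep["mean", "aupr"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep fixed layer-attention weight triples
#'
#' Cross-validates the three-layer model under a grid of fixed attention
#' weight triples, reporting each fold's AUC and the mean.
#'
#' @inheritParams cross_validate
#' @param triples list of numeric weight vectors of length 3.
#' @return Data frame with one row per triple: the weights, per-fold AUC
#'   columns and the mean AUC.
#' @export
sweep_attention <- function(ds, triples, mode = c("sequence", "profile"),
                            circ_seqs = NULL, mirna_seqs = NULL, k = 5L,
                            seed = 1L, sae = sae_config(),
                            gcn = gcn_config(), ...) {
  mode <- match.arg(mode)
  rows <- lapply(triples, function(w) {
    stopifnot(length(w) == 3L, all(w >= 0))
    cfg <- gcn_config(n_layers = 3L, dim = gcn$dim, attention = "fixed",
                      attention_weights = w, lr = gcn$lr,
                      epochs = gcn$epochs, omega = gcn$omega,
                      seed = gcn$seed)
    rep <- cross_validate(ds, mode = mode, circ_seqs = circ_seqs,
                          mirna_seqs = mirna_seqs, k = k, seed = seed,
                          sae = sae, gcn = cfg, ...)
    fold_auc <- rep$auc[seq_len(k)]
    out <- data.frame(weights = paste(w, collapse = ","))
    for (f in seq_len(k)) out[[paste0("fold", f)]] <- fold_auc[f]
    out$mean <- rep["mean", "auc"]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
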