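# High-level fit/predict interface over the full pipeline, used for final
# training on all known associations and for candidate ranking.

#' Fit the association model on all known pairs
#'
#' Runs the complete pipeline on the full dataset: featurization from the
#' bipartite adjacency (plus sequences in sequence mode), per-class sparse
#' autoencoder compression, balanced negative sampling, and GCN training
#' with the inner-product decoder.
#'
#' @inheritParams cross_validate
#' @param n_negatives number of sampled negative training pairs (default:
#'   one per positive).
#' @return Object of class `circmir_fit` holding the dataset, trained
#'   models, the normalized adjacency, latent features and training traces.
#' @export
fit_model <- function(ds, mode = c("sequence", "profile"), circ_seqs = NULL,
                      mirna_seqs = NULL, seed = 1L, sae = sae_config(),
                      gcn = gcn_config(), n_negatives = NULL, k_circ = 5L,
                      k_mirna = 2L, alpha_prime = 0.5, circular = FALSE) {
  mode <- match.arg(mode)
  if (mode == "sequence" && (is.null(circ_seqs) || is.null(mirna_seqs))) {
    stop("sequence mode requires both sequence catalogs", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 3L)
  B <- build_bipartite_adjacency(ds)
  feats <- fold_features(B, mode, circ_seqs, mirna_seqs, k_circ, k_mirna,
                         alpha_prime, circular)
  sae_cfg <- sae
  sae_cfg$seed <- seeds[1]
  comp <- sae_compress(feats, sae_cfg)
  H0 <- standardize_columns(comp$H0)
  if (is.null(n_negatives)) n_negatives <- nrow(ds$pairs)
  negs <- sample_negative_pairs(ds, n_negatives, seeds[2])
  C <- n_circ(ds)
  pairs <- global_pairs(rbind(ds$pairs, negs), C)
  labels <- rep(c(1, 0), c(nrow(ds$pairs), nrow(negs)))
  A_norm <- normalize_adjacency(add_self_loops(combined_adjacency(B)))
  gcn_cfg <- gcn
  gcn_cfg$seed <- seeds[3]
  fit <- gcn_train(H0, A_norm, pairs, labels, gcn_cfg)
  structure(
    list(dataset = ds, mode = mode, sae = comp, H0 = H0, gcn = fit$model,
         trace = fit$trace, A_norm = A_norm, seed = seed),
    class = "circmir_fit"
  )
}

#' @export
print.circmir_fit <- function(x, ...) {
  cat(sprintf(
    "circmir_fit (%s mode): %d circRNAs, %d miRNAs, %d known pairs\n",
    x$mode, length(x$dataset$circ_ids), length(x$dataset$mirna_ids),
    nrow(x$dataset$pairs)
  ))
  cat(sprintf("final training loss: %.4f\n", x$trace[length(x$trace)]))
  invisible(x)
}

#' Rank novel candidate associations from a fitted model
#'
#' Decodes all circRNA x miRNA scores from the fitted embeddings and ranks
#' the pairs not already known, ties broken by index.
#'
#' @param fit a `circmir_fit` from [fit_model()].
#' @param top number of top-ranked candidates to return (default 10).
#' @return Data frame with `circ_id`, `mirna_id`, `score`, `rank`.
#' @export
predict_associations <- function(fit, top = 10L) {
  stopifnot(inherits(fit, "circmir_fit"))
  M <- gcn_embed(fit$gcn, fit$A_norm, fit$H0)
  S <- inner_product_decode(M)
  S_cm <- score_block(S, length(fit$dataset$circ_ids))
  ranked <- rank_candidates(S_cm, fit$dataset$pairs, top = top)
  ranked[, c("circ_id", "mirna_id", "score", "rank")]
}
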