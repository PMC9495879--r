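# Node featurization: k-mer sequence profiles, GIP and sigmoid kernel
# similarities over interaction profiles, their fusion, and assembly of the
# per-class attribute blocks fed to the autoencoders.

RNA_ALPHABET <- c("A", "C", "G", "U")

#' k-mer profile matrix of a sequence catalog
#'
#' Scans each sequence with a length-`k` window moving one nucleotide at a
#' time and counts every window, giving a `4^k`-column profile per sequence.
#' Columns are ordered lexicographically over (A, C, G, U). With
#' `normalize = TRUE` counts are divided by the number of windows
#' (`L - k + 1`), so each row of frequencies sums to 1; frequencies make
#' sequences of very different lengths comparable, which matters because
#' circRNAs span orders of magnitude in length while miRNAs are ~21 nt.
#'
#' @param seqs named character vector of RNA sequences over `{A,C,G,U}`
#'   (see [read_fasta()]).
#' @param k window length; every sequence must be at least `k` long.
#' @param normalize divide counts by the window count (default `TRUE`).
#' @param circular if `TRUE`, append the first `k - 1` nucleotides to the end
#'   of each sequence before scanning, so windows crossing the back-splice
#'   junction of a circular molecule are counted. Default `FALSE` (linear
#'   scan).
#' @return Numeric matrix of dimension `length(seqs) x 4^k` with sequence ids
#'   as rownames and k-mer strings as colnames.
#' @export
kmer_matrix <- function(seqs, k, normalize = TRUE, circular = FALSE) {
  k <- stop_if_not_scalar_count(k, "k")
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (length(seqs) == 0L) stop("empty sequence catalog", call. = FALSE)
  lens <- nchar(seqs)
  short <- lens < k
  if (any(short)) {
    stop(sprintf("sequence %s is shorter than k = %d",
                 names(seqs)[short][1], k), call. = FALSE)
  }
  scan_seqs <- seqs
  if (circular && k > 1L) {
    scan_seqs <- paste0(seqs, substr(seqs, 1L, k - 1L))
  }
  set <- Biostrings::RNAStringSet(scan_seqs)
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  rownames(counts) <- names(seqs)
  counts <- counts[, order(colnames(counts)), drop = FALSE]
  storage.mode(counts) <- "double"
  if (normalize) {
    counts <- counts / rowSums(counts)
  }
  counts
}

#' Interaction profiles of both node classes
#'
#' The interaction profile `LP` of a node is its binary vector of known
#' partners: the corresponding row of the bipartite adjacency for a circRNA,
#' the corresponding column for a miRNA.
#'
#' @param B bipartite adjacency from [build_bipartite_adjacency()].
#' @return List with matrices `circ` (C x M, rows are circRNA profiles) and
#'   `mirna` (M x C, rows are miRNA profiles).
#' @export
interaction_profiles <- function(B) {
  stopifnot(is.matrix(B))
  list(circ = B, mirna = t(B))
}

#' Gaussian interaction profile (GIP) kernel
#'
#' Computes `G[i, j] = exp(-alpha * ||LP_i - LP_j||^2)` over the rows of a
#' profile matrix, with the bandwidth `alpha = alpha_prime / mean(||LP||^2)`
#' scaled by the mean squared profile norm so the kernel adapts to the
#' density of the interaction graph.
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @param alpha_prime bandwidth numerator (default 0.5).
#' @return Symmetric kernel matrix with unit diagonal and entries in (0, 1].
#' @export
gip_kernel <- function(profiles, alpha_prime = 0.5) {
  stopifnot(is.matrix(profiles))
  mean_sq <- mean(rowSums(profiles^2))
  if (mean_sq == 0) {
    stop("all interaction profiles are zero; GIP bandwidth is undefined",
         call. = FALSE)
  }
  alpha <- alpha_prime / mean_sq
  d2 <- as.matrix(stats::dist(profiles))^2
  G <- exp(-alpha * d2)
  diag(G) <- 1
  dimnames(G) <- list(rownames(profiles), rownames(profiles))
  G
}

#' Sigmoid kernel
#'
#' Computes `K[i, j] = tanh(beta * <x_i, x_j>)` over the rows of a feature
#' matrix, with `beta = 1 / V` where `V` is the feature dimension.
#'
#' @param vectors numeric matrix, one feature vector per row.
#' @return Symmetric matrix with entries in (-1, 1).
#' @export
sigmoid_kernel <- function(vectors) {
  stopifnot(is.matrix(vectors))
  V <- ncol(vectors)
  if (V == 0L) stop("feature dimension V must be >= 1", call. = FALSE)
  K <- tanh(tcrossprod(vectors) / V)
  dimnames(K) <- list(rownames(vectors), rownames(vectors))
  K
}

#' Fuse two similarity kernels
#'
#' Entrywise fusion of a GIP kernel and a sigmoid kernel for the same node
#' class: the average `(G + K) / 2` where both entries are nonzero, and the
#' sum `G + K` otherwise (so a single nonzero value passes through unchanged
#' and the entry is 0 where both are 0). The nonzero test is exact, since a
#' structurally absent kernel entry is exactly 0 while the GIP kernel itself
#' is never 0.
#'
#' @param G,K square matrices of identical dimension.
#' @return Fused similarity matrix.
#' @export
fuse_similarities <- function(G, K) {
  if (!all(dim(G) == dim(K))) {
    stop("kernel matrices must have identical shapes", call. = FALSE)
  }
  both <- (G != 0) & (K != 0)
  F_ <- G + K
  F_[both] <- (G[both] + K[both]) / 2
  F_
}

# Fused profile-based similarity for one node class: GIP and sigmoid kernels
# evaluated on the interaction profiles, then fused.
fused_profile_similarity <- function(profiles, alpha_prime = 0.5) {
  fuse_similarities(gip_kernel(profiles, alpha_prime), sigmoid_kernel(profiles))
}

#' Assemble per-class node feature blocks
#'
#' Concatenates the k-mer attribute block and the fused similarity block of
#' each node class into the per-class feature matrices `[KM | F]`. The two
#' classes keep separate blocks (their widths `4^k + C` and `4^k' + M`
#' differ); the autoencoder stage later compresses both to a common latent
#' width before they are stacked into one node table.
#'
#' @param km_c,km_m k-mer profile matrices for circRNAs and miRNAs.
#' @param F_c,F_m fused similarity matrices for circRNAs and miRNAs.
#' @return Object of class `node_features`: list with matrices `circ`
#'   (C x (4^k + C)) and `mirna` (M x (4^k' + M)) and `mode = "sequence"`.
#' @export
assemble_node_features <- function(km_c, F_c, km_m, F_m) {
  if (nrow(km_c) != nrow(F_c) || nrow(F_c) != ncol(F_c)) {
    stop("circRNA block row counts are inconsistent", call. = FALSE)
  }
  if (nrow(km_m) != nrow(F_m) || nrow(F_m) != ncol(F_m)) {
    stop("miRNA block row counts are inconsistent", call. = FALSE)
  }
  structure(
    list(circ = cbind(km_c, F_c), mirna = cbind(km_m, F_m),
         mode = "sequence"),
    class = "node_features"
  )
}

#' Profile-only node features
#'
#' Featurization used when no molecular sequences exist (e.g. circRNA-disease
#' or circRNA-gene association tables): each node class is described by the
#' fused GIP/sigmoid kernel similarity of its interaction profiles alone,
#' with no k-mer block.
#'
#' @param B bipartite adjacency matrix.
#' @param alpha_prime GIP bandwidth numerator (default 0.5 for both classes).
#' @return `node_features` object with `circ` (C x C), `mirna` (M x M) and
#'   `mode = "profile"`.
#' @export
profile_only_features <- function(B, alpha_prime = 0.5) {
  if (!is.matrix(B) || length(B) == 0L) {
    stop("adjacency must be a non-empty matrix", call. = FALSE)
  }
  lp <- interaction_profiles(B)
  structure(
    list(
      circ = fused_profile_similarity(lp$circ, alpha_prime),
      mirna = fused_profile_similarity(lp$mirna, alpha_prime),
      mode = "profile"
    ),
    class = "node_features"
  )
}

#' Sequence-mode node features
#'
#' Convenience wrapper assembling the full sequence-mode featurization from
#' an adjacency and sequence catalogs: per-class k-mer profiles (window 5 for
#' circRNAs, 2 for miRNAs by default, reflecting their length scales) plus
#' fused profile-kernel similarities.
#'
#' @param B bipartite adjacency matrix (rows circRNAs, columns miRNAs).
#' @param circ_seqs,mirna_seqs sequence catalogs covering the row/column ids
#'   of `B`.
#' @param k_circ,k_mirna k-mer window per class (defaults 5 and 2).
#' @param alpha_prime GIP bandwidth numerator.
#' @param circular scan circRNA sequences circularly (see [kmer_matrix()]).
#' @return `node_features` object (see [assemble_node_features()]).
#' @export
sequence_features <- function(B, circ_seqs, mirna_seqs, k_circ = 5L,
                              k_mirna = 2L, alpha_prime = 0.5,
                              circular = FALSE) {
  missing_c <- setdiff(rownames(B), names(circ_seqs))
  missing_m <- setdiff(colnames(B), names(mirna_seqs))
  if (length(missing_c) > 0L || length(missing_m) > 0L) {
    stop(sprintf("missing sequences for %d node id(s), e.g. %s",
                 length(missing_c) + length(missing_m),
                 c(missing_c, missing_m)[1]), call. = FALSE)
  }
  lp <- interaction_profiles(B)
  km_c <- kmer_matrix(circ_seqs[rownames(B)], k_circ, circular = circular)
  km_m <- kmer_matrix(mirna_seqs[colnames(B)], k_mirna)
  assemble_node_features(
    km_c, fused_profile_similarity(lp$circ, alpha_prime),
    km_m, fused_profile_similarity(lp$mirna, alpha_prime)
  )
}

#' @export
print.node_features <- function(x, ...) {
  cat(sprintf(
    "node_features (%s mode): circ %d x %d, mirna %d x %d\n",
    x$mode, nrow(x$circ), ncol(x$circ), nrow(x$mirna), ncol(x$mirna)
  ))
  invisible(x)
}
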