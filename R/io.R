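#' Construct an interaction dataset from id pairs
#'
#' An interaction dataset holds the labeled bipartite edge list of known
#' (circRNA, miRNA) association pairs, together with the id-to-index maps for
#' both node classes. Identifiers are indexed in order of first appearance,
#' duplicated pairs are removed (with a warning), and every id belongs to
#' exactly one node class.
#'
#' @param circ character vector of circRNA ids, one per pair.
#' @param mirna character vector of miRNA ids, parallel to `circ`.
#' @return An object of class `interaction_dataset` with elements
#'   `circ_ids`, `mirna_ids` (ordered unique ids) and `pairs` (integer matrix
#'   with columns `circ`, `mirna` of 1-based indices).
#' @export
interaction_dataset <- function(circ, mirna) {
  circ <- as.character(circ)
  mirna <- as.character(mirna)
  if (length(circ) != length(mirna)) {
    stop("`circ` and `mirna` must have the same length", call. = FALSE)
  }
  if (length(circ) == 0L) {
    stop("interaction dataset must contain at least one pair", call. = FALSE)
  }
  if (any(is.na(circ)) || any(is.na(mirna)) ||
      any(!nzchar(circ)) || any(!nzchar(mirna))) {
    stop("interaction ids must be non-missing, non-empty strings", call. = FALSE)
  }
  both <- intersect(unique(circ), unique(mirna))
  if (length(both) > 0L) {
    stop(sprintf(
      "id(s) appear in both node classes: %s",
      paste(utils::head(both, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  circ_ids <- unique(circ)
  mirna_ids <- unique(mirna)
  ci <- match(circ, circ_ids)
  mi <- match(mirna, mirna_ids)
  key <- paste(ci, mi)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("removed %d duplicated interaction pair(s)", sum(dup)),
            call. = FALSE)
    ci <- ci[!dup]
    mi <- mi[!dup]
  }
  structure(
    list(
      circ_ids = circ_ids,
      mirna_ids = mirna_ids,
      pairs = cbind(circ = ci, mirna = mi)
    ),
    class = "interaction_dataset"
  )
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf(
    "interaction_dataset: %d pairs between %d circRNAs and %d miRNAs\n",
    nrow(x$pairs), length(x$circ_ids), length(x$mirna_ids)
  ))
  invisible(x)
}

n_circ <- function(ds) length(ds$circ_ids)
n_mirna <- function(ds) length(ds$mirna_ids)

# Linear (column-major style) encoding of (circ, mirna) index pairs used for
# fast set operations on edges.
pair_key <- function(ci, mi, n_c) (as.numeric(mi) - 1) * n_c + as.numeric(ci)

key_to_pair <- function(key, n_c) {
  ci <- as.integer((key - 1) %% n_c + 1)
  mi <- as.integer((key - 1) %/% n_c + 1)
  cbind(circ = ci, mirna = mi)
}

#' Read an interaction table
#'
#' Reads a two-column delimited file of (circRNA id, miRNA id) pairs into an
#' [interaction_dataset]. Id ordering follows first appearance in the file;
#' duplicate rows are dropped with a warning.
#'
#' @param path path to a TSV/CSV file with at least two columns.
#' @param delimiter field separator (default tab).
#' @param header `"auto"` to treat the first row as a header when it repeats
#'   no id seen later and looks like column names, or `TRUE`/`FALSE` to force.
#' @return An [interaction_dataset].
#' @export
read_interaction_table <- function(path, delimiter = "\t", header = "auto") {
  if (!file.exists(path)) {
    stop(sprintf("interaction table not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop(sprintf("interaction table is empty: %s", path), call. = FALSE)
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(fields, function(f) length(f) < 2L || any(!nzchar(trimws(f[1:2]))), logical(1)))
  if (length(bad) > 0L) {
    stop(sprintf("line %d of %s has fewer than 2 fields", bad[1], path),
         call. = FALSE)
  }
  circ <- trimws(vapply(fields, `[[`, character(1), 1L))
  mirna <- trimws(vapply(fields, `[[`, character(1), 2L))
  drop_first <- isTRUE(header)
  if (identical(header, "auto") && length(circ) > 1L) {
    # Heuristic: treat the first row as a header when either token is a
    # conventional column label rather than an identifier.
    labels <- c("circrna", "circ", "circrna_id", "circ_id", "source",
                "mirna", "mir", "mirna_id", "target", "id", "node")
    drop_first <- tolower(circ[1]) %in% labels || tolower(mirna[1]) %in% labels
  }
  if (drop_first) {
    circ <- circ[-1]
    mirna <- mirna[-1]
  }
  if (length(circ) == 0L) {
    stop(sprintf("interaction table has no data rows: %s", path), call. = FALSE)
  }
  interaction_dataset(circ, mirna)
}

#' Write an interaction table
#'
#' Inverse of [read_interaction_table()]: writes the pairs in index order so
#' that a read/write round trip reproduces the identical dataset.
#'
#' @param ds an [interaction_dataset].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(ds, path, delimiter = "\t") {
  stopifnot(inherits(ds, "interaction_dataset"))
  lines <- paste(ds$circ_ids[ds$pairs[, "circ"]],
                 ds$mirna_ids[ds$pairs[, "mirna"]],
                 sep = delimiter)
  writeLines(lines, path)
  invisible(path)
}

#' Read RNA sequences from a FASTA file
#'
#' Parses a FASTA file into a named character vector of RNA sequences.
#' Sequences are upper-cased and DNA-style `T` is mapped to `U`, so public
#' sequence sets distributed in either alphabet are accepted. After
#' normalization only the unambiguous alphabet `{A,C,G,U}` is allowed.
#'
#' @param path path to a FASTA file; record headers are node ids.
#' @return Named character vector (a sequence catalog): id -> RNA sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  if (any(duplicated(ids))) {
    stop(sprintf("duplicate FASTA header: %s", ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop(sprintf("empty sequence for id: %s", ids[!nzchar(seqs)][1]),
         call. = FALSE)
  }
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop(sprintf(
      "sequence %s contains characters outside the unambiguous nucleotide alphabet",
      ids[bad][1]
    ), call. = FALSE)
  }
  stats::setNames(seqs, ids)
}

#' Build the bipartite adjacency matrix
#'
#' Builds the C x M binary incidence matrix `B` of the interaction graph:
#' `B[i, j] = 1` exactly when circRNA `i` is a known partner of miRNA `j`.
#'
#' @param ds an [interaction_dataset].
#' @return Binary matrix with `circ_ids` as rownames and `mirna_ids` as
#'   colnames; its entries sum to the number of positive pairs.
#' @export
build_bipartite_adjacency <- function(ds) {
  stopifnot(inherits(ds, "interaction_dataset"))
  B <- matrix(0, n_circ(ds), n_mirna(ds),
              dimnames = list(ds$circ_ids, ds$mirna_ids))
  B[ds$pairs] <- 1
  B
}

#' Sample negative (non-interacting) pairs
#'
#' Draws `n` distinct (circRNA, miRNA) pairs uniformly at random from the
#' non-edges of the bipartite graph, i.e. pairs not present among the known
#' positives. Used to balance the training set with label-0 examples.
#'
#' @param ds an [interaction_dataset].
#' @param n number of negative pairs to draw.
#' @param seed integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @param exclude optional extra integer pair matrix (columns circ, mirna) to
#'   exclude from the candidate non-edges, e.g. negatives already assigned to
#'   another fold.
#' @return Integer matrix with columns `circ` and `mirna`; zero rows if
#'   `n = 0`.
#' @export
sample_negative_pairs <- function(ds, n, seed = 1L, exclude = NULL) {
  stopifnot(inherits(ds, "interaction_dataset"))
  n <- stop_if_not_scalar_count(n, "n")
  nc <- n_circ(ds)
  nm <- n_mirna(ds)
  excl_keys <- pair_key(ds$pairs[, "circ"], ds$pairs[, "mirna"], nc)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    excl_keys <- c(excl_keys, pair_key(exclude[, 1], exclude[, 2], nc))
  }
  candidates <- setdiff(seq_len(nc * nm), excl_keys)
  if (n > length(candidates)) {
    stop(sprintf(
      "requested %d negative pairs but only %d non-edges are available",
      n, length(candidates)
    ), call. = FALSE)
  }
  if (n == 0L) {
    return(cbind(circ = integer(0), mirna = integer(0)))
  }
  keys <- local_seed(seed, sample(candidates, n))
  key_to_pair(keys, nc)
}
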