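# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state on
# exit. All user-facing functions that take a `seed` argument route their
# randomness through this so that a call never perturbs the global stream.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive `n` reproducible sub-seeds from a master seed; keeps derived seeds
# well inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max %/% 2L, n))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Column-wise standardization (zero mean, unit variance; constant columns
# become 0). Applied to the autoencoder latent table before graph
# convolution: sigmoid latents share a large common mean, and without
# centering the decoder's initial logits are uniformly positive, which
# drives training into the dead all-zero ReLU minimum.
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  out <- sweep(sweep(X, 2, mu, `-`), 2, sd_, `/`)
  dimnames(out) <- dimnames(X)
  out
}

relu <- function(x) pmax(x, 0)

# Numerically safe log for cross-entropy style expressions.
clamped_log <- function(x, eps = 1e-12) log(pmin(pmax(x, eps), 1))

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    stop(sprintf("`%s` must be a single non-negative integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}
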