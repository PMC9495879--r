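# Small fixtures built in code at test time.

tiny_dataset <- function() {
  interaction_dataset(c("c1", "c2", "c1"), c("m1", "m2", "m2"))
}

write_tmp_table <- function(lines, sep = "\t") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# Reduced-size configs so unit tests of the harness run in seconds.
small_sae <- function(seed = 1L) {
  sae_config(hidden_dim = 16L, epochs = 20L, seed = seed)
}

small_gcn <- function(seed = 1L, n_layers = 3L) {
  gcn_config(n_layers = n_layers, dim = 16L, epochs = 50L, seed = seed,
             attention_weights = if (n_layers == 3L) c(0.7, 0.2, 0.1) else
               rep(1 / n_layers, n_layers))
}

small_benchmark <- function(seed = 1L) {
  spec <- synthetic_spec(n_circ = 24L, n_mirna = 16L,
                         circ_len = c(60L, 120L), n_blocks = 2L,
                         p = 0.6, q = 0.02)
  list(dataset = generate_planted_bipartite(spec, seed),
       sequences = generate_sequences(spec, seed + 1L),
       spec = spec)
}
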