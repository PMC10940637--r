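# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

tiny_corpus <- function() {
  .memo("corpus", function() generate_toy_corpus(toy_corpus_spec(60, seed = 7)))
}

tiny_vocab <- function() {
  .memo("vocab", function() train_bpe(tiny_corpus(), 80))
}

tiny_stats <- function() {
  .memo("stats", function() {
    suppressWarnings(fit_normalization(tiny_corpus(), toy_registry()))
  })
}

tiny_config <- function() {
  model_config(hidden_dim = 16L, n_heads = 2L, n_layers_unimodal = 2L,
               n_layers_fusion = 2L, n_properties = 12L,
               vocab_size = length(tiny_vocab()$tokens),
               contrastive_dim = 8L, ff_mult = 2L)
}

# An untrained checkpoint with random weights: enough for structural and
# determinism tests that do not need a useful model.
tiny_ckpt <- function() {
  .memo("ckpt", function() {
    cfg <- tiny_config()
    checkpoint(init_model_params(cfg, seed = 2L), cfg, tiny_vocab(),
               tiny_stats(), toy_registry())
  })
}

# Normalized descriptor matrix for a set of SMILES under the tiny stats.
tiny_pv_matrix <- function(smiles) {
  st <- tiny_stats()
  raw <- compute_descriptors(smiles, toy_registry())
  sweep(sweep(raw, 2, st$mean), 2, st$std, "/")
}
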