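test_that("beam width 2 reproduces exhaustive enumeration on a toy table", {
  step_fn <- toy_table_step_fn()
  hyps <- beam_search(step_fn, bos = 1L, eos = 5L, beam_width = 2L,
                      max_len = 4L)
  truth <- oracle_enumerate_sequences(step_fn, bos = 1L, eos = 5L,
                                      n_tokens = 5L, max_len = 4L)
  # the enumerated top-2 are separated by a clear score gap (no ties)
  expect_gt(truth[[1]]$logp - truth[[2]]$logp, 1e-3)
  expect_gt(truth[[2]]$logp - truth[[3]]$logp, 1e-3)
  for (k in 1:2) {
    expect_identical(hyps[[k]]$ids, truth[[k]]$ids)
    expect_equal(hyps[[k]]$logp, truth[[k]]$logp, tolerance = 1e-12)
  }
})

test_that("beam width 1 equals greedy decoding", {
  step_fn <- toy_table_step_fn()
  hyp <- beam_search(step_fn, 1L, 5L, beam_width = 1L, max_len = 6L)[[1]]
  ids <- 1L
  repeat {
    tok <- which.max(step_fn(ids))
    ids <- c(ids, tok)
    if (tok == 5L || length(ids) >= 6L) break
  }
  expect_identical(hyp$ids, ids)
})

test_that("beam and greedy agree (width 1) on a real checkpoint", {
  ck <- tiny_ckpt()
  pv <- new_property_vector(rep(0, 12), rep(FALSE, 12))
  g1 <- generate_smiles(pv, ck, generation_config("greedy", max_len = 12))
  g2 <- generate_smiles(pv, ck, generation_config("beam", beam_width = 1L,
                                                  max_len = 12))
  expect_identical(g1, g2)
  # greedy decoding is deterministic
  expect_identical(g1, generate_smiles(pv, ck,
                                       generation_config("greedy",
                                                         max_len = 12)))
})

test_that("stochastic decoding is reproducible under a fixed seed", {
  ck <- tiny_ckpt()
  pv <- new_property_vector(rep(0, 12), rep(FALSE, 12))
  set.seed(30)
  a <- generate_smiles(pv, ck, generation_config("stochastic", max_len = 10),
                       n_samples = 3)
  set.seed(30)
  b <- generate_smiles(pv, ck, generation_config("stochastic", max_len = 10),
                       n_samples = 3)
  expect_identical(a, b)
})

test_that("generation metrics compute the exact defining fractions", {
  valid8 <- c("CCO", "CCN", "CCC", "CCCC", "CCO", "OCC", "c1ccccc1", "CC")
  generated <- c(valid8, "xx(", ")(bad")
  m <- generation_metrics(generated, pretraining_set = character())
  expect_equal(m$validity, 0.8)
  # "CCO" and "OCC" are one canonical molecule: 6 unique among 8 valid
  expect_equal(m$uniqueness, 0.75)
  pretrain_set <- smiles_canonical(c("CCO", "CCN", "CCC"))
  m2 <- generation_metrics(generated, pretrain_set)
  expect_equal(m2$novelty, 0.5)   # 3 of the 6 unique are novel
  expect_error(generation_metrics(character(), character()), "no generated")
})

test_that("adding an invalid string lowers validity and nothing else", {
  generated <- c("CCO", "CCN", "OCC")
  m1 <- generation_metrics(generated, character())
  m2 <- generation_metrics(c(generated, "not_a_smiles"), character())
  expect_lt(m2$validity, m1$validity)
  expect_equal(m2$uniqueness, m1$uniqueness)
  expect_equal(m2$novelty, m1$novelty)
})

test_that("normalized RMSE is zero at exact matches and averages otherwise", {
  st <- tiny_stats()
  reg <- toy_registry()
  mol <- "CC(=O)O"
  pv <- normalize_pv(compute_descriptors(mol, reg)[1, ], st)
  expect_equal(normalized_rmse(pv, c(mol, mol), st, reg), 0, tolerance = 1e-10)
  # one controlled property, one molecule, residual 1 (normalized) -> 1.0
  raw <- compute_descriptors(mol, reg)[1, ]
  target <- raw
  target["MW"] <- raw["MW"] + st$std[which(st$names == "MW")]
  pv1 <- new_property_vector((target - st$mean) / st$std,
                             known = st$names == "MW")
  expect_equal(normalized_rmse(pv1, mol, st, reg), 1, tolerance = 1e-10)
  # two controlled properties -> mean of the per-property RMSEs
  pv2 <- new_property_vector((target - st$mean) / st$std,
                             known = st$names %in% c("MW", "atoms"))
  r_mw <- 1; r_atoms <- 0
  expect_equal(normalized_rmse(pv2, mol, st, reg), mean(c(r_mw, r_atoms)),
               tolerance = 1e-10)
  expect_error(normalized_rmse(new_property_vector(rep(0, 12), rep(FALSE, 12)),
                               mol, st, reg), "no controlled")
  expect_error(normalized_rmse(pv, "zzz", st, reg), "no valid")
})

test_that("attention maps are head-means with rows summing to one", {
  ck <- tiny_ckpt()
  pv <- normalize_pv(compute_descriptors("CCO", toy_registry())[1, ],
                     tiny_stats())
  m <- attention_map("CCO", pv, ck)
  expect_equal(nrow(m), 12)
  expect_equal(unname(rowSums(m)), rep(1, 12), tolerance = 1e-6)
  expect_identical(rownames(m), toy_registry()$names)
  # single-head config: the map equals that head's scores
  cfg1 <- model_config(hidden_dim = 16L, n_heads = 1L, n_layers_unimodal = 2L,
                       n_layers_fusion = 2L, n_properties = 12L,
                       vocab_size = length(tiny_vocab()$tokens),
                       contrastive_dim = 8L, ff_mult = 2L)
  ck1 <- checkpoint(init_model_params(cfg1, 3), cfg1, tiny_vocab(),
                    tiny_stats(), toy_registry())
  ids <- tokenize("CCO", ck1$vocab)
  s <- encode_unimodal(embed_smiles(list(ids), ck1$params, cfg1),
                       ck1$params, cfg1, "enc_s")
  p <- encode_unimodal(embed_property_vector(matrix(pv$values, 1),
                                             matrix(pv$known, 1),
                                             ck1$params, cfg1),
                       ck1$params, cfg1, "enc_p")
  fus <- fuse(p, s, ck1$params, cfg1, collect_attention = TRUE)
  expect_equal(unname(attention_map("CCO", pv, ck1)),
               unname(fus$attention[[1]][-1, , drop = FALSE]),
               tolerance = 1e-12)
  # multi-head: elementwise mean of the per-head matrices
  fus4 <- fuse(.fix <- encode_unimodal(
    embed_property_vector(matrix(pv$values, 1), matrix(pv$known, 1),
                          ck$params, ck$config), ck$params, ck$config, "enc_p"),
    encode_unimodal(embed_smiles(list(tokenize("CCO", ck$vocab)),
                                 ck$params, ck$config),
                    ck$params, ck$config, "enc_s"),
    ck$params, ck$config, collect_attention = TRUE)
  manual <- Reduce(`+`, fus4$attention) / length(fus4$attention)
  expect_equal(unname(attention_map("CCO", pv, ck)),
               unname(manual[-1, , drop = FALSE]), tolerance = 1e-12)
})

test_that("attention maps export as TSV with a subword header", {
  ck <- tiny_ckpt()
  pv <- normalize_pv(compute_descriptors("CCO", toy_registry())[1, ],
                     tiny_stats())
  m <- attention_map("CCO", pv, ck)
  f <- tempfile(fileext = ".tsv")
  attention_map_save(m, f)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(header, c("property", colnames(m)))
  back <- utils::read.delim(f, check.names = FALSE)
  expect_identical(back$property, rownames(m))
  expect_equal(unname(as.matrix(back[, -1])), unname(m), tolerance = 1e-6)
})

test_that("property prediction is length-P and degenerates to the mean", {
  ck <- tiny_ckpt()
  pv <- generate_pv("CCO", ck)
  expect_length(pv, 12)
  expect_identical(names(pv), tiny_stats()$names)
  # a model whose prediction head is zero emits the per-property mean
  ck0 <- ck
  ck0$params$npp.W <- ck0$params$npp.W * 0
  ck0$params$npp.b <- 0
  expect_equal(unname(generate_pv("CCO", ck0)), unname(tiny_stats()$mean),
               tolerance = 1e-9)
  expect_error(generate_pv("zzz", ck), "invalid")
})

test_that("incremental property decoding equals full-recompute predictions", {
  # the package decodes by re-encoding the prefix; verify each step equals
  # an independent loop that rebuilds the whole input from scratch
  ck <- tiny_ckpt()
  cfg <- ck$config
  got <- generate_pv("CC(=O)O", ck)
  ids <- tokenize("CC(=O)O", ck$vocab)
  s_feats <- encode_unimodal(embed_smiles(list(ids), ck$params, cfg),
                             ck$params, cfg, "enc_s")
  vals <- numeric(cfg$n_properties)
  for (i in seq_len(cfg$n_properties)) {
    known <- seq_len(cfg$n_properties) < i
    emb <- embed_property_vector(matrix(vals, 1), matrix(known, 1),
                                 ck$params, cfg)
    enc <- encode_unimodal(emb, ck$params, cfg, "enc_p", causal = TRUE)
    fus <- fuse(enc, s_feats, ck$params, cfg, causal_self = TRUE)
    vals[i] <- as.numeric(fus$x[i, , drop = FALSE] %*% ck$params$npp.W +
                            ck$params$npp.b)
  }
  want <- vals * ck$stats$std + ck$stats$mean
  expect_equal(unname(got), want, tolerance = 1e-10)
})

test_that("condition_pv places named targets on the normalized scale", {
  ck <- tiny_ckpt()
  pv <- condition_pv(c(MW = 100), ck)
  expect_true(pv$known[which(ck$stats$names == "MW")])
  expect_equal(sum(pv$known), 1)
  i <- which(ck$stats$names == "MW")
  expect_equal(pv$values[i], (100 - ck$stats$mean[i]) / ck$stats$std[i])
  expect_error(condition_pv(c(bogus = 1), ck), "bogus")
})
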