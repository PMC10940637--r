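# Model architecture: embeddings, unimodal encoders, fusion encoder, heads.
#
# Sequences of a batch are stacked into one (sum of lengths) x hidden_dim
# matrix; attention uses block-diagonal additive masks so ragged sequences
# need no padding. Transformer blocks are pre-norm (LN -> sublayer ->
# residual) with a final LN per encoder; the fusion encoder inserts a
# cross-attention sublayer between self-attention and the feed-forward, and
# is the same parameter set whichever modality supplies the queries.

#' Model configuration
#'
#' @param hidden_dim Width of every encoder (divisible by `n_heads`).
#' @param n_layers_unimodal Transformer layers in each unimodal encoder.
#' @param n_layers_fusion Layers in the fusion encoder.
#' @param n_heads Attention heads.
#' @param n_properties Length P of the property vector.
#' @param vocab_size SMILES subword vocabulary size.
#' @param max_smiles_len Maximum framed SMILES token length.
#' @param contrastive_dim Dimension of the projected contrastive features.
#' @param ff_mult Feed-forward width multiplier.
#' @param dropout Dropout probability (0 disables; applied to sublayer
#'   outputs during training only).
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_dim = 64L, n_layers_unimodal = 2L,
                         n_layers_fusion = 2L, n_heads = 4L,
                         n_properties = 12L, vocab_size,
                         max_smiles_len = 100L, contrastive_dim = 32L,
                         ff_mult = 4L, dropout = 0) {
  stopifnot(hidden_dim %% n_heads == 0L, hidden_dim > 0, n_heads > 0,
            n_layers_unimodal > 0, n_layers_fusion > 0, n_properties > 0,
            vocab_size > 0, max_smiles_len > 1, dropout >= 0, dropout < 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_layers_unimodal = as.integer(n_layers_unimodal),
                 n_layers_fusion = as.integer(n_layers_fusion),
                 n_heads = as.integer(n_heads),
                 n_properties = as.integer(n_properties),
                 vocab_size = as.integer(vocab_size),
                 max_smiles_len = as.integer(max_smiles_len),
                 contrastive_dim = as.integer(contrastive_dim),
                 ff_mult = as.integer(ff_mult),
                 dropout = dropout),
            class = "model_config")
}

.mx <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

.init_block <- function(p, prefix, d, dff, cross = FALSE) {
  p[[paste0(prefix, ".ln1.g")]] <- rep(1, d)
  p[[paste0(prefix, ".ln1.b")]] <- rep(0, d)
  for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(prefix, ".", w)]] <- .mx(d, d)
  for (b in c("bq", "bk", "bv", "bo")) p[[paste0(prefix, ".", b)]] <- rep(0, d)
  if (cross) {
    p[[paste0(prefix, ".lnc.g")]] <- rep(1, d)
    p[[paste0(prefix, ".lnc.b")]] <- rep(0, d)
    for (w in c("cWq", "cWk", "cWv", "cWo")) p[[paste0(prefix, ".", w)]] <- .mx(d, d)
    for (b in c("cbq", "cbk", "cbv", "cbo")) p[[paste0(prefix, ".", b)]] <- rep(0, d)
  }
  p[[paste0(prefix, ".ln2.g")]] <- rep(1, d)
  p[[paste0(prefix, ".ln2.b")]] <- rep(0, d)
  p[[paste0(prefix, ".W1")]] <- .mx(d, dff)
  p[[paste0(prefix, ".b1")]] <- rep(0, dff)
  p[[paste0(prefix, ".W2")]] <- .mx(dff, d)
  p[[paste0(prefix, ".b2")]] <- rep(0, d)
  p
}

#' Initialize model parameters
#'
#' @param config A `model_config`.
#' @param seed Integer seed for the Gaussian initialization.
#' @return Named list of parameter matrices/vectors.
#' @export
init_model_params <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$hidden_dim
  dff <- d * config$ff_mult
  p <- list()
  p$tok_emb <- .mx(config$vocab_size, d)
  p$pos_emb_s <- .mx(config$max_smiles_len, d)
  p$pos_emb_p <- .mx(config$n_properties + 1L, d)
  p$cls_p <- .mx(1, d)
  p$unk_p <- .mx(1, d)
  p$val_W <- .mx(1, d)
  p$val_b <- rep(0, d)
  for (l in seq_len(config$n_layers_unimodal)) {
    p <- .init_block(p, paste0("enc_s.l", l), d, dff)
    p <- .init_block(p, paste0("enc_p.l", l), d, dff)
  }
  for (l in seq_len(config$n_layers_fusion)) {
    p <- .init_block(p, paste0("fus.l", l), d, dff, cross = TRUE)
  }
  for (enc in c("enc_s", "enc_p", "fus")) {
    p[[paste0(enc, ".lnf.g")]] <- rep(1, d)
    p[[paste0(enc, ".lnf.b")]] <- rep(0, d)
  }
  p$proj_s.W <- .mx(d, config$contrastive_dim)
  p$proj_s.b <- rep(0, config$contrastive_dim)
  p$proj_p.W <- .mx(d, config$contrastive_dim)
  p$proj_p.b <- rep(0, config$contrastive_dim)
  p$spm.W <- .mx(2 * d, 2)
  p$spm.b <- rep(0, 2)
  p$nwp.W <- .mx(d, config$vocab_size)
  p$nwp.b <- rep(0, config$vocab_size)
  p$npp.W <- .mx(d, 1)
  p$npp.b <- 0
  p$tau <- matrix(0.07, 1, 1)
  p
}

#' Exact copy of the parameters for the momentum (EMA) teacher
#'
#' The teacher is a value copy: it shares no storage with the student and is
#' never touched by the optimizer; it only moves through [ema_update()].
#'
#' @param params Student parameter list.
#' @return A deep copy.
#' @export
init_momentum_copy <- function(params) {
  lapply(params, function(x) x + 0)
}

# ---- attention masks -------------------------------------------------------

# Additive block mask for stacked ragged sequences: queries of sequence i may
# attend only to keys of sequence i; `causal` further restricts to key
# position <= query position (requires lens_q == lens_k).
.block_mask <- function(lens_q, lens_k = lens_q, causal = FALSE) {
  n_q <- sum(lens_q); n_k <- sum(lens_k)
  m <- matrix(-1e30, n_q, n_k)
  oq <- cumsum(c(0L, lens_q)); ok <- cumsum(c(0L, lens_k))
  for (i in seq_along(lens_q)) {
    qi <- (oq[i] + 1L):(oq[i] + lens_q[i])
    ki <- (ok[i] + 1L):(ok[i] + lens_k[i])
    if (causal) {
      stopifnot(lens_q[i] == lens_k[i])
      blk <- matrix(-1e30, lens_q[i], lens_k[i])
      blk[lower.tri(blk, diag = TRUE)] <- 0
      m[qi, ki] <- blk
    } else {
      m[qi, ki] <- 0
    }
  }
  m
}

#' Scaled dot-product attention
#'
#' Computes `Softmax(Q K^T / sqrt(d_k)) V`, optionally restricted by a mask.
#' Rows of the attention matrix are probability vectors over the permitted
#' keys.
#'
#' @param Q,K,V Matrices (or adnodes): `len_q x d_k`, `len_k x d_k`,
#'   `len_k x d_v`.
#' @param mask Either `NULL`, the string `"causal"` (requires
#'   `len_q == len_k`), or an additive numeric mask matrix (`-1e30` = blocked).
#' @param return_weights If `TRUE`, also return the attention matrix.
#' @return The `len_q x d_v` output, or a list `(output, weights)`.
#' @export
scaled_dot_attention <- function(Q, K, V, mask = NULL, return_weights = FALSE) {
  qv <- ad_value(Q); kv <- ad_value(K)
  stopifnot(ncol(qv) == ncol(kv), nrow(kv) == nrow(ad_value(V)))
  if (identical(mask, "causal")) {
    stopifnot(nrow(qv) == nrow(kv))
    mask <- matrix(-1e30, nrow(qv), nrow(kv))
    mask[lower.tri(mask, diag = TRUE)] <- 0
  }
  if (!is.null(mask)) {
    if (any(apply(mask, 1L, max) < -1e29)) {
      stop("attention mask leaves some query with no permitted key")
    }
  }
  scores <- ad_smul(ad_mm(Q, ad_t(K)), 1 / sqrt(ncol(qv)))
  w <- ad_softmax_rows(scores, mask)
  out <- ad_mm(w, V)
  if (return_weights) list(output = out, weights = w) else out
}

# Fused multi-head scaled-dot attention core: projected q/k/v in, the
# concatenated per-head contexts out, as a single tape op with a
# hand-derived backward (keeps the tape small; the per-head softmax
# matrices are saved from the forward). Optionally deposits the per-head
# attention matrices into `collect` (used by attention_map()).
.mha_core <- function(q, k, v, n_heads, mask, collect = NULL) {
  qv <- ad_value(q); kv <- ad_value(k); vv <- ad_value(v)
  d <- ncol(qv)
  dh <- d %/% n_heads
  scale <- 1 / sqrt(dh)
  probs <- vector("list", n_heads)
  out <- matrix(0, nrow(qv), d)
  for (h in seq_len(n_heads)) {
    cs <- ((h - 1L) * dh + 1L):(h * dh)
    s <- qv[, cs, drop = FALSE] %*% t(kv[, cs, drop = FALSE]) * scale
    if (!is.null(mask)) s <- s + mask
    m <- matrixStats::rowMaxs(s)
    e <- exp(s - m)
    p <- e / rowSums(e)
    probs[[h]] <- p
    out[, cs] <- p %*% vv[, cs, drop = FALSE]
  }
  if (!is.null(collect)) collect$weights <- probs
  .ad_op(out, list(q, k, v),
         function(g) {
           gq <- matrix(0, nrow(qv), d)
           gk <- matrix(0, nrow(kv), d)
           gv <- matrix(0, nrow(kv), d)
           for (h in seq_len(n_heads)) {
             cs <- ((h - 1L) * dh + 1L):(h * dh)
             p <- probs[[h]]
             go <- g[, cs, drop = FALSE]
             gv[, cs] <- t(p) %*% go
             gp <- go %*% t(vv[, cs, drop = FALSE])
             gs <- p * (gp - rowSums(gp * p)) * scale
             gq[, cs] <- gs %*% kv[, cs, drop = FALSE]
             gk[, cs] <- t(gs) %*% qv[, cs, drop = FALSE]
           }
           list(gq, gk, gv)
         })
}

# Multi-head attention sublayer on stacked sequences (pre-residual output).
.mha <- function(x_q, x_kv, params, prefix, n_heads, mask,
                 cross = FALSE, collect = NULL) {
  pfx <- function(s) params[[paste0(prefix, ".", if (cross) paste0("c", s) else s)]]
  q <- ad_add_vec(ad_mm(x_q, pfx("Wq")), pfx("bq"))
  k <- ad_add_vec(ad_mm(x_kv, pfx("Wk")), pfx("bk"))
  v <- ad_add_vec(ad_mm(x_kv, pfx("Wv")), pfx("bv"))
  o <- .mha_core(q, k, v, n_heads, mask, collect = collect)
  ad_add_vec(ad_mm(o, pfx("Wo")), pfx("bo"))
}

.maybe_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  v <- ad_value(x)
  keep <- matrix(stats::rbinom(length(v), 1L, 1 - rate), nrow(v), ncol(v))
  ad_mul_const(x, keep / (1 - rate))
}

# One pre-norm transformer block; `kv`/`cross_mask` enable the fusion
# cross-attention sublayer.
.block <- function(x, params, prefix, n_heads, self_mask,
                   kv = NULL, cross_mask = NULL, dropout = 0,
                   training = FALSE, collect = NULL) {
  pfx <- function(s) params[[paste0(prefix, ".", s)]]
  h <- ad_layernorm(x, pfx("ln1.g"), pfx("ln1.b"))
  a <- .mha(h, h, params, prefix, n_heads, self_mask)
  x <- ad_add(x, .maybe_dropout(a, dropout, training))
  if (!is.null(kv)) {
    h <- ad_layernorm(x, pfx("lnc.g"), pfx("lnc.b"))
    a <- .mha(h, kv, params, prefix, n_heads, cross_mask,
              cross = TRUE, collect = collect)
    x <- ad_add(x, .maybe_dropout(a, dropout, training))
  }
  h <- ad_layernorm(x, pfx("ln2.g"), pfx("ln2.b"))
  ff <- ad_add_vec(ad_mm(ad_gelu(ad_add_vec(ad_mm(h, pfx("W1")), pfx("b1"))),
                         pfx("W2")), pfx("b2"))
  ad_add(x, .maybe_dropout(ff, dropout, training))
}

# ---- embeddings ------------------------------------------------------------

#' Embed a batch of token id sequences
#'
#' Token embedding plus learned positional embedding, stacked over the batch.
#'
#' @param ids_list List of integer id vectors (framed sequences).
#' @param params Parameter list.
#' @param config A `model_config`.
#' @return List with `x` (stacked embeddings) and `lens`.
#' @export
embed_smiles <- function(ids_list, params, config) {
  lens <- vapply(ids_list, length, integer(1))
  stopifnot(all(lens >= 1L), all(lens <= config$max_smiles_len))
  all_ids <- unlist(ids_list, use.names = FALSE)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  x <- ad_add(ad_rows(params$tok_emb, all_ids), ad_rows(params$pos_emb_s, pos))
  list(x = x, lens = lens)
}

#' Embed a batch of property vectors
#'
#' Position 1 of each sequence is the learned `[CLS_P]` embedding; position
#' i+1 encodes property i as `value * W_val + b_val` when known, or the
#' learned `[UNK]` vector when masked -- in both cases plus the positional
#' embedding of property i.
#'
#' @param values Numeric B x P matrix of normalized values (entries at
#'   unknown positions are ignored).
#' @param known Logical B x P matrix.
#' @param params Parameter list.
#' @param config A `model_config`.
#' @return List with `x` (stacked B*(P+1) x d embeddings) and `lens`.
#' @export
embed_property_vector <- function(values, known, params, config) {
  stopifnot(is.matrix(values), is.matrix(known),
            ncol(values) == config$n_properties,
            all(dim(values) == dim(known)))
  if (any(known & !is.finite(values))) stop("known property values must be finite")
  B <- nrow(values); P <- ncol(values)
  vals <- as.numeric(t(values))            # property-major within molecule
  kn <- as.numeric(t(known))
  vals[kn == 0] <- 0
  val_rows <- ad_add_vec(ad_mm(matrix(vals, ncol = 1), params$val_W),
                         params$val_b)
  unk_rows <- ad_rows(params$unk_p, rep(1L, B * P))
  prop_rows <- ad_add(ad_mul_const(val_rows, kn),
                      ad_mul_const(unk_rows, 1 - kn))
  cls_rows <- ad_rows(params$cls_p, rep(1L, B))
  stacked <- ad_rbind2(cls_rows, prop_rows)
  # reorder [cls_1..cls_B, props_1.., props_2..] into per-molecule sequences
  perm <- unlist(lapply(seq_len(B), function(b) {
    c(b, B + (b - 1L) * P + seq_len(P))
  }), use.names = FALSE)
  x <- ad_rows(stacked, perm)
  pos <- rep(seq_len(P + 1L), times = B)
  x <- ad_add(x, ad_rows(params$pos_emb_p, pos))
  list(x = x, lens = rep(P + 1L, B))
}

# ---- encoder passes --------------------------------------------------------

#' Run a unimodal encoder over stacked embedded sequences
#'
#' @param emb Result of [embed_smiles()] or [embed_property_vector()].
#' @param params Parameter list.
#' @param config A `model_config`.
#' @param encoder `"enc_s"` or `"enc_p"`.
#' @param causal Use a causal self-attention mask?
#' @param training Apply dropout?
#' @return List with `x` (stacked features) and `lens`.
#' @export
encode_unimodal <- function(emb, params, config, encoder = c("enc_s", "enc_p"),
                            causal = FALSE, training = FALSE) {
  encoder <- match.arg(encoder)
  mask <- .block_mask(emb$lens, causal = causal)
  x <- emb$x
  for (l in seq_len(config$n_layers_unimodal)) {
    x <- .block(x, params, paste0(encoder, ".l", l), config$n_heads, mask,
                dropout = config$dropout, training = training)
  }
  x <- ad_layernorm(x, params[[paste0(encoder, ".lnf.g")]],
                    params[[paste0(encoder, ".lnf.b")]])
  list(x = x, lens = emb$lens)
}

#' Run the fusion encoder
#'
#' Each layer applies self-attention on the query side (optionally causal),
#' cross-attention to the key/value side, then a feed-forward. The parameter
#' set is identical whichever modality supplies the queries.
#'
#' @param query Stacked feature list (from an encoder pass) used as queries.
#' @param kv Stacked feature list providing keys/values.
#' @param params Parameter list.
#' @param config A `model_config`.
#' @param causal_self Causal mask on the query-side self-attention?
#' @param training Apply dropout?
#' @param collect_attention If `TRUE`, return the final layer's per-head
#'   cross-attention matrices in `$attention`.
#' @return List with `x`, `lens`, and optionally `attention`.
#' @export
fuse <- function(query, kv, params, config, causal_self = FALSE,
                 training = FALSE, collect_attention = FALSE) {
  stopifnot(length(query$lens) == length(kv$lens))
  self_mask <- .block_mask(query$lens, causal = causal_self)
  cross_mask <- .block_mask(query$lens, kv$lens, causal = FALSE)
  x <- query$x
  collect <- NULL
  for (l in seq_len(config$n_layers_fusion)) {
    if (collect_attention && l == config$n_layers_fusion) {
      collect <- new.env(parent = emptyenv())
      collect$weights <- vector("list", config$n_heads)
    }
    x <- .block(x, params, paste0("fus.l", l), config$n_heads, self_mask,
                kv = kv$x, cross_mask = cross_mask,
                dropout = config$dropout, training = training,
                collect = collect)
  }
  x <- ad_layernorm(x, params$fus.lnf.g, params$fus.lnf.b)
  out <- list(x = x, lens = query$lens)
  if (collect_attention) out$attention <- collect$weights
  out
}

# Row indices of the [CLS] feature (position 1) of every sequence in a
# stacked feature matrix.
.cls_rows <- function(lens) cumsum(c(0L, utils::head(lens, -1L))) + 1L

#' Extract the per-sequence [CLS] features from a stacked encoder output
#' @param feats List with `x` and `lens`.
#' @return B x d matrix (or node).
#' @export
cls_features <- function(feats) ad_rows(feats$x, .cls_rows(feats$lens))

#' Project and L2-normalize [CLS] features for the contrastive space
#' @param cls B x d features (node or matrix).
#' @param params Parameter list.
#' @param side `"s"` or `"p"`.
#' @return B x contrastive_dim L2-normalized features.
#' @export
project_features <- function(cls, params, side = c("s", "p")) {
  side <- match.arg(side)
  W <- params[[paste0("proj_", side, ".W")]]
  b <- params[[paste0("proj_", side, ".b")]]
  ad_l2norm_rows(ad_add_vec(ad_mm(cls, W), b))
}

# ---- checkpoints -----------------------------------------------------------

#' Bundle a model into a checkpoint object
#'
#' @param params Student parameters.
#' @param config A `model_config`.
#' @param vocab A `bpe_vocab`.
#' @param stats A `normalization_stats`.
#' @param registry A `property_registry`.
#' @param momentum_params Optional teacher parameters.
#' @param loss_log Optional data.frame of training losses.
#' @return A `checkpoint` object.
#' @export
checkpoint <- function(params, config, vocab, stats, registry,
                       momentum_params = NULL, loss_log = NULL) {
  stopifnot(length(stats$names) == config$n_properties,
            identical(stats$names, registry$names))
  structure(list(params = params, config = config, vocab = vocab,
                 stats = stats, registry = registry,
                 momentum_params = momentum_params, loss_log = loss_log),
            class = "checkpoint")
}

#' @export
print.checkpoint <- function(x, ...) {
  cat("<checkpoint> d =", x$config$hidden_dim,
      "| P =", x$config$n_properties,
      "| vocab =", x$config$vocab_size,
      "| params =", length(x$params), "tensors\n")
  invisible(x)
}

#' Save a checkpoint to disk
#' @param ckpt A `checkpoint`.
#' @param path File path (RDS).
#' @export
checkpoint_save <- function(ckpt, path) saveRDS(ckpt, path)

#' Load a checkpoint from disk
#' @param path File path written by [checkpoint_save()].
#' @return A `checkpoint`.
#' @export
checkpoint_load <- function(path) readRDS(path)
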