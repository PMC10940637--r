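# Bidirectional inference: property-conditioned SMILES decoding,
# autoregressive property prediction, generation metrics, and
# cross-attention inspection.

#' Generation configuration
#'
#' @param mode `"greedy"`, `"stochastic"` (temperature-1 sampling from the
#'   full softmax), or `"beam"`.
#' @param beam_width Beam width (>= 1); width 1 is identical to greedy.
#' @param max_len Maximum generated token count (frame included).
#' @return A `generation_config`.
#' @export
generation_config <- function(mode = c("greedy", "stochastic", "beam"),
                              beam_width = 2L, max_len = 100L) {
  mode <- match.arg(mode)
  stopifnot(beam_width >= 1L, max_len > 2L)
  structure(list(mode = mode, beam_width = as.integer(beam_width),
                 max_len = as.integer(max_len)),
            class = "generation_config")
}

#' Beam search over an arbitrary next-token distribution
#'
#' Expands hypotheses by joint log-probability (no length normalization);
#' hypotheses that emit `eos` are held finished and compared against live
#' beams. Exposed so the decoder can be exercised against exhaustive
#' enumeration with a hand-built distribution.
#'
#' @param step_fn `function(prefix_ids)` returning a numeric vector of
#'   log-probabilities for the next token (length = vocabulary size).
#' @param bos,eos Integer begin/end token ids.
#' @param beam_width Number of live hypotheses kept per step.
#' @param max_len Maximum sequence length including `bos` (sequences hitting
#'   it without `eos` are kept unfinished).
#' @return List of hypotheses sorted by decreasing log-probability, each
#'   `list(ids, logp, finished)`; `ids` includes `bos` (and `eos` if
#'   finished).
#' @export
beam_search <- function(step_fn, bos, eos, beam_width = 2L, max_len = 20L) {
  live <- list(list(ids = bos, logp = 0, finished = FALSE))
  done <- list()
  while (length(live) > 0L) {
    cand <- list()
    for (h in live) {
      if (length(h$ids) >= max_len) {
        done[[length(done) + 1L]] <- h
        next
      }
      lp <- step_fn(h$ids)
      ord <- order(lp, decreasing = TRUE)[seq_len(min(beam_width, length(lp)))]
      for (tok in ord) {
        cand[[length(cand) + 1L]] <- list(ids = c(h$ids, tok),
                                          logp = h$logp + lp[tok],
                                          finished = tok == eos)
      }
    }
    if (length(cand) == 0L) break
    ord <- order(vapply(cand, `[[`, numeric(1), "logp"), decreasing = TRUE)
    cand <- cand[ord][seq_len(min(beam_width, length(cand)))]
    live <- list()
    for (h in cand) {
      if (h$finished) {
        done[[length(done) + 1L]] <- h
      } else {
        live[[length(live) + 1L]] <- h
      }
    }
    # stop early once every live hypothesis is dominated by finished ones
    if (length(done) >= beam_width && length(live) > 0L) {
      best_live <- max(vapply(live, `[[`, numeric(1), "logp"))
      worst_keep <- sort(vapply(done, `[[`, numeric(1), "logp"),
                         decreasing = TRUE)[beam_width]
      if (best_live <= worst_keep) live <- list()
    }
  }
  done[order(vapply(done, `[[`, numeric(1), "logp"), decreasing = TRUE)]
}

# Next-token log-probabilities for a SMILES prefix, conditioned on encoded
# PV features: causal unimodal pass over the prefix, causal fusion
# cross-attending to the PV, next-word head at the last position. Special
# tokens other than [SEP] are excluded from generation.
.smiles_step_fn <- function(pv_feats, params, config, specials) {
  forbid <- setdiff(unname(specials), specials[["[SEP]"]])
  function(prefix_ids) {
    emb <- embed_smiles(list(prefix_ids), params, config)
    enc <- encode_unimodal(emb, params, config, "enc_s", causal = TRUE)
    fus <- fuse(enc, pv_feats, params, config, causal_self = TRUE)
    h <- fus$x[nrow(fus$x), , drop = FALSE]
    logits <- as.numeric(h %*% params$nwp.W + params$nwp.b)
    logits[forbid] <- -Inf
    logits - (max(logits) + log(sum(exp(logits - max(logits)))))
  }
}

# Encode a property_vector for conditioning (bidirectional PV pass).
.encode_condition <- function(pv, ckpt) {
  stopifnot(inherits(pv, "property_vector"))
  if (length(pv$values) != ckpt$config$n_properties) {
    stop("property vector length ", length(pv$values),
         " does not match checkpoint P = ", ckpt$config$n_properties)
  }
  emb <- embed_property_vector(matrix(pv$values, 1), matrix(pv$known, 1),
                               ckpt$params, ckpt$config)
  encode_unimodal(emb, ckpt$params, ckpt$config, "enc_p")
}

#' Generate SMILES conditioned on a (partial) property vector
#'
#' Autoregressive decoding with causal SMILES self-attention,
#' cross-attending to the bidirectionally encoded property vector. \[UNK\]
#' positions of the input leave the corresponding properties unconstrained.
#'
#' @param pv A `property_vector` on the normalized scale (use
#'   [normalize_pv()] / [apply_unk_mask()], or [condition_pv()] from raw
#'   target values).
#' @param ckpt A `checkpoint`.
#' @param gen_config A `generation_config`.
#' @param n_samples Number of sequences to return (stochastic mode draws
#'   independently; greedy returns one; beam returns up to `beam_width`).
#' @return Character vector of generated SMILES (may be invalid strings;
#'   sequences that hit `max_len` without \[SEP\] are kept as-is).
#' @export
generate_smiles <- function(pv, ckpt, gen_config = generation_config(),
                            n_samples = 1L) {
  stopifnot(inherits(ckpt, "checkpoint"))
  sp <- ckpt$vocab$specials
  pv_feats <- .encode_condition(pv, ckpt)
  step_fn <- .smiles_step_fn(pv_feats, ckpt$params, ckpt$config, sp)
  max_len <- min(gen_config$max_len, ckpt$config$max_smiles_len)
  bos <- sp[["[CLS_S]"]]; eos <- sp[["[SEP]"]]
  finish <- function(ids) {
    if (ids[length(ids)] != eos) ids <- c(ids, eos)  # frame for detokenize
    detokenize(ids, ckpt$vocab)
  }
  if (gen_config$mode == "beam") {
    hyps <- beam_search(step_fn, bos, eos, gen_config$beam_width, max_len)
    return(vapply(utils::head(hyps, n_samples), function(h) finish(h$ids),
                  character(1)))
  }
  out <- character(n_samples)
  for (s in seq_len(n_samples)) {
    ids <- bos
    repeat {
      lp <- step_fn(ids)
      tok <- if (gen_config$mode == "greedy") {
        which.max(lp)
      } else {
        p <- exp(lp); p[!is.finite(p)] <- 0
        sample.int(length(p), 1L, prob = p)
      }
      ids <- c(ids, tok)
      if (tok == eos || length(ids) >= max_len) break
    }
    out[s] <- finish(ids)
  }
  out
}

#' Build a conditioning property vector from raw-scale targets
#'
#' @param targets Named numeric vector of raw property targets; names must
#'   be registry names. Properties not named are left \[UNK\].
#' @param ckpt A `checkpoint` (supplies registry order and normalization).
#' @return A `property_vector` on the normalized scale.
#' @export
condition_pv <- function(targets, ckpt) {
  nm <- ckpt$stats$names
  bad <- setdiff(names(targets), nm)
  if (length(bad) > 0) stop("unknown property name(s): ", paste(bad, collapse = ", "))
  values <- rep(0, length(nm)); known <- rep(FALSE, length(nm))
  idx <- match(names(targets), nm)
  values[idx] <- (as.numeric(targets) - ckpt$stats$mean[idx]) / ckpt$stats$std[idx]
  known[idx] <- TRUE
  new_property_vector(values, known)
}

#' Predict a full property vector from a SMILES string
#'
#' Properties are generated left-to-right: the prediction head reads the
#' causal PV-side fusion output at each position, starting from \[CLS_P\]
#' alone, appending each predicted value as the next known input. The full
#' prefix is re-encoded every step (no state caching). Results are returned
#' on the raw descriptor scale.
#'
#' @param smiles A single SMILES string.
#' @param ckpt A `checkpoint`.
#' @return Named numeric vector of length P on the raw scale.
#' @export
generate_pv <- function(smiles, ckpt) {
  stopifnot(inherits(ckpt, "checkpoint"))
  if (!smiles_is_valid(smiles)) stop("invalid SMILES: ", smiles)
  cfg <- ckpt$config; P <- cfg$n_properties
  ids <- tokenize(smiles, ckpt$vocab, cfg$max_smiles_len)
  s_feats <- encode_unimodal(embed_smiles(list(ids), ckpt$params, cfg),
                             ckpt$params, cfg, "enc_s")
  vals <- numeric(P)
  for (i in seq_len(P)) {
    known <- c(rep(TRUE, i - 1L), rep(FALSE, P - i + 1L))
    emb <- embed_property_vector(matrix(vals, 1), matrix(known, 1),
                                 ckpt$params, cfg)
    enc <- encode_unimodal(emb, ckpt$params, cfg, "enc_p", causal = TRUE)
    fus <- fuse(enc, s_feats, ckpt$params, cfg, causal_self = TRUE)
    h <- fus$x[i, , drop = FALSE]   # position i predicts property i
    vals[i] <- as.numeric(h %*% ckpt$params$npp.W + ckpt$params$npp.b)
  }
  stats::setNames(vals * ckpt$stats$std + ckpt$stats$mean, ckpt$stats$names)
}

#' Validity, uniqueness and novelty of generated SMILES
#'
#' validity = valid / generated; uniqueness = distinct canonical forms /
#' valid; novelty = unique forms absent from the pre-training set / unique.
#'
#' @param generated Character vector of generated SMILES.
#' @param pretraining_set Character vector of canonical SMILES of the
#'   pre-training corpus (canonicalize with [smiles_canonical()]).
#' @return List with `validity`, `uniqueness`, `novelty` (novelty is `NA`
#'   if no molecule is valid).
#' @export
generation_metrics <- function(generated, pretraining_set) {
  if (length(generated) == 0L) stop("no generated SMILES to score")
  can <- smiles_canonical(generated)
  n_valid <- sum(!is.na(can))
  uniq <- unique(can[!is.na(can)])
  list(validity = n_valid / length(generated),
       uniqueness = if (n_valid > 0) length(uniq) / n_valid else NA_real_,
       novelty = if (length(uniq) > 0)
         sum(!(uniq %in% pretraining_set)) / length(uniq) else NA_real_)
}

#' Normalized RMSE between property targets and generated molecules
#'
#' For each controlled (non-\[UNK\]) property, the RMSE between the target
#' and the recomputed descriptor over the valid generated molecules, on the
#' z-scored scale; the returned value is the mean over controlled
#' properties. Invalid SMILES are excluded with a warning.
#'
#' @param pv Target `property_vector` on the normalized scale.
#' @param generated Character vector of generated SMILES.
#' @param stats A `normalization_stats`.
#' @param registry The `property_registry` used for the targets.
#' @return Mean per-property normalized RMSE.
#' @export
normalized_rmse <- function(pv, generated, stats, registry) {
  stopifnot(inherits(pv, "property_vector"))
  if (!any(pv$known)) stop("no controlled property in the target vector")
  ok <- smiles_is_valid(generated)
  if (!any(ok)) stop("no valid generated molecule to score")
  if (!all(ok)) warning(sum(!ok), " invalid SMILES excluded from RMSE")
  raw <- compute_descriptors(generated[ok], registry)
  z <- sweep(sweep(raw, 2, stats$mean), 2, stats$std, "/")
  ctrl <- which(pv$known)
  rmse <- vapply(ctrl, function(j) {
    sqrt(mean((z[, j] - pv$values[j])^2))
  }, numeric(1))
  mean(rmse)
}

#' Cross-attention map between properties and SMILES subwords
#'
#' Mean over heads of the final fusion layer's cross-attention in the
#' inspection pass (bidirectional masks), with PV features as queries and
#' SMILES features as keys/values. Rows are the P properties (the \[CLS_P\]
#' query row is dropped), columns the framed SMILES tokens; each row sums
#' to 1.
#'
#' @param smiles A single SMILES string.
#' @param pv A `property_vector` (\[UNK\] rows are still reported).
#' @param ckpt A `checkpoint`.
#' @return P x n_tokens numeric matrix with descriptor rownames and subword
#'   colnames.
#' @export
attention_map <- function(smiles, pv, ckpt) {
  stopifnot(inherits(ckpt, "checkpoint"))
  cfg <- ckpt$config
  ids <- tokenize(smiles, ckpt$vocab, cfg$max_smiles_len)
  s_feats <- encode_unimodal(embed_smiles(list(ids), ckpt$params, cfg),
                             ckpt$params, cfg, "enc_s")
  p_feats <- .encode_condition(pv, ckpt)
  fus <- fuse(p_feats, s_feats, ckpt$params, cfg, collect_attention = TRUE)
  m <- Reduce(`+`, fus$attention) / length(fus$attention)
  m <- m[-1L, , drop = FALSE]   # drop the [CLS_P] query row
  rownames(m) <- ckpt$registry$names
  colnames(m) <- ckpt$vocab$tokens[ids]
  m
}

#' Write an attention map as TSV (header row of SMILES subwords)
#'
#' @param m Matrix from [attention_map()].
#' @param path Output path.
#' @return Invisibly, the written data.frame.
#' @export
attention_map_save <- function(m, path) {
  df <- data.frame(property = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
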