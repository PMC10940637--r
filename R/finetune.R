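# Downstream adaptation: scalar prediction from the SMILES-encoder [CLS]
# feature, SMILES augmentation, reaction seq2seq through the fusion encoder,
# and Bemis-Murcko scaffold splitting.

#' Task specification for supervised fine-tuning
#'
#' @param kind `"regression"` or `"classification"` (binary).
#' @param label Name of the label column.
#' @param split Character vector (`"train"`/`"valid"`/`"test"`) assigning
#'   every molecule to exactly one split, or `NULL` to scaffold-split
#'   8:1:1 at fit time.
#' @return A `task_spec`.
#' @export
task_spec <- function(kind = c("regression", "classification"),
                      label = "label", split = NULL) {
  kind <- match.arg(kind)
  if (!is.null(split) && !all(split %in% c("train", "valid", "test"))) {
    stop("split values must be train/valid/test")
  }
  structure(list(kind = kind, label = label, split = split),
            class = "task_spec")
}

#' Attach a freshly initialized prediction head to a checkpoint
#'
#' One-hidden-layer MLP on the `[CLS_S]` feature (GELU activation);
#' 1 output for regression, 2 for binary classification.
#'
#' @param ckpt A `checkpoint`.
#' @param kind Task kind.
#' @param hidden Hidden width (default: the model width).
#' @param seed Initialization seed.
#' @return Named list of head parameters.
#' @export
init_head <- function(ckpt, kind = c("regression", "classification"),
                      hidden = NULL, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  d <- ckpt$config$hidden_dim
  h <- if (is.null(hidden)) d else hidden
  n_out <- if (kind == "regression") 1L else 2L
  list(head.W1 = .mx(d, h), head.b1 = rep(0, h),
       head.W2 = .mx(h, n_out), head.b2 = rep(0, n_out))
}

# Forward through encoder + head for a batch of token id lists. `params`
# must contain both the encoder parameters and the head.
.scalar_forward <- function(ids_list, params, config, kind, training = FALSE) {
  enc <- encode_unimodal(embed_smiles(ids_list, params, config), params,
                         config, "enc_s", training = training)
  cls <- cls_features(enc)
  h <- ad_gelu(ad_add_vec(ad_mm(cls, params$head.W1), params$head.b1))
  ad_add_vec(ad_mm(h, params$head.W2), params$head.b2)
}

#' Predict a scalar (or class probabilities) for SMILES
#'
#' @param smiles Character vector of SMILES.
#' @param ckpt A fine-tuned `checkpoint` whose parameters include a head
#'   (see [finetune_supervised()]), or a raw checkpoint plus `head`.
#' @param head Optional head parameter list overriding the checkpoint's.
#' @param kind Task kind (defaults to the head's output arity).
#' @return Numeric vector (regression) or matrix of class probabilities
#'   with columns `neg`/`pos` (classification).
#' @export
predict_scalar <- function(smiles, ckpt, head = NULL,
                           kind = NULL) {
  stopifnot(inherits(ckpt, "checkpoint"))
  params <- ckpt$params
  if (!is.null(head)) params[names(head)] <- head
  if (is.null(params$head.W1)) stop("checkpoint has no prediction head")
  if (is.null(kind)) {
    kind <- if (ncol(params$head.W2) == 1L) "regression" else "classification"
  }
  ok <- smiles_is_valid(smiles)
  if (!all(ok)) stop("invalid SMILES: ", paste(smiles[!ok], collapse = ", "))
  ids <- tokenize_batch(smiles, ckpt$vocab, ckpt$config$max_smiles_len)
  out <- ad_value(.scalar_forward(ids, params, ckpt$config, kind))
  if (kind == "regression") {
    as.numeric(out)
  } else {
    e <- exp(out - apply(out, 1, max))
    p <- e / rowSums(e)
    colnames(p) <- c("neg", "pos")
    p
  }
}

#' Model-selection rule: epoch with the lowest validation loss
#'
#' @param valid_losses Numeric vector of per-epoch validation losses.
#' @return The 1-based index of the selected epoch (first minimum on ties).
#' @export
best_epoch_index <- function(valid_losses) {
  stopifnot(length(valid_losses) > 0)
  which.min(valid_losses)
}

#' Supervised fine-tuning of the SMILES encoder plus prediction head
#'
#' Trains with AdamW on the training split, selects the epoch with the
#' lowest validation loss, and reports test RMSE (regression) or AUROC
#' (classification) for the selected parameters.
#'
#' @param data data.frame with a `smiles` column and the label column.
#' @param ckpt A pre-trained `checkpoint`.
#' @param task A `task_spec`.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param seed RNG seed (batching, head init, splitting).
#' @param verbose Print per-epoch losses.
#' @return List: `ckpt` (fine-tuned checkpoint including head), `metrics`
#'   (per-split), `best_epoch`, `history` (per-epoch train/valid loss).
#' @export
finetune_supervised <- function(data, ckpt, task, epochs = 10L, lr = 5e-4,
                                batch_size = 16L, seed = 1L, verbose = FALSE) {
  stopifnot(is.data.frame(data), "smiles" %in% names(data),
            task$label %in% names(data), inherits(task, "task_spec"))
  set.seed(seed)
  split <- task$split
  if (is.null(split)) {
    split <- scaffold_split(data$smiles, c(0.8, 0.1, 0.1), seed = seed)
  }
  stopifnot(length(split) == nrow(data))
  if (!all(c("train", "valid") %in% split)) stop("empty train or valid split")
  y <- data[[task$label]]
  if (task$kind == "classification") y <- as.integer(y)
  cfg <- ckpt$config
  ids <- tokenize_batch(data$smiles, ckpt$vocab, cfg$max_smiles_len)
  params <- ckpt$params
  params[names(init_head(ckpt, task$kind, seed = seed))] <-
    init_head(ckpt, task$kind, seed = seed)
  opt <- adamw_init(params)
  tr <- which(split == "train"); va <- which(split == "valid")
  te <- which(split == "test")

  batch_loss <- function(idx, p, training) {
    out <- .scalar_forward(ids[idx], p, cfg, task$kind, training = training)
    if (task$kind == "regression") {
      d <- ad_add(out, matrix(-y[idx], ncol = 1))
      ad_cmul(ad_sum(ad_hprod(d, d)), 1 / length(idx))
    } else {
      lab <- cbind(1 - y[idx], y[idx])
      ad_sum(ad_mul_const(ad_logsoftmax_rows(out), -lab / length(idx)))
    }
  }

  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), train = numeric(), valid = numeric())
  for (ep in seq_len(epochs)) {
    perm <- sample(tr)
    tr_losses <- c()
    for (start in seq(1L, length(perm), by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, length(perm))]
      ad_begin()
      pn <- lapply(params, ad_leaf)
      loss <- batch_loss(idx, pn, training = TRUE)
      gr <- ad_backward(loss)
      grads <- stats::setNames(
        lapply(names(params), function(nm) ad_grad(gr, pn[[nm]])),
        names(params))
      tr_losses <- c(tr_losses, as.numeric(ad_value(loss)))
      ad_end()
      upd <- adamw_step(opt, params, grads, lr, weight_decay = 0.02)
      params <- upd$params; opt <- upd$opt
    }
    vloss <- as.numeric(ad_value(batch_loss(va, params, training = FALSE)))
    history <- rbind(history, data.frame(epoch = ep, train = mean(tr_losses),
                                         valid = vloss))
    if (verbose) message(sprintf("epoch %d train %.4f valid %.4f",
                                 ep, mean(tr_losses), vloss))
    if (vloss < best$loss) best <- list(loss = vloss, params = params, epoch = ep)
  }

  tuned <- ckpt
  tuned$params <- best$params
  eval_split <- function(idx) {
    if (length(idx) == 0L) return(NULL)
    if (task$kind == "regression") {
      pred <- predict_scalar(data$smiles[idx], tuned)
      list(rmse = sqrt(mean((pred - y[idx])^2)))
    } else {
      p <- predict_scalar(data$smiles[idx], tuned)[, "pos"]
      auc <- if (length(unique(y[idx])) == 2L) {
        as.numeric(pROC::auc(pROC::roc(y[idx], p, quiet = TRUE,
                                       direction = "<", levels = c(0, 1))))
      } else NA_real_
      list(auroc = auc)
    }
  }
  list(ckpt = tuned,
       metrics = list(train = eval_split(tr), valid = eval_split(va),
                      test = eval_split(te)),
       best_epoch = best$epoch, history = history)
}

#' Randomized non-canonical SMILES augmentation
#'
#' With probability `p`, each molecule (each dot-separated fragment
#' independently) is rewritten starting from a uniformly chosen atom, which
#' changes the SMILES string but not the molecule; otherwise it is returned
#' unchanged. Uses R's global RNG stream.
#'
#' @param smiles A single valid SMILES string.
#' @param p Rewrite probability.
#' @return A SMILES string spelling the same molecule.
#' @export
augment_smiles <- function(smiles, p = 0.5) {
  stopifnot(length(smiles) == 1L, p >= 0, p <= 1)
  if (!smiles_is_valid(smiles)) stop("invalid SMILES: ", smiles)
  if (stats::runif(1) >= p) return(smiles)
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  out <- vapply(parts, function(frag) {
    n_atoms <- .ob_properties(frag, "atoms")[1, 1]
    if (is.na(n_atoms) || n_atoms < 2) return(frag)
    alt <- .ob_rewrite_from_atom(frag, sample.int(n_atoms, 1L))
    if (is.na(alt) || !nzchar(alt)) frag else alt
  }, character(1), USE.NAMES = FALSE)
  paste(out, collapse = ".")
}

#' Fine-tune for forward/retro reaction prediction (seq2seq)
#'
#' The source side (reactants for `"forward"`, product for `"retro"`) is
#' encoded bidirectionally with the SMILES encoder; the target side is
#' decoded causally through the fusion encoder with the next-word head,
#' trained with cross-entropy. With probability `augment_p` each side of a
#' training pair is replaced by a pre-computed randomized non-canonical
#' rewriting.
#'
#' @param pairs data.frame with columns `reactants`, `product`.
#' @param ckpt A pre-trained `checkpoint`.
#' @param direction `"forward"` or `"retro"`.
#' @param steps Optimizer steps.
#' @param batch_size Pairs per step.
#' @param lr Learning rate.
#' @param augment_p Probability of using an augmented SMILES per side.
#' @param n_augment Cached augmented variants per molecule.
#' @param seed RNG seed.
#' @param verbose Print progress.
#' @return List: `ckpt` (tuned), `history` (per-step loss), `direction`.
#' @export
reaction_seq2seq <- function(pairs, ckpt, direction = c("forward", "retro"),
                             steps = 200L, batch_size = 8L, lr = 1e-3,
                             augment_p = 0.5, n_augment = 4L, seed = 1L,
                             verbose = FALSE) {
  direction <- match.arg(direction)
  stopifnot(all(c("reactants", "product") %in% names(pairs)))
  set.seed(seed)
  cfg <- ckpt$config
  src_str <- if (direction == "forward") pairs$reactants else pairs$product
  tgt_str <- if (direction == "forward") pairs$product else pairs$reactants

  tok_or_null <- function(s) {
    tryCatch(tokenize(s, ckpt$vocab, cfg$max_smiles_len),
             error = function(e) NULL)
  }
  variants <- function(s) {
    alts <- if (augment_p > 0 && n_augment > 0) {
      unique(vapply(seq_len(n_augment), function(i) augment_smiles(s, 1),
                    character(1)))
    } else character()
    toks <- Filter(Negate(is.null), lapply(c(s, alts), tok_or_null))
    if (length(toks) == 0L) NULL else toks
  }
  src_tok <- lapply(src_str, variants)
  tgt_tok <- lapply(tgt_str, variants)
  usable <- which(!vapply(src_tok, is.null, logical(1)) &
                    !vapply(tgt_tok, is.null, logical(1)))
  if (length(usable) < length(src_tok)) {
    message(length(src_tok) - length(usable), " pair(s) skipped (too long)")
  }
  if (length(usable) < 2L) stop("not enough usable reaction pairs")

  params <- ckpt$params
  opt <- adamw_init(params)
  history <- numeric(steps)
  pick <- function(vlist, i, use_aug) {
    v <- vlist[[i]]
    if (use_aug && length(v) > 1L && stats::runif(1) < augment_p) {
      v[[sample.int(length(v) - 1L, 1L) + 1L]]
    } else {
      v[[1L]]
    }
  }
  for (step in seq_len(steps)) {
    idx <- sample(usable, min(batch_size, length(usable)))
    src <- lapply(idx, function(i) pick(src_tok, i, TRUE))
    tgt <- lapply(idx, function(i) pick(tgt_tok, i, TRUE))
    ad_begin()
    pn <- lapply(params, ad_leaf)
    src_enc <- encode_unimodal(embed_smiles(src, pn, cfg), pn, cfg, "enc_s",
                               training = TRUE)
    tgt_enc <- encode_unimodal(embed_smiles(tgt, pn, cfg), pn, cfg, "enc_s",
                               causal = TRUE, training = TRUE)
    fus <- fuse(tgt_enc, src_enc, pn, cfg, causal_self = TRUE, training = TRUE)
    lens <- tgt_enc$lens
    off <- .offsets(lens)
    B <- length(idx)
    pred_rows <- unlist(lapply(seq_len(B), function(b) off[b] + seq_len(lens[b] - 1L)),
                        use.names = FALSE)
    tgt_ids <- unlist(lapply(tgt, function(v) v[-1L]), use.names = FALSE)
    logits <- ad_add_vec(ad_mm(ad_rows(fus$x, pred_rows), pn$nwp.W), pn$nwp.b)
    loss <- nwp_loss(logits, tgt_ids, rep(seq_len(B), lens - 1L))
    gr <- ad_backward(loss)
    grads <- stats::setNames(
      lapply(names(params), function(nm) ad_grad(gr, pn[[nm]])), names(params))
    history[step] <- as.numeric(ad_value(loss))
    ad_end()
    upd <- adamw_step(opt, params, grads, lr, weight_decay = 0.02)
    params <- upd$params; opt <- upd$opt
    if (verbose && step %% 25L == 0L) {
      message(sprintf("step %d loss %.4f", step, history[step]))
    }
  }
  tuned <- ckpt
  tuned$params <- params
  list(ckpt = tuned, history = history, direction = direction)
}

#' Predict reaction outcomes with beam search
#'
#' @param source Character vector of source-side SMILES (reactants for a
#'   forward model, product for a retro model).
#' @param ckpt A checkpoint tuned by [reaction_seq2seq()].
#' @param beam_width Beam width (also the number of ranked candidates).
#' @param max_len Decoding length cap.
#' @return List (one element per input) of character vectors of candidate
#'   SMILES ranked by joint log-probability.
#' @export
predict_reaction <- function(source, ckpt, beam_width = 2L, max_len = NULL) {
  cfg <- ckpt$config
  if (is.null(max_len)) max_len <- cfg$max_smiles_len
  sp <- ckpt$vocab$specials
  lapply(source, function(s) {
    ids <- tokenize(s, ckpt$vocab, cfg$max_smiles_len)
    src_enc <- encode_unimodal(embed_smiles(list(ids), ckpt$params, cfg),
                               ckpt$params, cfg, "enc_s")
    step_fn <- .smiles_step_fn(src_enc, ckpt$params, cfg, sp)
    hyps <- beam_search(step_fn, sp[["[CLS_S]"]], sp[["[SEP]"]],
                        beam_width, max_len)
    vapply(hyps, function(h) {
      ids <- h$ids
      if (ids[length(ids)] != sp[["[SEP]"]]) ids <- c(ids, sp[["[SEP]"]])
      detokenize(ids, ckpt$vocab)
    }, character(1))
  })
}

#' Top-k exact-match accuracy for reaction prediction
#'
#' A prediction is correct if any of the k best candidates canonicalizes to
#' the same SMILES as the true target.
#'
#' @param predictions List of ranked candidate vectors (from
#'   [predict_reaction()]).
#' @param truth Character vector of true target SMILES.
#' @param k Ranks to consider.
#' @return Named numeric vector of accuracies, one per k.
#' @export
topk_accuracy <- function(predictions, truth, k = c(1L, 2L)) {
  stopifnot(length(predictions) == length(truth))
  truth_can <- smiles_canonical(truth)
  hits <- vapply(seq_along(truth), function(i) {
    cand <- smiles_canonical(predictions[[i]])
    m <- which(!is.na(cand) & cand == truth_can[i])
    if (length(m) == 0L) Inf else min(m)
  }, numeric(1))
  stats::setNames(vapply(k, function(kk) mean(hits <= kk), numeric(1)),
                  paste0("top", k))
}

#' Bemis-Murcko scaffold split
#'
#' The scaffold of a molecule is its ring systems plus connecting linkers,
#' obtained by iteratively deleting terminal (degree-1) heavy atoms from the
#' molecular graph. Scaffold identity uses a canonical graph labeling with
#' element vertex colors and bond orders, so molecules sharing a scaffold
#' never straddle splits. Acyclic molecules have an empty scaffold and form
#' singleton groups. Groups are sorted by size (descending) and assigned
#' greedily to train, then valid, then test.
#'
#' @param smiles Character vector of molecules.
#' @param fractions Length-3 numeric summing to 1 (train/valid/test).
#' @param seed Tie-breaking seed (groups of equal size are ordered by a
#'   deterministic key; the seed only affects nothing unless keys collide).
#' @return Character vector of `"train"`/`"valid"`/`"test"`.
#' @export
scaffold_split <- function(smiles, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  keys <- scaffold_keys(smiles)
  singles <- is.na(keys)
  keys[singles] <- paste0("singleton_", which(singles))
  groups <- split(seq_along(smiles), keys)
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  n <- length(smiles)
  targets <- c(train = fractions[1] * n, valid = fractions[2] * n,
               test = fractions[3] * n)
  counts <- c(train = 0, valid = 0, test = 0)
  out <- character(n)
  for (g in groups) {
    dest <- if (counts["train"] + length(g) <= targets["train"] + 1e-9) {
      "train"
    } else if (counts["valid"] + length(g) <= targets["valid"] + 1e-9) {
      "valid"
    } else if (counts["test"] + length(g) <= targets["test"] + 1e-9) {
      "test"
    } else {
      names(which.min(counts / pmax(targets, 1e-9)))
    }
    out[g] <- dest
    counts[dest] <- counts[dest] + length(g)
  }
  out
}

#' Canonical scaffold identity keys
#'
#' @param smiles Character vector.
#' @return Character vector of scaffold keys; `NA` for acyclic molecules
#'   (empty scaffold).
#' @export
scaffold_keys <- function(smiles) {
  graphs <- .smiles_to_graphs(smiles)
  vapply(graphs, function(g) {
    if (is.null(g)) return(NA_character_)
    repeat {
      deg1 <- which(igraph::degree(g) <= 1L)
      if (length(deg1) == 0L || igraph::vcount(g) == 0L) break
      g <- igraph::delete_vertices(g, deg1)
    }
    if (igraph::vcount(g) == 0L) return(NA_character_)
    elems <- igraph::V(g)$element
    colors <- as.integer(factor(elems, levels = sort(unique(elems))))
    cp <- igraph::canonical_permutation(g, colors = colors)
    gc <- igraph::permute(g, cp$labeling)
    el <- igraph::as_edgelist(gc)
    el <- t(apply(el, 1L, sort))
    eo <- order(el[, 1], el[, 2])
    paste(paste(igraph::V(gc)$element, collapse = ","),
          paste(el[eo, 1], el[eo, 2], round(igraph::E(gc)$order[eo], 2),
                sep = "-", collapse = ";"),
          sep = "|")
  }, character(1))
}
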