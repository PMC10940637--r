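# The multimodal pre-training loop.
#
# Each optimizer step: sample a batch, mask 50% of property positions,
# run the student encoders twice (bidirectional features for the contrastive
# and matching objectives; causal features for next-word and next-property
# prediction), compute the four losses with momentum pseudo-labels, update
# with AdamW, move the teacher by EMA, and enqueue the teacher's projected
# [CLS] features into the per-modality FIFO queues.

# Row offsets of each sequence in a stacked feature matrix.
.offsets <- function(lens) cumsum(c(0L, utils::head(lens, -1L)))

# Gather whole sequences (by batch index, in order) from a stacked feature
# list; returns a new stacked feature list.
.gather_seqs <- function(feats, batch_idx) {
  off <- .offsets(feats$lens)
  rows <- unlist(lapply(batch_idx, function(b) off[b] + seq_len(feats$lens[b])),
                 use.names = FALSE)
  list(x = ad_rows(feats$x, rows), lens = feats$lens[batch_idx])
}

# One pre-training step on an explicit batch. Returns loss values, gradient
# list, and the teacher-projected features for queue updates.
.pretrain_step <- function(ids_list, pv_values, pv_known, mask_known,
                           params, m_params, config, alpha,
                           queue_s, queue_p) {
  B <- length(ids_list)
  P <- config$n_properties

  ad_begin()
  on.exit(ad_end(), add = TRUE)
  pn <- lapply(params, ad_leaf)

  # ---- student encoder passes
  emb_s <- embed_smiles(ids_list, pn, config)
  emb_p <- embed_property_vector(pv_values, mask_known, pn, config)
  s_bid <- encode_unimodal(emb_s, pn, config, "enc_s", causal = FALSE, training = TRUE)
  p_bid <- encode_unimodal(emb_p, pn, config, "enc_p", causal = FALSE, training = TRUE)
  s_cau <- encode_unimodal(emb_s, pn, config, "enc_s", causal = TRUE, training = TRUE)
  p_cau <- encode_unimodal(emb_p, pn, config, "enc_p", causal = TRUE, training = TRUE)
  z_s <- project_features(cls_features(s_bid), pn, "s")
  z_p <- project_features(cls_features(p_bid), pn, "p")

  # ---- teacher passes (plain matrices, no tape)
  m_emb_s <- embed_smiles(ids_list, m_params, config)
  m_emb_p <- embed_property_vector(pv_values, mask_known, m_params, config)
  m_s_bid <- encode_unimodal(m_emb_s, m_params, config, "enc_s")
  m_p_bid <- encode_unimodal(m_emb_p, m_params, config, "enc_p")
  mz_s <- project_features(cls_features(m_s_bid), m_params, "s")
  mz_p <- project_features(cls_features(m_p_bid), m_params, "p")

  # ---- contrastive with queues and momentum pseudo-labels
  cand_s <- rbind(mz_s, queue_features(queue_s))
  cand_p <- rbind(mz_p, queue_features(queue_p))
  N <- nrow(cand_p)
  onehot <- matrix(0, B, N); onehot[cbind(seq_len(B), seq_len(B))] <- 1
  log_dists <- list(
    s2p = similarity_distribution(z_s, cand_p, pn$tau, log = TRUE),
    p2s = similarity_distribution(z_p, cand_s, pn$tau, log = TRUE),
    s2s = similarity_distribution(z_s, cand_s, pn$tau, log = TRUE),
    p2p = similarity_distribution(z_p, cand_p, pn$tau, log = TRUE))
  m_tau <- as.numeric(m_params$tau)
  momentum_dists <- if (alpha > 0) list(
    s2p = similarity_distribution(mz_s, cand_p, m_tau),
    p2s = similarity_distribution(mz_p, cand_s, m_tau),
    s2s = similarity_distribution(mz_s, cand_s, m_tau),
    p2p = similarity_distribution(mz_p, cand_p, m_tau)) else NULL
  targets <- list(s2p = onehot, p2s = onehot, s2s = onehot, p2p = onehot)
  l_con <- contrastive_loss(log_dists, targets, momentum_dists, alpha)

  # ---- next-word prediction (causal SMILES fused with bidirectional PV)
  fus_nwp <- fuse(s_cau, p_bid, pn, config, causal_self = TRUE, training = TRUE)
  lens_s <- s_cau$lens
  off_s <- .offsets(lens_s)
  pred_rows <- unlist(lapply(seq_len(B), function(b) off_s[b] + seq_len(lens_s[b] - 1L)),
                      use.names = FALSE)
  tgt_ids <- unlist(lapply(ids_list, function(v) v[-1L]), use.names = FALSE)
  seq_of_s <- rep(seq_len(B), lens_s - 1L)
  nwp_logits <- ad_add_vec(ad_mm(ad_rows(fus_nwp$x, pred_rows), pn$nwp.W), pn$nwp.b)
  m_probs <- NULL
  if (alpha > 0) {
    m_s_cau <- encode_unimodal(m_emb_s, m_params, config, "enc_s", causal = TRUE)
    m_fus <- fuse(m_s_cau, m_p_bid, m_params, config, causal_self = TRUE)
    m_logits <- sweep(m_fus$x[pred_rows, , drop = FALSE] %*% m_params$nwp.W,
                      2, m_params$nwp.b, "+")
    m_probs <- ad_softmax_rows(m_logits)
  }
  l_nwp <- nwp_loss(nwp_logits, tgt_ids, seq_of_s, m_probs, alpha)

  # ---- next-property prediction (causal PV fused with bidirectional SMILES)
  fus_npp <- fuse(p_cau, s_bid, pn, config, causal_self = TRUE, training = TRUE)
  off_p <- .offsets(fus_npp$lens)
  npp_rows <- unlist(lapply(seq_len(B), function(b) off_p[b] + seq_len(P)),
                     use.names = FALSE)
  npp_preds <- ad_add_vec(ad_mm(ad_rows(fus_npp$x, npp_rows), pn$npp.W), pn$npp.b)
  l_npp <- npp_loss(npp_preds, as.numeric(t(pv_values)),
                    as.numeric(t(mask_known)) > 0, rep(seq_len(B), each = P))

  # ---- matching with hard negatives
  sim_sp <- ad_value(similarity_distribution(ad_value(z_s)[, , drop = FALSE],
                                             ad_value(z_p), as.numeric(ad_value(pn$tau))))
  sim_ps <- ad_value(similarity_distribution(ad_value(z_p)[, , drop = FALSE],
                                             ad_value(z_s), as.numeric(ad_value(pn$tau))))
  neg_p <- select_hard_negatives(sim_sp)   # PV negative for each SMILES anchor
  neg_s <- select_hard_negatives(sim_ps)   # SMILES negative for each PV anchor
  q_idx_s <- c(seq_len(B), seq_len(B), neg_s)
  kv_idx_p <- c(seq_len(B), neg_p, seq_len(B))
  fs <- fuse(.gather_seqs(s_bid, q_idx_s), .gather_seqs(p_bid, kv_idx_p),
             pn, config, training = TRUE)
  fp <- fuse(.gather_seqs(p_bid, kv_idx_p), .gather_seqs(s_bid, q_idx_s),
             pn, config, training = TRUE)
  spm_in <- ad_cbind_list(list(cls_features(fs), cls_features(fp)))
  spm_logits <- ad_add_vec(ad_mm(spm_in, pn$spm.W), pn$spm.b)
  spm_labels <- c(rep(1L, B), rep(0L, 2L * B))
  l_spm <- spm_loss(spm_logits, spm_labels)

  total <- ad_add(ad_add(l_con, l_nwp), ad_add(l_npp, l_spm))
  losses <- c(contrastive = as.numeric(ad_value(l_con)),
              nwp = as.numeric(ad_value(l_nwp)),
              npp = as.numeric(ad_value(l_npp)),
              spm = as.numeric(ad_value(l_spm)),
              total = as.numeric(ad_value(total)))
  if (any(!is.finite(losses))) {
    stop("non-finite loss at this step: ",
         paste(names(losses)[!is.finite(losses)], collapse = ", "))
  }
  gr <- ad_backward(total)
  grads <- stats::setNames(lapply(names(params), function(nm) ad_grad(gr, pn[[nm]])),
                           names(params))
  list(losses = losses, grads = grads, mz_s = mz_s, mz_p = mz_p)
}

#' Pre-train the multimodal model on a SMILES corpus
#'
#' @param corpus Character vector of SMILES strings.
#' @param config A `model_config` (its `vocab_size` / `n_properties` are
#'   overwritten from the fitted vocabulary and registry).
#' @param schedule A `pretrain_schedule`.
#' @param registry A `property_registry`.
#' @param vocab Optional pre-trained `bpe_vocab`; fitted on `corpus` when
#'   `NULL`.
#' @param stats Optional `normalization_stats`; fitted on `corpus` when
#'   `NULL`.
#' @param vocab_size Target vocabulary size when fitting the tokenizer.
#' @param seed Integer seed controlling initialization, batching, masking,
#'   and mining.
#' @param verbose Print a progress line every `log_every` steps.
#' @param log_every Logging period (steps).
#' @return A `checkpoint` with student and teacher parameters and a loss log
#'   (`data.frame`: step, lr, alpha, four losses, total).
#' @export
pretrain <- function(corpus, config = NULL, schedule, registry = toy_registry(),
                     vocab = NULL, stats = NULL, vocab_size = 300L,
                     seed = 1L, verbose = FALSE, log_every = 25L) {
  stopifnot(inherits(schedule, "pretrain_schedule"))
  set.seed(seed)
  valid <- smiles_is_valid(corpus)
  if (!all(valid)) {
    warning(sum(!valid), " invalid SMILES dropped from the pre-training corpus")
    corpus <- corpus[valid]
  }
  if (length(corpus) < schedule$batch_size) {
    stop("corpus smaller than one batch")
  }
  if (is.null(vocab)) vocab <- train_bpe(corpus, vocab_size)
  if (is.null(stats)) stats <- fit_normalization(corpus, registry)
  if (is.null(config)) config <- model_config(vocab_size = length(vocab$tokens))
  config$vocab_size <- length(vocab$tokens)
  config$n_properties <- length(registry$names)

  ids_all <- tokenize_batch(corpus, vocab, config$max_smiles_len)
  raw <- compute_descriptors(corpus, registry)
  values_all <- sweep(sweep(raw, 2, stats$mean), 2, stats$std, "/")

  params <- init_model_params(config, seed = seed)
  params$tau <- matrix(schedule$tau_init, 1, 1)
  m_params <- init_momentum_copy(params)
  opt <- adamw_init(params)
  queue_s <- feature_queue(schedule$queue_capacity, config$contrastive_dim)
  queue_p <- feature_queue(schedule$queue_capacity, config$contrastive_dim)

  steps_per_epoch <- max(1L, floor(length(corpus) / schedule$batch_size))
  ramp <- if (is.null(schedule$alpha_ramp_steps)) steps_per_epoch
          else schedule$alpha_ramp_steps
  log <- vector("list", schedule$total_steps)

  for (step in seq_len(schedule$total_steps)) {
    batch <- sample.int(length(corpus), schedule$batch_size)
    drop <- matrix(stats::runif(schedule$batch_size * config$n_properties) <
                     schedule$mask_rate,
                   schedule$batch_size, config$n_properties)
    mask_known <- !drop
    alpha <- alpha_at(step, ramp, schedule$alpha_target)
    lr <- lr_at(step, schedule$warmup_steps, schedule$total_steps,
                schedule$lr_peak, schedule$lr_end)
    res <- .pretrain_step(ids_all[batch],
                          values_all[batch, , drop = FALSE],
                          matrix(TRUE, schedule$batch_size, config$n_properties),
                          mask_known, params, m_params, config, alpha,
                          queue_s, queue_p)
    upd <- adamw_step(opt, params, res$grads, lr,
                      schedule$weight_decay, schedule$grad_clip)
    params <- upd$params; opt <- upd$opt
    params$tau[1, 1] <- min(max(params$tau[1, 1], schedule$tau_min),
                            schedule$tau_max)
    m_params <- ema_update(params, m_params, schedule$lambda)
    queue_push(queue_s, res$mz_s)
    queue_push(queue_p, res$mz_p)
    log[[step]] <- c(step = step, lr = lr, alpha = alpha, res$losses)
    if (verbose && (step %% log_every == 0L || step == 1L)) {
      message(sprintf("step %4d lr %.2e alpha %.2f total %.3f", step, lr,
                      alpha, res$losses[["total"]]))
    }
  }
  loss_log <- as.data.frame(do.call(rbind, log))
  checkpoint(params, config, vocab, stats, registry,
             momentum_params = m_params, loss_log = loss_log)
}

#' Write a pre-training loss log as TSV
#' @param loss_log The `loss_log` from a checkpoint.
#' @param path Output path.
#' @export
loss_log_save <- function(loss_log, path) {
  utils::write.table(loss_log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}
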