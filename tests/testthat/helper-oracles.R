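# Independent straight-line reference implementations used as oracles.
# These deliberately share no code with the package internals: plain loops
# and base arithmetic only.

oracle_attention <- function(Q, K, V, mask = NULL) {
  dk <- ncol(Q)
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) {
      s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
      if (!is.null(mask)) s[j] <- s[j] + mask[i, j]
    }
    e <- exp(s - max(s))
    p <- e / sum(e)
    for (j in seq_len(nrow(K))) out[i, ] <- out[i, ] + p[j] * V[j, ]
  }
  out
}

oracle_softmax_row <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Contrastive loss from raw similarity logit matrices (anchor x candidate),
# one-hot positives on the first-block diagonal, momentum probabilities
# mixed with weight alpha.
oracle_contrastive <- function(logit_list, momentum_prob_list, alpha) {
  total <- 0
  for (d in names(logit_list)) {
    L <- logit_list[[d]]
    B <- nrow(L)
    dir_loss <- 0
    for (i in seq_len(B)) {
      p <- oracle_softmax_row(L[i, ])
      y <- rep(0, ncol(L)); y[i] <- 1
      if (alpha > 0) y <- (1 - alpha) * y + alpha * momentum_prob_list[[d]][i, ]
      dir_loss <- dir_loss - sum(y * log(p))
    }
    total <- total + dir_loss / B
  }
  total / 2
}

# NWP loss from logits rows, integer targets, per-row sequence index, and
# optional teacher probabilities.
oracle_nwp <- function(logits, targets, seq_of, momentum_probs = NULL,
                       alpha = 0) {
  B <- length(unique(seq_of))
  acc <- 0
  for (r in seq_len(nrow(logits))) {
    p <- oracle_softmax_row(logits[r, ])
    y <- rep(0, ncol(logits)); y[targets[r]] <- 1
    if (alpha > 0) y <- (1 - alpha) * y + alpha * momentum_probs[r, ]
    acc <- acc - sum(y * log(p))
  }
  acc / B
}

oracle_npp <- function(preds, targets, known, seq_of) {
  B <- length(unique(seq_of))
  acc <- 0
  for (r in seq_along(targets)) {
    if (known[r]) acc <- acc + (preds[r] - targets[r])^2
  }
  acc / B
}

oracle_spm <- function(logits, labels) {
  acc <- 0
  for (r in seq_len(nrow(logits))) {
    p <- oracle_softmax_row(logits[r, ])
    acc <- acc - log(p[labels[r] + 1L])
  }
  acc / nrow(logits)
}

# Exhaustive enumeration of all token sequences up to max_len under a
# step-function model; returns all complete sequences (ending in eos or at
# max_len) with their joint log-probabilities, best first.
oracle_enumerate_sequences <- function(step_fn, bos, eos, n_tokens, max_len) {
  results <- list()
  recurse <- function(prefix, logp) {
    if (length(prefix) >= max_len) {
      results[[length(results) + 1L]] <<- list(ids = prefix, logp = logp)
      return()
    }
    lp <- step_fn(prefix)
    for (tok in seq_len(n_tokens)) {
      if (!is.finite(lp[tok])) next
      if (tok == eos) {
        results[[length(results) + 1L]] <<- list(ids = c(prefix, tok),
                                                 logp = logp + lp[tok])
      } else {
        recurse(c(prefix, tok), logp + lp[tok])
      }
    }
  }
  recurse(bos, 0)
  results[order(vapply(results, `[[`, numeric(1), "logp"), decreasing = TRUE)]
}

# A hand-built next-token model over a 5-token alphabet (token 5 = eos):
# sharply ordered logits with small prefix- and position-dependent
# perturbations. The decay dominates the perturbations, so the global top-2
# sequences stay inside the per-step top-2 expansions and beam width 2 is
# exact on this table (beam search is not exact in general); the
# perturbations also break the permutation ties a prefix-independent table
# would have. Verified against exhaustive enumeration below.
toy_table_step_fn <- function() {
  function(prefix_ids) {
    r <- prefix_ids[length(prefix_ids)]
    t <- length(prefix_ids)
    l <- c(3, 1.8, 0.6, -0.6, -1.8) + 0.3 * sin(r * (1:5)) +
      0.17 * cos(t * (1:5))
    l - (max(l) + log(sum(exp(l - max(l)))))
  }
}
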