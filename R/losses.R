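# Pre-training objectives.
#
# All loss functions are written with the autodiff ops, so they accept
# either adnodes (training) or plain matrices (oracle comparisons in tests).
# Conventions: per-molecule sums over sequence positions, means over the
# batch, and the four contrastive directions averaged with the 1/2 factor.

#' Similarity between projected [CLS] features
#'
#' Dot products of the L2-normalized projections of a SMILES [CLS] feature
#' and a PV [CLS] feature; `sim(S, P)` and `sim(P, S)` are numerically equal.
#'
#' @param s_cls,p_cls 1 x d (or B x d) unimodal [CLS] features.
#' @param params Parameter list (projection heads).
#' @return Matrix of pairwise similarities (rows: S, cols: P).
#' @export
similarity <- function(s_cls, p_cls, params) {
  zs <- project_features(s_cls, params, "s")
  zp <- project_features(p_cls, params, "p")
  ad_value(ad_mm(zs, ad_t(zp)))
}

#' Temperature-scaled similarity distributions over candidate features
#'
#' For each anchor row of `z`, a softmax over the candidate set at
#' temperature `tau`. The candidate set is the concatenation of the current
#' batch's (momentum) features and the queue contents, so column `i` is the
#' positive for anchor `i`.
#'
#' @param z B x c anchor projections (node or matrix).
#' @param candidates N x c candidate projections (plain matrix; momentum
#'   features are not back-propagated through).
#' @param tau Temperature (scalar node or number), must be positive.
#' @param log If `TRUE` return log-probabilities.
#' @return B x N (log-)probability matrix; rows sum to 1 (probabilities).
#' @export
similarity_distribution <- function(z, candidates, tau, log = FALSE) {
  tv <- as.numeric(ad_value(tau))
  if (!is.finite(tv) || tv <= 0) stop("temperature tau must be positive")
  logits <- ad_smul(ad_mm(z, t(candidates)), ad_sinv(tau))
  if (log) ad_logsoftmax_rows(logits) else ad_softmax_rows(logits)
}

#' Queue-augmented contrastive loss with momentum pseudo-labels
#'
#' Cross-entropy of the four similarity distributions (s2p, p2s, s2s, p2p)
#' against targets mixed from one-hot labels and the momentum model's
#' distributions: `y~ = (1 - alpha) y + alpha s_momentum`. The four
#' directional terms are summed with a global factor 1/2; each term is a
#' batch mean.
#'
#' @param log_dists List of four B x N log-probability matrices (nodes or
#'   matrices), named `s2p`, `p2s`, `s2s`, `p2p`.
#' @param targets List of four B x N one-hot matrices (plain).
#' @param momentum_dists List of four B x N momentum probability matrices
#'   (plain), or `NULL` when `alpha = 0`.
#' @param alpha Pseudo-label mixing weight in \[0, 1\].
#' @return Scalar loss (1x1 node or matrix).
#' @export
contrastive_loss <- function(log_dists, targets, momentum_dists = NULL,
                             alpha = 0) {
  stopifnot(alpha >= 0, alpha <= 1)
  dirs <- c("s2p", "p2s", "s2s", "p2p")
  total <- NULL
  for (d in dirs) {
    lp <- log_dists[[d]]
    y <- targets[[d]]
    stopifnot(all(dim(ad_value(lp)) == dim(y)))
    if (alpha > 0) {
      y <- (1 - alpha) * y + alpha * momentum_dists[[d]]
    }
    B <- nrow(y)
    term <- ad_sum(ad_mul_const(lp, -y / B))
    total <- if (is.null(total)) term else ad_add(total, term)
  }
  ad_cmul(total, 0.5)
}

#' Next-word-prediction loss with momentum soft labels
#'
#' Causal cross-entropy over SMILES positions: the fusion output at position
#' t predicts token t+1. Targets are one-hot mixed with the teacher's
#' next-token distribution. Positions are summed per molecule and averaged
#' over the batch.
#'
#' @param logits M x V prediction logits (node or matrix), rows stacked over
#'   all predicting positions of the batch.
#' @param target_ids Integer vector (length M) of next-token ids.
#' @param seq_of Integer vector (length M) giving the molecule index of each
#'   row (used for the batch mean).
#' @param momentum_probs Optional M x V teacher probability matrix.
#' @param alpha Mixing weight in \[0, 1\].
#' @return Scalar loss.
#' @export
nwp_loss <- function(logits, target_ids, seq_of,
                     momentum_probs = NULL, alpha = 0) {
  V <- ncol(ad_value(logits))
  M <- length(target_ids)
  if (any(target_ids < 1L | target_ids > V)) {
    stop("target token id out of vocabulary range")
  }
  y <- matrix(0, M, V)
  y[cbind(seq_len(M), target_ids)] <- 1
  if (alpha > 0) y <- (1 - alpha) * y + alpha * momentum_probs
  B <- length(unique(seq_of))
  lp <- ad_logsoftmax_rows(logits)
  ad_sum(ad_mul_const(lp, -y / B))
}

#' Next-property-prediction loss
#'
#' Squared error between predicted and true normalized property values,
#' summed over the positions whose target was known (masked \[UNK\]
#' positions contribute nothing), averaged over the batch.
#'
#' @param preds M x 1 predictions (node or matrix), rows stacked over all
#'   property positions of the batch.
#' @param targets Numeric vector (length M) of normalized true values.
#' @param known Logical vector (length M); `FALSE` rows are excluded.
#' @param seq_of Integer vector giving the molecule index of each row.
#' @return Scalar loss.
#' @export
npp_loss <- function(preds, targets, known, seq_of) {
  stopifnot(length(targets) == length(known))
  B <- length(unique(seq_of))
  diff <- ad_add(preds, matrix(-targets, ncol = 1))
  ad_sum(ad_mul_const(ad_hprod(diff, diff),
                      matrix(as.numeric(known) / B, ncol = 1)))
}

#' SMILES-PV matching loss
#'
#' Mean two-way cross-entropy of the matching head over positive and mined
#' negative pairs.
#'
#' @param logits M x 2 matching-head logits (node or matrix); column 2 is
#'   the "matched" class.
#' @param labels Integer/logical vector (length M); 1 = matched pair.
#' @return Scalar loss.
#' @export
spm_loss <- function(logits, labels) {
  M <- length(labels)
  stopifnot(nrow(ad_value(logits)) == M)
  y <- cbind(1 - as.numeric(labels), as.numeric(labels))
  lp <- ad_logsoftmax_rows(logits)
  ad_sum(ad_mul_const(lp, -y / M))
}

#' Sample hard negatives proportionally to intermodal similarity
#'
#' For each anchor, draws one non-matching candidate with probability
#' proportional to its (softmax) intermodal similarity; the positive is
#' excluded and the remaining probabilities renormalized. Uses R's global
#' RNG stream.
#'
#' @param sim_probs B x B matrix of intermodal similarity probabilities
#'   (rows: anchors, cols: in-batch candidates of the other modality).
#' @return Integer vector of length B of sampled negative indices.
#' @export
select_hard_negatives <- function(sim_probs) {
  B <- nrow(sim_probs)
  if (B < 2L) stop("hard-negative mining needs a batch of at least 2")
  vapply(seq_len(B), function(i) {
    w <- sim_probs[i, ]
    w[i] <- 0
    if (sum(w) <= 0) w[-i] <- 1
    sample.int(B, 1L, prob = w / sum(w))
  }, integer(1))
}

#' Exponential-moving-average teacher update
#'
#' `w_teacher <- (1 - lambda) w_student + lambda w_teacher`, elementwise for
#' every parameter.
#'
#' @param student,teacher Parameter lists with identical names/shapes.
#' @param lambda EMA coefficient in \[0, 1\] (1 freezes the teacher).
#' @return Updated teacher parameter list.
#' @export
ema_update <- function(student, teacher, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (!identical(sort(names(student)), sort(names(teacher)))) {
    stop("student and teacher parameter sets do not match")
  }
  for (nm in names(teacher)) {
    if (!identical(dim(student[[nm]]), dim(teacher[[nm]])) ||
        length(student[[nm]]) != length(teacher[[nm]])) {
      stop("parameter shape mismatch for ", nm)
    }
    teacher[[nm]] <- (1 - lambda) * student[[nm]] + lambda * teacher[[nm]]
  }
  teacher
}

# ---- feature queue ---------------------------------------------------------

#' Create a fixed-capacity FIFO feature queue
#'
#' Stores projected [CLS] features row-wise; when capacity is exceeded the
#' oldest rows are evicted first.
#'
#' @param capacity Maximum number of stored feature rows.
#' @param dim Feature dimension.
#' @return A `feature_queue` (environment).
#' @export
feature_queue <- function(capacity, dim) {
  stopifnot(capacity >= 1, dim >= 1)
  q <- new.env(parent = emptyenv())
  q$capacity <- as.integer(capacity)
  q$data <- matrix(numeric(0), 0, dim)
  class(q) <- "feature_queue"
  q
}

#' Enqueue feature rows (evicting the oldest beyond capacity)
#' @param q A `feature_queue`.
#' @param rows Matrix of feature rows.
#' @export
queue_push <- function(q, rows) {
  stopifnot(inherits(q, "feature_queue"), ncol(rows) == ncol(q$data))
  q$data <- rbind(q$data, rows)
  n <- nrow(q$data)
  if (n > q$capacity) {
    q$data <- q$data[(n - q$capacity + 1L):n, , drop = FALSE]
  }
  invisible(q)
}

#' Current queue contents, oldest first
#' @param q A `feature_queue`.
#' @return Matrix (possibly 0 rows).
#' @export
queue_features <- function(q) q$data

#' @export
print.feature_queue <- function(x, ...) {
  cat("<feature_queue>", nrow(x$data), "/", x$capacity, "rows\n")
  invisible(x)
}
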