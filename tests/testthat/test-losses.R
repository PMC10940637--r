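test_that("similarity is the normalized projected dot product", {
  params <- tiny_ckpt()$params
  set.seed(10)
  d <- ncol(params$proj_s.W)
  s_cls <- matrix(rnorm(nrow(params$proj_s.W)), 1)
  p_cls <- matrix(rnorm(nrow(params$proj_p.W)), 1)
  got <- similarity(s_cls, p_cls, params)
  zs <- s_cls %*% params$proj_s.W + matrix(params$proj_s.b, 1)
  zp <- p_cls %*% params$proj_p.W + matrix(params$proj_p.b, 1)
  want <- sum((zs / sqrt(sum(zs^2))) * (zp / sqrt(sum(zp^2))))
  expect_equal(as.numeric(got), want, tolerance = 1e-10)
  # identical projections give similarity 1; orthogonal give 0
  z <- matrix(rnorm(8), 1)
  expect_equal(sum((z / sqrt(sum(z^2)))^2), 1, tolerance = 1e-12)
})

test_that("similarity distributions are softmax rows over candidates", {
  set.seed(11)
  z <- matrix(rnorm(8), 1, 8); z <- z / sqrt(sum(z^2))
  # single candidate -> probability 1
  expect_equal(as.numeric(similarity_distribution(z, z, 0.07)), 1)
  # equal similarities over N candidates -> 1/N each
  cand <- do.call(rbind, replicate(5, z, simplify = FALSE))
  expect_equal(as.numeric(similarity_distribution(z, cand, 0.1)),
               rep(1 / 5, 5))
  # 3x3 case against a hand-computed softmax at tau = 0.1
  zs <- matrix(rnorm(9), 3, 3)
  cs <- matrix(rnorm(9), 3, 3)
  got <- similarity_distribution(zs, cs, 0.1)
  for (i in 1:3) {
    logits <- as.numeric(zs[i, , drop = FALSE] %*% t(cs)) / 0.1
    expect_lt(max(abs(got[i, ] - oracle_softmax_row(logits))), 1e-6)
  }
  expect_equal(unname(rowSums(got)), rep(1, 3), tolerance = 1e-12)
  expect_error(similarity_distribution(zs, cs, -1), "tau")
})

test_that("contrastive loss hits its closed forms", {
  B <- 3L; N <- 7L
  onehot <- matrix(0, B, N); onehot[cbind(1:B, 1:B)] <- 1
  targets <- list(s2p = onehot, p2s = onehot, s2s = onehot, p2p = onehot)
  # model equals the one-hot target -> loss 0 (log-probs of 1 at positives)
  perfect <- log(onehot + 1e-300)
  dists <- list(s2p = perfect, p2s = perfect, s2s = perfect, p2p = perfect)
  expect_equal(as.numeric(contrastive_loss(dists, targets)), 0,
               tolerance = 1e-10)
  # uniform distributions in all four directions -> 2 ln N
  unif <- matrix(log(1 / N), B, N)
  dists <- list(s2p = unif, p2s = unif, s2s = unif, p2p = unif)
  expect_equal(as.numeric(contrastive_loss(dists, targets)), 2 * log(N),
               tolerance = 1e-10)
})

test_that("contrastive loss with momentum mixing matches the oracle", {
  set.seed(12)
  B <- 2L; N <- 6L
  logit_list <- lapply(stats::setNames(1:4, c("s2p", "p2s", "s2s", "p2p")),
                       function(i) matrix(rnorm(B * N), B, N))
  mom <- lapply(logit_list, function(L) {
    t(apply(L + rnorm(length(L)) * 0.3, 1, oracle_softmax_row))
  })
  onehot <- matrix(0, B, N); onehot[cbind(1:B, 1:B)] <- 1
  targets <- list(s2p = onehot, p2s = onehot, s2s = onehot, p2p = onehot)
  log_dists <- lapply(logit_list, function(L) {
    t(apply(L, 1, function(r) log(oracle_softmax_row(r))))
  })
  got <- as.numeric(contrastive_loss(log_dists, targets, mom, alpha = 0.4))
  want <- oracle_contrastive(logit_list, mom, alpha = 0.4)
  expect_lt(abs(got - want), 1e-6)
})

test_that("next-word loss hits closed forms and matches the oracle", {
  V <- 11L
  # perfectly confident and correct -> 0
  targets <- c(3L, 5L, 7L)
  logits <- matrix(-1e4, 3, V)
  logits[cbind(1:3, targets)] <- 1e4
  expect_equal(as.numeric(nwp_loss(logits, targets, rep(1L, 3))), 0,
               tolerance = 1e-8)
  # uniform prediction over V tokens, n positions in one sequence -> n ln V
  n <- 4L
  unif <- matrix(0, n, V)
  expect_equal(as.numeric(nwp_loss(unif, rep(2L, n), rep(1L, n))),
               n * log(V), tolerance = 1e-10)
  # fixed toy logits with alpha = 0.4 against the straight-line oracle
  set.seed(13)
  logits <- matrix(rnorm(3 * V), 3, V)
  mom <- t(apply(matrix(rnorm(3 * V), 3, V), 1, oracle_softmax_row))
  seq_of <- c(1L, 1L, 2L)
  got <- as.numeric(nwp_loss(logits, targets, seq_of, mom, alpha = 0.4))
  expect_lt(abs(got - oracle_nwp(logits, targets, seq_of, mom, 0.4)), 1e-6)
  expect_error(nwp_loss(logits, c(1L, 99L, 2L), seq_of), "vocabulary")
})

test_that("next-property loss sums squared error over known positions only", {
  preds <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(as.numeric(npp_loss(preds, c(1, 2, 3), rep(TRUE, 3),
                                   rep(1L, 3))), 0)
  # all-[UNK] -> 0 regardless of the predictions
  expect_equal(as.numeric(npp_loss(preds, c(9, 9, 9), rep(FALSE, 3),
                                   rep(1L, 3))), 0)
  # residuals (1, -2) on two known positions -> 5
  preds <- matrix(c(2, 0, 100), 3, 1)
  expect_equal(as.numeric(npp_loss(preds, c(1, 2, 0),
                                   c(TRUE, TRUE, FALSE), rep(1L, 3))), 5)
})

test_that("matching loss hits closed forms and matches the oracle", {
  # confident correct head -> 0
  logits <- rbind(c(-1e4, 1e4), c(1e4, -1e4))
  expect_equal(as.numeric(spm_loss(logits, c(1L, 0L))), 0, tolerance = 1e-8)
  # uniform head -> ln 2
  expect_equal(as.numeric(spm_loss(matrix(0, 4, 2), c(1L, 0L, 0L, 1L))),
               log(2), tolerance = 1e-12)
  set.seed(14)
  logits <- matrix(rnorm(8), 4, 2)
  labels <- c(1L, 1L, 0L, 0L)
  expect_lt(abs(as.numeric(spm_loss(logits, labels)) -
                  oracle_spm(logits, labels)), 1e-8)
})

test_that("hard negatives are similarity-proportional and never positive", {
  # batch of 2: the only negative is always chosen
  sim <- matrix(c(0.9, 0.1, 0.4, 0.6), 2, 2, byrow = TRUE)
  set.seed(15)
  for (i in 1:20) expect_identical(select_hard_negatives(sim), c(2L, 1L))
  expect_error(select_hard_negatives(matrix(1, 1, 1)), "at least 2")

  draw_table <- function(sim, n) {
    counts <- matrix(0L, nrow(sim), nrow(sim))
    for (i in seq_len(n)) {
      idx <- select_hard_negatives(sim)
      counts[cbind(seq_len(nrow(sim)), idx)] <- counts[cbind(seq_len(nrow(sim)), idx)] + 1L
    }
    counts
  }
  # uniform similarities -> uniform over negatives (chi-squared, 10k draws)
  set.seed(16)
  B <- 4L
  unif <- matrix(1 / B, B, B)
  counts <- draw_table(unif, 2500L)
  expect_true(all(diag(counts) == 0L))
  for (i in seq_len(B)) {
    p <- stats::chisq.test(counts[i, -i])$p.value
    expect_gt(p, 0.01)
  }
  # a 10x-weighted negative is chosen proportionally more often
  set.seed(17)
  sim <- unif
  sim[1, ] <- c(0.4, 0.5, 0.05, 0.05)   # candidate 2 has 10x the weight of 3/4
  counts <- draw_table(sim, 2500L)
  p <- stats::chisq.test(counts[1, -1], p = sim[1, -1] / sum(sim[1, -1]))$p.value
  expect_gt(p, 0.01)
  expect_gt(counts[1, 2], 5 * counts[1, 3])
})

test_that("EMA follows the closed form for every parameter", {
  cfg <- tiny_config()
  student <- init_model_params(cfg, seed = 20)
  teacher <- lapply(student, function(x) x + 1)
  expect_equal(ema_update(student, teacher, 1), teacher)        # frozen
  expect_equal(ema_update(student, teacher, 0), student)        # copy
  upd <- ema_update(student, teacher, 0.995)
  for (nm in names(student)) {
    expect_equal(upd[[nm]], 0.005 * student[[nm]] + 0.995 * teacher[[nm]],
                 tolerance = 1e-12)
  }
  expect_equal(ema_update(list(w = 0), list(w = 1), 0.995)$w, 0.995)
  bad <- student; bad$tok_emb <- NULL
  expect_error(ema_update(bad, teacher, 0.5), "match")
})

test_that("the feature queue is FIFO with capacity eviction", {
  q <- feature_queue(5, 2)
  queue_push(q, matrix(1:6, 3, 2))        # rows 1..3
  expect_equal(nrow(queue_features(q)), 3)
  queue_push(q, matrix(101:108, 4, 2))    # rows 4..7 -> oldest 2 evicted
  feats <- queue_features(q)
  expect_equal(nrow(feats), 5)
  expect_equal(feats[1, 1], 3)            # row 3 is now oldest
  expect_equal(feats[5, 1], 104)
  # after k + m pushes the m oldest are gone and order is preserved
  q2 <- feature_queue(4, 1)
  for (i in 1:9) queue_push(q2, matrix(i, 1, 1))
  expect_equal(as.numeric(queue_features(q2)), 6:9)
})
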