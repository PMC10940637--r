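# Minimal tape-based reverse-mode automatic differentiation over matrices.
#
# Every op accepts either plain numeric matrices/vectors or `adnode` objects.
# When a tape is active (between ad_begin()/ad_end()) and at least one input
# is a node, the op records itself; otherwise it just computes. This lets the
# same forward code serve training (with gradients) and inference (plain
# arithmetic) without duplication.
#
# Scalars are 1x1 matrices; biases and layer-norm scales are plain numeric
# vectors. Gradients are accumulated by node id during ad_backward().

# The tape is a hashed environment keyed by node id; assigning into an
# environment is O(1), whereas growing a list held in an environment copies
# the list on every insertion.
.ad <- new.env(parent = emptyenv())
.ad$recording <- FALSE
.ad$tape <- NULL
.ad$n <- 0L

#' Start recording an autodiff tape
#' @export
ad_begin <- function() {
  .ad$recording <- TRUE
  .ad$tape <- new.env(hash = TRUE, parent = emptyenv(), size = 8192L)
  .ad$n <- 0L
  invisible(NULL)
}

#' Stop recording and discard the tape
#' @export
ad_end <- function() {
  .ad$recording <- FALSE
  .ad$tape <- NULL
  .ad$n <- 0L
  invisible(NULL)
}

is_adnode <- function(x) inherits(x, "adnode")

#' Numeric value of a node or plain object
#' @param x An `adnode` or numeric object.
#' @return The underlying numeric value.
#' @export
ad_value <- function(x) if (is_adnode(x)) x$val else x

.ad_push <- function(node) {
  n <- .ad$n + 1L
  node$id <- n
  assign(as.character(n), node, envir = .ad$tape)
  .ad$n <- n
  node
}

# Create a recorded node (or return the raw value when not recording /
# no node inputs). `back` maps the output gradient to a list of gradients
# aligned with `parents`; entries for non-node parents are ignored.
.ad_op <- function(val, parents, back) {
  if (.ad$recording && any(vapply(parents, is_adnode, logical(1)))) {
    .ad_push(structure(list(val = val, parents = parents, back = back),
                       class = "adnode"))
  } else {
    val
  }
}

#' Wrap a value as a tape leaf (e.g. a trainable parameter)
#' @param val Numeric matrix or vector.
#' @return An `adnode` if a tape is active, else `val`.
#' @export
ad_leaf <- function(val) {
  if (!.ad$recording) return(val)
  .ad_push(structure(list(val = val, parents = list(), back = NULL),
                     class = "adnode"))
}

#' Backpropagate from a scalar loss node
#'
#' @param loss An `adnode` holding a 1x1 value.
#' @return A list mapping node id -> gradient; index it with [ad_grad()].
#' @export
ad_backward <- function(loss) {
  stopifnot(is_adnode(loss))
  grads <- new.env(hash = TRUE, parent = emptyenv(), size = 8192L)
  assign(as.character(loss$id), matrix(1, 1, 1), envir = grads)
  tape <- .ad$tape
  for (id in seq(loss$id, 1L)) {
    key <- as.character(id)
    g <- grads[[key]]
    if (is.null(g)) next
    node <- tape[[key]]
    if (is.null(node$back)) next
    gs <- node$back(g)
    ps <- node$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (is_adnode(p) && !is.null(gs[[k]])) {
        pk <- as.character(p$id)
        old <- grads[[pk]]
        grads[[pk]] <- if (is.null(old)) gs[[k]] else old + gs[[k]]
      }
    }
  }
  grads
}

#' Gradient of a leaf from an [ad_backward()] result
#' @param grads Result of [ad_backward()].
#' @param node The leaf node.
#' @return Gradient (zero-filled if the leaf never influenced the loss).
#' @export
ad_grad <- function(grads, node) {
  g <- grads[[as.character(node$id)]]
  if (is.null(g)) {
    v <- ad_value(node)
    g <- if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else numeric(length(v))
  }
  g
}

# ---- primitive ops ---------------------------------------------------------

#' Matrix product
#' @param a,b Nodes or matrices.
#' @return Node or matrix.
#' @export
ad_mm <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  .ad_op(av %*% bv, list(a, b),
         function(g) list(g %*% t(bv), t(av) %*% g))
}

#' Transpose
#' @param a Node or matrix.
#' @export
ad_t <- function(a) {
  .ad_op(t(ad_value(a)), list(a), function(g) list(t(g)))
}

#' Elementwise sum of two same-shaped values
#' @param a,b Nodes or matrices.
#' @export
ad_add <- function(a, b) {
  .ad_op(ad_value(a) + ad_value(b), list(a, b), function(g) list(g, g))
}

#' Add a bias vector to every row
#' @param a Node or matrix; `v` node or vector of length `ncol(a)`.
#' @param v Bias.
#' @export
ad_add_vec <- function(a, v) {
  av <- ad_value(a); vv <- ad_value(v)
  .ad_op(sweep(av, 2L, vv, "+"), list(a, v),
         function(g) list(g, colSums(g)))
}

#' Negation
#' @param a Node or matrix.
#' @export
ad_neg <- function(a) {
  .ad_op(-ad_value(a), list(a), function(g) list(-g))
}

#' Elementwise (Hadamard) product
#' @param a,b Nodes or matrices (same shape).
#' @export
ad_hprod <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  .ad_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' Multiply by a plain numeric constant
#' @param a Node or matrix; `k` numeric scalar.
#' @param k Constant.
#' @export
ad_cmul <- function(a, k) {
  .ad_op(ad_value(a) * k, list(a), function(g) list(g * k))
}

#' Elementwise product with a constant array (no gradient through `C`)
#' @param a Node or matrix; `C` conformable numeric constant.
#' @param C Constant multiplier.
#' @export
ad_mul_const <- function(a, C) {
  .ad_op(ad_value(a) * C, list(a), function(g) list(g * C))
}

#' Multiply a matrix by a scalar node (1x1)
#' @param a Node or matrix; `s` scalar node or number.
#' @param s Scalar.
#' @export
ad_smul <- function(a, s) {
  av <- ad_value(a); sv <- as.numeric(ad_value(s))
  .ad_op(av * sv, list(a, s),
         function(g) list(g * sv, matrix(sum(g * av), 1, 1)))
}

#' Reciprocal of a scalar (1x1)
#' @param s Scalar node or number.
#' @export
ad_sinv <- function(s) {
  sv <- as.numeric(ad_value(s))
  .ad_op(matrix(1 / sv, 1, 1), list(s),
         function(g) list(matrix(-as.numeric(g) / sv^2, 1, 1)))
}

#' Sum of all elements (1x1 result)
#' @param a Node or matrix.
#' @export
ad_sum <- function(a) {
  av <- ad_value(a)
  .ad_op(matrix(sum(av), 1, 1), list(a),
         function(g) {
           gk <- as.numeric(g)
           list(if (is.matrix(av)) matrix(gk, nrow(av), ncol(av))
                else rep(gk, length(av)))
         })
}

#' Mean of all elements (1x1 result)
#' @param a Node or matrix.
#' @export
ad_mean <- function(a) ad_cmul(ad_sum(a), 1 / length(ad_value(a)))

#' Gather rows by index (with scatter-add backward)
#' @param a Node or matrix; `idx` integer vector (repeats allowed).
#' @param idx Row indices.
#' @export
ad_rows <- function(a, idx) {
  av <- ad_value(a)
  .ad_op(av[idx, , drop = FALSE], list(a),
         function(g) {
           ga <- matrix(0, nrow(av), ncol(av))
           acc <- rowsum(g, group = idx)
           ga[as.integer(rownames(acc)), ] <- acc
           list(ga)
         })
}

#' Slice columns
#' @param a Node or matrix; `idx` integer vector of column positions.
#' @param idx Column indices.
#' @export
ad_cols <- function(a, idx) {
  av <- ad_value(a)
  .ad_op(av[, idx, drop = FALSE], list(a),
         function(g) {
           ga <- matrix(0, nrow(av), ncol(av))
           for (k in seq_along(idx)) {   # accumulate duplicated columns
             ga[, idx[k]] <- ga[, idx[k]] + g[, k]
           }
           list(ga)
         })
}

#' Stack two matrices by rows
#' @param a,b Nodes or matrices with equal column counts.
#' @export
ad_rbind2 <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  na <- nrow(av)
  .ad_op(rbind(av, bv), list(a, b),
         function(g) list(g[seq_len(na), , drop = FALSE],
                          g[-seq_len(na), , drop = FALSE]))
}

#' Concatenate a list of matrices by columns
#' @param lst List of nodes/matrices with equal row counts.
#' @export
ad_cbind_list <- function(lst) {
  vals <- lapply(lst, ad_value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  .ad_op(do.call(cbind, vals), lst,
         function(g) lapply(seq_along(lst), function(k) {
           g[, starts[k]:ends[k], drop = FALSE]
         }))
}

#' Row-wise softmax with an optional additive mask
#'
#' @param a Node or matrix of scores; `mask` constant matrix added before the
#'   softmax (use large negative entries, e.g. -1e30, to forbid positions).
#' @param mask Optional additive mask.
#' @export
ad_softmax_rows <- function(a, mask = NULL) {
  x <- ad_value(a)
  if (!is.null(mask)) x <- x + mask
  m <- matrixStats::rowMaxs(x)
  e <- exp(x - m)
  p <- e / rowSums(e)
  .ad_op(p, list(a),
         function(g) list(p * (g - rowSums(g * p))))
}

#' Row-wise log-softmax with an optional additive mask
#' @inheritParams ad_softmax_rows
#' @export
ad_logsoftmax_rows <- function(a, mask = NULL) {
  x <- ad_value(a)
  if (!is.null(mask)) x <- x + mask
  m <- matrixStats::rowMaxs(x)
  lse <- m + log(rowSums(exp(x - m)))
  lp <- x - lse
  .ad_op(lp, list(a),
         function(g) list(g - exp(lp) * rowSums(g)))
}

#' Elementwise natural log
#' @param a Node or matrix with positive entries.
#' @export
ad_log <- function(a) {
  av <- ad_value(a)
  .ad_op(log(av), list(a), function(g) list(g / av))
}

#' Row-wise layer normalization with learned scale and shift
#'
#' @param a Node or matrix (rows are normalized independently).
#' @param gamma,beta Scale/shift vectors of length `ncol(a)`.
#' @param eps Variance floor.
#' @export
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- ad_value(a); gv <- ad_value(gamma); bv <- ad_value(beta)
  mu <- rowMeans(x)
  xc <- x - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / sd_
  val <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  .ad_op(val, list(a, gamma, beta),
         function(g) {
           dxhat <- sweep(g, 2L, gv, "*")
           dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd_
           list(dx, colSums(g * xhat), colSums(g))
         })
}

#' Gaussian error linear unit, x * pnorm(x)
#' @param a Node or matrix.
#' @export
ad_gelu <- function(a) {
  x <- ad_value(a)
  Phi <- stats::pnorm(x)
  .ad_op(x * Phi, list(a),
         function(g) list(g * (Phi + x * stats::dnorm(x))))
}

#' L2-normalize each row
#' @param a Node or matrix.
#' @param eps Norm floor; rows with norm below `eps` raise an error.
#' @export
ad_l2norm_rows <- function(a, eps = 1e-12) {
  x <- ad_value(a)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm < eps)) stop("cannot L2-normalize a zero-norm row")
  y <- x / nrm
  .ad_op(y, list(a),
         function(g) list((g - y * rowSums(g * y)) / nrm))
}
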