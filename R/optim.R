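# AdamW optimizer, learning-rate and pseudo-label schedules.

#' Create AdamW optimizer state
#'
#' @param params Parameter list (names/shapes are frozen here).
#' @param beta1,beta2 Moment decay rates.
#' @param eps Denominator floor.
#' @return An `adamw` state object.
#' @export
adamw_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(params, function(x) x * 0)
  structure(list(m = zeros, v = zeros, t = 0L,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adamw")
}

#' One AdamW update (with global-norm gradient clipping)
#'
#' Decoupled weight decay is applied to weight matrices only (embeddings and
#' projection/attention/feed-forward weights), not to biases, layer-norm
#' scales, or the temperature.
#'
#' @param opt An `adamw` state.
#' @param params Parameter list.
#' @param grads Named list of gradients (missing names are treated as zero).
#' @param lr Learning rate for this step.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param clip Global gradient-norm clip (Inf disables).
#' @return List with updated `params` and `opt`.
#' @export
adamw_step <- function(opt, params, grads, lr, weight_decay = 0.02,
                       clip = 5) {
  stopifnot(inherits(opt, "adamw"))
  gnorm2 <- 0
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (!is.null(g)) gnorm2 <- gnorm2 + sum(g^2)
  }
  scale <- if (is.finite(clip) && sqrt(gnorm2) > clip) clip / sqrt(gnorm2) else 1
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) g <- params[[nm]] * 0
    g <- g * scale
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    upd <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
    decay <- if (is.matrix(params[[nm]]) && nm != "tau") weight_decay else 0
    params[[nm]] <- params[[nm]] - lr * (upd + decay * params[[nm]])
  }
  list(params = params, opt = opt)
}

#' Warmup-then-cosine learning-rate schedule
#'
#' Linear warmup from 0 to `peak` over `warmup_steps`, then cosine decay to
#' `end` at `total_steps`.
#'
#' @param step 1-based step index.
#' @param warmup_steps,total_steps Schedule breakpoints.
#' @param peak,end Peak and final learning rates.
#' @return Learning rate.
#' @export
lr_at <- function(step, warmup_steps, total_steps, peak = 1e-4, end = 1e-5) {
  stopifnot(step >= 1, total_steps >= warmup_steps)
  if (step <= warmup_steps) {
    return(peak * step / warmup_steps)
  }
  if (step >= total_steps) return(end)
  t <- (step - warmup_steps) / (total_steps - warmup_steps)
  end + (peak - end) * 0.5 * (1 + cos(pi * t))
}

#' Pseudo-label mixing schedule
#'
#' alpha ramps linearly from 0 (step 1) to `target` across the first
#' `ramp_steps` optimizer steps (one epoch), then stays constant.
#'
#' @param step 1-based step index.
#' @param ramp_steps Length of the ramp.
#' @param target Final mixing weight.
#' @return alpha for this step.
#' @export
alpha_at <- function(step, ramp_steps, target = 0.4) {
  stopifnot(step >= 1)
  min(target, target * (step - 1) / max(1, ramp_steps))
}

#' Pre-training schedule
#'
#' Defaults follow the reference recipe: batch 96, AdamW with weight decay
#' 0.02, warmup to 1e-4 with cosine decay to 1e-5, alpha ramped to 0.4 over
#' the first epoch, EMA lambda 0.995, 50% property masking, queue capacity
#' 24576.
#'
#' @param total_steps Number of optimizer steps.
#' @param batch_size Molecules per step.
#' @param warmup_steps Warmup length (default 10% of total).
#' @param alpha_ramp_steps Ramp length for alpha (default: one epoch).
#' @param lr_peak,lr_end,weight_decay,alpha_target,lambda,mask_rate
#'   Optimizer and objective hyperparameters.
#' @param queue_capacity Contrastive feature-queue capacity.
#' @param grad_clip Global gradient-norm clip.
#' @param tau_init,tau_min,tau_max Initial and clamp range for the learnable
#'   contrastive temperature.
#' @return A `pretrain_schedule` list.
#' @export
pretrain_schedule <- function(total_steps, batch_size = 96L,
                              warmup_steps = max(1L, round(total_steps / 10)),
                              alpha_ramp_steps = NULL,
                              lr_peak = 1e-4, lr_end = 1e-5,
                              weight_decay = 0.02, alpha_target = 0.4,
                              lambda = 0.995, mask_rate = 0.5,
                              queue_capacity = 24576L, grad_clip = 5,
                              tau_init = 0.07, tau_min = 1e-3, tau_max = 0.5) {
  stopifnot(total_steps >= 1, batch_size >= 2, lambda >= 0, lambda <= 1,
            mask_rate >= 0, mask_rate <= 1)
  structure(list(total_steps = as.integer(total_steps),
                 batch_size = as.integer(batch_size),
                 warmup_steps = as.integer(warmup_steps),
                 alpha_ramp_steps = alpha_ramp_steps,
                 lr_peak = lr_peak, lr_end = lr_end,
                 weight_decay = weight_decay, alpha_target = alpha_target,
                 lambda = lambda, mask_rate = mask_rate,
                 queue_capacity = as.integer(queue_capacity),
                 grad_clip = grad_clip, tau_init = tau_init,
                 tau_min = tau_min, tau_max = tau_max),
            class = "pretrain_schedule")
}
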