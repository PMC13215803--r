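#' Named hyperparameter profiles
#'
#' Two profiles ship with the package: `"defaults"` (AdamW, learning rate
#' 3e-4, weight decay 1e-4, batch 128, no label smoothing) and
#' `"exp1a-optimized"` (the independently optimized categorization profile:
#' learning rate ~3e-3, weight decay ~4e-4 for the cortical baseline and
#' ~3.1e-3 / 4.1e-3 for the pulvinar variant, label smoothing 0.18, and the
#' gate/fusion regularizer settings lambda_G = 0.01, lambda_alpha = 2e-4,
#' G* = 1.65).
#'
#' @param name Profile name.
#' @param variant Model variant (the optimized profile differs per variant).
#' @return A list of training hyperparameters.
#' @export
train_profile <- function(name = c("defaults", "exp1a-optimized"),
                          variant = "cortical") {
  name <- match.arg(name)
  if (name == "defaults") {
    list(profile_name = name, learning_rate = 3e-4, weight_decay = 1e-4,
         label_smoothing = 0, batch_size = 128L,
         lambda_G = 0, lambda_alpha = 0, G_target = 1.65)
  } else if (variant == "pulvinar") {
    list(profile_name = name, learning_rate = 3.1e-3, weight_decay = 4.1e-3,
         label_smoothing = 0.18, batch_size = 128L,
         lambda_G = 0.01, lambda_alpha = 2e-4, G_target = 1.65)
  } else {
    list(profile_name = name, learning_rate = 3e-3, weight_decay = 4e-4,
         label_smoothing = 0.18, batch_size = 128L,
         lambda_G = 0, lambda_alpha = 0, G_target = 1.65)
  }
}

#' Training configuration
#'
#' @param learning_rate AdamW step size (> 0).
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param label_smoothing Label smoothing in `[0, 1)`.
#' @param batch_size Mini-batch size (>= 1).
#' @param n_epochs Number of passes over the training set.
#' @param seed Seed controlling shuffling (data/parameter seeds are separate).
#' @param augment_flip,augment_crop Augmentation flags (horizontal flip and
#'   pad-4-then-random-crop); intended for categorization data only, never for
#'   detection stimuli.
#' @param normalize Standardize inputs by training-set channel statistics
#'   (mean and standard deviation, stored with the parameters and applied
#'   inside the forward pass).
#' @param profile_name Free-text provenance label.
#' @return Object of class `pv_train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, weight_decay = 1e-4,
                         label_smoothing = 0, batch_size = 128L,
                         n_epochs = 20L, seed = 1L, augment_flip = FALSE,
                         augment_crop = FALSE, normalize = TRUE,
                         profile_name = "custom") {
  if (learning_rate <= 0) stop("invalid config: learning_rate must be > 0", call. = FALSE)
  if (batch_size < 1) stop("invalid config: batch_size must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 label_smoothing = label_smoothing,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed),
                 augment_flip = isTRUE(augment_flip),
                 augment_crop = isTRUE(augment_crop),
                 normalize = isTRUE(normalize),
                 optimizer = "adamw", profile_name = profile_name),
            class = "pv_train_config")
}

## ---- AdamW ------------------------------------------------------------

.adamw_init <- function(params) {
  list(m = lapply(unclass(params), function(p) p * 0),
       v = lapply(unclass(params), function(p) p * 0), t = 0L)
}

## Decoupled weight decay: biases, gains and fusion logits are not decayed.
.decayed <- function(name) !grepl("_b$|_b[12]$|alpha_logit", name)

.adamw_step <- function(params, grads, state, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    p <- params[[nm]] - step
    if (wd > 0 && .decayed(nm)) p <- p - lr * wd * params[[nm]]
    params[[nm]] <- p
  }
  list(params = params, state = state)
}

## ---- data helpers ------------------------------------------------------

.augment_batch <- function(x, flip, crop) {
  d <- dim(x)
  if (flip) {
    do_flip <- stats::runif(d[4]) < 0.5
    if (any(do_flip)) x[, , , do_flip] <- x[d[1]:1, , , do_flip, drop = FALSE]
  }
  if (crop) {
    pad <- 4L
    for (n in seq_len(d[4])) {
      dx <- sample(-pad:pad, 1L); dy <- sample(-pad:pad, 1L)
      if (dx == 0 && dy == 0) next
      src <- x[, , , n]
      out <- array(0, d[1:3])
      rs <- max(1, 1 + dy):min(d[1], d[1] + dy)
      cs <- max(1, 1 + dx):min(d[2], d[2] + dx)
      out[rs, cs, ] <- src[rs - dy, cs - dx, ]
      x[, , , n] <- out
    }
  }
  x
}

## ---- core training loop ------------------------------------------------

#' Train a model variant
#'
#' Runs seeded AdamW optimization under one of three loss regimes: `"CE"`
#' (plain cross-entropy), `"SH"` (cross-entropy minus the weighted S and HL
#' representational terms computed on the contrast-perturbation set of each
#' mini-batch), or `"full"` (adds the gate and fusion regularizers; requires a
#' gated variant).  Deterministic given the configuration seeds.
#'
#' @param variant_config A [model_config()].
#' @param tc A [train_config()].
#' @param data List with `x` (H x W x 3 x N input array) and `y` (integer
#'   labels 1..K).
#' @param regime Loss regime.
#' @param weights A [loss_weights()]; label smoothing is taken from `tc`.
#' @param sigmas Contrast scale factors for the S/HL terms (must contain 1.0).
#' @param test_data Optional held-out list like `data` for per-epoch metrics.
#' @param params Optional initial parameters (default [init_params()]).
#' @param verbose Print per-epoch log lines.
#' @return List with `params` (trained) and `record` (a `pv_run_record`:
#'   config snapshots, per-epoch history, final S/HL/accuracy).
#' @export
train_model <- function(variant_config, tc, data, regime = c("CE", "SH", "full"),
                        weights = loss_weights(), sigmas = c(0.2, 0.6, 1.0),
                        test_data = NULL, params = NULL, verbose = FALSE) {
  regime <- match.arg(regime)
  stopifnot(inherits(variant_config, "pv_model_config"),
            inherits(tc, "pv_train_config"))
  if (regime == "full" && variant_config$variant != "pulvinar")
    stop("configuration error: full regime requires the gated pulvinar variant",
         call. = FALSE)
  if (regime != "CE" && !any(sigmas == 1))
    stop("invalid config: sigmas must include 1.0", call. = FALSE)
  N <- length(data$y)
  if (N == 0) stop("invalid config: empty training data", call. = FALSE)
  if (is.null(params)) params <- init_params(variant_config)
  if (isTRUE(tc$normalize) && is.null(params$input_mu)) {
    params$input_mu <- mean(data$x)
    params$input_sd <- max(stats::sd(as.vector(data$x)), 1e-8)
  }
  state <- .adamw_init(params)
  history <- data.frame(epoch = seq_len(tc$n_epochs), train_loss = NA_real_,
                        train_acc = NA_real_, test_loss = NA_real_,
                        test_acc = NA_real_)
  set.seed(tc$seed)
  for (epoch in seq_len(tc$n_epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, N, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, N)]
      xb <- data$x[, , , idx, drop = FALSE]
      yb <- data$y[idx]
      if (tc$augment_flip || tc$augment_crop)
        xb <- .augment_batch(xb, tc$augment_flip, tc$augment_crop)
      res <- .loss_and_grads(variant_config, params, xb, yb, regime, weights,
                             sigmas, tc$label_smoothing)
      if (!is.finite(res$loss))
        stop(sprintf("divergence: non-finite loss at epoch %d (batch starting %d)",
                     epoch, start), call. = FALSE)
      ep_loss <- ep_loss + res$loss * length(idx)
      ep_correct <- ep_correct + sum(res$pred == yb)
      upd <- .adamw_step(params, res$grads, state, tc$learning_rate,
                         tc$weight_decay)
      params <- upd$params; state <- upd$state
      if (variant_config$variant == "pulvinar") {
        a <- .sigmoid(params$alpha_logit)
        stopifnot(all(a > 0 & a < 1))
      }
    }
    history$train_loss[epoch] <- ep_loss / N
    history$train_acc[epoch] <- ep_correct / N
    if (!is.null(test_data)) {
      ev <- .evaluate(variant_config, params, test_data, tc$label_smoothing)
      history$test_loss[epoch] <- ev$loss
      history$test_acc[epoch] <- ev$acc
    }
    if (verbose)
      message(sprintf("[%s/%s] epoch %d/%d loss %.4f acc %.3f%s",
                      variant_config$variant, regime, epoch, tc$n_epochs,
                      history$train_loss[epoch], history$train_acc[epoch],
                      if (!is.null(test_data))
                        sprintf(" test_acc %.3f", history$test_acc[epoch]) else ""))
  }
  eval_data <- if (!is.null(test_data)) test_data else data
  mets <- model_metrics(variant_config, params, eval_data$x, sigmas)
  record <- structure(list(
    variant = variant_config$variant, regime = regime,
    model_config = variant_config, train_config = tc, weights = weights,
    history = history, S = mets$S, HL = mets$HL,
    accuracy = evaluate_accuracy(variant_config, params, eval_data),
    seed = tc$seed), class = "pv_run_record")
  list(params = params, record = record)
}

## Loss + parameter gradients for one mini-batch under a regime.
.loss_and_grads <- function(config, params, xb, yb, regime, weights, sigmas,
                            label_smoothing) {
  if (regime == "CE") {
    fw <- forward_variant(config, params, xb, keep_cache = TRUE)
    loss <- cross_entropy_loss(fw$probs, yb, label_smoothing)
    dz <- .ce_grad_logits(fw$probs, yb, label_smoothing)
    grads <- .backward_variant(config, params, fw$cache, dz)
    return(list(loss = loss, grads = grads,
                pred = max.col(fw$probs, ties.method = "first")))
  }
  ## SH / full: forward every contrast-scaled copy, keep caches
  ks <- order(sigmas)
  fws <- vector("list", length(sigmas))
  for (k in seq_along(sigmas))
    fws[[k]] <- forward_variant(config, params, xb * sigmas[k], keep_cache = TRUE)
  bank <- feature_bank(sigmas[ks], lapply(fws[ks], function(f) f$pooled))
  k1 <- which(sigmas == 1)[1]
  loss <- cross_entropy_loss(fws[[k1]]$probs, yb, label_smoothing)
  Sval <- suppressWarnings(direction_invariance_S(bank))
  HLval <- gain_linearity_HL(bank)
  loss <- loss - weights$lambda_S * as.numeric(Sval) - weights$lambda_H * HLval
  dS <- .S_grad(bank)
  dHL <- .HL_grad(bank)
  dgate <- NULL
  if (regime == "full") {
    gmat <- fws[[k1]]$cache$pulv$g
    alpha <- fws[[k1]]$cache$pulv$alpha
    loss <- loss + weights$lambda_G * gate_regularizer(gmat, weights$G_target) +
      weights$lambda_alpha * alpha_regularizer(alpha, weights$alpha_target)
    dgate <- matrix(weights$lambda_G * 2 * (mean(gmat) - weights$G_target) /
                      length(gmat), nrow(gmat), ncol(gmat))
  }
  grads <- NULL
  for (k in seq_along(sigmas)) {
    pos <- match(k, ks)  # position of copy k inside the ordered bank
    du <- -weights$lambda_S * dS[[pos]] - weights$lambda_H * dHL[[pos]]
    dz <- if (k == k1) .ce_grad_logits(fws[[k]]$probs, yb, label_smoothing) else
      matrix(0, nrow(fws[[k]]$probs), ncol(fws[[k]]$probs))
    gk <- .backward_variant(config, params, fws[[k]]$cache, dz, dpooled = du,
                            dgate = if (k == k1) dgate else NULL)
    grads <- if (is.null(grads)) gk else
      stats::setNames(lapply(names(gk), function(nm) grads[[nm]] + gk[[nm]]),
                      names(gk))
  }
  if (regime == "full" && weights$lambda_alpha > 0) {
    alpha <- fws[[k1]]$cache$pulv$alpha
    da <- weights$lambda_alpha * 2 * (alpha - weights$alpha_target) / length(alpha)
    grads$alpha_logit <- grads$alpha_logit + da * alpha * (1 - alpha)
  }
  list(loss = loss, grads = grads,
       pred = max.col(fws[[k1]]$probs, ties.method = "first"))
}

## Batched evaluation (loss + accuracy) without caches.
.evaluate <- function(config, params, data, label_smoothing = 0,
                      chunk = 256L) {
  N <- length(data$y)
  loss <- 0; correct <- 0
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    fw <- forward_variant(config, params, data$x[, , , idx, drop = FALSE])
    loss <- loss + cross_entropy_loss(fw$probs, data$y[idx], label_smoothing) *
      length(idx)
    correct <- correct + sum(max.col(fw$probs, ties.method = "first") == data$y[idx])
  }
  list(loss = loss / N, acc = correct / N)
}

#' Predicted classes and present-class scores
#'
#' @param config,params Model configuration and parameters.
#' @param x Input batch.
#' @param chunk Evaluation chunk size.
#' @return List with `pred` (argmax class, ties broken toward the lowest
#'   index), `probs`, and `taps` (per-image layer summaries, concatenated
#'   across chunks).
#' @export
predict_variant <- function(config, params, x, chunk = 256L) {
  x <- .as_batch(x)
  N <- dim(x)[4]
  probs <- NULL; v1 <- v4 <- pfc <- numeric(0)
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    fw <- forward_variant(config, params, x[, , , idx, drop = FALSE])
    probs <- rbind(probs, fw$probs)
    v1 <- c(v1, fw$taps$v1); v4 <- c(v4, fw$taps$v4); pfc <- c(pfc, fw$taps$pfc)
  }
  list(pred = max.col(probs, ties.method = "first"), probs = probs,
       taps = list(v1 = v1, v4 = v4, pfc = pfc))
}

#' Classification accuracy on labeled data
#'
#' Argmax accuracy with ties broken toward the lowest class index.
#'
#' @param config,params Model configuration and parameters.
#' @param data List with `x` and `y`.
#' @return Fraction correct in `[0, 1]`.
#' @export
evaluate_accuracy <- function(config, params, data) {
  .evaluate(config, params, data)$acc
}

#' Representational metrics of a trained model
#'
#' Computes S and HL from the pooled features of the model on the
#' contrast-perturbation set built from `x`.
#'
#' @param config,params Model configuration and parameters.
#' @param x Evaluation image batch.
#' @param sigmas Contrast scale factors.
#' @param eps HL clamp floor.
#' @param chunk Evaluation chunk size.
#' @return List with `S` and `HL`.
#' @export
model_metrics <- function(config, params, x, sigmas = c(0.2, 0.6, 1.0),
                          eps = 1e-6, chunk = 256L) {
  x <- .as_batch(x)
  N <- dim(x)[4]
  feats <- lapply(sigmas, function(s) NULL)
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1L, N)
    for (k in seq_along(sigmas)) {
      fw <- forward_variant(config, params,
                            x[, , , idx, drop = FALSE] * sigmas[k])
      feats[[k]] <- rbind(feats[[k]], fw$pooled)
    }
  }
  bank <- feature_bank(sigmas, feats)
  list(S = as.numeric(suppressWarnings(direction_invariance_S(bank))),
       HL = gain_linearity_HL(bank, eps))
}

#' Filter runs to a matched representational regime
#'
#' Retains runs whose final S lies strictly inside `S_range` and final HL
#' strictly inside `HL_range` (defaults: S in (0.97, 0.99), HL in (4.5, 5.5)).
#'
#' @param runs List of `pv_run_record` objects (each with final `S`, `HL`).
#' @param S_range,HL_range Open intervals `(lo, hi)`.
#' @return The retained sublist (empty, with a warning, if none qualify).
#' @export
matched_regime_filter <- function(runs, S_range = c(0.97, 0.99),
                                  HL_range = c(4.5, 5.5)) {
  keep <- vapply(runs, function(r)
    r$S > S_range[1] && r$S < S_range[2] &&
      r$HL > HL_range[1] && r$HL < HL_range[2], TRUE)
  out <- runs[keep]
  if (length(out) == 0 && length(runs) > 0)
    warning("matched-regime filter retained no runs")
  out
}

#' Shared (S, HL) overlap box across model groups
#'
#' Computes, for each model's runs, the axis-aligned (S, HL) bounding box and
#' returns the intersection — the matched representational region in which all
#' groups have support.
#'
#' @param runs List of `pv_run_record` objects.
#' @return List with `S_range` and `HL_range` (may be degenerate if the groups
#'   do not overlap).
#' @export
regime_overlap_box <- function(runs) {
  variants <- vapply(runs, function(r) r$variant, "")
  S_lo <- HL_lo <- -Inf; S_hi <- HL_hi <- Inf
  for (v in unique(variants)) {
    Ss <- vapply(runs[variants == v], function(r) r$S, 1.0)
    Hs <- vapply(runs[variants == v], function(r) r$HL, 1.0)
    S_lo <- max(S_lo, min(Ss)); S_hi <- min(S_hi, max(Ss))
    HL_lo <- max(HL_lo, min(Hs)); HL_hi <- min(HL_hi, max(Hs))
  }
  list(S_range = c(S_lo, S_hi), HL_range = c(HL_lo, HL_hi))
}
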