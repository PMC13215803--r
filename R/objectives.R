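#' Feature bank across contrast levels
#'
#' Collects the pooled feature vectors `u_i^(k)` of the same `N` images at
#' each contrast scale `sigma_k`, as produced by [forward_variant()] on a
#' [contrast_scale_batch()].
#'
#' @param sigmas Ordered contrast scale factors.
#' @param features List (one element per sigma) of N x D feature matrices.
#' @return Object of class `pv_feature_bank`.
#' @export
feature_bank <- function(sigmas, features) {
  if (length(sigmas) != length(features))
    stop("invalid config: one feature matrix per sigma required", call. = FALSE)
  ns <- vapply(features, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("invalid config: inconsistent image count across levels", call. = FALSE)
  structure(list(sigmas = sigmas, features = features), class = "pv_feature_bank")
}

#' Cross-entropy loss with label smoothing
#'
#' Mean negative log-likelihood of the smoothed targets
#' `(1 - ls) * onehot + ls / K`.  Probabilities of the true class are floored
#' at 1e-12 before the log.  Weight decay is not part of this term; it is
#' applied by the optimizer (decoupled, AdamW semantics).
#'
#' @param probs N x K matrix of predicted probabilities (rows sum to 1).
#' @param labels Integer class labels in 1..K.
#' @param label_smoothing Smoothing mass in `[0, 1)`.
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(probs, labels, label_smoothing = 0) {
  K <- ncol(probs); N <- nrow(probs)
  y <- matrix(label_smoothing / K, N, K)
  y[cbind(seq_len(N), labels)] <- y[cbind(seq_len(N), labels)] + (1 - label_smoothing)
  -mean(rowSums(y * log(pmax(probs, 1e-12))))
}

## Gradient of the cross-entropy w.r.t. the logits (softmax folded in).
.ce_grad_logits <- function(probs, labels, label_smoothing = 0) {
  K <- ncol(probs); N <- nrow(probs)
  y <- matrix(label_smoothing / K, N, K)
  y[cbind(seq_len(N), labels)] <- y[cbind(seq_len(N), labels)] + (1 - label_smoothing)
  (probs - y) / N
}

#' Direction invariance across contrast (S)
#'
#' Mean, over all contrast-level pairs `(a, b)` with `a < b`, of the per-image
#' mean cosine similarity between the pooled feature vectors at the two
#' levels.  Invariant to positive rescaling of any feature vector.  Images
#' with a zero-norm vector at either level of a pair are excluded from that
#' pair with a warning; the exclusion count is attached as attribute
#' `n_excluded`.
#'
#' @param bank A [feature_bank()] with at least two levels.
#' @return Scalar S in `[-1, 1]`.
#' @export
direction_invariance_S <- function(bank) {
  stopifnot(inherits(bank, "pv_feature_bank"))
  K <- length(bank$sigmas)
  if (K < 2) stop("invalid config: S requires at least two contrast levels", call. = FALSE)
  norms <- lapply(bank$features, function(u) sqrt(rowSums(u * u)))
  total <- 0; n_pairs <- 0L; n_excl <- 0L
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ok <- norms[[a]] > 0 & norms[[b]] > 0
    n_excl <- n_excl + sum(!ok)
    if (!any(ok)) {
      warning("all feature vectors zero-norm for a contrast pair; pair skipped")
      next
    }
    cs <- rowSums(bank$features[[a]][ok, , drop = FALSE] *
                  bank$features[[b]][ok, , drop = FALSE]) /
      (norms[[a]][ok] * norms[[b]][ok])
    total <- total + mean(cs)
    n_pairs <- n_pairs + 1L
  }
  if (n_excl > 0) warning(sprintf("%d zero-norm feature vectors excluded from S", n_excl))
  out <- total / n_pairs
  attr(out, "n_excluded") <- n_excl
  out
}

## Gradients of S w.r.t. every feature matrix in the bank.
.S_grad <- function(bank) {
  K <- length(bank$sigmas)
  norms <- lapply(bank$features, function(u) sqrt(rowSums(u * u)))
  grads <- lapply(bank$features, function(u) u * 0)
  n_pairs <- K * (K - 1) / 2
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ok <- norms[[a]] > 0 & norms[[b]] > 0
    n_ok <- sum(ok)
    if (n_ok == 0) next
    ua <- bank$features[[a]][ok, , drop = FALSE]
    ub <- bank$features[[b]][ok, , drop = FALSE]
    na <- norms[[a]][ok]; nb <- norms[[b]][ok]
    dot <- rowSums(ua * ub)
    cs <- dot / (na * nb)
    w <- 1 / (n_pairs * n_ok)
    grads[[a]][ok, ] <- grads[[a]][ok, ] +
      w * (ub / (na * nb) - ua * (cs / na^2))
    grads[[b]][ok, ] <- grads[[b]][ok, ] +
      w * (ua / (na * nb) - ub * (cs / nb^2))
  }
  grads
}

#' Gain-linearity index (HL)
#'
#' Computes the mean feature norm per contrast level,
#' `F(sigma_k) = mean_i ||u_i^(k)||`, then the mean over adjacent levels of
#' the log finite-difference slope, clamped below at `eps`:
#' `HL = mean_k log(max(eps, (F_{k+1} - F_k) / (sigma_{k+1} - sigma_k)))`.
#' Natural logarithm throughout; constant or decreasing norms give
#' `HL = log(eps)`.
#'
#' @param bank A [feature_bank()] with strictly increasing sigmas.
#' @param eps Positive clamp floor (default 1e-6).
#' @return Scalar HL (>= `log(eps)`).
#' @export
gain_linearity_HL <- function(bank, eps = 1e-6) {
  stopifnot(inherits(bank, "pv_feature_bank"))
  K <- length(bank$sigmas)
  if (K < 2) stop("invalid config: HL requires at least two contrast levels", call. = FALSE)
  if (any(diff(bank$sigmas) <= 0))
    stop("invalid config: sigmas must be strictly increasing", call. = FALSE)
  Fv <- vapply(bank$features, function(u) mean(sqrt(rowSums(u * u))), 1.0)
  slopes <- diff(Fv) / diff(bank$sigmas)
  mean(log(pmax(eps, slopes)))
}

## Gradients of HL w.r.t. every feature matrix (subgradient 0 at the clamp).
.HL_grad <- function(bank, eps = 1e-6) {
  K <- length(bank$sigmas)
  Fv <- vapply(bank$features, function(u) mean(sqrt(rowSums(u * u))), 1.0)
  dsig <- diff(bank$sigmas)
  slopes <- diff(Fv) / dsig
  dF <- numeric(K)
  for (k in seq_len(K - 1)) {
    if (slopes[k] > eps) {
      coef <- 1 / ((K - 1) * slopes[k] * dsig[k])
      dF[k + 1] <- dF[k + 1] + coef
      dF[k] <- dF[k] - coef
    }
  }
  lapply(seq_len(K), function(k) {
    u <- bank$features[[k]]
    nu <- sqrt(rowSums(u * u))
    scale <- ifelse(nu > 0, dF[k] / (nrow(u) * nu), 0)
    u * scale
  })
}

#' Gate and fusion regularizers
#'
#' `gate_regularizer` penalizes the squared deviation of the mean gate gain
#' from the target level `G*`; `alpha_regularizer` the mean squared deviation
#' of the per-channel fusion weights from `alpha_target`.
#'
#' @param g Matrix (or vector) of gate gains in (0, 1).
#' @param G_target Target mean gain `G*`.
#' @return Scalar penalty.
#' @export
gate_regularizer <- function(g, G_target) (mean(g) - G_target)^2

#' @rdname gate_regularizer
#' @param alpha Per-channel fusion weights in (0, 1).
#' @param alpha_target Target fusion weight `alpha*`.
#' @export
alpha_regularizer <- function(alpha, alpha_target) mean((alpha - alpha_target)^2)

#' Loss weights and targets for the composite objectives
#'
#' @param lambda_wd Weight-decay coefficient (handled by the optimizer).
#' @param lambda_S,lambda_H Weights of the S and HL representational terms.
#' @param lambda_G,lambda_alpha Weights of the gate and fusion regularizers.
#' @param G_target Target mean gate gain `G*`.  The printed profile value 1.65
#'   exceeds the reachable (0, 1) gate range and acts as an unreachable target
#'   pressing the gains toward 1.
#' @param alpha_target Target fusion weight (default 0.9, a high-fusion
#'   regime).
#' @param label_smoothing Label smoothing in `[0, 1)`.
#' @return Object of class `pv_loss_weights`.
#' @export
loss_weights <- function(lambda_wd = 1e-4, lambda_S = 0.1, lambda_H = 0.1,
                         lambda_G = 0, lambda_alpha = 0, G_target = 1.65,
                         alpha_target = 0.9, label_smoothing = 0) {
  vals <- c(lambda_wd, lambda_S, lambda_H, lambda_G, lambda_alpha)
  if (any(vals < 0)) stop("invalid config: negative loss weight", call. = FALSE)
  if (label_smoothing < 0 || label_smoothing >= 1)
    stop("invalid config: label_smoothing must be in [0, 1)", call. = FALSE)
  structure(list(lambda_wd = lambda_wd, lambda_S = lambda_S,
                 lambda_H = lambda_H, lambda_G = lambda_G,
                 lambda_alpha = lambda_alpha, G_target = G_target,
                 alpha_target = alpha_target, label_smoothing = label_smoothing),
            class = "pv_loss_weights")
}

#' Composite training loss
#'
#' Three regimes: `"CE"` is the plain (smoothed) cross-entropy;
#' `"SH"` subtracts the representational terms,
#' `CE - lambda_S * S - lambda_H * HL`; `"full"` additionally adds the gate
#' and fusion penalties `+ lambda_G * Reg_G + lambda_alpha * Reg_alpha`.
#'
#' @param probs N x K predicted probabilities for the unscaled batch.
#' @param labels Integer class labels.
#' @param weights A [loss_weights()].
#' @param regime One of `"CE"`, `"SH"`, `"full"`.
#' @param bank Feature bank over the contrast-perturbation set (required for
#'   `"SH"` and `"full"`).
#' @param gains Gate gains `g` (required for `"full"`).
#' @param alpha Fusion weights (required for `"full"`).
#' @param eps HL clamp floor.
#' @return Scalar loss.
#' @export
composite_loss <- function(probs, labels, weights, regime = c("CE", "SH", "full"),
                           bank = NULL, gains = NULL, alpha = NULL, eps = 1e-6) {
  regime <- match.arg(regime)
  loss <- cross_entropy_loss(probs, labels, weights$label_smoothing)
  if (regime == "CE") return(loss)
  if (is.null(bank))
    stop("invalid config: SH/full regimes require a feature bank", call. = FALSE)
  loss <- loss - weights$lambda_S * as.numeric(suppressWarnings(direction_invariance_S(bank))) -
    weights$lambda_H * gain_linearity_HL(bank, eps)
  if (regime == "SH") return(loss)
  if (is.null(gains) || is.null(alpha))
    stop("configuration error: full regime requires gate gains and fusion weights (no gate/fusion exists on this variant)",
         call. = FALSE)
  loss + weights$lambda_G * gate_regularizer(gains, weights$G_target) +
    weights$lambda_alpha * alpha_regularizer(alpha, weights$alpha_target)
}
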