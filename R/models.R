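#' Model variant configuration
#'
#' Describes one of the four architectures sharing a common three-block
#' convolutional trunk (3x3 convolution, ReLU, 2x2 max-pool per block) with
#' global average pooling and an affine readout:
#'
#' * `cortical` — the feedforward baseline.
#' * `pulvinar` — adds a long-range pathway from the output of block `m` to
#'   the input of block `n`: a 1x1-convolution projector with bilinear
#'   down-resampling, a squeeze-and-excitation style channel gate `g`, and a
#'   learned per-channel convex fusion
#'   `(1 - alpha) * h + alpha * (g * r)`.
#' * `se_control` — within-layer squeeze-and-excitation gains on the block-2
#'   output, no long-range routing.
#' * `skip_control` — the same projector combined additively with a fixed,
#'   non-learned scale `beta`.
#'
#' @param variant One of `"cortical"`, `"pulvinar"`, `"se_control"`,
#'   `"skip_control"`.
#' @param image_size Input side length; must be divisible by `2^n_blocks`.
#' @param channels Per-block output channel widths.
#' @param source_layer,target_layer Pathway endpoints `m < n`; the projected
#'   signal is fused into the input of block `target_layer` (i.e. with the
#'   output of block `target_layer - 1`).
#' @param gate_hidden Gate bottleneck width; default `channels[n-1] / 4`.
#' @param gate_enabled If `FALSE` the gate is fixed at 1 (non-modulatory skip).
#' @param alpha_init Initial per-channel fusion weight in (0, 1).
#' @param beta Fixed additive skip scale (skip_control only, never trained).
#' @param n_classes Number of output classes K.
#' @param seed Seed for parameter initialization.
#' @return An object of class `pv_model_config`.
#' @export
model_config <- function(variant = c("cortical", "pulvinar", "se_control",
                                     "skip_control"),
                         image_size = 32L, channels = c(64L, 128L, 256L),
                         source_layer = 1L, target_layer = 3L,
                         gate_hidden = NULL, gate_enabled = TRUE,
                         alpha_init = 0.1, beta = 1.0, n_classes = 2L,
                         seed = 1L) {
  variant <- match.arg(variant)
  n_blocks <- length(channels)
  if (n_blocks < 2L) stop("configuration error: need at least two blocks", call. = FALSE)
  if (any(channels <= 0)) stop("configuration error: channels must be positive", call. = FALSE)
  m <- as.integer(source_layer); n <- as.integer(target_layer)
  if (!(m >= 1L && m < n && n <= n_blocks))
    stop("configuration error: need 1 <= m < n <= number of blocks", call. = FALSE)
  if (image_size %% 2^n_blocks != 0)
    stop("configuration error: image_size must be divisible by 2^n_blocks", call. = FALSE)
  target_c <- channels[n - 1L]
  if (is.null(gate_hidden)) gate_hidden <- max(1L, target_c %/% 4L)
  if (alpha_init <= 0 || alpha_init >= 1)
    stop("configuration error: alpha_init must be in (0, 1)", call. = FALSE)
  if (beta < 0) stop("configuration error: beta must be nonnegative", call. = FALSE)
  structure(list(variant = variant, image_size = as.integer(image_size),
                 in_channels = 3L, channels = as.integer(channels),
                 n_blocks = as.integer(n_blocks), source_layer = m,
                 target_layer = n, gate_hidden = as.integer(gate_hidden),
                 gate_enabled = isTRUE(gate_enabled), alpha_init = alpha_init,
                 beta = beta, n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "pv_model_config")
}

.relu <- function(x) { x[x < 0] <- 0; x }
.sigmoid <- function(x) 1 / (1 + exp(-x))
.logit <- function(p) log(p / (1 - p))

## Global average pool: (H, W, C, N) -> N x C matrix.
.gap <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4]))
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## Broadcast helpers over an (H, W, C, N) array.
.bc_channel <- function(v, d) array(rep(rep(v, each = d[1] * d[2]), times = d[4]), d)
.bc_sample_channel <- function(m, d) array(rep(as.vector(t(m)), each = d[1] * d[2]), d)
.bc_pooled <- function(m, d) .bc_sample_channel(m, d) # same layout, divided by HW by caller

#' Initialize network parameters
#'
#' Fan-in-scaled Gaussian initialization, seeded from `config$seed`.  Only the
#' parameters used by `config$variant` are created; the shared trunk
#' parameters have identical shapes across variants so weights can be shared
#' for ablation.
#'
#' @param config A [model_config()].
#' @return Named list of parameter arrays (class `pv_params`).
#' @export
init_params <- function(config) {
  stopifnot(inherits(config, "pv_model_config"))
  set.seed(config$seed)
  ch <- c(config$in_channels, config$channels)
  p <- list()
  for (l in seq_len(config$n_blocks)) {
    fan_in <- 9 * ch[l]
    p[[paste0("conv", l, "_w")]] <-
      array(stats::rnorm(9 * ch[l] * ch[l + 1], sd = sqrt(2 / fan_in)),
            dim = c(3L, 3L, ch[l], ch[l + 1]))
    p[[paste0("conv", l, "_b")]] <- numeric(ch[l + 1])
  }
  cL <- config$channels[config$n_blocks]
  p$out_w <- matrix(stats::rnorm(cL * config$n_classes, sd = sqrt(1 / cL)),
                    cL, config$n_classes)
  p$out_b <- numeric(config$n_classes)
  src_c <- config$channels[config$source_layer]
  tgt_c <- config$channels[config$target_layer - 1L]
  if (config$variant %in% c("pulvinar", "skip_control")) {
    p$proj_w <- array(stats::rnorm(src_c * tgt_c, sd = sqrt(1 / src_c)),
                      dim = c(1L, 1L, src_c, tgt_c))
    p$proj_b <- numeric(tgt_c)
  }
  if (config$variant == "pulvinar") {
    hid <- config$gate_hidden
    p$gate_w1 <- matrix(stats::rnorm(tgt_c * hid, sd = sqrt(2 / tgt_c)), tgt_c, hid)
    p$gate_b1 <- numeric(hid)
    p$gate_w2 <- matrix(stats::rnorm(hid * tgt_c, sd = sqrt(1 / hid)), hid, tgt_c)
    p$gate_b2 <- numeric(tgt_c)
    p$alpha_logit <- rep(.logit(config$alpha_init), tgt_c)
  }
  if (config$variant == "se_control") {
    hid <- config$gate_hidden
    p$se_w1 <- matrix(stats::rnorm(tgt_c * hid, sd = sqrt(2 / tgt_c)), tgt_c, hid)
    p$se_w2 <- matrix(stats::rnorm(hid * tgt_c, sd = sqrt(1 / hid)), hid, tgt_c)
  }
  class(p) <- c("pv_params", "list")
  p
}

#' Count trainable parameters
#'
#' `beta` is a fixed constant, never counted or trained; input-normalization
#' statistics (`input_mu`, `input_sd`), when present, are data statistics,
#' not trainable parameters.
#'
#' @param params A [init_params()] result.
#' @return Total number of trainable scalars.
#' @export
param_count <- function(params) {
  p <- unclass(params)
  p <- p[!grepl("^input_", names(p))]
  sum(vapply(p, length, 1L))
}

#' Project an early feature map to the target-layer shape
#'
#' The projector realizes the cortico-pulvinar and pulvino-cortical linear
#' transformations jointly as a 1x1 convolution over channels followed by
#' bilinear down-resampling (factor-of-two cell-centre sampling) to the target
#' spatial size.
#'
#' @param h_m Source feature map, `(H_m, W_m, C_m, N)`.
#' @param params Parameter list containing `proj_w`, `proj_b`.
#' @param config A [model_config()].
#' @return Projected map `r` with the target-layer input shape.
#' @export
pulvinar_project <- function(h_m, params, config) {
  dw <- dim(params$proj_w)
  if (dim(h_m)[3] != dw[3])
    stop("configuration error: source channel mismatch", call. = FALSE)
  r <- .conv2d_fw(h_m, params$proj_w, params$proj_b)
  steps <- config$target_layer - 1L - config$source_layer
  if (steps > 0) for (i in seq_len(steps)) r <- .avgdown2_fw(r)
  r
}

#' Compute per-channel gate gains from a projected map
#'
#' Squeeze-and-excitation style: global average pooling over space, a
#' two-layer bottleneck with ReLU, then a sigmoid squashing, yielding one gain
#' strictly in (0, 1) per channel and image.
#'
#' @param r Projected map `(H, W, C, N)`.
#' @param params Parameter list containing `gate_w1`, `gate_b1`, `gate_w2`,
#'   `gate_b2`.
#' @return N x C matrix of gains in (0, 1).
#' @export
pulvinar_gate <- function(r, params) {
  cg <- .gap(r)
  hg <- .relu(sweep(cg %*% params$gate_w1, 2, params$gate_b1, "+"))
  .sigmoid(sweep(hg %*% params$gate_w2, 2, params$gate_b2, "+"))
}

#' Convex fusion of cortical and gated pulvinar signals
#'
#' `out = (1 - alpha) * h_n + alpha * (g * r)` per channel, where `alpha` is
#' the learned fusion weight and `g` the gate gain.  With `alpha = 0` the
#' model reduces exactly to the cortical stream; with gating disabled `g` is
#' fixed to 1.
#'
#' @param h_n Target map `(H, W, C, N)`.
#' @param r Projected map, same shape.
#' @param g N x C gain matrix (or the scalar 1).
#' @param alpha Per-channel fusion weights (length C, values in `[0, 1]`).
#' @return Fused map, same shape as `h_n`.
#' @export
fuse <- function(h_n, r, g, alpha) {
  d <- dim(h_n)
  if (!identical(d, dim(r)))
    stop("configuration error: fusion shape mismatch", call. = FALSE)
  af <- .bc_channel(alpha, d)
  gr <- if (is.matrix(g)) .bc_sample_channel(g, d) * r else g * r
  (1 - af) * h_n + af * gr
}

#' Squeeze-and-excitation modulation (control architecture)
#'
#' `out = h * s` with `s = sigmoid(W2 relu(W1 gap(h)))`; applied within the
#' layer, with no long-range routing and no bias terms.
#'
#' @param h Feature map `(H, W, C, N)`.
#' @param params Parameter list containing `se_w1`, `se_w2`.
#' @return Modulated map.
#' @export
se_modulate <- function(h, params) {
  s <- .sigmoid(.relu(.gap(h) %*% params$se_w1) %*% params$se_w2)
  h * .bc_sample_channel(s, dim(h))
}

#' Fixed additive projection skip (control architecture)
#'
#' `out = h_n + beta * proj(h_m)` with the shared projector and a constant,
#' non-learned `beta`.
#'
#' @param h_m Source map.
#' @param h_n Target map.
#' @param params Parameter list containing the projector.
#' @param config A [model_config()].
#' @param beta Fixed scale; defaults to `config$beta`.
#' @return Combined map.
#' @export
skip_project_add <- function(h_m, h_n, params, config, beta = config$beta) {
  h_n + beta * pulvinar_project(h_m, params, config)
}

## Ensure a batch has shape (H, W, 3, N).
.as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4L) stop("configuration error: expected (H, W, C, N) input", call. = FALSE)
  x
}

#' Forward pass through any model variant
#'
#' Dispatches on `config$variant`; the block stack and readout are identical
#' across variants.  Activations are captured at three taps: `v1` (block-1
#' post-ReLU pooled map), `v4` (block-2 map after any within-layer modulation,
#' before cross-layer fusion), and `pfc` (pre-softmax readout), plus the
#' pooled feature vector `u` used by the S/HL metrics.
#'
#' @param config A [model_config()].
#' @param params Matching [init_params()] parameters.
#' @param x Input batch `(H, W, 3, N)` (a single `(H, W, 3)` image is
#'   promoted).
#' @param keep_cache Keep intermediate activations for backpropagation.
#' @param alpha_override,gate_override Optional ablation overrides for the
#'   fusion weights (length-C vector or scalar) and gate/SE gains (for the
#'   `se_control` variant, `gate_override` overrides the SE gains `s`).
#' @return List with `probs` (N x K rows summing to 1), `logits`, `pooled`
#'   (N x C feature matrix), `taps` (per-image scalar summaries and per-layer
#'   maps), and `cache` when requested.
#' @export
forward_variant <- function(config, params, x, keep_cache = FALSE,
                            alpha_override = NULL, gate_override = NULL) {
  stopifnot(inherits(config, "pv_model_config"))
  x <- .as_batch(x)
  if (!is.null(params$input_mu))
    x <- (x - params$input_mu) / params$input_sd
  L <- config$n_blocks
  fuse_after <- config$target_layer - 1L  # block whose output receives the pathway
  cache <- list(x = x)
  h <- x
  h_src <- NULL
  taps <- list()
  for (l in seq_len(L)) {
    a <- .conv2d_fw(h, params[[paste0("conv", l, "_w")]],
                    params[[paste0("conv", l, "_b")]])
    pl <- .maxpool2_fw(.relu(a))
    hblk <- pl$out
    if (keep_cache) {
      cache[[paste0("a", l)]] <- a
      cache[[paste0("pidx", l)]] <- pl$idx
      cache[[paste0("hin", l)]] <- h
    }
    if (l == config$source_layer) {
      h_src <- hblk
      if (keep_cache) cache$h_src <- hblk
    }
    if (l == 1L) taps$v1_map <- hblk
    if (l == fuse_after) {
      h_pre <- hblk
      if (config$variant == "se_control") {
        cg <- .gap(hblk)
        z1 <- cg %*% params$se_w1
        hs <- .relu(z1)
        s <- if (!is.null(gate_override)) {
          if (is.matrix(gate_override)) gate_override
          else matrix(gate_override, nrow = dim(hblk)[4], ncol = dim(hblk)[3],
                      byrow = TRUE)
        } else .sigmoid(hs %*% params$se_w2)
        hblk <- hblk * .bc_sample_channel(s, dim(hblk))
        if (keep_cache) cache$se <- list(cg = cg, z1 = z1, hs = hs, s = s, h_pre = h_pre)
        taps$v4_map <- hblk
      } else if (config$variant %in% c("pulvinar", "skip_control")) {
        taps$v4_map <- hblk
        r <- pulvinar_project(h_src, params, config)
        if (config$variant == "skip_control") {
          hblk <- hblk + config$beta * r
          if (keep_cache) cache$skip <- list(r = r, h_pre = h_pre)
        } else {
          g <- if (!is.null(gate_override)) {
            if (is.matrix(gate_override)) gate_override
            else matrix(gate_override, nrow = dim(hblk)[4], ncol = dim(hblk)[3],
                        byrow = TRUE)
          } else if (config$gate_enabled) pulvinar_gate(r, params) else
            matrix(1, dim(hblk)[4], dim(hblk)[3])
          alpha <- if (!is.null(alpha_override)) {
            rep(alpha_override, length.out = dim(hblk)[3])
          } else .sigmoid(params$alpha_logit)
          fused <- fuse(hblk, r, g, alpha)
          if (keep_cache) {
            cg <- .gap(r)
            z1g <- sweep(cg %*% params$gate_w1, 2, params$gate_b1, "+")
            cache$pulv <- list(r = r, g = g, alpha = alpha, h_pre = h_pre,
                               cg = cg, z1g = z1g,
                               gate_free = is.null(gate_override) && config$gate_enabled,
                               alpha_free = is.null(alpha_override))
          }
          hblk <- fused
        }
      } else {
        taps$v4_map <- hblk
      }
    }
    h <- hblk
  }
  u <- .gap(h)
  logits <- sweep(u %*% params$out_w, 2, params$out_b, "+")
  probs <- .softmax_rows(logits)
  d1 <- dim(taps$v1_map); d4 <- dim(taps$v4_map)
  taps$v1 <- colMeans(matrix(taps$v1_map, d1[1] * d1[2] * d1[3]))
  taps$v4 <- colMeans(matrix(taps$v4_map, d4[1] * d4[2] * d4[3]))
  taps$pfc <- rowMeans(logits)
  taps$pooled_features <- u
  if (keep_cache) {
    cache$hL <- h
    cache$u <- u
    cache$probs <- probs
  }
  list(probs = probs, logits = logits, pooled = u, taps = taps,
       cache = if (keep_cache) cache else NULL)
}

#' Forward pass through the cortical baseline
#'
#' @param params Cortical parameters.
#' @param x Input batch.
#' @param config Optional explicit configuration (defaults to the cortical
#'   variant inferred from the parameter shapes).
#' @return See [forward_variant()].
#' @export
forward_cortical <- function(params, x, config = NULL) {
  if (is.null(config)) {
    x <- .as_batch(x)
    ch <- vapply(seq_len(3), function(l) dim(params[[paste0("conv", l, "_w")]])[4], 1L)
    config <- model_config("cortical", image_size = dim(x)[1], channels = ch,
                           n_classes = length(params$out_b))
  }
  forward_variant(config, params, x)
}
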