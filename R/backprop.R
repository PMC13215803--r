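## Manual reverse-mode differentiation through forward_variant().
## Gradients are seeded at the readout (dlogits, from the cross-entropy term)
## and optionally at the pooled feature vector (dpooled, from the S/HL terms)
## and at the gate output (dgate, from the gain regularizer).

## Sum an (H, W, C, N) array over space -> N x C.
.spatial_sum <- function(x) {
  d <- dim(x)
  t(matrix(colSums(matrix(x, d[1] * d[2])), d[3], d[4]))
}

.backward_variant <- function(config, params, cache, dlogits,
                              dpooled = NULL, dgate = NULL) {
  L <- config$n_blocks
  fuse_after <- config$target_layer - 1L
  g <- list()
  u <- cache$u
  g$out_w <- t(u) %*% dlogits
  g$out_b <- colSums(dlogits)
  du <- dlogits %*% t(params$out_w)
  if (!is.null(dpooled)) du <- du + dpooled
  dL <- dim(cache$hL)
  dh <- .bc_sample_channel(du / (dL[1] * dL[2]), dL)

  dh_src_extra <- NULL
  for (l in rev(seq_len(L))) {
    ## undo the fusion/modulation applied to the output of block l
    if (l == fuse_after && config$variant != "cortical") {
      if (config$variant == "se_control") {
        se <- cache$se
        d <- dim(se$h_pre)
        hw <- d[1] * d[2]
        sf <- .bc_sample_channel(se$s, d)
        ds <- .spatial_sum(dh * se$h_pre)
        dh <- dh * sf
        dz2 <- ds * se$s * (1 - se$s)
        g$se_w2 <- t(se$hs) %*% dz2
        dhs <- dz2 %*% t(params$se_w2)
        dz1 <- dhs * (se$z1 > 0)
        g$se_w1 <- t(se$cg) %*% dz1
        dcg <- dz1 %*% t(params$se_w1)
        dh <- dh + .bc_sample_channel(dcg / hw, d)
      } else if (config$variant == "skip_control") {
        dr <- config$beta * dh
        pb <- .project_bw(config, params, cache, dr)
        g$proj_w <- pb$dw; g$proj_b <- pb$db
        dh_src_extra <- pb$dx
      } else { # pulvinar
        pv <- cache$pulv
        d <- dim(pv$h_pre)
        hw <- d[1] * d[2]
        af <- .bc_channel(pv$alpha, d)
        gf <- .bc_sample_channel(pv$g, d)
        dh_tilde <- dh
        dh <- dh_tilde * (1 - af)
        d_gr <- dh_tilde * af
        if (pv$alpha_free) {
          dalpha <- .channel_sum(dh_tilde * (gf * pv$r - pv$h_pre))
          g$alpha_logit <- dalpha * pv$alpha * (1 - pv$alpha)
        }
        dr <- d_gr * gf
        dg <- .spatial_sum(d_gr * pv$r)
        if (!is.null(dgate)) dg <- dg + dgate
        if (pv$gate_free) {
          dz2 <- dg * pv$g * (1 - pv$g)
          hg <- .relu(pv$z1g)
          g$gate_w2 <- t(hg) %*% dz2
          g$gate_b2 <- colSums(dz2)
          dhg <- dz2 %*% t(params$gate_w2)
          dz1 <- dhg * (pv$z1g > 0)
          g$gate_w1 <- t(pv$cg) %*% dz1
          g$gate_b1 <- colSums(dz1)
          dcg <- dz1 %*% t(params$gate_w1)
          dr <- dr + .bc_sample_channel(dcg / hw, d)
        }
        pb <- .project_bw(config, params, cache, dr)
        g$proj_w <- pb$dw; g$proj_b <- pb$db
        dh_src_extra <- pb$dx
      }
    }
    if (l == config$source_layer && !is.null(dh_src_extra)) {
      dh <- dh + dh_src_extra
      dh_src_extra <- NULL
    }
    a <- cache[[paste0("a", l)]]
    dz <- .maxpool2_bw(dh, cache[[paste0("pidx", l)]], dim(a))
    da <- dz * (a > 0)
    cb <- .conv2d_bw(cache[[paste0("hin", l)]],
                     params[[paste0("conv", l, "_w")]], da)
    g[[paste0("conv", l, "_w")]] <- cb$dw
    g[[paste0("conv", l, "_b")]] <- cb$db
    dh <- cb$dx
  }
  g
}

## Per-channel sum of an (H, W, C, N) array -> length-C vector.
.channel_sum <- function(x) {
  d <- dim(x)
  rowSums(matrix(colSums(matrix(x, d[1] * d[2])), d[3], d[4]))
}

## Backward through the projector (1x1 conv + repeated factor-2 bilinear
## down-resampling): dr at target shape -> gradient at the source map.
.project_bw <- function(config, params, cache, dr) {
  steps <- config$target_layer - 1L - config$source_layer
  if (steps > 0) for (i in seq_len(steps)) dr <- .avgdown2_bw(dr)
  h_src <- .source_map(config, cache)
  cb <- .conv2d_bw(h_src, params$proj_w, dr)
  list(dx = cb$dx, dw = cb$dw, db = cb$db)
}

## Source-block output, cached during the forward pass.
.source_map <- function(config, cache) cache$h_src
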