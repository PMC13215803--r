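## ---- minimal 16-bit grayscale PNG writer --------------------------------
## png::writePNG only emits 8-bit samples; stimuli are stored losslessly at
## 16 bits, so the encoder is written here (IDAT zlib stream from
## memCompress(); CRC32 computed below).  Output is round-trip verified
## against png::readPNG in the test suite.

.crc32_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    t <- integer(256)
    for (n in 0:255) {
      cc <- as.integer(n)
      for (k in 1:8)
        cc <- if (bitwAnd(cc, 1L)) bitwXor(-306674912L, bitwShiftR(cc, 1L))
              else bitwShiftR(cc, 1L)
      t[n + 1] <- cc
    }
    tab <<- t
    tab
  }
})

## CRC32 over bytes (integer vector 0..255), in the signed 32-bit domain
## (bitwShiftR is a logical shift); returned as an unsigned double.
.crc32v <- function(bytes) {
  tab <- .crc32_table()
  crc <- -1L
  for (b in bytes)
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  crc <- as.numeric(bitwXor(crc, -1L))
  if (crc < 0) crc + 4294967296 else crc
}

.be32 <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                              (x %/% 256) %% 256, x %% 256))

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.be32(length(data)), body, .be32(.crc32v(as.integer(body))))
}

## img: matrix in [0,1]; writes a 16-bit grayscale PNG.
.write_png16 <- function(img, path) {
  h <- nrow(img); w <- ncol(img)
  v <- round(pmin(pmax(img, 0), 1) * 65535)
  ## scanlines: filter byte 0, then big-endian 16-bit samples, row-major
  vt <- t(v)
  hi <- as.raw(vt %/% 256); lo <- as.raw(vt %% 256)
  samples <- as.raw(rbind(hi, lo))          # interleave hi/lo per sample
  dim(samples) <- c(2L * w, h)
  scan <- as.raw(rbind(as.raw(0), samples)) # prepend filter byte per row
  ## memCompress(type = "gzip") emits an RFC-1950 zlib stream, as IDAT requires
  zlib <- memCompress(as.raw(scan), type = "gzip")
  ihdr <- c(.be32(w), .be32(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", zlib),
           .png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Write a trial set to disk
#'
#' Serializes stimuli as lossless 16-bit grayscale PNG files plus a manifest
#' CSV (`trial_id`, `label`, `center_x`, `center_y`, `radius`,
#' `contrast_pct`, `seed`) and a JSON snapshot of the stimulus configuration.
#'
#' @param trial_set A [generate_trial_set()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_set <- function(trial_set, dir) {
  stopifnot(inherits(trial_set, "pv_trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- trial_set$n_trials
  for (t in seq_len(n)) {
    img <- trial_set$stimuli[, , t]
    .write_png16(img, file.path(dir, sprintf("trial_%05d.png", t)))
  }
  manifest <- trial_set$specs
  manifest$seed <- trial_set$config$seed
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- unclass(trial_set$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a trial set written by [write_trial_set()]
#'
#' @param dir Directory containing the PNG files, manifest and config.
#' @return A `pv_trial_set` (pixels quantized at PNG bit depth).
#' @export
read_trial_set <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- stimulus_config(cfg$bg_amplitude, cfg$radius, cfg$contrast_pct,
                            cfg$image_size, cfg$noise_base_scale, cfg$seed)
  n <- nrow(manifest)
  stimuli <- array(0, dim = c(config$image_size, config$image_size, n))
  for (t in seq_len(n)) {
    img <- png::readPNG(file.path(dir, sprintf("trial_%05d.png", t)))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    stimuli[, , t] <- img
  }
  structure(list(stimuli = stimuli, labels = manifest$label,
                 specs = manifest[, setdiff(names(manifest), "seed")],
                 config = config, n_trials = n), class = "pv_trial_set")
}

#' Save a model checkpoint
#'
#' Single-file archive holding the configuration snapshot and the flat named
#' parameter arrays; loadable across variants for ablation studies.
#'
#' @param config,params Model configuration and parameters.
#' @param path Output file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(config, params, path) {
  saveRDS(list(config = unclass(config), params = unclass(params),
               format = "pulvinet-checkpoint-1"), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file from [save_checkpoint()].
#' @return List with `config` (`pv_model_config`) and `params` (`pv_params`).
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$format, "pulvinet-checkpoint-1"))
  config <- obj$config
  class(config) <- "pv_model_config"
  params <- obj$params
  class(params) <- c("pv_params", "list")
  list(config = config, params = params)
}

#' Flat metric report row for a run record
#'
#' @param record A `pv_run_record` from [train_model()].
#' @param run_id Identifier string.
#' @return One-row data frame: run id, variant, regime, S, HL, accuracy,
#'   seeds, and the loss weights.
#' @export
metric_report <- function(record, run_id = "run") {
  w <- record$weights
  data.frame(run_id = run_id, variant = record$variant, regime = record$regime,
             S = record$S, HL = record$HL, accuracy = record$accuracy,
             seed = record$seed, lambda_wd = w$lambda_wd,
             lambda_S = w$lambda_S, lambda_H = w$lambda_H,
             lambda_G = w$lambda_G, lambda_alpha = w$lambda_alpha,
             G_target = w$G_target, alpha_target = w$alpha_target,
             label_smoothing = record$train_config$label_smoothing)
}
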