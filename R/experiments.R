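#' Default (BG, R) stimulus grid
#'
#' The grid spanned by the global detection analyses: target radii 1-13 and
#' background amplitudes 0.25-2.5.  Quadrant analyses split each axis at its
#' median.
#'
#' @return List with `bg` and `radius` axis values.
#' @export
default_stimulus_grid <- function() {
  list(bg = c(0.25, 0.5, 1.0, 1.5, 2.0, 2.5),
       radius = c(1L, 3L, 5L, 7L, 9L, 11L, 13L))
}

#' Run the near-threshold detection experiment over a stimulus grid
#'
#' For every (BG, R) cell, generates one pooled, balanced training trial set
#' over the contrast ladder, trains each model variant from scratch on
#' bitwise-identical stimuli and seeds (the naive-observer protocol), and
#' evaluates on an independent held-out set of the same configuration
#' (different seed).  Training uses the plain cross-entropy regime: the
#' detection task removes the gate/fusion regularizers so the intrinsic
#' behavior of the transthalamic pathway can be expressed.
#'
#' @param bg_values,r_values Grid axes (background amplitude BG, radius R).
#' @param variants Model variants to train per cell.
#' @param tc A [train_config()].
#' @param n_per_contrast Trials per contrast level in the training set.
#' @param n_eval_per_contrast Trials per contrast level in the held-out set.
#' @param contrasts Contrast ladder (percent).
#' @param image_size,noise_base_scale,channels See [stimulus_config()] and
#'   [model_config()].
#' @param seed Master seed; per-cell stimulus and parameter seeds derive from
#'   it.
#' @param capture_taps Also record per-trial layer summaries for the probes.
#' @param verbose Print progress.
#' @return List with `predictions` (one data frame: bg, radius, model, trial
#'   id, label, contrast, prediction, present-class score, and tap summaries)
#'   and `failures` (cells excluded after a training failure, with a warning).
#' @export
run_experiment2 <- function(bg_values, r_values,
                            variants = c("cortical", "pulvinar"),
                            tc = train_config(), n_per_contrast = 40L,
                            n_eval_per_contrast = 40L,
                            contrasts = contrast_ladder(), image_size = 32L,
                            noise_base_scale = 0.002,
                            channels = c(16L, 32L, 64L), seed = 1L,
                            capture_taps = TRUE, verbose = FALSE) {
  if (length(bg_values) == 0 || length(r_values) == 0)
    stop("invalid config: empty stimulus grid", call. = FALSE)
  preds <- list()
  failures <- list()
  cell_i <- 0L
  for (bg in bg_values) for (r in r_values) {
    cell_i <- cell_i + 1L
    cell_seed <- .trial_seed(seed, cell_i * 7919L)
    scfg_train <- stimulus_config(bg, r, contrasts, image_size,
                                  noise_base_scale, seed = cell_seed)
    scfg_eval <- stimulus_config(bg, r, contrasts, image_size,
                                 noise_base_scale,
                                 seed = .trial_seed(cell_seed, 1L))
    n_train <- n_per_contrast * length(contrasts)
    ts_train <- generate_trial_set(scfg_train, n_train)
    ts_eval <- generate_trial_set(scfg_eval, n_eval_per_contrast * length(contrasts))
    train_data <- trial_set_input(ts_train)
    eval_data <- trial_set_input(ts_eval)
    for (v in variants) {
      mcfg <- model_config(v, image_size = image_size, channels = channels,
                           n_classes = 2L, seed = .trial_seed(seed, 13L))
      fit <- tryCatch(
        train_model(mcfg, tc, train_data, regime = "CE"),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf("cell (BG=%g, R=%d, %s) failed to train: %s; excluded",
                        bg, r, v, conditionMessage(fit)))
        failures[[length(failures) + 1L]] <-
          list(bg = bg, radius = r, model = v, message = conditionMessage(fit))
        next
      }
      pr <- predict_variant(mcfg, fit$params, eval_data$x)
      df <- data.frame(bg = bg, radius = r, model = v,
                       trial_id = ts_eval$specs$trial_id,
                       label = ts_eval$labels,
                       contrast_pct = ts_eval$specs$contrast_pct,
                       predicted = pr$pred - 1L,
                       score_present = pr$probs[, 2])
      if (capture_taps) {
        df$v1 <- pr$taps$v1; df$v4 <- pr$taps$v4; df$pfc <- pr$taps$pfc
      }
      preds[[length(preds) + 1L]] <- df
      if (verbose)
        message(sprintf("cell (BG=%g, R=%d) %s: accuracy %.3f", bg, r, v,
                        mean(df$predicted == df$label)))
    }
  }
  list(predictions = do.call(rbind, preds), failures = failures)
}

#' Matched-setting architectural comparison on fixture data
#'
#' Trains the requested variants across several seeds under byte-identical
#' training settings (only the variant differs), on the synthetic labeled
#' fixture set, using the `"SH"` regime so all models are driven toward a
#' shared representational (S, HL) regime.
#'
#' @param variants Architectures to compare.
#' @param n_seeds Number of seeded repetitions per variant.
#' @param n_classes,n_per_class,image_size Fixture-set shape.
#' @param fixture_noise_sd Pixel noise of the fixture set; the default keeps
#'   held-out accuracy away from ceiling so architectural differences are
#'   expressed.
#' @param channels Trunk widths.
#' @param tc A [train_config()] shared across variants.
#' @param weights A [loss_weights()] for the SH regime.
#' @param regime Loss regime (default `"SH"`).
#' @param holdout_frac Held-out fraction for evaluation.
#' @param seed Master seed.
#' @return List of `pv_run_record` objects (attribute `runs_by_seed` pairs
#'   them).
#' @export
run_matched_comparison <- function(variants = c("cortical", "pulvinar",
                                                "se_control", "skip_control"),
                                   n_seeds = 10L, n_classes = 4L,
                                   n_per_class = 80L, image_size = 16L,
                                   fixture_noise_sd = 0.6,
                                   channels = c(16L, 32L, 64L),
                                   tc = train_config(learning_rate = 3e-3,
                                                     batch_size = 64L,
                                                     n_epochs = 20L),
                                   weights = loss_weights(lambda_S = 0.1,
                                                          lambda_H = 0.1),
                                   regime = "SH", holdout_frac = 0.4,
                                   seed = 1L) {
  runs <- list()
  for (s in seq_len(n_seeds)) {
    data_seed <- .trial_seed(seed, s)
    fix <- make_fixture_classification_set(n_classes, n_per_class, image_size,
                                           seed = data_seed,
                                           noise_sd = fixture_noise_sd)
    N <- length(fix$labels)
    set.seed(data_seed)
    test_idx <- sample.int(N, round(holdout_frac * N))
    x <- to_three_channel(fix$images)
    train_data <- list(x = x[, , , -test_idx, drop = FALSE],
                       y = fix$labels[-test_idx])
    test_data <- list(x = x[, , , test_idx, drop = FALSE],
                      y = fix$labels[test_idx])
    for (v in variants) {
      tc_s <- tc; tc_s$seed <- .trial_seed(seed, 1000L + s)
      mcfg <- model_config(v, image_size = image_size, channels = channels,
                           n_classes = n_classes,
                           seed = .trial_seed(seed, 2000L + s))
      fit <- train_model(mcfg, tc_s, train_data, regime = regime,
                         weights = weights, test_data = test_data)
      rec <- fit$record
      rec$seed_index <- s
      runs[[length(runs) + 1L]] <- rec
    }
  }
  runs
}
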