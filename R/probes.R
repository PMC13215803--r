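#' Per-trial layer activation summaries
#'
#' Runs the model and returns, per trial, the mean activation over all units
#' at each of the three taps: V1 (block-1 post-ReLU map), V4 (block-2 map),
#' and PFC (pre-softmax readout pre-activations, which may be negative).
#'
#' @param config,params Model configuration and parameters.
#' @param x Input batch.
#' @return Data frame with columns `v1`, `v4`, `pfc` (one row per trial).
#' @export
capture_summaries <- function(config, params, x) {
  pr <- predict_variant(config, params, x)
  as.data.frame(pr$taps)
}

#' Outcome-conditioned activation difference (Hit minus Miss)
#'
#' Restricted to target-present trials: `delta = mean(summary | Hit) -
#' mean(summary | Miss)`.  Positive values indicate stronger activity on Hits.
#'
#' @param summaries Per-trial scalar layer summaries.
#' @param labels Binary ground truth (1 = present).
#' @param predictions Binary predictions (1 = "present").
#' @param layer Layer label to attach (`"V1"`, `"V4"`, `"PFC"`).
#' @return Object of class `pv_delta_activation`: list with `layer`,
#'   `mean_hit`, `mean_miss`, `delta`, `n_hits`, `n_misses`.  If there are no
#'   Hits or no Misses the means/delta are `NA` and `defined` is `FALSE` (an
#'   explicit marker, never a silent zero).
#' @export
delta_activation <- function(summaries, labels, predictions, layer = "PFC") {
  stopifnot(length(summaries) == length(labels),
            length(labels) == length(predictions))
  present <- labels == 1
  hit <- present & predictions == 1
  miss <- present & predictions == 0
  n_hits <- sum(hit); n_misses <- sum(miss)
  if (n_hits == 0 || n_misses == 0) {
    return(structure(list(layer = layer, mean_hit = NA_real_,
                          mean_miss = NA_real_, delta = NA_real_,
                          n_hits = n_hits, n_misses = n_misses,
                          defined = FALSE), class = "pv_delta_activation"))
  }
  mh <- mean(summaries[hit]); mm <- mean(summaries[miss])
  structure(list(layer = layer, mean_hit = mh, mean_miss = mm,
                 delta = mh - mm, n_hits = n_hits, n_misses = n_misses,
                 defined = TRUE), class = "pv_delta_activation")
}

#' Grid of outcome-conditioned activation differences
#'
#' Computes the Hit-minus-Miss activation difference per (BG, R) cell for both
#' models at one layer, and their paired difference (model_a minus model_b,
#' pulvinar minus cortex by default).  Cells where either model's delta is
#' undefined propagate as gaps (`NA`).
#'
#' @param predictions Prediction data frame from [run_experiment2()] with tap
#'   columns (`v1`, `v4`, `pfc`).
#' @param layer One of `"V1"`, `"V4"`, `"PFC"`.
#' @param model_a,model_b Model names; difference is `model_a - model_b`.
#' @return Data frame with per-cell `delta_<model_a>`, `delta_<model_b>`, and
#'   `difference`.
#' @export
delta_grid <- function(predictions, layer = c("PFC", "V1", "V4"),
                       model_a = "pulvinar", model_b = "cortical") {
  layer <- match.arg(layer)
  col <- c(PFC = "pfc", V1 = "v1", V4 = "v4")[[layer]]
  if (!col %in% names(predictions))
    stop("predictions lack tap summaries; rerun with capture_taps = TRUE",
         call. = FALSE)
  if (!all(c(model_a, model_b) %in% unique(predictions$model)))
    stop("model mismatch: both models required per cell", call. = FALSE)
  cells <- unique(predictions[, c("bg", "radius")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    bg <- cells$bg[i]; r <- cells$radius[i]
    da <- lapply(c(model_a, model_b), function(m) {
      sel <- predictions[predictions$bg == bg & predictions$radius == r &
                           predictions$model == m, , drop = FALSE]
      if (nrow(sel) == 0) return(NULL)
      delta_activation(sel[[col]], sel$label, sel$predicted, layer)
    })
    va <- if (is.null(da[[1]]) || !da[[1]]$defined) NA_real_ else da[[1]]$delta
    vb <- if (is.null(da[[2]]) || !da[[2]]$defined) NA_real_ else da[[2]]$delta
    out <- data.frame(bg = bg, radius = r, layer = layer, a = va, b = vb,
                      difference = va - vb)
    names(out)[4:5] <- paste0("delta_", c(model_a, model_b))
    out
  })
  do.call(rbind, rows)
}
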