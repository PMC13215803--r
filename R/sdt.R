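#' Confusion counts for binary detection
#'
#' Partitions trials into hits (H), misses / false negatives (FN), false
#' alarms / false positives (FP), and true negatives (TN).
#'
#' @param predictions Binary predictions (1 = "present").
#' @param labels Binary ground truth (1 = target present).
#' @return Object of class `pv_confusion`: list with `H`, `FN`, `FP`, `TN`.
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("length mismatch between predictions and labels", call. = FALSE)
  predictions <- as.integer(predictions != 0)
  labels <- as.integer(labels != 0)
  structure(list(H = sum(predictions == 1 & labels == 1),
                 FN = sum(predictions == 0 & labels == 1),
                 FP = sum(predictions == 1 & labels == 0),
                 TN = sum(predictions == 0 & labels == 0)),
            class = "pv_confusion")
}

#' Signal-detection metrics from confusion counts
#'
#' Hit rate `HR = H / (H + FN)`, false-alarm rate `FA = FP / (FP + TN)`,
#' sensitivity `dprime = qnorm(HR) - qnorm(FA)`, criterion
#' `c = -(qnorm(HR) + qnorm(FA)) / 2` (negative = liberal responding), and
#' accuracy.  When any rate is 0 or 1, the log-linear correction (0.5 added to
#' every cell) is applied and flagged.
#'
#' @param counts A [confusion_counts()] result.
#' @param correction `"loglinear"` (default) or `"none"` (infinite d-prime
#'   possible).
#' @return Object of class `pv_sdt`: list with `HR`, `FA`, `dprime`,
#'   `criterion`, `accuracy`, `correction_applied`, and the (possibly
#'   corrected) counts.
#' @export
sdt_metrics <- function(counts, correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(counts, "pv_confusion"))
  n_present <- counts$H + counts$FN
  n_absent <- counts$FP + counts$TN
  if (n_present == 0 || n_absent == 0)
    stop("undefined metric: need at least one present and one absent trial",
         call. = FALSE)
  HR <- counts$H / n_present
  FA <- counts$FP / n_absent
  accuracy <- (counts$H + counts$TN) / (n_present + n_absent)
  applied <- FALSE
  h <- counts$H; fn <- counts$FN; fp <- counts$FP; tn <- counts$TN
  if (correction == "loglinear" && (HR %in% c(0, 1) || FA %in% c(0, 1))) {
    applied <- TRUE
    h <- h + 0.5; fn <- fn + 0.5; fp <- fp + 0.5; tn <- tn + 0.5
  }
  HRc <- h / (h + fn); FAc <- fp / (fp + tn)
  zH <- stats::qnorm(HRc); zF <- stats::qnorm(FAc)
  structure(list(HR = HR, FA = FA, dprime = zH - zF,
                 criterion = -(zH + zF) / 2, accuracy = accuracy,
                 correction_applied = applied, counts = counts),
            class = "pv_sdt")
}

#' Psychometric curve: hit rate versus contrast
#'
#' Groups target-present trials by contrast and returns the hit rate per
#' level, in ascending contrast order.  Levels with no present trials are
#' omitted with a warning.
#'
#' @param df Data frame with columns `contrast_pct`, `label`, `predicted`
#'   (e.g. one model/cell slice of [run_experiment2()] predictions).
#' @return Data frame with `contrast_pct`, `n_present`, `hit_rate`.
#' @export
psychometric_curve <- function(df) {
  present <- df[!is.na(df$contrast_pct) & df$label == 1, , drop = FALSE]
  levels <- sort(unique(df$contrast_pct[!is.na(df$contrast_pct)]))
  out <- do.call(rbind, lapply(levels, function(cc) {
    sel <- present[present$contrast_pct == cc, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    data.frame(contrast_pct = cc, n_present = nrow(sel),
               hit_rate = mean(sel$predicted == 1))
  }))
  if (length(levels) > 0 && (is.null(out) || nrow(out) < length(levels)))
    warning("contrast level(s) with no present trials omitted")
  out
}

#' Grid analysis of paired model metrics
#'
#' Computes per-(BG, R)-cell confusion counts and SDT metrics for each of the
#' two models and the paired difference `delta = pulvinar - cortex` for every
#' metric.  Cells missing either model are reported as gaps and excluded from
#' the paired differences.
#'
#' @param predictions Prediction data frame from [run_experiment2()] (columns
#'   `bg`, `radius`, `model`, `label`, `predicted`).
#' @param model_a,model_b Names of the two models; the difference is
#'   `model_a - model_b` (default pulvinar minus cortical).
#' @return Object of class `pv_grid_result`: list with `metrics` (long data
#'   frame, one row per cell x model) and `delta` (one row per complete cell).
#' @export
grid_analysis <- function(predictions, model_a = "pulvinar",
                          model_b = "cortical") {
  models <- unique(predictions$model)
  if (!all(c(model_a, model_b) %in% models) || length(models) != 2L)
    stop("grid analysis requires predictions from exactly the two models",
         call. = FALSE)
  cells <- unique(predictions[, c("bg", "radius")])
  met_rows <- list(); delta_rows <- list()
  metric_names <- c("H", "FN", "FP", "TN", "HR", "FA", "dprime", "criterion",
                    "accuracy")
  for (i in seq_len(nrow(cells))) {
    bg <- cells$bg[i]; r <- cells$radius[i]
    row_m <- list()
    for (m in c(model_a, model_b)) {
      sel <- predictions[predictions$bg == bg & predictions$radius == r &
                           predictions$model == m, , drop = FALSE]
      if (nrow(sel) == 0) next
      sm <- sdt_metrics(confusion_counts(sel$predicted, sel$label))
      row <- data.frame(bg = bg, radius = r, model = m,
                        H = sm$counts$H, FN = sm$counts$FN, FP = sm$counts$FP,
                        TN = sm$counts$TN, HR = sm$HR, FA = sm$FA,
                        dprime = sm$dprime, criterion = sm$criterion,
                        accuracy = sm$accuracy)
      met_rows[[length(met_rows) + 1L]] <- row
      row_m[[m]] <- row
    }
    if (!is.null(row_m[[model_a]]) && !is.null(row_m[[model_b]])) {
      d <- row_m[[model_a]][metric_names] - row_m[[model_b]][metric_names]
      delta_rows[[length(delta_rows) + 1L]] <-
        cbind(data.frame(bg = bg, radius = r), d)
    }
  }
  structure(list(metrics = do.call(rbind, met_rows),
                 delta = do.call(rbind, delta_rows),
                 model_a = model_a, model_b = model_b),
            class = "pv_grid_result")
}

#' Quadrant summary of a stimulus grid
#'
#' Partitions grid cells into Q1 (low BG, small R), Q2 (high BG, small R),
#' Q3 (low BG, large R), Q4 (high BG, large R) and returns per-quadrant means
#' of every metric, for each model and for the paired differences.
#'
#' @param grid A [grid_analysis()] result.
#' @param bg_split,r_split Split points (defaults: axis medians). "Low" means
#'   value <= split.
#' @return List with `quadrants` (cell-to-quadrant assignment), `by_model`
#'   and `delta` per-quadrant mean data frames.
#' @export
quadrant_summary <- function(grid, bg_split = NULL, r_split = NULL) {
  stopifnot(inherits(grid, "pv_grid_result"))
  met <- grid$metrics
  bgs <- sort(unique(met$bg)); rs <- sort(unique(met$radius))
  if (is.null(bg_split)) bg_split <- stats::median(bgs)
  if (is.null(r_split)) r_split <- stats::median(rs)
  if (bg_split < min(bgs) || bg_split > max(bgs) ||
      r_split < min(rs) || r_split > max(rs))
    stop("split outside axis range", call. = FALSE)
  quad <- function(bg, r) {
    low_bg <- bg <= bg_split; small_r <- r <= r_split
    ifelse(low_bg & small_r, "Q1",
           ifelse(!low_bg & small_r, "Q2",
                  ifelse(low_bg & !small_r, "Q3", "Q4")))
  }
  met$quadrant <- quad(met$bg, met$radius)
  dl <- grid$delta
  dl$quadrant <- quad(dl$bg, dl$radius)
  num_cols <- function(df) names(df)[vapply(df, is.numeric, TRUE) &
                                       !names(df) %in% c("bg", "radius")]
  agg <- function(df, by) {
    cols <- num_cols(df)
    out <- stats::aggregate(df[cols], by = df[by], FUN = mean)
    out
  }
  list(bg_split = bg_split, r_split = r_split,
       quadrants = unique(met[, c("bg", "radius", "quadrant")]),
       by_model = agg(met, c("model", "quadrant")),
       delta = agg(dl, "quadrant"))
}

#' Proportion of high cells under a pooled z-threshold
#'
#' z-scores a metric over the pooled values of both models jointly (sample
#' standard deviation) and reports the proportion of cells exceeding the
#' threshold, globally per model and per model x quadrant.
#'
#' @param values Numeric metric values (pooled cells, both models).
#' @param model Model label per value.
#' @param quadrant Optional quadrant label per value.
#' @param z_threshold Threshold (default 1).
#' @return List with `global` (proportion high per model) and `by_quadrant`
#'   (if quadrants given).  Zero spread yields all-not-high with a warning.
#' @export
high_cell_enrichment <- function(values, model, quadrant = NULL,
                                 z_threshold = 1) {
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    warning("zero spread in pooled values; no cell is high")
    z <- rep(-Inf, length(values))
  } else {
    z <- (values - mean(values)) / s
  }
  high <- z > z_threshold
  global <- tapply(high, model, mean)
  out <- list(global = data.frame(model = names(global),
                                  prop_high = as.numeric(global)))
  if (!is.null(quadrant)) {
    byq <- stats::aggregate(list(prop_high = high),
                            by = list(model = model, quadrant = quadrant),
                            FUN = mean)
    out$by_quadrant <- byq
  }
  out
}
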