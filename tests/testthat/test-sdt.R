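test_that("confusion counts enumerate and partition all trials", {
  cc <- confusion_counts(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cc)[c("H", "FN", "FP", "TN")],
               list(H = 1L, FN = 1L, FP = 1L, TN = 1L))
  # all correct -> no errors
  cc2 <- confusion_counts(c(1, 1, 0), c(1, 1, 0))
  expect_equal(cc2$FN + cc2$FP, 0L)
  # counts always partition the trial total
  set.seed(8)
  for (i in 1:5) {
    n <- sample(4:30, 1)
    pr <- sample(0:1, n, TRUE); lb <- sample(0:1, n, TRUE)
    cc3 <- confusion_counts(pr, lb)
    expect_equal(cc3$H + cc3$FN + cc3$FP + cc3$TN, n)
  }
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("d-prime and criterion match a bisection inverse-normal oracle", {
  cc <- structure(list(H = 40L, FN = 10L, FP = 20L, TN = 30L),
                  class = "pv_confusion")
  m <- sdt_metrics(cc)
  expect_equal(m$HR, 0.8)
  expect_equal(m$FA, 0.4)
  zH <- qnorm_bisect(0.8); zF <- qnorm_bisect(0.4)
  expect_equal(m$dprime, zH - zF, tolerance = 1e-6)
  expect_equal(m$criterion, -(zH + zF) / 2, tolerance = 1e-6)
  expect_false(m$correction_applied)
  # symmetric chance performance
  m0 <- sdt_metrics(confusion_counts(rep(c(1, 0), 10), rep(c(1, 1, 0, 0), 5)))
  expect_equal(m0$dprime, 0)
  expect_equal(m0$criterion, 0)
})

test_that("negation symmetry: (HR, FA) -> (1-FA, 1-HR) preserves d-prime", {
  cc1 <- structure(list(H = 35L, FN = 15L, FP = 5L, TN = 45L),
                   class = "pv_confusion")
  # HR = .7, FA = .1; swapped: HR = .9, FA = .3
  cc2 <- structure(list(H = 45L, FN = 5L, FP = 15L, TN = 35L),
                   class = "pv_confusion")
  expect_equal(sdt_metrics(cc1)$dprime, sdt_metrics(cc2)$dprime,
               tolerance = 1e-12)
})

test_that("log-linear correction engages at extreme rates and is flagged", {
  cc <- confusion_counts(rep(1, 10), c(rep(1, 5), rep(0, 5)))
  m <- sdt_metrics(cc)
  expect_true(m$correction_applied)
  expect_true(is.finite(m$dprime))
  expect_error(sdt_metrics(confusion_counts(c(1, 0), c(1, 1))),
               "undefined metric")
})

test_that("d-prime monotonicity and criterion sign convention", {
  d_of <- function(h, fp) sdt_metrics(structure(
    list(H = h, FN = 50L - h, FP = fp, TN = 50L - fp),
    class = "pv_confusion"))
  # more hits never decrease d'
  ds <- vapply(10:45, function(h) d_of(h, 15L)$dprime, 1.0)
  expect_true(all(diff(ds) >= 0))
  # more false alarms never increase d'
  ds2 <- vapply(5:40, function(fp) d_of(30L, fp)$dprime, 1.0)
  expect_true(all(diff(ds2) <= 0))
  # liberal responding (high HR and FA together) drives c negative
  expect_lt(d_of(48L, 40L)$criterion, 0)
  expect_gt(d_of(10L, 2L)$criterion, 0)
})

test_that("psychometric curves preserve contrast order and handle degenerate levels", {
  ladder <- contrast_ladder()
  df <- data.frame(
    contrast_pct = c(rep(ladder, each = 4), rep(NA, 8)),
    label = c(rep(1, 4 * length(ladder)), rep(0, 8)),
    predicted = 1)
  curve <- psychometric_curve(df)
  expect_equal(nrow(curve), 17L)
  expect_equal(curve$contrast_pct, sort(ladder))
  expect_true(all(curve$hit_rate == 1))
  # constructed monotone data -> nondecreasing curve
  df2 <- data.frame(contrast_pct = rep(c(1, 2, 3), each = 10),
                    label = 1,
                    predicted = rep(c(0, 1), c(15, 15)))
  curve2 <- psychometric_curve(df2)
  expect_true(all(diff(curve2$hit_rate) >= 0))
})

test_that("grid analysis pairs cells with the pulvinar-minus-cortex convention", {
  mk <- function(bg, r, model, h, fn, fp, tn) {
    data.frame(bg = bg, radius = r, model = model,
               label = rep(c(1, 0), c(h + fn, fp + tn)),
               predicted = c(rep(c(1, 0), c(h, fn)), rep(c(1, 0), c(fp, tn))))
  }
  pr <- rbind(mk(0.25, 3, "pulvinar", 30, 20, 10, 40),
              mk(0.25, 3, "cortical", 25, 25, 15, 35),
              mk(2.5, 13, "pulvinar", 45, 5, 5, 45),
              mk(2.5, 13, "cortical", 40, 10, 10, 40))
  g <- grid_analysis(pr)
  expect_equal(nrow(g$delta), 2L)
  d1 <- g$delta[g$delta$bg == 0.25, ]
  expect_equal(d1$H, 5)       # manual subtraction: 30 - 25
  expect_equal(d1$FP, -5)
  expect_gt(d1$dprime, 0)
  # identical prediction sets -> all deltas zero
  pr_same <- rbind(mk(1, 3, "pulvinar", 20, 10, 10, 20),
                   mk(1, 3, "cortical", 20, 10, 10, 20))
  g0 <- grid_analysis(pr_same)
  expect_true(all(abs(as.matrix(g0$delta[, -(1:2)])) < 1e-12))
  expect_error(grid_analysis(pr[pr$model == "pulvinar", ]), "two models")
})

test_that("quadrant partition assigns each cell once and aggregates correctly", {
  mk <- function(bg, r, model, h) {
    data.frame(bg = bg, radius = r, model = model,
               label = rep(c(1, 0), each = 20),
               predicted = c(rep(c(1, 0), c(h, 20 - h)), rep(0, 20)))
  }
  cells <- expand.grid(bg = c(0.25, 2.5), r = c(3, 13))
  pr <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    rbind(mk(cells$bg[i], cells$r[i], "pulvinar", 15),
          mk(cells$bg[i], cells$r[i], "cortical", 15))))
  g <- grid_analysis(pr)
  qs <- quadrant_summary(g, bg_split = 1, r_split = 8)
  expect_setequal(qs$quadrants$quadrant, c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(nrow(qs$quadrants), 4L)
  # uniform values -> identical quadrant means
  expect_equal(length(unique(round(qs$by_model$HR, 12))), 1L)
  # a single elevated cell raises only its own quadrant (Q1: low BG, small R)
  pr2 <- pr
  sel <- pr2$bg == 0.25 & pr2$radius == 3 & pr2$model == "pulvinar" & pr2$label == 1
  pr2$predicted[sel] <- 1
  qs2 <- quadrant_summary(grid_analysis(pr2), bg_split = 1, r_split = 8)
  hr_q <- with(subset(qs2$by_model, model == "pulvinar"),
               stats::setNames(HR, quadrant))
  expect_gt(hr_q["Q1"], hr_q["Q2"])
  expect_equal(unname(hr_q["Q2"]), unname(hr_q["Q4"]))
  expect_error(quadrant_summary(g, bg_split = 99), "split outside")
})

test_that("z-threshold enrichment uses pooled sample statistics", {
  # nine cells, eight equal and one extreme -> exactly 1/9 flagged high
  vals <- c(rep(1, 8), 50)
  mod <- rep(c("a", "b"), c(4, 5))
  z <- (vals - mean(vals)) / sd(vals)   # direct z oracle, sample sd
  expect_equal(sum(z > 1), 1L)
  enr <- high_cell_enrichment(vals, mod, z_threshold = 1)
  expect_equal(sum(enr$global$prop_high * c(4, 5)), 1)
  # all equal -> proportion 0 with warning
  expect_warning(e0 <- high_cell_enrichment(rep(2, 6), rep(c("a", "b"), 3)),
                 "zero spread")
  expect_true(all(e0$global$prop_high == 0))
  # invariant to affine transforms of the pooled values
  enr2 <- high_cell_enrichment(vals * 3 + 10, mod, z_threshold = 1)
  expect_equal(enr$global, enr2$global)
})
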