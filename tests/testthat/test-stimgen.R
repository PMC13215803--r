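test_that("zero-amplitude background is constant mean luminance", {
  cfg <- stimulus_config(0, 3, 1, image_size = 16)
  img <- make_noise_background(cfg)
  expect_true(all(img == 0.5))
})

test_that("unclipped background mean is 0.5 by construction for any seed and BG", {
  for (bg in c(0.25, 1, 2.5)) for (seed in c(1, 99)) {
    cfg <- stimulus_config(bg, 3, 1, image_size = 32, seed = seed)
    set.seed(seed)
    img <- make_noise_background(cfg, clip = FALSE)
    expect_lt(abs(mean(img) - 0.5), 1e-12)
  }
})

test_that("noise field standard deviation tracks bg_amplitude x base scale", {
  cfg <- stimulus_config(2, 3, 1, image_size = 64, noise_base_scale = 0.01,
                         seed = 3)
  set.seed(3)
  img <- make_noise_background(cfg, clip = FALSE)
  expect_equal(sd(as.vector(img)), 2 * 0.01, tolerance = 1e-8)
})

test_that("radial amplitude spectrum has a 1/f slope (DFT oracle, sizes 32-128)", {
  # oracle: 2-D DFT of the generated field, amplitude binned by integer radial
  # frequency, log-log least-squares slope
  for (size in c(32L, 64L, 128L)) {
    cfg <- stimulus_config(1, 3, 1, image_size = size, noise_base_scale = 0.05,
                           seed = 11)
    set.seed(11)
    img <- make_noise_background(cfg, clip = FALSE) - 0.5
    amp <- Mod(stats::fft(img))
    f1 <- c(0:floor(size / 2), -(ceiling(size / 2) - 1):-1)
    fr <- sqrt(outer(f1^2, f1^2, "+"))
    bins <- round(fr)
    keep <- bins >= 2 & bins <= size / 4
    m <- tapply(amp[keep], bins[keep], mean)
    fx <- log(as.numeric(names(m)))
    slope <- coef(lm(log(m) ~ fx))[2]
    expect_gt(slope, -1.25)
    expect_lt(slope, -0.75)
  }
})

test_that("invalid stimulus configurations are rejected", {
  expect_error(stimulus_config(1, 3, 1, image_size = 4), "invalid config")
  expect_error(stimulus_config(-1, 3, 1), "invalid config")
  expect_error(stimulus_config(1, 20, 1, image_size = 32), "invalid config")
})

test_that("target insertion increments exactly the disk, by the Weber delta", {
  img <- matrix(0.5, 32, 32)
  out <- insert_target(img, c(16, 16), 3, 10)
  # brute-force lattice count oracle: dx^2 + dy^2 <= 9
  n_disk <- sum(outer((-3):3, (-3):3, function(a, b) a^2 + b^2) <= 9)
  expect_identical(n_disk, 29L)
  expect_equal(sum(out != 0.5), 29)
  expect_equal(unique(out[out != 0.5]), 0.5 + 10 / 100 * 0.5)
  # zero contrast is the identity
  expect_identical(insert_target(img, c(16, 16), 3, 0), img)
  # ladder endpoints accepted
  expect_silent(insert_target(img, c(16, 16), 3, 0.005))
  expect_silent(insert_target(img, c(16, 16), 3, 4))
  # out-of-bounds placement rejected
  expect_error(insert_target(img, c(2, 2), 3, 1), "placement error")
})

test_that("present/absent difference is the delta inside the disk, zero outside", {
  cfg <- stimulus_config(0.5, 4, 2, image_size = 24, noise_base_scale = 0.02,
                         seed = 9)
  set.seed(9)
  bgimg <- make_noise_background(cfg)
  tgt <- insert_target(bgimg, c(12, 12), 4, 2)
  diff <- tgt - bgimg
  cols <- matrix(1:24, 24, 24, byrow = TRUE); rows <- matrix(1:24, 24, 24)
  disk <- (cols - 12)^2 + (rows - 12)^2 <= 16
  expect_true(all(diff[!disk] == 0))
  expect_equal(mean(diff[disk]), 2 / 100 * 0.5, tolerance = 1e-6)
})

test_that("trial sets are balanced and reproducible", {
  cfg <- stimulus_config(1, 3, c(1, 2), image_size = 16, seed = 21)
  ts <- generate_trial_set(cfg, 1000)
  expect_equal(sum(ts$labels == 1), 500)
  expect_equal(sum(ts$labels == 0), 500)
  ts_min <- generate_trial_set(cfg, 2)
  expect_equal(sort(ts_min$labels), c(0L, 1L))
  # every present trial has a complete target spec
  pres <- ts_min$specs[ts_min$labels == 1, ]
  expect_false(anyNA(pres[, c("center_x", "center_y", "radius", "contrast_pct")]))
  # bitwise reproducibility under the same seed
  ts2 <- generate_trial_set(cfg, 2)
  expect_identical(ts2$stimuli, ts_min$stimuli)
  expect_error(generate_trial_set(cfg, 1), "invalid config")
})

test_that("trial order is exchangeable for downstream confusion counts", {
  set.seed(5)
  labels <- rep(c(1L, 0L), 20)
  preds <- sample(0:1, 40, TRUE)
  base <- confusion_counts(preds, labels)
  perm <- sample.int(40)
  expect_identical(unclass(base), unclass(confusion_counts(preds[perm], labels[perm])))
})

test_that("three-channel replication copies the grayscale plane", {
  m <- matrix(runif(64), 8)
  x <- to_three_channel(m)
  expect_identical(x[, , 1], m)
  expect_identical(x[, , 2], m)
  expect_identical(x[, , 3], m)
  expect_equal(apply(x, c(1, 2), mean), m)
  const <- to_three_channel(matrix(0.5, 8, 8))
  expect_true(all(const == 0.5))
})

test_that("contrast scaling produces aligned elementwise-scaled batches", {
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  ps <- contrast_scale_batch(x, c(0.2, 0.6, 1.0))
  expect_identical(ps$batches[[3]], x)
  for (k in 1:3) expect_equal(ps$batches[[k]], x * ps$sigmas[k])
  expect_true(all(contrast_scale_batch(x, 0)$batches[[1]] == 0))
  expect_error(contrast_scale_batch(x, c(-0.1, 1)), "invalid config")
})

test_that("fixture classification set is deterministic and separable", {
  fix <- make_fixture_classification_set(2, 50, image_size = 8, seed = 4)
  expect_equal(dim(fix$images)[3], 100)
  expect_equal(as.vector(table(fix$labels)), c(50, 50))
  fix2 <- make_fixture_classification_set(2, 50, image_size = 8, seed = 4)
  expect_identical(fix2$images, fix$images)
  # least-squares linear probe on raw pixels beats chance on a held-out split
  acc <- linear_probe_accuracy(fix$images, fix$labels)
  expect_gt(acc, 0.6)
})

test_that("trial sets round-trip through 16-bit PNG serialization", {
  cfg <- stimulus_config(1, 3, 2, image_size = 16, seed = 31)
  ts <- generate_trial_set(cfg, 4)
  d <- withr::local_tempdir()
  write_trial_set(ts, d)
  # the PNG files are readable by an independent decoder at 16-bit precision
  img <- png::readPNG(file.path(d, "trial_00001.png"))
  expect_lt(max(abs(img - ts$stimuli[, , 1])), 1 / 65535)
  ts2 <- read_trial_set(d)
  expect_lt(max(abs(ts2$stimuli - ts$stimuli)), 1 / 65535)
  expect_identical(ts2$labels, ts$labels)
  expect_equal(ts2$config$bg_amplitude, ts$config$bg_amplitude)
})
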