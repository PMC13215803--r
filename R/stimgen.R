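#' The printed 17-level contrast ladder (percent units)
#'
#' Contrast values used for the near-threshold detection task, from 0.005% to
#' 4%. Targets are luminance increments of `(contrast/100) * 0.5` relative to
#' the 0.5 mean-luminance background.
#'
#' @return Numeric vector of 17 contrast values in percent.
#' @export
contrast_ladder <- function() {
  c(0.005, 0.01, 0.025, 0.05, 0.08, 0.11, 0.15, 0.20, 0.25,
    0.30, 0.35, 0.40, 0.45, 0.65, 1.0, 2.0, 4.0)
}

#' Stimulus configuration for the detection simulator
#'
#' @param bg_amplitude Nonnegative background-noise amplitude multiplier (BG).
#'   The pixel standard deviation of the unclipped noise field is
#'   `bg_amplitude * noise_base_scale`.
#' @param radius Target radius in pixels; the disk must fit fully inside the
#'   image, so `radius <= floor((image_size - 1) / 2)`.
#' @param contrast_pct Contrast value(s) in percent for target-present trials;
#'   defaults to the full printed ladder ([contrast_ladder()]).
#' @param image_size Side length of the square stimulus in pixels.
#' @param noise_base_scale Base pixel standard deviation multiplied by
#'   `bg_amplitude` (see the methods vignette for the calibration).
#' @param seed Integer seed; trial sets derive an independent per-trial stream
#'   from it so individual trials are reproducible.
#'
#' @return An object of class `pv_stim_config`.
#' @export
stimulus_config <- function(bg_amplitude, radius, contrast_pct = contrast_ladder(),
                            image_size = 32L, noise_base_scale = 0.002,
                            seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 1L || image_size < 8)
    stop("invalid config: image_size must be a single integer >= 8", call. = FALSE)
  image_size <- as.integer(image_size)
  if (!is.numeric(bg_amplitude) || bg_amplitude < 0)
    stop("invalid config: bg_amplitude must be nonnegative", call. = FALSE)
  if (!is.numeric(radius) || radius < 1 || radius > floor((image_size - 1) / 2))
    stop("invalid config: radius must be in [1, floor((image_size-1)/2)]",
         call. = FALSE)
  if (any(contrast_pct < 0)) stop("invalid config: negative contrast", call. = FALSE)
  structure(list(bg_amplitude = bg_amplitude, radius = as.integer(radius),
                 contrast_pct = contrast_pct, image_size = image_size,
                 noise_base_scale = noise_base_scale, seed = as.integer(seed),
                 increment_convention = "weber_mean_luminance"),
            class = "pv_stim_config")
}

## Deterministic per-trial seed stream: a small LCG-style mix of the global
## seed and the trial counter, kept below 2^31.
.trial_seed <- function(seed, counter) {
  s <- (as.double(seed %% 2147483647L) * 69069 + 1) %% 2147483647
  as.integer((s + as.double(counter) * 104729) %% 2147483647)
}

## Radial frequency grid in cycles/image for an n x n DFT (wrap-around order).
.radial_freq <- function(n) {
  f1 <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)
  sqrt(outer(f1^2, f1^2, "+"))
}

#' Generate a 1/f-noise background image
#'
#' Synthesizes a white Gaussian field, shapes its Fourier amplitude by
#' `1 / max(f, 1)` (radial frequency in cycles/image; the floor avoids a DC
#' blow-up), removes the DC component, rescales the field so its pixel
#' standard deviation equals `bg_amplitude * noise_base_scale`, adds the 0.5
#' mean luminance, and clips to `[0, 1]`.  The unclipped field has spatial
#' mean exactly 0.5 by construction.
#'
#' @param config A [stimulus_config()].
#' @param clip If `FALSE`, return the unclipped field (useful for verifying
#'   the mean-luminance and spectrum contracts).
#' @return An `image_size` x `image_size` matrix of luminance values.
#' @export
make_noise_background <- function(config, clip = TRUE) {
  stopifnot(inherits(config, "pv_stim_config"))
  n <- config$image_size
  target_sd <- config$bg_amplitude * config$noise_base_scale
  if (target_sd == 0) return(matrix(0.5, n, n))
  white <- matrix(stats::rnorm(n * n), n, n)
  filt <- 1 / pmax(.radial_freq(n), 1)
  filt[1, 1] <- 0  # DC removed; mean luminance added back below
  field <- Re(stats::fft(stats::fft(white) * filt, inverse = TRUE)) / (n * n)
  field <- field - mean(field)
  s <- stats::sd(as.vector(field))
  if (s > 0) field <- field * (target_sd / s)
  img <- 0.5 + field
  if (clip) img <- pmin(pmax(img, 0), 1) else img
}

#' Insert a circular luminance increment into an image
#'
#' Pixels within Euclidean distance `radius` of `center` are incremented by
#' `delta = (contrast_pct / 100) * 0.5` (a Weber-style increment relative to
#' the 0.5 mean luminance), then the image is clipped to `[0, 1]`.
#'
#' @param image Luminance matrix.
#' @param center Length-2 vector `(x, y)` = (column, row) of the disk centre.
#' @param radius Disk radius in pixels; the disk must be fully contained.
#' @param contrast_pct Contrast in percent.
#' @return The modified image matrix.
#' @export
insert_target <- function(image, center, radius, contrast_pct) {
  h <- nrow(image); w <- ncol(image)
  cx <- center[[1]]; cy <- center[[2]]
  if (cx - radius < 1 || cx + radius > w || cy - radius < 1 || cy + radius > h)
    stop("placement error: target disk exceeds image bounds", call. = FALSE)
  if (contrast_pct == 0) return(image)
  delta <- (contrast_pct / 100) * 0.5
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rows <- matrix(seq_len(h), h, w)
  disk <- (cols - cx)^2 + (rows - cy)^2 <= radius^2
  out <- image
  out[disk] <- out[disk] + delta
  pmin(pmax(out, 0), 1)
}

#' Generate a balanced detection trial set
#'
#' Produces `ceiling(n_trials / 2)` target-present and `floor(n_trials / 2)`
#' target-absent stimuli.  Present-trial centres are drawn uniformly over all
#' positions at which the disk is fully contained; contrasts cycle through
#' `contrasts` so every ladder level is evenly represented.  Each trial uses
#' an independent seeded noise stream, so regeneration with the same seed is
#' bitwise identical.
#'
#' @param config A [stimulus_config()].
#' @param n_trials Total number of trials (>= 2).
#' @param contrasts Contrast levels in percent for present trials; defaults to
#'   `config$contrast_pct`.
#' @return A `pv_trial_set`: list with `stimuli` (H x W x N array), `labels`
#'   (1 = present, 0 = absent), `specs` (data frame of per-trial target
#'   parameters), `config`, `n_trials`.
#' @export
generate_trial_set <- function(config, n_trials, contrasts = config$contrast_pct) {
  stopifnot(inherits(config, "pv_stim_config"))
  if (!is.numeric(n_trials) || n_trials < 2)
    stop("invalid config: n_trials must be >= 2", call. = FALSE)
  n_trials <- as.integer(n_trials)
  n <- config$image_size; r <- config$radius
  n_present <- as.integer(ceiling(n_trials / 2))
  labels <- integer(n_trials)
  set.seed(.trial_seed(config$seed, 0L))
  labels[sample.int(n_trials, n_present)] <- 1L
  lo <- r + 1L; hi <- n - r
  stimuli <- array(0, dim = c(n, n, n_trials))
  specs <- data.frame(trial_id = seq_len(n_trials), label = labels,
                      center_x = NA_real_, center_y = NA_real_,
                      radius = ifelse(labels == 1L, r, NA_integer_),
                      contrast_pct = NA_real_)
  k <- 0L
  for (t in seq_len(n_trials)) {
    set.seed(.trial_seed(config$seed, t))
    img <- make_noise_background(config, clip = TRUE)
    if (labels[t] == 1L) {
      k <- k + 1L
      cx <- if (hi > lo) sample(lo:hi, 1L) else lo
      cy <- if (hi > lo) sample(lo:hi, 1L) else lo
      cpct <- contrasts[((k - 1L) %% length(contrasts)) + 1L]
      img <- insert_target(img, c(cx, cy), r, cpct)
      specs$center_x[t] <- cx; specs$center_y[t] <- cy
      specs$contrast_pct[t] <- cpct
    }
    stimuli[, , t] <- img
  }
  structure(list(stimuli = stimuli, labels = labels, specs = specs,
                 config = config, n_trials = n_trials),
            class = "pv_trial_set")
}

#' Replicate grayscale stimuli across three channels
#'
#' The network consumes RGB-format input; grayscale stimuli are replicated
#' across the three channel planes.
#'
#' @param image A single H x W matrix, or an H x W x N array of stimuli.
#' @return An H x W x 3 array (single image) or H x W x 3 x N array (batch).
#' @export
to_three_channel <- function(image) {
  if (is.matrix(image)) {
    return(array(image, dim = c(nrow(image), ncol(image), 3L)))
  }
  d <- dim(image)
  if (length(d) != 3L) stop("expected a matrix or an H x W x N array", call. = FALSE)
  out <- array(0, dim = c(d[1], d[2], 3L, d[3]))
  for (ch in 1:3) out[, , ch, ] <- image
  out
}

#' Contrast-scaled perturbation set
#'
#' Forms contrast-scaled copies `sigma_k * x` of a batch of images, used for
#' the S and HL representational metrics.
#'
#' @param images An image array (any shape; scaling is elementwise).
#' @param sigmas Ordered nonnegative scale factors (default `c(0.2, 0.6, 1.0)`).
#' @return A `pv_perturbation_set`: list with `sigmas` and `batches` (one
#'   scaled copy per sigma, index-aligned).
#' @export
contrast_scale_batch <- function(images, sigmas = c(0.2, 0.6, 1.0)) {
  if (length(sigmas) == 0) stop("invalid config: sigmas must be nonempty", call. = FALSE)
  if (any(sigmas < 0)) stop("invalid config: negative sigma", call. = FALSE)
  structure(list(sigmas = sigmas,
                 batches = lapply(sigmas, function(s) images * s)),
            class = "pv_perturbation_set")
}

#' Seeded synthetic labeled-image fixture set
#'
#' Generates a small class-separable image set for download-free training
#' tests: each class is an oriented sinusoidal grating with a class-specific
#' orientation, spatial frequency and base phase, plus white noise and a small
#' random phase jitter per image (kept small so the classes remain separable
#' by a linear probe on raw pixels).  Pixel values are clipped to `[0, 1]`.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_per_class Images per class.
#' @param image_size Side length in pixels.
#' @param seed Integer seed; the set is deterministic given the seed.
#' @param noise_sd Standard deviation of the additive pixel noise.
#' @return List with `images` (H x W x N array), `labels` (integer 1..K) and
#'   `n_classes`.
#' @export
make_fixture_classification_set <- function(n_classes, n_per_class,
                                            image_size = 16L, seed = 1L,
                                            noise_sd = 0.1) {
  if (n_classes < 2) stop("invalid config: n_classes must be >= 2", call. = FALSE)
  n <- as.integer(image_size)
  N <- as.integer(n_classes * n_per_class)
  images <- array(0, dim = c(n, n, N))
  labels <- rep(seq_len(n_classes), each = n_per_class)
  xs <- matrix(seq_len(n), n, n, byrow = TRUE) / n
  ys <- matrix(seq_len(n), n, n) / n
  set.seed(as.integer(seed %% 2147483647))
  for (i in seq_len(N)) {
    k <- labels[i]
    theta <- (k - 1) * pi / n_classes
    freq <- 2 + (k - 1) %% 3
    phase <- (k - 1) * pi / 5 + stats::runif(1, 0, pi / 6)
    grating <- sin(2 * pi * freq * (cos(theta) * xs + sin(theta) * ys) + phase)
    img <- 0.5 + 0.25 * grating + stats::rnorm(n * n, sd = noise_sd)
    images[, , i] <- pmin(pmax(img, 0), 1)
  }
  list(images = images, labels = labels, n_classes = as.integer(n_classes))
}

#' Stack a trial set into network input
#'
#' @param trial_set A [generate_trial_set()] result.
#' @return List with `x` (H x W x 3 x N input array) and `y` (class labels,
#'   1 = absent, 2 = present).
#' @export
trial_set_input <- function(trial_set) {
  stopifnot(inherits(trial_set, "pv_trial_set"))
  list(x = to_three_channel(trial_set$stimuli),
       y = trial_set$labels + 1L)
}
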