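# Shared fixtures: tiny model configurations and deterministic random batches.

tiny_config <- function(variant = "cortical", n_classes = 3L, ...) {
  model_config(variant, image_size = 8L, channels = c(4L, 6L, 8L),
               n_classes = n_classes, seed = 42L, ...)
}

tiny_batch <- function(n = 4L, size = 8L, seed = 7L) {
  set.seed(seed)
  array(runif(size * size * 3L * n), c(size, size, 3L, n))
}

# Independent inverse-normal oracle: bisection on the normal CDF.
qnorm_bisect <- function(p, lo = -10, hi = 10, tol = 1e-12) {
  vapply(p, function(pp) {
    a <- lo; b <- hi
    while (b - a > tol) {
      mid <- (a + b) / 2
      if (stats::pnorm(mid) < pp) a <- mid else b <- mid
    }
    (a + b) / 2
  }, 1.0)
}

# Exact Wilcoxon signed-rank oracle: enumerate all 2^n sign assignments.
wilcoxon_enum <- function(deltas, alternative = "greater") {
  d <- deltas[deltas != 0]
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% rk)
  p_ge <- mean(Vs >= V - 1e-9)
  p_le <- mean(Vs <= V + 1e-9)
  if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
}

# Least-squares linear probe on raw pixels (oracle for fixture separability).
linear_probe_accuracy <- function(images, labels, train_frac = 0.7, seed = 1) {
  n <- length(labels)
  X <- cbind(1, t(matrix(images, ncol = n)))
  K <- max(labels)
  Y <- outer(labels, seq_len(K), "==") * 1
  set.seed(seed)
  tr <- sample.int(n, round(train_frac * n))
  B <- qr.solve(crossprod(X[tr, ]) + diag(1e-6, ncol(X)),
                crossprod(X[tr, ], Y[tr, ]))
  pred <- max.col(X[-tr, ] %*% B)
  mean(pred == labels[-tr])
}
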