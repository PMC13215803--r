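#' Paired Wilcoxon signed-rank test
#'
#' Zeros are removed; ties receive midranks.  For fewer than 25 nonzero
#' differences the p-value is exact, computed from the full distribution of
#' the signed-rank statistic under sign flips (a dynamic program over doubled
#' midranks, so ties are handled exactly); otherwise a normal approximation
#' with continuity and tie correction is used.  One-sided `"greater"` tests
#' the a-priori hypothesis that the median difference is positive.
#'
#' @param deltas Paired differences.
#' @param alternative `"two_sided"` or `"greater"`.
#' @param exact_below Sample-size threshold below which the exact distribution
#'   is used.
#' @return List with `statistic` (V, the positive-rank sum), `p`, `n`
#'   (nonzero differences) and `method`.
#' @export
paired_wilcoxon <- function(deltas, alternative = c("two_sided", "greater"),
                            exact_below = 25L) {
  alternative <- match.arg(alternative)
  d <- deltas[deltas != 0]
  if (length(d) < 3) stop("degenerate input: need >= 3 nonzero differences",
                          call. = FALSE)
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  if (n < exact_below) {
    ## Exact null distribution of 2*V over all 2^n sign assignments via DP on
    ## doubled midranks (integers).
    w <- as.integer(round(2 * rk))
    total <- sum(w)
    dist <- numeric(total + 1L)  # dist[s + 1] = #assignments with 2V = s
    dist[1] <- 1
    for (wi in w) {
      shifted <- c(rep(0, wi), dist[seq_len(total + 1L - wi)])
      dist <- dist + shifted
    }
    dist <- dist / 2^n
    s_obs <- as.integer(round(2 * V))
    p_ge <- sum(dist[(s_obs + 1L):(total + 1L)])
    p_le <- sum(dist[seq_len(s_obs + 1L)])
    p <- if (alternative == "greater") p_ge else min(1, 2 * min(p_ge, p_le))
    method <- "exact (sign-flip distribution)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5  # continuity correction
    if (alternative == "greater") {
      z <- (V - mu - cc) / sqrt(sig2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    } else {
      z <- (V - mu - sign(V - mu) * cc) / sqrt(sig2)
      p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
      p <- min(1, p)
    }
    method <- "normal approximation with continuity correction"
  }
  list(statistic = V, p = p, n = n, method = method)
}

#' Welch two-sample t-test with Cohen's d
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom, plus
#' Cohen's d computed with the pooled standard deviation.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @return List with `t`, `df`, `p` (two-sided), `cohen_d`.
#' @export
welch_cohen <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least two values", call. = FALSE)
  na <- length(group_a); nb <- length(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0 && mean(group_a) != mean(group_b))
    stop("degenerate variance: groups are constants with distinct means",
         call. = FALSE)
  se2 <- va / na + vb / nb
  tt <- (mean(group_a) - mean(group_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  d <- if (sp == 0) 0 else (mean(group_a) - mean(group_b)) / sp
  if (va == 0 && vb == 0) { tt <- 0; p <- 1 }
  list(t = tt, df = df, p = p, cohen_d = d)
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Kruskal-Wallis rank test with tie correction, followed by Dunn's pairwise
#' z-tests on mean ranks, adjusted for multiple comparisons.
#'
#' @param groups Named list of numeric vectors (>= 2 groups).
#' @param correction Multiple-comparison adjustment: `"bonferroni"` (default)
#'   or `"holm"`.
#' @return List with `H_stat`, `p` (overall), and `pairwise` (data frame with
#'   group pair, Dunn z, raw and adjusted p).
#' @export
kruskal_dunn <- function(groups, correction = c("bonferroni", "holm")) {
  correction <- match.arg(correction)
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  kw <- stats::kruskal.test(values, g)
  N <- length(values)
  rk <- rank(values)
  mean_ranks <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                   z = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(base_var * (1 / ns[[a]] + 1 / ns[[b]]))
    pw$z[i] <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    pw$p[i] <- 2 * stats::pnorm(abs(pw$z[i]), lower.tail = FALSE)
  }
  pw$p_adj <- stats::p.adjust(pw$p, method = correction)
  list(H_stat = unname(kw$statistic), p = kw$p.value, pairwise = pw)
}
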