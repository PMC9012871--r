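#' Rank-based cohort statistics
#'
#' Two-sided rank tests with exact small-sample enumeration (so p-values are
#' reproducible without continuity-correction ambiguity at small n) and ROC
#' analysis by pair counting.
#'
#' @name cohort_stats
NULL

new_test_result <- function(test_name, statistic, p_value, group_summaries,
                            extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, group_summaries = group_summaries),
              extra),
            class = "cf_test")
}

#' @export
print.cf_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g\n",
              x$test_name, x$statistic, x$p_value))
  invisible(x)
}

group_summary <- function(x) {
  data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
             median = stats::median(x))
}

# Mann-Whitney U for group a vs b with 1/2 tie credit
mw_u <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-sided Mann-Whitney / Wilcoxon rank-sum test
#'
#' Exact permutation enumeration when \code{min(n) <= 8} (handles ties);
#' midrank normal approximation with continuity correction otherwise. All
#' values tied gives p = 1 with a warning.
#'
#' @param a,b numeric samples (non-empty).
#' @return A test result: statistic U (for \code{a}), two-sided p, per-group
#'   summaries.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  u <- mw_u(a, b)
  mu <- n1 * n2 / 2
  if (length(unique(pooled)) == 1L) {
    warning("all values tied; p = 1")
    p <- 1
  } else if (min(n1, n2) <= 8 && N <= 20) {
    combs <- utils::combn(N, n1)
    dev <- abs(u - mu) - 1e-9
    us <- apply(combs, 2, function(i) mw_u(pooled[i], pooled[-i]))
    p <- mean(abs(us - mu) >= dev)
  } else {
    r <- rank(pooled)
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  new_test_result("Mann-Whitney U", u, p,
                  list(a = group_summary(a), b = group_summary(b)))
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (count reported); exact sign-pattern
#' enumeration for up to 12 non-zero pairs, normal approximation with tie
#' correction and continuity correction beyond.
#'
#' @param pre,post equal-length paired measurements.
#' @return A test result: statistic W (sum of positive-difference ranks),
#'   two-sided p, n_zero dropped pairs.
#' @export
paired_signed_rank <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  d <- post - pre
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences zero; p = 1")
    return(new_test_result("Wilcoxon signed-rank", 0, 1,
                           list(pairs = group_summary(post - pre)),
                           list(n_zero = n_zero)))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
  } else {
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(w - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  new_test_result("Wilcoxon signed-rank", w, p,
                  list(pre = group_summary(pre), post = group_summary(post)),
                  list(n_zero = n_zero))
}

#' Kruskal-Wallis test across groups
#'
#' H statistic with midrank ties correction; p from the chi-square
#' distribution with k-1 degrees of freedom.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return A test result.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!vapply(groups, length, 0L))) stop("groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(v) length(v) * (mean(v) - (N + 1) / 2)^2))
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h <- if (corr > 0) h / corr else 0
  p <- stats::pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  new_test_result("Kruskal-Wallis", h, p, lapply(groups, group_summary))
}

#' ROC curve and AUC by pair counting
#'
#' AUC is the probability that a random positive outranks a random negative,
#' with ties credited 1/2 — identical to U/(n1*n0) from the rank-sum
#' statistic. The full threshold curve is returned.
#'
#' @param scores numeric classifier scores (higher = more positive-like).
#' @param labels binary labels (0/1, logical, or a two-level factor whose
#'   second level is positive).
#' @return A \code{roc_result}: auc and a data.frame of thresholds with
#'   sensitivity/specificity.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), 0),
    specificity = vapply(thr, function(t) mean(neg < t), 0))
  structure(list(auc = auc, curve = curve,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}
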