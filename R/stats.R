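# Distribution comparisons applied to simulation-derived samples (e.g. the
# per-frame radius-of-gyration values of several systems): Kruskal-Wallis
# omnibus from pooled mid-ranks with tie correction, Conover-Iman post hoc
# with multiplicity adjustment, and Cohen's d effect sizes.

.pooled_ranks <- function(samples) {
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(names(samples), lengths(samples)), levels = names(samples))
  list(x = x, g = g, r = rank(x))  # mid-ranks on ties
}

.check_groups <- function(samples) {
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    names(samples) <- paste0("group", seq_along(samples))
  if (length(samples) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(samples) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  lapply(samples, as.numeric)
}

#' Kruskal-Wallis rank-sum test
#'
#' H is computed from pooled mid-ranks with the standard tie correction;
#' the p-value comes from the chi-square approximation with k - 1 degrees
#' of freedom. Identical observations across all groups give H = 0 and
#' p = 1 (not an error).
#'
#' @param samples named list of numeric vectors, one per group (>= 2
#'   groups, each >= 2 observations).
#' @return list with \code{H}, \code{df}, \code{p_value}.
#' @export
kruskal_wallis <- function(samples) {
  samples <- .check_groups(samples)
  pr <- .pooled_ranks(samples)
  N <- length(pr$x)
  rbar <- tapply(pr$r, pr$g, mean)
  n <- tapply(pr$r, pr$g, length)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(pr$x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  df <- length(samples) - 1L
  p <- if (H == 0) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  list(H = as.numeric(H), df = df, p_value = as.numeric(p))
}

#' Conover-Iman post hoc comparisons
#'
#' All pairwise comparisons after a Kruskal-Wallis omnibus on the same
#' grouped data. The t statistic for groups i, j is
#' \deqn{t = (Rbar_i - Rbar_j) / \sqrt{S^2 \frac{N - 1 - H}{N - k}
#'   (1/n_i + 1/n_j)}}
#' with \eqn{S^2 = (\sum R^2 - N (N+1)^2 / 4) / (N - 1)} over the pooled
#' mid-ranks; two-sided p-values use Student's t with N - k degrees of
#' freedom and are adjusted for multiplicity (Holm by default). Fully tied
#' data yield p = 1 everywhere.
#'
#' @inheritParams kruskal_wallis
#' @param method multiplicity adjustment passed to [stats::p.adjust()]
#'   (default \code{"holm"}).
#' @return list with \code{statistic} and \code{p_value} (symmetric k x k
#'   matrices, diagonal \code{NA}), \code{method}, and \code{pairs}, a
#'   data.frame with one row per unordered pair (\code{a}, \code{b},
#'   \code{t}, \code{p_raw}, \code{p_adj}).
#' @export
conover_posthoc <- function(samples, method = "holm") {
  samples <- .check_groups(samples)
  k <- length(samples)
  pr <- .pooled_ranks(samples)
  N <- length(pr$x)
  rbar <- tapply(pr$r, pr$g, mean)
  n <- tapply(pr$r, pr$g, length)
  H <- kruskal_wallis(samples)$H
  S2 <- (sum(pr$r^2) - N * (N + 1)^2 / 4) / (N - 1)
  degenerate <- S2 <= 0  # every observation tied
  tmat <- matrix(NA_real_, k, k, dimnames = list(names(samples), names(samples)))
  pmat <- tmat
  pairs <- utils::combn(k, 2)
  praw <- numeric(ncol(pairs)); tval <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    if (degenerate) {
      tval[c] <- 0; praw[c] <- 1
    } else {
      se <- sqrt(S2 * (N - 1 - H) / (N - k) * (1 / n[i] + 1 / n[j]))
      tval[c] <- (rbar[i] - rbar[j]) / se
      praw[c] <- 2 * stats::pt(abs(tval[c]), df = N - k, lower.tail = FALSE)
    }
  }
  padj <- stats::p.adjust(praw, method = method)
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    tmat[i, j] <- tval[c]; tmat[j, i] <- -tval[c]
    pmat[i, j] <- pmat[j, i] <- padj[c]
  }
  list(statistic = tmat, p_value = pmat, method = method,
       pairs = data.frame(a = names(samples)[pairs[1, ]],
                          b = names(samples)[pairs[2, ]],
                          t = tval, p_raw = praw, p_adj = padj,
                          stringsAsFactors = FALSE))
}

#' Cohen's d standardized mean difference
#'
#' d = (mean_a - mean_b) / pooled SD with the pooled SD
#' sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)).
#'
#' @param a,b numeric vectors, each with >= 2 observations.
#' @return d (errors on zero pooled SD).
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs >= 2 observations",
                               call. = FALSE)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) {
    if (mean(a) == mean(b)) return(0)
    stop("zero pooled SD with unequal means", call. = FALSE)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Verbal label for an effect size
#'
#' Conventional |d| thresholds: < 0.2 negligible, < 0.5 small, < 0.8
#' medium, else large.
#'
#' @param d Cohen's d value(s).
#' @return character vector.
#' @export
effect_size_label <- function(d) {
  a <- abs(d)
  ifelse(a < 0.2, "negligible",
         ifelse(a < 0.5, "small", ifelse(a < 0.8, "medium", "large")))
}

#' Compare grouped samples end to end
#'
#' Convenience wrapper running the Kruskal-Wallis omnibus, the Conover
#' post hoc comparisons and pairwise Cohen's d on the same grouped data
#' (e.g. radius-of-gyration distributions per system).
#'
#' @inheritParams conover_posthoc
#' @return list with \code{omnibus}, \code{posthoc} and
#'   \code{effect_sizes} (data.frame a, b, d, label).
#' @export
compare_distributions <- function(samples, method = "holm") {
  samples <- .check_groups(samples)
  om <- kruskal_wallis(samples)
  ph <- conover_posthoc(samples, method = method)
  pairs <- utils::combn(length(samples), 2)
  es <- data.frame(
    a = names(samples)[pairs[1, ]], b = names(samples)[pairs[2, ]],
    d = apply(pairs, 2L, function(ij) cohens_d(samples[[ij[1]]],
                                               samples[[ij[2]]])),
    stringsAsFactors = FALSE)
  es$label <- effect_size_label(es$d)
  list(omnibus = om, posthoc = ph, effect_sizes = es)
}
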