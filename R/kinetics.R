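# Enzyme kinetics and growth-curve quantification: Michaelis-Menten rates,
# the Lineweaver-Burk (double-reciprocal) estimator of Km/Vmax/specific
# activity, a nonlinear cross-check fit, exponential doubling times and
# percent-growth normalization.

#' Michaelis-Menten rate
#'
#' v = Vmax * S / (Km + S).
#'
#' @param S substrate concentration(s), mM (>= 0).
#' @param Km Michaelis constant, mM (> 0).
#' @param Vmax maximal rate (> 0).
#' @return rate(s), same units as Vmax.
#' @export
michaelis_menten_rate <- function(S, Km, Vmax) {
  stopifnot(Km > 0, Vmax > 0, all(S >= 0))
  Vmax * S / (Km + S)
}

#' Fit Michaelis-Menten parameters by Lineweaver-Burk regression
#'
#' Ordinary least squares of 1/v against 1/S; Vmax = 1/intercept,
#' Km = slope/intercept, and the specific activity is Vmax divided by the
#' enzyme amount (in absorbance units of extract). Zero-rate points are
#' excluded with a warning (their reciprocal is undefined); a non-positive
#' intercept means the data cannot be described by saturable kinetics and
#' is an error.
#'
#' @param substrate_mM substrate concentrations (> 0, >= 3 distinct).
#' @param rate measured initial rates (same length).
#' @param enzyme_au enzyme amount in absorbance units (default 1).
#' @return list of class \code{kinetics_fit}: \code{Km}, \code{Vmax},
#'   \code{specific_activity}, \code{r_squared} (of the double-reciprocal
#'   regression), \code{n} points used, \code{intercept}, \code{slope}.
#' @export
fit_lineweaver_burk <- function(substrate_mM, rate, enzyme_au = 1) {
  stopifnot(length(substrate_mM) == length(rate), all(substrate_mM > 0),
            enzyme_au > 0)
  keep <- rate > 0
  if (any(!keep))
    warning(sum(!keep), " zero-rate point(s) excluded from the reciprocal fit")
  S <- substrate_mM[keep]; v <- rate[keep]
  if (length(unique(S)) < 3L)
    stop("need >= 3 distinct substrate concentrations with v > 0",
         call. = FALSE)
  fit <- stats::lm(I(1 / v) ~ I(1 / S))
  b <- unname(stats::coef(fit))
  if (b[1] <= 0)
    stop("non-positive double-reciprocal intercept: data not fittable",
         call. = FALSE)
  Vmax <- 1 / b[1]
  Km <- b[2] / b[1]
  y <- 1 / v
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(Km = Km, Vmax = Vmax,
                 specific_activity = Vmax / enzyme_au,
                 r_squared = r2,
                 n = length(S), intercept = b[1], slope = b[2]),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (Lineweaver-Burk, n = %d)\n", x$n))
  cat(sprintf("  Km   = %.4g mM\n  Vmax = %.4g\n  SA   = %.4g per au\n  R^2(1/v ~ 1/S) = %.6f\n",
              x$Km, x$Vmax, x$specific_activity, x$r_squared))
  invisible(x)
}

#' Fit Michaelis-Menten parameters by nonlinear least squares
#'
#' Direct Levenberg-Marquardt fit of v = Vmax S / (Km + S), provided as a
#' cross-check on the double-reciprocal estimator (the two agree exactly
#' on noiseless data).
#'
#' @inheritParams fit_lineweaver_burk
#' @return list of class \code{kinetics_fit} (with \code{r_squared} of the
#'   nonlinear fit and \code{NA} slope/intercept).
#' @export
fit_michaelis_menten <- function(substrate_mM, rate, enzyme_au = 1) {
  stopifnot(length(substrate_mM) == length(rate), all(substrate_mM > 0),
            enzyme_au > 0)
  start <- list(Km = stats::median(substrate_mM), Vmax = max(rate) * 1.2)
  fit <- minpack.lm::nlsLM(rate ~ Vmax * substrate_mM / (Km + substrate_mM),
                           start = start,
                           lower = c(Km = 1e-12, Vmax = 1e-12))
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((rate - mean(rate))^2)
  structure(list(Km = unname(cf["Km"]), Vmax = unname(cf["Vmax"]),
                 specific_activity = unname(cf["Vmax"]) / enzyme_au,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n = length(rate), intercept = NA_real_, slope = NA_real_),
            class = "kinetics_fit")
}

#' Doubling time from a growth curve
#'
#' td = ln(2) (t2 - t1) / (ln OD2 - ln OD1) over a caller-chosen window of
#' the exponential phase. Invariant to rescaling OD by a positive constant
#' and to shifting the time origin.
#'
#' @param time_h times in hours (strictly increasing).
#' @param od optical densities (A600, path-corrected; > 0 within the
#'   window).
#' @param t1,t2 window endpoints (must be observed time points,
#'   t1 < t2); if both \code{NULL}, the window is chosen automatically via
#'   [find_log_linear_window()].
#' @return doubling time in hours.
#' @export
doubling_time <- function(time_h, od, t1 = NULL, t2 = NULL) {
  stopifnot(length(time_h) == length(od), !is.unsorted(time_h, strictly = TRUE))
  if (is.null(t1) && is.null(t2)) {
    w <- find_log_linear_window(time_h, od)
    t1 <- w[1]; t2 <- w[2]
  }
  i1 <- match(t1, time_h); i2 <- match(t2, time_h)
  if (is.na(i1) || is.na(i2) || i1 >= i2)
    stop("t1 and t2 must be observed time points with t1 < t2", call. = FALSE)
  od1 <- od[i1]; od2 <- od[i2]
  if (od1 <= 0 || od2 <= od1)
    stop("OD must be positive and increasing over the window", call. = FALSE)
  log(2) * (t2 - t1) / (log(od2) - log(od1))
}

#' Locate the log-linear (exponential) portion of a growth curve
#'
#' Heuristic: among all candidate windows of at least \code{min_points}
#' consecutive positive-OD observations, pick the longest (ties: earliest)
#' whose regression of log(OD) on time has R^2 >= \code{r2_min}.
#'
#' @inheritParams doubling_time
#' @param r2_min minimum R^2 of log(OD) ~ time (default 0.99).
#' @param min_points minimum window size (default 4).
#' @return c(t1, t2), the chosen window endpoints.
#' @export
find_log_linear_window <- function(time_h, od, r2_min = 0.99, min_points = 4L) {
  stopifnot(length(time_h) == length(od))
  n <- length(time_h)
  best <- NULL; best_len <- 0L
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq.int(i + min_points - 1L, n)) {
      if (any(od[i:j] <= 0) || od[j] <= od[i]) next
      y <- log(od[i:j])
      fit <- stats::lm(y ~ time_h[i:j])
      r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
      if (r2 >= r2_min && (j - i + 1L) > best_len) {
        best <- c(time_h[i], time_h[j]); best_len <- j - i + 1L
      }
    }
  }
  if (is.null(best))
    stop("no log-linear window with R^2 >= ", r2_min, " found", call. = FALSE)
  best
}

#' Percent growth relative to an untreated culture
#'
#' 100 * OD_treated / OD_untreated, the normalization used for drug
#' resistance growth read-outs.
#'
#' @param od_treated,od_untreated final optical densities;
#'   \code{od_untreated} must be positive.
#' @return percent.
#' @export
percent_growth <- function(od_treated, od_untreated) {
  if (any(od_untreated <= 0)) stop("untreated OD must be positive",
                                   call. = FALSE)
  100 * od_treated / od_untreated
}
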