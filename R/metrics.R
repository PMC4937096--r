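#' Spearman rank correlation with p-value
#'
#' Pearson correlation of average ranks (ties allowed), with a p-value from
#' the large-sample approximation (via [stats::cor.test()]). Used for the
#' within-pair survival-duration correlations.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A list with `rho`, `p`, and `n`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho # 0.6
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_rho: correlation undefined for constant input",
         call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  list(rho = rho, p = p, n = length(x))
}

#' Gini coefficient
#'
#' The uncorrected relative mean absolute difference,
#' `G = sum_ij |w_i - w_j| / (2 n^2 mean(w))`, computed via the exact
#' sorted-sum identity `G = 2 sum(i * w_(i)) / (n * sum(w)) - (n + 1)/n`.
#' 0 means perfect equality; `(n-1)/n` means one holder owns everything.
#'
#' @param wealth Non-negative numeric vector with at least one positive
#'   value.
#' @return The Gini coefficient in `[0, 1)`.
#' @examples
#' gini(c(1, 1, 1, 1)) # 0
#' gini(c(0, 1))       # 0.5
#' @export
gini <- function(wealth) {
  stopifnot(is.numeric(wealth), length(wealth) >= 1)
  if (any(wealth < 0)) stop("gini: wealth must be non-negative", call. = FALSE)
  if (all(wealth == 0))
    stop("gini: undefined when all holdings are zero", call. = FALSE)
  n <- length(wealth)
  s <- sort(wealth)
  2 * sum(seq_len(n) * s) / (n * sum(s)) - (n + 1) / n
}

#' Lorenz curve
#'
#' Cumulative population share against cumulative wealth share with
#' holdings sorted ascending, starting at (0, 0). Perfect equality gives
#' the diagonal.
#'
#' @inheritParams gini
#' @return A data frame of class `lorenz_curve` with columns `pop_share`
#'   and `wealth_share`.
#' @examples
#' lorenz_curve(c(0, 1)) # points (0,0), (0.5,0), (1,1)
#' @export
lorenz_curve <- function(wealth) {
  stopifnot(is.numeric(wealth), length(wealth) >= 1)
  if (any(wealth < 0))
    stop("lorenz_curve: wealth must be non-negative", call. = FALSE)
  if (all(wealth == 0))
    stop("lorenz_curve: undefined when all holdings are zero", call. = FALSE)
  n <- length(wealth)
  s <- sort(wealth)
  out <- data.frame(pop_share = c(0, seq_len(n) / n),
                    wealth_share = c(0, cumsum(s) / sum(s)))
  class(out) <- c("lorenz_curve", "data.frame")
  out
}

# Gini from the area under a Lorenz curve (trapezoid rule); cross-oracle
# for gini() in the tests
lorenz_gini <- function(curve) {
  p <- curve$pop_share
  l <- curve$wealth_share
  auc <- sum(diff(p) * (l[-length(l)] + l[-1]) / 2)
  1 - 2 * auc
}

#' @export
plot.lorenz_curve <- function(x, ..., main = "Lorenz curve") {
  graphics::plot(x$pop_share, x$wealth_share, type = "l", lwd = 2,
                 xlab = "cumulative population share",
                 ylab = "cumulative wealth share", main = main, ...)
  graphics::abline(0, 1, col = "grey60")
  invisible(x)
}

# percentile bootstrap CI of a statistic over a vector; uses the current
# RNG stream (callers seed it)
boot_ci <- function(x, stat = mean, n_boot = 1000L, level = 0.95) {
  reps <- vapply(seq_len(n_boot),
                 function(i) stat(x[sample.int(length(x), replace = TRUE)]),
                 numeric(1))
  alpha <- (1 - level) / 2
  stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
}

#' Summarise survival times of a replicate collection
#'
#' Pools the survival times of both households (or one focal side) across
#' replicates and reports the median and mean survival duration and the
#' proportion of herds alive at the horizon, each with a
#' percentile-bootstrap 95 % confidence interval, plus the per-year
#' survival curve. The bootstrap resamples whole replicate pairs, so the
#' within-pair coupling that transfers create is respected. Censored times
#' enter at the horizon value: survival is treated as a plain duration,
#' not with survival-analysis censoring machinery.
#'
#' @param results A `herdpool_replicates` data frame from
#'   [run_replicates()].
#' @param focal `"both"` (pool the two agents), `"a"` or `"b"`.
#' @param n_boot Bootstrap resamples for the CIs (drawn from the current
#'   RNG stream; seed before calling for reproducibility).
#' @return A list of class `survival_summary` with `median`, `mean`,
#'   `prop_alive`, their `_ci` bounds, `curve` (data frame `year`,
#'   `prop_alive`), and `n`.
#' @export
survival_summary <- function(results, focal = c("both", "a", "b"),
                             n_boot = 1000L) {
  focal <- match.arg(focal)
  stopifnot(inherits(results, "herdpool_replicates"), nrow(results) >= 1)
  env <- attr(results, "env")
  horizon <- env$horizon
  surv_m <- switch(focal,
                   both = cbind(results$survival_a, results$survival_b),
                   a = cbind(results$survival_a),
                   b = cbind(results$survival_b))
  cens_m <- switch(focal,
                   both = cbind(results$censored_a, results$censored_b),
                   a = cbind(results$censored_a),
                   b = cbind(results$censored_b))
  surv <- as.vector(surv_m)
  cens <- as.vector(cens_m)
  years <- 0:horizon
  curve <- vapply(years, function(t) mean(cens | surv > t), numeric(1))

  n_rep <- nrow(surv_m)
  boot <- matrix(NA_real_, n_boot, 3L)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n_rep, replace = TRUE)
    s <- as.vector(surv_m[idx, , drop = FALSE])
    boot[i, ] <- c(stats::median(s), mean(s),
                   mean(as.vector(cens_m[idx, , drop = FALSE])))
  }
  ci <- function(k) stats::quantile(boot[, k], c(0.025, 0.975),
                                    names = FALSE, type = 7)
  out <- list(
    median = stats::median(surv),
    mean = mean(surv),
    prop_alive = mean(cens),
    median_ci = ci(1), mean_ci = ci(2), prop_ci = ci(3),
    curve = data.frame(year = years, prop_alive = curve),
    n = length(surv))
  class(out) <- "survival_summary"
  out
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf("Survival over %d household-runs\n", x$n))
  cat(sprintf("  median %g yr [%g, %g], mean %.2f yr [%.2f, %.2f]\n",
              x$median, x$median_ci[1], x$median_ci[2],
              x$mean, x$mean_ci[1], x$mean_ci[2]))
  cat(sprintf("  alive at horizon: %.1f%% [%.1f%%, %.1f%%]\n",
              100 * x$prop_alive, 100 * x$prop_ci[1], 100 * x$prop_ci[2]))
  invisible(x)
}

#' @export
plot.survival_summary <- function(x, ..., main = "Herd survival") {
  graphics::plot(x$curve$year, x$curve$prop_alive, type = "s", lwd = 2,
                 ylim = c(0, 1), xlab = "year",
                 ylab = "proportion of herds alive", main = main, ...)
  invisible(x)
}
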