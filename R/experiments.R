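# experiment drivers: each reproduces one results subsection of the study
# design. Every driver derives all of its randomness (replicate seeds,
# bootstrap resamples) from `base_seed`, in a fixed order, so a run is
# reproducible bit-for-bit.

derive_seeds <- function(base_seed, k) {
  set.seed(as.integer(base_seed))
  sample.int(2147483646L, k)
}

#' Within-pair survival correlation experiment
#'
#' Runs four conditions — no exchange, account keeping, mixed (agent A
#' account keeping, agent B need based), and need based — and reports the
#' Spearman rank correlation between the two households' survival durations
#' in each. Transfers couple the partners' fates: the correlation measures
#' how much risk the pair actually pools.
#'
#' @param n Replicate pairs per condition.
#' @param env An [env_params()] object (baseline ecology by default).
#' @param base_seed Integer seed driving every replicate.
#' @param nbt,ak Strategy templates for the need-based and account-keeping
#'   agents.
#' @return A data frame of class `herdpool_correlations` with columns
#'   `condition`, `n`, `rho`, `p`.
#' @examples
#' \donttest{
#' correlation_experiment(n = 500, base_seed = 7)
#' }
#' @export
correlation_experiment <- function(n = 10000L, env = env_params(),
                                   base_seed = 1L,
                                   nbt = strategy_params("need_based"),
                                   ak = strategy_params("account_keeping")) {
  stopifnot(n >= 100)
  none <- strategy_params("none")
  conditions <- list(
    none = list(none, none),
    account_keeping = list(ak, ak),
    mixed = list(ak, nbt),
    need_based = list(nbt, nbt))
  seeds <- derive_seeds(base_seed, length(conditions))
  rows <- vector("list", length(conditions))
  for (i in seq_along(conditions)) {
    st <- conditions[[i]]
    reps <- run_replicates(env, st[[1]], st[[2]], n = n, base_seed = seeds[i])
    ct <- spearman_rho(reps$survival_a, reps$survival_b)
    rows[[i]] <- data.frame(condition = names(conditions)[i], n = ct$n,
                            rho = ct$rho, p = ct$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "env") <- env
  attr(out, "base_seed") <- as.integer(base_seed)
  class(out) <- c("herdpool_correlations", "data.frame")
  out
}

#' @export
print.herdpool_correlations <- function(x, ...) {
  cat("Within-pair Spearman correlations of herd survival durations\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-16s rho = %6.3f  (p = %.3g, n = %d)\n",
                x$condition[i], x$rho[i], x$p[i], x$n[i]))
  invisible(x)
}

# run one pairing at one environment and summarise pooled survival
sweep_cell <- function(env, strat, n, run_seed, boot_seed, n_boot) {
  reps <- run_replicates(env, strat, strat, n = n, base_seed = run_seed)
  set.seed(boot_seed)
  survival_summary(reps, focal = "both", n_boot = n_boot)
}

sweep_row <- function(value, strategy, s) {
  data.frame(value = value, strategy = strategy,
             mean = s$mean, mean_lo = s$mean_ci[1], mean_hi = s$mean_ci[2],
             median = s$median, prop_alive = s$prop_alive,
             prop_lo = s$prop_ci[1], prop_hi = s$prop_ci[2])
}

#' Environmental volatility sweep
#'
#' Varies one volatility parameter — the mean loss size (`"size"`, 0 to
#' 50 % of the herd) or the annual loss rate (`"rate"`, 0 to 20 %/year) —
#' holding the other at its baseline, and compares pooled survival of
#' need-based-transfer pairs against account-keeping pairs (and optionally
#' no-exchange pairs) at every grid point.
#'
#' @param axis `"size"` (vary `shock_size_mean`) or `"rate"` (vary
#'   `shock_rate`).
#' @param grid Parameter values; defaults to 11 evenly spaced points over
#'   the swept range.
#' @param n Replicate pairs per grid cell and pairing.
#' @param env Baseline ecology; the swept key is overwritten per cell.
#' @param base_seed Integer seed.
#' @param include_none Also run the no-exchange pairing?
#' @param n_boot Bootstrap resamples for the 95 % CIs.
#' @inheritParams correlation_experiment
#' @return A data frame of class `herdpool_sweep` (columns `value`,
#'   `strategy`, `mean`, `mean_lo`, `mean_hi`, `median`, `prop_alive`).
#' @export
volatility_sweep <- function(axis = c("size", "rate"), grid = NULL,
                             n = 2000L, env = env_params(), base_seed = 1L,
                             include_none = FALSE, n_boot = 1000L,
                             nbt = strategy_params("need_based"),
                             ak = strategy_params("account_keeping")) {
  axis <- match.arg(axis)
  if (is.null(grid))
    grid <- if (axis == "size") seq(0, 0.5, by = 0.05) else seq(0, 0.2, by = 0.02)
  if (axis == "size") stopifnot(all(grid >= 0 & grid <= 0.5))
  else stopifnot(all(grid >= 0 & grid <= 0.2))
  stopifnot(!is.unsorted(grid, strictly = TRUE))

  strats <- list(need_based = nbt, account_keeping = ak)
  if (include_none) strats$none <- strategy_params("none")
  n_cells <- length(grid) * length(strats)
  seeds <- derive_seeds(base_seed, 2L * n_cells)
  rows <- vector("list", n_cells)
  k <- 0L
  for (g in grid) {
    cell_env <- env
    if (axis == "size") {
      cell_env$shock_size_mean <- g
      # severity spread scales with severity (constant CV), so that the
      # zero-size limit really is lossless
      cell_env$shock_size_sd <- if (env$shock_size_mean > 0)
        env$shock_size_sd * g / env$shock_size_mean else 0
    } else {
      cell_env$shock_rate <- g
    }
    for (sname in names(strats)) {
      k <- k + 1L
      s <- sweep_cell(cell_env, strats[[sname]], n,
                      run_seed = seeds[2L * k - 1L], boot_seed = seeds[2L * k],
                      n_boot = n_boot)
      rows[[k]] <- sweep_row(g, sname, s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "axis") <- axis
  attr(out, "env") <- env
  attr(out, "n") <- as.integer(n)
  attr(out, "base_seed") <- as.integer(base_seed)
  class(out) <- c("herdpool_sweep", "data.frame")
  out
}

#' @export
plot.herdpool_sweep <- function(x, ...,
                                main = paste("Volatility", attr(x, "axis"), "sweep")) {
  strategies <- unique(x$strategy)
  cols <- stats::setNames(c("firebrick", "steelblue", "darkgreen")[seq_along(strategies)],
                          strategies)
  graphics::plot(range(x$value), range(c(x$mean_lo, x$mean_hi)), type = "n",
                 xlab = attr(x, "axis"), ylab = "mean survival (yr)",
                 main = main, ...)
  for (s in strategies) {
    d <- x[x$strategy == s, ]
    graphics::polygon(c(d$value, rev(d$value)), c(d$mean_lo, rev(d$mean_hi)),
                      col = grDevices::adjustcolor(cols[[s]], 0.2), border = NA)
    graphics::lines(d$value, d$mean, col = cols[[s]], lwd = 2)
  }
  graphics::legend("topright", legend = strategies, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Generosity sweep
#'
#' Varies generosity — the probability of giving when asked and able
#' (need based) or when the partner is in good standing (account keeping) —
#' and compares each transfer strategy's survival against the no-exchange
#' baseline. Also detects, per strategy and jointly, the smallest
#' generosity level from which the strategy consistently beats the
#' baseline: 95 % bootstrap CIs non-overlapping at that level and at every
#' higher one.
#'
#' The comparison statistic is the proportion of herds alive at the
#' horizon (`threshold_stat = "prop_alive"`, the scale the payoff analyses
#' use) or the mean survival duration (`"mean"`).
#'
#' @param levels Generosity levels in `[0, 1]` (default a 10-point-step
#'   grid, 0 to 1).
#' @param n Replicate pairs per level per strategy (and for the baseline).
#' @param threshold_stat Statistic for the threshold detection:
#'   `"prop_alive"` (default) or `"mean"`.
#' @inheritParams volatility_sweep
#' @return A list of class `herdpool_generosity` with elements `table`
#'   (per-level summaries), `baseline` (the no-exchange summary row), and
#'   `thresholds` (per-strategy and `both`, as fractions; `NA` if never
#'   consistently better).
#' @export
generosity_sweep <- function(levels = seq(0, 1, by = 0.1), n = 2000L,
                             env = env_params(), base_seed = 1L,
                             n_boot = 1000L,
                             threshold_stat = c("prop_alive", "mean"),
                             nbt = strategy_params("need_based"),
                             ak = strategy_params("account_keeping")) {
  threshold_stat <- match.arg(threshold_stat)
  stopifnot(all(levels >= 0 & levels <= 1),
            !is.unsorted(levels, strictly = TRUE))
  templates <- list(need_based = nbt, account_keeping = ak)
  n_cells <- 2L * length(levels) + 1L
  seeds <- derive_seeds(base_seed, 2L * n_cells)
  rows <- vector("list", 2L * length(levels))
  k <- 0L
  for (g in levels) {
    for (sname in names(templates)) {
      k <- k + 1L
      strat <- templates[[sname]]
      strat$generosity <- g
      s <- sweep_cell(env, strat, n,
                      run_seed = seeds[2L * k - 1L], boot_seed = seeds[2L * k],
                      n_boot = n_boot)
      rows[[k]] <- sweep_row(g, sname, s)
    }
  }
  base_sum <- sweep_cell(env, strategy_params("none"), n,
                         run_seed = seeds[2L * n_cells - 1L],
                         boot_seed = seeds[2L * n_cells], n_boot = n_boot)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  baseline <- sweep_row(NA_real_, "none", base_sum)

  beats <- if (threshold_stat == "prop_alive")
    function(row) row$prop_lo > baseline$prop_hi
  else
    function(row) row$mean_lo > baseline$mean_hi
  wins <- function(sname) {
    d <- tab[tab$strategy == sname, ]
    vapply(seq_len(nrow(d)), function(i) beats(d[i, ]), logical(1))
  }
  first_level <- function(ok) if (!any(ok)) NA_real_ else levels[which(ok)[1]]
  w_nbt <- wins("need_based")
  w_ak <- wins("account_keeping")
  thr <- list(need_based = first_level(w_nbt),
              account_keeping = first_level(w_ak),
              both = first_level(w_nbt & w_ak))

  out <- list(table = tab, baseline = baseline, thresholds = thr)
  attr(out, "threshold_stat") <- threshold_stat
  attr(out, "env") <- env
  attr(out, "n") <- as.integer(n)
  attr(out, "base_seed") <- as.integer(base_seed)
  class(out) <- "herdpool_generosity"
  out
}

#' @export
print.herdpool_generosity <- function(x, ...) {
  cat("Generosity sweep: mean survival (yr) vs no-exchange baseline\n")
  cat(sprintf("  baseline (no exchange): %.2f [%.2f, %.2f]\n",
              x$baseline$mean, x$baseline$mean_lo, x$baseline$mean_hi))
  fmt_thr <- function(v) if (is.na(v)) "never" else sprintf("%.0f%%", 100 * v)
  cat(sprintf("  consistently beats baseline from: need-based %s, account-keeping %s, both %s\n",
              fmt_thr(x$thresholds$need_based),
              fmt_thr(x$thresholds$account_keeping), fmt_thr(x$thresholds$both)))
  print(x$table, digits = 4)
  invisible(x)
}

#' Survival payoff matrix with dominance check
#'
#' Builds the 2x2 payoff matrix over need-based and account-keeping
#' strategies: each cell is the percentage of focal (row-strategy)
#' households whose herds are still alive at the horizon when paired with a
#' column-strategy partner. Same-strategy cells pool both members of the
#' pair; mixed cells come from the same mixed runs with roles tracked.
#'
#' The game between the two transfer strategies is a Stag Hunt: both
#' same-strategy pairings are coordination points, and the claim that need
#' based "dominates" account keeping is payoff dominance of the mutual
#' need-based equilibrium — pairs of need-based households survive better
#' than pairs of account keepers. The verdict `dominant` therefore tests
#' `cell(NBT, NBT) > cell(AK, AK)` with non-overlapping 95 % bootstrap
#' CIs; `strictly_dominant` additionally reports the stronger (and, in a
#' coordination game, not expected) column-wise strategy dominance.
#'
#' @param n Replicate pairs per pairing.
#' @inheritParams volatility_sweep
#' @return A list of class `herdpool_payoff` with `payoff`, `ci_lo`,
#'   `ci_hi` (2x2 matrices, rows = focal strategy, in percent),
#'   `dominant` (payoff dominance of mutual need-based transfers) and
#'   `strictly_dominant` (column-wise strategy dominance).
#' @export
payoff_matrix <- function(n = 2000L, env = env_params(), base_seed = 1L,
                          n_boot = 1000L,
                          nbt = strategy_params("need_based"),
                          ak = strategy_params("account_keeping")) {
  stopifnot(n >= 100)
  seeds <- derive_seeds(base_seed, 4L)
  reps_nbt <- run_replicates(env, nbt, nbt, n = n, base_seed = seeds[1])
  reps_ak <- run_replicates(env, ak, ak, n = n, base_seed = seeds[2])
  reps_mix <- run_replicates(env, ak, nbt, n = n, base_seed = seeds[3])

  pooled_pct <- function(reps) {
    # bootstrap over replicates, keeping the two pair members together
    draw <- function(idx) 100 * mean(c(reps$alive_a[idx], reps$alive_b[idx]))
    list(value = draw(seq_len(nrow(reps))),
         boot = function() draw(sample.int(nrow(reps), replace = TRUE)))
  }
  focal_pct <- function(reps, side) {
    v <- if (side == "a") reps$alive_a else reps$alive_b
    list(value = 100 * mean(v),
         boot = function() 100 * mean(v[sample.int(length(v), replace = TRUE)]))
  }
  cells <- list(
    nbt_nbt = pooled_pct(reps_nbt),
    nbt_ak = focal_pct(reps_mix, "b"),   # mixed runs: a = AK, b = NBT
    ak_nbt = focal_pct(reps_mix, "a"),
    ak_ak = pooled_pct(reps_ak))

  set.seed(seeds[4])
  ci <- lapply(cells, function(cell) {
    reps <- vapply(seq_len(n_boot), function(i) cell$boot(), numeric(1))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  })

  strategies <- c("need_based", "account_keeping")
  mk <- function(f) matrix(f, 2, 2, byrow = TRUE,
                           dimnames = list(focal = strategies,
                                           partner = strategies))
  payoff <- mk(c(cells$nbt_nbt$value, cells$nbt_ak$value,
                 cells$ak_nbt$value, cells$ak_ak$value))
  ci_lo <- mk(c(ci$nbt_nbt[1], ci$nbt_ak[1], ci$ak_nbt[1], ci$ak_ak[1]))
  ci_hi <- mk(c(ci$nbt_nbt[2], ci$nbt_ak[2], ci$ak_nbt[2], ci$ak_ak[2]))

  # payoff dominance of the mutual-NBT coordination point over mutual AK
  dominant <- ci_lo["need_based", "need_based"] >
    ci_hi["account_keeping", "account_keeping"]
  # column-wise: NBT focal beats AK focal against the same partner type
  strictly_dominant <- all(ci_lo["need_based", ] >
                             ci_hi["account_keeping", ])

  out <- list(payoff = payoff, ci_lo = ci_lo, ci_hi = ci_hi,
              dominant = dominant, strictly_dominant = strictly_dominant)
  attr(out, "env") <- env
  attr(out, "n") <- as.integer(n)
  attr(out, "base_seed") <- as.integer(base_seed)
  class(out) <- "herdpool_payoff"
  out
}

#' @export
print.herdpool_payoff <- function(x, ...) {
  cat("Survival at horizon (% of focal households), focal x partner\n")
  print(round(x$payoff, 1))
  cat(if (x$dominant)
    "Mutual need-based transfers payoff-dominate mutual account keeping (non-overlapping 95% CIs).\n"
  else
    "Payoff dominance of need-based transfers NOT established at 95% CIs.\n")
  invisible(x)
}

#' Wealth-inequality experiment
#'
#' Runs the three symmetric conditions (no exchange, account keeping, need
#' based), pools the final-census herd sizes across replicates, and
#' computes the Gini coefficient and Lorenz curve per condition, optionally
#' with a per-year Gini series.
#'
#' @param n Replicate pairs per condition.
#' @param census `"living_final"` (default: final herds of living
#'   households only) or `"all_final"` (dead households enter at herd 0).
#' @param series Also compute the per-year Gini series (records
#'   trajectories; slower and more memory-hungry)?
#' @inheritParams volatility_sweep
#' @return A list of class `herdpool_inequality` with `table` (columns
#'   `condition`, `n_census`, `gini`), `lorenz` (one [lorenz_curve()] per
#'   condition), and, when `series = TRUE`, `series` (columns `year`,
#'   `condition`, `gini`).
#' @export
inequality_experiment <- function(n = 10000L, env = env_params(),
                                  base_seed = 1L,
                                  census = c("living_final", "all_final"),
                                  series = FALSE,
                                  nbt = strategy_params("need_based"),
                                  ak = strategy_params("account_keeping")) {
  stopifnot(n >= 100)
  census <- match.arg(census)
  conditions <- list(none = strategy_params("none"),
                     account_keeping = ak,
                     need_based = nbt)
  seeds <- derive_seeds(base_seed, length(conditions))
  tab <- vector("list", length(conditions))
  lorenz <- list()
  series_rows <- list()
  for (i in seq_along(conditions)) {
    cname <- names(conditions)[i]
    st <- conditions[[i]]
    reps <- run_replicates(env, st, st, n = n, base_seed = seeds[i],
                           trajectories = series)
    wealth <- if (census == "living_final")
      c(reps$herd_a[reps$alive_a], reps$herd_b[reps$alive_b])
    else
      c(ifelse(reps$alive_a, reps$herd_a, 0),
        ifelse(reps$alive_b, reps$herd_b, 0))
    if (length(wealth) == 0 || all(wealth == 0))
      stop("inequality_experiment: no surviving wealth in condition '",
           cname, "'", call. = FALSE)
    tab[[i]] <- data.frame(condition = cname, n_census = length(wealth),
                           gini = gini(wealth))
    lorenz[[cname]] <- lorenz_curve(wealth)
    if (series) {
      traj <- attr(reps, "trajectories")
      gs <- vapply(seq_len(env$horizon), function(t) {
        alive_a <- reps$censored_a | reps$survival_a > t
        alive_b <- reps$censored_b | reps$survival_b > t
        w <- c(traj[t + 1L, 1L, ][alive_a], traj[t + 1L, 2L, ][alive_b])
        if (length(w) < 2 || all(w == 0)) NA_real_ else gini(w)
      }, numeric(1))
      series_rows[[cname]] <- data.frame(year = seq_len(env$horizon),
                                         condition = cname, gini = gs)
    }
  }
  out <- list(table = do.call(rbind, tab), lorenz = lorenz)
  rownames(out$table) <- NULL
  if (series) {
    out$series <- do.call(rbind, series_rows)
    rownames(out$series) <- NULL
  }
  attr(out, "env") <- env
  attr(out, "n") <- as.integer(n)
  attr(out, "base_seed") <- as.integer(base_seed)
  attr(out, "census") <- census
  class(out) <- "herdpool_inequality"
  out
}

#' @export
print.herdpool_inequality <- function(x, ...) {
  cat("Wealth inequality at the final census (", attr(x, "census"), ")\n",
      sep = "")
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  %-16s Gini %.3f  (%d households)\n",
                x$table$condition[i], x$table$gini[i], x$table$n_census[i]))
  invisible(x)
}

#' @export
plot.herdpool_inequality <- function(x, ..., main = "Lorenz curves") {
  cols <- c(none = "darkgreen", account_keeping = "steelblue",
            need_based = "firebrick")
  graphics::plot(c(0, 1), c(0, 1), type = "n",
                 xlab = "cumulative population share",
                 ylab = "cumulative wealth share", main = main, ...)
  graphics::abline(0, 1, col = "grey60")
  for (cname in names(x$lorenz))
    graphics::lines(x$lorenz[[cname]]$pop_share,
                    x$lorenz[[cname]]$wealth_share,
                    col = cols[[cname]], lwd = 2)
  graphics::legend("topleft", legend = names(x$lorenz),
                   col = cols[names(x$lorenz)], lwd = 2, bty = "n")
  invisible(x)
}
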