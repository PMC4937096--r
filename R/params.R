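#' Environment (ecology) parameters
#'
#' Bundles the ecological constants of the herder world: stochastic annual
#' herd growth, the shock (drought/disease) process, the maximum herd a
#' household can manage, the minimum viable herd, the starting herd, and the
#' simulation horizon.
#'
#' Defaults reproduce the baseline ecology: herds of 70 head growing at a
#' mean 3.4 %/year, capped at 600 head, with a 10 %/year chance of losing a
#' Normal(30 %, 10 %) fraction of the herd, and a 64-head viability
#' threshold below which a household's herd fails, over a 50-year horizon.
#'
#' @param growth_mean Mean annual herd growth rate (fraction/year).
#' @param growth_sd Standard deviation of the annual growth rate.
#' @param shock_rate Per-year probability that a herd suffers a loss event
#'   (the "volatility rate").
#' @param shock_size_mean Mean fraction of the herd lost in a loss event
#'   (the "volatility size"); realized fractions are truncated to `[0, 1]`.
#' @param shock_size_sd Standard deviation of the loss fraction.
#' @param herd_cap Maximum herd size (head).
#' @param viability_threshold Minimum viable herd (head); a herd strictly
#'   below this at the end-of-year check dies.
#' @param initial_herd Starting herd size (head).
#' @param horizon Number of simulated years.
#'
#' @return An object of class `env_params` (a validated named list).
#' @examples
#' env <- env_params()
#' env$shock_rate
#' calm <- env_params(shock_rate = 0) # no losses ever occur
#' @export
env_params <- function(growth_mean = 0.034,
                       growth_sd = 0.025,
                       shock_rate = 0.10,
                       shock_size_mean = 0.30,
                       shock_size_sd = 0.10,
                       herd_cap = 600,
                       viability_threshold = 64,
                       initial_herd = 70,
                       horizon = 50L) {
  env <- list(
    growth_mean = as.numeric(growth_mean),
    growth_sd = as.numeric(growth_sd),
    shock_rate = as.numeric(shock_rate),
    shock_size_mean = as.numeric(shock_size_mean),
    shock_size_sd = as.numeric(shock_size_sd),
    herd_cap = as.numeric(herd_cap),
    viability_threshold = as.numeric(viability_threshold),
    initial_herd = as.numeric(initial_herd),
    horizon = as.integer(horizon)
  )
  class(env) <- "env_params"
  validate_env_params(env)
  env
}

validate_env_params <- function(env) {
  scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (key in c("growth_mean", "growth_sd", "shock_rate", "shock_size_mean",
                "shock_size_sd", "herd_cap", "viability_threshold",
                "initial_herd")) {
    if (!scalar_num(env[[key]]))
      stop("env_params: '", key, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  if (env$shock_rate < 0 || env$shock_rate > 1)
    stop("env_params: 'shock_rate' must be a probability in [0, 1], got ",
         env$shock_rate, call. = FALSE)
  if (env$growth_sd < 0 || env$shock_size_sd < 0)
    stop("env_params: standard deviations must be non-negative", call. = FALSE)
  if (env$shock_size_mean < 0 || env$shock_size_mean > 1)
    stop("env_params: 'shock_size_mean' must lie in [0, 1]", call. = FALSE)
  if (!(env$herd_cap > env$viability_threshold && env$viability_threshold > 0))
    stop("env_params: need herd_cap > viability_threshold > 0", call. = FALSE)
  if (env$initial_herd < env$viability_threshold)
    stop("env_params: 'initial_herd' must be at least the viability threshold",
         call. = FALSE)
  if (!is.integer(env$horizon) || length(env$horizon) != 1L ||
      is.na(env$horizon) || env$horizon < 1L)
    stop("env_params: 'horizon' must be an integer >= 1", call. = FALSE)
  invisible(env)
}

#' @export
print.env_params <- function(x, ...) {
  cat("Herder ecology parameters\n")
  cat(sprintf("  growth:    Normal(%.3f, %.3f) per year\n",
              x$growth_mean, x$growth_sd))
  cat(sprintf("  shocks:    rate %.2f/yr, size Normal(%.2f, %.2f) of herd\n",
              x$shock_rate, x$shock_size_mean, x$shock_size_sd))
  cat(sprintf("  herd:      start %g, cap %g, viability threshold %g head\n",
              x$initial_herd, x$herd_cap, x$viability_threshold))
  cat(sprintf("  horizon:   %d years\n", x$horizon))
  invisible(x)
}

#' Transfer-strategy parameters
#'
#' Describes one household's livestock-transfer institution. Three kinds are
#' supported: `"none"` (no exchange), `"need_based"` (ask only when the herd
#' is below the viability threshold, give what is asked if able without
#' dropping below that threshold yourself; no debt is created), and
#' `"account_keeping"` (the same asking rule, but gifts are loans: they
#' create debt that blocks further credit until repaid, subject to a
#' tolerated repayment delay and a per-loan credit limit).
#'
#' @param kind One of `"none"`, `"need_based"`, `"account_keeping"`.
#' @param generosity Probability of giving when asked and able (need-based)
#'   or when the partner is in good standing (account keeping).
#' @param repayment_probability Per-year probability that an indebted
#'   account-keeping agent attempts repayment. Ignored unless
#'   `kind = "account_keeping"`.
#' @param tolerated_delay Maximum age (years) an unrepaid debt may reach
#'   before the debtor loses good standing. Ignored unless account keeping.
#' @param credit_size Maximum loan size (head); `Inf` (the default) means
#'   unlimited credit. Ignored unless account keeping.
#'
#' @return An object of class `strategy_params`.
#' @examples
#' nbt <- strategy_params("need_based")
#' ak  <- strategy_params("account_keeping", credit_size = 20)
#' @export
strategy_params <- function(kind = c("none", "need_based", "account_keeping"),
                            generosity = 1.0,
                            repayment_probability = 1.0,
                            tolerated_delay = 5,
                            credit_size = Inf) {
  kind <- match.arg(kind)
  if (identical(credit_size, "inf") || identical(credit_size, "unlimited"))
    credit_size <- Inf
  strat <- list(
    kind = kind,
    generosity = as.numeric(generosity),
    repayment_probability = as.numeric(repayment_probability),
    tolerated_delay = as.numeric(tolerated_delay),
    credit_size = as.numeric(credit_size)
  )
  class(strat) <- "strategy_params"
  validate_strategy_params(strat)
  strat
}

validate_strategy_params <- function(strat) {
  for (key in c("generosity", "repayment_probability")) {
    p <- strat[[key]]
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("strategy_params: '", key, "' must be a probability in [0, 1]",
           call. = FALSE)
  }
  if (!is.numeric(strat$tolerated_delay) || strat$tolerated_delay < 0)
    stop("strategy_params: 'tolerated_delay' must be >= 0", call. = FALSE)
  if (!is.numeric(strat$credit_size) || is.na(strat$credit_size) ||
      strat$credit_size <= 0)
    stop("strategy_params: 'credit_size' must be positive (Inf = unlimited)",
         call. = FALSE)
  invisible(strat)
}

#' @export
print.strategy_params <- function(x, ...) {
  lab <- c(none = "no exchange", need_based = "need-based transfers",
           account_keeping = "account keeping")[[x$kind]]
  cat("Transfer strategy:", lab, "\n")
  cat(sprintf("  generosity %.2f", x$generosity))
  if (x$kind == "account_keeping")
    cat(sprintf(", repayment prob %.2f, tolerated delay %g yr, credit %s",
                x$repayment_probability, x$tolerated_delay,
                if (is.finite(x$credit_size)) format(x$credit_size) else "unlimited"))
  cat("\n")
  invisible(x)
}

# integer code used by the C++ engine; order is part of the RNG contract
strategy_kind_code <- function(kind) {
  match(kind, c("none", "need_based", "account_keeping")) - 1L
}

#' One household's state
#'
#' Constructs the state record of a single household: current herd, alive
#' flag, survival time (set at death, or at the horizon when censored), and
#' the debt ledger used by account-keeping partners.
#'
#' @param herd Current herd size (head, non-negative).
#' @param alive Logical flag.
#' @param survival_time Years survived; `NA` while alive and uncensored.
#' @param debt Outstanding debt owed to the partner (head, >= 0).
#' @param debt_age Years since the oldest unrepaid loan (0 when no debt).
#'
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(herd, alive = TRUE, survival_time = NA_real_,
                        debt = 0, debt_age = 0) {
  stopifnot(is.numeric(herd), length(herd) == 1L, herd >= 0,
            is.numeric(debt), debt >= 0, debt_age >= 0)
  if ((debt == 0) != (debt_age == 0))
    stop("agent_state: outstanding debt and debt age must be zero together",
         call. = FALSE)
  structure(list(herd = as.numeric(herd), alive = isTRUE(alive),
                 survival_time = as.numeric(survival_time),
                 debt = as.numeric(debt), debt_age = as.numeric(debt_age)),
            class = "agent_state")
}
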