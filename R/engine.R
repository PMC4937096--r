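#' Initial state of a herder pair
#'
#' @param env An [env_params()] object.
#' @param strategy_a,strategy_b [strategy_params()] for the two households.
#' @return A `pair_state` list with both agents at the initial herd, year 0,
#'   and an empty transfer log.
#' @export
pair_state <- function(env = env_params(),
                       strategy_a = strategy_params("need_based"),
                       strategy_b = strategy_params("need_based")) {
  stopifnot(inherits(env, "env_params"),
            inherits(strategy_a, "strategy_params"),
            inherits(strategy_b, "strategy_params"))
  structure(list(
    env = env,
    strats = list(a = strategy_a, b = strategy_b),
    agents = list(a = agent_state(env$initial_herd),
                  b = agent_state(env$initial_herd)),
    year = 0L,
    transfer_log = list()
  ), class = "pair_state")
}

# apply a transfer of `amount` from donor to recipient, snapping herds that
# the rules meant to land exactly on the viability threshold
apply_transfer <- function(state, donor, recipient, amount, spare, request,
                           type) {
  thresh <- state$env$viability_threshold
  d <- state$agents[[donor]]
  r <- state$agents[[recipient]]
  d$herd <- if (amount == spare) thresh else d$herd - amount
  r$herd <- if (amount == request) thresh else
    min(state$env$herd_cap, r$herd + amount)
  state$agents[[donor]] <- d
  state$agents[[recipient]] <- r
  state$transfer_log[[length(state$transfer_log) + 1L]] <-
    list(year = state$year, from = donor, to = recipient,
         amount = amount, type = type)
  state
}

#' Advance a herder pair by one year
#'
#' Runs one year of the schedule on a [pair_state()]: (1) stochastic growth
#' then shock for each living agent (A then B); (2) account-keeping
#' repayment attempts; (3) both living agents compute requests from
#' post-shock, post-repayment holdings; (4) requests are resolved in a
#' seeded random order; (5) outstanding debts age by one year; (6) the
#' viability check — agents strictly below the threshold die, and debts
#' owed to or by a dead agent are written off.
#'
#' This is the pure-R reference engine; it consumes the RNG stream
#' draw-for-draw identically to the C++ engine used by [run_pair()], so the
#' two produce bit-identical trajectories for the same seed.
#'
#' @param state A `pair_state` (at least one agent alive).
#' @return The updated `pair_state`, with `year` advanced by one.
#' @export
step_round <- function(state) {
  stopifnot(inherits(state, "pair_state"))
  env <- state$env
  thresh <- env$viability_threshold
  stopifnot(state$agents$a$alive || state$agents$b$alive)
  state$year <- state$year + 1L

  # 1. growth and shock
  for (id in c("a", "b")) {
    ag <- state$agents[[id]]
    if (!ag$alive) next
    ag$herd <- grow_herd(ag$herd, env)
    ag$herd <- apply_shock(ag$herd, env)
    state$agents[[id]] <- ag
  }

  # 2. repayment (account keepers with outstanding debt and a live partner)
  for (id in c("a", "b")) {
    partner <- setdiff(c("a", "b"), id)
    ag <- state$agents[[id]]
    if (!ag$alive || state$strats[[id]]$kind != "account_keeping" ||
        ag$debt <= 0 || !state$agents[[partner]]$alive) next
    res <- ak_repay(ag, state$strats[[id]], env)
    if (res$amount > 0) {
      state$agents[[id]] <- res$debtor
      p <- state$agents[[partner]]
      p$herd <- min(env$herd_cap, p$herd + res$amount)
      state$agents[[partner]] <- p
      state$transfer_log[[length(state$transfer_log) + 1L]] <-
        list(year = state$year, from = id, to = partner,
             amount = res$amount, type = "repayment")
    }
  }

  # 3. requests from post-shock, post-repayment holdings
  req <- c(a = 0, b = 0)
  for (id in c("a", "b"))
    if (state$agents[[id]]$alive)
      req[[id]] <- make_request(state$agents[[id]], state$strats[[id]], env)

  # 4. giving, in seeded random order
  if (any(req > 0)) {
    order_ids <- if (stats::runif(1L) < 0.5) c("a", "b") else c("b", "a")
    for (q in order_ids) {
      p <- setdiff(c("a", "b"), q)
      donor <- state$agents[[p]]
      if (req[[q]] <= 0 || !donor$alive) next
      dstrat <- state$strats[[p]]
      if (dstrat$kind == "need_based") {
        amt <- need_based_give(donor, req[[q]], dstrat, env)
        if (amt > 0) {
          state <- apply_transfer(state, p, q, amt,
                                  spare = max(0, donor$herd - thresh),
                                  request = req[[q]], type = "gift")
          # an account-keeping recipient books any incoming transfer as
          # debt it must repay, even a need-based gift
          if (state$strats[[q]]$kind == "account_keeping")
            state$agents[[q]]$debt <- state$agents[[q]]$debt + amt
        }
      } else if (dstrat$kind == "account_keeping") {
        requester <- state$agents[[q]]
        res <- ak_give(donor, requester, req[[q]], dstrat, env)
        if (res$amount > 0) {
          state <- apply_transfer(state, p, q, res$amount,
                                  spare = max(0, donor$herd - thresh),
                                  request = req[[q]], type = "loan")
          state$agents[[q]]$debt <- res$ledger$debt
          state$agents[[q]]$debt_age <- res$ledger$debt_age
        }
      }
    }
  }

  # 5. ledger aging
  for (id in c("a", "b"))
    if (state$agents[[id]]$debt > 0)
      state$agents[[id]]$debt_age <- state$agents[[id]]$debt_age + 1

  # 6. viability; write off debts touching a dead agent
  for (id in c("a", "b")) {
    ag <- state$agents[[id]]
    if (!ag$alive) next
    ag <- check_viability(ag, env, state$year)
    state$agents[[id]] <- ag
    if (!ag$alive)
      for (j in c("a", "b")) {
        state$agents[[j]]$debt <- 0
        state$agents[[j]]$debt_age <- 0
      }
  }
  state
}

run_pair_r <- function(env, strategy_a, strategy_b, trajectories,
                       transfer_log) {
  state <- pair_state(env, strategy_a, strategy_b)
  traj <- NULL
  if (trajectories) {
    traj <- matrix(env$initial_herd, nrow = env$horizon + 1L, ncol = 2L,
                   dimnames = list(0:env$horizon, c("a", "b")))
  }
  for (year in seq_len(env$horizon)) {
    if (!state$agents$a$alive && !state$agents$b$alive) break
    state <- step_round(state)
    if (trajectories)
      traj[year + 1L, ] <- c(state$agents$a$herd, state$agents$b$herd)
  }
  if (trajectories && state$year < env$horizon)
    for (y in (state$year + 1L):env$horizon)
      traj[y + 1L, ] <- c(state$agents$a$herd, state$agents$b$herd)

  surv <- cens <- numeric(2)
  for (k in 1:2) {
    ag <- state$agents[[k]]
    if (ag$alive) { surv[k] <- env$horizon; cens[k] <- TRUE }
    else { surv[k] <- ag$survival_time; cens[k] <- FALSE }
  }
  out <- list(survival = stats::setNames(surv, c("a", "b")),
              censored = stats::setNames(as.logical(cens), c("a", "b")),
              alive = c(a = state$agents$a$alive, b = state$agents$b$alive),
              final_herd = c(a = state$agents$a$herd,
                             b = state$agents$b$herd))
  if (trajectories) out$trajectory <- traj
  if (transfer_log) {
    tl <- state$transfer_log
    out$transfer_log <- data.frame(
      year = vapply(tl, `[[`, integer(1), "year"),
      from = vapply(tl, `[[`, character(1), "from"),
      to = vapply(tl, `[[`, character(1), "to"),
      amount = vapply(tl, `[[`, numeric(1), "amount"),
      type = vapply(tl, `[[`, character(1), "type"),
      stringsAsFactors = FALSE)
  }
  out
}

env_vec <- function(env) {
  c(env$growth_mean, env$growth_sd, env$shock_rate, env$shock_size_mean,
    env$shock_size_sd, env$herd_cap, env$viability_threshold,
    env$initial_herd, env$horizon)
}

run_pair_cpp <- function(env, strategy_a, strategy_b, trajectories,
                         transfer_log) {
  strats <- list(strategy_a, strategy_b)
  res <- cpp_run_pair(
    env_vec(env),
    vapply(strats, function(s) strategy_kind_code(s$kind), integer(1)),
    vapply(strats, `[[`, numeric(1), "generosity"),
    vapply(strats, `[[`, numeric(1), "repayment_probability"),
    vapply(strats, `[[`, numeric(1), "tolerated_delay"),
    vapply(strats, `[[`, numeric(1), "credit_size"),
    trajectories, transfer_log)
  ids <- c("a", "b")
  out <- list(survival = stats::setNames(res$survival, ids),
              censored = stats::setNames(res$censored, ids),
              alive = stats::setNames(res$alive, ids),
              final_herd = stats::setNames(res$final_herd, ids))
  if (trajectories) {
    dimnames(res$trajectory) <- list(0:env$horizon, ids)
    out$trajectory <- res$trajectory
  }
  if (transfer_log) {
    tl <- res$transfer_log
    out$transfer_log <- data.frame(
      year = tl$year, from = ids[tl$from], to = ids[tl$to],
      amount = tl$amount,
      type = c("gift", "loan", "repayment")[tl$type],
      stringsAsFactors = FALSE)
  }
  out
}

#' Simulate one herder pair
#'
#' Runs a single replicate of the dyadic simulation from year 1 to the
#' horizon (or until both herds have failed) and records each household's
#' survival time, censoring flag and final herd, optionally with per-year
#' herd trajectories and a log of every transfer.
#'
#' The result is bit-reproducible from `seed`: the `"cpp"` (default) and
#' `"r"` engines consume the same RNG stream and return identical results.
#'
#' @param env An [env_params()] object.
#' @param strategy_a,strategy_b [strategy_params()] for the two households.
#' @param seed Integer seed for this replicate; `NULL` continues the current
#'   RNG stream.
#' @param trajectories Record per-year herd sizes (census after the
#'   viability check)?
#' @param transfer_log Record every gift, loan and repayment?
#' @param engine `"cpp"` (fast) or `"r"` (reference implementation built
#'   from [step_round()]).
#' @return An object of class `pair_result`: a list with `survival`,
#'   `censored`, `alive` and `final_herd` (each named a/b), plus optional
#'   `trajectory` matrix and `transfer_log` data frame.
#' @examples
#' res <- run_pair(seed = 1)
#' res$survival
#' @export
run_pair <- function(env = env_params(),
                     strategy_a = strategy_params("need_based"),
                     strategy_b = strategy_params("need_based"),
                     seed = NULL, trajectories = FALSE, transfer_log = FALSE,
                     engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(env, "env_params"),
            inherits(strategy_a, "strategy_params"),
            inherits(strategy_b, "strategy_params"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- if (engine == "cpp")
    run_pair_cpp(env, strategy_a, strategy_b, trajectories, transfer_log)
  else
    run_pair_r(env, strategy_a, strategy_b, trajectories, transfer_log)
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  out$env <- env
  out$strategies <- list(a = strategy_a, b = strategy_b)
  class(out) <- "pair_result"
  out
}

#' @export
print.pair_result <- function(x, ...) {
  cat("Herder pair replicate (", x$strategies$a$kind, " / ",
      x$strategies$b$kind, ")\n", sep = "")
  for (id in c("a", "b"))
    cat(sprintf("  agent %s: survived %g yr%s, final herd %.1f\n", id,
                x$survival[[id]],
                if (x$censored[[id]]) " (censored at horizon)" else "",
                x$final_herd[[id]]))
  invisible(x)
}

#' Run many independent replicates of a herder pair
#'
#' Per-replicate seeds are derived deterministically from `base_seed`, so
#' the whole collection is reproducible bit-for-bit, and any aggregate over
#' the returned rows is independent of execution order.
#'
#' @inheritParams run_pair
#' @param n Number of replicate pairs.
#' @param base_seed Integer seed from which the `n` replicate seeds are
#'   derived.
#' @return A data frame of class `herdpool_replicates` with one row per
#'   replicate (`replicate`, `seed`, `survival_a/b`, `censored_a/b`,
#'   `alive_a/b`, `herd_a/b`) and the configuration in attributes. When
#'   `trajectories = TRUE` an attribute `trajectories` holds a
#'   `(horizon+1) x 2 x n` array of herd sizes; when `transfer_log = TRUE`
#'   an attribute `transfer_logs` holds one data frame per replicate.
#' @examples
#' reps <- run_replicates(n = 20, base_seed = 42)
#' summary(reps$survival_a)
#' @export
run_replicates <- function(env = env_params(),
                           strategy_a = strategy_params("need_based"),
                           strategy_b = strategy_params("need_based"),
                           n, base_seed, trajectories = FALSE,
                           transfer_log = FALSE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(n >= 1)
  n <- as.integer(n)
  set.seed(as.integer(base_seed))
  seeds <- sample.int(2147483646L, n)

  surv_a <- surv_b <- herd_a <- herd_b <- numeric(n)
  cens_a <- cens_b <- alive_a <- alive_b <- logical(n)
  traj <- if (trajectories)
    array(NA_real_, dim = c(env$horizon + 1L, 2L, n),
          dimnames = list(0:env$horizon, c("a", "b"), NULL))
  logs <- if (transfer_log) vector("list", n)

  for (i in seq_len(n)) {
    res <- run_pair(env, strategy_a, strategy_b, seed = seeds[i],
                    trajectories = trajectories, transfer_log = transfer_log,
                    engine = engine)
    surv_a[i] <- res$survival[["a"]]; surv_b[i] <- res$survival[["b"]]
    cens_a[i] <- res$censored[["a"]]; cens_b[i] <- res$censored[["b"]]
    alive_a[i] <- res$alive[["a"]]; alive_b[i] <- res$alive[["b"]]
    herd_a[i] <- res$final_herd[["a"]]; herd_b[i] <- res$final_herd[["b"]]
    if (trajectories) traj[, , i] <- res$trajectory
    if (transfer_log) logs[[i]] <- res$transfer_log
  }

  out <- data.frame(replicate = seq_len(n), seed = seeds,
                    survival_a = surv_a, survival_b = surv_b,
                    censored_a = cens_a, censored_b = cens_b,
                    alive_a = alive_a, alive_b = alive_b,
                    herd_a = herd_a, herd_b = herd_b)
  attr(out, "env") <- env
  attr(out, "strategies") <- list(a = strategy_a, b = strategy_b)
  attr(out, "base_seed") <- as.integer(base_seed)
  if (trajectories) attr(out, "trajectories") <- traj
  if (transfer_log) attr(out, "transfer_logs") <- logs
  class(out) <- c("herdpool_replicates", "data.frame")
  out
}

#' @export
print.herdpool_replicates <- function(x, ...) {
  st <- attr(x, "strategies")
  cat(sprintf("%d herder-pair replicates (%s / %s), base seed %d\n",
              nrow(x), st$a$kind, st$b$kind, attr(x, "base_seed")))
  surv <- c(x$survival_a, x$survival_b)
  cat(sprintf("  survival: median %g yr, mean %.1f yr, %.1f%% censored at horizon\n",
              stats::median(surv), mean(surv),
              100 * mean(c(x$censored_a, x$censored_b))))
  invisible(x)
}
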