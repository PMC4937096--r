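#' Annual herd growth
#'
#' Grows (or shrinks) a herd by one year's stochastic rate, drawn from
#' `Normal(growth_mean, growth_sd)`, and clips the result to
#' `[0, herd_cap]`. A herd of 0 stays at 0.
#'
#' @param herd Herd size (head, >= 0).
#' @param env An [env_params()] object.
#' @param r Optional forced growth rate (used in tests and the reference
#'   engine); when `NULL` a rate is drawn from the current RNG stream.
#' @return The new herd size.
#' @examples
#' env <- env_params()
#' grow_herd(100, env, r = 0.034) # 103.4
#' grow_herd(599, env, r = 0.034) # capped at 600
#' @export
grow_herd <- function(herd, env, r = NULL) {
  stopifnot(herd >= 0)
  if (is.null(r)) r <- stats::rnorm(1L, env$growth_mean, env$growth_sd)
  min(env$herd_cap, max(0, herd * (1 + r)))
}

#' Annual loss shock
#'
#' With probability `shock_rate` the herd loses a fraction
#' `f ~ Normal(shock_size_mean, shock_size_sd)` truncated to `[0, 1]`
#' (a drought or disease event); otherwise the herd is unchanged. Shocks are
#' independent across households and years.
#'
#' @inheritParams grow_herd
#' @param occurred Optional forced event indicator; `NULL` draws it.
#' @param frac Optional forced loss fraction (truncated to `[0, 1]`);
#'   `NULL` draws it when the event occurs.
#' @return The post-shock herd size.
#' @examples
#' env <- env_params()
#' apply_shock(100, env, occurred = TRUE, frac = 0.30) # 70
#' apply_shock(100, env, occurred = FALSE)             # 100
#' @export
apply_shock <- function(herd, env, occurred = NULL, frac = NULL) {
  stopifnot(herd >= 0)
  if (is.null(occurred)) occurred <- stats::runif(1L) < env$shock_rate
  if (!occurred) return(herd)
  if (is.null(frac))
    frac <- stats::rnorm(1L, env$shock_size_mean, env$shock_size_sd)
  frac <- min(1, max(0, frac))
  herd * (1 - frac)
}

#' End-of-year viability check
#'
#' A household whose herd is strictly below the viability threshold at the
#' end-of-year check dies: the herd can no longer feed the family. A herd of
#' exactly the threshold survives, so a full need-based gift restoring an
#' agent exactly to the threshold rescues it.
#'
#' @param agent An [agent_state()].
#' @param env An [env_params()] object.
#' @param year Current simulation year (recorded as the survival time at
#'   death).
#' @return The (possibly updated) `agent_state`.
#' @examples
#' env <- env_params()
#' check_viability(agent_state(63.9), env, year = 12)$alive # FALSE
#' check_viability(agent_state(64), env, year = 12)$alive   # TRUE
#' @export
check_viability <- function(agent, env, year) {
  stopifnot(inherits(agent, "agent_state"), agent$alive)
  if (agent$herd < env$viability_threshold) {
    agent$alive <- FALSE
    agent$survival_time <- as.numeric(year)
  }
  agent
}
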