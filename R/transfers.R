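#' Compute a transfer request
#'
#' Both transfer institutions share the same asking rule: ask the partner
#' for livestock only when the household's own herd has fallen below the
#' viability threshold, and ask only for the deficit. No-exchange agents
#' never ask, and an account keeper does not ask for fresh stock while it
#' still carries unrepaid debt (in a same-strategy pair the partner would
#' refuse a debtor anyway, so this only binds in mixed pairs).
#'
#' @param agent An [agent_state()] (must be alive).
#' @param strat A [strategy_params()] object.
#' @param env An [env_params()] object.
#' @return The requested amount (head); 0 means no request.
#' @examples
#' env <- env_params()
#' make_request(agent_state(50), strategy_params("need_based"), env)  # 14
#' make_request(agent_state(64), strategy_params("need_based"), env)  # 0
#' make_request(agent_state(10), strategy_params("none"), env)        # 0
#' @export
make_request <- function(agent, strat, env) {
  stopifnot(inherits(agent, "agent_state"), agent$alive)
  if (strat$kind == "none") return(0)
  if (strat$kind == "account_keeping" && agent$debt > 0) return(0)
  max(0, env$viability_threshold - agent$herd)
}

#' Need-based giving rule
#'
#' Give what is asked, but never so much that the donor's own herd drops
#' below the viability threshold. With probability `1 - generosity` the
#' donor declines even when able. The gift creates no debt.
#'
#' @param donor An [agent_state()] (must be alive).
#' @param request Requested amount (head, > 0).
#' @param strat The donor's [strategy_params()].
#' @param env An [env_params()] object.
#' @param give_draw Optional forced uniform draw for the generosity
#'   decision; `NULL` draws from the RNG stream.
#' @return The amount given (head).
#' @examples
#' env <- env_params()
#' nbt <- strategy_params("need_based")
#' need_based_give(agent_state(100), 14, nbt, env) # 14 (donor left at 86)
#' need_based_give(agent_state(70), 14, nbt, env)  # 6  (donor lands on 64)
#' @export
need_based_give <- function(donor, request, strat, env, give_draw = NULL) {
  stopifnot(inherits(donor, "agent_state"), donor$alive, request > 0)
  if (is.null(give_draw)) give_draw <- stats::runif(1L)
  if (give_draw >= strat$generosity) return(0)
  min(request, max(0, donor$herd - env$viability_threshold))
}

#' Account-keeping credit check
#'
#' A partner is in good standing when it has no outstanding debt, or when
#' its debt is within the credit limit and younger than the tolerated
#' repayment delay.
#'
#' @param partner_ledger A list (or [agent_state()]) with elements `debt`
#'   and `debt_age`.
#' @param strat The lender's [strategy_params()] (kind must be
#'   `"account_keeping"`).
#' @return `TRUE` if the partner is in good standing.
#' @examples
#' ak <- strategy_params("account_keeping")
#' ak_credit_check(list(debt = 0, debt_age = 0), ak)   # TRUE
#' ak_credit_check(list(debt = 10, debt_age = 6), ak)  # FALSE (delay 5)
#' ak_credit_check(list(debt = 10, debt_age = 1), ak)  # TRUE
#' @export
ak_credit_check <- function(partner_ledger, strat) {
  stopifnot(strat$kind == "account_keeping")
  debt <- partner_ledger$debt
  age <- partner_ledger$debt_age
  debt == 0 || (age <= strat$tolerated_delay && debt <= strat$credit_size)
}

#' Account-keeping giving rule
#'
#' An account-keeping donor extends a loan only when the requester carries
#' no outstanding debt and is in good standing. The loan is capped by the
#' credit limit and by what the donor can spare without dropping below the
#' viability threshold, and is recorded as new debt (age 0) on the
#' requester's ledger. With probability `1 - generosity` the donor declines
#' even when the conditions hold.
#'
#' @param donor An [agent_state()] (must be alive).
#' @param partner_ledger The requester's ledger (list with `debt`,
#'   `debt_age`).
#' @param request Requested amount (head, > 0).
#' @param strat The donor's [strategy_params()] (account keeping).
#' @param env An [env_params()] object.
#' @param give_draw Optional forced uniform draw; `NULL` draws it (only
#'   when the debt/standing conditions hold — declining a debtor costs no
#'   randomness).
#' @return A list with `amount` (head given) and `ledger` (the requester's
#'   updated ledger).
#' @examples
#' env <- env_params()
#' ak <- strategy_params("account_keeping")
#' ak_give(agent_state(100), list(debt = 0, debt_age = 0), 14, ak, env)$amount # 14
#' ak_give(agent_state(100), list(debt = 5, debt_age = 1), 14, ak, env)$amount # 0
#' @export
ak_give <- function(donor, partner_ledger, request, strat, env,
                    give_draw = NULL) {
  stopifnot(inherits(donor, "agent_state"), donor$alive, request > 0,
            strat$kind == "account_keeping")
  out <- list(amount = 0, ledger = partner_ledger)
  if (partner_ledger$debt > 0) return(out)
  if (!ak_credit_check(partner_ledger, strat)) return(out)
  if (is.null(give_draw)) give_draw <- stats::runif(1L)
  if (give_draw >= strat$generosity) return(out)
  amount <- min(request, strat$credit_size,
                max(0, donor$herd - env$viability_threshold))
  if (amount > 0) {
    out$amount <- amount
    out$ledger <- list(debt = amount, debt_age = 0)
  }
  out
}

#' Account-keeping repayment rule
#'
#' An indebted account-keeping agent attempts repayment each year with its
#' repayment probability, paying back as much of the outstanding debt as it
#' can afford without dropping below the viability threshold. Partial
#' repayments are allowed; the debt's age keeps running until the debt is
#' fully cleared, at which point the age resets to 0.
#'
#' @param debtor An [agent_state()] with positive outstanding debt.
#' @param strat The debtor's [strategy_params()] (account keeping).
#' @param env An [env_params()] object.
#' @param repay_draw Optional forced uniform draw for the repayment
#'   decision; `NULL` draws it.
#' @return A list with `amount` (head repaid) and `debtor` (updated state).
#' @examples
#' env <- env_params()
#' ak <- strategy_params("account_keeping")
#' ak_repay(agent_state(80, debt = 10, debt_age = 1), ak, env)$amount # 10
#' ak_repay(agent_state(66, debt = 10, debt_age = 1), ak, env)$amount # 2
#' ak_repay(agent_state(60, debt = 10, debt_age = 1), ak, env)$amount # 0
#' @export
ak_repay <- function(debtor, strat, env, repay_draw = NULL) {
  stopifnot(inherits(debtor, "agent_state"), debtor$alive, debtor$debt > 0,
            strat$kind == "account_keeping")
  if (is.null(repay_draw)) repay_draw <- stats::runif(1L)
  out <- list(amount = 0, debtor = debtor)
  if (repay_draw >= strat$repayment_probability) return(out)
  spare <- max(0, debtor$herd - env$viability_threshold)
  amount <- min(debtor$debt, spare)
  if (amount <= 0) return(out)
  # snap to the threshold when the clamp binds, so float rounding cannot
  # push the debtor strictly below the (survivable) threshold
  new_herd <- debtor$herd - amount
  if (amount == spare) new_herd <- env$viability_threshold
  debtor$herd <- new_herd
  debtor$debt <- debtor$debt - amount
  if (debtor$debt <= 0) {
    debtor$debt <- 0
    debtor$debt_age <- 0
  }
  out$amount <- amount
  out$debtor <- debtor
  out
}
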