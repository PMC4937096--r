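env <- env_params()

test_that("asking rule requests exactly the deficit below threshold", {
  expect_equal(make_request(agent_state(50), nbt, env), 14)
  expect_equal(make_request(agent_state(64), nbt, env), 0)
  expect_equal(make_request(agent_state(64), ak, env), 0)
  expect_equal(make_request(agent_state(50), ak, env), 14)
  expect_equal(make_request(agent_state(10), none, env), 0)
  # an indebted account keeper does not ask for more
  expect_equal(make_request(agent_state(50, debt = 5, debt_age = 1), ak, env), 0)
  # a need-based agent's (donor-booked) debt does not stop it asking
  expect_equal(make_request(agent_state(50, debt = 5, debt_age = 1), nbt, env), 14)
})

test_that("need-based giving honours the giving threshold and generosity", {
  expect_equal(need_based_give(agent_state(100), 14, nbt, env), 14)
  expect_equal(need_based_give(agent_state(70), 14, nbt, env), 6)
  expect_equal(need_based_give(agent_state(64), 14, nbt, env), 0)
  expect_equal(need_based_give(agent_state(60), 14, nbt, env), 0)
  stingy <- strategy_params("need_based", generosity = 0)
  expect_equal(need_based_give(agent_state(100), 14, stingy, env,
                               give_draw = 0.99), 0)
  half <- strategy_params("need_based", generosity = 0.5)
  expect_equal(need_based_give(agent_state(100), 14, half, env,
                               give_draw = 0.49), 14)
  expect_equal(need_based_give(agent_state(100), 14, half, env,
                               give_draw = 0.51), 0)
})

test_that("credit check combines debt, delay and credit size", {
  expect_true(ak_credit_check(list(debt = 0, debt_age = 0), ak))
  expect_false(ak_credit_check(list(debt = 10, debt_age = 6), ak))
  expect_true(ak_credit_check(list(debt = 10, debt_age = 1), ak))
  tight <- strategy_params("account_keeping", credit_size = 5)
  expect_false(ak_credit_check(list(debt = 10, debt_age = 1), tight))
  expect_true(ak_credit_check(list(debt = 4, debt_age = 1), tight))
})

test_that("account-keeping loans require a clean slate and record debt", {
  res <- ak_give(agent_state(100), list(debt = 0, debt_age = 0), 14, ak, env)
  expect_equal(res$amount, 14)
  expect_equal(res$ledger, list(debt = 14, debt_age = 0))
  expect_equal(ak_give(agent_state(100), list(debt = 5, debt_age = 1), 14,
                       ak, env)$amount, 0)
  tight <- strategy_params("account_keeping", credit_size = 10)
  expect_equal(ak_give(agent_state(100), list(debt = 0, debt_age = 0), 14,
                       tight, env)$amount, 10)
  # donor's own threshold binds symmetrically with the giving rule
  expect_equal(ak_give(agent_state(70), list(debt = 0, debt_age = 0), 14,
                       ak, env)$amount, 6)
})

test_that("repayment pays what is affordable and tracks the ledger", {
  res <- ak_repay(agent_state(80, debt = 10, debt_age = 2), ak, env)
  expect_equal(res$amount, 10)
  expect_equal(res$debtor$debt, 0)
  expect_equal(res$debtor$debt_age, 0)   # age resets only on full clearance
  res <- ak_repay(agent_state(66, debt = 10, debt_age = 2), ak, env)
  expect_equal(res$amount, 2)
  expect_equal(res$debtor$herd, 64)      # lands exactly on the threshold
  expect_equal(res$debtor$debt, 8)
  expect_equal(res$debtor$debt_age, 2)
  expect_equal(ak_repay(agent_state(60, debt = 10, debt_age = 1), ak,
                        env)$amount, 0)
  lazy <- strategy_params("account_keeping", repayment_probability = 0)
  expect_equal(ak_repay(agent_state(80, debt = 10, debt_age = 1), lazy, env,
                        repay_draw = 0.5)$amount, 0)
})

test_that("no give or repay ever leaves the giver below threshold", {
  set.seed(7)
  for (i in 1:200) {
    herd <- runif(1, 0, 200)
    req <- runif(1, 0, 64)
    g <- need_based_give(agent_state(herd), req, nbt, env, give_draw = 0)
    expect_true(g == 0 || herd - g >= 64 - 1e-12)
    if (herd >= 64) {
      res <- ak_repay(agent_state(herd, debt = req + 1e-9, debt_age = 1),
                      ak, env, repay_draw = 0)
      expect_gte(res$debtor$herd, 64)
    }
  }
})
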