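# shared fixtures: strategies and small worlds used across test files

nbt <- strategy_params("need_based")
ak <- strategy_params("account_keeping")
none <- strategy_params("none")

# deterministic world: no growth noise, no shocks
calm_env <- env_params(growth_sd = 0, shock_rate = 0)

# short-horizon baseline world for cheap replicate runs
short_env <- env_params(horizon = 25L)

# brute-force Gini: pairwise relative mean absolute difference
gini_brute <- function(w) {
  n <- length(w)
  sum(abs(outer(w, w, "-"))) / (2 * n^2 * mean(w))
}

# brute-force Spearman: rank then Pearson
spearman_brute <- function(x, y) stats::cor(rank(x), rank(y))
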