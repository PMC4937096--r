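# herdpool

Agent-based Monte-Carlo simulation of **risk pooling between two pastoralist
households**. Each household manages one herd that grows stochastically
(≈ 3.4 %/year) and occasionally suffers catastrophic losses from drought or
disease (baseline: a 10 %/year chance of losing ~30 % of the herd). A herd
that ends a year below 64 head can no longer feed its family and fails. The
package compares three livestock-transfer institutions, modelled on Maasai
practice, by how well they keep both herds alive:

* **no exchange** — the baseline; households never interact;
* **need-based transfers** (*osotua*): ask only when your herd is below the
  viability threshold and only for the deficit; give what is asked, with
  probability *generosity*, unless giving would push your own herd below the
  threshold. No debt is created;
* **account keeping** (*esile*): the same asking rule, but every transfer is
  a loan — it requires the requester to be debt-free and in good standing,
  is capped by a credit limit, and must be repaid (with probability
  *repayment probability* per year, whenever affordable without dropping
  below the threshold).

Formally, each year herd $h$ updates as
$h \leftarrow \min(600, h\,(1+r))$ with $r \sim N(0.034,\ 0.025)$, then with
probability $p_s = 0.10$ loses a fraction $f \sim N(0.30,\ 0.10)$ truncated
to $[0,1]$; transfers then move stock between the two herds under the rules
above, and a household dies when $h < 64$ at the year-end check. Experiment
drivers measure survival curves, within-pair Spearman correlations of
survival durations (how tightly partners' fates are coupled), volatility and
generosity sweeps with bootstrap CIs, a 2×2 survival payoff matrix with a
Stag Hunt dominance check, and wealth inequality (Gini coefficient, Lorenz
curves). The simulator exists twice — a pure-R reference engine and a C++
engine — which are bit-identical for the same seed; every experiment replays
exactly from one base seed.

## Worked example

```r
library(herdpool)

run_pair(seed = 7, transfer_log = TRUE)
#> Herder pair replicate (need_based / need_based)
#>   agent a: survived 50 yr (censored at horizon), final herd 171.8
#>   agent b: survived 3 yr, final herd 52.9
```

Household *b* was shocked early, received one rescue gift, was shocked
again, and failed in year 3; *a* survived to the 50-year horizon. Across
many replicates those fates become strongly coupled when transfers follow
need:

```r
correlation_experiment(n = 2000, base_seed = 42)
#> Within-pair Spearman correlations of herd survival durations
#>   none             rho = -0.009  (p = 0.7, n = 2000)
#>   account_keeping  rho =  0.411  (p = 2.7e-82, n = 2000)
#>   mixed            rho =  0.438  (p = 1.17e-94, n = 2000)
#>   need_based       rho =  0.603  (p = 1.1e-198, n = 2000)

payoff_matrix(n = 2000, base_seed = 42)
#> Survival at horizon (% of focal households), focal x partner
#>                  partner
#> focal             need_based account_keeping
#>   need_based            29.8            22.7
#>   account_keeping       21.7            22.4
#> Mutual need-based transfers payoff-dominate mutual account keeping (non-overlapping 95% CIs).
```

With no exchange the two herds fail independently (ρ ≈ 0). Need-based
pairs pool risk most tightly (ρ ≈ 0.6) and survive best (≈ 30 % at 50
years vs ≈ 22 % for account keepers); the two transfer strategies form a
Stag Hunt in which mutual need-based transfers are the payoff-dominant
coordination point. See `vignette sources in vignettes/` for the model
assumptions, parameter provenance, and known limitations (notably the
wealth-census definition for the Gini analysis).

## Command line

Each experiment is also a CLI subcommand writing tidy CSVs plus a
`config.json` sidecar:

```sh
Rscript inst/cli/herdpool.R correlations --n 2000 --seed 42 --outdir out/
Rscript inst/cli/herdpool.R inequality --seed 1 --outdir out/
```

## Acceptance script

`scripts/acceptance.R` recomputes the headline summaries from scratch with
the installed package — the four within-pair survival correlations
(10,000 pairs per condition), the three final-census wealth Gini
coefficients (10,000 pairs per condition), and the generosity level from
which both transfer strategies beat no exchange (10-point grid, 10,000
pairs per level) — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Runs in about a minute on one CPU.
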