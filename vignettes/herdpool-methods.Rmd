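---
title: "Modelling dyadic risk pooling among herders: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dyadic risk pooling among herders: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`herdpool` simulates two pastoralist households, each managing one herd,
over a multi-decade horizon. The model is deliberately minimal: a herd is
a single non-negative real number ("head of stock"), and a household's
fate is decided entirely by whether that number stays above a viability
threshold.

Each simulated year, for each living household:

1. **Growth.** The herd is multiplied by $1 + r$, with
   $r \sim N(\mu_g, \sigma_g)$; $\mu_g = 0.034$ is a typical annual cattle
   herd growth rate in East African pastoral ecologies. The herd is capped
   at 600 head (the most an average household can manage) and floored at 0.
2. **Shock.** With probability $p_s = 0.10$ per year the herd loses a
   fraction $f \sim N(\mu_f, \sigma_f)$, truncated to $[0,1]$, with
   $\mu_f = 0.30$: droughts, epidemics, raids. Shocks are independent
   across households and years.
3. **Repayment, requests, giving.** The transfer institution acts (below).
4. **Viability check.** A household whose herd ends the year strictly
   below 64 head can no longer feed itself: it is marked dead with that
   year as its survival time. A herd of exactly 64 survives — transfers
   that restore a household exactly to the threshold rescue it.

Both households start at 70 head, just above the threshold, which is what
makes early shocks dangerous and mutual insurance valuable. Survivors at
the 50-year horizon are recorded as censored at 50.

## The three transfer institutions

* **No exchange** (`kind = "none"`): the baseline; households never
  interact.
* **Need-based transfers** (`kind = "need_based"`, the Maasai *osotua*
  idiom): ask only when your herd is below 64, ask only for the deficit;
  give what is asked with probability `generosity`, but never so much
  that your own herd would drop below 64. Gifts create no obligation.
* **Account keeping** (`kind = "account_keeping"`, the *esile* idiom):
  the same asking rule, but every transfer is a loan. A lender extends
  credit only to a partner in good standing with no outstanding debt, up
  to `credit_size`; the debtor repays when it can do so without dropping
  below 64, attempting repayment each year with probability
  `repayment_probability`. Debts older than `tolerated_delay` years
  destroy good standing.

Two rules deserve emphasis because they only matter in *mixed* pairs
(one account keeper, one need-based partner), and were chosen to make
mixed pairs behave consistently with the published payoff structure
rather than let the account keeper free-ride:

* An account keeper books **any** incoming transfer as a debt it must
  repay — even a need-based gift. Account keeping is a mindset, not a
  property of the gift.
* An account keeper does not **ask** for fresh stock while still in debt.
  In a same-strategy pair this is invisible (the partner would refuse a
  debtor anyway), but it stops an account keeper from repeatedly drawing
  free gifts from a need-based partner.

A need-based agent, conversely, never repays: when an account keeper
lends to it, the lender's books show an unpaid debt forever, and lending
stops after the first loan. This asymmetric friction is intended: it is
what makes mixed pairs pool less risk than need-based pairs.

The resulting game between the two transfer strategies is a Stag Hunt.
Both same-strategy pairings are coordination points, and mutual
need-based transfers payoff-dominate mutual account keeping:
`payoff_matrix()` tests exactly that contrast (same-strategy diagonal
cells, non-overlapping bootstrap CIs). The stronger column-wise strategy
dominance is also reported (`strictly_dominant`) but is *not* expected to
hold in a coordination game — the off-diagonal cells tie statistically.

## Schedule and randomness

The yearly order is growth → shock → repayment → requests → giving →
ledger aging → viability check, with households processed A-then-B
within each phase and requests resolved in a seeded random order (order
only matters in degenerate rounds where both are needy and neither can
give). Requests are computed from post-shock, post-repayment holdings;
the viability check runs last so same-year rescues count. The source
publication's appendix with the exact schedule is not available; this
order is a reconstruction, fixed and documented here.

Every replicate is driven by one integer seed; `run_replicates()`
derives per-replicate seeds deterministically from a base seed, so every
experiment replays bit-for-bit. The simulator exists twice: a pure-R
reference engine (`step_round()`, composed of the exported rule
functions) and a C++ engine used by default. Both consume the RNG stream
draw-for-draw identically; a property test asserts bit-identical
trajectories, transfer logs and survival times across engines.

## Parameters, defaults, and what is calibrated

| key | default | provenance |
|---|---|---|
| `growth_mean` | 0.034/yr | published (typical herd growth) |
| `growth_sd` | 0.025/yr | declared; appendix value unavailable |
| `shock_rate` | 0.10/yr | published sweep baseline (see below) |
| `shock_size_mean` | 0.30 | published sweep baseline (see below) |
| `shock_size_sd` | 0.10 | declared; appendix value unavailable |
| `herd_cap` | 600 head | published |
| `viability_threshold` | 64 head | published |
| `initial_herd` | 70 head | published |
| `horizon` | 50 yr | published (payoffs at 50 years) |
| `generosity` | 1.0 | published ideal ("always give if able") |
| `repayment_probability` | 1.0 | declared; insensitive (±0.5 pp survival) |
| `tolerated_delay` | 5 yr | declared; only binds via good standing |
| `credit_size` | unlimited | published "(when applicable)" read as optional |

The published description pairs "likelihood and severity" with "30 % and
10 %"; we use rate 0.10 / size 0.30 because a 30 % *rate* would lie
outside the published sweep range for the rate (0–20 %), while
(0.10, 0.30) sits inside both sweep ranges. Both are ordinary config
keys, so the other reading is one argument away.

Herd sizes and transfers are continuous reals (3.4 % growth of 70 head
is fractional and no rounding rule is published). Transfers that would
land a herd exactly on the threshold (a full-deficit gift, a clamped
give or repayment) snap the stored herd to exactly 64, so binary
floating point cannot turn a rule-respecting transfer into a death.

## What the experiments compute

* `correlation_experiment()` — Spearman's rank correlation (average
  ranks, large-sample p) between the two households' survival durations,
  per condition. Risk pooling couples fates: the correlation rises from
  ≈ 0 (no exchange) through account keeping to need-based transfers.
* `volatility_sweep()` — pooled survival against the mean shock size
  (0–50 %) or annual shock rate (0–20 %), the other held at baseline.
  When the size is swept, the severity spread scales with the mean
  (constant coefficient of variation, 1/3 at the baseline), so the
  zero-size limit is genuinely lossless and every household survives —
  with a fixed absolute spread, a "zero-size" loss event would still
  remove a half-normal ~4 % of the herd, contradicting the published
  low-volatility limit.
* `generosity_sweep()` — survival per generosity level, with a threshold
  detector: the smallest level at which both transfer strategies beat
  the no-exchange baseline with non-overlapping 95 % bootstrap CIs. The
  comparison statistic is the proportion of herds alive at the horizon
  (the same scale as the payoff matrix); mean survival is available via
  `threshold_stat = "mean"` and separates much earlier, because the mean
  accumulates small early-death differences that the at-horizon
  proportion does not. The detected threshold is a *power-dependent*
  quantity: it moves down as replicates per level increase. We fix
  10,000 pairs per level, the same per-condition count the correlation
  analysis uses.
* `payoff_matrix()` — % of focal households alive at 50 years in a 2×2
  focal × partner matrix; same-strategy cells pool both pair members,
  mixed cells come from the same mixed runs with roles tracked.
* `inequality_experiment()` — Gini coefficient (uncorrected relative
  mean absolute difference, computed by the exact sorted-sum identity)
  and Lorenz curves of final-census herd wealth, plus an optional
  per-year Gini series.

Bootstrap intervals are percentile intervals over 1,000 resamples,
resampling whole replicate pairs so within-pair coupling is respected.

## The wealth census, and a known limitation

The inequality census is a genuine design fork. The default
(`census = "living_final"`) pools the final herds of living households:
dead households' herds are frozen at death and excluded. Under this
census all conditions produce a Gini near 0.24, and the published
ordering (no exchange most unequal, need-based least) does not emerge —
living herds are confined to [64, 600], which mathematically caps the
attainable Gini far below the published levels (≈ 0.58 for no exchange).
The dead-inclusive census (`census = "all_final"`, failed households at
0) recovers the published ordering robustly, but its levels sit well
above the published ones. No census definable on this model's stated
dynamics reproduces the published Gini levels; they evidently depend on
an unavailable appendix definition (for example, herds that keep
evolving after dropping below the threshold). We keep the census
explicit, configurable, and documented rather than redefining the
dynamics to chase the published numbers.

## What the synthetic world does and does not establish

All data are self-generated Monte Carlo: the generator *is* the stated
world (parameters above), so a green test establishes internal
consistency of rules, schedule and statistics — not ecological validity.
Real herds have age/sex structure, multiple species, spatially
correlated droughts (shocks here are independent within the pair, which
maximises the value of pooling), partner choice, and debts that outlive
households; none of that is modelled, and the no-partner-correlation
assumption in particular inflates transfer benefits relative to a world
where both herds fail together.

## Numerical and degenerate-input choices

* Spearman correlation on constant input (e.g. a shock-free world where
  everyone is censored at 50) raises an explicit error rather than
  returning NA silently; `gini()` and `lorenz_curve()` do the same for
  all-zero wealth.
* Censored survival times enter summaries at the horizon value; no
  survival-analysis machinery is used (the published analyses treat
  survival as a plain duration).
* Gini uses no small-sample correction; at census sizes in the thousands
  the n/(n−1) factor is far below reporting precision.
* Partial repayment is allowed (pay what is affordable above the
  threshold); the debt's age keeps running until fully cleared. Good
  standing is restored on full repayment: the ethnographic permanent
  mark for forgiven debts is out of scope, as are repayment premia,
  debt inheritance, and partner choice.
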