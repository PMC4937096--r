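#include <Rcpp.h>
using namespace Rcpp;

// One replicate of the dyadic herder simulation.
//
// Year schedule (fixed; the pure-R engine in R/engine.R mirrors this
// draw-for-draw so that both engines are bit-identical for a given seed):
//   1. growth then shock, per living agent, A then B
//   2. account-keeping repayment attempts, A then B
//   3. requests computed from post-shock, post-repayment holdings
//   4. giving, requests resolved in seeded random order
//   5. ledger aging (+1 year on any outstanding debt)
//   6. viability check (death strictly below threshold); debts to/from a
//      dead agent are written off
//
// env: gmean, gsd, srate, smean, ssd, cap, thresh, init, horizon
// kind: 0 = none, 1 = need_based, 2 = account_keeping (per agent)
// Transfers that exhaust the donor's spare stock or exactly fill the
// requester's deficit snap the resulting herd to the threshold, so float
// rounding cannot kill an agent the rules meant to leave viable.

// [[Rcpp::export]]
List cpp_run_pair(NumericVector env, IntegerVector kind,
                  NumericVector generosity, NumericVector repay_prob,
                  NumericVector tolerated_delay, NumericVector credit_size,
                  bool trajectories, bool transfer_log) {
  const double gmean = env[0], gsd = env[1], srate = env[2], smean = env[3],
               ssd = env[4], cap = env[5], thresh = env[6], init = env[7];
  const int horizon = (int) env[8];

  double herd[2] = {init, init};
  bool alive[2] = {true, true};
  double surv[2] = {NA_REAL, NA_REAL};
  double debt[2] = {0.0, 0.0};     // debt[i]: owed by i to partner
  double age[2] = {0.0, 0.0};

  NumericMatrix traj;
  if (trajectories) {
    traj = NumericMatrix(horizon + 1, 2);
    traj(0, 0) = herd[0];
    traj(0, 1) = herd[1];
  }
  std::vector<int> log_year, log_from, log_to, log_type;
  std::vector<double> log_amount;

  for (int year = 1; year <= horizon; ++year) {
    // 1. growth and shock
    for (int i = 0; i < 2; ++i) {
      if (!alive[i]) continue;
      double r = R::rnorm(gmean, gsd);
      herd[i] = std::min(cap, std::max(0.0, herd[i] * (1.0 + r)));
      double u = unif_rand();
      if (u < srate) {
        double f = R::rnorm(smean, ssd);
        f = std::min(1.0, std::max(0.0, f));
        herd[i] *= (1.0 - f);
      }
    }

    // 2. repayment
    for (int i = 0; i < 2; ++i) {
      int p = 1 - i;
      if (!alive[i] || kind[i] != 2 || debt[i] <= 0.0 || !alive[p]) continue;
      double u = unif_rand();
      if (u < repay_prob[i]) {
        double spare = std::max(0.0, herd[i] - thresh);
        double amt = std::min(debt[i], spare);
        if (amt > 0.0) {
          herd[i] = (amt == spare) ? thresh : herd[i] - amt;
          herd[p] = std::min(cap, herd[p] + amt);
          debt[i] -= amt;
          if (debt[i] <= 0.0) { debt[i] = 0.0; age[i] = 0.0; }
          if (transfer_log) {
            log_year.push_back(year); log_from.push_back(i + 1);
            log_to.push_back(p + 1); log_amount.push_back(amt);
            log_type.push_back(3);
          }
        }
      }
    }

    // 3. requests (deficit below the viability threshold); an account
    // keeper does not ask for fresh stock while still in debt
    double req[2] = {0.0, 0.0};
    for (int i = 0; i < 2; ++i)
      if (alive[i] && kind[i] != 0 && herd[i] < thresh &&
          !(kind[i] == 2 && debt[i] > 0.0))
        req[i] = thresh - herd[i];

    // 4. giving, in seeded random order
    if (req[0] > 0.0 || req[1] > 0.0) {
      int first = (unif_rand() < 0.5) ? 0 : 1;
      for (int k = 0; k < 2; ++k) {
        int q = (k == 0) ? first : 1 - first;  // requester
        int p = 1 - q;                          // donor
        if (req[q] <= 0.0 || !alive[p]) continue;
        if (kind[p] == 1) {                     // need-based gift
          double u = unif_rand();
          if (u < generosity[p]) {
            double spare = std::max(0.0, herd[p] - thresh);
            double amt = std::min(req[q], spare);
            if (amt > 0.0) {
              herd[p] = (amt == spare) ? thresh : herd[p] - amt;
              herd[q] = (amt == req[q]) ? thresh
                                        : std::min(cap, herd[q] + amt);
              // an account-keeping recipient books any incoming transfer
              // as debt it must repay, even a need-based gift
              if (kind[q] == 2) debt[q] += amt;
              if (transfer_log) {
                log_year.push_back(year); log_from.push_back(p + 1);
                log_to.push_back(q + 1); log_amount.push_back(amt);
                log_type.push_back(1);
              }
            }
          }
        } else if (kind[p] == 2 && debt[q] == 0.0) {  // account-keeping loan
          // zero debt implies good standing; the credit limit caps the loan
          double u = unif_rand();
          if (u < generosity[p]) {
            double spare = std::max(0.0, herd[p] - thresh);
            double amt = std::min(req[q], std::min(credit_size[p], spare));
            if (amt > 0.0) {
              herd[p] = (amt == spare) ? thresh : herd[p] - amt;
              herd[q] = (amt == req[q]) ? thresh
                                        : std::min(cap, herd[q] + amt);
              debt[q] = amt;
              age[q] = 0.0;
              if (transfer_log) {
                log_year.push_back(year); log_from.push_back(p + 1);
                log_to.push_back(q + 1); log_amount.push_back(amt);
                log_type.push_back(2);
              }
            }
          }
        }
      }
    }

    // 5. ledger aging
    for (int i = 0; i < 2; ++i)
      if (debt[i] > 0.0) age[i] += 1.0;

    // 6. viability; write off debts on death
    for (int i = 0; i < 2; ++i) {
      if (alive[i] && herd[i] < thresh) {
        alive[i] = false;
        surv[i] = year;
        debt[0] = debt[1] = 0.0;
        age[0] = age[1] = 0.0;
      }
    }

    if (trajectories) {
      traj(year, 0) = herd[0];
      traj(year, 1) = herd[1];
    }
    if (!alive[0] && !alive[1]) {
      if (trajectories)
        for (int y = year + 1; y <= horizon; ++y) {
          traj(y, 0) = herd[0];
          traj(y, 1) = herd[1];
        }
      break;
    }
  }

  LogicalVector censored(2);
  for (int i = 0; i < 2; ++i) {
    if (alive[i]) { surv[i] = horizon; censored[i] = true; }
    else censored[i] = false;
  }

  List out = List::create(
    _["survival"] = NumericVector::create(surv[0], surv[1]),
    _["censored"] = censored,
    _["alive"] = LogicalVector::create(alive[0], alive[1]),
    _["final_herd"] = NumericVector::create(herd[0], herd[1]));
  if (trajectories) out["trajectory"] = traj;
  if (transfer_log)
    out["transfer_log"] = DataFrame::create(
      _["year"] = wrap(log_year), _["from"] = wrap(log_from),
      _["to"] = wrap(log_to), _["amount"] = wrap(log_amount),
      _["type"] = wrap(log_type));
  return out;
}
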