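#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Strategy encoding: 1 = cooperator (C), 0 = defector (D).
//
// Weak prisoner's dilemma payoffs: a site's total payoff against its
// neighbourhood reduces to (number of cooperating neighbours) * price,
// where price = 1 (R) for a cooperator and b (T) for a defector; S = P = 0.
static inline double site_payoff(int s, int n_coop_nbrs, double b) {
  return s == 1 ? (double)n_coop_nbrs : b * (double)n_coop_nbrs;
}

// Fermi adoption probability with w prefactor; exponent clipped at +/-700
// so the probability saturates smoothly to 0 or w instead of overflowing.
static inline double fermi_prob(double px, double py, double w, double K) {
  double z = (px - py) / K;
  if (z > 700.0) z = 700.0;
  if (z < -700.0) z = -700.0;
  return w / (1.0 + std::exp(z));
}

struct Par {
  double b, K, d, w_min, w_max;
  int rule;        // 1 = both, 2 = cooperators only, 3 = defectors only
  bool gate_post;  // eligibility judged on post-adoption strategy
  int cmp;         // 0 = all neighbours, 1 = same strategy, 2 = different
};

static Par parse_par(const List& par) {
  Par p;
  p.b = as<double>(par["b"]);
  p.K = as<double>(par["K"]);
  p.d = as<double>(par["d"]);
  p.w_min = as<double>(par["w_min"]);
  p.w_max = as<double>(par["w_max"]);
  p.rule = as<int>(par["rule"]);
  p.gate_post = as<bool>(par["gate_post"]);
  p.cmp = as<int>(par["cmp"]);
  return p;
}

static inline bool rule_enabled(int rule, int strategy) {
  if (rule == 1) return true;
  if (rule == 2) return strategy == 1;
  return strategy == 0;
}

// Mutable simulation state with incremental bookkeeping:
// nc[i]  = number of cooperating neighbours of site i,
// ncoop  = total cooperators, sum_w_C / sum_w_D = per-class w totals.
struct State {
  std::vector<int> s;
  std::vector<double> w;
  std::vector<int> nc;
  const int* nbr;  // 0-based neighbour indices, CSR layout
  const int* ptr;  // offsets, length N + 1
  int N;
  long ncoop;
  double sum_w_C, sum_w_D;
  long empty_cmp;  // elementary steps whose comparison set was empty

  void init(const IntegerVector& strategy, const NumericVector& ww,
            const IntegerVector& nbr_, const IntegerVector& ptr_) {
    N = strategy.size();
    s.assign(strategy.begin(), strategy.end());
    w.assign(ww.begin(), ww.end());
    nbr = nbr_.begin();
    ptr = ptr_.begin();
    nc.assign(N, 0);
    ncoop = 0;
    sum_w_C = sum_w_D = 0.0;
    empty_cmp = 0;
    for (int i = 0; i < N; ++i) {
      if (s[i] == 1) { ++ncoop; sum_w_C += w[i]; } else { sum_w_D += w[i]; }
      for (int j = ptr[i]; j < ptr[i + 1]; ++j)
        if (s[nbr[j]] == 1) ++nc[i];
    }
  }
};

struct StepInfo {
  int site, neighbour;
  bool adopted;
  double px, py, pbar;
  bool pbar_valid;
  double w_before, w_after;
};

// One elementary update. Consumes exactly three uniforms (site, neighbour,
// acceptance) regardless of branch, so a seeded stream is reproducible.
// All payoffs are evaluated on the pre-adoption configuration; the w update
// reuses them. `want_info` forces the environment average to be computed
// even when the rule gating would skip the w update.
static void one_update(State& st, const Par& p, bool want_info, StepInfo* info) {
  double u1 = unif_rand();
  int x = (int)(u1 * st.N);
  if (x >= st.N) x = st.N - 1;
  int k0 = st.ptr[x], kx = st.ptr[x + 1] - k0;

  double u2 = unif_rand();
  int j = (int)(u2 * kx);
  if (j >= kx) j = kx - 1;
  int y = st.nbr[k0 + j];

  double px = site_payoff(st.s[x], st.nc[x], p.b);
  double py = site_payoff(st.s[y], st.nc[y], p.b);
  double prob = fermi_prob(px, py, st.w[x], p.K);
  double u3 = unif_rand();
  bool adopted = (u3 < prob);

  int s_pre = st.s[x];
  int s_post = adopted ? st.s[y] : s_pre;
  int s_gate = p.gate_post ? s_post : s_pre;
  bool enabled = rule_enabled(p.rule, s_gate);

  // Environment average from pre-adoption payoffs; comparison set is
  // selected against the focal player's pre-adoption strategy.
  double pbar = 0.0;
  bool pbar_valid = false;
  bool need_pbar = want_info || (enabled && p.d > 0.0);
  if (need_pbar) {
    double acc = 0.0;
    int nsel = 0;
    for (int jj = k0; jj < k0 + kx; ++jj) {
      int n = st.nbr[jj];
      bool take = (p.cmp == 0) ||
                  (p.cmp == 1 && st.s[n] == s_pre) ||
                  (p.cmp == 2 && st.s[n] != s_pre);
      if (take) {
        acc += site_payoff(st.s[n], st.nc[n], p.b);
        ++nsel;
      }
    }
    if (nsel > 0) { pbar = acc / nsel; pbar_valid = true; }
  }

  // Apply the strategy flip after all payoffs are read off.
  if (adopted && s_post != s_pre) {
    st.s[x] = s_post;
    int delta = (s_post == 1) ? 1 : -1;
    for (int jj = k0; jj < k0 + kx; ++jj) st.nc[st.nbr[jj]] += delta;
    st.ncoop += delta;
    if (s_post == 1) { st.sum_w_C += st.w[x]; st.sum_w_D -= st.w[x]; }
    else             { st.sum_w_D += st.w[x]; st.sum_w_C -= st.w[x]; }
  }

  double w_before = st.w[x], w_after = w_before;
  if (enabled && p.d > 0.0) {
    if (pbar_valid) {
      w_after = (px < pbar) ? w_before + p.d : w_before - p.d;
      if (w_after > p.w_max) w_after = p.w_max;
      if (w_after < p.w_min) w_after = p.w_min;
      if (w_after != w_before) {
        if (st.s[x] == 1) st.sum_w_C += w_after - w_before;
        else              st.sum_w_D += w_after - w_before;
        st.w[x] = w_after;
      }
    } else {
      ++st.empty_cmp;
    }
  }

  if (want_info) {
    info->site = x;
    info->neighbour = y;
    info->adopted = adopted;
    info->px = px;
    info->py = py;
    info->pbar = pbar;
    info->pbar_valid = pbar_valid;
    info->w_before = w_before;
    info->w_after = w_after;
  }
}

// [[Rcpp::export]]
List elementary_update_cpp(IntegerVector strategy, NumericVector w,
                           IntegerVector nbr, IntegerVector ptr, List par) {
  Par p = parse_par(par);
  State st;
  st.init(strategy, w, nbr, ptr);
  StepInfo info;
  one_update(st, p, true, &info);
  return List::create(
      _["strategy"] = IntegerVector(st.s.begin(), st.s.end()),
      _["w"] = NumericVector(st.w.begin(), st.w.end()),
      _["site"] = info.site,
      _["neighbour"] = info.neighbour,
      _["adopted"] = info.adopted,
      _["payoff_focal"] = info.px,
      _["payoff_neighbour"] = info.py,
      _["env_avg"] = info.pbar_valid ? info.pbar : NA_REAL,
      _["w_before"] = info.w_before,
      _["w_after"] = info.w_after);
}

// Monte Carlo driver: n_steps full MC steps of N elementary updates each.
// Records f_C and per-class mean w at step 0 and every `record_every`
// steps (plus the absorption step). Stationary f_C is the mean over the
// trailing `average_window` steps, or the absorbed value on early stop.
// [[Rcpp::export]]
List run_mc_cpp(IntegerVector strategy, NumericVector w,
                IntegerVector nbr, IntegerVector ptr, List par,
                int n_steps, int record_every, int average_window,
                bool early_stop) {
  Par p = parse_par(par);
  State st;
  st.init(strategy, w, nbr, ptr);
  int N = st.N;

  std::vector<int> rec_t;
  std::vector<double> rec_fc, rec_mwc, rec_mwd;
  std::vector<double> fc_all;
  fc_all.reserve(n_steps);

  auto record = [&](int t) {
    rec_t.push_back(t);
    rec_fc.push_back((double)st.ncoop / N);
    rec_mwc.push_back(st.ncoop > 0 ? st.sum_w_C / st.ncoop : NA_REAL);
    rec_mwd.push_back(st.ncoop < N ? st.sum_w_D / (N - st.ncoop) : NA_REAL);
  };
  record(0);

  int absorbed_step = -1;
  int steps_run = 0;
  for (int t = 1; t <= n_steps; ++t) {
    for (int e = 0; e < N; ++e) one_update(st, p, false, nullptr);
    steps_run = t;
    fc_all.push_back((double)st.ncoop / N);
    bool absorbed = (st.ncoop == 0 || st.ncoop == N);
    if (t % record_every == 0 || (absorbed && early_stop && absorbed_step < 0))
      record(t);
    if (absorbed && early_stop) { absorbed_step = t; break; }
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  double stationary;
  if (absorbed_step >= 0) {
    stationary = (double)st.ncoop / N;
  } else {
    int win = average_window < steps_run ? average_window : steps_run;
    double acc = 0.0;
    for (int i = steps_run - win; i < steps_run; ++i) acc += fc_all[i];
    stationary = win > 0 ? acc / win : (double)st.ncoop / N;
  }

  return List::create(
      _["strategy"] = IntegerVector(st.s.begin(), st.s.end()),
      _["w"] = NumericVector(st.w.begin(), st.w.end()),
      _["t"] = IntegerVector(rec_t.begin(), rec_t.end()),
      _["f_C"] = NumericVector(rec_fc.begin(), rec_fc.end()),
      _["mean_w_C"] = NumericVector(rec_mwc.begin(), rec_mwc.end()),
      _["mean_w_D"] = NumericVector(rec_mwd.begin(), rec_mwd.end()),
      _["stationary_f_C"] = stationary,
      _["absorbed_step"] = absorbed_step,
      _["steps_run"] = steps_run,
      _["empty_comparison"] = (double)st.empty_cmp);
}
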