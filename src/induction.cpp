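#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Log-rank machinery.
//
// All statistics are computed against the FULL dataset: covered group vs the
// rest. Records are bucketed by the distinct event times e_1 < ... < e_E of
// the whole dataset: bucket(i) = number of event times <= time[i] (bucket 0
// lies before the first event time and is never at risk at an event time).
// The at-risk weight of a group at e_t is then the suffix sum of its bucket
// weights over t..E, and its event weight at e_t is the weight of its events
// in bucket t. Terms with total at-risk weight <= 1 contribute 0; y == 0
// maps the statistic to 0 (degenerate splits rank lowest).
// ---------------------------------------------------------------------------

struct Buckets {
  int E;                       // number of distinct event times
  std::vector<int> bucket;     // per record, 0..E
  std::vector<double> Wtot;    // total weight per bucket (size E + 1)
  std::vector<double> Dtot;    // total event weight per bucket
};

static Buckets make_buckets(const NumericVector& time,
                            const IntegerVector& status,
                            const NumericVector& w) {
  const int n = time.size();
  std::vector<double> ev;
  ev.reserve(n);
  for (int i = 0; i < n; ++i)
    if (status[i] == 1) ev.push_back(time[i]);
  std::sort(ev.begin(), ev.end());
  ev.erase(std::unique(ev.begin(), ev.end()), ev.end());

  Buckets b;
  b.E = (int) ev.size();
  b.bucket.resize(n);
  b.Wtot.assign(b.E + 1, 0.0);
  b.Dtot.assign(b.E + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    const int t = (int) (std::upper_bound(ev.begin(), ev.end(), time[i]) -
                         ev.begin());
    b.bucket[i] = t;
    b.Wtot[t] += w[i];
    if (status[i] == 1) b.Dtot[t] += w[i];  // event times map exactly
  }
  return b;
}

// statistic of (covered group given by bucket arrays WC/DC) vs the rest
static double stat_from_buckets(const Buckets& b,
                                const std::vector<double>& WC,
                                const std::vector<double>& DC) {
  double rc = 0.0, r = 0.0, x = 0.0, y = 0.0;
  for (int t = b.E; t >= 1; --t) {
    rc += WC[t];
    r += b.Wtot[t];
    const double d = b.Dtot[t];
    if (d > 0.0 && r > 1.0) {
      const double dc = DC[t];
      const double du = d - dc;
      const double ru = r - rc;
      x += du - ru / r * d;
      y += rc * ru * d * (r - d) / (r * r * (r - 1.0));
    }
  }
  if (y <= 0.0) return 0.0;
  return x * x / y;
}

// plain-mask statistic (exported; also used by pruning)
static double logrank_mask(const Buckets& b, const std::vector<char>& covered,
                           const IntegerVector& status,
                           const NumericVector& w) {
  std::vector<double> WC(b.E + 1, 0.0), DC(b.E + 1, 0.0);
  for (size_t i = 0; i < covered.size(); ++i) {
    if (covered[i]) {
      WC[b.bucket[i]] += w[i];
      if (status[i] == 1) DC[b.bucket[i]] += w[i];
    }
  }
  return stat_from_buckets(b, WC, DC);
}

// [[Rcpp::export(name = ".logrank_mask_cpp")]]
double logrank_mask_cpp(NumericVector time, IntegerVector status,
                        NumericVector weight, LogicalVector covered) {
  Buckets b = make_buckets(time, status, weight);
  std::vector<char> cov(time.size());
  for (int i = 0; i < (int) time.size(); ++i) cov[i] = covered[i] ? 1 : 0;
  return logrank_mask(b, cov, status, weight);
}

// ---------------------------------------------------------------------------
// Rule growing.
// ---------------------------------------------------------------------------

struct Cond {
  int attr;    // 0-based column
  int op;      // 1 ==, 2 <, 3 >=
  double value;
};

struct Best {
  bool found = false;
  Cond cond = {-1, 0, 0.0};
  double stat = -1.0, cov_w = -1.0;
};

// tie order: larger statistic, larger covered weight, lower attribute index,
// smaller value, '<' before '>=' (op code 2 before 3)
static void consider(Best& best, const Cond& c, double stat, double cov_w) {
  bool better;
  if (!best.found) better = true;
  else if (stat != best.stat) better = stat > best.stat;
  else if (cov_w != best.cov_w) better = cov_w > best.cov_w;
  else if (c.attr != best.cond.attr) better = c.attr < best.cond.attr;
  else if (c.value != best.cond.value) better = c.value < best.cond.value;
  else better = c.op < best.cond.op;
  if (better) {
    best.found = true;
    best.cond = c;
    best.stat = stat;
    best.cov_w = cov_w;
  }
}

static bool in_premise(const std::vector<Cond>& premise, const Cond& c) {
  for (const Cond& pc : premise)
    if (pc.attr == c.attr && pc.op == c.op && pc.value == c.value) return true;
  return false;
}

// Greedy growing. X holds covariates (nominal columns coded 1..k, NA for
// missing); prev_covered marks records covered by earlier rules. At each
// step every candidate condition built from the currently covered records is
// scored by the log-rank statistic of (tentative covered) vs the rest of the
// full dataset; candidates leaving < mincov previously-uncovered weight
// covered are discarded, as are duplicates of premise conditions (a guard
// that guarantees termination: numeric candidates strictly shrink coverage,
// so only a repeated identical condition could cycle). Numeric candidates
// are evaluated by threshold sweeps that update the covered-group bucket
// arrays incrementally.
// [[Rcpp::export(name = ".grow_rule_cpp")]]
List grow_rule_cpp(NumericMatrix X, LogicalVector is_nominal,
                   NumericVector time, IntegerVector status,
                   NumericVector weight, LogicalVector prev_covered,
                   double mincov, int max_conditions) {
  const int n = X.nrow(), p = X.ncol();
  const double mincov_eps = mincov - 1e-9;
  Buckets b = make_buckets(time, status, weight);
  std::vector<char> covered(n, 1);   // empty premise covers everything
  std::vector<Cond> premise;

  std::vector<double> WC(b.E + 1), DC(b.E + 1);
  std::vector<std::pair<double, int> > vals;  // (value, record)
  vals.reserve(n);

  while (max_conditions <= 0 || (int) premise.size() < max_conditions) {
    Best best;

    for (int j = 0; j < p; ++j) {
      vals.clear();
      for (int i = 0; i < n; ++i)
        if (covered[i] && !NumericMatrix::is_na(X(i, j)))
          vals.push_back(std::make_pair(X(i, j), i));
      if (vals.empty()) continue;
      std::sort(vals.begin(), vals.end());
      const int m = (int) vals.size();

      // add record to the running tentative group
      double new_w = 0.0, cov_w = 0.0;
      auto reset_group = [&]() {
        std::fill(WC.begin(), WC.end(), 0.0);
        std::fill(DC.begin(), DC.end(), 0.0);
        new_w = cov_w = 0.0;
      };
      auto add_rec = [&](int i) {
        WC[b.bucket[i]] += weight[i];
        if (status[i] == 1) DC[b.bucket[i]] += weight[i];
        cov_w += weight[i];
        if (!prev_covered[i]) new_w += weight[i];
      };
      auto evaluate = [&](int op, double value) {
        Cond c = {j, op, value};
        if (new_w < mincov_eps || in_premise(premise, c)) return;
        consider(best, c, stat_from_buckets(b, WC, DC), cov_w);
      };

      if (is_nominal[j]) {
        // one equality candidate per observed value (level-code order)
        int lo = 0;
        while (lo < m) {
          int hi = lo;
          reset_group();
          while (hi < m && vals[hi].first == vals[lo].first)
            add_rec(vals[hi++].second);
          evaluate(1, vals[lo].first);
          lo = hi;
        }
      } else {
        // ascending sweep for 'value < split'
        reset_group();
        int lo = 0;
        while (lo < m) {
          int hi = lo;
          while (hi < m && vals[hi].first == vals[lo].first)
            add_rec(vals[hi++].second);
          if (hi < m)
            evaluate(2, (vals[lo].first + vals[hi].first) / 2.0);
          lo = hi;
        }
        // descending sweep for 'value >= split'
        reset_group();
        int hi2 = m - 1;
        while (hi2 >= 0) {
          int lo2 = hi2;
          while (lo2 >= 0 && vals[lo2].first == vals[hi2].first)
            add_rec(vals[lo2--].second);
          if (lo2 >= 0)
            evaluate(3, (vals[lo2].first + vals[hi2].first) / 2.0);
          hi2 = lo2;
        }
      }
    }

    if (!best.found) break;
    premise.push_back(best.cond);
    const Cond& c = best.cond;
    for (int i = 0; i < n; ++i) {
      if (!covered[i]) continue;
      const double v = X(i, c.attr);
      bool ok = !NumericMatrix::is_na(v);
      if (ok)
        ok = (c.op == 1) ? (v == c.value)
           : (c.op == 2) ? (v < c.value)
                         : (v >= c.value);
      covered[i] = ok ? 1 : 0;
    }
  }

  const int k = (int) premise.size();
  IntegerVector attr(k), op(k);
  NumericVector value(k);
  for (int i = 0; i < k; ++i) {
    attr[i] = premise[i].attr + 1;  // 1-based for R
    op[i] = premise[i].op;
    value[i] = premise[i].value;
  }
  LogicalVector cov_out(n);
  for (int i = 0; i < n; ++i) cov_out[i] = covered[i] == 1;
  return List::create(_["attr"] = attr, _["op"] = op, _["value"] = value,
                      _["covered"] = cov_out);
}

// ---------------------------------------------------------------------------
// Pruning: hill-climbing deletion. masks holds per-condition coverage of the
// full dataset; at each step the single removal that yields the largest
// STRICT increase of the statistic is performed; stop when none improves or
// one condition remains. Returns which conditions to keep.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".prune_rule_cpp")]]
List prune_rule_cpp(LogicalMatrix masks, NumericVector time,
                    IntegerVector status, NumericVector weight) {
  const int n = masks.nrow(), k = masks.ncol();
  Buckets b = make_buckets(time, status, weight);

  std::vector<char> active(k, 1);
  int n_active = k;
  std::vector<int> cnt(n, 0);   // active conditions covering each record
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j)
      if (masks(i, j)) ++cnt[i];

  std::vector<char> cov(n);
  for (int i = 0; i < n; ++i) cov[i] = cnt[i] == n_active ? 1 : 0;
  double quality = logrank_mask(b, cov, status, weight);

  while (n_active > 1) {
    int best_j = -1;
    double best_stat = quality;
    for (int j = 0; j < k; ++j) {
      if (!active[j]) continue;
      for (int i = 0; i < n; ++i)
        cov[i] = (cnt[i] - (masks(i, j) ? 1 : 0)) == n_active - 1 ? 1 : 0;
      const double s = logrank_mask(b, cov, status, weight);
      if (s > best_stat) {        // strict improvement, first index on ties
        best_stat = s;
        best_j = j;
      }
    }
    if (best_j < 0) break;
    active[best_j] = 0;
    --n_active;
    for (int i = 0; i < n; ++i)
      if (masks(i, best_j)) --cnt[i];
    quality = best_stat;
  }

  LogicalVector keep(k);
  for (int j = 0; j < k; ++j) keep[j] = active[j] == 1;
  LogicalVector covered(n);
  for (int i = 0; i < n; ++i) covered[i] = cnt[i] == n_active;
  return List::create(_["keep"] = keep, _["quality"] = quality,
                      _["covered"] = covered);
}
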