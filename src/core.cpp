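// Fast synchronous Boolean-network dynamics. The R side passes a "compiled"
// network: flat regulator/truth-table arrays with per-gene offsets. All
// randomness stays on the R side except derrida sampling, which draws from
// the R RNG (so set.seed() governs it too).
#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// enc fields (all 0-based):
//   n        gene count
//   reg_ptr  int[n+1]  offsets into reg_idx
//   reg_idx  positions (0..n-1) of each gene's distinct regulators,
//            ascending id; bit j of the truth-table index = activity of
//            the j-th regulator (lowest id = least significant bit)
//   tt_ptr   int[n+1]  offsets into tt_val
//   tt_val   truth-table outputs, 2^k entries per gene
struct Enc {
  int n;
  const int *reg_ptr, *reg_idx, *tt_ptr, *tt_val;
  explicit Enc(const List& e)
    : n(as<int>(e["n"])),
      reg_ptr(INTEGER(as<IntegerVector>(e["reg_ptr"]))),
      reg_idx(INTEGER(as<IntegerVector>(e["reg_idx"]))),
      tt_ptr(INTEGER(as<IntegerVector>(e["tt_ptr"]))),
      tt_val(INTEGER(as<IntegerVector>(e["tt_val"]))) {}
};

static inline void step_state(const Enc& e, const std::vector<int>& s,
                              std::vector<int>& out) {
  for (int i = 0; i < e.n; ++i) {
    int idx = 0, b = 0;
    for (int j = e.reg_ptr[i]; j < e.reg_ptr[i + 1]; ++j, ++b)
      idx |= s[e.reg_idx[j]] << b;
    out[i] = e.tt_val[e.tt_ptr[i] + idx];
  }
}

static inline std::string key_of(const std::vector<int>& s) {
  std::string k(s.size(), '0');
  for (size_t i = 0; i < s.size(); ++i) k[i] = s[i] ? '1' : '0';
  return k;
}

// [[Rcpp::export]]
IntegerVector rbn_step_cpp(List enc, IntegerVector state) {
  Enc e(enc);
  if ((int)state.size() != e.n) stop("state length does not match network size");
  std::vector<int> s(state.begin(), state.end()), out(e.n);
  step_state(e, s, out);
  return IntegerVector(out.begin(), out.end());
}

static IntegerMatrix cycle_matrix(const std::vector<std::vector<int> >& states,
                                  int from, int to, int n) {
  IntegerMatrix m(to - from, n);
  for (int t = from; t < to; ++t)
    for (int i = 0; i < n; ++i) m(t - from, i) = states[t][i];
  return m;
}

// Follow the trajectory from s0 until a state repeats; the cycle between the
// two visits is the attractor and the index of the first visit is the
// transient length. found=FALSE when max_steps is exhausted first.
// [[Rcpp::export]]
List rbn_traj_cpp(List enc, IntegerVector s0, int max_steps) {
  Enc e(enc);
  if ((int)s0.size() != e.n) stop("state length does not match network size");
  std::vector<std::vector<int> > states;
  std::unordered_map<std::string, int> seen;
  std::vector<int> s(s0.begin(), s0.end()), nxt(e.n);
  for (int t = 0; t <= max_steps; ++t) {
    std::string k = key_of(s);
    std::unordered_map<std::string, int>::iterator it = seen.find(k);
    if (it != seen.end()) {
      return List::create(_["found"] = true,
                          _["cycle"] = cycle_matrix(states, it->second,
                                                    (int)states.size(), e.n),
                          _["transient"] = it->second);
    }
    seen[k] = t;
    states.push_back(s);
    step_state(e, s, nxt);
    s.swap(nxt);
  }
  return List::create(_["found"] = false);
}

// Relaxation inside a fixed window: the cycle must close entirely within
// `window` steps or nothing is returned.
// [[Rcpp::export]]
List rbn_relax_cpp(List enc, IntegerVector s0, int window) {
  return rbn_traj_cpp(enc, s0, window);
}

// TRUE iff stepping row t of `cycle` yields row (t+1) mod period, i.e. the
// given state sequence is an exact periodic orbit of the network.
// [[Rcpp::export]]
bool rbn_closure_cpp(List enc, IntegerMatrix cycle) {
  Enc e(enc);
  int p = cycle.nrow();
  if (cycle.ncol() != e.n) stop("cycle width does not match network size");
  std::vector<int> s(e.n), nxt(e.n);
  for (int t = 0; t < p; ++t) {
    for (int i = 0; i < e.n; ++i) s[i] = cycle(t, i);
    step_state(e, s, nxt);
    int tn = (t + 1) % p;
    for (int i = 0; i < e.n; ++i)
      if (nxt[i] != cycle(tn, i)) return false;
  }
  return true;
}

// Exhaustive sweep of all 2^n states with memoised state -> attractor-id
// labels. States are encoded as integers (bit i = gene i), so n must stay
// below the width of a signed 32-bit code.
// [[Rcpp::export]]
List rbn_enum_cpp(List enc) {
  Enc e(enc);
  if (e.n > 28) stop("network too large for exhaustive enumeration");
  const long nstates = 1L << e.n;
  std::vector<int> label((size_t)nstates, -1);
  std::vector<std::vector<long> > cycles;
  std::vector<long> path;
  std::vector<int> s(e.n), nxt(e.n);

  for (long start = 0; start < nstates; ++start) {
    if (label[start] != -1) continue;
    path.clear();
    long code = start;
    int hit = -1;
    while (true) {
      if (label[code] >= 0) { hit = label[code]; break; }
      if (label[code] == -2) {
        // closed a new cycle inside the current path
        size_t pos = 0;
        while (path[pos] != code) ++pos;
        std::vector<long> cyc(path.begin() + pos, path.end());
        hit = (int)cycles.size();
        cycles.push_back(cyc);
        break;
      }
      label[code] = -2;
      path.push_back(code);
      for (int i = 0; i < e.n; ++i) s[i] = (int)((code >> i) & 1L);
      step_state(e, s, nxt);
      code = 0;
      for (int i = 0; i < e.n; ++i) if (nxt[i]) code |= 1L << i;
    }
    for (size_t t = 0; t < path.size(); ++t) label[path[t]] = hit;
  }

  IntegerVector basin((int)cycles.size());
  for (long c = 0; c < nstates; ++c) basin[label[c]]++;
  List cyc_out((int)cycles.size());
  for (size_t a = 0; a < cycles.size(); ++a) {
    IntegerMatrix m((int)cycles[a].size(), e.n);
    for (size_t t = 0; t < cycles[a].size(); ++t)
      for (int i = 0; i < e.n; ++i) m((int)t, i) = (int)((cycles[a][t] >> i) & 1L);
    cyc_out[(int)a] = m;
  }
  return List::create(_["cycles"] = cyc_out, _["basin_sizes"] = basin);
}

// One-step Derrida statistics: for each initial Hamming distance d in 1..n,
// average the normalised distance after one synchronous update over n_pairs
// random state pairs at distance d. Uses the R RNG.
// [[Rcpp::export]]
NumericVector rbn_derrida_cpp(List enc, int n_pairs) {
  Enc e(enc);
  RNGScope scope;
  NumericVector out(e.n);
  std::vector<int> s1(e.n), s2(e.n), n1(e.n), n2(e.n), perm(e.n);
  for (int d = 1; d <= e.n; ++d) {
    double acc = 0.0;
    for (int r = 0; r < n_pairs; ++r) {
      for (int i = 0; i < e.n; ++i) {
        s1[i] = unif_rand() < 0.5 ? 1 : 0;
        perm[i] = i;
      }
      // partial Fisher-Yates: first d entries = positions to flip
      for (int i = 0; i < d; ++i) {
        int j = i + (int)(unif_rand() * (e.n - i));
        if (j >= e.n) j = e.n - 1;
        std::swap(perm[i], perm[j]);
      }
      s2 = s1;
      for (int i = 0; i < d; ++i) s2[perm[i]] ^= 1;
      step_state(e, s1, n1);
      step_state(e, s2, n2);
      int h = 0;
      for (int i = 0; i < e.n; ++i) h += (n1[i] != n2[i]);
      acc += (double)h / e.n;
    }
    out[d - 1] = acc / n_pairs;
  }
  return out;
}
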