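// OOPS motif finder internals: exhaustive search over all position tuples
// and a Gibbs site sampler.  Sequences arrive as 0-based integer vectors.
// The sampler uses its own mt19937_64 stream keyed by the caller's seed so
// results are reproducible independently of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

typedef std::vector<std::vector<int> > SeqVec;

static SeqVec as_seqs(const List& seqs) {
  SeqVec out;
  out.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    out.push_back(std::vector<int>(v.begin(), v.end()));
  }
  return out;
}

// tab[k][c] = (c/n) * log2((c/n) / g_k), with the 0 log 0 = 0 convention
static std::vector<std::vector<double> > div_table(int n,
                                                   const NumericVector& g) {
  int A = g.size();
  std::vector<std::vector<double> > t(A, std::vector<double>(n + 1, 0.0));
  for (int k = 0; k < A; ++k)
    for (int c = 1; c <= n; ++c) {
      double f = (double)c / n;
      t[k][c] = f * std::log2(f / g[k]);
    }
  return t;
}

static double counts_divergence(const std::vector<int>& cnt, int W, int A,
                                const std::vector<std::vector<double> >& tab) {
  double d = 0.0;
  for (int j = 0; j < W; ++j)
    for (int k = 0; k < A; ++k)
      d += tab[k][cnt[j * A + k]];
  return d;
}

static bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i]) return a[i] < b[i];
  }
  return false;
}

struct ExhState {
  const SeqVec* seqs;
  int n, W, A;
  const std::vector<std::vector<double> >* tab;
  std::vector<int> cnt, pos, best_pos;
  double best;
  bool found;
};

static void exh_rec(ExhState& st, int i) {
  if (i == st.n) {
    double d = counts_divergence(st.cnt, st.W, st.A, *st.tab);
    // lexicographic enumeration: the first configuration reaching a score
    // is the lexicographically smallest, so strict improvement suffices
    if (!st.found || d > st.best + 1e-12) {
      st.best = d;
      st.best_pos = st.pos;
      st.found = true;
    }
    return;
  }
  const std::vector<int>& s = (*st.seqs)[i];
  int cand = (int)s.size() - st.W + 1;
  for (int p = 0; p < cand; ++p) {
    for (int j = 0; j < st.W; ++j) st.cnt[j * st.A + s[p + j]]++;
    st.pos[i] = p;
    exh_rec(st, i + 1);
    for (int j = 0; j < st.W; ++j) st.cnt[j * st.A + s[p + j]]--;
  }
}

// [[Rcpp::export]]
List cpp_exhaustive(List seqs, int W, NumericVector g) {
  ExhState st;
  SeqVec sv = as_seqs(seqs);
  st.seqs = &sv;
  st.n = (int)sv.size();
  st.W = W;
  st.A = (int)g.size();
  std::vector<std::vector<double> > tab = div_table(st.n, g);
  st.tab = &tab;
  st.cnt.assign(W * st.A, 0);
  st.pos.assign(st.n, 0);
  st.best = -1.0;
  st.found = false;
  exh_rec(st, 0);
  return List::create(_["positions"] = IntegerVector(st.best_pos.begin(),
                                                     st.best_pos.end()),
                      _["score"] = st.best);
}

// [[Rcpp::export]]
List cpp_gibbs(List seqs, int W, NumericVector g, int restarts,
               int iterations, double seed) {
  SeqVec sv = as_seqs(seqs);
  int n = (int)sv.size();
  int A = (int)g.size();
  std::vector<std::vector<double> > tab = div_table(n, g);
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<int> cand(n);
  int max_cand = 0;
  for (int i = 0; i < n; ++i) {
    cand[i] = (int)sv[i].size() - W + 1;
    if (cand[i] > max_cand) max_cand = cand[i];
  }

  std::vector<int> cnt(W * A), pos(n), best_pos;
  std::vector<double> lod(W * A), sc(max_cand);
  double bestD = -1.0;
  bool found = false;

  for (int r = 0; r < restarts; ++r) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) {
      pos[i] = (int)(rng() % (uint64_t)cand[i]);
      for (int j = 0; j < W; ++j) cnt[j * A + sv[i][pos[i] + j]]++;
    }
    double d0 = counts_divergence(cnt, W, A, tab);
    if (!found || d0 > bestD + 1e-12) {
      bestD = d0; best_pos = pos; found = true;
    } else if (d0 > bestD - 1e-12 && lex_less(pos, best_pos)) {
      best_pos = pos;
    }

    for (int it = 0; it < iterations; ++it) {
      int i = it % n;  // round-robin hold-out, for reproducibility
      const std::vector<int>& s = sv[i];
      for (int j = 0; j < W; ++j) cnt[j * A + s[pos[i] + j]]--;
      // predictive model from the remaining n-1 sites, pseudocount g_k
      // per column: model = (c + g_k) / ((n-1) + 1); log-odds vs g
      for (int j = 0; j < W; ++j)
        for (int k = 0; k < A; ++k)
          lod[j * A + k] = std::log((cnt[j * A + k] + g[k]) / ((double)n * g[k]));
      int C = cand[i];
      double mx = -HUGE_VAL;
      for (int p = 0; p < C; ++p) {
        double v = 0.0;
        const int* sp = &s[p];
        for (int j = 0; j < W; ++j) v += lod[j * A + sp[j]];
        sc[p] = v;
        if (v > mx) mx = v;
      }
      double tot = 0.0;
      for (int p = 0; p < C; ++p) {
        sc[p] = std::exp(sc[p] - mx);
        tot += sc[p];
      }
      double u = unif(rng) * tot, acc = 0.0;
      int newp = C - 1;
      for (int p = 0; p < C; ++p) {
        acc += sc[p];
        if (u <= acc) { newp = p; break; }
      }
      pos[i] = newp;
      for (int j = 0; j < W; ++j) cnt[j * A + s[newp + j]]++;

      double d = counts_divergence(cnt, W, A, tab);
      if (!found || d > bestD + 1e-12) {
        bestD = d; best_pos = pos; found = true;
      } else if (d > bestD - 1e-12 && lex_less(pos, best_pos)) {
        best_pos = pos;
      }
    }
  }
  return List::create(_["positions"] = IntegerVector(best_pos.begin(),
                                                     best_pos.end()),
                      _["score"] = bestD);
}
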