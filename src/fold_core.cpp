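#include <Rcpp.h>
using namespace Rcpp;

// Simplified nearest-neighbour-flavoured energetics for the built-in
// folding backend. Values are calibrated so that a >=16 bp near-perfect
// duplex scores well below -14 kcal/mol while unpairable sequence scores 0.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

// pair strength: 0 = no pair, else weight (GC > AU > GU)
static inline double pair_strength(int a, int b) {
  if (a < 0 || b < 0) return 0.0;
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return 2.6; // C-G
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1.2; // A-U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 0.7; // G-U
  return 0.0;
}

// stacking energy of pair (s1) stacked on pair (s2)
static inline double stack_energy(double s1, double s2) {
  return -(s1 + s2) / 2.0 - 0.8;
}

// [[Rcpp::export]]
List duplex_fold_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  const double INIT = 4.1;           // duplex initiation penalty
  const double LOOP_OPEN = 1.8;      // interior loop / bulge opening
  const double LOOP_NT = 0.45;       // per unpaired nt inside a loop
  const int MAX_GAP = 12;
  if (n == 0 || m == 0) stop("empty sequence in duplex fold");

  std::vector<int> ca(n), cb(m);
  for (int i = 0; i < n; ++i) ca[i] = base_code(a[i]);
  for (int j = 0; j < m; ++j) cb[j] = base_code(b[j]);

  const double INF = 1e9;
  // E[i][j]: best energy (excluding INIT) of duplex whose outermost-right
  // pair is (a_i, b_j); pairs run with i increasing and j decreasing.
  std::vector<std::vector<double> > E(n, std::vector<double>(m, INF));
  std::vector<std::vector<int> > Pi(n, std::vector<int>(m, -1)),
      Pj(n, std::vector<int>(m, -1));

  double best = INF;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      double s = pair_strength(ca[i], cb[j]);
      if (s <= 0.0) continue;
      E[i][j] = 0.0; // first pair of the duplex
      for (int p = std::max(0, i - 1 - MAX_GAP); p < i; ++p) {
        for (int q = j + 1; q <= std::min(m - 1, j + 1 + MAX_GAP); ++q) {
          if (E[p][q] >= INF) continue;
          double sp = pair_strength(ca[p], cb[q]);
          double cost;
          if (p == i - 1 && q == j + 1) {
            cost = stack_energy(sp, s);
          } else {
            int gap = (i - p - 1) + (q - j - 1);
            cost = LOOP_OPEN + LOOP_NT * gap;
          }
          double cand = E[p][q] + cost;
          if (cand < E[i][j]) {
            E[i][j] = cand;
            Pi[i][j] = p;
            Pj[i][j] = q;
          }
        }
      }
      if (E[i][j] + INIT < best) {
        best = E[i][j] + INIT;
        bi = i;
        bj = j;
      }
    }
  }

  if (bi < 0 || best >= 0.0) {
    return List::create(_["mfe"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2));
  }
  std::vector<std::pair<int, int> > pr;
  int i = bi, j = bj;
  while (i >= 0) {
    pr.push_back(std::make_pair(i + 1, j + 1));
    int ni = Pi[i][j], nj = Pj[i][j];
    i = ni;
    j = nj;
    if (i < 0) break;
  }
  IntegerMatrix pairs(pr.size(), 2);
  for (size_t k = 0; k < pr.size(); ++k) {
    pairs(k, 0) = pr[pr.size() - 1 - k].first;
    pairs(k, 1) = pr[pr.size() - 1 - k].second;
  }
  return List::create(_["mfe"] = best, _["pairs"] = pairs);
}

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq) {
  const int n = seq.size();
  const int MINLOOP = 3;
  if (n == 0) stop("empty sequence in hairpin fold");
  std::vector<int> c(n);
  for (int i = 0; i < n; ++i) c[i] = base_code(seq[i]);

  // maximise summed pair weights (Nussinov with weighted pairs)
  std::vector<std::vector<double> > W(n, std::vector<double>(n, 0.0));
  for (int len = MINLOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double bestv = W[i + 1][j]; // i unpaired
      if (W[i][j - 1] > bestv) bestv = W[i][j - 1];
      double s = pair_strength(c[i], c[j]);
      if (s > 0.0 && j - i > MINLOOP) {
        double v = s + (i + 1 <= j - 1 ? W[i + 1][j - 1] : 0.0);
        if (v > bestv) bestv = v;
      }
      for (int k = i + 1; k < j; ++k) {
        double v = W[i][k] + W[k + 1][j];
        if (v > bestv) bestv = v;
      }
      W[i][j] = bestv;
    }
  }

  // traceback
  std::string db(n, '.');
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    if (W[i][j] == W[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    if (W[i][j] == W[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    double s = pair_strength(c[i], c[j]);
    if (s > 0.0 && j - i > MINLOOP &&
        W[i][j] == s + (i + 1 <= j - 1 ? W[i + 1][j - 1] : 0.0)) {
      db[i] = '(';
      db[j] = ')';
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    bool done = false;
    for (int k = i + 1; k < j && !done; ++k) {
      if (W[i][j] == W[i][k] + W[k + 1][j]) {
        stack.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(k + 1, j));
        done = true;
      }
    }
  }

  double w = W[0][n - 1];
  double mfe = 0.0;
  if (w > 0.0) {
    mfe = 4.1 - 1.3 * w;
    if (mfe > 0.0) mfe = 0.0;
  }
  if (mfe == 0.0) std::fill(db.begin(), db.end(), '.');
  return List::create(_["mfe"] = mfe, _["structure"] = db);
}

// Classify one genome-unmapped read against a candidate precursor
// sequence: 2 = tailed (all mismatches form a contiguous 3'-terminal
// run of <= max_tail nt consisting only of A/T), 1 = mismatches
// elsewhere (1..max_other), 0 = no usable alignment.
// [[Rcpp::export]]
int classify_unmapped_cpp(std::string read, std::string tmpl,
                          int max_tail = 3, int max_other = 2) {
  const int L = read.size(), T = tmpl.size();
  if (L == 0 || T < L) return 0;
  bool any_other = false;
  std::vector<int> mm;
  mm.reserve(L);
  for (int off = 0; off + L <= T; ++off) {
    mm.clear();
    for (int k = 0; k < L; ++k) {
      if (read[k] != tmpl[off + k]) mm.push_back(k);
    }
    int cnt = (int)mm.size();
    if (cnt == 0) continue; // exact hit would have mapped genomically
    // tailed: mismatches are exactly the last cnt positions, cnt<=max_tail,
    // and the read bases there are all A or T
    if (cnt <= max_tail && mm[0] == L - cnt) {
      bool au = true;
      for (int k = L - cnt; k < L; ++k) {
        char ch = read[k];
        if (ch != 'A' && ch != 'a' && ch != 'T' && ch != 't' &&
            ch != 'U' && ch != 'u')
          au = false;
      }
      if (au) return 2;
    }
    if (cnt <= max_other) any_other = true;
  }
  return any_other ? 1 : 0;
}
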