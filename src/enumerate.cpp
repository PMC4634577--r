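// Exhaustive enumeration of injective residue correspondences between two
// catalytic sites, with optimal rigid-body (Kabsch) superposition of the
// represented points for every candidate mapping. Distance-based pruning is
// exact: a pair of residue pairs is co-mappable only if the difference of
// their C-alpha distances is within a bound implied by the RMSD cutoff, so
// no qualifying mapping is ever discarded.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Least-RMSD proper rotation mapping Q onto P (rows are points).
static double kabschRmsd(const arma::mat &P, const arma::mat &Q,
                         arma::mat &R, arma::vec &t) {
  const arma::rowvec pc = arma::mean(P, 0);
  const arma::rowvec qc = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - pc;
  arma::mat Qc = Q.each_row() - qc;
  arma::mat H = Qc.t() * Pc;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) Rcpp::stop("SVD failed in superposition");
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  if (d < 0) D(2, 2) = -1.0;
  R = V * D * U.t();
  t = pc.t() - R * qc.t();
  arma::mat fit = Qc * R.t();
  double ss = arma::accu(arma::square(Pc - fit));
  return std::sqrt(ss / P.n_rows);
}

struct Rec {
  std::vector<int> pairs;  // indices into pairIdx (0-based)
  double rmsd;
  arma::mat rot;
  arma::vec trans;
};

struct Ctx {
  std::vector<arma::mat> A;                 // fixed-side block per pair
  std::vector<std::vector<arma::mat>> B;    // variant blocks per pair
  std::vector<int> pi, pj;                  // residue indices per pair
  arma::mat dA, dB;
  double cutoff, distTol;
  int minSize;
  long long budget, evaluated;
  std::vector<Rec> out;
};

static void evalMapping(Ctx &c, const std::vector<int> &chosen) {
  if (++c.evaluated > c.budget) {
    Rcpp::stop("candidate-mapping budget (%lld) exceeded", c.budget);
  }
  // Stack fixed-side points once.
  size_t nrow = 0;
  for (int p : chosen) nrow += c.A[p].n_rows;
  arma::mat P(nrow, 3), Q(nrow, 3);
  size_t r = 0;
  for (int p : chosen) {
    P.rows(r, r + c.A[p].n_rows - 1) = c.A[p];
    r += c.A[p].n_rows;
  }
  // Exhaust variant labelings (symmetric side-chain atoms) jointly.
  std::vector<size_t> radix(chosen.size()), idx(chosen.size(), 0);
  for (size_t k = 0; k < chosen.size(); ++k) {
    radix[k] = c.B[chosen[k]].size();
  }
  double best = -1.0;
  arma::mat bestR;
  arma::vec bestT;
  bool done = false;
  while (!done) {
    r = 0;
    for (size_t k = 0; k < chosen.size(); ++k) {
      const arma::mat &blk = c.B[chosen[k]][idx[k]];
      Q.rows(r, r + blk.n_rows - 1) = blk;
      r += blk.n_rows;
    }
    arma::mat R;
    arma::vec t;
    double rmsd = kabschRmsd(P, Q, R, t);
    if (best < 0 || rmsd < best) {
      best = rmsd;
      bestR = R;
      bestT = t;
    }
    // advance mixed-radix counter
    done = true;
    for (size_t k = 0; k < idx.size(); ++k) {
      if (++idx[k] < radix[k]) { done = false; break; }
      idx[k] = 0;
    }
  }
  if (best >= 0 && best <= c.cutoff) {
    Rec rec;
    rec.pairs = chosen;
    rec.rmsd = best;
    rec.rot = bestR;
    rec.trans = bestT;
    c.out.push_back(std::move(rec));
  }
}

static void dfs(Ctx &c, int start, std::vector<int> &chosen,
                std::vector<char> &usedA, std::vector<char> &usedB) {
  const int P = static_cast<int>(c.pi.size());
  for (int p = start; p < P; ++p) {
    const int i = c.pi[p], j = c.pj[p];
    if (usedA[i] || usedB[j]) continue;
    bool ok = true;
    for (int q : chosen) {
      const double da = c.dA(i, c.pi[q]);
      const double db = c.dB(j, c.pj[q]);
      if (std::abs(da - db) > c.distTol) { ok = false; break; }
    }
    if (!ok) continue;
    chosen.push_back(p);
    usedA[i] = usedB[j] = 1;
    if (static_cast<int>(chosen.size()) >= c.minSize) evalMapping(c, chosen);
    dfs(c, p + 1, chosen, usedA, usedB);
    usedA[i] = usedB[j] = 0;
    chosen.pop_back();
  }
}

// [[Rcpp::export(name = ".cppEnumerateMatches")]]
List cppEnumerateMatches(List blocksA, List blocksB, IntegerMatrix pairIdx,
                         NumericMatrix dA, NumericMatrix dB, double cutoff,
                         int minSize, double distTol, double budget) {
  Ctx c;
  const int P = pairIdx.nrow();
  c.pi.resize(P);
  c.pj.resize(P);
  c.A.resize(P);
  c.B.resize(P);
  for (int p = 0; p < P; ++p) {
    c.pi[p] = pairIdx(p, 0) - 1;
    c.pj[p] = pairIdx(p, 1) - 1;
    c.A[p] = as<arma::mat>(blocksA[p]);
    List vb = blocksB[p];
    for (int v = 0; v < vb.size(); ++v) {
      c.B[p].push_back(as<arma::mat>(vb[v]));
    }
  }
  c.dA = as<arma::mat>(dA);
  c.dB = as<arma::mat>(dB);
  c.cutoff = cutoff;
  c.distTol = distTol;
  c.minSize = minSize;
  c.budget = static_cast<long long>(budget);
  c.evaluated = 0;

  std::vector<int> chosen;
  std::vector<char> usedA(c.dA.n_rows, 0), usedB(c.dB.n_rows, 0);
  dfs(c, 0, chosen, usedA, usedB);

  List res(c.out.size());
  for (size_t k = 0; k < c.out.size(); ++k) {
    const Rec &rec = c.out[k];
    const int n = static_cast<int>(rec.pairs.size());
    IntegerMatrix map(n, 2);
    for (int q = 0; q < n; ++q) {
      map(q, 0) = c.pi[rec.pairs[q]] + 1;
      map(q, 1) = c.pj[rec.pairs[q]] + 1;
    }
    res[k] = List::create(_["mapping"] = map, _["rmsd"] = rec.rmsd,
                          _["rotation"] = wrap(rec.rot),
                          _["translation"] = wrap(rec.trans));
  }
  return res;
}
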