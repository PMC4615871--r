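// Exact-event (Gillespie) simulation of the three-pool clonal repopulation
// model: C labeled clones + U unlabeled HSCs feed a carrying-capacity
// regulated progenitor pool; progenitors replicate, die, or terminally
// differentiate (symmetric with prob eta); differentiated cells turn over.
// Uses R's RNG so that set.seed() in R makes runs reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// Fenwick (binary indexed) tree over per-clone counts, for O(log C)
// weighted selection and update.  Index 0 is reserved for the unlabeled pool.
struct Fenwick {
  int n;
  std::vector<double> t;
  Fenwick(int n_) : n(n_), t(n_ + 1, 0.0) {}
  void add(int i, double v) {
    for (++i; i <= n; i += i & (-i)) t[i] += v;
  }
  double total() const {
    double s = 0; int i = n;
    for (; i > 0; i -= i & (-i)) s += t[i];
    return s;
  }
  // smallest index i with prefix-sum(0..i) > target
  int find(double target) const {
    int pos = 0;
    int logn = 1; while ((1 << logn) <= n) ++logn;
    for (int pw = 1 << (logn - 1); pw > 0; pw >>= 1) {
      int next = pos + pw;
      if (next <= n && t[next] <= target) { target -= t[next]; pos = next; }
    }
    return pos;  // 0-based index
  }
};

// [[Rcpp::export(name = ".ssa_simulate")]]
List ssa_simulate(double alpha, double p, double mu_p, double mu_d,
                  double eta, double omega, double K,
                  double U, int C, NumericVector sample_times,
                  double max_events) {
  const int nT = sample_times.size();
  // per-clone integer counts; slot 0 = unlabeled pool
  std::vector<double> nprog(C + 1, 0.0), ndiff(C + 1, 0.0);
  Fenwick fprog(C + 1), fdiff(C + 1);
  double Np = 0, Nd = 0;
  double t = 0;
  double nev = 0;

  NumericMatrix out_prog(nT, C), out_diff(nT, C);
  NumericVector out_uprog(nT), out_udiff(nT), out_Np(nT), out_Nd(nT);
  int ti = 0;

  RNGScope scope;
  auto record_until = [&](double tnew) {
    while (ti < nT && sample_times[ti] <= tnew) {
      for (int j = 0; j < C; ++j) {
        out_prog(ti, j) = nprog[j + 1];
        out_diff(ti, j) = ndiff[j + 1];
      }
      out_uprog[ti] = nprog[0]; out_udiff[ti] = ndiff[0];
      out_Np[ti] = Np; out_Nd[ti] = Nd;
      ++ti;
    }
  };

  const double t_end = sample_times[nT - 1];
  while (ti < nT) {
    double r = p * K / (Np + K);
    double rate_imm = alpha * (U + C);
    double rate_birth = r * Np;
    double rate_death = mu_p * Np;
    double rate_term = omega * Np;
    double rate_dd = mu_d * Nd;
    double total = rate_imm + rate_birth + rate_death + rate_term + rate_dd;
    if (!R_FINITE(total) || total < 0)
      stop("non-finite event propensity: invalid parameters");
    if (total == 0) { record_until(t_end + 1); break; }
    double dt = R::exp_rand() / total;
    double tnew = t + dt;
    record_until(tnew);            // states are right-continuous between events
    if (ti >= nT) break;
    t = tnew;
    if (++nev > max_events)
      stop("event cap exceeded (runaway growth? K inconsistent with exact-event method)");

    double u = unif_rand() * total;
    if (u < rate_imm) {
      // HSC asymmetric differentiation: HSC kept, one progenitor added;
      // the firing HSC is uniform over the U unlabeled + C labeled
      double v = unif_rand() * (U + C);
      int j = 0;
      if (v >= U) {
        int jj = (int)(v - U);
        if (jj >= C) jj = C - 1;
        j = jj + 1;
      }
      nprog[j] += 1; fprog.add(j, 1); Np += 1;
    } else if (u < rate_imm + rate_birth) {
      int j = fprog.find(unif_rand() * fprog.total());
      nprog[j] += 1; fprog.add(j, 1); Np += 1;
    } else if (u < rate_imm + rate_birth + rate_death) {
      int j = fprog.find(unif_rand() * fprog.total());
      nprog[j] -= 1; fprog.add(j, -1); Np -= 1;
    } else if (u < rate_imm + rate_birth + rate_death + rate_term) {
      int j = fprog.find(unif_rand() * fprog.total());
      if (unif_rand() < eta) {   // symmetric: progenitor -> 2 differentiated
        nprog[j] -= 1; fprog.add(j, -1); Np -= 1;
        ndiff[j] += 2; fdiff.add(j, 2); Nd += 2;
      } else {                   // asymmetric: progenitor kept, +1 differentiated
        ndiff[j] += 1; fdiff.add(j, 1); Nd += 1;
      }
    } else {
      int j = fdiff.find(unif_rand() * fdiff.total());
      ndiff[j] -= 1; fdiff.add(j, -1); Nd -= 1;
    }
  }

  return List::create(_["t"] = sample_times,
                      _["n_prog"] = out_prog, _["n_diff"] = out_diff,
                      _["u_prog"] = out_uprog, _["u_diff"] = out_udiff,
                      _["n_events"] = nev);
}
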