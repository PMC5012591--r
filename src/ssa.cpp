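#include <Rcpp.h>
using namespace Rcpp;

// Exact (Gillespie) stochastic simulation of the pathway reaction network in
// molecule numbers, used as an independent oracle for the linear noise
// approximation. The reaction list mirrors pathway_reactions() in R
// term-for-term: Michaelis-Menten aggregates are treated as elementary
// events with their macroscopic propensities evaluated at the current state.
//
// Species order: Q, M, A_P, B_P, Y_P (counts).
// Params vector (conc units, uM / 1/s / 1/(uM s)):
//  0 kQ, 1 kR, 2 kB, 3 KR, 4 KB, 5 aP, 6 aB, 7 aY, 8 dB, 9 dZ,
// 10 eps0, 11 eps1, 12 eps2, 13 N, 14 r, 15 ATot, 16 BTot, 17 YTot,
// 18 Z (already multiplied by chez_mult), 19 CheR, 20 TTot, 21 omega
// (molecules per uM), 22 deamidation flag (0/1)

static inline double activity(double Mc, double Qc, const double *p) {
  double E = p[10] + 2.0 * p[13] * (p[11] * Mc / (4.0 * p[20]) +
                                    p[12] * Qc / (4.0 * p[20]));
  return 1.0 / (1.0 + std::exp(E));
}

// [[Rcpp::export]]
List ssa_pathway_cpp(NumericVector n0, NumericVector pars, double t_burnin,
                     double t_sample, double max_events) {
  const double *p = pars.begin();
  const double om = p[21];
  const bool deam = p[22] > 0.5;
  double n[5];
  for (int i = 0; i < 5; ++i) n[i] = n0[i];

  // stoichiometry (5 species x 11 reactions), columns: deamid, Qsyn, Qdil,
  // meth, demeth, Mdil, autophos, transferB, transferY, BPdeph, YPdeph
  const int S[5][11] = {
    {-1, 1, -1, 0, 0, 0, 0, 0, 0, 0, 0},
    {0, 0, 0, 1, -1, -1, 0, 0, 0, 0, 0},
    {0, 0, 0, 0, 0, 0, 1, -1, -1, 0, 0},
    {0, 0, 0, 0, 0, 0, 0, 1, 0, -1, 0},
    {0, 0, 0, 0, 0, 0, 0, 0, 1, 0, -1}};

  double t = 0.0, events = 0.0;
  const double t_end = t_burnin + t_sample;
  // time-weighted first/second moments of the state over the sampling window
  double w = 0.0, m1[5] = {0, 0, 0, 0, 0}, m2[5] = {0, 0, 0, 0, 0};
  double a_rates[11];

  while (t < t_end && events < max_events) {
    const double Qc = n[0] / om, Mc = n[1] / om, APc = n[2] / om,
                 BPc = n[3] / om, YPc = n[4] / om;
    const double a = activity(Mc, Qc, p);
    const double freec = 4.0 * p[20] - Mc - Qc;
    a_rates[0] = deam ? om * a * p[0] * BPc * Qc / (p[4] + Qc) : 0.0;
    a_rates[1] = deam ? om * 2.0 * p[14] * p[20] : 0.0;
    a_rates[2] = deam ? om * p[14] * Qc : 0.0;
    a_rates[3] = om * (1.0 - a) * p[1] * p[19] * freec / (p[3] + freec);
    a_rates[4] = om * a * p[2] * BPc * Mc / (p[4] + Mc);
    a_rates[5] = om * p[14] * Mc;
    a_rates[6] = om * a * p[5] * (p[15] - APc);
    a_rates[7] = om * p[6] * APc * (p[16] - BPc);
    a_rates[8] = om * p[7] * APc * (p[17] - YPc);
    a_rates[9] = om * p[8] * BPc;
    a_rates[10] = om * p[9] * p[18] * YPc;
    double a0 = 0.0;
    for (int j = 0; j < 11; ++j) {
      if (a_rates[j] < 0.0) a_rates[j] = 0.0;
      a0 += a_rates[j];
    }
    if (a0 <= 0.0) break;
    double dt = exp_rand() / a0;
    double t_new = t + dt;
    // accumulate dwell time in the sampling window at the current state
    double lo = std::max(t, t_burnin), hi = std::min(t_new, t_end);
    if (hi > lo) {
      double dw = hi - lo;
      w += dw;
      for (int i = 0; i < 5; ++i) {
        m1[i] += dw * n[i];
        m2[i] += dw * n[i] * n[i];
      }
    }
    t = t_new;
    if (t >= t_end) break;
    double u = unif_rand() * a0;
    int j = 0;
    for (; j < 10; ++j) {
      u -= a_rates[j];
      if (u <= 0.0) break;
    }
    for (int i = 0; i < 5; ++i) n[i] += S[i][j];
    for (int i = 0; i < 5; ++i) if (n[i] < 0) n[i] = 0;
    events += 1.0;
  }
  NumericVector mean(5), var(5);
  for (int i = 0; i < 5; ++i) {
    mean[i] = m1[i] / w;
    var[i] = m2[i] / w - mean[i] * mean[i];
  }
  mean.names() = CharacterVector::create("Q", "M", "A_P", "B_P", "Y_P");
  var.names() = CharacterVector::create("Q", "M", "A_P", "B_P", "Y_P");
  return List::create(_["mean"] = mean, _["var"] = var,
                      _["events"] = events, _["t_final"] = t);
}
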