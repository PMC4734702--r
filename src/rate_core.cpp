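#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rate-coded circuit integrator. Forward Euler with synchronous updates:
// all excitatory/inhibitory drives are assembled from the previous state,
// every population is then advanced with its own (A, tau) under the global
// shunting bounds [-C, B], and the two plastic weight families take one
// reinforcement-gated step. Expression structure deliberately mirrors the
// pure-R reference stepper so the two agree bit-for-bit.

static inline double pos(double a) { return a > 0 ? a : 0; }
static inline double hside(double a) { return a > 0 ? 1.0 : 0.0; }

static void check_finite(const std::vector<double> &v, const char *name, int step) {
  for (size_t k = 0; k < v.size(); ++k) {
    if (!std::isfinite(v[k]))
      stop("non-finite activity in population %s at step %d", name, step);
  }
}

// [[Rcpp::export]]
List run_rate_cpp(List par, bool lesion_ba, bool lesion_pc,
                  NumericMatrix S, NumericMatrix R, NumericMatrix M,
                  List state0, double h, int record_stride) {
  const int N = as<int>(par["N"]);
  const int n_steps = S.nrow();
  if (S.ncol() != N) stop("stimulus matrix has %d columns but N = %d", S.ncol(), N);

#define PAR(x) const double x = as<double>(par[#x])
  PAR(W_SC_ST); PAR(W_ST_SC); PAR(W_SC_SR); PAR(W_ST_SR);
  PAR(W_SR_ST); PAR(W_SR_SR);
  PAR(W_BA_ST); PAR(W_BA_SC); PAR(W_BA_SR);
  PAR(W_PC_PT); PAR(W_PT_PC); PAR(W_PC_PR); PAR(W_PT_PR);
  PAR(W_PR_PT); PAR(W_PR_PR);
  PAR(W_BA_PT); PAR(W_BA_PC); PAR(W_BA_PR);
  PAR(W_LA_BA); PAR(W_yB); PAR(W_Lcy); PAR(W_Lvy);
  PAR(W_Lc); PAR(W_Lv); PAR(W_Ly); PAR(W_vv); PAR(W_yy);
  PAR(W_Lcv); PAR(W_Lyv); PAR(W_yP); PAR(W_Pcy); PAR(W_Pvy);
  PAR(W_Pc); PAR(W_Pv); PAR(W_Py); PAR(W_Pcv); PAR(W_Pyv);
  PAR(Gamma_PCB); PAR(Gamma_PCT); PAR(Gamma_L); PAR(Gamma_v);
  PAR(Gamma_yv); PAR(Gamma_y); PAR(Gamma_r); PAR(Gamma_P);
  PAR(Gamma_ST); PAR(Gamma_BA);
  PAR(B_ST_LA); PAR(B_PC_BA);
  PAR(tau_main); PAR(tau_w); PAR(tau_Lc_Pc); PAR(tau_Lv_Lvr); PAR(tau_Pv_Pvr);
  PAR(A_ST); PAR(A_SC_PC_LA_y); PAR(A_SR_PR_BA); PAR(A_PT); PAR(A_r);
  PAR(A_Lv_Pv); PAR(A_Lc_Pc);
  PAR(B); PAR(C);
#undef PAR

  // state: sensory map vectors length N; amygdala quantities 2*N stored
  // q-major (q = 0 appetitive first, then q = 1 aversive); plan map length 2.
  auto vec = [](SEXP x) { return as<std::vector<double>>(x); };
  std::vector<double> ST = vec(state0["ST"]), SC = vec(state0["SC"]), SR = vec(state0["SR"]);
  std::vector<double> LA = vec(state0["LA"]), BA = vec(state0["BA"]), BAIN = vec(state0["BAIN"]);
  std::vector<double> Lc = vec(state0["Lc"]), Lv = vec(state0["Lv"]), Lvr = vec(state0["Lvr"]);
  std::vector<double> PT = vec(state0["PT"]), PC = vec(state0["PC"]), PR = vec(state0["PR"]);
  std::vector<double> PCIN = vec(state0["PCIN"]), Pc = vec(state0["Pc"]),
                      Pv = vec(state0["Pv"]), Pvr = vec(state0["Pvr"]);
  std::vector<double> WstLA = vec(state0["WstLA"]), WpcBA = vec(state0["WpcBA"]);
  if ((int)ST.size() != N || (int)LA.size() != 2 * N || (int)WstLA.size() != 2 * N)
    stop("state dimensions do not match N = %d", N);

  const int n_rec = record_stride > 0 ? n_steps / record_stride : 0;
  const int n_cols = 1 + 20 * N + 18;
  NumericMatrix trace(n_rec, n_cols);
  int rec_row = 0;

  std::vector<double> posSR(N), posST(N), posBA1(N), posBA2(N);
  std::vector<double> E_ST(N), I_ST(N), E_SC(N), E_SR(N), I_SR(N);
  std::vector<double> E_LA(2 * N), E_BA(2 * N), I_BA(2 * N), E_BAIN(2 * N);
  std::vector<double> E_Lc(2 * N), E_Lv(2 * N), I_Lv(2 * N), E_Lvr(2 * N);
  double E_PT[2], I_PT[2], E_PC[2], I_PC[2], E_PR[2], I_PR[2];
  double E_PCIN[2], E_Pc[2], E_Pv[2], I_Pv[2], E_Pvr[2];

  for (int s = 1; s <= n_steps; ++s) {
    const int t = s - 1; // row of the drive matrices for this step
    if (s % 20000 == 0) checkUserInterrupt();

    for (int i = 0; i < N; ++i) {
      posSR[i] = pos(SR[i]);
      posST[i] = pos(ST[i]);
      posBA1[i] = pos(BA[i]);
      posBA2[i] = pos(BA[N + i]);
    }

    // --- sensory map drives ---
    for (int i = 0; i < N; ++i) {
      E_ST[i] = S(t, i) + W_SC_ST * SC[i] + W_BA_ST * (posBA1[i] + posBA2[i]);
      double acc = 0;
      for (int j = 0; j < N; ++j) if (j != i) acc = acc + W_SR_ST * posSR[j];
      I_ST[i] = acc;
      E_SC[i] = W_ST_SC * posST[i] + W_BA_SC * (posBA1[i] + posBA2[i]);
      E_SR[i] = W_SC_SR * SC[i] + W_ST_SR * posST[i] + W_BA_SR * (posBA1[i] + posBA2[i]);
      acc = 0;
      for (int j = 0; j < N; ++j) if (j != i) acc = acc + W_SR_SR * posSR[j];
      I_SR[i] = acc;
    }

    // --- salience map (amygdala) drives ---
    double sumBA[2];
    for (int q = 0; q < 2; ++q) {
      const double Rq = R(t, q);
      double sB = 0;
      for (int j = 0; j < N; ++j) sB = sB + pos(BA[q * N + j]);
      sumBA[q] = sB;
      for (int i = 0; i < N; ++i) {
        const int k = q * N + i;
        E_LA[k] = WstLA[k] * posST[i];
        E_BA[k] = W_LA_BA * pos(LA[k]) + WpcBA[k] * pos(PC[q] - Gamma_PCB);
        I_BA[k] = lesion_ba ? 0.0 : W_yB * BAIN[k];
        E_BAIN[k] = W_Lcy * pos(Lc[k]) + W_Lvy * pos(Lv[k]);
        E_Lc[k] = W_Lc * pos(LA[k]) * Rq;
        E_Lv[k] = W_Lv * pos(LA[k] - Gamma_L) + W_vv * pos(Lv[k] - Gamma_v);
        I_Lv[k] = W_Lcv * Lc[k] + W_Lyv * pos(Lvr[k] - Gamma_yv);
        E_Lvr[k] = W_Ly * pos(Lv[k]) + W_yy * pos(Lvr[k] - Gamma_y) * hside(Lv[k] - Gamma_r);
      }
    }

    // --- plan map drives ---
    for (int q = 0; q < 2; ++q) {
      const double Rq = R(t, q);
      const int o = 1 - q;
      E_PT[q] = M(t, q) + W_PC_PT * pos(PC[q] - Gamma_PCT) + W_BA_PT * sumBA[q];
      I_PT[q] = W_PR_PT * pos(PR[o]);
      E_PC[q] = W_PT_PC * pos(PT[q]) + W_BA_PC * sumBA[q];
      I_PC[q] = lesion_pc ? 0.0 : W_yP * PCIN[q];
      E_PR[q] = W_PC_PR * PC[q] + W_PT_PR * pos(PT[q]) + W_BA_PR * sumBA[q];
      I_PR[q] = W_PR_PR * pos(PR[o]);
      E_PCIN[q] = W_Pcy * pos(Pc[q]) + W_Pvy * pos(Pv[q]);
      E_Pc[q] = W_Pc * pos(PC[q]) * Rq;
      E_Pv[q] = W_Pv * pos(PC[q] - Gamma_P) + W_vv * pos(Pv[q] - Gamma_v);
      I_Pv[q] = W_Pcv * Pc[q] + W_Pyv * pos(Pvr[q] - Gamma_yv);
      E_Pvr[q] = W_Py * pos(Pv[q]) + W_yy * pos(Pvr[q] - Gamma_y) * hside(Pv[q] - Gamma_v);
    }

    // --- plastic weights (Euler step from the previous state) ---
    for (int q = 0; q < 2; ++q) {
      const double Rq = R(t, q);
      for (int i = 0; i < N; ++i) {
        const int k = q * N + i;
        WstLA[k] = WstLA[k] + (h / tau_w) * (B_ST_LA - WstLA[k]) * pos(ST[i] - Gamma_ST) * Rq;
        WpcBA[k] = WpcBA[k] + (h / tau_w) * (B_PC_BA - WpcBA[k]) * pos(BA[k] - Gamma_BA) * pos(PC[q]) * Rq;
      }
    }

    // --- shunting updates ---
#define SHUNT(x, E, I, A, tau) ((x) + (h / (tau)) * (-(A) * (x) + (B - (x)) * (E) - ((x) + C) * (I)))
    for (int i = 0; i < N; ++i) {
      ST[i] = SHUNT(ST[i], E_ST[i], I_ST[i], A_ST, tau_main);
      SC[i] = SHUNT(SC[i], E_SC[i], 0.0, A_SC_PC_LA_y, tau_main);
      SR[i] = SHUNT(SR[i], E_SR[i], I_SR[i], A_SR_PR_BA, tau_main);
    }
    for (int k = 0; k < 2 * N; ++k) {
      LA[k] = SHUNT(LA[k], E_LA[k], 0.0, A_SC_PC_LA_y, tau_main);
      BA[k] = SHUNT(BA[k], E_BA[k], I_BA[k], A_SR_PR_BA, tau_main);
      BAIN[k] = SHUNT(BAIN[k], E_BAIN[k], 0.0, A_SC_PC_LA_y, tau_main);
      Lc[k] = SHUNT(Lc[k], E_Lc[k], 0.0, A_Lc_Pc, tau_Lc_Pc);
      Lv[k] = SHUNT(Lv[k], E_Lv[k], I_Lv[k], A_Lv_Pv, tau_Lv_Lvr);
      if (Lv[k] < 0) Lv[k] = 0; // hard nonlinearity after resetting
      Lvr[k] = SHUNT(Lvr[k], E_Lvr[k], 0.0, A_r, tau_Lv_Lvr);
    }
    for (int q = 0; q < 2; ++q) {
      PT[q] = SHUNT(PT[q], E_PT[q], I_PT[q], A_PT, tau_main);
      PC[q] = SHUNT(PC[q], E_PC[q], I_PC[q], A_SC_PC_LA_y, tau_main);
      PR[q] = SHUNT(PR[q], E_PR[q], I_PR[q], A_SR_PR_BA, tau_main);
      PCIN[q] = SHUNT(PCIN[q], E_PCIN[q], 0.0, A_SC_PC_LA_y, tau_main);
      Pc[q] = SHUNT(Pc[q], E_Pc[q], 0.0, A_Lc_Pc, tau_Lc_Pc);
      Pv[q] = SHUNT(Pv[q], E_Pv[q], I_Pv[q], A_Lv_Pv, tau_Pv_Pvr);
      if (Pv[q] < 0) Pv[q] = 0;
      Pvr[q] = SHUNT(Pvr[q], E_Pvr[q], 0.0, A_r, tau_Pv_Pvr);
    }
#undef SHUNT

    {
      check_finite(ST, "sensory thalamus (x_ST)", s);
      check_finite(SC, "sensory cortex (x_SC)", s);
      check_finite(SR, "sensory TRN (x_SR)", s);
      check_finite(LA, "lateral amygdala (x_LA)", s);
      check_finite(BA, "basal amygdala (x_BA)", s);
      check_finite(BAIN, "BA interneuron (y_BAIN)", s);
      check_finite(Lc, "amygdala expectation confirmation (x_Lc)", s);
      check_finite(Lv, "amygdala expectation violation (x_Lv)", s);
      check_finite(Lvr, "amygdala EV reset (y_Lvr)", s);
      check_finite(PT, "plan thalamus (x_PT)", s);
      check_finite(PC, "plan cortex (x_PC)", s);
      check_finite(PR, "plan TRN (x_PR)", s);
      check_finite(PCIN, "plan interneuron (y_PCIN)", s);
      check_finite(Pc, "plan expectation confirmation (x_Pc)", s);
      check_finite(Pv, "plan expectation violation (x_Pv)", s);
      check_finite(Pvr, "plan EV reset (y_Pvr)", s);
    }

    if (record_stride > 0 && s % record_stride == 0 && rec_row < n_rec) {
      int c = 0;
      trace(rec_row, c++) = s * h;
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = ST[i];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = SC[i];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = SR[i];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = LA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = BA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = BAIN[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = Lc[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = Lv[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = Lvr[k];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = PT[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = PC[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = PR[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = PCIN[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = Pc[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = Pv[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = Pvr[q];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = WstLA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = WpcBA[k];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = S(t, i);
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = R(t, q);
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = M(t, q);
      ++rec_row;
    }
  }

  List fin = List::create(
    _["ST"] = ST, _["SC"] = SC, _["SR"] = SR,
    _["LA"] = LA, _["BA"] = BA, _["BAIN"] = BAIN,
    _["Lc"] = Lc, _["Lv"] = Lv, _["Lvr"] = Lvr,
    _["PT"] = PT, _["PC"] = PC, _["PR"] = PR, _["PCIN"] = PCIN,
    _["Pc"] = Pc, _["Pv"] = Pv, _["Pvr"] = Pvr,
    _["WstLA"] = WstLA, _["WpcBA"] = WpcBA
  );
  return List::create(_["trace"] = trace, _["state"] = fin);
}
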