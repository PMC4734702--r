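#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Spiking circuit integrator. Izhikevich point neurons (regular-spiking
// principal cells, fast-spiking interneurons) carry the wiring of the rate
// variant, with every presynaptic activity replaced by that neuron's
// saturating-differentials postsynaptic signal g. Expectation-related
// signals stay rate-style shunting equations. Synchronous update order:
// drives from the previous state, plastic weights, membrane integration
// (spike detection edge-triggered at the emission threshold), transmitter/
// postsynaptic signal, then the rate-style signals.

static inline double pos(double a) { return a > 0 ? a : 0; }
static inline double hside(double a) { return a > 0 ? 1.0 : 0.0; }

struct Raster {
  std::vector<int> step, pop, q, channel;
  void add(int s, int p, int qq, int ch) {
    step.push_back(s); pop.push_back(p); q.push_back(qq); channel.push_back(ch);
  }
};

// [[Rcpp::export]]
List run_spiking_cpp(List par, bool lesion_ba, bool lesion_pc,
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
  PAR(tau_w); PAR(tau_s); PAR(tau_Lc_Pc); PAR(tau_Lv_Lvr); PAR(tau_Pv_Pvr);
  PAR(tau_rise); PAR(tau_fall);
  PAR(A_r); PAR(A_Lv_Pv); PAR(A_Lc_Pc);
  PAR(B); PAR(C);
  PAR(izh_rs_a); PAR(izh_rs_b); PAR(izh_rs_c); PAR(izh_rs_d);
  PAR(izh_fs_a); PAR(izh_fs_b); PAR(izh_fs_c); PAR(izh_fs_d);
  PAR(spike_thresh); PAR(reset_thresh); PAR(W_S);
#undef PAR

  auto vec = [](SEXP x) { return as<std::vector<double>>(x); };
  // population order: ST SC SR LA BA BAIN PT PC PR PCIN (codes 1..10)
  std::vector<double>
      v_ST = vec(state0["v_ST"]), u_ST = vec(state0["u_ST"]),
      T_ST = vec(state0["T_ST"]), g_ST = vec(state0["g_ST"]),
      v_SC = vec(state0["v_SC"]), u_SC = vec(state0["u_SC"]),
      T_SC = vec(state0["T_SC"]), g_SC = vec(state0["g_SC"]),
      v_SR = vec(state0["v_SR"]), u_SR = vec(state0["u_SR"]),
      T_SR = vec(state0["T_SR"]), g_SR = vec(state0["g_SR"]),
      v_LA = vec(state0["v_LA"]), u_LA = vec(state0["u_LA"]),
      T_LA = vec(state0["T_LA"]), g_LA = vec(state0["g_LA"]),
      v_BA = vec(state0["v_BA"]), u_BA = vec(state0["u_BA"]),
      T_BA = vec(state0["T_BA"]), g_BA = vec(state0["g_BA"]),
      v_BAIN = vec(state0["v_BAIN"]), u_BAIN = vec(state0["u_BAIN"]),
      T_BAIN = vec(state0["T_BAIN"]), g_BAIN = vec(state0["g_BAIN"]),
      v_PT = vec(state0["v_PT"]), u_PT = vec(state0["u_PT"]),
      T_PT = vec(state0["T_PT"]), g_PT = vec(state0["g_PT"]),
      v_PC = vec(state0["v_PC"]), u_PC = vec(state0["u_PC"]),
      T_PC = vec(state0["T_PC"]), g_PC = vec(state0["g_PC"]),
      v_PR = vec(state0["v_PR"]), u_PR = vec(state0["u_PR"]),
      T_PR = vec(state0["T_PR"]), g_PR = vec(state0["g_PR"]),
      v_PCIN = vec(state0["v_PCIN"]), u_PCIN = vec(state0["u_PCIN"]),
      T_PCIN = vec(state0["T_PCIN"]), g_PCIN = vec(state0["g_PCIN"]);
  std::vector<double> Lc = vec(state0["Lc"]), Lv = vec(state0["Lv"]), Lvr = vec(state0["Lvr"]);
  std::vector<double> Pc = vec(state0["Pc"]), Pv = vec(state0["Pv"]), Pvr = vec(state0["Pvr"]);
  std::vector<double> WstLA = vec(state0["WstLA"]), WpcBA = vec(state0["WpcBA"]);

  const int n_rec = record_stride > 0 ? n_steps / record_stride : 0;
  const int n_izh = 9 * N + 8; // spiking neurons in total
  const int n_cols = 1 + 20 * N + 18 + 2 * n_izh; // rate schema + v,u columns
  NumericMatrix trace(n_rec, n_cols);
  int rec_row = 0;
  Raster raster;

  std::vector<double> E_ST(N), I_ST(N), E_SC(N), E_SR(N), I_SR(N);
  std::vector<double> E_LA(2 * N), E_BA(2 * N), I_BA(2 * N), E_BAIN(2 * N);
  std::vector<double> E_Lc(2 * N), E_Lv(2 * N), I_Lv(2 * N), E_Lvr(2 * N);
  double E_PT[2], I_PT[2], E_PC[2], I_PC[2], E_PR[2], I_PR[2];
  double E_PCIN[2], E_Pc[2], E_Pv[2], I_Pv[2], E_Pvr[2];

  // advance one Izhikevich neuron + its synaptic signal; returns spike flag
  auto izh = [&](double &v, double &u, double &T, double &g,
                 double E, double I, bool fs) -> int {
    const double a = fs ? izh_fs_a : izh_rs_a;
    const double b = fs ? izh_fs_b : izh_rs_b;
    const double c = fs ? izh_fs_c : izh_rs_c;
    const double d = fs ? izh_fs_d : izh_rs_d;
    double vn = v + (h / tau_s) * (0.04 * v * v + 5 * v + 140 - u + (E - I));
    double un = u + (h / tau_s) * (a * (b * v - u));
    const int K = (v <= spike_thresh && vn > spike_thresh) ? 1 : 0;
    if (vn >= reset_thresh) { vn = c; un = un + d; }
    double Tn = T + h * ((1 - T) * K / tau_s - T / tau_rise);
    double gn = g + h * ((tau_fall + tau_rise) / tau_fall) *
                        ((2 / tau_rise) * (1 - g) * T - g / tau_fall);
    v = vn; u = un; T = Tn; g = gn;
    return K;
  };

  for (int s = 1; s <= n_steps; ++s) {
    const int t = s - 1;
    if (s % 20000 == 0) checkUserInterrupt();

    // --- drives from previous postsynaptic signals ---
    for (int i = 0; i < N; ++i) {
      E_ST[i] = W_S * S(t, i) + W_SC_ST * g_SC[i] + W_BA_ST * (g_BA[i] + g_BA[N + i]);
      double acc = 0;
      for (int j = 0; j < N; ++j) if (j != i) acc = acc + W_SR_ST * g_SR[j];
      I_ST[i] = acc;
      E_SC[i] = W_ST_SC * g_ST[i] + W_BA_SC * (g_BA[i] + g_BA[N + i]);
      E_SR[i] = W_SC_SR * g_SC[i] + W_ST_SR * g_ST[i] + W_BA_SR * (g_BA[i] + g_BA[N + i]);
      acc = 0;
      for (int j = 0; j < N; ++j) if (j != i) acc = acc + W_SR_SR * g_SR[j];
      I_SR[i] = acc;
    }
    double sumBA[2];
    for (int q = 0; q < 2; ++q) {
      const double Rq = R(t, q);
      double sB = 0;
      for (int j = 0; j < N; ++j) sB = sB + g_BA[q * N + j];
      sumBA[q] = sB;
      for (int i = 0; i < N; ++i) {
        const int k = q * N + i;
        E_LA[k] = WstLA[k] * g_ST[i];
        E_BA[k] = W_LA_BA * g_LA[k] + WpcBA[k] * pos(g_PC[q] - Gamma_PCB);
        I_BA[k] = lesion_ba ? 0.0 : W_yB * g_BAIN[k];
        E_BAIN[k] = W_Lcy * pos(Lc[k]) + W_Lvy * pos(Lv[k]);
        E_Lc[k] = W_Lc * g_LA[k] * Rq;
        E_Lv[k] = W_Lv * pos(g_LA[k] - Gamma_L) + W_vv * pos(Lv[k] - Gamma_v);
        I_Lv[k] = W_Lcv * Lc[k] + W_Lyv * pos(Lvr[k] - Gamma_yv);
        E_Lvr[k] = W_Ly * pos(Lv[k]) + W_yy * pos(Lvr[k] - Gamma_y) * hside(Lv[k] - Gamma_r);
      }
    }
    for (int q = 0; q < 2; ++q) {
      const double Rq = R(t, q);
      const int o = 1 - q;
      E_PT[q] = M(t, q) + W_PC_PT * pos(g_PC[q] - Gamma_PCT) + W_BA_PT * sumBA[q];
      I_PT[q] = W_PR_PT * g_PR[o];
      E_PC[q] = W_PT_PC * g_PT[q] + W_BA_PC * sumBA[q];
      I_PC[q] = lesion_pc ? 0.0 : W_yP * g_PCIN[q];
      E_PR[q] = W_PC_PR * g_PC[q] + W_PT_PR * g_PT[q] + W_BA_PR * sumBA[q];
      I_PR[q] = W_PR_PR * g_PR[o];
      E_PCIN[q] = W_Pcy * pos(Pc[q]) + W_Pvy * pos(Pv[q]);
      E_Pc[q] = W_Pc * g_PC[q] * Rq;
      E_Pv[q] = W_Pv * pos(g_PC[q] - Gamma_P) + W_vv * pos(Pv[q] - Gamma_v);
      I_Pv[q] = W_Pcv * Pc[q] + W_Pyv * pos(Pvr[q] - Gamma_yv);
      E_Pvr[q] = W_Py * pos(Pv[q]) + W_yy * pos(Pvr[q] - Gamma_y) * hside(Pv[q] - Gamma_v);
    }

    // --- plastic weights, gated on previous postsynaptic signals ---
    for (int q = 0; q < 2; ++q) {
      const double Rq = R(t, q);
      for (int i = 0; i < N; ++i) {
        const int k = q * N + i;
        WstLA[k] = WstLA[k] + (h / tau_w) * (B_ST_LA - WstLA[k]) * pos(g_ST[i] - Gamma_ST) * Rq;
        WpcBA[k] = WpcBA[k] + (h / tau_w) * (B_PC_BA - WpcBA[k]) * pos(g_BA[k] - Gamma_BA) * pos(g_PC[q]) * Rq;
      }
    }

    // --- membrane + synapse integration ---
    for (int i = 0; i < N; ++i) {
      if (izh(v_ST[i], u_ST[i], T_ST[i], g_ST[i], E_ST[i], I_ST[i], false)) raster.add(s, 1, 0, i + 1);
      if (izh(v_SC[i], u_SC[i], T_SC[i], g_SC[i], E_SC[i], 0.0, false)) raster.add(s, 2, 0, i + 1);
      if (izh(v_SR[i], u_SR[i], T_SR[i], g_SR[i], E_SR[i], I_SR[i], true)) raster.add(s, 3, 0, i + 1);
    }
    for (int q = 0; q < 2; ++q) {
      for (int i = 0; i < N; ++i) {
        const int k = q * N + i;
        if (izh(v_LA[k], u_LA[k], T_LA[k], g_LA[k], E_LA[k], 0.0, false)) raster.add(s, 4, q + 1, i + 1);
        if (izh(v_BA[k], u_BA[k], T_BA[k], g_BA[k], E_BA[k], I_BA[k], false)) raster.add(s, 5, q + 1, i + 1);
        if (izh(v_BAIN[k], u_BAIN[k], T_BAIN[k], g_BAIN[k], E_BAIN[k], 0.0, true)) raster.add(s, 6, q + 1, i + 1);
      }
      if (izh(v_PT[q], u_PT[q], T_PT[q], g_PT[q], E_PT[q], I_PT[q], false)) raster.add(s, 7, q + 1, 1);
      if (izh(v_PC[q], u_PC[q], T_PC[q], g_PC[q], E_PC[q], I_PC[q], false)) raster.add(s, 8, q + 1, 1);
      if (izh(v_PR[q], u_PR[q], T_PR[q], g_PR[q], E_PR[q], I_PR[q], true)) raster.add(s, 9, q + 1, 1);
      if (izh(v_PCIN[q], u_PCIN[q], T_PCIN[q], g_PCIN[q], E_PCIN[q], 0.0, true)) raster.add(s, 10, q + 1, 1);
    }
    {
      auto scan = [&](const std::vector<double> &v, const char *nm) {
        for (size_t k = 0; k < v.size(); ++k)
          if (!std::isfinite(v[k])) stop("non-finite voltage in population %s at step %d", nm, s);
      };
      scan(v_ST, "x_ST"); scan(v_SC, "x_SC"); scan(v_SR, "x_SR");
      scan(v_LA, "x_LA"); scan(v_BA, "x_BA"); scan(v_BAIN, "y_BAIN");
      scan(v_PT, "x_PT"); scan(v_PC, "x_PC"); scan(v_PR, "x_PR"); scan(v_PCIN, "y_PCIN");
    }

    // --- rate-style expectation signals ---
#define SHUNT(x, E, I, A, tau) ((x) + (h / (tau)) * (-(A) * (x) + (B - (x)) * (E) - ((x) + C) * (I)))
    for (int k = 0; k < 2 * N; ++k) {
      Lc[k] = SHUNT(Lc[k], E_Lc[k], 0.0, A_Lc_Pc, tau_Lc_Pc);
      Lv[k] = SHUNT(Lv[k], E_Lv[k], I_Lv[k], A_Lv_Pv, tau_Lv_Lvr);
      if (Lv[k] < 0) Lv[k] = 0;
      Lvr[k] = SHUNT(Lvr[k], E_Lvr[k], 0.0, A_r, tau_Lv_Lvr);
    }
    for (int q = 0; q < 2; ++q) {
      Pc[q] = SHUNT(Pc[q], E_Pc[q], 0.0, A_Lc_Pc, tau_Lc_Pc);
      Pv[q] = SHUNT(Pv[q], E_Pv[q], I_Pv[q], A_Lv_Pv, tau_Pv_Pvr);
      if (Pv[q] < 0) Pv[q] = 0;
      Pvr[q] = SHUNT(Pvr[q], E_Pvr[q], 0.0, A_r, tau_Pv_Pvr);
    }
#undef SHUNT

    if (record_stride > 0 && s % record_stride == 0 && rec_row < n_rec) {
      int c = 0;
      trace(rec_row, c++) = s * h;
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = g_ST[i];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = g_SC[i];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = g_SR[i];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = g_LA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = g_BA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = g_BAIN[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = Lc[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = Lv[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = Lvr[k];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = g_PT[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = g_PC[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = g_PR[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = g_PCIN[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = Pc[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = Pv[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = Pvr[q];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = WstLA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = WpcBA[k];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = S(t, i);
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = R(t, q);
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = M(t, q);
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = v_ST[i];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = v_SC[i];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = v_SR[i];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = v_LA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = v_BA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = v_BAIN[k];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = v_PT[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = v_PC[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = v_PR[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = v_PCIN[q];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = u_ST[i];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = u_SC[i];
      for (int i = 0; i < N; ++i) trace(rec_row, c++) = u_SR[i];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = u_LA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = u_BA[k];
      for (int k = 0; k < 2 * N; ++k) trace(rec_row, c++) = u_BAIN[k];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = u_PT[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = u_PC[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = u_PR[q];
      for (int q = 0; q < 2; ++q) trace(rec_row, c++) = u_PCIN[q];
      ++rec_row;
    }
  }

  List fin = List::create(
    _["v_ST"] = v_ST, _["u_ST"] = u_ST, _["T_ST"] = T_ST, _["g_ST"] = g_ST,
    _["v_SC"] = v_SC, _["u_SC"] = u_SC, _["T_SC"] = T_SC, _["g_SC"] = g_SC,
    _["v_SR"] = v_SR, _["u_SR"] = u_SR, _["T_SR"] = T_SR, _["g_SR"] = g_SR,
    _["v_LA"] = v_LA, _["u_LA"] = u_LA, _["T_LA"] = T_LA, _["g_LA"] = g_LA,
    _["v_BA"] = v_BA, _["u_BA"] = u_BA, _["T_BA"] = T_BA, _["g_BA"] = g_BA
  );
  // Rcpp::List::create takes at most 20 arguments; extend in place.
  fin["v_BAIN"] = v_BAIN; fin["u_BAIN"] = u_BAIN; fin["T_BAIN"] = T_BAIN; fin["g_BAIN"] = g_BAIN;
  fin["v_PT"] = v_PT; fin["u_PT"] = u_PT; fin["T_PT"] = T_PT; fin["g_PT"] = g_PT;
  fin["v_PC"] = v_PC; fin["u_PC"] = u_PC; fin["T_PC"] = T_PC; fin["g_PC"] = g_PC;
  fin["v_PR"] = v_PR; fin["u_PR"] = u_PR; fin["T_PR"] = T_PR; fin["g_PR"] = g_PR;
  fin["v_PCIN"] = v_PCIN; fin["u_PCIN"] = u_PCIN; fin["T_PCIN"] = T_PCIN; fin["g_PCIN"] = g_PCIN;
  fin["Lc"] = Lc; fin["Lv"] = Lv; fin["Lvr"] = Lvr;
  fin["Pc"] = Pc; fin["Pv"] = Pv; fin["Pvr"] = Pvr;
  fin["WstLA"] = WstLA; fin["WpcBA"] = WpcBA;

  DataFrame spikes = DataFrame::create(
    _["step"] = raster.step, _["pop"] = raster.pop,
    _["q"] = raster.q, _["channel"] = raster.channel
  );
  return List::create(_["trace"] = trace, _["state"] = fin, _["spikes"] = spikes);
}
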