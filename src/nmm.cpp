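#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Potential-to-rate sigmoid S(v) = 2 e0 / (1 + exp(r (v0 - v))).
static inline double sigm(double v, double e0, double v0, double r) {
  return 2.0 * e0 / (1.0 + std::exp(r * (v0 - v)));
}

// One cortical region: three subpopulations (pyramidal, excitatory
// interneurons, inhibitory interneurons), each transformed by K parallel
// second-order synaptic branches.  Subpopulations 0 and 1 use excitatory
// kernels, subpopulation 2 the inhibitory ones.  Weights act on branch
// outputs only, so branch dynamics are weight-independent.
struct RegionC {
  double e0, v0, r;
  double C1, C2, C3, C4;
  int K;
  std::vector<double> Ge, we, Gi, wi, w;
  // y[sub][branch], yd[sub][branch]
  std::vector<double> y, yd;

  void init(const List& p) {
    NumericVector sg = p["sigmoid"];   // e0, v0, r
    e0 = sg[0]; v0 = sg[1]; r = sg[2];
    NumericVector cc = p["connectivity"]; // C1..C4
    C1 = cc[0]; C2 = cc[1]; C3 = cc[2]; C4 = cc[3];
    Ge = as<std::vector<double> >(p["Ge"]);
    we = as<std::vector<double> >(p["we"]);
    Gi = as<std::vector<double> >(p["Gi"]);
    wi = as<std::vector<double> >(p["wi"]);
    w  = as<std::vector<double> >(p["w"]);
    K = (int) w.size();
    y.assign(3 * K, 0.0);
    yd.assign(3 * K, 0.0);
  }

  inline double wsum(int sub) const {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += w[k] * y[sub * K + k];
    return s;
  }

  // Weighted region output Sum_k w_k y1_k - Sum_k w_k y2_k.
  inline double output() const { return wsum(1) - wsum(2); }

  // One explicit Euler step.  `ext` is the external firing-rate input
  // (noise + coupling drive); `inj` selects the subpopulation whose
  // presynaptic drive receives it (0 pyramidal, 1 excitatory, 2 inhibitory).
  inline bool step(double ext, double dt, int inj) {
    const double wy0 = wsum(0);
    double Sp = sigm(wsum(1) - wsum(2), e0, v0, r);
    double Se = C2 * sigm(C1 * wy0, e0, v0, r);
    double Si = C4 * sigm(C3 * wy0, e0, v0, r);
    if (inj == 0) Sp = ext + Sp;
    else if (inj == 1) Se = ext + Se;
    else Si = ext + Si;

    bool ok = true;
    for (int k = 0; k < K; ++k) {
      const double a0 = Ge[k] * we[k] * Sp - 2.0 * we[k] * yd[0 * K + k]
        - we[k] * we[k] * y[0 * K + k];
      const double a1 = Ge[k] * we[k] * Se - 2.0 * we[k] * yd[1 * K + k]
        - we[k] * we[k] * y[1 * K + k];
      const double a2 = Gi[k] * wi[k] * Si - 2.0 * wi[k] * yd[2 * K + k]
        - wi[k] * wi[k] * y[2 * K + k];
      y[0 * K + k] += dt * yd[0 * K + k]; yd[0 * K + k] += dt * a0;
      y[1 * K + k] += dt * yd[1 * K + k]; yd[1 * K + k] += dt * a1;
      y[2 * K + k] += dt * yd[2 * K + k]; yd[2 * K + k] += dt * a2;
      if (!(std::isfinite(y[0 * K + k]) && std::isfinite(y[1 * K + k]) &&
            std::isfinite(y[2 * K + k]))) ok = false;
    }
    return ok;
  }
};

// Cross-regional encoder: K parallel excitatory second-order filters
// driven by a firing-rate signal; output is the weight-merged state.
struct EncoderC {
  int K;
  std::vector<double> G, om, w, z, zd;
  void init(const List& p) {
    G  = as<std::vector<double> >(p["G"]);
    om = as<std::vector<double> >(p["omega"]);
    w  = as<std::vector<double> >(p["w"]);
    K = (int) w.size();
    z.assign(K, 0.0);
    zd.assign(K, 0.0);
  }
  inline double output() const {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += w[k] * z[k];
    return s;
  }
  inline void step(double in, double dt) {
    for (int k = 0; k < K; ++k) {
      const double a = G[k] * om[k] * in - 2.0 * om[k] * zd[k]
        - om[k] * om[k] * z[k];
      z[k] += dt * zd[k];
      zd[k] += dt * a;
    }
  }
};

//' @noRd
// [[Rcpp::export(name = ".sim_region_cpp")]]
NumericVector sim_region_cpp(List pars, NumericVector noise,
                             NumericVector drive, double dt,
                             int n_burn, int inj) {
  RegionC reg;
  reg.init(pars);
  const int n = noise.size();
  if (drive.size() != n) stop("drive length must equal noise length");
  NumericVector out(n - n_burn);
  for (int i = 0; i < n; ++i) {
    const double ext = noise[i] + drive[i];
    if (!reg.step(ext, dt, inj))
      stop("numerical divergence (non-finite state) at step %d", i + 1);
    if (i >= n_burn) out[i - n_burn] = reg.output();
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".sim_coupled_cpp")]]
List sim_coupled_cpp(List occ_pars, List par_pars, List coup,
                     NumericVector noise_o, NumericVector noise_p,
                     double dt, int n_burn, int inj) {
  RegionC occ, par;
  occ.init(occ_pars);
  par.init(par_pars);
  EncoderC enc_op, enc_po;          // occipital->parietal, parietal->occipital
  enc_op.init(as<List>(coup["encoder_op"]));
  enc_po.init(as<List>(coup["encoder_po"]));
  const double g_op = as<double>(coup["o_p"]);
  const double g_po = as<double>(coup["p_o"]);
  const int delay = as<int>(coup["delay"]);
  const int rm_mode = as<int>(coup["rm_mode"]);  // 0 running mean, 1 fixed
  const double rm_fixed_o = as<double>(coup["rm_fixed_o"]);
  const double rm_fixed_p = as<double>(coup["rm_fixed_p"]);

  const int n = noise_o.size();
  if (noise_p.size() != n) stop("regional noise streams differ in length");
  NumericVector out_o(n - n_burn), out_p(n - n_burn);

  // Ring buffers for an optional integer-step conduction delay.
  std::vector<double> buf_o(delay > 0 ? delay : 1, 0.0);
  std::vector<double> buf_p(delay > 0 ? delay : 1, 0.0);
  double mean_o = 0.0, mean_p = 0.0;

  for (int i = 0; i < n; ++i) {
    // Coupling rates from the CURRENT (pre-update) states; the running
    // mean includes the current sample (burn-in included).
    const double x_o = occ.output();
    const double x_p = par.output();
    double m_o, m_p;
    if (rm_mode == 1) { m_o = rm_fixed_o; m_p = rm_fixed_p; }
    else {
      mean_o += (x_o - mean_o) / (double)(i + 1);
      mean_p += (x_p - mean_p) / (double)(i + 1);
      m_o = mean_o; m_p = mean_p;
    }
    const double c_o = g_op * sigm(x_o - m_o, occ.e0, occ.v0, occ.r);
    const double c_p = g_po * sigm(x_p - m_p, par.e0, par.v0, par.r);

    double in_op = c_o, in_po = c_p;
    if (delay > 0) {
      const int j = i % delay;
      in_op = buf_o[j]; buf_o[j] = c_o;
      in_po = buf_p[j]; buf_p[j] = c_p;
    }

    // Encoder outputs feeding the target regions this step (pre-update),
    // then advance the encoder filters.
    const double drive_to_par = enc_op.output();
    const double drive_to_occ = enc_po.output();
    enc_op.step(in_op, dt);
    enc_po.step(in_po, dt);

    const double ext_o = noise_o[i] + drive_to_occ;
    const double ext_p = noise_p[i] + drive_to_par;
    if (!occ.step(ext_o, dt, inj))
      stop("numerical divergence in occipital region at step %d", i + 1);
    if (!par.step(ext_p, dt, inj))
      stop("numerical divergence in parietal region at step %d", i + 1);
    if (i >= n_burn) {
      out_o[i - n_burn] = occ.output();
      out_p[i - n_burn] = par.output();
    }
  }
  return List::create(_["occipital"] = out_o, _["parietal"] = out_p);
}
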