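// Compiled mirror of the reference right-hand side in R/system-assemble.R.
// The two implementations are kept in lockstep by a parity test; any change
// here must be made in the R reference first.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NC = 26;

enum Cmp {
  iSsu = 0, iSaa, iSfa, iSva, iSbu, iSpro, iSac, iSh2, iSch4, iSIC, iSIN,
  iSI, iXc, iXch, iXpr, iXli, iXsu, iXaa, iXfa, iXc4, iXpro, iXac, iXh2,
  iXI, iScat, iSan
};

// order frozen with .cpp_pars() in R
enum Kin {
  k_dis = 0, k_hyd_ch, k_hyd_pr, k_hyd_li, k_m_su, K_S_su, k_m_aa, K_S_aa,
  k_m_fa, K_S_fa, k_m_c4, K_S_c4, k_m_pro, K_S_pro, k_m_ac, K_S_ac, k_m_h2,
  K_S_h2, k_dec, Y_su, Y_aa, Y_fa, Y_c4, Y_pro, Y_ac, Y_h2, K_S_IN,
  K_I_h2_fa, K_I_h2_c4, K_I_h2_pro, K_I_nh3, pH_UL_aa, pH_LL_aa, pH_UL_ac,
  pH_LL_ac, pH_UL_h2, pH_LL_h2, Ka_va, Ka_bu, Ka_pro, Ka_ac
};

enum Ab { Ka_co2 = 0, Ka_IN, Kw, KH_h2, KH_ch4, KH_co2, p_h2o, RT };

static inline double softplus(double x, double w) {
  return (x / w > 30.0) ? x : w * log1p(exp(x / w));
}

// charge balance and its analytic derivative in the proton concentration
static inline double charge_balance(const double *C, const double *kin,
                                    const double *ab, double sh,
                                    double *dfdh) {
  double f = C[iScat] + C[iSIN] * sh / (ab[Ka_IN] + sh) + sh - C[iSan]
    - C[iSIC] * ab[Ka_co2] / (ab[Ka_co2] + sh)
    - (C[iSac] / 64.0) * kin[Ka_ac] / (kin[Ka_ac] + sh)
    - (C[iSpro] / 112.0) * kin[Ka_pro] / (kin[Ka_pro] + sh)
    - (C[iSbu] / 160.0) * kin[Ka_bu] / (kin[Ka_bu] + sh)
    - (C[iSva] / 208.0) * kin[Ka_va] / (kin[Ka_va] + sh)
    - ab[Kw] / sh;
  if (dfdh) {
    double d = C[iSIN] * ab[Ka_IN] / pow(ab[Ka_IN] + sh, 2) + 1.0
      + C[iSIC] * ab[Ka_co2] / pow(ab[Ka_co2] + sh, 2)
      + (C[iSac] / 64.0) * kin[Ka_ac] / pow(kin[Ka_ac] + sh, 2)
      + (C[iSpro] / 112.0) * kin[Ka_pro] / pow(kin[Ka_pro] + sh, 2)
      + (C[iSbu] / 160.0) * kin[Ka_bu] / pow(kin[Ka_bu] + sh, 2)
      + (C[iSva] / 208.0) * kin[Ka_va] / pow(kin[Ka_va] + sh, 2)
      + ab[Kw] / (sh * sh);
    *dfdh = d;
  }
  return f;
}

static double solve_ph(const double *C, const double *kin, const double *ab) {
  double lo = 1e-14, hi = 1.0, sh = 1e-7;
  for (int it = 0; it < 100; ++it) {
    double d, f = charge_balance(C, kin, ab, sh, &d);
    if (f > 0) hi = sh; else lo = sh;
    double shn = sh - f / d;
    if (!std::isfinite(shn) || shn <= lo || shn >= hi) shn = sqrt(lo * hi);
    if (fabs(shn - sh) <= 1e-13 * sh) { sh = shn; break; }
    sh = shn;
  }
  return -log10(sh);
}

// 19 ADM1 process rates at one point
static void process_rates(const double *C, const double *kin,
                          const double *ab, double fT, double ph,
                          double *rho) {
  // extinction threshold: biomass below ~single-cell density cannot react
  double xb[7];
  for (int g = 0; g < 7; ++g)
    xb[g] = (C[iXsu + g] < 1e-9) ? 0.0 : C[iXsu + g];
  double sh = pow(10.0, -ph);
  double S_nh3 = C[iSIN] * ab[Ka_IN] / (ab[Ka_IN] + sh);
  double I_IN = C[iSIN] / (C[iSIN] + kin[K_S_IN]);
  double I_nh3 = 1.0 / (1.0 + S_nh3 / kin[K_I_nh3]);
  auto hill = [&](double UL, double LL) {
    double n = 3.0 / (UL - LL);
    double K = pow(10.0, -(UL + LL) / 2.0);
    double Kn = pow(K, n);
    return Kn / (pow(sh, n) + Kn);
  };
  double I_aa = hill(kin[pH_UL_aa], kin[pH_LL_aa]) * I_IN;
  auto monod = [](double S, double K) { return S / (S + K); };
  auto Ih2 = [&](double KI) { return 1.0 / (1.0 + C[iSh2] / KI); };
  rho[0] = kin[k_dis] * fT * C[iXc];
  rho[1] = kin[k_hyd_ch] * fT * C[iXch];
  rho[2] = kin[k_hyd_pr] * fT * C[iXpr];
  rho[3] = kin[k_hyd_li] * fT * C[iXli];
  rho[4] = kin[k_m_su] * fT * monod(C[iSsu], kin[K_S_su]) * xb[0] * I_aa;
  rho[5] = kin[k_m_aa] * fT * monod(C[iSaa], kin[K_S_aa]) * xb[1] * I_aa;
  rho[6] = kin[k_m_fa] * fT * monod(C[iSfa], kin[K_S_fa]) * xb[2] * I_aa *
    Ih2(kin[K_I_h2_fa]);
  double comp = C[iSva] + C[iSbu] + 1e-12;
  rho[7] = kin[k_m_c4] * fT * monod(C[iSva], kin[K_S_c4]) * xb[3] *
    (C[iSva] / comp) * I_aa * Ih2(kin[K_I_h2_c4]);
  rho[8] = kin[k_m_c4] * fT * monod(C[iSbu], kin[K_S_c4]) * xb[3] *
    (C[iSbu] / comp) * I_aa * Ih2(kin[K_I_h2_c4]);
  rho[9] = kin[k_m_pro] * fT * monod(C[iSpro], kin[K_S_pro]) * xb[4] *
    I_aa * Ih2(kin[K_I_h2_pro]);
  rho[10] = kin[k_m_ac] * fT * monod(C[iSac], kin[K_S_ac]) * xb[5] *
    hill(kin[pH_UL_ac], kin[pH_LL_ac]) * I_IN * I_nh3;
  rho[11] = kin[k_m_h2] * fT * monod(C[iSh2], kin[K_S_h2]) * xb[6] *
    hill(kin[pH_UL_h2], kin[pH_LL_h2]) * I_IN;
  for (int g = 0; g < 7; ++g) rho[12 + g] = kin[k_dec] * fT * xb[g];
}

// [[Rcpp::export]]
NumericVector system_rhs_cpp(NumericVector y, List pars) {
  const int n_stage = as<int>(pars["n_stage"]);
  const int S = as<int>(pars["S"]);
  const int stages = as<int>(pars["stages"]);
  const bool enc = as<int>(pars["encapsulated"]) == 1;
  NumericMatrix nu = pars["nu"];
  NumericVector c_in = pars["c_in"];
  const double Q = as<double>(pars["Q"]);
  NumericVector V_liq = pars["V_liq"], V_gas = pars["V_gas"],
    area = pars["area"], n_beads = pars["n_beads"], p_set = pars["p_set"],
    mem_rate = pars["mem_rate"];
  const double part_div = as<double>(pars["part_div"]);
  const double kLa = as<double>(pars["kLa"]), k_p = as<double>(pars["k_p"]);
  const double cap_sharpness = as<double>(pars["cap_sharpness"]),
    cap = as<double>(pars["cap"]);
  NumericVector edges = pars["shell_edges"], vols = pars["shell_vols"],
    D_eff = pars["D_eff"];
  NumericVector kinv = pars["kin"], abv = pars["ab"];
  const double *kin = kinv.begin(), *ab = abv.begin();
  const double fT = as<double>(pars["fT"]);

  // solute indices that diffuse through the gel
  static const int sol[14] = {iSsu, iSaa, iSfa, iSva, iSbu, iSpro, iSac,
                              iSh2, iSch4, iSIC, iSIN, iSI, iScat, iSan};
  const double Yg[7] = {kin[Y_su], kin[Y_aa], kin[Y_fa], kin[Y_c4],
                        kin[Y_pro], kin[Y_ac], kin[Y_h2]};

  NumericVector dy(y.size());
  std::vector<double> bulk(NC), rho(19), react(NC), inflow(NC);
  std::vector<double> Cs(NC * std::max(S, 1)), dC(NC * std::max(S, 1));

  for (int k = 0; k < stages; ++k) {
    const int off = k * n_stage;
    for (int i = 0; i < NC; ++i) bulk[i] = std::max(y[off + i], 0.0);
    double gh2 = std::max(y[off + NC], 0.0);
    double gch4 = std::max(y[off + NC + 1], 0.0);
    double gco2 = std::max(y[off + NC + 2], 0.0);
    const double D = Q / V_liq[k];

    const double p_h2 = gh2 * ab[RT] / 16.0;
    const double p_ch4 = gch4 * ab[RT] / 64.0;
    const double p_co2 = gco2 * ab[RT];
    const double P = p_h2 + p_ch4 + p_co2 + ab[p_h2o];

    const double ph_b = solve_ph(bulk.data(), kin, ab);
    process_rates(bulk.data(), kin, ab, fT, ph_b, rho.data());
    for (int i = 0; i < NC; ++i) {
      double s = 0.0;
      for (int j = 0; j < 19; ++j) s += nu(i, j) * rho[j];
      react[i] = s;
    }

    const double sh = pow(10.0, -ph_b);
    const double s_co2 = bulk[iSIC] * sh / (sh + ab[Ka_co2]);
    const double rT_h2 = kLa * (bulk[iSh2] - 16.0 * ab[KH_h2] * p_h2);
    const double rT_ch4 = kLa * (bulk[iSch4] - 64.0 * ab[KH_ch4] * p_ch4);
    const double rT_co2 = kLa * (s_co2 - ab[KH_co2] * p_co2);

    if (k == 1) {
      for (int i = 0; i < NC; ++i) inflow[i] = std::max(y[i], 0.0);
      for (int i = iXc; i <= iXI; ++i) inflow[i] /= part_div;
    } else {
      for (int i = 0; i < NC; ++i) inflow[i] = c_in[i];
    }

    std::vector<double> dbulk(NC);
    for (int i = 0; i < NC; ++i) {
      double out = (i >= iXc && i <= iXI) ? bulk[i] / part_div : bulk[i];
      dbulk[i] = D * (inflow[i] - out) + react[i];
    }
    dbulk[iSh2] -= rT_h2;
    dbulk[iSch4] -= rT_ch4;
    dbulk[iSIC] -= rT_co2;
    if (mem_rate[k] > 0) dbulk[iSh2] -= mem_rate[k] / V_liq[k] * bulk[iSh2];

    if (enc) {
      for (int s = 0; s < S; ++s)
        for (int i = 0; i < NC; ++i)
          Cs[s * NC + i] = std::max(y[off + NC + 3 + s * NC + i], 0.0);
      std::fill(dC.begin(), dC.end(), 0.0);
      const double dr = edges[1] - edges[0];
      // interior faces
      for (int s = 0; s < S - 1; ++s) {
        const double faceA = 4.0 * M_PI * edges[s + 1] * edges[s + 1];
        for (int m = 0; m < 14; ++m) {
          const int i = sol[m];
          const double FA = D_eff[i] * (Cs[(s + 1) * NC + i] - Cs[s * NC + i])
            / dr * faceA;
          dC[s * NC + i] += FA / vols[s];
          dC[(s + 1) * NC + i] -= FA / vols[s + 1];
        }
      }
      // surface clamped to bulk
      const double surfA = 4.0 * M_PI * edges[S] * edges[S];
      double slough[7] = {0, 0, 0, 0, 0, 0, 0};
      double slough_xi = 0.0;
      std::vector<double> flux_in(NC, 0.0);
      for (int m = 0; m < 14; ++m) {
        const int i = sol[m];
        flux_in[i] = D_eff[i] * (bulk[i] - Cs[(S - 1) * NC + i]) / (dr / 2.0);
        dC[(S - 1) * NC + i] += flux_in[i] * surfA / vols[S - 1];
      }
      std::vector<double> rho_s(19);
      for (int s = 0; s < S; ++s) {
        double *C = &Cs[s * NC];
        const double ph_s = solve_ph(C, kin, ab);
        process_rates(C, kin, ab, fT, ph_s, rho_s.data());
        for (int i = 0; i < NC; ++i) {
          double r = 0.0;
          for (int j = 0; j < 19; ++j) r += nu(i, j) * rho_s[j];
          dC[s * NC + i] += r;
        }
        double xtot = 0.0;
        for (int g = 0; g < 7; ++g) xtot += C[iXsu + g];
        const double sig = pow(xtot / cap, cap_sharpness);
        const double G[7] = {Yg[0] * rho_s[4], Yg[1] * rho_s[5],
                             Yg[2] * rho_s[6], Yg[3] * (rho_s[7] + rho_s[8]),
                             Yg[4] * rho_s[9], Yg[5] * rho_s[10],
                             Yg[6] * rho_s[11]};
        for (int g = 0; g < 7; ++g) {
          const double dvt = sig * G[g];
          dC[s * NC + iXsu + g] -= dvt;
          slough[g] += dvt * vols[s];
        }
        // inert residue from disintegration leaves with the slough stream
        const double prod_xi = nu(iXI, 0) * rho_s[0];
        dC[s * NC + iXI] -= prod_xi;
        slough_xi += prod_xi * vols[s];
      }
      for (int g = 0; g < 7; ++g)
        dbulk[iXsu + g] += slough[g] * n_beads[k] / V_liq[k];
      dbulk[iXI] += slough_xi * n_beads[k] / V_liq[k];
      for (int i = 0; i < NC; ++i)
        dbulk[i] -= flux_in[i] * area[k] / V_liq[k];
      for (int s = 0; s < S; ++s)
        for (int i = 0; i < NC; ++i)
          dy[off + NC + 3 + s * NC + i] = dC[s * NC + i];
    }

    const double q_gas = k_p * V_gas[k] * softplus(P - p_set[k], 1e-3);
    dy[off + NC] = rT_h2 * V_liq[k] / V_gas[k] - gh2 * q_gas / V_gas[k];
    dy[off + NC + 1] = rT_ch4 * V_liq[k] / V_gas[k] - gch4 * q_gas / V_gas[k];
    dy[off + NC + 2] = rT_co2 * V_liq[k] / V_gas[k] - gco2 * q_gas / V_gas[k];
    for (int i = 0; i < NC; ++i) dy[off + i] = dbulk[i];
  }
  return dy;
}
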