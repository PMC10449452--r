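// Cellular Potts engine with Act-model protrusions, a T cell
// connectivity constraint, an explicit IFNg reaction-diffusion layer and
// per-cell regulatory ODE integration (multiscale coupling).
//
// Type codes: 0 medium, 1 E, 2 H (hybrid E/M), 3 M, 4 T cell.
// Regulatory state columns: u, mz, z, ms, s, st, mp, p, pm (9).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
using namespace Rcpp;

static const int NBX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int NBY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
// cyclic order around a site (for the local connectivity test)
static const int CYC[8] = {0, 1, 2, 4, 7, 6, 5, 3};

// molecules per lattice site per nM (site 2x2 um^2, 10 um slab)
static const double MOLEC_PER_NM_SITE = 6.02214076e23 * 1e-9 * 40.0 * 1e-15;

struct RegParams {
  double gu, ku, gmz, kmz, gz, kz, u0;
  double lz_u, nz_u, z0_u, ls_u, ns_u, s0_u;
  double lz_mz, nz_mz, z0_mz, ls_mz, ns_mz, s0_mz;
  int sites_z, sites_p;
  std::vector<double> l_z, gm_z, gu_z, l_p, gm_p, gu_p;
  double gst, kst, li_st, ni_st, i0_st;
  double gmp, kmp, lst_mp, nst_mp, st0_mp;
  double gp, kp, ktr, kpm;
  double lpm_u, npm_u, pm0_u;
  double g0ms, gms, kms, jms0, ntms, jms1, nsms, gs, ks;
  double lpm_i, npm_i, pm0_i, lt_i, nt_i, t0_i;
};

static RegParams load_reg(const List& p) {
  RegParams r;
  r.gu = p["gu"]; r.ku = p["ku"]; r.gmz = p["gmz"]; r.kmz = p["kmz"];
  r.gz = p["gz"]; r.kz = p["kz"]; r.u0 = p["u0"];
  r.lz_u = p["lz_u"]; r.nz_u = p["nz_u"]; r.z0_u = p["z0_u"];
  r.ls_u = p["ls_u"]; r.ns_u = p["ns_u"]; r.s0_u = p["s0_u"];
  r.lz_mz = p["lz_mz"]; r.nz_mz = p["nz_mz"]; r.z0_mz = p["z0_mz"];
  r.ls_mz = p["ls_mz"]; r.ns_mz = p["ns_mz"]; r.s0_mz = p["s0_mz"];
  r.sites_z = as<int>(p["mirna_sites_z"]);
  r.sites_p = as<int>(p["mirna_sites_p"]);
  r.l_z = as<std::vector<double> >(p["l_z"]);
  r.gm_z = as<std::vector<double> >(p["gm_z"]);
  r.gu_z = as<std::vector<double> >(p["gu_z"]);
  r.l_p = as<std::vector<double> >(p["l_p"]);
  r.gm_p = as<std::vector<double> >(p["gm_p"]);
  r.gu_p = as<std::vector<double> >(p["gu_p"]);
  r.gst = p["gst"]; r.kst = p["kst"]; r.li_st = p["li_st"];
  r.ni_st = p["ni_st"]; r.i0_st = p["i0_st"];
  r.gmp = p["gmp"]; r.kmp = p["kmp"]; r.lst_mp = p["lst_mp"];
  r.nst_mp = p["nst_mp"]; r.st0_mp = p["st0_mp"];
  r.gp = p["gp"]; r.kp = p["kp"]; r.ktr = p["ktr"]; r.kpm = p["kpm"];
  r.lpm_u = p["lpm_u"]; r.npm_u = p["npm_u"]; r.pm0_u = p["pm0_u"];
  r.g0ms = p["g0ms"]; r.gms = p["gms"]; r.kms = p["kms"];
  r.jms0 = p["jms0"]; r.ntms = p["ntms"]; r.jms1 = p["jms1"];
  r.nsms = p["nsms"]; r.gs = p["gs"]; r.ks = p["ks"];
  r.lpm_i = p["lpm_i"]; r.npm_i = p["npm_i"]; r.pm0_i = p["pm0_i"];
  r.lt_i = p["lt_i"]; r.nt_i = p["nt_i"]; r.t0_i = p["t0_i"];
  return r;
}

static inline double hs(double B, double B0, double n, double lam) {
  double hm = 1.0 / (1.0 + std::pow(B / B0, n));
  return hm + lam * (1.0 - hm);
}

// binomial-weighted miRNA-mRNA complex factors
static void mirna_factors(double u, double u0, int n,
                          const std::vector<double>& l,
                          const std::vector<double>& gm,
                          const std::vector<double>& gu,
                          double& L, double& Ym, double& Yu) {
  double x = u / u0, q = 1.0 / (1.0 + x);
  // w_i = C(n,i) x^i / (1+x)^n built iteratively
  double w = std::pow(q, n);
  L = Ym = Yu = 0.0;
  for (int i = 0; i <= n; ++i) {
    L += l[i] * w; Ym += gm[i] * w; Yu += i * gu[i] * w;
    if (i < n) w *= x * (double)(n - i) / (double)(i + 1);
  }
}

// 9-state regulatory RHS with IFNg (nM) and TGFb (nM) as clamped inputs;
// gu/gmz scaled by per-cell heterogeneity multipliers
static void reg_rhs(const double* y, double I, double Tg,
                    const RegParams& r, double mu, double mmz,
                    double* dy) {
  double u = y[0], mz = y[1], z = y[2], ms = y[3], s = y[4];
  double st = y[5], mp = y[6], P = y[7], pm = y[8];
  double Lz, Ymz, Yuz, Lp, Ymp, Yup;
  mirna_factors(u, r.u0, r.sites_z, r.l_z, r.gm_z, r.gu_z, Lz, Ymz, Yuz);
  mirna_factors(u, r.u0, r.sites_p, r.l_p, r.gm_p, r.gu_p, Lp, Ymp, Yup);
  dy[0] = mu * r.gu * hs(z, r.z0_u, r.nz_u, r.lz_u) *
          hs(s, r.s0_u, r.ns_u, r.ls_u) *
          hs(pm, r.pm0_u, r.npm_u, r.lpm_u) -
          mz * Yuz - mp * Yup - r.ku * u;
  dy[1] = mmz * r.gmz * hs(z, r.z0_mz, r.nz_mz, r.lz_mz) *
          hs(s, r.s0_mz, r.ns_mz, r.ls_mz) - mz * Ymz - r.kmz * mz;
  dy[2] = r.gz * mz * Lz - r.kz * z;
  double xt = std::pow(Tg / r.jms0, r.ntms);
  double hp_t = xt / (1.0 + xt);
  double hm_s = 1.0 / (1.0 + std::pow(s / r.jms1, r.nsms));
  dy[3] = r.g0ms + r.gms * hp_t * hm_s - r.kms * ms;
  dy[4] = r.gs * ms - r.ks * s;
  dy[5] = r.gst * hs(I, r.i0_st, r.ni_st, r.li_st) - r.kst * st;
  dy[6] = r.gmp * hs(st, r.st0_mp, r.nst_mp, r.lst_mp) -
          mp * Ymp - r.kmp * mp;
  dy[7] = r.gp * mp * Lp - (r.ktr + r.kp) * P;
  dy[8] = r.ktr * P - r.kpm * pm;
}

// fixed-step RK4 advance of one cell's regulatory state
static void reg_advance(double* y, double I, double Tg, const RegParams& r,
                        double mu, double mmz, double hours, double dt) {
  int n = (int)std::ceil(hours / dt);
  double h = hours / n;
  double k1[9], k2[9], k3[9], k4[9], tmp[9];
  for (int s = 0; s < n; ++s) {
    reg_rhs(y, I, Tg, r, mu, mmz, k1);
    for (int i = 0; i < 9; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
    reg_rhs(tmp, I, Tg, r, mu, mmz, k2);
    for (int i = 0; i < 9; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
    reg_rhs(tmp, I, Tg, r, mu, mmz, k3);
    for (int i = 0; i < 9; ++i) tmp[i] = y[i] + h * k3[i];
    reg_rhs(tmp, I, Tg, r, mu, mmz, k4);
    for (int i = 0; i < 9; ++i) {
      y[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      if (y[i] < 0) y[i] = 0;
    }
  }
}

// [[Rcpp::export]]
NumericVector reg_advance_cpp(NumericVector y0, double I, double Tg,
                              List reg_params, double mult_u,
                              double mult_mz, double hours, double dt) {
  RegParams r = load_reg(reg_params);
  NumericVector y = clone(y0);
  reg_advance(REAL(y), I, Tg, r, mult_u, mult_mz, hours, dt);
  return y;
}

// ---------------------------------------------------------------------
// CPM energies

struct CpmParams {
  NumericMatrix J;            // 5x5 by type code
  NumericVector target_area;  // by type code (sites)
  NumericVector target_perim; // by type code (interfaces)
  NumericVector sa, sl;       // by type code
  double lambda_act, max_act, temperature;
};

static CpmParams load_cpm(const List& p) {
  CpmParams c;
  c.J = as<NumericMatrix>(p["J"]);
  c.target_area = as<NumericVector>(p["target_area"]);
  c.target_perim = as<NumericVector>(p["target_perim"]);
  c.sa = as<NumericVector>(p["sa"]);
  c.sl = as<NumericVector>(p["sl"]);
  c.lambda_act = p["lambda_act"]; c.max_act = p["max_act"];
  c.temperature = p["temperature"];
  return c;
}

// geometric mean Act over the second-order Moore neighborhood of (x, y),
// restricted to sites of the same cell; 0 if any included site has Act 0
static double gm_act(const IntegerMatrix& spins, const NumericMatrix& acts,
                     int x, int y, int spin) {
  if (spin == 0) return 0.0;
  int H = spins.nrow(), W = spins.ncol();
  double logsum = 0.0; int cnt = 0;
  for (int dy = -2; dy <= 2; ++dy)
    for (int dx = -2; dx <= 2; ++dx) {
      int xx = x + dx, yy = y + dy;
      if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
      if (spins(yy, xx) != spin) continue;
      double a = acts(yy, xx);
      if (a <= 0) return 0.0;
      logsum += std::log(a); ++cnt;
    }
  if (cnt == 0) return 0.0;
  return std::exp(logsum / cnt);
}

// [[Rcpp::export]]
double gm_act_cpp(IntegerMatrix spins, NumericMatrix acts, int x, int y) {
  return gm_act(spins, acts, x - 1, y - 1, spins(y - 1, x - 1));
}

// total adhesion + area + perimeter energy, recomputed from scratch
// [[Rcpp::export]]
double cpm_global_hamiltonian(IntegerMatrix spins, IntegerVector cell_type,
                              List cpm_params) {
  CpmParams cp = load_cpm(cpm_params);
  int H = spins.nrow(), W = spins.ncol();
  int ncell = cell_type.size();
  std::vector<double> area(ncell + 1, 0.0), perim(ncell + 1, 0.0);
  double e_adh = 0.0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int s = spins(y, x);
      if (s > 0) area[s] += 1.0;
      int ts = (s > 0) ? cell_type[s - 1] : 0;
      for (int k = 0; k < 8; ++k) {
        int xx = x + NBX[k], yy = y + NBY[k];
        if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
        int s2 = spins(yy, xx);
        if (s2 == s) continue;
        int t2 = (s2 > 0) ? cell_type[s2 - 1] : 0;
        e_adh += 0.5 * cp.J(ts, t2); // each pair visited twice
        if (s > 0) perim[s] += 1.0;
      }
    }
  double e_area = 0.0, e_per = 0.0;
  for (int c = 1; c <= ncell; ++c) {
    int tc = cell_type[c - 1];
    double da = area[c] - cp.target_area[tc];
    e_area += cp.sa[tc] * da * da;
    double dl = perim[c] - cp.target_perim[tc];
    e_per += cp.sl[tc] * dl * dl;
  }
  return e_adh + e_area + e_per;
}

// local energy change for copying the spin at source site u into target
// site v; areas/perims supplied as current cached values
static void local_dh(const IntegerMatrix& spins,
                     const IntegerVector& cell_type,
                     const NumericMatrix& acts,
                     const std::vector<double>& area,
                     const std::vector<double>& perim,
                     int ux, int uy, int vx, int vy, const CpmParams& cp,
                     double& dh_adh, double& dh_area, double& dh_per,
                     double& dh_act) {
  int H = spins.nrow(), W = spins.ncol();
  int ss = spins(uy, ux), st_ = spins(vy, vx);
  int ts = (ss > 0) ? cell_type[ss - 1] : 0;
  int tt = (st_ > 0) ? cell_type[st_ - 1] : 0;
  // adhesion around v
  dh_adh = 0.0;
  int n_s = 0, n_t = 0, deg = 0;
  for (int k = 0; k < 8; ++k) {
    int xx = vx + NBX[k], yy = vy + NBY[k];
    if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
    ++deg;
    int s2 = spins(yy, xx);
    int t2 = (s2 > 0) ? cell_type[s2 - 1] : 0;
    double before = (s2 != st_) ? cp.J(tt, t2) : 0.0;
    double after = (s2 != ss) ? cp.J(ts, t2) : 0.0;
    dh_adh += after - before;
    if (s2 == ss) ++n_s;
    if (s2 == st_) ++n_t;
  }
  // area terms
  dh_area = 0.0;
  if (ss > 0) {
    double a = area[ss], A = cp.target_area[ts];
    dh_area += cp.sa[ts] * ((a + 1 - A) * (a + 1 - A) - (a - A) * (a - A));
  }
  if (st_ > 0) {
    double a = area[st_], A = cp.target_area[tt];
    dh_area += cp.sa[tt] * ((a - 1 - A) * (a - 1 - A) - (a - A) * (a - A));
  }
  // perimeter terms
  dh_per = 0.0;
  if (ss > 0) {
    double dl = deg - 2.0 * n_s;
    double l = perim[ss], L = cp.target_perim[ts];
    dh_per += cp.sl[ts] * ((l + dl - L) * (l + dl - L) - (l - L) * (l - L));
  }
  if (st_ > 0) {
    double dl = 2.0 * n_t - deg;
    double l = perim[st_], L = cp.target_perim[tt];
    dh_per += cp.sl[tt] * ((l + dl - L) * (l + dl - L) - (l - L) * (l - L));
  }
  // Act protrusion bias (T cells only); negative when the source
  // neighborhood is more recently active than the target's
  dh_act = 0.0;
  if (ts == 4 || tt == 4) {
    double gu_ = gm_act(spins, acts, ux, uy, ss);
    double gv_ = gm_act(spins, acts, vx, vy, st_);
    dh_act = -cp.lambda_act / cp.max_act * (gu_ - gv_);
  }
}

// [[Rcpp::export]]
List cpm_delta_hamiltonian(IntegerMatrix spins, IntegerVector cell_type,
                           NumericMatrix acts, int ux, int uy, int vx,
                           int vy, List cpm_params) {
  CpmParams cp = load_cpm(cpm_params);
  int H = spins.nrow(), W = spins.ncol();
  int ncell = cell_type.size();
  std::vector<double> area(ncell + 1, 0.0), perim(ncell + 1, 0.0);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int s = spins(y, x);
      if (s == 0) continue;
      area[s] += 1.0;
      for (int k = 0; k < 8; ++k) {
        int xx = x + NBX[k], yy = y + NBY[k];
        if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
        if (spins(yy, xx) != s) perim[s] += 1.0;
      }
    }
  double a, b, c, d;
  local_dh(spins, cell_type, acts, area, perim, ux - 1, uy - 1, vx - 1,
           vy - 1, cp, a, b, c, d);
  return List::create(_["adhesion"] = a, _["area"] = b,
                      _["perimeter"] = c, _["act"] = d,
                      _["total"] = a + b + c + d);
}

// local connectivity test for the cell losing site (vx, vy): its sites
// among the 8 neighbors must form a single arc in cyclic order
static bool stays_connected(const IntegerMatrix& spins, int vx, int vy,
                            int spin) {
  int H = spins.nrow(), W = spins.ncol();
  int occ[8];
  for (int k = 0; k < 8; ++k) {
    int xx = vx + NBX[CYC[k]], yy = vy + NBY[CYC[k]];
    occ[k] = (xx >= 0 && xx < W && yy >= 0 && yy < H &&
              spins(yy, xx) == spin) ? 1 : 0;
  }
  int arcs = 0, tot = 0;
  for (int k = 0; k < 8; ++k) {
    tot += occ[k];
    if (occ[k] == 1 && occ[(k + 7) % 8] == 0) ++arcs;
  }
  if (tot == 0) return false; // would strand the site group entirely
  return arcs <= 1;
}

// ---------------------------------------------------------------------
// IFNg field: FTCS diffusion with no-flux boundaries, per-site
// first-order uptake (exponential substep update) and continuous sources

// [[Rcpp::export]]
List ftcs_run(NumericMatrix field, NumericMatrix uptake,
              NumericMatrix source, double D, double h, double minutes,
              double max_cfl = 0.2) {
  int H = field.nrow(), W = field.ncol();
  double dt_stab = max_cfl * h * h / (4.0 * D);
  int nsub = std::max(1, (int)std::ceil(minutes / dt_stab));
  double dt = minutes / nsub;
  NumericMatrix cur = clone(field), nxt(H, W);
  double secreted = 0.0, consumed = 0.0;
  for (int s = 0; s < nsub; ++s) {
    double a = D * dt / (h * h);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        double c = cur(y, x), lap = 0.0;
        if (x > 0) lap += cur(y, x - 1) - c;
        if (x < W - 1) lap += cur(y, x + 1) - c;
        if (y > 0) lap += cur(y - 1, x) - c;
        if (y < H - 1) lap += cur(y + 1, x) - c;
        double cd = c + a * lap;
        double dec = cd * std::exp(-uptake(y, x) * dt);
        consumed += cd - dec;
        double add = source(y, x) * dt;
        secreted += add;
        nxt(y, x) = dec + add;
      }
    std::swap(cur, nxt);
  }
  return List::create(_["field"] = cur, _["secreted"] = secreted,
                      _["consumed"] = consumed, _["substeps"] = nsub);
}

// ---------------------------------------------------------------------
// full multiscale simulation

// [[Rcpp::export]]
List cpm_simulate(IntegerMatrix spins0, IntegerVector cell_type0,
                  NumericMatrix reg0, NumericMatrix reg_mult,
                  List cpm_params, List reg_params, List field_params,
                  List control) {
  CpmParams cp = load_cpm(cpm_params);
  RegParams rp = load_reg(reg_params);
  IntegerMatrix spins = clone(spins0);
  IntegerVector cell_type = clone(cell_type0);
  NumericMatrix reg = clone(reg0);
  int H = spins.nrow(), W = spins.ncol();
  int ncell = cell_type.size();

  // field configuration
  double D = field_params["D"];
  double site_um = field_params["site_um"];
  int fac = as<int>(field_params["field_fac"]);
  NumericVector uptake_by_type = field_params["uptake_by_type"]; // 1/min
  double secretion_rate = field_params["secretion_rate"]; // molecules/min
  NumericMatrix tgfb = as<NumericMatrix>(field_params["tgfb"]); // nM, site res
  double max_cfl = field_params["max_cfl"];

  // control
  int total_mcs = as<int>(control["total_mcs"]);
  int freeze_mcs = as<int>(control["freeze_mcs"]);
  int out_every = as<int>(control["output_every_mcs"]);
  double mcs_min = control["mcs_min"];
  double accel = control["accel"];
  double ode_dt = control["ode_dt_h"];
  int mode = as<int>(control["mode"]); // 0 none, 1 pdl1, 2 tgfb
  unsigned int seed = as<unsigned int>(control["seed"]);
  bool do_ode = as<bool>(control["ode_enabled"]);
  bool field_uptake_on = as<bool>(control["field_uptake"]);

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);
  std::uniform_int_distribution<int> rx(0, W - 1), ry(0, H - 1), rn(0, 7);

  // caches
  std::vector<double> area(ncell + 1, 0.0), perim(ncell + 1, 0.0);
  NumericMatrix acts(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int s = spins(y, x);
      if (s == 0) continue;
      area[s] += 1.0;
      for (int k = 0; k < 8; ++k) {
        int xx = x + NBX[k], yy = y + NBY[k];
        if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
        if (spins(yy, xx) != s) perim[s] += 1.0;
      }
    }

  // coarse field grid (molecules per lattice site)
  int FH = (H + fac - 1) / fac, FW = (W + fac - 1) / fac;
  double hf = site_um * fac;
  NumericMatrix field(FH, FW);
  std::vector<double> prod(ncell + 1, 0.0); // molecules/min per T cell
  double total_secreted = 0.0, total_consumed = 0.0;

  int n_out = total_mcs / out_every + 1;
  int max_rows = n_out * ncell + ncell;
  std::vector<double> o_time; o_time.reserve(max_rows);
  std::vector<int> o_id, o_type; o_id.reserve(max_rows);
  std::vector<double> o_x, o_y, o_area, o_mz, o_pm, o_si, o_st2, o_prod;

  std::vector<double> sense_i(ncell + 1, 0.0), sense_t(ncell + 1, 0.0);
  std::vector<double> cx(ncell + 1, 0.0), cy(ncell + 1, 0.0);

  // per-MCS occupancy scan: uptake map, sources, sensing, centroids,
  // PD-L1 contact summary for T cells
  NumericMatrix upt(FH, FW), src(FH, FW);
  std::vector<double> pm_contact(ncell + 1, 0.0), pm_contact_w(ncell + 1);

  auto scan = [&](bool frozen_phase) {
    std::fill(upt.begin(), upt.end(), 0.0);
    std::fill(src.begin(), src.end(), 0.0);
    std::fill(sense_i.begin(), sense_i.end(), 0.0);
    std::fill(sense_t.begin(), sense_t.end(), 0.0);
    std::fill(cx.begin(), cx.end(), 0.0);
    std::fill(cy.begin(), cy.end(), 0.0);
    std::fill(pm_contact.begin(), pm_contact.end(), 0.0);
    std::fill(pm_contact_w.begin(), pm_contact_w.end(), 0.0);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        int s = spins(y, x);
        int t = (s > 0) ? cell_type[s - 1] : 0;
        int fy = y / fac, fx = x / fac;
        if (field_uptake_on) upt(fy, fx) += uptake_by_type[t];
        if (s > 0) {
          sense_i[s] += field(fy, fx);
          sense_t[s] += tgfb(y, x);
          cx[s] += x; cy[s] += y;
          if (t == 4) { // T cell: secretion and PD-L1 contact
            if (!frozen_phase)
              src(fy, fx) += prod[s] / area[s];
            for (int k = 0; k < 8; ++k) {
              int xx = x + NBX[k], yy = y + NBY[k];
              if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
              int s2 = spins(yy, xx);
              if (s2 > 0 && cell_type[s2 - 1] >= 1 && cell_type[s2 - 1] <= 3) {
                pm_contact[s] += reg(s2 - 1, 8);
                pm_contact_w[s] += 1.0;
              }
            }
          }
        }
      }
    // normalize
    double f2 = (double)(fac * fac);
    for (int i = 0; i < FH * FW; ++i) upt[i] /= f2;
    for (int c = 1; c <= ncell; ++c)
      if (area[c] > 0) {
        sense_i[c] /= area[c]; sense_t[c] /= area[c];
        cx[c] /= area[c]; cy[c] /= area[c];
      }
  };

  // T cell production per MCS (instant relaxation to contact state)
  auto update_production = [&]() {
    for (int c = 1; c <= ncell; ++c) {
      if (cell_type[c - 1] != 4) { prod[c] = 0.0; continue; }
      double f = 1.0;
      if (mode == 1) {
        double pmc = (pm_contact_w[c] > 0) ? pm_contact[c] / pm_contact_w[c]
                                           : 0.0;
        f = hs(pmc, rp.pm0_i, rp.npm_i, rp.lpm_i);
      } else if (mode == 2) {
        f = hs(sense_t[c], rp.t0_i, rp.nt_i, rp.lt_i);
      }
      prod[c] = secretion_rate * f;
    }
  };

  auto record = [&](double tmin) {
    for (int c = 1; c <= ncell; ++c) {
      if (area[c] <= 0) continue;
      o_time.push_back(tmin); o_id.push_back(c);
      o_type.push_back(cell_type[c - 1]);
      o_x.push_back((cx[c] + 0.5) * site_um);
      o_y.push_back((cy[c] + 0.5) * site_um);
      o_area.push_back(area[c] * site_um * site_um);
      o_mz.push_back(reg(c - 1, 1)); o_pm.push_back(reg(c - 1, 8));
      o_si.push_back(sense_i[c] / MOLEC_PER_NM_SITE);
      o_st2.push_back(sense_t[c]);
      o_prod.push_back(prod[c]);
    }
  };

  double dt_stab = max_cfl * hf * hf / (4.0 * D);
  int nsub = std::max(1, (int)std::ceil(mcs_min / dt_stab));
  double dtf = mcs_min / nsub;
  NumericMatrix nxt(FH, FW);
  std::vector<double> decay(FH * FW, 1.0); // exp(-k dt), per MCS

  scan(true);
  update_production();
  record(0.0);

  for (int mcs = 1; mcs <= total_mcs; ++mcs) {
    bool frozen_phase = (mcs <= freeze_mcs);
    // --- Metropolis copy attempts
    int attempts = W * H;
    for (int a_ = 0; a_ < attempts; ++a_) {
      int uxx = rx(rng), uyy = ry(rng);
      int k = rn(rng);
      int vxx = uxx + NBX[k], vyy = uyy + NBY[k];
      if (vxx < 0 || vxx >= W || vyy < 0 || vyy >= H) continue;
      int ss = spins(uyy, uxx), st_ = spins(vyy, vxx);
      if (ss == st_) continue;
      int ts = (ss > 0) ? cell_type[ss - 1] : 0;
      int tt = (st_ > 0) ? cell_type[st_ - 1] : 0;
      if (frozen_phase && (ts == 4 || tt == 4)) continue; // frozen T cells
      if (st_ > 0 && area[st_] <= 1) continue;            // no annihilation
      if (tt == 4 && !stays_connected(spins, vxx, vyy, st_)) continue;
      double dadh, darea, dper, dact;
      local_dh(spins, cell_type, acts, area, perim, uxx, uyy, vxx, vyy,
               cp, dadh, darea, dper, dact);
      double dh = dadh + darea + dper + dact;
      if (dh > 0 && runif01(rng) >= std::exp(-dh / cp.temperature))
        continue;
      // accept: update caches
      int deg = 0, n_s = 0, n_t = 0;
      for (int kk = 0; kk < 8; ++kk) {
        int xx = vxx + NBX[kk], yy = vyy + NBY[kk];
        if (xx < 0 || xx >= W || yy < 0 || yy >= H) continue;
        ++deg;
        if (spins(yy, xx) == ss) ++n_s;
        if (spins(yy, xx) == st_) ++n_t;
      }
      spins(vyy, vxx) = ss;
      if (ss > 0) { area[ss] += 1; perim[ss] += deg - 2.0 * n_s; }
      if (st_ > 0) { area[st_] -= 1; perim[st_] += 2.0 * n_t - deg; }
      acts(vyy, vxx) = (ts == 4) ? cp.max_act : 0.0;
    }
    // --- Act decay
    for (int i = 0; i < H * W; ++i)
      if (acts[i] > 0) acts[i] -= 1.0;

    // --- occupancy scan, production, field substeps
    scan(frozen_phase);
    update_production();
    for (int i = 0; i < FH * FW; ++i)
      decay[i] = std::exp(-upt[i] * dtf);
    double a = D * dtf / (hf * hf), f2 = (double)(fac * fac);
    for (int s = 0; s < nsub; ++s) {
      for (int y = 0; y < FH; ++y)
        for (int x = 0; x < FW; ++x) {
          double c = field(y, x), lap = 0.0;
          if (x > 0) lap += field(y, x - 1) - c;
          if (x < FW - 1) lap += field(y, x + 1) - c;
          if (y > 0) lap += field(y - 1, x) - c;
          if (y < FH - 1) lap += field(y + 1, x) - c;
          double cd = c + a * lap;
          double dec = cd * decay[x * FH + y];
          total_consumed += (cd - dec) * f2;
          double add = src(y, x) * dtf / f2;
          total_secreted += add * f2;
          nxt(y, x) = dec + add;
        }
      std::swap(field, nxt);
    }

    // --- regulatory advance (accelerated ODE time)
    if (do_ode) {
      double hours = accel * mcs_min / 60.0;
      double ybuf[9];
      for (int c = 1; c <= ncell; ++c) {
        int t = cell_type[c - 1];
        if (t < 1 || t > 3) continue;
        double I = sense_i[c] / MOLEC_PER_NM_SITE;
        if (I < 0) I = 0;
        for (int j = 0; j < 9; ++j) ybuf[j] = reg(c - 1, j);
        reg_advance(ybuf, I, sense_t[c], rp,
                    reg_mult(c - 1, 0), reg_mult(c - 1, 1), hours, ode_dt);
        for (int j = 0; j < 9; ++j) reg(c - 1, j) = ybuf[j];
      }
    }

    // --- output interval: phenotype switching, recording
    if (mcs % out_every == 0) {
      for (int c = 1; c <= ncell; ++c) {
        int t = cell_type[c - 1];
        if (t < 1 || t > 3) continue;
        double mz = reg(c - 1, 1);
        int nt = t;
        if (t == 1 && mz >= 235) nt = 2;
        else if (t == 2 && mz >= 715) nt = 3;
        else if (t == 2 && mz <= 145) nt = 1;
        else if (t == 3 && mz <= 370) nt = 1; // no direct M -> H
        cell_type[c - 1] = nt;
      }
      record(mcs * mcs_min);
    }
  }

  DataFrame cells = DataFrame::create(
    _["time"] = o_time, _["id"] = o_id, _["type"] = o_type,
    _["x"] = o_x, _["y"] = o_y, _["area"] = o_area, _["mz"] = o_mz,
    _["pm"] = o_pm, _["sense_ifng"] = o_si, _["sense_tgfb"] = o_st2,
    _["production"] = o_prod);
  return List::create(
    _["cells"] = cells, _["spins"] = spins, _["cell_type"] = cell_type,
    _["reg"] = reg, _["acts"] = acts, _["field"] = field,
    _["secreted"] = total_secreted, _["consumed"] = total_consumed,
    _["field_substeps"] = nsub);
}
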