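// Toy binding-site engine: pairwise LJ + screened Coulomb potentials with
// Beutler-style soft-core lambda-coupling, analytic dH/dlambda, and a BAOAB
// Langevin integrator in a reflecting box.
//
// Units: kJ/mol, nm, ps, K, elementary charge, g/mol.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.008314462618;   // kJ mol^-1 K^-1
static const double FCOUL = 138.935458;    // kJ mol^-1 nm e^-2

struct Spec {
  double q, eps, sig, mass, solv;
};

struct Site {
  int n;
  std::vector<double> cx, cy, cz, q, eps, sig;
  double dielectric, cage_k, box_h, solv_scale;
  double sc[3]; // site / cage center
};

struct SCParams {
  double alpha, sigma_sc, power;
};

// mode codes
enum Mode { PLAIN = 0, RELATIVE = 1, DEC_COUL = 2, DEC_LJ = 3, RESTRAINT_ON = 4 };

struct Alch {
  int mode;
  double lam;
  Site siteA, siteB;
  Spec spA, spB;
  SCParams sc;
  bool has_restraint;
  double rk, rc[3];
};

static Spec parse_spec(const List& s) {
  Spec sp;
  sp.q = as<double>(s["charge"]);
  sp.eps = as<double>(s["lj_epsilon"]);
  sp.sig = as<double>(s["lj_sigma"]);
  sp.mass = as<double>(s["mass"]);
  sp.solv = as<double>(s["solvation"]);
  return sp;
}

static Site parse_site(const List& s) {
  Site st;
  NumericMatrix pos = as<NumericMatrix>(s["center_positions"]);
  st.n = pos.nrow();
  st.cx.resize(st.n); st.cy.resize(st.n); st.cz.resize(st.n);
  for (int i = 0; i < st.n; ++i) {
    st.cx[i] = pos(i, 0); st.cy[i] = pos(i, 1); st.cz[i] = pos(i, 2);
  }
  NumericVector q = as<NumericVector>(s["center_charges"]);
  NumericVector eps = as<NumericVector>(s["center_eps"]);
  NumericVector sig = as<NumericVector>(s["center_sigma"]);
  st.q.assign(q.begin(), q.end());
  st.eps.assign(eps.begin(), eps.end());
  st.sig.assign(sig.begin(), sig.end());
  st.dielectric = as<double>(s["dielectric"]);
  st.cage_k = as<double>(s["cage_k"]);
  st.box_h = as<double>(s["box_halfwidth"]);
  st.solv_scale = as<double>(s["solvation_scale"]);
  NumericVector sc = as<NumericVector>(s["site_center"]);
  st.sc[0] = sc[0]; st.sc[1] = sc[1]; st.sc[2] = sc[2];
  return st;
}

static Alch parse_alch(const List& a) {
  Alch al;
  al.mode = as<int>(a["mode_code"]);
  al.lam = as<double>(a["lam"]);
  List stA = a["state_A"];
  al.siteA = parse_site(as<List>(stA["site"]));
  al.spA = parse_spec(as<List>(stA["species"]));
  if (a.containsElementNamed("state_B") && !Rf_isNull(a["state_B"])) {
    List stB = a["state_B"];
    al.siteB = parse_site(as<List>(stB["site"]));
    al.spB = parse_spec(as<List>(stB["species"]));
  } else {
    al.siteB = al.siteA;
    al.spB = al.spA;
  }
  List sc = a["softcore"];
  al.sc.alpha = as<double>(sc["alpha"]);
  al.sc.sigma_sc = as<double>(sc["sigma_sc"]);
  al.sc.power = as<double>(sc["power"]);
  al.has_restraint = false;
  if (a.containsElementNamed("restraint") && !Rf_isNull(a["restraint"])) {
    List r = a["restraint"];
    al.has_restraint = true;
    al.rk = as<double>(r["k"]);
    NumericVector c = as<NumericVector>(r["center"]);
    al.rc[0] = c[0]; al.rc[1] = c[1]; al.rc[2] = c[2];
  }
  return al;
}

// Accumulator for one (site, species) pair-interaction evaluation at soft-core
// weight lam_off.  Energies are split so decoupling legs can scale the parts
// independently; d_dlam is the derivative of (e_lj + e_coul) w.r.t. lam_off.
struct PairEval {
  double e_lj, e_coul, d_dlam;
  double f_lj[3], f_coul[3]; // -(gradient) of the respective raw terms
};

static void eval_pairs(const Site& st, const Spec& sp, const double* x,
                       double lam_off, const SCParams& sc, PairEval& out,
                       bool lj_softcore, bool coul_softcore) {
  out.e_lj = 0.0; out.e_coul = 0.0; out.d_dlam = 0.0;
  for (int k = 0; k < 3; ++k) { out.f_lj[k] = 0.0; out.f_coul[k] = 0.0; }
  double sig6sc = std::pow(sc.sigma_sc, 6.0);
  double A = sc.alpha * sig6sc * std::pow(lam_off, sc.power);
  // d(A)/d(lam_off); pow(0,0) == 1 handles the power-1 endpoint
  double dA = sc.alpha * sig6sc * sc.power * std::pow(lam_off, sc.power - 1.0);
  for (int i = 0; i < st.n; ++i) {
    double dx = x[0] - st.cx[i], dy = x[1] - st.cy[i], dz = x[2] - st.cz[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    double r6 = r2 * r2 * r2;

    double eps_ij = std::sqrt(sp.eps * st.eps[i]);
    double sig_ij = 0.5 * (sp.sig + st.sig[i]);
    double qq = sp.q * st.q[i];

    // LJ on its (possibly) soft-cored distance
    if (eps_ij > 0.0) {
      double d6 = (lj_softcore ? A : 0.0) + r6;
      if (d6 <= 0.0) { out.e_lj = R_PosInf; continue; }
      double d = std::pow(d6, 1.0 / 6.0);
      double sig6 = std::pow(sig_ij, 6.0);
      double s6 = sig6 / d6;
      double ulj = 4.0 * eps_ij * (s6 * s6 - s6);
      out.e_lj += ulj;
      // du/dd
      double du_dd = 4.0 * eps_ij * (-12.0 * s6 * s6 + 6.0 * s6) / d;
      // force contribution: -du/dd * dd/dr * rhat ; dd/dr*rhat = r^4 (x-c)/d^5
      double d5 = d6 / d;
      double pref = -du_dd * (r2 * r2) / d5;
      out.f_lj[0] += pref * dx; out.f_lj[1] += pref * dy; out.f_lj[2] += pref * dz;
      if (lj_softcore) out.d_dlam += du_dd * dA / (6.0 * d5);
    }
    // Coulomb
    if (qq != 0.0) {
      double d6 = (coul_softcore ? A : 0.0) + r6;
      if (d6 <= 0.0) { out.e_coul = R_PosInf; continue; }
      double d = std::pow(d6, 1.0 / 6.0);
      double uc = FCOUL * qq / (st.dielectric * d);
      out.e_coul += uc;
      double du_dd = -FCOUL * qq / (st.dielectric * d * d);
      double d5 = d6 / d;
      double pref = -du_dd * (r2 * r2) / d5;
      out.f_coul[0] += pref * dx; out.f_coul[1] += pref * dy; out.f_coul[2] += pref * dz;
      if (coul_softcore) out.d_dlam += du_dd * dA / (6.0 * d5);
    }
  }
}

static double cage_energy(const Site& st, const double* x, double* f) {
  double dx = x[0] - st.sc[0], dy = x[1] - st.sc[1], dz = x[2] - st.sc[2];
  double e = 0.5 * st.cage_k * (dx * dx + dy * dy + dz * dz);
  f[0] = -st.cage_k * dx; f[1] = -st.cage_k * dy; f[2] = -st.cage_k * dz;
  return e;
}

// Full evaluation: potential, force, dH/dlam at x.
static double eval_alch(const Alch& al, const double* x, double* force,
                        double& dhdl) {
  double V = 0.0;
  dhdl = 0.0;
  force[0] = force[1] = force[2] = 0.0;
  double lam = al.lam;
  PairEval pa, pb;
  double fc[3];

  switch (al.mode) {
  case PLAIN: {
    eval_pairs(al.siteA, al.spA, x, 0.0, al.sc, pa, false, false);
    double ec = cage_energy(al.siteA, x, fc);
    V = pa.e_lj + pa.e_coul + ec + al.siteA.solv_scale * al.spA.solv;
    for (int k = 0; k < 3; ++k)
      force[k] = pa.f_lj[k] + pa.f_coul[k] + fc[k];
    break;
  }
  case RELATIVE: {
    // A fades out with weight (1-lam), soft-core weight lam;
    // B fades in with weight lam, soft-core weight (1-lam).
    eval_pairs(al.siteA, al.spA, x, lam, al.sc, pa, true, true);
    eval_pairs(al.siteB, al.spB, x, 1.0 - lam, al.sc, pb, true, true);
    double fca[3], fcb[3];
    double eca = cage_energy(al.siteA, x, fca);
    double ecb = cage_energy(al.siteB, x, fcb);
    double EA = pa.e_lj + pa.e_coul + eca + al.siteA.solv_scale * al.spA.solv;
    double EB = pb.e_lj + pb.e_coul + ecb + al.siteB.solv_scale * al.spB.solv;
    V = (1.0 - lam) * EA + lam * EB;
    for (int k = 0; k < 3; ++k)
      force[k] = (1.0 - lam) * (pa.f_lj[k] + pa.f_coul[k] + fca[k]) +
                 lam * (pb.f_lj[k] + pb.f_coul[k] + fcb[k]);
    dhdl = -EA + EB + (1.0 - lam) * pa.d_dlam - lam * pb.d_dlam;
    break;
  }
  case DEC_COUL: {
    // charges (and solvation) scale with (1-lam); LJ stays full and unsoftened
    eval_pairs(al.siteA, al.spA, x, lam, al.sc, pa, false, true);
    double ec = cage_energy(al.siteA, x, fc);
    double solv = al.siteA.solv_scale * al.spA.solv;
    V = pa.e_lj + (1.0 - lam) * (pa.e_coul + solv) + ec;
    for (int k = 0; k < 3; ++k)
      force[k] = pa.f_lj[k] + (1.0 - lam) * pa.f_coul[k] + fc[k];
    dhdl = -(pa.e_coul + solv) + (1.0 - lam) * pa.d_dlam;
    break;
  }
  case DEC_LJ: {
    // charges already off; LJ and cage scale with (1-lam), LJ soft-cored
    eval_pairs(al.siteA, al.spA, x, lam, al.sc, pa, true, false);
    double ec = cage_energy(al.siteA, x, fc);
    V = (1.0 - lam) * (pa.e_lj + ec);
    for (int k = 0; k < 3; ++k)
      force[k] = (1.0 - lam) * (pa.f_lj[k] + fc[k]);
    dhdl = -(pa.e_lj + ec) + (1.0 - lam) * pa.d_dlam;
    break;
  }
  case RESTRAINT_ON: {
    eval_pairs(al.siteA, al.spA, x, 0.0, al.sc, pa, false, false);
    double ec = cage_energy(al.siteA, x, fc);
    V = pa.e_lj + pa.e_coul + ec + al.siteA.solv_scale * al.spA.solv;
    for (int k = 0; k < 3; ++k)
      force[k] = pa.f_lj[k] + pa.f_coul[k] + fc[k];
    if (al.has_restraint) {
      double dx = x[0] - al.rc[0], dy = x[1] - al.rc[1], dz = x[2] - al.rc[2];
      double ur = 0.5 * al.rk * (dx * dx + dy * dy + dz * dz);
      V += lam * ur;
      dhdl = ur;
      force[0] -= lam * al.rk * dx;
      force[1] -= lam * al.rk * dy;
      force[2] -= lam * al.rk * dz;
    }
    return V; // restraint already applied (lambda-scaled)
  }
  }
  // constant (lambda-independent) restraint, if any
  if (al.has_restraint) {
    double dx = x[0] - al.rc[0], dy = x[1] - al.rc[1], dz = x[2] - al.rc[2];
    V += 0.5 * al.rk * (dx * dx + dy * dy + dz * dz);
    force[0] -= al.rk * dx; force[1] -= al.rk * dy; force[2] -= al.rk * dz;
  }
  return V;
}

// [[Rcpp::export(name = ".cpp_alch_eval")]]
List cpp_alch_eval(List alch, NumericVector x) {
  Alch al = parse_alch(alch);
  double xx[3] = { x[0], x[1], x[2] };
  double f[3], dhdl;
  double V = eval_alch(al, xx, f, dhdl);
  return List::create(_["energy"] = V,
                      _["dhdl"] = dhdl,
                      _["force"] = NumericVector::create(f[0], f[1], f[2]));
}

static inline void reflect(double& x, double& v, double h) {
  // reflecting wall at +-h; loop guards pathological overshoot
  int guard = 0;
  while ((x > h || x < -h) && guard++ < 64) {
    if (x > h) { x = 2.0 * h - x; v = -v; }
    else if (x < -h) { x = -2.0 * h - x; v = -v; }
  }
  if (x > h) x = h;
  if (x < -h) x = -h;
}

// BAOAB Langevin integrator.  Records positions (and dH/dlambda) every
// `stride` steps, starting at step `stride`.  Uses R's RNG.
// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List alch, NumericVector x0, int n_steps, double dt,
                  double temperature, double friction, int stride,
                  bool record_dhdl) {
  Alch al = parse_alch(alch);
  double m = al.spA.mass;
  double kT = KB * temperature;
  double h = al.siteA.box_h;
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * kT / m);

  double x[3] = { x0[0], x0[1], x0[2] };
  double v[3], f[3], dhdl;
  double sdv = std::sqrt(kT / m);
  for (int k = 0; k < 3; ++k) v[k] = sdv * norm_rand();

  eval_alch(al, x, f, dhdl);
  if (!R_finite(f[0]) || !R_finite(f[1]) || !R_finite(f[2]))
    stop("force overflow at the initial configuration (singular core?)");

  int n_out = n_steps / stride;
  NumericMatrix pos(n_out, 3);
  NumericVector dvals(record_dhdl ? n_out : 0);
  NumericVector times(n_out);

  int iout = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int k = 0; k < 3; ++k) v[k] += 0.5 * dt * f[k] / m;       // B
    for (int k = 0; k < 3; ++k) {                                   // A
      x[k] += 0.5 * dt * v[k];
      reflect(x[k], v[k], h);
    }
    for (int k = 0; k < 3; ++k) v[k] = c1 * v[k] + c2 * norm_rand(); // O
    for (int k = 0; k < 3; ++k) {                                   // A
      x[k] += 0.5 * dt * v[k];
      reflect(x[k], v[k], h);
    }
    eval_alch(al, x, f, dhdl);
    if (!R_finite(f[0]) || !R_finite(f[1]) || !R_finite(f[2]))
      stop("force overflow at step %d (particle inside a singular core)", step);
    for (int k = 0; k < 3; ++k) v[k] += 0.5 * dt * f[k] / m;       // B

    if (step % stride == 0) {
      times[iout] = step * dt;
      pos(iout, 0) = x[0]; pos(iout, 1) = x[1]; pos(iout, 2) = x[2];
      if (record_dhdl) dvals[iout] = dhdl;
      ++iout;
    }
  }
  List out = List::create(_["times"] = times, _["positions"] = pos,
                          _["final"] = NumericVector::create(x[0], x[1], x[2]));
  if (record_dhdl) out["dhdl"] = dvals;
  return out;
}
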