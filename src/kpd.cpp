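// Core numerics: transit-compartment myelosuppression model driven by K-PD
// virtual drug compartments, an embedded Dormand-Prince 5(4) integrator with
// hard restarts at dosing/indicator discontinuities, and the per-subject
// Laplace machinery (inner Newton over random effects + log-determinant
// correction) used by the population fit.
//
// The virtual drug amounts obey dA/dt = -KDE*A with bolus superposition, so
// they are propagated analytically per segment; only the PD system
// (Prol, Transit_1..n, Circ) is integrated numerically.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int MAXSTATE = 5;  // prol + up to 3 transits + circ

struct ModelSpec {
  int n_transit;    // 1..3
  int drug_model;   // 0 response_surface, 1 log_linear
  int gcsf_model;   // 0 none, 1 constant_split, 2 constant, 3 linear, 4 emax
  double rtol, atol;
  double circ_floor_frac;
  int max_steps;
  // fixed-step mode: likelihood evaluations during estimation use a
  // fixed-step integrator so the objective is smooth in the parameters
  // (adaptive step acceptance introduces non-smooth noise that defeats
  // finite-difference Newton steps)
  int fixed_step;
  double h_base, h_gcsf;
};

struct IndivPars {
  double circ0, mtt, gamma, ir50_p, ir50_c, kde_p, kde_c;
  double theta_ktr, theta_prol, u50, p_steep;
  double scale1, scale2, scale3, kde_g, ir50_g;
  double ktr0;  // (n_transit + 1) / mtt
};

struct SegmentCtx {
  double t0;            // segment start (absolute days)
  double ap0, ac0, ag0; // virtual amounts at t0 (post-bolus)
  int gcsf_on;          // indicator value on the segment
};

static ModelSpec spec_from_list(const List& sl) {
  ModelSpec s;
  s.n_transit = as<int>(sl["n_transit"]);
  s.drug_model = as<int>(sl["drug_model"]);
  s.gcsf_model = as<int>(sl["gcsf_model"]);
  s.rtol = as<double>(sl["rtol"]);
  s.atol = as<double>(sl["atol"]);
  s.circ_floor_frac = sl.containsElementNamed("circ_floor_frac")
      ? as<double>(sl["circ_floor_frac"]) : 1e-6;
  s.max_steps = sl.containsElementNamed("max_steps")
      ? as<int>(sl["max_steps"]) : 200000;
  s.fixed_step = sl.containsElementNamed("fixed_step")
      ? as<int>(sl["fixed_step"]) : 0;
  s.h_base = sl.containsElementNamed("h_base") ? as<double>(sl["h_base"])
                                               : 0.5;
  s.h_gcsf = sl.containsElementNamed("h_gcsf") ? as<double>(sl["h_gcsf"])
                                               : 0.125;
  if (s.n_transit < 1 || s.n_transit > 3) stop("n_transit must be 1, 2 or 3");
  return s;
}

static IndivPars pars_from_list(const List& pl, const ModelSpec& spec) {
  IndivPars p;
  p.circ0 = as<double>(pl["circ0"]);
  p.mtt = as<double>(pl["mtt"]);
  p.gamma = as<double>(pl["gamma"]);
  p.ir50_p = as<double>(pl["ir50_p"]);
  p.ir50_c = as<double>(pl["ir50_c"]);
  p.kde_p = as<double>(pl["kde_p"]);
  p.kde_c = as<double>(pl["kde_c"]);
  p.theta_ktr = as<double>(pl["theta_ktr"]);
  p.theta_prol = as<double>(pl["theta_prol"]);
  p.u50 = as<double>(pl["u50"]);
  p.p_steep = as<double>(pl["p_steep"]);
  p.scale1 = as<double>(pl["scale1"]);
  p.scale2 = as<double>(pl["scale2"]);
  p.scale3 = as<double>(pl["scale3"]);
  p.kde_g = as<double>(pl["kde_g"]);
  p.ir50_g = as<double>(pl["ir50_g"]);
  p.ktr0 = (spec.n_transit + 1.0) / p.mtt;
  return p;
}

// PD right-hand side at absolute time t within a segment.
static inline void rhs(double t, const double* y, double* dy,
                       const IndivPars& p, const ModelSpec& spec,
                       const SegmentCtx& seg) {
  const double dt = t - seg.t0;
  const double vir_p = p.kde_p * seg.ap0 * std::exp(-p.kde_p * dt);
  const double vir_c = p.kde_c * seg.ac0 * std::exp(-p.kde_c * dt);

  double ed = 1.0;
  if (spec.drug_model == 0) {
    const double u = vir_p / p.ir50_p + vir_c / p.ir50_c;
    if (u > 0.0) {
      const double x = std::pow(u / p.u50, p.p_steep);
      ed = 1.0 / (1.0 + x);
    }
  } else {
    ed = std::exp(-p.scale1 * vir_p - p.scale2 * vir_c);
  }

  double eg_ktr = 1.0, eg_kprol = 1.0;
  switch (spec.gcsf_model) {
    case 0: break;
    case 1:  // constant, Kprol effect split multiplicatively from Ktr effect
      eg_ktr = 1.0 + p.theta_ktr * seg.gcsf_on;
      eg_kprol = eg_ktr * (1.0 + p.theta_prol * seg.gcsf_on);
      break;
    case 2:  // constant, independent multipliers
      eg_ktr = 1.0 + p.theta_ktr * seg.gcsf_on;
      eg_kprol = 1.0 + p.theta_prol * seg.gcsf_on;
      break;
    case 3: {  // linear in the G-CSF virtual infusion rate
      const double vir_g = p.kde_g * seg.ag0 * std::exp(-p.kde_g * dt);
      eg_ktr = eg_kprol = 1.0 + p.scale3 * vir_g;
      break;
    }
    case 4: {  // Emax in the G-CSF virtual infusion rate
      const double vir_g = p.kde_g * seg.ag0 * std::exp(-p.kde_g * dt);
      eg_ktr = eg_kprol = 1.0 + vir_g / (vir_g + p.ir50_g);
      break;
    }
  }

  const double ktr = p.ktr0 * eg_ktr;
  const double kprol = p.ktr0 * eg_kprol;
  const double kcirc = p.ktr0;
  const int n = spec.n_transit;
  const double circ = y[n + 1];
  double fb = 1.0;
  if (p.gamma != 0.0) {
    const double cfl = std::max(circ, spec.circ_floor_frac * p.circ0);
    fb = std::pow(p.circ0 / cfl, p.gamma);
  }

  dy[0] = kprol * y[0] * ed * fb - ktr * y[0];
  for (int i = 1; i <= n; ++i) dy[i] = ktr * (y[i - 1] - y[i]);
  dy[n + 1] = ktr * y[n] - kcirc * circ;
}

// One Dormand-Prince 5(4) step from (t, y) with size h; fills y5 and k7
// (= f(t+h, y5), FSAL) and returns the scaled error estimate.
static inline double dp_step(double t, const double* y, double h,
                             const double* k1, double* y5, double* k7,
                             const IndivPars& p, const ModelSpec& spec,
                             const SegmentCtx& seg) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  const int dim = spec.n_transit + 2;
  double k2[MAXSTATE], k3[MAXSTATE], k4[MAXSTATE], k5[MAXSTATE],
      k6[MAXSTATE], ytmp[MAXSTATE];

  for (int i = 0; i < dim; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
  rhs(t + c2 * h, ytmp, k2, p, spec, seg);
  for (int i = 0; i < dim; ++i)
    ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
  rhs(t + c3 * h, ytmp, k3, p, spec, seg);
  for (int i = 0; i < dim; ++i)
    ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
  rhs(t + c4 * h, ytmp, k4, p, spec, seg);
  for (int i = 0; i < dim; ++i)
    ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
  rhs(t + c5 * h, ytmp, k5, p, spec, seg);
  for (int i = 0; i < dim; ++i)
    ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
  rhs(t + h, ytmp, k6, p, spec, seg);
  for (int i = 0; i < dim; ++i)
    y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                        b6 * k6[i]);
  rhs(t + h, y5, k7, p, spec, seg);

  double err = 0.0;
  for (int i = 0; i < dim; ++i) {
    const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                           e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
    const double sc = spec.atol +
        spec.rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
    const double r = ei / sc;
    err += r * r;
  }
  return std::sqrt(err / dim);
}

// Adaptive Dormand-Prince over one segment [t0, t1]; false on failure.
static bool integrate_segment(double t0, double t1, double* y,
                              const IndivPars& p, const ModelSpec& spec,
                              const SegmentCtx& seg, int* steps_used,
                              double* h_carry) {
  const int dim = spec.n_transit + 2;
  if (t1 <= t0) return true;

  if (spec.fixed_step) {
    // equidistant steps per segment: the solution is then a smooth function
    // of the model parameters (no acceptance decisions)
    const double h0 = seg.gcsf_on ? spec.h_gcsf : spec.h_base;
    const int n = (int)std::ceil((t1 - t0) / h0 - 1e-9);
    const double h = (t1 - t0) / n;
    double k1[MAXSTATE], k7[MAXSTATE], y5[MAXSTATE];
    rhs(t0, y, k1, p, spec, seg);
    for (int sstep = 0; sstep < n; ++sstep) {
      if (++(*steps_used) > spec.max_steps) return false;
      const double t = t0 + sstep * h;
      dp_step(t, y, h, k1, y5, k7, p, spec, seg);
      for (int i = 0; i < dim; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }
      if (!std::isfinite(y[0]) || !std::isfinite(y[dim - 1])) return false;
    }
    return true;
  }

  double t = t0;
  double h = std::min(t1 - t0, *h_carry);
  double k1[MAXSTATE], k7[MAXSTATE], y5[MAXSTATE];
  rhs(t, y, k1, p, spec, seg);

  while (t < t1 - 1e-12) {
    if (++(*steps_used) > spec.max_steps) return false;
    if (t + h > t1) h = t1 - t;
    const double err = dp_step(t, y, h, k1, y5, k7, p, spec, seg);
    if (!std::isfinite(err)) return false;

    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < dim; ++i) { y[i] = y5[i]; k1[i] = k7[i]; }  // FSAL
    }
    const double fac = (err <= 1e-30)
        ? 5.0 : std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
    h *= fac;
    if (h < 1e-12) return false;
  }
  *h_carry = std::max(h, 1e-6);
  return true;
}

// Full trajectory solve. Dose rows: time, amount, drug code
// (1 paclitaxel, 2 cisplatin, 3 gcsf). G-CSF doses both open an indicator
// window [t, t + window) (constant models) and feed the virtual compartment
// (linear/emax models). Returns state at out_times (rows).
static bool solve_traj(const IndivPars& p, const ModelSpec& spec,
                       const arma::mat& doses, double gcsf_window,
                       const arma::vec& out_times, arma::mat& out_state) {
  const int dim = spec.n_transit + 2;
  const int n_out = out_times.n_elem;
  out_state.set_size(n_out, dim);

  // Breakpoints: 0, dose times, indicator window edges, output times.
  std::vector<double> bp;
  bp.push_back(0.0);
  for (arma::uword i = 0; i < doses.n_rows; ++i) {
    bp.push_back(doses(i, 0));
    if (doses(i, 2) == 3.0 &&
        (spec.gcsf_model == 1 || spec.gcsf_model == 2)) {
      bp.push_back(doses(i, 0) + gcsf_window);
    }
  }
  for (int i = 0; i < n_out; ++i) bp.push_back(out_times[i]);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double a, double b) { return std::fabs(a - b) < 1e-9; }),
           bp.end());

  double y[MAXSTATE];
  for (int i = 0; i < dim; ++i) y[i] = p.circ0;  // steady-state start

  SegmentCtx seg;
  seg.t0 = bp[0];
  seg.ap0 = seg.ac0 = seg.ag0 = 0.0;
  int steps_used = 0;
  int next_out = 0;
  double h_carry = 0.1;

  auto record = [&](double tq) {
    while (next_out < n_out && std::fabs(out_times[next_out] - tq) < 1e-9) {
      for (int i = 0; i < dim; ++i) out_state(next_out, i) = y[i];
      ++next_out;
    }
  };

  auto gcsf_on_at = [&](double tq) -> int {
    if (spec.gcsf_model != 1 && spec.gcsf_model != 2) return 0;
    for (arma::uword i = 0; i < doses.n_rows; ++i) {
      if (doses(i, 2) == 3.0 && doses(i, 0) <= tq + 1e-9 &&
          tq < doses(i, 0) + gcsf_window - 1e-9) return 1;
    }
    return 0;
  };

  // Apply boluses at t = bp[0] (usually 0).
  for (arma::uword i = 0; i < doses.n_rows; ++i) {
    if (std::fabs(doses(i, 0) - seg.t0) < 1e-9) {
      if (doses(i, 2) == 1.0) seg.ap0 += doses(i, 1);
      else if (doses(i, 2) == 2.0) seg.ac0 += doses(i, 1);
      else if (doses(i, 2) == 3.0) seg.ag0 += doses(i, 1);
    }
  }
  seg.gcsf_on = gcsf_on_at(seg.t0);
  record(seg.t0);

  for (size_t s = 0; s + 1 < bp.size(); ++s) {
    const double t1 = bp[s + 1];
    if (!integrate_segment(seg.t0, t1, y, p, spec, seg, &steps_used,
                           &h_carry))
      return false;
    // advance analytic amounts to t1, then apply boluses falling at t1
    const double dt = t1 - seg.t0;
    seg.ap0 *= std::exp(-p.kde_p * dt);
    seg.ac0 *= std::exp(-p.kde_c * dt);
    seg.ag0 *= std::exp(-p.kde_g * dt);
    record(t1);  // observations at a dose time see the continuous Circ
    for (arma::uword i = 0; i < doses.n_rows; ++i) {
      if (std::fabs(doses(i, 0) - t1) < 1e-9) {
        if (doses(i, 2) == 1.0) seg.ap0 += doses(i, 1);
        else if (doses(i, 2) == 2.0) seg.ac0 += doses(i, 1);
        else if (doses(i, 2) == 3.0) seg.ag0 += doses(i, 1);
      }
    }
    seg.t0 = t1;
    seg.gcsf_on = gcsf_on_at(t1);
  }
  return next_out == n_out;
}

// [[Rcpp::export]]
arma::mat cpp_simulate(const arma::vec& out_times, const arma::mat& doses,
                       double gcsf_window, const List& pars, const List& spec) {
  ModelSpec s = spec_from_list(spec);
  IndivPars p = pars_from_list(pars, s);
  arma::mat out;
  if (!solve_traj(p, s, doses, gcsf_window, out_times, out))
    stop("ODE integration failed (step limit or non-finite state)");
  return out;
}

// ---------------------------------------------------------------------------
// Likelihood machinery
// ---------------------------------------------------------------------------

struct SubjectData {
  arma::mat doses;      // time, amount, drug code
  double gcsf_window;
  arma::vec obs_t, obs_y;
  arma::vec tv;         // circ0, mtt, gamma, ir50_p, ir50_c, kde_p, kde_c
};

static SubjectData subject_from_list(const List& sl) {
  SubjectData d;
  d.doses = as<arma::mat>(sl["doses"]);
  d.gcsf_window = as<double>(sl["gcsf_window"]);
  d.obs_t = as<arma::vec>(sl["obs_t"]);
  d.obs_y = as<arma::vec>(sl["obs_y"]);
  d.tv = as<arma::vec>(sl["tv"]);
  return d;
}

// etas multiply (circ0, mtt, ir50 shared, kde_p, kde_c) exponentially
static IndivPars indiv_pars(const SubjectData& d, const List& common,
                            const ModelSpec& spec, const arma::vec& eta) {
  IndivPars p;
  p.circ0 = d.tv[0] * std::exp(eta[0]);
  p.mtt = d.tv[1] * std::exp(eta[1]);
  p.gamma = d.tv[2];
  p.ir50_p = d.tv[3] * std::exp(eta[2]);
  p.ir50_c = d.tv[4] * std::exp(eta[2]);
  p.kde_p = d.tv[5] * std::exp(eta[3]);
  p.kde_c = d.tv[6] * std::exp(eta[4]);
  p.theta_ktr = as<double>(common["theta_ktr"]);
  p.theta_prol = as<double>(common["theta_prol"]);
  p.u50 = as<double>(common["u50"]);
  p.p_steep = as<double>(common["p_steep"]);
  p.scale1 = as<double>(common["scale1"]);
  p.scale2 = as<double>(common["scale2"]);
  p.scale3 = as<double>(common["scale3"]);
  p.kde_g = as<double>(common["kde_g"]);
  p.ir50_g = as<double>(common["ir50_g"]);
  p.ktr0 = (spec.n_transit + 1.0) / p.mtt;
  return p;
}

static const double LOG2PI = 1.8378770664093454836;
static const double BIG = 1e10;

// Joint -2 log-likelihood of (observations, etas):
//   sum_j [ log(2 pi v_j) + (y_j - f_j)^2 / v_j ] + sum_active [ eta^2/w2 +
//   log(2 pi w2) ]   with v_j = f_j^2 sp^2 + sa^2.
static double joint_neg2ll(const SubjectData& d, const List& common,
                           const ModelSpec& spec, const arma::vec& omega2,
                           double sp, double sa, const arma::vec& eta) {
  IndivPars p = indiv_pars(d, common, spec, eta);
  double out = 0.0;
  if (d.obs_t.n_elem > 0) {
    arma::mat st;
    if (!solve_traj(p, spec, d.doses, d.gcsf_window, d.obs_t, st)) return BIG;
    const int circ_col = spec.n_transit + 1;
    for (arma::uword j = 0; j < d.obs_t.n_elem; ++j) {
      const double f = st(j, circ_col);
      if (!std::isfinite(f)) return BIG;
      double v = f * f * sp * sp + sa * sa;
      if (v < 1e-12) v = 1e-12;
      const double r = d.obs_y[j] - f;
      out += std::log(v) + LOG2PI + r * r / v;
    }
  }
  for (arma::uword k = 0; k < omega2.n_elem; ++k) {
    if (omega2[k] > 0.0)
      out += eta[k] * eta[k] / omega2[k] + std::log(omega2[k]) + LOG2PI;
  }
  return std::isfinite(out) ? out : BIG;
}

// [[Rcpp::export]]
double cpp_subject_neg2ll(const List& subject, const List& common,
                          const List& spec, const arma::vec& omega2,
                          double sigma_prop, double sigma_add,
                          const arma::vec& eta) {
  ModelSpec s = spec_from_list(spec);
  SubjectData d = subject_from_list(subject);
  return joint_neg2ll(d, common, s, omega2, sigma_prop, sigma_add, eta);
}

// Finite-difference gradient and Hessian of g over the active etas.
// Uses central differences on the diagonal and forward cross terms:
// 1 + 2d + d(d-1)/2 evaluations.
static void fd_grad_hess(const SubjectData& d, const List& common,
                         const ModelSpec& spec, const arma::vec& omega2,
                         double sp, double sa, const arma::vec& eta,
                         const std::vector<int>& act, double h, double* g0out,
                         arma::vec& grad, arma::mat& hess) {
  const int da = (int)act.size();
  const double g0 = joint_neg2ll(d, common, spec, omega2, sp, sa, eta);
  *g0out = g0;
  arma::vec gp(da), gm(da);
  arma::vec e = eta;
  for (int i = 0; i < da; ++i) {
    e[act[i]] = eta[act[i]] + h;
    gp[i] = joint_neg2ll(d, common, spec, omega2, sp, sa, e);
    e[act[i]] = eta[act[i]] - h;
    gm[i] = joint_neg2ll(d, common, spec, omega2, sp, sa, e);
    e[act[i]] = eta[act[i]];
    grad[i] = (gp[i] - gm[i]) / (2.0 * h);
    hess(i, i) = (gp[i] - 2.0 * g0 + gm[i]) / (h * h);
  }
  for (int i = 0; i < da; ++i) {
    for (int j = i + 1; j < da; ++j) {
      e[act[i]] = eta[act[i]] + h;
      e[act[j]] = eta[act[j]] + h;
      const double gij = joint_neg2ll(d, common, spec, omega2, sp, sa, e);
      e[act[i]] = eta[act[i]];
      e[act[j]] = eta[act[j]];
      hess(i, j) = hess(j, i) = (gij - gp[i] - gp[j] + g0) / (h * h);
    }
  }
}

// Laplace contribution of one subject: minimise g over active etas by damped
// Newton from eta_start, then ofv_i = g(mode) + log det H - d log(4 pi).
// With quad_axes > 0 the Gaussian approximation is refined by a 3-node
// Gauss-Hermite product rule over the trailing quad_axes whitened axes
// (the most nonlinear random effects are ordered last), which corrects the
// Laplace value for skew/kurtosis in those directions.
static List laplace_subject(const SubjectData& d, const List& common,
                            const ModelSpec& spec, const arma::vec& omega2,
                            double sp, double sa, arma::vec eta,
                            int maxit, double gtol, int quad_axes) {
  std::vector<int> act;
  for (arma::uword k = 0; k < omega2.n_elem; ++k)
    if (omega2[k] > 0.0) act.push_back((int)k);
  const int da = (int)act.size();
  for (arma::uword k = 0; k < eta.n_elem; ++k) {
    bool is_act = false;
    for (int a : act) if (a == (int)k) { is_act = true; break; }
    if (!is_act) eta[k] = 0.0;
  }

  if (da == 0) {
    const double g0 = joint_neg2ll(d, common, spec, omega2, sp, sa, eta);
    return List::create(_["ofv"] = g0, _["eta"] = eta, _["g"] = g0,
                        _["flag"] = (g0 >= BIG) ? 1 : 0);
  }

  const double h = 1e-4;
  const double ptol = 1e-4;  // predicted-decrease convergence threshold
  arma::vec grad(da);
  arma::mat hess(da, da);
  double g0 = 0.0;    // g at the point where the last FD block was taken
  double g_cur = 0.0; // g at the current eta
  int flag = 0;

  for (int it = 0; it < maxit; ++it) {
    fd_grad_hess(d, common, spec, omega2, sp, sa, eta, act, h, &g0, grad,
                 hess);
    g_cur = g0;
    if (g0 >= BIG) { flag = 1; break; }
    if (arma::norm(grad, "inf") < gtol) break;

    arma::mat hreg = hess;
    double ridge = 0.0;
    arma::vec step;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat L;
      if (arma::chol(L, hreg, "lower")) {
        step = -arma::solve(arma::trimatu(L.t()),
                            arma::solve(arma::trimatl(L), grad));
        break;
      }
      ridge = (ridge == 0.0) ? 1e-4 * std::max(1.0, arma::trace(hess) / da)
                             : ridge * 10.0;
      hreg = hess + ridge * arma::eye(da, da);
    }
    if (step.n_elem == 0) { flag = 2; break; }
    const double pred_dec = -0.5 * arma::dot(grad, step);

    double alpha = 1.0;
    bool ok = false;
    arma::vec etry = eta;
    for (int ls = 0; ls < 8; ++ls) {
      for (int i = 0; i < da; ++i) etry[act[i]] = eta[act[i]] + alpha * step[i];
      const double gt =
          joint_neg2ll(d, common, spec, omega2, sp, sa, etry);
      if (gt < g0) { eta = etry; g_cur = gt; ok = true; break; }
      alpha *= 0.5;
    }
    if (!ok) break;  // no descent: at numerical mode, H current
    // near the mode a full Newton step with a tiny predicted decrease lands
    // on it; the pre-step Hessian differs from the mode Hessian at O(step)
    if (pred_dec < ptol && alpha == 1.0) break;
    if (alpha * arma::norm(step, 2) < 1e-8) break;
    if (it == maxit - 1) {
      fd_grad_hess(d, common, spec, omega2, sp, sa, eta, act, h, &g0, grad,
                   hess);
      g_cur = g0;
    }
  }

  // log det of the (ridged-to-PD) Hessian at the mode
  arma::mat hreg = hess;
  double ridge = 0.0;
  double logdet = 0.0;
  bool got = false;
  for (int tries = 0; tries < 12; ++tries) {
    arma::mat L;
    if (arma::chol(L, hreg, "lower")) {
      logdet = 2.0 * arma::sum(arma::log(L.diag()));
      got = true;
      break;
    }
    ridge = (ridge == 0.0) ? 1e-6 * std::max(1.0, std::fabs(arma::trace(hess)) / da)
                           : ridge * 10.0;
    hreg = hess + ridge * arma::eye(da, da);
    flag = std::max(flag, 3);
  }
  if (!got) { flag = 2; logdet = 0.0; }

  double ofv = g_cur + logdet - da * std::log(4.0 * M_PI);

  const int qa = std::min(quad_axes, da);
  if (qa > 0 && got) {
    // proposal N(mode, S), S = 2 H^-1; lower-Cholesky axes of S, trailing
    // columns spanning the last-ordered (most nonlinear) etas
    arma::mat L;
    arma::mat S = hreg;  // hreg is the PD (possibly ridged) Hessian
    S = 2.0 * arma::inv_sympd(S);
    if (arma::chol(L, S, "lower")) {
      const double gh_n[3] = {-1.7320508075688772, 0.0, 1.7320508075688772};
      const double gh_w[3] = {1.0 / 6, 2.0 / 3, 1.0 / 6};
      const int n_nodes = (int)std::pow(3.0, qa);
      double acc = 0.0;
      bool fail = false;
      arma::vec z(da, arma::fill::zeros), etry(eta.n_elem);
      for (int node = 0; node < n_nodes; ++node) {
        int idx = node;
        double w = 1.0, z2 = 0.0;
        z.zeros();
        for (int a = 0; a < qa; ++a) {
          const int which = idx % 3;
          idx /= 3;
          z[da - 1 - a] = gh_n[which];
          w *= gh_w[which];
          z2 += gh_n[which] * gh_n[which];
        }
        arma::vec x = L * z;
        etry = eta;
        for (int i = 0; i < da; ++i) etry[act[i]] += x[i];
        const double gk =
            joint_neg2ll(d, common, spec, omega2, sp, sa, etry);
        if (gk >= BIG) { fail = true; break; }
        // sum w_k exp(z^2/2) exp(-(g_k - g_cur)/2), stable around the mode
        acc += w * std::exp(0.5 * z2 - 0.5 * (gk - g_cur));
      }
      if (!fail && acc > 0.0) {
        // -2 log L_q with log|S| = da log 2 - log|H|
        const double logdetS = da * std::log(2.0) - logdet;
        ofv = -da * std::log(2.0 * M_PI) - logdetS + g_cur -
              2.0 * std::log(acc);
      } else {
        flag = std::max(flag, 4);
      }
    }
  }

  return List::create(_["ofv"] = ofv, _["eta"] = eta, _["g"] = g_cur,
                      _["flag"] = flag);
}

// [[Rcpp::export]]
List cpp_laplace_subject(const List& subject, const List& common,
                         const List& spec, const arma::vec& omega2,
                         double sigma_prop, double sigma_add,
                         const arma::vec& eta_start, int maxit, double gtol,
                         int quad_axes = 0) {
  ModelSpec s = spec_from_list(spec);
  SubjectData d = subject_from_list(subject);
  return laplace_subject(d, common, s, omega2, sigma_prop, sigma_add,
                         eta_start, maxit, gtol, quad_axes);
}

// Population OFV: sum of per-subject Laplace contributions. tv_matrix has one
// row per subject (circ0, mtt, gamma, ir50_p, ir50_c, kde_p, kde_c);
// eta_warm (n_subjects x 5) supplies warm starts and is returned updated.
// [[Rcpp::export]]
List cpp_pop_ofv(const List& subjects, const arma::mat& tv_matrix,
                 const List& common, const List& spec, const arma::vec& omega2,
                 double sigma_prop, double sigma_add,
                 const arma::mat& eta_warm, int maxit, double gtol,
                 int quad_axes = 0) {
  ModelSpec s = spec_from_list(spec);
  const int n = subjects.size();
  arma::vec indiv(n);
  arma::mat eta_out = eta_warm;
  IntegerVector flags(n);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    SubjectData d = subject_from_list(subjects[i]);
    d.tv = tv_matrix.row(i).t();
    List r = laplace_subject(d, common, s, omega2, sigma_prop, sigma_add,
                             eta_warm.row(i).t(), maxit, gtol, quad_axes);
    indiv[i] = as<double>(r["ofv"]);
    eta_out.row(i) = as<arma::vec>(r["eta"]).t();
    flags[i] = as<int>(r["flag"]);
    total += indiv[i];
  }
  return List::create(_["ofv"] = total, _["indiv"] = indiv,
                      _["eta"] = eta_out, _["flags"] = flags);
}
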