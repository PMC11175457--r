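// Planar articulated rigid-body engine for the sit-to-walk model.
//
// Generalized coordinates: 3 planar-free pelvis coordinates (tx, ty, tilt)
// followed by one angle per pin joint.  User coordinates follow gait
// conventions (flexion / dorsiflexion / anterior tilt positive); each joint
// record carries a sign mapping onto the internal counter-clockwise angle.
// Dynamics: mass matrix + velocity bias assembled from point Jacobians,
// semi-implicit (symplectic) Euler at a fixed step.  Muscles are Hill-type
// MTUs with series elastic tendon (rigid-tendon mode for tests), contact is
// Hunt-Crossley with velocity-regularized friction, and the controller is a
// table of delayed reflex / vestibular / constant pathway terms.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// ---------------------------------------------------------------- muscle curves

static const double FL_WIDTH   = 0.50;  // gaussian width of active force-length
static const double FV_K       = 0.25;  // shortening curvature
static const double FV_N       = 1.50;  // eccentric force plateau
static const double FV_SLOPE   = 5.0;   // d f_v / d(v/vmax) at v = 0
static const double PE_STRAIN  = 0.60;  // passive: f_pe = ((L-1)/0.6)^3
static const double TENDON_STRAIN = 0.045; // tendon strain at F = f_max
static const double ACT_FLOOR  = 0.01;  // floor on a*f_l in the f_v inversion

static inline double fl_curve(double L) {
  double d = (L - 1.0) / FL_WIDTH;
  return std::exp(-d * d);
}
static inline double fv_curve(double v) {  // v = V / vmax, lengthening positive
  if (v < -1.0) return 0.0;
  if (v <= 0.0) return (1.0 + v) / (1.0 - v / FV_K);
  return FV_N - (FV_N - 1.0) * std::exp(-FV_SLOPE * v / (FV_N - 1.0));
}
static inline double fv_inverse(double f) {
  if (f <= 0.0) return -1.0;
  if (f < 1.0) return (f - 1.0) / (1.0 + f / FV_K);
  double ff = clampd(f, 1.0, FV_N - 1e-6);
  return -(FV_N - 1.0) / FV_SLOPE * std::log((FV_N - ff) / (FV_N - 1.0));
}
static inline double pe_curve(double L) {
  if (L <= 1.0) return 0.0;
  double d = (L - 1.0) / PE_STRAIN;
  return d * d * d;
}
static inline double tendon_curve(double eps) {
  if (eps <= 0.0) return 0.0;
  double d = eps / TENDON_STRAIN;
  return d * d;
}

// [[Rcpp::export]]
List cpp_muscle_curves(NumericVector L, NumericVector v, NumericVector eps) {
  int n = L.size();
  NumericVector fl(n), fv(n), fpe(n), ft(eps.size());
  for (int i = 0; i < n; ++i) {
    fl[i] = fl_curve(L[i]);
    fv[i] = fv_curve(v[i]);
    fpe[i] = pe_curve(L[i]);
  }
  for (int i = 0; i < eps.size(); ++i) ft[i] = tendon_curve(eps[i]);
  return List::create(_["fl"] = fl, _["fv"] = fv, _["fpe"] = fpe, _["ft"] = ft);
}

// [[Rcpp::export]]
NumericVector cpp_fv_inverse(NumericVector f) {
  NumericVector out(f.size());
  for (int i = 0; i < f.size(); ++i) out[i] = fv_inverse(f[i]);
  return out;
}

struct MtuOut { double lce, L, V, F; };

// one explicit contraction-dynamics step (elastic tendon)
static inline MtuOut mtu_advance(double fmax, double lopt, double lslack,
                                 double vmax, double a, double lce,
                                 double lmt, double dt) {
  double lt = lmt - lce;
  double eps = (lt - lslack) / lslack;
  double Ft = tendon_curve(eps);
  double L = lce / lopt;
  double fl = fl_curve(L);
  double fpe = pe_curve(L);
  double denom = a * fl + ACT_FLOOR;
  double fvt = clampd((Ft - fpe) / denom, 0.0, FV_N - 1e-3);
  double v = clampd(fv_inverse(fvt), -1.0, 1.0);
  double V = v * vmax;                      // lopt/s, lengthening positive
  double lce_new = clampd(lce + V * lopt * dt, 0.3 * lopt, 1.7 * lopt);
  MtuOut o; o.lce = lce_new; o.L = L; o.V = V; o.F = Ft;
  return o;
}

// [[Rcpp::export]]
List cpp_mtu_step(double fmax, double lopt, double lslack, double vmax,
                  double a, double lce, double lmt, double dt,
                  bool rigid = false, double lmt_prev = NA_REAL) {
  if (rigid) {
    double lce_r = lmt - lslack;
    double L = lce_r / lopt;
    double V = NumericVector::is_na(lmt_prev) ? 0.0 : (lmt - lmt_prev) / dt / lopt;
    double F = a * fl_curve(L) * fv_curve(V / vmax) + pe_curve(L);
    return List::create(_["lce"] = lce_r, _["L"] = L, _["V"] = V,
                        _["F"] = std::max(0.0, F));
  }
  MtuOut o = mtu_advance(fmax, lopt, lslack, vmax, a, lce, lmt, dt);
  if (!std::isfinite(o.F) || !std::isfinite(o.lce))
    stop("MTU equilibrium step failed (lce=%f, lmt=%f)", lce, lmt);
  return List::create(_["lce"] = o.lce, _["L"] = o.L, _["V"] = o.V,
                      _["F"] = o.F);
}

// ------------------------------------------------------------------- contact

static const double SLIP_VTOL = 0.01;   // m/s, friction regularization
static const double STRIBECK_V = 0.05;  // m/s, static->dynamic decay

static inline double hc_normal(double x, double xdot, double k, double c) {
  if (x <= 0.0) return 0.0;
  double f = k * std::pow(x, 1.5) * (1.0 + 1.5 * c * xdot);
  return f > 0.0 ? f : 0.0;
}
static inline double reg_friction(double N, double vt, double mus, double mud) {
  if (N <= 0.0) return 0.0;
  double mu = mud + (mus - mud) * std::exp(-std::fabs(vt) / STRIBECK_V);
  return -N * mu * std::tanh(vt / SLIP_VTOL);
}

// [[Rcpp::export]]
NumericVector cpp_normal_force(NumericVector x, NumericVector xdot,
                               double k, double c) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = hc_normal(x[i], xdot[i], k, c);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_friction_force(NumericVector N, NumericVector vt,
                                 double mus, double mud) {
  NumericVector out(N.size());
  for (int i = 0; i < N.size(); ++i)
    out[i] = reg_friction(N[i], vt[i], mus, mud);
  return out;
}

// closest point on an axis-aligned rectangle (center bx,by, half-extents hx,hy)
// to a sphere center; returns penetration, contact point, outward normal
struct BoxHit { double pen, px, py, nx, ny; };
static inline BoxHit sphere_box(double cx, double cy, double r,
                                double bx, double by, double hx, double hy) {
  double dx = cx - bx, dy = cy - by;
  double qx = clampd(dx, -hx, hx), qy = clampd(dy, -hy, hy);
  BoxHit h;
  if (qx == dx && qy == dy) {               // center inside the box
    double ex = hx - std::fabs(dx), ey = hy - std::fabs(dy);
    if (ex < ey) { h.nx = dx >= 0 ? 1.0 : -1.0; h.ny = 0.0; h.pen = r + ex; }
    else         { h.nx = 0.0; h.ny = dy >= 0 ? 1.0 : -1.0; h.pen = r + ey; }
    h.px = bx + (h.nx != 0.0 ? h.nx * hx : qx);
    h.py = by + (h.ny != 0.0 ? h.ny * hy : qy);
    return h;
  }
  double ddx = dx - qx, ddy = dy - qy;
  double dist = std::sqrt(ddx * ddx + ddy * ddy);
  h.pen = r - dist;
  h.nx = ddx / dist; h.ny = ddy / dist;
  h.px = bx + qx; h.py = by + qy;
  return h;
}

// [[Rcpp::export]]
List cpp_sphere_box(double cx, double cy, double r,
                    double bx, double by, double hx, double hy) {
  BoxHit h = sphere_box(cx, cy, r, bx, by, hx, hy);
  return List::create(_["penetration"] = h.pen,
                      _["point"] = NumericVector::create(h.px, h.py),
                      _["normal"] = NumericVector::create(h.nx, h.ny));
}

// ------------------------------------------------------------ model structure

// dof influence entry for a body: a translation dof, or an ancestor rotation
// dof with sign s whose pivot is the origin of body `pivot`
struct DofJac { int dof; double s; int pivot; bool rot; };

struct Model {
  int nb, ndof, nm, ns;
  std::vector<int> parent, qindex;
  std::vector<double> jx, jy, jsign, mass, inertia, comx, comy;
  std::vector<double> qmin, qmax, limit_k, limit_c, passive;
  double gravity;
  std::vector<double> fmax, lopt, lslack, vmax;
  std::vector<int> vp_start, vp_body;
  std::vector<double> vp_x, vp_y;
  std::vector<int> sp_body, sp_buttock;
  std::vector<double> sp_x, sp_y, sp_r, sp_k, sp_c, sp_mus, sp_mud;
  double box_hx, box_hy, box_k, box_c, box_mus, box_mud;
  // derived
  std::vector<std::vector<int>> chain;   // root..b body chain per body
  std::vector<int> leg_of_body;          // 0 right, 1 left, -1 other
  std::vector<std::vector<DofJac>> bdofs;  // dof influence list per body
};

template <typename T>
static std::vector<T> as_vec(SEXP s) { return as<std::vector<T>>(s); }

static Model parse_model(const List& e) {
  Model m;
  m.nb = as<int>(e["nb"]); m.ndof = as<int>(e["ndof"]);
  m.nm = as<int>(e["nm"]); m.ns = as<int>(e["ns"]);
  m.parent = as_vec<int>(e["parent"]); m.qindex = as_vec<int>(e["qindex"]);
  m.jx = as_vec<double>(e["jx"]); m.jy = as_vec<double>(e["jy"]);
  m.jsign = as_vec<double>(e["jsign"]);
  m.mass = as_vec<double>(e["mass"]); m.inertia = as_vec<double>(e["inertia"]);
  m.comx = as_vec<double>(e["comx"]); m.comy = as_vec<double>(e["comy"]);
  m.qmin = as_vec<double>(e["qmin"]); m.qmax = as_vec<double>(e["qmax"]);
  m.limit_k = as_vec<double>(e["limit_k"]); m.limit_c = as_vec<double>(e["limit_c"]);
  m.passive = e.containsElementNamed("passive")
                ? as_vec<double>(e["passive"])
                : std::vector<double>(m.qmin.size(), 0.0);
  m.gravity = as<double>(e["gravity"]);
  m.fmax = as_vec<double>(e["fmax"]); m.lopt = as_vec<double>(e["lopt"]);
  m.lslack = as_vec<double>(e["lslack"]); m.vmax = as_vec<double>(e["vmax"]);
  m.vp_start = as_vec<int>(e["vp_start"]); m.vp_body = as_vec<int>(e["vp_body"]);
  m.vp_x = as_vec<double>(e["vp_x"]); m.vp_y = as_vec<double>(e["vp_y"]);
  m.sp_body = as_vec<int>(e["sp_body"]); m.sp_buttock = as_vec<int>(e["sp_buttock"]);
  m.sp_x = as_vec<double>(e["sp_x"]); m.sp_y = as_vec<double>(e["sp_y"]);
  m.sp_r = as_vec<double>(e["sp_r"]); m.sp_k = as_vec<double>(e["sp_k"]);
  m.sp_c = as_vec<double>(e["sp_c"]); m.sp_mus = as_vec<double>(e["sp_mus"]);
  m.sp_mud = as_vec<double>(e["sp_mud"]);
  m.box_hx = as<double>(e["box_hx"]); m.box_hy = as<double>(e["box_hy"]);
  m.box_k = as<double>(e["box_k"]); m.box_c = as<double>(e["box_c"]);
  m.box_mus = as<double>(e["box_mus"]); m.box_mud = as<double>(e["box_mud"]);
  m.chain.resize(m.nb);
  for (int b = 0; b < m.nb; ++b) {
    std::vector<int> up;
    for (int a = b; a >= 0; a = m.parent[a]) up.push_back(a);
    m.chain[b].assign(up.rbegin(), up.rend());
  }
  // legs: bodies whose chain passes through a body holding a foot sphere
  m.leg_of_body.assign(m.nb, -1);
  // heuristic: the two subtrees hanging off the root that contain spheres
  // with role "foot" define the legs; right leg = first such subtree.
  std::vector<int> foot_bodies;
  for (int s = 0; s < m.ns; ++s)
    if (!m.sp_buttock[s]) foot_bodies.push_back(m.sp_body[s]);
  std::vector<int> leg_roots;
  for (int fb : foot_bodies) {
    int top = fb;
    for (int a = fb; m.parent[a] >= 0; a = m.parent[a]) top = a;
    // top is root; find child of root on this chain
    int child = fb;
    for (int a = fb; m.parent[a] >= 0; a = m.parent[a])
      if (m.parent[a] == top) child = a;
    bool seen = false;
    for (int lr : leg_roots) if (lr == child) seen = true;
    if (!seen) leg_roots.push_back(child);
  }
  for (int b = 0; b < m.nb; ++b) {
    for (size_t k = 0; k < leg_roots.size() && k < 2; ++k) {
      for (int a : m.chain[b]) if (a == leg_roots[k]) m.leg_of_body[b] = (int)k;
    }
  }
  m.bdofs.resize(m.nb);
  for (int b = 0; b < m.nb; ++b) {
    std::vector<DofJac>& out = m.bdofs[b];
    out.push_back(DofJac{0, 0.0, -1, false});
    out.push_back(DofJac{1, 0.0, -1, false});
    out.push_back(DofJac{2, m.jsign[0], 0, true});
    for (int a : m.chain[b]) {
      if (a == 0) continue;
      out.push_back(DofJac{m.qindex[a], m.jsign[a], a, true});
    }
  }
  return m;
}

// ------------------------------------------------------- forward kinematics

struct Kin {
  std::vector<double> th, px, py, w, vx, vy;   // per body
  std::vector<double> cx, cy, vcx, vcy;        // COM
  std::vector<double> cth, sth;                // cached cos/sin
};

static void fk(const Model& m, const arma::vec& q, const arma::vec& qd, Kin& k) {
  int nb = m.nb;
  k.th.resize(nb); k.px.resize(nb); k.py.resize(nb);
  k.w.resize(nb); k.vx.resize(nb); k.vy.resize(nb);
  k.cx.resize(nb); k.cy.resize(nb); k.vcx.resize(nb); k.vcy.resize(nb);
  k.cth.resize(nb); k.sth.resize(nb);
  k.th[0] = m.jsign[0] * q[2];
  k.px[0] = q[0]; k.py[0] = q[1];
  k.w[0] = m.jsign[0] * qd[2];
  k.vx[0] = qd[0]; k.vy[0] = qd[1];
  k.cth[0] = std::cos(k.th[0]); k.sth[0] = std::sin(k.th[0]);
  for (int b = 1; b < nb; ++b) {
    int p = m.parent[b];
    double ax = k.cth[p] * m.jx[b] - k.sth[p] * m.jy[b];
    double ay = k.sth[p] * m.jx[b] + k.cth[p] * m.jy[b];
    k.px[b] = k.px[p] + ax;
    k.py[b] = k.py[p] + ay;
    k.th[b] = k.th[p] + m.jsign[b] * q[m.qindex[b]];
    k.cth[b] = std::cos(k.th[b]); k.sth[b] = std::sin(k.th[b]);
    k.w[b] = k.w[p] + m.jsign[b] * qd[m.qindex[b]];
    k.vx[b] = k.vx[p] - k.w[p] * ay;
    k.vy[b] = k.vy[p] + k.w[p] * ax;
  }
  for (int b = 0; b < nb; ++b) {
    double rx = k.cth[b] * m.comx[b] - k.sth[b] * m.comy[b];
    double ry = k.sth[b] * m.comx[b] + k.cth[b] * m.comy[b];
    k.cx[b] = k.px[b] + rx; k.cy[b] = k.py[b] + ry;
    k.vcx[b] = k.vx[b] - k.w[b] * ry;
    k.vcy[b] = k.vy[b] + k.w[b] * rx;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_body_poses(List engine, NumericVector q) {
  Model m = parse_model(engine);
  arma::vec qq(q.begin(), q.size()), qd(q.size(), arma::fill::zeros);
  Kin k; fk(m, qq, qd, k);
  NumericMatrix out(m.nb, 3);
  for (int b = 0; b < m.nb; ++b) {
    out(b, 0) = k.px[b]; out(b, 1) = k.py[b]; out(b, 2) = k.th[b];
  }
  return out;
}

// world position of one via point
static inline void vp_world(const Model& m, const Kin& k, int i,
                            double& x, double& y) {
  int b = m.vp_body[i];
  x = k.px[b] + k.cth[b] * m.vp_x[i] - k.sth[b] * m.vp_y[i];
  y = k.py[b] + k.sth[b] * m.vp_x[i] + k.cth[b] * m.vp_y[i];
}

// influence of a dof on a world point p attached to the body owning `d`:
// translations are unit vectors; an ancestor rotation dof with pivot body g
// and sign s contributes s * perp(p - origin(g)).
static inline void jac_point(const DofJac& d, const Kin& k,
                             double px, double py, double& jx, double& jy) {
  if (!d.rot) { jx = d.dof == 0 ? 1.0 : 0.0; jy = d.dof == 1 ? 1.0 : 0.0; return; }
  jx = d.s * (-(py - k.py[d.pivot]));
  jy = d.s * (px - k.px[d.pivot]);
}

// muscle-tendon length and d(length)/dq for all muscles
static void muscle_geometry(const Model& m, const Kin& k,
                            std::vector<double>& len, arma::mat* dldq) {
  len.assign(m.nm, 0.0);
  if (dldq) dldq->zeros(m.nm, m.ndof);
  for (int mu = 0; mu < m.nm; ++mu) {
    for (int i = m.vp_start[mu]; i < m.vp_start[mu + 1] - 1; ++i) {
      double x1, y1, x2, y2;
      vp_world(m, k, i, x1, y1);
      vp_world(m, k, i + 1, x2, y2);
      double ux = x2 - x1, uy = y2 - y1;
      double L = std::sqrt(ux * ux + uy * uy);
      len[mu] += L;
      if (dldq && L > 1e-12 && m.vp_body[i] != m.vp_body[i + 1]) {
        ux /= L; uy /= L;
        double jx, jy;
        for (const DofJac& d : m.bdofs[m.vp_body[i + 1]]) {
          jac_point(d, k, x2, y2, jx, jy);
          (*dldq)(mu, d.dof) += ux * jx + uy * jy;
        }
        for (const DofJac& d : m.bdofs[m.vp_body[i]]) {
          jac_point(d, k, x1, y1, jx, jy);
          (*dldq)(mu, d.dof) -= ux * jx + uy * jy;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_muscle_geometry(List engine, NumericVector q) {
  Model m = parse_model(engine);
  arma::vec qq(q.begin(), q.size()), qd(q.size(), arma::fill::zeros);
  Kin k; fk(m, qq, qd, k);
  std::vector<double> len;
  arma::mat dldq;
  muscle_geometry(m, k, len, &dldq);
  NumericMatrix arms(m.nm, m.ndof);
  for (int i = 0; i < m.nm; ++i)
    for (int j = 0; j < m.ndof; ++j) arms(i, j) = -dldq(i, j);
  return List::create(_["length"] = wrap(len), _["moment_arm"] = arms);
}

// joint-limit torque with a short damping ramp so the torque is continuous
// at the range boundary
static inline double limit_torque(double q, double qd, double qmin,
                                  double qmax, double k, double c) {
  double e = 0.0;
  if (q > qmax) e = q - qmax;
  else if (q < qmin) e = q - qmin;
  else return 0.0;
  double ramp = clampd(std::fabs(e) / 0.02, 0.0, 1.0);
  return -k * e - c * qd * ramp;
}

// [[Rcpp::export]]
double cpp_limit_torque(double q, double qd, double qmin, double qmax,
                        double k, double c) {
  return limit_torque(q, qd, qmin, qmax, k, c);
}

// ----------------------------------------------------------------- controller

// pathway table columns (one row per primitive term):
// 0 target (0..nm-1 muscle, nm lumbar torque, nm+1 thoracic torque)
// 1 phase (0 P1, 1 P2, 2 gait)
// 2 state mask (gait: bit0 stance, bit1 liftoff, bit2 swing)
// 3 type: 0 const, 1 L, 2 F, 3 V, 4 vest_p, 5 vest_v, 6 knee-angle (KA),
//         7 trunk_p, 8 trunk_v
// 4 source index (muscle for L/F/V; coordinate for KA/trunk)
// 5 gain, 6 offset, 7 delay_ms, 8 sign (+1 excitatory / -1 inhibitory)
// 9 leg of target (0 right, 1 left, -1 none)
struct Pathway {
  int target, phase, mask, type, src, delay_steps, leg;
  double gain, offset, sign;
};

// delay channel layout: [0..nm) L, [nm..2nm) F, [2nm..3nm) V,
// then theta, theta_dot, coord channels q (ndof), coord channels qd (ndof)
struct DelayBuf {
  int nchan, cap, head = 0, count = 0;
  std::vector<double> data;  // cap x nchan
  void init(int nc, int capacity) {
    nchan = nc; cap = capacity; head = 0; count = 0;
    data.assign((size_t)cap * nchan, 0.0);
  }
  void push(const std::vector<double>& v) {
    std::copy(v.begin(), v.end(), data.begin() + (size_t)head * nchan);
    head = (head + 1) % cap;
    if (count < cap) ++count;
  }
  // value of channel ch, `back` steps before the most recent push
  double get(int ch, int back) const {
    if (back >= count) back = count - 1;
    int idx = head - 1 - back;
    idx %= cap; if (idx < 0) idx += cap;
    return data[(size_t)idx * nchan + ch];
  }
};

// --------------------------------------------------------------- simulation

// [[Rcpp::export]]
List cpp_simulate(List engine, List params, Nullable<NumericMatrix> ctrl_table) {
  Model m = parse_model(engine);
  const int nd = m.ndof, nm = m.nm;

  arma::vec q = as<arma::vec>(params["q0"]);
  arma::vec qd = params.containsElementNamed("qd0") && !Rf_isNull(params["qd0"])
                   ? as<arma::vec>(params["qd0"]) : arma::vec(nd, arma::fill::zeros);
  if ((int)q.n_elem != nd) stop("q0 must have %d entries", nd);

  const double dt = as<double>(params["dt"]);
  const double tmax = as<double>(params["tmax"]);
  const double t0 = params.containsElementNamed("t0") ? as<double>(params["t0"]) : 0.0;
  const double rec_dt = params.containsElementNamed("record_dt")
                          ? as<double>(params["record_dt"]) : 0.01;
  const bool gravity_on = !params.containsElementNamed("gravity_on") ||
                          as<bool>(params["gravity_on"]);
  const bool contact_on = !params.containsElementNamed("contact_on") ||
                          as<bool>(params["contact_on"]);
  const bool limits_on = !params.containsElementNamed("limits_on") ||
                         as<bool>(params["limits_on"]);
  const bool joint_damping_on = !params.containsElementNamed("joint_damping_on") ||
                                as<bool>(params["joint_damping_on"]);
  const double trunk_tau_filter = params.containsElementNamed("trunk_tau_filter")
                                    ? as<double>(params["trunk_tau_filter"]) : 0.020;
  // rotational damping of the buttock-seat contact patch (N m per N rad/s):
  // stands in for the distributed flesh/thigh contact a single sphere lacks
  const double patch_damping = params.containsElementNamed("patch_damping")
                                 ? as<double>(params["patch_damping"]) : 0.02;
  const bool muscles_on = !params.containsElementNamed("muscles_on") ||
                          as<bool>(params["muscles_on"]);
  const bool chair_on = params.containsElementNamed("chair_on") &&
                        as<bool>(params["chair_on"]);
  const bool lock_root = params.containsElementNamed("lock_root") &&
                         as<bool>(params["lock_root"]);
  const bool rigid_tendon = params.containsElementNamed("rigid_tendon") &&
                            as<bool>(params["rigid_tendon"]);
  const bool fall_check = !params.containsElementNamed("fall_check") ||
                          as<bool>(params["fall_check"]);
  const double fall_ratio = params.containsElementNamed("fall_ratio")
                              ? as<double>(params["fall_ratio"]) : 0.6;
  const double seat_x = params.containsElementNamed("seat_x")
                          ? as<double>(params["seat_x"]) : 0.0;
  const double seat_top = params.containsElementNamed("seat_top")
                            ? as<double>(params["seat_top"]) : 0.44;
  const double trunk_limit = params.containsElementNamed("trunk_torque_limit")
                               ? as<double>(params["trunk_torque_limit"]) : 1000.0;
  const int head_body = params.containsElementNamed("head_body")
                          ? as<int>(params["head_body"]) : 2;
  const double head_lx = params.containsElementNamed("head_local")
                           ? as<NumericVector>(params["head_local"])[0] : 0.0;
  const double head_ly = params.containsElementNamed("head_local")
                           ? as<NumericVector>(params["head_local"])[1] : 0.60;

  // optional joint-space PD hold on pin coordinates (test utility)
  double hold_kp = params.containsElementNamed("hold_kp")
                     ? as<double>(params["hold_kp"]) : 0.0;
  double hold_kd = params.containsElementNamed("hold_kd")
                     ? as<double>(params["hold_kd"]) : 0.0;
  arma::vec hold_q = q;

  // constant external excitations (used when no controller is given)
  arma::vec ext_u(std::max(nm, 1), arma::fill::zeros);
  if (params.containsElementNamed("excitation") &&
      !Rf_isNull(params["excitation"])) {
    arma::vec tmp = as<arma::vec>(params["excitation"]);
    for (int i = 0; i < nm && i < (int)tmp.n_elem; ++i)
      ext_u[i] = clampd(tmp[i], 0.0, 1.0);
  }
  // constant external generalized forces (test utility)
  arma::vec ext_tau(nd, arma::fill::zeros);
  if (params.containsElementNamed("tau_ext") && !Rf_isNull(params["tau_ext"]))
    ext_tau = as<arma::vec>(params["tau_ext"]);

  // controller setup
  std::vector<Pathway> paths;
  std::vector<int> rows_p1, rows_p2, rows_gait;
  double T1 = 1e30, T2 = 1e30, stance_thr = 0.1;
  bool has_ctrl = ctrl_table.isNotNull();
  if (has_ctrl) {
    NumericMatrix tb(ctrl_table);
    T1 = as<double>(params["T1"]);
    T2 = as<double>(params["T2"]);
    stance_thr = as<double>(params["stance_threshold"]);
    for (int r = 0; r < tb.nrow(); ++r) {
      Pathway p;
      p.target = (int)tb(r, 0); p.phase = (int)tb(r, 1);
      p.mask = (int)tb(r, 2); p.type = (int)tb(r, 3);
      p.src = (int)tb(r, 4); p.gain = tb(r, 5); p.offset = tb(r, 6);
      p.delay_steps = (int)std::lround(tb(r, 7) / 1000.0 / dt);
      p.sign = tb(r, 8); p.leg = (int)tb(r, 9);
      paths.push_back(p);
      if (p.phase == 0) rows_p1.push_back(r);
      else if (p.phase == 1) rows_p2.push_back(r);
      else rows_gait.push_back(r);
    }
  }

  // muscle state init
  arma::vec act(std::max(nm, 1)), lce(std::max(nm, 1));
  act.fill(params.containsElementNamed("act0_value")
             ? as<double>(params["act0_value"]) : 0.02);
  if (params.containsElementNamed("act0") && !Rf_isNull(params["act0"]))
    act = as<arma::vec>(params["act0"]);
  const double tau_act = 0.010, tau_deact = 0.040;

  Kin k;
  fk(m, q, qd, k);
  std::vector<double> mlen, mlen_prev;
  arma::mat dldq;
  muscle_geometry(m, k, mlen, &dldq);
  mlen_prev = mlen;
  for (int i = 0; i < nm; ++i)
    lce[i] = clampd(mlen[i] - m.lslack[i], 0.3 * m.lopt[i], 1.7 * m.lopt[i]);
  if (params.containsElementNamed("lce0") && !Rf_isNull(params["lce0"]))
    lce = as<arma::vec>(params["lce0"]);

  // delay buffers
  const int nchan = 3 * nm + 2 + 2 * nd;
  const int max_delay_steps = (int)std::ceil(0.060 / dt) + 2;
  DelayBuf buf; buf.init(nchan, max_delay_steps);
  std::vector<double> chan(nchan, 0.0);
  arma::vec Fnorm(std::max(nm, 1), arma::fill::zeros);
  arma::vec Vnorm(std::max(nm, 1), arma::fill::zeros);
  arma::vec Lnorm(std::max(nm, 1), arma::fill::ones);
  for (int i = 0; i < nm; ++i) {
    Lnorm[i] = lce[i] / m.lopt[i];
    double eps = (mlen[i] - lce[i] - m.lslack[i]) / m.lslack[i];
    Fnorm[i] = tendon_curve(eps);
  }

  auto fill_chan = [&](void) {
    for (int i = 0; i < nm; ++i) {
      chan[i] = Lnorm[i];
      chan[nm + i] = Fnorm[i];
      chan[2 * nm + i] = Vnorm[i];
    }
    chan[3 * nm] = q[2];        // pelvis tilt, user convention
    chan[3 * nm + 1] = qd[2];
    for (int j = 0; j < nd; ++j) {
      chan[3 * nm + 2 + j] = q[j];
      chan[3 * nm + 2 + nd + j] = qd[j];
    }
  };
  fill_chan();
  buf.push(chan);

  // initial whole-body COM height (fall rule reference)
  double M_total = 0.0, com_y0 = 0.0;
  for (int b = 0; b < m.nb; ++b) { M_total += m.mass[b]; com_y0 += m.mass[b] * k.cy[b]; }
  com_y0 /= M_total;

  // chair box center
  const double box_cx = seat_x, box_cy = seat_top - m.box_hy;

  // active dofs
  std::vector<int> freedofs;
  for (int j = 0; j < nd; ++j)
    if (!lock_root || j >= 3) freedofs.push_back(j);
  const int nfree = (int)freedofs.size();
  std::vector<int> dofmap(nd, -1);
  for (int i = 0; i < nfree; ++i) dofmap[freedofs[i]] = i;

  // recording
  // heel sphere per leg: the foot sphere with the smallest local x offset
  int heel_sphere[2] = {-1, -1};
  for (int s = 0; s < m.ns; ++s) {
    if (m.sp_buttock[s]) continue;
    int leg = m.leg_of_body[m.sp_body[s]];
    if (leg < 0) continue;
    if (heel_sphere[leg] < 0 || m.sp_x[s] < m.sp_x[heel_sphere[leg]])
      heel_sphere[leg] = s;
  }

  const int n_steps = (int)std::llround(tmax / dt);
  const int rec_every = std::max(1, (int)std::llround(rec_dt / dt));
  const int n_rec_max = n_steps / rec_every + 2;
  const int ncol = 1 + 2 * nd + 5 * nm + 4 + 2 + 2 + 2 + 2 + 2 + 2 + 3;
  NumericMatrix traj(n_rec_max, ncol);
  int n_rec = 0;

  // per-step scratch
  arma::mat Mmat(nfree, nfree);
  arma::vec rhs(nfree);
  std::vector<double> fbx(m.nb), fby(m.nb), nbz(m.nb);
  std::vector<double> jxv(16), jyv(16);

  int gait_state[2] = {0, 2};
  double state_since[2] = {-1.0, -1.0};
  bool gait_started = false;
  const double dwell = 0.020;
  double grf[2][2] = {{0, 0}, {0, 0}};
  double heel_fy[2] = {0, 0};
  double seat_f[2] = {0, 0};
  double tau_trunk[2] = {0, 0};      // filtered (applied) trunk torques
  double tau_trunk_cmd[2] = {0, 0};  // raw controller commands
  arma::vec exc(std::max(nm, 1), arma::fill::zeros);
  bool fell = false;
  double t = t0;
  int lumbar_dof = -1, thor_dof = -1;
  // trunk torque coordinates: identified as the pin dofs of the bodies not on
  // a leg (in tree order: first non-leg pin = lumbar, second = thoracic)
  for (int b = 1; b < m.nb; ++b) {
    if (m.leg_of_body[b] < 0) {
      if (lumbar_dof < 0) lumbar_dof = m.qindex[b];
      else if (thor_dof < 0) thor_dof = m.qindex[b];
    }
  }

  auto record = [&](void) {
    if (n_rec >= n_rec_max) return;
    int c = 0;
    traj(n_rec, c++) = t;
    for (int j = 0; j < nd; ++j) traj(n_rec, c++) = q[j];
    for (int j = 0; j < nd; ++j) traj(n_rec, c++) = qd[j];
    for (int i = 0; i < nm; ++i) traj(n_rec, c++) = act[i];
    for (int i = 0; i < nm; ++i) traj(n_rec, c++) = exc[i];
    for (int i = 0; i < nm; ++i) traj(n_rec, c++) = Lnorm[i];
    for (int i = 0; i < nm; ++i) traj(n_rec, c++) = Vnorm[i];
    for (int i = 0; i < nm; ++i) traj(n_rec, c++) = Fnorm[i];
    traj(n_rec, c++) = grf[0][0]; traj(n_rec, c++) = grf[0][1];
    traj(n_rec, c++) = grf[1][0]; traj(n_rec, c++) = grf[1][1];
    traj(n_rec, c++) = seat_f[0]; traj(n_rec, c++) = seat_f[1];
    traj(n_rec, c++) = k.cx[0]; traj(n_rec, c++) = k.cy[0];   // pelvis COM
    double cx = 0, cy = 0;
    for (int b = 0; b < m.nb; ++b) { cx += m.mass[b] * k.cx[b]; cy += m.mass[b] * k.cy[b]; }
    traj(n_rec, c++) = cx / M_total; traj(n_rec, c++) = cy / M_total;
    double hcth = std::cos(k.th[head_body]), hsth = std::sin(k.th[head_body]);
    traj(n_rec, c++) = k.px[head_body] + hcth * head_lx - hsth * head_ly;
    traj(n_rec, c++) = k.py[head_body] + hsth * head_lx + hcth * head_ly;
    traj(n_rec, c++) = heel_fy[0]; traj(n_rec, c++) = heel_fy[1];
    traj(n_rec, c++) = tau_trunk[0]; traj(n_rec, c++) = tau_trunk[1];
    double phase = has_ctrl ? (t < T1 ? 0.0 : (t < T2 ? 1.0 : 2.0)) : 0.0;
    traj(n_rec, c++) = phase;
    traj(n_rec, c++) = gait_state[0]; traj(n_rec, c++) = gait_state[1];
    ++n_rec;
  };

  record();

  for (int step = 0; step < n_steps; ++step) {
    // ---- controller
    int phase = !has_ctrl ? -1 : (t < T1 ? 0 : (t < T2 ? 1 : 2));
    if (phase == 2 && !gait_started) {
      gait_started = true;
      double bw = M_total * m.gravity;
      for (int leg = 0; leg < 2; ++leg) {
        gait_state[leg] = (grf[leg][1] / bw >= stance_thr) ? 0 : 2;
        state_since[leg] = t;
      }
      // from double support the first step must be seeded: the less-loaded
      // leg (right on an exact tie) enters Lift-off, whose hip-flexor drive
      // unloads it into swing
      if (gait_state[0] == 0 && gait_state[1] == 0) {
        int step_leg = (grf[0][1] <= grf[1][1]) ? 0 : 1;
        gait_state[step_leg] = 1;
      }
    }
    if (phase == 2) {
      double bw = M_total * m.gravity;
      for (int leg = 0; leg < 2; ++leg) {
        double load = grf[leg][1] / bw;
        double oload = grf[1 - leg][1] / bw;
        if (t - state_since[leg] >= dwell) {
          int s = gait_state[leg];
          int ns = s;
          if (s == 0 && load < stance_thr && oload >= stance_thr) ns = 1;
          else if (s == 1 && load < 0.01) ns = 2;
          else if (s == 1 && load >= stance_thr) ns = 0;
          else if (s == 2 && load >= stance_thr) ns = 0;
          if (ns != s) { gait_state[leg] = ns; state_since[leg] = t; }
        }
      }
    }
    tau_trunk_cmd[0] = tau_trunk_cmd[1] = 0.0;
    if (has_ctrl) {
      exc.zeros();
      const std::vector<int>& rows =
        phase == 0 ? rows_p1 : (phase == 1 ? rows_p2 : rows_gait);
      for (int r : rows) {
        const Pathway& p = paths[r];
        if (phase == 2 && p.leg >= 0 &&
            !(p.mask & (1 << gait_state[p.leg]))) continue;
        double contrib = 0.0;
        switch (p.type) {
          case 0: contrib = p.gain; break;
          case 1: contrib = p.sign * p.gain *
                    (buf.get(p.src, p.delay_steps) - p.offset); break;
          case 2: contrib = p.sign * p.gain *
                    buf.get(nm + p.src, p.delay_steps); break;
          case 3: contrib = p.sign * p.gain *
                    buf.get(2 * nm + p.src, p.delay_steps); break;
          case 4: contrib = p.sign * p.gain *
                    (buf.get(3 * nm, p.delay_steps) - p.offset); break;
          case 5: contrib = p.sign * p.gain *
                    buf.get(3 * nm + 1, p.delay_steps); break;
          case 6: {  // knee-angle suppression near full extension
            double kq = buf.get(3 * nm + 2 + p.src, p.delay_steps);
            contrib = p.sign * p.gain * std::max(0.0, p.offset - kq);
            break;
          }
          case 7: contrib = -p.gain *
                    (buf.get(3 * nm + 2 + p.src, p.delay_steps) - p.offset); break;
          case 8: contrib = -p.gain *
                    buf.get(3 * nm + 2 + nd + p.src, p.delay_steps); break;
        }
        if (p.target < nm) exc[p.target] += contrib;
        else tau_trunk_cmd[p.target - nm] += contrib;
      }
      for (int i = 0; i < nm; ++i) exc[i] = clampd(exc[i], 0.0, 1.0);
      for (int j = 0; j < 2; ++j) {
        double cmd = clampd(tau_trunk_cmd[j], -trunk_limit, trunk_limit);
        if (trunk_tau_filter > 0.0)
          tau_trunk[j] += dt / trunk_tau_filter * (cmd - tau_trunk[j]);
        else
          tau_trunk[j] = cmd;
      }
    } else {
      for (int i = 0; i < nm; ++i) exc[i] = ext_u[i];
    }

    // ---- muscle dynamics
    if (nm > 0 && muscles_on) {
      for (int i = 0; i < nm; ++i) {
        double tau = exc[i] >= act[i] ? tau_act : tau_deact;
        act[i] = clampd(act[i] + dt * (exc[i] - act[i]) / tau, 0.0, 1.0);
        if (rigid_tendon) {
          double lr = mlen[i] - m.lslack[i];
          Lnorm[i] = lr / m.lopt[i];
          Vnorm[i] = (mlen[i] - mlen_prev[i]) / dt / m.lopt[i];
          Fnorm[i] = std::max(0.0, act[i] * fl_curve(Lnorm[i]) *
                       fv_curve(Vnorm[i] / m.vmax[i]) + pe_curve(Lnorm[i]));
        } else {
          MtuOut o = mtu_advance(m.fmax[i], m.lopt[i], m.lslack[i], m.vmax[i],
                                 act[i], lce[i], mlen[i], dt);
          lce[i] = o.lce; Lnorm[i] = o.L; Vnorm[i] = o.V; Fnorm[i] = o.F;
        }
      }
    }

    // ---- forces
    for (int b = 0; b < m.nb; ++b) { fbx[b] = 0; fby[b] = 0; nbz[b] = 0; }
    if (gravity_on)
      for (int b = 0; b < m.nb; ++b) fby[b] -= m.mass[b] * m.gravity;

    grf[0][0] = grf[0][1] = grf[1][0] = grf[1][1] = 0;
    heel_fy[0] = heel_fy[1] = 0;
    seat_f[0] = seat_f[1] = 0;
    if (contact_on) {
      for (int s = 0; s < m.ns; ++s) {
        int b = m.sp_body[s];
        double cth = std::cos(k.th[b]), sth = std::sin(k.th[b]);
        double rx = cth * m.sp_x[s] - sth * m.sp_y[s];
        double ry = sth * m.sp_x[s] + cth * m.sp_y[s];
        double cx = k.px[b] + rx, cy = k.py[b] + ry;
        double vcx_ = k.vx[b] - k.w[b] * ry, vcy_ = k.vy[b] + k.w[b] * rx;
        if (!m.sp_buttock[s]) {
          // ground plane y = 0
          double pen = m.sp_r[s] - cy;
          if (pen > 0) {
            double N = hc_normal(pen, -vcy_, m.sp_k[s], m.sp_c[s]);
            // contact-point velocity (sphere bottom) for friction
            double cpx = cx, cpy = cy - m.sp_r[s];
            double vtx = vcx_ - k.w[b] * (cpy - cy);
            double Ff = reg_friction(N, vtx, m.sp_mus[s], m.sp_mud[s]);
            fbx[b] += Ff; fby[b] += N;
            nbz[b] += (cpx - k.cx[b]) * N - (cpy - k.cy[b]) * Ff;
            int leg = m.leg_of_body[b];
            if (leg >= 0) {
              grf[leg][0] += Ff; grf[leg][1] += N;
              if (s == heel_sphere[leg]) heel_fy[leg] = N;
            }
          }
        } else if (chair_on) {
          BoxHit h = sphere_box(cx, cy, m.sp_r[s], box_cx, box_cy,
                                m.box_hx, m.box_hy);
          if (h.pen > 0) {
            // penetration rate along the outward normal
            double vpx = vcx_ - k.w[b] * (h.py - cy);
            double vpy = vcy_ + k.w[b] * (h.px - cx);
            double xdot = -(vpx * h.nx + vpy * h.ny);
            double N = hc_normal(h.pen, xdot, m.box_k, m.box_c);
            double tx = -h.ny, ty = h.nx;
            double vt = vpx * tx + vpy * ty;
            double Ff = reg_friction(N, vt, m.box_mus, m.box_mud);
            double fx = N * h.nx + Ff * tx, fy = N * h.ny + Ff * ty;
            fbx[b] += fx; fby[b] += fy;
            nbz[b] += (h.px - k.cx[b]) * fy - (h.py - k.cy[b]) * fx;
            nbz[b] += -patch_damping * N * k.w[b];
            seat_f[0] += fx; seat_f[1] += fy;
          }
        }
      }
    }

    // muscle path forces
    if (nm > 0 && muscles_on) {
      for (int mu = 0; mu < nm; ++mu) {
        double T = Fnorm[mu] * m.fmax[mu];
        if (T <= 0) continue;
        for (int i = m.vp_start[mu]; i < m.vp_start[mu + 1] - 1; ++i) {
          int b1 = m.vp_body[i], b2 = m.vp_body[i + 1];
          if (b1 == b2) continue;
          double x1, y1, x2, y2;
          vp_world(m, k, i, x1, y1);
          vp_world(m, k, i + 1, x2, y2);
          double ux = x2 - x1, uy = y2 - y1;
          double L = std::sqrt(ux * ux + uy * uy);
          if (L < 1e-12) continue;
          ux *= T / L; uy *= T / L;
          fbx[b1] += ux; fby[b1] += uy;
          nbz[b1] += (x1 - k.cx[b1]) * uy - (y1 - k.cy[b1]) * ux;
          fbx[b2] -= ux; fby[b2] -= uy;
          nbz[b2] += -((x2 - k.cx[b2]) * uy - (y2 - k.cy[b2]) * ux);
        }
      }
    }

    // ---- assemble and solve
    Mmat.zeros(); rhs.zeros();
    // direct generalized torques: limits, trunk commands, external, hold PD
    for (int j = 3; j < nd; ++j) {
      double tq = 0.0;
      if (limits_on)
        tq += limit_torque(q[j], qd[j], m.qmin[j], m.qmax[j],
                           m.limit_k[j], m.limit_c[j]);
      if (joint_damping_on)
        tq += -m.passive[j] * qd[j];
      if (hold_kp > 0)
        tq += -hold_kp * (q[j] - hold_q[j]) - hold_kd * qd[j];
      if (dofmap[j] >= 0) rhs[dofmap[j]] += tq;
    }
    if (has_ctrl) {
      if (lumbar_dof >= 0 && dofmap[lumbar_dof] >= 0)
        rhs[dofmap[lumbar_dof]] += tau_trunk[0];
      if (thor_dof >= 0 && dofmap[thor_dof] >= 0)
        rhs[dofmap[thor_dof]] += tau_trunk[1];
    }
    for (int j = 0; j < nd; ++j)
      if (dofmap[j] >= 0) rhs[dofmap[j]] += ext_tau[j];

    for (int b = 0; b < m.nb; ++b) {
      const std::vector<DofJac>& dv = m.bdofs[b];
      // velocity bias of the COM
      double ex = 0, ey = 0;
      for (const DofJac& d : dv) {
        if (!d.rot) continue;
        double relx = k.vcx[b] - k.vx[d.pivot];
        double rely = k.vcy[b] - k.vy[d.pivot];
        double sq = d.s * qd[d.dof];
        ex += sq * (-rely);
        ey += sq * (relx);
      }
      int nbd = (int)dv.size();
      for (int i = 0; i < nbd; ++i)
        jac_point(dv[i], k, k.cx[b], k.cy[b], jxv[i], jyv[i]);
      for (int i = 0; i < nbd; ++i) {
        int di = dofmap[dv[i].dof];
        if (di < 0) continue;
        // applied forces and velocity bias
        rhs[di] += jxv[i] * fbx[b] + jyv[i] * fby[b];
        if (dv[i].rot) rhs[di] += dv[i].s * nbz[b];
        rhs[di] -= m.mass[b] * (jxv[i] * ex + jyv[i] * ey);
        for (int jj = 0; jj < nbd; ++jj) {
          int dj = dofmap[dv[jj].dof];
          if (dj < 0) continue;
          double v = m.mass[b] * (jxv[i] * jxv[jj] + jyv[i] * jyv[jj]);
          if (dv[i].rot && dv[jj].rot)
            v += m.inertia[b] * dv[i].s * dv[jj].s;
          Mmat(di, dj) += v;
        }
      }
    }

    // in-place Cholesky solve of the small SPD system M qdd = rhs
    {
      double* A = Mmat.memptr();
      const int n = nfree;
      for (int c = 0; c < n; ++c) {
        double d = A[c + c * n];
        for (int kk = 0; kk < c; ++kk) d -= A[c + kk * n] * A[c + kk * n];
        if (d <= 0.0) stop("dynamics solve failed at t=%f", t);
        d = std::sqrt(d);
        A[c + c * n] = d;
        for (int r2 = c + 1; r2 < n; ++r2) {
          double v = A[r2 + c * n];
          for (int kk = 0; kk < c; ++kk) v -= A[r2 + kk * n] * A[c + kk * n];
          A[r2 + c * n] = v / d;
        }
      }
      double* bq = rhs.memptr();
      for (int r2 = 0; r2 < n; ++r2) {
        double v = bq[r2];
        for (int kk = 0; kk < r2; ++kk) v -= A[r2 + kk * n] * bq[kk];
        bq[r2] = v / A[r2 + r2 * n];
      }
      for (int r2 = n - 1; r2 >= 0; --r2) {
        double v = bq[r2];
        for (int kk = r2 + 1; kk < n; ++kk) v -= A[kk + r2 * n] * bq[kk];
        bq[r2] = v / A[r2 + r2 * n];
      }
    }

    // ---- integrate (semi-implicit Euler)
    for (int i = 0; i < nfree; ++i) qd[freedofs[i]] += dt * rhs[i];
    for (int i = 0; i < nfree; ++i) q[freedofs[i]] += dt * qd[freedofs[i]];
    t += dt;
    if (!q.is_finite() || !qd.is_finite())
      stop("non-finite state at t=%f", t);

    // ---- update kinematics & muscle geometry, push delay channels
    fk(m, q, qd, k);
    mlen_prev = mlen;
    muscle_geometry(m, k, mlen, nullptr);
    fill_chan();
    buf.push(chan);

    if ((step + 1) % rec_every == 0) record();

    if (fall_check) {
      double cy = 0;
      for (int b = 0; b < m.nb; ++b) cy += m.mass[b] * k.cy[b];
      cy /= M_total;
      if (cy < fall_ratio * com_y0) { fell = true; break; }
    }
  }
  if (fell && (n_rec == 0 || traj(n_rec - 1, 0) < t)) record();

  List fin = List::create(
      _["q"] = NumericVector(q.begin(), q.end()),
      _["qd"] = NumericVector(qd.begin(), qd.end()),
      _["act"] = NumericVector(act.begin(), act.end()),
      _["lce"] = NumericVector(lce.begin(), lce.end()),
      _["time"] = t);
  return List::create(_["trajectory"] = traj, _["n_rec"] = n_rec,
                      _["fell"] = fell, _["end_time"] = t,
                      _["state"] = fin, _["com_y0"] = com_y0);
}
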