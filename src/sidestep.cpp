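// Three-mass frontal-plane sidestep model: passive mechanics, switching
// mobility controller, and the fixed-step (forward Euler) simulation loop.
//
// Mass indexing: 0 = trunk, 1 = right foot, 2 = left foot.
// Actuator indexing: 0 = inter-leg (foot-to-foot), 1 = right leg, 2 = left leg.
//
// Floating-point mirror symmetry (x -> -x, feet swapped, command negated) is a
// tested invariant; per-mass force accumulation therefore groups the two leg
// terms into commutative pairwise sums so the swap cannot reorder additions.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec2 {
  double x, z;
};

inline Vec2 operator+(Vec2 a, Vec2 b) { return {a.x + b.x, a.z + b.z}; }
inline Vec2 operator-(Vec2 a, Vec2 b) { return {a.x - b.x, a.z - b.z}; }
inline Vec2 operator*(double s, Vec2 a) { return {s * a.x, s * a.z}; }
inline double dot(Vec2 a, Vec2 b) { return a.x * b.x + a.z * b.z; }
inline double norm(Vec2 a) { return std::sqrt(a.x * a.x + a.z * a.z); }

struct Params {
  double m_trunk, m_foot, g;
  double L0_leg, L0_inter;
  double k_leg_flight, k_leg_contact, b_leg;
  double ext_mult, ext_ratio;
  double k_inter, b_inter;
  double k_ground, b_ground, b_friction;
  double k_aux, b_aux, d_aux;
  double d_balance;
  double swing_ratio;
  double gain;
  double eps1, eps2;
  double dt;
  double fall_z;
};

Params as_params(const List& p) {
  Params q;
  q.m_trunk = p["m_trunk"];
  q.m_foot = p["m_foot"];
  q.g = p["g"];
  q.L0_leg = p["L0_leg"];
  q.L0_inter = p["L0_inter"];
  q.k_leg_flight = p["k_leg_flight"];
  q.k_leg_contact = p["k_leg_contact"];
  q.b_leg = p["b_leg"];
  q.ext_mult = p["ext_mult"];
  q.ext_ratio = p["ext_ratio"];
  q.k_inter = p["k_inter"];
  q.b_inter = p["b_inter"];
  q.k_ground = p["k_ground"];
  q.b_ground = p["b_ground"];
  q.b_friction = p["b_friction"];
  q.k_aux = p["k_aux"];
  q.b_aux = p["b_aux"];
  q.d_aux = p["d_aux"];
  q.d_balance = p["d_balance"];
  q.swing_ratio = p["swing_ratio"];
  q.gain = p["gain"];
  q.eps1 = p["eps1"];
  q.eps2 = p["eps2"];
  q.dt = p["dt"];
  q.fall_z = p["fall_z"];
  return q;
}

// State layout matches the R side: t, then positions, then velocities.
struct State {
  double t;
  Vec2 p[3];
  Vec2 v[3];
};

State as_state(const NumericVector& s) {
  if (s.size() != 13) stop("state vector must have 13 elements");
  State st;
  st.t = s[0];
  for (int i = 0; i < 3; ++i) {
    st.p[i] = {s[1 + 2 * i], s[2 + 2 * i]};
    st.v[i] = {s[7 + 2 * i], s[8 + 2 * i]};
  }
  return st;
}

NumericVector state_vec(const State& st) {
  NumericVector s(13);
  s[0] = st.t;
  for (int i = 0; i < 3; ++i) {
    s[1 + 2 * i] = st.p[i].x;
    s[2 + 2 * i] = st.p[i].z;
    s[7 + 2 * i] = st.v[i].x;
    s[8 + 2 * i] = st.v[i].z;
  }
  s.attr("names") = CharacterVector::create(
      "t", "x_trunk", "z_trunk", "x_rfoot", "z_rfoot", "x_lfoot", "z_lfoot",
      "vx_trunk", "vz_trunk", "vx_rfoot", "vz_rfoot", "vx_lfoot", "vz_lfoot");
  return s;
}

// Contact / role classification. dir is the sign of the desired velocity
// (+1 rightward, -1 leftward). anterior = foot farther along dir; on the
// measure-zero tie the foot on the desired side of the trunk label is taken
// (right for dir > 0), which keeps the rule mirror-equivariant.
struct Contact {
  bool grounded[2];  // [0] right, [1] left
  int phase;         // 0 double support, 1 single support, 2 double flight
  int anterior;      // 1 = right foot, 2 = left foot (mass index)
};

Contact classify(const State& st, int dir) {
  Contact c;
  c.grounded[0] = st.p[1].z <= 0.0;
  c.grounded[1] = st.p[2].z <= 0.0;
  int n = (c.grounded[0] ? 1 : 0) + (c.grounded[1] ? 1 : 0);
  c.phase = (n == 2) ? 0 : (n == 1 ? 1 : 2);
  double proj_r = dir * st.p[1].x;
  double proj_l = dir * st.p[2].x;
  if (proj_r > proj_l)
    c.anterior = 1;
  else if (proj_l > proj_r)
    c.anterior = 2;
  else
    c.anterior = (dir > 0) ? 1 : 2;
  return c;
}

// Axial spring-damper force of one leg about its natural length. Positive
// pushes the endpoints apart (compression), negative pulls them together
// (extension). The elastic branch stiffens by ext_mult for elongation beyond
// ext_ratio * L0, continuously at the breakpoint.
double leg_axial_force(double L, double Ldot, bool grounded, const Params& q) {
  double k = grounded ? q.k_leg_contact : q.k_leg_flight;
  double Lb = q.ext_ratio * q.L0_leg;
  double fe;
  if (L <= Lb)
    fe = -k * (L - q.L0_leg);
  else
    fe = -k * (Lb - q.L0_leg) - q.ext_mult * k * (L - Lb);
  return fe - q.b_leg * Ldot;
}

// Unilateral viscoelastic ground: vertical Kelvin-Voigt clamped at zero,
// horizontal viscous resistance while penetrating.
Vec2 ground_force(Vec2 p, Vec2 v, const Params& q) {
  if (p.z > 0.0) return {0.0, 0.0};
  double fz = -q.k_ground * p.z - q.b_ground * v.z;
  if (fz < 0.0) fz = 0.0;
  return {-q.b_friction * v.x, fz};
}

// Horizontal trunk-foot separation keeper: engages strictly inside d_aux,
// spring on the gap deficit plus damping on the closing rate, applied as an
// equal-and-opposite horizontal pair (outward positive on the trunk side).
double aux_gap_force(double dx, double dvx, const Params& q) {
  double gap = std::fabs(dx);
  if (gap >= q.d_aux || dx == 0.0) return 0.0;
  double s = (dx > 0.0) ? 1.0 : -1.0;
  double gapdot = s * dvx;
  return s * (q.k_aux * (q.d_aux - gap) - q.b_aux * gapdot);
}

struct Forces {
  Vec2 f[3];  // total per-mass force, gravity included
};

// Passive forces only (leg + extension limit + inter-leg + ground + auxiliary
// trunk), gravity excluded so callers can test the decomposition.
Forces passive_forces(const State& st, const Contact& c, const Params& q) {
  Vec2 leg_on_trunk[2], aux_on_trunk[2];
  Vec2 foot_extra[2];  // reaction of leg + aux on each foot
  for (int f = 0; f < 2; ++f) {
    int m = f + 1;
    Vec2 d = st.p[0] - st.p[m];
    double L = norm(d);
    Vec2 u = (1.0 / L) * d;  // foot -> trunk
    double Ldot = dot(st.v[0] - st.v[m], u);
    double fa = leg_axial_force(L, Ldot, c.grounded[f], q);
    leg_on_trunk[f] = fa * u;
    double fax = aux_gap_force(st.p[0].x - st.p[m].x, st.v[0].x - st.v[m].x, q);
    aux_on_trunk[f] = {fax, 0.0};
    foot_extra[f] = (-1.0) * (leg_on_trunk[f] + aux_on_trunk[f]);
  }
  // inter-leg spring-damper between the two feet (left -> right axis)
  Vec2 d = st.p[1] - st.p[2];
  double L1 = norm(d);
  Vec2 u1 = (1.0 / L1) * d;
  double L1dot = dot(st.v[1] - st.v[2], u1);
  double f1 = -q.k_inter * (L1 - q.L0_inter) - q.b_inter * L1dot;
  Vec2 inter_r = f1 * u1;

  Forces F;
  F.f[0] = (leg_on_trunk[0] + leg_on_trunk[1]) + (aux_on_trunk[0] + aux_on_trunk[1]);
  F.f[1] = foot_extra[0] + inter_r + ground_force(st.p[1], st.v[1], q);
  F.f[2] = foot_extra[1] + (-1.0) * inter_r + ground_force(st.p[2], st.v[2], q);
  return F;
}

// Full switching-mobility control step (axes -> switching coefficients ->
// local/residual split -> mobility -> cross requests -> command mixing ->
// proportional force), for the command vd = (vd_x, 0).
struct Control {
  Vec2 e[3];       // axis unit vectors
  double a[3];     // switching coefficients
  Vec2 vdl[3], vdr[3], vi[3];
  double k[3];
  Vec2 vtilde[3];
  double fscalar[3];  // signed axial force magnitude
  Vec2 fvec[3];
  Forces F;  // per-mass actuator force (gravity-free)
};

Control control_step(const State& st, const Contact& c, double vd_x,
                     const Params& q) {
  Control ct;
  Vec2 vd = {vd_x, 0.0};
  int ant = c.anterior;       // mass index of anterior foot
  int post = 3 - ant;         // the other foot
  bool ant_gr = c.grounded[ant - 1];
  bool post_gr = c.grounded[post - 1];

  // leg axes foot -> trunk; inter-leg axis trailing foot -> leading foot
  Vec2 dlegs[2];
  double Lleg[2];
  for (int f = 0; f < 2; ++f) {
    dlegs[f] = st.p[0] - st.p[f + 1];
    Lleg[f] = norm(dlegs[f]);
    if (Lleg[f] == 0.0) stop("coincident trunk and foot positions");
    ct.e[f + 1] = (1.0 / Lleg[f]) * dlegs[f];
  }
  Vec2 d1 = st.p[ant] - st.p[post];
  double L1 = norm(d1);
  if (L1 == 0.0) stop("coincident foot positions");
  ct.e[0] = (1.0 / L1) * d1;

  // switching coefficients
  double Lpost = Lleg[post - 1];
  for (int f = 0; f < 2; ++f) {
    int m = f + 1;
    double sign = 1.0;
    if (m == ant && std::fabs(st.p[0].x - st.p[m].x) < q.d_balance)
      sign = -1.0;  // balance: trunk about to topple over the anterior leg
    else if (m == post && !c.grounded[f] && Lleg[f] > q.L0_leg)
      sign = -1.0;  // swing: over-extended posterior leg in flight
    double mag = c.grounded[f] ? 1.0 : 0.5;
    ct.a[m] = sign * mag;
  }
  if (c.phase == 0) {
    ct.a[0] = 0.0;
  } else if (c.phase == 2) {
    ct.a[0] = (Lpost > q.swing_ratio * q.L0_leg) ? -0.5 : 0.5;
  } else {
    // single support: neutral, except anterior-leg support with a long
    // airborne posterior leg, which retracts to swing the trailing foot in
    ct.a[0] = (ant_gr && !post_gr && Lpost > q.swing_ratio * q.L0_leg) ? -1.0 : 0.0;
  }

  // produced velocities: the velocity each actuator realizes at the trunk,
  // projected on its axis. For the legs this is the trunk (endpoint)
  // velocity; the inter-leg actuator spans the two feet and produces no
  // trunk velocity directly, so its produced velocity is zero.
  Vec2 rel[3];
  rel[0] = {0.0, 0.0};
  rel[1] = st.v[0];
  rel[2] = st.v[0];
  for (int i = 0; i < 3; ++i) ct.vi[i] = dot(rel[i], ct.e[i]) * ct.e[i];

  const double four_ln2 = 4.0 * std::log(2.0);
  for (int i = 0; i < 3; ++i) {
    ct.vdl[i] = (ct.a[i] * dot(ct.e[i], vd)) * ct.e[i];
    ct.vdr[i] = vd - ct.vdl[i];
    Vec2 diff = ct.vdl[i] - ct.vi[i];
    double num = dot(diff, diff) + q.eps1;
    double den = dot(ct.vdl[i], ct.vdl[i]) + q.eps2;
    ct.k[i] = std::exp(-four_ln2 * num / den);
  }

  for (int i = 0; i < 3; ++i) {
    int j1 = (i + 1) % 3, j2 = (i + 2) % 3;
    // requests v_di<-j = (e_i . v_dj_r) e_i; pairwise sums/products commute,
    // so the mirror swap of j1/j2 cannot change the result bit pattern
    Vec2 req = (ct.k[j1] * dot(ct.e[i], ct.vdr[j1]) +
                ct.k[j2] * dot(ct.e[i], ct.vdr[j2])) * ct.e[i];
    double inhib = (1.0 - ct.k[j1]) * (1.0 - ct.k[j2]);
    ct.vtilde[i] = inhib * ct.vdl[i] + req;
    ct.fscalar[i] = q.gain * dot(ct.vtilde[i] - ct.vi[i], ct.e[i]);
    ct.fvec[i] = ct.fscalar[i] * ct.e[i];
  }

  // application: legs push the trunk, reaction on the foot; inter-leg pushes
  // the leading foot, reaction on the trailing foot
  ct.F.f[0] = ct.fvec[1] + ct.fvec[2];
  ct.F.f[1] = (-1.0) * ct.fvec[1];
  ct.F.f[2] = (-1.0) * ct.fvec[2];
  ct.F.f[ant] = ct.F.f[ant] + ct.fvec[0];
  ct.F.f[post] = ct.F.f[post] + (-1.0) * ct.fvec[0];
  return ct;
}

// One forward-Euler step of m x'' = F_active + m g + F_passive.
void euler_step(State& st, const Forces& Fa, const Forces& Fp, const Params& q) {
  double m[3] = {q.m_trunk, q.m_foot, q.m_foot};
  State next = st;
  for (int i = 0; i < 3; ++i) {
    Vec2 acc = (1.0 / m[i]) * (Fa.f[i] + Fp.f[i]);
    acc.z -= q.g;
    next.p[i] = st.p[i] + q.dt * st.v[i];
    next.v[i] = st.v[i] + q.dt * acc;
  }
  next.t = st.t + q.dt;
  st = next;
}

inline int dir_of(double vd_x) { return (vd_x < 0.0) ? -1 : 1; }

}  // namespace

// ---------------------------------------------------------------- exported --

// [[Rcpp::export]]
NumericVector cpp_classify_contact(NumericVector state, int dir) {
  State st = as_state(state);
  Contact c = classify(st, dir);
  NumericVector out = NumericVector::create(
      _["grounded_r"] = c.grounded[0], _["grounded_l"] = c.grounded[1],
      _["phase"] = c.phase, _["anterior"] = c.anterior);
  return out;
}

// [[Rcpp::export]]
double cpp_leg_force(double L, double Ldot, bool grounded, List params) {
  if (L <= 0) stop("leg length must be positive");
  Params q = as_params(params);
  return leg_axial_force(L, Ldot, grounded, q);
}

// [[Rcpp::export]]
NumericVector cpp_ground_reaction(NumericVector pos, NumericVector vel,
                                  List params) {
  Params q = as_params(params);
  Vec2 f = ground_force({pos[0], pos[1]}, {vel[0], vel[1]}, q);
  return NumericVector::create(_["fx"] = f.x, _["fz"] = f.z);
}

// [[Rcpp::export]]
double cpp_aux_gap_force(double dx, double dvx, List params) {
  Params q = as_params(params);
  return aux_gap_force(dx, dvx, q);
}

// [[Rcpp::export]]
NumericMatrix cpp_passive_forces(NumericVector state, int dir, List params) {
  State st = as_state(state);
  Params q = as_params(params);
  Contact c = classify(st, dir);
  Forces F = passive_forces(st, c, q);
  NumericMatrix out(3, 2);
  for (int i = 0; i < 3; ++i) {
    out(i, 0) = F.f[i].x;
    out(i, 1) = F.f[i].z;
  }
  rownames(out) = CharacterVector::create("trunk", "rfoot", "lfoot");
  colnames(out) = CharacterVector::create("fx", "fz");
  return out;
}

// [[Rcpp::export]]
List cpp_control_step(NumericVector state, double vd_x, List params) {
  State st = as_state(state);
  Params q = as_params(params);
  Contact c = classify(st, dir_of(vd_x));
  Control ct = control_step(st, c, vd_x, q);
  NumericMatrix axes(3, 2), vdl(3, 2), vdr(3, 2), vi(3, 2), vtilde(3, 2),
      fmass(3, 2);
  NumericVector a(3), k(3), fs(3);
  for (int i = 0; i < 3; ++i) {
    axes(i, 0) = ct.e[i].x;
    axes(i, 1) = ct.e[i].z;
    vdl(i, 0) = ct.vdl[i].x;
    vdl(i, 1) = ct.vdl[i].z;
    vdr(i, 0) = ct.vdr[i].x;
    vdr(i, 1) = ct.vdr[i].z;
    vi(i, 0) = ct.vi[i].x;
    vi(i, 1) = ct.vi[i].z;
    vtilde(i, 0) = ct.vtilde[i].x;
    vtilde(i, 1) = ct.vtilde[i].z;
    a[i] = ct.a[i];
    k[i] = ct.k[i];
    fs[i] = ct.fscalar[i];
    fmass(i, 0) = ct.F.f[i].x;
    fmass(i, 1) = ct.F.f[i].z;
  }
  rownames(fmass) = CharacterVector::create("trunk", "rfoot", "lfoot");
  return List::create(
      _["axes"] = axes, _["a"] = a, _["v_local"] = vdl, _["v_residual"] = vdr,
      _["v_produced"] = vi, _["k"] = k, _["v_command"] = vtilde,
      _["force_axial"] = fs, _["force_mass"] = fmass,
      _["grounded_r"] = c.grounded[0], _["grounded_l"] = c.grounded[1],
      _["phase"] = c.phase, _["anterior"] = c.anterior);
}

// [[Rcpp::export]]
NumericVector cpp_step_dynamics(NumericVector state, NumericMatrix actuator,
                                int dir, List params) {
  State st = as_state(state);
  Params q = as_params(params);
  Contact c = classify(st, dir);
  Forces Fp = passive_forces(st, c, q);
  Forces Fa;
  for (int i = 0; i < 3; ++i) Fa.f[i] = {actuator(i, 0), actuator(i, 1)};
  euler_step(st, Fa, Fp, q);
  for (int i = 0; i < 3; ++i)
    if (!std::isfinite(st.p[i].x) || !std::isfinite(st.p[i].z) ||
        !std::isfinite(st.v[i].x) || !std::isfinite(st.v[i].z))
      stop("non-finite state after integration step at t = %f", st.t);
  return state_vec(st);
}

// Full simulation loop. The command is vd_pre until t_switch (ignored when
// NA), then vd_post. When reach_dist is finite and a switch is set, the run
// stops as soon as the trunk has moved reach_dist along the post-switch
// direction from its position at the switch instant, resolved at dt.
// status: 0 ran to t_max, 1 reached, 2 fell, 3 diverged.
// [[Rcpp::export]]
List cpp_simulate(NumericVector state0, List params, double vd_pre,
                  double t_switch, double vd_post, double t_max,
                  double reach_dist, int log_every, bool log_diag) {
  State st = as_state(state0);
  Params q = as_params(params);
  bool has_switch = std::isfinite(t_switch);
  bool track_reach = has_switch && std::isfinite(reach_dist);

  long n_steps = (long)std::ceil((t_max - st.t) / q.dt - 1e-9);
  if (n_steps < 0) n_steps = 0;
  long n_log = n_steps / log_every + 1;
  int ncol = log_diag ? 24 : 15;
  NumericMatrix traj(n_log, ncol);

  double x_ref = NA_REAL;
  bool switched = false, capture_switch = false;
  double sw_grounded_r = NA_REAL, sw_grounded_l = NA_REAL;
  double reach_time = NA_REAL, fall_time = NA_REAL;
  int status = 0;
  long row = 0;

  for (long step = 0;; ++step) {
    double vd_x = vd_pre;
    if (has_switch && st.t >= t_switch) {
      vd_x = vd_post;
      if (!switched) {
        switched = true;
        capture_switch = true;
        x_ref = st.p[0].x;
      }
    }
    int dir = dir_of(vd_x);
    Contact c = classify(st, dir);
    if (capture_switch) {
      sw_grounded_r = c.grounded[0];
      sw_grounded_l = c.grounded[1];
      capture_switch = false;
    }
    Control ct = control_step(st, c, vd_x, q);

    if (step % log_every == 0 && row < n_log) {
      traj(row, 0) = st.t;
      for (int i = 0; i < 3; ++i) {
        traj(row, 1 + 2 * i) = st.p[i].x;
        traj(row, 2 + 2 * i) = st.p[i].z;
        traj(row, 7 + 2 * i) = st.v[i].x;
        traj(row, 8 + 2 * i) = st.v[i].z;
      }
      traj(row, 13) = c.grounded[0];
      traj(row, 14) = c.grounded[1];
      if (log_diag) {
        traj(row, 15) = c.phase;
        traj(row, 16) = c.anterior;
        for (int i = 0; i < 3; ++i) {
          traj(row, 17 + i) = ct.a[i];
          traj(row, 20 + i) = ct.k[i];
        }
        traj(row, 23) = vd_x;
      }
      ++row;
    }

    // terminal checks before stepping further
    if (track_reach && switched) {
      double disp = (st.p[0].x - x_ref) * (vd_post < 0 ? -1.0 : 1.0);
      if (disp >= reach_dist) {
        status = 1;
        reach_time = st.t - t_switch;
        break;
      }
    }
    if (st.p[0].z < q.fall_z) {
      status = 2;
      fall_time = st.t;
      break;
    }
    if (step >= n_steps) break;

    Forces Fp = passive_forces(st, c, q);
    euler_step(st, ct.F, Fp, q);
    if (!std::isfinite(st.p[0].x) || !std::isfinite(st.p[0].z) ||
        !std::isfinite(st.v[0].x) || !std::isfinite(st.v[0].z) ||
        !std::isfinite(st.p[1].z) || !std::isfinite(st.p[2].z)) {
      status = 3;
      fall_time = st.t;
      break;
    }
  }

  return List::create(
      _["trajectory"] = traj(Range(0, row > 0 ? row - 1 : 0), _),
      _["status"] = status, _["reach_time"] = reach_time,
      _["fall_time"] = fall_time, _["t_switch"] = has_switch ? t_switch : NA_REAL,
      _["x_at_switch"] = x_ref, _["grounded_r_at_switch"] = sw_grounded_r,
      _["grounded_l_at_switch"] = sw_grounded_l,
      _["final_state"] = state_vec(st), _["log_diag"] = log_diag);
}
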