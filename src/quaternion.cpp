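// Quaternion kinematics: exact gyro integration, complementary orientation
// filter, batch vector rotation.  Convention: scalar-first (w,x,y,z);
// q maps sensor-frame vectors to earth-frame vectors, v_E = q v_S q*.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double kDegToRad = M_PI / 180.0;

struct Quat {
  double w, x, y, z;
};

static inline Quat qmul(const Quat &a, const Quat &b) {
  Quat r;
  r.w = a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z;
  r.x = a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y;
  r.y = a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x;
  r.z = a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w;
  return r;
}

static inline void qnormalize(Quat &q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  q.w /= n; q.x /= n; q.y /= n; q.z /= n;
}

// rotation quaternion for body-rate step: exp( [0, 0.5*omega*dt] )
static inline Quat qexp_step(double wx, double wy, double wz, double dt) {
  double ang = std::sqrt(wx * wx + wy * wy + wz * wz) * dt; // radians
  Quat r;
  if (ang < 1e-14) {
    r.w = 1.0; r.x = 0.5 * wx * dt; r.y = 0.5 * wy * dt; r.z = 0.5 * wz * dt;
    qnormalize(r);
    return r;
  }
  double h = 0.5 * ang, s = std::sin(h) / (ang / dt); // = sin(h)/|omega|
  r.w = std::cos(h); r.x = s * wx; r.y = s * wy; r.z = s * wz;
  return r;
}

// v_S = q* v_E q : earth-frame vector expressed in sensor coordinates
static inline void rotate_inv(const Quat &q, const double v[3], double out[3]) {
  // R(q)^T v via quaternion conjugation
  double w = q.w, x = -q.x, y = -q.y, z = -q.z; // conjugate
  double tw = -x * v[0] - y * v[1] - z * v[2];
  double tx =  w * v[0] + y * v[2] - z * v[1];
  double ty =  w * v[1] - x * v[2] + z * v[0];
  double tz =  w * v[2] + x * v[1] - y * v[0];
  out[0] = -tw * x + tx * w - ty * z + tz * y;
  out[1] = -tw * y + tx * z + ty * w - tz * x;
  out[2] = -tw * z - tx * y + ty * x + tz * w;
}

static inline void rotate_fwd(const Quat &q, const double v[3], double out[3]) {
  double w = q.w, x = q.x, y = q.y, z = q.z;
  double tw = -x * v[0] - y * v[1] - z * v[2];
  double tx =  w * v[0] + y * v[2] - z * v[1];
  double ty =  w * v[1] - x * v[2] + z * v[0];
  double tz =  w * v[2] + x * v[1] - y * v[0];
  out[0] = -tw * x + tx * w - ty * z + tz * y;
  out[1] = -tw * y + tx * z + ty * w - tz * x;
  out[2] = -tw * z - tx * y + ty * x + tz * w;
}

// [[Rcpp::export]]
NumericMatrix cpp_integrate_gyro(NumericMatrix omega_deg, double dt,
                                 NumericVector q0) {
  int n = omega_deg.nrow();
  NumericMatrix q(n, 4);
  Quat cur = {q0[0], q0[1], q0[2], q0[3]};
  qnormalize(cur);
  q(0, 0) = cur.w; q(0, 1) = cur.x; q(0, 2) = cur.y; q(0, 3) = cur.z;
  for (int i = 1; i < n; ++i) {
    // midpoint body rate over the step, in rad/s
    double wx = 0.5 * (omega_deg(i - 1, 0) + omega_deg(i, 0)) * kDegToRad;
    double wy = 0.5 * (omega_deg(i - 1, 1) + omega_deg(i, 1)) * kDegToRad;
    double wz = 0.5 * (omega_deg(i - 1, 2) + omega_deg(i, 2)) * kDegToRad;
    cur = qmul(cur, qexp_step(wx, wy, wz, dt));
    qnormalize(cur);
    q(i, 0) = cur.w; q(i, 1) = cur.x; q(i, 2) = cur.y; q(i, 3) = cur.z;
  }
  return q;
}

// Complementary filter: gyro propagation then SLERP of the estimated gravity
// direction toward the accelerometer direction by fraction `gain` per sample.
// [[Rcpp::export]]
List cpp_orientation_filter(NumericMatrix omega_deg, NumericMatrix acc,
                            double dt, double gain, NumericVector q0) {
  int n = omega_deg.nrow();
  NumericMatrix q(n, 4), grav(n, 3);
  const double ez[3] = {0.0, 0.0, 1.0};
  Quat cur = {q0[0], q0[1], q0[2], q0[3]};
  qnormalize(cur);
  double g[3];
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double wx = 0.5 * (omega_deg(i - 1, 0) + omega_deg(i, 0)) * kDegToRad;
      double wy = 0.5 * (omega_deg(i - 1, 1) + omega_deg(i, 1)) * kDegToRad;
      double wz = 0.5 * (omega_deg(i - 1, 2) + omega_deg(i, 2)) * kDegToRad;
      cur = qmul(cur, qexp_step(wx, wy, wz, dt));
      qnormalize(cur);
    }
    if (gain > 0.0) {
      double an = std::sqrt(acc(i, 0) * acc(i, 0) + acc(i, 1) * acc(i, 1) +
                            acc(i, 2) * acc(i, 2));
      if (an > 1e-9) {
        double m[3] = {acc(i, 0) / an, acc(i, 1) / an, acc(i, 2) / an};
        rotate_inv(cur, ez, g); // current gravity estimate, sensor frame
        double dp = g[0] * m[0] + g[1] * m[1] + g[2] * m[2];
        if (dp > 1.0) dp = 1.0; else if (dp < -1.0) dp = -1.0;
        double ang = std::acos(dp);
        // rotation axis g_est x g_meas (sensor frame)
        double ax = g[1] * m[2] - g[2] * m[1];
        double ay = g[2] * m[0] - g[0] * m[2];
        double az = g[0] * m[1] - g[1] * m[0];
        double al = std::sqrt(ax * ax + ay * ay + az * az);
        if (al > 1e-12 && ang > 0.0) {
          ax /= al; ay /= al; az /= al;
          double half = -0.5 * gain * ang; // q' = q (x) r with r = (a, -gain*ang)
          double s = std::sin(half);
          Quat r = {std::cos(half), s * ax, s * ay, s * az};
          cur = qmul(cur, r);
          qnormalize(cur);
        }
      }
    }
    q(i, 0) = cur.w; q(i, 1) = cur.x; q(i, 2) = cur.y; q(i, 3) = cur.z;
    rotate_inv(cur, ez, g);
    grav(i, 0) = g[0]; grav(i, 1) = g[1]; grav(i, 2) = g[2];
  }
  return List::create(_["q"] = q, _["gravity_head"] = grav);
}

// Rotate rows of v by the matching row of q. inverse = FALSE: sensor -> earth.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_vectors(NumericMatrix q, NumericMatrix v,
                                 bool inverse) {
  int n = v.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    Quat cur = {q(i, 0), q(i, 1), q(i, 2), q(i, 3)};
    double in[3] = {v(i, 0), v(i, 1), v(i, 2)}, o[3];
    if (inverse) rotate_inv(cur, in, o); else rotate_fwd(cur, in, o);
    out(i, 0) = o[0]; out(i, 1) = o[1]; out(i, 2) = o[2];
  }
  return out;
}

// Integrate orientation while adding a gravity-restoring angular velocity
// k * (e_z_head x nothing) -- specifically omega_r = restore_gain * (u x g)
// with u = earth-up in head frame target (0,0,1) and g the current gravity
// direction in the head frame; this nudges tilt back toward upright so the
// simulated tilt trajectory stays realistic.  Returns the orientation and the
// total (applied) angular velocity in deg/s.
// [[Rcpp::export]]
List cpp_simulate_orientation(NumericMatrix omega_in_deg, double dt,
                              double restore_gain, NumericVector q0) {
  int n = omega_in_deg.nrow();
  NumericMatrix q(n, 4), om(n, 3);
  const double ez[3] = {0.0, 0.0, 1.0};
  Quat cur = {q0[0], q0[1], q0[2], q0[3]};
  qnormalize(cur);
  double g[3];
  // applied omega at sample i (deg/s)
  for (int i = 0; i < n; ++i) {
    rotate_inv(cur, ez, g);
    // restoring angular velocity, rad/s: k * (u x g), u = (0,0,1) head target
    double rx = restore_gain * (-g[1]);
    double ry = restore_gain * (g[0]);
    double rz = 0.0;
    om(i, 0) = omega_in_deg(i, 0) + rx / kDegToRad;
    om(i, 1) = omega_in_deg(i, 1) + ry / kDegToRad;
    om(i, 2) = omega_in_deg(i, 2) + rz / kDegToRad;
    q(i, 0) = cur.w; q(i, 1) = cur.x; q(i, 2) = cur.y; q(i, 3) = cur.z;
    if (i < n - 1) {
      // forward Euler on the applied rate at sample i (the generator's truth
      // is then re-integrated exactly from the emitted omega series)
      double wx = om(i, 0) * kDegToRad, wy = om(i, 1) * kDegToRad,
             wz = om(i, 2) * kDegToRad;
      cur = qmul(cur, qexp_step(wx, wy, wz, dt));
      qnormalize(cur);
    }
  }
  return List::create(_["q"] = q, _["omega_deg"] = om);
}
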