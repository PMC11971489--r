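// Event-driven integrator for the one-way two-pool (pyruvate -> lactate)
// Bloch-McConnell system with gamma bolus inflow.
//
// The system is piecewise linear: between RF pulses each isochromat obeys
//   dP+/dt = (-1/T2p - kPL + i*2*pi*fp) P+
//   dL+/dt = (-1/T2l       + i*2*pi*fl) L+ + kPL P+
//   dPz/dt = (-1/T1p - kPL) Pz + u(t)
//   dLz/dt = (-1/T1l)       Lz + kPL Pz
// (no thermal recovery: hyperpolarized magnetization is non-renewable),
// so the propagator over each interval is an exact 2x2 triangular matrix
// exponential with closed-form entries; the bolus term u(t) is handled by
// the closed form for a constant rate over each (sub-)interval.

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using cplx = std::complex<double>;

// (exp(a*dt) - 1) / a, stable as a -> 0
template <typename T>
static inline T em1_over(const T& a, double dt) {
  T x = a * dt;
  if (std::abs(x) < 1e-6) {
    return dt * (1.0 + x / 2.0 + x * x / 6.0 + x * x * x / 24.0);
  }
  return (std::exp(x) - 1.0) / a;
}

// (exp(a*dt) - exp(b*dt)) / (a - b), stable as a -> b
template <typename T>
static inline T diffexp_over(const T& a, const T& b, double dt) {
  T d = a - b;
  if (std::abs(d * dt) < 1e-6) {
    T m = (a + b) / 2.0;
    T y = d * dt / 2.0;
    return dt * std::exp(m * dt) * (1.0 + y * y / 6.0);
  }
  return (std::exp(a * dt) - std::exp(b * dt)) / d;
}

// d/da [ (exp(a*dt)-1)/a ], stable as a -> 0
static inline double dg_da(double a, double dt) {
  double x = a * dt;
  if (std::abs(x) < 1e-6) {
    return dt * dt * (0.5 + x / 3.0 + x * x / 8.0);
  }
  return (dt * std::exp(x) - em1_over(a, dt)) / a;
}

// (g(a,dt) - g(b,dt)) / (a - b) with g = em1_over, stable as a -> b
static inline double ddiff_over(double a, double b, double dt) {
  double d = a - b;
  if (std::abs(d * dt) < 1e-8) {
    return dg_da((a + b) / 2.0, dt);
  }
  return (em1_over(a, dt) - em1_over(b, dt)) / d;
}

struct Propagator {
  // transverse, per isochromat
  std::vector<cplx> Ep, El, Cx;
  // longitudinal, isochromat-independent
  double Fp, Fl, Cz, Gp, Gl;
};

// [[Rcpp::export(name = ".bm_simulate_cpp")]]
Rcpp::ComplexVector bm_simulate_cpp(Rcpp::NumericMatrix events,
                                    Rcpp::NumericVector dts,
                                    double kpl,
                                    double t1p, double t1l,
                                    double t2p, double t2l,
                                    double fp, double fl,
                                    Rcpp::NumericVector iso,
                                    double b1_scale,
                                    int n_out) {
  const int n_iso = iso.size();
  const int n_dt = dts.size();
  const double twopi = 2.0 * M_PI;

  const double r2p = 1.0 / t2p, r2l = 1.0 / t2l;
  const double a2 = -1.0 / t1p - kpl;
  const double b2 = -1.0 / t1l;

  std::vector<Propagator> prop(n_dt);
  for (int k = 0; k < n_dt; ++k) {
    const double dt = dts[k];
    Propagator& pr = prop[k];
    pr.Ep.resize(n_iso);
    pr.El.resize(n_iso);
    pr.Cx.resize(n_iso);
    for (int j = 0; j < n_iso; ++j) {
      cplx ap(-r2p - kpl, twopi * (fp + iso[j]));
      cplx bl(-r2l, twopi * (fl + iso[j]));
      pr.Ep[j] = std::exp(ap * dt);
      pr.El[j] = std::exp(bl * dt);
      pr.Cx[j] = kpl * diffexp_over(ap, bl, dt);
    }
    pr.Fp = std::exp(a2 * dt);
    pr.Fl = std::exp(b2 * dt);
    pr.Cz = kpl * diffexp_over(a2, b2, dt);
    pr.Gp = em1_over(a2, dt);
    pr.Gl = kpl * ddiff_over(a2, b2, dt);
  }

  std::vector<cplx> P(n_iso, cplx(0.0, 0.0)), L(n_iso, cplx(0.0, 0.0));
  std::vector<double> Pz(n_iso, 0.0), Lz(n_iso, 0.0);

  Rcpp::ComplexVector out(n_out);
  for (int i = 0; i < n_out; ++i) {
    out[i].r = 0.0;
    out[i].i = 0.0;
  }

  const int n_ev = events.nrow();
  const double deg = M_PI / 180.0;

  for (int e = 0; e < n_ev; ++e) {
    const int type = static_cast<int>(events(e, 0));
    if (type == 1) {  // free evolution over dts[a-1] with constant inflow b
      const Propagator& pr = prop[static_cast<int>(events(e, 1)) - 1];
      const double u = events(e, 2);
      for (int j = 0; j < n_iso; ++j) {
        cplx Lnew = pr.El[j] * L[j] + pr.Cx[j] * P[j];
        P[j] *= pr.Ep[j];
        L[j] = Lnew;
        double Lznew = pr.Fl * Lz[j] + pr.Cz * Pz[j] + u * pr.Gl;
        Pz[j] = pr.Fp * Pz[j] + u * pr.Gp;
        Lz[j] = Lznew;
      }
    } else if (type == 2) {  // RF rotation on one pool about an in-plane axis
      const int target = static_cast<int>(events(e, 1));
      const double th = events(e, 2) * b1_scale * deg;
      const double ph = events(e, 3) * deg;
      const double c = std::cos(th), s = std::sin(th);
      const double ux = std::cos(ph), uy = std::sin(ph);
      // Rodrigues rotation about unit axis (ux, uy, 0) by angle th
      const double r11 = c + (1 - c) * ux * ux;
      const double r12 = (1 - c) * ux * uy;
      const double r13 = s * uy;
      const double r21 = (1 - c) * ux * uy;
      const double r22 = c + (1 - c) * uy * uy;
      const double r23 = -s * ux;
      const double r31 = -s * uy;
      const double r32 = s * ux;
      const double r33 = c;
      if (target == 1) {
        for (int j = 0; j < n_iso; ++j) {
          double x = P[j].real(), y = P[j].imag(), z = Pz[j];
          P[j] = cplx(r11 * x + r12 * y + r13 * z, r21 * x + r22 * y + r23 * z);
          Pz[j] = r31 * x + r32 * y + r33 * z;
        }
      } else {
        for (int j = 0; j < n_iso; ++j) {
          double x = L[j].real(), y = L[j].imag(), z = Lz[j];
          L[j] = cplx(r11 * x + r12 * y + r13 * z, r21 * x + r22 * y + r23 * z);
          Lz[j] = r31 * x + r32 * y + r33 * z;
        }
      }
    } else if (type == 3) {  // record isochromat-mean transverse signal
      const int target = static_cast<int>(events(e, 1));
      const int idx = static_cast<int>(events(e, 2)) - 1;
      const double demod = events(e, 3);
      cplx acc(0.0, 0.0);
      if (target == 1) {
        for (int j = 0; j < n_iso; ++j) acc += P[j];
      } else {
        for (int j = 0; j < n_iso; ++j) acc += L[j];
      }
      acc /= static_cast<double>(n_iso);
      acc *= std::exp(cplx(0.0, -demod));
      // echoes of a block accumulate coherently into the block's sample
      out[idx].r += acc.real();
      out[idx].i += acc.imag();
    } else if (type == 4) {  // crush: zero transverse magnetization of one pool
      const int target = static_cast<int>(events(e, 1));
      if (target == 1) {
        for (int j = 0; j < n_iso; ++j) P[j] = cplx(0.0, 0.0);
      } else {
        for (int j = 0; j < n_iso; ++j) L[j] = cplx(0.0, 0.0);
      }
    } else {
      Rcpp::stop("unknown event type");
    }
  }
  return out;
}
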