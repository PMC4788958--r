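// ODE integration core: a stack-machine evaluator for compiled kinetic-law
// bytecode and two adaptive integrators (explicit Dormand-Prince 5(4) and a
// linearly implicit Rosenbrock 2(3) for stiff systems). Kept dependency-free:
// models at this scale (tens of states) need no external linear algebra.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

enum Op {
  OP_CONST = 1, OP_SPECIES = 2, OP_PARAM = 3, OP_TIME = 4,
  OP_ADD = 10, OP_SUB = 11, OP_MUL = 12, OP_DIV = 13, OP_POW = 14, OP_NEG = 15,
  OP_EXP = 20, OP_LN = 21, OP_LOG10 = 22, OP_SQRT = 23, OP_ABS = 24,
  OP_FLOOR = 25, OP_CEIL = 26, OP_SIN = 27, OP_COS = 28, OP_TAN = 29,
  OP_LT = 30, OP_LE = 31, OP_GT = 32, OP_GE = 33, OP_EQ = 34, OP_NE = 35,
  OP_AND = 36, OP_OR = 37, OP_NOT = 38,
  OP_SELECT = 40, OP_MIN = 41, OP_MAX = 42
};

struct Program {
  std::vector<int> op, arg, starts;  // starts has n_rates+1 entries
  std::vector<double> consts;
  int n_rates;
};

struct OdeSystem {
  Program prog;
  std::vector<int> trip_i, trip_r;   // species index, rate index (0-based)
  std::vector<double> trip_c;        // stoichiometric coefficient
  std::vector<double> vols;          // per-species compartment size
  std::vector<bool> dynamic;
  int n;
  mutable std::vector<double> stack, rates;

  void eval_rates(double t, const double* y, const double* p) const {
    for (int r = 0; r < prog.n_rates; ++r) {
      int sp = -1;
      for (int k = prog.starts[r]; k < prog.starts[r + 1]; ++k) {
        const int o = prog.op[k], a = prog.arg[k];
        double v;
        switch (o) {
          case OP_CONST:   stack[++sp] = prog.consts[a]; break;
          case OP_SPECIES: stack[++sp] = y[a]; break;
          case OP_PARAM:   stack[++sp] = p[a]; break;
          case OP_TIME:    stack[++sp] = t; break;
          case OP_ADD: v = stack[sp--]; stack[sp] += v; break;
          case OP_SUB: v = stack[sp--]; stack[sp] -= v; break;
          case OP_MUL: v = stack[sp--]; stack[sp] *= v; break;
          case OP_DIV: v = stack[sp--]; stack[sp] /= v; break;
          case OP_POW: v = stack[sp--]; stack[sp] = std::pow(stack[sp], v); break;
          case OP_NEG: stack[sp] = -stack[sp]; break;
          case OP_EXP: stack[sp] = std::exp(stack[sp]); break;
          case OP_LN: stack[sp] = std::log(stack[sp]); break;
          case OP_LOG10: stack[sp] = std::log10(stack[sp]); break;
          case OP_SQRT: stack[sp] = std::sqrt(stack[sp]); break;
          case OP_ABS: stack[sp] = std::fabs(stack[sp]); break;
          case OP_FLOOR: stack[sp] = std::floor(stack[sp]); break;
          case OP_CEIL: stack[sp] = std::ceil(stack[sp]); break;
          case OP_SIN: stack[sp] = std::sin(stack[sp]); break;
          case OP_COS: stack[sp] = std::cos(stack[sp]); break;
          case OP_TAN: stack[sp] = std::tan(stack[sp]); break;
          case OP_LT: v = stack[sp--]; stack[sp] = stack[sp] < v; break;
          case OP_LE: v = stack[sp--]; stack[sp] = stack[sp] <= v; break;
          case OP_GT: v = stack[sp--]; stack[sp] = stack[sp] > v; break;
          case OP_GE: v = stack[sp--]; stack[sp] = stack[sp] >= v; break;
          case OP_EQ: v = stack[sp--]; stack[sp] = stack[sp] == v; break;
          case OP_NE: v = stack[sp--]; stack[sp] = stack[sp] != v; break;
          case OP_AND: v = stack[sp--]; stack[sp] = (stack[sp] != 0) && (v != 0); break;
          case OP_OR:  v = stack[sp--]; stack[sp] = (stack[sp] != 0) || (v != 0); break;
          case OP_NOT: stack[sp] = stack[sp] == 0; break;
          case OP_SELECT: {  // stack: cond, then, else
            double e = stack[sp--], th = stack[sp--];
            stack[sp] = (stack[sp] != 0) ? th : e;
            break;
          }
          case OP_MIN: v = stack[sp--]; stack[sp] = std::min(stack[sp], v); break;
          case OP_MAX: v = stack[sp--]; stack[sp] = std::max(stack[sp], v); break;
          default: stop("bad opcode");
        }
      }
      rates[r] = stack[0];
    }
  }

  void rhs(double t, const double* y, const double* p, double* dy) const {
    eval_rates(t, y, p);
    for (int i = 0; i < n; ++i) dy[i] = 0.0;
    for (size_t k = 0; k < trip_i.size(); ++k) {
      dy[trip_i[k]] += trip_c[k] * rates[trip_r[k]];
    }
    for (int i = 0; i < n; ++i) {
      if (!dynamic[i]) dy[i] = 0.0;
      else dy[i] /= vols[i];
    }
  }
};

static OdeSystem make_system(const List& prog, const NumericVector& vols,
                             const LogicalVector& dynamic,
                             const IntegerVector& trip_i,
                             const IntegerVector& trip_r,
                             const NumericVector& trip_c) {
  OdeSystem sys;
  sys.prog.op = as<std::vector<int> >(prog["op"]);
  sys.prog.arg = as<std::vector<int> >(prog["arg"]);
  sys.prog.starts = as<std::vector<int> >(prog["starts"]);
  sys.prog.consts = as<std::vector<double> >(prog["consts"]);
  sys.prog.n_rates = sys.prog.starts.size() - 1;
  sys.trip_i = as<std::vector<int> >(trip_i);
  sys.trip_r = as<std::vector<int> >(trip_r);
  sys.trip_c = as<std::vector<double> >(trip_c);
  sys.vols = as<std::vector<double> >(vols);
  sys.dynamic.resize(dynamic.size());
  for (int i = 0; i < dynamic.size(); ++i) sys.dynamic[i] = dynamic[i];
  sys.n = vols.size();
  sys.stack.resize(sys.prog.op.size() + 4);
  sys.rates.resize(std::max(sys.prog.n_rates, 1));
  return sys;
}

static double err_norm(const std::vector<double>& e, const std::vector<double>& y0,
                       const std::vector<double>& y1, double atol, double rtol) {
  double s = 0.0;
  const int n = e.size();
  for (int i = 0; i < n; ++i) {
    double sc = atol + rtol * std::max(std::fabs(y0[i]), std::fabs(y1[i]));
    double q = e[i] / sc;
    s += q * q;
  }
  return std::sqrt(s / n);
}

// ---- Dormand-Prince 5(4) ----------------------------------------------------

static void dopri5(const OdeSystem& sys, std::vector<double>& y,
                   const double* p, const NumericVector& times,
                   double rtol, double atol, double hmax, int maxsteps,
                   NumericMatrix& out) {
  static const double
    a21 = 1.0 / 5,
    a31 = 3.0 / 40, a32 = 9.0 / 40,
    a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9,
    a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
    a54 = -212.0 / 729,
    a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
    a64 = 49.0 / 176, a65 = -5103.0 / 18656,
    b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
    b5 = -2187.0 / 6784, b6 = 11.0 / 84,
    e1 = b1 - 5179.0 / 57600, e3 = b3 - 7571.0 / 16695, e4 = b4 - 393.0 / 640,
    e5 = b5 + 92097.0 / 339200, e6 = b6 - 187.0 / 2100, e7 = -1.0 / 40;

  const int n = sys.n;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      yt(n), ynew(n), err(n);
  double t = times[0];
  for (int i = 0; i < n; ++i) out(0, i) = y[i];

  double h = std::min(hmax, (times[times.size() - 1] - t) / 100.0);
  if (h <= 0) h = 1e-6;
  sys.rhs(t, y.data(), p, k1.data());
  bool have_k1 = true;
  int steps = 0;

  for (int ti = 1; ti < times.size(); ++ti) {
    const double tend = times[ti];
    while (t < tend) {
      if (++steps > maxsteps) {
        stop("integration failure: step limit (%d) exceeded at t=%g (h=%g)",
             maxsteps, t, h);
      }
      double hs = std::min(h, tend - t);
      if (!have_k1) { sys.rhs(t, y.data(), p, k1.data()); have_k1 = true; }

      for (int i = 0; i < n; ++i) yt[i] = y[i] + hs * a21 * k1[i];
      sys.rhs(t + hs / 5.0, yt.data(), p, k2.data());
      for (int i = 0; i < n; ++i)
        yt[i] = y[i] + hs * (a31 * k1[i] + a32 * k2[i]);
      sys.rhs(t + 3.0 * hs / 10.0, yt.data(), p, k3.data());
      for (int i = 0; i < n; ++i)
        yt[i] = y[i] + hs * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      sys.rhs(t + 4.0 * hs / 5.0, yt.data(), p, k4.data());
      for (int i = 0; i < n; ++i)
        yt[i] = y[i] + hs * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      sys.rhs(t + 8.0 * hs / 9.0, yt.data(), p, k5.data());
      for (int i = 0; i < n; ++i)
        yt[i] = y[i] + hs * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                             a64 * k4[i] + a65 * k5[i]);
      sys.rhs(t + hs, yt.data(), p, k6.data());
      for (int i = 0; i < n; ++i)
        ynew[i] = y[i] + hs * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                               b5 * k5[i] + b6 * k6[i]);
      sys.rhs(t + hs, ynew.data(), p, k7.data());
      for (int i = 0; i < n; ++i)
        err[i] = hs * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);

      double en = err_norm(err, y, ynew, atol, rtol);
      if (en <= 1.0) {
        t += hs;
        y = ynew;
        k1 = k7;  // FSAL
        double fac = (en > 0) ? 0.9 * std::pow(en, -0.2) : 5.0;
        h = std::min(hmax, hs * std::min(5.0, std::max(0.2, fac)));
      } else {
        double fac = 0.9 * std::pow(en, -0.2);
        h = hs * std::min(0.9, std::max(0.1, fac));
        if (h < 1e-14 * std::max(1.0, std::fabs(t))) {
          stop("integration failure: step size underflow at t=%g", t);
        }
      }
    }
    for (int i = 0; i < n; ++i) out(ti, i) = y[i];
  }
}

// ---- Rosenbrock 2(3), Shampine-Reichelt coefficients ------------------------

static void lu_solve(std::vector<double>& A, std::vector<int>& piv, int n,
                     bool factor, double* b) {
  if (factor) {
    for (int i = 0; i < n; ++i) piv[i] = i;
    for (int k = 0; k < n; ++k) {
      int pk = k;
      double mx = std::fabs(A[k * n + k]);
      for (int i = k + 1; i < n; ++i) {
        if (std::fabs(A[i * n + k]) > mx) { mx = std::fabs(A[i * n + k]); pk = i; }
      }
      if (mx == 0.0) stop("integration failure: singular iteration matrix");
      if (pk != k) {
        for (int j = 0; j < n; ++j) std::swap(A[k * n + j], A[pk * n + j]);
        std::swap(piv[k], piv[pk]);
      }
      for (int i = k + 1; i < n; ++i) {
        A[i * n + k] /= A[k * n + k];
        for (int j = k + 1; j < n; ++j) A[i * n + j] -= A[i * n + k] * A[k * n + j];
      }
    }
  }
  std::vector<double> x(n);
  for (int i = 0; i < n; ++i) x[i] = b[piv[i]];
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < i; ++j) x[i] -= A[i * n + j] * x[j];
  }
  for (int i = n - 1; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) x[i] -= A[i * n + j] * x[j];
    x[i] /= A[i * n + i];
  }
  for (int i = 0; i < n; ++i) b[i] = x[i];
}

static void rosenbrock23(const OdeSystem& sys, std::vector<double>& y,
                         const double* p, const NumericVector& times,
                         double rtol, double atol, double hmax, int maxsteps,
                         NumericMatrix& out) {
  const double d = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  const int n = sys.n;
  std::vector<double> f0(n), f1(n), f2(n), k1(n), k2(n), k3(n),
      yt(n), ynew(n), err(n), jac(n * n), W(n * n), ypert(n), fpert(n);
  std::vector<int> piv(n);
  double t = times[0];
  for (int i = 0; i < n; ++i) out(0, i) = y[i];
  double h = std::min(hmax, (times[times.size() - 1] - t) / 100.0);
  if (h <= 0) h = 1e-6;
  int steps = 0;

  for (int ti = 1; ti < times.size(); ++ti) {
    const double tend = times[ti];
    while (t < tend) {
      if (++steps > maxsteps) {
        stop("integration failure: step limit (%d) exceeded at t=%g (h=%g)",
             maxsteps, t, h);
      }
      double hs = std::min(h, tend - t);
      sys.rhs(t, y.data(), p, f0.data());
      // finite-difference Jacobian
      for (int j = 0; j < n; ++j) {
        ypert = y;
        double dy = std::sqrt(2.2e-16) * std::max(1e-8, std::fabs(y[j]));
        ypert[j] += dy;
        sys.rhs(t, ypert.data(), p, fpert.data());
        for (int i = 0; i < n; ++i) jac[i * n + j] = (fpert[i] - f0[i]) / dy;
      }
      // W = I - h*d*J
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) W[i * n + j] = -hs * d * jac[i * n + j];
        W[i * n + i] += 1.0;
      }
      std::vector<double> Wf = W;
      k1 = f0;
      lu_solve(Wf, piv, n, true, k1.data());
      for (int i = 0; i < n; ++i) yt[i] = y[i] + 0.5 * hs * k1[i];
      sys.rhs(t + 0.5 * hs, yt.data(), p, f1.data());
      for (int i = 0; i < n; ++i) k2[i] = f1[i] - k1[i];
      lu_solve(Wf, piv, n, false, k2.data());
      for (int i = 0; i < n; ++i) k2[i] += k1[i];
      for (int i = 0; i < n; ++i) ynew[i] = y[i] + hs * k2[i];
      sys.rhs(t + hs, ynew.data(), p, f2.data());
      for (int i = 0; i < n; ++i)
        k3[i] = f2[i] - e32 * (k2[i] - f1[i]) - 2.0 * (k1[i] - f0[i]);
      lu_solve(Wf, piv, n, false, k3.data());
      for (int i = 0; i < n; ++i)
        err[i] = (hs / 6.0) * (k1[i] - 2.0 * k2[i] + k3[i]);

      double en = err_norm(err, y, ynew, atol, rtol);
      if (en <= 1.0) {
        t += hs;
        y = ynew;
        double fac = (en > 0) ? 0.9 * std::pow(en, -1.0 / 3.0) : 5.0;
        h = std::min(hmax, hs * std::min(5.0, std::max(0.2, fac)));
      } else {
        double fac = 0.9 * std::pow(en, -1.0 / 3.0);
        h = hs * std::min(0.9, std::max(0.1, fac));
        if (h < 1e-14 * std::max(1.0, std::fabs(t))) {
          stop("integration failure: step size underflow at t=%g", t);
        }
      }
    }
    for (int i = 0; i < n; ++i) out(ti, i) = y[i];
  }
}

// [[Rcpp::export(name = ".ode_integrate_cpp")]]
NumericMatrix ode_integrate_cpp(List prog, NumericVector y0, NumericVector params,
                                NumericVector vols, LogicalVector dynamic,
                                IntegerVector trip_i, IntegerVector trip_r,
                                NumericVector trip_c, NumericVector times,
                                double rtol, double atol, double hmax,
                                int maxsteps, std::string method) {
  OdeSystem sys = make_system(prog, vols, dynamic, trip_i, trip_r, trip_c);
  std::vector<double> y = as<std::vector<double> >(y0);
  NumericMatrix out(times.size(), sys.n);
  std::vector<double> p = as<std::vector<double> >(params);
  if (method == "dopri5") {
    dopri5(sys, y, p.data(), times, rtol, atol, hmax, maxsteps, out);
  } else if (method == "rosenbrock") {
    rosenbrock23(sys, y, p.data(), times, rtol, atol, hmax, maxsteps, out);
  } else {
    stop("unknown method '%s'", method.c_str());
  }
  return out;
}

// [[Rcpp::export(name = ".ode_rates_cpp")]]
NumericVector ode_rates_cpp(List prog, NumericVector y, NumericVector params,
                            NumericVector vols, LogicalVector dynamic,
                            IntegerVector trip_i, IntegerVector trip_r,
                            NumericVector trip_c, double t) {
  OdeSystem sys = make_system(prog, vols, dynamic, trip_i, trip_r, trip_c);
  std::vector<double> dy(sys.n);
  sys.rhs(t, REAL(y), REAL(params), dy.data());
  return wrap(dy);
}
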