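// Additive C-alpha structure-based (Go-like) potential and overdamped
// Langevin integrator. Energies are in kT at the reference temperature;
// coordinates in Angstrom. All indices arrive 0-based from R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Topology {
  // bonds
  std::vector<int> bi, bj;
  std::vector<double> br0;
  // native contacts
  std::vector<int> ci, cj;
  std::vector<double> cr0;
  // non-native excluded-volume pairs
  std::vector<int> ei, ej;
  // q_w pair list (|i-j| >= minSepQ) with native distances and 2*sigma^2
  std::vector<int> qi, qj;
  std::vector<double> qr0, q2s2;
};

inline void toVec(const IntegerVector& v, std::vector<int>& out) {
  out.assign(v.begin(), v.end());
}
inline void toVec(const NumericVector& v, std::vector<double>& out) {
  out.assign(v.begin(), v.end());
}

// energy and gradient of the Go potential; grad accumulated into g
double goEnergyGrad(const std::vector<double>& x, const Topology& top,
                    double bondK, double depth, double width,
                    double exclR, double exclK, std::vector<double>& g) {
  std::fill(g.begin(), g.end(), 0.0);
  double E = 0.0;
  const double w2 = width * width;
  for (size_t b = 0; b < top.bi.size(); ++b) {
    const int i = top.bi[b], j = top.bj[b];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - top.br0[b];
    E += 0.5 * bondK * dr * dr;
    double f = bondK * dr / std::max(r, 1e-12);
    g[3 * i] += f * dx; g[3 * i + 1] += f * dy; g[3 * i + 2] += f * dz;
    g[3 * j] -= f * dx; g[3 * j + 1] -= f * dy; g[3 * j + 2] -= f * dz;
  }
  for (size_t c = 0; c < top.ci.size(); ++c) {
    const int i = top.ci[c], j = top.cj[c];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - top.cr0[c];
    double e = -depth * std::exp(-dr * dr / (2.0 * w2));
    E += e;
    double f = -e * dr / (w2 * std::max(r, 1e-12));
    g[3 * i] += f * dx; g[3 * i + 1] += f * dy; g[3 * i + 2] += f * dz;
    g[3 * j] -= f * dx; g[3 * j + 1] -= f * dy; g[3 * j + 2] -= f * dz;
  }
  for (size_t p = 0; p < top.ei.size(); ++p) {
    const int i = top.ei[p], j = top.ej[p];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= exclR * exclR) continue;
    double r = std::sqrt(r2);
    double dr = exclR - r;
    E += 0.5 * exclK * dr * dr;
    double f = -exclK * dr / std::max(r, 1e-12);
    g[3 * i] += f * dx; g[3 * i + 1] += f * dy; g[3 * i + 2] += f * dz;
    g[3 * j] -= f * dx; g[3 * j + 1] -= f * dy; g[3 * j + 2] -= f * dz;
  }
  return E;
}

// Q_w of a configuration; optionally accumulate dQw/dx into gq
double qwValueGrad(const std::vector<double>& x, const Topology& top,
                   std::vector<double>* gq) {
  const size_t np = top.qi.size();
  double q = 0.0;
  if (gq) std::fill(gq->begin(), gq->end(), 0.0);
  for (size_t p = 0; p < np; ++p) {
    const int i = top.qi[p], j = top.qj[p];
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - top.qr0[p];
    double term = std::exp(-dr * dr / top.q2s2[p]);
    q += term;
    if (gq) {
      double f = -2.0 * term * dr / (top.q2s2[p] * std::max(r, 1e-12));
      (*gq)[3 * i] += f * dx; (*gq)[3 * i + 1] += f * dy;
      (*gq)[3 * i + 2] += f * dz;
      (*gq)[3 * j] -= f * dx; (*gq)[3 * j + 1] -= f * dy;
      (*gq)[3 * j + 2] -= f * dz;
    }
  }
  q /= double(np);
  if (gq)
    for (double& v : *gq) v /= double(np);
  return q;
}

Topology makeTopology(IntegerVector bi, IntegerVector bj, NumericVector br0,
                      IntegerVector ci, IntegerVector cj, NumericVector cr0,
                      IntegerVector ei, IntegerVector ej,
                      IntegerVector qi, IntegerVector qj,
                      NumericVector qr0, NumericVector q2s2) {
  Topology top;
  toVec(bi, top.bi); toVec(bj, top.bj); toVec(br0, top.br0);
  toVec(ci, top.ci); toVec(cj, top.cj); toVec(cr0, top.cr0);
  toVec(ei, top.ei); toVec(ej, top.ej);
  toVec(qi, top.qi); toVec(qj, top.qj);
  toVec(qr0, top.qr0); toVec(q2s2, top.q2s2);
  return top;
}

} // namespace

// [[Rcpp::export]]
List cppGoEnergy(NumericMatrix X,
                 IntegerVector bi, IntegerVector bj, NumericVector br0,
                 IntegerVector ci, IntegerVector cj, NumericVector cr0,
                 IntegerVector ei, IntegerVector ej,
                 double bondK, double depth, double width,
                 double exclR, double exclK) {
  const int n = X.nrow();
  Topology top = makeTopology(bi, bj, br0, ci, cj, cr0, ei, ej,
                              IntegerVector(0), IntegerVector(0),
                              NumericVector(0), NumericVector(0));
  std::vector<double> x(3 * n), g(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = X(i, k);
  double E = goEnergyGrad(x, top, bondK, depth, width, exclR, exclK, g);
  NumericMatrix G(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) G(i, k) = g[3 * i + k];
  return List::create(_["energy"] = E, _["gradient"] = G);
}

// Overdamped Langevin (Euler-Maruyama) on the Go potential, optionally with
// a harmonic umbrella bias on Q_w. Uses R's RNG: seed with set.seed() in R.
// [[Rcpp::export]]
List cppLangevin(NumericMatrix X0,
                 IntegerVector bi, IntegerVector bj, NumericVector br0,
                 IntegerVector ci, IntegerVector cj, NumericVector cr0,
                 IntegerVector ei, IntegerVector ej,
                 IntegerVector qi, IntegerVector qj,
                 NumericVector qr0, NumericVector q2s2,
                 double bondK, double depth, double width,
                 double exclR, double exclK,
                 double kT, double dt, double gamma,
                 int nsteps, int stride,
                 double biasCenter, double biasK,
                 double abortEnergy) {
  const int n = X0.nrow();
  Topology top = makeTopology(bi, bj, br0, ci, cj, cr0, ei, ej,
                              qi, qj, qr0, q2s2);
  std::vector<double> x(3 * n), g(3 * n), gq;
  const bool biased = biasK > 0.0;
  if (biased) gq.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = X0(i, k);

  const int nframes = nsteps / stride;
  NumericVector frames(double(nframes) * n * 3);
  NumericVector energies(nframes), qwOut(nframes);
  const double pref = dt / gamma;
  const double noise = std::sqrt(2.0 * kT * dt / gamma);
  bool aborted = false;
  int stepsDone = 0, rec = 0;

  for (int s = 1; s <= nsteps; ++s) {
    double E = goEnergyGrad(x, top, bondK, depth, width, exclR, exclK, g);
    if (!std::isfinite(E) || std::fabs(E) > abortEnergy) { aborted = true; break; }
    if (biased) {
      double q = qwValueGrad(x, top, &gq);
      double dU = biasK * (q - biasCenter);
      for (int k = 0; k < 3 * n; ++k) g[k] += dU * gq[k];
    }
    for (int k = 0; k < 3 * n; ++k)
      x[k] += -pref * g[k] + noise * norm_rand();
    stepsDone = s;
    if (s % stride == 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[double(rec) * n * 3 + i * 3 + k] = x[3 * i + k];
      std::vector<double> gdummy(0);
      energies[rec] = goEnergyGrad(x, top, bondK, depth, width, exclR,
                                   exclK, g);
      qwOut[rec] = qwValueGrad(x, top, nullptr);
      ++rec;
    }
  }
  NumericMatrix Xf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) Xf(i, k) = x[3 * i + k];
  return List::create(_["frames"] = frames, _["energy"] = energies,
                      _["qw"] = qwOut, _["final"] = Xf,
                      _["recorded"] = rec, _["aborted"] = aborted,
                      _["stepsDone"] = stepsDone);
}

// SMACOF majorization for 2D stress embedding. Returns coordinates and the
// per-iteration normalized stress trace. Coincident points are separated by
// a 1e-9 jitter drawn from R's RNG (seeded by the caller).
// [[Rcpp::export]]
List cppSmacof(NumericMatrix delta, NumericMatrix X0, int maxIter,
               double tol) {
  const int n = delta.nrow();
  std::vector<double> x(n), y(n), bx(n), by(n);
  for (int i = 0; i < n; ++i) { x[i] = X0(i, 0); y[i] = X0(i, 1); }
  double denom = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) denom += delta(i, j) * delta(i, j);
  std::vector<double> trace;
  double sPrev = R_PosInf;
  int iter = 0;
  std::vector<double> d(size_t(n) * n, 0.0);
  for (;;) {
    bool coincident = false;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j];
        double dij = std::sqrt(dx * dx + dy * dy);
        if (dij == 0.0) coincident = true;
        d[size_t(i) * n + j] = d[size_t(j) * n + i] = dij;
      }
    if (coincident) {
      for (int i = 0; i < n; ++i) {
        x[i] += 1e-9 * norm_rand();
        y[i] += 1e-9 * norm_rand();
      }
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = x[i] - x[j], dy = y[i] - y[j];
          d[size_t(i) * n + j] = d[size_t(j) * n + i] =
            std::sqrt(dx * dx + dy * dy);
        }
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r = delta(i, j) - d[size_t(i) * n + j];
        s += r * r;
      }
    s /= denom;
    trace.push_back(s);
    if (std::fabs(sPrev - s) < tol || iter >= maxIter) break;
    sPrev = s;
    ++iter;
    // Guttman transform: X <- B(X) X / n
    std::fill(bx.begin(), bx.end(), 0.0);
    std::fill(by.begin(), by.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double bxi = 0.0, byi = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dij = d[size_t(i) * n + j];
        double b = dij > 0.0 ? delta(i, j) / dij : 0.0;
        bxi += b * (x[i] - x[j]);
        byi += b * (y[i] - y[j]);
      }
      bx[i] = bxi / n;
      by[i] = byi / n;
    }
    x.swap(bx);
    y.swap(by);
  }
  NumericMatrix X(n, 2);
  for (int i = 0; i < n; ++i) { X(i, 0) = x[i]; X(i, 1) = y[i]; }
  return List::create(_["X"] = X, _["trace"] = NumericVector(trace.begin(),
                      trace.end()), _["iterations"] = iter);
}
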