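#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear recurrent self-coupling approximating the inverted
// N-shaped r-nullcline of rate models with adaptation.
inline double Fpl(double r) {
  if (r <= -0.5) return -1.0 - r;
  if (r >=  0.5) return  1.0 - r;
  return r;
}

// Euler-Maruyama integration of a single column:
//   eps * dr/dt = F(r) - a + W * (neighborSum - nNeighbors * r) + I
//        da/dt = g*r - a + f + sqrt(2Q) * xi   (noise in the adaptation variable)
// neighborSum is the per-step sum of neighbor rate variables (length 1 for a
// constant clamp, or nsteps for a time series); zero with nNeighbors = 0 for
// an isolated unit. Uses R's RNG stream (seeded from R with set.seed()).
// [[Rcpp::export]]
List cpp_simulate_column(double r0, double a0, int nsteps, double dt,
                         double eps, double g, double f, double Q,
                         double W, double I,
                         NumericVector neighborSum, int nNeighbors,
                         int recordEvery, bool noiseInRate) {
  int nrec = nsteps / recordEvery;
  NumericVector rOut(nrec), aOut(nrec);
  IntegerVector sOut(nrec);
  double r = r0, a = a0;
  double sq = std::sqrt(2.0 * Q * dt);
  bool clampConst = (neighborSum.size() == 1);
  int k = 0;
  for (int t = 0; t < nsteps; ++t) {
    double nb = clampConst ? neighborSum[0] : neighborSum[t];
    double coup = (nNeighbors > 0) ? W * (nb - nNeighbors * r) : 0.0;
    double xi = sq * R::norm_rand();
    double dr = (Fpl(r) - a + coup + I) * dt / eps;
    double da = (g * r - a + f) * dt;
    if (noiseInRate) { dr += xi / eps; } else { da += xi; }
    r += dr;
    a += da;
    if ((t + 1) % recordEvery == 0) {
      rOut[k] = r; aOut[k] = a;
      sOut[k] = (r > 0.0) ? 1 : 0;   // S(t) = Theta[r(t)], r == 0 counts Off
      ++k;
    }
  }
  return List::create(_["r"] = rOut, _["a"] = aOut, _["S"] = sOut,
                      _["r_final"] = r, _["a_final"] = a);
}

// 2-D lattice of coupled columns, 4-neighbor discrete Laplacian.
// I is a per-site external current (stimulus + attention patches baked in by
// the caller). Returns the binary field S recorded every recordEvery steps
// plus the final (r, a) state so protocols can be chained across periods.
// [[Rcpp::export]]
List cpp_simulate_lattice(NumericMatrix r, NumericMatrix a,
                          int nsteps, double dt,
                          double eps, double g, double f, double Q,
                          double W, NumericMatrix I,
                          int recordEvery, bool periodic) {
  int nx = r.nrow(), ny = r.ncol();
  int nrec = nsteps / recordEvery;
  IntegerVector S(Dimension(nx, ny, nrec));
  NumericMatrix rn(nx, ny);
  double sq = std::sqrt(2.0 * Q * dt);
  int k = 0;
  for (int t = 0; t < nsteps; ++t) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int ip = i + 1, im = i - 1, jp = j + 1, jm = j - 1;
        double lap;
        if (periodic) {
          if (ip == nx) ip = 0; if (im < 0) im = nx - 1;
          if (jp == ny) jp = 0; if (jm < 0) jm = ny - 1;
          lap = r(ip, j) + r(im, j) + r(i, jp) + r(i, jm) - 4.0 * r(i, j);
        } else {
          lap = 0.0; int nn = 0;
          if (ip < nx) { lap += r(ip, j); ++nn; }
          if (im >= 0) { lap += r(im, j); ++nn; }
          if (jp < ny) { lap += r(i, jp); ++nn; }
          if (jm >= 0) { lap += r(i, jm); ++nn; }
          lap -= nn * r(i, j);
        }
        rn(i, j) = r(i, j) + (Fpl(r(i, j)) - a(i, j) + W * lap + I(i, j)) * dt / eps;
      }
    }
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        a(i, j) += (g * r(i, j) - a(i, j) + f) * dt + sq * R::norm_rand();
        r(i, j) = rn(i, j);
      }
    }
    if ((t + 1) % recordEvery == 0) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          S[i + nx * j + nx * ny * k] = (r(i, j) > 0.0) ? 1 : 0;
      ++k;
    }
  }
  return List::create(_["S"] = S, _["r_final"] = r, _["a_final"] = a);
}

// Synchronous binary-unit (Glauber-like) lattice dynamics on a periodic
// 2-D lattice. Per-bin flip probabilities clip(w * dt, 0, 1) with
//   w(0->1) = alpha1 + beta1 * Lap(S),  w(1->0) = alpha2 - beta2 * Lap(S).
// Returns recorded fields and the number of rate-clipping events.
// [[Rcpp::export]]
List cpp_simulate_binary(IntegerMatrix S0, int nsteps, double dt,
                         double alpha1, double alpha2,
                         double beta1, double beta2, int recordEvery) {
  int nx = S0.nrow(), ny = S0.ncol();
  int nrec = nsteps / recordEvery;
  IntegerVector out(Dimension(nx, ny, nrec));
  IntegerMatrix S(clone(S0)), Sn(nx, ny);
  long clipped = 0;
  int k = 0;
  for (int t = 0; t < nsteps; ++t) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int ip = (i + 1 == nx) ? 0 : i + 1, im = (i == 0) ? nx - 1 : i - 1;
        int jp = (j + 1 == ny) ? 0 : j + 1, jm = (j == 0) ? ny - 1 : j - 1;
        int lap = S(ip, j) + S(im, j) + S(i, jp) + S(i, jm) - 4 * S(i, j);
        double w = S(i, j) ? (alpha2 - beta2 * lap) : (alpha1 + beta1 * lap);
        if (w < 0.0) { w = 0.0; ++clipped; }
        double p = w * dt;
        if (p > 1.0) { p = 1.0; ++clipped; }
        Sn(i, j) = (R::unif_rand() < p) ? 1 - S(i, j) : S(i, j);
      }
    }
    S = Sn; Sn = IntegerMatrix(nx, ny);
    if ((t + 1) % recordEvery == 0) {
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          out[i + nx * j + nx * ny * k] = S(i, j);
      ++k;
    }
  }
  return List::create(_["S"] = out, _["clipped"] = clipped);
}

// Exact continuous-time (Gillespie) realization of the binary-unit master
// equation for small systems with an arbitrary neighbor list (0-based,
// column j lists neighbors of unit j, padded with -1). States are sampled
// on a regular grid of sampleDt for histogramming.
// [[Rcpp::export]]
IntegerMatrix cpp_gillespie_binary(IntegerVector S0, IntegerMatrix nbr,
                                   double alpha1, double alpha2,
                                   double beta1, double beta2,
                                   double duration, double sampleDt) {
  int n = S0.size();
  int nsamp = (int) std::floor(duration / sampleDt);
  IntegerMatrix samples(n, nsamp);
  std::vector<int> S(S0.begin(), S0.end());
  std::vector<double> w(n);
  double t = 0.0;
  int k = 0;
  double tnext = sampleDt;
  auto rate = [&](int u) {
    int lap = 0, deg = 0;
    for (int m = 0; m < nbr.nrow(); ++m) {
      int v = nbr(m, u);
      if (v < 0) break;
      lap += S[v]; ++deg;
    }
    lap -= deg * S[u];
    double r = S[u] ? (alpha2 - beta2 * lap) : (alpha1 + beta1 * lap);
    return r > 0.0 ? r : 0.0;
  };
  for (int u = 0; u < n; ++u) w[u] = rate(u);
  while (k < nsamp) {
    double wtot = 0.0;
    for (int u = 0; u < n; ++u) wtot += w[u];
    double tau = (wtot > 0.0) ? R::exp_rand() / wtot : R_PosInf;
    double tev = t + tau;
    while (k < nsamp && tnext <= tev) {
      for (int u = 0; u < n; ++u) samples(u, k) = S[u];
      ++k;
      tnext += sampleDt;
    }
    if (!R_FINITE(tev)) break;
    t = tev;
    double x = R::unif_rand() * wtot, acc = 0.0;
    int flip = n - 1;
    for (int u = 0; u < n; ++u) { acc += w[u]; if (x <= acc) { flip = u; break; } }
    S[flip] = 1 - S[flip];
    w[flip] = rate(flip);
    for (int m = 0; m < nbr.nrow(); ++m) {
      int v = nbr(m, flip);
      if (v < 0) break;
      w[v] = rate(v);
    }
  }
  return samples;
}
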