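#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double BIG = 1e20;

// 1-D squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < (double)q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared distance (grid units) from every node to the nearest node where
// mask is true.  Nodes where the mask is true get 0.
static std::vector<double> edt3(const std::vector<char>& mask,
                                int nx, int ny, int nz) {
  std::vector<double> d(mask.size());
  for (size_t i = 0; i < mask.size(); i++) d[i] = mask[i] ? 0.0 : BIG;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), g(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      size_t off = (size_t)nx * (j + (size_t)ny * k);
      f.assign(d.begin() + off, d.begin() + off + nx);
      dt1d(f, g, v, z);
      std::copy(g.begin(), g.begin() + nx, d.begin() + off);
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      f.resize(ny);
      for (int j = 0; j < ny; j++) f[j] = d[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(f, g, v, z);
      for (int j = 0; j < ny; j++) d[i + (size_t)nx * (j + (size_t)ny * k)] = g[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      f.resize(nz);
      for (int k = 0; k < nz; k++) f[k] = d[i + (size_t)nx * (j + (size_t)ny * k)];
      dt1d(f, g, v, z);
      for (int k = 0; k < nz; k++) d[i + (size_t)nx * (j + (size_t)ny * k)] = g[k];
    }
  return d;
}

// Signed level function for the solute region on grid nodes.
// A(x) = min_k |x - c_k| - (r_k + probe) is the signed distance to the
// solvent-accessible surface; eroding the inflated region by the probe
// (via a Euclidean distance transform to the A >= 0 set) recovers the
// molecular (solvent-excluded) interior: L <= 0 inside the solute.
// [[Rcpp::export]]
NumericVector level_set_cpp(IntegerVector dims, NumericVector origin, double h,
                            NumericMatrix atoms, double probe) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  const int na = atoms.nrow();
  NumericVector L(n);
  std::vector<double> A(n);
  for (int k = 0; k < nz; k++) {
    double zc = origin[2] + h * k;
    for (int j = 0; j < ny; j++) {
      double yc = origin[1] + h * j;
      for (int i = 0; i < nx; i++) {
        double xc = origin[0] + h * i;
        double best = BIG;
        for (int a = 0; a < na; a++) {
          double dx = xc - atoms(a, 0), dy = yc - atoms(a, 1), dz = zc - atoms(a, 2);
          double dist = std::sqrt(dx * dx + dy * dy + dz * dz) - (atoms(a, 3) + probe);
          if (dist < best) best = dist;
        }
        A[i + (size_t)nx * (j + (size_t)ny * k)] = best;
      }
    }
  }
  if (probe <= 0.0 || na == 0) {
    for (size_t i = 0; i < n; i++) L[i] = A[i];
    return L;
  }
  std::vector<char> outside(n);
  for (size_t i = 0; i < n; i++) outside[i] = A[i] >= 0.0 ? 1 : 0;
  std::vector<double> d2 = edt3(outside, nx, ny, nz);
  for (size_t i = 0; i < n; i++) {
    if (A[i] >= 0.0) {
      L[i] = A[i];                        // outside SAS: solvent, positive
    } else {
      double s = std::sqrt(d2[i]) * h;    // distance to the A>=0 region
      // Node is solvent-excluded (protein) iff no probe sphere centred in the
      // A>=0 region can cover it, i.e. s >= probe.  Signed value: probe - s
      // is < 0 for protein interior, > 0 for reentrant solvent.
      double reent = probe - s;
      L[i] = std::max(A[i], reent);
    }
  }
  return L;
}

// Red-black SOR solution of the linearized Poisson-Boltzmann equation
//   div(eps grad phi) - kbar2 * phi = -source_density
// discretized on a uniform grid.  Face dielectrics are interpolated from the
// nodal level function L (harmonic mean weighted by the in/out fraction of
// each link).  `src` must be 4*pi*C*q/h accumulated on nodes; `phi` carries
// Dirichlet values on the outer faces (interior values are the initial
// guess).  `kbar2` (A^-2, already including the solvent scaling) is applied
// at nodes with L > 0.
// [[Rcpp::export]]
List sor_solve_cpp(IntegerVector dims, double h, NumericVector L,
                   double eps_in, double eps_out, double kbar2,
                   NumericVector src, NumericVector phi0,
                   double tol, int maxiter, double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> phi(phi0.begin(), phi0.end());

  auto idx = [&](int i, int j, int k) -> size_t {
    return (size_t)i + (size_t)nx * (j + (size_t)ny * k);
  };
  auto face_eps = [&](double la, double lb) -> double {
    bool ia = la <= 0.0, ib = lb <= 0.0;
    if (ia && ib) return eps_in;
    if (!ia && !ib) return eps_out;
    double t0 = la / (la - lb);            // crossing position along the link
    double fin = ia ? t0 : 1.0 - t0;       // fraction of the link inside
    return 1.0 / (fin / eps_in + (1.0 - fin) / eps_out);
  };

  // Precompute face dielectrics.
  std::vector<double> ex((size_t)(nx - 1) * ny * nz);
  std::vector<double> ey((size_t)nx * (ny - 1) * nz);
  std::vector<double> ez((size_t)nx * ny * (nz - 1));
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx - 1; i++)
        ex[(size_t)i + (size_t)(nx - 1) * (j + (size_t)ny * k)] =
          face_eps(L[idx(i, j, k)], L[idx(i + 1, j, k)]);
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny - 1; j++)
      for (int i = 0; i < nx; i++)
        ey[(size_t)i + (size_t)nx * (j + (size_t)(ny - 1) * k)] =
          face_eps(L[idx(i, j, k)], L[idx(i, j + 1, k)]);
  for (int k = 0; k < nz - 1; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++)
        ez[idx(i, j, k)] = face_eps(L[idx(i, j, k)], L[idx(i, j, k + 1)]);

  std::vector<double> kap(n, 0.0);
  if (kbar2 > 0.0)
    for (size_t i = 0; i < n; i++)
      if (L[i] > 0.0) kap[i] = kbar2 * h * h;

  double maxdel = 0.0;
  int iter = 0;
  for (iter = 1; iter <= maxiter; iter++) {
    maxdel = 0.0;
    for (int colour = 0; colour < 2; colour++) {
      for (int k = 1; k < nz - 1; k++) {
        for (int j = 1; j < ny - 1; j++) {
          int istart = 1 + ((j + k + colour) & 1);
          for (int i = istart; i < nx - 1; i += 2) {
            size_t id = idx(i, j, k);
            double exm = ex[(size_t)(i - 1) + (size_t)(nx - 1) * (j + (size_t)ny * k)];
            double exp_ = ex[(size_t)i + (size_t)(nx - 1) * (j + (size_t)ny * k)];
            double eym = ey[(size_t)i + (size_t)nx * ((j - 1) + (size_t)(ny - 1) * k)];
            double eyp = ey[(size_t)i + (size_t)nx * (j + (size_t)(ny - 1) * k)];
            double ezm = ez[idx(i, j, k - 1)];
            double ezp = ez[idx(i, j, k)];
            double num = exm * phi[idx(i - 1, j, k)] + exp_ * phi[idx(i + 1, j, k)] +
                         eym * phi[idx(i, j - 1, k)] + eyp * phi[idx(i, j + 1, k)] +
                         ezm * phi[idx(i, j, k - 1)] + ezp * phi[idx(i, j, k + 1)] +
                         src[id];
            double den = exm + exp_ + eym + eyp + ezm + ezp + kap[id];
            double upd = omega * (num / den - phi[id]);
            phi[id] += upd;
            double a = std::fabs(upd);
            if (a > maxdel) maxdel = a;
          }
        }
      }
    }
    if (maxdel < tol) break;
  }
  NumericVector out(phi.begin(), phi.end());
  return List::create(_["phi"] = out, _["iterations"] = iter,
                      _["max_update"] = maxdel,
                      _["converged"] = maxdel < tol);
}
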