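#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Distance-regularized level-set evolution on one 2D slice.
//
// Explicit-Euler updates of
//   dphi/dt = mu * div(d_p(|grad phi|) grad phi)
//           + lam * delta_eps(phi) * div(g grad phi / |grad phi|)
//           + alpha * g * delta_eps(phi)
// with the double-well potential p2 (wells at |grad phi| = 0 and 1),
// central differences, and replicate (Neumann) boundaries. g and its
// gradient are fixed over the evolution. Total updates = inner * outer;
// the per-outer-checkpoint foreground count {phi < 0} is recorded.
//
// Each update is two grid passes: pass A computes grad phi, the unit
// normal, the double-well flux (d_p - 1) grad phi and the laplacian;
// pass B takes divergences of the pass-A fields and writes phi in place
// (pass B reads phi only at the centre, so the in-place write keeps the
// scheme a plain Jacobi step).

static inline int clampi(int i, int n) {
  return i < 0 ? 0 : (i >= n ? n - 1 : i);
}

// d_p(s) = p'(s)/s for the double-well potential:
//   p(s) = (1/(2pi)^2) (1 - cos(2 pi s))   for s <= 1
//        = (1/2)(s - 1)^2                  for s >= 1
static inline double dp_over_s(double s) {
  if (s == 0.0) return 1.0;  // limit of sin(2 pi s)/(2 pi s)
  if (s <= 1.0) return std::sin(2.0 * M_PI * s) / (2.0 * M_PI * s);
  return (s - 1.0) / s;
}

static inline double dirac_eps(double x, double eps) {
  if (std::fabs(x) > eps) return 0.0;
  return (1.0 + std::cos(M_PI * x / eps)) / (2.0 * eps);
}

// [[Rcpp::export]]
List drlse_evolve_cpp(NumericMatrix phi0, NumericMatrix g,
                      double mu, double lam, double alpha,
                      double epsilon, double dt,
                      int inner, int outer) {
  const int nr = phi0.nrow(), nc = phi0.ncol();
  if (g.nrow() != nr || g.ncol() != nc)
    stop("phi and g must have the same shape");

  NumericMatrix phi(clone(phi0));
  NumericMatrix gx(nr, nc), gy(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      gx(i, j) = 0.5 * (g(clampi(i + 1, nr), j) - g(clampi(i - 1, nr), j));
      gy(i, j) = 0.5 * (g(i, clampi(j + 1, nc)) - g(i, clampi(j - 1, nc)));
    }

  NumericMatrix nx(nr, nc), ny(nr, nc), fx(nr, nc), fy(nr, nc), lap(nr, nc);
  IntegerVector counts(outer);
  const double tiny = 1e-10;

  for (int it_out = 0; it_out < outer; ++it_out) {
    for (int it_in = 0; it_in < inner; ++it_in) {
      for (int j = 0; j < nc; ++j) {
        const int jp = clampi(j + 1, nc), jm = clampi(j - 1, nc);
        for (int i = 0; i < nr; ++i) {
          const int ip = clampi(i + 1, nr), im = clampi(i - 1, nr);
          const double px = 0.5 * (phi(ip, j) - phi(im, j));
          const double py = 0.5 * (phi(i, jp) - phi(i, jm));
          const double s = std::sqrt(px * px + py * py);
          const double inv = 1.0 / (s + tiny);
          nx(i, j) = px * inv;
          ny(i, j) = py * inv;
          const double c = dp_over_s(s) - 1.0;
          fx(i, j) = c * px;
          fy(i, j) = c * py;
          lap(i, j) = phi(ip, j) + phi(im, j) + phi(i, jp) + phi(i, jm) -
                      4.0 * phi(i, j);
        }
      }
      for (int j = 0; j < nc; ++j) {
        const int jp = clampi(j + 1, nc), jm = clampi(j - 1, nc);
        for (int i = 0; i < nr; ++i) {
          const int ip = clampi(i + 1, nr), im = clampi(i - 1, nr);
          const double div_f = 0.5 * (fx(ip, j) - fx(im, j)) +
                               0.5 * (fy(i, jp) - fy(i, jm));
          const double curv = 0.5 * (nx(ip, j) - nx(im, j)) +
                              0.5 * (ny(i, jp) - ny(i, jm));
          const double del = dirac_eps(phi(i, j), epsilon);
          const double edge = del * (gx(i, j) * nx(i, j) +
                                     gy(i, j) * ny(i, j) + g(i, j) * curv);
          const double area = alpha * g(i, j) * del;
          phi(i, j) += dt * (mu * (div_f + lap(i, j)) + lam * edge + area);
        }
      }
    }
    int cnt = 0;
    bool finite = true;
    for (int j = 0; j < nc && finite; ++j)
      for (int i = 0; i < nr; ++i) {
        double v = phi(i, j);
        if (!R_finite(v)) { finite = false; break; }
        if (v < 0.0) ++cnt;
      }
    if (!finite)
      stop("level-set field became non-finite at outer iteration %d",
           it_out + 1);
    counts[it_out] = cnt;
  }

  return List::create(_["phi"] = phi, _["foreground_counts"] = counts);
}
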