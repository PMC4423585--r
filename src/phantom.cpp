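#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel fill for a radially perturbed ellipsoid.
//
// A voxel belongs to the cavity iff its centre lies inside the surface
//   R(theta, phi) = r_ell(theta, phi) + amp * P(theta, phi)
// where r_ell is the ellipsoid radius along the voxel direction and P is a
// band-limited angular perturbation with |P| <= 1 (coefficients are
// normalised on the R side so that sum(|coef|) == 1).
//
// Terms with k_phi > 0 carry a sin(theta) factor so the perturbation is
// continuous at the poles. Voxel centres sit at (i + 0.5) * spacing,
// 0-based index i; `centre` is in the same mm coordinates.
//
// Fast paths: points with r <= min(semi) - amp are inside for every
// admissible P, points with r(1 - 1/q) > amp (q = ellipsoidal norm) are
// outside, so trigonometry is only evaluated in a thin shell around the
// surface.
// [[Rcpp::export]]
IntegerVector fill_perturbed_ellipsoid(IntegerVector dim,
                                       NumericVector spacing,
                                       NumericVector centre,
                                       NumericVector semi,
                                       double amp,
                                       NumericVector coef,
                                       IntegerVector k_theta,
                                       IntegerVector k_phi,
                                       NumericVector phase_theta,
                                       NumericVector phase_phi) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double cx = centre[0], cy = centre[1], cz = centre[2];
  const double a = semi[0], b = semi[1], c = semi[2];
  const int nterm = coef.size();

  double smin = a, smax = a;
  if (b < smin) smin = b;
  if (c < smin) smin = c;
  if (b > smax) smax = b;
  if (c > smax) smax = c;
  const double rin2 = (smin - amp) > 0 ? (smin - amp) * (smin - amp) : 0.0;
  const double rout2 = (smax + amp) * (smax + amp);

  IntegerVector occ(static_cast<R_xlen_t>(n0) * n1 * n2);
  int *out = INTEGER(occ);

  const double inv_a2 = 1.0 / (a * a), inv_b2 = 1.0 / (b * b),
               inv_c2 = 1.0 / (c * c);

  // Phase factors are constant per term; cos/sin of multiple angles are
  // built per voxel by the angle-addition recurrence, so the shell loop is
  // free of inverse-trig calls.
  int kmax = 1;
  for (int t = 0; t < nterm; ++t) {
    if (k_theta[t] > kmax) kmax = k_theta[t];
    if (k_phi[t] > kmax) kmax = k_phi[t];
  }
  std::vector<double> cpt(nterm), spt(nterm), cpp_(nterm), spp(nterm);
  for (int t = 0; t < nterm; ++t) {
    cpt[t] = std::cos(phase_theta[t]);
    spt[t] = std::sin(phase_theta[t]);
    cpp_[t] = std::cos(phase_phi[t]);
    spp[t] = std::sin(phase_phi[t]);
  }
  std::vector<double> cth(kmax + 1), sth(kmax + 1), cph(kmax + 1),
      sph(kmax + 1);
  cth[0] = cph[0] = 1.0;
  sth[0] = sph[0] = 0.0;

  R_xlen_t idx = 0;
  for (int k = 0; k < n2; ++k) {
    const double dz = (k + 0.5) * sz - cz;
    const double dz2 = dz * dz;
    for (int j = 0; j < n1; ++j) {
      const double dy = (j + 0.5) * sy - cy;
      const double dy2 = dy * dy;
      for (int i = 0; i < n0; ++i, ++idx) {
        const double dx = (i + 0.5) * sx - cx;
        const double r2 = dx * dx + dy2 + dz2;
        if (r2 <= rin2) { out[idx] = 1; continue; }
        if (r2 > rout2) { out[idx] = 0; continue; }
        const double q2 = dx * dx * inv_a2 + dy2 * inv_b2 + dz2 * inv_c2;
        if (amp <= 0.0 || nterm == 0) {
          out[idx] = (q2 <= 1.0) ? 1 : 0;
          continue;
        }
        const double r = std::sqrt(r2);
        const double q = std::sqrt(q2);
        // signed radial excess over the unperturbed surface: r - r/q
        const double excess = r * (1.0 - 1.0 / q);
        if (excess > amp) { out[idx] = 0; continue; }
        if (excess < -amp) { out[idx] = 1; continue; }
        // cos/sin of theta (polar, from +z) and phi (azimuth)
        const double ct = dz / r;
        const double rxy = std::sqrt(dx * dx + dy2);
        const double st = rxy / r;
        double c1p, s1p;
        if (rxy > 0.0) { c1p = dx / rxy; s1p = dy / rxy; }
        else { c1p = 1.0; s1p = 0.0; }
        cth[1] = ct; sth[1] = st;
        cph[1] = c1p; sph[1] = s1p;
        for (int kk = 2; kk <= kmax; ++kk) {
          cth[kk] = cth[kk - 1] * ct - sth[kk - 1] * st;
          sth[kk] = sth[kk - 1] * ct + cth[kk - 1] * st;
          cph[kk] = cph[kk - 1] * c1p - sph[kk - 1] * s1p;
          sph[kk] = sph[kk - 1] * c1p + cph[kk - 1] * s1p;
        }
        double P = 0.0;
        for (int t = 0; t < nterm; ++t) {
          const int kt = k_theta[t];
          double term = coef[t] * (cth[kt] * cpt[t] - sth[kt] * spt[t]);
          const int kp = k_phi[t];
          if (kp > 0)
            term *= st * (cph[kp] * cpp_[t] - sph[kp] * spp[t]);
          P += term;
        }
        out[idx] = (excess <= amp * P) ? 1 : 0;
      }
    }
  }
  occ.attr("dim") = dim;
  return occ;
}

// Number of 26-connected components among occupied voxels (iterative
// flood fill; used to validate the phantom output contract).
// [[Rcpp::export]]
int count_components26(IntegerVector occ, IntegerVector dim) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(n0) * n1 * n2;
  const int *v = INTEGER(occ);
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!v[s] || seen[s]) continue;
    ++ncomp;
    seen[s] = 1;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int i = static_cast<int>(cur % n0);
      const int j = static_cast<int>((cur / n0) % n1);
      const int k = static_cast<int>(cur / (static_cast<R_xlen_t>(n0) * n1));
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= n2) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= n1) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= n0) continue;
            const R_xlen_t nb =
                ii + static_cast<R_xlen_t>(n0) * (jj + static_cast<R_xlen_t>(n1) * kk);
            if (v[nb] && !seen[nb]) {
              seen[nb] = 1;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  return ncomp;
}
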