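#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Longitudinal-only recursion of a spoiled multiband sequence: one group of
// bands fires per TR (groups cycle), every isochromat inside a firing band's
// profile support is saturated by cos(flip_eff), the band signal accumulates
// Mz * sin(flip_eff) (transverse magnetization created this TR), then all
// isochromats relax toward M0 = 1. Transverse magnetization is discarded each
// TR (perfect spoiling). Motion enters as a per-excitation rigid displacement
// added to the isochromat positions before profile lookup.

static inline double interp_profile(const NumericMatrix& prof, int b,
                                    double z, double z0, double dz, int nz) {
  double x = (z - z0) / dz;
  if (x <= 0.0 || x >= nz - 1) return 0.0;
  int k = (int)x;
  double fr = x - k;
  return prof(k, b) * (1.0 - fr) + prof(k + 1, b) * fr;
}

// [[Rcpp::export]]
List cpp_bloch_sim(NumericVector z, NumericVector E1, NumericVector mz0,
                   int n_exc, int n_groups, IntegerVector band_group,
                   NumericVector flip_rad, double prof_z0, double prof_dz,
                   NumericMatrix prof, NumericVector disp) {
  const int n = z.size();
  const int nb = band_group.size();
  const int nz = prof.nrow();
  if (E1.size() != n || mz0.size() != n)
    stop("z, E1 and mz0 must have equal length");
  if (disp.size() != n_exc) stop("disp must have one entry per excitation");
  if (prof.ncol() != nb || flip_rad.size() != nb)
    stop("profile matrix and flip vector must cover every band");

  NumericVector mz = clone(mz0);
  NumericMatrix sig(n_exc, nb);

  for (int m = 0; m < n_exc; ++m) {
    const int g = (m % n_groups) + 1;
    const double d = disp[m];
    for (int i = 0; i < n; ++i) {
      const double zi = z[i] + d;
      double ct = 1.0;
      bool hit = false;
      const double mzi = mz[i];
      for (int b = 0; b < nb; ++b) {
        if (band_group[b] != g) continue;
        const double p = interp_profile(prof, b, zi, prof_z0, prof_dz, nz);
        if (p == 0.0) continue;
        const double a = flip_rad[b] * p;
        sig(m, b) += mzi * std::sin(a);
        ct *= std::cos(a);
        hit = true;
      }
      if (hit) mz[i] = mzi * ct;
    }
    for (int i = 0; i < n; ++i) mz[i] = 1.0 + (mz[i] - 1.0) * E1[i];
  }
  return List::create(_["signal"] = sig, _["mz"] = mz);
}

// Dictionary generation: static geometry, one simulation per T1 grid value.
// Per-band flip angles at each isochromat are precomputed (sinf/cosf); only
// the per-slice signal templates for the requested bands ("keep", 0-based)
// are returned, as an array (excitations-per-band x n_T1 x n_keep).

// [[Rcpp::export]]
NumericVector cpp_bloch_dict(NumericVector T1_grid, double TR, int n_exc,
                             int n_groups, IntegerVector band_group,
                             NumericMatrix sinf, NumericMatrix cosf,
                             IntegerVector keep) {
  const int n = sinf.nrow();
  const int nb = sinf.ncol();
  const int nT = T1_grid.size();
  const int nk = keep.size();
  const int n_per = n_exc / n_groups;

  // support indices per band (isochromats actually excited)
  std::vector< std::vector<int> > supp(nb);
  for (int b = 0; b < nb; ++b)
    for (int i = 0; i < n; ++i)
      if (sinf(i, b) != 0.0) supp[b].push_back(i);

  // combined saturation factor per group
  NumericMatrix cosg(n, n_groups);
  std::fill(cosg.begin(), cosg.end(), 1.0);
  std::vector< std::vector<int> > gsupp(n_groups);
  for (int g = 0; g < n_groups; ++g) {
    for (int i = 0; i < n; ++i) {
      double c = 1.0;
      bool hit = false;
      for (int b = 0; b < nb; ++b) {
        if (band_group[b] != g + 1) continue;
        if (sinf(i, b) == 0.0) continue;
        c *= cosf(i, b);
        hit = true;
      }
      cosg(i, g) = c;
      if (hit) gsupp[g].push_back(i);
    }
  }

  NumericVector tmpl(Dimension(n_per, nT, nk));
  std::map<int, int> keep_pos;
  for (int k = 0; k < nk; ++k) keep_pos[keep[k]] = k;

  std::vector<double> mz(n);
  for (int t = 0; t < nT; ++t) {
    const double e1 = std::exp(-TR / T1_grid[t]);
    std::fill(mz.begin(), mz.end(), 1.0);
    std::vector<int> fired(nb, 0);
    for (int m = 0; m < n_exc; ++m) {
      const int g = m % n_groups;
      // readout of kept bands in this group (uses pre-saturation Mz)
      for (int b = 0; b < nb; ++b) {
        if (band_group[b] != g + 1) continue;
        std::map<int, int>::iterator it = keep_pos.find(b);
        if (it != keep_pos.end()) {
          double s = 0.0;
          const std::vector<int>& sp = supp[b];
          for (size_t j = 0; j < sp.size(); ++j)
            s += mz[sp[j]] * sinf(sp[j], b);
          tmpl[fired[b] + n_per * (t + nT * it->second)] = s;
        }
        fired[b] += 1;
      }
      // saturation then relaxation
      const std::vector<int>& gs = gsupp[g];
      for (size_t j = 0; j < gs.size(); ++j) mz[gs[j]] *= cosg(gs[j], g);
      for (int i = 0; i < n; ++i) mz[i] = 1.0 + (mz[i] - 1.0) * e1;
    }
  }
  return tmpl;
}
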