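#include <Rcpp.h>
using namespace Rcpp;

// Golden-spiral (Fibonacci) quasi-uniform unit-sphere points; deterministic.
static std::vector<double> fibonacci_sphere(int n) {
  std::vector<double> pts(3 * n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    pts[3 * i]     = r * std::cos(th);
    pts[3 * i + 1] = r * std::sin(th);
    pts[3 * i + 2] = z;
  }
  return pts;
}

// Shrake-Rupley SASA for the atoms in `subset` (1-based), occluded only by
// atoms in `subset`. A sphere point is buried iff strictly inside another
// subset atom's probe-expanded sphere.
static void sasa_core(const double* xyz, const double* radii, int n_atoms,
                      const int* subset, int n_sub, double probe, int npts,
                      const std::vector<double>& sp, double* out) {
  std::vector<double> er(n_sub);
  for (int k = 0; k < n_sub; ++k) er[k] = radii[subset[k]] + probe;
  for (int k = 0; k < n_sub; ++k) {
    int i = subset[k];
    double ri = er[k];
    double xi = xyz[3 * i], yi = xyz[3 * i + 1], zi = xyz[3 * i + 2];
    // neighbours: subset atoms whose expanded sphere can reach ours
    std::vector<int> nb;
    nb.reserve(16);
    for (int m = 0; m < n_sub; ++m) {
      if (m == k) continue;
      int j = subset[m];
      double dx = xyz[3 * j] - xi, dy = xyz[3 * j + 1] - yi,
             dz = xyz[3 * j + 2] - zi;
      double cut = ri + er[m];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(m);
    }
    int exposed = 0;
    for (int p = 0; p < npts; ++p) {
      double px = xi + ri * sp[3 * p];
      double py = yi + ri * sp[3 * p + 1];
      double pz = zi + ri * sp[3 * p + 2];
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = subset[nb[q]];
        double dx = px - xyz[3 * j], dy = py - xyz[3 * j + 1],
               dz = pz - xyz[3 * j + 2];
        double rj = er[nb[q]];
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++exposed;
    }
    out[k] = 4.0 * M_PI * ri * ri * (double)exposed / npts;
  }
}

// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       IntegerVector subset, double probe, int n_points) {
  int n = coords.nrow(), ns = subset.size();
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i) {
    xyz[3 * i] = coords(i, 0);
    xyz[3 * i + 1] = coords(i, 1);
    xyz[3 * i + 2] = coords(i, 2);
  }
  std::vector<int> sub(ns);
  for (int k = 0; k < ns; ++k) sub[k] = subset[k] - 1;
  std::vector<double> sp = fibonacci_sphere(n_points);
  NumericVector out(ns);
  sasa_core(xyz.data(), REAL(radii), n, sub.data(), ns, probe, n_points,
            sp, REAL(out));
  return out;
}

// Per-residue, per-frame delta-SASA: residue SASA over peptide atoms only
// minus residue SASA in the full complex, summed over residue atoms.
// coords: n_atoms x 3 x n_frames array (column-major as passed from R).
// [[Rcpp::export(name = ".delta_sasa_cpp")]]
NumericMatrix delta_sasa_cpp(NumericVector coords, NumericVector radii,
                             LogicalVector is_peptide, IntegerVector res_of_atom,
                             IntegerVector residues, double probe, int n_points) {
  IntegerVector dims = coords.attr("dim");
  int n = dims[0], nf = dims[2];
  int nres = residues.size();
  std::vector<int> all(n), pep;
  for (int i = 0; i < n; ++i) {
    all[i] = i;
    if (is_peptide[i]) pep.push_back(i);
  }
  int np = pep.size();
  // map residue id -> row
  std::map<int, int> rrow;
  for (int r = 0; r < nres; ++r) rrow[residues[r]] = r;
  std::vector<double> sp = fibonacci_sphere(n_points);
  std::vector<double> xyz(3 * n), s_all(n), s_pep(np);
  NumericMatrix out(nres, nf);
  for (int f = 0; f < nf; ++f) {
    for (int i = 0; i < n; ++i) {
      xyz[3 * i]     = coords[i + 0 * n + (size_t)f * 3 * n];
      xyz[3 * i + 1] = coords[i + 1 * n + (size_t)f * 3 * n];
      xyz[3 * i + 2] = coords[i + 2 * n + (size_t)f * 3 * n];
    }
    sasa_core(xyz.data(), REAL(radii), n, all.data(), n, probe, n_points,
              sp, s_all.data());
    sasa_core(xyz.data(), REAL(radii), n, pep.data(), np, probe, n_points,
              sp, s_pep.data());
    for (int k = 0; k < np; ++k) {
      int i = pep[k];
      int row = rrow[res_of_atom[i]];
      out(row, f) += s_pep[k] - s_all[i];
    }
    if (f % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
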