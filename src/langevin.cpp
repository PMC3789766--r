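#include <Rcpp.h>
using namespace Rcpp;

// Units: Å, ps, kcal/mol, amu. Acceleration (Å/ps^2) = KCAL * force/mass.
static const double KCAL = 418.4;       // (kcal/mol)/(amu*Å) -> Å/ps^2
static const double KB = 0.0019872;     // kcal/mol/K

struct Pair { int i, j; double sigma, eps_attr; };

// WCA repulsive core (fixed depth eps_rep) plus, when eps_attr > 0, the
// WCA-split attractive Lennard-Jones tail of depth eps_attr truncated and
// shifted at 2.5*sigma. Returns force magnitude dU/dr with sign convention
// F_on_i = -dU/dr * unit(i->j) handled by caller; here we return -dU/dr.
static inline double pair_force(double r, double sigma, double eps_rep,
                                double eps_attr, double rcut) {
  double f = 0.0;
  double rmin = std::pow(2.0, 1.0 / 6.0) * sigma;
  if (r < rmin) {
    double sr6 = std::pow(sigma / r, 6.0), sr12 = sr6 * sr6;
    f += 24.0 * eps_rep * (2.0 * sr12 - sr6) / r;   // repulsive part
    // attractive branch is flat (-eps_attr) inside rmin: no force
  } else if (eps_attr > 0.0 && r < rcut) {
    double sr6 = std::pow(sigma / r, 6.0), sr12 = sr6 * sr6;
    f += 24.0 * eps_attr * (2.0 * sr12 - sr6) / r;
  }
  return f;
}

// [[Rcpp::export(name = ".cg_langevin_cpp")]]
List cg_langevin_cpp(NumericMatrix coords0, LogicalVector is_ligand,
                     NumericVector mass, NumericVector eps_attr_bead,
                     double bond_length, double bond_k,
                     double angle_theta0, double angle_k,
                     double sigma_pp, double sigma_pl, double sigma_ll,
                     double lig_bond_length, double lig_bond_k,
                     double temperature, double friction, double dt,
                     int n_steps, int save_interval, double box) {
  const int n = coords0.nrow();
  std::vector<double> x(3 * n), v(3 * n), fc(3 * n), minv(n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = coords0(i, 0); x[3 * i + 1] = coords0(i, 1);
    x[3 * i + 2] = coords0(i, 2);
    minv[i] = 1.0 / mass[i];
  }
  // bonded lists
  std::vector<int> pep, lig;
  for (int i = 0; i < n; ++i) (is_ligand[i] ? lig : pep).push_back(i);
  struct Bond { int i, j; double b0, k; };
  std::vector<Bond> bonds;
  for (size_t k = 0; k + 1 < pep.size(); ++k)
    bonds.push_back({pep[k], pep[k + 1], bond_length, bond_k});
  for (size_t k = 0; k + 1 < lig.size(); ++k)
    bonds.push_back({lig[k], lig[k + 1], lig_bond_length, lig_bond_k});
  std::vector<std::array<int, 3>> angles;
  for (size_t k = 0; k + 2 < pep.size(); ++k)
    angles.push_back({pep[k], pep[k + 1], pep[k + 2]});
  // non-bonded pair list: all pairs except 1-2 bonded
  std::set<long long> excl;
  for (auto& b : bonds) excl.insert((long long)std::min(b.i, b.j) * n + std::max(b.i, b.j));
  std::vector<Pair> nb;
  double rcut_pl = 2.5 * sigma_pl;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (excl.count((long long)i * n + j)) continue;
      Pair p; p.i = i; p.j = j;
      bool li = is_ligand[i], lj = is_ligand[j];
      if (!li && !lj) { p.sigma = sigma_pp; p.eps_attr = 0.0; }
      else if (li && lj) { p.sigma = sigma_ll; p.eps_attr = 0.0; }
      else { p.sigma = sigma_pl; p.eps_attr = eps_attr_bead[li ? j : i]; }
      nb.push_back(p);
    }

  auto forces = [&](void) {
    std::fill(fc.begin(), fc.end(), 0.0);
    for (auto& b : bonds) {
      double dx = x[3 * b.j] - x[3 * b.i], dy = x[3 * b.j + 1] - x[3 * b.i + 1],
             dz = x[3 * b.j + 2] - x[3 * b.i + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-9) continue;
      double fm = -b.k * (r - b.b0) / r;  // E = 0.5 k (r-b0)^2
      fc[3 * b.j] += fm * dx; fc[3 * b.j + 1] += fm * dy; fc[3 * b.j + 2] += fm * dz;
      fc[3 * b.i] -= fm * dx; fc[3 * b.i + 1] -= fm * dy; fc[3 * b.i + 2] -= fm * dz;
    }
    if (angle_k > 0) {
      for (auto& a : angles) {
        int i = a[0], j = a[1], k = a[2];
        double rij[3] = {x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2]};
        double rkj[3] = {x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2]};
        double nij = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
        double nkj = std::sqrt(rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2]);
        if (nij < 1e-9 || nkj < 1e-9) continue;
        double c = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (nij * nkj);
        c = std::max(-1.0, std::min(1.0, c));
        double th = std::acos(c);
        double s = std::sqrt(std::max(1e-12, 1.0 - c * c));
        double dV = angle_k * (th - angle_theta0);   // E = 0.5 k (th-th0)^2
        double coef = dV / s;
        for (int d = 0; d < 3; ++d) {
          double gi = coef * (rkj[d] / (nij * nkj) - c * rij[d] / (nij * nij));
          double gk = coef * (rij[d] / (nij * nkj) - c * rkj[d] / (nkj * nkj));
          fc[3 * i + d] += gi;
          fc[3 * k + d] += gk;
          fc[3 * j + d] -= gi + gk;
        }
      }
    }
    for (auto& p : nb) {
      double dx = x[3 * p.j] - x[3 * p.i], dy = x[3 * p.j + 1] - x[3 * p.i + 1],
             dz = x[3 * p.j + 2] - x[3 * p.i + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double rc = (p.eps_attr > 0.0) ? 2.5 * p.sigma
                                     : std::pow(2.0, 1.0 / 6.0) * p.sigma;
      if (r2 >= rc * rc || r2 < 1e-12) continue;
      double r = std::sqrt(r2);
      double fm = pair_force(r, p.sigma, 1.0, p.eps_attr, rcut_pl) / r;
      // pair_force returns -dU/dr; force on j along +(j-i)
      fc[3 * p.j] += fm * dx; fc[3 * p.j + 1] += fm * dy; fc[3 * p.j + 2] += fm * dz;
      fc[3 * p.i] -= fm * dx; fc[3 * p.i + 1] -= fm * dy; fc[3 * p.i + 2] -= fm * dz;
    }
  };

  // Maxwell-Boltzmann start
  for (int i = 0; i < n; ++i) {
    double sd = std::sqrt(KB * temperature * KCAL * minv[i]);
    for (int d = 0; d < 3; ++d) v[3 * i + d] = sd * R::norm_rand();
  }
  forces();
  const double c1 = std::exp(-friction * dt);
  const double c2 = std::sqrt(1.0 - c1 * c1);
  int n_save = n_steps / save_interval;
  NumericVector traj((size_t)n * 3 * n_save);
  traj.attr("dim") = IntegerVector::create(n, 3, n_save);
  NumericVector temps(n_save);
  int isave = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] += 0.5 * dt * KCAL * minv[i] * fc[3 * i + d];
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    for (int i = 0; i < n; ++i) {
      double sd = std::sqrt(KB * temperature * KCAL * minv[i]);
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] = c1 * v[3 * i + d] + c2 * sd * R::norm_rand();
    }
    for (int k = 0; k < 3 * n; ++k) x[k] += 0.5 * dt * v[k];
    // reflecting walls on [0, box]
    for (int k = 0; k < 3 * n; ++k) {
      if (x[k] < 0.0) { x[k] = -x[k]; v[k] = -v[k]; }
      else if (x[k] > box) { x[k] = 2.0 * box - x[k]; v[k] = -v[k]; }
    }
    forces();
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] += 0.5 * dt * KCAL * minv[i] * fc[3 * i + d];
    if (step % save_interval == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
      ke /= KCAL;                      // -> kcal/mol
      temps[isave] = 2.0 * ke / (3.0 * n * KB);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          double val = x[3 * i + d];
          if (!std::isfinite(val))
            stop("integration diverged (non-finite coordinate) at step %d", step);
          traj[i + (size_t)d * n + (size_t)isave * 3 * n] = val;
        }
      ++isave;
      if (isave % 50 == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["coords"] = traj, _["temperature"] = temps);
}
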