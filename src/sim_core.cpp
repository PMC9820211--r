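// Overdamped Langevin (Euler-Maruyama) propagation of labelled particles on
// the pore axis.  Energies in kT, lengths in nm, time in ps.  Randomness
// comes from R's RNG so a set.seed() in the calling R code makes the run
// bit-reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// piecewise-cosine potential force, -dV/dz in kT/nm; extrema (ze, Ve).
// 'hint' caches the segment index per particle: positions move little per
// step, so the search is O(1) amortised.
static inline double extrema_force(const std::vector<double>& ze,
                                   const std::vector<double>& Ve,
                                   double z, int& hint) {
  if (z <= ze.front() || z >= ze.back()) return 0.0;
  int n = (int) ze.size();
  int k = hint;
  if (k < 0) k = 0;
  if (k > n - 2) k = n - 2;
  while (k > 0 && ze[k] > z) --k;
  while (k + 1 < n - 1 && ze[k + 1] < z) ++k;
  hint = k;
  double dz = ze[k + 1] - ze[k];
  double s = (z - ze[k]) / dz;
  return -(Ve[k + 1] - Ve[k]) * M_PI / (2.0 * dz) * std::sin(M_PI * s);
}

// [[Rcpp::export]]
List sim_core(NumericVector z0,
              NumericVector D,          // nm^2/ps per particle
              NumericVector charge,     // e, 0 for waters
              NumericVector vscale,     // landscape scale per particle
              NumericVector ze, NumericVector Ve,  // landscape extrema (kT)
              double dt,                // ps
              int n_steps, int stride,
              double field_force,       // kT/nm per unit charge, amplitude
              double omega,             // rad/ps
              double phi,
              double tilt_force,        // kT/nm per unit charge, in pore
              double pore_lo, double pore_hi,
              double z_min, double z_max,
              double coul_pref,         // kT*nm (already / eps_r)
              double lambda_d,          // nm
              double d_min,             // single-file exclusion, nm
              double max_step) {        // stability bound on |dz|, nm
  const int np = z0.size();
  std::vector<double> z(z0.begin(), z0.end());
  std::vector<double> ze_(ze.begin(), ze.end()), Ve_(Ve.begin(), Ve.end());
  const int n_saved = n_steps / stride + 1;
  NumericMatrix out(n_saved, np);
  for (int j = 0; j < np; ++j) out(0, j) = z[j];

  std::vector<double> force(np), znew(np);
  std::vector<int> seg_hint(np, 0);
  std::vector<int> ion_idx;
  for (int j = 0; j < np; ++j) if (charge[j] != 0.0) ion_idx.push_back(j);
  const double span = z_max - z_min;

  RNGScope scope;
  int saved = 1;
  for (int step = 1; step <= n_steps; ++step) {
    const double t = step * dt;
    const double efield = field_force * std::cos(omega * t + phi);
    for (int j = 0; j < np; ++j) {
      double f = vscale[j] * extrema_force(ze_, Ve_, z[j], seg_hint[j]);
      // constant-field coupling: both the membrane-voltage tilt and the
      // oscillating field act uniformly across the whole periodic box
      if (charge[j] != 0.0) f += charge[j] * (efield + tilt_force);
      force[j] = f;
    }
    // screened Coulomb repulsion between charged particles (1-D distance)
    for (size_t a = 0; a + 1 < ion_idx.size(); ++a) {
      for (size_t b = a + 1; b < ion_idx.size(); ++b) {
        int i = ion_idx[a], j = ion_idx[b];
        double dz = z[i] - z[j];
        double r = std::fabs(dz);
        // finite-size core: the screened-Coulomb force saturates at the
        // exclusion distance instead of diverging at contact
        if (r < d_min) r = d_min;
        if (r > 6.0 * lambda_d) continue;
        double mag = coul_pref * charge[i] * charge[j] *
          std::exp(-r / lambda_d) * (1.0 / (r * r) + 1.0 / (r * lambda_d));
        double sgn = (dz >= 0.0) ? 1.0 : -1.0;
        force[i] += sgn * mag;
        force[j] -= sgn * mag;
      }
    }
    for (int j = 0; j < np; ++j) {
      double drift = D[j] * force[j] * dt;
      if (std::fabs(drift) > max_step)
        stop("integration unstable at step %d (|drift| = %.3g nm > %.3g nm); use a smaller dt",
             step, std::fabs(drift), max_step);
      double dz = drift + std::sqrt(2.0 * D[j] * dt) * norm_rand();
      znew[j] = z[j] + dz;
    }
    // single-file order inside the pore: particles that started the step in
    // the pore region may not pass each other; resolve pairwise in old-z
    // order by symmetric separation to d_min
    if (np > 1) {
      std::vector<int> in_pore;
      in_pore.reserve(np);
      for (int j = 0; j < np; ++j)
        if (z[j] >= pore_lo - 0.1 && z[j] <= pore_hi + 0.1) in_pore.push_back(j);
      std::sort(in_pore.begin(), in_pore.end(),
                [&](int a, int b) { return z[a] < z[b]; });
      for (int pass = 0; pass < 3; ++pass) {
        bool moved = false;
        for (size_t k = 0; k + 1 < in_pore.size(); ++k) {
          int i = in_pore[k], j = in_pore[k + 1];
          double gap = znew[j] - znew[i];
          if (gap < d_min) {
            double mid = 0.5 * (znew[i] + znew[j]);
            znew[i] = mid - 0.5 * d_min;
            znew[j] = mid + 0.5 * d_min;
            moved = true;
          }
        }
        if (!moved) break;
      }
    }
    // recycling boundary: a particle leaving one end re-enters at the other
    for (int j = 0; j < np; ++j) {
      if (znew[j] > z_max) znew[j] -= span;
      else if (znew[j] < z_min) znew[j] += span;
      z[j] = znew[j];
    }
    if (step % stride == 0) {
      for (int j = 0; j < np; ++j) out(saved, j) = z[j];
      ++saved;
    }
  }
  return List::create(_["z"] = out);
}
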