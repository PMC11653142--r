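#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Off-lattice CA-bead Metropolis sampler. Energy terms:
//   bonds:   bond_k * (|r[t+1]-r[t]| - bond_length)^2 over consecutive
//            beads of the same chain
//   ev:      ev_k * (ev_radius - d)^2 for non-bonded pairs with d < ev_radius
//   restraints: flat-bottom pair potential with per-restraint ideal
//            distance and asymmetric slopes (linear or quadratic outside
//            the flat bottom)
// Moves displace one bead by an isotropic Gaussian; snapshots are taken
// every `snapshot_every` attempted moves so the frame schedule does not
// depend on acceptance history. Uses R's RNG, so a set.seed() on the R
// side makes runs bit-reproducible.

static inline double dist3(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z, int a, int b) {
  const double dx = x[a] - x[b], dy = y[a] - y[b], dz = z[a] - z[b];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static inline double restr_e(double d, double d0, double smin, double smax,
                             double hw, int quad) {
  double below = (d0 - hw) - d;
  double above = d - (d0 + hw);
  double e = 0.0;
  if (below > 0) e += quad ? smin * below * below : smin * below;
  if (above > 0) e += quad ? smax * above * above : smax * above;
  return e;
}

struct Model {
  int n;
  std::vector<double> x, y, z;
  std::vector<int> chain;                 // integer chain id per bead
  std::vector<int> ri, rj;                // restraint endpoints (0-based)
  std::vector<double> d0, smin, smax;
  std::vector<std::vector<int> > radj;    // restraint ids touching each bead
  double hw, bond_length, bond_k, ev_radius, ev_k;
  int quad;

  double bond_e(int a, int b) const {
    double dev = dist3(x, y, z, a, b) - bond_length;
    return bond_k * dev * dev;
  }
  bool bonded(int a, int b) const {
    return std::abs(a - b) == 1 && chain[a] == chain[b];
  }
  double ev_e(int a, int b) const {
    double d = dist3(x, y, z, a, b);
    if (d >= ev_radius) return 0.0;
    double dev = ev_radius - d;
    return ev_k * dev * dev;
  }
  // all energy terms that involve bead k
  double local_energy(int k) const {
    double e = 0.0;
    if (k > 0 && chain[k - 1] == chain[k]) e += bond_e(k - 1, k);
    if (k + 1 < n && chain[k + 1] == chain[k]) e += bond_e(k, k + 1);
    for (int j = 0; j < n; ++j) {
      if (j == k || bonded(j, k)) continue;
      e += ev_e(j, k);
    }
    for (size_t t = 0; t < radj[k].size(); ++t) {
      int r = radj[k][t];
      e += restr_e(dist3(x, y, z, ri[r], rj[r]), d0[r], smin[r], smax[r], hw, quad);
    }
    return e;
  }
  double total_energy() const {
    double e = 0.0;
    for (int a = 0; a + 1 < n; ++a)
      if (chain[a] == chain[a + 1]) e += bond_e(a, a + 1);
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b)
        if (!bonded(a, b)) e += ev_e(a, b);
    for (size_t r = 0; r < ri.size(); ++r)
      e += restr_e(dist3(x, y, z, ri[r], rj[r]), d0[r], smin[r], smax[r], hw, quad);
    return e;
  }
};

// [[Rcpp::export(name = ".mc_sample")]]
List mc_sample(NumericMatrix coords, IntegerVector chain,
               IntegerVector r_i, IntegerVector r_j,
               NumericVector r_d0, NumericVector r_smin, NumericVector r_smax,
               double flat_halfwidth, int quadratic,
               int n_steps, int snapshot_every,
               double temperature, double move_sigma,
               double bond_length, double bond_k,
               double ev_radius, double ev_k) {
  Model m;
  m.n = coords.nrow();
  m.x.resize(m.n); m.y.resize(m.n); m.z.resize(m.n);
  m.chain.assign(chain.begin(), chain.end());
  for (int i = 0; i < m.n; ++i) {
    m.x[i] = coords(i, 0); m.y[i] = coords(i, 1); m.z[i] = coords(i, 2);
  }
  m.ri.assign(r_i.begin(), r_i.end());
  m.rj.assign(r_j.begin(), r_j.end());
  m.d0.assign(r_d0.begin(), r_d0.end());
  m.smin.assign(r_smin.begin(), r_smin.end());
  m.smax.assign(r_smax.begin(), r_smax.end());
  m.hw = flat_halfwidth; m.quad = quadratic;
  m.bond_length = bond_length; m.bond_k = bond_k;
  m.ev_radius = ev_radius; m.ev_k = ev_k;
  m.radj.assign(m.n, std::vector<int>());
  for (size_t r = 0; r < m.ri.size(); ++r) {
    m.radj[m.ri[r]].push_back((int) r);
    m.radj[m.rj[r]].push_back((int) r);
  }

  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < m.n; ++i) { cx += m.x[i]; cy += m.y[i]; cz += m.z[i]; }
  cx /= m.n; cy /= m.n; cz /= m.n;

  const int n_frames = n_steps / snapshot_every + 1;
  NumericVector frames(Dimension(n_frames, m.n, 3));
  NumericVector energies(n_frames);
  double energy = m.total_energy();
  long accepted = 0;
  bool diverged = false;
  int frame = 0;

  RNGScope scope;
  auto record = [&](int f) {
    for (int i = 0; i < m.n; ++i) {
      frames[f + (long) n_frames * i] = m.x[i];
      frames[f + (long) n_frames * (i + (long) m.n)] = m.y[i];
      frames[f + (long) n_frames * (i + 2L * m.n)] = m.z[i];
      double dx = m.x[i] - cx, dy = m.y[i] - cy, dz = m.z[i] - cz;
      if (std::sqrt(dx * dx + dy * dy + dz * dz) > 1000.0) diverged = true;
    }
    energies[f] = energy;
  };
  record(frame++);

  for (int step = 1; step <= n_steps && !diverged; ++step) {
    int k = (int) std::floor(unif_rand() * m.n);
    if (k >= m.n) k = m.n - 1;
    const double ox = m.x[k], oy = m.y[k], oz = m.z[k];
    const double e_old = m.local_energy(k);
    m.x[k] = ox + norm_rand() * move_sigma;
    m.y[k] = oy + norm_rand() * move_sigma;
    m.z[k] = oz + norm_rand() * move_sigma;
    const double de = m.local_energy(k) - e_old;
    bool accept = de <= 0.0 || unif_rand() < std::exp(-de / temperature);
    if (accept) {
      energy += de;
      ++accepted;
    } else {
      m.x[k] = ox; m.y[k] = oy; m.z[k] = oz;
    }
    if (step % snapshot_every == 0) record(frame++);
  }

  return List::create(_["frames"] = frames,
                      _["energies"] = energies,
                      _["n_frames"] = frame,
                      _["accepted"] = (double) accepted,
                      _["attempted"] = (double) n_steps,
                      _["diverged"] = diverged);
}
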