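#include <Rcpp.h>
#if defined(__GNUC__)
#define RESTRICT __restrict__
#else
#define RESTRICT
#endif
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

// Reduced Lennard-Jones units throughout: sigma = 1, kBT = 1, tau = 1.

// --- deterministic, platform-independent RNG (PCG32 + polar normals) -------
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double runif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  bool has_spare = false;
  double spare = 0.0;
  double rnorm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m; has_spare = true;
    return u * m;
  }
};

struct Sim {
  int nm, nw;                       // mobile / wall counts
  std::vector<double> x, v, f;      // mobile coords (3*nm), wall appended to x
  std::vector<double> wall;         // 3*nw
  std::vector<double> eps;          // per mobile monomer
  std::vector<int> bond_a, bond_b;  // FENE bonds
  std::vector<int> ang_a, ang_b, ang_c;
  double fene_k, fene_r0, bend_k;
  double rc_attr;                   // attractive LJ cutoff
  double rc_wca;                    // 2^(1/6)
  bool soft_mode;
  double soft_A;
  // neighbor list
  double skin;
  std::vector<int> nl_i, nl_j;      // j may index wall as nm..nm+nw-1
  std::vector<double> nl_eps;       // eps_ij for attractive pairs, else -1 (WCA)
  std::vector<double> x_at_build;
  // cached cell grid (box fixed after first build; walls are static)
  bool grid_ready = false;
  double glo[3]; int gnc[3];
  std::vector<int> wall_head;       // per-cell chain over wall particles only
  std::vector<int> wall_next;

  double coord(int p, int d) const {
    return p < nm ? x[3 * p + d] : wall[3 * (p - nm) + d];
  }

  double rlist() const { return std::max(rc_attr, rc_wca) + skin; }
  // WCA-only pairs never interact beyond rc_wca: keep them on a short list
  double rlist_wca() const { return rc_wca + skin; }

  void build_list() {
    nl_i.clear(); nl_j.clear(); nl_eps.clear();
    int ntot = nm + nw;
    double rl = rlist(), rl2 = rl * rl;
    if (!grid_ready) {
      // fixed bounding box: walls enclose the mobile monomers; without walls
      // use the initial coordinates plus a generous margin
      double hi[3];
      for (int d = 0; d < 3; ++d) { glo[d] = 1e300; hi[d] = -1e300; }
      for (int p = 0; p < ntot; ++p)
        for (int d = 0; d < 3; ++d) {
          double c = coord(p, d);
          if (c < glo[d]) glo[d] = c;
          if (c > hi[d]) hi[d] = c;
        }
      double margin = (nw > 0) ? 0.0 : 50.0;
      for (int d = 0; d < 3; ++d) {
        glo[d] -= margin;
        gnc[d] = std::max(1, (int)std::floor((hi[d] + margin - glo[d]) / rl));
      }
      int ncell = gnc[0] * gnc[1] * gnc[2];
      wall_head.assign(ncell, -1);
      wall_next.assign(nw, -1);
      for (int w = 0; w < nw; ++w) {
        int ci = cell_index(nm + w);
        wall_next[w] = wall_head[ci]; wall_head[ci] = w;
      }
      grid_ready = true;
    }
    int ncell = gnc[0] * gnc[1] * gnc[2];
    std::vector<int> head(ncell, -1), nxt(nm, -1);
    for (int p = 0; p < nm; ++p) {
      int ci = cell_index(p);
      nxt[p] = head[ci]; head[ci] = p;
    }
    double rlw = rlist_wca(), rlw2 = rlw * rlw;
    for (int i = 0; i < nm; ++i) {
      int cx = cell_coord(i, 0), cy = cell_coord(i, 1), cz = cell_coord(i, 2);
      bool i_bound = eps[i] > 0;
      for (int dx = -1; dx <= 1; ++dx) for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int ax = cx + dx, ay = cy + dy, az = cz + dz;
          if (ax < 0 || ax >= gnc[0] || ay < 0 || ay >= gnc[1] || az < 0 || az >= gnc[2])
            continue;
          int ci = ax + gnc[0] * (ay + gnc[1] * az);
          for (int j = head[ci]; j >= 0; j = nxt[j]) {
            if (j <= i) continue;               // half list for mobile-mobile
            double r2 = pair_r2(i, j);
            bool attractive = !soft_mode && i_bound && eps[j] > 0;
            if (r2 >= (attractive ? rl2 : rlw2)) continue;
            if (is_excluded(i, j)) continue;
            nl_i.push_back(i); nl_j.push_back(j);
            nl_eps.push_back(attractive ? std::sqrt(eps[i] * eps[j]) : -1.0);
          }
          for (int w = wall_head[ci]; w >= 0; w = wall_next[w]) {
            double r2 = pair_r2(i, nm + w);
            if (r2 >= rlw2) continue;
            nl_i.push_back(i); nl_j.push_back(nm + w);
            nl_eps.push_back(-1.0);
          }
        }
    }
    x_at_build.assign(x.begin(), x.end());
  }

  int cell_coord(int p, int d) const {
    double rl = rlist();
    int c = (int)std::floor((coord(p, d) - glo[d]) / rl);
    if (c < 0) c = 0;
    if (c >= gnc[d]) c = gnc[d] - 1;
    return c;
  }
  int cell_index(int p) const {
    return cell_coord(p, 0) + gnc[0] * (cell_coord(p, 1) + gnc[1] * cell_coord(p, 2));
  }
  double pair_r2(int i, int j) const {
    double r2 = 0;
    for (int d = 0; d < 3; ++d) {
      double df = x[3 * i + d] - coord(j, d);
      r2 += df * df;
    }
    return r2;
  }

  std::vector<int> chain_id;          // per mobile monomer

  // 1-2 pairs interact via FENE+WCA (bond term). Nonbonded interactions act
  // only between monomers separated by more than four bonds: short-range
  // WCA between near neighbors along the contour would stiffen the chain
  // beyond the worm-like-chain mapping (l_k ~ 2 sigma at k_theta = 1) that
  // the model is built on. Distant pairs keep full excluded volume.
  bool is_excluded(int i, int j) const {
    return std::abs(i - j) <= 4 && chain_id[i] == chain_id[j];
  }

  bool need_rebuild() const {
    double lim = 0.25 * skin * skin;  // (skin/2)^2
    for (int i = 0; i < nm; ++i) {
      double d2 = 0;
      for (int d = 0; d < 3; ++d) {
        double df = x[3 * i + d] - x_at_build[3 * i + d];
        d2 += df * df;
      }
      if (d2 > lim) return true;
    }
    return false;
  }

  // returns potential energies (bond, angle, pair); fills f
  void forces(double* e_bond, double* e_ang, double* e_pair, int step) {
    std::fill(f.begin(), f.end(), 0.0);
    double eb = 0, ea = 0, ep = 0;
    const double r02 = fene_r0 * fene_r0;
    // FENE + WCA between bonded pairs
    for (size_t k = 0; k < bond_a.size(); ++k) {
      int i = bond_a[k], j = bond_b[k];
      double dr[3], r2 = 0;
      for (int d = 0; d < 3; ++d) {
        dr[d] = x[3 * i + d] - x[3 * j + d];
        r2 += dr[d] * dr[d];
      }
      if (r2 >= r02)
        stop("FENE bond overstretched (r = %f >= R0 = %f) at step %d, bond %d-%d",
             std::sqrt(r2), fene_r0, step, i + 1, j + 1);
      double frac = r2 / r02;
      eb += -0.5 * fene_k * r02 * std::log(1.0 - frac);
      double fpair = -fene_k / (1.0 - frac);  // dU/dr / r with sign: force = fpair * dr
      // WCA part (eps = 1)
      if (r2 < rc_wca * rc_wca) {
        double sr2 = 1.0 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        eb += 4.0 * (sr12 - sr6) + 1.0;
        fpair += 24.0 * (2.0 * sr12 - sr6) * sr2;
      }
      for (int d = 0; d < 3; ++d) {
        f[3 * i + d] += fpair * dr[d];
        f[3 * j + d] -= fpair * dr[d];
      }
    }
    // bending: U = k_theta (1 - cos theta), theta between adjacent bond vectors
    for (size_t k = 0; k < ang_a.size(); ++k) {
      int i = ang_a[k], j = ang_b[k], l = ang_c[k];
      double b1[3], b2[3], n1 = 0, n2 = 0, dot = 0;
      for (int d = 0; d < 3; ++d) {
        b1[d] = x[3 * j + d] - x[3 * i + d];
        b2[d] = x[3 * l + d] - x[3 * j + d];
        n1 += b1[d] * b1[d]; n2 += b2[d] * b2[d];
        dot += b1[d] * b2[d];
      }
      n1 = std::sqrt(n1); n2 = std::sqrt(n2);
      double c = dot / (n1 * n2);
      if (c > 1) c = 1; if (c < -1) c = -1;
      ea += bend_k * (1.0 - c);
      // F = +k * grad(c)
      for (int d = 0; d < 3; ++d) {
        double e1 = b1[d] / n1, e2 = b2[d] / n2;
        double dcb1 = (e2 - c * e1) / n1;   // d c / d b1
        double dcb2 = (e1 - c * e2) / n2;   // d c / d b2
        f[3 * i + d] += bend_k * (-dcb1);
        f[3 * j + d] += bend_k * (dcb1 - dcb2);
        f[3 * l + d] += bend_k * (dcb2);
      }
    }
    // nonbonded pairs
    const double rc_attr2 = rc_attr * rc_attr, rc_wca2 = rc_wca * rc_wca;
    const double sr6c = std::pow(1.0 / rc_attr, 6.0);
    const double eshift_attr = 4.0 * (sr6c * sr6c - sr6c);  // U(rc) per unit eps
    const size_t npair = nl_i.size();
    const int* RESTRICT pi = nl_i.data();
    const int* RESTRICT pj = nl_j.data();
    const double* RESTRICT pe = nl_eps.data();
    const double* RESTRICT xw = wall.data();
    double* RESTRICT xp = x.data();
    double* RESTRICT fp = f.data();
    const int nm_ = nm;
    for (size_t k = 0; k < npair; ++k) {
      int i = pi[k], j = pj[k];
      const double* xj = (j < nm_) ? xp + 3 * j : xw + 3 * (j - nm_);
      double d0 = xp[3 * i] - xj[0];
      double d1 = xp[3 * i + 1] - xj[1];
      double d2v = xp[3 * i + 2] - xj[2];
      double r2 = d0 * d0 + d1 * d1 + d2v * d2v;
      double fpair = 0, en = 0;
      if (soft_mode) {
        // push-off potential U = A (1 + cos(pi r / rc)), rc = 1
        if (r2 < 1.0) {
          double r = std::sqrt(r2);
          en = soft_A * (1.0 + std::cos(M_PI * r));
          fpair = soft_A * M_PI * std::sin(M_PI * r) / std::max(r, 1e-9);
        }
      } else {
        double e = pe[k];
        bool attractive = e > 0;
        double rc2 = attractive ? rc_attr2 : rc_wca2;
        if (r2 < rc2) {
          if (!attractive) e = 1.0;
          double sr2 = 1.0 / r2, sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
          en = 4.0 * e * (sr12 - sr6) - (attractive ? e * eshift_attr : -e);
          fpair = 24.0 * e * (2.0 * sr12 - sr6) * sr2;
        }
      }
      if (fpair != 0 || en != 0) {
        ep += en;
        fp[3 * i] += fpair * d0;
        fp[3 * i + 1] += fpair * d1;
        fp[3 * i + 2] += fpair * d2v;
        if (j < nm_) {
          fp[3 * j] -= fpair * d0;
          fp[3 * j + 1] -= fpair * d1;
          fp[3 * j + 2] -= fpair * d2v;
        }
      }
    }
    *e_bond = eb; *e_ang = ea; *e_pair = ep;
  }
};

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos0, NumericMatrix vel0, NumericVector eps,
                      IntegerVector chain_lengths, NumericMatrix wall,
                      NumericVector shell_axes,
                      double fene_k, double fene_r0, double bend_k,
                      double lj_cut, double dt, double gamma, double temp,
                      int n_steps, int sample_every, double seed,
                      bool soft_mode, double soft_A) {
  Sim s;
  s.nm = pos0.nrow(); s.nw = wall.nrow();
  s.x.resize(3 * s.nm); s.v.resize(3 * s.nm); s.f.resize(3 * s.nm);
  s.wall.resize(3 * s.nw);
  for (int i = 0; i < s.nm; ++i)
    for (int d = 0; d < 3; ++d) {
      s.x[3 * i + d] = pos0(i, d);
      s.v[3 * i + d] = vel0(i, d);
    }
  for (int i = 0; i < s.nw; ++i)
    for (int d = 0; d < 3; ++d) s.wall[3 * i + d] = wall(i, d);
  s.eps.assign(eps.begin(), eps.end());
  s.chain_id.resize(s.nm);
  int at = 0;
  for (int c = 0; c < chain_lengths.size(); ++c) {
    int len = chain_lengths[c];
    for (int k = 0; k < len; ++k) s.chain_id[at + k] = c;
    for (int k = 0; k < len - 1; ++k) {
      s.bond_a.push_back(at + k); s.bond_b.push_back(at + k + 1);
    }
    for (int k = 0; k < len - 2; ++k) {
      s.ang_a.push_back(at + k); s.ang_b.push_back(at + k + 1);
      s.ang_c.push_back(at + k + 2);
    }
    at += len;
  }
  if (at != s.nm) stop("chain lengths do not sum to the number of monomers");
  s.fene_k = fene_k; s.fene_r0 = fene_r0; s.bend_k = bend_k;
  s.rc_attr = lj_cut; s.rc_wca = std::pow(2.0, 1.0 / 6.0);
  s.soft_mode = soft_mode; s.soft_A = soft_A;
  s.skin = 0.5;
  s.build_list();

  Pcg32 rng((uint64_t)seed);
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * temp);

  int nsamp = sample_every > 0 ? n_steps / sample_every : 0;
  NumericVector frames(nsamp > 0 ? (R_xlen_t)nsamp * s.nm * 3 : 0);
  NumericVector e_bond(nsamp), e_ang(nsamp), e_pair(nsamp);
  NumericVector mean_bond(nsamp), mean_cos(nsamp), max_shell(nsamp);
  IntegerVector n_outside(nsamp);
  double a2 = 0, b2 = 0, cc2 = 0;
  bool has_shell = shell_axes.size() == 3;
  if (has_shell) {
    a2 = shell_axes[0] * shell_axes[0];
    b2 = shell_axes[1] * shell_axes[1];
    cc2 = shell_axes[2] * shell_axes[2];
  }

  double eb, ea, ep;
  s.forces(&eb, &ea, &ep, 0);
  int isamp = 0;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < 3 * s.nm; ++i) s.v[i] += 0.5 * dt * s.f[i];
    for (int i = 0; i < 3 * s.nm; ++i) s.x[i] += 0.5 * dt * s.v[i];
    for (int i = 0; i < 3 * s.nm; ++i) s.v[i] = c1 * s.v[i] + c2 * rng.rnorm();
    for (int i = 0; i < 3 * s.nm; ++i) s.x[i] += 0.5 * dt * s.v[i];
    if (s.need_rebuild()) s.build_list();
    s.forces(&eb, &ea, &ep, step);
    for (int i = 0; i < 3 * s.nm; ++i) s.v[i] += 0.5 * dt * s.f[i];

    if (sample_every > 0 && step % sample_every == 0) {
      for (int i = 0; i < s.nm; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)isamp * s.nm * 3 + (R_xlen_t)d * s.nm + i] = s.x[3 * i + d];
      e_bond[isamp] = eb; e_ang[isamp] = ea; e_pair[isamp] = ep;
      double bl = 0;
      for (size_t k = 0; k < s.bond_a.size(); ++k) {
        double r2 = 0;
        for (int d = 0; d < 3; ++d) {
          double df = s.x[3 * s.bond_a[k] + d] - s.x[3 * s.bond_b[k] + d];
          r2 += df * df;
        }
        bl += std::sqrt(r2);
      }
      mean_bond[isamp] = s.bond_a.empty() ? NA_REAL : bl / s.bond_a.size();
      double mc = 0;
      for (size_t k = 0; k < s.ang_a.size(); ++k) {
        double b1[3], b2v[3], n1 = 0, n2 = 0, dot = 0;
        for (int d = 0; d < 3; ++d) {
          b1[d] = s.x[3 * s.ang_b[k] + d] - s.x[3 * s.ang_a[k] + d];
          b2v[d] = s.x[3 * s.ang_c[k] + d] - s.x[3 * s.ang_b[k] + d];
          n1 += b1[d] * b1[d]; n2 += b2v[d] * b2v[d]; dot += b1[d] * b2v[d];
        }
        mc += dot / std::sqrt(n1 * n2);
      }
      mean_cos[isamp] = s.ang_a.empty() ? NA_REAL : mc / s.ang_a.size();
      if (has_shell) {
        double mx = 0; int nout = 0;
        for (int i = 0; i < s.nm; ++i) {
          double val = s.x[3 * i] * s.x[3 * i] / a2 +
                       s.x[3 * i + 1] * s.x[3 * i + 1] / b2 +
                       s.x[3 * i + 2] * s.x[3 * i + 2] / cc2;
          if (val > mx) mx = val;
          if (val >= 1.0) ++nout;
        }
        max_shell[isamp] = mx; n_outside[isamp] = nout;
      } else {
        max_shell[isamp] = NA_REAL; n_outside[isamp] = NA_INTEGER;
      }
      ++isamp;
    }
  }

  NumericMatrix xout(s.nm, 3), vout(s.nm, 3);
  for (int i = 0; i < s.nm; ++i)
    for (int d = 0; d < 3; ++d) {
      xout(i, d) = s.x[3 * i + d];
      vout(i, d) = s.v[3 * i + d];
    }
  if (nsamp > 0) frames.attr("dim") = IntegerVector::create(s.nm, 3, nsamp);
  return List::create(
    _["positions"] = xout, _["velocities"] = vout, _["frames"] = frames,
    _["e_bond"] = e_bond, _["e_angle"] = e_ang, _["e_pair"] = e_pair,
    _["mean_bond"] = mean_bond, _["mean_cos"] = mean_cos,
    _["max_shell"] = max_shell, _["n_outside"] = n_outside);
}
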