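// Probabilistic streamline propagation through a Bingham-lobe fODF field,
// and per-voxel streamline visit counting (ACM). All randomness comes from
// R's RNG, so set.seed() on the R side makes every run reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KAPPA_FLOOR = -1e4; // treated as a deterministic axis

// Exact Bingham sampler by rejection from an angular central Gaussian
// envelope (Kent, Ganeiber & Mardia 2013). In the lobe frame the density
// is prop. to exp(-l1 t1^2 - l2 t2^2) with l_j = -k_j >= 0 and the mode
// along u3 (l3 = 0). The envelope ACG uses Omega = I + (2/b) Lambda with b
// solving sum_j 1/(b + 2 l_j) = 1; acceptance is bounded below ~0.5 for
// every concentration, unlike uniform-sphere proposals whose acceptance
// collapses at large |kappa|. Floor kappas are delta lobes and return the
// mode (random antipodal sign); after max_rej failures the mode is a
// documented fallback.
static void sample_bingham_axis(const double* u1, const double* u2,
                                const double* u3, double k1, double k2,
                                int max_rej, double* out) {
  if (k1 <= KAPPA_FLOOR + 1e-6 && k2 <= KAPPA_FLOOR + 1e-6) {
    double s = (R::runif(0, 1) < 0.5) ? -1.0 : 1.0;
    for (int c = 0; c < 3; ++c) out[c] = s * u3[c];
    return;
  }
  double l[3] = {-k1, -k2, 0.0};
  // solve sum 1/(b + 2 l_j) = 1 for b in (0, 3] (monotone; Newton with
  // bisection safeguard)
  double lo = 1e-12, hi = 3.0, b = 1.0;
  for (int it = 0; it < 60; ++it) {
    double f = -1.0, fp = 0.0;
    for (int j = 0; j < 3; ++j) {
      double d = b + 2.0 * l[j];
      f += 1.0 / d;
      fp -= 1.0 / (d * d);
    }
    if (f > 0) lo = b; else hi = b;
    double bn = b - f / fp;
    b = (bn > lo && bn < hi) ? bn : 0.5 * (lo + hi);
    if (hi - lo < 1e-12) break;
  }
  double om[3], sdv[3];
  for (int j = 0; j < 3; ++j) {
    om[j] = 1.0 + 2.0 * l[j] / b;
    sdv[j] = 1.0 / std::sqrt(om[j]);
  }
  double logM = -(3.0 - b) / 2.0 + 1.5 * std::log(3.0 / b);
  double t[3];
  for (int it = 0; it < max_rej; ++it) {
    double y0 = R::norm_rand() * sdv[0];
    double y1 = R::norm_rand() * sdv[1];
    double y2 = R::norm_rand() * sdv[2];
    double n = std::sqrt(y0 * y0 + y1 * y1 + y2 * y2);
    if (n < 1e-12) continue;
    t[0] = y0 / n; t[1] = y1 / n; t[2] = y2 / n;
    double q = l[0] * t[0] * t[0] + l[1] * t[1] * t[1];
    double qe = om[0] * t[0] * t[0] + om[1] * t[1] * t[1] +
                om[2] * t[2] * t[2];
    double logacc = -q - logM + 1.5 * std::log(qe);
    if (std::log(R::runif(0, 1) + 1e-300) < logacc) {
      for (int c = 0; c < 3; ++c)
        out[c] = t[0] * u1[c] + t[1] * u2[c] + t[2] * u3[c];
      return;
    }
  }
  double s = (R::runif(0, 1) < 0.5) ? -1.0 : 1.0;
  for (int c = 0; c < 3; ++c) out[c] = s * u3[c];
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_bingham(NumericMatrix frame, double k1, double k2,
                                 int n, int max_rej) {
  NumericMatrix out(n, 3);
  double u1[3], u2[3], u3[3], x[3];
  for (int c = 0; c < 3; ++c) {
    u1[c] = frame(c, 0); u2[c] = frame(c, 1); u3[c] = frame(c, 2);
  }
  for (int i = 0; i < n; ++i) {
    sample_bingham_axis(u1, u2, u3, k1, k2, max_rej, x);
    for (int c = 0; c < 3; ++c) out(i, c) = x[c];
  }
  return out;
}

// --- fODF field view --------------------------------------------------------

struct FodfView {
  int nx, ny, nz, nvox;
  const int* nlobes;       // nvox
  const double* weights;   // nvox * 2
  const double* axes;      // nvox * 2 * 9 (u1, u2, u3 column-wise per lobe)
  const double* kappa;     // nvox * 2 * 2
  const int* mask;         // nvox
  double vx, vy, vz;       // voxel size, mm

  inline int lin(int i, int j, int k) const { return i + nx * (j + ny * k); }
  inline bool inside(int i, int j, int k) const {
    return i >= 0 && i < nx && j >= 0 && j < ny && k >= 0 && k < nz;
  }
  inline const double* lobe_axes(int v, int l) const {
    return axes + 9 * (2 * v + l);
  }
};

static FodfView make_view(List field) {
  FodfView f;
  IntegerVector dim = field["dim"];
  f.nx = dim[0]; f.ny = dim[1]; f.nz = dim[2];
  f.nvox = f.nx * f.ny * f.nz;
  f.nlobes = INTEGER(as<IntegerVector>(field["nlobes"]));
  f.weights = REAL(as<NumericVector>(field["weights"]));
  f.axes = REAL(as<NumericVector>(field["axes"]));
  f.kappa = REAL(as<NumericVector>(field["kappa"]));
  f.mask = INTEGER(as<IntegerVector>(field["mask"]));
  NumericVector vs = field["voxel_size"];
  f.vx = vs[0]; f.vy = vs[1]; f.vz = vs[2];
  return f;
}

// probabilistic-nearest interpolation: pick one of the 8 surrounding voxels
// with probability equal to its trilinear weight (independent per-axis
// Bernoulli draws realize exactly that product weight). Returns -1 when the
// selected voxel falls outside the grid.
static int pick_voxel(const FodfView& f, const double* pos) {
  int v[3];
  double p[3] = {pos[0], pos[1], pos[2]};
  int dims[3] = {f.nx, f.ny, f.nz};
  for (int a = 0; a < 3; ++a) {
    double base = std::floor(p[a]);
    double frac = p[a] - base;
    int idx = (int)base + ((R::runif(0, 1) < frac) ? 1 : 0);
    if (idx < 0 || idx >= dims[a]) return -1;
    v[a] = idx;
  }
  return f.lin(v[0], v[1], v[2]);
}

inline int nearest_voxel(const FodfView& f, const double* pos) {
  int i = (int)std::lround(pos[0]);
  int j = (int)std::lround(pos[1]);
  int k = (int)std::lround(pos[2]);
  if (!f.inside(i, j, k)) return -1;
  return f.lin(i, j, k);
}

// Termination codes
enum { TERM_MASK = 1, TERM_CURV = 2, TERM_MAXSTEP = 3 };

// Propagate one half-track from `seed` (continuous voxel coords) along
// `dir0` (unit, world mm frame). Appends points (excluding the seed) to
// `pts`. Returns the termination code.
static int track_half(const FodfView& f, const double* seed,
                      const double* dir0, double step_frac, int max_steps,
                      double curv_limit_rad, int max_rej,
                      std::vector<double>& pts) {
  double step_mm = step_frac * std::min(f.vx, std::min(f.vy, f.vz));
  double pos[3] = {seed[0], seed[1], seed[2]};
  double dir[3] = {dir0[0], dir0[1], dir0[2]};
  double cum_turn = 0.0;
  int cur_vox = nearest_voxel(f, pos);
  for (int s = 0; s < max_steps; ++s) {
    // select the fODF voxel stochastically, then the lobe most aligned
    // with the current heading
    int v = pick_voxel(f, pos);
    if (v < 0 || f.mask[v] == 0 || f.nlobes[v] == 0) return TERM_MASK;
    int nl = f.nlobes[v];
    int best = 0;
    double best_al = -1.0;
    for (int l = 0; l < nl; ++l) {
      const double* u3 = f.lobe_axes(v, l) + 6;
      double al = std::fabs(dir[0] * u3[0] + dir[1] * u3[1] + dir[2] * u3[2]);
      if (al > best_al) { best_al = al; best = l; }
    }
    const double* ax = f.lobe_axes(v, best);
    double k1 = f.kappa[2 * (2 * v + best)];
    double k2 = f.kappa[2 * (2 * v + best) + 1];
    double nd[3];
    sample_bingham_axis(ax, ax + 3, ax + 6, k1, k2, max_rej, nd);
    double dp = nd[0] * dir[0] + nd[1] * dir[1] + nd[2] * dir[2];
    if (dp < 0) { nd[0] = -nd[0]; nd[1] = -nd[1]; nd[2] = -nd[2]; dp = -dp; }
    // intra-voxel cumulative turning; reset on voxel change
    double cosang = std::max(-1.0, std::min(1.0, dp));
    double npos[3] = {pos[0] + step_mm * nd[0] / f.vx,
                      pos[1] + step_mm * nd[1] / f.vy,
                      pos[2] + step_mm * nd[2] / f.vz};
    int nvox = nearest_voxel(f, npos);
    if (nvox < 0 || f.mask[nvox] == 0) return TERM_MASK;
    if (nvox != cur_vox) {
      cum_turn = 0.0;
      cur_vox = nvox;
    } else {
      cum_turn += std::acos(cosang);
      if (cum_turn > curv_limit_rad) return TERM_CURV;
    }
    pts.push_back(npos[0]); pts.push_back(npos[1]); pts.push_back(npos[2]);
    pos[0] = npos[0]; pos[1] = npos[1]; pos[2] = npos[2];
    dir[0] = nd[0]; dir[1] = nd[1]; dir[2] = nd[2];
  }
  return TERM_MAXSTEP;
}

// Launch a full (optionally bidirectional) streamline from a seed voxel
// center. Fills `pts` with the ordered polyline and returns the two
// termination codes.
static void track_full(const FodfView& f, const int* seed_ijk,
                       double step_frac, int max_steps,
                       double curv_limit_rad, int max_rej, bool bidir,
                       std::vector<double>& pts, int* term) {
  double seed[3] = {(double)seed_ijk[0], (double)seed_ijk[1],
                    (double)seed_ijk[2]};
  int v = f.lin(seed_ijk[0], seed_ijk[1], seed_ijk[2]);
  term[0] = TERM_MASK; term[1] = TERM_MASK;
  pts.clear();
  if (f.nlobes[v] == 0) { // isotropic/background seed: the seed point only
    pts.push_back(seed[0]); pts.push_back(seed[1]); pts.push_back(seed[2]);
    return;
  }
  // seed lobe chosen by weight
  int nl = f.nlobes[v];
  double wsum = 0.0;
  for (int l = 0; l < nl; ++l) wsum += f.weights[2 * v + l];
  double u = R::runif(0, 1) * wsum, acc = 0.0;
  int lobe = nl - 1;
  for (int l = 0; l < nl; ++l) {
    acc += f.weights[2 * v + l];
    if (u <= acc) { lobe = l; break; }
  }
  const double* ax = f.lobe_axes(v, lobe);
  double k1 = f.kappa[2 * (2 * v + lobe)];
  double k2 = f.kappa[2 * (2 * v + lobe) + 1];
  double a0[3];
  sample_bingham_axis(ax, ax + 3, ax + 6, k1, k2, max_rej, a0);

  std::vector<double> fwd, bwd;
  term[1] = track_half(f, seed, a0, step_frac, max_steps, curv_limit_rad,
                       max_rej, fwd);
  if (bidir) {
    double neg[3] = {-a0[0], -a0[1], -a0[2]};
    term[0] = track_half(f, seed, neg, step_frac, max_steps, curv_limit_rad,
                         max_rej, bwd);
  }
  // polyline: reversed backward half, seed, forward half
  for (size_t i = bwd.size(); i >= 3; i -= 3) {
    pts.push_back(bwd[i - 3]); pts.push_back(bwd[i - 2]); pts.push_back(bwd[i - 1]);
  }
  pts.push_back(seed[0]); pts.push_back(seed[1]); pts.push_back(seed[2]);
  for (size_t i = 0; i < fwd.size(); ++i) pts.push_back(fwd[i]);
}

// [[Rcpp::export]]
List cpp_propagate(List field, IntegerVector seed, double step_frac,
                   int max_steps, double curv_limit_deg, int max_rej,
                   bool bidirectional) {
  FodfView f = make_view(field);
  int s[3] = {seed[0], seed[1], seed[2]};
  if (!f.inside(s[0], s[1], s[2]) || f.mask[f.lin(s[0], s[1], s[2])] == 0)
    stop("seed outside mask");
  std::vector<double> pts;
  int term[2];
  track_full(f, s, step_frac, max_steps, curv_limit_deg * M_PI / 180.0,
             max_rej, bidirectional, pts, term);
  int npt = pts.size() / 3;
  NumericMatrix P(npt, 3);
  for (int i = 0; i < npt; ++i)
    for (int c = 0; c < 3; ++c) P(i, c) = pts[3 * i + c];
  return List::create(_["points"] = P,
                      _["term"] = IntegerVector::create(term[0], term[1]));
}

// [[Rcpp::export]]
IntegerVector cpp_compute_acm(List field, IntegerVector seed_mask,
                              int n_per_seed, double step_frac, int max_steps,
                              double curv_limit_deg, int max_rej,
                              bool bidirectional, bool unique_visits) {
  FodfView f = make_view(field);
  double curv = curv_limit_deg * M_PI / 180.0;
  IntegerVector counts(f.nvox);
  std::vector<int> stamp(f.nvox, -1);
  std::vector<double> pts;
  int term[2];
  int sl_id = 0;
  for (int k = 0; k < f.nz; ++k)
    for (int j = 0; j < f.ny; ++j)
      for (int i = 0; i < f.nx; ++i) {
        int v = f.lin(i, j, k);
        if (seed_mask[v] == 0) continue;
        int s[3] = {i, j, k};
        for (int n = 0; n < n_per_seed; ++n) {
          track_full(f, s, step_frac, max_steps, curv, max_rej,
                     bidirectional, pts, term);
          ++sl_id;
          int prev = -1;
          int npt = pts.size() / 3;
          for (int p = 0; p < npt; ++p) {
            int vv = nearest_voxel(f, &pts[3 * p]);
            if (vv < 0) continue;
            if (unique_visits) {
              if (stamp[vv] != sl_id) { stamp[vv] = sl_id; counts[vv] += 1; }
            } else {
              if (vv != prev) counts[vv] += 1;
            }
            prev = vv;
          }
        }
      }
  return counts;
}
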