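// Compiled core: Catmull-Rom spline evaluation and discretization, the
// multi-tensor forward projection of fiber segments onto the voxel grid,
// and the simulated-annealing Metropolis-Hastings loop with incremental
// energy updates.  The R level holds reference implementations of the
// simple pieces; everything performance-critical lives here.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small geometry helpers
// ---------------------------------------------------------------------------

// world -> continuous voxel coordinate, ia = first 3 rows of the inverse
// affine, row-major [r*4 + c]
static inline void world_to_vox(const double *ia, const double *p, double *out) {
  for (int r = 0; r < 3; ++r)
    out[r] = ia[r * 4 + 0] * p[0] + ia[r * 4 + 1] * p[1] +
             ia[r * 4 + 2] * p[2] + ia[r * 4 + 3];
}

// nearest-voxel tissue lookup: k>0 GM label, -1 WM, 0 outside
static inline int classify_vox(const int *gm, const int *wm, const int *dims,
                               const double *v) {
  int ix = (int)std::floor(v[0] + 0.5);
  int iy = (int)std::floor(v[1] + 0.5);
  int iz = (int)std::floor(v[2] + 0.5);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= dims[0] || iy >= dims[1] ||
      iz >= dims[2])
    return 0;
  R_xlen_t lin = (R_xlen_t)ix + dims[0] * ((R_xlen_t)iy + dims[1] * (R_xlen_t)iz);
  if (gm[lin] > 0) return gm[lin];
  if (wm[lin] != 0) return -1;
  return 0;
}

static inline int classify_world(const int *gm, const int *wm, const int *dims,
                                 const double *ia, const double *p) {
  double v[3];
  world_to_vox(ia, p, v);
  return classify_vox(gm, wm, dims, v);
}

// uniform Catmull-Rom with duplicated end control points; t in [0,1]
// (clamped) spans the whole curve, knot i at t = i/(n-1)
static inline void cr_point(const double *C, int n, double t, double *out) {
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  double s = t * (n - 1);
  int i = (int)std::floor(s);
  if (i > n - 2) i = n - 2;
  double u = s - i;
  int im1 = i - 1 < 0 ? 0 : i - 1;
  int ip2 = i + 2 > n - 1 ? n - 1 : i + 2;
  const double *Pm1 = C + 3 * im1, *P0 = C + 3 * i, *P1 = C + 3 * (i + 1),
               *P2 = C + 3 * ip2;
  double u2 = u * u, u3 = u2 * u;
  for (int d = 0; d < 3; ++d) {
    out[d] = 0.5 * (2.0 * P0[d] + (-Pm1[d] + P1[d]) * u +
                    (2.0 * Pm1[d] - 5.0 * P0[d] + 4.0 * P1[d] - P2[d]) * u2 +
                    (-Pm1[d] + 3.0 * P0[d] - 3.0 * P1[d] + P2[d]) * u3);
  }
}

// copy an n x 3 R matrix into a flat row-major [i*3 + d] buffer
static std::vector<double> ctrl_buffer(const NumericMatrix &C) {
  int n = C.nrow();
  std::vector<double> buf(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) buf[3 * i + d] = C(i, d);
  return buf;
}

struct Segments {
  std::vector<double> mid;  // [3*j + d]
  std::vector<double> dir;  // unit chord, [3*j + d]
  double len;               // common arc length per segment
  int n;
};

// equal-arc-length discretization by dense sampling of the spline
static Segments discretize_ctrl(const std::vector<double> &C, int nc,
                                double seg_len, int dense_per_span = 64) {
  Segments out;
  int m = (nc - 1) * dense_per_span + 1;
  std::vector<double> pts(3 * m), cum(m, 0.0);
  for (int j = 0; j < m; ++j) {
    double t = (double)j / (m - 1);
    cr_point(C.data(), nc, t, &pts[3 * j]);
    if (j > 0) {
      double d2 = 0;
      for (int d = 0; d < 3; ++d) {
        double dd = pts[3 * j + d] - pts[3 * (j - 1) + d];
        d2 += dd * dd;
      }
      cum[j] = cum[j - 1] + std::sqrt(d2);
    }
  }
  double L = cum[m - 1];
  int nseg = (L <= seg_len) ? 1 : (int)std::ceil(L / seg_len - 1e-12);
  out.n = nseg;
  out.len = L / nseg;
  out.mid.resize(3 * nseg);
  out.dir.resize(3 * nseg);
  // walk the dense polyline to find the point at arc position s
  int cursor = 0;
  auto point_at = [&](double s, double *p) {
    if (s <= 0) { std::memcpy(p, &pts[0], 3 * sizeof(double)); return; }
    if (s >= L) { std::memcpy(p, &pts[3 * (m - 1)], 3 * sizeof(double)); return; }
    while (cursor < m - 2 && cum[cursor + 1] < s) ++cursor;
    while (cursor > 0 && cum[cursor] > s) --cursor;
    double seg = cum[cursor + 1] - cum[cursor];
    double a = seg > 0 ? (s - cum[cursor]) / seg : 0.0;
    for (int d = 0; d < 3; ++d)
      p[d] = pts[3 * cursor + d] +
             a * (pts[3 * (cursor + 1) + d] - pts[3 * cursor + d]);
  };
  std::vector<double> p0(3), p1(3);
  for (int j = 0; j < nseg; ++j) {
    double s0 = out.len * j, s1 = out.len * (j + 1);
    point_at(s0, p0.data());
    point_at(s1, p1.data());
    point_at(0.5 * (s0 + s1), &out.mid[3 * j]);
    double nrm = 0;
    for (int d = 0; d < 3; ++d) {
      out.dir[3 * j + d] = p1[d] - p0[d];
      nrm += out.dir[3 * j + d] * out.dir[3 * j + d];
    }
    nrm = std::sqrt(nrm);
    if (nrm > 0) {
      for (int d = 0; d < 3; ++d) out.dir[3 * j + d] /= nrm;
    } else {
      out.dir[3 * j] = 1.0; out.dir[3 * j + 1] = 0.0; out.dir[3 * j + 2] = 0.0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// forward model
// ---------------------------------------------------------------------------

struct ForwardParams {
  const double *dirs;   // G x 3, row-major [g*3 + d]
  const double *bvals;  // length G (s/mm^2; eigenvalues in um^2/ms => b/1000)
  int G;
  double la, lr;        // axial and (mean) radial eigenvalue, um^2/ms
  double sigma;         // kernel width, voxel units
  double trunc;         // truncation radius in multiples of sigma
  double seg_len;       // mm
  const double *ia;     // inverse affine rows
  const int *dims;
};

// per-fiber sparse contribution: voxel linear indices + per-direction values
struct Contrib {
  std::vector<int> vox;          // 0-based linear voxel index
  std::vector<double> vals;      // [row*G + g]
  int nv = 0;
};

// accumulate the unit-weight contribution of one fiber over the masked grid
static void fiber_contrib(const std::vector<double> &C, int nc,
                          const ForwardParams &fp, const int *mask,
                          Contrib &out) {
  Segments segs = discretize_ctrl(C, nc, fp.seg_len);
  int G = fp.G;
  double r = fp.trunc * fp.sigma;
  double r2 = r * r;
  double inv_s2 = 1.0 / (fp.sigma * fp.sigma);
  std::unordered_map<int, int> rowOf;
  rowOf.reserve(256);
  std::vector<double> tf(G);
  double v[3];
  for (int s = 0; s < segs.n; ++s) {
    const double *ns = &segs.dir[3 * s];
    for (int g = 0; g < G; ++g) {
      const double *n = fp.dirs + 3 * g;
      double c = n[0] * ns[0] + n[1] * ns[1] + n[2] * ns[2];
      // n' D n for an axially symmetric tensor oriented along the segment
      double adc = fp.lr + (fp.la - fp.lr) * c * c;        // um^2/ms
      tf[g] = std::exp(-fp.bvals[g] * 1e-3 * adc);         // b in s/mm^2
    }
    world_to_vox(fp.ia, &segs.mid[3 * s], v);
    int x0 = (int)std::ceil(v[0] - r), x1 = (int)std::floor(v[0] + r);
    int y0 = (int)std::ceil(v[1] - r), y1 = (int)std::floor(v[1] + r);
    int z0 = (int)std::ceil(v[2] - r), z1 = (int)std::floor(v[2] + r);
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
    if (x1 > fp.dims[0] - 1) x1 = fp.dims[0] - 1;
    if (y1 > fp.dims[1] - 1) y1 = fp.dims[1] - 1;
    if (z1 > fp.dims[2] - 1) z1 = fp.dims[2] - 1;
    for (int iz = z0; iz <= z1; ++iz) {
      double dz = v[2] - iz;
      for (int iy = y0; iy <= y1; ++iy) {
        double dy = v[1] - iy;
        for (int ix = x0; ix <= x1; ++ix) {
          double dx = v[0] - ix;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > r2) continue;
          int lin = ix + fp.dims[0] * (iy + fp.dims[1] * iz);
          if (mask && !mask[lin]) continue;
          double gauss = std::exp(-d2 * inv_s2);
          auto it = rowOf.find(lin);
          int row;
          if (it == rowOf.end()) {
            row = out.nv++;
            rowOf.emplace(lin, row);
            out.vox.push_back(lin);
            out.vals.resize((size_t)out.nv * G, 0.0);
          } else {
            row = it->second;
          }
          double *vp = &out.vals[(size_t)row * G];
          for (int g = 0; g < G; ++g) vp[g] += gauss * tf[g];
        }
      }
    }
  }
}

// add s * contrib to the field rho (voxel-major [v*G+g]) and return the
// induced change in sum((rho - data)^2) over the touched entries
static double apply_contrib(std::vector<double> &rho, const double *data,
                            int G, const Contrib &c, double s) {
  double dE = 0.0;
  for (int row = 0; row < c.nv; ++row) {
    size_t off = (size_t)c.vox[row] * G;
    const double *vp = &c.vals[(size_t)row * G];
    double *rp = &rho[off];
    const double *dp = data + off;
    for (int g = 0; g < G; ++g) {
      double e0 = rp[g] - dp[g];
      rp[g] += s * vp[g];
      double e1 = rp[g] - dp[g];
      dE += e1 * e1 - e0 * e0;
    }
  }
  return dE;
}

// ---------------------------------------------------------------------------
// exported primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_cr_eval(NumericMatrix ctrl, NumericVector t) {
  std::vector<double> C = ctrl_buffer(ctrl);
  int n = ctrl.nrow();
  NumericMatrix out(t.size(), 3);
  double p[3];
  for (R_xlen_t i = 0; i < t.size(); ++i) {
    cr_point(C.data(), n, t[i], p);
    for (int d = 0; d < 3; ++d) out(i, d) = p[d];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_discretize(NumericMatrix ctrl, double seg_len) {
  std::vector<double> C = ctrl_buffer(ctrl);
  Segments s = discretize_ctrl(C, ctrl.nrow(), seg_len);
  NumericMatrix mid(s.n, 3), dir(s.n, 3);
  for (int j = 0; j < s.n; ++j)
    for (int d = 0; d < 3; ++d) {
      mid(j, d) = s.mid[3 * j + d];
      dir(j, d) = s.dir[3 * j + d];
    }
  return List::create(_["mid"] = mid, _["dir"] = dir,
                      _["length"] = NumericVector(s.n, s.len));
}

static ForwardParams make_fp(const NumericMatrix &dirs,
                             const NumericVector &bvals,
                             const NumericVector &lambda, double sigma,
                             double trunc, double seg_len,
                             const std::vector<double> &ia,
                             const IntegerVector &dims,
                             std::vector<double> &dir_buf) {
  ForwardParams fp;
  int G = dirs.nrow();
  dir_buf.resize(3 * G);
  for (int g = 0; g < G; ++g)
    for (int d = 0; d < 3; ++d) dir_buf[3 * g + d] = dirs(g, d);
  fp.dirs = dir_buf.data();
  fp.bvals = REAL(bvals);
  fp.G = G;
  fp.la = lambda[0];
  fp.lr = 0.5 * (lambda[1] + lambda[2]);
  fp.sigma = sigma;
  fp.trunc = trunc;
  fp.seg_len = seg_len;
  fp.ia = ia.data();
  fp.dims = INTEGER(dims);
  return fp;
}

static std::vector<double> inv_affine_rows(const NumericMatrix &inv_affine) {
  std::vector<double> ia(12);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) ia[r * 4 + c] = inv_affine(r, c);
  return ia;
}

// [[Rcpp::export]]
List cpp_fiber_contribution(NumericMatrix ctrl, IntegerVector dims,
                            NumericMatrix inv_affine, NumericMatrix dirs,
                            NumericVector bvals, NumericVector lambda,
                            double sigma, double trunc, double seg_len,
                            Nullable<IntegerVector> mask = R_NilValue) {
  std::vector<double> ia = inv_affine_rows(inv_affine), dir_buf;
  ForwardParams fp =
      make_fp(dirs, bvals, lambda, sigma, trunc, seg_len, ia, dims, dir_buf);
  const int *mptr = nullptr;
  IntegerVector m;
  if (mask.isNotNull()) { m = mask.get(); mptr = INTEGER(m); }
  Contrib c;
  std::vector<double> C = ctrl_buffer(ctrl);
  fiber_contrib(C, ctrl.nrow(), fp, mptr, c);
  IntegerVector vox(c.nv);
  NumericMatrix vals(c.nv, fp.G);
  for (int row = 0; row < c.nv; ++row) {
    vox[row] = c.vox[row];  // 0-based; R side documents/offsets
    for (int g = 0; g < fp.G; ++g) vals(row, g) = c.vals[(size_t)row * fp.G + g];
  }
  return List::create(_["voxels"] = vox, _["values"] = vals);
}

// [[Rcpp::export]]
NumericVector cpp_predict_signal(List ctrl_list, NumericVector weights,
                                 IntegerVector dims, NumericMatrix inv_affine,
                                 NumericMatrix dirs, NumericVector bvals,
                                 NumericVector lambda, double sigma,
                                 double trunc, double seg_len) {
  std::vector<double> ia = inv_affine_rows(inv_affine), dir_buf;
  ForwardParams fp =
      make_fp(dirs, bvals, lambda, sigma, trunc, seg_len, ia, dims, dir_buf);
  R_xlen_t V = (R_xlen_t)dims[0] * dims[1] * dims[2];
  NumericVector out(V * fp.G);  // R array layout [v + V*g]
  for (int f = 0; f < ctrl_list.size(); ++f) {
    NumericMatrix ctrl = ctrl_list[f];
    std::vector<double> C = ctrl_buffer(ctrl);
    Contrib c;
    fiber_contrib(C, ctrl.nrow(), fp, nullptr, c);
    double w = weights[f];
    for (int row = 0; row < c.nv; ++row)
      for (int g = 0; g < fp.G; ++g)
        out[c.vox[row] + V * (R_xlen_t)g] += w * c.vals[(size_t)row * fp.G + g];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_classify(NumericMatrix points, IntegerVector gm,
                           IntegerVector wm, IntegerVector dims,
                           NumericMatrix inv_affine) {
  std::vector<double> ia = inv_affine_rows(inv_affine);
  IntegerVector out(points.nrow());
  double p[3];
  for (int i = 0; i < points.nrow(); ++i) {
    for (int d = 0; d < 3; ++d) p[d] = points(i, d);
    out[i] = classify_world(INTEGER(gm), INTEGER(wm), INTEGER(dims), ia.data(), p);
  }
  return out;
}

// ---------------------------------------------------------------------------
// simulated annealing
// ---------------------------------------------------------------------------

struct Fiber {
  std::vector<double> ctrl;  // 3 * nc
  int nc;
  double w;
  Contrib c;
};

static bool valid_ctrl(const std::vector<double> &C, int nc, const int *gm,
                       const int *wm, const int *dims, const double *ia,
                       double min_chord_cos) {
  int cls = classify_world(gm, wm, dims, ia, &C[0]);
  if (cls <= 0) return false;
  cls = classify_world(gm, wm, dims, ia, &C[3 * (nc - 1)]);
  if (cls <= 0) return false;
  for (int i = 1; i < nc - 1; ++i)
    if (classify_world(gm, wm, dims, ia, &C[3 * i]) != -1) return false;
  // smoothness: bound the turn between consecutive control-point chords;
  // an unbounded spline can fold back inside the mask, doubling its
  // density at half its weight with no data cost
  if (min_chord_cos > -1.0) {
    double prev[3];
    bool have_prev = false;
    for (int i = 0; i + 1 < nc; ++i) {
      double ch[3];
      double nrm = 0;
      for (int d = 0; d < 3; ++d) {
        ch[d] = C[3 * (i + 1) + d] - C[3 * i + d];
        nrm += ch[d] * ch[d];
      }
      nrm = std::sqrt(nrm);
      if (nrm <= 1e-12) continue;
      for (int d = 0; d < 3; ++d) ch[d] /= nrm;
      if (have_prev) {
        double dot = ch[0] * prev[0] + ch[1] * prev[1] + ch[2] * prev[2];
        if (dot < min_chord_cos) return false;
      }
      std::memcpy(prev, ch, sizeof(prev));
      have_prev = true;
    }
  }
  return true;
}

// truncated normal on [0,1] by rejection; returns false if it fails
static bool trunc_norm01(double mu, double sd, double &out) {
  for (int k = 0; k < 100; ++k) {
    double x = mu + sd * R::norm_rand();
    if (x >= 0.0 && x <= 1.0) { out = x; return true; }
  }
  return false;
}

static double full_energy(const std::vector<double> &rho, const double *data,
                          const std::vector<int> &mask_idx, int G) {
  double E = 0.0;
  for (int v : mask_idx) {
    size_t off = (size_t)v * G;
    for (int g = 0; g < G; ++g) {
      double e = rho[off + g] - data[off + g];
      E += e * e;
    }
  }
  return E;
}

// [[Rcpp::export]]
List cpp_sa_run(List ctrl_list, NumericVector weights, NumericVector data,
                NumericVector baseline, IntegerVector mask, IntegerVector gm,
                IntegerVector wm, IntegerVector dims,
                NumericMatrix inv_affine, NumericMatrix dirs,
                NumericVector bvals, NumericVector lambda, double sigma,
                double trunc, double seg_len, List control) {
  std::vector<double> ia = inv_affine_rows(inv_affine), dir_buf;
  ForwardParams fp =
      make_fp(dirs, bvals, lambda, sigma, trunc, seg_len, ia, dims, dir_buf);
  const int G = fp.G;
  const R_xlen_t V = (R_xlen_t)dims[0] * dims[1] * dims[2];
  const int *gmp = INTEGER(gm), *wmp = INTEGER(wm), *dimp = INTEGER(dims);
  const int *maskp = INTEGER(mask);

  // re-layout data voxel-major for cache locality
  std::vector<double> D((size_t)V * G);
  for (R_xlen_t v = 0; v < V; ++v)
    for (int g = 0; g < G; ++g) D[(size_t)v * G + g] = data[v + V * g];
  // fixed background prediction (e.g. free-water compartment), same layout
  std::vector<double> B((size_t)V * G, 0.0);
  if (baseline.size() == (R_xlen_t)V * G)
    for (R_xlen_t v = 0; v < V; ++v)
      for (int g = 0; g < G; ++g) B[(size_t)v * G + g] = baseline[v + V * g];

  std::vector<int> mask_idx;
  for (R_xlen_t v = 0; v < V; ++v)
    if (maskp[v]) mask_idx.push_back((int)v);

  // controls
  const int n_iter = as<int>(control["n_iter"]);
  NumericVector probs = control["probs"];
  const double move_scale = as<double>(control["move_scale"]);
  const double weight_scale = as<double>(control["weight_scale"]);
  double t_start = as<double>(control["t_start"]);  // NA => auto burn-in
  const double t_end_frac = as<double>(control["t_end_frac"]);
  const int trace_every = as<int>(control["trace_every"]);
  const int audit_every = as<int>(control["audit_every"]);
  const int burn_in = as<int>(control["burn_in"]);
  const bool planar = as<bool>(control["planar_moves"]);
  const double min_chord_cos = as<double>(control["min_chord_cos"]);
  const int ndim_move = planar ? 2 : 3;  // z frozen for planar acquisitions
  double cum[4];
  cum[0] = probs[0];
  for (int j = 1; j < 4; ++j) cum[j] = cum[j - 1] + probs[j];

  // build fibers + field
  int nf0 = ctrl_list.size();
  std::vector<Fiber> fib;
  fib.reserve(nf0 * 2);
  for (int f = 0; f < nf0; ++f) {
    Fiber fb;
    NumericMatrix ctrl = ctrl_list[f];
    fb.ctrl = ctrl_buffer(ctrl);
    fb.nc = ctrl.nrow();
    fb.w = weights[f];
    fiber_contrib(fb.ctrl, fb.nc, fp, maskp, fb.c);
    fib.push_back(std::move(fb));
  }
  std::vector<double> rho = B;
  for (auto &fb : fib) apply_contrib(rho, D.data(), G, fb.c, fb.w);
  double E = full_energy(rho, D.data(), mask_idx, G);
  const double E_init = E;

  std::vector<std::pair<std::vector<double>, double>> pool;  // (ctrl, w)

  // one proposal; applies the change, returns dE and a revert closure by
  // explicit bookkeeping (type/index/payload)
  int prop_counts[4] = {0, 0, 0, 0};
  int acc_counts[4] = {0, 0, 0, 0};
  long invalid = 0;

  std::vector<double> burn_dE;
  burn_dE.reserve(burn_in);

  auto rand_index = [](int n) {
    int i = (int)(R::unif_rand() * n);
    return i >= n ? n - 1 : i;
  };

  // proposal engine: if measure_only, always revert (used for burn-in)
  auto step = [&](double T, bool measure_only) {
    double u = R::unif_rand();
    int type = 3;
    for (int j = 0; j < 4; ++j)
      if (u < cum[j]) { type = j; break; }
    prop_counts[type]++;
    int nf = (int)fib.size();
    if ((type == 0 || type == 1) && nf == 0) { invalid++; return; }
    if (type == 3 && nf <= 1) { invalid++; return; }

    if (type == 0) {  // change weight
      int i = rand_index(nf);
      double wn;
      if (!trunc_norm01(fib[i].w, weight_scale, wn)) { invalid++; return; }
      double dE = apply_contrib(rho, D.data(), G, fib[i].c, wn - fib[i].w);
      bool ok = !measure_only &&
                (dE <= 0.0 || std::exp(-dE / T) > R::unif_rand());
      if (measure_only) burn_dE.push_back(dE);
      if (ok) {
        fib[i].w = wn;
        E += dE;
        acc_counts[0]++;
      } else {
        apply_contrib(rho, D.data(), G, fib[i].c, fib[i].w - wn);
      }
    } else if (type == 1) {  // move
      int i = rand_index(nf);
      std::vector<double> Cn = fib[i].ctrl;
      if (R::unif_rand() < 0.5) {
        int cp = rand_index(fib[i].nc);
        for (int d = 0; d < ndim_move; ++d)
          Cn[3 * cp + d] += move_scale * R::norm_rand();
      } else {
        double t[3] = {0, 0, 0};
        for (int d = 0; d < ndim_move; ++d) t[d] = move_scale * R::norm_rand();
        for (int j = 0; j < fib[i].nc; ++j)
          for (int d = 0; d < 3; ++d) Cn[3 * j + d] += t[d];
      }
      if (!valid_ctrl(Cn, fib[i].nc, gmp, wmp, dimp, ia.data(),
                      min_chord_cos)) {
        invalid++;
        return;
      }
      Contrib cn;
      fiber_contrib(Cn, fib[i].nc, fp, maskp, cn);
      double w = fib[i].w;
      double dE = apply_contrib(rho, D.data(), G, fib[i].c, -w);
      dE += apply_contrib(rho, D.data(), G, cn, w);
      bool ok = !measure_only &&
                (dE <= 0.0 || std::exp(-dE / T) > R::unif_rand());
      if (measure_only) burn_dE.push_back(dE);
      if (ok) {
        fib[i].ctrl = std::move(Cn);
        fib[i].c = std::move(cn);
        E += dE;
        acc_counts[1]++;
      } else {
        apply_contrib(rho, D.data(), G, cn, -w);
        apply_contrib(rho, D.data(), G, fib[i].c, w);
      }
    } else if (type == 2) {  // add
      Fiber fb;
      int pool_idx = -1;
      if (!pool.empty()) {
        pool_idx = rand_index((int)pool.size());
        fb.ctrl = pool[pool_idx].first;
        fb.nc = (int)fb.ctrl.size() / 3;
        fb.w = pool[pool_idx].second;
      } else {
        if (nf == 0) { invalid++; return; }
        int i = rand_index(nf);
        fb.ctrl = fib[i].ctrl;
        fb.nc = fib[i].nc;
        for (int j = 0; j < fb.nc; ++j)
          for (int d = 0; d < ndim_move; ++d)
            fb.ctrl[3 * j + d] += move_scale * R::norm_rand();
        double wn;
        if (!trunc_norm01(fib[i].w, weight_scale, wn)) { invalid++; return; }
        fb.w = wn;
      }
      if (!valid_ctrl(fb.ctrl, fb.nc, gmp, wmp, dimp, ia.data(),
                      min_chord_cos)) {
        invalid++;
        return;
      }
      fiber_contrib(fb.ctrl, fb.nc, fp, maskp, fb.c);
      double dE = apply_contrib(rho, D.data(), G, fb.c, fb.w);
      bool ok = !measure_only &&
                (dE <= 0.0 || std::exp(-dE / T) > R::unif_rand());
      if (measure_only) burn_dE.push_back(dE);
      if (ok) {
        if (pool_idx >= 0) {
          pool[pool_idx] = std::move(pool.back());
          pool.pop_back();
        }
        fib.push_back(std::move(fb));
        E += dE;
        acc_counts[2]++;
      } else {
        apply_contrib(rho, D.data(), G, fb.c, -fb.w);
      }
    } else {  // remove
      int i = rand_index(nf);
      double w = fib[i].w;
      double dE = apply_contrib(rho, D.data(), G, fib[i].c, -w);
      bool ok = !measure_only &&
                (dE <= 0.0 || std::exp(-dE / T) > R::unif_rand());
      if (measure_only) burn_dE.push_back(dE);
      if (ok) {
        pool.emplace_back(fib[i].ctrl, w);
        fib[i] = std::move(fib.back());
        fib.pop_back();
        E += dE;
        acc_counts[3]++;
      } else {
        apply_contrib(rho, D.data(), G, fib[i].c, w);
      }
    }
  };

  // burn-in to calibrate the starting temperature
  if (!R_finite(t_start)) {
    for (int k = 0; k < burn_in; ++k) step(1.0, true);
    if (burn_dE.size() >= 2) {
      double mu = 0, s2 = 0;
      for (double x : burn_dE) mu += x;
      mu /= burn_dE.size();
      for (double x : burn_dE) s2 += (x - mu) * (x - mu);
      t_start = std::sqrt(s2 / (burn_dE.size() - 1));
    }
    if (!R_finite(t_start) || t_start <= 0) t_start = 1e-6;
    // reset counters: burn-in proposals are not part of the chain
    for (int j = 0; j < 4; ++j) prop_counts[j] = 0;
    invalid = 0;
  }
  double t_end = t_start * t_end_frac;

  // best-visited snapshot
  double bestE = E;
  std::vector<std::vector<double>> best_ctrl;
  std::vector<int> best_nc;
  std::vector<double> best_w;
  auto snapshot = [&]() {
    best_ctrl.clear(); best_nc.clear(); best_w.clear();
    for (auto &fb : fib) {
      best_ctrl.push_back(fb.ctrl);
      best_nc.push_back(fb.nc);
      best_w.push_back(fb.w);
    }
  };
  snapshot();

  std::vector<double> tr_it, tr_E, tr_T;
  tr_it.push_back(0); tr_E.push_back(E); tr_T.push_back(t_start);

  int n_audit = 0;
  double audit_max_rel = 0.0;
  double log_ratio = std::log(t_end / t_start);
  for (int k = 0; k < n_iter; ++k) {
    double T = t_start * std::exp(log_ratio * ((double)k / std::max(1, n_iter - 1)));
    step(T, false);
    if (E < bestE) { bestE = E; snapshot(); }
    if (audit_every > 0 && (k + 1) % audit_every == 0) {
      rho = B;
      for (auto &fb : fib) apply_contrib(rho, D.data(), G, fb.c, fb.w);
      double Ex = full_energy(rho, D.data(), mask_idx, G);
      double rel = std::fabs(Ex - E) / std::max(1e-12, std::fabs(Ex));
      if (rel > audit_max_rel) audit_max_rel = rel;
      E = Ex;
      n_audit++;
    }
    if (trace_every > 0 && (k + 1) % trace_every == 0) {
      tr_it.push_back(k + 1); tr_E.push_back(E); tr_T.push_back(T);
    }
    if ((k & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  // exact final energy
  rho = B;
  for (auto &fb : fib) apply_contrib(rho, D.data(), G, fb.c, fb.w);
  E = full_energy(rho, D.data(), mask_idx, G);

  List out_ctrl(fib.size()), out_best((int)best_ctrl.size());
  NumericVector out_w(fib.size()), out_bw((int)best_w.size());
  for (size_t f = 0; f < fib.size(); ++f) {
    NumericMatrix m(fib[f].nc, 3);
    for (int i = 0; i < fib[f].nc; ++i)
      for (int d = 0; d < 3; ++d) m(i, d) = fib[f].ctrl[3 * i + d];
    out_ctrl[f] = m;
    out_w[f] = fib[f].w;
  }
  for (size_t f = 0; f < best_ctrl.size(); ++f) {
    NumericMatrix m(best_nc[f], 3);
    for (int i = 0; i < best_nc[f]; ++i)
      for (int d = 0; d < 3; ++d) m(i, d) = best_ctrl[f][3 * i + d];
    out_best[f] = m;
    out_bw[f] = best_w[f];
  }
  NumericMatrix trace(tr_it.size(), 3);
  for (size_t i = 0; i < tr_it.size(); ++i) {
    trace(i, 0) = tr_it[i]; trace(i, 1) = tr_E[i]; trace(i, 2) = tr_T[i];
  }
  colnames(trace) = CharacterVector::create("iteration", "energy", "temperature");
  return List::create(
      _["control_points"] = out_ctrl, _["weights"] = out_w,
      _["best_control_points"] = out_best, _["best_weights"] = out_bw,
      _["energy"] = E, _["best_energy"] = bestE,
      _["initial_energy"] = E_init, _["trace"] = trace,
      _["proposal_counts"] = IntegerVector(prop_counts, prop_counts + 4),
      _["accept_counts"] = IntegerVector(acc_counts, acc_counts + 4),
      _["invalid_proposals"] = (double)invalid,
      _["n_pool"] = (int)pool.size(),
      _["t_start"] = t_start, _["t_end"] = t_end,
      _["n_audits"] = n_audit, _["audit_max_rel"] = audit_max_rel);
}
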