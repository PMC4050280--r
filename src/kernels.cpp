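#include <Rcpp.h>
#include <queue>
#include <cmath>
#ifndef USE_FC_LEN_T
#define USE_FC_LEN_T
#endif
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Voxel convention shared with the R side: grids are numeric arrays with
// dim = (nx, ny, nz), x fastest; voxel indices are 0-based here, and a
// coordinate u == i (in voxel units) refers to the centre of voxel i.

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z,
                               double fill, bool *inside) {
  // sample at voxel-unit coordinate (x,y,z); outside -> fill
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) {
    if (inside) *inside = false;
    return fill;
  }
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  if (x0 >= 0 && y0 >= 0 && z0 >= 0 &&
      x0 + 1 < nx && y0 + 1 < ny && z0 + 1 < nz) {
    // interior fast path: no per-corner bounds checks
    const double *p000 = v + (size_t)z0 * nx * ny + (size_t)y0 * nx + x0;
    const double *p001 = p000 + (size_t)nx * ny;
    double c00 = p000[0] * (1 - fx) + p000[1] * fx;
    double c10 = p000[nx] * (1 - fx) + p000[nx + 1] * fx;
    double c01 = p001[0] * (1 - fx) + p001[1] * fx;
    double c11 = p001[nx] * (1 - fx) + p001[nx + 1] * fx;
    if (inside) *inside = true;
    return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
           (c01 * (1 - fy) + c11 * fy) * fz;
  }
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) { continue; }
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        acc += wx * wy * wz * v[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
      }
    }
  }
  // near the border missing corners are treated as fill
  if (inside) *inside = true;
  double wtot = 1.0; // weights always sum to 1; missing corners contribute fill
  (void)wtot;
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims_in,
                           IntegerVector dims_out, NumericMatrix M,
                           NumericVector t, double fill) {
  // out(i,j,k) = vol( M %*% (i,j,k) + t ), trilinear, voxel units
  int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  int ox = dims_out[0], oy = dims_out[1], oz = dims_out[2];
  NumericVector out((size_t)ox * oy * oz);
  const double *v = vol.begin();
  double *o = out.begin();
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i) {
        double x = M(0,0)*i + M(0,1)*j + M(0,2)*k + t[0];
        double y = M(1,0)*i + M(1,1)*j + M(1,2)*k + t[1];
        double z = M(2,0)*i + M(2,1)*j + M(2,2)*k + t[2];
        o[(size_t)k * ox * oy + (size_t)j * ox + i] =
          trilinear(v, nx, ny, nz, x, y, z, fill, nullptr);
      }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// [[Rcpp::export]]
void cpp_add_rotated(NumericVector target, IntegerVector dims_t,
                     NumericVector vol, IntegerVector dims_v,
                     NumericMatrix M, NumericVector t, double weight) {
  // target(i,j,k) += weight * vol( M %*% (i,j,k) + t ) over the bounding box
  // of vol's footprint in target space. Modifies `target` in place; callers
  // must pass a freshly allocated (unshared) array.
  int tx = dims_t[0], ty = dims_t[1], tz = dims_t[2];
  int nx = dims_v[0], ny = dims_v[1], nz = dims_v[2];
  // invert x_v = M x_t + t  ->  x_t = Minv (x_v - t)
  double a = M(0,0), b = M(0,1), c = M(0,2),
         d = M(1,0), e = M(1,1), f = M(1,2),
         g = M(2,0), h = M(2,1), ii = M(2,2);
  double det = a*(e*ii - f*h) - b*(d*ii - f*g) + c*(d*h - e*g);
  if (std::fabs(det) < 1e-12) stop("singular resampling matrix");
  double inv[9] = {
    (e*ii - f*h)/det, (c*h - b*ii)/det, (b*f - c*e)/det,
    (f*g - d*ii)/det, (a*ii - c*g)/det, (c*d - a*f)/det,
    (d*h - e*g)/det, (b*g - a*h)/det, (a*e - b*d)/det };
  double lo[3] = {1e30,1e30,1e30}, hi[3] = {-1e30,-1e30,-1e30};
  for (int cz = 0; cz <= 1; ++cz)
    for (int cy = 0; cy <= 1; ++cy)
      for (int cx = 0; cx <= 1; ++cx) {
        double vx = (cx ? nx - 0.5 : -0.5) - t[0];
        double vy = (cy ? ny - 0.5 : -0.5) - t[1];
        double vz = (cz ? nz - 0.5 : -0.5) - t[2];
        double px = inv[0]*vx + inv[1]*vy + inv[2]*vz;
        double py = inv[3]*vx + inv[4]*vy + inv[5]*vz;
        double pz = inv[6]*vx + inv[7]*vy + inv[8]*vz;
        lo[0] = std::min(lo[0], px); hi[0] = std::max(hi[0], px);
        lo[1] = std::min(lo[1], py); hi[1] = std::max(hi[1], py);
        lo[2] = std::min(lo[2], pz); hi[2] = std::max(hi[2], pz);
      }
  int i0 = std::max(0, (int)std::floor(lo[0]) - 1);
  int j0 = std::max(0, (int)std::floor(lo[1]) - 1);
  int k0 = std::max(0, (int)std::floor(lo[2]) - 1);
  int i1 = std::min(tx - 1, (int)std::ceil(hi[0]) + 1);
  int j1 = std::min(ty - 1, (int)std::ceil(hi[1]) + 1);
  int k1 = std::min(tz - 1, (int)std::ceil(hi[2]) + 1);
  const double *v = vol.begin();
  double *tg = target.begin();
  for (int k = k0; k <= k1; ++k)
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double x = a*i + b*j + c*k + t[0];
        double y = d*i + e*j + f*k + t[1];
        double z = g*i + h*j + ii*k + t[2];
        bool inside;
        double s = trilinear(v, nx, ny, nz, x, y, z, 0.0, &inside);
        if (inside)
          tg[(size_t)k * tx * ty + (size_t)j * tx + i] += weight * s;
      }
}

// [[Rcpp::export]]
double cpp_masked_cc(NumericVector a, NumericVector b, NumericVector w) {
  // weighted about-the-mean correlation; returns NA on zero variance
  size_t n = a.size();
  double W = 0, Sa = 0, Sb = 0, Saa = 0, Sbb = 0, Sab = 0;
  for (size_t i = 0; i < n; ++i) {
    double wi = w[i];
    if (wi == 0) continue;
    double ai = a[i], bi = b[i];
    W += wi; Sa += wi * ai; Sb += wi * bi;
    Saa += wi * ai * ai; Sbb += wi * bi * bi; Sab += wi * ai * bi;
  }
  if (W <= 0) return NA_REAL;
  double va = Saa - Sa * Sa / W, vb = Sbb - Sb * Sb / W;
  if (va <= 1e-300 || vb <= 1e-300) return NA_REAL;
  return (Sab - Sa * Sb / W) / std::sqrt(va * vb);
}

// [[Rcpp::export]]
List cpp_search_poses(NumericVector sub, NumericMatrix rgm,
                      IntegerVector dims, IntegerMatrix mask_ijk,
                      NumericVector mask_w, IntegerMatrix shifts) {
  // For every (rotation r, integer shift s) compute the weighted
  // about-the-mean correlation between ref_r (pre-gathered at the mask
  // voxels: column r of rgm) and the sub-volume sampled at mask voxel
  // + s.  Caller guarantees mask voxel + shift stays in bounds.
  // Returns the argmax.
  int nx = dims[0], ny = dims[1];
  int nm = mask_ijk.nrow(), ns = shifts.nrow();
  int nrot = rgm.ncol();
  if (rgm.nrow() != nm) stop("gathered reference rows != mask size");
  std::vector<size_t> midx(nm);
  std::vector<double> w(nm);
  double W = 0;
  for (int m = 0; m < nm; ++m) {
    midx[m] = (size_t)mask_ijk(m,2) * nx * ny + (size_t)mask_ijk(m,1) * nx +
              mask_ijk(m,0);
    w[m] = mask_w[m];
    W += w[m];
  }
  const double *rg = rgm.begin();
  // per-rotation reference moments
  std::vector<double> Sr(nrot, 0), Vr(nrot, 0);
  for (int r = 0; r < nrot; ++r) {
    const double *gp = rg + (size_t)r * nm;
    double s1 = 0, s2 = 0;
    for (int m = 0; m < nm; ++m) {
      s1 += w[m] * gp[m]; s2 += w[m] * gp[m] * gp[m];
    }
    Sr[r] = s1; Vr[r] = s2 - s1 * s1 / W;
  }
  // per-shift sub-volume moments and cached samples
  std::vector<double> Sb(ns, 0), Vb(ns, 0);
  std::vector<double> bs((size_t)ns * nm);
  const double *sv = sub.begin();
  for (int s = 0; s < ns; ++s) {
    long off = (long)shifts(s,2) * nx * ny + (long)shifts(s,1) * nx + shifts(s,0);
    double s1 = 0, s2 = 0;
    double *bp = bs.data() + (size_t)s * nm;
    for (int m = 0; m < nm; ++m) {
      double x = sv[(size_t)((long)midx[m] + off)];
      bp[m] = w[m] * x;                       // pre-weighted
      s1 += w[m] * x; s2 += w[m] * x * x;
    }
    Sb[s] = s1; Vb[s] = s2 - s1 * s1 / W;
  }
  // all cross terms in one blocked matrix product: C = rg^T %*% bs
  std::vector<double> C((size_t)nrot * ns);
  {
    const double one = 1.0, zero = 0.0;
    const int m_ = nm, n_ = ns, k_ = nrot;
    // C (nrot x ns) = t(rg (nm x nrot)) %*% bs (nm x ns)
    F77_CALL(dgemm)("T", "N", &k_, &n_, &m_, &one, rg, &m_,
                    bs.data(), &m_, &zero, C.data(), &k_ FCONE FCONE);
  }
  double best = -2.0; int bi = -1, bsh = -1;
  for (int s = 0; s < ns; ++s) {
    if (Vb[s] <= 1e-300) continue;
    for (int r = 0; r < nrot; ++r) {
      if (Vr[r] <= 1e-300) continue;
      double cross = C[(size_t)s * nrot + r];
      double cc = (cross - Sr[r] * Sb[s] / W) / std::sqrt(Vr[r] * Vb[s]);
      if (cc > best) { best = cc; bi = r; bsh = s; }
    }
  }
  return List::create(_["rot"] = bi + 1, _["shift"] = bsh + 1, _["cc"] = best);
}

// [[Rcpp::export]]
IntegerMatrix cpp_local_minima(NumericVector vol, IntegerVector dims,
                               double thresh) {
  // strict minima over the 26-neighbourhood with value < thresh;
  // the one-voxel border is excluded (incomplete neighbourhood)
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = vol.begin();
  std::vector<int> out;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        double c = v[(size_t)k * nx * ny + (size_t)j * nx + i];
        if (!(c < thresh)) continue;
        bool ok = true;
        for (int dk = -1; dk <= 1 && ok; ++dk)
          for (int dj = -1; dj <= 1 && ok; ++dj)
            for (int di = -1; di <= 1 && ok; ++di) {
              if (!di && !dj && !dk) continue;
              double nb = v[(size_t)(k+dk) * nx * ny + (size_t)(j+dj) * nx + (i+di)];
              if (!(c < nb)) ok = false;
            }
        if (ok) { out.push_back(i); out.push_back(j); out.push_back(k); }
      }
  int n = out.size() / 3;
  IntegerMatrix res(n, 3);
  for (int r = 0; r < n; ++r) {
    res(r,0) = out[3*r]; res(r,1) = out[3*r+1]; res(r,2) = out[3*r+2];
  }
  return res;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  // 26-connected components; labels 1..K in discovery order, 0 = background
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front(); q.pop();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ni = i + di, nj = j + dj, nk = k + dk;
            if (ni < 0 || nj < 0 || nk < 0 || ni >= nx || nj >= ny || nk >= nz)
              continue;
            size_t ns_ = (size_t)nk * nx * ny + (size_t)nj * nx + ni;
            if (mask[ns_] && !lab[ns_]) { lab[ns_] = next; q.push(ns_); }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// [[Rcpp::export]]
NumericVector cpp_splat_gaussians(IntegerVector dims, NumericMatrix pos,
                                  NumericVector amp, double sigma) {
  // sum of amp_i * exp(-r^2 / (2 sigma^2)) around pos_i (voxel units),
  // truncated at 4 sigma
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((size_t)nx * ny * nz);
  double *o = out.begin();
  int rad = (int)std::ceil(4.0 * sigma);
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int p = 0; p < pos.nrow(); ++p) {
    double px = pos(p,0), py = pos(p,1), pz = pos(p,2), A = amp[p];
    int i0 = std::max(0, (int)std::floor(px) - rad);
    int i1 = std::min(nx - 1, (int)std::ceil(px) + rad);
    int j0 = std::max(0, (int)std::floor(py) - rad);
    int j1 = std::min(ny - 1, (int)std::ceil(py) + rad);
    int k0 = std::max(0, (int)std::floor(pz) - rad);
    int k1 = std::min(nz - 1, (int)std::ceil(pz) + rad);
    for (int k = k0; k <= k1; ++k) {
      double dz = k - pz;
      for (int j = j0; j <= j1; ++j) {
        double dy = j - py;
        for (int i = i0; i <= i1; ++i) {
          double dx = i - px;
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 > 16.0 * sigma * sigma) continue;
          o[(size_t)k * nx * ny + (size_t)j * nx + i] += A * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
void cpp_add_shell(NumericVector target, IntegerVector dims,
                   NumericVector centre, double radius, double half_t,
                   double value, int ss) {
  // adds a spherical shell (|r - radius| <= half_t) of the given value with
  // ss^3 supersampled partial-volume edges; voxel units; in-place
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double cx = centre[0], cy = centre[1], cz = centre[2];
  double *tg = target.begin();
  double rmax = radius + half_t + 1.0, rmin = std::max(0.0, radius - half_t - 1.0);
  int i0 = std::max(0, (int)std::floor(cx - rmax));
  int i1 = std::min(nx - 1, (int)std::ceil(cx + rmax));
  int j0 = std::max(0, (int)std::floor(cy - rmax));
  int j1 = std::min(ny - 1, (int)std::ceil(cy + rmax));
  int k0 = std::max(0, (int)std::floor(cz - rmax));
  int k1 = std::min(nz - 1, (int)std::ceil(cz + rmax));
  double sub = 1.0 / ss, off = -0.5 + 0.5 * sub;
  int nsub = ss * ss * ss;
  for (int k = k0; k <= k1; ++k)
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double dx = i - cx, dy = j - cy, dz = k - cz;
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r > rmax || r < rmin - 1.0) continue;
        int cnt = 0;
        for (int a = 0; a < ss; ++a)
          for (int b = 0; b < ss; ++b)
            for (int c = 0; c < ss; ++c) {
              double sx = dx + off + a * sub;
              double sy = dy + off + b * sub;
              double sz = dz + off + c * sub;
              double rr = std::sqrt(sx*sx + sy*sy + sz*sz);
              if (std::fabs(rr - radius) <= half_t) ++cnt;
            }
        if (cnt)
          tg[(size_t)k * nx * ny + (size_t)j * nx + i] +=
            value * (double)cnt / nsub;
      }
}

// [[Rcpp::export]]
NumericVector cpp_wedge_cc(ComplexVector Fsub, ComplexVector Frefs, int nrot,
                           IntegerVector kept) {
  // normalized correlation between Fourier transforms over the retained
  // (particle-sampled) coefficient indices (0-based); one value per
  // rotation
  size_t n = Fsub.size();
  int nk = kept.size();
  std::vector<double> sr(nk), si(nk);
  double nsub = 0;
  const Rcomplex *fs = reinterpret_cast<const Rcomplex*>(Fsub.begin());
  for (int k = 0; k < nk; ++k) {
    Rcomplex v = fs[kept[k]];
    sr[k] = v.r; si[k] = v.i;
    nsub += v.r * v.r + v.i * v.i;
  }
  NumericVector out(nrot);
  for (int r = 0; r < nrot; ++r) {
    const Rcomplex *fr = reinterpret_cast<const Rcomplex*>(Frefs.begin()) +
      (size_t)r * n;
    double cross = 0, nref = 0;
    for (int k = 0; k < nk; ++k) {
      Rcomplex t = fr[kept[k]];
      cross += sr[k] * t.r + si[k] * t.i;   // Re(s * conj(t))
      nref += t.r * t.r + t.i * t.i;
    }
    out[r] = (nsub > 1e-300 && nref > 1e-300) ?
      cross / std::sqrt(nsub * nref) : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cc_shift_grid(NumericVector sub, NumericVector ref,
                                IntegerVector dims, IntegerMatrix mask_ijk,
                                NumericVector mask_w, IntegerMatrix shifts) {
  // weighted about-the-mean correlation of ref (at mask voxels) against
  // the sub-volume sampled at mask voxel + shift, for every shift
  int nx = dims[0], ny = dims[1];
  int nm = mask_ijk.nrow(), ns = shifts.nrow();
  std::vector<size_t> midx(nm);
  std::vector<double> w(nm);
  double W = 0, Sr = 0, Srr = 0;
  for (int m = 0; m < nm; ++m) {
    midx[m] = (size_t)mask_ijk(m,2) * nx * ny + (size_t)mask_ijk(m,1) * nx +
              mask_ijk(m,0);
    w[m] = mask_w[m];
    W += w[m];
    double x = ref[midx[m]];
    Sr += w[m] * x; Srr += w[m] * x * x;
  }
  double Vr = Srr - Sr * Sr / W;
  NumericVector out(ns);
  const double *sv = sub.begin();
  for (int s = 0; s < ns; ++s) {
    long off = (long)shifts(s,2) * nx * ny + (long)shifts(s,1) * nx + shifts(s,0);
    double Sb = 0, Sbb = 0, cross = 0;
    for (int m = 0; m < nm; ++m) {
      double x = sv[(size_t)((long)midx[m] + off)];
      Sb += w[m] * x; Sbb += w[m] * x * x;
      cross += w[m] * x * ref[midx[m]];
    }
    double Vb = Sbb - Sb * Sb / W;
    out[s] = (Vr > 1e-300 && Vb > 1e-300) ?
      (cross - Sr * Sb / W) / std::sqrt(Vr * Vb) : NA_REAL;
  }
  return out;
}
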