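#include "geom.h"
using namespace Rcpp;

// Axis-aligned voxel grid: dims, voxel size, world position of the grid
// center. Voxel (0,0,0) sits at the most-negative corner.
struct Grid {
  int nx, ny, nz;
  double vs[3];
  double corner[3];
  Grid(IntegerVector dims, NumericVector voxelSize, NumericVector center) {
    nx = dims[0]; ny = dims[1]; nz = dims[2];
    for (int a = 0; a < 3; ++a) {
      vs[a] = voxelSize[a];
      corner[a] = center[a] - 0.5 * dims[a] * voxelSize[a];
    }
  }
  long nvox() const { return (long)nx * ny * nz; }
};

// Exact Siddon/Amanatides traversal of the segment p1 -> p2 through the
// grid; emit(ix, iy, iz, intersectionLength) per voxel crossed.
template <class F>
static void traverseSegment(const double* p1, const double* p2,
                            const Grid& g, F&& emit) {
  double d[3], t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) d[a] = p2[a] - p1[a];
  for (int a = 0; a < 3; ++a) {
    double lo = g.corner[a];
    double hi = g.corner[a] + (a == 0 ? g.nx : a == 1 ? g.ny : g.nz) * g.vs[a];
    if (std::fabs(d[a]) < 1e-14) {
      if (p1[a] < lo || p1[a] > hi) return;
    } else {
      double u0 = (lo - p1[a]) / d[a], u1 = (hi - p1[a]) / d[a];
      if (u0 > u1) std::swap(u0, u1);
      if (u0 > t0) t0 = u0;
      if (u1 < t1) t1 = u1;
      if (t0 >= t1) return;
    }
  }
  double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  if (L <= 0) return;
  // entry voxel (nudged inside to avoid landing exactly on a boundary)
  double tEntry = t0 + 1e-12;
  int idx[3], dims[3] = { g.nx, g.ny, g.nz };
  double tMax[3], tDelta[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    double w = p1[a] + d[a] * tEntry - g.corner[a];
    int i = (int)std::floor(w / g.vs[a]);
    if (i < 0) i = 0;
    if (i >= dims[a]) i = dims[a] - 1;
    idx[a] = i;
    if (d[a] > 1e-14) {
      step[a] = 1;
      tMax[a] = (g.corner[a] + (i + 1) * g.vs[a] - p1[a]) / d[a];
      tDelta[a] = g.vs[a] / d[a];
    } else if (d[a] < -1e-14) {
      step[a] = -1;
      tMax[a] = (g.corner[a] + i * g.vs[a] - p1[a]) / d[a];
      tDelta[a] = -g.vs[a] / d[a];
    } else {
      step[a] = 0;
      tMax[a] = std::numeric_limits<double>::infinity();
      tDelta[a] = std::numeric_limits<double>::infinity();
    }
  }
  double t = t0;
  for (int guard = 0; guard < g.nx + g.ny + g.nz + 6; ++guard) {
    int amin = 0;
    if (tMax[1] < tMax[amin]) amin = 1;
    if (tMax[2] < tMax[amin]) amin = 2;
    double tn = std::min(tMax[amin], t1);
    if (tn > t) emit(idx[0], idx[1], idx[2], (tn - t) * L);
    if (tn >= t1) return;
    t = tn;
    idx[amin] += step[amin];
    if (idx[amin] < 0 || idx[amin] >= dims[amin]) return;
    tMax[amin] += tDelta[amin];
  }
}

// LOR endpoint on a crystal: eDepth millimeters behind the front face
// (0 = the face itself; the mean interaction depth removes the
// first-order radial parallax bias of face chords), offset (ft, fz) in
// [-0.5, 0.5] across the face in the tangential/axial directions.
static void facePoint(const Geom& G, int crystal, double ft, double fz,
                      double* e) {
  int it = crystal % G.Ct, ring = crystal / G.Ct;
  double phi = 2.0 * M_PI * it / G.Ct;
  double c = std::cos(phi), s = std::sin(phi);
  double off = ft * G.wt;
  double r = G.R + G.eDepth;
  e[0] = r * c - off * s;
  e[1] = r * s + off * c;
  e[2] = G.z0 + ring * G.pitch_z + fz * G.wz;
}

// Decode all unordered pairs once (a < b, lexicographic).
static void decodePairs(long C, std::vector<int>& A, std::vector<int>& B) {
  A.resize(C * (C - 1) / 2);
  B.resize(A.size());
  long k = 0;
  for (long a = 0; a < C; ++a)
    for (long b = a + 1; b < C; ++b) { A[k] = (int)a; B[k] = (int)b; ++k; }
}

// One LOR's rays; emit accumulated per-voxel coefficients via callback.
// nrays = 1 traces the front-face-center chord; nrays = m traces every
// pairing of an m x m sample grid on face A with one on face B (m^4
// chords), i.e. the full tube of response between the two faces.
template <class F>
static void lorRays(const Geom& G, int a, int b, int nrays, const Grid& g,
                    F&& emit) {
  if (nrays == 1) {
    double e1[3], e2[3];
    facePoint(G, a, 0.0, 0.0, e1);
    facePoint(G, b, 0.0, 0.0, e2);
    traverseSegment(e1, e2, g, [&](int ix, int iy, int iz, double len) {
      emit(ix, iy, iz, len);
    });
    return;
  }
  double inv = 1.0;
  for (int q = 0; q < 4; ++q) inv /= nrays;
  for (int i1 = 0; i1 < nrays; ++i1)
    for (int j1 = 0; j1 < nrays; ++j1) {
      double e1[3];
      facePoint(G, a, (i1 + 0.5) / nrays - 0.5, (j1 + 0.5) / nrays - 0.5,
                e1);
      for (int i2 = 0; i2 < nrays; ++i2)
        for (int j2 = 0; j2 < nrays; ++j2) {
          double e2[3];
          facePoint(G, b, (i2 + 0.5) / nrays - 0.5,
                    (j2 + 0.5) / nrays - 0.5, e2);
          traverseSegment(e1, e2, g,
                          [&](int ix, int iy, int iz, double len) {
                            emit(ix, iy, iz, len * inv);
                          });
        }
    }
}

// [[Rcpp::export]]
NumericVector cppForwardProject(NumericVector x, IntegerVector dims,
                                NumericVector voxelSize, NumericVector center,
                                List geometry, IntegerVector subset,
                                int nrays) {
  Geom G = geomFromList(geometry);
  Grid g(dims, voxelSize, center);
  long C = G.nCrystals();
  NumericVector y((R_xlen_t)G.nLORs());
  const double* xv = REAL(x);
  double* yv = REAL(y);
  std::vector<int> A, B;
  decodePairs(C, A, B);
  long nL = (long)A.size();
  bool useSubset = subset.size() > 0;
  long nIter = useSubset ? subset.size() : nL;
  for (long q = 0; q < nIter; ++q) {
    long L = useSubset ? subset[q] : q;
    double acc = 0.0;
    lorRays(G, A[L], B[L], nrays, g, [&](int ix, int iy, int iz, double w) {
      acc += w * xv[ix + (long)g.nx * (iy + (long)g.ny * iz)];
    });
    yv[L] = acc;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cppBackProject(NumericVector y, IntegerVector dims,
                             NumericVector voxelSize, NumericVector center,
                             List geometry, IntegerVector subset, int nrays) {
  Geom G = geomFromList(geometry);
  Grid g(dims, voxelSize, center);
  long C = G.nCrystals();
  NumericVector x((R_xlen_t)g.nvox());
  double* xv = REAL(x);
  const double* yv = REAL(y);
  std::vector<int> A, B;
  decodePairs(C, A, B);
  long nL = (long)A.size();
  bool useSubset = subset.size() > 0;
  long nIter = useSubset ? subset.size() : nL;
  for (long q = 0; q < nIter; ++q) {
    long L = useSubset ? subset[q] : q;
    double v = yv[L];
    if (v == 0.0) continue;
    lorRays(G, A[L], B[L], nrays, g, [&](int ix, int iy, int iz, double w) {
      xv[ix + (long)g.nx * (iy + (long)g.ny * iz)] += w * v;
    });
  }
  x.attr("dim") = dims;
  return x;
}

// Sparse system-matrix block restricted to an 11x11x11 (or smaller,
// border-clipped) patch: triplets (lor, local voxel, length).
// [[Rcpp::export]]
List cppPatchProjector(IntegerVector dims, NumericVector voxelSize,
                       NumericVector center, List geometry,
                       IntegerVector patchOrigin, int patchSize, int nrays) {
  Geom G = geomFromList(geometry);
  Grid vol(dims, voxelSize, center);
  long C = G.nCrystals();
  // patch grid in world coordinates (its own little volume)
  IntegerVector pd = IntegerVector::create(patchSize, patchSize, patchSize);
  NumericVector pc(3);
  for (int a = 0; a < 3; ++a)
    pc[a] = vol.corner[a] + (patchOrigin[a] + 0.5 * patchSize) * vol.vs[a];
  Grid pg(pd, voxelSize, pc);
  std::vector<int> A, B;
  decodePairs(C, A, B);
  long nL = (long)A.size();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  for (long L = 0; L < nL; ++L) {
    lorRays(G, A[L], B[L], nrays, pg, [&](int ix, int iy, int iz, double w) {
      int gx = patchOrigin[0] + ix, gy = patchOrigin[1] + iy,
          gz = patchOrigin[2] + iz;
      if (gx < 0 || gy < 0 || gz < 0 || gx >= vol.nx || gy >= vol.ny ||
          gz >= vol.nz)
        return;  // kernel mass outside the volume does not project
      ti.push_back((int)L + 1);
      tj.push_back(ix + patchSize * (iy + patchSize * iz) + 1);
      tx.push_back(w);
    });
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx),
                      _["nLors"] = (double)nL,
                      _["nVox"] = patchSize * patchSize * patchSize);
}

// ---- position-dependent image-space filtering -------------------------

// Stored-kernel lookup with optional octant mirroring. kernels is
// (nStored x k^3), kernel offsets run -h..h per axis, x-fastest layout.
struct KernelBank {
  const double* k;
  int nStored, klen, h, ksize;
  bool octant;
  int nx, ny, nz;
  KernelBank(const NumericMatrix& kernels, bool oct, int nx_, int ny_, int nz_)
      : k(REAL(kernels)), nStored(kernels.nrow()), klen(kernels.ncol()),
        octant(oct), nx(nx_), ny(ny_), nz(nz_) {
    ksize = (int)std::lround(std::cbrt((double)klen));
    h = (ksize - 1) / 2;
  }
  // stored row and per-axis flips for voxel (ix, iy, iz)
  void locate(int ix, int iy, int iz, long& row, bool* flip) const {
    if (nStored == 1) {  // spatially invariant kernel
      row = 0;
      flip[0] = flip[1] = flip[2] = false;
      return;
    }
    if (!octant) {
      row = ix + (long)nx * (iy + (long)ny * iz);
      flip[0] = flip[1] = flip[2] = false;
      return;
    }
    int hx = nx / 2, hy = ny / 2, hz = nz / 2;
    int jx = ix >= hx ? ix - hx : hx - 1 - ix;
    int jy = iy >= hy ? iy - hy : hy - 1 - iy;
    int jz = iz >= hz ? iz - hz : hz - 1 - iz;
    flip[0] = ix < hx; flip[1] = iy < hy; flip[2] = iz < hz;
    row = jx + (long)hx * (jy + (long)hy * jz);
  }
  // kernel value at effective offset (ox, oy, oz) given flips
  double at(long row, const bool* flip, int ox, int oy, int oz) const {
    int a = (flip[0] ? -ox : ox) + h;
    int b = (flip[1] ? -oy : oy) + h;
    int c = (flip[2] ? -oz : oz) + h;
    return k[row + (long)nStored * (a + ksize * (b + ksize * c))];
  }
};

// Per-voxel in-bounds kernel mass (for truncation renormalization at the
// volume border).
// [[Rcpp::export]]
NumericVector cppFilterNorms(NumericMatrix kernels, bool octant,
                             IntegerVector dims) {
  KernelBank bank(kernels, octant, dims[0], dims[1], dims[2]);
  long nv = (long)dims[0] * dims[1] * dims[2];
  NumericVector norms(nv);
  int h = bank.h;
  for (int iz = 0; iz < dims[2]; ++iz)
    for (int iy = 0; iy < dims[1]; ++iy)
      for (int ix = 0; ix < dims[0]; ++ix) {
        long row; bool flip[3];
        bank.locate(ix, iy, iz, row, flip);
        bool interior = ix >= h && ix < dims[0] - h && iy >= h &&
                        iy < dims[1] - h && iz >= h && iz < dims[2] - h;
        double s = 0.0;
        if (interior) {
          for (int oz = -h; oz <= h; ++oz)
            for (int oy = -h; oy <= h; ++oy)
              for (int ox = -h; ox <= h; ++ox)
                s += bank.at(row, flip, ox, oy, oz);
        } else {
          for (int oz = -h; oz <= h; ++oz) {
            if (iz + oz < 0 || iz + oz >= dims[2]) continue;
            for (int oy = -h; oy <= h; ++oy) {
              if (iy + oy < 0 || iy + oy >= dims[1]) continue;
              for (int ox = -h; ox <= h; ++ox) {
                if (ix + ox < 0 || ix + ox >= dims[0]) continue;
                s += bank.at(row, flip, ox, oy, oz);
              }
            }
          }
        }
        norms[ix + (long)dims[0] * (iy + (long)dims[1] * iz)] = s;
      }
  return norms;
}

// Scatter convention: each voxel's activity is distributed over its own
// kernel footprint; truncated kernels are renormalized so the total
// activity is preserved exactly.
// [[Rcpp::export]]
NumericVector cppApplyFilter(NumericVector x, NumericMatrix kernels,
                             bool octant, IntegerVector dims,
                             NumericVector norms) {
  KernelBank bank(kernels, octant, dims[0], dims[1], dims[2]);
  long nv = (long)dims[0] * dims[1] * dims[2];
  NumericVector out(nv);
  double* ov = REAL(out);
  const double* xv = REAL(x);
  const double* nv_ = REAL(norms);
  int h = bank.h;
  long v = 0;
  for (int iz = 0; iz < dims[2]; ++iz)
    for (int iy = 0; iy < dims[1]; ++iy)
      for (int ix = 0; ix < dims[0]; ++ix, ++v) {
        double val = xv[v];
        if (val == 0.0) continue;
        double nrm = nv_[v];
        if (nrm <= 0.0) { ov[v] += val; continue; }  // degenerate kernel
        double w = val / nrm;
        long row; bool flip[3];
        bank.locate(ix, iy, iz, row, flip);
        int zlo = std::max(-h, -iz), zhi = std::min(h, dims[2] - 1 - iz);
        int ylo = std::max(-h, -iy), yhi = std::min(h, dims[1] - 1 - iy);
        int xlo = std::max(-h, -ix), xhi = std::min(h, dims[0] - 1 - ix);
        for (int oz = zlo; oz <= zhi; ++oz)
          for (int oy = ylo; oy <= yhi; ++oy) {
            long base = (long)(ix + xlo) +
                        (long)dims[0] * ((iy + oy) + (long)dims[1] * (iz + oz));
            for (int ox = xlo; ox <= xhi; ++ox, ++base)
              ov[base] += w * bank.at(row, flip, ox, oy, oz);
          }
      }
  out.attr("dim") = dims;
  return out;
}

// Adjoint of the scatter filter: gather with the same (renormalized)
// kernels, out[v] = sum_off k_v(off) / norm[v] * y[v + off].
// [[Rcpp::export]]
NumericVector cppApplyFilterAdjoint(NumericVector y, NumericMatrix kernels,
                                    bool octant, IntegerVector dims,
                                    NumericVector norms) {
  KernelBank bank(kernels, octant, dims[0], dims[1], dims[2]);
  long nv = (long)dims[0] * dims[1] * dims[2];
  NumericVector out(nv);
  double* ov = REAL(out);
  const double* yv = REAL(y);
  const double* nv_ = REAL(norms);
  int h = bank.h;
  long v = 0;
  for (int iz = 0; iz < dims[2]; ++iz)
    for (int iy = 0; iy < dims[1]; ++iy)
      for (int ix = 0; ix < dims[0]; ++ix, ++v) {
        double nrm = nv_[v];
        if (nrm <= 0.0) { ov[v] = yv[v]; continue; }
        long row; bool flip[3];
        bank.locate(ix, iy, iz, row, flip);
        int zlo = std::max(-h, -iz), zhi = std::min(h, dims[2] - 1 - iz);
        int ylo = std::max(-h, -iy), yhi = std::min(h, dims[1] - 1 - iy);
        int xlo = std::max(-h, -ix), xhi = std::min(h, dims[0] - 1 - ix);
        double acc = 0.0;
        for (int oz = zlo; oz <= zhi; ++oz)
          for (int oy = ylo; oy <= yhi; ++oy) {
            long base = (long)(ix + xlo) +
                        (long)dims[0] * ((iy + oy) + (long)dims[1] * (iz + oz));
            for (int ox = xlo; ox <= xhi; ++ox, ++base)
              acc += yv[base] * bank.at(row, flip, ox, oy, oz);
          }
        ov[v] = acc / nrm;
      }
  out.attr("dim") = dims;
  return out;
}

// ---- LOR-space reference blur -----------------------------------------

// Spatially invariant endpoint-offset blur in the LOR domain. Each LOR's
// outgoing mass is distributed over offset pairs (independent per
// endpoint), renormalized over the reachable targets so rows sum to 1.
// Z holds the per-source normalization (from cppLorBlurNorm).
static long shiftedCrystal(const Geom& G, int crystal, int dt, int dz) {
  int it = crystal % G.Ct, ring = crystal / G.Ct;
  int nr2 = ring + dz;
  if (nr2 < 0 || nr2 >= G.nr) return -1;
  int it2 = ((it + dt) % G.Ct + G.Ct) % G.Ct;
  return (long)nr2 * G.Ct + it2;
}

// Sparse triplets of the full blur operator B, row-normalized so each
// source LOR's outgoing mass sums to 1: entry (src, tgt, w).
// [[Rcpp::export]]
List cppLorBlurTriplets(IntegerVector dt, IntegerVector dz,
                        NumericVector p, List geometry) {
  Geom G = geomFromList(geometry);
  long C = G.nCrystals();
  std::vector<int> A, B;
  decodePairs(C, A, B);
  long nL = (long)A.size();
  int K = dt.size();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  std::vector<long> tgts; std::vector<double> ws;
  for (long L = 0; L < nL; ++L) {
    tgts.clear(); ws.clear();
    double s = 0.0;
    for (int i = 0; i < K; ++i) {
      long c1 = shiftedCrystal(G, A[L], dt[i], dz[i]);
      if (c1 < 0) continue;
      for (int j = 0; j < K; ++j) {
        long c2 = shiftedCrystal(G, B[L], dt[j], dz[j]);
        if (c2 < 0 || c2 == c1) continue;
        tgts.push_back(lorIndexOf(c1, c2, C));
        ws.push_back(p[i] * p[j]);
        s += p[i] * p[j];
      }
    }
    if (s <= 0) continue;
    for (size_t q = 0; q < tgts.size(); ++q) {
      ti.push_back((int)L + 1);
      tj.push_back((int)tgts[q] + 1);
      tx.push_back(ws[q] / s);
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["n"] = (double)nL);
}

// [[Rcpp::export]]
NumericVector cppLorBlurNorm(IntegerVector dt, IntegerVector dz,
                             NumericVector p, List geometry) {
  Geom G = geomFromList(geometry);
  long C = G.nCrystals();
  std::vector<int> A, B;
  decodePairs(C, A, B);
  long nL = (long)A.size();
  int K = dt.size();
  NumericVector Z(nL);
  for (long L = 0; L < nL; ++L) {
    double s = 0.0;
    for (int i = 0; i < K; ++i) {
      long c1 = shiftedCrystal(G, A[L], dt[i], dz[i]);
      if (c1 < 0) continue;
      for (int j = 0; j < K; ++j) {
        long c2 = shiftedCrystal(G, B[L], dt[j], dz[j]);
        if (c2 < 0 || c2 == c1) continue;
        s += p[i] * p[j];
      }
    }
    Z[L] = s;
  }
  return Z;
}

// [[Rcpp::export]]
NumericVector cppApplyLorBlur(NumericVector y, IntegerVector dt,
                              IntegerVector dz, NumericVector p,
                              List geometry, NumericVector Z, bool adjoint) {
  Geom G = geomFromList(geometry);
  long C = G.nCrystals();
  std::vector<int> A, B;
  decodePairs(C, A, B);
  long nL = (long)A.size();
  int K = dt.size();
  NumericVector out(nL);
  double* ov = REAL(out);
  const double* yv = REAL(y);
  for (long L = 0; L < nL; ++L) {
    if (Z[L] <= 0.0) { if (!adjoint) ov[L] += 0; continue; }
    double src = adjoint ? 0.0 : yv[L];
    if (!adjoint && src == 0.0) continue;
    double acc = 0.0;
    double invZ = 1.0 / Z[L];
    for (int i = 0; i < K; ++i) {
      long c1 = shiftedCrystal(G, A[L], dt[i], dz[i]);
      if (c1 < 0) continue;
      for (int j = 0; j < K; ++j) {
        long c2 = shiftedCrystal(G, B[L], dt[j], dz[j]);
        if (c2 < 0 || c2 == c1) continue;
        long tgt = lorIndexOf(c1, c2, C);
        double w = p[i] * p[j] * invZ;
        if (adjoint) acc += w * yv[tgt];
        else ov[tgt] += w * src;
      }
    }
    if (adjoint) ov[L] = acc;
  }
  return out;
}

// In-place RAdam update for one parameter block: w, m, v are modified
// directly (the caller owns fresh copies). Returns nothing.
// [[Rcpp::export]]
void cppRadamUpdate(NumericVector w, NumericVector m, NumericVector v,
                    NumericVector g, double lr, double beta1, double beta2,
                    double eps, int t) {
  const int n = w.size();
  double* wp = REAL(w);
  double* mp = REAL(m);
  double* vp = REAL(v);
  const double* gp = REAL(g);
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  const double rhoInf = 2.0 / (1.0 - beta2) - 1.0;
  const double rhoT = rhoInf - 2.0 * t * std::pow(beta2, t) / bc2;
  const bool rect = rhoT > 5.0;
  double rT = 0.0;
  if (rect)
    rT = std::sqrt((rhoT - 4.0) * (rhoT - 2.0) * rhoInf /
                   ((rhoInf - 4.0) * (rhoInf - 2.0) * rhoT));
  for (int i = 0; i < n; ++i) {
    mp[i] = beta1 * mp[i] + (1.0 - beta1) * gp[i];
    vp[i] = beta2 * vp[i] + (1.0 - beta2) * gp[i] * gp[i];
    double mHat = mp[i] / bc1;
    if (rect) {
      double vHat = std::sqrt(vp[i] / bc2);
      wp[i] -= lr * rT * mHat / (vHat + eps);
    } else {
      wp[i] -= lr * mHat;
    }
  }
}
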