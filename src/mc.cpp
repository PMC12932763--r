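#include "geom.h"
using namespace Rcpp;

// ---- elementary samplers ----------------------------------------------

static void sampleSphere(RNG& rng, double* d) {
  double z = 2.0 * rng.u() - 1.0;
  double phi = 2.0 * M_PI * rng.u();
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  d[0] = r * std::cos(phi);
  d[1] = r * std::sin(phi);
  d[2] = z;
}

// Klein-Nishina scattering at photon energy E (keV). Composition-rejection
// sampling of eps = E'/E on [1/(1+2k), 1], k = E / 511.
static void sampleKleinNishina(RNG& rng, double E, double& cosTheta, double& Eout) {
  const double k = E / 511.0;
  const double eps0 = 1.0 / (1.0 + 2.0 * k);
  const double a1 = -std::log(eps0);
  const double a2 = 0.5 * (1.0 - eps0 * eps0);
  double eps, t;
  for (;;) {
    if (rng.u() * (a1 + a2) < a1)
      eps = std::exp(-a1 * rng.u());
    else
      eps = std::sqrt(eps0 * eps0 + (1.0 - eps0 * eps0) * rng.u());
    t = (1.0 - eps) / (k * eps);
    double sint2 = t * (2.0 - t);
    double greject = 1.0 - eps * sint2 / (1.0 + eps * eps);
    if (rng.u() <= greject) break;
  }
  cosTheta = 1.0 - t;
  Eout = eps * E;
}

// Thomson (Rayleigh limit): pdf(cos) proportional to 1 + cos^2.
static double sampleThomsonCos(RNG& rng) {
  for (;;) {
    double mu = 2.0 * rng.u() - 1.0;
    if (rng.u() < 0.5 * (1.0 + mu * mu)) return mu;
  }
}

static void rotateDirection(double* d, double cosTheta, double phi) {
  double sinTheta = std::sqrt(std::max(0.0, 1.0 - cosTheta * cosTheta));
  double a[3];
  if (std::fabs(d[2]) < 0.9) { a[0] = 0; a[1] = 0; a[2] = 1; }
  else { a[0] = 1; a[1] = 0; a[2] = 0; }
  double u[3] = { a[1] * d[2] - a[2] * d[1],
                  a[2] * d[0] - a[0] * d[2],
                  a[0] * d[1] - a[1] * d[0] };
  double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  for (int i = 0; i < 3; ++i) u[i] /= un;
  double v[3] = { d[1] * u[2] - d[2] * u[1],
                  d[2] * u[0] - d[0] * u[2],
                  d[0] * u[1] - d[1] * u[0] };
  double cp = std::cos(phi), sp = std::sin(phi);
  double nd[3];
  for (int i = 0; i < 3; ++i)
    nd[i] = cosTheta * d[i] + sinTheta * (cp * u[i] + sp * v[i]);
  double nn = std::sqrt(nd[0] * nd[0] + nd[1] * nd[1] + nd[2] * nd[2]);
  for (int i = 0; i < 3; ++i) d[i] = nd[i] / nn;
}

// ---- ring search ------------------------------------------------------

// Nearest crystal entered by the ray from p along d (unit). Returns crystal
// id or -1; on success tIn/tOut are the box entry/exit parameters.
static int nearestEntry(const Geom& G, const double* p, const double* d,
                        double& tIn, double& tOut) {
  const double rOut = std::sqrt((G.R + G.depth) * (G.R + G.depth) +
                                0.25 * G.wt * G.wt) + 1e-9;
  const double rIn = G.R - 1e-9;
  const double zmin = G.z0 - 0.5 * G.wz - 1e-9;
  const double zmax = G.z0 + (G.nr - 1) * G.pitch_z + 0.5 * G.wz + 1e-9;
  const double dphi = 2.0 * M_PI / G.Ct;
  const double tmin = 1e-9;

  const double a = d[0] * d[0] + d[1] * d[1];
  double iv0[2], iv1[2];  // up to two candidate t-intervals
  int nIv = 0;

  if (a < 1e-16) {
    // ray (nearly) parallel to the axis: stays at one azimuth
    double r2 = p[0] * p[0] + p[1] * p[1];
    if (r2 < rIn * rIn || r2 > rOut * rOut) return -1;
    double lo = tmin, hi = std::numeric_limits<double>::infinity();
    if (std::fabs(d[2]) > 1e-14) {
      double u0 = (zmin - p[2]) / d[2], u1 = (zmax - p[2]) / d[2];
      if (u0 > u1) std::swap(u0, u1);
      lo = std::max(lo, u0); hi = std::min(hi, u1);
    } else if (p[2] < zmin || p[2] > zmax) return -1;
    if (lo > hi) return -1;
    iv0[0] = lo; iv0[1] = std::min(hi, 4.0 * rOut + std::fabs(zmax - zmin));
    nIv = 1;
  } else {
    const double b = p[0] * d[0] + p[1] * d[1];
    const double cOut = p[0] * p[0] + p[1] * p[1] - rOut * rOut;
    double disc = b * b - a * cOut;
    if (disc <= 0) return -1;
    double sq = std::sqrt(disc);
    double tA = (-b - sq) / a, tB = (-b + sq) / a;
    if (tB < tmin) return -1;
    double lo = std::max(tA, tmin), hi = tB;
    // central hole
    const double cInn = p[0] * p[0] + p[1] * p[1] - rIn * rIn;
    double discI = b * b - a * cInn;
    double g0 = 1, g1 = 0;
    if (discI > 0) {
      double sqi = std::sqrt(discI);
      g0 = (-b - sqi) / a; g1 = (-b + sqi) / a;
    }
    // z clipping
    double zlo = -std::numeric_limits<double>::infinity();
    double zhi = std::numeric_limits<double>::infinity();
    if (std::fabs(d[2]) > 1e-14) {
      zlo = (zmin - p[2]) / d[2]; zhi = (zmax - p[2]) / d[2];
      if (zlo > zhi) std::swap(zlo, zhi);
    } else if (p[2] < zmin || p[2] > zmax) return -1;
    lo = std::max(lo, zlo); hi = std::min(hi, zhi);
    if (lo > hi) return -1;
    if (discI > 0 && g1 > lo && g0 < hi) {
      if (g0 > lo) { iv0[0] = lo; iv0[1] = g0; nIv = 1; }
      if (g1 < hi) {
        if (nIv == 0) { iv0[0] = g1; iv0[1] = hi; nIv = 1; }
        else { iv1[0] = g1; iv1[1] = hi; nIv = 2; }
      }
      if (nIv == 0) return -1;
    } else {
      iv0[0] = lo; iv0[1] = hi; nIv = 1;
    }
  }

  for (int q = 0; q < nIv; ++q) {
    const double* iv = (q == 0) ? iv0 : iv1;
    // sample azimuth along the interval to bound the candidate index range
    int ref = -1, dmin = 0, dmax = 0;
    const int NS = 7;
    for (int si = 0; si < NS; ++si) {
      double t = iv[0] + (iv[1] - iv[0]) * si / (NS - 1.0);
      double x = p[0] + d[0] * t, y = p[1] + d[1] * t;
      if (x == 0 && y == 0) continue;
      double phi = std::atan2(y, x);
      int idx = (int)std::lround(phi / dphi);
      idx = ((idx % G.Ct) + G.Ct) % G.Ct;
      if (ref < 0) { ref = idx; continue; }
      int diff = idx - ref;
      while (diff > G.Ct / 2) diff -= G.Ct;
      while (diff < -G.Ct / 2) diff += G.Ct;
      if (diff < dmin) dmin = diff;
      if (diff > dmax) dmax = diff;
    }
    if (ref < 0) continue;
    int itLo = ref + dmin - 2, itHi = ref + dmax + 2;
    if (itHi - itLo + 1 > G.Ct) { itLo = 0; itHi = G.Ct - 1; }
    // ring candidates from the z sweep
    double za = p[2] + d[2] * iv[0], zb = p[2] + d[2] * iv[1];
    if (za > zb) std::swap(za, zb);
    int rLo = (int)std::floor((za - G.z0) / G.pitch_z + 0.5) - 1;
    int rHi = (int)std::floor((zb - G.z0) / G.pitch_z + 0.5) + 1;
    if (rLo < 0) rLo = 0;
    if (rHi > G.nr - 1) rHi = G.nr - 1;

    int best = -1;
    double bestT = std::numeric_limits<double>::infinity();
    double bestOut = 0;
    for (int it = itLo; it <= itHi; ++it) {
      int itw = ((it % G.Ct) + G.Ct) % G.Ct;
      for (int r = rLo; r <= rHi; ++r) {
        double t0, t1;
        if (!rayCrystal(G, itw, r, p, d, t0, t1)) continue;
        if (t1 <= tmin) continue;
        if (t0 < tmin) t0 = tmin;
        if (t0 < bestT) { bestT = t0; bestOut = t1; best = r * G.Ct + itw; }
      }
    }
    if (best >= 0) { tIn = bestT; tOut = bestOut; return best; }
  }
  return -1;
}

// ---- photon tracer ----------------------------------------------------

struct Deposit { int crystal; double energy; int order; };

// fixed-capacity deposit buffer: avoids per-photon heap allocation in the
// hot pair loop (chains longer than the capacity are physically absurd)
struct DepositBuf {
  static const int CAP = 64;
  Deposit d[CAP];
  int n = 0;
  void push(int crystal, double energy, int order) {
    if (n < CAP) d[n++] = { crystal, energy, order };
  }
};

// Trace one photon; appends deposits and sets the escaping energy (0 when
// fully absorbed). Energies in keV, cutoff terminates sub-threshold photons
// depositing the remainder locally.
static void tracePhotonCore(const Geom& G, const AttenTable& T, RNG& rng,
                            double* pos, double* dir, double E0, double cutoff,
                            DepositBuf& deps, double& escapeE) {
  double E = E0;
  int inside = -1;
  int order = 0;
  escapeE = 0.0;
  for (int guard = 0; guard < 10000; ++guard) {
    if (inside < 0) {
      double tIn, tOut;
      inside = nearestEntry(G, pos, dir, tIn, tOut);
      if (inside < 0) { escapeE = E; return; }
      for (int i = 0; i < 3; ++i) pos[i] += dir[i] * (tIn + 1e-9);
    }
    double t0, t1;
    int it = inside % G.Ct, ring = inside / G.Ct;
    if (!rayCrystal(G, it, ring, pos, dir, t0, t1) || t1 <= 1e-12) {
      // numerically on the boundary: nudge out and search again
      for (int i = 0; i < 3; ++i) pos[i] += dir[i] * 1e-9;
      inside = -1;
      continue;
    }
    double muP, muC, muR;
    T.mu(E, muP, muC, muR);
    double muTot = muP + muC + muR;
    if (muTot <= 0) {
      for (int i = 0; i < 3; ++i) pos[i] += dir[i] * (t1 + 1e-9);
      inside = -1;
      continue;
    }
    double s = -std::log(rng.u()) / muTot;
    if (s >= t1) {
      for (int i = 0; i < 3; ++i) pos[i] += dir[i] * (t1 + 1e-9);
      inside = -1;
      continue;
    }
    for (int i = 0; i < 3; ++i) pos[i] += dir[i] * s;
    double pick = rng.u() * muTot;
    if (pick < muP) {
      deps.push(inside, E, order);
      return;
    } else if (pick < muP + muC) {
      double cosT, Eout;
      sampleKleinNishina(rng, E, cosT, Eout);
      double dE = E - Eout;
      if (dE > 0) deps.push(inside, dE, order);
      ++order;
      if (Eout < cutoff) {
        deps.push(inside, Eout, order);
        return;
      }
      E = Eout;
      rotateDirection(dir, cosT, 2.0 * M_PI * rng.u());
    } else {
      double cosT = sampleThomsonCos(rng);
      rotateDirection(dir, cosT, 2.0 * M_PI * rng.u());
      ++order;
    }
  }
  escapeE = E;  // guard bail-out; practically unreachable
}

// Crystal with the maximum summed deposit; ties broken by earliest
// interaction order. Returns -1 for an empty list. Also reports the first
// interaction's crystal.
static int registerHitCore(const Deposit* deps, int n, int& firstCrystal) {
  firstCrystal = -1;
  if (n == 0) return -1;
  int bestC = -1, bestOrder = 0;
  double bestE = -1;
  int minOrder = deps[0].order;
  firstCrystal = deps[0].crystal;
  for (int i = 0; i < n; ++i)
    if (deps[i].order < minOrder) { minOrder = deps[i].order; firstCrystal = deps[i].crystal; }
  for (int i = 0; i < n; ++i) {
    int c = deps[i].crystal;
    double tot = 0;
    int ord = deps[i].order;
    bool seen = false;
    for (int j = 0; j < i; ++j) if (deps[j].crystal == c) { seen = true; break; }
    if (seen) continue;
    for (int j = i; j < n; ++j)
      if (deps[j].crystal == c) {
        tot += deps[j].energy;
        if (deps[j].order < ord) ord = deps[j].order;
      }
    if (tot > bestE + 1e-12 ||
        (std::fabs(tot - bestE) <= 1e-12 && ord < bestOrder)) {
      bestE = tot; bestC = c; bestOrder = ord;
    }
  }
  return bestC;
}

// ---- exported interface ------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cppSampleDirection(int n, int seed) {
  NumericMatrix out(n, 3);
  RNG rng((uint64_t)seed, 0x5d1ec710);
  double d[3];
  for (int i = 0; i < n; ++i) {
    sampleSphere(rng, d);
    out(i, 0) = d[0]; out(i, 1) = d[1]; out(i, 2) = d[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cppSampleFreePath(int n, double mu, int seed) {
  NumericVector out(n);
  RNG rng((uint64_t)seed, 0xf4ee9a7b);
  for (int i = 0; i < n; ++i)
    out[i] = (mu <= 0) ? R_PosInf : -std::log(rng.u()) / mu;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cppSampleCompton(int n, double energy, int seed) {
  NumericMatrix out(n, 2);
  RNG rng((uint64_t)seed, 0xc03b7041);
  for (int i = 0; i < n; ++i) {
    double c, E;
    sampleKleinNishina(rng, energy, c, E);
    out(i, 0) = std::acos(std::min(1.0, std::max(-1.0, c)));
    out(i, 1) = E;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cppSampleRayleigh(int n, int seed) {
  NumericVector out(n);
  RNG rng((uint64_t)seed, 0x7a11e164);
  for (int i = 0; i < n; ++i)
    out[i] = std::acos(std::min(1.0, std::max(-1.0, sampleThomsonCos(rng))));
  return out;
}

// [[Rcpp::export]]
List cppTracePhoton(NumericVector position, NumericVector direction,
                    double energy, List geometry, NumericMatrix atten,
                    int seed, double cutoff) {
  Geom G = geomFromList(geometry);
  AttenTable T(atten);
  RNG rng((uint64_t)seed, 0x9e0cb1f2);
  double pos[3] = { position[0], position[1], position[2] };
  double dir[3] = { direction[0], direction[1], direction[2] };
  DepositBuf deps;
  double escapeE;
  tracePhotonCore(G, T, rng, pos, dir, energy, cutoff, deps, escapeE);
  int n = deps.n;
  IntegerVector crystal(n), order(n);
  NumericVector dep(n);
  for (int i = 0; i < n; ++i) {
    crystal[i] = deps.d[i].crystal;
    dep[i] = deps.d[i].energy;
    order[i] = deps.d[i].order;
  }
  return List::create(_["crystal"] = crystal, _["energy"] = dep,
                      _["order"] = order, _["escape"] = escapeE);
}

// [[Rcpp::export]]
IntegerVector cppRegisterHit(IntegerVector crystal, NumericVector energy,
                             IntegerVector order) {
  std::vector<Deposit> deps(crystal.size());
  for (int i = 0; i < crystal.size(); ++i)
    deps[i] = { crystal[i], energy[i], order[i] };
  int firstC;
  int c = registerHitCore(deps.data(), (int)deps.size(), firstC);
  return IntegerVector::create(c, firstC);
}

// Shared pair loop: trace a back-to-back 511 keV pair from `pos`, bin the
// coincidence. Returns 1 on coincidence.
static int tracePair(const Geom& G, const AttenTable& T, RNG& rng,
                     const double* src, double* counts, long C,
                     long& nIcsMismatch, long& nRegistered) {
  double d[3];
  sampleSphere(rng, d);
  int hit[2];
  for (int k = 0; k < 2; ++k) {
    double pos[3] = { src[0], src[1], src[2] };
    double dir[3] = { k == 0 ? d[0] : -d[0],
                      k == 0 ? d[1] : -d[1],
                      k == 0 ? d[2] : -d[2] };
    DepositBuf deps;
    double escapeE;
    tracePhotonCore(G, T, rng, pos, dir, 511.0, 10.0, deps, escapeE);
    int firstC;
    hit[k] = registerHitCore(deps.d, deps.n, firstC);
    if (hit[k] >= 0) {
      ++nRegistered;
      if (hit[k] != firstC) ++nIcsMismatch;
    }
  }
  if (hit[0] >= 0 && hit[1] >= 0 && hit[0] != hit[1]) {
    counts[lorIndexOf(hit[0], hit[1], C)] += 1.0;
    return 1;
  }
  return 0;
}

// [[Rcpp::export]]
List cppSimulatePointSource(NumericVector position, double nPairs,
                            List geometry, NumericMatrix atten, int seed) {
  Geom G = geomFromList(geometry);
  AttenTable T(atten);
  long C = G.nCrystals();
  NumericVector counts((R_xlen_t)G.nLORs());
  double src[3] = { position[0], position[1], position[2] };
  long nCoinc = 0, nIcs = 0, nReg = 0;
  long np = (long)nPairs;
  for (long i = 0; i < np; ++i) {
    RNG rng((uint64_t)seed, (uint64_t)i);
    nCoinc += tracePair(G, T, rng, src, REAL(counts), C, nIcs, nReg);
  }
  return List::create(_["counts"] = counts, _["nCoincidences"] = (double)nCoinc,
                      _["nRegistered"] = (double)nReg,
                      _["nIcsMismatch"] = (double)nIcs);
}

// Emission from a voxelized activity distribution: voxel picked by its
// cumulative activity, annihilation point uniform within the voxel.
// [[Rcpp::export]]
List cppSimulateEmission(NumericMatrix voxCenters, NumericVector cumProb,
                         NumericVector voxelSize, double nPairs,
                         List geometry, NumericMatrix atten, int seed) {
  Geom G = geomFromList(geometry);
  AttenTable T(atten);
  long C = G.nCrystals();
  NumericVector counts((R_xlen_t)G.nLORs());
  long nCoinc = 0, nIcs = 0, nReg = 0;
  int nvox = voxCenters.nrow();
  long np = (long)nPairs;
  for (long i = 0; i < np; ++i) {
    RNG rng((uint64_t)seed, (uint64_t)i);
    double u = rng.u();
    int lo = 0, hi = nvox - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cumProb[mid] < u) lo = mid + 1; else hi = mid;
    }
    double src[3];
    for (int a = 0; a < 3; ++a)
      src[a] = voxCenters(lo, a) + (rng.u() - 0.5) * voxelSize[a];
    nCoinc += tracePair(G, T, rng, src, REAL(counts), C, nIcs, nReg);
  }
  return List::create(_["counts"] = counts, _["nCoincidences"] = (double)nCoinc,
                      _["nRegistered"] = (double)nReg,
                      _["nIcsMismatch"] = (double)nIcs);
}

// Endpoint mislocation distribution: photons at perpendicular incidence on
// random crystal front faces; offsets of the registered crystal relative to
// the aimed crystal in (transaxial, axial) index units.
// [[Rcpp::export]]
List cppEstimateLorBlur(List geometry, NumericMatrix atten, double nPhotons,
                        int seed, int kt, int kz) {
  Geom G = geomFromList(geometry);
  AttenTable T(atten);
  NumericMatrix hist(2 * kt + 1, 2 * kz + 1);
  long nReg = 0;
  long np = (long)nPhotons;
  for (long i = 0; i < np; ++i) {
    RNG rng((uint64_t)seed, (uint64_t)i ^ 0xb10bULL);
    int it = (int)(rng.u() * G.Ct) % G.Ct;
    int ring = (int)(rng.u() * G.nr) % G.nr;
    double phi = 2.0 * M_PI * it / G.Ct;
    double c = std::cos(phi), s = std::sin(phi);
    double offT = (rng.u() - 0.5) * G.wt;
    double offZ = (rng.u() - 0.5) * G.wz;
    double pos[3] = { (G.R - 1e-6) * c - offT * s,
                      (G.R - 1e-6) * s + offT * c,
                      G.z0 + ring * G.pitch_z + offZ };
    double dir[3] = { c, s, 0.0 };
    DepositBuf deps;
    double escapeE;
    tracePhotonCore(G, T, rng, pos, dir, 511.0, 10.0, deps, escapeE);
    int firstC;
    int hit = registerHitCore(deps.d, deps.n, firstC);
    if (hit < 0) continue;
    ++nReg;
    int dt = (hit % G.Ct) - it;
    while (dt > G.Ct / 2) dt -= G.Ct;
    while (dt < -G.Ct / 2) dt += G.Ct;
    int dz = (hit / G.Ct) - ring;
    if (std::abs(dt) <= kt && std::abs(dz) <= kz)
      hist(dt + kt, dz + kz) += 1.0;
  }
  return List::create(_["hist"] = hist, _["nRegistered"] = (double)nReg);
}

// Brute-force nearest-entry oracle used by the tests to validate the
// pruned ring search.
// [[Rcpp::export]]
IntegerVector cppNearestEntryCompare(NumericMatrix origins,
                                     NumericMatrix dirs, List geometry) {
  Geom G = geomFromList(geometry);
  int n = origins.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = { origins(i, 0), origins(i, 1), origins(i, 2) };
    double d[3] = { dirs(i, 0), dirs(i, 1), dirs(i, 2) };
    double tIn, tOut;
    int pruned = nearestEntry(G, p, d, tIn, tOut);
    // exhaustive search
    int best = -1;
    double bestT = std::numeric_limits<double>::infinity();
    for (int c = 0; c < G.nCrystals(); ++c) {
      double t0, t1;
      if (!rayCrystal(G, c % G.Ct, c / G.Ct, p, d, t0, t1)) continue;
      if (t1 <= 1e-9) continue;
      if (t0 < 1e-9) t0 = 1e-9;
      if (t0 < bestT) { bestT = t0; best = c; }
    }
    out[i] = (pruned == best) ? 1 : 0;
  }
  return out;
}
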