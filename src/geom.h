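#ifndef ICSFILTER_GEOM_H
#define ICSFILTER_GEOM_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <limits>

// Cylindrical ring of radially oriented rectangular scintillator crystals.
// Crystal id = ring * Ct + it (0-based); azimuth of crystal it is 2*pi*it/Ct.
// Boxes span radius [R, R + depth]; tangential width wt, axial width wz.
struct Geom {
  double R;        // inner (front face) radius, mm
  double pitch_t;  // transaxial pitch (arc at inner radius), mm
  double pitch_z;  // axial pitch, mm
  double depth;    // radial crystal depth, mm
  double wt;       // tangential crystal width, mm (<= chord pitch)
  double wz;       // axial crystal width, mm
  int Ct;          // crystals per ring
  int nr;          // number of rings
  double z0;       // z of ring 0 centers, mm
  double eDepth;   // LOR endpoint depth behind the front face, mm

  int nCrystals() const { return Ct * nr; }
  long nLORs() const {
    long C = nCrystals();
    return C * (C - 1) / 2;
  }
};

inline Geom geomFromList(const Rcpp::List& g) {
  Geom G;
  G.R = Rcpp::as<double>(g["ringRadius"]);
  G.Ct = Rcpp::as<int>(g["nCrystalsTransaxial"]);
  G.nr = Rcpp::as<int>(g["nRings"]);
  G.pitch_t = Rcpp::as<double>(g["crystalPitchTransaxial"]);
  G.pitch_z = Rcpp::as<double>(g["crystalPitchAxial"]);
  G.depth = Rcpp::as<double>(g["crystalDepth"]);
  G.wt = Rcpp::as<double>(g["crystalWidthTransaxial"]);
  G.wz = Rcpp::as<double>(g["crystalWidthAxial"]);
  G.z0 = -0.5 * (G.nr - 1) * G.pitch_z;
  G.eDepth = g.containsElementNamed("endpointDepth")
      ? Rcpp::as<double>(g["endpointDepth"]) : 0.0;
  return G;
}

// Canonical unordered-pair LOR index: a < b, lexicographic enumeration.
inline long lorIndexOf(long a, long b, long C) {
  if (a > b) { long t = a; a = b; b = t; }
  return a * C - a * (a + 1) / 2 + (b - a - 1);
}

// Ray vs crystal oriented box. Returns false if missed; otherwise the
// entry/exit parameters along dir (may be negative if origin is inside or
// past the box).
inline bool rayCrystal(const Geom& G, int it, int ring,
                       const double* p, const double* d,
                       double& t0, double& t1) {
  const double phi = 2.0 * M_PI * it / G.Ct;
  const double c = std::cos(phi), s = std::sin(phi);
  const double rc = G.R + 0.5 * G.depth;
  const double zc = G.z0 + ring * G.pitch_z;
  // local frame: radial, tangential, axial
  const double px = p[0] - rc * c, py = p[1] - rc * s, pz = p[2] - zc;
  const double pl[3] = { px * c + py * s, -px * s + py * c, pz };
  const double dl[3] = { d[0] * c + d[1] * s, -d[0] * s + d[1] * c, d[2] };
  const double he[3] = { 0.5 * G.depth, 0.5 * G.wt, 0.5 * G.wz };
  t0 = -std::numeric_limits<double>::infinity();
  t1 = std::numeric_limits<double>::infinity();
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dl[a]) < 1e-14) {
      if (std::fabs(pl[a]) > he[a]) return false;
    } else {
      double u0 = (-he[a] - pl[a]) / dl[a];
      double u1 = (he[a] - pl[a]) / dl[a];
      if (u0 > u1) { double t = u0; u0 = u1; u1 = t; }
      if (u0 > t0) t0 = u0;
      if (u1 < t1) t1 = u1;
      if (t0 > t1) return false;
    }
  }
  return true;
}

// Counter-based reproducible RNG: xorshift128+ seeded from splitmix64 so
// that (seed, stream) fully determines the stream independently of call
// order or thread count.
struct RNG {
  uint64_t s0, s1;
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  RNG(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + stream;
    s0 = splitmix(x);
    s1 = splitmix(x);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform in (0, 1); never exactly 0 so log(u) is safe
  double u() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Energy-indexed attenuation table with log-log interpolation, clamped at
// the grid ends. Columns: photoelectric, Compton, Rayleigh (1/mm).
struct AttenTable {
  std::vector<double> logE, logPhoto, logCompton, logRayleigh;
  bool hasPhoto, hasCompton, hasRayleigh;

  static double safeLog(double v) { return std::log(v > 0 ? v : 1e-300); }

  AttenTable(const Rcpp::NumericMatrix& m) {
    int n = m.nrow();
    logE.resize(n); logPhoto.resize(n); logCompton.resize(n); logRayleigh.resize(n);
    hasPhoto = hasCompton = hasRayleigh = false;
    for (int i = 0; i < n; ++i) {
      logE[i] = std::log(m(i, 0));
      logPhoto[i] = safeLog(m(i, 1));
      logCompton[i] = safeLog(m(i, 2));
      logRayleigh[i] = safeLog(m(i, 3));
      if (m(i, 1) > 0) hasPhoto = true;
      if (m(i, 2) > 0) hasCompton = true;
      if (m(i, 3) > 0) hasRayleigh = true;
    }
  }

  void mu(double energy, double& photo, double& compton, double& rayleigh) const {
    const int n = (int)logE.size();
    double le = std::log(energy);
    if (le <= logE[0]) le = logE[0];
    if (le >= logE[n - 1]) le = logE[n - 1];
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (logE[mid] <= le) lo = mid; else hi = mid;
    }
    double w = (le - logE[lo]) / (logE[hi] - logE[lo] + 1e-300);
    photo = hasPhoto ? std::exp(logPhoto[lo] + w * (logPhoto[hi] - logPhoto[lo])) : 0.0;
    compton = hasCompton ? std::exp(logCompton[lo] + w * (logCompton[hi] - logCompton[lo])) : 0.0;
    rayleigh = hasRayleigh ? std::exp(logRayleigh[lo] + w * (logRayleigh[hi] - logRayleigh[lo])) : 0.0;
  }
};

#endif
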