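#pragma once
#include <cmath>
#include <vector>

// Crystal-level model of the 18-sector dual-layer staggered-crystal ring.
// Local sector frame: u radial (from axis, along sector normal), v transaxial
// within the face, z axial.  The thin (top) layer faces the FOV; the thick
// (bottom) layer sits behind it, coupled to the photosensors.
struct Scanner {
  int nsec;           // sectors around the ring
  double R;           // apothem: radial distance of the top-layer front face, mm
  double halfW;       // half transaxial sector width, mm
  double halfH;       // half axial extent, mm
  double tTop, tBot;  // layer thicknesses, mm
  double pitch;       // crystal pitch, mm
  double tileW;       // tile width, mm
  double topMargin;   // dead border of the top-layer grid inside a tile, mm
  int topN, botN;     // crystals per tile side, per layer
  int modAx;          // modules along z
  int tilesAxPerMod;  // axial tiles per module (2)
  int tilesTrans;     // transaxial tiles per sector (2)
  std::vector<double> cphi, sphi;

  int perTile() const { return topN * topN + botN * botN; }
  int nAxTiles() const { return modAx * tilesAxPerMod; }
  int tilesPerSector() const { return modAx * 4; }
  int crystalsPerSector() const { return tilesPerSector() * perTile(); }
  int nCrystals() const { return nsec * crystalsPerSector(); }
  double depth() const { return tTop + tBot; }

  void init() {
    cphi.resize(nsec);
    sphi.resize(nsec);
    for (int s = 0; s < nsec; ++s) {
      double phi = 2.0 * M_PI * s / nsec;
      cphi[s] = std::cos(phi);
      sphi[s] = std::sin(phi);
    }
  }

  // world -> sector local
  inline void toLocal(int s, double x, double y, double &u, double &v) const {
    u = cphi[s] * x + sphi[s] * y;
    v = -sphi[s] * x + cphi[s] * y;
  }
  inline void toWorld(int s, double u, double v, double &x, double &y) const {
    x = cphi[s] * u - sphi[s] * v;
    y = sphi[s] * u + cphi[s] * v;
  }

  // Intersection of a ray with one sector slab; returns false if missed.
  bool sectorIntersect(int s, const double p[3], const double d[3],
                       double &t0, double &t1) const {
    double pu, pv, du, dv;
    toLocal(s, p[0], p[1], pu, pv);
    toLocal(s, d[0], d[1], du, dv);
    t0 = 0.0;
    t1 = 1e300;
    // u in [R, R+depth]
    const double lo[3] = {R, -halfW, -halfH};
    const double hi[3] = {R + depth(), halfW, halfH};
    double pp[3] = {pu, pv, p[2]};
    double dd[3] = {du, dv, d[2]};
    for (int k = 0; k < 3; ++k) {
      if (std::fabs(dd[k]) < 1e-12) {
        if (pp[k] < lo[k] || pp[k] > hi[k]) return false;
      } else {
        double ta = (lo[k] - pp[k]) / dd[k];
        double tb = (hi[k] - pp[k]) / dd[k];
        if (ta > tb) { double tmp = ta; ta = tb; tb = tmp; }
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 >= t1) return false;
      }
    }
    return t1 > 0.0;
  }

  struct Interval { double t0, t1; int sec; };

  // All LYSO slab crossings of a ray, time-ordered (t >= 0).
  int intervals(const double p[3], const double d[3], Interval *out) const {
    int n = 0;
    for (int s = 0; s < nsec; ++s) {
      double t0, t1;
      if (sectorIntersect(s, p, d, t0, t1)) {
        out[n].t0 = t0 < 0 ? 0 : t0;
        out[n].t1 = t1;
        out[n].sec = s;
        ++n;
      }
    }
    // insertion sort by t0 (n is tiny)
    for (int i = 1; i < n; ++i) {
      Interval key = out[i];
      int j = i - 1;
      while (j >= 0 && out[j].t0 > key.t0) { out[j + 1] = out[j]; --j; }
      out[j + 1] = key;
    }
    return n;
  }

  // Is a local point inside scintillator (vs. the top-layer dead border)?
  // Assumes the point is inside the sector slab box.
  inline bool inLyso(double u, double v, double z) const {
    if (u - R >= tTop) return true;  // thick layer fills the tile
    // thin layer: only the central topN*pitch square of each tile
    double va = v + halfW, za = z + halfH;
    double vv = va - tileW * std::floor(va / tileW);
    double zz = za - tileW * std::floor(za / tileW);
    double topLo = topMargin, topHi = tileW - topMargin;
    return (vv >= topLo && vv < topHi && zz >= topLo && zz < topHi);
  }

  // Crystal flat id from a local interaction point; returns -1 if in a gap.
  int assign(int sec, double u, double v, double z) const {
    int layerTop = (u - R) < tTop ? 1 : 0;
    double vAll = v + halfW;     // [0, 2*halfW)
    double zAll = z + halfH;     // [0, 2*halfH)
    int tv = (int)(vAll / tileW);
    if (tv < 0) tv = 0;
    if (tv >= tilesTrans) tv = tilesTrans - 1;
    int az = (int)(zAll / tileW);
    if (az < 0) az = 0;
    if (az >= nAxTiles()) az = nAxTiles() - 1;
    int mod = az / tilesAxPerMod;
    int tz = az % tilesAxPerMod;
    double vv = vAll - tv * tileW;
    double zz = zAll - az * tileW;
    int row, col, off;
    if (layerTop) {
      vv -= topMargin;
      zz -= topMargin;
      if (vv < 0 || zz < 0) return -1;
      col = (int)(vv / pitch);
      row = (int)(zz / pitch);
      if (col >= topN || row >= topN) return -1;
      off = row * topN + col;
    } else {
      col = (int)(vv / pitch);
      row = (int)(zz / pitch);
      if (col >= botN) col = botN - 1;
      if (row >= botN) row = botN - 1;
      off = topN * topN + row * botN + col;
    }
    int tile = tv * tilesAxPerMod + tz;  // 0..3 within module
    return ((sec * modAx + mod) * (tilesTrans * tilesAxPerMod) + tile) * perTile() + off;
  }

  // Center of a crystal (world coordinates) from its flat id.
  void center(int id, double *xyz) const {
    int per = perTile();
    int off = id % per;
    int t = id / per;
    int tile = t % (tilesTrans * tilesAxPerMod);
    t /= (tilesTrans * tilesAxPerMod);
    int mod = t % modAx;
    int sec = t / modAx;
    int tv = tile / tilesAxPerMod;
    int tz = tile % tilesAxPerMod;
    int layerTop = off < topN * topN ? 1 : 0;
    int row, col;
    double u, vv, zz;
    if (layerTop) {
      row = off / topN;
      col = off % topN;
      u = R + 0.5 * tTop;
      vv = topMargin + (col + 0.5) * pitch;
      zz = topMargin + (row + 0.5) * pitch;
    } else {
      int o = off - topN * topN;
      row = o / botN;
      col = o % botN;
      u = R + tTop + 0.5 * tBot;
      vv = (col + 0.5) * pitch;
      zz = (row + 0.5) * pitch;
    }
    double v = -halfW + tv * tileW + vv;
    double z = -halfH + (mod * tilesAxPerMod + tz) * tileW + zz;
    double x, y;
    toWorld(sec, u, v, x, y);
    xyz[0] = x;
    xyz[1] = y;
    xyz[2] = z;
  }
};

inline Scanner scannerFromParams(const double *g) {
  Scanner sc;
  sc.nsec = (int)g[0];
  sc.R = g[1];
  sc.halfW = g[2];
  sc.halfH = g[3];
  sc.tTop = g[4];
  sc.tBot = g[5];
  sc.pitch = g[6];
  sc.tileW = g[7];
  sc.topMargin = g[8];
  sc.topN = (int)g[9];
  sc.botN = (int)g[10];
  sc.modAx = (int)g[11];
  sc.tilesAxPerMod = (int)g[12];
  sc.tilesTrans = (int)g[13];
  sc.init();
  return sc;
}
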