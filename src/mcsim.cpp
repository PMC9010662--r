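// Mesh-based Monte Carlo photon transport core.
//
// Photon packets carry a statistical weight, are attenuated continuously by
// absorption along each traversed segment, scatter according to the
// Henyey-Greenstein phase function, and are terminated by escape, time-gate
// overflow or Russian roulette.  Tetrahedron traversal uses barycentric
// gradients: the exit face is the face whose barycentric coordinate first
// reaches zero along the current direction.
//
// Everything is single threaded and driven by a self-contained PCG32 RNG so
// that a given seed reproduces results bitwise on any platform.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------- PCG32 RNG
// Minimal PCG-XSH-RR 64/32 generator (O'Neill's public-domain algorithm).
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 0xda3e39cb94b95bdbULL) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    next();
    state += seed;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  // uniform on (0,1), never exactly 0 or 1
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
};

static const double C_MM_PER_NS = 299.792458; // speed of light in vacuum

// ------------------------------------------------------------ face adjacency
// Faces are indexed by the local vertex they are opposite to: face f of tet
// (v0,v1,v2,v3) is the triangle omitting vf.  Neighbor 0 marks the boundary.
static inline uint64_t face_key(int a, int b, int c) {
  // sort three node ids (1-based, < 2^21) into a packed 63-bit key
  if (a > b) std::swap(a, b);
  if (b > c) std::swap(b, c);
  if (a > b) std::swap(a, b);
  return (((uint64_t)a) << 42) | (((uint64_t)b) << 21) | (uint64_t)c;
}

// [[Rcpp::export]]
IntegerMatrix cpp_tet_adjacency(IntegerMatrix elem, int nnode) {
  if (nnode >= (1 << 21))
    stop("adjacency table supports up to 2^21 nodes");
  int ne = elem.nrow();
  IntegerMatrix nb(ne, 4);
  std::unordered_map<uint64_t, int64_t> seen; // key -> packed (tet*4 + face)
  seen.reserve((size_t)ne * 2);
  static const int opp[4][3] = {{1, 2, 3}, {0, 2, 3}, {0, 1, 3}, {0, 1, 2}};
  for (int e = 0; e < ne; ++e) {
    for (int f = 0; f < 4; ++f) {
      uint64_t k = face_key(elem(e, opp[f][0]), elem(e, opp[f][1]),
                            elem(e, opp[f][2]));
      auto it = seen.find(k);
      if (it == seen.end()) {
        seen[k] = (int64_t)e * 4 + f;
      } else {
        int64_t packed = it->second;
        if (packed < 0)
          stop("face shared by more than two tetrahedra (non-manifold mesh)");
        int e2 = (int)(packed / 4), f2 = (int)(packed % 4);
        nb(e, f) = e2 + 1;
        nb(e2, f2) = e + 1;
        it->second = -1;
      }
    }
  }
  return nb;
}

// ------------------------------------------------------- geometry precompute
struct TetGeom {
  // gradients of barycentric lambda1..lambda3 (w.r.t. x,y,z) and vertex 0;
  // lambda0 = 1 - l1 - l2 - l3, grad lambda0 = -(g1+g2+g3)
  std::vector<double> g;  // 9 per tet
  std::vector<double> v0; // 3 per tet
  int ne;
};

static void precompute_geom(const NumericMatrix &node, const IntegerMatrix &elem,
                            TetGeom &geo) {
  int ne = elem.nrow();
  geo.ne = ne;
  geo.g.assign((size_t)ne * 9, 0.0);
  geo.v0.assign((size_t)ne * 3, 0.0);
  for (int e = 0; e < ne; ++e) {
    double M[3][3];
    int i0 = elem(e, 0) - 1;
    for (int j = 0; j < 3; ++j) {
      int ij = elem(e, j + 1) - 1;
      for (int k = 0; k < 3; ++k) M[k][j] = node(ij, k) - node(i0, k);
    }
    // invert M (columns are edge vectors); lambda_{1..3} = Minv * (p - v0)
    double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
                 M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
                 M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
    if (det == 0.0) stop("degenerate tetrahedron %d", e + 1);
    double inv[3][3];
    inv[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) / det;
    inv[0][1] = (M[0][2] * M[2][1] - M[0][1] * M[2][2]) / det;
    inv[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) / det;
    inv[1][0] = (M[1][2] * M[2][0] - M[1][0] * M[2][2]) / det;
    inv[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) / det;
    inv[1][2] = (M[0][2] * M[1][0] - M[0][0] * M[1][2]) / det;
    inv[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) / det;
    inv[2][1] = (M[0][1] * M[2][0] - M[0][0] * M[2][1]) / det;
    inv[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) / det;
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c) geo.g[(size_t)e * 9 + r * 3 + c] = inv[r][c];
    for (int k = 0; k < 3; ++k) geo.v0[(size_t)e * 3 + k] = node(i0, k);
  }
}

static inline void bary(const TetGeom &geo, int e, const double p[3],
                        double lam[4]) {
  const double *g = &geo.g[(size_t)e * 9];
  const double *v0 = &geo.v0[(size_t)e * 3];
  double d0 = p[0] - v0[0], d1 = p[1] - v0[1], d2 = p[2] - v0[2];
  lam[1] = g[0] * d0 + g[1] * d1 + g[2] * d2;
  lam[2] = g[3] * d0 + g[4] * d1 + g[5] * d2;
  lam[3] = g[6] * d0 + g[7] * d1 + g[8] * d2;
  lam[0] = 1.0 - lam[1] - lam[2] - lam[3];
}

static inline void bary_dir(const TetGeom &geo, int e, const double d[3],
                            double dlam[4]) {
  const double *g = &geo.g[(size_t)e * 9];
  dlam[1] = g[0] * d[0] + g[1] * d[1] + g[2] * d[2];
  dlam[2] = g[3] * d[0] + g[4] * d[1] + g[5] * d[2];
  dlam[3] = g[6] * d[0] + g[7] * d[1] + g[8] * d[2];
  dlam[0] = -dlam[1] - dlam[2] - dlam[3];
}

// outward unit normal of face f (the face where lambda_f = 0)
static inline void face_normal(const TetGeom &geo, int e, int f, double n[3]) {
  const double *g = &geo.g[(size_t)e * 9];
  double v[3];
  if (f == 0) {
    v[0] = g[0] + g[3] + g[6];
    v[1] = g[1] + g[4] + g[7];
    v[2] = g[2] + g[5] + g[8];
  } else {
    v[0] = -g[(f - 1) * 3 + 0];
    v[1] = -g[(f - 1) * 3 + 1];
    v[2] = -g[(f - 1) * 3 + 2];
  }
  double nn = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  n[0] = v[0] / nn; n[1] = v[1] / nn; n[2] = v[2] / nn;
}

// ----------------------------------------------------------- point location
struct LocGrid {
  double lo[3], cell[3];
  int dim[3];
  std::vector<int> start;   // CSR offsets
  std::vector<int> items;   // tet ids per grid cell
};

static void build_grid(const NumericMatrix &node, const IntegerMatrix &elem,
                       LocGrid &gr) {
  int ne = elem.nrow();
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < node.nrow(); ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], node(i, k));
      hi[k] = std::max(hi[k], node(i, k));
    }
  int target = (int)std::cbrt((double)ne / 2.0) + 1;
  for (int k = 0; k < 3; ++k) {
    gr.lo[k] = lo[k];
    gr.dim[k] = std::max(1, std::min(target, 128));
    double span = hi[k] - lo[k];
    gr.cell[k] = (span > 0 ? span : 1.0) / gr.dim[k] * (1.0 + 1e-12);
  }
  size_t ncell = (size_t)gr.dim[0] * gr.dim[1] * gr.dim[2];
  std::vector<std::vector<int>> buckets(ncell);
  for (int e = 0; e < ne; ++e) {
    double elo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double ehi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int j = 0; j < 4; ++j) {
      int id = elem(e, j) - 1;
      for (int k = 0; k < 3; ++k) {
        elo[k] = std::min(elo[k], node(id, k));
        ehi[k] = std::max(ehi[k], node(id, k));
      }
    }
    int c0[3], c1[3];
    for (int k = 0; k < 3; ++k) {
      c0[k] = std::max(0, std::min(gr.dim[k] - 1,
                                   (int)((elo[k] - gr.lo[k]) / gr.cell[k])));
      c1[k] = std::max(0, std::min(gr.dim[k] - 1,
                                   (int)((ehi[k] - gr.lo[k]) / gr.cell[k])));
    }
    for (int x = c0[0]; x <= c1[0]; ++x)
      for (int y = c0[1]; y <= c1[1]; ++y)
        for (int z = c0[2]; z <= c1[2]; ++z)
          buckets[((size_t)x * gr.dim[1] + y) * gr.dim[2] + z].push_back(e);
  }
  gr.start.assign(ncell + 1, 0);
  for (size_t c = 0; c < ncell; ++c)
    gr.start[c + 1] = gr.start[c] + (int)buckets[c].size();
  gr.items.resize(gr.start[ncell]);
  for (size_t c = 0; c < ncell; ++c)
    std::copy(buckets[c].begin(), buckets[c].end(),
              gr.items.begin() + gr.start[c]);
}

static int locate(const TetGeom &geo, const LocGrid &gr, const double p[3],
                  double tol = 1e-9) {
  int c[3];
  for (int k = 0; k < 3; ++k) {
    c[k] = (int)((p[k] - gr.lo[k]) / gr.cell[k]);
    if (c[k] < 0 || c[k] >= gr.dim[k]) return -1;
  }
  size_t cell = ((size_t)c[0] * gr.dim[1] + c[1]) * gr.dim[2] + c[2];
  double lam[4];
  for (int i = gr.start[cell]; i < gr.start[cell + 1]; ++i) {
    int e = gr.items[i];
    bary(geo, e, p, lam);
    if (lam[0] >= -tol && lam[1] >= -tol && lam[2] >= -tol && lam[3] >= -tol)
      return e;
  }
  return -1;
}

// [[Rcpp::export]]
IntegerVector cpp_locate_points(NumericMatrix node, IntegerMatrix elem,
                                NumericMatrix pts) {
  TetGeom geo;
  precompute_geom(node, elem, geo);
  LocGrid gr;
  build_grid(node, elem, gr);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    int e = locate(geo, gr, p);
    out[i] = e < 0 ? 0 : e + 1;
  }
  return out;
}

// --------------------------------------------------------- direction updates
static inline void hg_scatter(double g, double d[3], Pcg32 &rng) {
  double ct;
  double u1 = rng.unif(), u2 = rng.unif();
  if (std::fabs(g) < 1e-12) {
    ct = 2.0 * u1 - 1.0;
  } else {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u1);
    ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
  }
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * u2;
  double cp = std::cos(phi), sp = std::sin(phi);
  double dx = d[0], dy = d[1], dz = d[2];
  if (std::fabs(dz) > 0.999999) {
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = ct * (dz > 0 ? 1.0 : -1.0);
  } else {
    double den = std::sqrt(1.0 - dz * dz);
    d[0] = st * (dx * dz * cp - dy * sp) / den + dx * ct;
    d[1] = st * (dy * dz * cp + dx * sp) / den + dy * ct;
    d[2] = -st * cp * den + dz * ct;
  }
  double nn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= nn; d[1] /= nn; d[2] /= nn;
}

// Unpolarized Fresnel reflectance; ci = cos(incidence) > 0.
static inline double fresnel_R(double n1, double n2, double ci) {
  if (n1 == n2) return 0.0;
  double s2 = (n1 / n2) * (n1 / n2) * (1.0 - ci * ci);
  if (s2 >= 1.0) return 1.0; // total internal reflection
  double ct = std::sqrt(1.0 - s2);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// ------------------------------------------------------------- main MC loop
// props: one row per region index 1..L: columns mua, mus, g, n
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix node, IntegerMatrix elem, IntegerVector region,
                IntegerMatrix neighbor, NumericMatrix props, double n_exterior,
                NumericVector src_pos, NumericVector src_dir, int src_type,
                double src_radius, double nphoton, double seed,
                double tstart_ns, double tend_ns, double tstep_ns,
                bool do_reflection, double roulette_threshold,
                double roulette_survival) {
  int ne = elem.nrow(), nn = node.nrow();
  TetGeom geo;
  precompute_geom(node, elem, geo);
  LocGrid gr;
  build_grid(node, elem, gr);

  int ngate = std::max(1, (int)std::ceil((tend_ns - tstart_ns) / tstep_ns - 1e-9));
  NumericMatrix dep(nn, ngate); // sum of w*(1-exp(-mua s))/mua contributions
  double absorbed = 0.0, escaped = 0.0, truncated = 0.0, lost = 0.0;

  Pcg32 rng((uint64_t)seed);

  // orthonormal frame for the disk source
  double sd[3] = {src_dir[0], src_dir[1], src_dir[2]};
  double e1[3], e2[3];
  {
    double ax[3] = {1, 0, 0};
    if (std::fabs(sd[0]) > 0.9) { ax[0] = 0; ax[1] = 1; }
    e1[0] = sd[1] * ax[2] - sd[2] * ax[1];
    e1[1] = sd[2] * ax[0] - sd[0] * ax[2];
    e1[2] = sd[0] * ax[1] - sd[1] * ax[0];
    double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    for (int k = 0; k < 3; ++k) e1[k] /= n1;
    e2[0] = sd[1] * e1[2] - sd[2] * e1[1];
    e2[1] = sd[2] * e1[0] - sd[0] * e1[2];
    e2[2] = sd[0] * e1[1] - sd[1] * e1[0];
  }
  // bbox diagonal bounds the marching distance for outside launches
  double diag = 0.0;
  for (int k = 0; k < 3; ++k) {
    double span = gr.cell[k] * gr.dim[k];
    diag += span * span;
  }
  diag = std::sqrt(diag);
  double march_step = std::min({gr.cell[0], gr.cell[1], gr.cell[2]}) * 0.25;
  if (march_step <= 0) march_step = diag * 1e-3;

  long long nph = (long long)nphoton;
  for (long long iph = 0; iph < nph; ++iph) {
    if ((iph & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    double p[3] = {src_pos[0], src_pos[1], src_pos[2]};
    double d[3] = {sd[0], sd[1], sd[2]};
    if (src_type == 1) { // disk
      double r = src_radius * std::sqrt(rng.unif());
      double phi = 2.0 * M_PI * rng.unif();
      double c = std::cos(phi), s = std::sin(phi);
      for (int k = 0; k < 3; ++k) p[k] += r * (c * e1[k] + s * e2[k]);
    }
    double w = 1.0, t = 0.0;
    int tet = locate(geo, gr, p);
    if (tet < 0) {
      // march along the beam through vacuum until the mesh is entered
      double traveled = 0.0;
      bool found = false;
      while (traveled < 2.0 * diag) {
        traveled += march_step;
        double q[3] = {p[0] + traveled * d[0], p[1] + traveled * d[1],
                       p[2] + traveled * d[2]};
        tet = locate(geo, gr, q);
        if (tet >= 0) {
          // bisect back to the entry point
          double a = traveled - march_step, b = traveled;
          for (int it = 0; it < 40; ++it) {
            double m = 0.5 * (a + b);
            double qm[3] = {p[0] + m * d[0], p[1] + m * d[1], p[2] + m * d[2]};
            int tm = locate(geo, gr, qm);
            if (tm >= 0) { b = m; tet = tm; } else a = m;
          }
          for (int k = 0; k < 3; ++k) p[k] += b * d[k];
          t += b / C_MM_PER_NS; // vacuum flight
          found = true;
          break;
        }
      }
      if (!found) { escaped += w; continue; }
    }

    // dimensionless scattering length to the next interaction
    double sleft = -std::log(rng.unif());
    int stuck = 0;
    bool alive = true;
    while (alive) {
      int reg = region[tet] - 1;
      double mua = props(reg, 0), mus = props(reg, 1);
      double gg = props(reg, 2), nref = props(reg, 3);

      double lam[4], dlam[4];
      bary(geo, tet, p, lam);
      bary_dir(geo, tet, d, dlam);
      double texit = std::numeric_limits<double>::infinity();
      int fexit = -1;
      for (int f = 0; f < 4; ++f) {
        if (dlam[f] < -1e-30) {
          double tf = -lam[f] / dlam[f];
          if (tf < 0) tf = 0;
          if (tf < texit) { texit = tf; fexit = f; }
        }
      }
      if (fexit < 0) { lost += w; break; }

      double s_to_scatter =
          mus > 0 ? sleft / mus : std::numeric_limits<double>::infinity();
      double seg = std::min(texit, s_to_scatter);
      bool scatters = s_to_scatter <= texit;

      // time-gate clipping
      double dt = seg * nref / C_MM_PER_NS;
      bool out_of_time = false;
      if (t + dt > tend_ns) {
        seg = (tend_ns - t) * C_MM_PER_NS / nref;
        if (seg < 0) seg = 0;
        dt = tend_ns - t;
        out_of_time = true;
      }

      // deposit along the segment at its midpoint
      if (seg > 0) {
        double u;
        double x = mua * seg;
        if (x > 1e-8) u = w * (-std::expm1(-x)) / mua;
        else u = w * seg * (1.0 - 0.5 * x);
        double wend = w * std::exp(-x);
        absorbed += w - wend;
        double tmid = t + 0.5 * dt;
        int ig = (int)((tmid - tstart_ns) / tstep_ns);
        if (ig < 0) ig = 0;
        if (ig >= ngate) ig = ngate - 1;
        double half = 0.5 * seg;
        for (int v = 0; v < 4; ++v) {
          double lmid = lam[v] + dlam[v] * half;
          dep(elem(tet, v) - 1, ig) += u * lmid;
        }
        w = wend;
        for (int k = 0; k < 3; ++k) p[k] += seg * d[k];
        t += dt;
        if (mus > 0) sleft -= seg * mus;
        stuck = 0;
      }

      if (out_of_time) { truncated += w; break; }

      if (scatters) {
        hg_scatter(gg, d, rng);
        sleft = -std::log(rng.unif());
        // Russian roulette
        if (w < roulette_threshold) {
          if (rng.unif() < roulette_survival) {
            double wnew = w / roulette_survival;
            absorbed -= (wnew - w);
            w = wnew;
          } else {
            absorbed += w;
            break;
          }
        }
        continue;
      }

      // face crossing
      if (seg <= 0) {
        if (++stuck > 50) { lost += w; break; }
      }
      int nb = neighbor(tet, fexit);
      if (nb == 0) { // domain boundary
        if (do_reflection && nref != n_exterior) {
          double nrm[3];
          face_normal(geo, tet, fexit, nrm);
          double ci = -(d[0] * nrm[0] + d[1] * nrm[1] + d[2] * nrm[2]);
          ci = std::fabs(ci);
          double R = fresnel_R(nref, n_exterior, ci);
          if (rng.unif() < R) { // specular reflection, stay inside
            double dn = d[0] * nrm[0] + d[1] * nrm[1] + d[2] * nrm[2];
            for (int k = 0; k < 3; ++k) d[k] -= 2.0 * dn * nrm[k];
            continue;
          }
        }
        escaped += w;
        break;
      }
      int reg2 = region[nb - 1] - 1;
      double n2 = props(reg2, 3);
      if (do_reflection && n2 != nref) {
        double nrm[3];
        face_normal(geo, tet, fexit, nrm);
        double dn = d[0] * nrm[0] + d[1] * nrm[1] + d[2] * nrm[2];
        double ci = std::fabs(dn);
        double R = fresnel_R(nref, n2, ci);
        if (rng.unif() < R) {
          for (int k = 0; k < 3; ++k) d[k] -= 2.0 * dn * nrm[k];
          continue; // reflected, remain in current tet
        }
        // refract (Snell), normal component rescaled
        double eta = nref / n2;
        double s2 = eta * eta * (1.0 - ci * ci);
        double ct = std::sqrt(std::max(0.0, 1.0 - s2));
        double sgn = dn > 0 ? 1.0 : -1.0;
        for (int k = 0; k < 3; ++k)
          d[k] = eta * d[k] + (ct - eta * ci) * sgn * nrm[k];
        double dd = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
        for (int k = 0; k < 3; ++k) d[k] /= dd;
      }
      tet = nb - 1;
    }
  }

  return List::create(
      _["deposit"] = dep, _["launched"] = (double)nph, _["absorbed"] = absorbed,
      _["escaped"] = escaped, _["truncated"] = truncated, _["lost"] = lost,
      _["ngate"] = ngate);
}
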