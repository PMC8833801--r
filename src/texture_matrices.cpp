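#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique lattice directions at Chebyshev distance 1 (opposite vectors
// identified), the standard 3-D angle set for GLCM/GLRLM.
static const int DIRS[13][3] = {
    {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
    {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
    {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline int vidx(int x, int y, int z, int nx, int ny) {
    return x + nx * (y + (long)ny * z);
}

static inline bool inb(int x, int y, int z, int nx, int ny, int nz) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// levels: 0 outside the mask, 1..ng inside.

// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, int nx, int ny, int nz,
                              int ng) {
    NumericVector out(Dimension(ng, ng, 13));
    for (int d = 0; d < 13; ++d) {
        const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        double* slab = &out[(long)d * ng * ng];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int i = levels[vidx(x, y, z, nx, ny)];
                    if (i == 0) continue;
                    int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                    if (!inb(x2, y2, z2, nx, ny, nz)) continue;
                    int j = levels[vidx(x2, y2, z2, nx, ny)];
                    if (j == 0) continue;
                    // symmetric accumulation
                    slab[(i - 1) + ng * (j - 1)] += 1.0;
                    slab[(j - 1) + ng * (i - 1)] += 1.0;
                }
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector levels, int nx, int ny, int nz,
                               int ng) {
    int lmax = std::max(nx, std::max(ny, nz));
    NumericVector out(Dimension(ng, lmax, 13));
    for (int d = 0; d < 13; ++d) {
        const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
        double* slab = &out[(long)d * ng * lmax];
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    int i = levels[vidx(x, y, z, nx, ny)];
                    if (i == 0) continue;
                    // run start: predecessor absent or different level
                    int xp = x - dx, yp = y - dy, zp = z - dz;
                    if (inb(xp, yp, zp, nx, ny, nz) &&
                        levels[vidx(xp, yp, zp, nx, ny)] == i)
                        continue;
                    int len = 1;
                    int xn = x + dx, yn = y + dy, zn = z + dz;
                    while (inb(xn, yn, zn, nx, ny, nz) &&
                           levels[vidx(xn, yn, zn, nx, ny)] == i) {
                        ++len;
                        xn += dx; yn += dy; zn += dz;
                    }
                    slab[(i - 1) + ng * (len - 1)] += 1.0;
                }
    }
    return out;
}

// Zones of 26-connected equal-level voxels. Returns an nzones x 2 matrix of
// (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, int nx, int ny, int nz) {
    std::vector<char> seen((long)nx * ny * nz, 0);
    std::vector<int> zl, zs;
    std::vector<int> stack;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int v0 = vidx(x, y, z, nx, ny);
                int i = levels[v0];
                if (i == 0 || seen[v0]) continue;
                int size = 0;
                stack.clear();
                stack.push_back(v0);
                seen[v0] = 1;
                while (!stack.empty()) {
                    int v = stack.back();
                    stack.pop_back();
                    ++size;
                    int cx = v % nx, cy = (v / nx) % ny, cz = v / (nx * ny);
                    for (int dz = -1; dz <= 1; ++dz)
                        for (int dy = -1; dy <= 1; ++dy)
                            for (int dx = -1; dx <= 1; ++dx) {
                                if (!dx && !dy && !dz) continue;
                                int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
                                if (!inb(x2, y2, z2, nx, ny, nz)) continue;
                                int v2 = vidx(x2, y2, z2, nx, ny);
                                if (!seen[v2] && levels[v2] == i) {
                                    seen[v2] = 1;
                                    stack.push_back(v2);
                                }
                            }
                }
                zl.push_back(i);
                zs.push_back(size);
            }
    IntegerMatrix out(zl.size(), 2);
    for (size_t k = 0; k < zl.size(); ++k) {
        out(k, 0) = zl[k];
        out(k, 1) = zs[k];
    }
    return out;
}

// NGTDM: per level, count of voxels and summed |i - mean(26-neighbourhood)|.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, int nx, int ny, int nz, int ng) {
    NumericVector n(ng), s(ng);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int i = levels[vidx(x, y, z, nx, ny)];
                if (i == 0) continue;
                double sum = 0.0;
                int cnt = 0;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (!inb(x2, y2, z2, nx, ny, nz)) continue;
                            int j = levels[vidx(x2, y2, z2, nx, ny)];
                            if (j == 0) continue;
                            sum += j;
                            ++cnt;
                        }
                n[i - 1] += 1.0;
                if (cnt > 0) s[i - 1] += std::fabs(i - sum / cnt);
            }
    return List::create(_["n"] = n, _["s"] = s);
}

// GLDM with dependence threshold alpha = 0: dependence of a voxel is
// 1 + number of in-mask 26-neighbours with the same level.
// [[Rcpp::export]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, int nx, int ny, int nz,
                              int ng) {
    NumericMatrix out(ng, 27);
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                int i = levels[vidx(x, y, z, nx, ny)];
                if (i == 0) continue;
                int dep = 1;
                for (int dz = -1; dz <= 1; ++dz)
                    for (int dy = -1; dy <= 1; ++dy)
                        for (int dx = -1; dx <= 1; ++dx) {
                            if (!dx && !dy && !dz) continue;
                            int x2 = x + dx, y2 = y + dy, z2 = z + dz;
                            if (!inb(x2, y2, z2, nx, ny, nz)) continue;
                            if (levels[vidx(x2, y2, z2, nx, ny)] == i) ++dep;
                        }
                out(i - 1, dep - 1) += 1.0;
            }
    return out;
}

// ---------------------------------------------------------------------------
// Surface mesh of a binary mask by marching tetrahedra + Taubin smoothing.
//
// Voxel centres are grid nodes (value 1 inside, 0 outside, implicit zero
// padding); each lattice cell is split into 6 tetrahedra around the 0-6
// diagonal (Kuhn triangulation, face-consistent across cells) and the
// 0.5-isosurface is triangulated with vertices at edge midpoints. The raw
// midpoint mesh carries a large staircase surface-area bias, so vertices are
// relaxed by shrink-free Taubin smoothing before area and enclosed volume
// (divergence theorem) are computed.
// ---------------------------------------------------------------------------
#include <unordered_map>
#include <cstdint>

static const int CUBE[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                               {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
static const int TETS[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                               {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

struct Vec3 {
    double x, y, z;
};
static inline Vec3 vsub(const Vec3& a, const Vec3& b) {
    return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
    return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x};
}
static inline double vdot(const Vec3& a, const Vec3& b) {
    return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vmid(const Vec3& a, const Vec3& b) {
    return {(a.x + b.x) / 2, (a.y + b.y) / 2, (a.z + b.z) / 2};
}

struct MeshBuilder {
    // node id -> padded linear index; vertex keyed by unordered node pair
    std::unordered_map<uint64_t, int> vkey;
    std::vector<Vec3> verts;
    std::vector<int> faces;  // triples of vertex ids

    int midpoint(uint64_t a, uint64_t b, const Vec3& pa, const Vec3& pb) {
        uint64_t key = a < b ? (a << 32) | b : (b << 32) | a;
        auto it = vkey.find(key);
        if (it != vkey.end()) return it->second;
        int id = (int)verts.size();
        verts.push_back(vmid(pa, pb));
        vkey.emplace(key, id);
        return id;
    }

    void add_tri(int a, int b, int c, const Vec3& inside_ref) {
        const Vec3 &v1 = verts[a], &v2 = verts[b], &v3 = verts[c];
        Vec3 n = vcross(vsub(v2, v1), vsub(v3, v1));
        Vec3 cen = {(v1.x + v2.x + v3.x) / 3 - inside_ref.x,
                    (v1.y + v2.y + v3.y) / 3 - inside_ref.y,
                    (v1.z + v2.z + v3.z) / 3 - inside_ref.z};
        if (vdot(n, cen) < 0) std::swap(b, c);  // outward orientation
        faces.push_back(a);
        faces.push_back(b);
        faces.push_back(c);
    }
};

// [[Rcpp::export]]
List cpp_mask_mesh(IntegerVector mask, int nx, int ny, int nz,
                   NumericVector spacing, int smooth_iter = 60,
                   double lambda = 0.5, double nu = 0.53) {
    const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
    const uint64_t pnx = nx + 2, pny = ny + 2;
    MeshBuilder mb;
    // cells span nodes (x..x+1, y..y+1, z..z+1) with x in [-1, nx-1]
    for (int z = -1; z < nz; ++z)
        for (int y = -1; y < ny; ++y)
            for (int x = -1; x < nx; ++x) {
                bool in[8];
                int ninside = 0;
                uint64_t nid[8];
                Vec3 pc[8];
                for (int c = 0; c < 8; ++c) {
                    int cx = x + CUBE[c][0], cy = y + CUBE[c][1],
                        cz = z + CUBE[c][2];
                    in[c] = inb(cx, cy, cz, nx, ny, nz) &&
                            mask[vidx(cx, cy, cz, nx, ny)] != 0;
                    if (in[c]) ++ninside;
                    nid[c] = (uint64_t)(cx + 1) +
                             pnx * ((uint64_t)(cy + 1) + pny * (uint64_t)(cz + 1));
                    pc[c] = {cx * sx, cy * sy, cz * sz};
                }
                if (ninside == 0 || ninside == 8) continue;
                for (int t = 0; t < 6; ++t) {
                    int ins[4], outs[4], ni = 0, no = 0;
                    for (int k = 0; k < 4; ++k) {
                        int c = TETS[t][k];
                        if (in[c]) ins[ni++] = c; else outs[no++] = c;
                    }
                    if (ni == 0 || ni == 4) continue;
                    Vec3 ref = {0, 0, 0};
                    for (int k = 0; k < ni; ++k) {
                        ref.x += pc[ins[k]].x;
                        ref.y += pc[ins[k]].y;
                        ref.z += pc[ins[k]].z;
                    }
                    ref.x /= ni; ref.y /= ni; ref.z /= ni;
                    if (ni == 1) {
                        int a = mb.midpoint(nid[ins[0]], nid[outs[0]], pc[ins[0]], pc[outs[0]]);
                        int b = mb.midpoint(nid[ins[0]], nid[outs[1]], pc[ins[0]], pc[outs[1]]);
                        int c = mb.midpoint(nid[ins[0]], nid[outs[2]], pc[ins[0]], pc[outs[2]]);
                        mb.add_tri(a, b, c, ref);
                    } else if (ni == 3) {
                        int a = mb.midpoint(nid[outs[0]], nid[ins[0]], pc[outs[0]], pc[ins[0]]);
                        int b = mb.midpoint(nid[outs[0]], nid[ins[1]], pc[outs[0]], pc[ins[1]]);
                        int c = mb.midpoint(nid[outs[0]], nid[ins[2]], pc[outs[0]], pc[ins[2]]);
                        mb.add_tri(a, b, c, ref);
                    } else {  // ni == 2: quad split into two triangles
                        int q0 = mb.midpoint(nid[ins[0]], nid[outs[0]], pc[ins[0]], pc[outs[0]]);
                        int q1 = mb.midpoint(nid[ins[0]], nid[outs[1]], pc[ins[0]], pc[outs[1]]);
                        int q2 = mb.midpoint(nid[ins[1]], nid[outs[1]], pc[ins[1]], pc[outs[1]]);
                        int q3 = mb.midpoint(nid[ins[1]], nid[outs[0]], pc[ins[1]], pc[outs[0]]);
                        mb.add_tri(q0, q1, q2, ref);
                        mb.add_tri(q0, q2, q3, ref);
                    }
                }
            }

    const int nv = (int)mb.verts.size();
    const int nf = (int)mb.faces.size() / 3;

    // CSR vertex adjacency from face edges. In the closed manifold mesh every
    // neighbouring vertex appears exactly twice (once per shared triangle),
    // so the duplicated entries leave the umbrella mean unchanged.
    std::vector<int> deg(nv + 1, 0);
    for (int f = 0; f < nf; ++f) {
        deg[mb.faces[3 * f] + 1] += 2;
        deg[mb.faces[3 * f + 1] + 1] += 2;
        deg[mb.faces[3 * f + 2] + 1] += 2;
    }
    for (int v = 0; v < nv; ++v) deg[v + 1] += deg[v];
    std::vector<int> adj(deg[nv]);
    std::vector<int> fill(deg.begin(), deg.end() - 1);
    for (int f = 0; f < nf; ++f) {
        int a = mb.faces[3 * f], b = mb.faces[3 * f + 1], c = mb.faces[3 * f + 2];
        adj[fill[a]++] = b; adj[fill[a]++] = c;
        adj[fill[b]++] = a; adj[fill[b]++] = c;
        adj[fill[c]++] = a; adj[fill[c]++] = b;
    }

    // Taubin lambda|mu smoothing (mu = -nu), shrink-compensated
    std::vector<Vec3> cur = mb.verts, nxt(nv);
    for (int it = 0; it < smooth_iter; ++it) {
        for (int pass = 0; pass < 2; ++pass) {
            double f = pass == 0 ? lambda : -nu;
            for (int v = 0; v < nv; ++v) {
                int lo = deg[v], hi = deg[v + 1];
                if (lo == hi) { nxt[v] = cur[v]; continue; }
                Vec3 m = {0, 0, 0};
                for (int e = lo; e < hi; ++e) {
                    const Vec3& w = cur[adj[e]];
                    m.x += w.x; m.y += w.y; m.z += w.z;
                }
                double k = (double)(hi - lo);
                nxt[v] = {cur[v].x + f * (m.x / k - cur[v].x),
                          cur[v].y + f * (m.y / k - cur[v].y),
                          cur[v].z + f * (m.z / k - cur[v].z)};
            }
            cur.swap(nxt);
        }
    }

    double area = 0.0, vol6 = 0.0;
    for (int f = 0; f < nf; ++f) {
        const Vec3 &v1 = cur[mb.faces[3 * f]], &v2 = cur[mb.faces[3 * f + 1]],
                   &v3 = cur[mb.faces[3 * f + 2]];
        Vec3 n = vcross(vsub(v2, v1), vsub(v3, v1));
        area += 0.5 * std::sqrt(vdot(n, n));
        vol6 += vdot(v1, vcross(v2, v3));
    }
    return List::create(_["surface_area"] = area,
                        _["mesh_volume"] = std::fabs(vol6) / 6.0,
                        _["n_vertices"] = nv, _["n_faces"] = nf);
}

// Largest pairwise Euclidean distance among rows of a coordinate matrix.
// [[Rcpp::export]]
double cpp_max_pairwise(NumericMatrix pts) {
    const int n = pts.nrow();
    double best = 0.0;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
            double dx = pts(i, 0) - pts(j, 0);
            double dy = pts(i, 1) - pts(j, 1);
            double dz = pts(i, 2) - pts(j, 2);
            double d = dx * dx + dy * dy + dz * dz;
            if (d > best) best = d;
        }
    return std::sqrt(best);
}

// ---------------------------------------------------------------------------
// Weighted-lasso cyclic coordinate descent on the Gram formulation.
// Minimises ||y - X b||^2 / (2n) + lambda * sum_j w_j |b_j| given
// G = X'X / n and xty = X'y / n; columns with non-finite weight are pinned
// at zero. Solutions are computed along a decreasing lambda grid with warm
// starts. Returns a p x nlambda matrix.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_cd_lasso_path(NumericMatrix G, NumericVector xty,
                                NumericVector w, NumericVector lambdas,
                                double tol = 1e-10, int maxit = 100000) {
    const int p = G.nrow(), nl = lambdas.size();
    NumericMatrix out(p, nl);
    std::vector<double> beta(p, 0.0);
    for (int l = 0; l < nl; ++l) {
        const double lam = lambdas[l];
        for (int it = 0; it < maxit; ++it) {
            double delta = 0.0;
            for (int j = 0; j < p; ++j) {
                if (!std::isfinite(w[j])) { beta[j] = 0.0; continue; }
                double gj = G(j, j);
                if (gj <= 0) { beta[j] = 0.0; continue; }
                double z = xty[j] + gj * beta[j];
                for (int k = 0; k < p; ++k) z -= G(j, k) * beta[k];
                double t = lam * w[j];
                double b = 0.0;
                if (z > t) b = (z - t) / gj;
                else if (z < -t) b = (z + t) / gj;
                double d = std::fabs(b - beta[j]);
                if (d > delta) delta = d;
                beta[j] = b;
            }
            if (delta < tol) break;
        }
        for (int j = 0; j < p; ++j) out(j, l) = beta[j];
    }
    return out;
}
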