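// Geometry, elastic energy and force kernels for the closed-shell vertex
// model.  Cells are polygons given as cyclic vertex lists with consistent
// outward winding.  Per-cell quantities follow the fan construction: the
// cell center is the vertex mean, the cell is triangulated as
// (center, v_i, v_{i+1}), the cell area is the sum of fan-triangle areas
// and the cell normal is the (normalized) area-weighted mean of the fan
// triangle normals, which reduces to the polygon vector area
// sum_i R_i x R_{i+1} because the center is the vertex mean.
//
// Energy: E = sum_c K/2 (A_c - A0)^2 + sum_b Lambda L_b
//           + sum_c Gamma/2 P_c^2 + sum_b beta/2 theta_b^2
// Active energy (virtual-work construction, gradient taken at fixed
// nematic): E_act = zeta/2 sum_c sum_{v in c} r_v . Q3_c r_v with
// r_v = R_v - R_c and Q3_c the cell's traceless in-plane nematic tensor
// embedded in 3D.  Forces are exact analytic gradients of these
// expressions (checked against finite differences in the test suite).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// theta / sin(theta), stable near 0
inline double theta_over_sin(double theta) {
  if (theta < 1e-4) return 1.0 + theta * theta / 6.0;
  return theta / std::sin(theta);
}

}  // namespace

// [[Rcpp::export]]
List vm_forces_cpp(NumericMatrix pos, IntegerVector cell_vert,
                   IntegerVector cell_ptr, IntegerMatrix bond_verts,
                   IntegerMatrix bond_cells, double K, double A0,
                   double Lambda, double Gamma, double beta,
                   NumericMatrix q3, double zeta, bool want_forces) {
  const int nv = pos.nrow();
  const int nc = cell_ptr.size() - 1;
  const int nb = bond_verts.nrow();
  const bool active = (zeta != 0.0) && (q3.nrow() == nc);

  NumericVector areas(nc), perims(nc);
  NumericMatrix centers(nc, 3), normals(nc, 3);
  NumericVector wnorm(nc);
  double volume = 0.0;

  std::vector<double> P(3 * nv);
  for (int i = 0; i < nv; ++i) {
    P[3 * i] = pos(i, 0);
    P[3 * i + 1] = pos(i, 1);
    P[3 * i + 2] = pos(i, 2);
  }

  // ---- pass 1: per-cell geometry --------------------------------------
  for (int c = 0; c < nc; ++c) {
    const int s = cell_ptr[c], e = cell_ptr[c + 1];
    const int m = e - s;
    double C[3] = {0, 0, 0};
    for (int k = s; k < e; ++k) {
      const double* R = &P[3 * cell_vert[k]];
      C[0] += R[0]; C[1] += R[1]; C[2] += R[2];
    }
    C[0] /= m; C[1] /= m; C[2] /= m;
    centers(c, 0) = C[0]; centers(c, 1) = C[1]; centers(c, 2) = C[2];

    double A = 0.0, Pc = 0.0, W[3] = {0, 0, 0};
    for (int k = 0; k < m; ++k) {
      const double* Ri = &P[3 * cell_vert[s + k]];
      const double* Rj = &P[3 * cell_vert[s + (k + 1) % m]];
      double e1[3] = {Ri[0] - C[0], Ri[1] - C[1], Ri[2] - C[2]};
      double e2[3] = {Rj[0] - C[0], Rj[1] - C[1], Rj[2] - C[2]};
      double cr[3], crij[3];
      cross3(e1, e2, cr);
      A += 0.5 * norm3(cr);
      cross3(Ri, Rj, crij);
      W[0] += crij[0]; W[1] += crij[1]; W[2] += crij[2];
      volume += dot3(C, crij) / 6.0;
      double d[3] = {Rj[0] - Ri[0], Rj[1] - Ri[1], Rj[2] - Ri[2]};
      Pc += norm3(d);
    }
    areas[c] = A;
    perims[c] = Pc;
    double wn = norm3(W);
    wnorm[c] = wn;
    if (wn < 1e-14) stop("degenerate cell %d: vanishing vector area", c + 1);
    normals(c, 0) = W[0] / wn;
    normals(c, 1) = W[1] / wn;
    normals(c, 2) = W[2] / wn;
  }

  // ---- bonds: tension + bending ---------------------------------------
  double E_area = 0.0, E_perim = 0.0, E_tension = 0.0, E_bend = 0.0,
         E_act = 0.0;
  for (int c = 0; c < nc; ++c) {
    double da = areas[c] - A0;
    E_area += 0.5 * K * da * da;
    E_perim += 0.5 * Gamma * perims[c] * perims[c];
  }

  NumericVector blen(nb), theta(nb);
  // accumulated (dE/du_b) * N_other per cell, for bending gradients
  std::vector<double> sacc(3 * nc, 0.0);
  double minb = R_PosInf;
  for (int b = 0; b < nb; ++b) {
    const double* R1 = &P[3 * bond_verts(b, 0)];
    const double* R2 = &P[3 * bond_verts(b, 1)];
    double d[3] = {R2[0] - R1[0], R2[1] - R1[1], R2[2] - R1[2]};
    double L = norm3(d);
    blen[b] = L;
    if (L < minb) minb = L;
    E_tension += Lambda * L;
    const int c1 = bond_cells(b, 0), c2 = bond_cells(b, 1);
    double u = normals(c1, 0) * normals(c2, 0) +
               normals(c1, 1) * normals(c2, 1) +
               normals(c1, 2) * normals(c2, 2);
    if (u > 1.0) u = 1.0;
    if (u < -1.0) u = -1.0;
    double th = std::acos(u);
    theta[b] = th;
    E_bend += 0.5 * beta * th * th;
    if (want_forces && beta != 0.0) {
      double dEdu = -beta * theta_over_sin(th);
      for (int x = 0; x < 3; ++x) {
        sacc[3 * c1 + x] += dEdu * normals(c2, x);
        sacc[3 * c2 + x] += dEdu * normals(c1, x);
      }
    }
  }

  NumericMatrix grad(want_forces ? nv : 0, want_forces ? 3 : 0);
  NumericMatrix volgrad(want_forces ? nv : 0, want_forces ? 3 : 0);

  if (want_forces) {
    // bond tension gradient
    if (Lambda != 0.0) {
      for (int b = 0; b < nb; ++b) {
        const int v1 = bond_verts(b, 0), v2 = bond_verts(b, 1);
        const double* R1 = &P[3 * v1];
        const double* R2 = &P[3 * v2];
        double L = blen[b];
        if (L < 1e-14) continue;
        for (int x = 0; x < 3; ++x) {
          double u = (R2[x] - R1[x]) / L;
          grad(v1, x) -= Lambda * u;
          grad(v2, x) += Lambda * u;
        }
      }
    }

    // ---- pass 2: per-cell gradients ------------------------------------
    for (int c = 0; c < nc; ++c) {
      const int s = cell_ptr[c], e = cell_ptr[c + 1];
      const int m = e - s;
      double C[3] = {centers(c, 0), centers(c, 1), centers(c, 2)};
      const double coefA = K * (areas[c] - A0);
      const double coefP = Gamma * perims[c];
      // bending helper m_c = (I - N N^T) s_c / |W|
      double N[3] = {normals(c, 0), normals(c, 1), normals(c, 2)};
      double mb[3] = {0, 0, 0};
      if (beta != 0.0) {
        double ns = N[0] * sacc[3 * c] + N[1] * sacc[3 * c + 1] +
                    N[2] * sacc[3 * c + 2];
        for (int x = 0; x < 3; ++x)
          mb[x] = (sacc[3 * c + x] - ns * N[x]) / wnorm[c];
      }
      // active tensor (symmetric, 3x3), scaled by zeta
      double Q[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      if (active) {
        Q[0] = zeta * q3(c, 0);  // xx
        Q[4] = zeta * q3(c, 1);  // yy
        Q[8] = zeta * q3(c, 2);  // zz
        Q[1] = Q[3] = zeta * q3(c, 3);  // xy
        Q[2] = Q[6] = zeta * q3(c, 4);  // xz
        Q[5] = Q[7] = zeta * q3(c, 5);  // yz
      }

      double gcA[3] = {0, 0, 0}, gcV[3] = {0, 0, 0};
      for (int k = 0; k < m; ++k) {
        const int vi = cell_vert[s + k];
        const int vj = cell_vert[s + (k + 1) % m];
        const double* Ri = &P[3 * vi];
        const double* Rj = &P[3 * vj];
        double e1[3] = {Ri[0] - C[0], Ri[1] - C[1], Ri[2] - C[2]};
        double e2[3] = {Rj[0] - C[0], Rj[1] - C[1], Rj[2] - C[2]};
        double cr[3];
        cross3(e1, e2, cr);
        double a2 = norm3(cr);  // 2 * triangle area
        if (a2 > 1e-14) {
          double nt[3] = {cr[0] / a2, cr[1] / a2, cr[2] / a2};
          double dAi[3], dAj[3];
          cross3(e2, nt, dAi);
          cross3(nt, e1, dAj);
          for (int x = 0; x < 3; ++x) {
            dAi[x] *= 0.5;
            dAj[x] *= 0.5;
            grad(vi, x) += coefA * dAi[x];
            grad(vj, x) += coefA * dAj[x];
            gcA[x] -= coefA * (dAi[x] + dAj[x]);
          }
        }
        // volume gradient (fan tetrahedra from origin)
        double gi[3], gj[3], gc[3];
        cross3(Rj, C, gi);
        cross3(C, Ri, gj);
        cross3(Ri, Rj, gc);
        for (int x = 0; x < 3; ++x) {
          volgrad(vi, x) += gi[x] / 6.0;
          volgrad(vj, x) += gj[x] / 6.0;
          gcV[x] += gc[x] / 6.0;
        }
      }
      // cycle terms: perimeter, bending, active
      for (int k = 0; k < m; ++k) {
        const int v = cell_vert[s + k];
        const int vp = cell_vert[s + (k + m - 1) % m];
        const int vn = cell_vert[s + (k + 1) % m];
        const double* Rv = &P[3 * v];
        const double* Rp = &P[3 * vp];
        const double* Rn = &P[3 * vn];
        if (Gamma != 0.0) {
          double d1[3] = {Rv[0] - Rp[0], Rv[1] - Rp[1], Rv[2] - Rp[2]};
          double d2[3] = {Rv[0] - Rn[0], Rv[1] - Rn[1], Rv[2] - Rn[2]};
          double L1 = norm3(d1), L2 = norm3(d2);
          for (int x = 0; x < 3; ++x)
            grad(v, x) += coefP * (d1[x] / (L1 > 1e-14 ? L1 : 1.0) +
                                   d2[x] / (L2 > 1e-14 ? L2 : 1.0));
        }
        if (beta != 0.0) {
          double dnp[3] = {Rn[0] - Rp[0], Rn[1] - Rp[1], Rn[2] - Rp[2]};
          double g[3];
          cross3(dnp, mb, g);
          grad(v, 0) += g[0];
          grad(v, 1) += g[1];
          grad(v, 2) += g[2];
        }
        if (active) {
          double r[3] = {Rv[0] - C[0], Rv[1] - C[1], Rv[2] - C[2]};
          double qr[3] = {Q[0] * r[0] + Q[1] * r[1] + Q[2] * r[2],
                          Q[3] * r[0] + Q[4] * r[1] + Q[5] * r[2],
                          Q[6] * r[0] + Q[7] * r[1] + Q[8] * r[2]};
          E_act += 0.5 * dot3(r, qr);
          grad(v, 0) += qr[0];
          grad(v, 1) += qr[1];
          grad(v, 2) += qr[2];
        }
      }
      // distribute center gradients over the cell vertices
      for (int k = 0; k < m; ++k) {
        const int v = cell_vert[s + k];
        for (int x = 0; x < 3; ++x) {
          grad(v, x) += gcA[x] / m;
          volgrad(v, x) += gcV[x] / m;
        }
      }
    }
    // flip sign: forces = -dE/dR
    for (int i = 0; i < nv; ++i)
      for (int x = 0; x < 3; ++x) grad(i, x) = -grad(i, x);
  } else if (active) {
    // energy only
    for (int c = 0; c < nc; ++c) {
      const int s = cell_ptr[c], e = cell_ptr[c + 1];
      const int m = e - s;
      double C[3] = {centers(c, 0), centers(c, 1), centers(c, 2)};
      double Q[9];
      Q[0] = zeta * q3(c, 0); Q[4] = zeta * q3(c, 1); Q[8] = zeta * q3(c, 2);
      Q[1] = Q[3] = zeta * q3(c, 3);
      Q[2] = Q[6] = zeta * q3(c, 4);
      Q[5] = Q[7] = zeta * q3(c, 5);
      for (int k = 0; k < m; ++k) {
        const double* Rv = &P[3 * cell_vert[s + k]];
        double r[3] = {Rv[0] - C[0], Rv[1] - C[1], Rv[2] - C[2]};
        double qr[3] = {Q[0] * r[0] + Q[1] * r[1] + Q[2] * r[2],
                        Q[3] * r[0] + Q[4] * r[1] + Q[5] * r[2],
                        Q[6] * r[0] + Q[7] * r[1] + Q[8] * r[2]};
        E_act += 0.5 * dot3(r, qr);
      }
    }
  }

  List out = List::create(
      _["E_elastic"] = E_area + E_perim + E_tension + E_bend,
      _["E_area"] = E_area, _["E_perimeter"] = E_perim,
      _["E_tension"] = E_tension, _["E_bend"] = E_bend,
      _["E_active"] = E_act, _["volume"] = volume, _["areas"] = areas,
      _["perimeters"] = perims, _["centers"] = centers,
      _["normals"] = normals, _["bond_lengths"] = blen,
      _["dihedrals"] = theta, _["min_bond"] = minb);
  if (want_forces) {
    out["forces"] = grad;
    out["volgrad"] = volgrad;
  }
  return out;
}

// [[Rcpp::export]]
double vm_volume_cpp(NumericMatrix pos, IntegerVector cell_vert,
                     IntegerVector cell_ptr) {
  const int nc = cell_ptr.size() - 1;
  double volume = 0.0;
  for (int c = 0; c < nc; ++c) {
    const int s = cell_ptr[c], e = cell_ptr[c + 1];
    const int m = e - s;
    double C[3] = {0, 0, 0};
    for (int k = s; k < e; ++k) {
      C[0] += pos(cell_vert[k], 0);
      C[1] += pos(cell_vert[k], 1);
      C[2] += pos(cell_vert[k], 2);
    }
    C[0] /= m; C[1] /= m; C[2] /= m;
    for (int k = 0; k < m; ++k) {
      const int vi = cell_vert[s + k];
      const int vj = cell_vert[s + (k + 1) % m];
      double crij[3] = {
        pos(vi, 1) * pos(vj, 2) - pos(vi, 2) * pos(vj, 1),
        pos(vi, 2) * pos(vj, 0) - pos(vi, 0) * pos(vj, 2),
        pos(vi, 0) * pos(vj, 1) - pos(vi, 1) * pos(vj, 0)};
      volume += (C[0] * crij[0] + C[1] * crij[1] + C[2] * crij[2]) / 6.0;
    }
  }
  return volume;
}
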