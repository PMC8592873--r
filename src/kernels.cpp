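#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Per-frame residue centers of mass plus, per residue pair, (i) the count
// of frames whose minimum heavy-atom distance is within `cutoff` and
// (ii) first/second moments of the center-center distance series.
//
// xyz: F x 3A matrix, frame rows, (x1,y1,z1,x2,...) columns.
// res_index: 1-based residue id per atom (contiguous 1..R).
// mass: per-atom masses for the center of mass.
// [[Rcpp::export]]
List cpp_pair_stats(NumericMatrix xyz, IntegerVector res_index,
                    NumericVector mass, double cutoff) {
  const int F = xyz.nrow();
  const int A = res_index.size();
  if (xyz.ncol() != 3 * A) stop("xyz/res_index size mismatch");
  int R = 0;
  for (int a = 0; a < A; ++a) R = std::max(R, res_index[a]);
  std::vector< std::vector<int> > members(R);
  for (int a = 0; a < A; ++a) members[res_index[a] - 1].push_back(a);
  std::vector<double> rmass(R, 0.0);
  for (int r = 0; r < R; ++r) {
    for (size_t k = 0; k < members[r].size(); ++k)
      rmass[r] += mass[members[r][k]];
    if (rmass[r] <= 0) stop("residue with zero total mass (no heavy atoms?)");
  }
  const double cut2 = cutoff * cutoff;

  NumericMatrix occ(R, R), sumd(R, R), sumd2(R, R);
  NumericMatrix centers(F, 3 * R);
  std::vector<double> cx(R), cy(R), cz(R), rad(R);

  for (int f = 0; f < F; ++f) {
    const double *row = &xyz(f, 0);
    // centers of mass and bounding radii
    for (int r = 0; r < R; ++r) {
      double sx = 0, sy = 0, sz = 0;
      for (size_t k = 0; k < members[r].size(); ++k) {
        const int a = members[r][k];
        const double m = mass[a];
        sx += m * xyz(f, 3 * a);
        sy += m * xyz(f, 3 * a + 1);
        sz += m * xyz(f, 3 * a + 2);
      }
      cx[r] = sx / rmass[r]; cy[r] = sy / rmass[r]; cz[r] = sz / rmass[r];
      double mr = 0;
      for (size_t k = 0; k < members[r].size(); ++k) {
        const int a = members[r][k];
        const double dx = xyz(f, 3 * a) - cx[r];
        const double dy = xyz(f, 3 * a + 1) - cy[r];
        const double dz = xyz(f, 3 * a + 2) - cz[r];
        mr = std::max(mr, dx * dx + dy * dy + dz * dz);
      }
      rad[r] = std::sqrt(mr);
      centers(f, 3 * r) = cx[r];
      centers(f, 3 * r + 1) = cy[r];
      centers(f, 3 * r + 2) = cz[r];
    }
    (void)row;
    for (int i = 0; i < R; ++i) {
      for (int j = i + 1; j < R; ++j) {
        const double dx = cx[i] - cx[j], dy = cy[i] - cy[j], dz = cz[i] - cz[j];
        const double dc = std::sqrt(dx * dx + dy * dy + dz * dz);
        sumd(i, j) += dc;
        sumd2(i, j) += dc * dc;
        // a contact is impossible if even the closest conceivable atom
        // pair (centers minus bounding radii) exceeds the cutoff
        if (dc - rad[i] - rad[j] > cutoff) continue;
        double best = R_PosInf;
        for (size_t p = 0; p < members[i].size() && best > cut2; ++p) {
          const int a = members[i][p];
          const double ax = xyz(f, 3 * a), ay = xyz(f, 3 * a + 1),
                       az = xyz(f, 3 * a + 2);
          for (size_t q = 0; q < members[j].size(); ++q) {
            const int b = members[j][q];
            const double bx = ax - xyz(f, 3 * b), by = ay - xyz(f, 3 * b + 1),
                         bz = az - xyz(f, 3 * b + 2);
            const double d2 = bx * bx + by * by + bz * bz;
            if (d2 < best) best = d2;
          }
        }
        if (best <= cut2) occ(i, j) += 1.0;
      }
    }
  }
  for (int i = 0; i < R; ++i) {
    for (int j = i + 1; j < R; ++j) {
      occ(j, i) = occ(i, j);
      sumd(j, i) = sumd(i, j);
      sumd2(j, i) = sumd2(i, j);
    }
  }
  return List::create(_["contact_count"] = occ, _["sum_d"] = sumd,
                      _["sum_d2"] = sumd2, _["centers"] = centers);
}

// Shrake-Rupley SASA with a deterministic golden-spiral point set.
// The point set is expressed in a local frame built from each atom's two
// nearest neighbours, so the computed areas are exactly invariant under
// rigid motion of the whole structure.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  const int A = coords.nrow();
  if (coords.ncol() != 3) stop("coords must be A x 3");
  // unit sphere golden spiral
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double phi = ga * k;
    sx[k] = r * std::cos(phi); sy[k] = r * std::sin(phi); sz[k] = z;
  }
  NumericVector out(A);
  double maxr = 0;
  for (int a = 0; a < A; ++a) maxr = std::max(maxr, radii[a]);

  for (int i = 0; i < A; ++i) {
    const double ri = radii[i] + probe;
    // neighbour list
    std::vector<int> nb;
    double d1 = R_PosInf, d2 = R_PosInf;
    int n1 = -1, n2 = -1;
    for (int j = 0; j < A; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - coords(i, 0);
      const double dy = coords(j, 1) - coords(i, 1);
      const double dz = coords(j, 2) - coords(i, 2);
      const double d2j = dx * dx + dy * dy + dz * dz;
      const double reach = ri + radii[j] + probe;
      if (d2j < reach * reach) nb.push_back(j);
      // nearest-two selection with a relative tolerance so that exact
      // ties resolve by atom index, stable under rigid motion
      const double tol = 1e-9;
      if (d2j < d1 * (1.0 - tol)) { d2 = d1; n2 = n1; d1 = d2j; n1 = j; }
      else if (d2j < d2 * (1.0 - tol)) { d2 = d2j; n2 = j; }
    }
    // local orthonormal frame from the two nearest neighbours
    double e1[3] = {1, 0, 0}, e2[3] = {0, 1, 0}, e3[3] = {0, 0, 1};
    if (n1 >= 0) {
      double v1[3] = {coords(n1, 0) - coords(i, 0),
                      coords(n1, 1) - coords(i, 1),
                      coords(n1, 2) - coords(i, 2)};
      double nv = std::sqrt(v1[0] * v1[0] + v1[1] * v1[1] + v1[2] * v1[2]);
      if (nv > 1e-12) {
        for (int k = 0; k < 3; ++k) e1[k] = v1[k] / nv;
        bool have2 = false;
        if (n2 >= 0) {
          double v2[3] = {coords(n2, 0) - coords(i, 0),
                          coords(n2, 1) - coords(i, 1),
                          coords(n2, 2) - coords(i, 2)};
          const double dot = v2[0] * e1[0] + v2[1] * e1[1] + v2[2] * e1[2];
          double w[3] = {v2[0] - dot * e1[0], v2[1] - dot * e1[1],
                         v2[2] - dot * e1[2]};
          const double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
          if (nw > 1e-8) {
            for (int k = 0; k < 3; ++k) e2[k] = w[k] / nw;
            have2 = true;
          }
        }
        if (!have2) {
          // collinear/lone neighbour: any vector orthogonal to e1
          double axis[3] = {0, 0, 0};
          axis[std::fabs(e1[0]) < 0.9 ? 0 : 1] = 1.0;
          const double dot = axis[0] * e1[0] + axis[1] * e1[1] + axis[2] * e1[2];
          double w[3] = {axis[0] - dot * e1[0], axis[1] - dot * e1[1],
                         axis[2] - dot * e1[2]};
          const double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
          for (int k = 0; k < 3; ++k) e2[k] = w[k] / nw;
        }
        e3[0] = e1[1] * e2[2] - e1[2] * e2[1];
        e3[1] = e1[2] * e2[0] - e1[0] * e2[2];
        e3[2] = e1[0] * e2[1] - e1[1] * e2[0];
      }
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double px = coords(i, 0) + ri * (sx[k] * e1[0] + sy[k] * e2[0] + sz[k] * e3[0]);
      const double py = coords(i, 1) + ri * (sx[k] * e1[1] + sy[k] * e2[1] + sz[k] * e3[1]);
      const double pz = coords(i, 2) + ri * (sx[k] * e1[2] + sy[k] * e2[2] + sz[k] * e3[2]);
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double rj = radii[j] + probe;
        const double dx = px - coords(j, 0), dy = py - coords(j, 1),
                     dz = pz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * ((double)acc / n_points);
  }
  return out;
}
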