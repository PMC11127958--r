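#include <Rcpp.h>
using namespace Rcpp;

// Pairwise 12-6 sum between two atom sets. A and B are n1 x n2 matrices of
// pair constants (kcal A^6/mol, kcal A^12/mol). Coincident atoms (r^2 below
// 1e-12) contribute a large finite repulsion so optimizer trajectories stay
// finite; the R-level API raises a domain error before reaching that regime.
// [[Rcpp::export]]
double cpp_lj_pair_sum(NumericMatrix x1, NumericMatrix x2,
                       NumericMatrix a, NumericMatrix b) {
  const int n1 = x1.nrow(), n2 = x2.nrow();
  double e = 0.0;
  for (int i = 0; i < n1; ++i) {
    const double xi = x1(i, 0), yi = x1(i, 1), zi = x1(i, 2);
    for (int j = 0; j < n2; ++j) {
      const double dx = xi - x2(j, 0);
      const double dy = yi - x2(j, 1);
      const double dz = zi - x2(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-12) { e += 1e10; continue; }
      const double ir6 = 1.0 / (r2 * r2 * r2);
      e += (-a(i, j) + b(i, j) * ir6) * ir6;
    }
  }
  return e;
}

// Continuum plane term: sum over atoms of eta*pi*(-A/(2 z^4) + B/(5 z^10)).
// [[Rcpp::export]]
double cpp_lj_plane_sum(NumericVector z, NumericVector a, NumericVector b,
                        double eta) {
  const int n = z.size();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    const double z2 = z[i] * z[i];
    const double iz4 = 1.0 / (z2 * z2);
    e += -0.5 * a[i] * iz4 + 0.2 * b[i] * iz4 * iz4 / z2;
  }
  return e * eta * M_PI;
}

// Continuum sphere term for atoms at center distances r (all > radius).
// [[Rcpp::export]]
double cpp_lj_sphere_sum(NumericVector r, NumericVector a, NumericVector b,
                         double radius, double eta) {
  const int n = r.size();
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    const double dm = radius - r[i], dp = radius + r[i];
    const double im2 = 1.0 / (dm * dm), ip2 = 1.0 / (dp * dp);
    const double im4 = im2 * im2, ip4 = ip2 * ip2;
    const double im10 = im4 * im4 * im2, ip10 = ip4 * ip4 * ip2;
    e += (radius / r[i]) *
         (-0.5 * a[i] * (im4 - ip4) + 0.2 * b[i] * (im10 - ip10));
  }
  return e * eta * M_PI;
}

// Evaluate a whole GA population of 5n-variable pose vectors.
// xc: stacked centered coordinates of all molecules (sum n_i x 3)
// starts/counts: row offsets (0-based) and atom counts per molecule
// com0: n_mol x 3 default centers of mass
// pair_a/pair_b: stacked pair-constant matrices, one per unordered molecule
//   pair in combn(n, 2) column order, each of size counts[i] x counts[j];
//   pair_off gives the element offset of each block in pair_a/pair_b
// carr_a/carr_b: per-atom constants against the carrier carbon (aligned with
//   xc rows); ignored when carrier_type == 0
// carrier_type: 0 none, 1 plane (z = 0), 2 sphere at origin
// [[Rcpp::export]]
NumericVector cpp_eval_population(NumericMatrix v, NumericMatrix xc,
                                  IntegerVector starts, IntegerVector counts,
                                  NumericMatrix com0,
                                  NumericVector pair_a, NumericVector pair_b,
                                  IntegerVector pair_off,
                                  NumericVector carr_a, NumericVector carr_b,
                                  int carrier_type, double eta, double radius,
                                  double clearance) {
  const int pop = v.nrow();
  const int nmol = starts.size();
  const int ntot = xc.nrow();
  NumericVector out(pop);
  std::vector<double> px(ntot), py(ntot), pz(ntot);

  for (int s = 0; s < pop; ++s) {
    // pose all molecules
    for (int m = 0; m < nmol; ++m) {
      const double tx = v(s, 5 * m), ty = v(s, 5 * m + 1), tz = v(s, 5 * m + 2);
      const double ax = v(s, 5 * m + 3) * M_PI / 180.0;
      const double ay = v(s, 5 * m + 4) * M_PI / 180.0;
      const double cx = std::cos(ax), sx = std::sin(ax);
      const double cy = std::cos(ay), sy = std::sin(ay);
      // R = Ry(ay) * Rx(ax)
      const double r11 = cy, r12 = sy * sx, r13 = sy * cx;
      const double r21 = 0.0, r22 = cx, r23 = -sx;
      const double r31 = -sy, r32 = cy * sx, r33 = cy * cx;
      const double ox = com0(m, 0) + tx, oy = com0(m, 1) + ty,
                   oz = com0(m, 2) + tz;
      for (int k = 0; k < counts[m]; ++k) {
        const int row = starts[m] + k;
        const double x = xc(row, 0), y = xc(row, 1), z = xc(row, 2);
        px[row] = r11 * x + r12 * y + r13 * z + ox;
        py[row] = r21 * x + r22 * y + r23 * z + oy;
        pz[row] = r31 * x + r32 * y + r33 * z + oz;
      }
    }
    // carrier feasibility: atoms must clear the surface
    double e = 0.0;
    bool infeasible = false;
    if (carrier_type == 1) {
      double minz = R_PosInf;
      for (int i = 0; i < ntot; ++i) minz = std::min(minz, pz[i]);
      if (minz < clearance) {
        out[s] = 1e8 * (1.0 + (clearance - minz));
        infeasible = true;
      }
    } else if (carrier_type == 2) {
      double minr = R_PosInf;
      for (int i = 0; i < ntot; ++i) {
        minr = std::min(minr, std::sqrt(px[i] * px[i] + py[i] * py[i] +
                                        pz[i] * pz[i]));
      }
      if (minr < radius + clearance) {
        out[s] = 1e8 * (1.0 + (radius + clearance - minr));
        infeasible = true;
      }
    }
    if (infeasible) continue;
    // drug-drug double sums
    int kp = 0;
    for (int i = 0; i < nmol; ++i) {
      for (int j = i + 1; j < nmol; ++j, ++kp) {
        const int off = pair_off[kp];
        const int ni = counts[i];
        for (int a1 = 0; a1 < ni; ++a1) {
          const int ri = starts[i] + a1;
          const double xi = px[ri], yi = py[ri], zi = pz[ri];
          for (int a2 = 0; a2 < counts[j]; ++a2) {
            const int rj = starts[j] + a2;
            const double dx = xi - px[rj], dy = yi - py[rj], dz = zi - pz[rj];
            double r2 = dx * dx + dy * dy + dz * dz;
            const int idx = off + a2 * ni + a1;  // column-major block
            if (r2 < 1e-12) { e += 1e10; continue; }
            const double ir6 = 1.0 / (r2 * r2 * r2);
            e += (-pair_a[idx] + pair_b[idx] * ir6) * ir6;
          }
        }
      }
    }
    // carrier terms
    if (carrier_type == 1) {
      double ec = 0.0;
      for (int i = 0; i < ntot; ++i) {
        const double z2 = pz[i] * pz[i];
        const double iz4 = 1.0 / (z2 * z2);
        ec += -0.5 * carr_a[i] * iz4 + 0.2 * carr_b[i] * iz4 * iz4 / z2;
      }
      e += ec * eta * M_PI;
    } else if (carrier_type == 2) {
      double ec = 0.0;
      for (int i = 0; i < ntot; ++i) {
        const double r = std::sqrt(px[i] * px[i] + py[i] * py[i] +
                                   pz[i] * pz[i]);
        const double dm = radius - r, dp = radius + r;
        const double im2 = 1.0 / (dm * dm), ip2 = 1.0 / (dp * dp);
        const double im4 = im2 * im2, ip4 = ip2 * ip2;
        const double im10 = im4 * im4 * im2, ip10 = ip4 * ip4 * ip2;
        ec += (radius / r) *
              (-0.5 * carr_a[i] * (im4 - ip4) + 0.2 * carr_b[i] * (im10 - ip10));
      }
      e += ec * eta * M_PI;
    }
    out[s] = e;
  }
  return out;
}
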