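#include <Rcpp.h>
using namespace Rcpp;

// Grid point kinds
static const int OUTSIDE = 0, INTERIOR = 1, MEMBRANE = 2, WALL = 3;

// Directional exchange rate (s^-1) from point p to adjacent point q.
// Diffusion within a cell (interior+membrane of the same cell) and within the
// wall network; carrier-mediated + passive transport across membrane/wall
// interfaces; no direct exchange elsewhere.
static inline double rate_pq(int kp, int kq, int idp, int idq,
                             double wPINp, double wAUX1q, double wLAX3q,
                             const double *AUX1, const double *LAX3,
                             const double *PINexpr,
                             double Dcell2, double Dwall2,
                             double eff_basal, double inf_pas,
                             double p_PIN, double p_AUXLAX) {
  if (kp == OUTSIDE || kq == OUTSIDE) return 0.0;
  bool cellp = (kp == INTERIOR || kp == MEMBRANE);
  bool cellq = (kq == INTERIOR || kq == MEMBRANE);
  if (cellp && cellq) return (idp == idq) ? Dcell2 : 0.0;
  if (kp == WALL && kq == WALL) return Dwall2;
  if (kp == MEMBRANE && kq == WALL)       // efflux: basal + PIN
    return eff_basal + p_PIN * wPINp * PINexpr[idp - 1];
  if (kp == WALL && kq == MEMBRANE)       // influx: passive + AUX1/LAX3
    return inf_pas + p_AUXLAX * (wAUX1q * AUX1[idq - 1] + wLAX3q * LAX3[idq - 1]);
  return 0.0;                              // interior<->wall without membrane
}

// Thomas solve of a tridiagonal system, in place on d (rhs -> solution).
static void thomas(std::vector<double> &a, std::vector<double> &b,
                   std::vector<double> &c, std::vector<double> &d, int n) {
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    d[i] -= m * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i)
    d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// One auxin time step: explicit production/radial/boundary terms, then
// backward-Euler sweeps implicit in x (rows) and y (columns); transport and
// diffusion terms are assigned to the sweep of their direction, decay to the
// y sweep. Flux-form throughout, so a closed system conserves mass exactly.
// [[Rcpp::export]]
List step_auxin_cpp(NumericMatrix auxin, IntegerMatrix kind,
                    IntegerMatrix cell_id,
                    NumericMatrix wPIN, NumericMatrix wAUX1,
                    NumericMatrix wLAX3,
                    NumericVector AUX1, NumericVector LAX3,
                    NumericVector PINexpr, NumericVector prod_rate,
                    NumericVector decay_mult,
                    double dt, double dx, double D_cell, double D_wall,
                    double eff_basal, double inf_pas, double p_PIN,
                    double p_AUXLAX, double d_auxin,
                    int radial_mode, double D_rad,
                    IntegerVector src_idx, NumericVector src_rate,
                    IntegerVector sink_idx, NumericVector sink_rate) {
  const int nr = auxin.nrow(), nc = auxin.ncol();
  const double Dcell2 = D_cell / (dx * dx), Dwall2 = D_wall / (dx * dx);
  NumericMatrix c0(clone(auxin));
  const double *pA = AUX1.begin(), *pL = LAX3.begin(), *pP = PINexpr.begin();
  double prod_added = 0.0, boundary_net = 0.0, decay_removed = 0.0;

  // Precomputed directional pair rates: RXf(i,j) = rate (i,j)->(i,j+1),
  // RXb(i,j) = rate (i,j+1)->(i,j); RYf/RYb the same along columns.
  std::vector<double> RXf((size_t)nr * (nc - 1)), RXb((size_t)nr * (nc - 1));
  std::vector<double> RYf((size_t)(nr - 1) * nc), RYb((size_t)(nr - 1) * nc);
  for (int j = 0; j < nc - 1; ++j)
    for (int i = 0; i < nr; ++i) {
      int kp = kind(i, j), kq = kind(i, j + 1);
      int idp = cell_id(i, j), idq = cell_id(i, j + 1);
      RXf[(size_t)j * nr + i] = rate_pq(kp, kq, idp, idq, wPIN(i, j),
        wAUX1(i, j + 1), wLAX3(i, j + 1), pA, pL, pP, Dcell2, Dwall2,
        eff_basal, inf_pas, p_PIN, p_AUXLAX);
      RXb[(size_t)j * nr + i] = rate_pq(kq, kp, idq, idp, wPIN(i, j + 1),
        wAUX1(i, j), wLAX3(i, j), pA, pL, pP, Dcell2, Dwall2,
        eff_basal, inf_pas, p_PIN, p_AUXLAX);
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr - 1; ++i) {
      int kp = kind(i, j), kq = kind(i + 1, j);
      int idp = cell_id(i, j), idq = cell_id(i + 1, j);
      RYf[(size_t)j * (nr - 1) + i] = rate_pq(kp, kq, idp, idq, wPIN(i, j),
        wAUX1(i + 1, j), wLAX3(i + 1, j), pA, pL, pP, Dcell2, Dwall2,
        eff_basal, inf_pas, p_PIN, p_AUXLAX);
      RYb[(size_t)j * (nr - 1) + i] = rate_pq(kq, kp, idq, idp, wPIN(i + 1, j),
        wAUX1(i, j), wLAX3(i, j), pA, pL, pP, Dcell2, Dwall2,
        eff_basal, inf_pas, p_PIN, p_AUXLAX);
    }

  // explicit production
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int k = kind(i, j), id = cell_id(i, j);
      if (id > 0 && (k == INTERIOR || k == MEMBRANE)) {
        double add = dt * prod_rate[id - 1];
        c0(i, j) += add;
        prod_added += add;
      }
    }

  // explicit radial (3D-emulating) exchange between mirror columns
  if (radial_mode != 0 && D_rad > 0) {
    int mc = (nc - 1) / 2;  // centre column (0-based), nc odd
    for (int jl = 0; jl < mc; ++jl) {
      int jr = nc - 1 - jl;
      double raddist = (jr - jl) * dx;
      double f = dt * D_rad / raddist;
      for (int i = 0; i < nr; ++i) {
        int kl = kind(i, jl), kr = kind(i, jr);
        if (radial_mode == 1 || radial_mode == 3) {  // walls only
          if (kl == WALL && kr == WALL) {
            double ex = f * (auxin(i, jr) - auxin(i, jl));
            c0(i, jl) += ex;
            c0(i, jr) -= ex;
          }
        }
        if (radial_mode == 2) {  // walls + cells (efflux/influx-ratio weighted)
          if (kl == WALL && kr == WALL) {
            double ex = f * (auxin(i, jr) - auxin(i, jl));
            c0(i, jl) += ex;
            c0(i, jr) -= ex;
          } else if (kl != OUTSIDE && kl != WALL && kr != OUTSIDE && kr != WALL) {
            double el = eff_basal, il = inf_pas, er = eff_basal, ir = inf_pas;
            int idl = cell_id(i, jl), idr = cell_id(i, jr);
            if (kl == MEMBRANE && idl > 0) {
              el += p_PIN * wPIN(i, jl) * pP[idl - 1];
              il += p_AUXLAX * (wAUX1(i, jl) * pA[idl - 1] + wLAX3(i, jl) * pL[idl - 1]);
            }
            if (kr == MEMBRANE && idr > 0) {
              er += p_PIN * wPIN(i, jr) * pP[idr - 1];
              ir += p_AUXLAX * (wAUX1(i, jr) * pA[idr - 1] + wLAX3(i, jr) * pL[idr - 1]);
            }
            double rl = el / (el + il), rr = er / (er + ir);
            double ex = f * (rr * auxin(i, jr) - rl * auxin(i, jl));
            c0(i, jl) += ex;
            c0(i, jr) -= ex;
          }
        }
      }
    }
  }

  // explicit boundary exchange (shootward domain edge)
  for (int s = 0; s < src_idx.size(); ++s) {
    double add = dt * src_rate[s];
    c0[src_idx[s] - 1] += add;
    boundary_net += add;
  }
  for (int s = 0; s < sink_idx.size(); ++s) {
    double rem = dt * sink_rate[s] * c0[sink_idx[s] - 1];
    c0[sink_idx[s] - 1] -= rem;
    boundary_net -= rem;
  }

  // x sweep: implicit in-row diffusion and lateral membrane transport
  {
    std::vector<double> a(nc), b(nc), cc(nc), d(nc);
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        double out = 0.0, inL = 0.0, inR = 0.0;
        if (j > 0) {
          out += RXb[(size_t)(j - 1) * nr + i];
          inL = RXf[(size_t)(j - 1) * nr + i];
        }
        if (j < nc - 1) {
          out += RXf[(size_t)j * nr + i];
          inR = RXb[(size_t)j * nr + i];
        }
        a[j] = -dt * inL;
        cc[j] = -dt * inR;
        b[j] = 1.0 + dt * out;
        d[j] = c0(i, j);
      }
      thomas(a, b, cc, d, nc);
      for (int j = 0; j < nc; ++j) c0(i, j) = d[j];
    }
  }

  // y sweep: implicit in-column diffusion, apical/basal transport, decay
  {
    std::vector<double> a(nr), b(nr), cc(nr), d(nr);
    for (int j = 0; j < nc; ++j) {
      const double *ryf = &RYf[(size_t)j * (nr - 1)];
      const double *ryb = &RYb[(size_t)j * (nr - 1)];
      for (int i = 0; i < nr; ++i) {
        int k = kind(i, j), id = cell_id(i, j);
        double out = 0.0, inD = 0.0, inU = 0.0;
        if (i > 0) {
          out += ryb[i - 1];
          inD = ryf[i - 1];
        }
        if (i < nr - 1) {
          out += ryf[i];
          inU = ryb[i];
        }
        double dec = 0.0;
        if (id > 0 && (k == INTERIOR || k == MEMBRANE))
          dec = d_auxin * decay_mult[id - 1];
        a[i] = -dt * inD;
        cc[i] = -dt * inU;
        b[i] = 1.0 + dt * (out + dec);
        d[i] = c0(i, j);
      }
      thomas(a, b, cc, d, nr);
      for (int i = 0; i < nr; ++i) {
        int k = kind(i, j), id = cell_id(i, j);
        if (id > 0 && (k == INTERIOR || k == MEMBRANE))
          decay_removed += dt * d_auxin * decay_mult[id - 1] * d[i];
        c0(i, j) = d[i];
      }
    }
  }

  // non-negativity guard (solver should not need it at the default step)
  int n_clipped = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (c0(i, j) < 0) { c0(i, j) = 0.0; ++n_clipped; }

  // per-cell mean auxin over interior+membrane points
  int ncell = AUX1.size();
  NumericVector cmean(ncell), cnt(ncell);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int k = kind(i, j), id = cell_id(i, j);
      if (id > 0 && (k == INTERIOR || k == MEMBRANE)) {
        cmean[id - 1] += c0(i, j);
        cnt[id - 1] += 1.0;
      }
    }
  for (int q = 0; q < ncell; ++q)
    if (cnt[q] > 0) cmean[q] /= cnt[q];

  bool finite = true;
  for (int j = 0; j < nc && finite; ++j)
    for (int i = 0; i < nr; ++i)
      if (!R_finite(c0(i, j))) { finite = false; break; }

  return List::create(_["field"] = c0, _["cell_mean"] = cmean,
                      _["prod_added"] = prod_added,
                      _["boundary_net"] = boundary_net,
                      _["decay_removed"] = decay_removed,
                      _["n_clipped"] = n_clipped, _["finite"] = finite);
}

// Per-cell net membrane flux vector: sum of directed membrane fluxes
// (efflux out minus influx in), x component positive toward higher column
// (rightward), y component positive shootward.
// [[Rcpp::export]]
List flux_vectors_cpp(NumericMatrix auxin, IntegerMatrix kind,
                      IntegerMatrix cell_id,
                      NumericMatrix wPIN, NumericMatrix wAUX1,
                      NumericMatrix wLAX3,
                      NumericVector AUX1, NumericVector LAX3,
                      NumericVector PINexpr,
                      double eff_basal, double inf_pas, double p_PIN,
                      double p_AUXLAX) {
  const int nr = auxin.nrow(), nc = auxin.ncol();
  int ncell = AUX1.size();
  NumericVector fx(ncell), fy(ncell);
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (kind(i, j) != MEMBRANE) continue;
      int id = cell_id(i, j);
      if (id <= 0) continue;
      for (int m = 0; m < 4; ++m) {
        int ii = i + di[m], jj = j + dj[m];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (kind(ii, jj) != WALL) continue;
        double eff = (eff_basal + p_PIN * wPIN(i, j) * PINexpr[id - 1]) * auxin(i, j);
        double inf = (inf_pas + p_AUXLAX * (wAUX1(i, j) * AUX1[id - 1] +
                      wLAX3(i, j) * LAX3[id - 1])) * auxin(ii, jj);
        double net = eff - inf;  // positive = net outward through this face
        fy[id - 1] += net * di[m];
        fx[id - 1] += net * dj[m];
      }
    }
  return List::create(_["fx"] = fx, _["fy"] = fy);
}
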