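// Rigid-molecule NVT Metropolis Monte Carlo kernel and pair-histogram
// helpers. Energy model: Lennard-Jones (truncated at rc) + shifted-force
// Coulomb (zero energy and force at rc) + optional tabulated perturbation
// potential per site-type pair (linear interpolation), minimum-image
// convention in a cubic periodic box; intramolecular pairs excluded (rigid
// bodies).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct FF {
  const double *A, *B, *QQ, *rmin2; // nt x nt tables, column-major
  int nt;
  double rc, rc2;
  const double *pertU;  // pertNr x nPert, column-major (NULL if none)
  const int *pertIdx;   // nt x nt -> column of pertU, or -1
  int pertNr;
  double pertDr;
  bool softcore;        // clamp r for the warm-up sweeps
};

inline double pair_energy(double r2, int t1, int t2, const FF &ff,
                          bool &singular) {
  if (r2 >= ff.rc2) return 0.0;
  const int k = t1 * ff.nt + t2;
  double e = 0.0;
  const double a = ff.A[k];
  if (a != 0.0) {
    double r2lj = r2;
    if (ff.softcore && r2lj < ff.rmin2[k]) r2lj = ff.rmin2[k];
    const double ir2 = 1.0 / r2lj;
    const double ir6 = ir2 * ir2 * ir2;
    e += ir6 * (a * ir6 - ff.B[k]);
  }
  const double qq = ff.QQ[k];
  if (qq != 0.0) {
    if (r2 < 1e-12) { singular = true; return R_PosInf; }
    double r = std::sqrt(r2);
    if (ff.softcore && r < 0.8) r = 0.8;
    e += qq * (1.0 / r + r / ff.rc2 - 2.0 / ff.rc);
  }
  if (ff.pertU && ff.pertIdx[k] >= 0) {
    const double r = std::sqrt(r2);
    const double x = r / ff.pertDr;
    const int i0 = (int)x;
    if (i0 + 1 < ff.pertNr) {
      const double *col = ff.pertU + (size_t)ff.pertIdx[k] * ff.pertNr;
      e += col[i0] + (x - i0) * (col[i0 + 1] - col[i0]);
    }
  }
  return e;
}

inline void min_image(double &d, double L) { d -= L * std::nearbyint(d / L); }

// Energy between atoms [a0, a1) at coordinates (xa, ya, za) and all atoms of
// other molecules.
double mol_vs_rest(const std::vector<double> &xa, const std::vector<double> &ya,
                   const std::vector<double> &za, int a0, int a1,
                   const std::vector<double> &x, const std::vector<double> &y,
                   const std::vector<double> &z, const int *type,
                   const int *mol, int n, int m, double L, const FF &ff,
                   bool &singular) {
  double e = 0.0;
  for (int i = a0; i < a1; ++i) {
    const double xi = xa[i - a0], yi = ya[i - a0], zi = za[i - a0];
    const int ti = type[i];
    for (int j = 0; j < n; ++j) {
      if (mol[j] == m) continue;
      double dx = xi - x[j], dy = yi - y[j], dz = zi - z[j];
      min_image(dx, L); min_image(dy, L); min_image(dz, L);
      e += pair_energy(dx * dx + dy * dy + dz * dz, ti, type[j], ff, singular);
      if (singular) return R_PosInf;
    }
  }
  return e;
}

double total_energy_impl(const std::vector<double> &x,
                         const std::vector<double> &y,
                         const std::vector<double> &z, const int *type,
                         const int *mol, int n, double L, const FF &ff,
                         bool &singular) {
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (mol[i] == mol[j]) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      min_image(dx, L); min_image(dy, L); min_image(dz, L);
      e += pair_energy(dx * dx + dy * dy + dz * dz, type[i], type[j], ff,
                       singular);
      if (singular) return R_PosInf;
    }
  }
  return e;
}

FF make_ff(const NumericMatrix &A, const NumericMatrix &B,
           const NumericMatrix &QQ, const NumericMatrix &rmin2, double rc,
           const Nullable<NumericMatrix> &pertU, const IntegerMatrix &pertIdx,
           double pertDr, bool softcore, NumericMatrix &pert_store) {
  FF ff;
  ff.A = A.begin(); ff.B = B.begin(); ff.QQ = QQ.begin();
  ff.rmin2 = rmin2.begin();
  ff.nt = A.nrow();
  ff.rc = rc; ff.rc2 = rc * rc;
  ff.pertU = nullptr; ff.pertNr = 0; ff.pertDr = 1.0;
  ff.pertIdx = pertIdx.begin();
  if (pertU.isNotNull()) {
    pert_store = NumericMatrix(pertU.get());
    ff.pertU = pert_store.begin();
    ff.pertNr = pert_store.nrow();
    ff.pertDr = pertDr;
  }
  ff.softcore = softcore;
  return ff;
}

void fill_vectors(const NumericMatrix &coords, std::vector<double> &x,
                  std::vector<double> &y, std::vector<double> &z) {
  const int n = coords.nrow();
  x.resize(n); y.resize(n); z.resize(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
}

inline void quat_mul(const double *q, const double *p, double *out) {
  out[0] = q[0] * p[0] - q[1] * p[1] - q[2] * p[2] - q[3] * p[3];
  out[1] = q[0] * p[1] + q[1] * p[0] + q[2] * p[3] - q[3] * p[2];
  out[2] = q[0] * p[2] - q[1] * p[3] + q[2] * p[0] + q[3] * p[1];
  out[3] = q[0] * p[3] + q[1] * p[2] - q[2] * p[1] + q[3] * p[0];
}

inline void quat_rotate(const double *q, double px, double py, double pz,
                        double *out) {
  const double w = q[0], x = q[1], y = q[2], z = q[3];
  out[0] = (1 - 2 * (y * y + z * z)) * px + 2 * (x * y - w * z) * py +
           2 * (x * z + w * y) * pz;
  out[1] = 2 * (x * y + w * z) * px + (1 - 2 * (x * x + z * z)) * py +
           2 * (y * z - w * x) * pz;
  out[2] = 2 * (x * z - w * y) * px + 2 * (y * z + w * x) * py +
           (1 - 2 * (x * x + y * y)) * pz;
}

} // namespace

// [[Rcpp::export(name = ".energy_total_cpp")]]
double energy_total_cpp(NumericMatrix coords, IntegerVector mol,
                        IntegerVector type, NumericMatrix A, NumericMatrix B,
                        NumericMatrix QQ, NumericMatrix rmin2, double L,
                        double rc, Nullable<NumericMatrix> pertU,
                        IntegerMatrix pertIdx, double pertDr, bool softcore) {
  NumericMatrix pert_store;
  FF ff = make_ff(A, B, QQ, rmin2, rc, pertU, pertIdx, pertDr, softcore,
                  pert_store);
  std::vector<double> x, y, z;
  fill_vectors(coords, x, y, z);
  bool singular = false;
  double e = total_energy_impl(x, y, z, type.begin(), mol.begin(),
                               coords.nrow(), L, ff, singular);
  if (singular)
    stop("singular configuration: overlapping charged sites (r < 1e-6 A)");
  return e;
}

// Energy of one molecule (0-based index) with the rest of the box.
// [[Rcpp::export(name = ".mol_energy_cpp")]]
double mol_energy_cpp(NumericMatrix coords, IntegerVector mol,
                      IntegerVector type, int m, NumericMatrix A,
                      NumericMatrix B, NumericMatrix QQ, NumericMatrix rmin2,
                      double L, double rc, Nullable<NumericMatrix> pertU,
                      IntegerMatrix pertIdx, double pertDr, bool softcore) {
  NumericMatrix pert_store;
  FF ff = make_ff(A, B, QQ, rmin2, rc, pertU, pertIdx, pertDr, softcore,
                  pert_store);
  std::vector<double> x, y, z;
  fill_vectors(coords, x, y, z);
  const int n = coords.nrow();
  int a0 = -1, a1 = -1;
  for (int i = 0; i < n; ++i) {
    if (mol[i] == m) { if (a0 < 0) a0 = i; a1 = i + 1; }
  }
  if (a0 < 0) stop("molecule index out of range");
  std::vector<double> xa(x.begin() + a0, x.begin() + a1),
      ya(y.begin() + a0, y.begin() + a1), za(z.begin() + a0, z.begin() + a1);
  bool singular = false;
  double e = mol_vs_rest(xa, ya, za, a0, a1, x, y, z, type.begin(),
                         mol.begin(), n, m, L, ff, singular);
  if (singular) return R_PosInf;
  return e;
}

// [[Rcpp::export(name = ".run_mc_cpp")]]
List run_mc_cpp(NumericMatrix centers, NumericMatrix quats, List templates,
                IntegerVector topo_of_mol, IntegerVector type,
                IntegerVector mol, IntegerVector mol_first,
                IntegerVector mol_natoms, NumericMatrix A, NumericMatrix B,
                NumericMatrix QQ, NumericMatrix rmin2, double L, double rc,
                double kT, Nullable<NumericMatrix> pertU,
                IntegerMatrix pertIdx, double pertDr, int nsweeps,
                int sample_every, double maxtrans, double maxrot, bool tune,
                double target_acc, bool softcore) {
  NumericMatrix pert_store;
  FF ff = make_ff(A, B, QQ, rmin2, rc, pertU, pertIdx, pertDr, softcore,
                  pert_store);
  const int M = centers.nrow();
  const int n = type.size();

  // cache template coordinate arrays
  std::vector<NumericMatrix> tmpl(templates.size());
  for (int t = 0; t < templates.size(); ++t)
    tmpl[t] = as<NumericMatrix>(templates[t]);

  // working state
  std::vector<double> cx(M), cy(M), cz(M);
  std::vector<double> qw(M), qx(M), qy(M), qz(M);
  for (int m = 0; m < M; ++m) {
    cx[m] = centers(m, 0); cy[m] = centers(m, 1); cz[m] = centers(m, 2);
    qw[m] = quats(m, 0); qx[m] = quats(m, 1); qy[m] = quats(m, 2);
    qz[m] = quats(m, 3);
  }
  std::vector<double> x(n), y(n), z(n);
  for (int m = 0; m < M; ++m) {
    const NumericMatrix &T = tmpl[topo_of_mol[m]];
    const double q[4] = {qw[m], qx[m], qy[m], qz[m]};
    for (int i = 0; i < mol_natoms[m]; ++i) {
      double out[3];
      quat_rotate(q, T(i, 0), T(i, 1), T(i, 2), out);
      const int a = mol_first[m] + i;
      x[a] = cx[m] + out[0]; y[a] = cy[m] + out[1]; z[a] = cz[m] + out[2];
    }
  }

  bool singular = false;
  double E = total_energy_impl(x, y, z, type.begin(), mol.begin(), n, L, ff,
                               singular);
  if (singular)
    stop("singular configuration: overlapping charged sites at MC start");

  List frames;
  std::vector<double> etrace;
  long natt_t = 0, nacc_t = 0, natt_r = 0, nacc_r = 0;
  long rec_att_t = 0, rec_acc_t = 0, rec_att_r = 0, rec_acc_r = 0;

  std::vector<double> xa, ya, za; // candidate coordinates of moved molecule

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int step = 0; step < M; ++step) {
      int m = (int)(unif_rand() * M);
      if (m >= M) m = M - 1;
      const int a0 = mol_first[m], nat = mol_natoms[m];
      const int a1 = a0 + nat;
      const bool do_rot = (nat > 1) && (unif_rand() < 0.5);

      xa.assign(nat, 0.0); ya.assign(nat, 0.0); za.assign(nat, 0.0);
      double ncx = cx[m], ncy = cy[m], ncz = cz[m];
      double nq[4] = {qw[m], qx[m], qy[m], qz[m]};

      if (do_rot) {
        double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
        const double an = std::sqrt(ax * ax + ay * ay + az * az);
        ax /= an; ay /= an; az /= an;
        const double ang = (unif_rand() - 0.5) * 2.0 * maxrot;
        const double dq[4] = {std::cos(ang / 2), std::sin(ang / 2) * ax,
                              std::sin(ang / 2) * ay, std::sin(ang / 2) * az};
        const double q0[4] = {qw[m], qx[m], qy[m], qz[m]};
        quat_mul(dq, q0, nq);
        const double qn = std::sqrt(nq[0] * nq[0] + nq[1] * nq[1] +
                                    nq[2] * nq[2] + nq[3] * nq[3]);
        for (int k = 0; k < 4; ++k) nq[k] /= qn;
        const NumericMatrix &T = tmpl[topo_of_mol[m]];
        for (int i = 0; i < nat; ++i) {
          double out[3];
          quat_rotate(nq, T(i, 0), T(i, 1), T(i, 2), out);
          xa[i] = ncx + out[0]; ya[i] = ncy + out[1]; za[i] = ncz + out[2];
        }
        natt_r++; rec_att_r++;
      } else {
        const double dx = (unif_rand() - 0.5) * 2.0 * maxtrans;
        const double dy = (unif_rand() - 0.5) * 2.0 * maxtrans;
        const double dz = (unif_rand() - 0.5) * 2.0 * maxtrans;
        ncx += dx; ncy += dy; ncz += dz;
        // wrap the molecule center back into [0, L)
        const double sx = L * std::floor(ncx / L);
        const double sy = L * std::floor(ncy / L);
        const double sz = L * std::floor(ncz / L);
        ncx -= sx; ncy -= sy; ncz -= sz;
        for (int i = 0; i < nat; ++i) {
          xa[i] = x[a0 + i] + dx - sx;
          ya[i] = y[a0 + i] + dy - sy;
          za[i] = z[a0 + i] + dz - sz;
        }
        natt_t++; rec_att_t++;
      }

      bool sing_old = false, sing_new = false;
      std::vector<double> xo(x.begin() + a0, x.begin() + a1),
          yo(y.begin() + a0, y.begin() + a1), zo(z.begin() + a0, z.begin() + a1);
      const double e_old = mol_vs_rest(xo, yo, zo, a0, a1, x, y, z,
                                       type.begin(), mol.begin(), n, m, L, ff,
                                       sing_old);
      const double e_new = mol_vs_rest(xa, ya, za, a0, a1, x, y, z,
                                       type.begin(), mol.begin(), n, m, L, ff,
                                       sing_new);
      bool accept = false;
      if (!sing_new && R_finite(e_new)) {
        const double dU = e_new - e_old;
        accept = (dU <= 0.0) || (unif_rand() < std::exp(-dU / kT));
        if (accept) E += dU;
      }
      if (accept) {
        for (int i = 0; i < nat; ++i) {
          x[a0 + i] = xa[i]; y[a0 + i] = ya[i]; z[a0 + i] = za[i];
        }
        cx[m] = ncx; cy[m] = ncy; cz[m] = ncz;
        qw[m] = nq[0]; qx[m] = nq[1]; qy[m] = nq[2]; qz[m] = nq[3];
        if (do_rot) { nacc_r++; rec_acc_r++; } else { nacc_t++; rec_acc_t++; }
      }
    }

    if (tune && (sweep + 1) % 25 == 0) {
      if (rec_att_t > 0) {
        const double acc = (double)rec_acc_t / rec_att_t;
        maxtrans *= (acc > target_acc) ? 1.08 : 0.92;
        if (maxtrans > L / 4) maxtrans = L / 4;
        if (maxtrans < 0.01) maxtrans = 0.01;
      }
      if (rec_att_r > 0) {
        const double acc = (double)rec_acc_r / rec_att_r;
        maxrot *= (acc > target_acc) ? 1.08 : 0.92;
        if (maxrot > M_PI) maxrot = M_PI;
        if (maxrot < 0.02) maxrot = 0.02;
      }
      rec_att_t = rec_acc_t = rec_att_r = rec_acc_r = 0;
    }

    if (sample_every > 0 && (sweep + 1) % sample_every == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) {
        fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i];
      }
      frames.push_back(fr);
      etrace.push_back(E);
    }
    if ((sweep & 255) == 0) checkUserInterrupt();
  }

  NumericMatrix out_centers(M, 3), out_quats(M, 4), out_coords(n, 3);
  for (int m = 0; m < M; ++m) {
    out_centers(m, 0) = cx[m]; out_centers(m, 1) = cy[m];
    out_centers(m, 2) = cz[m];
    out_quats(m, 0) = qw[m]; out_quats(m, 1) = qx[m];
    out_quats(m, 2) = qy[m]; out_quats(m, 3) = qz[m];
  }
  for (int i = 0; i < n; ++i) {
    out_coords(i, 0) = x[i]; out_coords(i, 1) = y[i]; out_coords(i, 2) = z[i];
  }
  const long natt = natt_t + natt_r, nacc = nacc_t + nacc_r;
  return List::create(
      _["frames"] = frames, _["energy_trace"] = wrap(etrace),
      _["centers"] = out_centers, _["quats"] = out_quats,
      _["coords"] = out_coords, _["energy"] = E,
      _["n_attempted"] = (double)natt, _["n_accepted"] = (double)nacc,
      _["acc_ratio"] = natt > 0 ? (double)nacc / natt : NA_REAL,
      _["acc_trans"] = natt_t > 0 ? (double)nacc_t / natt_t : NA_REAL,
      _["acc_rot"] = natt_r > 0 ? (double)nacc_r / natt_r : NA_REAL,
      _["maxtrans"] = maxtrans, _["maxrot"] = maxrot);
}

// Histogram of minimum-image distances between selections ia and ib
// (0-based atom indices), over a list of N x 3 coordinate frames, skipping
// same-atom and same-molecule pairs. Ordered pairs are counted (i from ia,
// j from ib, i != j).
// [[Rcpp::export(name = ".rdf_hist_cpp")]]
NumericVector rdf_hist_cpp(List frames, IntegerVector ia, IntegerVector ib,
                           IntegerVector mol, double L, double dr, int nbins) {
  NumericVector counts(nbins);
  const int na = ia.size(), nb = ib.size();
  for (int f = 0; f < frames.size(); ++f) {
    NumericMatrix X = frames[f];
    for (int u = 0; u < na; ++u) {
      const int i = ia[u];
      const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2);
      const int mi = mol[i];
      for (int v = 0; v < nb; ++v) {
        const int j = ib[v];
        if (j == i || mol[j] == mi) continue;
        double dx = xi - X(j, 0), dy = yi - X(j, 1), dz = zi - X(j, 2);
        min_image(dx, L); min_image(dy, L); min_image(dz, L);
        const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        const int b = (int)(r / dr);
        if (b < nbins) counts[b] += 1.0;
      }
    }
  }
  return counts;
}
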