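// Explicit FTCS stepper for the modified Pennes bioheat equation on a
// node-centred cubic grid with zero-flux (mirror-node) boundaries and
// harmonic-mean face conductivities.
//
// The per-node update is
//   T'  = T + (ht/rho_c) * [ sum_faces k_half (T_nb - T)/h^2
//                            + perf (T_a - T) + Q_m + Q_r ]
// with perf = omega_b * rho_b * c_b and k_half the harmonic mean of the
// conductivities on the two sides of the face.
//
// For speed the domain is embedded in a one-node ghost layer (refilled by
// mirroring every step, which realises the zero-flux condition), and the
// sweep uses a single pair of reference coefficients valid wherever the
// node and its six neighbours carry the reference (majority) tissue
// parameters.  Every other node -- tumor tissue, tissue interfaces, or any
// node whose parameters differ from the reference -- is kept in a sparse
// correction list with its exact per-face coefficients and is rewritten
// after the sweep.  The arithmetic for reference nodes is bitwise the same
// expression as the literal stencil, so the result is identical to a
// triple-loop transcription up to the usual floating round-off of
// re-associated source terms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstddef>

using namespace Rcpp;

namespace {

// ht * harmonic_mean(ka, kb) / (rhoc * h^2): dimensionless face weight
inline double face_coef(double ka, double kb, double rhoc,
                        double ht, double h2) {
  return ht * (2.0 * ka * kb / (ka + kb)) / (rhoc * h2);
}

// mirror a physical axis index across the zero-flux boundary (0..n)
inline int mirror_idx(int p, int n) {
  if (p < 0) return 1;
  if (p > n) return n - 1;
  return p;
}

struct SpecialNode {
  std::ptrdiff_t m;   // padded linear index
  double a[6];        // face weights: -x,+x,-y,+y,-z,+z
  double d;           // diagonal weight
  double c;           // constant term (perfusion + metabolic + SAR)
};

} // namespace

// [[Rcpp::export(rng = false)]]
List pennes_run_cpp(NumericVector t0,
                    NumericVector kfield,
                    NumericVector perf,
                    NumericVector qmet,
                    NumericVector rhoc,
                    Nullable<NumericVector> qr,
                    Nullable<NumericMatrix> injections,
                    double inj_a, double inj_r0,
                    int nint, double len, double ht, int n_steps,
                    double t_a, double t_start,
                    double kref, double perfref, double qmref, double rhocref,
                    int trace_stride, int check_every) {
  const int np = nint + 1;                   // nodes per axis
  const std::ptrdiff_t nn = (std::ptrdiff_t)np * np * np;
  if (t0.size() != nn || kfield.size() != nn || perf.size() != nn ||
      qmet.size() != nn || rhoc.size() != nn)
    stop("field arrays must have (N+1)^3 elements");
  if (n_steps < 0) stop("n_steps must be >= 0");
  if (ht < 0) stop("ht must be >= 0");

  const double h = len / nint;
  const double h2 = h * h;

  const int P = np + 2;                      // padded axis length
  const std::ptrdiff_t sy = P;
  const std::ptrdiff_t sz = (std::ptrdiff_t)P * P;
  const std::ptrdiff_t pn = (std::ptrdiff_t)P * P * P;

  const bool has_qr = qr.isNotNull();
  NumericVector qrv;
  if (has_qr) {
    qrv = qr.get();
    if (qrv.size() != nn) stop("qr must have (N+1)^3 elements");
  }

  // Gaussian SAR source, separable per axis:
  //   Q_r(x) = sum_p A exp(-|x - x0_p|^2 / r0^2)
  //          = sum_p A gx_p[i] gy_p[j] gz_p[k]
  int n_inj = 0;
  std::vector<double> gx, gy, gzv;           // plain axis factors, np per inj
  std::vector<double> gxa;                   // A*(ht/rhocref)*gx, for the sweep
  if (injections.isNotNull()) {
    NumericMatrix pts(injections.get());
    if (pts.ncol() != 3) stop("injection points must be an Np x 3 matrix");
    n_inj = pts.nrow();
    gx.resize((size_t)n_inj * np);
    gy.resize((size_t)n_inj * np);
    gzv.resize((size_t)n_inj * np);
    gxa.resize((size_t)n_inj * np);
    const double r02 = inj_r0 * inj_r0;
    for (int p = 0; p < n_inj; ++p) {
      for (int i = 0; i < np; ++i) {
        const double xi = i * h;
        gx[(size_t)p * np + i]  = std::exp(-(xi - pts(p, 0)) * (xi - pts(p, 0)) / r02);
        gy[(size_t)p * np + i]  = std::exp(-(xi - pts(p, 1)) * (xi - pts(p, 1)) / r02);
        gzv[(size_t)p * np + i] = std::exp(-(xi - pts(p, 2)) * (xi - pts(p, 2)) / r02);
        gxa[(size_t)p * np + i] = (ht / rhocref) * inj_a * gx[(size_t)p * np + i];
      }
    }
  }

  // reference coefficients (majority tissue, all-equal neighbours)
  const double aref = face_coef(kref, kref, rhocref, ht, h2);
  const double dref = 1.0 - (aref + aref + aref + aref + aref + aref)
                          - ht * perfref / rhocref;
  const double ccref = ht * (perfref * t_a + qmref) / rhocref;

  // padded working arrays
  std::vector<double> bufA((size_t)pn, 0.0), bufB((size_t)pn, 0.0);
  double* cur = bufA.data();
  double* nxt = bufB.data();
  std::vector<double> ccpad;                 // per-node constant, qr-array mode
  if (has_qr) ccpad.assign((size_t)pn, 0.0);

  const std::ptrdiff_t snp = np;
  auto pidx = [&](int i, int j, int k) -> std::ptrdiff_t {
    return (std::ptrdiff_t)(k + 1) * sz + (std::ptrdiff_t)(j + 1) * sy + (i + 1);
  };
  auto fidx = [&](int i, int j, int k) -> std::ptrdiff_t {
    return ((std::ptrdiff_t)k * snp + j) * snp + i;
  };

  for (int k = 0; k < np; ++k)
    for (int j = 0; j < np; ++j)
      for (int i = 0; i < np; ++i)
        cur[pidx(i, j, k)] = t0[fidx(i, j, k)];

  // classify nodes; build the sparse correction list
  std::vector<SpecialNode> specials;
  {
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int k = 0; k < np; ++k) {
      for (int j = 0; j < np; ++j) {
        for (int i = 0; i < np; ++i) {
          const std::ptrdiff_t f = fidx(i, j, k);
          const double kc = kfield[f];
          bool special = (kc != kref) || (perf[f] != perfref) ||
                         (qmet[f] != qmref) || (rhoc[f] != rhocref);
          double knb[6];
          for (int d = 0; d < 6; ++d) {
            const int in = mirror_idx(i + di[d], nint);
            const int jn = mirror_idx(j + dj[d], nint);
            const int kn = mirror_idx(k + dk[d], nint);
            knb[d] = kfield[fidx(in, jn, kn)];
            if (knb[d] != kref) special = true;
          }
          if (!special) continue;
          SpecialNode s;
          s.m = pidx(i, j, k);
          double asum = 0.0;
          for (int d = 0; d < 6; ++d) {
            s.a[d] = face_coef(kc, knb[d], rhoc[f], ht, h2);
            asum += s.a[d];
          }
          s.d = 1.0 - asum - ht * perf[f] / rhoc[f];
          double qrn = 0.0;
          if (has_qr) {
            qrn = qrv[f];
          } else {
            for (int p = 0; p < n_inj; ++p)
              qrn += inj_a * gx[(size_t)p * np + i] * gy[(size_t)p * np + j] *
                     gzv[(size_t)p * np + k];
          }
          s.c = ht * (perf[f] * t_a + qmet[f] + qrn) / rhoc[f];
          specials.push_back(s);
        }
      }
    }
  }

  if (has_qr) {
    for (int k = 0; k < np; ++k)
      for (int j = 0; j < np; ++j)
        for (int i = 0; i < np; ++i)
          ccpad[pidx(i, j, k)] = ccref + ht * qrv[fidx(i, j, k)] / rhocref;
  }

  auto fill_ghosts = [&](double* T) {
    // x faces
    for (std::ptrdiff_t k = 0; k < P; ++k)
      for (std::ptrdiff_t j = 0; j < P; ++j) {
        double* row = T + k * sz + j * sy;
        row[0] = row[2];
        row[P - 1] = row[P - 3];
      }
    // y faces
    for (std::ptrdiff_t k = 0; k < P; ++k) {
      double* pl = T + k * sz;
      for (std::ptrdiff_t i = 0; i < P; ++i) {
        pl[i] = pl[2 * sy + i];
        pl[(std::ptrdiff_t)(P - 1) * sy + i] = pl[(std::ptrdiff_t)(P - 3) * sy + i];
      }
    }
    // z faces
    for (std::ptrdiff_t j = 0; j < P; ++j) {
      double* pl = T + j * sy;
      for (std::ptrdiff_t i = 0; i < P; ++i) {
        pl[i] = pl[2 * sz + i];
        pl[(std::ptrdiff_t)(P - 1) * sz + i] = pl[(std::ptrdiff_t)(P - 3) * sz + i];
      }
    }
  };

  std::vector<double> tr_step, tr_time, tr_min, tr_max;
  std::vector<double> wrow((size_t)std::max(n_inj, 1), 0.0);

  const int chk = check_every > 0 ? check_every : 500;
  for (int s = 0; s < n_steps; ++s) {
    fill_ghosts(cur);
    for (int k = 1; k <= np; ++k) {
      for (int j = 1; j <= np; ++j) {
        const double* tc = cur + (std::ptrdiff_t)k * sz + (std::ptrdiff_t)j * sy;
        double* tn = nxt + (std::ptrdiff_t)k * sz + (std::ptrdiff_t)j * sy;
        if (has_qr) {
          const double* cc = ccpad.data() + (std::ptrdiff_t)k * sz + (std::ptrdiff_t)j * sy;
          for (int i = 1; i <= np; ++i) {
            const double lap = tc[i - 1] + tc[i + 1] + tc[i - sy] + tc[i + sy] +
                               tc[i - sz] + tc[i + sz];
            tn[i] = dref * tc[i] + aref * lap + cc[i];
          }
        } else if (n_inj > 0) {
          for (int p = 0; p < n_inj; ++p)
            wrow[p] = gy[(size_t)p * np + (j - 1)] * gzv[(size_t)p * np + (k - 1)];
          if (n_inj == 1) {
            const double w0 = wrow[0];
            const double* g0 = gxa.data();
            for (int i = 1; i <= np; ++i) {
              const double lap = tc[i - 1] + tc[i + 1] + tc[i - sy] + tc[i + sy] +
                                 tc[i - sz] + tc[i + sz];
              tn[i] = dref * tc[i] + aref * lap + (ccref + w0 * g0[i - 1]);
            }
          } else {
            for (int i = 1; i <= np; ++i) {
              const double lap = tc[i - 1] + tc[i + 1] + tc[i - sy] + tc[i + sy] +
                                 tc[i - sz] + tc[i + sz];
              double c = ccref;
              for (int p = 0; p < n_inj; ++p)
                c += wrow[p] * gxa[(size_t)p * np + (i - 1)];
              tn[i] = dref * tc[i] + aref * lap + c;
            }
          }
        } else {
          for (int i = 1; i <= np; ++i) {
            const double lap = tc[i - 1] + tc[i + 1] + tc[i - sy] + tc[i + sy] +
                               tc[i - sz] + tc[i + sz];
            tn[i] = dref * tc[i] + aref * lap + ccref;
          }
        }
      }
    }
    // sparse correction: exact stencil for non-reference nodes
    for (const SpecialNode& sp : specials) {
      const std::ptrdiff_t m = sp.m;
      nxt[m] = sp.d * cur[m] +
               sp.a[0] * cur[m - 1] + sp.a[1] * cur[m + 1] +
               sp.a[2] * cur[m - sy] + sp.a[3] * cur[m + sy] +
               sp.a[4] * cur[m - sz] + sp.a[5] * cur[m + sz] + sp.c;
    }
    std::swap(cur, nxt);

    const bool last = (s == n_steps - 1);
    if ((s + 1) % chk == 0 || last) {
      bool bad = false;
      for (int k = 1; k <= np && !bad; ++k)
        for (int j = 1; j <= np && !bad; ++j) {
          const double* tc = cur + (std::ptrdiff_t)k * sz + (std::ptrdiff_t)j * sy;
          for (int i = 1; i <= np; ++i)
            if (!std::isfinite(tc[i])) { bad = true; break; }
        }
      if (bad)
        stop("non-finite temperature detected at step %d (t = %.6g s); "
             "the explicit scheme is unstable for this time step",
             s + 1, t_start + (s + 1) * ht);
      Rcpp::checkUserInterrupt();
    }
    if (trace_stride > 0 && ((s + 1) % trace_stride == 0 || last)) {
      double tmin = R_PosInf, tmax = R_NegInf;
      for (int k = 1; k <= np; ++k)
        for (int j = 1; j <= np; ++j) {
          const double* tc = cur + (std::ptrdiff_t)k * sz + (std::ptrdiff_t)j * sy;
          for (int i = 1; i <= np; ++i) {
            if (tc[i] < tmin) tmin = tc[i];
            if (tc[i] > tmax) tmax = tc[i];
          }
        }
      tr_step.push_back(s + 1);
      tr_time.push_back(t_start + (s + 1) * ht);
      tr_min.push_back(tmin);
      tr_max.push_back(tmax);
    }
  }

  NumericVector out(nn);
  for (int k = 0; k < np; ++k)
    for (int j = 0; j < np; ++j)
      for (int i = 0; i < np; ++i)
        out[fidx(i, j, k)] = cur[pidx(i, j, k)];

  NumericMatrix trace(tr_step.size(), 4);
  for (R_xlen_t r = 0; r < (R_xlen_t)tr_step.size(); ++r) {
    trace(r, 0) = tr_step[r];
    trace(r, 1) = tr_time[r];
    trace(r, 2) = tr_min[r];
    trace(r, 3) = tr_max[r];
  }
  colnames(trace) = CharacterVector::create("step", "time", "T_min", "T_max");

  return List::create(_["values"] = out,
                      _["time"] = t_start + (double)n_steps * ht,
                      _["n_steps"] = n_steps,
                      _["n_special"] = (double)specials.size(),
                      _["trace"] = trace);
}
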