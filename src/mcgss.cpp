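// Hot loops of the state-space MCG estimator:
//  - open-loop rollout of the Thiran all-pass propagation model
//  - neighbor-sparse Kalman filter over the 3Nv current-density states
//  - refinement-epoch forward pass with analytic gain / all-pass gradients
//
// Conventions: voxel and connection indices arrive 1-based from R and are
// converted here; state s of voxel v (0-based) is 3*v + s. Each connection
// carries 3 all-pass filters (one per source component); the 9 gains of a
// connection share those outputs, so gain (j,k) uses filter k.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// all-pass step: y(n) = a*(x(n-k) - y(n-1)) + x(n-k-1), zero state for n<0.
// Inputs are strictly causal: only rows <= n-1 of X are visible (k = 0,
// reachable through the coefficient wrap rules, reads 0 for the x(n) tap).
static inline double ap_step(const arma::mat& X, int n, int col, int k,
                             double a, double yprev) {
  const double x1 = (n - k >= 0 && k >= 1) ? X(n - k, col) : 0.0;
  const double x2 = (n - k - 1 >= 0) ? X(n - k - 1, col) : 0.0;
  return a * (x1 - yprev) + x2;
}

// [[Rcpp::export]]
arma::mat cpp_simulate(IntegerVector src, IntegerVector dst, IntegerVector k,
                       NumericVector a, NumericMatrix gains, NumericVector b,
                       NumericVector u, int nv, int n_steps) {
  const int nc = src.size();
  const int N = 3 * nv;
  arma::mat J(n_steps, N, arma::fill::zeros);
  arma::mat yprev(nc > 0 ? nc : 1, 3, arma::fill::zeros);
  for (int n = 0; n < n_steps; ++n) {
    arma::rowvec jn(N, arma::fill::zeros);
    for (int s = 0; s < N; ++s) jn(s) = b[s] * u[n];
    for (int c = 0; c < nc; ++c) {
      const int sv = 3 * (src[c] - 1), dv = 3 * (dst[c] - 1);
      double y[3];
      for (int kk = 0; kk < 3; ++kk) {
        y[kk] = ap_step(J, n, sv + kk, k[c], a[c], yprev(c, kk));
        yprev(c, kk) = y[kk];
      }
      for (int kk = 0; kk < 3; ++kk)
        for (int j = 0; j < 3; ++j)
          jn(dv + j) += gains(c, 3 * kk + j) * y[kk];
    }
    J.row(n) = jn;
  }
  return J;
}

// CSR helper: items[indptr[v] .. indptr[v+1]-1] belong to voxel v (0-based).
struct Csr {
  const int* indptr;
  const int* items;
};

// [[Rcpp::export]]
List cpp_kalman(IntegerVector src, IntegerVector dst, IntegerVector k,
                NumericVector a, NumericMatrix gains, NumericVector b,
                NumericVector u, const arma::mat& H, const arma::mat& Z,
                double q_diag, double r_diag, double p0_diag, int nv,
                IntegerVector supp_ptr, IntegerVector supp_idx,
                IntegerVector supp2_ptr, IntegerVector supp2_idx,
                bool feed_corrected) {
  const int nc = src.size();
  const int N = 3 * nv;
  const int Ns = H.n_rows;
  const int Nm = Z.n_rows;

  // incoming-connection lists per voxel
  std::vector<std::vector<int>> incoming(nv);
  for (int c = 0; c < nc; ++c) incoming[dst[c] - 1].push_back(c);

  arma::mat P(N, N, arma::fill::zeros);
  for (int i = 0; i < N; ++i) P(i, i) = p0_diag;
  arma::mat V(N, N, arma::fill::zeros);   // C*P on the 2-hop support
  arma::mat Pn(N, N, arma::fill::zeros);  // predicted covariance
  arma::mat HP(Ns, N);
  arma::mat Jc(Nm, N, arma::fill::zeros); // corrected trajectory
  arma::mat Jp(Nm, N, arma::fill::zeros); // predicted trajectory
  arma::mat innov(Nm, Ns, arma::fill::zeros);
  arma::mat Zhat(Nm, Ns, arma::fill::zeros);
  arma::mat yprev(nc > 0 ? nc : 1, 3, arma::fill::zeros);

  for (int n = 0; n < Nm; ++n) {
    const arma::mat& feed = feed_corrected ? Jc : Jp;
    // --- predict state (Eqs. 5, 7) ---
    arma::vec jp(N, arma::fill::zeros);
    for (int s = 0; s < N; ++s) jp(s) = b[s] * u[n];
    for (int c = 0; c < nc; ++c) {
      const int sv = 3 * (src[c] - 1), dv = 3 * (dst[c] - 1);
      for (int kk = 0; kk < 3; ++kk) {
        const double y = ap_step(feed, n, sv + kk, k[c], a[c], yprev(c, kk));
        yprev(c, kk) = y;
        for (int j = 0; j < 3; ++j) jp(dv + j) += gains(c, 3 * kk + j) * y;
      }
    }
    // --- predict covariance on the neighbor support (Eq. 11) ---
    // V(rows of d, cols in 2-hop of d) = sum over connections into d of C * P
    for (int d = 0; d < nv; ++d) {
      for (int p2 = supp2_ptr[d]; p2 < supp2_ptr[d + 1]; ++p2) {
        const int tv = 3 * (supp2_idx[p2] - 1);
        for (int j = 0; j < 3; ++j)
          for (int t = 0; t < 3; ++t) V(3 * d + j, tv + t) = 0.0;
      }
      for (size_t ci = 0; ci < incoming[d].size(); ++ci) {
        const int c = incoming[d][ci];
        const int sv = 3 * (src[c] - 1);
        for (int p2 = supp2_ptr[d]; p2 < supp2_ptr[d + 1]; ++p2) {
          const int tv = 3 * (supp2_idx[p2] - 1);
          for (int j = 0; j < 3; ++j)
            for (int t = 0; t < 3; ++t) {
              double acc = 0.0;
              for (int kk = 0; kk < 3; ++kk)
                acc += gains(c, 3 * kk + j) * P(sv + kk, tv + t);
              V(3 * d + j, tv + t) += acc;
            }
        }
      }
    }
    // Pn(i,o) = q + sum_t C(o,t) V(i,t), support pairs only
    for (int d = 0; d < nv; ++d) {
      for (int ps = supp_ptr[d]; ps < supp_ptr[d + 1]; ++ps) {
        const int ov = 3 * (supp_idx[ps] - 1);
        const int o_vox = supp_idx[ps] - 1;
        for (int j = 0; j < 3; ++j)
          for (int l = 0; l < 3; ++l) {
            double acc = 0.0;
            for (size_t ci = 0; ci < incoming[o_vox].size(); ++ci) {
              const int c = incoming[o_vox][ci];
              const int sv = 3 * (src[c] - 1);
              for (int kk = 0; kk < 3; ++kk)
                acc += gains(c, 3 * kk + l) * V(3 * d + j, sv + kk);
            }
            Pn(3 * d + j, ov + l) = acc;
          }
      }
    }
    for (int i = 0; i < N; ++i) Pn(i, i) += q_diag;
    // symmetrize on support
    for (int d = 0; d < nv; ++d)
      for (int ps = supp_ptr[d]; ps < supp_ptr[d + 1]; ++ps) {
        const int o = supp_idx[ps] - 1;
        if (o < d) continue;
        for (int j = 0; j < 3; ++j)
          for (int l = 0; l < 3; ++l) {
            const double m = 0.5 * (Pn(3 * d + j, 3 * o + l) +
                                    Pn(3 * o + l, 3 * d + j));
            Pn(3 * d + j, 3 * o + l) = m;
            Pn(3 * o + l, 3 * d + j) = m;
          }
      }
    // --- gain and innovation covariance (Eqs. 12-13) ---
    HP.zeros();
    for (int d = 0; d < nv; ++d)
      for (int ps = supp_ptr[d]; ps < supp_ptr[d + 1]; ++ps) {
        const int ov = 3 * (supp_idx[ps] - 1);
        for (int j = 0; j < 3; ++j) {
          const double* hc = H.colptr(3 * d + j);
          for (int l = 0; l < 3; ++l) {
            const double p = Pn(3 * d + j, ov + l);
            if (p != 0.0) {
              double* hp = HP.colptr(ov + l);
              for (int s = 0; s < Ns; ++s) hp[s] += p * hc[s];
            }
          }
        }
      }
    arma::mat S = HP * H.t();
    for (int i = 0; i < Ns; ++i) S(i, i) += r_diag;
    S = 0.5 * (S + S.t());
    arma::mat SiHP;
    bool ok = arma::solve(SiHP, S, HP, arma::solve_opts::likely_sympd);
    if (!ok) {
      arma::vec ev = arma::eig_sym(S);
      stop("innovation covariance S is singular (smallest eigenvalue %g)",
           ev.min());
    }
    // --- correct state (Eq. 14) ---
    arma::vec zh = H * jp;
    arma::vec resid = Z.row(n).t() - zh;
    arma::vec jc = jp + SiHP.t() * resid;  // K = (HP)' S^-1
    // --- correct covariance on support (Eq. 15): P - K HP ---
    for (int d = 0; d < nv; ++d)
      for (int ps = supp_ptr[d]; ps < supp_ptr[d + 1]; ++ps) {
        const int ov = 3 * (supp_idx[ps] - 1);
        for (int j = 0; j < 3; ++j) {
          const double* ki = SiHP.colptr(3 * d + j);  // K.row(i) as column of SiHP
          for (int l = 0; l < 3; ++l) {
            const double* hp = HP.colptr(ov + l);
            double acc = 0.0;
            for (int s = 0; s < Ns; ++s) acc += ki[s] * hp[s];
            P(3 * d + j, ov + l) = Pn(3 * d + j, ov + l) - acc;
          }
        }
      }
    for (int d = 0; d < nv; ++d)
      for (int ps = supp_ptr[d]; ps < supp_ptr[d + 1]; ++ps) {
        const int o = supp_idx[ps] - 1;
        if (o < d) continue;
        for (int j = 0; j < 3; ++j)
          for (int l = 0; l < 3; ++l) {
            const double m = 0.5 * (P(3 * d + j, 3 * o + l) +
                                    P(3 * o + l, 3 * d + j));
            P(3 * d + j, 3 * o + l) = m;
            P(3 * o + l, 3 * d + j) = m;
          }
      }
    for (int i = 0; i < N; ++i) if (P(i, i) < 0.0) P(i, i) = 0.0;

    Jp.row(n) = jp.t();
    Jc.row(n) = jc.t();
    Zhat.row(n) = zh.t();
    innov.row(n) = resid.t();
  }
  return List::create(_["filtered"] = Jc, _["predicted"] = Jp,
                      _["innovations"] = innov, _["z_hat"] = Zhat,
                      _["P_diag"] = arma::vec(P.diag()));
}

// [[Rcpp::export]]
List cpp_refine_forward(IntegerVector src, IntegerVector dst, IntegerVector k,
                        NumericVector a, NumericMatrix gains, NumericVector b,
                        NumericVector u, const arma::mat& H,
                        const arma::mat& Z, const arma::mat& Jhat,
                        double gamma, double hinge) {
  const int nc = src.size();
  const int N = H.n_cols;
  const int Ns = H.n_rows;
  const int Nm = Z.n_rows;

  arma::mat yprev(nc > 0 ? nc : 1, 3, arma::fill::zeros);
  arma::mat dprev(nc > 0 ? nc : 1, 3, arma::fill::zeros);
  arma::mat ycur(nc > 0 ? nc : 1, 3, arma::fill::zeros);
  arma::mat dcur(nc > 0 ? nc : 1, 3, arma::fill::zeros);
  arma::mat grad_c(nc > 0 ? nc : 1, 9, arma::fill::zeros);
  arma::vec grad_a(nc > 0 ? nc : 1, arma::fill::zeros);
  arma::vec Lm(Nm, arma::fill::zeros), Lv(Nm, arma::fill::zeros);
  arma::mat Jpred(Nm, N, arma::fill::zeros);
  arma::mat Zhat(Nm, Ns, arma::fill::zeros);

  for (int n = 0; n < Nm; ++n) {
    arma::vec jp(N, arma::fill::zeros);
    for (int s = 0; s < N; ++s) jp(s) = b[s] * u[n];
    for (int c = 0; c < nc; ++c) {
      const int sv = 3 * (src[c] - 1), dv = 3 * (dst[c] - 1);
      for (int kk = 0; kk < 3; ++kk) {
        const double x1 =
          (n - k[c] >= 0 && k[c] >= 1) ? Jhat(n - k[c], sv + kk) : 0.0;
        const double y = ap_step(Jhat, n, sv + kk, k[c], a[c], yprev(c, kk));
        // exact sensitivity of the all-pass recursion to a:
        // dy/da(n) = (x(n-k) - y(n-1)) - a * dy/da(n-1)
        const double d = (x1 - yprev(c, kk)) - a[c] * dprev(c, kk);
        ycur(c, kk) = y;
        dcur(c, kk) = d;
        for (int j = 0; j < 3; ++j) jp(dv + j) += gains(c, 3 * kk + j) * y;
      }
    }
    yprev = ycur;
    dprev = dcur;

    arma::vec zh = H * jp;
    arma::vec resid = zh - Z.row(n).t();          // z_hat - z
    Lm(n) = arma::dot(resid, resid) / Ns;
    arma::vec g = (2.0 / Ns) * (H.t() * resid);   // dLm/dj

    // hinge excess per voxel
    const int nv = N / 3;
    arma::vec hv(nv, arma::fill::zeros);
    for (int v = 0; v < nv; ++v) {
      const double l1 = std::abs(jp(3 * v)) + std::abs(jp(3 * v + 1)) +
                        std::abs(jp(3 * v + 2));
      const double e = l1 - hinge;
      if (e > 0.0) {
        hv(v) = e;
        Lv(n) += e * e;
      }
    }

    for (int c = 0; c < nc; ++c) {
      const int dvox = dst[c] - 1, dv = 3 * dvox;
      for (int kk = 0; kk < 3; ++kk) {
        const double y = ycur(c, kk), d = dcur(c, kk);
        double asum = 0.0;
        for (int j = 0; j < 3; ++j) {
          double gj = g(dv + j);
          if (hv(dvox) > 0.0) {
            const double sg = (jp(dv + j) > 0) - (jp(dv + j) < 0);
            gj += gamma * 2.0 * sg * hv(dvox);
          }
          grad_c(c, 3 * kk + j) += y * gj;
          asum += gains(c, 3 * kk + j) * g(dv + j);  // Lv excluded for a
        }
        grad_a(c) += d * asum;
      }
    }
    Jpred.row(n) = jp.t();
    Zhat.row(n) = zh.t();
  }
  return List::create(_["grad_c"] = grad_c, _["grad_a"] = grad_a,
                      _["Lm"] = Lm, _["Lv"] = Lv,
                      _["J_pred"] = Jpred, _["z_hat"] = Zhat);
}
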