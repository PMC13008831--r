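// Gibbs sampler core for multi-response linear mixed ("animal") models with
// pedigree-linked random effects, unstructured covariance blocks across age
// classes / response traits, right-censored Gaussian responses and binary
// probit (threshold) responses.
//
// Location effects are updated as one joint block: the mixed-model-equation
// coefficient matrix C = W' R^{-1} W + blockdiag(0, G_k^{-1} (x) K_k^{-1})
// is assembled on a fixed sparsity pattern, factored by a left-looking sparse
// Cholesky on the symbolic pattern precomputed in R (fill-reducing
// permutation from Matrix::Cholesky), and a draw is obtained as
// theta = C^{-1} W'R^{-1} y* + L^{-T} z. Covariance blocks are drawn from
// their conditional inverse-Wishart distributions; censored observations and
// binary liabilities are imputed from truncated-normal full conditionals.
//
// All randomness comes from R's RNG so that set.seed() in R makes runs
// exactly reproducible and chains prefix-extend when nitt is raised.

#include <Rcpp.h>
#include <Rmath.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------- small dense SPD helpers (d is 1..8) ----------

// in-place lower Cholesky, column-major; returns false if not PD
static bool chol_lower(std::vector<double>& A, int d) {
  for (int j = 0; j < d; ++j) {
    double s = A[j + j * d];
    for (int k = 0; k < j; ++k) s -= A[j + k * d] * A[j + k * d];
    if (s <= 0.0 || !R_finite(s)) return false;
    A[j + j * d] = std::sqrt(s);
    for (int i = j + 1; i < d; ++i) {
      double v = A[i + j * d];
      for (int k = 0; k < j; ++k) v -= A[i + k * d] * A[j + k * d];
      A[i + j * d] = v / A[j + j * d];
    }
  }
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < j; ++i) A[i + j * d] = 0.0;
  return true;
}

static bool inv_spd(const std::vector<double>& A, int d,
                    std::vector<double>& Ainv) {
  std::vector<double> L(A);
  if (!chol_lower(L, d)) return false;
  std::vector<double> Linv(d * d, 0.0);
  for (int j = 0; j < d; ++j) {
    Linv[j + j * d] = 1.0 / L[j + j * d];
    for (int i = j + 1; i < d; ++i) {
      double s = 0.0;
      for (int k = j; k < i; ++k) s += L[i + k * d] * Linv[k + j * d];
      Linv[i + j * d] = -s / L[i + i * d];
    }
  }
  Ainv.assign(d * d, 0.0);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) {
      double s = 0.0;
      for (int k = std::max(i, j); k < d; ++k)
        s += Linv[k + i * d] * Linv[k + j * d];
      Ainv[i + j * d] = s;
    }
  return true;
}

// G ~ IW(df, S)  <=>  G^{-1} ~ Wishart(df, S^{-1}); Bartlett decomposition.
// Returns both G and G^{-1}. Jitters a non-PD scale (counted in njit).
static bool riwish(int d, double df, std::vector<double> S,
                   std::vector<double>& G, std::vector<double>& Ginv,
                   int& njit) {
  std::vector<double> Sinv;
  bool ok = false;
  for (int tries = 0; tries < 8; ++tries) {
    if (inv_spd(S, d, Sinv)) { ok = true; break; }
    double tr = 0.0;
    for (int i = 0; i < d; ++i) tr += S[i + i * d];
    double eps = (tr <= 0.0 ? 1e-8 : tr * 1e-8) * std::pow(10.0, tries);
    for (int i = 0; i < d; ++i) S[i + i * d] += eps;
    ++njit;
  }
  if (!ok) return false;
  std::vector<double> Ls(Sinv);
  if (!chol_lower(Ls, d)) return false;
  std::vector<double> T(d * d, 0.0);
  for (int i = 0; i < d; ++i) {
    T[i + i * d] = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) T[i + j * d] = norm_rand();
  }
  std::vector<double> M(d * d, 0.0);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int k = j; k <= i; ++k) s += Ls[i + k * d] * T[k + j * d];
      M[i + j * d] = s;
    }
  Ginv.assign(d * d, 0.0);
  for (int i = 0; i < d; ++i)
    for (int j = 0; j < d; ++j) {
      double s = 0.0;
      for (int k = 0; k <= std::min(i, j); ++k)
        s += M[i + k * d] * M[j + k * d];
      Ginv[i + j * d] = s;
    }
  return inv_spd(Ginv, d, G);
}

// ---------- truncated normals (log-space inverse CDF, stable in the tail) --

static double rtnorm_lower(double mu, double sd, double a) {
  double alpha = (a - mu) / sd;
  double lp = R::pnorm(alpha, 0.0, 1.0, 0, 1); // log P(Z > alpha)
  double u = unif_rand();
  if (u < 1e-300) u = 1e-300;
  double z = R::qnorm(lp + std::log(u), 0.0, 1.0, 0, 1);
  if (!R_finite(z) || z < alpha) z = alpha + 1e-8;
  return mu + sd * z;
}

static double rtnorm_upper(double mu, double sd, double b) {
  return -rtnorm_lower(-mu, sd, -b);
}

// ---------- main sampler ----------

// [[Rcpp::export(name = ".gibbs_run")]]
List gibbs_run(List prob, List control) {
  // responses
  NumericVector y0 = prob["y"];          // observed value / bound / 0-1
  IntegerVector fam = prob["fam"];       // 0 gaussian, 1 right-censored, 2 binary
  NumericVector bound = prob["bound"];   // per-record censoring bound
  const int nrec = y0.size();

  // design rows (CSR)
  IntegerVector w_ptr = prob["w_ptr"], w_col = prob["w_col"];
  NumericVector w_val = prob["w_val"];
  const int ncol = as<int>(prob["ncol"]);
  const int p = as<int>(prob["p"]);

  // random-effect terms
  List terms = prob["terms"];
  const int nterm = terms.size();
  std::vector<int> t_off(nterm), t_q(nterm), t_d(nterm), t_iid(nterm);
  std::vector<IntegerVector> t_kp(nterm), t_ki(nterm);
  std::vector<NumericVector> t_kx(nterm);
  std::vector<IntegerVector> t_pidx(nterm), t_pa(nterm), t_pb(nterm);
  std::vector<NumericVector> t_pkx(nterm);
  std::vector<NumericVector> t_V(nterm);
  std::vector<double> t_nu(nterm);
  std::vector<int> t_px(nterm);
  std::vector<double> t_alphaV(nterm);
  std::vector<std::vector<double> > G(nterm), Ginv(nterm);
  for (int k = 0; k < nterm; ++k) {
    List tk = terms[k];
    t_off[k] = as<int>(tk["offset"]);
    t_q[k] = as<int>(tk["q"]);
    t_d[k] = as<int>(tk["d"]);
    t_iid[k] = as<int>(tk["iid"]);
    t_px[k] = as<int>(tk["px"]);
    t_alphaV[k] = as<double>(tk["alphaV"]);
    if (!t_iid[k]) {
      t_kp[k] = tk["kp"]; t_ki[k] = tk["ki"]; t_kx[k] = tk["kx"];
    }
    t_pidx[k] = tk["pidx"]; t_pa[k] = tk["pa"]; t_pb[k] = tk["pb"];
    t_pkx[k] = tk["pkx"];
    t_V[k] = tk["V"];
    t_nu[k] = as<double>(tk["nu"]);
    int d = t_d[k];
    G[k].assign(d * d, 0.0);
    for (int i = 0; i < d * d; ++i) G[k][i] = t_V[k][i];
    Ginv[k].assign(d * d, 0.0);
    int njit0 = 0;
    if (!inv_spd(G[k], d, Ginv[k]))
      stop("starting covariance for a random term is not positive definite");
    (void)njit0;
  }

  // residual structure
  const int rtype = as<int>(prob["rtype"]);
  IntegerVector rclass, rfixed, unit_r1, unit_r2;
  int nclass = 0, nunit = 0;
  double rv0 = 1.0, rnu = 0.002, lambda0 = 0.01;
  std::vector<double> rvar;
  double r11 = 1.0, r12 = 0.0; // bivariate unit residual (gaussian var, cov)
  if (rtype == 0) {
    rclass = prob["rclass"];
    rfixed = prob["rfixed"];
    nclass = as<int>(prob["nclass"]);
    rv0 = as<double>(prob["rv0"]);
    rnu = as<double>(prob["rnu"]);
    rvar.assign(nclass, rv0);
    for (int c = 0; c < nclass; ++c) if (rfixed[c]) rvar[c] = 1.0;
  } else {
    unit_r1 = prob["unit_r1"];
    unit_r2 = prob["unit_r2"];
    nunit = unit_r1.size();
    rv0 = as<double>(prob["rv0"]);
    rnu = as<double>(prob["rnu"]);
    lambda0 = as<double>(prob["lambda0"]);
  }

  // sparse-solve structures
  IntegerVector pivec = prob["pivec"];   // permuted slot -> original index
  IntegerVector Lp = prob["Lp"], Li = prob["Li"];
  IntegerVector rl_ptr = prob["rl_ptr"], rl_k = prob["rl_k"], rl_pos = prob["rl_pos"];
  IntegerVector cm_ptr = prob["cm_ptr"], cm_row = prob["cm_row"], cm_idx = prob["cm_idx"];
  IntegerVector dm_idx = prob["dm_idx"];
  IntegerVector xm_idx = prob["xm_idx"];
  IntegerVector ridge_idx = prob["ridge_idx"];
  const double ridge = as<double>(prob["ridge"]);
  const int ncnz = as<int>(prob["ncnz"]);
  const int Lnnz = Li.size();

  // controls
  const int nitt = as<int>(control["nitt"]);
  const int burnin = as<int>(control["burnin"]);
  const int thin = as<int>(control["thin"]);
  const bool store_latent = as<bool>(control["store_latent"]);
  // draw m is taken at iteration burnin + m*thin (1-based m), so the draw
  // count is floor((nitt - burnin) / thin)
  const int nstore = (nitt - burnin) / thin;

  // state
  std::vector<double> theta(ncol, 0.0), ystar(nrec), fitted(nrec, 0.0);
  for (int r = 0; r < nrec; ++r) {
    if (fam[r] == 0) ystar[r] = y0[r];
    else if (fam[r] == 1) ystar[r] = bound[r];
    else ystar[r] = (y0[r] > 0.5) ? 0.5 : -0.5;
  }
  std::vector<double> Cx(ncnz), rhs(ncol), Lx(Lnnz), xsc(ncol, 0.0),
    bp(ncol), vtmp(ncol);
  int njit = 0;

  // storage
  NumericMatrix fixed_draws(nstore, p);
  std::vector<NumericMatrix> vc_draws(nterm);
  for (int k = 0; k < nterm; ++k) {
    int d = t_d[k];
    vc_draws[k] = NumericMatrix(nstore, d * (d + 1) / 2);
  }
  NumericMatrix resid_draws(nstore, rtype == 0 ? nclass : 2);
  NumericMatrix latent_draws(store_latent ? nstore : 0,
                             store_latent ? nrec : 0);
  std::vector<double> theta_sum(ncol, 0.0);
  int istore = 0;

  for (int it = 0; it < nitt; ++it) {
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();

    // (1) impute censored observations and binary liabilities
    if (rtype == 0) {
      for (int r = 0; r < nrec; ++r) {
        if (fam[r] == 1) {
          double sd = std::sqrt(rvar[rclass[r]]);
          ystar[r] = rtnorm_lower(fitted[r], sd, bound[r]);
        } else if (fam[r] == 2) {
          double sd = std::sqrt(rvar[rclass[r]]); // fixed at 1 for probit
          ystar[r] = (y0[r] > 0.5)
            ? rtnorm_lower(fitted[r], sd, 0.0)
            : rtnorm_upper(fitted[r], sd, 0.0);
        }
      }
    } else {
      for (int u = 0; u < nunit; ++u) {
        int r1 = unit_r1[u], r2 = unit_r2[u];
        double e1 = ystar[r1] - fitted[r1];
        double cm = fitted[r2] + (r12 / r11) * e1;
        double cv = 1.0 - r12 * r12 / r11;
        if (cv < 1e-12) cv = 1e-12;
        ystar[r2] = (y0[r2] > 0.5)
          ? rtnorm_lower(cm, std::sqrt(cv), 0.0)
          : rtnorm_upper(cm, std::sqrt(cv), 0.0);
      }
    }

    // (2) assemble C (fixed pattern) and rhs = W' R^{-1} y*
    std::fill(Cx.begin(), Cx.end(), 0.0);
    std::fill(rhs.begin(), rhs.end(), 0.0);
    for (int t = 0; t < ridge_idx.size(); ++t) Cx[ridge_idx[t]] += ridge;
    for (int k = 0; k < nterm; ++k) {
      const IntegerVector& pidx = t_pidx[k];
      const IntegerVector& pa = t_pa[k];
      const IntegerVector& pb = t_pb[k];
      const NumericVector& pkx = t_pkx[k];
      const std::vector<double>& Gi = Ginv[k];
      const int d = t_d[k];
      const int np = pidx.size();
      for (int t = 0; t < np; ++t)
        Cx[pidx[t]] += Gi[pa[t] + pb[t] * d] * pkx[t];
    }
    if (rtype == 0) {
      int pos = 0;
      for (int r = 0; r < nrec; ++r) {
        double rinv = 1.0 / rvar[rclass[r]];
        int a0 = w_ptr[r], a1 = w_ptr[r + 1];
        double ry = rinv * ystar[r];
        for (int a = a0; a < a1; ++a) {
          double wa = w_val[a] * rinv;
          rhs[w_col[a]] += w_val[a] * ry;
          for (int b = a0; b < a1; ++b)
            Cx[dm_idx[pos++]] += wa * w_val[b];
        }
      }
    } else {
      double det = r11 - r12 * r12;
      double i11 = 1.0 / det, i22 = r11 / det, i12 = -r12 / det;
      int pos = 0;
      // same-record blocks
      for (int r = 0; r < nrec; ++r) {
        double rinv = (fam[r] == 2) ? i22 : i11;
        int a0 = w_ptr[r], a1 = w_ptr[r + 1];
        for (int a = a0; a < a1; ++a) {
          double wa = w_val[a] * rinv;
          for (int b = a0; b < a1; ++b)
            Cx[dm_idx[pos++]] += wa * w_val[b];
        }
      }
      // cross-record blocks within units + rhs
      int pos2 = 0;
      for (int u = 0; u < nunit; ++u) {
        int r1 = unit_r1[u], r2 = unit_r2[u];
        int a0 = w_ptr[r1], a1 = w_ptr[r1 + 1];
        int b0 = w_ptr[r2], b1 = w_ptr[r2 + 1];
        for (int a = a0; a < a1; ++a)
          for (int b = b0; b < b1; ++b) {
            double v = w_val[a] * w_val[b] * i12;
            Cx[xm_idx[pos2++]] += v;
            Cx[xm_idx[pos2++]] += v;
          }
        double z1 = i11 * ystar[r1] + i12 * ystar[r2];
        double z2 = i12 * ystar[r1] + i22 * ystar[r2];
        for (int a = a0; a < a1; ++a) rhs[w_col[a]] += w_val[a] * z1;
        for (int b = b0; b < b1; ++b) rhs[w_col[b]] += w_val[b] * z2;
      }
    }

    // (3) left-looking sparse Cholesky on the fixed pattern
    for (int j = 0; j < ncol; ++j) {
      for (int t = Lp[j]; t < Lp[j + 1]; ++t) xsc[Li[t]] = 0.0;
      for (int t = cm_ptr[j]; t < cm_ptr[j + 1]; ++t)
        xsc[cm_row[t]] = Cx[cm_idx[t]];
      for (int t = rl_ptr[j]; t < rl_ptr[j + 1]; ++t) {
        int k = rl_k[t], pos = rl_pos[t];
        double ljk = Lx[pos];
        for (int u = pos; u < Lp[k + 1]; ++u) xsc[Li[u]] -= Lx[u] * ljk;
      }
      double dj = xsc[j];
      if (dj < 1e-10 || !R_finite(dj)) { dj = 1e-10; ++njit; }
      dj = std::sqrt(dj);
      Lx[Lp[j]] = dj;
      for (int t = Lp[j] + 1; t < Lp[j + 1]; ++t) Lx[t] = xsc[Li[t]] / dj;
    }

    // (4) theta = C^{-1} rhs + L^{-T} z  (single fused backward solve)
    for (int k = 0; k < ncol; ++k) bp[k] = rhs[pivec[k]];
    for (int j = 0; j < ncol; ++j) {            // forward: L c = b
      double cj = bp[j] / Lx[Lp[j]];
      bp[j] = cj;
      for (int t = Lp[j] + 1; t < Lp[j + 1]; ++t) bp[Li[t]] -= Lx[t] * cj;
    }
    for (int j = 0; j < ncol; ++j) bp[j] += norm_rand();
    for (int j = ncol - 1; j >= 0; --j) {        // backward: L' v = c + z
      double s = bp[j];
      for (int t = Lp[j] + 1; t < Lp[j + 1]; ++t) s -= Lx[t] * vtmp[Li[t]];
      vtmp[j] = s / Lx[Lp[j]];
    }
    for (int k = 0; k < ncol; ++k) theta[pivec[k]] = vtmp[k];

    // (5) fitted values and residuals
    for (int r = 0; r < nrec; ++r) {
      double f = 0.0;
      for (int a = w_ptr[r]; a < w_ptr[r + 1]; ++a)
        f += w_val[a] * theta[w_col[a]];
      fitted[r] = f;
    }

    // (5b) parameter expansion: redundant working-scale draw per flagged
    // term (one multiplier per trait), improving mixing of variance blocks
    // near zero and of scale trade-offs between terms
    std::vector<std::vector<double> > px_alpha(nterm);
    for (int k = 0; k < nterm; ++k)
      px_alpha[k].assign(t_d[k], 1.0);
    for (int k = 0; k < nterm; ++k) {
      if (!t_px[k]) continue;
      const int d = t_d[k], q = t_q[k], off = t_off[k];
      const int hi = off + q * d;
      std::vector<double> Ca(d * d, 0.0), ra(d, 0.0);
      if (rtype == 0) {
        for (int r = 0; r < nrec; ++r) {
          double c = 0.0; int a = -1;
          for (int t = w_ptr[r]; t < w_ptr[r + 1]; ++t) {
            int col = w_col[t];
            if (col >= off && col < hi) {
              a = (col - off) / q; c = theta[col] * w_val[t]; break;
            }
          }
          if (a < 0) continue;
          double rinv = 1.0 / rvar[rclass[r]];
          double res = (ystar[r] - fitted[r]) + c;
          Ca[a + a * d] += c * c * rinv;
          ra[a] += c * res * rinv;
        }
      } else {
        double det = r11 - r12 * r12;
        double iv[2][2] = {{1.0 / det, -r12 / det},
                           {-r12 / det, r11 / det}};
        for (int u = 0; u < nunit; ++u) {
          int rr[2] = {unit_r1[u], unit_r2[u]};
          double cc[2] = {0.0, 0.0}, rs[2];
          int aa[2] = {-1, -1};
          for (int s = 0; s < 2; ++s) {
            int r = rr[s];
            for (int t = w_ptr[r]; t < w_ptr[r + 1]; ++t) {
              int col = w_col[t];
              if (col >= off && col < hi) {
                aa[s] = (col - off) / q; cc[s] = theta[col] * w_val[t]; break;
              }
            }
            rs[s] = (ystar[r] - fitted[r]) + (aa[s] >= 0 ? cc[s] : 0.0);
          }
          for (int s = 0; s < 2; ++s) {
            if (aa[s] < 0) continue;
            for (int t = 0; t < 2; ++t) {
              if (aa[t] >= 0)
                Ca[aa[s] + aa[t] * d] += cc[s] * iv[s][t] * cc[t];
              ra[aa[s]] += cc[s] * iv[s][t] * rs[t];
            }
          }
        }
      }
      for (int a = 0; a < d; ++a) Ca[a + a * d] += 1.0 / t_alphaV[k];
      std::vector<double> Lc(Ca);
      if (!chol_lower(Lc, d)) continue;
      std::vector<double> z1(d), mu(d);
      for (int i2 = 0; i2 < d; ++i2) {
        double s2 = ra[i2];
        for (int j2 = 0; j2 < i2; ++j2) s2 -= Lc[i2 + j2 * d] * z1[j2];
        z1[i2] = s2 / Lc[i2 + i2 * d];
      }
      for (int i2 = 0; i2 < d; ++i2) z1[i2] += norm_rand();
      for (int i2 = d - 1; i2 >= 0; --i2) {
        double s2 = z1[i2];
        for (int j2 = i2 + 1; j2 < d; ++j2) s2 -= Lc[j2 + i2 * d] * mu[j2];
        mu[i2] = s2 / Lc[i2 + i2 * d];
      }
      bool ok = true;
      for (int a = 0; a < d; ++a)
        if (!R_finite(mu[a]) || std::fabs(mu[a]) < 1e-8) ok = false;
      if (!ok) continue;
      for (int a = 0; a < d; ++a) {
        px_alpha[k][a] = mu[a];
        for (int i2 = 0; i2 < q; ++i2) theta[off + a * q + i2] *= mu[a];
      }
      for (int r = 0; r < nrec; ++r) {   // refresh fitted after rescale
        double f = 0.0;
        for (int a = w_ptr[r]; a < w_ptr[r + 1]; ++a)
          f += w_val[a] * theta[w_col[a]];
        fitted[r] = f;
      }
    }

    // (6) covariance blocks: G_k ~ IW(nu + q, nu V + U' K^{-1} U)
    for (int k = 0; k < nterm; ++k) {
      int d = t_d[k], q = t_q[k], off = t_off[k];
      std::vector<double> S(d * d, 0.0);
      if (t_iid[k]) {
        for (int a = 0; a < d; ++a)
          for (int b = 0; b <= a; ++b) {
            double s = 0.0;
            const double* ua = &theta[off + a * q];
            const double* ub = &theta[off + b * q];
            for (int i = 0; i < q; ++i) s += ua[i] * ub[i];
            S[a + b * d] = s; S[b + a * d] = s;
          }
      } else {
        const IntegerVector& kp = t_kp[k];
        const IntegerVector& ki = t_ki[k];
        const NumericVector& kx = t_kx[k];
        for (int j = 0; j < q; ++j)
          for (int t = kp[j]; t < kp[j + 1]; ++t) {
            int i = ki[t];
            double v = kx[t];
            for (int a = 0; a < d; ++a) {
              double uia = theta[off + a * q + i] * v;
              for (int b = 0; b < d; ++b)
                S[a + b * d] += uia * theta[off + b * q + j];
            }
          }
        for (int a = 0; a < d; ++a)  // enforce exact symmetry
          for (int b = 0; b < a; ++b) {
            double m = 0.5 * (S[a + b * d] + S[b + a * d]);
            S[a + b * d] = m; S[b + a * d] = m;
          }
      }
      double nu = t_nu[k];
      if (t_px[k]) {
        // S was accumulated on the effective scale; map to the working scale
        // v = u / alpha, draw the working covariance, then scale back
        const std::vector<double>& al = px_alpha[k];
        for (int a = 0; a < d; ++a)
          for (int b = 0; b < d; ++b)
            S[a + b * d] /= al[a] * al[b];
      }
      for (int i = 0; i < d; ++i)
        for (int j = 0; j < d; ++j)
          S[i + j * d] += nu * t_V[k][i + j * d];
      if (!riwish(d, nu + q, S, G[k], Ginv[k], njit))
        stop("inverse-Wishart draw failed for a covariance block (iteration %d)",
             it + 1);
      if (t_px[k]) {
        const std::vector<double>& al = px_alpha[k];
        for (int a = 0; a < d; ++a)
          for (int b = 0; b < d; ++b)
            G[k][a + b * d] *= al[a] * al[b];
        if (!inv_spd(G[k], d, Ginv[k]))
          stop("effective covariance not positive definite (iteration %d)",
               it + 1);
      }
    }

    // (7) residual covariances
    if (rtype == 0) {
      std::vector<double> sse(nclass, 0.0);
      std::vector<int> nobs(nclass, 0);
      for (int r = 0; r < nrec; ++r) {
        double e = ystar[r] - fitted[r];
        sse[rclass[r]] += e * e;
        nobs[rclass[r]] += 1;
      }
      for (int c = 0; c < nclass; ++c) {
        if (rfixed[c]) { rvar[c] = 1.0; continue; }
        rvar[c] = (rnu * rv0 + sse[c]) / R::rchisq(rnu + nobs[c]);
      }
    } else {
      // conditional-regression update of [[r11, r12], [r12, 1]] with the
      // binary diagonal fixed: e1 | e2 ~ N(gamma e2, psi)
      double s22 = 0.0, s12 = 0.0, s11 = 0.0;
      for (int u = 0; u < nunit; ++u) {
        double e1 = ystar[unit_r1[u]] - fitted[unit_r1[u]];
        double e2 = ystar[unit_r2[u]] - fitted[unit_r2[u]];
        s22 += e2 * e2; s12 += e1 * e2; s11 += e1 * e1;
      }
      double lam_n = lambda0 + s22;
      double gam_n = s12 / lam_n;
      double ss = s11 - gam_n * gam_n * lam_n;
      if (ss < 0.0) ss = 0.0;
      double psi = (rnu * rv0 + ss) / R::rchisq(rnu + nunit);
      double gam = gam_n + std::sqrt(psi / lam_n) * norm_rand();
      r12 = gam;
      r11 = psi + gam * gam;
    }

    // (8) store
    if (it >= burnin && (it - burnin + 1) % thin == 0 && istore < nstore) {
      for (int j = 0; j < p; ++j) fixed_draws(istore, j) = theta[j];
      for (int k = 0; k < nterm; ++k) {
        int d = t_d[k], col = 0;
        for (int b = 0; b < d; ++b)
          for (int a = b; a < d; ++a)
            vc_draws[k](istore, col++) = G[k][a + b * d];
      }
      if (rtype == 0) {
        for (int c = 0; c < nclass; ++c) resid_draws(istore, c) = rvar[c];
      } else {
        resid_draws(istore, 0) = r11;
        resid_draws(istore, 1) = r12;
      }
      if (store_latent)
        for (int r = 0; r < nrec; ++r) latent_draws(istore, r) = ystar[r];
      for (int j = 0; j < ncol; ++j) theta_sum[j] += theta[j];
      ++istore;
    }
  }

  NumericVector theta_mean(ncol);
  if (istore > 0)
    for (int j = 0; j < ncol; ++j) theta_mean[j] = theta_sum[j] / istore;

  List vc_out(nterm);
  for (int k = 0; k < nterm; ++k) vc_out[k] = vc_draws[k];
  return List::create(_["fixed"] = fixed_draws, _["vc"] = vc_out,
                      _["resid"] = resid_draws,
                      _["theta_mean"] = theta_mean,
                      _["latent"] = latent_draws,
                      _["njitter"] = njit, _["nstore"] = istore);
}
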