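#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Simulation engine and Gibbs sampler inner loops. All randomness goes
// through R's RNG so that set.seed() in R gives bit-identical output.

// Centered dosage matrix; column j ~ Binomial(2, maf[j]) i.i.d.
// [[Rcpp::export(name = ".gen_genotypes_cpp")]]
NumericMatrix gen_genotypes_cpp(int n, NumericVector maf) {
  int m = maf.size();
  NumericMatrix G(n, m);
  for (int j = 0; j < m; ++j) {
    double p = maf[j], s = 0.0;
    // inverse-CDF draw of Binomial(2, p) from one uniform
    double q0 = (1.0 - p) * (1.0 - p);
    double q1 = q0 + 2.0 * p * (1.0 - p);
    double *col = &G(0, j);
    for (int i = 0; i < n; ++i) {
      double u = unif_rand();
      double g = (u > q0 ? 1.0 : 0.0) + (u > q1 ? 1.0 : 0.0);
      col[i] = g;
      s += g;
    }
    double mu = s / n;
    for (int i = 0; i < n; ++i) col[i] -= mu;
  }
  return G;
}

// [[Rcpp::export(name = ".matvec_cpp")]]
NumericVector matvec_cpp(NumericMatrix G, NumericVector v) {
  int n = G.nrow(), m = G.ncol();
  NumericVector out(n);
  for (int j = 0; j < m; ++j) {
    double vj = v[j];
    if (vj == 0.0) continue;
    const double *col = &G(0, j);
    for (int i = 0; i < n; ++i) out[i] += col[i] * vj;
  }
  return out;
}

// Column sums of squares about the column mean, over rows a..b (1-based).
// [[Rcpp::export(name = ".col_ss_cpp")]]
NumericVector col_ss_cpp(NumericMatrix G, int a, int b) {
  int m = G.ncol();
  int n = b - a + 1;
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double *col = &G(0, j);
    double s = 0.0, s2 = 0.0;
    for (int i = a - 1; i < b; ++i) {
      s += col[i];
      s2 += col[i] * col[i];
    }
    out[j] = s2 - s * s / n;
  }
  return out;
}

// Per-SNP simple linear regression y ~ 1 + G_j over rows a..b of G.
// Returns m x 3 matrix (beta, se, p).
// [[Rcpp::export(name = ".gwas_scan_cpp")]]
NumericMatrix gwas_scan_cpp(NumericMatrix G, NumericVector y, int a, int b) {
  int m = G.ncol();
  int n = b - a + 1;
  double Sy = 0.0, Syy = 0.0;
  for (int i = 0; i < n; ++i) {
    Sy += y[i];
    Syy += y[i] * y[i];
  }
  double syy = Syy - Sy * Sy / n;
  NumericMatrix out(m, 3);
  for (int j = 0; j < m; ++j) {
    const double *col = &G(0, j);
    double Sx = 0.0, Sxx = 0.0, Sxy = 0.0;
    for (int i = 0; i < n; ++i) {
      double x = col[a - 1 + i];
      Sx += x;
      Sxx += x * x;
      Sxy += x * y[i];
    }
    double sxx = Sxx - Sx * Sx / n;
    double sxy = Sxy - Sx * Sy / n;
    double beta = sxy / sxx;
    double rss = syy - beta * sxy;
    if (rss < 0) rss = 0;
    double se = std::sqrt(rss / (n - 2) / sxx);
    double p = (se > 0) ? 2.0 * R::pnorm(-std::fabs(beta / se), 0.0, 1.0, 1, 0)
                        : 0.0;
    out(j, 0) = beta;
    out(j, 1) = se;
    out(j, 2) = p;
  }
  return out;
}

// Cholesky solve of a small SPD system; also returns the requested diagonal
// element of the inverse. A is k x k (row-major in flat array), overwritten.
static bool chol_small(double *A, int k) {
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = A[i * k + j];
      for (int l = 0; l < j; ++l) s -= A[i * k + l] * A[j * k + l];
      if (i == j) {
        if (s <= 0) return false;
        A[i * k + i] = std::sqrt(s);
      } else {
        A[i * k + j] = s / A[j * k + j];
      }
    }
  }
  return true;
}

static void chol_solve(const double *L, int k, const double *rhs, double *x) {
  // L lower-triangular from chol_small; solves L L' x = rhs
  for (int i = 0; i < k; ++i) {
    double s = rhs[i];
    for (int l = 0; l < i; ++l) s -= L[i * k + l] * x[l];
    x[i] = s / L[i * k + i];
  }
  for (int i = k - 1; i >= 0; --i) {
    double s = x[i];
    for (int l = i + 1; l < k; ++l) s -= L[l * k + i] * x[l];
    x[i] = s / L[i * k + i];
  }
}

// Per-SNP interaction scan: y ~ 1 + G_j + E + G_j:E over rows a..b.
// Reports the interaction coefficient. Returns m x 3 (beta, se, p).
// [[Rcpp::export(name = ".gwis_scan_cpp")]]
NumericMatrix gwis_scan_cpp(NumericMatrix G, NumericVector y, NumericVector E,
                            int a, int b) {
  int m = G.ncol();
  int n = b - a + 1;
  double Se = 0.0, See = 0.0, Sy = 0.0, Syy = 0.0, Sey = 0.0;
  for (int i = 0; i < n; ++i) {
    Se += E[i];
    See += E[i] * E[i];
    Sy += y[i];
    Syy += y[i] * y[i];
    Sey += E[i] * y[i];
  }
  NumericMatrix out(m, 3);
  for (int j = 0; j < m; ++j) {
    const double *col = &G(0, j) + (a - 1);
    double Sx = 0, Sxx = 0, Sxe = 0, Sxxe = 0, Sxee = 0, Sxxee = 0;
    double Sxy = 0, Sxey = 0;
    for (int i = 0; i < n; ++i) {
      double x = col[i], e = E[i], xe = x * e;
      Sx += x;
      Sxx += x * x;
      Sxe += xe;
      Sxxe += x * xe;
      Sxee += xe * e;
      Sxxee += xe * xe;
      Sxy += x * y[i];
      Sxey += xe * y[i];
    }
    double XtX[16] = {(double)n, Sx,   Se,   Sxe,  Sx,  Sxx,  Sxe,  Sxxe,
                      Se,        Sxe,  See,  Sxee, Sxe, Sxxe, Sxee, Sxxee};
    double Xty[4] = {Sy, Sxy, Sey, Sxey};
    double L[16];
    for (int k = 0; k < 16; ++k) L[k] = XtX[k];
    if (!chol_small(L, 4)) {
      out(j, 0) = NA_REAL;
      out(j, 1) = NA_REAL;
      out(j, 2) = NA_REAL;
      continue;
    }
    double coef[4], e4[4] = {0, 0, 0, 1}, inv4[4];
    chol_solve(L, 4, Xty, coef);
    chol_solve(L, 4, e4, inv4);
    double fit = 0;
    for (int k = 0; k < 4; ++k) fit += coef[k] * Xty[k];
    double rss = Syy - fit;
    if (rss < 0) rss = 0;
    double sigma2 = rss / (n - 4);
    double se = std::sqrt(sigma2 * inv4[3]);
    double beta = coef[3];
    double p = (se > 0) ? 2.0 * R::pnorm(-std::fabs(beta / se), 0.0, 1.0, 1, 0)
                        : 0.0;
    out(j, 0) = beta;
    out(j, 1) = se;
    out(j, 2) = p;
  }
  return out;
}

// Blocked Gibbs sampler for the MERLIN hierarchical model under an identity
// LD matrix (independent instruments), where every conditional factorizes
// over SNPs. Mean structure per SNP j (w3, w4 per modifier kind):
//   y1_j ~ N(g_j, s1_j^2)
//   y2_j ~ N(h_j, s2_j^2)
//   y3_j ~ N(bA*g_j + b_j + bI*w3_j*h_j, s3_j^2)
//   y4_j ~ N(bI*g_j + (bA + bI*w4_j)*h_j, s4_j^2)      [if use_block4]
// Priors g ~ N(0, sig1 I), b ~ N(0, sig2 I), h ~ N(0, sig3 I); flat on
// (bA, bI); sig_k ~ InvGamma(a0, b0).
// Returns n_keep x 5 matrix of draws (bA, bI, sig1, sig2, sig3).
// [[Rcpp::export(name = ".merlin_gibbs_diag_cpp")]]
NumericMatrix merlin_gibbs_diag_cpp(NumericVector y1, NumericVector y2,
                                    NumericVector y3, NumericVector y4,
                                    NumericVector s1, NumericVector s2,
                                    NumericVector s3, NumericVector s4,
                                    NumericVector w3, NumericVector w4,
                                    bool use_block4, double a0, double b0,
                                    int n_iter, int n_burnin, bool fixI,
                                    double betaI_fix) {
  int M = y1.size();
  std::vector<double> d1(M), d2(M), d3(M), d4(M), g(M), h(M), b(M, 0.0);
  for (int j = 0; j < M; ++j) {
    d1[j] = 1.0 / (s1[j] * s1[j]);
    d2[j] = 1.0 / (s2[j] * s2[j]);
    d3[j] = 1.0 / (s3[j] * s3[j]);
    d4[j] = use_block4 ? 1.0 / (s4[j] * s4[j]) : 0.0;
    g[j] = y1[j];
    h[j] = y2[j];
  }
  double sig1 = 0, sig2 = 0, sig3 = 0;
  for (int j = 0; j < M; ++j) {
    sig1 += y1[j] * y1[j];
    sig3 += y2[j] * y2[j];
  }
  sig1 = sig1 / M + 1e-6;
  sig3 = sig3 / M + 1e-6;
  sig2 = 1e-3;
  double bA = 0.0, bI = fixI ? betaI_fix : 0.0;
  int n_keep = n_iter - n_burnin;
  NumericMatrix draws(n_keep, 5);

  for (int it = 0; it < n_iter; ++it) {
    // g | rest
    for (int j = 0; j < M; ++j) {
      double P = d1[j] + bA * bA * d3[j] + bI * bI * d4[j] + 1.0 / sig1;
      double r3 = y3[j] - b[j] - bI * w3[j] * h[j];
      double r4 = y4[j] - (bA + bI * w4[j]) * h[j];
      double rhs = d1[j] * y1[j] + bA * d3[j] * r3 + bI * d4[j] * r4;
      g[j] = rhs / P + norm_rand() / std::sqrt(P);
    }
    // h | rest
    for (int j = 0; j < M; ++j) {
      double c3 = bI * w3[j];
      double c4 = bA + bI * w4[j];
      double P = d2[j] + c3 * c3 * d3[j] + c4 * c4 * d4[j] + 1.0 / sig3;
      double r3 = y3[j] - bA * g[j] - b[j];
      double r4 = y4[j] - bI * g[j];
      double rhs = d2[j] * y2[j] + c3 * d3[j] * r3 + c4 * d4[j] * r4;
      h[j] = rhs / P + norm_rand() / std::sqrt(P);
    }
    // b | rest (pleiotropy)
    for (int j = 0; j < M; ++j) {
      double P = d3[j] + 1.0 / sig2;
      double rhs = d3[j] * (y3[j] - bA * g[j] - bI * w3[j] * h[j]);
      b[j] = rhs / P + norm_rand() / std::sqrt(P);
    }
    // (bA, bI) | rest: GLS with regressors u (for bA) and v (for bI)
    double T11 = 0, T12 = 0, T22 = 0, R1 = 0, R2 = 0;
    for (int j = 0; j < M; ++j) {
      double u3 = g[j], v3 = w3[j] * h[j], e3 = y3[j] - b[j];
      T11 += d3[j] * u3 * u3;
      T12 += d3[j] * u3 * v3;
      T22 += d3[j] * v3 * v3;
      R1 += d3[j] * u3 * e3;
      R2 += d3[j] * v3 * e3;
      if (use_block4) {
        double u4 = h[j], v4 = g[j] + w4[j] * h[j], e4 = y4[j];
        T11 += d4[j] * u4 * u4;
        T12 += d4[j] * u4 * v4;
        T22 += d4[j] * v4 * v4;
        R1 += d4[j] * u4 * e4;
        R2 += d4[j] * v4 * e4;
      }
    }
    if (fixI) {
      bI = betaI_fix;
      double mean = (R1 - T12 * bI) / T11;
      bA = mean + norm_rand() / std::sqrt(T11);
    } else {
      // T = L L', draw = mean + L'^{-1} z has covariance T^{-1}
      double L11 = std::sqrt(T11);
      double L21 = T12 / L11;
      double L22 = std::sqrt(T22 - L21 * L21);
      double m1 = R1 / L11;
      double m2 = (R2 - L21 * m1) / L22;
      double meanI = m2 / L22;
      double meanA = (m1 - L21 * meanI) / L11;
      double z1 = norm_rand(), z2 = norm_rand();
      bI = meanI + z2 / L22;
      bA = meanA + (z1 - L21 * z2 / L22) / L11;
    }
    // variance components | rest
    double ssg = 0, ssb = 0, ssh = 0;
    for (int j = 0; j < M; ++j) {
      ssg += g[j] * g[j];
      ssb += b[j] * b[j];
      ssh += h[j] * h[j];
    }
    double shape = a0 + 0.5 * M;
    sig1 = (b0 + 0.5 * ssg) / R::rgamma(shape, 1.0);
    sig2 = (b0 + 0.5 * ssb) / R::rgamma(shape, 1.0);
    sig3 = (b0 + 0.5 * ssh) / R::rgamma(shape, 1.0);
    if (!(sig1 > 1e-12)) sig1 = 1e-12;
    if (!(sig2 > 1e-12)) sig2 = 1e-12;
    if (!(sig3 > 1e-12)) sig3 = 1e-12;

    if (it >= n_burnin) {
      int k = it - n_burnin;
      draws(k, 0) = bA;
      draws(k, 1) = bI;
      draws(k, 2) = sig1;
      draws(k, 3) = sig2;
      draws(k, 4) = sig3;
    }
  }
  return draws;
}
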