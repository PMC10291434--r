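#include <Rcpp.h>
using namespace Rcpp;

// Joint log-posterior (up to a constant) and gradient for the social
// relations model with block effects, on the unconstrained scale used by the
// HMC sampler.
//
// Parameter vector layout (all unconstrained):
//   [0]                    alpha
//   [1 .. ks]              gamma for sender covariates
//   [.. ks+kd]             gamma for dyadic covariates
//   [.. +4*nb]             block matrices, column-major per block
//   [.. +5]                log sigma_lambda, log sigma_pi, atanh rho_gen,
//                          log sigma_delta, atanh rho_dyad
//   [.. +4 if double]      logit recall_give, logit recall_receive,
//                          logit fp_give, logit fp_receive
//   [.. +2n]               z1_gen, z2_gen (non-centered sender/receiver)
//   [.. +2*nd]             u1_dyad, u2_dyad (non-centered dyadic), dyads
//                          enumerated in R upper.tri order (column-major)
//
// Random effects are non-centered: lambda_i = sl*z1_i,
// pi_i = sp*(rg*z1_i + sqrt(1-rg^2)*z2_i), and for dyad (i<j)
// delta_ij = sd*u1, delta_ji = sd*(rd*u1 + sqrt(1-rd^2)*u2).

static inline double srm_log1pexp(double x) {
  return x > 0 ? x + log1p(exp(-x)) : log1p(exp(x));
}

// [[Rcpp::export(name = ".srm_lp_grad")]]
List srm_lp_grad(NumericVector theta, List data) {
  const int mode = as<int>(data["mode"]); // 0 single, 1 double
  const int n = as<int>(data["n"]);
  List Xs = data["Xs"];
  List Xd = data["Xd"];
  List blocks = data["blocks"];
  const int ks = Xs.size(), kd = Xd.size(), nb = blocks.size();
  const int nd = n * (n - 1) / 2;

  const double sd_coef = as<double>(data["sd_coef"]);
  const double sd_scale = as<double>(data["sd_scale"]);
  const double recall_a = as<double>(data["recall_a"]);
  const double recall_b = as<double>(data["recall_b"]);
  const double fp_a = as<double>(data["fp_a"]);
  const double fp_b = as<double>(data["fp_b"]);

  int off = 0;
  const double alpha = theta[off++];
  std::vector<double> gs(ks), gd(kd);
  for (int k = 0; k < ks; ++k) gs[k] = theta[off++];
  for (int k = 0; k < kd; ++k) gd[k] = theta[off++];
  const int off_B = off;
  std::vector<double> B(4 * nb);
  for (int b = 0; b < 4 * nb; ++b) B[b] = theta[off++];
  const int off_re = off;
  const double t_sl = theta[off++], t_sp = theta[off++];
  const double a_rg = theta[off++];
  const double t_sd = theta[off++], a_rd = theta[off++];
  const double sl = exp(t_sl), sp = exp(t_sp), sd = exp(t_sd);
  const double rg = tanh(a_rg), rd = tanh(a_rd);
  const double cg = sqrt(1.0 - rg * rg), cd = sqrt(1.0 - rd * rd);
  int off_meas = off;
  double Rg = 0, Rr = 0, Fg = 0, Fr = 0;
  if (mode == 1) {
    Rg = 1.0 / (1.0 + exp(-theta[off])); ++off;
    Rr = 1.0 / (1.0 + exp(-theta[off])); ++off;
    Fg = 1.0 / (1.0 + exp(-theta[off])); ++off;
    Fr = 1.0 / (1.0 + exp(-theta[off])); ++off;
  }
  const int off_zg = off;
  const int off_zd = off + 2 * n;
  const int P = off_zd + 2 * nd;
  if (theta.size() != P) stop("theta length mismatch");

  // random effects
  std::vector<double> lambda(n), pi(n);
  for (int i = 0; i < n; ++i) {
    double z1 = theta[off_zg + i], z2 = theta[off_zg + n + i];
    lambda[i] = sl * z1;
    pi[i] = sp * (rg * z1 + cg * z2);
  }
  NumericMatrix delta(n, n);
  {
    int d = 0;
    for (int j = 1; j < n; ++j) {
      for (int i = 0; i < j; ++i, ++d) {
        double u1 = theta[off_zd + d], u2 = theta[off_zd + nd + d];
        delta(i, j) = sd * u1;
        delta(j, i) = sd * (rd * u1 + cd * u2);
      }
    }
  }

  // hoist covariate/block pointers out of the dyad loops
  std::vector<const int*> blk(nb);
  std::vector<IntegerVector> blk_keep(nb);
  for (int b = 0; b < nb; ++b) {
    blk_keep[b] = as<IntegerVector>(blocks[b]);
    blk[b] = INTEGER(blk_keep[b]);
  }
  std::vector<const double*> xs(ks), xd(kd);
  std::vector<NumericVector> xs_keep(ks);
  std::vector<NumericMatrix> xd_keep(kd);
  for (int k = 0; k < ks; ++k) {
    xs_keep[k] = as<NumericVector>(Xs[k]);
    xs[k] = REAL(xs_keep[k]);
  }
  for (int k = 0; k < kd; ++k) {
    xd_keep[k] = as<NumericMatrix>(Xd[k]);
    xd[k] = REAL(xd_keep[k]);
  }

  // phi and dll/dphi
  NumericMatrix phi(n, n), dphi(n, n);
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      double v = alpha + lambda[i] + pi[j] + delta(i, j);
      for (int b = 0; b < nb; ++b)
        v += B[4 * b + (blk[b][i] - 1) + 2 * (blk[b][j] - 1)];
      for (int k = 0; k < ks; ++k) v += gs[k] * xs[k][i];
      for (int k = 0; k < kd; ++k) v += gd[k] * xd[k][i + n * j];
      phi(i, j) = v;
    }
  }

  double ll = 0.0;
  double gRg = 0, gRr = 0, gFg = 0, gFr = 0;
  if (mode == 0) {
    IntegerMatrix A = data["A"];
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        if (i == j) continue;
        double v = phi(i, j), p = 1.0 / (1.0 + exp(-v));
        ll += A(i, j) * v - srm_log1pexp(v);
        dphi(i, j) = A(i, j) - p;
      }
  } else {
    IntegerMatrix OUT = data["OUT"], IN = data["IN"];
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        if (i == j) continue;
        double v = phi(i, j), p = 1.0 / (1.0 + exp(-v));
        int o = OUT(i, j), q = IN(i, j);
        double e1g = o ? Rg : 1.0 - Rg, e1r = q ? Rr : 1.0 - Rr;
        double e0g = o ? Fg : 1.0 - Fg, e0r = q ? Fr : 1.0 - Fr;
        double a1 = e1g * e1r, a0 = e0g * e0r;
        double m = p * a1 + (1.0 - p) * a0;
        if (m <= 0) return List::create(_["lp"] = R_NegInf,
                                        _["grad"] = NumericVector(P));
        ll += log(m);
        dphi(i, j) = (a1 - a0) * p * (1.0 - p) / m;
        double so = o ? 1.0 : -1.0, sq = q ? 1.0 : -1.0;
        gRg += p * so * e1r / m;
        gRr += p * sq * e1g / m;
        gFg += (1.0 - p) * so * e0r / m;
        gFr += (1.0 - p) * sq * e0g / m;
      }
  }

  NumericVector grad(P);
  // alpha, slopes, blocks
  double g_alpha = 0;
  std::vector<double> g_gs(ks, 0.0), g_gd(kd, 0.0), g_B(4 * nb, 0.0);
  std::vector<double> g_lambda(n, 0.0), g_pi(n, 0.0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      double d = dphi(i, j);
      g_alpha += d;
      g_lambda[i] += d;
      g_pi[j] += d;
      for (int b = 0; b < nb; ++b)
        g_B[4 * b + (blk[b][i] - 1) + 2 * (blk[b][j] - 1)] += d;
      for (int k = 0; k < ks; ++k) g_gs[k] += d * xs[k][i];
      for (int k = 0; k < kd; ++k) g_gd[k] += d * xd[k][i + n * j];
    }
  grad[0] = g_alpha;
  for (int k = 0; k < ks; ++k) grad[1 + k] = g_gs[k];
  for (int k = 0; k < kd; ++k) grad[1 + ks + k] = g_gd[k];
  for (int b = 0; b < 4 * nb; ++b) grad[off_B + b] = g_B[b];

  // random-effect scales/correlations and z gradients
  double g_tsl = 0, g_tsp = 0, g_arg = 0, g_tsd = 0, g_ard = 0;
  for (int i = 0; i < n; ++i) {
    double z1 = theta[off_zg + i], z2 = theta[off_zg + n + i];
    grad[off_zg + i] = g_lambda[i] * sl + g_pi[i] * sp * rg;
    grad[off_zg + n + i] = g_pi[i] * sp * cg;
    g_tsl += g_lambda[i] * lambda[i];
    g_tsp += g_pi[i] * pi[i];
    // d pi_i / d a_rg = sp * (z1 - rg*z2/cg) * (1 - rg^2)
    g_arg += g_pi[i] * sp * (z1 - rg * z2 / cg) * (cg * cg);
  }
  {
    int d = 0;
    for (int j = 1; j < n; ++j) {
      for (int i = 0; i < j; ++i, ++d) {
        double u1 = theta[off_zd + d], u2 = theta[off_zd + nd + d];
        double gd1 = dphi(i, j), gd2 = dphi(j, i);
        grad[off_zd + d] = sd * (gd1 + rd * gd2);
        grad[off_zd + nd + d] = sd * cd * gd2;
        g_tsd += gd1 * delta(i, j) + gd2 * delta(j, i);
        g_ard += gd2 * sd * (u1 - rd * u2 / cd) * (cd * cd);
      }
    }
  }
  grad[off_re] = g_tsl;
  grad[off_re + 1] = g_tsp;
  grad[off_re + 2] = g_arg;
  grad[off_re + 3] = g_tsd;
  grad[off_re + 4] = g_ard;
  if (mode == 1) {
    grad[off_meas] = gRg * Rg * (1.0 - Rg);
    grad[off_meas + 1] = gRr * Rr * (1.0 - Rr);
    grad[off_meas + 2] = gFg * Fg * (1.0 - Fg);
    grad[off_meas + 3] = gFr * Fr * (1.0 - Fr);
  }

  // ---- priors (with transform Jacobians) ----
  double lp = ll;
  const double v_coef = sd_coef * sd_coef;
  // Normal(0, sd_coef) on alpha, gammas, block entries
  lp += -0.5 * alpha * alpha / v_coef;
  grad[0] += -alpha / v_coef;
  for (int k = 0; k < ks; ++k) {
    lp += -0.5 * gs[k] * gs[k] / v_coef;
    grad[1 + k] += -gs[k] / v_coef;
  }
  for (int k = 0; k < kd; ++k) {
    lp += -0.5 * gd[k] * gd[k] / v_coef;
    grad[1 + ks + k] += -gd[k] / v_coef;
  }
  for (int b = 0; b < 4 * nb; ++b) {
    lp += -0.5 * B[b] * B[b] / v_coef;
    grad[off_B + b] += -B[b] / v_coef;
  }
  // half-Normal(sd_scale) on scales, log transform: lp += -s^2/2v + t
  const double v_scale = sd_scale * sd_scale;
  lp += -0.5 * sl * sl / v_scale + t_sl;
  grad[off_re] += 1.0 - sl * sl / v_scale;
  lp += -0.5 * sp * sp / v_scale + t_sp;
  grad[off_re + 1] += 1.0 - sp * sp / v_scale;
  lp += -0.5 * sd * sd / v_scale + t_sd;
  grad[off_re + 3] += 1.0 - sd * sd / v_scale;
  // uniform(-1,1) on correlations, atanh transform: Jacobian log(1 - rho^2)
  lp += log(cg * cg);
  grad[off_re + 2] += -2.0 * rg;
  lp += log(cd * cd);
  grad[off_re + 4] += -2.0 * rd;
  if (mode == 1) {
    // Beta(a,b) on probability, logit transform: lp += a log p + b log(1-p)
    double lRg = log(Rg), l1Rg = log1p(-Rg);
    double lRr = log(Rr), l1Rr = log1p(-Rr);
    double lFg = log(Fg), l1Fg = log1p(-Fg);
    double lFr = log(Fr), l1Fr = log1p(-Fr);
    lp += recall_a * lRg + recall_b * l1Rg;
    grad[off_meas] += recall_a - (recall_a + recall_b) * Rg;
    lp += recall_a * lRr + recall_b * l1Rr;
    grad[off_meas + 1] += recall_a - (recall_a + recall_b) * Rr;
    lp += fp_a * lFg + fp_b * l1Fg;
    grad[off_meas + 2] += fp_a - (fp_a + fp_b) * Fg;
    lp += fp_a * lFr + fp_b * l1Fr;
    grad[off_meas + 3] += fp_a - (fp_a + fp_b) * Fr;
  }
  // standard normal on all z
  for (int i = 0; i < 2 * n; ++i) {
    double z = theta[off_zg + i];
    lp += -0.5 * z * z;
    grad[off_zg + i] += -z;
  }
  for (int d = 0; d < 2 * nd; ++d) {
    double z = theta[off_zd + d];
    lp += -0.5 * z * z;
    grad[off_zd + d] += -z;
  }

  return List::create(_["lp"] = lp, _["grad"] = grad);
}
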