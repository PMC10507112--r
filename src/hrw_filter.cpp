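#include <Rcpp.h>
using namespace Rcpp;

// Truncated box blur (radius r) along one axis of a G x G grid, with
// per-cell window renormalization at the edges. In-place into `out`.
static void box_blur_cols(const NumericMatrix &m, NumericMatrix &out, int r) {
  // blur down columns (over rows)
  int G = m.nrow(), H = m.ncol();
  std::vector<double> cs(G + 1);
  for (int j = 0; j < H; ++j) {
    cs[0] = 0.0;
    for (int i = 0; i < G; ++i) cs[i + 1] = cs[i] + m(i, j);
    for (int i = 0; i < G; ++i) {
      int lo = std::max(i - r, 0), hi = std::min(i + r, G - 1);
      out(i, j) = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
    }
  }
}

static void box_blur_rows(const NumericMatrix &m, NumericMatrix &out, int r) {
  int G = m.nrow(), H = m.ncol();
  std::vector<double> cs(H + 1);
  for (int i = 0; i < G; ++i) {
    cs[0] = 0.0;
    for (int j = 0; j < H; ++j) cs[j + 1] = cs[j] + m(i, j);
    for (int j = 0; j < H; ++j) {
      int lo = std::max(j - r, 0), hi = std::min(j + r, H - 1);
      out(i, j) = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
    }
  }
}

// Sequential Bayesian filter for the heterogeneous random walk
// v[t+1] = q v[t] + a xi. Rows of the grid index persistence q, columns
// index activity a (same units as v). Per step: multiply the posterior by
// the step likelihood and renormalize (estimates are posterior means at
// this point), then propagate by a truncated box kernel of radii
// (r_q, r_a) and mix with the uniform distribution at weight p_min.
// [[Rcpp::export]]
List hrw_filter_cpp(NumericMatrix v, NumericVector q_grid,
                    NumericVector a_grid, double p_min, int r_q, int r_a) {
  int n = v.nrow(), d = v.ncol();
  int Gq = q_grid.size(), Ga = a_grid.size();
  if (n < 2) stop("need at least 2 velocity samples");

  NumericMatrix post(Gq, Ga), tmp(Gq, Ga);
  double u = 1.0 / (Gq * Ga);
  std::fill(post.begin(), post.end(), u);

  NumericVector q_hat(n - 1), a_hat(n - 1);
  NumericMatrix q_marg(n - 1, Gq), a_marg(n - 1, Ga);

  std::vector<double> log_norm(Ga), inv2a2(Ga), ss(Gq);
  for (int j = 0; j < Ga; ++j) {
    double a = a_grid[j];
    log_norm[j] = -d * std::log(a);
    inv2a2[j] = 1.0 / (2.0 * a * a);
  }

  for (int t = 1; t < n; ++t) {
    // residual sum of squares per q: |v[t] - q v[t-1]|^2
    for (int i = 0; i < Gq; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double r = v(t, k) - q_grid[i] * v(t - 1, k);
        s += r * r;
      }
      ss[i] = s;
    }
    // posterior *= exp(loglik - max), then renormalize
    double mx = -INFINITY;
    for (int j = 0; j < Ga; ++j)
      for (int i = 0; i < Gq; ++i) {
        double ll = log_norm[j] - ss[i] * inv2a2[j];
        tmp(i, j) = ll;
        if (ll > mx) mx = ll;
      }
    double tot = 0.0;
    for (int j = 0; j < Ga; ++j)
      for (int i = 0; i < Gq; ++i) {
        // weights below exp(-45) of the per-step maximum are numerically
        // irrelevant; skipping them avoids denormal-arithmetic stalls
        double diff = tmp(i, j) - mx;
        double w = (diff < -45.0) ? 0.0 : post(i, j) * std::exp(diff);
        post(i, j) = w;
        tot += w;
      }
    if (tot <= 0.0 || !std::isfinite(tot)) {
      // degenerate step (e.g. enormous residuals underflow every cell):
      // fall back to the uniform distribution
      std::fill(post.begin(), post.end(), u);
      tot = 1.0;
    } else {
      for (int j = 0; j < Ga; ++j)
        for (int i = 0; i < Gq; ++i) post(i, j) /= tot;
    }
    // posterior-mean estimates and marginals for this step
    double qm = 0.0, am = 0.0;
    for (int i = 0; i < Gq; ++i) {
      double s = 0.0;
      for (int j = 0; j < Ga; ++j) s += post(i, j);
      q_marg(t - 1, i) = s;
      qm += s * q_grid[i];
    }
    for (int j = 0; j < Ga; ++j) {
      double s = 0.0;
      for (int i = 0; i < Gq; ++i) s += post(i, j);
      a_marg(t - 1, j) = s;
      am += s * a_grid[j];
    }
    q_hat[t - 1] = qm;
    a_hat[t - 1] = am;
    // propagate: box blur + uniform mixing floor
    box_blur_cols(post, tmp, r_q);
    box_blur_rows(tmp, post, r_a);
    tot = 0.0;
    for (int j = 0; j < Ga; ++j)
      for (int i = 0; i < Gq; ++i) tot += post(i, j);
    for (int j = 0; j < Ga; ++j)
      for (int i = 0; i < Gq; ++i)
        post(i, j) = (1.0 - p_min) * post(i, j) / tot + p_min * u;
  }

  return List::create(_["q_hat"] = q_hat, _["a_hat"] = a_hat,
                      _["q_marginal"] = q_marg, _["a_marginal"] = a_marg,
                      _["posterior"] = post);
}
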