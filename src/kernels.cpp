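// Image-side numerical kernels: Gaussian spot rendering, local-maxima
// seeding, per-window Gaussian least-squares refinement, and elliptical
// mask photometry.  Coordinates are 1-based with pixel centers at integer
// positions; x indexes columns, y indexes rows.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Sum of isotropic/anisotropic 2D Gaussians rasterised onto an h x w image.
// Each spot is truncated at 7 combined sigma, far below render noise.
// [[Rcpp::export]]
NumericMatrix render_gaussians_cpp(int h, int w, NumericVector x,
                                   NumericVector y, NumericVector sx,
                                   NumericVector sy, NumericVector amp) {
  NumericMatrix img(h, w);
  int n = x.size();
  for (int i = 0; i < n; ++i) {
    if (amp[i] == 0.0) continue;
    double s2x = 2.0 * sx[i] * sx[i], s2y = 2.0 * sy[i] * sy[i];
    int r = (int)std::ceil(7.0 * std::max(sx[i], sy[i]));
    int c0 = std::max(1, (int)std::floor(x[i]) - r);
    int c1 = std::min(w, (int)std::ceil(x[i]) + r);
    int r0 = std::max(1, (int)std::floor(y[i]) - r);
    int r1 = std::min(h, (int)std::ceil(y[i]) + r);
    for (int c = c0; c <= c1; ++c) {
      double dx = c - x[i];
      double ex = dx * dx / s2x;
      for (int rr = r0; rr <= r1; ++rr) {
        double dy = rr - y[i];
        img(rr - 1, c - 1) += amp[i] * std::exp(-(ex + dy * dy / s2y));
      }
    }
  }
  return img;
}

// Local maxima above `thresh`, suppressed within a square window of
// half-width `radius` (Chebyshev separation).  Ties are broken in favour of
// the lexicographically first pixel.  Returns n x 2 matrix (row, col),
// 1-based.
// [[Rcpp::export]]
IntegerMatrix local_maxima_cpp(NumericMatrix img, int radius, double thresh) {
  int h = img.nrow(), w = img.ncol();
  std::vector<int> rows, cols;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      double v = img(r, c);
      if (v < thresh) continue;
      bool is_max = true;
      for (int dc = -radius; dc <= radius && is_max; ++dc) {
        int cc = c + dc;
        if (cc < 0 || cc >= w) continue;
        for (int dr = -radius; dr <= radius; ++dr) {
          int rr = r + dr;
          if (rr < 0 || rr >= h || (dr == 0 && dc == 0)) continue;
          double u = img(rr, cc);
          if (u > v || (u == v && (cc < c || (cc == c && rr < r)))) {
            is_max = false;
            break;
          }
        }
      }
      if (is_max) { rows.push_back(r + 1); cols.push_back(c + 1); }
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i];
    out(i, 1) = cols[i];
  }
  return out;
}

// Levenberg-Marquardt refinement of K Gaussian components plus a shared
// constant background over a rectangular window.  Parameter vector:
// (A_k, mx_k, my_k, log sx_k, log sy_k) for each component, then b.
// Returns a (K x 5 + 3) vector: per-component rows flattened
// (A, mx, my, sx, sy), then b, a convergence flag, and the residual sum
// of squares.
// [[Rcpp::export]]
NumericVector fit_gaussians_cpp(NumericMatrix img, NumericVector cy,
                                NumericVector cx, int halfwin,
                                NumericVector init_sigma,
                                NumericVector init_amp, double init_b,
                                int max_iter = 60) {
  int h = img.nrow(), w = img.ncol();
  int K = cy.size();
  int r0 = h, r1 = 1, c0 = w, c1 = 1;
  for (int k = 0; k < K; ++k) {
    r0 = std::min(r0, std::max(1, (int)std::round(cy[k]) - halfwin));
    r1 = std::max(r1, std::min(h, (int)std::round(cy[k]) + halfwin));
    c0 = std::min(c0, std::max(1, (int)std::round(cx[k]) - halfwin));
    c1 = std::max(c1, std::min(w, (int)std::round(cx[k]) + halfwin));
  }
  int nr = r1 - r0 + 1, nc = c1 - c0 + 1, npx = nr * nc;
  int np = 5 * K + 1;
  NumericVector fail(5 * K + 3, NA_REAL);
  fail[5 * K + 1] = 0.0;
  if (npx <= np) return fail;

  arma::vec z(npx), px(npx), py(npx);
  int idx = 0;
  for (int c = c0; c <= c1; ++c)
    for (int r = r0; r <= r1; ++r, ++idx) {
      z(idx) = img(r - 1, c - 1);
      px(idx) = c;
      py(idx) = r;
    }

  arma::vec theta(np);
  for (int k = 0; k < K; ++k) {
    theta(5 * k + 0) = std::max(init_amp[k], 1e-8);
    theta(5 * k + 1) = cx[k];
    theta(5 * k + 2) = cy[k];
    theta(5 * k + 3) = std::log(init_sigma[k]);
    theta(5 * k + 4) = std::log(init_sigma[k]);
  }
  theta(np - 1) = init_b;

  double lambda = 1e-3;
  arma::vec resid(npx);
  arma::mat J(npx, np);
  auto eval = [&](const arma::vec &th, arma::vec &res, arma::mat *Jm) {
    res.fill(-0.0);
    arma::vec model(npx, arma::fill::zeros);
    if (Jm) Jm->zeros();
    for (int k = 0; k < K; ++k) {
      double A = th(5 * k), mx = th(5 * k + 1), my = th(5 * k + 2);
      double sx = std::exp(th(5 * k + 3)), sy = std::exp(th(5 * k + 4));
      for (int i = 0; i < npx; ++i) {
        double dx = px(i) - mx, dy = py(i) - my;
        double ux = dx * dx / (sx * sx), uy = dy * dy / (sy * sy);
        double E = std::exp(-0.5 * (ux + uy));
        model(i) += A * E;
        if (Jm) {
          (*Jm)(i, 5 * k + 0) = E;
          (*Jm)(i, 5 * k + 1) = A * E * dx / (sx * sx);
          (*Jm)(i, 5 * k + 2) = A * E * dy / (sy * sy);
          (*Jm)(i, 5 * k + 3) = A * E * ux;
          (*Jm)(i, 5 * k + 4) = A * E * uy;
        }
      }
    }
    model += th(np - 1);
    if (Jm) Jm->col(np - 1).ones();
    res = model - z;
    return arma::dot(res, res);
  };

  double rss = eval(theta, resid, &J);
  bool converged = false;
  bool have_J = true;
  for (int it = 0; it < max_iter; ++it) {
    if (!have_J) eval(theta, resid, &J);
    arma::mat JtJ = J.t() * J;
    arma::vec g = J.t() * resid;
    arma::vec step;
    bool ok = false;
    arma::vec theta_new;
    double rss_new = rss;
    for (int tries = 0; tries < 12; ++tries) {
      arma::mat Aug = JtJ;
      Aug.diag() += lambda * (JtJ.diag() + 1e-12);
      if (!arma::solve(step, Aug, g, arma::solve_opts::no_approx)) {
        lambda *= 10.0;
        continue;
      }
      theta_new = theta - step;
      // keep log-sigmas sane
      bool bad = false;
      for (int k = 0; k < K; ++k) {
        if (theta_new(5 * k + 3) < std::log(0.2) ||
            theta_new(5 * k + 3) > std::log(50.0) ||
            theta_new(5 * k + 4) < std::log(0.2) ||
            theta_new(5 * k + 4) > std::log(50.0)) bad = true;
      }
      if (bad) { lambda *= 10.0; continue; }
      arma::vec res_new(npx);
      rss_new = eval(theta_new, res_new, nullptr);
      if (std::isfinite(rss_new) && rss_new <= rss) {
        resid = res_new;
        ok = true;
        break;
      }
      lambda *= 10.0;
    }
    if (!ok) { converged = true; break; }  // no descent left: at an optimum
    double rel = (rss - rss_new) / (rss + 1e-300);
    theta = theta_new;
    rss = rss_new;
    lambda = std::max(lambda * 0.3, 1e-12);
    have_J = false;
    if (rel < 1e-9) { converged = true; break; }
    if (it == max_iter - 1) converged = true;  // ran out but stable descent
  }

  NumericVector out(5 * K + 3);
  for (int k = 0; k < K; ++k) {
    out[5 * k + 0] = theta(5 * k);
    out[5 * k + 1] = theta(5 * k + 1);
    out[5 * k + 2] = theta(5 * k + 2);
    out[5 * k + 3] = std::exp(theta(5 * k + 3));
    out[5 * k + 4] = std::exp(theta(5 * k + 4));
  }
  out[5 * K] = theta(np - 1);
  out[5 * K + 1] = converged ? 1.0 : 0.0;
  out[5 * K + 2] = rss;
  return out;
}

// Photometry through elliptical masks (half-axes scale*sx, scale*sy around
// each center): per-spot pixel sum and pixel count, plus the union mask of
// all ellipses (for mask-free background estimation).
// [[Rcpp::export]]
List mask_photometry_cpp(NumericMatrix img, NumericVector x, NumericVector y,
                         NumericVector sx, NumericVector sy,
                         double scale = 2.0) {
  int h = img.nrow(), w = img.ncol();
  int n = x.size();
  NumericVector sum(n);
  IntegerVector count(n);
  LogicalMatrix mask(h, w);
  for (int i = 0; i < n; ++i) {
    double ax = scale * sx[i], ay = scale * sy[i];
    int c0 = std::max(1, (int)std::floor(x[i] - ax));
    int c1 = std::min(w, (int)std::ceil(x[i] + ax));
    int r0 = std::max(1, (int)std::floor(y[i] - ay));
    int r1 = std::min(h, (int)std::ceil(y[i] + ay));
    double s = 0.0;
    int cnt = 0;
    for (int c = c0; c <= c1; ++c) {
      double ex = (c - x[i]) / ax;
      ex *= ex;
      for (int r = r0; r <= r1; ++r) {
        double ey = (r - y[i]) / ay;
        if (ex + ey * ey <= 1.0) {
          s += img(r - 1, c - 1);
          ++cnt;
          mask(r - 1, c - 1) = true;
        }
      }
    }
    sum[i] = s;
    count[i] = cnt;
  }
  return List::create(_["sum"] = sum, _["count"] = count, _["mask"] = mask);
}
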