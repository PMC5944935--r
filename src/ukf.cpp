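// Unscented Kalman filter kernel for multi-tensor (+ free water) streamline
// tracking. State layout: per tissue compartment (m_x, m_y, m_z, l1, l2),
// compartments first, then (optionally) the free-water fraction as the last
// entry. Diffusivities in mm^2/s, directions unnormalized inside the filter
// (renormalized by the constraint projection after each update).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Per-gradient normalized signal for a packed state vector.
// dirs: n x 3 (unit rows for b > 0), bvals: n.
// fw_const in [0,1] is used when the state carries no FW entry
// (0 for plain tensor models, fixed value for pinned-FW runs).
arma::vec state_signal(const arma::vec& x, int nc, bool has_fw,
                       double fw_const, double d_fw, double lambda_min,
                       const arma::vec& bvals, const arma::mat& dirs) {
  const int n = bvals.n_elem;
  arma::vec out(n);
  double f = has_fw ? x(5 * nc) : fw_const;
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  for (int k = 0; k < n; ++k) {
    const double b = bvals(k);
    if (b <= 0.0) { out(k) = 1.0; continue; }
    double tissue = 0.0;
    for (int c = 0; c < nc; ++c) {
      const double mx = x(5 * c), my = x(5 * c + 1), mz = x(5 * c + 2);
      double l1 = x(5 * c + 3), l2 = x(5 * c + 4);
      if (l1 < lambda_min) l1 = lambda_min;
      if (l2 < lambda_min) l2 = lambda_min;
      const double mm = mx * mx + my * my + mz * mz;
      const double mg = mx * dirs(k, 0) + my * dirs(k, 1) + mz * dirs(k, 2);
      const double proj2 = (mm > 1e-12) ? (mg * mg) / mm : 0.0;
      tissue += std::exp(-b * (l2 + (l1 - l2) * proj2));
    }
    tissue /= nc;
    out(k) = (1.0 - f) * tissue + f * std::exp(-b * d_fw);
  }
  return out;
}

// Project the state back onto its constraint set.
void project_state(arma::vec& x, int nc, bool has_fw, double lambda_min) {
  for (int c = 0; c < nc; ++c) {
    double nrm = std::sqrt(x(5 * c) * x(5 * c) + x(5 * c + 1) * x(5 * c + 1) +
                           x(5 * c + 2) * x(5 * c + 2));
    if (nrm > 1e-12) {
      x(5 * c) /= nrm; x(5 * c + 1) /= nrm; x(5 * c + 2) /= nrm;
    } else {
      x(5 * c) = 1.0; x(5 * c + 1) = 0.0; x(5 * c + 2) = 0.0;
    }
    double l1 = x(5 * c + 3), l2 = x(5 * c + 4);
    if (l1 < l2) std::swap(l1, l2);
    if (l2 < lambda_min) l2 = lambda_min;
    if (l1 < l2) l1 = l2;
    x(5 * c + 3) = l1; x(5 * c + 4) = l2;
  }
  if (has_fw) {
    double f = x(5 * nc);
    if (f < 0.0) f = 0.0;
    if (f > 1.0) f = 1.0;
    x(5 * nc) = f;
  }
}

// Symmetrize and clamp covariance eigenvalues to keep it usable.
bool repair_cov(arma::mat& P) {
  P = 0.5 * (P + P.t());
  arma::vec eval; arma::mat evec;
  if (!arma::eig_sym(eval, evec, P)) return false;
  const double floorv = std::max(1e-12 * arma::trace(P), 1e-20);
  bool fixed = false;
  for (arma::uword i = 0; i < eval.n_elem; ++i)
    if (eval(i) < floorv) { eval(i) = floorv; fixed = true; }
  if (fixed) P = evec * arma::diagmat(eval) * evec.t();
  return true;
}

// One scaled-unscented-transform predict (identity + Q) / update (R) cycle.
// Returns false on irrecoverable numerical failure.
bool ukf_cycle(arma::vec& x, arma::mat& P, const arma::vec& z,
               int nc, bool has_fw, double fw_const, double d_fw,
               double lambda_min, const arma::vec& Qdiag, double r_meas,
               double alpha, double beta, double kappa,
               const arma::vec& bvals, const arma::mat& dirs) {
  const int n = x.n_elem;
  const int m = z.n_elem;
  P.diag() += Qdiag;                       // time update: identity process
  if (!repair_cov(P)) return false;
  const double lam = alpha * alpha * (n + kappa) - n;
  const double c = n + lam;
  arma::mat S;
  if (!arma::chol(S, c * P, "lower")) {
    if (!repair_cov(P)) return false;
    if (!arma::chol(S, c * P, "lower")) return false;
  }
  const int ns = 2 * n + 1;
  arma::mat X(n, ns);
  X.col(0) = x;
  for (int i = 0; i < n; ++i) {
    X.col(1 + i) = x + S.col(i);
    X.col(1 + n + i) = x - S.col(i);
  }
  arma::vec wm(ns), wc(ns);
  wm(0) = lam / c;
  wc(0) = lam / c + (1.0 - alpha * alpha + beta);
  for (int i = 1; i < ns; ++i) { wm(i) = 0.5 / c; wc(i) = 0.5 / c; }

  arma::mat Y(m, ns);
  for (int i = 0; i < ns; ++i)
    Y.col(i) = state_signal(X.col(i), nc, has_fw, fw_const, d_fw,
                            lambda_min, bvals, dirs);
  arma::vec ybar = Y * wm;
  arma::mat Pyy(m, m, arma::fill::zeros);
  arma::mat Pxy(n, m, arma::fill::zeros);
  for (int i = 0; i < ns; ++i) {
    arma::vec dy = Y.col(i) - ybar;
    arma::vec dx = X.col(i) - x;
    Pyy += wc(i) * dy * dy.t();
    Pxy += wc(i) * dx * dy.t();
  }
  Pyy.diag() += r_meas;
  arma::mat K;
  if (!arma::solve(K, Pyy.t(), Pxy.t())) return false;   // K = Pxy * Pyy^-1
  K = K.t();
  x += K * (z - ybar);
  P -= K * Pyy * K.t();
  project_state(x, nc, has_fw, lambda_min);
  return repair_cov(P);
}

struct Grid {
  const double* data; int nx, ny, nz, ng;
  inline double at(int i, int j, int k, int g) const {
    return data[i + nx * (j + (long)ny * (k + (long)nz * g))];
  }
};

// Trilinear interpolation of all gradient volumes at continuous voxel
// coordinate (centers at integers). Returns false when out of bounds.
bool interp_all(const Grid& gr, double x, double y, double z, arma::vec& out) {
  if (x < 0 || y < 0 || z < 0 ||
      x > gr.nx - 1 || y > gr.ny - 1 || z > gr.nz - 1) return false;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > gr.nx - 2) i0 = gr.nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > gr.ny - 2) j0 = gr.ny - 2; if (j0 < 0) j0 = 0;
  if (k0 > gr.nz - 2) k0 = gr.nz - 2; if (k0 < 0) k0 = 0;
  if (gr.nx == 1) i0 = 0; if (gr.ny == 1) j0 = 0; if (gr.nz == 1) k0 = 0;
  const double fx = x - i0, fy = y - j0, fz = z - k0;
  const int i1 = std::min(i0 + 1, gr.nx - 1);
  const int j1 = std::min(j0 + 1, gr.ny - 1);
  const int k1 = std::min(k0 + 1, gr.nz - 1);
  const double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
  const double w010 = (1 - fx) * fy * (1 - fz),       w110 = fx * fy * (1 - fz);
  const double w001 = (1 - fx) * (1 - fy) * fz,       w101 = fx * (1 - fy) * fz;
  const double w011 = (1 - fx) * fy * fz,             w111 = fx * fy * fz;
  for (int g = 0; g < gr.ng; ++g) {
    out(g) = w000 * gr.at(i0, j0, k0, g) + w100 * gr.at(i1, j0, k0, g) +
             w010 * gr.at(i0, j1, k0, g) + w110 * gr.at(i1, j1, k0, g) +
             w001 * gr.at(i0, j0, k1, g) + w101 * gr.at(i1, j0, k1, g) +
             w011 * gr.at(i0, j1, k1, g) + w111 * gr.at(i1, j1, k1, g);
  }
  return true;
}

inline double fa_cyl(double l1, double l2) {
  const double num = std::fabs(l1 - l2);
  const double den = std::sqrt(l1 * l1 + 2.0 * l2 * l2);
  return den > 0 ? num / den : 0.0;
}

// Compartment most aligned with prev_dir; direction oriented along it.
void pick_compartment(const arma::vec& x, int nc, const arma::vec3& prev,
                      int& idx, arma::vec3& dir) {
  double best = -1.0;
  idx = 0;
  for (int c = 0; c < nc; ++c) {
    arma::vec3 m = {x(5 * c), x(5 * c + 1), x(5 * c + 2)};
    const double d = std::fabs(arma::dot(m, prev));
    if (d > best) { best = d; idx = c; }
  }
  dir = {x(5 * idx), x(5 * idx + 1), x(5 * idx + 2)};
  if (arma::dot(dir, prev) < 0) dir = -dir;
  const double nrm = arma::norm(dir);
  if (nrm > 1e-12) dir /= nrm;
}

} // namespace

// [[Rcpp::export(name = ".predict_signal_cpp")]]
arma::vec predict_signal_cpp(const arma::vec& x, int nc, bool has_fw,
                             double fw_const, double d_fw,
                             const arma::vec& bvals, const arma::mat& dirs,
                             double lambda_min = 0.0) {
  return state_signal(x, nc, has_fw, fw_const, d_fw, lambda_min, bvals, dirs);
}

// [[Rcpp::export(name = ".ukf_update_cpp")]]
List ukf_update_cpp(arma::vec x, arma::mat P, const arma::vec& z,
                    int nc, bool has_fw, double fw_const, double d_fw,
                    double lambda_min, const arma::vec& Qdiag, double r_meas,
                    double alpha, double beta, double kappa,
                    const arma::vec& bvals, const arma::mat& dirs) {
  if (!z.is_finite()) stop("non-finite measurement vector");
  bool ok = ukf_cycle(x, P, z, nc, has_fw, fw_const, d_fw, lambda_min,
                      Qdiag, r_meas, alpha, beta, kappa, bvals, dirs);
  return List::create(_["x"] = x, _["P"] = P, _["ok"] = ok);
}

// [[Rcpp::export(name = ".choose_compartment_cpp")]]
List choose_compartment_cpp(const arma::vec& x, int nc,
                            const arma::vec& prev_dir) {
  int idx; arma::vec3 dir;
  arma::vec3 prev = {prev_dir(0), prev_dir(1), prev_dir(2)};
  pick_compartment(x, nc, prev, idx, dir);
  return List::create(_["index"] = idx + 1,
                      _["direction"] = NumericVector::create(dir(0), dir(1), dir(2)));
}

// [[Rcpp::export(name = ".interp_signals_cpp")]]
NumericVector interp_signals_cpp(const NumericVector& data4d,
                                 const IntegerVector& dims,
                                 const NumericVector& ijk) {
  Grid gr{data4d.begin(), dims[0], dims[1], dims[2], dims[3]};
  arma::vec out(gr.ng);
  if (!interp_all(gr, ijk[0], ijk[1], ijk[2], out))
    return NumericVector(gr.ng, NA_REAL);
  return wrap(out);
}

// [[Rcpp::export(name = ".interp_many_cpp")]]
NumericMatrix interp_many_cpp(const NumericVector& data4d,
                              const IntegerVector& dims,
                              const NumericMatrix& ijk) {
  Grid gr{data4d.begin(), dims[0], dims[1], dims[2], dims[3]};
  const int n = ijk.nrow();
  NumericMatrix out(n, gr.ng);
  arma::vec row(gr.ng);
  for (int i = 0; i < n; ++i) {
    if (interp_all(gr, ijk(i, 0), ijk(i, 1), ijk(i, 2), row)) {
      for (int g = 0; g < gr.ng; ++g) out(i, g) = row(g);
    } else {
      for (int g = 0; g < gr.ng; ++g) out(i, g) = NA_REAL;
    }
  }
  return out;
}

// Track one half-streamline from a seed. Returns recorded points (world mm)
// with per-point tracked-compartment FA, FW fraction and mean normalized
// signal, plus the stop reason.
// [[Rcpp::export(name = ".propagate_half_cpp")]]
List propagate_half_cpp(const NumericVector& data4d, const IntegerVector& dims,
                        const arma::mat& inv_affine, const arma::cube& mask,
                        const arma::vec& seed, const arma::vec& dir0,
                        const arma::vec& x0, const arma::mat& P0,
                        const List& cfg) {
  Grid gr{data4d.begin(), dims[0], dims[1], dims[2], dims[3]};
  const int nc = cfg["nc"];
  const bool has_fw = cfg["has_fw"];
  const double fw_const = cfg["fw_const"];
  const double d_fw = cfg["d_fw"];
  const double lambda_min = cfg["lambda_min"];
  const arma::vec Qdiag = cfg["q_diag"];
  const double r_meas = cfg["r_meas"];
  const double alpha = cfg["alpha"], beta = cfg["beta"], kappa = cfg["kappa"];
  const arma::vec bvals = cfg["bvals"];
  const arma::mat dirs = cfg["dirs"];
  const double step = cfg["step_mm"];
  const double stop_fa = cfg["stopping_fa"];
  const double stop_sig = cfg["stopping_signal"];
  const bool sig_sum = cfg["signal_sum"];
  const int max_steps = cfg["max_steps"];
  const double b0_floor = 1e-8;

  arma::uvec wdir = arma::find(bvals > 0);
  arma::uvec bdir = arma::find(bvals <= 0);

  arma::vec x = x0;
  arma::mat P = P0;
  arma::vec3 pos = {seed(0), seed(1), seed(2)};
  arma::vec3 dir = {dir0(0), dir0(1), dir0(2)};
  dir /= arma::norm(dir);

  std::vector<double> px, py, pz, fa_out, fw_out, sig_out;
  std::string reason = "max_length";
  arma::vec raw(gr.ng), z(gr.ng);

  for (int s = 0; s <= max_steps; ++s) {
    arma::vec4 ph = {pos(0), pos(1), pos(2), 1.0};
    arma::vec4 ijk = inv_affine * ph;
    if (!interp_all(gr, ijk(0), ijk(1), ijk(2), raw)) { reason = "bounds"; break; }
    const int mi = (int)std::lround(ijk(0));
    const int mj = (int)std::lround(ijk(1));
    const int mk = (int)std::lround(ijk(2));
    if (mi < 0 || mj < 0 || mk < 0 || mi >= (int)mask.n_rows ||
        mj >= (int)mask.n_cols || mk >= (int)mask.n_slices ||
        mask(mi, mj, mk) <= 0) { reason = "mask"; break; }
    double s0 = bdir.n_elem ? arma::mean(raw.elem(bdir)) : 1.0;
    if (s0 < b0_floor) s0 = b0_floor;
    z = raw / s0;
    if (!z.is_finite()) { reason = "signal"; break; }
    if (!ukf_cycle(x, P, z, nc, has_fw, fw_const, d_fw, lambda_min,
                   Qdiag, r_meas, alpha, beta, kappa, bvals, dirs)) {
      reason = "numerical"; break;
    }
    int idx; arma::vec3 ndir;
    pick_compartment(x, nc, dir, idx, ndir);
    const double fa = fa_cyl(x(5 * idx + 3), x(5 * idx + 4));
    double msig = arma::mean(z.elem(wdir));
    if (sig_sum) msig = arma::accu(z.elem(wdir));
    const double fw = has_fw ? x(5 * nc) : fw_const;

    px.push_back(pos(0)); py.push_back(pos(1)); pz.push_back(pos(2));
    fa_out.push_back(fa); fw_out.push_back(fw); sig_out.push_back(msig);

    if (fa < stop_fa) { reason = "fa"; break; }
    if (msig < stop_sig) { reason = "signal"; break; }
    dir = ndir;
    pos += step * dir;
  }
  const int np = px.size();
  NumericMatrix pts(np, 3);
  for (int i = 0; i < np; ++i) {
    pts(i, 0) = px[i]; pts(i, 1) = py[i]; pts(i, 2) = pz[i];
  }
  return List::create(_["points"] = pts,
                      _["fa"] = wrap(fa_out),
                      _["fw"] = wrap(fw_out),
                      _["signal"] = wrap(sig_out),
                      _["reason"] = reason);
}
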