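// Two-compartment (free-water elimination) voxel fit.
//
// Model: S(b,g) = s0 * [ (1-fw) exp(-b g'Dg) + fw exp(-b d_water) ]
// Single-shell variable projection: for each candidate fw the water signal
// is subtracted, the tissue tensor solved by log-linear least squares, its
// eigenvalues clipped to a physiological box, and the residual evaluated in
// signal space; fw is minimised over a deterministic coarse grid plus two
// local refinements.  The box bound on eigenvalues is what tames the
// single-shell fw/tensor degeneracy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct VoxelFit {
  double fw, fat, md, s0, resid;
  int converged;
  vec d6;
};

static double rss_for_fw(double fw, const vec& A, const vec& ew,
                         const vec& bpos, const mat& P, const mat& X,
                         double lmin, double lmax, vec& d6_out,
                         double& fat_out, double& md_out) {
  const double eps = 1e-6;
  vec At = (A - fw * ew) / (1.0 - fw);
  At = clamp(At, eps, 1.5);
  vec y = log(At);
  vec d = P * y;  // dxx dyy dzz dxy dxz dyz
  mat33 D = {{d(0), d(3), d(4)}, {d(3), d(1), d(5)}, {d(4), d(5), d(2)}};
  vec eigval;
  mat eigvec;
  if (!eig_sym(eigval, eigvec, D)) {
    d6_out.zeros(6);
    fat_out = 0; md_out = 0;
    return datum::inf;
  }
  vec lc = clamp(eigval, lmin, lmax);
  mat33 Dc = eigvec * diagmat(lc) * eigvec.t();
  vec dc = {Dc(0,0), Dc(1,1), Dc(2,2), Dc(0,1), Dc(0,2), Dc(1,2)};
  // predicted attenuation on the b>0 rows: X holds -b * quadratic forms
  vec q = X * dc;
  vec pred = (1.0 - fw) * exp(q) + fw * ew;
  double rss = accu(square(pred - A));
  d6_out = dc;
  md_out = mean(lc);
  double mdv = md_out;
  double num = accu(square(lc - mdv));
  double den = accu(square(lc));
  fat_out = den > 0 ? std::sqrt(1.5 * num / den) : 0.0;
  if (fat_out > 1.0) fat_out = 1.0;
  return rss;
}

// [[Rcpp::export]]
arma::mat fw_fit_cpp(const arma::mat& signals, const arma::vec& bvals,
                     const arma::mat& bvecs, double d_water,
                     double lmin, double lmax, double md_tissue_ref,
                     double coarse_step, double fine_step,
                     double prior_sd) {
  const uword nvox = signals.n_cols;
  uvec ib0 = find(bvals == 0);
  uvec ipos = find(bvals > 0);
  if (ib0.n_elem < 1) Rcpp::stop("free-water fit needs >= 1 b = 0 volume");
  if (ipos.n_elem < 6) Rcpp::stop("free-water fit needs >= 6 diffusion directions");
  const uword m = ipos.n_elem;
  vec bpos = bvals(ipos);
  mat gpos = bvecs.rows(ipos);
  vec ew = exp(-bpos * d_water);
  // design for log-attenuation regression (no intercept: s0 fixed)
  mat X(m, 6);
  for (uword i = 0; i < m; ++i) {
    double gx = gpos(i,0), gy = gpos(i,1), gz = gpos(i,2), b = bpos(i);
    X(i,0) = -b*gx*gx; X(i,1) = -b*gy*gy; X(i,2) = -b*gz*gz;
    X(i,3) = -2*b*gx*gy; X(i,4) = -2*b*gx*gz; X(i,5) = -2*b*gy*gz;
  }
  mat P = pinv(X);
  const double fw_max = 0.995;
  // anchor attenuations for the fw initialisation heuristic: where the
  // shell-average attenuation sits between typical tissue and free water
  double b_shell = mean(bpos);
  double att_tissue = std::exp(-b_shell * md_tissue_ref);
  double att_water = std::exp(-b_shell * d_water);

  mat out(12, nvox, fill::zeros);
  vec d6(6), d6_best(6);
  for (uword v = 0; v < nvox; ++v) {
    vec b0sig = vec(signals.col(v)).elem(ib0);
    double s0 = mean(b0sig);
    if (!(s0 > 0) || !vec(signals.col(v)).is_finite()) {
      out(4, v) = 0;  // converged = 0, everything else zero
      continue;
    }
    // noise level from the repeated b0 acquisitions; drives the shrinkage
    double sigma_hat = b0sig.n_elem > 1 ? stddev(b0sig) : 0.0;
    vec A = vec(signals.col(v)).elem(ipos) / s0;
    A = clamp(A, 1e-6, 2.0);
    // fw anchor: invert the isotropic two-compartment mixture at the
    // shell-average attenuation assuming tissue MD = md_tissue_ref
    double fw0 = (att_tissue - mean(A)) / (att_tissue - att_water);
    fw0 = std::min(std::max(fw0, 0.0), fw_max);
    // penalty weight sigma^2 / prior_sd^2: zero for noiseless data (the
    // fit stays an exact NLS), grows with noise to tame the single-shell
    // fw/tensor degeneracy
    double k = prior_sd > 0 ? (sigma_hat * sigma_hat) / (prior_sd * prior_sd)
                            : 0.0;

    double best_fw = 0, best_rss = datum::inf, best_fat = 0, best_md = 0;
    double best_data_rss = datum::inf;
    auto try_fw = [&](double f) {
      f = std::min(std::max(f, 0.0), fw_max);
      double fat, mdv;
      double data_rss = rss_for_fw(f, A, ew, bpos, P, X, lmin, lmax, d6,
                                   fat, mdv);
      double rss = data_rss + k * (f - fw0) * (f - fw0);
      if (rss < best_rss) {
        best_rss = rss; best_fw = f; best_fat = fat; best_md = mdv;
        best_data_rss = data_rss;
        d6_best = d6;
      }
    };
    for (double f = 0.0; f <= fw_max + 1e-9; f += coarse_step) try_fw(f);
    try_fw(fw_max);
    try_fw(fw0);
    double center = best_fw;
    for (double f = center - coarse_step; f <= center + coarse_step + 1e-9;
         f += fine_step) try_fw(f);
    center = best_fw;
    double micro = fine_step / 10.0;
    for (double f = center - fine_step; f <= center + fine_step + 1e-9;
         f += micro) try_fw(f);

    out(0, v) = best_fw;
    out(1, v) = best_fat;
    out(2, v) = best_md;
    out(3, v) = s0;
    out(4, v) = std::isfinite(best_rss) ? 1 : 0;
    out(5, v) = std::isfinite(best_data_rss) ? best_data_rss : 0.0;
    out.submat(6, v, 11, v) = d6_best;
  }
  return out;
}
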