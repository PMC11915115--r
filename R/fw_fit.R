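#' Fit the two-compartment free-water model in one voxel
#'
#' Estimates the free-water fraction `fw` and the tissue tensor (hence FAt,
#' the FW-corrected fractional anisotropy) from single-shell signals.  For
#' each candidate `fw` the isotropic water signal (diffusivity `d_water`)
#' is projected out, the tissue tensor solved in closed form and its
#' eigenvalues constrained to `lambda_bounds`; `fw` is minimised over a
#' deterministic grid with local refinement, seeded additionally by an
#' MD-interpolation heuristic from the plain tensor fit.  Optimiser
#' breakdown never raises: the voxel is returned with `converged = FALSE`.
#'
#' @param signals per-gradient intensities.
#' @param grad a [gradient_table()] (single shell, >= 1 b0).
#' @param d_water free-water diffusivity (mm^2/s); must exceed any
#'   plausible tissue diffusivity.
#' @param lambda_bounds allowed tissue eigenvalue range (mm^2/s).
#' @param md_tissue_ref reference tissue mean diffusivity (mm^2/s) used by
#'   the fw anchor: fw0 is where the shell-average attenuation sits between
#'   a typical tissue voxel and pure free water.
#' @param fw_prior_sd prior SD of the noise-scaled shrinkage of fw toward
#'   its anchor value (penalty weight `sigma_hat^2 / fw_prior_sd^2`, with
#'   `sigma_hat` the SD across the repeated b0 volumes); 0 disables.  The
#'   penalty vanishes for noiseless data, so exact recovery is unaffected;
#'   under noise it resolves the single-shell fw/tensor degeneracy.
#' @param coarse_step,fine_step fw search resolutions (final resolution is
#'   `fine_step / 10`).
#' @return list of class `fw_fit`: `fw`, `fat`, `md`, `tissue_tensor`
#'   (3x3), `s0`, `converged`, `residual`.
#' @export
fit_fw_voxel <- function(signals, grad, d_water = 3.0e-3,
                         lambda_bounds = c(0.1e-3, 2.5e-3),
                         md_tissue_ref = 0.7e-3,
                         coarse_step = 0.05, fine_step = 0.005,
                         fw_prior_sd = 0.05) {
  stopifnot(inherits(grad, "gradient_table"))
  if (length(signals) != length(grad$bvals))
    stop("signal count does not match gradient table")
  res <- fw_fit_cpp(matrix(signals, ncol = 1L), grad$bvals, grad$bvecs,
                    d_water, lambda_bounds[1], lambda_bounds[2],
                    md_tissue_ref, coarse_step, fine_step, fw_prior_sd)
  d <- res[7:12, 1]
  structure(list(
    fw = res[1, 1], fat = res[2, 1], md = res[3, 1],
    tissue_tensor = matrix(c(d[1], d[4], d[5],
                             d[4], d[2], d[6],
                             d[5], d[6], d[3]), 3, 3),
    s0 = res[4, 1], converged = res[5, 1] == 1, residual = res[6, 1]),
    class = "fw_fit")
}

#' Fit the free-water model over a masked volume
#'
#' Voxelwise, spatially independent application of [fit_fw_voxel()]
#' (C++ kernel).  Background (unmasked) voxels are 0 in all output maps.
#'
#' @param dwi 4D array (x, y, z, gradient).
#' @param mask 3D logical/0-1 array, nonempty.
#' @param grad a [gradient_table()].
#' @inheritParams fit_fw_voxel
#' @return list with 3D maps `fw`, `fat`, `md`, `s0`, `residual` and
#'   logical `converged` (the QC map).
#' @export
fit_fw_volume <- function(dwi, mask, grad, d_water = 3.0e-3,
                          lambda_bounds = c(0.1e-3, 2.5e-3),
                          md_tissue_ref = 0.7e-3,
                          coarse_step = 0.05, fine_step = 0.005,
                          fw_prior_sd = 0.05) {
  stopifnot(length(dim(dwi)) == 4L)
  shape <- dim(dwi)[1:3]
  if (!identical(dim(mask), shape))
    stop("mask shape does not match DWI volume")
  if (dim(dwi)[4] != length(grad$bvals))
    stop("gradient count does not match DWI 4th dimension")
  idx <- which(mask > 0)
  if (length(idx) == 0L) stop("mask is empty")
  sig <- matrix(dwi, ncol = dim(dwi)[4])[idx, , drop = FALSE]
  res <- fw_fit_cpp(t(sig), grad$bvals, grad$bvecs, d_water,
                    lambda_bounds[1], lambda_bounds[2], md_tissue_ref,
                    coarse_step, fine_step, fw_prior_sd)
  blank <- array(0, dim = shape)
  take <- function(r) { m <- blank; m[idx] <- res[r, ]; m }
  conv <- array(FALSE, dim = shape)
  conv[idx] <- res[5, ] == 1
  list(fw = take(1), fat = take(2), md = take(3), s0 = take(4),
       residual = take(6), converged = conv)
}
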