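# Shared fixtures and independent oracles.  Everything is generated in code;
# the forward-signal oracle is written directly from the model definition
# and stays independent of the package's synthesize_dwi() path.

# independent two-compartment forward model (pure R, per voxel)
fwd_signal <- function(grad, fw, D, s0 = 1, d_water = 3.0e-3) {
  vapply(seq_along(grad$bvals), function(i) {
    b <- grad$bvals[i]
    if (b == 0) return(s0)
    g <- grad$bvecs[i, ]
    s0 * ((1 - fw) * exp(-b * drop(g %*% D %*% g)) +
            fw * exp(-b * d_water))
  }, numeric(1))
}

# small boxy atlas: one region filling the interior
box_atlas <- function(n = 6L) {
  a <- array(0L, dim = rep(n, 3L))
  a[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- 1L
  a
}

# ground truth with uniform fields over a given atlas
uniform_truth <- function(atlas, fw = 0.2, fa = 0.5, md = 0.7e-3,
                          dir = c(1, 0, 0), s0 = 1) {
  shape <- dim(atlas)
  D <- tensor_from_fa_md(fa, md, dir)
  comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  tensor <- array(0, dim = c(shape, 6L))
  sel <- atlas > 0
  for (k in 1:6) {
    slice <- tensor[, , , k]; slice[sel] <- comp[k]; tensor[, , , k] <- slice
  }
  fwm <- array(0, dim = shape); fwm[sel] <- fw
  s0m <- array(0, dim = shape); s0m[sel] <- s0
  structure(list(fw = fwm, tensor = tensor, s0 = s0m, atlas = atlas),
            class = "ground_truth")
}

# brute-force grid-search oracle for the free-water voxel fit: exhaustive
# search over fw (0.005 steps) x axially symmetric tensors with known
# principal direction; independent of the package's fitting path
fw_grid_oracle <- function(signals, grad, dir, d_water = 3.0e-3,
                           fw_step = 0.005, lam_step = 0.05e-3,
                           lam_range = c(0.1e-3, 2.5e-3)) {
  ipos <- grad$bvals > 0
  b <- grad$bvals[ipos]
  g <- grad$bvecs[ipos, , drop = FALSE]
  s0 <- mean(signals[!ipos])
  A <- signals[ipos] / s0
  u <- dir / sqrt(sum(dir^2))
  cu2 <- drop(g %*% u)^2
  ew <- exp(-b * d_water)
  fws <- seq(0, 0.995, fw_step)
  lams <- seq(lam_range[1], lam_range[2], lam_step)
  best <- c(rss = Inf, fw = NA, lpar = NA, lperp = NA)
  for (lpar in lams) for (lperp in lams[lams <= lpar]) {
    q <- exp(-b * (lperp + (lpar - lperp) * cu2))
    # rss(fw) is quadratic in fw: minimise over the fw grid vectorised
    for (fw in fws) {
      r <- sum(((1 - fw) * q + fw * ew - A)^2)
      if (r < best["rss"]) best <- c(rss = r, fw = fw, lpar = lpar,
                                     lperp = lperp)
    }
  }
  fa <- fractional_anisotropy(best["lpar"], best["lperp"], best["lperp"])
  list(fw = unname(best["fw"]), fat = unname(fa),
       rss = unname(best["rss"]))
}

# per-subject ROI feature table computed directly from planted ground truth
# (no signal synthesis or voxel fitting) -- fast route for classifier and
# statistics tests
feature_table_from_truth <- function(cohort, truth, effect, noise_sd = 0,
                                     seed = 1L) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    st <- plant_effects(truth, effect, subj$diagnosis,
                        scale = subj$effect_scale)
    fa <- field_fa(st$tensor)
    fv <- extract_roi_features(st$fw, fa, truth$atlas, subj$age, subj$sex)
    if (noise_sd > 0) {
      nf <- length(fv) - 2L
      nz <- with_seed(derive_seed(seed, paste0("featnoise:", subj$subject_id)),
                      rnorm(nf, 0, noise_sd))
      fv[seq_len(nf)] <- fv[seq_len(nf)] + nz
    }
    data.frame(subject_id = subj$subject_id, diagnosis = subj$diagnosis,
               t(fv), check.names = FALSE)
  })
  do.call(rbind, rows)
}

# FA of a 6-component tensor field by voxelwise eigendecomposition
field_fa <- function(tensor) {
  shape <- dim(tensor)[1:3]
  tc <- matrix(tensor, ncol = 6L)
  fa <- apply(tc, 1L, function(d) {
    if (all(d == 0)) return(0)
    D <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
    ev <- pmax(eigen(D, symmetric = TRUE, only.values = TRUE)$values, 0)
    fractional_anisotropy(ev[1], ev[2], ev[3])
  })
  array(fa, dim = shape)
}
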