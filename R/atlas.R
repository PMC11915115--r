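#' Generate a contiguous region atlas on a voxel grid
#'
#' Partitions the interior of the grid (a 1-voxel background border is kept)
#' into `n_regions` contiguous, nonempty labels by a seeded Voronoi
#' tessellation: seed voxels are drawn uniformly and every interior voxel
#' takes the label of its nearest seed.  Voronoi cells are convex, so each
#' label is spatially contiguous.  Seeding is retried (deterministically) if
#' any region ends up with fewer than `min_voxels` voxels.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param n_regions number of labels (default 132, the atlas size the
#'   feature vector assumes).
#' @param seed integer seed.
#' @param min_voxels minimum voxels per region (default 8).
#' @param border background border width in voxels.
#' @return 3D integer array; 0 = background, 1..n_regions = regions.
#' @export
generate_atlas <- function(grid_shape, n_regions = 132L, seed = 1L,
                           min_voxels = 8L, border = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1), n_regions >= 1)
  inner <- grid_shape - 2L * border
  if (any(inner < 1) || prod(inner) < n_regions * min_voxels)
    stop("atlas capacity error: grid ", paste(grid_shape, collapse = "x"),
         " interior holds ", max(0, prod(pmax(inner, 0))),
         " voxels but ", n_regions, " regions x ", min_voxels,
         " voxels are required")
  ax <- lapply(1:3, function(d) (border + 1L):(grid_shape[d] - border))
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  n_vox <- nrow(coords)
  cn2 <- rowSums(coords^2)
  assign_nearest <- function(seeds) {
    # nearest seed per voxel (squared Euclidean)
    d2 <- outer(cn2, rep(1, n_regions)) - 2 * coords %*% t(seeds) +
      outer(rep(1, n_vox), rowSums(seeds^2))
    max.col(-d2, ties.method = "first")
  }
  with_seed(seed, {
    for (attempt in 1:50) {
      seeds <- coords[sample.int(n_vox, n_regions), , drop = FALSE]
      lab <- assign_nearest(seeds)
      # Lloyd relaxation equalises cell sizes (cells stay convex/contiguous)
      for (iter in 1:6) {
        for (j in 1:3) seeds[, j] <- tapply(coords[, j],
                                            factor(lab, levels = 1:n_regions),
                                            mean)
        if (anyNA(seeds)) break
        lab <- assign_nearest(seeds)
      }
      sizes <- tabulate(lab, nbins = n_regions)
      if (!anyNA(seeds) && all(sizes >= min_voxels)) {
        atlas <- array(0L, dim = grid_shape)
        atlas[coords] <- as.integer(lab)
        return(atlas)
      }
    }
  })
  stop("atlas capacity error: could not place ", n_regions,
       " regions of >= ", min_voxels, " voxels after 50 seedings")
}

#' Ground-truth parameter maps over an atlas
#'
#' Builds the voxelwise truth the signal simulator consumes: a free-water
#' fraction field, a tissue diffusion tensor field (stored as the 6 unique
#' components dxx, dyy, dzz, dxy, dxz, dyz in mm^2/s), and a baseline
#' signal field.  Each region gets its own baseline FW, FA and principal
#' fibre direction; mean diffusivity is constant at `md` (healthy
#' parenchyma scale).  Background voxels have zero signal.
#'
#' @param atlas integer label field from [generate_atlas()].
#' @param seed integer seed.
#' @param fw_range per-region baseline FW drawn uniformly from this range.
#' @param fa_range per-region baseline FA drawn uniformly from this range.
#' @param md mean diffusivity of tissue (mm^2/s).
#' @param s0 baseline (b = 0) signal inside the brain.
#' @return list of class `ground_truth`: `fw` (3D), `tensor` (4D, last dim
#'   6), `s0` (3D), `atlas` (3D).
#' @export
make_ground_truth <- function(atlas, seed = 1L, fw_range = c(0.10, 0.20),
                              fa_range = c(0.30, 0.60), md = 0.7e-3, s0 = 1) {
  labels <- sort(unique(as.vector(atlas[atlas > 0])))
  n <- length(labels)
  shape <- dim(atlas)
  with_seed(seed, {
    region_fw <- runif(n, fw_range[1], fw_range[2])
    region_fa <- runif(n, fa_range[1], fa_range[2])
    dirs <- matrix(rnorm(3L * n), ncol = 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    fw <- array(0, dim = shape)
    s0_map <- array(0, dim = shape)
    tensor <- array(0, dim = c(shape, 6L))
    for (i in seq_len(n)) {
      sel <- atlas == labels[i]
      fw[sel] <- region_fw[i]
      s0_map[sel] <- s0
      D <- tensor_from_fa_md(region_fa[i], md, dirs[i, ])
      comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
      for (k in 1:6) {
        slice <- tensor[, , , k]
        slice[sel] <- comp[k]
        tensor[, , , k] <- slice
      }
    }
    structure(list(fw = fw, tensor = tensor, s0 = s0_map, atlas = atlas),
              class = "ground_truth")
  })
}

#' Axially symmetric tensor with prescribed FA and MD
#'
#' @param fa target fractional anisotropy in `[0, 1)`.
#' @param md mean diffusivity (mm^2/s).
#' @param dir principal eigenvector (any nonzero 3-vector).
#' @return 3x3 symmetric positive-definite matrix.
#' @export
tensor_from_fa_md <- function(fa, md, dir = c(1, 0, 0)) {
  stopifnot(fa >= 0, fa < 1, md > 0)
  # prolate spindle: l1 = md(1 + 2f), l2 = l3 = md(1 - f) has
  # FA = 3f / sqrt(3 + 6 f^2); invert for f
  f <- if (fa == 0) 0 else sqrt(3) * fa / sqrt(9 - 6 * fa^2)
  l1 <- md * (1 + 2 * f)
  l23 <- md * (1 - f)
  u <- dir / sqrt(sum(dir^2))
  l23 * diag(3) + (l1 - l23) * tcrossprod(u)
}

# FA of a 6-component tensor field without eigendecomposition:
# FA^2 = (3/2) * ||D - MD I||_F^2 / ||D||_F^2
.field_fa_md <- function(tensor) {
  dxx <- tensor[, , , 1]; dyy <- tensor[, , , 2]; dzz <- tensor[, , , 3]
  dxy <- tensor[, , , 4]; dxz <- tensor[, , , 5]; dyz <- tensor[, , , 6]
  md <- (dxx + dyy + dzz) / 3
  dev2 <- (dxx - md)^2 + (dyy - md)^2 + (dzz - md)^2 +
    2 * (dxy^2 + dxz^2 + dyz^2)
  norm2 <- dev2 + 3 * md^2
  fa <- sqrt(1.5 * dev2 / pmax(norm2, .Machine$double.eps))
  fa[norm2 == 0] <- 0
  list(fa = fa, md = md, dev2 = dev2)
}

#' Disease-effect specification
#'
#' Additive shifts of regional FW and tissue FA applied to ground truth for
#' a given diagnosis, plus nuisance scales: a between-site random FW shift
#' and a within-subject session-2 (test-retest) jitter.
#'
#' @param effects named list (by diagnosis) of data.frames with columns
#'   `region`, `d_fw`, `d_fat`.
#' @param site_sd SD of the per-site global FW shift.
#' @param retest_sd SD of the session-2 FW jitter.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(effects = list(), site_sd = 0, retest_sd = 0) {
  stopifnot(site_sd >= 0, retest_sd >= 0)
  for (d in names(effects)) {
    ef <- effects[[d]]
    stopifnot(all(c("region", "d_fw", "d_fat") %in% names(ef)))
  }
  structure(list(effects = effects, site_sd = site_sd, retest_sd = retest_sd),
            class = "effect_spec")
}

#' Default disease-effect topography
#'
#' The published study does not disclose which of the 132 regions drive
#' discrimination; the defaults plant disjoint signatures in low-index
#' regions (standing in for the motor/brainstem/cerebellar circuits the
#' method images): MSA raises FW and lowers FAt in regions 1-6, PSP in
#' regions 7-12, PD mildly in region 13.  `strength` scales every shift.
#'
#' @param strength global multiplier on all shifts.
#' @param site_sd,retest_sd passed to [effect_spec()].
#' @return an [effect_spec()].
#' @export
default_effect_spec <- function(strength = 1, site_sd = 0.01,
                                retest_sd = 0.01) {
  effect_spec(effects = list(
    MSA = data.frame(region = 1:6, d_fw = 0.15 * strength,
                     d_fat = -0.10 * strength),
    PSP = data.frame(region = 7:12, d_fw = 0.12 * strength,
                     d_fat = -0.08 * strength),
    PD = data.frame(region = 13L, d_fw = 0.05 * strength, d_fat = 0)),
    site_sd = site_sd, retest_sd = retest_sd)
}

#' Apply disease-specific regional shifts to ground truth
#'
#' FW shifts are additive and clipped to `[0, 1]`; FAt shifts are realised
#' by rescaling the anisotropic (deviatoric) part of the tensor about its
#' mean diffusivity so the resulting FA equals the clipped target exactly
#' (closed form, no eigendecomposition).  Voxels outside the named regions
#' are untouched bit-for-bit; an empty effect table is the identity.
#'
#' @param truth a [make_ground_truth()] object.
#' @param effect an [effect_spec()].
#' @param diagnosis the subject's diagnosis (selects `effect$effects`).
#' @param scale subject-level multiplier on the shifts (default 1).
#' @return a modified `ground_truth`.
#' @export
plant_effects <- function(truth, effect, diagnosis, scale = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(effect, "effect_spec"))
  ef <- effect$effects[[diagnosis]]
  if (is.null(ef) || nrow(ef) == 0L) return(truth)
  present <- unique(as.vector(truth$atlas[truth$atlas > 0]))
  missing <- setdiff(ef$region, present)
  if (length(missing))
    stop("unknown atlas region id(s) in effect spec: ",
         paste(missing, collapse = ", "))
  fw <- truth$fw
  tensor <- truth$tensor
  inv <- .field_fa_md(tensor)
  for (i in seq_len(nrow(ef))) {
    sel <- truth$atlas == ef$region[i]
    fw[sel] <- clamp(fw[sel] + ef$d_fw[i] * scale, 0, 1)
    d_fat <- ef$d_fat[i] * scale
    if (d_fat != 0) {
      fa_new <- clamp(inv$fa[sel] + d_fat, 0, 0.99)
      md <- inv$md[sel]
      dev2 <- pmax(inv$dev2[sel], .Machine$double.eps)
      # scale s on the deviatoric part giving FA exactly fa_new:
      # s^2 = 3 MD^2 fa^2 / (dev2 (3/2 - fa^2))
      s <- sqrt(3 * md^2 * fa_new^2 / (dev2 * (1.5 - fa_new^2)))
      for (k in 1:6) {
        slice <- tensor[, , , k]
        iso <- if (k <= 3) md else 0
        slice[sel] <- iso + s * (slice[sel] - iso)
        tensor[, , , k] <- slice
      }
    }
  }
  structure(list(fw = fw, tensor = tensor, s0 = truth$s0,
                 atlas = truth$atlas), class = "ground_truth")
}
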