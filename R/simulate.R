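#' Synthesize a diffusion-weighted volume from ground truth
#'
#' Forward model of the two-compartment (free-water) signal: for b-value b
#' and unit direction g,
#' \deqn{S(b, g) = S_0 [(1 - fw)\,e^{-b\,g^T D g} + fw\, e^{-b\,d_{water}}]}
#' with an isotropic water compartment of fixed diffusivity `d_water`.
#' Noise is Rician (magnitude-MRI convention): the noiseless signal is
#' perturbed by two independent Gaussian channels and the magnitude taken;
#' Gaussian noise is available for analytic tests.
#'
#' @param truth a [make_ground_truth()] object (possibly after
#'   [plant_effects()]).
#' @param grad a [gradient_table()].
#' @param sigma noise SD in signal units (0 = exact forward model).
#' @param seed seed for the noise draws (required when `sigma > 0`).
#' @param d_water free-water diffusivity, default 3.0e-3 mm^2/s
#'   (body-temperature isotropic water).
#' @param noise `"rician"` (default) or `"gaussian"`.
#' @return 4D array, one 3D volume per gradient-table row.
#' @export
synthesize_dwi <- function(truth, grad, sigma = 0, seed = NULL,
                           d_water = 3.0e-3, noise = c("rician", "gaussian")) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "ground_truth"), inherits(grad, "gradient_table"),
            sigma >= 0)
  shape <- dim(truth$fw)
  if (!identical(dim(truth$s0), shape) ||
      !identical(dim(truth$tensor)[1:3], shape))
    stop("ground-truth field shapes disagree")
  n <- length(grad$bvals)
  fw <- as.vector(truth$fw)
  s0 <- as.vector(truth$s0)
  tc <- matrix(truth$tensor, ncol = 6L)  # dxx dyy dzz dxy dxz dyz
  dwi <- array(0, dim = c(shape, n))
  for (i in seq_len(n)) {
    b <- grad$bvals[i]
    if (b == 0) {
      sig <- s0
    } else {
      g <- grad$bvecs[i, ]
      q <- tc[, 1] * g[1]^2 + tc[, 2] * g[2]^2 + tc[, 3] * g[3]^2 +
        2 * (tc[, 4] * g[1] * g[2] + tc[, 5] * g[1] * g[3] +
               tc[, 6] * g[2] * g[3])
      sig <- s0 * ((1 - fw) * exp(-b * q) + fw * exp(-b * d_water))
    }
    dwi[, , , i] <- sig
  }
  if (sigma > 0) {
    add_noise <- function() {
      nv <- length(dwi)
      if (noise == "rician") {
        sqrt((dwi + array(rnorm(nv, sd = sigma), dim = dim(dwi)))^2 +
               array(rnorm(nv, sd = sigma), dim = dim(dwi))^2)
      } else {
        dwi + array(rnorm(nv, sd = sigma), dim = dim(dwi))
      }
    }
    dwi <- if (is.null(seed)) add_noise() else with_seed(seed, add_noise())
  }
  dwi
}

#' Simulate the diffusion sessions of one subject
#'
#' Applies the subject's disease effect (scaled by the cohort table's
#' `effect_scale`), a per-site global FW shift (seeded by the site label, so
#' all subjects of a site share it), and for session 2 a subject-specific
#' test-retest FW jitter, then synthesizes the noisy signal.
#'
#' @param subject one row of a [generate_cohort()] table.
#' @param truth base [make_ground_truth()] maps.
#' @param effect an [effect_spec()].
#' @param grad a [gradient_table()].
#' @param sigma Rician noise SD.
#' @param seed top-level seed (subject/session substreams are derived).
#' @param d_water free-water diffusivity.
#' @param sessions which sessions to simulate (default all the subject has).
#' @return named list of 4D arrays, one per session (`"1"`, `"2"`).
#' @export
simulate_subject_dwi <- function(subject, truth, effect, grad, sigma = 0,
                                 seed = 1L, d_water = 3.0e-3,
                                 sessions = seq_len(subject$sessions)) {
  st <- plant_effects(truth, effect, subject$diagnosis,
                      scale = subject$effect_scale)
  if (effect$site_sd > 0) {
    shift <- with_seed(derive_seed(seed, paste0("site:", subject$site)),
                       rnorm(1, 0, effect$site_sd))
    brain <- st$atlas > 0
    st$fw[brain] <- clamp(st$fw[brain] + shift, 0, 1)
  }
  out <- list()
  for (s in sessions) {
    sst <- st
    if (s > 1L && effect$retest_sd > 0) {
      jit <- with_seed(
        derive_seed(seed, paste0("retest:", subject$subject_id, ":", s)),
        rnorm(1, 0, effect$retest_sd))
      brain <- sst$atlas > 0
      sst$fw[brain] <- clamp(sst$fw[brain] + jit, 0, 1)
    }
    out[[as.character(s)]] <- synthesize_dwi(
      sst, grad, sigma = sigma,
      seed = derive_seed(seed, paste0("noise:", subject$subject_id, ":", s)),
      d_water = d_water)
  }
  out
}
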