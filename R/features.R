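#' Signal-to-noise QC from repeated b0 volumes
#'
#' Per masked voxel, SNR is the mean b0 signal divided by the SD across the
#' repeated b0 acquisitions; the report carries the across-voxel mean.
#' Noiseless data (zero SD everywhere) reports the `Inf` sentinel and
#' passes.
#'
#' @param dwi 4D array.
#' @param grad a [gradient_table()] with >= 2 b0 volumes.
#' @param mask 3D mask.
#' @param threshold pass threshold on SNR (default 5).
#' @param converged optional QC map from [fit_fw_volume()]; reported as
#'   `fraction_converged` within the mask.
#' @return list of class `qc_report`: `snr_b0`, `pass`,
#'   `fraction_converged`.
#' @export
compute_snr <- function(dwi, grad, mask, threshold = 5, converged = NULL) {
  ib0 <- which(grad$bvals == 0)
  if (length(ib0) < 2L)
    stop("SNR estimation needs >= 2 b = 0 volumes (protocol has 5)")
  idx <- which(mask > 0)
  if (length(idx) == 0L) stop("mask is empty")
  b0 <- matrix(dwi, ncol = dim(dwi)[4])[idx, ib0, drop = FALSE]
  mu <- rowMeans(b0)
  sdv <- apply(b0, 1L, sd)
  snr <- if (all(sdv == 0)) Inf else mean(mu[sdv > 0] / sdv[sdv > 0])
  fc <- if (is.null(converged)) NA_real_ else mean(converged[idx])
  structure(list(snr_b0 = snr, pass = snr >= threshold,
                 fraction_converged = fc), class = "qc_report")
}

# 6-connected components by flood fill over voxel indices
.largest_component <- function(mask) {
  shape <- dim(mask)
  lab <- array(0L, dim = shape)
  nxt <- 0L
  strides <- c(1L, shape[1], shape[1] * shape[2])
  coord <- which(mask, arr.ind = TRUE)
  idx_all <- which(mask)
  sizes <- integer(0)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    size <- 0L
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      ci <- arrayInd(cur, shape)
      for (d in 1:3) for (s in c(-1L, 1L)) {
        p <- ci[d] + s
        if (p < 1L || p > shape[d]) next
        nb <- cur + s * strides[d]
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
    sizes[nxt] <- size
  }
  if (nxt == 0L) return(mask)
  lab == which.max(sizes)
}

#' Desk-scale brain mask from the mean b0 volume
#'
#' Thresholds the mean b0 image at a fraction of its robust maximum (99th
#' percentile) and keeps the largest 6-connected component — a stand-in for
#' nonbrain-tissue removal on synthetic, already-aligned volumes.
#'
#' @param dwi 4D array.
#' @param grad a [gradient_table()] with >= 1 b0 volume.
#' @param frac threshold as a fraction of the robust maximum (default 0.2).
#' @return 3D logical array.
#' @export
brain_mask <- function(dwi, grad, frac = 0.2) {
  ib0 <- which(grad$bvals == 0)
  if (length(ib0) < 1L) stop("brain mask needs >= 1 b = 0 volume")
  b0 <- dwi[, , , ib0, drop = FALSE]
  mb0 <- apply(b0, 1:3, mean)
  rmax <- quantile(mb0, 0.99, names = FALSE)
  if (rmax <= 0) stop("all-zero volume: cannot form a brain mask")
  .largest_component(mb0 > frac * rmax)
}

#' Extract the region-of-interest feature vector
#'
#' The classifier input: mean FW then mean FAt for every atlas region in
#' ascending region-id order, then age (years) and sex (0 = female,
#' 1 = male).  With the default 132-region atlas the vector has length 266.
#'
#' @param fw_map,fat_map 3D maps aligned with `atlas`.
#' @param atlas integer label field; every label in `1..max` must be
#'   nonempty.
#' @param age subject age in years.
#' @param sex `"male"`/`"female"` (or 0/1).
#' @return named numeric vector (`fw_r001 ... fat_r132, age, sex`).
#' @export
extract_roi_features <- function(fw_map, fat_map, atlas, age, sex) {
  stopifnot(identical(dim(fw_map), dim(atlas)),
            identical(dim(fat_map), dim(atlas)))
  n_regions <- max(atlas)
  labels <- seq_len(n_regions)
  present <- sort(unique(as.vector(atlas[atlas > 0])))
  missing <- setdiff(labels, present)
  if (length(missing))
    stop("empty atlas region(s): ", paste(missing, collapse = ", "))
  sel <- atlas > 0
  lab <- factor(atlas[sel], levels = labels)
  fw_mean <- as.vector(tapply(fw_map[sel], lab, mean))
  fat_mean <- as.vector(tapply(fat_map[sel], lab, mean))
  sex01 <- if (is.character(sex) || is.factor(sex))
    as.numeric(as.character(sex) == "male") else as.numeric(sex)
  out <- c(fw_mean, fat_mean, age, sex01)
  names(out) <- c(sprintf("fw_r%03d", labels), sprintf("fat_r%03d", labels),
                  "age", "sex")
  out
}
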