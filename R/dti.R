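#' Fractional anisotropy from tensor eigenvalues
#'
#' \deqn{FA = \sqrt{\tfrac{3}{2}\,\sum_i(\lambda_i - \bar\lambda)^2 /
#'   \sum_i \lambda_i^2}}
#' Vectorised over voxels; the all-zero tensor is defined to have FA 0.
#'
#' @param l1,l2,l3 eigenvalues (any order), all `>= 0`.
#' @return FA in `[0, 1]`.
#' @export
fractional_anisotropy <- function(l1, l2, l3) {
  if (any(c(l1, l2, l3) < 0)) stop("eigenvalues must be >= 0")
  md <- (l1 + l2 + l3) / 3
  num <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5 * num / ifelse(den > 0, den, 1))
  fa[den == 0] <- 0
  pmin(fa, 1)
}

# design matrix for log-linear tensor regression:
# log S = log s0 - b g' D g, columns (1, dxx, dyy, dzz, dxy, dxz, dyz)
.dti_design <- function(grad) {
  b <- grad$bvals
  g <- grad$bvecs
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit a single diffusion tensor by weighted log-linear least squares
#'
#' Standard DTI estimator: regress `log S` on the b-matrix with weights
#' `S^2` (the delta-method weights for log-transformed Rician/Gaussian
#' data).  Nonpositive signals are clipped to `1e-6 * s0` before the log.
#' Negative eigenvalues are clipped to 0 for the derived scalars.
#'
#' @param signals per-gradient intensities (length = gradient-table rows).
#' @param grad a [gradient_table()].
#' @return list with `tensor` (3x3), `eigenvalues` (descending, clipped),
#'   `md`, `fa`, `s0`.
#' @export
fit_dti <- function(signals, grad) {
  stopifnot(inherits(grad, "gradient_table"))
  if (length(signals) != length(grad$bvals))
    stop("signal count does not match gradient table")
  if (length(signals) < 7L)
    stop("tensor fit needs >= 7 measurements (6 tensor components + s0)")
  if (grad$n_b0 < 1L)
    stop("tensor fit needs >= 1 b = 0 measurement")
  s0_hat <- mean(signals[grad$bvals == 0])
  s <- pmax(signals, 1e-6 * max(s0_hat, .Machine$double.eps))
  X <- .dti_design(grad)
  w <- s^2
  qrX <- qr(X * sqrt(w))
  if (qrX$rank < 7L)
    stop("rank-deficient gradient design: too few unique directions")
  beta <- qr.coef(qrX, log(s) * sqrt(w))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  evc <- pmax(ev, 0)
  list(tensor = D, eigenvalues = evc, md = mean(evc),
       fa = fractional_anisotropy(evc[1], evc[2], evc[3]),
       s0 = exp(beta[1]))
}
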