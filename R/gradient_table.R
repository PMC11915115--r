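#' Construct a gradient table
#'
#' An acquisition scheme: one b-value (s/mm^2) and one unit gradient
#' direction per diffusion-weighted volume, shared between the signal
#' simulator and the model fits.
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs N x 3 matrix of gradient directions; rows for `b > 0` must
#'   be unit-norm within 1e-4 (use `normalize = TRUE` to rescale).
#' @param normalize rescale nonzero-b rows to unit norm.
#' @return object of class `gradient_table`: list with `bvals`, `bvecs`
#'   (N x 3), `n_b0`, `n_dirs`.
#' @export
gradient_table <- function(bvals, bvecs, normalize = FALSE) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L && nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must be N x 3 (or 3 x N)")
  if (length(bvals) != nrow(bvecs))
    stop("bvals (", length(bvals), ") and bvecs (", nrow(bvecs),
         ") lengths differ")
  dwi <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (normalize && any(dwi)) bvecs[dwi, ] <- bvecs[dwi, ] / nrm[dwi]
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[dwi] - 1) > 1e-4))
    stop("nonzero-b gradient directions must be unit-norm (within 1e-4)")
  structure(list(bvals = as.numeric(bvals), bvecs = unname(bvecs),
                 n_b0 = sum(!dwi), n_dirs = sum(dwi)),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("gradient_table:", x$n_dirs, "diffusion directions (b =",
      paste(unique(x$bvals[x$bvals > 0]), collapse = ", "),
      "s/mm^2),", x$n_b0, "b0 volumes\n")
  invisible(x)
}

#' Deterministic single-shell protocol gradients
#'
#' Builds the acquisition the study protocol prescribes (>= 30 directions,
#' 5 b0 volumes, b = 1000 s/mm^2) with directions spread on the sphere by a
#' Fibonacci lattice, so the scheme is well-conditioned and reproducible
#' without randomness.
#'
#' @param n_dirs number of diffusion directions (default 30).
#' @param n_b0 number of b = 0 volumes (default 5).
#' @param bval shell b-value (default 1000).
#' @return a [gradient_table()].
#' @export
protocol_gradients <- function(n_dirs = 30L, n_b0 = 5L, bval = 1000) {
  i <- seq_len(n_dirs) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dirs
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  gradient_table(c(rep(0, n_b0), rep(bval, n_dirs)),
                 rbind(matrix(0, n_b0, 3), dirs), normalize = TRUE)
}

#' Read an FSL-style gradient table
#'
#' FSL dialect: `.bval` is one whitespace-separated row of N b-values,
#' `.bvec` is 3 rows x N columns.  A transposed (one row per entry) dialect
#' is accepted with `dialect = "column"`.  Directions with `b > 0` are
#' normalised to unit length; protocol deviations (fewer than 30 directions
#' or fewer than 5 b0 volumes) emit warnings but parse.
#'
#' @param bval_path,bvec_path text file paths.
#' @param dialect `"fsl"` (3 x N bvec) or `"column"` (N x 3 bvec).
#' @return a [gradient_table()].
#' @export
read_gradient_table <- function(bval_path, bvec_path, dialect = c("fsl", "column")) {
  dialect <- match.arg(dialect)
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (dialect == "fsl") {
    if (nrow(bv) != 3L) stop("FSL bvec file must have exactly 3 rows")
    bv <- t(bv)
  } else if (ncol(bv) != 3L) {
    stop("column-dialect bvec file must have exactly 3 columns")
  }
  if (length(bvals) != nrow(bv))
    stop("bval count (", length(bvals), ") does not match bvec count (",
         nrow(bv), ")")
  gt <- gradient_table(bvals, bv, normalize = TRUE)
  if (gt$n_dirs < 30L)
    warning("protocol deviation: ", gt$n_dirs, " diffusion directions (< 30)")
  if (gt$n_b0 < 5L)
    warning("protocol deviation: ", gt$n_b0, " b0 volumes (< 5)")
  gt
}

#' Write a gradient table in FSL dialect
#'
#' @param grad a [gradient_table()].
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_gradient_table <- function(grad, bval_path, bvec_path) {
  writeLines(paste(format(grad$bvals, trim = TRUE), collapse = " "), bval_path)
  m <- t(grad$bvecs)
  writeLines(apply(m, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}
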