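## Linear max-margin classifier: L2-regularised squared-hinge primal
## (the LIBLINEAR L2L2 formulation) solved with L-BFGS-B, plus Platt
## sigmoid calibration of margins to probabilities.

# objective and gradient of 0.5||w||^2 + C sum max(0, 1 - y f)^2, f = Xw + b
.svm_obj <- function(theta, X, y, C) {
  p <- ncol(X)
  w <- theta[seq_len(p)]
  b <- theta[p + 1L]
  f <- drop(X %*% w) + b
  xi <- pmax(0, 1 - y * f)
  0.5 * sum(w^2) + C * sum(xi^2)
}

.svm_grad <- function(theta, X, y, C) {
  p <- ncol(X)
  w <- theta[seq_len(p)]
  b <- theta[p + 1L]
  f <- drop(X %*% w) + b
  xi <- pmax(0, 1 - y * f)
  gy <- -2 * C * xi * y
  c(w + drop(crossprod(X, gy)), sum(gy))
}

#' Fit a linear max-margin classifier
#'
#' Features are z-scaled with statistics learned from the training data
#' only; zero-variance features are dropped from scaling and receive weight
#' zero.  Labels are coded +1 for the positive class.
#'
#' @param X numeric matrix (rows = samples).
#' @param y vector coercible to -1/+1 (logical, 0/1 or -1/+1).
#' @param C regularisation parameter (larger = less regularised).
#' @return list of class `svm_linear`: `weights` (on the original feature
#'   scale positions, zero for dropped features), `bias`, `C`, `scaling`
#'   (`center`, `scale`, `keep`), `calibration` (NULL until fitted).
#' @export
svm_linear_fit <- function(X, y, C = 1) {
  X <- as.matrix(X)
  y <- .to_pm1(y)
  if (length(unique(y)) < 2L) stop("training labels must contain both classes")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  keep <- sdv > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], "/")
  p <- ncol(Xs)
  fit <- optim(rep(0, p + 1L), .svm_obj, .svm_grad, X = Xs, y = y, C = C,
               method = "L-BFGS-B",
               control = list(maxit = 500L, factr = 1e7))
  w <- numeric(ncol(X))
  w[keep] <- fit$par[seq_len(p)]
  structure(list(weights = w, bias = fit$par[p + 1L], C = C,
                 scaling = list(center = mu, scale = sdv, keep = keep),
                 calibration = NULL, converged = fit$convergence == 0,
                 feature_names = colnames(X)),
            class = "svm_linear")
}

.to_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) return(ifelse(y == 1, 1, -1))
  if (all(y %in% c(-1, 1))) return(y)
  stop("labels must be logical, 0/1 or -1/+1")
}

#' Signed margin of a fitted linear model
#'
#' @param model an `svm_linear`.
#' @param X feature matrix with the training column count.
#' @return numeric margins (positive = positive class side).
#' @export
svm_margin <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$weights))
    stop("feature length (", ncol(X), ") does not match model (",
         length(model$weights), ")")
  k <- model$scaling$keep
  Xs <- sweep(sweep(X[, k, drop = FALSE], 2L, model$scaling$center[k]),
              2L, model$scaling$scale[k], "/")
  drop(Xs %*% model$weights[k]) + model$bias
}

#' Platt sigmoid calibration
#'
#' Fits `P(positive | margin) = plogis(a * margin + c)` by penalised
#' maximum likelihood with Platt's smoothed targets
#' `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`, which keeps the fit finite on
#' separable data.  Margins should be out-of-fold to avoid optimism.
#'
#' @param margins numeric margins.
#' @param y labels (+1/-1 after coercion).
#' @return `c(a, c)` with `a > 0` enforced by the fit (probability is
#'   monotone increasing in margin).
#' @export
platt_calibrate <- function(margins, y) {
  y <- .to_pm1(y)
  npos <- sum(y > 0); nneg <- sum(y < 0)
  t <- ifelse(y > 0, (npos + 1) / (npos + 2), 1 / (nneg + 2))
  nll <- function(par) {
    eta <- par[1] * margins + par[2]
    # cross-entropy with smoothed targets; log1p form is overflow-safe
    sum((1 - t) * eta + log1p(exp(-eta)))
  }
  fit <- optim(c(1, 0), nll, method = "BFGS", control = list(maxit = 300L))
  par <- fit$par
  if (par[1] <= 0) par <- c(1e-6, par[2])  # guard monotonicity
  par
}

#' @export
predict.svm_linear <- function(object, newdata, threshold = 0.5, ...) {
  m <- svm_margin(object, newdata)
  cal <- object$calibration
  prob <- if (is.null(cal)) plogis(m) else plogis(cal[1] * m + cal[2])
  data.frame(margin = m, probability = prob,
             label = ifelse(prob >= threshold, "positive", "negative"),
             stringsAsFactors = FALSE)
}
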