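#' AUROC by the Mann-Whitney estimator
#'
#' Fraction of (positive, negative) score pairs with the positive ranked
#' higher; ties count one half.
#'
#' @param pos scores of true positives.
#' @param neg scores of true negatives.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  if (m < 1L || n < 1L) stop("AUROC needs >= 1 score in each class")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# DeLong placement values: V10_i = mean_j psi(pos_i, neg_j), V01_j likewise
.delong_components <- function(pos, neg) {
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' AUROC with DeLong variance and confidence interval
#'
#' Nonparametric variance from the placement-value components
#' `var(V10)/m + var(V01)/n`; normal-approximation CI truncated to
#' `[0, 1]`.  All-tied (degenerate) scores give variance 0 and a point CI.
#'
#' @param pos,neg scores by true class (each >= 2 values).
#' @param level confidence level (default 0.95).
#' @return list: `auroc`, `ci_low`, `ci_high`, `variance`, `se`.
#' @export
delong_ci <- function(pos, neg, level = 0.95) {
  if (length(pos) < 2L || length(neg) < 2L)
    stop("DeLong variance needs >= 2 scores per class")
  cmp <- .delong_components(pos, neg)
  v <- var(cmp$v10) / length(pos) + var(cmp$v01) / length(neg)
  se <- sqrt(v)
  z <- qnorm(1 - (1 - level) / 2)
  list(auroc = cmp$auc,
       ci_low = max(0, cmp$auc - z * se),
       ci_high = min(1, cmp$auc + z * se),
       variance = v, se = se)
}

#' One-sided z test of AUROC against a null value
#'
#' `z = (AUROC - null) / se(DeLong)`; upper-tail p for
#' `alternative = "greater"`.  Zero variance with AUROC above the null
#' reports the 0 sentinel (below: 1).
#'
#' @param pos,neg scores by true class.
#' @param null_auroc null AUROC (the study design used 0.80).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return list: `auroc`, `z`, `p_value`, `variance`.
#' @export
auroc_z_test <- function(pos, neg, null_auroc = 0.8,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- delong_ci(pos, neg)
  if (d$variance == 0) {
    p <- if (d$auroc > null_auroc) 0 else if (d$auroc < null_auroc) 1 else 0.5
    return(list(auroc = d$auroc, z = Inf * sign(d$auroc - null_auroc),
                p_value = if (alternative == "two.sided" && p %in% c(0, 1))
                  abs(2 * p - ifelse(p == 1, 2, 0)) else p,
                variance = 0))
  }
  z <- (d$auroc - null_auroc) / d$se
  p <- switch(alternative,
              greater = pnorm(z, lower.tail = FALSE),
              two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  list(auroc = d$auroc, z = z, p_value = p, variance = d$variance)
}

#' Confusion-table metrics
#'
#' @param predictions predicted positivity (logical).
#' @param truths true positivity (logical).
#' @return list: `sensitivity`, `specificity`, `ppv`, `npv`, `counts`
#'   (TP/FP/TN/FN).  Undefined ratios (e.g. no predicted positives) are NA
#'   with counts intact.
#' @export
confusion_metrics <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  if (!any(truths) || all(truths))
    stop("confusion metrics need >= 1 positive and >= 1 negative truth")
  tp <- sum(predictions & truths)
  fp <- sum(predictions & !truths)
  tn <- sum(!predictions & !truths)
  fn <- sum(!predictions & truths)
  rat <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  list(sensitivity = rat(tp, fn), specificity = rat(tn, fp),
       ppv = rat(tp, fp), npv = rat(tn, fn),
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, `>=` raw, capped at 1), original
#'   order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  n <- length(p)
  if (n <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Assemble a full endpoint report
#'
#' AUROC with DeLong CI and one-sided z p-value against `null_auroc`, plus
#' confusion metrics at the decision threshold.
#'
#' @param pos,neg probability scores by true class.
#' @param predictions,truths logical vectors for the confusion table
#'   (order: positives then negatives if omitted).
#' @param endpoint,regime labels carried through.
#' @param null_auroc z-test null (default 0.80, the design null; 0.5 is the
#'   chance alternative).
#' @param level CI level.
#' @return list of class `endpoint_report`.
#' @export
endpoint_report <- function(pos, neg, predictions = NULL, truths = NULL,
                            endpoint = NA_character_, regime = NA_character_,
                            null_auroc = 0.8, level = 0.95) {
  ci <- delong_ci(pos, neg, level = level)
  zt <- auroc_z_test(pos, neg, null_auroc = null_auroc)
  if (is.null(predictions)) {
    predictions <- c(pos, neg) >= 0.5
    truths <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
  }
  cm <- confusion_metrics(predictions, truths)
  structure(list(endpoint = endpoint, regime = regime,
                 auroc = ci$auroc, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 variance = ci$variance, p_value = zt$p_value,
                 null_auroc = null_auroc,
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 ppv = cm$ppv, npv = cm$npv, counts = cm$counts,
                 bh_adjusted_p = NA_real_,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "endpoint_report")
}

#' @export
print.endpoint_report <- function(x, ...) {
  cat(sprintf("%s [%s]: AUROC %.3f (95%% CI %.3f-%.3f), p=%.3g vs null %.2f\n",
              x$endpoint, x$regime, x$auroc, x$ci_low, x$ci_high,
              x$p_value, x$null_auroc))
  cat(sprintf("  sens %.3f  spec %.3f  PPV %.3f  NPV %.3f  (TP %d FP %d TN %d FN %d)\n",
              x$sensitivity, x$specificity, x$ppv, x$npv,
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  invisible(x)
}

#' Apply BH correction across a regime's endpoint reports
#'
#' @param reports named list of `endpoint_report`s (one regime).
#' @return the list with `bh_adjusted_p` filled in.
#' @export
adjust_reports <- function(reports) {
  p <- vapply(reports, function(r) r$p_value, numeric(1))
  adj <- bh_adjust(p)
  for (i in seq_along(reports)) reports[[i]]$bh_adjusted_p <- adj[i]
  reports
}

#' Pooled summary of verification-run AUROCs
#'
#' @param run_aurocs numeric AUROCs, one per run (>= 2 for a CI).
#' @param level confidence level.
#' @return list: `mean`, `ci_low`, `ci_high` (t-based CI on the mean; NA
#'   and `ci_defined = FALSE` with a single run), `n_runs`.
#' @export
pooled_summary <- function(run_aurocs, level = 0.95) {
  n <- length(run_aurocs)
  if (n < 1L) stop("no runs to pool")
  m <- mean(run_aurocs)
  if (n == 1L)
    return(list(mean = m, ci_low = NA_real_, ci_high = NA_real_,
                n_runs = 1L, ci_defined = FALSE))
  se <- sd(run_aurocs) / sqrt(n)
  tq <- qt(1 - (1 - level) / 2, df = n - 1L)
  list(mean = m, ci_low = m - tq * se, ci_high = m + tq * se,
       n_runs = n, ci_defined = TRUE)
}

#' OLS regression of probability estimates on a clinical covariate
#'
#' @param probabilities response (e.g. atypical probability estimates).
#' @param covariate predictor (e.g. UMSARS); must be nonconstant.
#' @return list: `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   slope test), `n`.
#' @export
regress_probability <- function(probabilities, covariate) {
  ok <- complete.cases(probabilities, covariate)
  y <- probabilities[ok]; x <- covariate[ok]
  if (length(y) < 3L) stop("regression needs >= 3 complete observations")
  if (sd(x) == 0) stop("constant covariate: regression undefined")
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared, p_value = s$coefficients[2, 4],
       n = length(y))
}

# Hanley-McNeil variance approximation of the AUROC estimator
.hm_variance <- function(a, m, n) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  (a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) / (m * n)
}

#' Power of the one-sided AUROC z test
#'
#' Analytic path: binormal/Hanley-McNeil variance approximation at the null
#' and alternative AUROC.  Simulation path: binormal score sets at the
#' alternative AUROC, DeLong z test against the null, rejection fraction.
#' The study design: null 0.80, alternative 0.90, alpha .05 one-sided, 80%
#' power.
#'
#' @param null_auroc,alt_auroc design AUROCs (`0.5 <= null < alt <= 1`).
#' @param m,n positive and negative group sizes.
#' @param alpha one-sided significance level.
#' @param method `"analytic"` or `"simulation"`.
#' @param nsim simulation replicates.
#' @param seed simulation seed.
#' @return list: `power`, `method`, plus `small_sample` warning flag when
#'   `m` or `n < 5`.
#' @export
power_auroc <- function(null_auroc = 0.80, alt_auroc = 0.90, m, n,
                        alpha = 0.05, method = c("analytic", "simulation"),
                        nsim = 2000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(null_auroc >= 0.5, null_auroc < alt_auroc, alt_auroc <= 1,
            alpha > 0, alpha < 0.5, m >= 1, n >= 1)
  small <- m < 5 || n < 5
  if (method == "analytic") {
    # the z statistic standardises by the SE estimated from the data, which
    # under the alternative concentrates at se(alt); use it on both sides
    se1 <- sqrt(.hm_variance(alt_auroc, m, n))
    pw <- pnorm((alt_auroc - null_auroc) / se1 - qnorm(1 - alpha))
  } else {
    delta <- sqrt(2) * qnorm(alt_auroc)  # binormal separation for the AUROC
    rej <- with_seed(seed, {
      vapply(seq_len(nsim), function(i) {
        pos <- rnorm(m, mean = delta)
        neg <- rnorm(n)
        auroc_z_test(pos, neg, null_auroc = null_auroc)$p_value < alpha
      }, logical(1))
    })
    pw <- mean(rej)
  }
  list(power = pw, method = method, small_sample = small)
}

#' Concordance of model and clinical diagnoses with neuropathology
#'
#' Per-class and pooled percent agreement of the model-vs-pathology and
#' clinical-vs-pathology calls, and the diagnostic gain.  Following the
#' published arithmetic, `gain` is the difference of the two pooled
#' percentages after rounding each to one decimal (`gain_raw` is the
#' unrounded difference).
#'
#' @param predicted model diagnosis per brain.
#' @param clinical last clinical diagnosis per brain.
#' @param pathology neuropathological diagnosis per brain (reference; must
#'   be complete).
#' @return list: `model` and `clinical` (each with `per_class` counts,
#'   `correct`, `total`, `percent`), `gain`, `gain_raw`.
#' @export
concordance_report <- function(predicted, clinical, pathology) {
  if (length(pathology) == 0L) stop("empty concordance input")
  stopifnot(length(predicted) == length(pathology),
            length(clinical) == length(pathology),
            !any(is.na(pathology)))
  tally <- function(calls) {
    per <- lapply(split(calls == pathology, pathology), function(v)
      c(correct = sum(v), total = length(v)))
    correct <- sum(calls == pathology)
    list(per_class = per, correct = correct, total = length(pathology),
         percent = 100 * correct / length(pathology))
  }
  mo <- tally(predicted)
  cl <- tally(clinical)
  list(model = mo, clinical = cl,
       gain = round(mo$percent, 1) - round(cl$percent, 1),
       gain_raw = mo$percent - cl$percent)
}

#' Compare endpoint reports across the two scan sessions
#'
#' @param reports_session1,reports_session2 named lists of
#'   `endpoint_report`s over the same endpoints (same test subjects).
#' @param subjects1,subjects2 optional subject-id vectors backing each
#'   session's reports; if given they must contain the same subjects.
#' @return data.frame: endpoint, auroc_s1, auroc_s2, delta.
#' @export
test_retest_compare <- function(reports_session1, reports_session2,
                                subjects1 = NULL, subjects2 = NULL) {
  if (!setequal(names(reports_session1), names(reports_session2)))
    stop("sessions cover different endpoints")
  if (!is.null(subjects1) && !setequal(subjects1, subjects2 %||% character()))
    stop("mismatched subject sets between sessions")
  eps <- names(reports_session1)
  for (ep in eps) {
    r1 <- reports_session1[[ep]]; r2 <- reports_session2[[ep]]
    if (r1$n_pos != r2$n_pos || r1$n_neg != r2$n_neg)
      stop("mismatched subject sets between sessions for ", ep)
  }
  data.frame(
    endpoint = eps,
    auroc_s1 = vapply(reports_session1[eps], `[[`, numeric(1), "auroc"),
    auroc_s2 = vapply(reports_session2[eps], `[[`, numeric(1), "auroc"),
    delta = vapply(eps, function(ep)
      reports_session2[[ep]]$auroc - reports_session1[[ep]]$auroc,
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
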