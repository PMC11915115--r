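test_that("AUROC matches the exhaustive pair-count oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.7), c(0.6, 0.5, 0.4)), 1.0)
  expect_equal(auroc(c(0.8, 0.6, 0.4), c(0.7, 0.5, 0.3)), 6 / 9)
  expect_equal(auroc(0.5, 0.5), 0.5)
  expect_error(auroc(numeric(0), 1), ">= 1")
  # property: all m, n <= 8 against full pair enumeration (with ties)
  pair_count <- function(pos, neg) {
    s <- 0
    for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
    s / (length(pos) * length(neg))
  }
  set.seed(10)
  for (m in 1:8) for (n in 1:8) {
    pos <- sample(seq(0, 1, 0.1), m, replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    expect_equal(auroc(pos, neg), pair_count(pos, neg))
  }
})

test_that("DeLong variance equals the direct placement-value computation", {
  set.seed(11)
  for (i in 1:10) {
    pos <- rnorm(sample(3:12, 1), mean = 0.5)
    neg <- rnorm(sample(3:12, 1))
    d <- delong_ci(pos, neg)
    # independent recomputation of the structural components
    psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    v <- var(rowMeans(psi)) / length(pos) + var(colMeans(psi)) / length(neg)
    expect_equal(d$variance, v)
    expect_equal(d$auroc, mean(psi))
    expect_true(d$ci_low <= d$auroc && d$auroc <= d$ci_high)
    expect_true(d$ci_low >= 0 && d$ci_high <= 1)
  }
  # perfectly separated: variance 0, point CI at 1
  d1 <- delong_ci(c(3, 4, 5), c(0, 1, 2))
  expect_equal(d1$auroc, 1)
  expect_equal(d1$variance, 0)
  expect_equal(c(d1$ci_low, d1$ci_high), c(1, 1))
  expect_error(delong_ci(1, c(0, 0.5)), ">= 2")
})

test_that("AUROC z test covers its sentinels and directions", {
  set.seed(12)
  pos <- rnorm(30, 0.5); neg <- rnorm(30)
  a <- delong_ci(pos, neg)$auroc
  expect_equal(auroc_z_test(pos, neg, null_auroc = a)$p_value, 0.5,
               tolerance = 1e-9)
  expect_gt(auroc_z_test(pos, neg, null_auroc = 0.99)$p_value, 0.5)
  expect_equal(auroc_z_test(c(3, 4), c(1, 2), null_auroc = 0.8)$p_value, 0)
})

test_that("confusion metrics reproduce the published testing row", {
  # PD vs AP testing set: 85 AP (positive), 60 PD; TP 74 FN 11 TN 53 FP 7
  truths <- c(rep(TRUE, 85), rep(FALSE, 60))
  preds <- c(rep(TRUE, 74), rep(FALSE, 11), rep(FALSE, 53), rep(TRUE, 7))
  cm <- confusion_metrics(preds, truths)
  expect_equal(round(cm$sensitivity, 3), 0.871)
  expect_equal(round(cm$specificity, 3), 0.883)
  expect_equal(round(cm$ppv, 3), 0.914)
  expect_equal(round(cm$npv, 3), 0.828)
  expect_equal(sum(cm$counts), 145)

  cm1 <- confusion_metrics(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_true(all(unlist(cm1[1:4]) == 1))
  # no predicted positives: PPV undefined, counts intact
  cm2 <- confusion_metrics(c(FALSE, FALSE), c(TRUE, FALSE))
  expect_true(is.na(cm2$ppv))
  expect_equal(unname(cm2$counts["FN"]), 1)
  expect_error(confusion_metrics(c(TRUE, TRUE), c(TRUE, TRUE)), "negative")
})

test_that("BH adjustment matches the step-up rule and reference oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:10, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))  # independent reference
    expect_true(all(adj >= p))
    # monotone in the raw ranks
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("pooled verification summaries are t-based and degenerate-safe", {
  ps <- pooled_summary(c(0.9, 0.9, 0.9))
  expect_equal(ps$mean, 0.9)
  expect_equal(ps$ci_low, 0.9)
  expect_equal(ps$ci_high, 0.9)
  expect_equal(pooled_summary(c(0.8, 1.0))$mean, 0.9)
  p1 <- pooled_summary(0.85)
  expect_false(p1$ci_defined)
  # coverage: CI on the mean contains the generating mean in >= 90/100
  set.seed(14)
  cover <- vapply(1:100, function(i) {
    runs <- rnorm(49, 0.95, 0.01)
    s <- pooled_summary(runs)
    s$ci_low <= 0.95 && 0.95 <= s$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("probability regressions behave on exact, null and error cases", {
  x <- 1:10
  r <- suppressWarnings(regress_probability(2 * x, x))  # exact fit warns
  expect_equal(r$slope, 2)
  expect_equal(r$r_squared, 1)
  set.seed(15)
  rn <- regress_probability(runif(100), rnorm(100))
  expect_lt(rn$r_squared, 0.1)
  expect_error(regress_probability(runif(10), rep(3, 10)), "constant")
  expect_error(regress_probability(c(1, 2), c(1, 2)), ">= 3")
})

test_that("power calculation covers limits and design values", {
  # alt barely above null: power ~ alpha
  p0 <- power_auroc(0.80, 0.8001, m = 60, n = 85, method = "simulation",
                    nsim = 500, seed = 16)
  expect_lt(abs(p0$power - 0.05), 0.04)
  # extreme alternative with large n: power ~ 1
  p1 <- power_auroc(0.80, 0.999, m = 100, n = 100)
  expect_gt(p1$power, 0.999)
  expect_true(power_auroc(0.8, 0.9, m = 3, n = 10)$small_sample)
  expect_error(power_auroc(0.9, 0.8, m = 10, n = 10), "null_auroc")
})

test_that("concordance arithmetic reproduces the neuropathology accounting", {
  path <- c(rep("PD", 5), rep("MSA", 5), rep("PSP", 39))
  model <- path
  model[c(11, 12, 13)] <- "MSA"        # 3 PSP misses -> 36/39
  clinical <- path
  clinical[c(1, 6, 7, 11, 12, 13, 14, 15, 16)] <-
    c("MSA", "PD", "PSP", rep("MSA", 6))  # 4/5, 3/5, 33/39
  cr <- concordance_report(model, clinical, path)
  expect_equal(cr$model$correct, 46)
  expect_equal(round(cr$model$percent, 1), 93.9)
  expect_equal(round(cr$clinical$percent, 1), 81.6)
  expect_equal(cr$gain, 12.3)
  expect_equal(unname(cr$model$per_class$PSP["correct"]), 36)
  expect_error(concordance_report(character(), character(), character()),
               "empty")
})

test_that("test-retest comparison pairs sessions and flags mismatches", {
  r1 <- list(PD_vs_AP = endpoint_report(c(0.9, 0.8, 0.9), c(0.2, 0.1, 0.3)))
  expect_equal(test_retest_compare(r1, r1)$delta, 0)
  r2 <- list(PD_vs_AP = endpoint_report(c(0.7, 0.8), c(0.2, 0.1)))
  expect_error(test_retest_compare(r1, r2), "mismatched")
  expect_error(test_retest_compare(r1, list(MSA_vs_PSP = r1[[1]])),
               "different endpoints")
  expect_error(test_retest_compare(r1, r1, subjects1 = c("a", "b"),
                                   subjects2 = c("a", "c")), "mismatched")
})

test_that("endpoint reports assemble and BH-adjust across a regime", {
  set.seed(17)
  reports <- lapply(endpoint_names(), function(ep)
    endpoint_report(runif(20, 0.4, 1), runif(25, 0, 0.6), endpoint = ep,
                    regime = "primary", null_auroc = 0.5))
  names(reports) <- endpoint_names()
  adj <- adjust_reports(reports)
  raw <- vapply(adj, `[[`, numeric(1), "p_value")
  bh <- vapply(adj, `[[`, numeric(1), "bh_adjusted_p")
  expect_equal(unname(bh), bh_adjust(unname(raw)))
  expect_true(all(bh >= raw))
})
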