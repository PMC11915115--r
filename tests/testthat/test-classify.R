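test_that("endpoint specs partition the diagnoses as published", {
  ep <- endpoint_spec("PD_vs_AP")
  expect_setequal(ep$positive, c("MSA", "PSP"))
  expect_equal(ep$negative, "PD")
  expect_length(ep$excluded, 0L)
  for (nm in endpoint_names()) {
    e <- endpoint_spec(nm)
    expect_setequal(c(e$positive, e$negative, e$excluded),
                    c("PD", "MSA", "PSP"))
  }
  expect_equal(endpoint_labels(c("PD", "MSA", "PSP"), "PD_vs_MSA"),
               c(-1, 1, NA))
  expect_error(endpoint_spec("PD_vs_ET"), "unknown endpoint")
})

test_that("stratified split reproduces the published cohort accounting", {
  coh <- generate_cohort(cohort_spec(seed = 7))
  sp <- stratified_split(coh, test_counts = c(PD = 60, MSA = 27, PSP = 58),
                         seed = 11)
  a <- sp$assignment
  tr <- coh[a[coh$subject_id] == "train", ]
  te <- coh[a[coh$subject_id] == "test", ]
  expect_equal(as.integer(table(tr$diagnosis)[c("PD", "MSA", "PSP")]),
               c(250, 124, 126))
  expect_equal(as.integer(table(te$diagnosis)[c("PD", "MSA", "PSP")]),
               c(60, 27, 58))
  expect_equal(nrow(tr), 500L)
  expect_equal(nrow(te), 145L)
  # prospective train = 39/26/39; retrospective never tests
  prot <- tr[tr$cohort == "prospective", ]
  expect_equal(as.integer(table(prot$diagnosis)[c("PD", "MSA", "PSP")]),
               c(39, 26, 39))
  expect_true(all(te$cohort == "prospective"))
  # all 21 sites in both sets
  expect_true(sp$all_sites_covered)
  expect_setequal(unique(prot$site), unique(te$site))
  no_leakage_check(sp)
})

test_that("split edge cases: zero test fraction, seeds, infeasible targets", {
  coh <- generate_cohort(cohort_spec(
    n_prospective = c(PD = 10, MSA = 8, PSP = 9),
    n_retrospective = c(PD = 3, MSA = 2, PSP = 2), seed = 4))
  sp0 <- stratified_split(coh, test_fraction = 0, seed = 1)
  expect_true(all(sp0$assignment == "train"))
  s1 <- stratified_split(coh, test_counts = c(PD = 4, MSA = 3, PSP = 3),
                         seed = 1)
  s2 <- stratified_split(coh, test_counts = c(PD = 4, MSA = 3, PSP = 3),
                         seed = 2)
  ids1 <- names(s1$assignment)[s1$assignment == "test"]
  ids2 <- names(s2$assignment)[s2$assignment == "test"]
  expect_false(setequal(ids1, ids2))
  d1 <- coh$diagnosis[match(ids1, coh$subject_id)]
  d2 <- coh$diagnosis[match(ids2, coh$subject_id)]
  lv <- c("PD", "MSA", "PSP")
  expect_equal(as.integer(table(factor(d1, lv))),
               as.integer(table(factor(d2, lv))))
  expect_error(stratified_split(coh, test_counts = c(PD = 99, MSA = 1, PSP = 1)),
               "infeasible")
})

test_that("cross-validation folds are stratified, near-equal and leak-free", {
  coh <- generate_cohort(cohort_spec(seed = 7))
  sp <- stratified_split(coh, test_counts = c(PD = 60, MSA = 27, PSP = 58),
                         seed = 11)
  sp <- make_cv_folds(sp, coh, k = 5, seed = 2)
  sizes <- table(sp$folds)
  expect_equal(length(sizes), 5L)
  expect_lte(diff(range(sizes)), 2L)  # 500 subjects, <=1 per class per fold
  cls <- coh$diagnosis[match(names(sp$folds), coh$subject_id)]
  for (cl in c("PD", "MSA", "PSP"))
    expect_lte(diff(range(table(sp$folds[cls == cl]))), 1L)
  expect_true(all(sp$assignment[names(sp$folds)] == "train"))
  no_leakage_check(sp)

  # 7 subjects in one class, k = 5 -> sizes {2,2,1,1,1}
  coh7 <- generate_cohort(cohort_spec(
    n_prospective = c(PD = 7, MSA = 7, PSP = 7),
    n_retrospective = c(PD = 0, MSA = 0, PSP = 0), seed = 1))
  sp7 <- stratified_split(coh7, test_fraction = 0, seed = 1)
  sp7 <- make_cv_folds(sp7, coh7, k = 5, seed = 1)
  pd <- sp7$folds[coh7$subject_id[coh7$diagnosis == "PD"]]
  expect_equal(sort(as.integer(table(pd)), decreasing = TRUE),
               c(2, 2, 1, 1, 1))
  expect_error(make_cv_folds(sp7, coh7, k = 9, seed = 1), "exceeds")
})

test_that("site holdout isolates whole sites with classes represented", {
  coh <- generate_cohort(cohort_spec(seed = 7))
  sp <- site_holdout_split(coh, n_holdout_sites = 6, seed = 3)
  te <- coh[sp$assignment[coh$subject_id] == "test", ]
  tr <- coh[sp$assignment[coh$subject_id] == "train", ]
  expect_length(sp$holdout_sites, 6L)
  expect_length(setdiff(unique(tr$site[tr$cohort == "prospective"]),
                        "retro"), 15L)
  expect_length(intersect(unique(te$site),
                          unique(tr$site[tr$cohort == "prospective"])), 0L)
  expect_true(all(tr$subject_id[tr$cohort == "retrospective"] %in%
                    names(sp$assignment)[sp$assignment == "train"]))
  expect_setequal(unique(te$diagnosis), c("PD", "MSA", "PSP"))
  coh2 <- coh[coh$site %in% c("site01", "site02", "retro"), ]
  expect_error(site_holdout_split(coh2, 6), "too few sites")
})

test_that("site-confounded effects degrade site-holdout relative to random split", {
  # feature 1 carries a site-specific shift whose sign interacts with the
  # class signal: a random split shares sites between train and test and
  # can exploit it, a site holdout cannot (means over 3 splits per regime)
  coh <- generate_cohort(cohort_spec(
    n_prospective = c(PD = 80, MSA = 40, PSP = 40),
    n_retrospective = c(PD = 0, MSA = 0, PSP = 0),
    site_ids = sprintf("s%02d", 1:16), seed = 31))
  set.seed(32)
  n <- nrow(coh)
  X <- matrix(rnorm(n * 10), n, 10)
  lab <- ifelse(coh$diagnosis == "PD", -1, 1)
  site_shift <- rnorm(16)[as.integer(factor(coh$site))]
  X[, 1] <- X[, 1] + 0.4 * lab + 2 * site_shift * lab
  feats <- data.frame(subject_id = coh$subject_id,
                      diagnosis = coh$diagnosis, X, check.names = FALSE)
  rand <- mean(vapply(33:35, function(s) evaluate_endpoint(
    feats, make_cv_folds(stratified_split(coh, test_fraction = 0.3, seed = s),
                         coh, 5, s + 10),
    "PD_vs_AP", C_grid = c(0.1, 1))$report$auroc, numeric(1)))
  site <- mean(vapply(36:38, function(s) evaluate_endpoint(
    feats, make_cv_folds(site_holdout_split(coh, 5, seed = s), coh, 5, s + 10),
    "PD_vs_AP", C_grid = c(0.1, 1))$report$auroc, numeric(1)))
  expect_lte(site, rand)
})

test_that("verification runs produce distinct leak-free splits, run 1 = primary", {
  coh <- generate_cohort(cohort_spec(
    n_prospective = c(PD = 12, MSA = 9, PSP = 9),
    n_retrospective = c(PD = 0, MSA = 0, PSP = 0), seed = 21))
  a <- generate_atlas(c(10, 10, 10), 16, seed = 1)
  tr <- make_ground_truth(a, seed = 2)
  eff <- default_effect_spec(strength = 2, site_sd = 0, retest_sd = 0)
  feats <- feature_table_from_truth(coh, tr, eff, noise_sd = 0.02, seed = 3)
  tc <- c(PD = 4, MSA = 3, PSP = 3)
  runs <- run_verification(feats, coh, test_counts = tc,
                           endpoints = "PD_vs_AP", n_runs = 5, seed = 9,
                           C_grid = c(0.1, 10))
  expect_length(runs, 5L)
  expect_equal(runs[[1]]$PD_vs_AP$regime, "primary")
  expect_equal(runs[[2]]$PD_vs_AP$regime, "verification")
  # strong planted effect: every run discriminates well
  aucs <- vapply(runs, function(r) r$PD_vs_AP$auroc, numeric(1))
  expect_true(all(aucs >= 0.9))
  # run 1 reproduces the primary-seed split exactly
  sp <- stratified_split(coh, test_counts = tc, seed = 9)
  sp <- make_cv_folds(sp, coh, 5, seed = derive_seed(9, "folds"))
  ev <- evaluate_endpoint(feats, sp, "PD_vs_AP", C_grid = c(0.1, 10))
  expect_equal(runs[[1]]$PD_vs_AP$auroc, ev$report$auroc)
})

test_that("age/sex features are not load-bearing when effects are imaging-borne", {
  coh <- generate_cohort(cohort_spec(
    n_prospective = c(PD = 30, MSA = 20, PSP = 20),
    n_retrospective = c(PD = 0, MSA = 0, PSP = 0), seed = 41))
  a <- generate_atlas(c(10, 10, 10), 16, seed = 1)
  tr <- make_ground_truth(a, seed = 2)
  eff <- default_effect_spec(strength = 1, site_sd = 0, retest_sd = 0)
  feats <- feature_table_from_truth(coh, tr, eff, noise_sd = 0.02, seed = 3)
  sp <- make_cv_folds(stratified_split(coh, test_fraction = 0.3, seed = 5),
                      coh, 5, 6)
  full <- evaluate_endpoint(feats, sp, "PD_vs_AP", C_grid = c(0.1, 1, 10))
  slim <- evaluate_endpoint(feats[, setdiff(names(feats), c("age", "sex"))],
                            sp, "PD_vs_AP", C_grid = c(0.1, 1, 10))
  expect_lt(abs(full$report$auroc - slim$report$auroc), 0.02)
})
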