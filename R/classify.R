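#' The four binary diagnostic endpoints
#'
#' @return character vector of endpoint names.
#' @export
endpoint_names <- function() c("PD_vs_AP", "MSA_vs_PSP", "PD_vs_MSA", "PD_vs_PSP")

#' Endpoint specification
#'
#' Maps each diagnosis to positive / negative / excluded for one binary
#' endpoint.  The atypical (or later-named) class is the positive class:
#' MSA+PSP positive vs PD; PSP positive vs MSA; MSA positive vs PD; PSP
#' positive vs PD.  This convention is the one consistent with the
#' published confusion-table metrics at the printed test-set sizes.
#'
#' @param name one of [endpoint_names()].
#' @return list of class `endpoint_spec` with `name`, `positive`,
#'   `negative`, `excluded`.
#' @export
endpoint_spec <- function(name) {
  defs <- list(
    PD_vs_AP  = list(positive = c("MSA", "PSP"), negative = "PD",
                     excluded = character()),
    MSA_vs_PSP = list(positive = "PSP", negative = "MSA", excluded = "PD"),
    PD_vs_MSA = list(positive = "MSA", negative = "PD", excluded = "PSP"),
    PD_vs_PSP = list(positive = "PSP", negative = "PD", excluded = "MSA"))
  if (!name %in% names(defs))
    stop("unknown endpoint: ", name, " (expected one of ",
         paste(endpoint_names(), collapse = ", "), ")")
  structure(c(list(name = name), defs[[name]]), class = "endpoint_spec")
}

#' Binary labels for an endpoint
#'
#' @param diagnosis character vector of PD/MSA/PSP.
#' @param endpoint an [endpoint_spec()] or endpoint name.
#' @return +1 (positive), -1 (negative) or NA (excluded) per element.
#' @export
endpoint_labels <- function(diagnosis, endpoint) {
  if (is.character(endpoint)) endpoint <- endpoint_spec(endpoint)
  out <- rep(NA_real_, length(diagnosis))
  out[diagnosis %in% endpoint$positive] <- 1
  out[diagnosis %in% endpoint$negative] <- -1
  out
}

#' Stratified train/test split
#'
#' Retrospective subjects always train (they reinforce training and are
#' never tested).  Prospective subjects are split per class to hit the
#' requested test counts exactly; site coverage of both sets is sought by
#' deterministic re-draws and recorded in the result.
#'
#' @param cohort a [generate_cohort()] table.
#' @param test_counts named per-class prospective test counts, or
#'   `test_fraction` (per-class rounded).
#' @param test_fraction alternative to `test_counts`.
#' @param seed integer seed.
#' @return list of class `split_plan`: `assignment` (named vector
#'   subject_id -> "train"/"test"), `folds` (NULL until
#'   [make_cv_folds()]), `regime`, `seed`, `all_sites_covered`.
#' @export
stratified_split <- function(cohort, test_counts = NULL, test_fraction = NULL,
                             seed = 1L) {
  stopifnot(xor(is.null(test_counts), is.null(test_fraction)))
  pro <- cohort[cohort$cohort == "prospective", ]
  classes <- sort(unique(cohort$diagnosis))
  if (is.null(test_counts)) {
    test_counts <- vapply(classes, function(cl)
      round(sum(pro$diagnosis == cl) * test_fraction), numeric(1))
  }
  for (cl in names(test_counts)) {
    avail <- sum(pro$diagnosis == cl)
    if (test_counts[[cl]] > avail || test_counts[[cl]] < 0)
      stop("infeasible test count for ", cl, ": requested ",
           test_counts[[cl]], " of ", avail, " prospective subjects")
  }
  sites <- unique(pro$site)
  draw <- function(s) {
    with_seed(s, {
      test_ids <- character()
      for (cl in names(test_counts)) {
        ids <- pro$subject_id[pro$diagnosis == cl]
        k <- as.integer(test_counts[[cl]])
        if (k > 0L) test_ids <- c(test_ids, sample(ids, k))
      }
      test_ids
    })
  }
  covered <- FALSE
  test_ids <- draw(seed)
  for (try in 0:49) {
    ids <- if (try == 0L) test_ids else draw(derive_seed(seed, paste0("resplit:", try)))
    tr_sites <- unique(pro$site[!pro$subject_id %in% ids])
    te_sites <- unique(pro$site[pro$subject_id %in% ids])
    if (setequal(sites, tr_sites) && setequal(sites, te_sites) ||
        sum(lengths(list(ids))) == 0L) {
      test_ids <- ids
      covered <- TRUE
      break
    }
  }
  assignment <- setNames(rep("train", nrow(cohort)), cohort$subject_id)
  assignment[test_ids] <- "test"
  structure(list(assignment = assignment, folds = NULL, regime = "primary",
                 seed = as.integer(seed), all_sites_covered = covered),
            class = "split_plan")
}

#' Assign k cross-validation folds to the training set
#'
#' Stratified by class: within each class, training subjects are shuffled
#' and dealt round-robin, so per-class fold sizes differ by at most one.
#' Folds are per subject; both scan sessions of a subject share its fold
#' (leakage guard).
#'
#' @param split a `split_plan`.
#' @param cohort the cohort table the split was made from.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return the `split_plan` with `folds` set (named vector subject_id ->
#'   1..k).
#' @export
make_cv_folds <- function(split, cohort, k = 5L, seed = 1L) {
  train_ids <- names(split$assignment)[split$assignment == "train"]
  if (length(train_ids) == 0L) stop("training set is empty")
  tr <- cohort[cohort$subject_id %in% train_ids, ]
  folds <- integer(0)
  with_seed(seed, {
    for (cl in sort(unique(tr$diagnosis))) {
      ids <- tr$subject_id[tr$diagnosis == cl]
      if (k > length(ids))
        stop("k = ", k, " exceeds class count for ", cl, " (", length(ids), ")")
      ids <- sample(ids)
      folds <- c(folds, setNames(rep_len(seq_len(k), length(ids)), ids))
    }
  })
  split$folds <- folds[train_ids]
  names(split$folds) <- train_ids
  split
}

#' Cross-validated tuning and final fit of the linear classifier
#'
#' For every candidate `C`, the mean validation AUROC over the k folds is
#' computed; the `C` with maximal mean AUROC is selected (ties break to the
#' smallest `C`, i.e. the strongest regularisation).  The final model is
#' refit on the full training set at the selected `C` and a Platt sigmoid
#' is calibrated on the out-of-fold margins of that `C`.
#'
#' @param X training feature matrix.
#' @param y training labels (+1/-1, 0/1 or logical).
#' @param folds integer fold id per row.
#' @param C_grid candidate regularisation values (default `10^(-3..3)` in
#'   half-decade steps, 13 points).
#' @return an `svm_linear` with `calibration` set, plus `cv` (data.frame of
#'   C and mean validation AUROC) and `oof` (out-of-fold margins).
#' @export
tune_and_train <- function(X, y, folds,
                           C_grid = 10^seq(-3, 3, by = 0.5)) {
  X <- as.matrix(X)
  y <- .to_pm1(y)
  k_ids <- sort(unique(folds))
  for (k in k_ids) {
    if (length(unique(y[folds != k])) < 2L)
      stop("a training fold lost one class entirely; use stratified folds")
  }
  cv_auc <- numeric(length(C_grid))
  oof_by_C <- vector("list", length(C_grid))
  for (ci in seq_along(C_grid)) {
    oof <- rep(NA_real_, length(y))
    aucs <- numeric(length(k_ids))
    for (fi in seq_along(k_ids)) {
      hold <- folds == k_ids[fi]
      m <- svm_linear_fit(X[!hold, , drop = FALSE], y[!hold], C = C_grid[ci])
      mg <- svm_margin(m, X[hold, , drop = FALSE])
      oof[hold] <- mg
      aucs[fi] <- if (length(unique(y[hold])) < 2L) NA_real_ else
        auroc(mg[y[hold] > 0], mg[y[hold] < 0])
    }
    cv_auc[ci] <- mean(aucs, na.rm = TRUE)
    oof_by_C[[ci]] <- oof
  }
  best <- which(cv_auc == max(cv_auc))[1L]  # C_grid ascending: smallest C wins ties
  model <- svm_linear_fit(X, y, C = C_grid[best])
  oof <- oof_by_C[[best]]
  model$calibration <- platt_calibrate(oof[!is.na(oof)], y[!is.na(oof)])
  model$cv <- data.frame(C = C_grid, val_auroc = cv_auc)
  model$oof <- oof
  model
}

#' Audit a split plan for train/test leakage
#'
#' @param split a `split_plan` (folds optional).
#' @return TRUE invisibly; stops if any subject is in both sets or a fold
#'   spans the test set.
#' @export
no_leakage_check <- function(split) {
  a <- split$assignment
  if (any(duplicated(names(a))))
    stop("leakage: duplicated subject ids in assignment")
  if (!is.null(split$folds)) {
    if (any(a[names(split$folds)] != "train"))
      stop("leakage: CV fold assigned to a test subject")
  }
  invisible(TRUE)
}

#' Site-holdout split
#'
#' Entire prospective sites are held out for testing; retrospective
#' subjects always train.  Among deterministic candidate site draws, the
#' one whose test-set class proportions deviate least from the full
#' prospective cohort is kept (best-effort representativeness).
#'
#' @param cohort cohort table.
#' @param n_holdout_sites number of sites to hold out (default 6).
#' @param seed integer seed.
#' @param n_candidates candidate site draws to score (default 25).
#' @return a `split_plan` with `regime = "site_holdout"` and
#'   `holdout_sites`.
#' @export
site_holdout_split <- function(cohort, n_holdout_sites = 6L, seed = 1L,
                               n_candidates = 25L) {
  pro <- cohort[cohort$cohort == "prospective", ]
  sites <- sort(unique(pro$site))
  if (length(sites) < n_holdout_sites + 1L)
    stop("too few sites: ", length(sites), " available, ",
         n_holdout_sites, " requested for holdout")
  target <- prop.table(table(pro$diagnosis))
  best <- NULL; best_dev <- Inf
  for (i in seq_len(n_candidates)) {
    cand <- with_seed(derive_seed(seed, paste0("sites:", i)),
                      sample(sites, n_holdout_sites))
    te <- pro[pro$site %in% cand, ]
    if (nrow(te) == 0L || length(unique(te$diagnosis)) < length(target)) next
    dev <- sum(abs(prop.table(table(factor(te$diagnosis,
                                           levels = names(target)))) - target))
    if (dev < best_dev) { best_dev <- dev; best <- cand }
  }
  if (is.null(best)) stop("no feasible site holdout with all classes present")
  assignment <- setNames(rep("train", nrow(cohort)), cohort$subject_id)
  test_ids <- pro$subject_id[pro$site %in% best]
  assignment[test_ids] <- "test"
  structure(list(assignment = assignment, folds = NULL,
                 regime = "site_holdout", seed = as.integer(seed),
                 holdout_sites = best, class_deviation = best_dev),
            class = "split_plan")
}

#' Train and evaluate one endpoint under a split plan
#'
#' @param features data.frame with `subject_id`, `diagnosis` and feature
#'   columns (everything not in `id_cols`).
#' @param split a `split_plan`.
#' @param endpoint endpoint name or [endpoint_spec()].
#' @param k CV folds.
#' @param seed fold seed.
#' @param C_grid passed to [tune_and_train()].
#' @param null_auroc null for the endpoint z test.
#' @return list with `model`, `report` (an `endpoint_report` on the test
#'   set), `test_scores` (per-subject probabilities).
#' @export
evaluate_endpoint <- function(features, split, endpoint, k = 5L, seed = 1L,
                              C_grid = 10^seq(-3, 3, by = 0.5),
                              null_auroc = 0.8) {
  if (is.character(endpoint)) endpoint <- endpoint_spec(endpoint)
  id_cols <- intersect(c("subject_id", "session", "site", "cohort",
                         "diagnosis"), names(features))
  fcols <- setdiff(names(features), id_cols)
  lab <- endpoint_labels(features$diagnosis, endpoint)
  use <- !is.na(lab)
  feats <- features[use, ]
  lab <- lab[use]
  assign <- split$assignment[feats$subject_id]
  tr <- assign == "train"
  te <- assign == "test"
  if (!any(te)) stop("no test subjects for endpoint ", endpoint$name)
  folds_subj <- if (!is.null(split$folds)) split$folds else
    make_cv_folds(split, feats, k = k, seed = seed)$folds
  folds <- folds_subj[feats$subject_id[tr]]
  Xtr <- as.matrix(feats[tr, fcols])
  model <- tune_and_train(Xtr, lab[tr], folds, C_grid = C_grid)
  pred <- predict(model, as.matrix(feats[te, fcols]))
  pred$subject_id <- feats$subject_id[te]
  pred$truth <- lab[te]
  report <- endpoint_report(
    pos = pred$probability[pred$truth > 0],
    neg = pred$probability[pred$truth < 0],
    predictions = pred$label == "positive",
    truths = pred$truth > 0,
    endpoint = endpoint$name, regime = split$regime,
    null_auroc = null_auroc)
  list(model = model, report = report, test_scores = pred)
}

#' Repeat the train/test experiment over verification runs
#'
#' Run r uses its own derived stratified split with the same per-class test
#' counts; run 1 reproduces the primary-seed split exactly.
#'
#' @param features feature table (see [evaluate_endpoint()]).
#' @param cohort cohort table.
#' @param test_counts per-class prospective test counts.
#' @param endpoints endpoint names (default all four).
#' @param n_runs number of verification runs (the study used 49).
#' @param seed top-level seed.
#' @param ... passed to [evaluate_endpoint()].
#' @return list of runs; each run is a named list of `endpoint_report`s.
#' @export
run_verification <- function(features, cohort, test_counts,
                             endpoints = endpoint_names(), n_runs = 49L,
                             seed = 1L, ...) {
  stopifnot(n_runs >= 1L)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- if (r == 1L) seed else derive_seed(seed, paste0("verify:", r))
    split <- stratified_split(cohort, test_counts = test_counts,
                              seed = run_seed)
    split$regime <- if (r == 1L) "primary" else "verification"
    split <- make_cv_folds(split, cohort, k = 5L,
                           seed = derive_seed(run_seed, "folds"))
    no_leakage_check(split)
    runs[[r]] <- lapply(setNames(endpoints, endpoints), function(ep)
      evaluate_endpoint(features, split, ep, ...)$report)
  }
  runs
}
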