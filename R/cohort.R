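.classes <- c("PD", "MSA", "PSP")

#' Cohort specification
#'
#' The stated world of the study: a prospective multi-site cohort (two scan
#' sessions per subject, full clinical scales) and a retrospective auxiliary
#' cohort (single session; duration, UMSARS and PSP-RS not collected).
#' Defaults reproduce the published cohort accounting: prospective
#' 99 PD / 53 MSA / 97 PSP over 21 sites, retrospective 211 / 98 / 87, with
#' per-class age, diagnosis-duration and severity-scale means and SDs as
#' printed, and the overall male fractions (0.622 prospective, 0.591
#' retrospective) applied to every class because no per-class sex split is
#' published.
#'
#' Severity scores are generated with a planted coupling to each subject's
#' latent imaging-effect scale (`severity_coupling`, Pearson-scale): strong
#' for MSA, weak for PSP, none for PD, so the downstream
#' severity-vs-probability regressions have a known ground truth.
#'
#' @param n_prospective,n_retrospective named counts for PD/MSA/PSP.
#' @param site_ids prospective site labels (default 21 sites).
#' @param age_prospective,age_retrospective per-class `c(mean, sd)` years,
#'   truncated to the 40-80 eligibility window.
#' @param sex_male_frac fraction male per cohort (applied to every class).
#' @param duration per-class `c(mean, sd)` years since parkinsonism
#'   diagnosis (prospective only), truncated at 0.
#' @param updrs3_prospective,updrs3_retrospective,umsars,psprs per-class
#'   `c(mean, sd)` severity scales, truncated at 0.
#' @param severity_coupling per-class correlation between the latent imaging
#'   effect scale and severity scores.
#' @param effect_scale_sd SD of the subject-level multiplier on planted
#'   regional effects (mean 1).
#' @param seed integer seed; identical spec + seed gives a byte-identical
#'   cohort table.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_prospective = c(PD = 99, MSA = 53, PSP = 97),
    n_retrospective = c(PD = 211, MSA = 98, PSP = 87),
    site_ids = sprintf("site%02d", 1:21),
    age_prospective = list(PD = c(66.6, 7.9), MSA = c(66.1, 9.4), PSP = c(69.9, 6.0)),
    age_retrospective = list(PD = c(63.3, 8.9), MSA = c(66.9, 8.7), PSP = c(70.5, 6.9)),
    sex_male_frac = c(prospective = 0.622, retrospective = 0.591),
    duration = list(PD = c(6.3, 1.4), MSA = c(2.0, 2.3), PSP = c(1.9, 1.8)),
    updrs3_prospective = list(PD = c(22.0, 10.3), MSA = c(40.1, 15.3), PSP = c(39.8, 14.9)),
    updrs3_retrospective = list(PD = c(27.8, 13.1), MSA = c(55.7, 18.7), PSP = c(41.0, 18.1)),
    umsars = list(PD = c(19.1, 7.4), MSA = c(46.9, 16.8), PSP = c(44.7, 14.8)),
    psprs = list(PD = c(10.5, 5.0), MSA = c(28.5, 12.4), PSP = c(40.4, 13.7)),
    severity_coupling = c(PD = 0, MSA = 0.6, PSP = 0.1),
    effect_scale_sd = 0.25,
    seed = 1L) {
  spec <- list(n_prospective = n_prospective, n_retrospective = n_retrospective,
               site_ids = site_ids, age_prospective = age_prospective,
               age_retrospective = age_retrospective,
               sex_male_frac = sex_male_frac, duration = duration,
               updrs3_prospective = updrs3_prospective,
               updrs3_retrospective = updrs3_retrospective,
               umsars = umsars, psprs = psprs,
               severity_coupling = severity_coupling,
               effect_scale_sd = effect_scale_sd, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  for (nm in c("n_prospective", "n_retrospective")) {
    counts <- spec[[nm]]
    if (!all(.classes %in% names(counts)))
      stop(nm, " must name counts for PD, MSA and PSP")
    if (any(counts < 0)) stop(nm, " counts must be >= 0")
  }
  for (nm in c("age_prospective", "age_retrospective", "duration",
               "updrs3_prospective", "updrs3_retrospective", "umsars", "psprs")) {
    if (any(vapply(spec[[nm]], function(p) p[2] < 0, logical(1))))
      stop(nm, " SDs must be >= 0")
  }
  if (any(spec$sex_male_frac < 0 | spec$sex_male_frac > 1))
    stop("sex_male_frac must lie in [0, 1]")
  invisible(spec)
}

# correlated severity draw: target ~ N(mean, sd) with corr rho to z_effect
.severity_draw <- function(n, pars, rho, z_effect, lo = 0) {
  z <- rho * z_effect + sqrt(max(0, 1 - rho^2)) * rnorm(n)
  pmax(lo, pars[1] + pars[2] * z)
}

#' Generate a synthetic cohort table
#'
#' Class counts match the specification exactly; ages and scores are
#' truncated-normal
#' draws with the per-class parameters; prospective subjects are assigned to
#' sites round-robin after a seeded shuffle (so every site is populated as
#' evenly as possible) and carry 2 scan sessions; retrospective subjects
#' carry 1 session and NA duration/UMSARS/PSP-RS.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame, one row per subject, columns `subject_id, site,
#'   cohort, diagnosis, age, sex, duration, updrs3, umsars, psprs,
#'   pathology, sessions, effect_scale`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    rows <- list()
    idx <- 0L
    for (cohort in c("prospective", "retrospective")) {
      counts <- spec[[paste0("n_", cohort)]]
      age_pars <- spec[[paste0("age_", cohort)]]
      upd_pars <- spec[[paste0("updrs3_", cohort)]]
      male_frac <- spec$sex_male_frac[[cohort]]
      for (cls in .classes) {
        n <- as.integer(counts[[cls]])
        if (n == 0L) next
        z_eff <- rnorm(n)
        age <- rtruncnorm(n, age_pars[[cls]][1], age_pars[[cls]][2], 40, 80)
        n_male <- round(n * male_frac)
        sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))
        rho <- spec$severity_coupling[[cls]]
        updrs3 <- .severity_draw(n, upd_pars[[cls]], rho, z_eff)
        if (cohort == "prospective") {
          duration <- rtruncnorm(n, spec$duration[[cls]][1],
                                 spec$duration[[cls]][2], 0, 40)
          umsars <- .severity_draw(n, spec$umsars[[cls]], rho, z_eff)
          psprs <- .severity_draw(n, spec$psprs[[cls]], rho, z_eff)
          sessions <- 2L
        } else {
          duration <- umsars <- psprs <- rep(NA_real_, n)
          sessions <- 1L
        }
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          cohort = cohort, diagnosis = cls, age = age, sex = sex,
          duration = duration, updrs3 = updrs3, umsars = umsars,
          psprs = psprs, pathology = NA_character_, sessions = sessions,
          effect_scale = pmax(0.1, 1 + spec$effect_scale_sd * z_eff),
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) {
      return(data.frame(subject_id = character(), site = character(),
                        cohort = character(), diagnosis = character(),
                        age = numeric(), sex = character(),
                        duration = numeric(), updrs3 = numeric(),
                        umsars = numeric(), psprs = numeric(),
                        pathology = character(), sessions = integer(),
                        effect_scale = numeric(), stringsAsFactors = FALSE))
    }
    tab <- do.call(rbind, rows)
    tab$subject_id <- sprintf("S%04d", seq_len(nrow(tab)))
    # prospective sites: seeded shuffle then round-robin over site_ids
    pro <- tab$cohort == "prospective"
    tab$site <- "retro"
    if (any(pro)) {
      ord <- sample(which(pro))
      tab$site[ord] <- rep_len(spec$site_ids, length(ord))
    }
    rownames(tab) <- NULL
    tab[, c("subject_id", "site", "cohort", "diagnosis", "age", "sex",
            "duration", "updrs3", "umsars", "psprs", "pathology",
            "sessions", "effect_scale")]
  })
}

#' Cohort accounting from per-class split counts
#'
#' Pure arithmetic joining a prospective train/test split with the
#' retrospective training reinforcement: per-class and total training and
#' testing sizes and the testing share of all data.
#'
#' @param prospective_train,prospective_test,retrospective named per-class
#'   counts (PD/MSA/PSP).
#' @return list with `training_per_class`, `training_n`, `testing_per_class`,
#'   `testing_n`, `total_n`, `test_share` (fraction of total data) and
#'   `prospective_n`.
#' @export
cohort_accounting <- function(prospective_train, prospective_test,
                              retrospective) {
  pt <- prospective_train[.classes]
  pe <- prospective_test[.classes]
  rt <- retrospective[.classes]
  train <- pt + rt
  list(training_per_class = train,
       training_n = sum(train),
       testing_per_class = pe,
       testing_n = sum(pe),
       prospective_n = sum(pt + pe),
       total_n = sum(train) + sum(pe),
       test_share = sum(pe) / (sum(train) + sum(pe)))
}
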