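#' Build a pipeline run configuration
#'
#' One serialisable object holding every knob of the end-to-end run:
#' acquisition, cohort, atlas, effects, noise, classifier grid, endpoints
#' and the single top-level seed all stage substreams derive from.
#' All numeric scalars are stored as doubles so a JSON round trip
#' reproduces the object exactly.
#'
#' @param seed top-level integer seed.
#' @param grid_shape atlas/volume grid (default 16^3 demo scale).
#' @param n_regions atlas regions (default 132).
#' @param n_dirs,n_b0,bval acquisition scheme.
#' @param voxel_mm isotropic voxel size.
#' @param sigma Rician noise SD (signal units, s0 = 1).
#' @param effect_strength multiplier on the default planted effects.
#' @param site_sd,retest_sd nuisance scales (see [effect_spec()]).
#' @param n_prospective,n_retrospective per-class cohort counts.
#' @param test_counts per-class prospective test counts.
#' @param endpoints endpoint names to evaluate.
#' @param C_grid classifier regularisation grid.
#' @param null_auroc z-test null.
#' @param d_water free-water diffusivity.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       grid_shape = c(16, 16, 16),
                       n_regions = 132,
                       n_dirs = 30, n_b0 = 5, bval = 1000,
                       voxel_mm = 2,
                       sigma = 0,
                       effect_strength = 1,
                       site_sd = 0.01, retest_sd = 0.01,
                       n_prospective = c(PD = 10, MSA = 6, PSP = 10),
                       n_retrospective = c(PD = 8, MSA = 5, PSP = 5),
                       test_counts = c(PD = 4, MSA = 3, PSP = 4),
                       endpoints = endpoint_names(),
                       C_grid = 10^seq(-3, 3, by = 0.5),
                       null_auroc = 0.8,
                       d_water = 3.0e-3) {
  cfg <- list(seed = as.numeric(seed),
              grid_shape = as.numeric(grid_shape),
              n_regions = as.numeric(n_regions),
              n_dirs = as.numeric(n_dirs), n_b0 = as.numeric(n_b0),
              bval = as.numeric(bval), voxel_mm = as.numeric(voxel_mm),
              sigma = as.numeric(sigma),
              effect_strength = as.numeric(effect_strength),
              site_sd = as.numeric(site_sd),
              retest_sd = as.numeric(retest_sd),
              n_prospective = vapply(n_prospective[c("PD", "MSA", "PSP")],
                                     as.numeric, numeric(1)),
              n_retrospective = vapply(n_retrospective[c("PD", "MSA", "PSP")],
                                       as.numeric, numeric(1)),
              test_counts = vapply(test_counts[c("PD", "MSA", "PSP")],
                                   as.numeric, numeric(1)),
              endpoints = as.character(endpoints),
              C_grid = as.numeric(C_grid),
              null_auroc = as.numeric(null_auroc),
              d_water = as.numeric(d_water))
  bad <- setdiff(cfg$endpoints, endpoint_names())
  if (length(bad)) stop("unknown endpoint name(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Serialise / parse a run configuration (JSON)
#'
#' `read_run_config(write_run_config(cfg, path))` is identical to `cfg`.
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_run_config`: the path, invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  # named count vectors must serialise as JSON objects, not bare arrays
  for (nm in c("n_prospective", "n_retrospective", "test_counts"))
    out[[nm]] <- as.list(out[[nm]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

# md5 of an object via its serialisation (base tools only; no digest dep)
.obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full pipeline on a configuration
#'
#' simulate -> fit -> extract -> train -> evaluate.  Generates the cohort,
#' atlas and ground truth; simulates each subject's session-1 DWI; fits the
#' free-water model; extracts the ROI feature vector; runs the primary
#' stratified split and every configured endpoint; BH-adjusts p-values
#' across endpoints.  Deterministic given the config (all randomness flows
#' from `config$seed` via named substreams), which the manifest's stage
#' hashes witness.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param verbose print per-stage timing.
#' @return list: `cohort`, `features` (data.frame), `split`, `reports`
#'   (BH-adjusted, one per endpoint), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[3]
  manifest <- list(seed = config$seed, stages = list())
  stage <- function(name, val) {
    manifest$stages[[name]] <<- list(
      hash = .obj_hash(val), time = round(proc.time()[3] - t_all, 2))
    if (verbose) message(sprintf("[%s] %.1fs", name,
                                 proc.time()[3] - t_all))
    val
  }

  spec <- cohort_spec(n_prospective = config$n_prospective,
                      n_retrospective = config$n_retrospective,
                      seed = derive_seed(config$seed, "cohort"))
  cohort <- stage("cohort", generate_cohort(spec))

  atlas <- stage("atlas", generate_atlas(config$grid_shape, config$n_regions,
                                         seed = derive_seed(config$seed, "atlas")))
  truth <- make_ground_truth(atlas, seed = derive_seed(config$seed, "truth"))
  effect <- default_effect_spec(strength = config$effect_strength,
                                site_sd = config$site_sd,
                                retest_sd = config$retest_sd)
  grad <- protocol_gradients(config$n_dirs, config$n_b0, config$bval)
  mask <- atlas > 0

  feat_rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    dwi <- simulate_subject_dwi(subj, truth, effect, grad,
                                sigma = config$sigma, seed = config$seed,
                                d_water = config$d_water, sessions = 1L)[["1"]]
    maps <- fit_fw_volume(dwi, mask, grad, d_water = config$d_water)
    fv <- extract_roi_features(maps$fw, maps$fat, atlas, subj$age, subj$sex)
    feat_rows[[i]] <- data.frame(subject_id = subj$subject_id,
                                 diagnosis = subj$diagnosis,
                                 t(fv), check.names = FALSE)
  }
  features <- stage("features", do.call(rbind, feat_rows))

  split <- stratified_split(cohort, test_counts = config$test_counts,
                            seed = derive_seed(config$seed, "split"))
  split <- make_cv_folds(split, cohort, k = 5L,
                         seed = derive_seed(config$seed, "folds"))
  no_leakage_check(split)
  reports <- lapply(setNames(config$endpoints, config$endpoints), function(ep)
    evaluate_endpoint(features, split, ep, C_grid = config$C_grid,
                      null_auroc = config$null_auroc)$report)
  reports <- stage("reports", adjust_reports(reports))
  manifest$total_time <- round(proc.time()[3] - t_all, 2)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE,
              na = "")
    write.csv(features, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      lapply(reports, function(r) unclass(r)),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(cohort = cohort, features = features, split = split,
       reports = reports, manifest = manifest)
}
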