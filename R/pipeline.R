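# Pipeline orchestration: run configuration, per-patient feature
# extraction, and the full phantom-to-report run.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its documented default:
#' PET segmentation at 40% of the volume maximum, minimum component size
#' 10 voxels, COV heterogeneity cut 0.30, nSpCD peripheral cut 0.66,
#' significance level 0.05, Welch t-test, Efron ties. All values are echoed
#' into the run manifest of [run_pipeline()].
#'
#' @param pet_fraction_of_max PET threshold as fraction of SUVmax.
#' @param mri_absolute_threshold Absolute MRI threshold, or `NA` to choose
#'   per volume the candidate threshold maximising the largest connected
#'   enhancing component.
#' @param min_voxels Minimum lesion size in voxels.
#' @param low_rule Low (faint background) threshold rule for the
#'   multifocal/multicentric test, or `NULL` for the border-shell default.
#' @param cov_cut,nspcd_cut Classification cuts.
#' @param alpha Significance level for flags.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param seed Integer seed for all randomness in the run.
#' @return A `run_config` list.
#' @export
run_config <- function(pet_fraction_of_max = 0.40,
                       mri_absolute_threshold = NA,
                       min_voxels = 10L,
                       low_rule = NULL,
                       cov_cut = 0.30,
                       nspcd_cut = 0.66,
                       alpha = 0.05,
                       var_equal = FALSE,
                       seed = 1L) {
  stopifnot(pet_fraction_of_max > 0, pet_fraction_of_max <= 1,
            min_voxels >= 1, cov_cut >= 0, nspcd_cut >= 0,
            alpha > 0, alpha < 1)
  structure(list(pet_fraction_of_max = pet_fraction_of_max,
                 mri_absolute_threshold = mri_absolute_threshold,
                 min_voxels = as.integer(min_voxels),
                 low_rule = low_rule,
                 cov_cut = cov_cut, nspcd_cut = nspcd_cut,
                 alpha = alpha, var_equal = var_equal,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file take the documented defaults of
#' [run_config()].
#'
#' @param path Path to a YAML key-value file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

# Per-volume MRI threshold: scan candidate gray levels and keep the one
# maximising the size of the largest connected enhancing component, a
# deterministic stand-in for interactive threshold choice.
choose_mri_threshold <- function(grid, n_candidates = 15L, min_voxels = 10L) {
  vals <- grid$values
  lo <- stats::quantile(vals, 0.5, names = FALSE)
  hi <- max(vals) * 0.95
  cands <- seq(lo, hi, length.out = n_candidates)
  best <- cands[1]
  best_size <- -Inf
  for (ct in cands) {
    labels <- label_components(vals >= ct, connectivity = 26L)
    if (!max(labels)) next
    size <- max(tabulate(labels[labels > 0L]))
    if (size > best_size && size >= min_voxels) {
      best_size <- size
      best <- ct
    }
  }
  best
}

#' Extract the full feature row for one patient volume
#'
#' Segments the volume, classifies multilesionality, selects the largest
#' lesion and computes the combined SUV and geometric feature row.
#'
#' @param grid A [voxel_grid] (PET or MRI).
#' @param config A [run_config()].
#' @return A one-row tibble of features plus `classification` and
#'   `multilesional`.
#' @export
extract_patient_features <- function(grid, config = run_config()) {
  stopifnot(inherits(grid, "voxel_grid"))
  rule <- if (grid$modality == "PET") {
    list(fraction_of_max = config$pet_fraction_of_max)
  } else if (is.finite(config$mri_absolute_threshold)) {
    list(absolute = config$mri_absolute_threshold)
  } else {
    list(absolute = choose_mri_threshold(grid, min_voxels = config$min_voxels))
  }
  ls <- segment_threshold(grid, rule, min_voxels = config$min_voxels)
  cls <- if (grid$modality == "PET") {
    classify_multilesionality(grid, high_rule = rule,
                              low_rule = config$low_rule,
                              min_voxels = config$min_voxels)
  } else {
    tibble::tibble(classification = if (length(ls$N) == 1L) "unifocal" else "multicentric",
                   multilesional = length(ls$N) > 1L,
                   n_foci = length(ls$N),
                   high_threshold = ls$threshold,
                   low_threshold = NA_real_)
  }
  feats <- extract_lesion_features(grid, ls,
                                   cov_cut = config$cov_cut,
                                   nspcd_cut = config$nspcd_cut)
  dplyr::bind_cols(feats, cls)
}

#' Write a synthetic study to disk
#'
#' Generates `n` single- or two-lesion PET phantoms (NIfTI), a ground-truth
#' JSON sidecar, and a simulated cohort CSV, giving every pipeline stage a
#' self-contained input set. Deterministic for a fixed seed.
#'
#' @param dir Output directory (created if missing).
#' @param n Number of patients/phantoms.
#' @param seed Integer seed.
#' @return Invisibly, a list with the volume manifest tibble and the paths
#'   written.
#' @export
write_synthetic_study <- function(dir, n = 10, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(cohort_sim_spec(n = n, seed = seed))
  manifest <- with_seed(seed + 1L, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      two <- cohort$multilesional[i]
      r1 <- stats::runif(1, 8, 12)
      lesions <- list(lesion_spec(center = c(24, 24, 32), base_radius = r1,
                                  bumpiness = stats::runif(1, 0, 0.25),
                                  hotspot_radial_fraction = stats::runif(1, 0, 0.9),
                                  hotspot_suv = 4.5, rim_suv = 3))
      if (two) {
        lesions <- c(lesions, list(
          lesion_spec(center = c(46, 44, 32),
                      base_radius = stats::runif(1, 5, 7),
                      hotspot_suv = 3, rim_suv = 3)))
      }
      ph <- make_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                      spacing = c(1, 1, 1),
                                      lesions = lesions,
                                      background_suv = 0.3,
                                      noise_sd = 0.02,
                                      seed = seed + 100L + i))
      path <- file.path(dir, sprintf("%s_pet.nii.gz", cohort$patient_id[i]))
      write_volume(ph$grid, path)
      rows[[i]] <- tibble::tibble(patient_id = cohort$patient_id[i],
                                  pet_path = path,
                                  n_lesions_true = length(lesions))
    }
    dplyr::bind_rows(rows)
  })
  cohort_path <- file.path(dir, "cohort.csv")
  readr::write_csv(dplyr::select(cohort, -"lp_os"), cohort_path)
  manifest_path <- file.path(dir, "volumes.csv")
  readr::write_csv(manifest, manifest_path)
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(manifest, truth_path)
  invisible(list(manifest = manifest, cohort_path = cohort_path,
                 manifest_path = manifest_path, dir = dir))
}

#' Run the full pipeline: segment, extract, analyze
#'
#' For every patient in the volume manifest: load the PET (and optional
#' MRI) volume, segment, classify multilesionality, select the largest
#' lesion, extract the feature row; join with the clinical cohort table;
#' then run the survival stage (median dichotomization with group tests,
#' ROC cutoffs at the median-OS class, Kaplan-Meier/log-rank by
#' multilesionality, univariate and multivariate Cox). Per-patient failures
#' are logged and skipped with a summary count, not fatal. Reports and a
#' run manifest (all thresholds, seed, package version) are written to
#' `out_dir`.
#'
#' @param volumes_csv CSV with columns `patient_id, pet_path` and optional
#'   `mri_path` (missing MRI rows give `NA` MRI features).
#' @param cohort_csv Cohort table CSV (see [read_cohort()]).
#' @param out_dir Output directory for reports.
#' @param config A [run_config()].
#' @return A list: `features` (per-patient tibble), `dichotomized`, `roc`,
#'   `km`, `cox`, `failures`, and the manifest, invisibly written to disk.
#' @export
run_pipeline <- function(volumes_csv, cohort_csv, out_dir,
                         config = run_config()) {
  manifest <- readr::read_csv(volumes_csv, show_col_types = FALSE,
                              progress = FALSE)
  stopifnot(all(c("patient_id", "pet_path") %in% names(manifest)))
  cohort <- read_cohort(cohort_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  failures <- character()
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    row <- tryCatch({
      grid <- read_volume(manifest$pet_path[i], modality = "PET")
      pet_row <- extract_patient_features(grid, config)
      names(pet_row) <- paste0("pet_", names(pet_row))
      out <- dplyr::bind_cols(tibble::tibble(patient_id = pid), pet_row)
      if ("mri_path" %in% names(manifest) && !is.na(manifest$mri_path[i]) &&
          nzchar(manifest$mri_path[i])) {
        mgrid <- read_volume(manifest$mri_path[i], modality = "MRI")
        mri_row <- extract_patient_features(mgrid, config)
        names(mri_row) <- paste0("mri_", names(mri_row))
        out <- dplyr::bind_cols(out, mri_row)
      }
      out
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", pid, conditionMessage(e)))
      NULL
    })
    rows[[i]] <- row
  }
  features <- dplyr::bind_rows(rows)
  if (length(failures)) {
    message(length(failures), " patient(s) skipped:\n  ",
            paste(failures, collapse = "\n  "))
  }
  if (!nrow(features)) stop("no patient could be processed", call. = FALSE)

  tab <- dplyr::inner_join(cohort, features, by = "patient_id")
  readr::write_csv(tab, file.path(out_dir, "features.csv"))

  # downstream statistics degrade gracefully on very small cohorts:
  # a stage that cannot run is reported as NULL, not fatal
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      message("stage '", name, "' skipped: ", conditionMessage(e))
      NULL
    })
  }

  suv_feats <- intersect(c("pet_suv_max", "pet_suv_mean", "pet_suv_peak",
                           "pet_mtv_ml", "pet_tla", "pet_cov",
                           "pet_sphericity", "pet_nspcd"), names(tab))
  dich <- try_stage("dichotomize", dichotomize_and_test(
    tab, "os", suv_feats, var_equal = config$var_equal))
  if (!is.null(dich)) {
    readr::write_csv(dich, file.path(out_dir, "dichotomized_os.csv"))
  }

  tab$os_short <- tab$os_months <= stats::median(tab$os_months)
  roc <- try_stage("roc", dplyr::bind_rows(lapply(suv_feats, function(f) {
    tibble::as_tibble(roc_cutoff(tab, "os_short", f, endpoint = "OS_median"))
  })))
  if (!is.null(roc)) readr::write_csv(roc, file.path(out_dir, "roc_os.csv"))

  km <- try_stage("km", km_logrank(tab, "os", "pet_multilesional"))
  if (!is.null(km)) readr::write_csv(km$curves, file.path(out_dir, "km_os.csv"))

  cox_vars <- intersect(c("age", "stupp_complete", "pet_multilesional",
                          "pet_sphericity"), names(tab))
  cox <- try_stage("cox", suppressWarnings(cox_models(
    tab, "os", univariate = cox_vars, multivariate = cox_vars,
    per_tenth = "pet_sphericity")))
  if (!is.null(cox)) {
    readr::write_csv(tibble::as_tibble(cox), file.path(out_dir, "cox_os.csv"))
  }

  run_manifest <- list(
    config = unclass(config),
    n_patients = nrow(tab),
    n_failures = length(failures),
    failures = failures,
    package_version = as.character(utils::packageVersion("gliopet"))
  )
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, null = "null")

  invisible(list(features = tab, dichotomized = dich, roc = roc, km = km,
                 cox = cox, failures = failures, manifest = run_manifest))
}
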