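#' Default end-to-end pipeline configuration
#'
#' A nested, fully serializable key-value structure covering every stage.
#' Defaults follow the emulated study's stated analysis: 10 + 7 subjects, 8
#' runs, 16-s blocks, 4-mm FWHM smoothing, 128-s high-pass cutoff, 10-mm
#' searchlight radius, SVM cost 1, alpha 0.05, and the five category pairs
#' analyzed (face-object, face-body, face-body_part, object-body,
#' object-body_part; body-body_part is available but off by default).
#'
#' @param seed Master seed.
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_controls = 10L, n_cps = 7L,
                  grid_dims = c(24L, 28L, 16L),
                  voxel_size_mm = c(1.4, 1.4, 2.0),
                  tr_s = 3.0, n_volumes_per_run = 112L, n_runs = 8L,
                  block_duration_s = 16, blocks_per_category = 1L,
                  baseline = 100,
                  mean_amplitude = 1, pattern_sd = 1,
                  cp_separability_factor = 0.3,
                  cp_amplitude_factor = 1, subject_specific = TRUE,
                  white_sd = 1.2, drift_amplitude = 1, ar1_coefficient = 0.3),
    glm = list(fwhm_mm = 4, smooth_passes = 1L, cutoff_s = 128),
    searchlight = list(radius_mm = 10, svm_cost = 1, min_sphere_voxels = 2L),
    inference = list(n_permutations = 999L, cluster_forming_p = 0.001,
                     alpha = 0.05, connectivity = 18L),
    pairs = list(c("face", "object"), c("face", "body"),
                 c("face", "body_part"), c("object", "body"),
                 c("object", "body_part"))
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML or JSON by extension)
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_pipeline_config()
  for (k in names(cfg)) {
    if (k %in% c("cohort", "glm", "searchlight", "inference")) {
      for (kk in names(cfg[[k]])) base[[k]][[kk]] <- cfg[[k]][[kk]]
    } else base[[k]] <- cfg[[k]]
  }
  if (is.matrix(base$pairs)) {
    base$pairs <- lapply(seq_len(nrow(base$pairs)), function(i) base$pairs[i, ])
  }
  base
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(unclass(config), path)
  else jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}

#' Build the cohort specification a configuration describes
#' @param config A `pipeline_config`.
#' @return A [cohort_spec()].
#' @export
config_to_spec <- function(config) {
  co <- config$cohort
  geom <- acq_geometry(unlist(co$grid_dims), unlist(co$voxel_size_mm),
                       co$tr_s, co$n_volumes_per_run, co$n_runs)
  design <- make_design(geom, block_duration_s = co$block_duration_s,
                        blocks_per_category = co$blocks_per_category)
  truth <- make_ground_truth(geom, mean_amplitude = co$mean_amplitude,
                             pattern_sd = co$pattern_sd,
                             cp_separability_factor = co$cp_separability_factor,
                             cp_amplitude_factor = co$cp_amplitude_factor,
                             subject_specific = co$subject_specific,
                             seed = config$seed)
  cohort_spec(co$n_controls, co$n_cps, design, truth,
              noise_params(co$white_sd, co$drift_amplitude,
                           co$ar1_coefficient),
              seed = config$seed, baseline = co$baseline)
}

#' Simulate a cohort described by a configuration (CLI verb `simulate`)
#' @param config A `pipeline_config`.
#' @param out_dir Dataset output directory.
#' @return Invisibly, the dataset manifest.
#' @export
cmd_simulate <- function(config, out_dir) {
  spec <- config_to_spec(config)
  message(sprintf("simulating %d controls + %d CPs, seed %d",
                  spec$n_controls, spec$n_cps, config$seed))
  simulate_cohort(spec, out_dir)
}

#' Run the full analysis (CLI verb `run-all`)
#'
#' GLM, searchlight maps for every configured pair, within-group one-sample
#' inference against chance, between-group inference, the univariate arm on
#' the first pair, and the sensitivity report. Per-subject accuracy and
#' contrast maps are written as NIfTI with JSON sidecars and reused when
#' already present, so a rerun after deleting group outputs only recomputes
#' the group level.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Results directory.
#' @param dataset_dir Optional dataset written by [cmd_simulate()]; if
#'   `NULL`, the cohort is simulated in memory from `config`.
#' @param verbose Progress messages.
#' @return Invisibly, a list with the group results per pair and the
#'   sensitivity report.
#' @export
cmd_run_all <- function(config, out_dir, dataset_dir = NULL, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config_to_spec(config)
  geom <- spec$design$geometry
  cohort <- if (is.null(dataset_dir)) simulate_cohort_mem(spec)
            else load_cohort(dataset_dir)
  groups <- cohort$groups
  mask <- if (is.null(dataset_dir)) spec$truth$brain_mask else cohort$mask
  slc <- searchlight_config(config$searchlight$radius_mm,
                            config$searchlight$svm_cost,
                            config$searchlight$min_sphere_voxels)
  inf <- config$inference
  sub_dir <- file.path(out_dir, "subjects")
  dir.create(sub_dir, showWarnings = FALSE)
  pairs <- config$pairs
  pair_key <- vapply(pairs, paste, "", collapse = "-")

  acc <- lapply(pairs, function(p) vector("list", length(groups)))
  names(acc) <- pair_key
  con1 <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    if (verbose) message(sprintf("subject %d/%d: GLM + searchlight", i,
                                 length(groups)))
    sid <- sprintf("sub-%02d", i)
    acc_files <- file.path(sub_dir, sprintf("%s_pair-%s_accuracy.nii.gz",
                                            sid, pair_key))
    con_file <- file.path(sub_dir, sprintf("%s_contrast-%s.nii.gz",
                                           sid, pair_key[1]))
    if (all(file.exists(c(acc_files, con_file)))) {
      for (k in seq_along(pairs)) {
        acc[[k]][[i]] <- read_map(acc_files[k], geom$grid_dims)
      }
      con1[[i]] <- read_map(con_file, geom$grid_dims)
      next
    }
    betas <- fit_subject_glm(cohort$subjects[[i]], spec$design, mask,
                             fwhm_mm = config$glm$fwhm_mm,
                             smooth_passes = config$glm$smooth_passes,
                             cutoff_s = config$glm$cutoff_s)
    for (k in seq_along(pairs)) {
      am <- searchlight_map(betas, pairs[[k]], mask, slc,
                            voxel_size_mm = geom$voxel_size_mm)
      acc[[k]][[i]] <- am$data
      write_map(am$data, acc_files[k], geom,
                sidecar = list(subject = sid, pair = pairs[[k]],
                               radius_mm = slc$radius_mm,
                               classifier = "linear_svm",
                               svm_cost = slc$svm_cost,
                               n_folds = am$n_folds))
    }
    w <- setNames(rep(0, length(spec$design$condition_names)),
                  spec$design$condition_names)
    w[pairs[[1]]] <- c(1, -1)
    con1[[i]] <- compute_contrast(betas, w)
    write_map(con1[[i]], con_file, geom,
              sidecar = list(subject = sid, contrast = pairs[[1]]))
  }

  results <- list()
  for (k in seq_along(pairs)) {
    key <- pair_key[k]
    if (verbose) message("group inference: ", key)
    gdir <- file.path(out_dir, "group", key)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    within <- lapply(c(control = "control", cp = "cp"), function(g) {
      res <- permutation_correct(maps = acc[[key]][groups == g],
                                 scheme = "sign_flip", null_value = 0.5,
                                 n_permutations = inf$n_permutations,
                                 seed = config$seed,
                                 cluster_forming_p = inf$cluster_forming_p,
                                 alpha = inf$alpha,
                                 connectivity = inf$connectivity,
                                 geometry = geom)
      write_cluster_table(res$cluster_table,
                          file.path(gdir, paste0("within_", g, ".tsv")))
      res
    })
    between <- permutation_correct(maps_a = acc[[key]][groups == "control"],
                                   maps_b = acc[[key]][groups == "cp"],
                                   scheme = "label_shuffle",
                                   equal_variance = TRUE,
                                   n_permutations = inf$n_permutations,
                                   seed = config$seed,
                                   cluster_forming_p = inf$cluster_forming_p,
                                   alpha = inf$alpha,
                                   connectivity = inf$connectivity,
                                   geometry = geom)
    write_cluster_table(between$cluster_table,
                        file.path(gdir, "between.tsv"))
    write_map(between$observed$data,
              file.path(gdir, "between_tmap.nii.gz"), geom,
              sidecar = list(df = between$observed$df, tail = "one_sided_greater",
                             test = "two_sample_diff", pair = pairs[[k]]))
    results[[key]] <- list(within = within, between = between)
  }

  if (verbose) message("univariate arm: ", pair_key[1])
  udir <- file.path(out_dir, "univariate")
  dir.create(udir, showWarnings = FALSE)
  univ <- group_univariate_contrast(con1[groups == "control"],
                                    con1[groups == "cp"],
                                    n_permutations = inf$n_permutations,
                                    seed = config$seed,
                                    cluster_forming_p = inf$cluster_forming_p,
                                    alpha = inf$alpha,
                                    connectivity = inf$connectivity,
                                    geometry = geom)
  write_cluster_table(univ$cluster_table, file.path(udir, "between.tsv"))

  arm <- function(res) {
    p <- if (nrow(res$cluster_table)) min(res$cluster_table$p_corrected)
         else NA_real_
    list(min_cluster_p = p, detected = isTRUE(p <= inf$alpha),
         cluster_table = res$cluster_table)
  }
  report <- structure(
    list(mvpa = arm(results[[1]]$between), univariate = arm(univ),
         truth_rois = spec$truth$roi_masks,
         config = list(pair = pairs[[1]],
                       radius_mm = slc$radius_mm,
                       n_permutations = inf$n_permutations,
                       alpha = inf$alpha, cohort_seed = config$seed,
                       cp_separability_factor =
                         spec$truth$cp_separability_factor)),
    class = "sensitivity_report")
  write_sensitivity_report(report, file.path(out_dir, "sensitivity.json"))
  jsonlite::write_json(list(config = unclass(config),
                            package_version =
                              as.character(utils::packageVersion("searchlightr"))),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(pairs = results, univariate = univ, report = report))
}

read_map <- function(path, dims) {
  arr <- RNifti::readNifti(path)
  array(as.vector(arr), dims)
}
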