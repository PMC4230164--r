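#' Write a simulated cohort to disk
#'
#' Lays out a BIDS-flavoured dataset: one gzipped NIfTI-1 4-D file and one
#' events TSV (`onset`, `duration`, `trial_type`) per subject and run under
#' `sub-XX/func/`, a shared brain-mask NIfTI, the ground-truth region masks
#' and parameters under `truth/`, and a JSON manifest recording group
#' membership, per-subject seeds and the full specification. On any failure
#' partial outputs are removed.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created; must not already contain a
#'   manifest).
#' @return Invisibly, the manifest (also written as `dataset.json`).
#' @export
simulate_cohort <- function(spec, out_dir) {
  if (file.exists(file.path(out_dir, "dataset.json"))) {
    stop("out_dir already contains a dataset")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)

  geom <- spec$design$geometry
  aff <- geometry_affine(geom)
  groups <- cohort_groups(spec)
  write_vol(spec$truth$brain_mask * 1, file.path(out_dir, "mask.nii.gz"), aff)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  for (nm in names(spec$truth$roi_masks)) {
    write_vol(spec$truth$roi_masks[[nm]] * 1,
              file.path(out_dir, "truth", paste0("roi-", nm, ".nii.gz")), aff)
  }
  jsonlite::write_json(
    list(mean_amplitude = spec$truth$mean_amplitude,
         cp_separability_factor = spec$truth$cp_separability_factor,
         categories = spec$truth$categories, seed = spec$truth$seed),
    file.path(out_dir, "truth", "truth.json"), auto_unbox = TRUE, digits = NA)

  subjects <- list()
  for (i in seq_along(groups)) {
    sid <- sprintf("sub-%02d", i)
    func <- file.path(out_dir, sid, "func")
    dir.create(func, recursive = TRUE, showWarnings = FALSE)
    sseed <- subject_seed_for(spec, i)
    runs <- simulate_subject(spec$design, spec$truth, groups[i], spec$noise,
                             subject_seed = sseed, baseline = spec$baseline)
    files <- character(geom$n_runs)
    for (r in seq_len(geom$n_runs)) {
      f <- file.path(func, sprintf("%s_run-%02d_bold.nii.gz", sid, r))
      write_vol(runs[[r]], f, aff)
      ev <- spec$design$events[spec$design$events$run == r, ]
      write.table(
        data.frame(onset = ev$onset, duration = ev$duration,
                   trial_type = ev$condition),
        file.path(func, sprintf("%s_run-%02d_events.tsv", sid, r)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      files[r] <- f
    }
    subjects[[i]] <- list(id = sid, group = groups[i], seed = sseed,
                          runs = basename(files))
  }
  manifest <- list(
    n_controls = spec$n_controls, n_cps = spec$n_cps, seed = spec$seed,
    grid_dims = geom$grid_dims, voxel_size_mm = geom$voxel_size_mm,
    tr_s = geom$tr_s, n_volumes_per_run = geom$n_volumes_per_run,
    n_runs = geom$n_runs, baseline = spec$baseline,
    noise = unclass(spec$noise), subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(
    data.frame(participant_id = vapply(subjects, `[[`, "", "id"),
               group = groups),
    file.path(out_dir, "participants.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  ok <- TRUE
  invisible(manifest)
}

write_vol <- function(arr, path, affine) {
  img <- RNifti::asNifti(arr)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a cohort dataset written by [simulate_cohort()]
#'
#' @param dir Dataset directory.
#' @return List with `manifest`, `mask` (logical array), `groups`, and
#'   `subjects` (per-subject list of 4-D run arrays).
#' @export
load_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "dataset.json"),
                            simplifyVector = TRUE)
  mask <- array(as.vector(RNifti::readNifti(file.path(dir, "mask.nii.gz"))) > 0,
                unlist(mf$grid_dims))
  subjects <- lapply(seq_len(nrow(mf$subjects)), function(i) {
    sid <- mf$subjects$id[i]
    lapply(mf$subjects$runs[[i]], function(f) {
      arr <- RNifti::readNifti(file.path(dir, sid, "func", f))
      array(as.vector(arr), dim(arr))
    })
  })
  list(manifest = mf, mask = mask, groups = mf$subjects$group,
       subjects = subjects)
}

#' Write a 3-D map as NIfTI with a JSON sidecar
#'
#' @param map 3-D array.
#' @param path Output `.nii.gz` path; the sidecar replaces the extension with
#'   `.json`.
#' @param geometry Geometry supplying the affine.
#' @param sidecar Named list of metadata (may be empty).
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, geometry, sidecar = list()) {
  write_vol(map, path, geometry_affine(geometry))
  if (length(sidecar)) {
    jsonlite::write_json(sidecar, sub("\\.nii(\\.gz)?$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
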