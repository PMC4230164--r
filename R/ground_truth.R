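#' Spherical voxel mask
#'
#' @param geometry An [acq_geometry()].
#' @param center_vox Voxel triple (1-based) at the sphere center.
#' @param radius_mm Radius in mm (anisotropic voxel sizes respected).
#' @return 3-D logical array.
#' @export
sphere_mask <- function(geometry, center_vox, radius_mm) {
  d <- geometry$grid_dims; vs <- geometry$voxel_size_mm
  if (any(center_vox < 1) || any(center_vox > d)) stop("center outside grid")
  dx <- (seq_len(d[1]) - center_vox[1]) * vs[1]
  dy <- (seq_len(d[2]) - center_vox[2]) * vs[2]
  dz <- (seq_len(d[3]) - center_vox[3]) * vs[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= radius_mm^2
}

#' Default ellipsoidal brain mask
#'
#' An axis-aligned ellipsoid with semi-axes at 45% of each grid extent — a
#' stand-in for a brain outline that keeps searchlight spheres away from the
#' array corners.
#' @param geometry An [acq_geometry()].
#' @return 3-D logical array.
#' @export
default_brain_mask <- function(geometry) {
  d <- geometry$grid_dims
  c0 <- (d + 1) / 2
  ax <- 0.45 * d
  fx <- ((seq_len(d[1]) - c0[1]) / ax[1])^2
  fy <- ((seq_len(d[2]) - c0[2]) / ax[2])^2
  fz <- ((seq_len(d[3]) - c0[3]) / ax[3])^2
  outer(outer(fx, fy, `+`), fz, `+`) <= 1
}

#' Default informative-region layout
#'
#' Three spherical regions standing in for the face-sensitive areas whose
#' pattern discriminability the pipeline probes (an occipital, a fusiform-like
#' and an anterior-temporal-like site), placed inside the default brain mask.
#' @param geometry An [acq_geometry()].
#' @return Named list of `list(center_vox, radius_mm)` specs.
#' @export
default_roi_specs <- function(geometry = acq_geometry()) {
  d <- geometry$grid_dims
  at <- function(f) pmax(1L, pmin(d, as.integer(round(f * d))))
  list(
    ofa_like = list(center_vox = at(c(0.38, 0.30, 0.50)), radius_mm = 5),
    ffa_like = list(center_vox = at(c(0.62, 0.48, 0.44)), radius_mm = 5),
    atl_like = list(center_vox = at(c(0.50, 0.66, 0.56)), radius_mm = 5)
  )
}

#' Generative ground truth for a synthetic cohort
#'
#' Builds the informative regions and category response patterns the simulator
#' implants. Within each region every stimulus category evokes
#' `mean_amplitude + pattern`, where the pattern is a reproducible Gaussian
#' weight map that is mean-centered across the region's voxels. Centering
#' enforces mean-amplitude matching by construction: the regional mean
#' response is identical for all categories (and both groups), so a pure
#' amplitude analysis carries no category or group signal, while the
#' multivoxel patterns differ.
#'
#' The group effect is a pattern-separability deficit: in the CP group the
#' face and object patterns are shrunk toward their shared mean by
#' `cp_separability_factor` (1 = identical to controls, 0 = face and object
#' patterns collapse onto each other). Other category pairs are unaffected.
#'
#' By default (`subject_specific = TRUE`) every simulated subject draws their
#' own pattern maps by this construction, seeded from the subject seed: the
#' informative regions and the separability structure are shared, the voxel
#' layout of the patterns is not. This emulates the between-subject
#' variability of pattern topography in real cohorts and makes the voxelwise
#' univariate group contrast zero in expectation, while within-subject
#' decoding is unaffected. `subject_specific = FALSE` gives every subject the
#' template patterns stored in `pattern_weights`.
#'
#' @param geometry An [acq_geometry()].
#' @param roi_specs Named list of `list(center_vox, radius_mm)`.
#' @param categories Stimulus category names.
#' @param mean_amplitude Common block response amplitude (signal units).
#' @param pattern_sd Voxelwise standard deviation of the category patterns.
#' @param cp_separability_factor Face-object pattern separability retained in
#'   the CP group, in `[0, 1]`.
#' @param cp_amplitude_factor Scales the CP group's mean response amplitude
#'   to faces specifically (1 = amplitude-matched groups, the default).
#'   Values != 1 implant a face-selective amplitude group effect — the kind
#'   of effect a univariate face-minus-object contrast does detect — and
#'   deliberately break the amplitude-matching invariant as a positive
#'   control.
#' @param subject_specific Draw a fresh pattern layout per subject (default)
#'   or share the template patterns across the cohort.
#' @param brain_mask Optional 3-D logical mask; defaults to
#'   [default_brain_mask()].
#' @param seed Integer; fully determines the template patterns.
#' @return A list of class `ground_truth`.
#' @export
make_ground_truth <- function(geometry = acq_geometry(),
                              roi_specs = default_roi_specs(geometry),
                              categories = c("face", "object", "body", "body_part"),
                              mean_amplitude = 1,
                              pattern_sd = 1,
                              cp_separability_factor = 0.3,
                              cp_amplitude_factor = 1,
                              subject_specific = TRUE,
                              brain_mask = NULL,
                              seed = 1L) {
  stopifnot(cp_separability_factor >= 0, cp_separability_factor <= 1,
            mean_amplitude >= 0, pattern_sd >= 0, cp_amplitude_factor >= 0)
  if (is.null(brain_mask)) brain_mask <- default_brain_mask(geometry)
  roi_masks <- lapply(roi_specs, function(s) {
    m <- sphere_mask(geometry, s$center_vox, s$radius_mm) & brain_mask
    if (!any(m)) stop("an informative region is empty")
    m
  })
  pattern_weights <- draw_patterns(geometry$grid_dims, roi_masks, categories,
                                   pattern_sd, seed)
  structure(list(geometry = geometry, brain_mask = brain_mask,
                 roi_masks = roi_masks, pattern_weights = pattern_weights,
                 mean_amplitude = mean_amplitude, pattern_sd = pattern_sd,
                 cp_separability_factor = cp_separability_factor,
                 cp_amplitude_factor = cp_amplitude_factor,
                 subject_specific = isTRUE(subject_specific),
                 categories = categories, seed = as.integer(seed)),
            class = "ground_truth")
}

# Mean-centered Gaussian pattern maps, one per category, zero outside regions
draw_patterns <- function(dims, roi_masks, categories, pattern_sd, seed) {
  set.seed(as.integer(seed))
  weights <- list()
  for (cat in categories) {
    w <- array(0, dims)
    for (m in roi_masks) {
      p <- rnorm(sum(m)) * pattern_sd
      w[m] <- p - mean(p)        # mean-amplitude matching within the region
    }
    weights[[cat]] <- w
  }
  weights
}

#' Generative per-category response maps for one group
#'
#' Controls receive `mean_amplitude + pattern` inside each region; CP subjects
#' receive patterns whose face and object components are shrunk toward their
#' common mean by the separability factor, leaving regional means untouched.
#'
#' @param truth A [make_ground_truth()] object.
#' @param group `"control"` or `"cp"`.
#' @param patterns Pattern weight maps to use (defaults to the stored
#'   template).
#' @return Named list of 3-D response maps, one per category.
#' @export
group_response_maps <- function(truth, group = c("control", "cp"),
                                patterns = truth$pattern_weights) {
  group <- match.arg(group)
  pw <- patterns
  amp <- setNames(rep(truth$mean_amplitude, length(pw)), names(pw))
  if (group == "cp") {
    f <- truth$cp_separability_factor
    if (f < 1) {
      mid <- (pw$face + pw$object) / 2
      pw$face <- mid + f * (pw$face - mid)
      pw$object <- mid + f * (pw$object - mid)
    }
    amp["face"] <- amp["face"] * truth$cp_amplitude_factor
  }
  in_roi <- Reduce(`|`, truth$roi_masks)
  out <- lapply(names(pw), function(cat) {
    resp <- pw[[cat]]
    resp[in_roi] <- resp[in_roi] + amp[[cat]]
    resp
  })
  names(out) <- names(pw)
  out
}

#' Generative response maps for one simulated subject
#'
#' With subject-specific topography (the default) this redraws the pattern
#' layout from `subject_seed`, then applies the group structure (CP
#' separability shrinkage, amplitude factor); with a shared template it is
#' [group_response_maps()]. This function is the recovery oracle for
#' estimation tests: the noiseless GLM reproduces exactly these maps.
#'
#' @inheritParams group_response_maps
#' @param subject_seed The subject's seed.
#' @return Named list of 3-D response maps.
#' @export
subject_response_maps <- function(truth, group, subject_seed) {
  patterns <- if (truth$subject_specific) {
    draw_patterns(truth$geometry$grid_dims, truth$roi_masks,
                  truth$categories, truth$pattern_sd,
                  pattern_seed(subject_seed))
  } else truth$pattern_weights
  group_response_maps(truth, group, patterns)
}

# separate stream from the subject's noise seed
pattern_seed <- function(subject_seed) as.integer(subject_seed) + 777000L

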