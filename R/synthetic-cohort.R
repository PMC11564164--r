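#' Specification of a synthetic volumetric cohort
#'
#' Describes a multi-group cohort of modulated, smoothed gray-matter-volume
#' phantoms with planted cluster effects.  Subject volumes are built as a
#' smooth ellipsoidal baseline plus spatially smoothed Gaussian noise
#' (rescaled to unit variance, then multiplied by \code{noise_sd}), plus the
#' planted group effects and a small additive gender offset.  Effect sizes
#' are expressed in Cohen's d units of the voxel noise SD, so a cluster with
#' effect d shifts the group mean by \code{d * noise_sd} inside the cluster.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param n_per_group subjects per group.
#' @param groups ordered group labels; the first is the reference group.
#' @param effect_clusters list of clusters, each a list with \code{center}
#'   (1-based voxel index triple), \code{radius_mm}, and \code{d} (named
#'   numeric vector of per-group effect sizes; missing groups get 0).
#' @param smoothing_fwhm_mm FWHM of the Gaussian smoothing applied to the
#'   noise field, mm.
#' @param noise_sd SD of the smoothed voxel noise, in GMV units.
#' @param gender_p probability that a subject is male.
#' @param gender_effect additive global GMV offset for male subjects.
#' @param seed integer seed; fully determines the cohort.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(grid_shape = c(40L, 48L, 40L),
                        voxel_size_mm = 1.5,
                        n_per_group = 83L,
                        groups = c("NC", "EMCI", "LMCI", "AD"),
                        effect_clusters = default_effect_clusters(grid_shape, groups),
                        smoothing_fwhm_mm = 8,
                        noise_sd = 0.1,
                        gender_p = 0.5,
                        gender_effect = 0.02,
                        seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8),
            voxel_size_mm > 0, n_per_group >= 2L, length(groups) >= 2L,
            smoothing_fwhm_mm > 0, noise_sd > 0,
            gender_p >= 0, gender_p <= 1)
  for (cl in effect_clusters) {
    stopifnot(is.list(cl), length(cl$center) == 3L, cl$radius_mm >= voxel_size_mm)
    if (any(cl$center < 1L) || any(cl$center > grid_shape))
      stop("effect cluster center lies outside the grid")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_per_group = as.integer(n_per_group),
                 groups = groups,
                 effect_clusters = effect_clusters,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 noise_sd = noise_sd,
                 gender_p = gender_p,
                 gender_effect = gender_effect,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default planted effect: one left-hemisphere atrophy cluster
#'
#' One cluster in the left hemisphere (low x indices), with a d = -1.5
#' gray-matter reduction in every non-reference group.
#'
#' @param grid_shape voxels per axis.
#' @param groups group labels (first = reference).
#' @return list of effect-cluster descriptors.
#' @export
default_effect_clusters <- function(grid_shape, groups = c("NC", "EMCI", "LMCI", "AD")) {
  center <- c(round(grid_shape[1] * 0.30), round(grid_shape[2] * 0.5),
              round(grid_shape[3] * 0.5))
  d <- stats::setNames(c(0, rep(-1.5, length(groups) - 1L)), groups)
  list(list(center = as.integer(center), radius_mm = 9, d = d))
}

# Ellipsoidal in-brain mask centered on the grid; symmetric about the
# mid-sagittal plane.
ellipsoid_mask <- function(grid_shape, semi = 0.42) {
  ax <- lapply(1:3, function(a) {
    (seq_len(grid_shape[a]) - (grid_shape[a] + 1) / 2) / (semi * grid_shape[a])
  })
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  dim(r2) <- grid_shape
  r2 <= 1
}

# Hard-ball indicator in mm around a voxel center.
ball_indicator <- function(grid_shape, affine, center_vox, radius_mm) {
  ctr <- vox_to_world(affine, matrix(center_vox, 1))
  idx <- as.matrix(expand.grid(i = seq_len(grid_shape[1]),
                               j = seq_len(grid_shape[2]),
                               k = seq_len(grid_shape[3])))
  w <- vox_to_world(affine, idx)
  d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 + (w[, 3] - ctr[3])^2
  ind <- array(0, grid_shape)
  ind[d2 <= radius_mm^2] <- 1
  ind
}

#' Generate a synthetic GMV cohort
#'
#' Draws per-subject smoothed volumes with planted cluster effects and a
#' subject table (group, gender).  The same seed and spec always produce the
#' same cohort.
#'
#' @param spec a \code{cohort_spec}.
#' @return Object of class \code{gmv_cohort}: a list with \code{data}
#'   (voxels x subjects matrix, full grid in column-major voxel order),
#'   \code{subjects} (data.frame: subject_id, group, gender), \code{mask},
#'   \code{affine}, \code{grid_shape}, \code{effect_maps} (per-group arrays
#'   of planted mean shifts in GMV units), and \code{spec}.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape
  affine <- centered_affine(gs, spec$voxel_size_mm)
  mask <- ellipsoid_mask(gs)
  kern <- gaussian_kernel_fft(gs, spec$smoothing_fwhm_mm, spec$voxel_size_mm)

  baseline <- smooth_field(array(as.numeric(mask), gs) * 0.8, kern)

  # per-group planted mean-shift fields, in GMV units
  effect_maps <- lapply(spec$groups, function(g) array(0, gs))
  names(effect_maps) <- spec$groups
  for (cl in spec$effect_clusters) {
    ball <- ball_indicator(gs, affine, cl$center, cl$radius_mm)
    for (g in spec$groups) {
      dg <- if (g %in% names(cl$d)) cl$d[[g]] else 0
      effect_maps[[g]] <- effect_maps[[g]] + dg * spec$noise_sd * ball
    }
  }

  n_tot <- spec$n_per_group * length(spec$groups)
  subjects <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n_tot)),
    group = rep(spec$groups, each = spec$n_per_group),
    gender = ifelse(stats::runif(n_tot) < spec$gender_p, "M", "F"),
    stringsAsFactors = FALSE)

  data <- matrix(0, prod(gs), n_tot)
  for (s in seq_len(n_tot)) {
    noise <- smooth_field(array(stats::rnorm(prod(gs)), gs), kern)
    noise <- noise / stats::sd(noise)            # unit SD after smoothing
    vol <- baseline + spec$noise_sd * noise + effect_maps[[subjects$group[s]]]
    if (subjects$gender[s] == "M") vol <- vol + spec$gender_effect
    data[, s] <- vol
  }

  structure(list(data = data, subjects = subjects, mask = mask,
                 affine = affine, grid_shape = gs,
                 voxel_size_mm = spec$voxel_size_mm,
                 effect_maps = effect_maps, spec = spec),
            class = "gmv_cohort")
}

#' @export
print.gmv_cohort <- function(x, ...) {
  cat(sprintf("<gmv_cohort> %s grid, %d subjects (%s), %d in-mask voxels\n",
              paste(x$grid_shape, collapse = "x"), nrow(x$subjects),
              paste(sprintf("%s=%d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", "),
              sum(x$mask)))
  invisible(x)
}

#' Planted effect field of a group
#'
#' The per-voxel mean shift (in GMV units) planted for a group, as a
#' \code{volumetric_map}.  Useful as the spatial reference when planting
#' expression-atrophy correlations.
#'
#' @param cohort a \code{gmv_cohort}.
#' @param group group label.
#' @return \code{volumetric_map} of planted mean shifts.
#' @export
effect_field <- function(cohort, group) {
  stopifnot(inherits(cohort, "gmv_cohort"), group %in% cohort$spec$groups)
  volumetric_map(cohort$effect_maps[[group]], cohort$affine, cohort$mask)
}

#' Write cohort volumes as NIfTI files
#'
#' @param cohort a \code{gmv_cohort}.
#' @param dir output directory (created if absent).
#' @return data.frame mapping subject_id to file path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gmv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(cohort$subjects))
  for (s in seq_len(nrow(cohort$subjects))) {
    vol <- array(cohort$data[, s], cohort$grid_shape)
    paths[s] <- file.path(dir, paste0(cohort$subjects$subject_id[s], ".nii.gz"))
    write_volume(volumetric_map(vol, cohort$affine, cohort$mask), paths[s])
  }
  utils::write.table(cohort$subjects, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(data.frame(subject_id = cohort$subjects$subject_id, path = paths,
                       stringsAsFactors = FALSE))
}
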