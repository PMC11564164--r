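#' Regional mean t within spheres at sample coordinates
#'
#' For each tissue-sample coordinate, averages the t statistic over all
#' in-mask voxels whose center lies within \code{radius_mm} (Euclidean
#' distance in world mm, boundary inclusive) of the coordinate.  The
#' default radius, 4.5 mm, is three times a 1.5 mm voxel edge.  Samples
#' with no in-mask voxel inside their sphere are dropped with a warning;
#' callers must drop the same samples from the expression matrix (join by
#' \code{sample_id}).
#'
#' @param t_map a \code{volumetric_map} of t statistics (mask = analysis
#'   mask), or a \code{contrast_result}.
#' @param coords numeric matrix (samples x 3) of MNI mm coordinates.
#' @param radius_mm sphere radius in mm.
#' @param sample_id optional sample identifiers (default row numbers).
#' @return data.frame of class \code{regional_profile} with columns
#'   \code{sample_id}, \code{t_mean}, \code{n_voxels} (retained samples
#'   only).
#' @export
sphere_mean_t <- function(t_map, coords, radius_mm = 4.5, sample_id = NULL) {
  if (inherits(t_map, "contrast_result")) t_map <- t_map$t_map
  stopifnot(inherits(t_map, "volumetric_map"), radius_mm > 0)
  coords <- matrix(as.numeric(as.matrix(coords)), ncol = 3)
  stopifnot(all(is.finite(coords)))
  if (is.null(sample_id)) sample_id <- seq_len(nrow(coords))
  gs <- dim(t_map$values)
  vs <- voxel_size(t_map$affine)

  ctr_vox <- world_to_vox(t_map$affine, coords)    # continuous, 0-based
  half <- ceiling(radius_mm / vs)
  t_mean <- rep(NA_real_, nrow(coords))
  n_vox <- integer(nrow(coords))
  for (s in seq_len(nrow(coords))) {
    lo <- pmax(floor(ctr_vox[s, ] - half) + 1, 1)          # 1-based bounds
    hi <- pmin(ceiling(ctr_vox[s, ] + half) + 1, gs)
    if (any(lo > hi)) next
    cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
    w <- vox_to_world(t_map$affine, cand)
    d2 <- (w[, 1] - coords[s, 1])^2 + (w[, 2] - coords[s, 2])^2 +
      (w[, 3] - coords[s, 3])^2
    keep <- d2 <= radius_mm^2
    if (!any(keep)) next
    lin <- cand[keep, 1] + (cand[keep, 2] - 1L) * gs[1] +
      (cand[keep, 3] - 1L) * gs[1] * gs[2]
    lin <- lin[t_map$mask[lin]]
    n_vox[s] <- length(lin)
    if (length(lin)) t_mean[s] <- mean(t_map$values[lin])
  }
  drop <- n_vox == 0
  if (any(drop)) {
    warning(sum(drop), " sample(s) with no in-mask voxel in their sphere dropped")
  }
  out <- data.frame(sample_id = sample_id[!drop], t_mean = t_mean[!drop],
                    n_voxels = n_vox[!drop], stringsAsFactors = FALSE)
  class(out) <- c("regional_profile", "data.frame")
  out
}
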