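#' Voxelwise two-group GLM t statistics
#'
#' Fits, at every in-mask voxel, a GLM of GMV on an intercept, a group
#' indicator, and optional covariates, and returns the t statistic of the
#' group coefficient.  Positive t means group A > group B.
#'
#' @param cohort a \code{gmv_cohort} (or any list with \code{data},
#'   \code{subjects}, \code{mask}, \code{affine}, \code{grid_shape}).
#' @param group_a,group_b group labels to contrast (A minus B).
#' @param covariates character vector of subject-table columns to adjust
#'   for (default \code{"gender"}); character columns are coded as 0/1
#'   indicators of the non-reference level.
#' @param mask_rel_threshold voxels whose cohort-mean GMV falls below this
#'   fraction of the maximum cohort-mean are excluded from analysis.
#' @return Object of class \code{contrast_result}: \code{t_map}
#'   (\code{volumetric_map} over the analysis mask), \code{df},
#'   \code{resid} (in-mask voxels x subjects), \code{n}, and labels.
#' @export
voxelwise_glm_t <- function(cohort, group_a, group_b, covariates = "gender",
                            mask_rel_threshold = 0.1) {
  stopifnot(group_a %in% cohort$subjects$group, group_b %in% cohort$subjects$group)
  sel_a <- cohort$subjects$group == group_a
  sel_b <- cohort$subjects$group == group_b
  sub <- cohort$subjects[sel_a | sel_b, , drop = FALSE]
  Y <- cohort$data[, sel_a | sel_b, drop = FALSE]

  cov_mat <- NULL
  if (length(covariates)) {
    cov_mat <- sapply(covariates, function(cv) {
      v <- sub[[cv]]
      if (is.null(v)) stop("covariate not found in subject table: ", cv)
      if (is.character(v) || is.factor(v)) as.numeric(factor(v)) - 1 else as.numeric(v)
    })
    cov_mat <- matrix(cov_mat, nrow = nrow(sub))
  }

  gmean <- rowMeans(Y)
  amask <- cohort$mask & array(gmean > mask_rel_threshold * max(gmean),
                               cohort$grid_shape)
  fit <- glm_t_map(Y[amask, , drop = FALSE][, sub$group == group_a, drop = FALSE],
                   Y[amask, , drop = FALSE][, sub$group == group_b, drop = FALSE],
                   covariates = {
                     ord <- c(which(sub$group == group_a), which(sub$group == group_b))
                     if (is.null(cov_mat)) NULL else cov_mat[ord, , drop = FALSE]
                   })

  t_arr <- array(0, cohort$grid_shape)
  t_arr[amask] <- fit$t
  structure(list(t_map = volumetric_map(t_arr, cohort$affine, amask),
                 df = fit$df, resid = fit$resid, n = ncol(Y),
                 group_a = group_a, group_b = group_b,
                 voxel_size_mm = voxel_size(cohort$affine)),
            class = "contrast_result")
}

#' Two-sample GLM t at each row
#'
#' Low-level engine behind \code{\link{voxelwise_glm_t}}: rows are voxels,
#' columns subjects.  The design is intercept + group indicator (+
#' covariates); the returned t tests the indicator, signed A minus B.
#'
#' @param YA,YB numeric matrices (voxels x subjects) for the two groups.
#' @param covariates optional numeric matrix with \code{ncol(YA)+ncol(YB)}
#'   rows (A subjects first).
#' @return list with \code{t} (per row), \code{df}, \code{resid}.
#' @export
glm_t_map <- function(YA, YB, covariates = NULL) {
  YA <- rbind(YA); YB <- rbind(YB)
  stopifnot(nrow(YA) == nrow(YB))
  n <- ncol(YA) + ncol(YB)
  X <- cbind(intercept = 1, group = c(rep(1, ncol(YA)), rep(0, ncol(YB))))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    X <- cbind(X, covariates)
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  df <- n - ncol(X)
  if (df < 1) stop("not enough subjects for the design")
  Y <- cbind(YA, YB)
  Q <- solve(crossprod(X))
  beta <- Y %*% (X %*% Q)           # voxels x p
  resid <- Y - beta %*% t(X)
  sigma2 <- rowSums(resid^2) / df
  se <- sqrt(sigma2 * Q[2, 2])
  t <- unname(beta[, 2] / se)
  t[se == 0] <- 0
  list(t = t, df = df, resid = resid)
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s - %s: df = %d, %d in-mask voxels, t in [%.2f, %.2f]\n",
              x$group_a, x$group_b, x$df, sum(x$t_map$mask),
              min(x$t_map$values[x$t_map$mask]), max(x$t_map$values[x$t_map$mask])))
  if (!is.null(x$cluster_table)) {
    cat(sprintf("  %d corrected cluster(s)\n", nrow(x$cluster_table)))
  }
  invisible(x)
}

#' Estimate residual field smoothness (FWHM)
#'
#' Stationary-field smoothness estimator from the spatial derivatives of
#' normalized residual images: residual vectors are scaled to unit norm per
#' voxel, per-axis derivative variance v is accumulated over in-mask
#' neighbor pairs, and FWHM = h * sqrt(4 log 2 / (v h^2)) per axis.
#'
#' @param resid matrix of residuals, in-mask voxels x images, rows ordered
#'   as \code{which(mask)}.
#' @param mask logical 3-D array.
#' @param voxel_size_mm voxel edge lengths (scalar or length 3).
#' @return numeric length-3 vector of per-axis FWHM in mm.
#' @export
estimate_smoothness <- function(resid, mask, voxel_size_mm) {
  stopifnot(is.matrix(resid), nrow(resid) == sum(mask), ncol(resid) >= 2)
  h <- rep(voxel_size_mm, length.out = 3)
  ss <- sqrt(rowSums(resid^2))
  if (any(ss == 0)) stop("flat residuals: cannot estimate smoothness")
  u <- resid / ss
  gs <- dim(mask)
  idx <- array(NA_integer_, gs)
  idx[mask] <- seq_len(sum(mask))

  fwhm <- numeric(3)
  for (a in 1:3) {
    lo <- idx[slice.index(idx, a) < gs[a]]
    hi <- idx[slice.index(idx, a) > 1]
    keep <- !is.na(lo) & !is.na(hi)
    if (!any(keep)) stop("mask too thin along axis ", a)
    d <- (u[hi[keep], , drop = FALSE] - u[lo[keep], , drop = FALSE]) / h[a]
    v <- mean(rowSums(d^2))
    fwhm[a] <- sqrt(4 * log(2) / v)
  }
  fwhm
}

# neighbor offsets for 6/18/26 connectivity (half set; symmetric closure by
# undirected edges)
conn_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  deg <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
                "6"  = off[deg == 1, , drop = FALSE],
                "18" = off[deg <= 2, , drop = FALSE],
                "26" = off,
                stop("connectivity must be 6, 18 or 26"))
  # keep one direction per pair
  off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
        (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
}

#' Label connected components of a binary 3-D mask
#'
#' @param supra logical 3-D array.
#' @param connectivity 6, 18 or 26 (default).
#' @return integer array of cluster labels (0 outside), labels ordered by
#'   decreasing cluster size.
#' @export
label_clusters <- function(supra, connectivity = 26) {
  gs <- dim(supra)
  lin <- which(supra)
  lab <- array(0L, gs)
  if (!length(lin)) return(lab)
  coord <- arrayInd(lin, gs)
  off <- conn_offsets(connectivity)
  pos <- array(0L, gs)
  pos[lin] <- seq_along(lin)
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coord, 2, off[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= gs[1] & nb[, 2] >= 1 & nb[, 2] <= gs[2] &
      nb[, 3] >= 1 & nb[, 3] <= gs[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * gs[1] + (nb[ok, 3] - 1L) * gs[1] * gs[2]
    j <- pos[nb_lin]
    hit <- j > 0L
    if (any(hit)) edges <- rbind(edges, cbind(which(ok)[hit], j[hit]))
  }
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(lin), seq_along(lin))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(lin)]
  sizes <- table(comp)
  rk <- rank(-as.numeric(sizes), ties.method = "first")
  relabel <- stats::setNames(as.integer(rk), names(sizes))
  lab[lin] <- relabel[as.character(comp)]
  lab
}

# Expected-cluster-count (EC density) for a 3-D t field at threshold u,
# df nu, in resel units (Worsley-style 3-D term only).
ec_density_t3 <- function(u, nu) {
  (4 * log(2))^(3 / 2) / (2 * pi)^2 *
    (1 + u^2 / nu)^(-(nu - 1) / 2) * ((nu - 1) / nu * u^2 - 1)
}

# Cluster-level familywise p for a cluster of k voxels (Friston et al.
# Poisson clumping approximation).
cluster_p_grf <- function(k, u, df, n_mask_vox, resels) {
  em <- resels * max(ec_density_t3(u, df), .Machine$double.xmin)
  p0 <- stats::pt(u, df, lower.tail = FALSE)
  en <- n_mask_vox * p0 / em                 # expected voxels per cluster
  beta <- (gamma(5 / 2) / en)^(2 / 3)
  pk <- exp(-beta * k^(2 / 3))
  1 - exp(-em * pk)
}

#' GRF cluster-level correction of a contrast
#'
#' Two one-tailed analyses at the voxel threshold (matching separate
#' "decreased"/"increased" reporting): the t map is thresholded at the
#' voxel-level quantile in each direction, connected components are
#' labeled, and each cluster receives a familywise p from the stationary
#' Gaussian-random-field expected-cluster-count approximation given the
#' search volume in resels.  Clusters with p < \code{cluster_p} survive.
#'
#' @param cr a \code{contrast_result}.
#' @param voxel_p cluster-forming voxel-level p (one-tailed per direction).
#' @param cluster_p cluster-level familywise threshold.
#' @param fwhm_mm optional smoothness (scalar or length-3, mm); estimated
#'   from the residuals when missing.
#' @param connectivity cluster connectivity (default 26).
#' @return The input with added fields: \code{cluster_table} (label, sign,
#'   size_vox, peak_t, peak_x/y/z, p), \code{mask_pos}, \code{mask_neg}
#'   (logical arrays of surviving voxels), \code{fwhm_mm}, and thresholds.
#' @export
grf_cluster_correct <- function(cr, voxel_p = 0.001, cluster_p = 0.05,
                                fwhm_mm = NULL, connectivity = 26) {
  stopifnot(inherits(cr, "contrast_result"),
            voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  vs <- rep(cr$voxel_size_mm, length.out = 3)
  if (is.null(fwhm_mm)) {
    fwhm_mm <- estimate_smoothness(cr$resid, cr$t_map$mask, vs)
  }
  fwhm_mm <- rep(fwhm_mm, length.out = 3)
  if (any(fwhm_mm < vs)) {
    warning("estimated FWHM below voxel size; clamping")
    fwhm_mm <- pmax(fwhm_mm, vs)
  }
  mask <- cr$t_map$mask
  n_vox <- sum(mask)
  resels <- n_vox * prod(vs) / prod(fwhm_mm)
  u <- stats::qt(1 - voxel_p, cr$df)

  tab <- NULL
  out_masks <- list(pos = array(FALSE, dim(mask)), neg = array(FALSE, dim(mask)))
  for (sgn in c("pos", "neg")) {
    tv <- if (sgn == "pos") cr$t_map$values else -cr$t_map$values
    supra <- mask & (tv > u)
    lab <- label_clusters(supra, connectivity)
    for (L in seq_len(max(lab))) {
      vox <- which(lab == L)
      k <- length(vox)
      p <- cluster_p_grf(k, u, cr$df, n_vox, resels)
      pk <- vox[which.max(tv[vox])]
      peak <- vox_to_world(cr$t_map$affine, arrayInd(pk, dim(mask)))
      row <- data.frame(label = L, sign = sgn, size_vox = k,
                        peak_t = cr$t_map$values[pk],
                        peak_x = peak[1], peak_y = peak[2], peak_z = peak[3],
                        p = p)
      if (p < cluster_p) out_masks[[sgn]][vox] <- TRUE
      tab <- rbind(tab, row)
    }
  }
  if (is.null(tab)) {
    tab <- data.frame(label = integer(), sign = character(),
                      size_vox = integer(), peak_t = numeric(),
                      peak_x = numeric(), peak_y = numeric(),
                      peak_z = numeric(), p = numeric())
  }
  cr$cluster_table <- tab[order(tab$p), , drop = FALSE]
  cr$mask_pos <- out_masks$pos & TRUE
  cr$mask_neg <- out_masks$neg & TRUE
  cr$fwhm_mm <- fwhm_mm
  cr$voxel_p <- voxel_p
  cr$cluster_p <- cluster_p
  cr$t_threshold <- u
  cr
}

#' Cross-contrast overlap of corrected masks
#'
#' Voxelwise logical AND of corrected masks sharing a grid.
#'
#' @param masks list of logical arrays (e.g. \code{mask_neg} of several
#'   corrected contrasts).
#' @return logical array, the intersection.
#' @export
overlap_maps <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("mismatched mask grids")
  Reduce(`&`, masks)
}
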