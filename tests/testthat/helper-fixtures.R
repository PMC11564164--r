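# Shared fixture builders; everything is generated in code at test time.

# small two-group cohort with one planted atrophy cluster
small_cohort <- function(seed = 3, n = 10, d = -1.5,
                         grid = c(20L, 24L, 20L), groups = c("A", "B")) {
  eff <- if (is.na(d)) list() else {
    dv <- stats::setNames(c(0, rep(d, length(groups) - 1)), groups)
    list(list(center = c(7L, 12L, 10L), radius_mm = 6, d = dv))
  }
  make_cohort(cohort_spec(grid_shape = grid, n_per_group = n, groups = groups,
                          effect_clusters = eff, seed = seed))
}

# brute-force oracle for sphere extraction: enumerate EVERY voxel in the
# volume and apply the distance predicate directly
brute_sphere_mean <- function(t_map, coords, radius_mm) {
  gs <- dim(t_map$values)
  idx <- as.matrix(expand.grid(i = seq_len(gs[1]), j = seq_len(gs[2]),
                               k = seq_len(gs[3])))
  w <- imgtx:::vox_to_world(t_map$affine, idx)
  vapply(seq_len(nrow(coords)), function(s) {
    d2 <- (w[, 1] - coords[s, 1])^2 + (w[, 2] - coords[s, 2])^2 +
      (w[, 3] - coords[s, 3])^2
    keep <- d2 <= radius_mm^2 & t_map$mask[idx]
    if (!any(keep)) NA_real_ else mean(t_map$values[idx[keep, , drop = FALSE]])
  }, numeric(1))
}

# exhaustive hypergeometric oracle: enumerate all C(N, n) query draws
brute_hypergeom_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_term <- colSums(draws <= K)   # term = genes 1..K
  mean(in_term >= k)
}

# tiny two-donor expression set built by hand (not via make_expression)
tiny_donor_set <- function() {
  genes <- c("G1", "G2")
  probes <- data.frame(probe_id = c("P1", "P2", "P3"),
                       gene_symbol = c("G1", "G1", "G2"),
                       stringsAsFactors = FALSE)
  mk <- function(id, wells, xs, shift = 0) {
    set.seed(nchar(id))
    expr <- matrix(rnorm(3 * length(wells), mean = 6 + shift), 3, length(wells),
                   dimnames = list(probes$probe_id, wells))
    pa <- matrix(1L, 3, length(wells), dimnames = dimnames(expr))
    list(donor_id = id, probes = probes, expr = expr, pa = pa,
         samples = data.frame(well_id = wells, mni_x = xs,
                              mni_y = 0, mni_z = 0, stringsAsFactors = FALSE))
  }
  list(mk("A", sprintf("W%02d", 1:6), c(-30, -20, -10, -5, 10, 20)),
       mk("BB", sprintf("W%02d", 7:12), c(-25, -15, -8, -2, 5, 15), shift = 2))
}
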