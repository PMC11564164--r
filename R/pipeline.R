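#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis plus the
#' synthetic-data specifications.  All randomness descends from
#' \code{seed}: the cohort uses \code{seed}, the expression set
#' \code{seed + 1}, the gene sets \code{seed + 2}, and the per-contrast
#' bootstraps \code{seed + 10 + i}.
#'
#' @param seed master integer seed.
#' @param out_dir output directory for stage tables and the manifest.
#' @param cohort a \code{\link{cohort_spec}}.
#' @param expression an \code{\link{expression_spec}}.
#' @param contrasts list of c(group_a, group_b) pairs.
#' @param covariates covariate columns for the voxelwise GLM.
#' @param risk_genes character vector of risk-gene symbols.
#' @param gene_sets named list of gene sets, or \code{NULL} to synthesize
#'   sets with the planted positive genes as the planted term.
#' @param atrophy_reference group whose planted effect field seeds the
#'   expression generator.
#' @param radius_mm sphere radius for regional extraction.
#' @param voxel_p,cluster_p GRF correction thresholds.
#' @param n_boot,z_thr PLS bootstrap parameters.
#' @param alpha significance level (gene stats and enrichment).
#' @param n_tests Bonferroni family size (\code{NULL}: number of
#'   consistent genes).
#' @param min_overlap,kappa_thr enrichment parameters.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = file.path(tempdir(), "imgtx_run"),
                            cohort = cohort_spec(seed = seed),
                            expression = expression_spec(seed = seed + 1L),
                            contrasts = list(c("EMCI", "NC"), c("LMCI", "NC"),
                                             c("AD", "NC")),
                            covariates = "gender",
                            risk_genes = default_risk_genes(),
                            gene_sets = NULL,
                            atrophy_reference = NULL,
                            radius_mm = 4.5,
                            voxel_p = 0.001, cluster_p = 0.05,
                            n_boot = 1000L, z_thr = 5,
                            alpha = 0.05, n_tests = NULL,
                            min_overlap = 3L, kappa_thr = 0.3) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(expression, "expression_spec"),
            length(contrasts) >= 1, radius_mm > 0,
            voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1,
            n_boot >= 100, z_thr > 0, alpha > 0, alpha < 1,
            min_overlap >= 1, kappa_thr > 0, kappa_thr < 1)
  for (ct in contrasts) stopifnot(length(ct) == 2, all(ct %in% cohort$groups))
  if (is.null(atrophy_reference)) atrophy_reference <- utils::tail(cohort$groups, 1)
  structure(list(seed = as.integer(seed), out_dir = out_dir, cohort = cohort,
                 expression = expression, contrasts = contrasts,
                 covariates = covariates, risk_genes = risk_genes,
                 gene_sets = gene_sets, atrophy_reference = atrophy_reference,
                 radius_mm = radius_mm, voxel_p = voxel_p,
                 cluster_p = cluster_p, n_boot = as.integer(n_boot),
                 z_thr = z_thr, alpha = alpha, n_tests = n_tests,
                 min_overlap = as.integer(min_overlap), kappa_thr = kappa_thr),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full imaging-transcriptomics pipeline
#'
#' Executes, in order: synthetic cohort and donor-expression generation
#' (with a file round-trip through the AHBA-dialect CSV layout), the
#' expression-processing chain, per-contrast voxelwise GLM t-maps with GRF
#' cluster correction, cross-contrast overlap masks, sphere-based regional
#' t extraction, PLS1 with bootstrap Z gene ranking, signed consistent-gene
#' intersection, gene-wise Spearman/Bonferroni statistics, and
#' hypergeometric enrichment with kappa clustering.  Stage tables are
#' written under \code{out_dir} together with a provenance manifest.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param verbose emit one structured message per stage.
#' @return Object of class \code{imgtx_pipeline} bundling all stage
#'   results (see elements \code{contrasts}, \code{profiles}, \code{pls},
#'   \code{consistent}, \code{associations}, \code{enrichment},
#'   \code{manifest}).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- make_cohort(config$cohort)
  stage_log(verbose, "cohort", "%d subjects, grid %s, %d in-mask voxels",
            nrow(cohort$subjects), paste(cohort$grid_shape, collapse = "x"),
            sum(cohort$mask))

  eset <- make_expression(config$expression,
                          effect_field(cohort, config$atrophy_reference))
  donor_dir <- file.path(config$out_dir, "donors")
  write_donor_files(eset, donor_dir)
  donors <- read_ahba_donors(donor_dir)
  rnaseq <- read_rnaseq_reference(file.path(donor_dir, "rnaseq_reference.tsv"))
  em <- build_expression_matrix(donors, rnaseq)
  stage_log(verbose, "expression", "%d left samples x %d genes retained",
            nrow(em$values), ncol(em$values))

  interesting <- intersect_risk_genes(config$risk_genes, em$genes)
  stage_log(verbose, "risk", "%d of %d risk genes in background",
            length(interesting), length(config$risk_genes))

  contrasts <- list()
  profiles <- list()
  fits <- list()
  coords <- as.matrix(em$samples[, c("mni_x", "mni_y", "mni_z")])
  for (i in seq_along(config$contrasts)) {
    ct <- config$contrasts[[i]]
    cname <- paste0(ct[1], "-", ct[2])
    cr <- voxelwise_glm_t(cohort, ct[1], ct[2], covariates = config$covariates)
    cr <- grf_cluster_correct(cr, voxel_p = config$voxel_p,
                              cluster_p = config$cluster_p)
    cr$resid <- NULL
    stage_log(verbose, "contrast", "%s: df = %d, %d surviving cluster(s)",
              cname, cr$df, sum(cr$cluster_table$p < config$cluster_p))
    pr <- sphere_mean_t(cr, coords, radius_mm = config$radius_mm,
                        sample_id = em$samples$well_id)
    contrasts[[cname]] <- cr
    profiles[[cname]] <- pr
  }

  common <- Reduce(intersect, lapply(profiles, `[[`, "sample_id"))
  if (length(common) < 10) stop("too few samples with valid spheres")
  X <- em$values[match(common, em$samples$well_id), interesting, drop = FALSE]
  for (i in seq_along(contrasts)) {
    cname <- names(contrasts)[i]
    pr <- profiles[[cname]]
    y <- pr$t_mean[match(common, pr$sample_id)]
    fits[[cname]] <- pls1(X, y, n_boot = config$n_boot, z_thr = config$z_thr,
                          seed = config$seed + 10L + i)
    stage_log(verbose, "pls", "%s: r = %.3f, %d positive, %d negative genes",
              cname, fits[[cname]]$r, length(fits[[cname]]$pos_genes),
              length(fits[[cname]]$neg_genes))
  }

  pos_consistent <- intersect_gene_lists(lapply(fits, `[[`, "pos_genes"))
  neg_consistent <- intersect_gene_lists(lapply(fits, `[[`, "neg_genes"))
  consistent <- c(pos_consistent, neg_consistent)
  stage_log(verbose, "consistent", "%d positive + %d negative genes",
            length(pos_consistent), length(neg_consistent))

  assoc <- NULL
  if (length(consistent) >= 1) {
    profs <- lapply(profiles, function(pr) pr[match(common, pr$sample_id), ])
    assoc <- gene_t_associations(em, profs, genes = consistent,
                                 alpha = config$alpha,
                                 n_tests = if (is.null(config$n_tests))
                                   length(consistent) else config$n_tests)
  }

  sets <- config$gene_sets
  if (is.null(sets)) {
    planted_pos <- eset$planted$gene[eset$planted$rho > 0]
    sets <- make_gene_sets(em$genes, planted_pos, n_terms = 20L,
                           seed = config$seed + 2L)
  }
  gmt_path <- file.path(config$out_dir, "gene_sets.gmt")
  write_gmt(sets, gmt_path)
  sets <- read_gmt(gmt_path)
  enr <- list()
  for (sgn in c("positive", "negative")) {
    q <- if (sgn == "positive") pos_consistent else neg_consistent
    if (length(q) >= 1) {
      enr[[sgn]] <- hypergeom_enrich(q, sets, em$genes, alpha = config$alpha,
                                     min_overlap = config$min_overlap,
                                     kappa_thr = config$kappa_thr)
      stage_log(verbose, "enrichment", "%s list: %d surviving term(s)", sgn,
                nrow(enr[[sgn]]))
    }
  }

  # stage outputs + provenance manifest
  files <- character(0)
  for (cname in names(contrasts)) {
    f1 <- write_tsv(contrasts[[cname]]$cluster_table,
                    file.path(config$out_dir, paste0("clusters_", cname, ".tsv")))
    f2 <- write_tsv(profiles[[cname]],
                    file.path(config$out_dir, paste0("profile_", cname, ".tsv")))
    f3 <- write_tsv(summary(fits[[cname]])$table,
                    file.path(config$out_dir, paste0("pls_genes_", cname, ".tsv")))
    files <- c(files, f1, f2, f3)
  }
  files <- c(files, write_tsv(
    data.frame(gene = consistent,
               direction = rep(c("positive", "negative"),
                               c(length(pos_consistent), length(neg_consistent))),
               stringsAsFactors = FALSE),
    file.path(config$out_dir, "consistent_genes.tsv")))
  if (!is.null(assoc))
    files <- c(files, write_tsv(assoc, file.path(config$out_dir,
                                                 "gene_associations.tsv")))
  for (sgn in names(enr))
    files <- c(files, write_tsv(enr[[sgn]],
                                file.path(config$out_dir,
                                          paste0("enrichment_", sgn, ".tsv"))))

  manifest <- list(
    package_version = as.character(utils::packageVersion("imgtx")),
    seed = config$seed,
    parameters = config[c("radius_mm", "voxel_p", "cluster_p", "n_boot",
                          "z_thr", "alpha", "min_overlap", "kappa_thr")],
    n_subjects = nrow(cohort$subjects),
    n_left_samples = nrow(em$values),
    n_common_samples = length(common),
    n_background_genes = ncol(em$values),
    n_interesting_genes = length(interesting),
    consistent_genes = as.list(stats::setNames(
      rep(c("positive", "negative"),
          c(length(pos_consistent), length(neg_consistent))), consistent)),
    output_md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                         basename(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(config = config, cohort_subjects = cohort$subjects,
                 overlap_neg = overlap_maps(lapply(contrasts, `[[`, "mask_neg")),
                 overlap_pos = overlap_maps(lapply(contrasts, `[[`, "mask_pos")),
                 expression = em, interesting_genes = interesting,
                 contrasts = contrasts, profiles = profiles, pls = fits,
                 consistent = list(positive = pos_consistent,
                                   negative = neg_consistent),
                 associations = assoc, enrichment = enr,
                 manifest = manifest),
            class = "imgtx_pipeline")
}

#' @export
print.imgtx_pipeline <- function(x, ...) {
  cat("<imgtx_pipeline>\n")
  cat(sprintf("  contrasts: %s\n", paste(names(x$contrasts), collapse = ", ")))
  cat(sprintf("  interesting genes: %d; consistent: %d positive, %d negative\n",
              length(x$interesting_genes), length(x$consistent$positive),
              length(x$consistent$negative)))
  if (length(x$consistent$positive))
    cat("  positive:", paste(x$consistent$positive, collapse = ", "), "\n")
  if (length(x$consistent$negative))
    cat("  negative:", paste(x$consistent$negative, collapse = ", "), "\n")
  invisible(x)
}
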