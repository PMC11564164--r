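#' Specification of a synthetic donor expression set
#'
#' Describes an AHBA-dialect multi-donor microarray data set with planted
#' spatial gene-atrophy correlations and multi-probe structure.  Tissue
#' samples are drawn uniformly within the brain mask of a reference field,
#' on both hemispheres, so left-hemisphere filtering is exercised.  Each
#' gene carries \code{probes_per_gene} probes in decreasing fidelity: the
#' first is high-fidelity (low noise, low absent-call rate), the second is
#' degraded (heteroscedastic noise), the third - when present - has an
#' absent-call rate above 50\% so the background filter removes it.
#'
#' @param n_donors number of donor brains.
#' @param n_samples_left target number of left-hemisphere samples;
#'   \code{2 * n_samples_left} samples are drawn in total.
#' @param genes character vector of gene symbols in the background panel.
#' @param probes_per_gene probes per gene (>= 1).
#' @param planted data.frame with columns \code{gene} and \code{rho}, the
#'   target spatial correlation (in (-1, 1)) of each planted gene's
#'   noise-free profile with the reference field across left-hemisphere
#'   samples.
#' @param pa_dropout baseline fraction of absent calls for degraded probes.
#' @param seed integer seed; fully determines the output.
#' @return Object of class \code{expression_spec}.
#' @export
expression_spec <- function(n_donors = 6L,
                            n_samples_left = 1285L,
                            genes = background_gene_panel(),
                            probes_per_gene = 3L,
                            planted = default_planted_genes(),
                            pa_dropout = 0.3,
                            seed = 1L) {
  stopifnot(n_donors >= 1L, n_samples_left >= 10L, probes_per_gene >= 1L,
            pa_dropout >= 0, pa_dropout < 1,
            is.data.frame(planted), all(c("gene", "rho") %in% names(planted)))
  if (!all(planted$gene %in% genes))
    stop("planted gene(s) not in the gene panel: ",
         paste(setdiff(planted$gene, genes), collapse = ", "))
  if (any(abs(planted$rho) >= 1)) stop("planted correlations must lie in (-1, 1)")
  if (anyDuplicated(genes)) stop("gene panel must be unique")
  structure(list(n_donors = as.integer(n_donors),
                 n_samples_left = as.integer(n_samples_left),
                 genes = genes, probes_per_gene = as.integer(probes_per_gene),
                 planted = planted, pa_dropout = pa_dropout,
                 seed = as.integer(seed)),
            class = "expression_spec")
}

#' Default background gene panel
#'
#' The packaged risk-gene list's first 41 symbols (so 41 of the 52 risk
#' genes are covered by the background, and 11 are not) plus filler
#' symbols up to \code{n_genes}.
#'
#' @param n_genes panel size (>= 41).
#' @return character vector of unique gene symbols.
#' @export
background_gene_panel <- function(n_genes = 100L) {
  risk <- default_risk_genes()
  stopifnot(n_genes >= 41L)
  c(risk[1:41], sprintf("BG%04d", seq_len(n_genes - 41L)))
}

#' Default planted gene-atrophy correlations
#'
#' Twelve planted genes: eight with a positive and four with a negative
#' target spatial correlation (magnitude 0.4) with the reference atrophy
#' field, named after established AD risk genes.
#'
#' @return data.frame with columns \code{gene}, \code{rho}.
#' @export
default_planted_genes <- function() {
  data.frame(
    gene = c("ABCA7", "SORCS1", "SORL1", "PILRA", "PFDN1", "PLXNA4",
             "TRIP4", "CD2AP", "CD33", "PLCG2", "APOE", "ECHDC3"),
    rho = c(rep(0.4, 8), rep(-0.4, 4)),
    stringsAsFactors = FALSE)
}

#' Packaged default risk-gene list
#'
#' Reads the packaged synthetic stand-in risk list (52 symbols: the twelve
#' consistently associated genes plus forty literature AD GWAS locus
#' symbols).
#'
#' @return character vector of 52 gene symbols.
#' @export
default_risk_genes <- function() {
  path <- system.file("extdata", "ad_risk_genes_synthetic.txt", package = "imgtx")
  read_gene_list(path)
}

#' Read a gene list file
#'
#' One symbol per line; symbols are whitespace-trimmed and upper-cased,
#' blank lines and \code{#} comments skipped.
#'
#' @param path text file.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  toupper(x)
}

# fidelity tiers for probes 1..p: noise SD and absent-call rate
probe_tiers <- function(p, pa_dropout) {
  sds <- rep(c(0.25, 1.2, 1.5), length.out = max(p, 3))[seq_len(p)]
  drops <- rep(c(min(pa_dropout / 3, 0.1), pa_dropout, 0.65),
               length.out = max(p, 3))[seq_len(p)]
  list(sd = sds, drop = drops)
}

#' Generate a synthetic AHBA-dialect donor expression data set
#'
#' @param spec an \code{expression_spec}.
#' @param atrophy_field a \code{volumetric_map} giving the spatial
#'   reference (e.g. \code{\link{effect_field}} of a cohort); sample
#'   coordinates are drawn uniformly within its mask and planted genes'
#'   noise-free profiles correlate with its values, standardized over
#'   left-hemisphere samples, at the requested \code{rho}.
#' @return Object of class \code{donor_expression_data}: \code{donors} (a
#'   list per donor with \code{donor_id}, \code{probes}, \code{expr}
#'   (probes x samples, log2 intensities), \code{pa}, \code{samples}
#'   (well_id, mni_x/y/z)), \code{rnaseq} (gene x reference-well table),
#'   \code{genes}, \code{planted}, \code{truth} (latent profiles and field
#'   z-scores for validation), and \code{spec}.
#' @export
make_expression <- function(spec, atrophy_field) {
  stopifnot(inherits(spec, "expression_spec"),
            inherits(atrophy_field, "volumetric_map"))
  if (any(!is.finite(atrophy_field$values)))
    stop("atrophy field must be finite")
  set.seed(spec$seed)
  n_tot <- 2L * spec$n_samples_left
  gs <- dim(atrophy_field$values)
  vs <- voxel_size(atrophy_field$affine)

  in_mask <- which(atrophy_field$mask)
  vox <- in_mask[sample.int(length(in_mask), n_tot, replace = TRUE)]
  ctr <- vox_to_world(atrophy_field$affine, arrayInd(vox, gs))
  jit <- matrix(stats::runif(n_tot * 3, -0.5, 0.5), ncol = 3) *
    matrix(vs, n_tot, 3, byrow = TRUE)
  coords <- ctr + jit
  f <- atrophy_field$values[vox]

  left <- coords[, 1] < 0
  if (stats::sd(f[left]) == 0)
    stop("atrophy field is constant over left-hemisphere samples")
  z <- (f - mean(f[left])) / stats::sd(f[left])

  ng <- length(spec$genes)
  rho <- stats::setNames(rep(0, ng), spec$genes)
  rho[spec$planted$gene] <- spec$planted$rho
  latent <- matrix(stats::rnorm(n_tot * ng), n_tot, ng,
                   dimnames = list(NULL, spec$genes))
  latent <- sweep(latent, 2, sqrt(1 - rho^2), `*`) + outer(z, rho)

  well_id <- sprintf("W%05d", seq_len(n_tot))
  donor_of <- sample(rep_len(seq_len(spec$n_donors), n_tot))
  donor_ids <- sprintf("D%02d", seq_len(spec$n_donors))
  donor_offset <- stats::rnorm(spec$n_donors, 0, 1)
  donor_scale <- stats::runif(spec$n_donors, 0.8, 1.25)

  p <- spec$probes_per_gene
  tiers <- probe_tiers(p, spec$pa_dropout)
  n_probes <- ng * p
  probe_id <- sprintf("P%05d", seq_len(n_probes))
  probe_gene <- rep(spec$genes, each = p)
  probe_tier <- rep(seq_len(p), times = ng)
  sensitivity <- stats::rnorm(n_probes, 0, 0.5)

  donors <- vector("list", spec$n_donors)
  for (d in seq_len(spec$n_donors)) {
    sel <- which(donor_of == d)
    lat_d <- t(latent[sel, , drop = FALSE])        # genes x samples
    expr <- matrix(0, n_probes, length(sel))
    for (q in seq_len(p)) {
      rows <- probe_tier == q
      expr[rows, ] <- 6 + donor_offset[d] + sensitivity[rows] +
        donor_scale[d] * lat_d +
        matrix(stats::rnorm(sum(rows) * length(sel), 0, tiers$sd[q]),
               sum(rows), length(sel))
    }
    rownames(expr) <- probe_id
    colnames(expr) <- well_id[sel]
    pa <- matrix(0L, n_probes, length(sel), dimnames = dimnames(expr))
    donors[[d]] <- list(donor_id = donor_ids[d],
                        probes = data.frame(probe_id = probe_id,
                                            gene_symbol = probe_gene,
                                            stringsAsFactors = FALSE),
                        expr = expr, pa = pa,
                        samples = data.frame(well_id = well_id[sel],
                                             mni_x = coords[sel, 1],
                                             mni_y = coords[sel, 2],
                                             mni_z = coords[sel, 3],
                                             stringsAsFactors = FALSE))
  }

  # absent calls from pooled per-probe intensity quantiles, so PA is a
  # deterministic function of intensity
  expr_all <- do.call(cbind, lapply(donors, `[[`, "expr"))
  for (q in seq_len(p)) {
    rows <- which(probe_tier == q)
    thr <- apply(expr_all[rows, , drop = FALSE], 1, stats::quantile,
                 probs = tiers$drop[q], names = FALSE)
    for (d in seq_len(spec$n_donors)) {
      donors[[d]]$pa[rows, ] <-
        (donors[[d]]$expr[rows, , drop = FALSE] > thr) * 1L
    }
  }

  n_ref <- min(300L, n_tot)
  ref_wells <- sort(sample.int(n_tot, n_ref))
  rnaseq <- cbind(
    data.frame(gene_symbol = spec$genes, stringsAsFactors = FALSE),
    as.data.frame(t(latent[ref_wells, , drop = FALSE]) +
                    matrix(stats::rnorm(ng * n_ref, 0, 0.15), ng, n_ref)))
  names(rnaseq)[-1] <- well_id[ref_wells]

  structure(list(donors = donors, rnaseq = rnaseq, genes = spec$genes,
                 planted = spec$planted,
                 truth = list(latent = latent, field_z = z,
                              coords = coords, well_id = well_id,
                              donor_of = donor_ids[donor_of]),
                 spec = spec),
            class = "donor_expression_data")
}

#' @export
print.donor_expression_data <- function(x, ...) {
  n_samp <- sum(vapply(x$donors, function(d) nrow(d$samples), 0L))
  cat(sprintf("<donor_expression_data> %d donors, %d samples, %d genes x %d probes/gene, %d planted\n",
              length(x$donors), n_samp, length(x$genes),
              x$spec$probes_per_gene, nrow(x$planted)))
  invisible(x)
}

#' Write AHBA-dialect donor files
#'
#' Writes, per donor, \code{MicroarrayExpression.csv} and
#' \code{PACall.csv} (no header, first column probe ID),
#' \code{SampleAnnot.csv} and \code{Probes.csv} (with header), under
#' \code{dir/donor_<id>/}, plus the RNA-seq reference table as
#' \code{rnaseq_reference.tsv}.
#'
#' @param x a \code{donor_expression_data}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_donor_files <- function(x, dir) {
  stopifnot(inherits(x, "donor_expression_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in x$donors) {
    dd <- file.path(dir, paste0("donor_", d$donor_id))
    dir.create(dd, showWarnings = FALSE)
    data.table::fwrite(data.table::data.table(probe_id = rownames(d$expr),
                                              round(d$expr, 6)),
                       file.path(dd, "MicroarrayExpression.csv"),
                       col.names = FALSE)
    data.table::fwrite(data.table::data.table(probe_id = rownames(d$pa), d$pa),
                       file.path(dd, "PACall.csv"), col.names = FALSE)
    data.table::fwrite(d$samples, file.path(dd, "SampleAnnot.csv"))
    data.table::fwrite(d$probes, file.path(dd, "Probes.csv"))
  }
  data.table::fwrite(x$rnaseq, file.path(dir, "rnaseq_reference.tsv"),
                     sep = "\t")
  invisible(dir)
}

#' Read AHBA-dialect donor files
#'
#' Reads the per-donor file layout of \code{\link{write_donor_files}} (one
#' \code{donor_*} directory per donor).
#'
#' @param dir directory holding \code{donor_*} subdirectories.
#' @return list of donor sets (\code{donor_id}, \code{probes}, \code{expr},
#'   \code{pa}, \code{samples}).
#' @export
read_ahba_donors <- function(dir) {
  dds <- sort(list.dirs(dir, recursive = FALSE))
  dds <- dds[grepl("^donor_", basename(dds))]
  if (!length(dds)) stop("no donor_* directories under ", dir)
  lapply(dds, function(dd) {
    samples <- as.data.frame(data.table::fread(file.path(dd, "SampleAnnot.csv")))
    probes <- as.data.frame(data.table::fread(file.path(dd, "Probes.csv")))
    ex <- as.data.frame(data.table::fread(file.path(dd, "MicroarrayExpression.csv"),
                                          header = FALSE))
    pa <- as.data.frame(data.table::fread(file.path(dd, "PACall.csv"),
                                          header = FALSE))
    expr <- as.matrix(ex[, -1, drop = FALSE])
    pam <- as.matrix(pa[, -1, drop = FALSE])
    dimnames(expr) <- list(ex[[1]], samples$well_id)
    dimnames(pam) <- list(pa[[1]], samples$well_id)
    list(donor_id = sub("^donor_", "", basename(dd)),
         probes = probes, expr = expr, pa = pam, samples = samples)
  })
}

#' Read an RNA-seq reference table
#'
#' @param path TSV with a \code{gene_symbol} column and one column per
#'   reference well.
#' @return data.frame.
#' @export
read_rnaseq_reference <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
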