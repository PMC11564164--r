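#' Filter probes by above-background signal fraction
#'
#' A probe is retained iff its present-call fraction across all pooled
#' sample sites is at least \code{min_fraction} (default 50\%).
#'
#' @param pa binary matrix, probes x samples, rownames = probe IDs; pool
#'   donors by \code{cbind} before calling.
#' @param min_fraction minimum present fraction.
#' @return character vector of retained probe IDs.
#' @export
filter_probes_by_background <- function(pa, min_fraction = 0.5) {
  if (is.null(dim(pa)) || nrow(pa) == 0 || ncol(pa) == 0)
    stop("empty PA matrix")
  if (!all(pa %in% c(0, 1))) stop("PA matrix must be binary")
  rownames(pa)[rowMeans(pa) >= min_fraction]
}

#' Select one probe per gene by RNA-seq agreement
#'
#' Genes absent from the RNA-seq reference are dropped; for each remaining
#' gene the probe whose (log2-intensity) profile correlates most highly -
#' Spearman, across shared reference wells - with the gene's RNA-seq
#' profile is kept.
#'
#' @param expr probes x samples log2-intensity matrix (pooled donors),
#'   colnames = well IDs; restrict rows to background-filtered probes
#'   before calling.
#' @param probe_table data.frame with \code{probe_id}, \code{gene_symbol}.
#' @param rnaseq_ref data.frame with \code{gene_symbol} plus one column per
#'   reference well.
#' @return data.frame (\code{gene_symbol}, \code{probe_id}, \code{cor}),
#'   one row per retained gene; empty with a warning if nothing survives.
#' @export
select_probes_by_rnaseq <- function(expr, probe_table, rnaseq_ref) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  wells <- intersect(colnames(expr), names(rnaseq_ref)[-1])
  if (length(wells) < 3) stop("fewer than 3 shared reference wells")
  probe_table <- probe_table[probe_table$probe_id %in% rownames(expr), , drop = FALSE]
  genes <- intersect(unique(probe_table$gene_symbol), rnaseq_ref$gene_symbol)
  out <- NULL
  for (g in genes) {
    probes <- probe_table$probe_id[probe_table$gene_symbol == g]
    ref <- as.numeric(rnaseq_ref[match(g, rnaseq_ref$gene_symbol), wells])
    cc <- vapply(probes, function(p) {
      suppressWarnings(stats::cor(expr[p, wells], ref, method = "spearman"))
    }, numeric(1))
    cc[is.na(cc)] <- -Inf
    best <- which.max(cc)
    out <- rbind(out, data.frame(gene_symbol = g, probe_id = probes[best],
                                 cor = cc[best], stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    warning("no probes survive RNA-seq matching")
    out <- data.frame(gene_symbol = character(), probe_id = character(),
                      cor = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Left-hemisphere sample filter
#'
#' A sample is retained iff its MNI x coordinate is strictly negative; the
#' midline (x = 0) is excluded.  Samples with a missing coordinate are
#' rejected with a warning.
#'
#' @param samples data.frame with \code{well_id}, \code{mni_x}.
#' @return character vector of retained well IDs.
#' @export
filter_left_hemisphere <- function(samples) {
  stopifnot(all(c("well_id", "mni_x") %in% names(samples)))
  bad <- !is.finite(samples$mni_x)
  if (any(bad)) {
    warning(sum(bad), " sample(s) with missing coordinates rejected")
  }
  samples$well_id[!bad & samples$mni_x < 0]
}

#' Scaled robust sigmoid
#'
#' s = 1 / (1 + exp(-(x - median) / (IQR / 1.35))).  The median element
#' maps to 0.5.  A zero IQR falls back to rank-based uniform scores.
#'
#' @param x numeric vector.
#' @return numeric vector in (0, 1).
#' @export
scaled_robust_sigmoid <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr == 0) {
    message("zero IQR; falling back to rank-based uniform scores")
    return((rank(x, ties.method = "average") - 0.5) / length(x))
  }
  1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
}

#' Normalize donor expression matrices within and between brains
#'
#' Per donor and per gene, applies the scaled robust sigmoid and then
#' rescales to the unit interval within the donor, removing per-donor
#' location/scale shifts; donors are then concatenated sample-wise.
#'
#' @param donor_mats list of genes x samples matrices (identical rownames).
#' @return samples x genes matrix with values in [0, 1].
#' @export
normalize_expression <- function(donor_mats) {
  stopifnot(is.list(donor_mats), length(donor_mats) >= 1)
  genes <- rownames(donor_mats[[1]])
  blocks <- lapply(donor_mats, function(m) {
    stopifnot(identical(rownames(m), genes))
    norm <- t(apply(m, 1, function(x) {
      s <- scaled_robust_sigmoid(x)
      rng <- range(s)
      if (rng[1] == rng[2]) rep(0.5, length(s)) else (s - rng[1]) / diff(rng)
    }))
    dimnames(norm) <- dimnames(m)
    t(norm)                                   # samples x genes
  })
  do.call(rbind, blocks)
}

#' Assemble the normalized expression matrix from donor files
#'
#' Runs the full expression-processing chain: pooled background filtering
#' of probes, RNA-seq-guided probe selection, left-hemisphere sample
#' filtering, and within/between-donor normalization.
#'
#' @param donors list of donor sets as returned by
#'   \code{\link{read_ahba_donors}} (or \code{$donors} of
#'   \code{\link{make_expression}}).
#' @param rnaseq_ref RNA-seq reference data.frame.
#' @param min_fraction background present-call fraction threshold.
#' @return Object of class \code{expression_matrix}: \code{values}
#'   (samples x genes, in [0, 1]), \code{samples} (well_id, donor_id,
#'   mni_x/y/z), \code{genes}, \code{probe_map}.
#' @export
build_expression_matrix <- function(donors, rnaseq_ref, min_fraction = 0.5) {
  pa_all <- do.call(cbind, lapply(donors, `[[`, "pa"))
  keep_probes <- filter_probes_by_background(pa_all, min_fraction)
  if (!length(keep_probes)) stop("no probes pass the background filter")

  expr_all <- do.call(cbind, lapply(donors, `[[`, "expr"))
  probe_map <- select_probes_by_rnaseq(expr_all[keep_probes, , drop = FALSE],
                                       donors[[1]]$probes, rnaseq_ref)
  if (!nrow(probe_map)) stop("no genes survive probe selection")

  donor_mats <- list()
  sample_tab <- NULL
  for (d in donors) {
    left <- filter_left_hemisphere(d$samples)
    if (!length(left)) next
    m <- d$expr[probe_map$probe_id, left, drop = FALSE]
    rownames(m) <- probe_map$gene_symbol
    donor_mats[[length(donor_mats) + 1L]] <- m
    st <- d$samples[match(left, d$samples$well_id), , drop = FALSE]
    st$donor_id <- d$donor_id
    sample_tab <- rbind(sample_tab, st)
  }
  if (!length(donor_mats)) stop("no left-hemisphere samples retained")
  values <- normalize_expression(donor_mats)
  rownames(sample_tab) <- NULL
  structure(list(values = values, samples = sample_tab,
                 genes = probe_map$gene_symbol, probe_map = probe_map),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes, %d donor(s), values in [%.2f, %.2f]\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$donor_id)),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Intersect a risk-gene list with the background
#'
#' Symbols are whitespace-trimmed and upper-cased on both sides; the result
#' keeps the risk-list order.
#'
#' @param risk_list character vector of risk-gene symbols.
#' @param background character vector of background gene symbols.
#' @return character vector of interesting genes.
#' @export
intersect_risk_genes <- function(risk_list, background) {
  risk <- toupper(trimws(risk_list))
  bg <- toupper(trimws(background))
  out <- risk[risk %in% bg]
  out <- out[!duplicated(out)]
  if (!length(out)) stop("risk list and background genes are disjoint")
  out
}
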