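#' Spearman correlation with two-sided p
#'
#' Average-rank Spearman r; two-sided p from the t approximation
#' t = r sqrt((n - 2) / (1 - r^2)) on n - 2 df.  |r| = 1 yields the
#' smallest representable positive p so p stays in (0, 1].
#'
#' @param x,y aligned numeric vectors, length >= 3.
#' @return list with \code{r} and \code{p}.
#' @export
spearman_rp <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  r <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * stats::pt(-abs(tval), n - 2), .Machine$double.xmin)
  }
  list(r = r, p = p)
}

#' Bonferroni per-test threshold
#'
#' @param alpha familywise alpha.
#' @param n_tests family size.
#' @return the per-test threshold alpha / n_tests; comparisons against it
#'   are strict (p < threshold).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Gene-wise Spearman associations with regional t per contrast
#'
#' For each consistent gene and each contrast, the cross-sample Spearman
#' correlation between normalized expression and the regional t profile,
#' with Bonferroni significance flags over the gene family.
#'
#' @param expr an \code{expression_matrix} (or samples x genes matrix with
#'   gene column names).
#' @param profiles named list of \code{regional_profile} data.frames, one
#'   per contrast; joined to expression rows by sample order of
#'   \code{sample_id} when \code{expr} is an \code{expression_matrix}.
#' @param genes genes to test (default: all columns).
#' @param alpha familywise alpha.
#' @param n_tests Bonferroni family size; defaults to the number of genes
#'   tested.
#' @return Object of class \code{gene_association_table}: data.frame with
#'   gene, then r/p/significant per contrast; attributes \code{alpha},
#'   \code{n_tests}, \code{threshold}.
#' @export
gene_t_associations <- function(expr, profiles, genes = NULL, alpha = 0.05,
                                n_tests = NULL) {
  if (inherits(expr, "expression_matrix")) {
    values <- expr$values
    ids <- expr$samples$well_id
  } else {
    values <- as.matrix(expr)
    ids <- rownames(values)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  }
  if (is.null(genes)) genes <- colnames(values)
  stopifnot(all(genes %in% colnames(values)), is.list(profiles),
            length(profiles) >= 1, !is.null(names(profiles)))
  if (is.null(n_tests)) n_tests <- length(genes)
  thr <- bonferroni_threshold(alpha, n_tests)

  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cn in names(profiles)) {
    pr <- profiles[[cn]]
    m <- match(pr$sample_id, ids)
    if (any(is.na(m))) stop("profile sample_id not found in expression matrix")
    rs <- ps <- numeric(length(genes))
    for (i in seq_along(genes)) {
      sp <- spearman_rp(values[m, genes[i]], pr$t_mean)
      rs[i] <- sp$r
      ps[i] <- sp$p
    }
    out[[paste0(cn, "_r")]] <- rs
    out[[paste0(cn, "_p")]] <- ps
    out[[paste0(cn, "_significant")]] <- ps < thr
  }
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- n_tests
  attr(out, "threshold") <- thr
  class(out) <- c("gene_association_table", "data.frame")
  out
}

#' @export
print.gene_association_table <- function(x, ...) {
  cat(sprintf("Gene-wise Spearman associations (Bonferroni: alpha = %g over %d tests, p < %.3g)\n",
              attr(x, "alpha"), attr(x, "n_tests"), attr(x, "threshold")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
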