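#' Hypergeometric over-representation with kappa term clustering
#'
#' For each gene set, computes the upper-tail (cumulative) hypergeometric
#' p-value of the overlap with the query list over the background universe,
#' p = sum_{j >= k} C(K, j) C(N - K, n - j) / C(N, n), and the enrichment
#' factor (k / n) / (K / N).  Terms with overlap below \code{min_overlap}
#' or p at or above \code{alpha} are removed; survivors are sorted by
#' ascending p and clustered by Cohen's kappa similarity of their gene
#' memberships (see \code{\link{kappa_cluster}}), each cluster labeled by
#' its lowest-p member (ties: lexicographic term ID).
#'
#' @param query character vector of query genes (subset of background).
#' @param gene_sets named list of character vectors.
#' @param background character vector, the background gene universe.
#' @param alpha significance threshold on the hypergeometric p.
#' @param min_overlap minimum query-term overlap.
#' @param kappa_thr kappa threshold for term clustering.
#' @return Object of class \code{enrichment_result}: data.frame with term,
#'   k (overlap), K (term size in background), n (query size), N
#'   (background size), p, enrichment_factor, cluster, cluster_label.
#' @export
hypergeom_enrich <- function(query, gene_sets, background, alpha = 0.05,
                             min_overlap = 3L, kappa_thr = 0.3) {
  query <- unique(toupper(trimws(query)))
  background <- unique(toupper(trimws(background)))
  if (!length(query) || !length(background)) stop("empty query or background")
  if (!all(query %in% background))
    stop("query genes must be a subset of the background")
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))

  N <- length(background)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(tm) {
    members <- intersect(toupper(trimws(gene_sets[[tm]])), background)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               enrichment_factor = if (K > 0) (k / n) / (K / N) else 0,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$k >= min_overlap & tab$p < alpha, , drop = FALSE]
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab)) {
    memberships <- lapply(tab$term, function(tm) {
      intersect(toupper(trimws(gene_sets[[tm]])), background)
    })
    tab$cluster <- kappa_cluster(memberships, background, kappa_thr)
    lab <- vapply(sort(unique(tab$cluster)), function(cl) {
      sub <- tab[tab$cluster == cl, , drop = FALSE]
      sub$term[order(sub$p, sub$term)][1]
    }, character(1))
    tab$cluster_label <- lab[tab$cluster]
  } else {
    tab$cluster <- integer(0)
    tab$cluster_label <- character(0)
  }
  class(tab) <- c("enrichment_result", "data.frame")
  tab
}

#' Cohen's kappa between two membership vectors
#'
#' Chance-corrected agreement between two binary gene-membership
#' indicators over a background universe; absent-absent pairs count as
#' agreement.
#'
#' @param a,b logical vectors of equal length.
#' @return kappa in [-1, 1].
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Cluster terms by kappa similarity of gene memberships
#'
#' Pairwise Cohen's kappa over the background, average-linkage hierarchical
#' clustering on 1 - kappa, tree cut so that terms merged at similarity >=
#' \code{kappa_thr} share a cluster.
#'
#' @param memberships list of character vectors (term gene memberships).
#' @param background character vector, the gene universe.
#' @param kappa_thr kappa threshold.
#' @return integer vector of cluster labels, one per term.
#' @export
kappa_cluster <- function(memberships, background, kappa_thr = 0.3) {
  stopifnot(is.list(memberships), length(memberships) >= 1)
  m <- length(memberships)
  if (m == 1) return(1L)
  ind <- vapply(memberships, function(g) background %in% g,
                logical(length(background)))
  kap <- matrix(1, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      kap[i, j] <- kap[j, i] <- cohen_kappa(ind[, i], ind[, j])
    }
  }
  d <- stats::as.dist(1 - kap)
  hc <- stats::hclust(d, method = "average")
  as.integer(stats::cutree(hc, h = 1 - kappa_thr))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d surviving term(s)", nrow(x)))
  if (nrow(x)) cat(sprintf(" in %d cluster(s)", length(unique(x$cluster))))
  cat("\n")
  if (nrow(x)) print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
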