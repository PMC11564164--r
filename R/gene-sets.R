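#' Generate synthetic gene sets with one planted enriched term
#'
#' Builds \code{n_terms} gene sets over a background panel.  The first term
#' (\code{PLANTED_TERM}) is exactly the planted genes, so a query list
#' containing them is enriched by construction; remaining terms are random
#' draws.
#'
#' @param genes background gene symbols.
#' @param planted_term_genes genes of the planted term (subset of
#'   \code{genes}).
#' @param n_terms total number of terms (>= 1).
#' @param seed integer seed.
#' @param size_range min/max random-term size.
#' @return named list of character vectors (term -> genes).
#' @export
make_gene_sets <- function(genes, planted_term_genes, n_terms = 20L, seed = 1L,
                           size_range = c(5L, 25L)) {
  if (n_terms < 1L) stop("n_terms must be >= 1")
  if (!all(planted_term_genes %in% genes))
    stop("planted term genes must be a subset of the background genes")
  set.seed(seed)
  sets <- list(PLANTED_TERM = planted_term_genes)
  if (n_terms > 1L) {
    sizes <- sample(size_range[1]:min(size_range[2], length(genes)),
                    n_terms - 1L, replace = TRUE)
    for (i in seq_len(n_terms - 1L)) {
      sets[[sprintf("TERM%03d", i)]] <- sample(genes, sizes[i])
    }
  }
  sets
}

#' Write gene sets as GMT
#'
#' Tab-separated: term, description, then member genes, one term per line.
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector (recycled; default
#'   \code{"na"}).
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- rep(descriptions, length.out = length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from GMT
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
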