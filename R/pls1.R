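#' First-component partial least squares with bootstrap gene ranking
#'
#' Fits the first PLS component of a single response on a gene-expression
#' matrix: predictors are z-scored per gene, the response is centered, and
#' the unit-norm weight vector maximizing cov(Xw, y) is the normalized
#' cross-covariance X'y / ||X'y||.  The component sign is oriented so that
#' the scores correlate positively with the response.  With
#' \code{n_boot > 0}, samples are resampled with replacement, the component
#' is refit per replicate and sign-aligned to the full-data weights (PLS
#' components are sign-indeterminate), and each gene's Z score is its
#' full-data weight divided by the bootstrap SD of that weight.  Genes with
#' Z beyond \code{±z_thr} form the positive / negative gene lists.
#'
#' @param X numeric matrix, samples x genes (column names = gene symbols).
#' @param y numeric response (regional t profile), length \code{nrow(X)}.
#' @param n_boot bootstrap replicates (0 = no bootstrap; >= 100 otherwise).
#' @param z_thr absolute Z threshold for the signed gene lists.
#' @param seed integer seed for the bootstrap.
#' @return Object of class \code{pls1}: \code{weights} (unit norm),
#'   \code{scores}, \code{y}, \code{r} (Spearman of scores vs y),
#'   \code{center}/\code{scale} (per-gene standardization), and - when
#'   bootstrapped - \code{se}, \code{z}, \code{pos_genes},
#'   \code{neg_genes}.
#' @export
pls1 <- function(X, y, n_boot = 0L, z_thr = 5, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 3)
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%03d", seq_len(ncol(X)))
  if (stats::sd(y) == 0) stop("constant response")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant gene column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (n_boot > 0 && n_boot < 100) stop("n_boot must be 0 or >= 100")

  fit <- pls1_core(X, y)
  out <- structure(list(weights = fit$w, scores = fit$scores, y = y,
                        center = colMeans(X), scale = apply(X, 2, stats::sd),
                        r = stats::cor(fit$scores, y, method = "spearman"),
                        genes = colnames(X), n = nrow(X),
                        n_boot = n_boot, z_thr = z_thr,
                        call = match.call()),
                   class = "pls1")

  if (n_boot > 0) {
    set.seed(seed)
    W <- matrix(NA_real_, n_boot, ncol(X))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      wb <- pls1_core(X[idx, , drop = FALSE], y[idx], orient_to = fit$w)$w
      W[b, ] <- wb
    }
    se <- apply(W, 2, stats::sd)
    z <- fit$w / se
    bad <- se == 0 | !is.finite(z)
    if (any(bad)) {
      warning("zero bootstrap SE; excluding gene(s) from lists: ",
              paste(colnames(X)[bad], collapse = ", "))
      z[bad] <- NA_real_
    }
    names(z) <- names(se) <- colnames(X)
    pos <- colnames(X)[!is.na(z) & z > z_thr]
    neg <- colnames(X)[!is.na(z) & z < -z_thr]
    out$se <- se
    out$z <- z
    out$pos_genes <- pos[order(-z[pos])]
    out$neg_genes <- neg[order(z[neg])]
  }
  out
}

# Core single-response first PLS component on standardized X, centered y.
# With orient_to = NULL, orients scores to correlate positively with y;
# otherwise aligns the weight vector's sign with orient_to (maximal dot
# product), resolving the per-replicate sign ambiguity.
pls1_core <- function(X, y, orient_to = NULL) {
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  sds[sds == 0] <- Inf                       # degenerate resample: weight 0
  Xs <- sweep(sweep(X, 2, mu), 2, sds, `/`)
  yc <- y - mean(y)
  cvec <- as.numeric(crossprod(Xs, yc))
  nrm <- sqrt(sum(cvec^2))
  if (nrm == 0) {
    w <- rep(0, ncol(X))
  } else {
    w <- cvec / nrm
  }
  scores <- as.numeric(Xs %*% w)
  flip <- if (is.null(orient_to)) {
    sum(scores * yc) < 0
  } else {
    sum(w * orient_to) < 0
  }
  if (flip) {
    w <- -w
    scores <- -scores
  }
  list(w = stats::setNames(w, colnames(X)), scores = scores)
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("<pls1> %d samples x %d genes; Spearman(scores, y) = %.3f\n",
              x$n, length(x$genes), x$r))
  if (!is.null(x$z)) {
    cat(sprintf("  bootstrap n = %d, |Z| > %g: %d positive, %d negative\n",
                x$n_boot, x$z_thr, length(x$pos_genes), length(x$neg_genes)))
  }
  invisible(x)
}

#' @export
summary.pls1 <- function(object, ...) {
  tab <- data.frame(gene = object$genes, weight = unname(object$weights),
                    stringsAsFactors = FALSE)
  if (!is.null(object$z)) {
    tab$se <- unname(object$se)
    tab$z <- unname(object$z)
    tab$list <- ifelse(tab$gene %in% object$pos_genes, "positive",
                       ifelse(tab$gene %in% object$neg_genes, "negative", ""))
    tab <- tab[order(-tab$z), , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(list(table = tab, r = object$r, n = object$n,
                 n_boot = object$n_boot), class = "summary.pls1")
}

#' @export
print.summary.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 fit: n = %d, Spearman(scores, y) = %.3f\n", x$n, x$r))
  print(utils::head(x$table, 15), digits = 3)
  if (nrow(x$table) > 15) cat("  ...", nrow(x$table) - 15, "more genes\n")
  invisible(x)
}

#' @export
coef.pls1 <- function(object, type = c("weights", "z"), ...) {
  type <- match.arg(type)
  if (type == "z") {
    if (is.null(object$z)) stop("fit has no bootstrap Z scores")
    object$z
  } else object$weights
}

#' @export
predict.pls1 <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  newdata <- as.matrix(newdata)[, object$genes, drop = FALSE]
  # reuse the training standardization so scores are comparable
  as.numeric(sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`) %*%
               object$weights)
}

#' @export
fitted.pls1 <- function(object, ...) {
  stats::fitted(stats::lm(object$y ~ object$scores))
}

#' @export
residuals.pls1 <- function(object, ...) {
  stats::residuals(stats::lm(object$y ~ object$scores))
}

#' @export
plot.pls1 <- function(x, ...) {
  graphics::plot(x$scores, x$y, xlab = "PLS1 score",
                 ylab = "regional t", pch = 16, col = "#00000080", ...)
  graphics::abline(stats::lm(x$y ~ x$scores), col = "firebrick")
  graphics::mtext(sprintf("Spearman r = %.3f", x$r), side = 3, line = 0.2,
                  cex = 0.9)
  invisible(x)
}

#' Intersect signed gene lists across contrasts
#'
#' Set intersection preserving the first list's order; an empty result is
#' allowed.
#'
#' @param lists list (length >= 2) of character vectors.
#' @return character vector of consistent genes.
#' @export
intersect_gene_lists <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2)
  Reduce(intersect, lists)
}

#' Spearman correlation between PLS1 scores and the regional profile
#'
#' Average-rank Spearman r with a two-sided p from the t approximation.
#'
#' @param scores,y aligned numeric vectors (length >= 3).
#' @return list with \code{r} and \code{p}.
#' @export
pls_score_correlation <- function(scores, y) {
  spearman_rp(scores, y)
}
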