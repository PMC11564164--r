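test_that("PLS1 weights equal the single-response cross-covariance closed form", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(50 * 10), 50, 10,
                dimnames = list(NULL, sprintf("g%02d", 1:10)))
    y <- rnorm(50)
    fit <- pls1(X, y)
    cvec <- crossprod(scale(X), y - mean(y))[, 1]
    w <- cvec / sqrt(sum(cvec^2))
    if (cor(as.numeric(scale(X) %*% w), y) < 0) w <- -w
    expect_equal(unname(fit$weights), unname(w), tolerance = 1e-8)
    expect_equal(sum(fit$weights^2), 1, tolerance = 1e-12)
    expect_gte(cor(fit$scores, y), 0)
  }
})

test_that("PLS1 agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(5)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("g", 1:8)))
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(60)
  fit <- pls1(X, y)
  ref <- mixOmics::pls(X, y, ncomp = 1, mode = "regression", scale = TRUE)
  wref <- ref$loadings$X[, 1]
  expect_equal(abs(sum(fit$weights * wref) / sqrt(sum(wref^2))), 1,
               tolerance = 1e-6)
})

test_that("a single predictor maps monotonically to the scores", {
  set.seed(1)
  g <- rnorm(30)
  y <- 2 * g + rnorm(30, sd = 0.1)
  fit <- pls1(matrix(g, dimnames = list(NULL, "G")), y)
  expect_equal(cor(fit$scores, g, method = "spearman"), 1)
})

test_that("duplicated genes earn equal Z scores up to Monte-Carlo noise", {
  set.seed(2)
  g <- rnorm(100)
  X <- cbind(a = g, b = g, c = rnorm(100))
  y <- g + rnorm(100)
  fit <- pls1(X, y, n_boot = 1000, seed = 3)
  expect_equal(unname(fit$weights["a"]), unname(fit$weights["b"]))
  expect_lt(abs(fit$z["a"] - fit$z["b"]), 0.5)
})

test_that("negating the response flips weights, Z scores and lists exactly", {
  set.seed(4)
  X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- X[, 2] * 2 + rnorm(80, sd = 0.3)
  up <- pls1(X, y, n_boot = 200, z_thr = 3, seed = 9)
  dn <- pls1(X, -y, n_boot = 200, z_thr = 3, seed = 9)
  expect_equal(dn$weights, -up$weights)
  expect_equal(dn$z, -up$z)
  expect_equal(dn$pos_genes, up$neg_genes)
  expect_equal(dn$neg_genes, up$pos_genes)
})

test_that("gene order and response scale do not affect Z", {
  set.seed(6)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- rowSums(X[, 1:2]) + rnorm(60)
  fit <- pls1(X, y, n_boot = 150, seed = 2)
  perm <- c(4, 1, 5, 2, 3)
  fit_p <- pls1(X[, perm], y, n_boot = 150, seed = 2)
  expect_equal(fit_p$z, fit$z[perm])
  fit_s <- pls1(X, 7 * y, n_boot = 150, seed = 2)
  expect_equal(fit_s$z, fit$z, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or dropped with a warning", {
  set.seed(7)
  X <- cbind(g1 = rnorm(20), g2 = rep(1, 20))
  expect_warning(fit <- pls1(X, rnorm(20)), "constant gene")
  expect_equal(fit$genes, "g1")
  expect_error(pls1(matrix(rnorm(20), 20), rep(2, 20)), "constant response")
  expect_error(pls1(matrix(rnorm(10), 5), rnorm(5), n_boot = 50), "n_boot")
})

test_that("gene-list intersection preserves first-list order", {
  expect_equal(intersect_gene_lists(list(c("A", "B", "C"), c("B", "C", "D"),
                                         c("C", "B"))), c("B", "C"))
  expect_equal(intersect_gene_lists(list(c("X", "Y"), c("X", "Y"))), c("X", "Y"))
  expect_length(intersect_gene_lists(list("A", "B")), 0L)
})

test_that("score-profile Spearman handles ties and monotone inputs", {
  expect_equal(pls_score_correlation(1:6, c(2, 4, 6, 8, 10, 12))$r, 1)
  expect_equal(pls_score_correlation(1:6, -(1:6))$r, -1)
  sp <- pls_score_correlation(c(1, 2, 2, 3), c(1, 3, 2, 4))
  expect_equal(sp$r, 0.9487, tolerance = 1e-4)
})

test_that("pls1 methods expose the fit coherently", {
  set.seed(8)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- X[, 1] + rnorm(40)
  fit <- pls1(X, y, n_boot = 100, seed = 1)
  expect_equal(coef(fit), fit$weights)
  expect_equal(coef(fit, type = "z"), fit$z)
  expect_equal(predict(fit), fit$scores)
  expect_equal(predict(fit, X), fit$scores, tolerance = 1e-10)
  expect_equal(fitted(fit) + residuals(fit), y, ignore_attr = TRUE)
  s <- summary(fit)
  expect_setequal(s$table$gene, colnames(X))
  expect_output(print(fit), "pls1")
})
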