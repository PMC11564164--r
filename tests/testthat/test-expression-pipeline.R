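test_that("background filter keeps probes present in at least half the samples", {
  pa <- rbind(P1 = c(1, 1, 1, 0, 0),    # 3/5 -> retained
              P2 = c(1, 1, 0, 0, 0),    # 2/5 -> removed
              P3 = c(1, 1, 1, 1, 1))    # everywhere -> retained at any cut
  expect_equal(filter_probes_by_background(pa), c("P1", "P3"))
  expect_true("P3" %in% filter_probes_by_background(pa, min_fraction = 1))
  expect_equal(formals(filter_probes_by_background)$min_fraction, 0.5)
  expect_error(filter_probes_by_background(pa[0, ]), "empty")
  expect_error(filter_probes_by_background(pa * 2), "binary")
})

test_that("probe selection picks the probe most correlated with RNA-seq", {
  set.seed(1)
  ref <- rnorm(40)
  wells <- sprintf("W%02d", 1:40)
  expr <- rbind(P1 = 0.9 * ref + sqrt(1 - 0.81) * rnorm(40),
                P2 = 0.2 * ref + sqrt(1 - 0.04) * rnorm(40),
                P3 = ref + 0.1 * rnorm(40),
                P4 = rnorm(40))
  colnames(expr) <- wells
  probes <- data.frame(probe_id = c("P1", "P2", "P3", "P4"),
                       gene_symbol = c("GA", "GA", "GB", "GC"),
                       stringsAsFactors = FALSE)
  rnaseq <- cbind(data.frame(gene_symbol = c("GA", "GB")),
                  as.data.frame(rbind(ref, ref)))
  names(rnaseq)[-1] <- wells
  sel <- select_probes_by_rnaseq(expr, probes, rnaseq)
  expect_equal(sel$probe_id[sel$gene_symbol == "GA"], "P1")  # 0.9 beats 0.2
  expect_equal(sel$probe_id[sel$gene_symbol == "GB"], "P3")  # single probe
  expect_false("GC" %in% sel$gene_symbol)   # no RNA-seq entry -> dropped
})

test_that("left-hemisphere rule is strict and rejects missing coordinates", {
  s <- data.frame(well_id = c("a", "b", "c", "d"),
                  mni_x = c(-30, 30, 0, NA), stringsAsFactors = FALSE)
  expect_warning(kept <- filter_left_hemisphere(s), "missing")
  expect_equal(kept, "a")                    # +30 and the x = 0 midline excluded
})

test_that("scaled robust sigmoid maps the median to 0.5 and preserves ranks", {
  set.seed(2)
  x <- rnorm(51, mean = 4, sd = 2)
  s <- scaled_robust_sigmoid(x)
  expect_equal(s[which(x == median(x))], 0.5)
  expect_equal(rank(s), rank(x))
  expect_true(all(s > 0 & s < 1))
  expect_message(u <- scaled_robust_sigmoid(rep(3, 5)), "zero IQR")
  expect_true(all(u > 0 & u < 1))
})

test_that("normalization is location-scale invariant and rank-idempotent", {
  set.seed(3)
  m1 <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(paste0("G", 1:5), NULL))
  m2 <- 2.5 * m1 + 7                         # same donor data, affine-shifted
  out <- normalize_expression(list(m1, m2))
  expect_equal(out[1:30, ], out[31:60, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(out >= 0 & out <= 1))
  # re-running SRS on SRS output preserves within-donor gene ranks
  again <- normalize_expression(list(t(out[1:30, ])))
  for (g in 1:5) expect_equal(rank(again[, g]), rank(out[1:30, g]))
})

test_that("the assembled matrix is order-stable under sample permutation", {
  donors <- tiny_donor_set()
  wells <- donors[[1]]$samples$well_id
  rnaseq <- cbind(data.frame(gene_symbol = c("G1", "G2")),
                  as.data.frame(matrix(rnorm(2 * 12), 2)))
  names(rnaseq)[-1] <- c(wells, donors[[2]]$samples$well_id)
  em1 <- build_expression_matrix(donors, rnaseq)

  perm <- c(3, 1, 6, 2, 5, 4)
  d1 <- donors[[1]]
  d1$expr <- d1$expr[, perm]
  d1$pa <- d1$pa[, perm]
  d1$samples <- d1$samples[perm, ]
  em2 <- build_expression_matrix(list(d1, donors[[2]]), rnaseq)
  m <- match(em1$samples$well_id, em2$samples$well_id)
  expect_equal(em2$values[m, ], em1$values, ignore_attr = TRUE)
})

test_that("risk-gene intersection mirrors the 52 -> 41 reduction", {
  risk <- default_risk_genes()
  expect_length(risk, 52L)
  bg <- background_gene_panel(100)
  interesting <- intersect_risk_genes(risk, bg)
  expect_length(interesting, 41L)
  expect_equal(interesting, risk[1:41])      # risk-list order preserved
  expect_equal(intersect_risk_genes(c(" apoe ", "CD33"), c("APOE", "CD33", "X")),
               c("APOE", "CD33"))            # case/whitespace robust, identity
  expect_error(intersect_risk_genes(c("AA"), c("BB")), "disjoint")
})
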