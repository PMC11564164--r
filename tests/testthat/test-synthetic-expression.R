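ref_field <- function(seed = 4) {
  co <- small_cohort(seed = seed, n = 2, grid = c(20L, 24L, 20L))
  effect_field(co, "B")
}

test_that("unplanted genes show no spatial association", {
  spec <- expression_spec(n_samples_left = 300,
                          genes = background_gene_panel(50),
                          planted = data.frame(gene = character(),
                                               rho = numeric()),
                          seed = 2)
  ex <- make_expression(spec, ref_field())
  em <- build_expression_matrix(ex$donors, ex$rnaseq)
  z <- ex$truth$field_z[match(em$samples$well_id, ex$truth$well_id)]
  rs <- apply(em$values, 2, function(g) cor(g, z, method = "spearman"))
  expect_lt(abs(median(rs)), 0.05)
})

test_that("a planted rho = 0.5 is recovered within the Fisher-z 99% interval", {
  spec <- expression_spec(n_samples_left = 1000,
                          genes = background_gene_panel(45),
                          planted = data.frame(gene = "ABCA7", rho = 0.5),
                          seed = 3)
  ex <- make_expression(spec, ref_field())
  em <- build_expression_matrix(ex$donors, ex$rnaseq)
  z <- ex$truth$field_z[match(em$samples$well_id, ex$truth$well_id)]
  r <- cor(em$values[, "ABCA7"], z, method = "spearman")
  expect_gt(r, 0.35)
  expect_lt(r, 0.65)
})

test_that("samples cover both hemispheres and about half survive left filtering", {
  spec <- expression_spec(n_samples_left = 400, genes = background_gene_panel(42),
                          seed = 5)
  ex <- make_expression(spec, ref_field())
  xs <- unlist(lapply(ex$donors, function(d) d$samples$mni_x))
  expect_equal(length(xs), 800L)
  n_left <- sum(xs < 0)
  expect_lt(abs(n_left - 400), 4 * sqrt(800 * 0.25))   # binomial expectation
  expect_gt(sum(xs > 0), 0)
})

test_that("probe tiers exercise background filtering and RNA-seq selection", {
  spec <- expression_spec(n_samples_left = 300, genes = background_gene_panel(50),
                          probes_per_gene = 3, seed = 6)
  ex <- make_expression(spec, ref_field())
  pa_all <- do.call(cbind, lapply(ex$donors, `[[`, "pa"))
  kept <- filter_probes_by_background(pa_all)
  tier <- (match(kept, ex$donors[[1]]$probes$probe_id) - 1) %% 3 + 1
  expect_true(all(tier < 3))                  # junk tier removed ...
  expect_equal(sum(tier == 1), 50L)           # ... every high-fidelity kept
  expr_all <- do.call(cbind, lapply(ex$donors, `[[`, "expr"))
  sel <- select_probes_by_rnaseq(expr_all[kept, ], ex$donors[[1]]$probes,
                                 ex$rnaseq)
  sel_tier <- (match(sel$probe_id, ex$donors[[1]]$probes$probe_id) - 1) %% 3 + 1
  expect_gte(mean(sel_tier == 1), 0.95)       # high-fidelity probe wins
})

test_that("expression generation is seed-deterministic and validates input", {
  f <- ref_field()
  spec <- expression_spec(n_samples_left = 60, genes = background_gene_panel(42),
                          seed = 9)
  a <- make_expression(spec, f)
  b <- make_expression(spec, f)
  expect_identical(a$donors[[1]]$expr, b$donors[[1]]$expr)
  expect_identical(a$truth$coords, b$truth$coords)
  expect_error(
    expression_spec(planted = data.frame(gene = "NOSUCHGENE", rho = 0.2)),
    "not in the gene panel")
  expect_error(
    expression_spec(planted = data.frame(gene = "APOE", rho = 1.2)),
    "in \\(-1, 1\\)")
})

test_that("donor files round-trip through the AHBA-dialect CSV layout", {
  spec <- expression_spec(n_samples_left = 40, genes = background_gene_panel(42),
                          seed = 10)
  ex <- make_expression(spec, ref_field())
  d <- tempfile("donors")
  write_donor_files(ex, d)
  back <- read_ahba_donors(d)
  expect_length(back, 6L)
  i <- which(vapply(back, `[[`, "", "donor_id") == ex$donors[[1]]$donor_id)
  expect_equal(back[[i]]$expr, ex$donors[[1]]$expr, tolerance = 1e-6)
  expect_equal(back[[i]]$pa, ex$donors[[1]]$pa, ignore_attr = TRUE)
  expect_equal(back[[i]]$samples$mni_x, ex$donors[[1]]$samples$mni_x,
               tolerance = 1e-6)
  rn <- read_rnaseq_reference(file.path(d, "rnaseq_reference.tsv"))
  expect_equal(rn$gene_symbol, ex$rnaseq$gene_symbol)
})

test_that("synthetic gene sets plant one maximally enriched term", {
  genes <- sprintf("G%02d", 1:20)
  sets <- make_gene_sets(genes, planted_term_genes = genes[1:6], n_terms = 10,
                         seed = 1, size_range = c(4L, 10L))
  expect_equal(sets$PLANTED_TERM, genes[1:6])
  expect_length(sets, 10L)
  res <- hypergeom_enrich(genes[1:6], sets, genes, alpha = 1, min_overlap = 1)
  expect_equal(res$term[1], "PLANTED_TERM")   # minimum p among all terms
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(lengths(back)[names(sets)], lengths(sets))
  expect_error(make_gene_sets(genes, genes[1:2], n_terms = 0), "n_terms")
  expect_error(make_gene_sets(genes, c("ZZ"), n_terms = 3), "subset")
})
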