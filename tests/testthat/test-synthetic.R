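test_that("generated instances have the requested shape and a connected planted module", {
  spec <- synthetic_spec(n_genes = 300, n_per_group = 60, planted_size = 10,
                         effect = 1.5, rng_seed = 7)
  inst <- generate_instance(spec)
  expect_equal(dim(inst$expr), c(300, 120))
  expect_equal(nrow(inst$labels), 120)
  expect_length(inst$truth$planted_genes, 10)
  sub <- igraph::induced_subgraph(inst$net, inst$truth$planted_genes)
  expect_true(igraph::is_connected(sub))
  # connectivity holds across seeds
  for (s in 1:5) {
    i2 <- generate_instance(synthetic_spec(n_genes = 100, n_per_group = 10,
                                           planted_size = 6, rng_seed = s))
    expect_true(igraph::is_connected(
      igraph::induced_subgraph(i2$net, i2$truth$planted_genes)))
  }
})

test_that("instances are deterministic given the seed", {
  a <- generate_instance(synthetic_spec(rng_seed = 123))
  b <- generate_instance(synthetic_spec(rng_seed = 123))
  expect_identical(a$expr, b$expr)
  expect_identical(igraph::as_edgelist(a$net), igraph::as_edgelist(b$net))
  expect_identical(a$catalogue, b$catalogue)
  expect_identical(a$truth, b$truth)
  c <- generate_instance(synthetic_spec(rng_seed = 124))
  expect_false(identical(a$expr, c$expr))
})

test_that("the planted module separates groups as the effect size predicts", {
  inst <- generate_instance(synthetic_spec(rng_seed = 7))
  d <- disa(zscore_rows(inst$expr), inst$labels, inst$truth$planted_genes)
  # k genes shifted by `effect`: activity gap effect*sqrt(k) = 4.74 SDs
  expect_lt(d, 0.05)
  # empirical disa decreases with effect (median over repeats)
  med <- vapply(c(0.5, 1.0, 1.5, 2.0), function(eff) {
    median(vapply(1:8, function(s) {
      i <- generate_instance(synthetic_spec(n_genes = 100, n_per_group = 30,
                                            planted_size = 8, effect = eff,
                                            rng_seed = s))
      disa(zscore_rows(i$expr), i$labels, i$truth$planted_genes)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("null instances carry no signal", {
  null <- generate_null_instance(synthetic_spec(rng_seed = 17))
  expect_true(all(null$expr[null$truth$planted_genes, ] < 10)) # no shift applied
  res <- gene_t_tests(zscore_rows(null$expr), null$labels)
  frac <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(null$expr))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("background pathways overlap the planted module as configured", {
  inst <- generate_instance(synthetic_spec(rng_seed = 5))
  expect_length(inst$background, 10)
  expect_true(all(names(inst$background) %in% names(inst$catalogue)))
  frac_planted <- vapply(inst$background, function(s)
    mean(s %in% inst$truth$planted_genes), numeric(1))
  expect_gte(sum(frac_planted >= 0.5), ceiling(0.5 * 10))
})

test_that("instances round-trip through the pipeline file formats", {
  inst <- generate_instance(synthetic_spec(n_genes = 50, n_per_group = 8,
                                           planted_size = 5, rng_seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_instance(inst, dir)
  expect_equal(read_expression(paths["expression"]), inst$expr)
  expect_equal(read_phenotypes(paths["phenotypes"]), inst$labels)
  net <- read_network(paths["network"])
  expect_equal(igraph::ecount(net), igraph::ecount(inst$net))
  gs <- read_gene_sets(paths["catalogue"])
  expect_equal(lapply(gs, sort), lapply(inst$catalogue, sort))
})
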