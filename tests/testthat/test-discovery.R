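test_that("growth from an isolated seed returns the bare seed", {
  toy <- toy_dataset(n_genes = 4, n_per_group = 5, shift_genes = "g1",
                     shift = 3)
  net <- ppi_network(cbind("g2", "g3"), nodes = c("g1", "g4"))
  mod <- grow_module("g1", net, toy$expr, toy$labels)
  expect_s3_class(mod, "disa_module")
  expect_equal(mod$members, "g1")
  expect_equal(nrow(mod$trace), 0)
  expect_error(grow_module("nope", net, toy$expr, toy$labels), "nope")
})

test_that("the first greedy addition is the exhaustive single-addition argmin", {
  # star around the seed: exactly one neighbour carries group-shifted signal
  toy <- toy_dataset(n_genes = 5, n_per_group = 25,
                     shift_genes = c("g1", "g3"), shift = 2.5, seed = 8)
  net <- ppi_network(cbind("g1", c("g2", "g3", "g4", "g5")))
  mod <- grow_module("g1", net, toy$expr, toy$labels)
  cand_disa <- vapply(paste0("g", 2:5), function(g)
    disa(toy$expr, toy$labels, c("g1", g)), numeric(1))
  expect_equal(mod$trace$gene[1], "g3")
  expect_equal(names(which.min(cand_disa)), "g3")
  expect_equal(mod$trace$disa[1], unname(min(cand_disa)), tolerance = 1e-12)
})

test_that("accepted disa values strictly decrease and members stay connected", {
  inst <- generate_instance(synthetic_spec(n_genes = 80, n_per_group = 20,
                                           planted_size = 6, rng_seed = 31))
  expr <- zscore_rows(inst$expr)
  mod <- grow_module(inst$truth$planted_genes[1], inst$net, expr, inst$labels)
  seq_disa <- c(mod$seed_disa, mod$trace$disa)
  expect_true(all(diff(seq_disa) < 0))
  expect_equal(mod$disa, disa(expr, inst$labels, mod$members), tolerance = 1e-12)
  sub <- igraph::induced_subgraph(inst$net, mod$members)
  expect_true(igraph::is_connected(sub))
})

test_that("growth is deterministic and respects the size cap", {
  inst <- generate_instance(synthetic_spec(n_genes = 80, n_per_group = 20,
                                           planted_size = 6, rng_seed = 32))
  expr <- zscore_rows(inst$expr)
  seed <- inst$truth$planted_genes[1]
  m1 <- grow_module(seed, inst$net, expr, inst$labels)
  m2 <- grow_module(seed, inst$net, expr, inst$labels)
  expect_identical(m1$members, m2$members)
  capped <- grow_module(seed, inst$net, expr, inst$labels,
                        discovery_config(max_module_size = 3))
  expect_lte(length(capped$members), 3)
})

test_that("module discovery filters by disa, sorts, and deduplicates seeds", {
  inst <- generate_instance(synthetic_spec(n_genes = 120, n_per_group = 30,
                                           planted_size = 6, rng_seed = 33))
  expr <- zscore_rows(inst$expr)
  seeds <- c(inst$truth$planted_genes[1:3], inst$truth$planted_genes[1])
  mods <- discover_modules(seeds, inst$net, expr, inst$labels,
                           discovery_config(disa_filter = 1))
  expect_equal(nrow(mods), 3) # duplicate seed collapsed
  expect_true(all(diff(mods$disa) >= 0))
  expect_true(all(vapply(mods$members, function(m)
    igraph::is_connected(igraph::induced_subgraph(inst$net, m)), logical(1))))
  strict <- discover_modules(seeds, inst$net, expr, inst$labels,
                             discovery_config(disa_filter = 0.2))
  expect_true(all(strict$disa <= 0.2))
  expect_error(discover_modules(character(0), inst$net, expr, inst$labels),
               "non-empty")
})

test_that("activity correlations form a symmetric matrix with unit diagonal", {
  inst <- generate_instance(synthetic_spec(n_genes = 120, n_per_group = 30,
                                           planted_size = 6, rng_seed = 34))
  expr <- zscore_rows(inst$expr)
  mods <- discover_modules(inst$truth$planted_genes[1:3], inst$net, expr,
                           inst$labels, discovery_config(disa_filter = 1))
  cc <- activity_correlations(mods, expr)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, nrow(mods)))

  # single-gene module pair against a hand Pearson computation
  v <- c(1, 2, 3, 4); w <- c(1, 2, 3, 100)
  e2 <- rbind(a = v, b = w, c = -v)
  colnames(e2) <- paste0("s", 1:4)
  pair <- tibble::tibble(module_id = c("Ma", "Mb", "Mc"),
                         members = list("a", "b", "c"))
  cc2 <- activity_correlations(pair, e2)
  hand_r <- sum((v - mean(v)) * (w - mean(w))) /
    sqrt(sum((v - mean(v))^2) * sum((w - mean(w))^2))
  expect_equal(cc2["Ma", "Mb"], hand_r, tolerance = 1e-12)
  expect_equal(cc2["Ma", "Mc"], -1)
})

test_that("discovery config rejects inconsistent thresholds", {
  expect_error(discovery_config(delta = 0.3, disa_filter = 0.2), "delta")
  expect_error(discovery_config(disa_filter = 1.5), "delta")
})
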