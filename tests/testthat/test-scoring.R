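test_that("hypergeometric enrichment matches the combinatorial formula", {
  uni <- paste0("u", 1:10)
  pathway <- uni[1:5]
  mod <- uni[1:4]
  r <- enrichment_test(mod, pathway, uni)
  expect_equal(r$overlap_s, 4)
  expect_equal(r$p_value, 5 / 210, tolerance = 1e-14)

  # no overlap -> p exactly 1
  expect_equal(enrichment_test(uni[6:8], uni[1:3], uni)$p_value, 1)
  # pathway covering the whole universe -> overlap forced, p = 1
  expect_equal(enrichment_test(mod, uni, uni)$p_value, 1, tolerance = 1e-12)
  expect_error(enrichment_test(c(mod, "zz"), pathway, uni), "subset")
})

test_that("enrichment over a catalogue adjusts across pathways and defines MF", {
  uni <- paste0("u", 1:60)
  catalogue <- pathway_collection(list(hit = uni[1:6],
                                       miss1 = uni[c(6, 21:29)],
                                       miss2 = uni[c(5, 31:39)]))
  mod <- uni[1:6]
  tab <- enrichment_table(mod, catalogue, uni)
  expect_equal(tab$p_adjusted, adjust_bh(tab$p_value))
  mf <- enriched_pathways(mod, catalogue, uni, alpha_enrich = 0.05)
  expect_equal(names(mf), "hit")

  none <- enriched_pathways(paste0("u", 41:45),
                            pathway_collection(list(p = uni[1:6])), uni)
  expect_length(none, 0)
  wide <- enriched_pathways(mod, catalogue, uni, alpha_enrich = 0.999)
  expect_length(wide, 3)
  expect_error(enriched_pathways(mod, pathway_collection(list()), uni),
               "Empty")
})

test_that("Jaccard and bidirectional best-match similarity follow their formulas", {
  expect_equal(set_jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(set_jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(set_jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_error(set_jaccard(character(0), character(0)), "empty")

  ps1 <- pathway_collection(list(A = c("a", "b")))
  ps2 <- pathway_collection(list(A = c("a", "b"), B = "c"))
  expect_equal(pathway_set_similarity(ps1, ps2), 2 / 3)
  expect_equal(pathway_set_similarity(ps1, ps1), 1)
  disjoint <- pathway_collection(list(X = "z1", Y = "z2"))
  expect_equal(pathway_set_similarity(ps1, disjoint), 0)
  expect_warning(s0 <- pathway_set_similarity(ps1, pathway_collection(list())),
                 "Empty")
  expect_equal(s0, 0)
})

test_that("similarity is symmetric and agrees with brute force on random pairs", {
  genes <- paste0("g", 1:15)
  withr::with_seed(21, {
    for (i in 1:40) {
      a <- random_collection(sample(1:5, 1), genes)
      b <- random_collection(sample(1:5, 1), genes)
      s <- pathway_set_similarity(a, b)
      expect_equal(s, pathway_set_similarity(b, a), tolerance = 1e-14)
      expect_equal(s, sim_oracle(a, b), tolerance = 1e-12)
      # invariant to catalogue ordering
      expect_equal(s, pathway_set_similarity(a[rev(seq_along(a))], b),
                   tolerance = 1e-14)
    }
  })
})

test_that("module scoring ranks disease-annotated modules first", {
  uni <- paste0("u", 1:80)
  catalogue <- pathway_collection(list(
    dm1 = uni[1:8], dm2 = uni[c(1:4, 9:12)], other1 = uni[41:48],
    other2 = uni[51:58]))
  background <- catalogue[c("dm1", "dm2")]
  modules <- tibble::tibble(
    module_id = c("M_a", "M_b"),
    seed = c("u1", "u41"),
    size = c(6L, 6L),
    disa = c(0.05, 0.04),
    members = list(uni[1:6], uni[41:46]),
    trace = list(NULL, NULL))
  ranked <- score_modules(modules, catalogue, background, uni)
  expect_equal(ranked$module_id[1], "M_a")
  expect_gt(ranked$score[1], ranked$score[2])
  expect_true(all(ranked$score >= 0 & ranked$score <= 1))
  expect_equal(ranked$enriched_pathways[[1]], c("dm1", "dm2"))

  # identical modules tie and fall back to disa then seed order
  dup <- modules
  dup$members <- list(uni[1:6], uni[1:6])
  rd <- score_modules(dup, catalogue, background, uni)
  expect_equal(rd$score[1], rd$score[2])
  expect_equal(rd$module_id[1], "M_b") # smaller disa wins the tie
  # score invariant to member ordering
  shuf <- modules
  shuf$members <- lapply(shuf$members, rev)
  expect_equal(score_modules(shuf, catalogue, background, uni)$score,
               ranked$score)
})
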