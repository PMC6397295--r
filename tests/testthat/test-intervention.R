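test_that("intervention actions follow the stated arithmetic", {
  expr <- matrix(c(0.7, 0.6, 0.2), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  spec <- intervention_spec(c("g1", "g2", "g3"),
                            c("ko_hard", "ko_soft", "overexpress"))
  out <- apply_intervention(expr, spec, samples = "s1")
  expect_equal(unname(out[, "s1"]), c(0, 0.006, 1))
  expect_equal(out[, "s2"], expr[, "s2"])   # untouched sample

  sc <- apply_intervention(expr, intervention_spec("g1", "scale", 3))
  expect_equal(unname(sc["g1", ]), c(1, 1))  # clipped at 1
  st <- apply_intervention(expr, intervention_spec("g3", "set", 0.25))
  expect_equal(unname(st["g3", ]), c(0.25, 0.25))

  expect_error(apply_intervention(expr, spec, samples = character(0)),
               "empty sample")
  expect_error(intervention_spec(c("g1", "g1")), "listed twice")
  expect_warning(apply_intervention(expr, intervention_spec("nope")),
                 "absent")
})

test_that("ko_effect flags essential bridges and ignores absent genes", {
  ms <- module_set(list(make_chain(c("A", "B"), mid = "M1")))
  col <- c(gA = 1, gB = 1)
  # baseline activity 1; hard KO of the entry gene collapses it to ~0
  res <- ko_effect(ms, col, intervention_spec("gA", "ko_hard"))
  expect_equal(res$activity_before, 1)
  expect_equal(res$activity_after, 0)
  expect_true(res$flagged)
  expect_lt(res$fold_change, 1 / 2)

  # KO of a gene in no module: all fold changes exactly 1
  res2 <- ko_effect(ms, col, intervention_spec("zz", "ko_hard"))
  expect_equal(res2$fold_change, 1)
  expect_false(res2$flagged)

  # empty spec: fold change 1 for every module
  res3 <- ko_effect(ms, col, intervention_spec(character(0)))
  expect_equal(res3$fold_change, 1)

  expect_error(ko_effect(ms, col, intervention_spec("gA"), threshold = 1),
               "> 1")
})

test_that("parallel isoenzyme branches give a sub-threshold fold change", {
  ms <- module_set(list(make_parallel()))
  col <- c(gA = 0.5, gB = 0.5, gC = 1)
  # S_C = 1 - (1-0.5)(1-0.5) = 0.75; after KO of gA: 1 - 1*0.5 = 0.5
  res <- ko_effect(ms, col, intervention_spec("gA", "ko_hard"))
  expect_equal(res$activity_before, 0.75, tolerance = 1e-9)
  expect_equal(res$activity_after, 0.5, tolerance = 1e-6)
  expect_false(res$flagged)   # 0.75/0.5 = 1.5 < 2
})

test_that("drug_effect expands targets and delegates to ko_effect", {
  ms <- module_set(list(make_chain(c("A", "B"), mid = "M1")))
  col <- c(gA = 0.8, gB = 0.9)
  map <- data.frame(drug = c("d1", "d2", "d3"),
                    gene = c("gA", "gB", "zz"),
                    effect = c("inhibit", "activate", "inhibit"))
  # one inhibiting drug == ko_soft of its target
  d <- drug_effect(ms, col, "d1", map)
  k <- ko_effect(ms, col, intervention_spec("gA", "ko_soft"))
  expect_equal(d, k)
  # two drugs with disjoint targets == the combined spec
  d12 <- drug_effect(ms, col, c("d1", "d2"), map)
  k12 <- ko_effect(ms, col, intervention_spec(c("gA", "gB"),
                                              c("ko_soft", "overexpress")))
  expect_equal(d12, k12)
  expect_error(drug_effect(ms, col, "unknown", map), "unknown")
  expect_warning(d3 <- drug_effect(ms, col, "d3", map), "nothing can change")
  expect_false(any(d3$flagged))
})

test_that("auto_knockout recovers the planted causal gene", {
  w <- make_autoko_world(n_per_class = 15, seed = 4)
  rank <- auto_knockout(w$mset, w$expr, w$design,
                        source_class = "disease", target_class = "healthy",
                        seed = 1, params = list(ntree = 80))
  expect_equal(nrow(rank), length(w$mset$gene_universe))
  expect_equal(rank$gene[1], "gSTAR")
  expect_gt(rank$change[1], 0)
  expect_true(all(rank$p_target_before >= 0 & rank$p_target_before <= 1))
  expect_true(all(rank$p_target_after >= 0 & rank$p_target_after <= 1))
  expect_equal(rank$change, rank$p_target_after - rank$p_target_before)
})

test_that("auto_knockout edge contracts: outside genes, identity, seeding", {
  w <- make_autoko_world(n_per_class = 10, seed = 8)
  genes <- c(w$mset$gene_universe, "outside_gene")
  r1 <- auto_knockout(w$mset, w$expr, w$design, "disease", "healthy",
                      seed = 7, genes = genes, params = list(ntree = 40))
  expect_equal(r1$change[r1$gene == "outside_gene"], 0)

  # multiplier 1 is the identity intervention: all changes exactly 0
  r_id <- auto_knockout(w$mset, w$expr, w$design, "disease", "healthy",
                        seed = 7, multiplier = 1, params = list(ntree = 40))
  expect_true(all(r_id$change == 0))

  # byte-exact reproducibility under the same seed
  r2 <- auto_knockout(w$mset, w$expr, w$design, "disease", "healthy",
                      seed = 7, genes = genes, params = list(ntree = 40))
  expect_identical(r1, r2)

  one <- w$design; one[] <- "disease"
  expect_error(auto_knockout(w$mset, w$expr, one, "disease", "healthy"),
               ">= 2 samples")
})

test_that("module-recompute shortcut agrees with full recomputation", {
  w <- make_autoko_world(n_per_class = 8, seed = 12)
  src <- names(w$design)[w$design == "disease"]
  for (g in c("gSTAR", "a1", "c1")) {
    spec <- intervention_spec(g, "scale", 0.01)
    expr_ko <- apply_intervention(w$expr, spec, samples = src)
    full <- activity_matrix(w$mset, expr_ko[, src])
    mods <- metabact:::modules_with_gene(w$mset, g)
    base <- activity_matrix(w$mset, w$expr[, src])
    shortcut <- base
    sub <- module_set(w$mset$graphs[mods])
    shortcut[mods, ] <- activity_matrix(sub, expr_ko[, src])[mods, ]
    expect_equal(shortcut, full, ignore_attr = TRUE)
  }
})
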