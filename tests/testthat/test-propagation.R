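test_that("node activity implements complex-min / isoenzyme-OR logic", {
  nd <- reaction_node("n", list(gene_group("g1")))
  expect_equal(node_activity(nd, c(g1 = 0.7)), 0.7)

  cx <- reaction_node("n", list(gene_group(c("g1", "g2"), "complex")))
  expect_equal(node_activity(cx, c(g1 = 0.9, g2 = 0.2)), 0.2)

  # two isoenzymes: 1 - 0.5 * 0.2 = 0.9
  iso <- reaction_node("n", list(gene_group("g1"), gene_group("g2")))
  expect_equal(node_activity(iso, c(g1 = 0.5, g2 = 0.8)), 0.9)

  # unmeasured genes drop out of their group; empty groups are permissive
  expect_equal(node_activity(cx, c(g1 = 0.9)), 0.9)
  expect_warning(v <- node_activity(iso, c(other = 1)), "permissive")
  expect_equal(v, 1)
  expect_warning(v0 <- node_activity(reaction_node("sp"), c(g1 = 1)),
                 "permissive")
  expect_equal(v0, 1)

  # alternative combiner config
  expect_equal(node_activity(iso, c(g1 = 0.5, g2 = 0.8), group_rule = "max"),
               0.8)
  expect_equal(node_activity(cx, c(g1 = 0.9, g2 = 0.2),
                             complex_rule = "mean"), 0.55)
})

test_that("propagate reproduces the hand-computed examples exactly", {
  chain <- make_chain(c("A", "B"))
  st <- propagate(chain, c(A = 0.5, B = 0.8))
  expect_equal(unname(st$S["B"]), 0.4, tolerance = 1e-12)
  expect_true(st$converged)
  expect_equal(st$iterations, 1L)

  conv <- make_converging()
  st2 <- propagate(conv, c(A = 0.5, B = 0.8, C = 1))
  expect_equal(unname(st2$S["C"]), 0.9, tolerance = 1e-12)

  cyc <- make_cycle()
  st3 <- propagate(cyc, c(X = 1, A = 0.5, B = 0.5))
  expect_equal(unname(st3$S[c("X", "A", "B")]), c(1, 0.5, 0.25),
               tolerance = 1e-9)
  # the fixed point is stable: one more synchronous sweep does not move it
  parents <- attr(cyc, "parents")
  n <- c(X = 1, A = 0.5, B = 0.5)
  S <- st3$S
  for (v in names(S)) {
    inprod <- if (v == "X") 0 else prod(1 - S[parents[[v]]])
    expect_equal(unname(n[v] * (1 - inprod)), unname(S[v]), tolerance = 1e-8)
  }
})

test_that("entry nodes get a virtual unit input, so S_entry = n_entry", {
  chain <- make_chain(c("A", "B"))
  st <- propagate(chain, c(A = 0.3, B = 1))
  expect_equal(unname(st$S["A"]), 0.3)   # not forced to 1
  expect_equal(unname(st$S["B"]), 0.3)
})

test_that("module_activity summarizes terminals by mean or min", {
  fork <- module_graph("fork", nodes = list(
    reaction_node("A", list(gene_group("gA"))),
    reaction_node("B", list(gene_group("gB"))),
    reaction_node("C", list(gene_group("gC")))),
    edges = list(c("A", "B"), c("A", "C")))
  st <- propagate(fork, c(A = 1, B = 0.2, C = 0.6))
  expect_equal(as.numeric(module_activity(fork, st)), 0.4)
  expect_equal(as.numeric(module_activity(fork, st, "min")), 0.2)
  expect_equal(attr(module_activity(fork, st, "min"), "terminal_rule"),
               "min")
  chain <- make_chain(c("A", "B"))
  stc <- propagate(chain, c(A = 0.5, B = 0.8))
  expect_equal(as.numeric(module_activity(chain, stc)), 0.4)
})

test_that("activity_matrix: determinism, fixed points, coverage report", {
  ms <- module_set(list(make_chain(c("D", "E", "F"), mid = "M1"),
                        make_converging()))
  genes <- ms$gene_universe
  expr <- matrix(0.5, length(genes), 2,
                 dimnames = list(genes, c("s1", "s2")))
  act <- activity_matrix(ms, expr)
  expect_equal(act[, "s1"], act[, "s2"])   # identical columns in = out

  expect_equal(unname(activity_matrix(ms, expr * 0 + 1)),
               matrix(1, 2, 2), ignore_attr = TRUE)  # all-1 fixed point
  expect_equal(unname(activity_matrix(ms, expr * 0)),
               matrix(0, 2, 2), ignore_attr = TRUE)  # n = 0 absorbs

  # module with no measured gene: permissive policy + coverage flag
  expr_missing <- expr[setdiff(genes, module_genes(ms$graphs$M1)), ,
                       drop = FALSE]
  act2 <- activity_matrix(ms, expr_missing)
  cov <- activity_coverage(act2)
  expect_true(cov$M1$fully_unmeasured)
  expect_equal(cov$M1$measured_gene_fraction, 0)
  expect_equal(unname(act2["M1", ]), c(1, 1))  # all nodes permissive
  expect_equal(cov$conv$measured_gene_fraction, 1)
  expect_false(cov$conv$fully_unmeasured)
})

test_that("propagation is bounded and agrees with the naive oracle", {
  cfg_dag <- sim_config(n_modules = 25, cycle_p = 0, seed = 5)
  cfg_cyc <- sim_config(n_modules = 12, cycle_p = 1, seed = 6)
  graphs <- c(generate_module_set(cfg_dag)$graphs,
              generate_module_set(cfg_cyc)$graphs)
  set.seed(99)
  for (g in graphs) {
    n <- random_n(g)
    st <- propagate(g, n)
    o <- oracle_propagate(g, n)
    expect_true(all(st$S >= 0 & st$S <= 1))
    expect_lt(max(abs(st$S - o$S)), 1e-8)
  }
})

test_that("fixed-point iterates are monotone non-decreasing on cycles", {
  cyc <- make_cycle()
  n <- c(X = 0.9, A = 0.8, B = 0.7)
  parents <- attr(cyc, "parents")
  S <- c(X = 0, A = 0, B = 0)
  prev <- S
  for (it in 1:50) {
    Snew <- S
    for (v in names(S)) {
      inprod <- if (v == "X") 0 else prod(1 - S[parents[[v]]])
      Snew[v] <- n[v] * (1 - inprod)
    }
    expect_true(all(Snew >= S - 1e-15))
    S <- Snew
  }
  expect_lt(max(abs(S - propagate(cyc, n)$S)), 1e-6)
})

test_that("raising one gene never lowers any module activity", {
  cfg <- sim_config(n_modules = 8, cycle_p = 0.25, seed = 17)
  ms <- generate_module_set(cfg)
  set.seed(18)
  for (rep in 1:25) {
    g <- ms$graphs[[sample(length(ms$graphs), 1)]]
    genes <- module_genes(g)
    expr <- stats::setNames(stats::runif(length(genes)), genes)
    tgt <- sample(genes, 1)
    expr2 <- expr
    expr2[tgt] <- min(1, expr2[tgt] + stats::runif(1, 0, 1 - expr2[tgt]))
    a1 <- module_activity(g, propagate(g, node_activity_vector_t(g, expr)))
    a2 <- module_activity(g, propagate(g, node_activity_vector_t(g, expr2)))
    expect_gte(a2 + 1e-12, a1)
  }
})

test_that("zero-cut: n = 0 on an essential bridge forces activity 0", {
  chain <- make_chain(c("A", "B", "C"))
  st <- propagate(chain, c(A = 0.9, B = 0, C = 0.9))
  expect_equal(as.numeric(module_activity(chain, st)), 0)
})
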