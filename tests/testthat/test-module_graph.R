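test_that("load_module_set round-trips and validates the JSON dialect", {
  path <- tempfile(fileext = ".json")
  writeLines('{
    "modules": [{
      "module_id": "M1", "name": "toy", "species": "generic",
      "nodes": [
        {"node_id": "A", "label": "r1",
         "groups": [{"semantics": "single", "genes": ["g1"]}]},
        {"node_id": "B", "label": "r2",
         "groups": [{"semantics": "single", "genes": ["g2"]}]},
        {"node_id": "C", "label": "r3",
         "groups": [{"semantics": "complex", "genes": ["g3", "g4"]}]}
      ],
      "edges": [["A","B"], ["B","C"]]
    }]
  }', path)
  ms <- load_module_set(path)
  expect_length(ms$graphs, 1)
  expect_length(ms$graphs$M1$nodes, 3)
  expect_equal(ms$gene_universe, c("g1", "g2", "g3", "g4"))

  # load -> serialize -> load is the identity
  out <- tempfile(fileext = ".json")
  write_module_set(ms, out)
  ms2 <- load_module_set(out)
  expect_equal(ms2, ms)
})

test_that("dangling edges and schema violations are named in errors", {
  path <- tempfile(fileext = ".json")
  writeLines('{"modules": [{"module_id": "M1",
    "nodes": [{"node_id": "A", "groups": [{"semantics":"single","genes":["g1"]}]}],
    "edges": [["A","Z"]]}]}', path)
  expect_error(load_module_set(path), '"A","Z"')
  expect_error(load_module_set(path), "'Z'")

  path2 <- tempfile(fileext = ".json")
  writeLines('{"modules": [{"module_id": "M2",
    "nodes": [{"node_id": "A", "groups": [{"semantics":"single","genes":[]}]}],
    "edges": []}]}', path2)
  expect_error(load_module_set(path2), "M2.*A.*genes")
})

test_that("gene universe is an exact union across modules", {
  g1 <- make_chain(c("A", "B"), mid = "M1")
  shared <- module_graph("M2", nodes = list(
    reaction_node("X", list(gene_group("gA"))),    # shares gA with M1
    reaction_node("Y", list(gene_group("gY")))),
    edges = list(c("X", "Y")))
  ms <- module_set(list(g1, shared))
  expect_equal(sum(ms$gene_universe == "gA"), 1)
  expect_setequal(ms$gene_universe, c("gA", "gB", "gY"))
  expect_error(module_set(list(g1, g1)), "duplicate module_id")
})

test_that("initial and terminal nodes follow degree and declarations", {
  chain <- make_chain(c("A", "B", "C"))
  expect_equal(initial_nodes(chain), "A")
  expect_equal(terminal_nodes(chain), "C")

  conv <- make_converging()
  expect_setequal(initial_nodes(conv), c("A", "B"))
  expect_equal(terminal_nodes(conv), "C")

  fork <- module_graph("fork", nodes = list(
    reaction_node("A", list(gene_group("gA"))),
    reaction_node("B", list(gene_group("gB"))),
    reaction_node("C", list(gene_group("gC")))),
    edges = list(c("A", "B"), c("A", "C")))
  expect_setequal(terminal_nodes(fork), c("B", "C"))

  cyc <- make_cycle()
  expect_equal(initial_nodes(cyc), "X")
  expect_equal(terminal_nodes(cyc), "B")

  # pure cycle: must declare entry/terminal, declared values honored
  expect_error(
    module_graph("bad", nodes = list(
      reaction_node("A", list(gene_group("gA"))),
      reaction_node("B", list(gene_group("gB")))),
      edges = list(c("A", "B"), c("B", "A"))),
    "entry")
  pure <- module_graph("pure", nodes = list(
    reaction_node("A", list(gene_group("gA"))),
    reaction_node("B", list(gene_group("gB")))),
    edges = list(c("A", "B"), c("B", "A")),
    entry_ids = "A", terminal_ids = "B")
  expect_equal(initial_nodes(pure), "A")
  expect_equal(terminal_nodes(pure), "B")
})

test_that("topological order is exhaustive-checked on generated graphs", {
  chain <- make_chain(c("A", "B", "C"))
  expect_equal(topological_order(chain),
               list(cyclic = FALSE, order = c("A", "B", "C"),
                    cycle_nodes = character(0)))
  diamond <- module_graph("dia", nodes = lapply(c("A", "B", "C", "D"),
    function(v) reaction_node(v, list(gene_group(paste0("g", v))))),
    edges = list(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
  ord <- topological_order(diamond)$order
  expect_equal(ord[1], "A")
  expect_equal(ord[4], "D")

  cyc <- make_cycle()
  to <- topological_order(cyc)
  expect_true(to$cyclic)
  expect_setequal(to$cycle_nodes, c("A", "B"))

  # property: every edge goes forward in the order, on 30 random DAGs
  cfg <- sim_config(n_modules = 30, cycle_p = 0, seed = 11)
  ms <- generate_module_set(cfg)
  for (g in ms$graphs) {
    to <- topological_order(g)
    expect_false(to$cyclic)
    pos <- match(vapply(g$nodes, `[[`, character(1), "node_id"), to$order)
    names(pos) <- to$order[pos]
    for (e in g$edges) expect_lt(pos[e[1]], pos[e[2]])
  }
})

test_that("structural invariants reject bad graphs", {
  expect_error(make_chain(c("A", "A")), "duplicate node_id")
  expect_error(
    module_graph("dup", nodes = list(
      reaction_node("A", list(gene_group("gA"))),
      reaction_node("B", list(gene_group("gB")))),
      edges = list(c("A", "B"), c("A", "B"))),
    "duplicate edge")
  expect_error(gene_group(character(0)), "at least one gene")
  expect_error(gene_group(c("g1", "g1"), "complex"), "duplicate")
  expect_error(gene_group(c("g1", "g2"), "single"), "exactly one")
  # empty gene groups are legal (spontaneous reactions)
  sp <- module_graph("sp", nodes = list(
    reaction_node("A", list(gene_group("gA"))),
    reaction_node("B")),
    edges = list(c("A", "B")))
  expect_length(sp$nodes[[2]]$groups, 0)
})
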