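# Graph fixtures built in code, plus independent oracles used across tests.

# single-gene chain A -> B (-> C ...)
make_chain <- function(ids = c("A", "B"), mid = "chain") {
  nodes <- lapply(ids, function(v)
    reaction_node(v, list(gene_group(paste0("g", v)))))
  edges <- if (length(ids) > 1)
    lapply(seq_len(length(ids) - 1), function(k) c(ids[k], ids[k + 1]))
  else list()
  module_graph(mid, nodes = nodes, edges = edges)
}

# A -> C <- B (convergence)
make_converging <- function() {
  module_graph("conv", nodes = list(
    reaction_node("A", list(gene_group("gA"))),
    reaction_node("B", list(gene_group("gB"))),
    reaction_node("C", list(gene_group("gC")))),
    edges = list(c("A", "C"), c("B", "C")))
}

# entry X -> A <-> B cycle, declared entry X / terminal B
make_cycle <- function() {
  module_graph("cyc", nodes = list(
    reaction_node("X", list(gene_group("gX"))),
    reaction_node("A", list(gene_group("gA"))),
    reaction_node("B", list(gene_group("gB")))),
    edges = list(c("X", "A"), c("A", "B"), c("B", "A")),
    entry_ids = "X", terminal_ids = "B")
}

# two isoenzyme branches into one terminal: A -> C <- B, used for partial-KO
make_parallel <- function() {
  module_graph("par", nodes = list(
    reaction_node("A", list(gene_group("gA"))),
    reaction_node("B", list(gene_group("gB"))),
    reaction_node("C", list(gene_group("gC")))),
    edges = list(c("A", "C"), c("B", "C")))
}

# random [0,1] node-activity vector for a graph
random_n <- function(graph) {
  ids <- vapply(graph$nodes, `[[`, character(1), "node_id")
  stats::setNames(stats::runif(length(ids)), ids)
}

# internal node-activity vector (not exported)
node_activity_vector_t <- function(graph, expr_column)
  metabact:::node_activity_vector(graph, expr_column)

# independent AUC oracle: trapezoidal integration of the empirical ROC
auc_trapezoid <- function(scores, positive) {
  positive <- as.logical(positive)
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) mean(scores[positive] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[!positive] >= t), numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# planted auto-KO world: the only class difference is gene "gSTAR", the
# single-gene bridge node of module KOM1; all other nodes are isoenzyme
# pairs so no other single KO can zero a module.
make_autoko_world <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  iso_node <- function(id, g1, g2)
    reaction_node(id, list(gene_group(g1), gene_group(g2)))
  m1 <- module_graph("KOM1", nodes = list(
    iso_node("n1", "a1", "a2"),
    reaction_node("n2", list(gene_group("gSTAR"))),
    iso_node("n3", "b1", "b2")),
    edges = list(c("n1", "n2"), c("n2", "n3")))
  m2 <- module_graph("KOM2", nodes = list(
    iso_node("p1", "c1", "c2"), iso_node("p2", "d1", "d2")),
    edges = list(c("p1", "p2")))
  m3 <- module_graph("KOM3", nodes = list(
    iso_node("q1", "e1", "e2"), iso_node("q2", "f1", "f2")),
    edges = list(c("q1", "q2")))
  mset <- module_set(list(m1, m2, m3))
  genes <- mset$gene_universe
  samples <- sprintf("s%02d", seq_len(2 * n_per_class))
  design <- stats::setNames(rep(c("disease", "healthy"), each = n_per_class),
                            samples)
  expr <- matrix(stats::rnorm(length(genes) * length(samples), 0.7, 0.05),
                 length(genes), length(samples),
                 dimnames = list(genes, samples))
  expr["gSTAR", design == "disease"] <-
    stats::rnorm(n_per_class, 0.85, 0.05)
  expr["gSTAR", design == "healthy"] <-
    stats::rnorm(n_per_class, 0.15, 0.05)
  expr <- pmin(pmax(expr, 0), 1)
  list(mset = mset, expr = expr, design = design, causal = "gSTAR")
}
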