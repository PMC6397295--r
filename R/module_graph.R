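#' Gene group (isoenzyme alternative or enzymatic complex)
#'
#' A reaction node is catalyzed by one or several alternative gene groups.
#' A group with `semantics = "single"` is one isoenzyme; a group with
#' `semantics = "complex"` is a multi-subunit complex whose genes are all
#' required (AND logic). Alternative groups on a node combine with OR logic.
#'
#' @param genes character vector of gene identifiers (non-empty, unique).
#' @param semantics `"single"` or `"complex"`.
#' @return an object of class `metab_gene_group`.
#' @export
gene_group <- function(genes, semantics = c("single", "complex")) {
  semantics <- match.arg(semantics)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene group must contain at least one gene")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers within a group")
  if (semantics == "single" && length(genes) != 1L)
    stop("a 'single' group must contain exactly one gene")
  structure(list(genes = genes, semantics = semantics),
            class = "metab_gene_group")
}

#' Reaction node of a metabolic module
#'
#' One enzymatic step of the module. `groups` may be empty: such nodes model
#' spontaneous or unannotated reactions and are treated as always permissive
#' (node activity 1) by the propagation model.
#'
#' @param node_id unique node identifier within the module.
#' @param groups list of [gene_group()] objects (possibly empty).
#' @param label free-text label (reaction / EC number).
#' @return an object of class `metab_reaction_node`.
#' @export
reaction_node <- function(node_id, groups = list(), label = "") {
  if (!is.character(node_id) || length(node_id) != 1L || !nzchar(node_id))
    stop("node_id must be a non-empty string")
  if (!is.list(groups) ||
      !all(vapply(groups, inherits, logical(1), "metab_gene_group")))
    stop(sprintf("node '%s': groups must be a list of gene_group objects",
                 node_id))
  structure(list(node_id = node_id, groups = groups,
                 label = as.character(label)[1]),
            class = "metab_reaction_node")
}

#' Metabolic module graph
#'
#' A directed graph of reaction nodes describing the chain of reactions that
#' transforms a simple metabolite into a complex one. Edges point from the
#' reaction producing a metabolite to the reaction consuming it. Acyclic
#' modules need no declarations; cyclic modules must declare `entry_ids` and
#' `terminal_ids` explicitly so propagation is well defined.
#'
#' @param module_id,name,species identification strings.
#' @param nodes list of [reaction_node()] objects.
#' @param edges list of length-2 character vectors `c(source, target)` (or a
#'   two-column character matrix).
#' @param entry_ids optional explicit entry nodes (required for cyclic graphs
#'   with no in-degree-0 node).
#' @param terminal_ids optional explicit terminal nodes (required for cyclic
#'   graphs with no out-degree-0 node).
#' @return a validated object of class `metab_module_graph`.
#' @export
module_graph <- function(module_id, name = module_id, species = "generic",
                         nodes, edges = list(),
                         entry_ids = NULL, terminal_ids = NULL) {
  if (is.matrix(edges)) edges <- lapply(seq_len(nrow(edges)),
                                        function(i) edges[i, ])
  g <- structure(
    list(module_id = as.character(module_id)[1],
         name = as.character(name)[1],
         species = as.character(species)[1],
         nodes = nodes,
         edges = lapply(edges, as.character),
         entry_ids = if (is.null(entry_ids)) NULL else as.character(entry_ids),
         terminal_ids = if (is.null(terminal_ids)) NULL
                        else as.character(terminal_ids)),
    class = "metab_module_graph")
  validate_module_graph(g)
}

#' @export
print.metab_module_graph <- function(x, ...) {
  cat(sprintf("<module %s> '%s' (%s): %d nodes, %d edges%s\n",
              x$module_id, x$name, x$species,
              length(x$nodes), length(x$edges),
              if (isTRUE(attr(x, "cyclic"))) ", cyclic" else ""))
  invisible(x)
}

node_ids <- function(graph)
  vapply(graph$nodes, function(nd) nd$node_id, character(1))

#' Validate a module graph
#'
#' Enforces the structural invariants: unique node ids, edge endpoints exist,
#' no duplicate edges, an entry point exists (in-degree 0 or declared), a
#' terminal exists (out-degree 0 or declared), and cyclic graphs declare both
#' entry and terminal nodes. Attaches cached adjacency structure used by the
#' propagation engine.
#'
#' @param graph a `metab_module_graph`.
#' @return the graph, with `parents`, `children`, `cyclic` attributes set.
#' @export
validate_module_graph <- function(graph) {
  mid <- graph$module_id
  ids <- node_ids(graph)
  if (anyDuplicated(ids))
    stop(sprintf("module '%s': duplicate node_id '%s'",
                 mid, ids[duplicated(ids)][1]))
  for (e in graph$edges) {
    if (length(e) != 2L)
      stop(sprintf("module '%s': edge must have exactly two endpoints", mid))
    miss <- setdiff(e, ids)
    if (length(miss))
      stop(sprintf(
        "module '%s': edge (\"%s\",\"%s\") references undeclared node '%s'",
        mid, e[1], e[2], miss[1]))
  }
  ekey <- vapply(graph$edges, paste, character(1), collapse = "\r")
  if (anyDuplicated(ekey))
    stop(sprintf("module '%s': duplicate edge (%s)", mid,
                 gsub("\r", " -> ", ekey[duplicated(ekey)][1])))
  for (ex in c("entry_ids", "terminal_ids")) {
    miss <- setdiff(graph[[ex]], ids)
    if (length(miss))
      stop(sprintf("module '%s': %s names unknown node '%s'",
                   mid, ex, miss[1]))
  }

  src <- vapply(graph$edges, `[`, character(1), 1)
  dst <- vapply(graph$edges, `[`, character(1), 2)
  parents  <- lapply(ids, function(v) src[dst == v])
  children <- lapply(ids, function(v) dst[src == v])
  names(parents) <- names(children) <- ids

  topo <- topo_sort_ids(ids, parents)
  cyclic <- topo$cyclic

  indeg0  <- ids[lengths(parents) == 0L]
  outdeg0 <- ids[lengths(children) == 0L]
  if (length(indeg0) == 0L && is.null(graph$entry_ids))
    stop(sprintf("module '%s': no entry point (no in-degree-0 node and no declared entry_ids)",
                 mid))
  term <- if (!is.null(graph$terminal_ids)) graph$terminal_ids else outdeg0
  if (length(term) == 0L)
    stop(sprintf("module '%s': no terminal node (no out-degree-0 node and no declared terminal_ids)",
                 mid))
  if (cyclic && (is.null(graph$entry_ids) || is.null(graph$terminal_ids)))
    stop(sprintf("module '%s': cyclic module must declare both entry_ids and terminal_ids",
                 mid))

  attr(graph, "parents") <- parents
  attr(graph, "children") <- children
  attr(graph, "cyclic") <- cyclic
  attr(graph, "topo_order") <- topo$order      # NULL when cyclic
  attr(graph, "cycle_nodes") <- topo$cycle_nodes
  graph
}

# Kahn's algorithm on id/parent lists; returns order or the nodes left on
# cycles when no full order exists.
topo_sort_ids <- function(ids, parents) {
  indeg <- lengths(parents)
  names(indeg) <- ids
  order <- character(0)
  queue <- ids[indeg == 0L]
  remaining <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in ids) {
      if (v %in% parents[[w]]) {
        remaining[w] <- remaining[w] - sum(parents[[w]] == v)
        if (remaining[w] == 0L && !(w %in% order) && !(w %in% queue))
          queue <- c(queue, w)
      }
    }
  }
  if (length(order) == length(ids))
    list(cyclic = FALSE, order = order, cycle_nodes = character(0))
  else
    list(cyclic = TRUE, order = NULL, cycle_nodes = setdiff(ids, order))
}

#' Entry nodes of a module graph
#'
#' Nodes granted the virtual unit input signal: all in-degree-0 nodes, or the
#' explicitly declared `entry_ids` when no in-degree-0 node exists (cyclic
#' modules). Declared entries are added to any in-degree-0 nodes.
#'
#' @param graph a validated `metab_module_graph`.
#' @return character vector of node ids.
#' @export
initial_nodes <- function(graph) {
  parents <- attr(graph, "parents")
  ids <- node_ids(graph)
  res <- unique(c(ids[lengths(parents) == 0L], graph$entry_ids))
  if (length(res) == 0L)
    stop(sprintf("module '%s': no entry point", graph$module_id))
  res[order(match(res, ids))]
}

#' Terminal nodes of a module graph
#'
#' The nodes whose propagated activity summarizes the module: the declared
#' `terminal_ids` if present, otherwise all out-degree-0 nodes.
#'
#' @param graph a validated `metab_module_graph`.
#' @return character vector of node ids (never empty).
#' @export
terminal_nodes <- function(graph) {
  if (!is.null(graph$terminal_ids)) return(graph$terminal_ids)
  children <- attr(graph, "children")
  res <- node_ids(graph)[lengths(children) == 0L]
  if (length(res) == 0L)
    stop(sprintf("module '%s': no terminal node", graph$module_id))
  res
}

#' Topological order of a module graph
#'
#' @param graph a validated `metab_module_graph`.
#' @return a list with `cyclic` (logical), `order` (character vector of node
#'   ids when acyclic, `NULL` otherwise) and `cycle_nodes` (nodes lying on
#'   cycles when cyclic).
#' @export
topological_order <- function(graph) {
  list(cyclic = attr(graph, "cyclic"),
       order = attr(graph, "topo_order"),
       cycle_nodes = attr(graph, "cycle_nodes"))
}

#' Genes annotated on a module graph
#' @param graph a `metab_module_graph`.
#' @return character vector of unique gene ids, in order of first appearance.
#' @export
module_genes <- function(graph) {
  unique(unlist(lapply(graph$nodes, function(nd)
    unlist(lapply(nd$groups, `[[`, "genes"))), use.names = FALSE))
}

#' Collection of module graphs
#'
#' @param graphs list of `metab_module_graph` objects with unique module ids.
#' @return an object of class `metab_module_set` with a `gene_universe`
#'   field holding the exact union of all node genes.
#' @export
module_set <- function(graphs) {
  if (!is.list(graphs) ||
      !all(vapply(graphs, inherits, logical(1), "metab_module_graph")))
    stop("graphs must be a list of metab_module_graph objects")
  mids <- vapply(graphs, `[[`, character(1), "module_id")
  if (anyDuplicated(mids))
    stop(sprintf("duplicate module_id '%s'", mids[duplicated(mids)][1]))
  names(graphs) <- mids
  structure(list(graphs = graphs,
                 gene_universe = unique(unlist(lapply(graphs, module_genes),
                                               use.names = FALSE))),
            class = "metab_module_set")
}

#' @export
print.metab_module_set <- function(x, ...) {
  cat(sprintf("<module set> %d modules, %d genes in universe\n",
              length(x$graphs), length(x$gene_universe)))
  invisible(x)
}

#' Load a module set from its JSON description
#'
#' Reads the documented module-graph JSON dialect:
#' `{"modules":[{"module_id","name","species",`
#' `"nodes":[{"node_id","label","groups":[{"semantics","genes":[...]}]}],`
#' `"edges":[["src","dst"],...],"entry_ids":[...],"terminal_ids":[...]}]}`.
#' Node and module order are preserved; all structural invariants are
#' enforced on load.
#'
#' @param path path to a UTF-8 JSON file.
#' @return a validated [module_set()].
#' @export
load_module_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("module file '%s' does not exist", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(raw$modules))
    stop(sprintf("'%s': missing top-level \"modules\" field", path))
  graphs <- lapply(raw$modules, function(m) {
    mid <- m$module_id
    if (is.null(mid)) stop(sprintf("'%s': module without module_id", path))
    if (is.null(m$nodes))
      stop(sprintf("module '%s': missing field 'nodes'", mid))
    nodes <- lapply(m$nodes, function(nd) {
      if (is.null(nd$node_id))
        stop(sprintf("module '%s': node without node_id", mid))
      groups <- lapply(nd$groups, function(gr) {
        if (is.null(gr$genes) || length(gr$genes) == 0L)
          stop(sprintf("module '%s', node '%s': group field 'genes' empty or missing",
                       mid, nd$node_id))
        sem <- if (is.null(gr$semantics)) "single" else gr$semantics
        if (!sem %in% c("single", "complex"))
          stop(sprintf("module '%s', node '%s': invalid group semantics '%s'",
                       mid, nd$node_id, sem))
        gene_group(unlist(gr$genes), sem)
      })
      reaction_node(nd$node_id, groups,
                    label = if (is.null(nd$label)) "" else nd$label)
    })
    edges <- lapply(m$edges, function(e) unlist(e))
    module_graph(module_id = mid,
                 name = if (is.null(m$name)) mid else m$name,
                 species = if (is.null(m$species)) "generic" else m$species,
                 nodes = nodes, edges = edges,
                 entry_ids = if (length(m$entry_ids)) unlist(m$entry_ids)
                             else NULL,
                 terminal_ids = if (length(m$terminal_ids))
                                  unlist(m$terminal_ids) else NULL)
  })
  module_set(graphs)
}

#' Serialize a module set to the module-graph JSON dialect
#'
#' Inverse of [load_module_set()]: `load(write(x))` reproduces `x`.
#'
#' @param mset a `metab_module_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_module_set <- function(mset, path) {
  mods <- lapply(mset$graphs, function(g) {
    out <- list(
      module_id = g$module_id, name = g$name, species = g$species,
      nodes = lapply(g$nodes, function(nd) list(
        node_id = nd$node_id, label = nd$label,
        groups = lapply(nd$groups, function(gr)
          list(semantics = gr$semantics, genes = as.list(gr$genes))))),
      edges = lapply(g$edges, as.list))
    if (!is.null(g$entry_ids)) out$entry_ids <- as.list(g$entry_ids)
    if (!is.null(g$terminal_ids)) out$terminal_ids <- as.list(g$terminal_ids)
    out
  })
  jsonlite::write_json(list(modules = unname(mods)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
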