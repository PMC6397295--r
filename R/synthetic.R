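# Synthetic-data generators with known ground truth, plus the deliberately
# naive propagation oracle. Everything is a pure function of (config, seed),
# so the whole pipeline is testable without any download.

#' Simulation configuration
#'
#' Defaults describe a small but realistic world: modules of 3-15 reaction
#' nodes with occasional branching, 1-3 genes per node, a modest share of
#' enzymatic complexes, per-gene baselines drawn from Uniform(0.3, 0.7) so
#' planted shifts of +/-0.3 stay inside \[0,1\] after clipping, and Gaussian
#' noise with sd 0.1.
#'
#' @param n_modules number of modules.
#' @param nodes_range integer range of nodes per module.
#' @param branching_p probability of adding a forward branch edge.
#' @param cycle_p probability a module receives a back edge (cycle).
#' @param genes_range integer range of genes per gene group.
#' @param complex_p probability a group is a complex (AND) rather than a
#'   single isoenzyme.
#' @param groups_range integer range of alternative groups per node.
#' @param n_per_class samples per class.
#' @param classes class labels.
#' @param effect_genes named numeric vector: expression shift added to these
#'   genes in the second class.
#' @param noise_sd Gaussian noise sd on expression.
#' @param hazard_coef survival log-hazard coefficient on module activity.
#' @param censor_rate approximate censoring intensity (0 disables).
#' @param seed mandatory integer seed.
#' @return a list of class `metab_sim_config`.
#' @export
sim_config <- function(n_modules = 10L, nodes_range = c(3L, 15L),
                       branching_p = 0.25, cycle_p = 0, genes_range = c(1L, 3L),
                       complex_p = 0.3, groups_range = c(1L, 2L),
                       n_per_class = 30L, classes = c("control", "case"),
                       effect_genes = NULL, noise_sd = 0.1,
                       hazard_coef = 0, censor_rate = 0.25, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_modules >= 1L, nodes_range[1] >= 1L,
            nodes_range[1] <= nodes_range[2],
            branching_p >= 0, branching_p <= 1, cycle_p >= 0, cycle_p <= 1,
            genes_range[1] >= 1L, complex_p >= 0, complex_p <= 1,
            n_per_class >= 1L, noise_sd >= 0, length(classes) >= 2L)
  if (cycle_p > 0 && nodes_range[1] < 3L)
    stop("cyclic modules need at least 3 nodes; raise nodes_range[1]")
  structure(list(n_modules = as.integer(n_modules),
                 nodes_range = as.integer(nodes_range),
                 branching_p = branching_p, cycle_p = cycle_p,
                 genes_range = as.integer(genes_range),
                 complex_p = complex_p, groups_range = as.integer(groups_range),
                 n_per_class = as.integer(n_per_class), classes = classes,
                 effect_genes = effect_genes, noise_sd = noise_sd,
                 hazard_coef = hazard_coef, censor_rate = censor_rate,
                 seed = as.integer(seed)),
            class = "metab_sim_config")
}

# one random module graph: a chain backbone plus forward branch edges,
# optionally one back edge to create a cycle (entry/terminal then declared)
random_module_graph <- function(mid, config) {
  resample <- function(x) x[sample.int(length(x), 1)]
  nn <- resample(config$nodes_range[1]:config$nodes_range[2])
  ids <- sprintf("%s_n%02d", mid, seq_len(nn))
  nodes <- lapply(seq_len(nn), function(k) {
    ngr <- resample(config$groups_range[1]:config$groups_range[2])
    groups <- lapply(seq_len(ngr), function(j) {
      is_complex <- stats::runif(1) < config$complex_p
      ng <- if (is_complex)
        max(2L, resample(config$genes_range[1]:config$genes_range[2]))
      else 1L
      gene_group(sprintf("%s_g%02d_%d", ids[k], j, seq_len(ng)),
                 if (is_complex) "complex" else "single")
    })
    reaction_node(ids[k], groups)
  })
  edges <- lapply(seq_len(nn - 1), function(k) c(ids[k], ids[k + 1]))
  if (nn >= 3) {
    for (k in seq_len(nn - 2)) {
      if (stats::runif(1) < config$branching_p) {
        tgt <- resample((k + 2):nn)
        e <- c(ids[k], ids[tgt])
        if (!any(vapply(edges, identical, logical(1), e)))
          edges <- c(edges, list(e))
      }
    }
  }
  cyclic <- nn >= 3 && stats::runif(1) < config$cycle_p
  entry <- terminal <- NULL
  if (cyclic) {
    # back edge between interior nodes (node 1 keeps in-degree 0, node nn
    # stays downstream); entry/terminal must then be declared
    from <- if (nn == 3) 3L else resample(3:nn)
    to <- resample(2:(from - 1))
    edges <- c(edges, list(c(ids[from], ids[to])))
    entry <- ids[1]
    terminal <- ids[nn]
  }
  module_graph(mid, name = paste("synthetic module", mid),
               species = "synthetic", nodes = nodes, edges = edges,
               entry_ids = entry, terminal_ids = terminal)
}

#' Generate a random module set
#'
#' Random reaction graphs honoring every structural invariant: chain
#' backbones with forward branches, optional declared-entry/terminal cycles,
#' per-node isoenzyme/complex gene groups with globally unique gene ids.
#'
#' @param config a [sim_config()].
#' @return a validated [module_set()]; deterministic given `config$seed`.
#' @export
generate_module_set <- function(config) {
  stopifnot(inherits(config, "metab_sim_config"))
  set.seed(config$seed)
  graphs <- lapply(seq_len(config$n_modules), function(i)
    random_module_graph(sprintf("SM%03d", i), config))
  module_set(graphs)
}

# node ids from which a terminal node is reachable (forward closure)
nodes_reaching_terminal <- function(graph) {
  children <- attr(graph, "children")
  term <- terminal_nodes(graph)
  ids <- node_ids(graph)
  reach <- stats::setNames(ids %in% term, ids)
  repeat {
    new <- reach
    for (v in ids)
      if (!new[v] && any(reach[children[[v]]])) new[v] <- TRUE
    if (identical(new, reach)) break
    reach <- new
  }
  ids[reach]
}

genes_of_node <- function(graph, nid) {
  nd <- graph$nodes[[match(nid, node_ids(graph))]]
  unique(unlist(lapply(nd$groups, `[[`, "genes")))
}

#' Generate expression, design and ground truth for a module set
#'
#' Per-gene baselines are drawn from Uniform(0.3, 0.7); each sample adds
#' Gaussian noise (sd `config$noise_sd`); `config$effect_genes` are shifted
#' by their effect size in the second class; everything is clipped to
#' \[0,1\]. The ground truth lists, per effect gene, the modules whose
#' terminal node is reachable from a node carrying that gene — the modules
#' the propagation model itself can see the effect in.
#'
#' @param mset a [module_set()] (typically from [generate_module_set()]).
#' @param config a [sim_config()].
#' @return list with `expr` (genes x samples matrix in \[0,1\]), `design`
#'   (named vector), `truth` (list: `effect_genes`, `affected_modules`,
#'   `directions`).
#' @export
generate_expression <- function(mset, config) {
  stopifnot(inherits(mset, "metab_module_set"),
            inherits(config, "metab_sim_config"))
  set.seed(config$seed + 1L)
  genes <- mset$gene_universe
  eff <- config$effect_genes
  if (!is.null(eff)) {
    bad <- setdiff(names(eff), genes)
    if (length(bad))
      stop(sprintf("effect gene '%s' is not in any module", bad[1]))
  }
  classes <- config$classes[1:2]
  n <- config$n_per_class
  samples <- sprintf("s%03d", seq_len(2L * n))
  design <- stats::setNames(rep(classes, each = n), samples)

  base <- stats::runif(length(genes), 0.3, 0.7)
  expr <- matrix(stats::rnorm(length(genes) * length(samples),
                              mean = base, sd = config$noise_sd),
                 nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  if (!is.null(eff))
    expr[names(eff), design == classes[2]] <-
      expr[names(eff), design == classes[2]] + eff
  expr <- pmin(pmax(expr, 0), 1)

  affected <- list()
  if (!is.null(eff)) {
    for (g in names(eff)) {
      mods <- character(0)
      for (m in names(mset$graphs)) {
        gr <- mset$graphs[[m]]
        carrier <- Filter(function(v) g %in% genes_of_node(gr, v),
                          node_ids(gr))
        if (length(carrier) &&
            any(carrier %in% nodes_reaching_terminal(gr)))
          mods <- c(mods, m)
      }
      affected[[g]] <- mods
    }
  }
  truth <- list(
    effect_genes = eff,
    affected_modules = unique(unlist(affected, use.names = FALSE)),
    per_gene_modules = affected,
    directions = if (is.null(eff)) NULL else
      stats::setNames(ifelse(eff > 0, "up", "down"), names(eff)))
  list(expr = expr, design = design, truth = truth)
}

#' Generate survival records linked to a module's activity
#'
#' Event times are exponential with hazard
#' `h0 * exp(coefficient * activity)` (higher activity = worse survival for
#' positive coefficients); censoring times are independent exponentials with
#' rate `censor_rate * h0` (0 disables censoring).
#'
#' @param act modules x samples activity matrix.
#' @param module_id the module driving the hazard.
#' @param coefficient log-hazard coefficient (0 = null).
#' @param seed integer seed.
#' @param h0 baseline hazard (default 0.1).
#' @param censor_rate censoring intensity relative to `h0` (default 0.25).
#' @return data.frame with columns `sample`, `time`, `event`.
#' @export
generate_survival <- function(act, module_id, coefficient, seed,
                              h0 = 0.1, censor_rate = 0.25) {
  if (!module_id %in% rownames(act))
    stop(sprintf("module '%s' not present in the activity matrix", module_id))
  set.seed(as.integer(seed))
  a <- act[module_id, ]
  n <- length(a)
  tt <- stats::rexp(n, rate = h0 * exp(coefficient * a))
  if (censor_rate > 0) {
    cc <- stats::rexp(n, rate = h0 * censor_rate)
    event <- as.integer(tt <= cc)
    tt <- pmin(tt, cc)
  } else event <- rep(1L, n)
  data.frame(sample = colnames(act), time = tt, event = event,
             stringsAsFactors = FALSE)
}

#' Naive propagation oracle (tests only)
#'
#' An independent, deliberately simple implementation of the propagation
#' rule: dense synchronous sweeps from the all-zero state, re-reading the
#' full graph structure each sweep, no topological shortcut, run for up to
#' `10 * max_iter` sweeps. Used to cross-check [propagate()].
#'
#' @param graph a validated `metab_module_graph`.
#' @param n named node-activity vector in \[0,1\].
#' @param tol,max_iter as in [propagate()].
#' @return a `metab_propagation_state`.
#' @export
oracle_propagate <- function(graph, n, tol = 1e-9, max_iter = 1000L) {
  ids <- node_ids(graph)
  entries <- initial_nodes(graph)
  S <- stats::setNames(numeric(length(ids)), ids)
  it <- 0L
  converged <- FALSE
  while (it < 10L * max_iter) {
    it <- it + 1L
    Snew <- S
    for (v in ids) {
      pa <- character(0)
      for (e in graph$edges) if (e[2] == v) pa <- c(pa, e[1])
      signals <- S[pa]
      if (v %in% entries) signals <- c(signals, 1)
      Snew[v] <- if (length(signals)) n[[v]] * (1 - prod(1 - signals)) else 0
    }
    delta <- max(abs(Snew - S))
    S <- Snew
    if (delta == 0 || delta < tol) { converged <- TRUE; break }
  }
  structure(list(S = S, iterations = it, converged = converged),
            class = "metab_propagation_state")
}

#' Write a full synthetic dataset to a directory
#'
#' Produces `modules.json`, `expr.tsv`, `design.tsv`, `surv.tsv` and
#' `truth.json`, all loadable by the package's readers.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param survival_module module id for the survival link (default: first
#'   module).
#' @return invisibly, a list with the generated objects.
#' @export
write_simulation <- function(config, out_dir, survival_module = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mset <- generate_module_set(config)
  ds <- generate_expression(mset, config)
  act <- activity_matrix(mset, ds$expr)
  if (is.null(survival_module)) survival_module <- names(mset$graphs)[1]
  surv <- generate_survival(act, survival_module, config$hazard_coef,
                            seed = config$seed + 2L,
                            censor_rate = config$censor_rate)
  write_module_set(mset, file.path(out_dir, "modules.json"))
  write_expression(ds$expr, file.path(out_dir, "expr.tsv"))
  write_design(ds$design, file.path(out_dir, "design.tsv"))
  utils::write.table(surv, file.path(out_dir, "surv.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ds$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(mset = mset, expr = ds$expr, design = ds$design,
                 truth = ds$truth, act = act, surv = surv))
}
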