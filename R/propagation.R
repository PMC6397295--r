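#' Catalytic activity of one reaction node
#'
#' Combines the \[0,1\] expression values of a node's genes into the node
#' activity n_i. Within a complex group all subunits are required, so the
#' group scores the minimum of its measured genes (AND); a single group
#' scores its gene's value. Alternative groups are isoenzymes and combine as
#' a probabilistic OR: `1 - prod(1 - score_g)`. Genes absent from the
#' expression column are dropped from their group; a group with no measured
#' gene is dropped; a node left with no scorable group (including nodes with
#' no annotation at all, e.g. spontaneous reactions) is permissive and
#' returns 1 with a warning.
#'
#' @param node a [reaction_node()].
#' @param expr_column named numeric vector, gene -> value in \[0,1\].
#' @param complex_rule how a complex combines subunits: `"min"` (default) or
#'   `"mean"`.
#' @param group_rule how alternative groups combine: `"or"` (default,
#'   probabilistic OR), `"max"` or `"mean"`.
#' @return the node activity, a number in \[0,1\].
#' @export
node_activity <- function(node, expr_column,
                          complex_rule = c("min", "mean"),
                          group_rule = c("or", "max", "mean")) {
  complex_rule <- match.arg(complex_rule)
  group_rule <- match.arg(group_rule)
  scores <- numeric(0)
  for (gr in node$groups) {
    vals <- expr_column[gr$genes]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) next
    scores <- c(scores, if (gr$semantics == "complex") {
      if (complex_rule == "min") min(vals) else mean(vals)
    } else vals[[1]])
  }
  if (length(scores) == 0L) {
    warning(sprintf("node '%s' has no measurable gene group; treated as permissive (n = 1)",
                    node$node_id))
    return(1)
  }
  switch(group_rule,
         or = 1 - prod(1 - scores),
         max = max(scores),
         mean = mean(scores))
}

# Node activities for all nodes of a graph, without per-node warnings;
# returns the vector plus which nodes fell back to the permissive value.
node_activity_vector <- function(graph, expr_column,
                                 complex_rule = "min", group_rule = "or") {
  ids <- node_ids(graph)
  n <- numeric(length(ids))
  permissive <- logical(length(ids))
  for (k in seq_along(ids)) {
    nd <- graph$nodes[[k]]
    val <- withCallingHandlers(
      node_activity(nd, expr_column, complex_rule, group_rule),
      warning = function(w) invokeRestart("muffleWarning"))
    n[k] <- val
    permissive[k] <- length(nd$groups) == 0L ||
      !any(unlist(lapply(nd$groups, `[[`, "genes")) %in% names(expr_column))
  }
  names(n) <- ids
  attr(n, "permissive_nodes") <- ids[permissive]
  n
}

#' Propagate node activities through a module graph
#'
#' Implements the recursive propagation rule
#' `S_i = n_i * (1 - prod_{a in A_i} (1 - s_a))`, where `A_i` collects the
#' signals arriving at node i (the S values of its parent nodes). Entry
#' nodes receive one additional virtual incoming signal of 1, so an entry
#' node's propagated activity equals its own node activity (an absent entry
#' enzyme still blocks the chain). Acyclic graphs are evaluated in a single
#' topological pass; cyclic graphs are solved by synchronous fixed-point
#' iteration from the all-zero state, which converges monotonically to the
#' least fixed point.
#'
#' @param graph a validated `metab_module_graph`.
#' @param n named numeric vector of node activities in \[0,1\] covering all
#'   nodes (see [node_activity()]).
#' @param tol convergence tolerance on `max |S_new - S_old|` for cyclic
#'   graphs (default 1e-9).
#' @param max_iter iteration cap for cyclic graphs (default 1000).
#' @return an object of class `metab_propagation_state`: list with `S`
#'   (named vector of propagated activities), `iterations`, `converged`.
#' @export
propagate <- function(graph, n, tol = 1e-9, max_iter = 1000L) {
  ids <- node_ids(graph)
  if (!all(ids %in% names(n)))
    stop("node activity vector does not cover all nodes")
  n <- n[ids]
  if (any(n < 0 | n > 1)) stop("node activities must lie in [0,1]")
  parents <- attr(graph, "parents")
  entries <- initial_nodes(graph)
  is_entry <- ids %in% entries

  if (!attr(graph, "cyclic")) {
    S <- stats::setNames(numeric(length(ids)), ids)
    for (v in attr(graph, "topo_order")) {
      pa <- parents[[v]]
      inprod <- if (length(pa)) prod(1 - S[pa]) else 1
      if (v %in% entries) inprod <- 0        # virtual unit input
      S[v] <- n[[v]] * (1 - inprod)
    }
    state <- list(S = S, iterations = 1L, converged = TRUE)
  } else {
    S <- stats::setNames(numeric(length(ids)), ids)
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      Snew <- S
      for (k in seq_along(ids)) {
        pa <- parents[[ids[k]]]
        inprod <- if (length(pa)) prod(1 - S[pa]) else 1
        if (is_entry[k]) inprod <- 0
        Snew[k] <- n[[k]] * (1 - inprod)
      }
      delta <- max(abs(Snew - S))
      S <- Snew
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf("module '%s': propagation did not converge within %d iterations",
                   graph$module_id, max_iter))
    state <- list(S = S, iterations = it, converged = TRUE)
  }
  class(state) <- "metab_propagation_state"
  state
}

#' Module activity from a converged propagation state
#'
#' The module's activity is the propagated activity at its terminal node(s):
#' the S value of the single terminal, or the mean (default) or minimum of
#' several terminal S values.
#'
#' @param graph a validated `metab_module_graph`.
#' @param state a `metab_propagation_state` from [propagate()].
#' @param terminal_rule `"mean"` (default) or `"min"` for multi-terminal
#'   modules.
#' @return a number in \[0,1\], with the rule used attached as attribute
#'   `terminal_rule`.
#' @export
module_activity <- function(graph, state, terminal_rule = c("mean", "min")) {
  terminal_rule <- match.arg(terminal_rule)
  term <- terminal_nodes(graph)
  vals <- state$S[term]
  out <- if (length(vals) == 1L) unname(vals)
         else if (terminal_rule == "mean") mean(vals) else min(vals)
  attr(out, "terminal_rule") <- terminal_rule
  out
}

#' Module x sample activity matrix
#'
#' Runs the full inference for every module and every sample: node
#' activities from the sample's expression column, propagation through the
#' module graph, summary at the terminal node(s). Column s of the result
#' depends only on column s of the expression matrix.
#'
#' @param mset a [module_set()].
#' @param expr rescaled genes x samples matrix, all values in \[0,1\].
#' @param terminal_rule,complex_rule,group_rule see [module_activity()] and
#'   [node_activity()].
#' @param tol,max_iter passed to [propagate()].
#' @return a modules x samples numeric matrix in \[0,1\] with attribute
#'   `coverage`: per module, the fraction of annotated genes measured, the
#'   permissive nodes triggered, and the terminal rule used (see
#'   [activity_coverage()]).
#' @export
activity_matrix <- function(mset, expr, terminal_rule = c("mean", "min"),
                            complex_rule = "min", group_rule = "or",
                            tol = 1e-9, max_iter = 1000L) {
  terminal_rule <- match.arg(terminal_rule)
  stopifnot(inherits(mset, "metab_module_set"), is.matrix(expr))
  if (any(expr < 0 | expr > 1, na.rm = TRUE))
    stop("expression must be rescaled to [0,1] (see rescale_expression)")
  mids <- names(mset$graphs)
  samples <- colnames(expr)
  act <- matrix(NA_real_, length(mids), length(samples),
                dimnames = list(mids, samples))
  coverage <- vector("list", length(mids))
  names(coverage) <- mids
  for (m in mids) {
    g <- mset$graphs[[m]]
    genes <- module_genes(g)
    measured <- intersect(genes, rownames(expr))
    perm <- character(0)
    for (s in seq_along(samples)) {
      col <- expr[measured, s]
      names(col) <- measured
      n <- node_activity_vector(g, col, complex_rule, group_rule)
      if (s == 1L) perm <- attr(n, "permissive_nodes")
      st <- propagate(g, n, tol = tol, max_iter = max_iter)
      act[m, s] <- module_activity(g, st, terminal_rule)
    }
    coverage[[m]] <- list(
      measured_gene_fraction = if (length(genes)) length(measured) / length(genes) else NA_real_,
      permissive_nodes = perm,
      fully_unmeasured = length(genes) > 0 && length(measured) == 0,
      terminal_rule = terminal_rule)
  }
  attr(act, "coverage") <- coverage
  act
}

#' Coverage report of an activity matrix
#' @param act result of [activity_matrix()].
#' @return named list, one entry per module: `measured_gene_fraction`,
#'   `permissive_nodes`, `fully_unmeasured`, `terminal_rule`.
#' @export
activity_coverage <- function(act) attr(act, "coverage")

#' Write an activity matrix (and its coverage report) to disk
#' @param act modules x samples matrix from [activity_matrix()].
#' @param path output TSV path (header `module<TAB>samples...`).
#' @param coverage_path optional path for the JSON coverage report.
#' @return `path`, invisibly.
#' @export
write_activity <- function(act, path, coverage_path = NULL) {
  df <- data.frame(module = rownames(act), act, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coverage_path)) {
    cov <- activity_coverage(act)
    if (!is.null(cov))
      jsonlite::write_json(cov, coverage_path, auto_unbox = TRUE, digits = NA,
                           null = "null")
  }
  invisible(path)
}

#' Read an activity matrix written by [write_activity()]
#' @param path TSV path.
#' @return modules x samples numeric matrix.
#' @export
read_activity <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  mat <- as.matrix(df[-1])
  rownames(mat) <- as.character(df[[1]])
  mat
}
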