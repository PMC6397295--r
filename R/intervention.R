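# In-silico interventions: gene knock-outs, over-expressions and drug-target
# effects on the [0,1] expression scale, and the automatic search for the
# single-gene KO that best reverts one class's metabolic profile towards
# another.

#' Build an intervention specification
#'
#' One action per gene. Actions: `ko_hard` sets expression to 0, `ko_soft`
#' multiplies it by 0.01 (the soft knock-out used by the automatic search),
#' `overexpress` sets it to 1, `scale` multiplies by `value`, `set` assigns
#' `value` directly. Results are clipped to \[0,1\].
#'
#' @param genes character vector of gene ids (unique).
#' @param actions character vector (recycled) of actions.
#' @param values numeric vector (recycled) used by `scale` and `set`.
#' @return a data.frame of class `metab_intervention` with columns `gene`,
#'   `action`, `value`.
#' @export
intervention_spec <- function(genes, actions = "ko_hard", values = NA_real_) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop(sprintf("one action per gene: '%s' listed twice",
                 genes[duplicated(genes)][1]))
  actions <- rep_len(as.character(actions), length(genes))
  values <- rep_len(as.numeric(values), length(genes))
  ok <- c("ko_hard", "ko_soft", "overexpress", "scale", "set")
  bad <- setdiff(actions, ok)
  if (length(bad)) stop(sprintf("unknown action '%s'", bad[1]))
  if (any(actions == "set" & (is.na(values) | values < 0 | values > 1)))
    stop("'set' requires a value in [0,1]")
  if (any(actions == "scale" & is.na(values)))
    stop("'scale' requires a numeric factor")
  structure(data.frame(gene = genes, action = actions, value = values,
                       stringsAsFactors = FALSE),
            class = c("metab_intervention", "data.frame"))
}

#' Apply an intervention to an expression matrix
#'
#' @param expr rescaled genes x samples matrix.
#' @param spec a [intervention_spec()].
#' @param samples sample ids to modify (default: all). Genes of the spec
#'   absent from the matrix are skipped with a warning.
#' @return a modified copy of `expr`, values clipped to \[0,1\].
#' @export
apply_intervention <- function(expr, spec, samples = colnames(expr)) {
  stopifnot(is.matrix(expr))
  if (length(samples) == 0L) stop("empty sample subset")
  miss <- setdiff(samples, colnames(expr))
  if (length(miss))
    stop(sprintf("unknown sample '%s'", miss[1]))
  absent <- setdiff(spec$gene, rownames(expr))
  if (length(absent))
    warning(sprintf("%d intervention gene(s) absent from the expression matrix, skipped: %s",
                    length(absent), paste(utils::head(absent, 5), collapse = ", ")))
  out <- expr
  for (i in seq_len(nrow(spec))) {
    g <- spec$gene[i]
    if (g %in% absent) next
    x <- out[g, samples]
    x <- switch(spec$action[i],
                ko_hard = 0 * x,
                ko_soft = x * 0.01,
                overexpress = 0 * x + 1,
                scale = x * spec$value[i],
                set = 0 * x + spec$value[i])
    out[g, samples] <- pmin(pmax(x, 0), 1)
  }
  out
}

#' Module-activity fold changes caused by an intervention in one sample
#'
#' Recomputes every module's activity after applying `spec` to one sample
#' column and reports the before/after activities and their fold change.
#' Only two single conditions are compared, so no statistical test applies;
#' instead modules crossing the fold-change threshold are flagged. A
#' pseudo-activity of `eps` is added to numerator and denominator so
#' zero-activity baselines yield finite fold changes.
#'
#' @param mset a [module_set()].
#' @param expr_column named numeric vector (gene -> value in \[0,1\]) or a
#'   one-column matrix: the baseline sample.
#' @param spec a [intervention_spec()].
#' @param threshold fold-change threshold (> 1, default 2): flagged when
#'   `fold_change >= threshold` or `<= 1/threshold`.
#' @param eps pseudo-activity (default 1e-6).
#' @param ... passed to [activity_matrix()].
#' @return data.frame sorted by `|log2(fold_change)|` descending with
#'   columns `module_id`, `activity_before`, `activity_after`,
#'   `fold_change`, `flagged`.
#' @export
ko_effect <- function(mset, expr_column, spec, threshold = 2, eps = 1e-6,
                      ...) {
  if (threshold <= 1) stop("threshold must be > 1")
  if (is.matrix(expr_column)) {
    stopifnot(ncol(expr_column) == 1L)
    expr_column <- stats::setNames(expr_column[, 1], rownames(expr_column))
  }
  expr <- matrix(expr_column, ncol = 1,
                 dimnames = list(names(expr_column), "sample"))
  before <- activity_matrix(mset, expr, ...)[, 1]
  after <- activity_matrix(
    mset, suppressWarnings(apply_intervention(expr, spec)), ...)[, 1]
  fc <- (after + eps) / (before + eps)
  out <- data.frame(module_id = names(mset$graphs),
                    activity_before = unname(before),
                    activity_after = unname(after),
                    fold_change = unname(fc),
                    flagged = unname(fc >= threshold | fc <= 1 / threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(log2(out$fold_change)), out$module_id), ]
  rownames(out) <- NULL
  out
}

#' Read a drug -> target-genes map from TSV
#'
#' Three columns, no header: drug name, gene id, effect (`inhibit` or
#' `activate`).
#'
#' @param path path to a tab-delimited file.
#' @return a data.frame with columns `drug`, `gene`, `effect`.
#' @export
read_drug_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("drug map '%s' does not exist", path))
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3L) stop("drug map TSV needs columns: drug, gene, effect")
  names(df)[1:3] <- c("drug", "gene", "effect")
  bad <- setdiff(df$effect, c("inhibit", "activate"))
  if (length(bad)) stop(sprintf("unknown drug effect '%s'", bad[1]))
  df[1:3]
}

#' Simulated effect of drugs on module activities
#'
#' Expands each drug into gene actions (`inhibit` -> `ko_soft`,
#' `activate` -> `overexpress`), merges them with any extra gene actions,
#' and delegates to [ko_effect()]. A gene targeted both by a drug and in
#' `extra_spec` keeps the `extra_spec` action.
#'
#' @param mset a [module_set()].
#' @param expr_column baseline sample (see [ko_effect()]).
#' @param drugs character vector of drug names, all present in `drug_map`.
#' @param drug_map data.frame from [read_drug_map()].
#' @param threshold fold-change threshold (default 2).
#' @param extra_spec optional [intervention_spec()] merged in.
#' @param ... passed to [ko_effect()].
#' @return as [ko_effect()].
#' @export
drug_effect <- function(mset, expr_column, drugs, drug_map, threshold = 2,
                        extra_spec = NULL, ...) {
  unknown <- setdiff(drugs, drug_map$drug)
  if (length(unknown))
    stop(sprintf("unknown drug '%s' (not in the drug-target map)", unknown[1]))
  rows <- drug_map[drug_map$drug %in% drugs, ]
  genes <- rows$gene
  actions <- ifelse(rows$effect == "inhibit", "ko_soft", "overexpress")
  keep <- !duplicated(genes)
  genes <- genes[keep]; actions <- actions[keep]
  if (!is.null(extra_spec)) {
    drop <- genes %in% extra_spec$gene
    genes <- c(extra_spec$gene, genes[!drop])
    actions <- c(extra_spec$action, actions[!drop])
    values <- c(extra_spec$value, rep(NA_real_, sum(!drop)))
  } else values <- NA_real_
  spec <- intervention_spec(genes, actions, values)
  if (!any(genes %in% mset$gene_universe))
    warning("no targeted gene belongs to any module; nothing can change")
  ko_effect(mset, expr_column, spec, threshold = threshold, ...)
}

# modules whose graphs contain a given gene
modules_with_gene <- function(mset, gene) {
  names(mset$graphs)[vapply(mset$graphs,
                            function(g) gene %in% module_genes(g),
                            logical(1))]
}

#' Automatic search for the optimal knock-out target
#'
#' Finds the single-gene knock-out that makes samples of `source_class`
#' resemble samples of `target_class` the most at the level of their
#' metabolic module-activity profiles. A random forest is trained on the
#' module activities of both classes; then, for every candidate gene, its
#' expression is multiplied by `multiplier` (default 0.01, a soft KO) in all
#' source-class samples, the activities of the modules containing that gene
#' are recomputed, and the classifier re-estimates the mean probability
#' that the modified source samples belong to `target_class`. Genes are
#' ranked by the increase of that probability.
#'
#' @param mset a [module_set()].
#' @param expr rescaled genes x samples matrix.
#' @param design named character vector, sample -> class label.
#' @param source_class class whose samples are intervened (e.g. disease).
#' @param target_class class to resemble (e.g. healthy).
#' @param seed integer seed (forest training is randomized).
#' @param multiplier expression multiplier for the soft KO (default 0.01).
#' @param genes candidate genes (default: the module-set gene universe).
#'   Genes absent from every module have change exactly 0.
#' @param params hyperparameters for the forest (see [train_predictor()]).
#' @param ... passed to [activity_matrix()].
#' @return data.frame of class ranking, sorted by `change` descending (ties
#'   by gene id), with columns `gene`, `p_target_before`, `p_target_after`,
#'   `change`.
#' @export
auto_knockout <- function(mset, expr, design, source_class, target_class,
                          seed = 1L, multiplier = 0.01, genes = NULL,
                          params = list(), ...) {
  design <- design[names(design) %in% colnames(expr)]
  for (cl in c(source_class, target_class))
    if (sum(design == cl) < 2L)
      stop(sprintf("class '%s' needs >= 2 samples", cl))
  if (source_class == target_class)
    stop("source_class and target_class must differ")
  if (is.null(genes)) genes <- mset$gene_universe

  use <- names(design)[design %in% c(source_class, target_class)]
  act <- activity_matrix(mset, expr[, use, drop = FALSE], ...)

  set.seed(as.integer(seed))
  fit <- rf_fit(t(act), design[use],
                ntree = params$ntree %||% 200L, mtry = params$mtry,
                min_node = params$min_node %||% 2L)

  src <- use[design[use] == source_class]
  predict_p_target <- function(a) {
    probs <- rf_predict_prob(fit, t(a))
    mean(probs[, target_class])
  }
  p_before <- predict_p_target(act[, src, drop = FALSE])

  p_after <- vapply(genes, function(g) {
    mods <- modules_with_gene(mset, g)
    if (length(mods) == 0L || !g %in% rownames(expr)) return(p_before)
    spec <- intervention_spec(g, "scale", multiplier)
    expr_ko <- apply_intervention(expr[, src, drop = FALSE], spec)
    sub <- module_set(mset$graphs[mods])
    act_src <- act[, src, drop = FALSE]
    act_src[mods, ] <- activity_matrix(sub, expr_ko, ...)[mods, , drop = FALSE]
    predict_p_target(act_src)
  }, numeric(1))

  out <- data.frame(gene = genes,
                    p_target_before = p_before,
                    p_target_after = unname(p_after),
                    change = unname(p_after) - p_before,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$change, out$gene), ]
  rownames(out) <- NULL
  out
}
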