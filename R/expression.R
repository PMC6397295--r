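#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and a
#' numeric body (empty / `NA` cells are kept as missing and imputed later by
#' [rescale_expression()]). Duplicate gene rows are collapsed by the
#' per-sample maximum with a warning; duplicate sample ids are an error.
#'
#' @param path path to a tab-delimited UTF-8 file.
#' @return a numeric genes x samples matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop(sprintf("expression file '%s' does not exist", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#", na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus >=1 sample")
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample id '%s' in expression header",
                 samples[duplicated(samples)][1]))
  genes <- as.character(df[[1]])
  body <- df[-1]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                     genes[bad[1]], samples[j], col[bad[1]]))
      body[[j]] <- num
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- genes
  colnames(mat) <- samples
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("collapsing %d duplicated gene id(s) by per-sample maximum: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    keep <- unique(genes)
    collapsed <- matrix(NA_real_, length(keep), ncol(mat),
                        dimnames = list(keep, samples))
    for (g in keep) {
      rows <- mat[genes == g, , drop = FALSE]
      collapsed[g, ] <- suppressWarnings(apply(rows, 2, max, na.rm = TRUE))
    }
    collapsed[!is.finite(collapsed)] <- NA_real_   # all-NA columns
    mat <- collapsed
  }
  mat
}

#' Rescale expression to the [0,1] activity scale
#'
#' The propagation model consumes expression on a \[0,1\] scale. Values are
#' optionally `log2(x + 1)` transformed, then rescaled by quantile-truncated
#' min-max: per gene (default) or over the whole matrix, values are clipped
#' at the `truncate_quantiles` quantiles and mapped linearly onto \[0,1\].
#' Constant genes map to 0.5 everywhere. Missing values are ignored during
#' scaling and imputed afterwards with the gene's post-scaling median (0.5
#' when a gene is entirely missing).
#'
#' @param mat numeric genes x samples matrix (as from [read_expression()]).
#' @param log_transform apply `log2(x + 1)` first (inputs must be >= 0).
#' @param truncate_quantiles length-2 numeric in \[0,1\], low < high. The
#'   default `c(0, 0.99)` clips the top 1 percent to resist outlier-driven
#'   compression; use `c(0, 1)` for plain min-max.
#' @param scope `"gene"` (per-gene scaling, default) or `"global"` (one
#'   min/max for the whole matrix).
#' @return a matrix of the same shape with all values in \[0,1\] and no
#'   missing values.
#' @export
rescale_expression <- function(mat, log_transform = FALSE,
                               truncate_quantiles = c(0, 0.99),
                               scope = c("gene", "global")) {
  scope <- match.arg(scope)
  stopifnot(is.matrix(mat), is.numeric(mat))
  q <- truncate_quantiles
  if (length(q) != 2L || any(q < 0) || any(q > 1) || q[1] >= q[2])
    stop("truncate_quantiles must be a pair in [0,1] with low < high")
  if (log_transform) {
    if (any(mat < 0, na.rm = TRUE))
      stop("log_transform requires non-negative expression values")
    mat <- log2(mat + 1)
  }
  scale_vec <- function(x) {
    obs <- x[!is.na(x)]
    if (length(obs) == 0L) return(rep(NA_real_, length(x)))
    lim <- stats::quantile(obs, probs = q, names = FALSE, type = 7)
    if (lim[1] == lim[2]) {
      x[!is.na(x)] <- 0.5
      return(x)
    }
    pmin(pmax((x - lim[1]) / (lim[2] - lim[1]), 0), 1)
  }
  out <- if (scope == "gene") {
    res <- apply(mat, 1, scale_vec)
    if (is.matrix(res)) t(res) else matrix(res, nrow(mat), ncol(mat))
  } else {
    matrix(scale_vec(as.vector(mat)), nrow(mat), ncol(mat))
  }
  dimnames(out) <- dimnames(mat)
  if (anyNA(out)) {
    for (i in seq_len(nrow(out))) {
      miss <- is.na(out[i, ])
      if (any(miss)) {
        med <- stats::median(out[i, !miss])
        out[i, miss] <- if (is.finite(med)) med else 0.5
      }
    }
  }
  out
}

#' Read an experimental design from TSV
#'
#' Two columns, no header: sample id and class label.
#'
#' @param path path to a tab-delimited file.
#' @return a named character vector mapping sample id to class label.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop(sprintf("design file '%s' does not exist", path))
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("design TSV must have two columns: sample, label")
  samples <- as.character(df[[1]])
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample '%s' in design", samples[duplicated(samples)][1]))
  stats::setNames(as.character(df[[2]]), samples)
}

#' Write an expression matrix to TSV
#' @param mat genes x samples matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a design mapping to TSV
#' @param design named character vector (sample -> label).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(data.frame(names(design), unname(design)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
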