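# Class prediction on module-activity profiles.
#
# The classifiers are self-contained: a bagged-CART random forest (Gini
# splits, sqrt-mtry feature subsampling, leaf class proportions averaged
# over trees) and a linear SVM trained with the Pegasos subgradient method,
# with Platt-style sigmoid calibration and one-vs-rest handling for more
# than two classes.

## ---- AUC ----

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' @param scores numeric scores, higher = more positive.
#' @param positive logical vector, TRUE for positive-class observations.
#' @return AUC in \[0,1\]; `NA` if either class is empty.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

## ---- random forest ----

gini_impurity <- function(counts, n) 1 - rowSums((counts / n)^2)

# Best split for one feature at one tree node. Returns c(score, threshold)
# or NULL when the feature is constant.
best_split_feature <- function(x, ymat) {
  o <- order(x)
  xs <- x[o]
  cum <- apply(ymat[o, , drop = FALSE], 2, cumsum)
  if (!is.matrix(cum)) cum <- matrix(cum, nrow = 1)
  n <- length(xs)
  valid <- which(xs[-n] < xs[-1])
  if (length(valid) == 0L) return(NULL)
  nl <- valid
  nr <- n - nl
  left <- cum[valid, , drop = FALSE]
  tot <- cum[n, ]
  right <- sweep(-left, 2, tot, `+`)
  score <- nl / n * gini_impurity(left, nl) + nr / n * gini_impurity(right, nr)
  b <- which.min(score)
  c(score[b], (xs[valid[b]] + xs[valid[b] + 1]) / 2)
}

grow_tree <- function(X, ymat, mtry, min_node, max_depth) {
  var <- integer(0); split <- numeric(0)
  left <- integer(0); right <- integer(0)
  probs <- list()
  new_node <- function() {
    var[length(var) + 1L] <<- 0L
    split[length(split) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L
    right[length(right) + 1L] <<- 0L
    probs[[length(var)]] <<- NULL
    length(var)
  }
  build <- function(idx, depth) {
    id <- new_node()
    counts <- colSums(ymat[idx, , drop = FALSE])
    pure <- sum(counts > 0) <= 1L
    if (!pure && length(idx) >= min_node && depth < max_depth) {
      feats <- sample.int(ncol(X), min(mtry, ncol(X)))
      best <- NULL; bestf <- NA_integer_
      for (j in feats) {
        cand <- best_split_feature(X[idx, j], ymat[idx, , drop = FALSE])
        if (!is.null(cand) && (is.null(best) || cand[1] < best[1])) {
          best <- cand; bestf <- j
        }
      }
      if (!is.null(best)) {
        go_left <- X[idx, bestf] <= best[2]
        var[id] <<- bestf
        split[id] <<- best[2]
        left[id] <<- build(idx[go_left], depth + 1L)
        right[id] <<- build(idx[!go_left], depth + 1L)
        return(id)
      }
    }
    probs[[id]] <<- counts / sum(counts)
    id
  }
  build(seq_len(nrow(X)), 0L)
  list(var = var, split = split, left = left, right = right, probs = probs)
}

rf_fit <- function(X, y, ntree = 200L, mtry = NULL, min_node = 2L,
                   max_depth = 25L) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  ymat <- stats::model.matrix(~ y - 1)
  colnames(ymat) <- classes
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  trees <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- grow_tree(X[boot, , drop = FALSE],
                            ymat[boot, , drop = FALSE],
                            mtry, min_node, max_depth)
  }
  list(trees = trees, classes = classes, ntree = ntree)
}

tree_predict <- function(tree, X) {
  n <- nrow(X)
  leaf_ids <- which(tree$var == 0L)
  k <- length(tree$probs[[leaf_ids[1]]])
  out <- matrix(0, n, k)
  node <- rep(1L, n)
  repeat {
    at_leaf <- tree$var[node] == 0L
    if (all(at_leaf)) break
    act <- which(!at_leaf)
    nd <- node[act]
    goes_left <- X[cbind(act, tree$var[nd])] <= tree$split[nd]
    node[act] <- ifelse(goes_left, tree$left[nd], tree$right[nd])
  }
  for (id in unique(node))
    out[node == id, ] <- matrix(tree$probs[[id]], sum(node == id), k,
                                byrow = TRUE)
  out
}

rf_predict_prob <- function(fit, X) {
  k <- length(fit$classes)
  acc <- matrix(0, nrow(X), k)
  for (tree in fit$trees) acc <- acc + tree_predict(tree, X)
  acc <- acc / fit$ntree
  colnames(acc) <- fit$classes
  rownames(acc) <- rownames(X)
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- linear SVM (Pegasos + Platt) ----

pegasos_fit <- function(X, y01, lambda = 0.01, epochs = 40L) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0
  t <- 0L
  for (e in seq_len(epochs)) {
    for (i in sample.int(n, n)) {
      t <- t + 1L
      eta <- 1 / (lambda * t)
      margin <- y[i] * (sum(w * X[i, ]) + b)
      w <- (1 - eta * lambda) * w
      if (margin < 1) {
        w <- w + eta * y[i] * X[i, ]
        b <- b + eta * y[i] * 0.1
      }
    }
  }
  list(w = w, b = b)
}

platt_fit <- function(dec, y01) {
  # regularized sigmoid fit; robust to perfect separation
  fit <- suppressWarnings(stats::glm(y01 ~ dec, family = stats::binomial()))
  unname(stats::coef(fit))
}

svm_fit <- function(X, y, lambda = 0.01, epochs = 40L) {
  y <- droplevels(as.factor(y))
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    y01 <- as.integer(y == cl)
    m <- pegasos_fit(X, y01, lambda, epochs)
    dec <- as.vector(X %*% m$w + m$b)
    m$platt <- platt_fit(dec, y01)
    m
  })
  names(models) <- classes
  list(models = models, classes = classes)
}

svm_predict_prob <- function(fit, X) {
  probs <- vapply(fit$classes, function(cl) {
    m <- fit$models[[cl]]
    dec <- as.vector(X %*% m$w + m$b)
    eta <- m$platt[1] + m$platt[2] * dec
    1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
  }, numeric(nrow(X)))
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = nrow(X))
  colnames(probs) <- fit$classes
  rownames(probs) <- rownames(X)
  probs / pmax(rowSums(probs), .Machine$double.eps)
}

## ---- training with repeated stratified CV ----

downsample_balance <- function(samples, labels) {
  sizes <- table(labels)
  nmin <- min(sizes)
  unlist(lapply(names(sizes), function(cl) {
    memb <- samples[labels == cl]
    if (length(memb) > nmin) sample(memb, nmin) else memb
  }), use.names = FALSE)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    memb <- which(labels == cl)
    fold[memb[sample.int(length(memb))]] <-
      rep(seq_len(k), length.out = length(memb))
  }
  fold
}

fit_algorithm <- function(algorithm, X, y, params) {
  if (algorithm == "rf")
    rf_fit(X, y, ntree = params$ntree %||% 200L,
           mtry = params$mtry, min_node = params$min_node %||% 2L)
  else
    svm_fit(X, y, lambda = params$lambda %||% 0.01,
            epochs = params$epochs %||% 40L)
}

predict_algorithm <- function(algorithm, fit, X) {
  if (algorithm == "rf") rf_predict_prob(fit, X) else svm_predict_prob(fit, X)
}

macro_auc <- function(probs, y) {
  classes <- colnames(probs)
  if (length(classes) == 2L)
    return(auc_rank(probs[, classes[2]], y == classes[2]))
  mean(vapply(classes, function(cl) auc_rank(probs[, cl], y == cl),
              numeric(1)), na.rm = TRUE)
}

#' Train a class predictor on module activities
#'
#' Fits a random forest or linear SVM on the module-activity profiles of
#' labelled samples and estimates its accuracy by repeated stratified k-fold
#' cross-validation with the ROC AUC (rank formulation) on held-out class
#' probabilities; with more than two classes, AUC is the macro average of
#' one-vs-rest AUCs. By default the majority class is down-sampled to the
#' minority class size, re-drawn independently in each repeat (set
#' `balance_once = TRUE` to freeze one balanced subset). The final model is
#' refit on all (balanced) data. Fully reproducible given `seed`.
#'
#' @param act modules x samples activity matrix.
#' @param design named character vector, sample -> class label (only samples
#'   present in `act` are used).
#' @param algorithm `"rf"` (default) or `"svm"`.
#' @param k folds (default 5); each class needs at least `k` samples.
#' @param repeats cross-validation repeats (default 50; 0 skips CV).
#' @param seed integer seed controlling balancing, folds and model fitting.
#' @param balance down-sample the majority class (default TRUE).
#' @param balance_once freeze a single balanced subset across repeats.
#' @param params optional list of algorithm hyperparameters (`ntree`,
#'   `mtry`, `min_node` for rf; `lambda`, `epochs` for svm).
#' @return a list with `model` (class `metab_predictor`) and `cv` (class
#'   `metab_cv_report`: per-repeat per-fold AUCs plus mean, sd, median, mad).
#' @export
train_predictor <- function(act, design, algorithm = c("rf", "svm"),
                            k = 5L, repeats = 50L, seed = 1L,
                            balance = TRUE, balance_once = FALSE,
                            params = list()) {
  algorithm <- match.arg(algorithm)
  if (k < 2L) stop("k must be >= 2")
  design <- design[names(design) %in% colnames(act)]
  if (length(unique(design)) < 2L) stop("need >= 2 classes to train")
  sizes <- table(design)
  if (any(sizes < k))
    stop(sprintf("class '%s' has %d samples, fewer than k = %d folds",
                 names(sizes)[which.min(sizes)], min(sizes), k))
  set.seed(as.integer(seed))
  X_all <- t(act[, names(design), drop = FALSE])
  classes <- sort(unique(design))

  frozen <- if (balance && balance_once)
    downsample_balance(names(design), design) else NULL

  cv_rows <- NULL
  if (repeats > 0L) {
    cv_rows <- vector("list", repeats * k)
    idx <- 1L
    for (r in seq_len(repeats)) {
      use <- if (!balance) names(design)
             else if (balance_once) frozen
             else downsample_balance(names(design), design)
      y <- design[use]
      X <- X_all[use, , drop = FALSE]
      fold <- stratified_folds(y, k)
      for (f in seq_len(k)) {
        tr <- fold != f
        fit <- fit_algorithm(algorithm, X[tr, , drop = FALSE], y[tr], params)
        probs <- predict_algorithm(algorithm, fit, X[!tr, , drop = FALSE])
        cv_rows[[idx]] <- data.frame(rep = r, fold = f,
                                     auc = macro_auc(probs, y[!tr]))
        idx <- idx + 1L
      }
    }
    cv_rows <- do.call(rbind, cv_rows)
  }

  use <- if (!balance) names(design)
         else if (balance_once) frozen
         else downsample_balance(names(design), design)
  final <- fit_algorithm(algorithm, X_all[use, , drop = FALSE], design[use],
                         params)

  cv <- if (is.null(cv_rows)) NULL else structure(
    list(folds = cv_rows,
         summary = c(mean = mean(cv_rows$auc), sd = stats::sd(cv_rows$auc),
                     median = stats::median(cv_rows$auc),
                     mad = stats::mad(cv_rows$auc))),
    class = "metab_cv_report")

  model <- structure(
    list(algorithm = algorithm, classes = classes,
         feature_ids = rownames(act), fit = final,
         training = list(k = k, repeats = repeats, seed = as.integer(seed),
                         balance = balance, balance_once = balance_once,
                         n_per_class = as.list(sizes), cv = cv),
         version = 1L),
    class = "metab_predictor")
  list(model = model, cv = cv)
}

#' @export
print.metab_cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv report> %d fold evaluations | AUC mean %.3f sd %.3f median %.3f mad %.3f\n",
              nrow(x$folds), s["mean"], s["sd"], s["median"], s["mad"]))
  invisible(x)
}

#' @export
print.metab_predictor <- function(x, ...) {
  cat(sprintf("<predictor> %s, classes: %s, %d features\n",
              x$algorithm, paste(x$classes, collapse = "/"),
              length(x$feature_ids)))
  invisible(x)
}

#' Class probabilities for new samples
#'
#' @param object a `metab_predictor` from [train_predictor()].
#' @param act modules x samples activity matrix containing every feature
#'   module of the model (extra modules are ignored; missing ones are an
#'   error naming them).
#' @param ... unused.
#' @return samples x classes probability matrix; each row sums to 1. An
#'   activity matrix with zero samples yields a 0-row matrix.
#' @export
predict.metab_predictor <- function(object, act, ...) {
  miss <- setdiff(object$feature_ids, rownames(act))
  if (length(miss))
    stop(sprintf("activity matrix is missing %d feature module(s): %s",
                 length(miss), paste(utils::head(miss, 5), collapse = ", ")))
  X <- t(act[object$feature_ids, , drop = FALSE])
  if (nrow(X) == 0L) {
    out <- matrix(numeric(0), 0, length(object$classes),
                  dimnames = list(NULL, object$classes))
    return(out)
  }
  probs <- predict_algorithm(object$algorithm, object$fit, X)
  probs / rowSums(probs)
}

#' Persist / restore a predictor
#'
#' `load_model(save_model(m, path))` predicts identically to `m`.
#'
#' @param model a `metab_predictor`.
#' @param path file path.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "metab_predictor"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path),
                    error = function(e) stop(sprintf(
                      "cannot read model file '%s': corrupted or not a model", path)))
  if (!inherits(model, "metab_predictor"))
    stop(sprintf("file '%s' does not contain a predictor model", path))
  if (!identical(model$version, 1L))
    stop(sprintf("model version mismatch in '%s' (got %s, expected 1)",
                 path, format(model$version)))
  model
}
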