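#' Classifiers used for loneliness prediction
#'
#' Two supervised models are used throughout the pipeline: a CART-style
#' decision tree whose splits minimise Gini impurity, and a
#' gradient-boosting ensemble of shallow regression trees fit to the
#' logistic loss (Friedman-style, with Newton leaf values). Both expose
#' class-1 probabilities: the tree via leaf class fractions, the ensemble
#' via the boosted logit. Hyperparameters default to values appropriate
#' for cohorts of a few dozen samples.
#'
#' @param kind `"decision_tree"` or `"gradient_boosting"`.
#' @param ... hyperparameter overrides (see [fit_model()] defaults).
#' @param seed integer seed stored with the spec; the fits themselves are
#'   deterministic, the seed is kept so reports can record full provenance.
#' @return An object of class `lw_model_spec`.
#' @examples
#' spec <- model_spec("decision_tree", max_depth = 3)
#' @export
model_spec <- function(kind = c("decision_tree", "gradient_boosting"), ...,
                       seed = 1L) {
  kind <- match.arg(kind)
  hp <- list(...)
  defaults <- if (kind == "decision_tree") {
    list(max_depth = 4L, min_leaf = 2L)
  } else {
    list(n_rounds = 100L, learning_rate = 0.1, max_depth = 3L, min_leaf = 1L)
  }
  bad <- setdiff(names(hp), names(defaults))
  if (length(bad)) stop("unknown hyperparameters: ", paste(bad, collapse = ", "))
  defaults[names(hp)] <- hp
  structure(list(kind = kind, hyperparameters = defaults, seed = as.integer(seed)),
            class = "lw_model_spec")
}

#' Fit a classifier described by a model spec
#'
#' @param spec an [model_spec()] object.
#' @param x numeric feature matrix (samples x features).
#' @param y binary labels (0 = nonlonely, 1 = loneliness).
#' @return A fitted model of class `lw_tree` or `lw_gbm` with elements
#'   `importance` (impurity-decrease importances, normalised to sum 1 when
#'   positive) and `feature_names`.
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "lw_model_spec"))
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y disagree on sample count")
  if (anyNA(x) || anyNA(y)) stop("model matrix contains missing values")
  hp <- spec$hyperparameters
  if (spec$kind == "decision_tree") {
    fit <- .cart_fit(x, y, TRUE, hp$max_depth, hp$min_leaf)
    cls <- "lw_tree"
  } else {
    fit <- .gbm_fit(x, y, hp$n_rounds, hp$learning_rate, hp$max_depth,
                    hp$min_leaf)
    cls <- "lw_gbm"
  }
  imp <- as.numeric(fit$importance)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- colnames(x)
  structure(list(fit = fit, spec = spec, importance = imp,
                 feature_names = colnames(x)),
            class = cls)
}

#' @rdname fit_model
#' @param object fitted model.
#' @param newdata matrix with the same columns the model was fitted on.
#' @param ... unused.
#' @return numeric vector of class-1 probabilities.
#' @export
predict.lw_tree <- function(object, newdata, ...) {
  nd <- align_model_matrix(newdata, object$feature_names)
  as.numeric(.cart_predict(object$fit, nd))
}

#' @rdname fit_model
#' @export
predict.lw_gbm <- function(object, newdata, ...) {
  nd <- align_model_matrix(newdata, object$feature_names)
  as.numeric(.gbm_predict(object$fit, nd))
}

align_model_matrix <- function(newdata, feature_names) {
  nd <- as.matrix(newdata)
  if (!is.null(feature_names) && !is.null(colnames(nd))) {
    if (!all(feature_names %in% colnames(nd)))
      stop("newdata is missing model features")
    nd <- nd[, feature_names, drop = FALSE]
  }
  nd
}

#' Export a fitted decision tree as Graphviz DOT text
#'
#' Internal nodes are labelled with their split rule, leaves with the
#' class fraction of the loneliness class, mirroring the usual published
#' rendering of clinical decision trees.
#'
#' @param model an `lw_tree` fit.
#' @param file optional path; when given the DOT text is written there.
#' @return The DOT source, invisibly when `file` is given.
#' @export
tree_to_dot <- function(model, file = NULL) {
  stopifnot(inherits(model, "lw_tree"))
  t <- model$fit$tree
  fn <- model$feature_names
  lab <- function(i) {
    if (t$feature[i + 1] >= 0) {
      sprintf("\"n%d\" [label=\"%s <= %.4g\\nn=%d\", shape=box];", i,
              fn[t$feature[i + 1] + 1], t$threshold[i + 1], t$n_node[i + 1])
    } else {
      sprintf("\"n%d\" [label=\"p(lonely)=%.3f\\nn=%d\", shape=ellipse];", i,
              t$value[i + 1], t$n_node[i + 1])
    }
  }
  lines <- c("digraph decision_tree {", vapply(seq_along(t$feature) - 1L, lab, ""))
  for (i in seq_along(t$feature) - 1L) {
    if (t$feature[i + 1] >= 0) {
      lines <- c(lines,
                 sprintf("\"n%d\" -> \"n%d\" [label=\"yes\"];", i, t$left[i + 1]),
                 sprintf("\"n%d\" -> \"n%d\" [label=\"no\"];", i, t$right[i + 1]))
    }
  }
  dot <- paste(c(lines, "}"), collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}
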