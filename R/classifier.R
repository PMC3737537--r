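#' Fit a small-RNA locus classifier
#'
#' The front-door fitting function: optional backwards feature elimination
#' followed by a multi-class random forest on the selected features. The
#' returned object supports `print()`, `summary()`, `predict()` and
#' `plot()` (proximity MDS of the training loci).
#'
#' @param x A `smrna_features` table from [build_feature_matrix()] (its
#'   `label` column supplies `y`), or a numeric feature matrix.
#' @param y Class labels when `x` is a matrix.
#' @param select Run backwards feature elimination before the final fit
#'   (default `TRUE`).
#' @inheritParams select_features
#' @return A `smrna_classifier` object with fields `forest`
#'   (`smrna_forest`), `selection` (`smrna_selection` or `NULL`),
#'   `classes`, `seed`, and the training data (for the MDS plot).
#' @export
#' @examples
#' ds <- generate_dataset(n_per_class = 10, seed = 7)
#' fm <- dataset_features(ds)
#' fit <- smrna_classifier(fm, ntree = 100, seed = 7)
#' print(fit)
#' table(truth = fm$label, predicted = predict(fit, fm))
smrna_classifier <- function(x, y = NULL, select = TRUE, ntree = 1000L,
                             mtry_factor = 1, drop_frac = 0.35, se_rule = 1,
                             seed = 1L) {
  d <- as_xy(x, y)
  sel <- NULL
  feats <- colnames(d$x)
  if (select) {
    sel <- select_features(d$x, d$y, drop_frac = drop_frac, ntree = ntree,
                           se_rule = se_rule, mtry_factor = mtry_factor,
                           seed = seed)
    feats <- sel$selected
  }
  forest <- train_forest(d$x[, feats, drop = FALSE], d$y, ntree = ntree,
                         mtry_factor = mtry_factor, seed = seed + 1L)
  structure(list(forest = forest, selection = sel, classes = forest$classes,
                 seed = seed, training = list(x = d$x, y = d$y),
                 call = match.call()),
            class = "smrna_classifier")
}

#' @export
print.smrna_classifier <- function(x, ...) {
  cat("Small RNA locus classifier\n")
  cat("classes:", paste(x$classes, collapse = ", "), "\n")
  cat("features:", length(x$forest$selected_features), "of",
      ncol(x$training$x),
      if (is.null(x$selection)) "(no selection)" else "(backwards elimination)",
      "\n")
  cat(sprintf("OOB error: %.3f (%d trees)\n", x$forest$oob_error,
              x$forest$ntree))
  invisible(x)
}

#' @export
summary.smrna_classifier <- function(object, ...) {
  print(object)
  cat("\nselected features:\n ",
      paste(object$forest$selected_features, collapse = ", "), "\n")
  cat("\nOOB confusion matrix (rows = true):\n")
  print(object$forest$rf$confusion)
  invisible(object)
}

#' @export
predict.smrna_classifier <- function(object, newdata, type = "response", ...) {
  predict(object$forest, newdata, type = type, ...)
}

#' @export
plot.smrna_classifier <- function(x, dims = 2L, ...) {
  emb <- proximity_mds(x$forest, x$training$x, dims = dims,
                       labels = x$training$y)
  plot(emb, ...)
  invisible(emb)
}

#' Save / load a fitted classifier
#'
#' The archive is an RDS file wrapping the model with a manifest (package
#' version, feature names, classes, seed) that is checked on load.
#'
#' @param object A `smrna_classifier`.
#' @param path File path.
#' @return `save_classifier` returns the path invisibly; `load_classifier`
#'   the restored object.
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "smrna_classifier"))
  manifest <- list(package = "smrnaclass",
                   version = as.character(utils::packageVersion("smrnaclass")),
                   features = object$forest$selected_features,
                   classes = object$classes, seed = object$seed)
  saveRDS(list(manifest = manifest, model = object), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$manifest$package, "smrnaclass"))
    stop_("not a smrnaclass model archive: ", path)
  obj$model
}
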