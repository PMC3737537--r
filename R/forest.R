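#' Train a multi-class random forest on locus features
#'
#' @param x A `smrna_features` table or numeric feature matrix.
#' @param y Class labels (ignored when `x` carries a `label` column).
#' @param ntree Number of trees (default 1000).
#' @param mtry Variables tried per split; default
#'   `floor(mtry_factor * sqrt(p))`, capped at `p`.
#' @param mtry_factor Multiplier on `sqrt(p)` (default 1).
#' @param seed RNG seed; the fit is fully reproducible given the seed.
#' @param importance Record permutation importance (default `FALSE`).
#' @param proximity Record the training proximity matrix (default `FALSE`).
#' @return A `smrna_forest` object with fields `rf` (the underlying
#'   [randomForest::randomForest] fit), `ntree`, `mtry`,
#'   `selected_features`, `classes`, `seed` and `oob_error`.
#' @export
train_forest <- function(x, y = NULL, ntree = 1000L, mtry = NULL,
                         mtry_factor = 1, seed = 1L, importance = FALSE,
                         proximity = FALSE) {
  d <- as_xy(x, y)
  if (is.null(d$y)) stop_("class labels are required")
  if (nlevels(d$y) < 2L) stop_("training requires at least two classes")
  small <- table(d$y) < 2L
  if (any(small))
    warning("class(es) with fewer than 2 loci: ",
            paste(names(which(small)), collapse = ", "), call. = FALSE)
  p <- ncol(d$x)
  if (is.null(mtry)) mtry <- max(1L, min(p, floor(mtry_factor * sqrt(p))))
  rf <- with_seed(seed, randomForest::randomForest(
    x = d$x, y = d$y, ntree = ntree, mtry = mtry,
    importance = importance, proximity = proximity))
  structure(list(rf = rf, ntree = ntree, mtry = mtry,
                 selected_features = colnames(d$x),
                 classes = levels(d$y), seed = seed,
                 oob_error = unname(rf$err.rate[ntree, "OOB"])),
            class = "smrna_forest")
}

#' @export
print.smrna_forest <- function(x, ...) {
  cat("Random forest:", length(x$classes), "classes,",
      length(x$selected_features), "features,", x$ntree, "trees (mtry",
      paste0(x$mtry, ")"), "\n")
  cat(sprintf("OOB error: %.3f\n", x$oob_error))
  invisible(x)
}

#' @export
predict.smrna_forest <- function(object, newdata, type = "response", ...) {
  d <- as_xy(newdata)
  miss <- setdiff(object$selected_features, colnames(d$x))
  if (length(miss))
    stop_("newdata is missing feature column(s): ", paste(miss, collapse = ", "))
  predict(object$rf, d$x[, object$selected_features, drop = FALSE],
          type = type, ...)
}

#' Backwards feature elimination over random forests
#'
#' Iteratively fits a forest, ranks features by importance, drops the
#' `floor(drop_frac * p)` least important (at least one), and refits until
#' two features remain. The returned feature set is the smallest one whose
#' out-of-bag (OOB) error is within `se_rule` standard errors of the
#' minimum OOB error across the elimination trace (the one-standard-error
#' rule when `se_rule = 1`).
#'
#' @inheritParams train_forest
#' @param drop_frac Fraction of current features dropped per iteration
#'   (default 0.35).
#' @param se_rule Standard-error multiplier for the final choice (default 1).
#' @param importance_measure `"permutation"` (mean decrease in OOB accuracy,
#'   the default) or `"gini"`.
#' @return A `smrna_selection` object: `selected` (character vector),
#'   `trace` (data.frame of set size and OOB error), `sets` (the nested
#'   feature sets), `seed`.
#' @export
select_features <- function(x, y = NULL, drop_frac = 0.35, ntree = 1000L,
                            se_rule = 1, mtry_factor = 1, seed = 1L,
                            importance_measure = c("permutation", "gini")) {
  importance_measure <- match.arg(importance_measure)
  stopifnot(drop_frac > 0, drop_frac < 1)
  d <- as_xy(x, y)
  if (ncol(d$x) < 2L) stop_("feature selection requires at least 2 features")
  imp_col <- if (importance_measure == "permutation") "MeanDecreaseAccuracy"
             else "MeanDecreaseGini"
  feats <- colnames(d$x)
  sets <- list(); oob <- numeric(); step <- 0L
  repeat {
    step <- step + 1L
    fit <- train_forest(d$x[, feats, drop = FALSE], d$y, ntree = ntree,
                        mtry_factor = mtry_factor, seed = seed + step,
                        importance = TRUE)
    sets[[step]] <- feats
    oob[step] <- fit$oob_error
    if (length(feats) <= 2L) break
    imp <- randomForest::importance(fit$rf)[, imp_col]
    ndrop <- max(1L, floor(drop_frac * length(feats)))
    ndrop <- min(ndrop, length(feats) - 2L)
    feats <- feats[order(-imp)][seq_len(length(feats) - ndrop)]
  }
  n <- length(d$y)
  min_err <- min(oob)
  thr <- min_err + se_rule * sqrt(min_err * (1 - min_err) / n)
  sizes <- lengths(sets)
  chosen <- which(sizes == min(sizes[oob <= thr]))[1]
  structure(list(selected = sets[[chosen]],
                 trace = data.frame(size = sizes, oob_error = oob),
                 sets = sets, threshold = thr, seed = seed),
            class = "smrna_selection")
}

#' @export
print.smrna_selection <- function(x, ...) {
  cat("Backwards elimination:", nrow(x$trace), "steps; selected",
      length(x$selected), "feature(s)\n")
  cat(paste(x$selected, collapse = ", "), "\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Stability of feature selection across repeated runs
#'
#' For each class, the one-vs-rest labelling is re-selected `R` times with
#' different seeds; the report counts how often each feature is selected
#' and attaches the direction of the class effect: the sign of the
#' difference between the feature's mean within the class and its mean in
#' the rest of the data (0 when the means agree within 1e-12).
#'
#' @inheritParams select_features
#' @param R Number of repeated selection runs per class (default 100).
#' @param classes Classes to report on (default all levels of the labels).
#' @param ... Passed to [select_features()].
#' @return A `smrna_stability` object with `counts` and `sign` matrices
#'   (classes x features) and the run count `R`.
#' @export
stability_selection <- function(x, y = NULL, R = 100L, seed = 1L,
                                classes = NULL, ...) {
  stopifnot(is_count(R, 2L))
  d <- as_xy(x, y)
  classes <- classes %||% levels(d$y)
  feats <- colnames(d$x)
  counts <- matrix(0L, length(classes), length(feats),
                   dimnames = list(classes, feats))
  signs <- counts
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    yb <- factor(ifelse(d$y == cls, cls, ".rest"), levels = c(cls, ".rest"))
    for (r in seq_len(R)) {
      sel <- select_features(d$x, yb, seed = seed + (ci - 1L) * 100000L + r * 100L, ...)
      counts[ci, sel$selected] <- counts[ci, sel$selected] + 1L
    }
    delta <- colMeans(d$x[d$y == cls, , drop = FALSE]) -
             colMeans(d$x[d$y != cls, , drop = FALSE])
    signs[ci, ] <- ifelse(abs(delta) <= 1e-12, 0L, sign(delta))
  }
  structure(list(counts = counts, sign = signs, R = R, classes = classes),
            class = "smrna_stability")
}

#' @export
print.smrna_stability <- function(x, ...) {
  cat("Stability selection over", x$R, "runs per class\n")
  cat("selection counts (sign of class effect in parentheses):\n")
  for (cls in x$classes) {
    top <- sort(x$counts[cls, ], decreasing = TRUE)
    top <- top[top > 0]
    top <- head(top, 8)
    cat(sprintf("  %-14s %s\n", cls, paste(
      sprintf("%s=%d(%+d)", names(top), top, x$sign[cls, names(top)]),
      collapse = " ")))
  }
  invisible(x)
}
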