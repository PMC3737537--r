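# Multi-class evaluation: a pooled confusion matrix (rows = true classes,
# columns = predicted) with per-class recall REC_k = TP_k / (TP_k + FN_k),
# positive predictive value PPV_k = TP_k / (TP_k + FP_k), per-class accuracy
# ACC_k = (TP_k + TN_k) / total, and overall accuracy = trace / total.

#' Build an evaluation report from a confusion matrix
#'
#' @param confusion A K x K integer matrix, rows = true classes, columns =
#'   predicted classes, with identical row/column names.
#' @param baseline Optional numeric vector of permuted-label accuracies.
#' @return A `smrna_eval` object: `confusion`, `per_class` (data.frame with
#'   `class, count, TP, FN, FP, TN, recall, ppv, accuracy`),
#'   `overall_accuracy`, `baseline`.
#' @export
evaluation_report <- function(confusion, baseline = NULL) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion),
            identical(rownames(confusion), colnames(confusion)))
  total <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  per_class <- data.frame(
    class = rownames(confusion), count = rowSums(confusion),
    TP = tp, FN = fn, FP = fp, TN = tn,
    recall = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    accuracy = (tp + tn) / total,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(confusion = confusion, per_class = per_class,
                 overall_accuracy = sum(tp) / total, baseline = baseline),
            class = "smrna_eval")
}

#' @export
print.smrna_eval <- function(x, ...) {
  cat("Evaluation over", sum(x$confusion), "loci,",
      nrow(x$confusion), "classes\n")
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * x$overall_accuracy))
  if (!is.null(x$baseline))
    cat(sprintf("permutation baseline: %.1f%% (mean of %d permutations)\n",
                100 * mean(x$baseline), length(x$baseline)))
  df <- x$per_class
  cat("per class:\n")
  print(data.frame(class = df$class, count = df$count,
                   recall = sprintf("%.1f%%", 100 * df$recall),
                   ppv = sprintf("%.1f%%", 100 * df$ppv)),
        row.names = FALSE)
  invisible(x)
}

# Stratified fold assignment; classes smaller than k land in distinct folds
# (leave-one-out within the class).
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in levels(y)) {
      i <- which(y == cls)
      fold[i] <- rep_len(seq_len(k), length(i))[sample.int(length(i))]
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Feature selection can be `"nested"` (re-run inside each training split;
#' the default, which avoids selection bias), `"pooled"` (selection once on
#' the full data before cross-validation, the optimistic legacy behaviour)
#' or `"none"` (all features). Predictions from all held-out folds are
#' pooled into one confusion matrix.
#'
#' @inheritParams train_forest
#' @param k_folds Number of stratified folds (default 10). Classes with
#'   fewer members than folds are effectively leave-one-out and trigger a
#'   warning; classes with a single member are excluded with a warning.
#' @param selection `"nested"`, `"pooled"` or `"none"`.
#' @param drop_frac,se_rule Passed to [select_features()].
#' @return A `smrna_eval` report.
#' @export
cross_validate <- function(x, y = NULL, k_folds = 10L,
                           selection = c("nested", "pooled", "none"),
                           ntree = 1000L, mtry_factor = 1, seed = 1L,
                           drop_frac = 0.35, se_rule = 1) {
  selection <- match.arg(selection)
  stopifnot(is_count(k_folds, 2L))
  d <- as_xy(x, y)
  tab <- table(d$y)
  if (any(tab < 2L)) {
    warning("excluding class(es) with a single locus: ",
            paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
    keep <- d$y %in% names(tab)[tab >= 2L]
    d$x <- d$x[keep, , drop = FALSE]
    d$y <- droplevels(d$y[keep])
    tab <- table(d$y)
  }
  if (nlevels(d$y) < 2L) stop_("cross-validation requires at least two classes")
  if (any(tab < k_folds))
    warning("class(es) with fewer loci than folds (leave-one-out within class): ",
            paste(names(tab)[tab < k_folds], collapse = ", "), call. = FALSE)
  pooled_sel <- if (selection == "pooled")
    select_features(d$x, d$y, drop_frac = drop_frac, ntree = ntree,
                    se_rule = se_rule, mtry_factor = mtry_factor,
                    seed = seed)$selected
  fold <- make_folds(d$y, k_folds, seed)
  pred <- factor(rep(NA_character_, length(d$y)), levels = levels(d$y))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    feats <- switch(selection,
      nested = select_features(d$x[tr, , drop = FALSE], d$y[tr],
                               drop_frac = drop_frac, ntree = ntree,
                               se_rule = se_rule, mtry_factor = mtry_factor,
                               seed = seed + 17L * f)$selected,
      pooled = pooled_sel,
      none = colnames(d$x))
    fit <- train_forest(d$x[tr, feats, drop = FALSE], d$y[tr], ntree = ntree,
                        mtry_factor = mtry_factor, seed = seed + 1000L + f)
    pred[!tr] <- predict(fit, d$x[!tr, feats, drop = FALSE])
  }
  confusion <- table(true = d$y, predicted = pred)
  evaluation_report(unclass(as.matrix(confusion)))
}

#' Permutation baseline accuracy
#'
#' Repeatedly permutes the class labels (class sizes are preserved by
#' construction), runs the same cross-validation pipeline with feature
#' selection disabled, and records the overall accuracy of each run. The
#' mean of the returned accuracies is the chance-level baseline.
#'
#' @inheritParams cross_validate
#' @param n_perms Number of label permutations (default 100).
#' @param ntree Trees per forest; reducible to keep the baseline cheap
#'   (default 1000).
#' @return Numeric vector of permuted-label overall accuracies.
#' @export
permutation_baseline <- function(x, y = NULL, n_perms = 100L, seed = 1L,
                                 k_folds = 10L, ntree = 1000L,
                                 mtry_factor = 1) {
  stopifnot(is_count(n_perms, 1L))
  d <- as_xy(x, y)
  vapply(seq_len(n_perms), function(b) {
    yp <- with_seed(seed + b, sample(d$y))
    cross_validate(d$x, yp, k_folds = k_folds, selection = "none",
                   ntree = ntree, mtry_factor = mtry_factor,
                   seed = seed + 50000L + b)$overall_accuracy
  }, numeric(1))
}

#' Train on one dataset, evaluate on another
#'
#' Feature selection (optional) and training use the training data only;
#' the report is computed from predictions on the test data. Test classes
#' absent from training are dropped with a warning.
#'
#' @param train_x,test_x Feature tables (`smrna_features`) or matrices with
#'   identical feature columns.
#' @param train_y,test_y Labels when matrices are supplied.
#' @param selection `"pooled"` (backwards elimination on the training data,
#'   the default) or `"none"`.
#' @inheritParams cross_validate
#' @return A `smrna_eval` report; the fitted model is attached as
#'   attribute `"model"`.
#' @export
cross_dataset_validate <- function(train_x, test_x, train_y = NULL,
                                   test_y = NULL,
                                   selection = c("pooled", "none"),
                                   ntree = 1000L, mtry_factor = 1,
                                   seed = 1L, drop_frac = 0.35, se_rule = 1) {
  selection <- match.arg(selection)
  tr <- as_xy(train_x, train_y)
  te <- as_xy(test_x, test_y)
  if (!identical(colnames(tr$x), colnames(te$x)))
    stop_("train and test feature columns differ")
  extra <- setdiff(levels(te$y), levels(tr$y))
  if (length(extra)) {
    drop_n <- table(te$y)[extra]
    warning("dropping test class(es) absent from training: ",
            paste(sprintf("%s (%d loci)", extra, drop_n), collapse = ", "),
            call. = FALSE)
    keep <- !te$y %in% extra
    te$x <- te$x[keep, , drop = FALSE]
    te$y <- droplevels(te$y[keep])
  }
  feats <- if (selection == "pooled")
    select_features(tr$x, tr$y, drop_frac = drop_frac, ntree = ntree,
                    se_rule = se_rule, mtry_factor = mtry_factor,
                    seed = seed)$selected
  else colnames(tr$x)
  fit <- train_forest(tr$x[, feats, drop = FALSE], tr$y, ntree = ntree,
                      mtry_factor = mtry_factor, seed = seed + 1L)
  pred <- predict(fit, te$x[, feats, drop = FALSE])
  lev <- levels(tr$y)
  confusion <- table(true = factor(te$y, levels = lev),
                     predicted = factor(pred, levels = lev))
  rep <- evaluation_report(unclass(as.matrix(confusion)))
  attr(rep, "model") <- fit
  rep
}
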