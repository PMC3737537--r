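#' Classical MDS of a random-forest proximity matrix
#'
#' The forest proximity `P[i, j]` is the fraction of trees in which loci
#' `i` and `j` fall in the same terminal node. It is converted to the
#' distance `d = sqrt(1 - P)` and embedded with classical (Torgerson)
#' multidimensional scaling. The embedding quality is reported as the
#' Spearman correlation between embedding distances and `d` (`stress`).
#'
#' @param model A `smrna_forest` from [train_forest()] (or a
#'   `smrna_classifier`).
#' @param x The feature table/matrix the model was trained on.
#' @param dims Number of embedding dimensions, 1-5 (default 2).
#' @param labels Optional class labels stored for plotting.
#' @return A `smrna_mds` object: `points` (n x dims), `eig`, `stress`,
#'   `labels`.
#' @export
proximity_mds <- function(model, x, dims = 2L, labels = NULL) {
  stopifnot(is_count(dims, 1L), dims <= 5L)
  if (inherits(model, "smrna_classifier")) model <- model$forest
  stopifnot(inherits(model, "smrna_forest"))
  d <- as_xy(x)
  if (is.null(labels)) labels <- d$y
  prox <- predict(model$rf,
                  d$x[, model$selected_features, drop = FALSE],
                  proximity = TRUE)$proximity
  mds_from_proximity(prox, dims = dims, labels = labels)
}

#' @describeIn proximity_mds Embed a precomputed proximity matrix.
#' @param proximity A symmetric n x n proximity matrix with unit diagonal.
#' @export
mds_from_proximity <- function(proximity, dims = 2L, labels = NULL) {
  stopifnot(is_count(dims, 1L), dims <= 5L)
  proximity <- as.matrix(proximity)
  stopifnot(nrow(proximity) == ncol(proximity))
  if (dims > nrow(proximity) - 1L)
    stop_("dims must be at most n - 1")
  d <- 1 - proximity
  d[d < 0] <- 0
  d <- sqrt(d)
  diag(d) <- 0
  mds <- cmdscale(as.dist(d), k = dims, eig = TRUE)
  pts <- mds$points
  if (ncol(pts) < dims)  # degenerate geometry: pad with zero coordinates
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  colnames(pts) <- paste0("dim", seq_len(dims))
  stress <- if (nrow(pts) > 2L)
    suppressWarnings(cor(as.numeric(dist(pts)), as.numeric(as.dist(d)),
                         method = "spearman"))
  else NA_real_
  structure(list(points = pts, eig = mds$eig, stress = stress,
                 labels = labels), class = "smrna_mds")
}

#' @export
print.smrna_mds <- function(x, ...) {
  cat("Proximity MDS embedding:", nrow(x$points), "loci in",
      ncol(x$points), "dimension(s)\n")
  if (!is.na(x$stress))
    cat(sprintf("distance rank agreement (Spearman): %.3f\n", x$stress))
  invisible(x)
}

#' @export
plot.smrna_mds <- function(x, ...) {
  pts <- x$points
  if (ncol(pts) < 2L) pts <- cbind(pts, 0)
  col <- 1L
  if (!is.null(x$labels)) col <- as.integer(factor(x$labels))
  plot(pts[, 1], pts[, 2], col = col, pch = 19,
       xlab = "MDS dimension 1", ylab = "MDS dimension 2", ...)
  if (!is.null(x$labels))
    legend("topright", legend = levels(factor(x$labels)),
           col = seq_len(nlevels(factor(x$labels))), pch = 19, cex = 0.8)
  invisible(x)
}
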