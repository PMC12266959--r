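#' Mean per-class annotation accuracy
#'
#' Per class c present in the truth: `accuracy_c = #(correctly predicted c) /
#' #(truly c)`; the summary is the unweighted mean over those classes (macro
#' recall), which is robust to class imbalance. Classes that appear only among
#' predictions do not enter the mean.
#'
#' @param predicted,truth parallel label vectors.
#' @return A list: `per_class` (named numeric) and `mean`.
#' @export
mean_class_accuracy <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length", call. = FALSE)
  if (length(truth) == 0) stop("truth is empty", call. = FALSE)
  classes <- sort(unique(truth))
  per_class <- vapply(classes, function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1))
  list(per_class = per_class, mean = mean(per_class))
}

#' Confusion table
#'
#' @param predicted,truth parallel label vectors.
#' @return An integer matrix, rows = true classes, columns = predicted classes
#'   (the union of both label sets); row sums equal true class counts.
#' @export
confusion_table <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  lev <- sort(union(predicted, truth))
  as.matrix(table(factor(truth, levels = lev), factor(predicted, levels = lev)))
}

#' Silhouette score
#'
#' For each cell i with cluster C_i: a(i) is the mean distance to the other
#' members of C_i; b(i) is the minimum over other clusters of the mean
#' distance to that cluster's members; s(i) = (b - a) / max(a, b), with
#' s(i) = 0 for singleton clusters. The score is the mean of s(i) over all
#' cells. Distances are Euclidean.
#'
#' @param embeddings numeric matrix, cells x d.
#' @param cluster_labels per-cell cluster labels (>= 2 non-empty clusters).
#' @return Scalar in [-1, 1].
#' @export
silhouette_score <- function(embeddings, cluster_labels) {
  X <- as.matrix(embeddings)
  lab <- as.character(cluster_labels)
  if (length(lab) != nrow(X))
    stop("cluster_labels length must match rows of embeddings", call. = FALSE)
  clusters <- unique(lab)
  if (length(clusters) < 2)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  idx_by_cluster <- split(seq_len(nrow(X)), lab)
  sizes <- lengths(idx_by_cluster)
  s <- numeric(nrow(X))
  # mean distance of every cell to every cluster, via column aggregation
  cluster_sums <- vapply(idx_by_cluster,
                         function(ix) rowSums(D[, ix, drop = FALSE]),
                         numeric(nrow(X)))
  for (i in seq_len(nrow(X))) {
    own <- lab[i]
    n_own <- sizes[[own]]
    if (n_own <= 1) { s[i] <- 0; next }
    a <- cluster_sums[i, own] / (n_own - 1)     # excludes d(i,i) = 0
    others <- setdiff(names(idx_by_cluster), own)
    b <- min(cluster_sums[i, others] / sizes[others])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Evaluate a trained model on a simulated or benchmark pair
#'
#' Accuracy is computed on target cells only (Eqs. of macro recall).
#' Silhouette is computed on the combined source+target latent embedding with
#' cell types as clusters, so a high score means the two batches mix while the
#' types separate; a batch-label silhouette is reported as a diagnostic
#' (lower = better mixing). When target truth is missing, accuracy is omitted
#' and the cell-type silhouette falls back to predicted target labels (with a
#' message).
#'
#' @param model a `TrainedModel`.
#' @param source,target the (preprocessed) training datasets.
#' @param truth_target optional character vector of true target cell types;
#'   defaults to `target$labels`.
#' @return An `EvalReport` list: `per_class_accuracy`, `mean_accuracy`,
#'   `silhouette`, `silhouette_batch`, `confusion`, `n_cells`, `predictions`.
#' @export
evaluate_run <- function(model, source, target, truth_target = target$labels) {
  ann <- annotate(model, target)
  pred <- ann$predictions$predicted_type
  Zs <- encode(model, source$matrix)
  Z <- rbind(Zs, ann$embedding)

  if (!is.null(truth_target)) {
    acc <- mean_class_accuracy(pred, truth_target)
    confusion <- confusion_table(pred, truth_target)
    type_labels <- c(source$labels, truth_target)
  } else {
    message("no target truth supplied: accuracy omitted, silhouette uses ",
            "predicted target labels")
    acc <- list(per_class = NULL, mean = NA_real_)
    confusion <- NULL
    type_labels <- c(source$labels, pred)
  }
  batch_labels <- rep(c("source", "target"), c(nrow(Zs), nrow(ann$embedding)))
  structure(
    list(per_class_accuracy = acc$per_class,
         mean_accuracy = acc$mean,
         silhouette = silhouette_score(Z, type_labels),
         silhouette_batch = silhouette_score(Z, batch_labels),
         confusion = confusion,
         n_cells = c(source = nrow(Zs), target = nrow(ann$embedding)),
         predictions = ann$predictions),
    class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport\n")
  if (!is.na(x$mean_accuracy)) {
    cat(sprintf("  mean per-class accuracy: %.4f\n", x$mean_accuracy))
    for (cl in names(x$per_class_accuracy)) {
      cat(sprintf("    %-16s %.4f\n", cl, x$per_class_accuracy[[cl]]))
    }
  }
  cat(sprintf("  silhouette (cell types): %.4f\n", x$silhouette))
  cat(sprintf("  silhouette (batches):    %.4f\n", x$silhouette_batch))
  cat(sprintf("  cells: %d source, %d target\n",
              x$n_cells[["source"]], x$n_cells[["target"]]))
  invisible(x)
}
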