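# Thin R surface over the compiled k-nearest-neighbour kernel.

#' Fit a slice kNN classifier
#'
#' Stores the training feature vectors, their labels and originating track
#' ids. Prediction is majority vote among the `k` nearest training slices by
#' Euclidean distance; label-count ties go to the label with the smaller
#' mean neighbour distance, then to the smaller label; exact distance ties in
#' the neighbour ranking are broken by lower track id, then training order.
#'
#' @param features numeric matrix, one training slice per row.
#' @param labels integer label per slice (0/1 pulse membership in binary
#'   mode, time-after-pulse in interval mode).
#' @param track_ids integer track id per slice.
#' @param k neighbour count (default 20).
#' @return An object of class `knn_model`.
#' @export
knn_model <- function(features, labels, track_ids, k = 20L) {
  features <- as.matrix(features)
  if (nrow(features) < k)
    stop("fewer training slices than k")
  if (length(labels) != nrow(features) || length(track_ids) != nrow(features))
    stop("one label and track id per training slice required")
  structure(list(features = features,
                 labels = as.integer(labels),
                 track_ids = as.integer(track_ids),
                 k = as.integer(k)),
            class = "knn_model")
}

#' Predict labels for query slices
#'
#' @param model a [knn_model()].
#' @param features query feature matrix (or a single feature vector).
#' @return Integer vector of predicted labels.
#' @export
knn_predict <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != ncol(model$features))
    stop("feature dimension mismatch")
  knn_predict_cpp(model$features, model$track_ids, model$labels,
                  features, model$k)
}

#' Nearest-neighbour indices and distances
#'
#' @param model a [knn_model()].
#' @param features query feature matrix.
#' @return List with `idx` (m-by-k matrix of training row indices, nearest
#'   first) and `dist` (matching Euclidean distances).
#' @export
knn_neighbors <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  knn_neighbors_cpp(model$features, model$track_ids, as.matrix(features),
                    model$k)
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("kNN classifier: %d training slices, %d features, k = %d, %d labels\n",
              nrow(x$features), ncol(x$features), x$k,
              length(unique(x$labels))))
  invisible(x)
}
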