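# Train-set-fitted dimensionality reduction: per-feature standardization,
# principal component analysis down to 20 components, and Z-scoring of the
# component scores that feed the network. Fitted once on training data and
# applied frozen to any later matrix, so no test information leaks into the
# transform.

#' Fit the standardize + PCA + Z-score reducer
#'
#' Features are standardized to mean 0 / sd 1 (the 156 raw measures mix mV,
#' ms and mV*ms units, so unscaled PCA would be dominated by area and
#' duration), PCA is fitted on the standardized matrix, and the mean/sd of
#' each retained component score is stored so scores can be Z-scored with
#' training-set parameters. Component signs are fixed so that each loading's
#' largest-magnitude entry is positive.
#'
#' @param train_matrix numeric matrix, n x 156.
#' @param n_components number of components to keep (default 20).
#' @return object of class `ecg_reducer` with fields `feature_means`,
#'   `feature_sds`, `loadings` (156 x n_components, orthonormal columns),
#'   `eigenvalues`, `score_means`, `score_sds`, `n_components`.
#' @export
fit_reducer <- function(train_matrix, n_components = 20) {
  X <- as.matrix(train_matrix)
  n <- nrow(X)
  if (n < n_components + 1)
    stopf("need at least n_components + 1 = %d rows, got %d",
          n_components + 1, n)
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("%d constant feature column(s); their sd set to 1 (no variance to carry)",
          sum(sds == 0))
    sds[sds == 0] <- 1
  }
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(X), paste0("PC", seq_len(k)))
  scores <- Z %*% load
  structure(list(
    feature_means = mu,
    feature_sds = sds,
    loadings = load,
    eigenvalues = pc$sdev[seq_len(k)]^2,
    score_means = colMeans(scores),
    score_sds = apply(scores, 2, stats::sd),
    n_components = k
  ), class = "ecg_reducer")
}

#' Project a feature matrix through a fitted reducer
#'
#' Pure function: standardizes with the stored feature means/sds, projects
#' on the stored loadings, and Z-scores the component scores with the
#' stored training-set score parameters. Never refits on the new data.
#'
#' @param reducer an `ecg_reducer` from [fit_reducer()].
#' @param matrix numeric matrix, m x 156 (same columns as the training
#'   matrix).
#' @return m x n_components score matrix.
#' @export
apply_reducer <- function(reducer, matrix) {
  X <- as.matrix(matrix)
  if (is.null(dim(X)) || ncol(X) != length(reducer$feature_means))
    stopf("expected %d feature columns, got %d",
          length(reducer$feature_means), NCOL(X))
  Z <- sweep(sweep(X, 2, reducer$feature_means), 2, reducer$feature_sds, "/")
  S <- Z %*% reducer$loadings
  sweep(sweep(S, 2, reducer$score_means), 2, reducer$score_sds, "/")
}

#' Explained-variance fractions of a fitted reducer
#'
#' @param reducer an `ecg_reducer`.
#' @return numeric vector: each retained component's share of the total
#'   variance of the standardized features.
#' @export
explained_variance <- function(reducer) {
  reducer$eigenvalues / length(reducer$feature_means)
}

#' @export
print.ecg_reducer <- function(x, ...) {
  cat(sprintf("<ecg_reducer: %d features -> %d components (%.1f%% variance)>\n",
              length(x$feature_means), x$n_components,
              100 * sum(explained_variance(x))))
  invisible(x)
}

#' Serialize / restore a reducer as JSON
#'
#' @param reducer an `ecg_reducer`.
#' @param path JSON file path.
#' @return `read_reducer` returns the restored `ecg_reducer`.
#' @export
write_reducer <- function(reducer, path) {
  obj <- unclass(reducer)
  obj$loadings <- as.vector(reducer$loadings)
  obj$n_features <- length(reducer$feature_means)
  obj$feature_names <- names(reducer$feature_means)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_reducer
#' @export
read_reducer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pc_names <- paste0("PC", seq_len(obj$n_components))
  obj$loadings <- matrix(obj$loadings, nrow = obj$n_features,
                         dimnames = list(obj$feature_names, pc_names))
  names(obj$feature_means) <- obj$feature_names
  names(obj$feature_sds) <- obj$feature_names
  names(obj$score_means) <- pc_names
  names(obj$score_sds) <- pc_names
  obj$n_features <- NULL
  obj$feature_names <- NULL
  structure(obj, class = "ecg_reducer")
}
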