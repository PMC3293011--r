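# Bagged ensemble of single-hidden-layer perceptrons.
#
# Each member is a fully connected feed-forward network with one
# tanh-activated hidden layer (15 nodes by default) and a logistic output,
# trained by full-batch gradient descent on a cross-entropy error with an
# added weight-elimination penalty
#     lambda * sum_w (w^2/w0^2) / (1 + w^2/w0^2)
# over the connection weights (biases excluded). The penalty shrinks small
# weights toward zero while its per-weight contribution saturates at
# lambda, which controls network complexity without forbidding large
# weights outright. Members are trained on bootstrap resamples of the
# training set (bagging) and the ensemble prediction is the arithmetic mean
# of the member outputs.

#' Training configuration for the network ensemble
#'
#' @param lambda weight-elimination coefficient (>= 0).
#' @param w0 weight-elimination scale (> 0); 1 is the natural scale for
#'   Z-scored inputs.
#' @param n_hidden hidden-layer size.
#' @param n_members ensemble size (default 25).
#' @param learning_rate gradient-descent step applied to the mean gradient
#'   (the step is `learning_rate * gradient / n`, so it is independent of
#'   training-set size).
#' @param n_epochs number of full-batch epochs.
#' @param cv_folds folds for [cross_validate()].
#' @param lambda_grid,hidden_grid candidate grids for [cross_validate()].
#' @param seed integer seed from which member seeds are derived.
#' @return object of class `train_config`.
#' @export
train_config <- function(lambda = 0.01, w0 = 1, n_hidden = 15,
                         n_members = 25, learning_rate = 0.5,
                         n_epochs = 300, cv_folds = 5,
                         lambda_grid = c(0.001, 0.01, 0.1),
                         hidden_grid = 15, seed = 1L) {
  if (lambda < 0) stopf("'lambda' must be >= 0")
  if (w0 <= 0) stopf("'w0' must be > 0")
  if (n_members < 1) stopf("'n_members' must be >= 1")
  if (learning_rate <= 0) stopf("'learning_rate' must be > 0")
  if (!length(lambda_grid) || !length(hidden_grid))
    stopf("hyperparameter grids must be non-empty")
  structure(list(lambda = lambda, w0 = w0, n_hidden = as.integer(n_hidden),
                 n_members = as.integer(n_members),
                 learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 cv_folds = as.integer(cv_folds),
                 lambda_grid = lambda_grid, hidden_grid = hidden_grid,
                 seed = as.integer(seed)),
            class = "train_config")
}

init_params <- function(n_inputs, n_hidden, seed) {
  set.seed(seed)
  list(
    W1 = matrix(stats::runif(n_inputs * n_hidden, -0.1, 0.1), n_inputs, n_hidden),
    b1 = stats::runif(n_hidden, -0.1, 0.1),
    W2 = matrix(stats::runif(n_hidden, -0.1, 0.1), n_hidden, 1),
    b2 = stats::runif(1, -0.1, 0.1)
  )
}

#' Forward pass of one network
#'
#' tanh hidden layer, logistic output unit; returns scores in (0, 1).
#'
#' @param params list with W1 (inputs x hidden), b1, W2 (hidden x 1), b2.
#' @param x numeric matrix (m x inputs) or a single input vector.
#' @return numeric vector of m scores.
#' @export
ann_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(x))) stopf("non-finite network input")
  H <- tanh(sweep(x %*% params$W1, 2, params$b1, "+"))
  as.vector(stats::plogis(H %*% params$W2 + params$b2))
}

we_penalty <- function(params, w0) {
  w2 <- c(params$W1^2, params$W2^2) / w0^2
  sum(w2 / (1 + w2))
}

#' Cross-entropy + weight-elimination training loss
#'
#' `sum_i -[t log y + (1-t) log(1-y)] + lambda * sum_w (w^2/w0^2)/(1+w^2/w0^2)`
#' with the sum over the entries of W1 and W2 (biases unpenalized) and
#' outputs clipped to [1e-12, 1 - 1e-12] before the logarithms.
#'
#' @param params network parameters.
#' @param x input matrix (m x inputs).
#' @param targets 0/1 vector of length m.
#' @param lambda,w0 weight-elimination coefficient and scale.
#' @return scalar loss (>= 0).
#' @export
ann_loss <- function(params, x, targets, lambda = 0, w0 = 1) {
  if (!all(targets %in% c(0, 1))) stopf("targets must be 0/1")
  y <- pmin(pmax(ann_forward(params, x), 1e-12), 1 - 1e-12)
  ce <- -sum(targets * log(y) + (1 - targets) * log(1 - y))
  ce + lambda * we_penalty(params, w0)
}

#' Exact gradient of the training loss
#'
#' Backpropagation through the tanh/logistic network plus the
#' weight-elimination derivative `2 w w0^2 / (w^2 + w0^2)^2 * lambda` on the
#' connection weights.
#'
#' @inheritParams ann_loss
#' @return list with the same shapes as `params`.
#' @export
ann_gradient <- function(params, x, targets, lambda = 0, w0 = 1) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(targets %in% c(0, 1))) stopf("targets must be 0/1")
  H <- tanh(sweep(x %*% params$W1, 2, params$b1, "+"))
  y <- as.vector(stats::plogis(H %*% params$W2 + params$b2))
  dz <- y - targets                       # d(sum CE)/dz for logistic output
  dW2 <- crossprod(H, dz)
  db2 <- sum(dz)
  dH <- tcrossprod(dz, params$W2) * (1 - H^2)
  dW1 <- crossprod(x, dH)
  db1 <- colSums(dH)
  pen_grad <- function(w) 2 * w * w0^2 / (w^2 + w0^2)^2
  list(W1 = dW1 + lambda * pen_grad(params$W1),
       b1 = db1,
       W2 = dW2 + lambda * pen_grad(params$W2),
       b2 = db2)
}

#' Train a single ensemble member
#'
#' Initializes all weights and biases uniformly in [-0.1, 0.1] from
#' `member_seed`, then runs full-batch gradient descent with a fixed
#' learning rate applied to the mean gradient for `n_epochs` epochs. The
#' training loss is monitored; a warning is issued if it ever increases
#' (a sign the learning rate is too large for the problem).
#'
#' @param x training score matrix (n x inputs).
#' @param targets 0/1 vector; both classes must be present.
#' @param config a [train_config()].
#' @param member_seed integer seed for this member's initialization.
#' @return network parameter list (class `network_params`) with the final
#'   training loss as attribute `final_loss`.
#' @export
train_member <- function(x, targets, config, member_seed) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(unique(targets)) < 2)
    stopf("training set contains a single class")
  params <- init_params(ncol(x), config$n_hidden, member_seed)
  prev <- Inf
  increased <- FALSE
  for (epoch in seq_len(config$n_epochs)) {
    g <- ann_gradient(params, x, targets, config$lambda, config$w0)
    step <- config$learning_rate / n
    params$W1 <- params$W1 - step * g$W1
    params$b1 <- params$b1 - step * g$b1
    params$W2 <- params$W2 - step * g$W2
    params$b2 <- params$b2 - step * g$b2
    cur <- ann_loss(params, x, targets, config$lambda, config$w0)
    if (cur > prev + 1e-8) increased <- TRUE
    prev <- cur
  }
  if (increased)
    warnf("training loss increased during descent; consider a smaller learning_rate")
  structure(params, class = "network_params", final_loss = prev)
}

#' Bootstrap resample indices
#'
#' `n` draws with replacement from 1..n (bagging resample of the same size
#' as the training set), seeded.
#'
#' @param n training-set size.
#' @param seed integer seed.
#' @return integer vector of length n.
#' @export
bootstrap_sample <- function(n, seed) {
  if (n < 1) stopf("'n' must be >= 1")
  set.seed(seed)
  sample.int(n, n, replace = TRUE)
}

#' Train the bagged ensemble
#'
#' Trains `n_members` networks, each on its own bootstrap resample of the
#' training set with its own derived seed; resamples whose draw happens to
#' contain a single class are redrawn from the next seed stream.
#'
#' @inheritParams train_member
#' @return object of class `ann_ensemble`: `members`, `member_seeds`,
#'   `bootstrap_indices`, `config`.
#' @export
train_ensemble <- function(x, targets, config = train_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(unique(targets)) < 2)
    stopf("training set contains a single class")
  members <- vector("list", config$n_members)
  seeds <- integer(config$n_members)
  indices <- vector("list", config$n_members)
  for (j in seq_len(config$n_members)) {
    k <- j
    repeat {
      bs_seed <- mix_seed(config$seed, 10000 + k)
      idx <- bootstrap_sample(n, bs_seed)
      if (length(unique(targets[idx])) == 2) break
      k <- k + config$n_members   # degenerate resample: move to a new stream
    }
    seeds[j] <- mix_seed(config$seed, 20000 + j)
    indices[[j]] <- idx
    members[[j]] <- train_member(x[idx, , drop = FALSE], targets[idx],
                                 config, seeds[j])
  }
  structure(list(members = members, member_seeds = seeds,
                 bootstrap_indices = indices, config = config),
            class = "ann_ensemble")
}

#' Ensemble prediction
#'
#' Arithmetic mean of the member network outputs; always inside (0, 1).
#'
#' @param object an `ann_ensemble`.
#' @param x score matrix (m x inputs).
#' @param ... unused.
#' @return numeric vector of m ensemble scores.
#' @export
predict.ann_ensemble <- function(object, x, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  member_scores <- vapply(object$members, ann_forward, numeric(nrow(x)), x = x)
  if (is.null(dim(member_scores))) member_scores <- matrix(member_scores, nrow = 1)
  rowMeans(member_scores)
}

#' @export
print.ann_ensemble <- function(x, ...) {
  cat(sprintf("<ann_ensemble: %d members, %d hidden nodes, lambda = %g>\n",
              length(x$members), x$config$n_hidden, x$config$lambda))
  invisible(x)
}

stratified_folds <- function(targets, k, seed) {
  set.seed(seed)
  fold <- integer(length(targets))
  for (cls in unique(targets)) {
    i <- which(targets == cls)
    if (length(i) < k)
      stopf("class %s has fewer members (%d) than folds (%d); stratification impossible",
            cls, length(i), k)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

#' Hyperparameter selection by stratified cross-validation
#'
#' Evaluates every (lambda, n_hidden) grid point by stratified k-fold
#' cross-validation, training one network per fold, and selects the point
#' with the highest mean held-out AUROC. Exact ties are broken toward the
#' larger lambda, then the smaller hidden-layer size (prefer the simpler
#' model).
#'
#' @inheritParams train_member
#' @return list with `lambda`, `n_hidden`, `cv_auroc` and the full `grid`
#'   data frame of mean AUROCs.
#' @export
cross_validate <- function(x, targets, config = train_config()) {
  x <- as.matrix(x)
  if (config$cv_folds < 2) stopf("'cv_folds' must be >= 2")
  fold <- stratified_folds(targets, config$cv_folds,
                           mix_seed(config$seed, 999))
  grid <- expand.grid(lambda = config$lambda_grid,
                      n_hidden = config$hidden_grid)
  grid$auroc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$lambda <- grid$lambda[g]
    cfg$n_hidden <- as.integer(grid$n_hidden[g])
    aucs <- vapply(seq_len(config$cv_folds), function(f) {
      tr <- fold != f
      params <- train_member(x[tr, , drop = FALSE], targets[tr], cfg,
                             mix_seed(config$seed, 3000 + 100 * g + f))
      auroc(scored_cohort(ann_forward(params, x[!tr, , drop = FALSE]),
                          targets[!tr]))
    }, 0)
    grid$auroc[g] <- mean(aucs)
  }
  best <- grid[order(-grid$auroc, -grid$lambda, grid$n_hidden), ][1, ]
  list(lambda = best$lambda, n_hidden = as.integer(best$n_hidden),
       cv_auroc = best$auroc, grid = grid)
}

#' Serialize / restore an ensemble as JSON
#'
#' @param ensemble an `ann_ensemble`.
#' @param path JSON file path.
#' @return `read_ensemble` returns the restored `ann_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  obj <- list(
    config = unclass(ensemble$config),
    member_seeds = ensemble$member_seeds,
    bootstrap_indices = ensemble$bootstrap_indices,
    members = lapply(ensemble$members, function(p) list(
      W1 = as.vector(p$W1), b1 = p$b1, W2 = as.vector(p$W2), b2 = p$b2,
      n_inputs = nrow(p$W1), n_hidden = ncol(p$W1)))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- lapply(seq_len(nrow(obj$members)), function(i) {
    m <- obj$members[i, ]
    structure(list(
      W1 = matrix(unlist(m$W1), m$n_inputs, m$n_hidden),
      b1 = unlist(m$b1),
      W2 = matrix(unlist(m$W2), m$n_hidden, 1),
      b2 = unlist(m$b2)
    ), class = "network_params")
  })
  structure(list(members = members, member_seeds = obj$member_seeds,
                 bootstrap_indices = obj$bootstrap_indices,
                 config = structure(as.list(obj$config), class = "train_config")),
            class = "ann_ensemble")
}
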