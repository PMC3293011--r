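# The network ensemble: forward pass, loss and gradient, member training,
# bagging, prediction and hyperparameter selection.

zero_params <- function(n_in = 20, n_h = 15) {
  list(W1 = matrix(0, n_in, n_h), b1 = rep(0, n_h),
       W2 = matrix(0, n_h, 1), b2 = 0)
}

test_that("forward pass matches the tanh/logistic architecture", {
  p <- zero_params()
  expect_equal(ann_forward(p, rnorm(20)), 0.5)

  p2 <- zero_params(); p2$b2 <- 30
  expect_gt(ann_forward(p2, rnorm(20)), 1 - 1e-9)

  expect_error(ann_forward(p, c(NA, rnorm(19))), "non-finite")

  # hand-computed two-node check
  p3 <- list(W1 = matrix(c(1, -1), 1, 2), b1 = c(0.5, 0), W2 = matrix(c(2, 1), 2, 1), b2 = -0.3)
  x <- matrix(0.7, 1, 1)
  manual <- plogis(2 * tanh(1.2) + tanh(-0.7) - 0.3)
  expect_equal(ann_forward(p3, x), manual)
})

test_that("the loss is cross-entropy plus a bounded weight-elimination penalty", {
  set.seed(10)
  p <- stemiscreen:::init_params(6, 4, 77)
  x <- matrix(rnorm(30), 5, 6)
  t <- c(1, 0, 1, 1, 0)
  y <- ann_forward(p, x)
  expect_equal(ann_loss(p, x, t, lambda = 0),
               -sum(t * log(y) + (1 - t) * log(1 - y)))

  # each penalty term < 1, so total penalty < lambda * #weights
  n_w <- length(p$W1) + length(p$W2)
  pen <- ann_loss(p, x, t, lambda = 3, w0 = 0.5) - ann_loss(p, x, t, lambda = 0, w0 = 0.5)
  expect_lt(pen, 3 * n_w)
  expect_gt(pen, 0)

  # saturating network predicting targets perfectly: loss ~ penalty alone
  psat <- zero_params(2, 2)
  psat$W1[1, 1] <- 50; psat$W2[1, 1] <- 50
  xs <- matrix(c(5, -5), 2, 2)          # first input +/-5 drives the output
  ts <- c(1, 0)
  pen_only <- 2 * ann_loss(psat, xs, ts, 0) # CE part, tiny
  expect_lt(pen_only, 1e-6)
  expect_equal(ann_loss(psat, xs, ts, lambda = 0.7),
               0.7 * (50^2 / (1 + 50^2)) * 2, tolerance = 1e-6)

  expect_error(ann_loss(p, x, c(1, 0, 2, 1, 0)), "0/1")
})

test_that("the analytic gradient matches central finite differences", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    p <- stemiscreen:::init_params(4, 3, seed * 11)
    # move away from the small-weight regime
    p <- lapply(p, function(w) w * 8)
    x <- matrix(rnorm(20), 5, 4)
    t <- rbinom(5, 1, 0.5)
    lam <- 0.4; w0 <- 0.8
    g <- ann_gradient(p, x, t, lam, w0)
    h <- 1e-6
    for (field in c("W1", "b1", "W2", "b2")) {
      w <- p[[field]]
      for (i in seq_along(w)) {
        pp <- p; pp[[field]][i] <- w[i] + h
        pm <- p; pm[[field]][i] <- w[i] - h
        num <- (ann_loss(pp, x, t, lam, w0) - ann_loss(pm, x, t, lam, w0)) / (2 * h)
        expect_equal(g[[field]][i], num,
                     tolerance = 1e-5 * max(1, abs(num)))
      }
    }
  }
})

test_that("the gradient vanishes at the symmetric stationary point", {
  p <- zero_params(6, 4)
  set.seed(20)
  x <- matrix(rnorm(60), 10, 6)
  t <- rep(c(0, 1), 5)
  g <- ann_gradient(p, x, t, lambda = 0)
  expect_lt(max(abs(unlist(g))), 1e-12)
})

test_that("the weight-elimination gradient is odd in the weights", {
  set.seed(30)
  p <- stemiscreen:::init_params(4, 3, 5)
  x <- matrix(rnorm(12), 3, 4)
  t <- c(1, 0, 1)
  pen <- function(q) Map(`-`, ann_gradient(q, x, t, lambda = 2, w0 = 0.7),
                         ann_gradient(q, x, t, lambda = 0, w0 = 0.7))
  gp <- pen(p)
  pneg <- lapply(p, `-`)
  gn <- pen(pneg)
  expect_equal(gn$W1, -gp$W1, tolerance = 1e-10)
  expect_equal(gn$W2, -gp$W2, tolerance = 1e-10)
})

test_that("a member learns separable clusters deterministically", {
  toy <- toy_clusters(200, seed = 6)
  cfg <- train_config(n_epochs = 200)
  m1 <- train_member(toy$x, toy$y, cfg, member_seed = 9)
  acc <- mean((ann_forward(m1, toy$x) > 0.5) == toy$y)
  expect_gte(acc, 0.95)

  m2 <- train_member(toy$x, toy$y, cfg, member_seed = 9)
  expect_identical(unclass(m1), unclass(m2))

  expect_error(train_member(toy$x, rep(1, 200), cfg, 1), "single class")
})

test_that("an overwhelming penalty shrinks every weight below initialization", {
  toy <- toy_clusters(100, seed = 7)
  # learning rate small enough that the penalty-dominated descent contracts
  # (lambda * 2 * lr / n < 1) instead of oscillating
  cfg <- train_config(lambda = 1e6, n_epochs = 200, learning_rate = 2e-5)
  init <- stemiscreen:::init_params(20, cfg$n_hidden, 42)
  m <- suppressWarnings(train_member(toy$x, toy$y, cfg, member_seed = 42))
  expect_lt(max(abs(m$W1)), max(abs(init$W1)))
  expect_lt(max(abs(m$W2)), max(abs(init$W2)))
})

test_that("bootstrap resampling is seeded with the classic unique fraction", {
  expect_equal(bootstrap_sample(1, 5), 1L)
  expect_identical(bootstrap_sample(50, 3), bootstrap_sample(50, 3))
  u <- length(unique(bootstrap_sample(10000, 11))) / 10000
  expect_lt(abs(u - (1 - exp(-1))), 0.02)
})

test_that("the ensemble bags members reproducibly and averages predictions", {
  toy <- toy_clusters(80, seed = 8)
  cfg <- train_config(n_members = 4, n_epochs = 80)
  ens <- train_ensemble(toy$x, toy$y, cfg)
  expect_length(ens$members, 4)
  expect_length(unique(ens$member_seeds), 4)
  expect_true(all(lengths(ens$bootstrap_indices) == 80))

  ens2 <- train_ensemble(toy$x, toy$y, cfg)
  expect_identical(ens$members, ens2$members)

  # single-member ensemble is that member
  cfg1 <- train_config(n_members = 1, n_epochs = 80)
  e1 <- train_ensemble(toy$x, toy$y, cfg1)
  expect_equal(predict(e1, toy$x), ann_forward(e1$members[[1]], toy$x))

  # mean prediction bounded by member extremes and inside (0,1)
  p <- predict(ens, toy$x)
  member_p <- sapply(ens$members, ann_forward, x = toy$x)
  expect_true(all(p >= apply(member_p, 1, min) - 1e-12))
  expect_true(all(p <= apply(member_p, 1, max) + 1e-12))
  expect_true(all(p > 0 & p < 1))
})

test_that("bagging rarely falls below the worst member's discrimination", {
  wins <- 0
  for (seed in 1:20) {
    toy <- toy_clusters(60, sep = 0.35, seed = 100 + seed)
    cfg <- train_config(n_members = 5, n_epochs = 60, seed = seed)
    ens <- train_ensemble(toy$x, toy$y, cfg)
    worst <- min(vapply(ens$members, function(m)
      auroc(scored_cohort(ann_forward(m, toy$x), toy$y)), 0))
    ens_auc <- auroc(scored_cohort(predict(ens, toy$x), toy$y))
    if (ens_auc >= worst) wins <- wins + 1
  }
  expect_gte(wins / 20, 0.9)
})

test_that("cross-validation selects sensible hyperparameters", {
  toy <- toy_clusters(100, seed = 9)
  single <- train_config(lambda_grid = 0.05, hidden_grid = 7, n_epochs = 40)
  sel <- cross_validate(toy$x, toy$y, single)
  expect_equal(sel$lambda, 0.05)
  expect_equal(sel$n_hidden, 7L)

  # a crushing penalty loses to a workable one on separable data
  cfg <- train_config(lambda_grid = c(0.01, 1e9), hidden_grid = 15,
                      n_epochs = 60)
  sel2 <- suppressWarnings(cross_validate(toy$x, toy$y, cfg))
  expect_equal(sel2$lambda, 0.01)
  expect_gt(sel2$cv_auroc, 0.9)

  # pure-noise targets give a null CV AUROC
  set.seed(41)
  xn <- matrix(rnorm(150 * 20), 150, 20)
  yn <- rbinom(150, 1, 0.5)
  seln <- cross_validate(xn, yn, train_config(lambda_grid = 0.05,
                                              hidden_grid = 5, n_epochs = 40))
  expect_lt(abs(seln$cv_auroc - 0.5), 0.1)

  expect_error(cross_validate(toy$x, toy$y,
                              train_config(cv_folds = 1)), "cv_folds")
})

test_that("ensembles survive a JSON round-trip", {
  toy <- toy_clusters(60, seed = 12)
  ens <- train_ensemble(toy$x, toy$y, train_config(n_members = 3, n_epochs = 50))
  p <- tempfile(fileext = ".json")
  write_ensemble(ens, p)
  back <- read_ensemble(p)
  expect_equal(predict(back, toy$x), predict(ens, toy$x), tolerance = 1e-12)
  expect_equal(back$member_seeds, ens$member_seeds)
})
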