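# Fixtures built in code: noise-free generator configs, separable toy
# classification data, and hand-made fiducials for direct measurement tests.

clean_config <- function(n = 4, prevalence = 0, seed = 1, ...) {
  synth_config(n_cases = n, stemi_prevalence = prevalence,
               noise_sd = 0, baseline_wander = c(0, 0), seed = seed, ...)
}

# two Gaussian clusters in 20 dimensions, labels 1/0
toy_clusters <- function(n = 200, sep = 1.5, seed = 1, d = 20) {
  set.seed(seed)
  half <- n %/% 2
  x <- rbind(matrix(stats::rnorm(half * d, sep), half, d),
             matrix(stats::rnorm((n - half) * d, -sep), n - half, d))
  list(x = x, y = rep(c(1, 0), c(half, n - half)))
}

# fiducials for a hand-built single-beat record
manual_fiducials <- function(qrs_on, r_peak, qrs_off, t_end,
                             sampling_rate = 500, n_samples = 1000) {
  structure(list(r_peak = as.integer(r_peak), qrs_on = as.integer(qrs_on),
                 qrs_off = as.integer(qrs_off), t_end = as.integer(t_end),
                 sampling_rate = sampling_rate, n_samples = n_samples),
            class = "fiducial_points")
}

# random scored cohort with both classes
random_cohort <- function(n = 40, seed = 1, p = 0.4, ties = FALSE) {
  set.seed(seed)
  labels <- stats::runif(n) < p
  if (!any(labels)) labels[1] <- TRUE
  if (all(labels)) labels[1] <- FALSE
  scores <- if (ties) sample(seq(0, 1, 0.1), n, replace = TRUE)
            else stats::runif(n)
  scored_cohort(scores, labels)
}

# brute-force AUROC by enumerating all positive-negative pairs
pairs_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}
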