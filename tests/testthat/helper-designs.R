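# Shared fixtures: small designs and simulated data used across tests.

tiny_profile <- function(D = 3, m = 10, seed = 101, h = 0.1) {
  table1_design(D = D, h = h, m = m, seed = seed)
}

# exact PCC of a classifier by enumeration of all 3^l genotype vectors
enumerate_pcc <- function(classifier) {
  profile <- classifier$profile
  l <- classifier$l
  D <- classifier$D
  grid <- as.matrix(expand.grid(rep(list(0:2), l)))
  # P(x | class k) under independent HWE loci
  pcc <- 0
  post <- matrix(0, nrow(grid), D)
  for (k in seq_len(D)) {
    pk <- rep(1, nrow(grid))
    for (j in seq_len(l)) {
      pk <- pk * dbinom(grid[, j], 2, profile$theta[k, j])
    }
    post[, k] <- pk * profile$priors[k]
  }
  cls <- predict(classifier, grid)
  for (k in seq_len(D)) {
    pcc <- pcc + sum(post[cls == k, k])
  }
  pcc
}

# posterior argmax (the Bayes-optimal assignment) by direct computation
enumerate_argmax <- function(profile, l) {
  grid <- as.matrix(expand.grid(rep(list(0:2), l)))
  D <- nrow(profile$theta)
  post <- matrix(0, nrow(grid), D)
  for (k in seq_len(D)) {
    pk <- rep(1, nrow(grid))
    for (j in seq_len(l)) {
      pk <- pk * dbinom(grid[, j], 2, profile$theta[k, j])
    }
    post[, k] <- pk * profile$priors[k]
  }
  list(grid = grid, argmax = max.col(post, ties.method = "first"),
       post = post)
}
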