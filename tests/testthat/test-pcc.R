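test_that("score moments for a single SNP equal the binomial moments", {
  prof <- maf_profile(rbind(0.4, 0.2), priors = c(0.5, 0.5))
  fit <- snp_bayes(prof)
  ap <- gaussian_approx_infty(fit, 1)
  b <- log(0.4 * 0.8 / (0.2 * 0.6))
  expect_equal(ap$mu, b * 0.8)                      # b * E X, theta = 0.4
  expect_equal(ap$Sigma[1, 1], b^2 * 2 * 0.4 * 0.6) # b^2 Var X
})

test_that("orthant probability reduces to the normal tail for two classes", {
  for (mu in c(-1, 0.5, 2)) {
    for (kv in c(-2, 0, 1.3)) {
      ap <- structure(list(mu = mu, Sigma = matrix(4), kvec = kv, ks = 2L,
                           class_k = 1L, variant = "infty"),
                      class = "gaussian_approx")
      expect_equal(orthant_probability(ap),
                   pnorm((kv - mu) / 2, lower.tail = FALSE),
                   tolerance = 1e-6)
    }
  }
})

test_that("independent half-spaces give the product probability", {
  ap <- structure(list(mu = c(0, 0), Sigma = diag(2), kvec = c(0, 0),
                       ks = c(2L, 3L), class_k = 1L, variant = "infty"),
                  class = "gaussian_approx")
  expect_equal(orthant_probability(ap), 0.25, tolerance = 1e-6)
})

test_that("bivariate and trivariate orthants match mvtnorm and Monte Carlo", {
  set.seed(77)
  # random 2-d cases vs a large MC sample
  A <- matrix(c(2, 0.9, 0.9, 1.5), 2)
  mu <- c(0.4, -0.3)
  kv <- c(0.2, -0.5)
  ap <- structure(list(mu = mu, Sigma = A, kvec = kv, ks = c(2L, 3L),
                       class_k = 1L, variant = "infty"),
                  class = "gaussian_approx")
  p <- orthant_probability(ap)
  z <- matrix(rnorm(2e6), ncol = 2) %*% chol(A)
  emp <- mean(z[, 1] + mu[1] > kv[1] & z[, 2] + mu[2] > kv[2])
  expect_lt(abs(p - emp), 3 * sqrt(emp * (1 - emp) / 1e6))
  # 3-d vs mvtnorm directly
  S3 <- matrix(c(2, 1, 0.5, 1, 3, 0.8, 0.5, 0.8, 1.5), 3)
  mu3 <- c(0.3, -0.2, 0.5)
  for (i in 1:4) {
    a <- rnorm(3)
    mine <- snpvus:::orthant_upper_batch(matrix(a, 1), mu3, S3)
    ref <- mvtnorm::pmvnorm(lower = a, upper = rep(Inf, 3), mean = mu3,
                            sigma = S3,
                            algorithm = mvtnorm::Miwa(steps = 256))
    expect_lt(abs(mine - as.numeric(ref)), 1e-6)
  }
})

test_that("degenerate (zero-variance) scores are handled deterministically", {
  ap <- structure(list(mu = c(1, -1), Sigma = matrix(0, 2, 2),
                       kvec = c(0, 0), ks = c(2L, 3L), class_k = 1L,
                       variant = "infty"),
                  class = "gaussian_approx")
  expect_equal(orthant_probability(ap), 0)     # mu2 below its threshold
  ap$mu <- c(1, 1)
  expect_equal(orthant_probability(ap), 1)
})

test_that("approximate PCC matches empirical classification rates", {
  # oracle equivalence across a (D, h, m) grid, 2e4 simulated vectors
  for (spec in list(list(D = 2, h = 0.05, m = 50, seed = 1),
                    list(D = 3, h = 0.05, m = 50, seed = 2),
                    list(D = 3, h = 0.1, m = 100, seed = 3),
                    list(D = 4, h = 0.1, m = 50, seed = 4))) {
    prof <- table1_design(spec$D, spec$h, spec$m, seed = spec$seed)
    fit <- snp_bayes(prof)
    p_apx <- as.numeric(pcc(gaussian_approx_infty(fit)))
    n_mc <- 20000
    g <- simulate_genotypes(prof, n_per_class = ceiling(n_mc / spec$D),
                            seed = spec$seed + 100)
    p_emp <- mean(predict(fit, g) == g$labels)
    se <- sqrt(p_emp * (1 - p_emp) / nrow(g$values))
    expect_lt(abs(p_apx - p_emp), 3 * se + 0.005)
  }
})

test_that("estimation-adjusted PCC approaches the known-theta PCC as n grows", {
  prof <- table1_design(3, h = 0.1, m = 50, seed = 8)
  fit <- snp_bayes(prof)
  p_inf <- as.numeric(pcc(gaussian_approx_infty(fit)))
  p_at <- function(n, conv = "all") {
    des <- study_design(3, 50, n_per_class = n, alpha = 0.1)
    as.numeric(pcc(gaussian_approx_n(prof, des, threshold_snps = conv)))
  }
  for (conv in c("all", "selected")) {
    ps <- vapply(c(25, 50, 100, 400, 1600, 1e6), p_at, 0, conv = conv)
    expect_true(all(diff(ps) > -0.005))      # nondecreasing in n
    expect_true(all(ps <= p_inf + 0.02))     # estimation never helps
    expect_lt(abs(ps[length(ps)] - p_inf), 0.01)   # consistency limit
  }
})

test_that("with no real effects the adjusted PCC sits near chance level", {
  prof <- maf_profile(matrix(0.3, 3, 60))
  des <- study_design(3, 60, n_per_class = 100, alpha = 0.1)
  p <- as.numeric(pcc(gaussian_approx_n(prof, des)))
  # the strict all-pairwise rule leaves some no-winner mass, so the exact
  # chance level sits slightly below 1/3; compare against a simulation of
  # actually-fitted classifiers under the same rule
  set.seed(9)
  accs <- vapply(1:10, function(r) {
    train <- simulate_genotypes(prof, n_per_class = 100)
    fit <- snp_linear(train, alpha = 0.1)
    test <- simulate_genotypes(prof, n_per_class = 300)
    marg <- snpvus:::pairwise_margins(fit, test$values)
    ok <- 0
    for (k in 1:3) {
      rows <- which(test$labels == k)
      mk <- marg[rows, k, -k]
      ok <- ok + sum(mk[, 1] > 0 & mk[, 2] > 0)
    }
    ok / nrow(test$values)
  }, 0)
  expect_lt(abs(mean(accs) - 1 / 3), 0.07)   # near chance
  expect_lt(abs(p - mean(accs)), 0.05)       # approximation tracks truth
})

test_that("pcc is the prior-weighted average of the class rates", {
  prof <- table1_design(3, h = 0.1, m = 30, seed = 9)
  fit <- snp_bayes(prof)
  aps <- gaussian_approx_infty(fit)
  xi <- vapply(aps, orthant_probability, 0)
  expect_equal(as.numeric(pcc(aps)), mean(xi))
  expect_equal(as.numeric(pcc(aps, priors = c(1, 0, 0))), xi[1])
})
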