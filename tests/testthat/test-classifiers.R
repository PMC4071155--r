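test_that("Bayes coefficients and thresholds follow the log-odds formulas", {
  prof <- maf_profile(rbind(rep(0.4, 3), rep(0.2, 3)))
  fit <- snp_bayes(prof)
  expect_equal(fit$b[1, 2, 1], log(0.32 / 0.12))
  expect_equal(fit$b[1, 2, ], -fit$b[2, 1, ])
  expect_equal(fit$K[1, 2], 3 * 2 * log(0.8 / 0.6))
  expect_equal(fit$K[1, 2], -fit$K[2, 1])
  # identical classes: coefficients and thresholds vanish
  same <- maf_profile(rbind(rep(0.3, 4), rep(0.3, 4)))
  fit0 <- snp_bayes(same)
  expect_true(all(fit0$b == 0))
  expect_true(all(fit0$K == 0))
})

test_that("the pairwise rule reproduces the posterior argmax on all 3^l vectors", {
  for (spec in list(list(D = 2, l = 5, seed = 31),
                    list(D = 3, l = 4, seed = 32),
                    list(D = 3, l = 6, seed = 33))) {
    prof <- tiny_profile(D = spec$D, m = spec$l, seed = spec$seed)
    fit <- snp_bayes(prof)
    ref <- enumerate_argmax(prof, spec$l)
    cls <- predict(fit, ref$grid)
    expect_gt(mean(cls == ref$argmax), 0.999)
    # disagreement allowed only where the posterior is (numerically) tied
    disagree <- which(cls != ref$argmax)
    for (i in disagree) {
      top2 <- sort(ref$post[i, ], decreasing = TRUE)[1:2]
      expect_lt(abs(top2[1] - top2[2]) / top2[1], 1e-10)
    }
  }
})

test_that("non-uniform priors shift the rule exactly as the posterior does", {
  prof <- table1_design(3, h = 0.1, m = 4, seed = 35)
  prof$priors <- c(0.6, 0.3, 0.1)
  fit <- snp_bayes(prof)
  ref <- enumerate_argmax(prof, 4)
  expect_equal(as.integer(predict(fit, ref$grid)), ref$argmax)
})

test_that("classification of well-separated data is mostly correct", {
  prof <- table1_design(3, h = 0.15, m = 100, seed = 41)
  fit <- snp_bayes(prof)
  g <- simulate_genotypes(prof, n_per_class = 500, seed = 42)
  acc <- mean(predict(fit, g) == g$labels)
  expect_gt(acc, 0.9)
})

test_that("MLE frequencies count alleles and clip at the boundary", {
  g <- genotype_matrix(rbind(c(1L, 0L), c(2L, 0L)), labels = c(1, 2))
  th <- mle_theta(g)
  expect_equal(th[1, 1], 0.5)           # one sample, one minor allele: 1/2
  expect_equal(th[1, 2], 0.25)          # zero count clipped to 1/(4 n_k)
  expect_equal(th[2, 1], 0.75)          # count 2/2 clipped to 1 - 1/(4 n_k)
  # consistency at scale
  prof <- maf_profile(rbind(0.3, 0.35), priors = c(1, 1))
  big <- simulate_genotypes(prof, n_per_class = 1e4, seed = 44)
  th <- mle_theta(big)
  expect_lt(abs(th[1, 1] - 0.3), 3 * sqrt(0.3 * 0.7 / (2e4)))
})

test_that("Wald test holds its size and matches its analytic power", {
  set.seed(51)
  n <- 200
  reps <- 4000
  # size under H0 at theta = 0.3, alpha = 0.1
  x1 <- matrix(rbinom(reps * n, 2, 0.3), reps)
  x2 <- matrix(rbinom(reps * n, 2, 0.3), reps)
  th1 <- pmin(pmax(rowMeans(x1) / 2, 1 / (4 * n)), 1 - 1 / (4 * n))
  th2 <- pmin(pmax(rowMeans(x2) / 2, 1 / (4 * n)), 1 - 1 / (4 * n))
  rej <- wald_test(th1, th2, n, n, alpha = 0.1)$reject
  expect_lt(abs(mean(rej) - 0.1), 3 * sqrt(0.1 * 0.9 / reps) + 0.01)
  # power at a real effect vs the closed form
  n <- 100
  y1 <- matrix(rbinom(reps * n, 2, 0.45), reps)
  y2 <- matrix(rbinom(reps * n, 2, 0.30), reps)
  t1 <- pmin(pmax(rowMeans(y1) / 2, 1 / (4 * n)), 1 - 1 / (4 * n))
  t2 <- pmin(pmax(rowMeans(y2) / 2, 1 / (4 * n)), 1 - 1 / (4 * n))
  emp <- mean(wald_test(t1, t2, n, n, alpha = 0.1)$reject)
  ana <- wald_power(0.15, 0.45, n, n, alpha = 0.1)
  expect_lt(abs(emp - ana), 0.02 + 2 * sqrt(ana * (1 - ana) / reps))
})

test_that("analytic power has the right limits", {
  expect_equal(wald_power(0, 0.3, 100, 100, alpha = 0.1), 0.1)
  pw <- wald_power(0.05, 0.4, c(50, 200, 800, 3200), c(50, 200, 800, 3200),
                   alpha = 0.1)
  expect_true(all(diff(pw) > 0))
  expect_gt(pw[4], 0.99)
  expect_error(wald_power(0.5, 0.4, 10, 10), "inside")
})

test_that("linear classifier selects SNPs by evidence and converges to Bayes", {
  # identical classes: about alpha * m * pairs false selections
  prof0 <- maf_profile(matrix(0.3, 3, 60))
  g0 <- simulate_genotypes(prof0, n_per_class = 80, seed = 61)
  fit0 <- snp_linear(g0, alpha = 0.1)
  up <- which(upper.tri(matrix(0, 3, 3)), arr.ind = TRUE)
  n_sel <- sum(vapply(seq_len(nrow(up)),
                      function(i) sum(fit0$weights[up[i, 1], up[i, 2], ]), 0L))
  # Binomial(m * pairs, alpha): stay within 4 sd of the mean
  expect_lt(abs(n_sel - 0.1 * 60 * 3), 4 * sqrt(60 * 3 * 0.1 * 0.9) + 1)

  # strong separation at large n: all weights on, coefficients near truth
  prof <- table1_design(2, h = 0.15, m = 20, seed = 62)
  g <- simulate_genotypes(prof, n_per_class = 5000, seed = 63)
  fit <- snp_linear(g, alpha = 0.1)
  expect_true(all(fit$weights[1, 2, ] == 1L))
  bayes <- snp_bayes(prof)
  expect_lt(max(abs(fit$b[1, 2, ] - bayes$b[1, 2, ])), 0.1)
  expect_lt(abs(fit$K[1, 2] - bayes$K[1, 2]), 1)
})

test_that("weights are symmetric in the class pair and b-hat antisymmetric", {
  prof <- table1_design(3, h = 0.05, m = 30, seed = 71)
  g <- simulate_genotypes(prof, n_per_class = 60, seed = 72)
  fit <- snp_linear(g)
  for (k in 1:3) for (kp in 1:3) {
    if (k == kp) next
    expect_identical(fit$weights[k, kp, ], fit$weights[kp, k, ])
    expect_equal(fit$b[k, kp, ], -fit$b[kp, k, ])
  }
})

test_that("threshold conventions differ only on unselected SNPs", {
  prof <- table1_design(3, h = 0.05, m = 40, seed = 81)
  g <- simulate_genotypes(prof, n_per_class = 50, seed = 82)
  fa <- snp_linear(g, threshold_snps = "all")
  fs <- snp_linear(g, threshold_snps = "selected")
  expect_identical(fa$weights, fs$weights)
  expect_identical(fa$b, fs$b)
  # with every SNP selected the two conventions coincide
  prof2 <- table1_design(2, h = 0.15, m = 10, seed = 83)
  g2 <- simulate_genotypes(prof2, n_per_class = 4000, seed = 84)
  fa2 <- snp_linear(g2, threshold_snps = "all")
  fs2 <- snp_linear(g2, threshold_snps = "selected")
  expect_equal(fa2$K, fs2$K)
})

test_that("near-identical estimated classes spread assignments across classes", {
  prof0 <- maf_profile(matrix(0.3, 3, 50))
  train <- simulate_genotypes(prof0, n_per_class = 200, seed = 91)
  fit <- snp_linear(train, alpha = 0.1)
  test <- simulate_genotypes(prof0, n_per_class = 2000, seed = 92)
  tab <- tabulate(predict(fit, test), 3) / nrow(test$values)
  expect_true(all(tab > 0.1))   # no class monopolises the assignments
})

test_that("prediction validates dimensions and flags boundary cases", {
  prof <- tiny_profile(D = 2, m = 5)
  fit <- snp_bayes(prof)
  expect_error(predict(fit, matrix(0L, 2, 4)), "expected 5")
  cls <- predict(fit, matrix(0L, 3, 5))
  expect_length(attr(cls, "flagged"), 3)
})
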