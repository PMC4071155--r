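test_that("operating points hit the ROC endpoints at extreme thresholds", {
  prof <- table1_design(2, h = 0.1, m = 30, seed = 51)
  aps <- gaussian_approx_infty(snp_bayes(prof))
  lo <- operating_point(aps, -1e4)
  hi <- operating_point(aps, 1e4)
  # a huge negative offset on class 1 makes class 1 always win
  expect_equal(unclass(lo)[1:2], c(0, 1), tolerance = 1e-8)
  expect_equal(unclass(hi)[1:2], c(1, 0), tolerance = 1e-8)
})

test_that("identical classes give symmetric operating points at kvec = 0", {
  prof <- maf_profile(matrix(0.3, 3, 40))
  des <- study_design(3, 40, n_per_class = 100)
  aps <- gaussian_approx_n(prof, des)
  xi <- operating_point(aps, c(0, 0))
  expect_equal(unclass(xi)[1], unclass(xi)[2], tolerance = 1e-6)
  expect_equal(unclass(xi)[2], unclass(xi)[3], tolerance = 1e-6)
})

test_that("a random (identical-class) classifier has VUS at the 1/D! floor", {
  for (D in c(3, 4)) {
    prof <- maf_profile(matrix(0.3, D, 30))
    fit <- snp_bayes(prof)
    v <- vus(fit, seed = 60 + D)
    expect_lt(abs(v$volume - 1 / factorial(D)), 0.02)
  }
})

test_that("a perfectly separated classifier has VUS near 1", {
  # huge separation: h = 0.1 with many SNPs saturates the surface
  prof <- table1_design(3, h = 0.1, m = 400, seed = 61)
  v <- vus(snp_bayes(prof), seed = 62)
  expect_gt(v$volume, 0.98)
})

test_that("VUS search is reproducible and its history nondecreasing", {
  prof <- table1_design(3, h = 0.05, m = 50, seed = 63)
  fit <- snp_bayes(prof)
  v1 <- vus(fit, seed = 99)
  v2 <- vus(fit, seed = 99)
  expect_equal(v1$volume, v2$volume)
  expect_identical(v1$history, v2$history)
  expect_true(all(diff(v1$history) >= 0))
  expect_true(v1$volume >= 1 / 6 - 1e-9 && v1$volume <= 1)
})

test_that("stochastic search agrees with brute-force grid integration (D=3)", {
  # Riemann integration of the ROC surface over a dense threshold grid:
  # height xi_3 integrated over (xi_1, xi_2) by the Jacobian of the
  # threshold-to-rate map, plus the anchor simplex below the surface
  prof <- table1_design(3, h = 0.05, m = 40, seed = 71)
  fit <- snp_bayes(prof)
  aps <- gaussian_approx_infty(fit)
  R <- snpvus:::score_scale_from_approxes(aps)
  ng <- 201
  ks <- seq(-R, R, length.out = ng)
  XI <- array(0, c(ng, ng, 3))
  for (i in seq_len(ng)) {
    kv <- cbind(ks[i], ks)
    XI[i, , ] <- snpvus:::xi_batch(aps, kv)
  }
  ii <- 1:(ng - 1)
  x1 <- XI[, , 1]; x2 <- XI[, , 2]; x3 <- XI[, , 3]
  a1 <- x1[ii, ii]; a2 <- x2[ii, ii]
  b1 <- x1[ii + 1, ii]; b2 <- x2[ii + 1, ii]
  c1 <- x1[ii + 1, ii + 1]; c2 <- x2[ii + 1, ii + 1]
  d1 <- x1[ii, ii + 1]; d2 <- x2[ii, ii + 1]
  # exact area of each cell's image quadrilateral in the (xi1, xi2) plane
  area <- 0.5 * abs((a1 * b2 - b1 * a2) + (b1 * c2 - c1 * b2) +
                    (c1 * d2 - d1 * c2) + (d1 * a2 - a1 * d2))
  h3 <- (x3[ii, ii] + x3[ii + 1, ii] + x3[ii + 1, ii + 1] +
           x3[ii, ii + 1]) / 4
  vol <- sum(area * h3)
  # the grid covers the curved part of the surface; close the body with
  # the same anchor floor the hull uses (volume 1/3! below xi3-level 0
  # is already part of the integral through the Jacobian sweep), so
  # compare against the search volume directly
  v <- vus(fit, seed = 72)
  expect_lt(abs(v$volume - vol), 0.01)
})

test_that("empirical operating points converge to the analytic ones", {
  prof <- table1_design(3, h = 0.1, m = 60, seed = 81)
  fit <- snp_bayes(prof)
  test <- simulate_genotypes(prof, n_per_class = 4000, seed = 82)
  # empirical strict-rule rates at kvec = 0 vs orthant probabilities
  marg <- snpvus:::pairwise_margins(fit, test$values)
  aps <- gaussian_approx_infty(fit)
  for (k in 1:3) {
    rows <- which(test$labels == k)
    mk <- marg[rows, k, -k]
    emp <- mean(mk[, 1] > 0 & mk[, 2] > 0)
    ana <- orthant_probability(aps[[k]])
    expect_lt(abs(emp - ana), 3 * sqrt(ana * (1 - ana) / length(rows)) + 0.01)
  }
})

test_that("empirical VUS of a fitted classifier tracks the analytic VUS", {
  prof <- table1_design(3, h = 0.1, m = 60, seed = 83)
  fit <- snp_bayes(prof)
  v_ana <- vus(fit, seed = 85)
  test <- simulate_genotypes(prof, n_per_class = 1500, seed = 84)
  v_emp <- vus_empirical(fit, test, seed = 85)
  expect_lt(abs(v_ana$volume - v_emp$volume), 0.05)
  single <- genotype_matrix(test$values[test$labels == 1, ],
                            labels = rep(1, sum(test$labels == 1)))
  expect_error(vus_empirical(fit, single, seed = 1), "every class")
})

test_that("AUC has the right endpoints and matches the binormal closed form", {
  # identical classes: chance level
  prof0 <- maf_profile(matrix(0.3, 2, 40))
  expect_lt(abs(auc(snp_bayes(prof0)) - 0.5), 0.005)
  # strong separation approaches 1
  prof1 <- table1_design(2, h = 0.15, m = 200, seed = 91)
  expect_gt(auc(snp_bayes(prof1)), 0.99)
  # binormal closed form: AUC = Phi(dmu / sqrt(s1^2 + s2^2)) for the
  # one-dimensional pairwise score
  prof <- table1_design(2, h = 0.05, m = 50, seed = 92)
  fit <- snp_bayes(prof)
  aps <- gaussian_approx_infty(fit)
  # centred pairwise score S12 - K12 has mean mu - kvec under class 1 and
  # -(mu2 - kvec2) under class 2
  dmu <- (aps[[1]]$mu - aps[[1]]$kvec) + (aps[[2]]$mu - aps[[2]]$kvec)
  cf <- pnorm(dmu / sqrt(aps[[1]]$Sigma[1, 1] + aps[[2]]$Sigma[1, 1]))
  expect_lt(abs(auc(fit) - cf), 1e-3)
  expect_error(vus(snp_bayes(prof)), "D >= 3")
  prof3 <- table1_design(3, h = 0.05, m = 20, seed = 93)
  expect_error(auc(snp_bayes(prof3)), "D = 2")
})
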