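test_that("HWE pmf matches the binomial model and its moments", {
  expect_equal(hwe_pmf(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_pmf(0.4), c(0.36, 0.48, 0.16))
  for (theta in seq(0.02, 0.98, by = 0.06)) {
    p <- hwe_pmf(theta)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1)
    expect_equal(sum(p * 0:2), 2 * theta)
    expect_equal(sum(p * (0:2)^2) - (2 * theta)^2, 2 * theta * (1 - theta))
  }
  expect_error(hwe_pmf(0), "inside")
  expect_error(hwe_pmf(1.2), "inside")
})

test_that("maf_profile enforces the (0.01, 0.5) frequency band", {
  expect_s3_class(maf_profile(rbind(c(0.45, 0.3), c(0.2, 0.12))), "maf_profile")
  expect_error(maf_profile(rbind(c(0.45, 0.3), c(0.2, 0.005))),
               "class 2, SNP 2")
  expect_error(maf_profile(rbind(c(0.55, 0.3), c(0.2, 0.1))), "0.5")
  prof <- maf_profile(rbind(c(0.45, 0.3), c(0.2, 0.12)), priors = c(2, 1))
  expect_equal(sum(prof$priors), 1)
})

test_that("genotype simulation is reproducible and follows the HWE law", {
  prof <- maf_profile(rbind(c(0.4, 0.2, 0.35), c(0.3, 0.45, 0.12)))
  g1 <- simulate_genotypes(prof, n_per_class = c(20, 30), seed = 5)
  g2 <- simulate_genotypes(prof, n_per_class = c(20, 30), seed = 5)
  expect_identical(g1$values, g2$values)
  expect_equal(tabulate(g1$labels), c(20, 30))

  # law of large numbers: column means near 2 theta within 3 SE
  n <- 1e5
  big <- simulate_genotypes(maf_profile(rbind(0.4, 0.3), priors = c(1, 1)),
                            n_per_class = c(n, 1), seed = 9)
  x <- big$values[big$labels == 1, 1]
  se <- sqrt(2 * 0.4 * 0.6 / n)
  expect_lt(abs(mean(x) - 0.8), 3 * se)
  # chi-square goodness of fit against the pmf
  obs <- tabulate(x + 1, 3)
  gof <- suppressWarnings(chisq.test(obs, p = hwe_pmf(0.4)))
  expect_gt(gof$p.value, 1e-4)
})

test_that("simulate() method on a profile delegates to the simulator", {
  prof <- tiny_profile(D = 2, m = 4)
  g <- simulate(prof, nsim = 7, seed = 3)
  expect_s3_class(g, "genotype_matrix")
  expect_equal(nrow(g$values), 14)
})

test_that("the layered design has the promised gap structure", {
  prof <- table1_design(D = 3, h = 0.1, m = 200, seed = 11)
  expect_true(all(prof$theta[1, ] > 0.4 & prof$theta[1, ] < 0.49))
  gaps1 <- prof$theta[1, ] - prof$theta[2, ]
  gaps2 <- prof$theta[2, ] - prof$theta[3, ]
  expect_true(all(gaps1 > 0.098 & gaps1 < 0.102))
  expect_true(all(gaps2 > 0.098 & gaps2 < 0.102))
  expect_equal(prof$priors, rep(1 / 3, 3))
  # D = 4 extends the recursion one layer
  prof4 <- table1_design(D = 4, h = 0.05, m = 50, seed = 12)
  expect_equal(nrow(prof4$theta), 4)
  g3 <- prof4$theta[3, ] - prof4$theta[4, ]
  expect_true(all(g3 > 0.048 & g3 < 0.052))
  # mean class separation ~ h
  prof_h <- table1_design(D = 3, h = 0.02, m = 50, seed = 13)
  expect_lt(abs(mean(prof_h$theta[1, ] - prof_h$theta[2, ]) - 0.02), 0.002)
})

test_that("designs that would breach the MAF floor fail fast", {
  # theta1 >= 0.4; three drops of ~0.14 can push below 0.01
  expect_error(table1_design(D = 4, h = 0.14, m = 50, seed = 2), "floor")
  # and never silently emit a violating profile over a seed sweep
  for (s in 1:20) {
    prof <- try(table1_design(D = 4, h = 0.12, m = 30, seed = s), silent = TRUE)
    if (!inherits(prof, "try-error")) {
      expect_true(all(prof$theta > 0.01 & prof$theta < 0.5))
    }
  }
})

test_that("correlated fixture reproduces its declared structure", {
  g <- correlated_fixture(6, 4, noise = 0, n_samples = 300, seed = 21)
  parents <- attr(g, "parents")
  expect_equal(sum(parents == 0), 6)
  for (j in which(parents > 0)) {
    expect_identical(g$values[, j], g$values[, parents[j]])
  }
  # noise breaks exact copies but keeps strong association
  gn <- correlated_fixture(6, 4, noise = 0.1, n_samples = 500, seed = 22)
  pn <- attr(gn, "parents")
  for (j in which(pn > 0)) {
    expect_gt(kendall_tau(gn$values[, j], gn$values[, pn[j]]), 0.5)
  }
  # reductions
  g0 <- correlated_fixture(5, 0, n_samples = 50, seed = 23)
  expect_equal(ncol(g0$values), 5)
  expect_error(correlated_fixture(5, 2, noise = 0.6), "noise")
})

test_that("genotype_matrix validates its inputs", {
  expect_error(genotype_matrix(matrix(c(0, 3), 1), labels = 1), "0, 1 or 2")
  expect_error(genotype_matrix(matrix(NA_integer_, 1, 1), labels = 1),
               "missing")
  g <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L), 2), labels = c(1, 2))
  expect_equal(g$snp_ids, c("snp1", "snp2"))
})
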