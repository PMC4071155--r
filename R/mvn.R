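# Multivariate normal upper-orthant probabilities.
#
# The ROC machinery needs P(Z > a componentwise) for (D-1)-dimensional
# Gaussian scores at many thresholds sharing one covariance, so the
# bivariate and trivariate cases are computed by dedicated vectorised
# quadratures (validated against mvtnorm to ~1e-10); higher dimensions
# fall back to mvtnorm::pmvnorm.

# Gauss-Legendre nodes/weights on [-1, 1], cached (Golub-Welsch).
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    res <- list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
    cache[[key]] <<- res
    res
  }
})

# Vectorised standard bivariate normal CDF P(X <= h, Y <= k) at
# correlation rho (scalar). Moderate correlations use the single-integral
# reduction d Phi2 / d rho = phi2(h, k; rho) integrated from 0 to rho;
# |rho| > 0.925 switches to the high-correlation expansion of Genz's
# bivariate algorithm, which stays accurate up to |rho| -> 1.
pbvn <- function(h, k, rho) {
  if (abs(rho) >= 1) rho <- sign(rho) * (1 - 1e-15)
  if (abs(rho) > 0.925) {
    # P(X <= h, Y <= k) = P(X > -h, Y > -k)
    return(bvn_upper_highcorr(-h, -k, rho))
  }
  out <- stats::pnorm(h) * stats::pnorm(k)
  if (abs(rho) < 1e-12) return(out)
  gl <- gauss_legendre(96)
  t <- 0.5 * rho * (gl$x + 1)
  w <- 0.5 * abs(rho) * gl$w
  hk <- h * k
  h2k2 <- h * h + k * k
  s <- sign(rho)
  for (i in seq_along(t)) {
    om <- 1 - t[i] * t[i]
    out <- out + s * w[i] / (2 * pi * sqrt(om)) *
      exp(-(h2k2 - 2 * t[i] * hk) / (2 * om))
  }
  out
}

# Upper-quadrant probability P(X > dh, Y > dk) for |rho| near 1, by the
# expansion around the singular limit (the high-correlation branch of
# Genz's bivariate normal algorithm), vectorised over (dh, dk).
bvn_upper_highcorr <- function(dh, dk, r) {
  gl <- gauss_legendre(32)
  if (r < 0) dk <- -dk
  hk0 <- dh * dk
  bvn <- numeric(length(dh))
  as_ <- (1 - r) * (1 + r)
  a <- sqrt(as_)
  bs <- (dh - dk)^2
  cc <- (4 - hk0) / 8
  dd <- (12 - hk0) / 16
  asr <- -(bs / as_ + hk0) / 2
  ok <- asr > -100
  bvn[ok] <- a * exp(asr[ok]) *
    (1 - cc[ok] * (bs[ok] - as_) * (1 - dd[ok] * bs[ok] / 5) / 3 +
       cc[ok] * dd[ok] * as_ * as_ / 5)
  ok2 <- -hk0 < 100
  if (any(ok2)) {
    b <- sqrt(bs[ok2])
    bvn[ok2] <- bvn[ok2] - exp(-hk0[ok2] / 2) * sqrt(2 * pi) *
      stats::pnorm(-b / a) * b *
      (1 - cc[ok2] * bs[ok2] * (1 - dd[ok2] * bs[ok2] / 5) / 3)
  }
  a2 <- a / 2
  for (i in seq_along(gl$x)) {
    # node on (0, a): u = a (1 + x_i) / 2, weight a w_i / 2
    xs <- (a2 + a2 * gl$x[i])^2
    rs <- sqrt(1 - xs)
    asr1 <- -(bs / xs + hk0) / 2
    ok3 <- asr1 > -100
    if (any(ok3)) {
      bvn[ok3] <- bvn[ok3] + a2 * gl$w[i] * exp(asr1[ok3]) *
        (exp(-hk0[ok3] * (1 - rs) / (2 * (1 + rs))) / rs -
           (1 + cc[ok3] * xs * (1 + dd[ok3] * xs)))
    }
  }
  bvn <- -bvn / (2 * pi)
  if (r > 0) {
    bvn <- bvn + stats::pnorm(-pmax(dh, dk))
  } else {
    bvn <- -bvn + pmax(0, stats::pnorm(-dh) - stats::pnorm(-dk))
  }
  pmin(1, pmax(0, bvn))
}

# Upper-orthant probabilities P(Z > A[i, ] componentwise), Z ~ N(mu, Sigma),
# vectorised over the rows of A. Degenerate (near-zero variance) scores are
# treated as deterministic. Rank-deficient but nonzero covariances get a
# small diagonal jitter before the fallback solver.
orthant_upper_batch <- function(A, mu, Sigma, jitter = 1e-10, abstol = 1e-4) {
  d <- length(mu)
  if (is.null(dim(A))) A <- matrix(A, ncol = d)
  s2 <- diag(Sigma)
  if (all(s2 < 1e-16)) {
    return(as.numeric(apply(A, 1, function(a) all(mu > a))))
  }
  s <- sqrt(pmax(s2, 1e-16))
  Z <- sweep(sweep(A, 2, mu), 2, s, "/")
  if (d == 1L) return(stats::pnorm(Z[, 1], lower.tail = FALSE))
  R <- Sigma / (s %o% s)
  diag(R) <- 1
  if (d == 2L) {
    return(pmin(1, pmax(0, pbvn(-Z[, 1], -Z[, 2], R[1, 2]))))
  }
  if (d == 3L) {
    # condition on the first component; the conditional pair has a fixed
    # partial correlation, so each quadrature node is one vectorised pbvn.
    # With near-singular covariances the conditional probability is a
    # steep, almost-kinked function of the conditioning variable; the
    # integral is therefore split at the (linear-in-x) crossing points
    # where the two conditional thresholds coincide or mirror, which is
    # where the kinks sit in the singular limit.
    r12 <- R[1, 2]; r13 <- R[1, 3]; r23 <- R[2, 3]
    s2c <- sqrt(max(1e-12, 1 - r12^2))
    s3c <- sqrt(max(1e-12, 1 - r13^2))
    rc <- (r23 - r12 * r13) / (s2c * s3c)
    rc <- max(-(1 - 1e-14), min(1 - 1e-14, rc))
    gl <- gauss_legendre(32)
    nr <- nrow(Z)
    lo <- pmax(Z[, 1], -8.5)
    hi <- 8.5
    out <- numeric(nr)
    # impossible rows: some component is astronomically unlikely
    dead <- pmax(Z[, 1], Z[, 2], Z[, 3]) > 8.3
    # the conditional thresholds a2(x), a3(x) are linear in x with slopes
    # that blow up as the correlations approach 1, so the integrand can
    # have near-kinks where the thresholds cross each other, mirror each
    # other, or cross zero; the quadrature is split at all of them
    # (g2, g3 are scalars, so the guards must not vectorise over them)
    c2 <- Z[, 2] / s2c; g2 <- r12 / s2c
    c3 <- Z[, 3] / s3c; g3 <- r13 / s3c
    brks <- cbind(
      if (abs(g2 - g3) > 1e-12) (c2 - c3) / (g2 - g3) else rep(NA_real_, nr),
      if (abs(g2 + g3) > 1e-12) (c2 + c3) / (g2 + g3) else rep(NA_real_, nr),
      if (abs(g2) > 1e-12) c2 / g2 else rep(NA_real_, nr),
      if (abs(g3) > 1e-12) c3 / g3 else rep(NA_real_, nr))
    brks[is.na(brks)] <- -8.5
    brks <- pmin(pmax(brks, lo), hi)
    # row-sort the four breakpoints with a pmin/pmax sorting network
    l1 <- pmin(brks[, 1], brks[, 2]); h1 <- pmax(brks[, 1], brks[, 2])
    l2 <- pmin(brks[, 3], brks[, 4]); h2 <- pmax(brks[, 3], brks[, 4])
    b_min <- pmin(l1, l2); b_max <- pmax(h1, h2)
    m1 <- pmax(l1, l2); m2 <- pmin(h1, h2)
    brks <- cbind(b_min, pmin(m1, m2), pmax(m1, m2), b_max)
    seg <- function(x0, x1) {
      rng <- pmax(0, x1 - x0)
      for (i in seq_along(gl$x)) {
        x <- x0 + 0.5 * rng * (gl$x[i] + 1)
        wt <- 0.5 * rng * gl$w[i] * stats::dnorm(x)
        a2 <- c2 - g2 * x
        a3 <- c3 - g3 * x
        out <<- out + wt * pmax(0, pbvn(-a2, -a3, rc))
      }
    }
    seg(lo, brks[, 1])
    seg(brks[, 1], brks[, 2])
    seg(brks[, 2], brks[, 3])
    seg(brks[, 3], brks[, 4])
    seg(brks[, 4], hi)
    out[dead] <- 0
    return(pmin(1, pmax(0, out)))
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) diag(R) <- 1 + jitter * sum(diag(R)) / d
  apply(Z, 1, function(z) {
    as.numeric(mvtnorm::pmvnorm(
      lower = z, upper = rep(Inf, d), corr = R,
      algorithm = mvtnorm::GenzBretz(abseps = abstol)))
  })
}
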