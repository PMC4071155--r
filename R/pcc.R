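#' Gaussian approximation to the pairwise score distribution (known theta)
#'
#' For a sample truly from class k, the D - 1 pairwise scores
#' \eqn{S_{k,k'} = \sum_j b_{k,k'}^j X_j} of the optimal Bayes classifier
#' are sums of many independent bounded terms and are treated as jointly
#' Gaussian. Their exact first two moments under
#' \eqn{X_j \sim \mathrm{Binomial}(2, \theta_{k,j})} are
#' \eqn{\mu_{k'} = \sum_j 2\theta_{k,j} b_{k,k'}^j} and
#' \eqn{\Sigma_{k',k''} = \sum_j 2\theta_{k,j}(1-\theta_{k,j})
#' b_{k,k'}^j b_{k,k''}^j}.
#' The probability that class k is correctly classified is then the
#' orthant probability that all scores exceed their thresholds.
#'
#' @param classifier A fitted [snp_bayes()] classifier.
#' @param class_k Class index; if `NULL`, a list of approximations for
#'   all classes is returned.
#' @return An object of class `"gaussian_approx"`: list with `mu`
#'   ((D-1)-vector), `Sigma` ((D-1) x (D-1)), `kvec` (thresholds), `ks`
#'   (the competing class indices), `class_k`, `variant = "infty"`.
#' @seealso [orthant_probability()], [pcc()]
#' @export
gaussian_approx_infty <- function(classifier, class_k = NULL) {
  stopifnot(inherits(classifier, "snp_bayes"))
  if (is.null(class_k)) {
    return(lapply(seq_len(classifier$D),
                  function(k) gaussian_approx_infty(classifier, k)))
  }
  theta <- classifier$profile$theta[, seq_len(classifier$l), drop = FALSE]
  D <- classifier$D
  k <- as.integer(class_k)
  stopifnot(k >= 1L, k <= D)
  ks <- setdiff(seq_len(D), k)
  tk <- theta[k, ]
  v <- 2 * tk * (1 - tk)
  B <- t(vapply(ks, function(kp) classifier$b[k, kp, ], numeric(classifier$l)))
  mu <- as.numeric(B %*% (2 * tk))
  Sigma <- B %*% (v * t(B))
  structure(list(mu = mu, Sigma = Sigma, kvec = classifier$K[k, ks],
                 ks = ks, class_k = k, variant = "infty"),
            class = "gaussian_approx")
}

#' Estimation-adjusted Gaussian approximation (finite training sample)
#'
#' Approximates the distribution of the *linear* classifier's pairwise
#' scores when the classifier will be estimated from `n_k` training
#' samples per class, without simulating any training data. Writing the
#' per-SNP contribution of locus j to the pair (k, k') as
#' \eqn{g_j = W_j(\hat b_j X_j - \hat c_j)}, where
#' \eqn{\hat c_j = 2\log\{(1-\hat\theta_{k',j})/(1-\hat\theta_{k,j})\}}
#' is the SNP's threshold term, the moments account for
#' \itemize{
#' \item SNP inclusion: \eqn{W_j = 1} with probability equal to the Wald
#'   test's analytic power at effect \eqn{h_j = \theta_{k,j} -
#'   \theta_{k',j}} (independently across SNPs, to first order);
#' \item coefficient noise: delta-method variances and covariances of
#'   \eqn{\hat b_j} and \eqn{\hat c_j} around their true values, e.g.
#'   \eqn{\mathrm{Var}(\hat b_j) \approx 1/\{2n_k\theta_{k,j}
#'   (1-\theta_{k,j})\} + 1/\{2n_{k'}\theta_{k',j}(1-\theta_{k',j})\}};
#' \item cross-pair correlation: scores for pairs (k, k') and (k, k'')
#'   share both the genotype \eqn{X_j} and the class-k estimate
#'   \eqn{\hat\theta_{k,j}}.
#' }
#' The per-class correct-classification rate is the orthant probability
#' that all D - 1 adjusted scores exceed \eqn{\log(\pi_{k'}/\pi_k)}. As
#' all n grow the approximation converges to [gaussian_approx_infty()].
#'
#' `threshold_snps` selects the threshold convention of the linear rule
#' being approximated (see [snp_linear()]): with `"selected"` (default)
#' the threshold is restricted to the Wald-selected SNPs and the per-SNP
#' contribution is the fully centred \eqn{W_j(\hat b_j X_j - \hat c_j)};
#' this is the construction whose predictions agree with Monte Carlo
#' simulations of actually-fitted classifiers. With `"all"` the
#' threshold term \eqn{\hat c_j} of every SNP is kept whether or not the
#' SNP passed its Wald test, so unselected SNPs leave a systematic score
#' deficit that shrinks only as the tests' power approaches 1 — a far
#' more pessimistic account of the finite-sample penalty.
#'
#' @param profile A [maf_profile()] of true allele frequencies.
#' @param design A [study_design()] providing `n_per_class` and `alpha`.
#' @param class_k Class index; if `NULL`, approximations for all classes.
#' @param threshold_snps `"all"` or `"selected"` (see Details).
#' @return A `"gaussian_approx"` object with `variant = "n"`.
#' @export
gaussian_approx_n <- function(profile, design, class_k = NULL,
                              threshold_snps = c("selected", "all")) {
  threshold_snps <- match.arg(threshold_snps)
  stopifnot(inherits(profile, "maf_profile"), inherits(design, "study_design"))
  D <- nrow(profile$theta)
  if (design$D != D) stop("design and profile disagree on the number of classes")
  if (is.null(class_k)) {
    return(lapply(seq_len(D), function(k)
      gaussian_approx_n(profile, design, k, threshold_snps)))
  }
  k <- as.integer(class_k)
  theta <- profile$theta
  alpha <- design$alpha
  n <- design$n_per_class
  ks <- setdiff(seq_len(D), k)
  tk <- theta[k, ]
  nk <- n[k]
  EX <- 2 * tk
  EX2 <- 2 * tk * (1 - tk) + 4 * tk^2
  vthk <- tk * (1 - tk) / (2 * nk)
  all_m <- threshold_snps == "all"
  per_pair <- lapply(ks, function(kp) {
    tp <- theta[kp, ]
    np <- n[kp]
    b <- log(tk * (1 - tp)) - log(tp * (1 - tk))
    cc <- 2 * (log(1 - tp) - log(1 - tk))
    v_b <- 1 / (2 * nk * tk * (1 - tk)) + 1 / (2 * np * tp * (1 - tp))
    v_c <- (2 / (1 - tk))^2 * vthk + (2 / (1 - tp))^2 * tp * (1 - tp) / (2 * np)
    cov_bc <- 1 / (nk * (1 - tk)) + 1 / (np * (1 - tp))
    p <- wald_power(tk - tp, tk, nk, np, alpha)
    if (all_m) {
      # g_j = W_j bhat_j X_j - chat_j: the threshold term always enters
      mu_g <- p * EX * b - cc
      Eg2 <- p * (b^2 + v_b) * EX2 - 2 * p * (b * cc + cov_bc) * EX +
        cc^2 + v_c
    } else {
      # g_j = W_j (bhat_j X_j - chat_j)
      mu_g <- p * (EX * b - cc)
      Eg2 <- p * ((b^2 + v_b) * EX2 - 2 * (b * cc + cov_bc) * EX + cc^2 + v_c)
    }
    list(b = b, cc = cc, p = p, mu_g = mu_g, var_g = Eg2 - mu_g^2)
  })
  mu <- vapply(per_pair, function(q) sum(q$mu_g), 0)
  Sigma <- diag(vapply(per_pair, function(q) sum(q$var_g), 0),
                nrow = D - 1)
  if (D > 2L) {
    cov_bb <- 1 / (2 * nk * tk * (1 - tk))
    cov_bc_k <- 1 / (nk * (1 - tk))
    cov_cc <- 2 * tk / (nk * (1 - tk))
    for (a in 1:(D - 2)) {
      for (bq in (a + 1):(D - 1)) {
        qa <- per_pair[[a]]
        qb <- per_pair[[bq]]
        Egg <- if (all_m) {
          qa$p * qb$p * (qa$b * qb$b + cov_bb) * EX2 -
            qa$p * (qa$b * qb$cc + cov_bc_k) * EX -
            qb$p * (qa$cc * qb$b + cov_bc_k) * EX +
            qa$cc * qb$cc + cov_cc
        } else {
          qa$p * qb$p *
            ((qa$b * qb$b + cov_bb) * EX2 -
             (qa$b * qb$cc + cov_bc_k) * EX -
             (qa$cc * qb$b + cov_bc_k) * EX +
             qa$cc * qb$cc + cov_cc)
        }
        cv <- sum(Egg - qa$mu_g * qb$mu_g)
        Sigma[a, bq] <- cv
        Sigma[bq, a] <- cv
      }
    }
  }
  kvec <- log(profile$priors[ks] / profile$priors[k])
  structure(list(mu = mu, Sigma = Sigma, kvec = kvec,
                 ks = ks, class_k = k, variant = "n"),
            class = "gaussian_approx")
}

#' @export
print.gaussian_approx <- function(x, ...) {
  cat(sprintf("Gaussian score approximation (variant '%s') for class %d\n",
              x$variant, x$class_k))
  cat("  mu:   ", paste(signif(x$mu, 4), collapse = " "), "\n")
  cat("  sd:   ", paste(signif(sqrt(diag(x$Sigma)), 4), collapse = " "), "\n")
  cat("  kvec: ", paste(signif(x$kvec, 4), collapse = " "), "\n")
  invisible(x)
}

#' Per-class correct-classification rate (orthant probability)
#'
#' \eqn{\xi_k = P(Z > \mathrm{kvec} \textrm{ componentwise})} for
#' \eqn{Z \sim N(\mu, \Sigma)} from a [gaussian_approx_infty()] or
#' [gaussian_approx_n()] object, optionally with per-class threshold
#' offsets applied.
#'
#' @param approx A `"gaussian_approx"` object.
#' @param offsets Optional length-D numeric vector of per-class
#'   threshold offsets (the ROC sweep); entry `k'` shifts the pairwise
#'   threshold of (k, k') by `offsets[k'] - offsets[class_k]`.
#' @return A probability in \[0, 1\].
#' @export
orthant_probability <- function(approx, offsets = NULL) {
  stopifnot(inherits(approx, "gaussian_approx"))
  kv <- approx$kvec
  if (!is.null(offsets)) {
    kv <- kv + offsets[approx$ks] - offsets[approx$class_k]
  }
  orthant_upper_batch(matrix(kv, nrow = 1), approx$mu, approx$Sigma)[1]
}

#' Probability of correct classification
#'
#' Prior-weighted average of the per-class correct-classification rates:
#' \eqn{\mathrm{PCC} = \sum_k \pi_k \xi_k}. With `"infty"`-variant
#' approximations this is the PCC of the optimal Bayes classifier with
#' known frequencies; with `"n"`-variant approximations it is the
#' expected PCC of the linear classifier trained on n samples per class.
#'
#' @param approxes List of per-class `"gaussian_approx"` objects (one per
#'   class, as returned by the approximation builders with
#'   `class_k = NULL`).
#' @param priors Class priors; default uniform.
#' @return A scalar in \[0, 1\], with attribute `"xi"` holding the
#'   per-class rates.
#' @examples
#' prof <- table1_design(3, h = 0.1, m = 50, seed = 1)
#' fit <- snp_bayes(prof)
#' pcc(gaussian_approx_infty(fit))
#' @export
pcc <- function(approxes, priors = NULL) {
  stopifnot(is.list(approxes), length(approxes) >= 2L)
  D <- length(approxes)
  if (is.null(priors)) priors <- rep(1 / D, D)
  priors <- priors / sum(priors)
  xi <- vapply(approxes, orthant_probability, 0)
  structure(sum(priors * xi), xi = xi)
}
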