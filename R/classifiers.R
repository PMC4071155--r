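#' Optimal Bayes classifier for coded SNP data
#'
#' Builds the optimal Bayes classifier for D-class Hardy-Weinberg SNP
#' data with known allele frequencies. The classifier assigns a genotype
#' vector \eqn{x} to class k when, for every competing class k',
#' \deqn{\sum_{j=1}^l b_{k,k'}^j x_j > K_{k,k'},}
#' with pairwise log-odds coefficients
#' \eqn{b_{k,k'}^j = \log\{\theta_{k,j}(1-\theta_{k',j})\} -
#' \log\{\theta_{k',j}(1-\theta_{k,j})\}} and thresholds
#' \eqn{K_{k,k'} = \log(\pi_{k'}/\pi_k) +
#' \sum_{j=1}^l 2\log\{(1-\theta_{k',j})/(1-\theta_{k,j})\}}.
#' This rule is exactly the posterior-ratio (maximum a posteriori) rule
#' for the product-binomial genotype model.
#'
#' @param profile A [maf_profile()] of known allele frequencies.
#' @param l Number of leading SNPs used (the SNPs with marginal effect);
#'   defaults to all of them.
#' @return An object of class `c("snp_bayes", "snp_classifier")` with
#'   elements `b` (D x D x l coefficient array, antisymmetric in the
#'   first two indices), `K` (D x D threshold matrix), `profile`, `l`.
#' @seealso [snp_linear()], [predict.snp_classifier()]
#' @examples
#' prof <- table1_design(3, h = 0.1, m = 20, seed = 1)
#' fit <- snp_bayes(prof)
#' fit
#' @export
snp_bayes <- function(profile, l = ncol(profile$theta)) {
  stopifnot(inherits(profile, "maf_profile"))
  theta <- profile$theta
  D <- nrow(theta)
  m <- ncol(theta)
  l <- as.integer(l)
  if (l < 1L || l > m) stop("'l' must be between 1 and the number of SNPs")
  th <- theta[, seq_len(l), drop = FALSE]
  b <- array(0, c(D, D, l))
  K <- matrix(0, D, D)
  for (k in seq_len(D)) {
    for (kp in seq_len(D)) {
      if (k == kp) next
      b[k, kp, ] <- log(th[k, ] * (1 - th[kp, ])) -
        log(th[kp, ] * (1 - th[k, ]))
      K[k, kp] <- log(profile$priors[kp] / profile$priors[k]) +
        sum(2 * (log(1 - th[kp, ]) - log(1 - th[k, ])))
    }
  }
  structure(list(b = b, K = K, profile = profile, l = l, D = D),
            class = c("snp_bayes", "snp_classifier"))
}

#' Maximum likelihood allele-frequency estimates
#'
#' Per-class, per-SNP MLEs \eqn{\hat\theta_{k,j} = \sum_{i \in k}
#' x_{i,j} / (2 n_k)}, clipped to \eqn{[1/(4 n_k),\; 1 - 1/(4 n_k)]} so
#' that the log-odds coefficients built from them stay finite when a
#' class shows no (or only) minor alleles at a locus.
#'
#' @param data A [genotype_matrix()] in which every class has at least
#'   one sample.
#' @return A D x m matrix of clipped frequency estimates, with attribute
#'   `"n_per_class"`.
#' @export
mle_theta <- function(data) {
  stopifnot(inherits(data, "genotype_matrix"))
  D <- max(data$labels)
  m <- ncol(data$values)
  nk <- tabulate(data$labels, D)
  if (any(nk == 0L)) {
    stop(sprintf("class %d has no samples", which(nk == 0L)[1]))
  }
  th <- matrix(0, D, m)
  for (k in seq_len(D)) {
    xs <- colSums(data$values[data$labels == k, , drop = FALSE])
    est <- xs / (2 * nk[k])
    th[k, ] <- pmin(pmax(est, 1 / (4 * nk[k])), 1 - 1 / (4 * nk[k]))
  }
  attr(th, "n_per_class") <- nk
  th
}

#' Two-sample Wald test for equal allele frequencies
#'
#' Tests H0: theta_k = theta_k' at one locus from clipped MLEs, using the
#' unpooled large-sample statistic
#' \deqn{Z = (\hat\theta_k - \hat\theta_{k'}) \big/
#'   \sqrt{\hat\theta_k(1-\hat\theta_k)/(2n_k) +
#'         \hat\theta_{k'}(1-\hat\theta_{k'})/(2n_{k'})}.}
#' All arguments are vectorised over loci.
#'
#' @param theta_hat_k,theta_hat_kp Estimated frequencies in (0, 1).
#' @param n_k,n_kp Per-class sample sizes.
#' @param alpha Two-sided level.
#' @return List with `statistic` (Z values) and `reject` (logical:
#'   |Z| > z_{1-alpha/2}). A locus with zero estimated variance yields
#'   Z = 0 and no rejection.
#' @export
wald_test <- function(theta_hat_k, theta_hat_kp, n_k, n_kp, alpha = 0.1) {
  if (any(theta_hat_k <= 0 | theta_hat_k >= 1) ||
      any(theta_hat_kp <= 0 | theta_hat_kp >= 1)) {
    stop("frequency estimates must be strictly inside (0, 1)")
  }
  v <- theta_hat_k * (1 - theta_hat_k) / (2 * n_k) +
    theta_hat_kp * (1 - theta_hat_kp) / (2 * n_kp)
  z <- ifelse(v <= 0, 0, (theta_hat_k - theta_hat_kp) / sqrt(pmax(v, 1e-300)))
  list(statistic = z, reject = abs(z) > stats::qnorm(1 - alpha / 2))
}

#' Analytic power of the allele-frequency Wald test
#'
#' Normal-approximation power of the two-sided level-alpha Wald test when
#' the true frequency difference is `h`:
#' \deqn{1-\beta = \Phi(-z_{1-\alpha/2} + |h|/\sigma) +
#'                 \Phi(-z_{1-\alpha/2} - |h|/\sigma),}
#' \eqn{\sigma^2 = \theta_k(1-\theta_k)/(2n_k) +
#' \theta_{k'}(1-\theta_{k'})/(2n_{k'})} with
#' \eqn{\theta_{k'} = \theta_k - h}. At `h = 0` the expression equals the
#' test size alpha. Vectorised over loci.
#'
#' @param h True frequency difference(s) \eqn{\theta_k - \theta_{k'}}.
#' @param theta_k True frequency in class k.
#' @param n_k,n_kp Per-class sample sizes.
#' @param alpha Test level.
#' @return Power value(s) in \[0, 1\].
#' @export
wald_power <- function(h, theta_k, n_k, n_kp, alpha = 0.1) {
  theta_kp <- theta_k - h
  if (any(theta_k <= 0 | theta_k >= 1) || any(theta_kp <= 0 | theta_kp >= 1)) {
    stop("'theta_k' and 'theta_k - h' must lie strictly inside (0, 1)")
  }
  sig <- sqrt(theta_k * (1 - theta_k) / (2 * n_k) +
              theta_kp * (1 - theta_kp) / (2 * n_kp))
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(-z + abs(h) / sig) + stats::pnorm(-z - abs(h) / sig)
}

#' Linear classifier with Wald-test SNP weights
#'
#' Estimated (plug-in) version of the Bayes rule: allele frequencies are
#' replaced by clipped MLEs and each SNP enters the pairwise score for
#' classes (k, k') only when a level-alpha Wald test rejects equality of
#' its frequencies in the two classes. The rule assigns x to class k when
#' \deqn{\sum_{j=1}^m \hat b_{k,k'}^j w_{j,n}(k,k') x_j >
#' \tilde K_{k,k'}} for all k'.
#'
#' `threshold_snps` controls which SNPs contribute to the threshold
#' \eqn{\tilde K_{k,k'}}: `"selected"` (default) restricts the threshold
#' to the Wald-selected SNPs, keeping score and threshold on the same
#' loci; `"all"` keeps the threshold term of every SNP, so a SNP whose
#' Wald test fails still shifts the threshold while contributing nothing
#' to the score — with few training samples this handicaps the rule, and
#' the handicap disappears as the tests' power approaches 1.
#'
#' @param data A [genotype_matrix()] with at least two classes present.
#' @param priors Class priors; default uniform.
#' @param alpha Level of the per-SNP Wald tests.
#' @param threshold_snps `"all"` or `"selected"` (see Details).
#' @return An object of class `c("snp_linear", "snp_classifier")` with
#'   the coefficient array `b` (already weight-masked), thresholds `K`,
#'   binary `weights` (D x D x m, symmetric in the class pair),
#'   `theta_hat`, `n_per_class` and `alpha`.
#' @seealso [snp_bayes()], [predict.snp_classifier()]
#' @export
snp_linear <- function(data, priors = NULL, alpha = 0.1,
                       threshold_snps = c("selected", "all")) {
  threshold_snps <- match.arg(threshold_snps)
  stopifnot(inherits(data, "genotype_matrix"))
  th <- mle_theta(data)
  nk <- attr(th, "n_per_class")
  D <- nrow(th)
  m <- ncol(th)
  if (D < 2L) stop("need at least two classes")
  if (is.null(priors)) priors <- rep(1 / D, D)
  priors <- priors / sum(priors)
  b <- array(0, c(D, D, m))
  w <- array(0L, c(D, D, m))
  K <- matrix(0, D, D)
  for (k in seq_len(D)) {
    for (kp in seq_len(D)) {
      if (k == kp) next
      wt <- wald_test(th[k, ], th[kp, ], nk[k], nk[kp], alpha)
      sel <- wt$reject
      bj <- log(th[k, ] * (1 - th[kp, ])) - log(th[kp, ] * (1 - th[k, ]))
      b[k, kp, ] <- bj * sel
      w[k, kp, ] <- as.integer(sel)
      thr <- if (threshold_snps == "all") rep(TRUE, m) else sel
      K[k, kp] <- log(priors[kp] / priors[k]) +
        sum(2 * (log(1 - th[kp, thr]) - log(1 - th[k, thr])))
    }
  }
  structure(list(b = b, K = K, weights = w, theta_hat = th,
                 n_per_class = nk, priors = priors, alpha = alpha,
                 threshold_snps = threshold_snps, l = m, D = D),
            class = c("snp_linear", "snp_classifier"))
}

#' @export
print.snp_classifier <- function(x, ...) {
  kind <- if (inherits(x, "snp_bayes")) "optimal Bayes" else "linear (Wald-weighted)"
  cat(sprintf("SNP %s classifier: %d classes, %d SNPs\n", kind, x$D, x$l))
  if (inherits(x, "snp_linear")) {
    up <- which(upper.tri(matrix(0, x$D, x$D)), arr.ind = TRUE)
    frac <- mean(vapply(seq_len(nrow(up)),
                        function(i) mean(x$weights[up[i, 1], up[i, 2], ]), 0))
    cat(sprintf("  Wald level %g; mean fraction of SNPs selected per class pair: %.2f\n",
                x$alpha, frac))
  }
  invisible(x)
}

#' @export
coef.snp_classifier <- function(object, ...) object$b

#' Pairwise scores of a classifier on genotype data
#'
#' Returns, for each sample i and ordered class pair (k, k'), the score
#' \eqn{S_{k,k'}(x_i) = \sum_j b_{k,k'}^j x_{ij} - K_{k,k'}}, so a
#' positive value means "k beats k'". Used by classification and by
#' empirical operating-point evaluation.
#'
#' @param object A fitted classifier.
#' @param X Numeric matrix of genotypes (samples x SNPs).
#' @return A 3-d array N x D x D of margins; `[, k, k']`.
#' @keywords internal
pairwise_margins <- function(object, X) {
  D <- object$D
  l <- object$l
  if (ncol(X) < l) stop("genotype matrix has fewer SNPs than the classifier")
  X <- X[, seq_len(l), drop = FALSE]
  out <- array(0, c(nrow(X), D, D))
  for (k in seq_len(D)) {
    for (kp in seq_len(D)) {
      if (k == kp) next
      out[, k, kp] <- X %*% object$b[k, kp, ] - object$K[k, kp]
    }
  }
  out
}

#' Classify genotype vectors
#'
#' Applies the pairwise decision rule of a fitted classifier. A sample is
#' assigned to the class whose pairwise scores exceed all of its D - 1
#' thresholds. When no class satisfies all inequalities strictly (a
#' boundary case possible with discrete genotypes), the sample is
#' assigned to the class with the largest worst-case margin
#' \eqn{\mathrm{argmax}_k \min_{k'} (S_{k,k'} - K_{k,k'})}, residual ties
#' going to the smallest class index; such samples are flagged.
#'
#' @param object A fitted `"snp_classifier"`.
#' @param newdata A [genotype_matrix()], or a numeric matrix / vector of
#'   genotypes coded 0/1/2.
#' @param kvec Optional numeric vector of D per-class threshold offsets
#'   (the last one conventionally 0) shifting each pairwise threshold
#'   \eqn{K_{k,k'}} by \eqn{K_{k'} - K_k}; this is the family swept when
#'   tracing the ROC surface. Default: no shift.
#' @param ... Unused.
#' @return Integer vector of class assignments with attribute
#'   `"flagged"`: logical vector marking samples decided by the tie rule.
#' @export
predict.snp_classifier <- function(object, newdata, kvec = NULL, ...) {
  X <- if (inherits(newdata, "genotype_matrix")) newdata$values
       else if (is.null(dim(newdata))) matrix(newdata, nrow = 1)
       else as.matrix(newdata)
  if (ncol(X) != object$l) {
    stop(sprintf("expected %d SNPs, got %d", object$l, ncol(X)))
  }
  D <- object$D
  marg <- pairwise_margins(object, X)
  if (!is.null(kvec)) {
    if (length(kvec) == D - 1L) kvec <- c(kvec, 0)
    if (length(kvec) != D) stop("'kvec' must have length D or D - 1")
    for (k in seq_len(D)) {
      for (kp in seq_len(D)) {
        if (k == kp) next
        marg[, k, kp] <- marg[, k, kp] - (kvec[kp] - kvec[k])
      }
    }
  }
  n <- nrow(X)
  worst <- matrix(Inf, n, D)
  for (k in seq_len(D)) {
    others <- setdiff(seq_len(D), k)
    worst[, k] <- apply(marg[, k, others, drop = FALSE], 1, min)
  }
  cls <- max.col(worst, ties.method = "first")
  flagged <- worst[cbind(seq_len(n), cls)] <= 0
  structure(cls, flagged = flagged)
}

#' @export
summary.snp_classifier <- function(object, ...) {
  D <- object$D
  pairs <- which(upper.tri(matrix(0, D, D)), arr.ind = TRUE)
  info <- data.frame(
    k = pairs[, 1], kp = pairs[, 2],
    threshold = object$K[pairs],
    mean_abs_coef = vapply(seq_len(nrow(pairs)), function(i)
      mean(abs(object$b[pairs[i, 1], pairs[i, 2], ])), 0))
  if (inherits(object, "snp_linear")) {
    info$n_selected <- vapply(seq_len(nrow(pairs)), function(i)
      sum(object$weights[pairs[i, 1], pairs[i, 2], ]), 0L)
  }
  structure(list(D = D, l = object$l, pairs = info,
                 kind = class(object)[1]), class = "summary.snp_classifier")
}

#' @export
print.summary.snp_classifier <- function(x, ...) {
  cat(sprintf("%s classifier, %d classes, %d SNPs\nPairwise summary:\n",
              x$kind, x$D, x$l))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
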