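#' Hardy-Weinberg genotype probabilities
#'
#' Probability mass function of the coded genotype \eqn{X \in \{0,1,2\}}
#' (number of minor alleles) at a biallelic locus with minor allele
#' frequency `theta`, under Hardy-Weinberg equilibrium:
#' \eqn{P(X = x) = \binom{2}{x}\theta^x(1-\theta)^{2-x}}.
#'
#' @param theta Minor allele frequency, strictly inside (0, 1).
#' @return Numeric vector of length 3: probabilities of 0, 1 and 2 minor
#'   alleles. The mean of the distribution is \eqn{2\theta} and its
#'   variance \eqn{2\theta(1-\theta)}.
#' @examples
#' hwe_pmf(0.4)  # 0.36 0.48 0.16
#' @export
hwe_pmf <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta <= 0 || theta >= 1) {
    stop("'theta' must be a single number strictly inside (0, 1)")
  }
  stats::dbinom(0:2, size = 2, prob = theta)
}

#' Per-class minor allele frequency profile
#'
#' Bundles the D x m matrix of per-class minor allele frequencies
#' \eqn{\theta_{k,j}} with the class prior probabilities \eqn{\pi_k}.
#' This is the parametric description of a D-class SNP population from
#' which genotypes are simulated and classifiers are built.
#'
#' Frequencies must lie in (0.01, 0.5): below 0.5 because they are
#' *minor* allele frequencies, above 0.01 so that the locus is a genuine
#' polymorphism rather than a rare mutation.
#'
#' @param theta Numeric matrix, D rows (classes) by m columns (SNPs).
#' @param priors Length-D vector of nonnegative class priors; defaults to
#'   uniform. Normalised to sum to 1.
#' @return An object of class `"maf_profile"`: a list with elements
#'   `theta` and `priors`.
#' @examples
#' prof <- maf_profile(rbind(c(0.45, 0.40), c(0.35, 0.30)))
#' @export
maf_profile <- function(theta, priors = NULL) {
  theta <- as.matrix(theta)
  if (!is.numeric(theta) || nrow(theta) < 2L) {
    stop("'theta' must be a numeric matrix with at least 2 rows (classes)")
  }
  bad <- which(theta <= 0.01 | theta >= 0.5, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "minor allele frequencies must lie in (0.01, 0.5); violated at class %d, SNP %d (theta = %.4g)",
      bad[1, 1], bad[1, 2], theta[bad[1, 1], bad[1, 2]]))
  }
  D <- nrow(theta)
  if (is.null(priors)) priors <- rep(1 / D, D)
  if (length(priors) != D || any(priors < 0) || sum(priors) <= 0) {
    stop("'priors' must be a length-D vector of nonnegative weights")
  }
  priors <- priors / sum(priors)
  structure(list(theta = theta, priors = priors), class = "maf_profile")
}

#' @export
print.maf_profile <- function(x, ...) {
  cat(sprintf("MAF profile: %d classes x %d SNPs\n",
              nrow(x$theta), ncol(x$theta)))
  cat("  priors:", paste(signif(x$priors, 4), collapse = " "), "\n")
  cat("  per-class mean MAF:",
      paste(signif(rowMeans(x$theta), 4), collapse = " "), "\n")
  invisible(x)
}

#' Study design parameters
#'
#' Collects the design constants of a classification study: number of
#' classes D, number of independent SNPs m, the fraction `rho` of SNPs
#' with a marginal effect between classes (so that `l = floor(rho * m)`
#' SNPs enter the optimal classifier), the per-class sample sizes, and
#' the level `alpha` of the per-SNP Wald tests used by the linear
#' classifier.
#'
#' @param D Integer number of classes, at least 2.
#' @param m Number of statistically independent SNPs used.
#' @param n_per_class Integer vector of per-class sample sizes (recycled
#'   to length D).
#' @param rho Fraction in (0, 1] of the m SNPs with marginal effect.
#' @param alpha Wald test level in (0, 1).
#' @param p_total Optional total number of SNPs before the independence
#'   filtering step.
#' @param seed Optional integer seed recorded with the design.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(D, m, n_per_class, rho = 1, alpha = 0.1,
                         p_total = NULL, seed = NULL) {
  D <- as.integer(D)
  m <- as.integer(m)
  if (D < 2L) stop("'D' must be at least 2")
  if (m < 1L) stop("'m' must be at least 1")
  if (rho <= 0 || rho > 1) stop("'rho' must be in (0, 1]")
  l <- max(1L, as.integer(floor(rho * m)))
  n_per_class <- as.integer(rep_len(n_per_class, D))
  if (any(n_per_class < 1L)) stop("all per-class sample sizes must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  structure(list(D = D, m = m, rho = rho, l = l,
                 n_per_class = n_per_class, alpha = alpha,
                 p_total = p_total, seed = seed),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: D = %d classes, m = %d SNPs (l = %d with effect), alpha = %g\n",
              x$D, x$m, x$l, x$alpha))
  cat("  n per class:", paste(x$n_per_class, collapse = " "), "\n")
  invisible(x)
}

#' Coded genotype matrix with class labels
#'
#' @param values Integer matrix, samples x SNPs, entries in {0, 1, 2}
#'   (minor-allele counts).
#' @param labels Class assignment per sample: integers in 1..D or a
#'   factor.
#' @param snp_ids Optional character vector of SNP identifiers.
#' @return An object of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(values, labels, snp_ids = NULL) {
  values <- as.matrix(values)
  if (any(is.na(values))) stop("missing genotypes are not allowed")
  if (!all(values %in% c(0, 1, 2))) {
    stop("genotype values must be 0, 1 or 2 (minor-allele counts)")
  }
  storage.mode(values) <- "integer"
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (length(labels) != nrow(values)) {
    stop("'labels' must have one entry per row of 'values'")
  }
  if (any(is.na(labels)) || any(labels < 1L)) {
    stop("'labels' must be positive integers (class indices)")
  }
  if (is.null(snp_ids)) {
    snp_ids <- colnames(values)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(values)))
  }
  colnames(values) <- snp_ids
  structure(list(values = values, labels = labels, snp_ids = snp_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d SNPs, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  tab <- table(x$labels)
  cat("  class sizes:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Simulate coded genotypes under Hardy-Weinberg equilibrium
#'
#' Draws `n_per_class[k]` samples for each class k with independent SNPs,
#' each genotype `X_j ~ Binomial(2, theta[k, j])`.
#'
#' @param profile A [maf_profile()].
#' @param n_per_class Integer vector of per-class sample sizes (recycled
#'   to D).
#' @param seed Optional integer seed; when given, the draw is
#'   reproducible and the caller's RNG state is left untouched.
#' @return A [genotype_matrix()] with labels 1..D.
#' @export
simulate_genotypes <- function(profile, n_per_class, seed = NULL) {
  stopifnot(inherits(profile, "maf_profile"))
  D <- nrow(profile$theta)
  m <- ncol(profile$theta)
  n_per_class <- as.integer(rep_len(n_per_class, D))
  if (any(n_per_class < 1L)) stop("all per-class sample sizes must be >= 1")
  with_seed(seed, {
    vals <- matrix(0L, sum(n_per_class), m)
    labels <- rep(seq_len(D), n_per_class)
    row0 <- 0L
    for (k in seq_len(D)) {
      nk <- n_per_class[k]
      vals[row0 + seq_len(nk), ] <- matrix(
        stats::rbinom(nk * m, 2L, rep(profile$theta[k, ], each = nk)), nk, m)
      row0 <- row0 + nk
    }
    genotype_matrix(vals, labels)
  })
}

#' @rdname simulate_genotypes
#' @param object A [maf_profile()].
#' @param nsim Per-class sample size(s), passed on as `n_per_class`.
#' @param ... Unused.
#' @export
simulate.maf_profile <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_genotypes(object, n_per_class = nsim, seed = seed)
}

#' Layered allele-frequency simulation design
#'
#' Builds the D-class MAF profile used throughout the simulation studies:
#' the top class has frequencies drawn uniformly from (0.4, 0.49) and each
#' subsequent class is the previous one shifted down by per-SNP gaps drawn
#' uniformly from `(h - 0.002, h + 0.002)`, so that the scalar `h`
#' controls the separation between adjacent classes. Priors are uniform.
#'
#' The recursion is applied D - 1 times, so designs with four or more
#' classes extend the three-class construction one layer per extra class.
#' A design whose frequencies would leave (0.01, 0.5) is rejected with an
#' error naming the offending class and SNP.
#'
#' @param D Number of classes (>= 2).
#' @param h Mean per-SNP allele-frequency gap between adjacent classes.
#' @param m Number of SNPs.
#' @param seed Optional integer seed.
#' @return A [maf_profile()] with uniform priors.
#' @examples
#' prof <- table1_design(D = 3, h = 0.1, m = 50, seed = 1)
#' range(prof$theta[3, ])  # within (0.2, 0.29)
#' @export
table1_design <- function(D, h, m, seed = NULL) {
  D <- as.integer(D)
  m <- as.integer(m)
  if (D < 2L) stop("'D' must be at least 2")
  if (h <= 0) stop("'h' must be positive")
  with_seed(seed, {
    theta <- matrix(0, D, m)
    theta[1, ] <- stats::runif(m, 0.4, 0.49)
    for (k in 2:D) {
      theta[k, ] <- theta[k - 1, ] - stats::runif(m, h - 0.002, h + 0.002)
      bad <- which(theta[k, ] <= 0.01)
      if (length(bad)) {
        stop(sprintf(
          "invalid design: theta[%d, %d] = %.4g falls at or below the 0.01 minor-allele floor (h too large for D)",
          k, bad[1], theta[k, bad[1]]))
      }
    }
    maf_profile(theta)
  })
}

#' Correlated-SNP test fixture with known structure
#'
#' Generates a genotype matrix whose first `m_independent` columns are
#' independent Hardy-Weinberg SNPs and whose remaining `m_redundant`
#' columns are copies of randomly chosen earlier independent columns,
#' with each entry independently resampled from the parent's HWE
#' distribution with probability `noise`. The ground-truth dependence
#' structure is attached so that SNP-selection procedures can be scored
#' against it.
#'
#' @param m_independent Number of independent SNP columns.
#' @param m_redundant Number of correlated (copied) columns.
#' @param noise Per-entry resampling probability in [0, 0.5).
#' @param n_samples Number of samples (rows).
#' @param seed Optional integer seed.
#' @return A [genotype_matrix()] (single class) with attribute
#'   `"parents"`: an integer vector, 0 for independent columns, otherwise
#'   the column index of the parent SNP.
#' @export
correlated_fixture <- function(m_independent, m_redundant, noise = 0,
                               n_samples = 500, seed = NULL) {
  if (noise < 0 || noise >= 0.5) stop("'noise' must be in [0, 0.5)")
  if (m_independent < 1L) stop("'m_independent' must be >= 1")
  with_seed(seed, {
    theta <- stats::runif(m_independent, 0.1, 0.45)
    vals <- matrix(stats::rbinom(n_samples * m_independent, 2L,
                                 rep(theta, each = n_samples)),
                   n_samples, m_independent)
    parents <- rep(0L, m_independent + m_redundant)
    if (m_redundant > 0L) {
      par <- sample.int(m_independent, m_redundant, replace = TRUE)
      extra <- matrix(0L, n_samples, m_redundant)
      for (j in seq_len(m_redundant)) {
        col <- vals[, par[j]]
        flip <- stats::runif(n_samples) < noise
        col[flip] <- stats::rbinom(sum(flip), 2L, theta[par[j]])
        extra[, j] <- col
      }
      vals <- cbind(vals, extra)
      parents[m_independent + seq_len(m_redundant)] <- par
    }
    g <- genotype_matrix(vals, labels = rep(1L, n_samples))
    attr(g, "parents") <- parents
    g
  })
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
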