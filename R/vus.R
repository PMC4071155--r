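#' Search parameters for the VUS threshold search
#'
#' Tuning constants for the stochastic exploration of threshold space
#' used by [vus()] and [vus_empirical()]. The search alternates an
#' ant-colony style step (Gaussian perturbation of retained threshold
#' vectors, scale `noise` times their interquartile range) with a
#' genetic step (uniform crossover of retained parents plus mutation)
#' and stops when the hull volume has grown by less than `tol` over
#' `stall` consecutive iterations.
#'
#' @param tol Convergence tolerance on the hull-volume increment.
#' @param max_iter Maximum number of search iterations (the search
#'   usually converges well before this cap; a capped run is reported with
#'   `converged = FALSE`).
#' @param n_init Size of the initial uniform threshold sample; default
#'   `128 * (D - 1)`.
#' @param pop Ant/genetic population size per step; default
#'   `64 * (D - 1)`.
#' @param noise Ant-step perturbation scale (fraction of the IQR of the
#'   retained threshold components).
#' @param crossover,mutation Genetic-step crossover and per-gene
#'   mutation probabilities.
#' @param stall Number of consecutive iterations over which the volume
#'   increment is compared with `tol`.
#' @param min_iter Minimum number of iterations before convergence may
#'   be declared.
#' @param contrib_eps A threshold vector contributes only if every class
#'   rate exceeds this value.
#' @param snap Lattice resolution of the exact hull engine: operating
#'   points are rounded to this grid before insertion, which also
#'   deduplicates the dense clusters the search produces on flat parts
#'   of the surface. The induced volume error is of order `snap`, well
#'   below `tol`.
#' @return A list of class `"vus_search_params"`.
#' @export
vus_search_params <- function(tol = 0.001, max_iter = 60, n_init = NULL,
                              pop = NULL, noise = 0.25, crossover = 0.9,
                              mutation = 0.1, stall = 3, min_iter = 5,
                              contrib_eps = 1e-6, snap = 5e-4) {
  structure(list(tol = tol, max_iter = max_iter, n_init = n_init, pop = pop,
                 noise = noise, crossover = crossover, mutation = mutation,
                 stall = stall, min_iter = min_iter,
                 contrib_eps = contrib_eps, snap = snap),
            class = "vus_search_params")
}

# Operating points xi for a batch of threshold offset vectors.
# approxes: per-class gaussian_approx list; kvecs: M x (D-1), class D pinned at 0.
# Returns M x D matrix of per-class correct-classification rates.
xi_batch <- function(approxes, kvecs) {
  D <- length(approxes)
  if (is.null(dim(kvecs))) kvecs <- matrix(kvecs, ncol = D - 1)
  M <- nrow(kvecs)
  Koff <- cbind(kvecs, 0)
  XI <- matrix(0, M, D)
  for (k in seq_len(D)) {
    ap <- approxes[[k]]
    A <- matrix(ap$kvec, M, D - 1, byrow = TRUE) +
      Koff[, ap$ks, drop = FALSE] - Koff[, k]
    XI[, k] <- orthant_upper_batch(A, ap$mu, ap$Sigma)
  }
  XI
}

#' Operating point of a classifier at given threshold offsets
#'
#' Computes the vector \eqn{\xi = (\xi_1, \ldots, \xi_D)} of per-class
#' correct-classification rates when each pairwise threshold
#' \eqn{K_{k,k'}} is shifted by \eqn{K_{k'} - K_k} for a vector of D - 1
#' free per-class offsets (the last class pinned at 0) — the family of
#' rules swept out by varying the class priors. These are the points
#' whose cloud fills the ROC hypersurface.
#'
#' @param approxes Per-class list of `"gaussian_approx"` objects.
#' @param kvec Numeric vector of D - 1 threshold offsets.
#' @return An object of class `"operating_point"`: the length-D rate
#'   vector with the generating `kvec` attached.
#' @export
operating_point <- function(approxes, kvec) {
  D <- length(approxes)
  if (length(kvec) != D - 1L) stop("'kvec' must have length D - 1")
  xi <- drop(xi_batch(approxes, matrix(kvec, 1)))
  structure(xi, kvec = kvec, class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat("Operating point xi:", paste(signif(unclass(x), 4), collapse = " "), "\n")
  cat("  thresholds:", paste(signif(attr(x, "kvec"), 4), collapse = " "), "\n")
  invisible(x)
}

# Shared search engine. xi_fun(kvecs) -> M x D rate matrix.
# score_scale: half-width of the initial threshold sampling box.
vus_engine <- function(xi_fun, D, score_scale, search = vus_search_params(),
                      seed = NULL, keep_points = TRUE, log_kvecs = FALSE) {
  with_seed(seed, {
    n_init <- if (is.null(search$n_init)) 128L * (D - 1L) else search$n_init
    pop <- if (is.null(search$pop)) 64L * (D - 1L) else search$pop
    R <- max(score_scale, 1)
    hull <- incremental_hull(rbind(diag(D), 0), snap = search$snap)
    cloud <- NULL
    retained <- NULL
    history <- numeric(0)
    seen <- new.env(parent = emptyenv())   # snapped points already inserted
    kvlog <- list()
    eval_batch <- function(kv) {
      if (log_kvecs) kvlog[[length(kvlog) + 1L]] <<- kv
      XI <- xi_fun(kv)
      contrib <- rowSums(XI > search$contrib_eps) == D
      if (any(contrib)) {
        pts <- XI[contrib, , drop = FALSE]
        base <- pts
        base[, 1] <- 0
        ins <- round(rbind(pts, base) / search$snap) * search$snap
        keys <- apply(ins, 1, paste, collapse = ",")
        fresh <- !duplicated(keys) & !vapply(keys, exists, NA, envir = seen)
        for (k in keys[fresh]) assign(k, TRUE, envir = seen)
        if (any(fresh)) hull_insert(hull, ins[fresh, , drop = FALSE])
        retained <<- rbind(retained, kv[contrib, , drop = FALSE])
        if (keep_points) cloud <<- rbind(cloud, pts)
      }
    }
    # deterministic sweeps seed the surface: origin, per-axis, pairwise grids
    sweeps <- matrix(0, 1, D - 1)
    gr <- seq(-1, 1, length.out = 21)
    for (j in seq_len(D - 1)) {
      kv <- matrix(0, length(gr), D - 1)
      kv[, j] <- gr * R
      sweeps <- rbind(sweeps, kv)
    }
    if (D - 1L >= 2L) {
      g2 <- seq(-1, 1, length.out = 9)
      pg <- as.matrix(expand.grid(g2, g2))
      for (i in seq_len(D - 2L)) {
        for (j in (i + 1L):(D - 1L)) {
          for (sc in c(0.15, 0.5, 1)) {
            kv <- matrix(0, nrow(pg), D - 1)
            kv[, i] <- pg[, 1] * R * sc
            kv[, j] <- pg[, 2] * R * sc
            sweeps <- rbind(sweeps, kv)
          }
        }
      }
    }
    if (D - 1L == 3L) {
      g3 <- seq(-1, 1, length.out = 9)
      pg3 <- as.matrix(expand.grid(g3, g3, g3))
      for (sc in c(0.1, 0.3, 0.65, 1)) sweeps <- rbind(sweeps, pg3 * R * sc)
    }
    scales <- rep(c(0.1, 0.3, 1), length.out = n_init)
    eval_batch(rbind(sweeps,
                     matrix(stats::runif(n_init * (D - 1), -R, R),
                            ncol = D - 1) * scales))
    history <- hull_volume(hull)
    converged <- FALSE
    for (it in seq_len(search$max_iter)) {
      if (is.null(retained) || nrow(retained) < 2L) {
        kv <- matrix(stats::runif(n_init * (D - 1), -R, R), ncol = D - 1) *
          rep(c(0.05, 0.2, 0.6), length.out = n_init)
      } else {
        nr <- nrow(retained)
        iqr <- max(0.05, stats::IQR(retained))
        sel <- retained[sample.int(nr, min(pop, nr)), , drop = FALSE]
        ant <- sel + matrix(stats::rnorm(length(sel), 0, search$noise * iqr),
                            nrow(sel))
        p1 <- retained[sample.int(nr, pop, TRUE), , drop = FALSE]
        p2 <- retained[sample.int(nr, pop, TRUE), , drop = FALSE]
        cross <- matrix(stats::runif(length(p1)) < 0.5, nrow(p1))
        ga <- ifelse(cross, p1, p2)
        keep_parent <- matrix(stats::runif(nrow(ga)) >= search$crossover,
                              nrow(ga), ncol(ga))
        ga[keep_parent] <- p1[keep_parent]
        mut <- matrix(stats::runif(length(ga)) < search$mutation, nrow(ga))
        ga[mut] <- stats::runif(sum(mut), -R, R)
        kv <- rbind(ant, ga)
      }
      eval_batch(kv)
      history <- c(history, hull_volume(hull))
      nh <- length(history)
      if (it >= search$min_iter && nh > search$stall &&
          history[nh] - history[nh - search$stall] < search$tol) {
        converged <- TRUE
        break
      }
    }
    structure(list(volume = hull_volume(hull), iterations = length(history) - 1L,
                   converged = converged, history = history,
                   points = cloud, D = D,
                   kvecs = if (log_kvecs) kvlog else NULL),
              class = "vus_result")
  })
}

# half-width of the threshold sampling box: cover mu +/- 6 sd of every
# pairwise score relative to its threshold
score_scale_from_approxes <- function(approxes) {
  R <- 0
  for (ap in approxes) {
    R <- max(R, max(abs(ap$mu - ap$kvec) + 6 * sqrt(pmax(0, diag(ap$Sigma)))))
  }
  R
}

#' Volume under the ROC hypersurface
#'
#' Computes the VUS of a D-class classifier (D >= 3) by stochastic
#' exploration of the (D-1)-dimensional threshold space: threshold
#' vectors are sampled, perturbed (ant-colony step) and recombined
#' (genetic step); every operating point \eqn{\xi} with all-positive
#' components is added to a cumulative cloud together with its base
#' projection (first component zeroed); the cloud is closed from below
#' by the unit-simplex anchors (origin and unit vectors, giving the
#' random-classifier floor 1/D!), and the VUS is the convex hull volume,
#' monotonically nondecreasing across iterations. The search stops when
#' the volume stops growing by more than `search$tol`.
#'
#' `vus()` is generic: give it a fitted [snp_bayes()] classifier for the
#' known-frequency VUS, a [maf_profile()] plus a [study_design()] for the
#' estimation-adjusted VUS at finite training sample sizes, or a
#' prebuilt list of per-class Gaussian approximations.
#'
#' @param object A `"snp_bayes"` classifier, a `"maf_profile"`, or a
#'   list of `"gaussian_approx"` objects.
#' @param ... Passed between methods.
#' @param search A [vus_search_params()] list.
#' @param seed Optional integer seed (the search is reproducible under a
#'   fixed seed).
#' @param keep_points Keep the accumulated rate cloud for plotting.
#' @return An object of class `"vus_result"`: list with `volume`,
#'   `iterations`, `converged`, `history` (per-iteration volumes,
#'   nondecreasing) and `points`.
#' @examples
#' prof <- table1_design(3, h = 0.1, m = 50, seed = 7)
#' v <- vus(snp_bayes(prof), seed = 7)
#' v
#' @export
vus <- function(object, ...) UseMethod("vus")

#' @rdname vus
#' @export
vus.snp_bayes <- function(object, ..., search = vus_search_params(),
                          seed = NULL, keep_points = TRUE) {
  vus.list(gaussian_approx_infty(object), search = search, seed = seed,
           keep_points = keep_points)
}

#' @rdname vus
#' @param design A [study_design()] (for the `maf_profile` method).
#' @param threshold_snps Threshold convention for the finite-sample
#'   approximation; see [gaussian_approx_n()].
#' @export
vus.maf_profile <- function(object, design, ..., search = vus_search_params(),
                            seed = NULL, keep_points = TRUE,
                            threshold_snps = c("selected", "all")) {
  vus.list(gaussian_approx_n(object, design,
                             threshold_snps = match.arg(threshold_snps)),
           search = search, seed = seed, keep_points = keep_points)
}

#' @rdname vus
#' @param score_scale Half-width of the threshold sampling box; defaults
#'   to covering every pairwise score distribution to 6 standard
#'   deviations. Supply a common value to couple searches across
#'   classifiers (common random numbers).
#' @param log_kvecs Record the evaluated threshold batches in the result
#'   (component `kvecs`), so the identical threshold sequence can be
#'   replayed against another classifier's score surfaces.
#' @export
vus.list <- function(object, ..., search = vus_search_params(), seed = NULL,
                     keep_points = TRUE, score_scale = NULL,
                     log_kvecs = FALSE) {
  approxes <- object
  D <- length(approxes)
  if (D < 3L) stop("VUS needs D >= 3 classes; use auc() for D = 2")
  if (is.null(score_scale)) score_scale <- score_scale_from_approxes(approxes)
  vus_engine(function(kv) xi_batch(approxes, kv), D, score_scale,
             search = search, seed = seed, keep_points = keep_points,
             log_kvecs = log_kvecs)
}

#' @export
print.vus_result <- function(x, ...) {
  cat(sprintf("VUS = %.4f  (%d classes; floor 1/D! = %.4f)\n",
              x$volume, x$D, 1 / factorial(x$D)))
  cat(sprintf("  search: %d iterations, %sconverged, %d operating points\n",
              x$iterations, if (x$converged) "" else "NOT ",
              if (is.null(x$points)) 0L else nrow(x$points)))
  invisible(x)
}

#' @export
plot.vus_result <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1L, x$history, type = "s",
                 xlab = "search iteration", ylab = "hull volume (VUS)",
                 main = sprintf("VUS search convergence (final %.4f)", x$volume),
                 ...)
  graphics::abline(h = 1 / factorial(x$D), lty = 3)
  invisible(x)
}

#' Monte Carlo (empirical) VUS of a fitted classifier
#'
#' Runs the same threshold search as [vus()], but evaluates each
#' operating point empirically: \eqn{\xi_k} is the fraction of class-k
#' test samples whose pairwise scores all clear the offset-shifted
#' thresholds. This is the Monte Carlo estimate used to validate the
#' Gaussian approximations.
#'
#' @param classifier A fitted `"snp_classifier"`.
#' @param test_data A [genotype_matrix()] whose labels cover all D
#'   classes.
#' @param search A [vus_search_params()] list.
#' @param seed Optional integer seed.
#' @param keep_points Keep the rate cloud.
#' @return A `"vus_result"`.
#' @export
vus_empirical <- function(classifier, test_data, search = vus_search_params(),
                          seed = NULL, keep_points = TRUE) {
  stopifnot(inherits(classifier, "snp_classifier"),
            inherits(test_data, "genotype_matrix"))
  D <- classifier$D
  present <- sort(unique(test_data$labels))
  if (!identical(as.integer(present), seq_len(D))) {
    stop("test data must contain samples from every class")
  }
  if (D < 3L) stop("VUS needs D >= 3 classes")
  marg <- pairwise_margins(classifier, test_data$values)
  labs <- test_data$labels
  class_rows <- lapply(seq_len(D), function(k) which(labs == k))
  # worst-case margin per sample/class under offset kvec:
  # min_{k'} (marg[, k, k'] - (kv[k'] - kv[k]))
  xi_fun <- function(kvecs) {
    M <- nrow(kvecs)
    Koff <- cbind(kvecs, 0)
    XI <- matrix(0, M, D)
    for (k in seq_len(D)) {
      rows <- class_rows[[k]]
      mk <- marg[rows, k, , drop = FALSE]
      dim(mk) <- c(length(rows), D)
      for (i in seq_len(M)) {
        shifted <- mk - rep(Koff[i, ] - Koff[i, k], each = length(rows))
        shifted[, k] <- Inf
        XI[i, k] <- mean(apply(shifted, 1, min) > 0)
      }
    }
    XI
  }
  # score scale: spread of observed margins
  sc <- max(1, stats::quantile(abs(marg[is.finite(marg)]), 0.99))
  vus_engine(xi_fun, D, sc, search = search, seed = seed,
             keep_points = keep_points)
}

#' Area under the ROC curve for two classes
#'
#' For D = 2 the ROC is one-dimensional and the AUC is computed by
#' deterministic trapezoidal integration of \eqn{\xi_2} against
#' \eqn{1 - \xi_1} over a monotone grid of thresholds spanning both
#' score distributions (no stochastic search is needed).
#'
#' @param object A `"snp_bayes"` classifier (with D = 2), a
#'   `"maf_profile"` (with `design`, for the finite-sample variant), or
#'   a list of two `"gaussian_approx"` objects.
#' @param ... Passed between methods.
#' @param n_grid Number of thresholds (>= 512).
#' @return The AUC, a scalar in \[0, 1\].
#' @export
auc <- function(object, ...) UseMethod("auc")

#' @rdname auc
#' @export
auc.snp_bayes <- function(object, ..., n_grid = 1024) {
  if (object$D != 2L) stop("auc() is for D = 2 classes; use vus() for D >= 3")
  auc.list(gaussian_approx_infty(object), n_grid = n_grid)
}

#' @rdname auc
#' @param design A [study_design()] (for the `maf_profile` method).
#' @param threshold_snps Threshold convention; see [gaussian_approx_n()].
#' @export
auc.maf_profile <- function(object, design, ..., n_grid = 1024,
                            threshold_snps = c("selected", "all")) {
  if (nrow(object$theta) != 2L) stop("auc() is for D = 2 classes")
  auc.list(gaussian_approx_n(object, design,
                             threshold_snps = match.arg(threshold_snps)),
           n_grid = n_grid)
}

#' @rdname auc
#' @export
auc.list <- function(object, ..., n_grid = 1024) {
  approxes <- object
  if (length(approxes) != 2L) stop("auc() needs exactly 2 classes")
  n_grid <- max(512L, as.integer(n_grid))
  # class 1 score S_{1,2}: N(mu1, s1^2), threshold kvec1; class 2 score
  # S_{2,1} = -S_{1,2} (+ const). Sweep a scalar offset t over mu +/- 8 sd.
  a1 <- approxes[[1]]
  a2 <- approxes[[2]]
  s1 <- sqrt(a1$Sigma[1, 1])
  s2 <- sqrt(a2$Sigma[1, 1])
  if (s1 < 1e-8 && s2 < 1e-8) {
    # degenerate (deterministic) scores: the ROC is a single step
    d1 <- a1$mu - a1$kvec
    d2 <- a2$mu - a2$kvec
    return(if (d1 + d2 > 0) 1 else if (d1 + d2 < 0) 0 else 0.5)
  }
  lo <- min(a1$kvec - a1$mu - 8 * s1, -(a2$kvec - a2$mu) - 8 * s2)
  hi <- max(a1$kvec - a1$mu + 8 * s1, -(a2$kvec - a2$mu) + 8 * s2)
  t <- seq(lo, hi, length.out = n_grid)
  # offsets kvec = (t, 0): threshold of class 1 shifted by -t, class 2 by +t
  xi1 <- orthant_upper_batch(matrix(a1$kvec - t, ncol = 1), a1$mu, a1$Sigma)
  xi2 <- orthant_upper_batch(matrix(a2$kvec + t, ncol = 1), a2$mu, a2$Sigma)
  fpr <- 1 - xi1                       # decreasing in t
  o <- order(fpr)
  x <- fpr[o]
  y <- xi2[o]
  x <- c(0, x, 1)
  y <- c(min(y), y, max(y))
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}


# Replay a recorded sequence of threshold batches against a different set
# of class-score approximations: the coupled evaluation used for the
# sample-size criterion, where the same thresholds probe the known-theta
# surface and every finite-n surface so that their volume difference
# reflects the estimation effect rather than search randomness.
vus_replay <- function(approxes, kvecs, search = vus_search_params()) {
  D <- length(approxes)
  hull <- incremental_hull(rbind(diag(D), 0), snap = search$snap)
  seen <- new.env(parent = emptyenv())
  for (kv in kvecs) {
    XI <- xi_batch(approxes, kv)
    contrib <- rowSums(XI > search$contrib_eps) == D
    if (!any(contrib)) next
    pts <- XI[contrib, , drop = FALSE]
    base <- pts
    base[, 1] <- 0
    ins <- round(rbind(pts, base) / search$snap) * search$snap
    keys <- apply(ins, 1, paste, collapse = ",")
    fresh <- !duplicated(keys) & !vapply(keys, exists, NA, envir = seen)
    for (k in keys[fresh]) assign(k, TRUE, envir = seen)
    if (any(fresh)) hull_insert(hull, ins[fresh, , drop = FALSE])
  }
  hull_volume(hull)
}
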