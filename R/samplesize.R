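#' VUS gap criterion f(n)
#'
#' Evaluates \eqn{f(n) = \mathrm{VUS}(\infty) - \mathrm{VUS}(n) - \gamma}
#' for a given per-class training sample size n: the loss in volume under
#' the ROC hypersurface incurred by having to estimate the classifier
#' from n samples per class, minus the tolerated gap. Negative values
#' mean n is large enough.
#'
#' Both volumes are evaluated on the *same* recorded threshold sequence
#' (common random numbers): one stochastic search is run on the
#' known-frequency surface, its threshold batches are recorded, and every
#' finite-n surface is evaluated by replaying those batches, so the gap
#' reflects the estimation effect rather than independent search noise
#' and is smooth enough in n for the bisection's sign logic. The
#' reference search can be supplied precomputed via `reference`.
#'
#' @param profile A [maf_profile()].
#' @param design A [study_design()]; its `n_per_class` is overridden
#'   by `n`.
#' @param n Per-class sample size to evaluate.
#' @param gamma Gap threshold in (0, 1).
#' @param search A [vus_search_params()] list.
#' @param seed Integer seed for the reference search.
#' @param reference Optional precomputed reference, as returned in the
#'   `"reference"` attribute of an earlier call with the same profile,
#'   design and search settings.
#' @return f(n), with attributes `"vus_infty"`, `"vus_n"` and
#'   `"reference"`.
#' @export
vus_gap <- function(profile, design, n, gamma, search = vus_search_params(),
                    seed = NULL, reference = NULL) {
  if (n < 1) stop("'n' must be at least 1")
  if (gamma <= 0 || gamma >= 1) stop("'gamma' must be in (0, 1)")
  D <- design$D
  dn <- design
  dn$n_per_class <- rep(as.integer(n), D)
  if (D == 2L) {
    vus_infty <- if (is.null(reference)) auc(snp_bayes(profile, l = design$l))
                 else reference$volume
    vn <- auc(profile, dn)
    return(structure(vus_infty - vn - gamma, vus_infty = vus_infty,
                     vus_n = vn, reference = list(volume = vus_infty)))
  }
  ap_n <- gaussian_approx_n(profile, dn)
  if (is.null(reference)) {
    # one sampling-box scale wide enough for the whole family of surfaces
    ap_inf <- gaussian_approx_infty(snp_bayes(profile, l = design$l))
    scale <- max(score_scale_from_approxes(ap_inf),
                 score_scale_from_approxes(ap_n))
    ref_fit <- vus(ap_inf, search = search, seed = seed,
                   keep_points = FALSE, score_scale = scale,
                   log_kvecs = TRUE)
    reference <- list(volume = ref_fit$volume, kvecs = ref_fit$kvecs)
  }
  vn <- vus_replay(ap_n, reference$kvecs, search = search)
  structure(reference$volume - vn - gamma, vus_infty = reference$volume,
            vus_n = vn, reference = reference)
}

#' Smallest per-class sample size meeting a VUS gap threshold
#'
#' Integer bisection for the smallest per-class n with
#' \eqn{\mathrm{VUS}(\infty) - \mathrm{VUS}(n) < \gamma} (AUC for
#' D = 2): starting from a bracket `[n_S, n_L]` with \eqn{f(n_S) > 0}
#' and \eqn{f(n_L) < 0}, the midpoint replaces whichever end keeps the
#' sign change, until `n_L - n_S <= 1`; the answer is `n_L`. If the
#' initial bracket does not straddle the root it is expanded
#' geometrically (factor 4) up to `n_cap`. Evaluations use common
#' random numbers across n (one shared seed), and the returned root is
#' re-verified at `n_L` and `n_L - 1` with a tightened search tolerance,
#' locally re-bracketing if Monte Carlo noise flipped a sign.
#'
#' @param profile A [maf_profile()].
#' @param design A [study_design()]; per-class sizes are the search
#'   variable.
#' @param gamma Gap threshold in (0, 1).
#' @param bracket Integer vector `c(n_S, n_L)` of initial bracket ends.
#' @param search A [vus_search_params()] list.
#' @param seed Integer seed driving all VUS searches.
#' @param n_cap Upper limit for bracket expansion.
#' @param f Optional criterion function `f(n)` overriding the VUS-based
#'   one (used to exercise the bisection logic on deterministic stubs).
#' @param verify Re-verify the returned root with a 2x tighter tolerance.
#' @return An object of class `"samplesize_fit"`: list with `n`
#'   (per-class), `total` (D * n), `gamma`, `f_evals` (trace of
#'   evaluated n and f(n)), `vus_infty`, and the final bracket.
#' @examples
#' # exact integer root on a deterministic stub criterion
#' fit <- find_sample_size(gamma = 0.01, bracket = c(1, 4096),
#'                         f = function(n) 100 / n - 0.5)
#' fit$n  # 201
#' @export
find_sample_size <- function(profile = NULL, design = NULL, gamma = 0.01,
                             bracket = c(10, 5000),
                             search = vus_search_params(), seed = NULL,
                             n_cap = 2^18, f = NULL, verify = TRUE) {
  if (gamma <= 0 || gamma >= 1) stop("'gamma' must be in (0, 1)")
  evals <- data.frame(n = integer(0), f = numeric(0))
  vus_inf <- NULL
  refs <- new.env(parent = emptyenv())   # reference search per tolerance
  if (is.null(f)) {
    stopifnot(inherits(profile, "maf_profile"), inherits(design, "study_design"))
    base_f <- function(n, sch = search) {
      key <- as.character(sch$tol)
      g <- vus_gap(profile, design, n, gamma, search = sch, seed = seed,
                   reference = refs[[key]])
      if (is.null(refs[[key]])) refs[[key]] <- attr(g, "reference")
      if (is.null(vus_inf)) vus_inf <<- attr(g, "vus_infty")
      as.numeric(g)
    }
  } else {
    base_f <- function(n, sch = search) f(n)
  }
  fmem <- new.env(parent = emptyenv())
  feval <- function(n, sch = search) {
    key <- as.character(n)
    if (!is.null(fmem[[key]])) return(fmem[[key]])
    val <- base_f(n, sch)
    fmem[[key]] <- val
    evals[nrow(evals) + 1L, ] <<- list(as.integer(n), val)
    val
  }
  nS <- as.integer(bracket[1])
  nL <- as.integer(bracket[2])
  if (nS < 1L || nL <= nS) stop("invalid bracket")
  fS <- feval(nS)
  fL <- feval(nL)
  while (fS <= 0 && nS > 1L) {          # gap already small at n_S: shrink
    nS <- max(1L, nS %/% 4L)
    fS <- feval(nS)
  }
  while (fL >= 0 && nL < n_cap) {       # gap still large at n_L: expand
    nL <- min(n_cap, nL * 4L)
    fL <- feval(nL)
  }
  if (fS <= 0) {
    # even one sample per class meets the criterion
    if (feval(1L) < 0) {
      nL <- 1L
    } else {
      nS <- 1L
    }
  }
  if (fL >= 0) {
    stop(sprintf(
      "cannot bracket the root: f(%d) = %.4g is still positive; gamma = %g may be too small for this design (cap %d)",
      nL, fL, gamma, n_cap))
  }
  if (nL > 1L && feval(nS) > 0) {
    while (nL - nS > 1L) {
      nM <- (nS + nL) %/% 2L
      # the criterion is the strict inequality f < 0, so a midpoint with
      # f = 0 exactly still fails it and moves the lower end
      if (feval(nM) < 0) nL <- nM else nS <- nM
    }
  }
  if (verify && is.null(f) && nL > 1L) {
    tight <- search
    tight$tol <- search$tol / 2
    f_hi <- base_f(nL, tight)
    f_lo <- base_f(nL - 1L, tight)
    if (f_hi >= 0) {                       # root drifted up: re-bracket above
      nS <- nL
      nL <- min(n_cap, as.integer(ceiling(nL * 1.25)) + 1L)
      while (base_f(nL, tight) >= 0 && nL < n_cap) {
        nS <- nL
        nL <- min(n_cap, 2L * nL)
      }
      while (nL - nS > 1L) {
        nM <- (nS + nL) %/% 2L
        if (base_f(nM, tight) < 0) nL <- nM else nS <- nM
      }
    } else if (f_lo < 0) {                 # root drifted down: re-bracket
      nL <- nL - 1L
      nS2 <- max(1L, nL %/% 2L)
      while (nS2 > 1L && base_f(nS2, tight) < 0) {
        nL <- nS2
        nS2 <- max(1L, nS2 %/% 2L)
      }
      if (nS2 == 1L && base_f(1L, tight) < 0) {
        nL <- 1L
      } else {
        while (nL - nS2 > 1L) {
          nM <- (nS2 + nL) %/% 2L
          if (base_f(nM, tight) < 0) nL <- nM else nS2 <- nM
        }
      }
    }
  }
  D <- if (!is.null(design)) design$D else NA_integer_
  structure(list(n = nL, total = if (is.na(D)) NA_integer_ else D * nL,
                 D = D, gamma = gamma, f_evals = evals,
                 vus_infty = vus_inf, bracket = c(nS, nL)),
            class = "samplesize_fit")
}

#' @export
print.samplesize_fit <- function(x, ...) {
  cat(sprintf("Required sample size: n = %d per class", x$n))
  if (!is.na(x$D)) cat(sprintf(" (total %d over %d classes)", x$total, x$D))
  cat(sprintf("\n  gap threshold gamma = %g", x$gamma))
  if (!is.null(x$vus_infty)) {
    cat(sprintf("; VUS(infinity) = %.4f", x$vus_infty))
  }
  cat(sprintf("\n  criterion evaluations: %d\n", nrow(x$f_evals)))
  invisible(x)
}

#' Learning curve: required sample size over a grid of gap thresholds
#'
#' Runs [find_sample_size()] for each gamma in `gamma_grid`, reusing all
#' VUS(n) evaluations across thresholds (f is just shifted by gamma, so
#' one cache of gap evaluations serves the whole curve). The required n
#' is nonincreasing in gamma.
#'
#' @param profile A [maf_profile()].
#' @param design A [study_design()].
#' @param gamma_grid Increasing vector of gap thresholds in (0, 1).
#' @param search A [vus_search_params()] list.
#' @param seed Integer seed (common random numbers).
#' @param bracket Initial bisection bracket.
#' @return An object of class `"learning_curve"`: data frame with
#'   columns `gamma`, `n_per_class`, `n_total`.
#' @export
learning_curve <- function(profile, design, gamma_grid,
                           search = vus_search_params(), seed = NULL,
                           bracket = c(10, 5000)) {
  stopifnot(all(diff(gamma_grid) > 0), all(gamma_grid > 0 & gamma_grid < 1))
  D <- design$D
  gapmem <- new.env(parent = emptyenv())
  ref <- NULL
  gap_at <- function(n) {                # VUS(inf) - VUS(n), cached over n
    key <- as.character(n)
    if (!is.null(gapmem[[key]])) return(gapmem[[key]])
    g <- vus_gap(profile, design, n, gamma = 0.5, search = search,
                 seed = seed, reference = ref)
    if (is.null(ref)) ref <<- attr(g, "reference")
    gapmem[[key]] <- attr(g, "vus_infty") - attr(g, "vus_n")
    gapmem[[key]]
  }
  v_inf <- NULL
  rows <- lapply(gamma_grid, function(g) {
    fit <- find_sample_size(gamma = g, bracket = bracket,
                            f = function(n) gap_at(n) - g)
    data.frame(gamma = g, n_per_class = fit$n, n_total = D * fit$n)
  })
  gap_at(bracket[1])     # ensure the reference exists even on tiny grids
  v_inf <- attr(vus_gap(profile, design, bracket[1], gamma = 0.5,
                        search = search, seed = seed, reference = ref),
                "vus_infty")
  out <- do.call(rbind, rows)
  structure(out, vus_infty = v_inf, class = c("learning_curve", "data.frame"))
}

#' @export
plot.learning_curve <- function(x, ...) {
  graphics::plot(x$gamma, x$n_total, type = "b", log = "y",
                 xlab = expression(gamma), ylab = "total sample size",
                 main = "Learning curve", ...)
  invisible(x)
}
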