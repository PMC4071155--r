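#' Kendall's tau between two genotype columns
#'
#' Tie-corrected (tau-b) rank correlation between two 0/1/2-coded
#' genotype vectors, the statistic used to screen SNP pairs for
#' independence. Coded genotypes are massively tied, so the
#' tie-corrected variant is the only usable one. A constant column has
#' no defined correlation; it is reported as 0 (treated as independent)
#' with a warning.
#'
#' @param x,y Equal-length numeric vectors (genotype columns).
#' @return tau in \[-1, 1\].
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("constant genotype column: Kendall's tau undefined, returning 0")
    return(0)
  }
  unname(stats::cor(x, y, method = "kendall"))
}

#' Greedy extraction of a pairwise-independent SNP subset
#'
#' Builds a set S of approximately independent SNPs by the greedy scan
#' used to construct SNP panels from dense genotype data: seed S with
#' the first SNP in scan order; then, for each remaining SNP in order,
#' add it to S when its association with *every* current member of S is
#' below the cutoff; stop when no further SNP can be added. Every
#' retained pair satisfies |tau| < `threshold` (or a Kendall test
#' p-value above `threshold` in `"pvalue"` mode), and every rejected SNP
#' conflicts with at least one retained SNP, so S is maximal for the
#' scan order.
#'
#' @param data A [genotype_matrix()].
#' @param threshold Cutoff, default 0.05.
#' @param mode `"statistic"` compares |tau| itself with the cutoff
#'   (the default reading: small tau means independent); `"pvalue"`
#'   instead requires the Kendall test p-value to *exceed* the cutoff.
#' @param order_policy `"input"` scans columns in their given order;
#'   `"maf"` scans in decreasing minor-allele-frequency order.
#' @return An object of class `"snp_selection"`: list with `selected`
#'   (SNP ids in selection order), `selected_idx`, `rejected` (named
#'   integer vector mapping each rejected SNP to the first retained SNP
#'   that excluded it), `threshold`, `mode`, and `tau_matrix` (|tau|
#'   values examined; NA where never computed).
#' @examples
#' g <- correlated_fixture(5, 5, noise = 0, n_samples = 200, seed = 1)
#' sel <- select_independent(g)
#' length(sel$selected)  # 5: one per independent block
#' @export
select_independent <- function(data, threshold = 0.05,
                               mode = c("statistic", "pvalue"),
                               order_policy = c("input", "maf")) {
  stopifnot(inherits(data, "genotype_matrix"))
  mode <- match.arg(mode)
  order_policy <- match.arg(order_policy)
  X <- data$values
  m <- ncol(X)
  ord <- switch(order_policy,
                input = seq_len(m),
                maf = order(colMeans(X) / 2, decreasing = TRUE))
  tau_mat <- matrix(NA_real_, m, m, dimnames = list(data$snp_ids, data$snp_ids))
  indep <- function(i, j) {
    # a cutoff at or above 1 is vacuous (|tau| <= 1 always): keep all
    if (mode == "statistic" && threshold >= 1) return(TRUE)
    if (mode == "statistic") {
      tau <- abs(kendall_tau(X[, i], X[, j]))
      tau_mat[i, j] <<- tau
      tau_mat[j, i] <<- tau
      tau < threshold
    } else {
      ct <- suppressWarnings(
        stats::cor.test(X[, i], X[, j], method = "kendall"))
      tau_mat[i, j] <<- abs(unname(ct$estimate))
      tau_mat[j, i] <<- tau_mat[i, j]
      ct$p.value > threshold
    }
  }
  S <- ord[1]
  rejected <- integer(0)
  for (j in ord[-1]) {
    blocker <- 0L
    for (i in S) {
      if (!indep(i, j)) {
        blocker <- i
        break
      }
    }
    if (blocker == 0L) {
      S <- c(S, j)
    } else {
      rejected[data$snp_ids[j]] <- blocker
    }
  }
  structure(list(selected = data$snp_ids[S], selected_idx = S,
                 rejected = rejected, threshold = threshold, mode = mode,
                 order_policy = order_policy, tau_matrix = tau_mat),
            class = "snp_selection")
}

#' @export
print.snp_selection <- function(x, ...) {
  cat(sprintf("SNP independence screen (|tau| %s %g, %s mode): %d selected, %d rejected\n",
              if (x$mode == "statistic") "<" else "p >", x$threshold, x$mode,
              length(x$selected), length(x$rejected)))
  cat("  selected:", paste(utils::head(x$selected, 10), collapse = " "),
      if (length(x$selected) > 10) "..." else "", "\n")
  invisible(x)
}
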