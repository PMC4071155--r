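#' Simulation study: approximation accuracy of VUS(n)
#'
#' For each cell (D, h, m, n), draws `reps_design` allele-frequency
#' designs from [table1_design()], computes the known-frequency VUS and
#' the estimation-adjusted VUS(n), and estimates the Monte Carlo VUS by
#' fitting a linear classifier to `reps_data` simulated training sets
#' per design and running the empirical threshold search on an
#' independent test set. Reports per-cell averages, the bias of the
#' analytic approximation (MC minus approximation), and Monte Carlo
#' standard errors.
#'
#' @param cells List of numeric vectors `c(D, h, m, n)` (or a 4-column
#'   matrix / data frame).
#' @param reps_design Number of independent design draws per cell.
#' @param reps_data Number of training data sets per design draw.
#' @param n_test Per-class size of the independent test set used for the
#'   empirical rates.
#' @param alpha Wald level of the linear classifier.
#' @param search A [vus_search_params()] list.
#' @param seed Integer seed.
#' @return Data frame with one row per cell: `D, h, m, n, vus_infty,
#'   vus_n, vus_mc, bias, se_infty, se_mc`.
#' @export
run_table1 <- function(cells, reps_design = 5, reps_data = 5, n_test = 200,
                       alpha = 0.1, search = vus_search_params(),
                       seed = NULL) {
  cells <- normalize_cells(cells, 4L)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(cells)), function(ci) {
      D <- cells[ci, 1]
      h <- cells[ci, 2]
      m <- cells[ci, 3]
      n <- cells[ci, 4]
      v_inf <- v_n <- numeric(reps_design)
      v_mc <- matrix(0, reps_design, reps_data)
      for (r in seq_len(reps_design)) {
        prof <- table1_design(D, h, m)
        des <- study_design(D, m, n_per_class = n, alpha = alpha)
        sub_seed <- sample.int(.Machine$integer.max, 1)
        v_inf[r] <- vus(snp_bayes(prof), search = search, seed = sub_seed,
                        keep_points = FALSE)$volume
        v_n[r] <- vus(prof, des, search = search, seed = sub_seed,
                      keep_points = FALSE)$volume
        test <- simulate_genotypes(prof, n_per_class = n_test)
        for (t in seq_len(reps_data)) {
          train <- simulate_genotypes(prof, n_per_class = n)
          fit <- snp_linear(train, alpha = alpha)
          v_mc[r, t] <- vus_empirical(fit, test, search = search,
                                      seed = sub_seed,
                                      keep_points = FALSE)$volume
        }
      }
      data.frame(D = D, h = h, m = m, n = n,
                 vus_infty = mean(v_inf), vus_n = mean(v_n),
                 vus_mc = mean(v_mc), bias = mean(v_mc) - mean(v_n),
                 se_infty = stats::sd(v_inf) / sqrt(reps_design),
                 se_mc = stats::sd(rowMeans(v_mc)) / sqrt(reps_design))
    })
    do.call(rbind, rows)
  })
}

#' Simulation study: required sample sizes over designs
#'
#' For each cell (D, h, m), draws a design from [table1_design()] and
#' runs the bisection search for the smallest per-class n with
#' VUS(infinity) - VUS(n) < gamma.
#'
#' @param cells List of numeric vectors `c(D, h, m)` (or a 3-column
#'   matrix / data frame).
#' @param gamma Gap threshold.
#' @param reps Number of design draws averaged per cell.
#' @param alpha Wald level.
#' @param search A [vus_search_params()] list.
#' @param seed Integer seed.
#' @return Data frame with one row per cell: `D, h, m, gamma,
#'   n_per_class, n_total` (averaged over `reps`, rounded to integers).
#' @export
run_table2 <- function(cells, gamma = 0.01, reps = 1, alpha = 0.1,
                       search = vus_search_params(), seed = NULL) {
  cells <- normalize_cells(cells, 3L)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(cells)), function(ci) {
      D <- cells[ci, 1]
      h <- cells[ci, 2]
      m <- cells[ci, 3]
      ns <- numeric(reps)
      for (r in seq_len(reps)) {
        prof <- table1_design(D, h, m)
        des <- study_design(D, m, n_per_class = 100, alpha = alpha)
        sub_seed <- sample.int(.Machine$integer.max, 1)
        fit <- find_sample_size(prof, des, gamma = gamma, search = search,
                                seed = sub_seed)
        ns[r] <- fit$n
      }
      data.frame(D = D, h = h, m = m, gamma = gamma,
                 n_per_class = round(mean(ns)),
                 n_total = D * round(mean(ns)))
    })
    do.call(rbind, rows)
  })
}

normalize_cells <- function(cells, width) {
  if (is.list(cells) && !is.data.frame(cells)) {
    cells <- do.call(rbind, cells)
  }
  cells <- as.matrix(cells)
  if (ncol(cells) != width) {
    stop(sprintf("each cell must have %d entries", width))
  }
  cells
}
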