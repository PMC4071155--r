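#' Read a coded genotype matrix from TSV
#'
#' Expects a header row `sample_id<TAB>class<TAB><snp ids...>` followed
#' by one row per sample with integer genotype codes 0/1/2. Missing
#' values are rejected with an error.
#'
#' @param path File path.
#' @return A [genotype_matrix()]. Class labels are taken as integers if
#'   the `class` column is numeric, otherwise factor levels in order of
#'   appearance are mapped to 1..D (recorded in attribute
#'   `"class_levels"`).
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expected columns: sample_id, class, then SNPs")
  if (!identical(tolower(names(df)[1:2]), c("sample_id", "class"))) {
    stop("first two columns must be 'sample_id' and 'class'")
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  if (any(is.na(vals))) stop("missing genotypes are not allowed in TSV input")
  labels <- df[[2]]
  levels <- NULL
  if (!is.numeric(labels)) {
    levels <- unique(labels)
    labels <- match(labels, levels)
  }
  g <- genotype_matrix(vals, labels, snp_ids = names(df)[-(1:2)])
  rownames(g$values) <- df[[1]]
  attr(g, "class_levels") <- levels
  g
}

#' Write a coded genotype matrix to TSV
#'
#' @param data A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(data, path) {
  stopifnot(inherits(data, "genotype_matrix"))
  ids <- rownames(data$values)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(data$values)))
  df <- data.frame(sample_id = ids, class = data$labels,
                   data$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and code genotypes from a VCF file
#'
#' Codes biallelic SNP records as minor-allele counts: for each site the
#' in-sample allele frequency decides which allele is minor, and each
#' sample's code is its count of that allele. Multiallelic records and
#' records with any missing genotype are skipped (a message reports how
#' many). Class labels must be supplied separately, one per sample.
#'
#' @param path VCF file path (plain or gzipped; requires the `vcfR`
#'   package).
#' @param labels Class labels, one per sample in the VCF.
#' @return A [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, labels) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  # allele dosage of ALT; any unparseable/missing genotype drops the record
  dose <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(a, function(p) {
      if (length(p) != 2L || any(is.na(p)) || any(p == ".")) return(NA_real_)
      sum(as.numeric(p) > 0)
    }, 0)
  }
  keep <- !multi
  counts <- t(apply(gt[keep, , drop = FALSE], 1, dose))
  has_missing <- apply(counts, 1, anyNA)
  n_skipped <- sum(multi) + sum(has_missing)
  if (n_skipped > 0) {
    message(sprintf("skipped %d records (%d multiallelic, %d with missing genotypes)",
                    n_skipped, sum(multi), sum(has_missing)))
  }
  counts <- counts[!has_missing, , drop = FALSE]
  ids <- rownames(gt)[keep][!has_missing]
  # recode to minor-allele counts per site
  af <- rowMeans(counts) / 2
  flip <- af > 0.5
  counts[flip, ] <- 2 - counts[flip, , drop = FALSE]
  g <- genotype_matrix(t(counts), labels = labels, snp_ids = ids)
  g
}

#' Serialize a classifier to JSON
#'
#' Writes the full parameter set of a fitted classifier (frequencies,
#' priors, weights, thresholds) to a JSON document, from which
#' [read_classifier_json()] rebuilds an identical object.
#'
#' @param object A fitted `"snp_classifier"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier_json <- function(object, path) {
  stopifnot(inherits(object, "snp_classifier"))
  if (inherits(object, "snp_bayes")) {
    doc <- list(kind = "bayes",
                theta = object$profile$theta,
                priors = object$profile$priors,
                l = object$l)
  } else {
    doc <- list(kind = "linear",
                theta_hat = object$theta_hat,
                n_per_class = object$n_per_class,
                priors = object$priors,
                alpha = object$alpha,
                threshold_snps = object$threshold_snps,
                weights = object$weights)
  }
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_classifier_json
#' @param path JSON path written by [write_classifier_json()].
#' @return `read_classifier_json()` returns the rebuilt classifier.
#' @export
read_classifier_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$kind, "bayes")) {
    return(snp_bayes(maf_profile(doc$theta, doc$priors), l = doc$l))
  }
  if (identical(doc$kind, "linear")) {
    th <- as.matrix(doc$theta_hat)
    D <- nrow(th)
    m <- ncol(th)
    w <- array(as.integer(doc$weights), c(D, D, m))
    priors <- doc$priors
    conv <- if (is.null(doc$threshold_snps)) "selected" else doc$threshold_snps
    b <- array(0, c(D, D, m))
    K <- matrix(0, D, D)
    for (k in seq_len(D)) {
      for (kp in seq_len(D)) {
        if (k == kp) next
        sel <- w[k, kp, ] == 1L
        bj <- log(th[k, ] * (1 - th[kp, ])) - log(th[kp, ] * (1 - th[k, ]))
        b[k, kp, ] <- bj * sel
        thr <- if (conv == "all") rep(TRUE, m) else sel
        K[k, kp] <- log(priors[kp] / priors[k]) +
          sum(2 * (log(1 - th[kp, thr]) - log(1 - th[k, thr])))
      }
    }
    return(structure(list(b = b, K = K, weights = w, theta_hat = th,
                          n_per_class = doc$n_per_class, priors = priors,
                          alpha = doc$alpha, threshold_snps = conv,
                          l = m, D = D),
                     class = c("snp_linear", "snp_classifier")))
  }
  stop("unrecognised classifier JSON document")
}
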