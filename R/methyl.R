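#' Per-sample mean beta value by genomic region category
#'
#' For each requested sample and each of the six region categories
#' (TSS200, TSS1500, 5'UTR, 1st exon, gene body, 3'UTR), the mean beta
#' value over the CpG sites annotated to that category. Missing beta
#' values are excluded from the mean (pairwise deletion); a category with
#' no annotated CpG, or none observed for a sample, yields `NA`, never 0.
#'
#' @param M beta matrix, CpGs x samples, values in `[0, 1]` or `NA`.
#' @param A named character vector CpG id -> region category (a subset of
#'   the CpGs in `M` may be annotated; unannotated CpGs are ignored).
#' @param samples optional character vector restricting the profile to a
#'   sample subset; unknown ids are an error.
#' @return a `"region_profile"` list with matrices `means` and `counts`
#'   (samples x categories; counts = CpGs contributing to each mean).
#' @export
region_mean_beta <- function(M, A, samples = NULL) {
  stopifnot(is.matrix(M))
  bad <- setdiff(unique(unname(A)), REGION_CATEGORIES)
  if (length(bad)) stop("unknown region categories: ", paste(bad, collapse = ", "))
  if (is.null(samples)) samples <- colnames(M)
  missing <- setdiff(samples, colnames(M))
  if (length(missing)) stop("samples not in the methylation matrix: ", paste(missing, collapse = ", "))
  A <- A[names(A) %in% rownames(M)]
  means <- matrix(NA_real_, length(samples), length(REGION_CATEGORIES),
                  dimnames = list(samples, REGION_CATEGORIES))
  counts <- matrix(0L, length(samples), length(REGION_CATEGORIES),
                   dimnames = list(samples, REGION_CATEGORIES))
  for (cat in REGION_CATEGORIES) {
    cpgs <- names(A)[A == cat]
    if (length(cpgs) == 0L) next
    sub <- M[cpgs, samples, drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    mu[n_obs == 0L] <- NA_real_
    means[, cat] <- mu
    counts[, cat] <- n_obs
  }
  structure(list(means = means, counts = counts), class = "region_profile")
}

#' @export
print.region_profile <- function(x, ...) {
  cat(sprintf("region_profile: %d samples x %d region categories\n",
              nrow(x$means), ncol(x$means)))
  print(round(colMeans(x$means, na.rm = TRUE), 3))
  invisible(x)
}

#' Region methylation profiles restricted to bicluster sample sets
#'
#' Computes [region_mean_beta()] separately for the sample set of every
#' bicluster, so that region-wise methylation levels can be compared across
#' the subtypes the biclusters represent. Bicluster samples absent from the
#' methylation matrix are dropped (with a message); a bicluster with no
#' resolvable sample is skipped with a warning.
#'
#' @param M beta matrix, CpGs x samples.
#' @param A CpG region annotation (named character vector).
#' @param B a [bicluster_set()] or list of [bicluster()] records.
#' @return named list bicluster id -> `"region_profile"`.
#' @export
profile_biclusters <- function(M, A, B) {
  B <- as_record_list(B)
  out <- list()
  for (r in B) {
    found <- intersect(r$samples, colnames(M))
    if (length(found) == 0L) {
      warning("bicluster '", r$id, "' has no samples in the methylation matrix; skipped")
      next
    }
    if (length(found) < length(r$samples)) {
      message(sprintf("bicluster '%s': %d of %d samples lack methylation data",
                      r$id, length(r$samples) - length(found), length(r$samples)))
    }
    out[[r$id]] <- region_mean_beta(M, A, samples = found)
  }
  out
}
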