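# Entry keys of one record: every (sample, gene) pair of its sub-matrix.
entry_keys <- function(r) {
  as.vector(outer(r$samples, r$genes, paste, sep = "\r"))
}

as_record_list <- function(B) {
  if (inherits(B, "bicluster_set")) B <- B$records
  stopifnot(is.list(B))
  B
}

#' Effective number of biclusters
#'
#' Overlap-corrected count of a bicluster collection: every matrix entry
#' `x` (a sample-gene pair) contributes `1/N(x)` to each bicluster that
#' contains it, where `N(x)` is the number of biclusters containing `x`, so
#'
#' `F = sum_k (1/|U_k|) sum_{x in U_k} 1 / N(x)`
#'
#' with `U_k` the entry set of bicluster `k`. `F` lies in `[1, K]`; it
#' equals `K` iff the entry sets are pairwise disjoint, and equals `r`
#' whenever the collection splits into `r` non-overlapping groups of
#' identical biclusters. The ratio `F/K` is a scale-free measure of how
#' much independent signal the collection carries.
#'
#' @param B a [bicluster_set()] or list of [bicluster()] records, all
#'   non-empty.
#' @return a single number in `[1, K]`.
#' @export
effective_number <- function(B) {
  B <- as_record_list(B)
  if (length(B) == 0L) stop("empty bicluster list")
  keys <- lapply(B, entry_keys)
  n_entry <- table(unlist(keys, use.names = FALSE))
  sum(vapply(keys, function(k) mean(1 / as.numeric(n_entry[k])), numeric(1L)))
}

#' Per-bicluster size table
#'
#' @param B a [bicluster_set()] or list of records (possibly empty).
#' @return data frame `(id, n_samples, n_genes)`; per-axis min/median/max
#'   are attached as attribute `"axis_summary"`.
#' @export
size_summary <- function(B) {
  B <- as_record_list(B)
  df <- data.frame(
    id = vapply(B, `[[`, character(1L), "id"),
    n_samples = vapply(B, function(r) length(r$samples), integer(1L)),
    n_genes = vapply(B, function(r) length(r$genes), integer(1L)),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    attr(df, "axis_summary") <- rbind(
      samples = c(min = min(df$n_samples), median = stats::median(df$n_samples), max = max(df$n_samples)),
      genes = c(min = min(df$n_genes), median = stats::median(df$n_genes), max = max(df$n_genes))
    )
  }
  df
}

#' Cross-tabulate bicluster samples against reference labels
#'
#' One row per bicluster, one column per label category plus `NA` (samples
#' absent from the label vector) and a `total` column. A sample belonging
#' to several biclusters is counted in each of their rows; this is the
#' layout of a composition table of biclusters versus PAM50 calls.
#'
#' @param B a [bicluster_set()] or list of records.
#' @param labels named character vector (names = sample ids).
#' @return integer matrix, rownames = bicluster ids.
#' @export
capture_table <- function(B, labels) {
  B <- as_record_list(B)
  cats <- sort(unique(stats::na.omit(unname(labels))))
  out <- matrix(0L, length(B), length(cats) + 2L,
                dimnames = list(vapply(B, `[[`, character(1L), "id"), c(cats, "NA", "total")))
  for (i in seq_along(B)) {
    l <- labels[B[[i]]$samples]
    n_na <- sum(is.na(l))
    tab <- table(factor(l, levels = cats))
    out[i, cats] <- as.integer(tab)
    out[i, "NA"] <- n_na
    out[i, "total"] <- length(B[[i]]$samples)
  }
  out
}

#' Match biclusters to subtypes by majority label fraction
#'
#' A bicluster matches a label when at least `min_fraction` of its samples
#' carry that label; each bicluster can match at most one label (its
#' argmax). Labels matched by no bicluster are reported as not captured.
#'
#' @param B a [bicluster_set()] or list of records.
#' @param labels named character vector (names = sample ids).
#' @param min_fraction required majority fraction in `(0, 1]` (default 0.5).
#' @return named list label -> character vector of matching bicluster ids;
#'   attribute `"not_captured"` lists the label categories with no match.
#' @export
match_subtypes <- function(B, labels, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  B <- as_record_list(B)
  cats <- sort(unique(stats::na.omit(unname(labels))))
  hits <- stats::setNames(vector("list", length(cats)), cats)
  for (r in B) {
    l <- labels[r$samples]
    frac <- table(factor(l, levels = cats)) / length(r$samples)
    if (length(frac) && max(frac) >= min_fraction) {
      best <- cats[which.max(frac)]
      hits[[best]] <- c(hits[[best]], r$id)
    }
  }
  attr(hits, "not_captured") <- cats[vapply(hits, is.null, logical(1L))]
  hits
}
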