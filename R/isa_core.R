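#' Row- and column-normalize an expression matrix
#'
#' Produces the two standardized views the ISA iteration alternates between:
#' `E_C`, in which every sample row has mean 0 and sample standard deviation
#' 1 (used to score genes over a sample set), and `E_G`, in which every gene
#' column has mean 0 and sd 1 (used to score samples over a gene set).
#' Sample sd (n - 1 denominator) is used throughout the package.
#'
#' @param E samples-x-genes numeric matrix with dimnames.
#' @return a `"normalized_pair"` list with matrices `E_C` and `E_G`.
#' @export
normalize_expression <- function(E) {
  validate_expression(E)
  row_sd <- apply(E, 1L, stats::sd)
  col_sd <- apply(E, 2L, stats::sd)
  bad_rows <- rownames(E)[row_sd == 0]
  bad_cols <- colnames(E)[col_sd == 0]
  if (length(bad_rows) || length(bad_cols)) {
    stop("zero-variance rows/columns cannot be normalized; ",
         if (length(bad_rows)) paste0("samples: ", paste(bad_rows, collapse = ", "), "; ") else "",
         if (length(bad_cols)) paste0("genes: ", paste(bad_cols, collapse = ", ")) else "")
  }
  E_C <- (E - rowMeans(E)) / row_sd
  E_G <- sweep(sweep(E, 2L, colMeans(E)), 2L, col_sd, `/`)
  structure(list(E_C = E_C, E_G = E_G), class = "normalized_pair")
}

#' Threshold a score vector in standard-deviation units
#'
#' Scores are standardized to z-scores with their own mean and sample sd;
#' an index is kept when `z > t` (direction `"up"`, over-expression only) or
#' `|z| > t` (direction `"updown"`). A constant score vector keeps nothing
#' and raises a warning rather than an error.
#'
#' @param scores numeric vector, length >= 2.
#' @param t non-negative threshold in score-sd units.
#' @param direction `"up"` (default) or `"updown"`.
#' @return logical vector of kept indices (possibly all `FALSE`).
#' @export
threshold_scores <- function(scores, t, direction = c("up", "updown")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) >= 2L, is.finite(t), t >= 0)
  s <- stats::sd(scores)
  if (s == 0) {
    warning("constant scores: nothing passes the threshold")
    return(rep(FALSE, length(scores)))
  }
  z <- (scores - mean(scores)) / s
  if (direction == "up") z > t else abs(z) > t
}

#' One ISA half-iteration: samples -> genes -> samples
#'
#' Given the current binary sample vector `c`, gene scores are the mean of
#' the row-normalized matrix over the selected samples (equivalently
#' `t(E_C) %*% c / |c|`), thresholded at `t_G` to give the gene vector `g`;
#' sample scores are then the mean of the column-normalized matrix over the
#' selected genes (`E_G %*% g / |g|`), thresholded at `t_C`. Averaging (not
#' a bare matrix product) keeps the thresholds comparable across seed sizes.
#'
#' @param P a `"normalized_pair"` from [normalize_expression()].
#' @param c logical sample vector with at least one `TRUE`.
#' @param t_G,t_C gene and sample thresholds (score-sd units).
#' @param direction passed to [threshold_scores()].
#' @return list with `g` (logical gene vector), `c_next` (logical sample
#'   vector), `gene_scores`, `sample_scores` and `vanished` (`TRUE` when no
#'   gene survives `t_G`, in which case `c_next` is all-`FALSE`).
#' @export
isa_step <- function(P, c, t_G, t_C, direction = "up") {
  stopifnot(inherits(P, "normalized_pair"))
  c <- as.logical(c)
  if (!any(c)) stop("empty sample vector")
  gene_scores <- colMeans(P$E_C[c, , drop = FALSE])
  g <- threshold_scores(gene_scores, t_G, direction)
  if (!any(g)) {
    return(list(g = g, c_next = rep(FALSE, nrow(P$E_G)), gene_scores = gene_scores,
                sample_scores = rep(NA_real_, nrow(P$E_G)), vanished = TRUE))
  }
  sample_scores <- rowMeans(P$E_G[, g, drop = FALSE])
  c_next <- threshold_scores(sample_scores, t_C, direction)
  list(g = g, c_next = c_next, gene_scores = gene_scores,
       sample_scores = sample_scores, vanished = FALSE)
}

#' Iterate a seed to an ISA fixed point
#'
#' Repeats [isa_step()] from a sparse binary sample seed until the sample
#' and gene support sets are both unchanged for `min_stable` consecutive
#' iterations. Seeds whose module vanishes (no gene or no sample passes the
#' threshold) or that fail to stabilize within `max_iter` iterations return
#' `NULL`.
#'
#' @param P a `"normalized_pair"`.
#' @param seed integer vector of seed sample indices (or a logical vector of
#'   length m), non-empty.
#' @param t_G,t_C thresholds in score-sd units.
#' @param max_iter iteration cap.
#' @param min_stable consecutive identical-support iterations required.
#' @param direction passed to [threshold_scores()].
#' @param id identifier for the resulting record.
#' @param seed_group optional seed-group index stored as provenance.
#' @return a [bicluster()] with `converged = TRUE`, or `NULL`.
#' @export
run_seed <- function(P, seed, t_G, t_C, max_iter = 100L, min_stable = 2L,
                     direction = "up", id = "b1", seed_group = NA_integer_) {
  stopifnot(inherits(P, "normalized_pair"), max_iter >= min_stable, min_stable >= 1L)
  m <- nrow(P$E_C)
  if (is.logical(seed)) seed <- which(seed)
  if (length(seed) == 0L) stop("empty seed")
  c_cur <- seq_len(m) %in% seed
  g_prev <- NULL
  c_prev <- c_cur
  stable <- 0L
  for (it in seq_len(max_iter)) {
    st <- isa_step(P, c_cur, t_G, t_C, direction)
    if (st$vanished || !any(st$c_next)) return(NULL)
    if (!is.null(g_prev) && identical(st$g, g_prev) && identical(st$c_next, c_prev)) {
      stable <- stable + 1L
    } else {
      stable <- 0L
    }
    g_prev <- st$g
    c_prev <- st$c_next
    c_cur <- st$c_next
    if (stable >= min_stable) {
      return(bicluster(id = id,
                       samples = rownames(P$E_C)[st$c_next],
                       genes = colnames(P$E_C)[st$g],
                       seed_group = seed_group, t_G = t_G, t_C = t_C,
                       n_iterations = it, converged = TRUE))
    }
  }
  NULL
}
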