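#' Generate random sparse binary seeds
#'
#' Each seed is a set of `sparsity` distinct sample indices drawn uniformly
#' from `1..m`; the seed plays the role of the sparse 0/1 starting vector of
#' one ISA iteration.
#'
#' @param m number of samples.
#' @param n_seeds number of seeds (10,000 is a customary default: the number
#'   of distinct ISA fixed points at given thresholds is small, so this
#'   saturates them).
#' @param sparsity number of non-zero entries per seed, `1 <= sparsity <= m`.
#' @param rng_seed RNG seed for reproducibility.
#' @return integer matrix `n_seeds x sparsity` of sample indices, rows
#'   sorted increasingly.
#' @export
generate_seeds <- function(m, n_seeds = 10000L, sparsity = 2L, rng_seed = NULL) {
  stopifnot(m >= 1L, n_seeds >= 1L)
  if (sparsity < 1L || sparsity > m) stop("sparsity must lie in [1, m]")
  with_seed(rng_seed, {
    t(vapply(seq_len(n_seeds),
             function(i) sort(sample.int(m, sparsity)),
             integer(sparsity)))
  })
}

#' Group seeds by affinity propagation cluster membership
#'
#' A seed is retained and assigned to group `i` when all its support samples
#' carry AP label `i`; seeds spanning two or more AP clusters are discarded.
#' Larger AP clusters thus collect proportionally more seeds.
#'
#' @param seeds integer matrix from [generate_seeds()].
#' @param ap an `"ap_result"` whose `labels` cover all `m` samples.
#' @return a `"seed_groups"` list: `groups` (list of per-group seed
#'   matrices, one per AP cluster), `sizes` (AP cluster sizes, in samples),
#'   `discarded_count`, `t_G` / `t_C` (filled by [assign_thresholds()]).
#' @export
classify_seeds <- function(seeds, ap) {
  stopifnot(is.matrix(seeds), inherits(ap, "ap_result"))
  labels <- ap$labels
  if (max(seeds) > length(labels)) stop("seed indices exceed the labelled sample count")
  K <- length(unique(labels))
  lab_mat <- matrix(labels[seeds], nrow(seeds), ncol(seeds))
  pure <- rowSums(lab_mat == lab_mat[, 1L]) == ncol(seeds)
  grp <- ifelse(pure, lab_mat[, 1L], NA_integer_)
  groups <- lapply(seq_len(K), function(k) seeds[which(grp == k), , drop = FALSE])
  structure(list(groups = groups,
                 sizes = as.integer(tabulate(labels, K)),
                 discarded_count = sum(!pure),
                 t_G = NULL, t_C = NULL),
            class = "seed_groups")
}

#' @export
print.seed_groups <- function(x, ...) {
  cat(sprintf("seed_groups: %d groups (%s seeds), %d discarded\n",
              length(x$groups),
              paste(vapply(x$groups, nrow, integer(1L)), collapse = "/"),
              x$discarded_count))
  invisible(x)
}

#' Subsample retained seeds proportionally to group size
#'
#' Per-group quotas are the largest-remainder apportionment of `total` by
#' the number of retained seeds per group; within each group, quota seeds
#' are drawn uniformly without replacement. A group smaller than its quota
#' hands the shortfall to the largest groups, with a warning.
#'
#' @param G a `"seed_groups"` object.
#' @param total total number of seeds to keep across groups.
#' @param rng_seed RNG seed.
#' @return a `"seed_groups"` object with subsampled groups.
#' @export
sample_seeds <- function(G, total, rng_seed = NULL) {
  stopifnot(inherits(G, "seed_groups"))
  avail <- vapply(G$groups, nrow, integer(1L))
  if (total > sum(avail)) stop("total exceeds the number of retained seeds")
  quota <- largest_remainder(avail, total)
  short <- pmax(quota - avail, 0L)
  if (any(short > 0L)) {
    quota <- pmin(quota, avail)
    deficit <- total - sum(quota)
    ord <- order(-avail)
    i <- 1L
    while (deficit > 0L) {
      k <- ord[(i - 1L) %% length(ord) + 1L]
      if (quota[k] < avail[k]) { quota[k] <- quota[k] + 1L; deficit <- deficit - 1L }
      i <- i + 1L
    }
    warning("some groups had fewer seeds than their quota; shortfall moved to the largest groups")
  }
  G$groups <- with_seed(rng_seed, {
    lapply(seq_along(G$groups), function(k) {
      g <- G$groups[[k]]
      g[sort(sample.int(nrow(g), quota[k])), , drop = FALSE]
    })
  })
  G
}

#' Assign per-group ISA thresholds
#'
#' The gene threshold `t_G` is mapped from the rank of each group's size
#' (in samples) linearly onto `t_range`: the largest group gets the lowest
#' threshold (bigger, looser biclusters for the prevalent subtype), the
#' smallest the highest. Ties share the average rank; with a single group
#' the midpoint is used. The sample threshold `t_C` is constant across
#' groups. Explicit `overrides` (length-K vector of `t_G` values) bypass the
#' rank map, e.g. to reproduce a published configuration.
#'
#' @param G a `"seed_groups"` object.
#' @param t_range numeric `(low, high)` for the rank map.
#' @param t_C constant sample threshold.
#' @param overrides optional numeric vector of per-group `t_G` values.
#' @return `G` with `t_G` (per group) and `t_C` filled in.
#' @export
assign_thresholds <- function(G, t_range = c(1, 2), t_C = 1.0, overrides = NULL) {
  stopifnot(inherits(G, "seed_groups"), length(t_range) == 2L, t_range[1L] <= t_range[2L])
  K <- length(G$groups)
  if (!is.null(overrides)) {
    if (length(overrides) != K) stop("overrides must have one t_G per group (", K, ")")
    G$t_G <- as.numeric(overrides)
  } else {
    r <- rank(-G$sizes, ties.method = "average")
    frac <- if (K == 1L) 0.5 else (r - 1) / (K - 1)
    G$t_G <- t_range[1L] + frac * (t_range[2L] - t_range[1L])
  }
  G$t_C <- t_C
  G
}
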