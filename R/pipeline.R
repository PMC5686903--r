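#' Configuration for a full AP-ISA run
#'
#' Bundles every tunable of the three stages (AP clustering, seed
#' selection, per-seed ISA) plus the deduplication threshold. Defaults are
#' the package's operating point for a five-subtype expression matrix; see
#' the methods vignette for the rationale behind each value.
#'
#' @param K desired number of AP clusters (5 for breast-cancer subtypes).
#' @param n_seeds random sparse seeds generated (default 10,000).
#' @param sparsity non-zeros per seed (default 2).
#' @param total_selected seeds kept after proportional subsampling
#'   (default 100).
#' @param t_range range of the gene threshold rank map (default `c(1, 2)`).
#' @param t_C constant sample threshold (default 1.0).
#' @param t_G_overrides optional explicit per-group gene thresholds.
#' @param max_iter,min_stable ISA iteration cap and stability requirement.
#' @param dedup_jaccard combined-Jaccard overlap above which two fixed
#'   points are considered duplicates (default 0.8).
#' @param direction `"up"` or `"updown"` thresholding.
#' @param damping,ap_max_iter,ap_conv_iter,tol_steps AP parameters, see
#'   [affinity_propagation()] and [cluster_with_k()].
#' @param rng_seed master seed; all stage seeds are derived from it.
#' @return an `"apisa_config"` list.
#' @export
apisa_config <- function(K = 5L, n_seeds = 10000L, sparsity = 2L,
                         total_selected = 100L, t_range = c(1, 2), t_C = 1.0,
                         t_G_overrides = NULL, max_iter = 100L, min_stable = 2L,
                         dedup_jaccard = 0.8, direction = "up", damping = 0.5,
                         ap_max_iter = 1000L, ap_conv_iter = 50L,
                         tol_steps = 40L, rng_seed = 1L) {
  cfg <- list(K = as.integer(K), n_seeds = as.integer(n_seeds),
              sparsity = as.integer(sparsity),
              total_selected = as.integer(total_selected),
              t_range = as.numeric(t_range), t_C = as.numeric(t_C),
              t_G_overrides = t_G_overrides, max_iter = as.integer(max_iter),
              min_stable = as.integer(min_stable),
              dedup_jaccard = as.numeric(dedup_jaccard), direction = direction,
              damping = as.numeric(damping), ap_max_iter = as.integer(ap_max_iter),
              ap_conv_iter = as.integer(ap_conv_iter), tol_steps = as.integer(tol_steps),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$K >= 1L, cfg$n_seeds >= 1L, cfg$sparsity >= 1L,
            cfg$total_selected >= 1L, length(cfg$t_range) == 2L,
            cfg$dedup_jaccard >= 0, cfg$dedup_jaccard <= 1,
            cfg$direction %in% c("up", "updown"))
  structure(cfg, class = "apisa_config")
}

# Combined Jaccard of two records: samples and genes pooled into one
# tagged id set, so J = (|S int| + |G int|) / (|S uni| + |G uni|).
combined_jaccard <- function(a, b) {
  si <- length(intersect(a$samples, b$samples))
  gi <- length(intersect(a$genes, b$genes))
  su <- length(union(a$samples, b$samples))
  gu <- length(union(a$genes, b$genes))
  (si + gi) / (su + gu)
}

#' Deduplicate a fixed-point pool by overlap, keeping diverse records
#'
#' Builds a graph on the records with an edge wherever the combined Jaccard
#' overlap (samples and genes pooled) exceeds `dedup_jaccard`; within each
#' connected component the record with the largest basin count (number of
#' seeds that converged to it) survives, ties going to the record with more
#' samples and then to the lexicographically smallest id. Survivors are
#' returned sorted by basin count, largest first. Records connected only
#' through a dropped intermediate may still overlap more than the threshold
#' (the usual transitivity caveat of single-linkage grouping).
#'
#' @param pool a `"fixed_point_pool"`: list with `records` (biclusters) and
#'   `basin_counts` (integer per record). A plain list of biclusters is
#'   accepted and given unit basin counts.
#' @param dedup_jaccard overlap threshold in `[0, 1]`.
#' @return a [bicluster_set()]; each record carries its basin count in
#'   attribute `"basin_count"`.
#' @export
select_diverse <- function(pool, dedup_jaccard = 0.8) {
  if (!is.list(pool) || is.null(pool$records)) pool <- fixed_point_pool(pool)
  recs <- pool$records
  basins <- pool$basin_counts
  nr <- length(recs)
  if (nr == 0L) return(bicluster_set(list()))
  ## union-find over the overlap graph
  parent <- seq_len(nr)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(nr - 1L)) {
    for (j in seq.int(i + 1L, nr)) {
      if (combined_jaccard(recs[[i]], recs[[j]]) > dedup_jaccard) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(nr), find, integer(1L))
  keep <- integer(0)
  for (cmp in unique(comp)) {
    members <- which(comp == cmp)
    ns <- vapply(recs[members], function(r) length(r$samples), integer(1L))
    ids <- vapply(recs[members], `[[`, character(1L), "id")
    ord <- order(-basins[members], -ns, ids)
    best <- members[ord[1L]]
    keep <- c(keep, best)
    ## attribute the whole component's basin to the survivor
    basins[best] <- sum(basins[members])
  }
  keep <- keep[order(-basins[keep])]
  out <- lapply(keep, function(i) { r <- recs[[i]]; attr(r, "basin_count") <- basins[i]; r })
  bicluster_set(out)
}

# Collapse identical fixed points, counting how many seeds reached each.
fixed_point_pool <- function(records) {
  keys <- vapply(records, function(r) {
    paste(paste(sort(r$samples), collapse = ","), paste(sort(r$genes), collapse = ","), sep = "|")
  }, character(1L))
  ord <- !duplicated(keys)
  uni <- records[ord]
  counts <- as.integer(table(factor(keys, levels = keys[ord])))
  uni <- lapply(seq_along(uni), function(i) { r <- uni[[i]]; r$id <- sprintf("b%d", i); r })
  list(records = uni, basin_counts = counts)
}

#' Run the full AP-ISA biclustering pipeline
#'
#' Step 1 clusters the samples by affinity propagation at the requested
#' `K`. Step 2 generates `n_seeds` random sparse seeds, discards those
#' spanning AP clusters, subsamples `total_selected` of them proportionally
#' to group size and assigns per-group thresholds. Step 3 iterates every
#' selected seed to its ISA fixed point under its group's thresholds;
#' identical fixed points are pooled with basin counts and the pool is
#' deduplicated by [select_diverse()].
#'
#' @param E samples-x-genes expression matrix.
#' @param cfg an [apisa_config()].
#' @return a [bicluster_set()] whose `parameters` carry the full config and
#'   run provenance: AP labels/exemplars, seed discard count, per-group
#'   quotas and thresholds, counts of vanished and non-converged seeds.
#' @export
run_apisa <- function(E, cfg = apisa_config()) {
  validate_expression(E)
  stopifnot(inherits(cfg, "apisa_config"))
  ## derived stage seeds keep the stages independent of each other's draws
  s_ap <- cfg$rng_seed
  s_gen <- cfg$rng_seed + 1L
  s_sel <- cfg$rng_seed + 2L

  S <- similarity_matrix(E)
  ap <- cluster_with_k(S, cfg$K, tol_steps = cfg$tol_steps, rng_seed = s_ap,
                       damping = cfg$damping, max_iter = cfg$ap_max_iter,
                       conv_iter = cfg$ap_conv_iter)
  if (!ap$achieved_K) {
    stop(sprintf("AP could not attain K = %d (closest K_found = %d)", cfg$K, ap$K_found))
  }
  seeds <- generate_seeds(nrow(E), cfg$n_seeds, cfg$sparsity, rng_seed = s_gen)
  G <- classify_seeds(seeds, ap)
  G <- sample_seeds(G, cfg$total_selected, rng_seed = s_sel)
  G <- assign_thresholds(G, t_range = cfg$t_range, t_C = cfg$t_C,
                         overrides = cfg$t_G_overrides)

  P <- normalize_expression(E)
  records <- list()
  n_vanished <- 0L
  i <- 0L
  for (k in seq_along(G$groups)) {
    g <- G$groups[[k]]
    for (s in seq_len(nrow(g))) {
      i <- i + 1L
      rec <- run_seed(P, g[s, ], t_G = G$t_G[k], t_C = G$t_C,
                      max_iter = cfg$max_iter, min_stable = cfg$min_stable,
                      direction = cfg$direction, id = sprintf("seed%d", i),
                      seed_group = k)
      if (is.null(rec)) n_vanished <- n_vanished + 1L else records[[length(records) + 1L]] <- rec
    }
  }
  if (length(records) == 0L) {
    warning("no seed converged to a non-empty fixed point; returning an empty set")
    out <- bicluster_set(list())
  } else {
    out <- select_diverse(fixed_point_pool(records), cfg$dedup_jaccard)
  }
  out$parameters <- list(
    config = unclass(cfg),
    ap_labels = ap$labels, ap_exemplars = ap$exemplars,
    ap_preference = ap$preference, ap_converged = ap$converged,
    seed_discarded = G$discarded_count,
    group_sizes = G$sizes,
    group_quotas = vapply(G$groups, nrow, integer(1L)),
    t_G = G$t_G, t_C = G$t_C,
    n_seeds_run = i, n_vanished = n_vanished,
    n_fixed_points = length(records)
  )
  out
}
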