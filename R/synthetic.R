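#' Specification of a planted-bicluster expression instance
#'
#' Describes a samples-x-genes matrix of iid Gaussian background noise with
#' K latent sample groups of unequal prevalence, each carrying one planted
#' block of up-regulated genes (a constant additive shift of `delta` noise
#' sds on the group's samples at the group's genes). The default emulates a
#' five-subtype cohort at prevalences 0.30/0.15/0.35/0.15/0.05 with
#' disjoint 60-gene modules in a 200 x 500 matrix at shift 3, noise sd 1.
#'
#' @param m,n numbers of samples and genes.
#' @param prevalences per-group sample fractions, summing to 1.
#' @param genes_per_module planted genes per group (scalar or per-group
#'   vector); modules use disjoint consecutive gene blocks unless
#'   `gene_sets` is given.
#' @param delta additive up-shift in units of `noise_sd`.
#' @param noise_sd background noise standard deviation.
#' @param gene_sets optional list of explicit per-group gene index vectors;
#'   overlaps between them must be declared via `allow_overlap = TRUE`.
#' @param allow_overlap permit overlapping planted gene sets.
#' @return a `"plant_spec"` list.
#' @export
plant_spec <- function(m = 200L, n = 500L,
                       prevalences = c(0.30, 0.15, 0.35, 0.15, 0.05),
                       genes_per_module = 60L, delta = 3, noise_sd = 1,
                       gene_sets = NULL, allow_overlap = FALSE) {
  stopifnot(m >= 2L, n >= 2L, all(prevalences > 0), delta >= 0, noise_sd > 0)
  if (abs(sum(prevalences) - 1) > 1e-8) stop("prevalences must sum to 1")
  K <- length(prevalences)
  if (is.null(gene_sets)) {
    gpm <- rep_len(as.integer(genes_per_module), K)
    if (sum(gpm) > n) stop("planted gene blocks exceed the number of genes")
    ends <- cumsum(gpm)
    gene_sets <- lapply(seq_len(K), function(k) seq.int(ends[k] - gpm[k] + 1L, ends[k]))
  } else {
    stopifnot(length(gene_sets) == K)
    if (!allow_overlap) {
      all_g <- unlist(gene_sets)
      if (anyDuplicated(all_g)) stop("planted gene sets overlap; set allow_overlap = TRUE to permit this")
    }
  }
  structure(list(m = as.integer(m), n = as.integer(n), prevalences = prevalences,
                 gene_sets = gene_sets, delta = delta, noise_sd = noise_sd),
            class = "plant_spec")
}

#' Generate a planted-bicluster expression matrix
#'
#' Background entries are iid `Normal(0, noise_sd^2)`; every planted
#' (sample, gene) cell of group k receives an additive `+delta * noise_sd`.
#' Sample group sizes are the largest-remainder apportionment of `m` by the
#' prevalences; sample-to-group assignment is a seeded random permutation.
#'
#' @param spec a [plant_spec()].
#' @param rng_seed RNG seed; identical spec + seed give identical output.
#' @return list with `expr` (samples x genes matrix, ids `s...`/`g...`) and
#'   `truth`: per-module exact sample/gene id sets (`modules`), per-sample
#'   latent group labels (`labels`, integer named vector) and group sizes.
#' @export
planted_expression <- function(spec = plant_spec(), rng_seed = 1L) {
  stopifnot(inherits(spec, "plant_spec"))
  K <- length(spec$prevalences)
  sizes <- largest_remainder(spec$prevalences, spec$m)
  if (any(sizes == 0L)) stop("a group received zero samples; increase m or its prevalence")
  with_seed(rng_seed, {
    labels <- sample(rep.int(seq_len(K), sizes))
    E <- matrix(stats::rnorm(spec$m * spec$n, sd = spec$noise_sd), spec$m, spec$n)
    for (k in seq_len(K)) {
      E[labels == k, spec$gene_sets[[k]]] <- E[labels == k, spec$gene_sets[[k]]] +
        spec$delta * spec$noise_sd
    }
    rownames(E) <- sprintf("s%03d", seq_len(spec$m))
    colnames(E) <- sprintf("g%03d", seq_len(spec$n))
    names(labels) <- rownames(E)
    modules <- lapply(seq_len(K), function(k) {
      list(samples = rownames(E)[labels == k], genes = colnames(E)[spec$gene_sets[[k]]])
    })
    list(expr = E, truth = list(modules = modules, labels = labels, sizes = sizes))
  })
}

#' Generate a companion methylation matrix with region-specific levels
#'
#' Beta values are drawn from Beta distributions parameterized by mean and
#' concentration: CpG site j (annotated to region category `cat`) in a
#' sample of latent group k has mean `region_levels[k, cat]`. CpGs are
#' annotated round-robin over the six region categories.
#'
#' @param truth the `truth` element of [planted_expression()] output.
#' @param region_levels K x 6 matrix of means in (0, 1); columns named (or
#'   ordered) as [REGION_CATEGORIES].
#' @param concentration Beta concentration (mean * conc, (1-mean) * conc);
#'   larger = tighter around the mean.
#' @param cpgs_per_category CpG sites per region category.
#' @param rng_seed RNG seed.
#' @return list with `beta` (CpGs x samples matrix) and `annotation`
#'   (named character vector CpG id -> region).
#' @export
planted_methylation <- function(truth, region_levels, concentration = 50,
                                cpgs_per_category = 50L, rng_seed = 1L) {
  K <- length(truth$modules)
  region_levels <- as.matrix(region_levels)
  stopifnot(nrow(region_levels) == K, ncol(region_levels) == length(REGION_CATEGORIES),
            all(region_levels > 0), all(region_levels < 1), concentration > 0)
  if (is.null(colnames(region_levels))) colnames(region_levels) <- REGION_CATEGORIES
  n_cpg <- cpgs_per_category * length(REGION_CATEGORIES)
  annotation <- stats::setNames(rep(REGION_CATEGORIES, length.out = n_cpg),
                                sprintf("cg%05d", seq_len(n_cpg)))
  samples <- names(truth$labels)
  with_seed(rng_seed, {
    beta <- matrix(NA_real_, n_cpg, length(samples),
                   dimnames = list(names(annotation), samples))
    for (j in seq_len(n_cpg)) {
      mu <- region_levels[truth$labels, annotation[j]]
      beta[j, ] <- stats::rbeta(length(samples), mu * concentration, (1 - mu) * concentration)
    }
    list(beta = beta, annotation = annotation)
  })
}

#' Jaccard recovery score of a found bicluster against a planted module
#'
#' @param found a [bicluster()] (or any list with `samples` and `genes`).
#' @param truth_module list with `samples` and `genes` id vectors.
#' @return named numeric `(sample_jaccard, gene_jaccard)`.
#' @export
recovery_score <- function(found, truth_module) {
  c(sample_jaccard = jaccard(found$samples, truth_module$samples),
    gene_jaccard = jaccard(found$genes, truth_module$genes))
}

#' Best-match recovery of planted modules by a bicluster set
#'
#' Greedy assignment: repeatedly pair the (module, record) couple with the
#' highest sample-Jaccard among the unassigned, until every module is
#' paired or records run out. Modules left unpaired score (0, 0).
#'
#' @param B a [bicluster_set()] or list of records.
#' @param truth the `truth` element of [planted_expression()] output.
#' @return matrix with one row per planted module: `sample_jaccard`,
#'   `gene_jaccard`, `record` (index of the matched record, `NA` if none).
#' @export
match_modules <- function(B, truth) {
  B <- as_record_list(B)
  nm <- length(truth$modules)
  out <- matrix(NA_real_, nm, 3L,
                dimnames = list(sprintf("module%d", seq_len(nm)),
                                c("sample_jaccard", "gene_jaccard", "record")))
  if (length(B) == 0L) { out[, 1:2] <- 0; return(out) }
  sj <- outer(seq_len(nm), seq_along(B),
              Vectorize(function(i, j) jaccard(truth$modules[[i]]$samples, B[[j]]$samples)))
  free_m <- rep(TRUE, nm)
  free_r <- rep(TRUE, length(B))
  while (any(free_m) && any(free_r)) {
    sub <- sj
    sub[!free_m, ] <- -1
    sub[, !free_r] <- -1
    best <- arrayInd(which.max(sub), dim(sub))
    i <- best[1L]; j <- best[2L]
    out[i, ] <- c(sj[i, j], jaccard(truth$modules[[i]]$genes, B[[j]]$genes), j)
    free_m[i] <- FALSE
    free_r[j] <- FALSE
  }
  out[is.na(out[, 1L]), 1:2] <- 0
  out
}
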