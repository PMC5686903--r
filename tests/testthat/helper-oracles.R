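# Independent oracles and small generators used across the suite.

# Naive per-entry double loop for the effective number of biclusters:
# walks every (sample, gene) entry of every record and counts its
# containment in each record by direct membership tests.
naive_effective_number <- function(records) {
  if (inherits(records, "bicluster_set")) records <- records$records
  total <- 0
  for (r in records) {
    acc <- 0
    for (s in r$samples) {
      for (g in r$genes) {
        n_x <- 0L
        for (q in records) {
          if (s %in% q$samples && g %in% q$genes) n_x <- n_x + 1L
        }
        acc <- acc + 1 / n_x
      }
    }
    total <- total + acc / (length(r$samples) * length(r$genes))
  }
  total
}

# Random bicluster set over a small shared universe (entries bounded).
random_bicluster_set <- function(K = sample(1:8, 1), m = 12L, n = 15L) {
  samples <- sprintf("s%d", seq_len(m))
  genes <- sprintf("g%d", seq_len(n))
  recs <- lapply(seq_len(K), function(k) {
    bicluster(sprintf("b%d", k),
              sample(samples, sample.int(m, 1)),
              sample(genes, sample.int(n, 1)))
  })
  bicluster_set(recs)
}

# Exhaustive exemplar-subset optimum of the AP objective: the best net
# similarity over all non-empty exemplar subsets (feasible for m <= 12).
exhaustive_net_similarity <- function(S, preference) {
  m <- nrow(S)
  best <- -Inf
  for (mask in 1:(2^m - 1)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    best <- max(best, net_similarity(S, ex, preference))
  }
  best
}

# Adjusted Rand index between two partitions (label vectors).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Named random expression matrix.
rand_expr <- function(m, n, sd = 1) {
  matrix(rnorm(m * n, sd = sd), m, n,
         dimnames = list(sprintf("s%d", seq_len(m)), sprintf("g%d", seq_len(n))))
}
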