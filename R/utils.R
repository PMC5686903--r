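# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# When `seed` is NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Jaccard index of two sets
#'
#' @param a,b vectors interpreted as sets.
#' @return `|a n b| / |a u b|`; 0 when both sets are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# Largest-remainder apportionment of `total` integer units over `sizes`.
# Remainder seats go to the largest fractional parts; ties broken by
# larger size, then lower index. Always sums exactly to `total`.
largest_remainder <- function(sizes, total) {
  stopifnot(total >= 0, all(sizes >= 0), sum(sizes) > 0)
  exact <- total * sizes / sum(sizes)
  quota <- floor(exact)
  left <- total - sum(quota)
  if (left > 0L) {
    ord <- order(-(exact - quota), -sizes, seq_along(sizes))
    quota[ord[seq_len(left)]] <- quota[ord[seq_len(left)]] + 1L
  }
  as.integer(quota)
}

# TRUE when two index/id vectors denote the same set.
same_set <- function(a, b) {
  length(a) == length(b) && setequal(a, b)
}
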