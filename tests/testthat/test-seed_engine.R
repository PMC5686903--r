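fake_ap <- function(labels) {
  structure(list(labels = labels, exemplars = match(unique(labels), labels),
                 preference = NA_real_, n_iterations = 0L, converged = TRUE,
                 K_found = length(unique(labels)), net_similarity = NA_real_),
            class = "ap_result")
}

test_that("seeds have the requested sparsity and uniform inclusion frequency", {
  m <- 50L
  seeds <- generate_seeds(m, n_seeds = 10000L, sparsity = 2L, rng_seed = 5)
  expect_equal(dim(seeds), c(10000L, 2L))
  expect_true(all(seeds[, 1] < seeds[, 2])) # distinct, sorted
  # per-sample inclusion frequency ~ Binomial(n_seeds, sparsity/m)
  freq <- tabulate(seeds, m) / 10000
  p <- 2 / m
  expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / 10000)))
  expect_identical(seeds, generate_seeds(m, 10000L, 2L, rng_seed = 5))
  expect_error(generate_seeds(5, 10, sparsity = 6), "sparsity")
  full <- generate_seeds(4, 3, sparsity = 4, rng_seed = 1)
  expect_true(all(apply(full, 1, identical, 1:4)))
})

test_that("seeds are grouped by AP membership and spanning seeds discarded", {
  ap <- fake_ap(c(1L, 1L, 2L, 2L))
  seeds <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  G <- classify_seeds(seeds, ap)
  expect_equal(G$groups[[1]], rbind(c(1L, 2L)), ignore_attr = TRUE)
  expect_equal(G$groups[[2]], rbind(c(3L, 4L)), ignore_attr = TRUE)
  expect_equal(G$discarded_count, 1L)
  # single-cluster labelling discards nothing
  G1 <- classify_seeds(seeds, fake_ap(rep(1L, 4)))
  expect_equal(G1$discarded_count, 0L)
  expect_equal(nrow(G1$groups[[1]]), 3L)
})

test_that("retained fraction under sparsity 2 matches the sum of squared proportions", {
  m <- 200L
  p <- c(0.30, 0.15, 0.35, 0.15, 0.05)
  labels <- rep(1:5, times = m * p)
  seeds <- generate_seeds(m, 10000L, 2L, rng_seed = 77)
  G <- classify_seeds(seeds, fake_ap(labels))
  retained <- 1 - G$discarded_count / 10000
  expected <- sum(p^2)
  expect_lt(abs(retained - expected), 3 * sqrt(expected * (1 - expected) / 10000))
  # every retained seed's support lies inside its AP cluster
  for (k in 1:5) {
    g <- G$groups[[k]]
    if (nrow(g)) expect_true(all(labels[g] == k))
  }
})

test_that("proportional subsampling uses largest-remainder quotas", {
  sizes <- c(30L, 15L, 35L, 15L, 5L)
  expect_equal(apisa:::largest_remainder(sizes, 100L), sizes * 1L)
  # quotas always sum to the total
  set.seed(33)
  for (i in 1:100) {
    s <- sample.int(500, sample(2:8, 1))
    tot <- sample.int(200, 1)
    q <- apisa:::largest_remainder(s, tot)
    expect_equal(sum(q), tot)
    # apportionment is monotone: a larger group never gets fewer seeds
    expect_true(all(diff(q[order(s)]) >= 0))
  }
})

test_that("sample_seeds hits per-group quotas and identity at full total", {
  labels <- rep(1:5, times = c(60, 30, 70, 30, 10))
  seeds <- generate_seeds(200L, 10000L, 2L, rng_seed = 9)
  G <- classify_seeds(seeds, fake_ap(labels))
  sel <- sample_seeds(G, 100L, rng_seed = 10)
  quotas <- vapply(sel$groups, nrow, integer(1))
  expect_equal(sum(quotas), 100L)
  avail <- vapply(G$groups, nrow, integer(1))
  expect_equal(quotas, apisa:::largest_remainder(avail, 100L))
  # total = retained count reproduces the groups unchanged
  all_sel <- sample_seeds(G, sum(avail), rng_seed = 11)
  expect_equal(vapply(all_sel$groups, nrow, integer(1)), avail)
  expect_identical(sel$groups, sample_seeds(G, 100L, rng_seed = 10)$groups)
})

test_that("an empty group is never asked for seeds", {
  G <- structure(list(groups = list(rbind(c(1L, 2L)),
                                    matrix(integer(0), 0, 2),
                                    rbind(c(5L, 6L), c(6L, 7L), c(5L, 7L))),
                      sizes = c(3L, 4L, 3L), discarded_count = 0L,
                      t_G = NULL, t_C = NULL),
                 class = "seed_groups")
  sel <- sample_seeds(G, 4L, rng_seed = 1)
  expect_equal(vapply(sel$groups, nrow, integer(1)), c(1L, 0L, 3L))
  expect_error(sample_seeds(G, 5L), "exceeds")
})

test_that("gene thresholds follow the group-size rank map unless overridden", {
  G <- structure(list(groups = vector("list", 5), sizes = c(50L, 40L, 30L, 20L, 10L),
                      discarded_count = 0L, t_G = NULL, t_C = NULL),
                 class = "seed_groups")
  G2 <- assign_thresholds(G, t_range = c(1, 2), t_C = 1.6)
  expect_equal(G2$t_G, c(1, 1.25, 1.5, 1.75, 2)) # strictly decreasing sizes
  expect_equal(G2$t_C, 1.6)
  # equal sizes share the midpoint
  G$sizes <- rep(20L, 5)
  expect_equal(assign_thresholds(G, c(1, 2), 1)$t_G, rep(1.5, 5))
  # published configuration enters verbatim through overrides
  G3 <- assign_thresholds(G, c(1, 2), t_C = 1.6, overrides = c(1, 1.4, 0.9, 1.4, 2))
  expect_equal(G3$t_G, c(1, 1.4, 0.9, 1.4, 2))
  expect_error(assign_thresholds(G, c(1, 2), 1.6, overrides = c(1, 2)), "one t_G per group")
})
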