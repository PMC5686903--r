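test_that("normalization standardizes rows of E_C and columns of E_G", {
  E <- matrix(c(1, 2, 3, 5, 1, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  P <- normalize_expression(E)
  expect_equal(unname(P$E_C["s1", ]), c(-1, 0, 1)) # mean 2, sample sd 1
  expect_equal(rowMeans(P$E_C), c(s1 = 0, s2 = 0), tolerance = 1e-9)
  expect_equal(apply(P$E_G, 2, sd), c(g1 = 1, g2 = 1, g3 = 1), tolerance = 1e-9)
  expect_equal(colMeans(P$E_G), c(g1 = 0, g2 = 0, g3 = 0), tolerance = 1e-9)
  # normalization is idempotent on an already-normalized matrix
  expect_equal(normalize_expression(P$E_C)$E_C, P$E_C, tolerance = 1e-12)
})

test_that("constant rows or columns are rejected by name", {
  E <- rand_expr(4, 4)
  E[, "g2"] <- 7
  expect_error(normalize_expression(E), "g2")
  E2 <- rand_expr(4, 4)
  E2["s3", ] <- 0
  expect_error(normalize_expression(E2), "s3")
})

test_that("thresholding keeps z-scores above t and degrades gracefully", {
  scores <- c(0, 0, 0, 10) # mean 2.5, sample sd 5 -> z = (-.5,-.5,-.5,1.5)
  expect_equal(threshold_scores(scores, 1), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(threshold_scores(scores, 2), rep(FALSE, 4))
  expect_equal(threshold_scores(c(-10, 0, 0, 10), 1, direction = "updown"),
               c(TRUE, FALSE, FALSE, TRUE))
  expect_warning(kept <- threshold_scores(rep(3, 5), 1), "constant")
  expect_equal(kept, rep(FALSE, 5))
})

test_that("threshold monotonicity: higher t keeps a subset", {
  set.seed(14)
  for (i in 1:50) {
    scores <- rnorm(sample(5:50, 1))
    t1 <- runif(1, 0, 2)
    t2 <- t1 + runif(1, 0, 2)
    for (dir in c("up", "updown")) {
      k1 <- threshold_scores(scores, t1, dir)
      k2 <- threshold_scores(scores, t2, dir)
      expect_true(all(which(k2) %in% which(k1)))
    }
  }
})

test_that("isa_step scores equal an independent double-loop computation", {
  set.seed(15)
  for (i in 1:20) {
    E <- rand_expr(8, 12)
    P <- normalize_expression(E)
    c_vec <- seq_len(8) %in% sample.int(8, sample(1:4, 1))
    st <- suppressWarnings(isa_step(P, c_vec, t_G = 1, t_C = 1))
    # gene scores: mean over selected samples of the row-normalized values
    expected_g <- numeric(12)
    for (j in 1:12) {
      acc <- 0
      for (s in which(c_vec)) acc <- acc + P$E_C[s, j]
      expected_g[j] <- acc / sum(c_vec)
    }
    expect_equal(unname(st$gene_scores), expected_g, tolerance = 1e-12)
    if (!st$vanished) {
      expected_c <- numeric(8)
      for (s in 1:8) {
        acc <- 0
        for (j in which(st$g)) acc <- acc + P$E_G[s, j]
        expected_c[s] <- acc / sum(st$g)
      }
      expect_equal(unname(st$sample_scores), expected_c, tolerance = 1e-12)
    }
  }
})

test_that("under pure noise a t_G = 3 gene threshold almost always empties the module", {
  set.seed(99)
  vanished <- 0L
  for (i in 1:200) {
    P <- normalize_expression(rand_expr(16, 30))
    st <- suppressWarnings(isa_step(P, rep(TRUE, 16), t_G = 3, t_C = 1))
    if (st$vanished) vanished <- vanished + 1L
  }
  expect_gte(vanished / 200, 0.95)
})

test_that("a planted block is a fixed point reachable from a 2-sample seed", {
  spec <- plant_spec(m = 200, n = 500, prevalences = c(0.2, 0.8),
                     genes_per_module = 60, delta = 3, noise_sd = 1)
  inst <- planted_expression(spec, rng_seed = 31)
  P <- normalize_expression(inst$expr)
  truth1 <- inst$truth$modules[[1]] # the 40-sample x 60-gene module
  c_true <- rownames(inst$expr) %in% truth1$samples
  st <- isa_step(P, c_true, t_G = 1.5, t_C = 1.5)
  expect_equal(colnames(inst$expr)[st$g], truth1$genes)
  expect_equal(rownames(inst$expr)[st$c_next], truth1$samples)

  seed2 <- which(c_true)[1:2]
  rec <- run_seed(P, seed2, t_G = 1.5, t_C = 1.5)
  expect_s3_class(rec, "bicluster")
  score <- recovery_score(rec, truth1)
  expect_gte(score[["sample_jaccard"]], 0.9)
  expect_gte(score[["gene_jaccard"]], 0.9)

  # the recovered fixed point is threshold-consistent and stable under
  # re-seeding with its own sample set
  rec2 <- run_seed(P, which(rownames(inst$expr) %in% rec$samples),
                   t_G = 1.5, t_C = 1.5)
  expect_lte(rec2$n_iterations, 2 + 1) # min_stable + 1
  expect_setequal(rec2$samples, rec$samples)
  expect_setequal(rec2$genes, rec$genes)
})

test_that("run_seed on pure noise mostly finds nothing at t = 2", {
  set.seed(7)
  none <- 0L
  for (i in 1:100) {
    P <- normalize_expression(rand_expr(20, 40))
    r <- suppressWarnings(run_seed(P, sample.int(20, 2), t_G = 2, t_C = 2))
    if (is.null(r)) none <- none + 1L
  }
  expect_gt(none / 100, 0.5)
})

test_that("the ISA core is deterministic", {
  set.seed(21)
  E <- rand_expr(30, 50)
  E[1:10, 1:12] <- E[1:10, 1:12] + 3
  P <- normalize_expression(E)
  a <- run_seed(P, c(1L, 5L), t_G = 1.5, t_C = 1.2)
  b <- run_seed(P, c(1L, 5L), t_G = 1.5, t_C = 1.2)
  expect_identical(a, b)
})
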