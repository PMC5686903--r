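toy_beta <- function() {
  beta <- matrix(c(0.2, 0.4, 0.6, 0.5, 0.3, 0.7), 3, 2,
                 dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2")))
  ann <- c(cg1 = "TSS200", cg2 = "TSS200", cg3 = "GeneBody")
  list(beta = beta, ann = ann)
}

test_that("region means are plain averages of annotated CpGs per sample", {
  d <- toy_beta()
  prof <- region_mean_beta(d$beta, d$ann)
  expect_equal(prof$means["s1", "TSS200"], mean(c(0.2, 0.4))) # 0.3
  expect_equal(prof$means["s1", "GeneBody"], 0.6)
  expect_equal(prof$counts["s1", "TSS200"], 2L)
  # categories with no annotated CpG are missing, never zero
  expect_true(is.na(prof$means["s1", "3'UTR"]))
  expect_equal(prof$counts["s1", "3'UTR"], 0L)
  # a constant matrix profiles flat at that constant
  flat <- region_mean_beta(matrix(0.5, 3, 2, dimnames = dimnames(d$beta)), d$ann)
  expect_true(all(flat$means[, c("TSS200", "GeneBody")] == 0.5))
})

test_that("unknown samples and regions are rejected by name", {
  d <- toy_beta()
  expect_error(region_mean_beta(d$beta, d$ann, samples = c("s1", "sX")), "sX")
  bad <- d$ann
  bad[1] <- "Promoter"
  expect_error(region_mean_beta(d$beta, bad), "Promoter")
})

test_that("missing betas use pairwise deletion and means stay within [0, 1]", {
  set.seed(61)
  for (i in 1:20) {
    n_cpg <- 24L; n_s <- 6L
    beta <- matrix(runif(n_cpg * n_s), n_cpg, n_s,
                   dimnames = list(sprintf("cg%d", 1:n_cpg), sprintf("s%d", 1:n_s)))
    beta[sample(length(beta), length(beta) * 0.3)] <- NA
    ann <- setNames(rep(REGION_CATEGORIES, length.out = n_cpg), rownames(beta))
    prof <- region_mean_beta(beta, ann)
    ok <- !is.na(prof$means)
    expect_true(all(prof$means[ok] >= 0 & prof$means[ok] <= 1))
    expect_true(all(is.na(prof$means) == (prof$counts == 0L)))
  }
})

test_that("the all-sample profile is the count-weighted mean over any sample partition", {
  set.seed(62)
  beta <- matrix(runif(30 * 9), 30, 9,
                 dimnames = list(sprintf("cg%d", 1:30), sprintf("s%d", 1:9)))
  beta[sample(length(beta), 40)] <- NA
  ann <- setNames(rep(REGION_CATEGORIES, 5), rownames(beta))
  whole <- region_mean_beta(beta, ann)
  parts <- split(colnames(beta), rep(1:3, c(2, 3, 4)))
  for (cat in REGION_CATEGORIES) {
    # weight by observed (non-missing) CpG-value counts per part
    num <- 0; den <- 0
    for (p in parts) {
      pr <- region_mean_beta(beta, ann, samples = p)
      w <- sum(pr$counts[, cat])
      if (w > 0) { num <- num + sum(pr$means[, cat] * pr$counts[, cat], na.rm = TRUE); den <- den + w }
    }
    expect_equal(sum(whole$means[, cat] * whole$counts[, cat], na.rm = TRUE) /
                   sum(whole$counts[, cat]), num / den, tolerance = 1e-12)
  }
})

test_that("bicluster profiles recover planted group contrasts and skip unresolvable records", {
  inst <- planted_expression(plant_spec(m = 60, n = 100, prevalences = c(0.5, 0.5),
                                        genes_per_module = 20), rng_seed = 5)
  levels <- rbind(c(0.2, 0.5, 0.5, 0.5, 0.7, 0.5),
                  c(0.6, 0.5, 0.5, 0.5, 0.3, 0.5))
  meth <- planted_methylation(inst$truth, levels, concentration = 50,
                              cpgs_per_category = 50, rng_seed = 6)
  B <- list(bicluster("grp1", inst$truth$modules[[1]]$samples, "g001"),
            bicluster("grp2", inst$truth$modules[[2]]$samples, "g001"))
  prof <- profile_biclusters(meth$beta, meth$annotation, B)
  d_tss <- mean(prof$grp2$means[, "TSS200"]) - mean(prof$grp1$means[, "TSS200"])
  expect_gt(d_tss, 0.3) # planted 0.2 vs 0.6 contrast, CI ~ 0.01
  d_body <- mean(prof$grp2$means[, "GeneBody"]) - mean(prof$grp1$means[, "GeneBody"])
  expect_lt(d_body, -0.3)

  # bicluster covering all samples equals the global profile
  all_b <- list(bicluster("all", names(inst$truth$labels), "g001"))
  expect_equal(profile_biclusters(meth$beta, meth$annotation, all_b)$all$means,
               region_mean_beta(meth$beta, meth$annotation)$means)

  # records with no methylation samples are skipped, others still profiled
  expect_warning(
    out <- profile_biclusters(meth$beta, meth$annotation,
                              c(B, list(bicluster("ghost", c("zz1", "zz2"), "g001")))),
    "ghost")
  expect_setequal(names(out), c("grp1", "grp2"))
})
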