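# Allele frequencies, F_ST, HWE, private alleles, relatedness, PCA.

test_that("allele frequencies and heterozygosities match direct tallies", {
  m <- gm(matrix(c(0L, 1L, 2L), 3, 1))
  st <- allele_freq_stats(m)
  expect_equal(st$p_alt, 0.5)
  expect_equal(st$h_obs, 1 / 3)
  expect_equal(st$h_exp, 0.5)

  m2 <- gm(matrix(1L, 4, 1))
  st2 <- allele_freq_stats(m2)
  expect_equal(st2$h_obs, 1)
  expect_equal(st2$p_alt, 0.5)

  set.seed(3)
  calls <- matrix(sample(c(0:2, NA), 50, replace = TRUE), 50, 1)
  st3 <- allele_freq_stats(gm(calls))
  g <- calls[!is.na(calls)]
  expect_equal(st3$p_alt, sum(g) / (2 * length(g)))
  expect_equal(st3$h_obs, mean(g == 1))
  expect_equal(st3$n_typed, length(g))
})

test_that("undefined loci are flagged and invariants hold", {
  calls <- cbind(ok = c(0L, 1L), empty = c(NA, NA))
  rownames(calls) <- c("a", "b")
  st <- allele_freq_stats(genotype_matrix(calls))
  expect_false(st$defined[st$locus_id == "empty"])
  set.seed(8)
  big <- allele_freq_stats(gm(matrix(sample(0:2, 500, TRUE), 25, 20)))
  expect_true(all(big$maf <= 0.5 + 1e-12))
  expect_true(all(big$h_exp <= 0.5 + 1e-12))
})

test_that("MAF filter removes strictly below the threshold", {
  st <- data.frame(locus_id = c("a", "b", "c"),
                   maf = c(0.009, 0.01, 0.3), defined = TRUE)
  expect_setequal(filter_maf(st, 0.01), c("b", "c"))
})

test_that("per-locus WC84 theta matches the variance-component oracle", {
  # planted genotype counts, 2 populations of n = 10
  counts1 <- c(6L, 3L, 1L); counts2 <- c(1L, 4L, 5L)
  calls <- matrix(c(rep(0:2, counts1), rep(0:2, counts2)), ncol = 1)
  m <- gm(calls, population = rep(c("p1", "p2"), each = 10))
  got <- per_locus_fst(m)
  expect_equal(got$fst, wc84_oracle(list(counts1, counts2)),
               tolerance = 1e-12)

  # three populations, several random loci
  set.seed(21)
  for (rep in 1:5) {
    cts <- replicate(3, as.integer(rmultinom(1, 12, runif(3))),
                     simplify = FALSE)
    calls <- matrix(unlist(lapply(cts, function(x) rep(0:2, x))), ncol = 1)
    m <- gm(calls, population = rep(paste0("p", 1:3), each = 12))
    expect_equal(per_locus_fst(m)$fst, wc84_oracle(cts), tolerance = 1e-12)
  }
})

test_that("WC84 limits: fixed differences give 1, identical pops give ~0", {
  calls <- matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1)
  m <- gm(calls, population = rep(c("p1", "p2"), each = 10))
  expect_equal(per_locus_fst(m)$fst, 1)

  set.seed(14)
  p <- runif(50, 0.2, 0.8)
  calls <- rbind(sim_hwe_calls(200, p), sim_hwe_calls(200, p))
  m <- gm(calls, population = rep(c("p1", "p2"), each = 200))
  fst <- per_locus_fst(m)$fst
  expect_true(all(abs(fst) < 0.05, na.rm = TRUE))

  expect_error(per_locus_fst(gm(calls)), "two populations")
})

test_that("WC84 is invariant to ref/alt relabelling", {
  set.seed(31)
  calls <- matrix(sample(0:2, 60, TRUE), ncol = 2)
  m <- gm(calls, population = rep(c("p1", "p2", "p3"), each = 10))
  flipped <- gm(2L - calls, population = m$population)
  expect_equal(per_locus_fst(m)$fst, per_locus_fst(flipped)$fst,
               tolerance = 1e-12)
})

test_that("pairwise multilocus F_ST recovers the drift parameter", {
  spec <- simulation_spec(
    n_loci = 400, freq_range = c(0.2, 0.8),
    populations = data.frame(name = c("A", "B"), n = 50,
                             f = 0.03),
    families = NULL, null_loci_fraction = 0, epsilon = 0,
    missing_rate = 0, seed = 77)
  sim <- simulate_pedigree_dataset(spec)
  res <- pairwise_pop_fst_ci(sim$genotypes, min_n = 15, n_boot = 200,
                             seed = 1)
  expect_gt(res$fst, 0.01)
  expect_lt(res$fst, 0.05)

  res2 <- pairwise_pop_fst_ci(sim$genotypes, min_n = 15, n_boot = 200,
                              seed = 1)
  expect_identical(res, res2)           # seeded bootstrap is deterministic
})

test_that("splitting one panmictic pool gives a CI containing zero", {
  set.seed(55)
  calls <- sim_hwe_calls(60, runif(200, 0.2, 0.8))
  m <- gm(calls, population = rep(c("h1", "h2"), each = 30))
  res <- pairwise_pop_fst_ci(m, min_n = 15, n_boot = 300, seed = 2)
  expect_lte(res$ci_low, 0)
  expect_gte(res$ci_high, 0)
})

test_that("exact HWE test handles the canonical cases", {
  expect_equal(hwe_exact_pvalue(25, 50, 25), 1, tolerance = 1e-9)
  expect_lt(hwe_exact_pvalue(50, 0, 50), 1e-3)
  expect_equal(hwe_exact_pvalue(10, 0, 0), 1)   # monomorphic convention
})

test_that("exact HWE test agrees with a permutation oracle", {
  set.seed(9)
  cases <- list(c(3L, 5L, 2L), c(10L, 2L, 8L), c(4L, 12L, 4L))
  for (cs in cases) {
    exact <- hwe_exact_pvalue(cs[1], cs[2], cs[3])
    perm <- hwe_perm_oracle(cs[1], cs[2], cs[3])
    expect_equal(exact, perm, tolerance = 0.03)
  }
})

test_that("hwp_test flags but the caller keeps all loci", {
  calls <- cbind(bad = c(rep(0L, 10), rep(2L, 10)),
                 good = rep(c(0L, 1L, 1L, 2L), 5))
  rownames(calls) <- paste0("s", 1:20)
  res <- hwp_test(genotype_matrix(calls))
  expect_true(res$flag[res$locus_id == "bad"])
  expect_false(res$flag[res$locus_id == "good"])
  expect_equal(nrow(res), 2L)           # nothing dropped
})

test_that("private alleles are detected with occurrence counts", {
  # alt allele only in group X: 3 het + 1 homalt -> 5 copies... use planted
  calls <- cbind(L1 = c(1L, 1L, 2L, 0L, 0L, 0L),
                 L2 = c(1L, 0L, 0L, 1L, 0L, 0L))
  rownames(calls) <- paste0("s", 1:6)
  m <- genotype_matrix(calls, population = rep(c("X", "Y"), each = 3))
  pa <- private_alleles(m)
  row <- pa[pa$locus_id == "L1" & pa$allele == "alt", ]
  expect_equal(row$group, "X")
  expect_equal(row$count, 4L)           # 2 het + 1 homalt = 4 copies
  expect_false(any(pa$locus_id == "L2" & pa$allele == "alt"))  # both groups
})

test_that("a simulated private allele is recovered exactly", {
  set.seed(61)
  calls <- sim_hwe_calls(30, rep(0.3, 20))
  calls[, 5] <- 0L
  calls[1:2, 5] <- c(1L, 1L)            # alt allele only in first group
  m <- gm(calls, population = rep(c("G1", "G2"), each = 15))
  pa <- private_alleles(m)
  hit <- pa[pa$locus_id == "L005" & pa$allele == "alt", ]
  expect_equal(hit$group, "G1")
  expect_equal(hit$count, 2L)
})

test_that("Ritland estimator reproduces hand-evaluated cases", {
  # both individuals hom-ref at one locus with p_ref = 0.5:
  # r = 2 * ((1 * 1) / 0.5 - 1) / 1 = 2
  m <- gm(matrix(c(0L, 0L), 2, 1))
  r <- ritland_relatedness(m, freqs = c(L001 = 0.5))
  expect_equal(r$r, 2)
  # both het at p = 0.5: 2 * (0.25/0.5 + 0.25/0.5 - 1) = 0
  m2 <- gm(matrix(c(1L, 1L), 2, 1))
  r2 <- ritland_relatedness(m2, freqs = c(L001 = 0.5))
  expect_equal(r2$r, 0)
})

test_that("Ritland relatedness is symmetric and ~unbiased for unrelated pairs", {
  set.seed(101)
  p <- runif(500, 0.1, 0.9)
  calls <- sim_hwe_calls(21, p)          # 210 unrelated pairs
  m <- gm(calls)
  res <- ritland_relatedness(m, freqs = p)
  expect_equal(nrow(res), choose(21, 2))
  expect_lt(abs(mean(res$r)), 0.02)

  swapped <- ritland_relatedness(m, freqs = p,
                                 pairs = cbind(res$sample_b, res$sample_a))
  expect_equal(swapped$r, res$r)
})

test_that("first-degree purging leaves no pair above the threshold", {
  pairs <- data.frame(sample_a = "A", sample_b = "B", r = 0.4)
  out <- purge_first_degree(pairs, c(A = "p", B = "p"), threshold = 0.26)
  expect_length(out$retained, 1L)
  expect_length(out$removed, 1L)

  none <- purge_first_degree(data.frame(sample_a = "A", sample_b = "B",
                                        r = 0.1),
                             c(A = "p", B = "p"))
  expect_setequal(none$retained, c("A", "B"))

  # simulated full-sib families: postcondition check
  spec <- simulation_spec(n_loci = 200, epsilon = 0, missing_rate = 0,
                          null_loci_fraction = 0, seed = 303,
                          families = default_cross_design(n_offspring = 4))
  sim <- simulate_pedigree_dataset(spec)
  m <- sim$genotypes
  rel <- ritland_relatedness(m)
  out <- purge_first_degree(rel, m$population, threshold = 0.26,
                            genotyping_rate = genotyping_rate(m))
  kept <- rel[rel$sample_a %in% out$retained &
                rel$sample_b %in% out$retained, ]
  expect_true(all(kept$r <= 0.26))
})

test_that("dosage PCA separates clusters and matches an SVD oracle", {
  calls <- rbind(matrix(0L, 5, 12), matrix(2L, 5, 12))
  suppressWarnings(res <- pca_dosage(gm(calls), 2))
  expect_gt(abs(diff(range(res$scores[1:5, 1], res$scores[6:10, 1]))), 1)
  expect_gt(res$var_fraction[1], 0.99)
  expect_equal(res$scores[1, ], res$scores[2, ])  # duplicates identical

  set.seed(17)
  calls <- matrix(sample(0:2, 20 * 50, TRUE), 20, 50)
  m <- gm(calls)
  res <- pca_dosage(m, 4)
  X <- scale(calls, center = TRUE, scale = FALSE)
  sv <- svd(X)
  oracle_scores <- (sv$u %*% diag(sv$d))[, 1:4]
  expect_equal(abs(unname(res$scores)), abs(oracle_scores),
               tolerance = 1e-8)
  expect_equal(res$var_fraction, (sv$d^2 / sum(sv$d^2))[1:4],
               tolerance = 1e-10)
})
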