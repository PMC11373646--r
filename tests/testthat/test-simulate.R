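# The pedigree simulator: drift model, inheritance, nulls, error model.

make_bundle <- function(h1, h2, pop = "pop1") {
  ids <- rownames(h1)
  structure(list(h1 = h1, h2 = h2, founder_ids = ids,
                 population = stats::setNames(rep(pop, length(ids)), ids),
                 pedigree = NULL, dam_choice = NULL, sire_choice = NULL),
            class = "haplotype_bundle")
}

test_that("Balding-Nichols frequencies: F = 0 is exact, variance scales with F", {
  spec0 <- simulation_spec(n_loci = 100, populations =
                             data.frame(name = c("a", "b"), n = 5, f = 0),
                           families = NULL, seed = 5)
  fr <- simulate_base_frequencies(spec0)
  expect_equal(fr$per_population["a", ], fr$ancestral)
  expect_equal(fr$per_population["b", ], fr$ancestral)

  specF <- simulation_spec(n_loci = 4000, freq_range = c(0.5, 0.5),
                           populations = data.frame(name = "x", n = 5,
                                                    f = 0.5),
                           families = NULL, seed = 6)
  frF <- simulate_base_frequencies(specF)
  v <- var(frF$per_population["x", ])
  expect_equal(v, 0.5 * 0.5 * 0.5, tolerance = 0.05)

  fr2 <- simulate_base_frequencies(spec0)
  expect_identical(fr, fr2)             # same spec, same seed, same draw
})

test_that("offspring inherit one uniformly chosen allele per parent", {
  L <- 10000L
  h0 <- matrix(0L, 2, L, dimnames = list(c("pop1_01", "pop1_02"), NULL))
  colnames(h0) <- sprintf("L%05d", seq_len(L))
  b <- make_bundle(h0, h0)
  fam <- data.frame(dam = "pop1_01", sire = "pop1_02", n_offspring = 3)
  b2 <- simulate_families(b, fam, seed = 9)
  off <- genotype_calls(b2)[b2$pedigree$offspring_id, ]
  expect_true(all(off == 0L))           # homref x homref -> all homref

  # het x het: make both parents 0/1 at every locus
  h1 <- matrix(0L, 2, L, dimnames = dimnames(h0))
  h2 <- matrix(1L, 2, L, dimnames = dimnames(h0))
  colnames(h1) <- colnames(h2) <- colnames(h0)
  b3 <- simulate_families(make_bundle(h1, h2), fam, seed = 10)
  g <- genotype_calls(b3)[b3$pedigree$offspring_id[1], ]
  props <- table(factor(g, levels = 0:2)) / L
  expect_equal(unname(as.numeric(props)), c(0.25, 0.5, 0.25),
               tolerance = 0.03)        # 1:2:1 within binomial error

  expect_error(simulate_families(b, data.frame(dam = "nope", sire = "pop1_02",
                                               n_offspring = 1), seed = 1),
               "unknown founder")
})

test_that("full sibs show relatedness near 0.5 with the Ritland estimator", {
  spec <- simulation_spec(n_loci = 400, epsilon = 0, missing_rate = 0,
                          null_loci_fraction = 0, seed = 88,
                          families = data.frame(dam = "pop1_01",
                                                sire = "pop1_02",
                                                n_offspring = 12))
  sim <- simulate_pedigree_dataset(spec)
  offs <- sim$truth$pedigree$offspring_id
  # relatedness is measured against the population allele frequencies, not
  # frequencies re-estimated from the sib group itself (which would centre
  # the estimator at zero by construction)
  rel <- ritland_relatedness(sim$genotypes[offs, ],
                             freqs = sim$truth$frequencies$ancestral)
  expect_gt(mean(rel$r), 0.3)
  expect_lt(mean(rel$r), 0.7)
})

test_that("null alleles mask carriers as homozygotes and fail as missing", {
  L <- 4L
  ids <- c("pop1_01", "pop1_02")
  h1 <- matrix(c(0L, 0L, 1L, 0L,
                 0L, 1L, 1L, 0L), 2, L, byrow = TRUE,
               dimnames = list(ids, sprintf("L%02d", 1:L)))
  h2 <- matrix(c(1L, 0L, 1L, 0L,
                 0L, 1L, 0L, 0L), 2, L, byrow = TRUE,
               dimnames = list(ids, sprintf("L%02d", 1:L)))
  b <- make_bundle(h1, h2)
  # null_freq = 1: every founder haplotype at L01 becomes null
  b_null <- apply_null_alleles(b, "L01", null_freq = 1, seed = 3)
  g <- genotype_calls(b_null)
  expect_true(all(is.na(g[, "L01"])))
  expect_equal(g[, "L02"], genotype_calls(b)[, "L02"])  # untouched locus

  # null_freq = 0: nothing changes
  b_same <- apply_null_alleles(b, "L01", null_freq = 0, seed = 3)
  expect_identical(genotype_calls(b_same), genotype_calls(b))
})

test_that("an inherited null produces a traceable Mendelian incompatibility", {
  # dam A1/n typed A1A1 (homref), offspring inherits n from dam and A2 from
  # sire -> typed A2A2 (homalt): incompatible with both typed parents.
  ids <- c("pop1_01", "pop1_02")
  h1 <- matrix(c(0L, 1L), 2, 1, dimnames = list(ids, "L01"))
  h2 <- matrix(c(2L, 1L), 2, 1, dimnames = list(ids, "L01"))  # dam carries n
  b <- make_bundle(h1, h2)
  fam <- data.frame(dam = "pop1_01", sire = "pop1_02", n_offspring = 40)
  b <- simulate_families(b, fam, seed = 12)
  g <- genotype_calls(b)
  dam_g <- g["pop1_01", 1]; sire_g <- g["pop1_02", 1]
  expect_equal(unname(dam_g), 0L)       # spurious homref
  expect_equal(unname(sire_g), 2L)
  offs <- b$pedigree$offspring_id
  carried_null <- b$dam_choice[offs, 1] == 2L
  expect_true(any(carried_null))
  bad <- !mendelian_compatible(rep(dam_g, length(offs)),
                               rep(sire_g, length(offs)), g[offs, 1])
  # exactly the null inheritors are incompatible (typed homalt, not het)
  expect_equal(unname(bad), unname(carried_null))
})

test_that("error and missingness model reproduces closed-form concordance", {
  expect_identical(apply_error_and_missingness(
    matrix(c(0L, 1L, 2L, NA), 2, 2), 0, 0), matrix(c(0L, 1L, 2L, NA), 2, 2))

  set.seed(30)
  true_g <- matrix(rbinom(200000, 2, 0.4), 400, 500)
  eps <- 0.0125
  a <- apply_error_and_missingness(true_g, eps, 0)
  b <- apply_error_and_missingness(true_g, eps, 0)
  conc <- mean(a == b)
  # two independent observations agree iff both correct or both flipped to
  # the same wrong genotype: (1 - eps)^2 + eps^2 / 2
  expect_equal(conc, (1 - eps)^2 + eps^2 / 2, tolerance = 0.002)
})

test_that("identical specs reproduce the full dataset, replicates included", {
  spec <- simulation_spec(n_loci = 50, replicate_fraction = 0.2, seed = 99)
  s1 <- simulate_pedigree_dataset(spec)
  s2 <- simulate_pedigree_dataset(spec)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$truth$null_loci, s2$truth$null_loci)
  expect_true(any(grepl("_rep$", sample_ids(s1$genotypes))))
  rep_ids <- s1$truth$replicate_map
  expect_equal(nrow(rep_ids) %% 2, 0)
})

test_that("simulated replicates land in the expected concordance region", {
  spec <- simulation_spec(n_loci = 400, epsilon = 0.0125, missing_rate = 0.05,
                          null_loci_fraction = 0, replicate_fraction = 0.5,
                          seed = 121)
  sim <- simulate_pedigree_dataset(spec)
  res <- replicate_concordance(sim$genotypes, sim$truth$replicate_map)
  expect_equal(res$mean, (1 - 0.0125)^2 + 0.0125^2 / 2, tolerance = 0.01)
})
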