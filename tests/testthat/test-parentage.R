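# Assignment, trios, incompatibility tallying, null flagging, evaluation.

sim_small <- function(seed, epsilon = 0.005, null_fraction = 0.10,
                      n_loci = 300) {
  spec <- simulation_spec(n_loci = n_loci, epsilon = epsilon,
                          null_loci_fraction = null_fraction,
                          seed = seed)
  simulate_pedigree_dataset(spec)
}

split_generations <- function(sim) {
  gm <- sim$genotypes
  gen <- gm$generation
  list(off = gm[names(gen)[gen == "offspring"], ],
       par = gm[names(gen)[gen == "parent"], ])
}

test_that("Mendelian compatibility equals gamete enumeration on all 27 triples", {
  triples <- expand.grid(dam = 0:2, sire = 0:2, off = 0:2)
  got <- mendelian_compatible(triples$dam, triples$sire, triples$off)
  oracle <- mapply(mendel_oracle, triples$dam, triples$sire, triples$off)
  expect_equal(got, unname(oracle))
  # spot checks
  expect_false(mendelian_compatible(0L, 0L, 1L))
  expect_true(mendelian_compatible(0L, 2L, 1L))
  expect_error(mendelian_compatible(NA, 0L, 0L), "non-missing")
})

test_that("true parents score far above unrelated candidates", {
  sim <- sim_small(404, null_fraction = 0)
  gs <- split_generations(sim)
  all_pairs <- assign_parents(gs$off, gs$par, cutoff = -Inf,
                              epsilon = 0.005)
  expect_equal(nrow(all_pairs),
               nrow(gs$off$calls) * nrow(gs$par$calls))
  ped <- sim$truth$pedigree
  key <- paste(all_pairs$offspring_id, all_pairs$candidate_parent_id)
  truth_key <- c(paste(ped$offspring_id, ped$dam_id),
                 paste(ped$offspring_id, ped$sire_id))
  is_parent <- key %in% truth_key
  expect_gt(min(all_pairs$logl[is_parent]), 5)
  expect_lt(max(all_pairs$logl[!is_parent]), 0)
  expect_error(assign_parents(gs$off, gs$par[integer(0), ]), "empty")
})

test_that("trio identification enforces the exactly-two rule", {
  asg <- data.frame(
    offspring_id = c("o1", "o1", "o2", "o2", "o3", "o3", "o3",
                     "o4", "o4"),
    candidate_parent_id = c("p1", "p2", "p1", "p2", "p1", "p2", "p3",
                            "p1", "p2"),
    logl = c(30, 25, 28, 22, 30, 29, 12, 40, 8),
    n_shared_loci = 290L)
  trios <- identify_trios(asg, strong_cutoff = 10, min_obs = 2)
  # o3 has three candidates above the cutoff -> excluded;
  # o4's second parent is below the strong cutoff -> excluded
  expect_setequal(trios$offspring_id, c("o1", "o2"))
  expect_true(all(trios$confirmed))     # p1+p2 seen twice
  solo <- identify_trios(asg[1:2, ], min_obs = 2)
  expect_false(any(solo$confirmed))
})

test_that("error-free null-free trios show zero incompatibilities", {
  sim <- sim_small(505, epsilon = 0, null_fraction = 0)
  gs <- split_generations(sim)
  asg <- assign_parents(gs$off, gs$par, cutoff = 5, epsilon = 0.005)
  trios <- identify_trios(asg)
  expect_gt(sum(trios$confirmed), 50)
  tal <- tally_incompatibilities(trios, sim$genotypes)
  expect_true(all(tal$n_incompatible == 0L))
  expect_true(all(tal$n_incompatible <= tal$n_typed))
})

test_that("planted null alleles inflate incompatibility counts", {
  sim <- sim_small(606, epsilon = 0, null_fraction = 0.10)
  gs <- split_generations(sim)
  asg <- assign_parents(gs$off, gs$par, cutoff = 5, epsilon = 0.005)
  trios <- identify_trios(asg)
  tal <- tally_incompatibilities(trios, sim$genotypes)
  nulls <- sim$truth$null_loci
  clean <- setdiff(tal$locus_id, nulls)
  # with epsilon = 0 every incompatibility traces to a planted null
  expect_true(all(tal$n_incompatible[tal$locus_id %in% clean] == 0L))
  fl <- flag_null_loci(tal, min_count = 4)
  expect_true(all(fl$flagged %in% nulls))
  expect_gt(mean(nulls %in% fl$flagged), 0.8)
})

test_that("null-flag thresholds are boundaries on the tally", {
  tal <- data.frame(locus_id = c("a", "b", "c", "d"),
                    n_incompatible = c(4L, 3L, 2L, 0L),
                    n_typed = 40L)
  fl <- flag_null_loci(tal, min_count = 4, watch_count = 2)
  expect_equal(fl$flagged, "a")
  expect_setequal(fl$watch, c("a", "b", "c"))
})

test_that("assignment metrics follow the completeness and FP formulas", {
  m <- assignment_metrics(n_correct = 160, n_possible = 172, n_fp = 8)
  expect_equal(m$pct_complete, 100 * 160 / 172)
  expect_equal(m$pct_fp, 100 * 8 / 168)
  expect_equal(m$n_assigned_total, 168)
  z <- assignment_metrics(0, 10, 0)
  expect_equal(z$pct_fp, 0)
})

test_that("evaluation counts slots only for genotyped parents", {
  sim <- sim_small(707, null_fraction = 0)
  gs <- split_generations(sim)
  ped <- pedigree_table(sim$truth$pedigree$offspring_id,
                        sim$truth$pedigree$dam_id,
                        sim$truth$pedigree$sire_id)
  # remove one dam from the candidates: her offsprings' slots drop to 1
  gone <- ped$dam_id[1]
  par2 <- gs$par[setdiff(sample_ids(gs$par), gone), ]
  ev <- rerun_and_evaluate(gs$off, par2, ped)
  full <- rerun_and_evaluate(gs$off, gs$par, ped)
  n_off_of_gone <- sum(ped$dam_id == gone)
  expect_equal(full$metrics$n_possible - ev$metrics$n_possible,
               n_off_of_gone)
  expect_identical(ev$metrics$n_assigned_total,
                   ev$metrics$n_assigned_correct + ev$metrics$n_fp)
  expect_true(ev$metrics$pct_complete >= 0 &&
                ev$metrics$pct_complete <= 100)

  bad_ped <- pedigree_table("ghost", ped$dam_id[1], ped$sire_id[1])
  expect_error(rerun_and_evaluate(gs$off, gs$par, bad_ped), "absent")
})

test_that("removing flagged null loci never loses correct assignments", {
  for (seed in c(811, 812)) {
    sim <- sim_small(seed)
    gs <- split_generations(sim)
    ped <- pedigree_table(sim$truth$pedigree$offspring_id,
                          sim$truth$pedigree$dam_id,
                          sim$truth$pedigree$sire_id)
    asg <- assign_parents(gs$off, gs$par, cutoff = 5, epsilon = 0.005)
    trios <- identify_trios(asg)
    tal <- tally_incompatibilities(trios, sim$genotypes)
    fl <- flag_null_loci(tal)
    before <- rerun_and_evaluate(gs$off, gs$par, ped)
    after <- rerun_and_evaluate(gs$off, gs$par, ped,
                                flagged_loci = fl$flagged)
    expect_gte(after$metrics$n_assigned_correct,
               before$metrics$n_assigned_correct)
  }
})

test_that("the assignment network exports one weighted edge per record", {
  asg <- data.frame(offspring_id = c("o1", "o1", "o2"),
                    candidate_parent_id = c("p1", "p2", "p1"),
                    logl = c(31.5, 28.2, 40.0), n_shared_loci = 300L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  export_assignment_network(asg, tf)
  edges <- utils::read.table(tf, header = TRUE, sep = "\t")
  expect_equal(nrow(edges), 3L)
  expect_equal(edges$weight, asg$logl)

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  export_assignment_network(asg[0, ], tf2)
  expect_equal(length(readLines(tf2)), 1L)   # header only
})
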