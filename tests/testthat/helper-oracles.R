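# Shared fixtures and independent oracles used across the suite.

gm <- function(calls, population = NULL, ...) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("s%02d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("L%03d", seq_len(ncol(calls)))
  }
  genotype_matrix(calls, population = population, ...)
}

# HWE genotype draws at alternate-allele frequency p
sim_hwe_calls <- function(n, p) {
  matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), n,
         length(p))
}

# Weir & Cockerham (1984) theta from per-population genotype counts,
# written directly from the published variance-component formulas.
wc84_oracle <- function(counts_by_pop) {
  r <- length(counts_by_pop)
  n <- sapply(counts_by_pop, sum)
  p <- sapply(counts_by_pop, function(x) (x[2] + 2 * x[3]) / (2 * sum(x)))
  h <- sapply(counts_by_pop, function(x) x[2] / sum(x))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# Joint genotype-pair probabilities by exhaustive enumeration over parental
# allele transmissions (error-free). Alleles: 0 = ref, 1 = alt.
kin_joint_oracle <- function(p, rel) {
  q <- 1 - p
  af <- c(q, p)
  J <- matrix(0, 3, 3)
  add <- function(g1, g2, pr) J[g1 + 1, g2 + 1] <<- J[g1 + 1, g2 + 1] + pr
  if (rel == "U") {
    pri <- c(q^2, 2 * p * q, p^2)
    J <- outer(pri, pri)
  } else if (rel == "PO") {
    for (a1 in 0:1) for (a2 in 0:1) for (tr in 1:2) for (c2 in 0:1) {
      pr <- af[a1 + 1] * af[a2 + 1] * 0.5 * af[c2 + 1]
      add(a1 + a2, c(a1, a2)[tr] + c2, pr)
    }
  } else if (rel == "FS") {
    for (m1 in 0:1) for (m2 in 0:1) for (f1 in 0:1) for (f2 in 0:1) {
      base <- af[m1 + 1] * af[m2 + 1] * af[f1 + 1] * af[f2 + 1] / 16
      for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
        add(c(m1, m2)[i] + c(f1, f2)[j], c(m1, m2)[k] + c(f1, f2)[l], base)
      }
    }
  } else if (rel == "HS") {
    for (s1 in 0:1) for (s2 in 0:1) for (o1 in 0:1) for (o2 in 0:1) {
      base <- af[s1 + 1] * af[s2 + 1] * af[o1 + 1] * af[o2 + 1] / 4
      for (i in 1:2) for (k in 1:2) {
        add(c(s1, s2)[i] + o1, c(s1, s2)[k] + o2, base)
      }
    }
  }
  J
}

# Mendelian compatibility by brute force over the 2 x 2 gamete combinations
mendel_oracle <- function(dam, sire, off) {
  als <- function(g) switch(g + 1, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  any(outer(als(dam), als(sire), "+") == off)
}

# Permutation oracle for the exact HWE test: shuffle the observed alleles
# into genotypes and use the empirical heterozygote-count distribution.
hwe_perm_oracle <- function(n0, n1, n2, nperm = 40000) {
  n <- n0 + n1 + n2
  alleles <- c(rep(0L, 2 * n0 + n1), rep(1L, n1 + 2 * n2))
  hets <- replicate(nperm, {
    a <- sample(alleles)
    sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
  })
  tab <- table(hets) / nperm
  pobs <- tab[as.character(n1)]
  sum(tab[tab <= pobs * (1 + 1e-9)])
}

# Synthetic per-locus statistics table in which the top-n_hobs and top-n_fst
# rankings share exactly `overlap` loci; extras are disjoint from both.
make_selection_stats <- function(seed, n_loci = 1000, n_top = 300,
                                 overlap = 9, n_extra = 20) {
  set.seed(seed)
  ids <- sprintf("L%06d", sample.int(10 * n_loci, n_loci))
  both <- ids[seq_len(overlap)]
  hobs_only <- ids[overlap + seq_len(n_top - overlap)]
  fst_only <- ids[n_top + seq_len(n_top - overlap)]
  rest <- setdiff(ids, c(both, hobs_only, fst_only))
  extras <- rest[seq_len(n_extra)]
  h_obs <- stats::setNames(runif(n_loci, 0.05, 0.40), ids)
  fst <- stats::setNames(runif(n_loci, 0.001, 0.040), ids)
  h_obs[c(both, hobs_only)] <- runif(n_top, 0.41, 0.50)
  fst[c(both, fst_only)] <- runif(n_top, 0.046, 0.178)
  list(stats = data.frame(locus_id = ids, h_obs = unname(h_obs),
                          fst = unname(fst), stringsAsFactors = FALSE),
       extras = extras, both = both)
}
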