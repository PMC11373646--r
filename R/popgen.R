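# Per-locus and per-population statistics: allele frequencies,
# heterozygosities, Weir-Cockerham F_ST, exact Hardy-Weinberg tests,
# private alleles, Ritland relatedness, first-degree purging, PCA.

.genotype_counts <- function(calls) {
  # counts per locus over a call matrix
  list(n_ref = colSums(calls == GT_HOMREF, na.rm = TRUE),
       n_het = colSums(calls == GT_HET, na.rm = TRUE),
       n_alt = colSums(calls == GT_HOMALT, na.rm = TRUE))
}

#' Per-locus allele frequencies and heterozygosities
#'
#' Computes, per locus (optionally per population), the alternate-allele
#' frequency `p_alt = (2 n_homalt + n_het) / (2 n_typed)`, the minor allele
#' frequency `maf = min(p_alt, 1 - p_alt)`, observed heterozygosity
#' `h_obs = n_het / n_typed` and expected heterozygosity
#' `h_exp = 2 p (1 - p)` (no small-sample correction). Loci with zero typed
#' calls get `NA` statistics and `defined = FALSE`.
#'
#' @param x A [genotype_matrix()].
#' @param by_population If `TRUE`, statistics are computed within each
#'   population and the result gains a `population` column.
#' @return Data frame with columns `locus_id`, (`population`,) `n_typed`,
#'   `p_alt`, `maf`, `h_obs`, `h_exp`, `defined`.
#' @export
allele_freq_stats <- function(x, by_population = FALSE) {
  one <- function(calls, pop = NULL) {
    ct <- .genotype_counts(calls)
    n_typed <- ct$n_ref + ct$n_het + ct$n_alt
    p_alt <- ifelse(n_typed > 0, (2 * ct$n_alt + ct$n_het) / (2 * n_typed),
                    NA_real_)
    out <- data.frame(locus_id = colnames(calls),
                      n_typed = as.integer(n_typed),
                      p_alt = p_alt,
                      maf = pmin(p_alt, 1 - p_alt),
                      h_obs = ifelse(n_typed > 0, ct$n_het / n_typed,
                                     NA_real_),
                      h_exp = 2 * p_alt * (1 - p_alt),
                      defined = n_typed > 0,
                      stringsAsFactors = FALSE)
    if (!is.null(pop)) out <- cbind(population = pop, out,
                                    stringsAsFactors = FALSE)
    out
  }
  if (!by_population) return(one(x$calls))
  res <- lapply(unique(x$population), function(p) {
    one(x$calls[x$population == p, , drop = FALSE], pop = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Alternate-allele frequency vector
#'
#' Convenience accessor: named numeric vector of `p_alt` per locus.
#'
#' @param x A [genotype_matrix()].
#' @return Named numeric vector (NA where no calls).
#' @export
alt_freqs <- function(x) {
  st <- allele_freq_stats(x)
  stats::setNames(st$p_alt, st$locus_id)
}

#' Minor-allele-frequency filter
#'
#' Removes loci with `maf < min_maf` (strict removal below the threshold, so
#' a locus at exactly `min_maf` is kept). Loci with undefined statistics are
#' removed as well.
#'
#' @param stats Output of [allele_freq_stats()] (global, not per-population).
#' @param min_maf MAF threshold (default 0.01).
#' @return Character vector of retained locus ids.
#' @export
filter_maf <- function(stats, min_maf = 0.01) {
  keep <- stats$defined & !is.na(stats$maf) & stats$maf >= min_maf
  stats$locus_id[keep]
}

.wc84_components <- function(calls, population) {
  # Weir & Cockerham (1984) variance components a (among populations),
  # b (among individuals within populations), c (within individuals),
  # per locus, for biallelic SNPs. theta = a / (a + b + c).
  pops <- unique(population)
  L <- ncol(calls)
  n_i <- p_i <- h_i <- matrix(0, length(pops), L)
  for (k in seq_along(pops)) {
    sub <- calls[population == pops[k], , drop = FALSE]
    ct <- .genotype_counts(sub)
    n <- ct$n_ref + ct$n_het + ct$n_alt
    n_i[k, ] <- n
    p_i[k, ] <- ifelse(n > 0, (2 * ct$n_alt + ct$n_het) / (2 * n), NA_real_)
    h_i[k, ] <- ifelse(n > 0, ct$n_het / n, NA_real_)
  }
  a <- b <- cc <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    use <- which(n_i[, l] > 0 & !is.na(p_i[, l]))
    r <- length(use)
    if (r < 2L) next
    n <- n_i[use, l]; p <- p_i[use, l]; h <- h_i[use, l]
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    if (nc <= 0) next
    a[l] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[l] <- hbar / 2
  }
  data.frame(locus_id = colnames(calls), a = a, b = b, c = cc,
             stringsAsFactors = FALSE)
}

#' Per-locus Weir-Cockerham F_ST
#'
#' Computes the Weir & Cockerham (1984) theta estimator per locus over the
#' supplied populations, from the variance components a (among populations),
#' b (among individuals within populations) and c (within individuals):
#' `theta = a / (a + b + c)`. Loci where the estimator is undefined
#' (monomorphic, fewer than two populations with data) have `fst = NA` and
#' `defined = FALSE`. The components are returned so multilocus
#' ratio-of-averages estimates can be formed downstream.
#'
#' @param x A [genotype_matrix()].
#' @param populations Optional sample -> population labels overriding
#'   `x$population`.
#' @return Data frame with `locus_id`, `a`, `b`, `c`, `fst`, `defined`.
#' @export
per_locus_fst <- function(x, populations = NULL) {
  pop <- if (is.null(populations)) x$population
         else .match_sample_labels(populations, sample_ids(x), NA_character_)
  if (length(unique(pop)) < 2L) {
    stop("F_ST requires at least two populations", call. = FALSE)
  }
  comp <- .wc84_components(x$calls, pop)
  denom <- comp$a + comp$b + comp$c
  comp$fst <- ifelse(!is.na(denom) & denom != 0, comp$a / denom, NA_real_)
  comp$defined <- !is.na(comp$fst)
  comp
}

#' Pairwise population F_ST with bootstrap confidence intervals
#'
#' Multilocus Weir-Cockerham F_ST for every pair of sufficiently sampled
#' populations, as the ratio of averages `sum(a) / sum(a + b + c)` over
#' loci, with a percentile bootstrap over loci for the confidence interval.
#' Populations with fewer than `min_n` samples are excluded.
#'
#' @param x A [genotype_matrix()].
#' @param min_n Minimum samples per population (default 15; populations at
#'   or below this many samples are dropped, i.e. "more than 15" retained).
#' @param n_boot Bootstrap replicates over loci (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Data frame with `pop_a`, `pop_b`, `fst`, `ci_low`, `ci_high`,
#'   `n_loci`.
#' @export
pairwise_pop_fst_ci <- function(x, min_n = 15, n_boot = 1000, seed = NULL,
                                conf = 0.95) {
  tab <- table(x$population)
  pops <- names(tab)[tab > min_n]
  if (length(pops) < 2L) {
    stop("need at least two populations with more than ", min_n, " samples",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - conf) / 2
  rows <- list()
  for (i in seq_len(length(pops) - 1L)) {
    for (j in seq(i + 1L, length(pops))) {
      keep <- x$population %in% c(pops[i], pops[j])
      comp <- .wc84_components(x$calls[keep, , drop = FALSE],
                               x$population[keep])
      ok <- stats::complete.cases(comp[, c("a", "b", "c")])
      a <- comp$a[ok]; d <- (comp$a + comp$b + comp$c)[ok]
      use <- d != 0
      a <- a[use]; d <- d[use]
      fst <- sum(a) / sum(d)
      boots <- vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(a), replace = TRUE)
        sum(a[idx]) / sum(d[idx])
      }, numeric(1))
      ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                            names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        pop_a = pops[i], pop_b = pops[j], fst = fst,
        ci_low = ci[1], ci_high = ci[2], n_loci = length(a),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact Hardy-Weinberg test p-value for a biallelic locus
#'
#' Full-enumeration exact test: conditional on the observed allele counts,
#' the probability of every possible heterozygote count is computed by the
#' standard mid-point recurrence, and the p-value is the summed probability
#' of all configurations no more probable than the observed one. Monomorphic
#' samples return `p = 1` by convention.
#'
#' @param n_homref,n_het,n_homalt Genotype counts.
#' @return Two-sided exact p-value.
#' @export
hwe_exact_pvalue <- function(n_homref, n_het, n_homalt) {
  n <- n_homref + n_het + n_homalt
  if (n == 0L) return(1)
  n_a <- 2L * n_homalt + n_het           # alt allele copies
  n_rare <- min(n_a, 2L * n - n_a)
  if (n_rare == 0L) return(1)            # monomorphic
  # possible heterozygote counts share the parity of n_rare
  het_vals <- seq(n_rare %% 2L, n_rare, by = 2L)
  probs <- numeric(length(het_vals))
  # start at the mode-adjacent mid value and fill with the recurrence
  mid <- n_rare * (2 * n - n_rare) / (2 * n)
  mid <- floor(mid)
  if (mid %% 2L != n_rare %% 2L) mid <- mid + 1L
  i_mid <- match(mid, het_vals)
  probs[i_mid] <- 1
  # going down: P(h-2)/P(h) = h (h - 1) / ((n_rare - h + 2)(2n - n_rare - h + 2) ... )
  if (i_mid > 1L) {
    for (i in seq(i_mid, 2L)) {
      h <- het_vals[i]
      hom_r <- (n_rare - h) / 2          # rare homozygotes at h
      hom_c <- n - h - hom_r             # common homozygotes at h
      probs[i - 1L] <- probs[i] * h * (h - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  if (i_mid < length(het_vals)) {
    for (i in seq(i_mid, length(het_vals) - 1L)) {
      h <- het_vals[i]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      probs[i + 1L] <- probs[i] * 4 * hom_r * hom_c /
        ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, het_vals)]
  if (is.na(p_obs)) stop("inconsistent genotype counts", call. = FALSE)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg proportion flags per locus and population
#'
#' Runs the exact biallelic test within each population and flags loci with
#' `p < alpha`. Flagged loci are reported, never removed, mirroring
#' flag-only HWP usage in panel QC.
#'
#' @param x A [genotype_matrix()].
#' @param alpha Flagging threshold (default 0.05, uncorrected).
#' @return Data frame with `locus_id`, `population`, `n_homref`, `n_het`,
#'   `n_homalt`, `p_value`, `flag`.
#' @export
hwp_test <- function(x, alpha = 0.05) {
  rows <- list()
  for (pop in unique(x$population)) {
    sub <- x$calls[x$population == pop, , drop = FALSE]
    ct <- .genotype_counts(sub)
    p <- vapply(seq_len(ncol(sub)), function(l) {
      hwe_exact_pvalue(ct$n_ref[l], ct$n_het[l], ct$n_alt[l])
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = colnames(sub), population = pop,
      n_homref = as.integer(ct$n_ref), n_het = as.integer(ct$n_het),
      n_homalt = as.integer(ct$n_alt),
      p_value = p, flag = p < alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Private alleles per genetic grouping
#'
#' An allele (reference or alternate) at a locus is private to a grouping
#' when it is observed there (at least one copy) and in no other grouping.
#' The occurrence count is the number of allele copies within the grouping.
#'
#' @param x A [genotype_matrix()].
#' @param groupings Sample -> grouping labels (named vector, single value,
#'   or vector in sample order); defaults to `x$population`.
#' @return Data frame with `locus_id`, `allele` (`"ref"` or `"alt"`),
#'   `group`, `count`.
#' @export
private_alleles <- function(x, groupings = NULL) {
  grp <- if (is.null(groupings)) x$population
         else .match_sample_labels(groupings, sample_ids(x), NA_character_)
  groups <- unique(grp)
  L <- ncol(x$calls)
  ref_copies <- alt_copies <- matrix(0L, length(groups), L,
                                     dimnames = list(groups, NULL))
  for (k in seq_along(groups)) {
    sub <- x$calls[grp == groups[k], , drop = FALSE]
    ct <- .genotype_counts(sub)
    ref_copies[k, ] <- as.integer(2L * ct$n_ref + ct$n_het)
    alt_copies[k, ] <- as.integer(2L * ct$n_alt + ct$n_het)
  }
  rows <- list()
  for (allele in c("ref", "alt")) {
    copies <- if (allele == "ref") ref_copies else alt_copies
    present <- copies > 0L
    n_groups_with <- colSums(present)
    for (l in which(n_groups_with == 1L)) {
      g <- which(present[, l])
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = colnames(x$calls)[l], allele = allele,
        group = groups[g], count = copies[g, l],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus_id = character(0), allele = character(0),
                      group = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ritland pairwise relatedness
#'
#' Moment estimator of pairwise relatedness. Per locus with reference-allele
#' frequency `q` and alternate frequency `p`, writing `S_xa` for half the
#' count of allele `a` in individual x's genotype, the per-locus estimate
#' for a biallelic locus is
#' `r_l = 2 * (S_x,ref S_y,ref / q + S_x,alt S_y,alt / p - 1) / (A - 1)`
#' with `A = 2` alleles. The multilocus estimate weights loci by `A - 1`
#' (i.e. an unweighted mean across biallelic loci), over loci typed in both
#' individuals; loci monomorphic in the frequency table are skipped. The
#' estimator can legitimately be negative.
#'
#' @param x A [genotype_matrix()].
#' @param freqs Named vector of alternate-allele frequencies per locus;
#'   defaults to frequencies estimated from `x` itself.
#' @param pairs Optional two-column matrix/data frame of sample id pairs to
#'   evaluate; defaults to all unordered pairs.
#' @return Data frame with `sample_a`, `sample_b`, `r`, `n_loci_used`
#'   (pairs sharing no typed loci get `r = NA`).
#' @export
ritland_relatedness <- function(x, freqs = NULL, pairs = NULL) {
  if (is.null(freqs)) freqs <- alt_freqs(x)
  p <- if (is.null(names(freqs))) {
    if (length(freqs) != ncol(x$calls)) {
      stop("unnamed `freqs` must have one entry per locus", call. = FALSE)
    }
    freqs
  } else {
    freqs[locus_ids(x)]
  }
  usable <- which(!is.na(p) & p > 0 & p < 1)
  g <- x$calls[, usable, drop = FALSE]
  p <- p[usable]
  q <- 1 - p
  n <- nrow(g)
  # S_ref = (2 - g)/2, S_alt = g/2; per-locus term
  # t_l = S_xr*S_yr/q + S_xa*S_ya/p; r over shared loci = (2/L) sum(t_l - 1)
  s_ref <- (2 - g) / 2
  s_alt <- g / 2
  A <- sweep(s_ref, 2, sqrt(q), "/"); A[is.na(A)] <- 0
  B <- sweep(s_alt, 2, sqrt(p), "/"); B[is.na(B)] <- 0
  Tm <- (!is.na(g)) * 1
  cross <- A %*% t(A) + B %*% t(B)
  shared <- Tm %*% t(Tm)
  r <- 2 * (cross - shared) / shared
  r[shared == 0] <- NA_real_
  if (is.null(pairs)) {
    idx <- which(upper.tri(r), arr.ind = TRUE)
    out <- data.frame(sample_a = rownames(g)[idx[, 1]],
                      sample_b = rownames(g)[idx[, 2]],
                      r = r[idx],
                      n_loci_used = as.integer(shared[idx]),
                      stringsAsFactors = FALSE)
  } else {
    pairs <- as.matrix(pairs)
    ia <- match(pairs[, 1], rownames(g))
    ib <- match(pairs[, 2], rownames(g))
    out <- data.frame(sample_a = pairs[, 1], sample_b = pairs[, 2],
                      r = r[cbind(ia, ib)],
                      n_loci_used = as.integer(shared[cbind(ia, ib)]),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Purge putative first-degree relatives
#'
#' Iterative elimination of highly related individuals within populations:
#' while any within-population pair exceeds the relatedness threshold, the
#' individual participating in the most above-threshold pairs is removed
#' (ties broken by lower genotyping rate, then lexicographic sample id).
#'
#' @param pairs Relatedness table from [ritland_relatedness()].
#' @param populations Named sample -> population labels; pairs whose members
#'   are in different populations are ignored. Use a single constant label
#'   to purge across the whole dataset.
#' @param threshold Relatedness cutoff (default 0.26, a typical minimum
#'   full-sib value).
#' @param genotyping_rate Optional named per-sample genotyping rates used in
#'   tie-breaking.
#' @return List with `retained` and `removed` character vectors of sample
#'   ids (retained covers every sample seen in `pairs`).
#' @export
purge_first_degree <- function(pairs, populations, threshold = 0.26,
                               genotyping_rate = NULL) {
  samples <- unique(c(pairs$sample_a, pairs$sample_b))
  pop <- populations[samples]
  same_pop <- !is.na(pop[pairs$sample_a]) &
    pop[pairs$sample_a] == pop[pairs$sample_b]
  hot <- pairs[same_pop & !is.na(pairs$r) & pairs$r > threshold, ,
               drop = FALSE]
  removed <- character(0)
  while (nrow(hot) > 0L) {
    counts <- table(c(hot$sample_a, hot$sample_b))
    top <- max(counts)
    cand <- sort(names(counts)[counts == top])
    if (length(cand) > 1L && !is.null(genotyping_rate)) {
      gr <- genotyping_rate[cand]
      cand <- cand[order(gr, cand)]
    }
    victim <- cand[1]
    removed <- c(removed, victim)
    hot <- hot[hot$sample_a != victim & hot$sample_b != victim, ,
               drop = FALSE]
  }
  list(retained = setdiff(samples, removed), removed = removed)
}

#' PCA on genotype dosages
#'
#' Principal components analysis of the individuals-by-loci dosage matrix
#' (codes 0/1/2, missing values imputed to the locus mean, columns
#' centred). Scores come from the singular value decomposition of the
#' centred matrix; each component is oriented so that its
#' largest-magnitude locus loading is positive, making signs reproducible.
#'
#' @param x A [genotype_matrix()] with at least 5 samples and 2 polymorphic
#'   loci.
#' @param n_components Number of components to return (default 4); if fewer
#'   are available, all are returned with a warning.
#' @return List of class `panel_pca` with `scores` (samples x components),
#'   `var_fraction`, and `loadings`.
#' @export
pca_dosage <- function(x, n_components = 4) {
  g <- x$calls
  if (nrow(g) < 5L) stop("PCA needs at least 5 samples", call. = FALSE)
  X <- apply(g, 2, function(col) {
    m <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- m
    col
  })
  keep <- apply(X, 2, stats::sd) > 0
  if (sum(keep) < 2L) stop("PCA needs at least 2 polymorphic loci",
                           call. = FALSE)
  X <- scale(X[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  sv <- svd(X)
  avail <- sum(sv$d > sv$d[1] * 1e-10)
  k <- min(n_components, avail)
  if (k < n_components) {
    warning("only ", k, " components available", call. = FALSE)
  }
  load <- sv$v[, seq_len(k), drop = FALSE]
  scores <- X %*% load
  # deterministic orientation
  for (j in seq_len(k)) {
    piv <- which.max(abs(load[, j]))
    if (load[piv, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(k)))
  dimnames(load) <- list(colnames(g)[keep], paste0("PC", seq_len(k)))
  ev <- sv$d^2
  structure(list(scores = scores,
                 var_fraction = (ev / sum(ev))[seq_len(k)],
                 loadings = load),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat(sprintf("panel_pca: %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$var_fraction), collapse = " "), "\n")
  invisible(x)
}
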