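# Technical-replicate concordance, negative controls, and the
# sample-then-locus filtering cascade.

.as_replicate_groups <- function(replicate_groups) {
  if (is.data.frame(replicate_groups)) {
    if (!all(c("sample_id", "group") %in% names(replicate_groups))) {
      stop("replicate table needs sample_id and group columns", call. = FALSE)
    }
    out <- replicate_groups$group
    names(out) <- replicate_groups$sample_id
    out
  } else {
    if (is.null(names(replicate_groups))) {
      stop("replicate_groups must be a named vector (sample -> group) or a ",
           "data frame", call. = FALSE)
    }
    replicate_groups
  }
}

#' Technical-replicate genotype concordance
#'
#' For each replicate pair, compares genotypes at loci typed in both members
#' and classifies discordant calls into the three unordered genotype-pair
#' categories (hom-alt vs het, hom-ref vs het, hom-ref vs hom-alt). Pairs
#' where either member has a genotyping rate below `min_gr` are excluded.
#' The summary is the unweighted mean and sd of per-pair concordance, not a
#' pooled count ratio.
#'
#' @param x A [genotype_matrix()].
#' @param replicate_groups Named character vector (sample id -> group) or a
#'   data frame with `sample_id`, `group`. Groups with fewer than two
#'   qualifying members are skipped with a warning.
#' @param min_gr Minimum per-sample genotyping rate for a pair to qualify.
#' @return A list with `pairs` (one row per replicate pair: counts per
#'   category and `concordance`), `mean` and `sd` of per-pair concordance,
#'   and pooled category totals in `totals`.
#' @export
replicate_concordance <- function(x, replicate_groups, min_gr = 0.5) {
  rg <- .as_replicate_groups(replicate_groups)
  rg <- rg[names(rg) %in% sample_ids(x)]
  gr <- genotyping_rate(x, "sample")
  rows <- list()
  for (grp in unique(rg)) {
    members <- names(rg)[rg == grp]
    members <- members[gr[members] >= min_gr]
    if (length(members) < 2L) {
      warning("replicate group ", sQuote(grp),
              " has fewer than 2 qualifying members; skipped", call. = FALSE)
      next
    }
    cmb <- utils::combn(sort(members), 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      ga <- x$calls[a, ]; gb <- x$calls[b, ]
      both <- !is.na(ga) & !is.na(gb)
      ga <- ga[both]; gb <- gb[both]
      lo <- pmin(ga, gb); hi <- pmax(ga, gb)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, sample_a = a, sample_b = b,
        n_both_typed = sum(both),
        n_concordant = sum(ga == gb),
        n_homalt_het = sum(lo == GT_HET & hi == GT_HOMALT),
        n_homref_het = sum(lo == GT_HOMREF & hi == GT_HET),
        n_homref_homalt = sum(lo == GT_HOMREF & hi == GT_HOMALT),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(list(pairs = NULL, mean = NA_real_, sd = NA_real_, totals = NULL))
  }
  pairs <- do.call(rbind, rows)
  pairs$concordance <- ifelse(pairs$n_both_typed > 0,
                              pairs$n_concordant / pairs$n_both_typed,
                              NA_real_)
  totals <- discordance_rates(
    n_homalt_het = sum(pairs$n_homalt_het),
    n_homref_het = sum(pairs$n_homref_het),
    n_homref_homalt = sum(pairs$n_homref_homalt),
    n_total = sum(pairs$n_both_typed))
  list(pairs = pairs,
       mean = mean(pairs$concordance, na.rm = TRUE),
       sd = stats::sd(pairs$concordance, na.rm = TRUE),
       totals = totals)
}

#' Discordance category percentages
#'
#' Bookkeeping over pooled replicate-pair genotype comparisons: percentage of
#' shared genotypes falling in each discordance class.
#'
#' @param n_homalt_het,n_homref_het,n_homref_homalt Counts of discordant
#'   genotype pairs per unordered category.
#' @param n_total Total number of genotypes typed in both members over all
#'   pairs.
#' @return Data frame with one row per category: count and percentage of
#'   `n_total`.
#' @export
discordance_rates <- function(n_homalt_het, n_homref_het, n_homref_homalt,
                              n_total) {
  counts <- c(homalt_het = n_homalt_het, homref_het = n_homref_het,
              homref_homalt = n_homref_homalt)
  data.frame(category = names(counts), count = as.integer(counts),
             percent = 100 * counts / n_total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Keep the best-genotyped member of each replicate group
#'
#' Retains, per replicate group, the sample with the most non-missing calls;
#' ties break to the lexicographically first sample id. Samples outside any
#' group pass through unchanged.
#'
#' @inheritParams replicate_concordance
#' @return A [genotype_matrix()] with redundant replicates removed.
#' @export
select_best_replicate <- function(x, replicate_groups) {
  rg <- .as_replicate_groups(replicate_groups)
  rg <- rg[names(rg) %in% sample_ids(x)]
  gr <- genotyping_rate(x, "sample")
  drop <- character(0)
  for (grp in unique(rg)) {
    members <- sort(names(rg)[rg == grp])
    if (length(members) < 2L) next
    best <- members[which.max(gr[members])]   # which.max: first on ties
    drop <- c(drop, setdiff(members, best))
  }
  keep <- setdiff(sample_ids(x), drop)
  x[keep, ]
}

.log_step <- function(log, step, dimension, removed, remaining) {
  rbind(log, data.frame(step = step, dimension = dimension,
                        removed = as.integer(removed),
                        remaining = as.integer(remaining),
                        stringsAsFactors = FALSE))
}

#' Missingness filtering (samples, then loci)
#'
#' Drops samples whose missing-call fraction is `>= max_missing` (computed
#' over all loci), then loci whose missing fraction is `>= max_missing`
#' computed over the retained samples. The keep rule is strictly
#' "less than `max_missing` missing", so a sample missing exactly 30% of
#' calls is removed at the default. The two-pass order matters and is
#' deliberately samples-first; `order = "loci_then_samples"` is available
#' for sensitivity checks.
#'
#' @param x A [genotype_matrix()].
#' @param max_missing Missingness threshold in `(0, 1)`.
#' @param order `"samples_then_loci"` (default) or `"loci_then_samples"`.
#' @return A list with `matrix` (the filtered [genotype_matrix()]) and
#'   `log` (a filter-log data frame: step, dimension, removed, remaining).
#' @export
filter_missingness <- function(x, max_missing = 0.30,
                               order = c("samples_then_loci",
                                         "loci_then_samples")) {
  order <- match.arg(order)
  stopifnot(max_missing > 0, max_missing < 1)
  log <- NULL
  drop_dim <- function(x, dimension) {
    miss <- if (dimension == "samples") rowMeans(is.na(x$calls))
            else colMeans(is.na(x$calls))
    keep <- miss < max_missing
    if (dimension == "samples") {
      if (!any(keep)) stop("all samples removed by missingness filter",
                           call. = FALSE)
      list(x = x[which(keep), ], removed = sum(!keep))
    } else {
      list(x = x[, which(keep)], removed = sum(!keep))
    }
  }
  dims <- if (order == "samples_then_loci") c("samples", "loci")
          else c("loci", "samples")
  for (d in dims) {
    res <- drop_dim(x, d)
    x <- res$x
    rem <- if (d == "samples") nrow(x$calls) else ncol(x$calls)
    log <- .log_step(log, paste0("missingness_", d), d, res$removed, rem)
  }
  list(matrix = x, log = log)
}

#' Remove monomorphic loci
#'
#' A locus is monomorphic when all non-missing calls carry a single allele
#' (all hom-ref or all hom-alt); any heterozygote makes it polymorphic.
#' Loci with no observed calls at all are treated as monomorphic and
#' removed.
#'
#' @param x A [genotype_matrix()].
#' @return A list with `matrix` and `log`, as in [filter_missingness()].
#' @export
drop_monomorphic <- function(x) {
  g <- x$calls
  n_ref <- colSums(g == GT_HOMREF, na.rm = TRUE)
  n_het <- colSums(g == GT_HET, na.rm = TRUE)
  n_alt <- colSums(g == GT_HOMALT, na.rm = TRUE)
  typed <- n_ref + n_het + n_alt
  poly <- n_het > 0L | (n_ref > 0L & n_alt > 0L)
  poly[typed == 0L] <- FALSE
  out <- x[, which(poly)]
  log <- .log_step(NULL, "monomorphic", "loci", sum(!poly), sum(poly))
  list(matrix = out, log = log)
}

#' Flag contaminated negative controls
#'
#' Negative-control wells with mean amplicon depth strictly greater than
#' `max_mean_depth` are flagged as potentially contaminated.
#'
#' @param depth_table Data frame with `sample_id` and `mean_depth` for the
#'   negative controls.
#' @param max_mean_depth Depth threshold (default 40x).
#' @return Character vector of flagged control ids (empty, with a warning,
#'   when no controls are present).
#' @export
negative_control_check <- function(depth_table, max_mean_depth = 40) {
  if (is.null(depth_table) || nrow(depth_table) == 0L) {
    warning("no negative controls present", call. = FALSE)
    return(character(0))
  }
  stopifnot(all(c("sample_id", "mean_depth") %in% names(depth_table)))
  depth_table$sample_id[depth_table$mean_depth > max_mean_depth]
}
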