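# Likelihood-ratio parentage assignment, strong-trio discovery, Mendelian
# incompatibility tallying, null-allele flagging, and evaluation against a
# pedigree.

#' Assign candidate parents by log-likelihood ratio
#'
#' Scores every (offspring, candidate) pair with the parent-offspring vs
#' unrelated log-likelihood ratio over loci typed in both, and retains all
#' pairs with `logl > cutoff`. The number of putative parents per offspring
#' is deliberately not capped at two; surplus assignments are informative
#' about sample handling and relatedness structure. Candidates should be the
#' genotyped parent-generation individuals (sex is not used).
#'
#' @param offspring,candidates [genotype_matrix()] objects over the same
#'   loci (loci are intersected by id).
#' @param freqs Named alternate-allele frequencies; defaults to frequencies
#'   estimated from the pooled offspring + candidate genotypes.
#' @param cutoff Retention cutoff on the natural-log likelihood-ratio
#'   scale (default 5). Use `-Inf` to keep all pairs.
#' @param epsilon Per-genotype miscall rate in the likelihood model
#'   (default 0.005; keeps Mendelian exclusions finite).
#' @return Data frame of class `assignment_records` with `offspring_id`,
#'   `candidate_parent_id`, `logl`, `n_shared_loci`, sorted by offspring
#'   then decreasing logl.
#' @export
assign_parents <- function(offspring, candidates, freqs = NULL, cutoff = 5,
                           epsilon = 0.005) {
  if (nrow(candidates$calls) == 0L) {
    stop("empty candidate parent set", call. = FALSE)
  }
  loci <- intersect(locus_ids(offspring), locus_ids(candidates))
  if (length(loci) == 0L) stop("no loci shared between matrices",
                               call. = FALSE)
  O <- offspring$calls[, loci, drop = FALSE]
  C <- candidates$calls[, loci, drop = FALSE]
  if (is.null(freqs)) {
    pooled <- rbind(O, C[setdiff(rownames(C), rownames(O)), , drop = FALSE])
    n_alt <- colSums(pooled == GT_HOMALT, na.rm = TRUE) * 2 +
      colSums(pooled == GT_HET, na.rm = TRUE)
    n_typ <- colSums(!is.na(pooled))
    freqs <- ifelse(n_typ > 0, n_alt / (2 * n_typ), NA_real_)
    names(freqs) <- loci
  } else {
    freqs <- freqs[loci]
  }
  arr <- .logl_table(freqs, epsilon)
  usable <- attr(arr, "usable")
  arr[!is.finite(arr)] <- .LOGL_IMPOSSIBLE
  O <- O[, usable, drop = FALSE]
  C <- C[, usable, drop = FALSE]
  L <- length(usable)
  no <- nrow(O); nc <- nrow(C)
  logl <- matrix(0, no, nc)
  for (go in 0:2) {
    Io <- (!is.na(O) & O == go) * 1
    for (gc in 0:2) {
      Ic <- (!is.na(C) & C == gc) * 1
      w <- arr[cbind(rep(go + 1L, L), rep(gc + 1L, L), seq_len(L))]
      logl <- logl + (Io %*% (w * t(Ic)))
    }
  }
  shared <- ((!is.na(O)) * 1) %*% t((!is.na(C)) * 1)
  keep <- which(logl > cutoff & shared >= 1, arr.ind = TRUE)
  out <- data.frame(offspring_id = rownames(O)[keep[, 1]],
                    candidate_parent_id = rownames(C)[keep[, 2]],
                    logl = logl[keep],
                    n_shared_loci = as.integer(shared[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$offspring_id, -out$logl), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assignment_records", "data.frame")
  out
}

#' Identify strongly supported trios
#'
#' An offspring forms a putative trio when exactly two candidates exceeded
#' the assignment cutoff (i.e. it has exactly two rows in `assignments`)
#' and both have `logl >= strong_cutoff`. Parent pairs supported by at
#' least `min_obs` such offspring are marked `confirmed`; only confirmed
#' trios should feed incompatibility tallying.
#'
#' @param assignments Output of [assign_parents()].
#' @param strong_cutoff Elevated per-parent logl requirement (default 10).
#' @param min_obs Minimum offspring per parent pair for confirmation
#'   (default 2).
#' @return Data frame with `offspring_id`, `parent_a`, `parent_b`,
#'   `logl_a`, `logl_b`, `confirmed`.
#' @export
identify_trios <- function(assignments, strong_cutoff = 10, min_obs = 2) {
  empty <- data.frame(offspring_id = character(0), parent_a = character(0),
                      parent_b = character(0), logl_a = numeric(0),
                      logl_b = numeric(0), confirmed = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(assignments) == 0L) return(empty)
  rows <- list()
  for (off in unique(assignments$offspring_id)) {
    sub <- assignments[assignments$offspring_id == off, , drop = FALSE]
    if (nrow(sub) != 2L) next                 # exactly two above the cutoff
    if (any(sub$logl < strong_cutoff)) next
    ord <- order(sub$candidate_parent_id)
    rows[[length(rows) + 1L]] <- data.frame(
      offspring_id = off,
      parent_a = sub$candidate_parent_id[ord[1]],
      parent_b = sub$candidate_parent_id[ord[2]],
      logl_a = sub$logl[ord[1]], logl_b = sub$logl[ord[2]],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  pair_key <- paste(out$parent_a, out$parent_b, sep = "\r")
  out$confirmed <- table(pair_key)[pair_key] >= min_obs
  out$confirmed <- as.logical(out$confirmed)
  rownames(out) <- NULL
  out
}

#' Mendelian compatibility of an offspring genotype with a parent pair
#'
#' TRUE when the offspring genotype can be formed from one allele of each
#' parent: e.g. hom-ref x hom-ref can only yield hom-ref; hom-ref x hom-alt
#' only het; het x het any genotype. Vectorised over triples. Genotypes
#' must be non-missing — handle missing calls by skipping the locus before
#' calling.
#'
#' @param dam_g,sire_g,off_g Integer genotype codes in `{0, 1, 2}`.
#' @return Logical vector.
#' @export
mendelian_compatible <- function(dam_g, sire_g, off_g) {
  n <- max(length(dam_g), length(sire_g), length(off_g))
  dam_g <- rep_len(as.integer(dam_g), n)
  sire_g <- rep_len(as.integer(sire_g), n)
  off_g <- rep_len(as.integer(off_g), n)
  if (anyNA(dam_g) || anyNA(sire_g) || anyNA(off_g)) {
    stop("genotypes must be non-missing; skip missing loci upstream",
         call. = FALSE)
  }
  # alleles transmissible by a parent with genotype g: ref iff g < 2,
  # alt iff g > 0
  dam_ref <- dam_g < 2L; dam_alt <- dam_g > 0L
  sire_ref <- sire_g < 2L; sire_alt <- sire_g > 0L
  ifelse(off_g == 0L, dam_ref & sire_ref,
  ifelse(off_g == 2L, dam_alt & sire_alt,
         (dam_ref & sire_alt) | (dam_alt & sire_ref)))
}

#' Tally Mendelian incompatibilities per locus over confirmed trios
#'
#' For each locus, counts the trio offspring whose genotype is impossible
#' given both assigned parents; loci with any missing member at a trio are
#' skipped for that trio (counted in neither numerator nor denominator).
#' Elevated counts at a locus are the pedigree-free signature of a null
#' allele (heterozygous carriers typed as spurious homozygotes).
#'
#' @param trios Output of [identify_trios()]; only rows with
#'   `confirmed == TRUE` are used.
#' @param x A [genotype_matrix()] containing the offspring and parents.
#' @return Data frame with `locus_id`, `n_incompatible`, `n_typed` (trio
#'   offspring typed, with both parents typed, at the locus).
#' @export
tally_incompatibilities <- function(trios, x) {
  trios <- trios[trios$confirmed, , drop = FALSE]
  L <- ncol(x$calls)
  n_bad <- n_typed <- integer(L)
  for (i in seq_len(nrow(trios))) {
    off <- x$calls[trios$offspring_id[i], ]
    dam <- x$calls[trios$parent_a[i], ]
    sire <- x$calls[trios$parent_b[i], ]
    ok <- !is.na(off) & !is.na(dam) & !is.na(sire)
    n_typed[ok] <- n_typed[ok] + 1L
    if (any(ok)) {
      bad <- !mendelian_compatible(dam[ok], sire[ok], off[ok])
      n_bad[which(ok)[bad]] <- n_bad[which(ok)[bad]] + 1L
    }
  }
  data.frame(locus_id = colnames(x$calls),
             n_incompatible = n_bad, n_typed = n_typed,
             stringsAsFactors = FALSE)
}

#' Flag putative null-allele loci from the incompatibility tally
#'
#' Loci with at least `min_count` incompatible trio offspring are flagged
#' for removal; a secondary watch list at `watch_count` (default 2) is also
#' reported for reference.
#'
#' @param tally Output of [tally_incompatibilities()].
#' @param min_count Flagging threshold (default 4, i.e. "at least four").
#' @param watch_count Secondary reporting threshold (default 2).
#' @return List with `flagged` and `watch` character vectors of locus ids.
#' @export
flag_null_loci <- function(tally, min_count = 4, watch_count = 2) {
  list(flagged = tally$locus_id[tally$n_incompatible >= min_count],
       watch = tally$locus_id[tally$n_incompatible >= watch_count])
}

#' Assignment completeness and false-positive percentages
#'
#' The bookkeeping used to score a parentage run against pedigree truth:
#' completeness is `100 * n_correct / n_possible` where `n_possible` counts,
#' over offspring, their genotyped true parents (assignment "slots"); the
#' false-positive percentage is `100 * n_fp / (n_correct + n_fp)`, i.e. the
#' share of all assignment calls made that are wrong.
#'
#' @param n_correct Correct assignments made (offspring to true parent).
#' @param n_possible Total possible assignments.
#' @param n_fp Assignments made to non-parents.
#' @return List with `n_assigned_correct`, `n_possible`, `pct_complete`,
#'   `n_fp`, `pct_fp`, `n_assigned_total`.
#' @export
assignment_metrics <- function(n_correct, n_possible, n_fp) {
  total <- n_correct + n_fp
  list(n_assigned_correct = n_correct,
       n_possible = n_possible,
       pct_complete = 100 * n_correct / n_possible,
       n_fp = n_fp,
       pct_fp = if (total > 0) 100 * n_fp / total else 0,
       n_assigned_total = total)
}

#' Pedigree table constructor
#'
#' @param offspring_id,dam_id,sire_id Character vectors defining the true
#'   pedigree (one row per offspring; `NA` for an unknown parent).
#' @return Data frame with the three columns.
#' @export
pedigree_table <- function(offspring_id, dam_id, sire_id) {
  if (anyDuplicated(offspring_id)) {
    stop("duplicate offspring in pedigree", call. = FALSE)
  }
  data.frame(offspring_id = offspring_id, dam_id = dam_id,
             sire_id = sire_id, stringsAsFactors = FALSE)
}

#' Re-run parentage on a filtered locus set and evaluate against a pedigree
#'
#' Removes the flagged loci, re-assigns parents, and scores the run:
#' `n_possible` is the number of (offspring, true parent) slots where the
#' parent is genotyped and retained; an assignment is correct when the
#' candidate is a true parent of the offspring, otherwise a false positive.
#' Percentages follow [assignment_metrics()]. A per-family table mirrors
#' the usual reporting layout (two-parent/one-parent assignments, percent
#' identified, incorrect assignments), and a discrepancy report lists
#' offspring whose assignments contradict the declared pedigree rather than
#' auto-correcting them.
#'
#' @param offspring,candidates [genotype_matrix()] objects (candidates =
#'   genotyped parent-generation individuals).
#' @param pedigree A [pedigree_table()]; parents referenced but absent from
#'   `candidates` are treated as ungenotyped (they reduce `n_possible`),
#'   but offspring absent from `offspring` raise an integrity error.
#' @param flagged_loci Locus ids to remove before re-assignment (e.g. from
#'   [flag_null_loci()]).
#' @param cutoff,epsilon Passed to [assign_parents()].
#' @param freqs Optional frequency table passed to [assign_parents()].
#' @return List with `metrics` (see [assignment_metrics()]), `per_family`,
#'   `assignments`, `discrepancies`.
#' @export
rerun_and_evaluate <- function(offspring, candidates, pedigree,
                               flagged_loci = character(0), cutoff = 5,
                               epsilon = 0.005, freqs = NULL) {
  missing_off <- setdiff(pedigree$offspring_id, sample_ids(offspring))
  if (length(missing_off)) {
    stop("pedigree references offspring absent from the genotype data: ",
         paste(utils::head(missing_off, 5), collapse = ", "), call. = FALSE)
  }
  keep_loci <- setdiff(locus_ids(offspring), flagged_loci)
  off_f <- offspring[, keep_loci]
  cand_f <- candidates[, intersect(locus_ids(candidates), keep_loci)]
  asg <- assign_parents(off_f, cand_f, freqs = freqs, cutoff = cutoff,
                        epsilon = epsilon)

  genotyped <- sample_ids(candidates)
  ped <- pedigree
  true_parents <- function(off) {
    p <- c(ped$dam_id[ped$offspring_id == off],
           ped$sire_id[ped$offspring_id == off])
    p[!is.na(p)]
  }
  n_possible <- 0L; n_correct <- 0L; n_fp <- 0L
  fam_rows <- list(); disc <- list()
  ped$family <- paste(ped$dam_id, ped$sire_id, sep = " x ")
  for (fam in unique(ped$family)) {
    offs <- ped$offspring_id[ped$family == fam]
    offs <- intersect(offs, sample_ids(off_f))
    if (length(offs) == 0L) next
    fam_correct <- 0L; fam_fp <- 0L; fam_possible <- 0L
    n_two <- 0L; n_one <- 0L
    for (off in offs) {
      tp <- intersect(true_parents(off), genotyped)
      fam_possible <- fam_possible + length(tp)
      hits <- asg$candidate_parent_id[asg$offspring_id == off]
      good <- intersect(hits, tp)
      bad <- setdiff(hits, tp)
      fam_correct <- fam_correct + length(good)
      fam_fp <- fam_fp + length(bad)
      if (length(good) >= 2L) n_two <- n_two + 1L
      else if (length(good) == 1L) n_one <- n_one + 1L
      if (length(bad)) {
        disc[[length(disc) + 1L]] <- data.frame(
          offspring_id = off, expected_family = fam,
          unexpected_parent = bad,
          logl = asg$logl[asg$offspring_id == off &
                            asg$candidate_parent_id %in% bad],
          stringsAsFactors = FALSE)
      }
    }
    n_possible <- n_possible + fam_possible
    n_correct <- n_correct + fam_correct
    n_fp <- n_fp + fam_fp
    fam_rows[[length(fam_rows) + 1L]] <- data.frame(
      family = fam, n_offspring = length(offs),
      n_two_parent = n_two, n_one_parent = n_one,
      n_possible = fam_possible, n_correct = fam_correct,
      pct_id = if (fam_possible > 0) 100 * fam_correct / fam_possible
               else NA_real_,
      n_incorrect = fam_fp, stringsAsFactors = FALSE)
  }
  per_family <- do.call(rbind, fam_rows)
  rownames(per_family) <- NULL
  list(metrics = assignment_metrics(n_correct, n_possible, n_fp),
       per_family = per_family,
       assignments = asg,
       discrepancies = if (length(disc)) do.call(rbind, disc) else NULL)
}

#' Export the assignment network as an edge list
#'
#' Writes a TSV of offspring-parent edges with logl weights, one row per
#' retained assignment (all putative linkages, including more than two per
#' offspring), for plotting with any graph tool.
#'
#' @param assignments Output of [assign_parents()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_assignment_network <- function(assignments, path) {
  edges <- data.frame(from = assignments$offspring_id,
                      to = assignments$candidate_parent_id,
                      weight = assignments$logl,
                      stringsAsFactors = FALSE)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
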