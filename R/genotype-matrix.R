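# Genotype codes used throughout the package:
#   0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#   NA = missing (no call). Loci are biallelic SNPs.

GT_HOMREF <- 0L
GT_HET <- 1L
GT_HOMALT <- 2L

#' Construct a genotype matrix
#'
#' The central container of the package: an individuals-by-loci matrix of
#' biallelic genotype codes with per-sample population (and optionally
#' generation) labels. Codes are `0` (homozygous reference), `1`
#' (heterozygous), `2` (homozygous alternate) and `NA` (missing).
#'
#' @param calls Integer (or numeric coercible) matrix with unique rownames
#'   (sample ids) and unique colnames (locus ids); values in `{0, 1, 2, NA}`.
#' @param population Population/collection label per sample: either a single
#'   value recycled to all samples, an unnamed vector of length `nrow(calls)`,
#'   or a vector named by sample id. Defaults to `"pop1"`.
#' @param generation Optional generation label per sample, same conventions
#'   as `population`.
#' @param loci Optional data frame of per-locus metadata (see
#'   [locus_records()]); matched to columns by `locus_id`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `population`, `generation`, `loci`.
#' @examples
#' m <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("L1", "L2")))
#' g <- genotype_matrix(m, population = "wild")
#' g
#' @export
genotype_matrix <- function(calls, population = NULL, generation = NULL,
                            loci = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix", call. = FALSE)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% c(0L, 1L, 2L))
  if (any(bad)) {
    stop("genotype codes must be 0, 1, 2 or NA; found: ",
         paste(unique(calls[bad]), collapse = ", "), call. = FALSE)
  }
  sn <- rownames(calls)
  ln <- colnames(calls)
  if (is.null(sn) && nrow(calls) == 0L) sn <- character(0)
  if (is.null(ln) && ncol(calls) == 0L) ln <- character(0)
  if (is.null(sn) || is.null(ln)) {
    stop("`calls` must have rownames (samples) and colnames (loci)",
         call. = FALSE)
  }
  dimnames(calls) <- list(sn, ln)
  if (anyDuplicated(sn)) stop("duplicate sample ids", call. = FALSE)
  if (anyDuplicated(ln)) stop("duplicate locus ids", call. = FALSE)

  population <- .match_sample_labels(population, sn, "pop1")
  generation <- if (is.null(generation)) NULL else
    .match_sample_labels(generation, sn, NA_character_)
  if (!is.null(loci)) {
    if (!"locus_id" %in% names(loci)) {
      stop("`loci` must contain a locus_id column", call. = FALSE)
    }
    loci <- loci[match(ln, loci$locus_id), , drop = FALSE]
    rownames(loci) <- NULL
  }
  structure(list(calls = calls, population = population,
                 generation = generation, loci = loci),
            class = "genotype_matrix")
}

.match_sample_labels <- function(x, sample_ids, default) {
  n <- length(sample_ids)
  if (is.null(x)) x <- default
  x <- stats::setNames(as.character(x), names(x))
  if (!is.null(names(x))) {
    out <- unname(x[sample_ids])
    if (anyNA(out) && !anyNA(x)) {
      stop("labels missing for samples: ",
           paste(utils::head(sample_ids[is.na(out)], 5), collapse = ", "),
           call. = FALSE)
    }
  } else if (length(x) == 1L) {
    out <- rep(x, n)
  } else if (length(x) == n) {
    out <- x
  } else {
    stop("label vector must be length 1, length n_samples, or named",
         call. = FALSE)
  }
  names(out) <- sample_ids
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  populations: %s\n",
              paste(names(table(x$population)), collapse = ", ")))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param i,j Sample and locus indices (ids, logical or integer).
#' @param ... Unused.
#' @return A `genotype_matrix` restricted to the requested samples/loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  calls <- x$calls[i, j, drop = FALSE]
  genotype_matrix(calls,
                  population = x$population[rownames(calls)],
                  generation = if (is.null(x$generation)) NULL
                               else x$generation[rownames(calls)],
                  loci = x$loci)
}

#' Sample and locus identifiers
#' @param x A [genotype_matrix()].
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$calls)

#' @rdname sample_ids
#' @export
locus_ids <- function(x) colnames(x$calls)

#' Genotyping rate per sample or locus
#'
#' Fraction of non-missing calls along the requested dimension.
#'
#' @param x A [genotype_matrix()].
#' @param by `"sample"` or `"locus"`.
#' @return Named numeric vector of rates in `[0, 1]`.
#' @export
genotyping_rate <- function(x, by = c("sample", "locus")) {
  by <- match.arg(by)
  if (by == "sample") 1 - rowMeans(is.na(x$calls))
  else 1 - colMeans(is.na(x$calls))
}

#' Per-locus target metadata records
#'
#' Builds the per-locus metadata table used for hotspot parsing, panel design
#' and mapping summaries. Locus ids default to `<contig>_<position>`.
#'
#' @param contig Contig/chromosome name per locus.
#' @param position 1-based variant position.
#' @param ref_allele,alt_allele Single bases in `A/C/G/T`; must differ.
#' @param locus_id Optional explicit ids.
#' @param selection_reason One of `high_hobs`, `high_fst`, `private_allele`,
#'   `none` per locus.
#' @param mapping_category One of `single`, `multi`, `non_chromosome`,
#'   `unmapped`, `unknown` per locus.
#' @return A data frame with one row per locus.
#' @export
locus_records <- function(contig, position, ref_allele, alt_allele,
                          locus_id = NULL, selection_reason = "none",
                          mapping_category = "unknown") {
  position <- as.integer(position)
  if (any(position < 1L)) stop("positions must be >= 1", call. = FALSE)
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  ok <- function(a) all(a %in% c("A", "C", "G", "T"))
  if (!ok(ref_allele) || !ok(alt_allele)) {
    stop("alleles must be single bases A/C/G/T", call. = FALSE)
  }
  if (any(ref_allele == alt_allele)) {
    stop("ref_allele must differ from alt_allele", call. = FALSE)
  }
  if (is.null(locus_id)) locus_id <- paste(contig, position, sep = "_")
  reasons <- c("high_hobs", "high_fst", "private_allele", "none")
  cats <- c("single", "multi", "non_chromosome", "unmapped", "unknown")
  selection_reason <- rep_len(selection_reason, length(locus_id))
  mapping_category <- rep_len(mapping_category, length(locus_id))
  if (!all(selection_reason %in% reasons)) {
    stop("invalid selection_reason", call. = FALSE)
  }
  if (!all(mapping_category %in% cats)) {
    stop("invalid mapping_category", call. = FALSE)
  }
  data.frame(locus_id = locus_id, contig = contig, position = position,
             ref_allele = ref_allele, alt_allele = alt_allele,
             selection_reason = selection_reason,
             mapping_category = mapping_category,
             stringsAsFactors = FALSE)
}

#' Sample annotation table
#'
#' Validates a sample annotation table (collection, sample type, generation,
#' replicate group, negative-control flag) of the kind that accompanies a
#' genotyping run.
#'
#' @param x A data frame with at least `sample_id` and `collection` columns;
#'   optional `type` (`wild`, `naturalized`, `farm`, `hatchery`),
#'   `generation`, `replicate_group`, `is_negative_control`.
#' @return The validated data frame.
#' @export
sample_annotations <- function(x) {
  need <- c("sample_id", "collection")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("annotation table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id in annotations", call. = FALSE)
  }
  if ("type" %in% names(x)) {
    ok <- c("wild", "naturalized", "farm", "hatchery")
    if (!all(is.na(x$type) | x$type %in% ok)) {
      stop("sample type must be one of: ", paste(ok, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!"is_negative_control" %in% names(x)) x$is_negative_control <- FALSE
  x
}
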