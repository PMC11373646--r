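# Marker selection for panel design, flank-window extraction from a
# reference FASTA, and mapping-category bookkeeping.

#' Select panel markers from per-locus statistics
#'
#' Implements the two-ranking selection used to design SNP panels: loci with
#' observed heterozygosity above `hobs_cap` are dropped (a guard against
#' collapsed duplicated regions), then the top `n_hobs` loci by `h_obs` and
#' the top `n_fst` by `fst` are taken (ties broken by locus id), unioned
#' with any manually requested `extra_loci` (e.g. private-allele markers).
#' Each selected locus is labelled with every reason that applies.
#'
#' @param stats Data frame with columns `locus_id`, `h_obs`, `fst`.
#' @param n_hobs,n_fst Sizes of the two ranked lists (defaults 300/300).
#' @param hobs_cap Exclude loci with `h_obs > hobs_cap` from the
#'   heterozygosity ranking and candidate pool (default 0.5).
#' @param extra_loci Locus ids to add unconditionally (labelled
#'   `private_allele`).
#' @return Data frame with `locus_id` and `reason` (comma-joined labels),
#'   with attributes `overlap` (loci in both rankings) and `n_selected`.
#' @export
select_markers <- function(stats, n_hobs = 300, n_fst = 300, hobs_cap = 0.5,
                           extra_loci = character(0)) {
  cand <- stats[!is.na(stats$h_obs) & stats$h_obs <= hobs_cap, , drop = FALSE]
  top_by <- function(df, col, n) {
    df <- df[!is.na(df[[col]]), , drop = FALSE]
    ord <- order(-df[[col]], df$locus_id)
    n_take <- min(n, nrow(df))
    if (n_take < n) {
      warning("only ", n_take, " candidates available for ", col, " ranking",
              call. = FALSE)
    }
    df$locus_id[ord[seq_len(n_take)]]
  }
  top_hobs <- top_by(cand, "h_obs", n_hobs)
  top_fst <- top_by(cand, "fst", n_fst)
  overlap <- intersect(top_hobs, top_fst)
  all_ids <- unique(c(top_hobs, top_fst, extra_loci))
  reason <- vapply(all_ids, function(id) {
    r <- c(if (id %in% top_hobs) "high_hobs",
           if (id %in% top_fst) "high_fst",
           if (id %in% extra_loci) "private_allele")
    paste(r, collapse = ",")
  }, character(1))
  out <- data.frame(locus_id = all_ids, reason = unname(reason),
                    stringsAsFactors = FALSE)
  attr(out, "overlap") <- length(overlap)
  attr(out, "n_selected") <- nrow(out)
  out
}

#' Extract flanking windows around target SNPs
#'
#' For each target, extracts `reference[pos - flank .. pos + flank]`
#' (1-based, inclusive), a window of `2 * flank + 1` bp centred on the
#' variant — the amplicon design window. Targets whose contig is absent or
#' whose flanks run off the contig are skipped and reported, not padded.
#'
#' @param reference Path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param targets A [locus_records()] data frame.
#' @param flank Flank length on each side (default 200, i.e. 401-bp
#'   windows).
#' @return List with `windows` (data frame: `locus_id`, `contig`,
#'   `variant_position`, `window_start`, `window_end`, `variant_offset`
#'   (1-based index of the variant within the window), `ref_allele`,
#'   `alt_allele`, `sequence`, `ref_matches`) and `skipped` (data frame:
#'   `locus_id`, `reason`).
#' @export
extract_flanks <- function(reference, targets, flank = 200) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  contig_len <- stats::setNames(Biostrings::width(reference),
                                names(reference))
  win <- list(); skip <- list()
  for (i in seq_len(nrow(targets))) {
    t <- targets[i, ]
    if (!t$contig %in% names(reference)) {
      skip[[length(skip) + 1L]] <- data.frame(locus_id = t$locus_id,
                                              reason = "contig_absent")
      next
    }
    len <- contig_len[[t$contig]]
    if (t$position > len) {
      skip[[length(skip) + 1L]] <- data.frame(locus_id = t$locus_id,
                                              reason = "position_beyond_contig")
      next
    }
    start <- t$position - flank
    end <- t$position + flank
    if (start < 1L || end > len) {
      skip[[length(skip) + 1L]] <- data.frame(locus_id = t$locus_id,
                                              reason = "insufficient_flank")
      next
    }
    seq <- as.character(Biostrings::subseq(reference[[t$contig]], start, end))
    win[[length(win) + 1L]] <- data.frame(
      locus_id = t$locus_id, contig = t$contig,
      variant_position = t$position,
      window_start = start, window_end = end,
      variant_offset = flank + 1L,
      ref_allele = t$ref_allele, alt_allele = t$alt_allele,
      sequence = seq,
      ref_matches = substr(seq, flank + 1L, flank + 1L) == t$ref_allele,
      stringsAsFactors = FALSE)
  }
  empty_skip <- data.frame(locus_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  list(windows = if (length(win)) do.call(rbind, win) else NULL,
       skipped = if (length(skip)) do.call(rbind, skip) else empty_skip)
}

#' Write target windows as FASTA and BED
#'
#' Exports extracted windows; the BED uses 0-based half-open coordinates
#' converted from the package's 1-based inclusive internals.
#'
#' @param windows The `windows` element of [extract_flanks()].
#' @param fasta_path,bed_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the window table.
#' @export
write_target_windows <- function(windows, fasta_path = NULL,
                                 bed_path = NULL) {
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(windows$sequence)
    names(seqs) <- windows$locus_id
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = windows$contig,
                      start = windows$window_start - 1L,   # 0-based half-open
                      end = windows$window_end,
                      name = windows$locus_id)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(windows)
}

#' Summarise alignment mapping categories
#'
#' Tallies externally assigned mapping categories for the design sequences
#' and, for single mappers, the per-chromosome counts with mean, sd and
#' range — the usual panel-coverage summary.
#'
#' @param mapping_category Character vector with values in `single`,
#'   `multi`, `non_chromosome`, `unmapped`, `unknown`.
#' @param chromosome Chromosome label per target (used for single mappers;
#'   may be `NA` for non-single categories).
#' @param chromosomes Optional character vector of all chromosomes in the
#'   assembly; chromosomes with zero single mappers then enter the mean/sd.
#' @return List with `category_counts` (named integer vector),
#'   `per_chromosome` (data frame `chromosome`, `n_single`), `mean`, `sd`,
#'   `range`.
#' @export
mapping_summary <- function(mapping_category, chromosome = NULL,
                            chromosomes = NULL) {
  cats <- c("single", "multi", "non_chromosome", "unmapped")
  bad <- setdiff(unique(mapping_category), c(cats, "unknown"))
  if (length(bad)) {
    stop("unknown mapping category label(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  counts <- vapply(cats, function(k) sum(mapping_category == k), integer(1))
  per_chr <- NULL; m <- s <- NA_real_; rng <- c(NA_real_, NA_real_)
  if (!is.null(chromosome)) {
    chr_single <- chromosome[mapping_category == "single"]
    if (is.null(chromosomes)) chromosomes <- sort(unique(chr_single))
    n_single <- vapply(chromosomes, function(ch) sum(chr_single == ch),
                       integer(1))
    per_chr <- data.frame(chromosome = chromosomes,
                          n_single = as.integer(n_single),
                          stringsAsFactors = FALSE)
    m <- mean(n_single); s <- stats::sd(n_single)
    rng <- range(n_single)
  }
  list(category_counts = counts, per_chromosome = per_chr,
       mean = m, sd = s, range = rng)
}
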