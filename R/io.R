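# On-disk formats: hotspot variant-caller long tables, two-digit genepop,
# exclusion lists, annotation TSVs.

.HOTSPOT_COLS <- c(sample = "sample name", chrom = "chrom",
                   position = "position", ref = "ref", variant = "variant",
                   call = "allele call", source = "allele source")

#' Parse a hotspot variant-caller genotype table
#'
#' Reads the long-format genotype export of amplicon hotspot genotyping
#' (one row per sample x target) and converts it to a [genotype_matrix()].
#' Allele-call categories map to codes as: `"Absent"` (variant absent, i.e.
#' homozygous reference) -> 0, `"Heterozygous"` -> 1, `"Homozygous"`
#' (homozygous variant) -> 2, `"No Call"` -> NA. Note the `"Absent"`
#' convention: the caller reports the variant allele as absent, which this
#' package interprets as a homozygous *reference* genotype.
#'
#' Columns are matched case-insensitively by canonical names
#' (`Sample Name`, `Chrom`, `Position`, `Ref`, `Variant`, `Allele Call`,
#' `Allele Source`); extra columns are ignored. Rows whose allele source is
#' not `hotspot_label` are dropped (de novo calls outside the panel).
#'
#' @param path Path to a TSV/CSV table (delimiter auto-detected from the
#'   header line).
#' @param target_loci Optional [locus_records()] table; when given, only
#'   targets present in it (joined on contig + position) are kept and its
#'   locus ids are used. Otherwise locus ids are `<contig>_<position>`.
#' @param hotspot_label Allele-source value marking panel targets
#'   (default `"Hotspot"`, matched case-insensitively).
#' @return A [genotype_matrix()] with a `loci` metadata table.
#' @export
parse_hotspot_table <- function(path, target_loci = NULL,
                                hotspot_label = "Hotspot") {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  lc <- tolower(trimws(names(tab)))
  idx <- match(.HOTSPOT_COLS, lc)
  if (anyNA(idx)) {
    missing_cols <- .HOTSPOT_COLS[is.na(idx)]
    stop("hotspot table is missing required column(s): ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  }
  names(idx) <- names(.HOTSPOT_COLS)
  d <- data.frame(sample = as.character(tab[[idx["sample"]]]),
                  chrom = as.character(tab[[idx["chrom"]]]),
                  position = as.integer(tab[[idx["position"]]]),
                  ref = toupper(as.character(tab[[idx["ref"]]])),
                  variant = toupper(as.character(tab[[idx["variant"]]])),
                  call = as.character(tab[[idx["call"]]]),
                  source = as.character(tab[[idx["source"]]]),
                  stringsAsFactors = FALSE)
  d <- d[tolower(d$source) == tolower(hotspot_label), , drop = FALSE]
  if (nrow(d) == 0L) stop("no hotspot rows found in ", path, call. = FALSE)

  code_map <- c("absent" = 0L, "heterozygous" = 1L, "homozygous" = 2L,
                "no call" = NA_integer_)
  key <- tolower(trimws(d$call))
  unknown <- setdiff(unique(key), names(code_map))
  if (length(unknown)) {
    stop("unknown allele-call categories: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  d$code <- unname(code_map[key])
  d$locus <- paste(d$chrom, d$position, sep = "_")

  if (!is.null(target_loci)) {
    tkey <- paste(target_loci$contig, target_loci$position, sep = "_")
    keep <- d$locus %in% tkey
    d <- d[keep, , drop = FALSE]
    if (nrow(d) == 0L) stop("no rows match target_loci", call. = FALSE)
    d$locus <- target_loci$locus_id[match(d$locus, tkey)]
  }

  # conflicting duplicate (sample, locus) rows are an integrity error;
  # exact duplicates collapse silently
  pair <- paste(d$sample, d$locus, sep = "\r")
  dup <- duplicated(pair) | duplicated(pair, fromLast = TRUE)
  if (any(dup)) {
    conf <- vapply(split(d$code[dup], pair[dup]),
                   function(z) length(unique(z)) > 1L, logical(1))
    if (any(conf)) {
      offenders <- sub("\r", " / ", names(conf)[conf])
      stop("conflicting duplicate genotype rows for: ",
           paste(utils::head(offenders, 10), collapse = "; "), call. = FALSE)
    }
    d <- d[!duplicated(pair), , drop = FALSE]
  }

  samples <- unique(d$sample)
  loci <- if (is.null(target_loci)) unique(d$locus) else
    intersect(target_loci$locus_id, unique(d$locus))
  calls <- matrix(NA_integer_, length(samples), length(loci),
                  dimnames = list(samples, loci))
  calls[cbind(match(d$sample, samples), match(d$locus, loci))] <- d$code

  if (is.null(target_loci)) {
    li <- match(loci, d$locus)
    meta <- locus_records(contig = d$chrom[li], position = d$position[li],
                          ref_allele = d$ref[li], alt_allele = d$variant[li],
                          locus_id = loci)
  } else {
    meta <- target_loci[match(loci, target_loci$locus_id), , drop = FALSE]
  }
  genotype_matrix(calls, loci = meta)
}

#' Write a genotype matrix as a two-digit genepop file
#'
#' Emits the classic genepop dialect: a title line, one locus name per line,
#' `Pop` separators between collections (in order of first appearance), and
#' per-sample lines `id ,  0101 0102 ...`. Allele 01 is the reference allele
#' and 02 the alternate, so codes are `0101` (hom ref), `0102` (het),
#' `0202` (hom alt), `0000` (missing).
#'
#' @param x A non-empty [genotype_matrix()].
#' @param path Output file path.
#' @param title Title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "ampliparent genepop export") {
  if (!inherits(x, "genotype_matrix")) stop("`x` must be a genotype_matrix",
                                            call. = FALSE)
  if (nrow(x$calls) == 0L || ncol(x$calls) == 0L) {
    stop("cannot write an empty genotype matrix", call. = FALSE)
  }
  code <- c("0101", "0102", "0202")
  enc <- matrix("0000", nrow(x$calls), ncol(x$calls))
  ok <- !is.na(x$calls)
  enc[ok] <- code[x$calls[ok] + 1L]
  lines <- c(title, colnames(x$calls))
  for (pop in unique(x$population)) {
    lines <- c(lines, "Pop")
    rows <- which(x$population == pop)
    lines <- c(lines, vapply(rows, function(i) {
      paste0(rownames(x$calls)[i], " ,  ",
             paste(enc[i, ], collapse = " "))
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-digit genepop file
#'
#' Inverse of [write_genepop()] for the two-digit biallelic dialect. Allele
#' order within a genotype is normalised (`0201` is the same heterozygote as
#' `0102`). Population labels are taken as `pop1`, `pop2`, ... in file order
#' unless `pop_names` is supplied.
#'
#' @param path Path to a genepop file.
#' @param pop_names Optional character vector of population labels.
#' @return A [genotype_matrix()].
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("not a genepop file: ", path, call. = FALSE)
  is_pop <- tolower(trimws(lines)) == "pop"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L) {
    stop("no locus block / Pop separator found", call. = FALSE)
  }
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  # loci may be one per line or comma-separated on one line
  loci <- unlist(strsplit(locus_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]

  body <- lines[first_pop:length(lines)]
  pop_idx <- cumsum(tolower(trimws(body)) == "pop")
  sample_lines <- body[tolower(trimws(body)) != "pop"]
  sample_pop <- pop_idx[tolower(trimws(body)) != "pop"]
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(max(sample_pop)))

  n <- length(sample_lines)
  calls <- matrix(NA_integer_, n, length(loci))
  ids <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(sample_lines[i], ",")[[1]]
    if (length(parts) < 2L) {
      stop("malformed genepop sample line: ", sample_lines[i], call. = FALSE)
    }
    ids[i] <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    if (length(gts) != length(loci)) {
      stop("sample ", ids[i], " has ", length(gts), " genotypes, expected ",
           length(loci), call. = FALSE)
    }
    if (any(nchar(gts) != 4L)) {
      stop("unsupported genepop dialect: expected 4-character two-digit ",
           "genotypes, got e.g. ", sQuote(gts[nchar(gts) != 4L][1]),
           call. = FALSE)
    }
    a1 <- as.integer(substr(gts, 1, 2))
    a2 <- as.integer(substr(gts, 3, 4))
    if (any(a1 > 2L | a2 > 2L, na.rm = TRUE)) {
      stop("unsupported genepop dialect: more than two alleles at a locus",
           call. = FALSE)
    }
    g <- ifelse(a1 == 0L | a2 == 0L, NA_integer_, a1 + a2 - 2L)
    calls[i, ] <- g
  }
  if (anyDuplicated(ids)) stop("duplicate sample ids in genepop file",
                               call. = FALSE)
  dimnames(calls) <- list(ids, loci)
  genotype_matrix(calls, population = pop_names[sample_pop])
}

#' Load a locus exclusion list
#'
#' Reads loci to drop (e.g. multi-mapping amplicons determined by an external
#' alignment step). Accepts either a plain list of locus ids (one per line)
#' or a TSV with `locus_id` and `mapping_category` columns, in which case
#' loci with category `multi` are returned.
#'
#' @param path Path to the list.
#' @param known_loci Optional character vector; ids in the file but not in
#'   `known_loci` trigger a warning with a count (they are still returned).
#' @return Character vector of locus ids to exclude.
#' @export
load_exclusion_list <- function(path, known_loci = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(character(0))
  if (grepl("\t", lines[1])) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (!all(c("locus_id", "mapping_category") %in% names(tab))) {
      stop("TSV exclusion list needs locus_id and mapping_category columns",
           call. = FALSE)
    }
    out <- unique(tab$locus_id[tab$mapping_category == "multi"])
  } else {
    out <- unique(trimws(lines))
  }
  if (!is.null(known_loci)) {
    n_unknown <- sum(!out %in% known_loci)
    if (n_unknown > 0L) {
      warning(n_unknown, " excluded locus id(s) not present in the dataset",
              call. = FALSE)
    }
  }
  out
}

#' Read a sample annotation TSV
#'
#' @param path TSV with a header including `sample_id` and `collection`
#'   (see [sample_annotations()]).
#' @return Validated annotation data frame.
#' @export
read_sample_annotations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  sample_annotations(tab)
}
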