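# Pedigree simulator with known truth: Balding-Nichols multi-population
# allele frequencies, HWE founders, full-sib families, hidden null alleles
# carried on founder haplotypes, per-genotype miscall error, missingness,
# and technical replicates. Everything downstream is testable against the
# returned truth bundle.

#' Simulation specification
#'
#' Defines one synthetic dataset. Defaults emulate a single-hatchery
#' breeding-program test: 300 biallelic loci with ancestral alternate-allele
#' frequencies uniform on (0.1, 0.5), 18 founder parents crossed into 15
#' full-sib families of 7 offspring, per-genotype miscall rate 0.005, 5%
#' missing calls, 10% of loci carrying a hidden null allele at frequency
#' 0.25 among founder haplotypes.
#'
#' @param n_loci Number of loci.
#' @param freq_range Uniform range for ancestral alternate-allele
#'   frequencies, or a length-2 `c(shape1, shape2)` with
#'   `freq_distribution = "beta"`.
#' @param freq_distribution `"uniform"` or `"beta"`.
#' @param populations Data frame with `name`, `n` (founders sampled), `f`
#'   (Balding-Nichols drift coefficient; 0 means the ancestral frequencies
#'   are used unchanged).
#' @param families Data frame with `dam`, `sire`, `n_offspring`; parent ids
#'   must be founder ids (`<population>_<index>`). `NULL` for no crosses.
#' @param null_loci_fraction Fraction of loci carrying a null allele.
#' @param null_allele_freq Null-allele frequency on founder haplotypes at
#'   null loci.
#' @param epsilon Per-genotype miscall rate.
#' @param missing_rate Per-genotype missingness rate.
#' @param replicate_fraction Fraction of samples re-observed as technical
#'   replicates (independent error/missingness draws from the same true
#'   genotypes).
#' @param seed Integer seed (mandatory); all stage-level randomness derives
#'   from it.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(n_loci = 300,
                            freq_range = c(0.1, 0.5),
                            freq_distribution = c("uniform", "beta"),
                            populations = data.frame(name = "pop1", n = 18,
                                                     f = 0),
                            families = default_cross_design(),
                            null_loci_fraction = 0.10,
                            null_allele_freq = 0.25,
                            epsilon = 0.005,
                            missing_rate = 0.05,
                            replicate_fraction = 0,
                            seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  freq_distribution <- match.arg(freq_distribution)
  rates <- c(null_loci_fraction, null_allele_freq, epsilon, missing_rate,
             replicate_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]",
                                       call. = FALSE)
  stopifnot(all(c("name", "n", "f") %in% names(populations)))
  if (!is.null(families)) {
    stopifnot(all(c("dam", "sire", "n_offspring") %in% names(families)))
  }
  structure(list(n_loci = as.integer(n_loci), freq_range = freq_range,
                 freq_distribution = freq_distribution,
                 populations = populations, families = families,
                 null_loci_fraction = null_loci_fraction,
                 null_allele_freq = null_allele_freq,
                 epsilon = epsilon, missing_rate = missing_rate,
                 replicate_fraction = replicate_fraction,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Default breeding-program cross design
#'
#' Fifteen full-sib families produced from 18 unique founder parents (nine
#' disjoint crosses plus six crosses re-using parents), each with the given
#' number of offspring.
#'
#' @param pop Population name of the founders.
#' @param n_offspring Offspring per family.
#' @return Data frame with `dam`, `sire`, `n_offspring`.
#' @export
default_cross_design <- function(pop = "pop1", n_offspring = 7) {
  id <- function(i) sprintf("%s_%02d", pop, i)
  dams <- c(id(seq(1, 17, by = 2)),              # 9 disjoint crosses
            id(c(1, 2, 5, 6, 9, 10)))            # 6 re-using parents
  sires <- c(id(seq(2, 18, by = 2)),
             id(c(3, 4, 7, 8, 11, 12)))
  data.frame(dam = dams, sire = sires, n_offspring = n_offspring,
             stringsAsFactors = FALSE)
}

#' Balding-Nichols population allele frequencies
#'
#' Draws ancestral alternate-allele frequencies from the spec's
#' distribution, then per-population frequencies from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` — the Balding-Nichols drift
#' model, whose between-population variance at a locus is `F p (1 - p)`.
#' Populations with `F = 0` keep the ancestral frequencies exactly.
#'
#' @param spec A [simulation_spec()].
#' @return List with `ancestral` (length `n_loci`) and `per_population`
#'   (populations x loci matrix), plus `locus_ids`.
#' @export
simulate_base_frequencies <- function(spec) {
  set.seed(spec$seed + 1L)
  L <- spec$n_loci
  p <- if (spec$freq_distribution == "uniform") {
    stats::runif(L, spec$freq_range[1], spec$freq_range[2])
  } else {
    stats::rbeta(L, spec$freq_range[1], spec$freq_range[2])
  }
  pops <- spec$populations
  per_pop <- matrix(NA_real_, nrow(pops), L,
                    dimnames = list(pops$name, NULL))
  for (k in seq_len(nrow(pops))) {
    f <- pops$f[k]
    per_pop[k, ] <- if (f <= 0) p else {
      stats::rbeta(L, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    }
  }
  locus_ids <- sprintf("L%04d", seq_len(L))
  colnames(per_pop) <- locus_ids
  list(ancestral = stats::setNames(p, locus_ids), per_population = per_pop,
       locus_ids = locus_ids)
}

#' Simulate founder haplotypes
#'
#' Founders are drawn in Hardy-Weinberg proportions from their population's
#' allele frequencies, as two haplotype vectors per individual (allele
#' codes: 0 = reference, 1 = alternate; 2 = null, introduced later by
#' [apply_null_alleles()]). Founder ids are `<population>_<index>`.
#'
#' @param freqs Output of [simulate_base_frequencies()].
#' @param populations The spec's population table.
#' @param seed Integer seed.
#' @return A `haplotype_bundle`: list with haplotype matrices `h1`, `h2`,
#'   `founder_ids`, `population`, empty `pedigree`, and transmission
#'   bookkeeping.
#' @export
simulate_founders <- function(freqs, populations, seed) {
  set.seed(seed)
  L <- length(freqs$locus_ids)
  ids <- character(0); pop_of <- character(0)
  h1 <- h2 <- NULL
  for (k in seq_len(nrow(populations))) {
    n <- populations$n[k]
    p <- freqs$per_population[populations$name[k], ]
    draw <- function() {
      m <- matrix(stats::rbinom(n * L, 1L, rep(p, each = n)), n, L)
      storage.mode(m) <- "integer"
      m
    }
    h1 <- rbind(h1, draw()); h2 <- rbind(h2, draw())
    ids <- c(ids, sprintf("%s_%02d", populations$name[k], seq_len(n)))
    pop_of <- c(pop_of, rep(populations$name[k], n))
  }
  dimnames(h1) <- dimnames(h2) <- list(ids, freqs$locus_ids)
  structure(list(h1 = h1, h2 = h2, founder_ids = ids,
                 population = stats::setNames(pop_of, ids),
                 pedigree = NULL, dam_choice = NULL, sire_choice = NULL),
            class = "haplotype_bundle")
}

#' Simulate full-sib families from founder crosses
#'
#' Each offspring receives, at every locus independently, one uniformly
#' chosen haplotype from its dam and one from its sire (loci unlinked).
#' Transmission choices are recorded so hidden alleles introduced later on
#' founder haplotypes inherit deterministically.
#'
#' @param bundle A `haplotype_bundle` from [simulate_founders()].
#' @param families Data frame with `dam`, `sire`, `n_offspring`.
#' @param seed Integer seed.
#' @return The bundle extended with offspring haplotypes, a `pedigree`
#'   data frame, and transmission matrices.
#' @export
simulate_families <- function(bundle, families, seed) {
  set.seed(seed)
  missing_par <- setdiff(unique(c(families$dam, families$sire)),
                         bundle$founder_ids)
  if (length(missing_par)) {
    stop("families reference unknown founder id(s): ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  }
  L <- ncol(bundle$h1)
  off_ids <- character(0); dams <- character(0); sires <- character(0)
  fam_label <- character(0)
  for (i in seq_len(nrow(families))) {
    k <- families$n_offspring[i]
    off_ids <- c(off_ids, sprintf("F%02d_o%02d", i, seq_len(k)))
    dams <- c(dams, rep(families$dam[i], k))
    sires <- c(sires, rep(families$sire[i], k))
    fam_label <- c(fam_label, rep(sprintf("F%02d", i), k))
  }
  n_off <- length(off_ids)
  dam_choice <- matrix(sample(1:2, n_off * L, replace = TRUE), n_off, L)
  sire_choice <- matrix(sample(1:2, n_off * L, replace = TRUE), n_off, L)
  storage.mode(dam_choice) <- storage.mode(sire_choice) <- "integer"
  dimnames(dam_choice) <- dimnames(sire_choice) <-
    list(off_ids, colnames(bundle$h1))

  derive <- function(h1, h2) {
    oh1 <- ifelse(dam_choice == 1L, h1[dams, , drop = FALSE],
                  h2[dams, , drop = FALSE])
    oh2 <- ifelse(sire_choice == 1L, h1[sires, , drop = FALSE],
                  h2[sires, , drop = FALSE])
    storage.mode(oh1) <- storage.mode(oh2) <- "integer"
    dimnames(oh1) <- dimnames(oh2) <- list(off_ids, colnames(h1))
    list(oh1, oh2)
  }
  oh <- derive(bundle$h1, bundle$h2)
  bundle$h1 <- rbind(bundle$h1, oh[[1]])
  bundle$h2 <- rbind(bundle$h2, oh[[2]])
  bundle$pedigree <- data.frame(offspring_id = off_ids, dam_id = dams,
                                sire_id = sires, family = fam_label,
                                stringsAsFactors = FALSE)
  bundle$population <- c(bundle$population,
                         stats::setNames(bundle$population[dams], off_ids))
  bundle$dam_choice <- dam_choice
  bundle$sire_choice <- sire_choice
  bundle
}

#' Introduce hidden null alleles on founder haplotypes
#'
#' At each null locus, every founder haplotype allele is replaced by a null
#' allele with probability `null_freq`; offspring haplotypes are re-derived
#' through the recorded transmissions, so nulls inherit exactly like real
#' alleles. Null alleles are invisible to genotyping: see
#' [genotype_calls()] for the masking rule.
#'
#' @param bundle A `haplotype_bundle` (after [simulate_families()] if
#'   offspring are wanted).
#' @param null_loci Character vector of locus ids to affect.
#' @param null_freq Null-allele frequency on founder haplotypes.
#' @param seed Integer seed.
#' @return The bundle with nulls planted (allele code 2) and an attribute
#'   recording `null_loci`.
#' @export
apply_null_alleles <- function(bundle, null_loci, null_freq, seed) {
  set.seed(seed)
  founders <- bundle$founder_ids
  cols <- match(null_loci, colnames(bundle$h1))
  if (anyNA(cols)) stop("null_loci not a subset of simulated loci",
                        call. = FALSE)
  for (h in c("h1", "h2")) {
    m <- bundle[[h]]
    block <- m[founders, cols, drop = FALSE]
    hit <- matrix(stats::runif(length(block)) < null_freq, nrow(block))
    block[hit] <- 2L
    m[founders, cols] <- block
    bundle[[h]] <- m
  }
  # re-transmit so offspring inherit the planted nulls
  if (!is.null(bundle$pedigree)) {
    dams <- bundle$pedigree$dam_id
    sires <- bundle$pedigree$sire_id
    offs <- bundle$pedigree$offspring_id
    oh1 <- ifelse(bundle$dam_choice == 1L,
                  bundle$h1[dams, , drop = FALSE],
                  bundle$h2[dams, , drop = FALSE])
    oh2 <- ifelse(bundle$sire_choice == 1L,
                  bundle$h1[sires, , drop = FALSE],
                  bundle$h2[sires, , drop = FALSE])
    storage.mode(oh1) <- storage.mode(oh2) <- "integer"
    bundle$h1[offs, ] <- oh1
    bundle$h2[offs, ] <- oh2
  }
  attr(bundle, "null_loci") <- null_loci
  bundle
}

#' Visible genotype calls from haplotypes
#'
#' Applies the null-allele phenomenology of amplicon genotyping: a
#' heterozygous null carrier (`A/n`) amplifies only the visible allele and
#' is typed as the spurious homozygote `A/A`; a null homozygote (`n/n`)
#' fails to amplify and is missing.
#'
#' @param bundle A `haplotype_bundle`.
#' @return Integer call matrix (0/1/2/NA) over all simulated individuals.
#' @export
genotype_calls <- function(bundle) {
  a1 <- bundle$h1; a2 <- bundle$h2
  g <- a1 + a2                                  # valid when no null involved
  one_null <- (a1 == 2L) != (a2 == 2L)
  other <- ifelse(a1 == 2L, a2, a1)
  g[one_null] <- 2L * other[one_null]           # spurious homozygote
  g[a1 == 2L & a2 == 2L] <- NA_integer_         # amplification failure
  storage.mode(g) <- "integer"
  g
}

#' Apply genotyping error and missingness to a call matrix
#'
#' Each non-missing call is independently miscalled to one of the two other
#' genotype codes with probability `epsilon / 2` each, then set missing
#' with probability `missing_rate`.
#'
#' @param calls Integer genotype matrix (0/1/2/NA).
#' @param epsilon Per-genotype miscall rate.
#' @param missing_rate Per-genotype missingness rate.
#' @param seed Optional integer seed.
#' @return The perturbed matrix.
#' @export
apply_error_and_missingness <- function(calls, epsilon, missing_rate,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(calls)
  if (epsilon > 0) {
    u <- stats::runif(sum(ok))
    flip <- u < epsilon
    if (any(flip)) {
      shift <- 1L + (u[flip] < epsilon / 2)
      v <- calls[ok]
      v[flip] <- (v[flip] + shift) %% 3L
      calls[ok] <- v
    }
  }
  if (missing_rate > 0) {
    drop <- ok & matrix(stats::runif(length(calls)) < missing_rate,
                        nrow(calls))
    calls[drop] <- NA_integer_
  }
  storage.mode(calls) <- "integer"
  calls
}

#' Simulate a complete panel dataset with truth
#'
#' Orchestrates the full generator: allele frequencies, founders, families,
#' null alleles, error/missingness, and technical replicates. All
#' randomness flows from `spec$seed` through fixed stage offsets, so an
#' identical spec reproduces the dataset exactly.
#'
#' @param spec A [simulation_spec()].
#' @return List with `genotypes` (a [genotype_matrix()] of observed calls,
#'   replicates included as `<id>_rep`) and `truth` (list: `true_calls`
#'   pre-error post-null matrix, `clean_calls` pre-null matrix, `pedigree`,
#'   `null_loci`, `replicate_map`, `population`, `frequencies`, `bundle`).
#' @export
simulate_pedigree_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  freqs <- simulate_base_frequencies(spec)
  bundle <- simulate_founders(freqs, spec$populations, spec$seed + 2L)
  if (!is.null(spec$families) && nrow(spec$families) > 0L) {
    bundle <- simulate_families(bundle, spec$families, spec$seed + 3L)
  }
  clean_calls <- genotype_calls(bundle)

  null_loci <- character(0)
  if (spec$null_loci_fraction > 0 && spec$null_allele_freq > 0) {
    set.seed(spec$seed + 4L)
    n_null <- round(spec$null_loci_fraction * spec$n_loci)
    null_loci <- sort(sample(freqs$locus_ids, n_null))
    bundle <- apply_null_alleles(bundle, null_loci, spec$null_allele_freq,
                                 spec$seed + 5L)
  }
  true_calls <- genotype_calls(bundle)

  observed <- apply_error_and_missingness(true_calls, spec$epsilon,
                                          spec$missing_rate,
                                          spec$seed + 6L)

  replicate_map <- NULL
  if (spec$replicate_fraction > 0) {
    set.seed(spec$seed + 7L)
    n_rep <- max(1L, round(spec$replicate_fraction * nrow(true_calls)))
    rep_of <- sort(sample(rownames(true_calls), n_rep))
    rep_calls <- apply_error_and_missingness(
      true_calls[rep_of, , drop = FALSE],
      spec$epsilon, spec$missing_rate)
    rownames(rep_calls) <- paste0(rep_of, "_rep")
    observed <- rbind(observed, rep_calls)
    replicate_map <- data.frame(sample_id = c(rep_of,
                                              paste0(rep_of, "_rep")),
                                group = rep(rep_of, 2),
                                stringsAsFactors = FALSE)
  }

  base_id <- sub("_rep$", "", rownames(observed))
  pop_obs <- stats::setNames(unname(bundle$population[base_id]),
                             rownames(observed))
  gen <- stats::setNames(
    ifelse(base_id %in% bundle$founder_ids, "parent", "offspring"),
    rownames(observed))
  gm <- genotype_matrix(observed, population = pop_obs, generation = gen)
  list(genotypes = gm,
       truth = list(true_calls = true_calls, clean_calls = clean_calls,
                    pedigree = bundle$pedigree, null_loci = null_loci,
                    replicate_map = replicate_map,
                    population = bundle$population,
                    frequencies = freqs, bundle = bundle))
}
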