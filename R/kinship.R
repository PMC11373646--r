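# Pairwise relationship likelihoods under kappa IBD coefficients with a
# symmetric per-genotype miscall model, Monte-Carlo logl distributions for
# cutoff calibration, and duplicate detection.

.KAPPAS <- list(PO = c(0, 1, 0),
                FS = c(0.25, 0.5, 0.25),
                HS = c(0.5, 0.5, 0),
                U  = c(1, 0, 0))

# sentinel used in vectorised log-likelihood tables when epsilon = 0 makes
# a genotype pair impossible; large enough to dominate any panel sum
.LOGL_IMPOSSIBLE <- -1e6

#' Relationship model (kappa coefficients + error rate)
#'
#' A relationship is parameterised by the IBD-sharing coefficients
#' `kappa = (k0, k1, k2)` — the probabilities a pair shares 0, 1 or 2
#' alleles identical by descent — plus a symmetric per-genotype miscall
#' rate `epsilon`. Built-ins: `PO` (0,1,0), `FS` (0.25,0.5,0.25),
#' `HS` (0.5,0.5,0), `U` (1,0,0).
#'
#' @param name One of `"PO"`, `"FS"`, `"HS"`, `"U"`, or any label when
#'   `kappa` is supplied explicitly.
#' @param epsilon Per-genotype miscall rate (each wrong genotype observed
#'   with probability `epsilon / 2`).
#' @param kappa Optional explicit numeric triple summing to 1.
#' @return List of class `relationship_model`.
#' @export
relationship_model <- function(name, epsilon = 0, kappa = NULL) {
  if (is.null(kappa)) {
    if (!name %in% names(.KAPPAS)) {
      stop("unknown relationship ", sQuote(name),
           "; supply kappa explicitly", call. = FALSE)
    }
    kappa <- .KAPPAS[[name]]
  }
  kappa <- as.numeric(kappa)
  if (length(kappa) != 3L || any(kappa < 0) ||
      abs(sum(kappa) - 1) > 1e-9) {
    stop("kappa must be 3 non-negative values summing to 1", call. = FALSE)
  }
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]",
                                       call. = FALSE)
  structure(list(name = name, kappa = kappa, epsilon = epsilon),
            class = "relationship_model")
}

#' @export
print.relationship_model <- function(x, ...) {
  cat(sprintf("relationship_model %s: kappa = (%g, %g, %g), epsilon = %g\n",
              x$name, x$kappa[1], x$kappa[2], x$kappa[3], x$epsilon))
  invisible(x)
}

.hwe_prior <- function(p) {
  q <- 1 - p
  c(q^2, 2 * p * q, p^2)
}

.transition_one_shared <- function(p) {
  # T[g1+1, g2+1]: distribution of g2 given g1 when the pair shares exactly
  # one allele IBD; the shared allele is drawn uniformly from g1's two
  # alleles, the other allele from the population.
  q <- 1 - p
  matrix(c(q,      p,            0,
           q / 2,  1 / 2,        p / 2,
           0,      q,            p),
         nrow = 3, byrow = TRUE)
}

.error_kernel <- function(epsilon) {
  E <- matrix(epsilon / 2, 3, 3)
  diag(E) <- 1 - epsilon
  E
}

.pair_prob_table <- function(p, kappa, epsilon = 0) {
  # 3x3 joint probability of observed genotype pairs at a locus
  prior <- .hwe_prior(p)
  J <- kappa[1] * (prior %o% prior) +
    kappa[2] * (prior * .transition_one_shared(p)) +
    kappa[3] * diag(prior)
  if (epsilon > 0) {
    E <- .error_kernel(epsilon)
    J <- E %*% J %*% t(E)
  }
  J
}

#' Joint probability of a genotype pair under a relationship
#'
#' `P(g1, g2 | R) = k0 P(g1) P(g2) + k1 P(g1) T(g2 | g1) + k2 P(g1)
#' 1[g1 = g2]`, where `P` is the Hardy-Weinberg genotype prior at
#' alternate-allele frequency `p_alt` and `T` is the one-allele-shared
#' transition (shared allele uniform from g1's two alleles, the other from
#' the population). With `epsilon > 0` the true-pair probabilities are
#' pushed through the symmetric 3x3 observation kernel independently for
#' both individuals.
#'
#' @param g1,g2 Genotype codes in `{0, 1, 2}`.
#' @param p_alt Alternate-allele frequency in `(0, 1)` (fixed loci are not
#'   admissible and raise an error).
#' @param model A [relationship_model()].
#' @return The joint probability.
#' @export
pair_likelihood <- function(g1, g2, p_alt, model) {
  if (any(p_alt <= 0 | p_alt >= 1)) {
    stop("p_alt must be strictly inside (0, 1); fixed loci are skipped",
         call. = FALSE)
  }
  stopifnot(inherits(model, "relationship_model"))
  n <- max(length(g1), length(g2), length(p_alt))
  g1 <- rep_len(as.integer(g1), n)
  g2 <- rep_len(as.integer(g2), n)
  p_alt <- rep_len(p_alt, n)
  vapply(seq_len(n), function(i) {
    .pair_prob_table(p_alt[i], model$kappa, model$epsilon)[g1[i] + 1L,
                                                           g2[i] + 1L]
  }, numeric(1))
}

.logl_table <- function(freqs, epsilon, numerator = "PO",
                        denominator = "U") {
  # 3 x 3 x L array of log(P(pair | numerator) / P(pair | denominator));
  # loci with fixed or missing frequencies are excluded (attr "usable").
  usable <- which(!is.na(freqs) & freqs > 0 & freqs < 1)
  k_num <- .KAPPAS[[numerator]]
  k_den <- .KAPPAS[[denominator]]
  L <- length(usable)
  arr <- array(NA_real_, c(3, 3, L))
  for (l in seq_len(L)) {
    p <- freqs[usable[l]]
    num <- .pair_prob_table(p, k_num, epsilon)
    den <- .pair_prob_table(p, k_den, epsilon)
    arr[, , l] <- log(num) - log(den)
  }
  attr(arr, "usable") <- usable
  arr
}

#' Log-likelihood ratio for one genotyped pair
#'
#' Natural-log likelihood ratio of the numerator relationship (default
#' parent-offspring) against the denominator (default unrelated), summed
#' over loci typed in both individuals; loci missing in either individual
#' contribute zero. A Mendelian exclusion at `epsilon = 0` yields `-Inf`.
#'
#' @param g1,g2 Integer genotype vectors over the same loci (`NA` missing).
#' @param freqs Alternate-allele frequency per locus (fixed/NA loci are
#'   skipped).
#' @param epsilon Per-genotype miscall rate used in both hypotheses.
#' @param numerator,denominator Relationship names.
#' @return List with `logl` and `n_shared_loci` (`logl = NA` when no loci
#'   are shared).
#' @export
pair_logl <- function(g1, g2, freqs, epsilon = 0, numerator = "PO",
                      denominator = "U") {
  stopifnot(length(g1) == length(g2), length(g1) == length(freqs))
  arr <- .logl_table(freqs, epsilon, numerator, denominator)
  usable <- attr(arr, "usable")
  g1 <- g1[usable]; g2 <- g2[usable]
  shared <- which(!is.na(g1) & !is.na(g2))
  if (length(shared) == 0L) {
    return(list(logl = NA_real_, n_shared_loci = 0L))
  }
  idx <- (shared - 1L) * 9L + g2[shared] * 3L + g1[shared] + 1L
  list(logl = sum(arr[idx]), n_shared_loci = length(shared))
}

.simulate_pair_genotypes <- function(kappa, prior_cum, trans_cum, n_sim) {
  # one locus: draw n_sim genotype pairs under kappa
  g1 <- findInterval(stats::runif(n_sim), prior_cum) # 0,1,2
  mode <- findInterval(stats::runif(n_sim), cumsum(kappa)[1:2])  # 0,1,2 IBD
  g2 <- integer(n_sim)
  i0 <- mode == 0L
  g2[i0] <- findInterval(stats::runif(sum(i0)), prior_cum)
  i1 <- mode == 1L
  if (any(i1)) {
    u <- stats::runif(sum(i1))
    gg <- g1[i1]
    g2[i1] <- ifelse(gg == 0L, findInterval(u, trans_cum[1, ]),
              ifelse(gg == 1L, findInterval(u, trans_cum[2, ]),
                               findInterval(u, trans_cum[3, ])))
  }
  i2 <- mode == 2L
  g2[i2] <- g1[i2]
  cbind(g1, g2)
}

.apply_miscalls <- function(g, epsilon) {
  if (epsilon <= 0) return(g)
  u <- stats::runif(length(g))
  flip <- u < epsilon
  if (any(flip)) {
    # move to one of the two other genotypes with equal probability
    shift <- 1L + (u[flip] < epsilon / 2)      # 1 or 2
    g[flip] <- (g[flip] + shift) %% 3L
  }
  g
}

#' Monte-Carlo logl distributions per relationship
#'
#' Simulates genotype pairs locus-by-locus under each relationship's kappa
#' coefficients using the panel's allele frequencies, applies the miscall
#' and missingness model, and scores every pair with the parent-offspring
#' vs unrelated log-likelihood ratio. Used to calibrate assignment cutoffs
#' and quantify the power of a panel to separate relationship types.
#'
#' @param freqs Named alternate-allele frequencies (the panel's frequency
#'   table); fixed/NA loci are skipped.
#' @param relationships Character vector of relationship names to simulate.
#' @param n_sim Number of simulated pairs per relationship.
#' @param epsilon Per-genotype miscall rate applied to the simulated true
#'   genotypes and assumed when scoring.
#' @param missing_rate Probability a call is missing, independently per
#'   genotype.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List of class `logl_distributions`: per relationship a sorted
#'   numeric vector of logl values; attributes `n_sim`, `seed`, `epsilon`.
#' @export
simulate_logl_distributions <- function(freqs,
                                        relationships = c("PO", "FS", "HS",
                                                          "U"),
                                        n_sim = 10000, epsilon = 0.005,
                                        missing_rate = 0, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  arr <- .logl_table(freqs, epsilon)
  usable <- attr(arr, "usable")
  p_use <- freqs[usable]
  L <- length(p_use)
  out <- list()
  for (rel in relationships) {
    kappa <- .KAPPAS[[rel]]
    logl <- numeric(n_sim)
    for (l in seq_len(L)) {
      p <- p_use[l]
      prior_cum <- cumsum(.hwe_prior(p))[1:2]
      trans_cum <- t(apply(.transition_one_shared(p), 1,
                           function(r) cumsum(r)[1:2]))
      gp <- .simulate_pair_genotypes(kappa, prior_cum, trans_cum, n_sim)
      g1 <- .apply_miscalls(gp[, 1], epsilon)
      g2 <- .apply_miscalls(gp[, 2], epsilon)
      keep <- rep(TRUE, n_sim)
      if (missing_rate > 0) {
        keep <- stats::runif(n_sim) >= missing_rate &
          stats::runif(n_sim) >= missing_rate
      }
      contrib <- arr[cbind(g1 + 1L, g2 + 1L, l)]
      logl <- logl + ifelse(keep, contrib, 0)
    }
    out[[rel]] <- sort(logl)
  }
  structure(out, class = "logl_distributions", n_sim = n_sim, seed = seed,
            epsilon = epsilon)
}

#' @export
print.logl_distributions <- function(x, ...) {
  cat("logl_distributions (PO-vs-U log likelihood ratio):\n")
  for (rel in names(x)) {
    cat(sprintf("  %-3s mean %8.2f  [%.2f, %.2f]\n", rel, mean(x[[rel]]),
                min(x[[rel]]), max(x[[rel]])))
  }
  invisible(x)
}

#' False-positive and false-negative rates at a logl cutoff
#'
#' From simulated logl distributions: the false-positive rate per non-PO
#' relationship is the fraction of its pairs scoring above the cutoff; the
#' false-negative rate (reported for PO) is the fraction of true
#' parent-offspring pairs at or below the cutoff. Multiplying FPR by the
#' number of candidate comparisons gives the expected count of false
#' positives — the quantity used to pick the cutoff. Tail rates below the
#' Monte-Carlo resolution (`1 / n_sim`) are upper bounds only.
#'
#' @param dists A [simulate_logl_distributions()] result.
#' @param cutoff Retention cutoff on the logl scale.
#' @param n_comparisons Optional number of candidate comparisons for the
#'   expected false-positive count.
#' @return Data frame with `relationship`, `fpr`, `fnr`, `expected_fp`.
#' @export
false_positive_rate <- function(dists, cutoff, n_comparisons = NULL) {
  rows <- lapply(names(dists), function(rel) {
    v <- dists[[rel]]
    fpr <- if (rel == "PO") NA_real_ else mean(v > cutoff)
    fnr <- if (rel == "PO") mean(v <= cutoff) else NA_real_
    data.frame(relationship = rel, fpr = fpr, fnr = fnr,
               expected_fp = if (is.null(n_comparisons)) NA_real_
                             else fpr * n_comparisons,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect potential duplicate samples
#'
#' Reports every sample pair with at least `min_shared` loci typed in both
#' and genotype concordance at or above `min_concordance` — candidate
#' accidental duplicates (or unflagged technical replicates).
#'
#' @param x A [genotype_matrix()].
#' @param min_concordance Concordance threshold (default 0.95).
#' @param min_shared Minimum shared typed loci (default 100).
#' @return Data frame with `sample_a`, `sample_b`, `n_shared`,
#'   `concordance`.
#' @export
find_duplicates <- function(x, min_concordance = 0.95, min_shared = 100) {
  g <- x$calls
  n <- nrow(g)
  typed <- !is.na(g)
  Tm <- typed * 1
  shared <- Tm %*% t(Tm)
  # concordant calls: sum over loci of 1[g_a == g_b], both typed
  eq <- matrix(0, n, n)
  for (code in c(GT_HOMREF, GT_HET, GT_HOMALT)) {
    I <- (typed & g == code) * 1
    eq <- eq + I %*% t(I)
  }
  conc <- eq / shared
  rows <- which(upper.tri(shared) & shared >= min_shared &
                  conc >= min_concordance, arr.ind = TRUE)
  out <- data.frame(sample_a = rownames(g)[rows[, 1]],
                    sample_b = rownames(g)[rows[, 2]],
                    n_shared = as.integer(shared[rows]),
                    concordance = conc[rows],
                    stringsAsFactors = FALSE)
  out[order(-out$concordance), , drop = FALSE]
}
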