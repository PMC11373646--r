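---
title: "Amplicon-panel genotyping and parentage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon-panel genotyping and parentage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliparent)
```

# Scope

`ampliparent` covers the analysis stages of a SNP amplicon-panel workflow:
importing hotspot variant-caller genotype tables and genepop files;
technical-replicate and missingness QC; per-locus population-genetic
statistics; two-ranking marker selection and flank-window extraction for
panel design; kinship likelihood ratios and Monte-Carlo cutoff calibration;
parentage assignment with strong-trio discovery; pedigree-free null-allele
detection; and a truth-tracked pedigree simulator. Sequencing, alignment
and primer design are out of scope — alignment *categories* (single/multi/
unmapped) are consumed from external tools, never computed here.

# Genotype representation

Loci are biallelic SNPs coded 0 (homozygous reference), 1 (heterozygous),
2 (homozygous alternate), `NA` (missing), held in a `genotype_matrix` with
per-sample population and generation labels. Hotspot exports code the
variant allele as "Absent"/"Heterozygous"/"Homozygous"/"No Call"; note that
**"Absent" means the variant is absent**, i.e. homozygous *reference* — a
conversion worth stating prominently because it is an easy sign error.
Genepop I/O uses the two-digit dialect with allele 01 = reference,
02 = alternate; `0201` and `0102` denote the same unordered heterozygote.

# QC cascade

* **Replicate concordance** compares loci typed in both members of a pair
  (pairs qualify only when both members have a genotyping rate ≥ 0.5) and
  classifies discordances into the three unordered genotype-pair categories
  (hom-alt/het, hom-ref/het, hom-ref/hom-alt). The summary is the
  *unweighted mean ± sd over pairs*, not a pooled ratio; pooled category
  totals are reported separately (`discordance_rates()`).
* **Missingness filtering** runs samples first, then loci, with a strict
  keep-if-`< 0.30`-missing rule: a sample missing exactly 30% of calls is
  removed. The order matters — dropping poorly typed samples first can
  rescue loci the reverse order would discard — and the tests pin the
  implemented order. The filter is idempotent.
* **Monomorphic loci** (all non-missing calls implying one allele) are
  removed; loci that are entirely missing are treated as monomorphic and
  removed too (degenerate case, decided here).
* **Negative controls** are flagged at mean amplicon depth strictly
  greater than 40×.
* Replicate retention keeps the member with the most non-missing calls;
  ties break to the lexicographically first sample id (deterministic,
  otherwise arbitrary).

# Population-genetic statistics

Per locus: `p_alt = (2·n_homalt + n_het) / (2·n_typed)`,
`h_obs = n_het / n_typed`, `h_exp = 2p(1−p)` without small-sample
correction (the discovery-style pipeline this mirrors uses the plain
estimator). F_ST is the Weir–Cockerham (1984) θ from the a/b/c variance
components; multilocus and pairwise-population values use the
ratio-of-averages Σa / Σ(a+b+c), with a percentile bootstrap over loci
(default 1000 replicates, seeded) for 95% intervals. Populations with ≤ 15
samples are excluded from pairwise F_ST. Hardy–Weinberg proportions use the
exact biallelic test (full enumeration of heterozygote counts conditional
on allele counts, computed by the standard mid-point recurrence);
deviations at p < 0.05 (uncorrected) are *flagged, never removed*.
Monomorphic samples return p = 1 by convention.

Relatedness uses the Ritland (1996) moment estimator: per biallelic locus
`r_l = 2·(S_x,ref·S_y,ref/q + S_x,alt·S_y,alt/p − 1)`, with S half the
allele count in a genotype; the multilocus value weights loci by
(number of alleles − 1), i.e. an unweighted mean across biallelic loci
typed in both individuals. The estimator is relative to the supplied allele
frequencies: estimates can be negative, and if frequencies are estimated
from a group of close relatives the group's mean relatedness is pushed
toward zero by construction — supply population-level frequencies when
absolute levels matter. First-degree purging iteratively removes, within
populations, the individual in the most pairs above the threshold (default
0.26, a typical minimum full-sib value; ties break by lower genotyping
rate, then id) until no pair exceeds it.

PCA runs on the dosage matrix with missing calls imputed to the locus mean
and columns centred; scores come from the SVD, and each component is
oriented so its largest-magnitude loading is positive, making signs
reproducible across platforms.

# Marker selection and flank windows

Panel candidates first drop loci with `h_obs > 0.5` (a guard against
collapsed duplicated regions, where excess heterozygosity is an artifact),
then take the top 300 by observed heterozygosity and the top 300 by F_ST
(ties broken by locus id, for determinism), unioned with manually listed
private-allele markers. Flank extraction returns
`reference[pos − 200 … pos + 200]` (1-based inclusive; 401 bp windows with
the variant at offset 201). Edge targets are skipped and reported rather
than padded — a design process needs full windows. BED export converts to
0-based half-open coordinates.

# Kinship likelihoods and calibration

Relationships are parameterised by κ = (κ₀, κ₁, κ₂) IBD-sharing
coefficients: PO (0,1,0), FS (¼,½,¼), HS (½,½,0), U (1,0,0). The joint
genotype-pair probability combines the HWE prior, the one-allele-shared
transition, and identity, and is pushed through a symmetric per-genotype
miscall kernel (correct with 1 − ε, each wrong genotype with ε/2) applied
independently to both individuals. Defaults: ε = 0.005 — the minimal error
model that keeps Mendelian exclusions finite; richer allele-level error
models exist but add parameters this workflow cannot estimate from typical
panel data. Logs are natural; the default retention cutoff 5 and the strong
cutoff 10 are interpreted on that scale. If results are compared against
other kinship software, verify its log base first.

Cutoffs are calibrated by plain Monte Carlo: genotype pairs are simulated
locus-by-locus under each κ, the error/missingness model applied, and the
PO-vs-U logl computed. False-positive rates below ~1/n_sim are upper
bounds only (no importance sampling); with the default 10,000 simulations
per relationship that resolution suffices for cutoffs in the 5–10 range.
Loci are simulated independently — for panels averaging tens of amplicons
per chromosome, physical linkage is a second-order effect at these panel
sizes.

# Parentage, trios, and null-allele detection

All (offspring, candidate) pairs with logl > 5 are retained — deliberately
not capped at two per offspring, since surplus assignments reveal handling
errors and close-relative structure. Candidates are all genotyped
parent-generation individuals; sex is not used. Trios require *exactly two*
candidates above the assignment cutoff, both ≥ 10; an offspring with three
or more candidates above the cutoff never qualifies (the stricter reading
of an ambiguous rule — requiring exactly two above the lower cutoff — was
chosen because it is the more conservative filter for the tally that
follows). Parent pairs must recur (≥ 2 offspring) to be confirmed.

Confirmed trios feed the per-locus tally of offspring whose genotypes are
impossible given both parents (gamete enumeration; loci with any missing
member are skipped for that trio). Loci with ≥ 4 incompatible offspring are
flagged as putative null-allele loci — the pedigree-free signature of a
null allele, since a heterozygous carrier A/n is typed as the spurious
homozygote A/A — and removed before re-assignment; a watch list at ≥ 2 is
also reported. Evaluation against a declared pedigree counts, per
offspring, its genotyped true parents as assignment "slots":
completeness = 100·correct/possible and
false-positive % = 100·FP/(correct + FP), the share of calls made that are
wrong. Assignments contradicting the declared pedigree are surfaced in a
discrepancy report, never auto-corrected — conflicts may reflect pedigree
errors rather than genotyping errors, and that judgement belongs to the
analyst.

# The simulator: what it emulates, and what it does not

`simulation_spec()` defaults define a single-hatchery test condition:
300 loci with ancestral alternate-allele frequencies uniform on (0.1, 0.5),
18 founder parents crossed into 15 full-sib families of 7 offspring (nine
disjoint crosses plus six re-using parents), miscall rate ε = 0.005, 5%
missing calls, and 10% of loci carrying a hidden null allele at frequency
0.25 on founder haplotypes. The 5% missingness is a mildly optimistic but
realistic panel value (production runs often see 10–15%). Multi-population
scenarios draw per-population frequencies from the Balding–Nichols model,
Beta(p(1−F)/F, (1−p)(1−F)/F), whose between-population variance is
F·p(1−p) — the drift-recovery tests exploit exactly that moment identity.

Null alleles are planted on *founder haplotypes* and inherited through
recorded transmissions, so carrier offspring are consistent with their
carrier parents; visible genotypes follow the standard phenomenology
(A/n → spurious homozygote A/A; n/n → missing). Technical replicates are
independent re-observations of the same true genotypes, so expected
replicate concordance has the closed form (1−ε)² + ε²/2, which the tests
check.

The simulator does **not** model linkage or recombination maps, sweepstakes
reproductive success, locus-specific amplification bias, or depth-dependent
calling error. Passing tests therefore demonstrate correctness of the
inference machinery under idealised segregation, not robustness to every
artefact of real amplicon data.

A property worth knowing: null loci whose null allele happens to segregate
mostly with the reference allele at low minor-allele frequency can produce
*zero* visible Mendelian conflicts — the spurious homozygotes stay
consistent with the (equally masked) parents. Such loci are
information-theoretically invisible to incompatibility-based detection, so
the flagged set recovers most but not all planted nulls; the error-free
direction is clean (with ε = 0, every flagged locus is a planted null).

# Numerical choices and problem sizes

Tolerances: likelihood normalisation is checked to 1e-12; exact-test
p-values use a 1 + 1e-12 comparison guard against floating-point ties in
the enumeration. Degenerate inputs are defined rather than left to chance:
fixed-frequency loci are skipped in likelihoods and relatedness; zero-typed
loci are flagged undefined; empty candidate sets and empty matrices raise
usage errors. All simulation-based tests fix seeds; the test suite runs
simulations at moderate sizes (e.g. 300–500 loci, tens of individuals,
400–1000 Monte-Carlo pairs, 10 end-to-end seeds) — sizes chosen so the
properties under test (estimator bias, separation of logl distributions,
recovery rates) are resolved well above their sampling noise.

# Known limitations

* Biallelic SNPs only; microhaplotypes and multi-allelic loci are not
  supported.
* The error model is a single symmetric per-genotype rate; allele-specific
  dropout other than the explicit null-allele mechanism is not modelled.
* PO likelihoods are directional in interpretation but symmetric in value
  (κ symmetry), so parent/offspring roles must come from generation labels,
  not the statistic.
* Grandparentage, avuncular relationships and sibship reconstruction are
  not inference targets; FS/HS models exist for calibration only.
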