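---
title: "CNV-region discovery from SNP-array signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV-region discovery from SNP-array signals: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

SNP genotyping arrays report, per SNP, a normalised total-intensity ratio
(the Log R ratio, LRR) and a normalised allelic-intensity ratio (the
B allele frequency, BAF). Copy number changes shift both: deletions lower
the LRR and collapse BAF clusters, duplications raise the LRR and split
them. `cnvrforge` implements the population-level analysis used for
multi-breed dog cohorts genotyped on the CanineHD array: per-sample
segmentation of LRR/BAF into copy-number calls by two callers, merging of
overlapping calls into copy-number-variable regions (CNVRs), a dual-caller
consensus, genotyping of every sample at every consensus region, and
breed/gene annotation, with a qPCR relative-quantification module for wet-lab
validation arithmetic.

# Signal model and the synthetic cohort

The generator (`sim_config()`, `simulate_cohort()`) emulates the cohort
structure of a CanineHD-class screen at desk scale: 5 chromosomes of 40 Mb
with ~13 kb mean SNP spacing (about 15,000 SNPs), 5 breeds of 12 samples,
and 20 planted variants (8 shared among 2–3 breeds, 8 single-breed,
4 singletons) with spans of 8–30 SNPs and copy states in {0, 1, 3, 4}.
Within-breed carrier frequencies default to 0.17–0.42, the range reported
for breed-specific CNVRs on this array class. Per-sample LRR noise is
Gaussian with sd 0.15; a 5% minority of "bad" samples is simulated at
sd 0.35 so the QC stage has real work to do; BAF noise sd is 0.03, clipped
(not renormalised) to [0, 1], which reproduces the rails at 0 and 1 seen in
real data.

LRR state means follow the widely used five-state convention
(−3.5, −0.66, 0, 0.40, 0.68 for copy 0–4): the diploid state is the zero
baseline and the loss/gain asymmetry reflects the log2 response. BAF is
drawn from the genotype-cluster mixture of the SNP's copy state: cluster
centres k/c for k = 0..c weighted binomially in the SNP's population
B-allele frequency (drawn uniform [0.05, 0.95] per SNP), with copy 0
uniform. GC-correlated waviness can be injected
(`gc_wave_amplitude`), scaled per SNP as `amplitude * (gc − mean gc)/sd(gc)`.

What the generator does *not* emulate: linkage disequilibrium between SNPs,
pedigree/relatedness structure, the X chromosome, probe-specific response
differences, and the heavy segmentation artifacts of genuinely noisy
genomic regions (these are represented abstractly by variance-inflated
`noisy_regions` and, in the real analysis, by a config-supplied exclusion
file). Passing the recovery tests therefore demonstrates correctness of the
pipeline's logic under the stated noise model, not caller performance on
real arrays.

One desk-scale caveat is worth stating plainly: the sample standard
deviation of LRR — a QC statistic — is computed over ~15,000 SNPs here
versus ~170,000 on the real array. A planted homozygous deletion (mean
−3.5) occupying a few dozen SNPs measurably inflates its carrier's
whole-sample sd at this scale, so an occasional *good* sample fails QC by
carrying large deletions. On a real-sized manifest the same variant moves
the sd by well under 1%. For recovery accounting we therefore report both
an unconditional recovery rate and the rate over *discoverable* variants
(those with at least one QC-surviving carrier); a variant whose every
carrier was removed cannot be discovered in any screen, real or simulated
(`truth_recovery(..., cohort = )`).

# Quality control

LRR is first GC-corrected per sample: an ordinary least-squares fit of LRR
on the manifest's local GC fraction is removed while preserving the sample
mean (`corrected = lrr − b·(gc − mean gc)`). Subtracting the full fitted
line and re-adding only the intercept would shift the sample mean by
`b · mean(gc)`; centring the predictor keeps the correction mean-neutral,
idempotent, and exactly a no-op when GC is constant.

Sample QC applies the standard filtering ledger on the corrected signal:

* `sd(LRR) < 0.25`;
* waviness factor |WF| ≤ 0.04;
* fewer than 40 raw P-profile calls (a sample with exactly 40 fails — the
  rule is "40 or more", chosen because call counts are at or below ~30 in
  almost all good samples).

The waviness factor has no closed published definition (it comes from a
caller's helper tooling), so the package uses a documented stand-in: bin
the genome into 1 Mb windows, take each window's median corrected LRR, and
report `sd(window medians) × sign(cor(window medians, window mean GC))`.
The magnitude lives on the same ~0.04 scale as the common heuristic and the
sign encodes whether the wave tracks GC. The per-sample call-count
criterion uses the raw P-profile calls *before* SNP-span/LBF filtering,
because that is the file-level count the original QC was applied to.
Failed samples are removed from both callers' outputs downstream.

# The segmentation engine and its two profiles

The original cohort-scale analyses ran two external callers (QuantiSNP and PennCNV)
and kept only regions found by both. Reimplementing either program is out
of scope; instead the package runs one five-state hidden Markov model under
two parameter profiles, `Q` and `P`, differing in jump probability
(0.005 vs 0.01). This is an explicit stand-in whose job is to produce two
realistic, partially discordant call sets so the consensus stage — the
analysis's actual contribution — is exercised honestly. Thresholds are
honoured structurally, not numerically: the `Q` profile's Log Bayes factor
(LBF) is a natural-log emission likelihood ratio against the diploid state,
and the 10/30 thresholds are applied to it as relaxed/stringent cuts
exactly as in the original design, but no claim is made that its scale
matches QuantiSNP's internal Bayes factor.

Model details (`hmm_params()`):

* emissions: LRR Gaussian per state (sd 0.2 for states 1–4; 1.0 for the
  diffuse homozygous-deletion state); BAF from the same genotype-cluster
  mixture as the simulator plus a 1% uniform outlier component; missing
  values contribute zero log-likelihood;
* transitions: distance-dependent, `theta(d) = theta_max (1 − e^{−d/L})`
  with `L = 2 Mb`; from state i the jump mass is distributed as
  `theta · pi_j / (1 − pi_i)`, self-transition takes the remainder;
* priors: diploid-heavy (`pi_2 = 0.995`, remainder split evenly);
* population B-allele frequencies are estimated from the cohort per-SNP
  mean BAF (clipped to [0.05, 0.95]), mirroring the compile-PFB step of
  population-based callers;
* no EM re-estimation: parameters are fixed — the stand-in's job is
  segmentation, not parameter learning;
* Viterbi ties are broken deterministically towards the smaller
  copy-number change (state preference 2, 1, 3, 0, 4), so degenerate
  scores cannot introduce spurious state flips.

Calls are maximal constant-state runs; their LBF is additive over SNPs.
Call-level filters: at least 5 SNPs per call, no overlap with the
configured exclusion regions, and for the Q profile the LBF cut
(10 relaxed / 30 stringent; the P profile is deliberately not
LBF-filtered, matching the original design where the threshold was a
QuantiSNP-file concept).

# Consensus, genotyping and summaries

Per profile, calls merge into CNVRs by single-linkage union of overlapping
closed intervals: a CNVR's breakpoints are the outermost boundaries of its
constituent calls. Adjacent-but-not-overlapping calls (no shared base) do
not merge. The consensus keeps each stringent Q-profile CNVR with at least
10,000 shared bases (inclusive count) with some P-profile CNVR, and keeps
the *Q boundaries*.

Two deliberate coordinate conventions coexist: reported CNVR *length* is
`end − start` (the convention of the published tables this package
interoperates with, which every printed row satisfies exactly), while
*overlap* is an inclusive base count `min(end) − max(start) + 1`. The 1 bp
tension between the two is documented rather than hidden. Whether the
original 10 kb rule counted inclusively is unknowable from the text; the
inclusive reading is used and is exposed via `cross_caller_min_overlap_bp`.

Genotyping assigns each sample's *relaxed* Q calls to consensus CNVRs by
largest inclusive overlap (≥ 1 bp; ties broken by chromosome then start;
same-sample conflicts resolved to the larger-overlap call). Strict
containment — a literal reading of "located within the CNVR boundaries" —
would erase true carriers whose relaxed call overhangs the stringent
envelope by a few SNPs, so overlap is the default and containment is
available as `rule = "contain"`. CNVRs carried by exactly one sample
(singletons) are excluded from the final list as likely false positives;
zero-carrier regions (a stringent envelope never reached by a relaxed
call) are flagged rather than dropped, since their handling has no
published precedent.

Type classification calls a region a pure deletion if all non-diploid
genotypes are states {0,1}, a pure duplication for {3,4}, and del/dupl when
both occur. Size summaries use 50 kb histogram bins `[k·w, (k+1)·w)` and
the strata below 100 kb / 100 kb–1 Mb inclusive / above 1 Mb — the only
boundary reading under which the published stratum counts sum to the
region total. Deletion and duplication lengths are compared with a Welch
(unequal-variance) two-sided t-test; the original text says only
"two-sample t-test", and Welch is the safer default under the visibly
different spreads.

# Annotation

Breed frequencies are carriers over QC-passed screened samples, reported
half-up at 2 decimals (5/12 → 0.42). A raw single-breed CNVR has all its
carriers in one breed; the stringent list removes regions that overlap
(≥ 10 kb) a published CNVR reported in a *different* breed or one lacking
breed annotation — an unnamed breed cannot certify breed exclusivity, so
unknown triggers removal. Published-set overlap is stratified by cohort
frequency (all / > 5% / ≥ 1% / < 1%); the > 1% stratum is cumulative
(it contains the > 5% stratum), which is the only reading under which the
two lower strata partition the whole set. A region at exactly 1% falls in
the ≥ 1% stratum; a 351-sample cohort cannot hit 1% exactly, so the choice
is unobservable at the published scale and is documented here.

Gene annotation first reduces a gene table to 1:1 dog–human orthologs in a
fixed order — drop genes without a human ortholog, drop chrX/Un/MT, drop
non-unique dog ids, drop non-unique human ids — with per-step counts kept
for audit (the order matters: an X-linked duplicate must not knock out its
autosomal namesake's partner). Gene–CNVR overlap uses a liberal 1 bp rule
because CNVR breakpoints are rough envelope estimates; full containment is
flagged separately. The dosage-sensitivity report intersects the human
orthologs of CNVR genes with a supplied list of genes from
copy-number-stable human regions.

# qPCR validation arithmetic

Copy number is estimated from threshold cycles by the standard ΔΔCt method:
`ΔCt = mean Ct(target) − mean Ct(reference gene)` per individual,
`ΔΔCt = ΔCt(tested) − ΔCt(reference individual)`, and
`estimate = 2 × 2^(−ΔΔCt)`, assuming an amplification efficiency of 2.0
per cycle (dilution-series calibration is a wet-lab step outside
computational scope). The reference individual is one carrying no CNV at
any tested locus. Class boundaries are nearest-integer rounding of the
continuous estimate (halves upward): 0–1 deletion, 2 normal, ≥ 3
duplication — symmetric and parameter-free, since no published boundaries
exist. Concordance is the fraction of matched sample-locus pairs with equal
classes; a CNVR is validated when at least one array-carrier pair is
concordant. Percentages round half-up to integers (so 104/106 reports
as 98).

# Reference tables and synthetic stand-ins

The package bundles small plain-text tables from a published CanineHD
cohort (the 15 single-breed CNVRs, the 23 dosage-sensitive gene entries,
and the three excluded noisy regions totalling 9.2 Mb). The cohort's full
per-sample genotype matrix is not redistributable here, so
`synthetic_reference_matrix()` *constructs* a deterministic 110 × 351
matrix consistent with that cohort's published summary ledger (38
singletons; 31/30/11 types; 14/46/12 size strata; medians 194,559 /
154,574 / 281,565 / 447,710 bp; 38 kb minimum; 11/48/24 frequency
strata). It is synthetic by construction and by name: running the
genotyping-stage operations over it demonstrates that the package's
arithmetic reproduces the ledger from a matrix with those properties, not
that the real data were re-analysed. `synthetic_validation_outcomes()`
plays the same role for the qPCR campaign (106 pairs, 20 carriers, one
false positive and one false negative across nine regions).

# Problem sizes and numerical choices

The default synthetic cohort (60 samples × ~15,000 SNPs, two HMM profiles)
runs end to end in about one to two minutes on a single core; the property
suites use 4–8-SNP instances where the Viterbi optimum is verified against
exhaustive path enumeration. Numerical details: all likelihood work is in
natural-log space; the Viterbi recursion precomputes per-gap transition
terms; emission terms for missing values are exactly zero; BAF clipping is
applied after noise; interval operations route through closed 1-based
ranges so inclusive overlap counts are integer-exact. The permutation
check of the Welch t-test uses 100,000 resamples.

# Known limitations

* The segmentation engine is a stand-in: two profiles of one HMM, not two
  independent algorithms; inter-profile discordance is therefore milder
  than between real callers, and consensus filtering removes less than it
  would in practice.
* LBF magnitudes are not calibrated to any external caller's scale.
* The generator's i.i.d. noise understates the spatially correlated
  artifacts of real arrays; exclusion regions must come from a config file
  rather than being discovered.
* Sample QC at desk scale penalises carriers of large homozygous
  deletions (see above); at real manifest sizes the effect vanishes.
* GO/pathway enrichment, ortholog retrieval and raw-intensity
  normalisation are out of scope by design; their outputs enter as plain
  input tables.
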