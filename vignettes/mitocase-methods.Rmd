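---
title: "Methods and design of mitocase"
author: "mitocase authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of mitocase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocase)
```

# Scope

`mitocase` implements a case-control analysis of the human mitochondrial
genome from per-sample variant calls.  It deliberately starts downstream of
read processing: alignment, variant calling and nuMT filtering are assumed
done, and the package consumes a multi-sample VCF with per-allele depths
(`AD`) and total depth (`DP`).  Upstream of that boundary nothing is
modeled; downstream, everything is: heteroplasmy quantification, functional
annotation, conservation, a pathogenicity cascade, haplogroup assignment,
association statistics and population PCA.

# Heteroplasmy model

The heteroplasmy fraction (HF) of a call is the fraction of reads
supporting the alternate allele, `alt_reads / total_reads`.  Three states
follow from two thresholds:

* HF < 1% — excluded as likely sequencing error,
* 1% <= HF < 98% — heteroplasmic,
* HF >= 98% — homoplasmic.

The lower bound is taken inclusive (exactly 1% is heteroplasmic) and the
upper bound is the homoplasmic side (exactly 98% is homoplasmic).  The
literature phrases this band both as "between 1% and 98%" and as
"1% <= HF < 98%"; we adopt the inclusive-lower reading and state it here
once, because both classification boundaries are exercised by tests.
Multi-allelic VCF records are split into biallelic calls before HF is
computed — HF is a per-alternate-allele quantity.  Excluded calls are
dropped before any per-variant summary, and the count of dropped calls is
kept (`attr(*, "n_excluded_calls")`) so the bookkeeping between "variants
observed" and "variants analyzed" is always reconstructible.

A variant's cohort-level *state profile* is `heteroplasmic_only`,
`homoplasmic_only`, or `both` (homoplasmic in some carriers, heteroplasmic
in others).

# Functional annotation

The gene map ships with the published rCRS coordinates of the 37 genes,
the light-strand replication origin and the control region; the control
region wraps the circular origin (16024-576) and carries an explicit wrap
flag.  Several mitochondrial genes overlap (ATP8/ATP6, ND4L/ND4, two tRNA
pairs); a position in an overlap is attributed to the first feature in map
order, `featureOverlaps()` lists every ambiguous pair, and
`assignRegion(all = TRUE)` returns all containing features when the choice
matters.

Protein effects are predicted by rebuilding the affected codon in the
feature's reading frame.  Light-strand features (ND6 and eight tRNAs) are
reverse-complemented before translation.  Translation uses the vertebrate
mitochondrial genetic code (AGA/AGG are stops, TGA is tryptophan, ATA is
methionine), which differs from the standard code in exactly the ways that
make naive annotation wrong.  Genes ending in an incomplete stop codon
(ND1, ND2, ND3, ND4, COX3, CYTB) have the trailing codon completed with
`A`, mirroring post-transcriptional polyadenylation.  Indels inside
protein features are frameshifts when the length change is not a multiple
of 3; in-frame indels are reported as nonsynonymous.  A full-gene
translation route (`translateFeature()`, built on Biostrings) exists
independently of the codon-level route and is used as an oracle in the
test suite.

## The packaged reference sequence is synthetic

Interpreting real data requires the true rCRS (NC_012920), which the user
supplies as FASTA.  The *packaged* reference is a deterministic synthetic
stand-in with realistic base composition and the conventional N
placeholder at 3107; its role is to make simulation and the annotation
machinery fully testable.  Coordinates, gene boundaries and strand
assignments are real; the base at any given position generally is not.

# Conservation index

The conservation index (CI) of a site is the fraction of non-reference
species in a multi-species alignment carrying the human wild-type symbol.
The human row is excluded from numerator and denominator (43 comparison
species in a 44-species alignment); a switch (`includeReference`) exposes
the all-species convention because published descriptions are ambiguous
between the two.  Gaps and ambiguity codes count as mismatches — the
conservative choice, since counting them as matches inflates CI.  The
filter is strict: CI must exceed 75%, so exactly 75% fails.  Sites not
covered by the alignment are flagged `no_ci` and never pass silently.
Nonsynonymous protein variants are scored at the amino-acid level against
per-gene alignments indexed by codon number; everything else is scored at
the nucleotide level in genome coordinates.

# Pathogenicity cascade

Candidate variants pass three gates in order:

1. **Control frequency** — carrier frequency among healthy controls must
   be strictly below 1%; at or above it the variant is a polymorphism.
2. **Conservation** — CI > 75% at the appropriate level.
3. **Classifier** — for tRNA variants, the MitoTip quartile class
   (raw score > 16.25 = LP, 12.66-16.25 = PP, 8.44-12.66 = PB,
   < 8.44 = LB; LP and PP count as deleterious).  Scores exactly at 12.66
   or 8.44 take the higher class; 16.25 itself is PP because only the LP
   bound is printed strict.  For nonsynonymous protein variants, a
   consensus vote over 13 predictor programs: deleterious when more than
   six vote deleterious.  Missing predictor results count as
   non-deleterious votes while the absolute > 6-of-13 threshold is kept —
   the conservative reading.

MitoTip percentile displays are treated as display-only; the classifier
consumes raw scores.  The package never runs the external predictors —
their scores arrive as a long table — and the per-tool thresholds and
directions live in an editable TSV registry.  Every variant leaves the
cascade with an audit trail naming the stage that stopped it
(`not_eligible`, `frequency`, `conservation`, `classifier`, `no_data`),
so survivor counts at each stage are first-class outputs
(`cascadeAudit()`).  Synonymous protein variants are never prioritized,
whatever their votes.

The packaged cascade fixture (70 nonsynonymous protein candidates of
which 60 pass frequency, 55 pass conservation and 14 are voted
deleterious; 20 tRNA candidates thinning to 16, 14 and 3) mirrors the
scale of the study this design follows and has its stage counts frozen
into the acceptance tests against an independent brute-force evaluation.

# Haplogroup assignment

Full phylotree classifiers rank weighted partial matches over thousands
of nodes; that machinery is not the scientific point here, the downstream
association is.  `mitocase` therefore uses a deterministic, documented
stand-in: each node's defining-variant *closure* (union along its root
path) is scored against the sample's informative variants with the
symmetric Kulczynski-style overlap

\[ score(h) = \frac{1}{2}\left(\frac{|S \cap D_h|}{|D_h|} +
  \frac{|S \cap D_h|}{|S_{inf}|}\right) \]

where \(S_{inf}\) keeps only sample variants occurring anywhere in the
tree, so private variants neither help nor hurt.  Ties break to the
deeper node, then lexicographically.  Hotspot positions (the 302-316 and
16180s homopolymer tracts, 514-524, 3107, 16519) are masked before
scoring via a configurable list.  The stand-in is validated behaviorally:
on noise-free simulated cohorts it must recover the generating haplogroup
for every sample, and under default private-variant noise for at least
95% (in practice ~100%, since private variants rarely collide with
defining sites).  The packaged phylotree is synthetic: real East-Asian
haplogroup labels, invented defining-variant sets consistent with the
packaged synthetic reference.

Pooling to major groups truncates assigned labels by longest matching
prefix against the nine major labels (A, B, D4, D5, F, G, M7, R, Z);
everything else pools as "Others".  Which sub-lineages belong in
"Others" is study-specific, so the major-label list is an argument.

# Association statistics

* **Odds ratios** are cross-product ratios with Woolf 95% intervals,
  `exp(log OR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`.  Any zero cell
  triggers the Haldane-Anscombe 0.5 correction to every cell, recorded in
  the result.  The reference group for haplogroup tests is "all other
  haplogroups", matching the carrier-vs-rest construction of published
  association tables.
* **Fisher's exact test** is two-sided by the point-probability method
  (sum of hypergeometric point probabilities no larger than the observed
  table's), the convention of `stats::fisher.test`, stated explicitly
  because two-sided Fisher conventions differ across software.
* **Chi-square** is Pearson without Yates correction by default (a flag
  enables it); degenerate margins are flagged rather than errored.
* **Logistic regression** is the IRLS maximum-likelihood fit
  (convergence 1e-12, <= 100 iterations).  For a binary covariate its OR
  equals the contingency OR, which the tests enforce to 1e-6 on random
  tables.  Complete separation has no finite MLE; the fit falls back to
  the Haldane-corrected contingency OR with a warning.
* **Mann-Whitney U** uses midranks for ties; p is exact by enumeration
  when the two samples total at most 20 observations with no ties,
  otherwise the tie-corrected normal approximation with continuity
  correction.
* **SNP screening** retains variants whose minor allele (carrier)
  frequency reaches 5% in at least one group — exclusion requires being
  below the floor in *both* — and the floor is strict, so exactly 5% is
  retained.  Carrier frequency over individuals is the denominator
  throughout: mtDNA is effectively haploid per individual here.
* **Multiple testing**: raw p-values are primary (matching how such
  tables are usually published); Benjamini-Hochberg adjusted values are
  reported side by side and never gate any output.
* **Indel enrichment** contrasts variants observed only heteroplasmic
  with those observed only homoplasmic in a 2x2 against indel/SNV
  (chi-square and Fisher), plus a region-category table (chi-square).
  Variants seen in both states are excluded from the 2x2 contrast — how
  they should be counted is not derivable from the published analyses,
  and excluding them is the only choice that keeps the rows disjoint.

# Population PCA

Haplogroup frequency profiles are column-centered and
eigen-decomposed (covariance PCA); a correlation mode exists because
published analyses often do not state their normalization.  Variance
explained is reported as eigenvalue fractions of total variance.  The
sign of each component is fixed by making its largest-magnitude loading
positive, so results are platform-reproducible.  Rows that fail to sum
to 1 are renormalized with a message.  Distances between populations are
Euclidean in score space with lexicographic tie-breaks.

# The synthetic cohort generator

`simulateCohort()` makes the whole pipeline testable without sequencing
data.  Its defaults *are* the study conditions this design follows:

| parameter | default | rationale |
|---|---|---|
| group sizes | 146 cases / 120 controls | the emulated study design |
| haplogroup frequencies | per-group Table-style proportions (e.g. D4 14/146 vs 23/120, designed OR 0.447) | ties simulation to the printed design |
| private variants | Poisson(5) per individual | modest per-individual private load on top of lineage variants |
| heteroplasmic share | 0.6 of private variants | heteroplasmies dominate private calls in real cohorts |
| HF law | Uniform(0.01, 0.98) | covers the whole observable band, exercising both boundaries |
| depth law | 1 + NegBin(mu = 499, size = 10) | deep mtDNA capture (~500x) with realistic overdispersion |
| error rate | 0.001 per read, symmetric | makes the 1% exclusion rule meaningful |
| private indel share | 0.15 (het) / 0.02 (hom) | emulates the indel-heteroplasmy enrichment reported in real data |

Draws: haplogroup per group frequencies; the drawn node's defining
closure emitted homoplasmic (true HF 1); private variants at uniform
random positions outside defining sites and hotspots; per call, depth
from the depth law and alt reads Binomial(depth, f') with
`f' = f(1-e) + (1-f)e`.  One integer seed drives every draw through R's
generator, so cohorts and their VCFs are byte-reproducible.

What the generator does *not* emulate: nuMT contamination, strand bias,
alignment artifacts, position-dependent error, mutational hotspot
spectra, and linkage between private variants.  Tests passing on
synthetic cohorts therefore validate the *machinery* (thresholds,
estimators, classifiers, bookkeeping) and the recoverability of designed
effects — they do not certify performance on real sequencing data.

# Numerical choices and problem sizes

Logistic IRLS tolerance 1e-12 (gradient-scale), 100 iterations.  PCA uses
`prcomp` (SVD) with the sign convention above; degenerate inputs (all
rows equal) return zero eigenvalues flagged rather than erroring.
Fisher/Mann-Whitney conventions are as above.  Scores, CIs and HFs are
plain doubles; no rounding happens anywhere except in display.

The validation suite runs at sizes chosen to finish in minutes while
keeping Monte-Carlo noise well inside the asserted margins: the Fisher
oracle sweep covers all 46,376 tables with n <= 30; the odds-ratio
recovery uses 500 replicate cohorts at 146/120; HF recovery uses ~1,500
calls per depth at depths 50/200/1000; burden power uses 200 replicates
at 100/100.

# Known limitations

The haplogroup assigner is a validated stand-in, not a HaploGrep
replacement; with real PhyloTree-scale trees its unweighted score would
need hotspot weighting.  The cascade's predictor registry encodes
published per-tool thresholds but cannot validate them for any specific
cohort's ancestry.  The conservation filter assumes the user's alignment
is trustworthy; it does not build alignments.  Association models are
single-covariate by design — no age/sex/smoking adjustment, mirroring
the analysis style it implements — and survival analysis is out of
scope.
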