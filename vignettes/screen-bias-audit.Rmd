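---
title: "Auditing multi-target and mismatch-tolerance biases in pooled CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing multi-target and mismatch-tolerance biases in pooled CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenaudit)
```

## The problem

A pooled CRISPR knockout screen reads out gene essentiality as the
log-fold change (LFC) of each guide's abundance between the screened
population and the starting plasmid library; negative LFC means depletion,
hence essentiality. Two properties of SpCas9 break the implicit assumption
that one guide measures one gene:

* **Multi-targeting.** A 20-nt spacer can match several genomic loci
  perfectly. Every extra double-strand break costs viability independently
  of which gene is cut ("cleavage toxicity"), and when the co-targeted loci
  are related genes (typically paralogs or pseudogene families), genuine
  genetic interactions -- synthetic lethality above all -- enter the
  readout.
* **Mismatch tolerance.** Cas9 cuts protospacers that differ from the
  spacer at one or two positions, especially when the mismatches sit far
  from the PAM. Such off-targets silently add cut sites and can knock out
  unintended genes.

Single-nucleotide polymorphisms inside a protospacer or its NGG PAM make
both phenomena genotype-dependent: a cell line carrying the minor allele
may lose an on-target, gain one, or lose the PAM entirely.

This package implements the audit toolchain for these biases and a
synthetic screen generator with planted ground truth so that every
statistic can be validated end to end.

## Alignment model

`find_alignments()` reports every 20-nt window, on either strand, that
matches a spacer at up to two substitutions and is followed (3', in spacer
orientation) by a canonical NGG PAM. Conventions, which matter for
interoperability:

* Coordinates are 1-based inclusive. For minus-strand hits the stored
  `start` is the forward-strand coordinate of the window's 5' end;
  `bed_to_annotation()` converts 0-based half-open BED input.
* Mismatch positions are PAM-relative: position 1 is the base adjacent to
  the PAM, positions 1-10 form the PAM-proximal seed, 11-20 the PAM-distal
  region. Substitutions are written `reference>spacer`.
* Windows or PAMs containing an ambiguous base (N) are excluded, and there
  is no alignment-count cap (a warning is emitted above a configurable
  threshold). Indels and bulges are out of scope: only substitutions are
  modeled.
* A *clean* guide has exactly one perfect alignment and no single-mismatch
  alignments (`clean_level = "1mm"`, the definition used for library
  summary tables); analyses built on the delta coefficient additionally
  require no double-mismatch alignments (`"2mm"`), because a 2-mm
  off-target is precisely what some of them hunt for.

`apply_genotype()` realigns a library against a cell line's genome:
homozygous minor alleles are substituted outright; heterozygous sites are
evaluated on both haplotypes and each site is reported at its
fewest-mismatch haplotype with a `heterozygous` flag. Dosage-style
intermediate behaviour of heterozygotes is handled downstream in the
genotype-LFC correlations, not in the aligner.

## LFC processing

`compute_raw_lfc()` (plasmid filter at 30 reads, pseudocount 1),
`normalize_median_mad()` (per-replicate median centering, MAD scaling,
optionally centering on a non-essential reference set),
`scale_by_essentials()` (so that essential-gene guides sit near -1),
`average_replicates()`, and `correct_copy_number()` implement the standard
processing chain in that order. The copy-number correction fits, per cell
line, a continuous piecewise-linear spline of LFC on relative copy number
with four interior knots at the CN quantiles 0.2/0.4/0.6/0.8, and
subtracts the fitted effect relative to its value at CN = 1. The knot
placement approximates the linear-spline CN correction used by
iterative essentiality models; their exact parameterization is not
recoverable, so ours is documented rather than guessed. Below ten distinct
CN values the fit falls back to a straight line with a warning.
Multi-target guides carry the maximum CN across their perfect loci.

## Cleavage toxicity

Per cell line, `fit_toxicity_curve()` regresses guide LFC on the number of
alignments with a second-degree polynomial. On-target fits exclude guides
with any single-mismatch alignment (off-target confounding); off-target
fits are restricted to single-target guides. Counts above `n_max = 8` are
pooled -- the tail bins are too sparse to constrain a quadratic -- and the
fit is unweighted at the guide level. `adjust_for_toxicity()` subtracts
`f(n) - f(1)` so single-target guides are untouched; counts outside the
fitted domain are clamped to the boundary with a warning. The per-cell
summary metric (`toxicity_metric()`) is the mean LFC of guides with four
perfect (or four single-mismatch) alignments, requiring at least five
guides per bin.

## Interaction statistics

All three estimators are ordinary least squares with closed forms, and the
closed forms are what the implementation computes:

* **Delta coefficient** (`delta_coefficient()`): the model
  `y_ij = alpha + beta_i + delta * 1(j = 1) + r_ij` over cells i and
  guides j, with guide 1 the guide of interest and the rest clean guides
  for the same gene, under a sum-to-zero constraint on the cell effects.
  With this balanced design `delta_hat` is exactly the mean over cells of
  (guide-of-interest LFC minus clean-guide mean), a fact the test suite
  verifies against a dummy-coded `lm()` fit to 1e-10. The constraint
  affects only `alpha`; `delta_hat` is invariant to it. Deltas below
  -0.25 are labelled substantial off-target activity.
* **Additivity test** (`additivity_test()`): a three-group means model on
  pooled guide-by-cell LFCs for A-only, B-only and double-target guides,
  with a t test of the contrast `beta_A + beta_B - beta_AB`. Observations
  are pooled as exchangeable; because guides within a cell share that
  cell's knockout context, cluster-robust (CR1, by cell) standard errors
  are available via the `cluster` argument. Under synthetic lethality
  `beta_AB` falls below `beta_A + beta_B`. The additive expectation for a
  double knockout is `expected_min_lfc()` = min(y_A, y_B, y_A + y_B).
* **Design-system solver** (`solve_design_ols()`): per-gene scores from a
  guides-by-genes incidence matrix, with the score covariance reported
  because it is the point: shared guides make gene scores linearly
  interdependent (e.g. at a readthrough locus the gene whose score rests
  on a single unique guide contaminates the other two with fixed signs).
  Rank-deficient designs return NA for non-estimable genes plus an
  explicit null-space report rather than silently picking a solution.

`coessentiality_edges()` (Pearson r at a 0.35 cutoff) and
`self_expression_screen()` connect guide-level pathology to downstream
artifacts: the latter ranks genes by the correlation of their score with
their own expression and annotates exonic single-mismatch off-targets,
with Benjamini-Hochberg q-values alongside the raw p-values.

## SNP effects

`intersect_snps_with_targets()` locates SNPs inside protospacers or PAMs
and classifies the position (proximal/distal/PAM base);
`classify_snp_effect()` applies the case analysis: a minor allele at PAM
guanine 2 or 3 destroys the motif (`pam_destroying`); at the PAM's N
position it is inert (`pam_neutral`, a category added because the motif
cannot break there); at the mismatch position of a single-mismatch
off-target with the minor allele equal to the spacer base, the off-target
becomes an on-target (`offtarget_to_ontarget`); elsewhere in an off-target
window it adds a mismatch (`mm1_to_mm2`); in an on-target protospacer it
costs efficiency (`efficiency_loss`). A SNP at the mismatch position whose
minor allele matches neither reference nor spacer keeps the site at one
mismatch; this rare corner is folded into `mm1_to_mm2`.

Associations are Pearson correlations of guide LFC with genotype dose
(0/1/2), with missing genotypes dropped pairwise, against a seeded
permutation null (default B = 100). The empirical p uses the +1 correction
to avoid zero p-values, and tail calls are made at the 95% null quantile
one-sidedly in either direction; both one- and two-sided summaries are
available since either convention is defensible.

## Bespoke statistics

The Jonckheere trend test is implemented directly (`jonckheere()`): J sums
between-group concordances with half credit for ties over ordered group
pairs; inference uses the normal approximation with tie-corrected variance
and a continuity correction, switching to full enumeration for total n of
at most 12. Fisher's exact 2x2 test (`fisher_exact_2x2()`) uses the
point-probability two-sided rule and the conditional MLE of the odds
ratio, solved from the score equation E[X] = x of the noncentral
hypergeometric family -- both choices matching the conventions of the
field's standard implementation, against which the tests cross-check.
`lowess_fit()` delegates to the established LOWESS smoother.

## The synthetic screen generator

`generate_genome()` plants every guide target explicitly -- random 20-mers
followed by a TGG PAM in single-exon genes -- so the true target structure
is known exactly and random 20-mer collisions are vanishingly unlikely
(the self-consistency of aligner vs planted sites is itself a test).
Paralog families copy designated sites into the partner gene with
substitutions at configured PAM-relative positions; pseudogene copies add
perfect cut sites without knockout effects; readthrough constructs overlay
a fusion annotation across two genes with one guide unique to the second.
`plant_snps()` places SNPs at named positions of planted sites.

`simulate_screen()` computes, per guide g and cell c,

    y = a_c * tau(N) + sum_G d_G * e_Gc + sum_(A,B) d_A d_B i_ABc
        + gamma_c * (CN - 1) + eps

with per-site cutting efficiency eta the product of position-specific
tolerance weights w(pos) over the site's mismatches (0 if the genotype
breaks the PAM; heterozygotes get the haplotype mean), expected cut count
N the sum of eta over sites, knockout dosage d_G = 1 - prod(1 - eta)
(capped at 1 by construction), and toxicity
tau(N) = t1 * max(N - 1, 0) + t2 * max(N - 1, 0)^2, so a single cut -- or
none -- is toxicity-free. Non-targeting controls receive noise only.

Defaults are the study conditions used throughout: 100 cell lines, noise
sd 0.1, t1 = -0.05 and t2 = -0.01 (per extra cut site, LFC units), Cas9
activity a_c uniform on [0.2, 1], essential-gene effect -1 on 20% of
functional genes, CN slope gamma_c uniform on [-0.5, -0.1], and tolerance
weights 0.05 at seed positions 1-10, ramping 0.2 to 0.8 over 11-19 and
0.9 at position 20 -- a shape with minimal seed tolerance and maximal
tolerance at the 20th position. Double-mismatch efficiency multiplies the
two weights; multiplicativity is an assumption, recorded in the truth
object like every other planted parameter. Optional read counts are
negative binomial around plasmid * 2^LFC with dispersion 0.1; LFC-level
output is the primary path.

What the generator does **not** emulate: real human sequence composition
and mappability, chromatin and repair-outcome variability, guide-intrinsic
activity differences beyond the planted effects, indel-mediated
off-targets, and measurement artifacts of counting (beyond simple
overdispersion). Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to everything
real screens do.

## Named fixtures and the audit

`make_fixture()` provides five deterministic scenarios -- paralog
synthetic lethality (`myl12_like`), the mismatch-tolerance expression
confound (`sox9_sox10_like`), the readthrough design (`tmed7_ticam2_like`),
planted SNP effects (`snp_pam_like`), and double-mismatch promiscuity
(`double_mm_like`). `run_audit()` chains alignment, annotation, summaries,
toxicity fits, gene scores (per-gene mean guide LFC), the self-expression
screen (flagging genes with score-expression correlation at or below -0.3
that carry exonic single-mismatch off-targets), delta coefficients and the
SNP analysis, with stage toggles, a seeded permutation stage, a run log,
and optional CSV reports. `select_problematic_double_mm()` applies the
published selection (one on-target, no 1-mm alignments, at least five 2-mm
alignments with the distal mismatch at position 20) and compares each
delta against a 95% band of deltas from genes targeted by clean guides
only.

The numbered scripts under `analysis/` run these audits as a narrative
workflow at the sizes used for validation (40-100 cell lines, libraries of
60-180 guides, 2000-guide toxicity screens); each writes its tables under
`results/`.

## Numerical choices and degenerate inputs

Zero residual variance (noiseless fixtures) yields p = 1 for a zero
contrast and p = 0 otherwise instead of 0/0; zero-MAD replicates, constant
genotypes, empty guide classes and absent clean guides raise errors naming
the offending unit; empty strata propagate NA with counts; conditional-MLE
odds ratios at the support boundary return 0 or Inf; and all simulation,
permutation and null-band procedures take explicit seeds, making every
pipeline product a pure function of inputs plus configuration.

## Known limitations

Exonic annotation uses simple interval overlap (1 bp suffices) without
splice awareness; the aligner is a direct-search implementation intended
for synthetic and targeted genomes, not an FM-index scaling to
genome-wide human search; iterative guide-activity/offset estimation of
full essentiality models is intentionally out of scope (the additive OLS
core is the object of study); and heterozygous genotypes are treated as
dosage-intermediate in efficiency, which ignores allele-specific repair.
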