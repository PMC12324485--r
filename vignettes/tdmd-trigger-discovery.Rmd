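---
title: "Discovering TDMD triggers with tdmdkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering TDMD triggers with tdmdkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdmdkit)
```

# The scientific problem

In target-directed miRNA degradation (TDMD), a specialized target RNA — the
*trigger* — induces decay of the miRNA bound to it, through a ZSWIM8/EBAX-1
E3 ligase that degrades the Argonaute protein rather than the usual
target-repression outcome. Identifying the trigger behind a developmental
miRNA decay event requires several coupled analyses: finding which RNA the
miRNA family physically binds (chimeric eCLIP hybrid reads), showing that
those interactions accumulate when decay is blocked (genotype enrichment),
characterizing the base-pairing architecture of the binding sites, asking
whether decay proceeds with or without 3′ tailing/trimming of the miRNA,
separating decay-level from biogenesis-level effects, and quantifying how
many miRNA molecules each trigger molecule can destroy. `tdmdkit` implements
this workflow end to end and ships a synthetic-data generator that plants a
known trigger, so every stage can be validated by parameter recovery.

This vignette records the models, the tunable parameters with their defaults
and rationale, the numerical choices, and the limitations a user should know
about. It states no empirical result beyond what the package's test suite
and `scripts/acceptance.R` themselves compute.

# Chimera calling

**Preprocessing** follows the standard small-RNA order: (1) trim from the
first occurrence of the 3′ adapter (default `UGGAAUUCUCGGGUGCCAAGG`);
(2) collapse exact duplicate sequences, recording multiplicity;
(3) remove 4-nt UMIs from both ends; (4) drop reads under 18 nt. Collapsing
*before* UMI removal is deliberate: two molecules with the same insert but
different UMIs remain distinct, so the collapse step removes PCR duplicates
exactly and nothing else. The per-step read counts are logged and are
non-increasing from the collapse step on.

**Hybrid detection** requires a full-length occurrence of a *guide* miRNA as
a read substring (Hamming distance ≤ `max_mirna_mismatches`, default 0;
passengers are excluded because trigger discovery concerns guide-loaded
RISC). The flanking remainder, if at least `min_target_len` = 16 nt, must
map uniquely to one transcript locus by exact 12-mer seeding (flank start,
middle, and end) plus ungapped extension. *Unique* means the best locus
beats the runner-up by ≥ 2 matching bases and matches the flank nearly
exactly (≥ length − 2). Reads failing any stage carry a rejection reason
(`no_mirna_arm`, `multiple_mirna_arms`, `target_too_short`,
`ambiguous_target`); a read with two disjoint full-length miRNA occurrences
is rejected rather than split, since miRNA–miRNA chimeras are out of scope.
Coordinates are 0-based half-open on the transcript sense strand throughout.

**Normalization.** Each sample's interaction table reports RPM — reads per
million *total accepted hybrids* — so the per-sample RPM column always sums
to 10⁶. This makes samples comparable without any external size factor, at
the cost that a strongly enriched interaction slightly depresses the RPM of
everything else in that sample (visible below in the enrichment values).

**Binding sites** are single-linkage clusters of target spans with overlap
≥ 1 nt (computed by a sorted sweep, which is exact for interval overlap
graphs); the site span is the fragment union and the summit the leftmost
position of maximal fragment coverage. The pipeline wrapper clusters pooled
hybrids across all samples so that site definitions are shared.

# Trigger discovery

Per (miRNA, transcript, site), enrichment is
`(mean RPM_mut + p) / (mean RPM_wt + p)` with pseudocount `p` = 0.01 RPM on
both sides (bounded ratios with zeros, and depletions remain visible);
means are arithmetic over replicates, not pooled counts, since RPM already
handles library size. The abundance filter keeps pairs with
`max(mean RPM_wt, mean RPM_mut) > 0.1` — the permissive reading, applied to
whichever group is larger, and configurable. Ranking is descriptive
(descending enrichment; ties broken by higher mutant mean, then ids); no
p-value is attached, significance lives in the count-based module.

Family aggregation per site reports member coverage (distinct members with
any hybrid / family size) and the summed-RPM aggregate enrichment
`(Σ mean RPM_mut + p) / (Σ mean RPM_wt + p)`; candidates need coverage
≥ 0.5 to be ranked. Summing member RPM before forming the ratio weights
members by abundance; this is one of several defensible aggregation choices
and is fixed here as the definition.

# Duplex architecture

The intermolecular duplex is predicted by a score-based alignment DP rather
than a thermodynamic model: the downstream classification needs the pairing
*topology* (which miRNA positions pair), not a free energy, and a score
model keeps every parameter explicit and testable. Scoring: Watson-Crick
+2, G:U +1, mismatch −1, gap open −2, gap extend −1; strands are
antiparallel and the pair set non-crossing; terminal unpaired stretches are
free, interior unpaired stretches are charged as mismatches plus one affine
gap. The empty pair set (score 0) is always admissible, so a target with no
complementarity scores 0 with no pairs. Ties are broken deterministically:
more Watson-Crick pairs, then more seed pairs, then leftmost target start.
The test suite proves the DP equal to an independent exhaustive formulation
of the same pair-set optimum (pure enumeration on small instances validates
a polynomial last-pair chain oracle, which then checks the DP on 200 random
instances).

Classification uses fixed regions — seed g2–g8, central g9–g12, supplemental
g13–g16, tail g17–end (a pair at g1, rare because target position t1 is
typically unpaired, is counted in no region). Seed classes: `perfect_2_8`
(all of g2–g8 Watson-Crick; G:U does not qualify as perfect), `offset_3_8`
(g3–g8 paired, g2 not), `partial` (≥ 4 of g2–g8), else `none`. A duplex is
TDTT-prone — predicted to expose the miRNA 3′ end for tailing/trimming —
when ≥ 2 pairs fall in the last 3 miRNA positions *and* the 3′ pairing
extent (paired positions in g9..end) is ≥ 8. These thresholds are package
decisions: the literature calls such pairing "extensive" without
quantifying it.

A caveat discovered during validation and worth stating: under this scoring,
*incidental* 3′ pairing is common. Divergent family members still share
50–70% of their 3′ sequence with a site designed against one member, G:U
wobble adds options, and the Watson-Crick tie-break admits zero-net bulged
pairs; non-designed members therefore sometimes classify as TDTT-prone at a
site designed for another member. The classifier is faithful to its scoring
model; conclusions about "extensive" 3′ pairing should rest on the extent
and tail-region counts, not the boolean alone. For the same reason the
synthetic generator defines its planted "degraded" and "3′-paired" member
sets constructionally (which seed complement the site carries, how many 3′
positions were planted), never via the classifier.

The t-position map anchors the register on the 5′-most seed pair and indexes
trigger nucleotides by the miRNA position opposite (t8 opposite nucleotide
8); indices beyond the miRNA 3′ end extrapolate upstream with unit steps, so
t35 is 27 nt upstream of t8.

# isomiR decomposition

A read is assigned to a miRNA only if its first 14 nt exactly match the
canonical 5′ end (5′ isomiRs are out of scope). The templated reference is
the canonical sequence concatenated with ≥ 10 nt of genomic downstream
context; the templated length is the longest read prefix matching this
reference, the remaining suffix is the untemplated tail, and
`trim_len = max(0, canonical_length − templated_len)`. Greedy maximal
matching resolves the trim-versus-tail ambiguity in favor of "templated":
a 3′ addition identical to the genomic context is classified as a templated
extension (flagged, so the ambiguity rate is visible), not as a tail.
Tails longer than 5 nt mark the read unassigned as a likely mis-assignment.
The classifier is verified against exhaustive enumeration of the complete
read space of a 6-nt toy miRNA with 3-nt context (all 4¹…4⁹ = 349,512
reads).

Profiles report class fractions over assigned reads (canonical / trimmed /
tailed / trimmed+tailed partition; fractions sum to 1), mean trim length,
and tail nucleotide composition. Genotype comparisons use a two-proportion
z-test per miRNA on the chosen metric (a trimmed+tailed read counts as both
trimmed and tailed), Benjamini-Hochberg corrected, with groups under 50
reads flagged low-power.

# Abundance, fold changes and decay inference

Size factors are the per-sample totals of a *normalizer class* — all
features, the piRNA class, or spike-ins — divided by their geometric mean
across samples, mirroring size-factor specification by total/piRNA/spike-in
reads; normalized counts are `count / factor`. Note a property of this
scheme: rescaling one sample's counts rescales the geometric mean too, so
all normalized counts shift by one shared constant; every ratio between
normalized counts, and hence every fold change (exactly, without the
pseudocount), is invariant. Which normalizer to use is an analysis choice
the package exposes rather than decides; piRNA normalization is appropriate
when the perturbation spares piRNAs but moves a large miRNA class.

Fold changes are `log2((mean_b + c)/(mean_a + c))` with pseudocount
`c` = 0.5 on normalized means, after a baseMean ≥ 10 filter. Significance
comes from an exact permutation test on |log2fc|: all distinct group-label
assignments are enumerated when there are at most 5040 (otherwise 10⁴
random ones under a fixed seed), and p is the fraction reaching the observed
statistic. A negative-binomial model fit is intentionally not used: the
downstream logic consumes only a fold change and a significance flag, and
the permutation test makes no distributional assumption. Two granularity
facts matter: assignments come in complementary pairs with identical
|log2fc|, so at 3 vs 3 replicates the smallest attainable p is 2/20 = 0.1;
at 5 vs 5 it is 2/252, and the attainable rejection rate at α = 0.05 is
12/252 ≈ 0.048, which is why the suite calibrates type-I error at 5 vs 5.

Decay amplitude is `log2(normalized L1 mean / normalized embryo mean)`
(negative = decay), both stages under the same normalizer. The strand-level
rule encodes the guide/passenger logic: passengers are biogenesis
byproducts, so `decay_level` requires a guide fold change ≥ 1.5 (q < 0.05)
with the passenger below 1.3; both strands up ≥ 1.5 (q < 0.05) is
`biogenesis_level`; anything else is `no_call`. Pathway congruence compares
a double mutant to its single mutants on the log2 scale with a 0.5 log2
tolerance: phenocopying the stronger single mutant (epistasis) means
`same_pathway`; matching the sum means `additive`.

# Stoichiometry

Standard curves are ordinary least squares of Ct on log10(copies), requiring
≥ 4 dilution points over ≥ 3 decades; efficiency is `10^(−1/slope) − 1`
(slope −3.3219 ⇔ efficiency 1). Copies per reaction invert the curve,
`10^((Ct − intercept)/slope)`, and divide by input ng. Excess family
molecules extrapolate from one absolutely quantified reference member:
`excess = Σ_i ratio_i · ref_copies · (FC_i − 1)`, which is algebraically
identical to the direct mutant-minus-wild-type total. Trigger potency is
excess copies over trigger copies per ng, reported raw and rounded (nearest
integer at ≥ 20, one decimal below — matching how such ratios are
conventionally presented). Peak expression from a stage-mixed sample is
`measured / Σ_s w_s r_s` given mixture weights `w` and the temporal profile
`r` relative to peak; the estimate can never fall below the measurement when
all `r ≤ 1`. smFISH spots are binned to `max(1, round(intensity/unit))`
molecules with the unit calibrated as the median reference-stage spot
intensity (≥ 20 spots); every detected spot counts at least one molecule,
since sub-unit handling is not otherwise defined.

# The synthetic-data generator

The generator's defaults define the study conditions; they are chosen once
and are not tuned to test outcomes.

* **Family**: 8 guides of 22 nt sharing positions 2–8 exactly, 3′ halves
  pairwise ≥ 30% divergent; one passenger per guide from a synthetic hairpin
  rule (reverse complement with positions 1 and 10 substituted — only the
  guide/passenger labeling matters downstream); 20-nt genomic downstream
  context per record.
* **Transcriptome**: one 400-nt trigger lncRNA. Site 1 complements the
  shared seed exactly for all members, with a planted 12-nt 3′ complement
  for member 1 (the designated 3′-paired member). A single sequence cannot
  simultaneously complement several divergent 3′ ends at one register, so
  only the maximal configured member is planted exactly; the study's two
  3′-paired members are represented by one designed member. Site 2
  complements positions 3–8 only (the base opposite position 2 cannot pair,
  and the downstream flank is built unable to capture position 2 through a
  bulge) with a 10-nt 3′ complement for member 3. Fifty decoy transcripts,
  60% carrying a conventional seed-only site whose upstream flank is
  non-pairing for member 1.
* **Chimeric libraries**: interactions sampled proportional to duplex score;
  trigger-site interactions of degraded members multiplied by λ = 4 in the
  decay-deficient genotype (λ = 1 disables enrichment); 10% target-only
  background reads (the real hybrid:background ratio is not published; this
  default exercises the rejection path); fragments bracket the protected
  site with 0–4 nt jitter and a 22-nt minimum footprint; reads are
  `UMI(4) + [miRNA ∥ fragment, Bernoulli(0.5) order] + UMI(4) + adapter`,
  each molecule emitted Poisson(0.3) + 1 times (modest duplication that
  exercises UMI-aware collapse at full depth). 2 × 10⁵ molecules per
  library; single-end, pre-merged reads; no sequencing-error model.
* **Counts**: negative-binomial (dispersion 0.05) around a fixed baseline
  panel (family guides and passengers, 50 background guides, 60 piRNAs, 6
  spike-ins) at 10⁶ expected depth with ±15% library-size variation. Family
  guides decay 7.1-fold across the embryo-to-L1 transition in wild type and
  are restored in the decay-null genotype; passengers, piRNAs and spike-ins
  are genotype- and stage-independent.
* **isomiRs**: independent trim/tail coins per read (so class fractions
  equal the configured probabilities exactly in expectation): trimming 0.05
  baseline, elevated to 0.2 only for 3′-paired members in the decay-null
  genotype; tailing 0.1 everywhere; tails of 1–3 nt drawn U 0.7 / A 0.2 /
  C 0.05 / G 0.05 (uridylation-dominant), with the first tail base forced to
  differ from the next templated base, as required for it to be untemplated.
* **Quantification fixtures**: Ct = 40 + slope·log10(copies) + N(0, 0.15)
  with efficiency 0.95; standards 10²–10⁸ in triplicate; planted truths of
  2 × 10⁵ guide copies/ng, 9 × 10⁴ trigger copies/ng, a 4 × 10⁵ peak
  attenuated by a 50/50 stage mixture at relative expression 0.2/1.0; smFISH
  unit intensity 1000 (CV 0.15), reference-stage spots all single molecules,
  late-stage spots a 1–4 molecule mixture, and a planted 37.6-fold increase
  in molecules per embryo.

Retargeting experiments set `site1_seed_from` to an outsider miRNA
(`n_outsider_mirnas ≥ 1`): site 1 then complements the outsider's seed,
which constructionally flips the degraded set — hybrid enrichment and
guide-strand stabilization move from the family to the outsider, mirroring
a seed-swap experiment qualitatively.

What the generator does **not** emulate: sequencing errors, splice variants
and genome-level mapping ambiguity, RNA secondary structure (of either the
trigger or the miRNA), crosslink-induced mutations, real hybrid/background
proportions, biogenesis-coupled passenger dynamics, and multi-member 3′
pairing at one site. Passing recovery tests therefore demonstrate the
pipeline's correctness on clean interaction signal, not robustness to every
artifact of real libraries.

# Problem sizes used by the test and acceptance suites

Unit tests run on a reduced family (4 members, 8 decoys, 4 × 10³ molecules
per library). The recovery studies run at the full study conditions — 8
members, λ = 4, 4 replicates per genotype, 2 × 10⁵ molecules per library —
over 20 seeds for trigger ranking, and 3 replicates at 10⁶ counts over 20
seeds for decay-fold recovery; `scripts/acceptance.R` repeats the full
pipeline on 3 seeds plus the desk calculations. Permutation calibration
uses 5 vs 5 replicates for the granularity reason above, and the
strand-level decay calls are demonstrated at 6 vs 6: their q < 0.05 rule is
unreachable at 3 vs 3, where the permutation p floor of 0.1 survives any
multiple-testing correction. These sizes are the package's validation
design.

# Known limitations

* The duplex model scores topology, not thermodynamics; temperature has no
  analog and G:U is a flat +1. Pairing diagrams agree with free-energy
  methods on clear architectures but can differ in bulge placement.
* TDTT-proneness is a thresholded summary of a permissive alignment; see
  the incidental-pairing caveat above.
* The permutation test is exact but coarse at small replicate numbers
  (smallest p = 2/20 at 3 vs 3); experiments needing p < 0.1 at n = 3
  should use more replicates or a model-based test outside this package.
* Enrichment ranking is descriptive; RPM renormalization compresses
  enrichment toward 1 as the trigger's share of the library grows.
* The chimera caller requires full-length miRNA arms; trimmed/tailed arms
  in chimeras are not called (isomiR analysis operates on small-RNA data).
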