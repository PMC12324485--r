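# tdmdkit

Discovery and characterization of target-directed miRNA degradation (TDMD)
trigger RNAs, from chimeric CLIP-style sequencing through absolute
stoichiometry.

Most miRNA-target interactions repress the target. In TDMD the logic is
inverted: a specialized target RNA (the *trigger*, often a lncRNA) directs
degradation of the miRNA itself, via a ZSWIM8/EBAX-1 E3 ubiquitin ligase that
destroys the Argonaute protein carrying the miRNA. `tdmdkit` implements the
computational workflow for finding and characterizing such triggers for a
seed-sharing miRNA family:

* **Chimera calling** — UMI-aware preprocessing of chimeric eCLIP reads
  (adapter trim, duplicate collapse, UMI removal, length filter), hybrid
  detection (full-length guide-miRNA arm + unique k-mer mapping of the target
  fragment), normalization to reads per million total hybrids (RPM), and
  single-linkage clustering of target fragments into binding sites.
* **Trigger discovery** — per-pair genotype enrichment
  `(mean RPM_mut + p) / (mean RPM_wt + p)` between decay-deficient and
  wild-type libraries with an abundance filter (> 0.1 RPM), descriptive
  ranking, and family-level aggregation per binding site (member coverage and
  summed-RPM enrichment).
* **Duplex architecture** — an intermolecular miRNA:target alignment DP
  (Watson-Crick +2, G:U +1, mismatch −1, affine gaps −2/−1; non-crossing,
  antiparallel) and classification into seed classes (perfect g2–g8, offset
  g3–g8, partial, none), region pair counts (seed g2–g8, central g9–g12,
  supplemental g13–g16, tail g17–end), 3′ pairing extent, and a
  TDTT-proneness call; plus trigger "t position" register arithmetic
  (t8 = the base opposite miRNA nucleotide 8).
* **isomiR decomposition** — 3′ trimming/tailing analysis against the
  canonical sequence plus genomic downstream context (greedy maximal
  templated matching), per-miRNA isoform profiles, and two-proportion
  genotype comparisons with Benjamini-Hochberg correction.
* **Abundance and decay** — size factors from a normalizer class (total,
  piRNA, or spike-in counts over their geometric mean), fold changes with an
  exact permutation test, embryo-to-L1 decay amplitudes, decay-level versus
  biogenesis-level calls from the guide/passenger strand contrast, and
  single- versus double-mutant pathway-congruence classification.
* **Stoichiometry** — qPCR standard curves (Ct vs log10 copies; efficiency
  `10^(-1/slope) − 1`), absolute copies per ng, excess family molecules
  `Σ ratio_i · ref · (FC_i − 1)`, molecules degraded per trigger molecule,
  stage-mixture deconvolution of peak expression
  (`peak = measured / Σ w_s r_s`), and smFISH spot-to-molecule binning.
* **Synthetic data** — a generator that plants a complete ground-truth
  experiment (seed-sharing family, trigger lncRNA with a perfect-seed site
  and an offset-seed site, decoy transcriptome, genotype-dependent hybrid
  enrichment, stabilized guides with neutral passengers, trimming-elevated
  isomiRs, qPCR/smFISH fixtures), so the entire pipeline is testable without
  any external download.

## Worked example

Simulate a small experiment (8-member family, trigger-hybrid enrichment
λ = 4, two replicates per genotype, 5 × 10⁴ chimeric molecules per library),
call hybrids, and rank trigger candidates:

```r
library(tdmdkit)

cfg <- simConfig(rng_seed = 42, family_size = 8, n_replicates = 2,
                 hybrid_depth = 5e4)
fam <- makeMirnaFamily(cfg)
tr  <- makeTranscriptome(cfg, fam)

libs <- list()
for (gt in c("wild_type", "decay_null")) for (r in 1:2)
  libs[[paste0(gt, "_rep", r)]] <-
    simulateChimericReads(cfg, fam, tr$transcripts, tr$truth, gt, r)

res <- runChimeraPipeline(libs, fam, tr$transcripts)
enr <- computeEnrichment(res$tables[1:2], res$tables[3:4])
g   <- guideRecords(fam)
cand <- aggregateFamilySites(enr, setNames(g$family_id, g$id))
head(as.data.frame(cand), 3)
#>   transcript_id            site_id family_id member_coverage aggregate_enrichment rank
#> 1    lnc-trig-1 lnc-trig-1:236-266     miR-f               1            3.2608083    1
#> 2    lnc-trig-1 lnc-trig-1:116-146     miR-f               1            3.1446573    2
#> 3       tx-d010    tx-d010:149-179     miR-f               1            0.8548067    3
```

The two planted trigger sites rank first and second: every family member is
seen in hybrids there (coverage 1.0), and their summed-RPM enrichment (~3.2)
sits where the planted λ = 4 lands after renormalization to total hybrids,
far above the decoy sites (~0.85, depressed for the same reason).

The stoichiometry module turns absolute quantifications into trigger potency.
With 6.39 × 10⁶ excess family molecules per ng of decay-deficient L1 RNA and
89,836 trigger copies per ng:

```r
moleculesPerTrigger(6.39e6, 89836)$rounded
#> [1] 71
```

i.e. each trigger molecule accounts for ~71 degraded miRNA molecules — an
exceptionally potent trigger.

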