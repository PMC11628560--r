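# mefi — fragmentomics of circulating cell-free mitochondrial DNA

Plasma cell-free DNA of mitochondrial origin (ccf-mtDNA) is fragmented
differently from its nuclear counterpart: fragments are shorter (median
~128 bp vs ~166 bp), their 5′ ends favour G and A, and the fragmentation
pattern varies along the 16.6-kb circular mitochondrial genome with its
functional regions (D-loop, mRNA, rRNA, tRNA) and with disease state.
`mefi` implements the **m**itochondrial **e**valuation of
**f**ragmentomics for cancer **i**nvestigation workflow: it turns aligned
paired-end reads (or plain fragment tables) into interpretable
fragmentomic features, calls filtered heteroplasmic variants and relative
mtDNA copy number, and trains random-forest classifiers for cancer
detection and tissue-of-origin prediction. A fragment-cohort simulator
with known ground truth makes every stage testable without sequencing
data.

The package is aimed at researchers analysing mitochondrial capture or
whole-genome sequencing of plasma cfDNA who want the complete feature
extraction and modelling path in one place, on a circular coordinate
system that is handled correctly end to end.

## The quantities computed

For each sample the package computes, over the circular genome of length
*L* (1-based, closed; site *L* is adjacent to site 1):

- **Fragmentation profile (FSD score).** Fragments are split at the
  sample median length (≤ median ⇒ short). At every site *i*,
  `FSD(i) = (long_depth(i) + 1) / (short_depth(i) + 1)`, corrected for
  local GC content by LOESS regression (span 0.75, degree 1, GC measured
  in a 101-bp circular window) and z-scaled with the population standard
  deviation. Samples are compared with the z-scaled site-wise **median
  profile of a healthy-control panel** through Spearman correlation,
  peak calls (runs strictly above/below 0, width ≥ 5 bp), *new* peaks
  (apex more than 20 bp from every reference apex, circularly), and 255
  genome windows carrying positive/negative areas and Euclidean
  distances.
- **5′ end features.** Each fragment contributes a light-strand 5′ end
  (leftmost site) and a heavy-strand 5′ end (complement at the rightmost
  site). End-base proportions are normalized by the genome's base
  composition into **end-base preferences** (1 = no preference), and the
  256 possible 5′ 4-mer motifs yield the **motif diversity score**
  `MDS = Σᵢ −Pᵢ·log(Pᵢ)/log(256) ∈ [0, 1]`.
- **Feature vector.** Profile correlation, new-peak count, 3 × 255 window
  features, median fragment size, 4 end-base preferences, 256 motif
  proportions and the MDS — 1,029 named features per sample.
- **Variants and copy number.** Per-site minor-allele calls pass five
  filters (≥3 reads per strand, MAF ≥ 1%, outside repeat tracts
  66–71/303–311/514–523/12418–12425/16184–16193, no low-MAF C>A / G>T
  oxidation artifacts, binomial support tests at P ≤ 0.001), origin
  classification against paired tissue calls, and
  `CN = 2·depth(mt)/depth(nuclear)`.
- **Models.** Random forests (500 trees, 6 candidate features per split)
  for MT-vs-control detection (the forest's malignancy probability is the
  **MEFI score**), evaluated with seeded stratified tenfold CV, empirical
  ROC/AUC with DeLong CIs, Youden cutoffs and Clopper–Pearson CIs; a
  99.5%-specificity gate feeds a six-class tissue-of-origin forest with
  top-1/top-2 accuracies; leave-one-batch-out evaluation guards against
  batch confounding.

## Worked example

```r
library(mefi)

lo  <- mt_reference()          # vendored genome + region annotations
ref <- lo$reference
#> MtReference 'NC_001807.4': circular, 16571 bp

round(100 * sapply(c("D-loop", "mRNA", "rRNA", "tRNA"), function(cls)
  gc_content(ref, region_sites(lo$annotations, cls, ref$length))), 2)
#> D-loop   mRNA   rRNA   tRNA
#>  47.15  45.09  44.05  37.83
```

G+C content is highest in the D-loop and lowest in the tRNA genes, with
mRNA and rRNA indistinguishable — the ordering that co-varies with
protein occupancy and region-specific fragmentation.

```r
cfg  <- sim_config(ref = ref, annotations = lo$annotations)
cfgP <- sim_config(ref = ref, annotations = lo$annotations,
                   n_fragments = 100000)
panel <- lapply(1:30, function(i)
  site_profile(simulate_sample(cfgP, "HC", seed = 100 + i), ref))
ref_z <- reference_profile(panel)      # median HC profile, z-scaled

cohort <- simulate_cohort(cfg, c(MT = 15, HC = 15), seed = 1)
fm <- feature_matrix(cohort$samples, ref, ref_z)
dim(fm$features)
#> [1]   30 1029

round(fm$features["MT_001", c("profile_correlation", "new_peak_count",
                              "median_fragment_size", "mds")], 4)
#>  profile_correlation       new_peak_count median_fragment_size
#>               0.6761             182.0000             122.0000
#>                  mds
#>               0.9871
```

The malignant sample has the programmed short fragments (122 bp vs the
healthy 128-bp centre) and an elevated motif diversity score.

```r
model <- train_detection(fm$features, fm$meta$group, control_group = "HC",
                         seed = 7)
model$cv_eval
#> EvalReport: AUC 1.0000 (95% CI 1.0000-1.0000), cutoff 0.5070
#>   sensitivity 1.0000 (0.7820-1.0000), specificity 1.0000 (0.7820-1.0000)
```

At the simulator's default effect sizes the groups are fully separable;
`mefi_score(model, features)` scores new samples, `too_gate()` +
`train_too()` handle tissue-of-origin, and `leave_one_batch_out()` checks
batch robustness. A thin command line (`inst/scripts/mefi`) wraps
`simulate → extract → train → score → evaluate` for shell pipelines.

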