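---
title: "Methods: ccf-mtDNA fragmentomics, variant filtering and classification"
author: "mefi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ccf-mtDNA fragmentomics, variant filtering and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
simulator does and does not emulate, and the numerical choices made where
the design was genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The circular coordinate system and the reference genome

All coordinates are 1-based and closed on a circle: site `L` is adjacent
to site 1, and an interval with `start > end` wraps through the origin
(the D-loop is the canonical example). Every operation — coverage,
windows, peaks, motifs, distances — honours the wrap.

The package vendors a complete public human mitochondrial genome,
NC_001807.4 (16,571 bp), together with the standard gene annotation
(D-loop, the 13 protein-coding mRNAs, 12S/16S rRNA, the 22 tRNAs, and the
7S segment of the D-loop) lifted into that sequence's coordinate frame:
NC_001807.4 carries two extra cytosines in the 303–315 homopolymer tract
relative to the revised Cambridge reference sequence (rCRS,
NC_012920.1), so all annotation coordinates from site 316 onward shift by
+2. The rCRS itself is not redistributed with the package; analyses of
rCRS-aligned data should supply their own FASTA and annotation table via
`load_reference()` — everything downstream is generic in `L`. Because of
true sequence differences between the two accessions, region G+C
fractions of the vendored genome (D-loop 47.15%, mRNA 45.09%, rRNA
44.05%, tRNA 37.83%) differ by 0.3–1.3 percentage points from the values
reported for the rCRS (46.79/44.68/44.88/36.63); the qualitative ordering
— D-loop highest, tRNA lowest, mRNA ≈ rRNA — is identical. The test
suite asserts both the ordering and, deliberately, the rCRS values at
their printed precision, so the discrepancy is visible rather than
hidden.

The repeat-region filter intervals (66–71, 303–311, 514–523,
12,418–12,425, 16,184–16,193) are rCRS coordinates and are the
`call_variants()` default; for vendored-genome pileups the same +2 lift
applies and the intervals can be passed explicitly.

## Fragments and 5′ ends

A sequenced fragment is the outer span of a properly paired template
(both mates MAPQ ≥ 20, duplicates and secondary alignments excluded;
alignment, dedup and NUMT filtering are upstream concerns). Each
fragment exposes two 5′ ends: light strand at the leftmost site and
heavy strand at the rightmost site (complement base, reverse-complement
motif). Both ends enter every end-feature tally; a region-restricted
tally counts an end only when its 5′ site lies inside the region. End
bases and motifs are read from the reference at the terminal coordinates
— fragment tables then need no read sequence, and capture-scale depth
averages out terminal sequencing errors. Fragments shorter than 4 bp
contribute end bases but no motif.

One consequence of counting both ends deserves note: the pooled end-base
distribution mixes each base with its complement, so on a genome with
asymmetric composition (human mtDNA has ~31% C but only ~13% G per
reference strand) even perfectly uniform cleavage does not give
preference 1 for every base. The null-recovery test therefore uses a
composition-balanced toy genome, where the pooled null is exactly
neutral. Single-strand tallies can be recovered from
`five_prime_ends()` if needed.

## End-base preference and motif diversity

`preference(b) = proportion(b) / genome_fraction(b)` — the ratio form
makes 1 the no-preference point and is scale-free; a difference form is
available for sensitivity analysis. The motif diversity score is the
normalized Shannon entropy of the 256 4-mer frequencies,
`MDS = Σ −Pᵢ log Pᵢ / log 256`, which is 0 for a single motif and exactly
1 for the uniform spectrum (the quantity `scripts/acceptance.R`
recomputes). All 256 motifs are tracked; absent motifs carry
frequency 0.

## The fragmentation profile

Per sample: fragments are split at the median length (ties count as
short — deterministic under duplicated lengths); per-site long and short
coverage depths are accumulated in O(n + L) with a circular difference
array; the raw FSD score is `(long + 1)/(short + 1)` — the unit
pseudocount defines the score at uncovered sites (neutral ratio 1) and
is negligible at the hundreds-fold depths the profile is meant for; a
LOESS fit of the raw score on the 101-bp-window GC track (span 0.75,
degree 1) is subtracted and the grand mean added back, removing the GC
trend while preserving scale; finally the profile is z-scaled with the
population (n-denominator) standard deviation, since the 16,569-site
profile is the full population of sites, not a sample. A constant GC
track or zero-variance profile degrades to an identity/zero output with
a warning rather than an error.

The reference profile is the site-wise **median** of the GC-corrected
profiles of a healthy panel, z-scaled after the median — the median of
already-z-scaled members would re-weight panel members by their own
variances, and the median-then-scale order is also the natural reading
of a "median profile … scaled into the z-score". The median makes the
reference robust to a contaminated panel member.

## Peaks and windows

Peaks are maximal circular runs strictly above (or below) the baseline 0;
sites exactly at baseline break runs, since they carry no signal. Runs
shorter than 5 bp are discarded. The apex is the site of maximum |z|,
ties broken to the smallest genomic index. A sample peak is *new* when
its apex is more than 20 bp (circularly) from every reference apex; both
signs are compared by default (`match_sign` restricts it). No minimum
height is imposed beyond the baseline — none is defined for the rule.
A practical property worth knowing: a new peak can only be detected where
the reference profile does not already have an apex nearby, so
recoverability of an induced locus depends on the local reference
landscape, and a noisy (shallow or small) panel inflates reference
apexes and masks genuinely new peaks. This is why the panel in the test
suite is simulated at 30 members × ~770× coverage.

The genome is tiled into 255 windows of `ceiling(L/255)` = 65 bp (the
last window is shorter; exact equality is impossible since 255 does not
divide the genome length). Window areas integrate the full z track above
and below 0 — not only sites inside called peaks — which is
deterministic and lets the positive and negative areas balance exactly
on a z-scaled profile; Euclidean distances to the reference are computed
per window.

## Variant filtering

Five conjunctive filters on per-site strand-split allele counts: (1) ≥3
mutant reads on each strand; (2) minor-allele frequency ≥ 1%; (3) site
outside the homopolymer/repeat tracts; (4) C>A / G>T substitutions below
10% MAF removed as guanine-oxidation artifacts; (5) binomial support at
P ≤ 0.001. The named binomial tests are defined here as: *mutant rate* —
the one-sided tail `P(X ≥ alt | n = depth, p = p_err)` with `p_err` the
mean Phred-implied error over the site's calls; *mutant base quality* —
the same tail restricted to high-quality calls (Phred ≥ 30), so a
variant carried only by low-quality calls loses its support while under
uniform qualities the two tests coincide. (A literal "alt high-quality
fraction not lower than the reference's" one-sided test was considered
and rejected: under equal quality distributions its P is ~0.5, so *no*
true variant could ever pass at P ≤ 0.001 — the form chosen keeps
"pass iff P ≤ α" coherent.) Failed calls are retained with their failure
reasons; filters are evaluated independently of order. Origin
classification follows the paired-tissue definitions (tumor-only ⇒
tumor-derived; tumor + both controls ⇒ germline; anything else
unclassified, never silently dropped), and relative copy number is
`2 · mt_depth / nuclear_depth` with the nuclear locus depth supplied by
the user.

## The simulator and what it does (not) show

`simulate_sample()` draws a 5′ cut site with probability proportional to
`end_bias(base)^temp × motif multipliers / protection(site)`, then a
fragment length from the region's Gaussian law, closing the fragment on
the circle. Defaults are the package's model of the study conditions:

- lengths: healthy mean 128 bp, sd 35 (the observed ccf-mtDNA median);
  region offsets D-loop −8, mRNA/rRNA +2, tRNA +8 bp, reproducing the
  observed D-loop < rRNA ≈ mRNA < tRNA ordering of size and FSD;
- end bias A 1.2, C 0.9, G 1.4, T 0.8 — the G/A-favoured cleavage seen
  in plasma ccf-mtDNA;
- protection: region multipliers (D-loop 0.8 … tRNA 1.6) plus 12 fixed
  Gaussian bumps (amplitude 4, width 15 bp) shared by every individual —
  a protein-occupancy surrogate; protected sites lengthen the fragments
  whose midpoints fall there (6 bp per protection unit), which is what
  turns protection into FSD peaks;
- malignant samples: −10 bp size shift, two fixed protected loci per
  cancer type, and a motif "temperature" of 0.6 that flattens the whole
  per-motif cut-rate distribution (including the genome's own 4-mer
  abundance), raising the MDS as observed in patients — a pure
  flattening of the bias weights alone would not, because the genomic
  abundance term dominates the spectrum;
- spike-ins place a minor allele on a configured fraction of fragments
  covering a site, with a length offset applied while preserving
  coverage — modelling the shorter mutant molecules seen in plasma;
- per-sample fragment count 30,000 (~230× coverage; capture data runs
  deeper, but 230× is far above the ~50× threshold at which mtDNA
  fragmentomic features stabilise, and keeps 200-sample cohorts
  desk-sized). The reference panel is simulated at 100,000 fragments ×
  30 members, mirroring a 30-control panel at capture-like smoothness.

The simulator emulates the *statistical structure* the analysis assumes —
region-specific sizes, protection-driven profiles, end bias, group
shifts, heteroplasmy — not the biophysics of nuclease digestion, real
batch effects, library chemistry, or NUMT contamination. Passing tests
therefore demonstrate that the pipeline recovers programmed structure of
realistic magnitude from realistic sampling noise; they are not evidence
about any real cohort, and the real-cohort classification accuracies
reported for this approach are not reproducible without the original
sequencing data.

## Classifiers and evaluation

Random forests with 500 trees and 6 candidate features per split, on the
1,029-feature vector (profile correlation, new-peak count, 3 × 255
window features, median size, 4 preferences — included, reading the
ambiguous wording as "in addition to" rather than "except", with a flag
to drop them —, 256 motif proportions, MDS). Copy number is kept outside
the default vector and can be appended. Training reports out-of-fold
MEFI scores from seeded, label-stratified tenfold cross-validation; the
deployed forest is refit on the full cohort, and the Youden cutoff is
fixed on the out-of-fold scores (ties broken toward higher specificity —
the screening-appropriate direction). AUC is the rank-form empirical
Mann–Whitney statistic with a DeLong 95% CI (cross-checked in tests
against a brute-force pairwise count); sensitivity/specificity carry
Clopper–Pearson CIs. The tissue-of-origin forest trains only on MT
samples scoring above the smallest threshold reaching 99.5% specificity
on training controls (the `ceiling(0.995·n)`-th order statistic) and
reports top-1/top-2 accuracy and the confusion matrix.
Leave-one-batch-out evaluation exposes batch confounding: a batch whose
training complement is single-class is skipped with a warning, never
imputed.

## Numerical and testing choices

Problem sizes in the suite: oracle comparisons at L = 200 (1,000 random
tracks against an exhaustive circular-run finder), the error-only
variant simulation at depth 1,000 over 16,569 sites, the model suite on
the default 100 MT / 100 HC cohort, and recovery of an injected
protection locus (amplitude 8, width 15 bp, in the D-loop where the
background profile is negative and the induced run stays isolated) in 20
seeded replicates. All randomness flows through explicit seeds; global
RNG state is saved and restored by every seeded function, so library
calls never perturb caller reproducibility.

Known limitations: BAM mode does not reconstruct origin-wrapping
templates (a linearized BAM cannot represent them unambiguously — wrap
support lives in the fragment-table format and the simulator); the
heavy/light strand bookkeeping assumes the reference forward strand is
the light strand, as in the standard mitochondrial assemblies; indels
are out of scope for the variant caller (substitutions only); and the
new-peak count at moderate coverage is noise-dominated and should be
interpreted jointly with the window features rather than alone.
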