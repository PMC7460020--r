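---
title: "Runs of homozygosity, genomic inbreeding and population structure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runs of homozygosity, genomic inbreeding and population structure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## Scope

`rohscan` analyses diploid SNP-array genotypes for signatures of
autozygosity and population structure: it detects runs of homozygosity (ROH)
with the consecutive method, summarises them by sample, chromosome and
length class, calls high-incidence ROH islands, and computes two genomic
inbreeding coefficients (excess homozygosity *F* and F~ROH~), pairwise
Weir–Cockerham F~ST~, principal components and monomorphic-marker counts.
A companion simulator generates cohorts with known autozygous tracts,
known differentiation and a four-way hybrid-cross mode, so every estimator
in the package can be checked against ground truth.

Genotypes are stored as counts of a per-marker counted allele (0/1/2,
`NA` for missing) next to an ordered marker map. When reading PLINK PED/MAP
text files the counted allele is the lexicographically larger symbol — a
deterministic choice needing no reference genome, and harmless because every
statistic in the package is symmetric under allele relabeling (a property the
test suite asserts for F~ST~). One caveat follows from the text format
itself: a marker whose calls are all count 0 re-reads as count 2 of its only
observed allele, since PED carries no orientation for an unobserved allele.

## The consecutive ROH method

The detector scans each sample's markers per chromosome in map order, with
no sliding windows. A *candidate run* is a maximal stretch of consecutive
markers that contains at most `max_het` heterozygous and `max_missing`
missing calls and in which every adjacent-marker gap is at most
`max_gap_bp`; a larger gap terminates the candidate, so marker density
cannot stitch distant homozygous stretches together. A candidate is
reported when it carries at least `min_snps` *homozygous* markers and spans
at least `min_length_bp`.

Defaults are `min_snps = 150`, `min_length_bp = 1` Mb, `max_gap_bp = 1` Mb
and zero heterozygote/missing budgets — the usual array settings that
exclude short, LD-driven homozygous stretches. Conventions the package
fixes, because published tables are only reproducible under one choice:

* **Length is `end_bp − start_bp`**, the span between the first and last
  marker of the run, not the +1 closed-interval count. Island lengths use
  the same rule, and the worked-example tests pin it.
* **`min_snps` counts homozygous markers only.** With the default zero
  budgets this equals the window size.
* With zero budgets, maximal runs are unique and non-overlapping. With
  positive budgets the scan emits maximal windows left-to-right and drops
  windows contained in an emitted one; overlapping non-nested windows are
  all reported. The brute-force oracle (`detect_roh_oracle`) implements the
  same dialect by exhaustive enumeration, and the suite checks equivalence
  on hundreds of randomized instances over a parameter grid.
* Runs never span chromosomes. BED exports convert the 1-based closed
  coordinates to 0-based half-open.

## Length classes, incidence and islands

ROH are binned into half-open Mb classes, by default [0, 2), [2, 4),
[4, 8) and [8, Inf): half-open so a 2.000 Mb run falls in one class only,
with an overflow class so the partition is total. Class counts therefore
always sum to the group total, and per-class F~ROH~ sums exactly to total
F~ROH~.

For each group and marker, *incidence* is the fraction of the group's
samples (zero-ROH samples included in the denominator) with a ROH covering
the marker position. *Islands* are maximal stretches of consecutive markers
with incidence at or above a threshold — 0.70 by default, and the
comparison is inclusive because the definition is "at least 70%". Island
boundaries sit on the first and last qualifying marker (they are not
extended to the underlying ROH edges, a choice the literature leaves open);
single-marker islands are degenerate (zero length), so `min_snps = 2` per
island by default. Gene annotation reports any gene interval sharing at
least 1 bp with the island on the closed 1-based coordinates, implemented
with `GenomicRanges`; BED/GFF3 gene input is read with `rtracklayer`.

## Inbreeding coefficients

**Excess homozygosity.** Per sample, over its non-missing markers with a
defined reference frequency $p_i$,

$$F = \frac{O_{hom} - E_{hom}}{L - E_{hom}},\qquad
  E_{hom} = \sum_i \left(1 - 2 p_i (1-p_i)\right),$$

with $O_{hom}$ the observed homozygote count and $L$ the marker count used.
Monomorphic markers contribute 1 to both $O$ and $E$ and cancel from the
denominator; if everything cancels, $F$ is `NA` with a warning. Reference
frequencies default to the *full cohort*: this is what makes the hybrid
phenomenon visible, because a four-way cross of unrelated inbred lines is
more heterozygous than Hardy–Weinberg proportions at pooled frequencies
predict, driving $F$ negative. A within-group frequency option exists, as
does a small-sample correction $2p_iq_i \cdot 2n/(2n-1)$ ($n$ = genotyped
samples at the marker): the plug-in expectation biases mean $F$ by about
$-1/(2n-1)$ under equilibrium, which matters in cohorts of a few dozen
samples. The correction is off by default, as descriptive analyses usually
report the uncorrected form.

**F~ROH~** is the summed ROH length of a sample divided by the genome length
covered by markers. The default denominator is derived from the map — the
sum over chromosomes of (max − min marker position) — so the package is
self-contained; a fixed constant (e.g. a published assembly span such as
901,342,009 bp for a 30-autosome turkey map) can be supplied to mirror
reported values. Per-class F~ROH~ shares the total denominator (exact
additivity); per-chromosome F~ROH~ uses per-chromosome spans, and the
weighted recombination of those values reproduces the total, which the
suite checks.

The per-group ordinary-least-squares regression of $F$ on F~ROH~ separates
two regimes: populations whose homozygosity sits mainly inside ROH show
$R^2$ near 1; hybrid cohorts, whose $F$ is dominated by heterozygote excess
unrelated to the few co-selected ROH regions, show low $R^2$.

## Population structure

Pairwise F~ST~ uses the Weir–Cockerham (1984) two-population variance
components, aggregated as a ratio of sums across markers (not a mean of
ratios), with per-marker sample sizes from the non-missing calls and
markers monomorphic across the pooled pair skipped. Negative estimates are
reported as computed and floored at zero only in the summary column. The
Hudson estimator is available as a sensitivity option and doubles as an
independent cross-check in the tests, together with analytic edge cases
(identical groups, fixed alternate alleles) and Balding–Nichols recovery.

PCA mean-imputes missing calls per marker, centres columns (optional
binomial $\sqrt{p(1-p)}$ scaling) and takes the singular value
decomposition; eigenvalues are those of the sample covariance matrix, and
each component's sign is fixed by making its largest-magnitude loading
positive, so results are deterministic and invariant (up to that
convention) to marker order.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the study
conditions the package is validated under.

* **Genome**: 10 autosomes of 20 Mb, 2,000 markers per chromosome placed
  uniformly without replacement (1 marker / 10 kb) — dense enough that a
  1 Mb / 150-SNP run is attainable, small enough for desk-scale runs.
* **Differentiation**: per-marker ancestral frequencies
  $p \sim U(0.05, 0.95)$; each population draws
  $p_{pop} \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$,
  the Balding–Nichols construction, so `drift_F` is the expected F~ST~
  against the ancestral pool.
* **Autozygosity** is tract-based, not pedigree-based: non-overlapping
  tracts (exponential lengths by default, mean 3 Mb) are placed per sample
  until the target genome fraction α is covered, the last tract truncated
  so the realized fraction equals the target. Inside a tract one allele is
  drawn and doubled (strict identity by descent, no mutation); outside,
  genotypes are Hardy–Weinberg draws. This directly controls the quantity
  F~ROH~ estimates, making parameter recovery a clean validation surface.
  Missing calls are sprinkled independently of tracts — the detector
  forbids missing calls inside runs, so correlated missingness would be a
  separate stress test, off by default.
* **Hybrid cross**: four parental lines drift independently from the
  ancestral pool with drift `line_inbreeding`; each offspring receives one
  one-crossover-generation gamete from an (A×B) parent and one from a
  (C×D) parent, crossovers Poisson along bp (1 cM/Mb). Because the two
  gametes come from unrelated line pairs, observed heterozygosity exceeds
  the Hardy–Weinberg expectation and mean $F$ is negative. In addition, a
  fraction of the genome (`shared_selection_frac`, default 0.13) is placed
  in regions where all four lines are fixed for the same allele,
  representing directional selection common to the parental lines: with
  fully independent markers a four-way cross would essentially never
  produce a 150-marker homozygous run, whereas commercial hybrids
  demonstrably carry ROH and ROH islands; the shared regions are exactly
  the mechanism the hybrid-ROH literature proposes, and they give the
  simulated hybrid group its characteristic tight F~ROH~ distribution and
  group-wide islands.
* **Calibration**: `line_inbreeding = 0.45` with the 0.13 shared fraction
  was chosen once so that the emulated three-group design lands in the
  empirically reported ranges — hybrid-vs-local F~ST~ ≈ 0.16–0.17,
  local-vs-local ≈ 0.09, hybrid mean $F$ ≈ −0.14 — and was not revisited.
  `simulate_study_cohort()` additionally uses an array-like density
  (1 marker / 3.3 kb) and shorter tract means (1.3/1.2 Mb), under which
  the sub-2 Mb class is the modal ROH class, as on dense arrays.
  Autochthonous per-sample α are Beta draws (shape pairs 1.2/6.3 and
  1.1/15) clamped to [0.003, 0.38], spanning the low-to-high autozygosity
  range reported for unmanaged populations.

**What the simulator does not emulate:** linkage disequilibrium and
haplotype structure (markers are conditionally independent given tract
status and population frequencies), genotyping error inside tracts,
selection sweeps and coalescent ancestry. Passing recovery tests therefore
demonstrates correctness of the estimators under the generative model, not
robustness to array LD; on real arrays the 1 Mb / 150-SNP thresholds are
themselves the standard guard against LD-driven short runs.

## Numerical and degenerate-input choices

* Chromosome labels are opaque strings ordered naturally (numeric labels
  first, then alphabetic), for stable outputs.
* Positions are 1-based bp, strictly increasing within a chromosome
  (enforced at construction).
* A window of one marker has zero length and can never satisfy
  `min_length_bp ≥ 1`, so degenerate single-marker runs are impossible by
  construction.
* F~ST~ with no informative markers is `NA`; `F` with a vanishing
  denominator is `NA` with a warning; a zero-variance F~ROH~ regression
  reports `NA` slope.
* All table writers emit a deterministic column order, and the pipeline
  writes a JSON manifest (parameter echo, input and output md5 hashes) so
  reruns are byte-comparable.

## Problem sizes

The validation suite runs at desk scale, chosen so the full test run takes
a few minutes on one core: detector-vs-oracle equivalence on 200+ random
instances of 5 samples × 120 markers; F~ROH~ recovery on 5 × (30 samples ×
20,000 markers); F~ST~ recovery on 50 samples × 10,000 markers; the
three-group study emulation on 68 samples × 60,000 markers. The same code
paths scale to array-sized data (hundreds of thousands of markers) since
detection is linear in markers per sample.

## Known limitations

* The consecutive method only; no sliding-window (PLINK `--homozyg`-style)
  detection and no heterozygosity-rich-region calling.
* No LD pruning, kinship estimation or ancestry deconvolution; gene-list
  enrichment is left to external tools, the package only exports interval
  overlaps.
* In the combined three-group emulation the hybrid group's co-selected
  fixed regions raise its observed homozygosity under pooled frequencies,
  so its mean $F$ sits nearer zero than in a standalone hybrid cohort;
  the heterozygote-excess sign criterion is therefore defined on the
  hybrid-cross cohort itself.
* The PED orientation caveat above: all-reference-homozygous markers
  cannot round-trip their allele orientation through the text format.
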