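---
title: "Calling, classifying and error-profiling mitochondrial heteroplasmy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling, classifying and error-profiling mitochondrial heteroplasmy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
library(dplyr)
```

## The problem

Human mitochondrial DNA is present in hundreds to thousands of copies per
cell, so a new point mutation passes through a *heteroplasmic* state in
which two alleles coexist, usually with the variant at a few percent of the
molecules. Deep amplicon sequencing (tens of thousands of reads per
position) makes minor variants down to 2% of reads callable, and at that
resolution two maternally related individuals — who share a mitochondrial
haplotype by definition — frequently differ in their heteroplasmies,
because the germline bottleneck during oogenesis and replicative
segregation between somatic tissues drift variant frequencies rapidly.

`mitohet` implements this analysis for cohorts of mother–child pairs
sampled in two tissues (buccal and blood): a filter stack that turns
per-position allele counts into reported minor-variant calls, a three-way
classification of heteroplasmic sites across each family quartet, a
per-position substitution-error profiler that justifies the reporting
threshold, cohort summary statistics with Welch comparisons, and a
germline-bottleneck simulator that generates cohorts with known ground
truth. The per-pair pattern is the forensic and clinical payoff: a site
present in both tissues of one family member and absent from both tissues
of the other *differentiates* two maternal relatives who are
indistinguishable by consensus haplotype.

## Data model

The package is tidyverse-shaped: everything flows through tibbles.

* A **pileup** has one row per sample × position with forward/reverse read
  counts for A, C, G and T (and optionally per-base mean quality scores).
  This is deliberately a count table rather than a VCF: the unit of
  information is the full per-position count vector, before any genotype
  decision. A documented TSV dialect is read and written by
  `read_pileup()` / `write_pileup()`; pileups from any upstream aligner
  can be converted by tabulating base calls per position and strand.
* A **manifest** links `sample_id` to `family_id`, `role`
  (mother/child) and `tissue` (buccal/blood).
* Coordinates are 1-based rCRS positions (1..16,569). Position 3107 is the
  historical placeholder `N` and is never callable.

## Variant calling

`call_variants()` identifies the major (consensus) and minor allele at
each row and applies, in order: position exclusion (310, 3107 by default),
minimum total coverage (200), the analytical threshold (minor fraction ≥
1%), minimum variant reads (40), strand balance, quality-score balance
(only when quality columns exist), and finally the reporting threshold
(2%). A call's `status` names the first filter that rejected it, so filter
attrition is always auditable. Frequencies use total position coverage over
all four bases as the denominator.

Two numerical choices deserve comment.

* **Detection floor.** With a 40-read minimum, reporting at 2% needs at
  least 2000 reads; `detection_floor()` exposes
  `max(analytical threshold, 40 / coverage)` per position, and
  `coverage_assessment()` summarises how much of a cohort clears it. The
  classifier reuses this floor: "absent" only counts as absent where
  coverage could have revealed a 2% variant.
* **Strand balance.** Deep amplicon positions are often strand-imbalanced
  as a whole, so the default balance test (`balance_mode =
  "major_normalized"`) compares the minor allele's forward:reverse ratio
  against the major allele's at the same position (an odds ratio, ≤ 2.5 by
  default). A raw minor-only ratio (`"minor_only"`) is available; it is
  stricter at legitimately skewed positions. Sequencing artifacts that
  occur in only one read direction fail either version.

Major/minor ties are broken lexicographically (A < C < G < T) and
announced, never silent.

## Classifying heteroplasmy across a family quartet

For every (family, position) with at least one reported call,
`classify_sites()` assigns one of three labels:

* **shared** — reported in at least one tissue of both mother and child;
* **differentiating** — reported in both tissues of exactly one member and
  certifiably absent from both tissues of the other;
* **random** — reported in exactly one of the four samples.

These three labels exhaust all reported-call patterns over a complete
quartet (the package tests enumerate all 16 patterns). Two deliberate
rules sit on top of the literal definitions. First, a site reported in one
tissue of *each* member is shared — the definition asks only that both
members carry it somewhere. Second, absence is held to a stricter standard
than non-report: the other member's minor fraction must be below the
reporting threshold in both tissues *and* coverage there must clear the
2000-read floor; otherwise the candidate is downgraded to `unclassifiable`
rather than over-claimed as differentiating. Sites are identified by
position alone, so heteroplasmy towards the reference in one member still
matches heteroplasmy towards the variant in the other.

`primary_haplotype_change()` flags the drastic outcome where mother and
child have different *consensus* alleles at a heteroplasmic position, and
`site_comparison()` quantifies the carrier's buccal/blood contrast
(fold difference, direction, 10% bands). `cohort_summary()`,
`frequency_sets()`, `heteroplasmy_rate_tests()` (Welch unequal-variance
t tests via `stats::t.test()`) and `band_summary()` aggregate to cohort
level. Non-detected slots are excluded from frequency sets, not imputed as
zero — with below-floor slots in the data, only this convention gives
means that describe what was actually measured.

## Worked example: the packaged reference tables

The package vendors machine-readable transcriptions of two published
reference tables — 12 pairs with shared heteroplasmy (frequencies only)
and 17 pairs with differentiating heteroplasmy (full read counts) from a
39-family cohort — and `fixture_pileups()` renders them as pileups: the
differentiating rows exactly as printed, the shared rows synthesised at
coverage 10,000 (where a two-decimal percentage is exactly representable),
everything else flat at the reference base.

```{r worked}
fx <- fixture_pileups("both")
res <- run_heteroplasmy_analysis(fx$pileup, fx$manifest)
res
res$bands
```

Every count here is recomputed by the pipeline, and the test suite pins
them: 12 shared pairs at 14 distinct sites, 17 differentiating pairs at 21
sites (16 coding, 5 control region; 14 below 10% in both tissues, 19 with
buccal higher, 17 under a twofold tissue difference), class means 15.6%
and 8.6%, and a Welch p of ~9×10⁻⁴ between them. One transcription caveat:
printed frequency denominators included unprinted third/fourth-allele
reads, so frequencies recomputed from reconstructed counts can differ from
printed ones by up to ~0.05 percentage points; tests therefore compare
printed-value arithmetic exactly and pileup-path frequencies to 0.1
percentage points.

## Reference annotation

The mitochondrial gene map and genome are packaged data
(`mt_gene_map()`, `mt_genome()`). The control region is 16024..16569 ∪
1..576 — the standard rCRS convention, which places every
control-region-annotated site of the reference tables inside and every
coding-annotated site outside. Intergenic spacers are tiled as
`non_coding` so each position has exactly one category.
`mt_substitution_effect()` translates with the vertebrate mitochondrial
code (ATA→Met, TGA→Trp, AGA/AGG→stop), reverse-complementing light-strand
genes (ND6) before codon extraction, and reports 3-letter amino-acid
changes ("Val to Ala"). Incomplete terminal codons (polyadenylation-
completed stops) are left unannotated rather than guessed.

The packaged genome is a *synthetic reconstruction* of the rCRS
(NC_012920.1), rebuilt from the older NC_001807.4 mitochondrial reference
by resolving their documented indel and polymorphic-site differences. It
is verified in the test suite at every position the package's analyses
touch (all tabulated reference bases, >100 published flanking contexts,
and full-ORF translation of all 13 protein genes); a handful of
polymorphic positions outside any tested region could in principle differ
from the true rCRS, which is why the file is labelled synthetic.
`mt_adjacent_sequence()` renders a site's flanks three bases wide,
extending through a homopolymer run when one abuts the site (the
convention of published error-hotspot tables), and `mt_motif_flags()`
tests for the poly-A, poly-C and GGT motifs associated with elevated
sequencing error.

## Error profiling

`error_rates()` estimates substitution error conservatively: within each
sample, any base call at ≤ 50% of a position's reads is assumed to be an
error; numerators and denominators are then pooled across samples, per
position and overall. Known heteroplasmies are deliberately *not*
excluded, so a true variant at fraction f inflates its position's rate by
f — the estimate is an upper bound, which is the right direction for
justifying a reporting threshold. Positions whose assumed error exceeds
the reporting threshold are flagged (in practice such positions also fail
strand-balance and quality filters, which is why they do not surface as
calls). `error_hotspots()` ranks the top rates per substituting base with
sequence context; `autoplot()` methods draw the per-position profiles.

The published average error rates and hotspot tables themselves derive
from the study's 156-sample read set (>60 billion base calls), which is
not redistributable at package scale; the profiler is instead validated on
synthetic cohorts with known injected error (50 samples × 1000 positions
in the tests), plus conservation identities (summed average rates equal
the overall minority-call fraction).

## The simulator

`simulate_cohort()` generates the structure the analysis assumes, with
all rates configurable in `sim_config()`:

* founder (mother germline) frequencies uniform on [0.02, 0.5] at a
  configurable number of seeded positions per family;
* one binomial bottleneck of `bottleneck_size` (default 32, in the upper
  range of empirical human estimates; a variable-size model in the
  literature puts the mean far lower, so this is a knob, not a claim) to
  the child germline;
* one further binomial segregation per tissue (`tissue_drift_size`,
  buccal 200 vs blood 500 by default so buccal drifts harder, as observed
  in real tissue comparisons);
* lognormal coverage (median 24,000 by default, the deep-coverage scale)
  and multinomial read sampling with uniform substitution noise (default
  0.05%, the order of observed MiSeq error), split binomially across
  strands.

A single-generation binomial bottleneck is deliberately the simplest
model that produces the assumed structure — unbiased transmission with
variance f(1−f)/N — rather than a multi-generation Wright–Fisher chain;
the analysis uses the bottleneck only as a drift generator. The simulator
emits ground truth (founder, germline and tissue frequencies plus the
label an ideal detector would assign), which the tests use for recovery
properties: called frequencies within binomial error of tissue
frequencies, ≥95% label recovery away from the threshold boundary, and a
silent pipeline when no heteroplasmy is seeded. What the simulator does
*not* emulate: PCR jackpots and duplicates, alignment and motif-driven
coverage artifacts, length heteroplasmy in homopolymer stretches, and
selection against deleterious variants — so passing recovery tests shows
the statistical machinery is correct, not that real-data artifact modes
are handled.

Test problem sizes (subsampled genomes of 10²–10³ positions, cohorts of
tens of families, 10⁴ replicate transmissions for the drift closed-form
checks) were chosen to make the Monte-Carlo criteria statistically
meaningful at desk scale.

## Known limitations

* Only substitutions are modelled: no indel or length-heteroplasmy calling
  (the 302/310 C-stretch region is excluded by default for exactly that
  reason), and no read-level processing — alignment and per-read quality
  control happen upstream.
* The quality-score balance filter depends on the upstream tool's meaning
  of a per-base mean quality; it is applied only when quality columns are
  supplied.
* Welch tests are reported without multiple-testing correction, matching
  standard practice for the three planned class comparisons.
* No haplogroup assignment and no forensic match-statistic computation.
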