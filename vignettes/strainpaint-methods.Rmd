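---
title: "Methods: variant triage, private-variant cataloging and windowed ancestry painting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage, private-variant cataloging and windowed ancestry painting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainpaint)
```

## The problem

When a new wild-derived inbred mouse strain is sequenced, the post-alignment
questions are always the same. Which candidate variant calls survive basic
quality triage? Which of the surviving variants are *private* to the new
strain — never seen in the catalog of previously sequenced strains — and
what does their transition:transversion (Ts:Tv) ratio say about call
quality? What is the subspecies ancestry of each region of the genome, given
that house-mouse strains are mosaics of *M. m. domesticus*, *M. m.
musculus* and *M. m. castaneus* ancestry? And what do windowed read-depth
profiles say about genetic sex, the callable fraction of the genome, and
copy-number changes — in particular near the centromeres of chromosomes
involved in Robertsonian (Rb) fusions, where karyotype evolution might
plausibly leave sequence-level scars?

`strainpaint` implements this whole post-alignment layer as small,
composable stages with a deterministic synthetic-data generator, so that
every stage can be tested end to end against known truth without any
sequencing data.

## Hard filtering of candidate variants

Candidate SNVs and short indels arrive as VCF with site-level depth (`DP`),
mapping quality (`MQ`) and alternate-allele read support (from `DP4`, with a
`FORMAT/AD` fallback). A site passes the triage only if **all** rules hold;
every comparison is strict:

* read depth: `DP > 5` and `DP < 100` for nuclear chromosomes; `DP > 350`
  with no upper bound for the mitochondrial genome (mtDNA is high-copy, so
  its depth is far above nuclear depth and an upper bound would be
  meaningless);
* mapping quality: `MQ > 20`;
* alternate support: more than 5 reads carrying the alternate allele;
* indel proximity (SNVs only): the nearest indel anchor on the same
  chromosome must be more than 2 bp away. Distance is measured between VCF
  `POS` anchors, the simplest defensible convention, and is configurable;
  SNVs on indel-free chromosomes have infinite distance, so the rule can
  never fire for them;
* homozygosity: the focal strain's genotype must be homozygous.
  Heterozygous or missing genotypes fail. Each focal strain is filtered
  independently: one animal per strain is sequenced, and the joint panel
  only enters at privacy classification.

Sites missing a needed statistic fail with an explicit `MISSING_STAT`
verdict rather than passing — the downstream analyses are defined over
variants passing *all* filters, so absence of evidence is failure. A
failing site collects every reason that applies, and the summary counts
each reason independently.

Two invariants are tested: verdict-for-verdict agreement with a
straight-line per-site reference on randomized sites spanning every
threshold boundary (including the exact boundary values 5, 100, 20, 5 and
2, which never pass), and monotonicity (raising a threshold can only
shrink the pass set).

## Private-variant cataloging

A variant's privacy is a property of its alternate *allele*, classified
against two focal strains and a panel of previously sequenced strains:

* **known** — any panel strain carries the allele. A heterozygous panel
  genotype counts as carrying: this is the conservative choice for novelty
  claims.
* **private to A / private to B** — exactly one focal strain is homozygous
  for the allele and the other is resolved and not homozygous for it.
* **shared exclusive** — both focal strains are homozygous for it.
* **unclassifiable** — a genotype needed to decide is missing (a panel
  genotype when there is no panel hit, or the other focal genotype when one
  focal strain carries the allele). Sites where *neither* focal strain is
  homozygous for the allele are also unclassifiable; pass-filter input
  normally precludes them, but the function is total.

The panel size is arbitrary — the definition quantifies over panel strains,
it does not count them. Multiallelic sites are classified once per
alternate allele. The implementation is verified against an exhaustive
truth table over all genotype configurations of two focal plus three panel
samples, and against the generator's known privacy truth.

The Ts:Tv ratio is computed over the novel (non-known, classified)
biallelic SNVs: transitions are A↔G and C↔T. The ratio is reported as NaN
when no transversions were observed.

## Outgroup polarization and ancestry painting

At each biallelic pass-filter SNV, the outgroup species is assumed to carry
the ancestral allele: the ancestral allele is the outgroup's homozygous
allele and the derived allele is the other one (so the reference allele can
be derived). Sites where the outgroup is heterozygous or missing, and
multiallelic sites, are excluded with a reason.

A site is *informative for ancestry* when the focal strain is homozygous
for the derived allele and exactly one of the three subspecies
representatives carries it ("exclusive sharing"). Representative genotypes
that are missing make exclusivity undecidable, so such sites are excluded,
never imputed.

The genome is tiled into fixed-width windows (25 kb by default, the
conventional width for windowed ancestry statistics; the final window of a
chromosome is truncated and kept at its true length). Each window is
labelled:

* `masked` when more than `mask_threshold` (default 0.5) of its bases fall
  in the intersubspecific-introgression/contamination mask; masked windows
  carry no counts;
* `uninformative` when fewer than `min_sites` (default 10) sites show
  exclusive sharing;
* otherwise the subspecies with the largest exclusive-sharing count, with
  ties labelled `ambiguous`.

Every tally is bookkept so that per window the exclusive counts, the
non-exclusive sites, the sites where the focal strain is not homozygous
derived, the representative-missing sites and the excluded sites add up
exactly to the sites in the window — an identity asserted in the tests.

Three genome-fraction summaries are emitted, because "fraction of the
genome" is genuinely ambiguous for a windowed statistic: the fraction of
analyzed (non-masked) windows per label, a base-pair-weighted variant
(which differs only through truncated final windows), and
`fraction_informative`, the per-ancestry fraction among the
ancestry-labelled windows only. The last is the natural genome-composition
estimate — windows without signal say nothing about composition — and is
the statistic the recovery tests compare against simulated truth.

No HMM or probabilistic smoothing is applied: the method is deliberately
the plain windowed statistic.

## Depth analytics

Windowed depth tracks carry a mapping-quality-filtered mean depth
(`depth_mq20`) and a total mean depth per window. Normalization divides by
the autosome-wide median of `depth_mq20`, so a diploid window sits at ratio
1; the operation is idempotent because the autosomal median of the ratios
is 1 by construction.

* **Sex inference**: the median normalized X-chromosome depth is ~0.5 for
  XY and ~1 for XX individuals. The label is male when the ratio falls
  below 0.75 (configurable); the boundary value is assigned to female.
* **Callable fraction**: the length-weighted fraction of bases in windows
  with raw `depth_mq20` at or above the threshold (default 10, inclusive —
  "at least 10×").
* **CNV screen**: runs of at least `min_consecutive` (default 3) windows
  with normalized ratio below 0.25 (deletion) or above 1.5 (duplication)
  become calls. A call is *private* when every comparison track's mean
  ratio over the same windows lies inside [0.75, 1.25]. These thresholds
  are not dictated by any reference analysis — the screen is qualitative —
  so all four are configuration-exposed with the stated defaults.
* **Centromere screen**: for each Rb-fusion chromosome, private calls
  overlapping its centromere-proximal interval are reported. Mouse
  chromosomes are acrocentric, so "centromere-proximal" defaults to the
  first 5 Mb of each chromosome (configurable, including via an explicit
  BED). An all-zero report is the meaningful negative finding.

## The synthetic-data generator

The generator emits a complete dataset — VCF with focal strains,
subspecies representatives, outgroup and known panel; ancestry-segment
truth; depth tracks — from one configuration object and one seed.
Per-component seed streams use fixed offsets, so adding a component never
perturbs the draws of another, and identical configurations reproduce
byte-identical files.

**Ancestry mosaic.** Segment lengths are exponential with mean
`segment_length_mean` (default 1 Mb, a typical scale for introgressed
blocks in inbred strain genomes). Ancestries are assigned by
quota-depletion sampling: each ancestry owns a base quota equal to its
target fraction of the genome, a segment's ancestry is drawn with
probability proportional to the remaining quota, and a segment is capped
at its ancestry's remaining quota. Independent weighted sampling would
leave the *realized* fractions with a standard deviation of several
percentage points at these scales, making "recovery within ±2 points of
truth" a test of the draw rather than of the method; quota depletion pins
realized fractions to the targets while keeping segment placement random.

**Variants.** Sites are placed by a Poisson process (default density
1/500 bp). The reference allele plays the ancestral role: the outgroup is
homozygous reference with probability `p_polarizable` (default 0.9) and
heterozygous otherwise. Privacy categories are assigned by `privacy_spec`
through the focal and panel genotypes. The ancestry channel acts at the
sites the focal strain carries: inside a segment of ancestry *s* the
derived allele is carried exclusively by representative *s* with
probability 0.8, exclusively by a wrong representative with probability
0.05 (emulating incomplete lineage sorting and homoplasy, so recovery is
non-trivial), and otherwise by zero or two representatives. Derived
alleles the focal strain does not carry — variants private to the other
strain — are novel mutations that no representative shares. This is what
makes the permutation-safety property hold: ancestry information lives in
the focal-by-representative sharing pattern, so permuting the focal
genotypes across sites destroys window structure. A consequence is that
the mosaic truth is defined for focal strain A; strain B's painting of
synthetic data has low informative density and no associated truth. Site
statistics are drawn so a configurable fraction (default 0.9) passes the
filters, with each failing site violating one randomly chosen rule;
transitions are drawn with probability 0.68, placing the simulated Ts:Tv
near 2.1, the value typical of high-quality mouse call sets.

**Depth.** Window depths are *means* over tens of kilobases, so they are
drawn as continuous gamma variables (the mixing density of a negative
binomial) with shape `depth_dispersion` (default 200, CV ≈ 7%) and mean
`depth_mean × copy_ratio × sex_factor`, where the sex factor is 0.5 on the
X for males. Drawing integer counts instead would make the median-based
X:autosome ratio move in steps of 1/`depth_mean` and misstate the
tightness of real windowed coverage. At this dispersion the probability
that an unperturbed window crosses the CNV thresholds (ratio < 0.25 or
> 1.5, i.e. more than ±7 standard deviations) is negligible, which is what
the clean-genome specificity property requires.

**What the generator does not emulate.** No reads are simulated; no GC or
mappability structure exists (real callable fractions are far below the
synthetic ones, because repeats and segmental duplications depress real
MQ-filtered depth); the indel length spectrum is uniform insertions below
10 bp; linkage between neighbouring sites is only through the shared
segment ancestry; and population history is not simulated — sharing
probabilities are generated directly, because the windowed statistic
consumes only sharing patterns. Passing the recovery tests therefore shows
the *statistics* are computed correctly at realistic signal-to-noise, not
that real genomes behave this simply.

## Numerical and coordinate conventions

Intervals are held as `GenomicRanges::GRanges` (1-based, closed), the
standard container of the R genomics stack; BED input/output (0-based
half-open) and VCF positions (1-based) are converted at the I/O boundary
only. Window tiling is half-open in spirit: a 60 kb chromosome at 25 kb
width yields windows covering 0–25,000, 25,000–50,000 and 50,000–60,000 in
BED coordinates, every base exactly once. Mask normalization merges
overlapping and book-ended intervals and is idempotent. Degenerate inputs
are defined rather than accidental: empty variant sets summarize to
all-zero tables with an undefined (NaN) Ts:Tv; an all-masked window set is
an error for the ancestry summary; an all-zero autosomal depth track is an
error for normalization; ties in window painting go to `ambiguous`, never
to an arbitrary winner.

## Problem sizes used by the test-suite

The suite exercises a 50 Mb two-chromosome genome for mosaic recovery
(~100,000 candidate sites), ~10,000-site simulations for privacy
round-trips, 100 seeds per sex for sex inference, and 100 clean genomes
for CNV-screen specificity — sizes at which every stochastic property is
measured with comfortable margins while the whole suite stays fast.

## Known limitations

* The homozygosity filter consults only the focal sample; genotype
  likelihoods are taken at face value and never recalibrated.
* Indel proximity uses anchor positions, not allele spans; a long deletion
  whose span approaches an SNV is measured from its anchor.
* The CNV screen has no segmentation model and no breakpoint refinement;
  calls are unions of threshold-crossing window runs.
* Sex inference assumes an XX/XY system and a single-copy X in males.
* The ancestry painter reports window labels, not probabilities; regions
  dense in incomplete lineage sorting will show as noise or `ambiguous`
  windows rather than being modelled.
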