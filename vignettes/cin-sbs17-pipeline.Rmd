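---
title: "Linking chromosomal instability to SBS17-type mutational signatures in sparse single-cell DNA data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking chromosomal instability to SBS17-type mutational signatures in sparse single-cell DNA data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Barrett's esophagus (BE) is a premalignant columnar metaplasia of the
distal esophagus. As lesions progress toward dysplasia, some cell
populations acquire chromosomal instability (CIN) — segmental gains and
losses — while others in the same biopsy remain near-diploid
(chromosomally stable, CS). A second molecular hallmark of progression
is the COSMIC single-base-substitution signature SBS17: SBS17a, a T>C
substitution concentrated in the `C[T>C]T` trinucleotide context, and
SBS17b, a T>G substitution spread over the `N[T>G]T` contexts.

Plate-based single-cell whole-genome DNA sequencing can resolve both
hallmarks in the same cells, but at a price: each cell covers only
about 0.5–1% of the genome. Copy number must therefore be read from
coarse bins of pooled read counts, and point mutations are only
interpretable at the level of cell *clusters*, never single cells.
`cinsig` implements the complete analysis for this regime:

1. **Copy number**: per-cell binned counts are normalised, cells are
   clustered, each cluster's mean profile is segmented by circular
   binary segmentation (CBS), the CS cluster is identified, and CIN
   regions are called.
2. **Variant filtering**: candidate variant calls pass a fixed cascade
   — mapping-quality filter, germline blacklist, removal of variants
   shared by all patients, removal of variants supported by CS cells —
   followed by a per-cluster Fisher exact enrichment test.
3. **Signatures**: per-cluster trinucleotide spectra are built,
   depth-normalised, baseline-subtracted against the CS cluster, scored
   by cosine similarity against a signature catalog, and refit by
   non-negative least squares on a chosen signature subset
   (SBS17a/SBS17b by default).
4. **Simulation**: a generator produces clonal cell populations with
   known karyotypes, coverage, and signature mixtures, so every stage
   has a ground truth to be tested against.

## Copy-number model

**Normalisation.** Counts in each bin are divided by the bin weight
(the trailing bin of a contig may be fractional), then each cell's
vector is divided by its median and multiplied by 2. The model
assumption is that the median bin of every cell is diploid. This holds
only when most of the genome is copy-neutral; a karyotype with less
than half of its bins at CN 2 makes the median fall between copy-number
states and rescales the whole profile. This is an assumption inherited
from the method itself, not an implementation artefact, and it is why
the simulator's default CIN karyotype keeps 62.5% of bins diploid.
A related, smaller effect: the median of an overdispersed count
distribution sits slightly below its mean, so normalised profiles run a
few percent above the nominal copy number (CN 2 bins typically read
2.1–2.3 at the default noise level). The CS/CIN threshold of half a
copy absorbs this bias.

**Clustering.** Ward-linkage hierarchical clustering on Euclidean
distances between profile vectors, cut at a user-chosen `k`. The
cluster count is deliberately a per-sample analyst decision; an
average-silhouette suggestion can be printed (`suggest = TRUE`) but is
never applied automatically. Cells are processed in lexicographic
barcode order so that ties resolve deterministically.

**Segmentation.** Segmentation is performed per cluster on the cluster
mean profile (cells contribute through the mean, not individually —
at 0.5–1% coverage a single cell's profile is too noisy to segment on
its own). The CBS search considers every arc `(i, j]` of a contig and
contrasts bins inside against bins outside with a pooled-variance
two-sample t statistic; the maximising arc is accepted if a permutation
test on the maximal statistic gives `p < alpha`, and the search recurses
on the resulting pieces. Defaults: `alpha = 0.01`, 1,000 permutations,
minimum segment width 2 bins, seeded permutation RNG.

One numerical choice deserves a note. The permutation p-value counts
permutations whose maximal statistic *strictly* exceeds the observed one
(with a relative-tolerance guard against floating-point ties):

```
p = (1 + #{perm max stat > observed}) / (nperm + 1)
```

With the conventional `>=` counting, a short contig can never be split,
because permutations that merely re-create the observed partition (the
same values inside the arc, in any order) tie the observed maximum
exactly: for a 3-versus-3 step the tie probability alone is 0.3,
far above any sensible `alpha`. Counting only strict exceedances treats
such re-creations as what they are — the observed configuration
reappearing — while flat profiles remain unsplit because their best
statistic is indistinguishable from the permutation distribution
(and a zero statistic never qualifies).

**CS labelling and CIN regions.** Each cluster's *aberrant fraction* is
the weighted fraction of the binned genome in segments with
`|mean CN − 2| > cn_delta` (default half a copy). The cluster with the
smallest aberrant fraction is flagged CS provided the fraction is at
most `cs_max_aberrant` (default 5% of the weighted genome); otherwise
no CS flag is set and a warning is raised. Ties break by cell count,
then label. Segments beyond the `cn_delta` band become gain/loss
regions; same-direction neighbours merge; intersecting the region sets
of several samples yields their shared alterations. A gene table can be
restricted to stable regions with an any-overlap exclusion rule (a gene
overlapping a CIN region by a single base is excluded).

## Variant filter cascade

The cascade order is fixed: mapping quality, then blacklist, then
cross-patient sharing, then CS overlap, then enrichment. Each step
appends to the matrix's filter history, so attrition is auditable and
monotone by construction.

* **MQ**: strictly greater than 20 in single-cell mode (60 in
  whole-genome mode, where a VAF > 0.3 filter is additionally
  available). Variants without an MQ value cannot be qualified and are
  dropped with a counted warning.
* **Blacklist**: allele-exact key matching `(contig, pos, ref, alt)` —
  the conservative reading of removing "known germline variants"; a
  different alternative allele at a blacklisted position is kept.
* **Shared between all patients**: a key observed in every patient's
  matrix is removed from all of them (with one patient the step is an
  identity with a warning).
* **CS overlap**: any variant with at least one supporting CS cell is
  removed, as are variants with no supporting cells at all. Whether
  "overlapping the CS cluster" should mean one cell or a fraction is
  not obvious; one cell is the strictest reading and is what is
  implemented.
* **Fisher enrichment**: per (variant, cluster), the 2×2 table of
  supporting/non-supporting cells inside/outside the cluster, one-sided
  in the enrichment direction (the hypothesis is concentration in the
  cluster, so the upper hypergeometric tail is the natural test;
  a two-sided option exists). No multiple-testing correction is applied
  by default, mirroring a plain 0.05 threshold; Benjamini–Hochberg is
  available behind a flag. Significant variants are exported per
  cluster as VCF.

**Attributing variants to clusters for spectra.** After the cascade,
each cluster needs a variant set to build its spectrum from. The
package's default attributes to a cluster every variant with at least
one supporting cell in it (`attribution = "supported"`); restricting to
Fisher-enriched variants is available (`attribution = "enriched"`).
The default is a deliberate design choice: at 0.5–1% per-cell coverage
and tens of cells per cluster, a fully clonal variant is observed in
well under one cell on average, and a variant seen in one cell of a
50-versus-50 split has a one-sided Fisher p of 0.5 — the exact test has
essentially no power at these depths, and enriched-only spectra would
be empty. Because CS-supported variants were already removed, supported
attribution still yields cluster-specific sets. The enrichment test is
always computed and exported regardless of the attribution mode.

## Spectra, baseline, and refit

**Spectra.** SNVs are classified into the 96 pyrimidine-centred
trinucleotide channels (purine-centred calls are reverse-complemented);
ambiguous contexts are skipped and counted. Channel totals equal the
number of classified variants. A compact INDEL classifier covers the
channels relevant to hypermutated BE: 1-bp insertions/deletions of C/T
binned by homopolymer run length (1–4, 5+), multi-base insertions after
copies of themselves binned by preceding repeat count (1, 2, 3+), and
two catch-alls.

**Depth normalisation.** The reference condition is 100,000 reads per
cell and 1% genome coverage. The target is stated as a condition, not a
formula; the implementation applies the product of two linear factors,

```
scale = (100000 / mean reads per cell) * (0.01 / mean covered fraction)
```

and records both input means in the spectrum metadata. This is flagged
as interpretive: counts scale linearly in read depth and in covered
genome under a uniform-sampling model, which is the simplest model
consistent with the stated condition.

**Baseline subtraction.** The CS cluster's normalised spectrum (built
from all post-blacklist variants with CS support — the frequencies
observed in CS cells) is subtracted channel-wise from each cluster's
normalised spectrum; negatives clip to zero. "Frequencies" is read as
normalised counts, not proportions. A pooled mode replaces the
per-sample baseline with a cell-count-weighted mean of CS spectra
across samples, which damps the sampling noise of any single CS
cluster.

**Cosine and refit.** Cosine similarity is reported against every
catalog signature. The refit solves a non-negative least-squares
problem on the chosen signature columns (Lawson–Hanson NNLS). Its
headline summary, the *fraction explained*, is defined here as
`sum(reconstructed) / sum(observed)`, clipped to [0, 1] (0 for an
all-zero spectrum), with the cosine between observed and reconstructed
reported alongside — the informal notion of "how much the signatures
explain" is not a formally defined quantity, so both views are given.

**The proxy catalog.** To keep the package self-contained, a bundled
catalog provides four proxies constructed from verbal channel
definitions: `SBS17a-proxy` (0.90 on `C[T>C]T`, 0.10 uniform
elsewhere), `SBS17b-proxy` (0.225 on each `N[T>G]T`), `clocklike-proxy`
(0.225 on each `N[C>T]G`, the deamination contexts), and `flat-proxy`
(uniform). These are stand-ins with the right channel structure, not
the catalogued signatures; any COSMIC-format TSV is accepted via
`load_catalog()` when available.

## What the simulator emulates — and what it does not

The generator produces, per "patient": a synthetic reference genome
(i.i.d. bases at a chosen GC content, resampled until all 32
pyrimidine-centred trinucleotides occur per contig); clones with
explicit karyotypes; per-cell total reads (lognormal, sdlog 0.25,
around 100,000); negative-binomial bin counts with expectation
proportional to copy number × bin weight; clonal somatic variants drawn
channel-first from a signature mixture and placed uniformly on
matching, collision-free reference sites; germline SNPs carried by all
cells; and Bernoulli observation of each carried variant at the cell's
covered fraction (uniform on 0.5–1%).

Default study conditions (chosen once, on realism grounds, and
documented here): two clones of 50 cells; the CS clone diploid with
1,000 somatic variants from a 70/30 clock-like/flat mixture; the CIN
clone with a whole-contig loss and a half-contig gain (30 of 80 bins
aberrant — segmental changes on a majority-diploid background, as in
dysplastic biopsies, and compatible with the median-normalisation
assumption above) and 2,000 somatic variants from 45% SBS17a-proxy,
45% SBS17b-proxy, 10% flat; negative-binomial size 10, i.e. a per-bin
coefficient of variation of about 0.32 at 1,000-read bins — noisy
enough to be non-trivial, clean enough that per-cell profiles show
readable copy-number states, as real single-cell aneuploidy heat maps
do. The per-cell depth distribution of real plates is not published;
the lognormal is a modelling choice, not an inference.

Not modelled: read-level data (no FASTQ/BAM), GC or replication-timing
bias, doublets, allele-specific copy number, mosaic subclonality within
a clone, or locus dropout correlated across cells. Passing tests on
this generator therefore demonstrate the correctness of the
*computations* under a clean clonal model, not robustness to every
artefact of real plates.

## Numerical and testing notes

All coordinates are 0-based half-open internally; VCF output is
1-based; BED output follows BED. Variant sites avoid the first and last
base of each contig so a trinucleotide context always exists. All
randomness flows from one root seed split into per-stage sub-streams;
identical configurations reproduce byte-identical outputs.

The test suite verifies each stage against independent oracles:
exhaustive arc enumeration for the CBS search (profiles of up to 12
bins), explicit binomial-coefficient hypergeometric sums for the Fisher
p-values (tables up to N = 40, tolerance 1e-12), a 0.01-resolution grid
search over the 2-simplex for 2-signature refits (n = 2,000 draws,
weights recovered within ±0.05), and simulation ground truth for
clustering (adjusted Rand index ≥ 0.9 and a correct CS flag in at least
19 of 20 seeded replicates of the default conditions). The end-to-end
check simulates the default patient, runs the pipeline, and requires
the CIN cluster's SBS17a+b fraction explained to reach at least 75%
after CS-baseline subtraction while the CS cluster stays below 50%.
Problem sizes in the suite (genome of 4 × 2 Mb, 100 cells, bins of
100 kb) are deliberately compact so that the whole suite runs in a few
minutes.

## Known limitations

* The median-normalisation bias described above shifts segment means a
  few percent upward at realistic overdispersion; thresholds are wide
  enough to absorb it, but extreme aneuploidy (less than half the
  genome diploid) breaks the method's core assumption.
* The Fisher enrichment stage is faithful to its definition but
  underpowered at 0.5–1% coverage; its output is exported for
  inspection while spectra default to supported-cell attribution.
* Proxy signatures share their flat component, so refits against both
  proxies can slightly overshoot the observed total (the fraction
  explained is clipped at 1).
* With a single sample, the cross-patient filter is an identity and
  residual shared artefacts must be caught by the blacklist.
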