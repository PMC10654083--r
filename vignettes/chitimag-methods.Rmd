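---
title: "Methods: MAG selection, dereplication, detection and chitinase screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAG selection, dereplication, detection and chitinase screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chitimag)
```

`chitimag` implements the downstream comparative stages of a
metagenome-assembled-genome (MAG) study: which reconstructed bacterial
genomes are high quality, which are redundant with one another, where each
genome is detectable across a panel of host-associated samples, how
genomes distribute over a host species/order hierarchy, and which of them
are putatively chitinolytic. This vignette explains each model and the
choices behind it. Upstream steps — read cleaning, assembly, binning,
completeness estimation, read mapping, CAZyme annotation — are consumed as
inputs, never recomputed.

## Quality selection

Bin quality is taken from single-copy-gene estimates produced upstream
(completeness and redundancy, both percentages). Selection keeps bins with
completeness **strictly above 90%** and redundancy **strictly below 5%**;
the strict inequalities follow the usual phrasing "more than 90%, less
than 5%", so a bin at exactly 90/5 is excluded. Because synthetic or
hand-assembled inputs may violate what a binning tool normally guarantees,
a 200 kb minimum bin length is enforced at selection time as well; both
are configurable through `quality_thresholds()`. Contig-level trimming
(`trim_contigs()`) is likewise strict: "longer than 1,000 bp" keeps
1,001 bp and drops 1,000 bp.

## MinHash dereplication

Dereplication collapses near-identical genomes recovered from multiple
samples or assemblies. We follow the common two-pass design: a permissive
primary clustering at 90% average nucleotide identity (ANI) to form
"species-like" groups cheaply, then a strain-level secondary pass at 98%
ANI within each primary cluster, chosen to avoid cross-mapping of reads
between retained genomes when their distribution is profiled afterwards.

Both passes here use the same ANI estimator: bottom-$s$ MinHash sketches
over canonical $k$-mers ($k = 21$, $s = 1000$, hash seed 42 — standard
sketching defaults; the canonical $k$-mer is the lexicographic minimum of
a $k$-mer and its reverse complement, making sketches strand-independent).
For two sketches the Jaccard index $j$ is estimated on the merged bottom-$s$
sketch and converted through the Mash distance model
$d = -\frac{1}{k}\ln\frac{2j}{1+j}$, with ANI $= \max(0, 1-d)$. Using the
sketch estimator for the secondary pass as well (where alignment-based ANI
is traditional) is a deliberate simplification that keeps the package
self-contained with no external binaries; in the 90–100% identity range
where both thresholds operate the estimator is accurate to well under a
percentage point at these sketch sizes, which the test suite demonstrates
by parameter recovery: genome pairs simulated at substitution rates of
1%, 2% and 5% yield mean ANI estimates within ±0.01 of $1-p$.

The "minimum aligned fraction" gate of alignment-based dereplication (10%
by default) is approximated by sketch **containment**, estimated on the
same merged bottom sketch as $|A \cap B| / \min(|A|,|B|)$ restricted to
merged-bottom members. Containment, unlike Jaccard, scores a short genome
fully contained in a longer one near 1, which is the behaviour the
aligned-fraction filter is meant to capture. Pairs below 10% containment
are treated as unrelated at both stages.

Before clustering, genomes are pre-filtered as dereplication tools do by
default: length > 50 kb, completeness > 75%, redundancy < 25%. Clustering
is greedy single linkage; determinism is guaranteed by canonically sorting
bins by id, so results are invariant to input permutation. Each secondary
cluster keeps one representative, the member maximising

$$\mathrm{score} = \mathrm{completeness} - 5\,\mathrm{redundancy} + 0.5\log_{10} N50,$$

a simplified genome-quality score (weights configurable via the `scorer`
argument); ties break to the lexicographically smaller bin id.

## Detection and presence

"Detection" is breadth of coverage: the fraction of a genome's positions
covered by at least one read, as distinct from depth. Inputs are BED-like
intervals (0-based, half-open) of per-position read depth; breadth is the
size of the union of depth ≥ 1 intervals (computed with interval
arithmetic from `IRanges`), and mean coverage is total mapped bases over
genome length. Both are exact, not sampled, so they equal per-position
counting — the test suite asserts this against a brute-force
position-array oracle.

Presence is called at detection **> 0.25**: a bin counts as present in a
sample when more than a quarter of its positions are covered. The strict
`>` follows the ">0.25" convention of detection heatmaps; an inclusive
mode is available (`strict = FALSE`). The 0.25 value is a widely used
pragmatic threshold: high enough to suppress spurious cross-mapping from
conserved regions of related genomes, low enough to keep genuinely present
but lowly covered genomes. Note that 0.25 is a *fraction* of the genome,
not 0.25% — callers preferring a percent reading can simply pass
`threshold = 0.0025`.

## Sharing statistics

All host-level statistics are computed from the boolean presence matrix,
bin provenance (the sample each bin was assembled from) and sample
metadata:

- a bin is **shared** when detected in at least one fecal sample other
  than its source sample — by this wording a bin undetected in its own
  source can still be shared;
- species-level presence requires at least one detected fecal sample of
  that species (no quorum beyond one); order-level likewise;
- **soil samples never count** toward any host rollup — environmental
  overlap is a separate query (`environmental_overlap()`) that applies
  the same threshold rule to the soil columns only;
- means (samples, species, orders per bin) are computed over **all** bins,
  with never-detected bins contributing zero; this matches reported ranges
  that start at 0. A `include_undetected = FALSE` mode drops them from
  means only, since whether such bins belong in an average is a
  judgement call.

These definitions make the three partition identities exact:
single-sample + multi-sample + undetected = total, and likewise for
species and orders; the tests enforce them on hundreds of random
matrices. The chitinolytic overlay splits every category by whether the
bin carries an active-site GH18 sequence.

## GH18 active-site screening

GH18 family membership is an upstream annotation; the package screens the
candidate proteins for the conserved chitinolytic active-site motif
**DXXDXDXE** (three aspartate anchors and the catalytic glutamate of the
DXDXE catalytic machinery; `x` matches any residue). Scanning is
case-insensitive, reports all — possibly overlapping — match positions,
and by default removes alignment gaps first: degapped scanning is
alignment-independent and strictly more sensitive than scanning aligned
strings, where a gap inside the 8-residue window would mask a genuine
site. A `degap = FALSE` mode scans aligned strings as-is. Anchor positions
never match ambiguity codes (X, B, Z): an ambiguous residue is not
evidence of an aspartate.

Alignment cleaning (`mask_alignment()`) keeps columns whose non-gap
fraction is **at least** 50% — inclusive, so a column present in exactly
half the sequences is kept. A bin is **chitinolytic** when at least one of
its GH18 records has an active-site match; bins with GH18 sequences but no
active site are tallied separately (many such sequences are
chitin-binding rather than chitin-cleaving, e.g. LysM- or SH3-domain
proteins).

## The synthetic community generator

`generate_community()` produces a complete input bundle plus ground
truth. Its defaults emulate the shape of the motivating study: 29 fecal
samples from 9 host species in 5 orders (sample counts per species 1–6),
8 soil controls, 60 high-quality bins plus 6 low-quality decoys, and GH18
carriage in ~42% of bins with ~62% of carriers given an active site —
matching the observed ratios 132/314 and 82/132. Presence is planted
directly: each bin is a generalist (60%), a specialist confined to its
source species, or never detected (~1.5%, emulating the handful of bins
undetected in any sample); generalists appear in each non-source fecal
sample with probability 0.2 and specialists in conspecific samples with
probability 0.5, values chosen once so the planted means (≈4.8 samples
and ≈3 species per bin) sit near the reported study means (4.86 and
2.73). About 29% of bins are additionally planted in soil, matching
91/314.

Detection realism is deliberately sacrificed for controllability: instead
of simulating reads, each present bin gets a contiguous covered window per
contig sized to a Beta(50, 5) draw (mean ≈ 0.91) and each absent bin to a
Beta(1, 99) draw (mean ≈ 0.01), both far from the 0.25 threshold, written
as 1–3 depth intervals with Poisson(4)+1 depths. Setting
`detection_present = c(1, 0)` and `detection_absent = c(0, 1)` produces
degenerate (noiseless) coverage under which the pipeline must reproduce
every planted count exactly — the strongest end-to-end test. What the
generator does **not** emulate: read-level noise, conserved-region
cross-mapping between related genomes, GC/coverage biases, fragmented
coverage profiles, or realistic taxonomic composition. Passing tests
therefore validate the analysis arithmetic, not robustness to mapping
artefacts.

Genomes default to 250 kb — small for a bacterial genome but large enough
to pass the 200 kb selection floor and the 50 kb dereplication pre-filter
while keeping simulation fast; divergence groups (`divergence_groups`)
plant near-identical genome clusters for dereplication tests. All
randomness flows from the single spec seed, and generation restores the
caller's RNG state, so bundles are byte-reproducible.

## Numerical and engineering notes

- Hashes are 64-bit splitmix64 values of 2-bit-packed canonical k-mers,
  right-shifted by 11 bits so they are exactly representable as doubles;
  k ≤ 32 is enforced by the packing.
- k-mer windows containing non-ACGT characters are skipped rather than
  coerced, so an N breaks the window as in standard sketching tools.
- Jaccard 0 maps to ANI 0 (the Mash distance diverges); containment with
  an empty denominator is 0.
- Interval validation is eager and names the offending row/contig;
  degenerate inputs (empty depth files, bins absent from a sample) yield
  zeros, not errors.
- Cluster labels are assigned by lexicographically smallest member, so
  all outputs are stable under permutation of the inputs.
- Problem sizes in the shipped tests (genomes of 2–60 kb, communities of
  10–30 bins, 10 noisy seeds) were chosen as the smallest sizes at which
  every statistical check is comfortably powered; all package defaults
  are study-scale.

## Known limitations

- Sketch-model ANI is an approximation to alignment-based ANI; at 98%
  with s = 1000 the estimator's standard error is a few tenths of a
  percent, adequate for dereplication but not for reporting precise ANI
  values between specific genome pairs.
- Mean coverage ("abundance") is reported as length-weighted mean depth;
  tools differ in how they define abundance, and no attempt is made to
  match any specific tool's statistic.
- The sharing statistics assume one source sample per bin; co-assembled
  bins would need a convention for provenance.
- Detection tables produced by other tools can be ingested via
  `read_matrix_tsv()`/`call_presence()`, but their dialects may need a
  thin adapter.
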