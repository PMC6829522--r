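---
title: "Methods: differential-coverage binning of single-colony metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential-coverage binning of single-colony metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonybin)
```

# The problem

A single cyanobacterial (*Microcystis*) colony is a mutualistic aggregate of
algal cells and heterotrophic bacteria. Sequencing several such colonies gives
metagenomes in which the attached bacterial populations are represented at
very different abundances from colony to colony, because each colony hosts its
own community. That differential representation is the signal this package
exploits: after a joint assembly, every scaffold has a depth-of-coverage
vector across the colony samples, and scaffolds belonging to one population
share that vector. Grouping scaffolds by coverage profile — *differential-
coverage binning* — recovers draft population genomes that composition-only
binning (GC content plus overall coverage) cannot separate.

Two complications make the problem more than a clustering exercise:

* colony DNA is too scarce for direct library construction, so it is
  amplified by multiple displacement amplification (MDA), which
  over-amplifies low-GC fragments and distorts relative abundances; and
* populations with coincidentally similar abundance profiles land in the
  same coverage cluster and must be separated by sequence composition.

`colonybin` implements the full chain — read trimming, per-scaffold
profiling, GC-bias standardization against an unamplified bulk sample,
density-based binning in 3D log-coverage space, composition refinement,
single-copy-marker quality accounting, and replicate-similarity clustering —
plus a seeded synthetic-community simulator with planted ground truth that
makes every stage testable without external aligners or assemblers.

# The binning model

## Coverage space

For scaffold $i$ and binning sample $s$, mean depth is
$d_{is} = (\text{aligned bases on } i \text{ in } s) / L_i$, computed in one
pass from an alignment table (equivalent in expectation to a per-base
pileup). The binning coordinates are $x_{is} = \log_{10}(d_{is} + c)$ with
pseudocount $c = 0.01$. The log compresses the several-orders-of-magnitude
dynamic range of population abundances into roughly isotropic clouds; the
pseudocount keeps zero coverage finite, which matters because colony-specific
populations routinely have near-zero depth in other colonies. Three samples
are expected (one per colony species); other counts are allowed behind an
explicit flag since the geometry of the method is genuinely 3D.

## Density clustering

The original selection of coverage clusters was interactive; `colonybin`
substitutes DBSCAN with documented parameters so results are reproducible. A
scaffold with total neighbor weight $\ge$ `min_cluster_size` (default 10)
within Euclidean radius `neighborhood_radius` (default 0.3 log10 units) is a
core point; clusters are connected components of core points plus their
border points; the rest is noise. Defaults were validated on simulation (the
spec of the interactive original gives none): at the default study
conditions, within-population clouds have per-coordinate spread of roughly
0.03–0.12 log units (driven by Poisson depth noise on 1–30 kbp scaffolds)
while distinct populations sit 0.5–1.4 log units apart, so a 0.3 radius
separates them with a wide margin. Labels depend only on input order, which
is fixed by scaffold ID.

## Composition refinement

A coverage cluster whose duplicated single-copy-marker count exceeds
`max_duplicated` (default 5, the largest value seen among accepted clean
bins in single-colony practice) is treated as a mixture. Member scaffolds
are projected onto the first two principal components of a *length-weighted*
PCA of their 136-dimensional canonical tetranucleotide frequency (TNF)
matrix, and split by 2-means seeded from the two mutually most distant
members — a deterministic initialization. The split is accepted only if it
reduces the total duplicated-marker count, and accepted sub-bins are refined
recursively, so refinement never increases duplication.

Two design choices deserve justification because the obvious alternatives
fail quantitatively:

* **No separate GC axis, no per-axis standardization.** GC content is a
  linear combination of the TNF features (each 4-mer has a fixed GC count),
  so it is already inside the PCA space; appending it as a z-scored third
  axis equalizes a noisy, weakly informative coordinate with the signal
  coordinate. On simulated mixtures of two genomes at GC 0.676/0.685 with
  distinct composition skew, z-scored PC2+GC axes misassigned 2–4% of bin
  length; natural-scale PC1–2 of the length-weighted PCA misassigned at
  most 1.2% across ten seeds.
* **Length weighting.** Short scaffolds carry high-variance TNF estimates
  (a 1 kbp scaffold has ~1000 windows); weighting the covariance and the
  2-means centroids by scaffold length anchors the axes on reliable
  long scaffolds while still assigning every scaffold.

When the TNF matrix is degenerate (no varying 4-mer), per-scaffold GC is
used as the lone fallback axis.

## Marker accounting

Completeness is the fraction of a catalog of single-copy essential genes
(default size 107; 105/106 variants arise for taxa where some markers do not
apply, so the size is per-bin configurable) found at least once in a bin;
any marker with total count $\ge 2$ counts as duplicated. Quality flags use
the conventional strict thresholds: completeness $> 0.90$ with at most 5
duplicated markers is `near_complete`, $> 0.95$ is `high`, anything else —
including heavily duplicated chimeras, however complete — is `partial`.

In synthetic mode markers are unique random 60-base tags planted into the
genomes and recovered by exact, strand-aware substring search; a 60-mer
occurs in random background with probability $\sim L/4^{60}$, so detection
truth is exact. Real-data users import an external annotation table (e.g.
HMMER hits on predicted ORFs) instead; the accounting is identical.

## MDA bias standardization

The simulator and the estimator share one bias abstraction: a fragment of
GC fraction $g$ is amplified (accepted) with weight
$w(g) = \exp\{-\beta (g - g_0)\}$, $g_0 = 0.5$ — a single-parameter,
strictly decreasing model matching the qualitative behavior of MDA. No
quantitative bias magnitude is available for the real instrument, so
$\beta$ is a free simulation parameter; the default study conditions use
$\beta = 2$, which distorts a 50/50 two-genome community (GC 0.42 vs 0.68)
to roughly 63/37 — a visible, correctable distortion.

Standardization compares the GC histogram of the amplified data against an
unamplified bulk sample on 1-percentage-point bins (fine enough to resolve
the 42–69% range, coarse enough to populate bins):
$$f(b) = \frac{\text{bulk fraction in bin } b}{\text{amplified fraction in bin } b}.$$
Corrected read counts are `mapped_reads × f(bin(gc))` at scaffold
granularity (the finest available), and standardized relative abundances
are corrected-count shares renormalized to sum to 100%, making the output a
composition. Two estimator details:

* bins below 1% occupancy in either histogram do not get a direct ratio
  (a handful of reads would give wild factors); they inherit the nearest
  solid bin's factor and are flagged `smoothed`, as are bins occupied only
  in the amplified sample;
* histograms can be weighted by reads, length, or counts. The pipeline uses
  read weighting on both sides. For a designed 50/50 equal-length
  two-genome comparison, the package's bias-recovery analysis uses the
  deterministic length-weighted histogram as the bulk side, because there
  the bulk read share per bin equals the scaffold length share in
  expectation, and the length histogram has zero sampling variance.

## Read trimming

The trimmer applies, in order: optional exact-match adapter clipping
(full-match anywhere, or a $\ge 8$-base adapter prefix at the 3' end);
removal of leading and trailing bases below Phred 3; truncation at the
start of the first 4-base sliding window (advancing one base at a time,
trailing windows evaluated on their actual length) whose mean quality falls
below 20; and dropping of reads shorter than 50 bases. Because truncation
exposes new, shorter trailing windows, the end-cut and window rules are
reapplied until the kept range is stable; this makes trimming idempotent at
the cost of an occasional extra pass. Pairs in which both mates survive
stay paired; single survivors go to an orphan stream which is excluded from
binning coverage (whether orphans should enter downstream analysis is
genuinely ambiguous; excluding them is the conservative default).

## Replicate clustering

Per-sample genus-level abundance profiles are row-normalized, genera whose
cross-sample range falls below `min_range` (default 0.001 — no threshold is
canonical, and 0.1 percentage points removes only flat genera) are dropped,
and samples are clustered by average-linkage agglomeration on Euclidean
(default) or Bray-Curtis distance. Samples are sorted lexicographically
before clustering so merge tie-breaking is deterministic; trees serialize
to newick with merge heights as branch lengths. Colonies of the same
species should appear as sister leaves.

# The synthetic community

The generator's defaults are the package's study conditions, fixed once:

| parameter | default | role |
|---|---|---|
| genomes | 5 × 200 kbp, GC 0.42, 0.50, 0.54, 0.676, 0.685 | spans the observed GC range of single-colony population bins |
| composition skews | per-genome G/(G+C) and A/(A+T) splits | genome-specific TNF at fixed GC |
| colony samples | 3, strongly differential design | the binning signal |
| high-GC pair | identical abundance vectors | only composition can separate them |
| reads | 50 000 pairs/sample, 2 × 150 bp, insert 600 ± 60 | Illumina-like survey depth |
| errors | 0.5% substitutions, Phred+33 qualities ~ N(37→31, 2) | realistic trimmer input |
| MDA bias | β = 2 on fragment acceptance | correctable distortion |
| bulk sample | 50 000 pairs at the pooled composition, β = 0 | unbiased reference |
| scaffolds | geometric pieces, mean 5 kbp, minimum 1 kbp | wide assembly-like length distribution |
| markers | 105 of 107 60-base tags per genome | completeness truth |

Genome bases are i.i.d. within a genome; marker tags replace background
bases (keeping length exact, with background GC compensated so realized GC
hits the target); fragmentation avoids breakpoints inside marker intervals
by default so completeness truth stays exact (a stress mode allows
splitting). Read "mapping" is derived from the simulator's truth
coordinates: each mate is assigned to the retained scaffold piece with
maximal overlap (at least 30 bases), mirroring a mapper's primary
alignment; mates falling in discarded sub-1-kbp pieces go unmapped, as they
would against a real assembly.

**What the simulator does not emulate** — and hence what passing tests do
*not* establish about real data: chimeric MDA products, strand-displacement
branch artifacts, read indels, within-population strain variation,
repeat-induced misassembly, and real profile-HMM marker search. The
simulator tests the *computation* (binning geometry, bias correction,
accounting); field performance additionally depends on assembler and
aligner behavior that is explicitly out of scope.

# Numerical choices and degenerate inputs

* All coordinates are 0-based half-open; conversion to R's 1-based
  `substr()` happens at one internal boundary.
* N50 uses the dominant convention: the largest $L$ with scaffolds $\ge L$
  covering at least half the total.
* Canonical TNF uses 136 keys (lexicographically smaller of each
  reverse-complement pair; the 16 palindromes map to themselves); windows
  containing ambiguous bases are skipped; GC excludes ambiguous bases from
  numerator and denominator and errors on all-ambiguous input.
* 2-means ties: initialization from the farthest pair is deterministic;
  degenerate inputs (identical points, no varying 4-mer, sub-bins that
  would be empty, splits that do not reduce duplication) return the bin
  unchanged.
* DBSCAN neighbor counts exclude the point itself; weights default to 1.
* Rerunning `run_pipeline()` with the same config reproduces byte-identical
  tables; every stage seed derives from the config seed.

# Problem sizes used by the test suite

The shipped tests run the full study conditions for the end-to-end check
(five 200-kbp genomes, 3 × 50 000 pairs — about half a minute) and scaled
beds elsewhere: an 80-kbp two-genome pair for refinement, 100-kbp genomes
for bias recovery, 5 000-pair three-genome communities for pipeline
plumbing. The scaled beds keep every signal-to-noise ratio in the regime
argued above (scaffolds of 1–30 kbp, depths of 3–40×), so they exercise the
same operating point as the full conditions.

# Known limitations

* The factor-monotonicity diagnostic (Spearman rank correlation of factor
  against GC bin over solidly occupied bins) typically lands between 0.83
  and 1.0 at the stated study size but can dip to ~0.78 for unlucky seeds:
  with only two GC clusters occupied, a single rank inversion among 8–10
  bins moves the statistic substantially. Standardized abundances are far
  more stable (within ~1.5 percentage points of truth) because they
  aggregate over bins.
* Density clustering is $O(n^2)$ in scaffold count; at the intended scale
  (hundreds to a few thousand scaffolds after the 1 kbp filter) this is
  instantaneous, but million-contig assemblies would need an indexed
  neighbor search.
* The N-sample generalization of the coverage space is exposed behind a
  flag but tuned nowhere; radius defaults are argued for 3D only.
* Re-assembly of extracted bin read pairs is a documented external hook;
  the package emits the pair lists and FASTQ subsets but never invokes an
  assembler.
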