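---
title: "Methods: breakpoint-resolved insertion discovery and population genotyping"
author: "panins authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breakpoint-resolved insertion discovery and population genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Reference genomes miss sequence that is present in other individuals of the
same species. For *Bos indicus* cattle, haplotype-resolved ("pseudohaplotype")
assemblies of several breeds can be compared against a single reference to
catalogue **non-reference unique insertions (NUIs)**: stretches of at least
50 bp, anchored at a base-precise reference breakpoint, that the reference
simply does not contain. Genotyping those insertions across a read cohort then
separates rare, individual-private insertions from **common insertions
(BICIs)** segregating in the population, which can be characterized by repeat
content, genic context, population structure and sharing with sister species.

`panins` implements this workflow end to end at desk scale, with a synthetic
cohort generator that fabricates every required input (reference, repeat
library, insertions, diploid genotypes, pseudohaplotypes, paired reads) with
full ground truth, so that every stage is testable without any download.

# The two discovery branches

**Alignment branch** (`discover_nuis()`): sample reads are mapped to the
reference; pairs with an unmapped mate are remapped onto the sample's two
pseudohaplotypes; maximal runs of depth at least 8X (runs closer than 100 bp
merged, mean depth above 100X discarded) become read clusters; each cluster is
extended by 7,000 bp each side (clipped at contig ends) and the window aligned
back to the reference. The best co-linear anchor pair — two flank alignments
on the same chromosome and strand whose query gap is at least 50 bp while the
reference gap stays within 10 bp — defines the insertion: the unaligned query
bases become the inserted sequence and the reference coordinate between the
anchors the zero-width breakpoint. Candidates are dropped when their sequence
re-aligns to the reference at ≥ 95% identity with 100% query coverage, when
the breakpoint falls in a supplied assembly-gap or segmental-duplication
interval, or when fewer than 50 bases survive repeat plus low-complexity
masking. Per-sample calls merge into a non-redundant set when breakpoints lie
within 10 bp and sequences align at ≥ 95% identity with ≥ 95% mutual coverage.

**Graph branch** (`build_backbone()`, `augment()`): assemblies are ordered by
Mash distance to the reference and integrated closest-first into a
multi-assembly graph whose backbone is the reference. Only insertion bubbles
are modeled: adjacent co-linear anchors with a reference gap within 10 bp and
a query surplus strictly exceeding 50 bp either join an existing
non-reference segment at that breakpoint (≥ 95% identity, ≥ 95% mutual
coverage) or create a new one. `graph_stats()` reports the node/edge classes
and the core/flexible partition; `extract_nonref()` emits non-reference
segments longer than 50 bp. The two branches are intersected with best
bidirectional hits at 95% identity / 95% query coverage; alignment-branch
NUIs confirmed by a graph segment form the final set.

**Genotyping** (`genotype_cohort()`): cohort reads are mapped to a carrier
template and, per insertion interval, the covered fraction (positions with
depth ≥ 1) and the majority-consensus identity against the template are
computed; an insertion is *present* iff coverage ≥ 80% and identity ≥ 90%.
Presence frequencies f across all samples give MAF = min(f, 1−f); insertions
with MAF ≥ 5% (and not monomorphic) are the BICI set. Population structure
uses unscaled, centered PCA on the matrix and UPGMA over pairwise Jaccard
distances, serialized as Newick.

# The alignment engine

Every similarity computation runs through one engine (`build_index()`,
`local_align()`, `map_reads()`) so that thresholds mean the same thing
everywhere:

* canonical k-mer index (lexicographic minimum of k-mer and reverse
  complement; k = 15 for genome-scale targets, k = 12 for the repeat
  library); k-mers containing N are skipped;
* seeds grouped by diagonal, stitched with affine-gap dynamic programming
  (match +1, mismatch −4, gap open −6, gap extend −1; a gap of length L costs
  6 + (L − 1)) and extended from both chain ends with a banded X-drop
  (half-width 16, drop 50);
* **chains are split at net indels larger than 30 bp.** This is a deliberate
  engine policy: an insertion of ≥ 50 bp must surface as *two* flanking hits
  for breakpoint resolution to see an anchor pair. Without the split, small
  insertions (50–100 bp) would be absorbed into a single gapped alignment
  and silently vanish from both discovery branches. The corollary is that
  `local_align()` never reports a single hit spanning an indel above 30 bp;
  tools needing such hits should lower `max_bridge` knowingly;
* when aligning megabase contigs, sparse seed chains (fewer than
  `min_chain_bp` seed-covered bases) between diverged repeat copies are
  skipped before extension — a pure performance filter that leaves genuine
  flank anchors (hundreds of seed-covered bases) untouched;
* read mapping is ungapped best-diagonal placement by seed voting; a read is
  mapped iff its score reaches 60% of its length. With this scoring a read
  needs ≥ 92% matching bases, so reads overhanging an insertion boundary by
  more than ~8 bp go unmapped — exactly the reads the discovery branch
  wants back.

Breakpoints are left-aligned (while the last inserted base equals the
reference base before the breakpoint, the representation rotates one base
left), the convention VCF uses for indels. Ground-truth insertions are
normalized identically before any comparison; without a shared normalization
"exact breakpoint" is ill-defined in tandem contexts.

MinHash sketches (`mash_sketch()`, k = 21, s = 1000 — the conventions of the
tool this emulates) hash canonical k-mers to 53 bits so sketches are exact R
doubles; the distance is d = −(1/k)·ln(2J/(1+J)) with J estimated over the s
smallest hashes of the sketch union, capped at 1 when J = 0.

`sdust()` implements symmetric DUST with the interval score
S = Σ c_t(c_t−1)/2 / (w−2) over triplet counts c_t in a window of w bases
(window 64, threshold S > 2). Perfect intervals — score above threshold and
at least the score of every subinterval — are reported maximally and merged
when overlapping.

# The synthetic cohort and what it does (not) show

The generator fabricates the study conditions the workflow is tested under:

* **repeat library**: random consensi with class-typical lengths (LINE 2–6 kb,
  SINE 150–350 bp, LTR 0.3–1.5 kb, DNA 0.2–1.2 kb);
* **reference**: uniform-random background with repeat copies planted at
  5–15% divergence on random strands to a target density (default 25%);
* **insertions**: sizes from log-spaced bins skewed small (half of all
  insertions under ~350 bp, echoing the observed size landscape of common
  cattle insertions), bases ~60% mutated repeat slices with LINE the dominant
  class. Every insertion keeps at least 60 unique bases: an "insertion"
  without 50 unique bases would fail the NUI definition itself, so it cannot
  be ground truth for an NUI caller. Breakpoints sit ≥ 1 kb apart and ≥ 100 bp
  from planted repeats (clean context);
* **cohort**: allele frequencies from Beta(0.3, 0.3) truncated to
  [0.01, 0.99] (a stand-in; no published frequency spectrum exists for these
  events), diploid genotypes drawn binomially, the carrying haplotype of
  heterozygotes recorded; an optional breed offset (± offset/2 in a random
  half of the breeds) creates population structure;
* **reads**: uniform fragments over both haplotypes (half the requested depth
  each), substitution errors only. The substitution-only choice is
  deliberate: the 90% consensus-identity genotyping rule is exercised by
  divergence and error rate, not by sequencer realism.

Two presets define the study scales used by the tests, the analysis scripts
and `scripts/acceptance.R` (sizes are this package's desk-scale choices):
discovery on a 2 × 1 Mb reference with 60 insertions of 50 bp–5 kb, five
sequenced samples at 30X with 0.1% error; genotyping on a 300 kb reference
with 40 insertions of 50 bp–2 kb across 98 samples (five breeds: 20, 19, 20,
20, 19) at 30X.

Passing on these cohorts shows the machinery is correct under its stated
model: exact flanks, substitution-only divergence, clean breakpoints, no
structural noise. It does **not** show robustness to real assembly artifacts
(mis-joins, collapsed repeats, haplotype switches), indel sequencing error,
segmental duplications around breakpoints, or insertions inside young
high-identity repeats — on real data recall inside repeats will be lower
than the near-perfect recovery seen here.

# Numerical and design choices

* **Coordinates** are 0-based half-open everywhere; GFF3 (1-based inclusive)
  converts at the boundary and back on write.
* **Genotyping target**: the cohort is genotyped against a single *carrier
  template* — the reference with the final NUI set spliced in and interval
  bookkeeping kept. Every NUI keeps its native flank context, and one mapping
  pass per sample suffices; genotyping against per-sample pseudohaplotypes is
  the same computation against different targets.
* **resolve_insertion focus**: inside a 14 kb window two true insertions can
  co-occur (breakpoints are only guaranteed 1 kb apart). The pipeline passes
  the read-cluster interval as a *focus*; among qualifying anchor pairs those
  overlapping the focus win, then higher summed anchor score, then leftmost
  reference coordinate. Without a focus the score/leftmost rule alone
  applies.
* **Core/flexible**: a segment is core when its origin set contains all
  genomes, the reference counted as one. A reference segment is "traversed"
  by an assembly when the assembly's anchors cover at least half of it; with
  near-complete assemblies the rule is insensitive to the exact fraction.
* **Repeat-hit acceptance** at ≥ 80% identity and ≥ 30 bp: the engine detects
  library copies reliably up to ~15% divergence, which covers the
  generator's 2–15% range; the famous full-sensitivity repeat maskers go
  further, which is out of scope here. Low-complexity bases count as
  non-unique (the filter applies the union of both masks).
* **Percentages** round half-up at the displayed precision, with raw
  fractions emitted alongside.
* **Ties**: equal-scoring alignment hits sort by lower target id then lower
  start; best-bidirectional-hit ties break by longer alignment then
  lexicographic id; major-TE ties by larger summed hit score then the fixed
  order LINE > SINE > LTR > DNA; UPGMA runs over samples sorted by id.
* **Degenerate inputs**: non-ACGTN bases become N on read (warned, counted);
  N-containing k-mers are never indexed; empty interval lists, empty call
  sets and all-absent genotype profiles are legal and covered by tests.

# Known limitations

Single-threaded, in-memory; genomes beyond a few tens of Mb per index are
outside the intended scale. Deletions, inversions and translocations are not
called. Read mapping is ungapped, so indel sequencing errors would degrade
the depth signal (the generator does not produce them). Linked-read barcodes
are ignored throughout; read trimming is a no-op on simulated reads. The
graph models insertion bubbles only — no SNV/deletion divergent paths — which
is exactly what the non-reference-segment statistics need and nothing more.
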