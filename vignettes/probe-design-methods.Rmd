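---
title: "Two-tier probe design and capture evaluation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier probe design and capture evaluation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Target enrichment (hybridization capture) needs a panel of short probes
(baits) complementary to loci of interest. For non-model clades, no genome is
available to design probes from, and sequences diverged enough from any
reference will not hybridize efficiently. `skimprobe` implements a two-tier
strategy for this situation:

* **Tier 1** selects putatively single-copy nuclear (SCN) loci by combining
  transcriptomes from relatives of the focal clades with curated single-copy
  gene lists from two distant reference genomes, then merges in a universal
  locus set (filtered by taxon source), previously published SCN loci, and
  loci of functional interest.
* **Tier 2** brings the probe sequences close to the focal clades: shallow
  genome-skim reads from within each clade are assembled against the Tier-1
  references, and each locus ends up with one to four *template* sequences —
  clade-specific consensus contigs, the original transcriptome/universal
  sequence, or hybrids splicing a partial contig onto a full-length backbone.
* Templates are tiled into fixed-length probes with screening, and a final
  module computes capture-success statistics from capture-experiment reads.

The distinction between a *locus* (a region of the genome) and its
*templates* (up to four concrete sequences probes are tiled from) runs
through the whole package.

## Tier 1: locus selection

Candidate loci are transcript hits keyed to single-copy gene ids from two
reference genomes. Filters, in order:

* **Minimum gene length, 500 bp (inclusive).** "Minimum" is read as
  admitting the boundary; a 500-bp transcript passes.
* **Exon/intron structure: every exon > 120 bp, every intron < 100 bp
  (strict).** A 120-bp probe cannot be anchored in an exon at or below probe
  length, and long introns break tiling across the locus, so boundary values
  fail. Single-exon models pass the intron condition vacuously.
* **Representative choice.** Where both transcriptomes hit a locus, the
  longer transcript represents it; exact length ties go to a designated
  default transcriptome, and a tie with no default present falls back to the
  lexicographically smallest source name (deterministic, with a warning).

Loci retrieved from *both* genomes are collapsed by **reciprocal best hit**
(RBH): all-vs-all Smith–Waterman, a pair kept only when each member is the
other's *unique* best hit with score at least `min_score` (default 60, the
score of a perfect 60-bp match under +1/−1 scoring — a floor playing the
role of a BLAST e-value cutoff at desk scale). A tied best hit suppresses
the pairing entirely rather than breaking the tie arbitrarily: a tie is
exactly the signature of recent duplication, and silently picking one copy
would defeat the single-copy goal. The merged registry always satisfies
`|merged| = |A| + |B| − |pairs|`; paired loci are represented by the longer
transcript (length ties broken toward a configurable genome precedence).

Single-copy status *inside* the focal clades is not verified — the inputs
that would support that verification do not exist for clades without
genomes, which is the premise of the design. Downstream paralog flags are
the compensating control.

## The alignment engine

All pairwise alignment (global with affine gaps for projections; local for
RBH, screens, and recovery) is served by `Biostrings::pairwiseAlignment`
behind thin wrappers that fix the conventions: match +1, mismatch −1, a gap
of length L costs `gap_open + gap_extend × L` (defaults 3 + 1·L), terminal
gaps penalized in global mode. The test suite pins these semantics to two
independent oracles — a pure-R three-state Gotoh dynamic program and, for
tiny strings, full enumeration of all alignments — so the engine can be
swapped without silently changing scores.

Two derived definitions matter downstream:

* **Gapped percent identity**: matching non-gap columns divided by *all*
  columns, including gap runs and trailing ends. A perfect half-length
  contig globally aligned to its template scores 50, not 100. This is the
  identity reported in the capture statistics, and it is why reported
  identities are systematically lower than overlap-only identity.
* **Star alignment**: each sequence is globally aligned to the designated
  reference and projected into common columns; reference columns are
  preserved in order, and insertions open gap blocks sized by the longest
  insertion at that point. This reference-anchored construction is cheaper
  than a full progressive MSA and sufficient for reference-guided template
  curation, at the cost of ignoring contig-contig signal that the reference
  does not mediate.

## Tier 2: read mapping, consensus, template selection

The read mapper is an exact-k-mer seed-and-vote stage followed by local
alignment of each read against its top candidate references. Defaults:
`k = 13` with 12 seeds per read. The seed length is chosen for the regime
the pipeline targets: at ~15% divergence between a clade and the reference
transcriptome, an exact k-mer survives with probability ≈ 0.85^k, which is
~3% at k = 21 but ~12% at k = 13; with 12 seeds per 150-bp read the chance
of at least one surviving seed is high, and the 13-mer index over a
kilobase-scale reference set remains effectively collision-free. A read is
placed only if its best local alignment reaches 80% column identity over at
least 50 columns; a read whose two best placements tie in score is dropped
as ambiguous (and counted) — the read-level analogue of RBH tie
suppression, and the mechanism by which reads from duplicated loci decline
to choose a copy.

Consensus is a majority vote per reference position, ties broken toward the
reference base (the usual reference-guided convention, and deterministic);
positions where a deletion wins are dropped. Soft-clipped read tails are
laid down ungapped beyond their alignment block, so flanking sequence
(e.g., introns adjacent to a targeted exon) accumulates support; the pileup
window extends `flank_bp` (default 200) beyond each reference end. Maximal
runs with depth ≥ 2 become contigs. Insertions relative to the reference
are not called — the consensus lives in the reference coordinate frame; at
desk scale this costs a few bases around indels and is accepted for
determinism and simplicity.

Template selection clusters the locus's alignment rows (reference +
contigs ≥ 300 bp) by greedy single linkage at 90% gapped identity, visiting
rows longest-first; one template per cluster (its longest ungapped member),
capped at four with the smallest-representative clusters dropped and
logged. The 90% threshold and the 1–4 range are the stated study
conditions; greedy-by-length is this package's deterministic rendering of a
selection that was originally manual, honoring the two criteria that
selection used (relative length and similarity). Special cases:

* a locus from the genome-derived (MarkerMiner-style) source with **no**
  contigs is omitted — its presence in the focal clades has no support;
* loci from the other sources with no contigs keep their reference sequence
  as sole template;
* if all contigs are shorter than 300 bp (strict), the reference is the sole
  template;
* a cluster representative covering less than 90% of the backbone is
  completed into a **hybrid**: backbone prefix + contig + backbone suffix,
  with per-segment provenance recorded. Divergent probe-free gaps reduce
  capture efficiency, which is what hybrids exist to avoid.

Templates are screened against plastid and mitochondrial references (local
alignment, either strand, ≥ 90% identity over ≥ 60 columns ⇒ removed and
reported). The thresholds are package defaults — chosen as "a near-perfect
match at half probe length" — and configurable; a missing organellar
reference skips the screen with a prominent warning rather than silently
passing everything.

## Probe construction

Templates are sanitized (alignment gaps removed; each IUPAC ambiguity code
replaced by the most frequent unambiguous base in its alignment column, ties
to the alphabetically first compatible base; with no column support, the
first compatible base), then tiled: probe length 120, tiling 3× read as
step = 120/3 = 40 bp — the standard bait-design meaning of "k× coverage".
If the final window does not land flush on the template end, one terminal
probe is added at `L − 120` and flagged, so the 3′ end is never uncovered.
Probes with a homopolymer run ≥ 10 bp are rejected ("large homopolymer"
quantified as ≥ 10, configurable); survivors are screened against plastid,
mitochondrial, and nuclear decoy references with the same local-alignment
rule as above, flags accumulating additively (`organelle_hit`,
`nuclear_decoy_hit`). Everything emitted into the panel passes every enabled
screen; flagged probes appear only in the report. `panel_summary()` gives
the locus/template/probe totals and the template-multiplicity histogram,
with `tidy()`/`glance()`/`autoplot()` views.

## Capture evaluation

Capture reads are mapped to the template panel with the same mapper and
assembled per template. A template counts as **recovered** when some contig,
globally aligned to the template, has at least 55% of its own bases matching
(no length floor by default) — similarity over the whole query in the
exonerate style, so small high-identity islands inside an unrelated contig
do not qualify. The 55% default renders the "default similarity threshold"
convention of exon-recovery pipelines; it is a parameter, not a claim.
Derived statistics:

* templates recovered at ≥ 50% of reference length (inclusive);
* paralog flag: ≥ 2 distinct contigs each spanning ≥ 85% of the template
  (the documented "multiple long contigs" convention);
* percent on-target reads = placed / total × 100;
* locus rollup: a locus is recovered iff *any* of its templates is (union
  semantics; per-locus taxon counts are unions of per-template sets);
* clade summaries: mean and (min–max) of each per-sample statistic, with
  supercontig length = exon + intron length where both are present;
* alignment variation: a column is parsimony-informative iff ≥ 2 distinct
  non-missing states each occur in ≥ 2 sequences; constant iff exactly one
  state occurs; `N` and `-` are missing (gaps count as missing because the
  reported missing-data percentages coexist with gapped alignments).
  Percentages are rounded half-up to one decimal, matching how such tables
  are conventionally printed (`round()`'s half-to-even would disagree on
  exact halves).

## The simulator and what it does (not) show

`make_gene_space()` fabricates the full input bundle: an ancestral gene
space with exon/intron structure; two clades at 15% divergence (per-site
substitutions plus geometric indels, mean 3 bp, applied per segment so both
genomic and spliced truth are known); two transcriptomes at 2% divergence;
overlapping single-copy lists for two reference genomes; a taxon-annotated
universal set; published/functional query fragments; organellar and nuclear
decoy references. Planted adversaries with recorded truth: loci violating
the structure filter, loci under 500 bp, verbatim duplicate loci placed in
both genome lists, a plastid segment inside one locus, and a locus segment
inside the nuclear decoy. Reads are uniform-position, fixed-length,
constant-quality, with Bernoulli substitution errors — 15× skims and
enrichment-ratio-driven capture reads (on-target odds ratio/(1+ratio);
5.67 ≈ an 85% on-target regime).

Deliberately absent: quality-score and GC bias, paired-end insert-size
structure, de novo repeat structure, real hybridization chemistry. Passing
tests on these fixtures therefore demonstrates the pipeline's logic —
filters fire, bookkeeping identities hold, clade-matched templates recover
better than mismatched ones — not wet-lab capture efficiency on real
libraries.

Problem sizes used by the test suite and the acceptance script — 30
candidate loci plus auxiliary sets, two skim read sets at 15×, one capture
sample per clade — are the package's chosen demonstration scale: large
enough for every planted signal to be detectable, small enough to iterate
on.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere (BED-compatible); validators
  enforce it at the file boundaries.
* All ties anywhere (representative choice, dedupe, consensus, clustering
  order, ambiguity resolution) break deterministically, and every stochastic
  step consumes an explicit seed; the pipeline proper is deterministic.
* Empty inputs degrade explicitly: empty probe sets write empty files; a
  zero-read sample reports `NA` on-target with a message; screens without
  references warn and skip.
* `U` is normalized to `T` on read (transcriptome inputs may be
  RNA-alphabet); IUPAC codes are preserved until probe sanitization.

## Known limitations

* The star alignment never sees contig–contig homology that the reference
  does not mediate; two contigs identical to each other but 50% diverged
  from the reference would land in separate clusters.
* The consensus cannot represent insertions relative to the reference.
* The k-mer mapper has no mismatch-tolerant seeding; sensitivity decays
  quickly beyond ~20% divergence, which bounds the clade depth the Tier-2
  stage can serve.
* Recovery and screening thresholds are conventions rendered as defaults,
  not fitted quantities; the functions expose them all as arguments.
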