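---
title: "Context-based refinement of spliced read mappings: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-based refinement of spliced read mappings: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicerefine)
```

## The problem

Spliced short-read mappers leave three kinds of damage in an RNA-seq
mapping: reads they could not place at all, reads they placed in several
locations without choosing, and junction-spanning reads they forced into
ungapped or clipped placements. `splicerefine` takes any single-end SAM
mapping plus the reads and the genome, and refines it in three phases so
that every mappable read ends with exactly one location:

1. **Context identification.** Uniquely mapped reads are clustered into
   *expression contexts* — read clusters in which consecutive reads are at
   most `d_min` apart (default 10 kb), so distinct contexts are separated by
   more than `d_min`. A context approximates "one expressed region"; the
   intronic gap of a split read belongs to its span, so a context can bridge
   an unmapped stretch larger than `d_min` when that stretch is spliced out.
   Distance is measured between the outermost coordinates of two reads
   (`next start − previous end`, half-open). Gene annotations (BED) can
   replace the distance rule via the `annotation_bed` config key.

2. **Candidate extension.** All unmapped and multi-mapped reads are
   re-aligned against every context window (padded by one read length so
   junction anchors at the edge stay alignable). The aligner is a seed-and-
   extend search in both directions: a seed of 40% of the read, capped at
   40 bp, anchored at the read start (forward) or end (backward), tolerating
   `seed_mm = 1` mismatch in the seed, extended greedily until the
   alignment-wide budget `max_mm = 4` would be exceeded. Forward and
   backward hits of one read combine into a *full* alignment (one block) or
   a *split* alignment (two blocks across one intron of 20–400,000 bp); the
   junction point slides across the overlap of the two hits, and every
   placement satisfying the maximum-mismatch criterion is kept as a
   candidate. All split placements, plus the initial split records, define
   the *potential splice sites* `(s1, s2)` of the context; every full or
   partial alignment covering `s1` or `s2` is then additionally re-spliced
   at the site if that respects the mismatch budget (`splice_extend()`),
   which is how reads initially forced straight through an intron recover
   their junction.

   Instead of a compressed full-text index, the seed search uses an exact
   k-mer dictionary with pigeonhole splitting: the seed is cut into
   `seed_mm + 1` equal fragments and all fragments of all pool reads are
   matched exactly in one Aho–Corasick pass per window
   (`Biostrings::matchPDict`). Because a seed with at most `seed_mm`
   mismatches must contain one exact fragment, this reports exactly the hit
   set a mismatch-tolerant index search would, is trivially re-buildable per
   context, and is directly testable against a naive Hamming scan (the test
   suite does both).

3. **Ambiguity resolution.** See below.

## Resolving ambiguities

**Mismatch filter.** A read is dropped from every context where its best
candidate needs more than `delta_mm` mismatches beyond its best candidate
anywhere (default 2: one sequencing error plus one genuine variant — the
parameter is defined by the method but has no canonical published value).

**Splice-site evidence.** Each site's support tally `n_i` counts the reads
backing it with `i` mismatches — split candidates at the site, full
alignments ending exactly at `s1` or starting at `s2`, and partial
directional hits doing the same. Its evidence is

$$\mathrm{evidence} = \lambda \cdot \sum_{i=0}^{m} 0.3^i\, n_i,$$

with `λ = 2` when the intron is bounded by a configured splice signal
(default `GT..AG`, checked in both orientations so minus-strand `CT..AC`
introns qualify) and `λ = 1` otherwise. Two sites *overlap* when both donor
and acceptor coordinates differ by less than the read length — such sites
are alternative placements of the same reads or biologically implausible
neighbours. Within each connected set of pairwise-overlapping sites only the
maximum-evidence site survives; candidates using dropped sites are
discarded, and a read left with nothing re-enters splice extension against
the surviving sites.

**Coverage score.** Per context, `c_m` counts at every position the reads
whose candidates cover it; a read with several candidates counts once per
position in their union. Around each candidate, region 1 is its aligned
positions, region 2 everything within 200 bp beyond either end, region 3
(200, 500] bp, region 4 (500, 1000] bp; `score_i` is the maximum `c_m` in
region `i`, and

$$\mathrm{coverage} = \sum_{i=1}^{4} 2^{\,4-i}\,\ln(\max(score_i, 1)).$$

The log makes the sum behave like a geometric mean (robust to outliers),
the halving weights discount distant evidence, and intron interiors of
split candidates are excluded throughout. Zero-coverage regions enter as
`ln 1 = 0`; regions are clipped at the padded context window.

**Greedy assignment.** Full and split candidates of one read sharing a
start or an end are merged into one option; the final full-versus-split
choice is made afterwards over only the *distinguishing* positions (the
non-shared aligned positions, plus the flank on whichever side the
endpoints differ). Reads are resolved in priority order of the margin
between their best and second-best option. The default `static` mode scores
once and resolves everything on those scores — equivalent to a per-read
argmax with deterministic tie-breaking, and the variant the method's
authors themselves ran for speed. `dynamic` mode re-derives `c_m` after
each fixation (a fixed read stops covering its discarded candidates) and
re-scores affected reads before the next pop; it is exact but quadratic,
intended for small contexts. Between contexts the same greedy logic runs on
each read's per-context winner score; this phase is always static — the
within-context phase has already concentrated each context's evidence, and
a cross-context dynamic update would couple all contexts into one global
recomputation for marginal benefit.

All ties anywhere break deterministically by (mismatches ascending,
reference name, leftmost start, read id), so results are invariant to input
order.

**Expression filter.** A resolved read is emitted only if at least
`min_support = 100` other reads map within `support_window = 1000` bp
up- or downstream — an isolated placement does not suggest real expression.
Both thresholds are user-configurable; filtered reads are reported as
unmapped with reason `low_expression`.

## The simulator

`simulate_dataset()` generates the conditions the refinement is designed
for, with recorded truth:

* **Gene models** (`simulate_gene_models()`): 20 genes by default on a 1-Mb
  random genome, 2–5 exons of 150–400 bp, introns of 100–1000 bp carrying
  `GT..AG` in transcription orientation, loci separated by more than
  `d_min` so true contexts are unambiguous. Expression weights are drawn
  log-uniformly over two orders of magnitude so that expression-binned
  evaluation has populated bins. For 30% of genes an *identical intronless
  copy of the spliced transcript* is planted at a distant locus, emulating a
  recent processed pseudogene: reads of the parent gene then genuinely map
  to two places with equal mismatch counts, which is precisely the ambiguity
  class that coverage-based resolution (and not a fewest-mismatches rule)
  can break. The copy is identical rather than diverged because divergence
  would let mismatch counts resolve the ambiguity trivially.

* **Reads** (`simulate_reads()`): sampled per gene by weight, uniformly
  within the transcript; per-read error count `Binomial(l, rate)`;
  error offsets from the `uniform` model or the `polynomial` model with
  cumulative distribution `F(x) = x³/l³` (sampled by inversion,
  `x = l·U^{1/3}`), emulating quality decay toward the read end; the
  substituted base always differs from the original. Reads spanning two or
  more junctions are redrawn, matching the one-splice-per-read alignment
  model.

* **Degraded initial mapping** (`degrade_to_initial_mapping()`): each read
  is dropped (`p_drop = 0.05`), reported at truth plus a decoy locus
  (`p_multimap = 0.3`), reported *uniquely* at the decoy
  (`p_misplace = 0.05`, only for genes with a transcript copy — real
  mappers do misassign multi-mapping reads, and without some unique records
  at the copy no context would ever form there), or — junction reads only
  (`p_shift = 0.3`) — emitted without the splice, half as an ungapped
  read-through record with mismatches in the tail and half as a
  soft-clipped single-block record. The decoy locus is the homologous
  position in the transcript copy where one exists, else uniform random.
  Dropped reads are simply absent from the SAM.

What the simulator does *not* emulate: indels, quality strings, paired
ends, fragment-length and positional sampling bias, overlapping genes,
alternative isoforms, and divergence between gene and pseudogene copies.
Passing tests therefore demonstrate the machinery on clean substitution-only
data with well-separated single-isoform genes, not performance on real
libraries.

## Evaluation

A prediction is an **exact** true positive when every base is placed
correctly (identical blocks), a **relaxed** true positive when additionally
placements with the correct outermost start *or* end are accepted;
unmapped, doubly-reported and otherwise misplaced reads are false
negatives, and accuracy is `TP / (TP + FN)`, computed separately for
complete and junction-spanning reads. `coverage_binned_accuracy()` ranks
genes by average read count per transcript base and cuts them into four
near-equal groups (quantile cuts on the rank with stable ordering, fewer
groups when there are fewer genes).

The bundled comparison point, `baseline_min_mismatch()`, assigns each read
a minimum-mismatch candidate with random tie-breaking. When comparing it
against the refined mapping the test suite passes both through the same
expression filter, so the comparison isolates the resolution rule rather
than confounding it with the output filter.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at 20 genes × 20,000 reads of
74 bp (with and without errors), a scale chosen so the complete suite runs
in minutes on one core while every context still holds hundreds of reads;
error-model fidelity is checked at n = 10⁵ draws, and the scoring and
clustering oracles at 500–1000 randomized fixtures each. Coordinates are
0-based half-open internally, converted exactly at the SAM boundary.
Records with clips or indels in the initial mapping are treated as unmapped
and re-aligned (the alignment model is mismatch-only); initial unique
records are re-verified against the reference and moved to the
re-alignment pool when they exceed `max_mm`.

## Known limitations

* For reads near exon or gene boundaries, the coverage score can favour an
  intronless transcript copy over the true locus: the copy's flanking
  regions are uniformly covered while the true gene's introns and gene end
  contribute zeros to regions 2–4. A small fraction (~1% in the bundled
  conditions) of multi-mapped reads of pseudogene-bearing genes therefore
  resolve to the copy. This is a property of the scoring scheme, not of the
  implementation.
* Reads the initial mapper reports uniquely at a wrong locus are trusted
  and never re-aligned, per the method's contract.
* At most one splice per read; no indels; mismatch costs are not
  quality-weighted.
* The expression filter trades recall at weakly expressed genes for
  precision; at shallow simulated depth this visibly lowers accuracy for
  the weakest genes (set `min_support = 0` to disable).
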