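---
title: "Closing inter-contig gaps with an optical map: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing inter-contig gaps with an optical map: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omconnect)
```

## The problem

A draft bacterial assembly is a set of contigs plus a contig graph: a
bidirected graph whose nodes are contigs and whose edges join contig *ends*
(5' or 3'), recording which contigs the assembler saw adjacent in reads.
Repeats make the graph branch, so the walk the genome actually takes through
it is not determined by the graph alone. An optical map -- the ordered list
of restriction-fragment (RF) lengths along the chromosome, measured on
single molecules without base calls -- fixes the order and orientation of
the contigs it can place, but the *sequence* between two neighbouring placed
contigs is still missing. `omconnect` fills those gaps with other contigs:
it searches the contig graph for paths between each pair of neighbours and
keeps the path whose stitched length matches the measured gap.

The method stands on one physical observation: a gap on the map has a
*size*, and among the candidate walks through the graph usually only one has
that size. Exploiting it requires (i) trusting the map's length scale, hence
a rescaling step, and (ii) enumerating candidate walks including repeat
traversals without exploding, hence a loop-recording search.

## Workflow

1. **Placement.** Every large contig (default >= 500 bp, and at least
   `min_matched_rfs = 5` internal RFs) is digested in silico and aligned to
   the map by dynamic programming over fragments (`align_contig()`), or an
   external placement table is imported (`read_placements()`). Only the
   fragments *between* a contig's first and last cut site are matched: the
   two end fragments are truncated by the contig boundary, not by an enzyme
   site, and carry no sizing information. A contig is *uniquely* placed when
   its best location has no rival within a 20% score margin
   (`classify_uniqueness()`). Gap closing by default uses only unique
   placements; they terminate path searches because such a contig occurs
   once in the genome.

2. **Rescaling.** Optical maps systematically mis-size fragments; published
   bacterial maps run up to ~8% short of the sequence lengths. During alignment some blocks pair exactly
   one map RF with one contig RF; for those the ratio map/contig is a direct
   measurement of the scale. The factor is the arithmetic *mean* of these
   ratios over blocks whose contig-side fragment is at least 10 Kb
   (`fit_factor()`): shorter fragments show erratic ratios, and the mean --
   not the median -- is the method's definition; a `robust` median variant
   exists but is off by default. Gap sizes are *divided* by the factor, so a
   factor below 1 grows gaps into sequence bp.

3. **Gap census.** Neighbouring placements define gaps from the rightmost
   matched restriction site of the left contig to the leftmost matched site
   of the right contig; circular maps contribute the wrap-around pair. Each
   map RF inside the gap counts with a 2 Kb floor: fragments shorter than
   ~2 Kb tend to disappear from real maps, so a fragment that short which
   *is* reported cannot be trusted below that resolution.

4. **Path search.** A modified depth-first search (`find_paths()`) starts at
   the left flank's exit end (3' for `+`, 5' for `-`) and walks the
   bidirected graph honouring end orientation. A branch dies when its
   accumulated sequence length exceeds `length_slack = 1.2` times the
   rescaled gap, or when it meets a uniquely placed contig other than the
   right flank. Meeting a contig already on the path *in the same
   orientation* records a **loop** -- the cycle's members and its length per
   traversal -- and the branch is not re-expanded; this keeps the search
   linear in the graph rather than exponential in the repeat copy number.
   Re-entry in the *opposite* orientation is allowed (a contig flanked by
   the same inverted repeat is a real arrangement, and blocking it is a
   known failure mode of naive graph extraction). Recorded loops attach to
   every candidate path containing their anchor, transitively through other
   loops for nested repeats.

5. **Closure.** For each candidate, every loop's copy number `n >= 0`
   minimises `|base_length + n * loop_length - gap|` independently; the
   combinatorial space of joint assignments is deliberately not searched --
   with several loops the answer is rarely decidable by length alone, and
   the correct behaviour is to leave the gap open rather than guess
   (`optimize_loop_copies()`, `select_best()`). A gap closes only when the
   best candidate is within `match_tolerance = 2000` bp of the gap size and
   beats the runner-up's length by more than `ambiguity_cutoff = 2000` bp.
   Ambiguous candidate sets are written in full to an intermediate file so
   that mate pairs or coverage can arbitrate later. Closed paths are
   stitched (`stitch_path()`), minus-strand members reverse-complemented,
   with `junction_overlap` bp trimmed per junction (0 for
   Newbler-style graphs, k-1 for k-mer graph dialects).

## Parameters that matter

| parameter | default | units | why this value |
|---|---|---|---|
| `large_threshold` | 500 | bp | below this, contigs are noise-prone assembly stubs |
| `min_matched_rfs` | 5 | RFs | fewer matched fragments cannot identify a locus |
| `sizing_tolerance` | 0.10 | relative | per-block map sizing scatter envelope |
| `merge_penalty` | 0.25 | score | cost of a missed restriction site; without it the aligner would merge maximally because summed blocks let noise cancel |
| `max_unmatched_ends` / `end_skip_penalty` | 2 / 0.5 | RFs / score | a contig-boundary site that vanished from the map otherwise strands the whole contig |
| `min_rf_for_fit` | 10000 | bp | ratio of map to contig length stabilises above 10 Kb |
| `rf_floor` | 2000 | bp | map resolution: shorter RFs drop out of real maps |
| `length_slack` | 1.2 | fold | admissible path length overshoot during search |
| `match_tolerance` | 2000 | bp | maximum length disagreement for a closure |
| `ambiguity_cutoff` | 2000 | bp | two best paths closer than this are indistinguishable |

The aligner is a functional stand-in for an external placement tool, not a
replica of any: its internals (tolerance, penalties) are engineering
choices exposed in `align_params()`, and the pipeline is
placement-source-agnostic -- a placement TSV produced by another aligner
drives the identical downstream workflow. Because the global map scale is
unknown before rescaling, `run_pipeline()` aligns twice: a first pass at a
doubled tolerance yields 1-vs-1 blocks whose median ratio centres the
second, definitive pass (`scale_hint`). The reported rescaling model is
always fitted on the final placements, with the mean, per the method's
definition.

Two selection rules resolve questions the method's prose leaves open. The
ambiguity comparison is between the two best *path lengths* (not their
distances to the gap), because the motivating five-bp example compares path
lengths directly. Zero loop copies are admissible: a recorded loop edge may
simply not be used in a particular gap, and the candidate set must contain
both the looped and loop-free readings so that length can discriminate.

## What the generator emulates -- and what it does not

`generate_scenario()` builds a genome with planted repeat structure
(`dispersed`, `tandem` with spacer, `nested` two-level clusters), cuts it
into contigs exactly at repeat boundaries (one contig per repeat family --
an idealised assembler), derives the contig graph from genomic adjacencies,
and produces the map by in-silico digestion followed by: multiplication
with a true scale factor `s`, per-fragment lognormal sizing noise, and
stochastic loss of sub-2 Kb fragments (each vanishes with probability 0.8,
merging into its left neighbour -- the enzyme site is what went
undetected). Everything is deterministic given the seed, and the truth
table's path expansions are self-checked against the genome at generation
time.

Base composition defaults to GC 0.64 so that the AflII site density lands
near one site per 9 Kb, the density published bacterial optical maps show
(e.g. 508 RFs over a 4.6 Mb chromosome); uniform-random sequence would
double it and with it the small-fragment dropout rate. Scenario noise
levels (`s` in [0.9, 1.1], sigma <= 2%) follow the regime optical-map
rescaling is designed for.

Not emulated: read-level errors and misassembly (contig boundaries are
exact), chimeric map molecules, length-dependent sizing bias (real maps
over-claim short RFs; modelling that trend is out of scope and the 10 Kb
fit cutoff sidesteps it), and reverse-oriented repeat instances in the
default arrangements. Passing tests on these fixtures therefore shows the
*logic* is right under realistic sizing physics, not that any particular
real dataset would reach the same closure rate.

The standard validation suite (`standard_scenarios()`) fixes four study
conditions: `clean` (no repeats, no noise, no dropout -- the identity
round-trip), `dispersed` (four two-copy families, s = 0.95, 2% noise),
`tandem` (a three-copy tandem array plus dispersed families, s = 1.05, 2%
noise) and `nested` (loops inside loops, s = 0.9174, 1% noise). The first
three are constructed to be unambiguous. The nested gap needs a *joint*
copy-number assignment across two loops, which the closure rule refuses to
arbitrate, so that gap is expected to stay open -- by design, not defect.
Genome sizes (0.7-0.9 Mb) keep the whole suite under a minute; they are
desk-scale stand-ins chosen so each scenario still yields 6-10 gaps and
~20 rescaling blocks.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open at file boundaries; fragment indices on
  circular maps reduce modulo the fragment count, and the wrap-around gap
  is built explicitly.
* Rescaled gap sizes round to integer bp; loop-copy ties break toward
  fewer copies.
* Neighbour expansion during the search is ordered lexicographically by
  (contig id, end), and candidates, loops and report rows sort by their
  keys, so identical inputs give byte-identical outputs.
* Placements whose map spans overlap produce no gap (skipped with a
  warning); a flank placed without any matched cut site makes its gap
  undefined (`flank_without_site`); searches that trip the candidate or
  step valve mark the gap `search_overflow` and no closure is attempted.
* With no qualifying rescaling block the factor falls back to 1 with a
  prominent warning rather than failing the run.
* Contig ids are text, never integers: `006` stays `006`.

## Known limitations

* The built-in aligner does not model per-molecule stretch variation or
  chimeric joins; heavily fragmented maps (mean RF < ~4 Kb) defeat its
  missed-site allowance of two consecutive losses per block and three
  merged fragments per side.
* Gaps whose true path needs joint copy numbers across several loops stay
  open; coverage-based arbitration is a documented non-goal.
* One map, one enzyme per run; multi-map scaffolding is out of scope.
* Velvet-style `LastGraph` input is an extension point only: junction
  overlap is already a parameter (k-1), but no parser is shipped.
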