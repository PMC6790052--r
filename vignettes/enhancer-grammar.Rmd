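---
title: "Predicting enhancers and comparing binding-site grammars with cisgrammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting enhancers and comparing binding-site grammars with cisgrammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisgrammar)
```

## The problem

Compact genomes such as those of tunicates make it practical to locate a
developmental enhancer by its *structure* rather than by alignable sequence:
orthologous enhancers often retain a recognizable set of short
transcription-factor binding motifs even after the intervening DNA has
diverged beyond alignability. Two regimes are of particular interest:

* **enhanceosome-like** elements, in which the number, order, orientation,
  and spacing of binding sites are all conserved because the bound factors
  form a position-dependent complex (a 10 bp spacing change — one helical
  turn — can abolish function);
* **loosely organized** ("billboard") elements, which tolerate gain, loss,
  reordering, and respacing of sites.

`cisgrammar` implements three connected analyses for this setting:

1. a **sliding-window predictor** that scores windows of a candidate region
   (typically a 5′ intergenic region) against a characterized reference
   enhancer from a related species;
2. an **architecture comparison** quantifying conservation of the
   binding-site grammar between two elements;
3. **in-silico site-directed mutagenesis** (binding-site knockout and
   displacement) mirroring the reporter-construct manipulations used to
   test such elements in vivo.

Because the analyses are exercised on synthetic loci with planted ground
truth, the package also contains a first-class, seeded **synthetic-data
generator**.

## The window score

A window of width $w$ (default 150 bp) slides along the target region in
steps of $s$ (default 25 bp). Each window receives a linear combination of
four features, each normalized to $[0,1]$:

$$\mathrm{score} = \frac{\sum_i w_i F_i}{\sum_i w_i}, \qquad w_i \ge 0 .$$

**F1 — shared oligomer content.** Oligomers are substrings of length at
least `min_oligo` (default 4 bp) present in both the window and the
reference enhancer, allowing reverse complements. By default F1 counts the
*distinct* shared words of any qualifying length, normalized by
$2(w - k + 1)$ (one anchored word per position per strand) and clamped at 1.
A `tile_count` mode instead counts the greedy maximal tiling described
next.

**F2 — ordering similarity.** The window is tiled greedily left to right
by *maximal* shared substrings: at each position the longest substring
occurring anywhere in the reference (either strand) is taken, recorded,
and the walk resumes after it. Each tile is matched to a reference
occurrence (duplicate words consume occurrences left to right). F2 then
measures how much of this shared material is already in reference order:
the default `weighted_moves` model computes the maximal total tile length
over subsequences whose reference offsets increase, and divides by the
total tile length. Equivalently, $F2 = 1 - (\text{moved material})/
(\text{total material})$ under an element-move edit model weighted by
oligomer length. An unweighted `adjacent_swaps` model
($1 - \text{inversions}/n$, clamped) is available for comparison.

**F3 — positional similarity.** Enhancers often retain their approximate
position relative to the gene. With $d$ the distance from the window start
to the start codon and $L$ the length of the 5′ region,
$F3 = 1 - |d_\mathrm{window}/L_\mathrm{target} -
d_\mathrm{ref}/L_\mathrm{ref}|$, clamped to $[0,1]$. When the reference
element's genomic position is unknown, F3 is a neutral constant 1 and does
not affect the ranking.

**F4 — conserved motifs.** The count of gene-specific required motifs
(e.g. Ets1/2 `GGAW`, or TBX6 `GGNG`) on both strands, saturating at
`f4_cap` (default 3).

Candidates are the `top_n` (default 3) non-overlapping windows at or above
the 95th percentile score, ties broken toward the smaller start; optionally
overlapping above-threshold windows are merged into union intervals.

### Why these defaults for F1 and F2

Both defaults were chosen for identifiability at realistic parameters, and
the reasoning is worth recording. With `min_oligo = 4` and a ~200 bp
reference, almost every 4-mer occurs in the reference on one strand or the
other, so *any* 150 bp window — related or not — tiles almost completely
with short chance oligomers (~30 tiles). Two consequences follow:

* Counting *tiles* makes F1 anti-informative: a window that is an exact
  copy of the reference is a **single** maximal tile, scoring far below a
  random window's ~30. Counting *distinct shared words* restores the
  intended behavior (an exact copy shares every one of its substrings, the
  provable maximum).
* An unweighted inversion count over ~30 mostly-random tiles is almost
  surely larger than the tile count itself, so the clamped
  $1 - \mathrm{steps}/n$ collapses to 0 for every window, conserved or
  not. Weighting by tile length recognizes that a diverged ortholog's
  shared material is concentrated in a few long, collinear segments, while
  chance oligomers are short and randomly placed.

## Architecture extraction and comparison

`architecture_of()` scans an element for a motif set and returns the
ordered hit list, per-hit strands, and the end-to-start gaps between
consecutive hits. `compare_architectures()` aligns two architectures by
longest common subsequence of their motif-type strings and reports:

* per-type count differences;
* `order_conservation` = LCS length / max(hit counts);
* `orientation_agreement` over LCS-matched pairs;
* `spacing_deltas` (absolute gap differences between consecutive matched
  hits) and their residues modulo the helical period (default 10 bp,
  configurable to 10.5);
* `rigidity`, a scalar in $[0,1]$: the mean of order conservation,
  orientation agreement, and $\exp(-\overline{\Delta\mathrm{gap}}/10)$.
  Rigidity is exactly 1 iff number, order, orientation, and spacing all
  agree — the operational definition of enhanceosome-like conservation
  here — and each elementary perturbation (strand flip, respacing,
  site loss) strictly lowers it. The composite is this package's own
  summary, not a published statistic.

## In-silico mutagenesis

`knockout_motif()` replaces one motif occurrence with a same-length word
such that no configured motif matches anywhere overlapping the replaced
span on either strand. A fixed substitution table is consulted first — by
default the classic Ets1/2 knockout `GGAT -> GCTT` — but a fixed word is
*verified in context* and the policy falls back to seeded rejection
sampling (bounded at 100 draws) when flanking bases would turn the fixed
word into a new site (e.g. `GCTT` followed by `CC` reads `TTCC`, an Ets
site on the minus strand).

`displace_motif()` moves a site by a signed offset relative to an anchor:
the original site is knocked out and the site's word written at the
destination. The edit is accepted only if the motif's total hit count is
unchanged and no cryptic site of any configured motif appears at the
destination junctions. Moving a site 6 or 14 bp upstream of a 10 bp gap
yields gaps of 16 or 24 bp — 6 and 4 bp out of helical phase respectively.

## The synthetic-data generator

`simulate_locus()` produces a reference enhancer, a diverged ortholog, and
a background region with the ortholog planted at a recorded truth
interval.

* **Grammar.** The default reference grammar is FoxF-style: three Ets1/2
  words and two ATTA words (E1, A1, E2, E3, A2 along the element), the
  E1–A1 gap fixed at 10 bp (one helical turn) and the remaining gaps at
  15 bp. The 10 bp value is the biologically meaningful one; the 15 bp
  defaults are arbitrary and config-exposed. The element is padded with
  random spacer to 183 bp, the size of a well-characterized conserved TVC
  enhancer.
* **Spurious-site rejection.** Spacer bases are redrawn locally (only the
  offending non-planted positions, bounded iterations) until scanning the
  element recovers exactly the planted sites. Local redrawing matters:
  ~160 bp of random spacer contains several chance `GGAW`/`ATTA` matches
  in expectation, so global rejection would almost never terminate.
* **Rigid regime** substitutes spacer bases independently at a configured
  rate (default 0.3) while leaving motif words, order, orientation, and
  gaps untouched; such pairs always score rigidity 1.
* **Rearranged regime** perturbs the grammar itself (site loss and
  duplication at 0.15 per site, strand flip at 0.15, gap jitter up to
  ±8 bp, gaps floored at 2 bp) and rebuilds the element with fresh
  spacers; at least one realized change is guaranteed when any rate is
  positive, so rigidity is below 1.
* **Background** is i.i.d. sequence at a configured GC content (default
  0.40, reflecting AT-rich tunicate non-coding DNA), 866 bp by default —
  the size of the upstream region minimized in the founder-cell enhancer
  experiments the generator emulates. The planted element is verified to
  occur exactly once. Because the plant position is random by default, a
  synthetic locus carries no meaningful ATG-relative position, and
  predictions on such loci run with F3 neutral; supplying a fixed
  `plant_position` together with reference position metadata emulates
  position-conserved orthologs instead.
* **Seeding.** A single global seed expands into per-operation substreams
  (`seed * 101 + offset`, offsets 1–3 for reference/diverge/plant), so
  every stage is independently reproducible and byte-identical across
  runs.

What the generator does **not** model: indels in spacers (the rigid regime
preserves absolute gaps, which indels would break), repeat structure,
compositional heterogeneity, and any phylogenetic substitution model.
Passing the planted-recovery benchmark therefore demonstrates sensitivity
to grammar-preserving divergence in clean backgrounds, not performance on
real genomes with repeats and indel-riddled spacers.

## Numerical and convention choices

* Coordinates are 0-based, half-open everywhere, matching BED natively.
* Reporter-construct names of the form −a/−b (distances upstream of the
  start codon, ATG at 0) map to the half-open interval
  $[\mathrm{ATG}-|a|, \mathrm{ATG}-|b|)$ of length $|a|-|b|$, which
  reproduces the printed sizes of the minimal elements handled here
  (155 bp and 146 bp). Published construct sizes do not always satisfy a
  single consistent convention; where they do not, the interval arithmetic
  above is authoritative for this package.
* `N` participates in no oligomer and matches no motif letter, degenerate
  or literal. Sequences are uppercased on input; characters outside
  `ACGTN` are rejected, not coerced.
* Ties in candidate calling go to the smaller start; duplicate oligomer
  words match reference occurrences left to right; hit tables sort by
  start, then strand (`+` before `-`).
* `ordering_steps()` is the exact adjacent-transposition (Kendall)
  distance, computed as the inversion count of the induced permutation;
  the BFS over the transposition graph used in the tests is an
  independent oracle for it.
* Scoring a region shorter than one window is an explicit error rather
  than an empty result.

## Benchmark sizes

The planted-recovery property is evaluated on 50 seeded rigid-regime loci
(866 bp backgrounds, substitution rate 0.3), the oracle equivalences on
200 random instances each, and the architecture regimes on 10 seeded pairs
per regime; these sizes keep the full check suite comfortably fast on a
single CPU while leaving the binomial noise on a ≥ 90% recovery criterion
small. `scripts/acceptance.R` recomputes all of these quantities from
scratch for any seed.

## Limitations

* The predictor is a similarity ranker, not a classifier: scores are
  comparable within one run, and the percentile-based candidate threshold
  adapts to each region rather than carrying cross-locus meaning.
* Functional classification of individual sites (required vs redundant)
  is a wet-lab question; no sequence property computed here separates
  those classes.
* Whole-region alignment (phylogenetic footprinting) is out of scope;
  where elements are alignable, alignment-based tools are complementary.
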