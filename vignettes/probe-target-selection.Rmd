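---
title: "Selecting satellite DNA targets for chromosome enumeration probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting satellite DNA targets for chromosome enumeration probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satprobe)
```

## The problem

A chromosome enumeration FISH probe must bind one chromosome brightly and
nothing else. Satellite DNA blocks — tandem repeats reiterated over tens
to thousands of kilobases at a single locus — are ideal targets: copy
number supplies signal intensity, locality supplies specificity. But
repeat-rich regions also accumulate interspersed, transposon-derived
elements (SINE, LINE, LTR, DNA transposons) that occur genome-wide; any
probe overlapping them cross-hybridizes everywhere. The selection
criterion is therefore compositional: *dense in satellite, free of
interspersed repeats*. `satprobe` turns that visual browser-inspection
criterion into a reproducible computation, and adds the downstream steps
a probe developer needs: clone selection, consensus-avoiding primer
design, in-silico PCR verification, and a genome-wide specificity screen.

## Coordinate conventions

Internally, every interval is 0-based half-open, so lengths are
`end − start` and abutting intervals share a boundary without overlap.
Two paper-facing conventions are converted at the I/O boundary only:

* RepeatMasker `.out` query coordinates (1-based inclusive, strand `C`
  for minus) are converted on parse;
* BAC clone tables stay 1-based inclusive in the data model, because that
  is the convention under which a consistent clone row satisfies
  `insert = end − start + 1` — the check `check_clone_consistency()`
  performs. `select_clones()` converts at the comparison.

BED is already half-open and passes through untouched.

## The region scan

`scan_candidate_regions()` slides a window of `window` bp (default
10,000) by `step` bp (default 1,000) and computes, per window,
union-of-overlaps base coverage by two class sets:

* `satellite_classes` (default `Satellite`) must cover at least
  `min_satellite_fraction` (default 0.8);
* `interspersed_classes` (default SINE, LINE, LTR, DNA, Retroposon) must
  cover at most `max_interspersed_fraction` (default 0 — the criterion
  taken literally; relax it for noisier annotations).

`Simple_repeat` and `Low_complexity` count as neither by default: they
are short, ubiquitous and uninformative for this decision, and the
convention is configurable. Qualifying windows that overlap or abut
exactly are merged (no gap tolerance), merged regions shorter than
`min_region_length` (default 20,000 bp — below the scale at which a BAC
probe fits inside the region) are dropped, and both fractions are
recomputed over each merged span. A merged region whose recomputed
composition fails the thresholds is dropped too, so reported regions
always honour the criterion they were called by.

Two consequences of this design are worth knowing:

* **Edge slack.** A window qualifies while up to
  `window × (1 − min_satellite_fraction)` of it (2 kb at defaults) hangs
  past an array edge, so a called region overshoots each edge by up to
  that much. Reciprocal overlap with a clean planted array of length
  `L` is therefore `L / (L + 4 kb)` in the worst case — above 90% only
  for arrays larger than ~36 kb. The acceptance suite plants 50–70 kb
  arrays, the scale of the worked chromosome-16 region (~72 kb); for
  smaller arrays the bound degrades by geometry, not by bugs.
* **Mixtures.** Whether a target should consist of a *single* satellite
  family is left to the user: `single_family = TRUE` additionally
  requires one `rep_name` to account for all satellite coverage in a
  region (default off, since annotations often split one array into
  several names).

`rank_regions()` orders by satellite fraction, then length, then start —
a deterministic total order.

## Clone selection

Probes are cut from BAC clones, so the practical question is which clones
lie in a candidate region. The default `contained` policy keeps clones
entirely within the region (a probe chosen *within* the satellite block
cannot carry flanking unique sequence); `overlap` mode keeps clones whose
overlap fraction of their span reaches `min_overlap_fraction`. Contained
selection is monotone in the region and always a subset of any overlap
selection — both are tested properties.

Clones placed at "multiple" sites are a distinct category, not noise: a
probe made from such a clone targets a dispersed repeat and binds many
sites on its chromosome — useful as a high-signal enumeration probe, but
never as a unique-locus probe. `select_clones()` excludes them from
selection and, with `allow_multimapping = TRUE`, reports them separately
under `attr(x, "dispersed")`.

The packaged clone table (`table1_fixture()`) transcribes the published
six-clone selection verbatim, including comma thousands-separators and
the multi-mapping Y clone. One published inconsistency is carried as-is:
the prose names a different X-chromosome clone (RP11-294C12) than the
table lists (RP11-348G24); the fixture follows the table.

## Primer design against a consensus motif

Satellite families share short consensus motifs (the default `TTCCA` is
the human satellite III pentamer). A primer overlapping many motif copies
would amplify every related family; primer sites are therefore chosen for
*minimal* consensus homology. No scoring formula is standard, so the
package operationalizes homology as two numbers, both strand-symmetric by
default: the count of exact motif occurrences inside the primer, and the
fraction of primer bases covered by the union of those occurrence
footprints. `enumerate_primers()` scores every substring of the requested
lengths on both strands and ranks ascending by (coverage, count), then by
|GC − 0.5|, then by position, strand and length — fully deterministic.
Approximate (mismatched) motif matching exists behind `max_mismatch` in
`consensus_homology()`, default off. Melting temperature uses the Wallace
rule `2(A+T) + 4(G+C)` only; it ranks 18–30-mers adequately and keeps the
scorer closed-form. `N` bases never match any motif or primer position,
and GC/Tm are undefined (an error) for primers containing `N`.

## In-silico PCR

`insilico_pcr()` finds forward-primer sites on the plus strand and
reverse-primer sites as the reverse complement on the same strand, each
with at most `max_mismatch` Hamming mismatches — no indels, uniform
weighting, no 3'-end special-casing (the simplest model that reproduces
real primer-site geometry; thermodynamic site models are out of scope).
Every pairing with the forward 5' end at or left of the reverse 5' end,
both footprints inside the product, and product length at most
`max_product` (default 5,000 bp) is reported, 1-based inclusive, ordered
by start then length. On tandem templates this deliberately includes
cross-copy products under the size cap — real PCR on satellite DNA
produces exactly such ladders.

## The specificity screen

The historical workflow checked candidate sequences with an interactive
BLASTn search at permissive sensitivity. That is neither deterministic
nor offline, so the package substitutes exact canonical k-mer counting:
the probe's overlapping k-mers (default k = 16; k-mers containing `N`
skipped) are canonicalized to the lexicographic minimum of the k-mer and
its reverse complement, and every chromosome position whose k-mer falls
in the set is counted — overlaps included, because satellite targets are
tandem and collapsing overlaps would understate copy number. The mapping
from BLAST sensitivity settings to k is heuristic: smaller k is more
sensitive (hit counts are monotone non-decreasing as k decreases), and
k = 16 behaves like a stringent word match, not like an alignment.

`classify_probe()` applies thresholds the source describes only
qualitatively, so the defaults are package choices: chromosome-specific
when the target fraction is at least 0.95 *and* the target carries at
least 10 hits; dispersed when two or more chromosomes each carry strictly
more than the hit threshold (the signature of a repeat probe binding
genome-wide); otherwise at off-target risk.

## The synthetic world

`generate_fixture()` builds test genomes from a seeded specification:
uniform random background over A/C/G/T; tandem arrays as exact monomer
copies with i.i.d. per-base substitution at the stated divergence rate
(no indels, so planted coordinates stay exact — testability was chosen
over realism); interspersed elements as labeled random intervals; primer
sites spliced in verbatim. One integer seed governs all randomness
through an isolated RNG scope, and identical spec + seed gives
byte-identical files. The truth manifest records realized coordinates,
substitution offsets, and the expected downstream answers (regions,
selected clones, amplicons) computed from the planted geometry — not by
running the pipeline — so closure tests compare two independent routes.

What the generator does **not** emulate: higher-order repeat structure,
indel divergence, assembly gaps, annotation errors, or the scale of a
real genome. A green planted-recovery test establishes that the scanner
finds what the annotation declares, under the window geometry's
resolution limit — not that the thresholds are right for any particular
real annotation.

`dyz1_like_monomer()` deserves its own note: it is a *synthetic* 3,564 bp
stand-in for the Y-heterochromatin repeat monomer, built from
TTCCA-family pentamers with a 40 bp motif-free island and the two
published primer sites planted at the published binding geometry (forward
5' end at position 2965, product end at 3212, product 248 bp). The real
monomer sequence is not shipped; only the length and the primer-site
geometry follow the published description, and the construction verifies
site uniqueness (re-drawing the background deterministically if a site
recurs by chance) so the one-amplicon prediction is guaranteed for every
seed.

## Numerical and degenerate-input choices

* Fractions are exact rationals of integer base counts; no floating-point
  tolerance is needed anywhere in the scan.
* A window larger than the chromosome is a warning plus an empty result,
  not an error — common when batch-scanning scaffolds.
* An empty FASTA is an empty list; an empty clone-table body is an empty
  table; a primer pair with no sites is an empty amplicon frame. Errors
  are reserved for malformed input, and parse errors name the offending
  line.
* All ranking comparators end in a positional tie-break, so every ordered
  output is a total order and repeated runs are identical.

## Known limitations

* Interspersed-repeat exclusion is only as good as the annotation; the
  scanner never inspects sequence.
* The k-mer screen cannot see diverged homology below exact k-mer
  identity; it replaces a sensitivity-tunable alignment search with a
  deterministic lower bound on cross-hybridization risk.
* Wallace-rule Tm is a ranking heuristic, not a thermodynamic prediction.
* The in-silico PCR model ignores primer dimers, secondary structure and
  amplification efficiency; wet-lab validation is out of scope.
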