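# satprobe

Chromosome enumeration by FISH needs probes that light up one chromosome and
nothing else. The cheapest reliable targets are blocks of satellite DNA:
tandem repeats reiterated thousands of times at a single locus, so a probe
binding them gives a bright, countable signal. The catch is that a candidate
block must be *dense* in satellite repeats yet *free* of interspersed
elements (SINE/LINE/LTR/DNA transposons), which occur genome-wide and would
make the probe cross-hybridize everywhere.

`satprobe` implements the desk half of that probe-development workflow,
offline and deterministically:

1. **Target discovery** — slide a window (default 10 kb, step 1 kb) over a
   repeat annotation; keep windows with satellite coverage ≥ 0.8 and
   interspersed coverage ≤ 0 (union-of-overlaps base coverage); merge
   overlapping/abutting windows into candidate regions ≥ 20 kb and
   recompute composition over the merged span.
2. **Clone selection** — pick BAC clones lying within a candidate region
   (`contained` mode, or fractional `overlap` mode), and cross-check clone
   tables: under 1-based inclusive coordinates every consistent clone row
   satisfies `insert = end − start + 1`. Multi-mapping clones are modeled
   explicitly as dispersed-target probe candidates, never selected as
   unique probes.
3. **Primer design** — score primers on a repeat monomer by homology to a
   satellite consensus motif (default `TTCCA`, counted on both strands:
   occurrence count + footprint coverage; lower is better), with GC and
   Wallace-rule Tm (`2(A+T) + 4(G+C)`) filters.
4. **In-silico PCR** — Hamming-mismatch site search (no indels) for a
   primer pair on a template; every forward/reverse pairing with both
   footprints inside the product and length ≤ 5 kb is reported in 1-based
   inclusive coordinates.
5. **Specificity screen** — a deterministic k-mer surrogate for an
   interactive BLASTn check: canonical k-mer (default k = 16) hit counts
   per chromosome, a target-hit fraction, and a
   `chromosome_specific` / `dispersed` / `off_target_risk` / `no_hits`
   classification.
6. **Synthetic fixtures** — a seeded generator planting satellite arrays,
   interspersed elements, clone placements and primer sites into random
   genomes, with a JSON truth manifest; byte-identical output per seed.

## Worked example

```r
library(satprobe)

# Clone selection against the packaged published clone table:
clones <- parse_clone_table(table1_fixture())
check_clone_consistency(clones)
#>          name span_bp reported_insert delta consistent
#> 1 RP11-242E13      NA           98295    NA         NA    <- multi-mapping
#> 2 RP11-348G24  208607          208607     0       TRUE
#> 3  RP11-88G23   26624           26624     0       TRUE
#> 4 RP11-246K16   26678           26678     0       TRUE
#> 5  RP11-416F8   26678           26678     0       TRUE
#> 6 RP11-486E19   26550           26550     0       TRUE

region16 <- region_from_paper_coords("16", 46385500, 46457245)
select_clones(clones, region16)$name
#> [1] "RP11-88G23"  "RP11-246K16" "RP11-416F8"  "RP11-486E19"
```

All five mapped clones are internally consistent at tolerance 0, and the
chromosome-16 satellite region contains exactly four clones — the four a
probe developer would pick.

```r
# In-silico PCR of the historical Y-repeat primer pair on a synthetic
# 3,564 bp DYZ1-like monomer (primer sites planted at the published
# binding geometry):
mono <- dyz1_like_monomer(seed = 1)
insilico_pcr(mono, WYR4, WYR6)
#>           template_id start  end length fwd_start fwd_mismatches rev_start rev_mismatches
#> 1 DYZ1_like_synthetic  2965 3212    248      2965              0      3186              0
```

One product, 248 bp, spanning template positions 2965–3212: the forward
primer's 5' end is the product start, the reverse primer binds the
opposite strand with its 5' end at the product end.

```r
# Region scan over a generated fixture (50 kb satellite array planted at
# 40,000-90,000 in a 150 kb chromosome):
res <- generate_fixture(fixture_spec(
  seed = 9, chromosomes = data.frame(name = "chrA", length = 150000),
  planted_arrays = list(list(chrom = "chrA", start = 40000,
                             monomer = strrep("TTCCA", 4), copies = 2500,
                             divergence = 0.01))), tempdir())
scan_candidate_regions(res$annotation, 150000, scan_config())
#>   chrom start   end length satellite_fraction interspersed_fraction dominant_rep_name n_windows
#> 1  chrA 38000 92000  54000          0.9259259                     0    SAT_chrA_40000        45
```

The recovered region overshoots each array edge by up to
`window × (1 − min_satellite_fraction)` = 2 kb — the resolution limit of
the window criterion.

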