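---
title: "sequelkit: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sequelkit: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sequelkit)
```

This vignette is the package's own account of what it computes and why the
open design questions were settled the way they were. It states no empirical
result that the test suite does not itself compute.

## The data model

Single-molecule real-time sequencing circularizes a double-stranded insert
with hairpin adapters (an "SMRTbell") and lets an immobilized polymerase in
a zero-mode waveguide (ZMW) traverse it continuously, often several times.
The full contiguous sequence from one ZMW is the *polymerase read* or
*continuous long read* (CLR). Instrument software splits each CLR into
*subreads* (the insert copies) and *scraps* (adapters, barcodes, low-quality
regions), written to separate per-SMRTcell files. Each read is named
`movie/holeNumber/qStart_qEnd`, with `qStart`/`qEnd` 0-based, half-open
coordinates on the CLR; a read's length is always `q_end - q_start`. Scraps
additionally carry a one-character ZMW classification (`N`ormal, `C`ontrol,
`M`alformed, `S`entinel; tag `sz`) and a region type (`A`dapter, `B`arcode,
`L`Q region, `F`iltered; tag `sc`).

Everything sequelkit computes is coordinate arithmetic on these names: a
ZMW's CLR is reconstructed by summing its segment lengths, never by
comparing sequence. Segments of one ZMW must not overlap — overlap has no
physical meaning on a linear coordinate system and is treated as corrupt
input rather than silently merged.

Two deliberate conventions in the CLR definition:

- **CLR length is the sum of the provided segments**, not `max(q_end)`.
  The two differ only when segments are absent from the inputs, and the
  minimum-length filter is defined over the scraps the user *provided*;
  summation honors that exactly.
- **Only normal scraps enter QC.** Non-normal ZMW classes are instrument
  controls or artifacts; they are excluded before bundling, uniformly for
  every read group. (The filtering tool, by contrast, counts *all* provided
  scraps toward CLR length, because its criterion is defined that way.)

## Read groups and statistics

Per SMRTcell, reads are organised into up to four groups: subreads, longest
subreads (one per subread-bearing ZMW, ties in length broken by smallest
`q_start` so the choice is deterministic), CLRs (one per ZMW — a scraps-only
ZMW still has a CLR), and subedCLRs (CLRs containing at least one subread).
Without scraps files only subreads and longest subreads exist; with scraps a
two-group mode (subreads, subedCLRs) can be requested instead of all four.

For each group: read count, total bases, mean, median, N50, L50.

- **N50 / L50.** The descending-sorted lengths are accumulated until the
  running sum first reaches *at least half* the total; N50 is that element's
  length and L50 its 1-based rank. The `>= total/2` tie rule is the common
  convention; the statistic's source description leaves it unstated. N50 is
  always a member of the length list and never below the plain median.
- **Median** of an even-sized group is the midpoint average; the summary
  table prints mean/median at 0.1-base resolution (internal objects keep
  full precision).
- **Empty groups** report `NA`, not 0, so plots can skip rather than draw
  zero bars.

Two cross-group ratios summarize the cell:

- **PSR** = total longest-subread bases / total subread bases. 1 when every
  template was read at most once; decreases with multi-pass redundancy.
- **ZOR** = subedCLR count / subread count, ideally exactly 1.

As defined, both ratios are provably in (0, 1] whenever a subread exists
(longest-subread bases are a subset of subread bases; subedCLRs are at most
as numerous as subreads). The narrative description accompanying ZOR's
formula elsewhere speaks of values "above one" for multiply-loaded ZMWs;
that reading is inconsistent with the printed formula, which this package
implements as printed. Multiple templates (or passes) per ZMW drive the
ratio *below* one. Because PSR and ZOR are per-cell, cross-group
quantities, the summary table reports them once per cell, on the subreads
row — the table layout was otherwise unspecified.

## The plot suites

Ten plot codes: A (N50 barplot), B (L50), C (total bases), D (read-length
histograms), E (subreads per subedCLR), F (adapters per CLR), G (subread
length boxplot), H (subedCLR length boxplot), I (ZOR), J (PSR). With scraps
the full/intermediate/basic suites are A–J / A,C,G,H,I,J / A,C; without
scraps A,B,C,D,G,I,J / A,C,G,I,J / A,C; intermediate is the default. A, B,
C, G, H, I, J show all cells in one figure; D, E, F get one file per cell.
Boxplots overlay each cell's N50 as a blue diamond.

Design choices where the layout was open: cells are ordered
lexicographically by movie name; histogram bins are equal-width, auto-scaled
to the data range (Sturges' rule), with edges recorded in the sidecar; every
figure writes a `.tsv` sidecar of exactly its plotted numbers. The sidecars
are the supported extension point for custom plotting (tests assert figure
content through them rather than comparing pixels), replacing the upstream
idea of swapping in a user-edited plotting script. Per-ZMW intermediate
tables (`<movie>.zmw_summary.tsv`) are deleted at the end of a QC run unless
`keep_intermediates = TRUE`.

## Subsampling

*Longest* mode emits exactly one record per subread-bearing ZMW — the
per-ZMW argmax with the smallest-`q_start` tie rule. Providing scraps with
longest-only mode is defined (the scraps output is an identity copy) but
warned against, since the copy serves no purpose. *Random* mode selects
`max(1, floor(fraction × N))` ZMWs (or an exact `n_zmws`) uniformly without
replacement, and keeps every subread and scrap of a selected ZMW
(ZMW-atomicity) in input order. The seed is a required, logged parameter so
bootstrap draws are reproducible; the caller's RNG state is restored
afterwards. Combined mode selects ZMWs first, then takes the longest
subread of each. Outputs are always exact sub-multisets of inputs: no
record is ever rewritten.

## Filtering

Three composable criteria, all requiring both files:

1. **Minimum CLR length** — a ZMW survives iff its CLR (all provided
   scraps counted) is `>= threshold`; the boundary is inclusive by
   definition. Failing ZMWs are removed from *both* outputs: emitting
   scraps for deleted CLRs would break ZMW-atomicity downstream, even
   though the criterion's upstream step list mentions re-iterating only the
   subreads file.
2. **Complete pass** — operationalized as adapter adjacency: some subread
   has an adapter scrap ending exactly at its `q_start` and another
   beginning exactly at its `q_end`. A subread bounded by adapters on both
   sides implies at least one full SMRTbell traversal, and adjacency is
   computable from exactly the files the tool requires. Applied per ZMW, to
   the scraps output only (the alternative per-read reading would have the
   criterion delete subreads, contradicting its stated scope).
3. **Normal adapters** — a scrap survives iff class `N` *and* region `A`
   (1 of the 12 class × region combinations).

Within one run the criteria compose as an intersection over the *original*
input, so they commute, and each single criterion is idempotent. A combined
configuration is deliberately **not** idempotent: re-running it re-measures
CLR lengths and pass status on the already-reduced scraps. That
re-measurement is not a defect — it is exactly what the recommended two-run
workflow exploits: run the full-pass and normal-adapter filters first, then
the minimum-length filter on the first run's outputs, so that undesirable
scraps no longer count toward CLR length. The test suite asserts this
ordering difference on a hand-tiled fixture.

## The synthetic SMRTcell generator

Tests and acceptance run on simulated cells because the real reference data
sets are hundreds of gigabytes. The generator emits the world the tools
assume, with one closed-form truth table per cell:

- Each ZMW's segments tile `[0, clr_length)` exactly; a k-pass ZMW is
  alternating adapter/subread segments (k subreads, up to k+1 adapters),
  optionally preceded by a low-quality region and a barcode, with the
  leading/trailing adapter each missing with probability 0.25 (a polymerase
  that starts or stops mid-pass).
- Defaults, chosen once as a realistic mid-quality Sequel cell and not
  revisited: subread lengths log-normal with `meanlog = 9` (~8.1 kb
  median) and `sdlog = 0.55`; passes per ZMW `1 + Geometric` with mean 2;
  45-base adapters; 16-base barcodes; 5% scraps-only ZMWs (a single
  low-quality scrap); 5% non-normal scraps (C/M/S at 0.4/0.4/0.2); 10%
  barcodes; 15% leading LQ regions.
- Sequences are random ACGT of the correct lengths — no operation in the
  package reads sequence content — and a coordinates-only mode writes `*`
  for speed. The same spec always produces byte-identical files.

What the simulator does *not* emulate: sequencing errors, kinetics or
methylation tags, per-ZMW (rather than per-scrap) classification, correlated
pass lengths from a shared insert, or realistic per-base qualities. A green
oracle-equivalence test therefore establishes that the QC arithmetic is
correct over the stated segment model, not that the package has been
validated against instrument output; the file dialect, however, is the
standard one (headered SAM, PacBio names, `sz`/`sc` tags), and one
round-trip test exercises real `samtools` BAM conversion.

## Numerical and degenerate-input choices

- All statistics are computed in double precision from integer lengths;
  oracle comparisons in the tests use a 1e-9 tolerance for reals and
  exactness for integers.
- Empty inputs: an empty group is all-`NA`; an empty cell summarizes to
  all-`NA` with `NA` PSR/ZOR; empty record sets write valid header-only
  files; a zero-ZMW fixture is a valid empty pair with an empty truth table.
- Zero-length reads (`q_end <= q_start`) are rejected at parse time; a
  sequence whose length contradicts its coordinates is a parse error.
- Ties: longest subread by smallest `q_start`; N50 by the first element
  reaching half the total.
- Determinism: QC is pure; random subsampling is a pure function of
  (input, fraction/count, seed); multi-cell runs are deterministic in the
  thread count because parallelism is per SMRTcell (the natural unit of
  work) and results are re-ordered lexicographically before reporting.

## Known limitations

- BAM support shells out to `samtools`; without it on the PATH only SAM
  works (every contract is testable on SAM).
- `mean_passes` must be at least 1 and the last pass is drawn from the same
  length distribution as complete passes, so simulated final passes are not
  systematically truncated.
- The complete-pass criterion depends on adapter coordinates being exactly
  adjacent to subread coordinates; inputs that trim coordinates (e.g.
  re-processed files) would need a tolerance the tool does not currently
  expose.
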