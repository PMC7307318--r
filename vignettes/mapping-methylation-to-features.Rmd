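---
title: "Mapping array methylation onto genomic features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping array methylation onto genomic features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmapr)
```

## The procedure

Illumina 450K/EPIC arrays measure, at each CpG probe, a methylation fraction
β ∈ [0, 1] per sample group. Differential pipelines condense this into a
site-level table: per probe, the two group means, their difference Δβ
(experimental − control; negative = loss in the experimental group), and an
FDR-adjusted p-value. `methmapr` turns such a table plus a plain list of
feature names into per-feature statistics and genome-browser tracks. The
chain is deliberately simple and fully deterministic:

1. parse and canonicalize the table (`read_meth_table()`);
2. resolve feature names to intervals (`resolve_features()` /
   `resolve_repeat_features()`);
3. assign probes to features by interval overlap (`assign_probes()`);
4. summarize each feature per group (`summarize_group()`);
5. emit bedGraph tracks (`build_trackset()`, `emit_bedgraph()`).

`run_pipeline()` orchestrates all five for one or many comparisons.

The key assumption throughout is that a probe is a point measurement: it is
represented as a 1-bp interval at the interrogated CpG position (2 bp
optionally, to cover the dinucleotide), and feature membership is pure
co-occurrence — a probe belongs to a feature iff its interval overlaps any
of the feature's intervals by at least 1 bp. No distance-based or
nearest-feature assignment is attempted, and strand never enters the
overlap (probes are strandless).

## Coordinate conventions

Positions in RnBeads/ChAMP/custom exports are treated as 1-based (the
R-ecosystem convention) and converted to 0-based half-open on input; UCSC
refGene and rmsk dumps and BED are already 0-based half-open and are taken
as-is; RepeatMasker `.out` coordinates are 1-based inclusive and converted.
All output (bedGraph) is 0-based half-open per the UCSC standard. The
half-open convention is unit-tested at the boundaries: a probe starting
exactly at a feature's end coordinate does not overlap it.

Chromosome names are normalized to UCSC style (`1` → `chr1`, `MT`/`chrMT` →
`chrM`), and track lines sort by natural chromosome order (`chr2` before
`chr10`) then start.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `upstream` | 500 bp | promoter extent upstream of the TSS; the window is −`upstream` → +1, i.e. length `upstream`+1 including the TSS base, strand-aware, clipped at position 0 |
| `alpha` | 0.05 | FDR threshold for the significance track |
| `probe_width` | 1 bp | probe footprint (2 bp renders the CpG dinucleotide) |
| `region` | `"all"` | promoter, gene body, or their union per transcript |
| `column_map` | per dialect | column-name overrides, since export schemas drift across package versions |

The promoter default encodes the common "−500 to +1" working definition;
because manifest promoter definitions are a recurring source of
misclassification (probes in the first exon of single-exon genes, for
instance), the extent is a first-class parameter rather than a constant.

## Numerical choices

* **Scale.** Statistics are reported on a 1–1000 display scale (β×1000); 811
  means 81.1 % methylation. Scaling is exact internally; 3 decimals are
  applied only when formatting output. Percent conversions round
  half-away-from-zero to 1 decimal (base R's `round()` rounds half to even,
  which would turn 62.65 into 62.6 or 62.7 depending on parity).
* **Median** of an even probe count is the midpoint of the two central
  values; **SD** is the sample (n−1) standard deviation, reported as 0 for a
  single probe. Whether upstream tools use population or sample SD is not
  observable from their outputs; sample SD is the common default and the
  choice is isolated in one function.
* **Zero-coverage features** stay in the results with empty statistic cells:
  probe coverage is itself a quality signal, and silently dropping rows
  would hide it.
* **Delta tracks** stay on the −1…+1 β scale while absolute tracks use
  1–1000: the two kinds answer different questions (how large is the change
  vs how methylated is the site) and mixing scales would make small
  epidemiological effects invisible next to absolute levels. Rendering is
  blue for gains, red for losses, autoscaled so the largest change in view
  sets the axis.
* **FDR tracks** show passing probes at the *experimental* group's absolute
  methylation — p-values themselves do not scale meaningfully in a browser.
  The choice of group is a documented convention, not information from the
  input. When no probe passes, the emitted file is exactly the comment line
  `#No FDR significant sites`, a sentinel downstream tooling can match.

## Open design points, decided

* **Isoforms** are unioned: a gene's feature is the union of the mode's
  interval over every matching transcript, with exact duplicates removed.
  Picking the first or longest transcript would be a silent, version-
  dependent choice; the union is stable and matches the deduplication step
  of the original interactive workflow.
* **Overlapping intervals within a feature are not merged.** Merging is
  unnecessary — assignment already counts a probe at most once per feature —
  and keeping the raw intervals preserves the annotation's structure for
  debugging dumps.
* **Group order**: in two-mean schemas the first per-group mean column is
  the experimental group, the second the control, consistent with the
  convention Δβ = experimental − control; a `column_map` override can pin
  either explicitly.
* **Missing FDR columns** (allowed in the custom dialect) make the FDR track
  an error unless `allow_missing_fdr = TRUE`, which then emits the sentinel:
  silently producing an empty significance track would be indistinguishable
  from "nothing significant".
* **Repeat queries** resolve at the RepeatMasker *class* level (LINE, SINE,
  LTR, Satellite, …); family- and name-level granularity is out of scope.

## The synthetic-data generator

`fixture_spec()` → `make_annotation()` → `make_tables()` builds a complete
miniature study: non-overlapping genes with random strands on a synthetic
chromosome (`chrT`), repeat intervals per class, probes placed at distinct
positions inside each gene body plus background probes outside every
feature, per-group β values drawn from normals truncated to [0, 1] around
per-feature means, and an FDR column constructed so a chosen probe subset
passes 0.05. Every interval and record is returned as ground truth, and the
same records are emitted in all three dialects. One seed fixes everything,
so generation is byte-deterministic.

What it emulates: the shape of the data (schemas, coordinate conventions,
group structure, effect sizes, noise). What it does **not** emulate: probe
chemistry (type I/II design biases), SNP-affected probes, the beta-mixture
shape of real methylation distributions, correlated probes within CpG
islands, or real genome annotation complexity (overlapping genes, many
isoforms per locus). Passing tests therefore demonstrate that the machinery
is correct — parsing, geometry, assignment, statistics, track emission — not
that any biological preprocessing upstream was appropriate.

Truncated-normal noise (rather than a Beta distribution) is used because
the validation only interrogates moments; with the default sd of 0.05
around means well inside (0, 1), truncation bias is negligible
(&lt; 10⁻⁴ on the β scale).

## Problem sizes and validation

The test suite validates against independent oracles built in the tests
themselves: a quadratic all-pairs overlap scan for assignment, sort-based
medians and definitional SDs for statistics, and brute-force
promoter/gene-body unions for feature resolution. Representative sizes —
500 probes × 20 features for oracle equivalence, 1000 random genes for
promoter geometry, 20 features × 50 probes for parameter recovery (pooled
recovered means within 3 standard errors of the specified 0.8 and 0.3), and
a 3-comparison batch for the output contract (10 tracks, 6 results tables) —
keep the whole suite to well under a minute while exercising every code
path. Recovery error is additionally checked to shrink as probes per
feature grow through 5 → 50 → 500.

## Limitations

* No IDAT reading, normalization, QC, SNP filtering, or differential
  testing: the input *is* a finished differential table.
* No hypothesis testing or enrichment on the per-feature summaries; the
  statistics are descriptive.
* Annotation is whatever file the user supplies; there is no download
  mechanism or build verification beyond a tag comparison (mismatches warn).
* bedGraph only — no bigWig, track hubs, or browser session management.
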