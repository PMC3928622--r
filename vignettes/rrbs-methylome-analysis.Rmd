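---
title: "RRBS methylome analysis with rrbskit: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RRBS methylome analysis with rrbskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbskit)
```

# The analysis problem

Reduced-representation bisulfite sequencing (RRBS) measures DNA
methylation at single-base resolution over the CpG-dense slice of a
genome captured by restriction digestion. `rrbskit` implements the full
computational chain for an MspI/TaqI RRBS design comparing two dietary
exposure groups (low vs high maternal folic acid, LMFA vs HMFA) in
offspring brain tissue:

1. **In-silico digest** (`digest_genome`): sequential TaqI (`T^CGA`) +
   MspI (`C^CGG`) digestion, modelled as the union of both enzymes' cut
   sites, with size selection to the 40--350 bp analysis window.
2. **Converted reference** (`build_reference`): up to 50 bp from each
   end of each retained fragment, on both strands, fully C-to-T
   converted; each entry carries a per-base genome-offset map.
3. **Three-letter alignment** (`align_reads`): reads are C-to-T
   converted and placed in converted space (ungapped, exhaustive up to
   `max_mismatches`); mismatches are then recounted on the unconverted
   sequences, ignoring read-T over reference-C (a possibly unmethylated
   cytosine) but *not* the reverse; a read is kept only when its best
   placement beats the second best by at least 2 mismatches.
4. **Methylation calling** (`pileup`): at every covered reference
   cytosine, `m = count_C / (count_C + count_T)`; reads reporting any
   other base at the site are excluded from coverage. Context (CpG, CHG,
   CHH with H in {A, C, T}) is classified from the unconverted reference
   genome, never from reads.
5. **Differential testing** (`run_comparison`): per-site two-sided
   Fisher exact test on pooled counts (or Welch t-test across replicate
   levels), restricted to sites with at least 5 reads in *each* group,
   with `m2 - m1` effect sizes, hyper/hypo direction labels, and
   raw-P significance at 0.05 (a Benjamini--Hochberg column is emitted
   but not used for significance, matching raw-P reporting practice).
6. **Annotation** (`assign_feature`, `category_distribution`): promoter
   / exon / intron / intergenic categories with fixed precedence, CpG
   island membership, and category-distribution summaries.

A ground-truth simulator (`simulate_rrbs`) and a Pfaffl qRT-PCR utility
(`pfaffl_ratio`) round out the toolkit.

# The Fisher test and the published tables

The per-site test compares methylated counts `x1/n1` vs `x2/n2` as a
2x2 table. `fisher_site` computes the exact two-sided p using the
**minimum-likelihood tail**: the sum of all hypergeometric table
probabilities not exceeding the observed table's probability (log-space
`dhyper`, with the conventional `1 + 1e-7` relative tie tolerance).
This tail definition is the one consistent with published per-site
tables of this design: e.g. totals (5, 5) with counts 5/5 vs 0/5 give
p = 2/252 = 0.0079 (printed 0.01), and 5/5 vs 1/5 give 12/252 = 0.048
(printed 0.05); a one-sided tail would print 0.02 instead.

`reconstruct_table` inverts a published row (per-group totals plus
absolute methylation difference, rounded to 2 decimals) into the set of
integer 2x2 tables consistent with it. Candidates are canonicalised
under the C/T column-complement map `(x1, x2) -> (n1-x1, n2-x2)`, which
preserves both `|m1 - m2|` and the Fisher p; with equal totals two
genuinely different tables can remain (e.g. totals (5,5), difference
0.80: 5/5 vs 1/5 and 4/5 vs 0/5), but they always share the p-value by
the same symmetry, so the reconstruction is still usable for checking
printed p-values. The acceptance suite verifies this for every
reconstructible published row.

# Alignment: exactness over heuristics

The converted-space search must be exhaustive for the uniqueness margin
to be meaningful, so `candidate_hits` enumerates *every* placement with
at most `max_mismatches` (default 3) converted-space mismatches, using
`Biostrings::vmatchPattern` as the scan engine and re-filtering its
superset under the package's stricter N rule (N always mismatches,
including N-vs-N). There is no seed-and-extend loss: the `seed_length`
knob exists for interface compatibility only. Design choices:

- **No indels.** Fragment-end alignment of 50-bp reads in this design
  is ungapped; Hamming distance is the scoring model.
- **Ranking uses the bisulfite-aware recount**, not converted-space
  counts, because uniqueness is defined on the induced alignment of the
  unconverted sequences.
- **"Two more mismatches"** is implemented as
  `second_best - best >= 2`; ties at the best count are discarded as
  non-unique. This matches best-stratum semantics of Bowtie-era
  aligners.
- **No reverse-complement search at alignment time**: the reference
  already enumerates both strands of both fragment ends, which is also
  why a directional library's reads (all from C-poor post-conversion
  strands) land on the correct strand-specific entry.

When a fragment is no longer than `end_length`, its 5' and 3' end
records coincide and are stored once, so pileups cannot double-count a
read.

# The simulated world

The simulator's defaults encode the study design it stands in for:
2 groups x 2 sexes collapsed to 2 groups, 3 biological replicates per
group, 50-bp single-end reads from MspI--TaqI fragment ends,
`coverage_target = 12` (the reported 11--14x per-site depths),
`dm_fraction = 0.16` (the reported ~16% differential CpG fraction),
`dm_effect = 0.8` (the typical published |difference|), bisulfite
conversion efficiency 0.995 and per-base error 0.001 (routine values
for the chemistry and platform), and a 42% GC background with planted
GC-rich, CpG-forced islands (CpG dinucleotide frequency >= 3x
background) so island detection and annotation have real targets.

Context-mean methylation defaults are CpG 0.75, CHG/CHH 0.02: high
bimodal-leaning CpG methylation and low non-CpG methylation, as
expected for neonatal brain tissue. Per-site truth probabilities are
drawn from broad Beta distributions around these means (concentration
2), giving the dispersed, bimodal-ish landscape real methylomes show.

Three choices deserve justification:

- **Differential planting is restricted to assayable CpG sites** —
  CpG strand-sites within `read_length` of the sequencing end of a
  size-selected fragment. RRBS only observes this territory; the ~16%
  differential fraction in the emulated study is itself a fraction of
  assayed sites. Planting unassayable sites would make the truth table
  unreachable by construction rather than by any property of the
  method. At planted sites the group probabilities are
  `(1 - dm_effect)/2` and `(1 + dm_effect)/2`, so the effect magnitude
  is exactly `dm_effect` and `dm_effect = 1` gives the {0, 1} boundary.
- **Coverage semantics**: reads per (fragment, strand, group,
  replicate) are Poisson with mean `coverage_target /
  replicates_per_group`, making `coverage_target` the expected
  per-group depth of a strand-site near its fragment's sequencing end.
- **Reproducibility**: each generator stage seeds deterministically
  from `cfg$seed` plus a fixed stage offset, so stages are individually
  reproducible and `simulate_rrbs` runs are byte-identical under a
  fixed configuration.

What the simulator does **not** model — and therefore what a green test
does not establish robustness against: PCR duplicates, end-repair
fill-in cytosines at MspI overhangs (a fixed `end_trim` is provided as
the standard mitigation instead), quality-score variation (constant
Phred 40), paired-end protocols, SNPs, and genuine biological replicate
variance (replicates share the group's site probabilities). Recovery
statistics on simulated data are best read as correctness checks of the
estimator chain, not as power estimates for real libraries.

# Numerical and convention notes

- All internal coordinates are 0-based half-open; BED and bedGraph are
  written natively, and report TSVs use the single-base
  `(start, end = start + 1)` convention of the published tables.
- Strands are never merged: the two cytosines of a CpG are separate
  records, as in single-base-resolution reports.
- Sites whose context window crosses a contig edge or touches an N are
  skipped (and counted in a log message).
- `ttest_site` returns p = 1 with a degenerate flag when both groups
  have zero variance and equal means (no-signal convention), p = 0 when
  zero variance but different means.
- Island detection follows the Gardiner-Garden--Frommer criteria
  (length >= 200, GC >= 0.5, observed/expected CpG >= 0.6) with a
  sliding 200-bp window; overlapping qualifying windows are merged and
  each merged region is re-checked against all three criteria before
  being reported, so emitted intervals always satisfy them. A
  user-supplied island BED always takes precedence over the detector.
- The promoter window is `[TSS - 1000, TSS + 500]` in transcription
  orientation — a conventional default, configurable, since promoter
  extents are design choices rather than measurements.
- Published tables of the emulated study use inconsistent signs for the
  methylation difference across hyper- and hypomethylated lists;
  table-matching functionality therefore works with absolute
  differences, while `run_comparison` reports the signed `m2 - m1`.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(genome_length = 20000, seed = 7, dm_effect = 1)
sim <- simulate_rrbs(cfg)
refdb <- build_reference(sim$fragments, sim$simg$genome)
calls <- lapply(sim$reads, function(r)
  pileup(align_reads(r, refdb), r, refdb, sim$simg$genome))
dm <- run_comparison(pool_calls(calls[grep("LMFA", names(calls))]),
                     pool_calls(calls[grep("HMFA", names(calls))]),
                     labels = cfg$group_labels)
attr(dm, "summary")
```

Or in one call: `run_pipeline(run_config(out_dir = "run1", sim = cfg))`,
which writes every intermediate plus an md5 manifest; identical
configurations yield identical manifests.

# Known limitations

- Pure-R pileup and per-read search keep the package dependency-light
  but cap practical throughput at a few hundred thousand reads; the
  intended use is method validation and teaching-scale analyses, not
  production alignment of full flowcells.
- Fisher on pooled counts treats reads, not animals, as the unit of
  replication — the t-test route exists precisely because pooled-count
  tests overstate certainty under biological variance.
- No region-level DMR segmentation, covariate adjustment, smoothing,
  M-bias diagnostics or SNP-aware calling.
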