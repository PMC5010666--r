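---
title: "Benchmarking mappers and callers under controlled sequence divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking mappers and callers under controlled sequence divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divbench)
```

## The problem

Short-read variant discovery starts by mapping reads to a reference genome.
In most of the genome the sample differs from the reference by roughly one
base in a thousand, and mappers tuned to that regime work well. In a few
loci — most prominently the 4-Mb human leukocyte antigen (HLA) region on
chromosome 6 (chr6:29,500,000–33,500,000) — haplotypes diverge from the
reference by several percent, reads accumulate many mismatches, and both
mapping and downstream calling degrade in ways that are invisible without a
ground truth.

`divbench` makes that degradation measurable. It simulates exome-like reads
from target regions mutated to a *controlled divergence level*, records the
truth (every introduced variant, and the reference origin of every read),
and scores any mapper's SAM/BAM or any caller's VCF against that truth. The
package deliberately does **not** run or bundle any mapper or caller: it
produces their inputs and grades their outputs, so any combination of
external tools can be compared on equal terms.

## The divergence model

The divergence level is defined as the number of introduced events (SNPs
plus INDELs) divided by the total bases of the simulated regions. A level
of 0.01 on 50 kb of target territory therefore means exactly
`round(50000 * 0.01) = 500` events, rounding half away from zero. The
default grid `divergence_levels()` spans 0 (a control with no variation at
all) through 0.0005 up to 0.15, covering typical genomic background up to
HLA-like extremes.

Within the event budget:

* a fraction `snp_fraction` (default 0.9) of events are SNPs, the rest
  INDELs, split evenly between insertions and deletions. Human exonic
  variation is strongly SNP-dominated, which motivates the default; the
  split is fully configurable.
* INDEL lengths follow a geometric distribution with success probability
  0.5 truncated to 1..`indel_max_len` (default 10). Short INDELs dominate
  exome data; nothing in the benchmark depends on the exact tail.
* each event is heterozygous with probability `het_fraction` (default 0.5).
  Haplotype 1 carries every variant; haplotype 2 carries only
  homozygous-alternate variants, so het sites are truly heterozygous in the
  read pool. Setting `het_fraction = 0` yields a haploid-style simulation.
* positions are uniform, substitution alternates uniform over the three
  non-reference bases (no Ti/Tv bias), and reference footprints may never
  overlap — collisions are redrawn up to 1,000 times before the request is
  declared infeasible, which keeps the truth VCF unambiguous.

When several regions are simulated together, the global budget
`round(total_bases * level)` is apportioned to regions by largest
remainder, so the requested divergence is met *exactly* over the region
set rather than only in expectation.

```{r}
ref <- synthetic_reference(c(chr6 = 20000L), n_regions = 2,
                           region_length = 3000, seed = 1)
sim <- simulate_mutations(ref$reference, ref$regions, level = 0.01, seed = 1)
sim
```

## Read simulation and truth tracking

`simulate_pairs()` draws `ceiling(coverage * L / (2 * read_len))` fragments
per region (defaults: 100-base paired-end reads, normal fragment lengths
with mean 300 and sd 50 truncated to at least twice the read length, strand
and haplotype uniform). Sequencing errors are independent substitutions at
`error_rate` (default 0.001, a typical Illumina-like per-base rate);
qualities are constant at the Phred score implied by that rate. Every
mate's true origin — the reference coordinate of its first non-inserted
base, obtained through the haplotype-to-reference coordinate map — is
recorded in a sidecar table and encoded in the read name
(`sim|chrom|start1|start2|strand|serial`).

Two properties make the truth usable as an exact oracle: with
`error_rate = 0` and no variants every read is a verbatim reference
substring at its recorded origin, and identical seeds reproduce
byte-identical FASTQ/SAM output.

`subsample_pairs()` keeps each pair independently with probability
`target/full` (mates always together), which is how the 80/60/40/20/10/5x
ladder is derived from a single 100x simulation. `trim_and_filter()`
mirrors real-data preprocessing: pairs with a mate shorter than 100 bases
are dropped, survivors are truncated to their first 100 bases.

## Scoring mapping

Mates are treated as independent single-end reads. For each primary record
(secondary 0x100 and supplementary 0x800 records are excluded, so each
simulated read is counted once):

* **mapping rate** is mapped reads over *all* simulated reads; reads absent
  from the file count as unmapped.
* **mapping accuracy** is the fraction of all simulated reads whose
  *clip-adjusted* start equals the true origin.
* reads mapped to the wrong chromosome form their own class; the rest are
  binned by distance: 0, 1–2, 3–10, 11–20, >20 bp.

The clip adjustment deserves a note on direction. Mappers that soft-clip
report POS as the first *aligned* base, having skipped the clipped prefix.
Adding the clipped bases back to the reported location therefore means
subtracting the leading clip length from POS, which reconstructs where the
full read would start. Trailing clips do not move the start. Hard clips are
treated like soft clips for this purpose — the geometry of the start is the
same; only the record's sequence storage differs.

`perturb_alignments()` generates SAM fixtures with known per-read outcomes
(shifts, leading soft-clips with POS moved accordingly, unmapping, wrong
chromosome), which is how the classifier is verified label-by-label without
any external mapper: pure soft-clipping must leave accuracy at exactly 1.

## Scoring variants

Calls are read from VCF, split per alternate allele (multi-allelic records
share the record QUAL; an allele absent from the sample genotype is not a
call), normalized by trimming shared trailing bases and redundant leading
context, and filtered at QUAL ≥ 20 — the benchmark keeps variants with "a
quality score of at least 20", so 19.9 is out and 20.0 in.

* **SNPs** match on (chromosome, position, alternate allele); each truth
  record can be matched once. Position-only matching is available as an
  option for sensitivity analyses but is not the default, because two
  different substitutions at one site are different discoveries.
* **INDELs** are projected to reference intervals (deletions to their
  deleted span, insertions to the anchor base) and matched by interval
  overlap of at least `min_overlap = 1` base, in the spirit of
  intersect-based INDEL comparison: residual placement differences between
  equivalent representations should not be penalized. Assignment is greedy
  left-to-right over calls, each call taking the unmatched truth interval
  of maximal overlap (ties to the leftmost). This deterministic rule agrees
  with a brute-force all-pairs maximum-overlap matcher on randomized
  instances in the test suite.
* **sensitivity** = TP/(TP+FN), **precision** = TP/(TP+FP).
* **overall genotype concordance** is the fraction of truth-matched sites
  whose unordered diploid genotype (het vs hom-alt) equals the truth. With
  no matched pairs it is reported as `NA`, never 0 — an empty comparison is
  not a failed one. Restricting the denominator to matched sites is the
  conventional reading of "overall genotype concordance" when the original
  formula is not spelled out; the matched-pair table is returned so any
  alternative denominator can be recomputed.
* `classify_known()` partitions calls into known/novel by exact
  (chromosome, position, alt) membership in a catalog VCF, the dbSNP-style
  rule.

## Context annotation

`annotate_variants()` adds the three context flags used to dissect
discordant calls, plus the HLA label:

* **SnpCluster**: a SNP is flagged iff it belongs to a set of ≥ 3 SNPs
  contained in 20 consecutive bases. "Within a window of 20 bp" is read as
  span ≤ 19 (positions fitting inside 20 bases); all members of a
  qualifying window are flagged, and the implementation is checked against
  an O(n²) enumeration of every window.
* **LCR/SD**: membership by ≥ 1 base overlap between the variant's
  reference footprint and the supplied BED track. Tracks are external
  inputs (the package does not compute low-complexity or segmental
  duplication annotations from sequence); SD intervals shorter than the
  defining 1 kb draw a warning but still count.
* **region label**: HLA iff on chr6 within the closed 1-based window
  29,500,000–33,500,000. The source prints the endpoints without a
  convention; the closed reading matches the "4-Mb" description. Internally
  all intervals are 0-based half-open (BED-style) and converted at the
  SAM/VCF boundary, which keeps the arithmetic unambiguous.

## Two-step rescue

Divergent-region pairs that a fast mapper leaves (partially) unmapped can
be re-mapped by a divergence-tolerant mapper. `extract_unmapped_pairs()`
pulls every template with at least one unmapped primary mate back to FASTQ
in original orientation — both mates, because paired re-mapping needs both
— and `merge_alignments()` replaces (never duplicates) the primary records
of rescued templates, so downstream calling sees each template exactly
once.

## What the synthetic world does and does not establish

The generator reproduces the *structural* conditions of the benchmark:
controlled divergence, disjoint truth footprints, paired 100-base reads at
set coverages, uniform errors, and exact truth bookkeeping. It does not
model platform error profiles, GC or capture bias, PCR duplicates,
structural variants, or the linkage structure of real HLA haplotypes
(variants are placed independently and uniformly). A green round-trip test
therefore certifies the *evaluators and bookkeeping* — that scoring is
exact when the answer is known — not that any particular external tool will
reach a given sensitivity on real data. Real mapper/caller outputs are
supplied per grid cell through the `external` argument of
`run_benchmark()` and graded by the same machinery.

## Numerical and degenerate-input choices

* `round(L * level)` rounds half away from zero (deterministic and
  symmetric; base R's banker's rounding would make 0.5-events regions
  ambiguous).
* Regions shorter than twice the read length are skipped with a warning;
  regions shorter than the mean fragment fall back to region-length
  fragments.
* Undefined ratios (no truth, no calls, no matched pairs) are `NA`, not 0.
* All grid randomness derives from one root seed through fixed per-cell
  offsets, so any cell can be reproduced in isolation.
* Reads mapped to a chromosome with no recorded origin are an error (a
  corrupted truth table), not a mapping class.

## Worked example

```{r}
reads <- simulate_pairs(sim, sim_config(coverage = 10, seed = 2))
sam <- tempfile(fileext = ".sam")
emit_truth_alignments(reads, sam)
summarize_mapping(sam, reads)

psam <- tempfile(fileext = ".sam")
perturb_alignments(sam, psam, unmap = 0.1, shift = 0.1, softclip = 0.2,
                   shift_k = c(1, 3, 11, 21), seed = 3)
summarize_mapping(psam, reads)
```

## Limitations

Haplotype-aware comparison (vcfeval-style local replay), phasing
assessment, MNP/complex-allele decomposition, VQSR-like filtering, and
multi-sample evaluation are out of scope. INDEL matching is intentionally
permissive (interval overlap) and SNP matching intentionally strict
(allele-exact); both choices are surfaced as parameters where a defensible
alternative exists.
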