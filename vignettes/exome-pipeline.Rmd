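---
title: "Exome pipeline stages: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exome pipeline stages: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`exopipe` implements the bespoke computational stages of an exome
sequencing workflow — the parts between the standard external engines
(the aligner, the realigner, the variant caller, the annotation
databases): read quality control and preprocessing, alignment
filtering with PCR-duplicate marking, exome capture metrics, variant
post-processing, and a multi-section summary report. This vignette
explains the models and conventions behind each stage, the parameters
that matter, and the design decisions taken where the design was
genuinely open.

## Quality encodings and dialect detection

FASTQ files encode per-base qualities as ASCII characters in one of
three historical dialects. Sanger (Phred+33) and Illumina 1.3+
(Phred+64) both store Phred-scaled values, $q = -10\log_{10} p$, so
converting between them is pure offset arithmetic. Solexa qualities
are odds-scaled, $q_{sx} = -10\log_{10}\frac{p}{1-p}$, and conversion
to Phred must pass through probability space:

$$ q_{phred} = 10\,\log_{10}\!\left(10^{q_{sx}/10} + 1\right), $$

rounded half-up to match the published conversion tables. The two
scales converge above $q \approx 10$, where
$|q_{phred} - q_{sx}| \le 1$; the tests verify the full mapping over
the legal Solexa range $[-5, 62]$ against an independent
probability-space computation.

Dialect *detection* is necessarily heuristic because the three code
ranges overlap above ASCII 64. The detector uses the minimum observed
code point (below 59: Sanger; 59–63: Solexa; otherwise ambiguous and
resolved to a caller-supplied default), and every entry point also
accepts an explicit encoding that bypasses detection. ABI SOLiD
colour-space data (csfasta + qual FASTA pairs) is carried through as
colours with per-colour qualities; conversion to aligner-ready
double-encoding is out of scope because alignment itself is external.

## Read preprocessing

The preprocessing chain runs trimmers first, then filters, so that
length is always checked post-trim:

1. **N trimming** removes maximal leading/trailing runs of `N`
   (interior `N`s are data, not adapter artifacts).
2. **RSQCI trimming** removes the trailing run of quality-2 calls —
   the Illumina 1.3+/1.5+ *Read Segment Quality Control Indicator*
   (`B` in Phred+64), which marks a segment the instrument itself
   distrusts.
3. Optional quality-threshold and fixed-length 3' truncation.
4. **Length filter**: reads shorter than 25 bp fail (exactly 25
   passes — the rule is "shorter than").
5. **Unidentified-call filter**: more than 5% `N` fails (exactly 5%
   passes; the inequality is strict).
6. **Quality filter**: more than 5% of calls below Phred 20 fail.

The 25 bp, 5% and 5% thresholds are the pipeline's canonical
defaults; the Phred 20 "unreliable call" cutoff is our choice (the
conventional high-confidence boundary) and is exposed as a flag, since
only the 5% fraction is fixed by convention. Filters always see
post-trim reads.

For paired-end data the two streams must agree in length and
identifier order (mate decorations `/1`, `_R1`, … are ignored). When
either mate fails a filter the whole pair is dropped and both mates
are counted removed. Emitting orphaned singletons would keep slightly
more data but breaks the aligner-ready pairing of the output files;
dropping the pair is the simplest contract that keeps every
downstream stage well-defined.

Every stage emits an accounting row (`input`, `passed`, `removed`,
`passed_percent`) with the invariant `input = passed + removed`; the
end-to-end survivor count equals input minus the summed removals. An
empty stage reports 100% with zero counts rather than `NaN`.

## Alignment filtering

The filter chain runs in a fixed order: unmapped (plus secondary and
supplementary records, which would double-count coverage), then the
proper-pair filter (a logged no-op for single-end data), then
duplicate marking, then the on-target filter.

**Duplicate marking** is coordinate based. Two records are duplicates
iff their *duplicate keys* match: reference name, strand, and
unclipped 5' start — the mapped start with leading (forward strand)
or trailing (reverse strand) clips undone, which restores the
physical fragment end that PCR duplicated. For pairs the key is the
canonically ordered pair of both mates' triples and the pair is
flagged as a unit, because the duplicated entity is the fragment.
Within a key group the record (or pair) with the highest summed base
quality is kept, ties broken by lexicographically smallest read name;
this is the de-facto convention of standard duplicate-marking tools
and makes the outcome deterministic and order-independent. The tests
check equivalence against an $O(N^2)$ pairwise comparator on random
SAMs with soft-clipped and paired cases.

**On-target filtering** keeps a record iff its reference footprint —
the contiguous reference span consumed by M/D/=/X CIGAR operations,
so a read spanning a deletion still covers the deleted interval —
overlaps any capture target by at least `min_overlap` bases (default
1, the weakest reading of "overlaps"; configurable for padding-style
workflows). Whether the original tooling used the read start or the
full footprint is not documented; the footprint is the more faithful
geometric reading, and we note it as a divergence risk.

All BED input is 0-based half-open on disk and converted to the
Bioconductor 1-based closed convention at the boundary (rtracklayer);
SAM and VCF positions are 1-based throughout. No coordinate
arithmetic crosses a format boundary without an explicit conversion.

## Capture metrics

*Fold coverage* of an interval is aligned bases attributed to the
interval divided by interval length, where attribution intersects
each record's footprint with the interval. The aggregate exome fold
coverage is total on-target aligned bases over total target length —
not the mean of per-interval folds, which would up-weight short
exons. Interval fractions below 1× ("not covered") and at or above
20× ("highly covered") mirror the conventional reporting bins; both
edges are configurable.

*Capture specificity* is the fraction of mapped, deduplicated reads
overlapping the targets. Reads are the default unit (the figure is
conventionally quoted without a unit; a base-level variant is
available behind a flag).

*Expected PCR duplicates by chance* models fragment starts as uniform
draws over $P$ distinguishable start sites (both strands of the
target space, $P = 2 \times$ target length by default). The expected
number of occupied sites after $n$ draws is $P(1 - (1 - 1/P)^n)$, so
the expected flagged count is

$$ E[\mathrm{dup}] = n - P\left(1 - (1 - 1/P)^n\right). $$

This collision model is our own formulation (the original tooling
does not state one) and is validated against a Monte-Carlo oracle
only — never against published figures. It is monotone increasing in
$n$, decreasing in $P$, and vanishes as $P \to \infty$. The
implementation uses `expm1`/`log1p` so the value stays accurate when
$1/P$ underflows toward zero.

*Insert-size metrics* count one observation per fragment (only the
mate with positive TLEN). Fragments beyond 10× the median are
excluded from the mean and standard deviation — without this, rare
chimeric pairs dominate both moments — but stay in the histogram;
the factor is flag-controlled.

## Variant post-processing

Variants are classified by allele length alone (equal: SNP; longer
alt: insertion; shorter: deletion), and multi-allelic records are
split into per-alt rows on input so every count is well-defined.

Zygosity is decided differently for the two classes, mirroring how
callers report them. SNPs use the genotype field: two identical
non-reference alleles are homozygous, anything mixed is heterozygous
(two different alt alleles count as heterozygous, with a logged
notice). DIPs — deletion/insertion polymorphisms, i.e. small indels
— use the alt-allele fraction against the `dsP` percentage
threshold: homozygous iff $100 \cdot \mathrm{alt\_depth} /
\mathrm{depth} \ge \mathrm{dsP}$. The boundary is inclusive so that
`dsP = 100` still classifies pure-alt sites as homozygous and
`dsP = 0` degenerates to everything-homozygous; zero-depth records go
to an explicit "unclassifiable" bucket rather than erroring the run.
Whether the denominator should be total depth or ref+alt depth is
ambiguous in the wild; total depth is the default with a
`ref_alt` switch. Increasing `dsP` can only shrink the homozygous
set — a monotonicity the tests sweep in steps of 5.

The Ti/Tv ratio counts transitions (A↔G, C↔T) over the eight
transversions, ignoring non-SNP rows, and reports `NA` (not infinity)
when no transversion exists. dbSNP membership is a non-`.` VCF ID;
RefSeq association is a non-empty annotation under a configurable
key. "Coding" status of a DIP is read from an annotation column
(e.g. exonic function) rather than recomputed — annotation engines
are external and only their tabular output is consumed.

Annotation merging is a full outer join of two tab-delimited tables
on `(chrom, pos, ref, alt)`; colliding non-key columns are prefixed
with their source name, duplicate keys within one table are an error
(they would silently fan out the join), and output is sorted by
position.

## The summary report

`build_report()` assembles four sections: alignment key figures
(exome size, genome and exome fold coverage, capture specificity,
expected duplicates by chance), the complete filter table in stage
order, the DIP summary and the SNP summary. Sections not run are
rendered as explicit `not_run` rows. Output is sectioned TSV — one
`#section`-headed block per section — with percentages at one decimal
place for reading and a full-precision machine column so that parsing
the file reconstructs every numeric field exactly. Spreadsheet
rendering is deliberately out of scope: content over container.

`run_all()` is resumable per stage: a stage whose outputs exist and
are at least as new as its inputs is skipped, so re-running a
completed directory performs no recomputation and leaves the outputs
byte-identical. Nothing in any output file depends on the clock.

## The synthetic-data generator

`fixture_plan()` plus a seed fully determines every generated file
byte-for-byte (the RNG kind is pinned). The generator *plants
structure, not realism*: quantities a test asserts exactly are
constructed exactly (filter-failure counts, duplicate copies sharing
a duplicate key, Ti/Tv by count, zygosity fractions with allele
fractions placed well off the dsP boundary), while quantities checked
against a confidence interval are sampled (each unique fragment is
on-target with probability `on_target_fraction`).

The defaults describe a desk-scale single-end Illumina-like exome
run: 75 bp reads, a 100 kb single-chromosome genome with 50 targets
of 200 bp (a 10% "exome"), 63% of reads mappable, a 12% duplicate
rate, 21% improper pairs for PE plans, ~2% of raw reads failing
preprocessing, 3 000 SNPs at Ti/Tv 2.0 with 83% dbSNP membership,
and 400 DIPs at 99% RefSeq association with a 0.3 homozygous
fraction at `dsP = 80`. These mirror the filtering cascade of a
typical early-Illumina exome study at roughly 1/30 000 of the human
genome; the test suite and the acceptance script run the full
pipeline on them in seconds.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: position-dependent error and
quality profiles, quality-score covariation, indel sequencing
artifacts, GC and capture-efficiency bias across targets, optical
duplicates, chimeric and split reads, multi-chromosome references.
The generator demonstrates that the *bookkeeping and the arithmetic*
are correct, not that thresholds are well-chosen for any particular
instrument.

## Numerical and degenerate-input choices

* Solexa conversion rounds half-up (`floor(x + 0.5)`), matching the
  published tables; results clamp to the target dialect's range.
* Ratios over empty denominators are `NA` (capture specificity with
  no mapped reads, Ti/Tv without transversions, insert metrics for
  single-end data), except stage percentages, where an empty stage is
  100% by convention.
* All-`N` reads trim to empty reads and are removed by the length
  filter rather than erroring.
* Duplicate-key ties break by read name, so shuffling the input never
  changes which record survives.
* Targets are normalized (sorted, overlapping intervals merged)
  before any interval arithmetic.

## Problem sizes used in validation

The validation suite exercises: 100 seeded random alignment sets of
up to 2 000 reads on genomes up to 100 kb for coverage-oracle
equivalence; 100 seeded SAMs of up to 200 records (soft-clipped and
paired) for duplicate-marking oracle equivalence; the full Solexa
range for quality conversion; a 10 000-replicate Monte-Carlo run for
the collision model; and 10 000-read fixtures for parameter
recovery. These sizes keep the whole suite in the minutes range on a
single core while leaving every code path exercised.

## Known limitations

* SAM input is parsed from text; BAM/CRAM and index handling are
  delegated to external tools (`samtools view` produces the text this
  package consumes).
* The duplicate key uses both soft and hard clips when restoring the
  unclipped start; mate coordinates are taken from the mate's own
  record (both mates must be present in the input), not from `MC`
  tags.
* Optical duplicates are not distinguished from PCR duplicates.
* Variant calling, realignment, recalibration and annotation lookups
  are explicitly out of scope; the package consumes their outputs.
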