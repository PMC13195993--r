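---
title: "Characterising CNBP (CCTG)n repeat expansions from long reads"
author: "cnbpmosaic authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterising CNBP (CCTG)n repeat expansions from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnbpmosaic)
```

## The problem

Myotonic dystrophy type 2 (DM2) is caused by a (CCTG)n tetranucleotide
expansion in intron 1 of *CNBP*. Healthy alleles carry a complex
(TG)v(TCTG)w(CCTG)x(NCTG)y(CCTG)z motif with fewer than 25 CCTG units;
pathogenic expansions run from roughly 75 to beyond 11,000 units and are
strongly mosaic within an individual, so a patient is better described by a
*distribution* of per-molecule expansion lengths than by a single genotype.
Many expanded alleles additionally carry a variant (TCTG)m block at the 3'
end of the CCTG array; because repeat-primed diagnostic PCR uses primers
complementary to pure (CCTG)n, such alleles can escape standard 3' assays.

Targeted long-read (nanopore-style) sequencing can span the entire locus in
single molecules. `cnbpmosaic` implements the downstream analysis of such
data as a tested, reusable pipeline:

1. **read harvest** — find reads that span the whole repeat ("complete
   reads") by anchoring both flanks, and orient them on the locus plus
   strand;
2. **motif annotation** — segment each read's inter-flank region into
   classified quadruplet runs (CCTG, TCTG, optionally GCTG/ACTG) and
   unclassified gaps, under error-tolerant thresholds;
3. **mosaicism statistics** — per-sample expansion-length distributions,
   the fraction of expanded-allele reads carrying the 3' TCTG block, binned
   abundance with a kernel density, Tukey box statistics of motif lengths,
   and parent/child deltas;
4. **cohort arithmetic** — motif frequency tables, diagnostic sensitivity,
   transmission summaries, and onset-age comparison helpers;
5. **synthetic locus** — a simulator producing reads with known repeat
   architecture, mosaicism and errors, so every stage is testable with no
   external data.

## Flank anchoring and complete reads

A read is "complete" when both user-supplied flank sequences place inside
it by semi-global alignment (the whole flank against any substring of the
read) with edit distance at most `max_edit_fraction` (default 0.2) times
the flank length, in one consistent orientation. This operationalises
"spanning the repeat region" without an external aligner; a SAM/BAM import
path is available for reads already mapped near a stated locus interval
(soft-clipped bases are kept, since clipping inside giant repeats is
expected).

Placement ties are broken leftmost for the 5' flank and rightmost for the
3' flank, which conservatively maximises the enclosed span. The expansion
span is the gap between the anchors, and `unit_count()` converts it to
quadruplet units as `floor(span / 4)` — an 8,750 bp span is 2,187 units, a
40,290 bp span 10,072. For speed the search looks in the outer 25% windows
of the read first (where the flanks of a spanning read must sit) and falls
back to a full scan in both orientations before rejecting a read; every
rejection carries a reason code and the kept + rejected sets always
partition the input.

## The segmentation model

Classification works on whole-quadruplet evidence only. For each motif the
*phase profile* marks every base lying inside at least one exact occurrence
of the 4-mer, at any phase. CCTG and TCTG differ in one base but their
exact occurrences can never overlap (no offset of one motif against the
other is compatible), so per-base "voting" cross-talk between the two
motifs is structurally impossible. A single substitution inside a pure run
uncovers exactly its own quadruplet, which is how sequencing errors
perforate the profile.

A candidate segment `[a, b)` for motif `M` is *legal* when

* `a` and `b - 1` are covered by `M`'s profile (runs cannot annex uncovered
  residue at their ends),
* no internal uncovered gap exceeds `max_bridge` bp (default 8, two
  quadruplets: isolated errors are absorbed, distinct blocks are not
  merged),
* the covered fraction is at least `minratio` (default 0.75), and
* the length is at least `minlength` bp (default 16 — four contiguous
  units, the threshold below which a motif is not called).

Among all tilings of the inter-flank region by non-overlapping legal
segments, the annotator returns the optimum of an explicit lexicographic
objective: maximal classified bases, then maximal matched (covered) bases,
then fewest segments; residual ties prefer a segment over a gap at the
current position, then the longer segment, then the higher-priority motif
(CCTG before TCTG). Everything between chosen segments is emitted as
UNCLASSIFIED, so classified and unclassified segments exactly tile the
region. The `minratio` semantics (covered fraction of the run) and the
tie-break order are this package's own operational definitions; the
upstream parameter names (`--minlength`, `--minratio`, with `minratio 75`
meaning 75%) are kept for familiarity.

Because the two default profiles are disjoint, every optimal segment can be
assumed to start and end on boundaries of maximal covered blocks, which is
what the C++ dynamic program enumerates (block-chain spans with bounded
gaps). The test suite checks this implementation against an independent
reference segmenter that enumerates *raw* legal intervals and solves the
same objective by memoised search, on tens of thousands of fuzzed reads up
to 64 bp. With variant motifs enabled (GCTG can share its leading G with a
preceding CCTG occurrence) profiles may overlap by one base and the
block-boundary restriction is a documented approximation.

One property worth spelling out: raising `minlength` or `minratio` shrinks
the set of legal segments, so the total classified footprint is monotone
non-increasing — but the *number* of segments is not. A bridged run whose
ratio fails a stricter threshold decomposes into its legal sub-runs: with
`(CCTG)4 + 8 bp gap + (CCTG)4`, default settings yield one 40 bp segment
(ratio 0.8) while `minratio = 0.9` yields two 16 bp segments. Tests
therefore assert monotonicity of classified bases, the statement that is
actually true of threshold tightening.

A read's allele class follows its total classified CCTG units: below 25
"normal", 75 and above "expanded". The published class boundaries leave
25–26 units unassigned between the normal (<25) and grey (27–74) ranges;
the package assigns them to "grey" and flags them (`grey_boundary()`), so
no unit count silently changes class. The 3'-TCTG flag is true when a
classified TCTG segment starts past the end of the 3'-most classified CCTG
segment — a wild-type-style 5' TCTG block does not count, and with no CCTG
segment at all the flag is false (there is no array for the block to sit
3' of).

## Per-sample statistics

`summarize_sample()` computes statistics over expanded-class complete reads
by default — the denominator used for per-patient TCTG fractions — with an
option to widen to all complete reads. With zero qualifying reads the
fraction is an explicit `NA`, never 0, and the TSV writer keeps nulls
explicit. Span medians use the lower-middle convention for even counts so
the reported value is always an observed molecule; motif-length box
statistics use linear-interpolation quartiles (type 7) with Tukey fences at
1.5 IQR, whiskers at the most extreme points inside the fences, and
unclassified runs excluded. Binned abundance uses right-open 500 bp bins
from zero, and the kernel density is Gaussian with the normal-reference
(Scott) bandwidth, falling back to a pure sd-based bandwidth when the IQR
degenerates; the density accompanies the counts, never replaces them.
`detection_floor()` is the reciprocal of the complete-read count in
percent: 50 spanning reads resolve a 1-in-50 (2%) subpopulation, which is
the scale at which a single TCTG-bearing molecule among 50 is reported as a
2.0% fraction.

Intergenerational comparisons (`compare_generations()`) report child-minus-
parent deltas of per-motif minimum, median and maximum unit counts — the
summary statistics available when per-molecule progenitor lengths cannot be
estimated — plus retention/loss flags for the 3' TCTG block (lost means
present in the parent's expanded reads and absent from the child's).
Estimating the progenitor allele length itself is out of scope.

## The simulator: what it emulates and what it does not

`dm2_allele()` builds alleles of the conventional architecture
(TG)v(TCTG)w(CCTG)n[(TCTG)m]; `simulate_read_set()` draws reads from a
mixture of alleles, redraws the CCTG block's unit count per read from a
mosaicism model, assigns strands, optionally truncates reads so they lose a
flank, and applies uniform per-base errors.

Choices that matter, and why:

* **Mosaicism family.** Patients are described only by per-sample min /
  median / max expansion; the intra-patient length distribution's shape is
  not published. The default is a truncated lognormal parameterised by its
  median (dispersion = sdlog), whose heavy right tail reproduces the wide
  max/median gaps seen in patient tables; `fixed` and negative-binomial
  alternatives are provided. These defaults are stand-ins, not inferred
  parameters.
* **Error model.** Uniform substitution/insertion/deletion rates, defaults
  2% / 1.5% / 2.5% — nanopore-like figures chosen once; no published rates
  exist for this assay. Substitutions are uniform over the three alternative
  bases; this is the simplest model that still perforates runs into
  unclassified ("grey") stretches. Validation studies in the tests use
  2% / 1% / 2% so the aggregate rate is exactly 5%. Not modelled: per-base
  quality realism, position-specific or homopolymer-specific biases,
  basecaller artefacts, enrichment efficiency. Passing tests therefore show
  robustness to uniform noise of realistic magnitude, not to every failure
  mode of real reads.
* **Flanks.** 300 bp seeded-random sequences shipped as a synthetic FASTA
  fixture (`extdata/flanks_synthetic.fa`); real hg38 flanks can be supplied
  as FASTA instead.
* **Ground truth.** Truth segments are reported on the error-free read
  (coordinates flipped and motifs reverse-complemented for minus-strand
  reads) together with a pre- to post-error coordinate map, and locus-frame
  per-read unit totals are recorded separately, so recovery can be scored
  through indel shifts without coordinate gymnastics.
* **Exact mixtures.** Besides multinomial `weights`, exact per-allele
  `counts` give deterministic stratified assignment. The 1-in-50 fixture
  (one TCTG-bearing read among 50) uses `counts = c(tctg = 1, pure = 49)`
  rather than hunting for a seed whose multinomial draw happens to produce
  one carrier.

## Numerical and scale choices

Simulation-backed tests use 200 reads of median 2,000 units (truncated to
75–10,000) for recovery studies, 500 reads for fraction-recovery checks,
and ≥10,000 fuzzed reads of up to 64 bp for the reference-segmenter
equivalence; these sizes give stable statistics while keeping the whole
suite around a minute of compute. Under those conditions zero-error
segmentation reproduces simulator truth exactly, and at 5% aggregate error
per-motif unit totals stay within ±5% of truth for well over 90% of reads.
The residual bias under noise is a ~1% shrinkage from the insertion/
deletion imbalance plus occasional loss of quadruplets at run splits where
three or more adjacent units are corrupted (a >8 bp gap exceeds the default
bridge).

All coordinates everywhere — segments, truth, BED output — are 0-based
half-open, stated in output headers. Percentages print half-up at one
decimal place. Runs are pure functions of (inputs, config, seed): the
pipeline writes a resolved-config copy beside its outputs and reruns are
byte-identical.

## A worked example

```{r example, eval = FALSE}
library(cnbpmosaic)

alleles <- list(
  tctg = dm2_allele(cctg = 2000, tctg3 = 500, label = "tctg"),
  pure = dm2_allele(cctg = 2000, label = "pure"))

sim <- simulate_read_set(alleles, n_reads = 200,
                         counts = c(tctg = 120, pure = 80),
                         mosaic = mosaic_model("lognormal", 2000, 0.5,
                                               min_units = 75, max_units = 10000),
                         errors = error_model(0.02, 0.01, 0.02), seed = 11)

fl <- default_flanks()
complete <- extract_complete_reads(sim, flank_anchors(fl$flank5, fl$flank3))
ann <- annotate_reads(complete, annotator_params(minlength = 16, minratio = 75))
summarize_sample(ann)
```

## Known limitations

* The annotator detects quadruplet motifs only; other repeat periods and
  SNV-based phasing of the two germline alleles are out of scope.
* The "complete read" rule (dual flank anchoring within an edit budget) is
  this package's operationalisation; tools built on mapping quality or
  clip-length criteria may keep slightly different read sets.
* Reported per-sample medians summarise the sequenced molecules; without a
  progenitor-allele-length estimate they remain age-at-sampling dependent.
* Cohort helpers reproduce printed-count arithmetic; they do not attempt to
  reconcile internally inconsistent published tables, and onset p-values
  from unpublished raw ages are deliberately not targets — the t-test
  helper is validated against the reference statistical implementation
  instead.
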