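---
title: "Methods: G-rich motif scanning and mutation-accumulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: G-rich motif scanning and mutation-accumulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadtractMA)
```

# The analysis in one paragraph

A mutation-accumulation (MA) line propagated through repeated small
bottlenecks fixes new mutations nearly neutrally, so the per-generation
mutation rate can be read off directly as events divided by
(targets × generations). In a background lacking the FANCJ-family helicase
that resolves G-quadruplex (G4) structures, the interesting signal sits in
guanine-rich DNA: large deletions initiate where a replication fork meets a
G4-forming tract, removing the tract together with 5′-flanking sequence.
`quadtractMA` takes a genome and per-generation variant-caller tables,
reduces them to fixed homozygous variants, classifies each large deletion
by the G-rich motif at its initiating breakpoint, and converts counts to
rates. A planted-truth simulator exercises every stage.

# Motif model

## Signature families

A G-run signature is parameterised by `signature_spec()`: `n_tracts` runs
of at least `min_tract_len` guanines separated by loops of
`min_loop..max_loop` nucleotides. Three families are preconfigured:

| family     | tracts | min G per tract | loops |
|------------|--------|-----------------|-------|
| `strict`   | 4      | 3               | 1–7   |
| `relaxed4` | 4      | 2               | 1–7   |
| `relaxed3` | 3      | 2               | 1–7   |

Two modelling decisions deserve emphasis because they change counts:

* **Loop nucleotides may be G.** The loop alphabet is "any nucleotide",
  so a pure G15 homopolymer satisfies the strict signature
  (G3·G·G3·G·G3·G·G3). This is what makes every monoG/C tract of 15+ a
  strict site, and it is why the scanner works on maximal-end dynamic
  programming rather than a regular expression: for each candidate tract
  start the scanner computes the furthest reachable match end, then merges
  overlapping or bookended match intervals into one maximal site. One
  biological locus therefore yields exactly one site, which is the only
  convention under which a "site count" is stable.
* **Ambiguity bases stop everything.** `N` terminates tracts and is never
  accepted inside a loop. This is conservative: a locus interrupted by
  assembly ambiguity is not reported as a clean match.

The scanner runs on both strands; the C-version of the pattern on the
forward strand is recorded as a G-run site on the reverse strand. For
genome-wide counts `merge_sites_across_strands()` collapses overlapping
plus/minus sites into double-stranded loci, while per-strand records are
retained for breakpoint orientation. Because published site counts rarely
state these conventions, `calibration_sensitivity()` tabulates the count
under each (merged/collapsed, per-strand, single-strand), so an external
count can be bracketed and the matching convention identified. The package
ships no reference genome; rerunning the genome-wide census requires
supplying the assembly FASTA, and any residual discrepancy with a
published figure should be read against this table rather than resolved by
tuning.

The scanner is verified against an independent brute-force enumerator
(written directly from the pattern definition, recursing over all tract
and loop lengths) on a thousand random sequences in the test suite.

## Tract classes

Strict sites are subclassified by the structure of their G runs, read on
the strand that carries the G:

* `MONO_TRACT` — contains a pure G run of at least `mono_min_len`
  (default 15, a literal reading of "larger than 14 bp");
* `MONO_LIKE_LE2` — at most two interruption runs;
* `INTERRUPTED_GE3` — three or more.

Interruptions are counted as *runs*, not nucleotides, and the runs are
defined against G tracts of length ≥ 2 (exactly the subscripted segments
of the compact signature string, e.g. `G_14TG_6AGAAG_3`): a lone G inside
an interrupting segment belongs to the interruption. This was a genuinely
open choice; counting nucleotides would reclassify the canonical
mono-like example (five interrupting nucleotides, two runs), and counting
maximal non-G runs would split `AGAA` at its interior G. The chosen rule
is the one consistent with both worked examples and with the signature
string notation.

# Variant filtering

Small-variant thresholds follow the pileup-caller conventions for fixed
homozygous calls, read literally: depth **strictly** greater than 5 and at
most 200, variant frequency ≥ 0.9, base quality ≥ 30. Deduplication keeps
one variant per coordinate (highest VF, then lexicographically smallest
alternate allele — the rule itself is unstated in such pipelines, so the
tie-break is fixed and documented here). Large deletions require the
breakpoint homozygosity statistic `a/(a+b) > 0.5` (strict) and
size > 20 bp (strict); calls with `a + b = 0` are dropped with a message
rather than treated as division errors.

Variant identity is the exact key (contig, position, ref, alt, kind) for
substitutions and small InDels. Large deletions and duplications match
across sequencing batches by reciprocal overlap ≥ 0.9, absorbing
breakpoint re-estimation jitter; the first occurrence of an event names
it. The accumulation matrix counts variants first seen at each sampled
generation, with reversions (present, then absent) tracked separately —
structurally expected only for duplications, which may revert to single
copy, while fixed substitutions, InDels and deletions persist.

Orthogonal copy-number evidence (e.g. array-CGH intervals) is unioned with
breakpoint-resolved calls at reciprocal overlap ≥ 0.5, keeping the
coordinate-refined breakpoints for events seen by both.

# Deletion classification

A deletion initiates at a motif when its strand-appropriate breakpoint —
the right end for a plus-strand G run, the left end for a C run — lies
inside the motif or within `tolerance` bases of the motif's initiation end
(the 3′ end of the G run), and the deletion extends into the tract's 5′
flank. The tolerance defaults to 5 bp: observed initiating tracts are
"almost completely" removed, which motivates a small allowance but no
number; sensitivity to this choice can be probed by rerunning
classification at other tolerances, and the planted-truth tests pass for
any tolerance at or above the simulator's breakpoint jitter (≤ 2 bp).
Directionality is enforced by default; `require_orientation = FALSE`
switches to pure breakpoint-in-motif overlap for comparison.

Classes are assigned with strict family priority — strict subclass, then
relaxed four-tract, then relaxed three-tract, then non-G-rich — mirroring
a sequential analysis in which only deletions unexplained by the strict
signature are examined for relaxed matches. Within a family the nearest
initiation end wins; exact ties resolve toward the higher-priority class.
Every deletion receives exactly one class, so class counts always sum to
the deletion count.

A monoG/C tract counts as *deleted* when a single deletion covers at
least half of it. A 1-bp touch rule would overcount (the biology removes
tracts nearly completely); requiring total removal would undercount
against breakpoint jitter. The threshold is inclusive at exactly 50%.

# Rate estimation

All estimators are `n / (denominator × generations)` with the denominator
taken from a `rate_denominators()` bundle. Two conventions are supported:
the round literature figures for the C. elegans genome (10⁸ bases, 20,400
protein-coding genes) for reproducing published arithmetic, or measured
values (FASTA length, scanned site count) for self-contained analyses.
Display rounds to two significant figures with round-half-even
(`signif()`), which reproduces published rate strings exactly when fed the
published numerators; comparisons in the tests are made on the displayed
string, not on long doubles.

Transitions are A↔G and C↔T; with zero transversions the ratio is
reported as undefined (`NA`) rather than infinite, since small synthetic
sets legitimately hit that corner. The mutation spectrum collapses each
substitution with its reverse complement into six classes and, when a
genome is supplied, normalises per class by A:T versus G:C base content.

# The simulator

`build_toy_genome()` draws a uniform background and then rejection-checks
it: the most permissive configured family (three tracts of G2+) is scanned
on both strands — any match of any stricter family, or any monoG/C tract
of 15+, necessarily contains such a match — and matched windows are
redrawn from an alphabet that never extends a G or C into a run of two,
until the scan is clean. Motifs and single-exon genes are then planted at
least 200 bp apart inside 12 bp A/T buffers; since the longest loop is
7 bp, no planted locus can chain into background sequence, so each plant
scans back as exactly one site with its intended class (class generators
are constructed to match their family and nothing stricter).

`simulate_line()` is a single-lineage MA model with immediate fixation:
per generation, Poisson numbers of substitutions and small InDels land
uniformly on undeleted bases; G4 deletions pick a uniformly chosen *live*
motif site, remove the tract (up to a ≤ 2 bp jitter at its 3′ end) plus
5′-flanking sequence with size from a truncated log-normal; non-G4
deletions land away from every motif; duplications amplify planted genes
and may revert. Deleted regions cannot be hit again (target loss), and no
event class except duplication ever reverts, so sampled variant sets are
nested across generations. Emitted tables carry depth/VF/BQ (and a/b)
fields drawn so true calls pass the homozygosity filters, mixed with a
configurable fraction of decoy calls that each fail exactly one filter.

Default rates are the per-generation estimates of the 300-generation
study window (substitutions 3.1 × 10⁻⁹ and InDels 5.7 × 10⁻¹⁰ per base,
G4-site deletions 1.7 × 10⁻⁴ per site, non-G4 deletions 5.0 × 10⁻¹⁰ per
base, duplications 6.5 × 10⁻⁷ per gene); the duplication-loss probability
of 10⁻³ per duplication-generation reflects one observed reversion among
a few duplications over hundreds of generations. The deletion-size model
is log-normal with meanlog 4.75 and sdlog 0.8, truncated to the observed
49–10,228 bp range, chosen once so that about 86% of draws fall below
300 bp (the observed small-deletion fraction); non-G4 deletions truncate
to 21–299 bp, matching the observation that all non-G-rich deletions were
small. Tests and examples that need dense event counts pass explicitly
inflated rates; the defaults are the study conditions, not tuning knobs.

What the simulator does *not* model: read-level noise (no FASTQ/BAM),
heterozygosity and within-generation drift (fixation is immediate, a
deliberate simplification of few-individual transfer), selection, and
sequence-context mutation bias. Passing round-trip tests therefore show
the pipeline's bookkeeping and geometry are correct on data satisfying
the model's assumptions — they do not validate caller behaviour on real
reads.

## Parameter recovery

`recover_parameters()` runs the full pipeline on replicate simulated lines
and compares recovered with configured rates. The substitution rate is
events per base-generation. The per-site deletion rate accounts for target
loss: with each live site an exponential target removed once hit, the hit
fraction k/n estimates 1 − e^(−μG), giving the maximum-likelihood estimate
μ̂ = −log(1 − k/n)/G, to which a standard second-order correction for the
convexity of the log is applied (the raw MLE is biased upward by roughly
p/(2n(1−p)G)). Sites destroyed by a deletion sweeping in from a
neighbouring site are censored targets; this makes the estimator very
slightly conservative and is left uncorrected. The test suite checks
recovery within two Monte-Carlo standard errors over 100 replicate lines
on a 1 Mb toy genome with 50 planted sites — sizes at which one run of
the suite completes in a few minutes while the standard errors are tight
enough (≈ 0.6% for the substitution rate) to catch real biases.

# Pipeline and reproducibility

`run_pipeline()` executes scan → filter → subtract → accumulate →
classify → census → rates in order, always writing stage intermediates
(BED/TSV) plus a JSON report, so every reported number can be recomputed
from staged files; identical inputs and configuration produce
byte-identical reports. `validate_config()` schema-checks a JSON
configuration, rejecting unknown keys wholesale and filling every
threshold default discussed above. A `counts` mode evaluates the rate
block directly on supplied numerators, reproducing printed-rate arithmetic
without sequence data. Coordinates are 1-based inclusive internally (the
`GRanges` convention of the underlying Bioconductor stack); BED output is
0-based half-open and TSV reports print 1-based `start..end` loci.

# Known limitations

* Genome-wide site counts depend on the reference assembly and the
  counting convention; the sensitivity table documents the convention
  space but cannot adjudicate an external count without the same FASTA.
* The gene-impact module is deliberately lightweight: exon-overlap
  "affected" calls, single-transcript codon logic, no splice-site or UTR
  semantics. Totals from a full annotation engine will differ on real
  genomes.
* One reported figure is arithmetically over-determined in combination
  with the others: the non-G4 per-base deletion rate implied by 16
  non-G-rich deletions over 3 × 10¹⁰ base-generations is 5.3 × 10⁻¹⁰,
  while a printed 5.0 × 10⁻¹⁰ back-computes to 15 events. The package
  reports what it computes from its inputs and leaves such input
  inconsistencies visible rather than reconciling them.
* Ts/Tv on strongly transition-free sets is `NA` by design; downstream
  code must handle it.
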