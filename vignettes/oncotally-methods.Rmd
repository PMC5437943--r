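---
title: "Methods and design notes for oncotally"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for oncotally}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotally)
library(dplyr)
```

`oncotally` covers the bespoke, desk-scale computations that surround a
somatic variant-calling pipeline for a tumor cohort: planning how to
scatter per-chromosome caller jobs and gather their outputs, integrating
an ensemble of callers by voting, tabulating the annotated results into
gene-by-patient structures, and laying those structures out as
gene-centric circular plots and oncoprints. This vignette records the
models and conventions behind each step, the parameters that matter, and
the design choices that were genuinely open.

## Coordinate conventions

Three on-disk conventions coexist in this domain: MAF, SEG and VCF are
1-based inclusive, while BED is 0-based half-open. Internally every
structure on which the package performs *interval arithmetic* — copy-
number segments and gene bodies — is held 0-based half-open, converted at
the I/O boundary (`read_seg()` subtracts one from the start; BED gene
tables pass through unchanged; the writers invert the conversion). A
single internal convention removes the usual class of off-by-one bugs in
overlap computations: `end - start` is always a length, and two intervals
overlap iff `start1 < end2 && start2 < end1`. MAF and VCF positions, by
contrast, are record *identities* (nothing ever measures a length on
them), so their tibbles keep the on-disk 1-based convention that users of
those formats expect to see when they print a table.

Chromosome names are always matched exactly. A `chr`-prefix normalizer
(`strip_chr_prefix()`) exists but must be applied explicitly: silent
aliasing of `1` and `chr1` hides real data errors more often than it
fixes cosmetic ones.

## Interval planning

Variant callers that operate per chromosome can be scattered across CPUs
and merged afterwards. Chromosomes are never split into subchromosomal
windows — callers may rely on intrachromosomal context — so planning
reduces to grouping whole chromosomes. The wall-clock time of a scattered
run is governed by its longest job, i.e. by the longest chromosome, so
any grouping whose largest group does not exceed that length is free:
it reduces the number of concurrent jobs without extending the critical
path.

`plan_intervals(mode = "grouped")` therefore solves a bin-packing problem
with capacity equal to the longest chromosome, using first-fit-decreasing
(FFD): sort chromosomes by length descending (ties broken by the
chromosome-table order, for determinism), and place each into the first
group it fits. Pairing one large with one small chromosome is the special
case of this rule when only pairs fit; FFD generalizes it to groups of
any size and never produces more groups. Two properties follow directly:

* **Capacity** — by construction no group exceeds the longest chromosome.
* **Merge-maximality** — when the first chromosome of a later group was
  placed, it did not fit into any earlier group; groups only grow, so no
  two groups can ever be merged within capacity.

FFD is not guaranteed optimal in group count, but the test suite checks
it stays within one group of the exhaustive optimum (computed by a
subset-sum dynamic program) on every random table with up to eight
chromosomes; in practice, on human-like size distributions it is optimal.

Merging (`merge_variant_outputs()`) is deliberately strict: records are
pooled, sorted by (chromosome order, position, REF, ALT), exact
duplicates — same site *and* same INFO — collapse to one, but the same
site with *different* INFO raises an error. A correctly scattered run
partitions the genome, so a conflicting duplicate always indicates
planner misuse, and surfacing it beats silently picking a winner.

## Ensemble consensus

Somatic callers disagree; a standard remedy is to keep variants reported
by at least *k* of *n* callers. Votes are counted under a normalized
positional key (chromosome, position, REF, ALT): shared trailing bases
are trimmed first, then shared leading bases with the position advanced,
stopping while both alleles still have at least one base. This resolves
the padded-allele representation differences that actually occur for
SNVs and simple indels without requiring a reference FASTA; full
left-alignment against a genome is out of scope and documented as a
limitation (complex indels in repeat tracts may still split votes).

Defaults: `k = 2` (the smallest non-trivial consensus; `k = 1` is a
union and `k = n` an intersection, both of which the implementation
reproduces exactly) and `pass_only = TRUE`, so only records whose FILTER
is `PASS` or `.` vote — callers emit FILTER for a reason, and counting
their rejected calls would let two callers' noise outvote one caller's
confident call. An ensemble member that reports zero passing calls still
counts towards *n*: the ensemble size is declared by the inputs, not
inferred from surviving records. Voting is unweighted and treats indels
like SNVs; nothing in the consensus model distinguishes caller quality.

The consensus VCF annotates each record with `CALLERS` (sorted,
comma-joined supporter names) and `NCALLERS`, so downstream filtering by
support level remains possible after the fact.

## Cohort aggregation

`build_mutation_matrix()` produces the central gene-by-patient structure.
Each cell stores *all* classifications observed for that gene in that
patient plus the single worst one under a fixed severity ranking
(nonsense > frameshift > splice site > nonstop > translation start site >
in-frame indel > missense > silent > non-coding). The ranking is
consequence-severity-inspired and deliberately simple; it is a display
convention, not a biological claim, and `severity_ranks()` exposes it as
a table.

Gene recurrence is counted in **distinct non-silent mutated patients**,
not raw mutation records. Patient counting is robust to hypermutated
samples (one patient with forty passenger hits in a gene is one patient),
and non-silent filtering keeps silent/non-coding records — which are
still stored in the cells — from driving display thresholds. Both
choices are flags (`include_silent`) where the alternative is defensible.

Copy-number segments map to genes by **maximal overlap**: each
(gene, patient) takes the log2 ratio of the segment covering most of the
gene body, thresholded into the five ordinal states deep loss, loss,
neutral, gain, amplification. The default cut points (−1.0, −0.25,
+0.25, +1.0 on the log2 ratio, boundaries inclusive) are the
conventional exome heuristics; they are parameters, not constants,
because purity and ploidy shift them in real data. Overlap ties go to
the more extreme state, then the larger absolute ratio, then the
leftmost segment — an arbitrary but deterministic cascade. Genes with no
overlapping segment are neutral, not missing: absence of evidence of a
CNV is treated as a diploid call, which is the convention of discretized
gene-level tables. Externally discretized GISTIC-style integer calls
bypass all of this via `accept_gistic_states()`.

The six-class mutation spectrum collapses every SNP onto a pyrimidine
reference base by complementing purine ref/alt pairs, yielding
`C>A, C>G, C>T, T>A, T>C, T>G`. Trinucleotide (96-class) contexts would
need the reference genome and are out of scope.

## The gene-centric circular layout

Genome-coordinate circular plots waste nearly all of their angular
resolution on intergenic space when the data are gene-level summaries.
The layout here instead gives every retained gene one unit-width slot,
in genomic order along its chromosome; chromosomes with no retained gene
vanish. Equal slot widths are the simplest faithful reading of a
"relative order" layout; scaling widths by gene length or mutation count
was considered and rejected because it re-introduces the resolution
problem the layout exists to solve.

Genes are retained when mutated in at least `min_patients` patients and
not blacklisted (artefact-prone genes are conventionally hidden this
way). Labels are **bold** exactly when a gene reaches twice the display
threshold; genes on a user-supplied highlight list, or overlapping a
supplied recurrent-CNV region BED, are colored. The three inner
copy-number tracks are the gain fraction, the loss fraction and the mean
ordinal state per gene, with the full cohort as denominator — the paper
dialect this layout follows does not pin these semantics down, so they
are chosen, documented, and kept in separate files so a user can swap
any of them out. The deliverable is the text bundle (karyotype, data
tracks, labels, a minimal `circos.conf`): text is what can be tested
byte-exactly, and rendering is delegated to the standard external
renderer.

## Oncoprints and molecular subgroups

`build_oncoprint()` assembles the gene-by-patient matrix with covariates:
per-patient burden and subgroup on top, per-gene recurrence and
externally supplied significance values (e.g. driver Q values) on the
side — significance is consumed from a two-column table, never computed.
Cells print as `classification|CNSTATE` with `.` for empty.

Sample ordering defaults to the classic mutual-exclusivity ("memo")
sort: patients are compared lexicographically, descending, on their
binary mutation vector over the gene ordering. The implementation
encodes each vector as a fixed-width 0/1 string, which makes the
adjacent-pair ordering property directly checkable. `subgroup` ordering
blocks patients ABC, then GCB, then U, memo-sorting within blocks; and
`given` validates and applies any external ordering, so any published
layout can be reproduced exactly.

Subgroup classification uses marker gene lists (runtime inputs — the
package ships no gene lists): count each patient's mutated ABC-unique
and GCB-unique markers; the majority wins and ties are unclassifiable
(U). Zero evidence is the canonical U case; extending U to symmetric
non-zero conflicts is the conservative choice, since breaking a 2-2 tie
either way would assert information the markers do not contain. Genes
appearing on both lists are not unique to either subgroup and are
dropped with a warning before counting.

## The synthetic cohort generator

Real benchmark cohorts for this kind of toolkit are controlled-access;
the generator exists so that every pipeline stage can be exercised, with
known ground truth, from a seed. It emulates: a small multi-chromosome
genome; a gene table laid out deterministically with intergenic gaps;
driver genes mutated per patient by independent Bernoulli draws;
passenger mutations at a Poisson rate, confined to non-marker genes;
subgroup labels planted with their defining marker mutations (an ABC
patient gets at least one ABC-unique marker mutation and no GCB-unique
ones, and vice versa; U patients get neither); recurrent CNV regions hit
with a per-patient penetrance, emitted as segment tables whose log2
means encode the planted state (−1.5, −0.6, 0, +0.6, +1.5) plus optional
Gaussian noise; and an ensemble of imperfect callers, each detecting
every truth variant independently with its sensitivity and adding
Poisson false positives placed in intergenic space so truth and noise
can never collide.

The default design is the study condition used throughout the tests and
the acceptance script: 50 patients; chromosomes of 700/600/500/400/300
kb; 200 genes of 3 kb; 8 drivers at per-patient probability 0.5;
Poisson(35) passengers per patient, giving roughly 2,000 somatic
variants cohort-wide; 3+3 subgroup markers with label mix 0.4/0.4/0.2;
five CNV regions (two amplifications, a gain, a deep and a shallow
deletion) at penetrance 0.4; three callers at sensitivity 0.9 with
Poisson(3) false positives per patient; segment noise sd 0. These sizes
are scaled to what the algorithms actually stress (grouping, voting,
tabulation are all per-record computations) while keeping a full
end-to-end run interactive. With three callers at sensitivity 0.9 and
2-of-3 voting, per-variant recovery has the closed form
$3 p^2 (1-p) + p^3 = 0.972$, which the end-to-end checks use as their
binomial oracle.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: read-level evidence (no BAMs, hence
no mapping artefacts or coverage gaps), mutational signatures beyond a
uniform base model, clonal structure and subclonal allele fractions,
caller error modes that are correlated between callers (false positives
here are independent, which flatters consensus voting), and purity/
ploidy distortion of copy-number ratios. The tests demonstrate that the
bookkeeping — grouping, voting, tabulation, layout — is exact; they are
silent on caller quality itself.

## Numerical and degenerate-input choices

* Thresholding boundaries are inclusive on both sides (a log2 ratio of
  exactly −1.0 is a deep loss).
* All tie-breaks (FFD length ties, severity rank ties, overlap ties,
  gene-order ties, memo-sort ties) resolve by documented deterministic
  rules, so every output is byte-reproducible from the same inputs.
* Empty inputs are legal wherever a cohort can be empty (empty MAF,
  empty consensus, zero-patient design) and produce empty — not
  missing — structures; malformed inputs raise classified errors
  (`oncotally_parse_error`, `oncotally_validation_error`,
  `oncotally_schema_error`) naming the offending line or row.
* Randomness in the generator derives from one design seed through
  fixed arithmetic offsets per stream (truth, per-caller calls,
  segments), so regenerating one artifact reproduces it without
  replaying the others.

## Limitations

Key normalization is trim-based only; without a reference genome,
variants in repetitive contexts that callers represent differently after
left-alignment may fail to pool their votes. The severity ranking is a
fixed display convention, not a re-implementation of effect prediction.
Copy-number integration assigns one state per gene and ignores
intragenic breakpoints by design. Recurrence significance, signature
deconvolution and subgroup association statistics are consumed from, or
left to, dedicated tools.
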