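---
title: "Methods: factorial sensitivity analysis and barcoded IgH processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial sensitivity analysis and barcoded IgH processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighdoe)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The factorial screening model

### Design

Memory B cell expansion cultures are screened over a full factorial design
in four stimulants, each at three doses (`mbc_expansion_factors()`): IL-21
at 10/50/100 ng/ml, CpG ODN2006 at 0/0.25/1 µg/ml, R848 at 0/0.25/0.5
µg/ml, and CD40 stimulation delivered by CD40L-expressing feeder cells at
1:5/1:2/1:1 feeder-to-cell ratios. `enumerate_design()` produces the 3⁴ =
81 conditions as a deterministic lexicographic grid. Fixing any two
stimulants at given doses leaves a 9-condition sub-grid
(`count_fixed_pair_slice()`), the slice on which second-order interactions
are read.

### Variance decomposition

For a balanced response table (every design cell equally replicated, per
donor), `anova_decompose()` computes sums of squares directly from means:

* first order: `SS_f = Σ_levels n_l (ȳ_l − ȳ)²`,
* second order: `SS_fg = Σ_cells n_c (ȳ_c − ȳ)² − SS_f − SS_g`,
* donor: as a first-order additive block on donor means,
* residual: `SS_total − Σ SS_terms`, pooling replicate error, interactions
  of order > 2 and donor × stimulant structure.

On balanced data these mean-based sums of squares form an orthogonal
decomposition, so they equal the sequential ANOVA sums of squares in any
factor order; the test suite verifies every term against an independent
`stats::aov()` fit at 10⁻⁹ relative tolerance, and verifies additivity and
factor-order invariance. F statistics use the residual mean square; p-values
come from the F distribution. The 4-decimal p-value column in reports is
display-only — comparisons always use full precision.

### Sensitivity indices

The screening literature this package serves speaks of first- and
second-order "sensitivity indices" without fixing a formula. We define the
index of a term as its share of total variance, `SS_term / SS_total` (an
η², equivalently a main- or interaction-effect Sobol share under the
fixed-levels design). Normalising by `SS_total` rather than `SS_model`
keeps indices comparable across models; the residual fraction is reported
alongside so the two conventions are interconvertible. When `SS_total = 0`
(a constant table) all indices are defined as 0 and the report carries a
degenerate flag rather than erroring, keeping pipelines composable.

### Donor handling and response scale

Donors enter as an additive block (removing between-donor offsets) rather
than as a crossed factor — we do not invent donor × stimulant interactions
the screen is not powered to estimate; `include_donor_block = FALSE`
averages them into the residual instead, and both behaviours are exercised
in tests. Analysis is on the raw Ig readout scale, matching how such
screens are reported; a `log_transform` flag is available when
multiplicative noise is suspected.

### Optimal condition rule

`select_optimal()` encodes the decision rule of the screen: a stimulant
with a significant first-order effect (α = 0.05 by default) is set to the
dose maximising its marginal mean; a non-significant stimulant falls to its
lowest dose (the cheapest, least-perturbing choice — this is the rule under
which a null CpG drops to 0 µg/ml). Exact ties break toward the lower dose.

## 2. The read-processing cascade

Stages run in fixed order, and every read is accounted for in a ledger
(input = retained + rejected at each stage):

1. **Median Phred > 34**, strict, on both mates; the median of an
   even-length quality vector is the mean of the central pair, so a read at
   exactly 34 fails.
2. **Merging**: the longest *identical* suffix(forward) = prefix(reverse
   complement) overlap strictly longer than 50 nt; one mismatch anywhere in
   a candidate overlap disqualifies it, and a pair with no qualifying
   overlap is discarded (a result, not an error). Overlap qualities take
   the per-position maximum of the two reads — this affects only
   tie-breaking downstream, never the bases.
3. **Orientation** by the 20-nt universal handle; reads with the handle on
   both strands are binned as chimeric rather than silently dropped,
   handle-less reads go to an unassigned bin.
4. **Barcode**: the 14 nt following the handle in the primer-sense view.
   The running description of the library design writes the barcode
   template as `NNNNTNNNNTNNNNT`, but every constant-region primer in the
   scheme carries `NNNNTNNNNTNNNN` (14 nt) before its isotype-specific
   tail; we follow the primer sequences as authoritative: 14 nt, conserved
   T at 1-based positions 5 and 10, no ambiguity codes.
5. **Isotype** by counting shared 10-mers with the first 50 bp of each
   constant-region allele; the best allele wins, ties across isotypes or
   scores under `kmer_score_min` (default 10 of a possible 41) are
   ambiguous.
6. **Trimming** removes the FR1 forward primer (located at the 5′ end with
   ≤ 2 mismatches) and everything from the constant-region start (modal
   offset implied by the shared 10-mers), leaving the biological insert.
7. **Consensus** per (barcode, isotype) group — the isotype is part of the
   key so a barcode collision across isotypes cannot mix molecules, which
   is safe because barcodes sit inside isotype-specific primers.

"Sequence certainty" of a barcode group is not defined in the protocols
this cascade descends from; we define it as the mean over positions of the
plurality-base fraction across members, computed at the group's modal
length (members beyond ±2 nt of the modal length are dropped first). For
two members this equals pairwise identity; a singleton has certainty 1 and
is retained with support 1. Groups are retained at certainty strictly
greater than 0.80. Plurality ties break toward the base with the highest
summed Phred — with error bases carrying realistically lower qualities this
resolves most two-member disagreements correctly. The consensus is emitted
as a sequence record; because members and support counts are retained, a
filter-only reading (keep reads, build no consensus) is recoverable.

Coordinates are 0-based half-open internally; only human-facing
descriptions (e.g. barcode positions 5 and 10) are 1-based. The U bases of
the 3′ universal primer are matched as T, since sequencers report T at
uracil positions.

## 3. The simplified annotator

Full IMGT numbering is deliberately out of scope: the downstream statistics
need only V/J calls, frame status, SHM% and CDRH3 length. V and J genes are
assigned by a k-mer-seeded ungapped alignment (seeds k = 10 for V, k = 8
for J; the modal query-minus-reference offset defines the mapping), which
is exact for the substitution-only regime the package models and is
cross-checked against `Biostrings::pairwiseAlignment()` in the tests.
Retention thresholds — identity ≥ 80% over ≥ 100 aligned nt for V, ≥ 80%
over ≥ 25 nt for J — stand in for a BLAST-style significance screen and are
configurable.

* **Frame**: phase is inherited from the germline V (codon 0 at the V
  start); a sequence is in frame when the V-frame translation through the
  end of the aligned J span is stop-free and the J anchor motif falls on a
  codon boundary. A 1-nt junction indel therefore fails the phase check.
* **SHM%** is the mismatch fraction over the aligned V span at nucleotide
  level, excluding reference positions covered by the FR1 primer (primer
  bases are synthetic and would deflate the estimate) and counting
  substitutions only — indels are not SHM events here, matching the
  substitution-only simulator.
* **CDRH3** is anchor-exclusive: the nucleotides strictly between the V
  2nd-CYS codon and the J W/F anchor codon (TGG/TTT/TTC at the reference
  motif position). IMGT junction lengths include both anchors; add 6 nt to
  compare. Unlocatable or mutated anchors yield an undefined length, which
  summaries report as a separate fraction rather than dropping silently.

## 4. What the simulator emulates — and what it does not

`make_toy_references()` generates six V alleles (each headed by one of the
six real VH FR1 primers, ending on a 2nd-CYS codon, mutually < 90%
identical), four J alleles with W/F anchors at a fixed 9-nt offset, and
five constant-region alleles whose 50-bp prefixes end with the reverse
complement of the real isotype-specific primer tails. IMGT germline sets
are not redistributed; divergence floors make simulated truth unambiguous.
The amplicon layout is `[FR1 primer][V][junction][J][C 50 bp][revcomp
barcode][revcomp handle]` — the barcode is read primer-sense from the 3′
end, which is why `extract_barcode()` works on the reverse-complement view.

`simulate_repertoire()` builds in-frame V–junction–J transcripts per clone,
draws CDRH3 lengths from a configurable distribution (default: a bell over
24–81 nt centred at 45 nt), applies SHM as independent per-site
substitutions over non-primer V positions — applied per molecule, so
mutation counts are independent Binomials and closed-form expectations
hold — and assigns unique template-conformant barcodes.
`simulate_reads()` emits 300-bp paired reads (the two ends of the ~440–500
nt amplicon, overlapping in the middle by construction) with substitution
errors at a configured rate; erroneous bases carry lower Phred values
(18–28) than correct ones (36–40), emulating quality-aware base calling.

Deliberately not modelled: indels (in SHM or sequencing), PCR chimeras,
quality drift along the read, platform error motifs, barcode collisions
(barcodes are drawn without replacement) and clonal lineage structure.
Passing tests therefore demonstrate correctness of the *computational*
cascade under a clean substitution-only error model, not robustness to
every artefact of real MiSeq libraries — in particular the exact-overlap
merge rule and the ungapped annotator would both degrade on indel-rich
data, and results on real libraries depend on upstream quality of that
kind.

## 5. Study conditions, problem sizes and calibration

The synthetic study conditions mirror the screen: 3 donors × triplicate
over the 81 conditions; main effects rising with dose for IL-21 (0/10/20),
R848 (0/8/16) and CD40 (0/9/18) on a grand mean of 100, a null CpG, an
IL-21×CD40 interaction, donor offsets ±5, and Gaussian noise with SD 5 =
25% of the largest effect (`doe_effects_scenario()`). Recovery is assessed
over 100 seeded runs: all four true terms significant at 0.05, the null
CpG p-value uniform (KS test), and the injected optimum recovered by
`select_optimal()`. Note the structural ceiling: with α = 0.05 the null
stimulant is falsely significant in ~5% of runs, so optimum recovery is
expected near 96–97%, not 100%.

Sequencing-side checks use 2,000 molecules: exact consensus recovery at
zero error with 3 reads/molecule, and at 0.2% per-base error with 10
reads/molecule — a realistic UMI family size chosen because the strict
identical-overlap rule discards a fifth of error-bearing pairs, so deeper
families are what make molecule-level consensus reliable. Annotation
accuracy uses 500 molecules per SHM level {0, 1, 3, 6}% (binomial SE of
the mean SHM ≈ 0.04 points, comfortably inside the ±0.3 assertion band)
and 2,000 molecules for the CDRH3 goodness-of-fit. The stability
calibration of the no-class-switch, constant-SHM culture regime runs 100
seeded two-timepoint experiments at 250 records per day, building records
from the simulator's truth ledger (isotype and injected mutation counts);
the fidelity of the read-level path that would produce those records is
established separately by the round-trip and annotation checks, and a full
pipeline stability run is included as a smoke test. These sizes are the
package's chosen study scale; all of them are parameters, not constants.

## 6. Numerical conventions and degenerate inputs

* Strict inequalities throughout the filters (`> 34`, `> 50`, `> 0.80`),
  as specified by the protocol wording they implement.
* Balanced-only ANOVA: unbalanced tables are refused rather than silently
  reweighted; zero residual df yields `NA` F/p with indices still defined.
* Interaction SS are clamped at 0 against floating-point cancellation;
  additivity holds to 10⁻⁹ relative tolerance.
* All generators require an explicit seed; sub-streams are derived
  deterministically from it, so identical seeds give byte-identical FASTQ
  and reference files.
* Empty inputs error early with informative messages (empty read, empty
  barcode group, empty response table); discard-type outcomes (unmergeable
  pair, ambiguous isotype) are results recorded in the ledger, not errors.

## 7. Known limitations

Beyond the simulator's idealisations (§4): the annotator's ungapped
alignment misestimates identity in the presence of indels (such sequences
typically fail the frame check and are flagged unproductive rather than
corrected); IgG/IgA subclasses are resolved only to the extent the
constant references distinguish them (the toy set tracks classes, not
subclasses); and the baseline-contamination question for unswitched subsets
(switched reads attributable to sorting spill-over) is left to the analyst
— records carry isotype calls, so such reads can be excluded with a filter,
but no default exclusion is applied.
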