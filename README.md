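# ighdoe

Optimising memory B cell expansion cultures and checking that the optimised
conditions leave the B cell receptor repertoire unchanged are two halves of
one experimental programme. `ighdoe` implements both computational halves as
a tested, self-contained R package:

1. **Factorial stimulation screening.** Four stimulants — IL-21, CpG
   ODN2006, R848 and CD40 stimulation (CD40L⁺ feeder cells) — each at three
   dose levels give a 3⁴ = 81-condition full factorial design. On the
   balanced Ig-secretion response table the package computes an N-way ANOVA
   variance decomposition from level and cell means, first- and
   second-order **sensitivity indices**

   *S*<sub>term</sub> = SS<sub>term</sub> / SS<sub>total</sub>

   with F-test p-values (residual mean square as denominator, donors as an
   additive block), and selects the optimal condition: for each stimulant
   with a significant first-order effect the dose maximising its marginal
   mean, otherwise the lowest dose. Two-way ANOVA with Tukey's HSD is
   provided for final condition-versus-condition comparisons.

2. **Barcoded IgH repertoire processing.** Paired amplicon reads from
   barcoded (UMI) IgH libraries are pushed through the filtering cascade:
   median Phred > 34, merging on an identical overlap > 50 bp, orientation
   V-primer → constant-region primer via the universal handle, extraction
   and conserved-base validation of the 14-nt `NNNNTNNNNTNNNN` barcode,
   isotype assignment by 10-mer matching against the first 50 bp of the
   constant-region references, primer/constant trimming, and per-barcode
   consensus retained at > 80% sequence certainty. A simplified junction
   annotator then assigns germline V/J genes (k-mer-seeded similarity
   screen, ≥ 80% identity over ≥ 100 / ≥ 25 nt), checks reading frames, and
   computes SHM% (nucleotide mismatches over the aligned V segment,
   FR1-primer span excluded) and anchor-exclusive CDRH3 length. Summaries
   report per-sample isotype composition, SHM trajectories across culture
   days and CDRH3 length densities, with formal stability tests
   (total-variation distance + chi-square homogeneity; bootstrap CI on the
   SHM day difference).

3. **Synthetic data with full truth ledgers.** The deposited study data are
   access-controlled, so a first-class simulation module generates toy
   germline references (carrying the real primer scheme), clonal IgH
   repertoires with configurable isotype mixtures, per-site SHM rates and
   CDRH3 length distributions, paired 300-bp reads with Phred-annotated
   substitution errors, and factorial response tables with known main
   effects, interactions, donor offsets and noise — every claim the package
   makes is testable against known truth, offline.

Intended users: immunology labs running B cell culture optimisation screens
and anyone needing a transparent, dependency-light reference implementation
of UMI-consensus IgH preprocessing.

## Worked example

Simulate the study-shaped screen (3 donors × triplicate over the 81
conditions, increasing IL-21/R848/CD40 effects, an IL-21×CD40 interaction,
null CpG, noise at 25% of the largest effect) and analyse it:

```r
library(ighdoe)

des <- enumerate_design(mbc_expansion_factors())   # 81 conditions
tab <- simulate_doe_response(des, doe_effects_scenario(seed = 42))
report <- sensitivity_indices(anova_decompose(tab))
report
#> Sensitivity indices (SS_term / SS_total)
#>         term order          ss  df            f        index p_display
#> 1       IL21     1 70443.53286   2 1371.6295915 3.590154e-01    0.0000
#> 2        CpG     1    15.93819   2    0.3103379 8.122899e-05    0.7333
#> 3       R848     1 30999.36112   2  603.5989295 1.579882e-01    0.0000
#> 4       CD40     1 61541.44266   2 1198.2940155 3.136459e-01    0.0000
#> 7  IL21:CD40     2  2180.43183   4   21.2279587 1.111257e-02    0.0000
#> ...
#> 11     donor     1 12567.59937   2  244.7079312 6.405076e-02    0.0000
#> 12  residual    NA 17821.06923 694           NA 9.082507e-02        NA
```

IL-21 explains 36% of response variance, CD40 31%, R848 16%; CpG is
indistinguishable from noise (p = 0.73) and the only meaningful interaction
is IL-21×CD40 (p < 0.0001). Condition selection applies the
significant-max / default-lowest rule:

```r
factors <- mbc_expansion_factors()
marg <- setNames(lapply(factors, function(f) marginal_means(tab, f$name)),
                 vapply(factors, `[[`, "", "name"))
select_optimal(report, marg, factors)
#> Optimal condition (alpha = 0.05)
#>   factor level       rationale             p
#> 1   IL21   100 significant-max 7.692629e-242
#> 2    CpG     0  default-lowest  7.333009e-01
#> 3   R848   0.5 significant-max 1.346658e-152
#> 4   CD40   1:1 significant-max 8.081057e-226
```

— i.e. 100 ng/ml IL-21, 0.5 µg/ml R848, 1:1 feeder ratio, and CpG dropped.

The sequencing half runs the same way from simulated truth:

```r
refs  <- make_toy_references(seed = 1)
p     <- repertoire_sim_params(n_clones = 100, molecules_per_clone = 3,
                               reads_per_molecule = 10, error_rate = 0.002,
                               shm_rate = 0.02, seed = 1)
truth <- simulate_repertoire(p, refs)
reads <- simulate_reads(truth, p)
res   <- process_reads(reads$r1, reads$r2, refs)
rearr <- annotate_sequences(res$consensus, refs)
```

`res$ledger` accounts for every input read; `rearr` is an AIRR-style table
(`c_call`, `v_call`, `j_call`, `productive`, `shm_pct`,
`junction_length_nt`) ready for `summarize_repertoire()`,
`shm_trajectory()` and `composition_stability()`.

A thin command-line wrapper with `simulate-reads`, `process`,
`doe-simulate` and `doe-analyze` subcommands lives in
`inst/scripts/ighdoe-cli.R`.

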