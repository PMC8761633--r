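# mirhairpin

Structural and sequence determinants of miRNA hairpin processing, as a
tested, reusable R pipeline.

Animal pri-miRNAs are cropped by the Drosha–DGCR8 Microprocessor and then
diced by Dicer, and both enzymes discriminate between substrates. Much of
that discrimination is written into the hairpin: the free energy (ΔG,
kcal/mol) of its **terminal loop region**, **miRNA duplex**, **proximal
domain** (the 12-nt basal extensions beyond each pre-miRNA end) and
**distal domain** (the remaining flanks), plus the positional sequence
motifs **UG** (basal, −14/−13), **UGU** (start of the terminal loop),
**CNNC** (16–18 nt downstream of the 3′ Drosha site) and the bulged-GHG
(**mGHG**) basal-stem element scored from a lookup table. `mirhairpin` is
for researchers who want to compute these features for a hairpin cohort
and relate them to in-vitro cleavage efficiencies and in-vivo miRNA
expression.

The package provides:

* a minimum-free-energy RNA folder (nested structures, Watson–Crick + GU
  nearest-neighbor model with packaged, swappable energy tables; exact
  integer-centi-kcal arithmetic; deterministic tie-breaking) with
  loop-decomposition evaluation and **region-restricted** energies — the
  primitive behind per-domain ΔG attribution, where
  `dg_duplex = dg_pre − dg_loop` holds exactly by construction;
* domain demarcation following the structural definitions: the terminal
  loop region runs from the nucleotide after the miR-5p 3′ end to just
  inside its pairing partner on the 3′ arm, with a scan-inward rule when
  that end is unpaired, and a 2-nt-overhang rule to predict an
  unannotated arm;
* motif scanning with configurable windows and a documented
  `key → score` TSV format for mGHG tables (a synthetic demo table is
  included; the published values are external data);
* gel-lane quantification (`raw_ratio = product/(product+substrate)`,
  control lane normalized to exactly 100), Spearman rank correlation
  (Pearson-on-midranks; exact permutation p at n ≤ 9) and two-tailed
  Mann–Whitney U (exact enumeration at n ≤ 8), correlation reports,
  motif-count strata and conserved-vs-unique family comparisons;
* a seeded synthetic cohort generator that plants structural and motif
  effects through a log-linear latent efficiency model, so the whole
  pipeline is testable with known ground truth;
* I/O for FASTA, miRBase-style GFF3 / flat TSV arm annotations,
  lane/expression TSVs, and dot-bracket files.

## Worked example

Simulate a 150-hairpin cohort with the default planted effects, run the
full analysis, and look at the Drosha rows of the correlation report:

```r
library(mirhairpin)
library(dplyr)

coh <- generate_cohort(cohort_config(n_mirnas = 150, seed = 1))
res <- analyze_cohort(coh$records, coh$lanes,
                      mghg_table = mghg_demo_table())
filter(res$report, response == "drosha_efficiency")
#> # A tibble: 7 × 7
#>   feature     response              n     rho  p_value     p_bh note
#>   <chr>       <chr>             <int>   <dbl>    <dbl>    <dbl> <chr>
#> 1 dg_pri      drosha_efficiency   149 -0.163  4.76e- 2 7.41e- 2 <NA>
#> 2 dg_pre      drosha_efficiency   149 -0.0233 7.78e- 1 7.91e- 1 <NA>
#> 3 dg_loop     drosha_efficiency   149  0.379  1.82e- 6 6.38e- 6 <NA>
#> 4 dg_duplex   drosha_efficiency   149 -0.207  1.11e- 2 1.95e- 2 <NA>
#> 5 dg_proximal drosha_efficiency   149 -0.523  7.92e-12 3.70e-11 <NA>
#> 6 dg_distal   drosha_efficiency   149  0.266  1.05e- 3 2.10e- 3 <NA>
#> 7 mghg_score  drosha_efficiency   149  0.532  3.05e-12 2.13e-11 <NA>
```

Each row is one Spearman test of a feature against relative Drosha
cleavage efficiency over the 149 non-control substrates. The signs read
exactly as the biology says they should: a *more stable proximal domain*
(lower `dg_proximal`, ρ = −0.52) and a *less stable terminal loop* (higher
`dg_loop`, ρ = +0.38) predict better cleavage, and the mGHG score
correlates positively (ρ = +0.53) — these are the effect directions the
generator planted, recovered by the pipeline from sequence alone. The
control RNA's relative efficiency is exactly 100 by construction:

```r
eff <- res$efficiencies
eff$relative_efficiency[eff$is_control & eff$enzyme == "drosha"]
#> [1] 100
```

Individual primitives are just as accessible:

```r
fold_mfe("GGGGAAAACCCC")
#> <fold_result> 12 nt, dG = -4.18 kcal/mol
#>   GGGGAAAACCCC
#>   ((((....))))
```

(−4.18 = three GC-on-GC stacks at −3.26 plus a 5.6 size-4 hairpin-loop
penalty.) `plot_correlation_report()`, `plot_motif_strata()` and
`plot_timecourse()` draw the standard figures for each result type.

Real data enter through `read_hairpins()` (FASTA + GFF3/TSV arms),
`read_expression_table()` (per-arm, per-tissue counts) and a lane TSV;
`run_full()` orchestrates every stage from files and writes a
deterministic report bundle. `filter_human_mirna_number()` applies the
human name-number < 1000 restriction to keep only well-characterized
canonical human miRNAs.

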