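---
title: "Structural and sequence determinants of miRNA hairpin processing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural and sequence determinants of miRNA hairpin processing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhairpin)
library(dplyr)
```

## The scientific problem

Animal microRNAs are produced in two endonucleolytic steps: the
Drosha–DGCR8 Microprocessor crops the primary transcript (pri-miRNA) into a
precursor hairpin (pre-miRNA), and Dicer releases the mature duplex. Both
enzymes discriminate strongly between substrates, and much of that
discrimination is encoded in the hairpin itself:

* **Terminal loop region** — everything apical of the miR-5p 3' end. A
  flexible (less stable, higher free energy) loop region favors cleavage.
* **miRNA duplex** — the paired miR-5p/miR-3p body of the stem.
* **Proximal domain (basal stem)** — the 12-nt extensions immediately
  beyond the two pre-miRNA ends; a well-paired basal stem (lower free
  energy) favors Drosha cleavage.
* **Distal domain** — the remaining single-stranded flanks.
* **Sequence motifs** — a basal UG, an apical UGU, a downstream CNNC, and
  the bulged-GHG (mGHG) element of the basal stem, each at a canonical
  position relative to the Drosha cleavage sites.

`mirhairpin` implements this analysis end to end: it folds hairpins,
demarcates the domains, attributes free energy to each, scans the motifs,
converts gel band intensities into control-normalized cleavage
efficiencies, and links features to cleavage and to mature-miRNA expression
with rank statistics. A seeded synthetic-cohort generator with planted
effects makes every stage testable against known ground truth.

## The folding model

Secondary structures are predicted by a dynamic program over all nested
(pseudoknot-free) structures under a self-contained nearest-neighbor
energy model:

* Watson–Crick and GU wobble pairs, with a packaged 6×6 stacking table
  (kcal/mol at 37 °C) symmetric under strand flip;
* size-dependent initiation penalties for hairpin, bulge and interior
  loops, tabulated to size 30 and extended with a Jacobson–Stockmayer
  log law (`1.08 · ln(n/n_ref)` kcal/mol);
* an affine multiloop cost (offset 3.4, 0.4 per branch, 0 per unpaired
  nucleotide);
* minimum hairpin loop of 3 nt; interior loops capped at 30 unpaired
  nucleotides during folding; no dangles, coaxial stacks or pseudoknots.

This is intentionally **not** a bit-exact reproduction of any particular
folding program: the downstream statistics depend on the relative ordering
of domain free energies across a cohort, not on one program's absolute
values. The model tables ship as editable TSVs (`inst/extdata/`), so the
entire energy function is swappable.

Two numerical choices matter for testability. First, all energies are
handled internally as integer centi-kcal, so a folded structure, its
re-evaluated loop decomposition, and any region-restricted sum agree to the
last bit — "equal" in the test suite means `identical()`, not "close".
Second, ties between co-optimal structures are broken deterministically:
most base pairs first, then the lexicographically smallest dot-bracket.
The test suite verifies both the energy and the tie-break against an
independent exhaustive enumerator on hundreds of short random sequences,
so the dynamic program is exact by construction, not by convention.

## Domain demarcation and free-energy attribution

The pre-miRNA spans miR-5p start through miR-3p end. The terminal loop
region starts at the first nucleotide after the miR-5p 3' end and ends just
inside its "corresponding" 3'-arm nucleotide; *corresponding* is resolved
structurally as the pairing partner of the last paired position at or
5'-ward of the miR-5p 3' end (scanning inward when that end is unpaired).
This is the only structure-aware reading that is always well defined. Both
anchor positions are excluded from the region; the choice is switchable in
principle but fixed here for determinism.

When only one arm is annotated, the partner arm is predicted from the pair
table with the standard 2-nt 3'-overhang register: the annotated arm's end
partners, shifted 2 nt toward the hairpin 5' end (predicting miR-5p) or 3'
end (predicting miR-3p).

Free energies are attributed as follows:

* `dg_loop`, `dg_proximal`, `dg_distal` are **region-restricted sums** over
  the loop decomposition of the pri-miRNA MFE structure. An energy term
  belongs to a region only when *all* its participating nucleotides
  (including both strands of closing pairs) lie inside it; cross-boundary
  terms belong to no domain. This makes the additivity property exact:
  region energies over decomposition-aligned tilings sum to the total.
  We deliberately do **not** refold flanks in isolation — isolated flanks
  adopt non-native structures.
* `dg_pre` is the MFE of the pre-miRNA subsequence folded on its own, and
  `dg_duplex = dg_pre − dg_loop`, so the subtraction identity holds by
  construction.

A practical consequence of the all-inside rule: a terminal loop region
consisting only of unpaired bases has `dg_loop = 0` (its hairpin-loop term
needs the closing pair, which sits outside the region); loop regions
containing additional apical stem score negative. Likewise the proximal
domain's energy comes from the basal-stem stacks fully contained in the
12-nt extensions.

## Motif scanning

Motif windows are not re-derived here; the defaults follow the positions
established in the Microprocessor literature and every window is a
configuration parameter (`motif_windows()`):

| motif | default window | units |
|---|---|---|
| UG    | starting 14 nt upstream of the pre-miRNA 5' end | fixed position |
| UGU   | starting within the first 4 nt of the terminal loop region | window |
| CNNC  | first C 16–18 nt downstream of the pre-miRNA 3' end | window |
| mGHG  | 3 basal positions centered 5 nt below the 3' Drosha site | window |

The mGHG score is a pure table lookup: the three 3'-strand window positions
are encoded as `"<partner><base>"` (or `"-<base>"` when unpaired), joined
with `/`, and looked up in a `key → score` TSV. The published score values
are external data that this package does not restate; it ships the lookup
mechanism, the documented file format, and `mghg_demo_table()`, a fully
**synthetic** table whose scores vary deterministically with window
composition so the planted-effect recovery machinery can be exercised.
Unknown keys return `NA` — there is no nearest-key imputation.

## Quantification and statistics

Gel lanes are reduced to `raw_ratio = product / (product + substrate)`,
normalized per (enzyme, batch) to the control lane so the control is
exactly 100, and replicates are aggregated (mean by default). Expression
tables carry one row per mature arm; tissues are combined by summation
(order-invariant; a mean option exists since the combination rule is a
modeling choice) and a miRNA's expression is the 5p + 3p sum.

The correlation machinery is deliberately thin and fully specified:

* **Spearman**: Pearson correlation of midranks (tie-correct by
  construction); two-sided p by exact enumeration over permutations for
  n ≤ 9, t-approximation with n − 2 df otherwise. Pairwise-complete
  deletion per comparison, so N can differ across report rows.
* **Mann–Whitney U** (two-tailed): exact enumeration over all labelings
  when both groups have ≤ 8 members; tie-corrected normal approximation
  *without* continuity correction otherwise, which keeps the p value
  exactly symmetric under swapping the groups.

Both are cross-checked in the tests against `cor.test()` / `wilcox.test()`
where the standard methods coincide, and against brute-force enumeration
where they do not. No multiple-testing correction is applied to the calls;
a Benjamini–Hochberg column is emitted for reference. Expression is rank-
analyzed untransformed (rank statistics are invariant to monotone
transforms); log scaling is for plotting only. "Conserved" miRNAs are
members of families with ≥ 2 members within the analyzed cohort.

## The synthetic cohort generator

`generate_cohort()` builds each pri-miRNA around a planted structure:
a continuous helix of `basal` (6–12) + 22 (duplex) + `upper` (2–8) pairs,
an apical loop of 4–10 nt, flanks of 30 nt (5') and 40 nt (3') — the
substrate-design lengths — and, in half the cohort on average, a small
GC stem-loop in the 5' distal flank. Stem pair identities are drawn with a
per-hairpin GC propensity (0.25–0.85), which spreads the domain free
energies; flank filler is A-rich with scattered C so single-stranded
regions have little pairing potential against the planted helices. The UG,
UGU and CNNC motifs are planted at their canonical windows with probability
0.5 each, and the three mGHG basal window pairs are drawn explicitly (the
ground-truth key/score is recorded). Distal stem-loops shorter than 4 bp
are not planted: under the energy model their loop penalty exceeds the
stack gain, so they could not survive in the MFE structure.

The latent Drosha log-odds efficiency is linear in the cohort-standardized
true domain energies, the motif count and the standardized mGHG score:

```
eta = β0 + β_prox·z(dg_proximal) + β_loop·z(dg_loop) + β_dup·z(dg_duplex)
        + β_dist·z(dg_distal) + β_motif·count + β_mghg·z(score) + ε,
ε ~ N(0, 0.5²)
```

with defaults `β_prox = −0.5`, `β_loop = +0.5`, `β_dup = −0.3`,
`β_dist = +0.3`, `β_motif = +0.15`, `β_mghg = +0.5` — the signs the
correlation analysis is expected to recover, at magnitudes (½ SD per SD of
feature, against ½ SD of noise) typical of the reported rank correlations.
The raw cleavage ratio is `plogis(eta)`, and lane intensities are
back-computed (`product = r·T`, `substrate = (1−r)·T` with lognormal lane
totals) so `raw_cleavage_ratio()` recovers the latent ratio exactly.
A Dicer latent depends on the loop energy only. Expression is negative
binomial (dispersion 0.4) around 20 reads per unit relative efficiency,
split 65/35 between arms and binomially across two tissues. One designated
cohort substrate is the control for each enzyme and batch, mirroring the
control-RNA normalization scheme. A single seeded generator drives every
draw, so a config reproduces its cohort byte for byte, and cohort
generation leaves the caller's RNG state untouched.

What the generator does *not* emulate: isomiR end heterogeneity,
multi-hairpin or deeply branched pri-miRNAs, tissue-specific expression
structure, gel-quantification artifacts beyond lognormal lane scaling, and
any realistic distribution of absolute folding energies. Passing tests
therefore demonstrate that the *pipeline machinery* — folding, domain
attribution, motif lookup, normalization and rank statistics — recovers
planted signal faithfully; they are not evidence about real miRNA biology.

## Study sizes and reproducibility checks

The test suite runs each heavy check at the size it is specified for:
folding is verified against exhaustive enumeration on 200 random sequences
of length 8–18; null calibration and signed-effect recovery each use 100
seeded cohorts of n = 150 hairpins; time-course/end-point concordance uses
100 seeded panels of 8 substrates at 4 timepoints; the T7 G-substitution
rule is checked on 100 generated pre-miRNAs. The time-course panels use
log-spaced rate constants (0.002–0.035 min⁻¹), emulating a designed
substrate panel with distinct efficiencies rather than rates drawn at
random, and the range keeps the 60-min end point inside the assay's dynamic
range (fastest substrate ≈ 0.88 cleaved): an end point that has saturated
cannot rank substrates, and real end-point assays are designed not to
saturate. Ratio measurement noise is 0.01 SD, the reproducibility scale of
phosphorimager band ratios. `scripts/acceptance.R` re-runs the pipeline's headline
quantities from scratch at a caller-supplied seed.

## Known limitations

* The energy model is a reduced nearest-neighbor parameterization; its
  absolute ΔG values differ from Turner-complete implementations (no
  dangles, terminal-mismatch or special-loop terms). Cross-cohort rank
  structure, which the analyses consume, is robust to this.
* Only the single MFE structure is used; co-optimal and suboptimal
  ensembles are ignored (the tie-break makes the choice deterministic).
* Annotated canonical arm ends are taken as authoritative; isomiR end
  heterogeneity means real loop-region boundaries carry uncertainty the
  package does not model.
* The shipped mGHG tables are synthetic; real analyses must supply the
  published score table in the documented TSV format.
* Cleavage-site selection (where Drosha/Dicer cut, as opposed to how
  efficiently) is out of scope.

## A worked example

```{r example, eval = FALSE}
coh <- generate_cohort(cohort_config(n_mirnas = 150, seed = 1))
res <- analyze_cohort(coh$records, coh$lanes,
                      mghg_table = mghg_demo_table())
filter(res$report, response == "drosha_efficiency")
plot_correlation_report(res$report)
```

The README shows the numbers this prints and what they mean.
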