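---
title: "Methods: lipidome composition statistics and co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipidome composition statistics and co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how `lipidnet` defines its statistics, which
parameters matter, what the synthetic-data generators do and do not
emulate, and the design decisions taken where the underlying analysis
admitted more than one reading.

```{r setup, message = FALSE}
library(lipidnet)
```

## Lipid nomenclature

Species names are parsed as `CLASS C:D`, optionally with a resolved acyl
chain annotation `(a:b/c:d[...])`. The tokenizer accepts the dialects seen
in instrument exports — no separator, whitespace, or parentheses between
the class token and the composition block — and normalises the synonyms
`TG`→`TAG`, `DG`→`DAG`, `MG`→`MAG`, `LysoPE`→`LPE` before the vocabulary
check. The vocabulary is the fourteen classes of the temperature-stress
glycerolipidome (TAG, DAG, MAG, MGDG, DGDG, PC, PI, PE, PG, PS, CL, PA,
LPE, DGTS); the sulfolipid SQDG is deliberately absent because the
analyses this package supports exclude it upstream. Ether and oxidised
notations (`O-`, `P-`) are rejected rather than silently mis-parsed.
Chain annotations must sum to the stated totals (`lipidnet_inconsistent_chains`
otherwise); chain order is preserved as given and carries no sn-position
meaning. Categories are fixed: neutral (TAG/DAG/MAG), galactolipid
(MGDG/DGDG), phospholipid (the eight P-classes), betaine (DGTS);
"membrane lipids" means everything non-neutral.

## Composition statistics

All statistics aggregate replicates by the arithmetic mean within a
condition before any ratio is formed; standard deviations are reported
alongside for the bar-plot convention of mean ± SD over biological
replicates.

**mol%** is always relative to an explicit denominator scope — total
glycerolipids, phospholipids only, membrane lipids only, or (for species)
within the species' own class. Scope totals of zero raise
`lipidnet_degenerate_scope` rather than producing NaN.

**Fold changes** are ratios of mean absolute contents (nmol per mg dry
weight), not of mol%: "TAG increased 2.3-fold" refers to content, while
mol% is reported separately. A zero control mean yields `NA` with a
warning, never infinity.

**The double-bond index** is defined per molecule: DBI(S) = Σ xᵢ·dᵢ with
xᵢ the mol fraction of species *i* within scope *S* and dᵢ its total
double-bond count. The alternative — normalising per acyl chain, which
down-weights triacyl TAG relative to diacyl membrane lipids — was
considered and rejected: the published "total membrane lipids" index is
reproduced by the per-molecule form on whole-molecule species records,
and within the membrane scope (where DBI is typically quoted) all species
are diacyl (LPE/MAG monoacyl species are rare and minor), so the two
definitions differ only by a near-constant factor there. Per-class
relative DBI changes are 100·(DBI_trt − DBI_ctl)/DBI_ctl on the
within-class scope.

**Fatty-acid composition** of a class requires every species of that
class to carry resolved chains; each chain occurrence contributes its
species' mean amount once, so a di-18:3 species counts 18:3 twice. This
matches the convention of FA-composition bar charts derived from
species-resolved lipidomics rather than from FAME GC data.

**Kruskal–Wallis.** H is computed on ranks with the standard tie
correction. The default p-value uses the chi-square approximation with
k−1 degrees of freedom (identical to `stats::kruskal.test`, which the
test suite uses as an independent cross-check). With `exact = TRUE` the
p-value is the exact permutation tail: all distinct assignments of the
observed ranks to groups of the observed sizes are enumerated (34 650 for
three groups of four) and the proportion with H at least the observed H
is returned. Exact mode is limited to n ≤ 12, the design size of a
three-condition, four-replicate lipidomics experiment. Numerical note:
the tail comparison uses H ≥ H_obs − 1e−12 so that permutations
reproducing the observed statistic are never lost to floating-point
noise, and fully tied data (tie correction = 0) returns H = 0, p = 1 by
convention. The chi-square approximation should not be treated as
interchangeable with the exact tail at these sizes: across random
four-replicate datasets the two can differ by more than 0.05 in absolute
p, which is why the exact mode exists and why borderline significance
calls at n = 12 should use it.

## Expression profiles

Relative quantification follows the Livak 2^−ΔΔCt scheme: per replicate,
ΔCt = Ct_target − (mean reference Ct in the same sample); per condition
and timepoint, ΔΔCt = mean ΔCt_treatment − mean ΔCt_control; log2FC =
−ΔΔCt. With several reference genes the per-replicate reference Ct is
their arithmetic mean by default — in log-expression space the arithmetic
mean of Ct *is* the geometric mean of expression, which is the standard
multi-reference recommendation; a `"geometric"` option instead averages
the linear 2^−Ct values for users who prefer expression-space averaging.
log2FC is invariant to any constant shift of all Ct values, a property
the test suite checks.

Profiles are ordered vectors over the fixed grid LT_48, LT_96, LT_168,
HT_48, HT_96, HT_168 (hours, treatment vs same-timepoint control). The
0 h point is excluded by construction: its log2FC is identically zero for
every gene and would inject a shared anchor into every correlation,
inflating all pairwise r. Genes missing any grid point are flagged
incomplete and excluded from network analysis (with a mandatory warning)
rather than imputed — the same convention that drops a TF undetectable by
qPCR from the published network. Response classification uses
|log2FC| ≥ 1 with the boundary counted as a response (inclusive), so a
profile printed at exactly the cutoff is not silently dropped; 0.95 is
"unchanged". Differential-expression filtering retains q < 0.05 strictly,
per the stated rule.

## The co-expression network

Every TF × gene pair is scored by the Pearson correlation of their
6-point log2FC profiles; two-sided p comes from t = r√(n−2)/√(1−r²) with
n−2 degrees of freedom (|r| = 1 is reported as p = 0 rather than NaN).
Two threshold variants are in circulation for this construction and both
are exposed as presets: the main-text criterion (|R| > 0.9 strict,
P < 0.05) — the default — and the figure-caption variant (R ≥ 0.9
inclusive, P < 0.005). The source descriptions of the same network
disagree on which was used and even on the sign of the retained edges
(the prose says no positive correlations were observed while the figure
legend colours positive correlations); `lipidnet` follows the figure
convention — `sign = "positive"` keeps positively correlated pairs — and
offers `sign = "both"` for exploration. p-values are deliberately not
multiplicity-adjusted, matching the original construction; users wanting
FDR control can filter `tidy(net)` with `p.adjust` themselves.

The network object enforces the bipartite contract (no identifier on both
sides, no duplicate pairs), records its thresholds, and exports to SIF,
GraphML (with r and p edge attributes) and flat TSV for Cytoscape.

With only n = 6 profile points, the sampling variability of r is large:
under the null, P(r ≥ 0.9) ≈ 0.7% per pair, so a 17 × 32 screen is
expected to admit a few spurious edges at the default thresholds even
from pure noise. This is a property of the published criterion at this
grid size, not of the implementation, and is quantified by the decoy
admission rate in `scripts/acceptance.R`.

## Synthetic data

`simulate_lipidome()` draws baseline species abundances lognormally
within each class, scales class totals by planted per-condition fold
changes, redistributes abundance *within* classes by an exponential
unsaturation tilt (species weight × e^{t·d}, renormalised so class totals
are preserved), with the tilt t solved by 1-D root finding so the
membrane-scope DBI of each condition hits its planted target exactly at
the mean level; finally mean-preserving lognormal noise at the specified
CV is applied per replicate. Defaults embody the temperature-stress study
design: three conditions (LT/NT/HT) × 4 replicates, 287 species over 14
classes with TAG at 48 mol% of the control pool; TAG folds 2.3 (LT) and
3.4 (HT) — which, by arithmetic, put TAG at 68.0 and 75.8 mol% of total
glycerolipids; membrane DBI targets 2.46 (NT, HT) and 3.41 (LT); six
dominant polyunsaturated TAG species holding ~80% of the TAG pool; a
planted control-condition share of 0.62 for the di-18:3 (36:6) species of
MGDG and DGDG, which the LT tilt drives to class dominance (~63–65 mol%),
the cold-acclimation signature; and replicate CV 10%, a deliberately
clean but realistic figure for targeted lipidomics on biological
quadruplicates. Species names are emitted in a mix of the shorthand
dialects the parser accepts, so every simulation also exercises the
tokenizer.

What the generator does *not* emulate: correlated noise between species
sharing an internal standard, values censored at a detection limit,
class-specific fold changes of the minor membrane classes (all non-TAG
folds default to 1, though membrane composition still shifts via the
tilt), and any mechanistic kinetics of lipid biosynthesis — it is a
statistical emulator. Passing tests on it therefore demonstrate estimator
correctness under the stated statistical conditions, not robustness to
every artefact of real LC–MS data.

`simulate_expression()` draws TF profiles i.i.d. normal (SD 2, the scale
of strong log2FC responses) over the 6-point grid; each planted target
gene is slope × TF + Gaussian noise; decoy genes and TFs are independent
draws. The default planted adjacency mirrors the published topology: 7
regulating TFs over 16 target genes with degree sequence
(8, 3, 1, 1, 1, 1, 1) — the strongest hub regulating 8 genes — and the
remaining 16 genes and 10 TFs as decoys. Each planted gene has a single
driving TF: with a 6-point grid, a gene mixing two independent regulators
would correlate with neither above 0.9, so multi-parent planted edges
would be unrecoverable by construction under the published criterion.
The default noise SD is 0.4, putting the expected planted correlation
near 0.98. This strong-coupling regime is a deliberate choice: at an
expected r of 0.95 the n = 6 sampling distribution of r is so wide that
about one truly planted edge in six falls below the 0.9 cutoff
there, and no threshold-based
reconstruction could meet a 90% recovery expectation; at r ≈ 0.98
recovery settles near 97% while decoys stay
below 1%, which is the regime in which a thresholded screen is an
informative instrument. Both rates are recomputed, not assumed, by the
acceptance script and the test suite.

Both simulators take explicit seeds (never global state), are
byte-reproducible, and ship their ground truth alongside the data — the
truth file (YAML) lists the planted parameters so that tests never
re-derive truth from the generated data.

## Pipeline and numerical conventions

The orchestration layer (`run_simulate()`, `run_lipidome_summary()`,
`run_network()`, and the `inst/cli/lipidnet` front end) writes tidy TSVs
whose first line is a `#` comment naming units and denominator scope, and
a YAML manifest per run with the package version, configuration and input
MD5 checksums. Reruns on identical inputs are byte-identical for all data
tables. Report-level rounding (mol% to 0.1, DBI to 0.01) is left to the
consumer; all stored values are full precision.

Problem sizes used by the automated checks were chosen to keep the whole
suite desk-scale on a single CPU: 200 seeded simulations for fold-change
recovery, 100 for edge recovery, 300 for the null decoy-rate comparison
against the analytic (1 − r²) tail, and exact Kruskal–Wallis enumeration
at the native n = 12 design size.

## Known limitations

* The parser targets diacyl/triacyl shorthand; ether, oxidised and
  sphingolipid notations are out of scope by design.
* Exact Kruskal–Wallis enumeration is combinatorial and capped at n = 12;
  larger designs fall back to the chi-square approximation.
* Correlation-threshold networks on 6-point profiles are screening tools:
  edges are co-expression hypotheses, not causal or direct regulatory
  claims, and the expected spurious-edge count at the published
  thresholds is nonzero (see above).
* Fold changes and mol% assume amounts are already normalised to dry
  weight with internal standards upstream; the package performs no
  intensity-level normalisation.
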