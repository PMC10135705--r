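---
title: "Charge complementarity between TCR CDR3s and tumor antigens: model, pipeline and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge complementarity between TCR CDR3s and tumor antigens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrcs)
```

## The scoring model

The package quantifies how well a T-cell receptor CDR3 peptide could
electrostatically complement an antigen peptide. Residues carry charges
from a configurable table; the default assigns +1 to lysine and
arginine, -1 to aspartate and glutamate, +0.5 to histidine (partially
protonated at physiological pH) and 0 to the rest. For a CDR3 of charges
$q^c_1,\dots,q^c_m$ aligned at offset $o$ along an antigen fragment of
charges $q^a_1,\dots,q^a_n$ ($m \le n$), the register score is

$$S(o) = \sum_{i=1}^{m}\Big[w_d\,\varphi(q^c_i, q^a_{o+i})
       + w_a\big(\varphi(q^c_i, q^a_{o+i-1})
       + \varphi(q^c_i, q^a_{o+i+1})\big)\Big],
\qquad \varphi(x, y) = -xy,$$

with out-of-range antigen positions contributing zero. Opposite charges
directly across from each other raise the score by $w_d$ per unit
charge product; charges that are merely adjacent to an opposite charge
contribute the smaller $w_a$; like charges subtract symmetrically. The
pair score is $\max_o S(o)$ — the most complementary register — and the
shorter sequence always slides along the longer, which makes the score
symmetric in its arguments.

Assumptions worth keeping in mind: the model sees only charge, in a
strictly linear, gapless alignment. Hydrophobic packing, shape, MHC
restriction and three-dimensional geometry are all outside it. It is a
screening statistic for big-data settings, not a binding predictor for
any individual receptor.

### Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `w_direct` | 1.0 | dimensionless | scale of the score; direct opposition dominates |
| `w_adjacent` | 0.5 | dimensionless | proximity without direct alignment contributes less; constrained `<= w_direct` |
| H charge | +0.5 | unit charge | partial protonation near pH 7.4; set to 0 via `charge_table(c(H = 0))` for the fully deprotonated view |
| `normalize` | off | — | optional division by slider length for cross-length comparisons; off because the baseline analysis compares scores against one fixed antigen |

The exact weighting of near-alignment in prior charge-complementarity
tools is not published in reusable form, so these weights are this
package's own minimal realisation of "direct opposition counts most,
adjacency counts less"; both are exposed and every downstream function
accepts a custom `score_weights()` and `charge_table()`.

With the defaults, all scores are multiples of 0.125, so exact equality
against an independent brute-force enumeration is meaningful — the test
suite exploits this.

## From scores to cohort results

One case contributes many CDR3s. The per-case complementarity score is
the **maximum** over its CDR3 pair scores by default: a single strongly
complementary clone is the biologically salient event, and the maximum
is monotone under repertoire growth, which makes its behaviour easy to
reason about. The arithmetic mean is available
(`aggregation = "mean"`) for sensitivity analysis; on sparse
exome-derived repertoires the two often agree in rank.

The cohort is split at the **median** CS: strictly greater goes to the
upper group, ties and everything else to the lower. With an odd cohort
or ties at the median the lower group is therefore at least as large —
the convention that yields 21-versus-23 style splits on a 44-case
cohort. Quartile or continuous-score analyses are deliberately out of
scope.

Survival in each group is summarised by the Kaplan-Meier product-limit
estimator and compared with the two-group logrank test, both implemented
from first principles in this package (the analysis is the point, so it
should not be a black box): censoring tied with an event at the same
time is handled events-first, the logrank variance is the hypergeometric
form with the $n-1$ denominator guard, and the p-value is the upper tail
of $\chi^2_1$. Sidedness is therefore two-sided by construction. The
implementation is checked against a frozen set of reference chi-squares
computed once with the survival package on fifty seeded cohorts, and its
operating characteristics (type-I error near 0.05, power above 0.8 at a
hazard ratio of 2 with 100 cases per group) are measured by simulation
in the test suite.

The expression screen computes, per panel gene, the Pearson correlation
between expression and the per-case CS over the inner join of case ids,
with the two-sided t-transform p-value. Tables are ranked by ascending
raw p (ties by descending $|r|$, then symbol); a Benjamini-Hochberg
column is added across the screened panel but no row is ever filtered —
the ranked table, including non-significant rows, is the deliverable.
Correlations use linear expression values by default, with a
`log2(x + 1)` flag, because normalized expression is what the score is
plotted against; no normalisation of raw counts is attempted here.

## Candidate CDR3 recovery

`recover_cdr3s()` is a deliberately simplified stand-in for
recombination-read mining from exome or RNA-seq files, which in the
original setting is done by dedicated V/J-reference software against
controlled-access data. Here, each read is translated in six frames
(stop codons as `*`, N-containing codons as `X`) and scanned for the
immunogenetics convention: a CDR3 runs from a conserved cysteine to the
J-region phenylalanine/tryptophan that starts an `[FW]G.G` anchor.
Anchors are scanned left to right; for the first anchor that admits one,
the span from the **rightmost** upstream C whose length falls in the
5-30 window is returned — the shortest plausible CDR3 for that anchor,
minimising inclusion of V-region sequence. Chain identity is metadata,
not inferred; outputs are labelled candidates. Precision and recall
against a real V/J aligner are unknown and out of scope.

## What the synthetic cohort emulates

A single seeded `cohort_spec()` drives four generators, each consuming
its own RNG substream (master seed plus a fixed offset), so generating
one table never shifts another. Defaults are the package's fixed study
conditions:

- **44 cases** — the size of a fragment-level survival cohort that
  splits 21/23 at the median; repertoires of 2-12 CDR3s of 8-20
  residues, reflecting the sparsity of exome-derived recoveries.
- **Repertoires**: first residue C, last F, interiors drawn from the 19
  non-cysteine residues with the charged residues (K, R, D, E, H)
  weighted by `charge_enrichment` (1 = uniform). Interior cysteines are
  excluded and draws that would form a second J-anchor motif are
  redrawn, so the motif convention stays invertible: a simulated CDR3
  embedded in a read is recovered exactly, which is what makes a 100%
  round-trip sensitivity check meaningful. Real repertoires contain rare
  internal cysteines and anchor-like interior motifs; a real mining tool
  handles them with V/J references, and passing the round trip here says
  nothing about that harder problem. No V(D)J generative model or
  sequencing-error model is attempted.
- **Survival**: exponential event times at `baseline_hazard` (0.05 per
  month, median ~14 months in the lower group) times `hazard_ratio`
  (2.5) for the upper-CS group, uniformly censored on (0, 60] months.
  The hazard depends on the dichotomised group, not the continuous
  score, mirroring exactly the median-split analysis the pipeline runs —
  logrank power on this generator is therefore directly interpretable.
- **Expression**: gene value = `max(0, offset + beta * z + noise)` with
  `z` the standardized CS. The default six-gene panel couples two genes
  positively and four negatively with `|beta|` 0.9-1.15 against noise sd
  2, putting population correlations at 0.41-0.50 in magnitude — the
  band reported by small-cohort immune-marker screens. Clipping at zero
  honors nonnegative normalized expression; with offset 10 it is
  negligible (below 10^-5 per draw).

What passing tests on this generator shows: the pipeline's statistics do
what they claim on data with the assumed structure. What it does not
show: anything about batch effects, non-exponential hazards, nonlinear
expression coupling, repertoire sharing across cases, or the fidelity of
candidate CDR3s from real reads.

## Numerical and degenerate-input choices

- Scores are plain double sums; with default weights they are exactly
  representable, and no tolerance is needed in equality tests.
- `stratify_median()` refuses cohorts under 4 cases and cohorts where no
  score exceeds the median (no stratification exists); duplicate case
  ids are an error, not a silent collapse.
- `logrank_test()` refuses event-free inputs; a zero variance (possible
  only in degenerate tie patterns) yields a zero statistic rather than
  0/0.
- `pearson_cor()` refuses n < 3 and zero-variance inputs; constant
  expression columns are skipped with a warning by the screen, never
  silently dropped.
- Nonstandard residues (B, J, O, U, X, Z, `*`) are rejected with the
  offending character and position, not zero-charged: silent coercion
  would mask upstream parsing bugs.
- All file writers are deterministic; two runs from one seed produce
  byte-identical tables, which the test suite asserts.

## Problem sizes used by the test suite

Simulation-based checks use 200 replicates for test size, power and
sign-recovery properties, 100 replicates for the KM ordering property,
1000 random pairs for brute-force score equivalence, and cohorts of
44-200 cases elsewhere; these sizes give the binomial margins quoted in
the tests while keeping the default suite under a minute of simulation
time.

## Known limitations

- The score is charge-only and alignment-gapless; it ranks candidates,
  it does not predict binding.
- The recovery module's convention-based extraction cannot match
  V/J-reference mining and is not meant to.
- The logrank implementation is the standard two-group test; no
  stratified or weighted variants, no Cox modelling, no competing risks.
- The synthetic generator's realism is limited by design (see above);
  conclusions about real cohorts require real data.
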