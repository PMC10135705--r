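# tcrcs

Electrostatic complementarity scoring of T-cell receptor CDR3s against
tumor antigens, with the downstream survival and expression analyses that
turn the scores into cohort-level results.

## The problem

Tumor-resident T cells leave their receptor sequences in bulk sequencing
data: reads spanning a rearranged V(D)J junction encode the CDR3, the
hypervariable loop that contacts antigen. Whether those receptors could
engage a tumor antigen of interest — for example a cancer-testis antigen
aberrantly expressed by glioblastoma — cannot be measured directly at
cohort scale, but it can be approximated chemically: a CDR3 whose charged
residues line up oppositely to the charged residues of an antigen peptide
is a better electrostatic match than one that does not. This package
computes that charge-complementarity score (CS) and carries it through
the analyses a cohort study needs:

- **Scoring** (`pair_score`, `score_matrix`): slide the shorter peptide
  along the longer; at each register sum `-q_i * q_j` charge products
  (opposite charges add, like charges subtract) with weight 1 for the
  directly opposed antigen residue and 0.5 for each immediate neighbour;
  report the best register. Charges default to K/R = +1, D/E = -1,
  H = +0.5, all else 0, and are configurable.
- **Fragment sweep** (`fragment_protein`): split an antigen into k
  near-equal segments (lengths differ by at most 1) to localise which
  part of the protein drives an association.
- **Cohort aggregation and median split** (`score_cohort`,
  `stratify_median`): one CS per case (max over its CDR3s by default),
  then upper vs lower 50th-percentile groups, ties falling to the lower
  group.
- **Survival** (`km_estimate`, `logrank_test`): Kaplan-Meier
  product-limit curves per group and the two-group logrank test,
  implemented from first principles.
- **Expression screen** (`correlation_screen`): Pearson correlation of
  each gene in a panel with the per-case CS, with two-sided t-based
  p-values and a Benjamini-Hochberg column, ranked by p.
- **Candidate CDR3 recovery** (`recover_cdr3s`): a simplified
  motif-based extractor (conserved C through the J-region F/W of the
  FGXG anchor) that pulls candidate CDR3s out of raw reads via six-frame
  translation. It is a convention-based stand-in, not a V/J reference
  aligner.
- **Synthetic cohorts** (`cohort_spec`, `simulate_*`): fully seeded
  generators for repertoires, group-dependent survival, score-coupled
  expression and CDR3-embedding reads, so the whole pipeline runs and is
  tested without controlled-access patient data.

## Worked example

```r
library(tcrcs)

# one CDR3 against the benchmark 60-mer antigen fragment
pair_score("CASSIRSSYEQYF", spag9_fragment6()$sequence)
#> [1] 1.5
pair_score("CAKKRDEF", spag9_fragment6()$sequence)   # more charged CDR3
#> [1] 4

# a fully synthetic 44-case cohort, end to end
spec <- cohort_spec(seed = 1)
res <- run_pipeline(spec, config = run_config(log_level = "quiet"))

res$survival$stratification
#> Median-split cohort stratification
#>   threshold (median CS): 3
#>   upper group: 20 cases
#>   lower group: 24 cases

res$survival$logrank
#> Two-group logrank test
#>        n observed expected
#> lower 24       16   24.651
#> upper 20       17    8.349
#> chi-square = 14.5139 on 1 df, p = 0.0001391

head(res$correlation$correlations, 3)
#>      gene          r            p        p_adj  n
#> 1 COX7A2L -0.6002844 1.652710e-05 5.006601e-05 44
#> 2   AIFM3 -0.5988674 1.751087e-05 5.006601e-05 44
#> 3    CD19 -0.5899570 2.503300e-05 5.006601e-05 44
```

The logrank table reads: the 20 upper-CS cases suffered 17 events where
only 8.3 were expected under equal hazards, so the high-complementarity
group progresses faster (here by construction — the generator plants a
2.5-fold hazard ratio). The screen recovers the planted couplings: genes
simulated with negative coupling to the CS rank with negative `r`,
positive ones with positive `r`.

A command-line surface over the same functions is installed at
`system.file("cli", "tcrcs.R", package = "tcrcs")` with subcommands
`recover`, `fragment`, `score`, `stratify`, `survival`, `correlate`,
`simulate` and `pipeline`.

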