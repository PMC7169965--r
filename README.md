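# prionfam

Quantifying the conservation of prion-like composition and RNA-binding
domain architecture across protein ortholog families.

## The problem

Several RNA-binding proteins — the budding-yeast stress-granule protein
Pub1 and its human co-ortholog Tia1, and the related Nam8/Ngr1 family —
combine a scaffold of RRM (RNA recognition motif) domains with
intrinsically disordered, N/Q-rich regions of *prion-like* composition.
Asking how deeply that architecture is conserved across eukaryotes
requires a reproducible pipeline that can, for every protein in an
ortholog family:

1. score its composition for prion-like character,
2. locate its most compositionally biased Q/N subsequence,
3. consolidate curated and homology-derived domain annotations,
4. split it into inter-domain fragments and count how many of them are
   independently prion-like, and
5. aggregate the per-protein annotations into family-level statistics.

`prionfam` implements that pipeline as a tidyverse-style R package:
every user-facing function takes a data frame and returns a tibble, so
stages chain with the pipe.

## The models

**Prion-like LLR.** A two-state composition model with amino-acid
frequency tables *f*<sub>P</sub> (prion-like state, strongly N/Q-enriched)
and *f*<sub>B</sub> (background). Each residue *a* contributes
log(*f*<sub>P</sub>(*a*) / *f*<sub>B</sub>(*a*)); the score of a candidate
region is the summed per-residue LLR plus the transition log-odds of
entering, staying in, and leaving the prion-like state relative to the
all-background parse. `map_parse_llr()` finds the best single contiguous
run of length ≥ *c* (core length, default 60 residues); two decision
thresholds are used throughout: LLR > 0.0 (any prion-like propensity,
strict) and LLR ≥ 15.0 (strong, inclusive). `core_window_score()` is the
auxiliary fixed-window variant. All tables, the log base and *c* are
data, shipped as `inst/extdata/prion_score_params.tsv`.

**Compositional bias.** For residue sets {Q}, {N} and pooled {Q,N},
`scan_lowest_p()` finds the subsequence minimising the binomial
upper-tail probability P(X ≥ x) of seeing x target residues in a window
of n at expected frequency 0.05 per residue (0.10 pooled); window
lengths 15–500. `best_of_qn()` keeps the most biased of the three, and
log10 of its P-value is the per-protein bias statistic.

**Architecture.** `reduce_overlaps()` resolves overlapping domain
annotations greedily (longest first); `fragment_decompose()` splits a
sequence at the kept domains into N-terminal / internal / C-terminal
fragments, each extended 10 residues into the flanking domains; scoring
the fragments and counting threshold passes per protein yields the
multi-prion-domain statistics.

**Homology filters.** `rbh_pairs()` (reciprocal unique best hits by
bitscore), `cross_reference()` (reference-proteome membership), and
`paralog_sieve()` (candidate paralogs whose best qualifying self-proteome
hit, e ≤ 1e-4 and > 50% query coverage, prefers the Pub1/Nam8 sets over
the Pab1 outgroup) all operate on outfmt-6-style tabular hits.

A synthetic ortholog-family generator (`family_spec()`,
`generate_family()`, `generate_hit_table()`) plants domains, N/Q tracts
and hit-table scenarios with recorded ground truth, so every stage is
testable without external downloads.

## Worked example

```r
library(prionfam)
library(dplyr)

fam <- generate_family(family_spec(n_sequences = 20, seed = 3))
domains <- fam$truth |>
  filter(feature_type == "domain") |>
  transmute(seq_id, start, end, kind = "RRM", source = "curated")

rows <- annotate_family(fam$records, domains)
summarize_family(rows)
```

```
<family_summary> over 20 proteins

# A tibble: 2 x 9
  group         n fraction_gt0 fraction_ge15 fraction_multi_at_0
  <chr>     <int>        <dbl>         <dbl>               <dbl>
1 overall      20            1             1                   0
2 Pub1/Tia1    20            1             1                   0
# i 4 more variables: fraction_multi_at_15 <dbl>,
#   fraction_internal_extra <dbl>, fraction_rrm3 <dbl>, n_rrm_gt3 <int>

LLR vs compositional bias (-log10 P): r = 0.951  p = 1.33e-10  n = 20
```

Every generated protein carries one planted N/Q tract (Q+N fraction 0.7,
60 residues) and three RRM-like domains, so all 20 pass both LLR
thresholds, none has multiple prion-like fragments, and the run-parse
LLR correlates strongly (r = 0.95) with the binomial bias statistic —
the two composition measures agree on the same planted signal.
`plot_llr_distribution()`, `plot_disorder_vs_llr()`, `plot_rrm_counts()`
and `autoplot()` on a `family_summary` draw the standard figures.

## Scope notes

Multiple-sequence alignment, tree inference and disorder prediction are
out of scope: trees are consumed as Newick (`prune_clade()`), and
per-protein disorder percentages are consumed as input columns. See the
methods vignette (`vignettes/prionfam-methods.Rmd`) for the model
details, parameter choices and limitations.
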