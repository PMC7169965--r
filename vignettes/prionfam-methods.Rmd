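---
title: "Models and methods behind prionfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prionfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prionfam)
library(dplyr)
```

`prionfam` measures how strongly protein sequences in an ortholog family
conserve prion-like (N/Q-rich) composition alongside an RRM-domain
scaffold. This vignette explains the models, the parameters that matter,
the synthetic-data generator used for validation, and the numerical
choices — in enough detail that a reader can judge what a passing test
suite does and does not demonstrate.

## The two-state composition model

The prion-like scorer is a two-state model over amino-acid composition.
State P ("prion-like") emits residue $a$ with frequency $f_P(a)$; state B
("background") with $f_B(a)$. A residue's log-likelihood ratio is

$$\mathrm{llr}(a) = \log \frac{f_P(a)}{f_B(a)},$$

and the score of a candidate region $[i, j]$ in a sequence of length $n$
is its summed per-residue LLR plus the transition log-odds of the parse
with one prion run against the all-background parse:

$$S(i,j) = \sum_{k=i}^{j} \mathrm{llr}(x_k)
  + (j-i)\,\log\frac{a_{PP}}{a_{BB}}
  + [i>1]\,\log\frac{a_{BP}}{a_{BB}}
  + [j<n]\,\log\frac{a_{PB}}{a_{BB}},$$

with self-transition probabilities $a_{PP} = 1 - 1/L_P$,
$a_{BB} = 1 - 1/L_B$ parameterised by expected run lengths $L_P$, $L_B$.
`map_parse_llr()` maximises $S$ over all runs of length at least the core
length $c$ with an $O(n)$ prefix-sum recursion, then recovers the
attaining interval with the documented tie-break (leftmost start, then
shortest). With the default $L_P = L_B = 100$ the stay terms cancel and
a run that does not touch a sequence end pays a constant
$2\log\!\big((1/100)/(99/100)\big) \approx -9.19$ entry/exit penalty;
runs at the termini pay half. `core_window_score()` is the simpler
fixed-window variant (best window of exactly $c$ residues), kept because
the two scores bracket the behaviour of composition scanners in this
field and the window score is the natural monotonicity test bed.

### Parameters and defaults

Everything is table-driven (`score_params()`, shipped default in
`inst/extdata/prion_score_params.tsv`):

* `f_prion` — N/Q-enriched state table modelled on the composition of
  experimentally characterised yeast prion-forming domains
  (Q ≈ 0.21, N ≈ 0.23).
* `f_background` — budding-yeast-like proteome composition.
* `log_base` — natural log by default; every reported LLR scales by
  $1/\log(\text{base})$.
* `core_length` $c = 60$ residues: the shortest region the scorer will
  call, matching the scale of characterised prion-forming cores. Regions
  and whole sequences shorter than $c$ receive a "no domain" sentinel
  (`NA` score, both threshold flags `FALSE`) rather than an error or a
  truncated-window score, which keeps per-fragment counting
  architecture-determined.
* decision thresholds: LLR > 0.0 (strict; any prion-like propensity) and
  LLR ≥ 15.0 (inclusive; chosen in the source analyses because the
  weakest experimentally supported fungal prion-forming domain scores
  near 16).

Frequency tables are validated on load: each must sum to 1 (±0.05 before
normalisation), entries are floored at $10^{-6}$ and renormalised, so no
residue ever has zero likelihood in either state. Ambiguity codes X, B,
Z and U score exactly 0 and never terminate a run — neutral treatment
avoids crashes on real UniProt sequences while leaving scores unchanged.
Input is case-insensitive; `*` stop characters are stripped with a
warning.

## The compositional-bias scanner

Independently of the LLR model, `scan_lowest_p()` quantifies bias for a
residue set $R$ as the minimum over subsequences of the binomial upper
tail $P(X \ge x)$ with $X \sim \mathrm{Bin}(n, p)$, where $x$ counts
residues of $R$ in a window of length $n$ and $p$ is the expected
per-residue frequency — 0.05 for Q and for N, and the sum (0.10) for the
pooled set {Q,N}, consistent with treating the two expectations as
additive. Window lengths run 15–500 (clipped to the sequence), the scan
is exhaustive, and the tail probability is computed in log space via
`stats::pbinom(log.p = TRUE)`, exact at $x = 0$ by construction.
`best_of_qn()` takes the minimum over {Q}, {N}, {Q,N}, preferring the
pooled set on ties. No multiple-testing correction is applied across
windows: the statistic of record is the raw minimal $\log_{10} P$, which
is how such bias values are used as annotation rings downstream.

## Domain architecture and fragment counting

Domain annotations are 1-based inclusive intervals (Pfam/InterPro
convention) with a `kind` (RRM/other) and `source` (curated/homology).
`extend_annotations()` turns similarity hits against an RRM library with
e-value ≤ 1e-4 (inclusive) into homology-source intervals.
`reduce_overlaps()` then applies the greedy rule: sort by decreasing
length and keep an interval only if it shares no residue with anything
already kept on that sequence. Overlap means ≥ 1 shared residue — the
strictest reading. Length ties break by earlier start, then curated
before homology, then input order; this makes the output deterministic
and, as the tests verify, idempotent.

`fragment_decompose()` emits one fragment per inter-domain gap plus the
two termini, each extended `buffer = 10` residues *into* the flanking
domains (domain edge annotations are frequently imprecise, so the buffer
recovers tract residues clipped by a slightly-too-wide domain call); a
zero-length gap between adjacent domains still yields a
$2 \times \text{buffer}$ fragment straddling the junction. Fragments are
classed `n_terminal` / `internal` / `c_terminal`; internal means flanked
by kept domains on both sides. Counting fragments that pass each LLR
threshold gives the per-protein multi-prion-domain statistics; the
internal share of *extra* (beyond-first) prion-like regions caps each
protein's internal contribution at its extra count, so the share is a
true fraction even when both of a protein's prion-like fragments are
internal.

## Homology filters

`rbh_pairs()` demands mutual *unique* best hits by bitscore; a tied top
bitscore disqualifies the query rather than resolving arbitrarily.
`paralog_sieve()` operationalises "matches a Pub1/Tia1 or Nam8/Ngr1
sequence in preference to a Pab1 sequence" as a best-hit comparison by
bitscore (e-value as tie-break, unresolved ties excluded) among
qualifying hits (e ≤ 1e-4 inclusive, query coverage strictly > 0.5).
Bitscore is used for preference because it is database-size independent;
coverage is computed on the candidate (query) sequence, the reading most
consistent with "majority of a proteome sequence". Similarity searching
itself is out of process: the filters consume outfmt-6-style tables, so
any search engine can produce production inputs and tests use fabricated
tables with known answers.

## Family summaries and trees

`threshold_fractions()`, `multi_prion_fraction()` and
`rrm_distribution()` are exact counts with display percentages rounded
to whole numbers (machine-readable fractions keep full precision).
`pearson_r()` wraps the product-moment correlation with the two-tailed
t-transform p-value, dropping incomplete pairs pairwise and reporting
how many were dropped. `prune_clade()` removes a leaf set or the clade
under the most recent common ancestor of a label set, collapsing unary
nodes so path lengths among survivors are preserved (verified to 1e-9
in the tests). Clade membership for filtering is taken from explicit
columns in the annotation rows, not inferred from tree topology, which
keeps summaries reproducible independently of tree inference.

## The synthetic-data generator

`generate_family()` emulates the structure of a curated ortholog family:
each sequence is a chain of i.i.d. background linkers (default 60–120
residues, knowledgebase-average composition) and mutated copies of a
fixed 80-residue RRM-like consensus (default three copies — the
conserved scaffold; 10% per-site substitution), with N/Q tracts (default
one per sequence, 60 residues, Q+N fraction 0.7 — within the range of
characterised yeast prion domains) inserted into terminal and/or
internal linkers. Tract residues are Q/N with probability equal to the
target fraction and background-composition (Q/N excluded) otherwise, so
the expected tract Q+N fraction equals the target exactly. All
randomness flows from the single spec seed through one generator, and
the caller's RNG state is restored afterwards, so identical specs give
byte-identical FASTA output. Infeasible specs (more tracts than eligible
linkers, enrichment below the background Q+N level) error instead of
silently truncating.

What the generator deliberately does **not** emulate: phylogenetic
covariance (sequences are i.i.d. given the spec — no substitution model
or tree), length variation of domains, compositional drift between
clades, and annotation noise. Passing parameter-recovery tests therefore
demonstrates that the pipeline recovers *planted* signal under realistic
composition, not that it would resolve the subtler gradations of real
families; the filters' behaviour on real data additionally depends on
search-engine scoring, which is out of process.

`generate_hit_table()` fabricates the three tabular scenarios the
filters need — reciprocal-best-hit proteome pairs (with planted
asymmetric and tied-best negatives), paralog-sieve candidate tables (2
of every 5 candidates constructed as true preferrers, the rest failing
on preference, coverage or e-value), and domain-extension hits carrying
true planted coordinates with every third hit above the e-value
threshold — and attaches the expected downstream answer as an
attribute.

## Validation strategy and problem sizes

The test suite checks every scorer against an independent brute-force
oracle re-derived from first principles in the test helpers: exhaustive
window and run enumeration for the two LLR scores (sequences up to
200–300 residues), exhaustive start/length enumeration for the bias
scan, and direct term summation for the binomial tail ($n \le 50$).
Structural invariants run at scale: 1,000 random interval sets for
overlap-reduction idempotence and 1,000 random architectures for the
fragment tiling identity. Parameter recovery uses 100-sequence families
for tract detection (≥ 95% required at Q+N ≥ 0.7) and a 200-sequence
mixed family for recovering a planted 10% two-tract fraction within two
percentage points. The acceptance script runs two 150-protein families;
these sizes keep the whole validation run in the minutes range on one
CPU while leaving the statistical checks well-powered.

## Known limitations

* The shipped frequency tables are modelled on published yeast
  prion-domain and proteome compositions, not copied from any specific
  scanner's distribution; absolute LLR values will differ slightly from
  other tools even though the thresholds play the same role. Exact
  replication of another tool is a parameter-file question, not a code
  change.
* The run parse considers a single prion run per evaluation; proteins
  with several prion-like regions are handled by fragment decomposition
  rather than a multi-run parse, mirroring how the counting was defined.
* The bias scan's exhaustive window enumeration is $O(nW)$ per residue
  set; for proteome-scale inputs a pre-filter would be worthwhile, but
  family-scale inputs (hundreds of proteins) run in seconds to minutes.
* `paralog_sieve()` monotonicity in its thresholds holds when hit
  preference is stable across thresholds (as in the fabricated tables);
  adversarial tables where loosening a threshold flips the best hit to
  the outgroup can shrink the output, which is inherent to best-hit
  preference rules.

```{r example}
fam <- generate_family(family_spec(n_sequences = 10, seed = 42))
domains <- fam$truth |>
  filter(feature_type == "domain") |>
  transmute(seq_id, start, end, kind = "RRM", source = "curated")
rows <- annotate_family(fam$records, domains)
glance(summarize_family(rows))
```
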