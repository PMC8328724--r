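---
title: "Methods: paired fold-change deregulation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired fold-change deregulation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedDEP)
```

## The model and its assumptions

`pairedDEP` analyses label-free protein quantification from a paired
design: each animal is sampled at baseline (T0) and once more at an
endpoint (T50 or T90 minutes after LPS or vehicle), in four groups of six
animals (CT50, LPS50, CT90, LPS90), each sample measured in technical
duplicate. Pairing is the central assumption: between-animal abundance
variation — which in plasma spans orders of magnitude — cancels in the
within-animal ratio, so the per-animal statistic

$$\mathrm{log_2FC}(p, a) = \log_2 \frac{I(p, a, T_{end})}{I(p, a, T_0)}$$

needs no between-animal variance model. A protein is called deregulated
in a group when at least 4 of the 6 animals have
$\mathrm{log_2FC} \ge +1$ (up) or at least 4 have
$\mathrm{log_2FC} \le -1$ (down). This k-of-n count rule makes no
distributional assumption and is insensitive to single outlier animals;
its cost is a hard threshold with no graded evidence, which is why the
package reports the qualifying median and range alongside every call
rather than a p-value. The up and down tallies are counted
independently; at the defaults (4 of 6) they can never both pass, so no
tie-break is needed. Animals with a missing fold change count toward
neither tally and the denominator stays 6 — the rule is an absolute
count, not a proportion of observed animals, so missingness can only make
a call harder, never easier.

Before calling, intensities are normalized to a spiked internal standard
(yeast enolase 1, `P00924`, added in equal amount to every sample): each
sample column is divided by its spike intensity relative to the geometric
mean of the spike across samples. The geometric-mean reference makes the
result invariant to sample order and the operation idempotent; the
per-sample factors it removes are exactly the run-to-run instrument and
loading effects the spike is there to absorb. Rescaling any raw sample
column (spike included) therefore changes normalized values by at most
one global constant and leaves every between-sample ratio — and every
DEP call — unchanged.

## The filter funnel

Technical replicates are collapsed first, by the arithmetic mean of
observed replicate intensities on the raw scale (a collapsed cell is
missing only when all replicates are). Three protein-level filters
follow, each a pure row selection that emits a report row
(`n_before`, `n_after`, removed accessions), with the chain checked to be
gap-free:

| filter | rule | default |
|---|---|---|
| quantifiability | unique peptides ≥ `min_peptides` and score ≥ `min_score` | 2, 6 |
| missingness | ≤ `max_na_per_group` missing per (group, time point) cell of 6 animals | 2 |
| coverage | sequence coverage ≥ `min_coverage_pct` | 15 % |

All bounds are inclusive: a score of exactly 6 or coverage of exactly
15 % is retained, following the convention that proteins *below* the
cutoff are withdrawn (source descriptions of the coverage rule disagree
between "less than 15 % withdrawn" and "greater than 15 % kept"; this
package keeps ≥ 15 % and makes the bound configurable). The missingness
rule operates on the six animal-level columns of each (condition,
time point) cell after replicate collapsing, so "2 missing of 6" refers
to animals, not instrument runs. No imputation is performed anywhere:
with n = 6 and a count-based rule, imputed values could only manufacture
or destroy calls.

The two endpoints are filtered independently (they are separate
acquisition batches in the motivating design), so a protein can be
retained at one endpoint only. That is what makes the three-level
partition — common, T50-specific, T90-specific — non-trivial; the three
sets are disjoint by construction and their union is the set of all
retained proteins. Proteins called deregulated in a control group are
excluded from that endpoint's candidate list: such changes track the
procedure (anesthesia, cannulation, volume replacement, repeated
sampling), not the insult. Exclusion is applied per endpoint — the only
composable choice when endpoints are separate batches.

## Over-representation analysis

DEP sets are tested against a flat, user-supplied annotation (GMT). For
a term with $K$ members in a universe of $N$ proteins and a query of $n$
DEP containing $k$ members, the p-value is the hypergeometric upper tail
$P(X \ge k)$, identical to a one-sided Fisher exact test;
Benjamini-Hochberg adjustment is applied across tested terms, and terms
with fewer than 2 universe members are skipped. The universe is the set
of proteins surviving the filters at that endpoint, not the whole
proteome: plasma MS detection is strongly abundance-biased, and an
unconditioned background would report that bias as biology. Up- and
down-regulated sets are tested separately, since they answer different
questions. Network retrieval, graph clustering and ontology-DAG
reasoning are out of scope by design — the annotation is a flat table.

## The synthetic-data generator

`generate_dataset()` emulates the study conditions so that every stage
can be tested against ground truth: 4 groups × 6 animals × 2 time
points × 2 technical replicates (96 sample columns). Its components,
with defaults:

- **Baseline abundance**: per-protein mean log10 intensity uniform in
  [4, 8], per-animal deviation normal with sd 0.2 (log10) — the standard
  log-normal picture of label-free intensities.
- **Planted effects**: `floor(n_proteins × frac)` proteins per class.
  Up/down proteins change by exactly `± effect_log2fc` (default 2)
  between T0 and the endpoint in LPS groups; control-drift proteins
  (default fraction 0.02) change in every group and must be caught by
  control exclusion. Planted fold changes carry no biological noise:
  a planted protein's endpoint intensity is exactly $2^{\pm\Delta}$
  times its own baseline and a null protein's ratio is exactly 1, so
  with replicate noise disabled the recovered per-animal fold change
  equals the planted value to floating-point tolerance — the sharpest
  possible correctness check for the normalization–collapse–ratio path.
- **Per-sample scale factors**: log-uniform in [0.5, 2], applied to all
  proteins including the spike, forcing the normalization stage to
  matter.
- **Technical noise**: multiplicative log-normal, sd 0.05 in log10 per
  replicate.
- **Missingness**: overall rate `missing_rate` with probability
  proportional to `plogis(-mnar_strength · z)` of the standardized log10
  intensity — low-abundance dropout dominates plasma MS data. The spike
  is never missing and never planted.
- **Metadata**: planted proteins are always emitted quantifiable
  (≥ 2 peptides, score ≥ 6, coverage ≥ 15 %), so recovery tests probe
  the caller rather than the filters; 10 % of null proteins get
  low-evidence metadata so the filters have genuine work.

What the generator does *not* emulate: peptide-level identification,
retention-time structure, interference and ratio compression, batch
drift within a run, and realistic biological within-animal variability.
Passing tests on synthetic data therefore demonstrate the correctness of
the pipeline's logic under its own assumptions, not the sensitivity or
specificity to be expected on real plasma data, where fold-change noise
near the ±1 threshold will dominate error rates.

## Packaged fixtures

`make_fixtures()` transcribes published per-protein DEP summaries
(accession, gene, qualifying median, range, n of 6, direction, analysis
level — 43 rows) and reconstructs for each row a deterministic
six-animal fold-change vector: the printed range endpoints, the
remaining qualifying entries set to the printed median (exact median for
odd n, symmetric pair for even n), and zeros for the non-qualifying
animals. Re-calling these vectors reproduces every row's direction and
qualifying count, and the endpoint totals (10 and 33). In the source
tables the n-of-6 column is printed only when it changes; blank cells
inherit the value above. Two rows print internally inconsistent signs
(a median opposite in sign to its range); they are transcribed as
printed, flagged `sign_consistent = FALSE`, built from magnitudes with
their section's direction, and excluded from sign-reproduction checks.
One further row prints a median outside its own range; direction and
count still reproduce, so it is flagged nowhere but excluded from
median-reproduction checks by the coherence condition.

## Numerical and design choices

- Zero intensity is treated as an observed value, distinct from missing;
  a zero inside a baseline/endpoint pair is an error rather than a
  silent drop, because it signals an upstream quantification problem.
- Summary ranges are reported in magnitude orientation (`min` closest to
  the threshold, `max` most extreme, both signed), matching how such
  tables are printed.
- Replicate collapsing uses the raw-scale arithmetic mean (configurable
  in principle; the log-scale mean differs negligibly at sd 0.05 and the
  raw mean matches how label-free software averages runs).
- Determinism: one seed drives the generator; `run_pipeline()` hashes
  its configuration into the manifest and contains no time stamps, so a
  rerun with the same inputs is bit-identical.
- Problem sizes in the test-suite simulations (60–400 proteins) were
  chosen as the smallest sizes at which every planted class is populated
  and group-level properties are non-degenerate.

## Known limitations

- The count rule provides no graded significance; borderline proteins
  (n = 3 of 6) are invisible rather than "suggestive".
- Control exclusion is binary: a protein slightly deregulated in
  controls and strongly in LPS is discarded.
- The ORA stand-in ignores term-term dependence and annotation
  redundancy; with a DAG-structured ontology, parent terms will echo
  their children.
- With six animals the missingness filter's "at most 2 NA" bound means
  calls can rest on 4 observed animals — the rule's minimum — so single
  corrupted measurements can flip borderline calls.
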