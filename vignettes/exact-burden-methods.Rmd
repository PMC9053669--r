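---
title: "Exact burden inference for rare CNVs over miRNA target genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact burden inference for rare CNVs over miRNA target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirCNVburden)
```

## Scientific setting

Individuals with 22q11.2 deletion syndrome carry a strongly elevated risk of
schizophrenia, and one hypothesis for the incomplete penetrance is that
*additional* rare copy number variants (CNVs) elsewhere in the genome modify
risk — in particular CNVs that disturb genes under microRNA (miRNA)
regulation, since the 22q11.2 deletion itself removes *DGCR8*, a core
component of miRNA biogenesis. The package implements the full analysis that
this design calls for:

1. build a high-confidence catalog of experimentally supported miRNA target
   genes (`filter_interactions()`, `restrict_to_conserved()`),
2. call per-individual **carrier status** — does an individual have at least
   one qualifying rare CNV overlapping at least one catalog gene
   (`overlap_genes()`, `carrier_indicator()`),
3. compare carrier proportions between cases and controls with an **exact
   2×2 engine** (`exact_test_2x2()`) and a covariate-adjusted logistic model
   (`fit_logistic_burden()`),
4. ask *which gene sets* (`self_contained_enrichment()`,
   `competitive_enrichment()`) and *which miRNAs* (`classify_mirnas()`,
   `test_broad()`, `test_exclusive()`) drive the signal, and
5. generate fully synthetic cohorts with known ground truth so each stage is
   testable without individual-level data (`generate_cohort()`,
   `fixture_from_table()`).

The hemizygous 22q11.2 deletion itself is a constant across such a cohort
and plays no computational role here; the unit of analysis is the
*additional* rare CNV.

## The exact 2×2 engine

All primary comparisons reduce to a 2×2 table

|          | carrier | non-carrier |
|----------|---------|-------------|
| cases    | a       | b           |
| controls | c       | d           |

Conditioning on both margins, the count `A` in the case/carrier cell follows
the noncentral hypergeometric distribution with odds-ratio parameter
$\psi$:

$$P(A = x \mid \psi) \;=\;
\frac{\binom{m}{x}\binom{n}{k-x}\,\psi^{x}}
     {\sum_{u=\ell}^{h}\binom{m}{u}\binom{n}{k-u}\,\psi^{u}},$$

with $m = a+c$, $n = b+d$, $k = a+b$ and support
$\ell = \max(0, k-n) \le x \le h = \min(k, m)$.

* **Two-sided p-value** (`fisher_two_sided()`): the sum of central
  ($\psi = 1$) probabilities no larger than the observed one. Probabilities
  within a relative slack of `1e-7` of the observed probability count as
  ties and are included; without this slack, floating-point noise would make
  the p-value discontinuous in the cell counts for tables whose two tails
  contain numerically equal terms.
* **Conditional-MLE odds ratio** (`odds_ratio_cmle()`): the $\psi$ solving
  $E[A \mid \psi] = a$. The expectation is strictly increasing in
  $\log\psi$, so the root is found by bisection on the log scale over the
  bracket $[10^{-12}, 10^{12}]$ with 200 iterations — enough to drive the
  bracket below double-precision resolution regardless of scale, and free of
  the derivative pathologies a Newton step can hit far from the root. Tables
  with $a = \ell$ return 0, tables with $a = h$ return `Inf`, and
  single-point supports return `NA` with a warning (the odds ratio is not
  identified).
* **Exact confidence interval** (`odds_ratio_ci_exact()`): tail inversion at
  level $\alpha/2$ per side — the lower bound solves
  $P(A \ge a \mid \psi) = \alpha/2$, the upper bound solves
  $P(A \le a \mid \psi) = \alpha/2$. Zero cells yield the appropriate
  one-sided interval (bound 0 or `Inf`). The pmf is evaluated through
  log-space weights normalised by their maximum, so extreme $\psi$ never
  overflow.
* **Degenerate margins** (an empty row or column): the p-value is 1 by
  convention with a message, and the odds ratio is `NA` with a warning.
  These arise legitimately, e.g. when no individual in either group carries
  a qualifying CNV over a miRNA's targets.

A note on numerical agreement with other implementations: the widely used
reference implementation computes the same three quantities but stops its
optimiser at a much looser tolerance. For large upper confidence bounds the
discrepancy can reach a few parts per thousand and can flip the final
printed digit (e.g. an upper bound whose exact value is 15.5955 may print
as 15.59 from the looser optimiser and as 15.60 here). The package's own
tests therefore validate against a high-precision independent root-finder
and treat the reference implementation only as a sanity oracle on the log
scale.

`bh_fdr()` applies Benjamini–Hochberg adjustment *within declared test
families*; every function that performs multiple tests records the family it
adjusted over (e.g. `fdr_family_size` in `test_broad()`).

## Interval conventions

Internally all genomic intervals are **0-based half-open**; two intervals
overlap when `max(start1, start2) < min(end1, end2)`, i.e. they share at
least one base. GFF3 input is 1-based inclusive and converted on read
(`start - 1` at the lower boundary). Only autosomes are analysed, CNVs
shorter than 10 kb are dropped at ingest, and rarity (control-population
frequency below 0.1%) is *validated* on the input, not computed — frequency
estimation belongs to the upstream caller.

## Catalog construction

An interaction record survives `filter_interactions()` when it is human,
reports DOWN-regulation of the target, and the (miRNA, gene) pair is backed
by at least one low-throughput experiment **or** at least two distinct
high-throughput methods. `restrict_to_conserved()` then intersects with a
conservation list; the restriction is applied **per gene** (a conserved gene
keeps all of its surviving miRNA partners) because conservation annotations
are gene-level; a stricter per-pair mode is available via `per_pair = TRUE`.
`seed_filter_mouse()` admits mouse-derived evidence only when the mouse
miRNA's 6-mer seed (nucleotides 2–7) is identical to its human counterpart's.
Every filtering step records telescoping provenance counts so that the
catalog size is auditable.

## Enrichment and attribution

Two complementary enrichment views are computed:

* **Self-contained** (`self_contained_enrichment()`): individual-level — for
  each gene set, carrier status is recomputed against the catalog restricted
  to that set and tested with the exact engine (optionally with the adjusted
  logistic model). FDR families are the declared set *categories*.
* **Competitive** (`competitive_enrichment()`): gene-level — CNV-overlapped
  genes are split into four subgroups (case/control × target/non-target) and
  each subgroup is tested against a genome background with a one-sided
  hypergeometric tail. FDR families are subgroup × category, since the four
  subgroups ask distinct questions of distinct gene lists.

Attribution classifies every catalog miRNA by its carrier pattern:
**broadly targeting** (carriers in both groups; tested with the exact
engine, FDR across the whole broad family) versus **exclusively targeting**
(carriers in one group only). Exclusive miRNAs are only tested when their
carrier count reaches the *a-priori minimal count*
(`min_exclusive_count()`): the smallest count whose one-sided exclusive
table can possibly reach significance given the two group sizes — 4 for a
100-versus-118 design in the case direction, 6 in the control direction.
This pre-filter is part of the design, not a data-dependent choice, so the
exclusive FDR family contains exactly the tested miRNAs of one direction.

## The synthetic-cohort generator

`generate_cohort()` produces, from a single integer seed, a mutually
consistent set of artifacts: phenotypes, CNV calls, gene annotation (GFF3),
interaction records, a conservation list, a differential-expression miRNA
list, and gene sets — in exactly the dialects the readers consume. Defaults
(`generator_config()`) encode the cohort conditions the package was designed
around: 100 cases and 118 controls, female fractions 0.48/0.64, a baseline
carrier rate of 0.49 in controls with a carrier odds ratio of 2.3, CNV
lengths log-uniform between 10 kb and 2 Mb, and a Poisson CNV count per
individual. `solve_carrier_probs()` converts (base rate, odds ratio) into
the two group-wise carrier probabilities analytically, so the configured
odds ratio is the exact data-generating value — calibration tests then
verify that the pipeline recovers it.

Two deliberate design choices make ground truth *exactly* recoverable
rather than approximately: genes are laid out every 3 Mb with 50 kb bodies,
and each carrier CNV (at most 2 Mb) is anchored inside a gene body, so a
CNV can never straddle two genes; and carrier/non-carrier CNVs are placed so
that the intended carrier indicator equals what `overlap_genes()` +
`carrier_indicator()` compute. `fixture_from_table()` uses the same
machinery to realise an arbitrary 2×2 table as a full cohort, which is how
the package's reference values are recomputed end to end.

Scope and limits: the generator emulates the *statistical* structure
(margins, carrier mechanism, file dialects), not genome biology — there are
no CNV hotspots, no recombination model, no linkage between neighbouring
genes, and no simulation of the 22q11.2 deletion itself. Generation is
wrapped in `with_preserved_seed()`, so it never disturbs the caller's RNG
stream.

## Worked example

```{r}
fx <- fixture_from_table(69, 31, 58, 60)
carr <- carrier_indicator(fx$overlaps, fx$catalog, fx$cohort$sample_id)
exact_test_2x2(burden_table(fx$cohort, carr))
```

```{r}
run_subset_check(100, 158, 118, 171)
run_sex_check(counts = c(76, 42, 48, 52))
```

The full pipeline — catalog, overlap, burden, both enrichments, attribution,
result TSVs and a manifest with input digests — runs from one configuration
list via `run_all()`.
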