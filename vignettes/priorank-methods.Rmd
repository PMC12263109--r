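---
title: "Methods: phenotype-driven gene prioritization with black-box scorers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-driven gene prioritization with black-box scorers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorank)
```

## The setting

A patient with a suspected Mendelian disorder has clinical phenotypes
recorded as Human Phenotype Ontology (HPO) terms and an exome whose
variants have been annotated upstream. Variant filtering leaves a set of
candidate genes — typically 5 to 50 — among which exactly one (in resolved
cases) is causal. The prioritization task is to order the candidates so the
causal gene lands as close to rank 1 as possible. `priorank` treats the
scorer that judges gene–phenotype fit as a black box: in practice a large
language model queried with text prompts, in testing a fully deterministic
synthetic scorer.

## Candidate construction

`filter_variants()` keeps a variant if it satisfies **any** of three
criteria: population allele frequency strictly below 1%, a
pathogenic/likely-pathogenic clinical classification, or a splice-impact
(SpliceAI) score strictly above 0.8. Both numeric comparisons are strict —
a variant sitting exactly on a threshold fails that criterion — and an
absent splice score or classification fails its criterion, because absence
of evidence must never pass a filter. Genes are collapsed *after*
filtering: one qualifying variant suffices. All three thresholds are
arguments with these defaults.

`build_candidate_sets()` builds benchmark lists of sizes 5/25/50 around a
known causal gene: the noncausal portion is a uniform without-replacement
sample of the pool, the causal gene is inserted *before* the shuffle, so
its input position is uniform over list positions — the property the
positional-bias analysis relies on. The whole draw sits under one seed
(`withr::with_seed`), so a seed reproduces the lists byte for byte.

Phenotype terms are converted to text (`terms_to_text()`) before
prompting, preferring the term definition and falling back to the label,
because scorers hallucinate the meaning of raw ontology identifiers.
Duplicates collapse to first occurrence to keep prompts deterministic.

## Scoring backends

The scorer contract is one function: `scorer(genes, salt)` returning
per-gene scores in [0, 1] (or a `score_vector` carrying flags). The integer
`salt` distinguishes repeated queries on the same list — ensemble
iterations and divide-and-conquer rounds pass their round index — so a
stochastic backend can vary between calls while every run stays exactly
reproducible.

**Verbal scorers** reply in text; `parse_ranking_response()` is total:
every byte string yields a score vector. `SYMBOL: number` lines are
captured, out-of-range values are clamped to [0, 1] (replies are unreliable;
rejecting them would discard whole cases), genes missing from the reply
score 0 with a `missing_gene` flag, and a reply with no parseable line is a
`refusal` with all-zero scores. Scoring missing genes 0 rather than
re-prompting reproduces the degradation that missing solutions cause in
verbal evaluation, honestly, and keeps runs bounded; only a *truncated*
remote reply earns one re-prompt.

**Token-probability scorers** answer a single-gene yes/no prompt and
expose the probabilities of the "Yes" and "No" answer tokens. The gene's
score is the log-likelihood ratio

$$S(g_j) = \log\frac{\Pr(\text{Yes})}{\Pr(\text{No})},$$

with both probabilities floored at $10^{-12}$ first, since the ratio is
undefined at zero. Ranking by this score is equivalent to ranking by the
normalized yes-probability; the floor only matters when a backend reports
an exact zero.

**The remote adapter** (`remote_score_case()`) is a contract, not a
client: the transport function is injected, `NULL` by default, and raising
a typed error otherwise — the test suite exercises retries, mini-batching
(gene lists split into chunks, parsed vectors merged) and the
one-re-prompt truncation rule entirely with scripted transports. No test
or example ever opens a network connection.

**The synthetic scorer** is the package's controlled stand-in for a
language model. For gene $i$ at 1-based position $p_i$ in a presented list
of length $L$, with submission count $c_i$:

$$\text{score}_i = \operatorname{logistic}\!\big(b_0 + s\,[i\ \text{causal}]
  - \beta_{pos}\tfrac{p_i-1}{L-1} + \beta_{lit}\log(1+c_i)
  + \varepsilon_i\big),\qquad \varepsilon_i \sim N(0, \sigma^2).$$

The logistic link is the simplest monotone map onto (0, 1); the two bias
terms mirror the two failure modes documented for real scorers (later
positions penalized; heavily studied genes boosted). Noise is drawn from a
stream seeded by the parameter seed, the *sorted* gene set, and the call
salt, and is assigned to gene *identity*, not list position. Two
consequences matter: the scorer is exactly position-free when
$\beta_{pos}=0$ (permuting the input permutes the output with it), which
makes the aggregation identities below exact rather than approximate; and
identical calls return identical vectors.

Defaults, chosen once as the simulated study conditions: $b_0 = -1$ (a
noncausal, unboosted gene scores ≈ 0.27), $s = 2$ (a moderate causal
advantage, deliberately comparable to the $\beta_{pos} = 1.5$ bias span
used in the bias experiments so that positional bias visibly harms
single-shot ranking rather than being drowned out), $\sigma = 0.5$. The
bias experiments set $\beta_{pos} = 1.5$ with $\sigma = 0.5$, or
$\beta_{lit} \in \{0, 1\}$; the random-baseline experiment uses $s = 0$,
$\sigma = 1$ (any exchangeable continuous scorer yields uniform causal
ranks).

## Rank aggregation

**Ensemble ranking** (`ensemble_rank()`) averages `n_iter` full-list score
vectors; refusal iterations are dropped from the mean and counted, and a
case where every iteration refuses raises a classed error. Scores, not
ranks, are averaged (score averaging preserves the probability scale the
divide-and-conquer equation uses).

**Divide-and-conquer** (`dnc_rank()`) is the package's core: in each of
$N$ rounds the candidates are uniformly repartitioned into groups of
`group_size` (default 5), the scorer sees one group at a time with
positions renumbered from 1, and

$$S(g_j) = \frac{1}{N}\sum_{i=1}^{N} \Pr_i(g_j)$$

averages each gene's in-group probabilities. Showing the scorer only the
group — never the full list — is precisely what severs the link between a
gene's full-list position and its score. With 25 or 50 candidates and
groups of five this gives 5 or 10 groups per round.

Numerical/edge choices:

- *Remainder policy*: when `group_size` does not divide $n$, groups are
  balanced to differ by at most one (23 candidates at size 5 → sizes
  5,5,5,4,4); a strict policy that errors instead is available. Singleton
  groups never arise for $n \ge 2$.
- *Rounds* $N$ defaults to 5 and is exposed in `dnc_config()`; more rounds
  shrink the aggregation noise at linear cost.
- *Failures*: a scorer error or refusal in one round drops that round's
  observations for the affected genes (with a warning) rather than
  aborting the case; `n_observations` records coverage.
- *Ties*: `ranks_from_scores()` makes the tie rule explicit. The default
  `pessimistic` policy gives tied genes the worst rank of their block, so
  capture curves are lower bounds and ties can never inflate headline
  numbers; `stable` (input order) and `average` (fractional mean rank) are
  alternatives.

Two exact identities anchor the implementation and are enforced in tests:
with $N = 1$ and whole-list groups the final score equals the single
query's scores, and for any $N$ with whole-list groups it equals the plain
mean of $N$ full-list queries (the brute-force oracle), because the scorer
is position-free under $\beta_{pos} = 0$.

## Case classification

**Multi-agent**: an evaluator agent writes a ~100-word essay assessing all
candidates against the phenotypes; a summarizer agent reads the essay and
answers Yes/No on whether any gene is directly linked. Yes → `specific`,
No → `nonspecific`. The verdict is normalized aggressively (strip
non-letters, case-fold) but accepted only as an exact `yes`/`no`; one
retry, then `unevaluable`. Both agents are plain functions, so the
pipeline is deterministic under scripted agents.

**Dataset specificity index**: the structural alternative needs no scorer.
With shortest-path depths $d(t)$ (root = 0; in a DAG the shortest path is
the conservative choice under multiple parentage) and $D$ the ontology's
maximum depth,

$$\mathrm{DsI} = \frac{1}{|T|}\sum_{t \in T} \frac{d(t)}{D}
  \in [0, 1]$$

over the unique resolvable terms $T$: 0 when every term is the root, 1
when every term is a maximal-depth leaf. The published index this emulates
weights the full depth distribution and is defined in the publication of
the cohort-analysis tool it originates from; the depth mean is the
simplest function with the required
penalize-general / reward-specific behavior, and `dsi(index_fun = ...)`
accepts any replacement, so the published formula can be dropped in —
numeric agreement with it is *not* claimed. Cohorts are split at the
median (no published threshold exists): strictly above → `high_dsi`.

A limitation worth stating precisely: "replacing a term by an ancestor
never increases DsI" holds along a term's *shortest-path* parent and when
the ancestor is not already in the term set. In a DAG a term can have a
second, deeper parent (whose own shortest-path depth exceeds the term's),
and collapsing onto an ancestor already present shrinks the unique-term
set, either of which can raise the mean. The tests assert the guarded
form.

## Evaluation and bias analyses

The benchmark metric is the **capture curve**: the proportion of cases
whose causal gene ranks at or within each threshold $k = 1..K$ (default
$K = 10$); monotone and bounded by 1 by construction, both asserted at run
time. The **random baseline** is $k/n$, the probability a uniform ordering
lands the causal gene within rank $k$.

**Positional bias** regresses and correlates the causal gene's final rank
on its input position: per-position mean ranks, Spearman correlation
(primary — ranks are ordinal), and the descriptive least-squares slope.
**Literature bias** correlates rank with the causal gene's submission
count; the primary statistic uses $\log(1+c)$ given the counts' heavy
tail, with the raw-count correlation also reported. Degenerate inputs
(single position, zero count variance) raise errors rather than returning
`NA`; a constant rank vector reports zero correlation.

`compare_strategies()` runs strategies on the identical case set with
matched per-case seeds and reports aligned curves plus the number of cases
whose causal rank strictly improved over the first (baseline) strategy.

## The synthetic cohort and what passing tests show

`make_ontology()` builds a labeled random tree (optionally with
downward-safe cross-links for DAG testing): depth 4, branching 3 → 121
terms, the default fixture. `make_cohort()` emulates a multi-site
benchmark: named cohorts (default 3 × 90 = 270 patients) with one
`patient_case` per (patient, size ∈ {5, 25, 50}); high-specificity
patients draw terms from the deepest non-root depth quartile,
low-specificity from the shallowest, so the DsI machinery has real signal
to find. `make_counts()` draws log-normal submission counts (meanlog 2,
sdlog 1 — a heavy tail with a median around 7 and occasional hundreds,
qualitatively matching public submission-count distributions).

Simulation sizes used by the test suite and the acceptance script — 500
cases × 50 genes for bias mitigation, 400 for literature bias, 10,000
uniform-scorer cases for the baseline check — were chosen so Monte-Carlo
error is far below the effects being measured (e.g. the 2·SE band on a
Spearman coefficient at $n = 500$ is ±0.09 against an induced correlation
near 0.5).

What the generator does *not* emulate: real HPO semantics (terms are
random tree nodes, not clinically coherent phenotype profiles), genuine
gene–phenotype biology (causality is an injected logit bonus), scorer
pathologies beyond the three modeled axes (no prompt-format sensitivity,
no inter-gene interactions in a group), and clinical cohort structure
(site difficulty is a signal/specificity dial, not case-history modeling).
Passing tests therefore demonstrate that the *machinery* — filtering,
aggregation, bias measurement, mitigation — behaves as specified under
controlled conditions, not that any particular language model will achieve
a particular capture rate on real patients.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `af_max` | 0.01 | allele-frequency filter (strict `<`) |
| `splice_min` | 0.8 | splice-score filter (strict `>`) |
| `group_size` | 5 | divide-and-conquer group size |
| `n_rounds` (N) | 5 | repartition rounds averaged |
| `n_iter` | 5 | ensemble iterations |
| tie policy | pessimistic | worst rank in tie block |
| `signal` | 2 | synthetic causal boost (logits) |
| `intercept` | −1 | synthetic baseline logit |
| `noise_sd` | 0.5 | synthetic logit noise |
| `llr` floor | 1e−12 | token-probability floor |
| DsI split | median | strictly above → high |
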