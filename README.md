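# priorank

Phenotype-driven candidate gene prioritization with pluggable black-box
scorers.

## The problem

Rare Mendelian disorders are diagnosed by finding the one causal gene among
the candidates that survive variant-level filtering of a patient's exome —
typically a handful to ~50 genes, each supported by a rare, predicted
pathogenic, or splice-disrupting variant. Large language models can score
how well each candidate matches the patient's clinical phenotypes (Human
Phenotype Ontology terms), but they degrade on long option lists and carry
two systematic biases: genes presented **later in the prompt** are ranked
worse (positional bias), and genes with heavy database/literature
representation are ranked better regardless of the phenotype (literature
bias).

`priorank` implements the full workflow around any such scorer, treated as
a black box:

- **Candidate construction** — variant filtering by the disjunction
  *AF < 1%* ∨ *pathogenic/likely pathogenic* ∨ *SpliceAI > 0.8*
  (`filter_variants()`), and shuffled candidate sets of sizes 5/25/50 with
  the causal gene hidden at a uniformly random position
  (`build_candidate_sets()`).
- **Prompting and parsing** — HPO-term-to-text conversion over an OBO
  ontology (`read_obo()`, `terms_to_text()`), deterministic ranking and
  yes/no prompts, and a total parser for verbal replies
  (`parse_ranking_response()`) with missing-gene and refusal flags.
- **Token LLR ranking** — for backends that expose answer-token
  probabilities, genes are ordered by the log-likelihood ratio
  `S(g_j) = log(Pr(Yes) / Pr(No))` (`llr_score()`).
- **Divide-and-conquer aggregation** — the core mitigation for long lists:
  in each of `N` rounds the candidates are randomly repartitioned into
  groups of five, the scorer sees one group at a time, and each gene's
  final score is the mean of its in-group probabilities,
  `S(g_j) = (1/N) Σᵢ Prᵢ(g_j)` (`dnc_rank()`). Because a gene's within-group
  position is independent of its full-list position, positional bias cannot
  reach the final score.
- **Case classification** — a two-agent evaluator/summarizer pipeline
  (`multi_agent_classify()`) and the dataset specificity index, the mean
  relative ontology depth of a case's phenotype terms (`dsi()`,
  `split_by_dsi()`), for stratifying cases by expected solvability.
- **Evaluation and bias diagnostics** — causal-gene capture curves with the
  `k/n` random baseline (`capture_curve()`, `random_baseline()`), and
  Spearman-based positional / literature bias analyses
  (`positional_bias()`, `literature_bias()`).
- **Synthetic cohorts** — a simulator (`make_ontology()`, `make_cohort()`,
  `make_counts()`) plus a deterministic scorer with injectable causal
  signal, positional penalty, and literature boost
  (`synthetic_scorer()`), so every claim above is testable offline.

## Worked example

Simulate 100 patients with 50 candidates each, score them with a
positionally biased synthetic scorer (penalty 1.5 logits across the list,
noise 0.5), and compare single-shot full-list ranking against
divide-and-conquer (groups of 5, N = 5 rounds):

```r
library(priorank)

ont    <- make_ontology(depth = 4, branching = 3, seed = 1)
cohort <- make_cohort(cohort_spec(cohorts = c(SIM = 100L), sizes = 50L,
                                  seed = 20), ont)

params  <- synthetic_scorer_params(beta_pos = 1.5, noise_sd = 0.5, seed = 20)
factory <- function(cs) synthetic_scorer(params, cs$causal_gene)

cmp <- compare_strategies(cohort$cases, factory, c("single", "dnc"),
                          group_size = 5, n_rounds = 5, seed = 20)
subset(cmp$curves, k %in% c(1, 5, 10))
#>    strategy  k proportion
#> 1    single  1       0.76
#> 5    single  5       0.96
#> 10   single 10       0.97
#> 11      dnc  1       1.00
#> 15      dnc  5       1.00
#> 20      dnc 10       1.00

positional_bias(cmp$outcomes$single)$spearman  # 0.493
positional_bias(cmp$outcomes$dnc)$spearman     # 0
cmp$improved[["dnc"]]                          # 24 cases strictly improved
```

Read: single-shot ranking places the causal gene first in 76% of cases and
its rank correlates strongly with where the gene sat in the prompt
(Spearman 0.49); divide-and-conquer removes the positional correlation
entirely and lifts rank-1 capture to 100% on this synthetic cohort, with 24
of 100 cases strictly improving. A capture proportion at threshold k is the
fraction of cases whose causal gene ranks at or within k; a random guess
achieves `k/n` (`random_baseline(50, 1)` = 0.02).

A command-line front end for the same workflow is in
`inst/cli/priorank.R` (subcommands `simulate`, `cases-build`, `rank`,
`classify`, `evaluate`, `bias`).

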