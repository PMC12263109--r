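# Benchmark harness: run a strategy over a cohort, collect per-case
# outcomes (where did the causal gene land?), and diagnose positional and
# literature biases.

#' Rank one case under a ranking strategy
#'
#' @param case A [patient_case()].
#' @param scorer Scorer function (see [synthetic_scorer()]).
#' @param strategy `"single"` (one full-list query), `"ensemble"` (averaged
#'   full-list queries) or `"dnc"` (divide-and-conquer).
#' @param config A [dnc_config()]; its seed also drives the strategy's
#'   partition stream.
#' @param n_iter Ensemble iterations (strategy `"ensemble"`).
#' @param tie_policy Passed to [ranks_from_scores()].
#' @return A `rank_table` data frame (gene, score, rank).
#' @export
run_case <- function(case, scorer, strategy = c("single", "ensemble", "dnc"),
                     config = dnc_config(), n_iter = 5L,
                     tie_policy = "pessimistic") {
  strategy <- match.arg(strategy)
  fs <- switch(strategy,
    single = ensemble_rank(case, scorer, n_iter = 1L),
    ensemble = ensemble_rank(case, scorer, n_iter = n_iter),
    dnc = dnc_rank(case, scorer, config = config))
  ranks_from_scores(fs, tie_policy = tie_policy)
}

#' Evaluate a cohort and collect per-case outcomes
#'
#' Runs the chosen strategy over every case with a known causal gene and
#' records, per case: the causal gene's final rank, the candidate-list
#' length, the causal gene's 1-based position in the input list (the
#' quantity positional-bias analysis needs) and its submission count (the
#' quantity literature-bias analysis needs).
#'
#' @param cases List of [patient_case()] objects (each with a causal gene).
#' @param scorer_factory Function `(case) -> scorer` binding a scorer to a
#'   case's ground truth; see [synthetic_scorer()].
#' @param strategy,n_iter,tie_policy See [run_case()].
#' @param group_size,n_rounds Divide-and-conquer parameters.
#' @param counts Optional named numeric vector of per-gene submission
#'   counts; genes without an entry count 0.
#' @param seed Integer seed; each case gets an independent sub-seed.
#' @return Data frame of class `case_outcomes` with columns `case_id`,
#'   `causal_rank`, `n_candidates`, `causal_input_position`,
#'   `causal_submission_count`.
#' @export
run_cohort <- function(cases, scorer_factory,
                       strategy = c("single", "ensemble", "dnc"),
                       group_size = 5L, n_rounds = 5L, n_iter = 5L,
                       counts = NULL, seed = 1L,
                       tie_policy = "pessimistic") {
  strategy <- match.arg(strategy)
  stopifnot(is.function(scorer_factory), length(cases) >= 1L)
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    stopifnot(inherits(cs, "patient_case"))
    if (is.null(cs$causal_gene)) {
      stop("case ", cs$case_id, " has no causal gene; cannot evaluate",
           call. = FALSE)
    }
    cfg <- dnc_config(group_size = group_size, n_rounds = n_rounds,
                      seed = .mix_seed(seed, i))
    rt <- run_case(cs, scorer_factory(cs), strategy = strategy, config = cfg,
                   n_iter = n_iter, tie_policy = tie_policy)
    cnt <- if (is.null(counts)) 0 else {
      v <- counts[cs$causal_gene]
      if (is.na(v)) 0 else unname(v)
    }
    rows[[i]] <- data.frame(
      case_id = cs$case_id,
      causal_rank = rt$rank[rt$gene == cs$causal_gene],
      n_candidates = length(cs$candidate_genes),
      causal_input_position = match(cs$causal_gene, cs$candidate_genes),
      causal_submission_count = cnt,
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("case_outcomes", "data.frame"))
}

#' Causal-gene capture curve
#'
#' For each rank threshold k, the proportion of cases whose causal gene is
#' ranked at or within k: the cumulative number of causal genes captured at
#' rank <= k across all cases, divided by the number of cases. The curve is
#' nondecreasing in k and bounded by 1.
#'
#' @param outcomes A `case_outcomes` data frame (needs `causal_rank`).
#' @param max_rank Largest threshold K reported (default 10).
#' @return Data frame of class `capture_curve` with columns `k` (1..K) and
#'   `proportion`.
#' @examples
#' oc <- data.frame(causal_rank = c(1, 3, 11))
#' capture_curve(oc)$proportion[c(1, 3, 10)]  # 1/3, 2/3, 2/3
#' @export
capture_curve <- function(outcomes, max_rank = 10L) {
  if (NROW(outcomes) == 0L) stop("no outcomes to evaluate", call. = FALSE)
  stopifnot(all(outcomes$causal_rank >= 1))
  k <- seq_len(max_rank)
  prop <- vapply(k, function(kk) mean(outcomes$causal_rank <= kk), numeric(1))
  stopifnot(!is.unsorted(prop), max(prop) <= 1)  # definitional invariants
  structure(data.frame(k = k, proportion = prop),
            class = c("capture_curve", "data.frame"))
}

#' Random-guess capture baseline
#'
#' Probability that a uniformly random ordering places the causal gene at
#' or within rank k of an n-gene list: `k / n`.
#'
#' @param n_candidates List length n.
#' @param k Rank threshold(s), each in 1..n.
#' @return Numeric vector of probabilities.
#' @examples
#' random_baseline(50, 1)   # 0.02
#' random_baseline(50, 10)  # 0.2
#' @export
random_baseline <- function(n_candidates, k) {
  .assert_scalar_number(n_candidates, "n_candidates", lower = 1)
  if (any(k < 1 | k > n_candidates)) {
    stop("rank threshold k must lie in 1..n_candidates", call. = FALSE)
  }
  k / n_candidates
}

#' Positional-bias diagnostics
#'
#' Quantifies how the causal gene's rank depends on where it sat in the
#' input list: per-position mean ranks, the Spearman correlation between
#' input position and final rank (ranks are ordinal, so Spearman is the
#' primary statistic), and the descriptive least-squares slope of rank on
#' position. A positive correlation means genes presented later are ranked
#' worse.
#'
#' @param outcomes A `case_outcomes` data frame.
#' @return List of class `positional_bias` with `per_position` (data frame
#'   `position`, `mean_rank`, `n_cases`), `spearman`, `slope`, `slope_se`.
#' @export
positional_bias <- function(outcomes) {
  pos <- outcomes$causal_input_position
  rk <- outcomes$causal_rank
  if (length(unique(pos)) < 2L) {
    stop("positional bias undefined: fewer than two distinct input positions",
         call. = FALSE)
  }
  per_pos <- stats::aggregate(rk, by = list(position = pos),
                              FUN = function(x) c(mean(x), length(x)))
  per_position <- data.frame(position = per_pos$position,
                             mean_rank = per_pos$x[, 1],
                             n_cases = as.integer(per_pos$x[, 2]))
  fit <- stats::lm(rk ~ pos)
  coefs <- summary(fit)$coefficients
  slope <- unname(coefs["pos", "Estimate"])
  slope_se <- unname(coefs["pos", "Std. Error"])
  rho <- if (stats::var(rk) == 0) 0 else
    stats::cor(pos, rk, method = "spearman")
  structure(list(per_position = per_position, spearman = rho,
                 slope = slope, slope_se = slope_se),
            class = "positional_bias")
}

#' Literature-bias diagnostics
#'
#' Correlates the causal gene's final rank with its submission count in
#' variant databases (a proxy for how heavily studied the gene is). A
#' negative Spearman correlation means heavily submitted genes receive
#' better (smaller) ranks. Counts are heavy-tailed, so the primary
#' correlation uses `log(1 + count)`; the raw-count correlation is also
#' reported.
#'
#' @param outcomes A `case_outcomes` data frame.
#' @return List of class `literature_bias` with `spearman` (rank vs
#'   log1p count), `spearman_raw` (rank vs raw count) and `n`.
#' @export
literature_bias <- function(outcomes) {
  cnt <- outcomes$causal_submission_count
  rk <- outcomes$causal_rank
  stopifnot(all(cnt >= 0))
  if (stats::var(cnt) == 0) {
    stop("literature bias undefined: submission counts have zero variance",
         call. = FALSE)
  }
  rho <- if (stats::var(rk) == 0) 0 else
    stats::cor(log1p(cnt), rk, method = "spearman")
  rho_raw <- if (stats::var(rk) == 0) 0 else
    stats::cor(cnt, rk, method = "spearman")
  structure(list(spearman = rho, spearman_raw = rho_raw, n = length(rk)),
            class = "literature_bias")
}

#' Compare ranking strategies on the same cohort
#'
#' Runs each strategy over the identical case set (matched per-case seeds)
#' and emits aligned capture curves, per-strategy outcomes and, for each
#' non-baseline strategy, the number of cases whose causal rank strictly
#' improved over the baseline strategy.
#'
#' @inheritParams run_cohort
#' @param strategies Nonempty character vector drawn from
#'   `c("single", "ensemble", "dnc")`; the first entry is the baseline.
#' @param max_rank Capture-curve threshold K.
#' @return List of class `strategy_comparison` with `curves` (long data
#'   frame `strategy`, `k`, `proportion`), `outcomes` (named list of
#'   `case_outcomes`), `improved` (named integer vector of strictly improved
#'   case counts vs the baseline).
#' @export
compare_strategies <- function(cases, scorer_factory, strategies,
                               group_size = 5L, n_rounds = 5L, n_iter = 5L,
                               counts = NULL, seed = 1L,
                               tie_policy = "pessimistic", max_rank = 10L) {
  if (length(strategies) == 0L) {
    stop("'strategies' must be nonempty", call. = FALSE)
  }
  stopifnot(all(strategies %in% c("single", "ensemble", "dnc")))
  outcomes <- lapply(strategies, function(st) {
    run_cohort(cases, scorer_factory, strategy = st, group_size = group_size,
               n_rounds = n_rounds, n_iter = n_iter, counts = counts,
               seed = seed, tie_policy = tie_policy)
  })
  names(outcomes) <- strategies
  ids <- lapply(outcomes, `[[`, "case_id")
  if (length(unique(ids)) != 1L) {
    stop("strategies evaluated mismatched case sets", call. = FALSE)
  }
  curves <- do.call(rbind, lapply(strategies, function(st) {
    cc <- capture_curve(outcomes[[st]], max_rank = max_rank)
    data.frame(strategy = st, k = cc$k, proportion = cc$proportion,
               stringsAsFactors = FALSE)
  }))
  base_rank <- outcomes[[1]]$causal_rank
  improved <- vapply(strategies, function(st) {
    sum(outcomes[[st]]$causal_rank < base_rank)
  }, integer(1))
  structure(list(curves = curves, outcomes = outcomes, improved = improved,
                 baseline = strategies[1]),
            class = "strategy_comparison")
}
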