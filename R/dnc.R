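#' Divide-and-conquer configuration
#'
#' @param group_size Genes per group (default 5: candidate lists of 25 and
#'   50 split into 5 and 10 groups respectively).
#' @param n_rounds Number of independent repartition rounds N over which
#'   each gene's in-group probabilities are averaged (default 5).
#' @param seed Integer seed for the partition stream.
#' @param remainder_policy `"balance"` (default) makes group sizes differ by
#'   at most one when `group_size` does not divide the list length;
#'   `"strict"` errors instead.
#' @return An object of class `dnc_config`.
#' @export
dnc_config <- function(group_size = 5L, n_rounds = 5L, seed = 1L,
                       remainder_policy = c("balance", "strict")) {
  remainder_policy <- match.arg(remainder_policy)
  group_size <- as.integer(group_size)
  n_rounds <- as.integer(n_rounds)
  if (group_size < 2L) stop("group_size must be at least 2", call. = FALSE)
  if (n_rounds < 1L) stop("n_rounds must be at least 1", call. = FALSE)
  structure(list(group_size = group_size, n_rounds = n_rounds,
                 seed = as.integer(seed),
                 remainder_policy = remainder_policy),
            class = "dnc_config")
}

#' Randomly partition genes into scoring groups
#'
#' Uniformly permutes the gene list and cuts it into groups of
#' `group_size`. When the size does not divide the list length, the
#' `"balance"` policy spreads the remainder so group sizes differ by at most
#' one (no group is ever a singleton for `group_size >= 2` and `n >= 2`);
#' `"strict"` raises an error.
#'
#' @param genes Nonempty character vector.
#' @param group_size Target group size.
#' @param remainder_policy `"balance"` or `"strict"`.
#' @return List of character vectors; every gene appears in exactly one
#'   group. Draws from the current RNG stream (seed it with
#'   [withr::with_seed()] or via [dnc_config()] inside [dnc_rank()]).
#' @examples
#' withr::with_seed(1, partition_genes(paste0("G", 1:50), 5))  # 10 groups
#' @export
partition_genes <- function(genes, group_size,
                            remainder_policy = c("balance", "strict")) {
  remainder_policy <- match.arg(remainder_policy)
  n <- length(genes)
  if (n == 0L) stop("'genes' must be nonempty", call. = FALSE)
  group_size <- as.integer(group_size)
  if (remainder_policy == "strict" && n %% group_size != 0L) {
    stop(sprintf("group_size %d does not divide %d genes (strict policy)",
                 group_size, n), call. = FALSE)
  }
  if (group_size >= n) return(list(sample(genes)))
  n_groups <- ceiling(n / group_size)
  base <- n %/% n_groups
  extra <- n %% n_groups
  sizes <- c(rep(base + 1L, extra), rep(base, n_groups - extra))
  shuffled <- sample(genes)
  split(shuffled, rep(seq_len(n_groups), times = sizes))
}

# Normalize a scorer result to numeric scores (presented order) or NULL on
# refusal.
.scores_from_result <- function(res, genes) {
  if (inherits(res, "score_vector")) {
    if ("refusal" %in% score_flags(res)) return(NULL)
    stopifnot(identical(res$gene, genes))
    return(res$score)
  }
  stopifnot(is.numeric(res), length(res) == length(genes))
  res
}

#' Divide-and-conquer gene ranking
#'
#' The aggregation strategy for candidate lists too long to score reliably
#' in one query: in each of N rounds the candidate genes are randomly
#' repartitioned into small groups, the scorer assigns each gene an in-group
#' causality probability seeing only its group (positions renumbered from
#' 1), and a gene's final score is the arithmetic mean of its in-group
#' probabilities across rounds:
#' `S(g_j) = (1/N) * sum_i Pr_i(g_j)`.
#' Because a gene's within-group position is independent of its position in
#' the full input list, full-list positional bias cannot propagate into the
#' final score.
#'
#' @param case A [patient_case()].
#' @param scorer A scorer function `(genes, salt) -> scores` (see
#'   [synthetic_scorer()] for the contract).
#' @param config A [dnc_config()].
#' @return A data frame of class `final_scores` with columns `gene`, `score`
#'   (in \[0,1\]) and `n_observations` (rounds contributing to the mean), in
#'   candidate-list order. A scorer failure or refusal in one round drops
#'   that round's observations for the affected genes with a warning.
#' @export
dnc_rank <- function(case, scorer, config = dnc_config()) {
  stopifnot(inherits(case, "patient_case"), is.function(scorer),
            inherits(config, "dnc_config"))
  genes <- case$candidate_genes
  sums <- stats::setNames(numeric(length(genes)), genes)
  nobs <- stats::setNames(integer(length(genes)), genes)
  withr::with_seed(config$seed, {
    for (round in seq_len(config$n_rounds)) {
      groups <- partition_genes(genes, config$group_size,
                                config$remainder_policy)
      for (grp in groups) {
        res <- tryCatch(scorer(grp, salt = round), error = function(e) e)
        if (inherits(res, "error")) {
          warning("scorer failed in round ", round, " for group [",
                  paste(grp, collapse = ", "), "]: ",
                  conditionMessage(res), call. = FALSE)
          next
        }
        sc <- .scores_from_result(res, grp)
        if (is.null(sc)) {
          warning("scorer refused in round ", round, "; observations dropped",
                  call. = FALSE)
          next
        }
        if (any(sc < 0 | sc > 1)) {
          stop("scorer returned probabilities outside [0, 1]", call. = FALSE)
        }
        sums[grp] <- sums[grp] + sc
        nobs[grp] <- nobs[grp] + 1L
      }
    }
  })
  score <- ifelse(nobs > 0L, sums / nobs, NA_real_)
  structure(data.frame(gene = genes, score = unname(score[genes]),
                       n_observations = unname(nobs[genes]),
                       stringsAsFactors = FALSE),
            class = c("final_scores", "data.frame"))
}

#' Ensemble (repeated full-list) gene ranking
#'
#' Scores the full candidate list `n_iter` times and averages the per-gene
#' score vectors into a consensus. Iterations flagged as refusals are
#' dropped from the mean; if every iteration is refused the case is
#' unevaluable and a classed error (`priorank_unevaluable`) is raised.
#'
#' @inheritParams dnc_rank
#' @param n_iter Number of full-list iterations to average (default 5).
#' @return A `final_scores` data frame (see [dnc_rank()]); the attribute
#'   `n_refusals` records dropped iterations.
#' @export
ensemble_rank <- function(case, scorer, n_iter = 5L) {
  stopifnot(inherits(case, "patient_case"), is.function(scorer), n_iter >= 1L)
  genes <- case$candidate_genes
  kept <- list()
  n_refusals <- 0L
  for (i in seq_len(n_iter)) {
    res <- scorer(genes, salt = i)
    sc <- .scores_from_result(res, genes)
    if (is.null(sc)) {
      n_refusals <- n_refusals + 1L
      next
    }
    kept[[length(kept) + 1L]] <- sc
  }
  if (length(kept) == 0L) {
    stop(structure(class = c("priorank_unevaluable", "error", "condition"),
                   list(message = paste0("case ", case$case_id,
                                         ": all ", n_iter,
                                         " iterations refused"),
                        call = NULL)))
  }
  score <- Reduce(`+`, kept) / length(kept)
  structure(data.frame(gene = genes, score = score,
                       n_observations = length(kept),
                       stringsAsFactors = FALSE),
            n_refusals = n_refusals,
            class = c("final_scores", "data.frame"))
}

#' Ranks from final scores with an explicit tie policy
#'
#' Converts scores into 1-based ranks (rank 1 = highest score). Ties are
#' resolved by policy: `"pessimistic"` gives every tied gene the worst rank
#' of its tie block (capture curves then report lower bounds),
#' `"stable"` breaks ties by input order, `"average"` assigns the block's
#' mean rank (possibly fractional).
#'
#' @param scores A `final_scores` data frame (columns `gene`, `score`), or a
#'   named numeric vector of scores.
#' @param tie_policy One of `"pessimistic"`, `"stable"`, `"average"`.
#' @return A data frame of class `rank_table` with columns `gene`, `score`,
#'   `rank`, and attribute `tie_policy`.
#' @examples
#' ranks_from_scores(c(A = 0.9, B = 0.5, C = 0.1))
#' @export
ranks_from_scores <- function(scores,
                              tie_policy = c("pessimistic", "stable",
                                             "average")) {
  tie_policy <- match.arg(tie_policy)
  if (is.numeric(scores)) {
    scores <- data.frame(gene = names(scores) %||%
                           paste0("G", seq_along(scores)),
                         score = unname(scores), stringsAsFactors = FALSE)
  }
  if (anyNA(scores$score) || any(!is.finite(scores$score))) {
    stop("scores must be finite to rank", call. = FALSE)
  }
  method <- c(pessimistic = "max", stable = "first", average = "average")
  rk <- rank(-scores$score, ties.method = method[[tie_policy]])
  structure(data.frame(gene = scores$gene, score = scores$score, rank = rk,
                       stringsAsFactors = FALSE),
            tie_policy = tie_policy,
            class = c("rank_table", "data.frame"))
}
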