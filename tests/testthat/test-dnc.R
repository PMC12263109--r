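test_that("random partitions cover every gene once with balanced group sizes", {
  genes50 <- sprintf("G%02d", 1:50)
  withr::with_seed(1, {
    g50 <- partition_genes(genes50, 5)
    g25 <- partition_genes(genes50[1:25], 5)
    g23 <- partition_genes(genes50[1:23], 5)
  })
  expect_length(g50, 10L)
  expect_length(g25, 5L)
  expect_true(all(lengths(g50) == 5L))
  # remainder balanced: sizes differ by at most one, never a singleton
  expect_identical(sort(unname(lengths(g23))), c(4L, 4L, 5L, 5L, 5L))
  for (parts in list(g50, g25, g23)) {
    expect_false(anyDuplicated(unlist(parts)) > 0)
  }
  expect_setequal(unname(unlist(g23)), genes50[1:23])
  expect_error(withr::with_seed(1, partition_genes(genes50[1:23], 5, "strict")),
               "strict")
  # partitions are uniform over assignments: two genes share a group about
  # group_size-1 / (n-1) of the time
  share <- vapply(1:600, function(s) {
    parts <- withr::with_seed(s, partition_genes(genes50[1:20], 5))
    any(vapply(parts, function(p) all(c("G01", "G02") %in% p), logical(1)))
  }, logical(1))
  expect_gt(stats::binom.test(sum(share), 600, 4 / 19)$p.value, 1e-4)
})

test_that("divide-and-conquer scores are per-gene means of in-group probabilities", {
  case <- tiny_case()
  # N = 1: the final score is the single in-group probability
  fixed <- scripted_scorer(c(PAX6 = 0.9, BRCA2 = 0.4, TTN = 0.2,
                             MECP2 = 0.6, SCN1A = 0.1))
  fs1 <- dnc_rank(case, fixed, dnc_config(group_size = 5, n_rounds = 1,
                                          seed = 2))
  expect_equal(stats::setNames(fs1$score, fs1$gene)[case$candidate_genes],
               c(PAX6 = 0.9, BRCA2 = 0.4, TTN = 0.2, MECP2 = 0.6,
                 SCN1A = 0.1))
  # two observations 0.8 and 0.6 average to 0.7
  two <- patient_case("pair", "HP:1", c("AA", "BB"))
  seesaw <- salted_scorer(list(`1` = c(AA = 0.8, BB = 0.3),
                               `2` = c(AA = 0.6, BB = 0.5)))
  fs2 <- dnc_rank(two, seesaw, dnc_config(group_size = 2, n_rounds = 2,
                                          seed = 1))
  expect_equal(fs2$score[fs2$gene == "AA"], 0.7)
  expect_equal(fs2$score[fs2$gene == "BB"], 0.4)
  expect_identical(fs2$n_observations, c(2L, 2L))
  # a constant scorer yields that constant for every gene
  const <- function(genes, salt = 0L) rep(0.5, length(genes))
  fsc <- dnc_rank(case, const, dnc_config(group_size = 2, n_rounds = 3,
                                          seed = 3))
  expect_true(all(fsc$score == 0.5))
  # conservation: every gene observed in every round
  expect_identical(sum(fsc$n_observations), 3L * 5L)
})

test_that("with whole-list groups, divide-and-conquer equals plain averaging (brute-force oracle)", {
  genes <- c("AL", "BE", "GA", "DE", "EP", "ZE")
  case <- patient_case("oracle", "HP:1", genes, causal_gene = "GA")
  par <- synthetic_scorer_params(signal = 1.5, noise_sd = 0.6, seed = 8)
  scorer <- synthetic_scorer(par, causal_gene = "GA")
  n_rounds <- 4L
  fs <- dnc_rank(case, scorer, dnc_config(group_size = 6,
                                          n_rounds = n_rounds, seed = 12))
  # oracle: mean of N independent full-list score vectors, computed without
  # any partitioning machinery
  per_round <- vapply(seq_len(n_rounds),
                      function(i) scorer(genes, salt = i), numeric(6))
  oracle <- rowMeans(per_round)
  expect_equal(stats::setNames(fs$score, fs$gene)[genes],
               stats::setNames(oracle, genes))
})

test_that("same seed and scorer reproduce identical divide-and-conquer output", {
  case <- tiny_case()
  scorer <- synthetic_scorer(synthetic_scorer_params(seed = 4), "PAX6")
  cfg <- dnc_config(group_size = 2, n_rounds = 5, seed = 77)
  expect_identical(dnc_rank(case, scorer, cfg), dnc_rank(case, scorer, cfg))
})

test_that("scorer failures drop that round's observations with a warning", {
  two <- patient_case("flaky", "HP:1", c("AA", "BB"))
  flaky <- function(genes, salt = 0L) {
    if (salt == 1L) stop("backend exploded")
    c(AA = 0.6, BB = 0.2)[genes]
  }
  expect_warning(
    fs <- dnc_rank(two, flaky, dnc_config(group_size = 2, n_rounds = 3,
                                          seed = 1)),
    "scorer failed in round 1")
  expect_identical(fs$n_observations, c(2L, 2L))
  expect_equal(fs$score[fs$gene == "AA"], 0.6)
})

test_that("ensemble averaging drops refusal iterations and errors when all refuse", {
  case <- patient_case("ens", "HP:1", c("AA", "BB"))
  byslt <- list(`1` = c(AA = 0.2, BB = 0.9),
                `2` = "refuse",
                `3` = c(AA = 0.4, BB = 0.7),
                `4` = "refuse",
                `5` = c(AA = 0.6, BB = 0.5))
  fs <- ensemble_rank(case, salted_scorer(byslt), n_iter = 5)
  expect_equal(fs$score, c(0.4, 0.7))       # mean over the 3 kept iterations
  expect_identical(fs$n_observations, c(3L, 3L))
  expect_identical(attr(fs, "n_refusals"), 2L)
  # single deterministic iteration equals the single-shot scores
  fs1 <- ensemble_rank(case, salted_scorer(byslt), n_iter = 1)
  expect_equal(fs1$score, c(0.2, 0.9))
  all_refuse <- salted_scorer(list(`1` = "refuse", `2` = "refuse"))
  expect_error(ensemble_rank(case, all_refuse, n_iter = 2),
               class = "priorank_unevaluable")
})

test_that("tie policies assign pessimistic, stable, and average ranks as defined", {
  expect_identical(ranks_from_scores(c(A = 0.9, B = 0.5, C = 0.1))$rank,
                   c(1L, 2L, 3L))
  tied5 <- stats::setNames(rep(0.3, 5), paste0("G", 1:5))
  expect_identical(ranks_from_scores(tied5, "pessimistic")$rank,
                   rep(5L, 5L))
  expect_identical(ranks_from_scores(tied5, "stable")$rank, 1:5)
  top2 <- c(A = 0.8, B = 0.8, C = 0.1)
  expect_equal(ranks_from_scores(top2, "average")$rank, c(1.5, 1.5, 3))
  expect_error(ranks_from_scores(c(A = NA_real_, B = 1)), "finite")
})

test_that("a position-free scorer gives positionally exchangeable final scores", {
  genes <- c("AA", "BB", "CC", "DD", "EE", "FF")
  par <- synthetic_scorer_params(signal = 0, beta_pos = 0, noise_sd = 0.8,
                                 seed = 31)
  scorer <- synthetic_scorer(par)
  front <- patient_case("front", "HP:1", genes)
  back <- patient_case("back", "HP:1", rev(genes))
  mean_aa <- function(case) {
    mean(vapply(1:150, function(s) {
      fs <- dnc_rank(case, scorer, dnc_config(group_size = 3, n_rounds = 1,
                                              seed = s))
      fs$score[fs$gene == "AA"]
    }, numeric(1)))
  }
  # AA first vs AA last: seed-averaged final scores agree
  expect_lt(abs(mean_aa(front) - mean_aa(back)), 0.03)
})
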