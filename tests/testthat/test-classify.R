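test_that("evaluator/summarizer verdicts map onto specificity labels with normalization", {
  ont <- tiny_ontology()
  case <- tiny_case()
  essayist <- function(prompt) "A one-hundred-word assessment of the candidates."
  lab_yes <- multi_agent_classify(case, essayist, function(p) "Yes", ont)
  expect_identical(lab_yes$label, "specific")
  expect_identical(lab_yes$method, "multi_agent")
  expect_match(lab_yes$evidence, "assessment")
  # normalization: case, punctuation and whitespace stripped
  lab_no <- multi_agent_classify(case, essayist, function(p) "  no. \n", ont)
  expect_identical(lab_no$label, "nonspecific")
  # neither token twice -> unevaluable, and exactly one retry happened
  calls <- new.env(); calls$n <- 0L
  maybe <- function(p) { calls$n <- calls$n + 1L; "Maybe" }
  expect_warning(lab_uneval <- multi_agent_classify(case, essayist, maybe, ont),
                 "unevaluable")
  expect_identical(lab_uneval$label, "unevaluable")
  expect_identical(calls$n, 2L)
  # a flaky summarizer that recovers on retry is accepted
  flip <- local({
    n <- 0L
    function(p) { n <<- n + 1L; if (n == 1L) "hmm" else "YES" }
  })
  expect_identical(multi_agent_classify(case, essayist, flip, ont)$label,
                   "specific")
})

test_that("evaluator prompt covers genes and phenotypes and asks for a 100-word essay", {
  ont <- tiny_ontology()
  case <- tiny_case()
  p <- build_evaluator_prompt(case, ont)
  expect_match(p, "100-word essay")
  for (g in case$candidate_genes) expect_match(p, g, fixed = TRUE)
  sp <- build_summarizer_prompt("ESSAY BODY")
  expect_match(sp, "ESSAY BODY", fixed = TRUE)
  expect_match(sp, "Yes or No")
})

test_that("DsI hits its extremes and the worked depth-mix value", {
  ont <- tiny_ontology()  # max depth 4
  expect_identical(dsi(ont$root, ont)$dsi, 0)
  expect_identical(dsi("HP:0000005", ont)$dsi, 1)  # maximal-depth leaf
  # depths {2, 4} with max depth 4 -> mean(0.5, 1) = 0.75
  expect_equal(dsi(c("HP:0000003", "HP:0000005"), ont)$dsi, 0.75)
  # order- and duplication-invariant
  expect_equal(dsi(c("HP:0000005", "HP:0000003", "HP:0000003"), ont)$dsi, 0.75)
  expect_error(dsi("HP:9999999", ont), "no resolvable")
  expect_warning(d <- dsi(c("HP:0000005", "HP:9999999"), ont), "dropping")
  expect_identical(d$dsi, 1)
  # injectable specificity function
  expect_identical(dsi("HP:0000003", ont,
                       index_fun = function(depths, md) max(depths))$dsi, 2L)
})

test_that("replacing a term by an ancestor never increases DsI", {
  withr::with_seed(17, {
    for (rep in 1:40) {
      ont <- make_ontology(depth = sample(2:4, 1), branching = sample(2:3, 1),
                           seed = sample.int(1e6, 1),
                           cross_links = sample(0:2, 1))
      ids <- names(ont$terms)
      terms <- sample(ids, min(5, length(ids)))
      base <- dsi(terms, ont)$dsi
      # substitute a term by its shortest-path parent (the placement that
      # defines its depth); generalizing a term must not raise specificity
      with_parent <- terms[vapply(terms, function(t) {
        length(ont$terms[[t]]$parents) > 0
      }, logical(1))]
      if (!length(with_parent)) next
      victim <- with_parent[[1]]
      parents <- ont$terms[[victim]]$parents
      anc <- parents[which.min(term_depth(parents, ont))]
      if (anc %in% setdiff(terms, victim)) next  # collapse changes the set size
      swapped <- unique(c(setdiff(terms, victim), anc))
      expect_lte(dsi(swapped, ont)$dsi, base)
    }
  })
})

test_that("median and threshold policies split cohorts into DsI strata", {
  two <- c(a = 0.2, b = 0.8)
  s <- split_by_dsi(two)
  expect_identical(stats::setNames(s$label, s$case_id),
                   c(a = "low_dsi", b = "high_dsi"))
  s2 <- split_by_dsi(c(a = 0.4, b = 0.6), policy = "threshold",
                     threshold = 0.5)
  expect_identical(s2$label, c("low_dsi", "high_dsi"))
  expect_warning(s3 <- split_by_dsi(c(a = 0.5, b = 0.5, c = 0.5)),
                 "identical")
  expect_true(all(s3$label == "low_dsi"))
  expect_error(split_by_dsi(c(a = 0.5)), "at least two")
})

test_that("specific-stratum cases are captured more often than nonspecific ones", {
  # synthetic stratified cohort: "specific" cases carry a larger causal
  # signal, so their rank-1 capture must exceed the nonspecific stratum's
  pool <- sprintf("G%03d", 1:60)
  make_stratum <- function(label, signal, n) {
    lapply(seq_len(n), function(i) {
      sets <- build_candidate_sets("CAUSAL", setdiff(pool, "CAUSAL"),
                                   sizes = 25L, seed = i * 13 + signal)
      patient_case(sprintf("%s-%02d", label, i), "HP:1", sets[["25"]],
                   "CAUSAL")
    })
  }
  run_stratum <- function(cases, signal) {
    par <- synthetic_scorer_params(signal = signal, noise_sd = 1, seed = 3)
    oc <- run_cohort(cases, function(cs) synthetic_scorer(par, cs$causal_gene),
                     "single", seed = 3)
    capture_curve(oc, 1)$proportion[1]
  }
  spec_cases <- make_stratum("spec", 3, 60)
  nonspec_cases <- make_stratum("nonspec", 0.5, 60)
  expect_gt(run_stratum(spec_cases, 3), run_stratum(nonspec_cases, 0.5))
})
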