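count_occurrences <- function(needle, haystack) {
  m <- gregexpr(paste0("\\b", needle, "\\b"), haystack)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

test_that("ranking prompts enumerate every gene and phenotype exactly once, deterministically", {
  ont <- tiny_ontology()
  case <- tiny_case()
  p <- build_ranking_prompt(case, ont)
  for (g in case$candidate_genes) {
    expect_identical(count_occurrences(g, p), 1L)
  }
  for (txt in terms_to_text(case$phenotype_terms, ont)) {
    expect_true(grepl(txt, p, fixed = TRUE))
  }
  # guidance clause for evidence-poor genes (template wraps lines)
  expect_match(gsub("\\s+", " ", p),
               "gene function, expression sites, or analogous animal model")
  expect_match(p, "0 and 1\\.0")
  expect_identical(p, build_ranking_prompt(case, ont))  # byte-identical
  expect_error(build_ranking_prompt(case, ont, genes = character(0)),
               "empty candidate")
})

test_that("yes/no prompts cover the phenotypes and enforce gene membership", {
  ont <- tiny_ontology()
  case <- tiny_case()
  p <- build_yesno_prompt(case, "PAX6", ont)
  expect_match(p, "PAX6")
  expect_match(p, "Yes or No")
  for (txt in terms_to_text(case$phenotype_terms, ont)) {
    expect_true(grepl(txt, p, fixed = TRUE))
  }
  expect_identical(p, build_yesno_prompt(case, "PAX6", ont))
  expect_error(build_yesno_prompt(case, "NOTHERE", ont),
               "not in the case's candidate list")
})

test_that("well-formed, partial, and refusal replies parse per policy", {
  sv <- parse_ranking_response("A: 0.9\nB: 0.1", c("A", "B"))
  expect_equal(sv$score, c(0.9, 0.1))
  expect_length(score_flags(sv), 0L)
  # missing gene scores zero and is flagged
  sv2 <- parse_ranking_response("A: 0.9", c("A", "B"))
  expect_equal(sv2$score, c(0.9, 0))
  expect_true(sv2$missing[2])
  expect_identical(score_flags(sv2), "missing_gene")
  # no parseable line at all is a refusal
  sv3 <- parse_ranking_response("I cannot rank genes.", c("A", "B"))
  expect_equal(sv3$score, c(0, 0))
  expect_identical(score_flags(sv3), "refusal")
  # out-of-range numbers are clamped, enumeration prefixes stripped
  sv4 <- parse_ranking_response("1. A: 1.7\n2) B = -0.2\nC: 2e-1",
                                c("A", "B", "C"))
  expect_equal(sv4$score, c(1, 0, 0.2))
})

test_that("response parsing is total over fuzzed byte strings", {
  genes <- c("AAA", "BBB", "CCC")
  chars <- c(letters, LETTERS, 0:9, ":", ".", "\n", "\t", " ", "-", "%", "{",
             "é", "\\", "\"")
  withr::with_seed(99, {
    for (i in 1:200) {
      txt <- paste(sample(chars, sample(0:80, 1), replace = TRUE),
                   collapse = "")
      sv <- parse_ranking_response(txt, genes)
      expect_s3_class(sv, "score_vector")
      expect_identical(sv$gene, genes)
      expect_true(all(sv$score >= 0 & sv$score <= 1))
    }
  })
  expect_s3_class(parse_ranking_response("", genes), "score_vector")
  expect_s3_class(parse_ranking_response(NA_character_, genes), "score_vector")
})

test_that("log-likelihood-ratio scoring satisfies its algebraic identities", {
  expect_identical(llr_score(0.5, 0.5), 0)
  expect_equal(llr_score(0.9, 0.1), log(9))
  # antisymmetry and symmetry-zero on a probability grid
  grid <- expand.grid(a = c(1e-6, 0.01, 0.3, 0.5, 0.97),
                      b = c(1e-6, 0.01, 0.3, 0.5, 0.97))
  expect_equal(llr_score(grid$a, grid$b), -llr_score(grid$b, grid$a))
  expect_equal(llr_score(grid$a, grid$a), rep(0, nrow(grid)))
  # zero probability is floored, not infinite
  expect_equal(llr_score(0.9, 0), log(0.9 / 1e-12))
  expect_true(is.finite(llr_score(0, 0)))
  expect_error(llr_score(-0.1, 0.5), "nonnegative")
})

test_that("ranking by llr equals ranking by normalized yes-probability", {
  withr::with_seed(3, {
    p_yes <- runif(40, 1e-6, 1)
    p_no <- runif(40, 1e-6, 1)
  })
  r_llr <- rank(llr_score(p_yes, p_no))
  r_norm <- rank(p_yes / (p_yes + p_no))
  expect_identical(r_llr, r_norm)
})

test_that("synthetic scorer responds to signal, position, and literature axes as built", {
  genes <- sprintf("G%02d", 1:10)
  # pure signal: causal gene strictly on top
  s <- synthetic_score_group(genes, genes == "G07",
                             params = synthetic_scorer_params(
                               signal = 3, noise_sd = 0, seed = 1))
  expect_identical(which.max(s), 7L)
  expect_true(s[7] > max(s[-7]))
  # positional penalty: same gene scores strictly lower when presented last
  long <- sprintf("G%02d", 1:50)
  par_pos <- synthetic_scorer_params(signal = 0, beta_pos = 1.5,
                                     noise_sd = 0, seed = 1)
  first <- synthetic_score_group(long, rep(FALSE, 50), params = par_pos)
  moved <- c(long[-1], long[1])  # G01 now at position 50
  last <- synthetic_score_group(moved, rep(FALSE, 50), params = par_pos)
  expect_lt(last[50], first[1])
  # literature boost raises the scored probability
  par_lit <- synthetic_scorer_params(signal = 0, beta_lit = 1, noise_sd = 0,
                                     seed = 1)
  s_lit <- synthetic_score_group(c("A", "B"), c(FALSE, FALSE),
                                 counts = c(100, 0), params = par_lit)
  expect_gt(s_lit[1], s_lit[2])
  # single-gene list: positional term defined as zero
  expect_no_error(synthetic_score_group("A", FALSE,
                                        params = synthetic_scorer_params()))
})

test_that("synthetic scorer is deterministic and attaches noise to gene identity", {
  par <- synthetic_scorer_params(noise_sd = 0.7, seed = 5)
  genes <- c("AAA", "BBB", "CCC", "DDD")
  a <- synthetic_score_group(genes, c(TRUE, FALSE, FALSE, FALSE), params = par)
  b <- synthetic_score_group(genes, c(TRUE, FALSE, FALSE, FALSE), params = par)
  expect_identical(a, b)
  # with no positional bias, permuting the list permutes the scores with it
  perm <- c(3L, 1L, 4L, 2L)
  p <- synthetic_score_group(genes[perm],
                             c(TRUE, FALSE, FALSE, FALSE)[perm], params = par)
  expect_equal(p, a[perm])
  # a different salt redraws the noise
  c2 <- synthetic_score_group(genes, c(TRUE, FALSE, FALSE, FALSE),
                              params = par, salt = 1L)
  expect_false(identical(a, c2))
})
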