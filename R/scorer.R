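# Scorer contract: a scorer is a function(genes, salt = 0L) returning either
# a bare numeric vector of per-gene scores in [0, 1] (presented order) or a
# score_vector object. `salt` distinguishes repeated queries on the same gene
# list (ensemble iterations, divide-and-conquer rounds) so stochastic
# backends can vary between calls while staying reproducible.

#' Per-gene score vector from one scorer invocation
#'
#' @param genes Character vector of gene symbols (presented order).
#' @param scores Numeric scores, one per gene. Verbal and synthetic scores
#'   live in \[0,1\]; token log-likelihood-ratio scores are unbounded.
#' @param provenance One of `"verbal"`, `"token_llr"`, `"synthetic"`.
#' @param flags Character subset of `c("missing_gene", "refusal",
#'   "reprompted")` describing degradation during scoring.
#' @param missing Logical vector marking genes absent from the backend reply.
#' @return A data frame of class `score_vector` with columns `gene`, `score`,
#'   `missing` and attributes `provenance` and `flags`.
#' @export
score_vector <- function(genes, scores,
                         provenance = c("synthetic", "verbal", "token_llr"),
                         flags = character(0),
                         missing = rep(FALSE, length(genes))) {
  provenance <- match.arg(provenance)
  genes <- .normalize_genes(genes)
  stopifnot(length(scores) == length(genes), is.numeric(scores),
            length(missing) == length(genes))
  allowed <- c("missing_gene", "refusal", "reprompted")
  if (!all(flags %in% allowed)) {
    stop("unknown flags: ", paste(setdiff(flags, allowed), collapse = ", "),
         call. = FALSE)
  }
  if (provenance != "token_llr" && any(scores < 0 | scores > 1)) {
    stop(provenance, " scores must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(gene = genes, score = as.numeric(scores),
                       missing = as.logical(missing),
                       stringsAsFactors = FALSE),
            provenance = provenance, flags = unique(flags),
            class = c("score_vector", "data.frame"))
}

#' Scorer flags of a score vector
#' @param sv A [score_vector()].
#' @return Character vector of flags (possibly empty).
#' @export
score_flags <- function(sv) attr(sv, "flags") %||% character(0)

.load_template <- function(name, template = NULL) {
  if (!is.null(template)) return(template)
  path <- system.file("templates", paste0(name, ".txt"), package = "priorank")
  if (!nzchar(path)) stop("template '", name, "' not found", call. = FALSE)
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

.fill_template <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{", key, "}"), values[[key]], template,
                     fixed = TRUE)
  }
  template
}

#' Build the full-list ranking prompt for a case
#'
#' Enumerates the phenotype texts and the candidate gene symbols in case
#' order and instructs the backend to assign each gene a causality
#' probability in 0–1.0 without justification. Identical inputs yield
#' byte-identical prompts.
#'
#' @param case A [patient_case()].
#' @param ont A [ontology()] used to resolve phenotype terms to text.
#' @param genes Optional subset of candidate genes to enumerate (defaults to
#'   the full candidate list); used for mini-batched and in-group queries.
#' @param mode Passed to [terms_to_text()].
#' @param template Optional template string overriding the shipped one;
#'   placeholders `{phenotypes}` and `{genes}`.
#' @return Prompt text (single string).
#' @export
build_ranking_prompt <- function(case, ont, genes = NULL,
                                 mode = "definition", template = NULL) {
  stopifnot(inherits(case, "patient_case"))
  if (is.null(genes)) genes <- case$candidate_genes
  if (length(genes) == 0L) stop("empty candidate gene list", call. = FALSE)
  if (!all(genes %in% case$candidate_genes)) {
    stop("genes not in the case's candidate list: ",
         paste(setdiff(genes, case$candidate_genes), collapse = ", "),
         call. = FALSE)
  }
  phen <- terms_to_text(case$phenotype_terms, ont, mode = mode)
  .fill_template(.load_template("ranking", template), list(
    phenotypes = paste(sprintf("%d. %s", seq_along(phen), phen),
                       collapse = "\n"),
    genes = paste(sprintf("%d. %s", seq_along(genes), genes),
                  collapse = "\n")))
}

#' Build a single-gene yes/no causality prompt
#'
#' Produces the query used for token log-likelihood-ratio ranking: the only
#' well-formed answers are "Yes" and "No", whose token probabilities the
#' backend reports.
#'
#' @inheritParams build_ranking_prompt
#' @param gene Gene symbol; must be one of the case's candidate genes.
#' @return Prompt text (single string).
#' @export
build_yesno_prompt <- function(case, gene, ont, mode = "definition",
                               template = NULL) {
  stopifnot(inherits(case, "patient_case"))
  gene <- .normalize_genes(gene)
  if (length(gene) != 1L || !gene %in% case$candidate_genes) {
    stop("gene '", gene, "' is not in the case's candidate list",
         call. = FALSE)
  }
  phen <- terms_to_text(case$phenotype_terms, ont, mode = mode)
  .fill_template(.load_template("yesno", template), list(
    phenotypes = paste(sprintf("%d. %s", seq_along(phen), phen),
                       collapse = "\n"),
    gene = gene))
}

#' Parse a verbal ranking reply into a score vector
#'
#' Parsing is total: every byte string yields a [score_vector()]. Lines of
#' the form `SYMBOL: number` (optionally preceded by enumeration like
#' `"3."`) are captured; numbers outside \[0,1\] are clamped. Genes absent
#' from the reply score 0 and raise the `missing_gene` flag; a reply with no
#' parseable gene line at all is treated as a refusal and yields all-zero
#' scores with the `refusal` flag.
#'
#' @param text Raw backend reply (single string; may be empty or garbage).
#' @param genes Character vector of the genes that were queried.
#' @return A [score_vector()] with provenance `"verbal"`.
#' @examples
#' parse_ranking_response("A: 0.9\nB: 0.1", c("A", "B"))
#' @export
parse_ranking_response <- function(text, genes) {
  genes <- .normalize_genes(genes)
  if (length(genes) == 0L) stop("'genes' must be nonempty", call. = FALSE)
  scores <- stats::setNames(rep(NA_real_, length(genes)), genes)
  if (length(text) == 1L && !is.na(text) && nzchar(text)) {
    lines <- strsplit(text, "\r?\n")[[1]]
    # strip leading enumeration ("3.", "3)", "-") then expect SYMBOL : number
    lines <- sub("^\\s*(\\d+[.)]|[-*])\\s*", "", lines)
    m <- regmatches(lines, regexec(
      "^\\s*([A-Za-z][A-Za-z0-9_.-]*)\\s*[:=]\\s*([-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?)",
      lines))
    for (hit in m) {
      if (length(hit) < 3L) next
      sym <- toupper(hit[2])
      val <- suppressWarnings(as.numeric(hit[3]))
      if (sym %in% genes && is.na(scores[sym]) && !is.na(val)) {
        scores[sym] <- min(max(val, 0), 1)  # clamp out-of-range replies
      }
    }
  }
  flags <- character(0)
  if (all(is.na(scores))) flags <- "refusal"
  missing <- is.na(scores)
  if (any(missing) && !"refusal" %in% flags) flags <- c(flags, "missing_gene")
  scores[missing] <- 0
  score_vector(genes, unname(scores), provenance = "verbal", flags = flags,
               missing = unname(missing))
}

#' Log-likelihood-ratio score from yes/no token probabilities
#'
#' For a backend that exposes the output probabilities of its "Yes" and "No"
#' answer tokens, the causality score of a gene is
#' `log(Pr(Yes) / Pr(No))`. Both probabilities are floored at `eps` before
#' the ratio so the score is finite even when a token probability is
#' reported as exactly zero. Ranking by this score is equivalent to ranking
#' by the normalized yes-probability `Pr(Yes) / (Pr(Yes) + Pr(No))`.
#'
#' @param p_yes,p_no Nonnegative token probabilities (need not sum to 1).
#'   Vectorized.
#' @param eps Floor applied to both probabilities (default `1e-12`).
#' @return Numeric log-likelihood-ratio score(s).
#' @examples
#' llr_score(0.9, 0.1)  # log(9)
#' @export
llr_score <- function(p_yes, p_no, eps = 1e-12) {
  if (!is.numeric(p_yes) || !is.numeric(p_no) || anyNA(p_yes) || anyNA(p_no)) {
    stop("token probabilities must be non-missing numerics", call. = FALSE)
  }
  if (any(p_yes < 0) || any(p_no < 0)) {
    stop("token probabilities must be nonnegative", call. = FALSE)
  }
  log(pmax(p_yes, eps) / pmax(p_no, eps))
}

#' Parameters of the deterministic synthetic scorer
#'
#' The synthetic scorer is a fully controlled stand-in for a language-model
#' backend. It scores a presented gene list through a logistic link whose
#' linear predictor carries a causal-gene signal plus two injectable bias
#' axes that real backends are known to exhibit: a positional penalty that
#' grows with a gene's position in the presented list, and a literature
#' boost that grows with the gene's submission count in variant databases.
#'
#' @param signal Causal-gene boost on the logit scale (>= 0; default 2).
#' @param beta_pos Positional-bias weight: a gene at the end of an L-gene
#'   list is penalized by `beta_pos` logits relative to the first position
#'   (default 0 = no positional bias).
#' @param beta_lit Literature-bias weight applied to `log(1 + count)`
#'   (default 0).
#' @param noise_sd Standard deviation of the per-gene Gaussian logit noise
#'   (default 0.5).
#' @param intercept Baseline logit of a noncausal, unboosted gene
#'   (default -1).
#' @param seed Integer seed; together with the gene set and the call salt it
#'   fully determines the noise, so identical calls return identical scores.
#' @return An object of class `synthetic_scorer_params`.
#' @export
synthetic_scorer_params <- function(signal = 2, beta_pos = 0, beta_lit = 0,
                                    noise_sd = 0.5, intercept = -1,
                                    seed = 1L) {
  .assert_scalar_number(signal, "signal", lower = 0)
  .assert_scalar_number(beta_pos, "beta_pos")
  .assert_scalar_number(beta_lit, "beta_lit")
  .assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  .assert_scalar_number(intercept, "intercept")
  structure(list(signal = signal, beta_pos = beta_pos, beta_lit = beta_lit,
                 noise_sd = noise_sd, intercept = intercept,
                 seed = as.integer(seed)),
            class = "synthetic_scorer_params")
}

#' Score one presented gene list with the synthetic scorer
#'
#' Computes, for gene *i* at 1-based position `pos_i` in a presented list of
#' length L with submission count `count_i`:
#' `score_i = logistic(intercept + signal * is_causal_i
#'   - beta_pos * (pos_i - 1)/(L - 1) + beta_lit * log(1 + count_i) + e_i)`
#' with `e_i ~ Normal(0, noise_sd)` drawn from a stream seeded by the
#' parameter seed, the gene multiset and `salt`. Noise is attached to gene
#' identity (not position), so with `beta_pos = 0` the scorer is
#' position-free. For L = 1 the positional term is 0.
#'
#' @param genes Character vector of gene symbols in presented order.
#' @param is_causal Logical vector marking the causal gene(s).
#' @param counts Nonnegative submission counts, one per gene (default all 0).
#' @param params A [synthetic_scorer_params()].
#' @param salt Integer distinguishing repeated calls on the same list.
#' @return Numeric vector of scores in (0, 1), one per gene.
#' @export
synthetic_score_group <- function(genes, is_causal,
                                  counts = rep(0, length(genes)),
                                  params = synthetic_scorer_params(),
                                  salt = 0L) {
  stopifnot(inherits(params, "synthetic_scorer_params"))
  genes <- .normalize_genes(genes)
  L <- length(genes)
  stopifnot(length(is_causal) == L, length(counts) == L, all(counts >= 0))
  pos_term <- if (L == 1L) 0 else (seq_len(L) - 1) / (L - 1)
  noise <- if (params$noise_sd > 0) {
    sub_seed <- .mix_seed(params$seed, .str_hash(sort(genes)), salt)
    withr::with_seed(sub_seed, {
      drawn <- stats::rnorm(L, 0, params$noise_sd)
    })
    drawn[rank(genes, ties.method = "first")]  # noise follows gene identity
  } else {
    numeric(L)
  }
  lin <- params$intercept + params$signal * as.numeric(is_causal) -
    params$beta_pos * pos_term + params$beta_lit * log1p(counts) + noise
  stats::plogis(lin)
}

#' Create a synthetic scorer bound to a case's ground truth
#'
#' Returns a scorer function `function(genes, salt = 0)` following the
#' package scorer contract, with causality and submission counts looked up
#' from the supplied truth so it can be dropped into [dnc_rank()],
#' [ensemble_rank()] and [run_cohort()].
#'
#' @param params A [synthetic_scorer_params()].
#' @param causal_gene Causal gene symbol (or `NULL` for no causal signal).
#' @param counts Optional named numeric vector of submission counts per gene
#'   symbol; genes without an entry count 0.
#' @return A scorer function.
#' @export
synthetic_scorer <- function(params = synthetic_scorer_params(),
                             causal_gene = NULL, counts = NULL) {
  if (!is.null(causal_gene)) causal_gene <- .normalize_genes(causal_gene)
  if (!is.null(counts) && is.null(names(counts))) {
    stop("'counts' must be a named vector keyed by gene symbol", call. = FALSE)
  }
  function(genes, salt = 0L) {
    genes <- .normalize_genes(genes)
    cnt <- if (is.null(counts)) rep(0, length(genes)) else {
      out <- counts[genes]
      out[is.na(out)] <- 0
      unname(out)
    }
    synthetic_score_group(genes,
                          is_causal = genes %in% (causal_gene %||% character(0)),
                          counts = cnt, params = params, salt = salt)
  }
}
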