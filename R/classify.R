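# Solvability stratification: which cases can a phenotype-driven ranker be
# trusted on? Two routes: (i) a two-agent evaluator/summarizer pipeline that
# asks whether any candidate is directly linked to the phenotypes, and
# (ii) the dataset specificity index (DsI), a purely structural score of how
# deep a case's phenotype terms sit in the ontology.

#' Build the evaluator-agent prompt
#'
#' Asks for a ~100-word essay assessing every candidate gene against the
#' phenotypes.
#'
#' @inheritParams build_ranking_prompt
#' @return Prompt text.
#' @export
build_evaluator_prompt <- function(case, ont, mode = "definition",
                                   template = NULL) {
  stopifnot(inherits(case, "patient_case"))
  phen <- terms_to_text(case$phenotype_terms, ont, mode = mode)
  .fill_template(.load_template("evaluator", template), list(
    phenotypes = paste(sprintf("%d. %s", seq_along(phen), phen),
                       collapse = "\n"),
    genes = paste(sprintf("%d. %s", seq_along(case$candidate_genes),
                          case$candidate_genes), collapse = "\n")))
}

#' Build the summarizer-agent prompt
#'
#' Demands a bare Yes/No verdict on whether the essay identifies at least
#' one gene directly linked to the phenotypes.
#'
#' @param essay Evaluator essay text.
#' @param template Optional template override with placeholder `{essay}`.
#' @return Prompt text.
#' @export
build_summarizer_prompt <- function(essay, template = NULL) {
  stopifnot(is.character(essay), length(essay) == 1L)
  .fill_template(.load_template("summarizer", template), list(essay = essay))
}

# Strict normalization of the summarizer verdict: strip punctuation and
# whitespace, case-fold, accept only exactly "yes"/"no".
.normalize_verdict <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) return(NA_character_)
  t <- tolower(gsub("[^a-z]", "", tolower(text)))
  if (identical(t, "yes")) "yes" else if (identical(t, "no")) "no"
  else NA_character_
}

#' Two-agent specificity classification of a case
#'
#' The evaluator agent writes a short essay assessing every candidate gene
#' against the phenotypes; the summarizer agent reads the essay and answers
#' Yes/No on whether at least one gene is directly linked. "Yes" labels the
#' case `specific`, "No" labels it `nonspecific`. A summarizer output
#' matching neither token is retried once; a second failure yields
#' `unevaluable`.
#'
#' @param case A [patient_case()].
#' @param evaluator Function `(prompt) -> essay text`.
#' @param summarizer Function `(prompt) -> verdict text`.
#' @param ont A [ontology()].
#' @return A data frame row of class `classification_label` with columns
#'   `case_id`, `method` (`"multi_agent"`), `label` (`"specific"`,
#'   `"nonspecific"` or `"unevaluable"`) and `evidence` (the essay).
#' @export
multi_agent_classify <- function(case, evaluator, summarizer, ont) {
  stopifnot(inherits(case, "patient_case"), is.function(evaluator),
            is.function(summarizer))
  essay <- evaluator(build_evaluator_prompt(case, ont))
  sprompt <- build_summarizer_prompt(essay)
  verdict <- .normalize_verdict(summarizer(sprompt))
  if (is.na(verdict)) verdict <- .normalize_verdict(summarizer(sprompt))
  label <- if (is.na(verdict)) {
    warning("case ", case$case_id,
            ": summarizer produced neither Yes nor No twice; unevaluable",
            call. = FALSE)
    "unevaluable"
  } else if (verdict == "yes") "specific" else "nonspecific"
  structure(data.frame(case_id = case$case_id, method = "multi_agent",
                       label = label, evidence = essay,
                       stringsAsFactors = FALSE),
            class = c("classification_label", "data.frame"))
}

#' Dataset specificity index (DsI) of a case's phenotype terms
#'
#' Summarizes how specific a case's phenotype description is: general terms
#' near the ontology root are penalized, specific terms near the leaves
#' rewarded. The default index is the mean, over the unique resolvable
#' terms, of `depth(t) / max_depth(ontology)` with shortest-path depths, so
#' it lies in \[0,1\]: 0 when every term is the root, 1 when every term is a
#' maximal-depth leaf. Replacing a term by one of its ancestors can never
#' increase the index. The cited published index weights the full depth
#' distribution; `index_fun` lets callers drop in any alternative
#' `function(depths, max_depth) -> value`.
#'
#' @param term_ids Character vector of term identifiers (a case's
#'   phenotype). Unresolvable identifiers are dropped with a warning; if
#'   none resolve an error is raised.
#' @param ont A [ontology()].
#' @param index_fun Specificity function of the unique term depths; default
#'   the depth mean described above.
#' @return List of class `specificity_result` with elements `dsi` (in
#'   \[0,1\] for the default index), `depths` (named integer vector over the
#'   unique resolved terms) and `max_depth`.
#' @examples
#' ont <- make_ontology(depth = 3, branching = 2, seed = 1)
#' dsi(ont$root, ont)$dsi  # 0
#' @export
dsi <- function(term_ids, ont, index_fun = NULL) {
  stopifnot(inherits(ont, "priorank_ontology"))
  .assert_character(term_ids, "term_ids")
  term_ids <- unique(term_ids)
  unresolved <- setdiff(term_ids, names(ont$terms))
  term_ids <- setdiff(term_ids, unresolved)
  if (length(term_ids) == 0L) {
    stop("no resolvable phenotype terms; cannot compute DsI (unresolved: ",
         paste(unresolved, collapse = ", "), ")", call. = FALSE)
  }
  if (length(unresolved)) {
    warning("dropping unresolvable terms: ",
            paste(unresolved, collapse = ", "), call. = FALSE)
  }
  depths <- term_depth(term_ids, ont)
  md <- max_depth(ont)
  value <- if (is.null(index_fun)) {
    if (md == 0L) 0 else mean(depths / md)
  } else {
    index_fun(depths, md)
  }
  structure(list(dsi = value, depths = depths, max_depth = md),
            class = "specificity_result")
}

#' Split cases into high/low specificity strata
#'
#' @param values Named numeric vector of DsI values (names = case ids), or a
#'   data frame with columns `case_id` and `dsi`.
#' @param policy `"median"` (default) labels cases strictly above the cohort
#'   median `high_dsi` and the rest `low_dsi`; `"threshold"` compares to a
#'   fixed cutoff `threshold` (strictly above = high).
#' @param threshold Cutoff for the `"threshold"` policy.
#' @return Data frame with columns `case_id`, `dsi`, `label`
#'   (`"high_dsi"` / `"low_dsi"`).
#' @export
split_by_dsi <- function(values, policy = c("median", "threshold"),
                         threshold = NULL) {
  policy <- match.arg(policy)
  if (is.data.frame(values)) {
    df <- data.frame(case_id = values$case_id, dsi = values$dsi,
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(names(values))) {
      stop("'values' must be named by case id", call. = FALSE)
    }
    df <- data.frame(case_id = names(values), dsi = unname(values),
                     stringsAsFactors = FALSE)
  }
  if (policy == "median") {
    if (nrow(df) < 2L) {
      stop("median split needs at least two cases", call. = FALSE)
    }
    cut <- stats::median(df$dsi)
    if (length(unique(df$dsi)) == 1L) {
      warning("all specificity values identical; every case labeled low_dsi",
              call. = FALSE)
    }
  } else {
    if (is.null(threshold)) {
      stop("threshold policy requires 'threshold'", call. = FALSE)
    }
    cut <- threshold
  }
  df$label <- ifelse(df$dsi > cut, "high_dsi", "low_dsi")
  df
}
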