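# Synthetic-cohort simulator: a miniature phenotype ontology, patient cases
# with known causal genes and controllable phenotype specificity, and
# heavy-tailed submission-count tables — everything the rest of the package
# needs, generated offline and reproducibly.

#' Generate a synthetic phenotype ontology
#'
#' Builds a rooted is-a tree of the requested depth and branching factor
#' with synthetic labels and definitions, optionally adding extra is-a
#' cross-links (from deeper to strictly shallower levels, so the graph stays
#' acyclic) to exercise DAG code paths. A pure tree has
#' `(branching^(depth+1) - 1) / (branching - 1)` terms. Identical seeds
#' yield identical ontologies (and identical OBO bytes via [write_obo()]).
#'
#' @param depth Tree depth (root = level 0); at least 1.
#' @param branching Children per internal node; at least 1.
#' @param seed Integer seed (used for cross-link placement).
#' @param cross_links Number of extra is-a edges to add (default 0 = tree).
#'   Requires `branching >= 2`.
#' @return A [ontology()] object.
#' @examples
#' make_ontology(depth = 4, branching = 3, seed = 1)  # 121 terms
#' @export
make_ontology <- function(depth, branching, seed = 1L, cross_links = 0L) {
  stopifnot(depth >= 1L, branching >= 1L, cross_links >= 0L)
  if (cross_links > 0L && branching < 2L) {
    stop("cross-links require branching >= 2 (a chain has no alternative parents)",
         call. = FALSE)
  }
  id_of <- function(i) sprintf("HP:%07d", i)
  terms <- list()
  level_of <- integer(0)
  nxt <- 1L
  terms[[id_of(1L)]] <- list(label = "Phenotypic abnormality (synthetic root)",
                             definition = "Root of the synthetic phenotype hierarchy.",
                             parents = character(0))
  level_of[1L] <- 0L
  frontier <- 1L
  nxt <- 2L
  for (lvl in seq_len(depth)) {
    new_frontier <- integer(0)
    for (parent in frontier) {
      for (b in seq_len(branching)) {
        i <- nxt
        nxt <- nxt + 1L
        terms[[id_of(i)]] <- list(
          label = sprintf("Synthetic phenotype %d (level %d)", i, lvl),
          definition = sprintf(
            "A synthetic phenotype term at hierarchy level %d, child %d of %s.",
            lvl, b, id_of(parent)),
          parents = id_of(parent))
        level_of[i] <- lvl
        new_frontier <- c(new_frontier, i)
      }
    }
    frontier <- new_frontier
  }
  if (cross_links > 0L) {
    withr::with_seed(as.integer(seed), {
      for (j in seq_len(cross_links)) {
        # pick a node at level >= 2 and add a parent from a strictly
        # shallower level: acyclicity is preserved by construction
        deep <- which(level_of >= 2L)
        child <- .sample1(deep)
        shallow <- which(level_of < level_of[child] &
                         seq_along(level_of) != 1L)
        if (!length(shallow)) next
        extra <- id_of(.sample1(shallow))
        cid <- id_of(child)
        terms[[cid]]$parents <- unique(c(terms[[cid]]$parents, extra))
      }
    })
  }
  ontology(terms)
}

#' Synthetic cohort specification
#'
#' The study conditions the simulator emulates: several cohorts of patient
#' cases (mirroring multi-site benchmarks of 90 cases per site), candidate
#' lists of sizes 5/25/50 built by sampling noncausal genes around one
#' causal gene, a specificity mix controlling how many cases carry deep
#' (specific) versus shallow (general) phenotype terms, and log-normal
#' submission counts.
#'
#' @param cohorts Named integer vector: cases per cohort label
#'   (default `c(BG = 90, UDN = 90, DDD = 90)`, i.e. 270 cases).
#' @param sizes Candidate-list sizes per case (default `c(5, 25, 50)`).
#' @param gene_pool_size Size of the synthetic gene universe (default 200).
#' @param specificity_mix Fraction of cases drawing deep phenotype terms
#'   (default 0.5).
#' @param terms_per_case Range (length-2 integer) of phenotype terms per
#'   case (default `c(5, 12)`).
#' @param count_mu,count_sigma Log-normal meanlog/sdlog of submission counts
#'   (defaults 2 and 1).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohorts = c(BG = 90L, UDN = 90L, DDD = 90L),
                        sizes = c(5L, 25L, 50L), gene_pool_size = 200L,
                        specificity_mix = 0.5, terms_per_case = c(5L, 12L),
                        count_mu = 2, count_sigma = 1, seed = 1L) {
  stopifnot(length(cohorts) >= 1L, all(cohorts > 0L),
            !is.null(names(cohorts)), all(nzchar(names(cohorts))),
            all(sizes >= 2L), gene_pool_size > max(sizes),
            length(terms_per_case) == 2L,
            terms_per_case[1] >= 1L,
            terms_per_case[2] >= terms_per_case[1])
  .assert_scalar_number(specificity_mix, "specificity_mix", 0, 1)
  .assert_scalar_number(count_sigma, "count_sigma")
  if (count_sigma <= 0) stop("count_sigma must be positive", call. = FALSE)
  structure(list(cohorts = cohorts, sizes = as.integer(sizes),
                 gene_pool_size = as.integer(gene_pool_size),
                 specificity_mix = specificity_mix,
                 terms_per_case = as.integer(terms_per_case),
                 count_mu = count_mu, count_sigma = count_sigma,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Synthetic submission-count table
#'
#' Independent log-normal draws rounded to nonnegative integers:
#' heavy-tailed by construction, mimicking how a few intensively studied
#' genes accumulate most database submissions.
#'
#' @param genes Character vector of gene symbols.
#' @param mu,sigma Log-normal meanlog and sdlog (`sigma > 0`).
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `submission_count`.
#' @export
make_counts <- function(genes, mu = 2, sigma = 1, seed = 1L) {
  genes <- .normalize_genes(genes)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    counts <- round(stats::rlnorm(length(genes), meanlog = mu, sdlog = sigma))
  })
  data.frame(gene = genes, submission_count = pmax(as.integer(counts), 0L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic patient cohort
#'
#' For each case: one causal gene drawn from the gene pool; candidate lists
#' of every requested size built with [build_candidate_sets()] (noncausal
#' genes sampled uniformly, causal gene inserted, list shuffled); phenotype
#' terms drawn from the deepest ontology depth quartile for high-specificity
#' cases and the shallowest (non-root) quartile for low-specificity cases.
#' One [patient_case()] is emitted per (case, size), with identifiers like
#' `"BG-007-n50"`. The truth table records everything downstream evaluation
#' needs without re-reading generation internals.
#'
#' @param spec A [cohort_spec()].
#' @param ont A [ontology()]; needs enough depth spread for distinct
#'   quartiles (e.g. `make_ontology(depth = 4, branching = 3)`).
#' @return List of class `synthetic_cohort` with elements `cases` (list of
#'   [patient_case()]), `truth` (data frame: `case_id`, `cohort`,
#'   `base_case`, `size`, `causal_gene`, `causal_input_position`,
#'   `causal_submission_count`, `specificity`), `counts` (full count table)
#'   and `gene_pool`.
#' @export
make_cohort <- function(spec, ont) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(ont, "priorank_ontology"))
  pool <- sprintf("GENE%04d", seq_len(spec$gene_pool_size))
  counts_df <- make_counts(pool, mu = spec$count_mu, sigma = spec$count_sigma,
                           seed = .mix_seed(spec$seed, 7L))
  counts <- stats::setNames(counts_df$submission_count, counts_df$gene)

  depths <- term_depth(names(ont$terms), ont)
  nonroot <- depths[depths > 0L]
  qs <- stats::quantile(nonroot, c(0.25, 0.75), names = FALSE)
  shallow_terms <- names(nonroot[nonroot <= qs[1]])
  deep_terms <- names(nonroot[nonroot >= qs[2]])
  if (!length(shallow_terms) || !length(deep_terms)) {
    stop("ontology too flat to separate specificity quartiles", call. = FALSE)
  }

  cases <- list()
  truth <- list()
  idx <- 0L
  withr::with_seed(spec$seed, {
    for (cohort in names(spec$cohorts)) {
      for (j in seq_len(spec$cohorts[[cohort]])) {
        idx <- idx + 1L
        base_id <- sprintf("%s-%03d", cohort, j)
        causal <- .sample1(pool)
        high_spec <- stats::runif(1) < spec$specificity_mix
        term_source <- if (high_spec) deep_terms else shallow_terms
        n_terms <- .sample1(seq(spec$terms_per_case[1],
                                spec$terms_per_case[2]))
        terms <- sample(term_source, min(n_terms, length(term_source)))
        sets <- build_candidate_sets(causal, setdiff(pool, causal),
                                     sizes = spec$sizes,
                                     seed = .mix_seed(spec$seed, idx, 3L))
        for (sz in names(sets)) {
          case_id <- sprintf("%s-n%s", base_id, sz)
          cases[[case_id]] <- patient_case(case_id, terms, sets[[sz]],
                                           causal_gene = causal)
          truth[[case_id]] <- data.frame(
            case_id = case_id, cohort = cohort, base_case = base_id,
            size = as.integer(sz), causal_gene = causal,
            causal_input_position = match(causal, sets[[sz]]),
            causal_submission_count = unname(counts[causal]),
            specificity = if (high_spec) "high" else "low",
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  structure(list(cases = unname(cases), truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 counts = counts_df, gene_pool = pool),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases (%d base patients), %d-gene pool\n",
              length(x$cases), length(unique(x$truth$base_case)),
              length(x$gene_pool)))
  invisible(x)
}
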