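#' Construct a patient case
#'
#' A patient case bundles the clinical phenotype (ordered ontology term
#' identifiers), the ordered candidate gene list the prioritizer must rank,
#' and — for benchmark cases — the known causal gene hidden inside that list.
#'
#' @param case_id Case identifier string.
#' @param phenotype_terms Character vector of ontology term identifiers
#'   (at least one).
#' @param candidate_genes Character vector of unique gene symbols
#'   (case-normalized to uppercase at ingestion).
#' @param causal_gene Optional causal gene symbol; must be a member of
#'   `candidate_genes`.
#' @return An object of class `patient_case`.
#' @export
patient_case <- function(case_id, phenotype_terms, candidate_genes,
                         causal_gene = NULL) {
  stopifnot(is.character(case_id), length(case_id) == 1L, nzchar(case_id))
  .assert_character(phenotype_terms, "phenotype_terms")
  if (length(phenotype_terms) == 0L) {
    stop("a patient case needs at least one phenotype term", call. = FALSE)
  }
  candidate_genes <- .normalize_genes(candidate_genes)
  if (length(candidate_genes) == 0L) {
    stop("a patient case needs at least one candidate gene", call. = FALSE)
  }
  if (!is.null(causal_gene)) {
    causal_gene <- .normalize_genes(causal_gene)
    if (length(causal_gene) != 1L) {
      stop("'causal_gene' must be a single symbol", call. = FALSE)
    }
    if (!causal_gene %in% candidate_genes) {
      stop("causal gene '", causal_gene, "' is not among the candidate genes",
           call. = FALSE)
    }
  }
  structure(list(case_id = case_id,
                 phenotype_terms = phenotype_terms,
                 candidate_genes = candidate_genes,
                 causal_gene = causal_gene),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case> %s: %d phenotype terms, %d candidate genes%s\n",
              x$case_id, length(x$phenotype_terms), length(x$candidate_genes),
              if (is.null(x$causal_gene)) "" else
                paste0(" (causal: ", x$causal_gene, ")")))
  invisible(x)
}

#' Build shuffled candidate gene sets of several sizes
#'
#' For one patient with a known causal gene, draws candidate lists of the
#' requested sizes by uniform sampling without replacement from the pool of
#' noncausal genes, inserting the causal gene, and shuffling — so the causal
#' gene's position is uniform over list positions. The same seed reproduces
#' the same lists.
#'
#' @param causal_gene Causal gene symbol (must not be in the pool).
#' @param noncausal_pool Character vector of noncausal gene symbols; must
#'   hold at least `max(sizes) - 1` genes.
#' @param sizes Integer vector of list sizes (default `c(5, 25, 50)`).
#' @param seed Integer seed for the sampling and shuffling.
#' @return Named list (names = sizes); each element a character vector of
#'   length `size` containing `causal_gene` exactly once.
#' @examples
#' sets <- build_candidate_sets("CAUSAL", paste0("G", 1:60), c(5, 25), seed = 1)
#' lengths(sets)  # 5 25
#' @export
build_candidate_sets <- function(causal_gene, noncausal_pool,
                                 sizes = c(5L, 25L, 50L), seed) {
  causal_gene <- .normalize_genes(causal_gene)
  stopifnot(length(causal_gene) == 1L)
  noncausal_pool <- .normalize_genes(noncausal_pool)
  if (causal_gene %in% noncausal_pool) {
    stop("causal gene '", causal_gene, "' must not appear in the noncausal pool",
         call. = FALSE)
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 1L)) stop("sizes must be positive", call. = FALSE)
  need <- max(sizes) - 1L
  if (length(noncausal_pool) < need) {
    stop(sprintf(
      "noncausal pool too small: need %d genes for the largest list, have %d",
      need, length(noncausal_pool)), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    out <- lapply(sizes, function(sz) {
      picked <- sample(noncausal_pool, sz - 1L)
      sample(c(picked, causal_gene))
    })
  })
  stats::setNames(out, as.character(sizes))
}

#' Read patient cases from a JSON file
#'
#' The case file is a JSON array; each object has keys `case_id`,
#' `phenotype_terms` (strings like `"HP:0001250"`), `candidate_genes` and
#' `causal_gene` (may be `null`).
#'
#' @param path Path to the JSON case file.
#' @return List of [patient_case()] objects.
#' @export
read_cases <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    patient_case(case_id = r$case_id,
                 phenotype_terms = unlist(r$phenotype_terms),
                 candidate_genes = unlist(r$candidate_genes),
                 causal_gene = if (is.null(r$causal_gene)) NULL
                               else r$causal_gene)
  })
}

#' Write patient cases to a JSON file
#'
#' @param cases List of [patient_case()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  payload <- lapply(cases, function(cs) {
    stopifnot(inherits(cs, "patient_case"))
    list(case_id = cs$case_id,
         phenotype_terms = cs$phenotype_terms,
         candidate_genes = cs$candidate_genes,
         causal_gene = cs$causal_gene)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
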