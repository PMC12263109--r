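#' Construct a phenotype ontology object
#'
#' An `priorank_ontology` is a rooted directed acyclic is-a hierarchy of
#' phenotype terms, each carrying a human-readable label and (optionally) a
#' textual definition. It is the in-memory form of the subset of an OBO file
#' that phenotype-driven gene prioritization needs: `id`, `name`, `def` and
#' `is_a` tags.
#'
#' @param terms Named list; one entry per term identifier, each a list with
#'   elements `label` (string), `definition` (string, may be `""`) and
#'   `parents` (character vector of parent identifiers, empty for the root).
#' @param root Identifier of the unique root term (the single term with no
#'   parents).
#'
#' @return An object of class `priorank_ontology` with elements `terms` and
#'   `root`.
#'
#' @details The constructor validates that exactly one term has no parents,
#'   that every parent identifier resolves, that the graph is acyclic, and
#'   that every term reaches the root via is-a links.
#'
#' @seealso [read_obo()], [write_obo()], [term_depth()], [make_ontology()]
#' @export
ontology <- function(terms, root = NULL) {
  if (!is.list(terms) || is.null(names(terms)) || anyDuplicated(names(terms))) {
    stop("'terms' must be a uniquely named list of term records", call. = FALSE)
  }
  ids <- names(terms)
  n_parents <- vapply(terms, function(t) length(t$parents), integer(1))
  roots <- ids[n_parents == 0L]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root (term without parents); found ",
         length(roots), call. = FALSE)
  }
  if (is.null(root)) root <- roots
  if (!identical(root, roots)) {
    stop("declared root '", root, "' is not the parentless term '", roots, "'",
         call. = FALSE)
  }
  all_parents <- unique(unlist(lapply(terms, `[[`, "parents"), use.names = FALSE))
  unknown <- setdiff(all_parents, ids)
  if (length(unknown)) {
    stop("parent identifiers not defined as terms: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  obj <- structure(list(terms = terms, root = root), class = "priorank_ontology")
  depths <- .all_term_depths(obj)
  if (anyNA(depths)) {
    stop("terms cannot reach the root via is-a links: ",
         paste(ids[is.na(depths)], collapse = ", "), call. = FALSE)
  }
  attr(obj, ".depths") <- depths
  obj
}

#' @export
print.priorank_ontology <- function(x, ...) {
  cat(sprintf("<priorank_ontology> %d terms, root %s (max depth %d)\n",
              length(x$terms), x$root, max_depth(x)))
  invisible(x)
}

# Shortest-path depth of every term: breadth-first search downward from the
# root over child edges. Upward cycles would leave a term unreached, so this
# also serves as the acyclicity/reachability check. Returns named integer
# vector with NA for unreachable terms.
.all_term_depths <- function(ont) {
  ids <- names(ont$terms)
  children <- vector("list", length(ids))
  names(children) <- ids
  for (id in ids) {
    for (p in ont$terms[[id]]$parents) {
      children[[p]] <- c(children[[p]], id)
    }
  }
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[ont$root] <- 0L
  frontier <- ont$root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

#' Shortest-path depth of ontology terms
#'
#' The depth of a term is the length of the shortest is-a path from the term
#' up to the root; the root has depth 0. In a DAG with multiple parentage the
#' shortest path is used, which is the conservative choice for specificity:
#' a term is only as specific as its most general placement.
#'
#' @param term_ids Character vector of term identifiers.
#' @param ont A [ontology()] object.
#' @return Integer vector of depths, named by `term_ids`.
#' @examples
#' ont <- make_ontology(depth = 2, branching = 2, seed = 1)
#' term_depth(ont$root, ont)  # 0
#' @export
term_depth <- function(term_ids, ont) {
  stopifnot(inherits(ont, "priorank_ontology"))
  .assert_character(term_ids, "term_ids")
  missing <- setdiff(term_ids, names(ont$terms))
  if (length(missing)) {
    stop("unknown ontology terms: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  depths <- .ontology_depths(ont)
  stats::setNames(depths[term_ids], term_ids)
}

# Depths are computed once per ontology object and memoized in an attribute
# lookup keyed off the environment-free object; recompute on demand.
.ontology_depths <- function(ont) {
  d <- attr(ont, ".depths")
  if (is.null(d)) d <- .all_term_depths(ont)
  d
}

#' Maximum term depth of an ontology
#'
#' @inheritParams term_depth
#' @return Integer, the largest shortest-path depth over all terms.
#' @export
max_depth <- function(ont) {
  stopifnot(inherits(ont, "priorank_ontology"))
  max(.ontology_depths(ont))
}

#' Convert phenotype term identifiers to text
#'
#' Scoring backends consume text, not term identifiers: numerical phenotype
#' codes are replaced by their labels or definitions so a language model does
#' not have to (and cannot mis-)recall what a code means. Order is preserved
#' and duplicated identifiers are collapsed to their first occurrence so the
#' resulting prompt is deterministic.
#'
#' @param term_ids Character vector of term identifiers (e.g. `"HP:0001250"`).
#' @param ont A [ontology()] object.
#' @param mode `"definition"` (default) uses the term definition, falling back
#'   to the label when no definition is recorded; `"label"` always uses the
#'   label.
#' @return Character vector of nonempty strings, one per unique identifier,
#'   in first-occurrence order.
#' @export
terms_to_text <- function(term_ids, ont, mode = c("definition", "label")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ont, "priorank_ontology"))
  .assert_character(term_ids, "term_ids")
  term_ids <- term_ids[!duplicated(term_ids)]
  unresolved <- setdiff(term_ids, names(ont$terms))
  if (length(unresolved)) {
    stop("unresolved ontology terms: ", paste(unresolved, collapse = ", "),
         call. = FALSE)
  }
  out <- vapply(term_ids, function(id) {
    t <- ont$terms[[id]]
    txt <- if (mode == "definition" && nzchar(t$definition %||% "")) {
      t$definition
    } else {
      t$label
    }
    if (!nzchar(txt)) {
      stop("term ", id, " has neither definition nor label text", call. = FALSE)
    }
    txt
  }, character(1))
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a minimal OBO ontology file
#'
#' Parses `[Term]` stanzas, honouring only the tags needed here: `id`,
#' `name`, `def` (the quoted string) and `is_a` (trailing `! comment`
#' stripped). Obsolete terms (`is_obsolete: true`) are skipped.
#'
#' @param path Path to an OBO file.
#' @return A [ontology()] object.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(terms)
    terms[[cur$id]] <- list(label = cur$label %||% "",
                            definition = cur$definition %||% "",
                            parents = cur$parents %||% character(0))
    terms
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(parents = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) {  # another stanza type ([Typedef] etc.)
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (startsWith(ln, "name:")) {
      cur$label <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "def:")) {
      m <- regmatches(ln, regexpr('"[^"]*"', ln))
      cur$definition <- if (length(m)) gsub('"', "", m) else ""
    } else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
    } else if (startsWith(ln, "is_obsolete:")) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas found in ", path, call. = FALSE)
  ontology(terms)
}

#' Write an ontology to OBO format
#'
#' Serializes only the tags [read_obo()] consumes, so generated ontologies
#' round-trip losslessly. Terms are written in identifier order for
#' byte-reproducible output.
#'
#' @param ont A [ontology()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  stopifnot(inherits(ont, "priorank_ontology"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in sort(names(ont$terms))) {
    t <- ont$terms[[id]]
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", t$label), con)
    if (nzchar(t$definition %||% "")) {
      writeLines(sprintf('def: "%s" []', t$definition), con)
    }
    for (p in sort(t$parents)) {
      writeLines(paste0("is_a: ", p), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
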