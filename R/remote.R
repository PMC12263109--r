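# Remote-backend adapter. This is an integration contract: transport (the
# function that actually talks to a scoring service) is injected, nothing in
# the package opens a network connection, and the test suite exercises the
# adapter only with scripted transports.

#' Remote scorer configuration
#'
#' @param model Model identifier string passed to the service.
#' @param temperature Sampling temperature (default 0).
#' @param max_output_tokens Output clipping limit (default 512).
#' @param minibatch_size Genes per service call; longer candidate lists are
#'   split into chunks of this size and the parsed vectors merged
#'   (default 25).
#' @param max_retries Bounded transport retries before a typed error
#'   (default 3).
#' @param template Optional ranking-prompt template override.
#' @return An object of class `remote_scorer_config`.
#' @export
remote_scorer_config <- function(model, temperature = 0,
                                 max_output_tokens = 512L,
                                 minibatch_size = 25L, max_retries = 3L,
                                 template = NULL) {
  stopifnot(is.character(model), length(model) == 1L)
  .assert_scalar_number(temperature, "temperature", lower = 0)
  stopifnot(minibatch_size >= 1L, max_retries >= 0L)
  structure(list(model = model, temperature = temperature,
                 max_output_tokens = as.integer(max_output_tokens),
                 minibatch_size = as.integer(minibatch_size),
                 max_retries = as.integer(max_retries),
                 template = template),
            class = "remote_scorer_config")
}

#' Read a scorer backend configuration from YAML
#'
#' The YAML file names the backend (`synthetic` or `remote`) and its
#' parameters; remote entries map onto [remote_scorer_config()], synthetic
#' entries onto [synthetic_scorer_params()].
#'
#' @param path Path to the YAML file.
#' @return A `remote_scorer_config` or `synthetic_scorer_params` object.
#' @export
read_backend_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  backend <- cfg$backend %||% stop("backend config needs a 'backend' key",
                                   call. = FALSE)
  if (backend == "synthetic") {
    do.call(synthetic_scorer_params,
            cfg[intersect(names(cfg),
                          c("signal", "beta_pos", "beta_lit", "noise_sd",
                            "intercept", "seed"))])
  } else if (backend == "remote") {
    do.call(remote_scorer_config,
            cfg[intersect(names(cfg),
                          c("model", "temperature", "max_output_tokens",
                            "minibatch_size", "max_retries", "template"))])
  } else {
    stop("unknown backend '", backend, "'", call. = FALSE)
  }
}

# Single transport attempt loop with bounded retries. `transport` is
# function(prompt, config) -> list(text =, truncated = logical).
.remote_call <- function(prompt, config, transport) {
  if (is.null(transport)) {
    stop(structure(class = c("priorank_transport_error", "error", "condition"),
                   list(message = paste(
                     "no transport configured: remote scoring requires a",
                     "service adapter and credentials"),
                     call = NULL)))
  }
  last <- NULL
  for (attempt in seq_len(config$max_retries + 1L)) {
    res <- tryCatch(transport(prompt, config), error = function(e) e)
    if (!inherits(res, "error")) return(res)
    last <- res
  }
  stop(structure(class = c("priorank_transport_error", "error", "condition"),
                 list(message = paste0("transport failed after ",
                                       config$max_retries + 1L, " attempts: ",
                                       conditionMessage(last)),
                      call = NULL)))
}

#' Score a case's candidate genes through a remote backend
#'
#' Splits the candidate list into mini-batches of `config$minibatch_size`,
#' builds one ranking prompt per batch, sends each through the injected
#' transport with bounded retries, parses the replies with
#' [parse_ranking_response()] and merges the per-batch vectors into one
#' [score_vector()]. A truncated reply is re-prompted exactly once and the
#' merged vector carries the `reprompted` flag.
#'
#' @param case A [patient_case()].
#' @param ont A [ontology()].
#' @param config A [remote_scorer_config()].
#' @param transport Function `(prompt, config) -> list(text =, truncated =)`
#'   performing the actual service call. `NULL` (the default) raises a typed
#'   `priorank_transport_error`, making accidental live calls impossible.
#' @return A [score_vector()] over the case's candidate genes.
#' @export
remote_score_case <- function(case, ont, config, transport = NULL) {
  stopifnot(inherits(case, "patient_case"),
            inherits(config, "remote_scorer_config"))
  genes <- case$candidate_genes
  batches <- split(genes, ceiling(seq_along(genes) / config$minibatch_size))
  parts <- lapply(batches, function(chunk) {
    prompt <- build_ranking_prompt(case, ont, genes = chunk,
                                   template = config$template)
    res <- .remote_call(prompt, config, transport)
    if (isTRUE(res$truncated)) {  # one re-prompt for clipped output
      res <- .remote_call(prompt, config, transport)
      sv <- parse_ranking_response(res$text %||% "", chunk)
      attr(sv, "flags") <- unique(c(score_flags(sv), "reprompted"))
      sv
    } else {
      parse_ranking_response(res$text %||% "", chunk)
    }
  })
  merged <- do.call(rbind, lapply(parts, as.data.frame))
  flags <- unique(unlist(lapply(parts, score_flags)))
  score_vector(merged$gene, merged$score, provenance = "verbal",
               flags = flags, missing = merged$missing)
}
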