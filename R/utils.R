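# Internal helpers shared across modules.

# Cheap deterministic string hash used to derive sub-seeds for the synthetic
# scorer. Collisions are harmless (two inputs sharing a noise draw), so a
# simple weighted code sum is enough; values stay well inside 32-bit range.
.str_hash <- function(x) {
  codes <- utf8ToInt(paste(x, collapse = "\r"))
  if (length(codes) == 0L) return(0L)
  w <- (seq_along(codes) %% 64L) + 1L
  as.integer(sum(as.numeric(codes) * w) %% 1000003)
}

# Combine seed components into a valid 32-bit seed.
.mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  as.integer(sum(parts * c(7919, 104729, 31, 17, 13)[seq_along(parts)]) %% 2147483647)
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

.assert_character <- function(x, name) {
  if (!is.character(x) || anyNA(x)) {
    stop(sprintf("'%s' must be a character vector without NA", name), call. = FALSE)
  }
  invisible(x)
}

# sample() treats a length-1 numeric as 1:n; this never does.
.sample1 <- function(x) x[sample.int(length(x), 1L)]

# Normalize gene symbols: uppercase, trimmed. Duplicates after normalization
# are an input error because they would silently merge distinct rows.
.normalize_genes <- function(genes, allow_duplicates = FALSE) {
  .assert_character(genes, "genes")
  out <- toupper(trimws(genes))
  if (!allow_duplicates && anyDuplicated(out)) {
    dup <- unique(out[duplicated(out)])
    stop("duplicate gene symbols after case normalization: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out
}
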