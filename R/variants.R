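#' Read an annotated variant table
#'
#' Reads a TSV with header columns `gene`, `af` (population allele frequency,
#' fraction in \[0,1\]), `clinvar_class` (one of `pathogenic`,
#' `likely_pathogenic`, `benign`, `likely_benign`, `vus`, `unknown`) and
#' `spliceai` (splice-impact score in \[0,1\]). A `.` denotes an absent value.
#' Rows are validated; a frequency outside \[0,1\] raises an error naming the
#' offending line.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `gene`, `af`, `clinvar_class`,
#'   `spliceai` (`NA` for absent values).
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = ".",
                          check.names = FALSE)
  required <- c("gene", "af", "clinvar_class", "spliceai")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("variant table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    gene = toupper(trimws(df$gene)),
    af = suppressWarnings(as.numeric(df$af)),
    clinvar_class = ifelse(is.na(df$clinvar_class), "unknown",
                           tolower(trimws(df$clinvar_class))),
    spliceai = suppressWarnings(as.numeric(df$spliceai)),
    stringsAsFactors = FALSE
  )
  .validate_variants(out)
  out
}

.variant_classes <- c("pathogenic", "likely_pathogenic", "benign",
                      "likely_benign", "vus", "unknown")

.validate_variants <- function(variants) {
  bad_af <- which(is.na(variants$af) | variants$af < 0 | variants$af > 1)
  if (length(bad_af)) {
    stop("allele frequency outside [0, 1] (or missing) at row(s): ",
         paste(bad_af, collapse = ", "), call. = FALSE)
  }
  bad_cls <- which(!variants$clinvar_class %in% .variant_classes)
  if (length(bad_cls)) {
    stop("unrecognized clinical classification at row(s): ",
         paste(bad_cls, collapse = ", "), call. = FALSE)
  }
  present <- !is.na(variants$spliceai)
  bad_sp <- which(present & (variants$spliceai < 0 | variants$spliceai > 1))
  if (length(bad_sp)) {
    stop("splice score outside [0, 1] at row(s): ",
         paste(bad_sp, collapse = ", "), call. = FALSE)
  }
  invisible(variants)
}

#' Filter variants to a candidate gene set
#'
#' A variant passes if it satisfies at least one of three disjunctive
#' criteria: rare (allele frequency strictly below `af_max`), clinically
#' flagged (classification among `pathogenic_classes`), or splice-disrupting
#' (splice score strictly above `splice_min`). Both numeric comparisons are
#' strict; a variant sitting exactly on a threshold fails that criterion.
#' A gene enters the candidate set if any of its variants passes; genes are
#' deduplicated. An absent splice score fails the splice criterion — absence
#' of evidence never passes a filter.
#'
#' @param variants Data frame as returned by [read_variant_table()], or any
#'   data frame with columns `gene`, `af`, `clinvar_class`, `spliceai`.
#' @param af_max Allele-frequency cutoff (default 0.01, i.e. "rarer than 1%").
#' @param pathogenic_classes Classifications that pass the clinical criterion.
#' @param splice_min Splice-score cutoff (default 0.8).
#' @return Character vector of unique gene symbols, in first-passing order.
#' @examples
#' v <- data.frame(gene = c("A", "B"), af = c(0.005, 0.5),
#'                 clinvar_class = c("unknown", "benign"),
#'                 spliceai = c(NA, 0.2))
#' filter_variants(v)  # "A"
#' @export
filter_variants <- function(variants, af_max = 0.01,
                            pathogenic_classes = c("pathogenic",
                                                   "likely_pathogenic"),
                            splice_min = 0.8) {
  .validate_variants(variants)
  .assert_scalar_number(af_max, "af_max", 0, 1)
  .assert_scalar_number(splice_min, "splice_min", 0, 1)
  keep <- variants$af < af_max |
    variants$clinvar_class %in% pathogenic_classes |
    (!is.na(variants$spliceai) & variants$spliceai > splice_min)
  unique(toupper(variants$gene[keep]))
}
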