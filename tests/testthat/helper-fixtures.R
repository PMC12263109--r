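# Hand-built fixture ontology with known depths:
#   ROOT(0) -> A(1) -> B(2) -> C(3) -> D(4)
#   X has parents B (depth 2) and D (depth 4)  => shortest-path depth 3
#   LBL has a label but no definition          => label fallback
tiny_ontology <- function() {
  ontology(list(
    "HP:0000001" = list(label = "All", definition = "The root term.",
                        parents = character(0)),
    "HP:0000002" = list(label = "abnormal gait",
                        definition = "An abnormality of walking.",
                        parents = "HP:0000001"),
    "HP:0000003" = list(label = "spastic gait",
                        definition = "A stiff, scissoring walk.",
                        parents = "HP:0000002"),
    "HP:0000004" = list(label = "progressive spastic gait",
                        definition = "Spastic gait worsening over time.",
                        parents = "HP:0000003"),
    "HP:0000005" = list(label = "childhood-onset progressive spastic gait",
                        definition = "Progressive spastic gait from childhood.",
                        parents = "HP:0000004"),
    "HP:0000006" = list(label = "mixed-parentage gait anomaly",
                        definition = "A gait anomaly with two placements.",
                        parents = c("HP:0000003", "HP:0000005")),
    "HP:0000007" = list(label = "label-only term", definition = "",
                        parents = "HP:0000001")
  ))
}

tiny_case <- function(genes = c("PAX6", "BRCA2", "TTN", "MECP2", "SCN1A"),
                      causal = "PAX6",
                      terms = c("HP:0000002", "HP:0000004")) {
  patient_case("fixture-1", terms, genes, causal_gene = causal)
}

# Scorer returning fixed per-gene scores regardless of grouping/salt.
scripted_scorer <- function(map) {
  function(genes, salt = 0L) unname(map[genes])
}

# Scorer whose replies vary by salt: map is list(salt -> named scores);
# entries equal to "refuse" produce a refusal score_vector.
salted_scorer <- function(by_salt) {
  function(genes, salt = 0L) {
    entry <- by_salt[[as.character(salt)]]
    if (identical(entry, "refuse")) {
      return(score_vector(genes, rep(0, length(genes)), provenance = "verbal",
                          flags = "refusal",
                          missing = rep(TRUE, length(genes))))
    }
    unname(entry[genes])
  }
}

# Brute-force oracle for the three-clause variant filter: evaluates the
# disjunction literally, one variant at a time, then unions genes.
oracle_filter <- function(variants, af_max = 0.01,
                          patho = c("pathogenic", "likely_pathogenic"),
                          splice_min = 0.8) {
  kept <- character(0)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    pass <- FALSE
    if (v$af < af_max) pass <- TRUE
    if (v$clinvar_class %in% patho) pass <- TRUE
    if (!is.na(v$spliceai) && v$spliceai > splice_min) pass <- TRUE
    if (pass) kept <- union(kept, toupper(v$gene))
  }
  kept
}
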