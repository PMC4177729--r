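# Internal constants, condition constructors and string normalisation.

.RAG_GROUPS <- c("red", "amber", "green")
.RAG_WEIGHTS <- c(red = 3, amber = 2, green = 1)
.EVENT_CLASSES <- c("initiation_primary", "progression_secondary")
.ABERRATION_KINDS <- c("translocation", "trisomy", "deletion", "gain", "mutation")
.CYTOGENETIC_KINDS <- c("translocation", "trisomy", "deletion", "gain")
.DETECTION_METHODS <- c("FISH", "karyotype", "GEP", "sequencing")
.CONSEQUENCES <- c("nonsynonymous", "synonymous", "other")
.EVIDENCE_LEVELS <- c("I", "II", "III", "IV", "V")
.EVIDENCE_GRADES <- c("A", "B", "C", "D")
.RISK_BANDS <- c("low", "low_intermediate", "high_intermediate", "high")

# Lesions whose accumulation (>1) with ISS stage II/III defines the
# ultrahigh-risk group: 1q gain, del(17p) and the adverse IGH@
# translocations.
.ADVERSE_CATEGORIES <- c("+1q", "Del(17p)", "t(4;14)", "t(14;16)", "t(14;20)")

#' Adverse lesion categories
#'
#' The category names whose co-occurrence defines ultrahigh risk when
#' combined with ISS stage II or III: `+1q`, `Del(17p)` and the adverse
#' IGH translocations `t(4;14)`, `t(14;16)`, `t(14;20)`.
#'
#' @return Character vector of five category names.
#' @export
#' @examples
#' adverseCategories()
adverseCategories <- function() .ADVERSE_CATEGORIES

## Conditions -----------------------------------------------------------

ragValidationError <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("rag_validation_error", "rag_error")))
}

ragIOError <- function(...) {
  stop(errorCondition(paste0(...), class = c("rag_io_error", "rag_error")))
}

## Normalisation --------------------------------------------------------

# Canonical lesion notation: whitespace stripped, lower case, trisomies
# reduced to the bare chromosome token, gains prefixed "+".
normalizeDescriptor <- function(kind, descriptor) {
  s <- tolower(gsub("[[:space:]]+", "", as.character(descriptor)))
  if (kind == "trisomy") {
    s <- sub("^\\+", "", sub("^chr", "", s))
  } else if (kind == "gain" && nzchar(s) && !startsWith(s, "+")) {
    s <- paste0("+", s)
  }
  s
}

normalizeGene <- function(gene) toupper(gsub("[[:space:]]+", "", gene))

# Resolve gene symbols through an optional alias map (names = alias,
# values = canonical KB spelling); matching is case-insensitive.
resolveAliases <- function(genes, aliases = NULL) {
  g <- normalizeGene(genes)
  if (length(aliases)) {
    map <- setNames(as.character(aliases), normalizeGene(names(aliases)))
    hit <- g %in% names(map)
    g[hit] <- normalizeGene(map[g[hit]])
  }
  g
}

# Coarse functional-consequence classing for annotated variants. Protein-
# altering terms dominate; explicitly silent terms are "synonymous";
# anything unrecognised is "other" and is retained downstream.
classifyConsequence <- function(term) {
  t <- tolower(term)
  nonsyn <- paste0("missense|frameshift|stop_gained|stop_lost|start_lost|",
                   "nonsense|splice_acceptor|splice_donor|inframe|",
                   "protein_altering|non[_-]?synonymous")
  vapply(t, function(x) {
    if (grepl(nonsyn, x)) "nonsynonymous"
    else if (grepl("synonymous|stop_retained|start_retained|silent", x)) "synonymous"
    else "other"
  }, character(1), USE.NAMES = FALSE)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Stable numeric formatting for deterministic file output.
fmtNum <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}
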