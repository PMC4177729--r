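# Knowledge-base construction, YAML (de)serialisation and gene lookup.

#' Build the default RAG knowledge base
#'
#' Loads the 22-category knowledge base shipped with the package: the
#' hyperdiploid trisomy set, six IGH translocations, `+1q`, eight
#' chromosome-arm deletions, secondary `t(8;14)`, and seven functional
#' mutation categories, each with its candidate genes, red/amber/green
#' group and evidence metadata. The tier assignment (red =
#' `Del(17p)`, `t(14;16)`, `t(14;20)`, `+1q`; green = `Hyperdiploidy`,
#' `t(11;14)`, `t(6;14)`; amber = everything else, including `t(4;14)`)
#' reconstructs the model's stated tiering rules; see the knowledge-base
#' `provenance` field and the package vignette.
#'
#' @return A validated [RagKnowledgeBase-class] with exactly 22
#'   categories.
#' @export
#' @examples
#' kb <- buildDefaultKB()
#' kb
#' lookupGene(kb, "TP53")
buildDefaultKB <- function() {
  loadKB(system.file("extdata", "rag_kb.yaml", package = "ragmm",
                     mustWork = TRUE))
}

#' Load a knowledge base from a YAML document
#'
#' Reads and validates a knowledge-base configuration. The document must
#' carry a top-level `version` and a `categories` list; every category
#' needs `name`, `event_class` (`initiation_primary` or
#' `progression_secondary`), `group` (`red`/`amber`/`green`), a non-empty
#' `candidate_genes` list, and optionally `cytogenetic:` (`kind` +
#' `descriptors`) and `evidence:` (`level`, `grade`, `note`). Any
#' violation raises a validation error naming the offending field.
#'
#' @param path Path to a YAML knowledge-base document (see
#'   `system.file("extdata", "rag_kb.yaml", package = "ragmm")`).
#' @return A validated [RagKnowledgeBase-class].
#' @seealso [writeKB()] for the inverse, [buildDefaultKB()].
#' @export
loadKB <- function(path) {
  if (!file.exists(path)) ragIOError("knowledge-base file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    ragValidationError("cannot parse knowledge-base YAML '", path, "': ",
                       conditionMessage(e)))
  kbFromList(doc)
}

# Validate a parsed KB document and construct the S4 object.
kbFromList <- function(doc) {
  if (!is.list(doc) || is.null(doc$version))
    ragValidationError("knowledge base must declare a 'version'")
  if (is.null(doc$categories) || !length(doc$categories))
    ragValidationError("knowledge base must declare a non-empty 'categories' list")
  cats <- lapply(seq_along(doc$categories), function(i) {
    c0 <- doc$categories[[i]]
    where <- sprintf("category %d ('%s')", i,
                     if (is.null(c0$name)) "?" else c0$name)
    for (field in c("name", "event_class", "group"))
      if (is.null(c0[[field]]) || !nzchar(as.character(c0[[field]])[1]))
        ragValidationError(where, ": missing required field '", field, "'")
    if (!c0$group %in% .RAG_GROUPS)
      ragValidationError(where, ": unknown group '", c0$group,
                         "' (must be red, amber or green)")
    if (!c0$event_class %in% .EVENT_CLASSES)
      ragValidationError(where, ": unknown event_class '", c0$event_class, "'")
    genes <- unlist(c0$candidate_genes, use.names = FALSE)
    if (!length(genes))
      ragValidationError(where, ": 'candidate_genes' must be non-empty")
    kind <- character(0); pattern <- character(0)
    if (!is.null(c0$cytogenetic)) {
      kind <- as.character(c0$cytogenetic$kind)
      pattern <- as.character(unlist(c0$cytogenetic$descriptors,
                                     use.names = FALSE))
      if (length(kind) != 1L || !kind %in% .CYTOGENETIC_KINDS)
        ragValidationError(where, ": 'cytogenetic.kind' must be one of ",
                           paste(.CYTOGENETIC_KINDS, collapse = ", "))
      if (!length(pattern))
        ragValidationError(where, ": 'cytogenetic.descriptors' must be non-empty")
      pattern <- vapply(pattern, function(d) normalizeDescriptor(kind, d),
                        character(1), USE.NAMES = FALSE)
    }
    ev <- c0$evidence
    obj <- try(new("RagCategory", name = as.character(c0$name),
                   eventClass = as.character(c0$event_class),
                   candidateGenes = as.character(genes),
                   cytogeneticKind = kind, cytogeneticPattern = pattern,
                   group = as.character(c0$group),
                   evidenceLevel = if (is.null(ev$level)) "V" else as.character(ev$level),
                   evidenceGrade = if (is.null(ev$grade)) "D" else as.character(ev$grade),
                   evidenceNote = if (is.null(ev$note)) "" else as.character(ev$note)),
               silent = TRUE)
    if (inherits(obj, "try-error"))
      ragValidationError(where, ": ", attr(obj, "condition")$message)
    obj
  })
  nm <- vapply(cats, function(x) x@name, character(1))
  if (anyDuplicated(nm))
    ragValidationError("duplicate category name(s): ",
                       paste(unique(nm[duplicated(nm)]), collapse = ", "))
  new("RagKnowledgeBase", categories = cats,
      version = as.character(doc$version),
      provenance = if (is.null(doc$provenance)) "" else
        as.character(doc$provenance))
}

# Inverse of kbFromList.
kbToList <- function(kb) {
  list(version = kb@version, provenance = kb@provenance,
       categories = lapply(kb@categories, function(x) {
         out <- list(name = x@name, event_class = x@eventClass,
                     group = x@group,
                     candidate_genes = as.list(x@candidateGenes))
         if (length(x@cytogeneticKind))
           out$cytogenetic <- list(kind = x@cytogeneticKind,
                                   descriptors = as.list(x@cytogeneticPattern))
         out$evidence <- list(level = x@evidenceLevel,
                              grade = x@evidenceGrade,
                              note = x@evidenceNote)
         out
       }))
}

#' Serialise a knowledge base to YAML
#'
#' Writes `kb` in the same schema [loadKB()] reads, so that
#' `loadKB(writeKB(kb, path))` reproduces `kb` exactly.
#'
#' @param kb A [RagKnowledgeBase-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeKB <- function(kb, path) {
  stopifnot(is(kb, "RagKnowledgeBase"))
  ok <- try(yaml::write_yaml(kbToList(kb), path), silent = TRUE)
  if (inherits(ok, "try-error"))
    ragIOError("cannot write knowledge base to '", path, "'")
  invisible(path)
}

#' Find every category listing a gene
#'
#' Case-insensitive, whitespace-tolerant candidate-gene lookup across all
#' categories (both cytogenetic and functional): dual-listed genes such
#' as `TP53` or `MMSET` resolve to two categories, reflecting that a gene
#' can be disrupted either through a gross karyotypic lesion or through
#' an independent point mutation. An unknown symbol yields an empty list,
#' not an error.
#'
#' @param kb A [RagKnowledgeBase-class].
#' @param gene A gene symbol.
#' @param aliases Optional named character vector mapping alternative
#'   symbols to the knowledge base's spellings (e.g.
#'   `c(NSD2 = "MMSET", PRDM1 = "BLIMP1", MAF = "c-MAF")`). By default
#'   only the knowledge base's own spellings are recognised.
#' @return A (possibly empty) list of [RagCategory-class] objects.
#' @export
#' @examples
#' kb <- buildDefaultKB()
#' vapply(lookupGene(kb, "tp53"), function(x) x@name, character(1))
lookupGene <- function(kb, gene, aliases = NULL) {
  stopifnot(is(kb, "RagKnowledgeBase"), length(gene) == 1L)
  g <- resolveAliases(gene, aliases)
  hits <- vapply(kb@categories, function(x)
    g %in% normalizeGene(x@candidateGenes), logical(1))
  kb@categories[hits]
}

# All distinct candidate genes in a KB (canonical spellings).
kbGenes <- function(kb) {
  sort(unique(unlist(lapply(kb@categories, function(x) x@candidateGenes),
                     use.names = FALSE)))
}
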