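# Generics, accessors and show methods.

#' @name ragmm-accessors
#' @title Accessors for ragmm S4 classes
#' @description Small accessor generics: `categories()` and `kbVersion()`
#'   for knowledge bases, `categoryNames()` for the ordered category
#'   identifiers, `sampleId()` and `aberrations()` for samples,
#'   `ragScore()`, `riskBand()` and `matchedCategories()` for results,
#'   `plotSegments()` for plot specifications, and `groundTruth()` for
#'   simulated cohorts.
#' @param x An object of the documented class.
#' @return The slot value (see the class documentation).
#' @examples
#' kb <- buildDefaultKB()
#' kbVersion(kb)
#' head(categoryNames(kb))
NULL

#' @rdname ragmm-accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))
#' @rdname ragmm-accessors
#' @export
setGeneric("categoryNames", function(x) standardGeneric("categoryNames"))
#' @rdname ragmm-accessors
#' @export
setGeneric("kbVersion", function(x) standardGeneric("kbVersion"))
#' @rdname ragmm-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname ragmm-accessors
#' @export
setGeneric("aberrations", function(x) standardGeneric("aberrations"))
#' @rdname ragmm-accessors
#' @export
setGeneric("ragScore", function(x) standardGeneric("ragScore"))
#' @rdname ragmm-accessors
#' @export
setGeneric("riskBand", function(x) standardGeneric("riskBand"))
#' @rdname ragmm-accessors
#' @export
setGeneric("matchedCategories", function(x) standardGeneric("matchedCategories"))
#' @rdname ragmm-accessors
#' @export
setGeneric("plotSegments", function(x) standardGeneric("plotSegments"))
#' @rdname ragmm-accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname ragmm-accessors
#' @export
setMethod("categories", "RagKnowledgeBase", function(x) x@categories)
#' @rdname ragmm-accessors
#' @export
setMethod("categoryNames", "RagKnowledgeBase", function(x)
  vapply(x@categories, function(cat) cat@name, character(1)))
#' @rdname ragmm-accessors
#' @export
setMethod("kbVersion", "RagKnowledgeBase", function(x) x@version)
#' @rdname ragmm-accessors
#' @export
setMethod("kbVersion", "RagResult", function(x) x@kbVersion)
#' @rdname ragmm-accessors
#' @export
setMethod("sampleId", "RagSample", function(x) x@sampleId)
#' @rdname ragmm-accessors
#' @export
setMethod("sampleId", "RagResult", function(x) x@sampleId)
#' @rdname ragmm-accessors
#' @export
setMethod("aberrations", "RagSample", function(x) x@aberrations)
#' @rdname ragmm-accessors
#' @export
setMethod("ragScore", "RagResult", function(x) x@score)
#' @rdname ragmm-accessors
#' @export
setMethod("ragScore", "CombinedReport", function(x) x@rag@score)
#' @rdname ragmm-accessors
#' @export
setMethod("riskBand", "RagResult", function(x) x@band)
#' @rdname ragmm-accessors
#' @export
setMethod("riskBand", "CombinedReport", function(x) x@rag@band)
#' @rdname ragmm-accessors
#' @export
setMethod("matchedCategories", "RagResult", function(x)
  vapply(x@matches, function(m) m$category, character(1)))
#' @rdname ragmm-accessors
#' @export
setMethod("matchedCategories", "CombinedReport", function(x)
  matchedCategories(x@rag))
#' @rdname ragmm-accessors
#' @export
setMethod("plotSegments", "PizzaPlotSpec", function(x) x@segments)
#' @rdname ragmm-accessors
#' @export
setMethod("groundTruth", "RagCohort", function(x) x@groundTruth)

## show methods ---------------------------------------------------------

setMethod("show", "RagCategory", function(object) {
  cat(sprintf("RagCategory '%s' [%s, weight %.1f]\n", object@name,
              object@group, .RAG_WEIGHTS[[object@group]]))
  cat("  event class:", object@eventClass, "\n")
  if (length(object@cytogeneticKind))
    cat(sprintf("  cytogenetic: %s {%s}\n", object@cytogeneticKind,
                paste(object@cytogeneticPattern, collapse = ", ")))
  cat("  candidate genes:", paste(object@candidateGenes, collapse = ", "), "\n")
  cat(sprintf("  evidence: level %s, grade %s\n",
              object@evidenceLevel, object@evidenceGrade))
})

setMethod("show", "RagKnowledgeBase", function(object) {
  grp <- vapply(object@categories, function(x) x@group, character(1))
  cat(sprintf("RagKnowledgeBase v%s: %d categories (%d red, %d amber, %d green)\n",
              object@version, length(object@categories),
              sum(grp == "red"), sum(grp == "amber"), sum(grp == "green")))
})

setMethod("show", "Aberration", function(object) {
  lab <- if (identical(object@kind, "mutation"))
    sprintf("%s (%s)", object@gene,
            if (is.na(object@consequence)) "unknown" else object@consequence)
  else if (identical(object@kind, "trisomy"))
    paste0("trisomy ", object@descriptor)
  else object@descriptor
  cat(sprintf("Aberration: %s %s [%s]\n", object@kind, lab, object@method))
})

setMethod("show", "RagSample", function(object) {
  cat(sprintf("RagSample '%s': %d aberration(s)", object@sampleId,
              length(object@aberrations)))
  if (!is.na(object@timepoint))
    cat(sprintf(", timepoint %g", object@timepoint))
  cat("\n")
})

setMethod("show", "RagResult", function(object) {
  cat(sprintf("RagResult '%s' (KB v%s)\n", object@sampleId, object@kbVersion))
  if (length(object@matches)) {
    for (m in object@matches)
      cat(sprintf("  %-18s %-6s weight %.1f (%d supporting)\n",
                  m$category, m$group, m$weight, length(m$supporting)))
    cat(sprintf("  RAG score %.3f -> band '%s'\n", object@score, object@band))
  } else {
    cat("  no matched categories -> unscorable\n")
  }
  if (length(object@unmatched))
    cat(sprintf("  %d unmatched aberration(s)\n", length(object@unmatched)))
  if (length(object@filtered))
    cat(sprintf("  %d synonymous mutation(s) filtered\n", length(object@filtered)))
})

setMethod("show", "CombinedReport", function(object) {
  show(object@rag)
  cat(sprintf("  ISS stage: %s | adverse lesions: %d | ultrahigh: %s\n",
              ifelse(is.na(object@stage), "not staged", object@stage),
              object@adverseCount, object@ultrahigh))
})

setMethod("show", "PizzaPlotSpec", function(object) {
  cat(sprintf("PizzaPlotSpec: %d segment(s), score %.3f ('%s')\n",
              nrow(object@segments), object@score, object@band))
  print(object@segments, row.names = FALSE)
})

setMethod("show", "RagCohort", function(object) {
  cat(sprintf("RagCohort: %d patient(s), KB v%s, seed %d\n",
              length(object@samples), object@kbVersion, object@config@seed))
})
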