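# S4 classes for the RAG model. Validity methods enforce the model's
# closed enumerations so malformed objects cannot be constructed.

#' RagCategory: one knowledge-base category
#'
#' One row of the model's category table: a named lesion category with its
#' event class (initiating/primary vs progression/secondary), candidate
#' genes, optional cytogenetic pattern, red/amber/green group and evidence
#' metadata. Categories with a cytogenetic pattern are matched by
#' FISH/karyotype descriptors; categories without one ("functional"
#' categories) are matched by mutated candidate gene only.
#'
#' @slot name Category identifier, e.g. `"Del(17p)"`.
#' @slot eventClass `"initiation_primary"` or `"progression_secondary"`.
#' @slot candidateGenes Non-empty character vector of gene symbols.
#' @slot cytogeneticKind Lesion kind the pattern applies to
#'   (`"translocation"`, `"trisomy"`, `"deletion"`, `"gain"`), or
#'   length-zero for functional categories.
#' @slot cytogeneticPattern Normalised descriptors that match this
#'   category (for trisomy, the chromosome tokens of the hyperdiploid
#'   set); length-zero for functional categories.
#' @slot group `"red"`, `"amber"` or `"green"`.
#' @slot evidenceLevel Evidence level `"I"`–`"V"`.
#' @slot evidenceGrade Recommendation grade `"A"`–`"D"`.
#' @slot evidenceNote Free-text note.
#' @export
setClass("RagCategory",
  representation(name = "character", eventClass = "character",
                 candidateGenes = "character",
                 cytogeneticKind = "character",
                 cytogeneticPattern = "character",
                 group = "character", evidenceLevel = "character",
                 evidenceGrade = "character", evidenceNote = "character"))

setValidity("RagCategory", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@eventClass) != 1L ||
      !object@eventClass %in% .EVENT_CLASSES)
    msg <- c(msg, sprintf("'event_class' must be one of: %s",
                          paste(.EVENT_CLASSES, collapse = ", ")))
  if (length(object@group) != 1L || !object@group %in% .RAG_GROUPS)
    msg <- c(msg, sprintf("'group' must be one of: %s",
                          paste(.RAG_GROUPS, collapse = ", ")))
  if (length(object@candidateGenes) == 0L ||
      any(!nzchar(object@candidateGenes)))
    msg <- c(msg, "'candidate_genes' must be a non-empty set of symbols")
  if (length(object@cytogeneticKind) > 1L ||
      (length(object@cytogeneticKind) == 1L &&
       !object@cytogeneticKind %in% .CYTOGENETIC_KINDS))
    msg <- c(msg, "'cytogenetic' kind must be a single cytogenetic lesion kind")
  if (xor(length(object@cytogeneticKind) == 1L,
          length(object@cytogeneticPattern) >= 1L))
    msg <- c(msg, "cytogenetic kind and pattern must be given together")
  if (length(object@evidenceLevel) != 1L ||
      !object@evidenceLevel %in% .EVIDENCE_LEVELS)
    msg <- c(msg, "evidence 'level' must be one of I, II, III, IV, V")
  if (length(object@evidenceGrade) != 1L ||
      !object@evidenceGrade %in% .EVIDENCE_GRADES)
    msg <- c(msg, "evidence 'grade' must be one of A, B, C, D")
  if (length(msg)) msg else TRUE
})

#' RagKnowledgeBase: the full category system
#'
#' An ordered, versioned collection of [RagCategory-class] objects. The
#' default knowledge base ([buildDefaultKB()]) holds the model's 22
#' categories; users may load a re-tiered one with [loadKB()].
#'
#' @slot categories List of [RagCategory-class] objects with unique names.
#' @slot version Knowledge-base version string (embedded in results).
#' @slot provenance Free text describing where the tiering comes from.
#' @export
setClass("RagKnowledgeBase",
  representation(categories = "list", version = "character",
                 provenance = "character"))

setValidity("RagKnowledgeBase", function(object) {
  msg <- character(0)
  if (!all(vapply(object@categories, is, logical(1), "RagCategory")))
    msg <- c(msg, "'categories' must all be RagCategory objects")
  else {
    nm <- vapply(object@categories, function(x) x@name, character(1))
    if (anyDuplicated(nm))
      msg <- c(msg, sprintf("duplicate category name(s): %s",
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (length(object@version) != 1L || !nzchar(object@version))
    msg <- c(msg, "'version' must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' Aberration: one detected genetic lesion
#'
#' A single piece of lesion evidence: a cytogenetic event (translocation,
#' trisomy, deletion, gain) identified by its descriptor, or a gene
#' mutation identified by its gene symbol, together with the detection
#' method and (for mutations) the coding consequence.
#'
#' @slot kind One of `"translocation"`, `"trisomy"`, `"deletion"`,
#'   `"gain"`, `"mutation"`.
#' @slot descriptor Normalised lesion notation (e.g. `"t(4;14)"`,
#'   `"del(17p)"`, `"+1q"`, `"9"` for a trisomy); `NA` for mutations.
#' @slot gene Gene symbol; required for mutations, `NA` otherwise.
#' @slot method `"FISH"`, `"karyotype"`, `"GEP"` or `"sequencing"`.
#' @slot consequence For mutations: `"nonsynonymous"`, `"synonymous"` or
#'   `"other"`; `NA` for cytogenetic lesions.
#' @export
setClass("Aberration",
  representation(kind = "character", descriptor = "character",
                 gene = "character", method = "character",
                 consequence = "character"))

setValidity("Aberration", function(object) {
  msg <- character(0)
  if (length(object@kind) != 1L || !object@kind %in% .ABERRATION_KINDS)
    msg <- c(msg, sprintf("'kind' must be one of: %s",
                          paste(.ABERRATION_KINDS, collapse = ", ")))
  if (length(object@method) != 1L || !object@method %in% .DETECTION_METHODS)
    msg <- c(msg, sprintf("'method' must be one of: %s",
                          paste(.DETECTION_METHODS, collapse = ", ")))
  if (identical(object@kind, "mutation")) {
    if (is.na(object@gene) || !nzchar(object@gene))
      msg <- c(msg, "mutation aberrations require a 'gene' symbol")
    if (!is.na(object@consequence) &&
        !object@consequence %in% .CONSEQUENCES)
      msg <- c(msg, "'consequence' must be nonsynonymous, synonymous or other")
  } else if (object@kind %in% .CYTOGENETIC_KINDS) {
    if (is.na(object@descriptor) || !nzchar(object@descriptor))
      msg <- c(msg, sprintf("%s aberrations require a 'descriptor'", object@kind))
  }
  if (length(msg)) msg else TRUE
})

#' RagSample: one patient sample
#'
#' A set of detected aberrations for one sample, optionally with an
#' ordinal collection timepoint (for serial/relapse samples) and the
#' clinical biochemistry needed for ISS staging.
#'
#' @slot sampleId Non-empty sample identifier.
#' @slot timepoint Ordinal timepoint (`NA` if untimed).
#' @slot aberrations List of [Aberration-class] objects (may be empty).
#' @slot beta2m Serum beta-2-microglobulin in mg/L (`NA` if unknown).
#' @slot albumin Serum albumin in g/dL (`NA` if unknown).
#' @export
setClass("RagSample",
  representation(sampleId = "character", timepoint = "numeric",
                 aberrations = "list", beta2m = "numeric",
                 albumin = "numeric"))

setValidity("RagSample", function(object) {
  msg <- character(0)
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-empty string")
  if (!all(vapply(object@aberrations, is, logical(1), "Aberration")))
    msg <- c(msg, "'aberrations' must all be Aberration objects")
  if (length(msg)) msg else TRUE
})

#' RagResult: matched categories, score and band for one sample
#'
#' @slot sampleId Sample identifier.
#' @slot matches List of category matches; each element is a list with
#'   `category`, `group`, `weight` and `supporting` (the aberrations that
#'   evidence the category). Each category appears at most once.
#' @slot unmatched Aberrations that matched no category.
#' @slot filtered Synonymous mutations excluded from matching.
#' @slot score Mean group weight over matched categories in \[1, 3\], or
#'   `NA` when no category matched.
#' @slot band `"low"`, `"low_intermediate"`, `"high_intermediate"`,
#'   `"high"`, or `"unscorable"`.
#' @slot kbVersion Version of the knowledge base used.
#' @export
setClass("RagResult",
  representation(sampleId = "character", matches = "list",
                 unmatched = "list", filtered = "list",
                 score = "numeric", band = "character",
                 kbVersion = "character"))

setValidity("RagResult", function(object) {
  msg <- character(0)
  nm <- vapply(object@matches, function(m) m$category, character(1))
  if (anyDuplicated(nm))
    msg <- c(msg, "each category may appear at most once in 'matches'")
  if (length(object@score) != 1L)
    msg <- c(msg, "'score' must be a single number (NA when unscorable)")
  else if (!is.na(object@score) &&
           (object@score < 1 || object@score > 3))
    msg <- c(msg, "'score' must lie in [1.0, 3.0]")
  if (is.na(object@score) != (length(object@matches) == 0L))
    msg <- c(msg, "'score' must be present exactly when matches are non-empty")
  if (!object@band %in% c(.RISK_BANDS, "unscorable"))
    msg <- c(msg, "invalid 'band'")
  if (length(msg)) msg else TRUE
})

#' CombinedReport: RAG result joined with ISS stage
#'
#' The full per-sample report: the RAG scoring result, the ISS stage
#' derived from serum beta-2-microglobulin and albumin (when available),
#' the number of matched adverse lesions, and the ultrahigh-risk flag
#' (ISS stage II/III together with more than one adverse lesion).
#'
#' @slot rag A [RagResult-class].
#' @slot stage `"I"`, `"II"`, `"III"`, or `NA` when no clinical data.
#' @slot beta2m,albumin The clinical inputs used for staging (`NA` if
#'   absent).
#' @slot adverseCount Number of matched categories in
#'   [adverseCategories()].
#' @slot ultrahigh Logical ultrahigh-risk flag.
#' @export
setClass("CombinedReport",
  representation(rag = "RagResult", stage = "character",
                 beta2m = "numeric", albumin = "numeric",
                 adverseCount = "integer", ultrahigh = "logical"))

setValidity("CombinedReport", function(object) {
  msg <- character(0)
  if (!is.na(object@stage) && !object@stage %in% c("I", "II", "III"))
    msg <- c(msg, "'stage' must be I, II, III or NA")
  if (object@adverseCount < 0L)
    msg <- c(msg, "'adverseCount' must be non-negative")
  if (isTRUE(object@ultrahigh) &&
      (is.na(object@stage) || !object@stage %in% c("II", "III") ||
       object@adverseCount <= 1L))
    msg <- c(msg, "ultrahigh requires ISS II/III and more than one adverse lesion")
  if (length(msg)) msg else TRUE
})

#' PizzaPlotSpec: renderable segment list for the circular plot
#'
#' Segments of the RAG "pizza" plot, one per matched category, with
#' angles proportional to the category's group weight and start angles
#' accumulated clockwise from twelve o'clock.
#'
#' @slot segments `data.frame` with columns `category`, `group`, `weight`,
#'   `angle` (degrees), `start` (degrees).
#' @slot score,band The score and band printed at the centre.
#' @export
setClass("PizzaPlotSpec",
  representation(segments = "data.frame", score = "numeric",
                 band = "character"))

setValidity("PizzaPlotSpec", function(object) {
  msg <- character(0)
  seg <- object@segments
  need <- c("category", "group", "weight", "angle", "start")
  if (!all(need %in% names(seg)))
    msg <- c(msg, "segments need columns category, group, weight, angle, start")
  else {
    if (nrow(seg) == 0L) msg <- c(msg, "at least one segment required")
    if (nrow(seg) && abs(sum(seg$angle) - 360) > 1e-9)
      msg <- c(msg, "segment angles must sum to 360 degrees")
    if (nrow(seg) && any(seg$angle <= 0))
      msg <- c(msg, "all segment angles must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' CohortConfig: parameters for the synthetic cohort generator
#'
#' @slot nPatients Number of patients to simulate (>= 1).
#' @slot seed Integer RNG seed; identical seeds reproduce identical
#'   cohorts byte-for-byte.
#' @slot prevalence Named per-category lesion probabilities in \[0, 1\].
#'   Empty means "uniform 0.1 over all knowledge-base categories";
#'   categories absent from a non-empty map have prevalence 0.
#' @slot cosegregationBoost Multiplier (>= 1) raising the co-occurrence of
#'   adverse lesions, emulating their observed cosegregation.
#' @slot synonymousRate Probability that a patient receives a synonymous
#'   decoy mutation (which must never change a score).
#' @slot beta2mMeanlog,beta2mSdlog Log-normal parameters for serum
#'   beta-2-microglobulin (mg/L).
#' @slot albuminMeanlog,albuminSdlog Log-normal parameters for serum
#'   albumin (g/dL).
#' @export
setClass("CohortConfig",
  representation(nPatients = "integer", seed = "integer",
                 prevalence = "numeric", cosegregationBoost = "numeric",
                 synonymousRate = "numeric",
                 beta2mMeanlog = "numeric", beta2mSdlog = "numeric",
                 albuminMeanlog = "numeric", albuminSdlog = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (length(object@nPatients) != 1L || is.na(object@nPatients) ||
      object@nPatients < 1L)
    msg <- c(msg, "'nPatients' must be a positive integer")
  if (length(object@prevalence) &&
      (is.null(names(object@prevalence)) ||
       any(!nzchar(names(object@prevalence)))))
    msg <- c(msg, "'prevalence' must be named by category")
  if (any(object@prevalence < 0 | object@prevalence > 1, na.rm = FALSE) ||
      anyNA(object@prevalence))
    msg <- c(msg, "prevalences must lie in [0, 1]")
  if (object@cosegregationBoost < 1)
    msg <- c(msg, "'cosegregationBoost' must be >= 1")
  if (is.na(object@synonymousRate) || object@synonymousRate < 0 ||
      object@synonymousRate > 1)
    msg <- c(msg, "'synonymousRate' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' RagCohort: a simulated cohort with ground truth
#'
#' @slot samples List of [RagSample-class] objects.
#' @slot groundTruth `data.frame` with columns `sample_id`, `categories`
#'   (semicolon-joined intended category set) and `expected_score` (`NA`
#'   for patients with no model lesion).
#' @slot kbVersion Version of the knowledge base the cohort was drawn
#'   against.
#' @slot config The [CohortConfig-class] used.
#' @export
setClass("RagCohort",
  representation(samples = "list", groundTruth = "data.frame",
                 kbVersion = "character", config = "CohortConfig"))
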