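# The scoring engine: lesion-to-category matching, the mean-weight RAG
# score, risk bands, ISS staging, the ultrahigh-risk flag, trajectories.

#' Match aberrations to knowledge-base categories
#'
#' Cytogenetic aberrations (translocations, trisomies, deletions, gains)
#' match categories by normalised descriptor against the category's
#' cytogenetic pattern; any trisomy of the hyperdiploid chromosome set
#' matches `Hyperdiploidy`. Mutation aberrations match by candidate gene,
#' restricted to categories *without* a cytogenetic pattern: this is the
#' dual-listing resolution rule — a gene such as `MMSET` or `TP53` sits
#' in both a chromosomal and a functional category, and the detection
#' mechanism decides which one the evidence supports. Synonymous
#' mutations are never matched (they leave the protein unchanged) and are
#' returned in `filtered`. Each category appears at most once, with all
#' supporting aberrations aggregated; unmatched aberrations are returned
#' in a side list, never silently dropped.
#'
#' @param kb A [RagKnowledgeBase-class].
#' @param aberrations List of [Aberration-class] objects.
#' @param aliases Optional gene alias map, see [lookupGene()].
#' @return A list with `matches` (list of `list(category, group, weight,
#'   supporting)` in knowledge-base category order), `unmatched` and
#'   `filtered` (lists of [Aberration-class]).
#' @export
#' @examples
#' kb <- buildDefaultKB()
#' m <- matchLesions(kb, list(
#'   aberration("deletion", "del(17p)", method = "FISH"),
#'   aberration("mutation", gene = "BRAF", consequence = "nonsynonymous")))
#' vapply(m$matches, `[[`, character(1), "category")
matchLesions <- function(kb, aberrations, aliases = NULL) {
  stopifnot(is(kb, "RagKnowledgeBase"))
  catNames <- categoryNames(kb)
  support <- setNames(vector("list", length(catNames)), catNames)
  unmatched <- list(); filtered <- list()

  for (ab in aberrations) {
    stopifnot(is(ab, "Aberration"))
    if (identical(ab@kind, "mutation")) {
      if (identical(ab@consequence, "synonymous")) {
        filtered[[length(filtered) + 1L]] <- ab
        next
      }
      g <- resolveAliases(ab@gene, aliases)
      hits <- vapply(kb@categories, function(x)
        length(x@cytogeneticKind) == 0L &&
          g %in% normalizeGene(x@candidateGenes), logical(1))
    } else {
      d <- normalizeDescriptor(ab@kind, ab@descriptor)
      hits <- vapply(kb@categories, function(x)
        length(x@cytogeneticKind) == 1L &&
          identical(x@cytogeneticKind, ab@kind) &&
          d %in% x@cytogeneticPattern, logical(1))
    }
    if (!any(hits)) {
      unmatched[[length(unmatched) + 1L]] <- ab
    } else {
      for (nm in catNames[hits])
        support[[nm]] <- c(support[[nm]], ab)
    }
  }

  matched <- catNames[vapply(support, function(x) length(x) > 0L, logical(1))]
  matches <- lapply(matched, function(nm) {
    cat <- kb@categories[[match(nm, catNames)]]
    list(category = nm, group = cat@group,
         weight = unname(.RAG_WEIGHTS[[cat@group]]),
         supporting = support[[nm]])
  })
  list(matches = matches, unmatched = unmatched, filtered = filtered)
}

#' Compute the mean-weight RAG score
#'
#' The score is the arithmetic mean of the matched categories' group
#' weights (red 3, amber 2, green 1), computed as an integer sum divided
#' by the match count so that band boundaries (1.5, 2.0, 2.5) are exact.
#' A mean (rather than a sum) keeps the score independent of how
#' extensively a genome was assayed. An empty match set has no score:
#' absence of model lesions is not evidence of low risk.
#'
#' @param matches De-duplicated match list as returned in
#'   `matchLesions(...)$matches`.
#' @return The score in \[1.0, 3.0\], or `NA_real_` for no matches.
#' @export
#' @examples
#' kb <- buildDefaultKB()
#' m <- matchLesions(kb, list(aberration("deletion", "del(17p)"),
#'                            aberration("gain", "+1q")))
#' computeRagScore(m$matches)  # both red: 3.0
computeRagScore <- function(matches) {
  if (!length(matches)) return(NA_real_)
  w <- vapply(matches, function(m) as.integer(m$weight), integer(1))
  sum(w) / length(w)
}

#' Map a RAG score onto its risk band
#'
#' The four bands cover \[1.0, 3.0\] as lower-inclusive half-open
#' intervals with the top band closed: \[1.0, 1.5) low, \[1.5, 2.0)
#' low-intermediate, \[2.0, 2.5) high-intermediate, \[2.5, 3.0\] high.
#'
#' @param score Numeric vector of scores in \[1.0, 3.0\].
#' @return Character vector of band labels (`"low"`,
#'   `"low_intermediate"`, `"high_intermediate"`, `"high"`).
#' @export
#' @examples
#' classifyRisk(c(1, 1.5, 2, 2.5, 3))
classifyRisk <- function(score) {
  if (!length(score) || anyNA(score) || any(!is.finite(score)))
    ragValidationError("risk band requires finite scores")
  if (any(score < 1 | score > 3))
    ragValidationError("score out of the model's range [1.0, 3.0]: ",
                       paste(score[score < 1 | score > 3], collapse = ", "))
  .RISK_BANDS[findInterval(score, c(1, 1.5, 2, 2.5))]
}

#' Derive ISS stage from serum biochemistry
#'
#' International Staging System for myeloma: stage I requires serum
#' beta-2-microglobulin < 3.5 mg/L *and* serum albumin >= 3.5 g/dL;
#' stage III requires beta-2-microglobulin >= 5.5 mg/L; everything else
#' is stage II — which covers both defining cases, beta-2-microglobulin
#' < 3.5 with albumin < 3.5, and beta-2-microglobulin in \[3.5, 5.5)
#' irrespective of albumin.
#'
#' @param beta2m Serum beta-2-microglobulin in mg/L (vectorised).
#' @param albumin Serum albumin in g/dL (vectorised).
#' @return Character vector of stages (`"I"`, `"II"`, `"III"`).
#' @export
#' @examples
#' issStage(3.0, 3.6)  # "I"
#' issStage(4.0, 4.5)  # "II" (footnote case)
#' issStage(6.0, 4.0)  # "III"
issStage <- function(beta2m, albumin) {
  if (anyNA(beta2m) || anyNA(albumin) ||
      any(!is.finite(beta2m)) || any(!is.finite(albumin)) ||
      any(beta2m < 0) || any(albumin < 0))
    ragValidationError("ISS staging requires finite, non-negative ",
                       "beta-2-microglobulin and albumin values")
  ifelse(beta2m >= 5.5, "III",
         ifelse(beta2m < 3.5 & albumin >= 3.5, "I", "II"))
}

#' Combine a RAG result with ISS stage and the ultrahigh-risk rule
#'
#' Counts the matched categories belonging to the adverse lesion set
#' ([adverseCategories()]) and raises the ultrahigh flag when the sample
#' is ISS stage II or III *and* carries more than one adverse lesion.
#'
#' @param rag A [RagResult-class].
#' @param iss ISS stage `"I"`/`"II"`/`"III"`, or `NULL`/`NA` to derive it
#'   from `beta2m` and `albumin` (or leave unstaged when those are `NA`).
#' @param beta2m,albumin Clinical values used when `iss` is not given.
#' @return A [CombinedReport-class].
#' @export
combinedReport <- function(rag, iss = NULL, beta2m = NA_real_,
                           albumin = NA_real_) {
  stopifnot(is(rag, "RagResult"))
  stage <- if (!is.null(iss) && !is.na(iss)) {
    if (!iss %in% c("I", "II", "III"))
      ragValidationError("unknown ISS stage '", iss, "'")
    as.character(iss)
  } else if (!is.na(beta2m) && !is.na(albumin)) {
    issStage(beta2m, albumin)
  } else NA_character_
  adverse <- sum(matchedCategories(rag) %in% .ADVERSE_CATEGORIES)
  new("CombinedReport", rag = rag, stage = stage,
      beta2m = as.numeric(beta2m), albumin = as.numeric(albumin),
      adverseCount = as.integer(adverse),
      ultrahigh = !is.na(stage) && stage %in% c("II", "III") && adverse > 1L)
}

#' Score a set of aberrations
#'
#' Convenience pipeline: [matchLesions()] then [computeRagScore()] and
#' [classifyRisk()], packaged as a [RagResult-class].
#'
#' @param kb A [RagKnowledgeBase-class].
#' @param aberrations List of [Aberration-class] objects.
#' @param sampleId Identifier recorded in the result.
#' @param aliases Optional gene alias map, see [lookupGene()].
#' @return A [RagResult-class].
#' @export
#' @examples
#' kb <- buildDefaultKB()
#' scoreAberrations(kb, list(aberration("translocation", "t(4;14)")))
scoreAberrations <- function(kb, aberrations, sampleId = "sample",
                             aliases = NULL) {
  m <- matchLesions(kb, aberrations, aliases = aliases)
  score <- computeRagScore(m$matches)
  band <- if (is.na(score)) "unscorable" else classifyRisk(score)
  new("RagResult", sampleId = as.character(sampleId), matches = m$matches,
      unmatched = m$unmatched, filtered = m$filtered, score = score,
      band = band, kbVersion = kb@version)
}

#' Score a sample and combine with its clinical data
#'
#' @param kb A [RagKnowledgeBase-class].
#' @param sample A [RagSample-class]; its `beta2m`/`albumin`, when
#'   present, drive ISS staging.
#' @param aliases Optional gene alias map, see [lookupGene()].
#' @return A [CombinedReport-class].
#' @export
scoreSample <- function(kb, sample, aliases = NULL) {
  stopifnot(is(sample, "RagSample"))
  rag <- scoreAberrations(kb, sample@aberrations, sampleId = sample@sampleId,
                          aliases = aliases)
  combinedReport(rag, beta2m = sample@beta2m, albumin = sample@albumin)
}

#' Score serial samples of one patient
#'
#' Scores each timepointed sample independently and reports the score
#' trajectory: myeloma genomes shift through clonal expansion and
#' regression, so serial scoring at diagnosis and relapse tracks the
#' changing risk. Results are ordered by timepoint; per-interval score
#' deltas and newly appearing / lost categories are emitted.
#'
#' @param samples List of [RagSample-class] objects with distinct
#'   timepoints (any input order).
#' @param kb A [RagKnowledgeBase-class].
#' @param aliases Optional gene alias map.
#' @return A `data.frame` with columns `timepoint`, `sample_id`, `score`,
#'   `band`, `delta` (`NA` for the first row), `new_categories`,
#'   `lost_categories` (semicolon-joined).
#' @export
scoreTrajectory <- function(samples, kb, aliases = NULL) {
  if (!length(samples))
    ragValidationError("trajectory requires at least one sample")
  tp <- vapply(samples, function(s) s@timepoint, numeric(1))
  if (anyNA(tp))
    ragValidationError("every trajectory sample needs a timepoint")
  if (anyDuplicated(tp))
    ragValidationError("duplicate timepoint(s): ",
                       paste(unique(tp[duplicated(tp)]), collapse = ", "))
  ord <- order(tp)
  samples <- samples[ord]; tp <- tp[ord]
  results <- lapply(samples, function(s)
    scoreAberrations(kb, s@aberrations, sampleId = s@sampleId,
                     aliases = aliases))
  cats <- lapply(results, matchedCategories)
  n <- length(results)
  data.frame(
    timepoint = tp,
    sample_id = vapply(results, sampleId, character(1)),
    score = vapply(results, ragScore, numeric(1)),
    band = vapply(results, riskBand, character(1)),
    delta = c(NA_real_, if (n > 1)
      vapply(2:n, function(i) results[[i]]@score - results[[i - 1L]]@score,
             numeric(1))),
    new_categories = c("", if (n > 1) vapply(2:n, function(i)
      paste(setdiff(cats[[i]], cats[[i - 1L]]), collapse = ";"), character(1))),
    lost_categories = c("", if (n > 1) vapply(2:n, function(i)
      paste(setdiff(cats[[i - 1L]], cats[[i]]), collapse = ";"), character(1))),
    stringsAsFactors = FALSE)
}

#' Exact score range by exhaustive subset enumeration
#'
#' Enumerates every non-empty subset of the knowledge base's categories
#' and reports the minimum and maximum attainable mean score. A subset's
#' score depends only on how many red, amber and green categories it
#' contains, so the enumeration runs over all (red, amber, green) count
#' triples — an exact partition of all `2^k - 1` subsets into integer-
#' arithmetic equivalence classes (the subset multiplicity of each triple
#' is a product of binomial coefficients and is returned for audit).
#'
#' @param kb A [RagKnowledgeBase-class].
#' @return A list with `min`, `max`, `nSubsets` (total non-empty subsets
#'   covered) and `classes` (a `data.frame` of every count triple with
#'   its exact score and subset multiplicity).
#' @export
#' @examples
#' scoreRange(buildDefaultKB())[c("min", "max", "nSubsets")]
scoreRange <- function(kb) {
  stopifnot(is(kb, "RagKnowledgeBase"))
  grp <- vapply(kb@categories, function(x) x@group, character(1))
  nR <- sum(grp == "red"); nA <- sum(grp == "amber"); nG <- sum(grp == "green")
  grid <- expand.grid(red = 0:nR, amber = 0:nA, green = 0:nG)
  grid <- grid[rowSums(grid) > 0L, , drop = FALSE]
  grid$n <- grid$red + grid$amber + grid$green
  grid$score <- (3L * grid$red + 2L * grid$amber + 1L * grid$green) / grid$n
  grid$multiplicity <- choose(nR, grid$red) * choose(nA, grid$amber) *
    choose(nG, grid$green)
  list(min = min(grid$score), max = max(grid$score),
       nSubsets = sum(grid$multiplicity), classes = grid)
}
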