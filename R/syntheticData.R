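# Seeded synthetic cohorts with known ground truth. The generator
# realises category memberships as concrete lesions (FISH/karyotype
# findings and annotated VCF mutations), injects synonymous decoys, and
# records the intended category set and exact expected score per patient
# so every pipeline stage can be verified end-to-end.

#' Configure a synthetic cohort
#'
#' @param nPatients Number of patients (>= 1).
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @param prevalence Named per-category probabilities in \[0, 1\].
#'   `NULL` (default) gives every knowledge-base category prevalence 0.1;
#'   a non-empty map assigns 0 to categories it omits.
#' @param cosegregationBoost Multiplier >= 1: when a patient already
#'   carries an adverse lesion, each absent adverse category gets one
#'   extra draw at probability `min(1, prevalence * (boost - 1))`,
#'   emulating the observed cosegregation of adverse lesions. `1`
#'   disables the mechanism.
#' @param synonymousRate Probability that a patient receives one
#'   synonymous decoy mutation in a random model gene; decoys are written
#'   to the VCF but must never change a score.
#' @param beta2mMeanlog,beta2mSdlog,albuminMeanlog,albuminSdlog
#'   Log-normal parameters for serum beta-2-microglobulin (mg/L) and
#'   albumin (g/dL); the defaults place roughly a third of patients in
#'   each ISS stage so all staging branches are exercised.
#' @return A validated [CohortConfig-class].
#' @export
cohortConfig <- function(nPatients = 100L, seed = 1L, prevalence = NULL,
                         cosegregationBoost = 2, synonymousRate = 0.1,
                         beta2mMeanlog = 1.37, beta2mSdlog = 0.77,
                         albuminMeanlog = log(3.8), albuminSdlog = 0.12) {
  new("CohortConfig", nPatients = as.integer(nPatients),
      seed = as.integer(seed),
      prevalence = if (is.null(prevalence)) numeric(0) else prevalence,
      cosegregationBoost = as.numeric(cosegregationBoost),
      synonymousRate = as.numeric(synonymousRate),
      beta2mMeanlog = as.numeric(beta2mMeanlog),
      beta2mSdlog = as.numeric(beta2mSdlog),
      albuminMeanlog = as.numeric(albuminMeanlog),
      albuminSdlog = as.numeric(albuminSdlog))
}

# Realise one category membership as concrete aberration(s).
.realizeCategory <- function(cat) {
  if (length(cat@cytogeneticKind) == 0L) {
    gene <- if (length(cat@candidateGenes) > 1L)
      sample(cat@candidateGenes, 1L) else cat@candidateGenes
    return(list(aberration("mutation", gene = gene, method = "sequencing",
                           consequence = "nonsynonymous")))
  }
  if (identical(cat@cytogeneticKind, "trisomy")) {
    k <- sample(2:min(5L, length(cat@cytogeneticPattern)), 1L)
    chrs <- sample(cat@cytogeneticPattern, k)
    chrs <- chrs[order(as.integer(chrs))]
    return(lapply(chrs, function(ch)
      aberration("trisomy", ch, method = "karyotype")))
  }
  list(aberration(cat@cytogeneticKind, cat@cytogeneticPattern[1],
                  method = "FISH"))
}

#' Generate a seeded synthetic cohort
#'
#' Per patient, each category is sampled independently at its prevalence;
#' adverse categories are then re-sampled jointly under
#' `cosegregationBoost`. Memberships are realised as concrete
#' aberrations: the stored FISH descriptor for translocations, deletions
#' and gains; a random subset of at least two hyperdiploid trisomies for
#' `Hyperdiploidy`; a random candidate-gene nonsynonymous mutation for
#' functional categories. Synonymous decoy mutations are injected at
#' `synonymousRate`, and clinical values are drawn log-normally. The
#' ground truth records each patient's intended category set and the
#' exact expected mean score.
#'
#' @param config A [CohortConfig-class].
#' @param kb Knowledge base to draw against (default [buildDefaultKB()]).
#' @return A [RagCohort-class].
#' @export
#' @examples
#' cfg <- cohortConfig(nPatients = 3, seed = 7)
#' cohort <- generateCohort(cfg)
#' groundTruth(cohort)
generateCohort <- function(config, kb = buildDefaultKB()) {
  stopifnot(is(config, "CohortConfig"), is(kb, "RagKnowledgeBase"))
  catNames <- categoryNames(kb)
  prev <- setNames(rep(0, length(catNames)), catNames)
  if (!length(config@prevalence)) {
    prev[] <- 0.1
  } else {
    bad <- setdiff(names(config@prevalence), catNames)
    if (length(bad))
      ragValidationError("prevalence names not in the knowledge base: ",
                         paste(bad, collapse = ", "))
    prev[names(config@prevalence)] <- config@prevalence
  }
  adverse <- intersect(.ADVERSE_CATEGORIES, catNames)
  weights <- vapply(kb@categories, function(x)
    unname(.RAG_WEIGHTS[[x@group]]), numeric(1))
  names(weights) <- catNames
  allGenes <- kbGenes(kb)
  idWidth <- max(3L, nchar(as.character(config@nPatients)))

  set.seed(config@seed, kind = "Mersenne-Twister")
  samples <- vector("list", config@nPatients)
  truth <- data.frame(sample_id = character(config@nPatients),
                      categories = character(config@nPatients),
                      expected_score = numeric(config@nPatients),
                      stringsAsFactors = FALSE)
  for (i in seq_len(config@nPatients)) {
    present <- catNames[runif(length(catNames)) < prev]
    if (config@cosegregationBoost > 1 && any(adverse %in% present)) {
      for (a in setdiff(adverse, present)) {
        if (runif(1) < min(1, prev[[a]] * (config@cosegregationBoost - 1)))
          present <- c(present, a)
      }
    }
    present <- catNames[catNames %in% present]  # canonical order
    abs <- list()
    for (nm in present) {
      cat <- kb@categories[[match(nm, catNames)]]
      abs <- c(abs, .realizeCategory(cat))
    }
    if (runif(1) < config@synonymousRate) {
      decoyGene <- sample(allGenes, 1L)
      abs[[length(abs) + 1L]] <-
        aberration("mutation", gene = decoyGene, method = "sequencing",
                   consequence = "synonymous")
    }
    beta2m <- round(rlnorm(1, config@beta2mMeanlog, config@beta2mSdlog), 2)
    albumin <- round(rlnorm(1, config@albuminMeanlog, config@albuminSdlog), 2)
    id <- sprintf("P%0*d", idWidth, i)
    samples[[i]] <- ragSample(id, aberrations = abs, beta2m = beta2m,
                              albumin = albumin)
    truth$sample_id[i] <- id
    truth$categories[i] <- paste(present, collapse = ";")
    truth$expected_score[i] <- if (length(present))
      sum(as.integer(weights[present])) / length(present) else NA_real_
  }
  new("RagCohort", samples = samples, groundTruth = truth,
      kbVersion = kb@version, config = config)
}

# Minimal deterministic VCF 4.2 emitter for fixture stubs: one record per
# mutation aberration, SnpEff-style ANN annotation (gene in subfield 4).
.writeStubVcf <- function(sampleId, mutations, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=ragmm synthetic fixture (%s)", sampleId),
    "##contig=<ID=chr1,length=248956422>",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele | Annotation | Impact | Gene_Name'\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  rows <- character(0)
  for (j in seq_along(mutations)) {
    ab <- mutations[[j]]
    term <- switch(ab@consequence,
                   synonymous = "synonymous_variant|LOW",
                   nonsynonymous = "missense_variant|MODERATE",
                   "sequence_variant|MODIFIER")
    rows <- c(rows, paste(
      "chr1", 1000L * j, ".", "A", "G", ".", "PASS",
      sprintf("ANN=G|%s|%s", term, ab@gene), sep = "\t"))
  }
  writeLines(c(header, rows), path, useBytes = TRUE)
}

#' Write a cohort to on-disk fixture files
#'
#' Emits, under `directory`: one lesion TSV per patient (cytogenetic
#' findings, the dialect [parseLesionTable()] reads), one annotated VCF
#' per patient (sequencing mutations including synonymous decoys, the
#' dialect [parseVcf()] reads), a shared `clinical.csv`
#' (`sample_id,beta2m,albumin`), and `manifest.json` listing every path
#' together with the ground-truth category sets and expected scores.
#' Output is deterministic: the same cohort writes byte-identical files.
#'
#' @param cohort A [RagCohort-class].
#' @param directory Output directory (created if needed).
#' @return The manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
writeFixtureFiles <- function(cohort, directory) {
  stopifnot(is(cohort, "RagCohort"))
  ok <- try(dir.create(directory, recursive = TRUE, showWarnings = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error") || !dir.exists(directory))
    ragIOError("cannot create fixture directory: ", directory)
  truth <- cohort@groundTruth
  patients <- vector("list", length(cohort@samples))
  clin <- data.frame(sample_id = character(0), beta2m = character(0),
                     albumin = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(cohort@samples)) {
    s <- cohort@samples[[i]]
    isMut <- vapply(s@aberrations, function(a)
      identical(a@kind, "mutation"), logical(1))
    lesionPath <- file.path(directory, paste0(s@sampleId, ".lesions.tsv"))
    vcfPath <- file.path(directory, paste0(s@sampleId, ".vcf"))
    cyto <- s@aberrations[!isMut]
    tab <- data.frame(
      sample_id = rep(s@sampleId, length(cyto)),
      kind = vapply(cyto, function(a) a@kind, character(1)),
      descriptor = vapply(cyto, function(a) a@descriptor, character(1)),
      gene = rep("", length(cyto)),
      method = vapply(cyto, function(a) a@method, character(1)),
      timepoint = rep("", length(cyto)), stringsAsFactors = FALSE)
    write.table(tab, lesionPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    .writeStubVcf(s@sampleId, s@aberrations[isMut], vcfPath)
    clin[nrow(clin) + 1L, ] <- c(s@sampleId, fmtNum(s@beta2m, 2),
                                 fmtNum(s@albumin, 2))
    patients[[i]] <- list(
      sample_id = s@sampleId,
      lesions = basename(lesionPath), vcf = basename(vcfPath),
      truth_categories = truth$categories[i],
      expected_score = if (is.na(truth$expected_score[i])) NULL else
        truth$expected_score[i])
  }
  write.table(clin, file.path(directory, "clinical.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  manifest <- list(kb_version = cohort@kbVersion,
                   seed = cohort@config@seed,
                   n_patients = length(cohort@samples),
                   clinical = "clinical.csv",
                   patients = patients)
  # digits = I(17): exact significant digits, so expected scores like 7/3
  # survive the round trip bit-for-bit
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Re-score a fixture directory against its manifest
#'
#' End-to-end driver for simulated cohorts: reads `manifest.json`, parses
#' each patient's lesion TSV and VCF, scores the combined evidence, and
#' returns observed next to expected. Used to verify that parsing,
#' matching and scoring reproduce the generator's ground truth exactly.
#'
#' @param directory A directory written by [writeFixtureFiles()].
#' @param kb Knowledge base (default [buildDefaultKB()]).
#' @return A `data.frame` with columns `sample_id`, `score`, `band`,
#'   `expected_score`, `truth_categories`, `matched_categories`,
#'   `synonymous_filtered`.
#' @export
scoreFixtures <- function(directory, kb = buildDefaultKB()) {
  manifestPath <- file.path(directory, "manifest.json")
  if (!file.exists(manifestPath))
    ragIOError("no manifest.json under: ", directory)
  manifest <- jsonlite::read_json(manifestPath)
  out <- lapply(manifest$patients, function(p) {
    lesions <- parseLesionTable(file.path(directory, p$lesions))
    abs <- if (length(lesions)) aberrations(lesions[[1]]) else list()
    vcf <- parseVcf(file.path(directory, p$vcf))
    res <- scoreAberrations(kb, c(abs, vcf$aberrations),
                            sampleId = p$sample_id)
    data.frame(sample_id = p$sample_id, score = res@score, band = res@band,
               expected_score = if (is.null(p$expected_score)) NA_real_ else
                 as.numeric(p$expected_score),
               truth_categories = p$truth_categories,
               matched_categories = paste(matchedCategories(res),
                                          collapse = ";"),
               synonymous_filtered = vcf$synonymousFiltered,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
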