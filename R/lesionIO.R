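# Lesion evidence I/O: constructors, the lesion table and VCF readers,
# and the machine-readable report writer/reader.

#' Construct a single aberration
#'
#' @param kind Lesion kind: `"translocation"`, `"trisomy"`, `"deletion"`,
#'   `"gain"` or `"mutation"`.
#' @param descriptor Lesion notation for cytogenetic kinds (e.g.
#'   `"t(4;14)"`, `"del(17p)"`, `"+1q"`, `9` for a trisomy); normalised on
#'   construction.
#' @param gene Gene symbol (required for `kind = "mutation"`).
#' @param method Detection method: `"FISH"`, `"karyotype"`, `"GEP"` or
#'   `"sequencing"`.
#' @param consequence For mutations: `"nonsynonymous"`, `"synonymous"` or
#'   `"other"`; `NA` if unknown.
#' @return An [Aberration-class].
#' @export
#' @examples
#' aberration("translocation", "t(4;14)", method = "FISH")
#' aberration("mutation", gene = "BRAF", consequence = "nonsynonymous")
aberration <- function(kind, descriptor = NA_character_, gene = NA_character_,
                       method = if (identical(kind, "mutation")) "sequencing" else "FISH",
                       consequence = NA_character_) {
  if (!is.na(descriptor))
    descriptor <- normalizeDescriptor(kind, descriptor)
  if (!is.na(gene)) gene <- gsub("[[:space:]]+", "", as.character(gene))
  new("Aberration", kind = as.character(kind),
      descriptor = as.character(descriptor), gene = as.character(gene),
      method = as.character(method),
      consequence = as.character(consequence))
}

#' Construct a patient sample
#'
#' @param sampleId Sample identifier.
#' @param aberrations List of [Aberration-class] objects (may be empty:
#'   a sample with no detected lesion is representable, and scores as
#'   "unscorable").
#' @param timepoint Optional ordinal collection timepoint.
#' @param beta2m,albumin Optional clinical values for ISS staging
#'   (serum beta-2-microglobulin in mg/L, serum albumin in g/dL).
#' @return A [RagSample-class].
#' @export
ragSample <- function(sampleId, aberrations = list(), timepoint = NA_real_,
                      beta2m = NA_real_, albumin = NA_real_) {
  new("RagSample", sampleId = as.character(sampleId),
      timepoint = as.numeric(timepoint), aberrations = aberrations,
      beta2m = as.numeric(beta2m), albumin = as.numeric(albumin))
}

## Lesion table ---------------------------------------------------------

#' Read a FISH/karyotype lesion table
#'
#' Reads a tab-separated lesion table with header columns `sample_id`,
#' `kind`, `descriptor`, `gene`, `method` and optional `timepoint`; one
#' detected lesion per row. Descriptors are normalised (whitespace
#' stripped, `del`/`t` lower-cased). Rows are grouped into one
#' [RagSample-class] per distinct `sample_id`/`timepoint` pair, in order
#' of first appearance; parsing is deterministic and order-preserving
#' within a sample.
#'
#' @param path Path to the TSV file.
#' @return A list of [RagSample-class] objects.
#' @export
parseLesionTable <- function(path) {
  if (!file.exists(path)) ragIOError("lesion table not found: ", path)
  tab <- tryCatch(
    read.delim(path, sep = "\t", colClasses = "character",
               check.names = FALSE, na.strings = c("NA", "")),
    error = function(e) ragValidationError("cannot read lesion table '",
                                           path, "': ", conditionMessage(e)))
  need <- c("sample_id", "kind", "method")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    ragValidationError("lesion table '", path, "' lacks required column(s): ",
                       paste(missing, collapse = ", "))
  if (!"descriptor" %in% names(tab)) tab$descriptor <- NA_character_
  if (!"gene" %in% names(tab)) tab$gene <- NA_character_
  if (!"timepoint" %in% names(tab)) tab$timepoint <- NA_character_

  abs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- sprintf("row %d", i + 1L)  # +1 accounts for the header line
    kind <- tolower(trimws(tab$kind[i]))
    method <- trimws(tab$method[i])
    if (!kind %in% .ABERRATION_KINDS)
      ragValidationError(path, " ", row, ": unknown kind '", tab$kind[i], "'")
    if (!method %in% .DETECTION_METHODS)
      ragValidationError(path, " ", row, ": unknown method '", tab$method[i], "'")
    if (kind == "mutation" && (is.na(tab$gene[i]) || !nzchar(tab$gene[i])))
      ragValidationError(path, " ", row, ": mutation row lacks a gene symbol")
    if (kind != "mutation" &&
        (is.na(tab$descriptor[i]) || !nzchar(trimws(tab$descriptor[i]))))
      ragValidationError(path, " ", row, ": ", kind, " row lacks a descriptor")
    abs[[i]] <- aberration(kind, descriptor = tab$descriptor[i],
                           gene = tab$gene[i], method = method)
  }

  tp <- suppressWarnings(as.numeric(tab$timepoint))
  key <- paste(tab$sample_id, ifelse(is.na(tp), "", tp), sep = "\r")
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    out[[length(out) + 1L]] <-
      ragSample(tab$sample_id[idx[1]], aberrations = abs[idx],
                timepoint = tp[idx[1]])
  }
  out
}

## VCF ------------------------------------------------------------------

#' Read gene mutations from an annotated VCF
#'
#' Parses a VCF 4.x file whose records carry gene-bearing annotations and
#' returns one mutation [Aberration-class] per record-gene pair with a
#' protein-altering or unknown consequence. Records whose annotation is
#' explicitly synonymous impart no change to protein structure and are
#' excluded from scoring input; they are counted and returned alongside
#' the kept aberrations, never silently dropped.
#'
#' The default annotation dialect is the SnpEff-style `ANN` INFO field
#' (`Allele|Annotation|Impact|Gene_Name|...`): the consequence is read
#' from subfield `consequenceSubfield` and the gene symbol from subfield
#' `geneSubfield`. A plain single-value key (e.g. `annotationKey =
#' "GENE"` with `GENE=BRAF`) is also accepted; such records have unknown
#' consequence and are kept.
#'
#' @param path Path to an uncompressed or bgzipped VCF file.
#' @param annotationKey INFO key holding the annotation (default `"ANN"`).
#' @param geneSubfield 1-based index of the gene-symbol subfield within a
#'   pipe-delimited annotation (default 4, the SnpEff `Gene_Name` slot).
#' @param consequenceSubfield 1-based index of the consequence subfield
#'   (default 2, the SnpEff `Annotation` slot).
#' @return A list with elements `aberrations` (list of mutation
#'   [Aberration-class] objects, `method = "sequencing"`),
#'   `synonymousFiltered` (count of excluded record-gene pairs),
#'   `filtered` (the excluded aberrations themselves) and `records`
#'   (number of VCF records read).
#' @export
parseVcf <- function(path, annotationKey = "ANN", geneSubfield = 4L,
                     consequenceSubfield = 2L) {
  if (!file.exists(path)) ragIOError("VCF not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) ragValidationError("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  n <- nrow(vcf)
  kept <- list(); dropped <- list()
  if (n > 0L) {
    inf <- VariantAnnotation::info(vcf)
    if (!annotationKey %in% names(inf))
      ragValidationError("VCF '", path, "' has no INFO key '", annotationKey,
                         "' on any record")
    ann <- inf[[annotationKey]]
    for (i in seq_len(n)) {
      entries <- as.character(unlist(ann[i], use.names = FALSE))
      entries <- entries[!is.na(entries) & nzchar(entries)]
      if (!length(entries)) next
      genes <- character(0); cons <- character(0)
      for (e in entries) {
        if (grepl("|", e, fixed = TRUE)) {
          parts <- strsplit(e, "|", fixed = TRUE)[[1]]
          g <- if (length(parts) >= geneSubfield) parts[geneSubfield] else ""
          cc <- if (length(parts) >= consequenceSubfield)
            classifyConsequence(parts[consequenceSubfield]) else "other"
        } else {
          g <- e; cc <- "other"
        }
        if (!nzchar(g)) next
        genes <- c(genes, g); cons <- c(cons, cc)
      }
      # collapse entries per gene: any protein-altering call dominates
      for (g in unique(genes)) {
        cg <- cons[genes == g]
        cls <- if ("nonsynonymous" %in% cg) "nonsynonymous"
               else if ("other" %in% cg) "other" else "synonymous"
        ab <- aberration("mutation", gene = g, method = "sequencing",
                         consequence = cls)
        if (cls == "synonymous") dropped[[length(dropped) + 1L]] <- ab
        else kept[[length(kept) + 1L]] <- ab
      }
    }
    if ((length(kept) + length(dropped)) == 0L)
      ragValidationError("VCF '", path, "': INFO key '", annotationKey,
                         "' carries no gene symbol on any record")
  }
  list(aberrations = kept, synonymousFiltered = length(dropped),
       filtered = dropped, records = n)
}

## Reports --------------------------------------------------------------

aberrationToList <- function(ab) {
  list(kind = ab@kind,
       descriptor = if (is.na(ab@descriptor)) NULL else ab@descriptor,
       gene = if (is.na(ab@gene)) NULL else ab@gene,
       method = ab@method,
       consequence = if (is.na(ab@consequence)) NULL else ab@consequence)
}

aberrationFromList <- function(x) {
  aberration(x$kind,
             descriptor = if (is.null(x$descriptor)) NA_character_ else x$descriptor,
             gene = if (is.null(x$gene)) NA_character_ else x$gene,
             method = x$method,
             consequence = if (is.null(x$consequence)) NA_character_ else x$consequence)
}

reportToList <- function(report) {
  r <- report@rag
  list(
    sample_id = r@sampleId,
    kb_version = r@kbVersion,
    rag = list(
      score = if (is.na(r@score)) NULL else r@score,
      band = r@band,
      matches = lapply(r@matches, function(m)
        list(category = m$category, group = m$group, weight = m$weight,
             supporting = lapply(m$supporting, aberrationToList))),
      unmatched = lapply(r@unmatched, aberrationToList),
      filtered = lapply(r@filtered, aberrationToList)),
    iss = if (is.na(report@stage)) NULL else list(
      stage = report@stage,
      beta2m = if (is.na(report@beta2m)) NULL else report@beta2m,
      albumin = if (is.na(report@albumin)) NULL else report@albumin),
    adverse_count = report@adverseCount,
    ultrahigh = report@ultrahigh)
}

reportFromList <- function(x) {
  matches <- lapply(x$rag$matches, function(m)
    list(category = m$category, group = m$group,
         weight = as.numeric(m$weight),
         supporting = lapply(m$supporting, aberrationFromList)))
  rag <- new("RagResult", sampleId = x$sample_id, matches = matches,
             unmatched = lapply(x$rag$unmatched, aberrationFromList),
             filtered = lapply(x$rag$filtered, aberrationFromList),
             score = if (is.null(x$rag$score)) NA_real_ else
               as.numeric(x$rag$score),
             band = x$rag$band, kbVersion = x$kb_version)
  new("CombinedReport", rag = rag,
      stage = if (is.null(x$iss)) NA_character_ else x$iss$stage,
      beta2m = if (is.null(x$iss) || is.null(x$iss$beta2m)) NA_real_ else
        as.numeric(x$iss$beta2m),
      albumin = if (is.null(x$iss) || is.null(x$iss$albumin)) NA_real_ else
        as.numeric(x$iss$albumin),
      adverseCount = as.integer(x$adverse_count),
      ultrahigh = as.logical(x$ultrahigh))
}

#' Write a combined report to JSON or TSV
#'
#' JSON output follows the schema shipped at
#' `system.file("extdata", "report.schema.json", package = "ragmm")` and
#' round-trips exactly through [readReport()]. TSV output has one row per
#' matched category plus a terminal `SUMMARY` row carrying the score,
#' band, ISS stage and ultrahigh flag.
#'
#' @param report A [CombinedReport-class].
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, format = c("json", "tsv")) {
  stopifnot(is(report, "CombinedReport"))
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) ragIOError("output directory does not exist: ", dir)
  if (format == "json") {
    ok <- try(jsonlite::write_json(reportToList(report), path,
                                   auto_unbox = TRUE, digits = I(17),
                                   null = "null", pretty = TRUE),
              silent = TRUE)
    if (inherits(ok, "try-error")) ragIOError("cannot write report: ", path)
  } else {
    r <- report@rag
    rows <- data.frame(
      sample_id = character(0), row_type = character(0),
      category = character(0), group = character(0), weight = character(0),
      n_supporting = character(0), score = character(0), band = character(0),
      iss_stage = character(0), adverse_count = character(0),
      ultrahigh = character(0), stringsAsFactors = FALSE)
    for (m in r@matches)
      rows[nrow(rows) + 1L, ] <- c(r@sampleId, "category", m$category,
                                   m$group, fmtNum(m$weight, 1),
                                   length(m$supporting), "", "", "", "", "")
    rows[nrow(rows) + 1L, ] <- c(r@sampleId, "summary", "", "", "", "",
                                 fmtNum(r@score, 6), r@band,
                                 ifelse(is.na(report@stage), "NA", report@stage),
                                 report@adverseCount,
                                 tolower(report@ultrahigh))
    ok <- try(write.table(rows, path, sep = "\t", quote = FALSE,
                          row.names = FALSE), silent = TRUE)
    if (inherits(ok, "try-error")) ragIOError("cannot write report: ", path)
  }
  invisible(path)
}

#' Read a JSON report back into a CombinedReport
#'
#' @param path Path to a JSON file written by [writeReport()].
#' @return A [CombinedReport-class] equal to the one written.
#' @export
readReport <- function(path) {
  if (!file.exists(path)) ragIOError("report not found: ", path)
  reportFromList(jsonlite::read_json(path))
}
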