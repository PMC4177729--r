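test_that("lesion table rows map directly onto aberrations", {
  p <- withr::local_tempfile(fileext = ".tsv")
  makeLesionTsv(p, list(
    c("S1", "translocation", "t(4;14)", "", "FISH", ""),
    c("S1", "deletion", "del(17p)", "", "FISH", ""),
    c("S1", "trisomy", "9", "", "karyotype", ""),
    c("S1", "gain", "+1q", "", "FISH", ""),
    c("S1", "mutation", "", "BRAF", "sequencing", "")))
  samples <- parseLesionTable(p)
  expect_length(samples, 1L)
  abs <- aberrations(samples[[1]])
  expect_length(abs, 5L)
  expect_identical(abs[[1]]@kind, "translocation")
  expect_identical(abs[[1]]@descriptor, "t(4;14)")
  expect_identical(abs[[1]]@method, "FISH")
  expect_identical(abs[[2]]@descriptor, "del(17p)")
  expect_identical(abs[[3]]@kind, "trisomy")
  expect_identical(abs[[3]]@descriptor, "9")
  expect_identical(abs[[3]]@method, "karyotype")
  expect_identical(abs[[5]]@gene, "BRAF")
})

test_that("descriptors are normalised and parsing is deterministic", {
  p <- withr::local_tempfile(fileext = ".tsv")
  makeLesionTsv(p, list(
    c("S1", "translocation", "T (4; 14)", "", "FISH", ""),
    c("S1", "deletion", " DEL(17P) ", "", "FISH", ""),
    c("S1", "trisomy", "+9", "", "karyotype", "")))
  abs <- aberrations(parseLesionTable(p)[[1]])
  expect_identical(abs[[1]]@descriptor, "t(4;14)")
  expect_identical(abs[[2]]@descriptor, "del(17p)")
  expect_identical(abs[[3]]@descriptor, "9")
  # re-parsing the same file yields an identical collection
  expect_equal(parseLesionTable(p), parseLesionTable(p))
})

test_that("lesion table groups rows by sample and timepoint", {
  p <- withr::local_tempfile(fileext = ".tsv")
  makeLesionTsv(p, list(
    c("A", "deletion", "del(17p)", "", "FISH", "1"),
    c("B", "gain", "+1q", "", "FISH", ""),
    c("A", "translocation", "t(4;14)", "", "FISH", "1"),
    c("A", "deletion", "del(13q)", "", "FISH", "2")))
  samples <- parseLesionTable(p)
  expect_length(samples, 3L)
  expect_identical(vapply(samples, sampleId, character(1)),
                   c("A", "B", "A"))
  expect_identical(vapply(samples, function(s) s@timepoint, numeric(1)),
                   c(1, NA, 2))
  expect_length(aberrations(samples[[1]]), 2L)
})

test_that("lesion table errors carry row numbers and field names", {
  p <- withr::local_tempfile(fileext = ".tsv")
  makeLesionTsv(p, list(c("S1", "inversion", "inv(16)", "", "FISH", "")))
  expect_error(parseLesionTable(p), "row 2.*inversion",
               class = "rag_validation_error")
  makeLesionTsv(p, list(c("S1", "deletion", "del(17p)", "", "PCR", "")))
  expect_error(parseLesionTable(p), "method", class = "rag_validation_error")
  makeLesionTsv(p, list(c("S1", "mutation", "", "", "sequencing", "")))
  expect_error(parseLesionTable(p), "gene", class = "rag_validation_error")
  expect_error(parseLesionTable(file.path(tempdir(), "absent.tsv")),
               class = "rag_io_error")
})

test_that("parseVcf keeps protein-altering records and filters synonymous ones", {
  p <- withr::local_tempfile(fileext = ".vcf")

  makeTestVcf(p, list(list(gene = "BRAF", term = "missense_variant")))
  res <- parseVcf(p)
  expect_length(res$aberrations, 1L)
  ab <- res$aberrations[[1]]
  expect_identical(ab@kind, "mutation")
  expect_identical(ab@gene, "BRAF")
  expect_identical(ab@method, "sequencing")
  expect_identical(ab@consequence, "nonsynonymous")
  expect_identical(res$synonymousFiltered, 0L)

  makeTestVcf(p, list(list(gene = "KRAS", term = "synonymous_variant")))
  res <- parseVcf(p)
  expect_length(res$aberrations, 0L)
  expect_identical(res$synonymousFiltered, 1L)

  makeTestVcf(p, list(
    list(gene = "BRAF", term = "missense_variant"),
    list(gene = "TP53", term = "missense_variant"),
    list(gene = "KRAS", term = "synonymous_variant")))
  res <- parseVcf(p)
  expect_length(res$aberrations, 2L)
  expect_identical(res$synonymousFiltered, 1L)
  # conservation: kept + filtered = gene-annotated input records
  expect_identical(length(res$aberrations) + res$synonymousFiltered,
                   res$records)
  # unknown consequences are kept, not dropped
  makeTestVcf(p, list(list(gene = "DIS3", term = "upstream_gene_variant")))
  expect_identical(parseVcf(p)$aberrations[[1]]@consequence, "other")
})

test_that("parseVcf fails cleanly on bad inputs", {
  expect_error(parseVcf(file.path(tempdir(), "absent.vcf")),
               class = "rag_io_error")
  p <- withr::local_tempfile(fileext = ".vcf")
  makeTestVcf(p, list(list(gene = "BRAF", term = "missense_variant")))
  expect_error(parseVcf(p, annotationKey = "CSQ"), "CSQ",
               class = "rag_validation_error")
  writeLines(c("this is", "not a VCF"), p)
  expect_error(parseVcf(p), "malformed", class = "rag_validation_error")
})

test_that("JSON reports round-trip and encode the unscorable contract", {
  kb <- buildDefaultKB()
  dir <- withr::local_tempdir()

  rag <- scoreAberrations(kb, list(
    aberration("deletion", "del(17p)"), aberration("gain", "+1q"),
    aberration("mutation", gene = "ZZZ3", consequence = "nonsynonymous"),
    aberration("mutation", gene = "KRAS", consequence = "synonymous")),
    sampleId = "S1")
  rep <- combinedReport(rag, beta2m = 4.25, albumin = 3.5)
  path <- file.path(dir, "s1.json")
  writeReport(rep, path, format = "json")
  doc <- jsonlite::read_json(path)
  expect_identical(doc$sample_id, "S1")
  expect_identical(doc$kb_version, kbVersion(kb))
  expect_equal(doc$rag$score, 3)
  expect_identical(doc$rag$band, "high")
  expect_identical(doc$iss$stage, "II")
  expect_identical(doc$adverse_count, 2L)
  expect_true(doc$ultrahigh)
  expect_length(doc$rag$unmatched, 1L)
  expect_length(doc$rag$filtered, 1L)
  expect_equal(readReport(path), rep)

  # unscorable sample: null score, band "unscorable"
  rep0 <- combinedReport(scoreAberrations(kb, list(), sampleId = "S0"))
  path0 <- file.path(dir, "s0.json")
  writeReport(rep0, path0)
  doc0 <- jsonlite::read_json(path0)
  expect_null(doc0$rag$score)
  expect_identical(doc0$rag$band, "unscorable")
  expect_equal(readReport(path0), rep0)
})

test_that("TSV reports carry one category row plus a summary row", {
  kb <- buildDefaultKB()
  rag <- scoreAberrations(kb, list(aberration("deletion", "del(17p)"),
                                   aberration("translocation", "t(4;14)")),
                          sampleId = "S2")
  rep <- combinedReport(rag, iss = "III")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeReport(rep, path, format = "tsv")
  tab <- read.delim(path, colClasses = "character")
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$row_type, c("category", "category", "summary"))
  expect_setequal(tab$category[1:2], c("Del(17p)", "t(4;14)"))
  expect_identical(tab$score[3], "2.500000")
  expect_identical(tab$band[3], "high")
  expect_identical(tab$iss_stage[3], "III")
  expect_error(writeReport(rep, file.path(tempdir(), "no-such-dir", "x.json")),
               class = "rag_io_error")
})
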