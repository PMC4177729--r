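# Shared fixtures, built in code at test time.

# One deterministic aberration evidencing a given category.
lesionFor <- function(cat) {
  if (length(cat@cytogeneticKind) == 0L)
    return(aberration("mutation", gene = cat@candidateGenes[1],
                      method = "sequencing", consequence = "nonsynonymous"))
  if (identical(cat@cytogeneticKind, "trisomy"))
    return(aberration("trisomy", cat@cytogeneticPattern[1],
                      method = "karyotype"))
  aberration(cat@cytogeneticKind, cat@cytogeneticPattern[1], method = "FISH")
}

# All categories of a KB belonging to one group.
categoriesInGroup <- function(kb, group) {
  Filter(function(x) identical(x@group, group), categories(kb))
}

# Minimal SnpEff-dialect VCF writer; records = list(list(gene=, term=)).
makeTestVcf <- function(path, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=248956422>",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,",
           "Description=\"Allele | Annotation | Impact | Gene_Name\">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  rows <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    paste("chr1", 100L * i, ".", "A", "G", ".", "PASS",
          sprintf("ANN=G|%s|MODIFIER|%s", r$term, r$gene), sep = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# Lesion TSV writer; rows = list of character vectors
# (sample_id, kind, descriptor, gene, method, timepoint).
makeLesionTsv <- function(path, rows) {
  header <- paste("sample_id", "kind", "descriptor", "gene", "method",
                  "timepoint", sep = "\t")
  writeLines(c(header, vapply(rows, paste, character(1), collapse = "\t")),
             path)
  path
}

# Candidate-gene census transcribed literally from the published
# category/gene tables (legacy symbol spellings kept).
TABLE4_GENES <- list(
  "Hyperdiploidy" = c("CCND1", "CCND2", "CCND3"),
  "t(4;14)" = c("FGFR3", "MMSET"),
  "t(6;14)" = c("CCND3"),
  "t(11;14)" = c("CCND1"),
  "t(14;16)" = c("c-MAF"),
  "t(14;20)" = c("MAFB"),
  "+1q" = c("CKS1B", "ANP32E"),
  "Del(1p)" = c("CDKN2C", "FAF1", "FAM46C"),
  "Del(11q)" = c("BIRC2", "BIRC3"),
  "Del(12p)" = c("CD27"),
  "Del(13/13q)" = c("RB1", "DIS3"),
  "Del(14q)" = c("TRAF3"),
  "Del(16q)" = c("CYLD", "WWOX"),
  "Del(17p)" = c("TP53"),
  "Secondary t(8;14)" = c("MYC"),
  "Bone disease" = c("DKK1", "FRZB"),
  "Proliferation" = c("NRAS", "KRAS", "BRAF", "MYC"),
  "NF-kB" = c("TRAF2", "TRAF3", "CYLD", "NFKB1", "NFKB2", "NIK", "TACI",
              "LTBR", "BIRC2", "BIRC3", "WWOX", "CD40"),
  "Differentiation" = c("XBP1", "BLIMP1", "IRF4"),
  "DNA repair" = c("TP53", "PARP1"),
  "RNA editing" = c("DIS3", "FAM46C", "LRRK2"),
  "Epigenetic" = c("KDM6A", "KDM6B", "MLL", "MMSET", "HOXA9"))
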