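# Default RAG knowledge base for multiple myeloma.
# 22 lesion categories; each carries its event class (initiating/primary vs
# progression/secondary), candidate genes, an optional cytogenetic pattern
# (the descriptors a FISH/karyotype finding must normalise to), its
# red/amber/green group, and evidence metadata (level I-V, grade A-D).
# Edit and reload with loadKB() to re-tier the model.
version: "1.0.0"
provenance: >-
  Default knowledge base of the ragmm package. Category rows, candidate
  genes and the hyperdiploid trisomy set follow the published RAG model
  tables; gene symbols keep the legacy spellings used there (MMSET, c-MAF,
  BLIMP1, NIK, TACI, MLL). The red/amber/green tier of each category is a
  RECONSTRUCTION from the model's stated tiering rules (adverse-prognosis
  lesions red, superior-survival lesions green, neutral or uncharacterised
  lesions amber, t(4;14) demoted to amber in the bortezomib era): the
  original figure assigning tiers is not machine-readable. Re-tier by
  editing this file. The "Bone disease" category defaults to amber; its
  independent prognostic weight is not established.
categories:
  - name: "Hyperdiploidy"
    event_class: initiation_primary
    group: green
    candidate_genes: [CCND1, CCND2, CCND3]
    cytogenetic:
      kind: trisomy
      descriptors: ["1", "3", "5", "7", "9", "11", "15", "19", "21"]
    evidence: {level: I, grade: A, note: "Favourable hyperdiploid biology; trisomies of odd chromosomes 1,3,5,7,9,11,15,19,21."}
  - name: "t(4;14)"
    event_class: initiation_primary
    group: amber
    candidate_genes: [FGFR3, MMSET]
    cytogenetic:
      kind: translocation
      descriptors: ["t(4;14)"]
    evidence: {level: I, grade: A, note: "Historically high risk; demoted to intermediate under bortezomib-based therapy."}
  - name: "t(6;14)"
    event_class: initiation_primary
    group: green
    candidate_genes: [CCND3]
    cytogenetic:
      kind: translocation
      descriptors: ["t(6;14)"]
    evidence: {level: II, grade: A, note: "Cyclin D3 IGH translocation; standard risk."}
  - name: "t(11;14)"
    event_class: initiation_primary
    group: green
    candidate_genes: [CCND1]
    cytogenetic:
      kind: translocation
      descriptors: ["t(11;14)"]
    evidence: {level: I, grade: A, note: "Cyclin D1 IGH translocation; standard risk."}
  - name: "t(14;16)"
    event_class: initiation_primary
    group: red
    candidate_genes: [c-MAF]
    cytogenetic:
      kind: translocation
      descriptors: ["t(14;16)"]
    evidence: {level: I, grade: A, note: "Adverse IGH@ translocation (MAF)."}
  - name: "t(14;20)"
    event_class: initiation_primary
    group: red
    candidate_genes: [MAFB]
    cytogenetic:
      kind: translocation
      descriptors: ["t(14;20)"]
    evidence: {level: II, grade: A, note: "Adverse IGH@ translocation (MAFB)."}
  - name: "+1q"
    event_class: progression_secondary
    group: red
    candidate_genes: [CKS1B, ANP32E]
    cytogenetic:
      kind: gain
      descriptors: ["+1q", "+1q21"]
    evidence: {level: I, grade: A, note: "1q gain; adverse on multivariate FISH analysis."}
  - name: "Del(1p)"
    event_class: progression_secondary
    group: amber
    candidate_genes: [CDKN2C, FAF1, FAM46C]
    cytogenetic:
      kind: deletion
      descriptors: ["del(1p)", "del(1p32)"]
    evidence: {level: II, grade: A, note: ""}
  - name: "Del(11q)"
    event_class: progression_secondary
    group: amber
    candidate_genes: [BIRC2, BIRC3]
    cytogenetic:
      kind: deletion
      descriptors: ["del(11q)"]
    evidence: {level: III, grade: A, note: ""}
  - name: "Del(12p)"
    event_class: progression_secondary
    group: amber
    candidate_genes: [CD27]
    cytogenetic:
      kind: deletion
      descriptors: ["del(12p)"]
    evidence: {level: III, grade: A, note: ""}
  - name: "Del(13/13q)"
    event_class: progression_secondary
    group: amber
    candidate_genes: [RB1, DIS3]
    cytogenetic:
      kind: deletion
      descriptors: ["del(13)", "del(13q)", "del(13/13q)", "del(13q14)"]
    evidence: {level: I, grade: A, note: "Prognostic impact largely tied to co-occurring lesions."}
  - name: "Del(14q)"
    event_class: progression_secondary
    group: amber
    candidate_genes: [TRAF3]
    cytogenetic:
      kind: deletion
      descriptors: ["del(14q)"]
    evidence: {level: III, grade: A, note: ""}
  - name: "Del(16q)"
    event_class: progression_secondary
    group: amber
    candidate_genes: [CYLD, WWOX]
    cytogenetic:
      kind: deletion
      descriptors: ["del(16q)"]
    evidence: {level: III, grade: A, note: ""}
  - name: "Del(17p)"
    event_class: progression_secondary
    group: red
    candidate_genes: [TP53]
    cytogenetic:
      kind: deletion
      descriptors: ["del(17p)", "del(17p13)"]
    evidence: {level: I, grade: A, note: "TP53 locus deletion; adverse across treatment settings."}
  - name: "Secondary t(8;14)"
    event_class: progression_secondary
    group: amber
    candidate_genes: [MYC]
    cytogenetic:
      kind: translocation
      descriptors: ["t(8;14)"]
    evidence: {level: IV, grade: A, note: "Secondary MYC rearrangement."}
  - name: "Bone disease"
    event_class: progression_secondary
    group: amber
    candidate_genes: [DKK1, FRZB]
    evidence: {level: IV, grade: A, note: "Wnt-pathway mediators of myeloma bone disease; independent prognostic weight not established."}
  - name: "Proliferation"
    event_class: progression_secondary
    group: amber
    candidate_genes: [NRAS, KRAS, BRAF, MYC]
    evidence: {level: II, grade: A, note: "Recurrent MAPK-pathway drivers from WGS/WES studies."}
  - name: "NF-kB"
    event_class: progression_secondary
    group: amber
    candidate_genes: [TRAF2, TRAF3, CYLD, NFKB1, NFKB2, NIK, TACI, LTBR, BIRC2, BIRC3, WWOX, CD40]
    evidence: {level: II, grade: A, note: "Apoptosis / NF-kB pathway; included on functional characterisation and mutational recurrence rather than independent prognostic studies."}
  - name: "Differentiation"
    event_class: progression_secondary
    group: amber
    candidate_genes: [XBP1, BLIMP1, IRF4]
    evidence: {level: II, grade: A, note: "Plasma-cell differentiation programme."}
  - name: "DNA repair"
    event_class: progression_secondary
    group: amber
    candidate_genes: [TP53, PARP1]
    evidence: {level: II, grade: A, note: ""}
  - name: "RNA editing"
    event_class: progression_secondary
    group: amber
    candidate_genes: [DIS3, FAM46C, LRRK2]
    evidence: {level: II, grade: A, note: "Recurrently mutated RNA-processing genes."}
  - name: "Epigenetic"
    event_class: progression_secondary
    group: amber
    candidate_genes: [KDM6A, KDM6B, MLL, MMSET, HOXA9]
    evidence: {level: II, grade: A, note: "Chromatin modifiers; included on functional characterisation and mutational recurrence."}
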