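---
title: "The RAG risk model: methods and design notes"
author: "ragmm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RAG risk model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragmm)
```

## The model

Multiple myeloma genomes are heterogeneous: hyperdiploid trisomies, IGH
translocations, chromosome-arm deletions, 1q gain and recurrent driver
mutations each shift prognosis in different directions. The RAG
(red-amber-green) model compresses this into one number. Detected
lesions are matched to a fixed catalogue of 22 lesion *categories*; each
category belongs to one of three groups with an arbitrary but fixed
weight — red 3.0 (adverse), amber 2.0 (neutral/intermediate), green 1.0
(favourable) — and the patient's score is the **arithmetic mean of the
matched categories' weights**, so it always lies in [1.0, 3.0]:

$$\mathrm{RAG}(S) \;=\; \frac{1}{|C(S)|}\sum_{c \,\in\, C(S)} w_c,
\qquad w_c \in \{3, 2, 1\},$$

where $C(S)$ is the set of categories matched by sample $S$. A mean was
chosen over a sum because it is technique-independent: assaying more
extensively (karyotype + FISH + exome) must not inflate the score, only
refine it. The known corollary — a favourable lesion arithmetically
dilutes an adverse one — is inherent to the mean and is asserted as a
regression test, not endorsed as a clinical claim.

Scores map onto four bands as lower-inclusive half-open intervals with
the top band closed: [1.0, 1.5) low, [1.5, 2.0) low-intermediate,
[2.0, 2.5) high-intermediate, [2.5, 3.0] high. The published band table
prints overlapping endpoints (1.5, 2.0, 2.5 appear in two rows); the
half-open convention is the package's resolution, chosen so every score
has exactly one band. Because weights are small integers, the score is
computed as an integer sum over an integer count, making the boundary
values 1.5, 2.0, 2.5 exact in floating point — band assignment never
depends on rounding.

An empty match set yields **no score** ("unscorable"), never 1.0:
absence of catalogued lesions is absence of evidence, not evidence of
low risk.

## The knowledge base

`buildDefaultKB()` loads a YAML document shipped in `inst/extdata/`; the
catalogue is data, not code, so users can re-tier or extend it and the
KB version is embedded in every result. Fifteen categories are
karyotypic (hyperdiploidy, six IGH translocations, +1q, eight
deletions, secondary t(8;14)) and carry a *cytogenetic pattern* — the
normalised descriptors that match them, e.g. `del(13)` and `del(13q)`
both match `Del(13/13q)`, and any trisomy of {1, 3, 5, 7, 9, 11, 15,
19, 21} matches `Hyperdiploidy`. Seven categories are *functional*
(Bone disease, Proliferation, NF-kB, Differentiation, DNA repair, RNA
editing, Epigenetic) and are matched only by mutated candidate gene.

**Dual listing.** Several genes appear in two categories (MMSET, TP53,
DIS3, FAM46C, CCND1, CCND3, MYC, TRAF3, CYLD, WWOX, BIRC2, BIRC3): a
gene can be disrupted by a gross karyotypic lesion *or* independently
mutated. The detection mechanism resolves the ambiguity: cytogenetic
evidence matches the chromosomal category, a sequencing mutation
matches the functional category. A FISH t(4;14) therefore scores
`t(4;14)` while an MMSET point mutation scores `Epigenetic`.
`lookupGene()` deliberately ignores this restriction and returns *all*
listing categories, since it answers a different question ("where does
this gene sit in the model?").

**Tier assignment.** The original figure placing each category in a
group is an image and is not machine-readable, so the default tiers are
reconstructed from the model's stated rules: lesions tied to poor
prognosis are red (`Del(17p)`, `t(14;16)`, `t(14;20)`, `+1q` — the
adverse set of the MRC Myeloma IX multivariate analysis), lesions tied
to superior survival are green (`Hyperdiploidy`, `t(11;14)`,
`t(6;14)`), and everything else is amber — including `t(4;14)`, which
the model explicitly demotes to intermediate risk because
bortezomib-era outcomes no longer support a high-risk label, and the
functional mutation categories, which were included on functional
characterisation and recurrence rather than independent prognostic
studies. The KB's `provenance` field flags this reconstruction; whether
`Bone disease` (DKK1, FRZB) deserves prognostic weight at all is
unresolved and it defaults to amber. Gene symbols keep the catalogue's
legacy spellings (MMSET, c-MAF, BLIMP1, NIK, TACI, MLL); matching is
case-insensitive, and modern symbols can be mapped in via the optional
`aliases` argument (e.g. `c(NSD2 = "MMSET")`) rather than silently
assumed.

**Averaging over categories, not lesions.** Three trisomies are one
hyperdiploid state, not three favourable lesions; two probes confirming
del(17p) are one deletion. Matches are therefore de-duplicated by
category before averaging, which makes the score invariant to assay
redundancy. Each match keeps all supporting aberrations for the report.

## ISS staging and the ultrahigh-risk flag

`issStage()` implements the International Staging System: stage I needs
serum beta-2-microglobulin < 3.5 mg/L *and* albumin >= 3.5 g/dL; stage
III needs beta-2-microglobulin >= 5.5 mg/L; stage II is everything
else, which covers both of its defining cases (low beta-2-microglobulin
with low albumin, or beta-2-microglobulin in [3.5, 5.5) regardless of
albumin). The mapping is total on the non-negative quadrant.
`combinedReport()` counts matched categories in the adverse set
(`adverseCategories()`) and raises the **ultrahigh** flag when the
sample is ISS II or III *and* carries more than one adverse lesion —
the combination reported to define a group with very short survival.
The package deliberately reports the flag and not survival estimates:
outcome figures belong to the trials that produced them.

## Serial samples

Myeloma genomes drift through clonal expansion and regression, so the
score is designed to be recomputed at relapse. `scoreTrajectory()`
scores each timepointed sample independently and reports per-interval
score deltas plus newly appearing and lost categories; it refuses
duplicate timepoints rather than guessing an order.

## The pizza plot

`buildPlotSpec()` turns a result into circular sectors with angle
$360 \cdot w_c / \sum w$, so red slices are always wider than amber,
and amber wider than green. Layout details the source figure leaves
open are fixed for determinism: segments run red, amber, green,
alphabetically within a group, clockwise from twelve o'clock; only the
patient's matched categories are drawn (a patient plot, not a model
plot); the palette (#d7191c / #fdae61 / #1a9641) is colour-blind-safe.
`renderSvg()` is a pure function of the spec — no timestamps, no
generated ids — so identical specs give byte-identical SVG, and each
sector carries `data-*` attributes so the geometry can be re-read and
verified mechanically. An unscorable result has nothing to draw and is
an error, not an empty plot.

## Lesion input

`parseLesionTable()` reads one-lesion-per-row TSV (FISH/karyotype
findings) with descriptor normalisation, and `parseVcf()` reads
annotated VCF via Bioconductor's VariantAnnotation, taking gene symbols
from a SnpEff-style `ANN` field (configurable key and subfield, or a
plain `GENE=` key). Coordinates are never interpreted: the gene symbol
is the unit of evidence, so no liftover or strand handling exists.
Records annotated as synonymous impart no protein change and are
excluded from scoring input — but counted and returned, never silently
dropped; variants with unrecognised consequence terms are *kept*
(conservative inclusion, since silent mutations are expected to be rare
among the model's recurrently mutated genes). The same rule is enforced
again at matching time, so a synonymous record can never reach the
score through any entry path. Unmatched aberrations (e.g. a trisomy 8
or a mutation in a non-catalogue gene) are likewise returned in a side
list.

## The synthetic cohort generator

`generateCohort()` exists so every pipeline stage is testable without
patient data. Per patient, each category is drawn independently at its
configured prevalence (default: uniform 0.1 per category, a deliberate
literature-free placeholder — the model's sources publish no prevalence
table, and the generator's job is coverage of scoring paths, not
epidemiology). Because adverse lesions are reported to cosegregate,
patients already carrying one adverse lesion give each absent adverse
category one extra draw at probability
$\min(1,\, p \cdot (\text{boost} - 1))$ (default boost 2; 1 disables
it). Memberships are then realised as concrete evidence: the stored
FISH descriptor for translocations/deletions/gains, a random subset of
at least two hyperdiploid trisomies by karyotype, and a random
candidate-gene nonsynonymous mutation for functional categories.
Synonymous decoy mutations are injected at rate 0.1 by default and must
never change any score. The ground truth records each patient's
intended category set and exact expected mean score, and
`writeFixtureFiles()` + `scoreFixtures()` close the loop: parse the
written TSV/VCF fixtures, score them, and compare — equality is exact,
not approximate.

Clinical values are drawn log-normally. The defaults —
beta-2-microglobulin $\ln\mathcal{N}(1.37, 0.77^2)$ mg/L, albumin
$\ln\mathcal{N}(\ln 3.8, 0.12^2)$ g/dL — were solved analytically so
that roughly a third of patients land in each ISS stage
($P(\beta_2m < 3.5) \approx 0.44$, $P(\beta_2m \ge 5.5) \approx 0.33$,
$P(\text{alb} \ge 3.5) \approx 0.75$, independent draws), exercising
every staging branch.

What the generator does **not** emulate: real lesion prevalences and
their correlation structure beyond the single boost mechanism, clonal
fractions and subclonal tides (serial samples are just different lesion
sets), allele-level variant detail, and any lesion outside the
catalogue. Passing end-to-end recovery therefore demonstrates that the
pipeline is faithful to the model's arithmetic and file dialects — not
that the model is clinically valid, which remains untested.

## Numerical and testing choices

Seeding uses R's Mersenne-Twister with integer seeds, so cohorts are
reproducible across platforms; file emitters use fixed-format numbers
so repeated writes are byte-identical. JSON reports serialise doubles
at 17 significant digits so scores round-trip exactly. The score-range
property is verified by exhaustive enumeration of all $2^{22}-1$
non-empty category subsets, carried out over (red, amber, green) count
triples — an exact partition of the subset lattice, since the mean
depends only on the counts; a unit test cross-checks the class
enumeration against literal enumeration of all 511 subsets of a
9-category sub-model. The test suite exercises a 500-patient simulated
cohort end-to-end (plus smaller 40-patient runs with elevated decoy
rates); these sizes give every scoring path and both ISS footnote
branches multiple hits while keeping the suite quick.

## Limitations

The package scores genes, not mutations: two different TP53 missense
variants score identically, and functional-impact prediction is
explicitly out of scope. The default tiering is a reconstruction (see
above) and is expected to be revised — ship your own YAML to re-tier.
GEP signatures, hypodiploidy and treatment recommendation are outside
the catalogue and therefore outside the score. And the model itself is
a concept system: nothing here validates it against patient outcomes.
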