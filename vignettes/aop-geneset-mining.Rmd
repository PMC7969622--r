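---
title: "Mining literature co-occurrence networks for AOP key-event genesets"
author: "aopminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining literature co-occurrence networks for AOP key-event genesets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adverse outcome pathways (AOPs) decompose the route from a molecular
initiating event (e.g. oxidative stress from tobacco smoke) through a chain
of key events (KEs: EGFR activation, decreased apoptosis and increased
proliferation of epithelial cells, acquired CFTR dysfunction, impaired
ciliogenesis) to an adverse outcome such as mucus hypersecretion and
decreased lung function in COPD. Each KE can be turned into a *geneset* — a
curated list of genes with literature evidence tying them to that event —
which then serves as a disease-relevant probe into transcriptomic data.

aopminer implements the full desk workflow for engineering and validating
such genesets:

1. **Corpus building** (`buildQuery()`, `readCorpus()`, `mergeCorpora()`):
   per-seed-gene boolean queries of the form
   `SEED AND (smoke OR tobacco OR ...)` define a document corpus of
   abstracts, handled offline in MEDLINE, JSON-lines or TSV form.
2. **Dictionary NER and the term-document matrix** (`buildTDM()`): HGNC
   symbols are matched as exact, case-sensitive tokens in title+abstract,
   producing a binary gene × document incidence matrix.
3. **Cosine co-occurrence scoring** (`cosineMatrix()`, `topPairs()`):
   gene pairs are scored by
   $c(g,h) = n_{gh} / \sqrt{n_g n_h}$
   over binary document-incidence vectors, where $n_g$ counts abstracts
   mentioning $g$ and $n_{gh}$ abstracts mentioning both. $c=0$ means never
   co-mentioned, $c=1$ means identical abstract sets.
4. **Curation into S/R/A genesets** (`applyCuration()`,
   `assembleGeneset()`): an impact-factor filter plus a machine-readable
   decision ledger reduce the evidence to a curated corpus; genes from
   surviving pairs become R-genes, pooled with the seed S-genes and
   manually added A-genes.
5. **Validation** (`hierarchicalCluster()`, `pcaFit()`,
   `associatePCs()`): geneset-restricted expression matrices are Z-scored,
   clustered (Euclidean/Ward) against known sample labels, and examined by
   PCA with per-component covariate association tests.

A synthetic-data module (`simulateCorpus()`, `simulateExpression()`)
generates both kinds of input with known ground truth, so every stage is
testable without network access.

## Scoring model and its assumptions

Cosine similarity is computed on **binary** incidence, not mention counts:
only then do the endpoints carry their advertised meaning (1 = "the two
genes appear in exactly the same abstracts"). A count-weighted variant is
available (`cosineMatrix(tdm, useCounts = TRUE)`) but off by default.
Co-occurrence granularity is the abstract, not the sentence; this inflates
recall at the cost of precision, which is exactly what the downstream
curation stage is for.

NER policy (recorded here because upstream tools leave it implicit):

* matching is case-sensitive and token-exact, with tokens delimited by any
  non-alphanumeric character — so "EGFR-dependent" matches EGFR, while
  "egfr" and "xEGFRy" do not. Case-insensitive matching floods results
  with English-word homonyms of real symbols ("IMPACT", "SET").
* aliases map to their approved symbol; symbols containing
  non-alphanumerics ("HLA-A") are matched as bounded substrings.
* an exclusion list suppresses laboratory acronyms that collide with
  gene-shaped tokens (CBF — ciliary beat frequency — being the canonical
  offender); the shipped default (`defaultExclusions()`) seeds this class
  and is meant to be extended by the analyst. Exclusions apply at match
  time, so the dictionary itself is not mutilated.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| impact-factor cut | 3.0, inclusive | JCR impact factor | restricts curation effort to ranked journals; records with *missing* IF are dropped and counted, since an unmatched journal cannot attest the evidence quality |
| network threshold | 0.1, strict (`>`) | cosine | weak-edge floor for network plots; `strict = FALSE` gives the inclusive variant for sensitivity analyses |
| top pairs | n = 60 per KE | pairs | manual-curation budget; ties at the cutoff score are kept and flagged rather than truncated arbitrarily |
| min joint docs | 1 | abstracts | pairs never co-mentioned are not ranked |
| Z-score denominator | n−1 (sample SD) | — | recorded choice; idempotent up to 1e−10 |
| Ward variant | `ward.D2` | — | see below |

Category precedence on overlap is S > R > A: a gene that is both a seed
and a pair-derived gene counts once, as a seed. This makes the Table-1
style accounting identity `n_total = |S ∪ R ∪ A|` deterministic.

## Numerical choices

* **Ward linkage.** Two historical "Ward" variants exist; aopminer uses
  the Lance–Williams update on squared Euclidean distances
  (`stats::hclust(method = "ward.D2")`), whose merge heights equal
  $\sqrt{2\,\Delta SS}$. The test suite pins this choice by comparing
  merge sequences on all point sets of size ≤ 5 against exhaustive greedy
  minimization of the within-cluster variance increase.
* **PCA** is an SVD of the column-centered sample × gene matrix. The
  default `scaleGenes = TRUE` Z-scores gene rows first, so PCA and
  clustering see identical data; set it to `FALSE` to center only.
  Complete data are required — imputation is out of scope.
* **Association tests**: one-way ANOVA F for categorical covariates,
  Spearman rank correlation for continuous ones (exact = FALSE, so ties
  are tolerated). Raw p-values are reported with Benjamini–Hochberg
  adjusted companions; single-level covariates are skipped with a warning.
* **Tie-breaking** in `topPairs()` is deterministic: (score desc, joint
  count desc, lexicographic pair); "tie at the cutoff" is defined on the
  score alone.
* **Degenerate inputs**: zero-variance rows are dropped before Z-scoring
  (all-constant input errors); a term-document matrix needs ≥ 2 genes to
  score; an empty geneset ∩ matrix intersection is an error, a partial
  one a report.

## What the simulators emulate — and what they do not

`simulateCorpus()` draws from a block model: each document is assigned one
gene block uniformly at random, and gene $g$ is mentioned in document $d$
with probability $q \cdot p_{in}$ if $g$ belongs to $d$'s block, else
$q \cdot p_{out}$. This model was chosen because it has exactly the three
properties the pipeline needs to be tested against: forced co-mention
($q = p_{in} = 1$) gives cosine 1; separated blocks ($p_{out} = 0$) give
cross-block cosine exactly 0; and a single block with $p_{in} = 1$ makes
mentions independent Bernoulli($q$), for which the expected cosine is $q$.
`expectedCosine()` evaluates the closed form
$E[n_{ab}] / \sqrt{E[n_a] E[n_b]}$ (or a Monte-Carlo mean with standard
error). Document text is rendered from templates with gene symbols as
standalone tokens, so NER recall is 100% by construction and the
co-occurrence statistics — not tokenizer luck — are what tests exercise; an
adversarial mode stresses the NER policy instead (hyphenated mentions,
lowercase decoys, excluded acronyms). The simulator makes no attempt to
mimic real PubMed language statistics, journal metadata joint
distributions, or citation structure: a green planted-structure test shows
the arithmetic is right, not that real literature is this clean.

`simulateExpression()` produces a Gaussian baseline on a normalized
log-like scale (default mean 7, SD 1), a treated-group mean shift δ on the
geneset genes, and optionally a continuous technical confounder loading on
a disjoint gene block. Defaults state the validation world used throughout
the tests: 100 genes, a 25-gene geneset, 10 + 10 samples, δ = 5·noise SD.
The confounder block defaults (15 genes, loading 2·noise SD) follow an
a-priori eigenvalue argument: after row Z-scoring, the treatment axis
carries a signal fraction ≈ δ²/4 / (δ²/4 + 1) ≈ 0.86 over 25 genes
(eigenvalue ≈ 21.6), the confounder ≈ 4/5 over 15 genes (≈ 12), and the
noise bulk tops out near (1 + √(p/n))² ≈ 7.5 — so the treatment owns PC1,
the confounder PC2, and both stand clear of noise. Real RNA-seq count
distributions, library-size effects and batch structure are deliberately
not modelled; the validation module consumes already-normalized matrices.

## Design decisions that were genuinely open

* The source corpus is consumed **offline** (files in MEDLINE, JSON-lines
  or TSV dialects); any live-database fetcher is out of scope, which keeps
  runs reproducible and auditable. JSON-lines is the canonical lossless
  dialect; MEDLINE has no impact-factor tag, so annotate after import.
* The impact-factor year/version is the analyst's choice via the supplied
  table; journal matching is deterministic normalization (lowercase, trim,
  collapse whitespace), never fuzzy.
* Manual curation is represented as a replayable decision ledger rather
  than automated relevance classification; replaying the same ledger twice
  is bit-identical.
* Merging overlapping key events (e.g. decreased apoptosis with increased
  proliferation) is an explicit user action (`mergeGenesets()`), not an
  automatic overlap-threshold rule — no defensible threshold exists.
* Whether to Z-score before PCA or center only is exposed
  (`scaleGenes`); the default mirrors the clustering preprocessing.

## Known limitations

* Dictionary NER does no species or word-sense disambiguation beyond the
  exclusion list; a human-curated exclusion list remains necessary.
* Abstract-level co-occurrence cannot see interaction direction or sign;
  edges are undirected and unsigned by design.
* Cluster-label agreement (adjusted Rand index, purity) quantifies
  *separation*, not biological specificity: any gene list correlated with
  the contrast would separate the groups.
* Impact factor is a journal-level proxy and the 3.0 cut is a budget
  device, not a quality judgment on individual papers.
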