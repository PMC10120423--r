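---
title: "The varmat engine: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The varmat engine: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varmat)
```

## The problem

Resequencing and genotyping-by-sequencing projects produce variant call
matrices — samples × variants tables of genotypes — that routinely reach
hundreds of millions of variants for thousands of samples. Exploring such a
matrix interactively requires (i) random access to arbitrary windows of the
matrix without re-parsing the VCF, (ii) summary statistics computed on the
fly for whatever subset of samples (the *genotype panel*) the user selects,
and (iii) lightweight analyses — PCA, genetic distance — scoped to a gene or
genomic window rather than the whole genome. `varmat` is the server-side
engine for that workflow: it owns the storage, slicing, statistics, filters,
analyses, annotation search and export, and exposes them as R functions and
as a stateless JSON request handler that any front end can consume.

## The dosage model

All genotypes are reduced at conversion time to **alternate-allele dosage**:
for a genotype call at a variant, the number of non-reference alleles it
carries, an integer in `0..ploidy`. This is the quantity the engine's
analyses are defined on (genotype vectors for distance and PCA "contain the
number of alternative alleles").

Three conventions complete the model:

* **Multi-allelic collapse.** At sites with several ALT alleles, every
  non-reference allele counts 1 toward the dosage (`1/2` has dosage 2).
  Dosage does not record *which* alternate allele was seen; exports
  re-serialize collapsed calls with allele `1`. This was a genuinely open
  design point; collapse is the reading most consistent with defining
  genotype vectors by a single number per variant, and it is flagged here
  because analyses that distinguish alternate alleles cannot be run
  downstream of this store.
* **Missingness is atomic.** Any genotype containing a missing allele call
  (`./.`, `.`, and half-calls like `./1`) is stored as wholly missing,
  sentinel `-1`. Half-calls carry partial information, but treating them as
  data would make dosage a non-integer quantity; the conservative rule is
  simpler and safer.
* **Phase is discarded.** `0|1` and `0/1` have equal dosage; exports write
  unphased separators. Dosage is phase-invariant by construction.

Only haploid and diploid genotypes are supported, uniformly per file; mixed
or higher ploidy is rejected at conversion with an error naming the first
offending record. Positions must be strictly increasing within a
chromosome; duplicate positions are rejected, because position→index lookup
is a binary search whose semantics require strict ordering.

## The chunked store

`convert_vcf()` streams through the VCF (plain or gzip/BGZF-compressed) and
writes a directory store: JSON metadata, a per-chromosome variant table
(position, REF, ALT, QUAL, INFO/MQ, INFO/ANN), and the dosage matrix in
gzip-compressed binary chunks of `chunk_variants` columns (default 5000)
with all samples per chunk. Chunking is along the variant axis because every
access pattern in the engine is "a window of variants × a panel of samples".
Memory during conversion is bounded by the chunk, not the file. No other
INFO or FORMAT fields survive conversion; this is deliberate lossiness,
documented under Export below.

No R binding for a cloud-native chunked-array format was available in the
target environment, so the store is a purpose-built directory layout with
the same access properties (index-based random access to row/column
blocks); the on-disk format is private to the package and versioned in its
metadata.

## Ad hoc statistics

For each variant of a slice, over the current panel of size $n$ with
$n_c$ called genotypes and ploidy $m$:

* alternate-allele frequency $p = \sum d_i / (m\,n_c)$ over called dosages
  $d_i$;
* **minor allele frequency** $\mathrm{maf} = \min(p, 1-p) \in [0, 0.5]$,
  folded over the {reference, collapsed-alternate} pair;
* **heterozygosity fraction**: share of called diploid genotypes with
  dosage 1; identically 0 for haploid data;
* **missing fraction**: missing calls divided by the *full* panel size $n$.

Two denominator choices were open. `maf` and the heterozygosity fraction
use called genotypes only ($n_c$), the standard population-genetics
convention that keeps both statistics in range regardless of missingness;
the missing fraction uses the full panel, since it measures the panel, not
the calls. A variant with $n_c = 0$ has `maf` and `het_fraction`
**undefined** — `NA` in R, `null` in JSON payloads — never 0, because 0 is a
meaningful value for both (the browser colour tracks encode magnitude).

## Filters

`filter_criteria()` holds optional inclusive ranges over `maf`,
heterozygosity and missingness, plus lower bounds on the VCF-derived QUAL
and INFO/MQ attributes (which cannot be recomputed ad hoc — they come from
the variant caller). All bounds are inclusive. A variant with an undefined
statistic fails any criterion set on that statistic, so all-missing
variants cannot leak through a filter into PCA or export. Masks are pure
conjunctions; the monotonicity and conjunction properties are tested
against brute-force predicate loops.

## PCA

`run_pca()` is computed on demand over a region (viewport window, gene, or
explicit range), after removing variants with no called genotype and,
optionally, variants failing filter criteria. The variant count is capped at
`pca_max_variants` (default 10,000, an order of magnitude consistent with
interactive slice sizes; tunable in the config): the cap keeps the
*left-most* variants in position order, a deterministic and explainable
rule. Then:

1. missing dosages are imputed with the per-variant mean of called dosages;
2. columns are mean-centered; **no variance standardization** is applied
   (no Patterson scaling) — the method named is plain PCA on dosage
   vectors, and the simplest faithful reading was chosen and documented so
   users can compare against scaled PCAs;
3. scores are taken from the SVD of the centered matrix;
   `explained_variance_ratio` is $d_k^2 / \sum_j d_j^2$.

Monomorphic variants are retained (no prior filtering of the VCF content is
ever applied) and are exactly inert after centering. Each component's sign
is fixed so its largest-magnitude variant loading is positive, making
output reproducible across runs; note that for exactly degenerate
eigenvalues the component basis itself is arbitrary, as in any PCA.

## Genetic distance and sample ordering

The reference genome carries zero alternate alleles, so a sample's genetic
distance to it is the Euclidean norm of its (imputed) dosage vector over
the chosen region — the simplest estimator of genetic distance, matching
the pairwise-Euclidean-distance definition with an implicit all-zero
reference row. `sort_samples()` orders a panel alphabetically
(case-insensitive, ties stable) or ascending by this distance (ties broken
by identifier, so the ordering is a deterministic permutation).

## Annotation

`load_gff3()` parses GFF3 with 1-based inclusive coordinates kept
throughout (the VCF side is also 1-based inclusive, so no shift exists
anywhere in the engine). Parse errors carry line numbers; features
referencing unknown `Parent` ids are kept with a warning; children
extending beyond their parents are flagged. Chromosome labels rarely agree
between VCF and GFF3, so a label map is inferred: exact match first, then
match after stripping a leading `chr`/`Chr`/`CHR` from either side;
unresolved labels must be configured manually (they are written as `TODO`
markers by `infer_config()`).

Gene search matches case-insensitive substrings of id, Name, description
and Note (both description-bearing keys are searched, since GFF3 dialects
disagree on which one carries it). Variant counts per gene use interval
containment of store positions in the gene body; when
`count_exon_variants` is enabled, the count over the **union** of the
gene's exon intervals is added — union, not sum, so variants in exons
shared by several isoforms are not double-counted. Strand never affects
counting: variants are strandless positions. SnpEff `ANN` strings are
parsed into one record per annotation (allele, effect, impact, gene,
transcript); configured link templates substitute a URL-encoded id for the
`{id}` placeholder (ontology terms like `GO:0008150` percent-encode the
colon).

## Export

`export_vcf()` writes VCF 4.2 for a region, panel and optional filter mask.
Because the store is dosage-oriented, export is documented as lossy:
genotypes are re-serialized from dosage (`0/0`, `0/1`, `1/1`, `./.`;
haploid `0`, `1`, `.`), phasing is not preserved, multi-allelic calls come
back as allele `1`, and INFO is reconstructed minimally (MQ, ANN when
present). What is exact: positions, alleles, QUAL, MQ, ANN, and — the
tested invariant — the dosage matrix round-trips bit-exactly through
`convert_vcf(export_vcf(...))`. `export_gff3()` writes every feature
overlapping the region *plus all ancestors*, whole records with unmodified
coordinates, so the output is referentially closed.

## Server and CLI

The JSON facade is a pure function `vm_handle(app, method, path, body)`;
every endpoint is deterministic in (dataset on disk, request), which the
tests verify as byte-identical repeated responses. Errors carry the
library's machine-readable codes (`ploidy`, `ordering`, `format`,
`lookup`, `panel`, `argument`, `analysis`, `mapping`, `parse`, `config`).
Filtered slices drop excluded variants and keep scanning forward so a page
still carries `count` passing variants when available — pagination in
"passing variants" units, which is what a gapless display needs. An HTTP
binding (`vm_serve()`, httpuv) adds transport only. The BLAST entry point
requires an external alignment service and ships as an interface stub that
reports the feature as not configured.

The CLI (`vm_cli()`; verbs `convert`, `infer-config`, `start`) detects
`.vcf`/`.vcf.gz` and `.gff`/`.gff3` files in the working directory,
selects interactively when several are present (non-interactive runs must
pass `--vcf`), infers a YAML configuration (chromosome labels and counts,
label map, defaults), and starts a session, converting only when the store
is absent or older than its VCF. A corrupted store is never silently
overwritten; regeneration requires `force`.

## The synthetic-fixture world

`generate_vcf()` draws, per variant, an alternate-allele frequency
$p \sim U(0.02, 0.5)$, then genotypes per sample under Hardy–Weinberg
equilibrium (each of the `ploidy` alleles is alternate with probability
$p$), injects missing calls independently at `missing_rate` (default 0.05;
a fraction written as half-calls), makes a fraction of sites multi-allelic
(0.1) and of genotypes phased (0.2), and attaches QUAL/MQ values and
SnpEff-style ANN strings. The Hardy–Weinberg draw gives the heterozygosity
fraction the analytic expectation $2p(1-p)$, which anchors the stochastic
acceptance check. `generate_gff3()` lays out non-overlapping genes with 1–3
non-overlapping exons and emits ground-truth per-gene body and exon-union
variant counts.

What the generator does **not** emulate: linkage disequilibrium between
variants, population structure or relatedness among samples, realistic
site-frequency spectra, indels/structural variants, or correlated
missingness. A green test therefore establishes algorithmic correctness
(slicing, counting, algebra, round-trips) — not that biological inferences
from PCA on real panels will look like they do on these fixtures.

## Numerical and degenerate-input choices

* Statistics are ratios of exact integer counts; the oracle tests compare
  them bit-for-bit (`missing/n`, not `1 - called/n`, to keep division
  order canonical).
* PCA agreement with a dense eigendecomposition oracle is asserted at
  `1e-8` per component, up to sign.
* Empty slices, empty chromosomes, zero-record VCFs, header-only GFF3
  files and empty export regions are all valid and produce well-formed
  empty outputs; an empty panel, an invalid range (`lo > hi`), or a region
  with too few usable variants for PCA/distance raise typed errors with
  the post-filter counts attached.

## Limitations

* Single-nucleotide-style dosage only; structural variants and ploidy > 2
  are out of scope.
* The store is lossy beyond GT/QUAL/MQ/ANN; it is a browsing index, not an
  archival copy of the VCF.
* Per-genotype FORMAT-level filtering (e.g. read depth) is not supported;
  filters operate on variant-level statistics and attributes only.
* PCA at very large panel × variant sizes is bounded by `pca_max_variants`
  rather than by an incremental solver.
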