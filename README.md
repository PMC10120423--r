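# varmat

`varmat` is a server-side engine for interactively exploring **variant call
matrices** — the samples × variants genotype tables stored in VCF files by
resequencing and genotyping-by-sequencing pipelines. It is written for
maintainers of genomic-diversity resources (genebank genomics portals,
species diversity browsers) who need to serve slices and summaries of very
large VCFs to a web front end, and for analysts who want the same
primitives at the R console.

The engine:

* converts VCF (haploid or diploid) into a **chunked, compressed dosage
  store** with random access by variant index or physical position;
* serves **gapless variant slices**: a fixed count of consecutive variants
  for an arbitrary genotype panel, with physical coordinates alongside;
* computes ad hoc per-variant statistics over the current panel — minor
  allele frequency, heterozygosity fraction, missing fraction;
* applies inclusive **range filters** over those statistics and over
  VCF-derived QUAL / INFO/MQ attributes;
* runs **on-demand PCA** and **Euclidean genetic-distance sample
  ordering** over a viewport window, a gene, or an explicit range;
* searches **GFF3 gene annotation** (with per-gene and exon-union variant
  counts, SnpEff ANN parsing and configurable external links);
* exports standards-compliant **VCF and GFF3** subsets;
* exposes everything through a stateless **JSON request handler** (plus an
  optional httpuv binding) and a **CLI** with YAML configuration
  inference.

## The model in brief

Every genotype is reduced to an alternate-allele **dosage**
`d ∈ {0, …, ploidy}` (missing = −1; multi-allelic sites collapse all
alternate alleles; half-calls are missing). For a panel of size *n* with
*n<sub>c</sub>* called genotypes at a variant and ploidy *m*:

* allele frequency `p = Σd / (m·n_c)`, folded `maf = min(p, 1 − p)`;
* heterozygosity fraction = share of called diploid genotypes with `d = 1`;
* missing fraction = missing calls / *n*.

Variants with `n_c = 0` have undefined (`NA`/`null`) statistics — never 0.
PCA mean-imputes missing dosages per variant, mean-centers, and takes SVD
scores (no variance scaling; monomorphic variants are inert); genetic
distance to the reference is the Euclidean norm of the imputed dosage
vector. See the vignette (`vignettes/variant-matrix-engine.Rmd`) for every
convention and its rationale.

## Worked example

Everything below is generated synthetically — no downloads. The fixture
generator is part of the package and returns ground truth alongside each
file.

```r
library(varmat)

dir <- tempfile(); dir.create(dir)
spec <- fixture_spec(n_samples = 50, n_variants = c(chr1H = 500), seed = 42)
fx <- generate_vcf(spec, file.path(dir, "panel.vcf"))
gf <- generate_gff3(fx, file.path(dir, "panel.gff3"))

ds <- convert_vcf(fx$path, file.path(dir, "store"))
ds
#> <vm_dataset> /tmp/.../store
#>   samples: 50  ploidy: 2
#>   chr1H: 500 variants

# the first 5 variants at or after position 1, with panel statistics
sl <- slice_by_count(ds, "chr1H", start_position = 1, count = 5)
st <- compute_stats(sl)
data.frame(pos = sl$positions, maf = round(st$maf, 3),
           het = round(st$het_fraction, 3),
           miss = round(st$missing_fraction, 3), n_called = st$n_called)
#>   pos   maf   het miss n_called
#> 1 112 0.160 0.319 0.06       47
#> 2 265 0.438 0.542 0.04       48
#> 3 339 0.337 0.673 0.02       49
#> 4 567 0.256 0.422 0.10       45
#> 5 713 0.250 0.375 0.04       48
```

`maf` is the folded frequency of the rarer allele among called genotypes,
`het` the share of called genotypes that are heterozygous, `miss` the share
of the 50-sample panel without a call.

```r
pca <- run_pca(ds, vm_region(chromosome = "chr1H", start = 1, end = 1e9), k = 2)
pca
#> <vm_pca> 50 samples x 2 components; 500 variants (0 filtered out)
#>   explained variance ratio: 0.03667, 0.03473
head(pca$coordinates, 3)
#>             PC1       PC2
#> S001 -2.1327249 -1.004895
#> S002  0.1589693 -3.672958
#> S003  1.2134573  4.940822
```

With unstructured Hardy–Weinberg fixtures the leading components explain
little variance (~3.7%), exactly as population-structure-free data should.

```r
sort_samples(ds, mode = "distance",
             region = vm_region(chromosome = "chr1H", start = 1, end = 1e9))
#> <vm_ordering> mode=distance: S015, S037, S013, S047, S040, ...

ann <- set_label_map(load_gff3(gf$path), infer_label_map(ds$chromosomes, "1H"))
search_genes(ann, ds, query = "dwarf", count_exon_variants = TRUE)[,
  c("gene_id", "description", "start", "end", "n_variants_gene", "n_variants_exons")]
#>   gene_id        description start   end n_variants_gene n_variants_exons
#> 1 GENE004 dwarf growth habit 56170 65512              61               30

export_vcf(ds, file.path(dir, "window.vcf"),
           vm_region(chromosome = "chr1H", start = 1, end = 30000),
           criteria = filter_criteria(maf_range = c(0.1, 0.5)))
#> records exported: 162
```

The exported file is VCF 4.2; re-converting it reproduces the original
dosages bit-exactly (a tested invariant).

### JSON facade and CLI

```r
app <- vm_app(ds, ann, list(count_exon_variants = TRUE))
vm_handle(app, "POST", "/v1/slice",
          list(chromosome = "chr1H", start_position = 1, count = 5))$body
# vm_serve(app, port = 8090)   # optional live HTTP server (httpuv)
```

From a shell, in a directory containing a VCF (and optionally a GFF3):

```sh
Rscript -e 'varmat::vm_cli()' infer-config     # writes varmat.config.yml
Rscript -e 'varmat::vm_cli()' start --port 8090
```

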