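whole_chr1 <- function() vm_region(chromosome = "chr1", start = 1, end = 1e9)

test_that("mean imputation fills missing entries and leaves calls alone", {
  d <- matrix(c(0L, 2L, -1L,
                1L, -1L, -1L,
                0L, 1L, 2L), nrow = 3, byrow = FALSE)
  out <- impute_missing(d)
  expect_equal(out[, 1], c(0, 2, 1))      # mean of called = 1
  expect_equal(out[, 2], c(1, 1, 1))      # single-value mean
  expect_equal(out[, 3], c(0, 1, 2))      # untouched
  expect_error(impute_missing(matrix(c(-1L, -1L), ncol = 1)),
               class = "vm_internal_error")
})

test_that("PCA matches an independent eigendecomposition oracle to 1e-8", {
  fix <- the_fixture()
  panel <- fix$ds$samples[1:20]
  sl <- slice_by_range(fix$ds, "chr1", 1, 1e9, panel)
  usable <- which(colSums(sl$dosages >= 0) > 0)[1:50]
  res <- run_pca(fix$ds, whole_chr1(), panel = panel, k = 4)
  # oracle: gram-matrix eigendecomposition of the same usable columns
  keep <- which(colSums(sl$dosages >= 0) > 0)
  or <- oracle_pca_scores(sl$dosages[, keep, drop = FALSE], 4)
  for (j in 1:4)
    expect_equal(abs(unname(res$coordinates[, j])), abs(or$scores[, j]),
                 tolerance = 1e-8)
  expect_equal(res$explained_variance_ratio, or$evr, tolerance = 1e-8)
})

test_that("duplicated samples receive identical coordinates", {
  rows <- c(vcf_row("1", 10, c("0/1", "0/1", "1/1")),
            vcf_row("1", 20, c("1/1", "1/1", "0/0")),
            vcf_row("1", 30, c("0/0", "0/0", "0/1")))
  ds <- convert_vcf(write_test_vcf(rows, c("dup1", "dup2", "other")),
                    tempfile())
  res <- run_pca(ds, list(chromosome = "1", start = 1, end = 99), k = 2)
  expect_equal(res$coordinates["dup1", ], res$coordinates["dup2", ])
})

test_that("monomorphic variants are inert after centering", {
  # generic dosages (distinct singular values, so no degenerate eigenspace)
  gts <- list(c("0/1", "1/1", "0/0", "0/1", "0/0", "1/1"),
              c("1/1", "0/0", "0/1", "0/1", "0/0", "0/1"),
              c("0/0", "0/1", "1/1", "0/0", "0/1", "0/0"),
              c("0/1", "0/0", "0/1", "1/1", "1/1", "0/0"))
  s <- c("a", "b", "c", "d", "e", "f")
  rows_plain <- mapply(vcf_row, pos = c(10, 20, 30, 40), gts = gts,
                       MoreArgs = list(chrom = "1"))
  rows_mono <- c(rows_plain, vcf_row("1", 50, rep("1/1", 6)),
                 vcf_row("1", 60, rep("0/0", 6)))
  ds1 <- convert_vcf(write_test_vcf(rows_plain, s), tempfile())
  ds2 <- convert_vcf(write_test_vcf(rows_mono, s), tempfile())
  r1 <- run_pca(ds1, list(chromosome = "1", start = 1, end = 99), k = 2)
  r2 <- run_pca(ds2, list(chromosome = "1", start = 1, end = 99), k = 2)
  expect_equal(r1$coordinates, r2$coordinates, tolerance = 1e-10)
  expect_equal(r2$n_variants_used, 6L)    # monomorphic retained, not filtered
})

test_that("the variant cap keeps exactly the left-most variants", {
  fix <- the_fixture()
  capped <- run_pca(fix$ds, whole_chr1(), k = 2, max_variants = 10)
  expect_equal(capped$n_variants_used, 10L)
  sl <- slice_by_range(fix$ds, "chr1", 1, 1e9)
  usable_pos <- sl$positions[colSums(sl$dosages >= 0) > 0]
  explicit <- run_pca(fix$ds, vm_region(chromosome = "chr1", start = 1,
                                        end = usable_pos[10]), k = 2)
  expect_equal(explicit$n_variants_used, 10L)
  expect_equal(capped$coordinates, explicit$coordinates, tolerance = 1e-10)
})

test_that("filter criteria restrict the PCA and counts are reported", {
  fix <- the_fixture()
  crit <- filter_criteria(maf_range = c(0.1, 0.5))
  res <- run_pca(fix$ds, whole_chr1(), criteria = crit, k = 2)
  sl <- slice_by_range(fix$ds, "chr1", 1, 1e9)
  st <- compute_stats(sl)
  mask <- apply_filter(st, sl, crit)
  expect_equal(res$n_variants_used, sum(mask))
  expect_equal(res$variants_excluded_by_filter,
               sum(!mask & st$n_called > 0))
})

test_that("explained variance ratios are non-increasing and sum below 1", {
  fix <- the_fixture()
  res <- run_pca(fix$ds, whole_chr1(), k = 6)
  expect_true(all(diff(res$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(res$explained_variance_ratio), 1 + 1e-9)
})

test_that("permuting the panel permutes coordinate rows identically", {
  fix <- the_fixture()
  panel <- fix$ds$samples[1:12]
  perm <- sample(panel)
  a <- run_pca(fix$ds, whole_chr1(), panel = panel, k = 3)
  b <- run_pca(fix$ds, whole_chr1(), panel = perm, k = 3)
  expect_equal(a$coordinates[perm, ], b$coordinates, tolerance = 1e-9)
})

test_that("PCA failure modes carry post-filter counts", {
  fix <- the_fixture()
  err <- tryCatch(
    run_pca(fix$ds, whole_chr1(), criteria = filter_criteria(qual_min = 1e6)),
    vm_analysis_error = identity)
  expect_s3_class(err, "vm_analysis_error")
  expect_equal(err$details$n_variants, 0L)
  expect_error(run_pca(fix$ds, whole_chr1(), panel = fix$ds$samples[1]),
               class = "vm_analysis_error")
})

test_that("distance to the reference is the Euclidean norm of the dosage vector", {
  expect_equal(unname(distance_to_reference(matrix(c(2, 2), nrow = 1))),
               sqrt(8))
  expect_equal(unname(distance_to_reference(matrix(0, nrow = 1, ncol = 5))),
               0)
  expect_equal(unname(distance_to_reference(matrix(c(1, 0, 1, 1), nrow = 1))),
               sqrt(3))
})

test_that("alphabetical ordering is case-insensitive with stable ties", {
  rows <- vcf_row("1", 10, c("0/0", "0/1", "1/1"))
  ds <- convert_vcf(write_test_vcf(rows, c("b", "A", "c")), tempfile())
  asc <- sort_samples(ds, mode = "alpha_asc")
  expect_equal(asc$order, c("A", "b", "c"))
  desc <- sort_samples(ds, mode = "alpha_desc")
  expect_equal(desc$order, rev(asc$order))
})

test_that("distance ordering matches brute force and puts the reference first", {
  fix <- the_fixture()
  reg <- list(chromosome = "chr1", start = 1, end = 1e9)
  res <- sort_samples(fix$ds, mode = "distance", region = reg)
  sl <- slice_by_range(fix$ds, "chr1", 1, 1e9)
  usable <- colSums(sl$dosages >= 0) > 0
  x <- sl$dosages[, usable, drop = FALSE] * 1.0
  for (j in seq_len(ncol(x))) {            # brute-force imputation
    v <- x[, j]; v[v < 0] <- mean(v[v >= 0]); x[, j] <- v
  }
  dist <- sqrt(rowSums(x * x))             # explicit zero reference row
  expect_equal(res$order, fix$ds$samples[order(dist, fix$ds$samples)])
  expect_equal(res$key, unname(sort(dist)[seq_along(dist)]),
               tolerance = 1e-12)
})

test_that("an all-reference genotype sorts first in distance mode", {
  rows <- c(vcf_row("1", 10, c("0/1", "0/0", "1/1")),
            vcf_row("1", 20, c("1/1", "0/0", "0/1")))
  ds <- convert_vcf(write_test_vcf(rows, c("x", "ref", "y")), tempfile())
  res <- sort_samples(ds, mode = "distance",
                      region = list(chromosome = "1", start = 1, end = 99))
  expect_equal(res$order[1], "ref")
  expect_equal(res$key[1], 0)
})

test_that("distance mode requires a region that resolves to variants", {
  fix <- the_fixture()
  expect_error(sort_samples(fix$ds, mode = "distance"),
               class = "vm_argument_error")
  expect_error(
    sort_samples(fix$ds, mode = "distance",
                 region = list(chromosome = "chr1", start = 2, end = 3)),
    class = "vm_analysis_error")
})

test_that("feature regions resolve through the annotation's bounds", {
  fix <- the_fixture()
  g <- fix$gf$truth[1, ]
  res <- run_pca(fix$ds, vm_region(feature = g$gene_id), ann = fix$ann, k = 2)
  direct <- run_pca(fix$ds, vm_region(chromosome = g$vcf_chromosome,
                                      start = g$start, end = g$end), k = 2)
  expect_equal(res$coordinates, direct$coordinates)
  expect_error(run_pca(fix$ds, vm_region(feature = "NOPE"), ann = fix$ann),
               class = "vm_lookup_error")
})
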