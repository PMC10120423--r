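# Independent oracles. These deliberately re-derive results with naive
# loops and simple rules, sharing no code with the engine.

# line-by-line VCF text parse: returns samples, ploidy and, per chromosome,
# positions/ref/alt/qual/mq/ann and the dosage matrix (missing = -1)
naive_parse_vcf <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  lines <- readLines(con)
  close(con)
  hdr <- lines[startsWith(lines, "#")]
  samples <- strsplit(hdr[length(hdr)], "\t", fixed = TRUE)[[1]][-(1:9)]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  chroms <- list()
  ploidy <- NA_integer_
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    gts <- sub(":.*$", "", f[-(1:9)])
    allele_lists <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/",
                             fixed = TRUE)
    if (is.na(ploidy)) ploidy <- length(allele_lists[[1]])
    dos <- vapply(allele_lists, function(a) {
      if (any(a == ".")) -1L else sum(a != "0")
    }, integer(1))
    info_parts <- strsplit(f[8], ";", fixed = TRUE)[[1]]
    grab <- function(key) {
      hit <- info_parts[startsWith(info_parts, paste0(key, "="))]
      if (length(hit)) sub("^[^=]*=", "", hit[1]) else NA_character_
    }
    c <- f[1]
    if (is.null(chroms[[c]]))
      chroms[[c]] <- list(positions = integer(0), ref = character(0),
                          alt = character(0), qual = numeric(0),
                          mq = numeric(0), ann = character(0),
                          dosage = NULL)
    e <- chroms[[c]]
    e$positions <- c(e$positions, as.integer(f[2]))
    e$ref <- c(e$ref, f[4])
    e$alt <- c(e$alt, f[5])
    e$qual <- c(e$qual, if (f[6] == ".") NA_real_ else as.numeric(f[6]))
    e$mq <- c(e$mq, suppressWarnings(as.numeric(grab("MQ"))))
    e$ann <- c(e$ann, grab("ANN"))
    e$dosage <- cbind(e$dosage, dos)
    chroms[[c]] <- e
  }
  for (c in names(chroms)) rownames(chroms[[c]]$dosage) <- samples
  list(samples = samples, ploidy = ploidy, chroms = chroms)
}

# double-loop statistics recomputation over a dosage matrix
naive_stats <- function(dosage, ploidy) {
  n_panel <- nrow(dosage)
  nv <- ncol(dosage)
  maf <- het <- miss <- rep(NA_real_, nv)
  ncall <- integer(nv)
  for (j in seq_len(nv)) {
    called <- 0L; alt <- 0L; hets <- 0L; missing <- 0L
    for (i in seq_len(n_panel)) {
      d <- dosage[i, j]
      if (d < 0) { missing <- missing + 1L } else {
        called <- called + 1L
        alt <- alt + d
        if (ploidy == 2L && d == 1L) hets <- hets + 1L
      }
    }
    ncall[j] <- called
    miss[j] <- missing / n_panel
    if (called > 0L) {
      p <- alt / (ploidy * called)
      maf[j] <- min(p, 1 - p)
      het[j] <- if (ploidy == 2L) hets / called else 0
    }
  }
  list(maf = maf, het_fraction = het, missing_fraction = miss,
       n_called = ncall)
}

# per-variant brute-force filter predicate
naive_filter <- function(st, qual, mq, crit) {
  nv <- length(st$maf)
  ok <- logical(nv)
  pass_range <- function(v, r) !is.na(v) && v >= r[1] && v <= r[2]
  for (j in seq_len(nv)) {
    good <- TRUE
    if (!is.null(crit$maf_range)) good <- good && pass_range(st$maf[j], crit$maf_range)
    if (!is.null(crit$het_range)) good <- good && pass_range(st$het_fraction[j], crit$het_range)
    if (!is.null(crit$missing_range)) good <- good && pass_range(st$missing_fraction[j], crit$missing_range)
    if (!is.null(crit$qual_min)) good <- good && !is.na(qual[j]) && qual[j] >= crit$qual_min
    if (!is.null(crit$mq_min)) good <- good && !is.na(mq[j]) && mq[j] >= crit$mq_min
    ok[j] <- good
  }
  ok
}

# dense PCA oracle via eigendecomposition of the sample covariance of the
# centered, mean-imputed matrix (the engine uses svd(); routes differ)
oracle_pca_scores <- function(dosage, k) {
  x <- dosage * 1.0
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    v[v < 0] <- mean(v[v >= 0])
    x[, j] <- v - mean(v)
  }
  cv <- x %*% t(x)              # Gram matrix; eigenvectors = left singular
  eg <- eigen(cv, symmetric = TRUE)
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), nrow = k)
  evr <- eg$values / sum(pmax(eg$values, 0))
  list(scores = scores, evr = evr[seq_len(k)])
}
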