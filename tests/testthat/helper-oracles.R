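# Independent oracles used to freeze expected values. These deliberately use
# different computational routes than the package (full enumeration instead of
# closed forms / conditional recurrences).

# Exact HWE p-value by brute-force enumeration of all genotype-count triples
# compatible with the observed allele counts, using the multinomial formula.
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  configs <- expand.grid(i = 0:n, j = 0:n)
  configs <- configs[configs$i + configs$j <= n, ]
  configs$k <- n - configs$i - configs$j
  configs <- configs[2 * configs$i + configs$j == n_a, ]
  lw <- lfactorial(n) - lfactorial(configs$i) - lfactorial(configs$j) -
    lfactorial(configs$k) + configs$j * log(2)
  pr <- exp(lw - max(lw))
  pr <- pr / sum(pr)
  p_obs <- pr[configs$i == n_aa & configs$j == n_ab]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# all unordered genotypes for k alleles, with HWE frequencies
oracle_genotypes <- function(freqs) {
  k <- length(freqs)
  gt <- list(); pr <- numeric(0)
  for (i in seq_len(k)) for (j in i:k) {
    gt[[length(gt) + 1L]] <- c(i, j)
    pr <- c(pr, if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j])
  }
  list(gt = gt, pr = pr)
}

# PI by enumerating all genotype pairs: sum of squared HWE genotype frequencies
oracle_pi <- function(freqs) {
  sum(oracle_genotypes(freqs)$pr^2)
}

# PI-sibs by exhaustive enumeration over parental genotype pairs and the
# Mendelian offspring distribution of each.
oracle_pisib <- function(freqs) {
  g <- oracle_genotypes(freqs)
  n_g <- length(g$gt)
  geno_id <- function(a, b) paste(sort(c(a, b)), collapse = "/")
  ids <- vapply(g$gt, function(x) geno_id(x[1], x[2]), character(1))
  total <- 0
  for (m in seq_len(n_g)) for (f in seq_len(n_g)) {
    # offspring distribution given this parental pair
    off <- stats::setNames(numeric(length(ids)), ids)
    for (am in g$gt[[m]]) for (af in g$gt[[f]]) {
      off[geno_id(am, af)] <- off[geno_id(am, af)] + 0.25
    }
    total <- total + g$pr[m] * g$pr[f] * sum(off^2)
  }
  total
}

# small genotype matrix from per-locus call strings like "0/0", "1/2", "./."
make_gm <- function(calls, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                    samples = NULL) {
  L <- length(calls)
  n <- length(calls[[1]])
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) pos <- 1000L * seq_len(L)
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep(list("G"), L)
  if (!is.list(alt)) alt <- as.list(alt)
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(n))
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    parts <- strsplit(calls[[j]], "/", fixed = TRUE)
    v1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    v2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
    a1[, j] <- v1; a2[, j] <- v2
  }
  genotype_matrix(samples, locus_table(chrom, pos, NULL, ref, alt), a1, a2)
}

# write VCF text lines to a temp file
write_vcf_text <- function(records, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# random allele-frequency vector with n_alleles entries, all > min_f
random_freqs <- function(n_alleles, min_f = 0.05) {
  repeat {
    f <- stats::runif(n_alleles)
    f <- f / sum(f)
    if (all(f > min_f)) return(f)
  }
}
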