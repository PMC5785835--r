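#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count given the observed allele
#' counts: every heterozygote count compatible with the allele counts is
#' enumerated, its conditional probability computed, and the two-sided p-value
#' is the total probability of configurations no more probable than the
#' observed one (probability ordering).
#'
#' @param n_aa Count of reference homozygotes.
#' @param n_ab Count of heterozygotes.
#' @param n_bb Count of alternative homozygotes.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) stop("genotype counts must be >= 0")
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotyped individual required")
  n_a <- 2L * n_aa + n_ab            # count of the first allele
  n_b <- 2L * n - n_a
  if (n_a == 0L || n_b == 0L) return(1)  # monomorphic: single configuration

  x <- seq.int(n_a %% 2L, min(n_a, n_b), by = 2L)   # possible het counts
  # log P(het = x | n_a, n) up to the normalising constant
  lw <- x * log(2) - lfactorial((n_a - x) / 2) - lfactorial(x) -
    lfactorial((n_b - x) / 2)
  lw <- lw - max(lw)
  pr <- exp(lw) / sum(exp(lw))
  p_obs <- pr[match(n_ab, x)]
  # probability ordering with a relative tolerance for floating-point ties
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone), delegating to
#' [stats::p.adjust()]. Output has the same length and order as the input.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

locus_count_table <- function(gm) {
  # per-locus genotype/allele counting shared by the stat accessors
  n_loci <- nrow(gm$loci)
  lapply(seq_len(n_loci), function(j) {
    a1 <- gm$a1[, j]; a2 <- gm$a2[, j]
    called <- !is.na(a1)
    a1 <- a1[called]; a2 <- a2[called]
    n_alleles <- 1L + length(gm$loci$alt[[j]])
    counts <- tabulate(c(a1, a2) + 1L, nbins = n_alleles)
    list(n_total = length(called), n_called = sum(called),
         allele_counts = counts, het = sum(a1 != a2),
         geno = paste(a1, a2, sep = "/"))
  })
}

#' Per-locus statistics table
#'
#' Computes, for every locus: alternative-allele frequency (AAF), minor allele
#' frequency (MAF), call rate, number of observed alleles and genotype
#' classes, observed (Ho) and expected (He) heterozygosity, fixation index
#' F = (He - Ho)/He, and the exact HWE p-value with its BH-adjusted q-value.
#' HWE is computed for biallelic loci only (multi-allelic loci get NA; they
#' are filtered before HWE in the selection cascade). Missing calls are
#' excluded from all numerators and denominators.
#'
#' @param gm A [genotype_matrix()].
#' @return A data.frame, one row per locus in matrix order, with columns
#'   key, chrom, pos, id, in_hla, aaf, maf, call_rate, n_alleles_observed,
#'   n_genotype_classes, ho, he, f, hwe_p, hwe_q.
#' @export
locus_stats <- function(gm) {
  tabs <- locus_count_table(gm)
  n_loci <- nrow(gm$loci)
  out <- data.frame(
    key = gm$loci$key, chrom = gm$loci$chrom, pos = gm$loci$pos,
    id = gm$loci$id, in_hla = gm$loci$in_hla,
    aaf = NA_real_, maf = NA_real_, call_rate = NA_real_,
    n_alleles_observed = NA_integer_, n_genotype_classes = NA_integer_,
    ho = NA_real_, he = NA_real_, f = NA_real_,
    hwe_p = NA_real_, hwe_q = NA_real_,
    stringsAsFactors = FALSE
  )
  biallelic <- lengths(gm$loci$alt) == 1L
  for (j in seq_len(n_loci)) {
    tb <- tabs[[j]]
    out$call_rate[j] <- if (tb$n_total > 0L) tb$n_called / tb$n_total else NA_real_
    if (tb$n_called == 0L) next
    freqs <- tb$allele_counts / sum(tb$allele_counts)
    out$aaf[j] <- 1 - freqs[1]                    # total alternative allele frequency
    out$maf[j] <- min(freqs)                      # least common allele (incl. unobserved)
    out$n_alleles_observed[j] <- sum(tb$allele_counts > 0L)
    out$n_genotype_classes[j] <- length(unique(tb$geno))
    out$ho[j] <- tb$het / tb$n_called
    out$he[j] <- 1 - sum(freqs^2)
    out$f[j] <- if (out$he[j] > 0) (out$he[j] - out$ho[j]) / out$he[j] else NA_real_
    if (biallelic[j]) {
      cn <- tb$allele_counts
      n_bb <- (cn[2] - tb$het) / 2
      n_aa <- tb$n_called - tb$het - n_bb
      out$hwe_p[j] <- hwe_exact_test(n_aa, tb$het, n_bb)
    }
  }
  tested <- !is.na(out$hwe_p)
  out$hwe_q[tested] <- bh_adjust(out$hwe_p[tested])
  out
}

#' Allele frequencies at one locus
#'
#' @param gm A [genotype_matrix()].
#' @param key Locus key.
#' @return List with `aaf` (total alternative-allele frequency), `maf`, and
#'   `freqs` (the full allele frequency vector, ref first).
#' @export
allele_frequencies <- function(gm, key) {
  j <- match(key, gm$loci$key)
  if (is.na(j)) stop("unknown locus key: ", key)
  a1 <- gm$a1[, j]; a2 <- gm$a2[, j]
  called <- !is.na(a1)
  if (!any(called)) stop("all calls missing at ", key, ": statistic undefined")
  counts <- tabulate(c(a1[called], a2[called]) + 1L,
                     nbins = 1L + length(gm$loci$alt[[j]]))
  freqs <- counts / sum(counts)
  list(aaf = 1 - freqs[1], maf = min(freqs), freqs = freqs)
}

#' Call rate at one locus
#' @inheritParams allele_frequencies
#' @return Fraction of samples with a non-missing call.
#' @export
call_rate <- function(gm, key) {
  j <- match(key, gm$loci$key)
  if (is.na(j)) stop("unknown locus key: ", key)
  mean(!is.na(gm$a1[, j]))
}

#' Observed/expected heterozygosity and fixation index at one locus
#'
#' Ho is the fraction of heterozygous calls; He is 1 - sum(p_i^2) over the
#' observed allele frequencies; F = (He - Ho)/He, NA (flagged, not an error)
#' when the locus is monomorphic.
#'
#' @inheritParams allele_frequencies
#' @return List with `ho`, `he`, `f`.
#' @export
heterozygosities <- function(gm, key) {
  j <- match(key, gm$loci$key)
  if (is.na(j)) stop("unknown locus key: ", key)
  a1 <- gm$a1[, j]; a2 <- gm$a2[, j]
  called <- !is.na(a1)
  if (!any(called)) stop("all calls missing at ", key, ": statistic undefined")
  freqs <- tabulate(c(a1[called], a2[called]) + 1L,
                    nbins = 1L + length(gm$loci$alt[[j]]))
  freqs <- freqs / sum(freqs)
  ho <- mean(a1[called] != a2[called])
  he <- 1 - sum(freqs^2)
  list(ho = ho, he = he, f = if (he > 0) (he - ho) / he else NA_real_)
}

#' Concordance of allele frequencies between two call sets
#'
#' Pearson correlation (and its square) of matched per-locus AAF vectors,
#' e.g. DNA-derived vs RNA-derived frequencies over a shared locus set.
#'
#' @param aaf_a,aaf_b Numeric vectors of equal length >= 2, matched by locus.
#' @return List with `r` and `r2`; both NA (flagged) if either vector has
#'   zero variance.
#' @export
aaf_concordance <- function(aaf_a, aaf_b) {
  if (length(aaf_a) != length(aaf_b) || length(aaf_a) < 2L) {
    stop("need two matched AAF vectors of equal length >= 2")
  }
  if (stats::sd(aaf_a) == 0 || stats::sd(aaf_b) == 0) {
    return(list(r = NA_real_, r2 = NA_real_))
  }
  r <- stats::cor(aaf_a, aaf_b)
  list(r = r, r2 = r^2)
}
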