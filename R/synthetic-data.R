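#' Simulation configuration for a paired DNA/RNA cohort
#'
#' Defines the study conditions the generator emulates: a cohort of unrelated
#' Dutch-style samples genotyped at biallelic loci drawn under Hardy-Weinberg
#' equilibrium from a common-variant frequency spectrum, with configurable
#' planted violations of every filter in the selection cascade, full-sib
#' pairs, DNA-to-RNA genotype-call errors, missingness and RNA label swaps.
#'
#' Planted categories (all default 0): `n_low_maf` loci with MAF below 0.2,
#' `n_multiallelic` loci with three alleles, `n_hwe_violating` loci generated
#' with inbreeding-like homozygote excess (`f_plant`), `n_ld_pairs`
#' near-duplicate locus pairs (each pair uses two loci), `n_hla` loci placed
#' inside the HLA interval, and `n_low_callrate` loci with depressed RNA call
#' rate. Remaining loci are "clean": they violate no filter by construction.
#'
#' @param n_samples Number of samples (cohort default 2115, the discovery
#'   cohort size).
#' @param n_loci Total number of loci including planted ones.
#' @param aaf_range Range from which clean-locus alternative-allele
#'   frequencies are drawn uniformly (default `c(0.25, 0.75)`, i.e. MAF
#'   comfortably above the 0.2 filter, matching the common-variant spectrum
#'   the panel targets).
#' @param aaf Optional explicit per-locus AAF vector (length `n_loci`);
#'   overrides `aaf_range` for non-multiallelic, non-low-MAF loci.
#' @param missing_rate Per-call missingness probability, applied
#'   independently to the DNA and RNA matrices.
#' @param rna_error_rate Probability a true genotype is mis-called in the RNA
#'   matrix (error moves to a uniformly chosen different genotype).
#' @param n_multiallelic,n_low_maf,n_hwe_violating,n_ld_pairs,n_hla,n_low_callrate
#'   Planted-violation counts, see Details.
#' @param low_maf_range AAF range for planted low-MAF loci.
#' @param f_plant Inbreeding-like coefficient for planted HWE violations:
#'   genotype probabilities p^2 + f p q, 2 p q (1 - f), q^2 + f p q.
#' @param ld_flip_rate Per-sample probability that a planted duplicate locus
#'   deviates from its partner (the deviating call is re-drawn under HWE).
#' @param low_call_rate RNA call rate of planted low-call-rate loci.
#' @param n_sib_pairs Number of full-sib sample pairs (sibs of two
#'   Hardy-Weinberg parents via Mendelian transmission).
#' @param n_swaps Number of RNA samples whose labels are cycled relative to
#'   the truth (0 or >= 2; a value of 2 is a pairwise label exchange).
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 2115, n_loci = 100,
                       aaf_range = c(0.25, 0.75), aaf = NULL,
                       missing_rate = 0.02, rna_error_rate = 0.02,
                       n_multiallelic = 0, n_low_maf = 0,
                       low_maf_range = c(0.05, 0.15),
                       n_hwe_violating = 0, f_plant = 0.4,
                       n_ld_pairs = 0, ld_flip_rate = 0.01,
                       n_hla = 0, n_low_callrate = 0, low_call_rate = 0.7,
                       n_sib_pairs = 0, n_swaps = 0, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_loci = as.integer(n_loci),
              aaf_range = aaf_range, aaf = aaf,
              missing_rate = missing_rate, rna_error_rate = rna_error_rate,
              n_multiallelic = as.integer(n_multiallelic),
              n_low_maf = as.integer(n_low_maf), low_maf_range = low_maf_range,
              n_hwe_violating = as.integer(n_hwe_violating), f_plant = f_plant,
              n_ld_pairs = as.integer(n_ld_pairs), ld_flip_rate = ld_flip_rate,
              n_hla = as.integer(n_hla),
              n_low_callrate = as.integer(n_low_callrate),
              low_call_rate = low_call_rate,
              n_sib_pairs = as.integer(n_sib_pairs),
              n_swaps = as.integer(n_swaps), seed = as.integer(seed))
  counts <- c(cfg$n_samples, cfg$n_loci, cfg$n_multiallelic, cfg$n_low_maf,
              cfg$n_hwe_violating, cfg$n_ld_pairs, cfg$n_hla,
              cfg$n_low_callrate, cfg$n_sib_pairs, cfg$n_swaps)
  if (any(counts < 0)) stop("config counts must be >= 0")
  rates <- c(cfg$missing_rate, cfg$rna_error_rate, cfg$ld_flip_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$f_plant < 0 || cfg$f_plant > 1) stop("f_plant must lie in [0, 1]")
  n_planted <- cfg$n_multiallelic + cfg$n_low_maf + cfg$n_hwe_violating +
    2L * cfg$n_ld_pairs + cfg$n_hla + cfg$n_low_callrate
  if (n_planted > cfg$n_loci) {
    stop("infeasible planting: ", n_planted, " planted loci > n_loci = ", cfg$n_loci)
  }
  if (cfg$n_swaps == 1L) stop("n_swaps must be 0 or >= 2 (a swap needs partners)")
  if (cfg$n_swaps > cfg$n_samples) stop("n_swaps exceeds n_samples")
  if (2L * cfg$n_sib_pairs > cfg$n_samples) stop("too many sib pairs for n_samples")
  if (!is.null(cfg$aaf) && length(cfg$aaf) != cfg$n_loci) {
    stop("explicit aaf vector must have length n_loci")
  }
  structure(cfg, class = "sim_config")
}

# HWE genotype draw for one biallelic locus: dosage 0/1/2 with optional
# homozygote excess f; returns integer vector of length n.
draw_hwe_dosage <- function(n, q, f = 0) {
  p <- 1 - q
  probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
  sample.int(3L, n, replace = TRUE, prob = probs) - 1L
}

# Mendelian full-sib dosages for one locus: n_pairs x 2 matrix.
draw_sib_dosages <- function(n_pairs, q) {
  p1a <- stats::rbinom(n_pairs, 1L, q); p1b <- stats::rbinom(n_pairs, 1L, q)
  p2a <- stats::rbinom(n_pairs, 1L, q); p2b <- stats::rbinom(n_pairs, 1L, q)
  pick <- function() {
    from1 <- ifelse(stats::rbinom(n_pairs, 1L, 0.5) == 1L, p1a, p1b)
    from2 <- ifelse(stats::rbinom(n_pairs, 1L, 0.5) == 1L, p2a, p2b)
    from1 + from2
  }
  cbind(pick(), pick())
}

#' Simulate a paired DNA/RNA genotype cohort with known ground truth
#'
#' Generates a true genotype layer (Hardy-Weinberg draws from planted allele
#' frequencies, with the planted violations described in [sim_config()]),
#' derives the DNA matrix by applying missingness, and the RNA matrix by
#' applying independent genotype errors, missingness and label swaps. The
#' truth channel records every planted violation, the sib pairs, the swap
#' list and the expected query-to-reference sample map.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_cohort` with elements `dna`, `rna` (both
#'   [genotype_matrix()]) and `truth` (class `sim_truth`: list with `loci`
#'   data.frame of key/label/planted_aaf/ld_partner, `clean_locus_keys`,
#'   `sib_pairs`, `swaps`, `sample_map`, `cfg`). Locus labels are one of
#'   none/callrate/multiallelic/low_maf/hwe/ld/hla.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  L <- cfg$n_loci

  labels <- rep("none", L)
  slots <- seq_len(L)
  take <- function(k) {
    if (k == 0L) return(integer(0))
    s <- slots[seq_len(k)]; slots <<- slots[-seq_len(k)]; s
  }
  i_multi <- take(cfg$n_multiallelic); labels[i_multi] <- "multiallelic"
  i_lowmaf <- take(cfg$n_low_maf); labels[i_lowmaf] <- "low_maf"
  i_hwe <- take(cfg$n_hwe_violating); labels[i_hwe] <- "hwe"
  i_hla <- take(cfg$n_hla); labels[i_hla] <- "hla"
  i_lowcall <- take(cfg$n_low_callrate); labels[i_lowcall] <- "callrate"
  i_ld_a <- take(cfg$n_ld_pairs); i_ld_b <- take(cfg$n_ld_pairs)
  labels[c(i_ld_a, i_ld_b)] <- "ld"

  # planted allele frequencies
  aaf <- if (!is.null(cfg$aaf)) cfg$aaf else
    stats::runif(L, cfg$aaf_range[1], cfg$aaf_range[2])
  aaf[i_lowmaf] <- stats::runif(length(i_lowmaf), cfg$low_maf_range[1],
                                cfg$low_maf_range[2])
  aaf[i_ld_b] <- aaf[i_ld_a]   # duplicates share the partner's frequency

  # locus metadata: ACGT alleles; HLA loci sit inside the default interval
  hla <- hla_interval()
  chrom <- rep("1", L); pos <- 10000L * seq_len(L)
  chrom[i_hla] <- hla$chrom
  pos[i_hla] <- as.integer(hla$start + 1000L * seq_along(i_hla))
  pos[i_ld_b] <- pos[i_ld_a] + 5000L   # near-duplicates sit close by
  ref <- rep("A", L)
  alt <- rep(list("G"), L)
  alt[i_multi] <- list(c("G", "T"))
  multi_freqs <- lapply(i_multi, function(i) {
    fr <- stats::runif(3, 0.2, 0.5)
    fr / sum(fr)
  })

  sib_idx <- if (cfg$n_sib_pairs > 0)
    matrix(seq_len(2L * cfg$n_sib_pairs), ncol = 2, byrow = TRUE)
  else matrix(integer(0), ncol = 2)
  founder <- setdiff(seq_len(n), as.vector(sib_idx))

  # true genotype layer (allele-index matrices)
  t1 <- matrix(NA_integer_, n, L)
  t2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    if (j %in% i_multi) {
      fr <- multi_freqs[[match(j, i_multi)]]
      pairs <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 2L),
                     c(1L, 1L), c(1L, 2L), c(2L, 2L))
      pr <- c(fr[1]^2, 2 * fr[1] * fr[2], 2 * fr[1] * fr[3],
              fr[2]^2, 2 * fr[2] * fr[3], fr[3]^2)
      g <- sample.int(6L, n, replace = TRUE, prob = pr)
      t1[, j] <- pairs[g, 1]; t2[, j] <- pairs[g, 2]
    } else {
      f_loc <- if (j %in% i_hwe) cfg$f_plant else 0
      d <- integer(n)
      d[founder] <- draw_hwe_dosage(length(founder), aaf[j], f_loc)
      if (nrow(sib_idx) > 0) {
        sd <- draw_sib_dosages(nrow(sib_idx), aaf[j])
        d[sib_idx[, 1]] <- sd[, 1]; d[sib_idx[, 2]] <- sd[, 2]
      }
      t1[, j] <- as.integer(d >= 2L); t2[, j] <- as.integer(d >= 1L)
    }
  }
  # planted LD duplicates: copy the partner, re-draw a small fraction
  for (k in seq_along(i_ld_a)) {
    a <- i_ld_a[k]; b <- i_ld_b[k]
    t1[, b] <- t1[, a]; t2[, b] <- t2[, a]
    flip <- which(stats::runif(n) < cfg$ld_flip_rate)
    if (length(flip)) {
      d <- draw_hwe_dosage(length(flip), aaf[b])
      t1[flip, b] <- as.integer(d >= 2L); t2[flip, b] <- as.integer(d >= 1L)
    }
  }

  samples <- sprintf("S%04d", seq_len(n))
  loci <- locus_table(chrom, pos, paste0("snp", seq_len(L)), ref, alt, hla = hla)

  # DNA: truth + missingness
  dna1 <- t1; dna2 <- t2
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    dna1[miss] <- NA_integer_; dna2[miss] <- NA_integer_
  }

  # RNA: truth + genotype errors + missingness (+ planted low call rate)
  rna1 <- t1; rna2 <- t2
  if (cfg$rna_error_rate > 0) {
    err <- which(matrix(stats::runif(n * L) < cfg$rna_error_rate, n, L))
    for (e in err) {
      j <- (e - 1L) %/% n + 1L
      if (j %in% i_multi) {
        pairs <- rbind(c(0L, 0L), c(0L, 1L), c(0L, 2L),
                       c(1L, 1L), c(1L, 2L), c(2L, 2L))
        cur <- which(pairs[, 1] == t1[e] & pairs[, 2] == t2[e])
        new <- sample(setdiff(seq_len(6L), cur), 1L)
        rna1[e] <- pairs[new, 1]; rna2[e] <- pairs[new, 2]
      } else {
        d <- t1[e] + t2[e]
        new_d <- sample(setdiff(0:2, d), 1L)
        rna1[e] <- as.integer(new_d >= 2L); rna2[e] <- as.integer(new_d >= 1L)
      }
    }
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * L) < cfg$missing_rate, n, L)
    rna1[miss] <- NA_integer_; rna2[miss] <- NA_integer_
  }
  if (length(i_lowcall)) {
    extra <- max(0, 1 - cfg$low_call_rate - cfg$missing_rate)
    for (j in i_lowcall) {
      miss <- stats::runif(n) < extra
      rna1[miss, j] <- NA_integer_; rna2[miss, j] <- NA_integer_
    }
  }

  # RNA label swaps: cycle the chosen samples' rows, keep labels in place
  swaps <- data.frame(query = character(0), true_donor = character(0),
                      stringsAsFactors = FALSE)
  if (cfg$n_swaps >= 2L) {
    non_sib <- setdiff(seq_len(n), as.vector(sib_idx))
    chosen <- sort(sample(non_sib, cfg$n_swaps))
    donor <- c(chosen[-1], chosen[1])  # row shown under label i comes from donor i
    rna1[chosen, ] <- rna1[donor, ]
    rna2[chosen, ] <- rna2[donor, ]
    swaps <- data.frame(query = samples[chosen], true_donor = samples[donor],
                        stringsAsFactors = FALSE)
  }

  planted_aaf <- aaf
  planted_aaf[i_multi] <- NA_real_
  truth_loci <- data.frame(key = loci$key, label = labels,
                           planted_aaf = planted_aaf,
                           ld_partner = NA_character_, stringsAsFactors = FALSE)
  truth_loci$ld_partner[i_ld_a] <- loci$key[i_ld_b]
  truth_loci$ld_partner[i_ld_b] <- loci$key[i_ld_a]

  truth <- structure(list(
    loci = truth_loci,
    clean_locus_keys = loci$key[labels == "none"],
    sib_pairs = if (nrow(sib_idx)) data.frame(sample_a = samples[sib_idx[, 1]],
                                              sample_b = samples[sib_idx[, 2]],
                                              stringsAsFactors = FALSE)
                else data.frame(sample_a = character(0), sample_b = character(0)),
    swaps = swaps,
    sample_map = data.frame(query = samples, reference = samples,
                            stringsAsFactors = FALSE),
    cfg = cfg), class = "sim_truth")

  list(dna = genotype_matrix(samples, loci, dna1, dna2),
       rna = genotype_matrix(samples, loci, rna1, rna2),
       truth = truth)
}

#' Empirical multilocus match rate of unrelated pairs
#'
#' Monte-Carlo counterpart of the probability of identity: draws pairs of
#' unrelated individuals under Hardy-Weinberg equilibrium at the given
#' biallelic loci and returns the fraction of pairs with identical
#' multilocus genotypes.
#'
#' @param aafs Per-locus alternative-allele frequencies in \[0, 1\] (0 and 1
#'   allowed as degenerate monomorphic cases).
#' @param n_pairs Number of simulated pairs (>= 1).
#' @param seed Integer seed.
#' @return Match fraction in \[0, 1\].
#' @export
simulate_unrelated_pairs <- function(aafs, n_pairs, seed = 1L) {
  stopifnot(n_pairs >= 1, all(aafs >= 0 & aafs <= 1))
  set.seed(seed)
  match_all <- rep(TRUE, n_pairs)
  for (q in aafs) {
    d1 <- stats::rbinom(n_pairs, 2L, q)   # Binomial(2, q) is the HWE genotype draw
    d2 <- stats::rbinom(n_pairs, 2L, q)
    match_all <- match_all & (d1 == d2)
  }
  mean(match_all)
}

#' Empirical multilocus match rate of full-sib pairs
#'
#' As [simulate_unrelated_pairs()], but each pair are full siblings of two
#' Hardy-Weinberg parents under Mendelian transmission.
#'
#' @inheritParams simulate_unrelated_pairs
#' @return Match fraction in \[0, 1\].
#' @export
simulate_sib_pairs <- function(aafs, n_pairs, seed = 1L) {
  stopifnot(n_pairs >= 1, all(aafs >= 0 & aafs <= 1))
  set.seed(seed)
  match_all <- rep(TRUE, n_pairs)
  for (q in aafs) {
    sd <- draw_sib_dosages(n_pairs, q)
    match_all <- match_all & (sd[, 1] == sd[, 2])
  }
  mean(match_all)
}
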