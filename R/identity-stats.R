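check_freqs <- function(freqs) {
  if (any(freqs <= 0 | freqs > 1)) stop("allele frequencies must lie in (0, 1]")
  if (abs(sum(freqs) - 1) > 1e-9) stop("allele frequencies must sum to 1")
}

#' Per-locus probability of identity (unrelated individuals)
#'
#' The probability that two unrelated individuals drawn from a randomly
#' mating population share the same genotype at one locus: the sum over
#' genotypes of squared Hardy-Weinberg genotype frequencies,
#' `PI = sum_i p_i^4 + sum_{i<j} (2 p_i p_j)^2`.
#'
#' @param freqs Allele frequency vector (any number of alleles), summing to 1.
#' @return Probability in (0, 1].
#' @export
pi_locus <- function(freqs) {
  check_freqs(freqs)
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  # sum_{i<j} (2 p_i p_j)^2 = 4 * (s2^2 - s4)/2, so PI = 2 s2^2 - s4
  2 * s2^2 - s4
}

#' Per-locus probability of identity for full sibs
#'
#' The match probability for two full siblings, under Mendelian transmission
#' from Hardy-Weinberg parents:
#' `PIsib = 1/4 + (1/2) sum p_i^2 + (1/2) (sum p_i^2)^2 - (1/4) sum p_i^4`.
#' Always at least as large as [pi_locus()] (sibs are harder to tell apart).
#'
#' @inheritParams pi_locus
#' @return Probability in (0, 1].
#' @export
pisib_locus <- function(freqs) {
  check_freqs(freqs)
  s2 <- sum(freqs^2)
  s4 <- sum(freqs^4)
  0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
}

#' Multilocus probability of identity
#'
#' Product of per-locus match probabilities (locus independence is what the
#' LD filter buys). Accumulated in log space to avoid underflow at panel
#' scale (a 50-SNP panel reaches ~1e-20).
#'
#' @param per_locus Vector of per-locus probabilities in (0, 1].
#' @return List with `value` (linear scale) and `log10` of the product.
#' @export
multilocus_pi <- function(per_locus) {
  if (length(per_locus) == 0L) stop("need at least one per-locus probability")
  if (any(per_locus <= 0 | per_locus > 1)) {
    stop("per-locus probabilities must lie in (0, 1]")
  }
  lg <- sum(log10(per_locus))
  list(value = 10^lg, log10 = lg)
}

#' Cumulative probability-of-identity curve
#'
#' Orders loci (default: most informative first, i.e. ascending per-locus
#' probability) and returns the running product for panels of size 1..L.
#'
#' @param per_locus Vector of per-locus probabilities in (0, 1].
#' @param order `"informative"` (ascending probability) or `"given"` (keep
#'   input order).
#' @return Numeric vector of cumulative products; non-increasing in k.
#' @export
cumulative_pi_curve <- function(per_locus, order = c("informative", "given")) {
  order <- match.arg(order)
  if (length(per_locus) == 0L) stop("need at least one per-locus probability")
  if (any(per_locus <= 0 | per_locus > 1)) {
    stop("per-locus probabilities must lie in (0, 1]")
  }
  if (order == "informative") per_locus <- sort(per_locus)
  10^cumsum(log10(per_locus))
}

#' Minimum panel size for uniqueness in a cohort
#'
#' Smallest k such that the cumulative match probability drops below
#' `1 / (N(N-1)/2)`, i.e. the expected number of matching sample pairs in a
#' cohort of N falls below one.
#'
#' @param cumulative Non-increasing cumulative probability vector (from
#'   [cumulative_pi_curve()]).
#' @param n_samples Cohort size N >= 2.
#' @return List with `k` (NA if the criterion is never met), `achieved`,
#'   `threshold`, `expected_pairs` (expected matching pairs at k, or at the
#'   full panel when not achieved) and `criterion` (description string).
#' @export
min_snps_for_uniqueness <- function(cumulative, n_samples) {
  stopifnot(n_samples >= 2, length(cumulative) >= 1)
  if (any(diff(cumulative) > 1e-12)) stop("cumulative curve must be non-increasing")
  n_pairs <- n_samples * (n_samples - 1) / 2
  threshold <- 1 / n_pairs
  hit <- which(cumulative < threshold)
  if (length(hit) == 0L) {
    return(list(k = NA_integer_, achieved = FALSE, threshold = threshold,
                expected_pairs = cumulative[length(cumulative)] * n_pairs,
                criterion = "expected matching pairs < 1"))
  }
  k <- hit[1]
  list(k = k, achieved = TRUE, threshold = threshold,
       expected_pairs = cumulative[k] * n_pairs,
       criterion = "expected matching pairs < 1")
}

#' Identity report for a panel
#'
#' Per-locus and cumulative PI / PI-sibs over a panel, with allele
#' frequencies estimated from a genotype matrix (typically the DNA call set),
#' and the minimum panel size for uniqueness when a cohort size is given.
#'
#' @param gm A [genotype_matrix()] supplying allele frequency estimates.
#' @param panel Locus keys of the panel (default: all loci of `gm`).
#' @param n_samples Optional cohort size for the uniqueness criterion.
#' @return An object of class `identity_report`: list with `per_locus`
#'   (data.frame: key, aaf, pi, pisib, ordered most informative first),
#'   `cumulative_pi`, `cumulative_pisib`, `pi`, `pisib` (multilocus, with
#'   log10), and `uniqueness` (NULL unless `n_samples` given).
#' @export
identity_report <- function(gm, panel = NULL, n_samples = NULL) {
  if (is.null(panel)) panel <- gm$loci$key
  per <- do.call(rbind, lapply(panel, function(k) {
    af <- allele_frequencies(gm, k)
    fr <- af$freqs[af$freqs > 0]
    data.frame(key = k, aaf = af$aaf, pi = pi_locus(fr),
               pisib = pisib_locus(fr), stringsAsFactors = FALSE)
  }))
  per <- per[order(per$pi), , drop = FALSE]
  rownames(per) <- NULL
  cum_pi <- cumulative_pi_curve(per$pi, order = "given")
  cum_pisib <- cumulative_pi_curve(per$pisib, order = "given")
  uniq <- if (!is.null(n_samples)) min_snps_for_uniqueness(cum_pi, n_samples)
  structure(list(per_locus = per, cumulative_pi = cum_pi,
                 cumulative_pisib = cum_pisib,
                 pi = multilocus_pi(per$pi), pisib = multilocus_pi(per$pisib),
                 uniqueness = uniq),
            class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  L <- nrow(x$per_locus)
  cat("identity_report:", L, "loci\n")
  cat(sprintf("  multilocus PI      = %.3g (log10 = %.2f)\n",
              x$pi$value, x$pi$log10))
  cat(sprintf("  multilocus PI-sibs = %.3g (log10 = %.2f)\n",
              x$pisib$value, x$pisib$log10))
  if (!is.null(x$uniqueness)) {
    if (x$uniqueness$achieved) {
      cat(sprintf("  uniqueness (%s): k = %d loci\n",
                  x$uniqueness$criterion, x$uniqueness$k))
    } else {
      cat(sprintf("  uniqueness not achieved; expected matching pairs %.3g\n",
                  x$uniqueness$expected_pairs))
    }
  }
  invisible(x)
}
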