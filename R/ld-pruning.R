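#' Pairwise genotype r-squared
#'
#' Linkage disequilibrium between unphased biallelic loci, measured as the
#' squared Pearson correlation of alternative-allele dosage vectors (0/1/2)
#' over the samples where both loci are called. Pairs where either locus has
#' zero dosage variance in the shared-call subset are undefined (NA) and are
#' treated as r² = 0 by [prune_by_ld()]: a monomorphic locus carries no
#' linkage signal.
#'
#' @param gm A [genotype_matrix()].
#' @param keys Locus keys to include (default: all). All must be biallelic.
#' @return An object of class `ld_matrix`: list with `keys`, `r2` (symmetric
#'   matrix, NA diagonal), and `n_used` (samples with both loci called).
#' @export
pairwise_r2 <- function(gm, keys = NULL) {
  if (is.null(keys)) keys <- gm$loci$key
  sub <- subset_loci(gm, keys)
  d <- dosage_matrix(sub)
  r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  n_used <- crossprod(!is.na(d))
  diag(r2) <- NA_real_
  dimnames(r2) <- dimnames(n_used) <- list(keys, keys)
  structure(list(keys = keys, r2 = r2, n_used = n_used), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  v <- x$r2[upper.tri(x$r2)]
  cat("ld_matrix:", length(x$keys), "loci,", length(v), "pairs\n")
  if (length(v)) {
    cat(sprintf("  r2 median %.3g, max %.3g (NA pairs: %d)\n",
                stats::median(v, na.rm = TRUE), max(v, na.rm = TRUE), sum(is.na(v))))
  }
  invisible(x)
}

#' Long-format LD table
#' @param ld An `ld_matrix`.
#' @return data.frame with key_a, key_b, r2, n_used for every unique pair.
#' @export
ld_table <- function(ld) {
  idx <- which(upper.tri(ld$r2), arr.ind = TRUE)
  data.frame(key_a = ld$keys[idx[, 1]], key_b = ld$keys[idx[, 2]],
             r2 = ld$r2[idx], n_used = ld$n_used[idx],
             stringsAsFactors = FALSE)
}

#' Prune linked loci, keeping the more heterozygous of each pair
#'
#' Greedy pruning: pairs with r² at or above the threshold are visited in
#' descending r² order; for each pair whose members are both still unpruned,
#' the locus with lower observed heterozygosity is removed (ties broken by
#' lower MAF, then by removing the lexicographically larger key). Survivors
#' have all pairwise r² below the threshold.
#'
#' @param ld An `ld_matrix` from [pairwise_r2()].
#' @param stats Per-locus stats from [locus_stats()] covering all `ld$keys`
#'   (columns `key`, `ho`, `maf` are used).
#' @param threshold r² cutoff in (0, 1]; the selection default is 0.01.
#' @return Character vector of surviving locus keys, in `ld$keys` order.
#' @export
prune_by_ld <- function(ld, stats, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  m <- match(ld$keys, stats$key)
  if (anyNA(m)) stop("stats missing for locus ", ld$keys[which(is.na(m))[1]])
  ho <- stats$ho[m]; maf <- stats$maf[m]

  r2 <- ld$r2
  r2[is.na(r2)] <- 0                      # undefined pairs carry no linkage
  idx <- which(upper.tri(r2) & r2 >= threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(ld$keys)
  ord <- order(r2[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]

  alive <- rep(TRUE, length(ld$keys))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!alive[i] || !alive[j]) next
    drop <- if (ho[i] != ho[j]) {
      if (ho[i] < ho[j]) i else j
    } else if (maf[i] != maf[j]) {
      if (maf[i] < maf[j]) i else j
    } else {
      if (ld$keys[i] > ld$keys[j]) i else j
    }
    alive[drop] <- FALSE
  }
  ld$keys[alive]
}
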