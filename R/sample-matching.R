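# shared-allele count per locus for two unordered allele pairs (sorted):
# 2 if same multiset, 1 if one allele in common, 0 otherwise; NA if missing.
shared_allele_counts <- function(qa1, qa2, ra1, ra2) {
  eq <- qa1 == ra1 & qa2 == ra2
  any_common <- qa1 == ra1 | qa1 == ra2 | qa2 == ra1 | qa2 == ra2
  as.integer(eq) + as.integer(any_common)
}

#' Allele-concordance score between two genotype vectors
#'
#' For each panel locus, the number of shared alleles is the size of the
#' multiset intersection of the two unordered allele pairs (AA vs AA gives 2,
#' AA vs AB gives 1, AB vs AB gives 2, AA vs BB gives 0). Loci where either
#' call is missing are excluded from numerator and denominator. The score is
#' total shared alleles over total compared alleles (2 per compared locus);
#' with a complete 50-locus panel the denominator is 100 alleles.
#'
#' @param q,r Genotype vectors over the same panel in the same allele
#'   encoding: either matrices/data.frames with two columns of allele
#'   indices (one row per locus) or lists with elements `a1`, `a2`.
#' @return An object of class `concordance_score`: list with `score`,
#'   `shared_alleles`, `total_alleles`, `loci_compared` and
#'   `identical_genotypes`. With zero comparable loci, `score` is NA
#'   (flagged; treated as unsure downstream).
#' @export
concordance_score <- function(q, r) {
  q <- as_gt_pair(q); r <- as_gt_pair(r)
  if (length(q$a1) != length(r$a1)) stop("genotype vectors must cover the same panel")
  sh <- shared_allele_counts(pmin(q$a1, q$a2), pmax(q$a1, q$a2),
                             pmin(r$a1, r$a2), pmax(r$a1, r$a2))
  ok <- !is.na(sh)
  n_cmp <- sum(ok)
  structure(list(
    score = if (n_cmp > 0) sum(sh[ok]) / (2 * n_cmp) else NA_real_,
    shared_alleles = sum(sh[ok]),
    total_alleles = 2L * n_cmp,
    loci_compared = n_cmp,
    identical_genotypes = sum(sh[ok] == 2L)
  ), class = "concordance_score")
}

as_gt_pair <- function(x) {
  if (is.list(x) && !is.null(x$a1)) {
    list(a1 = as.integer(x$a1), a2 = as.integer(x$a2))
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 2L) stop("genotype vector must have two allele columns")
    list(a1 = as.integer(x[, 1]), a2 = as.integer(x[, 2]))
  }
}

#' @export
print.concordance_score <- function(x, ...) {
  cat(sprintf("concordance: %s (%d/%d alleles over %d loci; %d identical genotypes)\n",
              ifelse(is.na(x$score), "NA", sprintf("%.3f", x$score)),
              x$shared_alleles, x$total_alleles, x$loci_compared,
              x$identical_genotypes), sep = "")
  invisible(x)
}

# score matrix: queries x references, over panel loci; also returns the
# identical-genotype count matrix. Vectorised per query.
score_matrix <- function(queries, refs, panel) {
  qm <- subset_loci(queries, panel)
  rm_ <- subset_loci(refs, panel)
  nq <- length(qm$samples); nr <- length(rm_$samples)
  scores <- matrix(NA_real_, nq, nr, dimnames = list(qm$samples, rm_$samples))
  ident <- matrix(NA_integer_, nq, nr, dimnames = list(qm$samples, rm_$samples))
  r1 <- rm_$a1; r2 <- rm_$a2      # refs x loci, sorted pairs
  for (i in seq_len(nq)) {
    q1 <- matrix(qm$a1[i, ], nr, ncol(r1), byrow = TRUE)
    q2 <- matrix(qm$a2[i, ], nr, ncol(r1), byrow = TRUE)
    eq <- q1 == r1 & q2 == r2
    any_common <- q1 == r1 | q1 == r2 | q2 == r1 | q2 == r2
    sh <- eq + any_common
    n_cmp <- rowSums(!is.na(sh))
    scores[i, ] <- ifelse(n_cmp > 0, rowSums(sh, na.rm = TRUE) / (2 * n_cmp), NA_real_)
    ident[i, ] <- rowSums(sh == 2L, na.rm = TRUE)
  }
  list(scores = scores, identical = ident)
}

#' Match query samples against reference samples by allele concordance
#'
#' Computes all query-by-reference allele-concordance scores over the panel
#' loci, assigns each query its best-hit set (all references attaining the
#' maximum score, provided it reaches the threshold), and categorises each
#' query against the expected mapping: `PASSED_MATCHING` when any expected
#' reference is in the best-hit set, `FAILED_MATCHING` when the best-hit set
#' is non-empty but contains no expected reference, `UNSURE` when no
#' reference reaches the threshold.
#'
#' @param queries,refs [genotype_matrix()] objects sharing the panel loci and
#'   allele encoding (e.g. RNA-derived queries vs DNA/GWAS references).
#' @param panel Locus keys of the identification panel.
#' @param expected Expected sample map (data.frame with columns `query`,
#'   `reference`); many-to-one allowed. Queries absent from the map have no
#'   expected reference, so any best hit counts as FAILED unless
#'   `unmapped = "report"`.
#' @param threshold Minimal allele-concordance score for a best hit
#'   (default 0.8).
#' @param unmapped `"fail"` (default) or `"report"`: how to categorise
#'   queries missing from the expected map.
#' @param keep_scores Keep the full score matrix in the report.
#' @return An object of class `match_report`: list with `assignments`
#'   (data.frame: query, best_hits (comma-joined), best_score, expected,
#'   category), `counts` (table over categories), `threshold`, and optionally
#'   `scores`.
#' @export
match_samples <- function(queries, refs, panel, expected, threshold = 0.8,
                          unmapped = c("fail", "report"), keep_scores = TRUE) {
  unmapped <- match.arg(unmapped)
  stopifnot(threshold > 0)
  sm <- score_matrix(queries, refs, panel)
  nq <- nrow(sm$scores)
  exp_by_query <- split(expected$reference, expected$query)

  res <- data.frame(query = rownames(sm$scores),
                    best_hits = NA_character_, best_score = NA_real_,
                    expected = NA_character_, category = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nq)) {
    s <- sm$scores[i, ]
    if (all(is.na(s))) {
      res$category[i] <- "UNSURE"
      next
    }
    best <- max(s, na.rm = TRUE)
    hits <- colnames(sm$scores)[!is.na(s) & s == best]
    res$best_score[i] <- best
    exp_refs <- exp_by_query[[res$query[i]]]
    res$expected[i] <- if (is.null(exp_refs)) NA_character_ else
      paste(exp_refs, collapse = ",")
    if (best < threshold) {
      res$category[i] <- "UNSURE"
      next
    }
    res$best_hits[i] <- paste(hits, collapse = ",")
    if (is.null(exp_refs)) {
      res$category[i] <- if (unmapped == "fail") "FAILED_MATCHING" else "UNMAPPED"
    } else {
      res$category[i] <- if (any(exp_refs %in% hits)) "PASSED_MATCHING"
                         else "FAILED_MATCHING"
    }
  }
  counts <- table(factor(res$category,
                         levels = c("PASSED_MATCHING", "FAILED_MATCHING",
                                    "UNSURE", "UNMAPPED")))
  structure(list(assignments = res, counts = counts, threshold = threshold,
                 scores = if (keep_scores) sm$scores),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("match_report (threshold", x$threshold, "):\n")
  for (nm in names(x$counts)) {
    if (x$counts[[nm]] > 0 || nm != "UNMAPPED") {
      cat(sprintf("  %-16s %d\n", nm, x$counts[[nm]]))
    }
  }
  bad <- x$assignments[x$assignments$category == "FAILED_MATCHING", , drop = FALSE]
  if (nrow(bad)) {
    cat("  failed queries:", paste(bad$query, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Matched vs unmatched identical-genotype distributions
#'
#' For every expected query-reference pair, the number of panel loci with
#' fully identical genotype calls; and the same count for randomly drawn
#' non-matching pairs. A positive separation gap (minimum matched count minus
#' maximum unmatched count) means the two distributions do not overlap and a
#' hard decision threshold exists.
#'
#' @inheritParams match_samples
#' @param n_random Number of random non-matching pairs to draw.
#' @param seed Integer seed for the random pair draw.
#' @return List with `matched`, `unmatched` (integer vectors of
#'   identical-genotype counts), `gap` (min matched - max unmatched) and
#'   `n_loci` (panel size).
#' @export
concordance_distributions <- function(queries, refs, panel, expected,
                                      n_random = 1000, seed = 1L) {
  if (nrow(expected) == 0L) stop("expected map must be non-empty")
  set.seed(seed)
  sm <- score_matrix(queries, refs, panel)
  qn <- rownames(sm$identical); rn <- colnames(sm$identical)

  qi <- match(expected$query, qn); ri <- match(expected$reference, rn)
  ok <- !is.na(qi) & !is.na(ri)
  matched <- sm$identical[cbind(qi[ok], ri[ok])]

  exp_by_query <- split(expected$reference, expected$query)
  rq <- sample.int(length(qn), n_random, replace = TRUE)
  rr <- sample.int(length(rn), n_random, replace = TRUE)
  is_expected <- function(a, b) rn[b] %in% exp_by_query[[qn[a]]]
  is_match <- mapply(is_expected, rq, rr)
  while (any(is_match)) {
    rr[is_match] <- sample.int(length(rn), sum(is_match), replace = TRUE)
    is_match <- mapply(is_expected, rq, rr)
  }
  unmatched <- sm$identical[cbind(rq, rr)]
  list(matched = as.integer(matched), unmatched = as.integer(unmatched),
       gap = min(matched) - max(unmatched), n_loci = length(panel))
}
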