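#' @keywords internal
"_PACKAGE"

MISSING <- NA_integer_

#' Build a locus key
#'
#' A locus is identified by (chrom, pos, ref, alt-set); the key is the
#' canonical string `chrom:pos:ref:alt1,alt2,...` with alternative alleles
#' sorted, so the key is invariant to ALT ordering.
#'
#' @param chrom Chromosome labels.
#' @param pos 1-based positions (VCF convention).
#' @param ref Reference alleles.
#' @param alt List of character vectors of alternative alleles.
#' @return Character vector of keys.
#' @export
locus_key <- function(chrom, pos, ref, alt) {
  alt_str <- vapply(alt, function(a) paste(sort(a), collapse = ","), character(1))
  paste(chrom, pos, ref, alt_str, sep = ":")
}

#' Construct a locus table
#'
#' @param chrom,pos,id,ref Vectors of chromosome, 1-based position, variant
#'   identifier and reference allele. Missing/`"."` ids are synthesized as
#'   `"chrom:pos"`.
#' @param alt List of character vectors (one per locus) of alternative alleles.
#' @param hla HLA interval as returned by [hla_interval()]; loci falling inside
#'   it get `in_hla = TRUE`.
#' @return A data.frame with columns chrom, pos, id, ref, alt (list column),
#'   in_hla and key.
#' @export
locus_table <- function(chrom, pos, id = NULL, ref, alt, hla = hla_interval()) {
  n <- length(chrom)
  pos <- as.integer(pos)
  if (!is.list(alt)) alt <- as.list(alt)
  if (is.null(id)) id <- rep(".", n)
  id <- as.character(id)
  synth <- is.na(id) | id == "." | id == ""
  id[synth] <- paste0(chrom[synth], ":", pos[synth])

  if (any(pos < 1L)) stop("locus positions must be >= 1 (VCF 1-based convention)")
  if (any(!nzchar(ref))) stop("ref alleles must be non-empty")
  bad_alt <- vapply(seq_len(n), function(i) {
    a <- alt[[i]]
    length(a) == 0L || any(!nzchar(a)) || ref[i] %in% a || anyDuplicated(a) > 0L
  }, logical(1))
  if (any(bad_alt)) {
    stop("invalid alt alleles (empty, duplicated, or equal to ref) at locus ",
         which(bad_alt)[1])
  }

  key <- locus_key(chrom, pos, ref, alt)
  if (anyDuplicated(key)) {
    stop("duplicate locus key: ", key[duplicated(key)][1])
  }
  df <- data.frame(chrom = as.character(chrom), pos = pos, id = id,
                   ref = as.character(ref), stringsAsFactors = FALSE)
  df$alt <- alt
  df$in_hla <- in_hla_interval(df$chrom, df$pos, hla)
  df$key <- key
  df
}

#' Default HLA exclusion interval
#'
#' The extended MHC region on chromosome 6 (GRCh37), used to flag loci whose
#' sequencing-derived genotype calls are artefact-prone. Fully closed, 1-based.
#'
#' @param chrom Chromosome label (matched with or without a `"chr"` prefix).
#' @param start,end Interval bounds in base pairs.
#' @return A list with elements chrom, start, end.
#' @export
hla_interval <- function(chrom = "6", start = 28477797, end = 33448354) {
  stopifnot(start >= 1, end >= start)
  list(chrom = as.character(chrom), start = as.numeric(start), end = as.numeric(end))
}

strip_chr <- function(x) sub("^chr", "", x, ignore.case = TRUE)

in_hla_interval <- function(chrom, pos, hla) {
  strip_chr(chrom) == strip_chr(hla$chrom) & pos >= hla$start & pos <= hla$end
}

#' Construct a genotype matrix
#'
#' The central container: diploid, unphased genotype calls for `samples` x
#' `loci`. Calls are stored as two integer allele-index matrices (0 = ref,
#' 1.. = alt), elementwise sorted so phase is ignored; a missing call is NA in
#' both.
#'
#' @param samples Character vector of unique sample IDs.
#' @param loci Locus table from [locus_table()].
#' @param a1,a2 Integer matrices (samples x loci) of allele indices, NA for
#'   missing. Half-calls must already be encoded as missing.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, loci, a1, a2) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample IDs must be unique")
  a1 <- as.matrix(a1); storage.mode(a1) <- "integer"
  a2 <- as.matrix(a2); storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(length(samples), nrow(loci))) ||
      !all(dim(a2) == dim(a1))) {
    stop("allele matrices must be n_samples x n_loci")
  }
  # half-calls are not representable: NA in one slot implies NA in both
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("half-calls must be encoded as fully missing")
  # unordered genotypes: store sorted
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  n_alleles <- 1L + lengths(loci$alt)
  bad <- sweep(a2, 2, n_alleles, ">=") | a1 < 0L
  if (any(bad, na.rm = TRUE)) {
    j <- which(colSums(bad, na.rm = TRUE) > 0)[1]
    stop("allele index out of range at locus ", loci$key[j])
  }
  dimnames(a1) <- dimnames(a2) <- list(samples, loci$key)
  structure(list(samples = samples, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x", nrow(x$loci), "loci\n")
  n_miss <- sum(is.na(x$a1))
  cat("  missing calls:", n_miss,
      sprintf("(%.2f%%)", 100 * n_miss / max(1, length(x$a1))), "\n")
  cat("  HLA-flagged loci:", sum(x$loci$in_hla), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$loci))

#' Locus keys of a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Character vector of locus keys in matrix order.
#' @export
locus_keys <- function(gm) gm$loci$key

#' Subset a genotype matrix by locus keys
#'
#' @param gm A `genotype_matrix`.
#' @param keys Locus keys to keep; the result follows the order of `keys`.
#' @return A `genotype_matrix` restricted to `keys`.
#' @export
subset_loci <- function(gm, keys) {
  idx <- match(keys, gm$loci$key)
  if (anyNA(idx)) stop("unknown locus key: ", keys[which(is.na(idx))[1]])
  loci <- gm$loci[idx, , drop = FALSE]
  rownames(loci) <- NULL
  genotype_matrix(gm$samples, loci, gm$a1[, idx, drop = FALSE],
                  gm$a2[, idx, drop = FALSE])
}

#' Subset a genotype matrix by sample IDs
#' @param gm A `genotype_matrix`.
#' @param samples Sample IDs to keep, in the desired order.
#' @return A `genotype_matrix` restricted to `samples`.
#' @export
subset_samples <- function(gm, samples) {
  idx <- match(samples, gm$samples)
  if (anyNA(idx)) stop("unknown sample ID: ", samples[which(is.na(idx))[1]])
  genotype_matrix(gm$samples[idx], gm$loci, gm$a1[idx, , drop = FALSE],
                  gm$a2[idx, , drop = FALSE])
}

#' Alternative-allele dosage matrix
#'
#' For biallelic loci the 0/1/2 count of the alternative allele per call;
#' the encoding used for genotype r-squared.
#'
#' @param gm A `genotype_matrix`; all loci must be biallelic.
#' @return Integer matrix samples x loci, NA for missing calls.
#' @export
dosage_matrix <- function(gm) {
  if (any(lengths(gm$loci$alt) != 1L)) {
    stop("dosage is defined for biallelic loci only")
  }
  gm$a1 + gm$a2
}
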