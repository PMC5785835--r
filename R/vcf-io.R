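#' Read a multi-sample VCF into a genotype matrix
#'
#' Only the GT field is interpreted. Phase separators (`/` or `|`) are
#' ignored; `./.`, `.` and half-calls (e.g. `0/.`) all become missing.
#' Multi-allelic records are preserved as-is (filtering happens downstream,
#' not at read time).
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @param hla HLA interval used to set the per-locus `in_hla` flag.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, hla = hla_interval()) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- vcf@fix
  if (nrow(fix) == 0L) {
    # header-only file: recover sample names from the #CHROM line
    samples <- vcf_header_samples(path)
    loci <- locus_table(character(0), integer(0), character(0),
                        character(0), list(), hla = hla)
    a <- matrix(NA_integer_, nrow = length(samples), ncol = 0)
    return(genotype_matrix(samples, loci, a, a))
  }
  alt <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  loci <- tryCatch(
    locus_table(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "ID"],
                fix[, "REF"], alt, hla = hla),
    error = function(e) stop("invalid VCF '", path, "': ", conditionMessage(e))
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  n_loci <- nrow(gt)

  parts <- strsplit(as.vector(gt), "[/|]")
  first <- vapply(parts, function(p) if (length(p) >= 1L) p[1] else ".", character(1))
  second <- vapply(parts, function(p) if (length(p) >= 2L) p[2] else ".", character(1))
  bad_line <- lengths(parts) > 2L
  if (any(bad_line)) {
    i <- (which(bad_line)[1] - 1L) %% n_loci + 1L
    stop("malformed GT (more than two alleles in call) at ", loci$key[i])
  }
  a1 <- suppressWarnings(as.integer(first))
  a2 <- suppressWarnings(as.integer(second))
  miss <- is.na(a1) | is.na(a2)   # ".", "./." and half-calls -> MISSING
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  a1 <- matrix(a1, nrow = n_loci)
  a2 <- matrix(a2, nrow = n_loci)
  genotype_matrix(samples, loci, t(a1), t(a2))
}

vcf_header_samples <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("no #CHROM header line in VCF: ", path)
    if (startsWith(line, "#CHROM")) {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      return(if (length(f) > 9L) f[-(1:9)] else character(0))
    }
  }
}

#' Write a genotype matrix as an uncompressed VCF
#'
#' Emits a minimal VCF 4.2 with a GT-only FORMAT column. Reading the file back
#' with [read_vcf()] reproduces the calls, sample order and locus keys
#' (round-trip property). Missing calls are written as `./.`; multi-allelic
#' loci become a single record with comma-joined ALT.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @param header_comments Optional character vector of extra `##`-prefixed
#'   header lines (e.g. the simulation seed).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path, header_comments = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=iisnp",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(header_comments)) {
    hdr <- c(hdr, paste0("##", sub("^#+", "", header_comments)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", gm$samples), collapse = "\t"))
  n_loci <- nrow(gm$loci)
  body <- character(0)
  if (n_loci > 0L) {
    gt <- matrix(paste0(t(gm$a1), "/", t(gm$a2)), nrow = n_loci)  # loci x samples
    gt[is.na(t(gm$a1))] <- "./."
    alt_str <- vapply(gm$loci$alt, paste, character(1), collapse = ",")
    fixed <- paste(gm$loci$chrom, gm$loci$pos, gm$loci$id, gm$loci$ref,
                   alt_str, ".", ".", ".", "GT", sep = "\t")
    body <- if (length(gm$samples) == 0L) fixed else
      paste(fixed, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  }
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) stop("cannot write VCF to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Intersect the loci of two genotype matrices
#'
#' Loci are shared when (chrom, pos, ref) are identical and the alt-allele
#' sets overlap. Records at the same (chrom, pos) whose REF alleles disagree
#' are excluded from the intersection and reported as conflicts.
#'
#' @param a,b Two [genotype_matrix()] objects.
#' @return A list with `keys_a`/`keys_b` (the shared loci's keys in each
#'   matrix, ordered following `a`) and `conflicts` (data.frame of chrom, pos,
#'   ref_a, ref_b for REF disagreements).
#' @export
intersect_loci <- function(a, b) {
  la <- a$loci; lb <- b$loci
  cp_a <- paste(la$chrom, la$pos, sep = ":")
  cp_b <- paste(lb$chrom, lb$pos, sep = ":")
  cpr_a <- paste(cp_a, la$ref, sep = ":")
  cpr_b <- paste(cp_b, lb$ref, sep = ":")

  m <- match(cpr_a, cpr_b)
  shared <- which(!is.na(m))
  if (length(shared)) {
    overlap <- vapply(shared, function(i) {
      length(intersect(la$alt[[i]], lb$alt[[m[i]]])) > 0L
    }, logical(1))
    shared <- shared[overlap]
  }

  # same position, different ref -> conflict
  pos_m <- match(cp_a, cp_b)
  conf <- which(!is.na(pos_m) & is.na(m))
  conflicts <- data.frame(chrom = la$chrom[conf], pos = la$pos[conf],
                          ref_a = la$ref[conf], ref_b = lb$ref[pos_m[conf]],
                          stringsAsFactors = FALSE)
  list(keys_a = la$key[shared], keys_b = lb$key[m[shared]],
       conflicts = conflicts)
}

#' Read a query-to-reference sample map
#'
#' Two-column tab-separated text: query sample ID (e.g. RNA-seq) and the
#' expected reference (e.g. DNA/GWAS) sample ID. Many-to-one is allowed
#' (repeated reference measurements); query IDs must be unique.
#'
#' @param path Path to the map file. Lines starting with `#` are ignored.
#' @return A data.frame with columns `query` and `reference`.
#' @export
read_sample_map <- function(path) {
  if (!file.exists(path)) stop("sample map not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          colClasses = "character", col.names = c("query", "reference"))
  if (anyDuplicated(df$query)) {
    stop("duplicate query IDs in sample map: ", df$query[duplicated(df$query)][1])
  }
  df
}

#' Write a sample map
#' @param map Data.frame with columns `query` and `reference`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sample_map <- function(map, path) {
  utils::write.table(map[, c("query", "reference")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
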