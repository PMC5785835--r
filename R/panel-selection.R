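#' Panel-selection thresholds
#'
#' Default values are the published filter settings: genotype call rate above
#' 0.9, MAF above 0.2 in both call sets, Hardy-Weinberg exact test retained
#' at raw p > 0.01 and BH-FDR 1%, LD pruning at r-squared below 0.01.
#'
#' @param call_rate Minimum RNA genotype call rate (exclusive bound).
#' @param maf Minimum minor allele frequency in each call set (exclusive).
#' @param hwe_alpha Raw HWE p-value cut: loci with p <= `hwe_alpha` are
#'   removed. Set to 0 to disable.
#' @param fdr BH false-discovery-rate cut: loci with adjusted value < `fdr`
#'   are removed. Set to 0 to disable.
#' @param ld_r2 LD pruning threshold: pairs with r-squared at or above this
#'   are pruned to one member.
#' @param hla_exclude Drop loci flagged as inside the HLA interval.
#' @param hwe_on Which matrix feeds the HWE test: `"dna"` (default; the less
#'   error-prone calls) or `"rna"`.
#' @param ld_on Which matrix feeds the r-squared computation and the
#'   heterozygosity used for pruning.
#' @param panel_size Optional cap: keep the `panel_size` most informative
#'   survivors (lowest per-locus probability of identity). NULL keeps all.
#' @return A list of class `panel_params`.
#' @export
panel_params <- function(call_rate = 0.9, maf = 0.2, hwe_alpha = 0.01,
                         fdr = 0.01, ld_r2 = 0.01, hla_exclude = TRUE,
                         hwe_on = c("dna", "rna"), ld_on = c("dna", "rna"),
                         panel_size = NULL) {
  stopifnot(call_rate >= 0, call_rate <= 1, maf >= 0, maf < 0.5,
            hwe_alpha >= 0, hwe_alpha < 1, fdr >= 0, fdr < 1,
            ld_r2 > 0, ld_r2 <= 1)
  structure(list(call_rate = call_rate, maf = maf, hwe_alpha = hwe_alpha,
                 fdr = fdr, ld_r2 = ld_r2, hla_exclude = hla_exclude,
                 hwe_on = match.arg(hwe_on), ld_on = match.arg(ld_on),
                 panel_size = if (!is.null(panel_size)) as.integer(panel_size)),
            class = "panel_params")
}

#' Select an identification panel from paired DNA/RNA call sets
#'
#' Applies the filtering cascade, in order: (a) RNA genotype call rate;
#' (b) biallelic loci (at most two observed alleles and three observed
#' genotype classes, evaluated on the RNA calls); (c) MAF above the cut in
#' both the RNA and the DNA call set (each set's own frequencies); (d)
#' intersection of the surviving DNA and RNA locus sets; (e) Hardy-Weinberg
#' retention (exact test on the DNA genotypes by default; keep loci with raw
#' p above `hwe_alpha` and BH-adjusted value at or above `fdr`); (f) HLA
#' exclusion; (g) LD pruning at `ld_r2`, keeping the more heterozygous
#' member of each linked pair. An empty survivor set at any stage yields a
#' valid result with an empty final panel.
#'
#' @param dna,rna [genotype_matrix()] objects (non-empty).
#' @param params A [panel_params()] object.
#' @return An object of class `panel_selection`: list with `stages`
#'   (data.frame: stage, criterion, n_in, n_out), `survivors` (named list of
#'   key vectors per stage), `final_panel`, `params`, `conflicts` (REF
#'   disagreements from the intersection), and the per-locus stats tables
#'   used (`stats_rna`, `stats_dna`).
#' @export
select_panel <- function(dna, rna, params = panel_params()) {
  if (nrow(rna$loci) == 0L || nrow(dna$loci) == 0L) {
    stop("both call sets must contain at least one locus")
  }
  st_rna <- locus_stats(rna)
  st_dna <- locus_stats(dna)

  stages <- list(); survivors <- list()
  note <- function(name, criterion, n_in, keys) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, criterion = criterion, n_in = n_in,
      n_out = length(keys), stringsAsFactors = FALSE)
    survivors[[name]] <<- keys
    keys
  }

  # (a) RNA call rate
  keys <- st_rna$key[!is.na(st_rna$call_rate) & st_rna$call_rate > params$call_rate]
  keys <- note("call_rate", sprintf("RNA genotype call rate > %g", params$call_rate),
               nrow(st_rna), keys)

  # (b) biallelic on observed RNA calls
  s <- st_rna[match(keys, st_rna$key), ]
  ok <- !is.na(s$n_alleles_observed) & s$n_alleles_observed <= 2L &
    s$n_genotype_classes <= 3L
  keys <- note("biallelic", "<= 2 observed alleles and <= 3 genotype classes (RNA)",
               length(keys), keys[ok])

  # (c) MAF in both call sets
  s <- st_rna[match(keys, st_rna$key), ]
  keys <- note("maf_rna", sprintf("MAF > %g in RNA", params$maf),
               length(keys), keys[!is.na(s$maf) & s$maf > params$maf])
  dna_maf_keys <- st_dna$key[!is.na(st_dna$maf) & st_dna$maf > params$maf]
  stages[[length(stages) + 1L]] <- data.frame(
    stage = "maf_dna", criterion = sprintf("MAF > %g in DNA", params$maf),
    n_in = nrow(st_dna), n_out = length(dna_maf_keys), stringsAsFactors = FALSE)
  survivors[["maf_dna"]] <- dna_maf_keys

  # (d) intersection of surviving DNA and RNA loci
  shared <- intersect_loci(subset_loci(rna, keys),
                           subset_loci(dna, dna_maf_keys))
  # work with the RNA-side keys; record the DNA-side keys for lookups
  key_map <- stats::setNames(shared$keys_b, shared$keys_a)
  keys <- note("common", "common loci between DNA and RNA",
               length(keys), shared$keys_a)
  conflicts <- shared$conflicts

  # (e) HWE retention
  hwe_stats <- if (params$hwe_on == "dna") st_dna else st_rna
  hwe_keys <- if (params$hwe_on == "dna") unname(key_map[keys]) else keys
  hp <- hwe_stats$hwe_p[match(hwe_keys, hwe_stats$key)]
  hq <- if (any(!is.na(hp))) bh_adjust(ifelse(is.na(hp), NA, hp)) else hp
  keep <- !is.na(hp) &
    (params$hwe_alpha <= 0 | hp > params$hwe_alpha) &
    (params$fdr <= 0 | hq >= params$fdr)
  keys <- note("hwe", sprintf("HWE exact p > %g and BH q >= %g (%s)",
                              params$hwe_alpha, params$fdr, params$hwe_on),
               length(keys), keys[keep])

  # (f) HLA exclusion
  if (params$hla_exclude) {
    in_hla <- rna$loci$in_hla[match(keys, rna$loci$key)]
    keys <- note("hla", "outside the HLA interval", length(keys), keys[!in_hla])
  }

  # (g) LD pruning
  if (length(keys) >= 2L) {
    if (params$ld_on == "dna") {
      ld <- pairwise_r2(dna, unname(key_map[keys]))
      kept_dna <- prune_by_ld(ld, st_dna, params$ld_r2)
      kept <- keys[key_map[keys] %in% kept_dna]
    } else {
      ld <- pairwise_r2(rna, keys)
      kept <- prune_by_ld(ld, st_rna, params$ld_r2)
    }
    keys <- note("ld", sprintf("pairwise r2 < %g, keep more heterozygous (%s)",
                               params$ld_r2, params$ld_on),
                 length(keys), kept)
  } else {
    keys <- note("ld", sprintf("pairwise r2 < %g", params$ld_r2),
                 length(keys), keys)
  }

  # optional cap: most informative first
  if (!is.null(params$panel_size) && length(keys) > params$panel_size) {
    pis <- vapply(keys, function(k) {
      fr <- allele_frequencies(rna, k)$freqs
      pi_locus(fr[fr > 0])
    }, numeric(1))
    keys <- note("cap", sprintf("top %d by per-locus PI", params$panel_size),
                 length(keys), keys[order(pis)][seq_len(params$panel_size)])
  }

  structure(list(stages = do.call(rbind, stages), survivors = survivors,
                 final_panel = keys, params = params, conflicts = conflicts,
                 stats_rna = st_rna, stats_dna = st_dna),
            class = "panel_selection")
}

#' Stage table of a panel selection
#'
#' Per-stage audit trail: filter criterion, input and surviving locus counts.
#'
#' @param result A `panel_selection` from [select_panel()].
#' @return A data.frame with columns stage, criterion, n_in, n_out.
#' @export
stage_table <- function(result) {
  stopifnot(inherits(result, "panel_selection"))
  result$stages
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("panel_selection:\n")
  tb <- x$stages
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-10s %-55s %6d -> %d\n", tb$stage[i], tb$criterion[i],
                tb$n_in[i], tb$n_out[i]))
  }
  cat("  final panel:", length(x$final_panel), "loci\n")
  if (nrow(x$conflicts)) {
    cat("  REF conflicts excluded:", nrow(x$conflicts), "\n")
  }
  invisible(x)
}
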