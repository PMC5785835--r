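#' Run configuration for the end-to-end pipeline
#'
#' Collects input paths (or a simulation request), thresholds, the HLA
#' interval, the matching threshold and the seed. Every run writes its
#' resolved configuration next to its artifacts so results are reproducible.
#'
#' @param dna_vcf,rna_vcf Paths to the DNA and RNA multi-sample VCFs; leave
#'   NULL together with `simulate` to generate a synthetic cohort instead.
#' @param sample_map Optional path to the expected query-to-reference map
#'   (2-column TSV). For simulated cohorts the truth map is used.
#' @param simulate Optional [sim_config()]; when given, the cohort is
#'   simulated and also written to the output directory as VCF pairs plus
#'   truth tables.
#' @param params [panel_params()] thresholds.
#' @param match_threshold Minimal allele-concordance score for a best hit.
#' @param hla HLA interval from [hla_interval()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the random components (random unmatched
#'   pairs; simulation uses its own config seed).
#' @return List of class `run_config`.
#' @export
run_config <- function(dna_vcf = NULL, rna_vcf = NULL, sample_map = NULL,
                       simulate = NULL, params = panel_params(),
                       match_threshold = 0.8, hla = hla_interval(),
                       out_dir = "iisnp_out", seed = 1L) {
  if (is.null(simulate) && (is.null(dna_vcf) || is.null(rna_vcf))) {
    stop("either both VCF paths or a simulation config must be given")
  }
  stopifnot(match_threshold > 0)
  structure(list(dna_vcf = dna_vcf, rna_vcf = rna_vcf,
                 sample_map = sample_map, simulate = simulate,
                 params = params, match_threshold = match_threshold,
                 hla = hla, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv_report <- function(df, path, comments = character(0)) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

resolved_config_lines <- function(config) {
  p <- config$params
  c(sprintf("seed: %d", config$seed),
    sprintf("call_rate: %g", p$call_rate), sprintf("maf: %g", p$maf),
    sprintf("hwe_alpha: %g", p$hwe_alpha), sprintf("fdr: %g", p$fdr),
    sprintf("ld_r2: %g", p$ld_r2),
    sprintf("match_threshold: %g", config$match_threshold),
    sprintf("hla: %s:%d-%d", config$hla$chrom, config$hla$start, config$hla$end))
}

#' Run the full pipeline: (simulate) - select panel - identity - match
#'
#' Executes the whole analysis and writes tab-separated artifacts (with
#' `#`-prefixed header comments carrying the resolved thresholds and seed):
#' stage table, per-locus stats, identity report, match report, the panel as
#' a VCF subset, and for simulated cohorts the input VCF pair, truth table
#' and sample map. Rerunning with the same configuration and seed reproduces
#' the tabular artifacts byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`selection`,
#'   `identity`, `match`, `distributions`) and `artifacts` (named file
#'   paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- list()
  cfg_lines <- resolved_config_lines(config)

  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    dna <- cohort$dna; rna <- cohort$rna
    expected <- cohort$truth$sample_map
    seed_note <- sprintf("simulation seed: %d", config$simulate$seed)
    art$dna_vcf <- file.path(config$out_dir, "dna.vcf")
    art$rna_vcf <- file.path(config$out_dir, "rna.vcf")
    write_vcf(dna, art$dna_vcf, header_comments = seed_note)
    write_vcf(rna, art$rna_vcf, header_comments = seed_note)
    art$truth <- file.path(config$out_dir, "truth_loci.tsv")
    write_tsv_report(cohort$truth$loci, art$truth, c(cfg_lines, seed_note))
    art$sample_map <- file.path(config$out_dir, "sample_map.tsv")
    write_sample_map(expected, art$sample_map)
  } else {
    for (p in c(config$dna_vcf, config$rna_vcf)) {
      if (!file.exists(p)) stop("input not found: ", p)
    }
    dna <- read_vcf(config$dna_vcf, hla = config$hla)
    rna <- read_vcf(config$rna_vcf, hla = config$hla)
    expected <- if (!is.null(config$sample_map)) read_sample_map(config$sample_map)
      else data.frame(query = intersect(rna$samples, dna$samples),
                      reference = intersect(rna$samples, dna$samples),
                      stringsAsFactors = FALSE)
  }

  selection <- select_panel(dna, rna, config$params)
  art$stage_table <- file.path(config$out_dir, "stage_table.tsv")
  write_tsv_report(stage_table(selection), art$stage_table, cfg_lines)
  art$locus_stats <- file.path(config$out_dir, "locus_stats.tsv")
  write_tsv_report(selection$stats_rna, art$locus_stats,
                   c(cfg_lines, "per-locus stats (RNA)"))

  panel <- selection$final_panel
  if (length(panel) == 0L) {
    art$panel_vcf <- NULL
    warning("empty final panel; identity and matching skipped")
    out <- list(selection = selection, identity = NULL, match = NULL,
                distributions = NULL, artifacts = art)
    return(invisible(out))
  }
  # panel VCF subset (DNA-side calls)
  dna_keys <- intersect_loci(subset_loci(rna, panel), dna)$keys_b
  art$panel_vcf <- file.path(config$out_dir, "panel.vcf")
  write_vcf(subset_loci(dna, dna_keys), art$panel_vcf,
            header_comments = cfg_lines)

  identity <- identity_report(subset_loci(dna, dna_keys),
                              n_samples = length(dna$samples))
  art$identity <- file.path(config$out_dir, "identity.tsv")
  per <- identity$per_locus
  per$cumulative_pi <- identity$cumulative_pi
  per$cumulative_pisib <- identity$cumulative_pisib
  write_tsv_report(per, art$identity,
                   c(cfg_lines,
                     sprintf("multilocus PI log10: %.4f", identity$pi$log10),
                     sprintf("multilocus PI-sibs log10: %.4f", identity$pisib$log10)))

  match <- match_samples(rna, dna, panel, expected,
                         threshold = config$match_threshold)
  art$match <- file.path(config$out_dir, "match_report.tsv")
  write_tsv_report(match$assignments, art$match,
                   c(cfg_lines, paste(names(match$counts),
                                      as.integer(match$counts),
                                      sep = "=", collapse = " ")))
  dist <- concordance_distributions(rna, dna, panel, expected,
                                    n_random = min(1000, length(rna$samples)^2),
                                    seed = config$seed)
  art$config <- file.path(config$out_dir, "config_resolved.txt")
  writeLines(cfg_lines, art$config)

  invisible(list(selection = selection, identity = identity, match = match,
                 distributions = dist, artifacts = art))
}
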