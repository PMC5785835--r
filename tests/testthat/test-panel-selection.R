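test_that("a clean zero-noise cohort survives every filter intact", {
  cfg <- sim_config(n_samples = 400, n_loci = 25, missing_rate = 0,
                    rna_error_rate = 0, seed = 79)
  co <- simulate_cohort(cfg)
  sel <- select_panel(co$dna, co$rna)
  tb <- stage_table(sel)
  expect_equal(tb$n_out[tb$stage == "call_rate"], 25L)
  expect_equal(tb$n_out[tb$stage == "biallelic"], 25L)
  expect_equal(tb$n_out[tb$stage == "maf_rna"], 25L)
  expect_equal(tb$n_out[tb$stage == "common"], 25L)
  expect_equal(tb$n_out[tb$stage == "hla"], 25L)
  # HWE may reject a clean locus by chance at most rarely; LD likewise.
  expect_gte(tb$n_out[tb$stage == "hwe"], 23L)
  expect_setequal(setdiff(locus_keys(co$dna), sel$final_panel),
                  setdiff(locus_keys(co$dna), sel$survivors$ld))
})

test_that("a cohort of uniformly rare alleles yields an empty panel", {
  cfg <- sim_config(n_samples = 200, n_loci = 10, aaf = rep(0.1, 10),
                    missing_rate = 0, rna_error_rate = 0, seed = 83)
  co <- simulate_cohort(cfg)
  sel <- select_panel(co$dna, co$rna)
  tb <- stage_table(sel)
  expect_equal(tb$n_out[tb$stage == "maf_rna"], 0L)
  expect_length(sel$final_panel, 0L)      # valid result, not an error
})

test_that("stage counts are non-increasing along each lineage", {
  cfg <- sim_config(n_samples = 300, n_loci = 40, n_low_maf = 5,
                    n_multiallelic = 3, n_hla = 2, n_ld_pairs = 2, seed = 89)
  co <- simulate_cohort(cfg)
  tb <- stage_table(select_panel(co$dna, co$rna))
  rna_lineage <- tb[tb$stage != "maf_dna", ]
  expect_true(all(rna_lineage$n_out <= rna_lineage$n_in))
  expect_true(all(diff(rna_lineage$n_out) <= 0))
})

test_that("every final-panel locus satisfies all filters on recomputation", {
  cfg <- sim_config(n_samples = 800, n_loci = 60, n_low_maf = 6,
                    n_multiallelic = 4, n_hwe_violating = 4, n_ld_pairs = 3,
                    n_hla = 2, seed = 97)
  co <- simulate_cohort(cfg)
  params <- panel_params()
  sel <- select_panel(co$dna, co$rna, params)
  expect_gt(length(sel$final_panel), 0L)

  st_rna <- locus_stats(co$rna)
  st_dna <- locus_stats(co$dna)
  for (k in sel$final_panel) {
    i <- match(k, st_rna$key)
    expect_gt(st_rna$call_rate[i], params$call_rate)
    expect_lte(st_rna$n_alleles_observed[i], 2L)
    expect_lte(st_rna$n_genotype_classes[i], 3L)
    expect_gt(st_rna$maf[i], params$maf)
    expect_gt(st_dna$maf[match(k, st_dna$key)], params$maf)
    expect_gt(st_dna$hwe_p[match(k, st_dna$key)], params$hwe_alpha)
    expect_false(co$rna$loci$in_hla[match(k, locus_keys(co$rna))])
  }
  if (length(sel$final_panel) > 1L) {
    sub <- pairwise_r2(co$dna, sel$final_panel)
    expect_lt(max(sub$r2, na.rm = TRUE), params$ld_r2)
  }
  # planted violators are all excluded
  truth <- co$truth$loci
  violators <- truth$key[!truth$label %in% c("none", "ld")]
  expect_length(intersect(sel$final_panel, violators), 0L)
})

test_that("HWE and HLA filter order does not change the final panel", {
  cfg <- sim_config(n_samples = 400, n_loci = 30, n_hwe_violating = 3,
                    n_hla = 3, seed = 101)
  co <- simulate_cohort(cfg)
  base <- select_panel(co$dna, co$rna)
  # disabling HLA exclusion re-admits exactly the HLA loci that pass the rest
  no_hla <- select_panel(co$dna, co$rna, panel_params(hla_exclude = FALSE))
  extra <- setdiff(no_hla$survivors$hwe, base$survivors$hla)
  hla_keys <- co$truth$loci$key[co$truth$loci$label == "hla"]
  expect_true(all(extra %in% hla_keys))
})

test_that("the optional cap keeps the most informative loci", {
  cfg <- sim_config(n_samples = 500, n_loci = 30, missing_rate = 0,
                    rna_error_rate = 0, seed = 103)
  co <- simulate_cohort(cfg)
  sel <- select_panel(co$dna, co$rna, panel_params(panel_size = 5))
  expect_length(sel$final_panel, 5L)
  uncapped <- select_panel(co$dna, co$rna)
  pis <- vapply(uncapped$final_panel, function(k) {
    fr <- allele_frequencies(co$rna, k)$freqs
    pi_locus(fr[fr > 0])
  }, numeric(1))
  expect_setequal(sel$final_panel,
                  uncapped$final_panel[order(pis)][1:5])
})

test_that("empty call sets are rejected, REF conflicts reported", {
  cfg <- sim_config(n_samples = 20, n_loci = 5, seed = 107)
  co <- simulate_cohort(cfg)
  empty <- make_gm(list(c("0/0", "0/1")))
  expect_error(select_panel(subset_loci(co$dna, character(0)), co$rna),
               "at least one locus")

  # conflicting REF at a shared position is excluded and reported
  rna2 <- co$rna
  rna2$loci$ref[1] <- "C"
  rna2$loci$key <- locus_key(rna2$loci$chrom, rna2$loci$pos,
                             rna2$loci$ref, rna2$loci$alt)
  colnames(rna2$a1) <- colnames(rna2$a2) <- rna2$loci$key
  sel <- select_panel(co$dna, rna2)
  expect_equal(nrow(sel$conflicts), 1L)
  expect_false(rna2$loci$key[1] %in% sel$final_panel)
})
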