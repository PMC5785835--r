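gt <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

test_that("concordance score counts shared alleles per locus", {
  # identical vectors over 50 loci, no missing: score 1, 100 alleles total
  q <- gt(rep(c(0L, 1L), 50))
  cs <- concordance_score(q, q)
  expect_equal(cs$score, 1.0)
  expect_equal(cs$total_alleles, 100L)
  expect_equal(cs$identical_genotypes, 50L)

  # every locus AA vs AB: one shared allele of two
  q2 <- gt(rep(c(0L, 0L), 10)); r2 <- gt(rep(c(0L, 1L), 10))
  expect_equal(concordance_score(q2, r2)$score, 0.5)

  # 4 loci: (AA,AA),(AB,AA),(AA,BB),(AB,AB) -> shared 2+1+0+2 = 5 of 8
  q4 <- gt(0L,0L, 0L,1L, 0L,0L, 0L,1L)
  r4 <- gt(0L,0L, 0L,0L, 1L,1L, 0L,1L)
  cs4 <- concordance_score(q4, r4)
  expect_equal(cs4$shared_alleles, 5L)
  expect_equal(cs4$score, 0.625)
  expect_equal(cs4$identical_genotypes, 2L)

  # single-allele overlap across heterozygotes: AB vs BC shares one allele
  expect_equal(concordance_score(gt(0L, 1L), gt(1L, 2L))$shared_alleles, 1L)
  # phase must not matter
  expect_equal(concordance_score(gt(1L, 0L), gt(0L, 1L))$score, 1.0)
})

test_that("concordance score is symmetric and excludes missing loci", {
  set.seed(53)
  q <- gt(sample(0:1, 40, TRUE)); r <- gt(sample(0:1, 40, TRUE))
  expect_equal(concordance_score(q, r)$score, concordance_score(r, q)$score)

  qm <- gt(0L,0L, NA,NA, 0L,1L); rm_ <- gt(0L,0L, 1L,1L, NA,NA)
  cs <- concordance_score(qm, rm_)
  expect_equal(cs$loci_compared, 1L)
  expect_equal(cs$score, 1.0)

  # zero comparable loci: undefined, flagged
  expect_true(is.na(concordance_score(gt(NA, NA), gt(0L, 0L))$score))
})

test_that("zero-noise matching passes every query", {
  cfg <- sim_config(n_samples = 40, n_loci = 30, missing_rate = 0,
                    rna_error_rate = 0, n_swaps = 0, seed = 59)
  co <- simulate_cohort(cfg)
  rep <- match_samples(co$rna, co$dna, locus_keys(co$dna), co$truth$sample_map)
  expect_equal(unname(rep$counts[["PASSED_MATCHING"]]), 40L)
  expect_equal(unname(rep$counts[["FAILED_MATCHING"]]), 0L)
  expect_true(all(rep$assignments$best_score == 1))

  # unattainable threshold: everything unsure
  rep2 <- match_samples(co$rna, co$dna, locus_keys(co$dna),
                        co$truth$sample_map, threshold = 1.01)
  expect_equal(unname(rep2$counts[["UNSURE"]]), 40L)
})

test_that("planted swaps are flagged FAILED and only they fail", {
  cfg <- sim_config(n_samples = 100, n_loci = 50, missing_rate = 0.02,
                    rna_error_rate = 0.02, n_swaps = 2, seed = 61)
  co <- simulate_cohort(cfg)
  rep <- match_samples(co$rna, co$dna, locus_keys(co$dna), co$truth$sample_map)
  failed <- rep$assignments$query[rep$assignments$category == "FAILED_MATCHING"]
  expect_setequal(failed, co$truth$swaps$query)
  expect_equal(unname(rep$counts[["PASSED_MATCHING"]]), 98L)
  # the swapped query's best hit is its true donor
  for (i in seq_len(2)) {
    row <- rep$assignments[rep$assignments$query == co$truth$swaps$query[i], ]
    expect_equal(row$best_hits, co$truth$swaps$true_donor[i])
  }
})

test_that("repeated reference measurements count as PASSED via any copy", {
  cfg <- sim_config(n_samples = 20, n_loci = 30, missing_rate = 0,
                    rna_error_rate = 0, seed = 67)
  co <- simulate_cohort(cfg)
  # duplicate the reference cohort under new labels (repeat measurements)
  dna2 <- co$dna
  dna2$samples <- paste0(dna2$samples, "_rep")
  rownames(dna2$a1) <- rownames(dna2$a2) <- dna2$samples
  refs <- genotype_matrix(c(co$dna$samples, dna2$samples), co$dna$loci,
                          rbind(co$dna$a1, dna2$a1), rbind(co$dna$a2, dna2$a2))
  expected <- rbind(
    data.frame(query = co$rna$samples, reference = co$dna$samples),
    data.frame(query = co$rna$samples, reference = dna2$samples))
  rep <- match_samples(co$rna, refs, locus_keys(co$dna), expected)
  expect_equal(unname(rep$counts[["PASSED_MATCHING"]]), 20L)
  # best-hit set contains both repeated measurements (ties allowed)
  expect_true(all(grepl(",", rep$assignments$best_hits)))
})

test_that("queries missing from the expected map fail unless report-only", {
  cfg <- sim_config(n_samples = 10, n_loci = 30, missing_rate = 0,
                    rna_error_rate = 0, seed = 71)
  co <- simulate_cohort(cfg)
  expected <- co$truth$sample_map[-1, ]
  rep <- match_samples(co$rna, co$dna, locus_keys(co$dna), expected)
  cat1 <- rep$assignments$category[rep$assignments$query == co$rna$samples[1]]
  expect_equal(cat1, "FAILED_MATCHING")
  rep2 <- match_samples(co$rna, co$dna, locus_keys(co$dna), expected,
                        unmapped = "report")
  cat2 <- rep2$assignments$category[rep2$assignments$query == co$rna$samples[1]]
  expect_equal(cat2, "UNMAPPED")
})

test_that("matched and unmatched genotype-sharing distributions separate", {
  cfg <- sim_config(n_samples = 60, n_loci = 50, missing_rate = 0,
                    rna_error_rate = 0, seed = 73)
  co <- simulate_cohort(cfg)
  d <- concordance_distributions(co$rna, co$dna, locus_keys(co$dna),
                                 co$truth$sample_map, n_random = 500, seed = 5)
  expect_true(all(d$matched == 50L))   # zero noise: all loci identical
  expect_gt(d$gap, 0)

  # unrelated pairs share genotypes at about the per-locus PI rate
  aafs <- vapply(locus_keys(co$dna),
                 function(k) allele_frequencies(co$dna, k)$aaf, numeric(1))
  expected_mean <- sum(vapply(aafs, function(q) pi_locus(c(1 - q, q)),
                              numeric(1)))
  expect_lt(abs(mean(d$unmatched) - expected_mean), 3)
})
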