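test_that("simulation is deterministic given config and seed", {
  cfg <- sim_config(n_samples = 50, n_loci = 20, n_ld_pairs = 2, n_swaps = 2,
                    n_sib_pairs = 3, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$dna$a1, b$dna$a1)
  expect_identical(a$rna$a1, b$rna$a1)
  expect_identical(a$truth$swaps, b$truth$swaps)
})

test_that("zero-noise limit: RNA equals DNA at every call", {
  cfg <- sim_config(n_samples = 80, n_loci = 15, missing_rate = 0,
                    rna_error_rate = 0, n_swaps = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_identical(co$dna$a1, co$rna$a1)
  expect_identical(co$dna$a2, co$rna$a2)
})

test_that("planted violations are counted and labelled as configured", {
  cfg <- sim_config(n_samples = 40, n_loci = 100, n_low_maf = 10,
                    n_multiallelic = 5, n_hwe_violating = 4, n_ld_pairs = 3,
                    n_hla = 2, n_low_callrate = 2, seed = 5)
  co <- simulate_cohort(cfg)
  lab <- table(co$truth$loci$label)
  expect_equal(unname(lab["low_maf"]), 10L)
  expect_equal(unname(lab["multiallelic"]), 5L)
  expect_equal(unname(lab["hwe"]), 4L)
  expect_equal(unname(lab["ld"]), 6L)       # 3 pairs = 6 loci
  expect_equal(unname(lab["hla"]), 2L)
  expect_equal(unname(lab["callrate"]), 2L)
  expect_equal(sum(lab), 100L)              # labels partition the locus set

  # planted low-MAF frequencies are below 0.2, sample-independently
  low <- co$truth$loci$planted_aaf[co$truth$loci$label == "low_maf"]
  expect_true(all(pmin(low, 1 - low) < 0.2))
  # HLA-planted loci are flagged by the interval
  hla_keys <- co$truth$loci$key[co$truth$loci$label == "hla"]
  expect_true(all(co$dna$loci$in_hla[match(hla_keys, locus_keys(co$dna))]))
  # every ld locus has a recorded partner
  ld <- co$truth$loci[co$truth$loci$label == "ld", ]
  expect_true(all(ld$ld_partner %in% ld$key))
})

test_that("infeasible configs are rejected", {
  expect_error(sim_config(n_loci = 5, n_low_maf = 10), "infeasible")
  expect_error(sim_config(n_swaps = 1), "n_swaps")
  expect_error(sim_config(missing_rate = 1.2), "rates")
  expect_error(sim_config(n_samples = 4, n_sib_pairs = 3), "sib")
})

test_that("empirical AAF agrees with the planted value (binomial sampling)", {
  cfg <- sim_config(n_samples = 10000, n_loci = 1, aaf = 0.5,
                    missing_rate = 0, rna_error_rate = 0, seed = 21)
  co <- simulate_cohort(cfg)
  aaf <- allele_frequencies(co$dna, locus_keys(co$dna))$aaf
  se <- sqrt(0.5 * 0.5 / (2 * 10000))
  expect_lt(abs(aaf - 0.5), 3 * se)
})

test_that("unrelated-pair match fraction matches the analytic PI", {
  expect_equal(simulate_unrelated_pairs(0, 100, seed = 1), 1.0)  # monomorphic
  n <- 2e5
  pi1 <- 0.375
  f1 <- simulate_unrelated_pairs(0.5, n, seed = 42)
  expect_lt(abs(f1 - pi1), 3 * sqrt(pi1 * (1 - pi1) / n))
  pi3 <- 0.375^3
  f3 <- simulate_unrelated_pairs(c(0.5, 0.5, 0.5), n, seed = 42)
  expect_lt(abs(f3 - pi3), 3 * sqrt(pi3 * (1 - pi3) / n))
})

test_that("sib-pair match fraction matches the analytic PI-sibs", {
  expect_equal(simulate_sib_pairs(0, 100, seed = 1), 1.0)
  n <- 2e5
  ps1 <- 0.59375
  f1 <- simulate_sib_pairs(0.5, n, seed = 42)
  expect_lt(abs(f1 - ps1), 3 * sqrt(ps1 * (1 - ps1) / n))
  ps2 <- 0.59375^2
  f2 <- simulate_sib_pairs(c(0.5, 0.5), n, seed = 42)
  expect_lt(abs(f2 - ps2), 3 * sqrt(ps2 * (1 - ps2) / n))
})

test_that("label swaps cycle RNA rows and are recorded in the truth", {
  cfg <- sim_config(n_samples = 30, n_loci = 10, missing_rate = 0,
                    rna_error_rate = 0, n_swaps = 2, seed = 13)
  co <- simulate_cohort(cfg)
  sw <- co$truth$swaps
  expect_equal(nrow(sw), 2L)
  for (i in seq_len(nrow(sw))) {
    q <- match(sw$query[i], co$rna$samples)
    d <- match(sw$true_donor[i], co$dna$samples)
    expect_equal(unname(co$rna$a1[q, ]), unname(co$dna$a1[d, ]))
  }
  # a swapped label no longer matches its own DNA row
  q1 <- match(sw$query[1], co$rna$samples)
  expect_false(identical(unname(co$rna$a1[q1, ]),
                         unname(co$dna$a1[q1, ])))
})

test_that("sib pairs share more genotypes than unrelated pairs", {
  cfg <- sim_config(n_samples = 200, n_loci = 60, aaf = rep(0.5, 60),
                    missing_rate = 0, rna_error_rate = 0,
                    n_sib_pairs = 50, seed = 17)
  co <- simulate_cohort(cfg)
  d <- dosage_matrix(co$dna)
  sib_share <- mean(vapply(seq_len(50), function(k) {
    mean(d[2 * k - 1, ] == d[2 * k, ])
  }, numeric(1)))
  unrel_share <- mean(vapply(seq_len(49), function(k) {
    mean(d[2 * k, ] == d[2 * k + 1, ])  # across-family neighbours
  }, numeric(1)))
  expect_gt(sib_share, unrel_share)
  # sib sharing should be near PIsib(0.5) = 0.59375, unrelated near 0.375
  expect_lt(abs(sib_share - 0.59375), 0.05)
  expect_lt(abs(unrel_share - 0.375), 0.05)
})
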