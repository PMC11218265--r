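test_that("variant simulation respects null fraction, MAF range and effect scale", {
  cfg0 <- sim_config(n_genes = 2, variants_per_gene = 50, null_fraction = 1,
                     seed = 5)
  v0 <- simulate_variants(cfg0)
  expect_true(all(v0$effects$beta == 0))

  cfg1 <- sim_config(n_genes = 2, variants_per_gene = 30,
                     maf_range = c(1e-4, 1e-4), seed = 5)
  v1 <- simulate_variants(cfg1)
  expect_equal(v1$variants$maf, rep(1e-4, 60))

  cfg2 <- sim_config(n_genes = 10, variants_per_gene = 1000,
                     null_fraction = 0, effect_scale = 1, seed = 5)
  v2 <- simulate_variants(cfg2)
  expect_gt(mean(abs(v2$effects$beta)), 0.9)
  expect_lt(mean(abs(v2$effects$beta)), 1.1)

  expect_error(sim_config(maf_range = c(1e-4, 2e-3)), "maf_range",
               class = "vepbench_config_error")
  expect_error(sim_config(prevalence = 0), "prevalence",
               class = "vepbench_config_error")
})

test_that("genotype simulation matches binomial carrier expectations", {
  cfg <- sim_config(n_participants = 100000, n_genes = 1,
                    variants_per_gene = 1, maf_range = c(5e-4, 5e-4),
                    seed = 2)
  v <- simulate_variants(cfg)
  gt <- simulate_genotypes(v$variants, 100000, seed = 9)
  ac <- sum(gt$calls$dosage)
  # allele count ~ Binomial(2e5, 5e-4): mean 100, sd ~ 10
  expect_gt(ac, 70)
  expect_lt(ac, 130)

  gt2 <- simulate_genotypes(v$variants, 100000, seed = 9)
  expect_identical(gt$calls, gt2$calls)
  expect_identical(gt$site_qc, gt2$site_qc)

  # MAF 0 for every variant -> empty carrier matrix
  vz <- v$variants
  vz$maf <- 0
  gtz <- simulate_genotypes(vz, 1000, seed = 1)
  expect_equal(nrow(gtz$calls), 0)

  expect_error(simulate_genotypes(v$variants, 0, seed = 1),
               class = "vepbench_config_error")
})

test_that("traits are additive with a calibrated liability threshold", {
  cfg <- sim_config(n_participants = 3, trait_noise_sd = 0, seed = 1)
  effects <- data.frame(variant_id = c("v1", "v2"), beta = c(1.5, 2.0))
  gt <- list(calls = data.frame(participant_id = c("P1", "P1"),
                                variant_id = c("v1", "v2"),
                                dosage = c(1L, 1L)),
             participant_ids = c("P1", "P2", "P3"))
  ph <- simulate_traits(gt, effects, cfg, seed = 4)
  qt <- ph[ph$trait_id == "qt1", ]
  expect_equal(qt$value[qt$participant_id == "P1"], 3.5)
  expect_equal(qt$value[qt$participant_id == "P2"], 0)
  expect_equal(qt$value[qt$participant_id == "P3"], 0)

  # missing effect for a carried variant
  expect_error(simulate_traits(list(calls = data.frame(
    participant_id = "P1", variant_id = "vX", dosage = 1L),
    participant_ids = "P1"), effects, cfg, seed = 1),
    class = "vepbench_data_error")

  # realized prevalence concentrates around the target
  cfgp <- sim_config(n_participants = 100000, prevalence = 0.1, seed = 1)
  gt0 <- list(calls = data.frame(participant_id = character(0),
                                 variant_id = character(0),
                                 dosage = integer(0)),
              participant_ids = sprintf("P%06d", 1:100000))
  php <- simulate_traits(gt0, effects, cfgp, seed = 8)
  bt <- php[php$trait_id == "bt1", ]
  expect_gt(mean(bt$value), 0.09)
  expect_lt(mean(bt$value), 0.11)
})

test_that("predictor scores are noisy monotone transforms with orientation and missingness", {
  effects <- data.frame(variant_id = sprintf("v%04d", 1:1000),
                        beta = rnorm(1000))
  specs <- list(predictor_fidelity("perfect", noise_sd = 0),
                predictor_fidelity("neg", noise_sd = 0,
                                   orientation = "low_is_damaging",
                                   copy_of = "perfect"),
                predictor_fidelity("half", noise_sd = 0,
                                   missingness = 0.5))
  sc <- simulate_predictor_scores(effects, specs, seed = 3)
  perfect <- sc$scores[sc$scores$predictor_id == "perfect", ]
  expect_equal(order(perfect$score), order(abs(effects$beta)))
  neg <- sc$scores[sc$scores$predictor_id == "neg", ]
  expect_equal(neg$score, -perfect$score)
  n_half <- sum(sc$scores$predictor_id == "half")
  expect_gt(n_half, 500 - 3 * sqrt(250))
  expect_lt(n_half, 500 + 3 * sqrt(250))
  expect_equal(sc$meta$orientation,
               c("high_is_damaging", "low_is_damaging", "high_is_damaging"))
})

test_that("score-truth correlation decreases strictly with predictor noise", {
  cors <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    effects <- withr::with_seed(s, data.frame(
      variant_id = sprintf("v%03d", 1:300),
      beta = rexp(300) * sample(c(-1, 1), 300, TRUE)))
    sc <- simulate_predictor_scores(
      effects,
      list(predictor_fidelity("a", 0.1), predictor_fidelity("b", 0.5),
           predictor_fidelity("c", 2.0)), seed = s + 100)
    for (k in seq_along(c("a", "b", "c"))) {
      sub <- sc$scores[sc$scores$predictor_id == c("a", "b", "c")[k], ]
      cors[s, k] <- cor(sub$score, abs(effects$beta))
    }
  }
  m <- colMeans(cors)
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
})

test_that("noiseless quantitative trait is an exact linear function of dosage-weighted effects", {
  cfg <- sim_config(n_participants = 200, n_genes = 2,
                    variants_per_gene = 20, null_fraction = 0,
                    trait_noise_sd = 0, maf_range = c(5e-4, 9e-4),
                    seed = 17)
  co <- simulate_cohort(cfg)
  qt <- co$phenotypes[co$phenotypes$trait_id == "qt1", ]
  y <- setNames(qt$value, qt$participant_id)
  beta <- setNames(co$effects$beta, co$effects$variant_id)
  # independent accumulation, participant by participant
  expected <- setNames(numeric(length(co$participant_ids)),
                       co$participant_ids)
  for (i in seq_len(nrow(co$calls))) {
    p <- co$calls$participant_id[i]
    expected[p] <- expected[p] +
      co$calls$dosage[i] * beta[co$calls$variant_id[i]]
  }
  expect_equal(unname(y[names(expected)]), unname(expected),
               tolerance = 1e-12)
})

test_that("fixture files round-trip the carrier matrix and regenerate byte-identically", {
  cfg <- sim_config(n_participants = 80, n_genes = 2,
                    variants_per_gene = 10, maf_range = c(5e-4, 9e-4),
                    seed = 21)
  co <- simulate_cohort(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_cohort_fixture(co, d1)
  p2 <- write_cohort_fixture(co, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = paste("file", f))
  }
  g <- read_genotypes(p1[["vcf"]], "vcf")
  expect_equal(nrow(g$sites), nrow(co$variants))
  cols <- c("participant_id", "variant_id", "dosage", "depth",
            "allele_balance")
  a <- co$calls[order(co$calls$variant_id, co$calls$participant_id), cols]
  b <- g$calls[order(g$calls$variant_id, g$calls$participant_id), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})
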