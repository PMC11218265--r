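toy_vcf <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    # one missing genotype out of three samples
    "1\t100\tva\tA\tG\t45.2\tPASS\tGENE=g1;GNOMAD_AF=0.0002\tGT:DP:AD\t0/1:20:12,8\t0/0:30:30,0\t./.:.:.",
    # multi-allelic record, decomposed into two sites
    "1\t200\tvb\tC\tA,T\t50\tPASS\tGENE=g1\tGT:DP:AD\t1/2:24:6,10,8\t0/0:30:30,0,0\t2/2:18:0,0,18",
    # fully genotyped record
    "1\t300\tvc\tG\tT\t33\tPASS\tGENE=g2;GNOMAD_AF=0\tGT:DP:AD\t0/0:25:25,0\t0/1:14:7,7\t0/0:22:22,0")
  path <- file.path(dir, "toy.vcf")
  writeLines(lines, path)
  path
}

test_that("VCF reading computes missingness, allele balance and decomposes multi-allelics", {
  g <- read_genotypes(toy_vcf(), "vcf")
  expect_equal(nrow(g$sites), 4)  # va, vb_alt1, vb_alt2, vc
  va <- g$sites[g$sites$variant_id == "va", ]
  expect_equal(va$call_missingness, 1 / 3)
  expect_equal(va$site_quality, 45.2)
  expect_equal(va$gene_id, "g1")
  expect_equal(va$reference_maf, 2e-4)
  vc <- g$sites[g$sites$variant_id == "vc", ]
  expect_equal(vc$call_missingness, 0)
  expect_true(is.na(g$sites$reference_maf[g$sites$variant_id ==
                                            "vb_alt1"]))

  ca <- g$calls[g$calls$variant_id == "va", ]
  expect_equal(ca$participant_id, "S1")
  expect_equal(ca$dosage, 1L)
  expect_equal(ca$allele_balance, 8 / 20)

  b1 <- g$calls[g$calls$variant_id == "vb_alt1", ]
  expect_equal(b1$participant_id, "S1")
  expect_equal(b1$dosage, 1L)
  expect_equal(b1$allele_balance, 10 / 24)
  b2 <- g$calls[g$calls$variant_id == "vb_alt2", ]
  expect_equal(b2$dosage[b2$participant_id == "S1"], 1L)
  expect_equal(b2$dosage[b2$participant_id == "S3"], 2L)
  expect_equal(b2$allele_balance[b2$participant_id == "S3"], 1)

  expect_error(read_genotypes(file.path(tempdir(), "nope.vcf")),
               class = "vepbench_io_error")
})

test_that("QC filters apply the documented site and call rules", {
  sites <- data.frame(
    variant_id = paste0("s", 1:5), gene_id = "g", chrom = "1", pos = 1:5,
    ref = "A", alt = "G",
    site_quality = c(30, 30, 30, 15, 30),
    call_missingness = c(0.05, 0.05, 0.2, 0.05, 0.05),
    reference_maf = 0, stringsAsFactors = FALSE)
  calls <- data.frame(
    participant_id = paste0("P", 1:5),
    variant_id = paste0("s", 1:5),
    dosage = 1L,
    depth = c(10, 6, 10, 10, 10),
    allele_balance = c(0.5, 0.5, 0.5, 0.5, 0.1),
    stringsAsFactors = FALSE)
  out <- apply_qc(sites, calls, qc_thresholds())
  expect_equal(out$sites$variant_id, "s1")

  # quality exactly at / below the exclusive threshold fails
  s19 <- sites[1, ]; s19$site_quality <- 19
  expect_equal(nrow(apply_qc(s19, calls[1, ], qc_thresholds())$sites), 0)
  s20 <- sites[1, ]; s20$site_quality <- 20
  expect_equal(nrow(apply_qc(s20, calls[1, ], qc_thresholds())$sites), 0)

  # vacuous thresholds keep every site with at least one carrier
  lax <- qc_thresholds(min_quality = 0, max_missingness = 1,
                       min_depth = 0, min_allele_balance = 0)
  expect_equal(apply_qc(sites, calls, lax)$sites$variant_id,
               paste0("s", 1:5))

  # homozygous-alt carriers auto-pass the allele-balance rule
  hom <- calls[5, ]; hom$dosage <- 2L
  expect_equal(nrow(apply_qc(sites[5, ], hom, qc_thresholds())$sites), 1)

  # NA depth / allele balance auto-pass their filters
  nas <- calls[1, ]; nas$depth <- NA_integer_
  nas$allele_balance <- NA_real_
  expect_equal(nrow(apply_qc(sites[1, ], nas, qc_thresholds())$sites), 1)

  # call-level AB rule additionally drops sub-threshold heterozygous calls
  two <- rbind(calls[1, ], within(calls[1, ], {
    participant_id <- "P9"; allele_balance <- 0.05
  }))
  kept <- apply_qc(sites[1, ], two, qc_thresholds(ab_rule = "call"))
  expect_equal(kept$calls$participant_id, "P1")
  kept_site <- apply_qc(sites[1, ], two, qc_thresholds(ab_rule = "site"))
  expect_equal(sort(kept_site$calls$participant_id), c("P1", "P9"))
})

test_that("cohort MAF is allele-count arithmetic folded to the minor allele", {
  one_het <- data.frame(participant_id = "P1", variant_id = "v1",
                        dosage = 1L, depth = 30, allele_balance = 0.5)
  expect_equal(compute_cohort_maf(one_het, 1000)$cohort_maf, 5e-4)
  expect_equal(nrow(compute_cohort_maf(one_het[0, ], 1000)), 0)
  hom <- within(one_het, dosage <- 2L)
  expect_equal(compute_cohort_maf(hom, 1)$cohort_maf, 0)
  expect_error(compute_cohort_maf(hom, 0.5),
               class = "vepbench_config_error")
  too_many <- data.frame(participant_id = c("P1", "P2"),
                         variant_id = "v1", dosage = 2L,
                         depth = 30, allele_balance = 0.5)
  expect_error(compute_cohort_maf(too_many, 1),
               class = "vepbench_data_error")
})

test_that("rarity filter requires strict rarity in both cohort and reference", {
  sites <- data.frame(
    variant_id = paste0("r", 1:4),
    cohort_maf = c(0.001, 5e-4, 0, 5e-4),
    reference_maf = c(0, 0.002, 0, NA), stringsAsFactors = FALSE)
  out <- filter_rare(sites, qc_thresholds())
  expect_equal(out$variant_id, c("r3", "r4"))
})

test_that("QC and rarity filters commute and are monotone in thresholds", {
  for (s in 1:5) {
    toy <- random_qc_toy(30, seed = 100 + s)
    th <- qc_thresholds()
    a <- filter_rare(apply_qc(toy$sites, toy$calls, th)$sites, th)
    rb <- filter_rare(toy$sites, th)
    b <- apply_qc(rb, toy$calls[toy$calls$variant_id %in% rb$variant_id, ],
                  th)$sites
    expect_setequal(a$variant_id, b$variant_id)

    base_n <- nrow(apply_qc(toy$sites, toy$calls, th)$sites)
    relaxed <- list(qc_thresholds(min_quality = 10),
                    qc_thresholds(max_missingness = 0.5),
                    qc_thresholds(min_depth = 2),
                    qc_thresholds(min_allele_balance = 0.01))
    for (r in relaxed) {
      expect_gte(nrow(apply_qc(toy$sites, toy$calls, r)$sites), base_n)
    }
  }
})

test_that("passing sets match the per-rule brute-force oracle on random toys", {
  for (s in 1:8) {
    toy <- random_qc_toy(40, seed = 200 + s)
    for (profile in c("discovery", "validation")) {
      th <- qc_thresholds(profile)
      got <- filter_rare(apply_qc(toy$sites, toy$calls, th)$sites, th)
      want <- toy$sites$variant_id[oracle_qc_pass(toy$sites, toy$calls,
                                                  th) &
                                     oracle_rare_pass(toy$sites, th)]
      expect_setequal(got$variant_id, want)
    }
  }
})
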