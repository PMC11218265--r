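# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written as a naive, direct evaluation of the rule it
# checks, sharing no code with the implementation under test.

# Per-site QC evaluation, one rule at a time.
oracle_qc_pass <- function(sites, calls, th) {
  vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    if (is.na(s$site_quality) || s$site_quality <= th$min_quality) {
      return(FALSE)
    }
    if (is.na(s$call_missingness) ||
        s$call_missingness >= th$max_missingness) {
      return(FALSE)
    }
    cc <- calls[calls$variant_id == s$variant_id & calls$dosage >= 1, ,
                drop = FALSE]
    found <- FALSE
    for (j in seq_len(nrow(cc))) {
      depth_ok <- is.na(cc$depth[j]) || cc$depth[j] >= th$min_depth
      ab_ok <- cc$dosage[j] == 2 || is.na(cc$allele_balance[j]) ||
        cc$allele_balance[j] >= th$min_allele_balance
      if (depth_ok && ab_ok) found <- TRUE
    }
    found
  }, logical(1))
}

oracle_rare_pass <- function(sites, th) {
  vapply(seq_len(nrow(sites)), function(i) {
    ref <- sites$reference_maf[i]
    if (is.na(ref)) ref <- 0
    sites$cohort_maf[i] < th$maf_cutoff && ref < th$maf_cutoff
  }, logical(1))
}

# Exact two-tailed signed-rank p by full enumeration of sign patterns.
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(grid %*% r)
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# Kendall tau-b by explicit pair loops and the tie-corrected denominator.
oracle_kendall_taub <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1
    if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    tt <- table(v)
    sum(tt * (tt - 1) / 2)
  }
  (conc - disc) / sqrt((n0 - tie_term(x)) * (n0 - tie_term(y)))
}

# Build an evaluation set with an equal number of positives and negatives
# realizing the given TPR/FPR, and return its raw precision.
oracle_balanced_precision <- function(tpr, fpr, half = 1000) {
  tp <- round(tpr * half)
  fp <- round(fpr * half)
  labels <- c(rep(1, half), rep(0, half))
  predicted <- c(rep(1, tp), rep(0, half - tp),
                 rep(1, fp), rep(0, half - fp))
  sum(predicted == 1 & labels == 1) / sum(predicted == 1)
}

# Small random QC toy generator for property tests.
random_qc_toy <- function(n_sites, seed, n_participants = 500) {
  withr::with_seed(seed, {
    sites <- data.frame(
      variant_id = sprintf("rv%03d", seq_len(n_sites)),
      gene_id = "g1", chrom = "1", pos = seq_len(n_sites),
      ref = "A", alt = "C",
      site_quality = runif(n_sites, 10, 40),
      call_missingness = runif(n_sites, 0, 0.2),
      reference_maf = sample(c(0, 5e-4, 2e-3, NA), n_sites, TRUE),
      stringsAsFactors = FALSE)
    calls <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      data.frame(participant_id = sprintf("P%03d",
                                          sample(n_participants, k)),
                 variant_id = sites$variant_id[i],
                 dosage = sample(1:2, k, TRUE, prob = c(0.9, 0.1)),
                 depth = sample(4:30, k, TRUE),
                 allele_balance = round(runif(k, 0.05, 0.9), 3),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(calls)) {
      calls <- data.frame(participant_id = character(0),
                          variant_id = character(0), dosage = integer(0),
                          depth = integer(0), allele_balance = numeric(0))
    }
    maf <- compute_cohort_maf(calls, n_participants)
    sites <- merge(sites, maf, by = "variant_id", all.x = TRUE)
    sites$cohort_maf[is.na(sites$cohort_maf)] <- 0
    list(sites = sites, calls = calls, n_participants = n_participants)
  })
}

# The five-predictor panel of the recovery study: three fidelity levels,
# a sign-flipped copy of the best, and a 60%-missing copy of the best.
recovery_panel <- function() {
  list(predictor_fidelity("hi", 0.1),
       predictor_fidelity("mid", 0.5),
       predictor_fidelity("lo", 2.0),
       predictor_fidelity("flip", orientation = "low_is_damaging",
                          copy_of = "hi"),
       predictor_fidelity("sparse", missingness = 0.6, copy_of = "hi"))
}

recovery_sim <- function(seed) {
  sim_config(n_participants = 2000, n_genes = 2, n_quant_traits = 0,
             n_binary_traits = 3, predictor_specs = recovery_panel(),
             seed = seed)
}

# Small binary combo: 30 carriers of one gene, labels from the phenotype
# table, two predictors with configurable score tables.
make_binary_combo <- function(seed = 1, predictors = c("p1", "p2"),
                              identical_pair = FALSE) {
  withr::with_seed(seed, {
    n <- 30
    sites <- data.frame(variant_id = sprintf("v%02d", 1:12),
                        gene_id = "g1", stringsAsFactors = FALSE)
    calls <- data.frame(participant_id = sprintf("P%02d", 1:n),
                        variant_id = sample(sites$variant_id, n, TRUE),
                        dosage = 1L, stringsAsFactors = FALSE)
    ph <- data.frame(participant_id = sprintf("P%02d", 1:n),
                     trait_id = "b", trait_kind = "binary",
                     value = rbinom(n, 1, 0.4), stringsAsFactors = FALSE)
    scores <- do.call(rbind, lapply(seq_along(predictors), function(k) {
      data.frame(predictor_id = predictors[k],
                 variant_id = sites$variant_id,
                 score = rnorm(12),
                 stringsAsFactors = FALSE)
    }))
    if (identical_pair) {
      scores$score[scores$predictor_id == predictors[2]] <-
        scores$score[scores$predictor_id == predictors[1]]
    }
    build_combo_data("g1", "b", "binary", sites, calls, ph, scores,
                     min_predictions = 10)
  })
}
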