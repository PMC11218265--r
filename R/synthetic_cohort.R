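# Synthetic cohort simulator: rare missense variants with additive effects on
# a quantitative trait and a liability-threshold binary trait, plus a panel of
# predictors whose scores are noisy monotone transforms of the true effect
# magnitudes. Gives every downstream stage a fully specified, seedable input.

#' Describe the fidelity of one synthetic predictor
#'
#' Each synthetic predictor emits, per variant, `|beta| + N(0, noise_sd^2)`,
#' negated when its orientation is `low_is_damaging`, with a configurable
#' fraction of variants left unscored. `copy_of` reuses the realized raw
#' scores of an earlier predictor in the panel before applying this spec's
#' orientation and missingness — useful for building an exactly sign-flipped
#' or down-sampled twin of an existing predictor.
#'
#' @param predictor_id character label.
#' @param noise_sd non-negative score noise standard deviation.
#' @param orientation `"high_is_damaging"` or `"low_is_damaging"`.
#' @param missingness fraction of variants left unscored, in `[0, 1)`.
#' @param copy_of optional id of an earlier predictor whose realized raw
#'   scores are reused.
#' @return A `predictor_fidelity` list.
#' @export
predictor_fidelity <- function(predictor_id, noise_sd = 0,
                               orientation = c("high_is_damaging",
                                               "low_is_damaging"),
                               missingness = 0, copy_of = NULL) {
  orientation <- match.arg(orientation)
  vb_check(is.character(predictor_id) && length(predictor_id) == 1 &&
             nzchar(predictor_id), "predictor_id must be a non-empty string")
  vb_check(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd >= 0,
           "noise_sd must be a single non-negative number",
           "vepbench_config_error")
  vb_check(is.numeric(missingness) && length(missingness) == 1 &&
             missingness >= 0 && missingness < 1,
           "missingness must lie in [0, 1)", "vepbench_config_error")
  structure(list(predictor_id = predictor_id, noise_sd = noise_sd,
                 orientation = orientation, missingness = missingness,
                 copy_of = copy_of),
            class = "predictor_fidelity")
}

default_predictor_panel <- function() {
  list(predictor_fidelity("pred_hi",  noise_sd = 0.1),
       predictor_fidelity("pred_mid", noise_sd = 0.5),
       predictor_fidelity("pred_lo",  noise_sd = 2.0))
}

#' Configuration of a synthetic cohort
#'
#' Defaults define the simulator's reference conditions: rare variants
#' (MAF below 0.1% in cohort and reference by construction), exponential
#' effect magnitudes on the scale of one trait standard deviation, a
#' common binary trait (30% prevalence, as for medication use or a
#' prevalent condition) under a liability threshold, and per-gene carrier
#' mass such that roughly 1-2% of a gene's carriers hold multiple
#' variants.
#'
#' @param n_participants,n_genes,variants_per_gene cohort dimensions.
#' @param maf_range two allele frequencies, both below 0.001; per-variant
#'   minor allele frequencies are drawn log-uniformly between them.
#' @param null_fraction proportion of variants with effect exactly zero.
#' @param effect_scale mean of the exponential distribution of nonzero
#'   effect magnitudes (trait units per allele).
#' @param trait_noise_sd residual standard deviation of quantitative traits.
#' @param prevalence expected binary-trait prevalence in `(0, 1)`.
#' @param n_quant_traits,n_binary_traits number of traits of each kind.
#' @param effect_sign `"positive"` (all damaging effects increase the trait,
#'   as for burden-ascertained gene-trait pairs), `"gene"` (one random sign
#'   per gene), or `"variant"` (independent random signs).
#' @param predictor_specs list of [predictor_fidelity()] entries.
#' @param seed integer root seed; every simulation stage derives its own
#'   stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 2000, n_genes = 2,
                       variants_per_gene = 60,
                       maf_range = c(2e-4, 9e-4),
                       null_fraction = 0.3, effect_scale = 1,
                       trait_noise_sd = 1, prevalence = 0.3,
                       n_quant_traits = 1, n_binary_traits = 1,
                       effect_sign = c("positive", "gene", "variant"),
                       predictor_specs = default_predictor_panel(),
                       seed = 1L) {
  effect_sign <- match.arg(effect_sign)
  chk <- function(ok, field) {
    if (!isTRUE(ok)) {
      vb_error(sprintf("invalid simulation config: field '%s'", field),
               "vepbench_config_error")
    }
  }
  chk(is.numeric(n_participants) && n_participants >= 1, "n_participants")
  chk(is.numeric(n_genes) && n_genes >= 1, "n_genes")
  chk(is.numeric(variants_per_gene) && variants_per_gene >= 1,
      "variants_per_gene")
  chk(is.numeric(maf_range) && length(maf_range) == 2 &&
        all(maf_range > 0) && maf_range[1] <= maf_range[2] &&
        maf_range[2] < 0.001, "maf_range")
  chk(is.numeric(null_fraction) && null_fraction >= 0 && null_fraction <= 1,
      "null_fraction")
  chk(is.numeric(effect_scale) && effect_scale > 0, "effect_scale")
  chk(is.numeric(trait_noise_sd) && trait_noise_sd >= 0, "trait_noise_sd")
  chk(is.numeric(prevalence) && prevalence > 0 && prevalence < 1,
      "prevalence")
  chk(is.numeric(n_quant_traits) && n_quant_traits >= 0, "n_quant_traits")
  chk(is.numeric(n_binary_traits) && n_binary_traits >= 0, "n_binary_traits")
  chk(is.list(predictor_specs) &&
        all(vapply(predictor_specs, inherits, logical(1),
                   "predictor_fidelity")), "predictor_specs")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed")
  structure(list(
    n_participants = as.integer(n_participants),
    n_genes = as.integer(n_genes),
    variants_per_gene = as.integer(variants_per_gene),
    maf_range = as.numeric(maf_range),
    null_fraction = null_fraction, effect_scale = effect_scale,
    trait_noise_sd = trait_noise_sd, prevalence = prevalence,
    n_quant_traits = as.integer(n_quant_traits),
    n_binary_traits = as.integer(n_binary_traits),
    effect_sign = effect_sign,
    predictor_specs = predictor_specs,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a rare-variant catalogue with ground-truth effects
#'
#' Each variant gets a gene label, position, ref/alt alleles, a minor allele
#' frequency drawn log-uniformly from `config$maf_range`, and a true effect
#' beta: exactly `round(null_fraction * n)` variants have beta 0, the rest
#' have magnitudes drawn from an exponential with mean `effect_scale` and a
#' sign governed by `config$effect_sign`. The simulated MAF doubles as the
#' reference-panel (gnomAD-like) frequency.
#'
#' @param config a [sim_config()].
#' @param seed optional seed override (defaults to a stream derived from
#'   `config$seed`).
#' @return `list(variants = <data.frame>, effects = <data.frame>)` where
#'   `variants` has columns variant_id, gene_id, chrom, pos, ref, alt, maf,
#'   reference_maf and `effects` has variant_id, beta.
#' @export
simulate_variants <- function(config, seed = NULL) {
  vb_check(inherits(config, "sim_config"), "config must be a sim_config",
           "vepbench_config_error")
  if (is.null(seed)) seed <- derive_seed(config$seed, "variants")
  n_var <- config$n_genes * config$variants_per_gene
  with_seed(seed, {
    gene_idx <- rep(seq_len(config$n_genes), each = config$variants_per_gene)
    gene_id <- sprintf("gene%02d", gene_idx)
    within <- stats::ave(seq_len(n_var), gene_idx, FUN = seq_along)
    variant_id <- sprintf("%s_v%03d", gene_id, within)
    pos <- as.integer(gene_idx * 1000000L + within * 100L)
    nt <- c("A", "C", "G", "T")
    ref <- sample(nt, n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
    lo <- log(config$maf_range[1]); hi <- log(config$maf_range[2])
    maf <- exp(stats::runif(n_var, lo, hi))
    n_null <- round(config$null_fraction * n_var)
    null_idx <- sample.int(n_var, n_null)
    beta <- stats::rexp(n_var, rate = 1 / config$effect_scale)
    sgn <- switch(config$effect_sign,
      positive = rep(1, n_var),
      gene = rep(sample(c(-1, 1), config$n_genes, replace = TRUE),
                 each = config$variants_per_gene),
      variant = sample(c(-1, 1), n_var, replace = TRUE))
    beta <- beta * sgn
    beta[null_idx] <- 0
    list(
      variants = data.frame(variant_id = variant_id, gene_id = gene_id,
                            chrom = "1", pos = pos, ref = ref, alt = unname(alt),
                            maf = maf, reference_maf = maf,
                            stringsAsFactors = FALSE),
      effects = data.frame(variant_id = variant_id, beta = beta,
                           stringsAsFactors = FALSE))
  })
}

#' Simulate sparse genotype calls with per-call QC fields
#'
#' Per participant and variant, dosage is binomial with two trials at the
#' variant's MAF; only carrier calls (dosage >= 1) are materialized. Each
#' carrier call receives a read depth (Poisson) and an allele balance
#' realized as alt reads over depth (binomial at 0.5 for heterozygotes,
#' all-alt for homozygotes), and each site receives a Phred site quality and
#' a call-missingness proportion, so fixtures can exercise the QC filters.
#'
#' @param variants variant catalogue from [simulate_variants()].
#' @param n_participants cohort size.
#' @param seed integer seed.
#' @param depth_lambda mean sequencing depth.
#' @param site_quality_range uniform range of site Phred scores.
#' @param missingness_range uniform range of per-site call missingness.
#' @return `list(calls, site_qc)`: `calls` is the sparse carrier matrix in
#'   long form (participant_id, variant_id, dosage, depth, alt_reads,
#'   allele_balance); `site_qc` has variant_id, site_quality,
#'   call_missingness.
#' @export
simulate_genotypes <- function(variants, n_participants, seed,
                               depth_lambda = 30,
                               site_quality_range = c(30, 60),
                               missingness_range = c(0, 0.05)) {
  vb_check(is.numeric(n_participants) && n_participants >= 1,
           "n_participants must be >= 1", "vepbench_config_error")
  vb_check(all(variants$maf > 0 & variants$maf < 0.5) ||
             all(variants$maf >= 0 & variants$maf < 0.5),
           "variant MAFs must lie in [0, 0.5)", "vepbench_config_error")
  n_participants <- as.integer(n_participants)
  pid <- sprintf("P%06d", seq_len(n_participants))
  with_seed(seed, {
    res <- vector("list", nrow(variants))
    for (i in seq_len(nrow(variants))) {
      d <- stats::rbinom(n_participants, 2L, variants$maf[i])
      idx <- which(d > 0L)
      if (length(idx) == 0L) next
      depth <- pmax(1L, stats::rpois(length(idx), depth_lambda))
      alt <- ifelse(d[idx] == 2L, depth,
                    stats::rbinom(length(idx), depth, 0.5))
      res[[i]] <- data.frame(participant_id = pid[idx],
                             variant_id = variants$variant_id[i],
                             dosage = d[idx], depth = depth,
                             alt_reads = as.integer(alt),
                             allele_balance = alt / depth,
                             stringsAsFactors = FALSE)
    }
    site_qc <- data.frame(
      variant_id = variants$variant_id,
      site_quality = stats::runif(nrow(variants), site_quality_range[1],
                                  site_quality_range[2]),
      call_missingness = stats::runif(nrow(variants), missingness_range[1],
                                      missingness_range[2]),
      stringsAsFactors = FALSE)
    res <- res[!vapply(res, is.null, logical(1))]
    calls <- if (length(res)) do.call(rbind, res) else
      data.frame(participant_id = character(0), variant_id = character(0),
                 dosage = integer(0), depth = integer(0),
                 alt_reads = integer(0), allele_balance = numeric(0),
                 stringsAsFactors = FALSE)
    rownames(calls) <- NULL
    list(calls = calls, site_qc = site_qc,
         participant_ids = pid)
  })
}

#' Simulate quantitative and liability-threshold binary traits
#'
#' The quantitative trait is `y_p = sum_v dosage * beta_v + e_p` with
#' `e ~ N(0, trait_noise_sd^2)`. Each binary trait thresholds an independent
#' liability of the same form with unit-variance noise at
#' `qnorm(1 - prevalence)`; rare-variant genetic variance is negligible, so
#' realized prevalence matches the target in expectation.
#'
#' @param genotypes result of [simulate_genotypes()] (or a compatible list
#'   with `calls` and `participant_ids`).
#' @param effects data.frame (variant_id, beta).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return Long phenotype data.frame (participant_id, trait_id, trait_kind,
#'   value) covering every participant and trait.
#' @export
simulate_traits <- function(genotypes, effects, config, seed) {
  calls <- genotypes$calls
  pid <- genotypes$participant_ids
  missing_eff <- setdiff(unique(calls$variant_id), effects$variant_id)
  if (length(missing_eff)) {
    vb_error(sprintf("no effect defined for carried variant(s): %s",
                     paste(utils::head(missing_eff, 3), collapse = ", ")),
             "vepbench_data_error")
  }
  beta <- stats::setNames(effects$beta, effects$variant_id)
  g <- stats::setNames(numeric(length(pid)), pid)
  if (nrow(calls)) {
    contrib <- calls$dosage * beta[calls$variant_id]
    agg <- tapply(contrib, calls$participant_id, sum)
    g[names(agg)] <- agg
  }
  n <- length(pid)
  with_seed(seed, {
    out <- list()
    for (k in seq_len(config$n_quant_traits)) {
      y <- g + stats::rnorm(n, 0, config$trait_noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, trait_id = sprintf("qt%d", k),
        trait_kind = "quantitative", value = unname(y),
        stringsAsFactors = FALSE)
    }
    thr <- stats::qnorm(1 - config$prevalence)
    for (k in seq_len(config$n_binary_traits)) {
      liab <- g + stats::rnorm(n, 0, 1)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = pid, trait_id = sprintf("bt%d", k),
        trait_kind = "binary", value = as.numeric(liab > thr),
        stringsAsFactors = FALSE)
    }
    if (!length(out)) {
      return(data.frame(participant_id = character(0), trait_id = character(0),
                        trait_kind = character(0), value = numeric(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
  })
}

#' Simulate predictor score tables
#'
#' Raw score of variant v under spec k is `|beta_v| + N(0, noise_sd_k^2)`;
#' scores are negated before emission when the spec's orientation is
#' `low_is_damaging`, and a `missingness` fraction of variants is dropped
#' uniformly at random. Specs with `copy_of` reuse the realized raw scores
#' of the named earlier predictor.
#'
#' @param effects data.frame (variant_id, beta).
#' @param specs list of [predictor_fidelity()] entries.
#' @param seed integer seed.
#' @return `list(scores, meta)`: `scores` is long (predictor_id, variant_id,
#'   score); `meta` maps predictor_id to orientation.
#' @export
simulate_predictor_scores <- function(effects, specs, seed) {
  vb_check(length(specs) > 0, "predictor specs must be non-empty",
           "vepbench_config_error")
  n <- nrow(effects)
  with_seed(seed, {
    raw_store <- list()
    rows <- list()
    for (sp in specs) {
      if (!is.null(sp$copy_of)) {
        vb_check(sp$copy_of %in% names(raw_store),
                 sprintf("copy_of '%s' must name an earlier predictor",
                         sp$copy_of), "vepbench_config_error")
        raw <- raw_store[[sp$copy_of]]
      } else {
        raw <- abs(effects$beta) + stats::rnorm(n, 0, sp$noise_sd)
      }
      raw_store[[sp$predictor_id]] <- raw
      emitted <- if (sp$orientation == "low_is_damaging") -raw else raw
      keep <- stats::runif(n) >= sp$missingness
      rows[[sp$predictor_id]] <- data.frame(
        predictor_id = sp$predictor_id,
        variant_id = effects$variant_id[keep],
        score = emitted[keep], stringsAsFactors = FALSE)
    }
    meta <- data.frame(
      predictor_id = vapply(specs, `[[`, character(1), "predictor_id"),
      orientation = vapply(specs, `[[`, character(1), "orientation"),
      stringsAsFactors = FALSE)
    list(scores = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         meta = meta)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs variant, genotype, trait and predictor-score simulation from one
#' root seed and assembles the gene-trait combination list (every gene
#' crossed with every trait).
#'
#' @param config a [sim_config()].
#' @return A `synthetic_cohort` list with elements config, variants,
#'   effects, calls, site_qc, participant_ids, phenotypes, scores, meta,
#'   combos.
#' @export
simulate_cohort <- function(config) {
  vb_check(inherits(config, "sim_config"), "config must be a sim_config",
           "vepbench_config_error")
  vr <- simulate_variants(config)
  gt <- simulate_genotypes(vr$variants, config$n_participants,
                           derive_seed(config$seed, "genotypes"))
  ph <- simulate_traits(gt, vr$effects, config,
                        derive_seed(config$seed, "traits"))
  sc <- simulate_predictor_scores(vr$effects, config$predictor_specs,
                                  derive_seed(config$seed, "scores"))
  traits <- unique(ph[, c("trait_id", "trait_kind")])
  combos <- if (nrow(traits)) {
    merge(data.frame(gene_id = unique(vr$variants$gene_id),
                     stringsAsFactors = FALSE),
          traits, by = NULL)
  } else {
    data.frame(gene_id = character(0), trait_id = character(0),
               trait_kind = character(0), stringsAsFactors = FALSE)
  }
  combos <- combos[order(combos$gene_id, combos$trait_id), , drop = FALSE]
  rownames(combos) <- NULL
  structure(list(config = config, variants = vr$variants,
                 effects = vr$effects, calls = gt$calls,
                 site_qc = gt$site_qc, participant_ids = gt$participant_ids,
                 phenotypes = ph, scores = sc$scores, meta = sc$meta,
                 combos = combos),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort as fixture files in standard formats
#'
#' Emits a VCF v4.2 (one record per variant, sorted by chrom/pos; QUAL holds
#' the site Phred score; INFO carries GENE and GNOMAD_AF; per-sample
#' GT:DP:AD), a phenotype TSV, a long score TSV with a predictor metadata
#' TSV, the gene-trait combination list, and truth tables (beta, fidelity
#' ordering) for test assertions. Site call-missingness is realized by
#' masking a rounded fraction of non-carrier genotypes as `./.`; carrier
#' genotypes are never masked, so the carrier matrix round-trips exactly.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named character vector of written file paths.
#' @export
write_cohort_fixture <- function(cohort, dir) {
  vb_check(inherits(cohort, "synthetic_cohort"),
           "cohort must come from simulate_cohort()")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    vb_error(sprintf("cannot write to directory '%s'", dir),
             "vepbench_io_error")
  }
  v <- cohort$variants[order(cohort$variants$chrom, cohort$variants$pos), ,
                       drop = FALSE]
  qc <- cohort$site_qc[match(v$variant_id, cohort$site_qc$variant_id), ]
  pid <- cohort$participant_ids
  n <- length(pid)

  calls <- cohort$calls
  call_key <- split(seq_len(nrow(calls)), calls$variant_id)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=vepbench-synthetic-cohort",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene label\">",
    paste0("##INFO=<ID=GNOMAD_AF,Number=1,Type=Float,",
           "Description=\"Reference panel allele frequency\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pid), collapse = "\t"))

  filler_dp <- 30L
  recs <- character(nrow(v))
  mask_seed <- derive_seed(cohort$config$seed, "fixture-missingness")
  with_seed(mask_seed, {
    for (i in seq_len(nrow(v))) {
      samp <- rep(sprintf("0/0:%d:%d,0", filler_dp, filler_dp), n)
      rows <- call_key[[v$variant_id[i]]]
      carrier_pos <- integer(0)
      if (!is.null(rows)) {
        cr <- calls[rows, ]
        carrier_pos <- match(cr$participant_id, pid)
        gtst <- ifelse(cr$dosage == 2L, "1/1", "0/1")
        samp[carrier_pos] <- sprintf("%s:%d:%d,%d", gtst, cr$depth,
                                     cr$depth - cr$alt_reads, cr$alt_reads)
      }
      n_miss <- round(qc$call_missingness[i] * n)
      pool <- setdiff(seq_len(n), carrier_pos)
      n_miss <- min(n_miss, length(pool))
      if (n_miss > 0) {
        miss_idx <- sample(pool, n_miss)
        samp[miss_idx] <- "./.:.:."
      }
      info <- sprintf("GENE=%s;GNOMAD_AF=%s", v$gene_id[i],
                      vb_format_num(v$reference_maf[i]))
      recs[i] <- paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i],
                         v$alt[i], vb_format_num(qc$site_quality[i]), "PASS",
                         info, "GT:DP:AD", samp), collapse = "\t")
    }
  })
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    scores = file.path(dir, "scores.tsv"),
    predictors = file.path(dir, "predictors.tsv"),
    combos = file.path(dir, "combos.tsv"),
    truth_effects = file.path(dir, "truth_effects.tsv"),
    truth_predictors = file.path(dir, "truth_predictors.tsv"))
  writeLines(c(header, recs), paths[["vcf"]])
  vb_write_tsv(cohort$phenotypes[, c("participant_id", "trait_id", "value")],
               paths[["phenotypes"]])
  vb_write_tsv(cohort$scores, paths[["scores"]])
  vb_write_tsv(cohort$meta, paths[["predictors"]])
  vb_write_tsv(cohort$combos, paths[["combos"]])
  vb_write_tsv(cohort$effects, paths[["truth_effects"]])
  specs <- cohort$config$predictor_specs
  vb_write_tsv(data.frame(
    predictor_id = vapply(specs, `[[`, character(1), "predictor_id"),
    noise_sd = vapply(specs, `[[`, numeric(1), "noise_sd"),
    orientation = vapply(specs, `[[`, character(1), "orientation"),
    missingness = vapply(specs, `[[`, numeric(1), "missingness"),
    copy_of = vapply(specs, function(s)
      if (is.null(s$copy_of)) NA_character_ else s$copy_of, character(1)),
    stringsAsFactors = FALSE), paths[["truth_predictors"]])
  invisible(paths)
}
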