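# Orchestration: simulate (or load) -> qc -> prepare -> benchmark -> rank
# -> report, under one root seed, with per-stage bookkeeping and
# deterministic result files.

#' Pipeline run configuration
#'
#' @param simulation a [sim_config()] for a synthetic run, or NULL when
#'   reading files.
#' @param vcf,phenotypes,scores,predictors,combos input file paths (used
#'   when `simulation` is NULL): a VCF, a phenotype TSV (participant_id,
#'   trait_id, value), a long score TSV, a predictor metadata TSV, and a
#'   gene-trait combination TSV (gene_id, trait_id, trait_kind).
#' @param thresholds a [qc_thresholds()]; pick
#'   `qc_thresholds("validation")` for the 0.20 allele-balance profile.
#' @param iterations,seed bootstrap plan.
#' @param fdr tie-calling / significance FDR threshold.
#' @param min_predictions per-gene predictor coverage rule.
#' @param min_trait_count sparse-trait exclusion rule.
#' @param include_noncarriers see [build_combo_data()].
#' @param out_dir output directory, or NULL to skip writing files.
#' @param verbose emit progress messages.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, vcf = NULL, phenotypes = NULL,
                       scores = NULL, predictors = NULL, combos = NULL,
                       thresholds = qc_thresholds(),
                       iterations = 10000, seed = 1L, fdr = 0.10,
                       min_predictions = 10, min_trait_count = 10,
                       include_noncarriers = FALSE,
                       out_dir = NULL, verbose = TRUE) {
  vb_check(fdr > 0 && fdr < 1, "fdr must lie in (0, 1)",
           "vepbench_config_error")
  if (is.null(simulation)) {
    for (pth in c(vcf, phenotypes, scores, predictors, combos)) {
      vb_check(!is.null(pth) && file.exists(pth),
               sprintf("input path missing or nonexistent: %s",
                       if (is.null(pth)) "<NULL>" else pth),
               "vepbench_config_error")
    }
  } else {
    vb_check(inherits(simulation, "sim_config"),
             "simulation must be a sim_config", "vepbench_config_error")
  }
  structure(list(simulation = simulation, vcf = vcf,
                 phenotypes = phenotypes, scores = scores,
                 predictors = predictors, combos = combos,
                 thresholds = thresholds,
                 plan = bootstrap_plan(iterations, seed), fdr = fdr,
                 min_predictions = min_predictions,
                 min_trait_count = min_trait_count,
                 include_noncarriers = include_noncarriers,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

config_digest <- function(config) {
  hash_string(paste(deparse(config[setdiff(names(config), "out_dir")]),
                    collapse = ""))
}

#' Run the full benchmarking pipeline
#'
#' Executes simulate/load, QC, score preparation, paired bootstrap
#' benchmarking, per-combo tie-calling, and the overall ranking, writing
#' result TSVs, a report and a JSON manifest when `out_dir` is set. All
#' randomness derives from the single seed in the bootstrap plan plus the
#' simulation seed, so a rerun with the same config is byte-identical on
#' every result file (the manifest additionally records wall-clock times).
#'
#' @param config a [run_config()].
#' @return A `pipeline_result` list: qc (sites, calls), combos (with
#'   retention flags), summaries, pairwise, combo_rankings, counts,
#'   overall_matrix, ranking, manifest.
#' @export
run_pipeline <- function(config) {
  vb_check(inherits(config, "run_config"),
           "config must come from run_config()", "vepbench_config_error")
  old_opt <- options(vepbench.verbose = isTRUE(config$verbose))
  on.exit(options(old_opt), add = TRUE)
  stages <- list()
  tick <- function(name, n_in, n_out) {
    stages[[name]] <<- list(records_in = n_in, records_out = n_out,
                            records_dropped = n_in - n_out,
                            seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  t0 <- proc.time()[["elapsed"]]

  # --- stage 1: input -------------------------------------------------
  if (!is.null(config$simulation)) {
    dat <- cohort_input(simulate_cohort(config$simulation))
  } else {
    gt <- read_genotypes(config$vcf, "vcf")
    ph <- vb_read_tsv(config$phenotypes)
    combos <- vb_read_tsv(config$combos)
    kinds <- unique(combos[, c("trait_id", "trait_kind")])
    ph <- merge(ph, kinds, by = "trait_id", all.x = TRUE)
    dat <- list(sites = gt$sites, calls = gt$calls,
                phenotypes = ph[, c("participant_id", "trait_id",
                                    "trait_kind", "value")],
                scores = vb_read_tsv(config$scores),
                meta = vb_read_tsv(config$predictors), combos = combos,
                n_participants = gt$n_participants)
  }
  tick("input", nrow(dat$sites), nrow(dat$sites))

  result <- pipeline_core(dat, config, tick)

  # --- manifest + outputs ---------------------------------------------
  manifest <- list(
    package = "vepbench",
    version = as.character(utils::packageVersion("vepbench")),
    config_digest = config_digest(config),
    seed = config$plan$seed,
    iterations = config$plan$iterations,
    stages = stages)
  result$manifest <- manifest
  class(result) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_results(result, config$out_dir)
  result
}

# Assemble the pipeline input list from a synthetic cohort.
cohort_input <- function(cohort) {
  list(sites = merge(cohort$variants, cohort$site_qc, by = "variant_id",
                     sort = TRUE),
       calls = cohort$calls, phenotypes = cohort$phenotypes,
       scores = cohort$scores, meta = cohort$meta, combos = cohort$combos,
       n_participants = length(cohort$participant_ids))
}

#' Benchmark an in-memory synthetic cohort
#'
#' Runs the QC, preparation, bootstrap and ranking stages of the pipeline
#' on a cohort from [simulate_cohort()], optionally with replacement
#' orientation metadata — e.g. to study the effect of a wrong orientation
#' flag on the final ranking.
#'
#' @param cohort a `synthetic_cohort`.
#' @param config a [run_config()] (its `simulation`/file fields are
#'   ignored; thresholds, plan and rule parameters apply).
#' @param meta optional predictor metadata data.frame overriding
#'   `cohort$meta`.
#' @return A `pipeline_result` (without manifest timings of stage 1).
#' @export
benchmark_cohort <- function(cohort, config, meta = NULL) {
  vb_check(inherits(cohort, "synthetic_cohort"),
           "cohort must come from simulate_cohort()")
  old_opt <- options(vepbench.verbose = isTRUE(config$verbose))
  on.exit(options(old_opt), add = TRUE)
  dat <- cohort_input(cohort)
  if (!is.null(meta)) dat$meta <- meta
  result <- pipeline_core(dat, config, function(...) NULL)
  class(result) <- "pipeline_result"
  result$manifest <- list(seed = config$plan$seed,
                          iterations = config$plan$iterations)
  result
}

# Stages 2-5 (qc -> prepare -> benchmark -> rank) on an assembled input
# list; `tick` records per-stage bookkeeping.
pipeline_core <- function(dat, config, tick) {
  sites <- dat$sites; calls <- dat$calls; phenotypes <- dat$phenotypes
  scores_raw <- dat$scores; meta <- dat$meta; combos <- dat$combos
  n_participants <- dat$n_participants

  # --- stage 2: qc ----------------------------------------------------
  qc <- apply_qc(sites, calls, config$thresholds)
  maf <- compute_cohort_maf(qc$calls, n_participants)
  qc_sites <- merge(qc$sites, maf, by = "variant_id", all.x = TRUE)
  qc_sites$cohort_maf[is.na(qc_sites$cohort_maf)] <- 0
  rare_sites <- filter_rare(qc_sites, config$thresholds)
  rare_calls <- qc$calls[qc$calls$variant_id %in% rare_sites$variant_id, ,
                         drop = FALSE]
  tick("qc", nrow(sites), nrow(rare_sites))

  # --- stage 3: prepare -----------------------------------------------
  oriented <- orient_scores(scores_raw, meta)
  oriented <- oriented[oriented$variant_id %in% rare_sites$variant_id, ,
                       drop = FALSE]
  combos_checked <- exclude_sparse_traits(combos, phenotypes, rare_calls,
                                          rare_sites,
                                          config$min_trait_count)
  retained <- combos_checked[combos_checked$retained, , drop = FALSE]
  for (i in which(!combos_checked$retained)) {
    vb_log(sprintf("combo %s|%s excluded: %s", combos_checked$gene_id[i],
                   combos_checked$trait_id[i], combos_checked$reason[i]))
  }
  tick("prepare", nrow(combos), nrow(retained))

  # --- stage 4: benchmark ---------------------------------------------
  predictors <- sort(unique(meta$predictor_id))
  boots <- list()
  pairwise <- list()
  summaries <- list()
  coverage <- list()
  for (i in seq_len(nrow(retained))) {
    cd <- build_combo_data(retained$gene_id[i], retained$trait_id[i],
                           retained$trait_kind[i], rare_sites, rare_calls,
                           phenotypes, oriented,
                           config$min_predictions, predictors,
                           config$include_noncarriers)
    if (is.null(cd)) next
    bt <- bootstrap_performance(cd, config$plan)
    boots[[cd$combo_id]] <- bt
    cov <- cd$coverage
    cov$combo_id <- cd$combo_id
    coverage[[cd$combo_id]] <- cov
    sm <- bt$summary
    sm$combo_id <- cd$combo_id
    sm$metric <- bt$metric
    summaries[[cd$combo_id]] <- sm
    pairwise[[cd$combo_id]] <- combo_pairwise_pvalues(bt)
  }
  summaries <- if (length(summaries)) {
    do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  } else {
    data.frame(predictor_id = character(0), mean = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               n_retained = integer(0), n_dropped = integer(0),
               unreliable = logical(0), combo_id = character(0),
               metric = character(0), stringsAsFactors = FALSE)
  }
  pairwise <- if (length(pairwise)) {
    do.call(rbind, c(pairwise, list(make.row.names = FALSE)))
  } else {
    data.frame(combo_id = character(0), predictor_a = character(0),
               predictor_b = character(0), p = numeric(0),
               stringsAsFactors = FALSE)
  }
  # one pooled q-value family across all per-combo pairwise comparisons
  pairwise$q <- if (nrow(pairwise)) storey_qvalues(pairwise$p) else
    numeric(0)
  pairwise$significant <- pairwise$q < config$fdr
  tick("benchmark", nrow(retained), length(boots))

  # --- stage 5: rank --------------------------------------------------
  rankings <- lapply(names(boots), function(cid) {
    rank_combo(boots[[cid]]$summary[, c("predictor_id", "mean")],
               pairwise[pairwise$combo_id == cid, , drop = FALSE],
               config$fdr, combo_id = cid)
  })
  result <- list(config = config,
                 qc = list(sites = rare_sites, calls = rare_calls,
                           drops = qc$drops),
                 combos = combos_checked,
                 coverage = if (length(coverage))
                   do.call(rbind, c(coverage, list(make.row.names = FALSE)))
                 else NULL,
                 summaries = summaries, pairwise = pairwise,
                 combo_rankings = rankings)
  if (length(boots)) {
    counts <- count_best_or_tied(rankings, predictors)
    if (length(predictors) >= 2) {
      mat <- overall_pairwise_matrix(
        summaries[, c("combo_id", "predictor_id", "mean")], config$fdr)
      final <- final_ranking(counts, mat)
    } else {
      mat <- NULL
      final <- data.frame(predictor_id = predictors,
                          n_best_or_tied = counts$n_best_or_tied,
                          wins = 0L, lower_q_count = 0L, final_rank = 1L,
                          shared_rank = FALSE, stringsAsFactors = FALSE)
    }
    result$counts <- counts
    result$overall_matrix <- mat
    result$ranking <- final
  } else {
    vb_log("no gene-trait combination survived exclusions; empty results")
    result$counts <- NULL
    result$overall_matrix <- NULL
    result$ranking <- NULL
  }
  tick("rank", length(boots), length(boots))
  result
}

write_results <- function(result, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok) vb_error(sprintf("cannot create '%s'", dir), "vepbench_io_error")
  vb_write_tsv(result$qc$sites, file.path(dir, "qc_sites.tsv"))
  vb_write_tsv(result$combos, file.path(dir, "combos.tsv"))
  vb_write_tsv(result$summaries, file.path(dir, "combo_summary.tsv"))
  vb_write_tsv(result$pairwise, file.path(dir, "pairwise.tsv"))
  cr <- do.call(rbind, c(lapply(result$combo_rankings, function(r) {
    data.frame(combo_id = r$combo_id, top = r$top,
               tied_set = paste(r$tied, collapse = ","),
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  if (is.null(cr)) {
    cr <- data.frame(combo_id = character(0), top = character(0),
                     tied_set = character(0), stringsAsFactors = FALSE)
  }
  vb_write_tsv(cr, file.path(dir, "combo_rankings.tsv"))
  if (!is.null(result$overall_matrix)) {
    vb_write_tsv(result$overall_matrix,
                 file.path(dir, "overall_matrix.tsv"))
  }
  if (!is.null(result$ranking)) {
    vb_write_tsv(result$ranking, file.path(dir, "overall_ranking.tsv"))
  }
  writeLines(render_report(result), file.path(dir, "report.txt"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Render a human-readable summary report
#'
#' Per-combo tables of bootstrap means with 95% CIs and tied-set markers,
#' the overall best-or-tied counts with final ranks, and the pairwise
#' significance grid. Missing sections (e.g. when every combo was
#' excluded) are reported as explicit gaps.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @return character vector of report lines.
#' @export
render_report <- function(result) {
  lines <- c("vepbench benchmarking report",
             paste0("seed: ", result$manifest$seed,
                    "  iterations: ", result$manifest$iterations), "")
  if (!nrow(result$summaries)) {
    return(c(lines, "No gene-trait combination produced results."))
  }
  for (r in result$combo_rankings) {
    cid <- r$combo_id
    sm <- result$summaries[result$summaries$combo_id == cid, ,
                           drop = FALSE]
    sm <- sm[order(-sm$mean), , drop = FALSE]
    lines <- c(lines, sprintf("== %s (%s) ==", cid, sm$metric[1]))
    for (i in seq_len(nrow(sm))) {
      marker <- if (sm$predictor_id[i] %in% r$tied) " *tied-for-best*"
        else ""
      lines <- c(lines, sprintf(
        "  %-16s mean %.4f  [%.4f, %.4f]  (dropped %d)%s",
        sm$predictor_id[i], sm$mean[i], sm$ci_low[i], sm$ci_high[i],
        sm$n_dropped[i], marker))
    }
    lines <- c(lines, "")
  }
  if (!is.null(result$ranking)) {
    lines <- c(lines, "== overall ranking ==")
    rk <- result$ranking
    for (i in seq_len(nrow(rk))) {
      lines <- c(lines, sprintf(
        "  rank %2d%s  %-16s best-or-tied %d  wins %d",
        rk$final_rank[i], if (rk$shared_rank[i]) "=" else " ",
        rk$predictor_id[i], rk$n_best_or_tied[i], rk$wins[i]))
    }
  } else {
    lines <- c(lines, "Overall ranking unavailable.")
  }
  if (!is.null(result$overall_matrix)) {
    lines <- c(lines, "", "== pairwise significance (overall) ==")
    mt <- result$overall_matrix
    for (i in seq_len(nrow(mt))) {
      arrow <- if (!isTRUE(mt$significant[i])) "~"
        else if (mt$direction[i] == mt$predictor_a[i]) ">" else "<"
      lines <- c(lines, sprintf("  %-16s %s %-16s  p=%.4g q=%.4g",
                                mt$predictor_a[i], arrow,
                                mt$predictor_b[i], mt$p[i], mt$q[i]))
    }
  }
  lines
}

#' Print a pipeline result as its rendered report
#'
#' @param x a `pipeline_result`.
#' @param ... ignored.
#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat(paste(render_report(x), collapse = "\n"), "\n")
  invisible(x)
}
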