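# Predictor score preparation: orientation to a common "high = damaging"
# convention, the per-gene coverage rule, 5th/95th-percentile winsorized
# normalization, participant-centric additive aggregation, and the
# variant-mean trait table used for quantitative combos.

#' Orient predictor scores so that high means damaging
#'
#' Scores of predictors flagged `low_is_damaging` are negated; the output is
#' uniformly `high_is_damaging`. Orienting an already-oriented table with
#' updated metadata is the identity.
#'
#' @param scores long data.frame (predictor_id, variant_id, score).
#' @param meta data.frame (predictor_id, orientation).
#' @return `scores` with all predictors on the high-is-damaging scale.
#' @export
orient_scores <- function(scores, meta) {
  missing <- setdiff(unique(scores$predictor_id), meta$predictor_id)
  if (length(missing)) {
    vb_error(sprintf("no orientation metadata for predictor(s): %s",
                     paste(missing, collapse = ", ")),
             "vepbench_config_error")
  }
  ori <- stats::setNames(meta$orientation, meta$predictor_id)
  flip <- ori[scores$predictor_id] == "low_is_damaging"
  out <- scores
  out$score <- ifelse(flip, -scores$score, scores$score)
  out
}

#' Check per-gene predictor coverage
#'
#' A predictor takes part in comparisons for a gene only when it scores at
#' least `min_predictions` of the gene's (post-QC, rare) variants.
#'
#' @param scores long oriented score data.frame.
#' @param gene_variants character vector of the gene's variant ids.
#' @param min_predictions inclusive minimum number of scored variants.
#' @param predictors optional predictor id universe (defaults to those in
#'   `scores`).
#' @return data.frame (predictor_id, n_scored, included).
#' @export
check_coverage <- function(scores, gene_variants, min_predictions = 10,
                           predictors = NULL) {
  if (is.null(predictors)) predictors <- unique(scores$predictor_id)
  sub <- scores[scores$variant_id %in% gene_variants, , drop = FALSE]
  n_scored <- vapply(predictors, function(p)
    length(unique(sub$variant_id[sub$predictor_id == p])), integer(1))
  data.frame(predictor_id = predictors, n_scored = unname(n_scored),
             included = unname(n_scored) >= min_predictions,
             stringsAsFactors = FALSE)
}

#' Winsorize and normalize one gene's scores to [0, 1]
#'
#' Floors and ceilings the oriented score set at its 5th and 95th
#' percentiles (linear-interpolation percentiles, quantile type 7), then
#' maps affinely to `[0, 1]`: 0 is most neutral, 1 most damaging. When the
#' two percentiles coincide (e.g. all scores identical) the scale is
#' degenerate: the default raises a classed error; `on_degenerate =
#' "midpoint"` instead maps every variant to 0.5 with a warning.
#'
#' @param x named numeric vector of oriented scores (names = variant ids).
#' @param probs the floor/ceiling percentile pair.
#' @param on_degenerate `"error"` or `"midpoint"`.
#' @return `list(values, floor, ceiling)` with `values` in `[0, 1]`.
#' @export
winsorize_normalize <- function(x, probs = c(0.05, 0.95),
                                on_degenerate = c("error", "midpoint")) {
  on_degenerate <- match.arg(on_degenerate)
  vb_check(length(x) >= 1 && all(is.finite(x)),
           "scores must be a non-empty finite vector")
  qs <- stats::quantile(x, probs = probs, type = 7, names = FALSE)
  f <- qs[1]; cl <- qs[2]
  if (cl <= f) {
    if (on_degenerate == "error") {
      vb_error("degenerate score scale: floor and ceiling coincide",
               "vepbench_degenerate_scale")
    }
    warning("degenerate score scale; mapping all variants to 0.5",
            call. = FALSE)
    vals <- rep(0.5, length(x)); names(vals) <- names(x)
    return(list(values = vals, floor = f, ceiling = cl))
  }
  vals <- (pmin(pmax(x, f), cl) - f) / (cl - f)
  list(values = vals, floor = f, ceiling = cl)
}

#' Aggregate normalized scores into participant-centric values
#'
#' Under the additive model a participant's score for a gene is the sum,
#' over carried scored variants, of dosage times normalized score — e.g.
#' two heterozygous variants each normalized to 0.5 aggregate to 1.
#' Participants carrying no scored variant in the gene are absent from the
#' result.
#'
#' @param calls long carrier-call data.frame (participant_id, variant_id,
#'   dosage), restricted upstream to the gene's post-QC rare variants.
#' @param norm_values named numeric vector of normalized scores (names =
#'   variant ids; unscored variants simply absent).
#' @return data.frame (participant_id, score).
#' @export
aggregate_participant_scores <- function(calls, norm_values) {
  sub <- calls[calls$variant_id %in% names(norm_values), , drop = FALSE]
  if (!nrow(sub)) {
    return(data.frame(participant_id = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  contrib <- sub$dosage * norm_values[sub$variant_id]
  agg <- tapply(contrib, sub$participant_id, sum)
  data.frame(participant_id = names(agg), score = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Variant-level mean trait values
#'
#' For a quantitative trait, averages the trait values of each variant's
#' carriers (one value per carrier, regardless of dosage); carriers without
#' a measurement are excluded and variants with no measured carrier are
#' omitted.
#'
#' @param calls long carrier-call data.frame.
#' @param phenotypes long phenotype data.frame (participant_id, trait_id,
#'   value).
#' @param trait_id the quantitative trait to average.
#' @return data.frame (variant_id, mean_value, n_carriers).
#' @export
variant_mean_traits <- function(calls, phenotypes, trait_id) {
  ph <- phenotypes[phenotypes$trait_id == trait_id &
                     !is.na(phenotypes$value), , drop = FALSE]
  y <- stats::setNames(ph$value, ph$participant_id)
  sub <- calls[calls$participant_id %in% names(y), , drop = FALSE]
  if (!nrow(sub)) {
    return(data.frame(variant_id = character(0), mean_value = numeric(0),
                      n_carriers = integer(0), stringsAsFactors = FALSE))
  }
  vals <- y[sub$participant_id]
  mv <- tapply(vals, sub$variant_id, mean)
  nc <- tapply(vals, sub$variant_id, length)
  data.frame(variant_id = names(mv), mean_value = as.numeric(mv),
             n_carriers = as.integer(nc), stringsAsFactors = FALSE)
}

#' Drop gene-trait combinations with too few phenotyped carriers
#'
#' A binary combination is retained when at least `min_count` carriers in
#' the gene's evaluation set have the trait; a quantitative combination
#' when at least `min_count` trait measurements exist among carriers.
#'
#' @param combos data.frame (gene_id, trait_id, trait_kind).
#' @param phenotypes long phenotype data.frame.
#' @param calls post-QC carrier-call data.frame.
#' @param sites post-QC rare site data.frame (variant_id, gene_id).
#' @param min_count inclusive minimum count.
#' @return `combos` with added logical `retained` and character `reason`.
#' @export
exclude_sparse_traits <- function(combos, phenotypes, calls, sites,
                                  min_count = 10) {
  out <- combos
  out$retained <- FALSE
  out$reason <- ""
  for (i in seq_len(nrow(combos))) {
    gvars <- sites$variant_id[sites$gene_id == combos$gene_id[i]]
    carriers <- unique(calls$participant_id[calls$variant_id %in% gvars])
    ph <- phenotypes[phenotypes$trait_id == combos$trait_id[i] &
                       phenotypes$participant_id %in% carriers &
                       !is.na(phenotypes$value), , drop = FALSE]
    if (combos$trait_kind[i] == "binary") {
      n <- sum(ph$value == 1)
      ok <- n >= min_count
      out$reason[i] <- if (ok) "" else
        sprintf("only %d affected carriers (< %d)", n, min_count)
    } else {
      n <- nrow(ph)
      ok <- n >= min_count
      out$reason[i] <- if (ok) "" else
        sprintf("only %d trait measurements among carriers (< %d)",
                n, min_count)
    }
    out$retained[i] <- ok
  }
  out
}
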