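# Statistical machinery: paired bootstrap of participants (shared resample
# indices across predictors within a combo-iteration), empirical pairwise
# p-values, Storey q-values, the exact/approximate Wilcoxon signed-rank
# test, and Kendall tau-b.

#' Bootstrap plan
#'
#' @param iterations number of bootstrap iterations (default 10000).
#' @param seed integer root seed; each combo derives its own stream from it.
#' @return A `bootstrap_plan` list.
#' @export
bootstrap_plan <- function(iterations = 10000, seed = 1L) {
  vb_check(is.numeric(iterations) && iterations >= 1,
           "iterations must be >= 1", "vepbench_config_error")
  structure(list(iterations = as.integer(iterations),
                 seed = as.integer(seed)), class = "bootstrap_plan")
}

#' Assemble the evaluation data for one gene-trait combination
#'
#' The evaluation set is the set of participants carrying at least one
#' post-QC rare variant in the gene (optionally all phenotyped participants
#' when `include_noncarriers = TRUE`, non-carriers entering at aggregated
#' score 0). For binary traits, per-predictor participant scores are built
#' by winsorized normalization of the gene's oriented scores followed by
#' additive aggregation; carriers whose carried variants a predictor did
#' not score receive 0 for that predictor. For quantitative traits the
#' combo keeps the carrier-variant incidence, the carriers' trait values,
#' and each predictor's oriented raw scores over the gene's variants.
#'
#' @param gene_id,trait_id,trait_kind the combination.
#' @param sites post-QC rare site data.frame.
#' @param calls post-QC carrier-call data.frame.
#' @param phenotypes long phenotype data.frame.
#' @param scores oriented long score data.frame.
#' @param min_predictions per-gene coverage rule (see [check_coverage()]).
#' @param predictors optional predictor universe.
#' @param include_noncarriers include phenotyped non-carriers at score 0
#'   (binary traits only).
#' @return A `combo_data` list, or NULL (with a logged reason) when no
#'   predictor meets the coverage rule or the evaluation set is unusable.
#' @export
build_combo_data <- function(gene_id, trait_id, trait_kind, sites, calls,
                             phenotypes, scores, min_predictions = 10,
                             predictors = NULL,
                             include_noncarriers = FALSE) {
  gvars <- sites$variant_id[sites$gene_id == gene_id]
  cov <- check_coverage(scores, gvars, min_predictions, predictors)
  included <- cov$predictor_id[cov$included]
  combo_id <- paste(gene_id, trait_id, sep = "|")
  if (!length(included)) {
    vb_log(sprintf("combo %s skipped: no predictor scores >= %d of %d variants",
                   combo_id, min_predictions, length(gvars)))
    return(NULL)
  }
  gcalls <- calls[calls$variant_id %in% gvars, , drop = FALSE]
  ph <- phenotypes[phenotypes$trait_id == trait_id &
                     !is.na(phenotypes$value), , drop = FALSE]
  y_all <- stats::setNames(ph$value, ph$participant_id)
  carriers <- sort(unique(gcalls$participant_id))
  eval_ids <- intersect(carriers, names(y_all))
  if (include_noncarriers && trait_kind == "binary") {
    eval_ids <- sort(unique(c(eval_ids, names(y_all))))
  }
  if (length(eval_ids) < 2) {
    vb_log(sprintf("combo %s skipped: evaluation set too small", combo_id))
    return(NULL)
  }
  gscores <- scores[scores$variant_id %in% gvars &
                      scores$predictor_id %in% included, , drop = FALSE]
  out <- list(combo_id = combo_id, gene_id = gene_id, trait_id = trait_id,
              trait_kind = trait_kind, predictors = included,
              coverage = cov, eval_ids = eval_ids)
  if (trait_kind == "binary") {
    labels <- as.numeric(y_all[eval_ids])
    score_mat <- matrix(0, length(eval_ids), length(included),
                        dimnames = list(eval_ids, included))
    for (p in included) {
      ps <- gscores[gscores$predictor_id == p, , drop = FALSE]
      x <- stats::setNames(ps$score, ps$variant_id)
      norm <- winsorize_normalize(x, on_degenerate = "midpoint")
      agg <- aggregate_participant_scores(gcalls, norm$values)
      hit <- agg$participant_id %in% eval_ids
      score_mat[agg$participant_id[hit], p] <- agg$score[hit]
    }
    out$labels <- labels
    out$score_matrix <- score_mat
  } else {
    y <- as.numeric(y_all[eval_ids])
    sub <- gcalls[gcalls$participant_id %in% eval_ids, , drop = FALSE]
    vids <- sort(unique(sub$variant_id))
    inc <- Matrix::sparseMatrix(
      i = match(sub$variant_id, vids),
      j = match(sub$participant_id, eval_ids),
      x = 1, dims = c(length(vids), length(eval_ids)),
      dimnames = list(vids, eval_ids))
    # collapse duplicate (variant, participant) rows if any
    inc@x[inc@x > 1] <- 1
    var_scores <- lapply(included, function(p) {
      ps <- gscores[gscores$predictor_id == p, , drop = FALSE]
      stats::setNames(ps$score, ps$variant_id)
    })
    names(var_scores) <- included
    out$trait_values <- y
    out$incidence <- inc
    out$variant_scores <- var_scores
  }
  structure(out, class = "combo_data")
}

#' Paired bootstrap of per-combination performance
#'
#' Resamples the combo's evaluation set with replacement, applying the same
#' resample indices to every included predictor in each iteration. Binary
#' combos recompute participant scores/labels and the AUBPRC; quantitative
#' combos recompute variant-mean trait values on the resample and then
#' PCC^2 (squaring per iteration). Iterations where the metric is undefined
#' for any included predictor are dropped combo-wide so pairing is
#' preserved; combos losing more than half their iterations are flagged
#' unreliable.
#'
#' @param cd a `combo_data` from [build_combo_data()].
#' @param plan a [bootstrap_plan()].
#' @return list with `summary` (data.frame: predictor_id, mean, ci_low,
#'   ci_high, n_retained, n_dropped, unreliable), `values` (retained
#'   iterations x predictors matrix), `metric`, `combo_id`.
#' @export
bootstrap_performance <- function(cd, plan = bootstrap_plan()) {
  vb_check(inherits(cd, "combo_data"), "cd must come from build_combo_data()")
  it <- plan$iterations
  m <- length(cd$eval_ids)
  seed <- derive_seed(plan$seed, cd$combo_id)
  idx <- with_seed(seed,
                   matrix(sample.int(m, m * it, replace = TRUE), m, it))
  preds <- cd$predictors
  vals <- matrix(NA_real_, it, length(preds),
                 dimnames = list(NULL, preds))
  if (cd$trait_kind == "binary") {
    sm <- cd$score_matrix
    lab <- cd$labels
    for (i in seq_len(it)) {
      ii <- idx[, i]
      li <- lab[ii]
      for (k in seq_along(preds)) {
        vals[i, k] <- aubprc(sm[ii, k], li)
      }
    }
    metric <- "AUBPRC"
  } else {
    inc <- cd$incidence
    y <- cd$trait_values
    # multiplicity of each participant per iteration
    w <- matrix(0, m, it)
    for (i in seq_len(it)) {
      tb <- tabulate(idx[, i], nbins = m)
      w[, i] <- tb
    }
    num <- as.matrix(inc %*% (w * y))
    den <- as.matrix(inc %*% w)
    means <- num / den        # NaN where a variant has no resampled carrier
    means[den == 0] <- NA_real_
    for (k in seq_along(preds)) {
      vs <- cd$variant_scores[[preds[k]]]
      rows <- intersect(rownames(means), names(vs))
      if (length(rows) < 3) next
      vals[, k] <- colwise_pcc2(as.numeric(vs[rows]),
                                means[rows, , drop = FALSE])
    }
    metric <- "PCC2"
  }
  ok <- rowSums(is.na(vals)) == 0
  retained <- vals[ok, , drop = FALSE]
  n_drop <- it - nrow(retained)
  unreliable <- n_drop > it / 2
  if (unreliable) {
    vb_log(sprintf("combo %s: %d/%d bootstrap iterations dropped; flagged unreliable",
                   cd$combo_id, n_drop, it))
  }
  summ <- data.frame(
    predictor_id = preds,
    mean = if (nrow(retained)) colMeans(retained) else NA_real_,
    ci_low = if (nrow(retained))
      apply(retained, 2, stats::quantile, 0.025, type = 7) else NA_real_,
    ci_high = if (nrow(retained))
      apply(retained, 2, stats::quantile, 0.975, type = 7) else NA_real_,
    n_retained = nrow(retained), n_dropped = n_drop,
    unreliable = unreliable, stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(summary = summ, values = retained, metric = metric,
       combo_id = cd$combo_id)
}

#' Empirical pairwise p-value from paired bootstrap distributions
#'
#' The fraction of retained paired iterations in which predictor `a` does
#' not exceed predictor `b`: `sum((a - b) <= 0) / iterations`. Ties count in
#' the numerator, so `p(a, a) = 1`.
#'
#' @param dist_a,dist_b paired numeric vectors of equal length.
#' @return fraction in `[0, 1]`.
#' @export
empirical_pvalue <- function(dist_a, dist_b) {
  if (length(dist_a) != length(dist_b)) {
    vb_error("paired distributions must have equal length",
             "vepbench_pairing_error")
  }
  vb_check(length(dist_a) > 0, "distributions must be non-empty")
  mean((dist_a - dist_b) <= 0)
}

#' Estimate the null proportion pi0 by the smoother method
#'
#' Evaluates `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` on the grid
#' `lambda = 0.05, 0.10, ..., 0.95`, fits a df-3 cubic smoothing spline,
#' takes its value at the largest lambda, and clips to `(0, 1]`.
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param lambda evaluation grid.
#' @return pi0 estimate in `(0, 1]`.
#' @export
estimate_pi0 <- function(pvalues, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(pvalues)
  pl <- vapply(lambda, function(l) sum(pvalues > l) / (m * (1 - l)),
               numeric(1))
  fit <- stats::smooth.spline(lambda, pl, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(1, max(pi0, .Machine$double.eps))
}

#' Storey q-values
#'
#' For families of at least `min_family_size` p-values, pi0 is estimated by
#' the smoother method ([estimate_pi0()]); smaller families fix pi0 at 1,
#' reducing the q-value to the Benjamini-Hochberg step-up adjustment.
#' `q(p_(k)) = min over j >= k of pi0 * m * p_(j) / j`, returned in input
#' order and capped at 1.
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param pi0 optional fixed pi0 override.
#' @param min_family_size minimum family size for pi0 estimation.
#' @return q-values in input order.
#' @export
storey_qvalues <- function(pvalues, pi0 = NULL, min_family_size = 100) {
  vb_check(all(is.finite(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
           "p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  if (is.null(pi0)) {
    pi0 <- if (m < min_family_size) 1 else estimate_pi0(pvalues)
  }
  o <- order(pvalues, decreasing = TRUE)
  q <- pi0 * m * pvalues[o] / (m:1)
  q <- pmin(1, cummin(q))
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact null distribution of the signed-rank statistic over all sign
# assignments, via convolution on doubled (hence integer) midranks.
signed_rank_exact_p <- function(r2, w2) {
  s <- sum(r2)
  cnt <- numeric(s + 1)
  cnt[1] <- 1
  for (rj in r2) {
    shifted <- c(numeric(rj), cnt[seq_len(s + 1 - rj)])
    cnt <- cnt + shifted
  }
  mu <- s / 2
  dev <- abs(w2 - mu)
  support <- 0:s
  sum(cnt[abs(support - mu) >= dev - 1e-9]) / sum(cnt)
}

#' Two-tailed Wilcoxon signed-rank test
#'
#' Zero differences are dropped before midranking `|x - y|`. With at most
#' 25 nonzero pairs the two-tailed p-value comes from the exact null
#' distribution over all sign assignments (computed by convolution, exact
#' under ties via doubled midranks); above that, a normal approximation
#' with tie-corrected variance and continuity correction is used. All
#' differences zero yields the degenerate p = 1 with a warning.
#'
#' @param x,y paired numeric vectors.
#' @param exact_limit maximum nonzero-pair count for the exact path.
#' @return list with statistic (W, sum of positive-difference ranks),
#'   p_value, n_nonzero, method.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25) {
  vb_check(length(x) == length(y) && length(x) >= 1,
           "x and y must be non-empty and of equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; degenerate p = 1",
            call. = FALSE)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    p <- signed_rank_exact_p(r2, 2 * w)
    return(list(statistic = w, p_value = min(1, p), n_nonzero = n,
                method = "exact"))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(statistic = w, p_value = p, n_nonzero = n, method = "normal")
}

kendall_counts <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  prod <- dx[up] * dy[up]
  list(C = sum(prod == 1), D = sum(prod == -1), n = n,
       tx = as.numeric(table(x)), ty = as.numeric(table(y)))
}

kendall_taub_stat <- function(x, y) {
  kc <- kendall_counts(x, y)
  n0 <- kc$n * (kc$n - 1) / 2
  n1 <- sum(kc$tx * (kc$tx - 1) / 2)
  n2 <- sum(kc$ty * (kc$ty - 1) / 2)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) {
    vb_error("Kendall tau undefined: an input is constant",
             "vepbench_validation_error")
  }
  (kc$C - kc$D) / den
}

all_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- all_permutations(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

#' Kendall rank correlation tau-b with significance
#'
#' Tie-corrected tau-b. For 8 or fewer items the two-sided p-value is exact
#' by enumeration of all permutations of one ranking; above that, the
#' normal approximation with the full tie-corrected variance is used.
#'
#' @param x,y numeric vectors (ranks or scores) over the same item set;
#'   ties allowed.
#' @param exact_limit maximum item count for permutation enumeration.
#' @return list with tau, p_value, n, method.
#' @export
kendall_tau <- function(x, y, exact_limit = 8) {
  vb_check(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  if (n < 2) {
    vb_error("Kendall tau requires at least 2 items",
             "vepbench_validation_error")
  }
  tau <- kendall_taub_stat(x, y)
  if (n <= exact_limit) {
    perms <- all_permutations(seq_len(n))
    taus <- vapply(perms, function(pm) kendall_taub_stat(x, y[pm]),
                   numeric(1))
    p <- mean(abs(taus) >= abs(tau) - 1e-12)
    return(list(tau = tau, p_value = p, n = n, method = "exact"))
  }
  kc <- kendall_counts(x, y)
  s <- kc$C - kc$D
  tx <- kc$tx; ty <- kc$ty
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  vars <- (v0 - vt - vu) / 18 + v1 + v2
  z <- s / sqrt(vars)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(tau = tau, p_value = p, n = n, method = "normal")
}
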