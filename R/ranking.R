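# Turning bootstrap distributions and pairwise results into per-combination
# winners/tied sets, overall best-or-tied counts, the pairwise Wilcoxon
# significance matrix, the final tie-broken ranking, and cross-cohort
# agreement.

#' Pairwise empirical p-values within one combo
#'
#' For every unordered predictor pair, orients the pair so that `a` is the
#' predictor with the higher bootstrap mean (lexicographic on exact mean
#' ties) and computes the empirical p-value of `a` being outperformed by
#' `b` over the retained paired iterations.
#'
#' @param boot result of [bootstrap_performance()].
#' @return data.frame (combo_id, predictor_a, predictor_b, p).
#' @export
combo_pairwise_pvalues <- function(boot) {
  preds <- boot$summary$predictor_id
  means <- stats::setNames(boot$summary$mean, preds)
  if (length(preds) < 2) {
    return(data.frame(combo_id = character(0), predictor_a = character(0),
                      predictor_b = character(0), p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(preds, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    if (means[b] > means[a] ||
        (means[b] == means[a] && b < a)) {
      tmp <- a; a <- b; b <- tmp
    }
    data.frame(combo_id = boot$combo_id, predictor_a = a, predictor_b = b,
               p = empirical_pvalue(boot$values[, a], boot$values[, b]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Rank predictors within one combo and call ties with the top
#'
#' Orders predictors by bootstrap mean (descending; exact ties broken
#' lexicographically for a stable top). The tied set is the top predictor
#' plus every predictor whose comparison against the top has `q >= fdr`.
#'
#' @param means data.frame (predictor_id, mean) for the combo's included
#'   predictors.
#' @param pairwise data.frame (predictor_a, predictor_b, p, q) for the
#'   combo, `predictor_a` being the better-by-mean of each pair.
#' @param fdr tie-calling FDR threshold.
#' @param combo_id combo label carried into the result.
#' @return A `combo_ranking` list (combo_id, order, top, tied).
#' @export
rank_combo <- function(means, pairwise, fdr = 0.10,
                       combo_id = NA_character_) {
  vb_check(nrow(means) >= 1, "at least one predictor required")
  ord <- means$predictor_id[order(-means$mean, means$predictor_id)]
  top <- ord[1]
  vs_top <- pairwise[pairwise$predictor_a == top |
                       pairwise$predictor_b == top, , drop = FALSE]
  tied <- top
  if (nrow(vs_top)) {
    other <- ifelse(vs_top$predictor_a == top, vs_top$predictor_b,
                    vs_top$predictor_a)
    tied <- c(top, other[vs_top$q >= fdr])
  }
  structure(list(combo_id = combo_id, order = ord, top = top,
                 tied = unique(tied)), class = "combo_ranking")
}

#' Count combos where each predictor is best or tied for best
#'
#' @param rankings list of `combo_ranking` objects.
#' @param predictors predictor universe (rows of the output).
#' @return data.frame (predictor_id, n_best_or_tied).
#' @export
count_best_or_tied <- function(rankings, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- sort(unique(unlist(lapply(rankings, `[[`, "order"))))
  }
  cnt <- vapply(predictors, function(p)
    sum(vapply(rankings, function(r) p %in% r$tied, logical(1))),
    integer(1))
  data.frame(predictor_id = predictors, n_best_or_tied = unname(cnt),
             stringsAsFactors = FALSE)
}

#' Overall pairwise Wilcoxon signed-rank matrix
#'
#' For each unordered predictor pair, pairs the per-combo mean performance
#' values over the combos where both predictors participated and applies
#' the two-tailed Wilcoxon signed-rank test; q-values are computed over the
#' whole matrix family. Direction is the predictor with the larger paired
#' mean tendency (sign of the mean paired difference). Pairs sharing fewer
#' than two combos are marked incomparable (NA p).
#'
#' @param combo_means data.frame (combo_id, predictor_id, mean).
#' @param fdr significance threshold on q.
#' @return data.frame (predictor_a, predictor_b, n_combos, p, q,
#'   significant, direction); one row per unordered pair,
#'   `predictor_a < predictor_b` lexicographically.
#' @export
overall_pairwise_matrix <- function(combo_means, fdr = 0.10) {
  preds <- sort(unique(combo_means$predictor_id))
  vb_check(length(preds) >= 2, "need at least two predictors")
  pairs <- utils::combn(preds, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    ma <- combo_means[combo_means$predictor_id == a, c("combo_id", "mean")]
    mb <- combo_means[combo_means$predictor_id == b, c("combo_id", "mean")]
    shared <- merge(ma, mb, by = "combo_id", suffixes = c("_a", "_b"))
    n <- nrow(shared)
    if (n < 2) {
      return(data.frame(predictor_a = a, predictor_b = b, n_combos = n,
                        p = NA_real_, direction = NA_character_,
                        stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(
      wilcoxon_signed_rank(shared$mean_a, shared$mean_b))
    md <- mean(shared$mean_a - shared$mean_b)
    dir <- if (md > 0) a else if (md < 0) b else NA_character_
    data.frame(predictor_a = a, predictor_b = b, n_combos = n,
               p = wt$p_value, direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- storey_qvalues(out$p[ok])
  out$significant <- !is.na(out$q) & out$q < fdr & !is.na(out$direction)
  out
}

matrix_lookup <- function(matrix_df, a, b) {
  i <- (matrix_df$predictor_a == a & matrix_df$predictor_b == b) |
    (matrix_df$predictor_a == b & matrix_df$predictor_b == a)
  if (!any(i)) return(list(q = NA_real_, direction = NA_character_))
  j <- which(i)[1]
  list(q = matrix_df$q[j], direction = matrix_df$direction[j])
}

#' Final tie-broken overall ranking
#'
#' Sorts predictors by best-or-tied count (descending). Count ties are
#' broken first by the number of other predictors each one statistically
#' outperforms in the overall matrix (significant q below the threshold
#' with favorable direction), then by head-to-head comparison of q-value
#' rows within the remaining tie group: for tied a and b, count rivals r
#' with `q(a, r) < q(b, r)` among comparisons whose direction favors a —
#' a q-value only measures how clearly two predictors differ, so it is
#' credited as merit only when the difference runs the predictor's way
#' (Copeland-style within the group). Residual full ties share a rank.
#'
#' @param counts data.frame from [count_best_or_tied()].
#' @param matrix_df data.frame from [overall_pairwise_matrix()].
#' @return data.frame (predictor_id, n_best_or_tied, wins, lower_q_count,
#'   final_rank, shared_rank) ordered by final rank.
#' @export
final_ranking <- function(counts, matrix_df) {
  preds <- counts$predictor_id
  vb_check(all(unique(c(matrix_df$predictor_a, matrix_df$predictor_b)) %in%
                 preds),
           "matrix and counts must cover the same predictor set")
  wins <- vapply(preds, function(p) {
    sum(matrix_df$significant & matrix_df$direction == p, na.rm = TRUE)
  }, integer(1))
  df <- data.frame(predictor_id = preds,
                   n_best_or_tied = counts$n_best_or_tied,
                   wins = unname(wins), lower_q_count = 0L,
                   stringsAsFactors = FALSE)
  # head-to-head q-row comparison within groups tied on (count, wins)
  key <- paste(df$n_best_or_tied, df$wins)
  for (g in unique(key)) {
    members <- df$predictor_id[key == g]
    if (length(members) < 2) next
    beat <- stats::setNames(integer(length(members)), members)
    score_vs <- function(a, b) {
      rivals <- setdiff(preds, c(a, b))
      sum(vapply(rivals, function(r) {
        la <- matrix_lookup(matrix_df, a, r)
        lb <- matrix_lookup(matrix_df, b, r)
        !is.na(la$q) && !is.na(lb$q) && identical(la$direction, a) &&
          la$q < lb$q
      }, logical(1)))
    }
    for (a in members) for (b in members) {
      if (a == b) next
      if (score_vs(a, b) > score_vs(b, a)) beat[a] <- beat[a] + 1L
    }
    df$lower_q_count[match(members, df$predictor_id)] <- unname(beat)
  }
  o <- order(-df$n_best_or_tied, -df$wins, -df$lower_q_count,
             df$predictor_id)
  df <- df[o, , drop = FALSE]
  tie_key <- paste(df$n_best_or_tied, df$wins, df$lower_q_count)
  rank_vec <- integer(nrow(df))
  shared <- logical(nrow(df))
  pos <- 1L
  i <- 1L
  while (i <= nrow(df)) {
    # contiguous run of equal keys starting at i
    j <- i
    while (j < nrow(df) && tie_key[j + 1] == tie_key[i]) j <- j + 1L
    rank_vec[i:j] <- pos
    shared[i:j] <- (j > i)
    pos <- pos + (j - i + 1L)
    i <- j + 1L
  }
  df$final_rank <- rank_vec
  df$shared_rank <- shared
  rownames(df) <- NULL
  df
}

#' Cross-cohort ranking agreement
#'
#' Kendall tau-b (with its p-value) between two final rankings, restricted
#' to their shared predictor set.
#'
#' @param ranking_1,ranking_2 data.frames from [final_ranking()].
#' @return list with tau, p_value, n_shared.
#' @export
cross_cohort_agreement <- function(ranking_1, ranking_2) {
  shared <- intersect(ranking_1$predictor_id, ranking_2$predictor_id)
  if (length(shared) < 2) {
    vb_error("rankings share fewer than 2 predictors",
             "vepbench_validation_error")
  }
  r1 <- ranking_1$final_rank[match(shared, ranking_1$predictor_id)]
  r2 <- ranking_2$final_rank[match(shared, ranking_2$predictor_id)]
  kt <- kendall_tau(r1, r2, exact_limit = min(8, length(shared)))
  list(tau = kt$tau, p_value = kt$p_value, n_shared = length(shared))
}
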