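test_that("per-combo ranking calls ties against the top predictor only", {
  single <- rank_combo(data.frame(predictor_id = "a", mean = 0.7),
                       data.frame(predictor_a = character(0),
                                  predictor_b = character(0),
                                  p = numeric(0), q = numeric(0)),
                       combo_id = "c1")
  expect_equal(single$top, "a")
  expect_equal(single$tied, "a")

  # identical bootstrap distributions force p = 1, hence a tie
  cd <- make_binary_combo(seed = 6, identical_pair = TRUE)
  bt <- bootstrap_performance(cd, bootstrap_plan(200, seed = 1))
  pw <- combo_pairwise_pvalues(bt)
  expect_equal(pw$p, 1)
  pw$q <- storey_qvalues(pw$p)
  rc <- rank_combo(bt$summary[, c("predictor_id", "mean")], pw,
                   combo_id = bt$combo_id)
  expect_setequal(rc$tied, c("p1", "p2"))

  means <- data.frame(predictor_id = c("a", "b", "c"),
                      mean = c(0.9, 0.85, 0.2))
  pairwise <- data.frame(predictor_a = c("a", "a", "b"),
                         predictor_b = c("b", "c", "c"),
                         p = c(0.4, 0.001, 0.002),
                         q = c(0.5, 0.01, 0.01))
  rc3 <- rank_combo(means, pairwise)
  expect_equal(rc3$order, c("a", "b", "c"))
  expect_setequal(rc3$tied, c("a", "b"))
})

test_that("best-or-tied counts tally tied-set membership per combo", {
  mk <- function(id, ord, tied) structure(
    list(combo_id = id, order = ord, top = ord[1], tied = tied),
    class = "combo_ranking")
  rks <- list(mk("c1", c("a", "b", "c"), c("a", "b")),
              mk("c2", c("b", "a", "c"), "b"),
              mk("c3", c("c", "a"), c("c", "a")))   # b excluded from c3
  cnt <- count_best_or_tied(rks, c("a", "b", "c"))
  expect_equal(cnt$n_best_or_tied[cnt$predictor_id == "a"], 2)
  expect_equal(cnt$n_best_or_tied[cnt$predictor_id == "b"], 2)
  expect_equal(cnt$n_best_or_tied[cnt$predictor_id == "c"], 1)
  # every combo contributes at least its top
  expect_gte(sum(cnt$n_best_or_tied), length(rks))

  all_tied <- list(mk("c1", c("a", "b"), c("a", "b")),
                   mk("c2", c("a", "b"), c("a", "b")))
  cnt2 <- count_best_or_tied(all_tied)
  expect_equal(cnt2$n_best_or_tied, c(2, 2))
})

test_that("overall matrix applies the signed-rank test to shared combos", {
  cm <- data.frame(
    combo_id = rep(sprintf("c%d", 1:9), 2),
    predictor_id = rep(c("A", "B"), each = 9),
    mean = c(seq(0.51, 0.59, by = 0.01), seq(0.41, 0.49, by = 0.01)))
  mat <- overall_pairwise_matrix(cm)
  # A beats B in 9 of 9 combos: exact two-tailed p = 2 / 2^9
  expect_equal(mat$p, 2 / 512)
  expect_equal(mat$direction, "A")
  expect_equal(mat$n_combos, 9)

  # pair sharing fewer than two combos is incomparable
  cm2 <- rbind(cm, data.frame(combo_id = "c1", predictor_id = "C",
                              mean = 0.3))
  mat2 <- overall_pairwise_matrix(cm2)
  expect_true(all(is.na(mat2$p[mat2$predictor_a == "A" &
                                 mat2$predictor_b == "C"])))
  expect_false(any(mat2$significant[is.na(mat2$p)]))

  # relabeling the predictors flips direction, not p
  cm3 <- cm
  cm3$predictor_id <- ifelse(cm3$predictor_id == "A", "B", "A")
  mat3 <- overall_pairwise_matrix(cm3)
  expect_equal(mat3$p, mat$p)
  expect_equal(mat3$direction, "B")
})

test_that("final ranking applies count, wins, then directional lower-q tie-breaks", {
  counts <- data.frame(predictor_id = c("a", "b", "c", "d"),
                       n_best_or_tied = c(5, 3, 3, 1))
  mat <- data.frame(
    predictor_a = c("a", "a", "a", "b", "b", "c"),
    predictor_b = c("b", "c", "d", "c", "d", "d"),
    n_combos = 6,
    p = c(0.01, 0.01, 0.01, 0.5, 0.02, 0.3),
    q = c(0.02, 0.02, 0.02, 0.6, 0.04, 0.4),
    significant = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    direction = c("a", "a", "a", "b", "b", "c"),
    stringsAsFactors = FALSE)
  fr <- final_ranking(counts, mat)
  expect_equal(fr$predictor_id[1], "a")
  # b and c tie on count; b has 1 significant win, c has 0
  expect_lt(fr$final_rank[fr$predictor_id == "b"],
            fr$final_rank[fr$predictor_id == "c"])
  expect_equal(fr$final_rank, c(1L, 2L, 3L, 4L))
  expect_false(any(fr$shared_rank))

  # full tie yields an honest shared rank
  counts2 <- data.frame(predictor_id = c("x", "y"),
                        n_best_or_tied = c(2, 2))
  mat2 <- data.frame(predictor_a = "x", predictor_b = "y", n_combos = 4,
                     p = 1, q = 1, significant = FALSE,
                     direction = NA_character_, stringsAsFactors = FALSE)
  fr2 <- final_ranking(counts2, mat2)
  expect_equal(fr2$final_rank, c(1L, 1L))
  expect_true(all(fr2$shared_rank))

  # strictly decreasing counts leave tie-breaks untouched
  counts3 <- data.frame(predictor_id = c("a", "b", "c"),
                        n_best_or_tied = c(9, 5, 2))
  mat3 <- data.frame(predictor_a = c("a", "a", "b"),
                     predictor_b = c("b", "c", "c"), n_combos = 6,
                     p = 1, q = 1, significant = FALSE,
                     direction = NA_character_, stringsAsFactors = FALSE)
  expect_equal(final_ranking(counts3, mat3)$predictor_id,
               c("a", "b", "c"))
})

test_that("more pairwise wins ranks higher among equal best-or-tied counts", {
  # two tied leaders: one statistically outperforms 3 rivals, the other 2
  preds <- c("L1", "L2", "r1", "r2", "r3")
  counts <- data.frame(predictor_id = preds,
                       n_best_or_tied = c(4, 4, 1, 1, 1))
  pairs <- t(combn(preds, 2))
  mat <- data.frame(predictor_a = pairs[, 1], predictor_b = pairs[, 2],
                    n_combos = 6, p = 0.5, q = 0.5, significant = FALSE,
                    direction = NA_character_, stringsAsFactors = FALSE)
  set_win <- function(mat, w, l) {
    i <- (mat$predictor_a == w & mat$predictor_b == l) |
      (mat$predictor_a == l & mat$predictor_b == w)
    mat$significant[i] <- TRUE
    mat$q[i] <- 0.01
    mat$direction[i] <- w
    mat
  }
  for (l in c("r1", "r2", "r3")) mat <- set_win(mat, "L1", l)
  for (l in c("r1", "r2")) mat <- set_win(mat, "L2", l)
  fr <- final_ranking(counts, mat)
  expect_equal(fr$predictor_id[1:2], c("L1", "L2"))
  expect_equal(fr$wins[1:2], c(3L, 2L))
})

test_that("cross-cohort agreement is Kendall tau-b on shared final ranks", {
  rk <- function(ids, ranks) data.frame(predictor_id = ids,
                                        final_rank = ranks)
  same <- cross_cohort_agreement(rk(letters[1:6], 1:6),
                                 rk(letters[1:6], 1:6))
  expect_equal(same$tau, 1)
  rev <- cross_cohort_agreement(rk(letters[1:6], 1:6),
                                rk(letters[1:6], 6:1))
  expect_equal(rev$tau, -1)
  expect_error(cross_cohort_agreement(rk("a", 1), rk("b", 1)),
               class = "vepbench_validation_error")

  # tied ranks agree with the pair-counting oracle
  r1 <- c(1, 2, 2, 4, 5, 5, 7, 8, 9, 10)
  r2 <- c(2, 1, 3, 3, 6, 5, 7, 9, 8, 10)
  got <- cross_cohort_agreement(rk(letters[1:10], r1),
                                rk(letters[1:10], r2))
  expect_equal(got$tau, oracle_kendall_taub(r1, r2), tolerance = 1e-12)

  # independent random rankings of 24 predictors center near zero
  taus <- withr::with_seed(99, replicate(500, {
    kendall_tau(sample(24), sample(24))$tau
  }))
  expect_lt(abs(mean(taus)), 0.1)
})
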