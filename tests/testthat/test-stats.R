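test_that("control set requires exact zero delta-psi on both sides", {
  pairs <- data.frame(event_id_A = c("a1", "a2", "a3"),
                      event_id_B = c("b1", "b2", "b3"))
  psi_a <- data.frame(event_id = c("a1", "a2", "a3"),
                      dpsi_rep1 = c(0, 0, 0), dpsi_rep2 = c(0, 0.01, 0))
  psi_b <- data.frame(event_id = c("b1", "b2", "b3"),
                      dpsi_rep1 = c(0, 0, NA), dpsi_rep2 = c(0, 0, 0))
  got <- build_control_set(pairs, psi_a, psi_b)
  expect_equal(got$event_id_A, "a1")
  expect_equal(nrow(build_control_set(pairs[0, ], psi_a, psi_b)), 0L)
})

test_that("rank-sum p-values match brute-force enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12)), 0.1)
  expect_equal(wilcoxon_rank_sum(1, 2), 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 5, 8), c(1, 2, 5, 8)), 1)
  withr::with_seed(8, {
    for (i in 1:25) {
      n <- sample(2:5, 1); m <- sample(2:6, 1)
      v <- sample(1000, n + m)  # distinct: no ties
      x <- v[seq_len(n)]; y <- v[-seq_len(n)]
      expect_equal(wilcoxon_rank_sum(x, y), wilcox_enum(x, y),
                   tolerance = 1e-12)
    }
  })
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("nine-category table: expectations, chi-square, conservation", {
  # 4 pairs with 2x2 skip marginals: expected skip-skip cell = 2*2/4 = 1
  a <- c("skip", "skip", "no_effect", "no_effect")
  b <- c("skip", "no_effect", "skip", "no_effect")
  nc <- nine_category_analysis(a, b)
  expect_equal(nc$expected["skip", "skip"], 1)
  expect_equal(sum(nc$observed), sum(nc$expected))
  expect_equal(dim(nc$observed), c(3L, 3L))
  # observed == expected everywhere -> chi-square 0, p = 1
  ab <- expand.grid(x = c("skip", "no_effect", "inclusion"),
                    y = c("skip", "no_effect", "inclusion"),
                    stringsAsFactors = FALSE)
  nc0 <- nine_category_analysis(ab$x, ab$y)
  expect_equal(nc0$chisq, 0)
  expect_equal(nc0$p_value, 1)
  # diagonal 10/10/10: all marginals 10, E = 10/3, chi-square = 60 on 4 df
  a3 <- rep(c("skip", "no_effect", "inclusion"), each = 10)
  nc3 <- nine_category_analysis(a3, a3)
  expect_equal(nc3$chisq, 60)
  expect_equal(nc3$df, 4L)
  # agrees with stats::chisq.test when all margins are positive
  ct <- suppressWarnings(stats::chisq.test(table(a3, a3), correct = FALSE))
  expect_equal(nc3$chisq, unname(ct$statistic))
  expect_equal(nc3$p_value, ct$p.value)
})

test_that("chi-square is invariant under category relabeling", {
  withr::with_seed(13, {
    lv <- c("skip", "no_effect", "inclusion")
    a <- sample(lv, 60, TRUE); b <- sample(lv, 60, TRUE)
    nc1 <- nine_category_analysis(a, b)
    perm <- c(skip = "inclusion", no_effect = "skip", inclusion = "no_effect")
    nc2 <- nine_category_analysis(unname(perm[a]), unname(perm[b]))
    expect_equal(nc2$chisq, nc1$chisq)
  })
})

test_that("overlap test computes expected overlap and the 2x2 chi-square", {
  A <- paste0("g", 1:100); B <- paste0("g", 81:130)
  got <- overlap_independence_test(A, B, 1000)
  expect_equal(got$expected, 100 * 50 / 1000)
  expect_equal(got$observed, 20)
  # brute-force chi-square on the hand-filled table (20, 80, 30, 870)
  obs <- matrix(c(20, 80, 30, 870), 2, 2)
  e <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  expect_equal(got$chisq, sum((obs - e)^2 / e))
  # symmetric in A and B
  got_ba <- overlap_independence_test(B, A, 1000)
  expect_equal(got_ba$expected, got$expected)
  expect_equal(got_ba$chisq, got$chisq)
  # A = B: observed is |A|
  self <- overlap_independence_test(A, A, 1000)
  expect_equal(self$observed, 100)
  expect_error(overlap_independence_test(A, B, 100), "universe")
})

test_that("four-way comparison flags constructed shifts and not nulls", {
  fake_ft <- function(n, ppt_shift = 0, seed) {
    withr::with_seed(seed, data.frame(
      event_id = paste0("e", seed, "_", seq_len(n)),
      exon_length = sample(40:200, n, TRUE),
      n_ese = rpois(n, 3), n_ess = rpois(n, 5),
      score_5ss = rnorm(n), score_3ss = rnorm(n),
      branch_score = rnorm(n), ppt_score = rnorm(n, 25 + ppt_shift, 4),
      upstream_intron_length = sample(100:300, n, TRUE),
      downstream_intron_length = sample(100:300, n, TRUE),
      score_5ss_upstream_intron = rnorm(n),
      score_3ss_downstream_intron = rnorm(n)))
  }
  h_skip <- fake_ft(25, ppt_shift = -12, seed = 1)
  m_paired <- fake_ft(25, ppt_shift = +5, seed = 2)
  h_ctrl <- fake_ft(80, seed = 3)
  m_ctrl <- fake_ft(80, seed = 4)
  rep <- four_way_comparison(h_skip, m_paired, h_ctrl, m_ctrl)
  row <- rep[rep$feature == "ppt_score", ]
  expect_lt(row$p_A, 0.001)                 # constructed separation
  expect_lt(row$h_skip_median, row$m_paired_median)
  expect_gt(row$p_B, 0.05)                  # same null distribution
  # identical groups give p = 1 everywhere
  same <- four_way_comparison(h_ctrl, h_ctrl, h_ctrl, h_ctrl)
  expect_true(all(same$p_A == 1 & same$p_B == 1 & same$p_C == 1 &
                    same$p_D == 1))
  expect_error(four_way_comparison(h_skip[0, ], m_paired, h_ctrl, m_ctrl),
               "h_skip")
})

test_that("under the null about 5 % of comparisons reach 0.05", {
  withr::with_seed(77, {
    p <- replicate(400, wilcoxon_rank_sum(rnorm(20), rnorm(20)))
    expect_lt(abs(mean(p < 0.05) - 0.05), 0.03)
  })
})
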