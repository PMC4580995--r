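test_that("junction extraction applies the 8-nt anchor rule", {
  sam <- tempfile(fileext = ".sam")
  withr::with_seed(1, write_sam(sam, list(
    list(pos = 101L, cigar = "7M100N50M"),    # left anchor 7 < 8: dropped
    list(pos = 201L, cigar = "8M100N8M"),     # both anchors exactly 8: kept
    list(pos = 301L, cigar = "50M"),          # no junction
    list(pos = 401L, cigar = "20M50N5M"),     # right anchor 5 < 8: dropped
    list(pos = 501L, cigar = "10M30N10M20N10M") # two junctions, all anchors ok
  )))
  jc <- junctions_from_sam(sam, sample = "s1")
  expect_equal(attr(jc, "library_size"), 5L)
  expect_equal(nrow(jc), 3L)
  # 8M100N8M at 1-based pos 201: intron starts at 0-based 200 + 8
  expect_true(any(jc$intron_start == 208 & jc$intron_end == 308))
  expect_false(any(jc$intron_start == 107))
  expect_true(sum(jc$count[jc$intron_start %in% c(510, 550)]) == 2L)
})

test_that("unmapped and malformed records are skipped", {
  sam <- tempfile(fileext = ".sam")
  withr::with_seed(1, write_sam(sam, list(
    list(pos = 101L, cigar = "10M100N10M", flag = 4L),  # unmapped
    list(pos = 201L, cigar = "*"),                       # no CIGAR
    list(pos = 301L, cigar = "10M100N10M"))))
  expect_warning(jc <- junctions_from_sam(sam), "malformed")
  expect_equal(nrow(jc), 1L)
  expect_equal(attr(jc, "library_size"), 1L)
})

test_that("rpk30m follows count / (kb * 30M-scaled library)", {
  expect_equal(rpk30m(3, 300, 3e7), 10)
  expect_equal(rpk30m(0, 300, 3e7), 0)
  expect_equal(rpk30m(3, 300, 6e7), 5)
  expect_error(rpk30m(1, 0, 3e7), "positive")
  expect_error(rpk30m(1, 100, 0), "positive")
})

test_that("psi estimator weights inclusion junctions 1 and skip 2", {
  expect_equal(compute_psi(10, 10, 0), 1)
  expect_equal(compute_psi(0, 0, 7), 0)
  expect_equal(compute_psi(6, 4, 5), 0.5)
  expect_true(is.na(compute_psi(0, 0, 0)))
  expect_error(compute_psi(-1, 0, 0), "non-negative")
})

test_that("psi is scale-invariant and monotone in its counts", {
  withr::with_seed(5, {
    for (i in 1:50) {
      u <- sample(0:50, 1); d <- sample(0:50, 1); s <- sample(0:50, 1)
      if (u + d + s == 0) next
      k <- sample(2:9, 1)
      expect_equal(compute_psi(u * k, d * k, s * k), compute_psi(u, d, s))
      expect_true(compute_psi(u, d, s + 1) <= compute_psi(u, d, s) ||
                    is.na(compute_psi(u, d, s)))
      expect_true(compute_psi(u + 1, d, s) >= compute_psi(u, d, s) ||
                    is.na(compute_psi(u, d, s)))
    }
  })
})

test_that("expression filter implements both cutoff clauses", {
  # gene below 16 in all replicates: fail regardless of junctions
  expect_false(passes_expression_filter(rep(15, 4), rep(10, 4)))
  # gene at 16 in one replicate, junction totals fine: pass
  expect_true(passes_expression_filter(c(16, 2, 2, 2), rep(4, 4)))
  # junction total below 4 in any one replicate: fail
  expect_false(passes_expression_filter(rep(100, 4), c(10, 3.9, 10, 10)))
  expect_error(passes_expression_filter(numeric(0), rep(4, 4)), "missing")
})

test_that("response classification follows the replicate rules in order", {
  psi_ok <- c(0.5, 0.5, 0.4, 0.4)
  expect_equal(classify_response(c(-0.06, -0.02), psi_ok), "skip")
  expect_equal(classify_response(c(-0.06, 0.01), psi_ok), "others:inconsistent")
  expect_equal(classify_response(c(0.00, 0.04), psi_ok), "no_change")
  expect_equal(classify_response(c(0.06, 0.02), psi_ok), "inclusion")
  expect_equal(classify_response(c(NA, -0.5), psi_ok), "others:no_expression")
  expect_equal(classify_response(c(0.0, 0.0), rep(0.03, 4)), "others:psi_too_low")
  expect_error(classify_response(c(-0.1), psi_ok), "two replicate")
})

test_that("classification is total: exactly one class for any delta-psi pair", {
  classes <- c("skip", "inclusion", "no_change", "others:no_expression",
               "others:inconsistent", "others:psi_too_low")
  grid <- seq(-1, 1, by = 0.05)
  for (d1 in grid) for (d2 in sample(grid, 10)) {
    cl <- classify_response(c(d1, d2), c(0.5, 0.5, 0.5, 0.5))
    expect_true(cl %in% classes)
  }
})

test_that("strict skip call combines the delta-psi threshold and the t test", {
  # delta = -0.30; pooled sd from {0.80,0.82} vs {0.50,0.52}:
  # s_p^2 = 0.0002, t = 0.30 / (0.01414 * 1) = 21.2 on 2 df -> p ~ 0.002
  expect_true(strict_skip_call(c(0.80, 0.82), c(0.50, 0.52)))
  p_hand <- 2 * stats::pt(-0.30 / sqrt(2e-4 * (1 / 2 + 1 / 2)), df = 2)
  expect_lt(p_hand, 0.05)
  # fails the threshold despite a clean separation
  expect_false(strict_skip_call(c(0.80, 0.82), c(0.70, 0.72)))
  # identical values: delta 0
  expect_false(strict_skip_call(c(0.8, 0.8), c(0.8, 0.8)))
  expect_error(strict_skip_call(0.8, c(0.5, 0.5)), "two replicates")
})

test_that("delta-psi distribution reports averages and the baseline statistic", {
  ev <- toy_models(list(g1 = list(
    t1 = list(c(0, 100), c(200, 260), c(400, 500)),
    t2 = list(c(0, 100), c(400, 500)))))
  events <- extract_skipping_events(ev)
  design <- data.frame(sample = c("c1", "c2", "t1", "t2"),
                       condition = c("ctrl", "ctrl", "trt", "trt"),
                       replicate = c(1, 2, 1, 2))
  mk <- function(sample, up, down, skip) {
    data.frame(chrom = "chr1", intron_start = c(100, 260, 100),
               intron_end = c(200, 400, 400), strand = "+",
               sample = sample, count = c(up, down, skip))
  }
  # psi: ctrl (0.6, 0.6), treat (0.4, 0.5)
  junc <- rbind(mk("c1", 6, 6, 4), mk("c2", 6, 6, 4),
                mk("t1", 4, 4, 6), mk("t2", 5, 5, 5))
  psi <- psi_table(events, junc, design)
  expect_equal(unname(as.numeric(psi[1, 2:5])), c(0.6, 0.6, 0.4, 0.5))
  dd <- delta_psi_distribution(psi)
  expect_equal(dd$per_event$delta_psi_avg, -0.15)
  expect_equal(dd$per_event$baseline, (0.6 - 0.6 + 0.4 - 0.5) / 2)
  expect_equal(dd$n_skip_enhanced, 1L)
  expect_equal(dd$n_inclusion_enhanced, 0L)
  # identical psi everywhere: both statistics 0
  junc0 <- rbind(mk("c1", 6, 6, 4), mk("c2", 6, 6, 4),
                 mk("t1", 6, 6, 4), mk("t2", 6, 6, 4))
  dd0 <- delta_psi_distribution(psi_table(events, junc0, design))
  expect_equal(dd0$per_event$delta_psi_avg, 0)
  expect_equal(dd0$per_event$baseline, 0)
})
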