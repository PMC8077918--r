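test_that("Fisher exact reproduces the cohort-table p-values", {
  expect_equal(round(fisher_exact_2x2(matrix(c(6, 14, 0, 23), 2,
                                             byrow = TRUE)), 3), 0.006)
  expect_equal(round(fisher_exact_2x2(matrix(c(9, 11, 3, 20), 2,
                                             byrow = TRUE)), 3), 0.039)
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2)), 1)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher exact equals full margin-constrained enumeration", {
  set.seed(99)
  for (i in 1:200) {
    repeat {
      tab <- as.vector(rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
      if (sum(tab) > 0) break
    }
    p_pkg <- fisher_exact_2x2(matrix(tab, 2, byrow = TRUE))
    p_orc <- oracle_fisher_enum(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p_pkg, p_orc, tolerance = 1e-7)
  }
  # invariance to swapping both rows and both columns
  expect_equal(fisher_exact_2x2(matrix(c(3, 9, 7, 2), 2, byrow = TRUE)),
               fisher_exact_2x2(matrix(c(2, 7, 9, 3), 2, byrow = TRUE)))
})

test_that("bonferroni is the capped multiply rule and is monotone", {
  p <- fisher_exact_2x2(matrix(c(10, 10, 3, 20), 2, byrow = TRUE))
  expect_equal(round(bonferroni(p, m = 14), 2), 0.25)
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(c(0.2, 0.4), m = 2), c(0.4, 0.8))
  expect_equal(bonferroni(0.123, m = 1), 0.123)
  p_in <- sort(runif(20))
  expect_false(is.unsorted(bonferroni(p_in)))
  expect_true(all(bonferroni(p_in) >= p_in))
  expect_error(bonferroni(0.5, m = 0), "m must be")
})

test_that("Wilcoxon exact mode equals exhaustive permutation enumeration", {
  grids <- list(
    list(x = c(1, 2, 3), y = c(4, 5, 6)),
    list(x = c(1, 4, 6), y = c(2, 3, 5)),
    list(x = c(1, 2, 6), y = c(3, 4, 5)),
    list(x = c(2, 9, 10), y = c(1, 3, 4))
  )
  for (g in grids) {
    expect_equal(wilcoxon_rank_sum(g$x, g$y),
                 oracle_wilcoxon_enum(g$x, g$y))
  }
  # identical samples in the approximation regime give p near 1
  x <- seq(0.1, 2, length.out = 15)
  expect_gt(wilcoxon_rank_sum(x, x), 0.95)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("Wilcoxon power increases with location shift", {
  set.seed(12)
  shift_p <- vapply(c(0, 0.5, 1.5), function(s) {
    mean(vapply(1:40, function(i) {
      x <- rnorm(20); y <- rnorm(20) + s
      wilcoxon_rank_sum(x, y)
    }, numeric(1)) < 0.05)
  }, numeric(1))
  expect_true(all(diff(shift_p) >= 0))
  expect_gt(shift_p[3], 0.9)
})

test_that("two-proportion z with Yates matches the chi-square equivalence", {
  # z^2 equals the Yates-corrected chi-square statistic of prop.test
  for (case in list(c(40, 100, 60, 100), c(5, 30, 12, 28),
                    c(18, 20, 4, 23))) {
    p_pkg <- two_proportion_z_yates(case[1], case[2], case[3], case[4])
    p_orc <- suppressWarnings(
      prop.test(c(case[1], case[3]), c(case[2], case[4]),
                correct = TRUE)$p.value)
    expect_equal(p_pkg, p_orc, tolerance = 1e-12)
  }
  expect_equal(two_proportion_z_yates(50, 100, 50, 100), 1)
  # small same-proportion case: corrected difference clamps to zero
  expect_equal(two_proportion_z_yates(1, 10, 1, 10), 1)
  expect_equal(two_proportion_z_yates(0, 10, 0, 20), 1)
  expect_equal(two_proportion_z_yates(10, 10, 20, 20), 1)
})

test_that("per_bin_fisher delegates to the verified Fisher test", {
  gs <- test_genome()
  ids_a <- sprintf("A%02d", 1:20)
  ids_b <- sprintf("B%02d", 1:23)
  seg_all <- data.frame(chrom = "chr1", start = 5e6, end = 6e6, lr = 1,
                        call = "gain")
  none <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), lr = numeric(), call = character())
  calls <- c(stats::setNames(rep(list(seg_all), 20), ids_a),
             stats::setNames(rep(list(none), 23), ids_b))
  map_a <- bin_frequency_map(calls, gs, ids_a)
  map_b <- bin_frequency_map(calls, gs, ids_b)
  peaks <- per_bin_fisher(map_a, map_b)
  hot <- peaks[peaks$type == "gain" & peaks$bin_start == 5e6 &
                 peaks$chrom == "chr1", ]
  expect_equal(hot$p_raw,
               fisher_exact_2x2(matrix(c(20, 0, 0, 23), 2, byrow = TRUE)))
  expect_true(hot$significant)
  # identical maps give p = 1 everywhere
  same <- per_bin_fisher(map_a, map_a)
  expect_true(all(same$p_raw == 1))
  # significant count equals a brute-force recount
  expect_equal(sum(peaks$significant), sum(peaks$p_raw < 0.05))
  expect_true(all(peaks$p_adj >= peaks$p_raw))
})

test_that("randomization null is seeded, bounded and degenerates at alpha 0", {
  gs <- test_genome()
  ids <- sprintf("S%02d", 1:16)
  calls <- gen_segment_calls(ids, gs, events_per_sample = 4, seed = 23)
  labels <- data.frame(sample_id = ids,
                       cohort = rep(c("A", "B"), each = 8))
  r1 <- randomization_null(calls, labels, gs, n_iter = 25, seed = 5)
  r2 <- randomization_null(calls, labels, gs, n_iter = 25, seed = 5)
  expect_identical(r1$counts, r2$counts)
  expect_equal(r1$median, median(r1$counts))
  expect_equal(r1$min, min(r1$counts))
  expect_equal(r1$max, max(r1$counts))

  r0 <- randomization_null(calls, labels, gs, n_iter = 10, alpha = 0,
                           seed = 5)
  expect_true(all(r0$counts == 0))
  expect_error(randomization_null(calls, labels, gs, n_iter = 0), "n_iter")
})

test_that("per-bin Fisher p-values are super-uniform under the null", {
  gs <- test_genome()
  ids <- sprintf("S%02d", 1:30)
  set.seed(61)
  ps <- unlist(lapply(1:8, function(r) {
    calls <- gen_segment_calls(ids, gs, events_per_sample = 6,
                               seed = 600 + r)
    map_a <- bin_frequency_map(calls, gs, ids[1:15])
    map_b <- bin_frequency_map(calls, gs, ids[16:30])
    per_bin_fisher(map_a, map_b)$p_raw
  }))
  for (alpha in c(0.01, 0.05, 0.1)) {
    expect_lt(mean(ps < alpha),
              alpha + 3 * sqrt(alpha * (1 - alpha) / length(ps)))
  }
})
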