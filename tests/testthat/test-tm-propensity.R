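test_that("homopolymer and alternating sequences score as the scale says", {
  sc <- toy_scale()
  expect_identical(sequence_tm_score("AAAA", sc), 1)
  expect_identical(sequence_tm_score("ARAR", sc), 0)
  expect_identical(sequence_tm_score("FFFF", tm_tendency_scale()), 1.98)
})

test_that("score equals a brute-force lookup-and-average oracle", {
  sc <- tm_tendency_scale()
  v <- unclass(sc)
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- random_aa(50)
      expect_equal(sequence_tm_score(s, sc), oracle_tm_score(s, v),
                   tolerance = 1e-12)
    }
  })
})

test_that("core-region scoring picks exactly the stated intervals", {
  sc <- toy_scale()
  # residues 1-2 are A (score 1), 3-6 are R (score -1)
  s <- "AARRRR"
  expect_identical(
    sequence_tm_score(s, sc, use_core = TRUE,
                      core_regions = data.frame(aa_start = 1, aa_end = 2)),
    1)
  expect_identical(
    sequence_tm_score(s, sc, use_core = TRUE,
                      core_regions = data.frame(aa_start = c(1, 3),
                                                aa_end = c(2, 4))),
    0)
})

test_that("ambiguous residues follow the scale policy", {
  expect_message(
    got <- sequence_tm_score("AXA", toy_scale()), "ambiguous")
  expect_identical(got, 1)
  strict <- tm_scale(unclass(toy_scale()), ambiguity_policy = "error")
  expect_error(sequence_tm_score("AXA", strict),
               class = "famcontext_scoring_error")
})

test_that("score is the length-weighted mean of segment scores", {
  sc <- tm_tendency_scale()
  withr::with_seed(5, {
    s1 <- random_aa(30)
    s2 <- random_aa(70)
    whole <- sequence_tm_score(paste0(s1, s2), sc)
    parts <- (30 * sequence_tm_score(s1, sc) +
                70 * sequence_tm_score(s2, sc)) / 100
    expect_equal(whole, parts, tolerance = 1e-12)
    expect_equal(sequence_tm_score(paste0(s2, s1), sc), whole,
                 tolerance = 1e-12)
  })
})

test_that("adding a constant to the scale shifts every score by it", {
  base <- tm_tendency_scale()
  shifted <- tm_scale(unclass(base) + 2.5, name = "shifted")
  withr::with_seed(6, {
    for (i in 1:10) {
      s <- random_aa(40)
      expect_equal(sequence_tm_score(s, shifted),
                   sequence_tm_score(s, base) + 2.5, tolerance = 1e-12)
    }
  })
})

test_that("family grouping is order-invariant and complete", {
  withr::with_seed(7, {
    records <- data.frame(
      sequence_id = sprintf("s%d", 1:6),
      family_id = rep(c("famB", "famA"), each = 3),
      residues = replicate(6, random_aa(25)),
      stringsAsFactors = FALSE)
  })
  sets <- family_scores(records, tm_tendency_scale())
  expect_named(sets, c("famA", "famB"))
  expect_identical(lengths(sets), c(famA = 3L, famB = 3L))
  shuffled <- family_scores(records[c(4, 2, 6, 1, 3, 5), ],
                            tm_tendency_scale())
  expect_identical(sets, shuffled)
  tab <- score_table(sets)
  expect_named(tab, c("sequence_id", "family_id", "tm_score"))
  expect_identical(nrow(tab), 6L)
})

test_that("classification follows the statistic, ties go soluble", {
  sets <- structure(list(up = c(2, 2, 2), down = c(-1, -1),
                         tie = c(0, 0, 0)),
                    class = "family_score_set")
  expect_message(cls <- classify_families(sets, boundary = 0), "boundary")
  expect_identical(cls, c(up = "TM", down = "soluble", tie = "soluble"))
})

test_that("classification is monotone in the boundary", {
  withr::with_seed(8, {
    sets <- structure(
      lapply(1:12, function(i) rnorm(10, mean = runif(1, -2, 2))),
      names = sprintf("f%02d", 1:12), class = "family_score_set")
  })
  boundaries <- seq(-2, 2, by = 0.25)
  n_tm <- vapply(boundaries, function(b) {
    sum(classify_families(sets, boundary = b) == "TM")
  }, numeric(1))
  expect_true(all(diff(n_tm) <= 0))
})

test_that("Kruskal-Wallis matches the hand-ranked toy and symmetry cases", {
  res <- kruskal_wallis(list(a = c(1, 2), b = c(3, 4)))
  expect_equal(res$H_statistic, 2.4, tolerance = 1e-12)
  same <- kruskal_wallis(list(a = c(1, 5, 9), b = c(9, 1, 5)))
  expect_equal(same$H_statistic, 0, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(a = c(1, 1), b = c(1, 1))),
               class = "famcontext_degenerate_data_error")
})

test_that("Kruskal-Wallis holds its nominal type-I error rate", {
  withr::with_seed(42, {
    rejections <- vapply(1:2000, function(i) {
      groups <- split(rnorm(15), rep(1:3, each = 5))
      kruskal_wallis(groups)$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("Dunn separates extreme groups and unites identical ones", {
  far <- dunn_posthoc(list(lo = 1:10, hi = 101:110), alpha = 0.05)
  expect_lt(far$pairwise$p_adjusted, 0.05)
  expect_length(far$cd_groups, 2L)
  same <- dunn_posthoc(list(a = 1:6, b = 1:6, c = 1:6), alpha = 0.05)
  expect_true(all(same$pairwise$p_adjusted == 1))
  expect_length(same$cd_groups, 1L)
})

test_that("Bonferroni adjustment and grouping behave monotonically", {
  withr::with_seed(9, {
    sets <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2),
                 d = rnorm(8, 3))
  })
  res <- dunn_posthoc(sets, alpha = 0.05)
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adjusted <= 1))
  # lowering alpha can only merge cd groups, never split them
  n_groups <- vapply(c(0.2, 0.05, 0.01, 0.001), function(a) {
    length(dunn_posthoc(sets, alpha = a)$cd_groups)
  }, numeric(1))
  expect_true(all(diff(n_groups) <= 0))
  # cd_groups is a partition of the families
  expect_setequal(unlist(res$cd_groups), names(sets))
})
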