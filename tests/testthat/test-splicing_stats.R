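test_that("ESS percentages reproduce hand-evaluated density formulas", {
  cat <- toy_catalog()  # all exons 100 nt
  counts <- tibble::tibble(sample_id = "s",
                           category = c("noS", "E56S"),
                           count = c(60, 20))
  p <- ess_percentages(counts, cat)
  # d(noS) = 60/600 = 0.1, d(E56S) = 20/200 = 0.1 -> both P = 0.5
  expect_equal(p$density[p$isoform == "noS"], 0.1)
  expect_equal(p$density[p$isoform == "E56S"], 0.1)
  expect_equal(p$percentage[p$isoform == "noS"], 0.5)
  expect_equal(p$percentage[p$isoform == "E56S"], 0.5)
  expect_equal(sum(p$percentage[p$in_model]), 1, tolerance = 1e-12)

  # equal densities across all six categories -> each P = 1/6
  eq <- tibble::tibble(
    sample_id = "e",
    category = c("noS", "E3S", "E5S", "E6S", "E56S", "E3456S"),
    count = c(600, 200, 200, 200, 200, 200))
  pe <- ess_percentages(eq, cat)
  expect_equal(pe$percentage[pe$in_model], rep(1 / 6, 6), tolerance = 1e-12)

  # a single nonzero category takes the whole profile
  one <- tibble::tibble(sample_id = "o", category = "noS", count = 37)
  po <- ess_percentages(one, cat)
  expect_equal(po$percentage[po$isoform == "noS"], 1)
  expect_equal(sum(po$percentage[po$in_model]), 1)
})

test_that("denominators are the flanking exons of the skipped block", {
  cat <- toy_catalog()
  den <- ess_denominators(cat)
  expect_equal(den$denom_length,
               c(600, 200, 200, 200, 200, 200))
  expect_equal(den$denom_exons[[1]], paste0("E", 2:7))
  expect_equal(den$denom_exons[[2]], c("E2", "E4"))   # E3S
  expect_equal(den$denom_exons[[3]], c("E4", "E6"))   # E5S
  expect_equal(den$denom_exons[[4]], c("E5", "E7"))   # E6S
  expect_equal(den$denom_exons[[5]], c("E4", "E7"))   # E56S
  expect_equal(den$denom_exons[[6]], c("E2", "E7"))   # E3456S
})

test_that("non-model isoforms are reported but excluded from normalization", {
  gm <- default_gene_model()
  counts <- tibble::tibble(
    sample_id = "s",
    category = c("noS", "E56S", "E4S", "E3a"),
    count = c(50, 10, 7, 3))
  p <- ess_percentages(counts, gm)
  expect_equal(sum(p$percentage[p$in_model]), 1, tolerance = 1e-12)
  extra <- p[!p$in_model, ]
  expect_setequal(extra$isoform, c("E4S", "E3a"))
  expect_equal(extra$reads[extra$isoform == "E4S"], 7)
  expect_true(all(is.na(extra$percentage)))
})

test_that("an all-zero profile is flagged undefined, not zeroed", {
  cat <- toy_catalog()
  zero <- tibble::tibble(sample_id = "z", category = "noS", count = 0)
  expect_warning(p <- ess_percentages(zero, cat), "undefined")
  expect_true(all(is.na(p$percentage[p$in_model])))
})

test_that("AS percentages are plain count ratios", {
  expect_equal(as_percentage(75, 25), tibble::tibble(p_noas = 0.75,
                                                     p_as = 0.25))
  expect_equal(as_percentage(10, 0)$p_as, 0)
  expect_equal(as_percentage(0, 10)$p_noas, 0)
  expect_warning(res <- as_percentage(c(5, 0), c(5, 0)), "undefined")
  expect_equal(res$p_as, c(0.5, NA))
  expect_error(as_percentage(-1, 5), "non-negative")
})

test_that("spike-in scale factors are expected/observed and leave P unchanged", {
  gm <- default_gene_model()
  counts <- dplyr::bind_rows(
    tibble::tibble(sample_id = "A",
                   category = c("noS", "E56S", "spike_in"),
                   count = c(100, 40, 2000)),
    tibble::tibble(sample_id = "B",
                   category = c("noS", "E56S", "spike_in"),
                   count = c(300, 120, 1000)))
  sheet <- tibble::tibble(cell_id = c("A", "B"), spike_in_expected = 1000)
  norm <- spike_in_normalize(counts, sheet)
  expect_equal(unique(norm$scale_factor[norm$sample_id == "A"]), 0.5)
  expect_equal(unique(norm$scale_factor[norm$sample_id == "B"]), 1.0)
  # percentages are ratio statistics: unchanged by scaling
  p_raw <- ess_percentages(counts, gm)
  scaled <- dplyr::mutate(counts, count = count * 3L)
  p_scaled <- ess_percentages(scaled, gm)
  expect_equal(p_raw$percentage, p_scaled$percentage, tolerance = 1e-12)
  # zero spike-in: excluded with a warning
  bad <- dplyr::bind_rows(counts, tibble::tibble(
    sample_id = "C", category = c("noS", "spike_in"), count = c(10, 0)))
  sheet3 <- tibble::tibble(cell_id = c("A", "B", "C"),
                           spike_in_expected = 1000)
  expect_warning(norm3 <- spike_in_normalize(bad, sheet3), "zero spike-in")
  expect_false("C" %in% norm3$sample_id)
})

test_that("relative levels divide by the embryo maximum", {
  gm <- default_gene_model()
  mk_counts <- function(cell, noS, e56) {
    tibble::tibble(sample_id = cell, category = c("noS", "E56S", "spike_in"),
                   count = c(noS, e56, 100))
  }
  # cell ESS fractions engineered via counts: with only noS and E56S,
  # P(E56S) = (e56/200') share; use equal densities trick for 0.2 and 0.4
  counts <- dplyr::bind_rows(
    mk_counts("c1", 610 * 4, 190 * 1),   # d-ratio 1:0.25 -> ESS = 0.2
    mk_counts("c2", 610 * 3, 190 * 2))   # ESS = 0.4
  prof <- ess_percentages(counts, gm)
  ess <- 1 - prof$percentage[prof$isoform == "noS"]
  expect_equal(ess, c(0.2, 0.4), tolerance = 1e-12)
  sheet <- tibble::tibble(cell_id = c("c1", "c2"), embryo_id = "emb1",
                          spatial_label = c("pB", "npB"),
                          spike_in_expected = 100)
  summ <- relative_levels_within_embryo(prof, sheet)
  expect_equal(summ$relative_level, c(0.5, 1.0), tolerance = 1e-12)
  # equal metric values -> both exactly 1
  counts_eq <- dplyr::bind_rows(mk_counts("c1", 610, 190),
                                mk_counts("c2", 1220, 380))
  prof_eq <- ess_percentages(counts_eq, gm)
  summ_eq <- relative_levels_within_embryo(prof_eq, sheet)
  expect_equal(summ_eq$relative_level, c(1, 1))
  expect_error(relative_levels_within_embryo(
    prof, tibble::tibble(cell_id = "c1", embryo_id = "solo",
                         spatial_label = "pB", spike_in_expected = 100)),
    "at least 2")
})

test_that("expression relative levels use spike-in-normalized abundance", {
  counts <- dplyr::bind_rows(
    tibble::tibble(sample_id = "c1", category = c("noS", "spike_in"),
                   count = c(200, 100)),
    tibble::tibble(sample_id = "c2", category = c("noS", "spike_in"),
                   count = c(200, 50)))
  sheet <- tibble::tibble(cell_id = c("c1", "c2"), embryo_id = "e",
                          spatial_label = c("pB", "npB"),
                          spike_in_expected = 100)
  summ <- relative_levels_within_embryo(NULL, sheet, counts,
                                        metric = "expression")
  # c1: 200 * (100/100) = 200; c2: 200 * (100/50) = 400
  expect_equal(summ$value, c(200, 400))
  expect_equal(summ$relative_level, c(0.5, 1))
})

test_that("spatial group comparison is the classical equal-variance t", {
  a <- c(0.31, 0.45, 0.52, 0.38, 0.47, 0.41)
  b <- c(0.52, 0.61, 0.55, 0.67, 0.58, 0.63)
  cmp <- compare_spatial_groups(a, b)
  # textbook evaluation: pooled variance, t statistic, CDF
  sp2 <- (5 * var(a) + 5 * var(b)) / 10
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 6))
  p_hand <- 2 * pt(-abs(t_hand), df = 10)
  expect_equal(cmp$statistic, t_hand, tolerance = 1e-12)
  expect_equal(cmp$df, 10)
  expect_equal(cmp$p.value, p_hand, tolerance = 1e-12)
  # one-tailed halves the two-tailed p on the correct side
  cmp1 <- compare_spatial_groups(a, b, alternative = "less")
  expect_equal(cmp1$p.value, p_hand / 2, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- compare_spatial_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # complete separation with zero variance
  sep <- compare_spatial_groups(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(sep$p.value < 1e-10)
  expect_error(compare_spatial_groups(1, c(1, 2)), "at least 2")
  td <- tidy(cmp)
  expect_equal(td$p.value, p_hand)
  expect_equal(td$df, 10)
})

test_that("occupancy chi-squared matches the hand formula with df = 2", {
  tab <- matrix(c(10, 0, 5, 0, 10, 5), ncol = 2)
  ot <- occupancy_test(tab)
  # hand computation of sum (O - E)^2 / E with E from margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2_hand <- sum((tab - E)^2 / E)
  expect_equal(ot$statistic, x2_hand, tolerance = 1e-12)
  expect_equal(x2_hand, 20)  # frozen hand value for this fixture
  expect_equal(ot$df, 2)
  expect_equal(ot$p.value, pchisq(20, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # proportional table -> statistic 0
  prop <- matrix(c(10, 20, 30, 1, 2, 3), ncol = 2)
  expect_equal(occupancy_test(prop)$statistic, 0, tolerance = 1e-12)
  # degenerate margins are refused
  expect_error(occupancy_test(matrix(c(0, 0, 1, 1), 2)), "positive sum")
  expect_error(occupancy_test(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("profiles are scale-invariant and monotone in single counts", {
  cat <- toy_catalog()
  withr::local_seed(77)
  for (i in 1:25) {
    counts <- tibble::tibble(
      sample_id = "s",
      category = c("noS", "E3S", "E5S", "E6S", "E56S", "E3456S"),
      count = sample(0:500, 6, replace = TRUE))
    if (sum(counts$count) == 0) counts$count[1] <- 1
    p1 <- ess_percentages(counts, cat)
    k <- sample(2:9, 1)
    p2 <- ess_percentages(dplyr::mutate(counts, count = count * k), cat)
    expect_equal(p1$percentage, p2$percentage, tolerance = 1e-12)
    expect_equal(sum(p1$percentage[p1$in_model]), 1, tolerance = 1e-12)
    # bump E56S: its P strictly rises, every other P strictly falls
    bumped <- dplyr::mutate(counts, count = count +
                              ifelse(category == "E56S", 40L, 0L))
    p3 <- ess_percentages(bumped, cat)
    up <- p3$percentage[p3$isoform == "E56S"] -
      p1$percentage[p1$isoform == "E56S"]
    expect_gt(up, 0)
    others <- p1$isoform[p1$in_model & p1$isoform != "E56S" &
                           p1$percentage > 0]
    for (iso in others) {
      expect_lt(p3$percentage[p3$isoform == iso],
                p1$percentage[p1$isoform == iso])
    }
  }
})
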