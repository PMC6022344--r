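test_that("standard_error implements the binomial SE formula", {
  expect_equal(round_half_up(100 * standard_error(8, 53), 1), 4.9)
  expect_equal(round_half_up(100 * standard_error(37, 52), 1), 6.3)
  expect_equal(standard_error(0, 10), 0)
  expect_equal(standard_error(10, 10), 0)
  expect_error(standard_error(5, 0), ">= 1")
  expect_error(standard_error(11, 10), "k")
  # bound: se <= 0.5/sqrt(n), equality iff k/n = 1/2
  for (n in c(2, 10, 53)) {
    ks <- 0:n
    se <- vapply(ks, standard_error, numeric(1), n = n)
    expect_true(all(se <= 0.5 / sqrt(n) + 1e-12))
    expect_equal(se[ks == n / 2], rep(0.5 / sqrt(n), sum(ks == n / 2)))
  }
})

test_that("accuracy_table computes category rows with SEs", {
  samples <- annotation_samples(
    c(family_complex = 52, protein_gene = 172),
    c(family_complex = 37, protein_gene = 154)
  )
  acc <- accuracy_table(samples)
  fam <- acc[acc$category == "family_complex", ]
  expect_equal(fam$n_category, 52L)
  expect_equal(fam$k_correct, 37L)
  expect_equal(round_half_up(fam$correct_pct, 1), 71.2)
  expect_equal(round_half_up(fam$se_pct, 1), 6.3)
  pg <- acc[acc$category == "protein_gene", ]
  expect_equal(round_half_up(pg$correct_pct, 1), 89.5)
  expect_equal(round_half_up(pg$se_pct, 1), 2.3)

  # all-correct single category
  acc1 <- accuracy_table(annotation_samples(c(bio_process = 28), c(bio_process = 28)))
  expect_equal(acc1$correct_pct, 100)
  expect_equal(acc1$se_pct, 0)
  expect_equal(acc1$entity_pct, 100)

  # entity percentages always sum to 100
  set.seed(1)
  for (i in 1:5) {
    cats <- sample(c("a", "b", "c"), 50, replace = TRUE)
    s <- data.frame(category = cats, correct = sample(c(TRUE, FALSE), 50, TRUE))
    expect_equal(sum(accuracy_table(s)$entity_pct), 100)
  }
})

test_that("cumulative_curve orders by frequency and accumulates to 1", {
  freqs <- c(a = 10, b = 2, c = 2, d = 2, e = 2, f = 2)
  curve <- cumulative_curve(freqs)
  expect_equal(curve$string[[1L]], "a")
  expect_equal(curve$cum_fraction[[1L]], 0.5)
  expect_equal(curve$cum_fraction[[nrow(curve)]], 1)
  expect_true(all(diff(curve$cum_fraction) >= 0))
  expect_equal(top_share(freqs, 0.5), 1 / 6)

  # uniform counts put the curve on the diagonal
  uni <- cumulative_curve(setNames(rep(3, 8), letters[1:8]))
  expect_equal(uni$cum_fraction, uni$percentile)

  # random inputs: monotone, ends at 1, top_share matches a direct cumsum
  set.seed(3)
  for (i in 1:5) {
    f <- setNames(sample(1:50, 20, replace = TRUE), paste0("s", 1:20))
    cv <- cumulative_curve(f)
    expect_true(all(diff(cv$cum_fraction) >= -1e-12))
    expect_equal(cv$cum_fraction[[20L]], 1)
    srt <- sort(f, decreasing = TRUE)
    idx <- which(cumsum(as.numeric(srt)) / sum(srt) >= 0.5)[[1L]]
    expect_equal(top_share(f, 0.5), idx / 20)
  }
  expect_error(cumulative_curve(numeric()), "non-empty")
})

test_that("event_coverage counts any- and all-ungrounded events", {
  cov <- event_coverage(list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE)))
  expect_equal(cov$prop_any_ungrounded, 2 / 3)
  expect_equal(cov$prop_all_ungrounded, 1 / 3)

  allg <- event_coverage(list(TRUE, c(TRUE, TRUE)))
  expect_equal(allg$prop_any_ungrounded, 0)
  expect_equal(allg$prop_all_ungrounded, 0)

  expect_error(event_coverage(list(logical())), "at least one")

  set.seed(5)
  for (i in 1:5) {
    ev <- replicate(30, sample(c(TRUE, FALSE), sample(1:4, 1), replace = TRUE),
                    simplify = FALSE)
    cov <- event_coverage(ev)
    n_any <- sum(vapply(ev, function(e) sum(e == FALSE) > 0, logical(1)))
    n_all <- sum(vapply(ev, function(e) sum(e == TRUE) == 0, logical(1)))
    expect_equal(cov$n_any_ungrounded, n_any)
    expect_equal(cov$n_all_ungrounded, n_all)
    expect_true(cov$n_all_ungrounded <= cov$n_any_ungrounded)
    expect_true(cov$n_any_ungrounded <= cov$n_events)
  }
})

test_that("level_distribution returns fractions over the three levels", {
  g <- hierarchy_graph(inpaper_ontology())
  d <- level_distribution(c("FPLX:PLC", "FPLX:PLCG", "HGNC:PLCG1", "HGNC:PLCG1"),
                          g, "PLC")
  expect_equal(d[["top"]], 0.25)
  expect_equal(d[["intermediate"]], 0.25)
  expect_equal(d[["gene"]], 0.5)

  expect_equal(level_distribution("AMPK", g, "AMPK")[["top"]], 1)
  expect_error(level_distribution("RAS", g, "PLC"), "sub-hierarchy")

  set.seed(11)
  nodes <- c("FPLX:PLC", descendants(g, "PLC"))
  for (i in 1:5) {
    picks <- sample(nodes, 20, replace = TRUE)
    expect_equal(sum(level_distribution(picks, g, "PLC")), 1)
  }
})

test_that("coverage_pct handles exclusions", {
  expect_equal(round_half_up(coverage_pct(1908, 2439, 51), 1), 79.9)
  expect_equal(coverage_pct(23, 36), 100 * 23 / 36)
  expect_error(coverage_pct(10, 5, 5), "positive")
})
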