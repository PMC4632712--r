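test_that("strong-selection flags threshold |iHS| inclusively and drop unscored SNPs", {
  tr <- annotation_track(c("s1", "s2", "s3"), c(2.91, -2.6, 1.0))
  f <- strong_selection_flags(tr)
  expect_identical(f, c(s1 = 1L, s2 = 1L, s3 = 0L))

  expect_identical(strong_selection_flags(numeric(0)),
                   setNames(integer(0), character(0)))
  expect_identical(strong_selection_flags(c(s1 = -0.5), threshold = 0.5),
                   c(s1 = 1L))
  # unscored SNPs leave the universe entirely
  expect_identical(names(strong_selection_flags(c(a = 3, b = NA, c = 0))),
                   c("a", "c"))
  expect_error(strong_selection_flags(c(s1 = 1), threshold = 0),
               "threshold")
})

test_that("make_table tallies the flag cross-classification", {
  set.seed(5)
  ids <- sprintf("s%03d", 1:200)
  ch <- setNames(runif(200) < 0.4, ids)
  an <- setNames(runif(200) < 0.1, ids)
  tab <- make_table(ch, an)
  expect_equal(unclass(tab)[1, 1], sum(ch & an))
  expect_equal(unclass(tab)[1, 2], sum(ch & !an))
  expect_equal(unclass(tab)[2, 1], sum(!ch & an))
  expect_equal(unclass(tab)[2, 2], sum(!ch & !an))
  expect_equal(sum(tab), 200L)

  # nobody annotated: the annotated column is empty
  z <- make_table(setNames(c(TRUE, TRUE, FALSE, FALSE, FALSE), letters[1:5]),
                  setNames(rep(FALSE, 5), letters[1:5]))
  expect_equal(unclass(z)[, 1], c(yes = 0L, no = 0L))
  expect_equal(unclass(z)[, 2], c(yes = 2L, no = 3L))

  expect_message(make_table(ch, an[1:50]), "universes differ")
  expect_error(make_table(c(a = TRUE), c(b = TRUE)), "empty universe")
  expect_error(contingency_2x2(-1, 0, 0, 2), "non-negative")
  expect_error(contingency_2x2(0, 0, 0, 0), "empty table")
})

test_that("Fisher p equals full hypergeometric enumeration on small tables", {
  set.seed(15)
  for (i in 1:150) {
    repeat {
      x <- as.integer(rmultinom(1, sample(4:40, 1), prob = runif(4)))
      if (sum(x) > 0) break
    }
    tab <- contingency_2x2(x[1], x[2], x[3], x[4])
    if (any(rowSums(unclass(tab)) == 0) ||
        any(colSums(unclass(tab)) == 0)) next  # degenerate: tested below
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(fisher_exact(tab, alt),
                   oracle_fisher(x[1], x[2], x[3], x[4], alt),
                   tolerance = 1e-10)
    }
  }
})

test_that("degenerate and symmetric tables follow the stated conventions", {
  expect_equal(fisher_exact(contingency_2x2(1, 1, 1, 1)), 1.0)
  d <- fisher_exact(contingency_2x2(0, 0, 3, 4))
  expect_equal(as.numeric(d), 1)
  expect_true(isTRUE(attr(d, "degenerate")))
})

test_that("Fisher p is invariant under simultaneous row and column transposition", {
  set.seed(25)
  for (i in 1:30) {
    x <- as.integer(rmultinom(1, 60, prob = runif(4))) + 1L
    t1 <- contingency_2x2(x[1], x[2], x[3], x[4])
    t2 <- contingency_2x2(x[4], x[3], x[2], x[1])
    expect_equal(fisher_exact(t1), fisher_exact(t2), tolerance = 1e-12)
    # odds ratio maps to its reciprocal under a row swap
    t3 <- contingency_2x2(x[3], x[4], x[1], x[2])
    expect_equal(odds_ratio(t3), 1 / odds_ratio(t1), tolerance = 1e-12)
  }
})

test_that("the sample odds ratio matches reported rounding and edge conventions", {
  expect_equal(round(odds_ratio(contingency_2x2(59, 21237, 45, 25698)), 1),
               1.6)
  expect_equal(round(odds_ratio(contingency_2x2(1720, 19576, 1663, 24080)),
                     1), 1.3)
  expect_identical(odds_ratio(contingency_2x2(5, 0, 3, 7)), Inf)
  expect_true(is.nan(odds_ratio(contingency_2x2(0, 0, 3, 0))))
})

test_that("rank-sum test matches exhaustive rank-split enumeration for small samples", {
  set.seed(35)
  for (i in 1:20) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 3)
    y <- round(rnorm(n2, 0.5), 3)
    if (anyDuplicated(c(x, y))) next  # tie-free for the exact comparison
    expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcoxon_p(x, y),
                 tolerance = 1e-10)
  }
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty sample")
})

test_that("rank-sum test detects a planted |iHS| shift with adequate power", {
  set.seed(45)
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    a <- abs(rnorm(3000))        # |iHS|-like null scores
    b <- abs(rnorm(3000)) + 0.1  # planted location shift
    if (wilcoxon_rank_sum(b, a) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("run_enrichment composes flags, table, Fisher test and odds ratio", {
  set.seed(55)
  ids <- sprintf("s%04d", 1:2000)
  ch <- setNames(runif(2000) < 0.45, ids)
  ihs <- annotation_track(ids[1:900], rnorm(900, sd = 1.3),
                          population = "ASI")
  r <- run_enrichment(ch, ihs, mode = "selection", threshold = 2.5)
  expect_s3_class(r, "enrichment_result")
  expect_equal(sum(r$table), 900L)  # only scored SNPs enter the universe
  flags <- strong_selection_flags(ihs)
  tab <- make_table(ch, flags)
  expect_identical(unclass(r$table), unclass(tab))
  expect_equal(r$p_value, fisher_exact(tab))
  expect_equal(r$odds_ratio, odds_ratio(tab))

  dz <- annotation_track(ids, rbinom(2000, 1, 0.05), kind = "binary")
  r2 <- run_enrichment(ch, dz, mode = "disease", alternative = "greater")
  expect_identical(unclass(r2$table), unclass(make_table(ch, dz)))
  expect_equal(r2$p_value,
               fisher_exact(make_table(ch, dz), "greater"))
})
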