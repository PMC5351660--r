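test_that("rank_values gives ascending ranks with midranks at ties", {
  expect_equal(rank_values(c(5, 1, 3)), c(3, 1, 2))
  expect_equal(rank_values(c(2, 2, 7)), c(1.5, 1.5, 3))
  expect_equal(rank_values(4), 1)
  expect_error(rank_values(numeric(0)), "empty")
  expect_error(rank_values(c(1, -2)), "nonnegative")

  # sort-based oracle: midrank of a value = mean of the positions it spans
  withr::with_seed(5, {
    for (rep in 1:20) {
      x <- sample(round(runif(17, 0, 5), 1)) # plenty of ties
      r <- rank_values(x)
      srt <- sort(x)
      expected <- vapply(x, function(v) mean(which(srt == v)), numeric(1))
      expect_equal(r, expected)
    }
  })
})

test_that("count_gene_pairs matches the closed form", {
  expect_identical(count_gene_pairs(20031), 200610465)
  expect_equal(count_gene_pairs(2), 1)
  expect_equal(count_gene_pairs(5), 10)
  expect_error(count_gene_pairs(1), ">= 2")
})

test_that("rank_diff is the absolute within-sample rank difference", {
  r <- c(3, 1, 2)
  expect_equal(rank_diff(r, 1, 2), 2)
  expect_equal(rank_diff(setNames(c(1.5, 1.5, 3), c("A", "B", "C")),
                         "A", "B"), 0)
  n <- 9
  expect_equal(rank_diff(seq_len(n), 1, n), n - 1)
  expect_error(rank_diff(r, 2, 2), "distinct")
})

test_that("exclusion_mask drops floor(fraction * n_pairs) closest pairs", {
  r <- rank_values(c(10, 11, 50)) # pairs: (1,2) diff 1, (1,3) 2, (2,3) 1...
  expect_equal(nrow(exclusion_mask(r, 0, gene_ids = c("GA", "GB", "GC"))), 0L)
  m <- exclusion_mask(r, 0.5, gene_ids = c("GA", "GB", "GC"))
  expect_equal(nrow(m), 1L) # floor(0.5 * 3)
  expect_equal(m$gene_i, "GA")
  expect_equal(m$gene_j, "GB") # the smallest rank difference
  expect_equal(nrow(exclusion_mask(r, 0.1, gene_ids = c("GA", "GB", "GC"))),
               0L) # floor(0.3) = 0
  expect_error(exclusion_mask(r, 1), "\\[0, 1\\)")
})

test_that("exclusion ties at the cut break lexicographically by gene pair", {
  # four genes in arithmetic progression: all adjacent pairs share rank diff 1
  r <- rank_values(c(1, 2, 3, 4))
  ids <- c("GD", "GC", "GB", "GA") # reversed so lexicographic != positional
  m <- exclusion_mask(r, fraction = 2 / 6 + 1e-9, gene_ids = ids)
  expect_equal(nrow(m), 2L)
  # diff-1 pairs are (GD,GC),(GC,GB),(GB,GA); lexicographic keys pick
  # (GA,GB) then (GB,GC)
  expect_equal(m$gene_i, c("GA", "GB"))
  expect_equal(m$gene_j, c("GB", "GC"))
})

test_that("consistency_score reproduces enumerable cases", {
  expect_equal(consistency_score(c(1, 2, 3), c(2, 4, 6))$score, 1)
  expect_equal(consistency_score(c(1, 2, 3), c(2, 1, 3))$score, 2 / 3)
  expect_equal(consistency_score(c(1, 2, 3), c(3, 2, 1))$score, 0)
})

test_that("consistency_score excludes ties from numerator and denominator", {
  out <- consistency_score(c(1, 1, 2, 3), c(4, 3, 3, 5))
  # pairs: (1,2) FF-tied, (2,3) FFPE-tied, rest evaluable
  expect_equal(out$n_tied, 2)
  expect_equal(out$n_evaluated, 4)
  expect_error(consistency_score(c(1, 1), c(2, 3)), "no evaluable")
})

test_that("consistency_score is symmetric at fraction 0 without ties", {
  withr::with_seed(42, {
    ff <- runif(30); fp <- runif(30)
    expect_equal(consistency_score(ff, fp), consistency_score(fp, ff))
  })
})

test_that("REO scores are invariant under strictly increasing transforms", {
  withr::with_seed(9, {
    ff <- exp(rnorm(40)); fp <- exp(rnorm(40))
    base <- consistency_score(ff, fp, fraction = 0.1)
    expect_equal(consistency_score(ff^3, fp, fraction = 0.1), base)
    expect_equal(consistency_score(ff, log1p(fp), fraction = 0.1), base)
    expect_equal(consistency_score(2 * ff + 1, sqrt(fp), fraction = 0.1),
                 base)
  })
})

test_that("blocked consistency kernel equals brute-force enumeration", {
  cases <- expand.grid(n = c(8, 20, 50), seed = c(1, 2, 3),
                       fraction = c(0, 0.1, 0.3, 0.5))
  for (ci in seq_len(nrow(cases))) {
    n <- cases$n[ci]
    withr::with_seed(cases$seed[ci], {
      ff <- round(exp(rnorm(n, 0, 1)), 1)  # rounding injects ties
      fp <- round(exp(rnorm(n, 0, 1)), 1)
    })
    ids <- sprintf("G%02d", seq_len(n))
    got <- consistency_score(ff, fp, fraction = cases$fraction[ci],
                             gene_ids = ids)
    want <- oracle_consistency(ff, fp, fraction = cases$fraction[ci],
                               gene_ids = ids)
    expect_equal(got$n_evaluated, want$n_evaluated,
                 info = sprintf("case %d", ci))
    expect_equal(got$k_consistent, want$k_consistent)
    expect_equal(got$n_tied, want$n_tied)
    expect_equal(got$n_excluded, want$n_excluded)
  }
})

test_that("exclusion_mask agrees with the oracle's excluded set", {
  withr::with_seed(13, {
    ff <- round(exp(rnorm(25)), 1)
  })
  ids <- sprintf("G%02d", 1:25)
  r <- rank_values(ff)
  for (f in c(0.1, 0.25, 0.6)) {
    m <- exclusion_mask(r, f, gene_ids = ids)
    want <- oracle_consistency(ff, ff, fraction = f, gene_ids = ids)
    expect_setequal(paste(m$gene_i, m$gene_j, sep = "|"),
                    want$excluded_keys)
  }
})

test_that("cohort_consistency averages per-pair scores", {
  m <- random_expr(30, 4, seed = 21)
  co <- paired_cohort(m, m * 2) # monotone: perfect consistency
  rep <- cohort_consistency(co, fractions = c(0, 0.2))
  expect_equal(nrow(rep), 8L)
  expect_true(all(rep$score == 1))
  summ <- consistency_summary(rep)
  expect_equal(summ$mean_score, c(1, 1))

  # arithmetic-mean contract on unequal scores
  ff <- c(1, 2, 3); fp1 <- c(2, 4, 6); fp2 <- c(2, 1, 3)
  co2 <- paired_cohort(
    expr_table(cbind(ff, ff), genes = c("G1", "G2", "G3")),
    expr_table(cbind(fp1, fp2), genes = c("G1", "G2", "G3"),
               samples = c("F1", "F2")))
  s <- consistency_summary(cohort_consistency(co2, fractions = 0))
  expect_equal(s$mean_score, mean(c(1, 2 / 3)))
})

test_that("consistency report writes per-pair rows plus per-fraction means", {
  m <- random_expr(20, 3, seed = 31)
  rep <- cohort_consistency(paired_cohort(m, m + 0.5), fractions = c(0, 0.1))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_consistency_report(rep, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep) + 2L)
  expect_equal(back$score[back$ff_id == "ALL"],
               consistency_summary(rep)$mean_score)
})
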