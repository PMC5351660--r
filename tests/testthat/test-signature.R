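# two-class fixture: pair (GA, GB) perfectly reversed; (GC, GD) reversed in
# exactly 85% of class0 (boundary); remaining genes class-invariant
boundary_classes <- function() {
  n0 <- 20
  ga0 <- rep(5, n0); gb0 <- rep(3, n0)                  # A > B always
  gc0 <- c(rep(8, 17), rep(0.5, 3)); gd0 <- rep(1, n0)  # C > D in 17/20 = 0.85
  filler0 <- matrix(rep(c(10, 20), each = n0), ncol = n0, byrow = TRUE)
  class0 <- rbind(GA = ga0, GB = gb0, GC = gc0, GD = gd0, filler0)
  rownames(class0)[5:6] <- c("GE", "GF")
  colnames(class0) <- sprintf("A%02d", 1:n0)
  class1 <- rbind(GA = gb0, GB = ga0, GC = gd0, GD = gc0, filler0)
  rownames(class1)[5:6] <- c("GE", "GF")
  colnames(class1) <- sprintf("B%02d", 1:n0)
  list(class0 = class0, class1 = class1)
}

test_that("find_reversal_pairs keeps strict-threshold reversals only", {
  cl <- boundary_classes()
  out <- find_reversal_pairs(cl$class0, cl$class1, threshold = 0.85)
  keys <- paste(out$gene_a, out$gene_b)
  expect_true("GA GB" %in% keys)      # 100% both ways
  expect_false("GC GD" %in% keys)     # exactly 85% is not "more than 85%"
  row <- out[keys == "GA GB", ]
  expect_equal(row$class0_direction, "gt")
  expect_equal(row$consistency_class0, 1)
  expect_equal(row$consistency_class1, 1)
  # at a lower threshold the boundary pair enters
  out80 <- find_reversal_pairs(cl$class0, cl$class1, threshold = 0.80)
  expect_true("GC GD" %in% paste(out80$gene_a, out80$gene_b))
  expect_error(find_reversal_pairs(cl$class0, cl$class1, threshold = 0.4),
               "0.5")
})

test_that("find_reversal_pairs is antisymmetric in its class arguments", {
  m0 <- random_expr(15, 25, seed = 211)
  withr::with_seed(212, {
    m1 <- m0[, sample(25)] * exp(rnorm(15, 0, 2)) # per-gene class shifts
  })
  colnames(m0) <- sprintf("A%02d", 1:25)
  colnames(m1) <- sprintf("B%02d", 1:25)
  fwd <- find_reversal_pairs(m0, m1, 0.7)
  rev <- find_reversal_pairs(m1, m0, 0.7)
  expect_gt(nrow(fwd), 0)
  expect_equal(paste(fwd$gene_a, fwd$gene_b), paste(rev$gene_a, rev$gene_b))
  expect_equal(fwd$class0_direction,
               as.character(ifelse(rev$class0_direction == "gt",
                                   "lt", "gt")))
  expect_equal(fwd$consistency_class0, rev$consistency_class1)
})

test_that("find_reversal_pairs equals the brute-force oracle", {
  withr::with_seed(223, {
    m0 <- matrix(round(exp(rnorm(15 * 20)), 1), 15, 20,
                 dimnames = list(sprintf("G%02d", 1:15),
                                 sprintf("A%02d", 1:20)))
    m1 <- m0 * exp(rnorm(15, 0, 2))
    colnames(m1) <- sprintf("B%02d", 1:20)
  })
  for (thr in c(0.7, 0.85)) {
    got <- find_reversal_pairs(m0, m1, thr)
    want <- oracle_reversal_pairs(m0, m1, thr)
    expect_equal(got$gene_a, want$gene_a, info = paste("thr", thr))
    expect_equal(got$gene_b, want$gene_b)
    expect_equal(got$class0_direction, want$class0_direction)
    expect_equal(got$consistency_class0, want$consistency_class0)
    expect_equal(got$consistency_class1, want$consistency_class1)
  }
})

test_that("score_pairs multiplies the two class mean rank differences", {
  # pair (GA, GB): class0 rank diffs {2, 4}, class1 rank diffs {3, 5};
  # per sample, values give GA rank 1 and GB the target rank
  build <- function(b_ranks) {
    sapply(b_ranks, function(rb) {
      v <- numeric(6)
      v[1] <- 0.1                        # GA lowest
      v[2] <- 0.1 + 0.1 * (rb - 1)       # GB at rank rb
      fill <- setdiff(seq(0.1, 0.6, 0.1), v[1:2])
      v[3:6] <- fill[1:4]
      v
    })
  }
  m0 <- build(c(3, 5)); m1 <- build(c(4, 6))
  dimnames(m0) <- list(c("GA", "GB", "GC", "GD", "GE", "GF"),
                       c("A1", "A2"))
  dimnames(m1) <- list(rownames(m0), c("B1", "B2"))
  pairs <- tibble::tibble(gene_a = "GA", gene_b = "GB",
                          class0_direction = "lt",
                          consistency_class0 = 1, consistency_class1 = 1)
  out <- score_pairs(pairs, m0, m1)
  expect_equal(out$mean_rankdiff_class0, 3) # (2 + 4) / 2
  expect_equal(out$mean_rankdiff_class1, 4) # (3 + 5) / 2
  expect_equal(out$score, 12)
  expect_equal(out$score, oracle_pair_score("GA", "GB", m0, m1))

  # constant rank difference in both classes: product of the two constants
  m0dup <- m0[, c(1, 1)]; colnames(m0dup) <- c("A1", "A2")
  m1dup <- m1[, c(1, 1)]; colnames(m1dup) <- c("B1", "B2")
  expect_equal(score_pairs(pairs, m0dup, m1dup)$score, 2 * 3)

  # a class with zero mean rank difference annihilates the score
  m0_tied <- m0; m0_tied["GB", ] <- m0_tied["GA", ]
  expect_equal(score_pairs(pairs, m0_tied, m1)$score, 0)
})

test_that("ranking by the rank-difference product equals ranking by geometric mean", {
  withr::with_seed(229, {
    d0 <- runif(50, 0, 500); d1 <- runif(50, 0, 500)
  })
  expect_equal(order(d0 * d1), order(sqrt(d0 * d1)))
})

test_that("select_signature keeps the odd top-k with lexicographic tiebreak", {
  scored <- tibble::tibble(
    gene_a = c("GB", "GA", "GC", "GD"),
    gene_b = c("GZ", "GZ", "GZ", "GZ"),
    class0_direction = "gt",
    consistency_class0 = 1, consistency_class1 = 1,
    score = c(7, 7, 9, 3)
  )
  sig <- select_signature(scored, k = 3)
  expect_equal(sig$pairs$gene_a, c("GC", "GA", "GB")) # 9 then tied 7s by id
  expect_equal(sig$pairs$score, c(9, 7, 7))
  all5 <- select_signature(dplyr::bind_rows(scored, scored[1, ] |>
                                              dplyr::mutate(gene_a = "GE")),
                           k = 5)
  expect_equal(nrow(all5$pairs), 5L)
  expect_error(select_signature(scored, k = 2), "odd")
  expect_error(select_signature(scored, k = 5), "exceeds")
})

test_that("tidy and glance summarize a signature", {
  cl <- boundary_classes()
  sig <- build_signature(cl$class0, cl$class1, threshold = 0.7, k = 1)
  expect_s3_class(tidy(sig), "tbl_df")
  g <- glance(sig)
  expect_equal(g$k, 1L)
  expect_equal(g$threshold, 0.7)
  expect_true(g$n_candidates >= 1)
})

test_that("signature selection recovers implanted reversal pairs", {
  cfg <- sim_config(n_genes = 60, n_samples = 40, seed = 17,
                    n_reversal_pairs = 3)
  tc <- simulate_two_class_cohort(cfg)
  sig <- build_signature(tc$class0, tc$class1, k = 3)
  expect_setequal(paste(sig$pairs$gene_a, sig$pairs$gene_b),
                  paste(tc$truth$gene_a, tc$truth$gene_b))
  # every selected pair also passes the brute-force candidate check
  want <- oracle_reversal_pairs(reosig:::as_expr_matrix(tc$class0),
                                reosig:::as_expr_matrix(tc$class1), 0.85)
  expect_true(all(paste(sig$pairs$gene_a, sig$pairs$gene_b) %in%
                    paste(want$gene_a, want$gene_b)))
})

test_that("signatures round-trip through TSV", {
  cl <- boundary_classes()
  sig <- build_signature(cl$class0, cl$class1, threshold = 0.7, k = 1,
                         class0_name = "cirrhosis", class1_name = "hcc")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, tf)
  back <- read_signature(tf)
  expect_equal(back$k, sig$k)
  expect_equal(back$class0_name, "cirrhosis")
  expect_equal(back$pairs$gene_a, sig$pairs$gene_a)
  expect_equal(back$pairs$score, sig$pairs$score)
})
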