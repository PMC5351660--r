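# Naive brute-force oracles. They enumerate every gene pair with combn()
# and plain loops, independently of the package's blocked kernels.

oracle_pair_table <- function(ff, gene_ids) {
  r <- rank(ff, ties.method = "average")
  cmb <- utils::combn(seq_along(ff), 2)
  a <- gene_ids[cmb[1, ]]
  b <- gene_ids[cmb[2, ]]
  swap <- b < a
  data.frame(
    i = cmb[1, ], j = cmb[2, ],
    key_a = ifelse(swap, b, a), key_b = ifelse(swap, a, b),
    rij = abs(r[cmb[1, ]] - r[cmb[2, ]])
  )
}

# mirrors the documented rule: drop floor(fraction * n_pairs) smallest-Rij
# pairs (lexicographic gene-id tiebreak), then count strict-sign agreement,
# removing pairs tied in either sample from numerator and denominator
oracle_consistency <- function(ff, ffpe, fraction = 0,
                               gene_ids = sprintf("G%02d", seq_along(ff))) {
  tab <- oracle_pair_table(ff, gene_ids)
  m <- floor(fraction * nrow(tab))
  ord <- order(tab$rij, tab$key_a, tab$key_b, method = "radix")
  tab <- tab[ord, ]
  excluded <- head(tab, m)
  kept <- tab[setdiff(seq_len(nrow(tab)), seq_len(m)), ]
  sf <- sign(ff[kept$i] - ff[kept$j])
  sp <- sign(ffpe[kept$i] - ffpe[kept$j])
  tied <- sf == 0 | sp == 0
  list(
    n_evaluated = sum(!tied),
    k_consistent = sum(!tied & sf == sp),
    n_tied = sum(tied),
    n_excluded = m,
    excluded_keys = paste(excluded$key_a, excluded$key_b, sep = "|")
  )
}

oracle_stable_pairs <- function(m, threshold) {
  genes <- rownames(m)
  out <- list()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):nrow(m)) {
      gt <- sum(m[i, ] > m[j, ])
      lt <- sum(m[i, ] < m[j, ])
      if (max(gt, lt) / ncol(m) >= threshold) {
        a <- genes[i]; b <- genes[j]
        dir <- if (gt >= lt) "gt" else "lt"
        if (b < a) { tmp <- a; a <- b; b <- tmp
                     dir <- if (dir == "gt") "lt" else "gt" }
        out[[length(out) + 1]] <- data.frame(
          gene_i = a, gene_j = b, direction = dir,
          support_fraction = max(gt, lt) / ncol(m))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_i = character(), gene_j = character(),
                      direction = character(), support_fraction = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_i, res$gene_j, method = "radix"), ]
}

oracle_reversal_pairs <- function(m0, m1, threshold) {
  genes <- rownames(m0)
  out <- list()
  for (i in seq_len(nrow(m0) - 1)) {
    for (j in (i + 1):nrow(m0)) {
      f0gt <- mean(m0[i, ] > m0[j, ])
      f0lt <- mean(m0[i, ] < m0[j, ])
      f1gt <- mean(m1[i, ] > m1[j, ])
      f1lt <- mean(m1[i, ] < m1[j, ])
      hit <- (f0gt > threshold && f1lt > threshold) ||
             (f0lt > threshold && f1gt > threshold)
      if (hit) {
        a <- genes[i]; b <- genes[j]
        dir <- if (f0gt > threshold) "gt" else "lt"
        c0 <- if (dir == "gt") f0gt else f0lt
        c1 <- if (dir == "gt") f1lt else f1gt
        if (b < a) { tmp <- a; a <- b; b <- tmp
                     dir <- if (dir == "gt") "lt" else "gt" }
        out[[length(out) + 1]] <- data.frame(
          gene_a = a, gene_b = b, class0_direction = dir,
          consistency_class0 = c0, consistency_class1 = c1)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      class0_direction = character(),
                      consistency_class0 = numeric(),
                      consistency_class1 = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_a, res$gene_b, method = "radix"), ]
}

# mean |R_a - R_b| per class times each other, full-sample midranks
oracle_pair_score <- function(a, b, m0, m1) {
  r0 <- apply(m0, 2, rank)
  r1 <- apply(m1, 2, rank)
  mean(abs(r0[a, ] - r0[b, ])) * mean(abs(r1[a, ] - r1[b, ]))
}

# geometric mean across pairs of within-pair fold-change ranks
oracle_rank_product <- function(ff, ffpe, pseudocount = 1) {
  lfc <- log2((ffpe + pseudocount) / (ff + pseudocount))
  rd <- apply(lfc, 2, rank)
  ru <- apply(-lfc, 2, rank)
  list(rp_down = apply(rd, 1, function(x) prod(x)^(1 / length(x))),
       rp_up = apply(ru, 1, function(x) prod(x)^(1 / length(x))))
}

oracle_maintained <- function(stable, v) {
  ok <- 0; n <- 0
  for (r in seq_len(nrow(stable))) {
    a <- stable$gene_i[r]; b <- stable$gene_j[r]
    if (!(a %in% names(v)) || !(b %in% names(v))) next
    n <- n + 1
    d <- v[[a]] - v[[b]]
    if ((stable$direction[r] == "gt" && d > 0) ||
        (stable$direction[r] == "lt" && d < 0)) ok <- ok + 1
  }
  list(n_evaluated = n, n_maintained = ok,
       fraction = if (n > 0) ok / n else NaN)
}
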