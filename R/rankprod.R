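#' Per-pair FFPE/FF fold changes
#'
#' For every gene and every FF/FFPE sample pair the fold change
#' `(ffpe + pseudocount) / (ff + pseudocount)` is computed; the pseudocount
#' keeps ratios finite and positive when linear-scale values contain zeros.
#'
#' @param cohort A [paired_cohort()].
#' @param pseudocount Positive value added to both numerator and denominator
#'   (default 1).
#' @param per_pair If `TRUE`, return the long per-pair table; otherwise the
#'   gene-level summary.
#' @return Gene-level: tibble `gene_id`, `mean_log2fc`, `direction`
#'   (sign of `mean_log2fc`). Long form adds one row per gene per pair with
#'   `ff_id`, `ffpe_id`, `fold_change`, `log2_fold_change`.
#' @export
paired_fold_changes <- function(cohort, pseudocount = 1, per_pair = FALSE) {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("pseudocount must be > 0")
  }
  lfc <- fold_change_matrix(cohort, pseudocount)
  if (per_pair) {
    long <- tibble::tibble(
      gene_id = rep(rownames(lfc), times = ncol(lfc)),
      ff_id = rep(cohort$pairing$ff_id, each = nrow(lfc)),
      ffpe_id = rep(cohort$pairing$ffpe_id, each = nrow(lfc)),
      log2_fold_change = as.vector(lfc)
    )
    long$fold_change <- 2^long$log2_fold_change
    return(long[, c("gene_id", "ff_id", "ffpe_id", "fold_change",
                    "log2_fold_change")])
  }
  mean_lfc <- rowMeans(lfc)
  tibble::tibble(
    gene_id = rownames(lfc),
    mean_log2fc = unname(mean_lfc),
    direction = sign(unname(mean_lfc))
  )
}

# genes x pairs matrix of log2((ffpe + pc) / (ff + pc))
fold_change_matrix <- function(cohort, pseudocount) {
  ff <- cohort$ff[, cohort$pairing$ff_id, drop = FALSE]
  fp <- cohort$ffpe[, cohort$pairing$ffpe_id, drop = FALSE]
  log2((fp + pseudocount) / (ff + pseudocount))
}

#' Paired Rank Product test for degradation-shifted genes
#'
#' Rank Product statistic for the one-sample paired design: within each
#' FF/FFPE pair, genes are ranked by fold change (ascending ranks flag
#' down-shifts, descending ranks flag up-shifts) and each gene's statistic is
#' the geometric mean of its ranks across pairs. Because only within-pair
#' ranks enter, the statistic is unaffected by between-pair scaling or batch
#' effects. Significance comes from permuting gene labels within each pair:
#' p-values are the fraction of permuted statistics at least as extreme, and
#' the false discovery estimate is the Rank Product convention
#' `E[false positives] / rank` (expected permuted exceedances per permutation
#' divided by the gene's position in the sorted statistic), truncated at 1.
#'
#' @param cohort A [paired_cohort()] with at least 2 pairs.
#' @param n_perm Number of permutations (>= 100; default 200).
#' @param pseudocount Passed to the fold-change computation.
#' @param seed Optional integer; fixes the permutation stream.
#' @return Tibble: `gene_id`, `rp_up`, `rp_down`, `p_up`, `p_down`,
#'   `fdr_up`, `fdr_down`, `mean_log2fc`.
#' @export
rank_product_test <- function(cohort, n_perm = 200, pseudocount = 1,
                              seed = NULL) {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (nrow(cohort$pairing) < 2L) abort("need at least 2 sample pairs")
  if (n_perm < 100) abort("n_perm must be >= 100 for stable FDR estimates")
  lfc <- fold_change_matrix(cohort, pseudocount)
  G <- nrow(lfc)
  P <- ncol(lfc)
  rank_dn <- apply(lfc, 2L, rank, ties.method = "average")
  rank_up <- apply(-lfc, 2L, rank, ties.method = "average")
  log_rp_dn <- rowMeans(log(rank_dn))
  log_rp_up <- rowMeans(log(rank_up))

  run_perms <- function() {
    null_dn <- matrix(0, G, n_perm)
    null_up <- matrix(0, G, n_perm)
    for (b in seq_len(n_perm)) {
      acc_dn <- numeric(G)
      acc_up <- numeric(G)
      for (p in seq_len(P)) {
        idx <- sample.int(G) # permute gene labels within this pair
        acc_dn <- acc_dn + log(rank_dn[idx, p])
        acc_up <- acc_up + log(rank_up[idx, p])
      }
      null_dn[, b] <- acc_dn / P
      null_up[, b] <- acc_up / P
    }
    list(dn = null_dn, up = null_up)
  }
  nulls <- if (is.null(seed)) run_perms() else withr::with_seed(seed, run_perms())

  # count permuted statistics <= each observed one (smaller RP = stronger)
  exceed <- function(obs, null_vals) {
    srt <- sort(as.vector(null_vals))
    findInterval(obs, srt)
  }
  c_dn <- exceed(log_rp_dn, nulls$dn)
  c_up <- exceed(log_rp_up, nulls$up)
  pfp <- function(cnt, obs) {
    pmin(1, (cnt / n_perm) / rank(obs, ties.method = "max"))
  }
  tibble::tibble(
    gene_id = rownames(lfc),
    rp_up = unname(exp(log_rp_up)),
    rp_down = unname(exp(log_rp_dn)),
    p_up = unname(pmax(c_up, 1) / (n_perm * G)),
    p_down = unname(pmax(c_dn, 1) / (n_perm * G)),
    fdr_up = unname(pfp(c_up, log_rp_up)),
    fdr_down = unname(pfp(c_dn, log_rp_dn)),
    mean_log2fc = unname(rowMeans(lfc))
  )
}

#' Histogram of absolute log2 fold changes for a DEG set
#'
#' Counts differentially expressed genes in `|log2FC|` bins `[0,1)`, `[1,2)`,
#' `[2,3)`, `>=3`; every bin from `[1,2)` upward holds genes with at least a
#' 2-fold change.
#'
#' @param fc Gene-level output of [paired_fold_changes()].
#' @param deg_ids Character vector of DEG gene ids (must be a subset of
#'   `fc$gene_id`).
#' @return Tibble of class `reo_fc_bins` with columns `bin`, `count`.
#' @export
fold_change_bins <- function(fc, deg_ids = fc$gene_id) {
  if (!all(deg_ids %in% fc$gene_id)) {
    abort("deg_ids must be a subset of fc$gene_id")
  }
  lv <- c("[0,1)", "[1,2)", "[2,3)", ">=3")
  a <- abs(fc$mean_log2fc[match(deg_ids, fc$gene_id)])
  binned <- cut(a, breaks = c(0, 1, 2, 3, Inf), labels = lv, right = FALSE)
  counts <- table(factor(binned, levels = lv))
  out <- tibble::tibble(bin = factor(lv, levels = lv),
                        count = as.integer(counts[lv]))
  class(out) <- c("reo_fc_bins", class(out))
  out
}

#' Direction consistency of degradation effects across tissues
#'
#' Given per-tissue DEG tables, restricts to the genes shared by all tissues
#' and tests whether their up/down directions agree everywhere more often
#' than chance (two-sided exact binomial test against 0.5).
#'
#' @param deg_list Named list (>= 2 tissues) of gene-level
#'   [paired_fold_changes()] outputs, or of named numeric vectors of mean
#'   log2 fold changes.
#' @return One-row tibble: `n_tissues`, `n_shared`, `n_consistent`,
#'   `fraction`, `p_value`.
#' @export
direction_consistency_test <- function(deg_list) {
  if (!is.list(deg_list) || length(deg_list) < 2L) {
    abort("need DEG direction maps for at least 2 tissues")
  }
  dirs <- lapply(deg_list, function(d) {
    if (is.data.frame(d)) {
      setNames(sign(d$mean_log2fc), d$gene_id)
    } else if (is.numeric(d) && !is.null(names(d))) {
      sign(d)
    } else {
      abort("each element must be a fold-change table or a named numeric vector")
    }
  })
  shared <- Reduce(intersect, lapply(dirs, names))
  if (length(shared) == 0L) abort("no gene is shared by all tissue DEG sets")
  mat <- vapply(dirs, function(d) d[shared], numeric(length(shared)))
  mat <- matrix(mat, nrow = length(shared))
  consistent <- apply(mat, 1L, function(r) all(r == r[1L]) && r[1L] != 0)
  n_cons <- sum(consistent)
  tibble::tibble(
    n_tissues = length(dirs),
    n_shared = length(shared),
    n_consistent = n_cons,
    fraction = n_cons / length(shared),
    p_value = binom.test(n_cons, length(shared), p = 0.5,
                         alternative = "two.sided")$p.value
  )
}
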