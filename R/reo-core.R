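#' Ascending expression ranks within one sample
#'
#' Genes are ranked by expression in ascending order (rank 1 = lowest); genes
#' with exactly equal values share the midrank of the positions they span.
#'
#' @param values Numeric vector of finite, nonnegative expression values.
#' @return Numeric vector of (mid)ranks, same length and names as `values`.
#' @export
#' @examples
#' rank_values(c(5, 1, 3))   # 3 1 2
#' rank_values(c(2, 2, 7))   # 1.5 1.5 3
rank_values <- function(values) {
  if (length(values) == 0L) abort("cannot rank an empty vector")
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 0)) {
    abort("values must be finite and nonnegative")
  }
  rank(values, ties.method = "average")
}

#' Per-sample rank transform of an expression table
#'
#' Applies [rank_values()] to every sample column.
#'
#' @param x Expression table or matrix.
#' @return A tibble of the same shape holding within-sample ranks.
#' @export
rank_expression <- function(x) {
  m <- as_expr_matrix(x)
  expr_tbl(apply(m, 2L, rank_values))
}

#' Number of unordered gene pairs
#'
#' @param n_genes Number of genes (>= 2).
#' @return `n_genes * (n_genes - 1) / 2`.
#' @export
#' @examples
#' count_gene_pairs(20031)  # 200610465
count_gene_pairs <- function(n_genes) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 2) {
    abort("n_genes must be a single number >= 2")
  }
  n_genes * (n_genes - 1) / 2
}

#' Within-sample absolute rank difference of a gene pair
#'
#' The distance `|R_i - R_j|` between the ranks of two genes in one sample;
#' pairs with small rank difference have the closest expression levels.
#'
#' @param ranks Rank vector for one sample (see [rank_values()]).
#' @param i,j Gene indices, or gene names if `ranks` is named.
#' @return Nonnegative number.
#' @export
rank_diff <- function(ranks, i, j) {
  if (is.character(i)) i <- match(i, names(ranks))
  if (is.character(j)) j <- match(j, names(ranks))
  if (is.na(i) || is.na(j)) abort("gene not found in rank vector")
  if (i == j) abort("rank_diff needs two distinct genes")
  abs(ranks[[i]] - ranks[[j]])
}

#' Gene pairs excluded as closest-expressed in one reference sample
#'
#' Identifies the `floor(fraction * n_pairs)` gene pairs with the smallest
#' within-sample rank difference in the reference (FF) sample — the pairs
#' whose ordering is least reliable. Ties at the cut are broken by
#' lexicographic gene-id pair so the set is deterministic. This materializes
#' all pairs and is meant for modest gene counts; the consistency kernel
#' applies the identical rule without materializing pairs.
#'
#' @param ff_ranks Rank vector of the reference sample (named by gene, or
#'   supply `gene_ids`).
#' @param fraction Fraction of pairs to exclude, in `[0, 1)`.
#' @param gene_ids Gene identifiers (defaults to `names(ff_ranks)`).
#' @return Tibble with columns `gene_i`, `gene_j`, `rank_diff` (the excluded
#'   pairs; `gene_i < gene_j` lexicographically).
#' @export
exclusion_mask <- function(ff_ranks, fraction, gene_ids = names(ff_ranks)) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    abort("fraction must lie in [0, 1)")
  }
  n <- length(ff_ranks)
  if (n < 2L) abort("need at least 2 genes")
  if (is.null(gene_ids)) gene_ids <- sprintf("G%d", seq_len(n))
  m <- floor(fraction * count_gene_pairs(n))
  pairs <- all_pairs_tbl(ff_ranks, gene_ids)
  pairs <- pairs[order(pairs$rank_diff, pairs$gene_i, pairs$gene_j), ]
  out <- pairs[seq_len(m), c("gene_i", "gene_j", "rank_diff"), drop = FALSE]
  tibble::as_tibble(out)
}

# all unordered pairs with lexicographically ordered gene ids and rank diff
all_pairs_tbl <- function(ranks, gene_ids) {
  idx <- which(upper.tri(diag(length(ranks))), arr.ind = TRUE)
  a <- gene_ids[idx[, 1L]]
  b <- gene_ids[idx[, 2L]]
  swap <- b < a
  tibble::tibble(
    gene_i = ifelse(swap, b, a),
    gene_j = ifelse(swap, a, b),
    i = idx[, 1L], j = idx[, 2L],
    rank_diff = abs(ranks[idx[, 1L]] - ranks[idx[, 2L]])
  )
}

#' REO consistency between one FF sample and its paired FFPE sample
#'
#' Every unordered gene pair with a strict ordering (no tie) in both samples
#' is scored: consistent if the direction of `expr_i - expr_j` agrees, else
#' reversed. Pairs tied in either sample count toward neither `k` nor `n`.
#' Optionally the `floor(fraction * n_pairs)` pairs with the closest
#' expression (smallest rank difference) in the FF sample are excluded first.
#' The score is `k / n`.
#'
#' @param ff,ffpe Expression vectors over the identical gene list.
#' @param fraction Fraction of closest FF pairs to exclude, in `[0, 1)`.
#' @param gene_ids Gene identifiers (defaults to `names(ff)`).
#' @return One-row tibble: `n_evaluated`, `k_consistent`, `n_tied`,
#'   `n_excluded`, `score`.
#' @export
#' @examples
#' consistency_score(c(1, 2, 3), c(2, 1, 3))$score  # 2/3
consistency_score <- function(ff, ffpe, fraction = 0, gene_ids = names(ff)) {
  if (length(ff) != length(ffpe)) {
    abort("ff and ffpe must cover the identical gene list")
  }
  if (length(ff) < 2L) abort("need at least 2 genes")
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    abort("fraction must lie in [0, 1)")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("G%d", seq_along(ff))
  r2 <- as.integer(round(2 * rank_values(ff)))
  m <- floor(fraction * count_gene_pairs(length(ff)))
  res <- cpp_pair_consistency(as.numeric(ff), as.numeric(ffpe), r2, m,
                              as.character(gene_ids))
  if (res$n_evaluated == 0) {
    abort("no evaluable gene pairs (all tied or excluded)")
  }
  tibble::tibble(
    n_evaluated = res$n_evaluated,
    k_consistent = res$k_consistent,
    n_tied = res$n_tied,
    n_excluded = res$n_excluded,
    score = res$k_consistent / res$n_evaluated
  )
}

#' REO consistency across a paired FF/FFPE cohort
#'
#' Runs [consistency_score()] for every FF/FFPE sample pair at each requested
#' exclusion fraction.
#'
#' @param cohort A [paired_cohort()].
#' @param fractions Exclusion fractions to evaluate (default `0`, `0.1`,
#'   `0.2`).
#' @return Tibble of class `reo_consistency` with one row per sample pair per
#'   fraction: `ff_id`, `ffpe_id`, `fraction`, `n_evaluated`, `k_consistent`,
#'   `n_tied`, `n_excluded`, `score`.
#' @seealso [consistency_summary()], [autoplot.reo_consistency()]
#' @export
cohort_consistency <- function(cohort, fractions = c(0, 0.1, 0.2)) {
  stopifnot(inherits(cohort, "paired_cohort"))
  if (nrow(cohort$pairing) == 0L) abort("cohort pairing is empty")
  grid <- tidyr::expand_grid(cohort$pairing, fraction = fractions)
  rows <- purrr::pmap(grid, function(ff_id, ffpe_id, fraction) {
    rec <- consistency_score(cohort$ff[, ff_id], cohort$ffpe[, ffpe_id],
                             fraction = fraction,
                             gene_ids = rownames(cohort$ff))
    dplyr::bind_cols(tibble::tibble(ff_id = ff_id, ffpe_id = ffpe_id,
                                    fraction = fraction), rec)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("reo_consistency", class(out))
  out
}

#' Mean consistency score per exclusion fraction
#'
#' @param report Output of [cohort_consistency()].
#' @return Tibble with `fraction`, `n_samples`, `mean_score`.
#' @export
consistency_summary <- function(report) {
  report |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(n_samples = dplyr::n(),
                     mean_score = mean(.data$score),
                     .groups = "drop")
}

#' Write a consistency report (per-pair rows plus per-fraction means)
#'
#' @param report Output of [cohort_consistency()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_consistency_report <- function(report, path) {
  summ <- consistency_summary(report) |>
    dplyr::transmute(ff_id = "ALL", ffpe_id = "ALL", .data$fraction,
                     n_evaluated = NA_real_, k_consistent = NA_real_,
                     n_tied = NA_real_, n_excluded = NA_real_,
                     score = .data$mean_score)
  readr::write_tsv(dplyr::bind_rows(tibble::as_tibble(report), summ), path,
                   progress = FALSE)
  invisible(path)
}
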