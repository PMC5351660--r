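#' Mine gene pairs with highly stable REOs across a cohort
#'
#' For every unordered gene pair the fraction of samples with
#' `expr_i > expr_j` (and with `expr_i < expr_j`) is computed; exact ties
#' count toward neither direction, while the denominator stays the full
#' cohort size. A pair is emitted with its majority direction when that
#' direction's support reaches `threshold`. With `threshold = 0.99` this is
#' the classical highly-stable-REO rule used on accumulated normal cohorts.
#'
#' @param x Expression table or matrix with at least 2 samples.
#' @param threshold Minimum support fraction, in `(0.5, 1]`; comparison is
#'   `>=`.
#' @return Tibble of class `stable_pairs` with columns `gene_i`, `gene_j`
#'   (lexicographically ordered within pair, rows sorted), `direction`
#'   (`"gt"` if `gene_i > gene_j`, `"lt"` otherwise), `support_fraction`,
#'   `n_gt`, `n_lt`; attributes `threshold` and `cohort_size`.
#' @export
mine_stable_pairs <- function(x, threshold = 0.99) {
  m <- as_expr_matrix(x)
  if (ncol(m) < 2L) abort("cohort needs at least 2 samples")
  if (nrow(m) < 2L) abort("cohort needs at least 2 genes")
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1) {
    abort("threshold must lie in (0.5, 1]: direction is ill-defined below")
  }
  res <- cpp_stable_pairs(m, threshold)
  genes <- rownames(m)
  out <- tibble::tibble(
    gene_i = genes[res$i],
    gene_j = genes[res$j],
    direction = as.character(ifelse(res$n_gt >= res$n_lt, "gt", "lt")),
    n_gt = res$n_gt,
    n_lt = res$n_lt
  )
  # canonical lexicographic order within each pair
  swap <- out$gene_j < out$gene_i
  if (any(swap)) {
    tmp <- out$gene_i[swap]
    out$gene_i[swap] <- out$gene_j[swap]
    out$gene_j[swap] <- tmp
    out$direction[swap] <- ifelse(out$direction[swap] == "gt", "lt", "gt")
    tmp <- out$n_gt[swap]
    out$n_gt[swap] <- out$n_lt[swap]
    out$n_lt[swap] <- tmp
  }
  out$support_fraction <- pmax(out$n_gt, out$n_lt) / ncol(m)
  out <- out[order(out$gene_i, out$gene_j, method = "radix"),
             c("gene_i", "gene_j", "direction", "support_fraction",
               "n_gt", "n_lt")]
  attr(out, "threshold") <- threshold
  attr(out, "cohort_size") <- ncol(m)
  class(out) <- c("stable_pairs", class(out))
  out
}

#' Fraction of stable REOs maintained in one sample
#'
#' Checks each stable pair's consensus direction in a single (e.g. FFPE)
#' sample. A pair counts as maintained only when its direction holds
#' strictly; a tie in the sample counts as not maintained. Pairs whose genes
#' are absent from the sample are dropped and reported.
#'
#' @param sample A named expression vector, or a one-sample expression table
#'   (gene column plus one value column).
#' @param stable A [mine_stable_pairs()] result.
#' @return One-row tibble: `n_evaluated`, `n_maintained`, `n_dropped`,
#'   `fraction`.
#' @export
maintained_fraction <- function(sample, stable) {
  v <- as_sample_vector(sample)
  ia <- match(stable$gene_i, names(v))
  ja <- match(stable$gene_j, names(v))
  keep <- !is.na(ia) & !is.na(ja)
  n_dropped <- sum(!keep)
  if (!any(keep)) abort("no stable pair is evaluable in this sample")
  d <- v[ia[keep]] - v[ja[keep]]
  want_gt <- stable$direction[keep] == "gt"
  maintained <- (want_gt & d > 0) | (!want_gt & d < 0)
  tibble::tibble(
    n_evaluated = sum(keep),
    n_maintained = sum(maintained),
    n_dropped = n_dropped,
    fraction = sum(maintained) / sum(keep)
  )
}

#' Write / read a stable-pair table
#'
#' TSV with columns `gene_i`, `gene_j`, `direction`, `support_fraction`,
#' `n_gt`, `n_lt` plus header comments recording the mining threshold and
#' cohort size.
#'
#' @param stable A [mine_stable_pairs()] result.
#' @param path File path.
#' @return `path` (write) or a `stable_pairs` tibble (read).
#' @export
write_stable_pairs <- function(stable, path) {
  body <- readr::format_tsv(tibble::as_tibble(stable))
  writeLines(c(
    sprintf("# threshold=%s", format(attr(stable, "threshold"))),
    sprintf("# cohort_size=%d", attr(stable, "cohort_size")),
    sub("\n$", "", body)
  ), path)
  invisible(path)
}

#' @rdname write_stable_pairs
#' @export
read_stable_pairs <- function(path) {
  hdr <- readLines(path, n = 2L)
  out <- readr::read_tsv(path, comment = "#", col_types = "cccdii",
                         progress = FALSE, show_col_types = FALSE)
  attr(out, "threshold") <- as.numeric(sub("# threshold=", "", hdr[1L]))
  attr(out, "cohort_size") <- as.integer(sub("# cohort_size=", "", hdr[2L]))
  class(out) <- c("stable_pairs", class(out))
  out
}

# one-sample input: named numeric vector, or data frame (gene col + value col)
as_sample_vector <- function(sample) {
  if (is.data.frame(sample)) {
    if (ncol(sample) != 2L) {
      abort("a one-sample table needs exactly a gene column and a value column")
    }
    v <- as.numeric(sample[[2L]])
    names(v) <- as.character(sample[[1L]])
  } else if (is.numeric(sample)) {
    if (is.null(names(sample))) abort("sample vector must be named by gene")
    v <- sample
  } else {
    abort("sample must be a named numeric vector or a two-column data frame")
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("expression values must be finite and nonnegative")
  }
  v
}
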