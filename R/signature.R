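#' Find reversal gene pairs between two phenotype classes
#'
#' A pair qualifies when one ordering direction holds strictly in more than
#' `threshold` of the class-0 samples while the opposite direction holds
#' strictly in more than `threshold` of the class-1 samples (the comparisons
#' are strict `>`, so support of exactly `threshold` is excluded). Exact ties
#' count toward neither direction. Swapping the class arguments returns the
#' same pairs with directions flipped.
#'
#' @param class0,class1 Expression tables of the two phenotypes. Gene lists
#'   are intersected; an empty intersection is an error.
#' @param threshold Support threshold in `(0.5, 1)`; default `0.85`.
#' @return Tibble with columns `gene_a`, `gene_b` (lexicographic within
#'   pair), `class0_direction` (`"gt"` if `gene_a > gene_b` in class 0),
#'   `consistency_class0`, `consistency_class1`; attribute `threshold`.
#' @export
find_reversal_pairs <- function(class0, class1, threshold = 0.85) {
  m0 <- as_expr_matrix(class0)
  m1 <- as_expr_matrix(class1)
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold >= 1) {
    abort("threshold must lie in (0.5, 1)")
  }
  genes <- intersect(rownames(m0), rownames(m1))
  if (length(genes) < 2L) abort("classes share fewer than 2 genes")
  m0 <- m0[genes, , drop = FALSE]
  m1 <- m1[genes, , drop = FALSE]
  res <- cpp_reversal_pairs(m0, m1, threshold)
  a <- genes[res$i]
  b <- genes[res$j]
  # direction in class 0 decides the pair's orientation
  f0gt <- res$n0_gt / ncol(m0)
  f0lt <- res$n0_lt / ncol(m0)
  f1gt <- res$n1_gt / ncol(m1)
  f1lt <- res$n1_lt / ncol(m1)
  dir_gt <- f0gt > threshold  # else the qualifying direction was a < b
  out <- tibble::tibble(
    gene_a = a,
    gene_b = b,
    class0_direction = as.character(ifelse(dir_gt, "gt", "lt")),
    consistency_class0 = as.numeric(ifelse(dir_gt, f0gt, f0lt)),
    consistency_class1 = as.numeric(ifelse(dir_gt, f1lt, f1gt))
  )
  swap <- out$gene_b < out$gene_a
  if (any(swap)) {
    tmp <- out$gene_a[swap]
    out$gene_a[swap] <- out$gene_b[swap]
    out$gene_b[swap] <- tmp
    out$class0_direction[swap] <-
      ifelse(out$class0_direction[swap] == "gt", "lt", "gt")
  }
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), ]
  attr(out, "threshold") <- threshold
  out
}

#' Score reversal pairs by mean absolute rank difference in each class
#'
#' For each candidate pair the mean over class-0 samples of the within-sample
#' absolute rank difference `|R_a - R_b|` is multiplied by the same mean over
#' class-1 samples. Ranks are computed per sample over the full shared gene
#' list, not over the candidate genes only. Ranking pairs by this product is
#' equivalent to ranking by the geometric mean of the two class means; larger
#' scores mean a stronger reversal.
#'
#' @param pairs Output of [find_reversal_pairs()] (or any tibble with
#'   `gene_a`, `gene_b`).
#' @param class0,class1 The expression tables the pairs were mined from.
#' @return `pairs` with added columns `mean_rankdiff_class0`,
#'   `mean_rankdiff_class1`, `score`.
#' @export
score_pairs <- function(pairs, class0, class1) {
  m0 <- as_expr_matrix(class0)
  m1 <- as_expr_matrix(class1)
  genes <- intersect(rownames(m0), rownames(m1))
  r0 <- apply(m0[genes, , drop = FALSE], 2L, rank_values)
  r1 <- apply(m1[genes, , drop = FALSE], 2L, rank_values)
  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  if (anyNA(ia) || anyNA(ib)) abort("pair gene absent from the class tables")
  d0 <- rowMeans(abs(r0[ia, , drop = FALSE] - r0[ib, , drop = FALSE]))
  d1 <- rowMeans(abs(r1[ia, , drop = FALSE] - r1[ib, , drop = FALSE]))
  out <- dplyr::mutate(pairs,
                       mean_rankdiff_class0 = unname(d0),
                       mean_rankdiff_class1 = unname(d1),
                       score = unname(d0 * d1))
  attr(out, "threshold") <- attr(pairs, "threshold")
  out
}

#' Select the top-k reversal pairs as a classification signature
#'
#' Takes the `k` pairs with the largest score (ties broken by lexicographic
#' `gene_a`, `gene_b`). `k` must be odd so that the majority vote of
#' [classify_samples()] is always decisive when no pair is tied.
#'
#' @param scored Output of [score_pairs()].
#' @param k Odd number of pairs to keep (default 5).
#' @param class0_name,class1_name Labels the classifier will emit.
#' @return An object of class `reo_signature`.
#' @export
select_signature <- function(scored, k = 5,
                             class0_name = "class0", class1_name = "class1") {
  if (k %% 2 == 0) abort("k must be odd: the majority rule needs a tiebreak-free vote")
  if (k > nrow(scored)) {
    abort(sprintf("k = %d exceeds the %d candidate pairs", k, nrow(scored)))
  }
  if (is.null(scored$score)) abort("candidates must be scored (see score_pairs)")
  ord <- order(-scored$score, scored$gene_a, scored$gene_b, method = "radix")
  pairs <- tibble::as_tibble(scored[ord[seq_len(k)], ])
  structure(
    list(pairs = pairs, k = as.integer(k),
         class0_name = class0_name, class1_name = class1_name,
         threshold = attr(scored, "threshold"),
         n_candidates = nrow(scored)),
    class = "reo_signature"
  )
}

#' Train a reversal-pair signature in one call
#'
#' Convenience wrapper: [find_reversal_pairs()], [score_pairs()],
#' [select_signature()].
#'
#' @inheritParams find_reversal_pairs
#' @inheritParams select_signature
#' @return An object of class `reo_signature`.
#' @export
build_signature <- function(class0, class1, threshold = 0.85, k = 5,
                            class0_name = "class0", class1_name = "class1") {
  find_reversal_pairs(class0, class1, threshold = threshold) |>
    score_pairs(class0, class1) |>
    select_signature(k = k, class0_name = class0_name,
                     class1_name = class1_name)
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("<reo_signature> %d pairs (%s vs %s), threshold > %s, %d candidates\n",
              x$k, x$class0_name, x$class1_name,
              format(x$threshold %||% NA), x$n_candidates))
  print(x$pairs, ...)
  invisible(x)
}

#' @describeIn select_signature Tidy the pair table of a signature.
#' @param x A `reo_signature`.
#' @param ... Unused.
#' @export
tidy.reo_signature <- function(x, ...) x$pairs

#' @describeIn select_signature One-row summary of a signature.
#' @export
glance.reo_signature <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    threshold = x$threshold %||% NA_real_,
    n_candidates = x$n_candidates,
    class0_name = x$class0_name,
    class1_name = x$class1_name,
    min_score = min(x$pairs$score),
    max_score = max(x$pairs$score)
  )
}

#' Write / read a signature table
#'
#' TSV mirroring the pair table plus header comments holding `k`, the
#' training threshold and the class names.
#'
#' @param sig A `reo_signature`.
#' @param path File path.
#' @return `path` (write) or a `reo_signature` (read).
#' @export
write_signature <- function(sig, path) {
  writeLines(c(
    sprintf("# k=%d", sig$k),
    sprintf("# threshold=%s", format(sig$threshold %||% NA)),
    sprintf("# class0_name=%s", sig$class0_name),
    sprintf("# class1_name=%s", sig$class1_name),
    sprintf("# n_candidates=%d", sig$n_candidates),
    sub("\n$", "", readr::format_tsv(sig$pairs))
  ), path)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  hdr <- readLines(path, n = 5L)
  val <- function(key) sub(paste0("# ", key, "="), "", grep(key, hdr, value = TRUE)[1L])
  pairs <- readr::read_tsv(path, comment = "#", progress = FALSE,
                           show_col_types = FALSE)
  structure(
    list(pairs = pairs, k = as.integer(val("k")),
         class0_name = val("class0_name"), class1_name = val("class1_name"),
         threshold = suppressWarnings(as.numeric(val("threshold"))),
         n_candidates = as.integer(val("n_candidates"))),
    class = "reo_signature"
  )
}
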