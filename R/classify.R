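#' Classify samples by majority vote of a reversal-pair signature
#'
#' Each signature pair casts one vote per sample: for class 0 when the pair's
#' class-0 ordering holds strictly, for class 1 when the reverse holds
#' strictly, and a tie vote when the two genes are exactly equal. A sample is
#' labelled class 0 only when class-0 votes exceed half of `k`; otherwise it
#' is labelled class 1, so tie votes can never help class 0. The rule depends
#' only on within-sample orderings and is therefore invariant under any
#' strictly increasing transform of a sample's values.
#'
#' @param x Expression table (or matrix) containing every signature gene.
#' @param signature A [select_signature()] / [build_signature()] result.
#' @return Tibble with one row per sample: `sample_id`, `votes_class0`,
#'   `votes_class1`, `ties`, `label`.
#' @export
classify_samples <- function(x, signature) {
  stopifnot(inherits(signature, "reo_signature"))
  m <- as_expr_matrix(x)
  pairs <- signature$pairs
  ia <- match(pairs$gene_a, rownames(m))
  ib <- match(pairs$gene_b, rownames(m))
  missing <- unique(c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)]))
  if (length(missing)) {
    abort(paste0("signature gene(s) absent from the sample table: ",
                 paste(missing, collapse = ", ")))
  }
  d <- m[ia, , drop = FALSE] - m[ib, , drop = FALSE]      # pairs x samples
  want_gt <- pairs$class0_direction == "gt"
  vote0 <- (want_gt & d > 0) | (!want_gt & d < 0)
  vote1 <- (want_gt & d < 0) | (!want_gt & d > 0)
  k <- signature$k
  v0 <- colSums(vote0)
  v1 <- colSums(vote1)
  tibble::tibble(
    sample_id = colnames(m),
    votes_class0 = as.integer(v0),
    votes_class1 = as.integer(v1),
    ties = as.integer(k - v0 - v1),
    label = unname(ifelse(v0 > k / 2, signature$class0_name,
                          signature$class1_name))
  )
}

#' Classify one sample
#'
#' @param sample Named expression vector or one-sample table (see
#'   [maintained_fraction()] for the accepted forms).
#' @param signature A `reo_signature`.
#' @return One-row tibble as in [classify_samples()].
#' @export
classify_sample <- function(sample, signature) {
  v <- as_sample_vector(sample)
  m <- matrix(v, ncol = 1L, dimnames = list(names(v), "sample"))
  classify_samples(m, signature)
}

#' Per-class sensitivity of a signature on a labelled dataset
#'
#' All samples of `x` are assumed to share one true class label; the
#' sensitivity is the fraction of them assigned that label by
#' [classify_samples()]. Per-sample votes are attached as the
#' `"predictions"` attribute.
#'
#' @param x Expression table whose samples all have class `true_label`.
#' @param signature A `reo_signature`.
#' @param true_label Either the signature's `class0_name` or `class1_name`.
#' @return One-row tibble: `true_label`, `n_samples`, `n_correct`,
#'   `sensitivity`.
#' @export
evaluate_sensitivity <- function(x, signature, true_label) {
  stopifnot(inherits(signature, "reo_signature"))
  if (!true_label %in% c(signature$class0_name, signature$class1_name)) {
    abort(sprintf("true_label must be '%s' or '%s'",
                  signature$class0_name, signature$class1_name))
  }
  pred <- classify_samples(x, signature)
  if (nrow(pred) == 0L) abort("no samples to evaluate")
  out <- tibble::tibble(
    true_label = true_label,
    n_samples = nrow(pred),
    n_correct = sum(pred$label == true_label),
    sensitivity = sum(pred$label == true_label) / nrow(pred)
  )
  attr(out, "predictions") <- pred
  out
}

#' Write predictions to TSV
#'
#' @param predictions Output of [classify_samples()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(predictions, path, progress = FALSE)
  invisible(path)
}
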