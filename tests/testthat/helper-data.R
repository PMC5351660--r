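# fixture builders shared across test files

expr_table <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  tibble::as_tibble(cbind(data.frame(gene_id = genes),
                          as.data.frame(m)))
}

random_expr <- function(n_genes, n_samples, seed, round_digits = NULL) {
  withr::with_seed(seed, {
    mu <- rnorm(n_genes, 0, 2) # per-gene baseline so orderings have structure
    m <- exp(mu + matrix(rnorm(n_genes * n_samples, 0, 0.7),
                         n_genes, n_samples))
    if (!is.null(round_digits)) m <- round(m, round_digits) # inject ties
    dimnames(m) <- list(sprintf("G%02d", seq_len(n_genes)),
                        sprintf("S%02d", seq_len(n_samples)))
    m
  })
}

# hand-built signature over explicit pairs (class0 direction "gt" unless given)
toy_signature <- function(gene_a, gene_b, direction = NULL,
                          class0_name = "class0", class1_name = "class1") {
  k <- length(gene_a)
  pairs <- tibble::tibble(
    gene_a = gene_a, gene_b = gene_b,
    class0_direction = direction %||% rep("gt", k),
    consistency_class0 = 1, consistency_class1 = 1,
    score = rev(seq_len(k))
  )
  structure(list(pairs = pairs, k = k, class0_name = class0_name,
                 class1_name = class1_name, threshold = 0.85,
                 n_candidates = k),
            class = "reo_signature")
}

`%||%` <- rlang::`%||%`
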