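#' Configuration for the synthetic paired FF/FFPE generator
#'
#' The generator works on the log scale. Each gene g gets a baseline log-mean
#' `mu_g` drawn uniformly over `[-mu_halfwidth, mu_halfwidth]` (a wide, flat
#' dynamic range so that pair rank differences depend only weakly on where a
#' pair sits in it) and a fixed degradation shift `delta_g ~ N(0,
#' sigma_gene_deg^2)` drawn once per gene universe — the same `delta_g` is
#' reused whenever the same configuration degrades another cohort, which
#' reproduces degradation effects that are gene-specific but
#' tissue-independent. FF values are `exp(mu_g + e)` with sample noise
#' `e ~ N(0, sigma_sample^2)`; FFPE values add `delta_g` plus FFPE noise
#' `N(0, (storage_scale * sigma_ffpe)^2)` in log space, so values stay
#' strictly positive and fold changes and ordering flips are tunable
#' independently.
#'
#' Reversal pairs for the two-phenotype design are implanted by placing the
#' two genes of pair p at log-means `center_p +/- pair_separation/2` in class
#' 0; in class 1 gene A is shifted down and gene B up by `reversal_delta`,
#' flipping the pair's expected ordering. Pair centers are spread evenly
#' across the middle of the dynamic range, at least `pair_separation` apart,
#' so no cross-pair combination becomes a reversal pair itself.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_samples Samples per cohort / per class (default 80).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @param mu_halfwidth Half-width of the uniform log-mean spread (default 6
#'   natural-log units, about 17 log2 units of dynamic range).
#' @param sigma_sample Log-scale sample noise SD (default 0.3).
#' @param sigma_gene_deg SD of the per-gene degradation shift (default 0.7;
#'   about 32% of genes then exceed a 2-fold shift, i.e. `|delta_g| >=
#'   log(2)`).
#' @param sigma_ffpe Log-scale FFPE measurement noise SD (default 0.3).
#' @param storage_scale Multiplier on `sigma_ffpe` emulating longer paraffin
#'   storage (default 1).
#' @param n_reversal_pairs Number of implanted reversal pairs (default 5).
#' @param pair_separation Within-pair log-mean separation in class 0
#'   (default 2).
#' @param reversal_delta Class-1 log shift applied to each implanted gene
#'   (default 2; the class-1 separation is then
#'   `2 * reversal_delta - pair_separation`).
#' @param reversal_pairs Optional explicit tibble (`gene_a`, `gene_b`,
#'   `delta`) referencing generator gene ids; overrides the automatic
#'   placement (the drawn means are then used as-is).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_samples = 80, seed = 1,
                       mu_halfwidth = 6, sigma_sample = 0.3,
                       sigma_gene_deg = 0.7, sigma_ffpe = 0.3,
                       storage_scale = 1, n_reversal_pairs = 5,
                       pair_separation = 2, reversal_delta = 2,
                       reversal_pairs = NULL) {
  if (n_genes < 2) abort("n_genes must be >= 2")
  if (any(c(sigma_sample, sigma_gene_deg, sigma_ffpe) < 0)) {
    abort("noise SDs must be >= 0")
  }
  if (is.null(reversal_pairs) && 2 * n_reversal_pairs > n_genes) {
    abort("n_genes too small for the requested implanted pairs")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
         seed = as.integer(seed), mu_halfwidth = mu_halfwidth,
         sigma_sample = sigma_sample, sigma_gene_deg = sigma_gene_deg,
         sigma_ffpe = sigma_ffpe, storage_scale = storage_scale,
         n_reversal_pairs = as.integer(n_reversal_pairs),
         pair_separation = pair_separation,
         reversal_delta = reversal_delta,
         reversal_pairs = reversal_pairs,
         rng = "Mersenne-Twister"),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in setdiff(names(x), "reversal_pairs")) {
    cat(sprintf("  %s: %s\n", f, paste(format(x[[f]]), collapse = " ")))
  }
  cat(sprintf("  implanted pairs: %d\n", nrow(sim_truth(x))))
  invisible(x)
}

# Gene universe: ids, baseline log-means (with implants placed), per-gene
# degradation shifts, and the implant truth table. Depends only on the
# config (drawn under cfg$seed), so every cohort from one config shares it.
gene_universe <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_genes
    ids <- sprintf("G%05d", seq_len(n))
    mu <- runif(n, -cfg$mu_halfwidth, cfg$mu_halfwidth)
    delta_deg <- rnorm(n, 0, cfg$sigma_gene_deg)
    if (is.null(cfg$reversal_pairs)) {
      k <- cfg$n_reversal_pairs
      if (k > 0) {
        span <- max(cfg$mu_halfwidth - 1, 0)
        centers <- if (k == 1) 0 else seq(-span + 0.2, span - 0.2,
                                          length.out = k)
        a_idx <- 2 * seq_len(k) - 1
        b_idx <- 2 * seq_len(k)
        mu[a_idx] <- centers + cfg$pair_separation / 2
        mu[b_idx] <- centers - cfg$pair_separation / 2
        truth <- tibble::tibble(
          gene_a = ids[a_idx], gene_b = ids[b_idx],
          delta = cfg$reversal_delta, class0_direction = "gt"
        )
      } else {
        truth <- tibble::tibble(gene_a = character(), gene_b = character(),
                                delta = numeric(),
                                class0_direction = character())
      }
    } else {
      rp <- cfg$reversal_pairs
      truth <- tibble::tibble(
        gene_a = as.character(rp$gene_a), gene_b = as.character(rp$gene_b),
        delta = if ("delta" %in% names(rp)) rp$delta else cfg$reversal_delta
      )
      bad <- setdiff(c(truth$gene_a, truth$gene_b), ids)
      if (length(bad)) {
        abort(paste0("implanted pair gene(s) not in universe: ",
                     paste(bad, collapse = ", ")))
      }
      if (any(truth$gene_a == truth$gene_b)) {
        abort("implanted pairs must reference two distinct genes")
      }
      truth$class0_direction <-
        ifelse(mu[match(truth$gene_a, ids)] > mu[match(truth$gene_b, ids)],
               "gt", "lt")
      genes_used <- c(truth$gene_a, truth$gene_b)
      if (anyDuplicated(genes_used)) {
        message("note: implanted pairs share genes")
      }
    }
    list(ids = ids, mu = mu, delta_deg = delta_deg, truth = truth)
  })
}

#' Implanted reversal-pair truth table of a configuration
#'
#' @param cfg A [sim_config()].
#' @return Tibble `gene_a`, `gene_b`, `delta`, `class0_direction`.
#' @export
sim_truth <- function(cfg) gene_universe(cfg)$truth

#' Per-gene degradation shifts of a configuration
#'
#' The fixed log-scale shift `delta_g` every FFPE sample of this gene
#' universe receives.
#'
#' @param cfg A [sim_config()].
#' @return Tibble `gene_id`, `delta`.
#' @export
degradation_profile <- function(cfg) {
  u <- gene_universe(cfg)
  tibble::tibble(gene_id = u$ids, delta = u$delta_deg)
}

#' Simulate a fresh-frozen cohort
#'
#' @param cfg A [sim_config()].
#' @param n_samples Number of samples (default `cfg$n_samples`).
#' @param seed Seed for the sample-level noise (default `cfg$seed + 1`); the
#'   gene universe always comes from `cfg$seed`, so cohorts drawn with
#'   different `seed` share genes, means and degradation shifts.
#' @param sample_prefix Prefix for sample ids.
#' @return An expression tibble (genes x samples).
#' @export
simulate_ff_cohort <- function(cfg, n_samples = cfg$n_samples,
                               seed = cfg$seed + 1, sample_prefix = "FF") {
  u <- gene_universe(cfg)
  vals <- withr::with_seed(seed, {
    eps <- matrix(rnorm(cfg$n_genes * n_samples, 0, cfg$sigma_sample),
                  cfg$n_genes, n_samples)
    exp(u$mu + eps)
  })
  dimnames(vals) <- list(u$ids, paste0(sample_prefix, seq_len(n_samples)))
  expr_tbl(vals)
}

#' Degrade an FF cohort into a paired FFPE cohort
#'
#' Applies the configuration's fixed per-gene degradation shift plus FFPE
#' measurement noise in log space: `ffpe = exp(log(ff) + delta_g + eta)`,
#' `eta ~ N(0, (storage_scale * sigma_ffpe)^2)`. The construction never
#' produces negative values and pairs each FFPE sample with the FF sample it
#' was derived from.
#'
#' @param ff An FF expression table whose genes belong to `cfg`'s universe
#'   (any table produced from `cfg`).
#' @param cfg The [sim_config()] that defines the degradation profile.
#' @param seed Seed for the FFPE noise (default `cfg$seed + 11`).
#' @param storage_scale Multiplier on `sigma_ffpe` (default
#'   `cfg$storage_scale`); larger values emulate longer storage.
#' @return A [paired_cohort()] (FFPE sample ids get the suffix `"_FFPE"`).
#' @export
degrade_to_ffpe <- function(ff, cfg, seed = cfg$seed + 11,
                            storage_scale = cfg$storage_scale) {
  u <- gene_universe(cfg)
  m <- as_expr_matrix(ff)
  idx <- match(rownames(m), u$ids)
  if (anyNA(idx)) abort("ff contains genes outside the config's universe")
  sd_eta <- storage_scale * cfg$sigma_ffpe
  ffpe <- withr::with_seed(seed, {
    eta <- matrix(rnorm(length(m), 0, sd_eta), nrow(m), ncol(m))
    exp(log(m) + u$delta_deg[idx] + eta)
  })
  dimnames(ffpe) <- list(rownames(m), paste0(colnames(m), "_FFPE"))
  paired_cohort(m, ffpe)
}

#' Simulate a two-phenotype cohort with implanted reversal pairs
#'
#' Class 0 uses the baseline log-means; class 1 shifts every implanted
#' gene A down and gene B up by that pair's `delta`, flipping the pair's
#' expected ordering, while all other genes keep class-invariant means.
#'
#' @param cfg A [sim_config()].
#' @param n_samples Samples per class (default `cfg$n_samples`).
#' @param seed Base seed for the sample noise (default `cfg$seed + 2`); the
#'   two classes use `seed` and `seed + 1`.
#' @param prefixes Sample-id prefixes for the two classes.
#' @return List with elements `class0`, `class1` (expression tibbles) and
#'   `truth` (the implanted-pair table).
#' @export
simulate_two_class_cohort <- function(cfg, n_samples = cfg$n_samples,
                                      seed = cfg$seed + 2,
                                      prefixes = c("C0_", "C1_")) {
  u <- gene_universe(cfg)
  truth <- u$truth
  mu1 <- u$mu
  if (nrow(truth) > 0) {
    ia <- match(truth$gene_a, u$ids)
    ib <- match(truth$gene_b, u$ids)
    down <- ifelse(truth$class0_direction == "gt", ia, ib)
    up <- ifelse(truth$class0_direction == "gt", ib, ia)
    for (p in seq_len(nrow(truth))) { # additive so shared genes accumulate
      mu1[down[p]] <- mu1[down[p]] - truth$delta[p]
      mu1[up[p]] <- mu1[up[p]] + truth$delta[p]
    }
  }
  draw <- function(mu, s, prefix) {
    vals <- withr::with_seed(s, {
      eps <- matrix(rnorm(cfg$n_genes * n_samples, 0, cfg$sigma_sample),
                    cfg$n_genes, n_samples)
      exp(mu + eps)
    })
    dimnames(vals) <- list(u$ids, paste0(prefix, seq_len(n_samples)))
    expr_tbl(vals)
  }
  list(class0 = draw(u$mu, seed, prefixes[1L]),
       class1 = draw(mu1, seed + 1, prefixes[2L]),
       truth = truth)
}

#' Write a generator configuration next to its outputs
#'
#' Serializes the resolved configuration (and the implant truth table) so a
#' synthetic dataset is self-describing.
#'
#' @param cfg A [sim_config()].
#' @param path Output file path (JSON).
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$reversal_pairs <- if (is.null(x$reversal_pairs)) NULL else
    as.data.frame(x$reversal_pairs)
  x$truth <- as.data.frame(sim_truth(cfg))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
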