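#' Run the full REO analysis on a synthetic study
#'
#' Executes the whole pipeline on data drawn from one [sim_config()]:
#'
#' 1. simulate a normal FF cohort and a smaller paired FF set, degrade the
#'    paired set to FFPE, and score FF-vs-FFPE REO consistency at each
#'    exclusion fraction;
#' 2. mine highly stable REOs from the accumulated normal cohort and measure
#'    how many are maintained in each FFPE sample;
#' 3. simulate the two-phenotype cohorts, train the reversal-pair signature,
#'    and evaluate per-class sensitivity on freshly generated FF and
#'    FFPE-degraded test cohorts;
#' 4. run the paired Rank Product stage on two "tissues" sharing the same
#'    degradation profile, bin the DEG fold changes, and test cross-tissue
#'    direction consistency.
#'
#' Every stage is seeded from the configuration, so a rerun with the same
#' config reproduces every output byte for byte.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all stage outputs (TSV) and
#'   a JSON summary are written there.
#' @param fractions Exclusion fractions for the consistency stage.
#' @param stable_threshold Support threshold for stable-REO mining.
#' @param reversal_threshold Support threshold for reversal-pair selection.
#' @param k Signature size (odd).
#' @param n_paired Number of FF/FFPE pairs for the consistency and Rank
#'   Product stages (default 12).
#' @param n_test_samples Test-cohort size per class (default 100).
#' @param n_perm Rank Product permutations (default 200).
#' @param fdr_cutoff DEG call threshold on the Rank Product FDR (default
#'   0.05).
#' @param class_names Length-2 labels for the two phenotypes.
#' @return A list of class `reo_pipeline`; see the `summary` element for the
#'   headline numbers of each stage.
#' @export
run_reo_pipeline <- function(config = sim_config(), out_dir = NULL,
                             fractions = c(0, 0.1, 0.2),
                             stable_threshold = 0.99,
                             reversal_threshold = 0.85, k = 5,
                             n_paired = 12, n_test_samples = 100,
                             n_perm = 200, fdr_cutoff = 0.05,
                             class_names = c("class0", "class1")) {
  stopifnot(inherits(config, "sim_config"))
  if (k %% 2 == 0) abort("k must be odd")
  seed <- config$seed

  # -- stage 1: paired FF/FFPE consistency -----------------------------------
  ff_paired <- simulate_ff_cohort(config, n_samples = n_paired,
                                  seed = seed + 101, sample_prefix = "P")
  cohort <- drop_allzero_genes(
    degrade_to_ffpe(ff_paired, config, seed = seed + 102)
  )
  consistency <- cohort_consistency(cohort, fractions = fractions)
  cons_summary <- consistency_summary(consistency)

  # -- stage 2: stable REOs in the accumulated normal cohort -----------------
  normal <- simulate_ff_cohort(config, seed = seed + 103, sample_prefix = "N")
  stable <- mine_stable_pairs(normal, threshold = stable_threshold)
  maintained <- purrr::map_dfr(cohort$pairing$ffpe_id, function(sid) {
    dplyr::bind_cols(
      tibble::tibble(sample_id = sid),
      maintained_fraction(cohort$ffpe[, sid], stable)
    )
  })

  # -- stage 3: signature training and validation ----------------------------
  train <- simulate_two_class_cohort(config, seed = seed + 104)
  signature <- build_signature(train$class0, train$class1,
                               threshold = reversal_threshold, k = k,
                               class0_name = class_names[1L],
                               class1_name = class_names[2L])
  test <- simulate_two_class_cohort(config, n_samples = n_test_samples,
                                    seed = seed + 105,
                                    prefixes = c("T0_", "T1_"))
  test_ffpe0 <- degrade_to_ffpe(test$class0, config, seed = seed + 106)
  test_ffpe1 <- degrade_to_ffpe(test$class1, config, seed = seed + 107)
  sens <- dplyr::bind_rows(
    dplyr::mutate(
      evaluate_sensitivity(test$class0, signature, class_names[1L]),
      material = "FF", .before = 1L),
    dplyr::mutate(
      evaluate_sensitivity(test$class1, signature, class_names[2L]),
      material = "FF", .before = 1L),
    dplyr::mutate(
      evaluate_sensitivity(test_ffpe0$ffpe, signature, class_names[1L]),
      material = "FFPE", .before = 1L),
    dplyr::mutate(
      evaluate_sensitivity(test_ffpe1$ffpe, signature, class_names[2L]),
      material = "FFPE", .before = 1L)
  )
  truth_keys <- pair_key(train$truth$gene_a, train$truth$gene_b)
  sig_keys <- pair_key(signature$pairs$gene_a, signature$pairs$gene_b)
  recovered <- length(intersect(sig_keys, truth_keys))

  # -- stage 4: Rank Product degradation DEGs --------------------------------
  tissue2 <- drop_allzero_genes(degrade_to_ffpe(
    simulate_ff_cohort(config, n_samples = n_paired, seed = seed + 108,
                       sample_prefix = "Q"),
    config, seed = seed + 109
  ))
  rp1 <- rank_product_test(cohort, n_perm = n_perm, seed = seed + 110)
  rp2 <- rank_product_test(tissue2, n_perm = n_perm, seed = seed + 111)
  deg1 <- rp1$gene_id[rp1$fdr_up < fdr_cutoff | rp1$fdr_down < fdr_cutoff]
  deg2 <- rp2$gene_id[rp2$fdr_up < fdr_cutoff | rp2$fdr_down < fdr_cutoff]
  fc1 <- paired_fold_changes(cohort)
  fc2 <- paired_fold_changes(tissue2)
  bins <- fold_change_bins(fc1, deg1)
  direction <- direction_consistency_test(list(
    tissue1 = dplyr::filter(fc1, .data$gene_id %in% deg1),
    tissue2 = dplyr::filter(fc2, .data$gene_id %in% deg2)
  ))

  summary <- list(
    n_genes = nrow(cohort$ff),
    n_paired = n_paired,
    mean_consistency = setNames(cons_summary$mean_score,
                                paste0("fraction_", cons_summary$fraction)),
    n_stable_pairs = nrow(stable),
    mean_maintained_fraction = mean(maintained$fraction),
    n_candidate_pairs = signature$n_candidates,
    signature_pairs = sig_keys,
    n_implanted_recovered = recovered,
    sensitivity = setNames(
      sens$sensitivity, paste(sens$material, sens$true_label, sep = "_")),
    n_deg = c(tissue1 = length(deg1), tissue2 = length(deg2)),
    n_deg_2fold = sum(bins$count[-1L]),
    direction_consistent_fraction = direction$fraction
  )

  result <- structure(
    list(config = config, consistency = consistency,
         consistency_summary = cons_summary, stable = stable,
         maintained = maintained, signature = signature, truth = train$truth,
         sensitivity = sens, rank_product = list(tissue1 = rp1, tissue2 = rp2),
         fc_bins = bins, direction_consistency = direction,
         summary = summary),
    class = "reo_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_consistency_report(result$consistency, p("consistency.tsv"))
  write_stable_pairs(result$stable, p("stable_pairs.tsv"))
  readr::write_tsv(result$maintained, p("maintained.tsv"), progress = FALSE)
  write_signature(result$signature, p("signature.tsv"))
  readr::write_tsv(result$sensitivity, p("sensitivity.tsv"), progress = FALSE)
  readr::write_tsv(result$rank_product$tissue1, p("rank_product.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$fc_bins, p("fold_change_bins.tsv"),
                   progress = FALSE)
  write_sim_config(result$config, p("config.json"))
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.reo_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<reo_pipeline>\n")
  cat(sprintf("  genes: %d; paired samples: %d\n", s$n_genes, s$n_paired))
  cat("  mean FF-FFPE consistency:",
      paste(sprintf("%s=%.4f", names(s$mean_consistency),
                    s$mean_consistency), collapse = ", "), "\n")
  cat(sprintf("  stable pairs: %d (maintained in FFPE: %.4f)\n",
              s$n_stable_pairs, s$mean_maintained_fraction))
  cat(sprintf("  signature: %d pairs from %d candidates (%d implanted recovered)\n",
              x$signature$k, s$n_candidate_pairs, s$n_implanted_recovered))
  cat("  sensitivity:",
      paste(sprintf("%s=%.3f", names(s$sensitivity), s$sensitivity),
            collapse = ", "), "\n")
  cat(sprintf("  DEGs: %d / %d; >=2-fold: %d; direction-consistent: %.4f\n",
              s$n_deg[1L], s$n_deg[2L], s$n_deg_2fold,
              s$direction_consistent_fraction))
  invisible(x)
}
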