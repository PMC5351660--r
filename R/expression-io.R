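#' Read a gene-by-sample expression table
#'
#' Reads a tab-separated expression matrix: first column gene identifiers,
#' header row of sample identifiers, numeric body on linear (non-logged)
#' scale. Row and column order are preserved from the file.
#'
#' @param path Path to a TSV file.
#' @return A tibble whose first column (`gene_id`) holds gene identifiers and
#'   whose remaining columns are numeric sample profiles.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tS1\tS2", "G1\t1\t2", "G2\t3\t4"), tf)
#' read_expression(tf)
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    abort(paste0("parse error: '", path, "' is empty"))
  }
  # readr's lazy parsing warning is redundant: problems() is raised below
  x <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE,
    show_col_types = FALSE
  ))
  probs <- readr::problems(x)
  if (nrow(probs) > 0L) {
    p <- probs[1L, ]
    abort(sprintf(
      "parse error in '%s' at row %d, column %d: expected %s, got '%s'",
      path, p$row, p$col, p$expected, p$actual
    ))
  }
  if (ncol(x) < 2L) abort("expression table needs at least one sample column")
  names(x)[1L] <- "gene_id"
  validate_expression(x)
  x
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression()]: `read_expression(write_expression(x, f))`
#' reproduces `x`.
#'
#' @param x Expression table (tibble/data frame, first column gene ids) or a
#'   numeric matrix with gene row names and sample column names.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  x <- as_expr_tbl(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' Two-column TSV (`probe_id`, `gene_id`), one row per mapping; probes mapping
#' to several genes appear on several rows.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `probe_id` and `gene_id`.
#' @export
read_probe_map <- function(path) {
  m <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                       show_col_types = FALSE)
  names(m)[1:2] <- c("probe_id", "gene_id")
  m
}

#' Read an FF/FFPE sample pairing file
#'
#' Two-column TSV (`ff_id`, `ffpe_id`), one row per patient.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `ff_id` and `ffpe_id`.
#' @export
read_pairing <- function(path) {
  p <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                       show_col_types = FALSE)
  names(p)[1:2] <- c("ff_id", "ffpe_id")
  p
}

#' Collapse a probe-level table to gene level
#'
#' Probes mapping to zero or to multiple genes are dropped; when several
#' probes map to one gene, the gene's value per sample is the arithmetic mean
#' of the probe values. Output genes are sorted by gene identifier.
#'
#' @param x Probe-level expression table (first column probe ids).
#' @param probe_map Tibble with columns `probe_id`, `gene_id` (see
#'   [read_probe_map()]).
#' @return A gene-level expression tibble.
#' @export
collapse_probes <- function(x, probe_map) {
  x <- as_expr_tbl(x)
  if (!is.data.frame(probe_map) || nrow(probe_map) == 0L) {
    abort("probe_map must be a non-empty data frame with probe_id, gene_id")
  }
  map <- dplyr::distinct(
    tibble::tibble(probe_id = as.character(probe_map[[1L]]),
                   gene_id = as.character(probe_map[[2L]]))
  )
  n_targets <- dplyr::count(map, .data$probe_id, name = "n_genes")
  unique_map <- map |>
    dplyr::inner_join(n_targets, by = "probe_id") |>
    dplyr::filter(.data$n_genes == 1L) |>
    dplyr::select("probe_id", "gene_id")

  names(x)[1L] <- "probe_id"
  out <- x |>
    dplyr::inner_join(unique_map, by = "probe_id") |>
    dplyr::select(-"probe_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene_id)
  validate_expression(out)
  out
}

#' Pair FF and FFPE expression tables from the same patients
#'
#' Bundles a fresh-frozen and an FFPE expression table with a one-to-one
#' sample pairing. Both tables must carry the identical gene list in the same
#' order.
#'
#' @param ff,ffpe Expression tables (tibble or matrix, see
#'   [read_expression()]).
#' @param pairing Optional tibble with columns `ff_id`, `ffpe_id`. By default
#'   samples are paired by column position (both tables must then have the
#'   same number of samples).
#' @return A `paired_cohort` object.
#' @export
paired_cohort <- function(ff, ffpe, pairing = NULL) {
  ff <- as_expr_matrix(ff)
  ffpe <- as_expr_matrix(ffpe)
  if (!identical(rownames(ff), rownames(ffpe))) {
    abort("ff and ffpe must share an identical gene list in identical order")
  }
  if (is.null(pairing)) {
    if (ncol(ff) != ncol(ffpe)) {
      abort("positional pairing needs equal sample counts; supply `pairing`")
    }
    pairing <- tibble::tibble(ff_id = colnames(ff), ffpe_id = colnames(ffpe))
  } else {
    pairing <- tibble::tibble(ff_id = as.character(pairing[[1L]]),
                              ffpe_id = as.character(pairing[[2L]]))
  }
  if (anyDuplicated(pairing$ff_id) || anyDuplicated(pairing$ffpe_id)) {
    abort("pairing must be a bijection: duplicated sample id")
  }
  missing_ff <- setdiff(pairing$ff_id, colnames(ff))
  missing_fp <- setdiff(pairing$ffpe_id, colnames(ffpe))
  if (length(missing_ff) || length(missing_fp)) {
    abort(paste0("pairing refers to unknown samples: ",
                 paste(c(missing_ff, missing_fp), collapse = ", ")))
  }
  structure(list(ff = ff, ffpe = ffpe, pairing = pairing),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf(
    "<paired_cohort> %d genes; %d FF x %d FFPE samples; %d pairs\n",
    nrow(x$ff), ncol(x$ff), ncol(x$ffpe), nrow(x$pairing)
  ))
  invisible(x)
}

#' Remove genes with zero expression throughout a paired cohort
#'
#' Drops exactly the genes whose value is zero in every FF sample and every
#' FFPE sample of the cohort; the order of surviving genes is preserved. The
#' filter is defined jointly over both materials: a gene detected in a single
#' FFPE (or FF) sample is retained. The operation is idempotent.
#'
#' @param cohort A [paired_cohort()].
#' @return A `paired_cohort` restricted to the surviving genes.
#' @export
drop_allzero_genes <- function(cohort) {
  stopifnot(inherits(cohort, "paired_cohort"))
  keep <- rowSums(cohort$ff != 0) > 0 | rowSums(cohort$ffpe != 0) > 0
  paired_cohort(cohort$ff[keep, , drop = FALSE],
                cohort$ffpe[keep, , drop = FALSE],
                cohort$pairing)
}

#' Remove genes that are zero in every sample of one table
#'
#' Per-matrix counterpart of [drop_allzero_genes()] for unpaired cohorts.
#'
#' @param x Expression table.
#' @return Expression tibble without all-zero genes, order preserved.
#' @export
drop_zero_genes <- function(x) {
  m <- as_expr_matrix(x)
  expr_tbl(m[rowSums(m != 0) > 0, , drop = FALSE])
}

#' Column-concatenate cohorts over their shared gene list
#'
#' Emulates accumulating normal samples from several data sources: gene lists
#' are intersected (keeping the first cohort's order) and sample columns are
#' concatenated.
#'
#' @param cohorts A list of expression tables.
#' @param quiet Suppress the message reporting the intersection size.
#' @return A single expression tibble over the shared genes.
#' @export
accumulate_cohorts <- function(cohorts, quiet = FALSE) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1L)
  mats <- lapply(cohorts, as_expr_matrix)
  genes <- Reduce(intersect, lapply(mats, rownames))
  if (length(genes) < 2L) abort("fewer than 2 genes shared across cohorts")
  all_ids <- unlist(lapply(mats, colnames))
  if (anyDuplicated(all_ids)) abort("duplicate sample ids across cohorts")
  if (!quiet) {
    message(sprintf("accumulating %d cohorts: %d shared genes, %d samples",
                    length(mats), length(genes), length(all_ids)))
  }
  expr_tbl(do.call(cbind, lapply(mats, function(m) m[genes, , drop = FALSE])))
}

# ---- internal representation helpers ---------------------------------------

# Canonical internal form: numeric matrix, gene ids as rownames, sample ids
# as colnames. User-facing functions accept either the tidy table or this.
as_expr_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("expression matrix needs gene rownames and sample colnames")
    }
    m <- x
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2L) abort("expression table needs at least one sample column")
    ids <- as.character(x[[1L]])
    body <- x[, -1L, drop = FALSE]
    ok <- vapply(body, is.numeric, logical(1L))
    if (!all(ok)) {
      abort(paste0("non-numeric sample column: ",
                   paste(names(body)[!ok], collapse = ", ")))
    }
    m <- as.matrix(body)
    rownames(m) <- ids
  } else {
    abort("expected an expression table (data frame) or numeric matrix")
  }
  check_expr_values(m)
  m
}

as_expr_tbl <- function(x) {
  if (is.data.frame(x)) {
    validate_expression(x)
    out <- tibble::as_tibble(x)
    names(out)[1L] <- "gene_id"
    out$gene_id <- as.character(out$gene_id)
    return(out)
  }
  expr_tbl(as_expr_matrix(x))
}

expr_tbl <- function(m) {
  tibble::as_tibble(
    c(list(gene_id = rownames(m)),
      as.list(as.data.frame(m, optional = TRUE)))
  )
}

check_expr_values <- function(m) {
  if (anyDuplicated(rownames(m))) {
    dup <- rownames(m)[duplicated(rownames(m))][1L]
    abort(paste0("duplicate gene id: ", dup))
  }
  if (anyDuplicated(colnames(m))) {
    dup <- colnames(m)[duplicated(colnames(m))][1L]
    abort(paste0("duplicate sample id: ", dup))
  }
  if (!is.numeric(m)) abort("expression values must be numeric")
  if (any(!is.finite(m))) abort("expression values must be finite (no NA)")
  if (any(m < 0)) abort("expression values must be nonnegative")
  invisible(m)
}

validate_expression <- function(x) {
  invisible(as_expr_matrix(as.data.frame(x)))
}
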