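#' Read a feature-by-sample matrix from a tab-delimited file
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers (CpG site ids or gene symbols); every other cell is numeric.
#' Empty fields and the tokens `NA`, `NaN`, `null` are read as missing.
#' Methylation matrices are validated to the beta-value range `[0, 1]`; a
#' cell out of range or non-numeric raises an error naming the offending
#' feature and sample.
#'
#' @param path Path to the TSV file.
#' @param kind `"methylation"` or `"expression"` (controls range checks).
#' @return A numeric matrix, features x samples, with dimnames.
#' @export
read_matrix <- function(path, kind = c("methylation", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort_invalid(sprintf("File not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA", "NaN", "null"))
  if (ncol(df) < 2L) {
    abort_invalid(sprintf(
      "Malformed header in %s: need a feature-id column plus >= 1 sample.",
      path
    ))
  }
  feature_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) {
    abort_invalid(sprintf("Duplicate sample ids in %s.", path))
  }
  if (anyDuplicated(feature_ids)) {
    abort_invalid(sprintf("Duplicate feature ids in %s.", path))
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_invalid(sprintf(
      "Non-numeric value '%s' at feature '%s', sample '%s' in %s.",
      raw[bad[1, 1], bad[1, 2]], feature_ids[bad[1, 1]],
      sample_ids[bad[1, 2]], path
    ))
  }
  dimnames(num) <- list(feature_ids, sample_ids)
  if (kind == "methylation") {
    out_of_range <- which(num < 0 | num > 1, arr.ind = TRUE)
    if (nrow(out_of_range) > 0) {
      abort_invalid(sprintf(
        "Beta value %g out of [0, 1] at site '%s', sample '%s' in %s.",
        num[out_of_range[1, 1], out_of_range[1, 2]],
        feature_ids[out_of_range[1, 1]],
        sample_ids[out_of_range[1, 2]], path
      ))
    }
  } else if (any(num < 0, na.rm = TRUE)) {
    abort_invalid(sprintf("Negative expression value in %s.", path))
  }
  num
}

#' Write a feature-by-sample matrix as tab-delimited text
#'
#' Inverse of [read_matrix()]: full-precision values, `NA` for missing,
#' feature ids in the first column under the header `feature_id`.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path) {
  check_matrix(mat, "mat")
  df <- data.frame(feature_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CpG-to-gene annotation table
#'
#' Two tab-separated columns, `cpg_id` and `gene_id`; each CpG must map to
#' exactly one gene (a gene may own several CpGs).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `cpg_id`, `gene_id`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) abort_invalid("Annotation needs two columns.")
  names(df)[1:2] <- c("cpg_id", "gene_id")
  validate_annotation(df[1:2])
}

#' Read sample group labels
#'
#' Two tab-separated columns, `sample_id` and `group` (e.g. cancer type).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id`, `group`.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) abort_invalid("Group table needs two columns.")
  names(df)[1:2] <- c("sample_id", "group")
  if (anyDuplicated(df$sample_id)) {
    abort_invalid("Duplicate sample ids in the group table.")
  }
  tibble::as_tibble(df[1:2])
}

#' Restrict two matrices to their shared samples
#'
#' Columns are restricted to the exact-identifier intersection, ordered as
#' in the methylation matrix. Analysis proceeds on these overlapping samples
#' only.
#'
#' @param meth Methylation matrix (sites x samples).
#' @param expr Expression matrix (genes x samples).
#' @return A list with the aligned `meth` and `expr` plus a `report` tibble
#'   (`modality`, `n_total`, `n_kept`, `n_dropped`). An empty intersection
#'   is a fatal error.
#' @export
intersect_samples <- function(meth, expr) {
  check_matrix(meth, "meth")
  check_matrix(expr, "expr")
  shared <- colnames(meth)[colnames(meth) %in% colnames(expr)]
  if (length(shared) == 0L) {
    abort_invalid("No samples are shared between the two matrices.")
  }
  list(
    meth = meth[, shared, drop = FALSE],
    expr = expr[, shared, drop = FALSE],
    report = tibble::tibble(
      modality = c("methylation", "expression"),
      n_total = c(ncol(meth), ncol(expr)),
      n_kept = length(shared),
      n_dropped = c(ncol(meth), ncol(expr)) - length(shared)
    )
  )
}

#' Run the full silencing analysis on in-memory matrices
#'
#' End-to-end orchestration: align samples, apply the site filters
#' ([filter_sites()]), log-transform expression ([transform_expression()]),
#' build CpG-gene pairs ([build_pairs()]), fit [stepminer2d()] per pair,
#' test each pair pan-cohort and per group ([test_pair()]), and apply
#' Bonferroni correction with `m` = the number of submitted pairs --
#' direction-filtered and untestable pairs included -- separately within
#' each cohort label (pan and each group reuse the same `m`, since every
#' pair is submitted to every cohort). A pair is `significant` when it is
#' testable, not direction-excluded, and its p-value is strictly below
#' `alpha / m`.
#'
#' @param meth Methylation matrix (sites x samples, beta values).
#' @param expr Expression matrix (genes x samples, raw non-negative values
#'   unless `transform = FALSE`, then already log-scale).
#' @param annot Annotation data frame (`cpg_id`, `gene_id`).
#' @param groups Optional sample groups (data frame `sample_id`, `group`).
#' @param grid_size 2D fit grid size (default 50).
#' @param alpha Family-wise significance level (default 0.01).
#' @param direction_fraction Direction-filter fraction (default 0.1).
#' @param log_base Expression log base (default 2).
#' @param per_group_thresholds `"pan"` (default) or `"refit"`.
#' @param transform Set `FALSE` when `expr` is already log-scale.
#' @return A list: `results` (tibble, one row per pair x cohort with fit
#'   thresholds, SNR, quadrant counts, `p_value`, `direction_excluded`,
#'   `untestable`, `significant`), `summary` (per-cohort totals), and
#'   `reports` (sample intersection, site filtering, pair exclusions).
#' @export
run_silencing_analysis <- function(meth, expr, annot, groups = NULL,
                                   grid_size = 50, alpha = 0.01,
                                   direction_fraction = 0.1, log_base = 2,
                                   per_group_thresholds = c("pan", "refit"),
                                   transform = TRUE) {
  per_group_thresholds <- match.arg(per_group_thresholds)
  check_scalar_in(alpha, "alpha", 0, 1, closed = FALSE)
  check_scalar_in(direction_fraction, "direction_fraction", 0, 1)

  aligned <- intersect_samples(meth, expr)
  filtered <- filter_sites(aligned$meth, aligned$expr, annot)
  lexpr <- if (transform) {
    transform_expression(aligned$expr, base = log_base)
  } else {
    aligned$expr
  }
  pair_tbl <- build_pairs(filtered$meth, lexpr, annot)

  results <- purrr::map(seq_len(nrow(pair_tbl)), function(s) {
    pr <- pair_tbl$data[[s]]
    fit <- tryCatch(stepminer2d(pr, grid_size), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(
        cpg_id = pair_tbl$cpg_id[s], gene_id = pair_tbl$gene_id[s],
        group = "pan", n = nrow(pr),
        threshold_x = NA_real_, threshold_y = NA_real_, snr = NA_real_,
        upper_left = NA_integer_, upper_right = NA_integer_,
        lower_left = NA_integer_, lower_right = NA_integer_,
        p_value = NA_real_, direction_excluded = NA, untestable = TRUE
      ))
    }
    res <- test_pair(
      pr, fit, groups = groups,
      per_group_thresholds = per_group_thresholds, grid_size = grid_size,
      direction_fraction = direction_fraction,
      cpg_id = pair_tbl$cpg_id[s], gene_id = pair_tbl$gene_id[s]
    )
    dplyr::mutate(res, snr = fit$snr, .after = "threshold_y")
  })
  results <- dplyr::bind_rows(results)

  m <- nrow(pair_tbl)
  results <- results |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      significant = !.data$untestable &
        !dplyr::coalesce(.data$direction_excluded, TRUE) &
        !is.na(.data$p_value) & .data$p_value < alpha / m
    ) |>
    dplyr::ungroup()

  summary <- results |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      n_untestable = sum(.data$untestable),
      n_direction_excluded = sum(.data$direction_excluded, na.rm = TRUE),
      n_significant = sum(.data$significant),
      .groups = "drop"
    )

  list(
    results = results,
    summary = summary,
    reports = list(
      samples = aligned$report,
      site_filter = filtered$report,
      excluded_pairs = attr(pair_tbl, "excluded"),
      m_tests = m,
      alpha = alpha
    )
  )
}

#' Run the pipeline from files to a results table on disk
#'
#' File-level wrapper around [run_silencing_analysis()]: reads the two
#' matrices, the annotation and optional group labels, runs the analysis,
#' and writes a tab-delimited results table (one row per pair x cohort) and
#' a run summary next to it. Deterministic given inputs and configuration.
#'
#' @param config A named list: `meth_path`, `expr_path`, `annot_path`,
#'   optional `groups_path`, `out_path` (results TSV; the summary lands at
#'   `<out_path>.summary.tsv`), and the optional analysis settings
#'   `grid_size` (50), `alpha` (0.01), `direction_fraction` (0.1),
#'   `log_base` (2), `per_group_thresholds` ("pan").
#' @return The [run_silencing_analysis()] result list, invisibly.
#' @export
run_pipeline <- function(config) {
  required <- c("meth_path", "expr_path", "annot_path", "out_path")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort_invalid(sprintf("Config is missing: %s.",
                          paste(missing, collapse = ", ")))
  }
  cfg <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  meth <- read_matrix(config$meth_path, "methylation")
  expr <- read_matrix(config$expr_path, "expression")
  annot <- read_annotation(config$annot_path)
  groups <- if (!is.null(config$groups_path)) {
    read_groups(config$groups_path)
  } else {
    NULL
  }
  res <- run_silencing_analysis(
    meth, expr, annot, groups = groups,
    grid_size = cfg("grid_size", 50),
    alpha = cfg("alpha", 0.01),
    direction_fraction = cfg("direction_fraction", 0.1),
    log_base = cfg("log_base", 2),
    per_group_thresholds = cfg("per_group_thresholds", "pan")
  )
  readr::write_tsv(res$results, config$out_path)
  readr::write_tsv(res$summary, paste0(config$out_path, ".summary.tsv"))
  invisible(res)
}
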