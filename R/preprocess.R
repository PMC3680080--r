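#' Filter CpG sites before pairing with expression
#'
#' Applies the three site-level cleaning rules, in order, to a methylation
#' matrix (rows = CpG sites, columns = samples, entries = beta values in
#' `[0, 1]` with possible `NA`s):
#'
#' 1. drop sites whose annotated gene is absent from the expression matrix
#'    (sites without any annotation fall under this rule too);
#' 2. drop sites with more than 1% missing entries (strict);
#' 3. drop near-constant unmethylated sites, i.e. sites whose beta value is
#'    below 0.01 in more than 95% of samples (strict; missing entries do not
#'    count toward either side).
#'
#' Rule 3 removes sites that could only ever produce an empty methylated
#' margin, for which the one-sided test can never find evidence.
#'
#' @param meth Numeric methylation matrix, sites x samples, dimnames set.
#' @param expr Numeric expression matrix, genes x samples, same columns in
#'   the same order as `meth` (intersect first, see [intersect_samples()]).
#' @param annot A data frame with columns `cpg_id`, `gene_id`; each CpG maps
#'   to exactly one gene.
#' @param max_missing Maximum tolerated missing fraction (default 0.01).
#' @param low_beta Beta value under which a sample counts as unmethylated
#'   for rule 3 (default 0.01).
#' @param max_low_fraction Fraction of low-beta samples above which a site
#'   is dropped (default 0.95).
#' @return A list with `meth` (the filtered matrix) and `report`, a tibble
#'   with one row per rule (`rule`, `description`, `n_removed`) plus a
#'   final `retained` row.
#' @export
filter_sites <- function(meth, expr, annot,
                         max_missing = 0.01,
                         low_beta = 0.01,
                         max_low_fraction = 0.95) {
  check_matrix(meth, "meth")
  check_matrix(expr, "expr")
  annot <- validate_annotation(annot)
  if (!identical(colnames(meth), colnames(expr))) {
    abort_invalid(
      "`meth` and `expr` must share identical, identically ordered samples."
    )
  }
  check_scalar_in(max_missing, "max_missing", 0, 1)
  check_scalar_in(max_low_fraction, "max_low_fraction", 0, 1)

  gene_of <- annot$gene_id[match(rownames(meth), annot$cpg_id)]
  keep1 <- !is.na(gene_of) & gene_of %in% rownames(expr)
  n1 <- sum(!keep1)
  meth <- meth[keep1, , drop = FALSE]

  miss_frac <- rowMeans(is.na(meth))
  keep2 <- miss_frac <= max_missing
  n2 <- sum(!keep2)
  meth <- meth[keep2, , drop = FALSE]

  low_frac <- rowMeans(meth < low_beta, na.rm = TRUE)
  keep3 <- low_frac <= max_low_fraction
  n3 <- sum(!keep3)
  meth <- meth[keep3, , drop = FALSE]

  report <- tibble::tibble(
    rule = c("gene_unmatched", "missing_data", "low_beta", "retained"),
    description = c(
      "annotated gene absent from expression data (or no annotation)",
      sprintf("more than %.3g%% missing entries", 100 * max_missing),
      sprintf("beta < %.3g in more than %.3g%% of samples",
              low_beta, 100 * max_low_fraction),
      "sites retained"
    ),
    n_removed = c(n1, n2, n3, NA_integer_)
  )
  report$n_removed[4] <- nrow(meth)
  list(meth = meth, report = report)
}

validate_annotation <- function(annot) {
  if (!is.data.frame(annot) || !all(c("cpg_id", "gene_id") %in% names(annot))) {
    abort_invalid("`annot` must have columns `cpg_id` and `gene_id`.")
  }
  if (anyDuplicated(annot$cpg_id)) {
    abort_invalid("Each CpG site must map to exactly one gene.")
  }
  tibble::as_tibble(annot[c("cpg_id", "gene_id")])
}

#' Log-transform an expression matrix with per-gene zero replacement
#'
#' For each gene, zero entries are replaced by the smallest positive value of
#' that gene across all samples, then the whole matrix is log-transformed
#' (base 2 by default; the downstream rank-based fits are invariant to the
#' base, only reported thresholds change). Genes that are zero in every
#' sample have no usable floor and are dropped.
#'
#' @param expr Non-negative numeric expression matrix, genes x samples
#'   (raw RPKM-like values).
#' @param base Logarithm base, default 2.
#' @return The log-scale matrix, with attributes `log_base` and
#'   `dropped_genes` (character vector of all-zero genes).
#' @export
transform_expression <- function(expr, base = 2) {
  check_matrix(expr, "expr")
  if (any(expr < 0, na.rm = TRUE)) {
    abort_invalid("Expression values must be non-negative on the raw scale.")
  }
  check_scalar_in(base, "base", 1, Inf, closed = FALSE)
  row_has_pos <- apply(expr > 0, 1, any, na.rm = TRUE)
  dropped <- rownames(expr)[!row_has_pos]
  expr <- expr[row_has_pos, , drop = FALSE]
  min_pos <- apply(expr, 1, function(v) min(v[v > 0], na.rm = TRUE))
  floored <- pmax(expr, matrix(min_pos, nrow(expr), ncol(expr)))
  out <- log(floored, base = base)
  attr(out, "log_base") <- base
  attr(out, "dropped_genes") <- dropped
  out
}

#' Pair each retained CpG site with its gene's expression profile
#'
#' Builds one paired series per CpG site: `x` = the annotated gene's
#' log-scale expression, `y` = the site's beta values. A gene with several
#' CpG sites contributes one pair per site. Samples missing the beta value
#' are dropped from that pair only; pairs left with fewer than `min_samples`
#' complete observations are excluded and reported.
#'
#' @param meth Filtered methylation matrix (see [filter_sites()]).
#' @param expr Log-scale expression matrix (see [transform_expression()]),
#'   same samples in the same order.
#' @param annot Annotation data frame (`cpg_id`, `gene_id`).
#' @param min_samples Minimum complete pairs per series (default 4).
#' @return A nested tibble with one row per pair: `cpg_id`, `gene_id`,
#'   `n_samples` and a `data` list-column of paired-series tibbles
#'   (`sample_id`, `x`, `y`). Excluded pairs are recorded in the
#'   `"excluded"` attribute.
#' @export
build_pairs <- function(meth, expr, annot, min_samples = 4L) {
  check_matrix(meth, "meth")
  check_matrix(expr, "expr")
  annot <- validate_annotation(annot)
  if (!identical(colnames(meth), colnames(expr))) {
    abort_invalid(
      "`meth` and `expr` must share identical, identically ordered samples."
    )
  }
  samples <- colnames(meth)
  gene_of <- annot$gene_id[match(rownames(meth), annot$cpg_id)]
  if (anyNA(gene_of) || !all(gene_of %in% rownames(expr))) {
    abort_invalid("Run `filter_sites()` before `build_pairs()`.")
  }
  rows <- purrr::map(seq_len(nrow(meth)), function(s) {
    y <- meth[s, ]
    x <- expr[gene_of[s], ]
    keep <- is.finite(x) & is.finite(y)
    tibble::tibble(
      cpg_id = rownames(meth)[s],
      gene_id = gene_of[s],
      n_samples = sum(keep),
      data = list(tibble::tibble(
        sample_id = samples[keep],
        x = unname(x[keep]),
        y = unname(y[keep])
      ))
    )
  })
  out <- dplyr::bind_rows(rows)
  excluded <- dplyr::filter(out, .data$n_samples < min_samples)
  out <- dplyr::filter(out, .data$n_samples >= min_samples)
  attr(out, "excluded") <- dplyr::select(excluded, "cpg_id", "gene_id",
                                         "n_samples")
  out
}
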