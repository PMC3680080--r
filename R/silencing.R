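#' Count samples in the four quadrants after dichotomization
#'
#' Splits the methylation/expression plane at the two thresholds and counts
#' samples per quadrant. Horizontally, left/right = unmethylated/methylated
#' (beta above the methylation threshold = methylated); vertically,
#' lower/upper = low/high expression. Values equal to a threshold fall on
#' the low/unmethylated side (the `<=` convention shared with
#' [dichotomize()]).
#'
#' @param meth Numeric vector of methylation beta values, no missing entries.
#' @param expr Numeric vector of (log-scale) expression values, same length.
#' @param meth_threshold,expr_threshold Finite dichotomization cutoffs,
#'   typically `threshold_y` and `threshold_x` of a [stepminer2d()] fit.
#' @return An object of class `quadrant_counts`: `n_total`, `upper_left`,
#'   `upper_right`, `lower_left`, `lower_right`, plus the derived margins
#'   `r_methylated` (right column), `u_high` (upper row) and `k_upper_right`
#'   used by [hypergeom_pvalue()]. `tidy()` gives a one-row tibble.
#' @export
quadrant_counts <- function(meth, expr, meth_threshold, expr_threshold) {
  check_numeric_vector(meth, "meth", min_len = 1L)
  check_numeric_vector(expr, "expr", min_len = 1L)
  if (length(meth) != length(expr)) {
    abort_invalid("`meth` and `expr` must have equal length.")
  }
  if (!is.finite(meth_threshold) || !is.finite(expr_threshold)) {
    abort_invalid("Both thresholds must be finite.")
  }
  right <- meth > meth_threshold
  upper <- expr > expr_threshold
  new_quadrant_counts(
    upper_left = sum(upper & !right),
    upper_right = sum(upper & right),
    lower_left = sum(!upper & !right),
    lower_right = sum(!upper & right)
  )
}

#' Build quadrant counts directly from the four cell counts
#'
#' Constructor used when the table is already tabulated (e.g. from published
#' counts) rather than computed from raw values via [quadrant_counts()].
#'
#' @param upper_left,upper_right,lower_left,lower_right Non-negative integer
#'   cell counts (left/right = unmethylated/methylated, upper/lower =
#'   high/low expression).
#' @return A `quadrant_counts` object.
#' @export
new_quadrant_counts <- function(upper_left, upper_right, lower_left,
                                lower_right) {
  counts <- c(upper_left, upper_right, lower_left, lower_right)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_invalid("Quadrant counts must be non-negative integers.")
  }
  structure(
    list(
      n_total = sum(counts),
      upper_left = upper_left,
      upper_right = upper_right,
      lower_left = lower_left,
      lower_right = lower_right,
      r_methylated = upper_right + lower_right,
      u_high = upper_left + upper_right,
      k_upper_right = upper_right
    ),
    class = "quadrant_counts"
  )
}

#' @export
print.quadrant_counts <- function(x, ...) {
  cat("Quadrant counts (N =", x$n_total, ")\n")
  m <- matrix(
    c(x$upper_left, x$upper_right, x$lower_left, x$lower_right),
    2, 2, byrow = TRUE,
    dimnames = list(c("high expr", "low expr"),
                    c("unmethylated", "methylated"))
  )
  print(m)
  invisible(x)
}

#' @method tidy quadrant_counts
#' @export
tidy.quadrant_counts <- function(x, ...) {
  tibble::tibble(
    n_total = x$n_total,
    upper_left = x$upper_left, upper_right = x$upper_right,
    lower_left = x$lower_left, lower_right = x$lower_right,
    r_methylated = x$r_methylated, u_high = x$u_high
  )
}

#' One-sided hypergeometric test for methylation-driven silencing
#'
#' Conditional on the total sample count `N`, the number of methylated
#' samples `R` and the number of high-expression samples `U`, independence of
#' methylation and expression makes the methylated-and-high count follow a
#' hypergeometric distribution `p(k) = C(U,k) C(N-U, R-k) / C(N,R)`. The
#' returned p-value is the probability of observing the actual upper-right
#' count `K` *or fewer*: small values mean the methylated-and-high quadrant
#' is depleted, i.e. methylation accompanies silencing. This one-sidedness is
#' the point -- an enrichment of methylated-and-high samples, however
#' unbalanced, is never significant.
#'
#' With an empty margin (`R = 0` or `U = 0`) the only possible table is the
#' observed one and the p-value is exactly 1: no evidence either way, as for
#' a cohort in which (almost) no sample is methylated.
#'
#' @param counts A [quadrant_counts()] object.
#' @return A single p-value in `[0, 1]`, computed with the numerically
#'   stable distribution function (safe for `N` of 1e5 and beyond).
#' @export
hypergeom_pvalue <- function(counts) {
  if (!inherits(counts, "quadrant_counts")) {
    abort_invalid("`counts` must be a `quadrant_counts` object.")
  }
  n <- counts$n_total
  r <- counts$r_methylated
  u <- counts$u_high
  k <- counts$k_upper_right
  if (n < 1L) abort_invalid("At least one sample is required.")
  if (r > n || u > n || k > min(r, u) || k < max(0L, r + u - n)) {
    abort_invalid("Inconsistent quadrant margins.")
  }
  stats::phyper(k, m = u, n = n - u, k = r)
}

#' Direction filter: does the table even point toward silencing?
#'
#' A pair is excluded when the upper-right (methylated, high-expression)
#' count exceeds the lower-left (unmethylated, low-expression) count by more
#' than the given fraction of all samples -- a configuration that plainly
#' contradicts "methylation turns the gene off", whatever its p-value.
#'
#' @param counts A [quadrant_counts()] object.
#' @param fraction Exclusion fraction of `N` (default 0.1, i.e. 10%); the
#'   inequality is strict, so a difference of exactly `fraction * N` is
#'   retained.
#' @return `TRUE` to exclude the pair, `FALSE` to keep it.
#' @export
direction_filter <- function(counts, fraction = 0.1) {
  if (!inherits(counts, "quadrant_counts")) {
    abort_invalid("`counts` must be a `quadrant_counts` object.")
  }
  check_scalar_in(fraction, "fraction", 0, 1)
  (counts$upper_right - counts$lower_left) > fraction * counts$n_total
}

#' Bonferroni significance calls
#'
#' Flags each p-value as significant at the family-wise level `alpha` after
#' Bonferroni correction over all `m = length(p_values)` submitted tests
#' (strictly below `alpha / m`). Missing p-values (untestable pairs) yield
#' `FALSE` but still count toward `m`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param alpha Family-wise significance level, in `(0, 1)`; default 0.01.
#' @return Logical vector, same length as `p_values`.
#' @export
bonferroni_significant <- function(p_values, alpha = 0.01) {
  if (length(p_values) == 0L) {
    abort_invalid("`p_values` must be non-empty.")
  }
  if (!is.numeric(p_values) ||
      any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort_invalid("`p_values` must lie in [0, 1].")
  }
  check_scalar_in(alpha, "alpha", 0, 1, closed = FALSE)
  adj <- stats::p.adjust(p_values, method = "bonferroni",
                         n = length(p_values))
  out <- adj < alpha
  out[is.na(out)] <- FALSE
  out
}

#' Test one CpG-gene pair for silencing association, pan-cohort and per group
#'
#' Applies the thresholds of a [stepminer2d()] fit to the pair, counts
#' quadrants and computes the one-sided hypergeometric p-value and direction
#' flag -- once over all samples (group `"pan"`) and, when group labels are
#' supplied, once per group. Per-group tests reuse the pan-cohort thresholds
#' by default (the pooled cohort is what makes both methylation states
#' observable); `per_group_thresholds = "refit"` refits the 2D model within
#' each group instead. Groups with fewer than 2 samples (or for which a
#' refit is impossible) are reported as untestable rows with `NA` p-values
#' rather than errors.
#'
#' @param pairs A paired series (see [paired_series()]); `x` is expression,
#'   `y` is methylation.
#' @param fit A `step_fit_2d` with data-scale thresholds, from
#'   [stepminer2d()].
#' @param groups Optional: a data frame with columns `sample_id` and `group`,
#'   or a vector of labels aligned with `pairs` rows.
#' @param per_group_thresholds `"pan"` (default) or `"refit"`.
#' @param grid_size Grid size used when refitting per group.
#' @param direction_fraction Passed to [direction_filter()].
#' @param cpg_id,gene_id Optional identifiers carried into the result.
#' @return A tibble with one row per tested cohort: `cpg_id`, `gene_id`,
#'   `group`, `n`, `threshold_x`, `threshold_y`, the four quadrant counts,
#'   `p_value`, `direction_excluded`, `untestable`.
#' @export
test_pair <- function(pairs, fit, groups = NULL,
                      per_group_thresholds = c("pan", "refit"),
                      grid_size = 50, direction_fraction = 0.1,
                      cpg_id = NA_character_, gene_id = NA_character_) {
  pairs <- as_paired_series(pairs)
  per_group_thresholds <- match.arg(per_group_thresholds)
  if (!inherits(fit, "step_fit_2d") || !is.finite(fit$threshold_x) ||
      !is.finite(fit$threshold_y)) {
    abort_invalid("`fit` must be a `step_fit_2d` with data-scale thresholds.")
  }

  one_cohort <- function(sub, label, thr_x, thr_y) {
    if (nrow(sub) < 2L || is.na(thr_x) || is.na(thr_y)) {
      return(tibble::tibble(
        cpg_id = cpg_id, gene_id = gene_id, group = label,
        n = nrow(sub), threshold_x = thr_x, threshold_y = thr_y,
        upper_left = NA_integer_, upper_right = NA_integer_,
        lower_left = NA_integer_, lower_right = NA_integer_,
        p_value = NA_real_, direction_excluded = NA,
        untestable = TRUE
      ))
    }
    cts <- quadrant_counts(sub$y, sub$x, thr_y, thr_x)
    tibble::tibble(
      cpg_id = cpg_id, gene_id = gene_id, group = label,
      n = cts$n_total, threshold_x = thr_x, threshold_y = thr_y,
      upper_left = cts$upper_left, upper_right = cts$upper_right,
      lower_left = cts$lower_left, lower_right = cts$lower_right,
      p_value = hypergeom_pvalue(cts),
      direction_excluded = direction_filter(cts, direction_fraction),
      untestable = FALSE
    )
  }

  out <- one_cohort(pairs, "pan", fit$threshold_x, fit$threshold_y)
  if (!is.null(groups)) {
    labels <- resolve_groups(groups, pairs)
    for (g in sort(unique(labels))) {
      sub <- pairs[labels == g, , drop = FALSE]
      thr_x <- fit$threshold_x
      thr_y <- fit$threshold_y
      if (per_group_thresholds == "refit") {
        refit <- tryCatch(stepminer2d(sub, grid_size), error = function(e) NULL)
        thr_x <- if (is.null(refit)) NA_real_ else refit$threshold_x
        thr_y <- if (is.null(refit)) NA_real_ else refit$threshold_y
      }
      out <- dplyr::bind_rows(out, one_cohort(sub, g, thr_x, thr_y))
    }
  }
  out
}

# Accept group labels either aligned with the rows of `pairs` or as a
# sample_id -> group lookup table.
resolve_groups <- function(groups, pairs) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      abort_invalid("`groups` data frame needs columns `sample_id`, `group`.")
    }
    labels <- groups$group[match(pairs$sample_id, groups$sample_id)]
    if (anyNA(labels)) {
      abort_invalid("Some samples in `pairs` have no group label.")
    }
    as.character(labels)
  } else {
    if (length(groups) != nrow(pairs)) {
      abort_invalid("`groups` must have one label per pair.")
    }
    as.character(groups)
  }
}
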