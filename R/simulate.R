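#' Generate one variable from a named distribution family
#'
#' Seeded draws from the families used throughout the test suite: uniform
#' and Gaussian for the analytic SNR limits, beta mixtures for bimodal
#' methylation, lognormal (Gaussian-on-log) mixtures for bimodal expression,
#' and a two-point ("two delta") mixture whose step fit has unbounded SNR as
#' its within-mode noise vanishes. The global RNG state is left untouched.
#'
#' @param n Number of observations.
#' @param dist One of `"uniform"`, `"gaussian"`, `"beta_mixture"`,
#'   `"lognormal_mixture"`, `"two_delta"`.
#' @param seed Integer seed; identical `(n, dist, params, seed)` give
#'   identical output.
#' @param params Named list of family parameters:
#'   * uniform: `min` (0), `max` (1);
#'   * gaussian: `mean` (0), `sd` (1);
#'   * beta_mixture: `weights`, `shape1`, `shape2` (vectors, one entry per
#'     component; defaults to an unmethylated/methylated mix);
#'   * lognormal_mixture: `weights`, `meanlog`, `sdlog` -- means/sds on the
#'     log2 scale, values returned on the log2 scale;
#'   * two_delta: `values` (two levels), `weights`, `noise_sd` (0 gives the
#'     exact two-point distribution).
#' @return Numeric vector of length `n`.
#' @export
gen_univariate <- function(n, dist = c("uniform", "gaussian", "beta_mixture",
                                       "lognormal_mixture", "two_delta"),
                           seed = 1L, params = list()) {
  dist <- match.arg(dist)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    abort_invalid("`n` must be a positive integer.")
  }
  p <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  withr::with_seed(seed, {
    switch(
      dist,
      uniform = stats::runif(n, p("min", 0), p("max", 1)),
      gaussian = stats::rnorm(n, p("mean", 0), p("sd", 1)),
      beta_mixture = {
        w <- check_weights(p("weights", c(0.6, 0.4)))
        a <- p("shape1", c(1.5, 8))
        b <- p("shape2", c(25, 2))
        comp <- sample.int(length(w), n, replace = TRUE, prob = w)
        stats::rbeta(n, a[comp], b[comp])
      },
      lognormal_mixture = {
        w <- check_weights(p("weights", c(0.5, 0.5)))
        m <- p("meanlog", c(1, 4))
        s <- p("sdlog", c(0.5, 0.5))
        comp <- sample.int(length(w), n, replace = TRUE, prob = w)
        stats::rnorm(n, m[comp], s[comp])
      },
      two_delta = {
        w <- check_weights(p("weights", c(0.5, 0.5)))
        v <- p("values", c(0, 1))
        comp <- sample.int(2L, n, replace = TRUE, prob = w)
        v[comp] + stats::rnorm(n, 0, p("noise_sd", 0))
      }
    )
  })
}

check_weights <- function(w) {
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    abort_invalid("Mixture `weights` must be non-negative and sum to 1.")
  }
  w
}

#' Generate a methylation-expression pair with known structure
#'
#' Two generating regimes:
#' * `type = "silencing"` encodes the biological model under study: a
#'   methylated sample (probability `frac_meth`) draws its beta value from
#'   the high-beta mixture component and its expression from the low mode;
#'   an unmethylated sample draws beta from the low component and expression
#'   from the high mode with probability `p_high_given_unmeth`, else the low
#'   mode. Methylated-and-high samples therefore never occur by design.
#' * `type = "independent"` draws the two variables independently from the
#'   given marginal specs -- the null for calibration and the setting of the
#'   analytic SNR limits.
#'
#' Expression is produced directly on the log2 scale (a Gaussian mixture);
#' beta values come from beta distributions, supported on `[0, 1]`.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param type `"silencing"` or `"independent"`.
#' @param frac_meth Fraction of methylated samples (default 0.4).
#' @param p_high_given_unmeth P(high expression | unmethylated), default 0.5.
#' @param beta_meth_shape,beta_unmeth_shape `c(shape1, shape2)` of the
#'   methylated / unmethylated beta components (defaults centred near 0.8
#'   and 0.06).
#' @param expr_high_mean,expr_low_mean,expr_sd Log2-scale expression mode
#'   means and common sd (defaults 4, 1, 0.5).
#' @param x_dist,y_dist,x_params,y_params Marginals for
#'   `type = "independent"`, passed to [gen_univariate()] (`x` defaults to
#'   uniform expression-axis draws, `y` to uniform beta-axis draws).
#' @return A list with `pairs` (a [paired_series()] tibble; `x` = log2
#'   expression, `y` = beta) and `truth`, a tibble with the generator's
#'   ground-truth labels per sample: `methylated`, `expr_high`, `quadrant`.
#'   For independent pairs the truth labels are `NA`.
#' @export
gen_pair <- function(n, seed = 1L, type = c("silencing", "independent"),
                     frac_meth = 0.4, p_high_given_unmeth = 0.5,
                     beta_meth_shape = c(8, 2),
                     beta_unmeth_shape = c(1.5, 25),
                     expr_high_mean = 4, expr_low_mean = 1, expr_sd = 0.5,
                     x_dist = "uniform", y_dist = "uniform",
                     x_params = list(), y_params = list()) {
  type <- match.arg(type)
  if (!is.numeric(n) || length(n) != 1L || n < 4) {
    abort_invalid("`n` must be an integer >= 4.")
  }
  check_scalar_in(frac_meth, "frac_meth", 0, 1)
  check_scalar_in(p_high_given_unmeth, "p_high_given_unmeth", 0, 1)
  ids <- paste0("s", seq_len(n))
  if (type == "independent") {
    x <- gen_univariate(n, x_dist, seed = seed, params = x_params)
    y <- gen_univariate(n, y_dist, seed = seed + 1L, params = y_params)
    return(list(
      pairs = paired_series(x, y, ids),
      truth = tibble::tibble(
        sample_id = ids, methylated = NA, expr_high = NA,
        quadrant = NA_character_
      )
    ))
  }
  withr::with_seed(seed, {
    methylated <- stats::runif(n) < frac_meth
    expr_high <- !methylated & (stats::runif(n) < p_high_given_unmeth)
    y <- ifelse(
      methylated,
      stats::rbeta(n, beta_meth_shape[1], beta_meth_shape[2]),
      stats::rbeta(n, beta_unmeth_shape[1], beta_unmeth_shape[2])
    )
    x <- stats::rnorm(n, ifelse(expr_high, expr_high_mean, expr_low_mean),
                      expr_sd)
    list(
      pairs = paired_series(x, y, ids),
      truth = tibble::tibble(
        sample_id = ids,
        methylated = methylated,
        expr_high = expr_high,
        quadrant = dplyr::case_when(
          methylated & expr_high ~ "upper_right",
          methylated & !expr_high ~ "lower_right",
          !methylated & expr_high ~ "upper_left",
          TRUE ~ "lower_left"
        )
      )
    )
  })
}

#' Generate a multi-group cohort with planted association classes
#'
#' Emits a full synthetic dataset -- methylation matrix, raw-scale expression
#' matrix, CpG-gene annotation, group labels and per-site ground truth --
#' with four planted site classes:
#'
#' * `"silencing_all"`: the silencing pattern holds in every group;
#' * `"silencing_group"`: silencing holds only in the first group, while in
#'   the other groups methylation is bimodal but independent of expression
#'   (so pooled analysis is washed out by methylated-and-high samples);
#' * `"composition"`: every group is internally independent and nearly
#'   unimodal, but groups differ jointly in methylation and expression
#'   level, so only the pooled cohort shows an association -- the
#'   tissue-composition artifact;
#' * `"null"`: beta and expression bimodal, independent, identically
#'   distributed across groups.
#'
#' In addition, `n_filter_missing` sites get >1% missing betas,
#' `n_filter_low_beta` sites are near-zero beta in >95% of samples, and
#' `n_filter_unmatched` sites are annotated to genes absent from the
#' expression matrix -- targets for the three [filter_sites()] rules.
#'
#' @param groups A data frame with columns `label` and `n` (samples per
#'   group), or a named integer vector.
#' @param n_sites Named integer vector with any of `silencing_all`,
#'   `silencing_group`, `composition`, `null` (missing classes default
#'   to 0). `composition` requires at least 2 groups.
#' @param n_filter_missing,n_filter_low_beta,n_filter_unmatched Extra sites
#'   planted for the preprocessing filters (defaults 0).
#' @param seed Integer seed.
#' @param frac_meth,p_high_given_unmeth Silencing-class parameters, as in
#'   [gen_pair()].
#' @return A list with `meth` (sites x samples beta matrix), `expr`
#'   (genes x samples raw expression, `2^log2value`), `annot`, `groups`
#'   (tibble `sample_id`, `group`) and `truth` (tibble `cpg_id`, `gene_id`,
#'   `class`, `target_group`).
#' @export
gen_cohort <- function(groups,
                       n_sites = c(silencing_all = 5, silencing_group = 5,
                                   composition = 5, null = 10),
                       n_filter_missing = 0, n_filter_low_beta = 0,
                       n_filter_unmatched = 0, seed = 1L,
                       frac_meth = 0.4, p_high_given_unmeth = 0.5) {
  if (is.data.frame(groups)) {
    if (!all(c("label", "n") %in% names(groups))) {
      abort_invalid("`groups` must have columns `label` and `n`.")
    }
    glabels <- as.character(groups$label)
    gn <- as.integer(groups$n)
  } else {
    glabels <- names(groups)
    gn <- as.integer(groups)
  }
  if (length(glabels) < 1L || any(gn < 4L)) {
    abort_invalid("Need at least one group with at least 4 samples each.")
  }
  classes <- c("silencing_all", "silencing_group", "composition", "null")
  counts <- stats::setNames(rep(0L, 4), classes)
  if (!all(names(n_sites) %in% classes)) {
    abort_invalid(sprintf("`n_sites` names must be among: %s.",
                          paste(classes, collapse = ", ")))
  }
  counts[names(n_sites)] <- as.integer(n_sites)
  if (counts["composition"] > 0 && length(glabels) < 2L) {
    abort_invalid("`composition` sites need at least 2 groups.")
  }
  n <- sum(gn)
  group_of <- rep(glabels, gn)
  sample_ids <- paste0("s", seq_len(n))

  withr::with_seed(seed, {
    site_rows <- list()
    truth_rows <- list()
    site_idx <- 0L

    draw_silencing <- function(idx) {
      methylated <- stats::runif(length(idx)) < frac_meth
      expr_high <- !methylated & (stats::runif(length(idx)) < p_high_given_unmeth)
      beta <- ifelse(methylated, stats::rbeta(length(idx), 8, 2),
                     stats::rbeta(length(idx), 1.5, 25))
      lexpr <- stats::rnorm(length(idx), ifelse(expr_high, 4, 1), 0.5)
      list(beta = beta, lexpr = lexpr)
    }
    draw_independent_bimodal <- function(idx) {
      m <- length(idx)
      beta <- ifelse(stats::runif(m) < frac_meth,
                     stats::rbeta(m, 8, 2), stats::rbeta(m, 1.5, 25))
      lexpr <- stats::rnorm(m, ifelse(stats::runif(m) < 0.5, 4, 1), 0.5)
      list(beta = beta, lexpr = lexpr)
    }

    add_site <- function(class, beta, lexpr, target_group = NA_character_) {
      site_idx <<- site_idx + 1L
      cpg <- sprintf("cg%06d", site_idx)
      gene <- sprintf("GENE%04d", site_idx)
      site_rows[[site_idx]] <<- list(cpg = cpg, gene = gene, beta = beta,
                                     lexpr = lexpr)
      truth_rows[[site_idx]] <<- tibble::tibble(
        cpg_id = cpg, gene_id = gene, class = class,
        target_group = target_group
      )
    }

    for (s in seq_len(counts["silencing_all"])) {
      beta <- numeric(n); lexpr <- numeric(n)
      for (g in glabels) {
        idx <- which(group_of == g)
        d <- draw_silencing(idx)
        beta[idx] <- d$beta; lexpr[idx] <- d$lexpr
      }
      add_site("silencing_all", beta, lexpr)
    }
    for (s in seq_len(counts["silencing_group"])) {
      beta <- numeric(n); lexpr <- numeric(n)
      for (g in glabels) {
        idx <- which(group_of == g)
        d <- if (g == glabels[1]) draw_silencing(idx)
             else draw_independent_bimodal(idx)
        beta[idx] <- d$beta; lexpr[idx] <- d$lexpr
      }
      add_site("silencing_group", beta, lexpr, target_group = glabels[1])
    }
    for (s in seq_len(counts["composition"])) {
      # groups alternate between (unmethylated, high expr) and
      # (methylated, low expr) levels; within-group independence.
      beta <- numeric(n); lexpr <- numeric(n)
      for (gi in seq_along(glabels)) {
        idx <- which(group_of == glabels[gi])
        if (gi %% 2L == 1L) {
          beta[idx] <- stats::rbeta(length(idx), 1.5, 25)
          lexpr[idx] <- stats::rnorm(length(idx), 4, 0.5)
        } else {
          beta[idx] <- stats::rbeta(length(idx), 8, 2)
          lexpr[idx] <- stats::rnorm(length(idx), 1, 0.5)
        }
      }
      add_site("composition", beta, lexpr)
    }
    for (s in seq_len(counts["null"])) {
      d <- draw_independent_bimodal(seq_len(n))
      add_site("null", d$beta, d$lexpr)
    }

    meth <- do.call(rbind, purrr::map(site_rows, "beta"))
    lexpr_mat <- do.call(rbind, purrr::map(site_rows, "lexpr"))
    rownames(meth) <- purrr::map_chr(site_rows, "cpg")
    rownames(lexpr_mat) <- purrr::map_chr(site_rows, "gene")
    colnames(meth) <- colnames(lexpr_mat) <- sample_ids
    annot <- tibble::tibble(
      cpg_id = rownames(meth), gene_id = rownames(lexpr_mat)
    )
    truth <- dplyr::bind_rows(truth_rows)

    # Planted filter targets, appended after the analysis sites.
    extra_id <- nrow(meth)
    add_filter_site <- function(beta, gene_present, tag) {
      extra_id <<- extra_id + 1L
      cpg <- sprintf("cg%06d", extra_id)
      gene <- sprintf("GENE%04d", extra_id)
      meth <<- rbind(meth, stats::setNames(beta, NULL))
      rownames(meth)[nrow(meth)] <<- cpg
      if (gene_present) {
        lexpr_mat <<- rbind(lexpr_mat, stats::rnorm(n, 2, 1))
        rownames(lexpr_mat)[nrow(lexpr_mat)] <<- gene
      }
      annot <<- dplyr::bind_rows(annot,
                                 tibble::tibble(cpg_id = cpg, gene_id = gene))
      truth <<- dplyr::bind_rows(truth, tibble::tibble(
        cpg_id = cpg, gene_id = gene, class = tag,
        target_group = NA_character_
      ))
    }
    for (s in seq_len(n_filter_missing)) {
      beta <- stats::rbeta(n, 2, 2)
      n_na <- max(ceiling(0.02 * n), floor(0.01 * n) + 1L)
      beta[sample.int(n, n_na)] <- NA_real_
      add_filter_site(beta, gene_present = TRUE, tag = "filter_missing")
    }
    for (s in seq_len(n_filter_low_beta)) {
      beta <- stats::runif(n, 0, 0.009)
      n_hi <- floor(0.04 * n)           # leaves > 95% of samples below 0.01
      if (n_hi > 0) beta[sample.int(n, n_hi)] <- stats::runif(n_hi, 0.5, 0.9)
      add_filter_site(beta, gene_present = TRUE, tag = "filter_low_beta")
    }
    for (s in seq_len(n_filter_unmatched)) {
      add_filter_site(stats::rbeta(n, 2, 2), gene_present = FALSE,
                      tag = "filter_unmatched")
    }

    list(
      meth = meth,
      expr = 2^lexpr_mat,
      annot = annot,
      groups = tibble::tibble(sample_id = sample_ids, group = group_of),
      truth = truth
    )
  })
}
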