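#' Pearson correlation with a two-sided t test
#'
#' Thin wrapper around [stats::cor.test()] returning the coefficient, the
#' t statistic on `n - 2` degrees of freedom and the two-sided p-value,
#' plus a significance flag at `alpha`. Vectors must be non-constant: a
#' zero-variance input is an error rather than an `NA`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param alpha Significance level for the `significant` flag.
#' @param x_label,y_label Labels carried into the result.
#' @return Object of class `correlation_result`: list with `x_label`,
#'   `y_label`, `n`, `r`, `t_stat`, `p_value`, `significant`.
#' @examples
#' pearson(c(1, 2, 3), c(6, 4, 5))$r  # -0.5
#' @export
pearson <- function(x, y, alpha = 0.05,
                    x_label = deparse1(substitute(x)),
                    y_label = deparse1(substitute(y))) {
  force(x_label); force(y_label)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else unname(ct$p.value)
  structure(list(
    x_label = x_label, y_label = y_label, n = n, r = r,
    t_stat = unname(ct$statistic), p_value = p,
    significant = p < alpha
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r(%s, %s) = %.4f (n = %d, t = %.3f, p = %.4g)%s\n",
              x$x_label, x$y_label, x$r, x$n, x$t_stat, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Correlation panel: TE trajectories versus gene trajectories
#'
#' Computes one Pearson correlation per requested pair of rows drawn from
#' two matrices sharing the same ordered sample columns (typically
#' per-stage replicate means, n = 6 stages). Sample labels must match
#' exactly, in order.
#'
#' @param x_mat,y_mat Numeric matrices with rownames (trajectories) and
#'   identical colnames (samples). `pairs$x` indexes rows of `x_mat`,
#'   `pairs$y` rows of `y_mat`.
#' @param pairs Data frame with character columns `x` and `y`; defaults to
#'   the full cross of rows.
#' @param alpha Significance level.
#' @return Data frame with one row per pair: `x`, `y`, `n`, `r`, `t_stat`,
#'   `p_value`, `significant`.
#' @export
correlation_panel <- function(x_mat, y_mat, pairs = NULL, alpha = 0.05) {
  x_mat <- as.matrix(x_mat); y_mat <- as.matrix(y_mat)
  if (!identical(colnames(x_mat), colnames(y_mat))) {
    stop("sample-label mismatch between the two matrices")
  }
  if (is.null(pairs)) {
    pairs <- expand.grid(x = rownames(x_mat), y = rownames(y_mat),
                         stringsAsFactors = FALSE)
  }
  missing_x <- setdiff(pairs$x, rownames(x_mat))
  missing_y <- setdiff(pairs$y, rownames(y_mat))
  if (length(missing_x) || length(missing_y)) {
    stop("pair label(s) not found: ",
         paste(c(missing_x, missing_y), collapse = ", "))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- pearson(x_mat[pairs$x[i], ], y_mat[pairs$y[i], ], alpha = alpha,
                 x_label = pairs$x[i], y_label = pairs$y[i])
    data.frame(x = pairs$x[i], y = pairs$y[i], n = r$n, r = r$r,
               t_stat = r$t_stat, p_value = r$p_value,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Random-gene null control for the correlation panel
#'
#' Draws `n_random` genes uniformly without replacement from the rows of
#' `gene_mat` (optionally excluding target gene sets), correlates each
#' with each TE trajectory, and summarizes the null distribution of
#' coefficients. Under independence the fraction flagged significant
#' should approximate `alpha`. Deterministic given `seed`.
#'
#' @param te_mat TE trajectory matrix (rows = TE types).
#' @param gene_mat Gene expression matrix (rows = genes), same ordered
#'   sample columns.
#' @param n_random Number of null genes to draw (> 0).
#' @param seed Integer seed for the draw.
#' @param exclude Gene ids never drawn (the genes of interest).
#' @param alpha Significance level.
#' @return List with the per-TE-type summary data frame (`mean_r`, `sd_r`,
#'   `fraction_significant`, `n_random`) and the full `results` panel.
#' @export
null_correlation_control <- function(te_mat, gene_mat, n_random = 100,
                                     seed = 1, exclude = character(),
                                     alpha = 0.05) {
  if (!is.numeric(n_random) || n_random < 1) {
    stop("n_random must be a positive count")
  }
  pool <- setdiff(rownames(gene_mat), exclude)
  if (length(pool) < n_random) {
    stop("insufficient genes outside the target sets (",
         length(pool), " < ", n_random, ")")
  }
  drawn <- with_seed(seed, sample(pool, n_random))
  panel <- correlation_panel(
    as.matrix(te_mat), as.matrix(gene_mat),
    pairs = expand.grid(x = rownames(te_mat), y = drawn,
                        stringsAsFactors = FALSE),
    alpha = alpha
  )
  summ <- do.call(rbind, lapply(split(panel, panel$x), function(d) {
    data.frame(te_type = d$x[1], mean_r = mean(d$r), sd_r = stats::sd(d$r),
               fraction_significant = mean(d$significant),
               n_random = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(summary = summ, results = panel, seed = seed, alpha = alpha)
}

#' One-way ANOVA with significance stars
#'
#' Fixed-effects one-way analysis of variance across `k >= 2` groups
#' (each with at least two values), computed via
#' [stats::oneway.test()] with pooled variance, and annotated with the
#' conventional star code: `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001 (strict inequalities).
#'
#' @param groups Named list of `k` numeric vectors.
#' @return Object of class `anova_result`: list with `groups` (sizes),
#'   `F`, `df_between`, `df_within`, `p_value`, `stars`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))$F  # 13.5
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 values")
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  vals <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), sizes), levels = names(groups))
  within_var <- vapply(groups, stats::var, numeric(1))
  if (all(within_var == 0) && stats::var(vals) == 0) {
    stop("all values identical: F statistic undefined")
  }
  ow <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  structure(list(
    groups = stats::setNames(as.integer(sizes), names(groups)),
    F = unname(ow$statistic),
    df_between = unname(ow$parameter[["num df"]]),
    df_within = unname(ow$parameter[["denom df"]]),
    p_value = unname(ow$p.value),
    stars = p_stars(unname(ow$p.value))
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g %s\n",
              x$df_between, x$df_within, x$F, x$p_value, x$stars))
  invisible(x)
}

#' Significance stars from a p-value
#'
#' Strict thresholds: `***` below 0.001, `**` below 0.01, `*` below 0.05,
#' empty string otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Mean and standard error of the mean of replicate values
#'
#' @param values Numeric vector with `n >= 2`.
#' @return Object of class `replicate_summary`: list with `mean`, `sem`
#'   (`sample sd / sqrt(n)`), `n`.
#' @export
mean_sem <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 replicate values")
  structure(list(mean = mean(values),
                 sem = stats::sd(values) / sqrt(n),
                 n = n),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}

# Evaluate code under a temporary RNG state so callers' streams are
# untouched; restores (or removes) .Random.seed on exit.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
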