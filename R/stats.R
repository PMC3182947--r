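# Agreement machinery: Bland-Altman bias and limits of agreement, one-way
# within-subject (repeated-measures) ANOVA from explicit sums of squares
# with Bonferroni-corrected paired post-hoc tests, and the study-level
# method-comparison table.

#' Bland-Altman agreement analysis
#'
#' Differences are `a - b` per subject; the limits of agreement are
#' bias +/- 2 SD (the literal 2, not 1.96), with the sample SD (n - 1
#' denominator).
#'
#' @param a,b paired measurement vectors (same subjects, same order).
#' @return an object of class `agreement_result` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the `means`/`diffs` used for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("bland_altman: pairing error, lengths differ (", length(a), " vs ",
         length(b), ")")
  if (length(a) < 2L) stop("bland_altman: need at least 2 pairs")
  d <- a - b
  bias <- mean(d); s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s, loa_low = bias - 2 * s,
                 loa_high = bias + 2 * s, n = length(d),
                 means = (a + b) / 2, diffs = d),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, SD %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA of a complete subjects x methods matrix from
#' explicit sums of squares (methods, subjects, error); sphericity is
#' assumed (no Greenhouse-Geisser correction).  Post-hoc comparisons are
#' paired t tests on every method pair with Bonferroni correction.
#'
#' @param data numeric matrix, subjects in rows, methods in columns
#'   (column names label the methods); no missing cells.
#' @return an object of class `rm_anova_result` with `f_stat`,
#'   `df_between`, `df_error`, `p_value` and `posthoc` (data.frame of
#'   method pairs with raw and Bonferroni-adjusted p values).
#' @export
rm_anova <- function(data) {
  Y <- as.matrix(data)
  if (anyNA(Y)) stop("rm_anova: missing cells; a complete matrix is required")
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L || k < 2L) stop("rm_anova: need >= 2 subjects and >= 2 methods")
  if (is.null(colnames(Y))) colnames(Y) <- paste0("method", seq_len(k))
  grand <- mean(Y)
  ss_methods <- n * sum((colMeans(Y) - grand)^2)
  ss_subjects <- k * sum((rowMeans(Y) - grand)^2)
  ss_total <- sum((Y - grand)^2)
  ss_error <- ss_total - ss_methods - ss_subjects
  df_b <- k - 1L; df_e <- (n - 1L) * (k - 1L)
  ms_m <- ss_methods / df_b; ms_e <- ss_error / df_e
  f <- if (ms_e > 0) ms_m / ms_e else if (ms_m == 0) 0 else Inf
  p <- stats::pf(f, df_b, df_e, lower.tail = FALSE)
  pairs <- utils::combn(colnames(Y), 2L)
  n_comp <- ncol(pairs)
  posthoc <- data.frame(
    method_a = pairs[1L, ], method_b = pairs[2L, ],
    p_raw = apply(pairs, 2L, function(pr) {
      d <- Y[, pr[1L]] - Y[, pr[2L]]
      if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
      stats::t.test(d)$p.value
    }))
  posthoc$p_adjusted <- pmin(1, posthoc$p_raw * n_comp)
  structure(list(f_stat = f, df_between = df_b, df_error = df_e,
                 p_value = p, posthoc = posthoc,
                 ss = c(methods = ss_methods, subjects = ss_subjects,
                        error = ss_error)),
            class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_error, x$f_stat, x$p_value))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Study-level comparison of analysis methods
#'
#' Assembles per-animal function reports from several methods into the
#' mean +/- SD summary table (with standard-minus-GPM difference columns),
#' Bland-Altman agreement of every other method against the reference, and
#' a repeated-measures ANOVA per functional parameter.
#'
#' @param reports named list (one element per animal) of named lists of
#'   [function_report()]s (one per method); every animal must have every
#'   method.
#' @param reference method name differenced against the others (default
#'   `"standard"`).
#' @return list with `table` (data.frame: parameter, method, mean, sd, and
#'   reference-minus-method columns), `agreement` (per parameter, per
#'   method), `anova` (per parameter) and the raw `values` array.
#' @export
compare_protocols <- function(reports, reference = "standard") {
  animals <- names(reports)
  if (is.null(animals)) animals <- paste0("animal", seq_along(reports))
  methods <- names(reports[[1L]])
  incomplete <- animals[!vapply(reports, function(r)
    all(methods %in% names(r)), TRUE)]
  if (length(incomplete))
    stop("compare_protocols: incomplete animals: ",
         paste(incomplete, collapse = ", "))
  params <- c("edv_ul", "esv_ul", "sv_ul", "ef_pct", "lvm_mg")
  vals <- array(NA_real_, c(length(animals), length(methods), length(params)),
                dimnames = list(animals, methods, params))
  for (i in seq_along(animals))
    for (j in seq_along(methods))
      vals[i, j, ] <- report_fields(reports[[i]][[j]])[params]
  single <- length(animals) == 1L
  if (single)
    warning("compare_protocols: single animal; SD columns undefined")
  rows <- list(); agreement <- list(); anova <- list()
  for (p in params) {
    M <- matrix(vals[, , p], nrow = length(animals),
                dimnames = list(animals, methods))
    tab <- data.frame(parameter = p, method = methods,
                      mean = colMeans(M),
                      sd = if (single) NA_real_ else apply(M, 2L, stats::sd))
    if (reference %in% methods) {
      dd <- M[, reference] - M
      tab$diff_vs_reference_mean <- colMeans(dd)
      tab$diff_vs_reference_sd <-
        if (single) NA_real_ else apply(dd, 2L, stats::sd)
      if (!single)
        agreement[[p]] <- lapply(
          stats::setNames(setdiff(methods, reference),
                          setdiff(methods, reference)),
          function(m) bland_altman(M[, reference], M[, m]))
    }
    if (!single && length(methods) >= 2L) anova[[p]] <- rm_anova(M)
    rows[[p]] <- tab
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       agreement = agreement, anova = anova, values = vals)
}
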