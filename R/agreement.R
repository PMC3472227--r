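#' Assemble a subjects-by-raters ratings matrix
#'
#' Takes a tidy data frame (one row per subject/rater measurement) and
#' pivots it into the subjects x raters matrix the ICC needs. Subjects with
#' any missing cell are removed listwise, with a message reporting how many.
#'
#' @param df data frame with subject, rater and value columns.
#' @param subject,rater,value column names; defaults `"subject"`,
#'   `"rater"`, `"value"`.
#' @return Numeric matrix, subjects in rows, raters in columns.
#' @export
ratings_matrix <- function(df, subject = "subject", rater = "rater",
                           value = "value") {
  for (col in c(subject, rater, value))
    if (!col %in% names(df))
      stop(sprintf("missing column '%s'", col), call. = FALSE)
  subjects <- unique(df[[subject]])
  raters <- unique(df[[rater]])
  m <- matrix(NA_real_, length(subjects), length(raters),
              dimnames = list(as.character(subjects), as.character(raters)))
  m[cbind(match(df[[subject]], subjects), match(df[[rater]], raters))] <-
    df[[value]]
  keep <- complete.cases(m)
  if (any(!keep))
    message(sprintf("dropping %d subject(s) with missing cells", sum(!keep)))
  m[keep, , drop = FALSE]
}

#' Two-way random-effects intraclass correlation
#'
#' Single-measure absolute-agreement ICC(2,1) (the standard choice for
#' method reproducibility of a single reading), from the two-way
#' random-effects ANOVA decomposition with subjects and raters both random:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with `n` subjects, `k` raters, and row/column/error mean squares
#' `MS_R`, `MS_C`, `MS_E`. The 95 percent confidence interval uses the
#' F-distribution approximation of McGraw and Wong. Average-measure
#' agreement ICC(2,k) is available via `type = "average"`. Negative
#' estimates (degenerate variance structures) are reported as-is, never
#' clipped.
#'
#' @param m numeric matrix, subjects in rows, raters in columns (>= 2 each),
#'   or a data frame coercible to one.
#' @param type `"single"` (ICC(2,1), default) or `"average"` (ICC(2,k)).
#' @param conf_level confidence level; default 0.95.
#' @return An object of class `icc_fit`: `icc`, `ci` (length 2), `type`,
#'   `n`, `k`, and the mean squares `MSR`, `MSC`, `MSE` for audit.
#' @export
icc_two_way_random <- function(m, type = c("single", "average"),
                               conf_level = 0.95) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("ratings must be numeric", call. = FALSE)
  if (anyNA(m)) {
    keep <- complete.cases(m)
    message(sprintf("dropping %d subject(s) with missing cells", sum(!keep)))
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  SST <- sum((m - grand)^2)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST <= 0) {
    warning("zero total variance: ICC undefined")
    return(structure(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                          type = type, n = n, k = k,
                          MSR = MSR, MSC = MSC, MSE = MSE,
                          note = "zero total variance"),
                     class = "icc_fit"))
  }
  r1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  # F-based CI for the single-measure coefficient (McGraw & Wong case 2A),
  # Satterthwaite df for the rater/error combination
  alpha <- 1 - conf_level
  a <- (k * r1) / (n * (1 - r1))
  b <- 1 + (k * r1 * (n - 1)) / (n * (1 - r1))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  if (type == "average") {
    icc <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
    sb <- function(r) r * k / (1 + r * (k - 1))
    ci <- c(sb(lo), sb(hi))
  } else {
    icc <- r1
    ci <- c(lo, hi)
  }
  structure(list(icc = icc, ci = ci, conf_level = conf_level, type = type,
                 n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf(
    "<icc_fit> ICC(2,%s) = %.3f, %g%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
    if (x$type == "single") "1" else "k", x$icc,
    100 * (x$conf_level %||% 0.95), x$ci[1], x$ci[2], x$n, x$k))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bland-Altman bias and limits of agreement
#'
#' Differences are oriented `x - y` (first minus second observer), so a
#' positive bias means the first series reads higher. Limits of agreement
#' are `bias +/- 1.96 SD` of the differences.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return An object of class `bland_altman`: `bias`, `sd_diff`, `loa`
#'   (lower, upper), `n`, plus the per-pair `means` and `diffs` for
#'   plotting.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 n = length(d), orientation = "x - y",
                 means = (x + y) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias = %.4g (x - y), limits of agreement [%.4g, %.4g], n = %d\n",
    x$bias, x$loa[1], x$loa[2], x$n))
  invisible(x)
}

#' Unpaired two-sample t test
#'
#' Thin wrapper over [stats::t.test()] returning the pieces reported in
#' cohort comparisons. Equal-variance (classic) by default; Welch optional.
#'
#' @param x,y numeric samples, each with >= 2 values.
#' @param var_equal assume equal variances; default `TRUE`.
#' @return List with `t`, `df`, `p`, `mean_x`, `mean_y`, `diff`.
#' @export
unpaired_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y))
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                mean_x = mean(x), mean_y = mean(y), diff = 0))
  tt <- t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_x = mean(x), mean_y = mean(y),
       diff = mean(x) - mean(y))
}

#' Observer-agreement report
#'
#' Combines ICC(2,1) and Bland-Altman for each measured variable in a tidy
#' data frame of repeated readings, mirroring the usual layout of an
#' intra-/inter-observer variability table.
#'
#' @param df tidy data frame with subject, rater, value and (optionally)
#'   variable columns.
#' @param variable column naming the measured quantity; `NULL` when `df`
#'   holds a single variable.
#' @param ... column-name arguments passed to [ratings_matrix()].
#' @return Named list per variable, each with `icc` ([icc_two_way_random()])
#'   and `bland_altman` (first two raters). Serializable with
#'   [jsonlite::toJSON()].
#' @export
agreement_report <- function(df, variable = NULL, ...) {
  split_df <- if (is.null(variable)) list(value = df)
              else split(df, df[[variable]])
  lapply(split_df, function(sub) {
    m <- ratings_matrix(sub, ...)
    fit <- icc_two_way_random(m)
    ba <- bland_altman(m[, 1], m[, 2])
    list(icc = fit$icc, icc_ci = fit$ci, n = fit$n, k = fit$k,
         bias = ba$bias, limits_of_agreement = unname(ba$loa))
  })
}
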