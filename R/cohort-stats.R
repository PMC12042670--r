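#' Paired t-test
#'
#' Classic paired t on per-subject differences `d = a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-sided p from the
#' central t distribution. With zero variance of the differences the
#' statistic degenerates: identical samples give `t = 0, p = 1`; a constant
#' non-zero shift gives `t = +/-Inf, p = 0` with a warning.
#'
#' @param a,b numeric vectors of equal length `n >= 3`, no missing values.
#' @return List `t, df, p, mean_diff, n`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (anyNA(a) || anyNA(b)) stop("missing pairs are not allowed")
  n <- length(a)
  if (n < 3) stop("paired_t requires n >= 3")
  d <- a - b
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    warning("zero variance of differences: t reported as +/-Inf, p = 0")
    return(list(t = sign(m) * Inf, df = n - 1, p = 0, mean_diff = m, n = n))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1), mean_diff = m, n = n)
}

# cache of exact null distributions of D = sum d_i^2 by n
.spearman_cache <- new.env(parent = emptyenv())

.spearman_d_null <- function(n) {
  key <- as.character(n)
  if (is.null(.spearman_cache[[key]]))
    .spearman_cache[[key]] <- .spearman_d_null_cpp(n)
  .spearman_cache[[key]]
}

#' Spearman rank correlation with exact permutation p
#'
#' Spearman's rho on average ranks (midranks for ties). For tie-free
#' samples with `4 <= n <= 13` the two-sided p-value is exact: for untied
#' data rho is a monotone function of `D = sum (rank(x) - rank(y))^2`, and
#' the exact permutation distribution of D is computed by a dynamic
#' program over rank subsets (no enumeration of n!). With ties or larger
#' n, the usual t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2` df is used. Constant input
#' leaves rho undefined (`NA`).
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @return List `rho, p, n, method` (`"exact"` or `"t-approximation"`).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("samples must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 4) stop("spearman requires n >= 4")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant sample: rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (!ties && n <= 13) {
    D <- sum((rx - ry)^2)
    counts <- .spearman_d_null(n)
    dmax <- length(counts) - 1L
    # D-distribution is symmetric about dmax/2; two-sided tail on |rho|
    dlo <- min(D, dmax - D)
    p <- (sum(counts[seq_len(dlo + 1L)]) +
            sum(counts[seq.int(dmax - dlo + 1L, dmax + 1L)])) / sum(counts)
    p <- min(1, p)
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(t), df = n - 2)
  list(rho = rho, p = p, n = n, method = "t-approximation")
}

#' Validate a tidy cohort table
#'
#' Long-format per-subject metric table: one row per
#' `(subject_id, muscle, metric)` with `age`, `bmi`, and `value`. Each
#' combination may appear at most once; paired analyses use only subjects
#' present for both muscles.
#'
#' @param x data.frame with columns `subject_id, age, bmi, muscle, metric,
#'   value`; `muscle` must be `"splenius"` or `"vastus"`.
#' @return `x`, with `muscle` normalized to a factor, invisibly checked.
#' @export
cohort_table <- function(x) {
  need <- c("subject_id", "age", "bmi", "muscle", "metric", "value")
  if (!all(need %in% names(x)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  if (!all(x$muscle %in% c("splenius", "vastus")))
    stop("muscle must be 'splenius' or 'vastus'")
  key <- paste(x$subject_id, x$muscle, x$metric)
  if (anyDuplicated(key))
    stop("duplicate (subject, muscle, metric) rows")
  x$muscle <- factor(x$muscle, levels = c("splenius", "vastus"))
  x
}

#' Paired between-muscle comparisons over a cohort table
#'
#' Runs [paired_t()] per metric on subjects present for both muscles,
#' mirroring a between-muscle comparison column. P-values are unadjusted
#' (no multiple-testing correction across metrics).
#'
#' @param cohort a [cohort_table()] data.frame.
#' @param metrics metrics to test; default all present.
#' @return data.frame `metric, n, mean_splenius, mean_vastus, t, df, p`.
#' @export
compare_muscles <- function(cohort, metrics = NULL) {
  cohort <- cohort_table(cohort)
  if (is.null(metrics)) metrics <- unique(cohort$metric)
  rows <- lapply(metrics, function(mm) {
    d <- cohort[cohort$metric == mm, ]
    w <- merge(d[d$muscle == "splenius", c("subject_id", "value")],
               d[d$muscle == "vastus", c("subject_id", "value")],
               by = "subject_id", suffixes = c("_s", "_v"))
    tt <- paired_t(w$value_s, w$value_v)
    data.frame(metric = mm, n = tt$n,
               mean_splenius = mean(w$value_s), mean_vastus = mean(w$value_v),
               t = tt$t, df = tt$df, p = tt$p)
  })
  do.call(rbind, rows)
}

#' BMI correlations over a cohort table
#'
#' [spearman()] of each metric against BMI within each muscle.
#'
#' @param cohort a [cohort_table()] data.frame.
#' @param metrics metrics to test; default all present.
#' @return data.frame `muscle, metric, n, rho, p, method`.
#' @export
correlate_bmi <- function(cohort, metrics = NULL) {
  cohort <- cohort_table(cohort)
  if (is.null(metrics)) metrics <- unique(cohort$metric)
  rows <- list()
  for (mus in levels(cohort$muscle)) {
    for (mm in metrics) {
      d <- cohort[cohort$metric == mm & cohort$muscle == mus, ]
      if (nrow(d) < 4) next
      sp <- spearman(d$bmi, d$value)
      rows[[length(rows) + 1L]] <-
        data.frame(muscle = mus, metric = mm, n = sp$n, rho = sp$rho,
                   p = sp$p, method = sp$method)
    }
  }
  do.call(rbind, rows)
}
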