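# Cohort-level statistics over a per-case metrics table: descriptive
# summaries (median with [25th, 75th] percentiles), Shapiro-Wilk normality,
# Mann-Whitney U group differences, and a banded correlation matrix.

#' Descriptive summary of a numeric series
#'
#' Median, 25th/75th percentiles (linear interpolation), min, max, mean and
#' sd; missing values are excluded and counted.
#' @param x numeric vector.
#' @return one-row data frame with `n`, `n_missing`, `median`, `p25`, `p75`,
#'   `min`, `max`, `mean`, `sd`.
#' @export
describe <- function(x) {
  n_missing <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (length(x) == 0)
    return(data.frame(n = 0L, n_missing = n_missing, median = NA_real_,
                      p25 = NA_real_, p75 = NA_real_, min = NA_real_,
                      max = NA_real_, mean = NA_real_, sd = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(x), n_missing = n_missing, median = q[2],
             p25 = q[1], p75 = q[3], min = min(x), max = max(x),
             mean = mean(x),
             sd = if (length(x) > 1) stats::sd(x) else NA_real_)
}

#' Shapiro-Wilk normality test
#' @param x numeric vector with 3 to 5000 non-missing values, not constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
  if (length(unique(x)) == 1)
    stop("Shapiro-Wilk undefined for a constant series", call. = FALSE)
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact enumeration p-value when both groups have at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction.
#' @param a,b numeric samples.
#' @param exact_max largest per-group n for the exact path (default 8).
#' @return list with `U` (for sample `a`), `p`, and `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  na <- length(a)
  nb <- length(b)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && na <= exact_max && nb <= exact_max) {
    p <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    return(list(U = U, p = p, method = "exact"))
  }
  # normal approximation with tie correction
  n <- na + nb
  mu <- na * nb / 2
  tie_tab <- table(c(a, b))
  sig2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Correlation band of a coefficient
#'
#' Bands on the absolute coefficient: moderate for 0.5 <= |R| < 0.7, high
#' for 0.7 <= |R| < 0.9, very_high for 0.9 <= |R| <= 1, none below 0.5.
#' @param R correlation coefficient(s) in [-1, 1].
#' @return character vector of band labels.
#' @export
correlation_band <- function(R) {
  a <- abs(R)
  ifelse(is.na(a), NA_character_,
         ifelse(a >= 0.9, "very_high",
                ifelse(a >= 0.7, "high",
                       ifelse(a >= 0.5, "moderate", "none"))))
}

#' Pairwise correlation matrix with bands
#'
#' Pairwise-complete correlations between the numeric columns of a metrics
#' table, returned in long form with band labels. Pairs of trivially related
#' columns (an absolute value and its own relative value) can be flagged for
#' exclusion from interpretation.
#' @param table data frame (e.g. from [analyze_cohort()] or
#'   [read_metrics_table()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param exclude_trivial flag pairs like `loss_ml` vs `loss_pct` of
#'   the same sector.
#' @return data frame `var1`, `var2`, `R`, `band`, `trivial`; the square
#'   matrix is attached as attribute `"matrix"`.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman"),
                               exclude_trivial = TRUE) {
  method <- match.arg(method)
  num <- table[vapply(table, is.numeric, logical(1))]
  num <- num[vapply(num, function(x)
    sum(!is.na(x)) >= 3 && stats::sd(x, na.rm = TRUE) > 0, logical(1))]
  if (ncol(num) < 2)
    stop("need at least two numeric columns", call. = FALSE)
  R <- stats::cor(num, use = "pairwise.complete.obs", method = method)
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  v1 <- colnames(R)[pairs[, 1]]
  v2 <- colnames(R)[pairs[, 2]]
  trivial <- rep(FALSE, length(v1))
  if (exclude_trivial) {
    base1 <- sub("_(ml|pct)$", "", v1)
    base2 <- sub("_(ml|pct)$", "", v2)
    trivial <- base1 == base2 & v1 != v2
  }
  out <- data.frame(var1 = v1, var2 = v2, R = R[pairs],
                    band = correlation_band(R[pairs]), trivial = trivial,
                    row.names = NULL)
  attr(out, "matrix") <- R
  out
}

#' Summary statistics and tests over a metrics table
#'
#' Runs [describe()] and [shapiro_wilk()] on every numeric column and
#' pairwise [mann_whitney_u()] tests between the relative sector-loss
#' columns, mirroring a standard cohort report.
#' @param table per-case metrics data frame.
#' @param loss_cols columns holding relative sector loss for the pairwise
#'   tests; defaults to `loss_pct_<sector>` when present.
#' @return list with `descriptives`, `normality`, `pairwise` data frames.
#' @export
cohort_statistics <- function(table, loss_cols = NULL) {
  num <- table[vapply(table, is.numeric, logical(1))]
  desc <- do.call(rbind, lapply(names(num), function(v)
    cbind(variable = v, describe(num[[v]]))))
  normality <- do.call(rbind, lapply(names(num), function(v) {
    x <- num[[v]][!is.na(num[[v]])]
    if (length(x) < 3 || length(unique(x)) < 2)
      return(data.frame(variable = v, W = NA_real_, p = NA_real_,
                        normal = NA))
    sw <- shapiro_wilk(x)
    data.frame(variable = v, W = sw$W, p = sw$p, normal = sw$p >= 0.05)
  }))
  if (is.null(loss_cols))
    loss_cols <- intersect(paste0("loss_pct_", SECTORS), names(num))
  pairwise <- NULL
  if (length(loss_cols) >= 2) {
    cmb <- utils::combn(loss_cols, 2)
    pairwise <- do.call(rbind, apply(cmb, 2, function(p) {
      mw <- mann_whitney_u(num[[p[1]]], num[[p[2]]])
      data.frame(var1 = p[1], var2 = p[2], U = mw$U, p = mw$p,
                 significant = mw$p < 0.05)
    }))
  }
  list(descriptives = desc, normality = normality, pairwise = pairwise)
}
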