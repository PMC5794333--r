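#' Group summary constructor
#'
#' The (mean, sd, n) triple is the exchange currency of the statistical
#' layer: published results tables report groups in exactly this form, and
#' Welch's t-test needs nothing more.
#'
#' @param mean Group mean.
#' @param sd Sample standard deviation (>= 0; `NA` allowed when `n = 1`,
#'   where it is undefined).
#' @param n Group size (>= 1).
#' @param label Optional group label.
#' @return A one-row tibble with columns `label`, `mean`, `sd`, `n`.
#' @export
group_summary <- function(mean, sd, n, label = NA_character_) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (n == 1 && !is.na(sd)) stop("sd is undefined for n = 1; pass NA", call. = FALSE)
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0", call. = FALSE)
  tibble::tibble(label = label, mean = mean, sd = sd, n = as.integer(n))
}

as_group_summary <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) < 2) stop("raw sample needs n >= 2", call. = FALSE)
    return(group_summary(mean(x), stats::sd(x), length(x)))
  }
  x <- tibble::as_tibble(as.list(x)[c("mean", "sd", "n")] |> stats::setNames(c("mean", "sd", "n")))
  x
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test from raw samples or from (mean, sd, n)
#' summaries -- identical formulas either way:
#' t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b), with Welch-Satterthwaite
#' (fractional) degrees of freedom and a two-sided p from the t
#' distribution.
#'
#' @param a,b Either numeric vectors of raw observations (each n >= 2), or
#'   group summaries: the output of [group_summary()], or any list/one-row
#'   data frame with `mean`, `sd`, `n` fields.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_diff`.
#' @examples
#' welch_t(group_summary(10, 1, 6), group_summary(12, 1, 6))
#' @export
welch_t <- function(a, b) {
  a <- as_group_summary(a)
  b <- as_group_summary(b)
  if (a$n < 2 || b$n < 2) stop("Welch's t needs n >= 2 in both groups", call. = FALSE)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se <- sqrt(va + vb)
  if (se == 0) {
    # both groups constant: identical means -> t = 0, p = 1 by convention
    if (a$mean == b$mean) {
      return(tibble::tibble(t = 0, df = a$n + b$n - 2, p_value = 1, mean_diff = 0))
    }
    stop("zero variance in both groups with unequal means: t undefined", call. = FALSE)
  }
  t <- (a$mean - b$mean) / se
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  tibble::tibble(
    t = t, df = df,
    p_value = 2 * stats::pt(-abs(t), df = df),
    mean_diff = a$mean - b$mean
  )
}

#' Ordinary least-squares line with Pearson correlation
#'
#' Slope/intercept by least squares, R^2 as the squared Pearson
#' product-moment correlation, and a two-sided p for the slope from
#' t = r sqrt((n-2)/(1-r^2)).
#'
#' @param x,y Numeric vectors (>= 3 points; `x` must not be constant).
#' @return A one-row tibble: `slope`, `intercept`, `r`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant; no line can be fitted", call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- stats::cor(x, y)
  r2 <- r^2
  p <- if (1 - r2 < .Machine$double.eps) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(slope = slope, intercept = intercept, r = r,
                 r_squared = r2, p_value = p, n = n)
}

check_anova_groups <- function(data, value, group) {
  data <- tibble::as_tibble(data)
  if (!all(c(value, group) %in% names(data))) {
    stop("`data` needs columns '", value, "' and '", group, "'", call. = FALSE)
  }
  g <- split(data[[value]], data[[group]])
  if (length(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(g, length, 1L) < 2)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  g
}

#' One-way analysis of variance
#'
#' The classic between/within decomposition: F = MS_between / MS_within
#' with df1 = k - 1 and df2 = N - k, p from the F distribution. All groups
#' identical gives F = 0, p = 1.
#'
#' @param data Tidy data frame of observations.
#' @param value,group Column names of the response and the grouping factor.
#' @return A one-row tibble: `f`, `df1`, `df2`, `p_value`, `ss_between`,
#'   `ss_within`.
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  g <- check_anova_groups(data, value, group)
  ns <- vapply(g, length, 1L)
  means <- vapply(g, mean, 1)
  grand <- sum(ns * means) / sum(ns)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1))
  df1 <- length(g) - 1
  df2 <- sum(ns) - length(g)
  if (ssw == 0 && ssb == 0) {
    return(tibble::tibble(f = 0, df1 = df1, df2 = df2, p_value = 1,
                          ss_between = 0, ss_within = 0))
  }
  if (ssw == 0) stop("zero within-group variance with distinct means: F undefined", call. = FALSE)
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(
    f = f, df1 = df1, df2 = df2,
    p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
    ss_between = ssb, ss_within = ssw
  )
}

#' Tukey honest-significant-difference post-hoc test
#'
#' For every group pair, the studentized range statistic
#' q = |m_i - m_j| / sqrt(MSE/2 (1/n_i + 1/n_j)) is referred to the
#' studentized range distribution with k groups and N - k error degrees of
#' freedom (Tukey-Kramer for unequal n). Adjusted p-values control the
#' family-wise error across all pairs.
#'
#' @inheritParams one_way_anova
#' @return A tibble per pair: `group1`, `group2`, `diff`, `q`, `p_adj`.
#' @export
tukey_hsd <- function(data, value = "value", group = "group") {
  g <- check_anova_groups(data, value, group)
  k <- length(g)
  ns <- vapply(g, length, 1L)
  means <- vapply(g, mean, 1)
  df2 <- sum(ns) - k
  mse <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1)) / df2
  pairs <- utils::combn(names(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    diff <- means[[g1]] - means[[g2]]
    se <- sqrt(mse / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- if (se == 0) {
      if (diff == 0) 0 else Inf
    } else {
      abs(diff) / se
    }
    p <- if (is.infinite(q)) 0 else stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    tibble::tibble(group1 = g1, group2 = g2, diff = diff, q = q, p_adj = p)
  })
}

#' Fold change of a treatment over its control
#'
#' @param treatment_mean,control_mean Group means; `control_mean` must be positive.
#' @return The ratio treatment/control. Vectorised over treatments.
#' @examples
#' fold_change(3247, 280) # 11.6, i.e. "12 times" at integer rounding
#' @export
fold_change <- function(treatment_mean, control_mean) {
  if (any(control_mean <= 0)) stop("control mean must be > 0", call. = FALSE)
  treatment_mean / control_mean
}
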