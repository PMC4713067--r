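# Summary statistics and the significance tests used for group comparisons:
# mean +- SEM, Welch's two-sample t test, and a chi-square goodness-of-fit
# check for normality applied before t testing.

#' Summarize a group of measurements as mean and SEM
#'
#' @param values numeric vector, length >= 1.
#' @param label condition label.
#' @param unit measurement unit string.
#' @return a `group_summary` data.frame: `label`, `n`, `mean`, `sem`, `unit`,
#'   `sem_defined` (FALSE at n = 1, where the SEM is flagged as undefined).
#' @export
summarize_group <- function(values, label = "group", unit = "") {
  if (!length(values)) stop("empty value list")
  n <- length(values)
  sem <- if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_
  out <- data.frame(label = label, n = n, mean = mean(values), sem = sem,
                    unit = unit, sem_defined = n >= 2)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Compare two groups with Welch's t test
#'
#' Two-sample, two-sided, unequal-variance (Welch) form.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("degenerate comparison: both groups have zero variance")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Chi-square goodness-of-fit check for normality
#'
#' Values are binned into equal-probability bins of a fitted normal
#' distribution (bin count by Sturges' rule unless given) and the chi-square
#' statistic is referred to `bins - 3` degrees of freedom (two estimated
#' parameters). The normal parameters are estimated by minimizing the
#' grouped chi-square itself (starting from the sample moments): with
#' moment estimates the statistic is stochastically larger than
#' chi-square(bins - 3) (the Chernoff-Lehmann effect) and the test rejects
#' well above its nominal level.
#'
#' @param values numeric vector, length >= 20.
#' @param bins number of bins; default `nclass.Sturges(values)`.
#' @return list with `statistic`, `df`, `p`, `bins`.
#' @export
normality_check <- function(values, bins = NULL) {
  n <- length(values)
  if (n < 20) stop("insufficient n for the normality check (need >= 20)")
  if (stats::sd(values) == 0) stop("zero-variance sample")
  if (is.null(bins)) bins <- grDevices::nclass.Sturges(values)
  bins <- max(4L, as.integer(bins))
  mu0 <- mean(values); s0 <- stats::sd(values)
  edges <- stats::qnorm(seq(0, 1, length.out = bins + 1L), mu0, s0)
  edges[1] <- -Inf; edges[bins + 1L] <- Inf
  obs <- as.vector(table(cut(values, edges)))
  x2 <- function(par) {
    p <- diff(stats::pnorm(edges, par[1], exp(par[2])))
    if (any(p <= 0)) return(Inf)
    sum((obs - n * p)^2 / (n * p))
  }
  fit <- stats::optim(c(mu0, log(s0)), x2)
  statistic <- fit$value
  df <- bins - 3L
  list(statistic = statistic, df = df,
       p = stats::pchisq(statistic, df, lower.tail = FALSE), bins = bins)
}
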