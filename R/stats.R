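# Two-sample t-test and one-way ANOVA surfaces used by the study driver.
# Degenerate inputs (constant samples) are resolved by explicit convention
# before delegating to the standard tests.

#' Two-sample t-test on localization errors
#'
#' Classic Student's t-test with pooled variance by default (`var.equal =
#' TRUE`); Welch's unequal-variance form is available via the flag.
#' Convention for degenerate input: two constant samples give `t = 0,
#' p = 1` when their means are equal and `t = +/-Inf, p = 0` otherwise.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param var.equal Pool the variances (Student) or not (Welch).
#' @return List with elements `t`, `df` and `p` (two-sided).
#' @examples
#' t_test(rnorm(10), rnorm(10, 1))
#' @export
t_test <- function(sample_a, sample_b, var.equal = TRUE) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs >= 2 observations", call. = FALSE)
  if (sd(sample_a) == 0 && sd(sample_b) == 0) {
    dm <- mean(sample_a) - mean(sample_b)
    df <- length(sample_a) + length(sample_b) - 2
    if (dm == 0) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(dm) * Inf, df = df, p = 0))
  }
  ht <- t.test(sample_a, sample_b, var.equal = var.equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' One-way ANOVA across detector-subset groups
#'
#' Fixed-effects one-way analysis of variance (equal-variance form), used
#' to test whether localization accuracy depends on the number of
#' detectors. Convention for degenerate input: zero within-group variance
#' with equal group means gives `F = 0, p = 1`; zero within-group variance
#' with unequal means gives `F = Inf, p = 0`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each length >= 2).
#' @return List with elements `F`, `df` (numerator, denominator) and `p`.
#' @examples
#' one_way_anova(list(rnorm(10), rnorm(10), rnorm(10, 2)))
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("groups must be a list of >= 2 samples", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("each group needs >= 2 observations", call. = FALSE)
  df1 <- length(groups) - 1L
  df2 <- sum(lengths(groups)) - length(groups)
  if (all(vapply(groups, sd, numeric(1)) == 0)) {
    means <- vapply(groups, mean, numeric(1))
    if (max(means) - min(means) == 0)
      return(list(F = 0, df = c(df1, df2), p = 1))
    return(list(F = Inf, df = c(df1, df2), p = 0))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- oneway.test(values ~ labels, var.equal = TRUE)
  list(F = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
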