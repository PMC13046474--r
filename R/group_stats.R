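# Group statistics as pure functions with tidy (tibble) results. These wrap
# the standard base-R tests where one exists; the Dunn post-hoc z-tests are
# computed here (mid-rank ties, tie-corrected variance) since no installed
# package provides them.

#' Ratio-paired t-test
#'
#' Two-tailed paired t-test on natural-log ratios: a one-sample t of
#' `log(x/y)` against zero with `n - 1` degrees of freedom. Both members of
#' every pair must be positive.
#'
#' @param x,y Paired positive observations of equal length (n >= 2).
#' @return A tibble: `estimate` (geometric mean ratio x/y), `statistic`,
#'   `parameter` (df), `p.value`, `conf.low`, `conf.high`, `method`.
#' @export
#' @examples
#' ratio_paired_t(c(2.1, 3.9, 8.3), c(1, 2, 4))
ratio_paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_tm("need paired samples with n >= 2", "tm_parameter_error")
  }
  if (any(x <= 0) || any(y <= 0)) {
    stop_tm("ratio-paired t requires positive observations",
            "tm_parameter_error")
  }
  lr <- log(x / y)
  if (sd(lr) == 0) {
    stop_tm("degenerate_pairs: log-ratios have zero variance",
            "tm_degenerate_pairs")
  }
  tt <- t.test(lr)
  tibble(estimate = exp(mean(lr)),
         statistic = unname(tt$statistic),
         parameter = unname(tt$parameter),
         p.value = tt$p.value,
         conf.low = exp(tt$conf.int[1]),
         conf.high = exp(tt$conf.int[2]),
         method = "ratio paired t-test (t on log ratios)")
}

#' Nested t-test on per-unit summaries
#'
#' Summarizes each experimental unit (e.g. embryo) by one number (default
#' the median of its observations) and compares the two groups of unit
#' summaries by a two-sample t-test (equal-variance by default).
#'
#' @param data A data frame with one observation per row.
#' @param value,group,unit Column names (strings) of the observation value,
#'   group label and unit label.
#' @param summary Per-unit summary function (default [median]).
#' @param var_equal Equal-variance t (default TRUE); FALSE gives Welch.
#' @return A tibble: per-group unit counts and means of summaries,
#'   `statistic`, `parameter`, `p.value`, `method`.
#' @export
nested_t <- function(data, value, group, unit, summary = median,
                     var_equal = TRUE) {
  df <- tibble(value = data[[value]], group = data[[group]],
               unit = data[[unit]])
  per_unit <- df |>
    dplyr::summarise(s = summary(.data$value),
                     .by = c("group", "unit"))
  groups <- unique(per_unit$group)
  if (length(groups) != 2) stop_tm("need exactly 2 groups",
                                   "tm_parameter_error")
  s1 <- per_unit$s[per_unit$group == groups[1]]
  s2 <- per_unit$s[per_unit$group == groups[2]]
  if (length(s1) < 2 || length(s2) < 2) {
    stop_tm("need >= 2 units per group", "tm_parameter_error")
  }
  tt <- t.test(s1, s2, var.equal = var_equal)
  tibble(group1 = as.character(groups[1]), group2 = as.character(groups[2]),
         n1 = length(s1), n2 = length(s2),
         mean1 = mean(s1), mean2 = mean(s2),
         statistic = unname(tt$statistic), parameter = unname(tt$parameter),
         p.value = tt$p.value,
         method = paste0("nested t (per-unit summaries, ",
                         if (var_equal) "pooled" else "Welch", ")"))
}

#' Two-sample rank-sum test
#'
#' Wilcoxon rank-sum (Mann-Whitney) test with mid-rank ties, two-sided.
#'
#' @param x,y Numeric samples.
#' @return A tibble: `statistic` (the Mann-Whitney U of `x`), `p.value`,
#'   `method`.
#' @export
rank_sum <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    stop_tm("both groups must be non-empty", "tm_parameter_error")
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = TRUE, correct = TRUE))
  tibble(statistic = unname(wt$statistic), p.value = wt$p.value,
         method = "Wilcoxon rank-sum")
}

#' Welch two-sample t-test
#'
#' @param x,y Numeric samples.
#' @return A tibble: `statistic`, `parameter`, `p.value`, `method`.
#' @export
welch_t <- function(x, y) {
  tt <- t.test(x, y, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
         p.value = tt$p.value, method = "Welch t")
}

#' One-sample t-test
#'
#' @param x Numeric sample.
#' @param mu Null value (default 1, the no-change value for ratios).
#' @return A tibble: `estimate`, `statistic`, `parameter`, `p.value`.
#' @export
one_sample_t <- function(x, mu = 1) {
  tt <- t.test(x, mu = mu)
  tibble(estimate = mean(x), statistic = unname(tt$statistic),
         parameter = unname(tt$parameter), p.value = tt$p.value,
         method = sprintf("one-sample t vs %g", mu))
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Kruskal-Wallis rank test across all groups, followed by Dunn's pairwise
#' z-tests on mean ranks (mid-rank ties, tie-corrected variance), with
#' multiplicity adjustment (Holm by default, Bonferroni optional).
#'
#' @param data A data frame.
#' @param value,group Column names (strings).
#' @param p_adjust `"holm"` (default) or `"bonferroni"`.
#' @return A list: `kruskal` (tibble: `statistic`, `parameter`, `p.value`),
#'   `dunn` (tibble: `group1`, `group2`, `z`, `p.value`, `p.adjusted`).
#' @export
kruskal_dunn <- function(data, value, group,
                         p_adjust = c("holm", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  v <- data[[value]]
  gr <- factor(data[[group]])
  if (any(table(gr) == 0) || nlevels(gr) < 2) {
    stop_tm("need >= 2 non-empty groups", "tm_parameter_error")
  }
  kw <- kruskal.test(v, gr)
  n <- length(v)
  rk <- rank(v)  # mid-ranks
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(rk, gr, mean)
  ni <- tapply(rk, gr, length)
  pairs <- utils::combn(levels(gr), 2)
  dunn <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[a]] + 1 / ni[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    tibble(group1 = a, group2 = b, z = z,
           p.value = 2 * pnorm(-abs(z)))
  }) |> dplyr::bind_rows()
  dunn$p.adjusted <- p.adjust(dunn$p.value, method = p_adjust)
  list(kruskal = tibble(statistic = unname(kw$statistic),
                        parameter = unname(kw$parameter),
                        p.value = kw$p.value),
       dunn = dunn)
}
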