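#' Two-sided Mann-Whitney U test
#'
#' Wraps the rank-sum test in the convention used for the group
#' comparisons: two-sided, exact when both samples are small and untied,
#' normal approximation with continuity and tie correction otherwise.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @return data frame of class `"group_comparison"`: test, U statistic
#'   (for `sample_a` vs `sample_b`), raw and adjusted p (equal here),
#'   group sizes, effect direction.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  if (length(unique(c(sample_a, sample_b))) == 1) {
    warning("all observations tied; p set to 1")
    return(group_comparison("mann-whitney", statistic =
                              length(sample_a) * length(sample_b) / 2,
                            p = 1, p_adj = 1,
                            n = c(length(sample_a), length(sample_b)),
                            direction = "none"))
  }
  exact <- length(sample_a) <= 20 && length(sample_b) <= 20 &&
    !any(duplicated(c(sample_a, sample_b)))
  wt <- suppressWarnings(wilcox.test(sample_a, sample_b,
                                     alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  dir <- if (median(sample_a) > median(sample_b)) "a>b"
  else if (median(sample_a) < median(sample_b)) "a<b" else "none"
  group_comparison("mann-whitney", statistic = unname(wt$statistic),
                   p = wt$p.value, p_adj = wt$p.value,
                   n = c(length(sample_a), length(sample_b)),
                   direction = dir)
}

group_comparison <- function(test, statistic, p, p_adj, n, direction,
                             comparison = NA_character_) {
  out <- data.frame(test = test, comparison = comparison,
                    statistic = statistic, p = p, p_adj = p_adj,
                    n1 = n[1], n2 = if (length(n) > 1) n[2] else NA,
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Nonparametric comparison of three or more groups: a Kruskal-Wallis
#' omnibus test followed by Dunn's z-tests of each group against a
#' reference group, Bonferroni-adjusted.  Dunn's statistic uses the mean
#' ranks of the pooled (omnibus) ranking with the standard tie correction.
#'
#' @param groups named list of numeric vectors (>= 3 groups, each with at
#'   least 2 members).
#' @param reference_group name of the reference group.
#' @return `"group_comparison"` data frame, one row per comparison, with
#'   the omnibus test as attributes `omnibus_statistic`, `omnibus_p`,
#'   `omnibus_df`.
#' @export
kruskal_dunn <- function(groups, reference_group = names(groups)[1]) {
  stopifnot(is.list(groups), length(groups) >= 3,
            reference_group %in% names(groups))
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 members")
  kw <- kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, integer(1)))
  r <- rank(x)
  n <- length(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  others <- setdiff(names(groups), reference_group)
  rows <- lapply(others, function(gr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / ns[[gr]] + 1 / ns[[reference_group]]))
    z <- (rbar[[gr]] - rbar[[reference_group]]) / se
    p <- 2 * pnorm(-abs(z))
    group_comparison("dunn", statistic = z, p = p, p_adj = NA,
                     n = c(ns[[gr]], ns[[reference_group]]),
                     direction = if (z > 0) "group>ref" else
                       if (z < 0) "group<ref" else "none",
                     comparison = paste(gr, "vs", reference_group))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "bonferroni")
  attr(out, "omnibus_statistic") <- unname(kw$statistic)
  attr(out, "omnibus_p") <- kw$p.value
  attr(out, "omnibus_df") <- unname(kw$parameter)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Ordinary least-squares regression of a behavior score on a geometry
#' metric
#'
#' @param x predictor (e.g., per-fish dM between the conditioned odors).
#' @param y outcome (e.g., per-fish behavioral discrimination score).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value` (slope,
#'   two-sided), `n`.
#' @export
ols_regression <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired points")
  if (sd(x) == 0) stop("zero variance in the predictor")
  fit <- lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = s$coefficients[2, 4], n = length(x))
}

#' Significance stars in the display convention of the analyses
#'
#' @param p p-value(s).
#' @return character: `"n.s."`, `"*"`, `"**"` or `"***"`.
#' @export
significance_label <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) NA_character_
    else if (pp < 0.001) "***"
    else if (pp < 0.01) "**"
    else if (pp < 0.05) "*"
    else "n.s."
  }, character(1))
}

#' @export
print.group_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$signif <- significance_label(df$p_adj)
  if (!is.null(attr(x, "omnibus_p")))
    cat(sprintf("Kruskal-Wallis omnibus: H = %.3f, df = %d, P = %.3g\n",
                attr(x, "omnibus_statistic"), attr(x, "omnibus_df"),
                attr(x, "omnibus_p")))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
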