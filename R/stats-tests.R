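#' Two-tailed Welch t-test
#'
#' Two-sample, two-tailed t-test (Welch, unequal variances), the test used
#' for pairwise comparisons such as clone-ratio and contacting versus
#' non-contacting cytoneme punctum loads. Identical samples give t = 0,
#' p = 1.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
welchT <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    }
    stop("zero variance in both samples with unequal means")
  }
  tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' One-way ANOVA with Tukey HSD
#'
#' One-way analysis of variance across groups followed by Tukey's honestly
#' significant difference test on the group means (studentized range), as
#' used for multi-region cytoneme-count comparisons.
#'
#' @param groups either a named list of numeric vectors, or a numeric
#'   vector when \code{g} gives the grouping factor.
#' @param g optional grouping factor matching \code{groups}.
#' @return list with \code{F}, \code{p} and \code{hsd}, a data.frame of
#'   pairwise comparisons (diff, lwr, upr, p_adj).
#' @export
anovaTukey <- function(groups, g = NULL) {
  if (is.list(groups)) {
    if (is.null(names(groups))) {
      names(groups) <- paste0("g", seq_along(groups))
    }
    g <- factor(rep(names(groups), lengths(groups)),
                levels = names(groups))
    y <- unlist(groups, use.names = FALSE)
  } else {
    y <- groups
    g <- factor(g)
  }
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(tapply(y, g, length) < 2)) stop("each group needs n >= 2")
  wvar <- tapply(y, g, stats::var)
  if (all(wvar == 0)) {
    stop("zero within-group variance in every group")
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  hsd <- stats::TukeyHSD(fit)$g
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       hsd = data.frame(comparison = rownames(hsd),
                        diff = hsd[, "diff"], lwr = hsd[, "lwr"],
                        upr = hsd[, "upr"], p_adj = hsd[, "p adj"],
                        row.names = NULL))
}
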