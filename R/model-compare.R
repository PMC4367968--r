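#' Nonparametric comparison of IREG between groups
#'
#' Omnibus Kruskal-Wallis rank test (with tie correction) followed by
#' Dunn's pairwise post-hoc z tests. The Dunn statistic for groups i, j is
#' `(Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `Rbar` are mean ranks over the pooled sample and
#' `T = sum(t^3 - t)` over tie groups; two-sided p-values from the normal
#' distribution, optionally multiplicity-adjusted (classic unadjusted Dunn
#' by default, as is common practice; Bonferroni/Holm by argument).
#'
#' @param values list of numeric vectors (one per group, each length >= 2)
#'   or a single numeric vector accompanied by `groups`.
#' @param groups group labels when `values` is a vector.
#' @param adjust p-value adjustment for the pairwise tests: `"none"`
#'   (default), `"bonferroni"` or `"holm"`.
#' @return list with `kruskal` (statistic `H`, `df`, `p`) and `pairwise`
#'   (data frame: `group1`, `group2`, `z`, `p`, `p_adjusted`,
#'   `significant` at 0.05).
#' @examples
#' compareGroups(list(wt = c(0.9, 0.95, 0.92), deg = c(0.1, 0.2, 0.15)))
#' @export
compareGroups <- function(values, groups = NULL, adjust = "none") {
  if (is.list(values)) {
    groups <- rep(names(values) %||% seq_along(values),
                  lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(tabulate(groups) < 2L)) stop("every group needs at least 2 values")

  if (length(unique(values)) == 1L) {
    kw <- list(H = 0, df = nlevels(groups) - 1L, p = 1)
  } else {
    k <- stats::kruskal.test(values, groups)
    kw <- list(H = unname(k$statistic), df = unname(k$parameter),
               p = k$p.value)
  }

  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, groups, mean)
  n <- tabulate(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(groups)
  pairs <- utils::combn(seq_along(lv), 2)
  z <- p <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    sigma <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    z[c] <- if (sigma == 0) 0 else (rbar[i] - rbar[j]) / sigma
    p[c] <- 2 * stats::pnorm(abs(z[c]), lower.tail = FALSE)
  }
  p_adj <- stats::p.adjust(p, method = adjust)
  pairwise <- data.frame(group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
                         z = z, p = p, p_adjusted = p_adj,
                         significant = p_adj < 0.05)
  list(kruskal = kw, pairwise = pairwise)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
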