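# Group-level inference: Mann-Whitney rank-sum comparison of the two
# groups, Benjamini-Hochberg FDR adjustment, Hedges' g effect size, and
# Fisher's exact mid-P association test for the sex confound check.

#' Two-sample rank-sum (Mann-Whitney) test
#'
#' Two-sided Mann-Whitney U test comparing two independent samples: exact
#' enumeration when the pooled sample size is at most 12 and there are no
#' ties, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return list with \code{p} (two-sided p value) and \code{U} (the
#'   Mann-Whitney U statistic for the first sample).
#' @export
rank_sum_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("both samples must have at least 2 observations")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  list(p = wt$p.value, U = unname(wt$statistic))
}

#' Benjamini-Hochberg FDR adjustment with rejection flags
#'
#' Step-up procedure at level \code{q}; adjusted p values are the standard
#' monotone BH values and a hypothesis is rejected when its adjusted p is
#' at most \code{q}.
#'
#' @param p vector of p values in [0, 1].
#' @param q FDR level.
#' @return list with \code{rejected} (logical) and \code{p_adjusted}.
#' @export
bh_fdr <- function(p, q = 0.05) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(rejected = adj <= q, p_adjusted = adj)
}

#' Hedges' g standardized mean difference
#'
#' \eqn{g = J (\bar a - \bar b) / s_p} with pooled standard deviation
#' \eqn{s_p} and small-sample correction
#' \eqn{J = 1 - 3 / (4(n_a + n_b) - 9)}.
#'
#' @param a,b numeric samples with \code{n_a + n_b >= 3}.
#' @return an object of class \code{effect_size} with \code{g}, \code{n1},
#'   \code{n2}, \code{pooled_sd}.
#' @export
hedges_g <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n1 <- length(a); n2 <- length(b)
  if (n1 + n2 < 3) stop("need at least 3 observations in total")
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) stop("pooled variance is zero")
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  structure(list(g = J * (mean(a) - mean(b)) / sqrt(sp2),
                 n1 = n1, n2 = n2, pooled_sd = sqrt(sp2)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat("Hedges' g = ", signif(x$g, 4), " (n1 = ", x$n1, ", n2 = ", x$n2,
      ", pooled sd = ", signif(x$pooled_sd, 4), ")\n", sep = "")
  invisible(x)
}

#' Fisher's exact mid-P test for a 2x2 table
#'
#' Exact hypergeometric test with half-weighting of the observed table:
#' the one-sided mid-P is P(more extreme) + P(observed)/2 under the
#' hypergeometric null; the two-sided value doubles the smaller one-sided
#' mid-P, capped at 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}; sidedness refers to the [1,1] cell.
#' @return the mid-P value.
#' @export
fisher_mid_p <- function(table, alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("`table` must be a 2x2 matrix of non-negative integer counts")
  a <- tab[1, 1]
  m <- sum(tab[1, ])        # row-1 margin
  n <- sum(tab[2, ])        # row-2 margin
  k <- sum(tab[, 1])        # column-1 margin
  hi <- min(m, k)
  lo <- max(0, k - n)
  p_obs <- dhyper(a, k, m + n - k, m)
  p_greater <- p_obs / 2 +
    if (a < hi) sum(dhyper((a + 1):hi, k, m + n - k, m)) else 0
  p_less <- p_obs / 2 +
    if (a > lo) sum(dhyper(lo:(a - 1), k, m + n - k, m)) else 0
  switch(alternative,
         greater = p_greater,
         less = p_less,
         two.sided = min(1, 2 * min(p_greater, p_less)))
}

#' Group comparison table for spatial extents or connectivity measures
#'
#' Convenience wrapper: rank-sum p, BH adjustment across comparisons, and
#' Hedges' g for a named list of (control, injured) sample pairs.
#'
#' @param pairs named list; each element is a list with components \code{a}
#'   and \code{b} (the two groups' samples).
#' @param q FDR level for the adjustment across comparisons.
#' @return data frame with columns \code{comparison}, \code{U}, \code{p},
#'   \code{p_adjusted}, \code{rejected}, \code{g}, \code{n1}, \code{n2}.
#' @export
group_comparison_table <- function(pairs, q = 0.05) {
  rows <- lapply(names(pairs), function(nm) {
    a <- pairs[[nm]]$a; b <- pairs[[nm]]$b
    rs <- rank_sum_test(a, b)
    g <- tryCatch(hedges_g(a, b)$g, error = function(e) NA_real_)
    data.frame(comparison = nm, U = rs$U, p = rs$p, g = g,
               n1 = length(a), n2 = length(b))
  })
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p, q)
  out$p_adjusted <- adj$p_adjusted
  out$rejected <- adj$rejected
  out[, c("comparison", "U", "p", "p_adjusted", "rejected", "g", "n1", "n2")]
}
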