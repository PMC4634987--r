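#' Fisher's exact test for a 2x2 table with odds ratio
#'
#' Two-sided p-value by the sum-of-smaller-or-equal-probabilities convention:
#' the sum of hypergeometric probabilities (margins fixed) of all tables at
#' most as probable as the observed one. The odds ratio is `ad/bc` with the
#' Haldane-Anscombe +0.5 correction applied to all cells when any cell is
#' zero; the 95% CI uses the Woolf logit method on the (corrected) counts.
#'
#' @param tab 2x2 integer matrix (rows = groups, columns = absent/present),
#'   or a length-4 vector `(a, b, c, d)` filled by row.
#' @return list with `p`, `or`, `ci` (length 2), `table`.
#' @export
fisher_2x2 <- function(tab) {
  tab <- as_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("fisher_2x2: table has an empty margin")
  nd <- table_null(tab)
  obs <- tab[1, 1]
  p <- nd$pval[match(obs, nd$support)]
  cc <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (cc[1, 1] * cc[2, 2]) / (cc[1, 2] * cc[2, 1])
  se <- sqrt(sum(1 / cc))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(p = p, or = or, ci = ci, table = tab)
}

as_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    stop("fisher_2x2: need a 2x2 table of non-negative integers")
  tab
}

# Hypergeometric null of a 2x2 table with fixed margins: the support of the
# (1,1) cell, each table's null probability, and the two-sided p-value that
# each support point would yield. Shared by fisher_2x2 and carlson_fdr.
table_null <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- stats::dhyper(support, c1, n - c1, r1)
  rel <- 1 + 1e-7  # guard against FP noise when comparing equal probabilities
  pval <- vapply(prob, function(p0) sum(prob[prob <= p0 * rel]), numeric(1))
  list(support = support, prob = prob, pval = pmin(pval, 1))
}

#' Breslow-Day test of odds-ratio homogeneity
#'
#' Classic Breslow-Day statistic against the Mantel-Haenszel common odds
#' ratio; under homogeneity it is chi-squared with (#strata - 1) degrees of
#' freedom. Strata with an empty margin are dropped with a warning. Set
#' `tarone = TRUE` for the Tarone correction.
#'
#' @param strata list of 2x2 tables (as in [fisher_2x2()]).
#' @param tarone apply Tarone's correction.
#' @return list with `statistic`, `df`, `p`, `or_mh`.
#' @export
breslow_day <- function(strata, tarone = FALSE) {
  strata <- lapply(strata, as_2x2)
  ok <- vapply(strata, function(t)
    all(rowSums(t) > 0) && all(colSums(t) > 0), logical(1))
  if (any(!ok)) {
    warning("breslow_day: dropping ", sum(!ok), " strata with empty margins")
    strata <- strata[ok]
  }
  if (length(strata) < 2)
    stop("breslow_day: need at least 2 usable strata")
  n <- vapply(strata, sum, numeric(1))
  R <- sum(vapply(strata, function(t) t[1, 1] * t[2, 2], numeric(1)) / n)
  S <- sum(vapply(strata, function(t) t[1, 2] * t[2, 1], numeric(1)) / n)
  if (S == 0 || R == 0)
    stop("breslow_day: Mantel-Haenszel common odds ratio not estimable")
  or <- R / S
  stat <- 0
  resid_sum <- 0
  var_sum <- 0
  for (t in strata) {
    r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); N <- sum(t)
    # expected (1,1) cell under the common OR: root of a quadratic in a
    A <- or - 1
    B <- -(or * (r1 + c1) + (N - r1 - c1))
    C <- or * r1 * c1
    a_hat <- if (abs(A) < 1e-12) -C / B else {
      roots <- (-B + c(-1, 1) * sqrt(B^2 - 4 * A * C)) / (2 * A)
      roots[roots > max(0, r1 + c1 - N) - 1e-9 &
              roots < min(r1, c1) + 1e-9][1]
    }
    b_hat <- r1 - a_hat; c_hat <- c1 - a_hat; d_hat <- N - r1 - c1 + a_hat
    v <- 1 / (1 / a_hat + 1 / b_hat + 1 / c_hat + 1 / d_hat)
    stat <- stat + (t[1, 1] - a_hat)^2 / v
    resid_sum <- resid_sum + (t[1, 1] - a_hat)
    var_sum <- var_sum + v
  }
  if (tarone) stat <- stat - resid_sum^2 / var_sum
  df <- length(strata) - 1L
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), or_mh = or)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact by enumeration of rank assignments when the smaller group has at
#' most 8 observations, there are no ties, and the enumeration is tractable
#' (`choose(n1 + n2, n1) <= 5e5`); otherwise a normal approximation with tie
#' and continuity corrections.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `U` (statistic for `x`), `p`, `exact`.
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y))
    stop("mann_whitney: both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && min(n1, n2) <= 8 && choose(n1 + n2, n1) <= 5e5) {
    combos <- utils::combn(n1 + n2, min(n1, n2))
    u_all <- colSums(combos) - min(n1, n2) * (min(n1, n2) + 1) / 2
    u_ref <- if (n1 <= n2) U else n1 * n2 - U
    p <- min(1, 2 * min(mean(u_all <= u_ref), mean(u_all >= u_ref)))
    return(list(U = U, p = p, exact = TRUE))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Cohen's kappa for two binary vectors
#'
#' @param u,v binary (0/1 or logical) vectors of equal length >= 2.
#' @return kappa = (p_o - p_e) / (1 - p_e) with marginal-product expected
#'   agreement.
#' @export
cohens_kappa <- function(u, v) {
  u <- as.integer(u); v <- as.integer(v)
  if (length(u) != length(v) || length(u) < 2)
    stop("cohens_kappa: need two equal-length vectors of length >= 2")
  po <- mean(u == v)
  pe <- mean(u) * mean(v) + mean(1 - u) * mean(1 - v)
  if (1 - pe < 1e-12)
    stop("cohens_kappa: expected agreement is 1 (degenerate marginals)")
  (po - pe) / (1 - pe)
}

#' Benjamini-Hochberg q-values with explicit family size
#'
#' Step-up q-values `q_(i) = min_{k >= i} p_(k) * m / k`, clipped at 1 and
#' mapped back to input order. The family size `m` may exceed the number of
#' supplied p-values (tests not carried out still count toward the family).
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param m family size; defaults to `length(pvals)`.
#' @return q-values in input order.
#' @export
bh_qvalues <- function(pvals, m = length(pvals)) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("bh_qvalues: p-values must lie in (0, 1]")
  if (m < length(pvals))
    stop("bh_qvalues: family size m must be >= number of p-values")
  o <- order(pvals)
  n <- length(pvals)
  q <- pmin(1, rev(cummin(rev(pvals[o] * m / seq_len(n)))))
  q[order(o)]
}

#' Discrete false-discovery-rate q-values for families of 2x2 tables
#'
#' Estimates FDR q-values taking the discreteness of Fisher's exact test into
#' account: for each candidate threshold t (the observed p-values), the
#' expected number of null discoveries is the sum over family members of the
#' probability, under each member's own hypergeometric null, of attaining a
#' p-value at most t; `FDR(t)` divides by the observed discovery count, and
#' `q_i = min over t >= p_i of FDR(t)`, clipped at 1. When `filter` is on,
#' tables that cannot attain a p-value at or below `alpha_cap` under any
#' outcome with their margins (provably irrelevant tests) are removed from
#' the family first; their q-values are reported as NA.
#'
#' @param tables list of 2x2 tables (as in [fisher_2x2()]).
#' @param filter drop provably irrelevant tables from the family.
#' @param alpha_cap filtering cap on the minimum attainable p-value.
#' @return data.frame in input order: `p` (observed two-sided Fisher p),
#'   `min_p` (minimum attainable p given the margins), `filtered`, `q`.
#' @export
carlson_fdr <- function(tables, filter = TRUE, alpha_cap = 0.05) {
  tables <- lapply(tables, as_2x2)
  nulls <- lapply(tables, table_null)
  obs_p <- vapply(seq_along(tables), function(i)
    nulls[[i]]$pval[match(tables[[i]][1, 1], nulls[[i]]$support)], numeric(1))
  min_p <- vapply(nulls, function(nd) min(nd$pval), numeric(1))
  filtered <- if (filter) min_p > alpha_cap else rep(FALSE, length(tables))
  q <- rep(NA_real_, length(tables))
  keep <- which(!filtered)
  if (length(keep)) {
    pk <- obs_p[keep]
    thr <- sort(unique(pk))
    # expected null discoveries at each threshold
    e_null <- vapply(thr, function(t) {
      sum(vapply(nulls[keep], function(nd)
        sum(nd$prob[nd$pval <= t * (1 + 1e-12)]), numeric(1)))
    }, numeric(1))
    n_disc <- vapply(thr, function(t) sum(pk <= t * (1 + 1e-12)), numeric(1))
    fdr <- e_null / pmax(1, n_disc)
    q[keep] <- vapply(pk, function(p) {
      min(1, min(fdr[thr >= p * (1 - 1e-12)]))
    }, numeric(1))
  }
  data.frame(p = obs_p, min_p = min_p, filtered = filtered, q = q)
}
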