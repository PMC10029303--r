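#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control. Thin wrapper around
#' [stats::p.adjust()] kept as the single place multiple-testing
#' correction happens in this package; order-preserving and capped at 1.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stopifnot(is.numeric(pvalues), all(is.na(pvalues) | (pvalues > 0 & pvalues <= 1)))
  stats::p.adjust(pvalues, method = "BH")
}

#' Exact two-sided binomial test
#'
#' Exact binomial test of `k` successes in `n` trials against null
#' proportion `p0`, two-sided by the minimum-likelihood convention
#' (outcomes with probability no larger than that of `k` contribute to
#' the p-value), as in [stats::binom.test()].
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param p0 Null proportion in (0, 1).
#' @return A list of class `plastevo_test` with elements `statistic`
#'   (observed proportion), `pvalue`, `effect` (k, n, p0).
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("binomial test requires n > 0")
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  ht <- stats::binom.test(k, n, p = p0, alternative = "two.sided")
  structure(list(statistic = k / n, pvalue = ht$p.value,
                 effect = c(k = k, n = n, p0 = p0)),
            class = "plastevo_test")
}

#' Fisher exact test for 2 x C tables with post hoc pairwise tests
#'
#' For C = 2 the exact hypergeometric two-sided p-value; for C > 2 the
#' exact conditional test when the table is small enough to enumerate,
#' otherwise a Monte-Carlo p-value with `mc_reps` draws under a fixed
#' seed. When C > 2, all pairwise 2 x 2 column comparisons are run post
#' hoc and BH-adjusted.
#'
#' @param table A 2 x C matrix of non-negative integer counts.
#' @param mc_reps Monte-Carlo replicates used when enumeration is
#'   infeasible.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return A `plastevo_test` with `statistic` (NA; the test is exact),
#'   `pvalue`, and when C > 2 a data frame `posthoc` with columns
#'   `col_a`, `col_b`, `pvalue`, `padj`.
#' @export
fisher_exact <- function(table, mc_reps = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (nrow(table) != 2L || ncol(table) < 2L)
    stop("expected a 2 x C table with C >= 2")
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: Fisher exact p-value set to 1")
    return(structure(list(statistic = NA_real_, pvalue = 1,
                          effect = NULL, posthoc = NULL),
                     class = "plastevo_test"))
  }
  # fisher.test enumerates the conditional null exactly for workable
  # tables; fall back to Monte Carlo for large ones
  feasible <- prod(colSums(table) + 1) <= 1e7
  p <- if (feasible) {
    stats::fisher.test(table, workspace = 2e7)$p.value
  } else {
    set.seed(seed)
    stats::fisher.test(table, simulate.p.value = TRUE, B = mc_reps)$p.value
  }
  posthoc <- NULL
  if (ncol(table) > 2L) {
    pairs <- utils::combn(ncol(table), 2)
    pp <- apply(pairs, 2, function(ij)
      stats::fisher.test(table[, ij])$p.value)
    posthoc <- data.frame(col_a = pairs[1, ], col_b = pairs[2, ],
                          pvalue = pp, padj = bh_adjust(pp))
  }
  structure(list(statistic = NA_real_, pvalue = min(1, p),
                 effect = NULL, posthoc = posthoc),
            class = "plastevo_test")
}

#' Kruskal-Wallis omnibus test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) plus
#' two-sided Dunn z-tests on the pooled average ranks for every pair of
#' groups, BH-adjusted. The Dunn variance uses the standard tie
#' correction \eqn{(N(N+1)/12 - \sum(t^3 - t)/(12(N-1)))}.
#'
#' @param groups A list of numeric vectors, one per group (>= 2 groups,
#'   all non-empty).
#' @return A `plastevo_test` with `statistic` (H), `pvalue`, `effect`
#'   (group medians) and a data frame `posthoc` (group_a, group_b, z,
#'   pvalue, padj).
#' @export
kruskal_wallis_dunn <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) == 0L)) stop("empty group")
  labs <- names(groups)
  if (is.null(labs)) labs <- as.character(seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labs, vapply(groups, length, 1L)), levels = labs)
  kw <- stats::kruskal.test(x, g)

  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- table(x)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tiecor
  pairs <- utils::combn(length(labs), 2)
  z <- apply(pairs, 2, function(ij) {
    (rbar[ij[1]] - rbar[ij[2]]) /
      sqrt(s2 * (1 / n[ij[1]] + 1 / n[ij[2]]))
  })
  pp <- 2 * stats::pnorm(-abs(z))
  posthoc <- data.frame(group_a = labs[pairs[1, ]],
                        group_b = labs[pairs[2, ]],
                        z = as.numeric(z), pvalue = pp,
                        padj = bh_adjust(pp))
  structure(list(statistic = unname(kw$statistic), pvalue = kw$p.value,
                 effect = vapply(groups, stats::median, 1),
                 posthoc = posthoc),
            class = "plastevo_test")
}

#' One-sided Spearman correlation test
#'
#' Spearman's rho on average ranks with a one-sided p-value: exact by
#' permutation for n <= 9 (no ties), otherwise the t-approximation, as
#' in [stats::cor.test()].
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param alternative `"greater"` or `"less"`.
#' @return A `plastevo_test` with `statistic` (rho) and `pvalue`.
#' @export
spearman_one_sided <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation undefined")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ht <- suppressWarnings(stats::cor.test(
    x, y, method = "spearman", alternative = alternative,
    exact = length(x) <= 9L && !ties))
  structure(list(statistic = unname(ht$estimate), pvalue = ht$p.value,
                 effect = NULL),
            class = "plastevo_test")
}

#' Annotation-term enrichment with level-wise BH correction
#'
#' One-sided (enrichment) hypergeometric test of each annotation term
#' in a target gene set against a background universe. When a
#' parent-child hierarchy is supplied, terms are grouped by depth
#' (shortest path from a root, i.e. a term with no parent) and BH is
#' applied within each depth level; without a hierarchy all terms form
#' a single BH family.
#'
#' @param target Character vector of target gene ids (subset of
#'   `background`).
#' @param background Character vector: the gene universe.
#' @param annotations Named list: term id -> character vector of genes.
#' @param hierarchy Optional two-column data frame or matrix
#'   (child, parent) of term ids.
#' @return Data frame with columns `term`, `level`, `n_target`,
#'   `n_background`, `pvalue`, `padj`, one row per term with at least
#'   one background gene.
#' @export
term_enrichment <- function(target, background, annotations,
                            hierarchy = NULL) {
  if (!all(target %in% background))
    stop("target must be a subset of background")
  target <- unique(target); background <- unique(background)
  n_t <- length(target); n_b <- length(background)

  rows <- lapply(names(annotations), function(term) {
    genes <- intersect(annotations[[term]], background)
    if (length(genes) == 0L) return(NULL)
    k <- sum(genes %in% target)
    m <- length(genes)
    # P(X >= k), X ~ Hypergeom(m annotated, n_b - m not, n_t drawn)
    p <- stats::phyper(k - 1, m, n_b - m, n_t, lower.tail = FALSE)
    data.frame(term = term, n_target = k, n_background = m,
               pvalue = min(1, p))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term = character(0),
                                      level = integer(0),
                                      n_target = integer(0),
                                      n_background = integer(0),
                                      pvalue = numeric(0),
                                      padj = numeric(0)))
  out$level <- term_depths(out$term, hierarchy)
  out$padj <- NA_real_
  for (lv in unique(out$level)) {
    sel <- out$level == lv
    out$padj[sel] <- bh_adjust(out$pvalue[sel])
  }
  out[, c("term", "level", "n_target", "n_background", "pvalue", "padj")]
}

# Depth of each term: shortest path (number of edges) up to a root of
# the child->parent hierarchy; terms absent from the hierarchy (or when
# no hierarchy is given) are level 0 and share one BH family.
term_depths <- function(terms, hierarchy) {
  if (is.null(hierarchy)) return(rep(0L, length(terms)))
  hierarchy <- as.data.frame(hierarchy)
  child <- as.character(hierarchy[[1]])
  parent <- as.character(hierarchy[[2]])
  all_terms <- unique(c(child, parent))
  roots <- setdiff(all_terms, child)
  depth <- stats::setNames(rep(NA_integer_, length(all_terms)), all_terms)
  depth[roots] <- 0L
  frontier <- roots
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- unique(child[parent %in% frontier])
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  out <- depth[terms]
  out[is.na(out)] <- 0L
  unname(out)
}
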