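#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the reference expression of each
#' gene is its geometric mean over samples with nonzero counts; a
#' sample's factor is the median of its count-to-reference ratios over
#' genes it expresses, rescaled so the factors have geometric mean 1.
#'
#' @param x A [count_matrix()] or a counts matrix.
#' @return Named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (!any(rowSums(counts > 0) == ncol(counts)))
    stop("no gene expressed in all samples; supply counts with at least ",
         "one all-positive gene or normalize against a pseudo-reference")
  lc <- log(counts)
  lc[counts == 0] <- NA
  ref <- exp(rowMeans(lc, na.rm = TRUE))          # all-zero genes -> NaN
  fac <- vapply(seq_len(ncol(counts)), function(s) {
    r <- counts[, s] / ref
    stats::median(r[counts[, s] > 0 & is.finite(r)])
  }, 1.0)
  if (any(!is.finite(fac) | fac <= 0)) stop("degenerate size factors")
  fac <- fac / exp(mean(log(fac)))
  stats::setNames(fac, colnames(counts))
}

#' Log2 expression transform
#'
#' `log2(count / factor + 1)`, a simple variance-flattening transform
#' used for sample clustering and the co-expression stage (the
#' downstream statistics depend only on distances and correlations,
#' not the exact transform).
#'
#' @param x A [count_matrix()].
#' @param factors Size factors from [size_factors()] (computed if
#'   omitted).
#' @return Numeric matrix, genes x samples.
#' @export
log_transform <- function(x, factors = size_factors(x)) {
  log2(sweep(x$counts, 2, factors, "/") + 1)
}

#' Average-linkage sample clustering
#'
#' Euclidean distances between samples over all genes, agglomerated by
#' average linkage.
#'
#' @param expr Expression matrix from [log_transform()] (genes x
#'   samples).
#' @param k Optional number of flat clusters to cut.
#' @return List with `hclust` (the tree) and `labels` (flat cluster
#'   ids, `NULL` unless `k` given).
#' @export
sample_cluster <- function(expr, k = NULL) {
  if (ncol(expr) < 3) stop("need at least 3 samples to cluster")
  hc <- stats::hclust(stats::dist(t(expr)), method = "average")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels)
}

# Normalized per-group means and the ingredients of the delta-method
# SE. eps is a pseudo-mean of half a count on the normalized scale
# (0.5 divided by the harmonic mean of the size factors, ~0.5 since
# the factors have geometric mean 1): keeps log2 fold changes of
# near-zero genes finite with bounded bias.
norm_parts <- function(cm) {
  sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2, sf, "/")
  eps <- 0.5 / (1 / mean(1 / sf))
  list(norm = norm, sf = sf, eps = eps)
}

# Pooled method-of-moments NB dispersion across a list of sample-index
# groups, with a parametric mean trend alpha(mu) = a/mu + b fitted by
# least squares and gene estimates shrunk halfway to the trend.
moment_dispersion <- function(norm, groups, sf) {
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  if (length(groups) == 0L) stop("need at least one group with >= 2 samples")
  n_tot <- sum(vapply(groups, length, 1L))
  rss <- 0
  musum <- 0
  for (g in groups) {
    sub <- norm[, g, drop = FALSE]
    m <- rowMeans(sub)
    rss <- rss + rowSums((sub - m)^2)
    musum <- musum + length(g) * m
  }
  mu <- musum / n_tot
  s2 <- rss / (n_tot - length(groups))
  cbar <- mean(1 / sf[unlist(groups)])     # E Var(c/f) = mu/f + alpha mu^2
  raw <- (s2 - mu * cbar) / mu^2
  raw[!is.finite(raw)] <- NA
  ok <- is.finite(raw) & mu > 0
  alpha <- rep(1e-8, length(mu))
  if (sum(ok) >= 10) {
    fit <- stats::lm(raw[ok] ~ I(1 / mu[ok]))
    trend <- pmax(stats::coef(fit)[1] + stats::coef(fit)[2] / mu, 0)
    alpha[ok] <- 0.5 * raw[ok] + 0.5 * trend[ok]
  } else if (any(ok)) {
    alpha[ok] <- raw[ok]
  }
  pmax(alpha, 1e-8)
}

# Delta-method variance of a group's normalized mean on the natural
# scale: Var(mean) = (1/n^2) sum_s (mu/f_s + alpha mu^2).
group_mean_var <- function(mu, alpha, sf_group) {
  n <- length(sf_group)
  rowSums(outer(mu, 1 / sf_group) + alpha * mu^2) / n^2
}

resolve_samples <- function(cm, sel) {
  ids <- cm$design$sample
  if (is.logical(sel)) ids[sel]
  else if (is.numeric(sel)) ids[sel]
  else {
    if (!all(sel %in% ids)) stop("unknown sample ids in selector")
    sel
  }
}

#' Select sample ids by population and garden
#'
#' @param cm A [count_matrix()].
#' @param population Populations to keep (default: all).
#' @param garden Gardens to keep (default: all).
#' @return Character vector of sample ids.
#' @export
select_samples <- function(cm, population = NULL, garden = NULL) {
  keep <- rep(TRUE, nrow(cm$design))
  if (!is.null(population)) keep <- keep & cm$design$population %in% population
  if (!is.null(garden)) keep <- keep & cm$design$garden %in% garden
  cm$design$sample[keep]
}

#' Per-gene negative-binomial group contrast
#'
#' Normalized group-mean contrast of group A relative to group B:
#' log2 fold change `log2((mA + eps) / (mB + eps))` on median-of-ratios
#' normalized counts, with a delta-method standard error under
#' `Var = mu + alpha mu^2`, moment dispersion pooled across the two
#' groups and shrunk halfway to a fitted `alpha(mu) = a/mu + b` trend,
#' and a Wald p-value. Because the estimator is a difference of
#' log-means, contrasts are exactly additive across groups (which makes
#' TC = PC + GC hold downstream). Genes with zero counts in both
#' groups are flagged non-estimable and excluded from testing.
#'
#' @param cm A [count_matrix()]; size factors are computed over all of
#'   its samples so that contrasts from the same matrix share a
#'   normalization.
#' @param groupA,groupB Sample selectors: ids, logical or integer
#'   index; each must select >= 2 samples.
#' @return Data frame (`contrast_result`) with columns `gene`,
#'   `base_mean`, `log2fc`, `se`, `pvalue`, `padj`, `estimable`.
#' @export
estimate_contrast <- function(cm, groupA, groupB) {
  a <- resolve_samples(cm, groupA)
  b <- resolve_samples(cm, groupB)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 samples")
  parts <- norm_parts(cm)
  norm <- parts$norm; sf <- parts$sf; eps <- parts$eps
  mA <- rowMeans(norm[, a, drop = FALSE])
  mB <- rowMeans(norm[, b, drop = FALSE])
  alpha <- moment_dispersion(norm, list(a, b), sf)

  log2fc <- log2(mA + eps) - log2(mB + eps)
  vA <- group_mean_var(mA, alpha, sf[a])
  vB <- group_mean_var(mB, alpha, sf[b])
  se <- sqrt(vA / (mA + eps)^2 + vB / (mB + eps)^2) / log(2)

  estimable <- mA + mB > 0
  pvalue <- rep(NA_real_, length(log2fc))
  z <- log2fc[estimable] / se[estimable]
  # Wald p; huge |z| underflows to 0, clamp to the smallest double
  pvalue[estimable] <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  padj <- rep(NA_real_, length(log2fc))
  padj[estimable] <- bh_adjust(pvalue[estimable])
  se[!estimable] <- NA_real_

  out <- data.frame(gene = rownames(cm$counts),
                    base_mean = (mA + mB) / 2,
                    log2fc = log2fc, se = se,
                    pvalue = pvalue, padj = padj,
                    estimable = estimable)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Screen genes confounded by acclimation duration
#'
#' For each of four strata (lowland pooled x garden l, lowland pooled x
#' garden h, highland x l, highland x h), fits per-gene NB regressions
#' with and without a binned acclimation-duration covariate
#' (> 30 / > 60 / > 90 days) and compares them by a deviance
#' likelihood-ratio test (df = occupied bins - 1). Mean-count
#' independent filtering (threshold grid maximizing BH discoveries) is
#' applied per stratum before FDR control; the returned exclusion set
#' is the union of genes significant in any stratum.
#'
#' @param cm A [count_matrix()] whose design has `acclimation_days`.
#' @param fdr FDR level within each stratum.
#' @param filter_grid Mean normalized-count thresholds searched by the
#'   independent filter.
#' @param lowland Populations pooled as "lowland".
#' @param highland Population treated as highland.
#' @return Character vector of gene ids to exclude (possibly empty),
#'   with the per-stratum tables in attribute `strata`.
#' @export
duration_screen <- function(cm, fdr = 0.05,
                            filter_grid = c(0, 1, 2, 5, 10, 20),
                            lowland = c("L1", "L2"), highland = "H") {
  if (!"acclimation_days" %in% names(cm$design))
    stop("design lacks acclimation_days")
  parts <- norm_parts(cm)
  strata <- list(
    lowland_l = select_samples(cm, lowland, "l"),
    lowland_h = select_samples(cm, lowland, "h"),
    highland_l = select_samples(cm, highland, "l"),
    highland_h = select_samples(cm, highland, "h"))

  excluded <- character(0)
  details <- list()
  for (nm in names(strata)) {
    ids <- strata[[nm]]
    d <- cm$design[match(ids, cm$design$sample), ]
    bins <- factor(duration_bin(d$acclimation_days))
    if (nlevels(droplevels(bins)) < 2) {
      warning("stratum ", nm, " has a single occupied duration bin; skipped")
      next
    }
    pop <- factor(d$population)
    counts <- cm$counts[, ids, drop = FALSE]
    off <- log(parts$sf[ids])
    cells <- split(seq_along(ids), interaction(pop, bins, drop = TRUE))
    alpha <- moment_dispersion(parts$norm[, ids, drop = FALSE],
                               lapply(cells, function(i) ids[i]),
                               parts$sf)
    df_lrt <- nlevels(droplevels(bins)) - 1L
    has_pop <- nlevels(droplevels(pop)) > 1
    pvals <- vapply(seq_len(nrow(counts)), function(g) {
      y <- counts[g, ]
      if (all(y == 0)) return(NA_real_)
      fam <- MASS::negative.binomial(theta = 1 / alpha[g])
      dev <- tryCatch({
        full <- if (has_pop)
          stats::glm(y ~ pop + bins + offset(off), family = fam)
        else stats::glm(y ~ bins + offset(off), family = fam)
        red <- if (has_pop)
          stats::glm(y ~ pop + offset(off), family = fam)
        else stats::glm(y ~ 1 + offset(off), family = fam)
        red$deviance - full$deviance
      }, error = function(e) NA_real_, warning = function(w) {
        suppressWarnings({
          full <- if (has_pop)
            stats::glm(y ~ pop + bins + offset(off), family = fam)
          else stats::glm(y ~ bins + offset(off), family = fam)
          red <- if (has_pop)
            stats::glm(y ~ pop + offset(off), family = fam)
          else stats::glm(y ~ 1 + offset(off), family = fam)
          red$deviance - full$deviance
        })
      })
      if (!is.finite(dev)) return(NA_real_)
      max(stats::pchisq(max(dev, 0), df = df_lrt, lower.tail = FALSE),
          .Machine$double.xmin)
    }, 1.0)

    mean_count <- rowMeans(parts$norm[, ids, drop = FALSE])
    best <- pick_filter_threshold(pvals, mean_count, filter_grid, fdr)
    keep <- mean_count >= best & !is.na(pvals)
    padj <- rep(NA_real_, length(pvals))
    padj[keep] <- bh_adjust(pvals[keep])
    hit <- rownames(counts)[which(padj < fdr)]
    excluded <- union(excluded, hit)
    details[[nm]] <- data.frame(gene = rownames(counts), pvalue = pvals,
                                padj = padj, mean_count = mean_count,
                                threshold = best)
  }
  structure(excluded, strata = details)
}

# Independent filtering: the mean-count threshold in the grid that
# maximizes the number of BH discoveries at the given FDR.
pick_filter_threshold <- function(pvals, mean_count, grid, fdr) {
  hits <- vapply(grid, function(t) {
    keep <- mean_count >= t & !is.na(pvals)
    if (!any(keep)) return(0L)
    sum(bh_adjust(pvals[keep]) < fdr)
  }, 1L)
  grid[which.max(hits)]
}

#' Continuous plasticity-evolution magnitude
#'
#' The absolute population x acclimation-environment interaction on the
#' log2 scale: `|(L_h - L_l) - (H_h - H_l)|` over normalized group
#' means, i.e. the divergence between the lowland and highland
#' reaction norms. Zero for genes whose plasticity persisted unchanged
#' (parallel norms), and approaching `|PC|` for genes whose derived
#' population lost the plastic response entirely.
#'
#' @param cm A [count_matrix()].
#' @param lowland Populations pooled as the ancestral lowland group.
#' @param highland The derived highland population.
#' @return Data frame with columns `gene`, `magnitude`, `se`.
#' @export
interaction_magnitude <- function(cm, lowland = c("L1", "L2"),
                                  highland = "H") {
  sel <- list(Ll = select_samples(cm, lowland, "l"),
              Lh = select_samples(cm, lowland, "h"),
              Hl = select_samples(cm, highland, "l"),
              Hh = select_samples(cm, highland, "h"))
  if (any(vapply(sel, length, 1L) < 2))
    stop("every population x garden cell needs >= 2 samples")
  parts <- norm_parts(cm)
  norm <- parts$norm; sf <- parts$sf; eps <- parts$eps
  m <- lapply(sel, function(ids) rowMeans(norm[, ids, drop = FALSE]))
  alpha <- moment_dispersion(norm, sel, sf)
  est <- (log2(m$Lh + eps) - log2(m$Ll + eps)) -
    (log2(m$Hh + eps) - log2(m$Hl + eps))
  v <- mapply(function(mu, ids) group_mean_var(mu, alpha, sf[ids]) /
                ((mu + eps)^2), m, sel)
  se <- sqrt(rowSums(v)) / log(2)
  data.frame(gene = rownames(cm$counts), magnitude = abs(est), se = se)
}
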