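#' Filter genes with zero median absolute deviation
#'
#' Genes whose expression MAD across samples is zero (constant or
#' near-constant profiles) produce spuriously perfect correlations and
#' are removed before network construction.
#'
#' @param expr Expression matrix (genes x samples), e.g. from
#'   [log_transform()].
#' @return Character vector of retained gene ids.
#' @export
mad_filter <- function(expr) {
  mads <- apply(expr, 1, stats::mad, constant = 1)
  keep <- rownames(expr)[mads > 0]
  if (length(keep) == 0L) stop("all genes have zero MAD")
  keep
}

# Per-gene robust standardization for the biweight midcorrelation:
# u_i = (x_i - med) / (9 MAD); Tukey biweights w_i = (1 - u_i^2)^2 for
# |u_i| < 1, else 0. Side-specific capping rescales u on each side so
# that at most max_p_outliers of the samples per tail can receive zero
# weight (the u at the tail quantile is pulled back to +-1 when it
# would exceed 1). Zero-MAD genes fall back to a Pearson-standardized
# vector. Rows are scaled to unit L2 norm so the correlation matrix is
# a single tcrossprod.
bicor_prep <- function(x, max_p_outliers) {
  med <- stats::median(x)
  madv <- stats::mad(x, constant = 1)
  if (madv == 0) {
    d <- x - mean(x)
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) return(rep(0, length(x)))
    return(d / nrm)
  }
  u <- (x - med) / (9 * madv)
  if (max_p_outliers < 0.5) {
    qs <- stats::quantile(x, c(max_p_outliers, 1 - max_p_outliers),
                          names = FALSE)
    uL <- (qs[1] - med) / (9 * madv)
    uH <- (qs[2] - med) / (9 * madv)
    if (uL < -1) u[x < med] <- u[x < med] / abs(uL)
    if (uH > 1) u[x > med] <- u[x > med] / uH
  }
  w <- (1 - u^2)^2 * (abs(u) < 1)
  d <- (x - med) * w
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) return(rep(0, length(x)))
  d / nrm
}

#' Biweight midcorrelation matrix
#'
#' Robust gene-gene correlation: each profile is median-centered and
#' Tukey-biweighted, with side-specific capping so that at most
#' `max_p_outliers` of samples per tail are treated as outliers
#' (receive zero weight). Genes with zero MAD fall back to Pearson
#' standardization with a warning.
#'
#' @param expr Expression matrix (genes x samples), >= 5 samples.
#' @param max_p_outliers Maximum fraction of samples per tail that may
#'   be down-weighted to zero.
#' @return Gene x gene correlation matrix in `[-1, 1]`, unit diagonal.
#' @export
bicor_matrix <- function(expr, max_p_outliers = 0.1) {
  if (ncol(expr) < 5) stop("need at least 5 samples for bicor")
  mads <- apply(expr, 1, stats::mad, constant = 1)
  if (any(mads == 0))
    warning(sum(mads == 0),
            " zero-MAD gene(s): Pearson fallback used for them")
  w <- t(apply(expr, 1, bicor_prep, max_p_outliers = max_p_outliers))
  cor <- tcrossprod(w)
  cor[cor > 1] <- 1
  cor[cor < -1] <- -1
  diag(cor) <- 1
  dimnames(cor) <- list(rownames(expr), rownames(expr))
  cor
}

#' Signed adjacency
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`: positive correlations map near 1,
#' negative correlations near 0, so modules form around positively
#' co-regulated genes only.
#'
#' @param cor Correlation matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return Adjacency matrix in `[0, 1]` with unit diagonal.
#' @export
signed_adjacency <- function(cor, beta) {
  if (beta < 1) stop("beta must be >= 1")
  a <- ((1 + cor) / 2)^beta
  diag(a) <- 1
  a
}

#' Scale-free topology fit of an adjacency matrix
#'
#' Connectivities `k_i = sum_{j != i} a_ij` are binned into 10
#' equal-occupancy bins; the log10 frequency density (bin frequency
#' over bin width, since equal-occupancy bins make raw frequencies
#' constant by construction) is regressed on the log10 mean
#' connectivity per bin. Returns the R-squared, signed negative when
#' the slope is positive (an increasing degree distribution is the
#' opposite of scale-free), and the mean connectivity.
#'
#' @param adjacency Adjacency matrix (>= 50 genes for a meaningful
#'   fit).
#' @param n_bins Number of equal-occupancy bins.
#' @return List with `r2` (signed), `slope`, `mean_k`.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  k <- rowSums(adjacency) - 1
  if (stats::sd(k) == 0) {
    warning("degenerate connectivity (all equal); R^2 reported as 0")
    return(list(r2 = 0, slope = NA_real_, mean_k = mean(k)))
  }
  breaks <- unique(stats::quantile(k, seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(k, breaks = breaks, include.lowest = TRUE)
  width <- diff(breaks)
  dens <- tabulate(bins, nbins = nlevels(bins)) / length(k) / width
  kbar <- tapply(k, bins, mean)
  ok <- dens > 0 & kbar > 0 & width > 0
  if (sum(ok) < 3) {
    warning("too few occupied bins for a scale-free fit; R^2 reported as 0")
    return(list(r2 = 0, slope = NA_real_, mean_k = mean(k)))
  }
  fit <- stats::lm(log10(dens[ok]) ~ log10(kbar[ok]))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r2 = if (slope > 0) -r2 else r2, slope = slope, mean_k = mean(k))
}

#' Choose the soft-threshold power
#'
#' Scans a grid of powers and returns the smallest whose signed
#' scale-free R-squared exceeds `r2_cutoff` while the mean connectivity
#' stays at or above `k_floor` (high powers shrink connectivity toward
#' zero; a floor keeps the network informative). If no power
#' qualifies, the power maximizing R-squared is returned with a
#' warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param grid Candidate powers.
#' @param r2_cutoff Required signed R-squared.
#' @param k_floor Minimum acceptable mean connectivity.
#' @param max_p_outliers Passed to [bicor_matrix()].
#' @return List with `beta` and `table` (per-power diagnostics: power,
#'   r2, mean_k).
#' @export
pick_beta <- function(expr, grid = seq(2, 30, by = 2), r2_cutoff = 0.8,
                      k_floor = 30, max_p_outliers = 0.1) {
  if (length(grid) == 0) stop("empty power grid")
  cor <- bicor_matrix(expr, max_p_outliers)
  rows <- lapply(grid, function(b) {
    f <- suppressWarnings(scale_free_fit(signed_adjacency(cor, b)))
    data.frame(power = b, r2 = f$r2, mean_k = f$mean_k)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$r2 > r2_cutoff & tab$mean_k >= k_floor
  beta <- if (any(ok)) {
    tab$power[which(ok)[1]]
  } else {
    warning("no power met the scale-free and connectivity criteria; ",
            "returning the power with maximal R^2")
    tab$power[which.max(tab$r2)]
  }
  list(beta = beta, table = tab)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij)` with unit diagonal: similarity that
#' credits both the direct edge and the shared neighborhood of two
#' genes.
#'
#' @param adjacency Adjacency matrix in `[0, 1]`, unit diagonal.
#' @return TOM matrix in `[0, 1]`.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  k <- rowSums(a) - 1
  num <- a %*% a - a            # sum_u a_iu a_uj minus the two diag terms
  denom <- outer(k, k, pmin) + 1 - a
  tom <- num / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  tom
}

#' Detect modules by adaptive tree cutting
#'
#' Average-linkage clustering of the TOM dissimilarity followed by an
#' adaptive branch cut: the tree is cut at the merge-height quantile
#' mapped from `deep_split` (0..3 -> 0.95, 0.97, 0.99, 0.995; deeper
#' splits cut lower and produce more, smaller branches), and branches
#' below `min_size` genes are left unassigned (module 0). Modules are
#' labelled 1, 2, ... in decreasing size order.
#'
#' @param dissimilarity Square matrix, typically `1 - tom`.
#' @param min_size Minimum module size.
#' @param deep_split Split sensitivity in 0..3.
#' @return Integer vector of module labels named by gene, with the
#'   `hclust` tree and cut height in attributes.
#' @export
detect_modules <- function(dissimilarity, min_size = 30, deep_split = 2) {
  d <- as.matrix(dissimilarity)
  stopifnot(nrow(d) == ncol(d))
  if (!deep_split %in% 0:3) stop("deep_split must be in 0..3")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  q <- c(0.95, 0.97, 0.99, 0.995)[deep_split + 1]
  cut_h <- stats::quantile(hc$height, q, names = FALSE)
  raw <- stats::cutree(hc, h = cut_h)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- integer(length(raw))
  if (length(keep) > 0) {
    ord <- keep[order(-sizes[as.character(keep)])]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  names(labels) <- rownames(d)
  attr(labels, "hclust") <- hc
  attr(labels, "cut_height") <- cut_h
  labels
}

#' Intramodular connectivity
#'
#' `k_IM` of a gene is the sum of its adjacencies to the other genes
#' of its module; the scaled version divides by the module maximum so
#' values are comparable across modules of different sizes.
#' Unassigned genes (module 0) get `NA`.
#'
#' @param adjacency Adjacency matrix.
#' @param modules Integer module labels (0 = unassigned), in adjacency
#'   row order.
#' @return Data frame with `gene`, `module`, `k_im`, `k_im_scaled`.
#' @export
intramodular_connectivity <- function(adjacency, modules) {
  a <- as.matrix(adjacency)
  stopifnot(length(modules) == nrow(a))
  k_im <- rep(NA_real_, nrow(a))
  k_scaled <- rep(NA_real_, nrow(a))
  for (m in setdiff(unique(modules), 0L)) {
    idx <- which(modules == m)
    if (length(idx) == 0L) next
    sub <- a[idx, idx, drop = FALSE]
    k <- rowSums(sub) - 1
    k_im[idx] <- k
    k_scaled[idx] <- if (max(k) > 0) k / max(k) else NA_real_
  }
  data.frame(gene = rownames(a), module = as.integer(modules),
             k_im = k_im, k_im_scaled = k_scaled)
}

#' Full co-expression analysis
#'
#' Runs the network stage end to end: MAD filter, biweight
#' midcorrelation, soft-threshold selection, signed adjacency, TOM,
#' module detection, and intramodular connectivity.
#'
#' @param expr Expression matrix (genes x samples).
#' @param beta Soft-threshold power; `NULL` to select via
#'   [pick_beta()].
#' @param grid,r2_cutoff,k_floor Passed to [pick_beta()].
#' @param min_size,deep_split Passed to [detect_modules()].
#' @param max_p_outliers Passed to [bicor_matrix()].
#' @return List of class `coexpression_result`: `connectivity` (data
#'   frame from [intramodular_connectivity()]), `modules`, `beta`,
#'   `beta_table`, `r2`, `mean_k`.
#' @export
coexpression_analysis <- function(expr, beta = NULL,
                                  grid = seq(2, 30, by = 2),
                                  r2_cutoff = 0.8, k_floor = 30,
                                  min_size = 30, deep_split = 2,
                                  max_p_outliers = 0.1) {
  keep <- mad_filter(expr)
  expr <- expr[keep, , drop = FALSE]
  cor <- bicor_matrix(expr, max_p_outliers)
  beta_table <- NULL
  if (is.null(beta)) {
    pb <- pick_beta(expr, grid, r2_cutoff, k_floor, max_p_outliers)
    beta <- pb$beta
    beta_table <- pb$table
  }
  adj <- signed_adjacency(cor, beta)
  fit <- suppressWarnings(scale_free_fit(adj))
  tom <- tom_similarity(adj)
  modules <- detect_modules(1 - tom, min_size = min_size,
                            deep_split = deep_split)
  conn <- intramodular_connectivity(adj, modules)
  structure(list(connectivity = conn, modules = modules, beta = beta,
                 beta_table = beta_table, r2 = fit$r2,
                 mean_k = fit$mean_k),
            class = "coexpression_result")
}
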