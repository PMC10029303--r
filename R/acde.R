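#' The pi statistic
#'
#' Combines effect magnitude and significance of a per-gene contrast:
#' `pi = |log2fc| * -log10(p)`. Non-negative, increasing in both the
#' absolute fold change and the significance. Zero p-values are
#' clamped to the smallest positive double with a warning.
#'
#' @param log2fc Log2 fold change(s).
#' @param pvalue Raw p-value(s) in (0, 1].
#' @return Non-negative numeric vector.
#' @export
pi_value <- function(log2fc, pvalue) {
  if (any(pvalue <= 0, na.rm = TRUE)) {
    warning("p-values of 0 clamped to the smallest representable value")
    pvalue[pvalue <= 0] <- .Machine$double.xmin
  }
  abs(log2fc) * (-log10(pvalue))
}

#' Select altitudinally concordant differentially expressed (ACDE) genes
#'
#' Computes per-gene `dpi1 = pi(H vs L1) - pi(L1 vs L2)` and
#' `dpi2 = pi(H vs L2) - pi(L1 vs L2)`, takes genes at or above the
#' `1 - q` empirical quantile of both (ties at the threshold kept), and
#' flags as ACDE the selected genes whose H-vs-L1 and H-vs-L2 log2
#' fold changes share a sign. The quantile gate finds genes with large
#' inter-altitude but small intra-altitude expression difference; the
#' sign gate keeps only directionally concordant regulation.
#'
#' @param c_HL1,c_HL2,c_L1L2 Contrast results from
#'   [estimate_contrast()] for H vs L1, H vs L2 and L1 vs L2, over the
#'   same gene universe.
#' @param q Upper tail fraction selected (default 0.05).
#' @return Data frame (`acde_table`) with per-gene pi statistics,
#'   `dpi1`, `dpi2`, directions, `selected` and `is_acde` flags; counts
#'   of selected and concordant genes in attribute `summary`.
#' @export
acde_select <- function(c_HL1, c_HL2, c_L1L2, q = 0.05) {
  if (!identical(c_HL1$gene, c_HL2$gene) ||
      !identical(c_HL1$gene, c_L1L2$gene))
    stop("contrasts must share the same gene universe, in the same order")
  pi1 <- pi_value(c_HL1$log2fc, c_HL1$pvalue)
  pi2 <- pi_value(c_HL2$log2fc, c_HL2$pvalue)
  pi0 <- pi_value(c_L1L2$log2fc, c_L1L2$pvalue)
  dpi1 <- pi1 - pi0
  dpi2 <- pi2 - pi0
  thr1 <- stats::quantile(dpi1, 1 - q, na.rm = TRUE, names = FALSE)
  thr2 <- stats::quantile(dpi2, 1 - q, na.rm = TRUE, names = FALSE)
  selected <- !is.na(dpi1) & !is.na(dpi2) & dpi1 >= thr1 & dpi2 >= thr2
  same_dir <- sign(c_HL1$log2fc) == sign(c_HL2$log2fc) &
    sign(c_HL1$log2fc) != 0
  is_acde <- selected & same_dir

  out <- data.frame(gene = c_HL1$gene,
                    pi_HL1 = pi1, pi_HL2 = pi2, pi_L1L2 = pi0,
                    dpi1 = dpi1, dpi2 = dpi2,
                    direction_HL1 = ifelse(c_HL1$log2fc > 0, "up", "down"),
                    direction_HL2 = ifelse(c_HL2$log2fc > 0, "up", "down"),
                    selected = selected, is_acde = is_acde)
  attr(out, "summary") <- c(n_selected = sum(selected),
                            n_concordant = sum(is_acde))
  class(out) <- c("acde_table", "data.frame")
  out
}

#' Direction-concordance test against a neutral null
#'
#' Exact two-sided binomial test of the number of selected genes whose
#' two highland-vs-lowland contrasts agree in sign, against the null
#' proportion expected when per-population expression deviations drift
#' independently (2/3, rounded to 0.67): with iid deviations the two
#' contrasts share the highland term and correlate 1/2, giving
#' same-sign probability 2/3.
#'
#' @param k_same Number of concordant genes.
#' @param n_selected Number of selected genes.
#' @param p0 Null concordance proportion.
#' @return A `plastevo_test` (see [binomial_two_sided()]).
#' @export
concordance_test <- function(k_same, n_selected, p0 = 0.67) {
  binomial_two_sided(k_same, n_selected, p0)
}

#' Simulate the neutral sign-concordance fraction
#'
#' Draws iid standard-normal expression deviations for H, L1 and L2
#' across `n` genes and returns the fraction of genes for which the
#' contrasts H - L1 and H - L2 share a sign. Converges to 2/3, the
#' provenance of the 0.67 null used by [concordance_test()].
#'
#' @param n Number of simulated genes.
#' @param seed Seed.
#' @return The concordant fraction (scalar).
#' @export
neutral_concordance <- function(n = 1e5, seed = 1L) {
  set.seed(seed)
  eH <- stats::rnorm(n); eL1 <- stats::rnorm(n); eL2 <- stats::rnorm(n)
  mean(sign(eH - eL1) == sign(eH - eL2))
}
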