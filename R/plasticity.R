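#' Classify plasticity direction from PC and GC signs
#'
#' Reinforcing when the plastic change (PC) and the genetic change
#' (GC) have the same nonzero sign, reversing when opposite, undefined
#' when either is exactly zero.
#'
#' @param pc,gc Numeric vectors (log2 units), recycled to a common
#'   length.
#' @return Character vector in `{"reinforcing", "reversing",
#'   "undefined"}`.
#' @export
classify_direction <- function(pc, gc) {
  s <- sign(pc) * sign(gc)
  out <- rep("undefined", length(s))
  out[s > 0] <- "reinforcing"
  out[s < 0] <- "reversing"
  out
}

#' Parametric bootstrap support for the direction call
#'
#' For each gene, draws `B` independent Gaussian pairs
#' `(PC*, GC*)` with means equal to the estimated log2 fold changes
#' and standard deviations equal to their standard errors, classifies
#' each pair as reinforcing or reversing, and declares a supported
#' class only when one class is reached in at least `threshold` of the
#' `B` replicates. This screens out sign calls that arise purely from
#' sampling error in estimates sharing a noisy term (both PC and GC
#' use the same lowland samples), where naive sign comparison inflates
#' reversing calls.
#'
#' @param pc,se_pc,gc,se_gc Estimates and standard errors, equal
#'   length; SEs must be positive.
#' @param B Bootstrap replicates per gene.
#' @param threshold Minimum replicates for a supported call.
#' @param seed Seed.
#' @return Data frame with `n_reinforcing`, `n_reversing` (counts out
#'   of `B`) and `supported_class` in `{"reinforcing", "reversing",
#'   "none"}`.
#' @export
bootstrap_classify <- function(pc, se_pc, gc, se_gc,
                               B = 1000, threshold = 950, seed = 1L) {
  n <- length(pc)
  stopifnot(length(se_pc) == n, length(gc) == n, length(se_gc) == n)
  if (any(!is.finite(se_pc) | se_pc <= 0) ||
      any(!is.finite(se_gc) | se_gc <= 0))
    stop("standard errors must be positive and finite")
  set.seed(seed)
  n_ri <- integer(n); n_rv <- integer(n)
  chunk <- max(1L, floor(2e6 / B))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    m <- length(idx)
    ps <- matrix(stats::rnorm(m * B, mean = pc[idx], sd = se_pc[idx]), m, B)
    gs <- matrix(stats::rnorm(m * B, mean = gc[idx], sd = se_gc[idx]), m, B)
    s <- sign(ps) * sign(gs)
    n_ri[idx] <- rowSums(s > 0)
    n_rv[idx] <- rowSums(s < 0)
  }
  supported <- rep("none", n)
  supported[n_ri >= threshold] <- "reinforcing"
  supported[n_rv >= threshold] <- "reversing"
  data.frame(n_reinforcing = n_ri, n_reversing = n_rv,
             supported_class = supported)
}

#' Classify plasticity persistence versus evolution
#'
#' Classifies genes by the ratio `r = GC_b / GC` using half-open
#' intervals closed on the left. Binary scheme: persisting for
#' `r` in `[0.5, 1.5)` (parallel reaction norms), evolved for `r` in
#' `[-0.5, 0.5)` (expression converged in the ancestral garden),
#' otherwise unclassified. The 3-bin scheme orders `[0.75, 1.25)`,
#' `[0.25, 0.75)`, `[-0.25, 0.25)` and the 4-bin scheme
#' `[0.83, 1.17)`, `[0.50, 0.83)`, `[0.17, 0.50)`, `[-0.17, 0.17)`
#' from low to high degree of plasticity evolution.
#'
#' @param gcb,gc Back-garden and high-garden population contrasts
#'   (log2); `gc` must be nonzero (pre-filter degenerate genes).
#' @param scheme `"binary"`, `"bin3"` or `"bin4"`.
#' @return Character vector of categories; `"unclassified"` outside
#'   all bins. Binary categories are `"persisting"`/`"evolved"`; bin
#'   schemes use `"evo1"` (lowest) .. `"evo3"`/`"evo4"` (highest
#'   evolution).
#' @export
classify_evolution <- function(gcb, gc, scheme = c("binary", "bin3", "bin4")) {
  scheme <- match.arg(scheme)
  if (any(gc == 0)) stop("GC = 0: ratio undefined; filter such genes first")
  r <- gcb / gc
  breaks <- switch(scheme,
    binary = list(persisting = c(0.5, 1.5), evolved = c(-0.5, 0.5)),
    bin3 = list(evo1 = c(0.75, 1.25), evo2 = c(0.25, 0.75),
                evo3 = c(-0.25, 0.25)),
    bin4 = list(evo1 = c(0.83, 1.17), evo2 = c(0.50, 0.83),
                evo3 = c(0.17, 0.50), evo4 = c(-0.17, 0.17)))
  out <- rep("unclassified", length(r))
  for (nm in names(breaks)) {
    b <- breaks[[nm]]
    out[r >= b[1] & r < b[2]] <- nm
  }
  out
}

#' Assemble the per-gene plasticity table
#'
#' Joins the three contrasts into one table: PC (lowland plastic
#' response, garden h vs l), GC (H vs L in garden h), GC_b (H vs L in
#' garden l), the total change TC = PC + GC, the GC_b-to-GC ratio,
#' the naive direction class, its parametric bootstrap support, and
#' the evolution class under the binary, 3-bin and 4-bin schemes
#' (genes with GC = 0 are left unclassified).
#'
#' @param c_PC,c_GC,c_GCb Contrast results sharing a gene universe.
#' @param B,threshold,seed Bootstrap settings, see
#'   [bootstrap_classify()].
#' @param bootstrap Set `FALSE` to skip the bootstrap columns.
#' @return Data frame (`plasticity_table`).
#' @export
change_table <- function(c_PC, c_GC, c_GCb, B = 1000, threshold = 950,
                         seed = 1L, bootstrap = TRUE) {
  if (!identical(c_PC$gene, c_GC$gene) || !identical(c_PC$gene, c_GCb$gene))
    stop("contrasts must share the same gene universe, in the same order")
  out <- data.frame(gene = c_PC$gene,
                    pc = c_PC$log2fc, se_pc = c_PC$se,
                    gc = c_GC$log2fc, se_gc = c_GC$se,
                    gcb = c_GCb$log2fc, se_gcb = c_GCb$se)
  out$tc <- out$pc + out$gc
  out$ratio <- ifelse(out$gc == 0, NA_real_, out$gcb / out$gc)
  out$direction <- classify_direction(out$pc, out$gc)
  ok <- out$gc != 0 & !is.na(out$gc)
  for (scheme in c("binary", "bin3", "bin4")) {
    col <- c(binary = "evolution_binary", bin3 = "evolution_bin3",
             bin4 = "evolution_bin4")[[scheme]]
    out[[col]] <- "unclassified"
    out[[col]][ok] <- classify_evolution(out$gcb[ok], out$gc[ok], scheme)
  }
  if (bootstrap) {
    usable <- is.finite(out$se_pc) & out$se_pc > 0 &
      is.finite(out$se_gc) & out$se_gc > 0
    out$n_reinforcing <- NA_integer_
    out$n_reversing <- NA_integer_
    out$supported_class <- "none"
    if (any(usable)) {
      bs <- bootstrap_classify(out$pc[usable], out$se_pc[usable],
                               out$gc[usable], out$se_gc[usable],
                               B = B, threshold = threshold, seed = seed)
      out$n_reinforcing[usable] <- bs$n_reinforcing
      out$n_reversing[usable] <- bs$n_reversing
      out$supported_class[usable] <- bs$supported_class
    }
  }
  class(out) <- c("plasticity_table", "data.frame")
  out
}

#' Reversing fraction under independent PC and TC
#'
#' Simulates the geometric argument for the prevalence of reversing
#' plasticity: when PC and the total change TC are independent
#' zero-mean normals and GC = TC - PC, every gene with |PC| > |TC|
#' necessarily reverses, and among genes with |PC| < |TC| exactly half
#' do, so the overall reversing fraction is at least one half.
#'
#' @param sd_pc SD of PC (scalar or vector over a grid).
#' @param sd_tc SD of TC.
#' @param n Genes per grid point.
#' @param seed Seed.
#' @return Data frame with one row per `sd_pc`: the overall reversing
#'   fraction and the fraction among genes with |PC| < |TC|.
#' @export
reversing_fraction_sim <- function(sd_pc, sd_tc = 1, n = 1e5, seed = 1L) {
  set.seed(seed)
  rows <- lapply(sd_pc, function(s) {
    pc <- stats::rnorm(n, 0, s)
    tc <- stats::rnorm(n, 0, sd_tc)
    gc <- tc - pc
    rev <- classify_direction(pc, gc) == "reversing"
    small <- abs(pc) < abs(tc)
    data.frame(sd_pc = s,
               frac_reversing = mean(rev),
               frac_reversing_small_pc = mean(rev[small]))
  })
  do.call(rbind, rows)
}
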