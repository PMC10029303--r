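#' Simulation configuration for reciprocal-transplant count data
#'
#' Bundles every tunable of the synthetic-data generator: the sampling
#' design (birds per population x garden cell), the negative-binomial
#' noise model, the per-gene effect structure (plastic change PC,
#' genetic change GC, back-garden genetic change GC_b), modular
#' co-expression structure, and nuisance features (duration-sensitive
#' genes, constant genes, library-size variation).
#'
#' Defaults mirror a three-population design with one highland (H) and
#' two lowland (L1, L2) populations reciprocally acclimated to a
#' low-altitude (l) and a high-altitude (h) common garden: 10 H birds
#' and 5 birds per lowland population in each garden, 40 samples in
#' total, acclimated 35-94 days.
#'
#' @param n_genes Number of genes.
#' @param cells Data frame with columns `population`, `garden`, `n`
#'   giving birds per cell; every population x garden cell must have
#'   n >= 2.
#' @param acclim_range Integer range (days) acclimation durations are
#'   drawn from, uniformly.
#' @param libsize_sd Log-normal sd (log scale) of per-sample library
#'   size factors; factors have geometric mean 1.
#' @param baseline_mean,baseline_sd Normal parameters of per-gene
#'   baseline log2 mean expression. The defaults give a mean depth of
#'   roughly 400 counts per gene per sample, matching a bulk RNA-seq
#'   experiment of ~8 million read pairs over ~20,000 genes.
#' @param alpha_range NB dispersion range; per-gene dispersion alpha is
#'   drawn log-uniformly in this interval (Var = mu + alpha * mu^2).
#' @param prop_effect Proportion of genes carrying non-null PC/GC
#'   effects.
#' @param fraction_reversing Among effect genes, proportion with PC and
#'   GC of opposite sign.
#' @param fraction_evolved Among effect genes, proportion whose
#'   plasticity evolved (GC_b near 0); the rest persist (GC_b = GC).
#' @param pc_shape,pc_scale Gamma parameters of |PC| (log2 units).
#' @param gc_shape,gc_scale Gamma parameters of |GC| (log2 units).
#' @param n_modules,module_size Number and size of co-expression
#'   modules (size recycled to `n_modules`).
#' @param loading_strength Scale of latent-factor loadings shared
#'   within a module (log2 units per factor sd).
#' @param prop_duration Proportion of genes whose expression drifts
#'   with acclimation-duration bin.
#' @param duration_slope Log2 change per duration bin for
#'   duration-sensitive genes.
#' @param prop_mad_zero Proportion of genes with constant counts across
#'   samples (removed later by the MAD filter).
#' @param seed Default seed used by the generator operations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       cells = default_cells(),
                       acclim_range = c(35L, 94L),
                       libsize_sd = 0.25,
                       baseline_mean = 7.3, baseline_sd = 2,
                       alpha_range = c(0.01, 0.5),
                       prop_effect = 0.10,
                       fraction_reversing = 0.6,
                       fraction_evolved = 0.7,
                       pc_shape = 2, pc_scale = 0.75,
                       gc_shape = 2, gc_scale = 0.75,
                       n_modules = 5, module_size = 50,
                       loading_strength = 1,
                       prop_duration = 0.02, duration_slope = 1,
                       prop_mad_zero = 0.01,
                       seed = 1L) {
  props <- c(prop_effect, fraction_reversing, fraction_evolved,
             prop_duration, prop_mad_zero)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (n_genes < 1) stop("n_genes must be positive")
  cells <- as.data.frame(cells)
  stopifnot(all(c("population", "garden", "n") %in% names(cells)))
  if (any(cells$n < 2)) stop("every population x garden cell needs >= 2 birds")
  if (acclim_range[1] > acclim_range[2] || acclim_range[1] < 1)
    stop("invalid acclimation range")
  structure(list(n_genes = n_genes, cells = cells,
                 acclim_range = as.integer(acclim_range),
                 libsize_sd = libsize_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 alpha_range = alpha_range,
                 prop_effect = prop_effect,
                 fraction_reversing = fraction_reversing,
                 fraction_evolved = fraction_evolved,
                 pc_shape = pc_shape, pc_scale = pc_scale,
                 gc_shape = gc_shape, gc_scale = gc_scale,
                 n_modules = n_modules,
                 module_size = rep_len(module_size, n_modules),
                 loading_strength = loading_strength,
                 prop_duration = prop_duration,
                 duration_slope = duration_slope,
                 prop_mad_zero = prop_mad_zero,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_cells <- function() {
  data.frame(population = rep(c("H", "L1", "L2"), each = 2),
             garden = rep(c("h", "l"), 3),
             n = c(10L, 10L, 5L, 5L, 5L, 5L))
}

#' Build the per-bird sampling design
#'
#' Expands the configured population x garden cell sizes into one
#' record per bird, drawing acclimation durations uniformly from the
#' configured range.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to the config seed).
#' @param tissue,batch Labels attached to every sample.
#' @return Data frame with columns `sample`, `population`, `garden`,
#'   `acclimation_days`, `tissue`, `batch`.
#' @export
make_design <- function(config, seed = config$seed,
                        tissue = "tissue1", batch = "b1") {
  cells <- config$cells
  if (any(cells$n < 1)) stop("zero-size population x garden cell")
  set.seed(seed)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n[i]
    data.frame(
      sample = sprintf("%s_%s_%02d", cells$population[i], cells$garden[i],
                       seq_len(n)),
      population = cells$population[i],
      garden = cells$garden[i],
      acclimation_days = sample(seq(config$acclim_range[1],
                                    config$acclim_range[2]),
                                n, replace = TRUE),
      tissue = tissue, batch = batch)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(!anyDuplicated(out$sample))
  out
}

#' Draw per-gene ground truth
#'
#' Assigns every gene a baseline log2 mean, NB dispersion, and (for
#' effect genes) PC/GC/GC_b log2 effects whose signs encode the true
#' plasticity direction (reinforcing: same sign; reversing: opposite)
#' and whose GC_b encodes the true evolution class (persisting:
#' GC_b = GC; evolved: |GC_b| <= 0.25 |GC|). Module members receive a
#' latent-factor loading; a configured fraction of genes is
#' duration-sensitive or constant (MAD zero). TC_true = PC_true +
#' GC_true by construction.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to the config seed).
#' @return Data frame (`truth_table`) with columns `gene`, `baseline`,
#'   `pc_true`, `gc_true`, `gcb_true`, `tc_true`, `direction_true`,
#'   `evolution_true`, `module_id`, `loading`, `dispersion`,
#'   `duration_slope`, `mad_zero`.
#' @export
generate_truth <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_genes
  gene <- sprintf("g%05d", seq_len(n))
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  lar <- log(config$alpha_range)
  dispersion <- exp(stats::runif(n, lar[1], lar[2]))

  mad_zero <- stats::runif(n) < config$prop_mad_zero
  is_effect <- !mad_zero & stats::runif(n) < config$prop_effect
  reversing <- is_effect & stats::runif(n) < config$fraction_reversing
  evolved <- is_effect & stats::runif(n) < config$fraction_evolved

  pc <- gc <- gcb <- numeric(n)
  ne <- sum(is_effect)
  if (ne > 0) {
    sgn <- sample(c(-1, 1), ne, replace = TRUE)
    pc[is_effect] <- sgn * stats::rgamma(ne, config$pc_shape,
                                         scale = config$pc_scale)
    gmag <- stats::rgamma(ne, config$gc_shape, scale = config$gc_scale)
    gsgn <- ifelse(reversing[is_effect], -sgn, sgn)
    gc[is_effect] <- gsgn * gmag
    ratio <- ifelse(evolved[is_effect],
                    stats::runif(ne, -0.25, 0.25), 1)
    gcb[is_effect] <- ratio * gc[is_effect]
  }

  direction <- rep("none", n)
  direction[is_effect & reversing] <- "reversing"
  direction[is_effect & !reversing] <- "reinforcing"
  evolution <- rep("other", n)
  evolution[is_effect & evolved] <- "evolved"
  evolution[is_effect & !evolved] <- "persisting"

  module_id <- rep(0L, n)
  loading <- numeric(n)
  sizes <- config$module_size
  if (config$n_modules > 0 && sum(sizes) > 0) {
    eligible <- which(!mad_zero)
    if (sum(sizes) > length(eligible))
      stop("module sizes exceed the number of non-constant genes")
    members <- sample(eligible, sum(sizes))
    module_id[members] <- rep(seq_len(config$n_modules), sizes)
    loading[members] <- stats::runif(sum(sizes), 0.5, 1) *
      config$loading_strength
  }

  dur <- !mad_zero & stats::runif(n) < config$prop_duration
  duration_slope <- ifelse(dur, sample(c(-1, 1), n, replace = TRUE) *
                             config$duration_slope, 0)

  out <- data.frame(gene = gene, baseline = baseline,
                    pc_true = pc, gc_true = gc, gcb_true = gcb,
                    tc_true = pc + gc,
                    direction_true = direction,
                    evolution_true = evolution,
                    module_id = module_id, loading = loading,
                    dispersion = dispersion,
                    duration_slope = duration_slope,
                    mad_zero = mad_zero)
  class(out) <- c("truth_table", "data.frame")
  out
}

# log2-scale effect of a sample's population/garden cell given truth.
# Baseline cell: lowland population in the low garden. PC applies to
# lowland birds in the high garden; highland birds carry GC_b in the
# low garden and PC + GC in the high garden (so H-vs-L in garden h is
# GC, in garden l is GC_b, and TC = PC + GC across native sites).
cell_effect <- function(truth, population, garden) {
  highland <- population == "H"
  if (!highland && garden == "l") return(numeric(nrow(truth)))
  if (!highland && garden == "h") return(truth$pc_true)
  if (highland && garden == "l") return(truth$gcb_true)
  truth$pc_true + truth$gc_true
}

#' Simulate a count matrix from ground truth and a design
#'
#' Draws `count[g, s] ~ NB(mean = f_s * 2^(baseline_g + X_gs),
#' dispersion = alpha_g)` where `X_gs` composes the PC/GC/GC_b effects
#' according to the sample's population and garden, plus shared
#' module latent factors and duration-bin effects; `f_s` is a
#' log-normal library-size factor with geometric mean 1. Constant
#' (MAD-zero) genes receive the same rounded baseline count in every
#' sample.
#'
#' @param truth A truth table from [generate_truth()].
#' @param design A design from [make_design()].
#' @param seed Seed.
#' @param libsize_sd Log-normal sd of library-size factors.
#' @return A [count_matrix()] with the design attached and the truth
#'   stored in attribute `truth`.
#' @export
simulate_counts <- function(truth, design, seed = 1L, libsize_sd = 0.25) {
  stopifnot(inherits(truth, "data.frame"), nrow(truth) > 0)
  set.seed(seed)
  n_g <- nrow(truth)
  n_s <- nrow(design)
  lf <- stats::rnorm(n_s, 0, libsize_sd)
  lf <- lf - mean(lf)               # geometric mean exactly 1
  sf <- exp(lf)

  n_mod <- max(truth$module_id)
  factors <- if (n_mod > 0) {
    matrix(stats::rnorm(n_mod * n_s), n_mod, n_s)
  } else NULL

  dbin <- duration_bin(design$acclimation_days)

  mu <- matrix(0, n_g, n_s)
  for (s in seq_len(n_s)) {
    x <- truth$baseline +
      cell_effect(truth, design$population[s], design$garden[s]) +
      truth$duration_slope * (dbin[s] - 1)
    if (n_mod > 0) {
      inmod <- truth$module_id > 0
      x[inmod] <- x[inmod] +
        truth$loading[inmod] * factors[truth$module_id[inmod], s]
    }
    mu[, s] <- sf[s] * 2^x
  }

  counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu,
                                  size = 1 / pmax(truth$dispersion, 1e-8)),
                   n_g, n_s)
  if (any(truth$mad_zero)) {
    counts[truth$mad_zero, ] <- round(2^truth$baseline[truth$mad_zero])
  }
  dimnames(counts) <- list(truth$gene, design$sample)
  out <- count_matrix(counts, design)
  attr(out, "truth") <- truth
  out
}

#' Bin acclimation durations
#'
#' Durations are binned at the > 30, > 60 and > 90 day thresholds used
#' by the duration confounder screen.
#'
#' @param days Integer vector of acclimation durations.
#' @return Integer bin index (0 = <= 30 days, up to 3 = > 90 days).
#' @export
duration_bin <- function(days) {
  (days > 30) + (days > 60) + (days > 90)
}
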