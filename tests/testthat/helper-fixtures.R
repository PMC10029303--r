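# Shared fixture builders. All fixtures are generated in code under
# fixed seeds; nothing is read from disk.

# Small reciprocal-transplant simulation for smoke/integration tests.
small_sim <- function(n_genes = 300, n_per_cell = NULL, seed = 101,
                      n_modules = 0, ...) {
  cells <- default_cells()
  if (!is.null(n_per_cell)) cells$n <- n_per_cell
  cfg <- sim_config(n_genes = n_genes, cells = cells, seed = seed,
                    n_modules = n_modules, ...)
  truth <- generate_truth(cfg)
  cm <- simulate_counts(truth, make_design(cfg), seed = seed + 1)
  list(cfg = cfg, truth = truth, cm = cm)
}

# Two planted co-expression blocks driven by one latent factor each,
# with per-gene loadings spanning a wide signal-to-noise range so that
# intramodular connectivity is informative about the loading.
planted_modules <- function(n_per_block = 50, n_samples = 100,
                            load_range = c(0.5, 3), noise_sd = 1,
                            seed = 7) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  l1 <- runif(n_per_block, load_range[1], load_range[2])
  l2 <- runif(n_per_block, load_range[1], load_range[2])
  expr <- rbind(outer(l1, f1), outer(l2, f2)) +
    matrix(rnorm(2 * n_per_block * n_samples, sd = noise_sd),
           2 * n_per_block)
  rownames(expr) <- sprintf("g%03d", seq_len(2 * n_per_block))
  colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
  list(expr = expr, block = rep(1:2, each = n_per_block),
       loading = c(l1, l2))
}

# Independent brute-force BH step-up, used as the oracle for bh_adjust.
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force biweight midcorrelation of two vectors (no outlier cap),
# straight from the definition; oracle for bicor_matrix.
bicor_by_hand <- function(x, y) {
  pre <- function(v) {
    u <- (v - median(v)) / (9 * mad(v, constant = 1))
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - median(v)) * w
  }
  a <- pre(x); b <- pre(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Brute-force TOM from the double-loop definition; oracle for
# tom_similarity.
tom_by_hand <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - 1
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    out[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# all permutations of 1..n, for small-n exact-test oracles
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}
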