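make_cm <- function(counts) {
  colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  count_matrix(counts, data.frame(sample = colnames(counts),
                                  population = "L1", garden = "l"))
}

test_that("size factors follow the median-of-ratios closed forms", {
  m <- matrix(c(10, 20, 5, 10, 20, 5), ncol = 2)
  expect_equal(unname(size_factors(make_cm(m))), c(1, 1))

  m2 <- cbind(c(10, 20, 5), 2 * c(10, 20, 5))
  expect_equal(unname(size_factors(make_cm(m2))), c(2^-0.5, 2^0.5))

  # an all-zero gene does not perturb the reference
  m3 <- rbind(m2, c(0, 0))
  expect_equal(unname(size_factors(make_cm(m3))), c(2^-0.5, 2^0.5))

  m4 <- matrix(c(1, 0, 0, 1), 2)   # no gene expressed everywhere
  expect_error(size_factors(make_cm(m4)), "pseudo-reference")
})

test_that("log transform is exact on closed-form entries", {
  m <- matrix(c(0, 3, 4, 3, 0, 4), ncol = 2)
  cm <- make_cm(m)
  f <- c(s1 = 1, s2 = 1)
  lt <- log_transform(cm, f)
  expect_equal(lt[1, 1], 0)                       # count 0 -> 0
  expect_equal(log2(3 / 3 + 1), 1)                # count = factor -> 1
  expect_equal(log_transform(cm, c(s1 = 3, s2 = 1))[2, 1], 1)
  # doubling a sample's counts and its factor leaves values unchanged
  cm2 <- make_cm(cbind(m[, 1] * 2, m[, 2]))
  expect_equal(log_transform(cm2, c(s1 = 2, s2 = 1)),
               log_transform(cm, c(s1 = 1, s2 = 1)),
               ignore_attr = TRUE)
})

test_that("sample clustering separates planted tissue groups", {
  set.seed(9)
  base <- matrix(rnorm(100 * 12), 100, 12)
  base[, 7:12] <- base[, 7:12] + 8      # large tissue offset
  colnames(base) <- sprintf("s%02d", 1:12)
  cl <- sample_cluster(base, k = 2)
  expect_equal(length(unique(cl$labels[1:6])), 1)
  expect_equal(length(unique(cl$labels[7:12])), 1)
  expect_false(cl$labels[1] == cl$labels[7])

  # a duplicated sample sits at distance zero and merges first
  dup <- cbind(base, s13 = base[, 1])
  cl2 <- sample_cluster(dup)
  expect_equal(cl2$hclust$height[1], 0)

  # permuting the sample order relabels but preserves the tree heights
  perm <- sample(ncol(base))
  cl3 <- sample_cluster(base[, perm])
  expect_equal(sort(cl3$hclust$height), sort(cl$hclust$height))
  expect_error(sample_cluster(base[, 1:2]), "at least 3")
})

test_that("null contrasts are calibrated and effects are recovered", {
  set.seed(12)
  n_g <- 5000; n <- 20
  mu <- exp(rnorm(n_g, 5, 1))
  alpha <- 0.05
  counts <- matrix(rnbinom(n_g * 2 * n, mu = mu, size = 1 / alpha),
                   n_g, 2 * n)
  cm <- make_cm(counts)
  a <- sprintf("s%d", 1:n); b <- sprintf("s%d", (n + 1):(2 * n))
  res <- estimate_contrast(cm, a, b)
  ks <- suppressWarnings(ks.test(res$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.05)

  # log2fc = 2 injected into 500 genes (a global shift would be
  # absorbed by normalization) at low dispersion: recovered within 0.1
  counts2 <- matrix(rnbinom(n_g * 2 * n, mu = mu, size = 1 / 0.01),
                    n_g, 2 * n)
  counts2[1:500, 1:n] <- matrix(rnbinom(500 * n, mu = 4 * mu[1:500],
                                        size = 1 / 0.01), 500, n)
  res2 <- estimate_contrast(make_cm(counts2), a, b)
  expect_lt(abs(mean(res2$log2fc[1:500]) - 2), 0.1)

  # identical groups give exactly zero log2fc
  res3 <- estimate_contrast(cm, a, a)
  expect_true(all(res3$log2fc == 0))
  expect_error(estimate_contrast(cm, a[1], b), "at least 2")
})

test_that("contrasts are exactly additive across three groups", {
  sim <- small_sim(n_genes = 80, seed = 55)
  cm <- sim$cm
  A <- select_samples(cm, "H", "h")
  B <- select_samples(cm, c("L1", "L2"), "h")
  C <- select_samples(cm, c("L1", "L2"), "l")
  ab <- estimate_contrast(cm, A, B)$log2fc
  bc <- estimate_contrast(cm, B, C)$log2fc
  ac <- estimate_contrast(cm, A, C)$log2fc
  expect_equal(ab + bc, ac, tolerance = 1e-12)
})

test_that("padj never falls below the raw p-value", {
  sim <- small_sim(n_genes = 150, seed = 56)
  res <- estimate_contrast(sim$cm,
                           select_samples(sim$cm, "H", "h"),
                           select_samples(sim$cm, c("L1", "L2"), "h"))
  ok <- res$estimable
  expect_true(all(res$padj[ok] >= res$pvalue[ok] - 1e-12))
  expect_true(all(res$se[ok] > 0))
})

test_that("duration screen detects injected duration effects", {
  cells <- default_cells(); cells$n <- c(12L, 12L, 6L, 6L, 6L, 6L)
  cfg <- sim_config(n_genes = 400, cells = cells, prop_duration = 0.1,
                    duration_slope = 3, prop_effect = 0, n_modules = 0,
                    prop_mad_zero = 0, alpha_range = c(0.01, 0.05),
                    seed = 61)
  tr <- generate_truth(cfg)
  cm <- simulate_counts(tr, make_design(cfg), seed = 62)
  excl <- duration_screen(cm)
  affected <- tr$gene[tr$duration_slope != 0]
  expect_gt(length(affected), 10)
  power <- mean(affected %in% excl)
  expect_gt(power, 0.8)
})

test_that("duration screen keeps the false discovery rate in check", {
  cfg <- sim_config(n_genes = 800, prop_duration = 0, prop_effect = 0,
                    n_modules = 0, prop_mad_zero = 0, seed = 63)
  tr <- generate_truth(cfg)
  cm <- simulate_counts(tr, make_design(cfg), seed = 64)
  excl <- duration_screen(cm)
  # with no true effects every exclusion is false; expect almost none
  expect_lt(length(excl), 0.05 * 800)
})

test_that("a single occupied duration bin skips the stratum", {
  sim <- small_sim(n_genes = 60, seed = 65, acclim_range = c(40L, 50L))
  w <- capture_warnings(excl <- duration_screen(sim$cm))
  expect_true(any(grepl("single occupied", w)))
  expect_length(excl, 0)
})

test_that("interaction magnitude measures reaction-norm divergence", {
  cells <- default_cells(); cells$n <- c(50L, 50L, 25L, 25L, 25L, 25L)
  # a null backdrop anchors the median-of-ratios normalization (with
  # every gene differentially expressed the per-cell median acquires a
  # compositional offset); recovery is judged on well-expressed effect
  # genes, the estimator's documented domain
  cfg <- sim_config(n_genes = 600, cells = cells, prop_effect = 0.4,
                    fraction_evolved = 1, n_modules = 0,
                    baseline_mean = 9, baseline_sd = 1,
                    prop_duration = 0, prop_mad_zero = 0,
                    alpha_range = c(0.01, 0.05), seed = 71)
  tr <- generate_truth(cfg)
  cm <- simulate_counts(tr, make_design(cfg), seed = 72)
  im <- interaction_magnitude(cm)
  truth_mag <- abs(tr$gc_true - tr$gcb_true)
  mins <- 2^(tr$baseline - abs(tr$pc_true) - abs(tr$gc_true) -
               abs(tr$gcb_true))
  well <- mins > 10 & tr$direction_true != "none"
  expect_gt(sum(well), 100)
  expect_lt(stats::median(abs(im$magnitude - truth_mag)[well]), 0.15)

  # swapping the garden labels globally leaves the magnitude unchanged
  cm2 <- cm
  cm2$design$garden <- ifelse(cm$design$garden == "h", "l", "h")
  im2 <- interaction_magnitude(cm2)
  expect_equal(im2$magnitude, im$magnitude, tolerance = 1e-12)

  # persisting genes have magnitude near zero
  cfg_p <- sim_config(n_genes = 600, cells = cells, prop_effect = 0.4,
                      fraction_evolved = 0, n_modules = 0,
                      baseline_mean = 9, baseline_sd = 1,
                      prop_duration = 0, prop_mad_zero = 0,
                      alpha_range = c(0.01, 0.05), seed = 73)
  tr_p <- generate_truth(cfg_p)
  cm_p <- simulate_counts(tr_p, make_design(cfg_p), seed = 74)
  im_p <- interaction_magnitude(cm_p)
  expect_lt(stats::median(im_p$magnitude), 0.1)
})
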