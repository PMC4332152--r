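make_pcm <- function(counts, samples, positions = seq_len(nrow(counts)) - 1L,
                     n_genes = 1L) {
  structure(list(positions = positions, counts = counts, samples = samples,
                 n_genes = n_genes),
            class = "position_count_matrix")
}

test_that("build_position_counts sums over genes and drops null positions", {
  g <- tiny_genome()
  mk <- function(pos) data.frame(chromosome = "chrT", midpoint = pos,
                                 sample_id = "s", multiplicity = 1L)
  # one midpoint at +3 of gene gA
  pcm1 <- build_position_counts(list(s = mk(3003L)), g)
  expect_equal(pcm1$positions, 3L)
  expect_equal(unname(pcm1$counts[, "s"]), 1L)
  # two genes each with a midpoint at +3 (gB is minus-strand: tss - 3)
  pcm2 <- build_position_counts(list(s = mk(c(3003L, 14997L))), g)
  expect_equal(pcm2$positions, 3L)
  expect_equal(unname(pcm2$counts[, "s"]), 2L)
  expect_equal(unname(per_gene_average(pcm2)[, "s"]), 1.0)
})

test_that("normalisation factors implement the input-coverage policy", {
  samples <- data.frame(sample_id = c("ip1", "in1"),
                        condition = "A", is_input = c(FALSE, TRUE),
                        pair_id = "r1", stringsAsFactors = FALSE)
  counts <- cbind(ip1 = c(10L, 20L, 30L, 40L),
                  in1 = c(5L, 5L, 10L, 5L))
  f <- normalization_factors(make_pcm(counts, samples))
  # identity up to rescaling: doubled input count -> doubled factor
  expect_equal(unname(f[3, "ip1"] / f[1, "ip1"]), 2)
  expect_equal(exp(mean(log(f[, "ip1"]))), 1)  # geometric mean 1
  # equal input counts and equal totals -> all factors 1
  eq <- cbind(ip1 = c(10L, 10L, 10L, 10L), in1 = c(10L, 10L, 10L, 10L))
  expect_equal(unname(normalization_factors(make_pcm(eq, samples))[, 1]),
               rep(1, 4))
  # scale invariance: doubling every input count changes nothing
  half <- counts; half[, "in1"] <- half[, "in1"] * 2L
  expect_equal(normalization_factors(make_pcm(half, samples)), f)
  # zero input count replaced by position-wise minimum positive count
  z <- counts; z[2, "in1"] <- 0L
  fz <- normalization_factors(make_pcm(z, samples))
  expect_true(all(is.finite(fz) & fz > 0))
  expect_error(normalization_factors(make_pcm(
    cbind(ip1 = c(1L, 1L), in1 = c(0L, 0L)), samples)), "zero|empty")
})

test_that("NB Wald test: null identity and condition symmetry", {
  A <- matrix(c(5L, 9L, 14L, 30L, 41L, 52L), 2, 3)
  r0 <- nb_wald_test(A, A)
  expect_equal(r0$log2_fold_change, c(0, 0), tolerance = 1e-6)
  expect_equal(r0$wald_p, c(1, 1), tolerance = 1e-6)
  B <- matrix(c(9L, 20L, 11L, 35L, 60L, 41L), 2, 3)
  r1 <- nb_wald_test(A, B)
  r2 <- nb_wald_test(B, A)
  expect_equal(r1$log2_fold_change, -r2$log2_fold_change, tolerance = 1e-6)
  expect_equal(r1$wald_p, r2$wald_p, tolerance = 1e-6)
  expect_error(nb_wald_test(matrix(0L, 1, 3), matrix(0L, 1, 3)), "all-zero")
})

test_that("dispersion-zero limit matches the Poisson-likelihood oracle", {
  # independent oracle: Poisson GLM Wald statistic from stats::glm
  y <- c(100, 100, 100, 200, 200, 200)
  cond <- factor(rep(c("A", "B"), each = 3))
  fit <- stats::glm(y ~ cond, family = stats::poisson())
  oracle_z <- stats::coef(summary(fit))["condB", "z value"]
  r <- nb_wald_test(matrix(y[1:3], 1), matrix(y[4:6], 1),
                    dispersion = "fixed", alpha = 0)
  expect_equal(r$wald_stat, oracle_z, tolerance = 5e-4)
  expect_equal(round(r$wald_stat, 3), round(oracle_z, 3))
  expect_equal(r$log2_fold_change, 1, tolerance = 1e-6)
})

test_that("NB log2 fold change is recovered in simulation", {
  withr::with_seed(99, {
    n <- 1000
    qA <- 100; alpha <- 0.1
    KA <- matrix(rnbinom(3 * n, mu = qA, size = 1 / alpha), n, 3)
    KB <- matrix(rnbinom(3 * n, mu = 2 * qA, size = 1 / alpha), n, 3)
    keep <- rowSums(KA) > 0 & rowSums(KB) > 0
    r <- nb_wald_test(KA[keep, ], KB[keep, ])
    expect_lt(abs(mean(r$log2_fold_change) - 1), 0.1)
  })
})

test_that("type-I error is controlled at correctly specified dispersion", {
  withr::with_seed(7, {
    n <- 2000; alpha <- 0.1
    KA <- matrix(rnbinom(3 * n, mu = 100, size = 1 / alpha), n, 3)
    KB <- matrix(rnbinom(3 * n, mu = 100, size = 1 / alpha), n, 3)
    r <- nb_wald_test(KA, KB, dispersion = "fixed", alpha = alpha)
    frac <- mean(r$wald_p < 0.05)
    se <- sqrt(0.05 * 0.95 / n)
    expect_lt(abs(frac - 0.05), 4 * se)
  })
})

test_that("local FDR: pure-null behaviour, monotonicity, mixture power", {
  expect_error(local_fdr(runif(50)), "at least")
  withr::with_seed(31, {
    p0 <- runif(2000)
    l0 <- local_fdr(p0)
    expect_gte(median(l0), 0.9)
    # monotone nondecreasing in p by construction
    ord <- order(p0)
    expect_true(all(diff(l0[ord]) >= -1e-12))
    # 50% uniform / 50% Beta(0.1, 1) mixture with known labels
    n <- 10000
    null <- rbinom(n, 1, 0.5) == 1
    p <- ifelse(null, runif(n), rbeta(n, 0.1, 1))
    l <- local_fdr(p)
    dec <- p <= quantile(p, 0.1)
    expect_lt(mean(l[dec]), 0.2)
    # and the small-p stratum is indeed mostly non-null (oracle check)
    expect_gt(mean(!null[dec]), 0.8)
  })
})

test_that("significance thresholds use strict inequalities as calibrated", {
  res <- data.frame(log2_fold_change = c(0.04, 0.30, 0.30, -0.30),
                    lfdr = c(0.01, 0.19, 0.20, 0.10))
  out <- call_significant(res)
  expect_equal(out$significant, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("huber_mean matches its defining properties", {
  expect_equal(huber_mean(c(5, 5, 5)), 5)
  expect_equal(huber_mean(c(1, 2, 3)), 2)
  h <- huber_mean(c(1, 2, 3, 100))
  expect_gt(h, median(c(1, 2, 3, 100)))
  expect_lt(h, mean(c(1, 2, 3, 100)))
  expect_error(huber_mean(numeric(0)), "empty")
})
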