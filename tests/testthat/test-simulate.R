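test_that("zero-jitter placement yields exact 150 bp dyad lattices", {
  g <- tiny_genome()
  pr <- strain_preset("z", jitter_sd = 0)
  tr <- place_nucleosomes(g, pr, seed = 1)
  nucA <- tr$nucleosomes[tr$nucleosomes$gene_id == "gA", ]
  offs <- nucA$dyad - g$genes$tss[1]
  down <- sort(offs[nucA$nuc_index > 0])
  expect_equal(down, seq(75, by = 150, length.out = length(down)))
  up <- sort(offs[nucA$nuc_index < 0], decreasing = TRUE)
  expect_equal(up, seq(-275, by = -150, length.out = length(up)))
  # minus-strand gene mirrored in genomic coordinates
  nucB <- tr$nucleosomes[tr$nucleosomes$gene_id == "gB", ]
  expect_equal(sort(g$genes$tss[2] - nucB$dyad[nucB$nuc_index > 0]),
               seq(75, by = 150, length.out = sum(nucB$nuc_index > 0)))
  # no dyad inside the NDR interval, gene-relative [-170, -30]
  expect_false(any(offs >= -170 & offs <= -30))
})

test_that("absent marks are never carried; layout probabilities are respected", {
  g <- build_genome(1, 150, 1500, seed = 2)
  tr0 <- place_nucleosomes(g, preset_strain("set1d"), seed = 3)
  expect_equal(sum(tr0$nucleosomes$H3K4me1 | tr0$nucleosomes$H3K4me2 |
                     tr0$nucleosomes$H3K4me3), 0L)
  # wild type: fraction of +1 nucleosomes carrying H3K4me3 ~ Binom(n, 0.9)
  tr1 <- place_nucleosomes(g, preset_strain("WT"), seed = 4)
  plus1 <- tr1$nucleosomes[tr1$nucleosomes$nuc_index == 1L, ]
  p <- mean(plus1$H3K4me3)
  se <- sqrt(0.9 * 0.1 / nrow(plus1))
  expect_lt(abs(p - 0.9), 4 * se)
})

test_that("simulate_pool conserves originals, keeps provenance, is seeded", {
  g <- tiny_genome()
  tr <- place_nucleosomes(g, preset_strain("WT"), seed = 1, sample_id = "s1")
  bm <- random_barcode_map(1, "s1", seed = 2)
  p1 <- simulate_pool(list(s1 = tr), bm, "input", n_fragments = 500,
                      pcr_duplication_rate = 0.3, seed = 9)
  expect_equal(nrow(p1$fragments), 500L)       # originals, pre-duplication
  expect_true(all(p1$fragments$copies >= 1L))
  expect_identical(p1$fragments,
                   simulate_pool(list(s1 = tr), bm, "input",
                                 n_fragments = 500,
                                 pcr_duplication_rate = 0.3,
                                 seed = 9)$fragments)
  # mark logic: a set1d pool IPed for H3K4me3 never emits marked fragments
  tr0 <- place_nucleosomes(g, preset_strain("set1d"), seed = 1,
                           sample_id = "s1")
  p0 <- simulate_pool(list(s1 = tr0), bm, "H3K4me3",
                      background_rate = 0.1, n_fragments = 200, seed = 5)
  expect_false(any(p0$fragments$marked))
  # background_rate 0 in a markless strain -> empty pool error
  expect_error(simulate_pool(list(s1 = tr0), bm, "H3K4me3",
                             background_rate = 0, n_fragments = 10, seed = 5),
               "empty pool")
  expect_error(simulate_pool(list(), bm, "input", n_fragments = 10, seed = 1))
})

test_that("enrichment calibration: marked:unmarked odds converge", {
  g <- build_genome(1, 80, 1500, seed = 6)
  tr <- place_nucleosomes(g, preset_strain("WT"), seed = 7, sample_id = "s1")
  bm <- random_barcode_map(1, "s1", seed = 2)
  enrichment <- 10; background <- 0.2
  pool <- simulate_pool(list(s1 = tr), bm, "H3K4me3", enrichment = enrichment,
                        background_rate = background, n_fragments = 20000,
                        seed = 8)
  prev <- mean(tr$nucleosomes$H3K4me3)
  p_expected <- enrichment * prev / (enrichment * prev + background * (1 - prev))
  bt <- stats::binom.test(sum(pool$fragments$marked), nrow(pool$fragments),
                          p = p_expected)
  expect_gt(bt$p.value, 0.001)
  # no-enrichment identity: weights equal -> marked fraction ~ prevalence
  pool1 <- simulate_pool(list(s1 = tr), bm, "H3K4me3", enrichment = 1,
                         background_rate = 1, n_fragments = 20000, seed = 9)
  bt1 <- stats::binom.test(sum(pool1$fragments$marked), 20000, p = prev)
  expect_gt(bt1$p.value, 0.001)
})

test_that("without PCR duplication coordinate collisions stay at chance level", {
  g <- build_genome(1, 200, 1500, seed = 10)
  tr <- place_nucleosomes(g, preset_strain("WT"), seed = 11, sample_id = "s1")
  bm <- random_barcode_map(1, "s1", seed = 2)
  n <- 1000L
  pool <- simulate_pool(list(s1 = tr), bm, "input", n_fragments = n, seed = 12)
  expect_true(all(pool$fragments$copies == 1L))
  # oracle: expected collision pairs = C(n,2) * sum_i p_i^2 * sum_k q_k^2
  # with uniform nucleosome choice and the truncated-normal length pmf
  N <- nrow(tr$nucleosomes)
  k <- 100:250
  q <- stats::dnorm(k, 150, 10); q <- q / sum(q)
  lambda <- choose(n, 2) * (1 / N) * sum(q^2)
  key <- with(pool$fragments, paste(chromosome, start, end, sample_id))
  collisions <- n - length(unique(key))
  expect_lte(collisions, stats::qpois(0.9999, lambda))
})

test_that("cage tags: construction expectations and determinism", {
  g <- build_genome(1, 60, 1500, seed = 13)
  pr <- preset_strain("set2d", cryptic_gene_fraction = 0.2)
  tr <- place_nucleosomes(g, pr, seed = 14)
  t1 <- simulate_cage_tags(g, tr, tags_per_gene = 300,
                           internal_fraction_when_cryptic = 0.3, seed = 15)
  expect_identical(t1, simulate_cage_tags(g, tr, 300, 0.3, seed = 15))
  expect_false(identical(t1, simulate_cage_tags(g, tr, 300, 0.3, seed = 16)))
  # cryptic truth invariant: internal position always >= TSS + 200
  expect_true(all(tr$genes$internal_tss_position[tr$genes$cryptic] >= 200))
  # expected internal tag count at the cryptic site ~ tags * fraction
  gb <- nucleomux:::gene_body_bounds(g)
  cg <- tr$genes[tr$genes$cryptic, ][1, ]
  gi <- gb[gb$gene_id == cg$gene_id, ]
  off <- if (gi$strand == "+") t1$five_prime_position - gi$tss else
    gi$tss - t1$five_prime_position
  near <- sum(t1$chromosome == gi$chromosome &
                abs(off - cg$internal_tss_position) <= 40)
  expect_lt(abs(near - 300 * 0.3), 5 * sqrt(300 * 0.3))
  # internal_fraction 0: cryptic and non-cryptic genes indistinguishable
  t0 <- simulate_cage_tags(g, tr, tags_per_gene = 200,
                           internal_fraction_when_cryptic = 0,
                           baseline_internal_fraction = 0, seed = 17)
  ic <- internal_counts(t0, g)
  expect_equal(sum(ic[tr$genes$cryptic, ]), 0L)
  expect_equal(sum(ic[!tr$genes$cryptic, ]), 0L)
})
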