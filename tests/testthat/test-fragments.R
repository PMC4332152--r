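test_that("SAM ingestion classifies orientation, uniqueness and MAPQ", {
  sam <- write_test_sam(tempfile(fileext = ".sam"))
  pairs <- load_aligned_pairs(sam, sample_id = "s")
  pairs <- pairs[order(pairs$qname), ]
  fr <- pairs[pairs$qname == "fr1", ]
  expect_true(fr$proper_convergent && fr$unique)
  expect_equal(c(fr$start, fr$end), c(100L, 250L))
  expect_equal(fr$mapping_quality, 42L)
  expect_false(pairs$proper_convergent[pairs$qname == "rf1"])  # outward RF
  expect_false(pairs$unique[pairs$qname == "sec1"])            # secondary aln
  expect_true(pairs$unique[pairs$qname == "lo1"])              # low MAPQ only
})

test_that("size filtering follows the mono-nucleosome rules", {
  mk <- function(len) data.frame(chromosome = "c", start = 1000L,
                                 end = 1000L + len, sample_id = "s",
                                 proper_convergent = TRUE, unique = TRUE,
                                 mapping_quality = 42L)
  cfg <- filter_config()  # max 220, multiplex min 130, input min 100
  expect_equal(nrow(filter_fragments(mk(221), cfg)), 0L)  # too long
  expect_equal(nrow(filter_fragments(mk(150), cfg)), 1L)  # mono-nucleosomal
  expect_equal(nrow(filter_fragments(mk(129), cfg, is_input = FALSE)), 0L)
  expect_equal(nrow(filter_fragments(mk(129), cfg, is_input = TRUE)), 1L)
  expect_equal(nrow(filter_fragments(mk(99), cfg, is_input = TRUE)), 0L)
  # NA lower bound disables the rule (pairwise-comparison mode)
  cfg2 <- filter_config(min_fragment = NA)
  expect_equal(nrow(filter_fragments(mk(110), cfg2)), 1L)
  # orientation/uniqueness/MAPQ gates
  bad <- mk(150); bad$proper_convergent <- FALSE
  expect_equal(nrow(filter_fragments(bad, cfg)), 0L)
  low <- mk(150); low$mapping_quality <- 10L
  expect_equal(nrow(filter_fragments(low, cfg)), 0L)
  rep <- attr(filter_fragments(rbind(mk(150), mk(221), mk(129)), cfg), "report")
  expect_equal(unname(rep[c("too_long", "too_short", "kept")]), c(1L, 1L, 1L))
})

test_that("narrowing the size window never increases retained fragments", {
  set.seed(42)
  frs <- data.frame(chromosome = "c", start = 0L,
                    end = sample(80:300, 200, replace = TRUE),
                    sample_id = "s")
  kept <- sapply(c(250, 220, 180, 160), function(mx)
    nrow(filter_fragments(frs, filter_config(max_fragment = mx,
                                             min_fragment = 130))))
  expect_true(all(diff(kept) <= 0))
})

test_that("deduplication caps stacks and is idempotent", {
  stack <- function(n) data.frame(chromosome = "c", start = 500L, end = 650L,
                                  sample_id = "s")[rep(1, n), ]
  d5 <- deduplicate(stack(5), cap = 2)
  expect_equal(d5$copies, 2L)
  expect_equal(attr(d5, "removed"), 3)
  expect_equal(deduplicate(stack(1), cap = 2)$copies, 1L)
  d2 <- deduplicate(stack(2), cap = 2)
  expect_equal(d2$copies, 2L)
  expect_equal(attr(d2, "removed"), 0)
  # idempotence
  once <- deduplicate(stack(7), cap = 2)
  twice <- deduplicate(once, cap = 2)
  expect_equal(twice$copies, once$copies)
  expect_equal(attr(twice, "removed"), 0)
  # alternative reading: drop the whole over-duplicated stack
  expect_equal(nrow(deduplicate(stack(5), cap = 2, mode = "drop")), 0L)
  expect_equal(nrow(deduplicate(stack(2), cap = 2, mode = "drop")), 1L)
})

test_that("midpoints use the floor((start + end - 1) / 2) convention", {
  fr <- data.frame(chromosome = "c",
                   start = c(100L, 0L, 10L),
                   end = c(250L, 2L, 161L),
                   sample_id = "s")
  mp <- midpoints(fr)
  expect_equal(mp$midpoint, c(174L, 0L, 85L))
  expect_true(all(mp$midpoint >= fr$start & mp$midpoint < fr$end))
})

test_that("with zero jitter and duplication, midpoints equal true dyads", {
  g <- tiny_genome()
  pr <- strain_preset("z", jitter_sd = 0, fragment_length_sd = 0,
                      fragment_length_mean = 151)  # odd length: exact centre
  tr <- place_nucleosomes(g, pr, seed = 1, sample_id = "s1")
  bm <- random_barcode_map(1, "s1", seed = 2)
  pool <- simulate_pool(list(s1 = tr), bm, "input", n_fragments = 300,
                        pcr_duplication_rate = 0, seed = 3)
  mp <- midpoints(deduplicate(filter_fragments(pool$fragments,
                                               filter_config(), TRUE), 2))
  expect_true(all(mp$midpoint %in% tr$nucleosomes$dyad))
})
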