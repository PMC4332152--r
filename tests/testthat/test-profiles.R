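test_that("build_track is an exact, conserved per-base histogram", {
  g <- tiny_genome()
  mids <- data.frame(chromosome = "chrT", midpoint = c(500L, 500L, 501L),
                     sample_id = "s", multiplicity = c(1L, 1L, 3L))
  tr <- build_track(mids, g)
  expect_equal(tr$tracks$chrT[501], 2)   # two midpoints at base 500
  expect_equal(tr$tracks$chrT[502], 3)   # multiplicity respected
  expect_equal(sum(tr$tracks$chrT), tr$total)
  expect_equal(tr$total, 5)
  # empty input -> all-zero track
  empty <- build_track(mids[0, ], g)
  expect_equal(sum(empty$tracks$chrT), 0)
  # out-of-bounds midpoint errors, naming the record
  expect_error(build_track(data.frame(chromosome = "chrT", midpoint = 20000L,
                                      sample_id = "s", multiplicity = 1L), g),
               "out-of-bounds")
  # bedGraph export round-trips the nonzero runs
  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, bg)
  lines <- readLines(bg)
  expect_equal(lines[2], "chrT\t500\t501\t2")
  expect_equal(lines[3], "chrT\t501\t502\t3")
})

test_that("tss_profile orients genes and normalises genome-wide", {
  g <- tiny_genome()  # gA + at 3000, gB - at 15000
  # single midpoint at the TSS of the plus-strand gene
  p1 <- tss_profile(build_track(data.frame(chromosome = "chrT",
                                           midpoint = 3000L, sample_id = "s",
                                           multiplicity = 1L), g), g)
  expect_equal(p1$occupancy[p1$positions == 0], 1.0)
  expect_equal(sum(p1$occupancy), 1.0)  # gB window sees nothing
  # minus-strand gene: 10 bp downstream in gene orientation = tss - 10
  p2 <- tss_profile(build_track(data.frame(chromosome = "chrT",
                                           midpoint = 14990L, sample_id = "s",
                                           multiplicity = 1L), g), g)
  expect_equal(p2$occupancy[p2$positions == 10], 1.0)
  expect_equal(p2$occupancy[p2$positions == -10], 0.0)
  # conservation: sum occupancy = (midpoints inside windows) / all midpoints
  mids <- data.frame(chromosome = "chrT",
                     midpoint = c(3000L, 3100L, 9000L),  # 9000 outside both
                     sample_id = "s", multiplicity = 1L)
  p3 <- tss_profile(build_track(mids, g), g)
  expect_equal(sum(p3$occupancy), 2 / 3)
})

test_that("zero-jitter simulated occupancy peaks sit on true dyad offsets", {
  g <- tiny_genome()
  pr <- strain_preset("z", jitter_sd = 0, fragment_length_sd = 0,
                      fragment_length_mean = 151)
  tr <- place_nucleosomes(g, pr, seed = 1, sample_id = "s1")
  bm <- random_barcode_map(1, "s1", seed = 2)
  pool <- simulate_pool(list(s1 = tr), bm, "input", n_fragments = 2000,
                        seed = 3)
  prof <- tss_profile(build_track(midpoints(pool$fragments), g), g)
  hit <- prof$positions[prof$counts > 0]
  lattice <- c(seq(-275, -1000, by = -150), seq(75, 1500, by = 150))
  expect_true(all(hit %in% lattice))
})

test_that("mark_occupancy forms finite input-normalised ratios", {
  occ <- rep(0.001, 2501)
  a <- profile_from_occupancy(occ)
  expect_equal(mark_occupancy(a, a)$ratio, rep(1, 2501))  # identity
  b <- profile_from_occupancy(replace(occ, 100, 0))
  r <- mark_occupancy(a, b, pseudocount = 1e-4)
  expect_true(all(is.finite(r$ratio)))
  expect_error(mark_occupancy(a, profile_from_occupancy(rep(0.1, 101),
                                                        window = c(-50, 50))),
               "window")
})

test_that("peak spacing is recovered from constructed and simulated profiles", {
  occ <- numeric(2501)
  pos <- seq(-1000, 1500)
  occ[pos %% 150 == 75 & pos > -1000] <- 0.01  # delta peaks every 150 bp
  expect_equal(profile_peak_spacing(profile_from_occupancy(occ)), 150)
  occ2 <- numeric(2501)
  occ2[pos %% 165 == 0] <- 0.01
  expect_equal(profile_peak_spacing(profile_from_occupancy(occ2)), 165)
  expect_error(profile_peak_spacing(profile_from_occupancy(numeric(2501))),
               "maxima")
})

test_that("ndr_locator matches the constructed minimum and errors when flat", {
  pos <- seq(-1000, 1500)
  occ <- rep(0.002, 2501)
  occ[pos >= -170 & pos < -30] <- 0  # zero exactly on [-170, -30)
  nd <- ndr_locator(profile_from_occupancy(occ))
  expect_equal(nd$center, -100)
  expect_equal(nd$width, 140)
  expect_error(ndr_locator(profile_from_occupancy(rep(0.001, 2501))), "flat")
})

test_that("widening the preset NDR widens the recovered NDR accordingly", {
  run_one <- function(width) {
    g <- build_genome(1, 150, 1500, seed = 21)
    tr <- place_nucleosomes(g, strain_preset("w", ndr_width = width),
                            seed = 22, sample_id = "s")
    bm <- random_barcode_map(1, "s", seed = 2)
    pool <- simulate_pool(list(s = tr), bm, "input", n_fragments = 120000,
                          seed = 23)
    fr <- deduplicate(filter_fragments(pool$fragments, filter_config(), TRUE), 2)
    ndr_locator(tss_profile(build_track(midpoints(fr), g), g))
  }
  narrow <- run_one(140L)
  wide <- run_one(190L)
  expect_lt(abs((wide$width - narrow$width) - 50), 25)  # smoothing tolerance
  expect_lt(abs(wide$center - narrow$center), 20)
})

test_that("a 5'-mark IP is enriched over input within the first 500 bp", {
  g <- build_genome(1, 100, 1500, seed = 41)
  tr <- place_nucleosomes(g, preset_strain("WT"), seed = 42, sample_id = "s")
  bm <- random_barcode_map(1, "s", seed = 2)
  mids_of <- function(pool) midpoints(deduplicate(
    filter_fragments(pool$fragments, filter_config(),
                     is_input = pool$ip_mark == "input"), 2))
  ip <- simulate_pool(list(s = tr), bm, "H3K4me3", enrichment = 20,
                      background_rate = 0.05, n_fragments = 60000, seed = 43)
  input <- simulate_pool(list(s = tr), bm, "input", n_fragments = 60000,
                         seed = 44)
  r <- mark_occupancy(tss_profile(build_track(mids_of(ip), g), g),
                      tss_profile(build_track(mids_of(input), g), g))
  five_prime <- r$positions > 0 & r$positions <= 500
  three_prime <- r$positions > 500
  expect_gt(mean(r$ratio[five_prime]), mean(r$ratio[three_prime]))
  expect_gt(mean(r$ratio[five_prime]), 1)
})

test_that("profiles are invariant under genome mirroring", {
  g <- tiny_genome()
  L <- g$chromosomes$length
  pr <- preset_strain("WT")
  tr <- place_nucleosomes(g, pr, seed = 5, sample_id = "s")
  bm <- random_barcode_map(1, "s", seed = 2)
  pool <- simulate_pool(list(s = tr), bm, "input", n_fragments = 5000, seed = 6)
  mp <- midpoints(pool$fragments)
  prof <- tss_profile(build_track(mp, g), g)
  # mirror: coordinate x -> L - 1 - x, strands flipped
  gm <- genome_model(g$chromosomes,
                     transform(g$genes,
                               strand = ifelse(strand == "+", "-", "+"),
                               tss = L - 1L - tss))
  mpm <- transform(mp, midpoint = L - 1L - midpoint)
  profm <- tss_profile(build_track(mpm, gm), gm)
  expect_equal(profm$occupancy, prof$occupancy)
})
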