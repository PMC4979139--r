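test_that("Haldane mapping function matches its closed form and domain", {
  expect_equal(haldane_cm(0), 0)
  expect_equal(haldane_cm(0.25), -50 * log(0.5))           # 34.657 cM
  expect_equal(haldane_cm(0.25), 34.657, tolerance = 1e-4)
  expect_equal(haldane_cm(0.49), -50 * log(0.02))          # 195.6 cM
  expect_equal(haldane_cm(0.49), 195.6, tolerance = 1e-3)
  expect_error(haldane_cm(0.5), "0.5")
  expect_error(haldane_cm(-0.01), "0.5")
})

test_that("inverse Haldane function roundtrips to 1e-9 across [0, 0.499]", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(-50 * log(0.5)), 0.25, tolerance = 1e-12)
  expect_lt(haldane_r(1000), 0.5)   # asymptote approached but not attained
  expect_lte(haldane_r(1e6), 0.5)   # saturates at the bound in double precision
  expect_error(haldane_r(-1), ">= 0")
  r <- seq(0, 0.499, by = 0.001)
  expect_true(all(abs(haldane_r(haldane_cm(r)) - r) < 1e-9))
  d <- seq(0, 300, by = 0.5)
  expect_true(all(abs(haldane_cm(haldane_r(d)) - d) < 1e-9))
})

test_that("testcross recombination fractions count mismatches with phase folding", {
  a <- rep(c(0L, 1L), 50)
  est <- estimate_rf_testcross(a, a)
  expect_equal(est$r_hat, 0)
  expect_equal(est$phase, "coupling")
  expect_equal(est$n_informative, 100)

  b <- a; b[1:25] <- 1L - b[1:25]
  est <- estimate_rf_testcross(a, b)
  expect_equal(est$r_hat, 0.25)
  expect_equal(est$phase, "coupling")

  # 75 mismatches of 100: repulsion phase, folded to 0.25
  b <- 1L - a; b[1:25] <- 1L - b[1:25]
  est <- estimate_rf_testcross(a, b)
  expect_equal(est$r_hat, 0.25)
  expect_equal(est$phase, "repulsion")

  # pairwise-complete handling and sentinels
  est <- estimate_rf_testcross(c(0L, 1L, NA, 1L), c(0L, NA, 1L, 1L))
  expect_equal(est$n_informative, 2)
  expect_true(est$low_confidence)
  est <- estimate_rf_testcross(c(NA, NA), c(0L, 1L))
  expect_true(is.na(est$r_hat))
  expect_equal(est$n_informative, 0L)
})

test_that("F2 dominant ML estimator matches known solutions and the grid oracle", {
  # perfect coupling counts (3k, 0, 0, k): p = 1 so r = 0
  est <- estimate_rf_f2_dominant(c(300, 0, 0, 100))
  expect_equal(est$r_hat, 0, tolerance = 1e-6)
  expect_equal(est$phase, "coupling")

  est <- estimate_rf_f2_dominant(c(570, 90, 90, 250))
  oracle <- grid_rf_f2(c(570, 90, 90, 250))
  expect_equal(est$r_hat, oracle$r_hat, tolerance = 1e-3)
  expect_equal(est$phase, oracle$phase)

  expect_true(is.na(estimate_rf_f2_dominant(c(0, 0, 0, 0))$r_hat))

  # fixed phase is honoured
  est <- estimate_rf_f2_dominant(c(570, 90, 90, 250), phase = "repulsion")
  expect_equal(est$phase, "repulsion")
})

test_that("map built from three equidistant markers sums Haldane distances", {
  # construct calls with exactly 10/100 recombinants in each adjacent interval
  a <- rep(c(0L, 1L), 50)
  b <- a; b[1:10] <- 1L - b[1:10]
  c_ <- b; c_[41:50] <- 1L - c_[41:50]
  geno <- rbind(m1 = a, m2 = b, m3 = c_)
  markers <- data.frame(marker_id = c("m1", "m2", "m3"), chromosome = 1,
                        pos_bp = c(1e6, 2e6, 3e6), seg_type = "1:1",
                        informative_parent = "female")
  map <- build_map(geno, markers, "female", 1)
  expect_s3_class(map, "linkage_map")
  expect_equal(map$total_cm, 2 * haldane_cm(0.1))
  expect_equal(map$total_cm, 22.31, tolerance = 1e-3)
  expect_equal(map$positions$cum_cm, c(0, haldane_cm(0.1), 2 * haldane_cm(0.1)))
  expect_equal(map$phys_span_mb, 2)

  # reversing the physical orientation leaves the total length unchanged
  markers_rev <- markers
  markers_rev$pos_bp <- rev(markers$pos_bp)
  map_rev <- build_map(geno, markers_rev, "female", 1)
  expect_equal(map_rev$total_cm, map$total_cm)
})

test_that("markers with no joint estimate are bridged by skipping them", {
  a <- rep(c(0L, 1L), 50)
  b <- a; b[1:10] <- 1L - b[1:10]
  dead <- rep(NA_integer_, 100)
  geno <- rbind(m1 = a, m2 = dead, m3 = b)
  markers <- data.frame(marker_id = c("m1", "m2", "m3"), chromosome = 1,
                        pos_bp = c(1e6, 2e6, 3e6), seg_type = "1:1",
                        informative_parent = "female")
  map <- build_map(geno, markers, "female", 1)
  expect_equal(map$positions$marker_id, c("m1", "m3"))
  expect_equal(map$total_cm, haldane_cm(0.1))
  # fewer than two estimable markers: empty-map sentinel
  expect_null(build_map(rbind(m1 = a, m2 = dead),
                        markers[1:2, ], "female", 1))
})

test_that("interval filter removes the marker causing implausible RR and is idempotent", {
  # markers 0.1 Mb from their neighbours with r implying ~5 cM: RR ~ 50
  r_small <- haldane_r(2)   # 2 cM over 2 Mb: RR 1
  r_spike <- haldane_r(5)   # 5 cM over 0.1 Mb: RR 50
  map <- eucrr:::new_linkage_map("p", 1,
    c("m1", "m2", "bad", "m3"),
    c(1e6, 3e6, 3.1e6, 5.1e6),
    c(r_small, r_spike, r_spike))
  filtered <- filter_intervals(map, max_rr = 25)
  expect_equal(filtered$positions$marker_id, c("m1", "m2", "m3"))
  expect_true(all(filtered$intervals$rr < 25))

  # a clean map passes through unchanged, and filtering is a fixed point
  clean <- eucrr:::new_linkage_map("p", 1, c("a", "b", "c"),
                                   c(1e6, 2e6, 3e6),
                                   c(haldane_r(2), haldane_r(3)))
  expect_equal(filter_intervals(clean, 25), clean)
  expect_equal(filter_intervals(filtered, 25), filtered)
})

test_that("marker selection honours the coverage and segregation priorities", {
  markers <- data.frame(
    marker_id = c("tc1", "dom1", "tc2", "dom2", "lost", "weak"),
    pos_bp = c(1e6, 1.05e6, 10e6, 16e6, 30e6, 11e6),
    anchored = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    redundant = FALSE,
    seg_type = c("1:1", "3:1", "1:1", "3:1", "1:1", "1:1"),
    linkage_ok = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  kept <- select_markers(markers, gap_mb = 2)
  # 3:1 at the same locus as a 1:1 is dropped; 3:1 in a 6 Mb gap is kept
  expect_false("dom1" %in% kept$marker_id)
  expect_true("dom2" %in% kept$marker_id)
  # unanchored dropped regardless; weak linkage 1 Mb from a core marker dropped
  expect_false("lost" %in% kept$marker_id)
  expect_false("weak" %in% kept$marker_id)
  expect_true(all(c("tc1", "tc2") %in% kept$marker_id))
  expect_equal(kept$pos_bp, sort(kept$pos_bp))
})

test_that("estimated chromosome length converges to simulated truth without noise", {
  cfg <- uniform_config(length_mb = 50, rr = 2, n_progeny = 1000,
                        markers = 12, seed = 17)
  ped <- simulate_pedigree(cfg)
  map <- build_map(ped$geno, ped$markers, "female", 1)
  mf <- marey_function(cfg$chromosomes[[1]])
  pos_mb <- map$positions$pos_bp / 1e6
  true_span_cm <- mf$g(max(pos_mb)) - mf$g(min(pos_mb))
  d_true <- diff(mf$g(sort(pos_mb)))
  r_true <- haldane_r(d_true)
  se <- sqrt(sum((100 / (1 - 2 * r_true))^2 * r_true * (1 - r_true) / 1000))
  expect_lt(abs(map$total_cm - true_span_cm), 3 * se)
})
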