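test_that("HSP grouping clusters by scaffold, strand and proximity", {
  one <- make_hsp("m1", "scf1", 99, 60, 1000, 1059)
  expect_length(group_hsps(one), 1)

  near <- rbind(make_hsp("m1", "scf1", 99, 60, 1000, 1059),
                make_hsp("m1", "scf1", 98, 40, 1160, 1199))
  expect_length(group_hsps(near, window_bp = 5000), 1)

  far <- rbind(make_hsp("m1", "scf1", 99, 60, 1000, 1059),
               make_hsp("m1", "scf1", 98, 40, 9000, 9039))
  expect_length(group_hsps(far, window_bp = 1000), 2)

  two_scaffolds <- rbind(make_hsp("m1", "scf1", 99, 60, 1000, 1059),
                         make_hsp("m1", "scf2", 99, 60, 1000, 1059))
  expect_length(group_hsps(two_scaffolds), 2)

  opposite_strands <- rbind(make_hsp("m1", "scf1", 99, 60, 1000, 1059),
                            make_hsp("m1", "scf1", 99, 60, 1100, 1041))
  expect_length(group_hsps(opposite_strands), 2)

  expect_length(group_hsps(make_hsp("x", "s", 99, 10, 1, 10)[0, ]), 0)

  # every HSP lands in exactly one locus
  set.seed(21)
  starts <- sample(1:50000, 30)
  hsps <- make_hsp("m1", sample(c("s1", "s2"), 30, TRUE), 95,
                   sample(30:80, 30, TRUE), starts, starts + 49)
  loci <- group_hsps(hsps, window_bp = 2000)
  expect_equal(sum(vapply(loci, nrow, integer(1))), 30)
})

test_that("CIP is the length-weighted identity and CALP the alignment coverage", {
  perfect <- make_hsp("m1", "scf1", 100, 500, 1, 500)
  sc <- score_locus(perfect, 500)
  expect_equal(sc$cip, 100)
  expect_equal(sc$calp, 100)

  # two HSPs (30 bp @ 90 %, 70 bp @ 100 %) on a 50 bp query:
  # CIP = 100 * (0.9*30 + 1.0*70) / 100 = 97; CALP = 100 * 100 / 50 = 200
  two <- rbind(make_hsp("m1", "scf1", 90, 30, 100, 129),
               make_hsp("m1", "scf1", 100, 70, 200, 269))
  sc <- score_locus(two, 50)
  expect_equal(sc$cip, 97)
  expect_equal(sc$calp, 200)

  # CIP invariant to HSP order, bounded in [0, 100]
  sc_rev <- score_locus(two[2:1, ], 50)
  expect_equal(sc_rev$cip, sc$cip)
  expect_true(sc$cip >= 0 && sc$cip <= 100)
})

test_that("anchor selection follows CIP, then CALP, then uniqueness", {
  # CALP cutoff is strictly greater-than 200
  over <- list(make_hsp("m1", "scf1", 99, 250, 1, 250))
  expect_equal(select_anchor(over, 100)$status, "rejected_calp")
  at_limit <- list(make_hsp("m1", "scf1", 99, 200, 1, 200))
  expect_equal(select_anchor(at_limit, 100)$status, "accepted")

  # higher CIP wins
  loci <- list(make_hsp("m1", "scf1", 98, 100, 1, 100),
               make_hsp("m1", "scf2", 95, 100, 1, 100))
  res <- select_anchor(loci, 100)
  expect_equal(res$status, "accepted")
  expect_equal(res$scaffold, "scf1")
  expect_equal(res$cip, 98)

  # exact tie without context: no unique location, rejected
  tied <- list(make_hsp("m1", "scf1", 98, 100, 1, 100),
               make_hsp("m1", "scf2", 98, 100, 5000, 5099))
  expect_equal(select_anchor(tied, 100)$status, "rejected_ambiguous")

  # tie broken by minimal implied RR when a context is available
  ctx <- function(scaffold, bp) if (scaffold == "scf2") 1.5 else 30
  res <- select_anchor(tied, 100, rr_context = ctx)
  expect_equal(res$status, "accepted")
  expect_equal(res$scaffold, "scf2")

  # deterministic: repeated calls agree
  expect_identical(select_anchor(loci, 100), select_anchor(loci, 100))
})

test_that("anchor position is the minimum subject coordinate, strand-aware", {
  minus <- list(make_hsp("m1", "scf1", 99, 60, 1159, 1100))
  res <- select_anchor(minus, 60)
  expect_equal(res$anchor_bp, 1100)
  expect_equal(res$strand, "-")
})

test_that("redundancy removal keeps one representative per alignment component", {
  ids <- c("A", "B", "C")
  none <- data.frame(qseqid = character(0), sseqid = character(0),
                     length = numeric(0), evalue = numeric(0))
  res <- remove_redundant(none, ids)
  expect_false(any(res$redundant))

  ab <- data.frame(qseqid = "A", sseqid = "B", length = 60, evalue = 1e-60)
  res <- remove_redundant(ab, ids)
  expect_equal(sort(res$marker_id[!res$redundant]), c("A", "C"))

  chain <- data.frame(qseqid = c("A", "B"), sseqid = c("B", "C"),
                      length = c(60, 55), evalue = c(1e-60, 1e-80))
  res <- remove_redundant(chain, ids)
  expect_equal(res$marker_id[!res$redundant], "A")
  expect_equal(unique(res$representative), "A")

  # edges below threshold (short alignment or weak e-value) are ignored
  weak <- data.frame(qseqid = c("A", "B"), sseqid = c("B", "C"),
                     length = c(40, 60), evalue = c(1e-60, 1e-10))
  res <- remove_redundant(weak, ids)
  expect_false(any(res$redundant))
})

test_that("BLAST tabular reader validates shape and derives strand", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("m1\tscf1\t99.0\t60\t0\t0\t1\t60\t1000\t1059\t1e-60\t120",
               "m2\tscf2\t95.5\t50\t2\t0\t1\t50\t900\t851\t1e-55\t90"), path)
  hsps <- read_blast_tab(path)
  expect_equal(nrow(hsps), 2)
  expect_equal(hsps$strand, c("+", "-"))

  writeLines(c("m1\tscf1\t99.0\t60\t0\t0\t1\t60\t1000\t1059\t1e-60\t120",
               "m2\tscf1\tbroken"), path)
  expect_error(read_blast_tab(path), "line 2")

  writeLines(character(0), path)
  expect_equal(nrow(read_blast_tab(path)), 0)
})

test_that("anchor TSV and BED exports agree up to the coordinate convention", {
  anchors <- anchor_markers(make_hsp("m1", "scf1", 100, 80, 501, 580),
                            c(m1 = 80))
  expect_equal(anchors$status, "accepted")
  tsv <- tempfile(); bed <- tempfile()
  write_anchor_tsv(anchors, tsv)
  write_anchor_bed(anchors, bed)
  tsv_in <- utils::read.delim(tsv)
  bed_in <- utils::read.delim(bed, header = FALSE)
  expect_equal(tsv_in$anchor_bp, 501)          # 1-based inclusive
  expect_equal(bed_in$V2, 500)                 # 0-based half-open start
  expect_equal(bed_in$V3, 501)
})
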