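# Paired-end pipeline: terminal-overlap detection/trimming and junction
# confirmation by read pairs.

test_that("terminal overlap detection matches worked examples", {
  th4 <- thresholds(min_terminal_overlap = 4)
  expect_equal(find_terminal_overlap("ATGCCGTTAAGCATGCC", th4), 5L)
  th2 <- thresholds(min_terminal_overlap = 2)
  expect_true(is.na(find_terminal_overlap("AAAATTTT", th2)))
  # k = 6 would also match but is excluded by the half-length cap
  expect_equal(find_terminal_overlap("ATATATAT", th2), 4L)
  # too short: skipped, not an error
  expect_true(is.na(find_terminal_overlap("ACGT", thresholds())))
})

test_that("terminal overlap agrees with the all-k brute-force oracle", {
  set.seed(41)
  th <- thresholds(min_terminal_overlap = 10)
  for (i in 1:200) {
    dup <- sample(0:60, 1)
    s <- planted_overlap_contig(sample(150:400, 1), dup)
    expect_identical(find_terminal_overlap(s, th),
                     oracle_terminal_overlap(s, 10L), info = paste("case", i))
  }
})

test_that("trimming removes exactly the duplication", {
  expect_equal(trim_terminal_overlap("ATGCCGTTAAGCATGCC", 5), "ATGCCGTTAAGC")
  expect_equal(nchar(trim_terminal_overlap("ATGCCGTTAAGCATGCC", 5)), 12L)
  expect_equal(trim_terminal_overlap("ACGT", 0), "ACGT")
  expect_error(trim_terminal_overlap("ACGT", 4), "smaller")
})

test_that("pair junction support encodes window, orientation and length rules", {
  th <- thresholds()
  plus <- function(s, e) list(contig_id = "c", start = s, end = e, strand = "+",
                              aligned_len = e - s)
  minus <- function(s, e) list(contig_id = "c", start = s, end = e, strand = "-",
                               aligned_len = e - s)
  expect_true(pair_supports_junction(3000, plus(2600, 2700), minus(100, 190), th))
  # either argument order
  expect_true(pair_supports_junction(3000, minus(100, 190), plus(2600, 2700), th))
  # + mate too far from the end (must sit within the last 500 nt)
  expect_false(pair_supports_junction(3000, plus(2300, 2400), minus(100, 190), th))
  # 85 nt mate violates the 90 nt minimum mapping
  expect_false(pair_supports_junction(3000, plus(2610, 2695), minus(100, 190), th))
  # wrong orientation: both plus
  expect_false(pair_supports_junction(3000, plus(2600, 2700), plus(100, 190), th))
  # mate overlapping the window boundary is rejected outright
  expect_false(pair_supports_junction(3000, plus(2450, 2550), minus(100, 190), th))
  other <- minus(1, 100); other$contig_id <- "other"
  expect_error(pair_supports_junction(3000, plus(1, 100), other),
               "different contigs")
})

test_that("paired-end round trip recovers simulated circles exactly", {
  sim <- simulate_metamobilome(sim_config(n_circles = 6, n_linear = 4,
                                          length_range = c(1100, 3000),
                                          sub_rate = 0, seed = 51))
  det <- detect_circular_pe(sim$contigs, reads = sim$pe_reads)
  truth <- sim$truth[sim$truth$class == "circle" & grepl("^pe_", sim$truth$contig_id), ]
  expect_setequal(det$id, truth$contig_id)
  expect_setequal(det$canonical_seq, canonical_rotation(unname(sim$circles)))
  expect_equal(det$overlap_trimmed,
               truth$dup_len[match(det$id, truth$contig_id)])
  expect_true(all(det$n_supporting_pairs >= 1))
  f <- glance(det)
  expect_equal(f$pe_confirmed, 6L)
  expect_equal(f$input, 10L)
})

test_that("sub-minimum contigs are dropped by the length filter", {
  circ <- simulate_circle(900, seed = 7)
  mda <- make_mda_contig(circ, 60, 0, id = "small")
  det <- detect_circular_pe(
    mda$contig,
    alignments = data.frame(contig_id = character(0), pair_id = character(0),
                            mate = integer(0), start = integer(0),
                            end = integer(0), strand = character(0))
  )
  expect_equal(nrow(det), 0L)
  f <- attr(det, "funnel")
  expect_equal(f$count[f$stage == "length_pass"], 0L)
  expect_match(attr(det, "skipped")$reason[1], "min_contig_len_pe")
})

test_that("a 1 nt indel inside one terminal copy defeats step one", {
  set.seed(61)
  for (i in 1:5) {
    circ <- simulate_circle(1500 + 100 * i)
    mda <- make_mda_contig(circ, 80, 0, id = "x")
    seq <- mda$contig$seq
    L <- nchar(seq)
    # edit inside the duplicated terminal copy, away from its edges
    pos <- L - 40L
    broken <- if (i %% 2 == 0) indel_base(seq, pos, "del") else indel_base(seq, pos, "ins")
    expect_true(is.na(find_terminal_overlap(broken, thresholds())))
  }
})

test_that("detection demands evidence and known contig ids", {
  circ <- simulate_circle(1500, seed = 8)
  mda <- make_mda_contig(circ, 60, 0, id = "c1")
  expect_error(detect_circular_pe(mda$contig), "reads.*alignments")
  bad_aln <- data.frame(contig_id = "ghost", pair_id = "p1", mate = 1L,
                        start = 0L, end = 100L, strand = "+")
  expect_error(detect_circular_pe(mda$contig, alignments = bad_aln), "unknown contig")
})

test_that("zero supporting pairs means no call even after a perfect overlap", {
  circ <- simulate_circle(2000, seed = 9)
  mda <- make_mda_contig(circ, 70, 0, id = "c1")
  empty <- data.frame(contig_id = character(0), pair_id = character(0),
                      mate = integer(0), start = integer(0), end = integer(0),
                      strand = character(0))
  det <- detect_circular_pe(mda$contig, alignments = empty)
  expect_equal(nrow(det), 0L)
  f <- attr(det, "funnel")
  expect_equal(f$count[f$stage == "overlap_pass"], 1L)
  expect_equal(f$count[f$stage == "pe_confirmed"], 0L)
})
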