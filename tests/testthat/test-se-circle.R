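# Single-end pipeline: junction windows, spanning reads, uniqueness screen.

test_that("junction window is suffix + prefix with the right length", {
  th <- thresholds()
  s <- simulate_circle(1500, seed = 1)
  w <- build_junction_window(s, th)
  expect_equal(nchar(w), 200L)
  expect_equal(w, paste0(substr(s, 1401, 1500), substr(s, 1, 100)))
  th3 <- thresholds(se_end_window = 3, se_min_span_per_side = 3)
  expect_equal(build_junction_window("ACGTTGCA", th3), "GCAACG")
  expect_true(is.na(build_junction_window(strrep("A", 199), th)))
})

test_that("span test applies identity, gap and per-side coverage rules", {
  th <- thresholds()
  # full window, 2 mismatches: identity 99% >= 98, 100 nt per side
  expect_true(read_spans_junction(
    data.frame(window_start = 0, window_end = 200, identity = 99, gapped = FALSE), th))
  # left span 95 < 99
  expect_false(read_spans_junction(
    data.frame(window_start = 5, window_end = 200, identity = 100, gapped = FALSE), th))
  # gapped alignment fails unless gaps are allowed
  aln <- data.frame(window_start = 0, window_end = 200, identity = 100, gapped = TRUE)
  expect_false(read_spans_junction(aln, th))
  expect_true(read_spans_junction(aln, thresholds(se_allow_gaps = TRUE)))
  # identity below threshold: ceil(0.02 * 200) + 1 = 5 mismatches -> 97.5%
  expect_false(read_spans_junction(
    data.frame(window_start = 0, window_end = 200, identity = 100 * 195 / 200,
               gapped = FALSE), th))
  expect_error(read_spans_junction(
    data.frame(window_start = 100, window_end = 50, identity = 100, gapped = FALSE), th),
    "greater")
})

test_that("window aligner agrees with the exhaustive diagonal oracle", {
  set.seed(71)
  for (i in 1:60) {
    win <- planted_overlap_contig(200, 0L)
    # reads overlapping the window at a random offset, with noise
    d <- sample(-150:150, 1)
    read <- planted_overlap_contig(sample(120:400, 1), 0L)
    ws <- max(0, -d); we <- min(200, nchar(read) - d)
    if (we - ws > 30) {
      # plant the window segment into the read so a clear diagonal exists
      substr(read, d + ws + 1, d + we) <- substr(win, ws + 1, we)
    }
    got <- align_read_to_window(read, win)
    exp <- oracle_window_align(read, win)
    expect_equal(got$matches, exp$matches, info = paste("case", i))
    expect_equal(got$window_start, exp$window_start, info = paste("case", i))
    expect_equal(got$window_end, exp$window_end, info = paste("case", i))
  }
})

test_that("uniqueness screen flags windows duplicated within one record", {
  win <- simulate_circle(200, seed = 2)
  pad <- function(...) paste0(...)
  x <- simulate_circle(300, seed = 3); y <- simulate_circle(250, seed = 4)
  dup_rec <- pad(x, win, y, win, x)
  single_rec <- pad(x, win, y)
  expect_false(junction_uniqueness_screen(win, dup_rec))
  expect_true(junction_uniqueness_screen(win, single_rec))
  expect_true(junction_uniqueness_screen(win, character(0)))
  # two occurrences on opposite strands still count
  rc_rec <- pad(x, win, y, dna_revcomp(win), x)
  expect_false(junction_uniqueness_screen(win, rc_rec))
  # spread over two records: each record clean
  expect_true(junction_uniqueness_screen(win, c(pad(x, win), pad(y, win))))
})

test_that("single-end round trip detects circles and not linears", {
  sim <- simulate_metamobilome(sim_config(n_circles = 5, n_linear = 4,
                                          length_range = c(1100, 2500),
                                          sub_rate = 0, se_indel_rate = 0,
                                          seed = 81))
  det <- detect_circular_se(sim$se_contigs, reads = sim$se_reads)
  truth_ids <- sim$truth$contig_id[sim$truth$class == "circle" &
                                     grepl("^se_", sim$truth$contig_id)]
  expect_setequal(det$id, truth_ids)
  expect_setequal(det$canonical_seq, canonical_rotation(unname(sim$circles)))
  expect_true(all(det$overlap_trimmed == 0L))
  expect_true(all(det$n_spanning_reads >= 1L))
  expect_true(all(det$uniqueness_clean))
})

test_that("150 nt reads cannot satisfy the two-sided 99 nt span", {
  circ <- simulate_circle(1500, seed = 9)
  contig <- data.frame(id = "c1", seq = circ)
  reads <- simulate_se_reads(circ, coverage = 30, len_mean = 150, len_sd = 0,
                             sub_rate = 0, indel_rate = 0, seed = 10)
  det <- detect_circular_se(contig, reads = reads)
  expect_equal(nrow(det), 0L)
})

test_that("pre-computed window alignments are honoured", {
  circ <- simulate_circle(1200, seed = 12)
  contig <- data.frame(id = "c1", seq = circ)
  wa <- data.frame(contig_id = "c1", read_id = "r1", window_start = 0L,
                   window_end = 200L, identity = 100, gapped = FALSE)
  det <- detect_circular_se(contig, window_alignments = wa)
  expect_equal(det$id, "c1")
  expect_equal(det$n_spanning_reads, 1L)
  wa_bad <- transform(wa, contig_id = "ghost")
  expect_error(detect_circular_se(contig, window_alignments = wa_bad), "unknown")
})

test_that("duplicate contig ids are rejected", {
  expect_error(
    detect_circular_se(data.frame(id = c("a", "a"),
                                  seq = c(strrep("ACGT", 100), strrep("ACGT", 100))),
                       reads = data.frame(read_id = "r", seq = "ACGT")),
    "duplicate")
})
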