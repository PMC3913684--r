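# Virtual inverse PCR: primer regions, product prediction, capped-edit
# binding search, mispriming screen on doubled templates.

test_that("primer regions respect the junction buffer", {
  s <- simulate_circle(3000, seed = 1)
  reg <- propose_primer_regions(s, primer_len = 20, junction_buffer = 150)
  expect_equal(reg$region, c("rev", "fwd"))
  expect_true(all(reg$start >= 150))
  expect_true(all(reg$end <= 3000 - 150))
  expect_true(reg$end[reg$region == "rev"] <= reg$start[reg$region == "fwd"])
  expect_error(propose_primer_regions(simulate_circle(300, seed = 2)),
               "too short.*342")
  # degenerate but allowed: zero buffer
  reg0 <- propose_primer_regions(simulate_circle(500, seed = 2),
                                 junction_buffer = 0)
  expect_equal(reg0$start[1], 0L)
})

test_that("predicted product length counts both arms across the junction", {
  expect_equal(predicted_inverse_product_len(100, 80, 30), 51L)
  # back-to-back 20-mers: product is exactly the two primers
  expect_equal(predicted_inverse_product_len(1000, 980, 19), 40L)
  expect_equal(predicted_inverse_product_len(100, 99, 0), 2L)
  expect_error(predicted_inverse_product_len(100, 30, 80), "rev_5prime < fwd_5prime")
})

test_that("product predictions are rotation-invariant", {
  set.seed(101)
  L <- 2000L
  for (i in 1:10) {
    fwd <- sample(1000:1990, 1); rev <- sample(0:990, 1)
    len0 <- predicted_inverse_product_len(L, fwd, rev)
    k <- sample(0:(L - 1), 1)
    # rotating the linearization origin by k moves both primers by -k mod L;
    # when both stay on the same side order the prediction is unchanged
    f2 <- (fwd - k) %% L; r2 <- (rev - k) %% L
    if (r2 < f2 && f2 < L) {
      expect_equal(predicted_inverse_product_len(L, f2, r2) %% L, len0 %% L)
    }
  }
})

test_that("binding search matches exact, single-edit and rejected sites", {
  th <- thresholds()
  set.seed(111)
  tpl <- planted_overlap_contig(400, 0L)
  primer <- substr(tpl, 101, 120)
  h <- find_primer_bindings(primer, tpl, th)
  h <- h[h$strand == "+", ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 100L)
  expect_equal(c(h$mm, h$ins, h$del), c(0L, 0L, 0L))
  # reverse-strand hit
  hrc <- find_primer_bindings(dna_revcomp(primer), tpl, th)
  expect_true(any(hrc$strand == "-" & hrc$start == 100L))
  # one substitution: accepted as (1,0,0)
  t1 <- mutate_base(tpl, 110)
  h1 <- find_primer_bindings(primer, t1, th)
  expect_true(any(h1$mm == 1 & h1$ins == 0 & h1$del == 0))
  # two substitutions: rejected
  t2 <- mutate_base(t1, 115)
  expect_equal(nrow(find_primer_bindings(primer, t2, th)), 0L)
  # one deletion / one insertion in the site: accepted
  hd <- find_primer_bindings(primer, indel_base(tpl, 110, "del"), th)
  expect_true(any(hd$del == 1))
  hi <- find_primer_bindings(primer, indel_base(tpl, 110, "ins", "C"), th)
  expect_true(any(hi$ins == 1))
  # primer longer than template: empty, not an error
  expect_equal(nrow(find_primer_bindings(strrep("ACGT", 10), "ACGTACGT", th)), 0L)
})

test_that("binding search agrees with the scalar DP oracle", {
  th <- thresholds()
  set.seed(121)
  for (i in 1:40) {
    tpl <- planted_overlap_contig(sample(80:250, 1), 0L)
    m <- sample(15:25, 1)
    pos <- sample(1:(nchar(tpl) - m), 1)
    primer <- substr(tpl, pos, pos + m - 1L)
    n_ed <- sample(0:3, 1)
    t2 <- tpl
    for (e in seq_len(n_ed)) {
      p <- pos + sample(2:(m - 2), 1)
      t2 <- switch(sample(c("mm", "ins", "del"), 1),
                   mm = mutate_base(t2, p),
                   ins = indel_base(t2, p, "ins", sample(c("A", "C", "G", "T"), 1)),
                   del = indel_base(t2, p, "del"))
    }
    got <- find_primer_bindings(primer, t2, th)
    got <- got[got$strand == "+", ]
    exp <- oracle_primer_binding(primer, t2)
    expect_equal(nrow(got) > 0L, exp$any_hit, info = paste("case", i))
    if (exp$any_hit && nrow(got) > 0L) {
      expect_equal(min(got$mm + got$ins + got$del), exp$best_total,
                   info = paste("case", i))
    }
  }
})

test_that("virtual PCR passes on its own element and fails on a decoy", {
  th <- thresholds()
  el <- simulate_circle(1500, seed = 31)
  pr <- design_outward_primers(el, "E1")
  scr <- virtual_pcr_screen(pr, data.frame(id = "E1", seq = el), th)
  expect_true(scr$pass)
  expect_equal(scr$amplicons$product_len, scr$predicted_len)
  expect_equal(scr$predicted_len,
               predicted_inverse_product_len(1500, pr$fwd_5prime, pr$rev_5prime))
  # second contig carrying both sites convergently -> two amplicons -> fail
  decoy <- paste0(simulate_circle(300, seed = 32), pr$fwd_seq,
                  simulate_circle(200, seed = 33), dna_revcomp(pr$rev_seq),
                  simulate_circle(300, seed = 34))
  scr2 <- virtual_pcr_screen(pr, data.frame(id = c("E1", "D"), seq = c(el, decoy)), th)
  expect_false(scr2$pass)
  expect_equal(nrow(scr2$amplicons), 2L)
  # primers that bind nowhere: empty amplicon list, fail
  scr3 <- virtual_pcr_screen(
    data.frame(element_id = "E1", fwd_seq = strrep("A", 20),
               rev_seq = strrep("C", 20), fwd_5prime = 1000L, rev_5prime = 100L),
    data.frame(id = "E1", seq = el), th)
  expect_false(scr3$pass)
  expect_equal(nrow(scr3$amplicons), 0L)
})

test_that("short contigs are excluded from the mispriming database", {
  th <- thresholds()
  el <- simulate_circle(1500, seed = 41)
  pr <- design_outward_primers(el, "E1")
  # a 200 nt decoy carrying the fwd site is below the >200 nt template rule
  tiny <- paste0(substr(simulate_circle(200, seed = 42), 1, 180), pr$fwd_seq)
  expect_equal(nchar(tiny), 200L)
  scr <- virtual_pcr_screen(pr, data.frame(id = c("E1", "tiny"),
                                           seq = c(el, tiny)), th)
  expect_true(scr$pass)
})

test_that("doubled templates equal explicit rotation enumeration", {
  th <- thresholds()
  set.seed(131)
  for (i in 1:12) {
    L <- sample(250:400, 1)
    el <- planted_overlap_contig(L, 0L)
    pr <- design_outward_primers(el, "E", primer_len = 18, junction_buffer = 60)
    scr <- virtual_pcr_screen(pr, data.frame(id = "E", seq = el), th)
    # oracle: exact occurrences of both sites on every rotation, products
    # fully inside the rotated linear sequence
    prods <- integer(0)
    fwd <- pr$fwd_seq; rvc <- dna_revcomp(pr$rev_seq)
    for (k in 0:(L - 1)) {
      rot <- rotate_seq(el, k)
      fpos <- gregexpr(fwd, rot, fixed = TRUE)[[1]]
      rpos <- gregexpr(rvc, rot, fixed = TRUE)[[1]]
      if (fpos[1] == -1 || rpos[1] == -1) next
      for (fp in fpos) for (rp in rpos) {
        q <- rp + nchar(rvc) - 1L
        if (q > fp) prods <- c(prods, q - fp + 1L)
      }
    }
    expect_true(scr$pass, info = paste("case", i))
    expect_equal(sort(unique(prods[prods <= L])),
                 sort(unique(scr$amplicons$product_len)), info = paste("case", i))
  }
})
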