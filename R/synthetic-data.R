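# Synthetic metamobilome generator. Emulates the sequencing geometry the
# detection pipelines were designed for -- small circular plasmids (1--13 kb)
# MDA-amplified and assembled into contigs with ~40-100 nt terminal
# duplication, 100 nt paired-end reads from 450--550 nt inserts, and ~400 nt
# single-end reads -- so every stage can be tested at desk scale against
# known truth.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: circle lengths uniform
#' on 1,000--13,000 nt, GC 0.45, terminal duplications of 40--100 nt
#' (rolling-circle linearization artefacts), 100 nt paired-end reads from
#' 450--550 nt inserts at 20x, single-end read lengths ~N(400, 80) at 10x,
#' and a 0.001 per-base substitution rate.
#'
#' @param n_circles,n_linear,n_repeat_confounded Numbers of true circles,
#'   plain linear contigs, and linear contigs carrying an interspersed
#'   repeat (see [make_negative_controls()]).
#' @param length_range,gc,dup_len_range Circle/contig geometry.
#' @param pe_read_len,insert_range,pe_coverage Paired-end read geometry.
#' @param se_len_mean,se_len_sd,se_coverage Single-end read geometry.
#' @param sub_rate Per-base substitution error rate (both platforms).
#' @param se_indel_rate Per-base indel rate for single-end reads only.
#' @param repeat_len Interspersed-repeat length for confounded contigs; must
#'   exceed `pe_read_len`.
#' @param mda_skew Range of the log-uniform per-circle coverage multiplier
#'   emulating MDA copy-number skew; `c(1, 1)` disables it.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_circles = 20L, n_linear = 20L, n_repeat_confounded = 0L,
                       length_range = c(1000L, 13000L), gc = 0.45,
                       dup_len_range = c(40L, 100L),
                       pe_read_len = 100L, insert_range = c(450L, 550L),
                       pe_coverage = 20, se_len_mean = 400, se_len_sd = 80,
                       se_coverage = 10, sub_rate = 0.001, se_indel_rate = 2e-4,
                       repeat_len = 300L, mda_skew = c(1, 1), seed = NULL) {
  cfg <- list(n_circles = as.integer(n_circles), n_linear = as.integer(n_linear),
              n_repeat_confounded = as.integer(n_repeat_confounded),
              length_range = as.integer(length_range), gc = as.numeric(gc),
              dup_len_range = as.integer(dup_len_range),
              pe_read_len = as.integer(pe_read_len),
              insert_range = as.integer(insert_range),
              pe_coverage = as.numeric(pe_coverage),
              se_len_mean = as.numeric(se_len_mean), se_len_sd = as.numeric(se_len_sd),
              se_coverage = as.numeric(se_coverage),
              sub_rate = as.numeric(sub_rate), se_indel_rate = as.numeric(se_indel_rate),
              repeat_len = as.integer(repeat_len), mda_skew = as.numeric(mda_skew),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (any(diff(cfg$length_range) < 0) || any(diff(cfg$dup_len_range) < 0) ||
      any(diff(cfg$insert_range) < 0)) {
    abort("ranges must be non-empty (low <= high).")
  }
  if (cfg$gc < 0 || cfg$gc > 1 || cfg$sub_rate < 0 || cfg$sub_rate > 1) {
    abort("`gc` and `sub_rate` must be in [0, 1].")
  }
  structure(cfg, class = "sim_config")
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Simulate one circular sequence
#'
#' @param length Circle length (nt, >= 1).
#' @param gc Target GC fraction.
#' @param seed Optional integer seed for reproducibility.
#' @return A DNA string.
#' @export
simulate_circle <- function(length, gc = 0.45, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) abort("`length` must be >= 1.")
  with_opt_seed(seed, random_dna(length, gc))
}

#' Linearize a circle the way MDA + assembly does
#'
#' Rolling-circle amplification turns a circle into linear concatemers; the
#' assembled contig is a rotation of the circle carrying a duplication of
#' its own first `dup_len` bases at the end:
#' `rotate(circle, offset) + prefix(rotate(circle, offset), dup_len)`.
#'
#' @param circle Circle sequence.
#' @param dup_len Terminal duplication length (0 <= dup_len <= circle
#'   length).
#' @param rotation_offset Linearization origin (0 <= offset < circle
#'   length).
#' @param id Contig id recorded in both outputs.
#' @return List with `contig` (one-row tibble: `id`, `seq`) and `truth`
#'   (one-row tibble: `contig_id`, `is_circular`, `true_circle_len`,
#'   `dup_len`, `rotation_offset`, `class`).
#' @examples
#' make_mda_contig("ATGCCGTTAAGC", 5, 0)$contig$seq  # "ATGCCGTTAAGCATGCC"
#' @export
make_mda_contig <- function(circle, dup_len, rotation_offset = 0L, id = "contig_1") {
  assert_dna(circle, "circle")
  L <- str_length(circle)
  dup_len <- as.integer(dup_len); rotation_offset <- as.integer(rotation_offset)
  if (dup_len < 0L || dup_len > L) abort("`dup_len` must be in [0, circle length].")
  if (rotation_offset < 0L || rotation_offset >= L) {
    abort("`rotation_offset` must be in [0, circle length).")
  }
  rot <- rotate_seq(circle, rotation_offset)
  seq <- paste0(rot, str_sub(rot, 1L, dup_len))
  list(
    contig = tibble(id = id, seq = seq),
    truth = tibble(contig_id = id, is_circular = TRUE, true_circle_len = L,
                   dup_len = dup_len, rotation_offset = rotation_offset,
                   class = "circle")
  )
}

# Apply substitution errors in place; sub_rate per base.
apply_substitutions <- function(seqs, sub_rate) {
  if (sub_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, sub_rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1L), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

apply_indels <- function(seqs, indel_rate) {
  if (indel_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, indel_rate)
    if (k == 0L) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (p in sort(sample.int(length(ch), min(k, length(ch))), decreasing = TRUE)) {
      if (runif(1) < 0.5 && length(ch) > 1L) {
        ch <- ch[-p]
      } else {
        ch <- append(ch, sample(bases, 1L), after = p)
      }
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired-end reads from a circular template
#'
#' Fragments are drawn uniformly on the circle (wrapping the origin), with
#' insert sizes uniform on `insert_range`; the two mates are the fragment's
#' first and last `pe_read_len` bases, the second reverse-complemented
#' (forward--reverse library). The expected fraction of junction-spanning
#' fragments is about `mean(insert) / circle length`.
#'
#' @param circle Circle sequence (must be longer than the largest insert).
#' @param coverage Target nucleotide coverage.
#' @param pe_read_len Read length.
#' @param insert_range Insert (fragment) length range.
#' @param sub_rate Per-base substitution rate.
#' @param seed Optional seed.
#' @param prefix Pair-id prefix.
#' @param circular Set `FALSE` to sample fragments without wrapping (for
#'   linear contigs).
#' @return Tibble: `pair_id`, `mate` (1/2), `seq`.
#' @export
simulate_pe_reads <- function(circle, coverage = 20, pe_read_len = 100L,
                              insert_range = c(450L, 550L), sub_rate = 0.001,
                              seed = NULL, prefix = "frag", circular = TRUE) {
  assert_dna(circle, "circle")
  L <- str_length(circle)
  if (L <= max(insert_range)) abort("template shorter than the largest insert.")
  with_opt_seed(seed, {
    n_frag <- max(1L, as.integer(ceiling(coverage * L / (2 * pe_read_len))))
    ins <- sample.int(insert_range[2] - insert_range[1] + 1L, n_frag, replace = TRUE) +
      insert_range[1] - 1L
    start <- if (circular) {
      sample.int(L, n_frag, replace = TRUE) - 1L
    } else {
      vapply(ins, function(x) sample.int(L - x + 1L, 1L) - 1L, integer(1))
    }
    tmpl <- if (circular) paste0(circle, circle) else circle
    frag <- str_sub(tmpl, start + 1L, start + ins)
    r1 <- str_sub(frag, 1L, pe_read_len)
    r2 <- dna_revcomp(str_sub(frag, str_length(frag) - pe_read_len + 1L, str_length(frag)))
    r1 <- apply_substitutions(r1, sub_rate)
    r2 <- apply_substitutions(r2, sub_rate)
    ids <- sprintf("%s_%05d", prefix, seq_len(n_frag))
    tibble(pair_id = rep(ids, 2L), mate = rep(c(1L, 2L), each = n_frag),
           seq = c(r1, r2))
  })
}

#' Simulate single-end reads
#'
#' Read lengths are normal(`len_mean`, `len_sd`) truncated below at 50 nt;
#' start positions uniform on the template, wrapping the origin when
#' `circular`. Errors: substitutions at `sub_rate` plus rare indels at
#' `indel_rate` (long-read chemistry).
#'
#' @param template Template sequence.
#' @param coverage Target nucleotide coverage.
#' @param len_mean,len_sd Read length distribution (nt).
#' @param sub_rate,indel_rate Error rates.
#' @param seed Optional seed.
#' @param prefix Read-id prefix.
#' @param circular Wrap the origin when sampling.
#' @return Tibble: `read_id`, `seq`.
#' @export
simulate_se_reads <- function(template, coverage = 10, len_mean = 400,
                              len_sd = 80, sub_rate = 0.001, indel_rate = 2e-4,
                              seed = NULL, prefix = "seread", circular = TRUE) {
  assert_dna(template, "template")
  L <- str_length(template)
  with_opt_seed(seed, {
    n_reads <- max(1L, as.integer(ceiling(coverage * L / len_mean)))
    lens <- pmax(50L, pmin(as.integer(round(rnorm(n_reads, len_mean, len_sd))),
                           if (circular) L else L))
    start <- if (circular) {
      sample.int(L, n_reads, replace = TRUE) - 1L
    } else {
      vapply(lens, function(x) sample.int(max(L - x + 1L, 1L), 1L) - 1L, integer(1))
    }
    tmpl <- if (circular) paste0(template, template) else template
    seqs <- str_sub(tmpl, start + 1L, start + lens)
    seqs <- apply_substitutions(seqs, sub_rate)
    seqs <- apply_indels(seqs, indel_rate)
    strand <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
    seqs[strand] <- dna_revcomp(seqs[strand])
    tibble(read_id = sprintf("%s_%05d", prefix, seq_len(n_reads)), seq = seqs)
  })
}

#' Negative-control contigs
#'
#' `n_linear` plain linear contigs (no terminal duplication) and
#' `n_repeat_confounded` linear contigs carrying two interspersed copies of
#' a repeat longer than a read, placed away from the termini -- the
#' configuration in which short-read assemblers fail on repeats and which a
#' circularity detector must not mistake for a circle.
#'
#' @param n_linear,n_repeat_confounded Counts.
#' @param repeat_len Repeat length (must exceed `pe_read_len`).
#' @param length_range,gc Contig geometry.
#' @param pe_read_len Read length the repeat must exceed.
#' @param seed Optional seed.
#' @param id_prefix Prefixes for the two classes.
#' @return List with `contigs` (tibble `id`, `seq`) and `truth`.
#' @export
make_negative_controls <- function(n_linear, n_repeat_confounded = 0L,
                                   repeat_len = 300L,
                                   length_range = c(1000L, 13000L), gc = 0.45,
                                   pe_read_len = 100L, seed = NULL,
                                   id_prefix = c("lin", "rep")) {
  n_linear <- as.integer(n_linear)
  n_repeat_confounded <- as.integer(n_repeat_confounded)
  if (n_repeat_confounded > 0L && repeat_len <= pe_read_len) {
    abort("`repeat_len` must exceed `pe_read_len` to model the repeat failure mode.")
  }
  with_opt_seed(seed, {
    contigs <- list(); truth <- list()
    for (i in seq_len(n_linear)) {
      L <- sample.int(length_range[2] - length_range[1] + 1L, 1L) + length_range[1] - 1L
      id <- sprintf("%s%03d", id_prefix[1], i)
      contigs[[length(contigs) + 1L]] <- tibble(id = id, seq = random_dna(L, gc))
      truth[[length(truth) + 1L]] <- tibble(contig_id = id, is_circular = FALSE,
                                            true_circle_len = NA_integer_, dup_len = 0L,
                                            rotation_offset = NA_integer_, class = "linear")
    }
    for (i in seq_len(n_repeat_confounded)) {
      Lmin <- max(length_range[1], 4L * repeat_len)
      L <- sample.int(max(length_range[2] - Lmin + 1L, 1L), 1L) + Lmin - 1L
      base <- random_dna(L, gc)
      rep_unit <- random_dna(repeat_len, gc)
      # two interior copies, separated, away from both termini
      p1 <- as.integer(round(L * 0.2))
      p2 <- as.integer(round(L * 0.6))
      ch <- base
      substr(ch, p1 + 1L, p1 + repeat_len) <- rep_unit
      substr(ch, p2 + 1L, p2 + repeat_len) <- rep_unit
      id <- sprintf("%s%03d", id_prefix[2], i)
      contigs[[length(contigs) + 1L]] <- tibble(id = id, seq = ch)
      truth[[length(truth) + 1L]] <- tibble(contig_id = id, is_circular = FALSE,
                                            true_circle_len = NA_integer_, dup_len = 0L,
                                            rotation_offset = NA_integer_,
                                            class = "repeat_confounded")
    }
    list(contigs = bind_rows(contigs), truth = bind_rows(truth))
  })
}

#' Simulate a complete synthetic metamobilome experiment
#'
#' Generates circles, their MDA-linearized paired-end contigs (with terminal
#' duplication), single-end contigs (plain rotations of the same circles at
#' a different origin), negative controls, and reads for every contig on
#' both platforms. Circle coverage is `pe_coverage`/`se_coverage` times an
#' optional log-uniform MDA skew multiplier.
#'
#' @param config A [sim_config()].
#' @return List: `circles` (named character), `contigs` (paired-end contig
#'   table incl. negatives), `se_contigs`, `pe_reads`, `se_reads`, `truth`
#'   (one row per emitted contig, across both tables).
#' @export
simulate_metamobilome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_opt_seed(config$seed, {
    nc <- config$n_circles
    circ_len <- sample.int(config$length_range[2] - config$length_range[1] + 1L,
                           nc, replace = TRUE) + config$length_range[1] - 1L
    circles <- setNames(
      vapply(circ_len, function(L) random_dna(L, config$gc), character(1)),
      sprintf("circle%03d", seq_len(nc))
    )
    skew <- exp(runif(nc, log(config$mda_skew[1]), log(config$mda_skew[2])))

    pe_contigs <- list(); se_contigs <- list(); truth <- list()
    pe_reads <- list(); se_reads <- list()
    for (i in seq_len(nc)) {
      L <- circ_len[i]
      dup <- sample.int(config$dup_len_range[2] - config$dup_len_range[1] + 1L, 1L) +
        config$dup_len_range[1] - 1L
      off_pe <- sample.int(L, 1L) - 1L
      mda <- make_mda_contig(circles[[i]], dup, off_pe, id = sprintf("pe_circ%03d", i))
      pe_contigs[[i]] <- mda$contig
      truth[[length(truth) + 1L]] <- mda$truth

      off_se <- sample.int(L, 1L) - 1L
      se_id <- sprintf("se_circ%03d", i)
      se_contigs[[i]] <- tibble(id = se_id, seq = rotate_seq(circles[[i]], off_se))
      truth[[length(truth) + 1L]] <- tibble(contig_id = se_id, is_circular = TRUE,
                                            true_circle_len = L, dup_len = 0L,
                                            rotation_offset = off_se, class = "circle")

      pe_reads[[i]] <- simulate_pe_reads(circles[[i]], coverage = config$pe_coverage * skew[i],
                                         pe_read_len = config$pe_read_len,
                                         insert_range = config$insert_range,
                                         sub_rate = config$sub_rate,
                                         prefix = sprintf("c%03dp", i), circular = TRUE)
      se_reads[[i]] <- simulate_se_reads(circles[[i]], coverage = config$se_coverage * skew[i],
                                         len_mean = config$se_len_mean,
                                         len_sd = config$se_len_sd,
                                         sub_rate = config$sub_rate,
                                         indel_rate = config$se_indel_rate,
                                         prefix = sprintf("c%03ds", i), circular = TRUE)
    }
    neg <- make_negative_controls(config$n_linear, config$n_repeat_confounded,
                                  repeat_len = config$repeat_len,
                                  length_range = config$length_range, gc = config$gc,
                                  pe_read_len = config$pe_read_len)
    for (j in seq_len(nrow(neg$contigs))) {
      s <- neg$contigs$seq[j]
      if (str_length(s) > max(config$insert_range)) {
        pe_reads[[length(pe_reads) + 1L]] <-
          simulate_pe_reads(s, coverage = config$pe_coverage,
                            pe_read_len = config$pe_read_len,
                            insert_range = config$insert_range,
                            sub_rate = config$sub_rate,
                            prefix = sprintf("n%03dp", j), circular = FALSE)
      }
      se_reads[[length(se_reads) + 1L]] <-
        simulate_se_reads(s, coverage = config$se_coverage,
                          len_mean = config$se_len_mean, len_sd = config$se_len_sd,
                          sub_rate = config$sub_rate, indel_rate = config$se_indel_rate,
                          prefix = sprintf("n%03ds", j), circular = FALSE)
    }
    pe_ct <- bind_rows(bind_rows(pe_contigs), neg$contigs)
    pe_ct$platform <- "paired_end"
    se_ct <- bind_rows(bind_rows(se_contigs), neg$contigs)
    se_ct$platform <- "single_end"
    neg_truth_pe <- neg$truth
    neg_truth_se <- neg$truth
    list(
      circles = circles,
      contigs = pe_ct,
      se_contigs = se_ct,
      pe_reads = bind_rows(pe_reads),
      se_reads = bind_rows(se_reads),
      truth = bind_rows(bind_rows(truth), neg$truth)
    )
  })
}
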